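test_that("cubic B-spline basis is a partition of unity", {
  u <- seq(0, 1, length.out = 1001)
  expect_lt(max(abs(rowSums(bspline_basis(u)) - 1)), 1e-12)
  expect_true(all(bspline_basis(u) >= 0))
})

test_that("FFD displacement evaluation follows the tensor-product rule", {
  dm <- c(40, 40)
  z <- bspline_ffd(spacing = 8, dim = dm)
  pts <- cbind(runif(30, 0, 39), runif(30, 0, 39))
  expect_equal(bspline_displacement(z, pts[, 1], pts[, 2]),
               cbind(out_x = rep(0, 30), out_y = rep(0, 30)),
               ignore_attr = TRUE)

  # constant control displacements reproduce the constant (unity partition)
  g <- dim(z$control_x)
  cst <- bspline_ffd(matrix(2.5, g[1], g[2]), matrix(-1.25, g[1], g[2]),
                     spacing = 8, dim = dm)
  d <- bspline_displacement(cst, pts[, 1], pts[, 2])
  expect_lt(max(abs(d[, 1] - 2.5)), 1e-12)
  expect_lt(max(abs(d[, 2] + 1.25)), 1e-12)

  # single displaced control point evaluated at a grid node where it takes
  # basis role l = m = 1: weight B1(0)^2 = (4/6)^2
  one <- bspline_ffd(spacing = 8, dim = dm)
  one$control_x[2 + 2, 2 + 2] <- 1   # model index (2,2)
  expect_equal(as.vector(bspline_displacement(one, 16, 16)),
               c((4 / 6)^2, 0), tolerance = 1e-12)

  expect_error(bspline_displacement(z, -1, 5), "outside")
  expect_error(bspline_displacement(z, 5, 41), "outside")
})

test_that("warping is exact for identity and integer shifts, linear for ramps", {
  img <- matrix(runif(50 * 40), 50, 40)
  idt <- composite_transform(affine_transform(), dim = dim(img))
  expect_identical(apply_transform(idt, img), img)

  sh <- composite_transform(affine_transform(t = c(3, 0)), dim = dim(img))
  w <- apply_transform(sh, img)
  expect_identical(w[, 1:37], img[, 4:40])
  expect_true(all(w[, 38:40] == 0))

  # half-pixel shift of a linear ramp: interior equals the shifted ramp
  ramp <- matrix(rep(0:39, each = 50), 50, 40)
  hw <- apply_transform(composite_transform(
    affine_transform(t = c(0.5, 0)), dim = dim(ramp)), ramp)
  expect_lt(max(abs(hw[, 1:39] - (matrix(rep(0:38, each = 50), 50, 39)
                                  + 0.5))), 1e-9)
})

test_that("affine registration recovers identity, translations and scalings", {
  co <- fix_silence_cohort()
  base <- co$silence$sp1$M
  dm <- dim(base)

  idt <- register_affine(base, base)
  expect_lt(mean_epe_affine(idt, affine_transform(), dm), 0.1)

  G <- centered_scale_affine(1, dm, shift = c(5, -3))
  mov <- apply_transform(composite_transform(G, dim = dm), base)
  rec <- register_affine(mov, base)
  expect_lt(mean_epe_affine(rec, affine_invert(G), dm), 0.5)

  Gs <- centered_scale_affine(1.1, dm)
  movs <- apply_transform(composite_transform(Gs, dim = dm), base)
  recs <- register_affine(movs, base)
  expect_lt(abs(recs$A[1, 1] - 1 / 1.1), 0.02 / 1.1)
  expect_lt(abs(recs$A[2, 2] - 1 / 1.1), 0.02 / 1.1)
})

test_that("B-spline registration recovers known smooth deformations", {
  co <- fix_silence_cohort()
  base <- co$silence$sp2$M
  dm <- dim(base)

  same <- register_bspline(base, base, spacing = 12)
  expect_lt(max(abs(c(same$local$control_x, same$local$control_y))), 0.5)

  set.seed(31)
  ffd <- bspline_ffd(spacing = 12, dim = dm)
  g <- dim(ffd$control_x)
  ffd$control_x[] <- rnorm(prod(g), 0, 1.2)
  ffd$control_y[] <- rnorm(prod(g), 0, 1.2)
  G <- composite_transform(affine_transform(), ffd)
  mov <- apply_transform(G, base)
  rec <- register_bspline(mov, base, spacing = 12)
  inv <- invert_transform_map(G)
  mp <- vtatlas:::transform_map(rec)
  epe <- mean(sqrt((mp$x - inv$x)^2 + (mp$y - inv$y)^2))
  expect_lt(epe, 1)
  # registration must improve on the affine-only stage
  expect_lte(attr(rec, "value"), attr(rec, "affine_value"))
})

test_that("pure translations are recovered in the interior of a checkerboard", {
  cells <- matrix(rep(rep(c(0.2, 0.8), each = 8), 3), 48, 48)
  board <- cells * t(cells) + 0.1
  # mov(x) = board(x + 2): the backward map recovering board from mov is
  # the 2 px displacement x -> x - 2, despite the board's 16 px period
  G <- affine_transform(t = c(2, 0))
  mov <- apply_transform(composite_transform(G, dim = dim(board)), board)
  rec <- register_bspline(mov, board, spacing = 12)
  mp <- vtatlas:::transform_map(rec)
  dx <- matrix(mp$x, 48, 48) - matrix(rep(0:47, each = 48), 48, 48)
  dy <- matrix(mp$y, 48, 48) - matrix(rep(0:47, times = 48), 48, 48)
  interior <- 13:36
  expect_lt(max(abs(dx[interior, interior] + 2)), 0.35)
  expect_lt(max(abs(dy[interior, interior])), 0.35)
})

test_that("transform averaging is linear, permutation-invariant and idempotent", {
  dm <- c(32, 32)
  mk <- function(tx, ty, fx = 0) {
    ffd <- bspline_ffd(spacing = 8, dim = dm)
    ffd$control_x[] <- fx
    composite_transform(affine_transform(t = c(tx, ty)), ffd)
  }
  one <- average_transforms(list(mk(2, 0)))
  expect_equal(one$global$t, c(2, 0))

  two <- average_transforms(list(mk(2, 0), mk(0, 0)))
  expect_equal(two$global$t, c(1, 0))

  pm <- average_transforms(list(mk(1, 2, fx = 3), mk(4, -2, fx = -1),
                                mk(0, 0, fx = 2)))
  pm2 <- average_transforms(list(mk(0, 0, fx = 2), mk(1, 2, fx = 3),
                                 mk(4, -2, fx = -1)))
  expect_equal(pm$global$t, pm2$global$t)
  expect_equal(pm$local$control_x, pm2$local$control_x)

  same <- average_transforms(list(mk(3, 1, fx = 5), mk(3, 1, fx = 5)))
  expect_equal(same$local$control_x, mk(3, 1, fx = 5)$local$control_x)

  # opposite fields cancel
  fa <- mk(0, 0, fx = 2); fb <- mk(0, 0, fx = -2)
  expect_equal(max(abs(average_transforms(list(fa, fb))$local$control_x)), 0)

  ffd_other <- bspline_ffd(spacing = 16, dim = dm)
  other <- composite_transform(affine_transform(), ffd_other)
  expect_error(average_transforms(list(mk(0, 0), other)), "mismatch")
})

test_that("composite transforms serialize to JSON and back", {
  dm <- c(24, 20)
  ffd <- bspline_ffd(spacing = 6, dim = dm)
  ffd$control_x[] <- rnorm(length(ffd$control_x))
  tr <- composite_transform(affine_transform(matrix(c(1.05, 0.02, -0.01,
                                                      0.97), 2, 2),
                                             c(1.5, -2.25)), ffd)
  p <- withr::local_tempfile(fileext = ".json")
  write_transform(tr, p)
  rt <- read_transform(p)
  expect_equal(rt$global$A, tr$global$A)
  expect_equal(rt$global$t, tr$global$t)
  expect_equal(rt$local$control_x, tr$local$control_x)
  expect_equal(rt$local$spacing, tr$local$spacing)
  expect_identical(rt$dim, tr$dim)
})
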