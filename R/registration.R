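#' Cubic B-spline basis functions
#'
#' Evaluates the four cubic B-spline blending polynomials at fractional
#' offsets `u` in `[0, 1)`:
#' `B0 = (1-u)^3/6`, `B1 = (3u^3-6u^2+4)/6`, `B2 = (-3u^3+3u^2+3u+1)/6`,
#' `B3 = u^3/6`.  They form a partition of unity.
#'
#' @param u Numeric vector in `[0, 1]`.
#' @return `length(u) x 4` matrix of basis values.
#' @export
bspline_basis <- function(u) {
  cbind((1 - u)^3 / 6,
        (3 * u^3 - 6 * u^2 + 4) / 6,
        (-3 * u^3 + 3 * u^2 + 3 * u + 1) / 6,
        u^3 / 6)
}

#' 2D affine transform
#'
#' Maps 0-based pixel coordinates `p = (x, y)` to `A %*% p + t` (backward
#' mapping convention: the transform sends output coordinates into the
#' moving image).
#'
#' @param A 2x2 linear part, `|det| > 1e-8`.
#' @param t Length-2 translation in pixels.
#' @return Object of class `vt_affine`.
#' @export
affine_transform <- function(A = diag(2), t = c(0, 0)) {
  A <- matrix(as.numeric(A), 2, 2)
  t <- as.numeric(t)
  stopifnot(length(t) == 2L, all(is.finite(A)), all(is.finite(t)))
  if (abs(det(A)) <= 1e-8) stop("affine linear part is singular")
  structure(list(A = A, t = t), class = "vt_affine")
}

affine_points <- function(af, x, y) {
  list(x = af$A[1, 1] * x + af$A[1, 2] * y + af$t[1],
       y = af$A[2, 1] * x + af$A[2, 2] * y + af$t[2])
}

#' Invert an affine transform
#' @param af A `vt_affine`.
#' @return The inverse `vt_affine`.
#' @export
affine_invert <- function(af) {
  Ai <- solve(af$A)
  affine_transform(Ai, -Ai %*% af$t)
}

# grid geometry for an image of size dim = c(M rows, W cols):
# control index i = floor(x/dx) - 1 ranges over -1 .. nx-1, and the 4-point
# support touches -1 .. nx+2, so the stored grid has nx+4 columns in x
# (model index i maps to storage index i + 3).
ffd_grid_dims <- function(dim, spacing) {
  nx <- floor((dim[2] - 1) / spacing[1])
  ny <- floor((dim[1] - 1) / spacing[2])
  c(gx = nx + 4L, gy = ny + 4L)
}

#' B-spline free-form deformation
#'
#' A displacement field parameterized by 2-vector displacements on a
#' control-point grid with spacing `spacing = c(dx, dy)` pixels, evaluated
#' with the cubic tensor-product basis.  The grid is padded by one control
#' point beyond each border so every image pixel has a full 4x4 support.
#'
#' @param control_x,control_y `gx x gy` matrices of control displacements
#'   (pixels); `NULL` gives an all-zero field.
#' @param spacing Length-2 (or scalar) control spacing in pixels, > 0.
#' @param dim Image dimensions `c(rows, cols)` the field is defined on.
#' @return Object of class `vt_ffd`.
#' @export
bspline_ffd <- function(control_x = NULL, control_y = NULL,
                        spacing = 16, dim) {
  if (length(spacing) == 1L) spacing <- c(spacing, spacing)
  stopifnot(all(spacing > 0), length(dim) == 2L)
  g <- ffd_grid_dims(dim, spacing)
  if (is.null(control_x)) control_x <- matrix(0, g["gx"], g["gy"])
  if (is.null(control_y)) control_y <- matrix(0, g["gx"], g["gy"])
  stopifnot(identical(dim(control_x), as.integer(unname(g))),
            identical(dim(control_y), as.integer(unname(g))))
  structure(list(control_x = control_x, control_y = control_y,
                 spacing = as.numeric(spacing), dim = as.integer(dim)),
            class = "vt_ffd")
}

#' Evaluate a B-spline FFD displacement
#'
#' Returns the displacement
#' `sum_{l,m} B_l(u) B_m(v) phi_{i+l, j+m}` with `i = floor(x/dx) - 1`,
#' `u = x/dx - floor(x/dx)` (and likewise for `j`, `v`).
#'
#' @param ffd A `vt_ffd`.
#' @param x,y 0-based pixel coordinates (vectors), inside the image domain.
#' @return `length(x) x 2` matrix of `(dx, dy)` displacements in pixels.
#' @export
bspline_displacement <- function(ffd, x, y) {
  stopifnot(inherits(ffd, "vt_ffd"), length(x) == length(y))
  if (any(x < 0 | x > ffd$dim[2] - 1 | y < 0 | y > ffd$dim[1] - 1))
    stop("point outside the padded FFD support")
  dx <- ffd$spacing[1]; dy <- ffd$spacing[2]
  i <- floor(x / dx) - 1; u <- x / dx - floor(x / dx)
  j <- floor(y / dy) - 1; v <- y / dy - floor(y / dy)
  Bu <- bspline_basis(u); Bv <- bspline_basis(v)
  gx <- nrow(ffd$control_x)
  out_x <- numeric(length(x)); out_y <- numeric(length(x))
  for (l in 0:3) for (m in 0:3) {
    # model index i+l in -1..nx+2 maps to storage row i+l+2
    lin <- (j + m + 1) * gx + (i + l + 2)   # 1-based linear storage index
    w <- Bu[, l + 1] * Bv[, m + 1]
    out_x <- out_x + w * ffd$control_x[lin]
    out_y <- out_y + w * ffd$control_y[lin]
  }
  cbind(out_x, out_y)
}

# Sparse pixel-grid basis matrix B (npix x ncontrol) so that the field over
# the whole image is B %*% phi.  Cached per (dim, spacing).
ffd_basis_matrix <- function(dim, spacing) {
  key <- paste0("B_", dim[1], "x", dim[2], "_", spacing[1], "_", spacing[2])
  if (!is.null(.vt_cache[[key]])) return(.vt_cache[[key]])
  M <- dim[1]; W <- dim[2]
  x <- rep(0:(W - 1), each = M)    # column-major pixel order
  y <- rep(0:(M - 1), times = W)
  dx <- spacing[1]; dy <- spacing[2]
  i <- floor(x / dx) - 1; u <- x / dx - floor(x / dx)
  j <- floor(y / dy) - 1; v <- y / dy - floor(y / dy)
  Bu <- bspline_basis(u); Bv <- bspline_basis(v)
  g <- ffd_grid_dims(dim, spacing)
  gx <- g["gx"]
  rows <- integer(0); cols <- integer(0); vals <- numeric(0)
  pix <- seq_along(x)
  for (l in 0:3) for (m in 0:3) {
    rows <- c(rows, pix)
    cols <- c(cols, (j + m + 1) * gx + (i + l + 2))
    vals <- c(vals, Bu[, l + 1] * Bv[, m + 1])
  }
  B <- Matrix::sparseMatrix(i = rows, j = cols, x = vals,
                            dims = c(length(x), g["gx"] * g["gy"]))
  .vt_cache[[key]] <- B
  B
}

#' Composite transform: affine plus B-spline FFD
#'
#' The total mapping is the sum of the global affine map and the local FFD
#' displacement: `T(x, y) = T_global(x, y) + T_local(x, y)`.
#'
#' @param global A `vt_affine`.
#' @param local A `vt_ffd` (defaults to a zero field on `dim`).
#' @param dim Image dimensions `c(rows, cols)`; taken from `local` if absent.
#' @return Object of class `vt_transform`.
#' @export
composite_transform <- function(global = affine_transform(), local = NULL,
                                dim = NULL) {
  if (is.null(local)) {
    stopifnot(!is.null(dim))
    local <- bspline_ffd(spacing = 16, dim = dim)
  }
  if (is.null(dim)) dim <- local$dim
  stopifnot(identical(as.integer(dim), local$dim))
  structure(list(global = global, local = local, dim = as.integer(dim)),
            class = "vt_transform")
}

# dense backward map of a composite transform over the pixel grid
transform_map <- function(tr) {
  M <- tr$dim[1]; W <- tr$dim[2]
  x <- rep(0:(W - 1), each = M)
  y <- rep(0:(M - 1), times = W)
  p <- affine_points(tr$global, x, y)
  B <- ffd_basis_matrix(tr$dim, tr$local$spacing)
  mx <- p$x + as.vector(B %*% as.vector(tr$local$control_x))
  my <- p$y + as.vector(B %*% as.vector(tr$local$control_y))
  list(x = mx, y = my)
}

# Bilinear sampling at 0-based coordinates; out-of-bounds -> fill.
# Thin wrapper over the compiled kernel (the innermost loop of every
# warp and every optimizer iteration).
bilinear_sample <- function(img, x, y, fill = 0) {
  .bilinear_sample_cpp(img, as.numeric(x), as.numeric(y), fill)
}

#' Apply a transform to an image
#'
#' Backward-mapping resampling: `out(x, y) = in(T(x, y))` with bilinear
#' interpolation and zero fill outside the moving image.  Integer shifts are
#' resampled exactly.
#'
#' @param tr A `vt_transform` (or `vt_affine`, promoted with a zero FFD).
#' @param image Matrix or `vt_frame` with dimensions matching `tr$dim`.
#' @return Warped image, same type and shape as `image`.
#' @export
apply_transform <- function(tr, image) {
  px <- as_pixels(image)
  if (inherits(tr, "vt_affine"))
    tr <- composite_transform(tr, dim = dim(px))
  stopifnot(inherits(tr, "vt_transform"),
            identical(as.integer(dim(px)), tr$dim))
  mp <- transform_map(tr)
  out <- matrix(bilinear_sample(px, mp$x, mp$y), nrow(px), ncol(px))
  if (inherits(image, "vt_frame"))
    image_frame(pmax(out, 0), image$plane, image$frame_index)
  else out
}

## ---- registration ---------------------------------------------------------

# central-difference gradient images
grad_images <- function(img) {
  M <- nrow(img); W <- ncol(img)
  gx <- matrix(0, M, W); gy <- matrix(0, M, W)
  gx[, 2:(W - 1)] <- (img[, 3:W] - img[, 1:(W - 2)]) / 2
  gx[, 1] <- img[, 2] - img[, 1]; gx[, W] <- img[, W] - img[, W - 1]
  gy[2:(M - 1), ] <- (img[3:M, ] - img[1:(M - 2), ]) / 2
  gy[1, ] <- img[2, ] - img[1, ]; gy[M, ] <- img[M, ] - img[M - 1, ]
  list(gx = gx, gy = gy)
}

# 2x2 block-mean downsampling (odd trailing row/col dropped)
downsample2 <- function(img) {
  M <- 2L * (nrow(img) %/% 2L); W <- 2L * (ncol(img) %/% 2L)
  img <- img[seq_len(M), seq_len(W)]
  (img[seq(1, M, 2), seq(1, W, 2)] + img[seq(2, M, 2), seq(1, W, 2)] +
   img[seq(1, M, 2), seq(2, W, 2)] + img[seq(2, M, 2), seq(2, W, 2)]) / 4
}

# centered params p = (a11, a21, a12, a22, tx, ty) about center c:
# X = c + A (x - c) + tc
centered_to_affine <- function(p, cc) {
  A <- matrix(p[1:4], 2, 2)
  t_abs <- p[5:6] + cc - as.vector(A %*% cc)
  affine_transform(A, t_abs)
}
affine_to_centered <- function(af, cc) {
  tc <- af$t - cc + as.vector(af$A %*% cc)
  c(af$A[1, 1], af$A[2, 1], af$A[1, 2], af$A[2, 2], tc)
}

affine_objective <- function(mov, fix, cc) {
  M <- nrow(fix); W <- ncol(fix); n <- length(fix)
  X <- rep(0:(W - 1), each = M) - cc[1]
  Y <- rep(0:(M - 1), times = W) - cc[2]
  g <- grad_images(mov)
  fixv <- as.vector(fix)
  last_p <- NULL; last <- NULL
  eval_point <- function(p) {          # shared by fn and gr at one iterate
    if (!identical(p, last_p)) {
      mx <- cc[1] + p[1] * X + p[3] * Y + p[5]
      my <- cc[2] + p[2] * X + p[4] * Y + p[6]
      last <<- list(mx = mx, my = my,
                    r = bilinear_sample(mov, mx, my) - fixv)
      last_p <<- p
    }
    last
  }
  fn <- function(p) { e <- eval_point(p); mean(e$r * e$r) }
  gr <- function(p) {
    e <- eval_point(p)
    gxs <- bilinear_sample(g$gx, e$mx, e$my)
    gys <- bilinear_sample(g$gy, e$mx, e$my)
    (2 / n) * c(sum(e$r * gxs * X), sum(e$r * gys * X),
                sum(e$r * gxs * Y), sum(e$r * gys * Y),
                sum(e$r * gxs), sum(e$r * gys))
  }
  list(fn = fn, gr = gr)
}

#' Affine registration
#'
#' Estimates the affine transform `T` maximizing similarity between
#' `moving(T(x))` and `fixed(x)` by multi-resolution (default 3 levels)
#' L-BFGS-B minimization of the mean squared intensity difference with
#' analytic gradients.  Inputs are expected to be histogram-matched (the
#' pipeline always matches before registering).  Fully deterministic.
#'
#' @param moving,fixed Same-shape matrices or `vt_frame`s.
#' @param levels Pyramid levels (coarsest has min dimension >= 16).
#' @param max_iter L-BFGS-B iteration cap per level.
#' @param init Optional initial `vt_affine` (warm start).
#' @return A `vt_affine` with attributes `value` (final mean squared
#'   difference) and `convergence` (from [stats::optim()]).
#' @export
register_affine <- function(moving, fixed, levels = 3L, max_iter = 60L,
                            init = NULL) {
  mov <- as_pixels(moving); fix <- as_pixels(fixed)
  stopifnot(identical(dim(mov), dim(fix)))
  pyr_m <- list(mov); pyr_f <- list(fix)
  while (length(pyr_m) < levels && min(dim(pyr_m[[length(pyr_m)]])) >= 32) {
    pyr_m[[length(pyr_m) + 1L]] <- downsample2(pyr_m[[length(pyr_m)]])
    pyr_f[[length(pyr_f) + 1L]] <- downsample2(pyr_f[[length(pyr_f)]])
  }
  nl <- length(pyr_m)
  p <- c(1, 0, 0, 1, 0, 0)
  if (!is.null(init)) {
    cc_full <- c((ncol(fix) - 1) / 2, (nrow(fix) - 1) / 2)
    p <- affine_to_centered(init, cc_full)
    p[5:6] <- p[5:6] / 2^(nl - 1)   # translation in coarsest-level pixels
  }
  res <- NULL
  for (lev in nl:1) {
    m <- pyr_m[[lev]]; f <- pyr_f[[lev]]
    cc <- c((ncol(f) - 1) / 2, (nrow(f) - 1) / 2)
    obj <- affine_objective(m, f, cc)
    res <- optim(p, obj$fn, obj$gr, method = "L-BFGS-B",
                 control = list(maxit = max_iter, factr = 1e7))
    p <- res$par
    if (lev > 1) p[5:6] <- p[5:6] * 2
  }
  cc <- c((ncol(fix) - 1) / 2, (nrow(fix) - 1) / 2)
  out <- centered_to_affine(res$par, cc)
  attr(out, "value") <- res$value
  attr(out, "convergence") <- res$convergence
  out
}

#' B-spline non-rigid registration
#'
#' Two-stage registration: an affine stage ([register_affine()]) followed by
#' refinement of a cubic B-spline FFD on a control grid with the given
#' spacing, minimizing mean squared intensity difference plus a small
#' membrane (first-difference) penalty on the control displacements, with
#' analytic gradients through the sparse pixel-basis matrix.
#'
#' @param moving,fixed Same-shape matrices or `vt_frame`s.
#' @param spacing Control-point spacing in pixels (>= 4; default 16).
#' @param max_iter L-BFGS-B iteration cap for the FFD stage.
#' @param lambda Membrane penalty weight (per squared pixel of control
#'   displacement difference).
#' @param affine_init Optional `vt_affine` used instead of running the
#'   affine stage.
#' @return A `vt_transform` with attributes `value` (final objective) and
#'   `affine_value` (objective after the affine stage alone).
#' @export
register_bspline <- function(moving, fixed, spacing = 16, max_iter = 60L,
                             lambda = 1e-4, affine_init = NULL) {
  mov <- as_pixels(moving); fix <- as_pixels(fixed)
  stopifnot(identical(dim(mov), dim(fix)), spacing >= 4)
  af <- if (is.null(affine_init)) register_affine(mov, fix) else affine_init
  dm <- dim(fix)
  sp <- if (length(spacing) == 1L) c(spacing, spacing) else spacing
  B <- ffd_basis_matrix(dm, sp)
  g <- ffd_grid_dims(dm, sp)
  ncp <- as.integer(g["gx"]) * as.integer(g["gy"])
  M <- dm[1]; W <- dm[2]; n <- length(fix)
  X <- rep(0:(W - 1), each = M); Y <- rep(0:(M - 1), times = W)
  p0 <- affine_points(af, X, Y)
  gi <- grad_images(mov)
  fixv <- as.vector(fix)
  gxn <- as.integer(g["gx"]); gyn <- as.integer(g["gy"])
  memb <- function(phi) {            # value and gradient of membrane term
    m <- matrix(phi, gxn, gyn)
    d1 <- m[-1, , drop = FALSE] - m[-gxn, , drop = FALSE]
    d2 <- m[, -1, drop = FALSE] - m[, -gyn, drop = FALSE]
    gr <- matrix(0, gxn, gyn)
    gr[-1, ] <- gr[-1, ] + 2 * d1; gr[-gxn, ] <- gr[-gxn, ] - 2 * d1
    gr[, -1] <- gr[, -1] + 2 * d2; gr[, -gyn] <- gr[, -gyn] - 2 * d2
    list(v = sum(d1^2) + sum(d2^2), g = as.vector(gr))
  }
  last_p <- NULL; last <- NULL
  eval_point <- function(ph) {
    if (!identical(ph, last_p)) {
      mx <- p0$x + as.vector(B %*% ph[1:ncp])
      my <- p0$y + as.vector(B %*% ph[(ncp + 1):(2 * ncp)])
      last <<- list(mx = mx, my = my,
                    r = bilinear_sample(mov, mx, my) - fixv)
      last_p <<- ph
    }
    last
  }
  fn <- function(ph) {
    e <- eval_point(ph)
    mean(e$r * e$r) + lambda * (memb(ph[1:ncp])$v +
                                memb(ph[(ncp + 1):(2 * ncp)])$v) / ncp
  }
  gr <- function(ph) {
    e <- eval_point(ph)
    gxs <- bilinear_sample(gi$gx, e$mx, e$my)
    gys <- bilinear_sample(gi$gy, e$mx, e$my)
    mx_g <- memb(ph[1:ncp]); my_g <- memb(ph[(ncp + 1):(2 * ncp)])
    c((2 / n) * as.vector(Matrix::crossprod(B, e$r * gxs)) +
        lambda * mx_g$g / ncp,
      (2 / n) * as.vector(Matrix::crossprod(B, e$r * gys)) +
        lambda * my_g$g / ncp)
  }
  av <- fn(numeric(2 * ncp))
  res <- optim(numeric(2 * ncp), fn, gr, method = "L-BFGS-B",
               control = list(maxit = max_iter, factr = 1e7))
  ffd <- bspline_ffd(matrix(res$par[1:ncp], gxn, gyn),
                     matrix(res$par[(ncp + 1):(2 * ncp)], gxn, gyn),
                     spacing = sp, dim = dm)
  out <- composite_transform(af, ffd)
  attr(out, "value") <- res$value
  attr(out, "affine_value") <- av
  attr(out, "convergence") <- res$convergence
  out
}

#' Average composite transforms
#'
#' Unweighted parameter-wise arithmetic mean: affine entries and
#' control-point displacements are averaged component by component.  All
#' transforms must share one image domain, grid and spacing.
#'
#' @param transforms Non-empty list of `vt_transform`s (bare `vt_affine`s
#'   are promoted with zero FFDs).
#' @return A `vt_transform`.
#' @export
average_transforms <- function(transforms) {
  stopifnot(is.list(transforms), length(transforms) >= 1L)
  transforms <- lapply(transforms, function(tr) {
    if (inherits(tr, "vt_affine")) stop("promote vt_affine with composite_transform() first")
    stopifnot(inherits(tr, "vt_transform")); tr
  })
  t1 <- transforms[[1]]
  for (tr in transforms) {
    if (!identical(tr$dim, t1$dim) ||
        !identical(dim(tr$local$control_x), dim(t1$local$control_x)) ||
        !isTRUE(all.equal(tr$local$spacing, t1$local$spacing)))
      stop("transforms have mismatched domains or control grids")
  }
  nn <- length(transforms)
  A <- Reduce(`+`, lapply(transforms, function(tr) tr$global$A)) / nn
  tt <- Reduce(`+`, lapply(transforms, function(tr) tr$global$t)) / nn
  cx <- Reduce(`+`, lapply(transforms, function(tr) tr$local$control_x)) / nn
  cy <- Reduce(`+`, lapply(transforms, function(tr) tr$local$control_y)) / nn
  composite_transform(affine_transform(A, tt),
                      bspline_ffd(cx, cy, t1$local$spacing, t1$dim))
}

#' Serialize / deserialize a composite transform as JSON
#'
#' Stores the six affine parameters, image dimensions, control-grid shape,
#' spacing and control displacements, so pairwise transforms can be cached
#' between pipeline runs.
#'
#' @param tr A `vt_transform`.
#' @param path JSON path.
#' @return `read_transform` returns the `vt_transform`.
#' @export
write_transform <- function(tr, path) {
  stopifnot(inherits(tr, "vt_transform"))
  obj <- list(affine = c(tr$global$A, tr$global$t),
              dim = tr$dim, spacing = tr$local$spacing,
              grid = dim(tr$local$control_x),
              control_x = as.vector(tr$local$control_x),
              control_y = as.vector(tr$local$control_y))
  jsonlite::write_json(obj, path, digits = NA)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  af <- affine_transform(matrix(obj$affine[1:4], 2, 2), obj$affine[5:6])
  ffd <- bspline_ffd(matrix(obj$control_x, obj$grid[1], obj$grid[2]),
                     matrix(obj$control_y, obj$grid[1], obj$grid[2]),
                     spacing = obj$spacing, dim = obj$dim)
  composite_transform(af, ffd)
}

# dense displacement field (pixels) of a composite transform relative to
# identity; used for endpoint-error diagnostics against known ground truth
transform_displacement <- function(tr) {
  mp <- transform_map(tr)
  M <- tr$dim[1]; W <- tr$dim[2]
  list(dx = mp$x - rep(0:(W - 1), each = M),
       dy = mp$y - rep(0:(M - 1), times = W))
}

#' Mean endpoint error between two transforms
#'
#' Mean Euclidean distance, over all pixels of the domain, between the
#' backward maps of two transforms.  The standard registration-recovery
#' diagnostic when ground truth is known.
#'
#' @param tr_a,tr_b `vt_transform`s on the same domain.
#' @return Mean endpoint error in pixels.
#' @export
mean_endpoint_error <- function(tr_a, tr_b) {
  stopifnot(identical(tr_a$dim, tr_b$dim))
  ma <- transform_map(tr_a); mb <- transform_map(tr_b)
  mean(sqrt((ma$x - mb$x)^2 + (ma$y - mb$y)^2))
}

#' Numerically invert a composite transform
#'
#' Fixed-point iteration on `z <- x - d(z)` where `d` is the total
#' displacement field; adequate for the moderate, smooth deformations used
#' here.  Returns the inverse backward map sampled on the pixel grid (a
#' function-free representation: matrices of map coordinates).
#'
#' @param tr A `vt_transform`.
#' @param iters Fixed-point iterations (default 20).
#' @return List with vectors `x`, `y` of the inverse map over the pixel
#'   grid in column-major order.
#' @export
invert_transform_map <- function(tr, iters = 20L) {
  M <- tr$dim[1]; W <- tr$dim[2]
  X <- rep(0:(W - 1), each = M); Y <- rep(0:(M - 1), times = W)
  dsp <- transform_displacement(tr)
  dxm <- matrix(dsp$dx, M, W); dym <- matrix(dsp$dy, M, W)
  zx <- X; zy <- Y
  for (it in seq_len(iters)) {
    ex <- bilinear_sample(dxm, zx, zy)
    ey <- bilinear_sample(dym, zx, zy)
    zx <- X - ex
    zy <- Y - ey
  }
  list(x = zx, y = zy)
}
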