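test_that("adaptive kernel weights follow the stated sigma rule", {
  cfg <- kernel_config(k = 3)

  # degenerate: all selected samples at tau -> uniform
  kw0 <- adaptive_kernel_weights(c(0.01, 0.01, 0.01), 0.01, cfg)
  expect_equal(kw0$weights, rep(1 / 3, 3))

  # symmetric pair about tau
  kwp <- adaptive_kernel_weights(c(0.006, 0.014), 0.010,
                                 kernel_config(k = 2))
  expect_equal(kwp$weights, c(0.5, 0.5))

  # samples at 4, 8, 12 ms, tau = 9 ms, k = 3: direct evaluation of the
  # formulas gives sigma^2 = 25/(2 ln(1/0.35)) ms^2 and normalized weights
  # 0.35^(25/25), 0.35^(1/25), 0.35^(9/25) over their sum
  kw <- adaptive_kernel_weights(c(0.004, 0.008, 0.012), 0.009, cfg)
  raw_expected <- 0.35^(c(25, 1, 9) / 25)
  w_expected <- raw_expected / sum(raw_expected)
  ord <- order(kw$indices)
  expect_equal(kw$weights[ord], w_expected, tolerance = 1e-12)
  expect_equal(kw$tau_f, 0.004)
  expect_equal(round(kw$weights[ord], 3), c(0.176, 0.481, 0.344))

  expect_error(adaptive_kernel_weights(numeric(0), 0, cfg), "empty")
  expect_error(kernel_config(k = 0), "k >= 1")
  expect_error(kernel_config(weight_floor = 1), "weight_floor")
})

test_that("the raw-weight floor is exact and k samples are always selected", {
  set.seed(91)
  for (i in 1:25) {
    n <- sample(3:40, 1)
    times <- sort(runif(n, 0, 0.3))
    tau <- runif(1, 0, 0.3)
    cfg <- kernel_config(k = sample(1:9, 1), window = 1)  # wide: no warning
    kw <- adaptive_kernel_weights(times, tau, cfg)
    expect_length(kw$indices, min(cfg$k, n))
    expect_equal(sum(kw$weights), 1, tolerance = 1e-12)
    if (abs(kw$tau_f - tau) > 0) {
      # raw weight at the farthest sample is exactly 0.35 of the peak (1)
      expect_equal(min(kw$raw) / 1, 0.35, tolerance = 1e-12)
      expect_equal(kw$raw[length(kw$raw)], 0.35, tolerance = 1e-12)
    }
  }
  # the k-th neighbor beyond the window triggers a warning
  expect_warning(
    adaptive_kernel_weights(c(0, 0.1), 0, kernel_config(k = 2)),
    "window")
})

test_that("frame synthesis is a convex, histogram-matched combination", {
  img <- matrix(runif(16 * 16), 16, 16)
  mk <- function(t, im, sp = "sp1", f = 0L)
    list(image = im, time = t, speaker_id = sp,
         source_frame_index = as.integer(f))

  # identical contributors reproduce the image exactly
  gs_same <- structure(list(cv_label = "tu", plane = "M",
                            samples = list(mk(0, img), mk(0.01, img),
                                           mk(0.02, img))),
                       class = "vt_global_series")
  fr <- synthesize_frame(gs_same, 0.01, kernel_config(k = 3))
  expect_lt(max(abs(fr$image - img)), 1e-9)
  expect_equal(sum(fr$contributors$weight), 1, tolerance = 1e-12)

  # two equally weighted contributors with one histogram -> plain mean
  perm <- matrix(sample(as.vector(img)), 16, 16)
  gs_two <- structure(list(cv_label = "tu", plane = "M",
                           samples = list(mk(0.008, img),
                                          mk(0.012, perm, "sp2"))),
                      class = "vt_global_series")
  fr2 <- synthesize_frame(gs_two, 0.010, kernel_config(k = 2))
  expect_lt(max(abs(fr2$image - (img + perm) / 2)), 1e-9)

  # convexity: synthesized values within the contributors' range
  set.seed(12)
  imgs <- replicate(5, matrix(runif(64, 0, 3), 8, 8), simplify = FALSE)
  gs5 <- structure(list(cv_label = "tu", plane = "M",
                        samples = Map(mk, as.list((0:4) / 100), imgs)),
                   class = "vt_global_series")
  fr5 <- synthesize_frame(gs5, 0.02, kernel_config(k = 5))
  lo <- min(vapply(imgs, min, numeric(1)))
  hi <- max(vapply(imgs, max, numeric(1)))
  expect_true(all(fr5$image >= lo - 1e-9 & fr5$image <= hi + 1e-9))

  # a linear-in-time probe pixel: explicit-sum oracle over the selection,
  # sigma and matching rules
  probe_oracle <- function(samples, tau, k) {
    times <- vapply(samples, `[[`, numeric(1), "time")
    ord <- order(abs(times - tau), times)
    sel <- ord[seq_len(k)]
    tau_f <- times[sel[k]]
    raw <- if (tau_f == tau) rep(1, k) else {
      s2 <- -(tau - tau_f)^2 / (2 * log(0.35))
      exp(-(times[sel] - tau)^2 / (2 * s2))
    }
    w <- raw / sum(raw)
    imgs <- lapply(samples[sel], `[[`, "image")
    lims <- range(unlist(lapply(imgs, range)))
    rh <- compute_histogram(imgs[[1]], 256, lims)
    matched <- lapply(imgs, match_histogram, reference = rh)
    Reduce(`+`, Map(`*`, matched, w))
  }
  base <- matrix(runif(64, 0, 1), 8, 8)
  ramp_imgs <- lapply(0:5, function(i) base + i * 0.1)
  gsr <- structure(list(cv_label = "tu", plane = "M",
                        samples = Map(mk, as.list((0:5) / 50), ramp_imgs)),
                   class = "vt_global_series")
  fr_r <- suppressWarnings(synthesize_frame(gsr, 0.045,
                                            kernel_config(k = 4)))
  expect_equal(fr_r$image, probe_oracle(gsr$samples, 0.045, 4),
               tolerance = 1e-12)
})

test_that("atlas grids and contributor counts follow the configuration", {
  co <- fix_identical_cohort()
  gs <- raw_global_series(co)

  # default grid: 20 ms steps over a 240 ms reference duration -> 13 frames
  atlas <- suppressWarnings(build_atlas(gs, config = kernel_config(),
                                        ref_duration = 0.240))
  expect_length(atlas$tau, 13L)
  expect_length(atlas$planes$M, 13L)
  for (fr in atlas$planes$M)
    expect_equal(nrow(fr$contributors), 7L)

  # identical speakers: atlas frames equal the common gesture frames
  sp1 <- co$series$sp1$tu$M
  dur <- compute_reference_durations(co$annotations)
  ann <- co$annotations[co$annotations$speaker == "sp1", ]
  ts <- piecewise_align(sp1, segment_annotation(ann$c_onset, ann$v_onset,
                                                ann$v_offset), dur)
  own_times <- vapply(ts, `[[`, numeric(1), "time")
  atl2 <- suppressWarnings(build_atlas(gs, tau_grid = own_times,
                                       config = kernel_config()))
  for (i in seq_along(own_times))
    expect_lt(mean(abs(atl2$planes$M[[i]]$image - ts[[i]]$image)), 0.01)

  # k = 1 reproduces the nearest sample exactly
  atl1 <- build_atlas(gs, tau_grid = own_times[2],
                      config = kernel_config(k = 1))
  expect_lt(max(abs(atl1$planes$M[[1]]$image - ts[[2]]$image)), 1e-9)

  # synthesis is invariant to the sample order in the series
  shuf <- gs
  set.seed(4)
  shuf$samples <- sample(gs$samples)
  f_a <- suppressWarnings(synthesize_frame(gs, 0.05))
  f_b <- suppressWarnings(synthesize_frame(shuf, 0.05))
  expect_identical(f_a$image, f_b$image)
})

test_that("atlases serialize with provenance", {
  co <- fix_identical_cohort()
  gs <- raw_global_series(co)
  atlas <- suppressWarnings(build_atlas(gs, tau_grid = c(0, 0.05, 0.1)))
  dir <- withr::local_tempdir()
  write_atlas(atlas, dir)
  expect_true(file.exists(file.path(dir, "atlas_tu_M.nii.gz")))
  prov <- jsonlite::read_json(file.path(dir, "atlas_tu_provenance.json"),
                              simplifyVector = TRUE)
  expect_equal(prov$config$k, 7)
  expect_equal(length(prov$tau), 3)
  arr <- as.array(RNifti::readNifti(file.path(dir, "atlas_tu_M.nii.gz")))
  expect_equal(dim(arr)[3], 3L)
  expect_equal(arr[, , 2], atlas$planes$M[[2]]$image, tolerance = 1e-12)
})
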