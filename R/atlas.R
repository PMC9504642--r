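#' Adaptive Gaussian kernel configuration
#'
#' `k` samples contribute to every synthesized frame; the Gaussian is
#' centered at the synthesis time `tau` and its width rescaled per frame so
#' that the raw weight of the farthest selected sample `tau_f` is
#' `weight_floor` (0.35) of the peak: `sigma^2 = -(tau - tau_f)^2 /
#' (2 ln weight_floor)`.  `window` (seconds) is the recording period used as
#' the default atlas sampling step and as a sanity bound on neighbor
#' distance.
#'
#' @param k Samples per synthesized frame (default 7).
#' @param window Seconds (default 0.020, one frame period at 50 frames/s).
#' @param weight_floor Raw-weight ratio at the farthest sample (0.35).
#' @return Object of class `vt_kernel_config`.
#' @export
kernel_config <- function(k = 7L, window = 0.020, weight_floor = 0.35) {
  k <- as.integer(k)
  stopifnot(k >= 1L, window > 0, weight_floor > 0, weight_floor < 1)
  structure(list(k = k, window = window, weight_floor = weight_floor),
            class = "vt_kernel_config")
}

#' Adaptive Gaussian kernel weights
#'
#' Selects the `k` samples nearest in time to `tau` (ties broken toward the
#' earlier time, then the smaller speaker id) and computes Gaussian weights
#' with mean `tau` and variance set from the farthest selected sample so its
#' raw weight is exactly `weight_floor` of the peak.  If the farthest
#' selected sample coincides with `tau` the weights degenerate to uniform.
#'
#' @param sample_times Numeric vector of sample times (seconds), >= 1.
#' @param tau Synthesis time (seconds).
#' @param config A [kernel_config()].
#' @param speaker_ids Optional per-sample ids used in the tie-break.
#' @return List: `indices` (into `sample_times`, nearest first), `weights`
#'   (normalized, sum 1), `raw` (unnormalized; the peak of the Gaussian is
#'   1), `tau_f`, `sigma2`.
#' @export
adaptive_kernel_weights <- function(sample_times, tau,
                                    config = kernel_config(),
                                    speaker_ids = NULL) {
  n <- length(sample_times)
  if (n < 1L) stop("empty sample series")
  if (is.null(speaker_ids)) speaker_ids <- rep("", n)
  ord <- order(abs(sample_times - tau), sample_times, speaker_ids,
               seq_len(n))
  k <- min(config$k, n)
  sel <- ord[seq_len(k)]
  tau_f <- sample_times[sel[k]]
  dt_f <- abs(tau_f - tau)
  if (dt_f > config$window)
    warning(sprintf("farthest selected sample is %.1f ms from tau (window %.1f ms)",
                    1000 * dt_f, 1000 * config$window))
  if (dt_f == 0) {
    raw <- rep(1, k)
  } else {
    sigma2 <- -(tau - tau_f)^2 / (2 * log(config$weight_floor))
    raw <- exp(-(sample_times[sel] - tau)^2 / (2 * sigma2))
  }
  list(indices = sel, weights = raw / sum(raw), raw = raw,
       tau_f = tau_f, sigma2 = if (dt_f == 0) 0 else sigma2)
}

#' Synthesize one atlas frame
#'
#' The `k` nearest-in-time samples of the global series are histogram-
#' matched to the contributor nearest to `tau` and averaged pixel-wise with
#' the normalized adaptive Gaussian weights.
#'
#' @param gs A `vt_global_series`.
#' @param tau Synthesis time (seconds).
#' @param config A [kernel_config()].
#' @param n_bins Histogram bins for contributor matching.
#' @return Object of class `vt_atlas_frame`: `image`, `tau`, `contributors`
#'   (`data.frame(speaker, source_frame, time, weight)`).
#' @export
synthesize_frame <- function(gs, tau, config = kernel_config(),
                             n_bins = 256L) {
  stopifnot(inherits(gs, "vt_global_series"))
  if (!length(gs$samples)) stop("empty global series")
  times <- gs_times(gs)
  sp <- vapply(gs$samples, `[[`, character(1), "speaker_id")
  kw <- adaptive_kernel_weights(times, tau, config, speaker_ids = sp)
  imgs <- lapply(gs$samples[kw$indices], `[[`, "image")
  limits <- range(unlist(lapply(imgs, range)))
  ref_hist <- compute_histogram(imgs[[1]], n_bins = n_bins, limits = limits)
  matched <- lapply(imgs, match_histogram, reference = ref_hist)
  img <- Reduce(`+`, Map(`*`, matched, kw$weights))
  contributors <- data.frame(
    speaker = sp[kw$indices],
    source_frame = vapply(gs$samples[kw$indices], `[[`, integer(1),
                          "source_frame_index"),
    time = times[kw$indices],
    weight = kw$weights,
    stringsAsFactors = FALSE)
  structure(list(image = img, tau = tau, contributors = contributors),
            class = "vt_atlas_frame")
}

#' Build an atlas for one CV
#'
#' Synthesizes one frame per `(plane, tau)` from per-plane global series.
#' All planes share the same time grid; the default grid steps by
#' `config$window` (20 ms) from 0 to the reference CV duration, so the
#' atlas frame rate is independent of the acquisition frame rate and the
#' grid may be chosen freely.
#'
#' @param gs_by_plane Named list (plane -> `vt_global_series`), or a single
#'   `vt_global_series`.
#' @param tau_grid Time points in seconds; default
#'   `seq(0, ref_duration, by = config$window)`.
#' @param config A [kernel_config()].
#' @param ref_duration Reference CV duration in seconds (required when
#'   `tau_grid` is absent).
#' @return Object of class `vt_atlas`: `cv_label`, `tau`, `planes` (named
#'   list of lists of `vt_atlas_frame`), `config`.
#' @export
build_atlas <- function(gs_by_plane, tau_grid = NULL,
                        config = kernel_config(), ref_duration = NULL) {
  if (inherits(gs_by_plane, "vt_global_series"))
    gs_by_plane <- setNames(list(gs_by_plane), gs_by_plane$plane)
  stopifnot(is.list(gs_by_plane), length(gs_by_plane) >= 1L)
  if (is.null(tau_grid)) {
    if (is.null(ref_duration))
      stop("supply tau_grid or ref_duration")
    tau_grid <- seq(0, ref_duration, by = config$window)
  }
  tau_grid <- sort(tau_grid)
  planes <- lapply(gs_by_plane, function(gs) {
    lapply(tau_grid, function(tau) synthesize_frame(gs, tau, config))
  })
  structure(list(cv_label = gs_by_plane[[1]]$cv_label, tau = tau_grid,
                 planes = planes, config = config),
            class = "vt_atlas")
}

#' @export
print.vt_atlas <- function(x, ...) {
  cat(sprintf("<vt_atlas> /%s/: %d planes x %d frames (tau %.0f..%.0f ms, k=%d)\n",
              x$cv_label, length(x$planes), length(x$tau),
              1000 * min(x$tau), 1000 * max(x$tau), x$config$k))
  invisible(x)
}

#' Write an atlas to disk
#'
#' One NIfTI stack per plane (time axis = tau grid) plus a JSON provenance
#' file with the kernel configuration and the full contributor table.
#'
#' @param atlas A `vt_atlas`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_atlas <- function(atlas, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (pl in names(atlas$planes)) {
    frames <- lapply(atlas$planes[[pl]], `[[`, "image")
    arr <- array(0, dim = c(dim(frames[[1]]), length(frames)))
    for (i in seq_along(frames)) arr[, , i] <- frames[[i]]
    RNifti::writeNifti(RNifti::asNifti(arr, datatype = "double"),
                       file.path(dir, paste0("atlas_", atlas$cv_label, "_",
                                             pl, ".nii.gz")),
                       datatype = "double")
  }
  contrib <- do.call(rbind, lapply(names(atlas$planes), function(pl) {
    do.call(rbind, lapply(atlas$planes[[pl]], function(fr) {
      cbind(plane = pl, tau = fr$tau, fr$contributors)
    }))
  }))
  jsonlite::write_json(
    list(cv_label = atlas$cv_label, tau = atlas$tau,
         config = unclass(atlas$config), contributors = contrib),
    file.path(dir, paste0("atlas_", atlas$cv_label, "_provenance.json")),
    dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
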