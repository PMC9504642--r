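#' Anatomically normalize a dynamic series
#'
#' Each frame is histogram-matched to the reference-space histogram and then
#' registered to the reference image with an affine transform only (one
#' independent affine per frame, warm-started from the previous frame).
#' This removes the speaker's global anatomy while leaving articulator
#' configuration — the local shape — untouched.
#'
#' @param series A `vt_series`.
#' @param ref A `vt_reference` for the series' plane.
#' @param max_iter Iteration cap per frame for [register_affine()].
#' @return A `vt_series` of normalized frames with the per-frame
#'   `vt_affine`s in `attr(, "affines")`.
#' @export
normalize_series <- function(series, ref, max_iter = 60L) {
  stopifnot(inherits(series, "vt_series"), inherits(ref, "vt_reference"))
  if (!identical(series$plane, ref$plane))
    stop("series plane ", series$plane, " does not match reference plane ",
         ref$plane)
  out <- vector("list", length(series$frames))
  affines <- vector("list", length(series$frames))
  prev <- NULL
  for (i in seq_along(series$frames)) {
    m <- match_histogram(series$frames[[i]], ref$histogram)
    # consecutive frames differ little: after the first frame a single
    # fine-level refinement from the previous affine suffices
    af <- if (is.null(prev))
      register_affine(m, ref$reference, max_iter = max_iter)
    else
      register_affine(m, ref$reference, levels = 1L,
                      max_iter = max(20L, max_iter %/% 2L), init = prev)
    if (!is.finite(attr(af, "value")))
      stop("affine normalization failed at frame index ",
           series$frame_index[i])
    out[[i]] <- apply_transform(composite_transform(af, dim = dim(m)), m)
    affines[[i]] <- af
    prev <- af
  }
  res <- image_series(out, fps = series$fps, speaker_id = series$speaker_id,
                      cv_label = series$cv_label, plane = series$plane,
                      frame_index = series$frame_index)
  attr(res, "affines") <- affines
  res
}

#' Per-CV reference durations from annotations
#'
#' The arithmetic mean, across all annotated series (all speakers and
#' planes), of the consonant duration `v_onset - c_onset` and the vowel
#' duration `v_offset - v_onset`, in frames.
#'
#' @param annotations `data.frame` with columns `cv`, `c_onset`, `v_onset`,
#'   `v_offset` (rows per speaker/plane).
#' @param cvs CV labels that must be present (default: those in the data).
#' @return `data.frame(syllable, c_frames, v_frames, cv_frames)`.
#' @export
compute_reference_durations <- function(annotations, cvs = NULL) {
  stopifnot(all(c("cv", "c_onset", "v_onset", "v_offset") %in%
                  names(annotations)))
  if (is.null(cvs)) cvs <- unique(annotations$cv)
  missing <- setdiff(cvs, unique(annotations$cv))
  if (length(missing))
    stop("no annotations for CV(s): ", paste(missing, collapse = ", "))
  cd <- annotations$v_onset - annotations$c_onset
  vd <- annotations$v_offset - annotations$v_onset
  if (any(cd <= 0 | vd <= 0)) stop("non-positive segment duration")
  out <- data.frame(
    syllable = cvs,
    c_frames = vapply(cvs, function(s) mean(cd[annotations$cv == s]),
                      numeric(1)),
    v_frames = vapply(cvs, function(s) mean(vd[annotations$cv == s]),
                      numeric(1)),
    stringsAsFactors = FALSE)
  out$cv_frames <- out$c_frames + out$v_frames
  rownames(out) <- NULL
  out
}

duration_row <- function(ref_durations, cv) {
  r <- ref_durations[ref_durations$syllable == cv, , drop = FALSE]
  if (nrow(r) != 1L) stop("no reference duration for CV ", cv)
  r
}

#' Piecewise-linear temporal alignment of one CV series
#'
#' The consonant and vowel segments are independently, linearly stretched or
#' compressed onto the reference durations.  A frame at offset `f` within a
#' segment of `n` frames whose reference length is `r` frames is placed at
#' `segment_start + (f/n) * r / fps` seconds; the consonant maps onto
#' `[0, r_C/fps)` and the vowel continues from `r_C/fps`.  Frames are placed
#' on the global axis, not mapped frame-to-frame onto a reference series.
#'
#' @param series A `vt_series` (anatomically normalized in the pipeline).
#' @param ann A `vt_annotation` valid for `series`.
#' @param ref_durations `data.frame` as from [compute_reference_durations()]
#'   (or [cv_duration_reference()]).
#' @param fps Frame rate used for the frame-to-seconds conversion.
#' @return List of timed samples, each a list with `image`, `time`
#'   (seconds), `speaker_id`, `source_frame_index`.
#' @export
piecewise_align <- function(series, ann, ref_durations, fps = series$fps) {
  stopifnot(inherits(series, "vt_series"), inherits(ann, "vt_annotation"))
  if (ann$v_offset > length(series$frames))
    stop("annotation extends past the series")
  r <- duration_row(ref_durations, series$cv_label)
  n_c <- ann$v_onset - ann$c_onset
  n_v <- ann$v_offset - ann$v_onset
  if (n_c <= 0L || n_v <= 0L) stop("zero-length segment")
  samples <- vector("list", n_c + n_v)
  t_c <- r$c_frames / fps          # reference consonant duration, seconds
  for (f in seq_len(n_c) - 1L) {
    pos <- ann$c_onset + f + 1L
    samples[[f + 1L]] <- list(
      image = series$frames[[pos]],
      time = (f / n_c) * t_c,
      speaker_id = series$speaker_id,
      source_frame_index = series$frame_index[pos])
  }
  t_v <- r$v_frames / fps
  for (f in seq_len(n_v) - 1L) {
    pos <- ann$v_onset + f + 1L
    samples[[n_c + f + 1L]] <- list(
      image = series$frames[[pos]],
      time = t_c + (f / n_v) * t_v,
      speaker_id = series$speaker_id,
      source_frame_index = series$frame_index[pos])
  }
  samples
}

#' Pool aligned samples into a global series
#'
#' Concatenates per-speaker timed samples for one CV and plane and sorts
#' them stably by `(time, speaker_id, source_frame_index)`.  Multiple
#' samples at the same time point are preserved.
#'
#' @param aligned List of per-speaker sample lists (from
#'   [piecewise_align()]).
#' @param cv_label,plane Identity of the pooled series.
#' @return Object of class `vt_global_series` with fields `cv_label`,
#'   `plane`, `samples`.
#' @export
pool_global_series <- function(aligned, cv_label, plane = "M") {
  samples <- do.call(c, aligned)
  if (length(samples)) {
    ord <- order(vapply(samples, `[[`, numeric(1), "time"),
                 vapply(samples, `[[`, character(1), "speaker_id"),
                 vapply(samples, `[[`, integer(1), "source_frame_index"))
    samples <- samples[ord]
  }
  structure(list(cv_label = cv_label, plane = plane, samples = samples),
            class = "vt_global_series")
}

#' Sample times of a global series
#' @param gs A `vt_global_series`.
#' @return Numeric vector of times in seconds.
#' @export
gs_times <- function(gs) vapply(gs$samples, `[[`, numeric(1), "time")

#' @export
print.vt_global_series <- function(x, ...) {
  cat(sprintf("<vt_global_series> /%s/ plane %s: %d samples over [%.1f, %.1f] ms\n",
              x$cv_label, x$plane, length(x$samples),
              if (length(x$samples)) 1000 * min(gs_times(x)) else NA,
              if (length(x$samples)) 1000 * max(gs_times(x)) else NA))
  invisible(x)
}
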