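#' Build the anatomically neutral reference space for one plane
#'
#' From one silence frame per speaker: (a) the average intensity histogram
#' is computed and every input matched to it; (b) each speaker's frame is
#' registered non-rigidly (affine + B-spline FFD) to every other speaker's
#' frame, giving the `N(N-1)` pairwise transforms `T[i,j]`; (c) the `N-1`
#' transforms of each speaker are averaged without weighting into `Tbar[i]`;
#' (d) applying `Tbar[i]` to speaker `i`'s matched frame yields the
#' neutralized image; (e) the pixel-wise mean of the neutralized images is
#' the reference image.  The result is deterministic and invariant to
#' speaker ordering.
#'
#' @param silence_images Named list (speaker id -> matrix or `vt_frame`) of
#'   same-shape silence frames; length >= 2.
#' @param plane Plane label recorded on the output.
#' @param spacing B-spline control spacing in pixels.
#' @param n_bins Histogram bins for matching.
#' @param reg_maxit Iteration cap passed to [register_bspline()].
#' @param verbose Emit one message per pairwise registration.
#' @return Object of class `vt_reference`: fields `reference` (the mean
#'   image), `avg_transforms`, `neutral_images`, `matched_images`,
#'   `histogram`, `limits`, `plane`, `speakers`, `spacing`.
#' @export
build_reference_space <- function(silence_images, plane = "M", spacing = 16,
                                  n_bins = 256L, reg_maxit = 60L,
                                  verbose = FALSE) {
  stopifnot(is.list(silence_images))
  if (length(silence_images) < 2L)
    stop("need at least two speakers to build a reference space")
  ids <- names(silence_images)
  if (is.null(ids) || anyNA(ids) || any(ids == ""))
    ids <- paste0("sp", seq_along(silence_images))
  px <- lapply(silence_images, as_pixels)
  d <- dim(px[[1]])
  if (!all(vapply(px, function(m) identical(dim(m), d), logical(1))))
    stop("silence frames must share one shape")
  limits <- range(unlist(lapply(px, range)))
  hists <- lapply(px, compute_histogram, n_bins = n_bins, limits = limits)
  avg_hist <- average_histograms(hists)
  matched <- lapply(px, match_histogram, reference = avg_hist)
  n <- length(matched)
  avg_tr <- vector("list", n)
  for (i in seq_len(n)) {
    pair <- vector("list", n - 1L)
    k <- 1L
    for (j in seq_len(n)) {
      if (j == i) next
      if (verbose) message("registering ", ids[i], " -> ", ids[j])
      tr <- register_bspline(matched[[i]], matched[[j]], spacing = spacing,
                             max_iter = reg_maxit)
      if (!is.finite(attr(tr, "value")))
        stop("registration failed for pair (", ids[i], ", ", ids[j], ")")
      pair[[k]] <- tr
      k <- k + 1L
    }
    avg_tr[[i]] <- average_transforms(pair)
  }
  neutral <- Map(function(tr, img) apply_transform(tr, img), avg_tr, matched)
  reference <- Reduce(`+`, neutral) / n
  structure(list(plane = plane, reference = reference,
                 avg_transforms = setNames(avg_tr, ids),
                 neutral_images = setNames(neutral, ids),
                 matched_images = setNames(matched, ids),
                 histogram = avg_hist, limits = limits,
                 speakers = ids, spacing = spacing),
            class = "vt_reference")
}

#' @export
print.vt_reference <- function(x, ...) {
  d <- dim(x$reference)
  cat(sprintf("<vt_reference> plane %s: %d speakers, %dx%d, spacing %g px\n",
              x$plane, length(x$speakers), d[1], d[2], x$spacing))
  invisible(x)
}
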