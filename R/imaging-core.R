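#' Single image frame
#'
#' A 2D grayscale frame: a non-negative intensity matrix plus the sagittal
#' plane it was acquired in and its (0-based) index within its series.
#' Throughout the package the coordinate convention is 0-based and
#' pixel-centered with `x` the column index and `y` the row index.
#'
#' @param pixels Numeric matrix of non-negative, finite intensities.
#' @param plane One of [vt_planes()].
#' @param frame_index Integer >= 0.
#' @return Object of class `vt_frame`.
#' @export
image_frame <- function(pixels, plane = "M", frame_index = 0L) {
  stopifnot(is.matrix(pixels), is.numeric(pixels))
  if (length(pixels) == 0L || nrow(pixels) == 0L || ncol(pixels) == 0L)
    stop("empty image")
  if (!all(is.finite(pixels)) || any(pixels < 0))
    stop("intensities must be finite and non-negative")
  plane <- match.arg(plane, VT_PLANES)
  frame_index <- as.integer(frame_index)
  stopifnot(length(frame_index) == 1L, frame_index >= 0L)
  structure(list(pixels = pixels, plane = plane, frame_index = frame_index),
            class = "vt_frame")
}

# Accept a bare matrix or a vt_frame wherever pixel data is needed.
as_pixels <- function(x) {
  if (inherits(x, "vt_frame")) return(x$pixels)
  if (is.matrix(x) && is.numeric(x)) return(x)
  stop("expected an image matrix or vt_frame, got ", class(x)[1])
}

#' Ordered image series
#'
#' An ordered sequence of same-shape frames from one speaker, plane and CV
#' (or silence), with its frame rate.
#'
#' @param frames List of numeric matrices (or `vt_frame`s), all same shape.
#' @param fps Frame rate in frames/s (default 50, the acquisition rate).
#' @param speaker_id Speaker identifier (character).
#' @param cv_label One of [vt_cv_labels()] or `"silence"`.
#' @param plane One of [vt_planes()].
#' @param frame_index Optional strictly increasing integer vector of 0-based
#'   source frame indices; defaults to `0:(n-1)`.
#' @return Object of class `vt_series`.
#' @export
image_series <- function(frames, fps = 50, speaker_id = "sp1",
                         cv_label = "silence", plane = "M",
                         frame_index = NULL) {
  stopifnot(is.list(frames), length(frames) >= 1L, fps > 0)
  plane <- match.arg(plane, VT_PLANES)
  if (!cv_label %in% c(vt_cv_labels(), "silence"))
    stop("unknown cv_label: ", cv_label)
  px <- lapply(frames, as_pixels)
  d <- dim(px[[1]])
  ok <- vapply(px, function(m) identical(dim(m), d), logical(1))
  if (!all(ok)) stop("all frames must share one shape")
  if (is.null(frame_index)) frame_index <- seq_along(px) - 1L
  frame_index <- as.integer(frame_index)
  stopifnot(length(frame_index) == length(px))
  if (any(diff(frame_index) <= 0L))
    stop("frame_index must be strictly increasing")
  structure(list(frames = px, frame_index = frame_index, fps = fps,
                 speaker_id = as.character(speaker_id),
                 cv_label = cv_label, plane = plane),
            class = "vt_series")
}

#' @export
print.vt_series <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<vt_series> %s /%s/ plane %s: %d frames of %dx%d at %g fps\n",
              x$speaker_id, x$cv_label, x$plane, length(x$frames),
              d[1], d[2], x$fps))
  invisible(x)
}

#' Number of frames in a series
#' @param series A `vt_series`.
#' @return Integer frame count.
#' @export
n_frames <- function(series) length(series$frames)

#' Phoneme segment annotation
#'
#' 0-based frame indices of the consonant onset, vowel onset (constriction
#' release) and vowel offset (following lip closure) within an image series.
#' The consonant occupies frames `[c_onset, v_onset)` and the vowel
#' `[v_onset, v_offset)`.
#'
#' @param c_onset,v_onset,v_offset Integer frame indices,
#'   `c_onset < v_onset < v_offset`.
#' @param n_frames Optional series length to validate against
#'   (`v_offset <= n_frames`).
#' @return Object of class `vt_annotation`.
#' @export
segment_annotation <- function(c_onset, v_onset, v_offset, n_frames = NULL) {
  c_onset <- as.integer(c_onset); v_onset <- as.integer(v_onset)
  v_offset <- as.integer(v_offset)
  if (!(c_onset < v_onset && v_onset < v_offset))
    stop("need c_onset < v_onset < v_offset")
  if (c_onset < 0L) stop("c_onset must be >= 0")
  if (!is.null(n_frames) && v_offset > n_frames)
    stop("annotation extends past the series (", v_offset, " > ", n_frames, ")")
  structure(list(c_onset = c_onset, v_onset = v_onset, v_offset = v_offset),
            class = "vt_annotation")
}

#' Intensity histogram
#'
#' @param bin_edges Strictly increasing numeric vector of bin edges.
#' @param counts Non-negative numeric vector, one entry per bin.
#' @return Object of class `vt_histogram`.
#' @export
intensity_histogram <- function(bin_edges, counts) {
  stopifnot(is.numeric(bin_edges), is.numeric(counts),
            length(counts) == length(bin_edges) - 1L)
  if (any(diff(bin_edges) <= 0)) stop("bin_edges must be strictly increasing")
  if (any(counts < 0)) stop("counts must be non-negative")
  structure(list(bin_edges = as.numeric(bin_edges),
                 counts = as.numeric(counts)),
            class = "vt_histogram")
}

#' Compute an intensity histogram
#'
#' Uniform binning over `limits` (defaults to the image's own range).  The
#' first/last bins absorb values at or beyond the limits, so counts always
#' sum to the pixel count.
#'
#' @param image Matrix or `vt_frame`.
#' @param n_bins Number of bins (>= 2; default 256).
#' @param limits Length-2 intensity range covered by the bins.
#' @return A `vt_histogram`.
#' @export
compute_histogram <- function(image, n_bins = 256L, limits = NULL) {
  px <- as_pixels(image)
  if (length(px) == 0L) stop("empty image")
  stopifnot(n_bins >= 2L)
  if (is.null(limits)) limits <- range(px)
  if (limits[2] <= limits[1]) limits[2] <- limits[1] + 1e-6
  edges <- seq(limits[1], limits[2], length.out = n_bins + 1L)
  idx <- findInterval(px, edges, rightmost.closed = TRUE, all.inside = TRUE)
  intensity_histogram(edges, tabulate(idx, nbins = n_bins))
}

#' Average several histograms
#'
#' Histograms are first normalized to probability mass (images may differ in
#' size), averaged bin-wise, and rescaled to the mean total count of the
#' inputs.
#'
#' @param histograms List of `vt_histogram`s on identical bin edges.
#' @return A `vt_histogram`.
#' @export
average_histograms <- function(histograms) {
  stopifnot(is.list(histograms), length(histograms) >= 1L)
  edges <- histograms[[1]]$bin_edges
  for (h in histograms) {
    if (!inherits(h, "vt_histogram")) stop("inputs must be vt_histogram")
    if (!isTRUE(all.equal(h$bin_edges, edges)))
      stop("histograms have mismatched bin edges")
  }
  totals <- vapply(histograms, function(h) sum(h$counts), numeric(1))
  if (any(totals <= 0)) stop("histogram with zero total mass")
  probs <- Map(function(h, tot) h$counts / tot, histograms, totals)
  avg <- Reduce(`+`, probs) / length(probs)
  intensity_histogram(edges, avg * mean(totals))
}

# cumulative distribution of a histogram (length n_bins, ends at 1)
hist_cdf <- function(h) {
  tot <- sum(h$counts)
  if (tot <= 0) stop("histogram has zero total mass")
  cumsum(h$counts) / tot
}

#' Match an image's histogram to a reference
#'
#' Monotone CDF inversion: the image is quantized on the reference's bin
#' grid, its empirical CDF computed, and each occupied source bin mapped to
#' the lowest reference bin whose cumulative mass reaches the source
#' cumulative mass.  Pixels whose bin maps to itself keep their original
#' value, so matching an image to its own histogram is an exact no-op and
#' the operation is idempotent.
#'
#' @param image Matrix or `vt_frame`.
#' @param reference A `vt_histogram` with positive total mass.
#' @return Same type as `image`, histogram-matched.
#' @export
match_histogram <- function(image, reference) {
  px <- as_pixels(image)
  if (!inherits(reference, "vt_histogram")) stop("reference must be a vt_histogram")
  if (sum(reference$counts) <= 0) stop("reference histogram has zero total mass")
  edges <- reference$bin_edges
  nb <- length(edges) - 1L
  src_bin <- findInterval(px, edges, rightmost.closed = TRUE, all.inside = TRUE)
  src_counts <- tabulate(src_bin, nbins = nb)
  cdf_src <- cumsum(src_counts) / length(px)
  cdf_ref <- hist_cdf(reference)
  # first reference bin with cdf_ref >= cdf_src[b] (tolerance keeps the
  # mapping stable under float rounding, which is what makes it idempotent)
  tgt <- findInterval(cdf_src - 1e-12, cdf_ref, left.open = TRUE) + 1L
  tgt <- pmin(tgt, nb)
  centers <- (edges[-1L] + edges[-length(edges)]) / 2
  out <- centers[tgt[src_bin]]
  keep <- tgt[src_bin] == src_bin        # bin fixed points keep exact values
  out[keep] <- px[keep]
  out <- matrix(out, nrow(px), ncol(px))
  if (inherits(image, "vt_frame"))
    image_frame(out, image$plane, image$frame_index)
  else out
}

## ---- file I/O -------------------------------------------------------------

series_sidecar <- function(series) {
  list(speaker_id = series$speaker_id, plane = series$plane,
       cv_label = series$cv_label, fps = series$fps,
       frame_index = series$frame_index)
}

apply_sidecar <- function(frames, meta) {
  image_series(frames, fps = as.numeric(meta$fps),
               speaker_id = meta$speaker_id,
               cv_label = meta$cv_label, plane = meta$plane,
               frame_index = meta$frame_index)
}

#' Write / read an image series as NIfTI
#'
#' One NIfTI file per series with time as the third dimension (stored as
#' float64, so integer data round-trips losslessly), plus a `.json` sidecar
#' holding `speaker_id`, `plane`, `cv_label`, `fps` and the frame indices.
#'
#' @param series A `vt_series`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `write_series_nifti` returns `path` invisibly;
#'   `read_series_nifti` returns a `vt_series`.
#' @export
write_series_nifti <- function(series, path) {
  stopifnot(inherits(series, "vt_series"))
  arr <- array(0, dim = c(dim(series$frames[[1]]), length(series$frames)))
  for (i in seq_along(series$frames)) arr[, , i] <- series$frames[[i]]
  img <- RNifti::asNifti(arr, pixdim = c(1, 1, 1 / series$fps),
                         datatype = "double")
  RNifti::writeNifti(img, path, datatype = "double")
  jsonlite::write_json(series_sidecar(series), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_series_nifti
#' @export
read_series_nifti <- function(path) {
  arr <- as.array(RNifti::readNifti(path))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (length(dim(arr)) == 2L)           # single-frame series
    arr <- array(arr, dim = c(dim(arr), 1L))
  frames <- lapply(seq_len(dim(arr)[3]), function(i) arr[, , i])
  apply_sidecar(frames, meta)
}

#' Write / read an image series as multi-page TIFF
#'
#' Frames are stored as 16-bit pages.  Intensities are scaled by the
#' series-wide maximum (recorded in the sidecar), so integer-valued data
#' with range up to 65535 round-trips losslessly; other data is quantized
#' to 16 bits.
#'
#' @param series A `vt_series`.
#' @param path Output `.tif` path.
#' @return `write_series_tiff` returns `path` invisibly;
#'   `read_series_tiff` returns a `vt_series`.
#' @export
write_series_tiff <- function(series, path) {
  stopifnot(inherits(series, "vt_series"))
  mx <- max(vapply(series$frames, max, numeric(1)), 1e-12)
  is_int <- all(vapply(series$frames,
                       function(m) all(m == round(m)), logical(1)))
  scale <- if (is_int && mx <= 65535) 65535 else mx
  pages <- lapply(series$frames, function(m) m / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  meta <- series_sidecar(series)
  meta$intensity_scale <- scale
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_series_tiff
#' @export
read_series_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  scale <- meta$intensity_scale
  frames <- lapply(pages, function(p) {
    v <- p * scale
    if (scale == 65535) v <- round(v)
    v
  })
  apply_sidecar(frames, meta)
}

#' Write / read segment annotations as CSV
#'
#' Columns: `speaker`, `plane`, `cv`, `c_onset`, `v_onset`, `v_offset`
#' (0-based frame indices).
#'
#' @param annotations `data.frame` in the above layout.
#' @param path CSV path.
#' @return `read_annotations` returns the validated `data.frame`.
#' @export
write_annotations <- function(annotations, path) {
  stopifnot(all(c("speaker", "plane", "cv", "c_onset", "v_onset",
                  "v_offset") %in% names(annotations)))
  write.csv(annotations, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  ann <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("speaker", "plane", "cv", "c_onset", "v_onset", "v_offset")
  if (!all(need %in% names(ann)))
    stop("annotation CSV must have columns: ", paste(need, collapse = ", "))
  bad <- !(ann$c_onset < ann$v_onset & ann$v_onset < ann$v_offset)
  if (any(bad)) stop("invalid segment ordering in rows ",
                     paste(which(bad), collapse = ", "))
  ann
}

## ---- similarity helpers ---------------------------------------------------

#' Simple image similarity
#'
#' Zero-normalized cross-correlation (`"ncc"`, in `[-1, 1]`) or negative
#' mean squared difference (`"nssd"`).  Used for before/after comparisons in
#' tests and diagnostics; registration itself optimizes SSD on
#' histogram-matched images.
#'
#' @param a,b Same-shape matrices or `vt_frame`s.
#' @param method `"ncc"` or `"nssd"`.
#' @return Scalar similarity (larger is more similar).
#' @export
image_similarity <- function(a, b, method = c("ncc", "nssd")) {
  method <- match.arg(method)
  a <- as_pixels(a); b <- as_pixels(b)
  stopifnot(identical(dim(a), dim(b)))
  if (method == "nssd") return(-mean((a - b)^2))
  ac <- a - mean(a); bc <- b - mean(b)
  den <- sqrt(sum(ac^2) * sum(bc^2))
  if (den == 0) return(0)
  sum(ac * bc) / den
}
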