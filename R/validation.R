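#' Gender-balanced cross-validation folds
#'
#' Four folds over a cohort of four male and four female speakers; each
#' fold's test pair is one male plus one female, every speaker is tested
#' exactly once, and the remaining six speakers train the fold's atlas.
#' Deterministic for a given seed.
#'
#' @param speakers `data.frame` with columns `speaker_id`, `gender`
#'   (`"M"`/`"F"`).
#' @param n_folds Number of folds (must be 4).
#' @param seed Integer seed for the pairing shuffle.
#' @return List of fold specs: `fold`, `train`, `test` (character vectors).
#' @export
make_folds <- function(speakers, n_folds = 4L, seed = 1L) {
  stopifnot(is.data.frame(speakers),
            all(c("speaker_id", "gender") %in% names(speakers)))
  males <- speakers$speaker_id[speakers$gender == "M"]
  females <- speakers$speaker_id[speakers$gender == "F"]
  if (length(males) != 4L || length(females) != 4L)
    stop("need exactly 4 male and 4 female speakers (got ",
         length(males), "M/", length(females), "F)")
  if (n_folds != 4L) stop("the protocol uses 4 folds")
  with_seed(seed, {
    males <- sample(males)
    females <- sample(females)
  })
  lapply(seq_len(n_folds), function(i) {
    test <- c(males[i], females[i])
    list(fold = i,
         train = setdiff(speakers$speaker_id, test),
         test = test)
  })
}

#' Link atlas frames to the temporally closest test frames
#'
#' Each atlas time maps to the test sample minimizing `|t - tau|`; ties go
#' to the earlier test frame.  Test frames may be reused or unused.
#'
#' @param atlas_times Numeric vector of atlas frame times (seconds).
#' @param test_times Numeric vector of aligned test sample times (sorted).
#' @return Integer vector, same length as `atlas_times`, of 1-based indices
#'   into `test_times`.
#' @export
link_frames <- function(atlas_times, test_times) {
  stopifnot(length(atlas_times) >= 1L, length(test_times) >= 1L)
  vapply(atlas_times,
         function(tau) which.min(abs(test_times - tau)),
         integer(1))
}

# max over all integer lags (zero-padded) of the 2D cross-correlation,
# computed in the frequency domain
xcorr_max <- function(X, Y) {
  M <- nrow(X); W <- ncol(X)
  P <- 2L * M - 1L; Q <- 2L * W - 1L
  Xp <- matrix(0, P, Q); Xp[1:M, 1:W] <- X
  Yp <- matrix(0, P, Q); Yp[1:M, 1:W] <- Y
  cc <- fft(fft(Xp) * Conj(fft(Yp)), inverse = TRUE) / (P * Q)
  max(Re(cc))
}

#' Normalized maximum cross-correlation similarity
#'
#' The maximum over all integer lags (with zero padding) of the 2D
#' cross-correlation of `X` and `Y`, normalized by the maximum of the
#' autocorrelation of the atlas frame `A`.  With `X`, `Y` the unregistered
#' test frames this is the before-atlas score (BA); with the registered
#' frames it is the after-atlas score (AA).
#'
#' @param A Atlas frame (matrix or `vt_frame`), not all-zero.
#' @param X,Y Test frames, same shape as `A`.
#' @return Scalar similarity ratio.
#' @export
xcorr_similarity <- function(A, X, Y) {
  A <- as_pixels(A); X <- as_pixels(X); Y <- as_pixels(Y)
  stopifnot(identical(dim(A), dim(X)), identical(dim(A), dim(Y)))
  den <- xcorr_max(A, A)
  if (den <= 0) stop("atlas frame is all zero: zero autocorrelation")
  xcorr_max(X, Y) / den
}

#' Validation configuration
#'
#' @param seed Fold-pairing seed.
#' @param spacing B-spline control spacing (pixels).
#' @param kernel A [kernel_config()].
#' @param tau_spacing Atlas time-grid step (seconds); defaults to the
#'   kernel window (20 ms).
#' @param planes Planes to evaluate (default: all present in the dataset).
#' @param n_bins Histogram bins.
#' @param reg_maxit Iteration cap for the B-spline stage.
#' @param affine_maxit Iteration cap for per-frame affine normalization.
#' @param verbose Progress messages.
#' @return List of class `vt_validation_config`.
#' @export
validation_config <- function(seed = 1L, spacing = 16, kernel = kernel_config(),
                              tau_spacing = NULL, planes = NULL,
                              n_bins = 256L, reg_maxit = 40L,
                              affine_maxit = 40L, verbose = FALSE) {
  structure(list(seed = seed, spacing = spacing, kernel = kernel,
                 tau_spacing = if (is.null(tau_spacing)) kernel$window
                               else tau_spacing,
                 planes = planes, n_bins = n_bins, reg_maxit = reg_maxit,
                 affine_maxit = affine_maxit, verbose = verbose),
            class = "vt_validation_config")
}

# annotation lookup for one speaker/cv/plane
lookup_annotation <- function(annotations, speaker, cv, plane) {
  r <- annotations[annotations$speaker == speaker & annotations$cv == cv &
                     annotations$plane == plane, , drop = FALSE]
  if (nrow(r) != 1L)
    stop("expected one annotation for (", speaker, ", ", cv, ", ", plane, ")")
  segment_annotation(r$c_onset, r$v_onset, r$v_offset)
}

#' Four-fold cross-validated atlas evaluation
#'
#' For each fold: a reference space and an atlas per CV/plane are built from
#' the six training speakers; the two held-out speakers' CV series are
#' affinely normalized into the fold's reference space and piecewise
#' aligned; each atlas frame is linked to the temporally closest test frame
#' of each test speaker; the linked frames are histogram-matched to the
#' atlas frame and registered to it with the B-spline method; and the
#' before/after similarity of the test pair, normalized by the atlas
#' frame's autocorrelation, is recorded.  Scores are pooled over frames,
#' planes and folds into a per-CV mean and standard deviation.
#'
#' @param dataset A cohort as returned by [phantom_cohort()]: list with
#'   `speakers` (`data.frame(speaker_id, gender)`), `silence`
#'   (`[[speaker]][[plane]]` matrices), `series`
#'   (`[[speaker]][[cv]][[plane]]` `vt_series`), `annotations`
#'   (`data.frame`).
#' @param config A [validation_config()].
#' @return List of class `vt_similarity_report`: `report`
#'   (`data.frame(cv, mean_before, sd_before, mean_after, sd_after)`) and
#'   `stacks` (per-stack scores with fold/plane/tau identity).
#' @export
run_validation <- function(dataset, config = validation_config()) {
  speakers <- dataset$speakers
  planes <- config$planes
  if (is.null(planes)) planes <- names(dataset$silence[[1]])
  cvs <- sort(unique(dataset$annotations$cv))
  fps <- dataset$series[[1]][[1]][[1]]$fps
  folds <- make_folds(speakers, seed = config$seed)
  say <- function(...) if (config$verbose) message(...)
  rows <- list()
  for (fd in folds) {
    say("fold ", fd$fold, ": test = ", paste(fd$test, collapse = ", "))
    train_ann <- dataset$annotations[dataset$annotations$speaker %in%
                                       fd$train, , drop = FALSE]
    durations <- compute_reference_durations(train_ann, cvs = cvs)
    for (pl in planes) {
      say("  plane ", pl, ": reference space")
      sil <- lapply(setNames(fd$train, fd$train),
                    function(sp) dataset$silence[[sp]][[pl]])
      ref <- build_reference_space(sil, plane = pl,
                                   spacing = config$spacing,
                                   n_bins = config$n_bins,
                                   reg_maxit = config$reg_maxit)
      for (cv in cvs) {
        rd <- duration_row(durations, cv)
        tau_grid <- seq(0, rd$cv_frames / fps, by = config$tau_spacing)
        aligned_train <- lapply(fd$train, function(sp) {
          ser <- dataset$series[[sp]][[cv]][[pl]]
          ann <- lookup_annotation(dataset$annotations, sp, cv, pl)
          ns <- normalize_series(ser, ref, max_iter = config$affine_maxit)
          piecewise_align(ns, ann, durations)
        })
        gs <- pool_global_series(aligned_train, cv_label = cv, plane = pl)
        atlas <- build_atlas(setNames(list(gs), pl), tau_grid = tau_grid,
                             config = config$kernel)
        # test speakers stay anatomically raw: they are temporally aligned
        # and histogram-matched only, then mapped to the atlas frame with
        # the full (affine + B-spline) registration below
        aligned_test <- lapply(setNames(fd$test, fd$test), function(sp) {
          ser <- dataset$series[[sp]][[cv]][[pl]]
          ann <- lookup_annotation(dataset$annotations, sp, cv, pl)
          piecewise_align(ser, ann, durations)
        })
        test_times <- lapply(aligned_test, function(s)
          vapply(s, `[[`, numeric(1), "time"))
        links <- lapply(test_times, function(tt) link_frames(tau_grid, tt))
        for (i in seq_along(tau_grid)) {
          A <- atlas$planes[[pl]][[i]]$image
          limits <- range(A)
          a_hist <- compute_histogram(A, n_bins = config$n_bins,
                                      limits = range(c(limits, unlist(lapply(
                                        fd$test, function(sp)
                                          range(aligned_test[[sp]][[
                                            links[[sp]][i]]]$image))))))
          O <- lapply(fd$test, function(sp)
            match_histogram(aligned_test[[sp]][[links[[sp]][i]]]$image,
                            a_hist))
          A_m <- match_histogram(A, a_hist)
          # every image entering the similarity is matched to the atlas
          # frame's histogram, including the registered ones: warping
          # (interpolation, zero fill) perturbs the intensity distribution,
          # and the stack is defined as histogram-matched to A
          R <- lapply(O, function(img) {
            tr <- register_bspline(img, A_m, spacing = config$spacing,
                                   max_iter = config$reg_maxit)
            match_histogram(apply_transform(tr, img), a_hist)
          })
          ba <- xcorr_similarity(A_m, O[[1]], O[[2]])
          aa <- xcorr_similarity(A_m, R[[1]], R[[2]])
          rows[[length(rows) + 1L]] <-
            data.frame(fold = fd$fold, cv = cv, plane = pl,
                       tau = tau_grid[i], ba = ba, aa = aa,
                       stringsAsFactors = FALSE)
        }
        say("  plane ", pl, " /", cv, "/ done")
      }
    }
  }
  stacks <- do.call(rbind, rows)
  report <- do.call(rbind, lapply(cvs, function(cv) {
    s <- stacks[stacks$cv == cv, , drop = FALSE]
    data.frame(cv = cv,
               mean_before = mean(s$ba), sd_before = sd(s$ba),
               mean_after = mean(s$aa), sd_after = sd(s$aa),
               stringsAsFactors = FALSE)
  }))
  structure(list(report = report, stacks = stacks),
            class = "vt_similarity_report")
}

#' @export
print.vt_similarity_report <- function(x, ...) {
  cat("<vt_similarity_report> per-CV pooled similarity (before / after atlas)\n")
  print(x$report, row.names = FALSE, digits = 3)
  invisible(x)
}
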