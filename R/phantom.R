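## Synthetic multi-speaker vocal-tract phantom.
##
## Renders a simplified 2D sagittal head — head outline, hard palate,
## tongue (body + tip bumps), lips, pharynx, spine — with smooth
## anti-aliased edges, per-speaker global anatomy (scale, tilt, shift,
## small palate/jaw shape offsets, vertebra count, intensity gain) and a
## shared articulatory gesture per CV executed with speaker-specific
## segment durations.  Off-center planes get increasing blur (partial
## volume) and more closed lips.  All geometry is known, so ground-truth
## inter-speaker affines, durations and landmarks are exported.

# smooth indicator: ~1 where d > 0, ~0 where d < 0; eps is the edge width
sstep <- function(d, eps) stats::plogis(d / eps)

# canonical geometry constants (unit head coordinates, y down)
phantom_geometry <- function() {
  list(head_c = c(0.50, 0.52), head_r = c(0.36, 0.42),
       lip_x = c(0.14, 0.20), mouth_x = c(0.20, 0.58),
       palate_y0 = 0.40, palate_curv = 0.10, palate_cx = 0.39,
       palate_hw = 0.19,
       jaw_y = 0.60, tip_x = 0.23, tip_w = 0.025, body_w = 0.09,
       phar_x = c(0.58, 0.655), phar_y1 = 0.78,
       spine_x = c(0.72, 0.80), spine_y0 = 0.34, vert_h = 0.075,
       vert_gap = 0.028,
       folds = c(0.615, 0.78), esoph = c(0.64, 0.84),
       lips_pt = c(0.14, 0.50), axis_pt = c(0.72, 0.505),
       wall_x = 0.655, px_mm = 1.41)
}

# articulatory targets: lip aperture, tongue tip height, body height,
# body position (all in unit head coordinates)
phantom_targets <- function() {
  g <- phantom_geometry()
  contact <- g$jaw_y - (g$palate_y0 + g$palate_curv *
                          ((g$tip_x - g$palate_cx) / g$palate_hw)^2)
  list(
    sil = c(ap = 0.000, At = 0.020, Ab = 0.060, xb = 0.450),
    f   = c(ap = 0.012, At = 0.030, Ab = 0.070, xb = 0.420),
    p   = c(ap = 0.000, At = 0.020, Ab = 0.060, xb = 0.450),
    s   = c(ap = 0.040, At = contact - 0.012, Ab = 0.080, xb = 0.400),
    t   = c(ap = 0.050, At = contact + 0.004, Ab = 0.080, xb = 0.400),
    i   = c(ap = 0.050, At = 0.040, Ab = 0.160, xb = 0.330),
    a   = c(ap = 0.090, At = 0.010, Ab = 0.030, xb = 0.480),
    u   = c(ap = 0.018, At = 0.010, Ab = 0.160, xb = 0.540))
}

smoothstep01 <- function(z) { z <- pmin(pmax(z, 0), 1); z * z * (3 - 2 * z) }

#' Articulator pose of the shared phantom gesture
#'
#' The pose (lip aperture `ap`, tongue-tip height `At`, tongue-body height
#' `Ab`, tongue-body position `xb`, unit head coordinates) of the common
#' gesture for a CV: the consonant target is reached over the first 40% of
#' the consonant and held; the articulators then glide to the vowel target
#' over the first 60% of the vowel and hold it.
#'
#' @param cv One of [vt_cv_labels()], or `"silence"`.
#' @param segment `"C"` or `"V"` (ignored for silence).
#' @param frac Normalized position in the segment, in `[0, 1]`.
#' @return Named numeric vector `(ap, At, Ab, xb)`.
#' @export
phantom_pose <- function(cv, segment = "C", frac = 0) {
  tg <- phantom_targets()
  if (cv == "silence") return(tg$sil)
  cons <- tg[[substr(cv, 1, 1)]]
  vow <- tg[[substr(cv, 2, 2)]]
  if (segment == "C") {
    r <- smoothstep01(frac / 0.4)
    tg$sil + (cons - tg$sil) * r
  } else {
    r <- smoothstep01(frac / 0.6)
    cons + (vow - cons) * r
  }
}

#' Render one phantom frame
#'
#' @param anatomy List/row with `scale`, `tilt_deg`, `shift_x`, `shift_y`,
#'   `palate_offset`, `jaw_offset`, `n_vertebrae`, `gain`, `bias` (use
#'   `phantom_neutral_anatomy()` for the canonical speaker).
#' @param pose Named vector from [phantom_pose()].
#' @param plane One of [vt_planes()] (off-center planes are blurrier with
#'   more closed lips).
#' @param size Image side in pixels.
#' @return `size x size` intensity matrix in roughly `[0, 1]`.
#' @export
render_phantom_frame <- function(anatomy, pose, plane = "M", size = 136L) {
  g <- phantom_geometry()
  off <- c(R2 = 2, R1 = 1, M = 0, L1 = 1, L2 = 2)[[plane]]
  eps <- 0.8 / size
  cc <- (size - 1) / 2
  th <- anatomy$tilt_deg * pi / 180
  co <- cos(th); si <- sin(th)
  x <- matrix(rep(0:(size - 1), each = size), size, size) - cc -
    anatomy$shift_x
  y <- matrix(rep(0:(size - 1), times = size), size, size) - cc -
    anatomy$shift_y
  ux <- (co * x + si * y) / (anatomy$scale * size) + 0.5
  uy <- (-si * x + co * y) / (anatomy$scale * size) + 0.5
  paint <- function(img, mask, val) img * (1 - mask) + val * mask
  shrink <- 1 - 0.03 * off
  # head tissue
  hd <- 1 - ((ux - g$head_c[1]) / (g$head_r[1] * shrink))^2 -
    ((uy - g$head_c[2]) / (g$head_r[2] * shrink))^2
  img <- matrix(0.05, size, size)
  img <- paint(img, sstep(hd, 4 * eps), 0.55)
  air_val <- 0.07 + 0.04 * off
  # palate line and tongue surface
  y_pal <- g$palate_y0 + anatomy$palate_offset +
    g$palate_curv * ((ux - g$palate_cx) / g$palate_hw)^2
  jaw <- g$jaw_y + anatomy$jaw_offset
  ap <- pose[["ap"]] * (1 - 0.35 * off)
  body_w <- g$body_w * anatomy$tongue_w
  y_tng <- jaw - pose[["Ab"]] * exp(-(ux - pose[["xb"]])^2 /
                                      (2 * body_w^2)) -
    pose[["At"]] * exp(-(ux - g$tip_x)^2 / (2 * g$tip_w^2))
  in_mouth <- sstep(ux - g$mouth_x[1], eps) * sstep(g$mouth_x[2] - ux, eps)
  # oral airway between palate and tongue surface
  m_air <- in_mouth * sstep(uy - y_pal, eps) * sstep(y_tng - uy, eps)
  img <- paint(img, m_air, air_val)
  # pharyngeal airway
  m_phar <- sstep(ux - g$phar_x[1], eps) * sstep(g$phar_x[2] - ux, eps) *
    sstep(uy - (y_pal - 0.01), eps) * sstep(g$phar_y1 - uy, eps)
  img <- paint(img, m_phar, air_val)
  # tongue body (brighter muscle)
  m_tng <- in_mouth * sstep(uy - y_tng, eps) * sstep(jaw + 0.06 - uy, eps)
  img <- paint(img, m_tng, 0.75)
  # palate ridge
  m_ridge <- in_mouth * sstep(uy - (y_pal - 0.025), eps) *
    sstep(y_pal - uy, eps)
  img <- paint(img, m_ridge, 0.85)
  # spine vertebrae
  in_spine_x <- sstep(ux - (g$spine_x[1] + anatomy$spine_dx), eps) *
    sstep(g$spine_x[2] + anatomy$spine_dx - ux, eps)
  for (v in seq_len(anatomy$n_vertebrae) - 1L) {
    y0 <- g$spine_y0 + v * (g$vert_h + g$vert_gap)
    m_v <- in_spine_x * sstep(uy - y0, eps) * sstep(y0 + g$vert_h - uy, eps)
    img <- paint(img, m_v, 0.78)
  }
  # lips: tissue block with an aperture gap
  in_lip_x <- sstep(ux - g$lip_x[1], eps) * sstep(g$lip_x[2] - ux, eps)
  lh <- 0.09 * anatomy$lip_h
  m_lip <- in_lip_x * sstep(uy - (0.50 - lh), eps) * sstep(0.50 + lh - uy, eps)
  img <- paint(img, m_lip, 0.80)
  if (ap > 0) {
    m_gap <- in_lip_x * sstep(uy - (0.50 - ap / 2), eps) *
      sstep(0.50 + ap / 2 - uy, eps)
    img <- paint(img, m_gap, air_val)
  }
  # smooth receive-coil-like shading and mild tissue texture, attached to
  # the anatomy (u coordinates) so speakers stay affine-consistent and
  # histograms are spread over many intensity levels
  shade <- 0.80 + 0.35 * exp(-((ux - 0.32)^2 + (uy - 0.48)^2) / 0.22)
  texture <- 1 + 0.06 * sin(9 * pi * ux) * sin(7 * pi * uy)
  img <- img * shade * texture
  img <- anatomy$gain * img + anatomy$bias
  sigma <- 0.5 + 0.8 * off
  img <- EBImage::imageData(EBImage::gblur(img, sigma = sigma))
  pmax(img, 0)
}

#' Canonical (neutral) phantom anatomy
#' @return Anatomy list for the unscaled, untilted canonical speaker.
#' @export
phantom_neutral_anatomy <- function() {
  list(scale = 1, tilt_deg = 0, shift_x = 0, shift_y = 0,
       palate_offset = 0, jaw_offset = 0, tongue_w = 1, spine_dx = 0,
       lip_h = 1, n_vertebrae = 5L, gain = 1, bias = 0)
}

# forward affine F_sp: canonical-speaker pixel coords -> this speaker's
# pixel coords
phantom_forward_affine <- function(anatomy, size) {
  th <- anatomy$tilt_deg * pi / 180
  A <- anatomy$scale * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  cc <- c((size - 1) / 2, (size - 1) / 2)
  tt <- cc + c(anatomy$shift_x, anatomy$shift_y) - as.vector(A %*% cc)
  affine_transform(A, tt)
}

#' Ground-truth affine between two phantom speakers
#'
#' The backward-mapping transform `T` such that warping speaker
#' `moving_id`'s image with `T` reproduces speaker `fixed_id`'s image (up
#' to the small non-affine shape offsets): `T = F_moving o F_fixed^-1`
#' where `F` maps canonical to speaker pixels.
#'
#' @param cohort A [phantom_cohort()] result.
#' @param moving_id,fixed_id Speaker ids.
#' @return A `vt_affine`.
#' @export
phantom_true_affine <- function(cohort, moving_id, fixed_id) {
  Fm <- cohort$ground_truth$affines[[moving_id]]
  Ff <- cohort$ground_truth$affines[[fixed_id]]
  Fi <- affine_invert(Ff)
  affine_transform(Fm$A %*% Fi$A, as.vector(Fm$A %*% Fi$t) + Fm$t)
}

phantom_landmarks <- function(anatomy, size) {
  g <- phantom_geometry()
  Fa <- phantom_forward_affine(anatomy, size)
  u2mm <- function(u) {
    cc <- (size - 1) / 2
    q <- c(cc + (u[1] - 0.5) * size, cc + (u[2] - 0.5) * size)
    p <- affine_points(Fa, q[1], q[2])
    c(p$x, p$y) * g$px_mm
  }
  wall <- rbind(u2mm(c(g$wall_x, 0.35)), u2mm(c(g$wall_x, 0.90)))
  landmark_set(lips = u2mm(g$lips_pt), axis = u2mm(g$axis_pt),
               palate_tangent = u2mm(c(g$palate_cx,
                                       g$palate_y0 + anatomy$palate_offset)),
               vocal_folds = u2mm(g$folds), esophagus = u2mm(g$esoph),
               pharyngeal_wall = wall)
}

#' Generate a synthetic multi-speaker phantom cohort
#'
#' Deterministic for a given seed.  Produces, per speaker: one silence
#' frame per plane; one dynamic series per CV and plane rendering the
#' shared gesture at that speaker's anatomy and segment durations (drawn as
#' the cohort reference durations plus an integer jitter); annotations with
#' `c_onset = 0`, `v_onset = nC`, `v_offset = nC + nV`; and ground truth
#' (forward affines, durations, landmarks, plane visibility fractions).
#'
#' @param n_speakers Number of speakers (>= 2; genders alternate M, F).
#' @param cvs CV labels to render (default all 12).
#' @param planes Planes to render (default all 5).
#' @param fps Frame rate (frames/s).
#' @param size Image side in pixels (nominal 136).
#' @param seed Integer seed; the only source of randomness.
#' @param anatomy_spread Multiplier on anatomical variability (0 renders
#'   identical speakers).
#' @param duration_jitter Multiplier on the +/-1 frame duration jitter.
#' @param noise_sd Gaussian intensity noise SD.
#' @return Object of class `vt_cohort`; see [run_validation()] for the
#'   field layout.
#' @export
phantom_cohort <- function(n_speakers = 8L, cvs = vt_cv_labels(),
                           planes = vt_planes(), fps = 50, size = 136L,
                           seed = 1L, anatomy_spread = 1,
                           duration_jitter = 1, noise_sd = 0.01) {
  stopifnot(n_speakers >= 2L, size >= 24L, fps > 0)
  planes <- match.arg(planes, VT_PLANES, several.ok = TRUE)
  stopifnot(all(cvs %in% vt_cv_labels()))
  ref_dur <- cv_duration_reference()
  ids <- paste0("sp", seq_len(n_speakers))
  with_seed(seed, {
    speakers <- data.frame(
      speaker_id = ids,
      gender = rep(c("M", "F"), length.out = n_speakers),
      scale = pmin(pmax(1 + anatomy_spread * runif(n_speakers, -0.13, 0.13),
                        0.85), 1.15),
      tilt_deg = anatomy_spread * runif(n_speakers, -4, 4),
      shift_x = anatomy_spread * runif(n_speakers, -3, 3) * size / 136,
      shift_y = anatomy_spread * runif(n_speakers, -3, 3) * size / 136,
      palate_offset = anatomy_spread * runif(n_speakers, -0.018, 0.018),
      jaw_offset = anatomy_spread * runif(n_speakers, -0.018, 0.018),
      tongue_w = 1 + anatomy_spread * runif(n_speakers, -0.12, 0.12),
      spine_dx = anatomy_spread * runif(n_speakers, -0.015, 0.015),
      lip_h = 1 + anatomy_spread * runif(n_speakers, -0.15, 0.15),
      n_vertebrae = if (anatomy_spread > 0)
        sample(4:6, n_speakers, replace = TRUE) else rep(5L, n_speakers),
      gain = 1 + anatomy_spread * runif(n_speakers, -0.08, 0.08),
      bias = anatomy_spread * runif(n_speakers, 0, 0.02),
      stringsAsFactors = FALSE)
    durations <- if (!length(cvs)) {
      data.frame(speaker = character(0), cv = character(0),
                 n_c = integer(0), n_v = integer(0))
    } else do.call(rbind, lapply(ids, function(sp) {
      jc <- if (duration_jitter > 0)
        sample(-duration_jitter:duration_jitter, length(cvs), TRUE)
      else rep(0L, length(cvs))
      jv <- if (duration_jitter > 0)
        sample(-duration_jitter:duration_jitter, length(cvs), TRUE)
      else rep(0L, length(cvs))
      base <- ref_dur[match(cvs, ref_dur$syllable), ]
      data.frame(speaker = sp, cv = cvs,
                 n_c = pmax(3L, as.integer(round(base$c_frames) + jc)),
                 n_v = pmax(3L, as.integer(round(base$v_frames) + jv)),
                 stringsAsFactors = FALSE)
    }))
    silence <- list(); series <- list(); ann_rows <- list()
    landmarks <- list(); visible <- list()
    for (si in seq_len(n_speakers)) {
      sp <- ids[si]
      an <- as.list(speakers[si, ])
      silence[[sp]] <- list(); series[[sp]] <- list()
      for (pl in planes) {
        fr <- render_phantom_frame(an, phantom_pose("silence"), pl, size)
        if (noise_sd > 0)
          fr <- pmax(fr + matrix(rnorm(length(fr), 0, noise_sd),
                                 nrow(fr)), 0)
        silence[[sp]][[pl]] <- fr
      }
      for (cv in cvs) {
        d <- durations[durations$speaker == sp & durations$cv == cv, ]
        series[[sp]][[cv]] <- list()
        poses <- c(lapply(seq_len(d$n_c) - 1L, function(f)
                     phantom_pose(cv, "C", f / d$n_c)),
                   lapply(seq_len(d$n_v) - 1L, function(f)
                     phantom_pose(cv, "V", f / d$n_v)))
        for (pl in planes) {
          frames <- lapply(poses, function(ps) {
            fr <- render_phantom_frame(an, ps, pl, size)
            if (noise_sd > 0)
              fr <- pmax(fr + matrix(rnorm(length(fr), 0, noise_sd),
                                     nrow(fr)), 0)
            fr
          })
          series[[sp]][[cv]][[pl]] <-
            image_series(frames, fps = fps, speaker_id = sp,
                         cv_label = cv, plane = pl)
          ann_rows[[length(ann_rows) + 1L]] <-
            data.frame(speaker = sp, plane = pl, cv = cv,
                       c_onset = 0L, v_onset = d$n_c,
                       v_offset = d$n_c + d$n_v, stringsAsFactors = FALSE)
        }
      }
      landmarks[[sp]] <- phantom_landmarks(an, size)
      fo <- pmin(pmax((an$scale - 0.85) / 0.30 * 0.75 + 0.25, 0.25), 1)
      visible[[sp]] <- setNames(ifelse(VT_PLANES %in% c("R2", "L2"), fo, 1),
                                VT_PLANES)[planes]
    }
  })
  gt <- list(
    affines = setNames(lapply(seq_len(n_speakers), function(i)
      phantom_forward_affine(as.list(speakers[i, ]), size)), ids),
    durations = durations, landmarks = landmarks,
    visible_fraction = visible, geometry = phantom_geometry())
  structure(list(speakers = speakers[, c("speaker_id", "gender")],
                 anatomy = speakers, silence = silence, series = series,
                 annotations = if (length(ann_rows)) do.call(rbind, ann_rows)
                               else data.frame(
                                 speaker = character(0), plane = character(0),
                                 cv = character(0), c_onset = integer(0),
                                 v_onset = integer(0), v_offset = integer(0)),
                 ground_truth = gt,
                 params = list(n_speakers = n_speakers, cvs = cvs,
                               planes = planes, fps = fps, size = size,
                               seed = seed, anatomy_spread = anatomy_spread,
                               duration_jitter = duration_jitter,
                               noise_sd = noise_sd)),
            class = "vt_cohort")
}

#' @export
print.vt_cohort <- function(x, ...) {
  cat(sprintf("<vt_cohort> %d speakers x %d CVs x %d planes, %dx%d px, seed %d\n",
              nrow(x$speakers), length(x$params$cvs),
              length(x$params$planes), x$params$size, x$params$size,
              x$params$seed))
  invisible(x)
}

#' Write a phantom cohort to a dataset directory
#'
#' NIfTI series plus sidecars, an annotation CSV, and a ground-truth JSON —
#' the on-disk layout the command-line pipeline consumes.
#'
#' @param cohort A [phantom_cohort()] result.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (sp in names(cohort$series)) {
    for (pl in names(cohort$silence[[sp]])) {
      ser <- image_series(list(cohort$silence[[sp]][[pl]]),
                          fps = cohort$params$fps, speaker_id = sp,
                          cv_label = "silence", plane = pl)
      write_series_nifti(ser, file.path(dir, paste0(sp, "_silence_", pl,
                                                    ".nii.gz")))
    }
    for (cv in names(cohort$series[[sp]]))
      for (pl in names(cohort$series[[sp]][[cv]]))
        write_series_nifti(cohort$series[[sp]][[cv]][[pl]],
                           file.path(dir, paste0(sp, "_", cv, "_", pl,
                                                 ".nii.gz")))
  }
  write_annotations(cohort$annotations, file.path(dir, "annotations.csv"))
  jsonlite::write_json(cohort$params, file.path(dir, "params.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
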