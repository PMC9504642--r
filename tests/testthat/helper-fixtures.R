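# Shared fixtures, built once per test run and memoized.  Everything is
# generated in code from fixed seeds; nothing is read from disk.

.fix <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (is.null(.fix[[name]])) .fix[[name]] <- force(expr)
  .fix[[name]]
}

# three varied speakers, silence frames only, midsagittal, 64 px
fix_silence_cohort <- function() memo("sil3", {
  phantom_cohort(n_speakers = 3, cvs = character(0), planes = "M",
                 size = 64, seed = 11)
})

# reference space built from the three silence frames above
fix_reference <- function() memo("ref3", {
  co <- fix_silence_cohort()
  sil <- lapply(setNames(names(co$silence), names(co$silence)),
                function(s) co$silence[[s]]$M)
  build_reference_space(sil, spacing = 12, reg_maxit = 40)
})

# three varied speakers with a /tu/ series, 48 px
fix_dynamic_cohort <- function() memo("dyn3", {
  phantom_cohort(n_speakers = 3, cvs = "tu", planes = "M",
                 size = 48, seed = 7)
})

# eight identical speakers (no anatomy/duration/noise variation), /tu/
fix_identical_cohort <- function() memo("ident8", {
  phantom_cohort(n_speakers = 8, cvs = "tu", planes = "M", size = 48,
                 seed = 5, anatomy_spread = 0, duration_jitter = 0,
                 noise_sd = 0)
})

# pool one CV of a cohort into a global series from raw (unnormalized)
# frames -- adequate wherever anatomical neutrality is irrelevant
raw_global_series <- function(cohort, cv = "tu", plane = "M") {
  dur <- compute_reference_durations(cohort$annotations)
  aligned <- lapply(cohort$speakers$speaker_id, function(sp) {
    ser <- cohort$series[[sp]][[cv]][[plane]]
    ann <- cohort$annotations[cohort$annotations$speaker == sp &
                                cohort$annotations$cv == cv &
                                cohort$annotations$plane == plane, ]
    piecewise_align(ser, segment_annotation(ann$c_onset, ann$v_onset,
                                            ann$v_offset), dur)
  })
  pool_global_series(aligned, cv_label = cv, plane = plane)
}

# brute-force double-loop maximum cross-correlation over all zero-padded
# integer lags: the independent oracle for the frequency-domain version
xcorr_max_bruteforce <- function(X, Y) {
  M <- nrow(X); W <- ncol(X)
  best <- -Inf
  for (k in -(M - 1):(M - 1)) {
    for (l in -(W - 1):(W - 1)) {
      s <- 0
      for (m in seq_len(M)) {
        mm <- m - k
        if (mm < 1 || mm > M) next
        for (w in seq_len(W)) {
          ww <- w - l
          if (ww >= 1 && ww <= W) s <- s + X[m, w] * Y[mm, ww]
        }
      }
      if (s > best) best <- s
    }
  }
  best
}

# dense backward map of an affine over a dim-sized grid (0-based coords)
affine_map_grid <- function(af, dm) {
  X <- rep(0:(dm[2] - 1), each = dm[1])
  Y <- rep(0:(dm[1] - 1), times = dm[2])
  list(x = af$A[1, 1] * X + af$A[1, 2] * Y + af$t[1],
       y = af$A[2, 1] * X + af$A[2, 2] * Y + af$t[2])
}

mean_epe_affine <- function(af_a, af_b, dm) {
  pa <- affine_map_grid(af_a, dm)
  pb <- affine_map_grid(af_b, dm)
  mean(sqrt((pa$x - pb$x)^2 + (pa$y - pb$y)^2))
}

# scaling affine about the image center (backward convention)
centered_scale_affine <- function(s, dm, shift = c(0, 0), rot_deg = 0) {
  cc <- c((dm[2] - 1) / 2, (dm[1] - 1) / 2)
  th <- rot_deg * pi / 180
  A <- s * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  affine_transform(A, cc - as.vector(A %*% cc) + shift)
}
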