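## Automatic division of a feeding sequence into approach, intake, stasis,
## reverse-flow (rf) and backflow (bf) phases from the anteroposterior
## velocity of the water tracers. Frames inside the asymmetric dead band
## (-4.5 to +2 cm/s) are treated as stagnant; the band is asymmetric because
## posterior drift at the approach speed must not trigger a phase.

#' Segmentation configuration
#'
#' @param dead_band_low lower dead-band edge, cm/s (default -4.5): frames with
#'   more negative (posterior) velocity count as moving.
#' @param dead_band_high upper edge, cm/s (default +2).
#' @param min_phase_duration s; runs shorter than this are merged into their
#'   neighbours (default 0.02 s = 15 frames at 750 fps, an order of magnitude
#'   below the shortest real phase).
#' @param intake_fraction the first posterior run whose peak speed reaches
#'   this fraction of the global posterior maximum is the intake (default
#'   0.5); backflows are "similar but slower" posterior runs.
#' @param smoothing_cutoff low-pass cutoff (Hz) applied to positions before
#'   differentiation (default 25; phase dynamics are below ~2.5 Hz).
#' @param segmentation_smoothing additional low-pass cutoff (Hz) applied to
#'   the anteroposterior velocity inside [segment_phases()] only (default
#'   8). Phase boundaries gain from heavier smoothing than the reported
#'   velocities; the boundary refinement models the smoother's corner
#'   response exactly, so the extra smoothing does not bias the knots.
#' @return a list of class `segmentation_config`.
#' @export
segmentation_config <- function(dead_band_low = -4.5, dead_band_high = 2,
                                min_phase_duration = 0.02,
                                intake_fraction = 0.5,
                                smoothing_cutoff = 25,
                                segmentation_smoothing = 8) {
  stopifnot(dead_band_low < 0, dead_band_high > 0, min_phase_duration > 0,
            intake_fraction > 0, intake_fraction <= 1, smoothing_cutoff > 0,
            segmentation_smoothing > 0)
  structure(list(dead_band_low = dead_band_low, dead_band_high = dead_band_high,
                 min_phase_duration = min_phase_duration,
                 intake_fraction = intake_fraction,
                 smoothing_cutoff = smoothing_cutoff,
                 segmentation_smoothing = segmentation_smoothing),
            class = "segmentation_config")
}

#' Velocity of a 3D path
#'
#' Central finite differences on low-pass-smoothed positions, in cm/s.
#' Frames adjacent to interior tracking gaps are flagged invalid; the global
#' series ends use one-sided differences.
#'
#' @param path n-by-3 position matrix (mm), anatomical frame.
#' @param frame_rate frames/s.
#' @param config a [segmentation_config()] (supplies the smoothing cutoff).
#' @return a list of class `velocity_series`: `t` (s), `v` (n-by-3, cm/s),
#'   `valid`, `frame_rate`.
#' @export
compute_velocity <- function(path, frame_rate,
                             config = segmentation_config()) {
  path <- as.matrix(path)
  n <- nrow(path)
  obs <- stats::complete.cases(path)
  if (sum(obs) < 3) stop("fewer than 3 valid frames in path")
  sm <- smooth_positions(path, frame_rate, config$smoothing_cutoff)
  dt <- 1 / frame_rate
  v <- matrix(NA_real_, n, 3)
  valid <- logical(n)
  for (run in na_runs(obs)) {
    i0 <- run[1]; i1 <- run[2]
    if (i1 - i0 < 2) next
    idx <- (i0 + 1):(i1 - 1)
    v[idx, ] <- (sm[idx + 1, , drop = FALSE] - sm[idx - 1, , drop = FALSE]) / (2 * dt)
    valid[idx] <- TRUE
    # run edges: one-sided only at the global sequence ends, invalid at gaps
    if (i0 == 1) {
      v[i0, ] <- (sm[i0 + 1, ] - sm[i0, ]) / dt
      valid[i0] <- TRUE
    }
    if (i1 == n) {
      v[i1, ] <- (sm[i1, ] - sm[i1 - 1, ]) / dt
      valid[i1] <- TRUE
    }
  }
  v <- mm_per_s_to_cm_per_s(v)
  colnames(v) <- c("x", "y", "z")
  structure(list(t = (seq_len(n) - 1) * dt, v = v, valid = valid,
                 frame_rate = frame_rate), class = "velocity_series")
}

#' Mean anteroposterior water-tracer velocity
#'
#' Per-frame mean and sample SD of the anteroposterior (x) velocity across
#' all water tracers with a valid velocity at that frame. Frames with no
#' valid tracer are flagged invalid.
#'
#' @param ts an anatomical-frame [trajectory_set()].
#' @param config a [segmentation_config()].
#' @return a list of class `velocity_series` with elements `t`, `mean`, `sd`,
#'   `n_valid`, `valid`, `frame_rate` (`$v` is the mean, as a 1-column
#'   matrix, so the object can be segmented directly).
#' @export
aggregate_water_velocity <- function(ts, config = segmentation_config()) {
  stopifnot(inherits(ts, "trajectory_set"))
  water <- tracks_of_kind(ts, "water_tracer")
  if (length(water) == 0) stop("no water tracers in trajectory set")
  nfr <- n_frames(ts)
  ap <- matrix(NA_real_, nfr, length(water))
  for (j in seq_along(water)) {
    vsj <- tryCatch(compute_velocity(water[[j]], ts$frame_rate, config),
                    error = function(e) NULL)
    if (is.null(vsj)) next
    ap[vsj$valid, j] <- vsj$v[vsj$valid, 1]
  }
  n_valid <- rowSums(!is.na(ap))
  m <- ifelse(n_valid > 0, rowMeans(ap, na.rm = TRUE), NA_real_)
  s <- apply(ap, 1, function(r) {
    r <- r[!is.na(r)]
    if (length(r) >= 2) stats::sd(r) else if (length(r) == 1) 0 else NA_real_
  })
  structure(list(t = time_axis(ts), mean = m, sd = s, n_valid = n_valid,
                 valid = n_valid > 0, v = matrix(m, ncol = 1),
                 frame_rate = ts$frame_rate), class = "velocity_series")
}

ap_component <- function(vs) {
  if (!is.null(vs$mean)) vs$mean else vs$v[, 1]
}

#' Segment a feeding sequence into phases
#'
#' Frames are classified posterior (`v < dead_band_low`), anterior
#' (`v > dead_band_high`) or stagnant; runs shorter than
#' `min_phase_duration` are merged into their neighbours. The first posterior
#' run whose peak speed reaches `intake_fraction` of the global posterior
#' maximum is the intake; slow posterior drift before it is the approach;
#' later anterior runs are reverse flows (rf) and posterior runs backflows
#' (bf); the remainder is stasis. Phase onsets and offsets are then refined
#' from the dead-band crossing to the underlying velocity knot by a local
#' quadratic-departure fit (see Details).
#'
#' Details: a smooth velocity pulse leaves its baseline with zero slope, so
#' any fixed threshold is crossed O(sqrt(threshold)) late. For each run edge
#' the square root of the baseline-referenced excursion — which is linear in
#' time for a locally quadratic departure — is regressed over the pulse
#' flank and extrapolated to zero. Step-like onsets leave too few flank
#' samples for the fit and keep the raw crossing.
#'
#' If no run exceeds the dead band the whole sequence is returned as a single
#' stasis interval with attribute `"warning"` set.
#'
#' @param vs a `velocity_series` ([compute_velocity()] output, or
#'   [aggregate_water_velocity()] for the cross-tracer mean — the default
#'   analysis path).
#' @param config a [segmentation_config()].
#' @return a data frame of class `phase_table`: `label` (approach | intake |
#'   stasis | rf | bf), `start_time`, `end_time` (s), `peak_ap_velocity`
#'   (cm/s).
#' @export
segment_phases <- function(vs, config = segmentation_config()) {
  stopifnot(inherits(vs, "velocity_series"))
  v <- lowpass(ap_component(vs), vs$frame_rate, config$segmentation_smoothing)
  t <- vs$t
  n <- length(v)
  dt <- 1 / vs$frame_rate
  if (sum(vs$valid) * dt < config$min_phase_duration) {
    stop("velocity series valid on less than min_phase_duration")
  }
  cls <- integer(n)                       # 0 stasis, -1 posterior, +1 anterior
  cls[vs$valid & !is.na(v) & v < config$dead_band_low] <- -1L
  cls[vs$valid & !is.na(v) & v > config$dead_band_high] <- 1L

  min_len <- max(1L, round(config$min_phase_duration * vs$frame_rate))
  cls <- merge_short_runs(cls, min_len)

  r <- rle(cls)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- data.frame(start = starts, end = ends, class = r$values)

  active <- which(runs$class != 0L)
  if (length(active) == 0) {
    out <- phase_table(data.frame(
      label = "stasis", start_time = t[1], end_time = t[n],
      peak_ap_velocity = peak_signed(v, seq_len(n))))
    attr(out, "warning") <- "no run exceeds the dead band"
    return(out)
  }

  post <- active[runs$class[active] == -1L]
  gmax <- if (length(post)) {
    max(vapply(post, function(k) max(-v[runs$start[k]:runs$end[k]], na.rm = TRUE),
               numeric(1)))
  } else -Inf
  intake_k <- NA_integer_
  for (k in post) {
    if (max(-v[runs$start[k]:runs$end[k]], na.rm = TRUE) >=
        config$intake_fraction * gmax) {
      intake_k <- k
      break
    }
  }

  label_of <- function(k) {
    if (!is.na(intake_k) && k == intake_k) return("intake")
    if (!is.na(intake_k) && k < intake_k) {
      return(if (runs$class[k] == -1L) "approach" else "rf")
    }
    if (runs$class[k] == -1L) "bf" else "rf"
  }

  # refine each active run edge toward the velocity knot
  iv <- list()
  for (k in active) {
    lab <- label_of(k)
    s_idx <- runs$start[k]; e_idx <- runs$end[k]
    sgn <- runs$class[k]
    prev_act <- max(c(0, active[active < k]))
    next_act <- min(c(length(r$values) + 1, active[active > k]))
    lo_lim <- if (prev_act > 0) runs$end[prev_act] + 1 else 1
    hi_lim <- if (next_act <= length(r$values)) runs$start[next_act] - 1 else n
    # water at rest in the anatomical frame has zero velocity, so every edge
    # baseline is 0 except ahead of the intake, where the approach plateau
    # (swimming speed) is estimated from the data
    base_start <- if (prev_act == 0 || (!is.na(intake_k) && k == intake_k)) {
      NA_real_
    } else 0
    t_start <- refine_edge(v, t, s_idx, e_idx, sgn, "start", lo_lim, config,
                           baseline = base_start)
    t_end <- refine_edge(v, t, s_idx, e_idx, sgn, "end", hi_lim, config,
                         baseline = 0)
    iv[[length(iv) + 1]] <- data.frame(
      label = lab, start_time = t_start, end_time = t_end,
      peak_ap_velocity = if (sgn == -1L) {
        min(v[s_idx:e_idx], na.rm = TRUE)
      } else max(v[s_idx:e_idx], na.rm = TRUE))
  }
  iv <- do.call(rbind, iv)
  iv <- iv[order(iv$start_time), , drop = FALSE]
  # clip any refinement overlap at the midpoint
  if (nrow(iv) > 1) {
    for (k in seq_len(nrow(iv) - 1)) {
      if (iv$end_time[k] > iv$start_time[k + 1]) {
        mid <- (iv$end_time[k] + iv$start_time[k + 1]) / 2
        iv$end_time[k] <- mid
        iv$start_time[k + 1] <- mid
      }
    }
  }

  # assemble with approach / stasis filler intervals
  rows <- list()
  cursor <- t[1]
  intake_start <- if (!is.na(intake_k)) {
    iv$start_time[iv$label == "intake"][1]
  } else NA_real_
  for (k in seq_len(nrow(iv))) {
    if (iv$start_time[k] - cursor > dt / 2) {
      gap_idx <- which(t >= cursor & t <= iv$start_time[k])
      gap_lab <- if (!is.na(intake_start) && iv$start_time[k] <= intake_start &&
                     mean(v[gap_idx], na.rm = TRUE) < 0) "approach" else "stasis"
      rows[[length(rows) + 1]] <- data.frame(
        label = gap_lab, start_time = cursor, end_time = iv$start_time[k],
        peak_ap_velocity = peak_signed(v, gap_idx))
    }
    rows[[length(rows) + 1]] <- iv[k, ]
    cursor <- iv$end_time[k]
  }
  if (t[n] - cursor > dt / 2) {
    gap_idx <- which(t >= cursor)
    rows[[length(rows) + 1]] <- data.frame(
      label = "stasis", start_time = cursor, end_time = t[n],
      peak_ap_velocity = peak_signed(v, gap_idx))
  }
  out <- do.call(rbind, rows)
  # a pre-intake approach run followed by an approach filler (or vice versa)
  # is one approach phase
  out <- merge_adjacent_same_label(out)
  rownames(out) <- NULL
  phase_table(out)
}

peak_signed <- function(v, idx) {
  vv <- v[idx]
  vv <- vv[!is.na(vv)]
  if (!length(vv)) return(NA_real_)
  vv[which.max(abs(vv))]
}

merge_adjacent_same_label <- function(df) {
  keep <- rep(TRUE, nrow(df))
  for (k in seq_len(nrow(df))[-1]) {
    prev <- max(which(keep[seq_len(k - 1)]))
    if (df$label[k] == df$label[prev]) {
      df$end_time[prev] <- df$end_time[k]
      df$peak_ap_velocity[prev] <- if (abs(df$peak_ap_velocity[k]) >
                                       abs(df$peak_ap_velocity[prev])) {
        df$peak_ap_velocity[k]
      } else df$peak_ap_velocity[prev]
      keep[k] <- FALSE
    }
  }
  df[keep, , drop = FALSE]
}

phase_table <- function(df) {
  df$label <- as.character(df$label)
  class(df) <- c("phase_table", "data.frame")
  df
}

# iteratively absorb runs shorter than min_len into their longer neighbour
merge_short_runs <- function(cls, min_len) {
  repeat {
    r <- rle(cls)
    if (length(r$lengths) <= 1) return(cls)
    short <- which(r$lengths < min_len)
    if (!length(short)) return(cls)
    k <- short[which.min(r$lengths[short])]
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    nb <- if (k == 1) {
      k + 1
    } else if (k == length(r$lengths)) {
      k - 1
    } else if (r$lengths[k - 1] >= r$lengths[k + 1]) k - 1 else k + 1
    cls[starts[k]:ends[k]] <- r$values[nb]
  }
}

# Extrapolate a run edge from dead-band crossing back to the velocity knot.
# v: full velocity vector; [s_idx, e_idx] the run; sgn its class sign;
# lim: furthest frame the refined edge may move into (adjacent stagnant zone).
refine_edge <- function(v, t, s_idx, e_idx, sgn, side, lim, config,
                        baseline = 0) {
  n <- length(v)
  dtf <- t[2] - t[1]
  exc <- function(i, b) sgn * (v[i] - b)         # positive excursion in-pulse
  ip <- (s_idx:e_idx)[which.max(exc(s_idx:e_idx, 0))]   # run peak
  if (side == "start") {
    base_idx <- seq(lim, max(lim, s_idx - 3))
    scan <- seq(ip, lim)                          # peak outward, backwards
    edge_t <- t[s_idx] - dtf / 2
  } else {
    base_idx <- seq(min(lim, e_idx + 3), lim)
    scan <- seq(ip, lim)                          # peak outward, forwards
    edge_t <- t[e_idx] + dtf / 2
  }
  # baseline: fixed (0 in the anatomical frame) unless NA, in which case the
  # pre-intake plateau — the swimming speed, which may itself exceed the
  # dead band and then belongs to the run — is estimated from the outer part
  # of the pre-run region and scan tail
  noise <- 0
  if (is.na(baseline)) {
    bvals <- v[base_idx]
    tailq <- v[scan[seq(ceiling(0.75 * length(scan)), length(scan))]]
    bvals <- c(bvals, tailq)
    bvals <- bvals[!is.na(bvals)]
    if (length(bvals) >= 10) {
      b <- stats::median(bvals)
      noise <- stats::mad(bvals)
    } else {
      b <- 0
    }
  } else {
    b <- baseline
  }
  peak <- max(exc(s_idx:e_idx, b), na.rm = TRUE)
  hi <- 0.4 * peak    # the quartic-corrected flank model holds to ~1% here
  sig <- sqrt(gaussian_sigma_for_cutoff(config$smoothing_cutoff)^2 +
                gaussian_sigma_for_cutoff(config$segmentation_smoothing)^2)
  dtf2 <- dtf
  ex <- exc(scan, b)

  # window: from where the excursion drops to `hi` (coming from the peak)
  # to a few smoothing widths past the first sub-noise-floor sample
  istart <- which(!is.na(ex) & ex <= hi)[1]
  jcross <- which(!is.na(ex) & ex < max(0.3, 2 * noise))[1]
  if (is.na(istart) || is.na(jcross) || jcross <= istart) return(edge_t)
  iend <- min(length(scan), jcross + ceiling(3 * sig / dtf2) + 5)
  W <- istart:iend
  yw <- ex[W]
  tw <- t[scan[W]]
  ok <- !is.na(yw)
  yw <- yw[ok]; tw <- tw[ok]
  if (length(yw) < 5) return(edge_t)

  # exact model: a one-sided quadratic flank c * max(tau, 0)^2 convolved
  # with the Gaussian smoother has closed form
  #   m(tau) = (tau^2 + sig^2) Phi(tau/sig) + tau sig phi(tau/sig).
  # A contiguous opposite-sign pulse sharing the knot (an rf/bf junction)
  # contributes -c2 * m(-tau), so both amplitudes are solved linearly while
  # the knot t0 is grid-searched.
  m_fun <- function(tau) {
    a <- tau / sig
    (tau^2 + sig^2) * stats::pnorm(a) + tau * sig * stats::dnorm(a)
  }
  # smoothed one-sided quartic max(tau,0)^4: corrects the next Taylor term
  # of a raised-cosine flank (sin^2 x = x^2 - x^4/3 + ...)
  m4_fun <- function(tau) {
    a <- tau / sig
    sig^4 * ((a^4 + 6 * a^2 + 3) * stats::pnorm(a) +
               (a^3 + 5 * a) * stats::dnorm(a))
  }
  tau_of <- if (side == "start") {
    function(t0) tw - t0
  } else {
    function(t0) t0 - tw
  }
  # uniform weights: the velocity noise is homoscedastic and the quartic
  # correction absorbs the flank's model error
  wts <- rep(1, length(yw))
  # pulse duration implied by the run length, given that a cosine-like pulse
  # of peak `peak` spends 2 asin(sqrt(theta/peak))/pi of its duration below
  # the classification threshold theta; fixes the quartic/quadratic ratio
  theta <- if (sgn == -1L) {
    max(b - config$dead_band_low, 0.1)
  } else {
    max(config$dead_band_high - b, 0.1)
  }
  run_len <- t[e_idx] - t[s_idx] + dtf2
  frac <- min(max(theta / peak, 1e-3), 0.9)
  D_hat <- run_len / max(1 - 2 * asin(sqrt(frac)) / pi, 0.2)
  k4 <- (pi / D_hat)^2 / 3
  t_ref <- t[scan[jcross]]
  cand <- if (side == "start") {
    t_ref + seq(-0.08, 0.04, by = dtf2)
  } else {
    t_ref + seq(-0.04, 0.08, by = dtf2)
  }
  # LS over sign-constrained bases: the corrected flank model and, for a
  # contiguous opposite-sign pulse sharing the knot (rf/bf junction), its
  # mirror; a negative mirror coefficient drops that basis
  flank <- function(tau) m_fun(tau) - k4 * m4_fun(tau)
  sse <- vapply(cand, function(t0) {
    tau <- tau_of(t0)
    m1 <- flank(tau)
    m2 <- flank(-tau)
    s11 <- sum(wts * m1^2); s22 <- sum(wts * m2^2); s12 <- sum(wts * m1 * m2)
    c1 <- c2 <- 0
    det2 <- s11 * s22 - s12^2
    if (s22 > 1e-9 * s11 && det2 > 1e-12 * s11 * s22) {
      b1 <- sum(wts * yw * m1); b2 <- sum(wts * yw * m2)
      c1 <- (b1 * s22 - b2 * s12) / det2           # y ~ c1 m1 - c2 m2
      c2 <- -(b2 * s11 - b1 * s12) / det2
    }
    if (c2 < 0 || c1 <= 0) {                       # fall back to single flank
      c1 <- sum(wts * yw * m1) / max(s11, 1e-300)
      c2 <- 0
    }
    if (c1 <= 0) return(Inf)
    sum(wts * (yw - c1 * m1 + c2 * m2)^2)
  }, numeric(1))
  j <- which.min(sse)
  if (!is.finite(sse[j])) return(edge_t)
  t0 <- cand[j]
  if (j > 1 && j < length(cand) && is.finite(sse[j - 1]) &&
      is.finite(sse[j + 1])) {
    den <- sse[j - 1] - 2 * sse[j] + sse[j + 1]
    if (den > 0) t0 <- t0 + dtf2 / 2 * (sse[j - 1] - sse[j + 1]) / den
  }
  if (side == "start") {
    min(max(t0, t[lim]), t[scan[istart]])
  } else {
    max(min(t0, t[lim]), t[scan[istart]])
  }
}

#' Periodicity of reverse-flow / backflow transitions
#'
#' Times of transitions between successive rf and bf phases (midpoint of the
#' stagnant gap separating them, or the shared boundary when contiguous), and
#' the mean and SD of the intervals between successive transitions.
#'
#' @param pt a `phase_table`.
#' @return list: `mean` (s), `sd` (s), `n` (number of intervals),
#'   `transitions` (times).
#' @export
transition_periodicity <- function(pt) {
  stopifnot(inherits(pt, "phase_table"))
  hb <- pt[pt$label %in% c("rf", "bf"), , drop = FALSE]
  trans <- c()
  if (nrow(hb) >= 2) {
    for (k in seq_len(nrow(hb) - 1)) {
      if (hb$label[k] != hb$label[k + 1]) {
        trans <- c(trans, (hb$end_time[k] + hb$start_time[k + 1]) / 2)
      }
    }
  }
  if (length(trans) < 2) {
    stop("fewer than 2 rf/bf transitions in phase table")
  }
  iv <- diff(trans)
  list(mean = mean(iv), sd = if (length(iv) >= 2) stats::sd(iv) else 0,
       n = length(iv), transitions = trans)
}

#' Boundary times of a phase table
#'
#' Sorted unique start/end times of all phases — convenient for comparing a
#' detected table against ground truth.
#'
#' @param pt a `phase_table`.
#' @param labels optionally restrict to these phase labels.
#' @return numeric vector of times (s).
#' @export
phase_boundaries <- function(pt, labels = NULL) {
  if (!is.null(labels)) pt <- pt[pt$label %in% labels, , drop = FALSE]
  sort(unique(round(c(pt$start_time, pt$end_time), 9)))
}
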