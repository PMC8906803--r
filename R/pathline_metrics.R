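## Path-geometry statistics separating water from food: dorsoventral-plane
## (x,z) Menger curvature binned along the standardized anteroposterior
## trajectory, per-phase travel distances, Kendall positional correlations
## and flow-pattern labels.

#' Menger curvature of a path in the dorsoventral plane
#'
#' For each interior frame, the three consecutive positions are projected to
#' the (x, z) plane and the curvature of their circumcircle is returned:
#' kappa = 4 * Area / (|ab| |bc| |ca|), in 1/mm. Because frame-to-frame
#' measurement noise (about +/- 0.1 mm) dominates three-point circumcircles
#' at 750 frames/s, the path is low-pass smoothed before the computation; the
#' default cutoff (6 Hz) is well below the velocity-smoothing cutoff because
#' curvature differentiates the path twice (its noise floor grows with the
#' 2.5th power of the bandwidth), while the intraoral path geometry itself
#' evolves on the pulse timescale (under ~4 Hz).
#'
#' @param path n-by-3 anatomical positions (mm).
#' @param frame_rate frames/s (needed when `smooth_cutoff` is finite).
#' @param smooth_cutoff low-pass cutoff in Hz, or `Inf` for the raw path.
#' @return numeric vector of per-frame curvatures (1/mm); `NA` at the ends,
#'   at missing samples and where two of the three points coincide.
#' @export
menger_curvature <- function(path, frame_rate = 750, smooth_cutoff = 6) {
  path <- as.matrix(path)
  n <- nrow(path)
  if (n < 3) stop("path shorter than 3 frames")
  if (sum(stats::complete.cases(path)) < 3) stop("fewer than 3 valid frames")
  sm <- smooth_positions(path, frame_rate, smooth_cutoff)
  a <- sm[1:(n - 2), c(1, 3), drop = FALSE]
  b <- sm[2:(n - 1), c(1, 3), drop = FALSE]
  ce <- sm[3:n, c(1, 3), drop = FALSE]
  ab <- sqrt(rowSums((b - a)^2))
  bc <- sqrt(rowSums((ce - b)^2))
  ca <- sqrt(rowSums((a - ce)^2))
  # twice the signed triangle area via the 2D cross product
  cross <- (b[, 1] - a[, 1]) * (ce[, 2] - a[, 2]) -
    (b[, 2] - a[, 2]) * (ce[, 1] - a[, 1])
  area <- abs(cross) / 2
  kappa <- 4 * area / (ab * bc * ca)
  kappa[ab == 0 | bc == 0 | ca == 0] <- NA_real_
  c(NA_real_, kappa, NA_real_)
}

#' Maximum curvature per standardized anteroposterior interval
#'
#' The anteroposterior coordinate is standardized to the percentage of the
#' tracer's own trajectory (0% at the start, 100% at the end of the supplied
#' samples) and the maximum curvature is taken in each of `n_bins` equal
#' percentage intervals.
#'
#' @param kappa per-frame curvature series (1/mm), as from
#'   [menger_curvature()].
#' @param x_positions aligned anteroposterior coordinates (mm).
#' @param n_bins number of intervals (default 10).
#' @param tracer optional tracer name carried on the result.
#' @return a data frame of class `curvature_profile`: `tracer`, `bin_lo`,
#'   `bin_hi` (%), `max_curvature` (1/mm, `NA` for empty bins).
#' @export
interval_max_curvature <- function(kappa, x_positions, n_bins = 10,
                                   tracer = NA_character_) {
  stopifnot(length(kappa) == length(x_positions), n_bins >= 1)
  ok <- !is.na(x_positions)
  if (!any(ok)) stop("no valid anteroposterior positions")
  x0 <- x_positions[ok][1]
  x1 <- x_positions[ok][length(x_positions[ok])]
  if (abs(x1 - x0) < 1e-9) stop("zero anteroposterior span: degenerate path")
  pct <- (x_positions - x0) / (x1 - x0) * 100
  pct <- pmin(pmax(pct, 0), 100)
  edges <- seq(0, 100, length.out = n_bins + 1)
  bin <- pmin(findInterval(pct, edges, rightmost.closed = TRUE), n_bins)
  mx <- rep(NA_real_, n_bins)
  for (bidx in seq_len(n_bins)) {
    kk <- kappa[which(bin == bidx)]
    kk <- kk[!is.na(kk)]
    if (length(kk)) mx[bidx] <- max(kk)
  }
  structure(data.frame(tracer = tracer, bin_lo = edges[-length(edges)],
                       bin_hi = edges[-1], max_curvature = mx),
            class = c("curvature_profile", "data.frame"))
}

#' Compare water and food path curvature
#'
#' Kruskal-Wallis rank-sum test on the per-interval maximum curvatures of the
#' two tracer groups. `pooled` mode (default) pools all interval maxima of
#' each group into one comparison; `per_interval` mode tests each interval
#' separately and returns one result per interval.
#'
#' @param water list of `curvature_profile`s (or one) for water tracers.
#' @param food same for food tracers.
#' @param mode `"pooled"` or `"per_interval"`.
#' @return for `pooled`, a list of class `test_result`: `statistic` (H),
#'   `p_value`, `method`, `n` (group sizes), `median_water`, `median_food`,
#'   `direction`. For `per_interval`, a data frame with one row per interval.
#' @export
compare_curvature <- function(water, food, mode = c("pooled", "per_interval")) {
  mode <- match.arg(mode)
  as_list <- function(x) if (inherits(x, "curvature_profile")) list(x) else x
  water <- as_list(water)
  food <- as_list(food)
  pull <- function(profiles, bin = NULL) {
    vals <- unlist(lapply(profiles, function(p) {
      if (is.null(bin)) p$max_curvature else p$max_curvature[bin]
    }))
    vals[!is.na(vals)]
  }
  run_test <- function(w, f) {
    if (length(w) < 2 || length(f) < 2) stop("need >= 2 observations per group")
    kt <- stats::kruskal.test(list(water = w, food = f))
    structure(list(statistic = unname(kt$statistic), p_value = kt$p.value,
                   method = "Kruskal-Wallis rank-sum test",
                   n = c(water = length(w), food = length(f)),
                   median_water = stats::median(w),
                   median_food = stats::median(f),
                   direction = if (stats::median(w) > stats::median(f)) {
                     "water > food"
                   } else "water <= food"),
              class = "test_result")
  }
  if (mode == "pooled") return(run_test(pull(water), pull(food)))
  n_bins <- nrow(water[[1]])
  do.call(rbind, lapply(seq_len(n_bins), function(bidx) {
    res <- tryCatch(run_test(pull(water, bidx), pull(food, bidx)),
                    error = function(e) NULL)
    data.frame(bin_lo = water[[1]]$bin_lo[bidx], bin_hi = water[[1]]$bin_hi[bidx],
               statistic = if (is.null(res)) NA_real_ else res$statistic,
               p_value = if (is.null(res)) NA_real_ else res$p_value)
  }))
}

#' Per-phase travel distance and normalized displacement components
#'
#' For each phase interval: the summed frame-to-frame 3D step length, and the
#' per-axis summed absolute steps expressed as percentages of the three-axis
#' total (components sum to 100% where the distance is positive). Phases with
#' fewer than two valid frames are omitted with a warning.
#'
#' @param path n-by-3 anatomical positions (mm).
#' @param pt a `phase_table`.
#' @param t time axis (s) aligned with `path`; defaults to 750 fps from 0.
#' @return data frame: `label`, `start_time`, `end_time`,
#'   `total_distance_mm`, `comp_x_pct`, `comp_y_pct`, `comp_z_pct`.
#' @export
phase_distance <- function(path, pt, t = NULL) {
  path <- as.matrix(path)
  if (is.null(t)) t <- (seq_len(nrow(path)) - 1) / 750
  rows <- list()
  for (k in seq_len(nrow(pt))) {
    idx <- which(t >= pt$start_time[k] & t <= pt$end_time[k] &
                   stats::complete.cases(path))
    if (length(idx) < 2) {
      warning("phase '", pt$label[k], "' has fewer than 2 valid frames; omitted")
      next
    }
    steps <- diff(path[idx, , drop = FALSE])
    total <- sum(sqrt(rowSums(steps^2)))
    axis_abs <- colSums(abs(steps))
    comp <- if (sum(axis_abs) > 0) axis_abs / sum(axis_abs) * 100 else rep(NA_real_, 3)
    rows[[length(rows) + 1]] <- data.frame(
      label = pt$label[k], start_time = pt$start_time[k],
      end_time = pt$end_time[k], total_distance_mm = total,
      comp_x_pct = comp[1], comp_y_pct = comp[2], comp_z_pct = comp[3])
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(label = character(), start_time = numeric(),
               end_time = numeric(), total_distance_mm = numeric(),
               comp_x_pct = numeric(), comp_y_pct = numeric(),
               comp_z_pct = numeric())
  rownames(out) <- NULL
  out
}

#' Kendall correlation of tracer positions across the intake
#'
#' Over the water tracers, correlates either the lateromedial position at the
#' beginning vs the end of the intake (`z_begin_vs_z_end`, side preservation)
#' or the anteroposterior position at 25% of the intake duration vs the final
#' lateromedial position (`x25_vs_z_end`, ingestion-timing effect). Kendall's
#' tau-b with the usual tie handling.
#'
#' @param ts anatomical-frame [trajectory_set()].
#' @param pt a `phase_table` containing an intake.
#' @param spec `"z_begin_vs_z_end"` or `"x25_vs_z_end"`.
#' @return a list of class `test_result`: `statistic` (tau), `p_value`,
#'   `method`, `n`, and the paired coordinates in `pairs`.
#' @export
positional_correlation <- function(ts, pt,
                                   spec = c("z_begin_vs_z_end", "x25_vs_z_end")) {
  spec <- match.arg(spec)
  stopifnot(inherits(ts, "trajectory_set"))
  intake <- pt[pt$label == "intake", , drop = FALSE]
  if (nrow(intake) == 0) stop("no intake phase in table")
  t <- time_axis(ts)
  t0 <- intake$start_time[1]
  t1 <- intake$end_time[1]
  t25 <- t0 + 0.25 * (t1 - t0)
  at_time <- function(p, tq) {
    i <- which.min(abs(t - tq))
    p[i, ]
  }
  water <- tracks_of_kind(ts, "water_tracer")
  a <- b <- rep(NA_real_, length(water))
  for (j in seq_along(water)) {
    p <- water[[j]]
    zb <- at_time(p, t0)[3]
    ze <- at_time(p, t1)[3]
    x25 <- at_time(p, t25)[1]
    if (spec == "z_begin_vs_z_end") {
      a[j] <- zb; b[j] <- ze
    } else {
      a[j] <- x25; b[j] <- ze
    }
  }
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 3) stop("fewer than 3 water tracers with both endpoints defined")
  ct <- suppressWarnings(stats::cor.test(a[ok], b[ok], method = "kendall"))
  structure(list(statistic = unname(ct$estimate), p_value = ct$p.value,
                 method = paste("Kendall tau-b,", spec), n = sum(ok),
                 pairs = data.frame(a = a[ok], b = b[ok])),
            class = "test_result")
}

#' Classify a tracer's intake flow pattern
#'
#' Heuristic labels for the three intraoral flow archetypes. A sustained
#' (`>= min_duration`) positive anteroposterior velocity segment after mouth
#' entry is the signature of the anterior return flow of a central jet
#' (`anterior_return`); a net medial shift — final |z| below
#' `(1 - medial_fraction)` of the intake-maximum |z| while the tracer moves
#' posteriorly — is the crossflow signature (`posteromedial`); everything
#' else is plain diverging `posterior` flow. The thresholds are analysis
#' heuristics exposed as arguments.
#'
#' @param path n-by-3 anatomical positions (mm) of one tracer.
#' @param pt a `phase_table` containing an intake.
#' @param cavity_halfwidth mm; |z| must exceed this fraction context to count
#'   as having been lateral (entry check uses `x` only).
#' @param frame_rate frames/s.
#' @param min_duration s, sustained-segment duration (default 0.02).
#' @param medial_fraction fraction of the maximum |z| that must be shed to
#'   count as posteromedial (default 0.5).
#' @param config a [segmentation_config()] for the velocity smoothing.
#' @return one of `"posterior"`, `"anterior_return"`, `"posteromedial"`.
#' @export
classify_flow_pattern <- function(path, pt, cavity_halfwidth = 25,
                                  frame_rate = 750, min_duration = 0.02,
                                  medial_fraction = 0.5,
                                  config = segmentation_config()) {
  intake <- pt[pt$label == "intake", , drop = FALSE]
  if (nrow(intake) == 0) stop("no intake phase in table")
  path <- as.matrix(path)
  t <- (seq_len(nrow(path)) - 1) / frame_rate
  vs <- compute_velocity(path, frame_rate, config)
  # window: intake extended by half the intake duration to catch the return leg
  t1 <- intake$end_time[1] + 0.5 * (intake$end_time[1] - intake$start_time[1])
  win <- which(t >= intake$start_time[1] & t <= t1)
  win <- win[vs$valid[win] & stats::complete.cases(path[win, , drop = FALSE])]
  if (length(win) < 3) stop("path not valid during intake")
  vx <- vs$v[win, 1]
  # anterior return: sustained positive AP velocity after mouth entry
  entered <- path[win, 1] < max(path[win, 1], na.rm = TRUE) - 1e-9
  pos <- vx > config$dead_band_high & entered
  min_len <- max(1L, round(min_duration * frame_rate))
  runs <- rle(pos)
  if (any(runs$values & runs$lengths >= min_len)) return("anterior_return")
  z <- path[win, 3]
  x <- path[win, 1]
  zmax <- max(abs(z))
  zfin <- abs(z[length(z)])
  if (zmax > 0.05 * cavity_halfwidth &&
      zfin < (1 - medial_fraction) * zmax &&
      x[length(x)] < x[1]) {
    return("posteromedial")
  }
  "posterior"
}
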