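## Gape, hyoid depression and opercula abduction traces from anatomical-frame
## locator trajectories, and the phase-wise ordering of their peaks. During
## the intake the canonical order is gape -> hyoid -> opercula (an anterior-
## to-posterior expansion wave); during reverse flows it is inverted.

kinematic_trace <- function(variable, t, value, rest = NA_real_) {
  structure(list(variable = variable, t = t, value = value, rest = rest),
            class = "kinematic_trace")
}

#' Gape trace
#'
#' Per-frame 3D Euclidean distance between the upper- and lower-jaw tip
#' locators (mm). Symmetric in its two arguments.
#'
#' @param upper_jaw_tip,lower_jaw_tip n-by-3 anatomical positions (mm).
#' @param frame_rate frames/s.
#' @return a `kinematic_trace` (variable `"gape"`).
#' @export
gape_trace <- function(upper_jaw_tip, lower_jaw_tip, frame_rate = 750) {
  u <- as.matrix(upper_jaw_tip)
  l <- as.matrix(lower_jaw_tip)
  stopifnot(nrow(u) == nrow(l))
  d <- sqrt(rowSums((u - l)^2))
  if (all(is.na(d))) stop("jaw tip series do not overlap")
  kinematic_trace("gape", (seq_len(nrow(u)) - 1) / frame_rate, d)
}

rest_mean <- function(t, value, rest_window) {
  idx <- which(t >= rest_window[1] & t <= rest_window[2] & !is.na(value))
  if (!length(idx)) stop("empty rest window")
  mean(value[idx])
}

#' Hyoid depression trace
#'
#' Ventral excursion of the hyoid tip: (rest mean y) - y(t), positive when
#' the hyoid drops below its rest height. The rest reference is the mean over
#' `rest_window` (conventionally the approach phase).
#'
#' @param hyoid_tip n-by-3 anatomical positions (mm).
#' @param rest_window c(start, end) in seconds.
#' @param frame_rate frames/s.
#' @return a `kinematic_trace` (variable `"hyoid_depression"`).
#' @export
hyoid_depression_trace <- function(hyoid_tip, rest_window, frame_rate = 750) {
  p <- as.matrix(hyoid_tip)
  t <- (seq_len(nrow(p)) - 1) / frame_rate
  rest <- rest_mean(t, p[, 2], rest_window)
  kinematic_trace("hyoid_depression", t, rest - p[, 2], rest)
}

#' Opercula abduction trace
#'
#' Lateral excursion of the operculum tip from the midsagittal plane:
#' |z(t)| - (rest mean |z|), positive when abducted beyond rest.
#'
#' @param operculum_tip n-by-3 anatomical positions (mm).
#' @param rest_window c(start, end) in seconds.
#' @param frame_rate frames/s.
#' @return a `kinematic_trace` (variable `"opercula_abduction"`).
#' @export
opercula_abduction_trace <- function(operculum_tip, rest_window,
                                     frame_rate = 750) {
  p <- as.matrix(operculum_tip)
  t <- (seq_len(nrow(p)) - 1) / frame_rate
  absz <- abs(p[, 3])
  rest <- rest_mean(t, absz, rest_window)
  kinematic_trace("opercula_abduction", t, absz - rest, rest)
}

#' Ordered kinematic peaks within a phase
#'
#' For each trace, the time of its maximum inside the phase window; variables
#' are returned sorted by peak time, with an order label: `intake_like` for
#' the canonical gape -> hyoid depression -> opercula abduction sequence,
#' `rf_like` for the inverted sequence, `other` otherwise (including when a
#' trace is entirely missing in the phase).
#'
#' @param traces list of the three `kinematic_trace`s.
#' @param pt a `phase_table`.
#' @param phase phase label to analyse (`"intake"`, `"rf"`, ...). If several
#'   phases share the label, `which` selects the instance (default 1).
#' @param which instance index among phases with that label.
#' @return a list of class `peak_sequence`: `phase`, `order` (data frame
#'   variable/peak_time/peak_value sorted by time), `label`.
#' @export
peak_sequence <- function(traces, pt, phase, which = 1) {
  rows <- pt[pt$label == phase, , drop = FALSE]
  if (nrow(rows) < which) stop("phase '", phase, "' (instance ", which,
                               ") not present in table")
  w <- rows[which, ]
  res <- list()
  for (tr in traces) {
    idx <- base::which(tr$t >= w$start_time & tr$t <= w$end_time & !is.na(tr$value))
    if (!length(idx)) next
    i <- idx[base::which.max(tr$value[idx])]
    res[[length(res) + 1]] <- data.frame(variable = tr$variable,
                                         peak_time = tr$t[i],
                                         peak_value = tr$value[i])
  }
  ord <- if (length(res)) {
    o <- do.call(rbind, res)
    o[order(o$peak_time), , drop = FALSE]
  } else {
    data.frame(variable = character(), peak_time = numeric(),
               peak_value = numeric())
  }
  rownames(ord) <- NULL
  canonical <- c("gape", "hyoid_depression", "opercula_abduction")
  label <- if (nrow(ord) == 3 && identical(ord$variable, canonical)) {
    "intake_like"
  } else if (nrow(ord) == 3 && identical(ord$variable, rev(canonical))) {
    "rf_like"
  } else "other"
  structure(list(phase = phase, order = ord, label = label),
            class = "peak_sequence")
}
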