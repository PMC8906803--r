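# shared helpers: tiny builders and independent brute-force oracles

rot_z <- function(theta) {
  matrix(c(cos(theta), sin(theta), 0,
           -sin(theta), cos(theta), 0,
           0, 0, 1), 3, 3)
}

rot_x <- function(theta) {
  matrix(c(1, 0, 0,
           0, cos(theta), sin(theta),
           0, -sin(theta), cos(theta)), 3, 3)
}

# angle (deg) between two rotation matrices
rotation_angle_deg <- function(R1, R2) {
  tr <- sum(diag(t(R1) %*% R2))
  acos(min(max((tr - 1) / 2, -1), 1)) * 180 / pi
}

# four non-coplanar reference markers, mm scale
ref_markers <- function() {
  rbind(a = c(0, 0, 0), b = c(30, 0, 0), c = c(0, 25, 0), d = c(8, 8, 18))
}

# a minimal trajectory set with one constant-velocity track
make_line_ts <- function(n = 30, v_mm_s = c(10, 0, 0), frame_rate = 750,
                         kind = "water_tracer", name = "water_01") {
  t <- (seq_len(n) - 1) / frame_rate
  p <- cbind(v_mm_s[1] * t, v_mm_s[2] * t, v_mm_s[3] * t)
  trajectory_set(stats::setNames(list(p), name), frame_rate = frame_rate,
                 track_kind = stats::setNames(kind, name))
}

# brute-force Kruskal-Wallis H with tie correction, from first principles
kw_brute <- function(groups) {
  x <- unlist(groups)
  n <- vapply(groups, length, integer(1))
  N <- length(x)
  r <- rank(x)
  idx <- split(seq_len(N), rep(seq_along(groups), n))
  H <- 12 / (N * (N + 1)) *
    sum(vapply(seq_along(groups), function(i) {
      n[i] * (mean(r[idx[[i]]]) - (N + 1) / 2)^2
    }, numeric(1)))
  ties <- table(x)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# brute-force Kendall tau-b by exhaustive pair counting
tau_brute <- function(x, y) {
  n <- length(x)
  conc <- disc <- tx <- ty <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dx <- sign(x[j] - x[i])
      dy <- sign(y[j] - y[i])
      if (dx == 0 && dy == 0) next
      if (dx == 0) tx <- tx + 1
      else if (dy == 0) ty <- ty + 1
      else if (dx == dy) conc <- conc + 1
      else disc <- disc + 1
    }
  }
  (conc - disc) / sqrt((conc + disc + tx) * (conc + disc + ty))
}

# boundary recall of a detected phase table against ground truth
boundary_errors_frames <- function(truth_pt, detected_pt, frame_rate = 750) {
  tru <- phase_boundaries(truth_pt)
  det <- phase_boundaries(detected_pt)
  vapply(tru, function(b) min(abs(det - b)), numeric(1)) * frame_rate
}
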