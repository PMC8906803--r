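test_that("Menger curvature matches analytic circumcircles", {
  # collinear points
  straight <- cbind(0:10, 0 * (0:10), 0 * (0:10))
  k <- menger_curvature(straight, smooth_cutoff = Inf)
  expect_equal(unname(k[2:10]), rep(0, 9))
  # (0,0),(1,1),(2,0) in the (x,z) plane: circumradius 1 mm
  tri <- rbind(c(0, 5, 0), c(1, 5, 1), c(2, 5, 0))
  k <- menger_curvature(tri, smooth_cutoff = Inf)
  expect_equal(k[2], 1, tolerance = 1e-12)
  # points on a circle of radius 7 mm at irregular spacing
  th <- cumsum(runif(40, 0.05, 0.3))
  circ <- cbind(7 * cos(th), rnorm(40), 7 * sin(th))
  k <- menger_curvature(circ, smooth_cutoff = Inf)
  expect_lt(max(abs(k[2:39] - 1 / 7)), 1e-9)
  expect_error(menger_curvature(tri[1:2, ], smooth_cutoff = Inf), "shorter")
})

test_that("curvature is rigid-motion invariant and scales as 1/s", {
  set.seed(2)
  th <- seq(0, 3, by = 0.1)
  path <- cbind(10 * th, 0 * th, 4 * sin(th))
  k0 <- menger_curvature(path, smooth_cutoff = Inf)
  # in-plane rotation about the y axis keeps (x,z) geometry
  ang <- 0.7
  Ry <- matrix(c(cos(ang), 0, -sin(ang), 0, 1, 0, sin(ang), 0, cos(ang)), 3, 3)
  k1 <- menger_curvature(sweep(path %*% t(Ry), 2, c(3, -2, 8), `+`),
                         smooth_cutoff = Inf)
  expect_equal(k0, k1, tolerance = 1e-9)
  k2 <- menger_curvature(path * 2.5, smooth_cutoff = Inf)
  expect_equal(k2, k0 / 2.5, tolerance = 1e-9)
})

test_that("interval maxima standardize each tracer's own trajectory", {
  n <- 200
  x <- seq(100, 0, length.out = n)     # posterior travel
  kconst <- rep(0.3, n)
  prof <- interval_max_curvature(kconst, x, n_bins = 10)
  expect_equal(prof$max_curvature, rep(0.3, 10))
  # curvature only in the last 10% of the trajectory
  klate <- rep(0, n)
  klate[x < 10] <- 0.5
  prof <- interval_max_curvature(klate, x, n_bins = 10)
  expect_equal(prof$max_curvature[10], 0.5)
  expect_true(all(prof$max_curvature[1:9] == 0))
  expect_error(interval_max_curvature(kconst, rep(1, n)), "degenerate")
})

test_that("an S-curved lateral path out-curves a straight path in every bin", {
  n <- 400
  x <- seq(120, 5, length.out = n)
  u <- (120 - x) / 115
  water <- cbind(x, 0 * x, 15 * (u^2 * (3 - 2 * u)))
  food <- cbind(x, 0 * x + 8, 0 * x)
  kw <- menger_curvature(water, smooth_cutoff = Inf)
  kf <- menger_curvature(food, smooth_cutoff = Inf)
  pw <- interval_max_curvature(kw, x, 10)
  pf <- interval_max_curvature(kf, x, 10)
  ok <- !is.na(pw$max_curvature) & !is.na(pf$max_curvature)
  expect_true(all(pw$max_curvature[ok] >= pf$max_curvature[ok]))
})

test_that("Kruskal-Wallis agrees with a brute-force rank oracle", {
  same <- data.frame(tracer = "a", bin_lo = 0, bin_hi = 100,
                     max_curvature = NA)
  mk_prof <- function(vals) {
    structure(data.frame(tracer = "x", bin_lo = seq_along(vals),
                         bin_hi = seq_along(vals) + 1, max_curvature = vals),
              class = c("curvature_profile", "data.frame"))
  }
  r <- compare_curvature(mk_prof(c(1, 2, 3)), mk_prof(c(1, 2, 3)))
  expect_equal(r$statistic, 0, tolerance = 1e-12)
  expect_equal(r$p_value, 1, tolerance = 1e-12)

  r <- compare_curvature(mk_prof(c(10, 20, 30)), mk_prof(c(1, 2, 3)))
  expect_equal(r$statistic, kw_brute(list(c(10, 20, 30), c(1, 2, 3))),
               tolerance = 1e-12)
  expect_lte(r$p_value, 0.05)
  expect_equal(r$direction, "water > food")

  set.seed(31)
  for (rep in 1:25) {
    n1 <- sample(2:4, 1)
    n2 <- sample(2:4, 1)
    # quantized values force ties
    g1 <- round(runif(n1, 0, 4))
    g2 <- round(runif(n2, 0, 4))
    if (length(unique(c(g1, g2))) < 2) next
    r <- compare_curvature(mk_prof(g1), mk_prof(g2))
    expect_equal(r$statistic, kw_brute(list(g1, g2)), tolerance = 1e-9)
  }
})

test_that("Kendall tau matches exhaustive pair counting (tau-b)", {
  set.seed(17)
  for (rep in 1:25) {
    n <- sample(4:8, 1)
    x <- round(runif(n, 0, 5))
    y <- round(runif(n, 0, 5))
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    expect_equal(unname(cor(x, y, method = "kendall")), tau_brute(x, y),
                 tolerance = 1e-12)
  }
})

test_that("positional correlation follows the intake endpoints", {
  fr <- 750
  n <- 400
  t <- (0:(n - 1)) / fr
  pt <- phase_table(data.frame(label = "intake", start_time = 0.05,
                               end_time = 0.45, peak_ap_velocity = -50))
  mk_tracer <- function(z0, z1) {
    u <- pmin(pmax((t - 0.05) / 0.4, 0), 1)
    cbind(100 - 90 * u, 0 * t, z0 + (z1 - z0) * u)
  }
  # perfectly monotone: final z ordered like initial z
  z0 <- c(-3, -1, 1, 3, 5)
  pts <- lapply(seq_along(z0), function(i) mk_tracer(z0[i], z0[i] * 2))
  names(pts) <- sprintf("water_%02d", seq_along(z0))
  ts <- trajectory_set(pts, track_kind = stats::setNames(
    rep("water_tracer", length(z0)), names(pts)))
  r <- positional_correlation(ts, pt, "z_begin_vs_z_end")
  expect_equal(unname(r$statistic), 1, tolerance = 1e-12)
  # one discordant swap among 4: tau from exhaustive counting
  z1 <- c(-6, 2, -2, 6)
  pts <- lapply(1:4, function(i) mk_tracer(c(-3, -1, 1, 3)[i], z1[i]))
  names(pts) <- sprintf("water_%02d", 1:4)
  ts <- trajectory_set(pts, track_kind = stats::setNames(
    rep("water_tracer", 4), names(pts)))
  r <- positional_correlation(ts, pt, "z_begin_vs_z_end")
  expect_equal(unname(r$statistic), tau_brute(c(-3, -1, 1, 3), z1),
               tolerance = 1e-12)
  expect_error(positional_correlation(
    trajectory_set(pts[1:2], track_kind = stats::setNames(
      rep("water_tracer", 2), names(pts)[1:2])), pt), "fewer than 3")
})

test_that("per-phase distances and components are additive and normalized", {
  fr <- 750
  n <- 5
  t <- (0:(n - 1)) / fr
  pt <- phase_table(data.frame(label = "intake", start_time = 0,
                               end_time = t[n], peak_ap_velocity = -10))
  # straight 10 mm of pure x motion, arbitrary sampling
  px <- cbind(seq(0, 10, length.out = n), rep(0, n), rep(0, n))
  d <- phase_distance(px, pt, t)
  expect_equal(d$total_distance_mm, 10)
  expect_equal(c(d$comp_x_pct, d$comp_y_pct, d$comp_z_pct), c(100, 0, 0))
  # equal motion on all axes
  peq <- cbind(t, t, t) * 100
  d <- phase_distance(peq, pt, t)
  expect_equal(c(d$comp_x_pct, d$comp_y_pct, d$comp_z_pct),
               rep(100 / 3, 3), tolerance = 1e-9)
  expect_equal(d$comp_x_pct + d$comp_y_pct + d$comp_z_pct, 100,
               tolerance = 1e-6)
  # a phase without enough valid frames is omitted with a warning
  pt2 <- rbind(pt, data.frame(label = "rf", start_time = 1, end_time = 2,
                              peak_ap_velocity = 5))
  expect_warning(d2 <- phase_distance(px, phase_table(pt2), t), "omitted")
  expect_equal(nrow(d2), 1)
})

test_that("flow patterns are classified by their velocity/medial signatures", {
  fr <- 750
  n <- 600
  t <- (0:(n - 1)) / fr
  pt <- phase_table(data.frame(label = "intake", start_time = 0.1,
                               end_time = 0.5, peak_ap_velocity = -60))
  u <- pmin(pmax((t - 0.1) / 0.4, 0), 1)
  base_x <- 100 - 80 * (u^2 * (3 - 2 * u))
  # straight posterior path at constant z
  expect_equal(classify_flow_pattern(cbind(base_x, 0 * t, 0 * t + 2), pt),
               "posterior")
  # an anterior excursion strong enough to reverse the decaying base flow
  bump <- ifelse(t > 0.4 & t < 0.46, 300, 0)   # mm/s
  x_ret <- base_x + c(0, cumsum((bump[-1] + bump[-n]) / 2) / fr)
  expect_equal(classify_flow_pattern(cbind(x_ret, 0 * t, 0 * t + 2), pt),
               "anterior_return")
  # z swinging out to ~8 mm and shed to ~1 mm while moving posteriorly
  z_med <- 8 * sin(pi * pmin(u, 1)) + u
  expect_equal(classify_flow_pattern(cbind(base_x, 0 * t, z_med), pt),
               "posteromedial")
  expect_error(classify_flow_pattern(cbind(base_x, 0 * t, 0 * t),
                                     phase_table(data.frame(
                                       label = "stasis", start_time = 0,
                                       end_time = 1,
                                       peak_ap_velocity = 0))), "no intake")
})
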