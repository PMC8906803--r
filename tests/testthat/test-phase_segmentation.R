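test_that("velocity of simple motions is exact", {
  fr <- 750
  n <- 300
  # constant position -> zero velocity
  vs <- compute_velocity(matrix(5, n, 3), fr)
  expect_lt(max(abs(vs$v[vs$valid, ])), 1e-9)
  # x(t) = -10 t cm -> anteroposterior velocity -10 cm/s
  t <- (0:(n - 1)) / fr
  vs <- compute_velocity(cbind(-100 * t, 0 * t, 0 * t), fr)
  expect_equal(unname(vs$v[vs$valid, 1]), rep(-10, sum(vs$valid)),
               tolerance = 1e-6)
})

test_that("a 92.1 cm/s intake pulse survives default smoothing within 2%", {
  fr <- 750
  t <- seq(0, 1, by = 1 / fr)
  peak <- -92.1
  v_prog <- ifelse(t > 0.4 & t < 0.66,
                   peak * sin(pi * (t - 0.4) / 0.26)^2, 0)  # cm/s
  x <- c(0, cumsum((v_prog[-1] + v_prog[-length(v_prog)]) / 2) / fr) * 10
  vs <- compute_velocity(cbind(x, 0 * x, 0 * x), fr)
  expect_equal(min(vs$v[, 1], na.rm = TRUE), peak, tolerance = 0.02)
})

test_that("frames adjacent to tracking gaps are invalid", {
  p <- matrix(0, 100, 3)
  p[, 1] <- seq_len(100)
  p[50, ] <- NA
  vs <- compute_velocity(p, 750)
  expect_false(any(vs$valid[49:51]))
  expect_true(vs$valid[2])
  expect_error(compute_velocity(matrix(NA_real_, 10, 3), 750), "valid frames")
})

test_that("water velocity aggregation matches hand arithmetic", {
  fr <- 750
  n <- 150
  t <- (0:(n - 1)) / fr
  mk <- function(v_cm) cbind(cm_per_s_to_mm_per_s(v_cm) * t, 0 * t, 0 * t)
  one <- trajectory_set(list(water_01 = mk(5)),
                        track_kind = c(water_01 = "water_tracer"))
  agg <- aggregate_water_velocity(one)
  i <- which(agg$valid)[5]
  expect_equal(agg$mean[i], 5, tolerance = 1e-6)
  expect_equal(agg$sd[i], 0)

  two <- trajectory_set(list(water_01 = mk(5), water_02 = mk(-5)),
                        track_kind = c(water_01 = "water_tracer",
                                       water_02 = "water_tracer"))
  agg <- aggregate_water_velocity(two)
  expect_equal(agg$mean[i], 0, tolerance = 1e-6)
  expect_equal(agg$sd[i], sqrt(50), tolerance = 1e-4)   # sample SD of +-5

  no_water <- trajectory_set(list(neuro_a = mk(1)),
                             track_kind = c(neuro_a = "bone_marker"))
  expect_error(aggregate_water_velocity(no_water), "no water tracers")
})

test_that("cross-tracer mean converges to the shared profile", {
  set.seed(11)
  fr <- 750
  t <- seq(0, 0.6, by = 1 / fr)
  prog <- -40 * sin(pi * pmin(pmax((t - 0.1) / 0.3, 0), 1))^2
  x <- c(0, cumsum((prog[-1] + prog[-length(prog)]) / 2) / fr) * 10
  pts <- lapply(1:15, function(i) {
    cbind(x, 0 * x, 0 * x) + matrix(rnorm(3 * length(x), 0, 0.1),
                                    length(x), 3)
  })
  names(pts) <- sprintf("water_%02d", 1:15)
  ts <- trajectory_set(pts, track_kind = stats::setNames(
    rep("water_tracer", 15), names(pts)))
  agg <- aggregate_water_velocity(ts)
  mid <- which.min(abs(t - 0.25))
  se <- agg$sd[mid] / sqrt(15)
  expect_lt(abs(agg$mean[mid] - prog[mid]), 4 * se + 0.2)
})

test_that("piecewise-constant programs are labelled by the rule set", {
  fr <- 750
  t <- seq(0, 1.45, by = 1 / fr)
  v <- numeric(length(t))
  v[t < 0.5] <- -3
  v[t >= 0.5 & t < 0.75] <- -80
  v[t >= 0.75 & t < 1.05] <- 0
  v[t >= 1.05 & t < 1.25] <- 10
  v[t >= 1.25] <- -15
  vs <- structure(list(t = t, v = matrix(v, ncol = 1),
                       valid = rep(TRUE, length(t)), frame_rate = fr),
                  class = "velocity_series")
  cfg <- segmentation_config(segmentation_smoothing = Inf)
  pt <- segment_phases(vs, cfg)
  expect_equal(pt$label, c("approach", "intake", "stasis", "rf", "bf"))
  expected <- c(0, 0.5, 0.75, 1.05, 1.25, 1.45)
  got <- c(pt$start_time[1], pt$start_time[-1], pt$end_time[nrow(pt)])
  expect_lt(max(abs(sort(unique(got)) - expected)), 2.5 / fr)
  expect_equal(pt$peak_ap_velocity[pt$label == "intake"], -80)
  expect_gt(pt$peak_ap_velocity[pt$label == "rf"], 0)
  expect_lt(pt$peak_ap_velocity[pt$label == "bf"], 0)
})

test_that("all-stagnant input yields one stasis interval with a warning flag", {
  fr <- 750
  n <- 400
  vs <- structure(list(t = (0:(n - 1)) / fr, v = matrix(0, n, 1),
                       valid = rep(TRUE, n), frame_rate = fr),
                  class = "velocity_series")
  pt <- segment_phases(vs)
  expect_equal(pt$label, "stasis")
  expect_false(is.null(attr(pt, "warning")))
})

test_that("segmentation is deterministic and monotone in the dead band", {
  w <- generate_feeding_sequence(species_preset("carp"), n_cycles = 2, seed = 3)
  res <- analyze_feeding_sequence(w)
  res2 <- analyze_feeding_sequence(w)
  expect_identical(res$phases, res2$phases)
  labelled_dur <- function(pt) {
    act <- pt[pt$label %in% c("intake", "rf", "bf", "approach"), ]
    sum(act$end_time - act$start_time)
  }
  narrow <- analyze_feeding_sequence(
    w, segmentation_config(dead_band_low = -2.5, dead_band_high = 1))
  expect_gte(labelled_dur(narrow$phases) + 1e-9, labelled_dur(res$phases))
})

test_that("rf/bf peaks alternate in sign and periodicity is exact on knots", {
  w <- generate_feeding_sequence(species_preset("carp"), n_cycles = 3, seed = 5)
  pt <- analyze_feeding_sequence(w)$phases
  hb <- pt[pt$label %in% c("rf", "bf"), ]
  expect_true(all(sign(hb$peak_ap_velocity) == ifelse(hb$label == "rf", 1, -1)))

  exact <- phase_table(data.frame(
    label = c("rf", "bf", "rf", "bf"),
    start_time = c(0.8, 1.0, 1.5, 2.0),
    end_time = c(1.0, 1.5, 2.0, 2.5),
    peak_ap_velocity = c(10, -10, 10, -10)))
  tp <- transition_periodicity(exact)
  expect_equal(tp$mean, 0.5)
  expect_equal(tp$sd, 0)
  one <- exact[1:2, ]
  expect_error(transition_periodicity(phase_table(one)), "fewer than 2")
})

test_that("a noise-free generated sequence is recovered to the frame", {
  w <- generate_feeding_sequence(species_preset("carp", noise_sd = 0),
                                 n_cycles = 2, seed = 1)
  res <- analyze_feeding_sequence(w)
  err <- boundary_errors_frames(w$truth$phase_table, res$phases)
  expect_lt(max(err), 1.5)
})
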