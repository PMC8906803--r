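## Tracer-fidelity physics: Stokes-law density estimation from drop tests and
## a reduced-order suction-flow particle-advection model. The inflow is the
## potential flow through a circular aperture in a plane wall (smooth, exact)
## developing to plug flow inside the cavity, with the aperture speed from a
## Bernoulli closure of the suction pressure; the particle follows a reduced
## Maxey-Riley balance (Stokes drag, buoyant weight, added mass, fluid
## pressure-gradient force; Basset history and Faxen terms neglected).

#' Tracer density from Stokes' law
#'
#' rho_tracer = 18 mu V_settle / (g d^2) + rho_water, with `v_settle`
#' positive when the particle sinks. A settling speed of zero returns the
#' fluid density exactly (neutral buoyancy). When the particle Reynolds
#' number exceeds 1 the Stokes assumption is advisory only and a warning is
#' issued.
#'
#' @param v_settle settling speed, m/s, positive downward (a rising tracer
#'   has negative `v_settle`).
#' @param fluid a [fluid_properties()].
#' @param d sphere diameter, m.
#' @return density, kg/m^3.
#' @export
stokes_density <- function(v_settle, fluid = fluid_properties(), d = 1.4e-3) {
  if (d <= 0) stop("diameter must be positive")
  re <- abs(v_settle) * d * fluid$density / fluid$dynamic_viscosity
  if (any(re > 1)) {
    warning(sprintf("particle Reynolds number %.2g > 1: Stokes regime advisory",
                    max(re)))
  }
  18 * fluid$dynamic_viscosity * v_settle / (fluid$gravity * d^2) + fluid$density
}

#' Settling speed implied by a tracer density (inverse of [stokes_density()])
#' @param density tracer density, kg/m^3.
#' @param fluid a [fluid_properties()].
#' @param d sphere diameter, m.
#' @return settling speed, m/s, positive downward.
#' @export
stokes_settling_velocity <- function(density, fluid = fluid_properties(),
                                     d = 1.4e-3) {
  (density - fluid$density) * fluid$gravity * d^2 /
    (18 * fluid$dynamic_viscosity)
}

#' Terminal velocity from a drop-test trajectory
#'
#' Fits the mean slope of the steady tail (final fraction of the record) of a
#' vertical position series. Vertical position is up-positive, so a rising
#' tracer yields a positive terminal velocity and a sinking one negative. The
#' fit fails if the tail has not converged: the slopes of its two halves must
#' agree within `drift_tol` of their magnitude.
#'
#' @param drop_path vertical positions, metres, up positive.
#' @param frame_rate frames/s (drop tests are filmed at 50 fps).
#' @param tail_fraction fraction of the record treated as terminal
#'   (default 0.5).
#' @param drift_tol relative slope drift allowed between tail halves
#'   (default 0.1).
#' @return list: `v_terminal` (m/s, signed, + up), `fit_quality` (residual
#'   SD of the tail fit, m).
#' @export
terminal_velocity <- function(drop_path, frame_rate = 50, tail_fraction = 0.5,
                              drift_tol = 0.1) {
  y <- as.numeric(drop_path)
  n <- length(y)
  if (n < 8) stop("drop-test record too short")
  t <- (seq_len(n) - 1) / frame_rate
  tail_idx <- seq(ceiling(n * (1 - tail_fraction)), n)
  fit <- stats::lm(y[tail_idx] ~ t[tail_idx])
  slope <- unname(coef(fit)[2])
  half <- length(tail_idx) %/% 2
  s1 <- unname(coef(stats::lm(y[tail_idx[1:half]] ~ t[tail_idx[1:half]]))[2])
  s2 <- unname(coef(stats::lm(y[tail_idx[(half + 1):length(tail_idx)]] ~
                                t[tail_idx[(half + 1):length(tail_idx)]]))[2])
  scale <- max(abs(slope), 1e-12)
  if (abs(s2 - s1) > drift_tol * scale + 1e-9) {
    stop(sprintf(paste0("terminal velocity not reached: tail slope drifts ",
                        "from %.3g to %.3g m/s"), s1, s2))
  }
  list(v_terminal = slope, fit_quality = stats::sd(stats::residuals(fit)))
}

#' Reduced-order suction model
#'
#' Cylindrical mouth cavity of the given length and radius, sucking through
#' its aperture (at the origin, cavity along -x, inflow half-space x > 0)
#' under a sinusoidal suction pressure that reaches `pressure_amplitude`
#' after `ramp_time` and is then held. The aperture speed follows the
#' quasi-steady orifice estimate u = sqrt(2 |p| / rho) (about 2 m/s at
#' 2 kPa). The inflow is the potential flow through a circular aperture in a
#' plane wall (far field a half-space sink, no flow through the wall),
#' developing into plug flow over one radius of cavity depth.
#'
#' @param cavity_length m (default 0.040).
#' @param cavity_radius m (default 0.010).
#' @param pressure_amplitude Pa, magnitude of the suction pressure (default
#'   2000).
#' @param ramp_time s, quarter-period of the sinusoidal ramp (default 0.020).
#' @param total_time s (default 0.100).
#' @param time_step s (default 1.25e-4; must be at most `ramp_time`/10).
#' @param fluid a [fluid_properties()].
#' @param gravity_direction unit 3-vector, direction of gravity (default
#'   -y).
#' @return a list of class `suction_model`.
#' @export
suction_model <- function(cavity_length = 0.040, cavity_radius = 0.010,
                          pressure_amplitude = 2000, ramp_time = 0.020,
                          total_time = 0.100, time_step = 1.25e-4,
                          fluid = fluid_properties(),
                          gravity_direction = c(0, -1, 0)) {
  stopifnot(cavity_length > 0, cavity_radius > 0, ramp_time > 0,
            total_time > 0, time_step > 0, time_step <= ramp_time / 10,
            cavity_radius < cavity_length, pressure_amplitude >= 0)
  g <- gravity_direction / sqrt(sum(gravity_direction^2))
  structure(list(cavity_length = cavity_length, cavity_radius = cavity_radius,
                 pressure_amplitude = pressure_amplitude,
                 ramp_time = ramp_time, total_time = total_time,
                 time_step = time_step, fluid = fluid, gravity_direction = g),
            class = "suction_model")
}

#' Default tracer release points
#'
#' On-axis 5 mm ahead of the aperture, and 5 mm ahead with a 5 mm off-axis
#' offset (toward +y, the anti-gravity side of the default model).
#'
#' @param model a [suction_model()].
#' @return list of two 3-vectors (m).
#' @export
default_release_points <- function(model = suction_model()) {
  list(rp1 = c(0.005, 0, 0), rp2 = c(0.005, 0.005, 0))
}

# suction pressure magnitude (Pa, >= 0) at time t
suction_pressure <- function(model, t) {
  p <- model$pressure_amplitude * sin(pi * pmax(t, 0) / (2 * model$ramp_time))
  p[t >= model$ramp_time] <- model$pressure_amplitude
  pmax(p, 0)
}

# aperture (plug) speed, m/s
aperture_speed <- function(model, t) {
  sqrt(2 * suction_pressure(model, t) / model$fluid$density)
}

# fluid velocity at position p (3-vector, m) and time t.
# The inflow is the exact potential flow through a circular aperture of
# radius R in a plane wall (oblate-spheroidal solution): far field a
# half-space sink, zero normal flow on the wall, smooth through the
# aperture. Inside the cavity it develops into plug flow over one radius of
# depth. The flux is anchored so the mean aperture speed equals the
# Bernoulli estimate U(t).
suction_fluid_velocity <- function(model, p, t) {
  U <- aperture_speed(model, t)
  if (U == 0) return(c(0, 0, 0))
  R <- model$cavity_radius
  x <- p[1]
  rho <- sqrt(p[2]^2 + p[3]^2)
  a <- x / R
  b <- rho / R
  if (abs(a) < 1e-12) a <- 1e-12          # keep xi off the wall branch cut
  cc <- 1 - a^2 - b^2
  root <- sqrt(cc^2 + 4 * a^2)            # = 2 s + cc, s = xi^2
  s <- 2 * a^2 / (cc + root)              # stable near the aperture disc
  g <- sqrt((cc + root) / 2)              # = a / xi >= 0
  xi <- a / g
  # Phi = A arccot(xi), A = U R / 2; u = grad Phi
  A <- U * R / 2
  u_x <- -(A / R) * g / root
  u_rho <- -(A / R) * b * xi / ((1 + s) * root)
  u <- c(u_x, if (rho > 0) u_rho * p[2:3] / rho else c(0, 0))
  if (x < 0) {
    w <- smoothstep(min(-x / R, 1))
    u <- (1 - w) * u + w * c(-U, 0, 0)
  }
  spd <- sqrt(sum(u^2))
  if (spd > 3 * U) u <- u * (3 * U / spd) # soft guard near the aperture rim
  u
}

# d/dt of the aperture speed (the ramp is sinusoidal in pressure, so U has a
# square-root onset whose derivative is handled analytically)
aperture_speed_rate <- function(model, t) {
  if (t >= model$ramp_time || model$pressure_amplitude == 0) return(0)
  theta <- pi * max(t, 0) / (2 * model$ramp_time)
  if (sin(theta) < 1e-12) return(0)   # limit handled by the caller at t = 0
  C <- sqrt(2 * model$pressure_amplitude / model$fluid$density)
  C * (pi / (2 * model$ramp_time)) * cos(theta) / (2 * sqrt(sin(theta)))
}

# material derivative Du/Dt at (p, t). The field factorizes as
# u(p, t) = U(t) w(p), so the local part is exact, U'(t) w(p); the
# convective part is differenced on the smooth spatial shape.
suction_fluid_accel <- function(model, p, t, u = NULL) {
  if (is.null(u)) u <- suction_fluid_velocity(model, p, t)
  U <- aperture_speed(model, t)
  dudt <- if (U > 0) {
    aperture_speed_rate(model, t) * (u / U)
  } else {
    ht <- model$time_step / 4
    suction_fluid_velocity(model, p, t + ht) / ht
  }
  hx <- 1e-5
  conv <- c(0, 0, 0)
  for (ax in 1:3) {
    e <- c(0, 0, 0); e[ax] <- hx
    du <- (suction_fluid_velocity(model, p + e, t) -
             suction_fluid_velocity(model, p - e, t)) / (2 * hx)
    conv <- conv + u[ax] * du
  }
  dudt + conv
}

#' Advect a tracer particle through the suction flow
#'
#' Integrates the particle equation of motion (reduced Maxey-Riley: Stokes
#' drag, buoyant weight, added mass, fluid pressure-gradient force) and, from
#' the same release point, the pure fluid pathline, both by fourth-order
#' Runge-Kutta on the model's time step. Integration of either path ends
#' early when it leaves the domain or reaches the cavity base.
#'
#' @param model a [suction_model()].
#' @param spec a [tracer_spec()].
#' @param release_point 3-vector, m; must be in the inflow half-space
#'   (x > 0).
#' @param drag_correction if `TRUE`, apply the Schiller-Naumann finite-
#'   Reynolds drag factor 1 + 0.15 Re^0.687 to the Stokes drag (slip
#'   Reynolds numbers during peak suction reach O(100)). Default `FALSE`:
#'   the baseline force balance uses bare Stokes drag.
#' @param gravity if `FALSE`, switch gravity off (for neutral-limit checks).
#' @return list of class `suction_trajectory`: `time` (s), `particle`,
#'   `particle_velocity`, `fluid_pathline`, `fluid_velocity_pathline`
#'   (n-by-3, m and m/s), `fluid_velocity_at_particle`, `status_particle`,
#'   `status_fluid` (`"completed"`, `"reached_base"` or `"left_domain"`),
#'   `model`, `spec`.
#' @export
simulate_suction <- function(model, spec, release_point,
                             drag_correction = FALSE, gravity = TRUE) {
  stopifnot(inherits(model, "suction_model"), inherits(spec, "tracer_spec"))
  release_point <- as.numeric(release_point)
  if (length(release_point) != 3 || release_point[1] <= 0) {
    stop("release point must lie in the inflow half-space (x > 0)")
  }
  if (spec$density <= 0) stop("non-physical tracer density")
  fl <- model$fluid
  rho_p <- spec$density
  rho_f <- fl$density
  d <- spec$diameter
  nu <- fl$dynamic_viscosity / rho_f
  g_vec <- if (gravity) fl$gravity * model$gravity_direction else c(0, 0, 0)
  m_eff <- rho_p + rho_f / 2            # per unit volume, incl. added mass
  drag0 <- 18 * fl$dynamic_viscosity / d^2

  accel <- function(p, v, t) {
    u <- suction_fluid_velocity(model, p, t)
    du <- suction_fluid_accel(model, p, t, u)
    slip <- u - v
    re <- sqrt(sum(slip^2)) * d / nu
    phi <- if (drag_correction && re > 0) 1 + 0.15 * re^0.687 else 1
    ((3 * rho_f / 2) * du + (rho_p - rho_f) * g_vec + drag0 * phi * slip) / m_eff
  }
  in_domain <- function(p) {
    if (p[1] <= -model$cavity_length) return("reached_base")
    if (sqrt(sum(p^2)) > 0.3) return("left_domain")
    if (p[1] <= 0 && sqrt(p[2]^2 + p[3]^2) > model$cavity_radius) {
      return("left_domain")                     # behind the head wall
    }
    "ok"
  }

  nt <- floor(model$total_time / model$time_step) + 1
  tt <- (seq_len(nt) - 1) * model$time_step
  h <- model$time_step
  # the Bernoulli aperture speed rises like sqrt(t), so the first part of the
  # ramp is integrated with substeps to keep the impulsive fluid acceleration
  # resolved (a velocity error seeded here would persist for a full Stokes
  # relaxation time)
  substeps <- function(t) {
    if (t < model$ramp_time / 5) 64L else if (t < model$ramp_time) 8L else 1L
  }

  # the Bernoulli ramp opens with U ~ sqrt(t) (integrable infinite
  # acceleration); across the first step both the fluid element and the
  # particle move analytically with u = U(t) w(p), whose displacement is
  # (2/3) h u(p, h). Applied identically to particle and pathline.
  u_h <- suction_fluid_velocity(model, release_point, h)
  first <- if (sum(u_h^2) > 0) {
    p2 <- release_point + (2 / 3) * h * u_h
    list(p = p2, v = suction_fluid_velocity(model, p2, h) +
           (rho_p - rho_f) * g_vec / m_eff * h)
  } else NULL

  # particle: RK4 on (position, velocity)
  pp <- matrix(NA_real_, nt, 3)
  pv <- matrix(NA_real_, nt, 3)
  up <- matrix(NA_real_, nt, 3)
  pp[1, ] <- release_point
  pv[1, ] <- suction_fluid_velocity(model, release_point, 0)
  up[1, ] <- pv[1, ]
  i_start <- 1L
  if (!is.null(first)) {
    pp[2, ] <- first$p
    pv[2, ] <- first$v
    up[2, ] <- suction_fluid_velocity(model, first$p, tt[2])
    i_start <- 2L
  }
  status_particle <- "completed"
  np <- nt
  for (i in i_start:(nt - 1)) {
    pn <- pp[i, ]; vn <- pv[i, ]; t0i <- tt[i]
    ns <- substeps(t0i)
    hs <- h / ns
    for (k in seq_len(ns)) {
      p <- pn; v <- vn; t <- t0i + (k - 1) * hs
      k1p <- v;               k1v <- accel(p, v, t)
      k2p <- v + hs / 2 * k1v; k2v <- accel(p + hs / 2 * k1p, v + hs / 2 * k1v, t + hs / 2)
      k3p <- v + hs / 2 * k2v; k3v <- accel(p + hs / 2 * k2p, v + hs / 2 * k2v, t + hs / 2)
      k4p <- v + hs * k3v;     k4v <- accel(p + hs * k3p, v + hs * k3v, t + hs)
      pn <- p + hs / 6 * (k1p + 2 * k2p + 2 * k3p + k4p)
      vn <- v + hs / 6 * (k1v + 2 * k2v + 2 * k3v + k4v)
    }
    st <- in_domain(pn)
    if (st != "ok") {
      status_particle <- st
      np <- i
      break
    }
    pp[i + 1, ] <- pn
    pv[i + 1, ] <- vn
    up[i + 1, ] <- suction_fluid_velocity(model, pn, tt[i + 1])
  }

  # fluid pathline: RK4 on position only
  fp <- matrix(NA_real_, nt, 3)
  fv <- matrix(NA_real_, nt, 3)
  fp[1, ] <- release_point
  fv[1, ] <- suction_fluid_velocity(model, release_point, 0)
  if (!is.null(first)) {
    fp[2, ] <- release_point + (2 / 3) * h * u_h
    fv[2, ] <- suction_fluid_velocity(model, fp[2, ], tt[2])
  }
  status_fluid <- "completed"
  nf <- nt
  for (i in i_start:(nt - 1)) {
    pn <- fp[i, ]; t0i <- tt[i]
    ns <- substeps(t0i)
    hs <- h / ns
    for (k in seq_len(ns)) {
      p <- pn; t <- t0i + (k - 1) * hs
      k1 <- suction_fluid_velocity(model, p, t)
      k2 <- suction_fluid_velocity(model, p + hs / 2 * k1, t + hs / 2)
      k3 <- suction_fluid_velocity(model, p + hs / 2 * k2, t + hs / 2)
      k4 <- suction_fluid_velocity(model, p + hs * k3, t + hs)
      pn <- p + hs / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    st <- in_domain(pn)
    if (st != "ok") {
      status_fluid <- st
      nf <- i
      break
    }
    fp[i + 1, ] <- pn
    fv[i + 1, ] <- suction_fluid_velocity(model, pn, tt[i + 1])
  }

  structure(list(
    time = tt, particle = pp[seq_len(np), , drop = FALSE],
    particle_velocity = pv[seq_len(np), , drop = FALSE],
    fluid_pathline = fp[seq_len(nf), , drop = FALSE],
    fluid_velocity_pathline = fv[seq_len(nf), , drop = FALSE],
    fluid_velocity_at_particle = up[seq_len(np), , drop = FALSE],
    status_particle = status_particle, status_fluid = status_fluid,
    model = model, spec = spec), class = "suction_trajectory")
}

#' Tracer fidelity metrics
#'
#' Compares a particle path with the fluid pathline released from the same
#' point, over their common time grid: `max_lag` is the largest shortfall of
#' particle speed behind the local fluid speed while the flow accelerates,
#' `max_overshoot` the largest excess while it decelerates,
#' `gravity_deviation` the largest displacement of the particle from the
#' matched pathline point along gravity, and `path_separation` the largest
#' 3D distance. Signed speed differences are also returned raw.
#'
#' @param particle_path n-by-3 particle positions (m).
#' @param fluid_pathline m-by-3 fluid pathline positions (m), same time grid.
#' @param particle_velocity n-by-3 particle velocities (m/s).
#' @param fluid_velocity_at_particle n-by-3 fluid velocity sampled at the
#'   particle position (m/s).
#' @param gravity_direction unit 3-vector (default -y).
#' @return a list of class `fidelity_report`: `max_lag`, `max_overshoot`
#'   (m/s), `gravity_deviation`, `path_separation` (m), `speed_difference`
#'   (signed fluid-minus-particle series, m/s).
#' @export
fidelity_metrics <- function(particle_path, fluid_pathline,
                             particle_velocity = NULL,
                             fluid_velocity_at_particle = NULL,
                             gravity_direction = c(0, -1, 0)) {
  pp <- as.matrix(particle_path)
  fp <- as.matrix(fluid_pathline)
  if (nrow(pp) == 0 || nrow(fp) == 0) stop("empty path")
  n <- min(nrow(pp), nrow(fp))
  ghat <- gravity_direction / sqrt(sum(gravity_direction^2))
  dvec <- pp[seq_len(n), , drop = FALSE] - fp[seq_len(n), , drop = FALSE]
  grav_dev <- max(c(dvec %*% ghat, 0))
  path_sep <- max(sqrt(rowSums(dvec^2)))
  max_lag <- 0
  max_overshoot <- 0
  speed_diff <- NULL
  if (!is.null(particle_velocity) && !is.null(fluid_velocity_at_particle)) {
    m <- min(nrow(particle_velocity), nrow(fluid_velocity_at_particle))
    sp <- sqrt(rowSums(as.matrix(particle_velocity)[seq_len(m), , drop = FALSE]^2))
    sf <- sqrt(rowSums(as.matrix(fluid_velocity_at_particle)[seq_len(m), , drop = FALSE]^2))
    speed_diff <- sf - sp
    if (m >= 3) {
      dsf <- c(diff(sf), 0)
      acc <- dsf > 0
      dec <- dsf < 0
      if (any(acc)) max_lag <- max(c(speed_diff[acc], 0))
      if (any(dec)) max_overshoot <- max(c(-speed_diff[dec], 0))
    }
  }
  structure(list(max_lag = max_lag, max_overshoot = max_overshoot,
                 gravity_deviation = grav_dev, path_separation = path_sep,
                 speed_difference = speed_diff),
            class = "fidelity_report")
}

#' One-call tracer fidelity assessment
#'
#' Runs [simulate_suction()] from each release point and summarises
#' [fidelity_metrics()] per release point.
#'
#' @param model a [suction_model()].
#' @param spec a [tracer_spec()].
#' @param release_points list of 3-vectors (default
#'   [default_release_points()]).
#' @param ... passed to [simulate_suction()].
#' @return data frame, one row per release point: `release`, `max_lag`,
#'   `max_overshoot`, `gravity_deviation_mm`, `path_separation_mm`,
#'   `status_particle`.
#' @export
assess_tracer_fidelity <- function(model = suction_model(),
                                   spec = tracer_spec(),
                                   release_points = default_release_points(model),
                                   ...) {
  rows <- lapply(seq_along(release_points), function(i) {
    sim <- simulate_suction(model, spec, release_points[[i]], ...)
    fm <- fidelity_metrics(sim$particle, sim$fluid_pathline,
                           sim$particle_velocity,
                           sim$fluid_velocity_at_particle,
                           model$gravity_direction)
    data.frame(release = names(release_points)[i] %||% sprintf("rp%d", i),
               max_lag = fm$max_lag, max_overshoot = fm$max_overshoot,
               gravity_deviation_mm = m_to_mm(fm$gravity_deviation),
               path_separation_mm = m_to_mm(fm$path_separation),
               status_particle = sim$status_particle)
  })
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
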