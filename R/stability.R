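#' Rigid-body parameters for the hovering stability model
#'
#' A hovering fish is modeled as a rigid body rotating about one axis
#' (roll by default; run a second instance with the radius of gyration
#' proportional to body length for pitch). The separation \code{d_comcob}
#' between the centers of mass and buoyancy creates a torque
#' \code{m g d sin(theta)} that amplifies angular displacement when the
#' COM is dorsal of the COB (\code{d_comcob > 0}, the inverted-pendulum
#' case); a negative \code{d_comcob} encodes the statically stable,
#' hanging-pendulum arrangement. The moment of inertia is
#' \code{I = mass * r_gyration^2} and rotational drag is linear in angular
#' velocity with coefficient \code{drag_coeff} (low Reynolds rotational
#' damping, proportional to wetted surface area).
#'
#' @param mass Body mass (kg).
#' @param d_comcob Signed COM–COB separation (m); positive = COM dorsal of
#'   COB (unstable).
#' @param r_gyration Radius of gyration (m) about the rotation axis
#'   (proportional to body width for roll, body length for pitch).
#' @param drag_coeff Rotational drag coefficient (N m s rad^-1).
#' @param g Gravitational acceleration (m s^-2).
#' @return Object of class \code{rigid_body} (also carries \code{inertia}).
#' @export
rigid_body <- function(mass = 0.01, d_comcob = 0.002, r_gyration = 0.004,
                       drag_coeff = 1e-5, g = 9.81) {
  stopifnot(mass > 0, r_gyration > 0, drag_coeff >= 0, g > 0)
  structure(list(mass = mass, d_comcob = d_comcob,
                 r_gyration = r_gyration, drag_coeff = drag_coeff, g = g,
                 inertia = mass * r_gyration^2),
            class = "rigid_body")
}

#' Destabilizing COM–COB torque
#'
#' \code{tau = mass * g * d_comcob * sin(theta)}: zero at the upright
#' equilibrium and, for positive \code{d_comcob}, acting to amplify any
#' angular displacement. It scales linearly with body mass and with the
#' COM–COB separation.
#'
#' @param theta Body angle (rad).
#' @param body A \code{\link{rigid_body}}.
#' @return Torque (N m), vectorized over \code{theta}.
#' @export
destabilizing_torque <- function(theta, body) {
  body$mass * body$g * body$d_comcob * sin(theta)
}

#' Corrective fin controller
#'
#' Proportional–derivative control of posture by the fins. The fish is
#' assumed to modulate fin \emph{force}; the fin's lever arm (distance of
#' its force application point from the COM) converts force to torque, so
#' the applied torque is
#' \code{tau_fin = lever_arm * clip(-(force_p * theta + force_d * omega),
#' +/- max_force)}. Fins positioned farther from the COM therefore achieve
#' the same corrective torque with smaller forces — the leverage mechanism
#' that makes distal fins more efficient stabilizers.
#'
#' @param lever_arm Fin position distance from the COM (m), positive.
#' @param force_p,force_d Proportional and derivative force gains
#'   (N rad^-1, N s rad^-1), non-negative.
#' @param max_force Force saturation (N).
#' @return Object of class \code{fin_controller}.
#' @export
fin_controller <- function(lever_arm = 0.01, force_p = 0, force_d = 0,
                           max_force = Inf) {
  stopifnot(lever_arm > 0, force_p >= 0, force_d >= 0, max_force > 0)
  structure(list(lever_arm = lever_arm, force_p = force_p,
                 force_d = force_d, max_force = max_force),
            class = "fin_controller")
}

#' Default stabilizing controller for a body
#'
#' Gains sized from the plant: torque stiffness is
#' \code{stiffness_factor} times the critical destabilizing stiffness
#' \code{m g |d|}, and torque damping is the critical damping of the
#' resulting closed loop, both divided by the lever arm to express them as
#' force gains.
#'
#' @param body A \code{\link{rigid_body}}.
#' @param lever_arm Fin lever arm (m).
#' @param stiffness_factor Multiple of the critical stiffness (default 5).
#' @param max_force Force saturation (N).
#' @return A \code{\link{fin_controller}}.
#' @export
default_controller <- function(body, lever_arm = 0.01, stiffness_factor = 5,
                               max_force = Inf) {
  mgd <- body$mass * body$g * abs(body$d_comcob)
  kp <- stiffness_factor * mgd
  kd <- 2 * sqrt(body$inertia * max(kp - mgd, .Machine$double.eps))
  fin_controller(lever_arm = lever_arm, force_p = kp / lever_arm,
                 force_d = kd / lever_arm, max_force = max_force)
}

#' Perturbation specification
#'
#' Internal perturbations are modeled as a sinusoidal ventilation torque
#' plus white torque noise. The noise is generated on a fixed 100 Hz grid
#' and linearly interpolated, so the perturbation signal — and hence the
#' simulation — is independent of the integration step and reproducible
#' from the seed.
#'
#' @param ventilation_amp Ventilation torque amplitude (N m).
#' @param ventilation_freq Ventilation frequency (Hz).
#' @param noise_sd White-noise torque standard deviation (N m).
#' @param seed Integer seed (mandatory for reproducibility).
#' @return Object of class \code{perturbation}.
#' @export
perturbation <- function(ventilation_amp = 0, ventilation_freq = 2,
                         noise_sd = 0, seed = 1L) {
  stopifnot(ventilation_amp >= 0, noise_sd >= 0, ventilation_freq > 0)
  structure(list(ventilation_amp = ventilation_amp,
                 ventilation_freq = ventilation_freq,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "perturbation")
}

#' Simulate hovering stabilization dynamics
#'
#' Integrates the single-axis torque balance
#' \deqn{I \ddot\theta = \tau_{COM-COB}(\theta) - D\,\omega + \tau_{fin} +
#'   \tau_{perturb}(t)}
#' with fixed-step 4th-order Runge–Kutta. Solving the same balance for the
#' fin torque recovers the quasi-static stability statement
#' \eqn{\tau_{fin} = \tau_{COM-COB} - I\alpha - D}: the fins must supply
#' whatever torque the destabilizing couple produces beyond what inertia
#' and drag absorb. The stabilization cost is the mechanical work of the
#' fin torque, \eqn{\int |\tau_{fin}\,\omega|\,dt}, counting positive and
#' negative work equally (no elastic storage).
#'
#' If the body angle exceeds 90 degrees the run is flagged as capsized
#' (and truncated) rather than raising an error.
#'
#' @param body A \code{\link{rigid_body}}.
#' @param controller A \code{\link{fin_controller}} (or \code{NULL} for no
#'   control).
#' @param perturb A \code{\link{perturbation}} (or \code{NULL}).
#' @param dt Integration step (s); keep below 1/(20 x natural frequency).
#' @param duration Simulated time (s).
#' @param theta0,omega0 Initial angle (rad) and angular velocity
#'   (rad s^-1).
#' @return Object of class \code{hover_sim}: vectors \code{t},
#'   \code{theta}, \code{omega}, \code{tau_fin}; scalars \code{cost} (J),
#'   \code{cost_per_kg} (J kg^-1), \code{max_angle} (rad),
#'   \code{capsized}; plus the inputs.
#' @export
simulate_hover <- function(body, controller = NULL, perturb = NULL,
                           dt = 1e-3, duration = 10,
                           theta0 = 0, omega0 = 0) {
  stopifnot(inherits(body, "rigid_body"), dt > 0, duration > 0)
  n <- as.integer(ceiling(duration / dt))
  mgd <- body$mass * body$g * body$d_comcob
  inertia <- body$inertia
  cdrag <- body$drag_coeff
  lever <- 0; kp <- 0; kd <- 0; tmax <- Inf
  if (!is.null(controller)) {
    stopifnot(inherits(controller, "fin_controller"))
    lever <- controller$lever_arm
    kp <- controller$force_p * lever
    kd <- controller$force_d * lever
    tmax <- controller$max_force * lever
  }
  # perturbation torque as a dt-independent function of time
  ptorque <- function(t) 0
  if (!is.null(perturb) &&
      (perturb$ventilation_amp > 0 || perturb$noise_sd > 0)) {
    amp <- perturb$ventilation_amp
    om <- 2 * pi * perturb$ventilation_freq
    if (perturb$noise_sd > 0) {
      tg <- seq(0, duration + 0.01, by = 0.01)
      nz <- with_seed(perturb$seed,
                      function() rnorm(length(tg), 0, perturb$noise_sd))
      nfun <- stats::approxfun(tg, nz, rule = 2)
      ptorque <- function(t) amp * sin(om * t) + nfun(t)
    } else {
      ptorque <- function(t) amp * sin(om * t)
    }
  }
  fin_torque <- function(th, om_) {
    tau <- -(kp * th + kd * om_)
    if (tau > tmax) tau <- tmax else if (tau < -tmax) tau <- -tmax
    tau
  }
  tvec <- numeric(n + 1); thv <- numeric(n + 1); omv <- numeric(n + 1)
  tauv <- numeric(n + 1)
  th <- theta0; om_ <- omega0
  thv[1] <- th; omv[1] <- om_; tauv[1] <- fin_torque(th, om_)
  cost <- 0
  capsized <- FALSE
  accel <- function(th, om_, pt) {
    (mgd * sin(th) - cdrag * om_ + fin_torque(th, om_) + pt) / inertia
  }
  last <- n + 1L
  for (i in seq_len(n)) {
    t0 <- (i - 1) * dt
    p1 <- ptorque(t0); p2 <- ptorque(t0 + dt / 2); p3 <- ptorque(t0 + dt)
    k1t <- om_;               k1o <- accel(th, om_, p1)
    k2t <- om_ + dt / 2 * k1o
    k2o <- accel(th + dt / 2 * k1t, om_ + dt / 2 * k1o, p2)
    k3t <- om_ + dt / 2 * k2o
    k3o <- accel(th + dt / 2 * k2t, om_ + dt / 2 * k2o, p2)
    k4t <- om_ + dt * k3o
    k4o <- accel(th + dt * k3t, om_ + dt * k3o, p3)
    th <- th + dt / 6 * (k1t + 2 * k2t + 2 * k3t + k4t)
    om_ <- om_ + dt / 6 * (k1o + 2 * k2o + 2 * k3o + k4o)
    tf <- fin_torque(th, om_)
    tvec[i + 1] <- i * dt; thv[i + 1] <- th; omv[i + 1] <- om_
    tauv[i + 1] <- tf
    cost <- cost + abs(tf * om_) * dt
    if (abs(th) > pi / 2) {
      capsized <- TRUE
      last <- i + 1L
      break
    }
  }
  idx <- seq_len(last)
  structure(list(t = tvec[idx], theta = thv[idx], omega = omv[idx],
                 tau_fin = tauv[idx], cost = cost,
                 cost_per_kg = cost / body$mass,
                 max_angle = max(abs(thv[idx])), capsized = capsized,
                 body = body, controller = controller, perturb = perturb,
                 dt = dt, duration = duration),
            class = "hover_sim")
}

#' @export
print.hover_sim <- function(x, ...) {
  cat(sprintf("Hovering stabilization simulation: %.1f s at dt = %g s\n",
              x$duration, x$dt))
  cat(sprintf("  max |angle| %.2f deg%s, fin work %.3g J (%.3g J/kg)\n",
              x$max_angle * 180 / pi,
              if (x$capsized) " [CAPSIZED]" else "", x$cost, x$cost_per_kg))
  invisible(x)
}

#' @export
plot.hover_sim <- function(x, ...) {
  op <- par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(par(op))
  plot(x$t, x$theta * 180 / pi, type = "l", xlab = "time (s)",
       ylab = "angle (deg)", ...)
  abline(h = 0, lty = 3)
  plot(x$t, x$tau_fin, type = "l", xlab = "time (s)",
       ylab = "fin torque (N m)", ...)
  invisible(x)
}

#' Stabilization cost of a simulated run
#'
#' Mechanical work of the corrective fin torque divided by a muscle
#' efficiency fraction, reported both absolute and mass-specific (with
#' the mean mass-specific power).
#'
#' @param result A \code{\link{hover_sim}}.
#' @param efficiency Conversion efficiency in (0, 1].
#' @return List with \code{work_j}, \code{work_j_per_kg},
#'   \code{power_w_per_kg}.
#' @export
stabilization_cost <- function(result, efficiency = 1) {
  stopifnot(inherits(result, "hover_sim"))
  if (efficiency <= 0 || efficiency > 1)
    stop("efficiency must be in (0, 1]")
  w <- result$cost / efficiency
  elapsed <- max(result$t)
  list(work_j = w, work_j_per_kg = w / result$body$mass,
       power_w_per_kg = w / result$body$mass / elapsed)
}

#' Sweep morphology and regress stabilization cost on it
#'
#' Simulates stabilization over a factorial grid of morphological factors
#' and regresses the mass-specific stabilization cost on them, reporting
#' coefficients and their signs. Factors:
#' \describe{
#'   \item{mass}{Body mass (kg). The radius of gyration and the drag
#'     surface scale isometrically with mass (\code{r ~ m^(1/3)},
#'     \code{surface ~ m^(2/3)}) from the reference body.}
#'   \item{comcob_dv}{Signed dorsal–ventral COM–COB offset (proportion of
#'     body depth, dorsal origin: negative = COB ventral of COM). The
#'     metric separation is \code{|comcob_dv|} times a fixed reference
#'     body depth \code{tl / fineness_ref}, so the factor stays
#'     independent of the fineness factor.}
#'   \item{fineness}{Fineness ratio, entering only through the
#'     drag/surface proxy: drag scales with \code{fineness_ref /
#'     fineness} (thinner bodies, less wetted area, less damping).}
#'   \item{lever_arm}{Pectoral fin lever arm (m), converting the fixed
#'     force gains to torque gains.}
#' }
#' Under a fixed controller and perturbation, this morphospace reproduces
#' the predicted coefficient pattern: negative for mass and for the
#' (dorsal-origin, signed) COM–COB offset, negative for fin lever arm and
#' positive for fineness.
#'
#' @param grid Named list of factor levels (each with >= 2 unique values):
#'   \code{mass}, \code{comcob_dv}, \code{fineness}, \code{lever_arm}.
#' @param controller A \code{\link{fin_controller}} whose force gains are
#'   held fixed across the grid (default: sized for the reference body).
#' @param perturb A \code{\link{perturbation}}; defaults to ventilation at
#'   2 Hz plus torque noise under \code{seed}.
#' @param seed Seed for the perturbation noise.
#' @param dt,duration Integration settings per cell.
#' @param tl Reference total length (m).
#' @param fineness_ref Reference fineness ratio fixing body depth and the
#'   drag scale.
#' @param drag0 Drag coefficient of the reference body (N m s rad^-1).
#' @param r_ref,m_ref Reference radius of gyration (m) and mass (kg)
#'   anchoring the isometric scalings.
#' @return Object of class \code{hover_sweep}: \code{table} (one row per
#'   cell with factors and costs), \code{fit} (a \code{\link{hover_lm}}),
#'   \code{coefficients}, \code{signs}, \code{n_capsized}.
#' @export
sweep_and_fit <- function(grid = list(mass = c(0.005, 0.02),
                                      comcob_dv = c(-0.20, -0.05),
                                      fineness = c(3, 6),
                                      lever_arm = c(0.005, 0.015)),
                          controller = NULL, perturb = NULL, seed = 1L,
                          dt = 5e-4, duration = 10, tl = 0.05,
                          fineness_ref = 4, drag0 = 1e-5,
                          r_ref = 0.004, m_ref = 0.01) {
  stopifnot(all(c("mass", "comcob_dv", "fineness", "lever_arm") %in%
                  names(grid)))
  for (nm in names(grid))
    if (length(unique(grid[[nm]])) < 2)
      stop("grid factor '", nm, "' has fewer than 2 levels: ",
           "its coefficient is undefined")
  depth_ref <- tl / fineness_ref
  if (is.null(controller)) {
    # stiffness sized on the worst-case destabilizing couple (largest mass
    # and separation); damping sized critically for the smallest inertia in
    # the grid so no cell's closed loop is overdamped-stiff
    mgd_max <- max(grid$mass) * 9.81 * max(abs(grid$comcob_dv)) * depth_ref
    i_min <- min(grid$mass) *
      (r_ref * (min(grid$mass) / m_ref)^(1 / 3))^2
    kp <- 5 * mgd_max
    kd <- 2 * sqrt(i_min * (kp - mgd_max))
    lev0 <- min(grid$lever_arm)
    controller <- fin_controller(lever_arm = lev0, force_p = kp / lev0,
                                 force_d = kd / lev0)
  }
  perturb <- perturb %||% perturbation(ventilation_amp = 4e-5,
                                       ventilation_freq = 2,
                                       noise_sd = 1e-5, seed = seed)
  cells <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE)
  cells$cost_j <- NA_real_
  cells$cost_j_per_kg <- NA_real_
  cells$max_angle_deg <- NA_real_
  cells$capsized <- FALSE
  for (i in seq_len(nrow(cells))) {
    mass <- cells$mass[i]
    body <- rigid_body(
      mass = mass,
      d_comcob = abs(cells$comcob_dv[i]) * depth_ref,
      r_gyration = r_ref * (mass / m_ref)^(1 / 3),
      drag_coeff = drag0 * (mass / m_ref)^(2 / 3) *
        fineness_ref / cells$fineness[i])
    ctrl <- fin_controller(lever_arm = cells$lever_arm[i],
                           force_p = controller$force_p,
                           force_d = controller$force_d,
                           max_force = controller$max_force)
    sim <- simulate_hover(body, ctrl, perturb, dt = dt,
                          duration = duration)
    cells$cost_j[i] <- sim$cost
    cells$cost_j_per_kg[i] <- sim$cost_per_kg
    cells$max_angle_deg[i] <- sim$max_angle * 180 / pi
    cells$capsized[i] <- sim$capsized
  }
  if (any(cells$capsized))
    warning(sum(cells$capsized), " capsized cell(s) excluded from the fit")
  if (mean(cells$capsized) > 0.5)
    stop("more than 50% of sweep cells capsized: grid or controller ",
         "ill-posed")
  ok <- !cells$capsized
  fit <- hover_lm(cost_j_per_kg ~ mass + comcob_dv + fineness + lever_arm,
                  cells[ok, ])
  cf <- coef(fit)[-1]
  structure(list(table = cells, fit = fit, coefficients = cf,
                 signs = sign(cf), n_capsized = sum(cells$capsized)),
            class = "hover_sweep")
}

#' @export
print.hover_sweep <- function(x, ...) {
  cat(sprintf("Morphology sweep: %d cells (%d capsized), cost model R2 = %.3f\n",
              nrow(x$table), x$n_capsized, x$fit$r2))
  print(data.frame(coefficient = x$coefficients, sign = x$signs))
  invisible(x)
}
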