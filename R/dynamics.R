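#' Define a steering force
#'
#' User steering: an elastic pull between the geometric center of a
#' selected particle group and a movable target point (the "input
#' device"). The total pull is `F = k (target - center)`, capped at
#' `max_force`, then divided equally among the group members, so the
#' force is a pure function of the current coordinates and the current
#' target -- independent of how often the target is updated.
#'
#' @param selection non-empty `selection` to pull.
#' @param k spring constant (kcal/mol/A^2), >= 0.
#' @param target length-3 target point (A); updatable between steps.
#' @param max_force cap on the total pull magnitude (kcal/mol/A),
#'   default 500 -- excessive forces destabilize the dynamics.
#' @return object of class `steering_force`.
#' @export
steering_force <- function(selection, k, target, max_force = 500) {
  stopifnot(inherits(selection, "selection"))
  if (k < 0) stop("steering spring constant must be >= 0")
  if (max_force <= 0) stop("max_force must be > 0")
  target <- as.numeric(target)
  stopifnot(length(target) == 3L)
  structure(list(selection = selection, k = k, target = target,
                 max_force = max_force),
            class = "steering_force")
}

#' Evaluate steering forces
#'
#' @param steers list of `steering_force`s (may be empty).
#' @param coords N x 3 coordinate matrix.
#' @return N x 3 force matrix (kcal/mol/A).
#' @export
apply_steering <- function(steers, coords) {
  coords <- as_coord_matrix(coords)
  forces <- matrix(0, nrow(coords), 3)
  for (s in steers) {
    stopifnot(inherits(s, "steering_force"))
    check_selection(s$selection, nrow(coords))
    center <- geometric_center(coords, s$selection)
    pull <- s$k * (s$target - center)
    mag <- sqrt(sum(pull * pull))
    if (mag > s$max_force) pull <- pull * (s$max_force / mag)
    idx <- s$selection$indices
    share <- matrix(pull / length(idx), length(idx), 3, byrow = TRUE)
    forces[idx, ] <- forces[idx, ] + share
  }
  forces
}

#' Create a simulation state
#'
#' Holds coordinates, velocities, the step counter and the integrator
#' settings. Two deterministic integrators are available:
#' \describe{
#'   \item{`damped-verlet`}{(default) per dynamic particle
#'     `v <- (1 - damping) * (v + F/m * c * dt)`, `x <- x + v dt`, where c
#'     converts (kcal/mol/A)/amu to A/fs^2. `damping` in (0, 1] is the
#'     per-step velocity loss (the retained fraction is 1 - damping).}
#'   \item{`overdamped`}{`x <- x + mobility * F * dt` (no inertia); exists
#'     to make closed-form relaxation solutions exact.}
#' }
#' Static particles (dynamic flag FALSE) keep zero velocity and never
#' move. A global per-step displacement cap (default 0.5 A) guards
#' against destabilizing forces. There is no thermal noise anywhere: runs
#' are fully deterministic.
#'
#' @param system a `particle_system` (supplies masses and the static set).
#' @param coords optional starting coordinates (default: the system's).
#' @param time_step dt in fs, default 1. For the stiffest enabled spring
#'   the guideline is `dt <= 0.5 * sqrt(m_min / (2 K_max * c))`.
#' @param damping gamma in (0, 1], default 0.1.
#' @param integrator `"damped-verlet"` or `"overdamped"`.
#' @param mobility overdamped mobility mu (A^2 mol/kcal/fs), default 1e-3.
#' @param displacement_cap max per-particle displacement per step (A).
#' @return object of class `simulation_state`.
#' @export
simulation_state <- function(system, coords = NULL, time_step = 1,
                             damping = 0.1,
                             integrator = c("damped-verlet", "overdamped"),
                             mobility = 1e-3, displacement_cap = 0.5) {
  integrator <- match.arg(integrator)
  if (damping <= 0 || damping > 1) stop("damping must be in (0, 1]")
  if (time_step <= 0) stop("time_step must be > 0")
  if (is.null(coords)) coords <- get_coords(system)
  coords <- as_coord_matrix(coords, n_particles(system))
  if (integrator == "damped-verlet" && any(system$atoms$mass <= 0 &
                                           system$atoms$dynamic))
    stop("damped-verlet needs positive masses for all dynamic particles; run assign_parameters()")
  structure(list(coords = coords,
                 velocities = matrix(0, nrow(coords), 3),
                 step = 0L, time_step = time_step, damping = damping,
                 integrator = integrator, mobility = mobility,
                 displacement_cap = displacement_cap,
                 mass = system$atoms$mass,
                 static_mask = !system$atoms$dynamic),
            class = "simulation_state")
}

#' Advance the simulation by one step
#'
#' Computes total forces (terms + steering), applies the damped update to
#' the dynamic set, caps per-particle displacements, leaves the static set
#' untouched and increments the step counter. Non-finite coordinates after
#' the update raise a stability error naming the worst particle.
#'
#' @param state a `simulation_state`.
#' @param terms list of `force_term`s (at least one enabled).
#' @param steers list of `steering_force`s, default none.
#' @return the updated `simulation_state`, with the energy report of the
#'   evaluated terms attached as attribute `report`.
#' @export
step_dynamics <- function(state, terms, steers = list()) {
  tf <- total_energy_forces(terms, state$coords)
  forces <- tf$forces + apply_steering(steers, state$coords)
  state <- advance_state(state, forces)
  attr(state, "report") <- tf$report
  state
}

advance_state <- function(state, forces) {
  dt <- state$time_step
  mob <- state$static_mask
  if (state$integrator == "damped-verlet") {
    acc <- forces / state$mass * .ACCEL
    v <- (1 - state$damping) * (state$velocities + acc * dt)
    v[mob, ] <- 0
    dx <- v * dt
  } else {
    dx <- state$mobility * forces * dt
    dx[mob, ] <- 0
    v <- matrix(0, nrow(forces), 3)
  }
  # per-particle displacement cap
  norm <- sqrt(rowSums(dx * dx))
  over <- norm > state$displacement_cap
  if (any(over)) {
    fac <- state$displacement_cap / norm[over]
    dx[over, ] <- dx[over, ] * fac
    if (state$integrator == "damped-verlet") v[over, ] <- dx[over, ] / dt
  }
  coords <- state$coords + dx
  if (!all(is.finite(coords))) {
    bad <- which(!apply(is.finite(coords), 1, all))[1]
    stop(sprintf("stability error: non-finite coordinates at step %d (worst particle %d)",
                 state$step + 1L, bad))
  }
  state$coords <- coords
  state$velocities <- v
  state$step <- state$step + 1L
  state
}

#' Run several dynamics steps
#'
#' Convenience loop over [step_dynamics()].
#'
#' @param state a `simulation_state`.
#' @param terms list of `force_term`s.
#' @param n_steps number of steps.
#' @param steers list of `steering_force`s applied every step.
#' @return the updated `simulation_state`.
#' @export
run_steps <- function(state, terms, n_steps, steers = list()) {
  for (k in seq_len(n_steps)) state <- step_dynamics(state, terms, steers)
  state
}

#' Steepest-descent energy minimization with adaptive step
#'
#' Moves along the force direction with a trial step that is halved
#' whenever the energy would increase (so the accepted energy sequence is
#' monotone non-increasing) and grown gently after success. Stops when the
#' max per-particle force norm drops below `force_tol` or `max_steps` is
#' reached.
#'
#' @param coords starting N x 3 coordinates.
#' @param terms list of `force_term`s.
#' @param max_steps iteration budget, >= 1.
#' @param force_tol convergence threshold on the max per-particle force
#'   (kcal/mol/A), default 1e-4.
#' @param step0 initial step scale (A^2 mol/kcal), default 1e-2.
#' @param static_mask optional logical vector freezing particles.
#' @return list with `coords`, `energy`, `converged`, `n_steps`.
#' @export
minimize_energy <- function(coords, terms, max_steps = 1000,
                            force_tol = 1e-4, step0 = 1e-2,
                            static_mask = NULL) {
  stopifnot(max_steps >= 1)
  coords <- as_coord_matrix(coords)
  if (is.null(static_mask)) static_mask <- rep(FALSE, nrow(coords))
  tf <- total_energy_forces(terms, coords)
  energy <- tf$report$total
  forces <- tf$forces
  forces[static_mask, ] <- 0
  alpha <- step0
  steps <- 0L
  converged <- max(sqrt(rowSums(forces * forces))) < force_tol
  while (!converged && steps < max_steps) {
    trial <- coords + alpha * forces
    tt <- tryCatch(total_energy_forces(terms, trial), error = function(e) NULL)
    if (is.null(tt) || tt$report$total > energy) {
      alpha <- alpha / 2
      if (alpha < 1e-12) break
      next
    }
    coords <- trial
    energy <- tt$report$total
    forces <- tt$forces
    forces[static_mask, ] <- 0
    alpha <- alpha * 1.2
    steps <- steps + 1L
    converged <- max(sqrt(rowSums(forces * forces))) < force_tol
  }
  list(coords = coords, energy = energy, converged = converged,
       n_steps = steps)
}
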