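#' Run a simulation from a validated configuration
#'
#' Builds the system (read, optional coarse-grain, parameter assignment,
#' static set), the spring layers and every enabled augmented term, then
#' integrates the configured number of steps. A trajectory frame and one
#' observables row are emitted every `output.stride` steps (frame 0 is
#' always written, so a 0-step run produces one frame and one row). The
#' engine contains no randomness: identical configs give bit-identical
#' output files.
#'
#' The observables table has one header row and fixed column order: `step`,
#' one energy column per enabled term (`e_springs`, `e_lj`, `e_coulomb`,
#' `e_field`, `e_membrane`, `e_sasa`), `e_total`, then `depth` and `tilt`
#' when a membrane is configured (tilt only when `tilt_a`/`tilt_b` are
#' given), `sasa_total` when the surface term is enabled, and `steer_mag`
#' when steering is configured. The score-only surface term is recomputed
#' every `sasa.stride` observable frames (cost control), not every step.
#'
#' @param config an `aenm_config` from [load_config()], or a path to one.
#' @return list with `system`, `state` (final), `observables` (data.frame)
#'   and the output file paths.
#' @export
run_simulation <- function(config) {
  if (is.character(config)) config <- load_config(config)
  stopifnot(inherits(config, "aenm_config"))
  sys <- read_structure(config$system$structure)
  if (isTRUE(config$system$coarse_grain))
    sys <- coarse_grain(sys, scheme = config$system$scheme)
  table <- if (!is.null(config$system$parameters))
    read_parameter_table(config$system$parameters) else default_parameter_table()
  sys <- assign_parameters(sys, table, keep_charge = TRUE)
  if (!is.null(config$system$static)) {
    st <- select_particles(sys, config$system$static)
    sys$atoms$dynamic[st$indices] <- FALSE
  }

  layers <- lapply(config$springs, function(lay) {
    within <- if (!is.null(lay$within)) select_particles(sys, lay$within)
    build_springs(sys, cutoff = lay$cutoff, stiffness = lay$stiffness,
                  within = within, layer = lay$layer)
  })
  net <- if (length(layers)) merge_layers(layers) else NULL

  terms <- list()
  if (!is.null(net)) terms <- c(terms, list(spring_term(net)))
  if (!is.null(config$nonbonded) && isTRUE(config$nonbonded$enabled))
    terms <- c(terms, nonbonded_terms(
      sys, net = net,
      lj_cutoff = config$nonbonded$lj_cutoff,
      coulomb_cutoff = config$nonbonded$coulomb_cutoff,
      dielectric = config$nonbonded$dielectric,
      lj_enabled = isTRUE(config$nonbonded$lj),
      coulomb_enabled = isTRUE(config$nonbonded$coulomb)))
  if (!is.null(config$field) && !is.null(config$field$file)) {
    grid <- read_dx(config$field$file, mode = config$field$mode)
    terms <- c(terms, list(field_term(grid, sys, weight = config$field$weight)))
  }
  mem <- NULL
  if (!is.null(config$membrane)) {
    mem <- membrane_model(config$membrane$center_z,
                          config$membrane$half_thickness,
                          config$membrane$interface_width,
                          config$membrane$scale,
                          config$membrane$second_center_z)
    terms <- c(terms, list(membrane_term(mem, sys)))
  }
  sasa_cfg <- config$sasa
  sasa_dynamic <- !is.null(sasa_cfg) && isTRUE(sasa_cfg$enabled) &&
    identical(sasa_cfg$mode, "finite_difference")
  sasa_score <- !is.null(sasa_cfg) && isTRUE(sasa_cfg$enabled) && !sasa_dynamic
  stm <- if (!is.null(sasa_cfg) && isTRUE(sasa_cfg$enabled))
    sasa_term(sys, probe_radius = sasa_cfg$probe_radius,
              n_points = sasa_cfg$n_points,
              mode = if (sasa_dynamic) "finite_difference" else "score")
  if (sasa_dynamic) terms <- c(terms, list(stm))
  if (length(terms) == 0L) stop("config enables no force term")

  steers <- lapply(config$steering, function(s)
    steering_force(select_particles(sys, s$selection), k = s$k,
                   target = as.numeric(s$target), max_force = s$max_force))
  steer_window <- lapply(config$steering, function(s)
    c(s$from_step %||% 0, s$until_step %||% Inf))

  dyn <- config$dynamics
  state <- simulation_state(sys, time_step = dyn$time_step,
                            damping = dyn$damping,
                            integrator = dyn$integrator,
                            mobility = dyn$mobility,
                            displacement_cap = dyn$displacement_cap)

  traj_con <- NULL
  if (!is.null(config$output$trajectory)) {
    traj_con <- file(config$output$trajectory, "wt")
    on.exit(close(traj_con), add = TRUE)
  }
  stride <- max(1L, as.integer(config$output$stride))
  depth_sel <- if (!is.null(mem))
    select_particles(sys, config$membrane$depth_selection)
  tilt_sels <- if (!is.null(mem) && !is.null(config$membrane$tilt_a) &&
                   !is.null(config$membrane$tilt_b))
    list(a = select_particles(sys, config$membrane$tilt_a),
         b = select_particles(sys, config$membrane$tilt_b))

  obs_rows <- list()
  frame <- 0L
  sasa_counter <- 0L
  sasa_total <- NA_real_
  emit <- function(state) {
    tf <- total_energy_forces(terms, state$coords)
    row <- list(step = state$step)
    for (nm in names(tf$report))
      if (nm != "total") row[[paste0("e_", nm)]] <- tf$report[[nm]]
    if (sasa_score) {
      if (sasa_counter %% max(1L, as.integer(sasa_cfg$stride)) == 0L) {
        r <- stm$evaluate(state$coords)
        sasa_total <<- sum(stm$cache$areas)
        row$e_sasa <- r$energy
      } else row$e_sasa <- obs_rows[[length(obs_rows)]]$e_sasa
      sasa_counter <<- sasa_counter + 1L
    }
    row$e_total <- sum(unlist(row[grepl("^e_", names(row))]))
    if (!is.null(mem)) {
      row$depth <- insertion_depth(mem, state$coords, depth_sel)
      if (!is.null(tilt_sels))
        row$tilt <- tilt_angle(state$coords, tilt_sels$a, tilt_sels$b)
    }
    if (sasa_score || sasa_dynamic) row$sasa_total <-
      if (sasa_score) sasa_total else sum(stm$cache$areas)
    if (length(steers)) {
      mags <- vapply(active_steers(state$step), function(s) {
        pull <- s$k * (s$target - geometric_center(state$coords, s$selection))
        min(sqrt(sum(pull^2)), s$max_force)
      }, numeric(1))
      row$steer_mag <- if (length(mags)) sum(mags) else 0
    }
    obs_rows[[length(obs_rows) + 1L]] <<- row
    if (!is.null(traj_con)) {
      frame <<- frame + 1L
      write_trajectory_frame(traj_con, sys, state$coords, frame)
    }
  }
  active_steers <- function(step)
    steers[vapply(seq_along(steers), function(k)
      step >= steer_window[[k]][1] && step < steer_window[[k]][2],
      logical(1))]

  emit(state)
  n_steps <- as.integer(dyn$steps)
  for (k in seq_len(n_steps)) {
    state <- step_dynamics(state, terms, active_steers(state$step))
    if (state$step %% stride == 0L || state$step == n_steps) emit(state)
  }

  obs <- do.call(rbind, lapply(obs_rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  obs <- obs[!duplicated(obs$step), , drop = FALSE]
  rownames(obs) <- NULL
  if (!is.null(config$output$observables))
    write_observables(obs, config$output$observables)
  list(system = sys, state = state, observables = obs,
       trajectory = config$output$trajectory,
       observables_file = config$output$observables)
}

# fixed-format observables writer: deterministic output for identical runs
write_observables <- function(obs, path) {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(paste(names(obs), collapse = "\t"), con)
  rows <- apply(obs, 1, function(r)
    paste(vapply(r, function(x)
      if (is.na(suppressWarnings(as.numeric(x)))) as.character(x)
      else format(as.numeric(x), digits = 15), character(1)),
      collapse = "\t"))
  writeLines(rows, con)
  invisible(path)
}

#' Read an observables file written by [run_simulation()]
#' @param path observables TSV path.
#' @return data.frame.
#' @export
read_observables <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
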