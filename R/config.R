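# configuration schema: known keys and defaults per block
config_schema <- function() {
  list(
    system = list(structure = NULL, parameters = NULL, coarse_grain = FALSE,
                  scheme = "auto", static = NULL, name = NULL),
    springs = list(cutoff = 9, stiffness = 0.6, within = NULL,
                   between = NULL, layer = NULL),
    nonbonded = list(enabled = TRUE, lj = TRUE, coulomb = TRUE,
                     lj_cutoff = 12, coulomb_cutoff = 16, dielectric = 1),
    field = list(file = NULL, mode = "potential", weight = 1),
    membrane = list(center_z = 0, half_thickness = 15, interface_width = 1.5,
                    scale = 1, second_center_z = NULL,
                    depth_selection = "all", tilt_a = NULL, tilt_b = NULL),
    sasa = list(probe_radius = 1.4, n_points = 256, mode = "score",
                stride = 10, enabled = TRUE),
    dynamics = list(integrator = "damped-verlet", time_step = 1,
                    damping = 0.1, mobility = 1e-3, steps = 0,
                    displacement_cap = 0.5),
    steering = list(selection = NULL, k = 1, target = NULL, max_force = 500,
                    from_step = 0, until_step = NULL),
    output = list(trajectory = NULL, observables = NULL, stride = 10)
  )
}

# fill one block with defaults, rejecting unknown keys (with a suggestion)
validate_block <- function(block, name, given, errors) {
  defaults <- config_schema()[[name]]
  out <- defaults
  for (key in names(given)) {
    if (!key %in% names(defaults)) {
      near <- agrep(key, names(defaults), max.distance = 2, value = TRUE)
      hint <- if (length(near)) paste0(" (did you mean '", near[1], "'?)") else ""
      errors$msgs <- c(errors$msgs,
                       sprintf("unknown key '%s.%s'%s", name, key, hint))
    } else out[[key]] <- given[[key]]
  }
  out
}

#' Load and validate a simulation configuration
#'
#' Configurations are YAML files with blocks `system`, `springs` (a list
#' of layers), `nonbonded`, `field`, `membrane`, `sasa`, `dynamics`,
#' `steering` (a list of pulls) and `output`. Validation materializes all
#' defaults, rejects unknown keys (with a nearest-key suggestion against
#' typos) and reports every violation at once. Relative paths are resolved
#' against the config file's directory. A spring cutoff outside the
#' commonly used 7-15 A range produces a warning but the run proceeds.
#'
#' @param path YAML configuration file.
#' @return validated config (named list) with class `aenm_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path)
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) stop("config is not a mapping: ", path)
  errors <- new.env(parent = emptyenv())
  errors$msgs <- character(0)
  known_blocks <- names(config_schema())
  for (b in names(raw))
    if (!b %in% known_blocks) {
      near <- agrep(b, known_blocks, max.distance = 2, value = TRUE)
      hint <- if (length(near)) paste0(" (did you mean '", near[1], "'?)") else ""
      errors$msgs <- c(errors$msgs, sprintf("unknown block '%s'%s", b, hint))
    }
  cfg <- list()
  cfg$system <- validate_block(raw$system %||% list(), "system",
                               raw$system %||% list(), errors)
  if (is.null(cfg$system$structure))
    errors$msgs <- c(errors$msgs, "system.structure is required")
  layers <- raw$springs %||% list()
  if (!is.null(names(layers)) && length(names(layers)))
    layers <- list(layers)  # single mapping means one layer
  cfg$springs <- lapply(seq_along(layers), function(k) {
    lay <- validate_block(layers[[k]], "springs", layers[[k]], errors)
    if (is.null(lay$layer)) lay$layer <- paste0("layer", k)
    if (!is.null(lay$cutoff) && lay$cutoff > 0 &&
        (lay$cutoff < 7 || lay$cutoff > 15))
      warning(sprintf("springs layer %d: cutoff %.1f A is outside the commonly used 7-15 A range",
                      k, lay$cutoff))
    if (!is.null(lay$cutoff) && lay$cutoff <= 0)
      errors$msgs <- c(errors$msgs,
                       sprintf("springs layer %d: cutoff must be > 0", k))
    lay
  })
  for (b in c("nonbonded", "field", "membrane", "sasa", "dynamics", "output"))
    cfg[[b]] <- if (is.null(raw[[b]])) NULL
      else validate_block(raw[[b]], b, raw[[b]], errors)
  steers <- raw$steering %||% list()
  if (!is.null(names(steers)) && length(names(steers))) steers <- list(steers)
  cfg$steering <- lapply(seq_along(steers), function(k) {
    s <- validate_block(steers[[k]], "steering", steers[[k]], errors)
    if (is.null(s$selection) || is.null(s$target))
      errors$msgs <- c(errors$msgs,
                       sprintf("steering %d: selection and target are required", k))
    s
  })
  if (is.null(cfg$output)) cfg$output <- config_schema()$output
  if (is.null(cfg$dynamics)) cfg$dynamics <- config_schema()$dynamics
  if (length(errors$msgs))
    stop("invalid config '", path, "':\n  - ",
         paste(errors$msgs, collapse = "\n  - "))
  # resolve relative paths against the config directory
  base <- dirname(normalizePath(path))
  fix_path <- function(p) {
    if (is.null(p)) return(NULL)
    if (grepl("^(/|[A-Za-z]:)", p)) p else file.path(base, p)
  }
  cfg$system$structure <- fix_path(cfg$system$structure)
  cfg$system$parameters <- fix_path(cfg$system$parameters)
  if (!is.null(cfg$field)) cfg$field$file <- fix_path(cfg$field$file)
  cfg$output$trajectory <- fix_path(cfg$output$trajectory)
  cfg$output$observables <- fix_path(cfg$output$observables)
  class(cfg) <- "aenm_config"
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a
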