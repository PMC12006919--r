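#' Create a live-control session
#'
#' Core of the newline-delimited text command protocol used to steer a
#' running simulation. The session is a pure value: [live_command()] maps
#' (session, command line) to (updated session, one text reply), so the
#' protocol can be served over any line-based transport (a socket loop, a
#' pipe, a REPL) and is trivially testable. Live-tunable parameters are
#' `damping`, `membrane.scale` and `steer.k`.
#'
#' Commands (one per line, one reply per command):
#' \describe{
#'   \item{`SELECT <expr>`}{set the steering selection.}
#'   \item{`TARGET x y z`}{set/update the steering target point.}
#'   \item{`K <value>`}{set the steering spring constant.}
#'   \item{`PARAM <key> <value>`}{set a live-tunable parameter.}
#'   \item{`GET ENERGY|DEPTH|SASA`}{query the latest observables row.}
#' }
#'
#' @param system a `particle_system` (selections are parsed against it).
#' @param params named list of live-tunable values (defaults:
#'   `damping = 0.1`, `membrane.scale = 1`, `steer.k = 1`).
#' @return object of class `live_session`.
#' @export
live_session <- function(system, params = list()) {
  defaults <- list(damping = 0.1, membrane.scale = 1, steer.k = 1)
  for (k in names(params)) defaults[[k]] <- params[[k]]
  structure(list(system = system, selection = NULL, target = NULL,
                 params = defaults,
                 observables = list(ENERGY = NA_real_, DEPTH = NA_real_,
                                    SASA = NA_real_)),
            class = "live_session")
}

#' Process one live-protocol command
#'
#' @param session a `live_session`.
#' @param line one command line (see [live_session()]).
#' @return list with `session` (updated) and `reply` (one text line,
#'   starting `OK`, a value, or `ERR <reason>`).
#' @export
live_command <- function(session, line) {
  toks <- strsplit(trimws(line), "[[:space:]]+")[[1]]
  if (length(toks) == 0L)
    return(list(session = session, reply = "ERR empty command"))
  cmd <- toupper(toks[1])
  reply <- tryCatch(switch(cmd,
    "SELECT" = {
      expr <- paste(toks[-1], collapse = " ")
      session$selection <- select_particles(session$system, expr)
      sprintf("OK %d particles", length(session$selection$indices))
    },
    "TARGET" = {
      if (length(toks) != 4L) stop("TARGET needs x y z")
      v <- as.numeric(toks[2:4])
      if (any(is.na(v))) stop("TARGET needs numeric x y z")
      session$target <- v
      "OK"
    },
    "K" = {
      v <- as.numeric(toks[2])
      if (is.na(v) || v < 0) stop("K needs a non-negative number")
      session$params$steer.k <- v
      "OK"
    },
    "PARAM" = {
      if (length(toks) != 3L) stop("PARAM needs <key> <value>")
      key <- toks[2]
      if (!key %in% c("damping", "membrane.scale", "steer.k"))
        stop("unknown live parameter '", key, "'")
      v <- as.numeric(toks[3])
      if (is.na(v)) stop("PARAM needs a numeric value")
      session$params[[key]] <- v
      "OK"
    },
    "GET" = {
      key <- toupper(toks[2] %||% "")
      if (!key %in% names(session$observables))
        stop("GET needs one of ENERGY, DEPTH, SASA")
      format(session$observables[[key]], digits = 10)
    },
    stop("unknown command '", cmd, "'")
  ), error = function(e) paste("ERR", conditionMessage(e)))
  list(session = session, reply = reply)
}

#' Push fresh observable values into a live session
#'
#' Called by a serving loop after each observable frame so `GET` replies
#' reflect the current state.
#'
#' @param session a `live_session`.
#' @param energy,depth,sasa latest values (NA allowed).
#' @return the updated session.
#' @export
live_update_observables <- function(session, energy = NA_real_,
                                    depth = NA_real_, sasa = NA_real_) {
  session$observables <- list(ENERGY = energy, DEPTH = depth, SASA = sasa)
  session
}

#' Current steering force defined by a live session
#'
#' @param session a `live_session`.
#' @param max_force cap passed through to [steering_force()].
#' @return a `steering_force`, or `NULL` if no selection/target is set.
#' @export
live_steering <- function(session, max_force = 500) {
  if (is.null(session$selection) || is.null(session$target)) return(NULL)
  steering_force(session$selection, k = session$params$steer.k,
                 target = session$target, max_force = max_force)
}
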