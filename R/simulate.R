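#' Integrate one iron challenge
#'
#' Integrates the chosen model over a single challenge window with a
#' stiff-capable adaptive solver. The apical concentration is not integrated
#' as a separate state: it is recovered algebraically from the exact mass
#' balance `V_a * FeOUT + V_cb * FeIN = const`, so iron conservation holds to
#' machine precision along the trajectory. For the switch model, mode
#' transitions are located by root-finding on the threshold functions
#' `P5 - alpha_E` (endocytic mode) and `P1+P2+P3+P4 - alpha_M` (exocytic
#' mode), after which integration restarts in the flipped mode. For the swing
#' model the kinetic correction factor is re-evaluated continuously from the
#' instantaneous `FeIN` via [rho_factor()].
#'
#' @param params A [switch_params()] or [swing_params()] object (the model is
#'   inferred from its class).
#' @param geometry A [cell_geometry()] object.
#' @param initial_state A [model_state()]; its `FeOUT` is the challenge
#'   concentration.
#' @param duration Challenge duration (min).
#' @param output_times Times (min, relative to challenge start) at which to
#'   report the state; defaults to a uniform grid of 151 points. Mode-switch
#'   times are inserted automatically.
#' @param rtol,atol Solver tolerances.
#' @param clamp_rho Floor the kinetic correction factor at zero (see
#'   [rho_factor()]).
#' @param t_offset Absolute time of the challenge start (min), used only to
#'   label the output.
#' @param max_switches Safety cap on mode transitions per challenge.
#' @return A `dmt1_trajectory` tibble with columns `challenge`, `time_min`
#'   (absolute), `time_rel`, `P1`..`P6`, `FeIN_uM`, `FeOUT_uM`,
#'   `membrane_fraction`, `endocyted_fraction`, `mode`, `rho`. The final
#'   [model_state()] is attached as attribute `final_state`.
#' @examples
#' tr <- integrate_challenge(swing_params(), cell_geometry(),
#'                           swing_initial_state(), duration = 15)
#' tail(tr)
#' @export
integrate_challenge <- function(params, geometry, initial_state, duration,
                                output_times = NULL, rtol = 1e-8, atol = 1e-10,
                                clamp_rho = FALSE, t_offset = 0,
                                max_switches = 1000L) {
  stopifnot(inherits(initial_state, "model_state"))
  if (!is.finite(duration) || duration <= 0) {
    stop("`duration` must be positive", call. = FALSE)
  }
  model <- model_kind(params)
  if (is.null(output_times)) output_times <- seq(0, duration, length.out = 151)
  output_times <- sort(unique(c(0, output_times[output_times <= duration],
                                duration)))

  st <- initial_state
  FeIN0 <- st$FeIN
  FeOUT0 <- st$FeOUT
  ratio <- geometry$V_cb / geometry$V_a
  # FeOUT recovered from the within-challenge mass balance
  feout_of <- function(FeIN) FeOUT0 - ratio * (FeIN - FeIN0)

  if (model == "swing") {
    j <- st$j
    pv <- c(params$k12, params$k23, params$k34, params$k41, params$k14,
            params$k45, params$k56, params$k64, params$DMT1_E,
            geometry$gamma, ratio, FeOUT0, FeIN0,
            as.numeric(j > 1),
            st$FeUP_history[j],
            if (j > 1) st$FeCHG_history[j - 1] / st$FeCHG_history[j] else 0,
            as.numeric(clamp_rho))
    y0 <- c(st$P, st$FeIN)
    sol <- deSolve::lsoda(y = y0, times = output_times,
                          func = "swing_derivs", parms = pv,
                          dllname = "ferroflux", initfunc = "swing_initmod",
                          rtol = rtol, atol = atol)
    check_solver(sol)
    out <- as.data.frame(sol)
    names(out) <- c("time_rel", paste0("P", 1:6), "FeIN_uM")
    out$mode <- NA_character_
    final_mode <- st$mode
  } else {
    # switch model: piecewise integration between hysteretic mode flips
    mode <- st$mode
    y <- c(st$P, st$FeIN)
    t_cur <- 0
    segs <- list()
    n_switch <- 0L
    repeat {
      endo <- mode == "endocytic"
      pv <- c(params$k12, params$k23, params$k34, params$k41, params$k14,
              if (endo) params$k45 else 0,
              if (endo) 0 else params$k54,
              params$DMT1_E, geometry$gamma, ratio, FeOUT0, FeIN0,
              if (endo) params$alpha_E else params$alpha_M,
              as.numeric(!endo))
      times <- sort(unique(c(t_cur, output_times[output_times > t_cur],
                             duration)))
      sol <- deSolve::lsodar(y = y, times = times, func = "switch_derivs",
                             parms = pv, dllname = "ferroflux",
                             initfunc = "switch_initmod",
                             rootfunc = "switch_root", nroot = 1L,
                             rtol = rtol, atol = atol)
      check_solver(sol)
      seg <- as.data.frame(sol)
      names(seg) <- c("time_rel", paste0("P", 1:6), "FeIN_uM")
      seg$mode <- mode
      troot <- attr(sol, "troot")
      segs[[length(segs) + 1L]] <- seg
      if (is.null(troot) || length(troot) == 0 ||
          troot[1] >= duration - 1e-12) {
        y <- as.numeric(seg[nrow(seg), 2:8])
        break
      }
      y <- as.numeric(seg[nrow(seg), 2:8])
      t_cur <- troot[1]
      mode <- if (mode == "endocytic") "exocytic" else "endocytic"
      n_switch <- n_switch + 1L
      if (n_switch > max_switches) {
        stop("mode switch cap exceeded; check thresholds", call. = FALSE)
      }
    }
    out <- do.call(rbind, segs)
    out <- out[order(out$time_rel), , drop = FALSE]
    # segment boundaries duplicate the switch time; keep the post-flip row
    out <- out[!duplicated(out$time_rel, fromLast = TRUE), , drop = FALSE]
    final_mode <- mode
  }

  out$FeOUT_uM <- feout_of(out$FeIN_uM)
  out$membrane_fraction <- out$P1 + out$P2 + out$P3 + out$P4
  out$endocyted_fraction <- out$P5 + out$P6
  if (model == "swing") {
    out$rho <- vapply(out$FeIN_uM, function(f) {
      if (st$j <= 1) 1
      else rho_factor(max(f, 1e-300), st$j, st$FeUP_history, st$FeCHG_history,
                      clamp = clamp_rho)
    }, numeric(1))
  } else {
    out$rho <- 1
  }
  out$challenge <- st$j
  out$time_min <- t_offset + out$time_rel
  traj <- tibble::as_tibble(out[, c("challenge", "time_min", "time_rel",
                                    paste0("P", 1:6), "FeIN_uM", "FeOUT_uM",
                                    "membrane_fraction", "endocyted_fraction",
                                    "mode", "rho")])
  last <- traj[nrow(traj), ]
  final_state <- model_state(
    P = as.numeric(last[, paste0("P", 1:6)]),
    FeIN = last$FeIN_uM, FeOUT = max(last$FeOUT_uM, 0),
    mode = final_mode, j = st$j,
    FeUP_history = st$FeUP_history, FeCHG_history = st$FeCHG_history,
    tol = 1e-4
  )
  new_trajectory(traj, model = model, params = params, geometry = geometry,
                 final_state = final_state)
}

check_solver <- function(sol) {
  istate <- attr(sol, "istate")
  if (!is.null(istate) && istate[1] < 0) {
    stop("ODE integration failed (istate = ", istate[1],
         "); try looser tolerances or check parameters", call. = FALSE)
  }
  invisible(sol)
}

new_trajectory <- function(tbl, model, params, geometry, final_state) {
  structure(tbl,
            class = c("dmt1_trajectory", class(tibble::tibble())),
            model = model, params = params, geometry = geometry,
            final_state = final_state)
}

#' Simulate a multi-challenge protocol
#'
#' Integrates the model through each challenge of a [challenge_protocol()] in
#' sequence. The inter-challenge ice wash is instantaneous: at each challenge
#' start the apical concentration is reset to that challenge's `FeCHG`, all
#' transporter fractions and the intracellular concentration carry over
#' unchanged, the current `FeIN` is appended to the uptake history (feeding
#' the kinetic correction factor of the swing model), and — for the switch
#' model — the mode is re-initialised to endocytic (configurable via
#' `reset_mode`).
#'
#' @inheritParams integrate_challenge
#' @param protocol A [challenge_protocol()].
#' @param initial_state Optional starting [model_state()]; defaults to the
#'   model's standard initial condition (`P1 = 1` for the switch model;
#'   `P1 = 0.98`, `P5 = P6 = 0.01` for the swing model), `FeIN = 0` and
#'   `FeOUT` equal to the first challenge concentration.
#' @param reset_mode Re-enter the endocytic mode at each challenge start
#'   (switch model).
#' @param points_per_challenge Size of the uniform reporting grid per
#'   challenge; sampling times from the protocol are always included.
#' @return A `dmt1_trajectory` tibble spanning all challenges.
#' @examples
#' tr <- run_protocol(swing_params(), cell_geometry(), challenge_protocol())
#' dplyr::count(tr, challenge)
#' @export
run_protocol <- function(params, geometry = cell_geometry(),
                         protocol = challenge_protocol(),
                         initial_state = NULL, rtol = 1e-8, atol = 1e-10,
                         clamp_rho = FALSE, reset_mode = TRUE,
                         points_per_challenge = 151L) {
  stopifnot(inherits(protocol, "challenge_protocol"))
  if (nrow(protocol) < 1) stop("empty protocol", call. = FALSE)
  model <- model_kind(params)
  if (is.null(initial_state)) {
    initial_state <- if (model == "switch") {
      switch_initial_state(protocol$FeCHG[1])
    } else {
      swing_initial_state(protocol$FeCHG[1])
    }
  }
  st <- initial_state
  t_offset <- 0
  pieces <- vector("list", nrow(protocol))
  for (i in seq_len(nrow(protocol))) {
    if (i > 1L) {
      # instantaneous cold wash: freeze fractions and FeIN, renew apical iron
      st <- model_state(
        P = st$P, FeIN = st$FeIN, FeOUT = protocol$FeCHG[i],
        mode = if (model == "switch" && reset_mode) "endocytic" else st$mode,
        j = st$j + 1L,
        FeUP_history = c(st$FeUP_history, st$FeIN),
        FeCHG_history = c(st$FeCHG_history, protocol$FeCHG[i]),
        tol = 1e-4
      )
    }
    grid <- sort(unique(c(
      seq(0, protocol$duration[i], length.out = points_per_challenge),
      protocol$sampling_times[[i]]
    )))
    piece <- integrate_challenge(params, geometry, st,
                                 duration = protocol$duration[i],
                                 output_times = grid, rtol = rtol, atol = atol,
                                 clamp_rho = clamp_rho, t_offset = t_offset)
    pieces[[i]] <- piece
    st <- attr(piece, "final_state")
    t_offset <- t_offset + protocol$duration[i]
  }
  traj <- dplyr::bind_rows(lapply(pieces, tibble::as_tibble))
  out <- new_trajectory(traj, model = model, params = params,
                        geometry = geometry, final_state = st)
  attr(out, "protocol") <- protocol
  out
}

#' Convert a trajectory to cumulative uptake observables
#'
#' Cumulative apical uptake at time `t` within a challenge is
#' `(FeIN(t) - FeIN(t_start)) * V_cb` in pmol/insert (uM x uL = pmol): the
#' experimental readout pools cells plus basolateral medium, matching the
#' model's pooled compartment, and each challenge is baseline-subtracted,
#' mirroring the subtraction of the first-challenge radioactivity from the
#' second-challenge counts.
#'
#' @param trajectory A `dmt1_trajectory`.
#' @param geometry A [cell_geometry()]; defaults to the one stored in the
#'   trajectory.
#' @param challenge Challenge index (or vector of indices) to extract.
#' @param times Optional sampling times (min, challenge-relative); values not
#'   on the trajectory grid are linearly interpolated.
#' @return A tibble with columns `challenge`, `time_min` (challenge-relative),
#'   `uptake_pmol`, `membrane_fraction`, `endocyted_fraction`.
#' @export
uptake_series <- function(trajectory, geometry = attr(trajectory, "geometry"),
                          challenge = 1L, times = NULL) {
  stopifnot(inherits(trajectory, "dmt1_trajectory"))
  avail <- unique(trajectory$challenge)
  if (!all(challenge %in% avail)) {
    stop("challenge index out of range; trajectory covers ",
         paste(avail, collapse = ", "), call. = FALSE)
  }
  purrr::map_dfr(challenge, function(ch) {
    tr <- trajectory[trajectory$challenge == ch, ]
    base <- tr$FeIN_uM[which.min(tr$time_rel)]
    tt <- if (is.null(times)) tr$time_rel else times
    interp <- function(col) {
      stats::approx(tr$time_rel, tr[[col]], xout = tt, ties = "ordered")$y
    }
    tibble::tibble(
      challenge = ch,
      time_min = tt,
      uptake_pmol = (interp("FeIN_uM") - base) * geometry$V_cb,
      membrane_fraction = interp("membrane_fraction"),
      endocyted_fraction = interp("endocyted_fraction")
    )
  })
}

#' @export
print.dmt1_trajectory <- function(x, ...) {
  cat(sprintf("<dmt1_trajectory: %s model, %d challenge(s), %d rows>\n",
              attr(x, "model"), length(unique(x$challenge)), nrow(x)))
  NextMethod()
}
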