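#' Right-hand side of the binary switching-mechanism model
#'
#' Evaluates the time derivatives of the five transporter fractions and the
#' two iron pools under mass-action kinetics. In the endocytic mode the
#' exocytosis constant `k54` is zeroed; in the exocytic mode the endocytosis
#' constant `k45` is zeroed, so the two trafficking processes are mutually
#' exclusive. Iron enters the pooled intracellular-basolateral compartment
#' through direct transport (`k34 * DMT1_E * P3`) and through vesicular
#' release (`gamma * k54 * DMT1_E * P5`); the apical pool balances it exactly,
#' `dFeOUT = -(V_cb/V_a) * dFeIN`.
#'
#' @param state A [model_state()].
#' @param params A [switch_params()] object.
#' @param geometry A [cell_geometry()] object.
#' @param mode `"endocytic"` or `"exocytic"`; defaults to the state's mode.
#' @return A named numeric vector with components `dP1`..`dP6`, `dFeIN`,
#'   `dFeOUT` (per minute).
#' @export
switch_rhs <- function(state, params, geometry, mode = state$mode) {
  mode <- match.arg(mode, c("endocytic", "exocytic"))
  k45 <- if (mode == "endocytic") params$k45 else 0
  k54 <- if (mode == "endocytic") 0 else params$k54
  d <- switch_core(state$P, state$FeOUT, params, k45, k54, geometry$gamma)
  dFeOUT <- -(geometry$V_cb / geometry$V_a) * d[7]
  c(dP1 = d[1], dP2 = d[2], dP3 = d[3], dP4 = d[4], dP5 = d[5], dP6 = d[6],
    dFeIN = d[7], dFeOUT = dFeOUT)
}

# mass-action core; returns c(dP1..dP6, dFeIN); k45/k54 already mode-resolved
switch_core <- function(P, FeOUT, params, k45, k54, gamma) {
  bind <- params$k12 * P[1] * FeOUT
  endo <- k45 * FeOUT * P[4]
  exo <- k54 * P[5]
  dP1 <- -bind - params$k14 * P[1] + params$k41 * P[4]
  dP2 <- bind - params$k23 * P[2]
  dP3 <- params$k23 * P[2] - params$k34 * P[3]
  dP4 <- params$k34 * P[3] + params$k14 * P[1] - params$k41 * P[4] + exo - endo
  dP5 <- endo - exo
  dFeIN <- params$k34 * params$DMT1_E * P[3] +
    gamma * k54 * params$DMT1_E * P[5]
  c(dP1, dP2, dP3, dP4, dP5, 0, dFeIN)
}

#' Right-hand side of the swinging-mechanism model
#'
#' Evaluates the six-state cycle coupled to the autocatalytic oscillator.
#' The endocytosis term `rho * k45 * FeOUT * P4 * P5`, the conversion term
#' `k56 * P5 * P6` and the membrane-return term `rho * k64 * P6 * P4` are
#' all second-order in the transporter fractions, so sustained oscillations
#' require P5 and P6 to start non-zero. The kinetic correction factor `rho`
#' (see [rho_factor()]) damps endocytosis and exocytosis after repeated
#' challenges; iron release from vesicles is `gamma * rho * k64 * DMT1_E * P6`.
#'
#' @param state A [model_state()].
#' @param params A [swing_params()] object.
#' @param geometry A [cell_geometry()] object.
#' @param rho Kinetic correction factor (dimensionless), 1 during the first
#'   challenge.
#' @return A named numeric vector with components `dP1`..`dP6`, `dFeIN`,
#'   `dFeOUT` (per minute).
#' @export
swing_rhs <- function(state, params, geometry, rho = 1) {
  stopifnot(is.finite(rho))
  d <- swing_core(state$P, state$FeOUT, params, rho, geometry$gamma)
  dFeOUT <- -(geometry$V_cb / geometry$V_a) * d[7]
  c(dP1 = d[1], dP2 = d[2], dP3 = d[3], dP4 = d[4], dP5 = d[5], dP6 = d[6],
    dFeIN = d[7], dFeOUT = dFeOUT)
}

# autocatalytic core; returns c(dP1..dP6, dFeIN)
swing_core <- function(P, FeOUT, params, rho, gamma) {
  bind <- params$k12 * P[1] * FeOUT
  endo <- rho * params$k45 * FeOUT * P[4] * P[5]
  conv <- params$k56 * P[5] * P[6]
  back <- rho * params$k64 * P[6] * P[4]
  dP1 <- -bind - params$k14 * P[1] + params$k41 * P[4]
  dP2 <- bind - params$k23 * P[2]
  dP3 <- params$k23 * P[2] - params$k34 * P[3]
  dP4 <- params$k34 * P[3] + params$k14 * P[1] - params$k41 * P[4] +
    back - endo
  dP5 <- endo - conv
  dP6 <- conv - back
  dFeIN <- params$k34 * params$DMT1_E * P[3] +
    gamma * rho * params$k64 * params$DMT1_E * P[6]
  c(dP1, dP2, dP3, dP4, dP5, dP6, dFeIN)
}

#' Kinetic correction factor for repeated iron challenges
#'
#' After a first iron dose, uptake of a second dose is reduced (mucosal
#' block); the cumulative iron absorbed at the end of the second dose is
#' about 1.67 times that absorbed in the first. The correction factor
#' \deqn{\rho(t, j) = 1 - 2.8\,\frac{FeIN(t) - 1.67\,FeUP(j-1)}{FeIN(t)}
#'   \cdot \frac{FeCHG(j-1)}{FeCHG(j)}}
#' damps the endo/exocytosis rates of the swing model accordingly. `FeUP` and
#' `FeCHG` are defined as zero before the first challenge, so `rho = 1`
#' identically throughout challenge 1.
#'
#' By default the expression is evaluated literally (it may exceed 1 or, in
#' principle, go negative); `clamp = TRUE` floors it at 0.
#'
#' @param FeIN_t Current intracellular-basolateral iron concentration (uM).
#' @param j 1-based index of the current challenge.
#' @param FeUP_history FeIN recorded at the start of each challenge so far
#'   (uM, length >= j). Element `i` is the concentration frozen at the start
#'   of challenge `i`, so element `j` — the value at the start of the current
#'   challenge — is the iron accumulated through challenge `j - 1` and plays
#'   the role of the previous-uptake term in the damping expression.
#' @param FeCHG_history Challenge concentrations so far (uM, length >= j).
#' @param clamp Floor `rho` at zero?
#' @return The dimensionless factor.
#' @examples
#' rho_factor(0.5, 1, 0, 20)                      # 1 during challenge 1
#' rho_factor(0.01, 2, c(0, 0.01), c(20, 20))     # 2.876 just after challenge 2
#' @export
rho_factor <- function(FeIN_t, j, FeUP_history, FeCHG_history, clamp = FALSE) {
  if (length(FeUP_history) < j || length(FeCHG_history) < j) {
    stop("challenge histories must have length >= `j`", call. = FALSE)
  }
  if (j <= 1) return(1)  # FeUP and FeCHG are zero before the first challenge
  if (FeIN_t <= 0) {
    stop("`FeIN_t` must be positive after a completed first challenge",
         call. = FALSE)
  }
  FeUP_prev <- FeUP_history[j]
  FeCHG_prev <- FeCHG_history[j - 1]
  FeCHG_cur <- FeCHG_history[j]
  rho <- 1 - 2.8 * ((FeIN_t - 1.67 * FeUP_prev) / FeIN_t) *
    (FeCHG_prev / FeCHG_cur)
  if (clamp) rho <- max(rho, 0)
  rho
}

#' Hysteretic mode update for the switch model
#'
#' The endocytic mode persists while the endocyted fraction P5 is below
#' `alpha_E` and flips to exocytic once `P5 >= alpha_E`; the exocytic mode
#' persists while the membrane fraction P1+P2+P3+P4 is below `alpha_M` and
#' flips back once it reaches `alpha_M`. Ties at exact equality resolve
#' toward switching. The model is initialised in the endocytic mode.
#'
#' @param state A [model_state()].
#' @param params A [switch_params()] object.
#' @param mode Current mode; defaults to the state's mode.
#' @return The updated mode string.
#' @export
update_switch_mode <- function(state, params, mode = state$mode) {
  mode <- match.arg(mode, c("endocytic", "exocytic"))
  P <- state$P
  if (mode == "endocytic" && P[5] >= params$alpha_E) return("exocytic")
  if (mode == "exocytic" && sum(P[1:4]) >= params$alpha_M) return("endocytic")
  mode
}
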