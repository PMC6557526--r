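#' Instantaneous state of a DMT1 cycling model
#'
#' The state comprises the transporter fractions P1..P6 (P6 is fixed at zero
#' for the switch model), the pooled intracellular-basolateral iron
#' concentration `FeIN` (uM), the apical concentration `FeOUT` (uM), the
#' endo/exocytic mode (switch model only), and the challenge bookkeeping used
#' by the kinetic correction factor: the 1-based index `j` of the current
#' challenge, `FeUP_history` (FeIN recorded at the start of each challenge)
#' and `FeCHG_history` (the challenge concentrations applied so far).
#'
#' @param P Numeric vector of length 6 of transporter state fractions;
#'   must be non-negative and sum to 1.
#' @param FeIN Intracellular-basolateral iron concentration (uM).
#' @param FeOUT Apical iron concentration (uM).
#' @param mode `"endocytic"` or `"exocytic"` (used by the switch model).
#' @param j Index of the current challenge.
#' @param FeUP_history,FeCHG_history Numeric vectors of length `j`.
#' @param tol Tolerance on the fraction sum.
#' @return An object of class `model_state`.
#' @examples
#' switch_initial_state()
#' swing_initial_state()
#' @export
model_state <- function(P, FeIN = 0, FeOUT = 20, mode = "endocytic",
                        j = 1L, FeUP_history = 0, FeCHG_history = FeOUT,
                        tol = 1e-6) {
  stopifnot(length(P) == 6)
  if (any(P < -tol) || abs(sum(P) - 1) > tol) {
    stop("state fractions must be non-negative and sum to 1", call. = FALSE)
  }
  if (FeIN < 0 || FeOUT < 0) {
    stop("concentrations must be non-negative", call. = FALSE)
  }
  mode <- match.arg(mode, c("endocytic", "exocytic"))
  if (length(FeUP_history) != j || length(FeCHG_history) != j) {
    stop("challenge histories must have length `j`", call. = FALSE)
  }
  structure(list(P = as.numeric(P), FeIN = FeIN, FeOUT = FeOUT, mode = mode,
                 j = as.integer(j), FeUP_history = as.numeric(FeUP_history),
                 FeCHG_history = as.numeric(FeCHG_history)),
            class = "model_state")
}

#' @rdname model_state
#' @param FeCHG Apical iron concentration of the first challenge (uM).
#' @export
switch_initial_state <- function(FeCHG = 20) {
  model_state(P = c(1, 0, 0, 0, 0, 0), FeIN = 0, FeOUT = FeCHG,
              mode = "endocytic", j = 1L,
              FeUP_history = 0, FeCHG_history = FeCHG)
}

#' @rdname model_state
#' @export
swing_initial_state <- function(FeCHG = 20) {
  model_state(P = c(0.98, 0, 0, 0, 0.01, 0.01), FeIN = 0, FeOUT = FeCHG,
              mode = "endocytic", j = 1L,
              FeUP_history = 0, FeCHG_history = FeCHG)
}

#' @export
print.model_state <- function(x, ...) {
  cat("<model_state>\n")
  cat("  P: ", paste(sprintf("%.4g", x$P), collapse = " "), "\n")
  cat(sprintf("  FeIN = %.4g uM, FeOUT = %.4g uM, mode = %s, challenge %d\n",
              x$FeIN, x$FeOUT, x$mode, x$j))
  invisible(x)
}
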