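#' Sequential iron-challenge protocol
#'
#' Describes an ordered series of apical iron challenges. At each challenge
#' start the apical medium is replaced with fresh medium at concentration
#' `FeCHG`; between challenges the monolayer is ice-washed, which is modelled
#' as an instantaneous freeze of all state variables. Sampling times are
#' expressed relative to each challenge start.
#'
#' The default reproduces the reference two-challenge uptake experiment:
#' two sequential 15-min challenges at 20 uM apical iron, sampled at
#' 3, 6, 9, 12 and 15 min.
#'
#' @param FeCHG Apical iron concentration at each challenge start (uM);
#'   recycled against `duration`.
#' @param duration Challenge durations (min).
#' @param sampling_times Sampling times relative to challenge start (min);
#'   either a numeric vector shared by all challenges or a list with one
#'   vector per challenge.
#' @return An object of class `challenge_protocol`: a tibble with columns
#'   `challenge`, `FeCHG`, `duration` and list-column `sampling_times`.
#' @examples
#' challenge_protocol()                      # the two-challenge experiment
#' challenge_protocol(FeCHG = 20, duration = 15)   # single challenge
#' @export
challenge_protocol <- function(FeCHG = c(20, 20), duration = c(15, 15),
                               sampling_times = c(3, 6, 9, 12, 15)) {
  n <- max(length(FeCHG), length(duration))
  FeCHG <- rep_len(FeCHG, n)
  duration <- rep_len(duration, n)
  if (n < 1) stop("protocol needs at least one challenge", call. = FALSE)
  if (any(FeCHG <= 0)) stop("`FeCHG` must be positive", call. = FALSE)
  if (any(duration <= 0)) stop("`duration` must be positive", call. = FALSE)
  if (!is.list(sampling_times)) sampling_times <- rep(list(sampling_times), n)
  if (length(sampling_times) != n) {
    stop("`sampling_times` must have one vector per challenge", call. = FALSE)
  }
  for (i in seq_len(n)) {
    st <- sampling_times[[i]]
    if (any(diff(st) <= 0) || any(st <= 0) || any(st > duration[i])) {
      stop("sampling times must be strictly increasing, positive and within ",
           "the challenge duration", call. = FALSE)
    }
  }
  out <- tibble::tibble(challenge = seq_len(n), FeCHG = FeCHG,
                        duration = duration, sampling_times = sampling_times)
  class(out) <- c("challenge_protocol", class(out))
  out
}

n_challenges <- function(protocol) nrow(protocol)
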