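#' Measurement-noise model for synthetic uptake data
#'
#' Describes how replicate scatter is applied to noise-free model
#' predictions. Multiplicative Gaussian noise (`uptake * (1 + cv * Z)`)
#' emulates radiotracer counting error that grows with the signal; additive
#' Gaussian noise has a fixed standard deviation in pmol. Generated values
#' are floored at zero.
#'
#' @param kind `"multiplicative-gaussian"` or `"additive-gaussian"`.
#' @param cv Coefficient of variation (multiplicative kind).
#' @param sd Standard deviation in pmol (additive kind).
#' @return An object of class `noise_model`.
#' @examples
#' noise_model(cv = 0.2)
#' noise_model("additive-gaussian", sd = 0.5)
#' @export
noise_model <- function(kind = c("multiplicative-gaussian",
                                 "additive-gaussian"),
                        cv = 0.20, sd = 1) {
  kind <- match.arg(kind)
  if (cv < 0 || sd < 0) stop("`cv` and `sd` must be >= 0", call. = FALSE)
  structure(list(kind = kind, cv = cv, sd = sd), class = "noise_model")
}

apply_noise <- function(u, noise) {
  eps <- stats::rnorm(length(u))
  out <- switch(noise$kind,
    "multiplicative-gaussian" = u * (1 + noise$cv * eps),
    "additive-gaussian" = u + noise$sd * eps
  )
  pmax(out, 0)
}

#' Generate a synthetic two-challenge uptake dataset
#'
#' Simulates the chosen model through the protocol, samples cumulative
#' uptake at the protocol sampling times of each challenge, and applies the
#' noise model independently per replicate. This emulates the structure of
#' the triplicate radiotracer experiments the models were built for: two
#' sequential 15-min challenges at 20 uM apical iron, sampled at 3-15 min,
#' cumulative uptake of order 0-20 pmol/insert, and a reduced second
#' challenge (mucosal block).
#'
#' @param params Parameter object selecting the generating model.
#' @param geometry A [cell_geometry()].
#' @param protocol A [challenge_protocol()].
#' @param noise A [noise_model()]; `noise_model(cv = 0)` gives noise-free
#'   data.
#' @param n_replicates Replicates per (challenge, time) point.
#' @param seed Integer seed; all randomness flows from it.
#' @param ... Passed to [run_protocol()].
#' @return An uptake dataset: a tibble with columns `challenge`, `time_min`,
#'   `replicate`, `uptake_pmol`, tagged with attributes `provenance`
#'   (`"synthetic"`), `seed`, `model` and `FeCHG`.
#' @examples
#' d <- generate_uptake_dataset(swing_params(), seed = 1)
#' nrow(d) # 2 challenges x 5 times x 3 replicates = 30 records
#' @export
generate_uptake_dataset <- function(params, geometry = cell_geometry(),
                                    protocol = challenge_protocol(),
                                    noise = noise_model(cv = 0.20),
                                    n_replicates = 3L, seed = 1L, ...) {
  stopifnot(n_replicates >= 1)
  traj <- run_protocol(params, geometry, protocol, ...)
  truth <- purrr::map_dfr(protocol$challenge, function(ch) {
    uptake_series(traj, geometry, challenge = ch,
                  times = protocol$sampling_times[[ch]])[
      , c("challenge", "time_min", "uptake_pmol")]
  })
  out <- withr::with_seed(seed, {
    purrr::map_dfr(seq_len(n_replicates), function(rep) {
      tibble::tibble(challenge = truth$challenge, time_min = truth$time_min,
                     replicate = rep,
                     uptake_pmol = apply_noise(truth$uptake_pmol, noise))
    })
  })
  out <- dplyr::arrange(out, .data$challenge, .data$time_min, .data$replicate)
  attr(out, "provenance") <- "synthetic"
  attr(out, "seed") <- seed
  attr(out, "model") <- model_kind(params)
  attr(out, "FeCHG") <- protocol$FeCHG
  out
}

#' Summarise the mucosal block between two challenges
#'
#' Per sampling time: the mean cumulative uptake in each challenge, the
#' percent reduction `100 * (u1 - u2) / u1` and the fold ratio `u1 / u2`.
#' Additionally reports cumulative-window fold ratios (first vs second
#' challenge uptake accumulated to each time point). Times at which the
#' first-challenge uptake is zero give undefined reductions, reported as
#' `NA`.
#'
#' @param dataset Uptake data frame containing both challenges.
#' @param challenges Length-2 vector: which challenge indices to compare.
#' @return A tibble with columns `time_min`, `u1`, `u2`, `reduction_pct`,
#'   `fold`.
#' @examples
#' d <- generate_uptake_dataset(swing_params(), noise = noise_model(cv = 0),
#'                              seed = 1)
#' mucosal_block_summary(d)
#' @export
mucosal_block_summary <- function(dataset, challenges = c(1L, 2L)) {
  stopifnot(length(challenges) == 2)
  if (!all(challenges %in% dataset$challenge)) {
    stop("dataset must contain both requested challenges", call. = FALSE)
  }
  means <- dataset |>
    dplyr::filter(.data$challenge %in% challenges) |>
    dplyr::group_by(.data$challenge, .data$time_min) |>
    dplyr::summarise(uptake = mean(.data$uptake_pmol), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "challenge", values_from = "uptake",
                       names_prefix = "ch")
  u1 <- means[[paste0("ch", challenges[1])]]
  u2 <- means[[paste0("ch", challenges[2])]]
  tibble::tibble(
    time_min = means$time_min,
    u1 = u1, u2 = u2,
    reduction_pct = ifelse(u1 > 0, 100 * (u1 - u2) / u1, NA_real_),
    fold = ifelse(u2 > 0, u1 / u2, NA_real_)
  )
}

#' Fraction of the apical iron dose absorbed
#'
#' Expresses a cumulative uptake (pmol/insert) as a percentage of the iron
#' dose initially present in the apical medium.
#'
#' @param uptake_pmol Cumulative uptake (pmol).
#' @param dose_pmol Initial apical dose (pmol).
#' @return Percentage of the dose.
#' @examples
#' dose_fraction(9.4, 2000)  # 0.47%
#' @export
dose_fraction <- function(uptake_pmol, dose_pmol) {
  stopifnot(dose_pmol > 0)
  100 * uptake_pmol / dose_pmol
}

#' Read and write uptake datasets
#'
#' CSV serialisation of the uptake-record schema with header
#' `challenge,time_min,replicate,uptake_pmol`. Reading validates the schema:
#' missing columns, negative uptake values and duplicate
#' (challenge, time, replicate) keys are rejected with messages naming the
#' offending rows.
#'
#' @param dataset Uptake data frame.
#' @param path File path.
#' @return `read_uptake_table()` returns the dataset tibble;
#'   `write_uptake_table()` returns `path` invisibly.
#' @export
write_uptake_table <- function(dataset, path) {
  utils::write.csv(
    dataset[, c("challenge", "time_min", "replicate", "uptake_pmol")],
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_uptake_table
#' @param format `"csv"` (default) or `"xlsx"`; the latter needs the readxl
#'   package and expects the same column layout on the first sheet.
#' @export
read_uptake_table <- function(path, format = c("csv", "xlsx")) {
  format <- match.arg(format)
  d <- if (format == "csv") {
    utils::read.csv(path)
  } else {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      stop("reading xlsx requires the readxl package", call. = FALSE)
    }
    as.data.frame(readxl::read_excel(path))
  }
  need <- c("challenge", "time_min", "replicate", "uptake_pmol")
  missing <- setdiff(need, names(d))
  if (length(missing) > 0) {
    stop("missing columns: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  bad <- which(d$uptake_pmol < 0)
  if (length(bad) > 0) {
    stop("negative uptake at rows ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  key <- paste(d$challenge, d$time_min, d$replicate)
  dup <- which(duplicated(key))
  if (length(dup) > 0) {
    stop("duplicate (challenge, time, replicate) keys at rows ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  tibble::as_tibble(d[, need])
}
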