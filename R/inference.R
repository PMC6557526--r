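#' Model-predicted cumulative uptake at sampling times
#'
#' Runs the protocol once and reads cumulative uptake (pmol/insert) off the
#' trajectory at the requested challenge/time pairs. Only the challenges that
#' are actually requested are integrated.
#'
#' @param params A [switch_params()] or [swing_params()] object.
#' @param geometry A [cell_geometry()].
#' @param protocol A [challenge_protocol()].
#' @param challenge,time Paired vectors of challenge indices and
#'   challenge-relative times (min). Defaults to every sampling time of every
#'   challenge in the protocol.
#' @param rtol,atol Solver tolerances (slightly looser defaults than
#'   [run_protocol()], adequate for the pmol-scale observables being fitted).
#' @param ... Passed to [run_protocol()].
#' @return A tibble with columns `challenge`, `time_min`, `uptake_pmol`.
#' @export
predict_uptake <- function(params, geometry = cell_geometry(),
                           protocol = challenge_protocol(),
                           challenge = NULL, time = NULL,
                           rtol = 1e-6, atol = 1e-8, ...) {
  if (is.null(challenge)) {
    grid <- tidyr::unnest(protocol[, c("challenge", "sampling_times")],
                          "sampling_times")
    challenge <- grid$challenge
    time <- grid$sampling_times
  }
  stopifnot(length(challenge) == length(time))
  if (length(challenge) == 0) {
    return(tibble::tibble(challenge = integer(), time_min = numeric(),
                          uptake_pmol = numeric()))
  }
  n_need <- max(challenge)
  prot <- protocol[seq_len(n_need), , drop = FALSE]
  class(prot) <- class(protocol)
  traj <- run_protocol(params, geometry, prot, points_per_challenge = 2L,
                       rtol = rtol, atol = atol, ...)
  purrr::map_dfr(unique(challenge), function(ch) {
    sel <- challenge == ch
    us <- uptake_series(traj, geometry, challenge = ch, times = time[sel])
    tibble::tibble(challenge = ch, time_min = time[sel],
                   uptake_pmol = us$uptake_pmol)
  })
}

#' Mean squared error between observed and model-predicted uptake
#'
#' The objective minimised during parameter fitting. By default replicate
#' observations are first averaged per (challenge, time) point
#' (`aggregate = "mean"`), matching a fit to triplicate means;
#' `aggregate = "replicates"` scores every replicate record.
#'
#' @param params Parameter object to evaluate.
#' @param dataset An uptake dataset: a data frame with columns `challenge`,
#'   `time_min`, `replicate`, `uptake_pmol` (see [generate_uptake_dataset()]).
#' @param geometry,protocol Passed to [predict_uptake()].
#' @param aggregate `"mean"` or `"replicates"`.
#' @param challenges Which challenges to score; defaults to challenge 1 only,
#'   the training window of the reference experiment.
#' @param ... Passed to [predict_uptake()].
#' @return Mean squared error in pmol^2.
#' @export
uptake_mse <- function(params, dataset, geometry = cell_geometry(),
                       protocol = challenge_protocol(),
                       aggregate = c("mean", "replicates"),
                       challenges = 1L, ...) {
  aggregate <- match.arg(aggregate)
  obs <- aggregate_dataset(dataset, aggregate, challenges)
  if (nrow(obs) == 0) stop("no observations to score", call. = FALSE)
  pred <- predict_uptake(params, geometry, protocol,
                         challenge = obs$challenge, time = obs$time_min, ...)
  mean((obs$uptake_pmol - pred$uptake_pmol)^2)
}

aggregate_dataset <- function(dataset, aggregate, challenges) {
  stopifnot(all(c("challenge", "time_min", "uptake_pmol") %in% names(dataset)))
  d <- dplyr::filter(dataset, .data$challenge %in% challenges)
  if (aggregate == "mean") {
    d <- dplyr::summarise(dplyr::group_by(d, .data$challenge, .data$time_min),
                          uptake_pmol = mean(.data$uptake_pmol),
                          .groups = "drop")
  }
  dplyr::arrange(d, .data$challenge, .data$time_min)
}

# log/logit transform pair used so Nelder-Mead works on an unconstrained scale
par_to_theta <- function(params, free) {
  vals <- unlist(params[free])
  is_alpha <- grepl("^alpha_", free)
  theta <- ifelse(is_alpha, stats::qlogis(vals), log(vals))
  stats::setNames(theta, free)
}

theta_to_par <- function(theta, params) {
  for (nm in names(theta)) {
    params[[nm]] <- if (grepl("^alpha_", nm)) stats::plogis(theta[[nm]])
                    else exp(theta[[nm]])
  }
  params
}

#' Fit model parameters by Nelder-Mead minimisation of the MSE
#'
#' Minimises [uptake_mse()] over the free parameters with the Nelder-Mead
#' simplex. Rate constants and `DMT1_E` are optimised on the log scale
#' (enforcing positivity); the switch-model thresholds `alpha_E`/`alpha_M`
#' on the logit scale (enforcing (0, 1)). Non-convergence within the
#' iteration budget is flagged in the result, not raised.
#'
#' The few-point objective of an oscillatory transporter model is rugged:
#' mis-phased oscillations create local minima that trap any purely local
#' search. `n_starts > 1` therefore runs a deterministic multistart —
#' `n_starts - 1` log-normally jittered copies of the initial guess
#' (sd `start_sd` natural-log units, seeded by `start_seed`) alongside the
#' guess itself — and polishes the best basin with the restart loop.
#'
#' @param initial_guess Parameter object supplying both the starting point
#'   and the model kind.
#' @param dataset Uptake data frame (see [uptake_mse()]).
#' @param geometry,protocol,aggregate,challenges As in [uptake_mse()].
#' @param fixed Character vector of parameter names held at their
#'   `initial_guess` values.
#' @param maxit Maximum simplex iterations per round.
#' @param restarts Number of fresh-simplex restarts from the incumbent
#'   optimum. Nelder-Mead simplices collapse on narrow valleys; restarting
#'   re-expands the simplex and is the standard remedy.
#' @param n_starts Number of multistart points (1 = plain single start).
#' @param start_sd Log-scale standard deviation of the multistart jitter.
#' @param start_seed Seed making the multistart jitter reproducible.
#' @param reltol Relative convergence tolerance on the objective.
#' @param ... Passed to the objective (solver tolerances etc.).
#' @return A list with elements `params` (fitted parameter object), `mse`,
#'   `convergence` (0 = converged), `counts`, and `converged` (logical).
#' @export
fit_parameters <- function(initial_guess, dataset,
                           geometry = cell_geometry(),
                           protocol = challenge_protocol(),
                           aggregate = "mean", challenges = 1L,
                           fixed = NULL, maxit = 2000L, restarts = 3L,
                           n_starts = 1L, start_sd = 0.35, start_seed = 1L,
                           reltol = 1e-8, ...) {
  free <- setdiff(names(unclass(initial_guess)), fixed)
  obj <- function(theta) {
    p <- theta_to_par(stats::setNames(as.list(theta), free), initial_guess)
    # simplex excursions can reach regimes the solver cannot integrate
    # (e.g. apical depletion); score them as very poor, not fatal
    val <- suppressWarnings(tryCatch(
      uptake_mse(p, dataset, geometry, protocol, aggregate = aggregate,
                 challenges = challenges, ...),
      error = function(e) NA_real_))
    if (!is.finite(val)) 1e10 else val
  }
  if (length(free) == 0) {
    m <- uptake_mse(initial_guess, dataset, geometry, protocol,
                    aggregate = aggregate, challenges = challenges, ...)
    return(list(params = initial_guess, mse = m, convergence = 0L,
                counts = c(`function` = 1L), converged = TRUE))
  }
  theta0 <- par_to_theta(unclass(initial_guess), free)
  starts <- list(theta0)
  if (n_starts > 1) {
    jitters <- withr::with_seed(start_seed, {
      replicate(n_starts - 1, stats::rnorm(length(theta0), 0, start_sd),
                simplify = FALSE)
    })
    starts <- c(starts, lapply(jitters, function(j) theta0 + j))
  }
  # transformed parameters span ~26 log units; normalise simplex steps
  ctl <- list(maxit = maxit, reltol = reltol,
              parscale = pmax(abs(theta0), 1))
  opt <- NULL
  counts <- c(`function` = 0L, gradient = NA_integer_)
  for (s in starts) {
    cand <- stats::optim(s, obj, method = "Nelder-Mead", control = ctl)
    counts[1] <- counts[1] + cand$counts[1]
    if (is.null(opt) || cand$value < opt$value) opt <- cand
  }
  for (r in seq_len(restarts)) {
    if (opt$convergence == 0L) break
    ctl$parscale <- pmax(abs(opt$par), 1)
    nxt <- stats::optim(opt$par, obj, method = "Nelder-Mead", control = ctl)
    counts <- counts + nxt$counts
    if (nxt$value <= opt$value) opt[c("par", "value")] <- nxt[c("par", "value")]
    opt$convergence <- nxt$convergence
  }
  fitted <- theta_to_par(stats::setNames(as.list(opt$par), free),
                         initial_guess)
  list(params = fitted, mse = opt$value, convergence = opt$convergence,
       counts = counts, converged = opt$convergence == 0L)
}

#' Jackknife (leave-one-out) parameter estimation
#'
#' Runs the full leave-one-out loop of the inverse problem: the model is
#' refit once per observation with that observation removed, the left-out
#' point is predicted, and the squared leave-one-out errors are aggregated
#' into the generalisation error `MSE_jk`. Parameter confidence half-widths
#' (alpha = 0.05) and p-values for a two-sided t-test of H0: parameter = 0
#' are computed from the spread of the fold estimates via the jackknife
#' standard error. Fold fits are warm-started from the full-data fit.
#'
#' @inheritParams fit_parameters
#' @param fold_maxit Iteration budget per fold refit (folds are warm-started
#'   from the full-data fit and run without restarts).
#' @param mse_jk_aggregate `"mean"` (default) or `"sum"` of the squared
#'   leave-one-out errors.
#' @param conventions Optional list overriding the information-criterion
#'   convention, see [aicc()]; elements `n` ("observations" to use the folded
#'   observation count, "replicates" to use the raw record count) are
#'   honoured.
#' @return A `dmt1_fit` object; see [tidy.dmt1_fit()] and
#'   [glance.dmt1_fit()].
#' @export
jackknife_fit <- function(initial_guess, dataset,
                          geometry = cell_geometry(),
                          protocol = challenge_protocol(),
                          aggregate = "mean", challenges = 1L,
                          fixed = NULL, maxit = 2000L, fold_maxit = 400L,
                          restarts = 3L, n_starts = 1L,
                          mse_jk_aggregate = c("mean", "sum"),
                          reltol = 1e-8, ...) {
  mse_jk_aggregate <- match.arg(mse_jk_aggregate)
  obs <- aggregate_dataset(dataset, aggregate, challenges)
  n <- nrow(obs)
  if (n < 3) stop("jackknife needs at least 3 observations", call. = FALSE)

  full <- fit_parameters(initial_guess, dataset, geometry, protocol,
                         aggregate = aggregate, challenges = challenges,
                         fixed = fixed, maxit = maxit, restarts = restarts,
                         n_starts = n_starts, reltol = reltol, ...)
  free <- setdiff(names(unclass(initial_guess)), fixed)

  folds <- vector("list", n)
  loo_err <- numeric(n)
  for (i in seq_len(n)) {
    train <- obs[-i, , drop = FALSE]
    train$replicate <- 1L
    f <- fit_parameters(full$params, train, geometry, protocol,
                        aggregate = "replicates", challenges = challenges,
                        fixed = fixed, maxit = fold_maxit, restarts = 0L,
                        reltol = reltol, ...)
    pred <- predict_uptake(f$params, geometry, protocol,
                           challenge = obs$challenge[i],
                           time = obs$time_min[i], ...)
    loo_err[i] <- obs$uptake_pmol[i] - pred$uptake_pmol
    folds[[i]] <- f
  }
  mse_jk <- if (mse_jk_aggregate == "mean") mean(loo_err^2) else sum(loo_err^2)

  fold_est <- t(vapply(folds, function(f) unlist(unclass(f$params)[free]),
                       numeric(length(free))))
  colnames(fold_est) <- free
  est <- unlist(unclass(full$params)[free])
  se <- apply(fold_est, 2, function(v) {
    sqrt((n - 1) / n * sum((v - mean(v))^2))
  })
  tq <- stats::qt(0.975, df = n - 1)
  ci_half <- tq * se
  tstat <- ifelse(se > 0, est / se, Inf)
  pval <- 2 * stats::pt(abs(tstat), df = n - 1, lower.tail = FALSE)

  pred_full <- predict_uptake(full$params, geometry, protocol,
                              challenge = obs$challenge,
                              time = obs$time_min, ...)
  r2 <- r_squared(obs$uptake_pmol, pred_full$uptake_pmol)

  structure(list(
    model = model_kind(initial_guess),
    params = full$params,
    estimates = tibble::tibble(term = free, estimate = est,
                               std_error = unname(se),
                               ci_half_width = unname(ci_half),
                               p_value = unname(pval)),
    fold_estimates = tibble::as_tibble(fold_est),
    loo_errors = loo_err,
    mse = full$mse, mse_jk = mse_jk, r_squared = r2,
    n_obs = n, n_free = length(free),
    observations = obs,
    aggregate = aggregate, challenges = challenges,
    diagnostics = tibble::tibble(
      fold = c(0L, seq_len(n)),
      mse = c(full$mse, vapply(folds, `[[`, numeric(1), "mse")),
      converged = c(full$converged,
                    vapply(folds, `[[`, logical(1), "converged"))
    )
  ), class = "dmt1_fit")
}

#' Coefficient of determination
#'
#' `R^2 = 1 - SS_res / SS_tot`, with the total sum of squares taken about the
#' observed mean.
#'
#' @param observed,predicted Numeric vectors of equal length (>= 2).
#' @return Dimensionless coefficient (1 for a perfect fit, 0 for predicting
#'   the mean).
#' @export
r_squared <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted), length(observed) >= 2)
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) {
    stop("observations have zero variance; R^2 undefined", call. = FALSE)
  }
  1 - sum((observed - predicted)^2) / ss_tot
}

#' Bias-corrected Akaike information criterion
#'
#' `AICc = n * log(mse) + 2K + 2K(K+1)/(n - K - 1)`, the least-squares form
#' of AIC with the small-sample correction. The correction is undefined for
#' `n <= K + 1`; with a handful of per-time means and 9-10 fitted kinetic
#' quantities this regime is easily reached, in which case scoring at the
#' replicate level (larger `n`) is the usable convention.
#'
#' @param n Number of observations.
#' @param K Number of fitted parameters.
#' @param mse Mean squared error of the fit (pmol^2).
#' @return The criterion value (lower is better).
#' @examples
#' aicc(15, 10, 1) # 75
#' @export
aicc <- function(n, K, mse) {
  stopifnot(n > 0, K >= 0, mse > 0)
  if (n <= K + 1) {
    stop("AICc correction undefined for n <= K + 1 (n = ", n, ", K = ", K,
         "); score at the replicate level to increase n", call. = FALSE)
  }
  n * log(mse) + 2 * K + 2 * K * (K + 1) / (n - K - 1)
}

#' Compare two fitted models by AICc
#'
#' Scores both fits with [aicc()] under a common convention and selects the
#' model with the lower criterion. Both fits must have been evaluated on the
#' same observations.
#'
#' @param fit_a,fit_b `dmt1_fit` objects.
#' @param n Observation count convention; defaults to the replicate-level
#'   count when both fits carry the same observations, otherwise the folded
#'   count. Must be identical for the two fits.
#' @return A list with the per-model AICc values, `delta_aicc`
#'   (`aicc_a - aicc_b`) and `selected` (`"a"`, `"b"` or `"tie"`), plus the
#'   model kinds.
#' @export
compare_models <- function(fit_a, fit_b, n = NULL) {
  stopifnot(inherits(fit_a, "dmt1_fit"), inherits(fit_b, "dmt1_fit"))
  if (fit_a$n_obs != fit_b$n_obs) {
    stop("fits were evaluated on different numbers of observations; ",
         "comparison would be meaningless", call. = FALSE)
  }
  n <- n %||% fit_a$n_obs
  a <- aicc(n, fit_a$n_free, fit_a$mse)
  b <- aicc(n, fit_b$n_free, fit_b$mse)
  list(
    model_a = fit_a$model, model_b = fit_b$model,
    aicc_a = a, aicc_b = b, delta_aicc = a - b,
    selected = if (a < b) "a" else if (b < a) "b" else "tie",
    selected_model = if (a < b) fit_a$model
                     else if (b < a) fit_b$model else "tie"
  )
}

#' @export
print.dmt1_fit <- function(x, ...) {
  cat(sprintf("<dmt1_fit: %s model, %d observations, %d free parameters>\n",
              x$model, x$n_obs, x$n_free))
  cat(sprintf("  MSE = %.4g, MSE_jk = %.4g, R^2 = %.4f\n",
              x$mse, x$mse_jk, x$r_squared))
  print(x$estimates, n = Inf)
  invisible(x)
}

#' Tidy the per-parameter jackknife statistics
#' @param x A `dmt1_fit`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std_error`,
#'   `ci_half_width`, `p_value`.
#' @export
tidy.dmt1_fit <- function(x, ...) x$estimates

#' One-row fit summary
#' @param x A `dmt1_fit`.
#' @param ... Unused.
#' @return A tibble with `model`, `n_obs`, `n_free`, `mse`, `mse_jk`,
#'   `r_squared`.
#' @export
glance.dmt1_fit <- function(x, ...) {
  tibble::tibble(model = x$model, n_obs = x$n_obs, n_free = x$n_free,
                 mse = x$mse, mse_jk = x$mse_jk, r_squared = x$r_squared)
}
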