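#' Build the pooled observation dataset for the response models
#'
#' One row per *alive* individual-wave for waves 2 through J — the pooled
#' sample on which the logistic observation (response) models are fitted.
#' Each row carries the response indicator and the regressors of the
#' missing-at-random (MAR) model: sex, a study-entry indicator (wave j is
#' the first post-entry interview opportunity), the FI at the previous
#' visit if available, an indicator of having been observed at the previous
#' visit, and the lagged-FI-by-sex interaction. When the lagged FI is not
#' available it is imputed with the sample mean of the baseline (first
#' observed wave) FI, and flagged.
#'
#' @param panel a [as_cohort_panel()].
#' @param include_education also carry education and the lagged-FI-by-
#'   education interaction (the sensitivity specification of the weight
#'   models).
#' @param lag_mode `"last_observed"` (default): the most recent observed FI
#'   before wave j; `"previous_wave"`: strictly the wave j-1 FI, imputing
#'   whenever that wave was unobserved.
#' @param baseline_mean optional externally supplied imputation mean;
#'   by default the mean FI at each individual's first observed wave,
#'   computed from `panel` itself (so bootstrap replicates are
#'   self-contained).
#' @return data frame of class `obs_dataset` with columns `id`, `wave`,
#'   `r` (response), `sex`, `entry_ind`, `lag_fi`, `prev_obs`, `imputed`
#'   (and `educ` when requested); attribute `baseline_mean`.
#' @export
build_observation_dataset <- function(panel,
                                      include_education = FALSE,
                                      lag_mode = c("last_observed",
                                                   "previous_wave"),
                                      baseline_mean = NULL) {
  lag_mode <- match.arg(lag_mode)
  d <- as.data.frame(panel)
  d <- d[order(d$id, d$wave), , drop = FALSE]
  first <- !duplicated(d$id)
  base_fi <- d$fi[first]
  if (all(is.na(base_fi))) {
    stop("no individual has a wave-1 FI; cannot compute the imputation mean",
         call. = FALSE)
  }
  if (is.null(baseline_mean)) baseline_mean <- mean(base_fi, na.rm = TRUE)

  entry_wave <- stats::ave(d$wave, d$id, FUN = min)
  # most recent observed FI strictly before each row
  last_obs_fi <- stats::ave(ifelse(d$observed == 1, d$fi, NA_real_), d$id,
                            FUN = function(v) {
                              out <- c(NA_real_, v[-length(v)])
                              filled <- out
                              for (k in seq_along(filled)[-1]) {
                                if (is.na(filled[k])) filled[k] <- filled[k - 1]
                              }
                              filled
                            })
  prev_fi <- stats::ave(ifelse(d$observed == 1, d$fi, NA_real_), d$id,
                        FUN = function(v) c(NA_real_, v[-length(v)]))
  prev_obs <- stats::ave(d$observed, d$id,
                         FUN = function(v) c(1L, v[-length(v)]))

  keep <- d$alive == 1 & d$wave > entry_wave
  lag <- if (lag_mode == "last_observed") last_obs_fi[keep] else prev_fi[keep]
  imputed <- is.na(lag)
  lag[imputed] <- baseline_mean
  out <- data.frame(
    id = d$id[keep], wave = d$wave[keep], r = d$observed[keep],
    sex = d$sex[keep],
    entry_ind = as.integer(d$wave[keep] == entry_wave[keep] + 1),
    lag_fi = lag, prev_obs = prev_obs[keep],
    imputed = imputed)
  if (include_education) out$educ <- d$educ_years[keep]
  class(out) <- c("obs_dataset", "data.frame")
  attr(out, "baseline_mean") <- baseline_mean
  attr(out, "include_education") <- include_education
  attr(out, "lag_mode") <- lag_mode
  out
}

#' Fit the MAR and MCAR observation (response) models
#'
#' Two logistic regressions for the probability of being interviewed given
#' alive, on the pooled waves-2+ dataset of [build_observation_dataset()]:
#' \describe{
#'   \item{MAR}{response ~ sex + entry indicator + lagged FI + previously-
#'     observed indicator + lagged FI x sex (+ education and lagged FI x
#'     education in the sensitivity specification).}
#'   \item{MCAR}{response ~ sex + entry indicator.}
#' }
#' The MCAR fit is the stabilizing numerator model; the MAR fit is the
#' denominator.
#'
#' @param rows an `obs_dataset`.
#' @param penalize use a small ridge penalty (logistic IRLS with L2
#'   regularization) instead of plain maximum likelihood — the suggested
#'   remedy when separation is detected.
#' @return object of class `obs_models`: `mar`, `mcar` (each with
#'   `coefficients`, `fitted`, `converged`), plus the metadata needed to
#'   score new rows.
#' @export
fit_observation_models <- function(rows, penalize = FALSE) {
  stopifnot(inherits(rows, "obs_dataset"))
  if (length(unique(rows$r)) < 2) {
    stop("response indicator is constant; the observation models are not ",
         "identifiable (degenerate outcome)", call. = FALSE)
  }
  include_education <- isTRUE(attr(rows, "include_education"))
  mar_form <- if (include_education) {
    r ~ sex + entry_ind + lag_fi + prev_obs + lag_fi:sex + educ + lag_fi:educ
  } else {
    r ~ sex + entry_ind + lag_fi + prev_obs + lag_fi:sex
  }
  fit1 <- fit_logistic(mar_form, rows, penalize)
  fit0 <- fit_logistic(r ~ sex + entry_ind, rows, penalize)
  structure(list(mar = fit1, mcar = fit0,
                 include_education = include_education,
                 baseline_mean = attr(rows, "baseline_mean"),
                 lag_mode = attr(rows, "lag_mode")),
            class = "obs_models")
}

fit_logistic <- function(form, data, penalize) {
  if (!penalize) {
    fit <- suppressWarnings(
      stats::glm(form, family = stats::binomial(), data = data))
    p <- stats::fitted(fit)
    sep <- any(p < 1e-8 | p > 1 - 1e-8) && max(abs(stats::coef(fit))) > 10
    if (sep) {
      stop("perfect (or quasi-perfect) separation in an observation model; ",
           "refit with penalize = TRUE", call. = FALSE)
    }
    if (!fit$converged) {
      stop(sprintf(paste0("observation model did not converge after %d IRLS ",
                          "iterations (deviance %.4g); consider penalize = TRUE"),
                   fit$iter, fit$deviance), call. = FALSE)
    }
    list(formula = form, coefficients = stats::coef(fit), fitted = p,
         converged = fit$converged, glm = fit)
  } else {
    X <- stats::model.matrix(form, data)
    yv <- stats::model.response(stats::model.frame(form, data))
    cf <- ridge_logistic(X, yv, lambda = 1e-3)
    eta <- drop(X %*% cf)
    list(formula = form, coefficients = cf, fitted = stats::plogis(eta),
         converged = TRUE, glm = NULL)
  }
}

# ridge-penalized logistic regression by Newton iterations (no penalty on
# the intercept)
ridge_logistic <- function(X, y, lambda = 1e-3, maxit = 100, tol = 1e-10) {
  p <- ncol(X)
  beta <- rep(0, p)
  pen <- diag(c(0, rep(lambda, p - 1)), p)
  for (k in seq_len(maxit)) {
    mu <- stats::plogis(drop(X %*% beta))
    wv <- pmax(mu * (1 - mu), 1e-10)
    g <- crossprod(X, y - mu) - pen %*% beta
    H <- crossprod(X * wv, X) + pen
    step <- solve(H, g)
    beta <- beta + drop(step)
    if (max(abs(step)) < tol) break
  }
  stats::setNames(beta, colnames(X))
}

predict_obs_model <- function(model, rows) {
  X <- stats::model.matrix(stats::delete.response(
    stats::terms(model$formula)), rows)
  stats::plogis(drop(X %*% model$coefficients[colnames(X)]))
}

#' Compute stabilized inverse-probability-of-observation weights
#'
#' For every observed row at waves 2+ the stabilized weight is
#' \deqn{w^*_{ij} = \frac{\hat P(R_{ij}=1 \mid Al_{ij}=1, x_{ij})}
#'                       {\hat P(R_{ij}=1 \mid Al_{ij}=1, x_{ij},
#'                        \bar{FI}_{ik})},}
#' the MCAR-model probability over the MAR-model probability. Entry-wave
#' rows get weight 1 (everyone is interviewed at entry by construction).
#' Fitted probabilities are clipped to `clip` before the division to guard
#' against unstable weights; `clip = NULL` disables clipping to match the
#' estimator exactly as defined.
#'
#' @param panel a [as_cohort_panel()].
#' @param models an `obs_models` from [fit_observation_models()], fitted on
#'   the matching observation dataset.
#' @param clip length-2 probability bounds, default `c(0.01, 0.99)`.
#' @param obs_rows optional: the `obs_dataset` the models were fitted on
#'   (rebuilt from `panel` if omitted).
#' @return a `weight_table` data frame: `id`, `wave`, `p_mcar`, `p_mar`,
#'   `weight`, `clipped`, `imputed_lag`, one row per observed person-wave;
#'   attribute `n_clipped`.
#' @export
compute_stabilized_weights <- function(panel, models, clip = c(0.01, 0.99),
                                       obs_rows = NULL) {
  stopifnot(inherits(models, "obs_models"))
  if (is.null(obs_rows)) {
    obs_rows <- build_observation_dataset(
      panel, include_education = models$include_education,
      lag_mode = models$lag_mode %||% "last_observed",
      baseline_mean = models$baseline_mean)
  }
  d <- as.data.frame(panel)
  d <- d[order(d$id, d$wave), , drop = FALSE]
  entry_wave <- stats::ave(d$wave, d$id, FUN = min)
  obs <- d$observed == 1

  scored <- obs_rows[obs_rows$r == 1, , drop = FALSE]
  p_mar <- predict_obs_model(models$mar, scored)
  p_mcar <- predict_obs_model(models$mcar, scored)
  clipped <- rep(FALSE, length(p_mar))
  if (!is.null(clip)) {
    stopifnot(length(clip) == 2, clip[1] > 0, clip[2] <= 1)
    clipped <- p_mar < clip[1] | p_mar > clip[2] |
               p_mcar < clip[1] | p_mcar > clip[2]
    p_mar <- pmin(pmax(p_mar, clip[1]), clip[2])
    p_mcar <- pmin(pmax(p_mcar, clip[1]), clip[2])
  }
  if (any(p_mar == 0)) {
    bad <- scored[p_mar == 0, c("id", "wave")]
    stop("MAR probability of 0 for rows: ",
         paste(sprintf("(%s, %s)", bad$id, bad$wave), collapse = " "),
         call. = FALSE)
  }

  out <- data.frame(id = d$id[obs], wave = d$wave[obs],
                    p_mcar = NA_real_, p_mar = NA_real_,
                    weight = 1, clipped = FALSE, imputed_lag = FALSE)
  key <- paste(out$id, out$wave)
  skey <- paste(scored$id, scored$wave)
  m <- match(skey, key)
  out$p_mcar[m] <- p_mcar
  out$p_mar[m] <- p_mar
  out$weight[m] <- p_mcar / p_mar
  out$clipped[m] <- clipped
  out$imputed_lag[m] <- scored$imputed
  class(out) <- c("weight_table", "data.frame")
  attr(out, "n_clipped") <- sum(clipped)
  out
}

#' Estimate stabilized observation weights for a panel
#'
#' Convenience wrapper: builds the pooled observation dataset, fits the MAR
#' and MCAR response models, and returns the stabilized weight table.
#'
#' @inheritParams build_observation_dataset
#' @inheritParams compute_stabilized_weights
#' @inheritParams fit_observation_models
#' @return a `weight_table` (see [compute_stabilized_weights()]) with the
#'   fitted `obs_models` attached as attribute `models`.
#' @examples
#' pan <- simulate_cohort(sim_config(n_individuals = 400, seed = 3))
#' wt <- estimate_weights(pan)
#' summary(wt$weight)
#' @export
estimate_weights <- function(panel, include_education = FALSE,
                             lag_mode = "last_observed",
                             clip = c(0.01, 0.99), penalize = FALSE) {
  rows <- build_observation_dataset(panel, include_education, lag_mode)
  if (all(rows$r == 1)) {
    # universal response: both response probabilities are identically 1,
    # so every stabilized weight is exactly 1
    d <- as.data.frame(panel)
    d <- d[order(d$id, d$wave), , drop = FALSE]
    obs <- d$observed == 1
    wt <- data.frame(id = d$id[obs], wave = d$wave[obs],
                     p_mcar = NA_real_, p_mar = NA_real_, weight = 1,
                     clipped = FALSE, imputed_lag = FALSE)
    class(wt) <- c("weight_table", "data.frame")
    attr(wt, "n_clipped") <- 0L
    return(wt)
  }
  models <- fit_observation_models(rows, penalize = penalize)
  wt <- compute_stabilized_weights(panel, models, clip = clip,
                                   obs_rows = rows)
  attr(wt, "models") <- models
  wt
}
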