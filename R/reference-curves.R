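#' Covariate profile for a reference curve
#'
#' Describes the individual for whom a predicted FI quantile trajectory is
#' drawn: sex, education in raw years (`NULL` = the education mean the fit
#' was centered at), baseline age, cohort indicator, and the age grid.
#'
#' @param sex 1 = female, 0 = male.
#' @param educ_years years of education, raw scale; `NULL` for the fit's
#'   centering mean.
#' @param base_age age at study entry, years.
#' @param born_1946plus cohort indicator (needed for the cohort formula).
#' @param ages strictly increasing age grid, starting at or after
#'   `base_age`.
#' @return object of class `covariate_profile`.
#' @export
covariate_profile <- function(sex, educ_years = NULL, base_age = 65,
                              born_1946plus = 0, ages = 65:90) {
  if (is.unsorted(ages, strictly = TRUE)) {
    stop("ages must be strictly increasing", call. = FALSE)
  }
  if (min(ages) < base_age) {
    stop("age grid must start at or after the baseline age", call. = FALSE)
  }
  structure(list(sex = sex, educ_years = educ_years, base_age = base_age,
                 born_1946plus = born_1946plus, ages = ages),
            class = "covariate_profile")
}

profile_design <- function(profile, centers, formula, terms) {
  if (formula == "cohort" && is.null(profile$born_1946plus)) {
    stop("the cohort formula needs a born_1946plus value in the profile",
         call. = FALSE)
  }
  educ <- profile$educ_years %||% centers$educ
  age_c <- profile$ages - centers$age
  educ_c <- educ - centers$educ
  ba_c <- profile$base_age - centers$base_age
  X <- cbind(
    "(Intercept)"  = rep(1, length(age_c)),
    "sex"          = profile$sex,
    "educ"         = educ_c,
    "base_age"     = ba_c,
    if (formula == "cohort") cbind("cohort" = profile$born_1946plus),
    "age"          = age_c,
    "age:sex"      = age_c * profile$sex,
    "age:educ"     = age_c * educ_c,
    "age:base_age" = age_c * ba_c,
    if (formula == "cohort") cbind("age:cohort" = age_c * profile$born_1946plus))
  X[, terms, drop = FALSE]
}

#' Predict an FI quantile trajectory for a covariate profile
#'
#' Builds the profile's design rows with the fit's own centering constants
#' and multiplies by the coefficient vector. Predictions are linear-model
#' outputs; a version clipped to the FI range \[0, 1\] is reported
#' alongside for display.
#'
#' @param fit a `wqr_fit` produced via [fit_all()] (so it carries centering
#'   constants and the formula).
#' @param profile a [covariate_profile()].
#' @return data frame: `age`, `fi_pred` (unclipped), `fi_pred_clipped`,
#'   `tau`.
#' @export
predict_curve <- function(fit, profile) {
  stopifnot(inherits(fit, "wqr_fit"), inherits(profile, "covariate_profile"))
  if (is.null(fit$centers)) {
    stop("fit carries no centering constants; fit it through fit_all()",
         call. = FALSE)
  }
  X <- profile_design(profile, fit$centers, fit$formula, names(coef(fit)))
  pred <- drop(X %*% coef(fit))
  data.frame(age = profile$ages, fi_pred = pred,
             fi_pred_clipped = pmin(pmax(pred, 0), 1), tau = fit$tau)
}

#' Reference curve with bootstrap percentile confidence bands
#'
#' Per grid age, the band is the percentile interval of the replicate
#' predictions at the requested level. Bands are built from unclipped
#' predictions (the model is linear); clipped versions are reported for
#' display.
#'
#' @param ensemble a `wqr_boot` containing `tau`.
#' @param profile a [covariate_profile()].
#' @param tau quantile level.
#' @param level band coverage, default 0.95.
#' @return data frame of class `reference_curve`: `age`, `fit`, `lwr`,
#'   `upr`, clipped counterparts, `tau`, `level`.
#' @export
curve_bands <- function(ensemble, profile, tau, level = 0.95) {
  stopifnot(inherits(ensemble, "wqr_boot"))
  if (ensemble$B < 20) {
    stop("at least 20 bootstrap replicates are required for bands",
         call. = FALSE)
  }
  kt <- as_tau(ensemble, tau)
  fit <- ensemble$point[[kt]]
  X <- profile_design(profile, fit$centers, fit$formula, ensemble$terms)
  point <- drop(X %*% coef(fit))
  cf <- ensemble$coef[, , kt, drop = TRUE]
  cf <- cf[stats::complete.cases(cf), , drop = FALSE]
  preds <- cf %*% t(X)                       # replicates x ages
  alpha <- (1 - level) / 2
  lwr <- apply(preds, 2, stats::quantile, probs = alpha, names = FALSE)
  upr <- apply(preds, 2, stats::quantile, probs = 1 - alpha, names = FALSE)
  out <- data.frame(age = profile$ages, fit = point, lwr = lwr, upr = upr,
                    fit_clipped = pmin(pmax(point, 0), 1),
                    lwr_clipped = pmin(pmax(lwr, 0), 1),
                    upr_clipped = pmin(pmax(upr, 0), 1),
                    tau = tau, level = level)
  class(out) <- c("reference_curve", "data.frame")
  out
}

#' Years of education offsetting one year of age in the FI trajectory
#'
#' In the fitted trajectory the FI slope with age is
#' \eqn{\beta_a + \beta_{ae} (E - \bar E)}; when education slows
#' progression (\eqn{\beta_{ae} < 0}), the additional education needed to
#' offset the FI increase of one more year of age is
#' \eqn{\beta_a / |\beta_{ae}|}.
#'
#' @param fit a `wqr_fit`, or a named numeric vector holding coefficients
#'   `age` and `age:educ`.
#' @return years of education (a single number).
#' @examples
#' education_offset_years(c("age" = 0.0067, "age:educ" = -0.0004))  # 16.75
#' @export
education_offset_years <- function(fit) {
  b <- if (inherits(fit, "wqr_fit")) coef(fit) else fit
  if (!all(c("age", "age:educ") %in% names(b))) {
    stop("coefficients must include 'age' and 'age:educ'", call. = FALSE)
  }
  if (b[["age:educ"]] == 0) {
    stop("the age-by-education coefficient is zero; the education offset ",
         "is undefined", call. = FALSE)
  }
  unname(b[["age"]] / abs(b[["age:educ"]]))
}

#' Plot reference curves
#'
#' Simple ggplot2 rendering of one or more [curve_bands()] outputs.
#'
#' @param curves a `reference_curve` or a named list of them (names become
#'   panel labels).
#' @param clipped plot the \[0, 1\]-clipped curves.
#' @return a ggplot object.
#' @export
plot_reference_curves <- function(curves, clipped = TRUE) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  if (inherits(curves, "reference_curve")) curves <- list(curve = curves)
  df <- do.call(rbind, lapply(names(curves), function(nm) {
    cbind(as.data.frame(curves[[nm]]), label = nm)
  }))
  if (clipped) {
    df$fit <- df$fit_clipped; df$lwr <- df$lwr_clipped; df$upr <- df$upr_clipped
  }
  df$grp <- interaction(df$label, df$tau)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$age, y = .data$fit,
                                   colour = .data$label,
                                   group = .data$grp)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lwr, ymax = .data$upr,
                                      fill = .data$label),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_line(ggplot2::aes(linetype = factor(.data$tau))) +
    ggplot2::labs(x = "Age (years)", y = "Frailty Index",
                  linetype = "tau", colour = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' Run the full trajectory analysis pipeline
#'
#' Orchestrates: (optional) simulation or panel intake, (optional) FI
#' construction from deficit items, stabilized-weight estimation, weighted
#' and/or unweighted quantile fits, cluster-bootstrap inference, and
#' reference curves for a set of covariate profiles. Returns everything
#' plus a manifest (seed, configuration echo, package version, clamp and
#' clip diagnostics) so a run is reproducible from its output.
#'
#' @param config a list with elements:
#'   \describe{
#'     \item{panel / sim}{either an [as_cohort_panel()] (or CSV path), or a
#'       [sim_config()] to simulate from.}
#'     \item{formula}{`"base"` (default) or `"cohort"`.}
#'     \item{taus}{quantile levels, default `c(0.1, 0.5, 0.9)`.}
#'     \item{B}{bootstrap replicates, default 200.}
#'     \item{seed}{integer, default 1.}
#'     \item{weighting}{`"both"` (default), `"weighted"` or `"unweighted"`.}
#'     \item{weight_args}{arguments for [estimate_weights()].}
#'     \item{profiles}{named list of [covariate_profile()]; default: women
#'       and men at mean education entering at 65, ages 65-90.}
#'   }
#' @return object of class `frailtyq_report`: `panel`, `weights`, `fits`
#'   (per weighting mode), `boot`, `tables` (coefficient tables with
#'   cross-quantile tests), `curves`, `manifest`.
#' @export
run_pipeline <- function(config) {
  cfg <- config
  seed <- cfg$seed %||% 1L
  taus <- cfg$taus %||% c(0.1, 0.5, 0.9)
  B <- cfg$B %||% 200
  formula <- cfg$formula %||% "base"
  weighting <- cfg$weighting %||% "both"
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  panel <- stage("data", {
    if (!is.null(cfg$sim)) simulate_cohort(cfg$sim, seed = seed)
    else if (is.character(cfg$panel)) read_cohort_panel(cfg$panel)
    else as_cohort_panel(cfg$panel)
  })
  modes <- switch(weighting, both = c("weighted", "unweighted"),
                  weighted = "weighted", unweighted = "unweighted",
                  stop("unknown weighting mode: ", weighting, call. = FALSE))
  wt <- NULL
  if ("weighted" %in% modes) {
    wt <- stage("weights",
                do.call(estimate_weights,
                        c(list(panel), cfg$weight_args %||% list())))
  }
  fits <- list(); boot <- list(); tables <- list()
  for (m in modes) {
    fits[[m]] <- stage(paste0("fit-", m),
      fit_all(panel, weights = if (m == "weighted") wt,
              formula = formula, taus = taus))
    boot[[m]] <- stage(paste0("bootstrap-", m),
      cluster_bootstrap(panel, formula = formula, taus = taus, B = B,
                        seed = seed + match(m, modes),
                        weighting = if (m == "weighted") "reestimate" else "none",
                        weight_args = cfg$weight_args %||% list()))
    tables[[m]] <- coef_table(boot[[m]])
  }
  profiles <- cfg$profiles %||% list(
    female = covariate_profile(sex = 1, base_age = 65, ages = 65:90),
    male = covariate_profile(sex = 0, base_age = 65, ages = 65:90))
  curves <- stage("curves", {
    out <- list()
    for (m in modes) {
      for (pn in names(profiles)) {
        for (t in taus) {
          out[[sprintf("%s.%s.tau%g", m, pn, t)]] <-
            curve_bands(boot[[m]], profiles[[pn]], t)
        }
      }
    }
    out
  })
  manifest <- list(
    package = "frailtyq",
    version = as.character(utils::packageVersion("frailtyq")),
    seed = seed, taus = taus, B = B, formula = formula,
    weighting = weighting,
    n_individuals = length(unique(panel$id)),
    n_person_waves = sum(panel$observed),
    clamp_frac = attr(panel, "clamp_frac"),
    n_clipped_weights = if (!is.null(wt)) attr(wt, "n_clipped"),
    config = cfg[setdiff(names(cfg), c("panel"))])
  structure(list(panel = panel, weights = wt, fits = fits, boot = boot,
                 tables = tables, curves = curves, manifest = manifest),
            class = "frailtyq_report")
}

#' @export
print.frailtyq_report <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("<frailtyq_report> %d individuals, formula = %s, B = %d\n",
              m$n_individuals, m$formula, m$B))
  for (nm in names(x$tables)) {
    cat("--", nm, "coefficients --\n")
    tab <- x$tables[[nm]]
    print(round(stats::reshape(tab[c("term", "tau", "estimate")],
                               idvar = "term", timevar = "tau",
                               direction = "wide"), 5))
  }
  invisible(x)
}
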