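#' Bootstrap for longitudinal data: resample individuals, not observations
#'
#' Standard errors for the quantile trajectory coefficients by resampling
#' whole individuals with replacement, carrying all their waves, so the
#' within-person correlation is preserved. Within a replicate the same
#' resample is used for every \eqn{\tau} — required for valid cross-quantile
#' covariance — and, by default, the education centering and the
#' observation-weight models are re-estimated from the replicate's own
#' sample, so the weight-estimation variability enters the standard errors.
#' Duplicate individuals receive distinct replicate-local ids so clustering
#' stays well defined.
#'
#' @param panel a [as_cohort_panel()].
#' @param formula `"base"` or `"cohort"`.
#' @param taus quantile levels, fitted on identical resamples.
#' @param B number of replicates (the conventional choice for these models
#'   is 200).
#' @param seed RNG seed; the replicate draw sequence is fully determined by
#'   it.
#' @param weighting `"reestimate"`: refit the observation models and
#'   stabilized weights inside each replicate (default); `"fixed"`: reuse
#'   the point-estimate weights of the sampled individuals; `"none"`: the
#'   unweighted procedure.
#' @param weight_args list of arguments passed to [estimate_weights()]
#'   (e.g. `include_education`, `clip`).
#' @param fixed_weights a `weight_table` for `weighting = "fixed"`; when
#'   omitted it is estimated once from `panel`.
#' @param max_fail_frac error out when more than this fraction of
#'   replicates fails (solver or separation failures are dropped and
#'   counted, never redrawn, so the draw sequence stays seed-stable).
#' @return object of class `wqr_boot`: `coef` (array B x terms x taus, with
#'   `NA` rows for failed replicates), `point` (the [fit_all()] point
#'   fits), `taus`, `terms`, `B`, `seed`, `n_failed`, `weighting`.
#' @examples
#' pan <- simulate_cohort(sim_config(n_individuals = 200, seed = 5))
#' bt <- cluster_bootstrap(pan, taus = c(0.5, 0.9), B = 25, seed = 9,
#'                         weighting = "none")
#' wald_test_zero(bt, "age", tau = 0.9)
#' @export
cluster_bootstrap <- function(panel, formula = c("base", "cohort"),
                              taus = c(0.1, 0.5, 0.9), B = 200, seed = 1L,
                              weighting = c("reestimate", "fixed", "none"),
                              weight_args = list(), fixed_weights = NULL,
                              max_fail_frac = 0.2) {
  formula <- match.arg(formula)
  weighting <- match.arg(weighting)
  stopifnot(B >= 1)
  d <- as.data.frame(panel)
  ids <- unique(d$id)
  n <- length(ids)

  point_w <- switch(weighting,
    reestimate = do.call(estimate_weights, c(list(panel), weight_args)),
    fixed = fixed_weights %||%
      do.call(estimate_weights, c(list(panel), weight_args)),
    none = NULL)
  point <- fit_all(panel, weights = point_w, formula = formula, taus = taus)
  terms <- names(coef(point[[1]]))

  rows_by_id <- split(seq_len(nrow(d)), d$id)
  coefarr <- array(NA_real_, dim = c(B, length(terms), length(taus)),
                   dimnames = list(NULL, terms, as.character(taus)))
  draws <- with_seed(seed,
    replicate(B, sample(ids, n, replace = TRUE), simplify = FALSE))
  n_failed <- 0L
  for (b in seq_len(B)) {
    take <- draws[[b]]
    idx <- unlist(rows_by_id[as.character(take)], use.names = FALSE)
    rep_panel <- d[idx, , drop = FALSE]
    # distinct replicate-local ids for duplicated individuals
    nw <- lengths(rows_by_id[as.character(take)])
    rep_panel$id <- rep(seq_along(take), nw)
    res <- tryCatch({
      rp <- as_cohort_panel(rep_panel)
      w <- switch(weighting,
        reestimate = do.call(estimate_weights, c(list(rp), weight_args)),
        fixed = {
          # point-estimate weights looked up by original id, re-keyed to
          # the replicate-local ids
          obs <- rep_panel$observed == 1
          orig_id <- rep(take, nw)
          data.frame(id = rep_panel$id[obs], wave = rep_panel$wave[obs],
                     weight = point_w$weight[match(
                       paste(orig_id[obs], rep_panel$wave[obs]),
                       paste(point_w$id, point_w$wave))])
        },
        none = NULL)
      fit_all(rp, weights = w, formula = formula, taus = taus)
    }, error = function(e) NULL)
    if (is.null(res)) {
      n_failed <- n_failed + 1L
    } else {
      for (k in seq_along(taus)) coefarr[b, , k] <- coef(res[[k]])
    }
  }
  if (n_failed > max_fail_frac * B) {
    stop(sprintf(paste0("%d of %d bootstrap replicates failed; increase the ",
                        "sample size or use penalized observation models"),
                 n_failed, B), call. = FALSE)
  }
  structure(list(coef = coefarr, point = point, taus = taus, terms = terms,
                 B = B, seed = seed, n_failed = n_failed,
                 weighting = weighting, formula = formula),
            class = "wqr_boot")
}

#' @export
print.wqr_boot <- function(x, ...) {
  cat(sprintf("<wqr_boot> B = %d (%d failed), taus = %s, weighting = %s\n",
              x$B, x$n_failed, paste(x$taus, collapse = ", "), x$weighting))
  invisible(x)
}

boot_slice <- function(ensemble, term, tau) {
  kt <- as.character(tau)
  if (!kt %in% dimnames(ensemble$coef)[[3]]) {
    stop("tau ", tau, " is not in the ensemble", call. = FALSE)
  }
  if (!term %in% ensemble$terms) {
    stop("term '", term, "' is not in the fitted formula", call. = FALSE)
  }
  v <- ensemble$coef[, term, kt]
  v[!is.na(v)]
}

#' Wald test of a single coefficient against zero
#'
#' The bootstrap standard error is the standard deviation of the
#' coefficient across replicates; the statistic is the point estimate over
#' that SE, referred to the standard normal.
#'
#' @param ensemble a `wqr_boot`.
#' @param term coefficient name (e.g. `"age"`, `"age:sex"`).
#' @param tau quantile level present in the ensemble.
#' @return one-row data frame: `hypothesis`, `estimate`, `se`, `z`, `p`.
#' @export
wald_test_zero <- function(ensemble, term, tau) {
  v <- boot_slice(ensemble, term, tau)
  if (length(v) < 2) stop("need at least 2 successful replicates",
                          call. = FALSE)
  est <- coef(ensemble$point[[as.character(tau)]])[term]
  se <- stats::sd(v)
  if (se == 0) {
    stop("degenerate bootstrap distribution (SE = 0) for ", term,
         call. = FALSE)
  }
  z <- est / se
  data.frame(hypothesis = sprintf("beta[%s, tau=%g] = 0", term, tau),
             estimate = unname(est), se = se, z = unname(z),
             p = unname(2 * stats::pnorm(-abs(z))), row.names = NULL)
}

#' Cross-quantile equality test for one coefficient
#'
#' Tests whether a covariate effect differs between two quantile levels.
#' Because every replicate fits all \eqn{\tau} on the same resample, the
#' standard deviation of the per-replicate differences captures the
#' covariance between the two estimates; the test statistic is the
#' difference of the point estimates over that SE.
#'
#' @param ensemble a `wqr_boot`.
#' @param term coefficient name.
#' @param tau1,tau2 distinct quantile levels present in the ensemble.
#' @return one-row data frame: `hypothesis`, `estimate` (the difference),
#'   `se`, `z`, `p`.
#' @export
cross_quantile_test <- function(ensemble, term, tau1, tau2) {
  if (tau1 == tau2) {
    stop("tau1 and tau2 must differ; the self-comparison is not a valid ",
         "hypothesis", call. = FALSE)
  }
  v1 <- ensemble$coef[, term_check(ensemble, term), as_tau(ensemble, tau1)]
  v2 <- ensemble$coef[, term, as_tau(ensemble, tau2)]
  keep <- !is.na(v1) & !is.na(v2)
  if (sum(keep) < 2) stop("need at least 2 successful replicates",
                          call. = FALSE)
  diffs <- v1[keep] - v2[keep]
  est <- coef(ensemble$point[[as.character(tau1)]])[term] -
         coef(ensemble$point[[as.character(tau2)]])[term]
  se <- stats::sd(diffs)
  if (se == 0) {
    stop("degenerate bootstrap distribution of the difference (SE = 0); ",
         "the replicate series are identical up to a constant offset",
         call. = FALSE)
  }
  z <- est / se
  data.frame(
    hypothesis = sprintf("beta[%s, tau=%g] = beta[%s, tau=%g]",
                         term, tau1, term, tau2),
    estimate = unname(est), se = se, z = unname(z),
    p = unname(2 * stats::pnorm(-abs(z))), row.names = NULL)
}

term_check <- function(ensemble, term) {
  if (!term %in% ensemble$terms) {
    stop("term '", term, "' is not in the fitted formula", call. = FALSE)
  }
  term
}

as_tau <- function(ensemble, tau) {
  kt <- as.character(tau)
  if (!kt %in% dimnames(ensemble$coef)[[3]]) {
    stop("tau ", tau, " is not in the ensemble", call. = FALSE)
  }
  kt
}

#' Coefficient table with bootstrap inference
#'
#' Tidy summary in the conventional reporting layout for quantile
#' trajectory models: one row per model term, estimate and bootstrap SE per
#' \eqn{\tau}, the Wald p-value against zero, and cross-quantile equality
#' p-values for adjacent \eqn{\tau} pairs.
#'
#' @param ensemble a `wqr_boot`.
#' @return data frame with columns `term`, `tau`, `estimate`, `se`, `p`,
#'   and (attached attribute `cross`) the adjacent-pair equality tests.
#' @export
coef_table <- function(ensemble) {
  taus <- ensemble$taus
  rows <- do.call(rbind, lapply(taus, function(t) {
    do.call(rbind, lapply(ensemble$terms, function(tm) {
      w <- wald_test_zero(ensemble, tm, t)
      data.frame(term = tm, tau = t, estimate = w$estimate, se = w$se,
                 p = w$p)
    }))
  }))
  cross <- NULL
  if (length(taus) >= 2) {
    pairs <- cbind(taus[-length(taus)], taus[-1])
    cross <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(k) {
      do.call(rbind, lapply(ensemble$terms, function(tm) {
        ct <- cross_quantile_test(ensemble, tm, pairs[k, 1], pairs[k, 2])
        data.frame(term = tm, tau1 = pairs[k, 1], tau2 = pairs[k, 2],
                   diff = ct$estimate, se = ct$se, p = ct$p)
      }))
    }))
  }
  attr(rows, "cross") <- cross
  rows
}
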