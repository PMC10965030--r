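#' Build the design matrix for a quantile trajectory model
#'
#' Two model formulas are supported for the conditional FI quantile
#' \eqn{Q_\tau(FI_{ij} | x_{ij})}:
#' \describe{
#'   \item{base}{intercept, sex, educ, baseline age, age, and the
#'     interactions of age with sex, educ and baseline age.}
#'   \item{cohort}{the base terms plus a born-1946-or-later indicator and
#'     its interaction with age.}
#' }
#' Centering follows the reporting conventions for such trajectories: age
#' and baseline age are centered at 65 years; education is centered at the
#' mean over the individuals in the analysis sample (recomputed for each
#' sample unless `educ_center` is supplied, so bootstrap replicates are
#' self-contained). Interaction columns are products of the centered mains.
#'
#' @param panel a [as_cohort_panel()]; only rows with non-missing FI enter.
#' @param formula `"base"` or `"cohort"`.
#' @param educ_center optional fixed centering constant for education.
#' @return list with `X` (design matrix, columns in declared term order),
#'   `y` (FI), `index` (id/wave of each row), `centers` (the centering
#'   constants), `formula`.
#' @examples
#' pan <- simulate_cohort(sim_config(n_individuals = 100, seed = 1))
#' d <- build_design(pan, "base")
#' colnames(d$X)
#' @export
build_design <- function(panel, formula = c("base", "cohort"),
                         educ_center = NULL) {
  formula <- match.arg(formula)
  rows <- !is.na(panel$fi)
  d <- as.data.frame(panel)[rows, , drop = FALSE]
  need <- c("age", "sex", "educ_years", "base_age",
            if (formula == "cohort") "born_1946plus")
  bad <- sapply(need, function(v) any(is.na(d[[v]])))
  if (any(bad)) {
    stop("missing covariates on observed rows: ",
         paste(need[bad], collapse = ", "), call. = FALSE)
  }
  if (is.null(educ_center)) {
    educ_center <- mean(d$educ_years[!duplicated(d$id)])
  }
  age_c <- d$age - 65
  educ_c <- d$educ_years - educ_center
  ba_c <- d$base_age - 65
  X <- cbind(
    "(Intercept)"  = 1,
    "sex"          = d$sex,
    "educ"         = educ_c,
    "base_age"     = ba_c,
    if (formula == "cohort") cbind("cohort" = d$born_1946plus),
    "age"          = age_c,
    "age:sex"      = age_c * d$sex,
    "age:educ"     = age_c * educ_c,
    "age:base_age" = age_c * ba_c,
    if (formula == "cohort") cbind("age:cohort" = age_c * d$born_1946plus))
  list(X = X, y = d$fi, index = d[c("id", "wave")],
       centers = list(age = 65, base_age = 65, educ = educ_center),
       formula = formula)
}

#' Fit a weighted quantile regression by check-loss minimization
#'
#' Minimizes \eqn{\sum_i w_i \rho_\tau(y_i - x_i'\beta)} with
#' \eqn{\rho_\tau(u) = u(\tau - 1\{u < 0\})}, the estimator of a marginal
#' conditional quantile under an independence working assumption. The
#' default solver is an exact interior-point solution of the equivalent
#' linear program followed by a vertex polish; `method = "irls"` selects a
#' smoothed iteratively-reweighted fallback (also used automatically if the
#' interior point fails to converge).
#'
#' @param X design matrix (or a list from [build_design()], in which case
#'   `y` is taken from it).
#' @param y response vector.
#' @param weights positive observation weights; `NULL` means unweighted.
#' @param tau quantile level in (0, 1).
#' @param method `"fn"` (interior point) or `"irls"`.
#' @return object of class `wqr_fit`: named `coefficients`, `tau`, `loss`
#'   (weighted check loss at the optimum), `n_obs`, `converged`,
#'   `iterations`, `method`, and — when fitted through [fit_all()] — the
#'   centering constants and formula used.
#' @examples
#' fit <- fit_wqr(matrix(1, 5), c(1, 2, 3, 4, 100), tau = 0.5)
#' coef(fit)  # the sample median, 3
#' @export
fit_wqr <- function(X, y = NULL, weights = NULL, tau,
                    method = c("fn", "irls")) {
  method <- match.arg(method)
  design <- NULL
  if (is.list(X) && !is.null(X$X)) { design <- X; y <- X$y; X <- X$X }
  if (length(tau) != 1 || tau <= 0 || tau >= 1) {
    stop("tau must be a single value in (0, 1)", call. = FALSE)
  }
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("length(y) must equal nrow(X)", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(!is.finite(weights)) || any(weights <= 0)) {
    stop("weights must be positive, finite, and aligned with rows",
         call. = FALSE)
  }
  qrX <- qr(X)
  if (qrX$rank < p) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(colnames(X)[setdiff(seq_len(p), keep)], collapse = ", "),
         call. = FALSE)
  }
  Xw <- X * weights
  yw <- y * weights
  sol <- if (method == "fn") solve_qr_fn(Xw, yw, tau) else
    solve_qr_irls(Xw, yw, tau)
  if (method == "fn" && !sol$converged) {
    sol <- solve_qr_irls(Xw, yw, tau)
    sol$method <- "irls-fallback"
  }
  beta <- polish_vertex(Xw, yw, tau, sol$beta)
  names(beta) <- colnames(X)
  structure(list(
    coefficients = beta, tau = tau,
    loss = check_loss(y - drop(X %*% beta), tau, weights),
    n_obs = n, converged = sol$converged,
    iterations = sol$iterations, gap = sol$gap,
    method = sol$method %||% method,
    centers = design$centers, formula = design$formula),
    class = "wqr_fit")
}

#' @export
coef.wqr_fit <- function(object, ...) object$coefficients

#' @export
print.wqr_fit <- function(x, ...) {
  cat(sprintf("<wqr_fit> tau = %g, n = %d, check loss = %.6g (%s)\n",
              x$tau, x$n_obs, x$loss, x$method))
  print(round(x$coefficients, 6))
  invisible(x)
}

#' Subgradient optimality check for a fitted quantile regression
#'
#' At a check-loss minimizer, the weighted share of strictly negative
#' residuals must be at most \eqn{\tau} and the weighted share of
#' non-positive residuals at least \eqn{\tau} (the slack is the weight mass
#' sitting exactly on the fitted hyperplane). Used as a standing
#' correctness property of the solver.
#'
#' @param X,y,weights,tau the fitted problem (weights `NULL` = unweighted).
#' @param beta coefficient vector.
#' @return list `frac_neg`, `frac_nonpos`, `ok`.
#' @export
subgradient_check <- function(X, y, weights = NULL, tau, beta) {
  X <- as.matrix(X)
  if (is.null(weights)) weights <- rep(1, nrow(X))
  r <- as.numeric(y) - drop(X %*% beta)
  tol <- 1e-8 * (1 + max(abs(y)))
  W <- sum(weights)
  frac_neg <- sum(weights[r < -tol]) / W
  frac_nonpos <- sum(weights[r <= tol]) / W
  list(frac_neg = frac_neg, frac_nonpos = frac_nonpos,
       ok = frac_neg <= tau + 1e-8 && frac_nonpos >= tau - 1e-8)
}

#' Fit the quantile trajectory model at several quantile levels
#'
#' Builds the design once and runs independent weighted fits per
#' \eqn{\tau} on identical rows and weights. `weights = NULL` is the
#' unweighted procedure; a `weight_table` from [estimate_weights()] is
#' matched to design rows by (id, wave).
#'
#' @param panel a [as_cohort_panel()].
#' @param weights `NULL`, a numeric vector aligned with the observed-FI
#'   rows, or a `weight_table`.
#' @param formula `"base"` or `"cohort"`.
#' @param taus quantile levels.
#' @param educ_center optional fixed education centering.
#' @return object of class `wqr_fits`: a list of `wqr_fit` keyed by
#'   `tau`, with the shared design information attached.
#' @examples
#' pan <- simulate_cohort(sim_config(n_individuals = 300, seed = 7))
#' fits <- fit_all(pan, formula = "base", taus = c(0.1, 0.5, 0.9))
#' sapply(fits, function(f) coef(f)["age"])
#' @export
fit_all <- function(panel, weights = NULL, formula = c("base", "cohort"),
                    taus = c(0.1, 0.5, 0.9), educ_center = NULL) {
  design <- build_design(panel, formula, educ_center = educ_center)
  w <- resolve_weights(weights, design$index)
  fits <- lapply(taus, function(tau) {
    f <- fit_wqr(design$X, design$y, weights = w, tau = tau)
    f$centers <- design$centers
    f$formula <- design$formula
    f
  })
  names(fits) <- as.character(taus)
  structure(fits, class = "wqr_fits", taus = taus,
            formula = design$formula, centers = design$centers)
}

resolve_weights <- function(weights, index) {
  if (is.null(weights)) return(NULL)
  if (inherits(weights, "weight_table") || is.data.frame(weights)) {
    key <- paste(index$id, index$wave)
    wk <- paste(weights$id, weights$wave)
    m <- match(key, wk)
    if (any(is.na(m))) {
      stop("weight table is missing weights for ", sum(is.na(m)),
           " observed rows", call. = FALSE)
    }
    return(weights$weight[m])
  }
  as.numeric(weights)
}

#' @export
print.wqr_fits <- function(x, ...) {
  cat(sprintf("<wqr_fits> formula = %s, taus = %s\n", attr(x, "formula"),
              paste(attr(x, "taus"), collapse = ", ")))
  tab <- sapply(x, coef)
  print(round(tab, 6))
  invisible(x)
}
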