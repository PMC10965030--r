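#' Configuration of the synthetic mortal-cohort generator
#'
#' Defines a location-scale data-generating process for Frailty Index (FI)
#' trajectories in a biennial panel of adults aged 65+, with FI-dependent
#' mortality and missing-at-random intermittent non-response. The defaults
#' emulate the structure of a large European ageing panel: six waves two
#' years apart, right-skewed FI, roughly a fifth of the cohort dying during
#' follow-up, and heavy intermittent missingness.
#'
#' The generative model for the latent FI of individual \eqn{i} at wave
#' \eqn{j} is
#' \deqn{FI_{ij} = x_{ij}'\beta + (\sigma_0 + \gamma A_{ij}) \epsilon_{ij},}
#' where \eqn{x_{ij}} holds the centered covariates (age and baseline age
#' centered at 65, education centered at `educ_mean`), \eqn{\beta} is
#' `coef_location`, \eqn{\sigma_0} = `scale_intercept`, \eqn{\gamma} =
#' `scale_age` and \eqn{\epsilon} has median zero. Because the scale is
#' linear in age, the true age slope of the conditional \eqn{\tau}-quantile
#' is \eqn{\beta_a + \gamma q_\epsilon(\tau)}: quantile trajectories fan out
#' with age when \eqn{\gamma > 0}. Errors are equicorrelated within
#' individual through a Gaussian copula (`within_corr`), which leaves every
#' marginal quantile — and hence the closed-form truth of
#' [true_quantile_coefficients()] — unchanged.
#'
#' @param n_individuals number of individuals.
#' @param n_waves number of scheduled waves (>= 2).
#' @param wave_gap_years years between waves.
#' @param entry_age_range numeric length 2, minimum >= 65; entry ages are
#'   drawn from truncated normals within this range (see Details).
#' @param coef_location named numeric vector of location coefficients on the
#'   centered scale; names must be
#'   `intercept, sex, educ, base_age, cohort, age, age:sex, age:educ,
#'   age:base_age, age:cohort`.
#' @param scale_intercept \eqn{\sigma_0 > 0}, FI units.
#' @param scale_age \eqn{\gamma}, FI units per year of age; the scale
#'   \eqn{\sigma_0 + \gamma (age - 65)} must stay positive over the
#'   simulated age span.
#' @param error_dist `"skew-positive"` (centered standard exponential,
#'   right-skewed like empirical FI distributions) or `"normal"`.
#' @param within_corr within-individual equicorrelation of the error copula,
#'   in \[0, 1).
#' @param death_model named numeric `(intercept, fi, age)`: per-wave logistic
#'   death hazard evaluated at waves >= 2 on the current latent FI and
#'   age - 65. `-Inf` intercept disables mortality.
#' @param obs_model named numeric `(intercept, lag_fi, sex)`: per-wave
#'   logistic interview probability for alive individuals at waves >= 2,
#'   driven by the previous wave's latent FI. `Inf` intercept forces full
#'   observation.
#' @param prop_female proportion of women.
#' @param educ_mean,educ_sd years of education (truncated normal on
#'   \[0, 25\]).
#' @param prop_born_1946plus proportion born 1946 or later; the later-born
#'   enter young (ages near 65-68) as they do in a calendar-anchored panel.
#' @param seed integer RNG seed used by [simulate_cohort()].
#' @return an object of class `sim_config` (a validated list).
#' @details Entry ages: individuals born before 1946 draw from a truncated
#'   normal with mean 74.5 and SD 6.6; those born 1946+ from mean 66 and SD
#'   1.2 — matching the age structure such a cohort shows at entry. Both are
#'   truncated to `entry_age_range`.
#'
#'   Default mortality and observation parameters were calibrated by forward
#'   simulation so that about 21-22% of individuals die within six waves and
#'   the per-wave interview probability among the alive is about 0.6,
#'   producing the heavy 1-2-interview tail typical of ageing panels.
#' @examples
#' cfg <- sim_config(n_individuals = 200, seed = 42)
#' pan <- simulate_cohort(cfg)
#' true_quantile_coefficients(cfg, 0.9)
#' @export
sim_config <- function(n_individuals = 2000,
                       n_waves = 6,
                       wave_gap_years = 2,
                       entry_age_range = c(65, 90),
                       coef_location = c(
                         "intercept"    = 0.10,
                         "sex"          = 0.0036,
                         "educ"         = -0.0008,
                         "base_age"     = -0.0070,
                         "cohort"       = 0.0080,
                         "age"          = 0.0067,
                         "age:sex"      = 0.0020,
                         "age:educ"     = -0.0004,
                         "age:base_age" = 0.0004,
                         "age:cohort"   = 0.0007),
                       scale_intercept = 0.08,
                       scale_age = 0.004,
                       error_dist = c("skew-positive", "normal"),
                       within_corr = 0.5,
                       death_model = c(intercept = -4.65, fi = 3.0, age = 0.04),
                       obs_model = c(intercept = 0.62, lag_fi = -2.0, sex = 0.10),
                       prop_female = 0.53,
                       educ_mean = 9.6,
                       educ_sd = 4.5,
                       prop_born_1946plus = 0.08,
                       seed = 1L) {
  error_dist <- match.arg(error_dist)
  cfg <- list(
    n_individuals = n_individuals, n_waves = n_waves,
    wave_gap_years = wave_gap_years, entry_age_range = entry_age_range,
    coef_location = coef_location, scale_intercept = scale_intercept,
    scale_age = scale_age, error_dist = error_dist,
    within_corr = within_corr, death_model = death_model,
    obs_model = obs_model, prop_female = prop_female,
    educ_mean = educ_mean, educ_sd = educ_sd,
    prop_born_1946plus = prop_born_1946plus, seed = seed)
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

sim_coef_names <- c("intercept", "sex", "educ", "base_age", "cohort", "age",
                    "age:sex", "age:educ", "age:base_age", "age:cohort")

validate_sim_config <- function(cfg) {
  if (!is.numeric(cfg$n_individuals) || cfg$n_individuals < 1) {
    stop_config("n_individuals", "must be a positive count")
  }
  if (!is.numeric(cfg$n_waves) || cfg$n_waves < 2) {
    stop_config("n_waves", "must be >= 2")
  }
  if (cfg$wave_gap_years <= 0) stop_config("wave_gap_years", "must be positive")
  r <- cfg$entry_age_range
  if (length(r) != 2 || r[1] < 65 || r[2] < r[1]) {
    stop_config("entry_age_range", "must be [min, max] with min >= 65")
  }
  if (!all(sim_coef_names %in% names(cfg$coef_location))) {
    stop_config("coef_location", paste("must name all of:",
                paste(sim_coef_names, collapse = ", ")))
  }
  if (cfg$scale_intercept <= 0) stop_config("scale_intercept", "must be > 0")
  max_age_c <- r[2] + (cfg$n_waves - 1) * cfg$wave_gap_years - 65
  if (cfg$scale_intercept + cfg$scale_age * max_age_c <= 0 ||
      cfg$scale_intercept + cfg$scale_age * 0 <= 0) {
    stop_config("scale_age", "scale must stay positive at every simulated age")
  }
  if (cfg$within_corr < 0 || cfg$within_corr >= 1) {
    stop_config("within_corr", "must be in [0, 1)")
  }
  for (f in c("prop_female", "prop_born_1946plus")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop_config(f, "must be in [0, 1]")
  }
  if (!all(c("intercept", "fi", "age") %in% names(cfg$death_model))) {
    stop_config("death_model", "must name intercept, fi, age")
  }
  if (!all(c("intercept", "lag_fi", "sex") %in% names(cfg$obs_model))) {
    stop_config("obs_model", "must name intercept, lag_fi, sex")
  }
  invisible(cfg)
}

# quantile function of the standardized error distribution (median 0)
error_quantile <- function(dist, tau) {
  switch(dist,
    "normal" = stats::qnorm(tau),
    "skew-positive" = -log(1 - tau) - log(2),
    stop("unsupported error distribution: ", dist, call. = FALSE))
}

error_sample <- function(dist, u) {
  # u: uniform(0,1) draws (copula probabilities)
  error_quantile(dist, u)
}

#' True conditional-quantile coefficients of the generative model
#'
#' Closed-form coefficients of the conditional \eqn{\tau}-quantile of FI
#' implied by a [sim_config()]: the location coefficients with the intercept
#' shifted by \eqn{\sigma_0 q_\epsilon(\tau)} and the age coefficient
#' shifted by \eqn{\gamma q_\epsilon(\tau)}; all other coefficients are
#' unchanged because the scale depends on age only. These are the targets
#' recovered by [fit_all()] on clean simulated data.
#'
#' @param config a [sim_config()].
#' @param tau quantile level(s) in (0, 1).
#' @return data frame with one row per `tau` and one column per coefficient.
#' @examples
#' cfg <- sim_config()
#' true_quantile_coefficients(cfg, c(0.1, 0.5, 0.9))
#' @export
true_quantile_coefficients <- function(config, tau) {
  stopifnot(inherits(config, "sim_config"))
  if (any(tau <= 0 | tau >= 1)) stop("tau must be in (0, 1)", call. = FALSE)
  q <- vapply(tau, function(t) error_quantile(config$error_dist, t), 0)
  beta <- config$coef_location[sim_coef_names]
  out <- do.call(rbind, lapply(seq_along(tau), function(k) {
    b <- beta
    b["intercept"] <- b["intercept"] + config$scale_intercept * q[k]
    b["age"] <- b["age"] + config$scale_age * q[k]
    b
  }))
  data.frame(tau = tau, out, check.names = FALSE)
}

#' Simulate a mortal-cohort FI panel
#'
#' Draws individuals, their latent FI trajectories from the location-scale
#' model of [sim_config()], then applies the mortality process
#' ([apply_death_process()]) and the interview/observation process
#' ([apply_observation_process()]). Latent FI values falling outside
#' \[0, 1\] are clamped; the clamped fraction is reported as the
#' `clamp_frac` attribute (default parameters keep it well below 1% so the
#' closed-form truth stays valid to tolerance).
#'
#' @param config a [sim_config()].
#' @param seed optional override of `config$seed`.
#' @return a [as_cohort_panel()] data frame with one row per individual and
#'   wave; extra columns `fi_true` (latent FI, kept for validation against
#'   ground truth) and `death_wave` (`NA` if the individual survives).
#'   Attributes: `clamp_frac`, `config`.
#' @export
simulate_cohort <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  seed <- seed %||% config$seed
  with_seed(seed, {
    n <- config$n_individuals
    J <- config$n_waves
    sex <- stats::rbinom(n, 1, config$prop_female)
    cohort <- stats::rbinom(n, 1, config$prop_born_1946plus)
    educ <- rtruncnorm(n, config$educ_mean, config$educ_sd, 0, 25)
    r <- config$entry_age_range
    base_age <- ifelse(cohort == 1,
                       rtruncnorm(n, 66, 1.2, r[1], min(r[2], 68)),
                       rtruncnorm(n, 74.5, 6.6, r[1], r[2]))

    id <- rep(seq_len(n), each = J)
    wave <- rep(seq_len(J), n)
    age <- base_age[id] + (wave - 1) * config$wave_gap_years

    # centered design, matching the fitted models' conventions
    age_c <- age - 65
    b <- config$coef_location
    mu <- b["intercept"] +
      b["sex"] * sex[id] +
      b["educ"] * (educ[id] - config$educ_mean) +
      b["base_age"] * (base_age[id] - 65) +
      b["cohort"] * cohort[id] +
      (b["age"] +
         b["age:sex"] * sex[id] +
         b["age:educ"] * (educ[id] - config$educ_mean) +
         b["age:base_age"] * (base_age[id] - 65) +
         b["age:cohort"] * cohort[id]) * age_c

    # Gaussian copula errors: equicorrelated normal scores, exact marginals
    rho <- config$within_corr
    zeta <- sqrt(rho) * stats::rnorm(n)[id] + sqrt(1 - rho) * stats::rnorm(n * J)
    eps <- error_sample(config$error_dist, stats::pnorm(zeta))
    sigma <- config$scale_intercept + config$scale_age * age_c
    fi_raw <- as.numeric(mu + sigma * eps)

    clamp <- fi_raw < 0 | fi_raw > 1
    fi_true <- pmin(pmax(fi_raw, 0), 1)

    panel <- data.frame(
      id = id, wave = wave, age = age, sex = sex[id],
      educ_years = educ[id], base_age = base_age[id],
      born_1946plus = cohort[id], fi_true = fi_true)

    panel <- apply_death_process(panel, config$death_model, seed = NULL)
    panel <- apply_observation_process(panel, config$obs_model, seed = NULL)

    panel$fi <- ifelse(panel$observed == 1, panel$fi_true, NA_real_)
    out <- as_cohort_panel(panel)
    attr(out, "clamp_frac") <- mean(clamp)
    attr(out, "config") <- config
    out
  })
}

#' Apply the per-wave mortality process to a panel
#'
#' Waves 2 and later expose each still-alive individual to a logistic death
#' hazard on the current latent FI and on age - 65; death is absorbing and a
#' death at wave j removes the wave-j interview opportunity. Everyone is
#' alive at wave 1 (study entry).
#'
#' @param panel data frame with columns id, wave, age, fi_true.
#' @param death_model named numeric `(intercept, fi, age)` on the logit
#'   scale; `-Inf` intercept means no deaths.
#' @param seed optional seed; `NULL` uses the current RNG stream.
#' @return `panel` with columns `alive` (0/1) and `death_wave` added.
#' @export
apply_death_process <- function(panel, death_model, seed = NULL) {
  if (!all(c("intercept", "fi", "age") %in% names(death_model))) {
    stop_config("death_model", "must name intercept, fi, age")
  }
  run <- function() {
    panel <- panel[order(panel$id, panel$wave), , drop = FALSE]
    J <- max(panel$wave)
    n <- length(unique(panel$id))
    if (nrow(panel) != n * J || !all(panel$wave == rep(seq_len(J), n))) {
      stop("panel must contain one row per individual for each wave 1..J",
           call. = FALSE)
    }
    wmat <- matrix(seq_len(nrow(panel)), nrow = J)  # column k = rows of id k
    alive <- matrix(1L, J, n)
    death_wave <- rep(NA_integer_, n)
    for (j in 2:J) {
      rows <- wmat[j, ]
      h <- stats::plogis(death_model["intercept"] +
                         death_model["fi"] * panel$fi_true[rows] +
                         death_model["age"] * (panel$age[rows] - 65))
      atrisk <- alive[j - 1, ] == 1
      dies <- atrisk & stats::runif(n) < h
      alive[j, ] <- as.integer(atrisk & !dies)
      death_wave[dies & is.na(death_wave)] <- j
    }
    panel$alive <- as.vector(alive)  # column-major matches id-major sort
    panel$death_wave <- death_wave[match(panel$id, unique(panel$id))]
    panel
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Apply the interview/observation process to a panel
#'
#' Wave-1 rows are always observed (study entry). For alive rows at waves
#' >= 2, observation is Bernoulli with logistic probability driven by the
#' previous wave's latent FI and sex. Dead rows are never observed. The
#' generator deliberately uses the *latent* FI history; downstream weight
#' estimation only sees the observed history and must impute the gap —
#' mirroring real panels.
#'
#' @param panel data frame with columns id, wave, sex, fi_true, alive.
#' @param obs_model named numeric `(intercept, lag_fi, sex)` on the logit
#'   scale; `Inf` intercept forces observation of every alive row.
#' @param seed optional seed; `NULL` uses the current RNG stream.
#' @return `panel` with column `observed` (0/1) added.
#' @export
apply_observation_process <- function(panel, obs_model, seed = NULL) {
  if (!all(c("intercept", "lag_fi", "sex") %in% names(obs_model))) {
    stop_config("obs_model", "must name intercept, lag_fi, sex")
  }
  if (!"alive" %in% names(panel)) {
    stop("panel must carry alive flags; run apply_death_process() first",
         call. = FALSE)
  }
  run <- function() {
    panel <- panel[order(panel$id, panel$wave), , drop = FALSE]
    lag_fi <- stats::ave(panel$fi_true, panel$id,
                         FUN = function(v) c(NA, v[-length(v)]))
    p <- stats::plogis(obs_model["intercept"] +
                       obs_model["lag_fi"] * lag_fi +
                       obs_model["sex"] * panel$sex)
    obs <- as.integer(panel$alive == 1 & stats::runif(nrow(panel)) < p)
    obs[panel$wave == 1] <- 1L  # entry interview by construction
    panel$observed <- obs
    panel
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}
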