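test_that("degenerate processes give a fully observed immortal panel", {
  pan <- simulate_cohort(clean_config(n = 100, seed = 3))
  expect_equal(nrow(pan), 600)
  expect_true(all(pan$observed == 1))
  expect_true(all(pan$alive == 1))
  expect_true(all(!is.na(pan$fi)))
})

test_that("simulation is deterministic given the seed and leaves the RNG alone", {
  cfg <- sim_config(n_individuals = 80, seed = 99)
  p1 <- simulate_cohort(cfg)
  set.seed(123); before <- runif(3)
  set.seed(123); p2 <- simulate_cohort(cfg); after <- runif(3)
  expect_identical(p1, p2)
  expect_identical(before, after)  # caller RNG stream untouched
  p3 <- simulate_cohort(cfg, seed = 100)
  expect_false(identical(p1$fi_true, p3$fi_true))
})

test_that("true quantile coefficients follow the location-scale closed form", {
  cfg <- clean_config(error_dist = "normal")
  tr <- true_quantile_coefficients(cfg, c(0.1, 0.5, 0.9))
  # symmetric zero-median error: tau = 0.5 truth equals the location coefs
  expect_equal(unlist(tr[tr$tau == 0.5, -1]),
               cfg$coef_location, ignore_attr = TRUE)
  # intercept/age shifts are sigma0*z_tau and gamma*z_tau (normal oracle)
  z9 <- qnorm(0.9)
  expect_equal(tr$intercept[3] - tr$intercept[2], cfg$scale_intercept * z9)
  expect_equal(tr$age[3] - tr$age[2], cfg$scale_age * z9)
  # symmetric error: tau = 0.1 and 0.9 shifts mirror each other
  expect_equal(tr$intercept[2] - tr$intercept[1],
               tr$intercept[3] - tr$intercept[2])
  # worked case: beta_age = 0.005, gamma = 0.003 => true 0.9 slope 0.00884
  cl <- cfg$coef_location; cl["age"] <- 0.005
  cfg2 <- clean_config(error_dist = "normal", coef_location = cl,
                       scale_age = 0.003)
  expect_equal(true_quantile_coefficients(cfg2, 0.9)$age,
               0.005 + 0.003 * qnorm(0.9), tolerance = 1e-12)
})

test_that("intercept-only shift applies when the scale has no age term", {
  cfg <- clean_config(error_dist = "normal", scale_intercept = 0.05,
                      scale_age = 0)
  tr <- true_quantile_coefficients(cfg, 0.9)
  expect_equal(tr$intercept, cfg$coef_location[["intercept"]] +
                 0.05 * qnorm(0.9))
  expect_equal(tr$age, cfg$coef_location[["age"]])
})

test_that("death process: hazard-free survival, calibrated rate, FI selection", {
  cfg <- clean_config(n = 5000, seed = 21)
  pan <- simulate_cohort(cfg)

  # probability-zero hazard: everyone survives
  p0 <- apply_death_process(as.data.frame(pan),
                            c(intercept = -Inf, fi = 0, age = 0), seed = 1)
  expect_true(all(p0$alive == 1))

  # flat hazard logit(0.1): per-wave death fraction ~0.10 among at-risk
  pd <- apply_death_process(as.data.frame(pan),
                            c(intercept = qlogis(0.1), fi = 0, age = 0),
                            seed = 2)
  # wave-2 deaths / wave-1 alive is a clean binomial draw
  d2 <- sum(pd$wave == 2 & pd$alive == 0)
  expect_lt(abs(d2 / 5000 - 0.10), 3 * sqrt(0.1 * 0.9 / 5000))

  # strong FI dependence: the deceased are frailer than survivors
  ph <- apply_death_process(as.data.frame(pan),
                            c(intercept = -3, fi = 6, age = 0), seed = 3)
  died <- tapply(ph$alive, ph$id, min) == 0
  base_fi <- ph$fi_true[!duplicated(ph$id)]
  expect_gt(mean(base_fi[died]), mean(base_fi[!died]))
})

test_that("observation process: full response, selection direction, rate", {
  cfg <- clean_config(n = 4000, seed = 31)
  pan <- as.data.frame(simulate_cohort(cfg))

  p1 <- apply_observation_process(pan, c(intercept = Inf, lag_fi = 0,
                                         sex = 0), seed = 1)
  expect_true(all(p1$observed[p1$alive == 1] == 1))

  # negative lag-FI coefficient: observed alive rows have lower lagged FI
  p2 <- apply_observation_process(pan, c(intercept = 0.5, lag_fi = -3,
                                         sex = 0), seed = 2)
  lag <- ave(p2$fi_true, p2$id, FUN = function(v) c(NA, v[-length(v)]))
  alive2 <- p2$alive == 1 & p2$wave > 1
  expect_lt(mean(lag[alive2 & p2$observed == 1]),
            mean(lag[alive2 & p2$observed == 0]))

  # flat logit(0.7): response rate among alive waves 2+ is ~0.70
  p3 <- apply_observation_process(pan, c(intercept = qlogis(0.7), lag_fi = 0,
                                         sex = 0), seed = 3)
  rate <- mean(p3$observed[p3$alive == 1 & p3$wave > 1])
  expect_lt(abs(rate - 0.7), 3 * sqrt(0.7 * 0.3 / (4000 * 5)))
})

test_that("panel invariants: monotone mortality, no post-death observation, clamping reported", {
  pan <- simulate_cohort(sim_config(n_individuals = 500, seed = 8))
  for (id in unique(pan$id)[1:50]) {
    a <- pan$alive[pan$id == id]
    expect_true(all(diff(a) <= 0))
  }
  expect_true(all(pan$observed[pan$alive == 0] == 0))
  expect_true(all(pan$fi >= 0 & pan$fi <= 1, na.rm = TRUE))
  expect_lt(attr(pan, "clamp_frac"), 0.01)
})

test_that("with scale_age > 0 the true age slope increases strictly in tau", {
  tr <- true_quantile_coefficients(sim_config(), c(0.1, 0.25, 0.5, 0.75, 0.9))
  expect_true(all(diff(tr$age) > 0))
})

test_that("invalid configurations are rejected with the field named", {
  expect_error(sim_config(n_waves = 1), "n_waves")
  expect_error(sim_config(entry_age_range = c(60, 80)), "entry_age_range")
  expect_error(sim_config(scale_intercept = -1), "scale_intercept")
  expect_error(sim_config(scale_age = -0.1), "scale_age")
  expect_error(sim_config(within_corr = 1), "within_corr")
  expect_error(sim_config(prop_female = 1.2), "prop_female")
  expect_error(true_quantile_coefficients(sim_config(), 1.2), "tau")
})

test_that("panel round-trips through CSV", {
  pan <- simulate_cohort(sim_config(n_individuals = 40, seed = 5))
  path <- tempfile(fileext = ".csv")
  write_cohort_panel(pan, path)
  back <- read_cohort_panel(path)
  expect_equal(as.data.frame(back)[c("id", "wave", "fi", "observed", "alive")],
               as.data.frame(pan)[c("id", "wave", "fi", "observed", "alive")],
               tolerance = 1e-12)
})
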