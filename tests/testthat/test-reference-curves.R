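make_fit <- function(coefs, centers = list(age = 65, base_age = 65,
                                           educ = 9.6),
                     formula = "base", tau = 0.5) {
  structure(list(coefficients = coefs, tau = tau, centers = centers,
                 formula = formula), class = "wqr_fit")
}

base_coefs <- c("(Intercept)" = 0.12, "sex" = 0.004, "educ" = -0.001,
                "base_age" = -0.007, "age" = 0.0067, "age:sex" = 0.002,
                "age:educ" = -0.0004, "age:base_age" = 0.0004)

test_that("prediction linearity: profile algebra matches the coefficients", {
  fit <- make_fit(base_coefs)
  # male, mean education, entry and current age 65: prediction = intercept
  pm <- predict_curve(fit, covariate_profile(sex = 0, base_age = 65,
                                             ages = 65:67))
  expect_equal(pm$fi_pred[1], 0.12)
  # unit age step adds the age coefficient for that profile
  expect_equal(diff(pm$fi_pred), rep(0.0067, 2))
  # female profile slope = age + age:sex
  pf <- predict_curve(fit, covariate_profile(sex = 1, base_age = 65,
                                             ages = 65:67))
  expect_equal(diff(pf$fi_pred), rep(0.0067 + 0.002, 2), tolerance = 1e-12)
  # superposition: prediction is linear in the coefficient vector
  fit2 <- make_fit(2 * base_coefs)
  p2 <- predict_curve(fit2, covariate_profile(sex = 1, base_age = 65,
                                              ages = 65:67))
  expect_equal(p2$fi_pred, 2 * pf$fi_pred, tolerance = 1e-12)
})

test_that("profile validation and formula compatibility", {
  expect_error(covariate_profile(sex = 1, ages = c(70, 69)), "increasing")
  expect_error(covariate_profile(sex = 1, base_age = 70, ages = 65:80),
               "baseline age")
  fit <- make_fit(base_coefs)
  expect_error(predict_curve(structure(list(coefficients = base_coefs,
                                            tau = 0.5),
                                       class = "wqr_fit"),
                             covariate_profile(sex = 1)),
               "centering")
})

test_that("degenerate ensembles give zero-width bands on the point curve", {
  cf <- matrix(rep(base_coefs, each = 20), nrow = 20,
               dimnames = list(NULL, names(base_coefs)))
  ens <- structure(list(
    coef = array(cf, dim = c(20, 8, 1),
                 dimnames = list(NULL, names(base_coefs), "0.5")),
    point = list("0.5" = make_fit(base_coefs)),
    taus = 0.5, terms = names(base_coefs), B = 20, n_failed = 0),
    class = "wqr_boot")
  rc <- curve_bands(ens, covariate_profile(sex = 0), 0.5)
  expect_equal(rc$lwr, rc$fit, tolerance = 1e-12)
  expect_equal(rc$upr, rc$fit, tolerance = 1e-12)
  # bands always contain the point prediction (up to fp rounding)
  expect_true(all(rc$lwr <= rc$fit + 1e-10 & rc$fit <= rc$upr + 1e-10))
  # fewer than 20 replicates is refused
  ens$B <- 19
  expect_error(curve_bands(ens, covariate_profile(sex = 0), 0.5),
               "at least 20")
})

test_that("bands widen with age when only the slope varies across replicates", {
  B <- 40
  cf <- matrix(rep(base_coefs, each = B), nrow = B,
               dimnames = list(NULL, names(base_coefs)))
  cf[, "age"] <- base_coefs["age"] + seq(-0.002, 0.002, length.out = B)
  ens <- structure(list(
    coef = array(cf, dim = c(B, 8, 1),
                 dimnames = list(NULL, names(base_coefs), "0.5")),
    point = list("0.5" = make_fit(base_coefs)),
    taus = 0.5, terms = names(base_coefs), B = B, n_failed = 0),
    class = "wqr_boot")
  rc <- curve_bands(ens, covariate_profile(sex = 0), 0.5)
  widths <- rc$upr - rc$lwr
  expect_true(all(diff(widths) >= -1e-12))
  expect_gt(widths[length(widths)], widths[1])
})

test_that("band coverage of the true synthetic quantile curve is near nominal", {
  # desk-scale Monte-Carlo: tau = 0.5 curve for a male mean-educ profile
  # entering at 74; cohort share zeroed so the base formula is the truth
  reps <- 12
  profile <- covariate_profile(sex = 0, base_age = 74, ages = c(74, 80))
  cfg0 <- clean_config(n = 250, prop_born_1946plus = 0)
  tr <- true_quantile_coefficients(cfg0, 0.5)
  true_curve <- tr$intercept + tr$base_age * (74 - 65) +
    (tr$age + tr$`age:base_age` * (74 - 65)) * (profile$ages - 65)
  hits <- 0; cells <- 0
  for (r in seq_len(reps)) {
    pan <- simulate_cohort(clean_config(n = 250, prop_born_1946plus = 0,
                                        seed = 7000 + r))
    bt <- cluster_bootstrap(pan, taus = 0.5, B = 40, seed = r,
                            weighting = "none")
    rc <- curve_bands(bt, profile, 0.5)
    hits <- hits + sum(rc$lwr <= true_curve & true_curve <= rc$upr)
    cells <- cells + nrow(rc)
  }
  expect_gte(hits / cells, 0.95 - 3 * sqrt(0.95 * 0.05 / cells))
})

test_that("education offset in years: worked values and contracts", {
  # published weighted median coefficients: 0.0067 / |-0.0004| = 16.75
  expect_equal(education_offset_years(c("age" = 0.0067,
                                        "age:educ" = -0.0004)), 16.75)
  expect_equal(education_offset_years(c("age" = 0.01, "age:educ" = -0.01)), 1)
  expect_error(education_offset_years(c("age" = 0.01, "age:educ" = 0)),
               "undefined")
  fit <- make_fit(base_coefs)
  expect_equal(education_offset_years(fit),
               0.0067 / 0.0004, tolerance = 1e-12)
})

test_that("pipeline: no-attrition run makes weighted and unweighted agree", {
  rep0 <- run_pipeline(list(sim = clean_config(n = 250, seed = 123),
                            taus = 0.5, B = 20, seed = 123))
  cw <- coef(rep0$fits$weighted[["0.5"]])
  cu <- coef(rep0$fits$unweighted[["0.5"]])
  # with full observation the MAR and MCAR probabilities coincide: the
  # weights are ~1 and both procedures see the same minimization problem
  expect_lt(max(abs(rep0$weights$weight - 1)), 0.05)
  expect_equal(cw, cu, tolerance = 0.01)
})

test_that("pipeline reruns with the same config are identical; outputs complete", {
  cfg <- list(sim = sim_config(n_individuals = 150, seed = 77),
              taus = c(0.5, 0.9), B = 20, seed = 77)
  r1 <- run_pipeline(cfg)
  r2 <- run_pipeline(cfg)
  expect_identical(r1$tables, r2$tables)
  expect_identical(r1$curves, r2$curves)
  expect_named(r1$fits, c("weighted", "unweighted"))
  expect_equal(nrow(r1$tables$weighted), 8 * 2)
  expect_true(all(c("weighted.female.tau0.5", "unweighted.male.tau0.9")
                  %in% names(r1$curves)))
  expect_equal(r1$manifest$seed, 77)
})
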