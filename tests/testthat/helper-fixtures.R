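# shared fixtures built in code

# small clean cohort: no deaths, everyone observed
clean_config <- function(n = 300, seed = 1, ...) {
  sim_config(n_individuals = n,
             death_model = c(intercept = -Inf, fi = 0, age = 0),
             obs_model = c(intercept = Inf, lag_fi = 0, sex = 0),
             seed = seed, ...)
}

# independent check-loss oracle: exact minimum over all p-point basic
# solutions (the LP optimum lies at a vertex interpolating p observations)
oracle_qr_loss <- function(X, y, tau, w = NULL) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (is.null(w)) w <- rep(1, n)
  best <- Inf
  for (idx in utils::combn(n, p, simplify = FALSE)) {
    Xb <- X[idx, , drop = FALSE]
    b <- tryCatch(solve(Xb, y[idx]), error = function(e) NULL)
    if (is.null(b)) next
    u <- y - drop(X %*% b)
    l <- sum(w * u * (tau - (u < 0)))
    if (l < best) best <- l
  }
  best
}

# hand-rolled panel with explicit observation/vital history
toy_panel <- function() {
  as_cohort_panel(data.frame(
    id = rep(1:3, each = 3),
    wave = rep(1:3, 3),
    age = rep(c(70, 72, 74), 3),
    sex = rep(c(1, 0, 1), each = 3),
    educ_years = rep(c(9, 12, 6), each = 3),
    base_age = rep(70, 9),
    born_1946plus = 0,
    # id 1: observed every wave; id 2: wave 1 only, alive throughout;
    # id 3: dies at wave 3
    fi = c(0.10, 0.20, 0.30, 0.15, NA, NA, 0.40, 0.50, NA),
    observed = c(1, 1, 1, 1, 0, 0, 1, 1, 0),
    alive = c(1, 1, 1, 1, 1, 1, 1, 1, 0)))
}
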