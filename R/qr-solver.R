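# Weighted quantile regression by exact linear programming.
#
# The weighted check-loss problem min_b sum_i w_i * rho_tau(y_i - x_i'b)
# is equivalent (rho_tau is positively homogeneous) to the unweighted
# problem on the row-scaled data (w_i * y_i, w_i * x_i). Its LP dual is the
# box-constrained program
#     min -y'a  s.t.  X'a = (1 - tau) X'1,  0 <= a <= 1,
# solved here with a Mehrotra predictor-corrector primal-dual interior
# point method (the Frisch-Newton approach); the regression coefficients
# are the negated equality-constraint multipliers. A final "polish" step
# refits through the p interpolated observations so the returned solution
# is an exact basic (vertex) solution whenever the problem is
# non-degenerate.

check_loss <- function(u, tau, w = NULL) {
  v <- u * (tau - (u < 0))
  if (is.null(w)) sum(v) else sum(w * v)
}

# interior point core on the scaled (unweighted) problem
solve_qr_fn <- function(X, y, tau, tol = 1e-10, maxit = 100) {
  n <- nrow(X); p <- ncol(X)
  y <- as.numeric(y)
  A <- t(X)
  c0 <- -y
  b0 <- (1 - tau) * colSums(X)
  a <- rep(1 - tau, n)
  s <- 1 - a
  nu <- tryCatch(qr.solve(tcrossprod(A), A %*% c0),
                 error = function(e) rep(0, p))
  r <- c0 - drop(crossprod(A, nu))
  z <- pmax(r, 0) + 1e-4
  w <- z - r
  eps <- 1e-12
  step <- function(x1, d1, x2, d2) {
    min(c(ifelse(d1 < 0, -x1 / d1, Inf), ifelse(d2 < 0, -x2 / d2, Inf),
          1 / 0.9995))
  }
  it <- 0L; mu <- Inf
  for (it in seq_len(maxit)) {
    gap <- sum(a * z) + sum(s * w)
    mu <- gap / (2 * n)
    rp <- b0 - drop(A %*% a)
    ru <- 1 - a - s
    rd <- c0 - drop(crossprod(A, nu)) - z + w
    if (mu < tol && max(abs(rp)) < tol * (1 + max(abs(b0)))) break
    d <- 1 / (z / a + w / s)
    M <- A %*% (d * t(A))
    rhs1 <- rd + z - w - (w / s) * ru
    dnu <- tryCatch(solve(M, rp + drop(A %*% (d * rhs1))),
                    error = function(e) NULL)
    if (is.null(dnu)) break
    da <- d * (drop(crossprod(A, dnu)) - rhs1)
    ds <- ru - da
    dz <- -z - (z / a) * da
    dw <- -w - (w / s) * ds
    ap <- step(a, da, s, ds); ad <- step(z, dz, w, dw)
    ga <- sum((a + ap * da) * (z + ad * dz)) +
          sum((s + ap * ds) * (w + ad * dw))
    sigma <- max(min((ga / gap)^3, 0.99), 1e-6)
    # corrector pass with Mehrotra's second-order complementarity target
    ca <- (sigma * mu - da * dz) / a
    cs <- (sigma * mu - ds * dw) / s
    rhs1 <- rd + z - w - ca - (w / s) * ru + cs
    dnu <- tryCatch(solve(M, rp + drop(A %*% (d * rhs1))),
                    error = function(e) NULL)
    if (is.null(dnu)) break
    da <- d * (drop(crossprod(A, dnu)) - rhs1)
    ds <- ru - da
    dz <- -z - (z / a) * da + ca
    dw <- -w - (w / s) * ds + cs
    ap <- min(0.9995 * step(a, da, s, ds), 1)
    ad <- min(0.9995 * step(z, dz, w, dw), 1)
    a <- pmax(a + ap * da, eps); s <- pmax(s + ap * ds, eps)
    z <- pmax(z + ad * dz, eps); w <- pmax(w + ad * dw, eps)
    nu <- nu + ad * dnu
  }
  list(beta = -drop(nu), iterations = it, gap = mu, converged = mu < 1e-6)
}

# smoothed fallback: iteratively reweighted least squares on a sequence of
# shrinking smoothings of the check function
solve_qr_irls <- function(X, y, tau, maxit = 200) {
  y <- as.numeric(y)
  beta <- qr.coef(qr(X), y)
  beta[is.na(beta)] <- 0
  for (delta in c(1e-2, 1e-4, 1e-6, 1e-8)) {
    for (k in seq_len(maxit)) {
      r <- y - drop(X %*% beta)
      wi <- abs(tau - (r < 0)) / pmax(abs(r), delta)
      bnew <- tryCatch(qr.coef(qr(X * sqrt(wi)), y * sqrt(wi)),
                       error = function(e) beta)
      bnew[is.na(bnew)] <- 0
      if (max(abs(bnew - beta)) < delta * 1e-3) { beta <- bnew; break }
      beta <- bnew
    }
  }
  list(beta = drop(beta), iterations = NA_integer_, gap = NA_real_,
       converged = TRUE)
}

# refit through the p observations the current solution (nearly)
# interpolates; keeps the result only if the loss does not increase
polish_vertex <- function(X, y, tau, beta) {
  p <- ncol(X)
  r <- as.numeric(y) - drop(X %*% beta)
  idx <- order(abs(r))[seq_len(p)]
  Xb <- X[idx, , drop = FALSE]
  bb <- tryCatch(solve(Xb, y[idx]), error = function(e) NULL)
  if (is.null(bb)) return(beta)
  if (check_loss(y - drop(X %*% bb), tau) <=
      check_loss(y - drop(X %*% beta), tau) + 1e-12) drop(bb) else beta
}
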