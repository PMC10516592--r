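# Profile least-squares engine for the left-flat sigmoid regression.
#
# Model: y = v0 - delta * ramp(cap; tau, scale) + Z beta + eps,  delta >= 0.
# For fixed (tau, scale) the fit is linear in (v0, delta, beta).  The engine
# precomputes, once per design, the orthonormal basis Q of [1, Z] and the
# Q-residualised ramp columns over a (tau x scale) grid, so that profiling a
# new response vector y costs one matrix-vector product.  This is what makes
# subject-block bootstrap refitting affordable: replicates share the design
# and differ only in y.

.default_tau_grid <- function(cap, step = 5) {
  qs <- stats::quantile(cap, c(0.05, 0.95), names = FALSE, type = 7)
  if (diff(qs) < step)
    stop("observed CAP range is narrower than the tau grid spacing")
  grid <- seq(ceiling(qs[1] / step) * step, floor(qs[2] / step) * step, by = step)
  # extra point at the observed minimum: with a wide transition the family
  # then contains near-linear members, so a straight-line fit is (numerically)
  # nested in the sigmoid family
  lo <- floor(min(cap))
  if (lo < grid[1]) grid <- c(lo, grid)
  grid
}

.default_scale_bounds <- function(cap, tau_step = 5) {
  c(max(tau_step / 2, 1e-3), 20 * diff(range(cap)))
}

# Build the reusable profiling state for a fixed design.
make_engine <- function(cap, Z, tau_grid = NULL, tau_step = 5,
                        scale_bounds = NULL, n_scale = 25,
                        refine_tol = 1e-9) {
  n <- length(cap)
  Z <- as.matrix(Z)
  if (nrow(Z) == 0L || ncol(Z) == 0L) Z <- matrix(0, n, 0)
  X0 <- cbind(`(Intercept)` = 1, Z)
  qr0 <- qr(X0)
  if (qr0$rank < ncol(X0)) {
    dep <- colnames(X0)[qr0$pivot[-seq_len(qr0$rank)]]
    stop("degenerate design: collinear column(s) ", paste(dep, collapse = ", "))
  }
  Q <- qr.Q(qr0)
  if (is.null(tau_grid)) tau_grid <- .default_tau_grid(cap, tau_step)
  if (is.null(scale_bounds)) scale_bounds <- .default_scale_bounds(cap, tau_step)
  stopifnot(length(scale_bounds) == 2L, scale_bounds[1] > 0,
            scale_bounds[2] > scale_bounds[1])
  scale_grid <- exp(seq(log(scale_bounds[1]), log(scale_bounds[2]),
                        length.out = n_scale))
  nt <- length(tau_grid); ns <- length(scale_grid)
  # ramp columns, tau varying fastest
  S <- matrix(0, n, nt * ns)
  k <- 0L
  for (j in seq_len(ns)) {
    for (i in seq_len(nt)) {
      k <- k + 1L
      S[, k] <- half_logistic_ramp(cap, tau_grid[i], scale_grid[j])
    }
  }
  RS <- S - Q %*% crossprod(Q, S)
  den <- colSums(RS * RS)
  list(cap = cap, Z = Z, X0 = X0, qr0 = qr0, Q = Q,
       tau_grid = tau_grid, scale_grid = scale_grid,
       nt = nt, ns = ns, RS = RS, den = den,
       scale_bounds = scale_bounds, refine_tol = refine_tol,
       qr_lin = qr(cbind(X0, cap = cap)))
}

# Constrained (delta >= 0) profiled RSS for one (tau, scale) and a
# pre-residualised response r_y with squared norm ryy.
.rss_at <- function(engine, r_y, ryy, tau, scale) {
  s <- half_logistic_ramp(engine$cap, tau, scale)
  rs <- s - engine$Q %*% crossprod(engine$Q, s)
  den <- sum(rs * rs)
  num <- sum(rs * r_y)
  if (den < 1e-12 || num >= 0) ryy else ryy - num * num / den
}

# Fit the sigmoid stage for one response vector: coarse (tau x scale) grid via
# one matrix-vector product, then a continuous golden-section refinement of
# the transition width at the leading changepoint candidates.  Refining
# several candidates (not just the coarse winner) keeps the grid coarseness
# from flipping the selected changepoint between near-tied neighbours.
engine_fit <- function(engine, y, refine = TRUE, refine_top = 8L) {
  Q <- engine$Q
  r_y <- y - Q %*% crossprod(Q, y)
  ryy <- sum(r_y * r_y)
  num <- as.numeric(crossprod(engine$RS, r_y))
  gain <- ifelse(engine$den > 1e-12 & num < 0, num * num / engine$den, 0)
  gm <- matrix(gain, engine$nt, engine$ns)       # tau x scale
  prof_gain <- apply(gm, 1L, max)                # profile over scale per tau
  profile_rss <- ryy - prof_gain
  best_gain <- max(prof_gain)
  tol_tie <- 1e-12 * max(ryy, 1)
  if (refine && best_gain > 0) {
    cand <- order(profile_rss)[seq_len(min(refine_top, engine$nt))]
    for (ci in cand) {
      tau_c <- engine$tau_grid[ci]
      si <- which.max(gm[ci, ])
      lo <- engine$scale_grid[max(1L, si - 1L)]
      hi <- engine$scale_grid[min(engine$ns, si + 1L)]
      if (hi > lo) {
        opt <- stats::optimize(
          function(ls) .rss_at(engine, r_y, ryy, tau_c, exp(ls)),
          interval = c(log(lo), log(hi)), tol = engine$refine_tol)
        if (opt$objective < profile_rss[ci]) {
          profile_rss[ci] <- opt$objective
          attr(profile_rss, paste0("s", ci)) <- exp(opt$minimum)
        }
      }
    }
  }
  # ties on RSS broken by the smallest changepoint
  ti <- which(profile_rss <= min(profile_rss) + tol_tie)
  ti <- ti[which.min(engine$tau_grid[ti])]
  tau <- engine$tau_grid[ti]
  scale <- attr(profile_rss, paste0("s", ti))
  if (is.null(scale)) scale <- engine$scale_grid[which.max(gm[ti, ])]
  profile_rss <- pmax(profile_rss, 0)   # guard against rounding at perfect fits
  rss <- profile_rss[ti]
  # full coefficients at the selected (tau, scale)
  s <- half_logistic_ramp(engine$cap, tau, scale)
  X <- cbind(engine$X0, ramp = s)
  fit <- stats::lm.fit(X, y)
  cf <- fit$coefficients
  delta <- -cf[["ramp"]]
  if (!is.finite(delta) || delta < 0 || best_gain <= 0) {
    fit <- stats::lm.fit(engine$X0, y)
    cf <- c(fit$coefficients, ramp = 0)
    delta <- 0
    rss <- sum(fit$residuals^2)
    profile_rss[ti] <- min(profile_rss[ti], rss)
  }
  nt <- engine$nt
  list(v0 = cf[["(Intercept)"]],
       delta = delta, tau = tau, scale = scale,
       beta = cf[setdiff(names(cf), c("(Intercept)", "ramp"))],
       rss = rss,
       fitted = y - fit$residuals,
       residuals = fit$residuals,
       converged = !(ti == 1L || ti == nt),
       profile = data.frame(tau = engine$tau_grid, rss = as.numeric(profile_rss)))
}

# Ordinary least squares on the same covariates, with / without the CAP slope.
engine_linear <- function(engine, y) {
  r <- qr.resid(engine$qr_lin, y)
  cf <- qr.coef(engine$qr_lin, y)
  list(coefficients = cf, rss = sum(r * r), residuals = r, fitted = y - r)
}

engine_constant <- function(engine, y) {
  r <- qr.resid(engine$qr0, y)
  cf <- qr.coef(engine$qr0, y)
  list(coefficients = cf, rss = sum(r * r), residuals = r, fitted = y - r)
}

.gauss_ll <- function(rss, n) {
  rss <- max(rss, .Machine$double.xmin)   # perfect fits: finite log-likelihood
  -n / 2 * (log(2 * pi) + log(rss / n) + 1)
}

.aic_bic <- function(rss, n, p) {
  ll <- .gauss_ll(rss, n)
  c(aic = -2 * ll + 2 * (p + 1), bic = -2 * ll + log(n) * (p + 1))
}
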