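# Independent oracles and fixture generators used across the suite.
# Everything here is written against the model definitions directly and
# deliberately avoids the package's solver/posterior code paths.

# random interior parameter tuples with separation margins on the class
# prevalences and on both conditional contrasts
draw_generators <- function(n, seed, margin = 0.05, box = c(0.05, 0.95)) {
  withr::with_seed(seed, {
    out <- vector("list", n)
    i <- 0L
    while (i < n) {
      x <- stats::runif(6, box[1], box[2])
      # order: delta, phi0, phi1, lambda0, lambda1, delta_prime
      if (abs(x[1] - x[6]) >= margin && abs(x[3] - x[2]) >= margin &&
          abs(x[5] - x[4]) >= margin) {
        i <- i + 1L
        out[[i]] <- x
      }
    }
    out
  })
}

freqs_from <- function(gen) {
  p <- lca_params(gen[1], gen[2], gen[3], gen[4], gen[5])
  list(pre = lcident:::exact_frequencies(cell_probabilities(p), "pre"),
       post = lcident:::exact_frequencies(cell_probabilities(p, gen[6]),
                                          "post"),
       params = p, delta_prime = gen[6])
}

# Closed-form method-of-moments solution of the six-equation system,
# derived from first and mixed moments: the difference of the pre/post
# F- and L-marginals is (delta' - delta) times the conditional contrast,
# and the covariances are delta(1-delta) resp. delta'(1-delta') times the
# product of the contrasts. Returns the branch with delta' < delta, or NULL
# in degenerate configurations.
closed_form_solution <- function(freq_pre, freq_post) {
  r <- freq_pre$r; rp <- freq_post$r
  mF <- r[["r10"]] + r[["r11"]]; mL <- r[["r01"]] + r[["r11"]]
  mFp <- rp[["r10"]] + rp[["r11"]]; mLp <- rp[["r01"]] + rp[["r11"]]
  dF <- mFp - mF; dL <- mLp - mL
  if (abs(dF) < 1e-10 || abs(dL) < 1e-10) return(NULL)
  c1 <- (r[["r11"]] - mF * mL) / (dF * dL)
  c2 <- (rp[["r11"]] - mFp * mLp) / (dF * dL)
  k <- 1 + c2 - c1
  disc <- 4 * c1 + k^2
  if (disc <= 0) return(NULL)
  for (u in c(-1, 1) / sqrt(disc)) {
    delta <- (1 - k * u) / 2
    delta_p <- delta + u
    a <- dF / u; b <- dL / u
    phi0 <- mF - delta * a; phi1 <- phi0 + a
    lam0 <- mL - delta * b; lam1 <- lam0 + b
    sol <- c(delta, phi0, phi1, lam0, lam1, delta_p)
    if (all(sol >= -1e-9 & sol <= 1 + 1e-9) && delta_p < delta) {
      return(pmin(pmax(sol, 0), 1))
    }
  }
  NULL
}

# Exact parameterisation of the observational solution family by
# (phi0, phi1): delta follows from the F-marginal and the lambdas from the
# two remaining linear equations.
manifold_point_from_phis <- function(freq_pre, phi0, phi1) {
  r <- freq_pre$r
  mF <- r[["r10"]] + r[["r11"]]; mL <- r[["r01"]] + r[["r11"]]
  if (abs(phi1 - phi0) < 1e-10) return(NULL)
  delta <- (mF - phi0) / (phi1 - phi0)
  if (delta <= 0 || delta >= 1) return(NULL)
  # delta*lam1 + (1-delta)*lam0 = mL ; delta*phi1*lam1 + (1-delta)*phi0*lam0 = r11
  A <- rbind(c(1 - delta, delta), c((1 - delta) * phi0, delta * phi1))
  sol <- tryCatch(solve(A, c(mL, r[["r11"]])), error = function(e) NULL)
  if (is.null(sol) || any(sol < 0 | sol > 1)) return(NULL)
  c(delta, phi0, phi1, sol[1], sol[2])
}

# Brute-force grid posterior by direct summation over the full tensor grid
# (observational: 5 axes; with post counts: 6 axes, optionally truncated to
# delta' < delta). Same midpoint grid convention as the package.
brute_force_posterior <- function(prior, counts_pre, counts_post = NULL,
                                  n_grid = 7L, direction = "unconstrained") {
  m <- (seq_len(n_grid) - 0.5) / n_grid
  axes <- list(delta = m, phi0 = m, phi1 = m, lambda0 = m, lambda1 = m)
  if (!is.null(counts_post)) axes$delta_prime <- m
  grid <- do.call(expand.grid, axes)
  sh <- prior$shapes
  w <- stats::dbeta(grid$delta, sh$delta[1], sh$delta[2]) *
    stats::dbeta(grid$phi0, sh$phi0[1], sh$phi0[2]) *
    stats::dbeta(grid$phi1, sh$phi1[1], sh$phi1[2]) *
    stats::dbeta(grid$lambda0, sh$lambda0[1], sh$lambda0[2]) *
    stats::dbeta(grid$lambda1, sh$lambda1[1], sh$lambda1[2])
  if (!is.null(counts_post))
    w <- w * stats::dbeta(grid$delta_prime, sh$delta_prime[1],
                          sh$delta_prime[2])
  loglik <- function(prev, n) {
    t00 <- prev * (1 - grid$phi1) * (1 - grid$lambda1) +
      (1 - prev) * (1 - grid$phi0) * (1 - grid$lambda0)
    t01 <- prev * (1 - grid$phi1) * grid$lambda1 +
      (1 - prev) * (1 - grid$phi0) * grid$lambda0
    t10 <- prev * grid$phi1 * (1 - grid$lambda1) +
      (1 - prev) * grid$phi0 * (1 - grid$lambda0)
    t11 <- prev * grid$phi1 * grid$lambda1 +
      (1 - prev) * grid$phi0 * grid$lambda0
    n[1] * log(t00) + n[2] * log(t01) + n[3] * log(t10) + n[4] * log(t11)
  }
  ll <- loglik(grid$delta, counts_pre)
  if (!is.null(counts_post))
    ll <- ll + loglik(grid$delta_prime, counts_post)
  if (direction == "reduced") w[grid$delta_prime >= grid$delta] <- 0
  if (direction == "increased") w[grid$delta_prime <= grid$delta] <- 0
  wt <- w * exp(ll - max(ll))
  wt <- wt / sum(wt)
  vapply(names(axes), function(nm) sum(wt * grid[[nm]]), numeric(1))
}

# standard worked-example generator used throughout the suite
std_gen <- function() lca_params(0.6, 0.2, 0.7, 0.1, 0.8)
std_regime <- function() intervention_regime(0.3, "reduced")
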