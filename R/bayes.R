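#' Independent Beta prior over the model parameters
#'
#' Specifies an independent Beta(a, b) prior for each chance parameter of the
#' latent class model (and for the post-intervention prevalence delta' when
#' intervention data are analysed). The default is uniform Beta(1, 1) on
#' every component.
#'
#' @param delta,phi0,phi1,lambda0,lambda1,delta_prime length-2 positive
#'   shape vectors `c(a, b)`.
#' @return A `prior_spec` of type `"beta"`.
#' @export
beta_prior <- function(delta = c(1, 1), phi0 = c(1, 1), phi1 = c(1, 1),
                       lambda0 = c(1, 1), lambda1 = c(1, 1),
                       delta_prime = c(1, 1)) {
  shapes <- list(delta = delta, phi0 = phi0, phi1 = phi1,
                 lambda0 = lambda0, lambda1 = lambda1,
                 delta_prime = delta_prime)
  for (nm in names(shapes)) {
    s <- shapes[[nm]]
    if (length(s) != 2L || any(!is.finite(s)) || any(s <= 0))
      stop(sprintf("'%s' must be two strictly positive Beta shapes", nm),
           call. = FALSE)
  }
  structure(list(type = "beta", shapes = shapes), class = "prior_spec")
}

#' Point-mass prior
#'
#' @param params an [lca_params] object carrying the point.
#' @param delta_prime optional point value for the post-intervention
#'   prevalence.
#' @return A `prior_spec` of type `"point"`.
#' @export
point_prior <- function(params, delta_prime = NULL) {
  stopifnot(inherits(params, "lca_params"))
  if (!is.null(delta_prime)) .check_prob(delta_prime, "delta_prime")
  structure(list(type = "point", params = params, delta_prime = delta_prime),
            class = "prior_spec")
}

#' A rho-indexed family of priors
#'
#' A finite family of [beta_prior()] specifications indexed by a
#' hyperparameter rho, with a prior weight on each member. Used by
#' [estimate_hyperprior()] to estimate which prior best suits the data once
#' a delta'-delta coupling restores identifiability.
#'
#' @param rho numeric index values (one per member).
#' @param priors list of `prior_spec` objects of type `"beta"`.
#' @param weights prior weights over rho; default uniform. Normalised to
#'   sum to 1.
#' @return A `prior_family`.
#' @export
prior_family <- function(rho, priors, weights = NULL) {
  if (length(rho) != length(priors))
    stop("'rho' and 'priors' must have the same length", call. = FALSE)
  if (!all(vapply(priors, function(p)
    inherits(p, "prior_spec") && p$type == "beta", logical(1))))
    stop("every family member must be a Beta 'prior_spec'", call. = FALSE)
  if (is.null(weights)) weights <- rep(1 / length(rho), length(rho))
  if (length(weights) != length(rho) || any(weights < 0) || sum(weights) <= 0)
    stop("'weights' must be non-negative with positive sum", call. = FALSE)
  structure(list(rho = rho, priors = priors,
                 weights = weights / sum(weights)),
            class = "prior_family")
}

# counts for posterior updates: a zero total is allowed (prior recovery)
.check_counts_bayes <- function(counts) {
  if (length(counts) != 4L || any(!is.finite(counts)) || any(counts < 0))
    stop("'counts' must be four finite non-negative numbers (order 00, 01, 10, 11)",
         call. = FALSE)
  as.numeric(counts)
}

# midpoint grid (avoids boundary cells and improper prior endpoints)
.mid_grid <- function(n_grid) (seq_len(n_grid) - 0.5) / n_grid

# coordinates of the (phi0, phi1, lambda0, lambda1) tensor grid, flattened
.rest_grid <- function(n_grid) {
  m <- .mid_grid(n_grid)
  list(
    f0 = rep(m, times = n_grid^3),
    f1 = rep(rep(m, each = n_grid), times = n_grid^2),
    l0 = rep(rep(m, each = n_grid^2), times = n_grid),
    l1 = rep(m, each = n_grid^3)
  )
}

.axis_weights <- function(n_grid, shapes) {
  m <- .mid_grid(n_grid)
  w <- stats::dbeta(m, shapes[1], shapes[2])
  w / sum(w)
}

# multinomial log-likelihood matrix: rows = prevalence grid values, columns
# = flattened conditional-probability grid. Midpoint grids keep every cell
# probability strictly positive, so no -Inf handling is needed here.
.loglik_matrix <- function(prev_values, rest, counts) {
  out <- matrix(NA_real_, length(prev_values), length(rest$f0))
  for (i in seq_along(prev_values)) {
    cl <- .cells_list(prev_values[i], rest$f0, rest$f1, rest$l0, rest$l1)
    out[i, ] <- counts[1] * log(cl$t00) + counts[2] * log(cl$t01) +
      counts[3] * log(cl$t10) + counts[4] * log(cl$t11)
  }
  out
}

#' Grid posterior over the latent class parameters
#'
#' Computes the posterior distribution of the model parameters on a midpoint
#' tensor grid (5 axes for observational data; 6 including delta' when
#' post-intervention counts are supplied), under independent Beta priors and
#' multinomial likelihoods of the observed cell counts, and returns the
#' posterior expectation of every parameter. Because the pre- and
#' post-regime likelihoods each involve only their own prevalence axis, the
#' sums over delta and delta' factorise and the 6-dimensional grid never has
#' to be materialised.
#'
#' With observational data alone the model is unidentifiable and the
#' expectations retain a dependence on the prior that no amount of data
#' removes; with intervention data the posterior concentrates and the prior
#' washes out. The optional `direction` argument encodes the qualitative
#' assumption about the intervention (e.g. `"reduced"`: delta' < delta),
#' which breaks the label-swap symmetry; without it the posterior is bimodal
#' across the two mirror branches.
#'
#' @param prior a `prior_spec` ([beta_prior()] or [point_prior()]).
#' @param counts_pre four observational cell counts, order (00, 01, 10, 11).
#' @param counts_post optional four post-intervention cell counts.
#' @param n_grid grid points per axis (default 21).
#' @param direction `"unconstrained"` (default), `"reduced"` (restrict to
#'   delta' < delta) or `"increased"`; only meaningful with `counts_post`.
#' @return A `posterior_summary`: list with `expectations` (named vector),
#'   `n_grid`, `log_evidence` (log marginal likelihood of the counts under
#'   the discretised prior, multinomial coefficient omitted).
#' @export
posterior_over_parameters <- function(prior, counts_pre, counts_post = NULL,
                                      n_grid = 21L,
                                      direction = c("unconstrained",
                                                    "reduced", "increased")) {
  direction <- match.arg(direction)
  counts_pre <- .check_counts_bayes(counts_pre)
  if (!is.null(counts_post)) counts_post <- .check_counts_bayes(counts_post)
  stopifnot(inherits(prior, "prior_spec"))

  if (prior$type == "point") {
    ll <- if (sum(counts_pre) > 0) log_likelihood(prior$params, counts_pre)
    else 0
    if (!is.null(counts_post)) {
      if (is.null(prior$delta_prime))
        stop("point prior must carry 'delta_prime' when post counts are supplied",
             call. = FALSE)
      if (sum(counts_post) > 0)
        ll <- ll + log_likelihood(prior$params, counts_post,
                                  prevalence = prior$delta_prime)
    }
    if (!is.finite(ll))
      stop("prior mass lies entirely on a zero-likelihood point", call. = FALSE)
    e <- c(.par_vec(prior$params),
           if (!is.null(counts_post)) prior$delta_prime)
    names(e) <- c("delta", "phi0", "phi1", "lambda0", "lambda1",
                  if (!is.null(counts_post)) "delta_prime")
    return(structure(list(expectations = e, n_grid = NA_integer_,
                          log_evidence = ll), class = "posterior_summary"))
  }

  m <- .mid_grid(n_grid)
  rest <- .rest_grid(n_grid)
  sh <- prior$shapes
  w_d <- .axis_weights(n_grid, sh$delta)
  w_rest <- .axis_weights(n_grid, sh$phi0)[
    rep(seq_len(n_grid), times = n_grid^3)] *
    .axis_weights(n_grid, sh$phi1)[
      rep(rep(seq_len(n_grid), each = n_grid), times = n_grid^2)] *
    .axis_weights(n_grid, sh$lambda0)[
      rep(rep(seq_len(n_grid), each = n_grid^2), times = n_grid)] *
    .axis_weights(n_grid, sh$lambda1)[rep(seq_len(n_grid), each = n_grid^3)]

  logA <- .loglik_matrix(m, rest, counts_pre)
  MA <- max(logA)
  S <- exp(logA - MA)

  if (is.null(counts_post)) {
    a <- drop(crossprod(S, w_d))              # sum_i w_d S[i, ]
    ad <- drop(crossprod(S, w_d * m))
    Z <- sum(w_rest * a)
    if (Z <= 0) stop("posterior mass vanished on the grid", call. = FALSE)
    e <- c(delta = sum(w_rest * ad) / Z,
           phi0 = sum(w_rest * rest$f0 * a) / Z,
           phi1 = sum(w_rest * rest$f1 * a) / Z,
           lambda0 = sum(w_rest * rest$l0 * a) / Z,
           lambda1 = sum(w_rest * rest$l1 * a) / Z)
    return(structure(list(expectations = e, n_grid = n_grid,
                          log_evidence = MA + log(Z)),
                     class = "posterior_summary"))
  }

  w_dp <- .axis_weights(n_grid, sh$delta_prime)
  logB <- .loglik_matrix(m, rest, counts_post)
  MB <- max(logB)
  Tm <- exp(logB - MB)

  if (direction == "unconstrained") {
    a <- drop(crossprod(S, w_d))
    ad <- drop(crossprod(S, w_d * m))
    b <- drop(crossprod(Tm, w_dp))
    bd <- drop(crossprod(Tm, w_dp * m))
    Z <- sum(w_rest * a * b)
    if (Z <= 0) stop("posterior mass vanished on the grid", call. = FALSE)
    e <- c(delta = sum(w_rest * ad * b) / Z,
           phi0 = sum(w_rest * rest$f0 * a * b) / Z,
           phi1 = sum(w_rest * rest$f1 * a * b) / Z,
           lambda0 = sum(w_rest * rest$l0 * a * b) / Z,
           lambda1 = sum(w_rest * rest$l1 * a * b) / Z,
           delta_prime = sum(w_rest * a * bd) / Z)
    return(structure(list(expectations = e, n_grid = n_grid,
                          log_evidence = MA + MB + log(Z)),
                     class = "posterior_summary"))
  }

  # directional truncation: sum over ordered (delta, delta') pairs via a
  # running sum of the post factor along the delta' axis
  if (direction == "increased") {
    ord <- rev(seq_len(n_grid))     # delta' > delta == reversed "reduced"
  } else {
    ord <- seq_len(n_grid)
  }
  Sw <- S[ord, , drop = FALSE] * w_d[ord]
  Tw <- Tm[ord, , drop = FALSE] * w_dp[ord]
  Twd <- Tm[ord, , drop = FALSE] * (w_dp * m)[ord]
  npt <- ncol(S)
  a <- numeric(npt); ad <- numeric(npt); adp <- numeric(npt)
  runT <- numeric(npt); runTd <- numeric(npt)
  for (i in seq_len(n_grid)) {
    # runT holds sum over strictly preceding delta' values
    a <- a + Sw[i, ] * runT
    ad <- ad + (m[ord])[i] * Sw[i, ] * runT
    adp <- adp + Sw[i, ] * runTd
    runT <- runT + Tw[i, ]
    runTd <- runTd + Twd[i, ]
  }
  Z <- sum(w_rest * a)
  if (Z <= 0)
    stop("posterior mass vanished on the grid under the direction constraint",
         call. = FALSE)
  e <- c(delta = sum(w_rest * ad) / Z,
         phi0 = sum(w_rest * rest$f0 * a) / Z,
         phi1 = sum(w_rest * rest$f1 * a) / Z,
         lambda0 = sum(w_rest * rest$l0 * a) / Z,
         lambda1 = sum(w_rest * rest$l1 * a) / Z,
         delta_prime = sum(w_rest * adp) / Z)
  structure(list(expectations = e, n_grid = n_grid,
                 log_evidence = MA + MB + log(Z)),
            class = "posterior_summary")
}

#' @export
print.posterior_summary <- function(x, digits = 4, ...) {
  cat("Posterior expectations (grid posterior):\n")
  print(round(x$expectations, digits))
  cat(sprintf("  grid: %s points/axis; log evidence: %.4f\n",
              ifelse(is.na(x$n_grid), "point prior", x$n_grid),
              x$log_evidence))
  invisible(x)
}

#' Prior sensitivity of the posterior expectations
#'
#' Computes the posterior expectations under each supplied prior and returns,
#' per parameter, the maximum absolute pairwise difference. With
#' observational data only, the unidentified directions keep this spread
#' bounded away from zero however large the sample; with intervention data
#' the spread collapses.
#'
#' @param priors a list of at least two `prior_spec` objects.
#' @param counts_pre,counts_post cell counts as in
#'   [posterior_over_parameters()].
#' @param ... further arguments (`n_grid`, `direction`) passed on.
#' @return Named numeric vector of per-parameter spreads.
#' @export
prior_sensitivity <- function(priors, counts_pre, counts_post = NULL, ...) {
  if (length(priors) < 2L)
    stop("need at least two priors to measure sensitivity", call. = FALSE)
  posts <- lapply(priors, posterior_over_parameters, counts_pre = counts_pre,
                  counts_post = counts_post, ...)
  E <- do.call(rbind, lapply(posts, `[[`, "expectations"))
  apply(E, 2, function(col) max(col) - min(col))
}

#' Estimate the prior hyperparameter rho from intervention data
#'
#' Realises the bookkeeping by which intervention data can select a prior:
#' indexing the prior by a hyperparameter rho adds one dimension, and a
#' known coupling of the post-intervention prevalence to the observational
#' one (delta' fixed, or delta' = f(delta)) removes one, so all parameters
#' including rho become estimable. The joint posterior over (parameters,
#' rho) is computed on the 5-axis grid with delta' eliminated through the
#' coupling; the marginal posterior over rho and the model-averaged
#' parameter expectations are returned.
#'
#' Only deterministic couplings are supported; a stochastic relation between
#' the two prevalences is beyond this implementation.
#'
#' @param family a [prior_family()].
#' @param counts_pre,counts_post cell counts of the two regimes (both
#'   required).
#' @param coupling either a fixed numeric delta' or a function
#'   `function(delta)` returning delta'.
#' @param n_grid grid points per axis.
#' @return A list with `rho`, `prior_weights`, `rho_posterior`,
#'   `log_evidence` (per family member) and `summary` (model-averaged
#'   `posterior_summary`).
#' @export
estimate_hyperprior <- function(family, counts_pre, counts_post, coupling,
                                n_grid = 21L) {
  stopifnot(inherits(family, "prior_family"))
  if (missing(counts_post) || is.null(counts_post))
    stop("intervention counts are required: without them rho is not estimable",
         call. = FALSE)
  if (missing(coupling) || is.null(coupling))
    stop("a delta' coupling (fixed value or function of delta) is required",
         call. = FALSE)
  counts_pre <- .check_counts_bayes(counts_pre)
  counts_post <- .check_counts_bayes(counts_post)
  cpl <- if (is.function(coupling)) coupling else function(delta) {
    rep(coupling, length(delta))
  }
  m <- .mid_grid(n_grid)
  dp <- vapply(m, function(d) cpl(d)[1], numeric(1))
  if (any(!is.finite(dp)) || any(dp < 0) || any(dp > 1))
    stop("coupling must map [0, 1] into [0, 1]", call. = FALSE)
  rest <- .rest_grid(n_grid)
  logL <- .loglik_matrix(m, rest, counts_pre) +
    .loglik_matrix(dp, rest, counts_post)
  ML <- max(logL)
  S <- exp(logL - ML)

  k <- length(family$rho)
  log_ev <- numeric(k)
  E <- matrix(NA_real_, k, 6,
              dimnames = list(NULL, c("delta", "phi0", "phi1", "lambda0",
                                      "lambda1", "delta_prime")))
  for (r in seq_len(k)) {
    sh <- family$priors[[r]]$shapes
    w_d <- .axis_weights(n_grid, sh$delta)
    w_rest <- .axis_weights(n_grid, sh$phi0)[
      rep(seq_len(n_grid), times = n_grid^3)] *
      .axis_weights(n_grid, sh$phi1)[
        rep(rep(seq_len(n_grid), each = n_grid), times = n_grid^2)] *
      .axis_weights(n_grid, sh$lambda0)[
        rep(rep(seq_len(n_grid), each = n_grid^2), times = n_grid)] *
      .axis_weights(n_grid, sh$lambda1)[rep(seq_len(n_grid), each = n_grid^3)]
    a <- drop(crossprod(S, w_d))
    ad <- drop(crossprod(S, w_d * m))
    adp <- drop(crossprod(S, w_d * dp))
    Z <- sum(w_rest * a)
    log_ev[r] <- ML + log(Z)
    E[r, ] <- c(sum(w_rest * ad), sum(w_rest * rest$f0 * a),
                sum(w_rest * rest$f1 * a), sum(w_rest * rest$l0 * a),
                sum(w_rest * rest$l1 * a), sum(w_rest * adp)) / Z
  }
  lp <- log(family$weights) + log_ev
  lp <- lp - max(lp)
  rho_post <- exp(lp) / sum(exp(lp))
  e_avg <- drop(crossprod(E, rho_post))
  names(e_avg) <- colnames(E)
  list(rho = family$rho, prior_weights = family$weights,
       rho_posterior = rho_post, log_evidence = log_ev,
       summary = structure(list(expectations = e_avg, n_grid = n_grid,
                                log_evidence = max(lp) + log(sum(exp(lp)))),
                           class = "posterior_summary"))
}
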