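#' @title Moment-system identification machinery
#' @description Internal helpers shared by the solvers: residual functions of
#'   the pre/post moment equations, the multistart bound-constrained
#'   least-squares driver, solution clustering, and the dense grid oracle
#'   used to distinguish solver non-convergence from genuine infeasibility.
#' @name identify-internals
#' @keywords internal
NULL

# frequencies as a plain 4-vector in the fixed (00, 01, 10, 11) order
.freq_vec <- function(freq) {
  stopifnot(inherits(freq, "observed_freq"))
  as.numeric(freq$r)
}

# x = (delta, phi0, phi1, lambda0, lambda1): observational residuals.
# A structural zero is appended so the Levenberg-Marquardt backend (which
# needs >= as many residuals as parameters) accepts the 5-parameter system.
.resid_pre <- function(x, r_pre) {
  c(.cells(x[1], x[2], x[3], x[4], x[5]) - r_pre, 0)
}

# x = (delta, phi0, phi1, lambda0, lambda1, delta_prime): stacked residuals
.resid_both <- function(x, r_pre, r_post) {
  c(.cells(x[1], x[2], x[3], x[4], x[5]) - r_pre,
    .cells(x[6], x[2], x[3], x[4], x[5]) - r_post)
}

# Multistart bound-constrained Levenberg-Marquardt over [0,1]^n_par.
# Starts are a Latin hypercube drawn under a fixed internal seed so the
# solver is deterministic. Returns a list of (par, maxres) per start.
.multistart_ls <- function(resid_fn, n_par, n_starts = 32L,
                           extra_starts = NULL, start_seed = 1848941L, ...) {
  starts <- if (n_starts >= 1L) {
    0.02 + 0.96 * withr::with_seed(start_seed, lhs::randomLHS(n_starts, n_par))
  } else {
    matrix(numeric(0), 0L, n_par)
  }
  if (!is.null(extra_starts))
    starts <- rbind(starts, matrix(extra_starts, ncol = n_par, byrow = FALSE))
  ctrl <- minpack.lm::nls.lm.control(maxiter = 400, ftol = 1e-15,
                                     ptol = 1e-15, gtol = 0)
  lapply(seq_len(nrow(starts)), function(i) {
    fit <- minpack.lm::nls.lm(par = starts[i, ], lower = rep(0, n_par),
                              upper = rep(1, n_par), fn = resid_fn,
                              control = ctrl, ...)
    par <- pmin(pmax(fit$par, 0), 1)
    list(par = par, maxres = max(abs(resid_fn(par, ...))))
  })
}

# Merge solutions whose objective ties the best (within keep_slack) into
# clusters of L-infinity radius merge_tol; representatives sorted by residual.
.cluster_solutions <- function(sols, merge_tol = 1e-5, keep_slack = NULL) {
  res <- vapply(sols, `[[`, numeric(1), "maxres")
  fbest <- min(res)
  if (is.null(keep_slack)) keep_slack <- max(fbest * 0.5, 1e-9)
  keep <- sols[res <= fbest + keep_slack]
  keep <- keep[order(vapply(keep, `[[`, numeric(1), "maxres"))]
  reps <- list()
  for (s in keep) {
    hit <- FALSE
    for (r in reps)
      if (max(abs(s$par - r$par)) < merge_tol) { hit <- TRUE; break }
    if (!hit) reps[[length(reps) + 1L]] <- s
  }
  list(fbest = fbest, reps = reps)
}

# Dense grid search for the minimum over [0,1]^(5 or 6) of the max-abs
# moment residual. The conditional-probability axes are enumerated once
# (n_grid^4 points); each prevalence axis is then a cheap affine sweep, so
# the full 6-d grid costs n_grid^2 vector operations of length n_grid^4.
.grid_min_residual <- function(r_pre, r_post = NULL, n_grid = 21L) {
  g <- seq(0, 1, length.out = n_grid)
  n4 <- n_grid^4
  f0 <- rep(g, times = n_grid^3)
  f1 <- rep(rep(g, each = n_grid), times = n_grid^2)
  l0 <- rep(rep(g, each = n_grid^2), times = n_grid)
  l1 <- rep(g, each = n_grid^3)
  A <- .cells_list(1, f0, f1, l0, l1)   # class-1 product cells
  B <- .cells_list(0, f0, f1, l0, l1)   # class-0 product cells
  res_at <- function(prev, r) {
    pmax(abs(prev * A$t00 + (1 - prev) * B$t00 - r[1]),
         abs(prev * A$t01 + (1 - prev) * B$t01 - r[2]),
         abs(prev * A$t10 + (1 - prev) * B$t10 - r[3]),
         abs(prev * A$t11 + (1 - prev) * B$t11 - r[4]))
  }
  if (is.null(r_post)) {
    best <- Inf; arg <- NULL
    for (i in seq_len(n_grid)) {
      ri <- res_at(g[i], r_pre)
      k <- which.min(ri)
      if (ri[k] < best) {
        best <- ri[k]
        arg <- c(delta = g[i], phi0 = f0[k], phi1 = f1[k],
                 lambda0 = l0[k], lambda1 = l1[k])
      }
    }
    return(list(min_residual = best, argmin = arg))
  }
  pre_res <- matrix(NA_real_, n_grid, n4)
  post_res <- matrix(NA_real_, n_grid, n4)
  for (i in seq_len(n_grid)) {
    pre_res[i, ] <- res_at(g[i], r_pre)
    post_res[i, ] <- res_at(g[i], r_post)
  }
  best <- Inf; arg <- NULL
  for (i in seq_len(n_grid)) for (j in seq_len(n_grid)) {
    rij <- pmax(pre_res[i, ], post_res[j, ])
    k <- which.min(rij)
    if (rij[k] < best) {
      best <- rij[k]
      arg <- c(delta = g[i], phi0 = f0[k], phi1 = f1[k],
               lambda0 = l0[k], lambda1 = l1[k], delta_prime = g[j])
    }
  }
  list(min_residual = best, argmin = arg)
}

# numeric Jacobian of the 3 independent cells (01, 10, 11) per regime
.constraint_jacobian <- function(par_vec, with_post = FALSE) {
  f <- if (with_post) {
    function(x) c(.cells(x[1], x[2], x[3], x[4], x[5])[2:4],
                  .cells(x[6], x[2], x[3], x[4], x[5])[2:4])
  } else {
    function(x) .cells(x[1], x[2], x[3], x[4], x[5])[2:4]
  }
  pracma::jacobian(f, par_vec)
}

.swap6 <- function(x) c(1 - x[1], x[3], x[2], x[5], x[4], 1 - x[6])

.is_interior <- function(x, margin = 1e-3) all(x > margin & x < 1 - margin)

#' Solve the combined pre/post-intervention moment equations
#'
#' Recovers the six model parameters (delta, phi0, phi1, lambda0, lambda1,
#' delta') from the observed cell frequencies of the observational regime and
#' of the regime after a stochastic intervention on the latent class. The
#' system equates the model cell probabilities at prevalence delta with the
#' pre-intervention frequencies and those at delta' with the
#' post-intervention frequencies (six independent equations for six
#' unknowns). Away from degenerate configurations the solution is unique up
#' to the latent label swap, so solutions come in mirror-image pairs; the
#' qualitative `direction` assumption (e.g. the treatment reduces the latent
#' prevalence, delta' < delta) selects the canonical branch.
#'
#' The solver is a multistart bound-constrained Levenberg-Marquardt
#' least-squares on the stacked residuals (Latin hypercube starts), followed
#' by clustering of the tied minima. With finite-sample frequencies the
#' equations are solved in the least-squares sense and the attained residual
#' is reported. A coarse dense-grid search over the parameter box backs up
#' the infeasibility decision, so solver non-convergence is not mistaken for
#' genuine overdetermination.
#'
#' @param freq_pre an [observed_frequencies()] record with regime `"pre"`.
#' @param freq_post an [observed_frequencies()] record with regime `"post"`.
#' @param direction qualitative knowledge about the intervention:
#'   `"reduced"` (delta' < delta, canonical branch listed first),
#'   `"increased"`, or `"unconstrained"` (pair returned unordered, with a
#'   warning).
#' @param n_starts number of multistart Latin hypercube starts (>= 32
#'   recommended).
#' @param feas_tol max-abs cell residual above which the input is considered
#'   incompatible with the model (after grid confirmation).
#' @param merge_tol L-infinity radius for merging equivalent solutions.
#' @param degen_tol recovered `|delta - delta'|` below this flags the
#'   degenerate (unidentified) regime.
#' @param sv_tol smallest-singular-value threshold of the 6 x 6 constraint
#'   Jacobian below which the solution family is flagged degenerate.
#' @param grid_n resolution per axis of the fallback grid oracle.
#' @return A `solution_set`: list with `status` (one of `"identified_pair"`,
#'   `"degenerate_infinite"`, `"infeasible"`, `"boundary"`), `branches` (for
#'   an identified pair, exactly two, each a list with `params`
#'   ([lca_params]) and `delta_prime`), `residual` (max-abs moment violation
#'   at the best branch) and `direction`.
#' @examples
#' gen <- lca_params(0.6, 0.2, 0.7, 0.1, 0.8)
#' pre <- lcident:::exact_frequencies(cell_probabilities(gen), "pre")
#' post <- lcident:::exact_frequencies(cell_probabilities(gen, 0.3), "post")
#' fit <- solve_moment_system(pre, post, direction = "reduced")
#' fit$status
#' fit$branches[[1]]$params
#' @export
solve_moment_system <- function(freq_pre, freq_post,
                                direction = c("reduced", "increased",
                                              "unconstrained"),
                                n_starts = 32L, feas_tol = 0.01,
                                merge_tol = 1e-5, degen_tol = 1e-3,
                                sv_tol = 1e-8, grid_n = 11L) {
  direction <- match.arg(direction)
  r_pre <- .freq_vec(freq_pre)
  r_post <- .freq_vec(freq_post)
  if (freq_pre$regime != "pre" || freq_post$regime != "post")
    stop("freq_pre must carry regime 'pre' and freq_post regime 'post'",
         call. = FALSE)

  sols <- .multistart_ls(.resid_both, 6L, n_starts,
                         r_pre = r_pre, r_post = r_post)
  cl <- .cluster_solutions(sols, merge_tol)

  if (cl$fbest > feas_tol) {
    # fell short everywhere: consult the grid oracle before declaring
    # the input overdetermined
    grid <- .grid_min_residual(r_pre, r_post, n_grid = grid_n)
    retry <- .multistart_ls(.resid_both, 6L, n_starts = 0L,
                            extra_starts = matrix(grid$argmin, nrow = 1),
                            r_pre = r_pre, r_post = r_post)
    cl2 <- .cluster_solutions(c(sols, retry), merge_tol)
    if (cl2$fbest > feas_tol) {
      return(structure(list(status = "infeasible", branches = list(),
                            residual = cl2$fbest, direction = direction,
                            grid_min_residual = grid$min_residual),
                       class = "solution_set"))
    }
    cl <- cl2
  }

  best <- cl$reps[[1]]$par

  # degeneracy: collapsed intervention or rank-deficient constraint system
  J <- .constraint_jacobian(best, with_post = TRUE)
  sv <- svd(J)$d
  degenerate <- abs(best[1] - best[6]) < degen_tol || min(sv) < sv_tol
  if (degenerate) {
    branches <- lapply(cl$reps, function(s)
      list(params = .vec_par(s$par[1:5]), delta_prime = s$par[6]))
    return(structure(list(status = "degenerate_infinite", branches = branches,
                          residual = cl$reps[[1]]$maxres,
                          direction = direction),
                     class = "solution_set"))
  }

  if (!.is_interior(best, margin = 1e-6)) {
    branches <- lapply(cl$reps, function(s)
      list(params = .vec_par(s$par[1:5]), delta_prime = s$par[6]))
    return(structure(list(status = "boundary", branches = branches,
                          residual = cl$reps[[1]]$maxres,
                          direction = direction),
                     class = "solution_set"))
  }

  # identified pair: the mirror image always solves the same system, so
  # complete the pair by the label swap even if multistart found only one
  mirror <- .swap6(best)
  pair <- list(best, mirror)
  if (direction == "reduced") {
    pair <- pair[order(vapply(pair, function(x) x[6] < x[1], logical(1)),
                       decreasing = TRUE)]
  } else if (direction == "increased") {
    pair <- pair[order(vapply(pair, function(x) x[6] > x[1], logical(1)),
                       decreasing = TRUE)]
  } else {
    warning("direction = 'unconstrained': the two mirror branches are ",
            "returned in no particular order", call. = FALSE)
  }
  branches <- lapply(pair, function(x)
    list(params = .vec_par(x[1:5]), delta_prime = x[6]))
  structure(list(status = "identified_pair", branches = branches,
                 residual = cl$reps[[1]]$maxres, direction = direction),
            class = "solution_set")
}

#' @export
print.solution_set <- function(x, ...) {
  cat(sprintf("Moment-system solution set: status = %s, residual = %.3g\n",
              x$status, x$residual))
  for (i in seq_along(x$branches)) {
    b <- x$branches[[i]]
    cat(sprintf("  branch %d: delta = %.6g, phi = (%.6g, %.6g), ",
                i, b$params$delta, b$params$phi0, b$params$phi1))
    cat(sprintf("lambda = (%.6g, %.6g), delta' = %.6g\n",
                b$params$lambda0, b$params$lambda1, b$delta_prime))
  }
  invisible(x)
}

#' Traverse the observational solution manifold
#'
#' With observational data alone the moment equations (three independent
#' cell frequencies for five parameters) leave a two-dimensional family of
#' parameter tuples that all reproduce the observed table exactly. This
#' function returns `n_points` distinct members of that family by
#' predictor-corrector continuation: from a feasible point it steps in the
#' 2-D null space of the constraint Jacobian and corrects back onto the
#' manifold by bound-constrained least squares, falling back to rejection
#' sampling when a step cannot be corrected.
#'
#' @param freq_pre an [observed_frequencies()] record, regime `"pre"`.
#' @param n_points number of distinct solutions requested.
#' @param seed integer seed controlling the traversal.
#' @param tol max-abs residual each returned point must satisfy.
#' @param step_size predictor step length in parameter space.
#' @return A list of [lca_params], each reproducing the input frequencies
#'   within `tol`.
#' @export
solution_manifold <- function(freq_pre, n_points, seed, tol = 1e-8,
                              step_size = 0.15) {
  r_pre <- .freq_vec(freq_pre)
  sols <- .multistart_ls(.resid_pre, 5L, 32L, r_pre = r_pre)
  cl <- .cluster_solutions(sols, merge_tol = 1e-5)
  if (cl$fbest > 1e-6)
    stop(structure(class = c("lcident_infeasible", "error", "condition"),
                   list(message = sprintf(
                     "frequencies are not attainable by the model (best residual %.3g)",
                     cl$fbest), call = NULL)))
  ctrl <- minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-15, ptol = 1e-15)
  correct <- function(x0) {
    fit <- minpack.lm::nls.lm(par = x0, lower = rep(0, 5), upper = rep(1, 5),
                              fn = .resid_pre, r_pre = r_pre, control = ctrl)
    pmin(pmax(fit$par, 0), 1)
  }
  withr::with_seed(.substream_seed(seed, 7L), {
    pts <- list(cl$reps[[1]]$par)
    cur <- pts[[1]]
    fails <- 0L
    while (length(pts) < n_points) {
      cand <- NULL
      if (fails < 5L) {
        J <- .constraint_jacobian(cur, with_post = FALSE)
        N <- pracma::nullspace(J)
        if (!is.null(N) && ncol(N) >= 1) {
          dir <- N %*% stats::rnorm(ncol(N))
          dir <- dir / max(sqrt(sum(dir^2)), 1e-12)
          pred <- pmin(pmax(cur + step_size * dir[, 1], 1e-4), 1 - 1e-4)
          cand <- correct(pred)
        }
      } else {
        cand <- correct(stats::runif(5))   # rejection-sampling fallback
      }
      ok <- !is.null(cand) &&
        max(abs(.resid_pre(cand, r_pre))) < tol &&
        all(vapply(pts, function(p) max(abs(p - cand)) > 1e-6, logical(1)))
      if (ok) {
        pts[[length(pts) + 1L]] <- cand
        cur <- cand
        fails <- 0L
      } else {
        fails <- fails + 1L
        if (fails > 200L)
          stop("could not collect the requested number of distinct solutions",
               call. = FALSE)
        if (fails %% 10L == 0L) cur <- pts[[sample.int(length(pts), 1L)]]
      }
    }
    lapply(pts, .vec_par)
  })
}

#' Degrees-of-freedom accounting for the moment equations
#'
#' Counts parameters against independent cell constraints and measures the
#' local dimension of the solution set as `n_parameters - rank(J)`, where J
#' is the numerically differentiated Jacobian of the forward map (three
#' independent cell probabilities per supplied regime) at the given point.
#' Observationally there are 5 parameters and 3 constraints, leaving a 2-D
#' solution family; adding a post-intervention regime with delta' != delta
#' gives 6 parameters and 6 constraints with full rank, i.e. a locally
#' unique solution. With delta' = delta the post constraints duplicate the
#' pre constraints and the rank deficiency is reported, not hidden.
#'
#' @param params an [lca_params] object; must be strictly interior for the
#'   rank computation to be meaningful.
#' @param regime optional [intervention_regime]; when supplied the combined
#'   6-parameter, 6-constraint system is analysed.
#' @param sv_rel_tol singular values below `sv_rel_tol * max(singular value)`
#'   count as zero.
#' @return A `dof_report`: list with `n_parameters`, `n_constraints`,
#'   `jacobian_rank`, `solution_dimension`, `singular_values` and `status`
#'   (`"ok"` or `"boundary"`; for a boundary point the rank fields are `NA`).
#' @examples
#' p <- lca_params(0.6, 0.2, 0.7, 0.1, 0.8)
#' dof_analysis(p)                                      # 5 - 3 = 2 dof
#' dof_analysis(p, intervention_regime(0.3))            # 6 - 6 = 0 dof
#' @export
dof_analysis <- function(params, regime = NULL, sv_rel_tol = 1e-10) {
  stopifnot(inherits(params, "lca_params"))
  x <- .par_vec(params)
  with_post <- !is.null(regime)
  if (with_post) {
    stopifnot(inherits(regime, "intervention_regime"))
    x <- c(x, regime$delta_prime)
  }
  n_par <- length(x)
  n_con <- if (with_post) 6L else 3L
  if (!.is_interior(x, margin = 0)) {
    return(structure(list(n_parameters = n_par, n_constraints = n_con,
                          jacobian_rank = NA_integer_,
                          solution_dimension = NA_integer_,
                          singular_values = NULL, status = "boundary"),
                     class = "dof_report"))
  }
  J <- .constraint_jacobian(x, with_post = with_post)
  sv <- svd(J)$d
  rank <- sum(sv > sv_rel_tol * max(sv))
  structure(list(n_parameters = n_par, n_constraints = n_con,
                 jacobian_rank = rank,
                 solution_dimension = n_par - rank,
                 singular_values = sv, status = "ok"),
            class = "dof_report")
}

#' @export
print.dof_report <- function(x, ...) {
  cat("Degrees-of-freedom report\n")
  cat(sprintf("  parameters: %d, constraints: %d\n",
              x$n_parameters, x$n_constraints))
  if (x$status == "boundary") {
    cat("  boundary parameter point: rank not computed\n")
  } else {
    cat(sprintf("  Jacobian rank: %d, solution dimension: %d\n",
                x$jacobian_rank, x$solution_dimension))
  }
  invisible(x)
}

#' Feasibility of observed frequencies under the latent class model
#'
#' Classifies a frequency table (or a pre/post pair) as `"feasible"` (some
#' parameter tuple reproduces it, an interior witness is returned),
#' `"boundary"` (only boundary parameter tuples fit — the extremal case in
#' which an infinity of boundary solutions remains), or `"infeasible"` (no
#' parameters within `tol`; with intervention data the model is
#' overdetermined by such input). The least-squares decision is validated
#' against a dense grid search over the parameter box; a disagreement raises
#' a warning.
#'
#' @param freq_pre an [observed_frequencies()] record, regime `"pre"`.
#' @param freq_post optional post-intervention record.
#' @param tol max-abs residual below which the table counts as attainable.
#' @param n_grid grid resolution per axis for the validation oracle.
#' @param grid_tol grid residual threshold; defaults to `2 / (n_grid - 1)`,
#'   the Lipschitz bound on how far the forward map can move between grid
#'   nodes.
#' @param interior_margin coordinates closer than this to 0 or 1 make a
#'   witness a boundary witness.
#' @return A `feasibility` object: `status`, `witness` (list with `params`
#'   and possibly `delta_prime`; `NULL` if infeasible), `residual`,
#'   `grid_min_residual`, `grid_feasible`.
#' @export
check_feasibility <- function(freq_pre, freq_post = NULL, tol = 1e-6,
                              n_grid = 21L, grid_tol = 2 / (n_grid - 1),
                              interior_margin = 1e-3) {
  r_pre <- .freq_vec(freq_pre)
  r_post <- if (is.null(freq_post)) NULL else .freq_vec(freq_post)
  if (is.null(r_post)) {
    sols <- .multistart_ls(.resid_pre, 5L, 32L, r_pre = r_pre)
  } else {
    sols <- .multistart_ls(.resid_both, 6L, 32L,
                           r_pre = r_pre, r_post = r_post)
  }
  res <- vapply(sols, `[[`, numeric(1), "maxres")
  fbest <- min(res)
  grid <- .grid_min_residual(r_pre, r_post, n_grid = n_grid)
  grid_feasible <- grid$min_residual < grid_tol
  fits <- sols[res <= max(tol, fbest + 1e-12)]
  if (fbest <= tol) {
    interior <- Filter(function(s) .is_interior(s$par, interior_margin), fits)
    status <- if (length(interior)) "feasible" else "boundary"
    wsol <- if (length(interior)) interior[[which.min(
      vapply(interior, `[[`, numeric(1), "maxres"))]] else fits[[which.min(
        vapply(fits, `[[`, numeric(1), "maxres"))]]
    witness <- list(params = .vec_par(wsol$par[1:5]))
    if (!is.null(r_post)) witness$delta_prime <- wsol$par[6]
  } else {
    status <- "infeasible"
    witness <- NULL
  }
  if ((status != "infeasible") != grid_feasible)
    warning(sprintf(
      "least-squares (%s) and grid oracle (grid residual %.3g vs threshold %.3g) disagree",
      status, grid$min_residual, grid_tol), call. = FALSE)
  structure(list(status = status, witness = witness, residual = fbest,
                 grid_min_residual = grid$min_residual,
                 grid_feasible = grid_feasible),
            class = "feasibility")
}

#' @export
print.feasibility <- function(x, ...) {
  cat(sprintf("Feasibility: %s (residual %.3g; grid minimum %.3g)\n",
              x$status, x$residual, x$grid_min_residual))
  invisible(x)
}

#' Doubly labelled Bernoulli model demonstration
#'
#' The toy unidentifiable model: hypotheses G_xi with success chance xi^2,
#' xi in \[-1, 1\]. G_xi and G_-xi assign identical likelihoods to every
#' outcome sequence, so the model is unidentifiable: the binomial likelihood
#' is maximised on the set \{+sqrt(s/t), -sqrt(s/t)\} (a single point only
#' when s = 0).
#'
#' @param xi a value in \[-1, 1\].
#' @param successes observed number of successes (0 <= successes <= trials).
#' @param trials number of trials (>= 1).
#' @return A list with `log_lik_xi`, `log_lik_neg_xi` (always equal) and
#'   `mle_set` (the maximising xi values).
#' @export
double_labelled_demo <- function(xi, successes, trials) {
  if (length(xi) != 1L || !is.finite(xi) || xi < -1 || xi > 1)
    stop("'xi' must lie in [-1, 1]", call. = FALSE)
  if (trials < 1 || trials != round(trials))
    stop("'trials' must be a positive integer", call. = FALSE)
  if (successes < 0 || successes > trials || successes != round(successes))
    stop("'successes' must be an integer in [0, trials]", call. = FALSE)
  ll <- function(z) stats::dbinom(successes, trials, z^2, log = TRUE)
  phat <- successes / trials
  mle <- if (phat == 0) 0 else c(sqrt(phat), -sqrt(phat))
  list(log_lik_xi = ll(xi), log_lik_neg_xi = ll(-xi), mle_set = mle)
}
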