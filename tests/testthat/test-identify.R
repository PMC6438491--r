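test_that("the worked example is identified up to its mirror pair", {
  ex <- freqs_from(c(0.6, 0.2, 0.7, 0.1, 0.8, 0.3))
  expect_equal(unname(ex$pre$r), c(0.324, 0.176, 0.156, 0.344),
               tolerance = 1e-12)
  expect_equal(unname(ex$post$r), c(0.522, 0.128, 0.168, 0.182),
               tolerance = 1e-12)
  fit <- solve_moment_system(ex$pre, ex$post, direction = "reduced")
  expect_identical(fit$status, "identified_pair")
  expect_length(fit$branches, 2)
  b1 <- fit$branches[[1]]
  expect_lt(max(abs(lcident:::.par_vec(b1$params) - c(0.6, 0.2, 0.7, 0.1, 0.8))),
            1e-6)
  expect_lt(abs(b1$delta_prime - 0.3), 1e-6)
  # mirror-pair closure: branch 2 is the label-swap image of branch 1
  sw <- label_swap(b1$params, b1$delta_prime)
  b2 <- fit$branches[[2]]
  expect_lt(max(abs(lcident:::.par_vec(sw$params) -
                      lcident:::.par_vec(b2$params))), 1e-10)
  expect_lt(abs(sw$delta_prime - b2$delta_prime), 1e-10)
  # forward-evaluating either branch reproduces the inputs
  for (b in fit$branches) {
    expect_lt(max(abs(unclass(cell_probabilities(b$params)) - ex$pre$r)), 1e-8)
    expect_lt(max(abs(unclass(cell_probabilities(b$params, b$delta_prime)) -
                        ex$post$r)), 1e-8)
  }
})

test_that("the multistart solver agrees with the closed-form moment solution", {
  for (g in draw_generators(25, seed = 314)) {
    fr <- freqs_from(g)
    fit <- solve_moment_system(fr$pre, fr$post, direction = "reduced")
    expect_identical(fit$status, "identified_pair")
    oracle <- closed_form_solution(fr$pre, fr$post)
    expect_false(is.null(oracle))
    got <- c(lcident:::.par_vec(fit$branches[[1]]$params),
             fit$branches[[1]]$delta_prime)
    # oracle gives the delta' < delta branch; compare against it or its mirror
    d <- min(max(abs(got - oracle)), max(abs(lcident:::.swap6(got) - oracle)))
    expect_lt(d, 1e-6)
  }
})

test_that("an intervention that does not move the prevalence leaves the model degenerate", {
  gen <- std_gen()
  pre <- lcident:::exact_frequencies(cell_probabilities(gen), "pre")
  post <- lcident:::exact_frequencies(cell_probabilities(gen), "post")
  fit <- solve_moment_system(pre, post)
  expect_identical(fit$status, "degenerate_infinite")
})

test_that("independent manifest items leave the latent node unconstrained", {
  unif <- observed_frequencies(0.25, 0.25, 0.25, 0.25, t = 4, regime = "pre")
  unif_post <- observed_frequencies(0.25, 0.25, 0.25, 0.25, t = 4,
                                    regime = "post")
  fit <- solve_moment_system(unif, unif_post)
  expect_identical(fit$status, "degenerate_infinite")
})

test_that("parameters are recovered from finite samples up to sampling error", {
  gen <- std_gen()
  ds <- simulate_intervention_study(gen, std_regime(), 1e5, 1e5, seed = 2718)
  fit <- solve_moment_system(compute_frequencies(ds, "pre"),
                             compute_frequencies(ds, "post"),
                             direction = "reduced")
  expect_identical(fit$status, "identified_pair")
  got <- c(lcident:::.par_vec(fit$branches[[1]]$params),
           fit$branches[[1]]$delta_prime)
  expect_lt(max(abs(got - c(0.6, 0.2, 0.7, 0.1, 0.8, 0.3))), 0.02)
})

test_that("regime tags are enforced", {
  ex <- freqs_from(c(0.6, 0.2, 0.7, 0.1, 0.8, 0.3))
  expect_error(solve_moment_system(ex$post, ex$post), "regime")
  expect_warning(solve_moment_system(ex$pre, ex$post,
                                     direction = "unconstrained"),
                 "no particular order")
})

test_that("the observational solution manifold is 2-dimensional and exact", {
  ex <- freqs_from(c(0.6, 0.2, 0.7, 0.1, 0.8, 0.3))
  pts <- solution_manifold(ex$pre, n_points = 25, seed = 42)
  expect_gte(length(pts), 25)
  for (p in pts) {
    expect_lt(max(abs(unclass(cell_probabilities(p)) - ex$pre$r)), 1e-8)
    # local dimension at each interior member is 2
    if (all(lcident:::.par_vec(p) > 1e-3 & lcident:::.par_vec(p) < 1 - 1e-3)) {
      expect_identical(dof_analysis(p)$solution_dimension, 2L)
    }
  }
  # distinctness
  mat <- do.call(rbind, lapply(pts, lcident:::.par_vec))
  expect_gt(min(stats::dist(mat, method = "maximum")), 1e-6)
  # each point agrees with the exact (phi0, phi1) parameterisation of the family
  for (p in pts[1:10]) {
    rec <- manifold_point_from_phis(ex$pre, p$phi0, p$phi1)
    if (!is.null(rec))
      expect_lt(max(abs(rec - lcident:::.par_vec(p))), 1e-6)
  }
})

test_that("the uniform table admits the disconnected-latent family", {
  unif <- observed_frequencies(0.25, 0.25, 0.25, 0.25, t = 4, regime = "pre")
  # every tuple with matched conditionals at 0.5 solves the equations, for
  # any prevalence
  for (d in c(0.1, 0.5, 0.9)) {
    p <- lca_params(d, 0.5, 0.5, 0.5, 0.5)
    expect_lt(max(abs(unclass(cell_probabilities(p)) - 0.25)), 1e-15)
  }
  pts <- solution_manifold(unif, n_points = 10, seed = 1)
  for (p in pts)
    expect_lt(max(abs(unclass(cell_probabilities(p)) - 0.25)), 1e-8)
})

test_that("even extreme-dependence observational tables stay feasible", {
  # the two-class mixture with free conditionals covers the entire 2x2
  # simplex, so misfit can only arise once a second regime is added
  bad <- observed_frequencies(0.05, 0.45, 0.45, 0.05, t = 20, regime = "pre")
  fz <- check_feasibility(bad)
  expect_identical(fz$status, "feasible")
  pts <- solution_manifold(bad, n_points = 5, seed = 1)
  for (p in pts)
    expect_lt(max(abs(unclass(cell_probabilities(p)) - bad$r)), 1e-8)
})

test_that("degrees of freedom: 5 parameters, 3 constraints, 2 left over", {
  rep_obs <- dof_analysis(std_gen())
  expect_identical(rep_obs$n_parameters, 5L)
  expect_identical(rep_obs$n_constraints, 3L)
  expect_identical(rep_obs$jacobian_rank, 3L)
  expect_identical(rep_obs$solution_dimension, 2L)
})

test_that("degrees of freedom: intervention data close the gap", {
  rep_both <- dof_analysis(std_gen(), std_regime())
  expect_identical(rep_both$n_parameters, 6L)
  expect_identical(rep_both$n_constraints, 6L)
  expect_identical(rep_both$jacobian_rank, 6L)
  expect_identical(rep_both$solution_dimension, 0L)
})

test_that("a prevalence-preserving intervention leaves a rank-deficient system", {
  gen <- std_gen()
  rep_eq <- dof_analysis(gen, intervention_regime(gen$delta))
  # the post equations add only the delta'-column copy of the delta
  # direction: rank 4 of 6, so a 2-dimensional family remains
  expect_lt(rep_eq$jacobian_rank, 6L)
  expect_identical(rep_eq$jacobian_rank, 4L)
  expect_identical(rep_eq$solution_dimension, 2L)
})

test_that("boundary parameter points are flagged, not ranked", {
  rep_b <- dof_analysis(lca_params(0, 0.2, 0.7, 0.1, 0.8))
  expect_identical(rep_b$status, "boundary")
  expect_true(is.na(rep_b$jacobian_rank))
})

test_that("feasibility classification matches the grid oracle", {
  ex <- freqs_from(c(0.6, 0.2, 0.7, 0.1, 0.8, 0.3))
  fz <- check_feasibility(ex$pre, ex$post)
  expect_identical(fz$status, "feasible")
  expect_true(fz$grid_feasible)
  w <- fz$witness
  expect_lt(max(abs(unclass(cell_probabilities(w$params)) - ex$pre$r)), 1e-6)
  expect_lt(max(abs(unclass(cell_probabilities(w$params, w$delta_prime)) -
                      ex$post$r)), 1e-6)
})

test_that("an all-in-one-cell table is extremal: only boundary solutions", {
  ext <- observed_frequencies(0, 0, 0, 1, t = 5, regime = "pre")
  fz <- check_feasibility(ext)
  expect_identical(fz$status, "boundary")
  expect_lt(fz$residual, 1e-6)
})

test_that("covariance sign reversal across regimes is infeasible", {
  # pre has strongly positive (F, L) dependence, post strongly negative;
  # the shared-conditional mixture forces both covariances to share sign
  pre <- observed_frequencies(0.4, 0.1, 0.1, 0.4, t = 10, regime = "pre")
  post <- observed_frequencies(0.1, 0.4, 0.4, 0.1, t = 10, regime = "post")
  fz <- check_feasibility(pre, post)
  expect_identical(fz$status, "infeasible")
  expect_false(fz$grid_feasible)
  expect_gt(fz$residual, 0.1)
  fit <- solve_moment_system(pre, post)
  expect_identical(fit$status, "infeasible")
  expect_length(fit$branches, 0)
})

test_that("the doubly labelled Bernoulli model is unidentified in pairs", {
  for (xi in c(-0.9, -0.2, 0, 0.4, 1)) {
    demo <- double_labelled_demo(xi, successes = 7, trials = 20)
    expect_identical(demo$log_lik_xi, demo$log_lik_neg_xi)
  }
  demo <- double_labelled_demo(0.3, successes = 25, trials = 100)
  expect_equal(sort(demo$mle_set), c(-0.5, 0.5))
  # 1-D grid oracle: no xi beats +-sqrt(s/t)
  grid <- seq(-1, 1, by = 0.001)
  ll <- stats::dbinom(25, 100, grid^2, log = TRUE)
  expect_equal(sort(unique(abs(grid[ll == max(ll)]))), 0.5, tolerance = 1e-3)
  expect_identical(double_labelled_demo(0.5, 0, 10)$mle_set, 0)
  expect_error(double_labelled_demo(0.5, 1, 0), "positive integer")
  expect_error(double_labelled_demo(1.5, 1, 2), "xi")
})
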