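test_that("a point-mass prior is returned unchanged", {
  p <- std_gen()
  post <- posterior_over_parameters(point_prior(p), counts_pre = c(3, 1, 2, 4))
  expect_equal(unname(post$expectations), lcident:::.par_vec(p))
  # zero-likelihood point mass is rejected
  degenerate <- point_prior(lca_params(1, 1, 1, 1, 1))
  expect_error(posterior_over_parameters(degenerate, c(1, 0, 0, 0)),
               "zero-likelihood")
  expect_error(posterior_over_parameters(point_prior(p), c(1, 0, 0, 0),
                                         counts_post = c(1, 0, 0, 0)),
               "delta_prime")
})

test_that("with no observations the uniform prior is recovered exactly", {
  post <- posterior_over_parameters(beta_prior(), counts_pre = c(0, 0, 0, 0),
                                    n_grid = 11)
  expect_equal(unname(post$expectations), rep(0.5, 5), tolerance = 1e-12)
})

test_that("the factorised grid posterior equals direct summation", {
  # observational, single observation in cell (1, 1), uniform prior
  e1 <- posterior_over_parameters(beta_prior(), c(0, 0, 0, 1),
                                  n_grid = 11)$expectations
  b1 <- brute_force_posterior(beta_prior(), c(0, 0, 0, 1), n_grid = 11)
  expect_lt(max(abs(e1 - b1[names(e1)])), 1e-10)

  # combined regimes, informative prior, unconstrained and truncated
  pr <- beta_prior(delta = c(2, 3), phi0 = c(1, 2), phi1 = c(3, 1),
                   lambda0 = c(2, 2), lambda1 = c(1, 1),
                   delta_prime = c(2, 1))
  cp <- c(5, 3, 2, 8); cq <- c(7, 1, 4, 2)
  for (dir in c("unconstrained", "reduced", "increased")) {
    e <- posterior_over_parameters(pr, cp, cq, n_grid = 7,
                                   direction = dir)$expectations
    b <- brute_force_posterior(pr, cp, cq, n_grid = 7, direction = dir)
    expect_lt(max(abs(e - b[names(e)])), 1e-10)
  }
})

test_that("a swap-symmetric prior yields a swap-symmetric posterior", {
  gen <- std_gen()
  ds <- sample_dataset(gen, 2000, seed = 6)
  counts <- compute_frequencies(ds, "pre")$r * 2000
  e <- posterior_over_parameters(beta_prior(), counts, n_grid = 15)$expectations
  # observational data cannot break the label symmetry: delta centres at
  # 1/2 and the conditional pairs have exchanged-image expectations
  expect_equal(unname(e["delta"]), 0.5, tolerance = 1e-10)
  expect_equal(unname(e["phi0"]), unname(e["phi1"]), tolerance = 1e-10)
  expect_equal(unname(e["lambda0"]), unname(e["lambda1"]), tolerance = 1e-10)
})

test_that("identical priors have zero sensitivity spread", {
  spread <- prior_sensitivity(list(beta_prior(), beta_prior()),
                              counts_pre = c(3, 1, 2, 4), n_grid = 7)
  expect_equal(unname(spread), rep(0, 5), tolerance = 1e-14)
  expect_error(prior_sensitivity(list(beta_prior()), c(1, 1, 1, 1)),
               "at least two")
})

test_that("grid refinement moves expectations only slightly", {
  counts <- c(120, 40, 60, 180)
  e_coarse <- posterior_over_parameters(beta_prior(), counts,
                                        n_grid = 15)$expectations
  e_fine <- posterior_over_parameters(beta_prior(), counts,
                                      n_grid = 31)$expectations
  expect_lt(max(abs(e_coarse - e_fine)), 0.02)
})

test_that("the hyperprior is inert without a likelihood signal", {
  rhos <- c(0.2, 0.5, 0.8)
  fam <- prior_family(rhos, lapply(rhos, function(r) beta_prior()),
                      weights = c(0.5, 0.3, 0.2))
  hp <- estimate_hyperprior(fam, c(4, 2, 3, 1), c(5, 1, 1, 3),
                            coupling = 0.3, n_grid = 7)
  # all members identical: the posterior over rho equals its prior
  expect_equal(hp$rho_posterior, hp$prior_weights, tolerance = 1e-12)
})

test_that("hyperprior estimation demands post counts and a coupling", {
  fam <- prior_family(c(0.3, 0.7), list(beta_prior(), beta_prior()))
  expect_error(estimate_hyperprior(fam, c(1, 1, 1, 1), NULL, coupling = 0.3),
               "intervention counts")
  expect_error(estimate_hyperprior(fam, c(1, 1, 1, 1), c(1, 1, 1, 1),
                                   coupling = NULL), "coupling")
  expect_error(estimate_hyperprior(fam, c(1, 1, 1, 1), c(1, 1, 1, 1),
                                   coupling = function(d) 2 * d + 1),
               "into")
})

test_that("intervention data concentrate the hyperprior on the generating member", {
  rhos <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  mk <- function(r) beta_prior(delta = c(1 + 4 * r, 1 + 4 * (1 - r)),
                               phi0 = c(1 + 2 * (1 - r), 1 + 2 * r),
                               phi1 = c(1 + 4 * r, 1 + 4 * (1 - r)),
                               lambda0 = c(1 + 2 * (1 - r), 1 + 2 * r),
                               lambda1 = c(1 + 4 * r, 1 + 4 * (1 - r)))
  fam <- prior_family(rhos, lapply(rhos, mk))
  # generator drawn from the rho* = 0.7 member; coupling delta' = delta / 2
  gen <- withr::with_seed(7, {
    sh <- fam$priors[[4]]$shapes
    lca_params(stats::rbeta(1, sh$delta[1], sh$delta[2]),
               stats::rbeta(1, sh$phi0[1], sh$phi0[2]),
               stats::rbeta(1, sh$phi1[1], sh$phi1[2]),
               stats::rbeta(1, sh$lambda0[1], sh$lambda0[2]),
               stats::rbeta(1, sh$lambda1[1], sh$lambda1[2]))
  })
  ds <- simulate_intervention_study(gen, intervention_regime(gen$delta / 2),
                                    1e4, 1e4, seed = 99)
  cp <- compute_frequencies(ds, "pre"); cq <- compute_frequencies(ds, "post")
  hp <- estimate_hyperprior(fam, cp$r * cp$t, cq$r * cq$t,
                            coupling = function(d) d / 2)
  expect_gt(hp$rho_posterior[4], hp$prior_weights[4])
  expect_equal(sum(hp$rho_posterior), 1, tolerance = 1e-12)
})
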