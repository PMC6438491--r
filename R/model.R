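#' Observable cell probabilities of the latent class model
#'
#' Forward map from the model parameters to the joint distribution of the two
#' manifest items (F, L). Cell `theta_jk` is the probability of observing
#' F = j, L = k, obtained by mixing the two conditional product-Bernoulli
#' distributions with the supplied class prevalence:
#' `theta_jk = prev * phi1^j (1-phi1)^(1-j) * lambda1^k (1-lambda1)^(1-k) +
#'  (1-prev) * phi0^j (1-phi0)^(1-j) * lambda0^k (1-lambda0)^(1-k)`.
#'
#' Passing `prevalence = params$delta` (the default) gives the observational
#' regime; passing the post-intervention prevalence delta' gives the
#' post-intervention cells, since a stochastic intervention on the latent
#' node leaves the conditionals untouched.
#'
#' @param params an [lca_params] object.
#' @param prevalence class prevalence to mix with; defaults to
#'   `params$delta`.
#' @return A `cell_dist`: named numeric vector
#'   `c(theta00, theta01, theta10, theta11)` (index order F, L), summing to 1.
#' @examples
#' p <- lca_params(0.3, 0.2, 0.7, 0.1, 0.6)
#' cell_probabilities(p)
#' cell_probabilities(p, prevalence = 0.1)  # after an intervention
#' @export
cell_probabilities <- function(params, prevalence = params$delta) {
  stopifnot(inherits(params, "lca_params"))
  .check_prob(prevalence, "prevalence")
  th <- .cells(prevalence, params$phi0, params$phi1,
               params$lambda0, params$lambda1)
  structure(th, class = "cell_dist")
}

# Vectorised kernel shared by solvers and grid sweeps: arguments may be
# equal-length vectors; returns a length-4 list (00, 01, 10, 11).
.cells_list <- function(prev, phi0, phi1, lambda0, lambda1) {
  q <- 1 - prev
  list(
    t00 = prev * (1 - phi1) * (1 - lambda1) + q * (1 - phi0) * (1 - lambda0),
    t01 = prev * (1 - phi1) * lambda1       + q * (1 - phi0) * lambda0,
    t10 = prev * phi1 * (1 - lambda1)       + q * phi0 * (1 - lambda0),
    t11 = prev * phi1 * lambda1             + q * phi0 * lambda0
  )
}

.cells <- function(prev, phi0, phi1, lambda0, lambda1) {
  l <- .cells_list(prev, phi0, phi1, lambda0, lambda1)
  c(theta00 = l$t00, theta01 = l$t01, theta10 = l$t10, theta11 = l$t11)
}

#' @export
print.cell_dist <- function(x, digits = 6, ...) {
  cat("Cell probabilities P(F = j, L = k):\n")
  m <- matrix(c(x[["theta00"]], x[["theta01"]], x[["theta10"]], x[["theta11"]]),
              2, 2, byrow = TRUE,
              dimnames = list("F" = 0:1, "L" = 0:1))
  print(round(m, digits))
  invisible(x)
}

#' Full joint distribution over (D, F, L)
#'
#' The latent class model factorises as
#' P(D, F, L) = P(D) P(F | D) P(L | D): the manifest items are conditionally
#' independent given the class. Marginalising D reproduces
#' [cell_probabilities()].
#'
#' @param params an [lca_params] object.
#' @return A 2 x 2 x 2 array with `dimnames` `D`, `F`, `L` (values "0", "1"),
#'   non-negative and summing to 1.
#' @examples
#' p <- lca_params(0.3, 0.2, 0.7, 0.1, 0.6)
#' j <- joint_distribution(p)
#' j["1", "1", "1"]                   # 0.3 * 0.7 * 0.6
#' apply(j, c(2, 3), sum)             # == cell_probabilities(p) as a matrix
#' @export
joint_distribution <- function(params) {
  stopifnot(inherits(params, "lca_params"))
  pd <- c(1 - params$delta, params$delta)
  pf <- rbind(c(1 - params$phi0, params$phi0),
              c(1 - params$phi1, params$phi1))     # row: D, col: F
  pl <- rbind(c(1 - params$lambda0, params$lambda0),
              c(1 - params$lambda1, params$lambda1))
  out <- array(0, dim = c(2, 2, 2),
               dimnames = list(D = c("0", "1"), F = c("0", "1"),
                               L = c("0", "1")))
  for (d in 1:2) for (f in 1:2) for (l in 1:2)
    out[d, f, l] <- pd[d] * pf[d, f] * pl[d, l]
  out
}

#' Multinomial log-likelihood of observed cell counts
#'
#' Computes `sum_jk n_jk * log theta_jk` for counts over the four (F, L)
#' cells under the cell probabilities implied by `params` and `prevalence`
#' (the multinomial coefficient, constant in the parameters, is omitted).
#' Returns `-Inf` when a cell with positive count has probability zero; a
#' zero count contributes zero even at a zero-probability cell. The value is
#' invariant under [label_swap()] of the parameters.
#'
#' @param params an [lca_params] object.
#' @param counts numeric vector of four non-negative cell counts in the order
#'   (00, 01, 10, 11); names, if present, are ignored. Total must be
#'   positive.
#' @param prevalence mixing prevalence, default `params$delta`.
#' @return The log-likelihood (a single number, possibly `-Inf`).
#' @export
log_likelihood <- function(params, counts, prevalence = params$delta) {
  counts <- .check_counts(counts)
  th <- unclass(cell_probabilities(params, prevalence))
  terms <- ifelse(counts > 0, counts * log(th), 0)
  sum(terms)
}

.check_counts <- function(counts) {
  if (length(counts) != 4L || any(!is.finite(counts)) || any(counts < 0))
    stop("'counts' must be four finite non-negative numbers (order 00, 01, 10, 11)",
         call. = FALSE)
  if (sum(counts) <= 0)
    stop("'counts' must have a positive total", call. = FALSE)
  as.numeric(counts)
}
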