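#' Latent class model parameters
#'
#' Bundles the five chances of the binary two-class, two-item latent class
#' model: the latent prevalence `delta` = P(D = 1) and the conditional
#' response probabilities `phi0` = P(F = 1 | D = 0), `phi1` = P(F = 1 | D = 1),
#' `lambda0` = P(L = 1 | D = 0), `lambda1` = P(L = 1 | D = 1). Here D is the
#' latent class indicator (e.g. depression) and F, L the two manifest binary
#' items (e.g. fear and loathing).
#'
#' Boundary values 0 and 1 are legal; identifiability diagnostics, not this
#' constructor, flag them.
#'
#' @param delta latent prevalence P(D = 1), in \[0, 1\].
#' @param phi0,phi1 P(F = 1 | D = 0) and P(F = 1 | D = 1), in \[0, 1\].
#' @param lambda0,lambda1 P(L = 1 | D = 0) and P(L = 1 | D = 1), in \[0, 1\].
#' @return An object of class `lca_params`: a named list with the five fields.
#' @examples
#' p <- lca_params(0.3, phi0 = 0.2, phi1 = 0.7, lambda0 = 0.1, lambda1 = 0.6)
#' label_swap(p)
#' @seealso [cell_probabilities()], [label_swap()]
#' @export
lca_params <- function(delta, phi0, phi1, lambda0, lambda1) {
  vals <- list(delta = delta, phi0 = phi0, phi1 = phi1,
               lambda0 = lambda0, lambda1 = lambda1)
  for (nm in names(vals)) .check_prob(vals[[nm]], nm)
  structure(vals, class = "lca_params")
}

.check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(sprintf("'%s' must be a single probability in [0, 1], got %s",
                 name, deparse(x)), call. = FALSE)
  invisible(x)
}

#' @export
print.lca_params <- function(x, digits = 4, ...) {
  cat("Latent class parameters (2 classes, 2 binary items)\n")
  cat(sprintf("  delta = P(D=1)      : %.*g\n", digits, x$delta))
  cat(sprintf("  phi0, phi1 = P(F=1|D=0,1)   : %.*g, %.*g\n",
              digits, x$phi0, digits, x$phi1))
  cat(sprintf("  lambda0, lambda1 = P(L=1|D=0,1): %.*g, %.*g\n",
              digits, x$lambda0, digits, x$lambda1))
  invisible(x)
}

#' Swap the latent class labels
#'
#' Relabelling the latent classes D = 0 <-> D = 1 maps the parameter tuple
#' (delta, phi0, phi1, lambda0, lambda1) to
#' (1 - delta, phi1, phi0, lambda1, lambda0) without changing the
#' distribution of the observables. Applied twice it is the identity. This is
#' the mirror symmetry under which the intervention-identified model is
#' determined only up to a pair of solutions.
#'
#' @param params an [lca_params] object.
#' @param delta_prime optional post-intervention prevalence; when supplied,
#'   the swapped value `1 - delta_prime` is returned in the
#'   `delta_prime` attribute-free second list slot (see Value).
#' @return If `delta_prime` is `NULL`, the swapped `lca_params`. Otherwise a
#'   list with elements `params` (swapped `lca_params`) and `delta_prime`
#'   (`1 - delta_prime`).
#' @export
label_swap <- function(params, delta_prime = NULL) {
  stopifnot(inherits(params, "lca_params"))
  sw <- lca_params(1 - params$delta, params$phi1, params$phi0,
                   params$lambda1, params$lambda0)
  if (is.null(delta_prime)) return(sw)
  .check_prob(delta_prime, "delta_prime")
  list(params = sw, delta_prime = 1 - delta_prime)
}

#' Post-intervention regime description
#'
#' Records the latent prevalence after a stochastic intervention on the
#' latent node, P'(D = 1) = delta', together with the qualitative knowledge
#' of how it compares with the observational prevalence delta ("reduced"
#' encodes the assumption delta' < delta, e.g. a treatment lowering the
#' probability of depression).
#'
#' @param delta_prime post-intervention prevalence, in \[0, 1\].
#' @param direction one of `"reduced"`, `"increased"`, `"unconstrained"`.
#' @return An object of class `intervention_regime`.
#' @export
intervention_regime <- function(delta_prime,
                                direction = c("reduced", "increased",
                                              "unconstrained")) {
  .check_prob(delta_prime, "delta_prime")
  direction <- match.arg(direction)
  structure(list(delta_prime = delta_prime, direction = direction),
            class = "intervention_regime")
}

#' @export
print.intervention_regime <- function(x, ...) {
  cat(sprintf("Stochastic intervention on D: P'(D=1) = %g (%s)\n",
              x$delta_prime, x$direction))
  invisible(x)
}

# Coerce a flat named list/vector (delta, phi0, ...) to lca_params.
as_lca_params <- function(x) {
  if (inherits(x, "lca_params")) return(x)
  x <- as.list(x)
  lca_params(x$delta, x$phi0, x$phi1, x$lambda0, x$lambda1)
}

# Numeric 5-vector view used by the solvers, fixed order.
.par_vec <- function(params) {
  c(params$delta, params$phi0, params$phi1, params$lambda0, params$lambda1)
}

.vec_par <- function(x) {
  lca_params(x[1], x[2], x[3], x[4], x[5])
}
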