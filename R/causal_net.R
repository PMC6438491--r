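#' Discrete causal Bayesian network over binary nodes
#'
#' A directed acyclic graph over binary variables together with one
#' conditional probability table per node. Tables give the probability that
#' the node equals 1 for each assignment of its parents, stored as an array
#' with one dimension of extent 2 per parent (dimension order = parent
#' order; index 1 = parent value 0, index 2 = parent value 1). A root node's
#' table is a single probability.
#'
#' @param nodes character vector of node names.
#' @param parents named list mapping each node to its (possibly empty)
#'   character vector of parents.
#' @param cpt named list mapping each node to its table of P(node = 1 |
#'   parents).
#' @return A `bayes_net` object.
#' @examples
#' # common-cause net D -> F, D -> L
#' net <- bayes_net(
#'   nodes = c("D", "F", "L"),
#'   parents = list(D = character(), F = "D", L = "D"),
#'   cpt = list(D = 0.6, F = c(0.2, 0.7), L = c(0.1, 0.8)))
#' joint_from_network(net)
#' @export
bayes_net <- function(nodes, parents, cpt) {
  if (!is.character(nodes) || anyDuplicated(nodes))
    stop("'nodes' must be distinct node names", call. = FALSE)
  if (!setequal(names(parents), nodes) || !setequal(names(cpt), nodes))
    stop("'parents' and 'cpt' must name exactly the nodes", call. = FALSE)
  for (v in nodes) {
    pa <- parents[[v]]
    if (length(pa) && !all(pa %in% nodes))
      stop(sprintf("node '%s' has unknown parent(s)", v), call. = FALSE)
    tab <- cpt[[v]]
    if (length(tab) != 2^length(pa))
      stop(sprintf("table for '%s' must have 2^%d entries", v, length(pa)),
           call. = FALSE)
    if (any(!is.finite(tab)) || any(tab < 0) || any(tab > 1))
      stop(sprintf("table for '%s' must contain probabilities", v),
           call. = FALSE)
  }
  net <- structure(list(nodes = nodes, parents = parents,
                        cpt = lapply(cpt, as.numeric)),
                   class = "bayes_net")
  .topo_order(net)  # errors on a cyclic graph
  net
}

# topological order; error if cyclic
.topo_order <- function(net) {
  remaining <- net$nodes
  ordered <- character()
  while (length(remaining)) {
    free <- remaining[vapply(remaining, function(v)
      all(net$parents[[v]] %in% ordered), logical(1))]
    if (!length(free))
      stop("graph is cyclic", call. = FALSE)
    ordered <- c(ordered, free)
    remaining <- setdiff(remaining, free)
  }
  ordered
}

#' @export
print.bayes_net <- function(x, ...) {
  cat(sprintf("Discrete Bayesian network over %d binary nodes\n",
              length(x$nodes)))
  for (v in x$nodes) {
    pa <- x$parents[[v]]
    cat(sprintf("  %s | %s\n", v,
                if (length(pa)) paste(pa, collapse = ", ") else "(root)"))
  }
  invisible(x)
}

# P(v = val | parent assignment named vector pa_vals)
.cond_prob <- function(net, v, val, pa_vals) {
  pa <- net$parents[[v]]
  idx <- if (length(pa)) sum(pa_vals[pa] * 2^(seq_along(pa) - 1)) + 1 else 1
  p1 <- net$cpt[[v]][idx]
  if (val == 1) p1 else 1 - p1
}

#' Joint distribution determined by a Bayesian network
#'
#' Multiplies the conditional tables over all assignments:
#' P(X1, ..., Xn) = prod_v P(Xv | parents(Xv)) — the factorisation licensed
#' by the (causal) Markov condition.
#'
#' @param net a [bayes_net()].
#' @return An array of dimension `rep(2, n)` with `dimnames` the node names
#'   (values "0", "1"), non-negative and summing to 1.
#' @export
joint_from_network <- function(net) {
  stopifnot(inherits(net, "bayes_net"))
  n <- length(net$nodes)
  grid <- as.matrix(expand.grid(rep(list(0:1), n)))
  colnames(grid) <- net$nodes
  probs <- apply(grid, 1, function(row) {
    # left-associated double-precision product, bit-identical to the
    # hand-written factorisation of the three-node model joint
    Reduce(`*`, lapply(net$nodes, function(v)
      .cond_prob(net, v, row[[v]], row)))
  })
  out <- array(probs, dim = rep(2, n),
               dimnames = stats::setNames(rep(list(c("0", "1")), n),
                                          net$nodes))
  out
}

#' Marginal probability that a node equals 1
#'
#' @param joint a joint array as returned by [joint_from_network()].
#' @param node node name.
#' @return P(node = 1).
#' @export
marginal_prob <- function(joint, node) {
  nd <- names(dimnames(joint))
  if (!(node %in% nd)) stop(sprintf("node '%s' not in joint", node),
                            call. = FALSE)
  m <- apply(joint, which(nd == node), sum)
  m[["1"]]
}

#' Apply a stochastic intervention to a network
#'
#' Graph surgery for a stochastic (parametric) intervention: all arrows into
#' the target are removed and its table replaced by the new marginal, while
#' every other node keeps its conditional table unchanged (modularity). Any
#' non-descendant of the target therefore keeps its marginal distribution,
#' and all conditionals given the target are preserved.
#'
#' @param net a [bayes_net()].
#' @param target node to intervene on.
#' @param marginal new P(target = 1).
#' @return The surgered `bayes_net`.
#' @examples
#' net <- bayes_net(c("D", "F", "L"),
#'                  list(D = character(), F = "D", L = "D"),
#'                  list(D = 0.6, F = c(0.2, 0.7), L = c(0.1, 0.8)))
#' post <- apply_stochastic_intervention(net, "D", 0.3)
#' marginal_prob(joint_from_network(post), "F")  # 0.3*0.7 + 0.7*0.2
#' @export
apply_stochastic_intervention <- function(net, target, marginal) {
  stopifnot(inherits(net, "bayes_net"))
  if (!(target %in% net$nodes))
    stop(sprintf("target '%s' is not a node of the network", target),
         call. = FALSE)
  .check_prob(marginal, "marginal")
  parents <- net$parents
  cpt <- net$cpt
  parents[[target]] <- character()
  cpt[[target]] <- marginal
  bayes_net(net$nodes, parents, cpt)
}

#' The common-cause network of the latent class model
#'
#' Builds the three-node network D -> F, D -> L whose joint distribution
#' equals [joint_distribution()] of the same parameters.
#'
#' @param params an [lca_params] object.
#' @param prevalence P(D = 1); defaults to `params$delta`.
#' @return A [bayes_net()].
#' @export
lca_network <- function(params, prevalence = params$delta) {
  stopifnot(inherits(params, "lca_params"))
  bayes_net(nodes = c("D", "F", "L"),
            parents = list(D = character(), F = "D", L = "D"),
            cpt = list(D = prevalence,
                       F = c(params$phi0, params$phi1),
                       L = c(params$lambda0, params$lambda1)))
}

#' A three-node chain network
#'
#' Builds `from -> D -> to` over the nodes D, F, L, the two chain
#' alternatives to the common-cause structure that are observationally
#' indistinguishable from it (all three render F and L conditionally
#' independent given D) but respond differently to interventions on D.
#'
#' @param from,to the manifest nodes, a permutation of `c("F", "L")`.
#' @param p_from marginal P(from = 1).
#' @param p_d length-2 vector P(D = 1 | from = 0, 1).
#' @param p_to length-2 vector P(to = 1 | D = 0, 1).
#' @return A [bayes_net()].
#' @export
chain_network <- function(from = "F", to = "L", p_from, p_d, p_to) {
  if (!setequal(c(from, to), c("F", "L")))
    stop("'from' and 'to' must be F and L in some order", call. = FALSE)
  parents <- stats::setNames(list(character(), from, "D"),
                             c(from, "D", to))
  cpt <- stats::setNames(list(p_from, p_d, p_to), c(from, "D", to))
  bayes_net(nodes = c("D", "F", "L"), parents = parents, cpt = cpt)
}

#' Discriminate candidate causal structures from intervention data
#'
#' The three candidate structures — common cause (D -> F, D -> L), chain
#' F -> D -> L, chain L -> D -> F — imply the same observational
#' independencies but respond differently to an intervention on D: if both
#' manifest marginals change, the common-cause structure is favoured; if
#' only L changes, the F -> D -> L chain; if only F, the L -> D -> F chain;
#' if neither changes, this intervention cannot tell the candidates apart.
#'
#' @param pre_joint,post_joint joint arrays (from [joint_from_network()])
#'   over nodes including F and L, before and after the intervention.
#' @param candidates candidate structure labels to consider.
#' @param epsilon threshold above which a marginal counts as changed. The
#'   default 1e-9 is for exact joints; with marginals estimated from finite
#'   samples set it explicitly (e.g. a standard-error multiple).
#' @return A list with `supported` (subset of `candidates`),
#'   `indistinguishable` (`TRUE` when no marginal moved), and the observed
#'   marginal `changes` for F and L.
#' @export
discriminate_structure <- function(pre_joint, post_joint,
                                   candidates = c("common_cause",
                                                  "chain_F_to_L",
                                                  "chain_L_to_F"),
                                   epsilon = 1e-9) {
  candidates <- match.arg(candidates, several.ok = TRUE)
  dF <- abs(marginal_prob(post_joint, "F") - marginal_prob(pre_joint, "F"))
  dL <- abs(marginal_prob(post_joint, "L") - marginal_prob(pre_joint, "L"))
  f_moved <- dF > epsilon
  l_moved <- dL > epsilon
  if (!f_moved && !l_moved) {
    return(list(supported = candidates, indistinguishable = TRUE,
                changes = c(F = dF, L = dL)))
  }
  pick <- if (f_moved && l_moved) "common_cause"
  else if (l_moved) "chain_F_to_L"
  else "chain_L_to_F"
  list(supported = intersect(candidates, pick), indistinguishable = FALSE,
       changes = c(F = dF, L = dL))
}
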