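#' Observed relative cell frequencies
#'
#' Container for the relative frequencies r_jk of the four (F, L) cells in a
#' sample of size `t` from one regime. The frequencies must sum to 1 and each
#' `r_jk * t` must be (numerically) an integer count.
#'
#' @param r00,r01,r10,r11 relative frequencies of the cells (F = j, L = k).
#' @param t positive integer sample size.
#' @param regime `"pre"` (observational) or `"post"` (after intervention).
#' @return An object of class `observed_freq`.
#' @export
observed_frequencies <- function(r00, r01, r10, r11, t,
                                 regime = c("pre", "post")) {
  regime <- match.arg(regime)
  r <- c(r00 = r00, r01 = r01, r10 = r10, r11 = r11)
  if (any(!is.finite(r)) || any(r < 0) || any(r > 1))
    stop("relative frequencies must lie in [0, 1]", call. = FALSE)
  if (abs(sum(r) - 1) > 1e-12)
    stop("relative frequencies must sum to 1 (within 1e-12)", call. = FALSE)
  if (length(t) != 1L || !is.finite(t) || t < 1 || t != round(t))
    stop("'t' must be a positive integer sample size", call. = FALSE)
  if (any(abs(r * t - round(r * t)) > 1e-9))
    stop("each r_jk * t must be an integer count (within 1e-9)", call. = FALSE)
  structure(list(r = r, t = as.integer(t), regime = regime),
            class = "observed_freq")
}

#' @export
print.observed_freq <- function(x, ...) {
  cat(sprintf("Observed frequencies (%s regime, t = %d):\n", x$regime, x$t))
  print(round(x$r, 6))
  invisible(x)
}

# Frequencies taken directly from exact cell probabilities, for
# noise-free moment systems. t is nominal (frequencies are not counts).
exact_frequencies <- function(cells, regime = c("pre", "post"), t = 1L) {
  regime <- match.arg(regime)
  cells <- unclass(cells)
  structure(list(r = c(r00 = cells[["theta00"]], r01 = cells[["theta01"]],
                       r10 = cells[["theta10"]], r11 = cells[["theta11"]]),
                 t = as.integer(t), regime = regime),
            class = "observed_freq")
}

# deterministic substream seeds below 2^31 derived from one master seed
.substream_seed <- function(seed, k) {
  if (length(seed) != 1L || !is.finite(seed) || seed != round(seed) || seed < 0)
    stop("'seed' must be a single non-negative integer", call. = FALSE)
  as.integer((seed * 48271 + k * 65537) %% 2147483629)
}

#' Draw a synthetic sample from the latent class model
#'
#' Each subject is drawn i.i.d.: D ~ Bernoulli(prevalence), then
#' F | D = j ~ Bernoulli(phi_j) and L | D = j ~ Bernoulli(lambda_j).
#' Identical inputs and seed reproduce the identical table bit-for-bit; the
#' caller's RNG state is left untouched.
#'
#' @param params an [lca_params] object.
#' @param n_subjects number of subjects (>= 1).
#' @param seed non-negative integer seed.
#' @param prevalence class prevalence; defaults to `params$delta`.
#' @param regime regime tag written on every row, `"pre"` or `"post"`.
#' @param keep_latent if `TRUE`, retain the latent class column `D` (for
#'   testing only; D is unobservable in the modelled study).
#' @return A `data.frame` with columns `subject_id`, `regime`, `F`, `L`
#'   (and `D` when `keep_latent = TRUE`).
#' @export
sample_dataset <- function(params, n_subjects, seed,
                           prevalence = params$delta,
                           regime = c("pre", "post"),
                           keep_latent = FALSE) {
  stopifnot(inherits(params, "lca_params"))
  .check_prob(prevalence, "prevalence")
  regime <- match.arg(regime)
  if (length(n_subjects) != 1L || !is.finite(n_subjects) || n_subjects < 1)
    stop("'n_subjects' must be at least 1", call. = FALSE)
  n <- as.integer(n_subjects)
  withr::with_seed(.substream_seed(seed, 0L), {
    d <- stats::rbinom(n, 1L, prevalence)
    f <- stats::rbinom(n, 1L, ifelse(d == 1L, params$phi1, params$phi0))
    l <- stats::rbinom(n, 1L, ifelse(d == 1L, params$lambda1, params$lambda0))
    out <- data.frame(subject_id = seq_len(n), regime = regime, F = f, L = l,
                      stringsAsFactors = FALSE)
    if (keep_latent) out$D <- d
    out
  })
}

#' Reduce subject-level data to cell frequencies
#'
#' Counts the rows of one regime in each (F, L) cell and divides by the
#' regime sample size: `r_jk = #\{F = j, L = k\} / t`.
#'
#' @param dataset a data frame with columns `regime`, `F`, `L` (as produced
#'   by [sample_dataset()] or [read_dataset()]).
#' @param regime which regime to tabulate, `"pre"` or `"post"`.
#' @return An [observed_frequencies()] record.
#' @export
compute_frequencies <- function(dataset, regime = c("pre", "post")) {
  regime <- match.arg(regime)
  .validate_dataset(dataset)
  rows <- dataset[dataset$regime == regime, , drop = FALSE]
  if (nrow(rows) == 0L)
    stop(sprintf("no rows with regime '%s' in the dataset", regime),
         call. = FALSE)
  t <- nrow(rows)
  n <- c(sum(rows$F == 0 & rows$L == 0), sum(rows$F == 0 & rows$L == 1),
         sum(rows$F == 1 & rows$L == 0), sum(rows$F == 1 & rows$L == 1))
  observed_frequencies(n[1] / t, n[2] / t, n[3] / t, n[4] / t, t = t,
                       regime = regime)
}

.validate_dataset <- function(dataset) {
  need <- c("regime", "F", "L")
  miss <- setdiff(need, names(dataset))
  if (length(miss))
    stop("dataset is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad <- which(!(dataset$F %in% c(0, 1)) | !(dataset$L %in% c(0, 1)) |
                 !(dataset$regime %in% c("pre", "post")))
  if (length(bad))
    stop("invalid rows (F/L not 0/1 or regime not pre/post) at row(s): ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  invisible(dataset)
}

#' Simulate a two-regime intervention study
#'
#' Draws an observational sample at prevalence delta and an independent
#' post-intervention sample at prevalence delta', both regimes sharing the
#' conditional response probabilities (phi0, phi1, lambda0, lambda1): the
#' stochastic intervention changes only the latent prevalence. Each regime
#' uses its own deterministic substream of the master seed, so either half is
#' reproducible on its own.
#'
#' @param params an [lca_params] object (observational prevalence
#'   `params$delta`).
#' @param regime an [intervention_regime] giving delta'.
#' @param n_pre,n_post sample sizes of the two regimes.
#' @param seed master seed.
#' @param keep_latent retain the latent `D` column (testing only).
#' @return A `data.frame` with rows of both regimes (`regime` column `"pre"`
#'   / `"post"`).
#' @export
simulate_intervention_study <- function(params, regime, n_pre, n_post, seed,
                                        keep_latent = FALSE) {
  stopifnot(inherits(params, "lca_params"),
            inherits(regime, "intervention_regime"))
  pre <- sample_dataset(params, n_pre, seed = .substream_seed(seed, 1L),
                        regime = "pre", keep_latent = keep_latent)
  post <- sample_dataset(params, n_post, seed = .substream_seed(seed, 2L),
                         prevalence = regime$delta_prime, regime = "post",
                         keep_latent = keep_latent)
  post$subject_id <- post$subject_id + nrow(pre)
  rbind(pre, post)
}
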