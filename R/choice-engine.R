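## Choice-probability engines: exact enumeration over presentation orders
## and seeded Monte Carlo, plus the ratio/difference summary metrics.

#' Engine configuration
#'
#' @param n_trials Positive integer number of Monte-Carlo trials
#'   (default 100000).
#' @param seed Optional integer seed; identical seeds give bitwise-identical
#'   results.
#' @param mc_mode `"probability_average"` (average the softmax probabilities
#'   over sampled order sets; lower variance) or `"sampled_choice"` (sample
#'   one choice per trial and tally). Both have the same expectation.
#' @param enumeration_limit Maximum number of order combinations
#'   [exact_choice_probs()] will enumerate (default 10000).
#' @return An object of class `engine_config`.
#' @export
engine_config <- function(n_trials = 100000L, seed = NULL,
                          mc_mode = c("probability_average", "sampled_choice"),
                          enumeration_limit = 10000L) {
  mc_mode <- match.arg(mc_mode)
  if (!is.numeric(n_trials) || length(n_trials) != 1L || n_trials < 1 ||
      n_trials != round(n_trials))
    stop("`n_trials` must be a positive integer")
  if (!is.null(seed) &&
      (!is.numeric(seed) || length(seed) != 1L || seed != round(seed)))
    stop("`seed` must be a single integer or NULL")
  if (!is.numeric(enumeration_limit) || enumeration_limit < 1)
    stop("`enumeration_limit` must be a positive integer")
  structure(list(n_trials = as.integer(n_trials),
                 seed = if (is.null(seed)) NULL else as.integer(seed),
                 mc_mode = mc_mode,
                 enumeration_limit = as.integer(enumeration_limit)),
            class = "engine_config")
}

## Batch valuation: `orders` is a list with one n x N integer matrix per
## attribute (row = trial, entry = option considered at that step). The
## posterior-variance path is order-independent, so the per-step gains are
## scalars shared by all trials; only the means differ.
batch_option_values <- function(problem, params, orders) {
  I <- n_attributes(problem); N <- n_options(problem)
  params <- expand_params(params, I)
  n <- nrow(orders[[1L]])
  rows <- seq_len(n)
  total <- matrix(0, n, N)
  for (i in seq_len(I)) {
    ord <- orders[[i]]
    m <- rep(params$prior_mean[i], n)
    v <- params$prior_var[i]
    for (t in seq_len(N)) {
      g <- v / (v + params$reward_var[i])
      idx <- ord[, t]
      val <- g * (problem[i, idx] - m)
      m <- m + val
      v <- v - g * v
      total[cbind(rows, idx)] <- total[cbind(rows, idx)] + val
    }
  }
  colnames(total) <- colnames(problem)
  total
}

## Row-wise overflow-safe softmax of an n x N value matrix.
batch_softmax <- function(values, beta) {
  z <- beta * values
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Exact choice probabilities by order enumeration
#'
#' Averages the softmax choice distribution over all `(N!)^I` equally
#' weighted combinations of per-attribute presentation orders. Deterministic
#' and exact; refuses problems whose combination count exceeds
#' `enumeration_limit` (use [mc_choice_probs()] instead for those).
#'
#' @param problem A [choice_problem()].
#' @param params A [bcv_params()].
#' @param enumeration_limit Maximum admissible number of order combinations.
#' @return A `choice_distribution` with `method = "exact"` and zero
#'   standard errors.
#' @examples
#' exact_choice_probs(choice_problem(c(10, 6)),
#'                    bcv_params(reward_var = 0.1))
#' @export
exact_choice_probs <- function(problem, params, enumeration_limit = 10000L) {
  stopifnot(inherits(problem, "choice_problem"), inherits(params, "bcv_params"))
  I <- n_attributes(problem); N <- n_options(problem)
  n_combos <- factorial(N)^I
  if (n_combos > enumeration_limit)
    stop(sprintf(paste0("enumeration would need %.0f order combinations ",
                        "(limit %d); use mc_choice_probs()"),
                 n_combos, enumeration_limit))
  perms <- matrix(as.integer(pracma::perms(seq_len(N))), ncol = N)
  combo <- as.matrix(expand.grid(rep(list(seq_len(nrow(perms))), I)))
  orders <- lapply(seq_len(I), function(i) perms[combo[, i], , drop = FALSE])
  P <- batch_softmax(batch_option_values(problem, params, orders),
                     params$beta)
  choice_distribution(colMeans(P), stderr = rep(0, N), method = "exact",
                      labels = colnames(problem))
}

#' Monte-Carlo choice probabilities
#'
#' Draws `n_trials` independent order sets (uniform over permutations,
#' independently per attribute) and estimates choice probabilities either by
#' averaging softmax probabilities (`probability_average`) or by tallying
#' sampled choices (`sampled_choice`). Reproducible given `config$seed`.
#'
#' @param problem A [choice_problem()].
#' @param params A [bcv_params()].
#' @param config An [engine_config()].
#' @return A `choice_distribution` with `method = "monte_carlo"` and
#'   per-option standard errors.
#' @examples
#' mc_choice_probs(choice_problem(c(10, 6)), bcv_params(reward_var = 0.1),
#'                 engine_config(n_trials = 1000, seed = 1))
#' @export
mc_choice_probs <- function(problem, params, config = engine_config()) {
  stopifnot(inherits(problem, "choice_problem"),
            inherits(params, "bcv_params"),
            inherits(config, "engine_config"))
  I <- n_attributes(problem); N <- n_options(problem)
  n <- config$n_trials
  with_seed(config$seed, {
    perms <- matrix(as.integer(pracma::perms(seq_len(N))), ncol = N)
    orders <- lapply(seq_len(I), function(i) {
      perms[sample.int(nrow(perms), n, replace = TRUE), , drop = FALSE]
    })
    P <- batch_softmax(batch_option_values(problem, params, orders),
                       params$beta)
    if (config$mc_mode == "probability_average") {
      probs <- colMeans(P)
      se <- apply(P, 2L, stats::sd) / sqrt(n)
    } else {
      cum <- t(apply(P, 1L, cumsum))
      pick <- 1L + rowSums(cum < stats::runif(n))
      counts <- tabulate(pick, nbins = N)
      probs <- counts / n
      se <- sqrt(probs * (1 - probs) / n)
    }
    choice_distribution(probs, stderr = se, method = "monte_carlo",
                        labels = colnames(problem), n_trials = n)
  })
}

## Evaluate `expr` under a temporarily seeded RNG, restoring the caller's
## RNG state afterwards. A NULL seed leaves the RNG alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

resolve_option <- function(dist, idx) {
  if (is.character(idx)) {
    pos <- match(idx, names(dist$probs))
    if (is.na(pos)) stop("unknown option label: ", idx)
    return(pos)
  }
  if (!is.numeric(idx) || length(idx) != 1L || is.na(idx) ||
      idx < 1 || idx > length(dist$probs) || idx != round(idx))
    stop("option index out of range")
  as.integer(idx)
}

#' Choice ratio between two options
#'
#' `P[a] / P[b]`, the summary used for single-attribute scans.
#'
#' @param dist A `choice_distribution`.
#' @param a,b Option indices or labels (numerator, denominator).
#' @return Numeric ratio.
#' @export
choice_ratio <- function(dist, a, b) {
  stopifnot(inherits(dist, "choice_distribution"))
  a <- resolve_option(dist, a); b <- resolve_option(dist, b)
  if (dist$probs[b] <= 0)
    stop("denominator option has zero choice probability")
  unname(dist$probs[a] / dist$probs[b])
}

#' Choice-probability difference between two options
#'
#' `P[a] - P[b]`, the summary used for multiattribute decoy and compromise
#' designs. Always lies in `[-1, 1]`.
#'
#' @inheritParams choice_ratio
#' @return Numeric difference.
#' @export
choice_difference <- function(dist, a, b) {
  stopifnot(inherits(dist, "choice_distribution"))
  a <- resolve_option(dist, a); b <- resolve_option(dist, b)
  unname(dist$probs[a] - dist$probs[b])
}
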