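## Core single-trial model: choice problems, Gaussian belief updating,
## incentive valuation, softmax choice.

#' Define a choice problem
#'
#' A choice problem is a matrix of reward amounts with one row per attribute
#' and one column per option. Single-attribute problems may be given as a
#' plain numeric vector of option rewards.
#'
#' @param rewards Numeric matrix (attributes x options) of reward amounts,
#'   or a numeric vector for a single-attribute problem. All cells must be
#'   finite.
#' @param attribute_labels Optional character vector of attribute names.
#' @param option_labels Optional character vector of option names.
#' @return An object of class `choice_problem`: the reward matrix with
#'   dimnames attached.
#' @examples
#' choice_problem(c(H = 10, L = 6))
#' choice_problem(cbind(A = c(1, 10), B = c(10, 1)),
#'                attribute_labels = c("price", "quality"))
#' @export
choice_problem <- function(rewards, attribute_labels = NULL,
                           option_labels = NULL) {
  if (is.vector(rewards) && is.numeric(rewards)) {
    option_labels <- option_labels %||% names(rewards)
    rewards <- matrix(rewards, nrow = 1)
  }
  if (!is.matrix(rewards) || !is.numeric(rewards))
    stop("`rewards` must be a numeric matrix (attributes x options) or vector")
  if (nrow(rewards) < 1L || ncol(rewards) < 1L)
    stop("a choice problem needs at least one attribute and one option")
  if (!all(is.finite(rewards)))
    stop("all reward amounts must be finite")
  rownames(rewards) <- attribute_labels %||% rownames(rewards) %||%
    paste0("attr", seq_len(nrow(rewards)))
  colnames(rewards) <- option_labels %||% colnames(rewards) %||%
    paste0("option", seq_len(ncol(rewards)))
  structure(rewards, class = c("choice_problem", "matrix", "array"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.choice_problem <- function(x, ...) {
  cat(sprintf("Choice problem: %d attribute(s) x %d option(s)\n",
              nrow(x), ncol(x)))
  print(unclass(x))
  invisible(x)
}

n_attributes <- function(problem) nrow(problem)
n_options <- function(problem) ncol(problem)

#' Model parameters for contextual valuation
#'
#' Per-attribute parameters of the generative model: the Gaussian prior over
#' each attribute's population-average reward (mean `prior_mean`, variance
#' `prior_var`), the reward noise `reward_var` around that average, and the
#' softmax inverse temperature `beta`. Scalar parameters are recycled across
#' attributes when the problem has several.
#'
#' @param prior_mean Numeric, prior mean of the average reward (per
#'   attribute or scalar). Default 0.
#' @param prior_var Positive numeric, prior variance. Default 1.
#' @param reward_var Positive numeric, reward variance. Default 1.
#' @param beta Non-negative scalar inverse temperature. Default 1.
#' @return An object of class `bcv_params`.
#' @examples
#' bcv_params(prior_mean = 0, prior_var = 1, reward_var = 0.1)
#' @export
bcv_params <- function(prior_mean = 0, prior_var = 1, reward_var = 1,
                       beta = 1) {
  stopifnot(is.numeric(prior_mean), is.numeric(prior_var),
            is.numeric(reward_var), is.numeric(beta), length(beta) == 1L)
  if (!all(is.finite(prior_mean)))
    stop("`prior_mean` must be finite")
  if (!all(is.finite(prior_var)) || any(prior_var <= 0))
    stop("`prior_var` must be a finite positive number")
  if (!all(is.finite(reward_var)) || any(reward_var <= 0))
    stop("`reward_var` must be a finite positive number")
  if (!is.finite(beta) || beta < 0)
    stop("`beta` must be a finite non-negative number")
  structure(list(prior_mean = prior_mean, prior_var = prior_var,
                 reward_var = reward_var, beta = beta),
            class = "bcv_params")
}

#' @export
print.bcv_params <- function(x, ...) {
  cat("Valuation model parameters:\n")
  cat("  prior mean  :", paste(x$prior_mean, collapse = ", "), "\n")
  cat("  prior var   :", paste(x$prior_var, collapse = ", "), "\n")
  cat("  reward var  :", paste(x$reward_var, collapse = ", "), "\n")
  cat("  inverse temp:", x$beta, "\n")
  invisible(x)
}

## Recycle per-attribute parameter vectors against a problem's attributes.
expand_params <- function(params, I) {
  for (f in c("prior_mean", "prior_var", "reward_var")) {
    v <- params[[f]]
    if (!length(v) %in% c(1L, I))
      stop(sprintf("`%s` must have length 1 or %d (one per attribute)", f, I))
    params[[f]] <- rep_len(v, I)
  }
  params
}

#' Expected value of options
#'
#' The expected value of an option is the sum of its reward amounts across
#' attributes.
#'
#' @param problem A [choice_problem()].
#' @param option Optional option index or label; if omitted, expected values
#'   of all options are returned.
#' @return Numeric vector (or scalar) of expected values.
#' @examples
#' expected_value(choice_problem(cbind(A = c(1, 10), B = c(10, 1))))
#' @export
expected_value <- function(problem, option = NULL) {
  stopifnot(inherits(problem, "choice_problem"))
  ev <- colSums(unclass(problem))
  if (is.null(option)) return(ev)
  if (is.character(option)) {
    if (!option %in% names(ev)) stop("unknown option label: ", option)
    return(ev[[option]])
  }
  if (!is.numeric(option) || length(option) != 1L || is.na(option) ||
      option < 1 || option > length(ev) || option != round(option))
    stop("`option` must be a valid option index or label")
  ev[[option]]
}

#' Precision weight (gain) of a Gaussian belief update
#'
#' The gain applied to a prediction error when a Gaussian prior with
#' variance `prior_var` is updated by an observation with noise variance
#' `obs_var`: `prior_var / (prior_var + obs_var)`. Always strictly inside
#' (0, 1) for finite positive variances; it grows with prior uncertainty and
#' shrinks with observation noise.
#'
#' @param prior_var Positive numeric, prior (current belief) variance.
#' @param obs_var Positive numeric, observation noise variance.
#' @return Numeric in (0, 1), vectorized over inputs.
#' @examples
#' bcv_gain(1, 1)    # 0.5
#' bcv_gain(1, 0.1)  # 0.909...
#' @export
bcv_gain <- function(prior_var, obs_var) {
  if (!is.numeric(prior_var) || !is.numeric(obs_var) ||
      !all(is.finite(prior_var)) || !all(is.finite(obs_var)) ||
      any(prior_var <= 0) || any(obs_var <= 0))
    stop("variances must be finite and strictly positive")
  prior_var / (prior_var + obs_var)
}

#' Gaussian belief about an attribute's average reward
#'
#' @param mean Numeric belief mean.
#' @param var Positive belief variance.
#' @return An object of class `belief_state`.
#' @export
belief_state <- function(mean = 0, var = 1) {
  stopifnot(is.numeric(mean), length(mean) == 1L,
            is.numeric(var), length(var) == 1L)
  if (!is.finite(mean)) stop("belief mean must be finite")
  if (!is.finite(var) || var <= 0) stop("belief variance must be positive")
  structure(list(mean = mean, var = var), class = "belief_state")
}

#' @export
print.belief_state <- function(x, ...) {
  cat(sprintf("Belief state: mean %.6g, variance %.6g\n", x$mean, x$var))
  invisible(x)
}

#' One belief update and its incentive value
#'
#' Updates a Gaussian belief about an attribute's average reward with one
#' observed reward amount. The incentive value attributed to the reward is
#' the precision-weighted prediction error `g * (reward - mean)`, with
#' `g = bcv_gain(var, reward_var)`; the posterior mean is the prior mean
#' plus that value and the posterior variance contracts to `var - g * var`.
#'
#' @param state A [belief_state()].
#' @param reward Finite numeric reward amount.
#' @param reward_var Positive reward noise variance.
#' @return A list with elements `state` (the posterior [belief_state()]) and
#'   `value` (the incentive value of `reward`).
#' @examples
#' update_belief(belief_state(0, 1), reward = 10, reward_var = 0.1)
#' @export
update_belief <- function(state, reward, reward_var) {
  stopifnot(inherits(state, "belief_state"))
  if (!is.numeric(reward) || length(reward) != 1L || !is.finite(reward))
    stop("`reward` must be a single finite number")
  g <- bcv_gain(state$var, reward_var)
  value <- g * (reward - state$mean)
  list(state = belief_state(state$mean + value, state$var - g * state$var),
       value = value)
}

#' Presentation orders for a choice problem
#'
#' Sequential updating considers one option's reward at a time, in an order
#' that may differ between attributes. An order set is an integer matrix with
#' one row per attribute; row `i` is the permutation of option indices giving
#' the order in which attribute `i`'s rewards are considered.
#' `random_orders()` draws each row independently and uniformly over all
#' permutations.
#'
#' @param problem A [choice_problem()].
#' @return Integer matrix (attributes x options).
#' @examples
#' set.seed(1); random_orders(choice_problem(cbind(c(1, 10), c(10, 1))))
#' @export
random_orders <- function(problem) {
  stopifnot(inherits(problem, "choice_problem"))
  N <- n_options(problem)
  t(vapply(seq_len(n_attributes(problem)),
           function(i) sample.int(N), integer(N)))
}

check_orders <- function(orders, I, N) {
  if (!is.matrix(orders) || nrow(orders) != I || ncol(orders) != N)
    stop(sprintf("`orders` must be a %d x %d matrix of option indices", I, N))
  for (i in seq_len(I))
    if (!identical(sort(as.integer(orders[i, ])), seq_len(N)))
      stop("each row of `orders` must be a permutation of 1..", N)
  invisible(orders)
}

#' Evaluate a choice set under given presentation orders
#'
#' For each attribute independently, starts from the attribute's prior
#' belief and applies [update_belief()] to each option's reward in the given
#' order, recording the incentive value generated at each step. The value of
#' an option is the sum, over attributes, of the incentive values of its
#' rewards. Deterministic given `orders`.
#'
#' @param problem A [choice_problem()].
#' @param params A [bcv_params()].
#' @param orders Order matrix as returned by [random_orders()]; defaults to
#'   a freshly drawn random order set.
#' @return An object of class `valuation_trace`: a list with `orders`,
#'   `step_values` (attributes x steps incentive values, in presentation
#'   order), `value_by_option` (attributes x options), `option_values`
#'   (summed per option), and `final_beliefs` (list of [belief_state()]s).
#' @examples
#' pr <- choice_problem(c(10, 6))
#' evaluate_option_set(pr, bcv_params(reward_var = 0.1),
#'                     orders = matrix(c(1L, 2L), 1))
#' @export
evaluate_option_set <- function(problem, params, orders = random_orders(problem)) {
  stopifnot(inherits(problem, "choice_problem"), inherits(params, "bcv_params"))
  I <- n_attributes(problem); N <- n_options(problem)
  check_orders(orders, I, N)
  params <- expand_params(params, I)
  step_values <- matrix(NA_real_, I, N)
  value_by_option <- matrix(0, I, N,
                            dimnames = dimnames(unclass(problem)))
  final_beliefs <- vector("list", I)
  for (i in seq_len(I)) {
    st <- belief_state(params$prior_mean[i], params$prior_var[i])
    for (t in seq_len(N)) {
      n <- orders[i, t]
      up <- update_belief(st, problem[i, n], params$reward_var[i])
      st <- up$state
      step_values[i, t] <- up$value
      value_by_option[i, n] <- up$value
    }
    final_beliefs[[i]] <- st
  }
  structure(list(orders = orders, step_values = step_values,
                 value_by_option = value_by_option,
                 option_values = colSums(value_by_option),
                 final_beliefs = final_beliefs),
            class = "valuation_trace")
}

#' @export
print.valuation_trace <- function(x, ...) {
  cat("Valuation trace\n  option values:\n")
  print(round(x$option_values, 6))
  cat("  incentive values by (attribute, option):\n")
  print(round(x$value_by_option, 6))
  invisible(x)
}

#' Softmax choice distribution
#'
#' Choice probabilities proportional to `exp(beta * value)`, computed with
#' max-subtraction for overflow safety. `beta = 0` yields the uniform
#' distribution.
#'
#' @param option_values Finite numeric vector of option values.
#' @param beta Non-negative scalar inverse temperature.
#' @return An object of class `choice_distribution` with fields `probs`,
#'   `stderr` (zeros: the computation is exact) and `method` (`"exact"`).
#' @examples
#' softmax_choice(c(9.09, -1.47), beta = 1)
#' @export
softmax_choice <- function(option_values, beta = 1) {
  if (!is.numeric(option_values) || length(option_values) < 1L)
    stop("`option_values` must be a non-empty numeric vector")
  if (!all(is.finite(option_values)))
    stop("option values must be finite")
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta) || beta < 0)
    stop("`beta` must be a finite non-negative number")
  z <- beta * option_values
  p <- exp(z - max(z))
  choice_distribution(p / sum(p), stderr = rep(0, length(p)),
                      method = "exact", labels = names(option_values))
}

choice_distribution <- function(probs, stderr, method, labels = NULL,
                                n_trials = NA_integer_) {
  probs <- as.numeric(probs)
  if (!is.null(labels)) names(probs) <- labels
  structure(list(probs = probs, stderr = as.numeric(stderr),
                 method = method, n_trials = n_trials),
            class = "choice_distribution")
}

#' @export
print.choice_distribution <- function(x, digits = 6, ...) {
  cat(sprintf("Choice distribution (%s%s):\n", x$method,
              if (is.na(x$n_trials)) "" else
                sprintf(", %d trials", x$n_trials)))
  m <- rbind(prob = round(x$probs, digits), stderr = round(x$stderr, digits))
  print(m)
  invisible(x)
}
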