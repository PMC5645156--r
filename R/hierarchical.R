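## Between-choice contextual valuation: a contextual observation (at one
## level, or at two hierarchical levels) shifts reward expectation before a
## reward arrives, and the incentive value is the precision-weighted
## prediction error with respect to that shifted expectation.

#' Single-level contextual model
#'
#' Generative model for one attribute with a contextual cue: the population
#' average `C` has a zero-mean Gaussian prior with variance `prior_var`; a
#' contextual observation `O` is `C` plus noise of variance
#' `context_obs_var`; the reward is `C` plus noise of variance `reward_var`.
#'
#' @param prior_var Positive prior variance (default 1).
#' @param context_obs_var Positive context-observation variance (default 1).
#' @param reward_var Positive reward variance (default 1).
#' @param prior_mean Prior mean; the canonical model fixes it at 0, a
#'   nonzero mean is accepted as a generalization.
#' @return An object of class `single_level_context_model`.
#' @export
single_level_context_model <- function(prior_var = 1, context_obs_var = 1,
                                       reward_var = 1, prior_mean = 0) {
  for (v in c(prior_var, context_obs_var, reward_var))
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("all variances must be finite and strictly positive")
  if (!is.numeric(prior_mean) || !is.finite(prior_mean))
    stop("`prior_mean` must be finite")
  structure(list(prior_var = prior_var, context_obs_var = context_obs_var,
                 reward_var = reward_var, prior_mean = prior_mean),
            class = "single_level_context_model")
}

#' Incentive value given a single-level contextual observation
#'
#' The context posterior after observing `O` has mean
#' `mu + g_O * (O - mu)` with `g_O = bcv_gain(prior_var, context_obs_var)`
#' and contracted variance; the incentive value of a subsequent reward `R`
#' is the precision-weighted prediction error with respect to that
#' posterior. A larger contextual cue therefore lowers the value of the
#' same reward (subtractive normalization), and a smaller reward variance
#' magnifies it (divisive normalization).
#'
#' @param O Contextual observation (finite scalar).
#' @param R Reward amount(s); vectorized.
#' @param model A [single_level_context_model()].
#' @return A list with `value` (incentive value(s) of `R`),
#'   `context_belief` (the [belief_state()] for the population average
#'   after `O`), and `posterior` (after `O` and the first element of `R`).
#' @examples
#' single_level_value(O = 4, R = 4,
#'   single_level_context_model(1, 1, 0.5))  # value 1
#' @export
single_level_value <- function(O, R, model) {
  stopifnot(inherits(model, "single_level_context_model"))
  if (!is.numeric(O) || length(O) != 1L || !is.finite(O))
    stop("`O` must be a single finite number")
  if (!is.numeric(R) || !all(is.finite(R)))
    stop("`R` must be finite")
  g_O <- bcv_gain(model$prior_var, model$context_obs_var)
  ctx_mean <- model$prior_mean + g_O * (O - model$prior_mean)
  ctx_var <- model$prior_var - g_O * model$prior_var
  g_R <- bcv_gain(ctx_var, model$reward_var)
  value <- g_R * (R - ctx_mean)
  list(value = value,
       context_belief = belief_state(ctx_mean, ctx_var),
       posterior = belief_state(ctx_mean + value[1L],
                                ctx_var - g_R * ctx_var))
}

#' Two-level hierarchical contextual model
#'
#' A high-level context (mean zero, variance `var_hc`) generates a noisy
#' high-level observation (`var_ho`) and the mean of a low-level context
#' (`var_lc`), which in turn generates a noisy low-level observation
#' (`var_lo`) and the reward (`var_r`).
#'
#' @param var_hc,var_ho,var_lc,var_lo,var_r Positive variances of the
#'   high-level context, high-level observation, low-level context,
#'   low-level observation and reward (defaults 1).
#' @return An object of class `hierarchical_context_model`.
#' @export
hierarchical_context_model <- function(var_hc = 1, var_ho = 1, var_lc = 1,
                                       var_lo = 1, var_r = 1) {
  vars <- c(var_hc = var_hc, var_ho = var_ho, var_lc = var_lc,
            var_lo = var_lo, var_r = var_r)
  if (!is.numeric(vars) || !all(is.finite(vars)) || any(vars <= 0))
    stop("all variances must be finite and strictly positive")
  structure(as.list(vars), class = "hierarchical_context_model")
}

#' Normalization factors of the hierarchical model
#'
#' Sequentially propagating the two contextual observations through the
#' hierarchy yields an incentive value of the closed form
#' `V(R) = K * (R - tau_lo * LO - tau_ho * HO)`: two subtractive
#' normalization weights `tau_lo` and `tau_ho` (the relative precision of
#' the low- and high-level observations) and a divisive gain `K`. All three
#' lie strictly inside (0, 1) for finite positive variances; `tau_lo -> 1`
#' and `tau_ho -> 0` as the low-level observation becomes exact (it then
#' screens the reward expectation off from the high level), and `K` shrinks
#' as reward variance grows.
#'
#' @param model A [hierarchical_context_model()].
#' @return An object of class `normalization_factors`: list with `tau_lo`,
#'   `tau_ho`, `k`, and the intermediate posterior variances
#'   `var_hc_post`, `var_lc_given_ho`, `var_lc_given_ho_lo`.
#' @examples
#' hierarchical_factors(hierarchical_context_model())  # 0.6, 0.2, 0.375
#' @export
hierarchical_factors <- function(model) {
  stopifnot(inherits(model, "hierarchical_context_model"))
  g_hc <- bcv_gain(model$var_hc, model$var_ho)
  var_hc_post <- model$var_hc - g_hc * model$var_hc
  var_lc_given_ho <- var_hc_post + model$var_lc
  g_lo <- bcv_gain(var_lc_given_ho, model$var_lo)
  var_lc_given_ho_lo <- var_lc_given_ho - g_lo * var_lc_given_ho
  structure(list(
    tau_lo = g_lo,
    tau_ho = (model$var_lo / (var_lc_given_ho + model$var_lo)) * g_hc,
    k = bcv_gain(var_lc_given_ho_lo, model$var_r),
    var_hc_post = var_hc_post,
    var_lc_given_ho = var_lc_given_ho,
    var_lc_given_ho_lo = var_lc_given_ho_lo),
    class = "normalization_factors")
}

#' @export
print.normalization_factors <- function(x, ...) {
  cat(sprintf(paste0("Normalization factors: tau_lo = %.6g, ",
                     "tau_ho = %.6g, K = %.6g\n"), x$tau_lo, x$tau_ho, x$k))
  invisible(x)
}

#' Incentive value under the hierarchical contextual model
#'
#' `K * (R - tau_lo * LO - tau_ho * HO)` with factors from
#' [hierarchical_factors()]. `method = "sequential"` instead performs the
#' level-by-level posterior updates explicitly and takes the final
#' precision-weighted prediction error; the two routes are algebraically
#' identical and agree to machine precision.
#'
#' @param HO,LO High- and low-level contextual observations (finite
#'   scalars).
#' @param R Reward amount(s); vectorized.
#' @param model A [hierarchical_context_model()].
#' @param method `"closed_form"` (default) or `"sequential"`.
#' @return Numeric incentive value(s), linear in `R` with slope `K`.
#' @examples
#' hierarchical_value(HO = 2, LO = 4, R = 6,
#'                    hierarchical_context_model())  # 1.2
#' @export
hierarchical_value <- function(HO, LO, R, model,
                               method = c("closed_form", "sequential")) {
  stopifnot(inherits(model, "hierarchical_context_model"))
  method <- match.arg(method)
  for (v in c(HO, LO))
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("`HO` and `LO` must be single finite numbers")
  if (!is.numeric(R) || !all(is.finite(R))) stop("`R` must be finite")
  if (method == "closed_form") {
    f <- hierarchical_factors(model)
    return(f$k * (R - f$tau_lo * LO - f$tau_ho * HO))
  }
  ## explicit sequential inference down the hierarchy
  g_hc <- bcv_gain(model$var_hc, model$var_ho)
  mu_hc <- g_hc * HO
  var_hc_post <- model$var_hc - g_hc * model$var_hc
  mu_lc <- mu_hc
  var_lc <- var_hc_post + model$var_lc
  g_lo <- bcv_gain(var_lc, model$var_lo)
  mu_lc2 <- mu_lc + g_lo * (LO - mu_lc)
  var_lc2 <- var_lc - g_lo * var_lc
  bcv_gain(var_lc2, model$var_r) * (R - mu_lc2)
}

#' Define a between-choice context scenario
#'
#' A scenario is a set of named contexts, each a list of the rewards it can
#' deliver. One-level scenarios are a named list of numeric reward vectors;
#' two-level scenarios are a named list of high-level contexts, each itself
#' a named list of low-level reward vectors.
#'
#' @param contexts Named list as described above.
#' @return An object of class `context_scenario` with a `levels` attribute
#'   (1 or 2).
#' @examples
#' context_scenario(list(LA = c(-1.5, -0.5, 0.5), HA = c(-0.5, 0.5, 1.5)))
#' @export
context_scenario <- function(contexts) {
  if (!is.list(contexts) || length(contexts) == 0L ||
      is.null(names(contexts)) || any(names(contexts) == ""))
    stop("`contexts` must be a non-empty named list")
  two_level <- all(vapply(contexts, is.list, logical(1)))
  if (two_level) {
    for (hl in contexts)
      for (ll in hl)
        if (!is.numeric(ll) || length(ll) == 0L || !all(is.finite(ll)))
          stop("every low-level context needs a non-empty finite reward list")
  } else {
    for (ctx in contexts)
      if (!is.numeric(ctx) || length(ctx) == 0L || !all(is.finite(ctx)))
        stop("every context needs a non-empty finite reward list")
  }
  structure(list(contexts = contexts),
            class = "context_scenario", levels = if (two_level) 2L else 1L)
}

#' Canonical scenarios
#'
#' Three ready-made scenarios over a base reward `x`:
#' \describe{
#'   \item{`scenario_mean_shift()`}{two contexts with shifted averages,
#'     `{x, x+1, x+2}` versus `{x+1, x+2, x+3}`; the model attributes
#'     larger values to the shared rewards in the lower-average context.}
#'   \item{`scenario_variance()`}{a high-variance context
#'     `{x, x+1, x+2, x+3}` versus a low-variance one `{x+1, x+2}` with the
#'     same average; the model stretches values apart in the low-variance
#'     context (the smaller of the two shared rewards is valued lower
#'     there, the larger one higher).}
#'   \item{`scenario_two_level()`}{two high-level contexts each alternating
#'     two low-level contexts (low/medium average versus medium/high);
#'     values integrate both levels, lowest when both are high-average and
#'     highest when both are low-average.}
#' }
#' The default `x = -1.5` centres the reward lists on the model's zero
#' prior mean, so contexts straddle the prior expectation.
#'
#' @param x Base reward (default -1.5).
#' @return A [context_scenario()].
#' @export
scenario_mean_shift <- function(x = -1.5) {
  context_scenario(list(LA = x + 0:2, HA = x + 1:3))
}

#' @rdname scenario_mean_shift
#' @export
scenario_variance <- function(x = -1.5) {
  context_scenario(list(HV = x + 0:3, LV = x + 1:2))
}

#' @rdname scenario_mean_shift
#' @export
scenario_two_level <- function(x = -1.5) {
  context_scenario(list(
    HL_LA = list(LL_LA = x + 0:2, LL_MA = x + 1:3),
    HL_HA = list(LL_MA = x + 1:3, LL_HA = x + 2:4)))
}

population_var <- function(x) mean((x - mean(x))^2)

#' Incentive values predicted for a context scenario
#'
#' Maps every context to a contextual observation (the mean of its reward
#' list) and a reward variance (the population variance of the list,
#' floored at `var_floor`), then evaluates the incentive value of each
#' reward in each context with [single_level_value()] (one-level
#' scenarios) or [hierarchical_value()] (two-level scenarios, where the
#' high-level observation is the mean over all rewards of the high-level
#' context). Only the ordinal pattern of the output is meaningful; the
#' mapping from reward lists to observations is a modelling convention.
#'
#' @param scenario A [context_scenario()].
#' @param prior_var Context prior variance(s) (default 1; for two-level
#'   scenarios used for both context levels).
#' @param obs_var Observation variance at each level (default 1).
#' @param var_floor Lower bound for the mapped reward variance
#'   (default 0.01).
#' @return A data frame with columns `context` (and `hl_context`,
#'   `ll_context` for two-level scenarios), `reward`, `value`.
#' @examples
#' scenario_predictions(scenario_mean_shift())
#' @export
scenario_predictions <- function(scenario, prior_var = 1, obs_var = 1,
                                 var_floor = 0.01) {
  stopifnot(inherits(scenario, "context_scenario"))
  if (attr(scenario, "levels") == 1L) {
    out <- lapply(names(scenario$contexts), function(nm) {
      rewards <- scenario$contexts[[nm]]
      model <- single_level_context_model(
        prior_var = prior_var, context_obs_var = obs_var,
        reward_var = max(population_var(rewards), var_floor))
      data.frame(context = nm, reward = rewards,
                 value = single_level_value(mean(rewards), rewards,
                                            model)$value)
    })
    return(do.call(rbind, out))
  }
  out <- list()
  for (hl in names(scenario$contexts)) {
    lls <- scenario$contexts[[hl]]
    HO <- mean(unlist(lls))
    for (ll in names(lls)) {
      rewards <- lls[[ll]]
      model <- hierarchical_context_model(
        var_hc = prior_var, var_ho = obs_var, var_lc = prior_var,
        var_lo = obs_var,
        var_r = max(population_var(rewards), var_floor))
      out[[length(out) + 1L]] <- data.frame(
        hl_context = hl, ll_context = ll,
        context = paste(hl, ll, sep = ":"), reward = rewards,
        value = hierarchical_value(HO, mean(rewards), rewards, model))
    }
  }
  do.call(rbind, out)
}
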