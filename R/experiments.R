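## Experiment drivers: parameter-grid scans over the canonical within-choice
## context-effect designs, returning tidy long-format tables.

result_columns <- c("experiment", "mu_C", "sigma_R2", "sigma_C2", "beta",
                    "metric", "value", "stderr", "method", "n_trials", "seed")

## One driver cell: choice distribution by enumeration or seeded MC. MC cells
## get distinct seeds derived by offsetting the configured seed, so a grid is
## reproducible without being perfectly correlated across cells.
cell_dist <- function(problem, params, method, config, cell) {
  if (method == "exact")
    return(exact_choice_probs(problem, params, config$enumeration_limit))
  seed <- if (is.null(config$seed)) NULL else
    (config$seed + cell) %% .Machine$integer.max
  mc_choice_probs(problem, params,
                  engine_config(config$n_trials, seed, config$mc_mode,
                                config$enumeration_limit))
}

new_experiment <- function(df, experiment, method, config, extra_cols,
                           manifest = list()) {
  df$experiment <- experiment
  df$method <- if (method == "exact") "exact" else config$mc_mode
  df$n_trials <- if (method == "exact") NA_integer_ else config$n_trials
  df$seed <- if (method == "exact" || is.null(config$seed)) NA_integer_
             else config$seed
  df <- df[, c("experiment", extra_cols,
               setdiff(result_columns, c("experiment", extra_cols)))]
  structure(df, class = c("bcv_experiment", "data.frame"),
            manifest = c(list(experiment = experiment, method = df$method[1L],
                              package_version = as.character(
                                utils::packageVersion("bcv"))),
                         manifest))
}

check_grid <- function(values, name) {
  if (!is.numeric(values) || length(values) < 1L || anyNA(values))
    stop("`", name, "` must be a non-empty numeric grid")
  if (length(values) > 1L && any(diff(values) <= 0))
    stop("`", name, "` must be strictly increasing")
  values
}

#' Two-option scan over prior mean and reward uncertainty
#'
#' Single-attribute choice between a better option (reward `R_H`) and a
#' worse option (reward `R_L`). For every prior mean in `mu_grid` and every
#' reward variance in `reward_vars`, computes the choice ratio
#' `P[H] / P[L]`. The ratio is a bell-shaped function of the prior mean,
#' peaking at `(R_H + R_L) / 2`, and flattens as reward uncertainty grows.
#'
#' @param R_H,R_L Rewards of the better and worse option (`R_H > R_L`);
#'   defaults 10 and 6.
#' @param mu_grid Strictly increasing grid of prior means (default
#'   `seq(-6, 14, by = 0.5)`, spanning both rewards).
#' @param reward_vars Reward variances to scan (default `c(0.1, 1, 10)`).
#' @param prior_var Prior variance (default 1).
#' @param beta Inverse temperature (default 1).
#' @param method `"exact"` (order enumeration) or `"mc"`.
#' @param config An [engine_config()] used when `method = "mc"`.
#' @return A `bcv_experiment` data frame with metric `"ratio"`.
#' @export
run_binary_scan <- function(R_H = 10, R_L = 6,
                            mu_grid = seq(-6, 14, by = 0.5),
                            reward_vars = c(0.1, 1, 10),
                            prior_var = 1, beta = 1,
                            method = c("exact", "mc"),
                            config = engine_config()) {
  method <- match.arg(method)
  if (R_H <= R_L) stop("`R_H` must exceed `R_L`")
  check_grid(mu_grid, "mu_grid"); check_grid(reward_vars, "reward_vars")
  problem <- choice_problem(c(H = R_H, L = R_L))
  grid <- expand.grid(mu_C = mu_grid, sigma_R2 = reward_vars)
  rows <- lapply(seq_len(nrow(grid)), function(k) {
    params <- bcv_params(grid$mu_C[k], prior_var, grid$sigma_R2[k], beta)
    d <- cell_dist(problem, params, method, config, k)
    data.frame(mu_C = grid$mu_C[k], sigma_R2 = grid$sigma_R2[k],
               sigma_C2 = prior_var, beta = beta, metric = "ratio",
               value = choice_ratio(d, "H", "L"),
               stderr = ratio_stderr(d, "H", "L"))
  })
  new_experiment(do.call(rbind, rows), "binary-scan", method, config,
                 character(0),
                 list(R_H = R_H, R_L = R_L, mu_grid = mu_grid,
                      reward_vars = reward_vars, sigma_C2 = prior_var,
                      beta = beta))
}

## Delta-method standard error for P[a]/P[b]; zero for exact distributions.
ratio_stderr <- function(dist, a, b) {
  a <- resolve_option(dist, a); b <- resolve_option(dist, b)
  if (all(dist$stderr == 0)) return(0)
  r <- dist$probs[a] / dist$probs[b]
  r * sqrt((dist$stderr[a] / dist$probs[a])^2 +
           (dist$stderr[b] / dist$probs[b])^2)
}

#' Three-option scan over a third option's reward
#'
#' Single-attribute choice among the two targets (`R_H`, `R_L`) and a third
#' option with reward `R_3` drawn from `r3_grid`. Reports the target choice
#' ratio `P[H] / P[L]` per `(R_3, mu_C)` cell. With small reward variance
#' the ratio is a U-shaped function of `R_3`; with large reward variance the
#' third option barely matters.
#'
#' @inheritParams run_binary_scan
#' @param r3_grid Grid of third-option rewards (default `seq(0, 10, 0.5)`).
#' @param mu_grid Prior means to scan (default `c(-2, 0, 2)`).
#' @param reward_var Single reward variance (default 0.1).
#' @return A `bcv_experiment` data frame with grid column `R_3` and metric
#'   `"ratio"`.
#' @export
run_trinary_scan <- function(R_H = 10, R_L = 6,
                             r3_grid = seq(0, 10, by = 0.5),
                             mu_grid = c(-2, 0, 2),
                             reward_var = 0.1,
                             prior_var = 1, beta = 1,
                             method = c("exact", "mc"),
                             config = engine_config()) {
  method <- match.arg(method)
  if (R_H <= R_L) stop("`R_H` must exceed `R_L`")
  check_grid(r3_grid, "r3_grid"); check_grid(mu_grid, "mu_grid")
  grid <- expand.grid(R_3 = r3_grid, mu_C = mu_grid)
  rows <- lapply(seq_len(nrow(grid)), function(k) {
    problem <- choice_problem(c(H = R_H, L = R_L, third = grid$R_3[k]))
    params <- bcv_params(grid$mu_C[k], prior_var, reward_var, beta)
    d <- cell_dist(problem, params, method, config, k)
    data.frame(R_3 = grid$R_3[k], mu_C = grid$mu_C[k],
               sigma_R2 = reward_var, sigma_C2 = prior_var, beta = beta,
               metric = "ratio", value = choice_ratio(d, "H", "L"),
               stderr = ratio_stderr(d, "H", "L"))
  })
  new_experiment(do.call(rbind, rows), "trinary-scan", method, config, "R_3",
                 list(R_H = R_H, R_L = R_L, r3_grid = r3_grid,
                      mu_grid = mu_grid, sigma_R2 = reward_var,
                      sigma_C2 = prior_var, beta = beta))
}

#' Decoy grid for two-attribute choice
#'
#' Two-attribute (price/quality) choice between targets A and B plus a
#' third option K whose attribute rewards range over a grid. Reports
#' `P[A] - P[B]` per K position. With the default symmetric targets
#' `A = (1, 10)` and `B = (10, 1)` the surface is antisymmetric about the
#' diagonal; its sign structure locates the similarity- and attraction-type
#' context effects (see [decoy_probe_effects()]).
#'
#' @param A,B Length-2 reward vectors `(price, quality)` for the two
#'   targets; defaults `c(1, 10)` and `c(10, 1)`.
#' @param k_p_grid,k_q_grid Grids for K's price and quality rewards
#'   (default `seq(1, 10, 0.5)`).
#' @param mu_C Prior mean shared by both attributes (default 0).
#' @param reward_var Reward variance shared by both attributes
#'   (default 0.1).
#' @inheritParams run_binary_scan
#' @return A `bcv_experiment` data frame with grid columns `R_p_K`,
#'   `R_q_K` and metric `"difference"`.
#' @export
run_decoy_grid <- function(A = c(1, 10), B = c(10, 1),
                           k_p_grid = seq(1, 10, by = 0.5),
                           k_q_grid = seq(1, 10, by = 0.5),
                           mu_C = 0, reward_var = 0.1,
                           prior_var = 1, beta = 1,
                           method = c("exact", "mc"),
                           config = engine_config()) {
  method <- match.arg(method)
  if (length(A) != 2L || length(B) != 2L)
    stop("the decoy design uses exactly two attributes")
  check_grid(k_p_grid, "k_p_grid"); check_grid(k_q_grid, "k_q_grid")
  params <- bcv_params(mu_C, prior_var, reward_var, beta)
  grid <- expand.grid(R_p_K = k_p_grid, R_q_K = k_q_grid)
  rows <- lapply(seq_len(nrow(grid)), function(k) {
    problem <- choice_problem(
      cbind(A = A, B = B, K = c(grid$R_p_K[k], grid$R_q_K[k])),
      attribute_labels = c("price", "quality"))
    d <- cell_dist(problem, params, method, config, k)
    se <- if (all(d$stderr == 0)) 0 else
      sqrt(d$stderr[1L]^2 + d$stderr[2L]^2)
    data.frame(R_p_K = grid$R_p_K[k], R_q_K = grid$R_q_K[k], mu_C = mu_C,
               sigma_R2 = reward_var, sigma_C2 = prior_var, beta = beta,
               metric = "difference", value = choice_difference(d, "A", "B"),
               stderr = se)
  })
  new_experiment(do.call(rbind, rows), "decoy-grid", method, config,
                 c("R_p_K", "R_q_K"),
                 list(A = A, B = B, k_p_grid = k_p_grid, k_q_grid = k_q_grid,
                      mu_C = mu_C, sigma_R2 = reward_var,
                      sigma_C2 = prior_var, beta = beta))
}

#' Context-effect probes on the decoy surface
#'
#' Samples `P[A] - P[B]` at four probe decoys that sit in the surface's
#' four signed regions under the default targets `A = (1, 10)`,
#' `B = (10, 1)`:
#' \describe{
#'   \item{`near_A` = (2, 9), `near_B` = (9, 2)}{decoys adjacent to one
#'     target in attribute space (similarity-type regions); the model
#'     favours the adjacent target, so the difference is positive at
#'     `near_A` and negative at `near_B`.}
#'   \item{`dominated_by_B` = (5, 1), `dominated_by_A` = (1, 5)}{decoys
#'     dominated by one target (attraction-type regions); the model favours
#'     the opposite target, so the difference is positive at
#'     `dominated_by_B` and negative at `dominated_by_A`.}
#' }
#' The prior mean shifts the balance between the two effect types (the
#' dominated-pair magnitudes dominate at low `mu_C`, the near-pair
#' magnitudes at high `mu_C`) and both shrink as `reward_var` grows.
#'
#' @inheritParams run_decoy_grid
#' @return A data frame with columns `probe`, `effect`
#'   (`"similarity"`/`"attraction"`), `R_p_K`, `R_q_K`, `value`, `stderr`.
#' @export
decoy_probe_effects <- function(A = c(1, 10), B = c(10, 1), mu_C = 0,
                                reward_var = 0.1, prior_var = 1, beta = 1,
                                method = c("exact", "mc"),
                                config = engine_config()) {
  method <- match.arg(method)
  probes <- data.frame(
    probe = c("near_A", "near_B", "dominated_by_B", "dominated_by_A"),
    effect = c("similarity", "similarity", "attraction", "attraction"),
    R_p_K = c(2, 9, 5, 1),
    R_q_K = c(9, 2, 1, 5))
  params <- bcv_params(mu_C, prior_var, reward_var, beta)
  vals <- lapply(seq_len(nrow(probes)), function(k) {
    problem <- choice_problem(
      cbind(A = A, B = B, K = c(probes$R_p_K[k], probes$R_q_K[k])),
      attribute_labels = c("price", "quality"))
    d <- cell_dist(problem, params, method, config, k)
    se <- if (all(d$stderr == 0)) 0 else
      sqrt(d$stderr[1L]^2 + d$stderr[2L]^2)
    c(choice_difference(d, "A", "B"), se)
  })
  probes$value <- vapply(vals, `[`, numeric(1), 1L)
  probes$stderr <- vapply(vals, `[`, numeric(1), 2L)
  probes
}

#' Compromise design: intermediate option versus extremes
#'
#' Two-attribute options `A = (5 - d, 5 + d)`, `B = (5 + d, 5 - d)` and the
#' intermediate `K = (5, 5)`, with the proximity parameter `d` scanned over
#' `d_grid`. Reports, per `(d, mu_C, sigma_R2)` cell, the binary control
#' `P[K | A, K] - P[A | A, K]` (identically zero under enumeration, by
#' symmetry of the order-averaged value differences) and the trinary
#' difference `P[K | A, B, K] - P[A | A, B, K]`, which grows with `d` for
#' small reward variance.
#'
#' @param d_grid Grid of proximity parameters in `[0, 4]`
#'   (default `seq(0, 4, 0.5)`).
#' @param reward_vars Reward variances to scan (default `c(0.1, 1, 10)`).
#' @param mu_values Prior means to scan (default `c(-2, 0, 2)`).
#' @param include_binary Also compute the binary control (default TRUE).
#' @inheritParams run_binary_scan
#' @return A `bcv_experiment` data frame with grid column `d` and metrics
#'   `"binary_difference"` and `"trinary_difference"`.
#' @export
run_compromise <- function(d_grid = seq(0, 4, by = 0.5),
                           reward_vars = c(0.1, 1, 10),
                           mu_values = c(-2, 0, 2),
                           include_binary = TRUE,
                           prior_var = 1, beta = 1,
                           method = c("exact", "mc"),
                           config = engine_config()) {
  method <- match.arg(method)
  check_grid(d_grid, "d_grid")
  if (any(d_grid < 0 | d_grid > 4))
    stop("`d_grid` values must lie in [0, 4]")
  check_grid(reward_vars, "reward_vars")
  grid <- expand.grid(d = d_grid, mu_C = sort(mu_values),
                      sigma_R2 = reward_vars)
  rows <- lapply(seq_len(nrow(grid)), function(k) {
    d <- grid$d[k]
    params <- bcv_params(grid$mu_C[k], prior_var, grid$sigma_R2[k], beta)
    A <- c(5 - d, 5 + d); B <- c(5 + d, 5 - d); K <- c(5, 5)
    out <- list()
    if (include_binary) {
      pb <- choice_problem(cbind(A = A, K = K),
                           attribute_labels = c("price", "quality"))
      db <- cell_dist(pb, params, method, config, k)
      out$binary <- data.frame(
        d = d, mu_C = grid$mu_C[k], sigma_R2 = grid$sigma_R2[k],
        sigma_C2 = prior_var, beta = beta, metric = "binary_difference",
        value = choice_difference(db, "K", "A"),
        stderr = if (all(db$stderr == 0)) 0 else
          sqrt(sum(db$stderr^2)))
    }
    pt <- choice_problem(cbind(A = A, B = B, K = K),
                         attribute_labels = c("price", "quality"))
    dt <- cell_dist(pt, params, method, config, k + nrow(grid))
    out$trinary <- data.frame(
      d = d, mu_C = grid$mu_C[k], sigma_R2 = grid$sigma_R2[k],
      sigma_C2 = prior_var, beta = beta, metric = "trinary_difference",
      value = choice_difference(dt, "K", "A"),
      stderr = if (all(dt$stderr == 0)) 0 else
        sqrt(dt$stderr[3L]^2 + dt$stderr[1L]^2))
    do.call(rbind, out)
  })
  new_experiment(do.call(rbind, rows), "compromise", method, config, "d",
                 list(d_grid = d_grid, reward_vars = reward_vars,
                      mu_values = mu_values, include_binary = include_binary,
                      sigma_C2 = prior_var, beta = beta))
}

#' @export
print.bcv_experiment <- function(x, ...) {
  man <- attr(x, "manifest")
  cat(sprintf("<bcv_experiment: %s, %d cells, method %s>\n",
              man$experiment, nrow(x), man$method))
  print(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...", nrow(x) - 6, "more rows\n")
  invisible(x)
}

#' Quick-look plot of an experiment result
#'
#' Line plots of the metric against the scanned variable (grouped by prior
#' mean and reward variance) for scans, or a signed image of the surface for
#' the decoy grid. Base-graphics diagnostics, not publication figures.
#'
#' @param x A `bcv_experiment`.
#' @param ... Passed to the underlying base-graphics call.
#' @return `x`, invisibly.
#' @export
plot.bcv_experiment <- function(x, ...) {
  man <- attr(x, "manifest")
  df <- as.data.frame(x)
  if (man$experiment == "decoy-grid") {
    zp <- sort(unique(df$R_p_K)); zq <- sort(unique(df$R_q_K))
    z <- matrix(df$value[order(df$R_q_K, df$R_p_K)], length(zp), length(zq))
    lim <- max(abs(z))
    graphics::image(zp, zq, z, xlab = "decoy price reward",
                    ylab = "decoy quality reward",
                    main = "P[A] - P[B]", zlim = c(-lim, lim),
                    col = grDevices::hcl.colors(64, "Blue-Red 2"), ...)
    graphics::contour(zp, zq, z, add = TRUE, levels = 0)
    return(invisible(x))
  }
  xvar <- switch(man$experiment,
                 "binary-scan" = "mu_C", "trinary-scan" = "R_3",
                 "compromise" = "d", names(df)[2L])
  groups <- interaction(df$metric, df$mu_C, df$sigma_R2, drop = TRUE)
  xs <- sort(unique(df[[xvar]]))
  ys <- sapply(split(df, groups), function(g) g$value[order(g[[xvar]])])
  graphics::matplot(xs, ys, type = "l", lty = 1,
                    xlab = xvar, ylab = unique(df$metric)[1L],
                    main = man$experiment, ...)
  invisible(x)
}
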