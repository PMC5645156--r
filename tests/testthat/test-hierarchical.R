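test_that("single-level contextual value matches the hand-worked example", {
  m <- single_level_context_model(prior_var = 1, context_obs_var = 1,
                                  reward_var = 0.5)
  out <- single_level_value(O = 4, R = 4, m)
  expect_equal(out$context_belief$mean, 2)
  expect_equal(out$context_belief$var, 0.5)
  expect_equal(out$value, 1)
  ## with no contextual cue this is one core update from the contracted prior
  m2 <- single_level_context_model(1, 1, 0.1)
  o0 <- single_level_value(O = 0, R = 3, m2)
  core <- update_belief(belief_state(0, o0$context_belief$var), 3, 0.1)
  expect_equal(o0$value, core$value, tolerance = 1e-12)
  ## subtractive normalization: larger cues lower the same reward's value
  vals <- sapply(seq(-3, 3), function(O) single_level_value(O, 2, m2)$value)
  expect_true(all(diff(vals) < 0))
  expect_error(single_level_value(Inf, 1, m2), "finite")
  expect_error(single_level_context_model(prior_var = -1), "positive")
})

test_that("hierarchical normalization factors match the unit-variance example", {
  f <- hierarchical_factors(hierarchical_context_model())
  expect_equal(f$tau_lo, 0.6)
  expect_equal(f$tau_ho, 0.2)
  expect_equal(f$k, 0.375)
  expect_equal(hierarchical_value(2, 4, 6, hierarchical_context_model()),
               0.375 * (6 - 0.6 * 4 - 0.2 * 2), tolerance = 1e-12)
  ## zero prediction error and the no-context special cases
  expect_equal(hierarchical_value(2, 4, 0.6 * 4 + 0.2 * 2,
                                  hierarchical_context_model()), 0,
               tolerance = 1e-12)
  expect_equal(hierarchical_value(0, 0, 3, hierarchical_context_model()),
               0.375 * 3, tolerance = 1e-12)
})

test_that("factors stay in (0,1) and respond lawfully to the variances", {
  set.seed(4)
  for (rep in 1:20) {
    m <- hierarchical_context_model(var_hc = stats::runif(1, 0.05, 20),
                                    var_ho = stats::runif(1, 0.05, 20),
                                    var_lc = stats::runif(1, 0.05, 20),
                                    var_lo = stats::runif(1, 0.05, 20),
                                    var_r = stats::runif(1, 0.05, 20))
    f <- hierarchical_factors(m)
    expect_true(f$tau_lo > 0 && f$tau_lo < 1)
    expect_true(f$tau_ho > 0 && f$tau_ho < 1)
    expect_true(f$k > 0 && f$k < 1)
    ## K strictly decreasing in reward variance
    m2 <- m; m2$var_r <- m$var_r * 3
    expect_lt(hierarchical_factors(m2)$k, f$k)
    ## closed form equals explicit sequential inference
    expect_equal(hierarchical_value(1.7, -0.4, 2.2, m),
                 hierarchical_value(1.7, -0.4, 2.2, m,
                                    method = "sequential"),
                 tolerance = 1e-12)
  }
})

test_that("hierarchical value is monotone in reward and both observations", {
  m <- hierarchical_context_model(2, 0.5, 1, 3, 0.2)
  rs <- seq(-4, 4)
  expect_true(all(diff(hierarchical_value(1, 1, rs, m)) > 0))
  v_lo <- sapply(rs, function(LO) hierarchical_value(1, LO, 2, m))
  v_ho <- sapply(rs, function(HO) hierarchical_value(HO, 1, 2, m))
  expect_true(all(diff(v_lo) < 0))
  expect_true(all(diff(v_ho) < 0))
})

test_that("precise low-level observations screen off the high level", {
  m <- hierarchical_context_model(var_lo = 1e-12)
  f <- hierarchical_factors(m)
  expect_equal(f$tau_lo, 1, tolerance = 1e-9)
  expect_equal(f$tau_ho, 0, tolerance = 1e-9)
})

test_that("an uninformative high level reduces to the single-level model", {
  m <- hierarchical_context_model(var_hc = 1, var_ho = 1e8, var_lc = 1,
                                  var_lo = 1.5, var_r = 0.3)
  single <- single_level_context_model(prior_var = 1 + 1,
                                       context_obs_var = 1.5,
                                       reward_var = 0.3)
  for (R in c(-2, 0, 3.7))
    expect_equal(hierarchical_value(HO = 5, LO = 1.2, R, m),
                 single_level_value(O = 1.2, R, single)$value,
                 tolerance = 1e-6)
})

test_that("scenario predictions reproduce the ordinal context patterns", {
  ## shifted averages: shared rewards worth more in the low-average context
  ms <- scenario_predictions(scenario_mean_shift())
  for (r in c(-0.5, 0.5))
    expect_gt(ms$value[ms$context == "LA" & ms$reward == r],
              ms$value[ms$context == "HA" & ms$reward == r])
  ## variance: low-variance context stretches shared values apart
  vs <- scenario_predictions(scenario_variance())
  expect_gt(vs$value[vs$context == "HV" & vs$reward == -0.5],
            vs$value[vs$context == "LV" & vs$reward == -0.5])
  expect_gt(vs$value[vs$context == "LV" & vs$reward == 0.5],
            vs$value[vs$context == "HV" & vs$reward == 0.5])
  ## two levels: for a reward common to all cells, value falls as either
  ## context level's average rises; extremes are the low/low and high/high
  tl <- scenario_predictions(scenario_two_level())
  common <- 0.5   # present in every low-level context
  v <- with(tl[tl$reward == common, ], setNames(value, context))
  expect_gt(v[["HL_LA:LL_LA"]], v[["HL_LA:LL_MA"]])
  expect_gt(v[["HL_LA:LL_MA"]], v[["HL_HA:LL_MA"]])
  expect_gt(v[["HL_HA:LL_MA"]], v[["HL_HA:LL_HA"]])
})

test_that("scenario construction validates its inputs", {
  expect_error(context_scenario(list()), "named")
  expect_error(context_scenario(list(A = numeric(0))), "non-empty")
  expect_error(context_scenario(list(A = c(1, NA))), "finite")
  sc <- scenario_two_level()
  expect_identical(attr(sc, "levels"), 2L)
})
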