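test_that("choice problems and parameters validate their invariants", {
  pr <- choice_problem(cbind(A = c(1, 10), B = c(10, 1)),
                       attribute_labels = c("price", "quality"))
  expect_s3_class(pr, "choice_problem")
  expect_identical(dim(pr), c(2L, 2L))
  expect_error(choice_problem(matrix(c(1, NA), 1)), "finite")
  expect_error(choice_problem(matrix(c(1, Inf), 1)), "finite")
  expect_error(choice_problem("a"), "numeric")

  expect_error(bcv_params(prior_var = 0), "prior_var")
  expect_error(bcv_params(reward_var = -1), "reward_var")
  expect_error(bcv_params(beta = -0.1), "beta")
  expect_silent(bcv_params(beta = 0))
})

test_that("expected value sums reward amounts across attributes", {
  pr <- choice_problem(cbind(A = c(1, 10), B = c(10, 1), Z = c(0, 0)))
  expect_equal(unname(expected_value(pr)), c(11, 11, 0))
  expect_equal(expected_value(pr, "A"), 11)
  expect_equal(expected_value(choice_problem(6), 1), 6)
  expect_error(expected_value(pr, 4), "index")
  expect_error(expected_value(pr, "Q"), "unknown option")
})

test_that("the precision weight is the prior share of total variance", {
  expect_equal(bcv_gain(1, 1), 0.5)
  expect_equal(bcv_gain(1, 0.1), 10 / 11)
  expect_equal(bcv_gain(1, 10), 1 / 11)
  ## strictly inside (0,1), increasing in prior var, decreasing in obs var
  vs <- 10^seq(-3, 3, by = 0.5)
  g <- bcv_gain(vs, 1)
  expect_true(all(g > 0 & g < 1))
  expect_true(all(diff(g) > 0))
  expect_true(all(diff(bcv_gain(1, vs)) < 0))
  expect_error(bcv_gain(0, 1), "positive")
  expect_error(bcv_gain(1, -2), "positive")
})

test_that("belief updates produce precision-weighted prediction errors", {
  ## no surprise, no value, no mean shift
  up0 <- update_belief(belief_state(0, 1), reward = 0, reward_var = 0.1)
  expect_equal(up0$value, 0)
  expect_equal(up0$state$mean, 0)

  ## first and second steps of the canonical {10, 6} problem, fractions
  ## chained by hand: g1 = 10/11, posterior (100/11, 1/11); g2 = 10/21,
  ## value2 = 10/21 * (6 - 100/11) = -340/231
  up1 <- update_belief(belief_state(0, 1), reward = 10, reward_var = 0.1)
  expect_equal(up1$value, 100 / 11, tolerance = 1e-12)
  expect_equal(up1$state$mean, 100 / 11, tolerance = 1e-12)
  expect_equal(up1$state$var, 1 / 11, tolerance = 1e-12)
  up2 <- update_belief(up1$state, reward = 6, reward_var = 0.1)
  expect_equal(up2$value, -340 / 231, tolerance = 1e-12)

  expect_error(update_belief(belief_state(0, 1), NaN, 0.1), "finite")
})

test_that("variance contraction matches the closed-form precision sum", {
  for (vc in c(0.3, 1, 4)) for (vr in c(0.1, 1, 10)) {
    st <- belief_state(0, vc)
    for (t in 1:6) {
      st <- update_belief(st, reward = rnorm_fixed(t), reward_var = vr)$state
      expect_equal(st$var, 1 / (1 / vc + t / vr), tolerance = 1e-10)
    }
  }
})

test_that("option-set evaluation chains updates and books values per option", {
  pr <- binary_problem()
  tr <- evaluate_option_set(pr, default_params(),
                            orders = matrix(c(1L, 2L), 1))
  expect_equal(unname(tr$option_values),
               c(100 / 11, -340 / 231), tolerance = 1e-12)
  ## conservation: summed incentive values telescope to the belief shift
  expect_equal(sum(tr$step_values[1, ]),
               tr$final_beliefs[[1]]$mean - 0, tolerance = 1e-12)

  ## all rewards at the prior mean generate no value at any step
  flat <- choice_problem(matrix(2, 2, 3))
  tr0 <- evaluate_option_set(flat, bcv_params(prior_mean = 2),
                             orders = rbind(1:3, 3:1))
  expect_equal(unname(tr0$option_values), rep(0, 3))

  ## posterior order-invariance: final beliefs identical, step values not
  tr_fwd <- evaluate_option_set(pr, default_params(),
                                orders = matrix(c(1L, 2L), 1))
  tr_rev <- evaluate_option_set(pr, default_params(),
                                orders = matrix(c(2L, 1L), 1))
  expect_equal(tr_fwd$final_beliefs[[1]]$mean, tr_rev$final_beliefs[[1]]$mean,
               tolerance = 1e-12)
  expect_equal(tr_fwd$final_beliefs[[1]]$var, tr_rev$final_beliefs[[1]]$var,
               tolerance = 1e-12)
  expect_false(isTRUE(all.equal(tr_fwd$option_values, tr_rev$option_values)))

  expect_error(evaluate_option_set(pr, default_params(),
                                   orders = matrix(c(1L, 1L), 1)),
               "permutation")
})

test_that("valuation is invariant to common translation of rewards and priors", {
  set.seed(42)
  for (rep in 1:10) {
    I <- sample(1:3, 1); N <- sample(2:4, 1)
    R <- matrix(stats::rnorm(I * N, sd = 4), I, N)
    shift <- stats::rnorm(1, sd = 10)
    mu <- stats::rnorm(I)
    vr <- stats::runif(I, 0.05, 5)
    orders <- t(vapply(seq_len(I), function(i) sample.int(N), integer(N)))
    tr1 <- evaluate_option_set(choice_problem(R),
                               bcv_params(mu, 1, vr), orders)
    tr2 <- evaluate_option_set(choice_problem(R + shift),
                               bcv_params(mu + shift, 1, vr), orders)
    expect_equal(tr1$option_values, tr2$option_values, tolerance = 1e-9)
    expect_equal(softmax_choice(tr1$option_values)$probs,
                 softmax_choice(tr2$option_values)$probs, tolerance = 1e-9)
  }
})

test_that("incentive value grows with reward and shrinks with reward noise", {
  ## monotone in the option's own reward, all else fixed
  vals <- sapply(seq(2, 9, by = 0.5), function(r2) {
    pr <- choice_problem(c(10, r2))
    evaluate_option_set(pr, default_params(),
                        orders = matrix(c(1L, 2L), 1))$option_values[2]
  })
  expect_true(all(diff(vals) > 0))
  ## for a fixed prediction error the magnitude decreases in reward variance
  mag <- sapply(c(0.1, 1, 10), function(vr)
    abs(update_belief(belief_state(0, 1), 5, vr)$value))
  expect_true(all(diff(mag) < 0))
})

test_that("softmax choice is overflow-safe, normalized, and handles limits", {
  expect_equal(softmax_choice(c(3, 3, 3))$probs, rep(1 / 3, 3))
  expect_equal(softmax_choice(c(-4, 2, 13), beta = 0)$probs, rep(1 / 3, 3))
  big <- softmax_choice(c(1e4, 0), beta = 1)
  expect_true(all(is.finite(big$probs)))
  expect_equal(sum(big$probs), 1, tolerance = 1e-12)
  d <- softmax_choice(c(100 / 11, -340 / 231), beta = 1)
  expect_equal(d$probs[[1]], 1 / (1 + exp(-2440 / 231)), tolerance = 1e-12)
  expect_equal(sum(d$probs), 1, tolerance = 1e-12)
  expect_error(softmax_choice(numeric(0)), "non-empty")
  expect_error(softmax_choice(c(1, NA)), "finite")
})
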