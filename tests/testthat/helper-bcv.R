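## Shared fixtures: canonical problems and parameter sets used across tests.

binary_problem <- function(R_H = 10, R_L = 6) choice_problem(c(H = R_H, L = R_L))

default_params <- function(mu = 0, vr = 0.1, vc = 1, beta = 1)
  bcv_params(prior_mean = mu, prior_var = vc, reward_var = vr, beta = beta)

decoy_problem <- function(kp, kq)
  choice_problem(cbind(A = c(1, 10), B = c(10, 1), K = c(kp, kq)),
                 attribute_labels = c("price", "quality"))

compromise_problem <- function(d, with_B = TRUE) {
  opts <- if (with_B)
    cbind(A = c(5 - d, 5 + d), B = c(5 + d, 5 - d), K = c(5, 5))
  else cbind(A = c(5 - d, 5 + d), K = c(5, 5))
  choice_problem(opts, attribute_labels = c("price", "quality"))
}

## Independent scalar reference for one attribute's sequential update chain:
## returns per-option incentive values without going through the package's
## state objects or the vectorized engine.
reference_attribute_values <- function(rewards, order, mu, vc, vr) {
  vals <- numeric(length(rewards))
  m <- mu; v <- vc
  for (n in order) {
    g <- v / (v + vr)
    vals[n] <- g * (rewards[n] - m)
    m <- m + vals[n]
    v <- v * vr / (v + vr)   # harmonic form of the conjugate update
  }
  vals
}

## deterministic pseudo-rewards so variance-path loops need no RNG
rnorm_fixed <- function(t) c(2.3, -1.1, 0.4, 5.0, -3.2, 0.0)[t]
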