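# small shared fixtures: a cheap analytic target and a tiny dataset
make_tiny_series <- function() {
  design <- make_reference_design()
  design$exp1_enzyme_nM <- c(0.128, 1.024)
  design$exp2_Xa_nM <- c(0, 1)
  design$times <- c(120, 360, 720)
  design
}

test_that("parameter bounds encode the biophysical box and the
           Michaelis constraint", {
  b <- param_bounds("full")
  expect_equal(rownames(b),
               c("k_plus_1", "k_plus_2", "k_plus_3", "k_plus_4",
                 "k_plus_6", "k_minus_6", "k_plus_7", "k_minus_7",
                 "k_plus_8", "k_minus_8", "sigma"))
  expect_equal(b["k_plus_1", "upper"], 1)    # diffusion limit
  expect_equal(b["k_plus_2", "upper"], 238)  # k2 <= K_M
  expect_equal(b["k_minus_7", "upper"], 1e-2)
  expect_equal(b["k_plus_7", "upper"], 500)

  # derived reverse rates come from the fixed constants
  theta <- make_reference_design()$theta_true
  r <- theta_to_rates(theta)
  expect_equal(unname(r["k_minus_1"]), 238 * 0.51 - 16.23)
  expect_equal(unname(r["k_minus_3"]), 520 * 0.16)
  expect_equal(unname(r["k_minus_4"]), 2.63e-2 * 3.67e-3)
  expect_equal(unname(r["k_plus_5"]), 0)

  # the alternative scheme drops the conformational-change rates
  b2 <- param_bounds("no_reaction_7")
  expect_false(any(c("k_plus_7", "k_minus_7") %in% rownames(b2)))
  r2 <- theta_to_rates(theta[rownames(b2)], "no_reaction_7")
  expect_equal(unname(r2[c("k_plus_7", "k_minus_7")]), c(0, 0))
})

test_that("log-likelihood attains its analytic maximum on noise-free
           data and decomposes over measurements", {
  design <- make_tiny_series()
  nf <- generate_dataset(design, noise_free = TRUE)
  theta <- design$theta_true
  sigma <- theta[["sigma"]]
  mu <- nf$Xa_nM
  expect_equal(log_likelihood(theta, nf),
               -sum(log(sigma * mu) + 0.5 * log(2 * pi)))

  # a single observation displaced one standard deviation costs 1/2
  one <- nf[1, , drop = FALSE]
  one$Xa_nM <- one$Xa_nM * (1 + sigma)
  shifted <- as_dataset(rbind(one, nf[-1, ]))
  expect_equal(log_likelihood(theta, shifted),
               log_likelihood(theta, nf) - 0.5)

  # shuffling rows leaves the total unchanged
  set.seed(1)
  shuf <- as_dataset(nf[sample(nrow(nf)), ])
  expect_equal(log_likelihood(theta, shuf), log_likelihood(theta, nf))

  # out-of-bounds theta is rejected with -Inf
  theta_bad <- theta; theta_bad[["k_plus_1"]] <- 2
  expect_identical(log_likelihood(theta_bad, nf), -Inf)
  theta_bad <- theta; theta_bad[["sigma"]] <- 0
  expect_identical(log_likelihood(theta_bad, nf), -Inf)
  # violating k_minus_1 >= 0 (k_plus_1 < k_plus_2/K_M)
  theta_bad <- theta
  theta_bad[["k_plus_1"]] <- 0.01; theta_bad[["k_plus_2"]] <- 100
  expect_identical(log_likelihood(theta_bad, nf), -Inf)
})

test_that("LHS pre-exploration is seeded, bounded and centred on the
           top draws", {
  design <- make_tiny_series()
  nf <- generate_dataset(design, noise_free = TRUE)
  series <- tfpiflow:::dataset_series(nf)
  pre1 <- lhs_preexplore(series, n_samples = 60, top_k = 20, seed = 5)
  pre2 <- lhs_preexplore(series, n_samples = 60, top_k = 20, seed = 5)
  expect_identical(pre1$theta0, pre2$theta0)

  b <- param_bounds("full")
  top <- pre1$top
  expect_true(all(t(top) > b$lower & t(top) <= b$upper))
  # every retained draw honors the derived-rate constraint
  expect_true(all(238 * top[, "k_plus_1"] - top[, "k_plus_2"] >= 0))
  expect_equal(pre1$theta0, colMeans(top))
  expect_error(lhs_preexplore(series, n_samples = 10, top_k = 20),
               "top_k")
})

test_that("metropolis sampler is correct on analytic targets", {
  # zero proposal spread: the chain never moves
  lp <- function(x) -0.5 * sum(x^2)
  ch0 <- metropolis(lp, c(a = 0.3, b = -0.2), c(0, 0), 50, seed = 1)
  expect_true(all(ch0$samples[, "a"] == 0.3))

  # 1-D standard normal: long-run mean within 3 standard errors
  ch <- metropolis(lp, c(x = 0), diag(1, 1), 20000, seed = 2)
  x <- ch$samples[, 1]
  ess_guess <- 20000 / (2 / mean(ch$accepted))  # crude but conservative
  expect_lt(abs(mean(x)), 3 / sqrt(ess_guess))
  expect_gt(sd(x), 0.8); expect_lt(sd(x), 1.2)

  # flat target on a box: acceptance equals the in-box proposal rate
  box_lp <- function(x) if (all(x >= 0 & x <= 1)) 0 else -Inf
  chb <- metropolis(box_lp, c(u = 0.5, v = 0.5), diag(0.25, 2), 20000,
                    seed = 3)
  set.seed(3)
  # oracle: direct Monte-Carlo counting of in-box proposals from the
  # stationary uniform distribution
  from <- matrix(runif(2 * 20000), ncol = 2)
  props <- from + matrix(rnorm(2 * 20000, sd = 0.5), ncol = 2)
  inbox <- mean(props[, 1] >= 0 & props[, 1] <= 1 &
                props[, 2] >= 0 & props[, 2] <= 1)
  expect_equal(mean(chb$accepted), inbox, tolerance = 0.05)
})

test_that("adaptive metropolis adapts its proposal to the target scale
           and beats the fixed proposal on a correlated target", {
  # correlated 2-D normal target
  S <- matrix(c(1, 0.9, 0.9, 1), 2)
  Sinv <- solve(S)
  lp <- function(x) -0.5 * drop(x %*% Sinv %*% x)
  seed_chain <- metropolis(lp, c(x = 0, y = 0), diag(0.01, 2), 500,
                           seed = 4)
  am <- adaptive_metropolis(lp, seed_chain, 20000, seed = 5)
  # proposal covariance adaptation: the empirical covariance of the AM
  # half of the chain approaches the target's within a factor of 2
  emp <- cov(am$samples[10001:20000, ])
  expect_gt(emp[1, 2] / sqrt(emp[1, 1] * emp[2, 2]), 0.7)
  expect_gt(emp[1, 1] / S[1, 1], 0.5)
  expect_lt(emp[1, 1] / S[1, 1], 2)

  # determinism under seeding
  am2 <- adaptive_metropolis(lp, seed_chain, 20000, seed = 5)
  expect_identical(am$samples, am2$samples)

  # paired comparison against the fixed-proposal sampler from the same
  # start: AM mixes at least as well (lag-1 autocorrelation not worse)
  ma <- metropolis(lp, seed_chain$samples[500, ], diag(0.01, 2), 20000,
                   seed = 5)
  ac_am <- cor(am$samples[-1, 1], am$samples[-20000, 1])
  ac_ma <- cor(ma$samples[-1, 1], ma$samples[-20000, 1])
  expect_lte(ac_am, ac_ma + 0.01)
})

test_that("thinning keeps the documented sample count and reports
           autocorrelation", {
  # cheap fixture standing in for the full-scale 1e5 + 6e6 run
  d <- 2
  mk <- function(n, phase) tfpiflow:::new_chain(
    matrix(rnorm(n * d), ncol = d,
           dimnames = list(NULL, c("a", "b"))),
    rnorm(n), rep(TRUE, n), rep(phase, n), 1)
  ma <- mk(1000, "MA"); am <- mk(60000, "AM")
  th <- thin_chain(ma, am, burn = 1000, stride = 100)
  expect_equal(nrow(th$samples), 600)  # (61000 - 1000) / 100
  expect_true(all(th$phase == "AM"))
  # white-noise fixture: lag-1 autocorrelation below 5%
  expect_true(all(abs(th$lag1) < 0.05))

  # identity thinning
  th0 <- thin_chain(ma, am, burn = 0, stride = 1)
  expect_equal(nrow(th0$samples), 61000)
  expect_error(thin_chain(ma, NULL, burn = 2000, stride = 1), "burn")
})

test_that("summaries give medians, nested intervals and per-sample
           derived constants", {
  # constant chain: medians equal the constant, zero-width intervals
  theta <- make_reference_design()$theta_true
  const <- tfpiflow:::new_chain(
    matrix(rep(theta, each = 10), nrow = 10,
           dimnames = list(NULL, names(theta))),
    rep(0, 10), rep(TRUE, 10), rep("AM", 10), 1)
  s <- summarize_chain(const)
  expect_s3_class(s, "posterior_summary")
  expect_true(all(s$lower_95 <= s$median & s$median <= s$upper_95))
  expect_equal(s$median[s$parameter == "k_plus_2"], 16.23)
  expect_equal(s$lower_95, s$upper_95)

  # monotone transforms commute with the median on a random chain
  set.seed(9)
  rnd <- const
  rnd$samples <- matrix(runif(110, 0.01, 0.99), nrow = 10,
                        dimnames = list(NULL, names(theta)))
  s2 <- summarize_chain(rnd)
  expect_equal(s2$median[s2$parameter == "k_minus_3"],
               520 * s2$median[s2$parameter == "k_plus_3"])
  expect_equal(s2$median[s2$parameter == "k_minus_4"] /
                 s2$median[s2$parameter == "k_plus_4"], 2.63e-2)
})

test_that("prediction bands collapse for one sample and nest across
           levels", {
  theta <- make_reference_design()$theta_true
  cond <- experiment_condition(1L, enzyme_nM = 0.128)
  times <- c(120, 360, 720)
  single <- tfpiflow:::new_chain(
    matrix(theta, nrow = 1, dimnames = list(NULL, names(theta))),
    0, TRUE, "AM", 1)
  pb <- prediction_bands(single, cond, times)
  expect_equal(pb$lower_70, pb$median)
  expect_equal(pb$upper_99, pb$median)

  # perturbed chain: nested bands and truth inside the 99% band
  set.seed(12)
  n <- 40
  samples <- t(replicate(n, {
    th <- theta
    th[["k_plus_2"]] <- th[["k_plus_2"]] * runif(1, 0.9, 1.1)
    th[["k_plus_4"]] <- th[["k_plus_4"]] * runif(1, 0.9, 1.1)
    th
  }))
  chain <- tfpiflow:::new_chain(samples, rep(0, n), rep(TRUE, n),
                                rep("AM", n), 1)
  pb2 <- prediction_bands(chain, cond, times)
  expect_true(all(pb2$lower_99 <= pb2$lower_90 &
                  pb2$lower_90 <= pb2$lower_70 &
                  pb2$upper_70 <= pb2$upper_90 &
                  pb2$upper_90 <= pb2$upper_99))
  truth <- predict_condition(cond, theta_to_rates(theta), times)
  inside <- truth >= pb2$lower_99 & truth <= pb2$upper_99
  expect_gte(mean(inside), 0.95)
})
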