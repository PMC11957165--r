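test_that("logit scaling divides columns and softens distributions", {
  z <- matrix(c(2, 2, 2), 1)
  expect_equal(scale_logits(z, c(1, 1, 1)), z)
  expect_equal(unname(scale_logits(z, c(2, 2, 2))), matrix(1, 1, 3))
  expect_error(scale_logits(z, c(0, 1, 1)), "positive")

  # T = 5 raises entropy relative to T = 1
  set.seed(1)
  zr <- matrix(rnorm(300), 100, 3)
  entropy <- function(p) -rowSums(p * log(pmax(p, 1e-12)))
  p1 <- spliceworks:::softmax_rows(zr)
  p5 <- spliceworks:::softmax_rows(scale_logits(zr, c(5, 5, 5)))
  expect_true(all(entropy(p5) >= entropy(p1) - 1e-12))
})

test_that("NLL matches hand values and excludes pad rows", {
  expect_equal(nll(diag(3), diag(3)), 0, tolerance = 1e-9)
  expect_equal(nll(matrix(1 / 3, 3, 3), diag(3)), log(3), tolerance = 1e-12)
  P <- rbind(c(0.2, 0.3, 0.5), c(1 / 3, 1 / 3, 1 / 3))
  Y <- rbind(c(0, 0, 0), c(0, 0, 1))
  expect_equal(nll(P, Y), log(3), tolerance = 1e-12)
})

simulate_logits <- function(n, seed, scale = 1) {
  with_seed_local(seed, {
    z <- cbind(rnorm(n, 1.5, 1.5), rnorm(n, -0.5, 1.5), rnorm(n, -0.5, 1.5))
    p <- spliceworks:::softmax_rows(z)
    cls <- vapply(seq_len(n), function(i) sample(3, 1, prob = p[i, ]),
                  integer(1))
    list(z = z * scale, Y = diag(3)[cls, ])
  })
}

test_that("temperature fitting recovers a planted scaling factor", {
  sim <- simulate_logits(20000, seed = 21, scale = 2)
  tv <- fit_temperature(sim$z, sim$Y)
  expect_true(all(abs(tv$T - 2) < 0.05))
  expect_lte(tv$nll_after, tv$nll_before + 1e-9)

  # already-calibrated logits give T close to 1
  sim1 <- simulate_logits(20000, seed = 22, scale = 1)
  tv1 <- fit_temperature(sim1$z, sim1$Y)
  expect_true(all(abs(tv1$T - 1) < 0.05))

  # coarse grid oracle confirms the optimum for a shared temperature
  grid <- seq(0.5, 4, by = 0.05)
  nll_at <- vapply(grid, function(t) {
    nll(spliceworks:::softmax_rows(sim$z / t), sim$Y)
  }, numeric(1))
  t_grid <- grid[which.min(nll_at)]
  expect_lt(abs(t_grid - mean(tv$T)), 0.1)
})

test_that("temperatures are clamped to the [0.05, 5] bounds", {
  # logits scaled by 8: unconstrained optimum ~8, returned value at bound
  sim <- simulate_logits(5000, seed = 23, scale = 8)
  tv <- fit_temperature(sim$z, sim$Y)
  expect_true(all(tv$T <= 5))
  expect_true(any(abs(tv$T - 5) < 1e-6))
})

test_that("a class absent from the labels leaves its temperature at 1", {
  set.seed(3)
  z <- matrix(rnorm(600), 200, 3)
  Y <- cbind(1, 0, 0)[rep(1, 200), ]
  expect_warning(tv <- fit_temperature(z, Y), "absent")
  expect_equal(tv$T[2], 1)
  expect_equal(tv$T[3], 1)
})

test_that("ECE matches its hand example and stays in [0, 1]", {
  # perfectly sharp, perfectly correct predictor -> 0
  P <- diag(3)[c(1, 2, 3, 1, 2), ]
  expect_equal(ece(P, P), 0)

  # single occupied bin: conf 0.9, acc 0.6 -> 0.3
  n <- 10
  P1 <- matrix(c(0.9, 0.07, 0.03), n, 3, byrow = TRUE)
  correct <- c(rep(1, 6), rep(2, 4)) # 6 of 10 are class 1
  Y1 <- diag(3)[correct, ]
  expect_equal(ece(P1, Y1), abs(0.6 - 0.9), tolerance = 1e-12)

  set.seed(9)
  for (i in 1:10) {
    z <- matrix(rnorm(150), 50, 3)
    P <- spliceworks:::softmax_rows(z)
    Y <- diag(3)[sample(3, 50, replace = TRUE), ]
    e <- ece(P, Y)
    expect_gte(e, 0)
    expect_lte(e, 1)
  }
  expect_error(ece(matrix(0, 0, 3), matrix(0, 0, 3)), "no labeled")
})

test_that("reliability bins report the normal-approximation interval", {
  # one bin with p_hat = 0.5, n = 100 -> SE 0.05, CI [0.402, 0.598]
  p <- rep(0.705, 100)
  y <- c(rep(1, 50), rep(0, 50))
  P <- cbind(1 - p, p, 0)
  Y <- cbind(1 - y, y, 0)
  rc <- reliability_curve(P, Y, class = 1, M = 10)
  expect_equal(nrow(rc), 1)
  expect_equal(rc$se, 0.05)
  expect_equal(rc$ci_lower, 0.5 - 1.96 * 0.05)
  expect_equal(rc$ci_upper, 0.5 + 1.96 * 0.05)

  # p_hat = 0 clamps the lower bound at 0; p_hat = 1 with n = 1 gives [1,1]
  rc0 <- reliability_curve(cbind(0.5, 0.5, 0), cbind(1, 0, 0), class = 1,
                           M = 2)
  expect_equal(rc0$ci_lower, 0)
  rc1 <- reliability_curve(cbind(0.2, 0.8, 0), cbind(0, 1, 0), class = 1,
                           M = 2)
  expect_equal(rc1$se, 0)
  expect_equal(c(rc1$ci_lower, rc1$ci_upper), c(1, 1))
})

test_that("within-class ranking and top-k accuracy survive calibration", {
  # dividing a class's logits by a positive constant preserves the
  # ordering of positions on that class's logit scale exactly
  set.seed(11)
  z <- matrix(rnorm(900), 300, 3)
  zs <- scale_logits(z, c(1.7, 0.6, 3.2))
  for (cl in 1:3) {
    expect_equal(order(z[, cl]), order(zs[, cl]))
  }

  # on the probability scale the near-uniform fitted temperatures leave
  # top-k accuracy essentially unchanged (exact invariance holds on the
  # logit scale; probability-scale ranks can swap at the k boundary when
  # classes scale differently, the same effect that lets argmax change)
  sim <- simulate_logits(4000, seed = 12, scale = 2.5)
  tv <- fit_temperature(sim$z, sim$Y)
  p_before <- spliceworks:::softmax_rows(sim$z)
  p_after <- spliceworks:::softmax_rows(scale_logits(sim$z, tv))
  labels <- spliceworks:::onehot_to_labels(sim$Y)
  before <- topk_accuracy(p_before, labels, k = 1)
  after <- topk_accuracy(p_after, labels, k = 1)
  expect_true(all(abs(before$accuracy - after$accuracy) < 0.01))
})

test_that("calibrating a scorer never worsens NLL and reports diagnostics", {
  fx <- shared_fixture()
  ds <- create_dataset(fx$fasta, fx$gff,
                       split = split_spec("random", 0.8, seed = 10))
  cfg <- splice_config(W = c(5, 5, 5, 5), AR = c(1, 1, 1, 1), channels = 6)
  fit <- train_loop(ds$train, cfg, epochs = 1, seed = 4, batch_size = 8)
  rep <- calibrate_scorer(fit$scorer, fit$validation, bins = 15)
  expect_lte(rep$nll_after, rep$nll_before + 1e-9)
  expect_gte(rep$ece_before, 0)
  expect_true(all(rep$temperature$T >= 0.05 & rep$temperature$T <= 5))
  expect_true(all(c("class", "conf", "acc", "n") %in%
                    names(tidy(rep))))
  expect_equal(nrow(glance(rep)), 1)
})
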