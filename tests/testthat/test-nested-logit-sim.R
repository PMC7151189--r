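test_that("the 2PL stage evaluates and behaves as a logistic model", {
  expect_equal(p_correct(0, 1, 0), 0.5)
  expect_equal(p_correct(0, 1, -2), 1 / (1 + exp(2)))
  expect_gt(p_correct(30, 1, 0), 1 - 1e-12)
  # strictly increasing in theta for positive slope
  th <- seq(-4, 4, length.out = 81)
  expect_true(all(diff(p_correct(th, 0.3, -1)) > 0))
})

test_that("option probabilities follow the nested logit composition", {
  p <- p_options(0, 1, 0, zeta = c(0, 0, 0), lambda = c(0, 0, 0))
  expect_equal(unname(p), c(0.5, 1/6, 1/6, 1/6))

  # direct softmax arithmetic as an independent oracle
  theta <- 0.7; alpha <- 1; beta <- -1
  zeta <- c(0.3, -0.2, 0.1); lambda <- c(-1, 0, 1)
  pc <- 1 / (1 + exp(-(beta + alpha * theta)))
  e <- exp(zeta + lambda * theta)
  expect_equal(unname(p_options(theta, alpha, beta, zeta, lambda)),
               c(pc, (1 - pc) * e / sum(e)), tolerance = 1e-12)
})

test_that("probabilities conserve mass and constant slopes kill theta dependence", {
  set.seed(1)
  for (rep in 1:40) {
    m <- sample(c(3, 7), 1)
    p <- p_options(rnorm(1, sd = 2), runif(1, 0.2, 2), rnorm(1),
                   runif(m, -1, 1), rnorm(m))
    expect_lt(abs(sum(p) - 1), 1e-12)
    expect_true(all(p > 0 & p < 1))
  }
  # softmax shift invariance: equal slopes leave conditional shares flat
  zeta <- c(0.5, -0.5, 0)
  th <- seq(-3, 3, length.out = 13)
  shares <- sapply(th, function(t) {
    p <- p_options(t, 1, -1, zeta, lambda = rep(0.8, 3))
    p[-1] / sum(p[-1])
  })
  expect_lt(max(abs(shares - shares[, 1])), 1e-12)
})

test_that("NRM slope grids match the design table", {
  expect_equal(nrm_lambda("zero", 3), c(0, 0, 0))
  expect_equal(nrm_lambda("zero", 7), rep(0, 7))
  expect_equal(nrm_lambda("moderate", 3), c(-0.4, 0, 0.4))
  expect_equal(nrm_lambda("moderate", 7), seq(-1.2, 1.2, by = 0.4))
  expect_equal(nrm_lambda("high", 3), c(-1, 0, 1))
  expect_equal(nrm_lambda("high", 7), -3:3)
  expect_equal(nrm_lambda("very_high", 3), c(-1.75, 0, 1.75))
  expect_equal(nrm_lambda("very_high", 7), 1.75 * (-3:3))
  expect_error(nrm_lambda("high", 5), "3 or 7")
})

test_that("item banks sample parameters inside the level ranges", {
  banks <- lapply(1:40, function(s)
    sample_item_bank(design_cell(100, 50, 3, "difficult", "high", "moderate"),
                     seed = s))
  betas <- unlist(lapply(banks, `[[`, "beta"))
  alphas <- unlist(lapply(banks, `[[`, "alpha"))
  zetas <- unlist(lapply(banks, `[[`, "zeta"))
  expect_length(betas, 2000)
  expect_true(all(betas >= -1.15 & betas <= -0.85))
  expect_true(all(alphas >= 1.60 & alphas <= 1.90))
  expect_true(all(zetas >= -1 & zetas <= 1))
  expect_equal(banks[[1]]$lambda, c(-0.4, 0, 0.4))
  zero_bank <- sample_item_bank(design_cell(100, 10, 7, "moderate", "low", "zero"), 1)
  expect_true(all(zero_bank$lambda == 0))
})

test_that("item banks round-trip through CSV", {
  bank <- sample_item_bank(design_cell(100, 10, 3, "difficult", "moderate", "high"), 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_item_bank(bank, path)
  back <- read_item_bank(path)
  expect_equal(back$alpha, bank$alpha)
  expect_equal(back$beta, bank$beta)
  expect_equal(back$zeta, bank$zeta, ignore_attr = TRUE)
  expect_equal(back$lambda, bank$lambda)
})

test_that("simulation is reproducible and respects edge cases", {
  cell <- design_cell(200, 10, 7, "difficult", "moderate", "very_high")
  bank <- sample_item_bank(cell, seed = 3)
  r1 <- simulate_responses(bank, 200, seed = 9)
  r2 <- simulate_responses(bank, 200, seed = 9)
  expect_identical(r1$data, r2$data)
  expect_identical(r1$theta, r2$theta)
  empty <- simulate_responses(bank, 0, seed = 1)
  expect_equal(dim(empty), c(0L, 10L))
})

test_that("simulated accuracy matches the 2PL at fixed abilities", {
  bank <- sample_item_bank(design_cell(500, 10, 3, "difficult", "high", "zero"),
                           seed = 4)
  th_grid <- c(-1.5, 0, 1.5)
  n_per <- 4000
  theta <- rep(th_grid, each = n_per)
  resp <- simulate_responses(bank, length(theta), seed = 8, theta = theta)
  correct <- resp$data == 0L
  for (j in c(1, 5, 10)) {
    for (g in seq_along(th_grid)) {
      idx <- (g - 1) * n_per + seq_len(n_per)
      p <- p_correct(th_grid[g], bank$alpha[[j]], bank$beta[[j]])
      se <- sqrt(p * (1 - p) / n_per)
      expect_lt(abs(mean(correct[idx, j]) - p), 3.5 * se)
    }
  }
})

test_that("zero distractor slopes leave distractor shares independent of ability", {
  bank <- sample_item_bank(design_cell(100, 10, 3, "moderate", "moderate", "zero"),
                           seed = 10)
  th <- seq(-3, 3, length.out = 25)
  for (j in c(1, 7)) {
    shares <- sapply(th, function(t) {
      p <- p_options(t, bank$alpha[[j]], bank$beta[[j]], bank$zeta[j, ],
                     bank$lambda)
      p[-1] / sum(p[-1])
    })
    expect_lt(max(abs(shares - shares[, 1])), 1e-12)
  }
})

test_that("under the null model distractor choice is independent of ability terciles", {
  # calibration of the generator: chi-squared independence test among
  # non-solvers should be non-significant in about 95% of replicates
  cell <- design_cell(500, 10, 3, "difficult", "moderate", "zero")
  n_sig <- 0L
  reps <- 600
  for (r in seq_len(reps)) {
    bank <- sample_item_bank(cell, seed = derive_seed(777, r, 1))
    resp <- simulate_responses(bank, 500, seed = derive_seed(777, r, 2))
    ns <- resp$data[, 1] != 0L
    terc <- cut(resp$theta[ns], stats::quantile(resp$theta[ns], c(0, 1/3, 2/3, 1)),
                include.lowest = TRUE)
    tab <- table(resp$data[ns, 1], terc)
    p <- suppressWarnings(stats::chisq.test(tab)$p.value)
    if (p < 0.05) n_sig <- n_sig + 1L
  }
  expect_gte(1 - n_sig / reps, 0.94)
})
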