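test_that("ER precision matrices are symmetric positive definite", {
  for (sd0 in c(1, 7, 99)) {
    tr <- simulate_er_precision(40, 0.1, seed = sd0)
    expect_equal(tr$omega_true, t(tr$omega_true))
    expect_equal(diag(tr$omega_true), rep(1, 40), ignore_attr = TRUE)
    ev <- eigen(tr$omega_true, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), 0)
    # sparsity pattern matches the adjacency
    off <- tr$omega_true; diag(off) <- 0
    expect_identical(unname(off != 0), unname(tr$adjacency == 1L))
    expect_equal(tr$sigma_true %*% tr$omega_true, diag(40),
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("ER edge counts match the binomial expectation over many seeds", {
  p <- 40; rho <- 0.1; nseed <- 500
  ec <- vapply(seq_len(nseed), function(sd0)
    sum(simulate_er_precision(p, rho, seed = sd0)$adjacency) / 2, numeric(1))
  npairs <- p * (p - 1) / 2
  se <- sqrt(npairs * rho * (1 - rho) / nseed)
  expect_lt(abs(mean(ec) - rho * npairs), 3 * se)
})

test_that("multinomial conservation holds before zero injection", {
  tr <- simulate_er_precision(15, 0.1, seed = 3)
  sim <- simulate_dm_counts(tr, n = 30, pi0 = 0, seed = 4)
  expect_equal(unname(rowSums(sim$counts_pre_zero)), sim$N)
  expect_identical(sum(sim$zero_mask), 0L)
  expect_identical(unclass(sim$counts), sim$counts_pre_zero)
})

test_that("injected zero count is exact and recorded in the mask", {
  tr <- simulate_er_precision(40, 0.1, seed = 5)
  sim <- simulate_dm_counts(tr, n = 100, pi0 = 0.2, seed = 6)
  expect_identical(sum(sim$zero_mask), as.integer(round(0.2 * 100 * 40)))
  expect_true(all(unclass(sim$counts)[sim$zero_mask] == 0))
  idx <- !sim$zero_mask
  expect_identical(unclass(sim$counts)[idx], sim$counts_pre_zero[idx])
})

test_that("count proportions converge to the expected Dirichlet fractions", {
  # large library sizes and concentrated Dirichlet: proportions ~ E psi
  tr <- list(adjacency = diag(0L, 8), omega_true = diag(8),
             sigma_true = diag(8) * 1e-4)
  sim <- simulate_dm_counts(tr, n = 40, mu_range = c(4, 4.0001),
                            N_range = c(1e6, 1e6), pi0 = 0, seed = 8)
  props <- unclass(sim$counts) / rowSums(unclass(sim$counts))
  # per sample, proportions track the realized Dirichlet fractions within
  # multinomial error at N = 1e6
  expect_lt(max(abs(props - sim$psi)), 0.005)
  # all taxa share mu = 4 and negligible variance, so E psi = 1/8; averaging
  # over samples shrinks the Dirichlet noise below 1%
  expect_lt(max(abs(colMeans(props) - 1 / 8)), 0.01)
})

test_that("simulated data show zero inflation, overdispersion, uneven depth", {
  tr <- simulate_er_precision(40, 0.1, seed = 9)
  sim <- simulate_dm_counts(tr, n = 100, pi0 = 0.1, seed = 10)
  Y <- unclass(sim$counts)
  expect_gt(mean(Y == 0), 0.1)                     # more zeros than injected
  disp <- apply(Y, 2, var) > colMeans(Y)
  expect_gt(mean(disp), 0.9)                       # variance exceeds mean
  expect_lte(max(sim$N) / min(sim$N), 2)           # stated depth range
  expect_true(all(rowSums(sim$psi) - 1 < 1e-12))
})

test_that("simulation is reproducible from its seed", {
  tr <- simulate_er_precision(10, 0.1, seed = 11)
  s1 <- simulate_dm_counts(tr, n = 20, pi0 = 0.1, seed = 12)
  s2 <- simulate_dm_counts(tr, n = 20, pi0 = 0.1, seed = 12)
  expect_identical(unclass(s1$counts), unclass(s2$counts))
  expect_identical(s1$zero_mask, s2$zero_mask)
})

test_that("NorTA preserves marginals under an identity covariance", {
  marg <- data.frame(pi = rep(0, 6), mu = rep(10, 6), phi = rep(5, 6))
  cm <- simulate_norta(diag(6), marg, n = 4000, seed = 13)
  Y <- unclass(cm)
  se <- sqrt((10 + 100 / 5) / 4000)
  expect_true(all(abs(colMeans(Y) - 10) < 3 * se + 0.2))
  C <- cor(Y)
  expect_lt(max(abs(C[upper.tri(C)])), 0.08)
})

test_that("a pure point-mass marginal yields an all-zero taxon", {
  marg <- data.frame(pi = c(1, 0), mu = c(5, 5), phi = c(2, 2))
  cm <- suppressWarnings(simulate_norta(diag(2), marg, n = 50, seed = 14))
  expect_true(all(unclass(cm)[, 1] == 0))
})

test_that("a strong Gaussian pair survives the NorTA transform", {
  sig <- diag(8); sig[1, 2] <- sig[2, 1] <- 0.8
  marg <- data.frame(pi = rep(0.3, 8), mu = rep(20, 8), phi = rep(2, 8))
  wins <- 0L
  for (sd0 in 1:10) {
    Y <- unclass(simulate_norta(sig, marg, n = 300, seed = sd0))
    rc <- cor(Y, method = "spearman")
    target <- rc[1, 2]
    null_max <- max(abs(rc[upper.tri(rc)][-1]))
    if (target > 0 && target > null_max) wins <- wins + 1L
  }
  expect_gte(wins, 9L)
})

test_that("ZINB marginal fitting recovers generating parameters roughly", {
  set.seed(15)
  y <- cbind(t1 = ifelse(rbinom(3000, 1, 0.3) == 1, 0L,
                         rnbinom(3000, mu = 30, size = 2)),
             t2 = rnbinom(3000, mu = 8, size = 5))
  marg <- fit_zinb_marginals(y)
  expect_equal(marg["t1", "pi"], 0.3, tolerance = 0.1)
  expect_equal(marg["t1", "mu"], 30, tolerance = 0.15)
  expect_equal(marg["t2", "mu"], 8, tolerance = 0.1)
  expect_lt(marg["t2", "pi"], 0.1)
})

test_that("invalid covariance inputs are rejected", {
  marg <- data.frame(pi = c(0, 0), mu = c(5, 5), phi = c(2, 2))
  bad <- matrix(c(1, 2, 2, 1), 2, 2)   # indefinite
  expect_error(simulate_norta(bad, marg, n = 10), "positive semi-definite")
  expect_error(simulate_dm_counts(list(sigma_true = diag(3)), n = 10,
                                  pi0 = 1.2), "pi0")
})

test_that("exploding Dirichlet parameters raise an actionable error", {
  tr <- list(adjacency = diag(0L, 3), omega_true = diag(3),
             sigma_true = diag(3))
  expect_error(simulate_dm_counts(tr, n = 5, mu_range = c(700, 800), seed = 1),
               "mu_range")
})
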