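test_that("NB parameterization has variance lambda + lambda^2/phi", {
  # the package's ZINB quantile (pi = 0) must agree with the NB whose
  # mean/size parameterization gives this variance: lambda 10, phi 5 -> 30
  qs <- c(0.05, 0.25, 0.5, 0.75, 0.95, 0.99)
  expect_equal(qzinb(qs, 0, 10, 5), qnbinom(qs, mu = 10, size = 5))
  set.seed(1)
  y <- rnbinom(2e5, mu = 10, size = 5)
  expect_equal(var(y), 10 + 100 / 5, tolerance = 0.03)
})

test_that("closed-form column marginal matches numerical NIG integration", {
  a0 <- 2; b0 <- 1; h0 <- 10
  dinvgamma <- function(s2) b0^a0 / gamma(a0) * s2^(-a0 - 1) * exp(-b0 / s2)
  for (x in list(c(0.3, -1.2, 0.5), c(1, 1, 1, 1), c(-2, 0.1))) {
    n <- length(x)
    num <- integrate(function(s2v) {
      vapply(s2v, function(s2) {
        inner <- integrate(function(muv) {
          vapply(muv, function(m) {
            exp(sum(dnorm(x, m, sqrt(s2), log = TRUE)) +
                  dnorm(m, 0, sqrt(h0 * s2), log = TRUE))
          }, numeric(1))
        }, -40, 40, rel.tol = 1e-10)$value
        inner * dinvgamma(s2)
      }, numeric(1))
    }, 1e-4, 400, rel.tol = 1e-10)$value
    expect_equal(dlog_abundance_marginal(x, a0, b0, h0), log(num),
                 tolerance = 1e-6)
  }
})

test_that("inner size-factor mixture has mean exactly zero", {
  for (t in c(0.01, 0.2, 0.5, 0.77, 0.99)) {
    for (nu in c(-3, -0.5, 0, 1e-4, 2, 10)) {
      # t*nu + (1-t)*(-t*nu/(1-t)) cancels identically; only floating-point
      # round-off of the division survives
      expect_lt(abs(inner_mixture_mean(t, nu)), 1e-14 * max(1, abs(nu)))
    }
  }
})

test_that("stick-breaking weights are a probability vector with remainder", {
  set.seed(5)
  for (r in 1:10) {
    V <- runif(sample(2:15, 1), 0.01, 0.99)
    psi <- stick_breaking_weights(V)
    expect_true(all(psi >= 0))
    expect_equal(sum(psi), 1)
    expect_equal(psi[1], V[1])
    expect_equal(psi[2], V[2] * (1 - V[1]))
  }
})

test_that("pi draws follow the closed-form Beta conditional when eta is pinned", {
  # with no observed zeros eta is identically 0 and the full conditional of
  # every pi_i is Beta(a_pi, b_pi + p), independent of all other parameters;
  # the sampler's draws must be indistinguishable from that closed form
  set.seed(21)
  n <- 25; p <- 6
  y <- matrix(rnbinom(n * p, mu = 50, size = 10), n, p) + 1L  # strictly positive
  fit <- fit_zinb_dpp(count_matrix(y), n_iter = 2000, burn_in = 500, seed = 3)
  draws <- as.vector(fit$pi_draws)
  expect_equal(mean(draws), 1 / (1 + (1 + p)), tolerance = 0.02)
  ks <- suppressWarnings(stats::ks.test(draws[seq(1, length(draws), 37)],
                                        stats::pbeta, 1, 1 + p))
  expect_gt(ks$p.value, 0.001)
})

test_that("equal library sizes give posterior mean log size factors near zero", {
  y <- gen_zinb_counts(40, 12, pi_true = 0.1, phi_true = 3, seed = 8)
  fit <- fit_zinb_dpp(count_matrix(y), n_iter = 3000, burn_in = 1500, seed = 9)
  post_ls <- colMeans(fit$logs_draws)
  # per-sample size factors track realized depth, which fluctuates around 1
  expect_lt(max(abs(post_ls)), 0.8)
  expect_lt(sd(post_ls), 0.35)
  expect_equal(mean(post_ls), 0, tolerance = 1e-10)  # recentring identity
})

test_that("fits are deterministic given the seed", {
  y <- gen_zinb_counts(15, 5, 0.15, 2, seed = 4)
  f1 <- fit_zinb_dpp(count_matrix(y), n_iter = 400, burn_in = 200, seed = 77)
  f2 <- fit_zinb_dpp(count_matrix(y), n_iter = 400, burn_in = 200, seed = 77)
  expect_identical(f1$z_mean, f2$z_mean)
  expect_identical(f1$p_l, f2$p_l)
  f3 <- fit_zinb_dpp(count_matrix(y), n_iter = 400, burn_in = 200, seed = 78)
  expect_false(identical(f1$z_mean, f3$z_mean))
})

test_that("degenerate inputs are rejected with informative errors", {
  y <- gen_zinb_counts(10, 4, 0.1, 2, seed = 2)
  y[, 3] <- 0L
  cm <- suppressWarnings(count_matrix(y, taxon_ids = c("t1", "t2", "bad", "t4")))
  expect_error(fit_zinb_dpp(cm), "bad")
  y2 <- gen_zinb_counts(10, 4, 0.1, 2, seed = 2)
  expect_error(fit_zinb_dpp(count_matrix(y2), n_iter = 100, burn_in = 100),
               "burn_in")
})

test_that("MH acceptance rates sit in a healthy band on a default fixture", {
  y <- gen_zinb_counts(40, 10, 0.15, 2, seed = 31)
  fit <- fit_zinb_dpp(count_matrix(y), n_iter = 3000, burn_in = 1500, seed = 5)
  acc <- unlist(fit$acceptance)
  expect_true(all(acc > 0.1 & acc < 0.9))
})
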