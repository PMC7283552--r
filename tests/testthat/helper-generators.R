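# Independent data generators used as oracles. These deliberately bypass the
# package's samplers: plain rnbinom/rbinom draws from the generative story.

# direct ZINB sampler with a lognormal per-cell abundance layer (matches the
# fitted hierarchy: log alpha_ij ~ N(mu_j, sig2), equal size factors s_i = 1)
gen_zinb_counts <- function(n, p, pi_true, phi_true, sig2 = 0.5,
                            mu_range = c(1, 4), seed = 1) {
  set.seed(seed)
  muj <- runif(p, mu_range[1L], mu_range[2L])
  la <- vapply(seq_len(p), function(j) rnorm(n, muj[j], sqrt(sig2)),
               numeric(n))
  y <- matrix(rnbinom(n * p, mu = exp(la), size = phi_true), n, p)
  z <- matrix(rbinom(n * p, 1L, pi_true), n, p)
  y[z == 1L] <- 0L
  y
}

# brute-force Bayesian-FDR threshold scan (independent of bfdr_select)
bfdr_scan_oracle <- function(p, c_eta) {
  q <- 1 - p
  best <- list(selected = rep(FALSE, length(p)), fdr = 0, n_sel = 0L)
  for (t0 in sort(unique(q))) {
    sel <- q <= t0
    fdr <- mean(q[sel])
    if (fdr <= c_eta && sum(sel) > best$n_sel)
      best <- list(selected = sel, fdr = fdr, n_sel = sum(sel))
  }
  best
}

# penalized Gaussian log-likelihood of Eq-style glasso objective (diagonal
# penalized), used for direct maximization oracles at p = 2
glasso_objective <- function(omega, S, lam) {
  ev <- eigen(omega, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) return(-Inf)
  determinant(omega, logarithm = TRUE)$modulus[1L] -
    sum(S * omega) - lam * sum(abs(omega))
}

# exhaustive pair-level confusion enumeration (independent of signed_confusion)
confusion_enum_oracle <- function(est, tru, wrong_sign = "fp", tol = 1e-8) {
  p <- nrow(tru)
  lab <- character(0)
  for (m in seq_len(p - 1)) for (k in seq(m + 1, p)) {
    e <- est[m, k]; t0 <- tru[m, k]
    lab <- c(lab, if (abs(t0) > tol) {
      if (abs(e) > tol) {
        if (sign(e) == sign(t0)) "tp" else wrong_sign
      } else "fn"
    } else {
      if (abs(e) > tol) "fp" else "tn"
    })
  }
  as.list(table(factor(lab, c("tp", "tn", "fp", "fn"))))
}
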