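#' Hyperparameters of the ZINB-DPP normalization model
#'
#' Prior settings for the hierarchical zero-inflated negative binomial model.
#' Defaults follow the weakly informative specification used throughout the
#' package: flat Beta(1, 1) on the zero-inflation probabilities, Gamma(0.001,
#' 0.001) on the dispersions, a Normal-Inverse-Gamma prior on the per-taxon
#' Gaussian log-abundance parameters (mu_j | sigma_j^2 ~ N(0, h0 sigma_0^2
#' sigma_j^2), sigma_j^2 ~ IG(a_0, b_0)), and a stick-breaking Dirichlet
#' process prior at truncation M on the log size factors whose inner
#' two-component mixture has mean exactly zero.
#'
#' @param a_pi,b_pi Beta prior shapes for the zero-inflation probability.
#' @param a_phi,b_phi Gamma prior shape/rate for the NB dispersion phi_j.
#' @param a_0,b_0 Inverse-Gamma shape/scale for sigma_j^2.
#' @param h_0 prior variance multiplier for mu_j.
#' @param sigma_0_sq fixed variance scale multiplying h_0 (kept at 1).
#' @param M Dirichlet-process truncation; `NULL` means floor(n / 2) at fit time.
#' @param sigma_s_sq fixed variance of the size-factor mixture components.
#' @param tau_nu prior variance of the component means nu_m.
#' @param a_t,b_t Beta prior for the inner-mixture weight t_m.
#' @param a_m,b_m Beta prior for the stick-breaking fractions V_m.
#' @return a list of class `zinb_hyper`.
#' @export
zinb_hyper <- function(a_pi = 1, b_pi = 1, a_phi = 0.001, b_phi = 0.001,
                       a_0 = 2, b_0 = 1, h_0 = 10, sigma_0_sq = 1,
                       M = NULL, sigma_s_sq = 1, tau_nu = 1,
                       a_t = 1, b_t = 1, a_m = 1, b_m = 1) {
  h <- list(a_pi = a_pi, b_pi = b_pi, a_phi = a_phi, b_phi = b_phi,
            a_0 = a_0, b_0 = b_0, h_0 = h_0, sigma_0_sq = sigma_0_sq,
            M = M, sigma_s_sq = sigma_s_sq, tau_nu = tau_nu,
            a_t = a_t, b_t = b_t, a_m = a_m, b_m = b_m)
  num <- h[setdiff(names(h), "M")]
  if (any(unlist(num) <= 0)) stop("all hyperparameters must be strictly positive")
  if (!is.null(M) && (M < 1 || M != round(M))) stop("M must be a positive integer")
  structure(h, class = "zinb_hyper")
}

#' Fit the ZINB-DPP normalization model by MCMC
#'
#' Runs a Metropolis-within-Gibbs sampler for the hierarchical model
#' y_ij ~ pi_i I(y_ij = 0) + (1 - pi_i) NB(s_i alpha_ij, phi_j), where the NB
#' has mean lambda = s_i alpha_ij and variance lambda + lambda^2 / phi_j.
#' Log size factors carry a truncated Dirichlet-process mixture prior whose
#' components are zero-mean two-point Gaussian mixtures, enforcing the
#' stochastic constraint E(log s_i) = 0; after every sweep log s is re-centered
#' to mean zero with the offset moved into log alpha (a likelihood-invariant
#' move, since the NB mean only depends on their sum).
#'
#' @param counts a [count_matrix]; every taxon must have at least one nonzero
#'   count (apply [filter_low_abundance] first).
#' @param hyper a [zinb_hyper] object.
#' @param n_iter total MCMC iterations.
#' @param burn_in burn-in iterations (must be < `n_iter`); random-walk steps
#'   are adapted only during burn-in.
#' @param seed integer seed; the fit is deterministic given the seed.
#' @return an object of class `zinb_fit` with elements `z_mean` (posterior
#'   mean of log alpha), `z_col_mean` (per-taxon posterior mean of log
#'   abundance over cells observed nonzero), `p_l` (marginal posterior
#'   probabilities that each observed zero is a sampling zero), `zero_index`
#'   (cell coordinates of the observed zeros), posterior draws of pi, phi and
#'   log s, and per-block MH acceptance rates.
#' @export
fit_zinb_dpp <- function(counts, hyper = zinb_hyper(), n_iter = 10000,
                         burn_in = 5000, seed = 1) {
  counts <- count_matrix(as.matrix(counts))
  if (burn_in >= n_iter || burn_in < 1) stop("need 1 <= burn_in < n_iter")
  Y <- unclass(counts)
  n <- nrow(Y); p <- ncol(Y)
  all_zero <- colSums(Y > 0) == 0
  if (any(all_zero))
    stop("taxon with all-zero counts: ", colnames(Y)[which(all_zero)[1L]],
         " (filter low-abundance taxa first)")
  M <- hyper$M
  if (is.null(M)) M <- max(1L, floor(n / 2))

  set.seed(as.integer(seed) %% .Machine$integer.max)
  # moment-based initialization
  pi0 <- pmin(pmax(rowMeans(Y == 0), 0.01), 0.99)
  lib <- rowSums(Y)
  s0 <- lib / exp(mean(log(lib)))
  la0 <- log((Y + 0.5) / s0)
  eta0 <- matrix(0L, n, p)
  zero_cells <- Y == 0
  eta0[zero_cells] <- rbinom(sum(zero_cells), 1L, rep(pi0, times = p)[zero_cells])

  res <- .zinb_dpp_mcmc(Y, as.integer(n_iter), as.integer(burn_in),
                        hyper$a_pi, hyper$b_pi, hyper$a_phi, hyper$b_phi,
                        hyper$a_0, hyper$b_0, hyper$h_0 * hyper$sigma_0_sq,
                        as.integer(M), hyper$sigma_s_sq, hyper$tau_nu,
                        hyper$a_t, hyper$b_t, hyper$a_m, hyper$b_m,
                        pi0, rep(1, p), log(s0), la0,
                        matrix(as.integer(eta0), n, p))

  z_mean <- res$z_mean
  dimnames(z_mean) <- dimnames(Y)
  zero_index <- which(zero_cells, arr.ind = TRUE)
  p_l <- res$p_eta[zero_index]
  # per-taxon posterior mean log abundance, averaged over observed-nonzero cells
  nz <- Y > 0
  z_col_mean <- vapply(seq_len(p),
                       function(j) mean(z_mean[nz[, j], j]), numeric(1))
  names(z_col_mean) <- colnames(Y)

  structure(list(
    z_mean = z_mean, z_col_mean = z_col_mean,
    p_l = p_l, zero_index = zero_index,
    pi_mean = colMeans(res$pi_draws), phi_mean = colMeans(res$phi_draws),
    pi_draws = res$pi_draws, phi_draws = res$phi_draws,
    logs_draws = res$logs_draws,
    acceptance = res$acceptance, n_kept = res$n_kept,
    n_iter = n_iter, burn_in = burn_in, seed = seed, hyper = hyper,
    counts = counts
  ), class = "zinb_fit")
}

#' @export
print.zinb_fit <- function(x, ...) {
  cat(sprintf(
    "zinb_fit: %d x %d counts, %d kept draws (%d iterations, burn-in %d)\n",
    nrow(x$z_mean), ncol(x$z_mean), x$n_kept, x$n_iter, x$burn_in))
  acc <- unlist(x$acceptance)
  cat("MH acceptance:", paste(sprintf("%s=%.2f", names(acc), acc),
                              collapse = ", "), "\n")
  invisible(x)
}

#' Dichotomize observed zeros and impute sampling zeros
#'
#' Thresholds the marginal posterior probabilities p_l (probability that each
#' observed zero is a sampling zero, i.e. a missing value rather than a true
#' absence) so the realized Bayesian FDR of the imputed set is at most
#' `c_eta` (see [bfdr_select]). Zeros with high p_l are classified sampling
#' zeros and imputed; by default with the per-taxon posterior mean log
#' abundance over that taxon's observed-nonzero cells (`impute = "column"`),
#' or with the cell's own posterior mean (`impute = "cell"`). Remaining zeros
#' are flagged structural and keep the cell posterior mean (small by
#' construction) so the output stays finite for graphical-model input.
#'
#' @param fit a [fit_zinb_dpp] result.
#' @param c_eta nominal Bayesian FDR level; 0.05 is the usual choice for
#'   simulation work, 0.01 for real data.
#' @param impute `"column"` or `"cell"` imputation source for sampling zeros.
#' @return an object of class `normalized_abundance`: `z` (n x p finite log
#'   abundances), `zero_class` (codes `nonzero`, `sampling_zero_imputed`,
#'   `structural_zero`), `fdr_threshold` (selected probability cutoff on p_l),
#'   `realized_fdr`, and `c_eta`.
#' @export
classify_zeros <- function(fit, c_eta = 0.05, impute = c("column", "cell")) {
  stopifnot(inherits(fit, "zinb_fit"))
  impute <- match.arg(impute)
  z <- fit$z_mean
  zero_class <- matrix("nonzero", nrow(z), ncol(z), dimnames = dimnames(z))
  L <- length(fit$p_l)
  if (L > 0L) {
    sel <- bfdr_select(fit$p_l, c_eta)
    idx <- fit$zero_index
    zero_class[idx] <- ifelse(sel$selected, "sampling_zero_imputed",
                              "structural_zero")
    if (impute == "column" && any(sel$selected)) {
      jsel <- idx[sel$selected, "col"]
      z[idx[sel$selected, , drop = FALSE]] <- fit$z_col_mean[jsel]
    }
    thr <- if (is.na(sel$threshold)) NA_real_ else 1 - sel$threshold
    fdr <- sel$fdr
  } else {
    thr <- NA_real_
    fdr <- 0
  }
  stopifnot(all(is.finite(z)))
  structure(list(z = z, zero_class = zero_class, fdr_threshold = thr,
                 realized_fdr = fdr, c_eta = c_eta, impute = impute),
            class = "normalized_abundance")
}

#' @export
print.normalized_abundance <- function(x, ...) {
  tab <- table(factor(x$zero_class,
                      c("nonzero", "sampling_zero_imputed", "structural_zero")))
  cat(sprintf("normalized_abundance: %d x %d, c_eta = %g (realized FDR %.4f)\n",
              nrow(x$z), ncol(x$z), x$c_eta, x$realized_fdr))
  print(tab)
  invisible(x)
}

#' Normalize a count matrix (fit + zero classification)
#'
#' Convenience composition of [fit_zinb_dpp] and [classify_zeros]: fits the
#' ZINB-DPP model and returns finite normalized log abundances Z with the
#' per-cell zero classification. Deterministic given `seed`.
#'
#' @inheritParams fit_zinb_dpp
#' @inheritParams classify_zeros
#' @return a `normalized_abundance`, with the `zinb_fit` attached as
#'   attribute `"fit"`.
#' @export
normalize_counts <- function(counts, hyper = zinb_hyper(), n_iter = 10000,
                             burn_in = 5000, c_eta = 0.05, seed = 1,
                             impute = "column") {
  fit <- fit_zinb_dpp(counts, hyper, n_iter, burn_in, seed)
  out <- classify_zeros(fit, c_eta, impute)
  attr(out, "fit") <- fit
  out
}

#' Closed-form marginal log density of a taxon's log abundances
#'
#' Log density of a column x = (log alpha_1j, ..., log alpha_nj) after
#' integrating mu_j and sigma_j^2 out of the conjugate Normal-Inverse-Gamma
#' prior (mu_j | sigma_j^2 ~ N(0, h0 sigma_j^2), sigma_j^2 ~ IG(a0, b0)): a
#' non-standardized multivariate Student-t density,
#' (2 pi)^{-n/2} (n h0 + 1)^{-1/2} b0^{a0} Gamma(a0 + n/2) / Gamma(a0) *
#' (b0 + [sum x^2 - (sum x)^2 / (n + 1/h0)] / 2)^{-(a0 + n/2)}.
#'
#' @param x numeric vector of log abundances for one taxon.
#' @param a0,b0 Inverse-Gamma shape/scale.
#' @param h0 prior variance multiplier for the mean.
#' @return the log marginal density (a single number).
#' @export
dlog_abundance_marginal <- function(x, a0 = 2, b0 = 1, h0 = 10) {
  n <- length(x)
  kn <- n + 1 / h0
  Q <- sum(x^2) - sum(x)^2 / kn
  -0.5 * n * log(2 * pi) - 0.5 * log(n * h0 + 1) +
    a0 * log(b0) + lgamma(a0 + n / 2) - lgamma(a0) -
    (a0 + n / 2) * log(b0 + Q / 2)
}

#' Mean of the inner two-component size-factor mixture
#'
#' The Dirichlet-process components for log s_i are two-point Gaussian
#' mixtures t N(nu, sigma_s^2) + (1 - t) N(-t nu / (1 - t), sigma_s^2); this
#' returns their mean, t nu + (1 - t)(-t nu / (1 - t)), which is identically
#' zero for every (t, nu) -- the construction that enforces E(log s_i) = 0.
#'
#' @param t inner-mixture weight in (0, 1).
#' @param nu first component mean.
#' @return the mixture mean (0 up to floating-point identity).
#' @export
inner_mixture_mean <- function(t, nu) {
  t * nu + (1 - t) * (-t * nu / (1 - t))
}

#' Stick-breaking weights from breaking fractions
#'
#' psi_1 = V_1, psi_m = V_m prod_{u < m} (1 - V_u); the remainder of the unit
#' stick is assigned to the last (truncation) component.
#'
#' @param V vector of breaking fractions in (0, 1).
#' @return weights summing to 1 (last entry absorbs the remainder).
#' @export
stick_breaking_weights <- function(V) {
  stopifnot(all(V > 0 & V <= 1))
  M <- length(V)
  V[M] <- 1
  cp <- cumprod(1 - V)
  psi <- V * c(1, cp[-M])
  psi
}
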