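#' Simulate an Erdos-Renyi graph with a compatible precision matrix
#'
#' Draws each of the p(p-1)/2 possible edges independently with probability
#' `rho`, then builds a precision matrix in the style of Peng et al.'s sparse
#' partial-correlation simulations: unit diagonal; nonzero off-diagonals drawn
#' Unif[-0.1, 0.1]; each off-diagonal divided by 1.5 times the absolute sum of
#' the off-diagonal entries of its row (computed once on the pre-rescaled
#' matrix); the result averaged with its transpose and the diagonal reset
#' to 1. The rescaling makes every row strictly diagonally dominant, so the
#' matrix is positive definite; this is still verified, with bounded
#' seed-incremented retries as a safety net.
#'
#' @param p number of taxa (>= 2).
#' @param rho edge probability in (0, 1).
#' @param seed integer seed.
#' @param max_tries retries on a positive-definiteness failure.
#' @return list with `adjacency` (binary, zero diagonal), `omega_true`,
#'   `sigma_true` = solve(omega_true).
#' @export
simulate_er_precision <- function(p, rho, seed = 1, max_tries = 20) {
  if (p < 2) stop("p must be >= 2")
  if (!(rho > 0 && rho < 1)) stop("rho must be in (0, 1)")
  for (try in seq_len(max_tries)) {
    set.seed((as.integer(seed) + try - 1L) %% .Machine$integer.max)
    adj <- matrix(0L, p, p)
    ut <- upper.tri(adj)
    adj[ut] <- rbinom(sum(ut), 1L, rho)
    adj <- adj + t(adj)
    # both triangles drawn independently; symmetry is restored by the final
    # average with the transpose
    omega <- diag(p)
    edge_pos <- which(adj == 1L)
    omega[edge_pos] <- runif(length(edge_pos), -0.1, 0.1)
    # rescale off-diagonals by 1.5 x the row's absolute off-diagonal sum,
    # using row sums computed once on the pre-rescaled matrix
    off <- omega; diag(off) <- 0
    rs <- rowSums(abs(off))
    scale <- ifelse(rs > 0, 1.5 * rs, 1)
    off <- off / scale
    omega <- off
    omega <- (omega + t(omega)) / 2
    diag(omega) <- 1
    ev <- min(eigen(omega, symmetric = TRUE, only.values = TRUE)$values)
    if (ev > 0) {
      taxa <- paste0("taxon", seq_len(p))
      sigma <- solve(omega)
      dimnames(adj) <- dimnames(omega) <- dimnames(sigma) <- list(taxa, taxa)
      return(list(adjacency = adj, omega_true = omega, sigma_true = sigma))
    }
  }
  stop("failed to generate a positive-definite precision matrix")
}

#' Simulate Dirichlet-multinomial counts with known network truth
#'
#' Generative chain: mu_j ~ Unif(mu_range); latent abundances D_i. ~
#' MVN(mu, Sigma); Dirichlet fractions psi_i ~ Dirichlet(exp(D_i.)); counts_i
#' ~ Multinomial(N_i, psi_i) with library size N_i ~ DiscreteUnif(N_range);
#' finally exactly round(pi0 * n * p) uniformly chosen cells are set to zero
#' to mimic zero-inflation (recorded in `zero_mask`). The generative scheme
#' deliberately differs from the ZINB analysis model.
#'
#' @param truth list with `adjacency`, `omega_true`, `sigma_true` (e.g. from
#'   [simulate_er_precision]).
#' @param n number of samples.
#' @param mu_range range of the Gaussian means.
#' @param N_range integer range of library sizes.
#' @param pi0 proportion of cells zeroed (0 <= pi0 < 1).
#' @param seed integer seed.
#' @return a `sim_truth` list: `counts` ([count_matrix]), `adjacency`,
#'   `omega_true`, `sigma_true`, `mu`, `D`, `psi`, `N`, `pi0`, `zero_mask`,
#'   `counts_pre_zero`.
#' @export
simulate_dm_counts <- function(truth, n, mu_range = c(0, 10),
                               N_range = c(50000, 100000), pi0 = 0.1,
                               seed = 1) {
  if (!(pi0 >= 0 && pi0 < 1)) stop("pi0 must be in [0, 1)")
  Sigma <- truth$sigma_true
  p <- nrow(Sigma)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  mu <- runif(p, mu_range[1L], mu_range[2L])
  D <- rmvnorm_chol(n, mu, Sigma)
  ed <- exp(D)
  if (any(!is.finite(ed)))
    stop("exp overflow in Dirichlet parameters; use a narrower mu_range")
  # psi_i ~ Dirichlet(exp(D_i.)) via normalized gammas
  G <- matrix(rgamma(n * p, shape = ed, rate = 1), n, p)
  G[G <= 0] <- .Machine$double.xmin   # guard tiny shapes underflowing to 0
  psi <- G / rowSums(G)
  Ns <- seq(N_range[1L], N_range[2L])
  N <- Ns[sample.int(length(Ns), n, replace = TRUE)]
  Y <- t(vapply(seq_len(n), function(i) rmultinom(1L, N[i], psi[i, ])[, 1L],
                integer(p)))
  Y_pre <- Y
  n_zero <- round(pi0 * n * p)
  zero_mask <- matrix(FALSE, n, p)
  if (n_zero > 0) {
    cells <- sample(n * p, n_zero)
    zero_mask[cells] <- TRUE
    Y[cells] <- 0L
  }
  counts <- count_matrix(Y)
  dimnames(zero_mask) <- dimnames(Y_pre) <- dimnames(counts)
  structure(list(counts = counts, adjacency = truth$adjacency,
                 omega_true = truth$omega_true, sigma_true = truth$sigma_true,
                 mu = mu, D = D, psi = psi, N = N, pi0 = pi0,
                 zero_mask = zero_mask, counts_pre_zero = Y_pre,
                 seed = seed),
            class = "sim_truth")
}

# multivariate normal draw via Cholesky (deterministic given the RNG state)
rmvnorm_chol <- function(n, mu, Sigma) {
  p <- length(mu)
  R <- chol((Sigma + t(Sigma)) / 2)
  Z <- matrix(rnorm(n * p), n, p)
  sweep(Z %*% R, 2L, mu, `+`)
}

#' @export
print.sim_truth <- function(x, ...) {
  ne <- sum(x$adjacency[upper.tri(x$adjacency)])
  cat(sprintf(
    "sim_truth: %d x %d counts, %d true edges, pi0 = %g (%d injected zeros)\n",
    nrow(x$counts), ncol(x$counts), ne, x$pi0, sum(x$zero_mask)))
  invisible(x)
}

#' ZINB quantile function
#'
#' Quantile q maps to 0 when q <= pi (the zero-inflation mass), otherwise to
#' the NB quantile of (q - pi) / (1 - pi) with mean `mu` and size `phi`.
#'
#' @param q probabilities in [0, 1].
#' @param pi zero-inflation probability.
#' @param mu NB mean.
#' @param phi NB size (dispersion; variance mu + mu^2/phi).
#' @return integer counts.
#' @export
qzinb <- function(q, pi, mu, phi) {
  out <- numeric(length(q))
  hi <- q > pi
  if (pi >= 1) return(out)
  out[hi] <- qnbinom((q[hi] - pi) / (1 - pi), mu = mu, size = phi)
  out
}

#' Fit ZINB marginals to each taxon of a count matrix
#'
#' Per-taxon maximum likelihood for the zero-inflated negative binomial
#' (method-of-moments start, L-BFGS-B on (logit pi, log mu, log phi)).
#'
#' @param counts a [count_matrix] or integer matrix (samples x taxa).
#' @return data.frame with columns `pi`, `mu`, `phi`, one row per taxon.
#' @export
fit_zinb_marginals <- function(counts) {
  Y <- as.matrix(counts)
  fit1 <- function(y) {
    pz <- mean(y == 0)
    ypos <- y[y > 0]
    m <- if (length(ypos)) mean(ypos) else 0.5
    v <- if (length(ypos) > 1) var(ypos) else m + 1
    phi0 <- if (v > m) m^2 / (v - m) else 10
    par0 <- c(qlogis(min(max(pz, 0.02), 0.98)), log(max(m, 0.1)),
              log(min(max(phi0, 0.05), 50)))
    nll <- function(par) {
      pii <- plogis(par[1L]); mu <- exp(par[2L]); phi <- exp(par[3L])
      ll0 <- log(pii + (1 - pii) * dnbinom(0, mu = mu, size = phi))
      llp <- log1p(-pii) + dnbinom(y[y > 0], mu = mu, size = phi, log = TRUE)
      -(sum(y == 0) * ll0 + sum(llp))
    }
    opt <- tryCatch(
      optim(par0, nll, method = "L-BFGS-B",
            lower = c(-7, log(1e-3), log(1e-3)),
            upper = c(7, log(1e7), log(1e3))),
      error = function(e) list(par = par0))
    c(pi = plogis(opt$par[1L]), mu = exp(opt$par[2L]), phi = exp(opt$par[3L]))
  }
  res <- t(apply(Y, 2L, fit1))
  data.frame(pi = res[, "pi"], mu = res[, "mu"], phi = res[, "phi"],
             row.names = colnames(Y))
}

#' Normal-to-Anything (NorTA) count simulation with ZINB marginals
#'
#' Generates correlated counts with specified marginals: draws Z0 ~ MVN(0,
#' Sigma0), maps each column through the normal CDF (with that column's
#' standard deviation) to [0, 1], and applies the taxon's ZINB quantile
#' function [qzinb].
#'
#' @param sigma_0 p x p target covariance (symmetric positive semi-definite),
#'   e.g. the covariance of log counts of a reference dataset or
#'   a `sigma_true` from [simulate_er_precision].
#' @param marginals data.frame with columns `pi`, `mu`, `phi` (one row per
#'   taxon), e.g. from [fit_zinb_marginals].
#' @param n number of samples.
#' @param seed integer seed.
#' @return a [count_matrix].
#' @export
simulate_norta <- function(sigma_0, marginals, n, seed = 1) {
  sigma_0 <- as.matrix(sigma_0)
  p <- nrow(sigma_0)
  if (max(abs(sigma_0 - t(sigma_0))) > 1e-8 * max(1, max(abs(sigma_0))))
    stop("sigma_0 must be symmetric")
  ev <- min(eigen((sigma_0 + t(sigma_0)) / 2, symmetric = TRUE,
                  only.values = TRUE)$values)
  if (ev < -1e-8 * max(abs(sigma_0)))
    stop("sigma_0 is not positive semi-definite; repair it (e.g. nearest-PSD) first")
  if (nrow(marginals) != p) stop("marginals must have one row per taxon")
  set.seed(as.integer(seed) %% .Machine$integer.max)
  Z0 <- rmvnorm_chol(n, rep(0, p), sigma_0 + diag(1e-10, p))
  U <- pnorm(Z0, mean = 0, sd = rep(sqrt(pmax(diag(sigma_0), 1e-12)),
                                    each = n))
  Y <- vapply(seq_len(p), function(j)
    qzinb(U[, j], marginals$pi[j], marginals$mu[j], marginals$phi[j]),
    numeric(n))
  count_matrix(Y, taxon_ids = rownames(marginals))
}
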