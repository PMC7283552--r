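#' Graphical lasso precision estimation
#'
#' Maximizes the l1-penalized Gaussian log-likelihood
#' log det(Omega) - trace(S Omega) - lambda ||Omega||_1 over positive-definite
#' Omega (diagonal penalized), by block coordinate descent. With lambda = 0 and
#' invertible S this is the unpenalized MLE S^-1; with
#' lambda >= max |off-diagonal of S| the estimate is diagonal (empty graph).
#'
#' @param S symmetric positive semi-definite sample covariance (or
#'   correlation) matrix.
#' @param lam non-negative penalty; must be > 0 when S is singular.
#' @param thr relative convergence threshold on the working covariance.
#' @param max_iter maximum outer sweeps.
#' @return symmetric positive-definite precision matrix estimate.
#' @export
glasso <- function(S, lam, thr = 1e-7, max_iter = 1000) {
  S <- as.matrix(S)
  if (nrow(S) != ncol(S) || max(abs(S - t(S))) > 1e-8 * max(1, max(abs(S))))
    stop("S must be a symmetric matrix")
  if (lam < 0) stop("lam must be non-negative")
  S <- (S + t(S)) / 2
  res <- .glasso_cpp(S, lam, thr, as.integer(max_iter))
  if (!res$converged)
    stop(sprintf("graphical lasso did not converge at lambda = %g", lam))
  omega <- res$omega
  dimnames(omega) <- dimnames(S)
  omega
}

#' Graphical lasso along a penalty path (warm starts)
#'
#' @param S symmetric covariance/correlation matrix.
#' @param lambdas strictly decreasing positive penalties.
#' @inheritParams glasso
#' @return list of precision matrices, one per penalty.
#' @export
glasso_path <- function(S, lambdas, thr = 1e-6, max_iter = 1000) {
  S <- (as.matrix(S) + t(as.matrix(S))) / 2
  if (any(diff(lambdas) >= 0)) stop("lambdas must be strictly decreasing")
  res <- .glasso_path_cpp(S, lambdas, thr, as.integer(max_iter))
  if (!all(res$converged)) {
    bad <- lambdas[which(!res$converged)[1L]]
    stop(sprintf("graphical lasso did not converge at lambda = %g", bad))
  }
  lapply(seq_along(lambdas), function(l) {
    o <- res$omegas[, , l]
    dimnames(o) <- dimnames(S)
    o
  })
}

#' Partial correlations from a precision matrix
#'
#' rho_mk = -omega_mk / sqrt(omega_mm omega_kk), with a unit diagonal. The
#' sign of rho encodes cooperative (+) versus competing (-) association
#' between a taxon pair, conditional on all the others.
#'
#' @param omega symmetric positive-definite precision matrix.
#' @return symmetric partial-correlation matrix with unit diagonal.
#' @export
partial_corr <- function(omega) {
  d <- diag(omega)
  if (any(d <= 0)) stop("precision matrix must have positive diagonal")
  r <- -omega / sqrt(outer(d, d))
  diag(r) <- 1
  (r + t(r)) / 2
}

#' StARS configuration
#'
#' @param lambda_path strictly decreasing positive penalties, or NULL to use
#'   30 log-spaced values from lambda_max (the smallest penalty giving an
#'   empty graph, max |off-diagonal of S|) down to 0.01 lambda_max.
#' @param n_subsamples number of subsamples N.
#' @param subsample_size subsample size b, or NULL for floor(10 sqrt(n))
#'   capped at floor(0.8 n).
#' @param beta_tol instability tolerance in (0, 0.5).
#' @param seed integer seed for the subsampling.
#' @return a list of class `stars_config`.
#' @export
stars_config <- function(lambda_path = NULL, n_subsamples = 20,
                         subsample_size = NULL, beta_tol = 0.05, seed = 1) {
  if (!is.null(lambda_path) && any(diff(lambda_path) >= 0))
    stop("lambda_path must be strictly decreasing")
  if (n_subsamples < 2) stop("need at least 2 subsamples")
  if (!(beta_tol > 0 && beta_tol < 0.5)) stop("beta_tol must be in (0, 0.5)")
  structure(list(lambda_path = lambda_path, n_subsamples = n_subsamples,
                 subsample_size = subsample_size, beta_tol = beta_tol,
                 seed = seed), class = "stars_config")
}

default_lambda_path <- function(S, n_lambda = 30, ratio = 0.01) {
  lmax <- max(abs(S[row(S) != col(S)]))
  if (lmax <= 0) lmax <- 1e-3
  exp(seq(log(lmax), log(ratio * lmax), length.out = n_lambda))
}

#' StARS penalty selection by subsampling stability
#'
#' For each penalty on the path, fits the graphical lasso on N subsamples of
#' size b drawn without replacement, computes per-edge selection frequencies
#' theta_mk, and summarizes graph instability as the mean over the p(p-1)/2
#' edges of 2 theta (1 - theta). Instability is monotonized along the path
#' (running maximum from the largest penalty down) and the selected lambda* is
#' the smallest penalty whose monotonized instability stays at or below
#' `beta_tol`. If no penalty qualifies, the largest penalty is returned with a
#' warning flag.
#'
#' @param Z n x p matrix of normalized log abundances.
#' @param cfg a [stars_config].
#' @param use_correlation use the sample correlation (default) rather than
#'   covariance of each subsample.
#' @param n_threads subsample fits may run in parallel; results are identical
#'   at any concurrency level (each subsample's rows are drawn up front under
#'   `cfg$seed`).
#' @return list with `lambda_star`, `lambda_index`, `lambda_path`,
#'   `instability` (raw), `instability_mono`, `edge_stability` (p x p selection
#'   frequencies at lambda*), and `no_lambda_ok` flag.
#' @export
stars_select <- function(Z, cfg = stars_config(), use_correlation = TRUE,
                         n_threads = 1) {
  Z <- as.matrix(Z)
  n <- nrow(Z); p <- ncol(Z)
  if (p < 2) stop("need at least 2 taxa")
  b <- cfg$subsample_size
  # floor(10 sqrt(n)) for large n; capped at 0.8 n so subsamples stay
  # genuinely distinct when n is small (the cited method's standard default)
  if (is.null(b)) b <- min(floor(10 * sqrt(n)), floor(0.8 * n), n - 1)
  if (b <= 1 || b >= n) stop("subsample size must satisfy 1 < b < n")
  S_full <- if (use_correlation) cor(Z) else cov(Z)
  lambdas <- cfg$lambda_path
  if (is.null(lambdas)) lambdas <- default_lambda_path(S_full)
  nl <- length(lambdas)

  set.seed(as.integer(cfg$seed) %% .Machine$integer.max)
  subs <- lapply(seq_len(cfg$n_subsamples), function(k) sample(n, b))

  fit_one <- function(idx) {
    Sb <- if (use_correlation) cor(Z[idx, , drop = FALSE])
          else cov(Z[idx, , drop = FALSE])
    oms <- .glasso_path_cpp((Sb + t(Sb)) / 2, lambdas, 1e-4, 500L)$omegas
    adj <- array(0L, dim(oms))
    adj[abs(oms) > 1e-8] <- 1L
    for (l in seq_len(nl)) diag(adj[, , l]) <- 0L
    adj
  }
  adjs <- if (n_threads > 1 && requireNamespace("parallel", quietly = TRUE)) {
    parallel::mclapply(subs, fit_one, mc.cores = n_threads)
  } else {
    lapply(subs, fit_one)
  }
  freq <- Reduce(`+`, adjs) / cfg$n_subsamples   # p x p x nl

  ut <- upper.tri(matrix(0, p, p))
  inst <- vapply(seq_len(nl), function(l) {
    th <- freq[, , l][ut]
    mean(2 * th * (1 - th))
  }, numeric(1))
  inst_mono <- cummax(inst)
  ok <- which(inst_mono <= cfg$beta_tol)
  if (length(ok)) {
    li <- max(ok)     # smallest penalty still within tolerance
    flag <- FALSE
  } else {
    li <- 1L
    warning("no penalty met the instability tolerance; returning the largest")
    flag <- TRUE
  }
  stab <- freq[, , li]
  dimnames(stab) <- list(colnames(Z), colnames(Z))
  list(lambda_star = lambdas[li], lambda_index = li, lambda_path = lambdas,
       instability = inst, instability_mono = inst_mono,
       edge_stability = stab, subsample_size = b,
       n_subsamples = cfg$n_subsamples, no_lambda_ok = flag)
}

#' Infer a sparse signed partial-correlation network
#'
#' Full pipeline stage two: computes the sample correlation (or covariance)
#' of the normalized log abundances, selects the graphical-lasso penalty by
#' StARS, refits on the full data at lambda*, and reports the precision
#' matrix, partial correlations, adjacency, and edge stabilities.
#'
#' @param Z a `normalized_abundance` (from [normalize_counts]) or a plain
#'   finite n x p matrix of log abundances.
#' @param cfg a [stars_config].
#' @param use_correlation use the sample correlation matrix (default) rather
#'   than covariance as graphical-lasso input.
#' @param edge_tol absolute precision threshold defining edge presence.
#' @param n_threads passed to [stars_select].
#' @return an object of class `network_estimate`: `omega`, `partial_corr`,
#'   `adjacency`, `lambda_star`, `edge_stability`, `stars` (full selection
#'   detail), `taxon_ids`.
#' @export
infer_network <- function(Z, cfg = stars_config(), use_correlation = TRUE,
                          edge_tol = 1e-8, n_threads = 1) {
  if (inherits(Z, "normalized_abundance")) Z <- Z$z
  Z <- as.matrix(Z)
  if (ncol(Z) < 2) stop("need at least 2 taxa")
  if (!all(is.finite(Z))) stop("Z must be finite")
  sel <- stars_select(Z, cfg, use_correlation, n_threads)
  S <- if (use_correlation) cor(Z) else cov(Z)
  omega <- glasso((S + t(S)) / 2, sel$lambda_star, thr = 1e-7)
  pc <- partial_corr(omega)
  adj <- (abs(omega) > edge_tol) * 1L
  diag(adj) <- 0L
  taxa <- colnames(Z)
  if (is.null(taxa)) taxa <- paste0("taxon", seq_len(ncol(Z)))
  dimnames(omega) <- dimnames(pc) <- dimnames(adj) <- list(taxa, taxa)
  structure(list(omega = omega, partial_corr = pc, adjacency = adj,
                 lambda_star = sel$lambda_star, edge_stability = sel$edge_stability,
                 stars = sel, taxon_ids = taxa,
                 use_correlation = use_correlation),
            class = "network_estimate")
}

#' @export
print.network_estimate <- function(x, ...) {
  ne <- sum(x$adjacency[upper.tri(x$adjacency)])
  cat(sprintf("network_estimate: %d taxa, %d edges at lambda* = %.4g\n",
              length(x$taxon_ids), ne, x$lambda_star))
  invisible(x)
}

#' Edge list of an estimated network
#'
#' @param net a `network_estimate`.
#' @return data.frame with columns taxon_a, taxon_b, partial_correlation,
#'   stability, one row per detected edge, strongest first.
#' @export
network_edges <- function(net) {
  ut <- which(upper.tri(net$adjacency) & net$adjacency == 1L, arr.ind = TRUE)
  df <- data.frame(
    taxon_a = net$taxon_ids[ut[, 1L]],
    taxon_b = net$taxon_ids[ut[, 2L]],
    partial_correlation = net$partial_corr[ut],
    stability = net$edge_stability[ut],
    stringsAsFactors = FALSE)
  df[order(-abs(df$partial_correlation)), , drop = FALSE]
}

#' Export a network as GraphML (signed edge weights)
#'
#' Requires the igraph package.
#'
#' @param net a `network_estimate`.
#' @param path output .graphml path.
#' @export
write_graphml <- function(net, path) {
  if (!requireNamespace("igraph", quietly = TRUE))
    stop("igraph is required for GraphML export")
  g <- igraph::graph_from_adjacency_matrix(net$partial_corr * net$adjacency,
                                           mode = "undirected", weighted = TRUE,
                                           diag = FALSE)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
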