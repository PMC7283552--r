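#' Pipeline run configuration
#'
#' Collects the parameters of the simulate -> normalize -> infer -> evaluate
#' chain. Every output artifact embeds the full parameter set and the seed.
#'
#' @param out_dir output directory (created if missing).
#' @param seed global integer seed; stage seeds are derived from it.
#' @param counts_path optional TSV count table to analyse instead of
#'   simulating (samples x taxa; see [read_count_table]).
#' @param transpose logical, passed to [read_count_table].
#' @param n,p,rho,pi0,mu_range,N_range simulation parameters (used when
#'   `counts_path` is NULL), see [simulate_dm_counts].
#' @param filter_min_nonzero_frac low-abundance filter threshold,
#'   see [filter_low_abundance].
#' @param n_iter,burn_in,c_eta normalization parameters, see
#'   [normalize_counts].
#' @param n_subsamples,beta_tol StARS parameters, see [stars_config].
#' @param n_threads StARS concurrency (results are concurrency-independent).
#' @return list of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1, counts_path = NULL,
                       transpose = FALSE,
                       n = 100, p = 40, rho = 0.1, pi0 = 0.1,
                       mu_range = c(0, 10), N_range = c(50000, 100000),
                       filter_min_nonzero_frac = 0.5,
                       n_iter = 10000, burn_in = 5000, c_eta = 0.05,
                       n_subsamples = 20, beta_tol = 0.05, n_threads = 1) {
  if (!is.null(counts_path) && !file.exists(counts_path))
    stop("input count table not found: ", counts_path)
  structure(as.list(environment()), class = "run_config")
}

write_matrix_tsv <- function(x, path, id_col = "id") {
  write_count_table(x, path, id_col = id_col)
}

write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(path)
}

#' Run the full analysis pipeline and write artifacts to disk
#'
#' Stages: (1) load or simulate a count table; (2) low-abundance filter;
#' (3) ZINB-DPP normalization with Bayesian-FDR zero classification;
#' (4) StARS + graphical-lasso network inference; (5) when simulation truth is
#' available, benchmark metrics (sign-aware confusion at lambda*, MCC, AUC
#' along the penalty path, AUPR from edge stabilities, Pearson baseline).
#' All artifacts are TSV/JSON with the full parameter set and seed embedded in
#' `provenance.json`. Deterministic given the config seed.
#'
#' @param cfg a [run_config].
#' @return (invisibly) a list with the in-memory stage results and the paths
#'   of all written artifacts.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  paths <- list()
  seed <- as.integer(cfg$seed)

  # --- stage 1: input
  truth <- NULL
  if (is.null(cfg$counts_path)) {
    net0 <- simulate_er_precision(cfg$p, cfg$rho, seed = seed)
    truth <- simulate_dm_counts(net0, n = cfg$n, mu_range = cfg$mu_range,
                                N_range = cfg$N_range, pi0 = cfg$pi0,
                                seed = seed + 1L)
    counts <- truth$counts
    paths$counts <- file.path(cfg$out_dir, "counts.tsv")
    write_count_table(counts, paths$counts)
    paths$adjacency_true <- file.path(cfg$out_dir, "adjacency_true.tsv")
    write_matrix_tsv(truth$adjacency, paths$adjacency_true, "taxon_id")
    paths$omega_true <- file.path(cfg$out_dir, "omega_true.tsv")
    write_matrix_tsv(truth$omega_true, paths$omega_true, "taxon_id")
  } else {
    counts <- read_count_table(cfg$counts_path, transpose = cfg$transpose)
  }

  # --- stage 2: filter
  counts_f <- filter_low_abundance(counts, cfg$filter_min_nonzero_frac)

  # --- stage 3: normalization
  norm <- normalize_counts(counts_f, n_iter = cfg$n_iter,
                           burn_in = cfg$burn_in, c_eta = cfg$c_eta,
                           seed = seed + 2L)
  paths$z <- file.path(cfg$out_dir, "z_normalized.tsv")
  write_matrix_tsv(norm$z, paths$z)
  paths$zero_class <- file.path(cfg$out_dir, "zero_class.tsv")
  write_matrix_tsv(norm$zero_class, paths$zero_class)
  fit <- attr(norm, "fit")
  paths$fit_report <- file.path(cfg$out_dir, "fit_report.json")
  write_json_report(list(
    n_iter = cfg$n_iter, burn_in = cfg$burn_in, c_eta = cfg$c_eta,
    fdr_threshold = norm$fdr_threshold, realized_fdr = norm$realized_fdr,
    acceptance_rates = fit$acceptance, seed = seed + 2L,
    n_sampling_zeros = sum(norm$zero_class == "sampling_zero_imputed"),
    n_structural_zeros = sum(norm$zero_class == "structural_zero")
  ), paths$fit_report)

  # --- stage 4: network inference
  scfg <- stars_config(n_subsamples = cfg$n_subsamples,
                       beta_tol = cfg$beta_tol, seed = seed + 3L)
  net <- infer_network(norm, scfg, n_threads = cfg$n_threads)
  paths$omega <- file.path(cfg$out_dir, "omega_hat.tsv")
  write_matrix_tsv(net$omega, paths$omega, "taxon_id")
  paths$partial_corr <- file.path(cfg$out_dir, "partial_corr.tsv")
  write_matrix_tsv(net$partial_corr, paths$partial_corr, "taxon_id")
  paths$stability <- file.path(cfg$out_dir, "edge_stability.tsv")
  write_matrix_tsv(net$edge_stability, paths$stability, "taxon_id")
  paths$edges <- file.path(cfg$out_dir, "edges.tsv")
  write.table(network_edges(net), paths$edges, sep = "\t", quote = FALSE,
              row.names = FALSE)
  paths$network_report <- file.path(cfg$out_dir, "network_report.json")
  write_json_report(list(
    lambda_path = net$stars$lambda_path, instability = net$stars$instability,
    lambda_star = net$lambda_star, no_lambda_ok = net$stars$no_lambda_ok,
    n_edges = sum(net$adjacency[upper.tri(net$adjacency)]),
    seed = seed + 3L
  ), paths$network_report)

  # --- stage 5: evaluation against truth (simulation runs only)
  metrics <- NULL
  if (!is.null(truth)) {
    keep <- match(net$taxon_ids, colnames(truth$counts))
    om_true <- truth$omega_true[keep, keep]
    metrics <- evaluate_network(net, om_true, Z = norm$z)
    paths$metrics <- file.path(cfg$out_dir, "metrics.json")
    write_json_report(metrics, paths$metrics)
  }

  paths$provenance <- file.path(cfg$out_dir, "provenance.json")
  write_json_report(list(
    package = "zinbnet",
    version = as.character(packageVersion("zinbnet")),
    parameters = unclass(cfg)[setdiff(names(unclass(cfg)), "out_dir")],
    seed = seed,
    started = format(t0), elapsed_sec = as.numeric(Sys.time() - t0, "secs")
  ), paths$provenance)

  invisible(list(counts = counts, truth = truth, normalized = norm,
                 network = net, metrics = metrics, paths = paths))
}

#' Benchmark an estimated network against a known truth
#'
#' Computes the sign-aware confusion at the selected penalty, MCC, the
#' ROC/AUC along the graphical-lasso penalty path, AUPR from the StARS edge
#' stabilities, and the Pearson-correlation baseline (oracle-thresholded MCC
#' and score-mode AUC) when `Z` is supplied.
#'
#' @param net a `network_estimate`.
#' @param omega_true true precision matrix over the same taxa.
#' @param Z the normalized abundances the network was fitted on.
#' @return list of metrics.
#' @export
evaluate_network <- function(net, omega_true, Z) {
  cc <- signed_confusion(net$omega, omega_true)
  S <- if (net$use_correlation) cor(Z) else cov(Z)
  out <- list(confusion = unclass(cc), mcc = mcc(cc))
  path_fits <- glasso_path((S + t(S)) / 2, net$stars$lambda_path, thr = 1e-5)
  roc <- roc_auc_path(path_fits, omega_true)
  out$auc <- roc$auc
  pr <- aupr(net$edge_stability, omega_true)
  out$aupr <- pr$aupr
  if (!is.null(Z)) {
    C <- pearson_baseline(Z)
    k_true <- sum(abs(omega_true[upper.tri(omega_true)]) > 1e-8)
    C_sparse <- oracle_threshold(C, k_true)
    # correlation-mode truth: sign agreement against true partial correlations
    pc_true <- -omega_true; diag(pc_true) <- 1
    cc_p <- signed_confusion(C_sparse, pc_true)
    out$pearson <- list(confusion = unclass(cc_p), mcc = mcc(cc_p),
                        auc = roc_auc_path(C, omega_true)$auc)
  }
  out
}
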