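make_truth <- function() {
  # 4-node toy: true edges (1,2) positive, (3,4) negative (precision scale)
  om <- diag(4)
  om[1, 2] <- om[2, 1] <- 0.4
  om[3, 4] <- om[4, 3] <- -0.3
  om
}

test_that("confusion counts match exhaustive pair enumeration on the toy", {
  tru <- make_truth()
  est <- diag(4)
  est[1, 2] <- est[2, 1] <- -0.2   # wrong sign at a true edge
  est[3, 4] <- est[4, 3] <- -0.5   # correct
  est[1, 3] <- est[3, 1] <- 0.1    # spurious
  for (ws in c("fp", "fn")) {
    cc <- signed_confusion(est, tru, wrong_sign = ws)
    orc <- confusion_enum_oracle(est, tru, wrong_sign = ws)
    expect_equal(cc$tp, orc$tp)
    expect_equal(cc$tn, orc$tn)
    expect_equal(cc$fp, orc$fp)
    expect_equal(cc$fn, orc$fn)
  }
  cc <- signed_confusion(est, tru)     # default: wrong sign counts FP
  expect_equal(unlist(cc[c("tp", "tn", "fp", "fn")]),
               c(tp = 1, tn = 3, fp = 2, fn = 0))
})

test_that("perfect and empty estimates give the boundary counts", {
  tru <- make_truth()
  cc <- signed_confusion(tru, tru)
  expect_equal(cc$fp + cc$fn, 0)
  expect_equal(cc$tp, 2)
  cc0 <- signed_confusion(diag(4), tru)
  expect_equal(cc0$tp, 0)
  expect_equal(cc0$fn, 2)
  expect_equal(cc0$fp, 0)
  expect_error(signed_confusion(diag(3), tru), "dimension")
})

test_that("confusion counts always partition the taxon pairs", {
  set.seed(33)
  for (r in 1:20) {
    p <- sample(4:12, 1)
    tru <- simulate_er_precision(p, 0.2, seed = r)$omega_true
    est <- matrix(0, p, p)
    ut <- upper.tri(est)
    est[ut] <- sample(c(0, 0.3, -0.3), sum(ut), replace = TRUE)
    est <- est + t(est); diag(est) <- 1
    ws <- sample(c("fp", "fn"), 1)
    cc <- signed_confusion(est, tru, wrong_sign = ws)
    expect_equal(cc$tp + cc$tn + cc$fp + cc$fn, p * (p - 1) / 2)
  }
})

test_that("MCC follows the closed formula and its symmetries", {
  expect_equal(mcc(list(tp = 5, tn = 100, fp = 0, fn = 0)), 1)
  c1 <- list(tp = 2, tn = 3, fp = 1, fn = 1)
  expect_equal(mcc(c1), (2 * 3 - 1 * 1) / sqrt(3 * 3 * 4 * 4))
  expect_equal(mcc(list(tp = 0, tn = 5, fp = 0, fn = 2)), 0)  # zero factor
  set.seed(44)
  for (r in 1:50) {
    cc <- as.list(setNames(rpois(4, 10), c("tp", "tn", "fp", "fn")))
    v <- mcc(cc)
    expect_true(v >= -1 && v <= 1)
    swapped <- list(tp = cc$tn, tn = cc$tp, fp = cc$fn, fn = cc$fp)
    expect_equal(mcc(swapped), v)
  }
})

test_that("ROC is 1 for perfect ranking and flagged without true edges", {
  tru <- make_truth()
  pc_true <- -tru; diag(pc_true) <- 1
  roc <- roc_auc_path(pc_true, tru)     # scores = true partial correlations
  expect_equal(roc$auc, 1)
  none <- roc_auc_path(pc_true, diag(4))
  expect_true(none$flagged)
  expect_true(is.na(none$auc))
})

test_that("permuted rank-only scores give a null AUC near one half", {
  set.seed(55)
  tru <- simulate_er_precision(12, 0.2, seed = 2)$omega_true
  p <- nrow(tru)
  aucs <- replicate(100, {
    sc <- matrix(0, p, p)
    ut <- upper.tri(sc)
    sc[ut] <- runif(sum(ut))
    sc <- sc + t(sc)
    roc_auc_path(sc, tru, sign_aware = FALSE)$auc
  })
  se <- sd(aucs) / sqrt(length(aucs))
  expect_lt(abs(mean(aucs) - 0.5), 3 * se + 0.01)
})

test_that("AUC and AUPR are invariant to monotone score transforms", {
  set.seed(66)
  tru <- simulate_er_precision(10, 0.2, seed = 3)$omega_true
  p <- nrow(tru)
  sc <- matrix(0, p, p)
  ut <- upper.tri(sc)
  sc[ut] <- runif(sum(ut))
  sc <- sc + t(sc)
  a1 <- roc_auc_path(sc, tru, sign_aware = FALSE)$auc
  a2 <- roc_auc_path(sc^3, tru, sign_aware = FALSE)$auc
  expect_equal(a1, a2)
  p1 <- aupr(sc, tru)$aupr
  p2 <- aupr(1 - exp(-5 * sc), tru)$aupr
  expect_equal(p1, p2)
})

test_that("AUPR hits its perfect and constant-classifier limits", {
  tru <- make_truth()
  conf <- abs(-tru); diag(conf) <- 0
  expect_equal(aupr(conf, tru)$aupr, 1)
  const <- matrix(0.7, 4, 4); diag(const) <- 0
  prevalence <- 2 / 6
  expect_equal(aupr(const, tru)$aupr, prevalence)
  expect_true(aupr(const, diag(4))$flagged)
})

test_that("path-mode ROC orders an informative path above chance", {
  truth <- simulate_er_precision(15, 0.15, seed = 21)
  set.seed(22)
  Z <- zinbnet:::rmvnorm_chol(400, rep(0, 15), truth$sigma_true)
  S <- cor(Z)
  lams <- zinbnet:::default_lambda_path(S)
  path <- glasso_path(S, lams, thr = 1e-5)
  roc <- roc_auc_path(path, truth$omega_true)
  expect_gt(roc$auc, 0.5)
})

test_that("Pearson baseline scores behave at their limits", {
  set.seed(77)
  Z <- matrix(rnorm(500 * 6), 500, 6)
  Z[, 6] <- Z[, 1]
  C <- pearson_baseline(Z)
  expect_equal(C[1, 6], 1)
  expect_lt(max(abs(C[upper.tri(C)][1:9])), 0.15)   # independent pairs
  Zc <- cbind(Z[, 1:3], const = 1)
  expect_warning(Cc <- pearson_baseline(Zc), "constant")
  expect_equal(Cc[4, 1:3], c(0, 0, 0), ignore_attr = TRUE)
  expect_error(pearson_baseline(Z[1:2, ]), "3 samples")
})

test_that("oracle thresholding keeps exactly the k strongest edges", {
  set.seed(88)
  sc <- matrix(0, 6, 6)
  ut <- upper.tri(sc)
  sc[ut] <- runif(sum(ut), -1, 1)
  sc <- sc + t(sc)
  th <- oracle_threshold(sc, 4)
  expect_equal(sum(abs(th[upper.tri(th)]) > 0), 4)
  kept <- abs(th[ut])[abs(th[ut]) > 0]
  dropped <- abs(sc[ut])[abs(th[ut]) == 0]
  expect_true(min(kept) >= max(dropped))
  expect_identical(oracle_threshold(sc, 0), matrix(0, 6, 6))
})
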