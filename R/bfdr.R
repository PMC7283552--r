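#' Bayesian FDR selection from marginal posterior probabilities
#'
#' Given marginal posterior probabilities `p` that each observed zero is a
#' sampling zero (a missing value rather than a true absence), selects the
#' zeros to impute so that the realized Bayesian false discovery rate
#'
#' \deqn{FDR(t) = \frac{\sum_l (1 - p_l)\, I(1 - p_l < t)}{\sum_l I(1 - p_l < t)}}
#'
#' is at most the nominal level `c_eta`. The threshold is the most permissive
#' one (largest selected set) still satisfying the bound: sort q_l = 1 - p_l
#' ascending and select the longest prefix whose running mean of q stays at or
#' below `c_eta` (ties in q are included or excluded together).
#'
#' @param p numeric vector of posterior probabilities in [0, 1].
#' @param c_eta nominal Bayesian FDR level in (0, 1).
#' @return list with `selected` (logical, same length as `p`), `threshold`
#'   (largest q = 1 - p selected, or NA when the selection is empty), and
#'   `fdr` (realized Bayesian FDR of the selection; 0 for an empty selection).
#' @export
bfdr_select <- function(p, c_eta) {
  stopifnot(is.numeric(p), all(p >= 0 & p <= 1))
  if (!(c_eta > 0 && c_eta < 1)) stop("c_eta must be in (0, 1)")
  L <- length(p)
  if (L == 0L)
    return(list(selected = logical(0), threshold = NA_real_, fdr = 0))
  q <- 1 - p
  ord <- order(q)
  qs <- q[ord]
  cm <- cumsum(qs) / seq_len(L)
  # candidate cut points: last occurrence of each distinct q (ties together)
  last_of_tie <- c(qs[-L] != qs[-1L], TRUE)
  ok <- which(last_of_tie & cm <= c_eta)
  if (!length(ok))
    return(list(selected = rep(FALSE, L), threshold = NA_real_, fdr = 0))
  k <- max(ok)
  thr <- qs[k]
  selected <- q <= thr
  list(selected = selected, threshold = thr, fdr = mean(q[selected]))
}

#' Realized Bayesian FDR of a selection
#'
#' @param p posterior probabilities of the selected items' hypotheses.
#' @param selected logical vector marking the selected items.
#' @return the realized Bayesian FDR (mean of 1 - p over the selection), 0 if
#'   nothing is selected.
#' @export
bayesian_fdr <- function(p, selected) {
  if (!any(selected)) return(0)
  mean(1 - p[selected])
}
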