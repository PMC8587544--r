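# Independent oracle implementations used across test files. These are
# deliberately naive (brute force / direct formula evaluation) and share no
# code with the package internals they check.

# ROC area by explicit pair counting: P(score_active > score_inactive)
# + 0.5 P(tie), over all active x inactive pairs.
oracle_roc_paircount <- function(scores, labels) {
  sa <- scores[labels == 1]
  si <- scores[labels == 0]
  if (!length(sa) || !length(si)) return(NA_real_)
  cmp <- outer(sa, si, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# BEDROC by direct evaluation of the exponential-sum closed form.
oracle_bedroc_direct <- function(active_ranks, N, alpha) {
  A <- length(active_ranks)
  Ra <- A / N
  num <- sum(exp(-alpha * active_ranks / N))
  den <- Ra * (1 - exp(-alpha)) / (exp(alpha / N) - 1)
  rie <- num / den
  rie * Ra * sinh(alpha / 2) /
    (cosh(alpha / 2) - cosh(alpha / 2 - alpha * Ra)) +
    1 / (1 - exp(alpha * (1 - Ra)))
}

# EF by direct arithmetic on a known active placement.
oracle_ef_direct <- function(a_in_top, n_top, A, N) {
  (a_in_top / n_top) / (A / N)
}

# Confusion-table metrics by direct formula evaluation.
oracle_metrics_direct <- function(TP, FN, TN, FP) {
  sdiv <- function(n, d) if (d == 0) NA_real_ else n / d
  mcc_den <- (TP + FN) * (TP + FP) * (TN + FN) * (TN + FP)
  list(SE = sdiv(TP, TP + FN), SP = sdiv(TN, TN + FP),
       Qplus = sdiv(TP, TP + FP), Qminus = sdiv(TN, TN + FN),
       MCC = if (mcc_den == 0) NA_real_
             else (TP * TN - FN * FP) / sqrt(mcc_den))
}

# random small screen for property tests
random_screen <- function(n, n_active, seed) {
  set.seed(seed)
  ranks <- sort(sample(n, n_active))
  make_ranked_screen(n, n_active, ranks, seed)
}

# swap the active at rank r with the inactive directly above it
promote_active <- function(screen, r) {
  stopifnot(screen$is_active[r], r > 1, !screen$is_active[r - 1])
  ia <- screen$is_active
  ia[c(r - 1, r)] <- ia[c(r, r - 1)]
  ranked_screen(screen$id, screen$score, ia)
}
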