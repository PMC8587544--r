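# Early-recognition metrics for ranked virtual-screening output:
# enrichment factor at a fraction, BEDROC(alpha) in the Truchon-Bayly
# exact-normalization form, ROC area by the rank statistic, and AUAC.
#
# Undefined cases (no actives, single class) are reported as NA, never
# silently coerced to zero.

#' Construct a ranked screen
#'
#' Compounds are ordered by score, best first, with a stable sort so ties
#' keep their input order (which callers make deterministic by passing
#' compounds in id order). Ranks are 1-based.
#'
#' @param id character vector of compound ids.
#' @param score numeric scores, larger = better. `-Inf` is the conventional
#'   sentinel for compounds that failed a filter but are retained at the
#'   bottom for enrichment computation.
#' @param is_active logical actives flag.
#' @return object of class `ranked_screen`: data.frame (id, score,
#'   is_active) in rank order, with attributes `N` and `A`.
#' @export
ranked_screen <- function(id, score, is_active) {
  stopifnot(length(id) == length(score), length(score) == length(is_active))
  ord <- order(-score)   # stable in R (method radix for numeric)
  df <- data.frame(id = as.character(id)[ord], score = score[ord],
                   is_active = as.logical(is_active)[ord],
                   stringsAsFactors = FALSE)
  structure(df, class = c("ranked_screen", "data.frame"),
            N = nrow(df), A = sum(df$is_active))
}

.screen_counts <- function(screen) {
  list(N = nrow(screen), A = sum(screen$is_active),
       ranks = which(screen$is_active))
}

#' Enrichment factor at a top fraction
#'
#' `EF_f = (a / n_top) / (A / N)` where the top bin holds
#' `n_top = ceiling(f * N)` compounds and `a` of them are active. The
#' ceiling guarantees a non-empty bin. Ties at the bin boundary are
#' resolved by the screen's stable rank order.
#'
#' @param screen a [ranked_screen()].
#' @param fraction top fraction in (0, 1] (default 0.01).
#' @return numeric EF (>= 0), or `NA` when the screen has no actives.
#' @export
ef_at <- function(screen, fraction = 0.01) {
  stopifnot(inherits(screen, "ranked_screen"),
            fraction > 0, fraction <= 1)
  sc <- .screen_counts(screen)
  if (sc$A == 0L) return(NA_real_)
  n_top <- ceiling(fraction * sc$N)
  a <- sum(screen$is_active[seq_len(n_top)])
  (a / n_top) / (sc$A / sc$N)
}

#' BEDROC early-recognition score
#'
#' Boltzmann-enhanced discrimination of ROC (Truchon & Bayly), with the
#' exact min/max normalization: the exponentially weighted sum over active
#' ranks is scaled against its random expectation (RIE) and mapped onto
#' \[0, 1\] via the closed-form best/worst-case bounds. Larger `alpha`
#' concentrates the weight earlier in the list; `alpha = 160.9` weights
#' roughly the top 1%.
#'
#' @param screen a [ranked_screen()].
#' @param alpha positive early-recognition parameter (default 160.9).
#' @return numeric in \[0, 1\], or `NA` when the screen has no actives.
#' @export
bedroc <- function(screen, alpha = 160.9) {
  stopifnot(inherits(screen, "ranked_screen"), alpha > 0)
  sc <- .screen_counts(screen)
  N <- sc$N; A <- sc$A
  if (A == 0L) return(NA_real_)
  Ra <- A / N
  s <- sum(exp(-alpha * sc$ranks / N))
  rand <- Ra * (1 - exp(-alpha)) / (exp(alpha / N) - 1)
  rie <- s / rand
  val <- rie * Ra * sinh(alpha / 2) /
    (cosh(alpha / 2) - cosh(alpha / 2 - alpha * Ra)) +
    1 / (1 - exp(alpha * (1 - Ra)))
  min(1, max(0, val))   # guard floating-point underflow at the extremes
}

#' ROC area of a ranked screen
#'
#' The Mann-Whitney rank statistic on scores, with tied scores receiving
#' average ranks (so an all-tied screen scores exactly 0.5).
#'
#' @param screen a [ranked_screen()].
#' @return numeric in \[0, 1\], or `NA` unless both classes are present.
#' @export
roc_area <- function(screen) {
  stopifnot(inherits(screen, "ranked_screen"))
  A <- sum(screen$is_active); I <- sum(!screen$is_active)
  if (A == 0L || I == 0L) return(NA_real_)
  r <- rank(screen$score, ties.method = "average")
  (sum(r[screen$is_active]) - A * (A + 1) / 2) / (A * I)
}

#' Area under the accumulation curve
#'
#' Discrete form `AUAC = 1 - mean(r_i / N)` over active ranks `r_i`.
#' Promoting an active up the list never decreases it.
#'
#' @param screen a [ranked_screen()].
#' @return numeric in \[0, 1\], or `NA` when the screen has no actives.
#' @export
auac <- function(screen) {
  stopifnot(inherits(screen, "ranked_screen"))
  sc <- .screen_counts(screen)
  if (sc$A == 0L) return(NA_real_)
  1 - mean(sc$ranks / sc$N)
}

#' Full enrichment report for one screen
#'
#' @param screen a [ranked_screen()].
#' @param fraction EF fraction (default 0.01).
#' @param alpha BEDROC alpha (default 160.9).
#' @return one-row data.frame: EF, BEDROC, ROC, AUAC, N, A.
#' @export
enrichment_report <- function(screen, fraction = 0.01, alpha = 160.9) {
  data.frame(EF = ef_at(screen, fraction), BEDROC = bedroc(screen, alpha),
             ROC = roc_area(screen), AUAC = auac(screen),
             N = nrow(screen), A = sum(screen$is_active))
}

#' Read a ranked screen from TSV
#'
#' Expects columns id, score, is_active (0/1).
#'
#' @param path input file.
#' @return a [ranked_screen()].
#' @export
read_ranked_screen <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "score", "is_active")
  if (!all(need %in% names(df)))
    stop("ranked screen TSV must have columns: ", paste(need, collapse = ", "))
  ranked_screen(df$id, as.numeric(df$score), df$is_active != 0)
}

#' Write a ranked screen to TSV
#'
#' @param screen a [ranked_screen()].
#' @param path output file.
#' @export
write_ranked_screen <- function(screen, path) {
  df <- as.data.frame(screen)
  df$is_active <- as.integer(df$is_active)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
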