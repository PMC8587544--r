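# The three-stage screening funnel: deep-learning consensus filter,
# pharmacophore k-of-n filter, and cascade percentage filtering over
# externally produced docking score tables, followed by a top-K shortlist
# annotated with Tanimoto novelty versus a reference active set.
#
# Docking itself is never computed here: each cascade stage consumes a
# (id, score) table produced by any external engine. The final "visual
# inspection" step of manual campaigns is replaced by a configurable
# top-K shortlist plus novelty report.

#' Funnel configuration
#'
#' @param dense_classifier `lig_classifier` (or checkpoint path) for the
#'   fingerprint network.
#' @param nfp_classifier `lig_classifier` (or checkpoint path) for the
#'   graph network.
#' @param consensus `"intersection"` (default, both must predict active),
#'   or `"union"`.
#' @param threshold consensus probability threshold (default 0.5).
#' @param hypothesis `pharm_hypothesis` (or JSON path).
#' @param k minimum matched pharmacophore features (default: the
#'   hypothesis' own `k`).
#' @param docking_tables list of docking score tables (data.frames or TSV
#'   paths with columns id, score), one per cascade stage, in order;
#'   empty list = skip the docking cascade.
#' @param cascade_fractions retained fraction per docking stage
#'   (default 0.25 each).
#' @param final_cap optional hard cap on compounds retained after the last
#'   docking stage (the percentage rule is applied first, then the cap).
#' @param shortlist_size final shortlist length (default 10).
#' @param novelty_refs list of `lig_fp` (or fingerprint-cache TSV path)
#'   of known actives for the novelty column; NULL = skip novelty.
#' @param lower_is_better docking score convention (default TRUE).
#' @return object of class `funnel_config`.
#' @export
funnel_config <- function(dense_classifier, nfp_classifier,
                          consensus = c("intersection", "union"),
                          threshold = 0.5, hypothesis, k = NULL,
                          docking_tables = list(),
                          cascade_fractions = rep(0.25, length(docking_tables)),
                          final_cap = NULL, shortlist_size = 10L,
                          novelty_refs = NULL, lower_is_better = TRUE) {
  consensus <- match.arg(consensus)
  if (is.character(dense_classifier))
    dense_classifier <- load_classifier(dense_classifier)
  if (is.character(nfp_classifier))
    nfp_classifier <- load_classifier(nfp_classifier)
  if (is.character(hypothesis)) hypothesis <- read_hypothesis(hypothesis)
  if (is.character(novelty_refs)) novelty_refs <- read_fp_cache(novelty_refs)
  stopifnot(inherits(dense_classifier, "lig_classifier"),
            inherits(nfp_classifier, "lig_classifier"),
            inherits(hypothesis, "pharm_hypothesis"),
            all(cascade_fractions > 0), all(cascade_fractions <= 1),
            shortlist_size >= 1)
  if (length(docking_tables) != length(cascade_fractions))
    stop("one cascade fraction per docking table required")
  structure(list(dense_classifier = dense_classifier,
                 nfp_classifier = nfp_classifier, consensus = consensus,
                 threshold = threshold, hypothesis = hypothesis,
                 k = if (is.null(k)) hypothesis$k else as.integer(k),
                 docking_tables = docking_tables,
                 cascade_fractions = cascade_fractions,
                 final_cap = final_cap,
                 shortlist_size = as.integer(shortlist_size),
                 novelty_refs = novelty_refs,
                 lower_is_better = lower_is_better),
            class = "funnel_config")
}

#' Consensus filter over two classifiers
#'
#' Scores every library compound with both classifiers and keeps, under
#' the default intersection rule, exactly the compounds both predict
#' active at the threshold.
#'
#' @param library named list of `lig_mol`.
#' @param classifier_a,classifier_b `lig_classifier` objects (or paths).
#' @param threshold probability threshold (default 0.5).
#' @param rule `"intersection"` or `"union"`.
#' @return data.frame (id, prob_a, prob_b, pass) for the whole library;
#'   passing ids in `attr(result, "pass_ids")`.
#' @export
consensus_filter <- function(library, classifier_a, classifier_b,
                             threshold = 0.5,
                             rule = c("intersection", "union")) {
  rule <- match.arg(rule)
  if (is.character(classifier_a)) classifier_a <- load_classifier(classifier_a)
  if (is.character(classifier_b)) classifier_b <- load_classifier(classifier_b)
  stopifnot(!is.null(names(library)))
  ids <- names(library)
  inputs_for <- function(clf) {
    if (clf$arch == "ecfp_dense") lapply(library, ecfp4, length = clf$fp_length)
    else library
  }
  pa <- predict(classifier_a, inputs_for(classifier_a))
  pb <- predict(classifier_b, inputs_for(classifier_b))
  pass <- if (rule == "intersection") pa >= threshold & pb >= threshold
          else pa >= threshold | pb >= threshold
  out <- data.frame(id = ids, prob_a = pa, prob_b = pb, pass = pass,
                    stringsAsFactors = FALSE)
  attr(out, "pass_ids") <- ids[pass]
  out
}

#' Cascade percentage filter
#'
#' Retains the top `floor(fraction * n)` compounds (never fewer than 1 on
#' non-empty input); ties are broken stably by id.
#'
#' @param scored data.frame with columns id and score (higher = better).
#' @param fraction retained fraction in (0, 1].
#' @return the retained rows, in score order.
#' @export
cascade_percent_filter <- function(scored, fraction) {
  stopifnot(fraction > 0, fraction <= 1,
            all(c("id", "score") %in% names(scored)))
  n <- nrow(scored)
  if (n == 0L) return(scored)
  keep <- max(1L, floor(fraction * n))
  ord <- order(-scored$score, scored$id)
  scored[ord[seq_len(keep)], , drop = FALSE]
}

#' Attach externally produced docking scores
#'
#' Inner join on compound id. Duplicate table rows for an id keep the best
#' score (lowest under the lower-is-better convention). The returned
#' `score` column is sign-normalized so that higher = better, ready for
#' [cascade_percent_filter()]; the raw value is kept in `docking_score`.
#'
#' @param ids character vector of compound ids entering the stage.
#' @param score_table data.frame or TSV path with columns id, score.
#' @param lower_is_better docking convention (default TRUE).
#' @return data.frame (id, docking_score, score); unmatched ids in
#'   `attr(result, "unmatched")`. Zero joined rows is an error.
#' @export
attach_docking_scores <- function(ids, score_table, lower_is_better = TRUE) {
  if (is.character(score_table)) {
    if (!file.exists(score_table))
      stop("docking score table not found: ", score_table)
    score_table <- utils::read.delim(score_table, stringsAsFactors = FALSE)
  }
  if (!all(c("id", "score") %in% names(score_table)))
    stop("docking table must have columns id, score")
  st <- score_table
  st$id <- as.character(st$id)
  st$score <- as.numeric(st$score)
  # best score per id
  st <- st[order(st$id, if (lower_is_better) st$score else -st$score), ]
  st <- st[!duplicated(st$id), ]
  hit <- ids %in% st$id
  if (!any(hit)) stop("no compound ids matched the docking score table")
  joined <- data.frame(id = ids[hit],
                       docking_score = st$score[match(ids[hit], st$id)],
                       stringsAsFactors = FALSE)
  joined$score <- if (lower_is_better) -joined$docking_score
                  else joined$docking_score
  attr(joined, "unmatched") <- ids[!hit]
  joined
}

#' Run the full screening funnel
#'
#' Stage order: classifier consensus, pharmacophore k-of-n filter, then
#' one cascade percentage filter per supplied docking table, then the
#' top-K shortlist with novelty annotation. Every stage's output is a
#' subset of its input; a stage that eliminates everything finalizes the
#' report early with an empty shortlist (no error). The per-compound trace
#' assigns each library member to exactly one elimination bucket or the
#' shortlist.
#'
#' @param library named list of `lig_mol` with conformers.
#' @param config a [funnel_config()].
#' @return object of class `funnel_report`: list with `stage_counts`
#'   (data.frame stage/n_in/n_out), `trace` (named character: bucket per
#'   compound), `table` (the shortlist: id, prob_dense, prob_nfp,
#'   pharm_fit, docking scores if present, novelty_tc).
#' @export
run_funnel <- function(library, config) {
  stopifnot(inherits(config, "funnel_config"), length(library) > 0,
            !is.null(names(library)))
  ids <- names(library)
  trace <- stats::setNames(rep(NA_character_, length(ids)), ids)
  stage_counts <- data.frame(stage = character(), n_in = integer(),
                             n_out = integer())
  note_stage <- function(stage, n_in, n_out) {
    stage_counts <<- rbind(stage_counts,
                           data.frame(stage = stage, n_in = n_in,
                                      n_out = n_out))
  }

  # stage 1: consensus
  cons <- consensus_filter(library, config$dense_classifier,
                           config$nfp_classifier, config$threshold,
                           config$consensus)
  alive <- attr(cons, "pass_ids")
  trace[setdiff(ids, alive)] <- "consensus"
  note_stage("consensus", length(ids), length(alive))

  # stage 2: pharmacophore
  scored <- NULL
  if (length(alive)) {
    scr <- screen_with_hypothesis(library[alive], config$hypothesis,
                                  config$k)
    pass <- attr(scr, "pass_ids")
    fits <- stats::setNames(scr$score, scr$id)
    trace[setdiff(alive, pass)] <- "pharmacophore"
    note_stage("pharmacophore", length(alive), length(pass))
    alive <- pass
    scored <- data.frame(id = alive, score = unname(fits[alive]),
                         stringsAsFactors = FALSE)
  } else {
    note_stage("pharmacophore", 0L, 0L)
  }

  # stage 3: docking cascade
  dock_cols <- list()
  if (length(config$docking_tables)) {
    for (si in seq_along(config$docking_tables)) {
      stage <- sprintf("docking_%d", si)
      if (!length(alive)) { note_stage(stage, 0L, 0L); next }
      joined <- attach_docking_scores(alive, config$docking_tables[[si]],
                                      config$lower_is_better)
      unmatched <- attr(joined, "unmatched")
      trace[unmatched] <- paste0(stage, "_unscored")
      kept <- cascade_percent_filter(joined, config$cascade_fractions[si])
      if (si == length(config$docking_tables) &&
          !is.null(config$final_cap) && nrow(kept) > config$final_cap)
        kept <- kept[seq_len(config$final_cap), , drop = FALSE]
      trace[setdiff(joined$id, kept$id)] <- stage
      note_stage(stage, length(alive), nrow(kept))
      alive <- kept$id
      dock_cols[[stage]] <- stats::setNames(kept$docking_score, kept$id)
      scored <- kept[, c("id", "score")]
    }
  }

  # shortlist
  shortlist <- character(0)
  if (length(alive)) {
    final_scored <- scored[scored$id %in% alive, , drop = FALSE]
    top <- cascade_percent_filter(final_scored, 1.0)
    shortlist <- top$id[seq_len(min(config$shortlist_size, nrow(top)))]
  }
  trace[setdiff(alive, shortlist)] <- "not_shortlisted"
  trace[shortlist] <- "shortlist"
  note_stage("shortlist", length(alive), length(shortlist))

  tab <- NULL
  if (length(shortlist)) {
    pd <- stats::setNames(cons$prob_a, cons$id)
    pn <- stats::setNames(cons$prob_b, cons$id)
    fit <- stats::setNames(scored$score, scored$id)
    tab <- data.frame(id = shortlist,
                      prob_dense = unname(pd[shortlist]),
                      prob_nfp = unname(pn[shortlist]),
                      score = unname(fit[shortlist]),
                      stringsAsFactors = FALSE)
    for (nm in names(dock_cols))
      tab[[nm]] <- unname(dock_cols[[nm]][shortlist])
    if (!is.null(config$novelty_refs) && length(config$novelty_refs)) {
      tab$novelty_tc <- vapply(shortlist, function(id)
        max_tanimoto_novelty(ecfp4(library[[id]]), config$novelty_refs),
        numeric(1))
    }
  } else {
    tab <- data.frame(id = character(0))
  }
  structure(list(stage_counts = stage_counts, trace = trace, table = tab),
            class = "funnel_report")
}

#' @export
print.funnel_report <- function(x, ...) {
  cat("<funnel_report>\n")
  print(x$stage_counts, row.names = FALSE)
  cat(sprintf("shortlist: %d compound(s)\n", nrow(x$table)))
  invisible(x)
}
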