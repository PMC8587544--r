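# Funnel orchestration: consensus filter, cascade percentage filter,
# docking-score adapter, end-to-end run with trace completeness.

# a tiny trained classifier pair shared across tests (cheap configs)
make_test_classifiers <- function(lib, labels, seed = 7) {
  fps <- lapply(lib, ecfp4, length = 512L)
  gx <- lapply(lib, encode_graph)
  y <- unname(labels)
  n <- length(lib)
  tr <- seq_len(floor(0.7 * n)); va <- setdiff(seq_len(n), tr)
  dcfg <- classifier_config(batch_size = 50L, hidden_widths = c(32L),
                            epochs = 30L, early_stop_patience = 10L,
                            seed = seed)
  ncfg <- classifier_config(batch_size = 40L, nfp_hidden = 12L,
                            nfp_fp_length = 24L, head_width = 12L,
                            epochs = 15L, early_stop_patience = 6L,
                            seed = seed)
  list(dense = train_dense_classifier(list(x = fps[tr], y = y[tr]),
                                      list(x = fps[va], y = y[va]), dcfg),
       nfp = train_nfp_classifier(list(x = gx[tr], y = y[tr]),
                                  list(x = gx[va], y = y[va]), ncfg))
}

test_that("consensus_filter is exactly a set intersection", {
  lib <- make_motif_library(60, seed = 201)
  clf <- make_test_classifiers(lib$mols, lib$labels)
  out <- consensus_filter(lib$mols, clf$dense, clf$nfp, threshold = 0.5)
  # oracle: two independent single-model passes, then intersect
  pa <- predict(clf$dense, lapply(lib$mols, ecfp4, length = 512L))
  pb <- predict(clf$nfp, lib$mols)
  want <- names(lib$mols)[pa >= 0.5 & pb >= 0.5]
  expect_setequal(attr(out, "pass_ids"), want)
  # union rule is a superset
  un <- consensus_filter(lib$mols, clf$dense, clf$nfp, rule = "union")
  expect_true(all(attr(out, "pass_ids") %in% attr(un, "pass_ids")))
  # degenerate thresholds
  all_in <- consensus_filter(lib$mols, clf$dense, clf$nfp, threshold = 0)
  expect_setequal(attr(all_in, "pass_ids"), names(lib$mols))
  none <- consensus_filter(lib$mols, clf$dense, clf$nfp, threshold = 1.01)
  expect_length(attr(none, "pass_ids"), 0)
})

test_that("cascade_percent_filter takes floor(fraction*n), minimum 1", {
  sc <- data.frame(id = sprintf("c%02d", 1:4), score = c(3, 9, 1, 5))
  top <- cascade_percent_filter(sc, 0.25)
  expect_equal(nrow(top), 1)
  expect_equal(top$id, "c02")   # the max
  sc10 <- data.frame(id = sprintf("c%02d", 1:10), score = 10:1)
  expect_equal(nrow(cascade_percent_filter(sc10, 0.25)), 2)  # floor(2.5)
  expect_equal(cascade_percent_filter(sc10, 1.0)$id, sc10$id)
  # stable tie-break by id
  tie <- data.frame(id = c("b", "a", "c"), score = c(1, 1, 1))
  expect_equal(cascade_percent_filter(tie, 0.67)$id, c("a", "b"))
  expect_equal(nrow(cascade_percent_filter(sc10[0, ], 0.5)), 0)
})

test_that("attach_docking_scores joins, reports unmatched, dedupes", {
  ids <- sprintf("m%d", 1:5)
  tab <- data.frame(id = c("m1", "m3", "m3"), score = c(-8.2, -6.1, -7.5))
  got <- attach_docking_scores(ids, tab)
  expect_equal(got$id, c("m1", "m3"))
  expect_equal(got$docking_score[got$id == "m3"], -7.5)  # best kept
  expect_equal(got$score, -got$docking_score)            # sign normalized
  expect_setequal(attr(got, "unmatched"), c("m2", "m4", "m5"))
  # full coverage
  full <- attach_docking_scores(ids, data.frame(id = ids, score = -(1:5)))
  expect_equal(nrow(full), 5)
  expect_length(attr(full, "unmatched"), 0)
  # zero join -> input error; TSV path input works
  expect_error(attach_docking_scores(ids, data.frame(id = "zz", score = 1)),
               "no compound ids matched")
  tf <- tempfile(fileext = ".tsv")
  utils::write.table(tab, tf, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_equal(attach_docking_scores(ids, tf)$id, c("m1", "m3"))
})

test_that("run_funnel produces monotone stages and a complete trace", {
  # small planted world: motif actives that also realize the pharmacophore
  set.seed(31)
  ps <- make_pharmacophore_set(8, 52, seed = 31)
  mols <- ps$mols
  labels <- ps$labels
  clf <- make_test_classifiers(mols, labels, seed = 9)
  hyp <- generate_hypotheses(mols[names(labels)[labels == 1][1:4]],
                             sizes = 4, min_actives_matched = 4)[[1]]
  # synthetic docking table: actives better (lower) scores
  dock <- data.frame(id = names(mols),
                     score = ifelse(labels == 1, -9, -5) + runif(60))
  cfg <- funnel_config(clf$dense, clf$nfp, hypothesis = hyp,
                       docking_tables = list(dock),
                       cascade_fractions = c(0.5),
                       shortlist_size = 5,
                       novelty_refs = lapply(mols[labels == 1][1:3], ecfp4))
  rep <- run_funnel(mols, cfg)
  expect_s3_class(rep, "funnel_report")
  # monotone shrinkage
  expect_true(all(rep$stage_counts$n_out <= rep$stage_counts$n_in))
  # trace completeness: every compound in exactly one bucket
  expect_setequal(names(rep$trace), names(mols))
  expect_false(any(is.na(rep$trace)))
  expect_equal(sum(rep$trace == "shortlist"), nrow(rep$table))
  # novelty column present and in [0,1]
  expect_true(all(rep$table$novelty_tc >= 0 & rep$table$novelty_tc <= 1))
})

test_that("run_funnel is invariant to library ordering", {
  ps <- make_pharmacophore_set(5, 25, seed = 41)
  mols <- ps$mols
  labels <- ps$labels
  clf <- make_test_classifiers(mols, labels, seed = 11)
  hyp <- generate_hypotheses(mols[names(labels)[labels == 1][1:3]],
                             sizes = 4, min_actives_matched = 3)[[1]]
  cfg <- funnel_config(clf$dense, clf$nfp, hypothesis = hyp,
                       shortlist_size = 4)
  r1 <- run_funnel(mols, cfg)
  set.seed(5)
  r2 <- run_funnel(mols[sample(length(mols))], cfg)
  expect_setequal(r1$table$id, r2$table$id)
  expect_equal(r1$stage_counts$n_out, r2$stage_counts$n_out)
  for (id in names(r1$trace)) expect_equal(r1$trace[[id]], r2$trace[[id]])
})

test_that("a stage that eliminates everything finalizes early, not fatally", {
  ps <- make_pharmacophore_set(3, 12, seed = 51)
  clf <- make_test_classifiers(ps$mols, ps$labels, seed = 13)
  hyp <- generate_hypotheses(ps$mols[1:3], sizes = 4,
                             min_actives_matched = 3)[[1]]
  cfg <- funnel_config(clf$dense, clf$nfp, hypothesis = hyp,
                       threshold = 1.01)   # consensus removes everything
  rep <- run_funnel(ps$mols, cfg)
  expect_equal(nrow(rep$table), 0)
  expect_true(all(rep$stage_counts$n_out[-1] == 0))
  expect_true(all(rep$trace == "consensus"))
})
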