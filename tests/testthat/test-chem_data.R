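# Data curation: activity table parsing, threshold labeling, stratified
# splitting, clustering to representatives, decoy selection, round trips.

write_activity_csv <- function(rows) {
  tf <- tempfile(fileext = ".csv")
  writeLines(c("id,smiles,pKi", rows), tf)
  tf
}

test_that("parse_activity_table reads valid rows and reports bad ones", {
  tf <- write_activity_csv(c("a1,CCO,8.5", "a2,c1ccccc1,5.0", "a3,CCN,7.0"))
  res <- parse_activity_table(tf, "csv")
  expect_equal(nrow(res$records), 3L)
  expect_equal(res$records$pKi, c(8.5, 5.0, 7.0))
  expect_equal(nrow(res$rejected), 0L)

  # unclosed ring -> rejected, not dropped silently
  tf2 <- write_activity_csv(c("a1,CCO,8.5", "bad,C1CC,6.5"))
  res2 <- parse_activity_table(tf2, "csv")
  expect_equal(res2$records$id, "a1")
  expect_equal(res2$rejected$id, "bad")
  expect_match(res2$rejected$reason, "unparseable")

  # duplicated id -> single record with median pKi, logged
  tf3 <- write_activity_csv(c("d1,CCO,6.0", "d1,CCO,9.0", "d1,CCO,7.0"))
  res3 <- parse_activity_table(tf3, "csv")
  expect_equal(nrow(res3$records), 1L)
  expect_equal(res3$records$pKi, 7.0)   # oracle: median(6, 9, 7)
  expect_equal(res3$duplicates$n, 3L)

  # missing column -> configuration error; zero parseable -> input error
  tf4 <- tempfile(fileext = ".csv")
  writeLines(c("id,structure", "a,CCO"), tf4)
  expect_error(parse_activity_table(tf4, "csv"), "missing required column")
  tf5 <- write_activity_csv("x,NOTSMILES((,5")
  expect_error(parse_activity_table(tf5, "csv"), "no parseable rows")
})

test_that("assign_labels follows strict-inequality thresholds", {
  rec <- data.frame(id = letters[1:5], smiles = "C",
                    pKi = c(8.5, 5.0, 7.0, 8.0, NA), label = "unknown")
  out <- assign_labels(rec, curation_config())
  expect_equal(out$label, c("active", "inactive", "excluded", "excluded",
                            "unknown"))
  # partition: every record with pKi maps to exactly one category
  set.seed(3)
  rec2 <- data.frame(id = sprintf("r%d", 1:200), pKi = runif(200, 3, 11))
  out2 <- assign_labels(rec2)
  expect_true(all(out2$label %in% c("active", "inactive", "excluded")))
  expect_equal(sum(out2$label == "active"), sum(out2$pKi > 8))
  expect_equal(sum(out2$label == "inactive"), sum(out2$pKi < 6))
})

test_that("largest-remainder apportionment matches the hand oracle", {
  expect_equal(apportion_largest_remainder(10, c(.7, .2, .1)), c(7L, 2L, 1L))
  # oracle: floor quotas + seats by fractional remainder
  oracle <- function(n, r) {
    q <- n * r; b <- floor(q); left <- n - sum(b)
    if (left > 0) {
      o <- order(q - b, decreasing = TRUE)[seq_len(left)]
      b[o] <- b[o] + 1
    }
    as.integer(b)
  }
  expect_equal(apportion_largest_remainder(1573, c(.7, .2, .1)),
               oracle(1573, c(.7, .2, .1)))
  for (n in c(3, 17, 100, 999, 1573, 4001)) {
    got <- apportion_largest_remainder(n, c(.7, .2, .1))
    expect_equal(sum(got), n)
    expect_equal(got, oracle(n, c(.7, .2, .1)))
  }
})

test_that("split_dataset partitions, stratifies and is seed-reproducible", {
  set.seed(9)
  rec <- data.frame(id = sprintf("r%04d", 1:500),
                    pKi = c(runif(300, 8.1, 11), runif(200, 3, 5.9)))
  rec <- assign_labels(rec)
  cfg <- curation_config(seed = 42)
  sp1 <- split_dataset(rec, cfg)
  sp2 <- split_dataset(rec, cfg)
  expect_identical(sp1, sp2)
  expect_false(identical(sp1$split,
                         split_dataset(rec, curation_config(seed = 43))$split))
  # partition
  expect_equal(sort(table(sp1$split), decreasing = TRUE),
               sort(table(rep(c("train", "test", "validation"),
                              apportion_largest_remainder(500, cfg$split_ratios))),
                    decreasing = TRUE), ignore_attr = TRUE)
  # per-stratum deviation < 1 record from exact proportionality
  for (lab in unique(rec$label)) {
    n_lab <- sum(rec$label == lab)
    for (s in c("train", "test", "validation")) {
      got <- sum(sp1$label == lab & sp1$split == s)
      want <- n_lab * cfg$split_ratios[match(s, c("train", "test", "validation"))]
      expect_lt(abs(got - want), 1)
    }
  }
  # tiny stratum warns
  tiny <- assign_labels(data.frame(id = c("a", "b", "c", "d"),
                                   pKi = c(9, 9, 9, 3)))
  expect_warning(split_dataset(tiny, cfg), "fewer than 3 splits")
})

test_that("cluster_representatives picks medoids of similarity blobs", {
  # two well-separated blobs of fingerprints: shared core bits per blob
  mk <- function(core, extra) bit_fp(c(core, extra), 64)
  blob1 <- lapply(1:5, function(i) mk(0:9, 20 + i))
  blob2 <- lapply(1:5, function(i) mk(40:49, 30 + i))
  fps <- c(blob1, blob2)
  reps <- cluster_representatives(fps, 2)
  expect_length(reps, 2)
  expect_true(xor(reps[1] <= 5, reps[2] <= 5) || (reps[1] <= 5 & reps[2] > 5))
  expect_setequal(c(reps[1] <= 5, reps[2] <= 5), c(TRUE, FALSE))
  # oracle: exhaustive medoid within each blob
  sim <- function(i, j) tanimoto(fps[[i]], fps[[j]])
  for (members in list(1:5, 6:10)) {
    ms <- vapply(members, function(i)
      mean(vapply(setdiff(members, i), function(j) sim(i, j), numeric(1))),
      numeric(1))
    expect_true(members[which.max(ms)] %in% reps)
  }
  # n_clusters = n -> identity
  expect_setequal(cluster_representatives(fps, 10), 1:10)
  expect_error(cluster_representatives(fps, 0), "positive")
  expect_error(cluster_representatives(fps, 11), "exceeds")
})

test_that("select_decoys enforces windows, similarity cap and quotas", {
  actives <- list(act1 = parse_smiles("CCCCOc1ccccc1"))
  # self-copies are excluded by the similarity cap
  pool_same <- list(p1 = parse_smiles("CCCCOc1ccccc1"),
                    p2 = parse_smiles("CCCCOc1ccccc1"))
  expect_length(select_decoys(actives, pool_same), 0)

  # toy pool: qualifying candidates identified by brute-force oracle
  pool <- list(
    q1 = parse_smiles("CCCOc1ccccc1C"),     # close analog, inside windows
    q2 = parse_smiles("CCCCSc1ccccc1"),     # S-for-O swap
    far1 = parse_smiles("C"),               # tiny: MW window fails
    far2 = parse_smiles("OCC(O)C(O)C(O)C(O)CO"),  # polar: logp/hba fail
    far3 = parse_smiles("ClC(Cl)(Cl)Cl")
  )
  spec <- decoy_spec(max_tc_to_actives = 0.6)
  got <- select_decoys(actives, pool, spec)
  # oracle: explicit per-candidate window + similarity check
  desc_a <- descriptor_table(actives)
  fp_a <- ecfp4(actives[[1]])
  oracle_ok <- vapply(names(pool), function(id) {
    d <- descriptor_table(pool[id])
    all(abs(desc_a$mw - d$mw) <= spec$mw_window,
        abs(desc_a$logp - d$logp) <= spec$logp_window,
        abs(desc_a$hbd - d$hbd) <= spec$hbd_window,
        abs(desc_a$hba - d$hba) <= spec$hba_window,
        abs(desc_a$rotb - d$rotb) <= spec$rotb_window) &&
      tanimoto(ecfp4(pool[[id]]), fp_a) <= spec$max_tc_to_actives
  }, logical(1))
  expect_setequal(got, names(pool)[oracle_ok])

  # invariant to pool ordering
  got_rev <- select_decoys(actives, rev(pool), spec)
  expect_identical(got, got_rev)

  # quota cap
  spec1 <- decoy_spec(n_per_active = 1, max_tc_to_actives = 0.6)
  expect_length(select_decoys(actives, pool, spec1), 1)

  expect_warning(out <- select_decoys(actives, list(), spec), "empty")
  expect_length(out, 0)
})

test_that("curated records round-trip through CSV on id/structure/pKi/label", {
  tf <- write_activity_csv(c("a1,CCO,8.5", "a2,c1ccc(Cl)cc1,5.0",
                             "a3,CC(=O)NC,7.0"))
  res <- parse_activity_table(tf, "csv")
  rec <- assign_labels(res$records)
  # 3 records -> one per stratum; the degenerate-stratum warning is expected
  rec <- suppressWarnings(split_dataset(rec, curation_config(seed = 1)))
  out <- tempfile(fileext = ".csv")
  write_curated_csv(rec, out)
  back <- read_curated_csv(out)
  expect_equal(back$id, rec$id)
  expect_equal(back$pKi, rec$pKi)
  expect_equal(back$label, rec$label)
  expect_equal(back$split, rec$split)
  # canonical structure identity survives
  expect_equal(vapply(back$mol, mol_identity, character(1)),
               vapply(rec$mol, mol_identity, character(1)))
})

test_that("SMILES and SDF files round-trip structures", {
  mols <- list(eth = parse_smiles("CCO"),
               asa = parse_smiles("CC(=O)Oc1ccccc1C(=O)O"),
               chg = parse_smiles("C[N+](C)(C)C"))
  tf <- tempfile(fileext = ".smi")
  write_smi(mols, tf)
  back <- read_smi(tf)
  expect_equal(names(back$records), names(mols))
  expect_equal(vapply(back$records, mol_identity, character(1)),
               vapply(mols, mol_identity, character(1)))

  # rejection report for a bad line
  writeLines(c("CCO eth", "C1CC broken"), tf)
  back2 <- read_smi(tf)
  expect_equal(back2$rejected$id, "broken")

  # SDF with 3D conformer
  ps <- make_pharmacophore_set(1, 0, seed = 1)
  sf <- tempfile(fileext = ".sdf")
  write_sdf(ps$mols, sf, fields = list(act001 = list(pKi = "8.5")))
  ent <- read_sdf(sf)
  expect_length(ent, 1)
  expect_equal(ent[[1]]$id, "act001")
  expect_equal(ent[[1]]$fields$pKi, "8.5")
  expect_equal(mol_identity(ent[[1]]$mol), mol_identity(ps$mols[[1]]))
  expect_equal(ent[[1]]$mol$conformers[[1]], ps$mols[[1]]$conformers[[1]],
               tolerance = 1e-4)
})
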