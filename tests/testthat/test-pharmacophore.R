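# Pharmacophore perception, hypothesis generation, k-of-n matching and
# screening, against construction oracles (planted geometry is known).

test_that("perceive_features applies the documented dictionary", {
  # benzene with a flat conformer: exactly one R at the centroid
  benz <- parse_smiles("c1ccccc1")
  ang <- seq(0, 2 * pi, length.out = 7)[1:6]
  benz$conformers <- list(cbind(1.39 * cos(ang), 1.39 * sin(ang), 0))
  ft <- perceive_features(benz)
  expect_equal(vapply(ft, `[[`, character(1), "kind"), "R")
  expect_equal(ft[[1]]$center, c(0, 0, 0), tolerance = 1e-9)
  expect_equal(abs(ft[[1]]$direction[3]), 1, tolerance = 1e-9)

  # acetone: one A on the carbonyl oxygen (oracle: the O of C=O),
  # plus no D; the two methyls and central C form one hydrophobe run
  ace <- parse_smiles("CC(=O)C")
  ace$conformers <- list(rbind(c(-1.3, 0, 0), c(0, 0, 0), c(0, 1.2, 0),
                               c(1.3, 0, 0)))
  fa <- perceive_features(ace)
  kinds <- vapply(fa, `[[`, character(1), "kind")
  expect_equal(sum(kinds == "A"), 1)
  expect_equal(fa[[which(kinds == "A")]]$center, c(0, 1.2, 0))
  expect_equal(sum(kinds == "D"), 0)

  # n-hexane: >= 1 hydrophobe, zero A/D/R
  hex <- parse_smiles("CCCCCC")
  hex$conformers <- list(cbind(seq(0, 6.25, length.out = 6), 0, 0))
  fh <- perceive_features(hex)
  kh <- vapply(fh, `[[`, character(1), "kind")
  expect_gte(sum(kh == "H"), 1)
  expect_equal(sum(kh %in% c("A", "D", "R")), 0)

  # charged atoms map to P/N
  tma <- parse_smiles("C[N+](C)(C)C")
  tma$conformers <- list(matrix(rnorm(15), 5, 3))
  expect_true("P" %in% vapply(perceive_features(tma), `[[`, character(1),
                              "kind"))
  expect_error(perceive_features(parse_smiles("CCO")), "no conformer")
})

test_that("kabsch alignment recovers rigid transforms exactly", {
  set.seed(71)
  for (k in 1:10) {
    P <- matrix(rnorm(18), 6, 3)
    # random rotation via QR of a random matrix
    Q <- qr.Q(qr(matrix(rnorm(9), 3)))
    if (det(Q) < 0) Q[, 1] <- -Q[, 1]
    t0 <- rnorm(3)
    moved <- P %*% Q + matrix(t0, 6, 3, byrow = TRUE)
    al <- ligfunnel:::kabsch_align(moved, P)
    expect_lt(al$rmsd, 1e-9)
    expect_equal(al$aligned, P, tolerance = 1e-8)
  }
})

test_that("hypotheses from identical rigid actives match their sources", {
  ps <- make_pharmacophore_set(3, 0, seed = 81)
  hyps <- generate_hypotheses(ps$mols, sizes = 4:5, min_actives_matched = 3)
  expect_gt(length(hyps), 0)
  h <- hyps[[1]]
  expect_equal(h$actives_matched, 3)
  expect_lt(h$mean_rmsd, 1e-6)
  # distance matrix invariants
  expect_true(isSymmetric(h$distances))
  expect_equal(diag(h$distances), rep(0, nrow(h$distances)))
  for (m in ps$mols) {
    res <- match_hypothesis(m, h, k = length(h$features))
    expect_true(res$matched)
    expect_lt(res$rmsd, 1e-6)
  }
  # two molecules with no common feature kinds -> empty list
  hexa <- parse_smiles("CCCCCC")
  hexa$conformers <- list(cbind(seq(0, 6, length.out = 6), 0, 0))
  benz <- parse_smiles("c1ccccc1")
  ang <- seq(0, 2 * pi, length.out = 7)[1:6]
  benz$conformers <- list(cbind(cos(ang), sin(ang), 0))
  expect_length(generate_hypotheses(list(hexa, benz), sizes = 4:5), 0)
})

test_that("matching is invariant under rigid motion of the query", {
  ps <- make_pharmacophore_set(2, 0, seed = 91)
  h <- generate_hypotheses(ps$mols, sizes = 4, min_actives_matched = 2)[[1]]
  mol <- ps$mols[[1]]
  base <- match_hypothesis(mol, h, k = length(h$features))
  set.seed(12)
  for (k in 1:5) {
    Q <- qr.Q(qr(matrix(rnorm(9), 3)))
    if (det(Q) < 0) Q[, 1] <- -Q[, 1]
    tr <- rnorm(3, sd = 5)
    m2 <- mol
    m2$conformers <- list(sweep(mol$conformers[[1]] %*% Q, 2, tr, `+`))
    res <- match_hypothesis(m2, h, k = length(h$features))
    expect_true(res$matched)
    expect_lt(abs(res$rmsd - base$rmsd), 1e-6)
  }
})

test_that("displaced features break k=n but not k=n-1 matching", {
  ps <- make_pharmacophore_set(2, 1, seed = 101)
  hyps <- generate_hypotheses(ps$mols[1:2], sizes = 4, min_actives_matched = 2)
  # take a hypothesis containing a donor (the arm displaced in decoys) but
  # no feature co-located with it (the amine N doubles as an acceptor, so
  # some hypotheses carry two features at the displaced site)
  ok <- vapply(hyps, function(h) {
    kinds <- vapply(h$features, `[[`, character(1), "kind")
    d <- h$distances
    "D" %in% kinds && min(d[upper.tri(d)]) > 0.5
  }, logical(1))
  h <- hyps[ok][[1]]
  n <- length(h$features)
  dec <- ps$mols[["dec001"]]
  full <- match_hypothesis(dec, h, k = n)
  expect_false(full$matched)
  part <- match_hypothesis(dec, h, k = n - 1L)
  expect_true(part$matched)
  expect_equal(part$n_matched, n - 1L)
})

test_that("screening ranks planted actives on top; k-relaxation is monotone", {
  ps <- make_pharmacophore_set(5, 30, seed = 111)
  h <- generate_hypotheses(ps$mols[1:5], sizes = 4:5,
                           min_actives_matched = 5)[[1]]
  act_ids <- names(ps$labels)[ps$labels == 1]
  scr <- screen_with_hypothesis(ps$mols, h, k = h$k, is_active = act_ids)
  pass <- attr(scr, "pass_ids")
  expect_setequal(pass, act_ids)
  expect_true(all(scr$is_active[seq_len(5)]))
  # relaxing k never shrinks the pass list
  pass_relaxed <- attr(screen_with_hypothesis(ps$mols, h, k = h$k - 1L),
                       "pass_ids")
  expect_true(all(pass %in% pass_relaxed))
  # zero-match library -> empty pass list; empty library -> empty screen
  scr0 <- screen_with_hypothesis(ps$mols[6:10], h, k = length(h$features))
  expect_length(attr(scr0, "pass_ids"), 0)
  expect_equal(nrow(screen_with_hypothesis(list(), h)), 0)
})

test_that("hypotheses round-trip through JSON", {
  ps <- make_pharmacophore_set(2, 0, seed = 121)
  h <- generate_hypotheses(ps$mols, sizes = 4, min_actives_matched = 2)[[1]]
  tf <- tempfile(fileext = ".json")
  write_hypothesis(h, tf)
  h2 <- read_hypothesis(tf)
  expect_equal(h2$name, h$name)
  expect_equal(h2$k, h$k)
  expect_equal(length(h2$features), length(h$features))
  expect_equal(h2$distances, h$distances, tolerance = 1e-12)
  mol <- ps$mols[[1]]
  r1 <- match_hypothesis(mol, h)
  r2 <- match_hypothesis(mol, h2)
  expect_equal(r1$fit, r2$fit, tolerance = 1e-9)
})

test_that("arrangement hash is invariant to feature enumeration order", {
  set.seed(17)
  pts <- matrix(rnorm(12, sd = 3), 4, 3)
  kinds <- c("A", "H", "H", "R")
  k0 <- ligfunnel:::.arrangement_key(kinds, pts, 1.0)
  for (i in 1:10) {
    p <- sample(4)
    expect_identical(ligfunnel:::.arrangement_key(kinds[p],
                                                  pts[p, , drop = FALSE],
                                                  1.0), k0)
  }
})
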