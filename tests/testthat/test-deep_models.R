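# Classifiers: analytic gradients vs finite differences, training behavior
# on separable synthetic data, evaluation metrics vs direct-formula oracles.

test_that("dense-net backprop matches finite-difference gradients", {
  set.seed(21)
  X <- matrix(rbinom(6 * 8, 1, 0.4), 6, 8)
  y <- c(1, 0, 1, 1, 0, 0)
  l2 <- 0.01
  params <- ligfunnel:::.mlp_init(c(8, 5, 1))
  loss_fn <- function(p) {
    fwd <- ligfunnel:::.mlp_forward(p, X)
    wsq <- sum(vapply(grep("^W", names(p)), function(i) sum(p[[i]]^2),
                      numeric(1)))
    ligfunnel:::.bce(fwd$prob, y) + l2 * wsq
  }
  fwd <- ligfunnel:::.mlp_forward(params, X)
  grads <- ligfunnel:::.mlp_backward(params, fwd, y, l2)
  eps <- 1e-6
  for (nm in names(params)) {
    for (j in sample(length(params[[nm]]), min(5, length(params[[nm]])))) {
      p2 <- params; p2[[nm]][j] <- p2[[nm]][j] + eps
      p3 <- params; p3[[nm]][j] <- p3[[nm]][j] - eps
      num <- (loss_fn(p2) - loss_fn(p3)) / (2 * eps)
      expect_equal(grads[[nm]][j], num, tolerance = 1e-4)
    }
  }
})

test_that("graph-net backprop matches finite-difference gradients", {
  set.seed(22)
  g <- encode_graph("CC(=O)NC1CC1S")
  y <- 1
  cfg <- classifier_config(nfp_hidden = 6L, nfp_fp_length = 7L,
                           head_width = 4L, nfp_depth = 2L)
  params <- ligfunnel:::.nfp_init(cfg, ncol(g$atom_features),
                                  ncol(g$bond_features))
  loss_fn <- function(p) {
    cache <- ligfunnel:::.nfp_forward(p, g, 2L)
    ligfunnel:::.bce(cache$p, y)
  }
  cache <- ligfunnel:::.nfp_forward(params, g, 2L)
  grads <- ligfunnel:::.nfp_backward(params, g, cache, 2L, cache$p - y)
  eps <- 1e-6
  for (nm in names(params)) {
    for (j in sample(length(params[[nm]]), min(4, length(params[[nm]])))) {
      p2 <- params; p2[[nm]][j] <- p2[[nm]][j] + eps
      p3 <- params; p3[[nm]][j] <- p3[[nm]][j] - eps
      num <- (loss_fn(p2) - loss_fn(p3)) / (2 * eps)
      expect_equal(grads[[nm]][j], num, tolerance = 1e-4)
    }
  }
})

# small, fast configs for behavioral tests; acceptance runs the full scale
small_dense_cfg <- function(seed = 1, batch = 50L)
  classifier_config(batch_size = batch, hidden_widths = c(32L, 16L),
                    epochs = 40L, early_stop_patience = 10L, seed = seed)

test_that("dense classifier separates a rule-labeled set and logs config", {
  ds <- make_fingerprint_dataset(300, fp_length = 256, seed = 31)
  tr <- list(x = ds$x[1:200], y = ds$y[1:200])
  va <- list(x = ds$x[201:250], y = ds$y[201:250])
  te <- list(x = ds$x[251:300], y = ds$y[251:300])
  m <- train_dense_classifier(tr, va, small_dense_cfg())
  expect_s3_class(m, "lig_classifier")
  expect_equal(m$config$batch_size, 50L)
  p <- predict(m, te$x)
  expect_true(all(p >= 0 & p <= 1))
  expect_gte(auc_scores(p, te$y), 0.95)
  # determinism: same seed, same model
  m2 <- train_dense_classifier(tr, va, small_dense_cfg())
  expect_identical(m$params, m2$params)
  expect_identical(predict(m2, te$x), p)
  # batch size 300 accepted and recorded
  m300 <- train_dense_classifier(tr, va, small_dense_cfg(batch = 300L))
  expect_equal(m300$config$batch_size, 300L)
  # single-class training set errors
  expect_error(train_dense_classifier(list(x = ds$x[1:10], y = rep(1, 10)),
                                      va, small_dense_cfg()),
               "single class")
})

test_that("nfp classifier separates a motif-labeled set, invariantly", {
  lib <- make_motif_library(120, seed = 32)
  gx <- lapply(lib$mols, encode_graph)
  y <- unname(lib$labels)
  cfg <- classifier_config(batch_size = 30L, nfp_hidden = 16L,
                           nfp_fp_length = 32L, head_width = 16L,
                           epochs = 25L, early_stop_patience = 8L, seed = 5)
  m <- train_nfp_classifier(list(x = gx[1:80], y = y[1:80]),
                            list(x = gx[81:100], y = y[81:100]), cfg)
  expect_equal(m$config$batch_size, 30L)
  p <- predict(m, gx[101:120])
  expect_gte(auc_scores(p, y[101:120]), 0.95)
  # the planted motif is itself a perfect classifier (construction oracle)
  motif_flag <- vapply(lib$mols[101:120], has_substructure, logical(1),
                       lib$motif)
  expect_equal(as.integer(motif_flag), y[101:120])
  # permutation invariance of the prediction
  set.seed(6)
  mol <- lib$mols[[1]]
  pm <- permute_atoms(mol, sample(nrow(mol$atoms)))
  expect_equal(predict(m, list(mol)), predict(m, list(pm)), tolerance = 1e-10)
})

test_that("predict handles empty input, repeats, and classify threshold", {
  ds <- make_fingerprint_dataset(120, fp_length = 128, seed = 33)
  m <- train_dense_classifier(list(x = ds$x[1:80], y = ds$y[1:80]),
                              list(x = ds$x[81:100], y = ds$y[81:100]),
                              small_dense_cfg(batch = 20L))
  expect_identical(predict(m, list()), numeric(0))
  p <- predict(m, ds$x[c(101, 101, 101)])
  expect_equal(p[1], p[2])
  expect_equal(p[2], p[3])
  expect_identical(classify(m, ds$x[101:120]),
                   as.integer(predict(m, ds$x[101:120]) >= 0.5))
  # architecture/input mismatch
  expect_error(predict(m, list(encode_graph("CCO"))), "lig_fp")
})

test_that("confusion counts match hand enumeration", {
  expect_equal(confusion(rep(c(1, 0), each = 5), rep(c(1, 0), each = 5)),
               list(TP = 5L, FN = 0L, TN = 5L, FP = 0L))
  expect_equal(confusion(rep(c(1, 0), each = 5), rep(c(0, 1), each = 5)),
               list(TP = 0L, FN = 5L, TN = 0L, FP = 5L))
  lab <- c(1, 1, 0, 1, 0, 0, 1, 0)
  prd <- c(1, 0, 0, 1, 1, 0, 0, 1)
  # oracle: explicit loop
  cnt <- c(TP = 0, FN = 0, TN = 0, FP = 0)
  for (i in seq_along(lab)) {
    k <- if (lab[i] == 1 && prd[i] == 1) "TP"
         else if (lab[i] == 1) "FN"
         else if (prd[i] == 0) "TN" else "FP"
    cnt[k] <- cnt[k] + 1
  }
  expect_equal(unlist(confusion(lab, prd)), cnt)
  expect_error(confusion(c(1, 0), c(1)), "length")
})

test_that("eval_metrics matches direct-formula oracles on random tables", {
  # frozen worked example
  r <- eval_metrics(list(TP = 50, FN = 5, TN = 40, FP = 10))
  expect_equal(r$SE, 50 / 55)
  expect_equal(r$MCC, (2000 - 50) / sqrt(55 * 60 * 45 * 50))
  # perfect classifier
  rp <- eval_metrics(list(TP = 5, FN = 0, TN = 5, FP = 0),
                     scores = c(rep(1, 5), rep(0, 5)),
                     labels = rep(c(1, 0), each = 5))
  expect_equal(unlist(rp[c("SE", "SP", "Qplus", "Qminus", "MCC", "AUC")]),
               rep(1, 6), ignore_attr = TRUE)
  # degenerate denominators are NA, not 0
  rd <- eval_metrics(list(TP = 6, FN = 0, TN = 0, FP = 4))
  expect_equal(rd$SP, 0)
  expect_true(is.na(rd$Qminus))
  # random tables vs oracle + label-flip antisymmetry of MCC
  set.seed(41)
  got <- list(); want <- list(); mcc <- numeric(0); mcc_flip <- numeric(0)
  for (k in 1:500) {
    v <- as.list(stats::setNames(sample(0:30, 4, replace = TRUE),
                                 c("TP", "FN", "TN", "FP")))
    got[[k]] <- unlist(eval_metrics(v)[c("SE", "SP", "Qplus", "Qminus",
                                         "MCC")])
    want[[k]] <- unlist(oracle_metrics_direct(v$TP, v$FN, v$TN, v$FP))
    mcc[k] <- got[[k]][["MCC"]]
    mcc_flip[k] <- eval_metrics(list(TP = v$FN, FN = v$TP, TN = v$FP,
                                     FP = v$TN))$MCC
  }
  expect_equal(do.call(rbind, got), do.call(rbind, want),
               ignore_attr = TRUE)
  ok <- !is.na(mcc)
  expect_true(all(mcc[ok] >= -1 & mcc[ok] <= 1))
  both <- ok & !is.na(mcc_flip)
  expect_equal(mcc_flip[both], -mcc[both])
})

test_that("batch_size_sweep trains one model per size and selects by AUC", {
  ds <- make_fingerprint_dataset(200, fp_length = 128, seed = 51)
  tr <- list(x = ds$x[1:140], y = ds$y[1:140])
  te <- list(x = ds$x[141:200], y = ds$y[141:200])
  cfg <- classifier_config(hidden_widths = c(16L), epochs = 15L,
                           early_stop_patience = 5L, seed = 3)
  tab <- batch_size_sweep(tr, te, c(50), "ecfp_dense", cfg)
  expect_equal(nrow(tab), 1)
  tab2 <- batch_size_sweep(tr, te, c(50, 100), "ecfp_dense", cfg)
  expect_equal(nrow(tab2), 2)
  expect_equal(tab2$batch_size, c(50, 100))
  expect_equal(tab2$model, c("Model_D1", "Model_D2"))
  best <- attr(tab2, "best")
  expect_equal(best, order(-tab2$AUC, -tab2$MCC)[1])
  expect_s3_class(attr(tab2, "best_model"), "lig_classifier")
  tf <- tempfile(fileext = ".tsv")
  write_metrics_tsv(tab2, tf)
  expect_equal(utils::read.delim(tf)$batch_size, c(50, 100))
})

test_that("classifier checkpoints round-trip", {
  ds <- make_fingerprint_dataset(100, fp_length = 64, seed = 61)
  m <- train_dense_classifier(list(x = ds$x[1:60], y = ds$y[1:60]),
                              list(x = ds$x[61:80], y = ds$y[61:80]),
                              classifier_config(batch_size = 20L,
                                                hidden_widths = c(8L),
                                                epochs = 5L, seed = 1))
  tf <- tempfile(fileext = ".rds")
  save_classifier(m, tf)
  m2 <- load_classifier(tf)
  expect_identical(predict(m2, ds$x[81:100]), predict(m, ds$x[81:100]))
  expect_error(load_classifier(tempfile()), "not found")
})
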