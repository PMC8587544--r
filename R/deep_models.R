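# The two trainable classifiers of the screening funnel:
#   * a dense feedforward network on circular-fingerprint bits ("DNN"),
#   * a graph-convolutional neural-fingerprint network ("CNN"/NFP) that
#     learns its own fingerprint from the molecular graph.
# Both use ReLU activations, sigmoid probability output, binary
# cross-entropy loss, L2 weight decay, dropout (dense net) and Adam, with
# early stopping on validation loss. Training is deterministic for a fixed
# seed. Implemented directly on BLAS matrix ops; the networks are small by
# design (desk-scale CPU training on ~10^3 compounds).

#' Classifier training configuration
#'
#' Defaults follow common practice for small bioactivity models: learning
#' rate 0.001, L2 0.0001, dropout 0.25, two dense hidden layers (512, 128),
#' graph depth 2 with a learned fingerprint of length 128 and a 64-unit
#' head, at most 200 epochs with patience 20. Batch size defaults to 300
#' for the dense net and 350 for the graph net (see [train_dense_classifier()]
#' and [train_nfp_classifier()]).
#'
#' @param learning_rate Adam step size (> 0).
#' @param batch_size minibatch size (>= 1); `NA` = architecture default.
#' @param l2 L2 regularization coefficient.
#' @param dropout_rate dropout probability in \[0, 1) (dense layers).
#' @param hidden_widths dense-net hidden layer widths.
#' @param nfp_depth number of graph-convolution rounds.
#' @param nfp_fp_length learned fingerprint length.
#' @param nfp_hidden graph-layer hidden width.
#' @param head_width dense head width of the graph net.
#' @param epochs maximum training epochs.
#' @param early_stop_patience epochs without validation improvement before
#'   stopping.
#' @param seed RNG seed controlling init, batching and dropout.
#' @return object of class `classifier_config`.
#' @export
classifier_config <- function(learning_rate = 0.001, batch_size = NA_integer_,
                              l2 = 0.0001, dropout_rate = 0.25,
                              hidden_widths = c(512L, 128L),
                              nfp_depth = 2L, nfp_fp_length = 128L,
                              nfp_hidden = 32L, head_width = 64L,
                              epochs = 200L, early_stop_patience = 20L,
                              seed = 1L) {
  stopifnot(learning_rate > 0, is.na(batch_size) || batch_size >= 1,
            l2 >= 0, dropout_rate >= 0, dropout_rate < 1,
            nfp_depth >= 1, epochs >= 1)
  structure(list(learning_rate = learning_rate,
                 batch_size = if (is.na(batch_size)) NA_integer_
                              else as.integer(batch_size),
                 l2 = l2, dropout_rate = dropout_rate,
                 hidden_widths = as.integer(hidden_widths),
                 nfp_depth = as.integer(nfp_depth),
                 nfp_fp_length = as.integer(nfp_fp_length),
                 nfp_hidden = as.integer(nfp_hidden),
                 head_width = as.integer(head_width),
                 epochs = as.integer(epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 seed = as.integer(seed)),
            class = "classifier_config")
}

.sigmoid <- function(z) 1 / (1 + exp(-pmin(pmax(z, -30), 30)))

.bce <- function(p, y) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Convert fingerprints to a dense 0/1 matrix
#'
#' @param fps list of `lig_fp` of equal length.
#' @return numeric matrix, one row per fingerprint.
#' @export
fp_matrix <- function(fps) {
  stopifnot(length(fps) > 0)
  L <- fps[[1]]$length
  X <- matrix(0, length(fps), L)
  for (i in seq_along(fps)) {
    stopifnot(fps[[i]]$length == L)
    X[i, fps[[i]]$on_bits + 1L] <- 1
  }
  X
}

# ---- Adam optimizer over a flat list of parameter matrices ----------------

.adam_new <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

.adam_step <- function(params, grads, state, lr,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  for (k in seq_along(params)) {
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * grads[[k]]
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * grads[[k]]^2
    mhat <- state$m[[k]] / (1 - beta1^state$t)
    vhat <- state$v[[k]] / (1 - beta2^state$t)
    params[[k]] <- params[[k]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# ---- Dense network --------------------------------------------------------

.mlp_init <- function(sizes) {
  params <- list()
  for (i in seq_len(length(sizes) - 1L)) {
    fan_in <- sizes[i]
    params[[paste0("W", i)]] <- matrix(stats::rnorm(fan_in * sizes[i + 1L],
                                                    sd = sqrt(2 / fan_in)),
                                       fan_in, sizes[i + 1L])
    params[[paste0("b", i)]] <- matrix(0, 1, sizes[i + 1L])
  }
  params
}

.mlp_forward <- function(params, X, dropout = 0, training = FALSE) {
  L <- length(params) / 2L
  acts <- list(X); masks <- vector("list", L)
  H <- X
  for (i in seq_len(L)) {
    Z <- sweep(H %*% params[[paste0("W", i)]], 2,
               params[[paste0("b", i)]], `+`)
    if (i < L) {
      H <- pmax(Z, 0)
      if (training && dropout > 0) {
        mask <- matrix(stats::rbinom(length(H), 1, 1 - dropout) /
                         (1 - dropout), nrow(H), ncol(H))
        H <- H * mask
        masks[[i]] <- mask
      }
    } else {
      H <- .sigmoid(Z)
    }
    acts[[i + 1L]] <- H
  }
  list(acts = acts, masks = masks, prob = as.numeric(H))
}

.mlp_backward <- function(params, fwd, y, l2) {
  L <- length(params) / 2L
  n <- length(y)
  grads <- params
  # dL/dz_out for BCE + sigmoid
  delta <- (fwd$acts[[L + 1L]] - matrix(y, n, 1)) / n
  for (i in L:1) {
    Wn <- paste0("W", i); bn <- paste0("b", i)
    grads[[Wn]] <- crossprod(fwd$acts[[i]], delta) + 2 * l2 * params[[Wn]]
    grads[[bn]] <- matrix(colSums(delta), 1)
    if (i > 1L) {
      delta <- delta %*% t(params[[Wn]])
      if (!is.null(fwd$masks[[i - 1L]])) delta <- delta * fwd$masks[[i - 1L]]
      delta <- delta * (fwd$acts[[i]] > 0)
    }
  }
  grads
}

#' Train the dense fingerprint classifier
#'
#' Feedforward network on fingerprint bit vectors: ReLU hidden layers with
#' dropout, sigmoid output, binary cross-entropy with L2 penalty, Adam,
#' early stopping on validation loss (best weights restored).
#'
#' @param train_set list with `x` (list of `lig_fp`, or a 0/1 matrix) and
#'   `y` (binary labels). Must contain both classes.
#' @param validation_set same structure; used for early stopping.
#' @param config a [classifier_config()]; `batch_size` defaults to 300.
#' @return object of class `lig_classifier` with architecture tag
#'   `"ecfp_dense"`.
#' @export
train_dense_classifier <- function(train_set, validation_set,
                                   config = classifier_config()) {
  stopifnot(inherits(config, "classifier_config"))
  X <- if (is.matrix(train_set$x)) train_set$x else fp_matrix(train_set$x)
  y <- as.numeric(train_set$y)
  Xv <- if (is.matrix(validation_set$x)) validation_set$x
        else fp_matrix(validation_set$x)
  yv <- as.numeric(validation_set$y)
  if (length(unique(y)) < 2L)
    stop("training set contains a single class")
  batch <- if (is.na(config$batch_size)) 300L else config$batch_size
  sizes <- c(ncol(X), config$hidden_widths, 1L)

  with_seed(config$seed, {
    params <- .mlp_init(sizes)
    state <- .adam_new(params)
    best <- list(loss = Inf, params = params, epoch = 0L)
    stall <- 0L
    history <- data.frame(epoch = integer(), train_loss = numeric(),
                          val_loss = numeric())
    for (epoch in seq_len(config$epochs)) {
      idx <- sample(nrow(X))
      starts <- seq(1, length(idx), by = batch)
      for (s in starts) {
        b <- idx[s:min(s + batch - 1L, length(idx))]
        fwd <- .mlp_forward(params, X[b, , drop = FALSE],
                            config$dropout_rate, training = TRUE)
        grads <- .mlp_backward(params, fwd, y[b], config$l2)
        upd <- .adam_step(params, grads, state, config$learning_rate)
        params <- upd$params; state <- upd$state
      }
      pv <- .mlp_forward(params, Xv)$prob
      vl <- .bce(pv, yv)
      # train loss monitored on a fixed subsample (cost control)
      sub <- seq_len(min(nrow(X), 256L))
      pt <- .mlp_forward(params, X[sub, , drop = FALSE])$prob
      history <- rbind(history, data.frame(epoch = epoch,
                                           train_loss = .bce(pt, y[sub]),
                                           val_loss = vl))
      if (vl < best$loss - 1e-6) {
        best <- list(loss = vl, params = params, epoch = epoch)
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= config$early_stop_patience) break
      }
    }
    structure(list(arch = "ecfp_dense", params = best$params,
                   fp_length = ncol(X), threshold = 0.5,
                   config = utils::modifyList(unclass(config),
                                              list(batch_size = batch)),
                   history = history, best_epoch = best$epoch),
              class = "lig_classifier")
  })
}

# ---- Neural-fingerprint (graph convolution) network -----------------------

.nfp_init <- function(config, n_atom_feat, n_bond_feat) {
  h <- config$nfp_hidden; F <- config$nfp_fp_length
  params <- list()
  fin <- n_atom_feat
  for (d in seq_len(config$nfp_depth)) {
    params[[paste0("Wg", d)]] <- matrix(stats::rnorm(fin * h, sd = sqrt(2 / fin)),
                                        fin, h)
    params[[paste0("Wb", d)]] <- matrix(stats::rnorm(n_bond_feat * h,
                                                     sd = sqrt(2 / n_bond_feat)),
                                        n_bond_feat, h)
    params[[paste0("bg", d)]] <- matrix(0, 1, h)
    params[[paste0("Ws", d)]] <- matrix(stats::rnorm(h * F, sd = sqrt(2 / h)),
                                        h, F)
    params[[paste0("bs", d)]] <- matrix(0, 1, F)
    fin <- h
  }
  params$Wh <- matrix(stats::rnorm(F * config$head_width, sd = sqrt(2 / F)),
                      F, config$head_width)
  params$bh <- matrix(0, 1, config$head_width)
  params$Wo <- matrix(stats::rnorm(config$head_width, sd = sqrt(2 / config$head_width)),
                      config$head_width, 1)
  params$bo <- matrix(0, 1, 1)
  params
}

.row_softmax <- function(U) {
  U <- U - apply(U, 1, max)
  E <- exp(U)
  E / rowSums(E)
}

# forward pass for one molecule; returns cache for backprop
.nfp_forward <- function(params, graph, depth) {
  H <- graph$atom_features
  n <- nrow(H)
  # neighbor aggregation matrices are implicit (neighbor lists)
  agg <- function(M) {
    out <- M * 0
    for (a in seq_len(n)) {
      nb <- graph$neighbors[[a]]
      if (length(nb)) out[a, ] <- colSums(M[nb, , drop = FALSE])
    }
    out
  }
  Bagg <- matrix(0, n, ncol(graph$bond_features))
  for (a in seq_len(n)) {
    bi <- graph$neighbor_bonds[[a]]
    if (length(bi)) Bagg[a, ] <- colSums(graph$bond_features[bi, , drop = FALSE])
  }
  cache <- list(H = list(H), M = list(), S = list(), U = list(), Bagg = Bagg,
                agg = agg)
  Fp <- NULL
  for (d in seq_len(depth)) {
    M <- H + agg(H)
    Z <- M %*% params[[paste0("Wg", d)]] + Bagg %*% params[[paste0("Wb", d)]]
    Z <- sweep(Z, 2, params[[paste0("bg", d)]], `+`)
    H <- pmax(Z, 0)
    U <- sweep(H %*% params[[paste0("Ws", d)]], 2, params[[paste0("bs", d)]], `+`)
    S <- .row_softmax(U)
    Fp <- if (is.null(Fp)) colSums(S) else Fp + colSums(S)
    cache$M[[d]] <- M; cache$H[[d + 1L]] <- H
    cache$S[[d]] <- S; cache$U[[d]] <- U
  }
  fp <- matrix(Fp, 1)
  zh <- fp %*% params$Wh + params$bh
  ah <- pmax(zh, 0)
  p <- .sigmoid(ah %*% params$Wo + params$bo)
  cache$fp <- fp; cache$zh <- zh; cache$ah <- ah; cache$p <- as.numeric(p)
  cache
}

# backward pass for one molecule; dout = dL/dlogit (scalar)
.nfp_backward <- function(params, graph, cache, depth, dout) {
  grads <- lapply(params, function(p) p * 0)
  grads$Wo <- t(cache$ah) * dout
  grads$bo <- matrix(dout, 1, 1)
  dah <- dout * t(params$Wo)
  dzh <- dah * (cache$zh > 0)
  grads$Wh <- t(cache$fp) %*% dzh
  grads$bh <- dzh
  dfp <- as.numeric(dzh %*% t(params$Wh))
  dH_next <- NULL   # dL/dH_d flowing from layer d+1
  for (d in depth:1) {
    S <- cache$S[[d]]
    # dL/dU through row softmax: dU = S * (dfp - rowSums(S * dfp))
    G <- matrix(dfp, nrow(S), length(dfp), byrow = TRUE)
    dU <- S * (G - rowSums(S * G))
    H <- cache$H[[d + 1L]]
    dH <- dU %*% t(params[[paste0("Ws", d)]])
    if (!is.null(dH_next)) dH <- dH + dH_next
    grads[[paste0("Ws", d)]] <- crossprod(H, dU)
    grads[[paste0("bs", d)]] <- matrix(colSums(dU), 1)
    dZ <- dH * (H > 0)
    M <- cache$M[[d]]
    grads[[paste0("Wg", d)]] <- crossprod(M, dZ)
    grads[[paste0("Wb", d)]] <- crossprod(cache$Bagg, dZ)
    grads[[paste0("bg", d)]] <- matrix(colSums(dZ), 1)
    dM <- dZ %*% t(params[[paste0("Wg", d)]])
    dH_next <- dM + cache$agg(dM)   # (I + N) since adjacency is symmetric
  }
  grads
}

#' Train the neural-fingerprint (graph convolution) classifier
#'
#' Each graph-convolution round updates atom states by aggregating
#' neighbor states (plus summed incident bond features) through a ReLU
#' layer; every round contributes a softmax-sparsified projection of the
#' atom states, summed over atoms, to a learned fingerprint. Summation
#' makes the prediction invariant to atom numbering. A small ReLU head
#' maps the fingerprint to a probability. Loss, optimizer and early
#' stopping are as in [train_dense_classifier()] (no dropout; the learned
#' fingerprint is already heavily regularized by its softmax).
#'
#' @param train_set list with `x` (list of `lig_graph`, `lig_mol` or SMILES)
#'   and `y` (binary labels).
#' @param validation_set same structure.
#' @param config a [classifier_config()]; `batch_size` defaults to 350.
#' @return object of class `lig_classifier` with architecture tag
#'   `"nfp_graphconv"`.
#' @export
train_nfp_classifier <- function(train_set, validation_set,
                                 config = classifier_config()) {
  stopifnot(inherits(config, "classifier_config"))
  gx <- .as_graphs(train_set$x)
  y <- as.numeric(train_set$y)
  gv <- .as_graphs(validation_set$x)
  yv <- as.numeric(validation_set$y)
  if (length(unique(y)) < 2L)
    stop("training set contains a single class")
  batch <- if (is.na(config$batch_size)) 350L else config$batch_size
  depth <- config$nfp_depth

  with_seed(config$seed, {
    params <- .nfp_init(config, ncol(gx[[1]]$atom_features),
                        ncol(gx[[1]]$bond_features))
    state <- .adam_new(params)
    best <- list(loss = Inf, params = params, epoch = 0L)
    stall <- 0L
    history <- data.frame(epoch = integer(), train_loss = numeric(),
                          val_loss = numeric())
    predict_all <- function(p, graphs) vapply(graphs, function(g)
      .nfp_forward(p, g, depth)$p, numeric(1))
    for (epoch in seq_len(config$epochs)) {
      idx <- sample(length(gx))
      starts <- seq(1, length(idx), by = batch)
      for (s in starts) {
        b <- idx[s:min(s + batch - 1L, length(idx))]
        grads <- NULL
        for (i in b) {
          cache <- .nfp_forward(params, gx[[i]], depth)
          dlogit <- (cache$p - y[i]) / length(b)
          g1 <- .nfp_backward(params, gx[[i]], cache, depth, dlogit)
          grads <- if (is.null(grads)) g1
                   else Map(`+`, grads, g1)
        }
        grads <- Map(function(g, p) g + 2 * config$l2 * p / length(starts),
                     grads, params)
        upd <- .adam_step(params, grads, state, config$learning_rate)
        params <- upd$params; state <- upd$state
      }
      pv <- predict_all(params, gv)
      vl <- .bce(pv, yv)
      history <- rbind(history,
                       data.frame(epoch = epoch,
                                  train_loss = .bce(predict_all(params, gx), y),
                                  val_loss = vl))
      if (vl < best$loss - 1e-6) {
        best <- list(loss = vl, params = params, epoch = epoch)
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= config$early_stop_patience) break
      }
    }
    structure(list(arch = "nfp_graphconv", params = best$params,
                   depth = depth, threshold = 0.5,
                   config = utils::modifyList(unclass(config),
                                              list(batch_size = batch)),
                   history = history, best_epoch = best$epoch),
              class = "lig_classifier")
  })
}

.as_graphs <- function(x) {
  lapply(x, function(it) {
    if (inherits(it, "lig_graph")) it
    else encode_graph(it)
  })
}

#' @export
print.lig_classifier <- function(x, ...) {
  cat(sprintf("<lig_classifier> %s, trained %d epoch(s), threshold %.2f\n",
              x$arch, if (nrow(x$history)) max(x$history$epoch) else 0L,
              x$threshold))
  invisible(x)
}

#' Predict activity probabilities
#'
#' @param object a `lig_classifier`.
#' @param items list of `lig_fp` (dense architecture) or `lig_graph` /
#'   `lig_mol` / SMILES (graph architecture). May be empty.
#' @param ... unused.
#' @return numeric vector of probabilities in \[0, 1\], same length as
#'   `items`; deterministic (no dropout at inference).
#' @export
predict.lig_classifier <- function(object, items, ...) {
  if (!length(items)) return(numeric(0))
  if (object$arch == "ecfp_dense") {
    if (!all(vapply(items, inherits, logical(1), "lig_fp")))
      stop("dense classifier expects lig_fp inputs")
    X <- fp_matrix(items)
    if (ncol(X) != object$fp_length)
      stop("fingerprint length does not match the trained model")
    .mlp_forward(object$params, X)$prob
  } else {
    gx <- .as_graphs(items)
    vapply(gx, function(g) .nfp_forward(object$params, g, object$depth)$p,
           numeric(1))
  }
}

#' Predicted binary labels at the decision threshold
#'
#' @param classifier a `lig_classifier`.
#' @param items as in [predict.lig_classifier()].
#' @return integer vector of 0/1 labels.
#' @export
classify <- function(classifier, items) {
  as.integer(predict(classifier, items) >= classifier$threshold)
}

# ---- Evaluation -----------------------------------------------------------

#' Confusion counts
#'
#' @param labels true binary labels (0/1).
#' @param predictions predicted binary labels (0/1).
#' @return list with TP, FN, TN, FP.
#' @export
confusion <- function(labels, predictions) {
  if (length(labels) != length(predictions))
    stop("labels and predictions differ in length")
  labels <- as.integer(labels); predictions <- as.integer(predictions)
  stopifnot(all(labels %in% 0:1), all(predictions %in% 0:1))
  list(TP = sum(labels == 1L & predictions == 1L),
       FN = sum(labels == 1L & predictions == 0L),
       TN = sum(labels == 0L & predictions == 0L),
       FP = sum(labels == 0L & predictions == 1L))
}

#' AUC from scores by the rank statistic
#'
#' Average ranks for ties; `NA` unless both classes are present.
#'
#' @param scores numeric scores (higher = more likely active).
#' @param labels binary labels.
#' @return numeric in \[0, 1\] or NA.
#' @export
auc_scores <- function(scores, labels) {
  labels <- as.integer(labels)
  A <- sum(labels == 1L); I <- sum(labels == 0L)
  if (A == 0L || I == 0L) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - A * (A + 1) / 2) / (A * I)
}

#' Classification metrics (SE, SP, Q+, Q-, MCC, AUC)
#'
#' Sensitivity `SE = TP/(TP+FN)`, specificity `SP = TN/(TN+FP)`, positive
#' and negative predictive accuracy `Q+ = TP/(TP+FP)`, `Q- = TN/(TN+FN)`,
#' Matthews correlation
#' `MCC = (TP*TN - FN*FP) / sqrt((TP+FN)(TP+FP)(TN+FN)(TN+FP))` and AUC by
#' the rank statistic on `scores`. Any zero denominator yields `NA` for
#' that metric (never a silent 0).
#'
#' @param counts list with TP, FN, TN, FP (from [confusion()]).
#' @param scores optional numeric scores for AUC.
#' @param labels optional binary labels matching `scores`.
#' @return one-row data.frame: SE, SP, Qplus, Qminus, MCC, AUC.
#' @export
eval_metrics <- function(counts, scores = NULL, labels = NULL) {
  TP <- counts$TP; FN <- counts$FN; TN <- counts$TN; FP <- counts$FP
  sdiv <- function(num, den) if (den == 0) NA_real_ else num / den
  denom <- (TP + FN) * (TP + FP) * (TN + FN) * (TN + FP)
  data.frame(
    SE = sdiv(TP, TP + FN),
    SP = sdiv(TN, TN + FP),
    Qplus = sdiv(TP, TP + FP),
    Qminus = sdiv(TN, TN + FN),
    MCC = if (denom == 0) NA_real_ else (TP * TN - FN * FP) / sqrt(denom),
    AUC = if (is.null(scores)) NA_real_ else auc_scores(scores, labels)
  )
}

#' Batch-size sweep with model selection
#'
#' Trains one model per batch size and evaluates on the test set; the best
#' model is selected by AUC, ties broken by MCC (mirrors the funnel's
#' model-selection protocol, where sweeps ran 50..350 step 50 for the dense
#' net and 50..400 for the graph net).
#'
#' @param train_set,test_set input pairs as for the train functions
#'   (the test set doubles as the early-stopping validation set here).
#' @param sizes integer vector of batch sizes.
#' @param architecture `"ecfp_dense"` or `"nfp_graphconv"`.
#' @param config base [classifier_config()]; its batch size is overridden.
#' @return data.frame with one row per size (model, batch_size, SE, SP,
#'   Qplus, Qminus, MCC, AUC); the winning model is in
#'   `attr(result, "best_model")`, its row index in `attr(result, "best")`.
#' @export
batch_size_sweep <- function(train_set, test_set, sizes,
                             architecture = c("ecfp_dense", "nfp_graphconv"),
                             config = classifier_config()) {
  architecture <- match.arg(architecture)
  stopifnot(length(sizes) >= 1)
  tag <- if (architecture == "ecfp_dense") "Model_D" else "Model_C"
  rows <- list(); models <- list()
  for (i in seq_along(sizes)) {
    cfg <- config; cfg$batch_size <- as.integer(sizes[i])
    model <- if (architecture == "ecfp_dense")
      train_dense_classifier(train_set, test_set, cfg)
    else train_nfp_classifier(train_set, test_set, cfg)
    p <- predict(model, test_set$x)
    cm <- confusion(test_set$y, as.integer(p >= model$threshold))
    met <- eval_metrics(cm, p, test_set$y)
    rows[[i]] <- cbind(data.frame(model = paste0(tag, i),
                                  batch_size = sizes[i]), met)
    models[[i]] <- model
  }
  out <- do.call(rbind, rows)
  best <- order(-out$AUC, -out$MCC)[1]
  attr(out, "best") <- best
  attr(out, "best_model") <- models[[best]]
  out
}

#' Save / load a trained classifier
#'
#' The checkpoint is a single RDS archive holding weights, configuration
#' and architecture tag.
#'
#' @param classifier a `lig_classifier`.
#' @param path checkpoint file.
#' @export
save_classifier <- function(classifier, path) {
  stopifnot(inherits(classifier, "lig_classifier"))
  saveRDS(classifier, path)
  invisible(path)
}

#' @rdname save_classifier
#' @return `load_classifier` returns the `lig_classifier`.
#' @export
load_classifier <- function(path) {
  if (!file.exists(path)) stop("classifier checkpoint not found: ", path)
  obj <- readRDS(path)
  stopifnot(inherits(obj, "lig_classifier"))
  obj
}

#' Write a metrics table as TSV
#'
#' Column order mirrors the model-selection tables: model, batch size, SE,
#' SP, Q+, Q-, MCC, AUC.
#'
#' @param table data.frame from [batch_size_sweep()].
#' @param path output file.
#' @export
write_metrics_tsv <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
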