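# Ligand-based 3D pharmacophores: typed feature perception on conformers,
# common-arrangement hypothesis generation across actives, and k-of-n
# partial matching by rigid least-squares superposition.
#
# This is an open re-specification of what commercial packages do with
# proprietary algorithms: feature chemistry comes from a documented rule
# dictionary, common arrangements are found by hashing binned pairwise
# distance geometry, and matching superposes candidate feature points onto
# the hypothesis with the Kabsch algorithm. No numerical agreement with any
# commercial tool is claimed.

#' Pharmacophore feature
#'
#' @param kind one of `"A"` (H-bond acceptor), `"D"` (donor), `"H"`
#'   (hydrophobe), `"R"` (aromatic ring), `"P"` (positive), `"N"`
#'   (negative).
#' @param center numeric length-3 position (Angstrom).
#' @param direction optional unit vector (ring normals; checked during
#'   matching only when both sides define one).
#' @param tolerance matching sphere radius in Angstrom (> 0, default 2).
#' @param atoms integer indices of the source atoms (optional, provenance).
#' @return object of class `pharm_feature`.
#' @export
pharm_feature <- function(kind, center, direction = NULL, tolerance = 2.0,
                          atoms = integer(0)) {
  kind <- match.arg(kind, c("A", "D", "H", "R", "P", "N"))
  stopifnot(length(center) == 3L, tolerance > 0)
  if (!is.null(direction)) {
    nv <- sqrt(sum(direction^2))
    stopifnot(nv > 0)
    direction <- direction / nv
  }
  structure(list(kind = kind, center = as.numeric(center),
                 direction = direction, tolerance = tolerance,
                 atoms = as.integer(atoms)),
            class = "pharm_feature")
}

#' Perceive pharmacophore features on a conformer
#'
#' Rule dictionary (documented, deliberately simple):
#' \itemize{
#'   \item A: N or O with formal charge <= 0, excluding pyrrole-type
#'     aromatic N-H (lone pair committed to the ring).
#'   \item D: N or O bearing at least one hydrogen, at the heavy atom.
#'   \item H: each Cl/Br/I atom; a carbon with >= 2 fluorines (CF3-like,
#'     centroid of the group); connected runs (>= 2 atoms) of nonaromatic
#'     carbons whose neighbors are only carbon or halogen, at the run
#'     centroid.
#'   \item R: each aromatic ring, at the ring centroid, with the ring
#'     normal as direction.
#'   \item P / N: formally charged atoms (positive / negative).
#' }
#'
#' @param mol a `lig_mol` with at least one conformer.
#' @param conformer conformer index (default 1).
#' @param tolerance tolerance assigned to each produced feature.
#' @return list of [pharm_feature()].
#' @export
perceive_features <- function(mol, conformer = 1L, tolerance = 2.0) {
  stopifnot(inherits(mol, "lig_mol"))
  if (!length(mol$conformers)) stop("molecule has no conformer")
  xyz <- mol$conformers[[conformer]]
  at <- mol$atoms
  adj <- .adjacency(mol)
  feats <- list()
  add <- function(kind, center, direction = NULL, atoms = integer(0)) {
    feats[[length(feats) + 1L]] <<- pharm_feature(kind, center, direction,
                                                  tolerance, atoms)
  }
  rings <- mol_rings(mol)
  arom_rings <- Filter(function(r) all(at$aromatic[r]), rings)
  pyrrole_n <- unique(unlist(lapply(arom_rings, function(r)
    r[at$element[r] == "N" & at$hcount[r] > 0L])))

  for (a in seq_len(nrow(at))) {
    el <- at$element[a]
    if (el %in% c("N", "O") && at$charge[a] <= 0L && !(a %in% pyrrole_n))
      add("A", xyz[a, ], atoms = a)
    if (el %in% c("N", "O") && at$hcount[a] > 0L)
      add("D", xyz[a, ], atoms = a)
    if (el %in% c("Cl", "Br", "I"))
      add("H", xyz[a, ], atoms = a)
    if (el == "C") {
      fl <- adj[[a]][at$element[adj[[a]]] == "F"]
      if (length(fl) >= 2L) {
        grp <- c(a, fl)
        add("H", colMeans(xyz[grp, , drop = FALSE]), atoms = grp)
      }
    }
    if (at$charge[a] > 0L) add("P", xyz[a, ], atoms = a)
    if (at$charge[a] < 0L) add("N", xyz[a, ], atoms = a)
  }
  # aliphatic carbon runs
  hali <- c("F", "Cl", "Br", "I")
  qual <- vapply(seq_len(nrow(at)), function(a) {
    at$element[a] == "C" && !at$aromatic[a] &&
      all(at$element[adj[[a]]] %in% c("C", hali))
  }, logical(1))
  seen <- logical(nrow(at))
  for (a in which(qual)) {
    if (seen[a]) next
    comp <- a; queue <- a; seen[a] <- TRUE
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) if (qual[w] && !seen[w]) {
        seen[w] <- TRUE; comp <- c(comp, w); queue <- c(queue, w)
      }
    }
    if (length(comp) >= 2L)
      add("H", colMeans(xyz[comp, , drop = FALSE]), atoms = comp)
  }
  # aromatic rings
  for (r in arom_rings) {
    pts <- xyz[r, , drop = FALSE]
    ctr <- colMeans(pts)
    sv <- svd(sweep(pts, 2, ctr))
    add("R", ctr, direction = sv$v[, 3], atoms = r)
  }
  feats
}

# ---------------------------------------------------------------------------
# Rigid superposition (Kabsch)

# Least-squares superposition of P onto Q (both n x 3). Returns the
# transformed P, rotation, translation and RMSD.
kabsch_align <- function(P, Q) {
  stopifnot(nrow(P) == nrow(Q), ncol(P) == 3L, ncol(Q) == 3L)
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  H <- crossprod(Pc, Qc)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  aligned <- Pc %*% t(R)
  aligned <- sweep(aligned, 2, cq, `+`)
  rmsd <- sqrt(mean(rowSums((aligned - Q)^2)))
  list(aligned = aligned, rotation = R, rmsd = rmsd,
       center_from = cp, center_to = cq)
}

# ---------------------------------------------------------------------------
# Hypothesis generation

.pairwise_dist <- function(pts) {
  unname(as.matrix(stats::dist(pts)))
}

# order-invariant key for an arrangement of typed points
.arrangement_key <- function(kinds, pts, bin_width) {
  n <- length(kinds)
  D <- .pairwise_dist(pts)
  toks <- character(0)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    kk <- sort(c(kinds[i], kinds[j]))
    toks <- c(toks, sprintf("%s%s:%d", kk[1], kk[2],
                            as.integer(floor(D[i, j] / bin_width))))
  }
  paste(paste(sort(kinds), collapse = ""), paste(sort(toks), collapse = "|"),
        sep = "/")
}

# best kind-preserving correspondence of (kindsP, ptsP) onto (kindsQ, ptsQ):
# enumerate per-kind permutations, minimize Kabsch RMSD.
.best_correspondence <- function(kindsP, ptsP, kindsQ, ptsQ) {
  stopifnot(length(kindsP) == length(kindsQ))
  if (!identical(sort(kindsP), sort(kindsQ))) return(NULL)
  .perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in .perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  kinds <- unique(kindsP)
  per_kind <- lapply(kinds, function(k) .perms(which(kindsQ == k)))
  best <- NULL
  idxP <- lapply(kinds, function(k) which(kindsP == k))
  grid <- expand.grid(lapply(per_kind, seq_along))
  for (g in seq_len(nrow(grid))) {
    map <- integer(length(kindsP))
    for (ki in seq_along(kinds))
      map[idxP[[ki]]] <- per_kind[[ki]][[grid[g, ki]]]
    al <- kabsch_align(ptsP, ptsQ[map, , drop = FALSE])
    if (is.null(best) || al$rmsd < best$rmsd)
      best <- list(map = map, rmsd = al$rmsd, aligned = al$aligned)
  }
  best
}

#' Generate common pharmacophore hypotheses from active molecules
#'
#' Enumerates size-`n` feature combinations on every active conformer,
#' hashes each arrangement by its sorted kind multiset and binned pairwise
#' distances, and emits one hypothesis per arrangement found in at least
#' `min_actives_matched` distinct actives. Feature centers are the mean
#' positions after superposing all contributing actives onto the first;
#' the hypothesis score is
#' `w1 * (actives_matched / n_actives) + w2 * (1 - mean_RMSD / rmsd_cap)`.
#' Hypotheses are named by their sorted kind string
#' (`AAHHR_1`, `AAHHR_2`, ...) and returned sorted by score.
#'
#' @param mols list of `lig_mol` actives with conformers (>= 2).
#' @param sizes hypothesis sizes to enumerate (default 4:5).
#' @param min_actives_matched minimum distinct actives sharing the
#'   arrangement (default 2).
#' @param bin_width distance hash bin width, Angstrom (default 1).
#' @param tolerance matching sphere radius for emitted features (default 2).
#' @param rmsd_cap RMSD scale in the score (default 2).
#' @param weights score weights `c(w1, w2)` (default 0.7, 0.3).
#' @return list of `pharm_hypothesis` objects (possibly empty), each with
#'   elements `name`, `features`, `distances`, `k`, `actives_matched`,
#'   `mean_rmsd`, `score`.
#' @export
generate_hypotheses <- function(mols, sizes = 4:5, min_actives_matched = 2L,
                                bin_width = 1.0, tolerance = 2.0,
                                rmsd_cap = 2.0, weights = c(0.7, 0.3)) {
  stopifnot(length(mols) >= 2L, all(sizes >= 3L))
  feats <- lapply(mols, perceive_features, tolerance = tolerance)
  buckets <- new.env(parent = emptyenv())
  for (m in seq_along(mols)) {
    fl <- feats[[m]]
    if (!length(fl)) next
    kinds <- vapply(fl, `[[`, character(1), "kind")
    pts <- do.call(rbind, lapply(fl, `[[`, "center"))
    for (n in sizes) {
      if (length(fl) < n) next
      subs <- utils::combn(length(fl), n)
      for (ci in seq_len(ncol(subs))) {
        sel <- subs[, ci]
        key <- .arrangement_key(kinds[sel], pts[sel, , drop = FALSE], bin_width)
        cur <- if (exists(key, envir = buckets)) get(key, envir = buckets)
               else list()
        if (any(vapply(cur, function(e) e$mol == m, logical(1)))) next
        cur[[length(cur) + 1L]] <- list(mol = m, sel = sel)
        assign(key, cur, envir = buckets)
      }
    }
  }
  hyps <- list()
  for (key in ls(buckets)) {
    entries <- get(key, envir = buckets)
    if (length(entries) < min_actives_matched) next
    e1 <- entries[[1]]
    f1 <- feats[[e1$mol]][e1$sel]
    kinds1 <- vapply(f1, `[[`, character(1), "kind")
    pts1 <- do.call(rbind, lapply(f1, `[[`, "center"))
    all_pts <- list(pts1)
    rmsds <- 0
    ok <- TRUE
    for (e in entries[-1]) {
      fe <- feats[[e$mol]][e$sel]
      ke <- vapply(fe, `[[`, character(1), "kind")
      pe <- do.call(rbind, lapply(fe, `[[`, "center"))
      bc <- .best_correspondence(kinds1, pts1, ke, pe)
      if (is.null(bc)) { ok <- FALSE; break }
      # align contributor onto the reference frame
      al <- kabsch_align(pe[bc$map, , drop = FALSE], pts1)
      all_pts[[length(all_pts) + 1L]] <- al$aligned
      rmsds <- c(rmsds, al$rmsd)
    }
    if (!ok) next
    centers <- Reduce(`+`, all_pts) / length(all_pts)
    mean_rmsd <- mean(rmsds[-1])
    if (!length(rmsds[-1])) mean_rmsd <- 0
    n <- length(kinds1)
    features <- lapply(seq_len(n), function(i)
      pharm_feature(kinds1[i], centers[i, ], tolerance = tolerance))
    score <- weights[1] * (length(entries) / length(mols)) +
      weights[2] * max(0, 1 - mean_rmsd / rmsd_cap)
    hyps[[length(hyps) + 1L]] <- structure(
      list(name = NA_character_, features = features,
           distances = .pairwise_dist(centers), k = min(4L, n),
           actives_matched = length(entries), mean_rmsd = mean_rmsd,
           score = score),
      class = "pharm_hypothesis")
  }
  if (!length(hyps)) return(list())
  hyps <- hyps[order(-vapply(hyps, `[[`, numeric(1), "score"))]
  kindstr <- vapply(hyps, function(h)
    paste(sort(vapply(h$features, `[[`, character(1), "kind")), collapse = ""),
    character(1))
  for (ks in unique(kindstr)) {
    sel <- which(kindstr == ks)
    for (j in seq_along(sel))
      hyps[[sel[j]]]$name <- sprintf("%s_%d", ks, j)
  }
  hyps
}

#' @export
print.pharm_hypothesis <- function(x, ...) {
  cat(sprintf("<pharm_hypothesis> %s: %d features, k=%d, matched %d active(s), score %.3f\n",
              x$name, length(x$features), x$k, x$actives_matched, x$score))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Matching and screening

#' Match a molecule against a pharmacophore hypothesis
#'
#' Over all conformers and all correspondences of at least `k`
#' kind-compatible features, the molecule's feature points are rigidly
#' superposed onto the hypothesis; a correspondence is accepted when every
#' matched molecule feature lands within the hypothesis feature's
#' tolerance sphere (and, where both sides define a direction, within a
#' 45-degree cone). The best acceptance maximizes matched count, then
#' minimizes RMSD. Fit score: `matched_count - RMSD / mean(tolerance)`.
#'
#' @param mol a `lig_mol` with conformers.
#' @param hypothesis a `pharm_hypothesis`.
#' @param k minimum matched features (default the hypothesis' own `k`).
#' @param max_angle direction cone half-angle, degrees (default 45).
#' @return list with `matched` (logical), `n_matched`, `correspondence`
#'   (hypothesis-feature index -> molecule-feature index, NA = unmatched),
#'   `rmsd`, `fit`, `conformer`.
#' @export
match_hypothesis <- function(mol, hypothesis, k = hypothesis$k,
                             max_angle = 45) {
  stopifnot(inherits(hypothesis, "pharm_hypothesis"))
  if (!length(mol$conformers)) stop("molecule has no conformer")
  n <- length(hypothesis$features)
  stopifnot(k >= 1L, k <= n)
  hk <- vapply(hypothesis$features, `[[`, character(1), "kind")
  hp <- do.call(rbind, lapply(hypothesis$features, `[[`, "center"))
  tol <- vapply(hypothesis$features, `[[`, numeric(1), "tolerance")
  hd <- lapply(hypothesis$features, `[[`, "direction")
  Dh <- .pairwise_dist(hp)
  best <- NULL
  cosmax <- cos(max_angle * pi / 180)

  for (cfi in seq_along(mol$conformers)) {
    feats <- perceive_features(mol, conformer = cfi)
    if (!length(feats)) next
    mk <- vapply(feats, `[[`, character(1), "kind")
    mp <- do.call(rbind, lapply(feats, `[[`, "center"))
    md <- lapply(feats, `[[`, "direction")
    Dm <- .pairwise_dist(mp)
    for (m in n:k) {
      if (!is.null(best) && best$n_matched >= m + 1L) break
      subs <- utils::combn(n, m)
      for (ci in seq_len(ncol(subs))) {
        sel <- subs[, ci]
        res <- .match_subset(sel, hk, hp, tol, hd, Dh, mk, mp, md, Dm,
                             cosmax)
        if (!is.null(res) &&
            (is.null(best) || res$n_matched > best$n_matched ||
             (res$n_matched == best$n_matched && res$rmsd < best$rmsd))) {
          res$conformer <- cfi
          best <- res
        }
      }
      if (!is.null(best) && best$n_matched >= m) break
    }
  }
  if (is.null(best)) {
    return(list(matched = FALSE, n_matched = 0L,
                correspondence = rep(NA_integer_, n), rmsd = NA_real_,
                fit = -Inf, conformer = NA_integer_))
  }
  best$matched <- TRUE
  best$fit <- best$n_matched - best$rmsd / mean(tol)
  corr <- rep(NA_integer_, n)
  corr[best$sel] <- best$map
  best$correspondence <- corr
  best[c("matched", "n_matched", "correspondence", "rmsd", "fit", "conformer")]
}

# backtracking assignment of hypothesis subset `sel` to molecule features
.match_subset <- function(sel, hk, hp, tol, hd, Dh, mk, mp, md, Dm, cosmax) {
  m <- length(sel)
  cand <- lapply(sel, function(i) which(mk == hk[i]))
  if (any(!lengths(cand))) return(NULL)
  best <- NULL
  map <- integer(m)
  assign_next <- function(j) {
    if (j > m) {
      al <- kabsch_align(mp[map, , drop = FALSE], hp[sel, , drop = FALSE])
      devs <- sqrt(rowSums((al$aligned - hp[sel, , drop = FALSE])^2))
      if (any(devs > tol[sel])) return()
      # direction cones where both sides define one
      for (jj in seq_len(m)) {
        dh <- hd[[sel[jj]]]; dm <- md[[map[jj]]]
        if (!is.null(dh) && !is.null(dm)) {
          dmr <- as.numeric(al$rotation %*% dm)
          if (abs(sum(dmr * dh)) < cosmax) return()  # normals are axial
        }
      }
      if (is.null(best) || al$rmsd < best$rmsd)
        best <<- list(sel = sel, map = map, rmsd = al$rmsd, n_matched = m)
      return()
    }
    for (c0 in cand[[j]]) {
      if (c0 %in% map[seq_len(j - 1L)]) next
      ok <- TRUE
      for (jp in seq_len(j - 1L)) {
        if (abs(Dm[c0, map[jp]] - Dh[sel[j], sel[jp]]) >
            tol[sel[j]] + tol[sel[jp]]) { ok <- FALSE; break }
      }
      if (!ok) next
      map[j] <<- c0
      assign_next(j + 1L)
    }
  }
  assign_next(1L)
  best
}

#' Screen a library with a pharmacophore hypothesis
#'
#' Molecules are matched with [match_hypothesis()]; matches are ranked by
#' fit score (ties stable by compound id), non-matching molecules are kept
#' at the bottom with score `-Inf` so enrichment metrics see the whole
#' library.
#'
#' @param library named list of `lig_mol` with conformers.
#' @param hypothesis a `pharm_hypothesis`.
#' @param k minimum matched features (default the hypothesis' `k`).
#' @param is_active optional logical vector (or character vector of active
#'   ids) marking known actives for enrichment computation.
#' @return a [ranked_screen()]; the pass list (matched compounds only) is
#'   in `attr(result, "pass_ids")`, fit details in
#'   `attr(result, "matches")`.
#' @export
screen_with_hypothesis <- function(library, hypothesis, k = hypothesis$k,
                                   is_active = NULL) {
  if (!length(library)) {
    scr <- ranked_screen(character(0), numeric(0), logical(0))
    attr(scr, "pass_ids") <- character(0)
    return(scr)
  }
  stopifnot(!is.null(names(library)))
  ids <- sort(names(library))
  act <- if (is.null(is_active)) rep(FALSE, length(ids))
         else if (is.character(is_active)) ids %in% is_active
         else as.logical(is_active)[match(ids, names(library))]
  fits <- numeric(length(ids)); details <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    res <- match_hypothesis(library[[ids[i]]], hypothesis, k)
    fits[i] <- res$fit
    details[[i]] <- res
  }
  scr <- ranked_screen(ids, fits, act)
  attr(scr, "pass_ids") <- ids[is.finite(fits)]
  attr(scr, "matches") <- stats::setNames(details, ids)
  scr
}

# ---------------------------------------------------------------------------
# Serialization

#' Write a pharmacophore hypothesis to JSON
#'
#' @param hypothesis a `pharm_hypothesis`.
#' @param path output file.
#' @export
write_hypothesis <- function(hypothesis, path) {
  obj <- list(
    name = hypothesis$name,
    k = hypothesis$k,
    actives_matched = hypothesis$actives_matched,
    mean_rmsd = hypothesis$mean_rmsd,
    score = hypothesis$score,
    features = lapply(hypothesis$features, function(f) {
      out <- list(kind = f$kind, center = f$center, tolerance = f$tolerance)
      if (!is.null(f$direction)) out$direction <- f$direction
      out
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a pharmacophore hypothesis from JSON
#'
#' @param path file written by [write_hypothesis()].
#' @return a `pharm_hypothesis`.
#' @export
read_hypothesis <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  features <- lapply(obj$features, function(f)
    pharm_feature(f$kind, unlist(f$center),
                  direction = if (!is.null(f$direction)) unlist(f$direction),
                  tolerance = f$tolerance))
  centers <- do.call(rbind, lapply(features, `[[`, "center"))
  structure(list(name = obj$name, features = features,
                 distances = .pairwise_dist(centers), k = as.integer(obj$k),
                 actives_matched = obj$actives_matched,
                 mean_rmsd = obj$mean_rmsd, score = obj$score),
            class = "pharm_hypothesis")
}
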