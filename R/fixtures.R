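# Synthetic data generators: every pipeline stage is testable without
# external downloads. Each generator is a pure function of its parameters
# and seed. Fixture chemistry deliberately sticks to common elements
# (C, N, O, S, F, Cl); the generators encode statistical structure (class
# separability, planted substructures, planted 3D geometry, prescribed
# active ranks), not the property distributions of real vendor libraries.

#' Labeled fingerprint dataset with a planted bit rule
#'
#' Background bits are sparse Bernoulli noise. The first
#' `informative_bits` positions carry the signal: each sample draws them
#' either from a high-density regime (`p = 0.5 + margin`) or a low-density
#' regime (`p = 0.5 - margin`), and the label is always the
#' majority-threshold rule `sum(informative) >= ceiling((k+1)/2)` applied
#' to the realized bits, flipped with probability `noise`. The margin
#' controls class separability (the fixture's explicit knob): at
#' `margin = 0.35` (default) boundary samples are rare and the classes are
#' cleanly linearly separable; at `margin = 0` the two regimes coincide
#' and separation rests on the razor-edge threshold. A rule-based
#' classifier achieves accuracy `1 - noise` by construction regardless of
#' margin. `null_labels = TRUE` replaces the labels with independent fair
#' coins (the no-signal negative control).
#'
#' @param n number of samples.
#' @param fp_length fingerprint length (default 2048).
#' @param informative_bits number of signal bits (default 11, odd).
#' @param noise label flip probability in \[0, 0.5).
#' @param margin regime separation in \[0, 0.5) (default 0.35).
#' @param background_density P(bit on) outside the informative block.
#' @param null_labels if TRUE, labels are independent coin flips.
#' @param seed RNG seed.
#' @return list with `x` (list of `lig_fp`), `y` (0/1), `rule` (function
#'   lig_fp -> 0/1 implementing the noise-free generating rule).
#' @export
make_fingerprint_dataset <- function(n, fp_length = 2048L,
                                     informative_bits = 11L, noise = 0,
                                     margin = 0.35,
                                     background_density = 0.05,
                                     null_labels = FALSE, seed = 1L) {
  stopifnot(n >= 1, informative_bits < fp_length, noise >= 0, noise < 0.5,
            margin >= 0, margin < 0.5)
  thresh <- ceiling((informative_bits + 1) / 2)
  rule <- function(fp) {
    as.integer(sum(fp$on_bits < informative_bits) >= thresh)
  }
  with_seed(seed, {
    x <- vector("list", n); y <- integer(n)
    for (i in seq_len(n)) {
      p_info <- if (stats::runif(1) < 0.5) 0.5 + margin else 0.5 - margin
      info_on <- which(stats::runif(informative_bits) < p_info) - 1L
      bg_on <- informative_bits - 1L +
        which(stats::runif(fp_length - informative_bits) < background_density)
      fp <- bit_fp(c(info_on, bg_on), fp_length)
      x[[i]] <- fp
      lab <- if (null_labels) stats::rbinom(1, 1, 0.5) else rule(fp)
      if (!null_labels && noise > 0 && stats::runif(1) < noise)
        lab <- 1L - lab
      y[i] <- lab
    }
    list(x = x, y = y, rule = rule)
  })
}

# -- random aliphatic scaffold graphs ---------------------------------------

# grow a random tree of heavy atoms with valence bookkeeping
.random_scaffold <- function(n_heavy, elements = c("C", "C", "C", "N", "O")) {
  val <- c(C = 4L, N = 3L, O = 2L)
  el <- sample(elements, n_heavy, replace = TRUE)
  el[1] <- "C"
  free <- val[el]
  bonds <- NULL
  for (a in seq_len(n_heavy)[-1]) {
    open <- which(free[seq_len(a - 1L)] > 0L)
    if (!length(open)) { el <- el[seq_len(a - 1L)]; break }
    parent <- if (length(open) == 1L) open else sample(open, 1L)
    bonds <- rbind(bonds, data.frame(a1 = parent, a2 = a, order = 1,
                                     aromatic = FALSE))
    free[parent] <- free[parent] - 1L
    free[a] <- free[a] - 1L
  }
  n <- length(el)
  hc <- vapply(seq_len(n), function(a) {
    sel <- if (is.null(bonds)) logical(0) else bonds$a1 == a | bonds$a2 == a
    .implied_h(el[a], 0L, FALSE,
               if (is.null(bonds)) numeric(0) else bonds$order[sel],
               if (is.null(bonds)) logical(0) else bonds$aromatic[sel])
  }, integer(1))
  lig_mol(data.frame(element = el, aromatic = FALSE, charge = 0L,
                     hcount = hc, stringsAsFactors = FALSE), bonds)
}

#' Molecule library with a planted substructure motif
#'
#' Scaffolds are random aliphatic C/N/O trees (no sulfur); actives
#' additionally carry the motif -- by default a sulfonamide
#' `S(N)(=O)=O` -- grafted onto a scaffold carbon, so a substructure
#' search for the motif recovers exactly the actives.
#'
#' @param n library size.
#' @param frac_active fraction of actives (default 0.5).
#' @param motif motif SMILES; its first atom is the attachment point and
#'   must have a free valence (default `"S(N)(=O)=O"`).
#' @param scaffold_size range of scaffold heavy-atom counts (default 4:9).
#' @param seed RNG seed.
#' @return list with `mols` (named list of `lig_mol`), `labels` (named
#'   0/1), `motif` (the motif as `lig_mol`, for substructure checks).
#' @export
make_motif_library <- function(n, frac_active = 0.5, motif = "S(N)(=O)=O",
                               scaffold_size = 4:9, seed = 1L) {
  stopifnot(n >= 1, frac_active >= 0, frac_active <= 1)
  pat <- try_parse_smiles(motif)
  if (is.null(pat)) stop("motif is not valid chemistry: ", motif)
  if (any(pat$atoms$element == "C"))
    stop("motif must not contain carbon (scaffolds are carbon-based, ",
         "which would blur the planted signal)")
  n_active <- round(n * frac_active)
  with_seed(seed, {
    mols <- vector("list", n); labels <- integer(n)
    for (i in seq_len(n)) {
      # regenerate until a graft point exists (a carbon with a free H);
      # rarely needed, keeps actives and inactives drawn from one family
      repeat {
        sc <- .random_scaffold(sample(scaffold_size, 1L))
        if (any(sc$atoms$element == "C" & sc$atoms$hcount > 0L)) break
      }
      active <- i <= n_active
      if (active) {
        # graft: bond motif atom 1 to a scaffold carbon with free valence
        nc <- n_atoms(sc)
        cand <- which(sc$atoms$element == "C" & sc$atoms$hcount > 0L)
        att <- if (length(cand) == 1L) cand else sample(cand, 1L)
        at <- rbind(sc$atoms, pat$atoms)
        bd <- rbind(sc$bonds[, c("a1", "a2", "order", "aromatic")],
                    data.frame(a1 = pat$bonds$a1 + nc, a2 = pat$bonds$a2 + nc,
                               order = pat$bonds$order,
                               aromatic = pat$bonds$aromatic),
                    data.frame(a1 = att, a2 = nc + 1L, order = 1,
                               aromatic = FALSE))
        at$hcount[att] <- at$hcount[att] - 1L
        k <- nc + 1L
        sel <- bd$a1 == k | bd$a2 == k
        at$hcount[k] <- .implied_h(at$element[k], at$charge[k], at$aromatic[k],
                                   bd$order[sel], bd$aromatic[sel])
        sc <- lig_mol(at, bd)
      }
      mols[[i]] <- sc
      labels[i] <- as.integer(active)
    }
    ids <- sprintf("syn%04d", seq_len(n))
    # shuffle so actives are not a prefix
    ord <- sample(n)
    list(mols = stats::setNames(mols[ord], ids),
         labels = stats::setNames(labels[ord], ids),
         motif = pat)
  })
}

# -- planted 3D pharmacophore molecules -------------------------------------

.DEFAULT_PHARM_GEOMETRY <- rbind(
  A = c(0.0, 0.0, 0.0),
  D = c(5.4, 0.0, 0.0),
  H = c(2.2, 4.3, 0.0),
  R = c(2.6, 1.8, 3.4)
)

# embed a distance matrix in 3D via classical scaling; error if infeasible
.embed_distances <- function(D, tol = 1e-6) {
  D <- as.matrix(D)
  n <- nrow(D)
  stopifnot(isSymmetric(unname(D)), all(diag(D) == 0))
  for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n))
    if (D[i, j] > D[i, k] + D[k, j] + tol)
      stop("distance matrix violates the triangle inequality")
  J <- diag(n) - 1 / n
  B <- -0.5 * J %*% (D^2) %*% J
  e <- eigen(B, symmetric = TRUE)
  if (any(e$values < -1e-6 * max(abs(e$values))) ||
      sum(e$values > 1e-8) > 3L)
    stop("distance matrix is not embeddable in 3D")
  keep <- which(e$values > 1e-8)
  X <- e$vectors[, keep, drop = FALSE] %*% diag(sqrt(e$values[keep]),
                                                length(keep))
  cbind(X, matrix(0, n, 3L - ncol(X)))
}

# build one rigid molecule realizing an A/D/H/R feature quadrilateral
.planted_pharm_mol <- function(targets, displace_d = 0) {
  A <- targets["A", ]; Dv <- targets["D", ]; H <- targets["H", ]
  R <- targets["R", ]
  if (displace_d != 0) {
    u <- Dv - colMeans(targets)
    u <- u / sqrt(sum(u^2))
    Dv <- Dv + displace_d * u
  }
  ring_r <- 1.39
  ang <- seq(0, 2 * pi, length.out = 7L)[1:6]
  ring <- cbind(R[1] + ring_r * cos(ang), R[2] + ring_r * sin(ang),
                rep(R[3], 6))
  uA <- A - R; uA <- uA / sqrt(sum(uA^2))
  C8 <- A + 1.23 * uA          # carbonyl carbon, O sits exactly at A
  C7 <- (ring[1, ] + C8) / 2   # CH2 linker ring->carbonyl
  N11 <- Dv                    # amine N at the donor site
  C10 <- (ring[4, ] + N11) / 2 # CH2 linker ring->amine
  prop_dir <- c(1, 0, 0)
  C12 <- H + 1.3 * prop_dir; C13 <- H; C14 <- H - 1.3 * prop_dir
  coords <- rbind(ring, C7, C8, A, C10, N11, C12, C13, C14)
  atoms <- data.frame(
    element = c(rep("C", 6), "C", "C", "O", "C", "N", "C", "C", "C"),
    aromatic = c(rep(TRUE, 6), rep(FALSE, 8)),
    charge = 0L,
    hcount = c(1L, 1L, 0L, 1L, 0L, 1L,   # ring: 1,4 substituted later
               2L, 1L, 0L, 2L, 2L, 2L, 2L, 3L),
    stringsAsFactors = FALSE
  )
  # ring substitution pattern: atoms 1 (to C7), 3 (to C12), 4 (to C10)
  atoms$hcount[c(1, 3, 4)] <- 0L
  atoms$hcount[c(2, 5, 6)] <- 1L
  bonds <- data.frame(
    a1 = c(1, 2, 3, 4, 5, 6, 1, 7, 8, 4, 10, 3, 12, 13),
    a2 = c(2, 3, 4, 5, 6, 1, 7, 8, 9, 10, 11, 12, 13, 14),
    order = c(rep(1, 6), 1, 1, 2, 1, 1, 1, 1, 1),
    aromatic = c(rep(TRUE, 6), rep(FALSE, 8))
  )
  lig_mol(atoms, bonds, list(coords))
}

#' Rigid 3D molecules realizing a planted pharmacophore geometry
#'
#' Actives are rigid toy molecules whose perceived features (carbonyl-O
#' acceptor, amine donor, propyl hydrophobe centroid, benzene ring
#' centroid) sit exactly at the target A/D/H/R positions (optionally with
#' Gaussian jitter). Decoys use the same chemistry with the donor arm
#' displaced by `decoy_displacement` Angstrom, violating its distance
#' geometry by more than the matching tolerance.
#'
#' @param n_active number of planted actives.
#' @param n_decoy number of decoys.
#' @param geometry either a 4 x 3 coordinate matrix with rownames
#'   A, D, H, R, or a 4 x 4 distance matrix (embedded in 3D; an
#'   infeasible matrix is an error). Default: a fixed quadrilateral with
#'   pairwise distances 4.3-5.4 Angstrom.
#' @param jitter per-coordinate Gaussian sd applied to feature targets of
#'   each active (default 0: exact realization).
#' @param decoy_displacement donor-arm displacement for decoys, Angstrom
#'   (default 8). Note that a rigid least-squares fit spreads a single
#'   displaced point's error over all matched features, so the
#'   displacement must comfortably exceed the sum of matching tolerances
#'   for decoys to fail a k-of-n match; 8 Angstrom guarantees failure at
#'   the default 2 Angstrom tolerance.
#' @param seed RNG seed.
#' @return list with `mols` (named list: actives then decoys), `labels`
#'   (named 0/1), `geometry` (the A/D/H/R target coordinates).
#' @export
make_pharmacophore_set <- function(n_active = 5L, n_decoy = 20L,
                                   geometry = .DEFAULT_PHARM_GEOMETRY,
                                   jitter = 0, decoy_displacement = 8,
                                   seed = 1L) {
  geometry <- as.matrix(geometry)
  if (ncol(geometry) == nrow(geometry) && ncol(geometry) == 4L &&
      all(diag(geometry) == 0)) {
    geometry <- .embed_distances(geometry)
    rownames(geometry) <- c("A", "D", "H", "R")
  }
  stopifnot(identical(rownames(geometry), c("A", "D", "H", "R")),
            ncol(geometry) == 3L)
  with_seed(seed, {
    mols <- list()
    for (i in seq_len(n_active)) {
      tg <- geometry + matrix(stats::rnorm(12, sd = jitter), 4, 3)
      rownames(tg) <- rownames(geometry)
      mols[[sprintf("act%03d", i)]] <- .planted_pharm_mol(tg)
    }
    for (i in seq_len(n_decoy)) {
      tg <- geometry + matrix(stats::rnorm(12, sd = max(jitter, 0.05)), 4, 3)
      rownames(tg) <- rownames(geometry)
      mols[[sprintf("dec%03d", i)]] <-
        .planted_pharm_mol(tg, displace_d = decoy_displacement)
    }
    labels <- stats::setNames(rep(c(1L, 0L), c(n_active, n_decoy)),
                              names(mols))
    list(mols = mols, labels = labels, geometry = geometry)
  })
}

#' Ranked screen with actives at prescribed ranks
#'
#' Scores are strictly decreasing down the list, so the requested 1-based
#' ranks are exactly the final ranks.
#'
#' @param N total compounds.
#' @param A number of actives.
#' @param active_ranks integer vector of distinct ranks in 1..N, length A.
#' @param seed kept for interface uniformity (ids only; scores are
#'   deterministic).
#' @return a [ranked_screen()].
#' @export
make_ranked_screen <- function(N, A, active_ranks, seed = 1L) {
  active_ranks <- as.integer(active_ranks)
  if (length(active_ranks) != A) stop("|active_ranks| must equal A")
  if (anyDuplicated(active_ranks)) stop("active rank collision")
  if (any(active_ranks < 1L | active_ranks > N))
    stop("active ranks out of 1..N")
  ids <- sprintf("cpd%06d", seq_len(N))
  scores <- 1 - (seq_len(N) - 1L) / N
  ranked_screen(ids, scores, seq_len(N) %in% active_ranks)
}
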