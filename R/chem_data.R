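# Activity data curation: reading activity tables, threshold labeling,
# stratified 7:2:1 splitting, clustering potent actives to representative
# compounds, and property-matched decoy selection.
#
# A "record set" is a data.frame with columns id (character), smiles
# (canonical form), pKi (numeric, NA when unknown), label (one of active /
# inactive / excluded / unknown), optionally split, plus a list-column `mol`
# of lig_mol objects.

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores the global `.Random.seed`, so library calls do not
#' perturb user RNG state.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Curation configuration
#'
#' Thresholds follow the strict-inequality convention: pKi strictly above
#' `active_threshold` is active, strictly below `inactive_threshold` is
#' inactive, and everything in between (boundaries included) is excluded
#' from model training.
#'
#' @param active_threshold pKi above which a compound is active (default 8,
#'   i.e. Ki < 10 nM).
#' @param inactive_threshold pKi below which a compound is inactive
#'   (default 6, Ki > 1 uM).
#' @param split_ratios train/test/validation fractions, must sum to 1
#'   (default 0.7/0.2/0.1).
#' @param seed RNG seed used by [split_dataset()].
#' @return object of class `curation_config`.
#' @export
curation_config <- function(active_threshold = 8, inactive_threshold = 6,
                            split_ratios = c(0.7, 0.2, 0.1), seed = 1L) {
  stopifnot(active_threshold > inactive_threshold,
            length(split_ratios) == 3L, all(split_ratios > 0),
            abs(sum(split_ratios) - 1) < 1e-8)
  structure(list(active_threshold = active_threshold,
                 inactive_threshold = inactive_threshold,
                 split_ratios = split_ratios, seed = as.integer(seed)),
            class = "curation_config")
}

#' Parse a compound activity table
#'
#' Reads a CSV/TSV with columns `id`, `smiles`, `pKi` (extra columns are
#' ignored). Rows whose SMILES do not parse are collected in a rejection
#' report rather than silently dropped. Rows duplicating an id are merged
#' into a single record carrying the median pKi (robust to assay outliers);
#' merges are reported in the `duplicates` element.
#'
#' @param path input file.
#' @param format `"csv"` or `"tsv"`.
#' @return list with elements `records` (record-set data.frame, labels
#'   `unknown`), `rejected` (data.frame id/smiles/reason) and `duplicates`
#'   (data.frame id/n/pKi_values).
#' @export
parse_activity_table <- function(path, format = c("csv", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("activity table not found: ", path)
  df <- utils::read.table(path, sep = if (format == "csv") "," else "\t",
                          header = TRUE, stringsAsFactors = FALSE,
                          comment.char = "", quote = "\"")
  need <- c("id", "smiles", "pKi")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("activity table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  df$id <- as.character(df$id)
  df$pKi <- suppressWarnings(as.numeric(df$pKi))
  if (any(!is.na(df$pKi) & df$pKi < 0)) stop("negative pKi values present")

  rejected <- list(); keep <- logical(nrow(df)); mols <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    m <- try_parse_smiles(df$smiles[i])
    if (is.null(m)) {
      rejected[[length(rejected) + 1L]] <-
        data.frame(id = df$id[i], smiles = df$smiles[i],
                   reason = "unparseable SMILES")
    } else {
      keep[i] <- TRUE; mols[[i]] <- m
    }
  }
  df <- df[keep, , drop = FALSE]; mols <- mols[keep]
  if (!nrow(df)) stop("no parseable rows in activity table")

  # merge duplicate ids: median pKi, first structure
  dup_report <- data.frame(id = character(), n = integer(),
                           pKi_values = character())
  if (anyDuplicated(df$id)) {
    dup_ids <- unique(df$id[duplicated(df$id)])
    dup_report <- do.call(rbind, lapply(dup_ids, function(d) {
      v <- df$pKi[df$id == d]
      data.frame(id = d, n = length(v),
                 pKi_values = paste(v, collapse = ";"))
    }))
    first <- !duplicated(df$id)
    med <- vapply(df$id[first], function(d)
      stats::median(df$pKi[df$id == d]), numeric(1))
    mols <- mols[first]
    df <- df[first, , drop = FALSE]
    df$pKi <- med
  }
  records <- data.frame(id = df$id,
                        smiles = vapply(mols, write_smiles, character(1)),
                        pKi = df$pKi, label = "unknown",
                        stringsAsFactors = FALSE)
  records$mol <- mols
  list(records = records,
       rejected = if (length(rejected)) do.call(rbind, rejected)
                  else data.frame(id = character(), smiles = character(),
                                  reason = character()),
       duplicates = dup_report)
}

#' Assign activity labels from pKi thresholds
#'
#' Strict inequalities on both thresholds: a compound at exactly the active
#' threshold is excluded, as is the whole mid-range. Records without pKi
#' keep the label `unknown`.
#'
#' @param records record-set data.frame with a `pKi` column.
#' @param config a [curation_config()].
#' @return the records with the `label` column filled in.
#' @export
assign_labels <- function(records, config = curation_config()) {
  stopifnot(inherits(config, "curation_config"))
  lab <- ifelse(is.na(records$pKi), "unknown",
         ifelse(records$pKi > config$active_threshold, "active",
         ifelse(records$pKi < config$inactive_threshold, "inactive",
                "excluded")))
  records$label <- lab
  records
}

#' Largest-remainder apportionment
#'
#' Distributes `n` items over groups proportional to `ratios`: each group
#' gets the floor of its quota, and the leftover items go to the groups
#' with the largest fractional remainders (ties broken by group order).
#'
#' @param n total count.
#' @param ratios positive fractions summing to 1.
#' @return integer vector summing to `n`.
#' @export
apportion_largest_remainder <- function(n, ratios) {
  stopifnot(n >= 0, all(ratios > 0), abs(sum(ratios) - 1) < 1e-8)
  quota <- n * ratios
  base <- floor(quota)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(quota - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Split a record set into train/test/validation
#'
#' Stratified by label: each stratum is shuffled (seeded) and apportioned
#' over the three splits by largest-remainder rounding, so per-split label
#' proportions deviate from the global ones by less than one record per
#' stratum. Deterministic for a fixed seed.
#'
#' @param records labeled record-set data.frame (>= 3 rows).
#' @param config a [curation_config()] providing `split_ratios` and `seed`.
#' @return the records with a `split` column (`train`/`test`/`validation`).
#' @export
split_dataset <- function(records, config = curation_config()) {
  stopifnot(inherits(config, "curation_config"), nrow(records) >= 3L)
  splits <- c("train", "test", "validation")
  records$split <- NA_character_
  with_seed(config$seed, {
    for (lab in unique(records$label)) {
      idx <- which(records$label == lab)
      if (length(idx) < length(splits))
        warning(sprintf("stratum '%s' has %d record(s), fewer than 3 splits",
                        lab, length(idx)))
      sizes <- apportion_largest_remainder(length(idx), config$split_ratios)
      idx <- sample(idx)
      assign_to <- rep(splits, times = sizes)
      records$split[idx] <- assign_to
    }
  })
  records
}

#' Pick cluster representatives by Tanimoto medoid
#'
#' Average-linkage hierarchical clustering on (1 - Tanimoto) distance,
#' cut into `n_clusters` groups; the representative of each cluster is its
#' medoid, the member with the highest mean intra-cluster Tanimoto
#' similarity (ties broken by index).
#'
#' @param fingerprints list of `lig_fp`.
#' @param n_clusters number of clusters (1..n molecules).
#' @return integer vector of `n_clusters` representative indices, ordered
#'   by cluster id.
#' @export
cluster_representatives <- function(fingerprints, n_clusters) {
  n <- length(fingerprints)
  if (n_clusters <= 0L) stop("n_clusters must be positive")
  if (n_clusters > n) stop("n_clusters exceeds number of molecules")
  sim <- matrix(1, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) if (j > i) {
    s <- tanimoto(fingerprints[[i]], fingerprints[[j]])
    sim[i, j] <- s; sim[j, i] <- s
  }
  cl <- if (n_clusters == n) seq_len(n)
        else stats::cutree(stats::hclust(stats::as.dist(1 - sim),
                                         method = "average"), k = n_clusters)
  vapply(sort(unique(cl)), function(k) {
    members <- which(cl == k)
    if (length(members) == 1L) return(members)
    mean_sim <- vapply(members, function(i) mean(sim[i, setdiff(members, i)]),
                       numeric(1))
    members[which.max(mean_sim)]
  }, integer(1))
}

#' Decoy selection settings
#'
#' Property windows follow DUD-E-style matched-decoy practice: a candidate
#' qualifies when it sits inside every window of at least one active while
#' staying topologically dissimilar (ECFP4 Tanimoto) to all actives.
#'
#' @param n_per_active decoys accepted per active (default 30).
#' @param mw_window molecular weight window, +/- Da (default 25).
#' @param logp_window logP window (default 1.0).
#' @param hbd_window H-bond donor count window (default 1).
#' @param hba_window H-bond acceptor count window (default 1).
#' @param rotb_window rotatable bond count window (default 1).
#' @param max_tc_to_actives maximum allowed Tanimoto to any active
#'   (default 0.75).
#' @return object of class `decoy_spec`.
#' @export
decoy_spec <- function(n_per_active = 30L, mw_window = 25, logp_window = 1.0,
                       hbd_window = 1, hba_window = 1, rotb_window = 1,
                       max_tc_to_actives = 0.75) {
  stopifnot(n_per_active >= 1L, mw_window >= 0, logp_window >= 0,
            hbd_window >= 0, hba_window >= 0, rotb_window >= 0,
            max_tc_to_actives >= 0, max_tc_to_actives <= 1)
  structure(list(n_per_active = as.integer(n_per_active),
                 mw_window = mw_window, logp_window = logp_window,
                 hbd_window = hbd_window, hba_window = hba_window,
                 rotb_window = rotb_window,
                 max_tc_to_actives = max_tc_to_actives),
            class = "decoy_spec")
}

#' Select property-matched decoys
#'
#' Each accepted decoy lies within all property windows of at least one
#' active and has Tanimoto (ECFP4) at most `max_tc_to_actives` to every
#' active. Candidates are processed in id order (so the result does not
#' depend on pool ordering) and each is charged against the first active
#' whose windows it satisfies and whose quota (`n_per_active`) is not yet
#' full; duplicates (by id) are dropped.
#'
#' @param actives named list of `lig_mol` (names are ids).
#' @param candidate_pool named list of `lig_mol`.
#' @param spec a [decoy_spec()].
#' @return character vector of selected decoy ids (subset of pool names).
#' @export
select_decoys <- function(actives, candidate_pool, spec = decoy_spec()) {
  stopifnot(inherits(spec, "decoy_spec"))
  if (!length(candidate_pool)) {
    warning("empty candidate pool; no decoys selected")
    return(character(0))
  }
  stopifnot(!is.null(names(actives)), !is.null(names(candidate_pool)))
  pool_ids <- sort(unique(names(candidate_pool)))
  act_desc <- descriptor_table(actives)
  act_fps <- lapply(actives, ecfp4)
  quota <- rep(spec$n_per_active, length(actives))
  selected <- character(0)
  for (pid in pool_ids) {
    mol <- candidate_pool[[pid]]
    d <- descriptor_table(list(mol))
    fits <- which(
      abs(act_desc$mw - d$mw) <= spec$mw_window &
      abs(act_desc$logp - d$logp) <= spec$logp_window &
      abs(act_desc$hbd - d$hbd) <= spec$hbd_window &
      abs(act_desc$hba - d$hba) <= spec$hba_window &
      abs(act_desc$rotb - d$rotb) <= spec$rotb_window)
    if (!length(fits)) next
    fp <- ecfp4(mol)
    if (max_tanimoto_novelty(fp, act_fps) > spec$max_tc_to_actives) next
    open <- fits[quota[fits] > 0L]
    if (!length(open)) next
    quota[open[1]] <- quota[open[1]] - 1L
    selected <- c(selected, pid)
  }
  selected
}

#' Write a curated record set to CSV
#'
#' Columns: id, canonical_smiles, pKi, label, split (empty when absent).
#'
#' @param records record-set data.frame.
#' @param path output file.
#' @export
write_curated_csv <- function(records, path) {
  out <- data.frame(id = records$id, canonical_smiles = records$smiles,
                    pKi = records$pKi, label = records$label,
                    split = if ("split" %in% names(records)) records$split
                            else NA_character_)
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' Read a curated record set written by [write_curated_csv()]
#'
#' Structures are re-parsed from the canonical SMILES column.
#'
#' @param path input CSV.
#' @return record-set data.frame.
#' @export
read_curated_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(id = "character"))
  mols <- lapply(df$canonical_smiles, parse_smiles)
  records <- data.frame(id = df$id, smiles = df$canonical_smiles,
                        pKi = as.numeric(df$pKi), label = df$label,
                        stringsAsFactors = FALSE)
  if ("split" %in% names(df)) records$split <- df$split
  records$mol <- mols
  records
}

#' Write a rejection report
#'
#' @param rejected data.frame (id, smiles, reason) from
#'   [parse_activity_table()] or [read_smi()].
#' @param path output TSV.
#' @export
write_rejection_report <- function(rejected, path) {
  utils::write.table(rejected, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
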