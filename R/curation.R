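# Curation of the structure corpus: per-chain hydration statistics, sequence
# clustering into redundancy groups, representative selection, and the
# resolution/water-content filters.

#' Curation parameter set
#'
#' Defaults: chains are kept at resolution <= 2.6 A (boundary inclusive) with
#' more than 1.0 observed waters per nucleotide (boundary exclusive);
#' sequences shorter than 24 nt cluster together when they differ at <= 2
#' positions, longer ones when they differ at <= floor(N_nuc / 12) positions
#' (continuous with the short rule at 24 nt, and configurable); resolution
#' ties within 0.1 A are decided by water content.
#'
#' @param max_resolution Angstrom.
#' @param min_waters_per_nt waters-per-nucleotide lower bound (exclusive).
#' @param resolution_tie_window Angstrom.
#' @param short_seq_len length below which the fixed mismatch count applies.
#' @param short_seq_mismatches allowed mismatches for short sequences.
#' @param long_mismatch_fn function of sequence length giving the allowed
#'   mismatch count for long sequences.
#' @param water_contact_cutoff Angstrom, for [waters_per_nucleotide()].
#' @param min_n_nuc minimum chain length admitted at intake.
#' @return list of class `dnahydro_curation_params`.
#' @export
curation_params <- function(max_resolution = 2.6, min_waters_per_nt = 1.0,
                            resolution_tie_window = 0.1, short_seq_len = 24L,
                            short_seq_mismatches = 2L,
                            long_mismatch_fn = function(n) floor(n / 12),
                            water_contact_cutoff = 3.4, min_n_nuc = 6L) {
  stopifnot(max_resolution > 0, resolution_tie_window >= 0,
            water_contact_cutoff > 0, short_seq_len > 0)
  if (long_mismatch_fn(short_seq_len) < short_seq_mismatches) {
    warning("long_mismatch_fn(", short_seq_len, ") < ", short_seq_mismatches,
            ": mismatch rule is discontinuous at the length threshold")
  }
  structure(list(max_resolution = max_resolution,
                 min_waters_per_nt = min_waters_per_nt,
                 resolution_tie_window = resolution_tie_window,
                 short_seq_len = as.integer(short_seq_len),
                 short_seq_mismatches = as.integer(short_seq_mismatches),
                 long_mismatch_fn = long_mismatch_fn,
                 water_contact_cutoff = water_contact_cutoff,
                 min_n_nuc = as.integer(min_n_nuc)),
            class = "dnahydro_curation_params")
}

#' Chain-entry table constructor
#'
#' One row per crystallographically unique DNA chain, the unit of curation.
#'
#' @param structure_id,chain_id identifiers.
#' @param resolution Angstrom.
#' @param sequence string over A, C, G, T, N.
#' @param waters_per_nucleotide nonnegative real, see [waters_per_nucleotide()].
#' @param is_complexed TRUE for protein-DNA complexes, FALSE for uncomplexed.
#' @return data.frame with class `dnahydro_chain_table`, `n_nuc` derived from
#'   the sequence, `cluster_id` unset.
#' @export
chain_table <- function(structure_id, chain_id, resolution, sequence,
                        waters_per_nucleotide, is_complexed = FALSE) {
  stopifnot(all(waters_per_nucleotide >= 0))
  bad <- grepl("[^ACGTN]", sequence)
  if (any(bad)) stop("sequence contains letters outside {A,C,G,T,N}: ",
                     sequence[bad][1L])
  df <- data.frame(structure_id = structure_id, chain_id = chain_id,
                   resolution = resolution, sequence = sequence,
                   n_nuc = nchar(sequence),
                   waters_per_nucleotide = waters_per_nucleotide,
                   cluster_id = NA_integer_,
                   is_complexed = is_complexed,
                   stringsAsFactors = FALSE)
  class(df) <- c("dnahydro_chain_table", class(df))
  df
}

#' Waters per nucleotide of one chain
#'
#' Counts distinct waters -- asymmetric-unit waters plus symmetry mates, each
#' ASU water counted once even if both it and a mate qualify -- whose O atom
#' lies closer than `cutoff` to any heavy atom of the chain, divided by the
#' number of nucleotides.
#'
#' @param model a `dnahydro_model`.
#' @param chain_id chain to score.
#' @param expansion optional water symmetry expansion from [expand_symmetry()].
#' @param cutoff contact cutoff, Angstrom (strict `<`).
#' @param mapping residue-name mapping.
#' @return waters-per-nucleotide ratio.
#' @export
waters_per_nucleotide <- function(model, chain_id, expansion = NULL,
                                  cutoff = 3.4, mapping = nucleotide_mapping()) {
  stopifnot(cutoff > 0)
  res <- residues_from_model(model, chain_id, mapping)
  if (length(res) == 0L) stop("chain ", chain_id, " has no nucleotides")
  chain_xyz <- do.call(rbind, lapply(res, function(r) {
    as.matrix(r$atoms[, c("x", "y", "z")])
  }))
  w <- extract_waters(model, expansion)
  if (nrow(w) == 0L) return(0)
  d <- min_dist_to_set(as.matrix(w[, c("x", "y", "z")]), chain_xyz)
  length(unique(w$water_id[d < cutoff])) / length(res)
}

#' @noRd
hamming <- function(a, b) sum(strsplit(a, "")[[1L]] != strsplit(b, "")[[1L]])

# Best ungapped sliding alignment of the shorter sequence within the longer;
# returns the minimum mismatch count over all offsets.
#' @noRd
sliding_mismatches <- function(short, long) {
  s <- strsplit(short, "")[[1L]]
  l <- strsplit(long, "")[[1L]]
  n <- length(s)
  best <- n
  for (off in 0:(length(l) - n)) {
    best <- min(best, sum(s != l[off + seq_len(n)]))
  }
  best
}

#' @noRd
mismatch_threshold <- function(len, params) {
  if (len < params$short_seq_len) params$short_seq_mismatches
  else params$long_mismatch_fn(len)
}

#' @noRd
sequences_similar <- function(sa, sb, params) {
  la <- nchar(sa); lb <- nchar(sb)
  if (la == lb) return(hamming(sa, sb) <= mismatch_threshold(la, params))
  if (la < lb) sliding_mismatches(sa, sb) <= mismatch_threshold(la, params)
  else sliding_mismatches(sb, sa) <= mismatch_threshold(lb, params)
}

#' Group chains into sequence-redundancy clusters
#'
#' Single-linkage grouping: two chains join when their sequences are the same
#' or similar (equal length: Hamming distance within the length-dependent
#' mismatch allowance; unequal length: best ungapped sliding alignment of the
#' shorter within the longer, allowance from the shorter length). Clusters
#' are the transitive closures. Cluster ids are assigned deterministically in
#' the order of the lexicographically smallest (structure_id, chain_id)
#' member.
#'
#' @param entries a `dnahydro_chain_table`.
#' @param params a `dnahydro_curation_params`.
#' @return the table with `cluster_id` filled in.
#' @export
cluster_chains <- function(entries, params = curation_params()) {
  n <- nrow(entries)
  if (n == 0L) return(entries)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (sequences_similar(entries$sequence[i], entries$sequence[j], params)) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  root <- vapply(seq_len(n), find, integer(1L))
  key <- paste(entries$structure_id, entries$chain_id, sep = "\r")
  smallest <- vapply(split(key, root), min, character(1L))
  ord <- order(smallest)
  id_of_root <- stats::setNames(seq_along(ord), names(smallest)[ord])
  entries$cluster_id <- as.integer(id_of_root[as.character(root)])
  entries
}

#' Select the representative chain of one cluster
#'
#' The best-resolution chain wins; among chains within the resolution tie
#' window of the best, the highest waters-per-nucleotide wins; remaining ties
#' fall back to lexicographic (structure_id, chain_id) order.
#'
#' @param cluster rows of a `dnahydro_chain_table` forming one cluster.
#' @param params a `dnahydro_curation_params`.
#' @return the selected single row.
#' @export
select_representative <- function(cluster, params = curation_params()) {
  if (nrow(cluster) == 0L) stop("empty cluster")
  best_res <- min(cluster$resolution)
  cand <- cluster[cluster$resolution <= best_res + params$resolution_tie_window, ,
                  drop = FALSE]
  cand <- cand[order(-cand$waters_per_nucleotide, cand$structure_id,
                     cand$chain_id), , drop = FALSE]
  cand[1L, , drop = FALSE]
}

#' Filter chains on resolution, water content and length
#'
#' Keeps entries with resolution <= `max_resolution` (inclusive), waters per
#' nucleotide > `min_waters_per_nt` (exclusive) and at least `min_n_nuc`
#' nucleotides; input order is preserved.
#'
#' @inheritParams cluster_chains
#' @return the filtered table.
#' @export
filter_chains <- function(entries, params = curation_params()) {
  keep <- entries$resolution <= params$max_resolution &
    entries$waters_per_nucleotide > params$min_waters_per_nt &
    entries$n_nuc >= params$min_n_nuc
  entries[keep, , drop = FALSE]
}

#' Full curation pass: filter, cluster, select representatives
#'
#' @inheritParams cluster_chains
#' @return a `dnahydro_chain_table` of representatives, one per cluster,
#'   ordered by cluster id; attribute `attrition` records per-stage counts.
#' @export
curate_chains <- function(entries, params = curation_params()) {
  filtered <- filter_chains(entries, params)
  clustered <- cluster_chains(filtered, params)
  reps <- if (nrow(clustered) == 0L) clustered else do.call(rbind, lapply(
    split(clustered, clustered$cluster_id),
    select_representative, params = params))
  rownames(reps) <- NULL
  attr(reps, "attrition") <- c(input = nrow(entries), filtered = nrow(filtered),
                               clusters = length(unique(clustered$cluster_id)))
  reps
}

#' Read / write the chain curation table as CSV
#'
#' @param path CSV file path.
#' @return [read_chain_table()]: a `dnahydro_chain_table`.
#' @export
read_chain_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(chain_id = "character"))
  out <- chain_table(df$structure_id, df$chain_id, df$resolution, df$sequence,
                     df$waters_per_nucleotide,
                     df$is_complexed %||% FALSE)
  if ("cluster_id" %in% names(df)) out$cluster_id <- df$cluster_id
  out
}

#' @rdname read_chain_table
#' @param entries a `dnahydro_chain_table`.
#' @export
write_chain_table <- function(entries, path) {
  utils::write.csv(as.data.frame(entries), path, row.names = FALSE)
  invisible(path)
}
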