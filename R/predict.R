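# Whole-structure hydration prediction by block overlay, and evaluation of
# predicted hydration sites against crystallographically observed waters.

#' Overlay a hydrated block onto a target step
#'
#' Superposes the block reference onto the target step over all shared named
#' heavy atoms (falling back to backbone atoms when base names mismatch,
#' e.g. for modified bases) and applies the transform to the block waters.
#' Each transferred water's weight is scaled by 1 / n_steps of the block, so
#' that populous blocks do not outweigh sparsely populated ones in the
#' accumulated density.
#'
#' @param block a `dnahydro_block`.
#' @param target_step a `dnahydro_step` with the same conformer/sequence
#'   combination.
#' @return data.frame of weighted waters in the target frame (same columns
#'   as block waters); attribute `fit_rmsd` records the overlay r.m.s.d.
#' @export
overlay_block <- function(block, target_step) {
  if (!identical(block$seq2, target_step$seq2) ||
      (!is.na(target_step$ntc) && !identical(block$ntc, target_step$ntc))) {
    stop("block ", block$ntc, "/", block$seq2,
         " does not match target step ", target_step$ntc, "/", target_step$seq2)
  }
  ref <- block$reference
  tgt <- step_atoms(target_step)
  shared <- intersect(ref$label, tgt$label)
  if (length(shared) < 3L) {
    bb <- ref$label[!ref$is_base]
    shared <- intersect(bb, tgt$label)
  }
  if (length(shared) < 3L) stop("fewer than 3 shared atoms for overlay")
  fit <- kabsch_superpose(
    as.matrix(ref[match(shared, ref$label), c("x", "y", "z")]),
    as.matrix(tgt[match(shared, tgt$label), c("x", "y", "z")]))
  out <- block$waters
  if (nrow(out) > 0L) {
    moved <- apply_superposition(as.matrix(out[, c("x", "y", "z")]), fit)
    out$x <- moved[, 1L]; out$y <- moved[, 2L]; out$z <- moved[, 3L]
    out$weight <- out$weight / block$n_steps
  }
  attr(out, "fit_rmsd") <- fit$rmsd
  out
}

#' Predict the hydration structure of a DNA model
#'
#' Splits every DNA chain of the target into overlapping dinucleotide steps,
#' assigns each a conformer/sequence combination, overlays the matching
#' hydrated block, and accumulates all transferred waters into two global
#' density grids (base-flagged waters into the base grid, backbone-flagged
#' into the backbone grid; dual-flagged waters contribute to both). Peaks
#' and occupancies are then computed per grid; because transferred weights
#' already carry the 1 / n_steps scaling, occupancies use divisor 1.
#'
#' Steps classified NANT, and combinations absent from the library or
#' unreliable (unless `allow_unreliable`), are skipped with a log entry.
#'
#' @param target a `dnahydro_model` with at least one extractable step.
#' @param library a `dnahydro_library`.
#' @param classifier a `dnahydro_classifier` (assignment or centroid table).
#' @param dparams a `dnahydro_density_params`.
#' @param aparams a `dnahydro_assoc_params`.
#' @param allow_unreliable overlay blocks below the reliability threshold.
#' @param mapping residue-name mapping.
#' @return object of class `dnahydro_prediction`: list with `base_grid`,
#'   `backbone_grid`, `base_sites`, `backbone_sites`, `per_step_log`
#'   (data.frame: chain, residue_number, ntc, seq2, status), `total_weight`
#'   (summed weight of all transferred waters) and the transferred `waters`.
#' @export
predict_hydration <- function(target, library, classifier,
                              dparams = density_params(),
                              aparams = assoc_params(),
                              allow_unreliable = FALSE,
                              mapping = nucleotide_mapping()) {
  if (length(library$blocks) == 0L) stop("empty block library")
  chains <- unique(target$atoms$chain_id[!target$atoms$is_water &
                                           is_dna_residue(target$atoms$residue_name, mapping)])
  all_waters <- list()
  log <- list()
  n_usable <- 0L
  frame <- target$atoms[!target$atoms$is_water & !target$atoms$is_hydrogen &
                          is_dna_residue(target$atoms$residue_name, mapping), ,
                        drop = FALSE]
  if (nrow(frame) == 0L) stop("target contains no DNA residues")
  for (ch in chains) {
    res <- residues_from_model(target, ch, mapping)
    steps <- extract_steps(res, source = list(structure_id = target$structure_id,
                                              chain_id = ch))
    for (s in steps) {
      s$ntc <- assign_ntc(s, classifier)
      key <- paste0(s$ntc, "/", s$seq2)
      entry <- data.frame(chain_id = ch, residue_number = s$source$residue_number,
                          ntc = s$ntc, seq2 = s$seq2, status = "",
                          stringsAsFactors = FALSE)
      if (s$ntc == "NANT") {
        entry$status <- "skipped: NANT"
      } else if (is.null(library$blocks[[key]])) {
        entry$status <- "skipped: combination absent from library"
      } else if (!library$blocks[[key]]$reliable && !allow_unreliable) {
        entry$status <- "skipped: block below reliability threshold"
      } else {
        w <- tryCatch(overlay_block(library$blocks[[key]], s),
                      error = function(e) NULL)
        if (is.null(w)) {
          entry$status <- "skipped: degenerate overlay superposition"
        } else {
          entry$status <- paste0("used block ", key)
          n_usable <- n_usable + 1L
          if (nrow(w) > 0L) all_waters[[length(all_waters) + 1L]] <- w
        }
      }
      log[[length(log) + 1L]] <- entry
    }
  }
  log <- if (length(log)) do.call(rbind, log) else
    data.frame(chain_id = character(0), residue_number = integer(0),
               ntc = character(0), seq2 = character(0), status = character(0))
  if (nrow(log) == 0L) stop("target yields no extractable steps")
  waters <- if (length(all_waters)) do.call(rbind, all_waters) else
    data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
               near_base = logical(0), near_backbone = logical(0),
               weight = numeric(0))
  rownames(waters) <- NULL
  frame_xyz <- as.matrix(frame[, c("x", "y", "z")])
  base_hs <- hydration_sites(waters[waters$near_base, , drop = FALSE],
                             frame_xyz, n_steps = 1L, category = "base",
                             dparams = dparams, aparams = aparams)
  bb_hs <- hydration_sites(waters[waters$near_backbone, , drop = FALSE],
                           frame_xyz, n_steps = 1L, category = "backbone",
                           dparams = dparams, aparams = aparams)
  structure(list(structure_id = target$structure_id,
                 base_grid = base_hs$grid, backbone_grid = bb_hs$grid,
                 base_sites = base_hs$sites, backbone_sites = bb_hs$sites,
                 per_step_log = log,
                 n_steps_used = n_usable,
                 total_weight = sum(waters$weight),
                 waters = waters),
            class = "dnahydro_prediction")
}

#' @export
print.dnahydro_prediction <- function(x, ...) {
  cat("dnahydro hydration prediction for '", x$structure_id, "'\n", sep = "")
  cat("  steps used: ", x$n_steps_used, " of ", nrow(x$per_step_log),
      "; transferred weight ", signif(x$total_weight, 4L), "\n", sep = "")
  cat("  sites: ", nrow(x$base_sites), " base, ", nrow(x$backbone_sites),
      " backbone\n", sep = "")
  invisible(x)
}

#' All predicted sites of a prediction as one table
#'
#' @param result a `dnahydro_prediction`.
#' @return data.frame of base and backbone sites.
#' @export
predicted_sites <- function(result) {
  rbind(result$base_sites, result$backbone_sites)
}

#' Evaluate predicted hydration sites against observed waters
#'
#' For each predicted hydration site, measures the distance to the nearest
#' observed water molecule (asymmetric-unit waters plus symmetry mates when
#' provided), bins the distances in 0.5 A intervals, and reports the
#' fraction within 1.0 A -- the consensus measure between prediction and
#' crystallographic hydration -- split by category and overall.
#'
#' @param result a `dnahydro_prediction`.
#' @param observed data.frame of observed waters (`x`, `y`, `z`), e.g. from
#'   [extract_waters()] with a symmetry expansion.
#' @return object of class `dnahydro_evaluation`: list with `distances`
#'   (data.frame: category, distance), `histogram` (data.frame: bin_lo,
#'   bin_hi, base, backbone, overall counts) and `frac_within_1A` (named
#'   vector: base, backbone, overall; `NaN` where no sites).
#' @export
evaluate_prediction <- function(result, observed) {
  if (is.null(observed) || nrow(observed) == 0L) {
    stop("no observed waters: evaluation is meaningless")
  }
  sites <- predicted_sites(result)
  obs <- as.matrix(observed[, c("x", "y", "z")])
  dist <- if (nrow(sites) > 0L) {
    min_dist_to_set(as.matrix(sites[, c("x", "y", "z")]), obs)
  } else numeric(0)
  distances <- data.frame(category = sites$category, distance = dist,
                          stringsAsFactors = FALSE)
  max_bin <- if (length(dist)) max(ceiling(max(dist) / 0.5), 2L) else 2L
  bin_lo <- (seq_len(max_bin) - 1L) * 0.5
  counts <- function(d) {
    if (length(d) == 0L) return(integer(max_bin))
    idx <- pmin(max_bin, floor(d / 0.5) + 1L)
    tabulate(idx, nbins = max_bin)
  }
  hist <- data.frame(
    bin_lo = bin_lo, bin_hi = bin_lo + 0.5,
    base = counts(dist[sites$category == "base"]),
    backbone = counts(dist[sites$category == "backbone"]),
    overall = counts(dist))
  # fraction in the first two bins, i.e. strictly below 1.0 A
  frac <- c(
    base = mean(dist[sites$category == "base"] < 1.0),
    backbone = mean(dist[sites$category == "backbone"] < 1.0),
    overall = mean(dist < 1.0))
  structure(list(distances = distances, histogram = hist,
                 frac_within_1A = frac),
            class = "dnahydro_evaluation")
}

#' @export
print.dnahydro_evaluation <- function(x, ...) {
  cat("dnahydro prediction evaluation\n")
  f <- x$frac_within_1A
  cat(sprintf("  within 1.0 A of an observed water: overall %.1f%% (base %.1f%%, backbone %.1f%%)\n",
              100 * f[["overall"]], 100 * f[["base"]], 100 * f[["backbone"]]))
  cat("  sites evaluated:", nrow(x$distances), "\n")
  invisible(x)
}
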