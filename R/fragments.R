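# Dinucleotide fragmentation: residue assembly, overlapping step extraction,
# base/backbone atom partition, backbone torsions, and conformer-class (NtC)
# assignment via external tables or a nearest-centroid approximation.

#' Assemble nucleotide residues of one chain
#'
#' Groups the atoms of a chain into residue records ordered by residue number
#' and insertion code, keeping only residues whose names map to a parent
#' A/C/G/T via `mapping`. Hydrogens are dropped here: every downstream
#' distance computation is heavy-atom only.
#'
#' @param model a `dnahydro_model`.
#' @param chain_id chain identifier.
#' @param mapping residue-name mapping, see [nucleotide_mapping()].
#' @return list of residue records: `list(residue_name, one_letter,
#'   residue_number, ins, atoms)` with `atoms` a data.frame of heavy atoms.
#' @export
residues_from_model <- function(model, chain_id, mapping = nucleotide_mapping()) {
  at <- model$atoms
  at <- at[at$chain_id == chain_id & !at$is_water & !at$is_hydrogen, ,
           drop = FALSE]
  at <- at[is_dna_residue(at$residue_name, mapping), , drop = FALSE]
  if (nrow(at) == 0L) return(list())
  key <- paste(at$residue_number, at$ins, sep = "\r")
  ord <- order(at$residue_number, at$ins)
  at <- at[ord, , drop = FALSE]
  key <- key[ord]
  idx <- split(seq_len(nrow(at)), factor(key, levels = unique(key)))
  lapply(idx, function(i) {
    r <- at[i, , drop = FALSE]
    list(residue_name = r$residue_name[1L],
         one_letter = unname(mapping[r$residue_name[1L]]),
         residue_number = r$residue_number[1L],
         ins = r$ins[1L],
         atoms = r)
  })
}

#' Partition residue atoms into base and backbone sets
#'
#' The split is by atom name, not geometry: the sugar-phosphate vocabulary
#' (P, OP1, OP2, OP3, O5', C5', C4', O4', C3', O3', C2', C1') is backbone --
#' C1' and O4' included -- and every other heavy atom is base.
#'
#' @param residue a residue record from [residues_from_model()].
#' @return list with character vectors `base` and `backbone` of atom names.
#' @export
partition_atoms <- function(residue) {
  nm <- residue$atoms$atom_name
  if (length(nm) == 0L) stop("residue has no heavy atoms")
  bb <- nm[nm %in% BACKBONE_ATOMS]
  list(base = setdiff(nm, BACKBONE_ATOMS), backbone = bb)
}

#' @noRd
new_step <- function(first, second, source) {
  structure(list(first = first, second = second,
                 seq2 = paste0(first$one_letter, second$one_letter),
                 ntc = NA_character_,
                 source = source),
            class = "dnahydro_step")
}

#' @export
print.dnahydro_step <- function(x, ...) {
  cat("dnahydro step ", x$seq2, " (ntc: ", x$ntc %||% NA, ") from ",
      x$source$structure_id %||% "?", " chain ", x$source$chain_id %||% "?",
      " residue ", x$source$residue_number %||% NA, "\n", sep = "")
  invisible(x)
}

#' Heavy atoms of a step as one labeled coordinate table
#'
#' @param step a `dnahydro_step`.
#' @return data.frame with `res_index` (1 or 2), `atom_name`, `label`
#'   (`"1:P"` style, unique within the step), `x`, `y`, `z`, `is_base`.
#' @export
step_atoms <- function(step) {
  out <- lapply(1:2, function(i) {
    r <- if (i == 1L) step$first else step$second
    data.frame(res_index = i,
               atom_name = r$atoms$atom_name,
               label = paste0(i, ":", r$atoms$atom_name),
               x = r$atoms$x, y = r$atoms$y, z = r$atoms$z,
               is_base = !(r$atoms$atom_name %in% BACKBONE_ATOMS),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Split a chain into overlapping dinucleotide steps
#'
#' Yields one step per consecutive covalently linked residue pair (i, i+1).
#' Pairs failing the O3'(i)-P(i+1) linkage test (cutoff generous relative to
#' the ~1.6 A bond so that conformational strain is tolerated but lattice
#' neighbors are not) are skipped, as are residues that did not map to a
#' parent base; an intact chain of n nucleotides gives n-1 steps.
#'
#' @param residues residue list from [residues_from_model()].
#' @param source list with `structure_id` and `chain_id` recorded on steps.
#' @param link_cutoff covalent-linkage cutoff on O3'-P, Angstrom.
#' @return list of `dnahydro_step`; attribute `skipped` holds a data.frame of
#'   skipped pairs and reasons.
#' @export
extract_steps <- function(residues, source = list(structure_id = NA, chain_id = NA),
                          link_cutoff = 2.5) {
  steps <- list()
  skipped <- list()
  if (length(residues) >= 2L) {
    for (i in seq_len(length(residues) - 1L)) {
      r1 <- residues[[i]]
      r2 <- residues[[i + 1L]]
      o3 <- r1$atoms[r1$atoms$atom_name == "O3'", c("x", "y", "z")]
      p <- r2$atoms[r2$atoms$atom_name == "P", c("x", "y", "z")]
      reason <- NULL
      if (is.na(r1$one_letter) || is.na(r2$one_letter)) {
        reason <- "unmapped residue name"
      } else if (nrow(o3) == 0L || nrow(p) == 0L) {
        reason <- "missing O3' or P linkage atoms"
      } else if (vnorm(as.numeric(o3[1L, ]) - as.numeric(p[1L, ])) > link_cutoff) {
        reason <- "chain break (O3'-P beyond cutoff)"
      }
      if (is.null(reason)) {
        steps[[length(steps) + 1L]] <- new_step(
          r1, r2, c(source, list(residue_number = r1$residue_number)))
      } else {
        skipped[[length(skipped) + 1L]] <- data.frame(
          residue_number = r1$residue_number, reason = reason,
          stringsAsFactors = FALSE)
      }
    }
  }
  attr(steps, "skipped") <- if (length(skipped)) do.call(rbind, skipped)
                            else data.frame(residue_number = integer(0),
                                            reason = character(0))
  steps
}

# The nine torsions used by the simplified conformer classifier.
TORSION_NAMES <- c("delta1", "epsilon1", "zeta1", "alpha2", "beta2", "gamma2",
                   "delta2", "chi1", "chi2")

#' @noRd
atom_xyz <- function(residue, name) {
  r <- residue$atoms[residue$atoms$atom_name == name, c("x", "y", "z")]
  if (nrow(r) == 0L) return(NULL)
  as.numeric(r[1L, ])
}

#' @noRd
chi_atoms <- function(residue) {
  if (residue$one_letter %in% c("A", "G")) c("O4'", "C1'", "N9", "C4")
  else c("O4'", "C1'", "N1", "C2")
}

#' Backbone and glycosidic torsions of a step
#'
#' Computes the nine-torsion vector (delta, epsilon, zeta of the first
#' nucleotide; alpha, beta, gamma, delta of the second; chi of both) used by
#' the nearest-centroid conformer classifier. Angles are reported in degrees
#' in `[0, 360)`. If any constituent atom is missing the vector is marked
#' incomplete (`NA` for the affected angles).
#'
#' @param step a `dnahydro_step`.
#' @return named numeric vector of length 9 with attribute `complete`.
#' @export
step_torsions <- function(step) {
  r1 <- step$first
  r2 <- step$second
  quads <- list(
    delta1 = list(c("C5'", "C4'", "C3'", "O3'"), c(1L, 1L, 1L, 1L)),
    epsilon1 = list(c("C4'", "C3'", "O3'", "P"), c(1L, 1L, 1L, 2L)),
    zeta1 = list(c("C3'", "O3'", "P", "O5'"), c(1L, 1L, 2L, 2L)),
    alpha2 = list(c("O3'", "P", "O5'", "C5'"), c(1L, 2L, 2L, 2L)),
    beta2 = list(c("P", "O5'", "C5'", "C4'"), c(2L, 2L, 2L, 2L)),
    gamma2 = list(c("O5'", "C5'", "C4'", "C3'"), c(2L, 2L, 2L, 2L)),
    delta2 = list(c("C5'", "C4'", "C3'", "O3'"), c(2L, 2L, 2L, 2L)),
    chi1 = list(chi_atoms(r1), c(1L, 1L, 1L, 1L)),
    chi2 = list(chi_atoms(r2), c(2L, 2L, 2L, 2L)))
  out <- vapply(quads, function(q) {
    pts <- lapply(seq_len(4L), function(j) {
      atom_xyz(if (q[[2L]][j] == 1L) r1 else r2, q[[1L]][j])
    })
    if (any(vapply(pts, is.null, logical(1L)))) return(NA_real_)
    dihedral_angle(pts[[1L]], pts[[2L]], pts[[3L]], pts[[4L]])
  }, numeric(1L))
  attr(out, "complete") <- !anyNA(out)
  out
}

#' Build a conformer classifier table
#'
#' Two dialects: a centroid table (`label` + nine torsion columns) for
#' nearest-centroid classification, or an assignment table
#' (`structure_id`, `chain_id`, `residue_number`, `label`) exported by an
#' external classifier for lookup.
#'
#' @param df data.frame in one of the two dialects.
#' @return the validated table with class `dnahydro_classifier`.
#' @export
classifier_table <- function(df) {
  if (all(TORSION_NAMES %in% names(df))) {
    if (anyDuplicated(df$label)) stop("duplicate centroid labels")
    attr(df, "dialect") <- "centroid"
  } else if (all(c("structure_id", "chain_id", "residue_number", "label")
                 %in% names(df))) {
    key <- paste(df$structure_id, df$chain_id, df$residue_number)
    if (anyDuplicated(key)) stop("duplicate assignment rows")
    attr(df, "dialect") <- "assignment"
  } else {
    stop("classifier table must be a centroid or an assignment table")
  }
  bad <- setdiff(df$label, ntc_classes())
  if (length(bad) > 0L) {
    stop("labels outside the conformer vocabulary: ", paste(bad, collapse = ", "))
  }
  class(df) <- c("dnahydro_classifier", class(df))
  df
}

#' @rdname classifier_table
#' @param path TSV file with a header row.
#' @export
read_classifier_table <- function(path) {
  classifier_table(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' @rdname classifier_table
#' @param table a `dnahydro_classifier`.
#' @export
write_classifier_table <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

# Per-angle wrapped difference in (-180, 180], Euclidean norm over the nine
# torsions.
#' @noRd
circular_torsion_distance <- function(a, b) {
  d <- (a - b) %% 360
  d[d > 180] <- d[d > 180] - 360
  sqrt(sum(d^2))
}

#' Assign a conformer class to a step
#'
#' In `lookup` mode returns the externally tabulated label for the step's
#' source (structure, chain, first-residue number), or NANT when absent. In
#' `nearest-centroid` mode returns the label of the closest torsion centroid
#' under the circular Euclidean metric, or NANT when the best distance
#' exceeds `rejection_radius` or the torsion vector is incomplete. Ties are
#' broken by the fixed vocabulary order of [ntc_classes()].
#'
#' @param step a `dnahydro_step`.
#' @param table a `dnahydro_classifier`.
#' @param mode `"lookup"` or `"nearest-centroid"` (default: match the table
#'   dialect).
#' @param rejection_radius per-vector Euclidean norm, degrees.
#' @return single conformer label.
#' @export
assign_ntc <- function(step, table, mode = NULL, rejection_radius = 60) {
  mode <- mode %||% switch(attr(table, "dialect"),
                           centroid = "nearest-centroid", assignment = "lookup")
  if (mode == "lookup") {
    hit <- table$structure_id == (step$source$structure_id %||% NA) &
      table$chain_id == (step$source$chain_id %||% NA) &
      table$residue_number == (step$source$residue_number %||% NA)
    hit[is.na(hit)] <- FALSE
    return(if (any(hit)) table$label[which(hit)[1L]] else "NANT")
  }
  tv <- step_torsions(step)
  if (!attr(tv, "complete")) return("NANT")
  cen <- as.matrix(as.data.frame(table)[, TORSION_NAMES])
  d <- apply(cen, 1L, circular_torsion_distance, a = as.numeric(tv))
  best <- min(d)
  if (best > rejection_radius) return("NANT")
  cand <- table$label[abs(d - best) < 1e-9]
  cand[order(match(cand, ntc_classes()))][1L]
}

#' Select the reference dinucleotide of a conformer/sequence group
#'
#' Returns the step with the lowest Cartesian r.m.s.d. (after least-squares
#' superposition over the shared named heavy atoms) with respect to the class
#' representative coordinates. Ties within 1e-4 A are broken by input order.
#' When no representative is available the medoid of the group (minimum
#' summed pairwise r.m.s.d.) is used instead.
#'
#' @param steps nonempty list of `dnahydro_step` sharing conformer/sequence.
#' @param representative optional labeled coordinates: data.frame with
#'   `label`, `x`, `y`, `z` (labels as in [step_atoms()]).
#' @return the selected `dnahydro_step`.
#' @export
select_reference <- function(steps, representative = NULL) {
  if (length(steps) == 0L) stop("empty step collection")
  if (length(steps) == 1L) return(steps[[1L]])
  combos <- unique(vapply(steps, function(s) paste(s$ntc, s$seq2), character(1L)))
  if (length(combos) > 1L) stop("steps mix conformer/sequence combinations")
  if (!is.null(representative)) {
    rms <- vapply(steps, function(s) {
      a <- step_atoms(s)
      shared <- intersect(a$label, representative$label)
      if (length(shared) < 3L) return(Inf)
      superposed_rmsd(
        as.matrix(a[match(shared, a$label), c("x", "y", "z")]),
        as.matrix(representative[match(shared, representative$label),
                                 c("x", "y", "z")]))
    }, numeric(1L))
  } else {
    n <- length(steps)
    tabs <- lapply(steps, step_atoms)
    pm <- matrix(0, n, n)
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      shared <- intersect(tabs[[i]]$label, tabs[[j]]$label)
      r <- if (length(shared) < 3L) Inf else superposed_rmsd(
        as.matrix(tabs[[i]][match(shared, tabs[[i]]$label), c("x", "y", "z")]),
        as.matrix(tabs[[j]][match(shared, tabs[[j]]$label), c("x", "y", "z")]))
      pm[i, j] <- pm[j, i] <- r
    }
    rms <- rowSums(pm)
  }
  best <- min(rms)
  steps[[which(rms <= best + 1e-4)[1L]]]
}
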