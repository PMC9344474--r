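# Hydrated building blocks: water association with dinucleotide steps,
# six-nearest-atom rigid transfer onto the reference dinucleotide, and
# assembly of the per-conformer/sequence block library.

#' Association and occupancy parameters
#'
#' @param d_assoc water-to-dinucleotide association cutoff, Angstrom.
#' @param d_calc base/backbone category cutoff used for the density split,
#'   Angstrom.
#' @param r_occ occupancy radius around a hydration site, Angstrom
#'   (boundary inclusive).
#' @param min_waters_reliable minimum associated waters for a block to be
#'   flagged reliable (boundary inclusive).
#' @param transfer_max_rmsd acceptance threshold on the six-atom transfer
#'   superposition r.m.s.d.; waters with a worse local fit are dropped.
#' @return list of class `dnahydro_assoc_params`.
#' @export
assoc_params <- function(d_assoc = 4.0, d_calc = 3.4, r_occ = 1.0,
                         min_waters_reliable = 800L, transfer_max_rmsd = 0.75) {
  stopifnot(d_calc > 0, d_calc <= d_assoc, r_occ > 0, transfer_max_rmsd > 0)
  structure(list(d_assoc = d_assoc, d_calc = d_calc, r_occ = r_occ,
                 min_waters_reliable = as.integer(min_waters_reliable),
                 transfer_max_rmsd = transfer_max_rmsd),
            class = "dnahydro_assoc_params")
}

#' Associate waters with a dinucleotide step
#'
#' A water is associated when its O atom lies closer than `d_assoc` to any
#' heavy atom of the step. Category flags are set independently at `d_calc`
#' against the base atoms and against the sugar-phosphate atoms of the two
#' residues: a water may be base-flagged, backbone-flagged, both, or neither
#' (associated at 4.0 A but outside 3.4 A of either category). A water may
#' associate with several overlapping steps; each association is independent.
#'
#' @param step a `dnahydro_step`.
#' @param waters data.frame with `x`, `y`, `z` and optionally `water_id`,
#'   `occupancy` (e.g. from [extract_waters()]).
#' @param params a `dnahydro_assoc_params`.
#' @return data.frame of associated waters: `x`, `y`, `z`, `water_id`,
#'   `near_base`, `near_backbone`, `nearest_distance`, `weight` (initial 1),
#'   `transfer_rmsd` (`NA` until transfer).
#' @export
associate_waters <- function(step, waters, params = assoc_params()) {
  at <- step_atoms(step)
  wxyz <- as.matrix(waters[, c("x", "y", "z")])
  axyz <- as.matrix(at[, c("x", "y", "z")])
  d_all <- min_dist_to_set(wxyz, axyz)
  keep <- d_all < params$d_assoc
  base_xyz <- axyz[at$is_base, , drop = FALSE]
  bb_xyz <- axyz[!at$is_base, , drop = FALSE]
  d_base <- min_dist_to_set(wxyz, base_xyz)
  d_bb <- min_dist_to_set(wxyz, bb_xyz)
  out <- data.frame(
    x = waters$x[keep], y = waters$y[keep], z = waters$z[keep],
    water_id = if ("water_id" %in% names(waters)) waters$water_id[keep]
               else as.character(which(keep)),
    near_base = d_base[keep] < params$d_calc,
    near_backbone = d_bb[keep] < params$d_calc,
    nearest_distance = d_all[keep],
    weight = rep(1, sum(keep)),
    transfer_rmsd = rep(NA_real_, sum(keep)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# Six source-step heavy atoms nearest to the water that have same-named
# counterparts in the reference; stable tie-break by (distance, residue
# position, atom name).
#' @noRd
six_nearest_shared <- function(water_xyz, source_tab, ref_labels) {
  shared <- source_tab[source_tab$label %in% ref_labels, , drop = FALSE]
  if (nrow(shared) < 6L) return(NULL)
  d <- sqrt((shared$x - water_xyz[1L])^2 + (shared$y - water_xyz[2L])^2 +
              (shared$z - water_xyz[3L])^2)
  ord <- order(d, shared$res_index, shared$atom_name)
  shared[ord[1:6], , drop = FALSE]
}

#' Transfer a water into the reference-dinucleotide frame
#'
#' Selects the six heavy atoms of the source step closest to the water that
#' have same-named counterparts in the reference, superposes them onto the
#' reference counterparts and applies the resulting rigid transform to the
#' water position. The six-atom r.m.s.d. is recorded as transfer quality.
#'
#' @param water_xyz numeric 3-vector, source frame.
#' @param source_step the `dnahydro_step` the water is associated with.
#' @param reference reference coordinates: a `dnahydro_step` or a labeled
#'   data.frame (`label`, `x`, `y`, `z`).
#' @return list with `position` (3-vector in the reference frame) and `rmsd`,
#'   or `NULL` when fewer than six atoms can be matched.
#' @export
transfer_water <- function(water_xyz, source_step, reference) {
  src <- step_atoms(source_step)
  ref <- if (inherits(reference, "dnahydro_step")) step_atoms(reference)
         else reference
  sel <- six_nearest_shared(as.numeric(water_xyz), src, ref$label)
  if (is.null(sel)) return(NULL)
  fit <- kabsch_superpose(
    as.matrix(sel[, c("x", "y", "z")]),
    as.matrix(ref[match(sel$label, ref$label), c("x", "y", "z")]))
  list(position = as.vector(apply_superposition(rbind(as.numeric(water_xyz)), fit)),
       rmsd = fit$rmsd)
}

#' Assemble a hydrated building block
#'
#' Transfers every associated water of every contributing step onto the
#' reference dinucleotide. Waters whose six-atom transfer r.m.s.d. exceeds
#' the acceptance threshold, or that cannot be matched to six reference
#' atoms, are dropped with a log entry. The block is flagged reliable when it
#' carries at least `min_waters_reliable` waters.
#'
#' @param ntc,seq2 the conformer/sequence combination.
#' @param hydrated_steps list of `list(step = <dnahydro_step>, waters =
#'   <associated-water data.frame>)`; all steps must share the combination.
#' @param reference optional reference `dnahydro_step`; defaults to the
#'   medoid of the contributing steps via [select_reference()].
#' @param params a `dnahydro_assoc_params`.
#' @return object of class `dnahydro_block`: list with `ntc`, `seq2`,
#'   `reference` (labeled coordinate data.frame), `waters` (reference-frame
#'   associated waters), `n_steps`, `n_waters`, `reliable`, `dropped`
#'   (count), `n_associated` (before transfer gating).
#' @export
build_block <- function(ntc, seq2, hydrated_steps, reference = NULL,
                        params = assoc_params()) {
  for (hs in hydrated_steps) {
    s <- hs$step
    if (!identical(s$seq2, seq2) ||
        (!is.na(s$ntc) && !identical(s$ntc, ntc))) {
      stop("mixed conformer/sequence combinations in block input")
    }
  }
  if (is.null(reference) && length(hydrated_steps) > 0L) {
    reference <- select_reference(lapply(hydrated_steps, `[[`, "step"))
  }
  ref_tab <- if (inherits(reference, "dnahydro_step")) step_atoms(reference)
             else reference
  waters <- list()
  dropped <- 0L
  n_associated <- 0L
  for (hs in hydrated_steps) {
    aw <- hs$waters
    n_associated <- n_associated + nrow(aw)
    if (nrow(aw) == 0L) next
    for (i in seq_len(nrow(aw))) {
      tr <- transfer_water(c(aw$x[i], aw$y[i], aw$z[i]), hs$step, ref_tab)
      if (is.null(tr) || tr$rmsd > params$transfer_max_rmsd) {
        dropped <- dropped + 1L
        next
      }
      row <- aw[i, , drop = FALSE]
      row$x <- tr$position[1L]; row$y <- tr$position[2L]; row$z <- tr$position[3L]
      row$transfer_rmsd <- tr$rmsd
      waters[[length(waters) + 1L]] <- row
    }
  }
  waters <- if (length(waters) == 0L) {
    data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
               water_id = character(0), near_base = logical(0),
               near_backbone = logical(0), nearest_distance = numeric(0),
               weight = numeric(0), transfer_rmsd = numeric(0))
  } else do.call(rbind, waters)
  rownames(waters) <- NULL
  structure(list(ntc = ntc, seq2 = seq2, reference = ref_tab,
                 waters = waters, n_steps = length(hydrated_steps),
                 n_waters = nrow(waters),
                 reliable = nrow(waters) >= params$min_waters_reliable,
                 dropped = dropped, n_associated = n_associated),
            class = "dnahydro_block")
}

#' @export
print.dnahydro_block <- function(x, ...) {
  cat("dnahydro hydrated block ", x$ntc, "/", x$seq2, ": ", x$n_waters,
      " waters from ", x$n_steps, " steps (",
      if (x$reliable) "reliable" else "unreliable", ")\n", sep = "")
  invisible(x)
}

#' Build a block library from classified hydrated steps
#'
#' Groups steps by (conformer, sequence) and builds one block per
#' combination. Steps labeled NANT are excluded.
#'
#' @param hydrated_steps list of `list(step, waters)` with `step$ntc` set.
#' @param references optional named list (`"NTC/SEQ2"`) of reference steps or
#'   labeled coordinate tables.
#' @param params a `dnahydro_assoc_params`.
#' @return object of class `dnahydro_library`: list with `blocks` (named
#'   list, keys `"NTC/SEQ2"`) and `params`.
#' @export
build_block_library <- function(hydrated_steps, references = NULL,
                                params = assoc_params()) {
  labs <- vapply(hydrated_steps, function(h) h$step$ntc %||% "NANT", character(1L))
  seqs <- vapply(hydrated_steps, function(h) h$step$seq2, character(1L))
  keep <- !is.na(labs) & labs != "NANT"
  if (!any(keep)) {
    return(structure(list(blocks = list(), params = params),
                     class = "dnahydro_library"))
  }
  keys <- paste0(labs[keep], "/", seqs[keep])
  groups <- split(hydrated_steps[keep], keys)
  blocks <- lapply(names(groups), function(k) {
    parts <- strsplit(k, "/", fixed = TRUE)[[1L]]
    build_block(parts[1L], parts[2L], groups[[k]],
                reference = references[[k]], params = params)
  })
  names(blocks) <- names(groups)
  structure(list(blocks = blocks, params = params),
            class = "dnahydro_library")
}

#' @export
print.dnahydro_library <- function(x, ...) {
  cat("dnahydro block library: ", length(x$blocks), " combination(s)\n", sep = "")
  for (k in names(x$blocks)) {
    b <- x$blocks[[k]]
    cat("  ", k, ": ", b$n_waters, " waters / ", b$n_steps, " steps",
        if (b$reliable) " [reliable]" else "", "\n", sep = "")
  }
  invisible(x)
}

#' Summary table of a block library
#'
#' One row per conformer/sequence combination with the step count, water
#' count, waters-per-step ratio and reliability flag.
#'
#' @param library a `dnahydro_library`.
#' @return data.frame.
#' @export
library_summary <- function(library) {
  do.call(rbind, lapply(names(library$blocks), function(k) {
    b <- library$blocks[[k]]
    data.frame(ntc = b$ntc, seq2 = b$seq2, n_steps = b$n_steps,
               n_waters = b$n_waters,
               waters_per_step = ifelse(b$n_steps > 0, b$n_waters / b$n_steps, 0),
               reliable = b$reliable, stringsAsFactors = FALSE)
  }))
}

#' Persist / load a block library
#'
#' The on-disk layout is a directory with a JSON manifest (parameters,
#' counts, reliability) plus, per combination, a PDB file with the reference
#' coordinates (as pseudo-atoms labeled by step atom) and a TSV water table.
#'
#' @param library a `dnahydro_library`.
#' @param dir directory to create/overwrite.
#' @return invisibly, `dir`.
#' @export
save_block_library <- function(library, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    format = "dnahydro-block-library/1",
    params = unclass(library$params),
    combinations = lapply(names(library$blocks), function(k) {
      b <- library$blocks[[k]]
      list(key = k, ntc = b$ntc, seq2 = b$seq2, n_steps = b$n_steps,
           n_waters = b$n_waters, reliable = b$reliable,
           reference_file = paste0(gsub("/", "_", k), "_ref.tsv"),
           waters_file = paste0(gsub("/", "_", k), "_waters.tsv"))
    }))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (co in manifest$combinations) {
    b <- library$blocks[[co$key]]
    utils::write.table(b$reference, file.path(dir, co$reference_file),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(b$waters, file.path(dir, co$waters_file),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}

#' @rdname save_block_library
#' @export
load_block_library <- function(dir) {
  mf_path <- file.path(dir, "manifest.json")
  if (!file.exists(mf_path)) stop("not a block library: missing manifest.json")
  mf <- jsonlite::read_json(mf_path, simplifyVector = FALSE)
  if (!identical(mf$format, "dnahydro-block-library/1")) {
    stop("malformed library manifest (unknown format field)")
  }
  p <- mf$params
  params <- assoc_params(p$d_assoc, p$d_calc, p$r_occ, p$min_waters_reliable,
                         p$transfer_max_rmsd)
  blocks <- list()
  for (co in mf$combinations) {
    ref <- utils::read.delim(file.path(dir, co$reference_file),
                             stringsAsFactors = FALSE)
    waters <- utils::read.delim(file.path(dir, co$waters_file),
                                stringsAsFactors = FALSE,
                                colClasses = c(water_id = "character"))
    blocks[[co$key]] <- structure(
      list(ntc = co$ntc, seq2 = co$seq2, reference = ref, waters = waters,
           n_steps = co$n_steps, n_waters = co$n_waters,
           reliable = co$reliable, dropped = NA_integer_,
           n_associated = NA_integer_),
      class = "dnahydro_block")
  }
  structure(list(blocks = blocks, params = params),
            class = "dnahydro_library")
}
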