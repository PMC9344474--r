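# Synthetic fixtures: idealized dinucleotides built from embedded internal
# geometry tables, planted hydration sites, and rigid-body-scattered corpora
# with ground truth. Everything is generated in code; fixtures test the
# machinery, not hydration biology.

# Canonical torsion sets (degrees) and frozen branch placements for the two
# helical forms. The branch offsets were tuned once so the deoxyribose ring
# closes (C1'-O4' = 1.42 A) with a C2'-endo-like pucker for B and a
# C3'-endo-like pucker for A; t_n places the glycosidic nitrogen at ~110
# degrees from O4' on the face away from the phosphate.
TEMPLATE_GEOM <- list(
  B = list(tor = c(al = 299, be = 176, ga = 48, de = 128, ep = 184, ze = 265),
           offs = c(o4 = -120.486, c2 = 128.818, nu2 = 326.597),
           t_n = 277.75, chi = 241),
  A = list(tor = c(al = 295, be = 173, ga = 54, de = 80, ep = 212, ze = 289),
           offs = c(o4 = -120.103, c2 = 131.541, nu2 = 33.403),
           t_n = 208.5, chi = 199))

# Planar idealized base templates in a local frame: pyrimidine ring as a
# regular hexagon of side 1.38 A, purine with a fused regular pentagon;
# exocyclic substituents point away from the ring centroid. Good bond
# lengths and exact planarity; not crystallographic geometry.
#' @noRd
base_template <- function(one_letter) {
  hex_names <- c("N1", "C2", "N3", "C4", "C5", "C6")
  ang <- (c(240, 300, 0, 60, 120, 180)) * pi / 180
  hex <- cbind(1.38 * cos(ang), 1.38 * sin(ang), 0)
  rownames(hex) <- hex_names
  add_exo <- function(m, name, anchor, bond, center = c(0, 0)) {
    a <- m[anchor, ]
    dirv <- unitv(a[1:2] - center)
    m <- rbind(m, c(a[1:2] + bond * dirv, 0))
    rownames(m)[nrow(m)] <- name
    m
  }
  if (one_letter %in% c("C", "T")) {
    m <- hex
    m <- add_exo(m, "O2", "C2", 1.23)
    if (one_letter == "C") {
      m <- add_exo(m, "N4", "C4", 1.34)
    } else {
      m <- add_exo(m, "O4", "C4", 1.23)
      m <- add_exo(m, "C7", "C5", 1.50)
    }
    attach <- c("N1", "C2", "C6")
  } else {
    # purine: pentagon fused on the C4-C5 edge
    mid <- (hex["C4", 1:2] + hex["C5", 1:2]) / 2
    outward <- unitv(mid)
    r5 <- 1.38 / (2 * sin(pi / 5))
    a5 <- r5 * cos(pi / 5)
    pc <- mid + a5 * outward
    rot2 <- function(p, th) {
      c(cos(th) * p[1L] - sin(th) * p[2L], sin(th) * p[1L] + cos(th) * p[2L])
    }
    # direction of 72-degree steps chosen so four steps map C4 onto C5
    v4 <- hex["C4", 1:2] - pc
    v5 <- hex["C5", 1:2] - pc
    th <- 2 * pi / 5
    s <- if (vnorm(rot2(v4, 4 * th) - v5) < vnorm(rot2(v4, -4 * th) - v5)) 1 else -1
    penta <- list(N9 = rot2(v4, s * th), C8 = rot2(v4, s * 2 * th),
                  N7 = rot2(v4, s * 3 * th))
    m <- hex
    for (nm in names(penta)) {
      m <- rbind(m, c(pc + penta[[nm]], 0))
      rownames(m)[nrow(m)] <- nm
    }
    if (one_letter == "A") {
      m <- add_exo(m, "N6", "C6", 1.34)
    } else {
      m <- add_exo(m, "O6", "C6", 1.23)
      m <- add_exo(m, "N2", "C2", 1.34)
    }
    attach <- c("N9", "C4", "C8")
  }
  list(coords = m, attach = attach)
}

# Build n_res linked nucleotides with the given sequence by NeRF chain
# construction; deterministic, no randomness. Returns a list of residue
# records compatible with residues_from_model().
#' @noRd
build_ideal_residues <- function(seq, form = c("B", "A"), chain_id = "A") {
  form <- match.arg(form)
  g <- TEMPLATE_GEOM[[form]]
  tor <- g$tor
  letters1 <- strsplit(seq, "")[[1L]]
  if (!all(letters1 %in% c("A", "C", "G", "T"))) {
    stop("sequence must be over {A,C,G,T}: ", seq)
  }
  res <- vector("list", length(letters1))
  prev <- NULL
  for (i in seq_along(letters1)) {
    if (is.null(prev)) {
      p <- c(0, 0, 0)
      o5 <- c(1.59, 0, 0)
      c5 <- o5 + 1.44 * c(0.5, sqrt(3) / 2, 0)
    } else {
      p <- place_atom(prev[["C4'"]], prev[["C3'"]], prev[["O3'"]], 1.60, 119, tor["ep"])
      o5 <- place_atom(prev[["C3'"]], prev[["O3'"]], p, 1.59, 104, tor["ze"])
      c5 <- place_atom(prev[["O3'"]], p, o5, 1.44, 120, tor["al"])
    }
    c4 <- place_atom(p, o5, c5, 1.51, 111, tor["be"])
    c3 <- place_atom(o5, c5, c4, 1.52, 115, tor["ga"])
    o3 <- place_atom(c5, c4, c3, 1.42, 110, tor["de"])
    o4 <- place_atom(o5, c5, c4, 1.45, 109, tor["ga"] + g$offs["o4"])
    c2 <- place_atom(c5, c4, c3, 1.53, 102.5, tor["de"] + g$offs["c2"])
    c1 <- place_atom(c4, c3, c2, 1.52, 102, g$offs["nu2"])
    op1 <- place_atom(c5, o5, p, 1.48, 108, tor["al"] + 120)
    op2 <- place_atom(c5, o5, p, 1.48, 108, tor["al"] - 120)
    nn <- place_atom(c3, c2, c1, 1.47, 114, g$t_n)

    bt <- base_template(letters1[i])
    nb <- bt$attach
    ring_at_n <- {
      v1 <- bt$coords[nb[2L], ] - bt$coords[nb[1L], ]
      v2 <- bt$coords[nb[3L], ] - bt$coords[nb[1L], ]
      acos(sum(unitv(v1) * unitv(v2))) * 180 / pi
    }
    half <- (360 - ring_at_n) / 2
    d1 <- vnorm(bt$coords[nb[2L], ] - bt$coords[nb[1L], ])
    d2 <- vnorm(bt$coords[nb[3L], ] - bt$coords[nb[1L], ])
    nb1 <- place_atom(o4, c1, nn, d1, half, g$chi)
    nb2 <- place_atom(o4, c1, nn, d2, half, g$chi + 180)
    fit <- kabsch_superpose(bt$coords[nb, , drop = FALSE], rbind(nn, nb1, nb2))
    base_xyz <- apply_superposition(bt$coords, fit)
    rownames(base_xyz) <- rownames(bt$coords)

    bb <- rbind(P = p, OP1 = op1, OP2 = op2, `O5'` = o5, `C5'` = c5,
                `C4'` = c4, `O4'` = o4, `C3'` = c3, `O3'` = o3,
                `C2'` = c2, `C1'` = c1)
    base_order <- setdiff(rownames(base_xyz), nb[1L])
    all_xyz <- rbind(bb, base_xyz[c(nb[1L], base_order), , drop = FALSE])
    atom_name <- rownames(all_xyz)
    resname <- paste0("D", letters1[i])
    atoms <- new_atom_table(
      atom_name = atom_name, element = guess_element(atom_name),
      residue_name = rep(resname, nrow(all_xyz)),
      chain_id = rep(chain_id, nrow(all_xyz)),
      residue_number = rep(i, nrow(all_xyz)), ins = rep("", nrow(all_xyz)),
      x = all_xyz[, 1L], y = all_xyz[, 2L], z = all_xyz[, 3L],
      occupancy = rep(1, nrow(all_xyz)), b_factor = rep(0, nrow(all_xyz)),
      altloc = rep("", nrow(all_xyz)))
    res[[i]] <- list(residue_name = resname, one_letter = letters1[i],
                     residue_number = i, ins = "", atoms = atoms)
    prev <- list(`C4'` = c4, `C3'` = c3, `O3'` = o3)
  }
  res
}

#' Idealized dinucleotide step
#'
#' Builds a chemically sensible two-nucleotide fragment with standard atom
#' names, a correct base/backbone partition and an O3'-P linkage of 1.60 A,
#' from embedded idealized geometry for the B or A helical form. The output
#' is deterministic: identical arguments give identical coordinates.
#'
#' @param seq2 two-letter sequence over A, C, G, T.
#' @param form helical form of the template geometry, `"B"` or `"A"`.
#' @return a `dnahydro_step`.
#' @export
make_ideal_step <- function(seq2, form = c("B", "A")) {
  form <- match.arg(form)
  if (nchar(seq2) != 2L) stop("seq2 must have exactly two letters")
  res <- build_ideal_residues(seq2, form)
  new_step(res[[1L]], res[[2L]],
           source = list(structure_id = paste0("ideal-", form),
                         chain_id = "A", residue_number = 1L))
}

#' Idealized DNA chain as a structure model
#'
#' @param seq sequence over A, C, G, T (any length >= 1).
#' @param form helical form, `"B"` or `"A"`.
#' @param structure_id id recorded on the model.
#' @return a `dnahydro_model` (no waters, no cell).
#' @export
make_ideal_model <- function(seq, form = c("B", "A"), structure_id = "ideal") {
  res <- build_ideal_residues(seq, match.arg(form))
  atoms <- do.call(rbind, lapply(res, `[[`, "atoms"))
  rownames(atoms) <- NULL
  structure(list(structure_id = structure_id, resolution = NA_real_,
                 model_number = 1L, atoms = atoms, cell = NULL,
                 spacegroup = NULL, symops = NULL),
            class = "dnahydro_model")
}

#' Default planted hydration sites for a step
#'
#' Four sites anchored to polar atoms of the step, 2.8 A from the anchor in
#' the direction away from the step centroid: two base sites (major-groove
#' nitrogen/oxygen of each residue) and two backbone sites (a charged
#' phosphate O and the O5' of the second residue). Occupancies follow the
#' planted-site recovery study conditions: 0.9, 0.6, 0.4, 0.2 with 0.25 A
#' positional jitter.
#'
#' @param step a `dnahydro_step`.
#' @param occupancies length-4 occupancy vector for the four sites.
#' @param jitter isotropic positional jitter sigma, Angstrom.
#' @return data.frame with `x`, `y`, `z` (site position in the step frame),
#'   `occupancy`, `jitter`, `category`, `anchor`.
#' @export
default_planted_sites <- function(step, occupancies = c(0.9, 0.6, 0.4, 0.2),
                                  jitter = 0.25) {
  stopifnot(length(occupancies) == 4L)
  at <- step_atoms(step)
  centroid <- colMeans(at[, c("x", "y", "z")])
  base_anchor <- function(res_idx) {
    cand <- at[at$res_index == res_idx & at$is_base &
                 grepl("^[NO]", at$atom_name), , drop = FALSE]
    # prefer major-groove-facing atoms: last named ring substituents
    cand[which.max(sqrt((cand$x - centroid[1L])^2 + (cand$y - centroid[2L])^2 +
                          (cand$z - centroid[3L])^2)), , drop = FALSE]
  }
  bb_anchor <- function(res_idx, name) {
    at[at$res_index == res_idx & at$atom_name == name, , drop = FALSE]
  }
  anchors <- rbind(base_anchor(1L), base_anchor(2L),
                   bb_anchor(2L, "OP2"), bb_anchor(1L, "OP1"))
  category <- c("base", "base", "backbone", "backbone")
  pos <- t(vapply(seq_len(4L), function(i) {
    a <- as.numeric(anchors[i, c("x", "y", "z")])
    a + 2.8 * unitv(a - centroid)
  }, numeric(3L)))
  data.frame(x = pos[, 1L], y = pos[, 2L], z = pos[, 3L],
             occupancy = occupancies, jitter = jitter, category = category,
             anchor = anchors$label, stringsAsFactors = FALSE)
}

#' Sample waters at planted hydration sites
#'
#' For each site, a water is drawn with probability equal to the site
#' occupancy, at the site position plus isotropic Gaussian jitter.
#' Reproducible under the seed.
#'
#' @param step a `dnahydro_step` (waters are positioned in its frame).
#' @param sites data.frame as from [default_planted_sites()].
#' @param seed integer RNG seed.
#' @return data.frame with `x`, `y`, `z`, `water_id`, `site_index`.
#' @export
plant_waters <- function(step, sites, seed = 1L) {
  set.seed(seed)
  draw_planted_waters(sites)
}

#' @noRd
draw_planted_waters <- function(sites) {
  rows <- list()
  for (i in seq_len(nrow(sites))) {
    if (stats::runif(1L) <= sites$occupancy[i]) {
      jit <- stats::rnorm(3L, 0, sites$jitter[i])
      rows[[length(rows) + 1L]] <- data.frame(
        x = sites$x[i] + jit[1L], y = sites$y[i] + jit[2L],
        z = sites$z[i] + jit[3L],
        water_id = paste0("W", i), site_index = i,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      water_id = character(0), site_index = integer(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Synthetic-corpus specification
#'
#' @param n_structures number of corpus structures.
#' @param seq2 two-letter step sequence.
#' @param form template helical form.
#' @param ntc conformer label recorded in the ground-truth assignment table.
#' @param planted_sites site table, default [default_planted_sites()] of the
#'   ideal step.
#' @param max_rotation,max_translation rigid scatter ranges (degrees about a
#'   random axis; Angstrom along a random direction).
#' @param coordinate_noise isotropic sigma added to dinucleotide atoms, A.
#' @param with_cell emit a P1 crystal context (cell chosen to place one
#'   translated neighbor near the fragment) to exercise symmetry expansion.
#' @param seed integer seed; a fixed seed gives byte-identical output.
#' @return list of class `dnahydro_synth_spec`.
#' @export
synthetic_spec <- function(n_structures = 40L, seq2 = "CG", form = "B",
                           ntc = "BB00", planted_sites = NULL,
                           max_rotation = 180, max_translation = 20,
                           coordinate_noise = 0, with_cell = FALSE,
                           seed = 1L) {
  step <- make_ideal_step(seq2, form)
  sites <- planted_sites %||% default_planted_sites(step)
  stopifnot(all(sites$occupancy >= 0), all(sites$occupancy <= 1))
  structure(list(n_structures = as.integer(n_structures), seq2 = seq2,
                 form = form, ntc = ntc, planted_sites = sites,
                 max_rotation = max_rotation,
                 max_translation = max_translation,
                 coordinate_noise = coordinate_noise,
                 with_cell = with_cell, seed = as.integer(seed)),
            class = "dnahydro_synth_spec")
}

#' @noRd
random_corpus_transform <- function(max_rotation, max_translation) {
  axis <- unitv(stats::rnorm(3L))
  ang <- stats::runif(1L, -1, 1) * max_rotation * pi / 180
  k <- matrix(c(0, -axis[3L], axis[2L], axis[3L], 0, -axis[1L],
                -axis[2L], axis[1L], 0), 3L, 3L, byrow = TRUE)
  rot <- diag(3) + sin(ang) * k + (1 - cos(ang)) * (k %*% k)
  trans <- stats::runif(3L, -1, 1) * max_translation
  list(rot = rot, trans = trans)
}

#' Generate a synthetic hydrated-dinucleotide corpus
#'
#' Produces `n_structures` single-step structure models, each a random rigid
#' transform of the ideal template step (optionally with atom-coordinate
#' noise), together with waters sampled from the planted hydration sites and
#' transformed identically. Also returns the ground truth (per-structure
#' true site positions and occupancies) and a conformer assignment table for
#' lookup classification, and optionally writes the models as PDB files.
#'
#' @param spec a `dnahydro_synth_spec`.
#' @param dir optional directory; when given, each model is written as
#'   `<id>.pdb` and the ground truth as `ground_truth.tsv`.
#' @return list with `models` (list of `dnahydro_model`), `ground_truth`
#'   (data.frame: structure_id, site_index, x, y, z, occupancy, category),
#'   `assignments` (a `dnahydro_classifier` assignment table), `spec`.
#' @export
make_corpus <- function(spec, dir = NULL) {
  set.seed(spec$seed)
  template <- make_ideal_step(spec$seq2, spec$form)
  tat <- step_atoms(template)
  models <- vector("list", spec$n_structures)
  gt <- list()
  for (s in seq_len(spec$n_structures)) {
    id <- sprintf("synth%03d", s)
    tf <- random_corpus_transform(spec$max_rotation, spec$max_translation)
    res <- lapply(list(template$first, template$second), function(r) {
      a <- r$atoms
      xyz <- apply_rigid(as.matrix(a[, c("x", "y", "z")]), tf$rot, tf$trans)
      if (spec$coordinate_noise > 0) {
        xyz <- xyz + matrix(stats::rnorm(length(xyz), 0, spec$coordinate_noise),
                            ncol = 3L)
      }
      a$x <- xyz[, 1L]; a$y <- xyz[, 2L]; a$z <- xyz[, 3L]
      r$atoms <- a
      r
    })
    w <- draw_planted_waters(spec$planted_sites)
    if (nrow(w) > 0L) {
      wxyz <- apply_rigid(as.matrix(w[, c("x", "y", "z")]), tf$rot, tf$trans)
      w$x <- wxyz[, 1L]; w$y <- wxyz[, 2L]; w$z <- wxyz[, 3L]
    }
    true_xyz <- apply_rigid(as.matrix(spec$planted_sites[, c("x", "y", "z")]),
                            tf$rot, tf$trans)
    gt[[s]] <- data.frame(structure_id = id,
                          site_index = seq_len(nrow(spec$planted_sites)),
                          x = true_xyz[, 1L], y = true_xyz[, 2L],
                          z = true_xyz[, 3L],
                          occupancy = spec$planted_sites$occupancy,
                          category = spec$planted_sites$category,
                          stringsAsFactors = FALSE)
    water_atoms <- if (nrow(w) > 0L) {
      new_atom_table(atom_name = rep("O", nrow(w)),
                     element = rep("O", nrow(w)),
                     residue_name = rep("HOH", nrow(w)),
                     chain_id = rep("W", nrow(w)),
                     residue_number = seq_len(nrow(w)),
                     ins = rep("", nrow(w)),
                     x = w$x, y = w$y, z = w$z,
                     occupancy = rep(1, nrow(w)), b_factor = rep(0, nrow(w)),
                     altloc = rep("", nrow(w)))
    } else NULL
    atoms <- rbind(res[[1L]]$atoms, res[[2L]]$atoms, water_atoms)
    rownames(atoms) <- NULL
    cell <- NULL; ops <- NULL; sg <- NULL
    if (spec$with_cell) {
      span <- apply(as.matrix(atoms[, c("x", "y", "z")]), 2L, range)
      cell <- c(span[2L, ] - span[1L, ] + 6, 90, 90, 90)
      sg <- "P 1"
      ops <- spacegroup_ops("P 1")
    }
    models[[s]] <- structure(
      list(structure_id = id, resolution = 1.0, model_number = 1L,
           atoms = atoms, cell = cell, spacegroup = sg, symops = ops),
      class = "dnahydro_model")
  }
  gt <- do.call(rbind, gt)
  assignments <- classifier_table(data.frame(
    structure_id = vapply(models, `[[`, character(1L), "structure_id"),
    chain_id = "A", residue_number = 1L, label = spec$ntc,
    stringsAsFactors = FALSE))
  files <- NULL
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    files <- vapply(models, function(m) {
      f <- file.path(dir, paste0(m$structure_id, ".pdb"))
      write_structure_pdb(m, f)
      f
    }, character(1L))
    utils::write.table(gt, file.path(dir, "ground_truth.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    write_classifier_table(assignments, file.path(dir, "assignments.tsv"))
  }
  list(models = models, ground_truth = gt, assignments = assignments,
       files = files, spec = spec)
}
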