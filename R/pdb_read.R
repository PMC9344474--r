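# PDB dialect reader: atom records via bio3d, crystal metadata from the
# header text (bio3d does not expose CRYST1 / REMARK 290 / REMARK 2).

#' @noRd
read_structure_pdb <- function(path, model_number = 1L) {
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE,
                                     rm.alt = FALSE)),
    error = function(e) stop("PDB parse error in ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  a <- pdb$atom
  nmodel <- nrow(pdb$xyz)
  if (model_number < 1L || model_number > nmodel) {
    stop("model ", model_number, " not present (file has ", nmodel, ")")
  }
  xyz <- matrix(pdb$xyz[model_number, ], ncol = 3L, byrow = TRUE)
  n <- nrow(a)
  if (nrow(xyz) < n) {
    stop("model ", model_number, " has fewer coordinates than atom records")
  }
  atoms <- new_atom_table(
    atom_name = a$elety, element = a$elesy, residue_name = a$resid,
    chain_id = ifelse(is.na(a$chain), "A", a$chain),
    residue_number = a$resno, ins = a$insert,
    x = xyz[seq_len(n), 1L], y = xyz[seq_len(n), 2L], z = xyz[seq_len(n), 3L],
    occupancy = a$o, b_factor = a$b, altloc = a$alt)

  hdr <- readLines(path, warn = FALSE)
  cr <- parse_pdb_cryst1(hdr)
  list(structure_id = NA_character_,
       resolution = parse_pdb_resolution(hdr),
       atoms = atoms,
       cell = cr$cell,
       spacegroup = cr$spacegroup,
       symops = parse_pdb_smtry(hdr, cr$cell, cr$spacegroup))
}

#' @noRd
parse_pdb_resolution <- function(lines) {
  ln <- grep("^REMARK   2 RESOLUTION\\.", lines, value = TRUE)
  if (length(ln) == 0L) return(NA_real_)
  m <- regmatches(ln[1L], regexpr("[0-9]+\\.[0-9]+", ln[1L]))
  if (length(m) == 0L) NA_real_ else as.numeric(m)
}

#' @noRd
parse_pdb_cryst1 <- function(lines) {
  ln <- grep("^CRYST1", lines, value = TRUE)
  if (length(ln) == 0L) return(list(cell = NULL, spacegroup = NULL))
  ln <- ln[1L]
  cell <- as.numeric(c(substr(ln, 7, 15), substr(ln, 16, 24), substr(ln, 25, 33),
                       substr(ln, 34, 40), substr(ln, 41, 47), substr(ln, 48, 54)))
  if (any(is.na(cell))) return(list(cell = NULL, spacegroup = NULL))
  sg <- trimws(substr(ln, 56, 66))
  list(cell = cell, spacegroup = if (nzchar(sg)) sg else "P 1")
}

# REMARK 290 SMTRY records express the operations on *Cartesian* coordinates;
# internally operations are stored in the fractional convention (integer
# rotation entries, translations in fractions of the cell), so the parsed
# matrices are converted through the orthogonalization matrix and snapped to
# the nearest exact crystallographic values.
#' @noRd
parse_pdb_smtry <- function(lines, cell = NULL, spacegroup = NULL) {
  ln <- grep("^REMARK 290   SMTRY", lines, value = TRUE)
  if (length(ln) == 0L) {
    if (is.null(spacegroup)) return(NULL)
    return(spacegroup_ops(spacegroup))
  }
  if (is.null(cell)) return(NULL)
  row <- as.integer(substr(ln, 19, 19))
  opno <- as.integer(substr(ln, 20, 23))
  nums <- t(vapply(ln, function(s) {
    as.numeric(strsplit(trimws(substring(s, 24)), "\\s+")[[1L]][1:4])
  }, numeric(4L), USE.NAMES = FALSE))
  m <- frac_to_cart_matrix(cell)
  minv <- solve(m)
  ops <- lapply(sort(unique(opno)), function(k) {
    sel <- which(opno == k)
    sel <- sel[order(row[sel])]
    if (length(sel) != 3L) stop("malformed REMARK 290 SMTRY block (op ", k, ")")
    rc <- rbind(nums[sel[1L], 1:3], nums[sel[2L], 1:3], nums[sel[3L], 1:3])
    tc <- nums[sel, 4L]
    rf <- minv %*% rc %*% m
    tf <- as.vector(minv %*% tc)
    list(rot = round(rf), trans = round(tf * 12) / 12)
  })
  ops
}

# Built-in operator lists for the toy spacegroups the synthetic corpus uses.
# Other groups must carry explicit REMARK 290 / mmCIF symmetry records.
#' @noRd
spacegroup_ops <- function(name) {
  key <- toupper(gsub("[ ()]", "", name))
  if (key == "P1") {
    return(list(list(rot = diag(3), trans = c(0, 0, 0))))
  }
  if (key %in% c("P21", "P1211", "P121")) {
    return(list(
      list(rot = diag(3), trans = c(0, 0, 0)),
      list(rot = diag(c(-1, 1, -1)), trans = c(0, 0.5, 0))))
  }
  NULL
}
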