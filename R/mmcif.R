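# Minimal mmCIF reader: atom_site loop, cell, symmetry operation strings.
# Covers the coordinate-file subset this package consumes; no R package for
# mmCIF is available, so the loop parser is implemented here.

#' @noRd
cif_tokenize <- function(line) {
  # mmCIF values are whitespace-separated, with '...' / "..." quoting
  out <- character(0)
  s <- line
  while (nzchar(s <- sub("^\\s+", "", s))) {
    ch <- substr(s, 1L, 1L)
    if (ch == "'" || ch == "\"") {
      m <- regexpr(paste0(ch, "[^", ch, "]*", ch), s)
      if (m == -1L) stop("unterminated quote in mmCIF line: ", line)
      tok <- substr(s, 2L, attr(m, "match.length") - 1L)
      s <- substring(s, attr(m, "match.length") + 1L)
    } else {
      m <- regexpr("^\\S+", s)
      tok <- substr(s, 1L, attr(m, "match.length"))
      s <- substring(s, attr(m, "match.length") + 1L)
    }
    out <- c(out, tok)
  }
  out
}

#' @noRd
read_structure_mmcif <- function(path, model_number = 1L) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines)]

  # ---- atom_site loop ----
  hdr_idx <- grep("^_atom_site\\.", lines)
  if (length(hdr_idx) == 0L) {
    stop("mmCIF parse error in ", path, ": no _atom_site loop found")
  }
  fields <- sub("^_atom_site\\.", "", trimws(lines[hdr_idx]))
  body_start <- max(hdr_idx) + 1L
  body <- character(0)
  for (i in body_start:length(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) next
    if (grepl("^(_|loop_|data_|stop_)", ln)) break
    body <- c(body, lines[i])
  }
  toks <- lapply(body, cif_tokenize)
  bad <- which(vapply(toks, length, 1L) != length(fields))
  if (length(bad) > 0L) {
    stop("mmCIF parse error in ", path, ": atom_site row ", bad[1L],
         " has ", length(toks[[bad[1L]]]), " values, expected ", length(fields))
  }
  tab <- as.data.frame(do.call(rbind, toks), stringsAsFactors = FALSE)
  names(tab) <- fields

  get <- function(nm, default = NA_character_) {
    if (nm %in% names(tab)) {
      v <- tab[[nm]]
      v[v %in% c(".", "?")] <- NA_character_
      v
    } else rep(default, nrow(tab))
  }
  model_num <- suppressWarnings(as.integer(get("pdbx_PDB_model_num", "1")))
  model_num[is.na(model_num)] <- 1L
  if (!model_number %in% model_num) {
    stop("model ", model_number, " not present in ", path)
  }
  sel <- model_num == model_number
  tab <- tab[sel, , drop = FALSE]
  get1 <- function(nm, default = NA_character_) get(nm, default)[sel]

  atoms <- new_atom_table(
    atom_name = get1("label_atom_id"),
    element = get1("type_symbol"),
    residue_name = get1("label_comp_id"),
    chain_id = {
      ch <- get1("auth_asym_id")
      ifelse(is.na(ch), get1("label_asym_id"), ch)
    },
    residue_number = {
      rn <- suppressWarnings(as.integer(get1("auth_seq_id")))
      alt <- suppressWarnings(as.integer(get1("label_seq_id")))
      ifelse(is.na(rn), ifelse(is.na(alt), 0L, alt), rn)
    },
    ins = get1("pdbx_PDB_ins_code"),
    x = as.numeric(get1("Cartn_x")),
    y = as.numeric(get1("Cartn_y")),
    z = as.numeric(get1("Cartn_z")),
    occupancy = suppressWarnings(as.numeric(get1("occupancy"))),
    b_factor = suppressWarnings(as.numeric(get1("B_iso_or_equiv"))),
    altloc = get1("label_alt_id"))

  # ---- cell and symmetry ----
  scalar <- function(tag) {
    ln <- grep(paste0("^", tag, "\\s"), lines, value = TRUE)
    if (length(ln) == 0L) return(NA_character_)
    tok <- cif_tokenize(ln[1L])
    if (length(tok) < 2L) NA_character_ else tok[2L]
  }
  cell <- suppressWarnings(as.numeric(c(
    scalar("_cell\\.length_a"), scalar("_cell\\.length_b"),
    scalar("_cell\\.length_c"), scalar("_cell\\.angle_alpha"),
    scalar("_cell\\.angle_beta"), scalar("_cell\\.angle_gamma"))))
  if (any(is.na(cell))) cell <- NULL

  res <- suppressWarnings(as.numeric(scalar("_refine\\.ls_d_res_high")))
  sgname <- scalar("_symmetry\\.space_group_name_H-M")

  ops <- cif_symops(lines)
  if (is.null(ops) && !is.na(sgname)) ops <- spacegroup_ops(sgname)

  list(structure_id = NA_character_, resolution = res, atoms = atoms,
       cell = cell, spacegroup = if (is.na(sgname)) NULL else sgname,
       symops = ops)
}

# Collect symmetry operator strings ("x,y,z", "-x,y+1/2,-z", ...) from either
# the single-value tags or a symop loop.
#' @noRd
cif_symops <- function(lines) {
  tags <- c("_symmetry_equiv\\.pos_as_xyz", "_symmetry_equiv_pos_as_xyz",
            "_space_group_symop\\.operation_xyz")
  strs <- character(0)
  for (tag in tags) {
    idx <- grep(paste0("^", tag, "(\\s|$)"), lines)
    if (length(idx) == 0L) next
    inline <- trimws(sub(paste0("^", tag), "", lines[idx]))
    if (all(nzchar(inline))) {
      strs <- vapply(inline, function(s) cif_tokenize(s)[1L], character(1L),
                     USE.NAMES = FALSE)
    } else {
      # loop form: operators follow the header (possibly with a leading id)
      after <- lines[(max(idx) + 1L):length(lines)]
      for (ln in after) {
        t <- trimws(ln)
        if (!nzchar(t)) next
        if (grepl("^(_|loop_|data_)", t)) break
        tok <- cif_tokenize(t)
        strs <- c(strs, tok[grepl(",", tok)][1L])
      }
    }
    if (length(strs) > 0L) break
  }
  if (length(strs) == 0L) return(NULL)
  lapply(strs, parse_symop_xyz)
}

#' Parse a crystallographic operator string
#'
#' Converts an operator like `"-x,y+1/2,-z"` into a fractional-coordinate
#' rotation matrix and translation vector.
#'
#' @param s operator string with comma-separated x, y, z expressions.
#' @return list with `rot` (3 x 3) and `trans` (length 3).
#' @export
parse_symop_xyz <- function(s) {
  parts <- strsplit(tolower(gsub("\\s", "", s)), ",")[[1L]]
  if (length(parts) != 3L) stop("malformed symmetry operator: ", s)
  rot <- matrix(0, 3L, 3L)
  trans <- numeric(3L)
  for (i in 1:3) {
    expr <- parts[i]
    # split into signed terms
    terms <- regmatches(expr, gregexpr("[+-]?[^+-]+", expr))[[1L]]
    for (tm in terms) {
      sign <- if (startsWith(tm, "-")) -1 else 1
      body <- sub("^[+-]", "", tm)
      if (body %in% c("x", "y", "z")) {
        rot[i, match(body, c("x", "y", "z"))] <- sign
      } else if (grepl("^[0-9]+/[0-9]+$", body)) {
        nn <- as.numeric(strsplit(body, "/")[[1L]])
        trans[i] <- trans[i] + sign * nn[1L] / nn[2L]
      } else if (grepl("^[0-9.]+$", body)) {
        trans[i] <- trans[i] + sign * as.numeric(body)
      } else {
        stop("cannot parse symmetry operator term '", tm, "' in: ", s)
      }
    }
  }
  list(rot = rot, trans = trans)
}
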