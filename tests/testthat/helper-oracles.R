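# Independent oracles and small fixtures used across the suite. Each oracle
# implements the checked quantity by a different route than the package code.

# Rigid superposition via Horn's closed-form quaternion method: build the
# 4x4 key matrix from the covariance and take the top eigenvector. Fully
# independent of the SVD route in kabsch_superpose().
horn_superpose <- function(moving, target) {
  n <- nrow(moving)
  cm <- colMeans(moving)
  ct <- colMeans(target)
  a <- sweep(moving, 2, cm)
  b <- sweep(target, 2, ct)
  s <- t(a) %*% b
  sxx <- s[1, 1]; sxy <- s[1, 2]; sxz <- s[1, 3]
  syx <- s[2, 1]; syy <- s[2, 2]; syz <- s[2, 3]
  szx <- s[3, 1]; szy <- s[3, 2]; szz <- s[3, 3]
  k <- matrix(c(
    sxx + syy + szz, syz - szy,       szx - sxz,       sxy - syx,
    syz - szy,       sxx - syy - szz, sxy + syx,       szx + sxz,
    szx - sxz,       sxy + syx,       syy - sxx - szz, syz + szy,
    sxy - syx,       szx + sxz,       syz + szy,       szz - sxx - syy),
    4, 4, byrow = TRUE)
  ev <- eigen(k, symmetric = TRUE)
  q <- ev$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  rot <- matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    3, 3, byrow = TRUE)
  trans <- ct - as.vector(rot %*% cm)
  moved <- sweep(moving %*% t(rot), 2, trans, "+")
  list(rotation = rot, translation = trans,
       rmsd = sqrt(mean(rowSums((moved - target)^2))))
}

random_rot <- function() {
  q <- qr(matrix(rnorm(9), 3, 3))
  r <- qr.Q(q)
  d <- diag(qr.R(q))
  r <- r %*% diag(sign(d + (d == 0)))
  if (det(r) < 0) r[, 1] <- -r[, 1]
  r
}

rigid <- function(xyz, rot, trans) sweep(as.matrix(xyz) %*% t(rot), 2, trans, "+")

# Brute-force symmetry expansion: every operation x every lattice translation
# in a fixed +-2 cell range, filtered by distance. No bounding-box logic.
brute_force_expansion <- function(model, radius, what = "waters") {
  m <- frac_to_cart_matrix(model$cell)
  minv <- solve(m)
  at <- model$atoms
  dna <- at[!at$is_water & !at$is_hydrogen &
              at$residue_name %in% names(nucleotide_mapping()), , drop = FALSE]
  dna_xyz <- as.matrix(dna[, c("x", "y", "z")])
  src <- if (what == "waters") at[at$is_water, , drop = FALSE] else at
  hits <- list()
  for (k in seq_along(model$symops)) {
    op <- model$symops[[k]]
    for (na in -2:2) for (nb in -2:2) for (nc in -2:2) {
      ident <- all(op$rot == diag(3)) && all(op$trans == 0)
      if (ident && na == 0 && nb == 0 && nc == 0) next
      for (i in seq_len(nrow(src))) {
        f <- as.vector(minv %*% c(src$x[i], src$y[i], src$z[i]))
        g <- as.vector(op$rot %*% f) + op$trans + c(na, nb, nc)
        cart <- as.vector(m %*% g)
        d <- sqrt(min(rowSums(sweep(dna_xyz, 2, cart)^2)))
        if (d <= radius) {
          hits[[length(hits) + 1]] <- c(op = k, na = na, nb = nb, nc = nc,
                                        i = i, x = cart[1], y = cart[2],
                                        z = cart[3])
        }
      }
    }
  }
  if (length(hits) == 0) {
    return(data.frame(op = integer(0), x = numeric(0), y = numeric(0),
                      z = numeric(0)))
  }
  as.data.frame(do.call(rbind, hits))
}

# Brute-force kernel-sum argmax on a fine candidate lattice around the
# waters; independent of the gridded accumulation + interpolation route.
brute_force_peak <- function(waters, sigma, center, half_width = 1.2,
                             lattice = 0.05) {
  ax <- lapply(1:3, function(k) {
    seq(center[k] - half_width, center[k] + half_width, by = lattice)
  })
  gridpts <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]]))
  w <- if ("weight" %in% names(waters)) waters$weight else rep(1, nrow(waters))
  dens <- numeric(nrow(gridpts))
  for (i in seq_len(nrow(waters))) {
    d2 <- (gridpts[, 1] - waters$x[i])^2 + (gridpts[, 2] - waters$y[i])^2 +
      (gridpts[, 3] - waters$z[i])^2
    dens <- dens + w[i] * exp(-d2 / (2 * sigma^2))
  }
  gridpts[which.max(dens), ]
}

# Brute-force transitive closure of the chain-similarity relation.
brute_force_clusters <- function(entries, params) {
  n <- nrow(entries)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    adj[i, j] <- i == j ||
      dnahydro:::sequences_similar(entries$sequence[i], entries$sequence[j],
                                   params)
  }
  reach <- adj
  for (k in seq_len(n)) {
    reach <- reach | (reach[, k, drop = FALSE] %*% reach[k, , drop = FALSE] > 0)
  }
  comp <- rep(NA_integer_, n)
  nxt <- 0L
  for (i in seq_len(n)) {
    if (is.na(comp[i])) {
      nxt <- nxt + 1L
      comp[which(reach[i, ])] <- nxt
    }
  }
  comp
}

# A minimal hand-written two-nucleotide PDB fixture (plus optional waters
# and an altloc pair) exercising fixed-width parsing.
write_mini_pdb <- function(path, waters = 0, altloc = FALSE) {
  fmt <- "%-6s%5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s"
  ln <- c(
    "REMARK   2 RESOLUTION.    1.50 ANGSTROMS.",
    sprintf(fmt, "ATOM", 1, " P", " ", "DG", "A", 1, 0, 0, 0, 1, 10, "P"),
    sprintf(fmt, "ATOM", 2, " O5'", " ", "DG", "A", 1, 1.59, 0, 0, 1, 10, "O"),
    sprintf(fmt, "ATOM", 3, " C1'", " ", "DG", "A", 1, 3.2, 1.1, 0.5, 1, 10, "C"),
    sprintf(fmt, "ATOM", 4, " N9", " ", "DG", "A", 1, 4.5, 1.4, 0.6, 1, 10, "N"),
    sprintf(fmt, "ATOM", 5, " P", " ", "DC", "A", 2, 2.2, 4.4, 1.0, 1, 10, "P"),
    sprintf(fmt, "ATOM", 6, " O5'", " ", "DC", "A", 2, 3.1, 5.2, 1.2, 1, 10, "O"))
  if (altloc) {
    ln <- c(ln,
      sprintf(fmt, "ATOM", 7, " C5'", "A", "DC", "A", 2, 4.0, 6.0, 1.5, 0.6, 10, "C"),
      sprintf(fmt, "ATOM", 8, " C5'", "B", "DC", "A", 2, 4.4, 6.4, 1.9, 0.4, 10, "C"))
  }
  if (waters > 0) {
    for (i in seq_len(waters)) {
      ln <- c(ln, sprintf(fmt, "HETATM", 100 + i, " O", " ", "HOH", "W",
                          i, 5 + i, 5, 5, 1, 20, "O"))
    }
  }
  writeLines(c(ln, "END"), path)
  path
}

# Small corpus + library shared by block/predict tests (cached per session).
tiny_corpus_cache <- new.env(parent = emptyenv())

tiny_library <- function(n_structures = 40, seed = 42,
                         min_reliable = 10) {
  key <- paste(n_structures, seed, min_reliable)
  if (!is.null(tiny_corpus_cache[[key]])) return(tiny_corpus_cache[[key]])
  spec <- synthetic_spec(n_structures = n_structures, seed = seed)
  corpus <- make_corpus(spec)
  ap <- assoc_params(min_waters_reliable = min_reliable)
  template <- make_ideal_step(spec$seq2, spec$form)
  hydrated <- lapply(corpus$models, function(m) {
    res <- residues_from_model(m, "A")
    step <- extract_steps(res, source = list(structure_id = m$structure_id,
                                             chain_id = "A"))[[1]]
    step$ntc <- spec$ntc
    list(step = step, waters = associate_waters(step, extract_waters(m), ap))
  })
  lib <- build_block_library(hydrated,
                             references = setNames(list(template),
                                                   paste0(spec$ntc, "/", spec$seq2)),
                             params = ap)
  out <- list(spec = spec, corpus = corpus, library = lib, params = ap,
              template = template)
  tiny_corpus_cache[[key]] <- out
  out
}

# Centroid classifier built from the ideal template torsions.
template_centroid_classifier <- function(label = "BB00", seq2 = "CG",
                                         form = "B") {
  tv <- step_torsions(make_ideal_step(seq2, form))
  df <- as.data.frame(as.list(as.numeric(tv)))
  names(df) <- dnahydro:::TORSION_NAMES
  classifier_table(cbind(data.frame(label = label), df))
}
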