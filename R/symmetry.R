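# Crystallographic symmetry expansion: generate the symmetry mates (within a
# distance cutoff of the asymmetric unit DNA) that contribute surface waters
# from neighboring copies in the lattice.

#' Orthogonalization matrix from cell parameters
#'
#' Standard crystallographic convention: a along x, b in the xy plane.
#' Multiplying a fractional coordinate column vector by this matrix yields
#' Cartesian Angstrom.
#'
#' @param cell numeric(6): a, b, c (Angstrom), alpha, beta, gamma (degrees).
#' @return 3 x 3 matrix.
#' @export
frac_to_cart_matrix <- function(cell) {
  stopifnot(length(cell) == 6L, all(cell[1:3] > 0))
  a <- cell[1L]; b <- cell[2L]; cc <- cell[3L]
  al <- cell[4L] * pi / 180; be <- cell[5L] * pi / 180; ga <- cell[6L] * pi / 180
  v <- sqrt(1 - cos(al)^2 - cos(be)^2 - cos(ga)^2 +
              2 * cos(al) * cos(be) * cos(ga))
  matrix(c(a, b * cos(ga), cc * cos(be),
           0, b * sin(ga), cc * (cos(al) - cos(be) * cos(ga)) / sin(ga),
           0, 0, cc * v / sin(ga)),
         nrow = 3L, byrow = TRUE)
}

#' Expand crystallographic symmetry around the asymmetric unit
#'
#' Applies every space-group operation combined with the lattice translations
#' whose images can fall within `radius` of the bounding box of the ASU DNA
#' heavy atoms (box inflated by `radius`, converted to fractional ranges),
#' then retains only atoms that actually lie within `radius` of some ASU DNA
#' heavy atom. The identity operation with zero lattice translation is
#' excluded (it would duplicate the ASU).
#'
#' @param model a `dnahydro_model` with `cell` and `symops` present.
#' @param radius cutoff in Angstrom (> 0 for a non-empty result).
#' @param what `"waters"` to expand water O atoms only, `"all"` for all atoms.
#' @param mapping residue-name mapping used to recognize DNA residues.
#' @return object of class `dnahydro_symexp`: list with `radius`, `what` and
#'   `mates`, a data.frame of atom records plus `op_index` and `lat_a/b/c`
#'   lattice translation columns.
#' @export
expand_symmetry <- function(model, radius, what = c("waters", "all"),
                            mapping = nucleotide_mapping()) {
  what <- match.arg(what)
  if (is.null(model$cell) || is.null(model$symops)) {
    stop("no-symmetry condition: model lacks cell or symmetry operations")
  }
  if (radius < 0) stop("radius must be nonnegative")
  at <- model$atoms
  dna <- at[!at$is_water & !at$is_hydrogen &
              is_dna_residue(at$residue_name, mapping), , drop = FALSE]
  empty <- structure(list(radius = radius, what = what,
                          mates = cbind(at[0, , drop = FALSE],
                                        op_index = integer(0),
                                        lat_a = integer(0), lat_b = integer(0),
                                        lat_c = integer(0))),
                     class = "dnahydro_symexp")
  if (nrow(dna) == 0L || radius == 0) return(empty)

  m <- frac_to_cart_matrix(model$cell)
  minv <- solve(m)
  dna_xyz <- as.matrix(dna[, c("x", "y", "z")])

  src <- if (what == "waters") at[at$is_water, , drop = FALSE] else at
  if (nrow(src) == 0L) return(empty)
  src_frac <- as.matrix(src[, c("x", "y", "z")]) %*% t(minv)

  # fractional range that any mate atom must intersect
  box_lo <- apply(dna_xyz, 2L, min) - radius
  box_hi <- apply(dna_xyz, 2L, max) + radius
  corners <- as.matrix(expand.grid(c(box_lo[1L], box_hi[1L]),
                                   c(box_lo[2L], box_hi[2L]),
                                   c(box_lo[3L], box_hi[3L])))
  fr <- corners %*% t(minv)
  f_lo <- apply(fr, 2L, min)
  f_hi <- apply(fr, 2L, max)

  mates <- list()
  for (k in seq_along(model$symops)) {
    op <- model$symops[[k]]
    g <- src_frac %*% t(op$rot)
    g <- sweep(g, 2L, op$trans, "+")
    rng <- lapply(1:3, function(ax) {
      seq.int(floor(f_lo[ax] - max(g[, ax])), ceiling(f_hi[ax] - min(g[, ax])))
    })
    is_ident <- all(op$rot == diag(3)) && all(op$trans == 0)
    for (na in rng[[1L]]) for (nb in rng[[2L]]) for (nc in rng[[3L]]) {
      if (is_ident && na == 0L && nb == 0L && nc == 0L) next
      gf <- sweep(g, 2L, c(na, nb, nc), "+")
      cart <- gf %*% t(m)
      d <- min_dist_to_set(cart, dna_xyz)
      keep <- which(d <= radius)
      if (length(keep) > 0L) {
        rec <- src[keep, , drop = FALSE]
        rec$x <- cart[keep, 1L]; rec$y <- cart[keep, 2L]; rec$z <- cart[keep, 3L]
        rec$op_index <- k
        rec$lat_a <- na; rec$lat_b <- nb; rec$lat_c <- nc
        mates[[length(mates) + 1L]] <- rec
      }
    }
  }
  mates <- if (length(mates) == 0L) empty$mates else do.call(rbind, mates)
  rownames(mates) <- NULL
  structure(list(radius = radius, what = what, mates = mates),
            class = "dnahydro_symexp")
}

#' @export
print.dnahydro_symexp <- function(x, ...) {
  cat("dnahydro symmetry expansion: ", nrow(x$mates), " mate atoms (",
      x$what, ", radius ", x$radius, " A)\n", sep = "")
  invisible(x)
}
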