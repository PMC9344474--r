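# Water probability densities on Cartesian grids, hydration-site peak
# detection, and site occupancies. The density is a truncated-Gaussian kernel
# sum: a band-limited stand-in for crystallographic Fourier averaging, with
# the kernel width playing the role of the pseudo-atom form-factor width.

#' Density and peak-detection parameters
#'
#' @param spacing grid spacing, Angstrom.
#' @param sigma isotropic Gaussian width per water, Angstrom. A warning is
#'   issued when `sigma < spacing / 2` (undersampled kernel).
#' @param margin grid padding around the frame atoms, Angstrom.
#' @param peak_min_separation minimum distance between reported peaks;
#'   closer candidates merge into the higher one.
#' @param w_min occupancy-equivalent threshold fraction: the default peak
#'   threshold is the central density of a point cluster of total weight
#'   `w_min * n_steps`, so thresholds transfer across block populations.
#' @param peak_threshold explicit absolute density threshold; overrides the
#'   `w_min` rule when set.
#' @return list of class `dnahydro_density_params`.
#' @export
density_params <- function(spacing = 0.2, sigma = 0.4, margin = 4.0,
                           peak_min_separation = 1.0, w_min = 0.05,
                           peak_threshold = NULL) {
  stopifnot(spacing > 0, sigma > 0, margin >= 0, peak_min_separation >= spacing)
  if (sigma < spacing / 2) {
    warning("sigma < spacing/2: kernel undersampled on this grid")
  }
  structure(list(spacing = spacing, sigma = sigma, margin = margin,
                 peak_min_separation = peak_min_separation, w_min = w_min,
                 peak_threshold = peak_threshold),
            class = "dnahydro_density_params")
}

#' @noRd
gaussian_peak_height <- function(sigma) (2 * pi * sigma^2)^(-1.5)

#' @noRd
new_grid <- function(origin, spacing, dims, values, category) {
  structure(list(origin = as.numeric(origin), spacing = spacing,
                 dims = as.integer(dims), values = values,
                 category = category),
            class = "dnahydro_grid")
}

#' @export
print.dnahydro_grid <- function(x, ...) {
  cat("dnahydro density grid (", x$category, "): ",
      paste(x$dims, collapse = " x "), " voxels @ ", x$spacing, " A, total ",
      signif(sum(x$values) * x$spacing^3, 4L), "\n", sep = "")
  invisible(x)
}

#' Accumulate weighted waters into a probability density grid
#'
#' The grid covers the bounding box of `frame_atoms` inflated by the margin.
#' Each water adds a normalized isotropic Gaussian (total integral equal to
#' its weight, truncated at four sigma) sampled at voxel centers. Only
#' waters carrying the requested category flag should be passed in; the
#' base/backbone split is decided upstream at the category cutoff.
#'
#' @param waters data.frame with `x`, `y`, `z` and optionally `weight`
#'   (default 1). An empty set gives an all-zero grid.
#' @param frame_atoms n x 3 matrix (or data.frame with x, y, z) of the
#'   fragment atoms the grid must cover.
#' @param params a `dnahydro_density_params`.
#' @param category label stored on the grid (`"base"` or `"backbone"`).
#' @return a `dnahydro_grid`.
#' @export
accumulate_density <- function(waters, frame_atoms, params = density_params(),
                               category = "base") {
  if (is.data.frame(frame_atoms)) {
    frame_atoms <- as.matrix(frame_atoms[, c("x", "y", "z")])
  }
  if (nrow(frame_atoms) == 0L) stop("no frame atoms: nothing to cover")
  h <- params$spacing
  lo <- apply(frame_atoms, 2L, min) - params$margin
  hi <- apply(frame_atoms, 2L, max) + params$margin
  dims <- pmax(1L, as.integer(ceiling((hi - lo) / h)) + 1L)
  vals <- array(0, dim = dims)
  if (nrow(waters) > 0L) {
    w <- if ("weight" %in% names(waters)) waters$weight else rep(1, nrow(waters))
    sigma <- params$sigma
    cut <- 4 * sigma
    norm <- gaussian_peak_height(sigma)
    ax <- lapply(1:3, function(k) lo[k] + (seq_len(dims[k]) - 1L) * h)
    for (i in seq_len(nrow(waters))) {
      p <- c(waters$x[i], waters$y[i], waters$z[i])
      rng <- lapply(1:3, function(k) {
        which(ax[[k]] >= p[k] - cut & ax[[k]] <= p[k] + cut)
      })
      if (any(vapply(rng, length, 1L) == 0L)) next
      dx2 <- (ax[[1L]][rng[[1L]]] - p[1L])^2
      dy2 <- (ax[[2L]][rng[[2L]]] - p[2L])^2
      dz2 <- (ax[[3L]][rng[[3L]]] - p[3L])^2
      block <- outer(outer(dx2, dy2, "+"), dz2, "+")
      vals[rng[[1L]], rng[[2L]], rng[[3L]]] <-
        vals[rng[[1L]], rng[[2L]], rng[[3L]]] +
        w[i] * norm * exp(-block / (2 * sigma^2))
    }
  }
  new_grid(origin = lo, spacing = h, dims = dims, values = vals,
           category = category)
}

#' Locate density peaks (hydration-site candidates)
#'
#' Candidate voxels are strict 26-neighborhood local maxima at or above the
#' density threshold. Each candidate is refined to sub-voxel position by
#' independent quadratic interpolation along the three axes, then candidates
#' closer than the minimum separation are merged greedily by descending peak
#' value (the higher peak wins).
#'
#' @param grid a `dnahydro_grid`.
#' @param params a `dnahydro_density_params`.
#' @param threshold absolute density threshold; when `NULL` uses
#'   `params$peak_threshold`, or the `w_min` occupancy-equivalent rule with
#'   `n_steps` contributing dinucleotides.
#' @param n_steps population used by the `w_min` threshold rule.
#' @return data.frame with `x`, `y`, `z`, `peak_value`, ordered by
#'   descending peak value.
#' @export
find_peaks <- function(grid, params = density_params(), threshold = NULL,
                       n_steps = 1L) {
  thr <- threshold %||% params$peak_threshold %||%
    (params$w_min * n_steps * gaussian_peak_height(params$sigma))
  v <- grid$values
  d <- dim(v)
  empty <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      peak_value = numeric(0))
  if (any(d < 3L)) {
    # degenerate thin grids: fall back to global maximum if above threshold
    mx <- which.max(v)
    if (v[mx] < thr) return(empty)
    idx <- arrayInd(mx, d)
    return(data.frame(x = grid$origin[1L] + (idx[1L] - 1L) * grid$spacing,
                      y = grid$origin[2L] + (idx[2L] - 1L) * grid$spacing,
                      z = grid$origin[3L] + (idx[3L] - 1L) * grid$spacing,
                      peak_value = v[mx]))
  }
  core <- v[2:(d[1L] - 1L), 2:(d[2L] - 1L), 2:(d[3L] - 1L), drop = FALSE]
  is_max <- core >= thr
  for (sx in -1:1) for (sy in -1:1) for (sz in -1:1) {
    if (sx == 0L && sy == 0L && sz == 0L) next
    nb <- v[(2:(d[1L] - 1L)) + sx, (2:(d[2L] - 1L)) + sy,
            (2:(d[3L] - 1L)) + sz, drop = FALSE]
    is_max <- is_max & (core > nb)
    if (!any(is_max)) break
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(empty)
  idx <- idx + 1L  # back to full-grid indices
  peaks <- data.frame(x = numeric(nrow(idx)), y = numeric(nrow(idx)),
                      z = numeric(nrow(idx)), peak_value = numeric(nrow(idx)))
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, ]
    offs <- numeric(3L)
    for (ax in 1:3) {
      im <- i; im[ax] <- im[ax] - 1L
      ip <- i; ip[ax] <- ip[ax] + 1L
      fm <- v[im[1L], im[2L], im[3L]]
      f0 <- v[i[1L], i[2L], i[3L]]
      fp <- v[ip[1L], ip[2L], ip[3L]]
      den <- fm - 2 * f0 + fp
      offs[ax] <- if (abs(den) > 1e-300) {
        max(-0.5, min(0.5, 0.5 * (fm - fp) / den))
      } else 0
    }
    pos <- grid$origin + (i - 1L + offs) * grid$spacing
    peaks$x[r] <- pos[1L]; peaks$y[r] <- pos[2L]; peaks$z[r] <- pos[3L]
    peaks$peak_value[r] <- v[i[1L], i[2L], i[3L]]
  }
  peaks <- peaks[order(-peaks$peak_value), , drop = FALSE]
  keep <- logical(nrow(peaks))
  for (r in seq_len(nrow(peaks))) {
    if (!any(keep)) { keep[r] <- TRUE; next }
    acc <- peaks[keep, , drop = FALSE]
    dmin <- min(sqrt((acc$x - peaks$x[r])^2 + (acc$y - peaks$y[r])^2 +
                       (acc$z - peaks$z[r])^2))
    keep[r] <- dmin >= params$peak_min_separation
  }
  out <- peaks[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Occupancy of a hydration site
#'
#' The occupancy is the summed weight of waters within the occupancy radius
#' of the peak (boundary inclusive at exactly `r_occ`), divided by the number
#' of contributing dinucleotides. Occupancies above 1 (merged dense
#' clusters) are reported with a warning, not clamped.
#'
#' @param peak numeric 3-vector, site position.
#' @param waters data.frame of weighted reference-frame waters.
#' @param n_steps number of contributing dinucleotides (>= 1).
#' @param params a `dnahydro_assoc_params` (for `r_occ`).
#' @return list with `occupancy` and `n_support`.
#' @export
site_occupancy <- function(peak, waters, n_steps, params = assoc_params()) {
  if (n_steps < 1L) stop("n_steps must be >= 1")
  if (nrow(waters) == 0L) return(list(occupancy = 0, n_support = 0L))
  d <- sqrt((waters$x - peak[1L])^2 + (waters$y - peak[2L])^2 +
              (waters$z - peak[3L])^2)
  w <- if ("weight" %in% names(waters)) waters$weight else rep(1, nrow(waters))
  inside <- d <= params$r_occ
  occ <- sum(w[inside]) / n_steps
  if (occ > 1) warning("site occupancy ", signif(occ, 3L), " exceeds 1 (merged site)")
  list(occupancy = occ, n_support = sum(inside))
}

#' Hydration sites of one category from weighted waters
#'
#' Convenience wrapper: accumulates the density, finds peaks, and attaches
#' occupancies.
#'
#' @param waters weighted reference-frame waters of one category.
#' @param frame_atoms coordinates the grid must cover.
#' @param n_steps contributing dinucleotide count (occupancy divisor and
#'   threshold scale).
#' @param category `"base"` or `"backbone"`.
#' @param dparams a `dnahydro_density_params`.
#' @param aparams a `dnahydro_assoc_params`.
#' @return list with `grid` and `sites` (data.frame `x`, `y`, `z`,
#'   `peak_value`, `occupancy`, `category`, `n_support`).
#' @export
hydration_sites <- function(waters, frame_atoms, n_steps, category,
                            dparams = density_params(),
                            aparams = assoc_params()) {
  grid <- accumulate_density(waters, frame_atoms, dparams, category)
  peaks <- find_peaks(grid, dparams, n_steps = n_steps)
  if (nrow(peaks) == 0L) {
    sites <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                        peak_value = numeric(0), occupancy = numeric(0),
                        category = character(0), n_support = integer(0))
  } else {
    occ <- lapply(seq_len(nrow(peaks)), function(r) {
      site_occupancy(c(peaks$x[r], peaks$y[r], peaks$z[r]), waters, n_steps,
                     aparams)
    })
    sites <- data.frame(peaks,
                        occupancy = vapply(occ, `[[`, numeric(1L), "occupancy"),
                        category = category,
                        n_support = vapply(occ, `[[`, integer(1L), "n_support"),
                        stringsAsFactors = FALSE)
  }
  list(grid = grid, sites = sites)
}
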