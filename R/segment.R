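# Dense 1D Gaussian smoothing matrix (truncated at 3 sigma, renormalized at
# the edges). sigma in samples; sigma = 0 gives the identity.
gauss_matrix <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  W <- matrix(0, n, n)
  for (j in seq(-r, r)) {
    idx <- seq_len(n) + j
    ok <- idx >= 1 & idx <= n
    W[cbind(which(ok), idx[ok])] <- W[cbind(which(ok), idx[ok])] + k[j + r + 1]
  }
  W / rowSums(W)
}

# Separable 3D Gaussian blur; sigma_vox is per-axis in voxels.
gauss_blur_3d <- function(vol, sigma_vox) {
  d <- dim(vol)
  W1 <- gauss_matrix(d[1], sigma_vox[1])
  W2 <- gauss_matrix(d[2], sigma_vox[2])
  W3 <- gauss_matrix(d[3], sigma_vox[3])
  # axis 1
  m <- W1 %*% matrix(vol, d[1], d[2] * d[3])
  vol <- array(m, d)
  # axis 2
  vol <- aperm(vol, c(2, 1, 3))
  m <- W2 %*% matrix(vol, d[2], d[1] * d[3])
  vol <- aperm(array(m, c(d[2], d[1], d[3])), c(2, 1, 3))
  # axis 3
  vol <- aperm(vol, c(3, 1, 2))
  m <- W3 %*% matrix(vol, d[3], d[1] * d[2])
  aperm(array(m, c(d[3], d[1], d[2])), c(2, 3, 1))
}

# 3D local maxima (26-neighborhood) above a threshold.
local_maxima_3d <- function(vol, threshold) {
  d <- dim(vol)
  is_max <- vol > threshold
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dz == 0 && dy == 0 && dx == 0) next
    shifted <- array(-Inf, d)
    src_r <- intersect(seq_len(d[1]) + dy, seq_len(d[1]))
    src_c <- intersect(seq_len(d[2]) + dx, seq_len(d[2]))
    src_s <- intersect(seq_len(d[3]) + dz, seq_len(d[3]))
    shifted[src_r - dy, src_c - dx, src_s - dz] <- vol[src_r, src_c, src_s]
    is_max <- is_max & (vol >= shifted)
  }
  which(is_max, arr.ind = TRUE)
}

#' Segment cell bodies in a stitched 3D volume
#'
#' Classical scale-selective pipeline: band-pass at the soma scale
#' (difference of Gaussians with per-axis sigmas honoring anisotropic voxel
#' sizes), local-maxima seed detection with non-maximum suppression,
#' seeded region assignment (each above-threshold voxel near a seed joins
#' its nearest seed, splitting touching cells along the midline, i.e. a
#' marker-based watershed on the distance transform), and a size filter
#' keeping ROIs within `[0.5, 2]` times the nominal soma volume.
#'
#' @param volume A `volume_stack` (or a plain 3D array if `voxel_size` is
#'   given).
#' @param scale Expected soma diameter in um.
#' @param voxel_size Length-3 voxel size in um (y, x, z); taken from the
#'   `volume_stack` when omitted.
#' @param seed_k Seed threshold in robust sds (median + k * MAD) of the
#'   band-passed volume.
#' @param rel_level Relative intensity level (fraction of each seed's
#'   smoothed peak) that delimits its soma. For an ideal Gaussian soma
#'   profile the half-diameter sits at `exp(-2)` (0.135), but detection
#'   blur (PSF, light-sheet thickness, pre-smoothing) widens the observed
#'   blob, so the half-diameter of a realistically blurred soma crosses
#'   nearer 0.25 — the default; masks cut at `exp(-2)` over-extend and
#'   push identical somata across the size filter depending on their z
#'   alignment with the slice grid.
#' @param size_filter Length-2 multiplier range on the nominal soma volume.
#' @return An object of class `roi_set`: `labels` (integer array),
#'   `table` (per-ROI voxel count, centroid in um, equivalent diameter),
#'   `voxel_size`.
#' @export
segment_3d <- function(volume, scale = 7.7, voxel_size = NULL,
                       seed_k = 4, rel_level = 0.25,
                       size_filter = c(0.5, 2)) {
  z_of_voxel <- NULL
  if (inherits(volume, "volume_stack")) {
    vol <- volume$data
    dz <- if (length(volume$slice_z) > 1) stats::median(diff(volume$slice_z)) else scale / 2
    voxel_size <- c(volume$pixel_size, volume$pixel_size, dz)
    slice_z <- volume$slice_z # stitched slices are not uniformly spaced
    # within a half-plane z still varies across rows (rolling-shutter tilt);
    # the provenance + z-map give every voxel its true focal z
    zmap <- volume$zmap
    if (!is.null(zmap)) {
      d0 <- dim(vol)
      half <- d0[1] %/% 2
      z_rs <- matrix(0, d0[1], d0[3])
      for (s in seq_len(d0[3])) {
        pr <- volume$provenance[s, ]
        f_top <- which(zmap$stroke == pr$top_stroke &
                         zmap$plane == pr$top_plane)
        f_bot <- which(zmap$stroke == pr$bottom_stroke &
                         zmap$plane == pr$bottom_plane)
        z_rs[seq_len(half), s] <- zmap$z[seq_len(half), f_top]
        z_rs[(half + 1):d0[1], s] <- zmap$z[(half + 1):d0[1], f_bot]
      }
      z_of_voxel <- array(0, d0)
      for (s in seq_len(d0[3])) {
        z_of_voxel[, , s] <- matrix(z_rs[, s], d0[1], d0[2])
      }
    }
  } else {
    vol <- volume
    if (is.null(voxel_size)) stop("segment_3d: voxel_size required for plain arrays")
    slice_z <- (seq_len(dim(vol)[3]) - 0.5) * voxel_size[3]
  }
  d <- dim(vol)
  # DoG kernels at FWHM scale/2 (matched to the soma core) and scale
  fw <- 2 * sqrt(2 * log(2))
  sig1 <- (scale / 2 / fw) / voxel_size
  sig2 <- (scale / fw) / voxel_size
  dog <- gauss_blur_3d(vol, sig1) - gauss_blur_3d(vol, sig2)
  thr <- stats::median(dog) + seed_k * stats::mad(dog)
  seeds <- local_maxima_3d(dog, thr)
  empty <- function() {
    structure(list(labels = array(0L, d),
                   table = data.frame(label = integer(0), n_vox = integer(0),
                                      x = numeric(0), y = numeric(0),
                                      z = numeric(0),
                                      equivalent_diameter = numeric(0)),
                   voxel_size = voxel_size), class = "roi_set")
  }
  if (nrow(seeds) == 0) {
    warning("segment_3d: no seeds found; returning 0 ROIs")
    return(empty())
  }
  # non-maximum suppression at 0.8 * scale um
  seed_um <- t(t(seeds - 0.5) * voxel_size)
  seed_um[, 3] <- if (is.null(z_of_voxel)) slice_z[seeds[, 3]] else z_of_voxel[seeds]
  ord <- order(dog[seeds], decreasing = TRUE)
  keep <- logical(nrow(seeds))
  min_sep2 <- (0.8 * scale)^2
  for (i in ord) {
    if (!any(keep)) { keep[i] <- TRUE; next }
    d2 <- colSums((t(seed_um[keep, , drop = FALSE]) - seed_um[i, ])^2)
    if (all(d2 >= min_sep2)) keep[i] <- TRUE
  }
  seeds <- seeds[keep, , drop = FALSE]
  seed_um <- seed_um[keep, , drop = FALSE]
  n_seed <- nrow(seeds)

  # lightly smoothed intensity for region growing and subvoxel centroids
  sm <- gauss_blur_3d(vol, 1 / voxel_size)
  bg <- stats::median(sm)
  peak_val <- sm[seeds] - bg
  labels <- array(0L, d)
  coords_um <- cbind(
    rep((seq_len(d[1]) - 0.5) * voxel_size[1], times = d[2] * d[3]),
    rep(rep((seq_len(d[2]) - 0.5) * voxel_size[2], each = d[1]), times = d[3]),
    if (is.null(z_of_voxel)) rep(slice_z, each = d[1] * d[2])
    else as.numeric(z_of_voxel)
  )
  # nearest seed within `scale` um; note coords are (y, x, z) ordered as
  # (row, col, slice)
  best_d2 <- rep(Inf, prod(d))
  best_seed <- integer(prod(d))
  for (i in seq_len(n_seed)) {
    d2 <- (coords_um[, 1] - seed_um[i, 1])^2 +
      (coords_um[, 2] - seed_um[i, 2])^2 +
      (coords_um[, 3] - seed_um[i, 3])^2
    upd <- d2 < best_d2
    best_d2[upd] <- d2[upd]
    best_seed[upd] <- i
  }
  in_roi <- best_d2 <= scale^2 &
    (as.numeric(sm) - bg) > rel_level * peak_val[pmax(best_seed, 1L)]
  labels[in_roi] <- best_seed[in_roi]

  vox_vol <- prod(voxel_size)
  nominal <- pi / 6 * scale^3
  tab_list <- list()
  new_label <- 0L
  relabeled <- array(0L, d)
  for (i in seq_len(n_seed)) {
    vix <- which(labels == i)
    nv <- length(vix)
    v_um3 <- nv * vox_vol
    if (v_um3 < size_filter[1] * nominal || v_um3 > size_filter[2] * nominal) next
    new_label <- new_label + 1L
    relabeled[vix] <- new_label
    w <- as.numeric(sm)[vix] - bg
    w <- pmax(w, 0)
    if (sum(w) <= 0) w <- rep(1, nv)
    cy <- sum(coords_um[vix, 1] * w) / sum(w)
    cx <- sum(coords_um[vix, 2] * w) / sum(w)
    cz <- sum(coords_um[vix, 3] * w) / sum(w)
    tab_list[[new_label]] <- data.frame(
      label = new_label, n_vox = nv, x = cx, y = cy, z = cz,
      equivalent_diameter = (6 * v_um3 / pi)^(1 / 3)
    )
  }
  if (new_label == 0L) {
    warning("segment_3d: all candidate ROIs rejected by the size filter")
    return(empty())
  }
  structure(list(labels = relabeled, table = do.call(rbind, tab_list),
                 voxel_size = voxel_size), class = "roi_set")
}

#' Voxel coordinates of one ROI
#'
#' @param rois A `roi_set`.
#' @param label ROI label.
#' @return Integer matrix with columns `row`, `col`, `slice`.
#' @export
roi_voxels <- function(rois, label) {
  stopifnot(inherits(rois, "roi_set"))
  ix <- which(rois$labels == label, arr.ind = TRUE)
  colnames(ix) <- c("row", "col", "slice")
  ix
}

#' Neuron size statistics
#'
#' Mean and standard error of the equivalent spherical diameter
#' `(6 V / pi)^(1/3)` over all ROIs.
#'
#' @param rois A `roi_set` (or a numeric vector of equivalent diameters).
#' @return List with `mean`, `sem`, `n`, and the per-ROI `diameters`.
#' @export
neuron_size_stats <- function(rois) {
  diam <- if (inherits(rois, "roi_set")) rois$table$equivalent_diameter else rois
  if (length(diam) < 1) stop("neuron_size_stats: need at least one ROI")
  sem <- if (length(diam) > 1) stats::sd(diam) / sqrt(length(diam)) else 0
  list(mean = mean(diam), sem = sem, n = length(diam), diameters = diam)
}

#' Background shell around an ROI
#'
#' Morphological annulus: voxels whose distance (in index space) to the ROI
#' lies in `[r_inner, r_outer]` voxels and that belong to no ROI.
#'
#' @param rois A `roi_set`.
#' @param label ROI label.
#' @param r_inner,r_outer Annulus radii in voxels.
#' @return Integer matrix with columns `row`, `col`, `slice`.
#' @export
background_shell <- function(rois, label, r_inner = 2, r_outer = 4) {
  stopifnot(inherits(rois, "roi_set"))
  d <- dim(rois$labels)
  vox <- roi_voxels(rois, label)
  if (nrow(vox) == 0) stop("background_shell: empty ROI")
  r <- ceiling(r_outer)
  lo <- pmax(apply(vox, 2, min) - r, 1L)
  hi <- pmin(apply(vox, 2, max) + r, d)
  grid <- as.matrix(expand.grid(row = lo[1]:hi[1], col = lo[2]:hi[2],
                                slice = lo[3]:hi[3]))
  # min distance to any ROI voxel (index-space Euclidean)
  dmin <- rep(Inf, nrow(grid))
  for (i in seq_len(nrow(vox))) {
    d2 <- (grid[, 1] - vox[i, 1])^2 + (grid[, 2] - vox[i, 2])^2 +
      (grid[, 3] - vox[i, 3])^2
    dmin <- pmin(dmin, d2)
  }
  dmin <- sqrt(dmin)
  sel <- dmin >= r_inner & dmin <= r_outer
  grid <- grid[sel, , drop = FALSE]
  lab_at <- rois$labels[grid]
  grid[lab_at == 0L, , drop = FALSE]
}
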