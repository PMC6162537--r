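#' Detect telomere spots in the Q-FISH channel
#'
#' Band-pass (difference-of-Gaussians) filtering followed by local
#' maxima detection above a relative threshold; each maximum grows into
#' a region by nearest-seed assignment of the above-threshold voxels.
#' Maxima outside the nucleus are discarded; centroids are
#' intensity-weighted over the raw channel. Spot counts are invariant
#' under positive rescaling of the channel (all thresholds relative).
#'
#' @param telo telomere [voxel_grid()].
#' @param nucleus_mask logical 3D array from [segment_nucleus()].
#' @param spot_sigma_um expected spot sigma `(z, y, x)` or scalar (um);
#'   sets the band-pass scales.
#' @param rel_threshold maxima must exceed this fraction of the largest
#'   band-pass response.
#' @param min_separation_um minimum distance between distinct maxima.
#' @param region_radius_um cap on a spot region's lateral-equivalent
#'   reach around its maximum (axial distances scaled by the
#'   lateral-to-axial sigma ratio); keeps regions local, so stray
#'   band-pass response elsewhere in the nucleus never joins a spot.
#' @return tibble of spots: `spot_id`, `z`, `y`, `x` (um, weighted
#'   centroid), `total_intensity`, `volume` (um^3, measured at half the
#'   spot's own band-pass peak -- the FWHM volume, so unresolved
#'   multi-telomere clusters read larger than single spots), `peak`;
#'   attribute `"regions"` holds the labeled region array.
#' @export
detect_spots <- function(telo, nucleus_mask,
                         spot_sigma_um = c(0.25, 0.15, 0.15),
                         rel_threshold = 0.15,
                         min_separation_um = 0.25,
                         region_radius_um = 0.35) {
  stopifnot(inherits(telo, "voxel_grid"))
  if (!identical(dim(telo$data), dim(nucleus_mask)))
    stop("telomere grid and nucleus mask geometry mismatch", call. = FALSE)
  if (!any(nucleus_mask)) stop("empty nucleus mask", call. = FALSE)
  vs <- telo$voxel_size
  dims <- dim(telo$data)
  if (length(spot_sigma_um) == 1L) spot_sigma_um <- rep(spot_sigma_um, 3)

  g1 <- gauss_blur(telo$data, spot_sigma_um, vs)
  g2 <- gauss_blur(telo$data, 2 * spot_sigma_um, vs)
  bp <- g1 - g2
  bp[bp < 0] <- 0
  bp[!nucleus_mask] <- 0

  peak <- max(bp)
  empty <- tibble::tibble(
    spot_id = integer(0), z = numeric(0), y = numeric(0), x = numeric(0),
    total_intensity = numeric(0), volume = numeric(0), peak = numeric(0)
  )
  if (peak <= 0) {
    attr(empty, "regions") <- array(0L, dims)
    return(empty)
  }
  thr <- rel_threshold * peak
  rad <- pmax(1L, as.integer(round(min_separation_um / vs)))
  maxima <- cpp_local_maxima(as.numeric(bp), dims, rad, thr)
  if (!length(maxima)) {
    attr(empty, "regions") <- array(0L, dims)
    return(empty)
  }
  seeds <- arrayInd(maxima, dims)

  fg <- bp > 0.25 * thr
  regions <- array(cpp_nearest_seed(as_int_mask(fg), dims, vs, seeds - 1L),
                   dims)
  # cap each region's reach around its seed (lateral-equivalent metric)
  sep_scale <- min(spot_sigma_um) / spot_sigma_um * vs
  reg_idx <- which(regions > 0L)
  pos <- arrayInd(reg_idx, dims)
  d2 <- ((pos[, 1] - seeds[regions[reg_idx], 1]) * sep_scale[1])^2 +
        ((pos[, 2] - seeds[regions[reg_idx], 2]) * sep_scale[2])^2 +
        ((pos[, 3] - seeds[regions[reg_idx], 3]) * sep_scale[3])^2
  regions[reg_idx[d2 > region_radius_um^2]] <- 0L
  spots <- purrr::map_dfr(seq_len(nrow(seeds)), function(s) {
    vox <- which(regions == s)
    w <- telo$data[vox]
    pos <- (arrayInd(vox, dims) - 1) * rep(vs, each = length(vox))
    ctr <- colSums(pos * w) / sum(w)
    pk <- bp[maxima[s]]
    tibble::tibble(
      spot_id = s,
      z = ctr[1], y = ctr[2], x = ctr[3],
      total_intensity = sum(w),
      volume = sum(bp[vox] > 0.5 * pk) * prod(vs),
      peak = pk
    )
  })
  attr(spots, "regions") <- regions
  spots
}

#' Flag telomere aggregates
#'
#' A spot is an aggregate when another spot centroid lies within
#' `merge_distance_um` (signals not resolvable as separate at optical
#' resolution) or when its volume exceeds `volume_multiple` times the
#' median spot volume (an unresolved cluster detected as one large
#' signal).
#'
#' @param spots spot tibble from [detect_spots()].
#' @param merge_distance_um centroid distance gate (um).
#' @param volume_multiple large-volume gate as a multiple of the median
#'   volume.
#' @return `spots` with a logical `is_aggregate` column.
#' @export
flag_aggregates <- function(spots, merge_distance_um = 0.2,
                            volume_multiple = 1.4) {
  stopifnot(merge_distance_um > 0)
  n <- nrow(spots)
  if (n == 0L) return(dplyr::mutate(spots, is_aggregate = logical(0)))
  pts <- as.matrix(spots[, c("z", "y", "x")])
  near <- rep(FALSE, n)
  if (n > 1L) {
    d <- as.matrix(stats::dist(pts))
    diag(d) <- Inf
    near <- apply(d, 1, min) <= merge_distance_um
  }
  big <- spots$volume > volume_multiple * stats::median(spots$volume)
  dplyr::mutate(spots, is_aggregate = unname(near | big))
}

#' Telomere distribution shape (a/c) ratio
#'
#' Principal-axis statistic of the 3D telomere centroid cloud:
#' the square root of the ratio of the largest to the smallest
#' eigenvalue of the centroid covariance matrix (physical units). It is
#' ~1 for isotropic distributions (G0/G1-like nuclear telomere
#' organisation) and grows as the distribution flattens or elongates;
#' invariant under rotation and uniform scaling.
#'
#' @param spots spot tibble (needs `z`, `y`, `x`) or an n x 3 matrix.
#' @param tol degeneracy tolerance: smallest eigenvalue below `tol`
#'   times the largest marks a coplanar configuration.
#' @return scalar ratio >= 1, or `NA` (undefined) for fewer than 4
#'   spots or degenerate configurations.
#' @export
ac_ratio <- function(spots, tol = 1e-6) {
  pts <- if (is.matrix(spots)) spots else as.matrix(spots[, c("z", "y", "x")])
  if (nrow(pts) < 4L) return(NA_real_)
  ev <- eigen(stats::cov(pts), symmetric = TRUE, only.values = TRUE)$values
  if (ev[1] <= 0 || ev[3] < tol * ev[1]) return(NA_real_)
  sqrt(ev[1] / ev[3])
}

#' Telomere-lamin co-localization fraction (binary gate)
#'
#' Each spot's region (dilated by one voxel to absorb PSF boundary
#' jitter) is tested for overlap with the internal lamin mask; the gate
#' is 1 if at least one voxel overlaps, else 0. Returns the mean gate
#' over spots -- the fraction of telomeres touching internal lamin
#' structures. Order-independent and idempotent by construction.
#'
#' @param spots spot tibble from [detect_spots()].
#' @param spot_regions labeled region array (attribute `"regions"` of
#'   [detect_spots()] output; taken from there when `NULL`).
#' @param internal_mask logical array of internal lamin.
#' @param voxel_size `(dz, dy, dx)` um, for the one-voxel dilation.
#' @return list with `fraction` (`NA` when no spots), `gates` (0/1 per
#'   spot).
#' @export
coloc_fraction <- function(spots, spot_regions = NULL, internal_mask,
                           voxel_size = c(0.2, 0.1, 0.1)) {
  if (is.null(spot_regions)) spot_regions <- attr(spots, "regions")
  stopifnot(!is.null(spot_regions))
  if (!identical(dim(spot_regions), dim(internal_mask)))
    stop("regions and internal mask geometry mismatch", call. = FALSE)
  if (nrow(spots) == 0L)
    return(list(fraction = NA_real_, gates = integer(0)))
  # dilate the internal mask once instead of each spot region: a spot
  # region overlaps dilated(internal) iff its one-lateral-voxel dilation
  # overlaps internal (structuring element symmetry)
  one_vox <- min(voxel_size) * 1.001
  internal_d <- dilate_ball(internal_mask, one_vox, voxel_size)
  gates <- vapply(spots$spot_id, function(s)
    as.integer(any(internal_d[spot_regions == s])), 0L)
  list(fraction = mean(gates), gates = gates)
}

#' Per-nucleus telomere metric vector
#'
#' TeloView-style summary for one nucleus: signal count, aggregate
#' count, a/c ratio, nuclear volume, mean and total signal intensity,
#' and the lamin co-localization fraction.
#'
#' @param spots spot tibble (after [flag_aggregates()]).
#' @param seg `nucleus_segmentation` for the nuclear volume.
#' @param coloc result of [coloc_fraction()] or `NULL`.
#' @return one-row tibble.
#' @export
telomere_metrics <- function(spots, seg, coloc = NULL) {
  n <- nrow(spots)
  tibble::tibble(
    n_signals = n,
    n_aggregates = if ("is_aggregate" %in% names(spots))
      sum(spots$is_aggregate) else NA_integer_,
    ac_ratio = ac_ratio(spots),
    nuclear_volume = seg$nuclear_volume,
    mean_intensity = if (n) mean(spots$total_intensity) else NA_real_,
    total_intensity = if (n) sum(spots$total_intensity) else 0,
    coloc_fraction = if (is.null(coloc)) NA_real_ else coloc$fraction
  )
}
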