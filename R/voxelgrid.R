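#' Single-channel 3D voxel grid
#'
#' The basic substrate of the pipeline: one channel of a 3D fluorescence
#' z-stack (or a mask derived from one) together with its physical voxel
#' dimensions. Arrays are indexed `[z, y, x]`, 0-based voxel `(i, j, k)`
#' sits at physical position `(i*dz, j*dy, k*dx)` micrometres
#' (voxel-centre convention).
#'
#' @param data 3D numeric array with dim `(nz, ny, nx)`.
#' @param voxel_size numeric length-3, `(dz, dy, dx)` in micrometres.
#' @param channel_role one of `"DAPI"`, `"LAMIN"`, `"TELO"`, `"MASK"`.
#' @return An object of class `voxel_grid`.
#' @export
voxel_grid <- function(data, voxel_size, channel_role = c("DAPI", "LAMIN", "TELO", "MASK")) {
  channel_role <- match.arg(channel_role)
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array indexed (z, y, x)", call. = FALSE)
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) || any(voxel_size <= 0))
    stop("`voxel_size` must be three positive numbers (dz, dy, dx) in um", call. = FALSE)
  if (any(dim(data) < 1L)) stop("all dimensions must be >= 1", call. = FALSE)
  if (any(data < 0, na.rm = TRUE))
    stop("intensity values must be non-negative", call. = FALSE)
  if (channel_role == "MASK") {
    if (any(data != round(data)))
      stop("MASK grids must contain non-negative integer labels", call. = FALSE)
    storage.mode(data) <- "double"
  }
  structure(
    list(data = data, voxel_size = voxel_size, channel_role = channel_role),
    class = "voxel_grid"
  )
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<voxel_grid %s> %d x %d x %d (z,y,x), voxel %.3f x %.3f x %.3f um, range [%g, %g]\n",
    x$channel_role, d[1], d[2], d[3],
    x$voxel_size[1], x$voxel_size[2], x$voxel_size[3],
    min(x$data), max(x$data)
  ))
  invisible(x)
}

#' @export
dim.voxel_grid <- function(x) dim(x$data)

#' Physical volume of one voxel in cubic micrometres
#' @param x a `voxel_grid` or a numeric `(dz, dy, dx)` vector.
#' @return scalar volume in um^3.
#' @export
voxel_volume <- function(x) {
  vs <- if (inherits(x, "voxel_grid")) x$voxel_size else as.numeric(x)
  prod(vs)
}

#' Multi-channel cell stack
#'
#' Bundles the channels acquired for one cell. All channels must share
#' shape and voxel size; DAPI and LAMIN are mandatory, TELO optional.
#'
#' @param channels named list of [voxel_grid()] objects; names are roles.
#' @param cell_id,experiment_id identifiers carried through the pipeline.
#' @return An object of class `cell_stack`.
#' @export
cell_stack <- function(channels, cell_id = "cell_1", experiment_id = "exp_1") {
  if (!is.list(channels) || is.null(names(channels)))
    stop("`channels` must be a named list of voxel_grid objects", call. = FALSE)
  if (!all(c("DAPI", "LAMIN") %in% names(channels)))
    stop("DAPI and LAMIN channels are mandatory", call. = FALSE)
  ref <- channels[[1]]
  for (nm in names(channels)) {
    ch <- channels[[nm]]
    if (!inherits(ch, "voxel_grid")) stop("channel ", nm, " is not a voxel_grid", call. = FALSE)
    if (!identical(dim(ch$data), dim(ref$data)))
      stop("channel ", nm, " shape differs from ", names(channels)[1], call. = FALSE)
    if (max(abs(ch$voxel_size - ref$voxel_size)) > 1e-9)
      stop("channel ", nm, " voxel size differs", call. = FALSE)
  }
  structure(
    list(channels = channels, cell_id = cell_id, experiment_id = experiment_id),
    class = "cell_stack"
  )
}

#' @export
print.cell_stack <- function(x, ...) {
  d <- dim(x$channels[[1]]$data)
  cat(sprintf(
    "<cell_stack %s/%s> channels: %s; %d x %d x %d (z,y,x)\n",
    x$experiment_id, x$cell_id, paste(names(x$channels), collapse = ", "),
    d[1], d[2], d[3]
  ))
  invisible(x)
}

# ---- internal volumetric helpers -------------------------------------------
# These operate on plain logical/numeric 3D arrays plus a (dz,dy,dx)
# spacing; the anisotropy-aware distance transform underlies erosion,
# dilation, opening and shell-depth computations everywhere.

as_int_mask <- function(mask) {
  m <- mask
  storage.mode(m) <- "integer"
  m
}

# Euclidean distance (um) from each voxel to the nearest background
# (FALSE) voxel centre; 0 on the background itself.
dist_to_background <- function(mask, spacing) {
  d <- cpp_sqedt(as_int_mask(mask), dim(mask), spacing)
  array(sqrt(d), dim(mask))
}

# Euclidean distance (um) from each voxel to the nearest TRUE voxel centre.
dist_to_mask <- function(mask, spacing) {
  d <- cpp_sqedt(as_int_mask(!mask), dim(mask), spacing)
  array(sqrt(d), dim(mask))
}

# Morphological erosion / dilation / opening by a ball of radius r um.
# The ball is defined in physical units (offsets o with ||o * spacing||
# <= r), so these are exact counterparts of explicit structuring-element
# morphology with an anisotropy-aware voxelized ball. Membership is
# decided on squared distances with a relative tolerance so that voxels
# lying exactly on the ball surface are classified identically to an
# explicit-offset implementation despite floating-point rounding.
ball_tol <- function(r) 1e-9 * max(1, r * r)

erode_ball <- function(mask, r, spacing) {
  if (r <= 0) return(mask)
  sq <- array(cpp_sqedt(as_int_mask(mask), dim(mask), spacing), dim(mask))
  mask & (sq > r * r + ball_tol(r))
}

dilate_ball <- function(mask, r, spacing) {
  if (r <= 0) return(mask)
  sq <- array(cpp_sqedt(as_int_mask(!mask), dim(mask), spacing), dim(mask))
  sq <= r * r + ball_tol(r)
}

open_ball <- function(mask, r, spacing) {
  if (r <= 0) return(mask)
  dilate_ball(erode_ball(mask, r, spacing), r, spacing)
}

# 26-connected components; returns integer array, attr "n_labels".
label_components <- function(mask) {
  lab <- cpp_label3d(as_int_mask(mask), dim(mask))
  out <- array(lab, dim(mask))
  attr(out, "n_labels") <- attr(lab, "n_labels")
  out
}

# Fill cavities: background components not touching the array border.
fill_holes <- function(mask) {
  lab <- label_components(!mask)
  border <- unique(c(
    lab[1, , ], lab[dim(lab)[1], , ],
    lab[, 1, ], lab[, dim(lab)[2], ],
    lab[, , 1], lab[, , dim(lab)[3]]
  ))
  border <- border[border > 0]
  mask | (lab > 0 & !(lab %in% border))
}

# Separable Gaussian blur with sigma given in micrometres per axis.
gauss_blur <- function(arr, sigma_um, spacing) {
  sig_vox <- sigma_um / spacing
  array(cpp_gauss_blur3d(as.numeric(arr), dim(arr), sig_vox), dim(arr))
}

# Otsu threshold of a numeric vector (256 bins between min and max).
otsu_threshold <- function(values, n_bins = 256L) {
  values <- values[is.finite(values)]
  rng <- range(values)
  if (diff(rng) <= 0) return(rng[1])
  h <- tabulate(
    pmin(n_bins, 1L + floor((values - rng[1]) / diff(rng) * n_bins)),
    nbins = n_bins
  )
  p <- h / sum(h)
  omega <- cumsum(p)
  mids <- rng[1] + (seq_len(n_bins) - 0.5) / n_bins * diff(rng)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  mids[which.max(sigma_b)]
}

# Half-of-peak threshold: Otsu isolates the foreground, then the
# threshold is half the foreground's 90th-percentile brightness. For a
# blurred step edge this places the boundary at the true edge (half-max
# criterion); for a blurred ridge it tracks the half-height width.
# Scale-invariant like plain Otsu, but far less sensitive to the
# foreground/background volume imbalance of thin shells.
half_peak_threshold <- function(values) {
  t1 <- otsu_threshold(values)
  fg <- values[values > t1]
  if (!length(fg)) return(t1)
  max(t1 * 0.5, 0.5 * stats::quantile(fg, 0.9, names = FALSE))
}

# voxel (z,y,x) 1-based indices of TRUE voxels, as an n x 3 matrix
which_voxels <- function(mask) {
  idx <- which(mask)
  arrayInd(idx, dim(mask))
}
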