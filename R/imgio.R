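#' Write a multi-channel 3D stack to TIFF
#'
#' Pages are written channel-major (all z planes of the first channel,
#' then the second, ...) as 32-bit float. Because baseline TIFF floats
#' are stored in `[0, 1]`, every channel is divided by a power-of-two
#' scale (exact in binary floating point) that is recorded, together
#' with the voxel size, channel roles and identifiers, in a JSON sidecar
#' `<path>.json`. [read_stack()] restores the original values; the
#' round trip is exact at 32-bit float precision.
#'
#' @param stack a [cell_stack()].
#' @param path output TIFF path; the sidecar is written next to it.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "cell_stack"))
  roles <- names(stack$channels)
  d <- dim(stack$channels[[1]]$data)
  scales <- numeric(length(roles))
  pages <- list()
  for (i in seq_along(roles)) {
    arr <- stack$channels[[roles[i]]]$data
    mx <- max(arr)
    scales[i] <- if (mx <= 1) 1 else 2^ceiling(log2(mx))
    sc <- arr / scales[i]
    for (z in seq_len(d[1])) {
      # page = (y, x) matrix of plane z
      pages[[length(pages) + 1L]] <- matrix(sc[z, , ], nrow = d[2], ncol = d[3])
    }
  }
  ok <- tryCatch(
    tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none"),
    error = function(e) stop("cannot write TIFF at ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  meta <- list(
    format = "laminatlas-stack",
    version = 1L,
    shape_zyx = as.integer(d),
    voxel_size_um = stack$channels[[1]]$voxel_size,
    channels = roles,
    channel_scales = scales,
    cell_id = stack$cell_id,
    experiment_id = stack$experiment_id
  )
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

sidecar_path <- function(path) paste0(path, ".json")

# Minimal OME-XML metadata scrape: physical sizes and channel names.
parse_ome_description <- function(desc) {
  if (is.null(desc) || !any(grepl("PhysicalSize", desc))) return(NULL)
  desc <- paste(desc, collapse = "")
  grab <- function(attr) {
    m <- regmatches(desc, regexpr(sprintf('%s="[0-9.eE+-]+"', attr), desc))
    if (!length(m)) return(NA_real_)
    as.numeric(sub('.*="([0-9.eE+-]+)"', "\\1", m))
  }
  vs <- c(grab("PhysicalSizeZ"), grab("PhysicalSizeY"), grab("PhysicalSizeX"))
  nc <- regmatches(desc, gregexpr('Channel[^>]*Name="([^"]*)"', desc))[[1]]
  ch <- if (length(nc)) sub('.*Name="([^"]*)".*', "\\1", nc) else NULL
  sz <- grab("SizeZ")
  list(voxel_size = vs, channels = ch, size_z = sz)
}

#' Read a multi-channel 3D stack from TIFF
#'
#' Accepts stacks written by [write_stack()] (JSON sidecar metadata),
#' OME-TIFFs carrying `PhysicalSize*` attributes in their ImageDescription,
#' and plain TIFFs when `voxel_size_override` and `channel_roles` supply
#' the missing metadata. Pages must be ordered channel-major in z.
#'
#' @param path TIFF file path.
#' @param voxel_size_override optional `(dz, dy, dx)` in micrometres;
#'   takes precedence only when the file metadata carries no voxel size.
#' @param channel_roles optional character vector naming the channels in
#'   page order (required for plain TIFFs without a sidecar).
#' @return a [cell_stack()].
#' @export
read_stack <- function(path, voxel_size_override = NULL, channel_roles = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)

  meta <- NULL
  if (file.exists(sidecar_path(path))) {
    meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
    if (!identical(meta$format, "laminatlas-stack")) meta <- NULL
  }
  ome <- parse_ome_description(attr(pages[[1]], "description"))

  if (!is.null(meta)) {
    roles <- meta$channels
    vs <- as.numeric(meta$voxel_size_um)
    nz <- meta$shape_zyx[1]
    scales <- meta$channel_scales
    cell_id <- meta$cell_id
    experiment_id <- meta$experiment_id
  } else {
    roles <- if (!is.null(channel_roles)) channel_roles else ome$channels
    if (is.null(roles))
      stop("cannot map channels: no sidecar/OME metadata and no `channel_roles`",
           call. = FALSE)
    vs <- if (!is.null(ome) && all(is.finite(ome$voxel_size))) ome$voxel_size
          else as.numeric(voxel_size_override)
    if (is.null(vs) || length(vs) != 3L || any(!is.finite(vs)))
      stop("no voxel size in metadata and no `voxel_size_override` given",
           call. = FALSE)
    if (length(pages) %% length(roles) != 0L)
      stop("page count ", length(pages), " is not a multiple of ",
           length(roles), " channels", call. = FALSE)
    nz <- length(pages) %/% length(roles)
    scales <- rep(1, length(roles))
    cell_id <- sub("\\.[^.]*$", "", basename(path))
    experiment_id <- "unknown"
  }

  known <- c("DAPI", "LAMIN", "TELO", "MASK")
  if (!all(roles %in% known))
    stop("unmappable channel roles: ",
         paste(setdiff(roles, known), collapse = ", "), call. = FALSE)

  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  channels <- list()
  for (i in seq_along(roles)) {
    arr <- array(0, c(nz, ny, nx))
    for (z in seq_len(nz)) arr[z, , ] <- pages[[(i - 1L) * nz + z]]
    arr <- arr * scales[i]
    if (roles[i] == "MASK") arr <- round(arr)
    channels[[roles[i]]] <- voxel_grid(arr, vs, roles[i])
  }
  cell_stack(channels, cell_id = cell_id, experiment_id = experiment_id)
}
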