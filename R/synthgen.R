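#' Pattern taxonomy labels
#'
#' The nine cell classes used throughout: mononuclear Hodgkin (H) cells
#' graded 0/A/B/C/D by their internal lamin compartmentalization, and
#' Reed-Sternberg (RS) cells graded by nuclear lobe count
#' (bi/tri/tetra/multi-nuclear).
#'
#' @return character vector of the nine labels in canonical order.
#' @export
pattern_labels <- function() {
  c("H0", "HA", "HB", "HC", "HD", "RS2", "RS3", "RS4", "RSmulti")
}

#' Observed pattern frequencies in the HDLM-2 cell line
#'
#' Published frequencies of the lamin A/C 3D patterns among 90 H and 90
#' RS cells (three experiments of 30 cells each), renormalized to sum to
#' one within each family. Used as the default sampling weights of
#' [sample_population()].
#'
#' @param family `"H"` or `"RS"`.
#' @return named numeric vector of probabilities.
#' @export
hodgkin_pattern_freqs <- function(family = c("H", "RS")) {
  family <- match.arg(family)
  f <- switch(family,
    H  = c(H0 = 0.1548, HA = 0.2915, HB = 0.4216, HC = 0.1163, HD = 0.0159),
    RS = c(RS2 = 0.5766, RS3 = 0.2227, RS4 = 0.1029, RSmulti = 0.0979)
  )
  f / sum(f)
}

pattern_geometry <- function(pattern) {
  switch(pattern,
    H0 = list(n_lobes = 1L, n_compartments = 1L),
    HA = list(n_lobes = 1L, n_compartments = 1L),
    HB = list(n_lobes = 1L, n_compartments = 2L),
    HC = list(n_lobes = 1L, n_compartments = 3L),
    HD = list(n_lobes = 1L, n_compartments = 4L),
    RS2 = list(n_lobes = 2L, n_compartments = 2L),
    RS3 = list(n_lobes = 3L, n_compartments = 3L),
    RS4 = list(n_lobes = 4L, n_compartments = 4L),
    RSmulti = list(n_lobes = 5L, n_compartments = 5L),
    stop("unknown pattern: ", pattern, call. = FALSE)
  )
}

#' Specify a synthetic cell
#'
#' Parameter bundle consumed by [render_cell()]. Defaults emulate the
#' acquisition geometry of deconvolved widefield z-stacks (200 nm axial
#' step, ~100 nm lateral sampling) and nuclei a few micrometres in
#' radius; brightness units are arbitrary, as fluorescence intensity is
#' uncalibrated.
#'
#' @param pattern one of [pattern_labels()]. Fixes `n_lobes` and the
#'   ground-truth compartment count.
#' @param n_lobes number of nuclear lobes; defaults from `pattern`
#'   (RSmulti: 5).
#' @param semi_axes lobe ellipsoid semi-axes `(z, y, x)` in um. The
#'   default scales with pattern complexity (HC 1.15x, HD 1.3x the base
#'   `(2.0, 2.6, 2.6)`): nuclei carrying three or four lamin-bounded
#'   compartments are the largest cells in these samples, and the extra
#'   volume is what makes four optically-resolvable compartments
#'   geometrically possible at all.
#' @param shell_thickness,septum_thickness laminar shell / septum
#'   thickness in um.
#' @param shell_brightness,septum_brightness shell intensity (a.u.) and
#'   septum intensity relative to the shell.
#' @param n_accumulation_points,accumulation_brightness count of
#'   localized lamin accumulation blobs and their brightness multiple of
#'   the shell.
#' @param n_internal_fragments short internal lamin structures that do
#'   not subdivide the nucleus (the A-pattern phenotype).
#' @param fragment_radius_um radius of the clipping ball bounding each
#'   internal fragment (um).
#' @param target_ratio optional ground-truth external/internal intensity
#'   ratio; when set, internal structure brightness is calibrated so the
#'   noiseless integrals satisfy it exactly.
#' @param n_telomeres,coloc_fraction,aggregate_fraction telomere spot
#'   count, target fraction overlapping internal lamin, and fraction
#'   placed as sub-resolution doublets.
#' @param spot_clearance_um distance non-co-localized telomere spots
#'   keep from any lamin structure (shell or internal), so their binary
#'   gate is unambiguously 0; relaxed stepwise when the nucleus
#'   geometry cannot honour it.
#' @param min_spot_separation_um minimum lateral-equivalent distance
#'   between distinct spot centres (axial distances are scaled by the
#'   lateral-to-axial PSF sigma ratio, since axial resolution is
#'   poorer); individual telomeres are placed resolvably apart, only
#'   aggregate clusters sit below resolution.
#' @param free_space_radii two-component mixture of cavity radii (um):
#'   list with `means`, `sds`, `weights`.
#' @param n_cavities number of DNA-free cavities per lobe.
#' @param dapi_brightness,telo_brightness channel brightness (a.u.).
#' @param psf_sigma anisotropic Gaussian PSF sigma `(z, y, x)` um.
#' @param noise list with `poisson_scale` (photons per intensity unit; 0
#'   disables shot noise) and `gaussian_sd` (read noise, a.u.).
#' @param voxel_size `(dz, dy, dx)` um; default `(0.2, 0.1, 0.1)`.
#' @param margin_um padding between nucleus and stack border.
#' @param truth_shell_depth_um,truth_axial_scale the external/internal
#'   depth convention the ground-truth intensity integrals adopt
#'   (defaults match [decompose_lamin()]): lamin material within
#'   `truth_shell_depth_um` of the nuclear surface (z-distance scaled
#'   by `truth_axial_scale`) counts as external shell, deeper material
#'   as internal. There is no canonical boundary between "external"
#'   and "internal" lamin, so truth and analysis must share one
#'   declared convention for intensity recovery to be well-posed.
#' @return an object of class `cell_spec`.
#' @export
cell_spec <- function(pattern = "H0",
                      n_lobes = NULL,
                      semi_axes = NULL,
                      shell_thickness = 0.3,
                      septum_thickness = 0.3,
                      shell_brightness = 100,
                      septum_brightness = 1.0,
                      n_accumulation_points = 2L,
                      accumulation_brightness = 2.0,
                      n_internal_fragments = if (pattern == "HA") 3L else 0L,
                      fragment_radius_um = 0.9,
                      target_ratio = NULL,
                      n_telomeres = 30L,
                      coloc_fraction = 0.33,
                      aggregate_fraction = 0.1,
                      min_spot_separation_um = 0.6,
                      spot_clearance_um = 0.8,
                      free_space_radii = list(means = c(0.25, 0.55),
                                              sds = c(0.05, 0.08),
                                              weights = c(0.5, 0.5)),
                      n_cavities = 25L,
                      dapi_brightness = 80,
                      telo_brightness = 800,
                      psf_sigma = c(0.25, 0.12, 0.12),
                      noise = list(poisson_scale = 1, gaussian_sd = 2),
                      voxel_size = c(0.2, 0.1, 0.1),
                      margin_um = 0.8,
                      truth_shell_depth_um = 0.55,
                      truth_axial_scale = 0.85) {
  pattern <- match.arg(pattern, pattern_labels())
  if (is.null(semi_axes))
    semi_axes <- c(2.0, 2.6, 2.6) *
      switch(pattern, HC = 1.15, HD = 1.3, 1)
  geo <- pattern_geometry(pattern)
  if (is.null(n_lobes)) n_lobes <- geo$n_lobes
  if (startsWith(pattern, "H") && n_lobes != 1L)
    stop("H patterns are mononuclear (n_lobes must be 1)", call. = FALSE)
  if (pattern %in% c("RS2", "RS3", "RS4") && n_lobes != geo$n_lobes)
    stop(pattern, " requires n_lobes = ", geo$n_lobes, call. = FALSE)
  if (pattern == "RSmulti" && n_lobes < 5L)
    stop("RSmulti requires n_lobes >= 5", call. = FALSE)
  n_compartments <- if (startsWith(pattern, "H")) geo$n_compartments else n_lobes
  stopifnot(
    all(semi_axes > 0), shell_thickness > 0, septum_thickness > 0,
    coloc_fraction >= 0, coloc_fraction <= 1,
    aggregate_fraction >= 0, aggregate_fraction <= 1,
    n_telomeres >= 0
  )
  structure(
    list(
      pattern = pattern, n_lobes = as.integer(n_lobes),
      n_compartments = as.integer(n_compartments),
      semi_axes = semi_axes, shell_thickness = shell_thickness,
      septum_thickness = septum_thickness,
      shell_brightness = shell_brightness,
      septum_brightness = septum_brightness,
      n_accumulation_points = as.integer(n_accumulation_points),
      accumulation_brightness = accumulation_brightness,
      n_internal_fragments = as.integer(n_internal_fragments),
      fragment_radius_um = fragment_radius_um,
      target_ratio = target_ratio,
      n_telomeres = as.integer(n_telomeres),
      coloc_fraction = coloc_fraction,
      aggregate_fraction = aggregate_fraction,
      min_spot_separation_um = min_spot_separation_um,
      spot_clearance_um = spot_clearance_um,
      free_space_radii = free_space_radii,
      n_cavities = as.integer(n_cavities),
      dapi_brightness = dapi_brightness,
      telo_brightness = telo_brightness,
      psf_sigma = psf_sigma, noise = noise,
      voxel_size = voxel_size, margin_um = margin_um,
      truth_shell_depth_um = truth_shell_depth_um,
      truth_axial_scale = truth_axial_scale
    ),
    class = "cell_spec"
  )
}

# Evaluate an RNG-using expression under a fixed seed, restoring the
# caller's RNG state afterwards.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  force(code)
}

derive_seed <- function(seed, index) {
  (as.numeric(seed) * 48271 + as.numeric(index) * 1299709) %% 2147483629
}

# mask of the ellipsoid (semi in um, centre in um) on the grid coords
ellipsoid_field <- function(coords, centre, semi) {
  nz <- length(coords$z); ny <- length(coords$y); nx <- length(coords$x)
  a <- ((coords$z - centre[1]) / semi[1])^2
  b <- ((coords$y - centre[2]) / semi[2])^2
  c_ <- ((coords$x - centre[3]) / semi[3])^2
  array(rep(a, times = ny * nx), c(nz, ny, nx)) +
    array(rep(rep(b, each = nz), times = nx), c(nz, ny, nx)) +
    array(rep(c_, each = nz * ny), c(nz, ny, nx))
}

# signed coordinate along a unit normal, relative to centre
plane_coord <- function(coords, centre, normal) {
  nz <- length(coords$z); ny <- length(coords$y); nx <- length(coords$x)
  array(rep((coords$z - centre[1]) * normal[1], times = ny * nx), c(nz, ny, nx)) +
    array(rep(rep((coords$y - centre[2]) * normal[2], each = nz), times = nx),
          c(nz, ny, nx)) +
    array(rep((coords$x - centre[3]) * normal[3], each = nz * ny), c(nz, ny, nx))
}

runif_sphere <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

#' Render a synthetic cell with ground truth
#'
#' Builds the pre-blur geometry (nucleus lobes, laminar shell, internal
#' septa/fragments/accumulation points, DNA with DNA-free cavities,
#' telomere spots), records it as ground truth, then renders the three
#' fluorescence channels: intensity assignment, anisotropic Gaussian PSF
#' blur, Poisson shot noise and Gaussian read noise. Identical
#' `(spec, seed)` give bit-identical output.
#'
#' @param spec a [cell_spec()].
#' @param seed integer seed.
#' @return list with elements `stack` (a [cell_stack()]) and `truth`
#'   (class `synth_truth`: masks, telomere table, noiseless intensity
#'   integrals `true_Ie`/`true_Ii`, realized co-localization fraction,
#'   the spec and the seed).
#' @export
render_cell <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "cell_spec"))
  with_local_seed(seed, render_cell_impl(spec, seed))
}

render_cell_impl <- function(spec, seed) {
  vs <- spec$voxel_size
  semi <- spec$semi_axes
  k <- spec$n_lobes

  # lobe layout: chain along x, tangent-with-slight-overlap so the
  # voxelized union is connected; per-lobe size jitter for realism
  scales <- if (k == 1L) 1 else stats::runif(k, 0.85, 1.05)
  semis <- lapply(scales, function(s) semi * s)
  xs <- numeric(k)
  if (k > 1L) {
    for (i in 2:k)
      xs[i] <- xs[i - 1] + 0.97 * (semis[[i - 1]][3] + semis[[i]][3])
  }
  span_x <- (xs[k] + semis[[k]][3]) - (xs[1] - semis[[1]][3])
  max_sz <- max(vapply(semis, `[`, 0, 1))
  max_sy <- max(vapply(semis, `[`, 0, 2))
  m <- spec$margin_um
  nz <- ceiling((2 * (max_sz + m)) / vs[1])
  ny <- ceiling((2 * (max_sy + m)) / vs[2])
  nx <- ceiling((span_x + 2 * m) / vs[3])
  dims <- c(nz, ny, nx)
  coords <- list(
    z = (seq_len(nz) - 1) * vs[1],
    y = (seq_len(ny) - 1) * vs[2],
    x = (seq_len(nx) - 1) * vs[3]
  )
  cz <- (nz - 1) * vs[1] / 2
  cy <- (ny - 1) * vs[2] / 2
  x0 <- m + semis[[1]][3]
  centres <- lapply(seq_len(k), function(i) c(cz, cy, x0 + xs[i]))

  # nucleus, lobes, shell, interior
  lobe_fields <- lapply(seq_len(k), function(i)
    ellipsoid_field(coords, centres[[i]], semis[[i]]))
  lobe_masks <- lapply(lobe_fields, function(f) f <= 1)
  inner_masks <- lapply(seq_len(k), function(i)
    ellipsoid_field(coords, centres[[i]],
                    pmax(semis[[i]] - spec$shell_thickness, 0.2)) <= 1)
  nucleus <- Reduce(`|`, lobe_masks)
  interior <- Reduce(`|`, inner_masks)
  annulus <- nucleus & !interior   # all laminar shell material

  lobe_labels <- array(0L, dims)
  best <- array(Inf, dims)
  for (i in seq_len(k)) {
    better <- lobe_masks[[i]] & (lobe_fields[[i]] < best)
    lobe_labels[better] <- i
    best[better] <- lobe_fields[[i]][better]
  }

  # septa: parallel slabs along one random normal per lobe needing them
  septa <- array(FALSE, dims)
  n_septa <- if (startsWith(spec$pattern, "H")) spec$n_compartments - 1L else 0L
  if (n_septa > 0L) {
    normal <- runif_sphere()
    pc <- plane_coord(coords, centres[[1]], normal)
    r_n <- 1 / sqrt(sum((normal / semis[[1]])^2))  # lobe semi-extent along normal
    offs <- (seq_len(n_septa) / (n_septa + 1) * 2 - 1) * 0.8 * r_n
    offs <- offs + stats::runif(n_septa, -0.04, 0.04) * r_n
    for (o in offs)
      septa <- septa | (abs(pc - o) <= spec$septum_thickness / 2)
    septa <- septa & interior
  }

  # short internal fragments (HA): slabs clipped to a small ball, so
  # they never separate the interior
  fragments <- array(FALSE, dims)
  if (spec$n_internal_fragments > 0L) {
    for (j in seq_len(spec$n_internal_fragments)) {
      u <- runif_sphere() * stats::runif(1, 0, 0.55)
      p <- centres[[1]] + u * semis[[1]]
      nrm <- runif_sphere()
      pc <- plane_coord(coords, p, nrm)
      ball <- ellipsoid_field(coords, p, rep(spec$fragment_radius_um, 3)) <= 1
      fragments <- fragments |
        (abs(pc) <= spec$septum_thickness / 2 & ball & interior)
    }
    fragments <- fragments & !septa
  }

  # localized accumulation points just inside the shell
  accum <- array(FALSE, dims)
  if (spec$n_accumulation_points > 0L) {
    for (j in seq_len(spec$n_accumulation_points)) {
      li <- sample.int(k, 1)
      u <- runif_sphere() * 0.72
      p <- centres[[li]] + u * semis[[li]]
      accum <- accum | (ellipsoid_field(coords, p, rep(0.18, 3)) <= 1)
    }
    accum <- accum & interior & !septa
  }

  # split all laminar material into external shell vs internal by the
  # declared depth convention: within truth_shell_depth_um of the
  # nuclear surface (axial distance scaled) it is shell, deeper it is
  # internal. Septum rims inside the band therefore count as shell,
  # and the walls between fused lobes of multinucleated cells are
  # internal, consistently with how the analysis reads a stack.
  eff_depth <- dist_to_background(nucleus, vs * c(spec$truth_axial_scale, 1, 1))
  band <- eff_depth <= spec$truth_shell_depth_um
  laminal <- annulus | septa | fragments | accum
  outer_shell <- laminal & band
  internal <- laminal & !band

  # ground-truth compartments: interior split by septa / contact walls
  comp_src <- interior & !septa
  compartment_labels <- label_components(comp_src)
  n_comp_found <- attr(compartment_labels, "n_labels")
  # voxelization slivers: drop components below 1% of the interior
  if (n_comp_found > spec$n_compartments) {
    tab <- tabulate(compartment_labels[compartment_labels > 0], n_comp_found)
    keep <- which(tab >= 0.01 * sum(interior))
    relab <- integer(n_comp_found)
    relab[keep] <- seq_along(keep)
    compartment_labels <- array(
      ifelse(compartment_labels > 0, relab[pmax(compartment_labels, 1)], 0L), dims)
    n_comp_found <- length(keep)
  }
  if (n_comp_found != spec$n_compartments)
    stop("septum geometry realized ", n_comp_found, " compartments, not ",
         spec$n_compartments, " (semi-axes too small for the requested count?)",
         call. = FALSE)

  # DNA-free cavities and DNA mask
  cavities <- array(FALSE, dims)
  fsr <- spec$free_space_radii
  int_idx <- which(interior & !septa)
  if (spec$n_cavities > 0L && length(int_idx)) {
    n_cav <- spec$n_cavities * k
    comp_pick <- sample.int(2L, n_cav, replace = TRUE, prob = fsr$weights)
    radii <- pmax(stats::rnorm(n_cav, fsr$means[comp_pick], fsr$sds[comp_pick]),
                  0.08)
    ctr_idx <- sample(int_idx, n_cav, replace = TRUE)
    pos <- arrayInd(ctr_idx, dims)
    for (j in seq_len(n_cav)) {
      p <- c((pos[j, 1] - 1) * vs[1], (pos[j, 2] - 1) * vs[2],
             (pos[j, 3] - 1) * vs[3])
      cavities <- cavities | (ellipsoid_field(coords, p, rep(radii[j], 3)) <= 1)
    }
    cavities <- cavities & interior & !septa
  }
  dna_mask <- interior & !septa & !cavities
  free_space <- interior & cavities

  # telomere spots with per-spot co-localization / aggregate flags
  n_t <- spec$n_telomeres
  telo <- tibble::tibble(
    z = numeric(0), y = numeric(0), x = numeric(0),
    coloc = logical(0), aggregate = logical(0)
  )
  if (n_t > 0L) {
    coloc_flag <- stats::runif(n_t) < spec$coloc_fraction
    agg_flag <- stats::runif(n_t) < spec$aggregate_fraction
    # co-localized spots sit on internal lamin well below the shell
    # junction (where shell/internal attribution is unambiguous);
    # non-overlapping spots keep a clearance from any lamin so their
    # detected regions cannot graze blur-widened structures. Both
    # constraints are relaxed stepwise when the eligible region is too
    # small to hold the requested spots at the minimum separation
    # (~0.7 um^3 of eligible volume per spot).
    depth_true <- dist_to_background(nucleus, vs)
    deep_int <- internal & (depth_true > 1.1)
    if (!any(deep_int)) deep_int <- internal
    near_int <- dilate_ball(deep_int, 0.15, vs) & nucleus
    away <- array(FALSE, dims)
    for (clr in c(spec$spot_clearance_um, 0.6 * spec$spot_clearance_um, 0.3)) {
      away <- interior & !dilate_ball(internal | annulus, clr, vs)
      if (any(away)) break
    }
    if (!any(away)) away <- interior & !internal
    near_idx <- which(near_int)
    away_idx <- which(away)
    if (!length(near_idx)) coloc_flag[] <- FALSE
    pts <- matrix(0, n_t, 3)
    min_sep2 <- spec$min_spot_separation_um^2
    # separations measured in lateral-equivalent units: the axial PSF is
    # wider, so spots need proportionally more z-distance to resolve
    sep_scale <- c(min(spec$psf_sigma) / spec$psf_sigma[1], 1, 1)
    for (j in seq_len(n_t)) {
      src <- if (coloc_flag[j]) near_idx else away_idx
      best <- NULL
      best_d2 <- -Inf
      for (try in 1:80) {
        ii <- src[sample.int(length(src), 1)]
        p <- arrayInd(ii, dims)
        cand <- (p - 1) * vs + stats::runif(3, -0.5, 0.5) * vs
        if (j == 1L) { best <- cand; break }
        d2 <- min(colSums(((t(pts[seq_len(j - 1L), , drop = FALSE]) - c(cand)) *
                             sep_scale)^2))
        if (d2 > best_d2) { best_d2 <- d2; best <- cand }
        if (d2 >= min_sep2) break
      }
      pts[j, ] <- best
    }
    telo <- tibble::tibble(
      z = pts[, 1], y = pts[, 2], x = pts[, 3],
      coloc = coloc_flag, aggregate = agg_flag
    )
  }

  # ---- render ----
  bright <- array(0, dims)
  bright[annulus] <- spec$shell_brightness
  sb <- spec$septum_brightness * spec$shell_brightness
  bright[septa | fragments] <- sb
  bright[accum] <- spec$accumulation_brightness * spec$shell_brightness

  if (!is.null(spec$target_ratio)) {
    # rescale internal-structure brightness uniformly (rim included,
    # so each septum stays uniformly bright) to hit the target exactly:
    # target = (A + r B) / (r C) with A the pure-shell intensity, B the
    # structure intensity inside the shell band, C the structure
    # intensity below it.
    structures <- septa | fragments | accum
    A <- sum(bright[outer_shell & !structures])
    B <- sum(bright[outer_shell & structures])
    C <- sum(bright[internal])
    r_adj <- A / (spec$target_ratio * C - B)
    if (!is.finite(r_adj) || r_adj <= 0)
      stop("target_ratio ", spec$target_ratio,
           " is infeasible for this geometry", call. = FALSE)
    bright[structures] <- bright[structures] * r_adj
  }
  true_Ie <- sum(bright[outer_shell])
  true_Ii <- sum(bright[internal])

  lamin_clean <- bright
  lamin <- gauss_blur(bright, spec$psf_sigma, vs)
  dapi <- gauss_blur(spec$dapi_brightness * dna_mask, spec$psf_sigma, vs)

  telo_arr <- array(0, dims)
  if (nrow(telo)) {
    for (j in seq_len(nrow(telo))) {
      vpos <- pmin(pmax(round(c(telo$z[j], telo$y[j], telo$x[j]) / vs) + 1, 1),
                   dims)
      amp <- spec$telo_brightness
      if (telo$aggregate[j]) {
        # sub-resolution cluster: two extra telomeres within ~0.3 um
        for (extra in 1:2) {
          off <- runif_sphere() * stats::runif(1, 0.15, 0.3)
          v2 <- pmin(pmax(round((c(telo$z[j], telo$y[j], telo$x[j]) + off) / vs) + 1, 1),
                     dims)
          telo_arr[v2[1], v2[2], v2[3]] <- telo_arr[v2[1], v2[2], v2[3]] + amp
        }
      }
      telo_arr[vpos[1], vpos[2], vpos[3]] <- telo_arr[vpos[1], vpos[2], vpos[3]] + amp
    }
    telo_arr <- gauss_blur(telo_arr, sqrt(spec$psf_sigma^2 + 0.08^2), vs)
  }

  add_noise <- function(arr) {
    ps <- spec$noise$poisson_scale
    gs <- spec$noise$gaussian_sd
    out <- arr
    if (!is.null(ps) && ps > 0)
      out <- array(stats::rpois(length(out), out * ps) / ps, dims)
    if (!is.null(gs) && gs > 0)
      out <- out + array(stats::rnorm(length(out), 0, gs), dims)
    out[out < 0] <- 0
    out
  }
  lamin <- add_noise(lamin)
  dapi <- add_noise(dapi)
  telo_arr <- add_noise(telo_arr)

  channels <- list(
    DAPI = voxel_grid(dapi, vs, "DAPI"),
    LAMIN = voxel_grid(lamin, vs, "LAMIN"),
    TELO = voxel_grid(telo_arr, vs, "TELO")
  )
  stack <- cell_stack(channels,
                      cell_id = sprintf("%s_seed%d", spec$pattern, as.integer(seed)))

  mask_grid <- function(m) voxel_grid(array(as.numeric(m), dims), vs, "MASK")
  truth <- structure(list(
    nucleus_mask = mask_grid(nucleus),
    lobe_labels = mask_grid(lobe_labels),
    shell_mask = mask_grid(outer_shell),
    internal_mask = mask_grid(internal),
    compartment_labels = mask_grid(compartment_labels),
    dna_mask = mask_grid(dna_mask),
    free_space_mask = mask_grid(free_space),
    telomere_centres = telo,
    realized_coloc_fraction = if (nrow(telo)) mean(telo$coloc) else NA_real_,
    true_Ie = true_Ie,
    true_Ii = true_Ii,
    lamin_clean = lamin_clean,
    spec = spec,
    seed = as.integer(seed)
  ), class = "synth_truth")

  list(stack = stack, truth = truth)
}

#' @export
print.synth_truth <- function(x, ...) {
  cat(sprintf(
    "<synth_truth %s> lobes %d, compartments %d, %d telomeres (coloc %.2f), Ie/Ii %s\n",
    x$spec$pattern, x$spec$n_lobes, x$spec$n_compartments,
    nrow(x$telomere_centres),
    ifelse(is.na(x$realized_coloc_fraction), NA, x$realized_coloc_fraction),
    ifelse(x$true_Ii > 0, sprintf("%.2f", x$true_Ie / x$true_Ii), "undefined")
  ))
  invisible(x)
}

#' Sample a synthetic cell population
#'
#' Draws pattern labels i.i.d. from `pattern_freqs` with a seeded
#' generator and renders one cell per draw; per-cell seeds are derived
#' deterministically from `(seed, index)`, so populations are
#' reproducible and individual cells can be re-rendered in isolation.
#'
#' @param pattern_freqs named probabilities over [pattern_labels()]
#'   entries (must sum to 1).
#' @param n_cells number of cells.
#' @param base_spec named list of [cell_spec()] argument overrides
#'   applied to every cell.
#' @param seed master seed.
#' @param experiment_ids optional vector of experiment labels recycled
#'   over cells (default: three equal experiments).
#' @param render if `FALSE`, skip rendering and return only the sampled
#'   design table (fast; for frequency checks at large n).
#' @return a tibble with columns `cell_id`, `experiment_id`, `pattern`,
#'   `seed` and (when `render = TRUE`) list-columns `stack`, `truth`.
#' @export
sample_population <- function(pattern_freqs, n_cells, base_spec = list(),
                              seed = 1L, experiment_ids = NULL,
                              render = TRUE) {
  if (!length(pattern_freqs)) stop("empty frequency map", call. = FALSE)
  if (any(pattern_freqs < 0) || abs(sum(pattern_freqs) - 1) > 1e-9)
    stop("frequencies must be non-negative and sum to 1", call. = FALSE)
  labs <- names(pattern_freqs)
  if (!all(labs %in% pattern_labels()))
    stop("unknown pattern labels: ",
         paste(setdiff(labs, pattern_labels()), collapse = ", "), call. = FALSE)
  patterns <- with_local_seed(seed,
    sample(labs, n_cells, replace = TRUE, prob = pattern_freqs))
  if (is.null(experiment_ids))
    experiment_ids <- paste0("exp_", rep_len(1:3, n_cells))
  else experiment_ids <- rep_len(experiment_ids, n_cells)
  seeds <- vapply(seq_len(n_cells), function(i) derive_seed(seed, i), 0)

  out <- tibble::tibble(
    cell_id = sprintf("cell_%04d", seq_len(n_cells)),
    experiment_id = experiment_ids,
    pattern = patterns,
    seed = seeds
  )
  if (!render) return(out)
  rendered <- purrr::map(seq_len(n_cells), function(i) {
    sp <- do.call(cell_spec, c(list(pattern = patterns[i]), base_spec))
    rc <- render_cell(sp, seeds[i])
    rc$stack$cell_id <- out$cell_id[i]
    rc$stack$experiment_id <- out$experiment_id[i]
    rc
  })
  out$stack <- purrr::map(rendered, "stack")
  out$truth <- purrr::map(rendered, "truth")
  out
}
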