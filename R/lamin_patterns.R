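#' Classify a cell into the lamin A/C pattern taxonomy
#'
#' Mononuclear (H) cells are graded by how their internal lamin
#' structures subdivide the nucleus: one compartment with negligible
#' internal lamin is pattern 0; one compartment but an internal lamin
#' burden at or above `burden_threshold` (short structures that do not
#' yet separate the interior) is pattern A; two, three and four-or-more
#' compartments are patterns B, C and D. Multi-lobed (RS) cells are
#' graded purely by lobe count: bi-, tri-, tetra-nuclear and
#' multi-nuclear (five or more lobes); their compartment structure is
#' recorded but does not affect the label.
#'
#' @param n_lobes,n_compartments integers >= 1.
#' @param internal_burden internal lamin volume / nuclear volume.
#' @param burden_threshold burden separating H0 from HA (default 1%).
#' @return one of [pattern_labels()].
#' @examples
#' classify_pattern(1, 2, 0.05)  # "HB"
#' classify_pattern(3, 3, 0.1)   # "RS3"
#' @export
classify_pattern <- function(n_lobes, n_compartments, internal_burden,
                             burden_threshold = 0.01) {
  stopifnot(n_lobes >= 1, n_compartments >= 1,
            internal_burden >= 0, internal_burden <= 1)
  if (n_lobes >= 5) return("RSmulti")
  if (n_lobes >= 2) return(c("RS2", "RS3", "RS4")[n_lobes - 1L])
  if (n_compartments >= 4) return("HD")
  if (n_compartments == 3) return("HC")
  if (n_compartments == 2) return("HB")
  if (internal_burden >= burden_threshold) "HA" else "H0"
}

#' External / internal lamin intensity ratio
#'
#' Integrates the raw lamin channel over the shell and internal masks of
#' a decomposition: \eqn{I_e} is the total external (shell) lamin
#' intensity, \eqn{I_i} the total internal intensity, and their ratio
#' the pattern-complexity statistic. The ratio is flagged undefined when
#' the internal mask is empty. Invariant under positive rescaling of the
#' channel.
#'
#' @param lamin lamin [voxel_grid()].
#' @param decomp a `lamin_decomposition` from [decompose_lamin()].
#' @return one-row tibble with `I_e`, `I_i`, `ratio`, `ratio_defined`.
#' @export
intensity_ratio <- function(lamin, decomp) {
  stopifnot(inherits(lamin, "voxel_grid"),
            inherits(decomp, "lamin_decomposition"))
  if (!identical(dim(lamin$data), dim(decomp$shell_mask)))
    stop("lamin grid and decomposition geometry mismatch", call. = FALSE)
  I_e <- sum(lamin$data[decomp$shell_mask])
  I_i <- sum(lamin$data[decomp$internal_mask])
  defined <- I_i > 0
  tibble::tibble(
    I_e = I_e,
    I_i = I_i,
    ratio = if (defined) I_e / I_i else NA_real_,
    ratio_defined = defined
  )
}

#' Classify one measured cell end to end
#'
#' Convenience wrapper: segmentation + decomposition + classification +
#' intensity ratio for a single [cell_stack()].
#'
#' @param stack a [cell_stack()].
#' @param shell_depth_um,burden_threshold see [decompose_lamin()] and
#'   [classify_pattern()].
#' @param ... further arguments passed to [decompose_lamin()].
#' @return one-row tibble (a `PatternCall`): `cell_id`, `experiment_id`,
#'   `label`, `n_lobes`, `n_compartments`, `internal_burden`,
#'   `nuclear_volume`, `I_e`, `I_i`, `ratio`, `ratio_defined`.
#' @export
call_pattern <- function(stack, shell_depth_um = 0.55,
                         burden_threshold = 0.01, ...) {
  stopifnot(inherits(stack, "cell_stack"))
  seg <- segment_nucleus(stack$channels$DAPI, stack$channels$LAMIN)
  dec <- decompose_lamin(stack$channels$LAMIN, seg,
                         shell_depth_um = shell_depth_um, ...)
  ir <- intensity_ratio(stack$channels$LAMIN, dec)
  tibble::tibble(
    cell_id = stack$cell_id,
    experiment_id = stack$experiment_id,
    label = classify_pattern(seg$n_lobes, dec$n_compartments,
                             dec$internal_burden, burden_threshold),
    n_lobes = seg$n_lobes,
    n_compartments = dec$n_compartments,
    internal_burden = dec$internal_burden,
    nuclear_volume = seg$nuclear_volume
  ) |>
    dplyr::bind_cols(ir)
}

#' Per-pattern frequency table over experiments
#'
#' Per-label counts within each experiment, their mean and sample SD
#' over experiment replicates, and the percentage of cells carrying each
#' label. Percentages are computed within the H family and within the RS
#' family separately, so each family's percentages sum to 100.
#'
#' @param calls tibble of pattern calls (needs `label`,
#'   `experiment_id`).
#' @return a tibble of class `pattern_table`: `label`, `family`,
#'   per-experiment counts (list-col `counts`), `mean`, `sd`, `total`,
#'   `percentage`.
#' @export
pattern_table <- function(calls) {
  stopifnot(all(c("label", "experiment_id") %in% names(calls)))
  if (!nrow(calls)) stop("no pattern calls supplied", call. = FALSE)
  bad <- setdiff(unique(calls$label), pattern_labels())
  if (length(bad))
    stop("unknown pattern labels: ", paste(bad, collapse = ", "), call. = FALSE)
  exps <- sort(unique(calls$experiment_id))
  grid <- tidyr::expand_grid(label = pattern_labels(), experiment_id = exps)
  counts <- calls |>
    dplyr::count(.data$label, .data$experiment_id) |>
    dplyr::right_join(grid, by = c("label", "experiment_id")) |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L))
  out <- counts |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(
      counts = list(stats::setNames(.data$n, .data$experiment_id)),
      mean = mean(.data$n),
      sd = if (dplyr::n() > 1) stats::sd(.data$n) else 0,
      total = sum(.data$n),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      family = ifelse(startsWith(.data$label, "H"), "H", "RS"),
      label = factor(.data$label, levels = pattern_labels())
    ) |>
    dplyr::arrange(.data$label) |>
    dplyr::group_by(.data$family) |>
    dplyr::mutate(
      percentage = if (sum(.data$total) > 0)
        100 * .data$total / sum(.data$total) else NA_real_
    ) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$family %in% unique(
      ifelse(startsWith(calls$label, "H"), "H", "RS"))) |>
    dplyr::select("label", "family", "counts", "mean", "sd", "total",
                  "percentage")
  class(out) <- c("pattern_table", class(out))
  out
}

#' Per-pattern mean intensity ratio
#'
#' Mean and sample SD of the external/internal intensity ratio per
#' pattern label. Cells with undefined ratios (empty internal mask) are
#' excluded from the statistics but counted; labels with no defined
#' ratio at all are dropped with a warning rather than fabricated.
#'
#' @param calls tibble of pattern calls (needs `label`, `ratio`,
#'   `ratio_defined`).
#' @return tibble: `label`, `n`, `n_undefined`, `mean_ratio`,
#'   `sd_ratio` (0 with `n = 1`).
#' @export
ratio_summary <- function(calls) {
  stopifnot(all(c("label", "ratio", "ratio_defined") %in% names(calls)))
  dropped <- calls |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(any_def = any(.data$ratio_defined), .groups = "drop") |>
    dplyr::filter(!.data$any_def)
  if (nrow(dropped))
    warning("labels with no defined ratio omitted: ",
            paste(dropped$label, collapse = ", "), call. = FALSE)
  calls |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(
      n = sum(.data$ratio_defined),
      n_undefined = sum(!.data$ratio_defined),
      mean_ratio = if (any(.data$ratio_defined))
        mean(.data$ratio[.data$ratio_defined]) else NA_real_,
      sd_ratio = if (sum(.data$ratio_defined) > 1)
        stats::sd(.data$ratio[.data$ratio_defined]) else 0,
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n > 0) |>
    dplyr::mutate(label = factor(.data$label, levels = pattern_labels())) |>
    dplyr::arrange(.data$label)
}
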