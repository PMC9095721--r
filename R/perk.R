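#' Normalize pERK intensities to the control-group mean
#'
#' Two schemes: `"pooled_po_pt"` divides every cell by the mean intensity of
#' all control cells (PO and PT combined); `"per_region"` divides by the
#' control mean of the cell's own region.  Under either scheme the control
#' group's normalized mean is 1 by construction.
#'
#' @param pt a `perk_table` (data frame with `intensity`, `group`,
#'   `region`).
#' @param scheme normalization scheme.
#' @param control_group control group label.
#' @return `pt` with a `normalized` column.
#' @export
normalize_perk <- function(pt, scheme = c("pooled_po_pt", "per_region"),
                           control_group = "group") {
  scheme <- match.arg(scheme)
  stopifnot(all(c("intensity", "group", "region") %in% names(pt)))
  ctrl <- pt$group == control_group
  if (!any(ctrl)) stop("empty control group '", control_group, "'")
  if (scheme == "pooled_po_pt") {
    pt$normalized <- pt$intensity / mean(pt$intensity[ctrl])
  } else {
    refs <- tapply(pt$intensity[ctrl], pt$region[ctrl], mean)
    missing <- setdiff(unique(pt$region), names(refs))
    if (length(missing)) {
      stop("empty control stratum for region(s): ",
           paste(missing, collapse = ", "))
    }
    pt$normalized <- pt$intensity / as.numeric(refs[pt$region])
  }
  attr(pt, "scheme") <- scheme
  attr(pt, "control_group") <- control_group
  pt
}

#' Control-calibrated active-cell threshold
#'
#' The activity threshold is the empirical `(1 - alpha)` quantile (linear
#' interpolation convention) of the control group's normalized values, so
#' that only a fraction `alpha` (default 10%) of control cells (PO and PT
#' combined) exceed it; cells strictly above the threshold are flagged
#' active.
#'
#' @param pt a normalized `perk_table` (see [normalize_perk()]).
#' @param control_group control group label.
#' @param alpha target control active fraction (default 0.10).
#' @return `pt` with a logical `active` column; the threshold is stored in
#'   `attr(, "active_threshold")`.
#' @export
active_cell_threshold <- function(pt, control_group = "group",
                                  alpha = 0.10) {
  stopifnot("normalized" %in% names(pt), alpha >= 0, alpha < 1)
  ctrl <- pt$normalized[pt$group == control_group]
  if (length(ctrl) < 10) stop("need at least 10 control cells")
  thr <- if (alpha == 0) Inf else
    as.numeric(stats::quantile(ctrl, 1 - alpha, type = 7))
  pt$active <- pt$normalized > thr
  attr(pt, "active_threshold") <- thr
  pt
}

#' Anterior-posterior distribution of active cells
#'
#' @param pt a `perk_table` with `active` flags (see
#'   [active_cell_threshold()]).
#' @param groups groups to include (default: all).
#' @param bins strictly increasing AP bin edges, micrometres.
#' @return data frame of per-group, per-bin counts and densities of active
#'   cells; counts sum to each group's active total.
#' @export
ap_distribution <- function(pt, groups = unique(pt$group),
                            bins = seq(-100, 100, by = 20)) {
  stopifnot("active" %in% names(pt), !is.unsorted(bins, strictly = TRUE))
  out <- do.call(rbind, lapply(groups, function(g) {
    ap <- pt$ap_um[pt$group == g & pt$active]
    if (any(ap < bins[1] | ap > bins[length(bins)])) {
      stop("active cells outside the AP bin range for group '", g, "'")
    }
    cells <- cut(ap, bins, include.lowest = TRUE)
    counts <- as.integer(table(cells))
    widths <- diff(bins)
    data.frame(group = g, bin_lo = utils::head(bins, -1),
               bin_hi = bins[-1], count = counts,
               density = if (length(ap)) counts / (sum(counts) * widths)
                         else rep(0, length(counts)),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Two-stage stratified sampling of pERK cells
#'
#' Same scheme as [subsample_neurons()]: a fixed number of cells per fish
#' without replacement, then an equal number per treatment group from the
#' pooled sample, ensuring even representation across fish and groups.
#'
#' @param pt a `perk_table` with `fish_id` and `group` columns.
#' @param per_fish cells kept per fish.
#' @param per_group cells kept per group (`NULL` skips stage 2).
#' @param seed RNG seed.
#' @return the subsampled `perk_table`.
#' @export
stratified_sample <- function(pt, per_fish = 25, per_group = 200, seed = 0) {
  idx <- two_stage_sample(pt, per_fish, per_group, fish_col = "fish_id",
                          group_col = "group", seed = seed)
  out <- pt[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}
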