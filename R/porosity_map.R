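#' Compute the windowed porosity map
#'
#' Partitions the labelled volume into non-overlapping cubic windows of edge
#' `window_size_mm` (rounded to a whole number of voxels) anchored at the
#' bounding box of the colony (non-mask) voxels, and computes for every
#' window the four response variables relative to the colony voxels it
#' contains: microporosity `mip = 100 * micropore / (solid+micropore+air)`,
#' macroporosity `map` and solid volume fraction `svf` likewise, and total
#' porosity `tp = mip + map`. Windows whose colony fraction (non-mask
#' voxels over all voxels in the window) falls below `min_colony_fraction`
#' are flagged invalid and excluded from downstream statistics; edge
#' windows clipped by the bounding box are kept when they pass that filter.
#'
#' @param phases A [phase_volume()].
#' @param window_size_mm Window edge in mm (default 0.9, the sampling
#'   interval of the porosity analysis).
#' @param min_colony_fraction Validity threshold on the colony fraction.
#' @return A data.frame of class `"porosity_map"`, one row per window of
#'   the full 3D grid, with window indices `i, j, k` (0-based), center
#'   coordinates in voxels (volume frame) and mm (colony bounding-box
#'   frame), phase counts, `mip`, `map`, `tp`, `svf`, `colony_fraction`
#'   and `valid`. Attributes: `window_size_mm`, `window_vox`,
#'   `voxel_size_um`, `fragment_id`, `grid`, `bbox_origin_vox`.
#' @export
compute_porosity_map <- function(phases, window_size_mm = 0.9,
                                 min_colony_fraction = 0.05) {
  stopifnot(inherits(phases, "phase_volume"))
  lab <- phases$labels
  d <- dim(lab)
  vox_mm <- phases$voxel_size_um / 1000
  w <- round(window_size_mm / vox_mm)
  if (w < 1L) stop("window smaller than one voxel")
  colony_idx <- which(lab != .PH_MASK)
  if (!length(colony_idx)) stop("label volume contains no colony voxels")
  ai <- arrayInd(colony_idx, d)
  bb0 <- c(min(ai[, 1]), min(ai[, 2]), min(ai[, 3]))
  bb1 <- c(max(ai[, 1]), max(ai[, 2]), max(ai[, 3]))
  ng <- (bb1 - bb0) %/% w + 1L
  ## window id for every voxel inside the bounding box
  xr <- bb0[1]:bb1[1]; yr <- bb0[2]:bb1[2]; zr <- bb0[3]:bb1[3]
  sub <- lab[xr, yr, zr, drop = FALSE]
  wi <- (seq_along(xr) - 1L) %/% w
  wj <- (seq_along(yr) - 1L) %/% w
  wk <- (seq_along(zr) - 1L) %/% w
  id <- array(0L, dim(sub))
  id <- outer(outer(wi, wj * ng[1], "+"), wk * ng[1] * ng[2], "+") + 1L
  nb <- prod(ng)
  v <- as.integer(sub)
  idv <- as.integer(id)
  n_tot <- tabulate(idv, nb)
  n_mask <- tabulate(idv[v == .PH_MASK], nb)
  n_air <- tabulate(idv[v == .PH_AIR], nb)
  n_mic <- tabulate(idv[v == .PH_MICROPORE], nb)
  n_sol <- tabulate(idv[v == .PH_SOLID], nb)
  colony <- n_air + n_mic + n_sol
  g <- seq_len(nb) - 1L
  i <- as.integer(g %% ng[1])
  j <- as.integer((g %/% ng[1]) %% ng[2])
  k <- as.integer(g %/% (ng[1] * ng[2]))
  w_eff_mm <- w * vox_mm
  mip <- ifelse(colony > 0, 100 * n_mic / colony, NA_real_)
  map <- ifelse(colony > 0, 100 * n_air / colony, NA_real_)
  svf <- ifelse(colony > 0, 100 * n_sol / colony, NA_real_)
  cf <- ifelse(n_tot > 0, colony / n_tot, 0)
  out <- data.frame(
    i = i, j = j, k = k,
    cx_vox = as.integer(bb0[1] + i * w + (w - 1L) %/% 2L),
    cy_vox = as.integer(bb0[2] + j * w + (w - 1L) %/% 2L),
    cz_vox = as.integer(bb0[3] + k * w + (w - 1L) %/% 2L),
    cx_mm = (i + 0.5) * w_eff_mm,
    cy_mm = (j + 0.5) * w_eff_mm,
    cz_mm = (k + 0.5) * w_eff_mm,
    n_solid = n_sol, n_micropore = n_mic, n_air = n_air, n_mask = n_mask,
    n_total = n_tot,
    mip = mip, map = map, tp = mip + map, svf = svf,
    colony_fraction = cf,
    valid = cf >= min_colony_fraction & colony > 0L)
  if (!any(out$valid))
    stop("all windows invalid: no window reaches min_colony_fraction")
  structure(out, class = c("porosity_map", "data.frame"),
            window_size_mm = window_size_mm, window_vox = as.integer(w),
            voxel_size_um = phases$voxel_size_um,
            fragment_id = phases$fragment_id,
            grid = as.integer(ng), bbox_origin_vox = as.integer(bb0))
}

#' Fragment-level means of the response variables
#'
#' Averages the porosity-map values of a fragment into a single value per
#' variable (the representation used for inter-specific comparisons), with
#' the standard error of the mean over valid windows. Because windows hold
#' different colony volumes, `mean(tp) + mean(svf)` need not equal 100;
#' the values are deliberately not renormalized.
#'
#' @param map A `"porosity_map"`.
#' @return Data frame with columns `variable` (`mip`, `map`, `tp`, `svf`),
#'   `mean`, `sem` (`sd/sqrt(n)`; 0 when `n = 1`) and `n`.
#' @export
fragment_mean <- function(map) {
  stopifnot(inherits(map, "porosity_map"))
  ok <- map$valid
  if (!any(ok)) stop("no valid windows")
  vars <- c("mip", "map", "tp", "svf")
  n <- sum(ok)
  means <- vapply(vars, function(v) mean(map[[v]][ok]), numeric(1))
  sems <- vapply(vars, function(v) {
    if (n < 2L) 0 else sd(map[[v]][ok]) / sqrt(n)
  }, numeric(1))
  data.frame(variable = vars, mean = unname(means), sem = unname(sems),
             n = n, row.names = NULL)
}
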