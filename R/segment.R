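## ---- 3D flood fill -------------------------------------------------------
## Vectorized breadth-first flood over a logical array. The array is padded
## with a one-voxel FALSE border so plain linear-index offsets cannot wrap
## across faces. No installed package offers a 3D connected-region flood
## (EBImage's bwlabel is per-slice), so this primitive is implemented here.

neighbor_offsets <- function(pd, connectivity) {
  nx <- pd[1]; nxy <- pd[1] * pd[2]
  if (connectivity == 6L) {
    c(-1L, 1L, -nx, nx, -nxy, nxy)
  } else {
    o <- as.integer(outer(outer(c(-1L, 0L, 1L), c(-nx, 0L, nx), "+"),
                          c(-nxy, 0L, nxy), "+"))
    o[o != 0L]
  }
}

## seeds: "boundary" (all open voxels on the volume faces) or a vector of
## linear indices into the unpadded array
flood_fill_3d <- function(open, seeds = "boundary", connectivity = 6L) {
  stopifnot(is.logical(open), length(dim(open)) == 3L,
            connectivity %in% c(6L, 26L))
  d <- dim(open)
  pd <- d + 2L
  op <- array(FALSE, pd)
  op[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- open
  offs <- neighbor_offsets(pd, connectivity)
  nx <- pd[1]; nxy <- pd[1] * pd[2]
  if (identical(seeds, "boundary")) {
    idx <- array(seq_along(op), pd)
    b <- c(idx[2, , ], idx[pd[1] - 1L, , ], idx[, 2, ], idx[, pd[2] - 1L, ],
           idx[, , 2], idx[, , pd[3] - 1L])
    seeds_p <- unique(b[op[b]])
  } else {
    ai <- arrayInd(as.integer(seeds), d)
    seeds_p <- (ai[, 3]) * nxy + (ai[, 2]) * nx + ai[, 1] + 1L
    seeds_p <- seeds_p[op[seeds_p]]
  }
  vis <- logical(length(op))
  vis[seeds_p] <- TRUE
  frontier <- seeds_p
  while (length(frontier)) {
    nb <- rep(frontier, each = length(offs)) + offs
    nb <- unique(nb[op[nb] & !vis[nb]])
    vis[nb] <- TRUE
    frontier <- nb
  }
  dim(vis) <- pd
  vis[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)]
}

## ---- multi-level Otsu ----------------------------------------------------
## Two-threshold (three-class) Otsu: maximize between-class variance, i.e.
## sum_k w_k * mu_k^2, over all bin cut pairs. Fully vectorized over the
## (n_bins x n_bins) cut grid. EBImage ships only the single-threshold
## criterion, hence the in-house version.
multilevel_otsu <- function(v, n_bins = 256L) {
  v <- v[is.finite(v)]
  if (length(unique(v)) < 3L)
    stop("degenerate histogram: need >= 3 distinct intensity values for automatic thresholds")
  rng <- range(v)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  cnt <- tabulate(
    pmin(pmax(findInterval(v, breaks, all.inside = TRUE), 1L), n_bins),
    n_bins)
  w <- cnt / sum(cnt)
  m <- (breaks[-1] + breaks[-(n_bins + 1L)]) / 2
  P <- cumsum(w)
  S <- cumsum(w * m)
  ST <- S[n_bins]
  i <- seq_len(n_bins - 2L)            # last bin of class 0
  j <- seq.int(2L, n_bins - 1L)        # last bin of class 1
  term0 <- ifelse(P[i] > 0, S[i]^2 / P[i], -Inf)
  w1 <- outer(P[j], P[i], "-")         # [j, i]
  s1 <- outer(S[j], S[i], "-")
  term1 <- ifelse(w1 > 0, s1^2 / w1, -Inf)
  w2 <- 1 - P[j]
  term2 <- ifelse(w2 > 0, (ST - S[j])^2 / w2, -Inf)
  crit <- sweep(term1 + term2, 2L, term0, "+")
  crit[outer(j, i, "<=")] <- -Inf
  best <- arrayInd(which.max(crit), dim(crit))
  ti <- i[best[1, 2]]; tj <- j[best[1, 1]]
  c(t_low = breaks[ti + 1L], t_high = breaks[tj + 1L])
}

## ---- masking filter ------------------------------------------------------

#' Masking filter: exclude exterior air and non-colony structures
#'
#' Identifies the voxels that belong to the colony. Air is everything below
#' `air_threshold`; air connected to the volume boundary (by the face
#' adjacency of `connectivity`) is exterior and masked, while enclosed voids
#' remain colony voxels (candidate macropores) — including large voids, which
#' are masked only if a channel connects them to the exterior, in which case
#' they are not counted as pores. With
#' `container_policy = "components"`, non-air structures not connected to the
#' main colony body — the sample container and fragment separators — are
#' masked too: the colony is the non-air region flooded from the voxel
#' nearest the centroid of all non-air voxels, and every other non-air voxel
#' is mask.
#'
#' When `air_threshold` is `NULL` it is set to the lower cut of a
#' three-class Otsu on the whole volume. (A two-class Otsu is unreliable
#' here: on the trimodal air/micropore/solid histogram its cut can sit just
#' below the micropore level, and noise then lets the boundary flood leak
#' through surface micropores.)
#'
#' @param tom A [tomogram()].
#' @param air_threshold Intensity below which a voxel is air, or `NULL` for
#'   automatic selection.
#' @param container_policy `"components"` (default) or `"none"`.
#' @param connectivity 6 (face) or 26 (face+edge+corner) adjacency for the
#'   boundary flood; 6 is conservative against diagonal leaks through thin
#'   walls.
#' @return Logical 3D array, `TRUE` for colony voxels, with attributes
#'   `air_threshold` and `container_policy`.
#' @export
apply_mask_filter <- function(tom, air_threshold = NULL,
                              container_policy = c("components", "none"),
                              connectivity = 6L) {
  stopifnot(inherits(tom, "tomogram"))
  container_policy <- match.arg(container_policy)
  I <- tom$intensities
  if (is.null(air_threshold))
    air_threshold <- unname(multilevel_otsu(as.vector(I))[1])
  rngI <- range(I)
  if (air_threshold < rngI[1] || air_threshold > rngI[2] + 1e-12)
    cp_log("mask", tom$fragment_id, "air threshold outside intensity range")
  air <- I < air_threshold
  exterior <- flood_fill_3d(air, "boundary", connectivity)
  nonair <- !air
  mask <- exterior
  if (container_policy == "components" && any(nonair)) {
    na_idx <- which(nonair)
    ai <- arrayInd(na_idx, dim(I))
    cen <- colMeans(ai)
    seed <- na_idx[which.min((ai[, 1] - cen[1])^2 + (ai[, 2] - cen[2])^2 +
                               (ai[, 3] - cen[3])^2)]
    colony_body <- flood_fill_3d(nonair, seed, connectivity)
    mask <- mask | (nonair & !colony_body)
  }
  colony <- !mask
  if (!any(colony))
    stop("no colony found: mask covers the entire volume")
  cp_log("mask", tom$fragment_id,
         sprintf("air_threshold=%.4g colony=%d/%d", air_threshold,
                 sum(colony), length(colony)))
  structure(colony, air_threshold = air_threshold,
            container_policy = container_policy)
}

## ---- threshold selection and phase segmentation --------------------------

#' Select the two segmentation thresholds
#'
#' In `"auto"` mode the two cut points are chosen by a three-class Otsu
#' criterion on the intensity histogram of non-mask voxels; the three
#' classes correspond to air (macropores), micropores (intermediate
#' attenuation from sub-resolution porosity) and solid carbonate. In
#' `"fixed"` mode the supplied thresholds are validated and returned.
#'
#' @param tom A [tomogram()].
#' @param mode `"auto"` or `"fixed"`.
#' @param colony_mask Optional logical array from [apply_mask_filter()];
#'   when given, only colony voxels enter the histogram.
#' @param t_low,t_high Thresholds for `"fixed"` mode.
#' @param n_bins Histogram bins for `"auto"` mode.
#' @return Numeric `c(t_low, t_high)` with `t_low < t_high`.
#' @export
select_thresholds <- function(tom, mode = c("auto", "fixed"),
                              colony_mask = NULL, t_low = NULL,
                              t_high = NULL, n_bins = 256L) {
  stopifnot(inherits(tom, "tomogram"))
  mode <- match.arg(mode)
  if (mode == "fixed") {
    if (is.null(t_low) || is.null(t_high))
      stop("fixed mode requires t_low and t_high")
    if (!(t_low < t_high)) stop("need t_low < t_high")
    return(c(t_low = t_low, t_high = t_high))
  }
  v <- if (is.null(colony_mask)) as.vector(tom$intensities) else
    tom$intensities[colony_mask]
  multilevel_otsu(v, n_bins)
}

#' Segment a tomogram into the four phases
#'
#' Applies the two-threshold rule to every colony voxel: intensity below
#' `t_low` is air (macropore), between `t_low` and `t_high` is micropore,
#' at or above `t_high` is solid. Mask voxels keep the mask label. The
#' operation is deterministic.
#'
#' @param tom A [tomogram()].
#' @param colony_mask Logical array from [apply_mask_filter()] (`TRUE` =
#'   colony voxel).
#' @param t_low,t_high Segmentation thresholds, `t_low < t_high`.
#' @return A [phase_volume()].
#' @export
segment_phases <- function(tom, colony_mask, t_low, t_high) {
  stopifnot(inherits(tom, "tomogram"))
  if (!(t_low < t_high)) stop("need t_low < t_high")
  if (!identical(dim(colony_mask), dim(tom$intensities)))
    stop("colony_mask dimensions do not match the tomogram")
  I <- tom$intensities
  lab <- array(.PH_SOLID, dim(I))
  lab[I < t_high] <- .PH_MICROPORE
  lab[I < t_low] <- .PH_AIR
  lab[!colony_mask] <- .PH_MASK
  phase_volume(lab, tom$voxel_size_um, tom$fragment_id,
               thresholds = c(t_low = unname(t_low), t_high = unname(t_high)),
               provenance = list(
                 air_threshold = attr(colony_mask, "air_threshold"),
                 container_policy = attr(colony_mask, "container_policy")))
}

#' Mask and segment a tomogram in one step
#'
#' Convenience wrapper running [apply_mask_filter()], [select_thresholds()]
#' and [segment_phases()] with the parameters of a [run_config()].
#'
#' @param tom A [tomogram()].
#' @param config A [run_config()].
#' @return A [phase_volume()].
#' @export
segment_tomogram <- function(tom, config = run_config()) {
  colony <- apply_mask_filter(tom, air_threshold = config$air_threshold,
                              container_policy = config$container_policy,
                              connectivity = config$connectivity)
  thr <- select_thresholds(tom, mode = config$segmentation_mode,
                           colony_mask = colony, t_low = config$t_low,
                           t_high = config$t_high, n_bins = config$n_bins)
  segment_phases(tom, colony, thr[1], thr[2])
}
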