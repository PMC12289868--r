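#' Ground-truth parameters for a synthetic phantom
#'
#' Describes a synthetic coral-skeleton fragment: a solid carbonate cylinder
#' holding spherical macropore voids and voxel-scale micropores, with a
#' depth-localized band in which the micropore fraction rises and the
#' macropore fraction falls — the tomographic signature of the green band of
#' endolithic algae. The colony sits inside an air margin and (optionally) a
#' thin container tube wall, so the masking filter has realistic work to do.
#'
#' Defaults emulate the conditions reported for massive *Porites*
#' fragments: baseline microporosity ~5% rising by ~5 points in the band
#' (fragment means 3.9–10.9%), baseline macroporosity ~35% dipping by ~10
#' points (fragment means 20–47%), a band 1.2 mm wide (the mean measured
#' green-band width) centered 2.5 mm below the apical end, and additive
#' Gaussian noise with a standard deviation of 5% of the solid–air
#' intensity gap. Macropore radii default to 0.05–0.2 mm: resolvable at the
#' 24.3 um scan resolution but small against the ~2.4 mm phantom colony so
#' that windowed macroporosity is an average over many voids rather than a
#' count of one or two.
#'
#' @param band_center_mm Band center, mm below the apical (Z = 0) end of the
#'   colony.
#' @param band_width_mm Band width (mm); the band interval is
#'   `center +/- width/2` and the Gaussian modulation uses
#'   `sigma = width/2`.
#' @param mip_baseline_pct Baseline micropore fraction, % of colony volume.
#' @param mip_amplitude_pct Peak in-band micropore increment (percentage
#'   points).
#' @param map_baseline_pct Baseline macropore fraction, % of colony volume.
#' @param map_dip_pct Peak in-band macropore decrement (percentage points).
#' @param macropore_radius_mm Range `c(min, max)` of sphere radii (mm),
#'   drawn uniformly; spheres may overlap (Boolean model).
#' @param band_skew Skew of the band profile (skew-normal shape parameter);
#'   negative values skew the band towards the apical end, 0 (default) is
#'   symmetric.
#' @param levels Intensities of the three pure phases, strictly increasing:
#'   `c(air, micropore, solid)`.
#' @param container Add a container tube wall around the colony?
#' @param container_level Intensity of the container wall.
#' @param noise_sd Standard deviation of additive Gaussian intensity noise.
#' @param margin_vox Air margin between the volume faces and the container.
#' @param shell_vox Thickness of the container wall (voxels).
#' @param gap_vox Air gap between container wall and colony (voxels).
#' @param crust_vox Minimum solid clearance kept between any macropore
#'   sphere and the colony surface. Without it the (percolating) macropore
#'   network opens onto the surface and the masking convention — voids
#'   connected to the exterior are not pores — would discard it wholesale;
#'   real fragments keep macroporosities up to 47%, so their internal voids
#'   are mostly enclosed at scan resolution.
#' @param seed Random seed; identical seeds give bit-identical phantoms.
#' @return A list of class `"synthetic_truth"`.
#' @export
synthetic_truth <- function(band_center_mm = 2.5, band_width_mm = 1.2,
                            mip_baseline_pct = 5, mip_amplitude_pct = 5,
                            map_baseline_pct = 35, map_dip_pct = 10,
                            macropore_radius_mm = c(0.05, 0.2),
                            band_skew = 0,
                            levels = c(air = 0, micropore = 100, solid = 200),
                            container = TRUE, container_level = 150,
                            noise_sd = 10, margin_vox = 4L, shell_vox = 2L,
                            gap_vox = 4L, crust_vox = 1.5, seed = NULL) {
  if (length(levels) != 3L || !all(diff(levels) > 0))
    stop("phase intensity levels must be strictly increasing (air < micropore < solid)")
  if (band_width_mm <= 0) stop("band_width_mm must be > 0")
  if (length(macropore_radius_mm) != 2L ||
      !(0 < macropore_radius_mm[1] && macropore_radius_mm[1] <= macropore_radius_mm[2]))
    stop("macropore_radius_mm must be c(min, max) with 0 < min <= max")
  pk_mip <- mip_baseline_pct + mip_amplitude_pct
  pk_map <- map_baseline_pct            # macropores peak away from the band
  if (min(mip_baseline_pct, map_baseline_pct - map_dip_pct) < 0 ||
      pk_mip + pk_map > 100)
    stop(sprintf(
      "infeasible phase fractions: micropore + macropore targets reach %.1f%%",
      pk_mip + pk_map))
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(
    band_center_mm = band_center_mm, band_width_mm = band_width_mm,
    mip_baseline_pct = mip_baseline_pct,
    mip_amplitude_pct = mip_amplitude_pct,
    map_baseline_pct = map_baseline_pct, map_dip_pct = map_dip_pct,
    macropore_radius_mm = macropore_radius_mm, band_skew = band_skew,
    levels = levels, container = container,
    container_level = container_level, noise_sd = noise_sd,
    margin_vox = as.integer(margin_vox), shell_vox = as.integer(shell_vox),
    gap_vox = as.integer(gap_vox), crust_vox = crust_vox, seed = seed),
    class = "synthetic_truth")
}

## unit-peak band modulation profile; skew-normal shape, renormalized so the
## maximum is exactly 1 (the amplitude then is the true peak increment)
band_bump <- function(z_mm, truth) {
  sigma <- truth$band_width_mm / 2
  u <- (z_mm - truth$band_center_mm) / sigma
  b <- exp(-0.5 * u^2)
  if (truth$band_skew != 0) {
    b <- b * stats::pnorm(truth$band_skew * u)
    ## renormalize on a fine grid spanning the bump
    zf <- seq(truth$band_center_mm - 5 * sigma,
              truth$band_center_mm + 5 * sigma, length.out = 2001)
    uf <- (zf - truth$band_center_mm) / sigma
    b <- b / max(exp(-0.5 * uf^2) * stats::pnorm(truth$band_skew * uf))
  }
  b
}

#' Generate a synthetic phantom tomogram with exact ground truth
#'
#' Builds the noisy intensity volume and its exact phase labels. Macropores
#' are overlapping spheres placed by an inhomogeneous Boolean model whose
#' z-dependent intensity is calibrated so the expected void fraction tracks
#' the target macroporosity profile (`lambda(z) = -log(1 - f(z)) / E[v]`);
#' micropores are single voxels of intermediate attenuation (a
#' partial-volume proxy for channels below the scan resolution) drawn at a
#' z-dependent rate. Following the masking convention of the porosity
#' analysis, truth labels mark exterior-connected air and the container as
#' mask; only enclosed voids are air.
#'
#' @param truth A [synthetic_truth()].
#' @param dims Volume dimensions `c(nx, ny, nz)` in voxels; the Z extent
#'   must fit at least three 0.9 mm windows.
#' @param voxel_size_um Voxel edge length (default 24.3, the minimum scan
#'   resolution of the targeted instrument).
#' @return A list of class `"coral_phantom"`: `tomogram` (a [tomogram()]),
#'   `labels` (a [phase_volume()] of ground truth), and `truth` augmented
#'   with the realized geometry (`colony_z_range_vox`, `colony_radius_vox`,
#'   `band_interval_mm`).
#' @export
generate_phantom <- function(truth, dims = c(120L, 120L, 300L),
                             voxel_size_um = 24.3) {
  stopifnot(inherits(truth, "synthetic_truth"))
  d <- as.integer(dims)
  if (length(d) != 3L || any(d < 1L)) stop("dims must be 3 positive integers")
  vox_mm <- voxel_size_um / 1000
  win_vox <- max(1L, round(0.9 / vox_mm))
  z_colony <- d[3] - 2L * truth$margin_vox
  if (z_colony < 3L * win_vox)
    stop("dims too small: at least three 0.9 mm windows must fit along Z inside the colony")
  with_seed(truth$seed, function() {
    margin <- truth$margin_vox; shell <- truth$shell_vox; gap <- truth$gap_vox
    cx <- (seq_len(d[1])) - (d[1] + 1) / 2
    cy <- (seq_len(d[2])) - (d[2] + 1) / 2
    r2 <- outer(cx^2, cy^2, "+")
    rcol <- min(d[1], d[2]) / 2 - margin -
      (if (truth$container) shell else 0L) - gap
    if (rcol < 2) stop("dims too small for the colony cross-section")
    colony_xy <- r2 <= rcol^2
    z0 <- margin + 1L; z1 <- d[3] - margin
    colony <- array(FALSE, d)
    colony[, , z0:z1] <- colony_xy
    container <- array(FALSE, d)
    if (truth$container) {
      shell_xy <- r2 > (rcol + gap)^2 & r2 <= (rcol + gap + shell)^2
      container[, , z0:z1] <- shell_xy
    }
    ## target fractions per colony z-layer (of total colony volume)
    zmm <- ((z0:z1) - z0 + 0.5) * vox_mm
    bump <- band_bump(zmm, truth)
    f_map <- (truth$map_baseline_pct - truth$map_dip_pct * bump) / 100
    f_mip <- (truth$mip_baseline_pct + truth$mip_amplitude_pct * bump) / 100
    if (any(f_map + f_mip >= 1))
      stop("infeasible phase fractions along Z (micropore + macropore >= 100%)")
    ## Boolean model: spheres with radius ~ U(rmin, rmax)
    rmin <- truth$macropore_radius_mm[1] / vox_mm
    rmax <- truth$macropore_radius_mm[2] / vox_mm
    mean_sphere_vol <- 4 / 3 * pi *
      (rmax^4 - rmin^4) / (4 * (rmax - rmin))   # E[4/3 pi r^3]
    area <- sum(colony_xy)
    lam_z <- -log(1 - f_map) / mean_sphere_vol * area
    air <- array(FALSE, d)
    n_sph <- rpois(1L, sum(lam_z))
    if (n_sph > 0 && any(lam_z > 0)) {
      zc <- sample.int(length(lam_z), n_sph, replace = TRUE, prob = lam_z) +
        z0 - 1L
      rr <- runif(n_sph, rmin, rmax)
      ctr <- (c(d[1], d[2]) + 1) / 2
      crust <- truth$crust_vox
      for (s in seq_len(n_sph)) {
        r <- rr[s]
        rmax_c <- rcol - r - crust          # xy freedom for this radius
        if (rmax_c <= 0) next
        u <- sqrt(runif(1)) * rmax_c
        th <- runif(1, 0, 2 * pi)
        zlo <- z0 + r + crust; zhi <- z1 - r - crust
        zs <- zc[s]; tries <- 0L
        while ((zs < zlo || zs > zhi) && tries < 100L) {  # keep sphere sealed
          zs <- sample.int(length(lam_z), 1L, prob = lam_z) + z0 - 1L
          tries <- tries + 1L
        }
        if (zs < zlo || zs > zhi) next
        c0 <- c(ctr[1] + u * cos(th), ctr[2] + u * sin(th), zs)
        lo <- pmax(1L, as.integer(floor(c0 - r)))
        hi <- pmin(d, as.integer(ceiling(c0 + r)))
        if (any(lo > hi)) next
        inside <- outer(outer((lo[1]:hi[1] - c0[1])^2,
                              (lo[2]:hi[2] - c0[2])^2, "+"),
                        (lo[3]:hi[3] - c0[3])^2, "+") <= r^2
        w3 <- which(inside) - 1L
        n1 <- hi[1] - lo[1] + 1L; n2 <- hi[2] - lo[2] + 1L
        air[cbind(lo[1] + w3 %% n1,
                  lo[2] + (w3 %/% n1) %% n2,
                  lo[3] + w3 %/% (n1 * n2))] <- TRUE
      }
      air <- air & colony
    }
    ## micropores: voxel-scale draws among the remaining solid, at a rate
    ## giving the target fraction of *total* colony volume
    lab <- array(.PH_MASK, d)
    lab[colony] <- .PH_SOLID
    lab[air] <- .PH_AIR
    solid_idx <- which(lab == .PH_SOLID)
    kz <- ((solid_idx - 1L) %/% (d[1] * d[2])) + 1L
    p_z <- numeric(d[3])
    p_z[z0:z1] <- f_mip / (1 - f_map)
    mk <- runif(length(solid_idx)) < p_z[kz]
    lab[solid_idx[mk]] <- .PH_MICROPORE
    ## intensities reflect the physical material (set before any masking
    ## relabels voxels)
    lev <- truth$levels
    I <- array(lev[[1]], d)
    I[lab == .PH_MICROPORE] <- lev[[2]]
    I[lab == .PH_SOLID] <- lev[[3]]
    I[container] <- truth$container_level
    if (truth$noise_sd > 0)
      I <- I + rnorm(length(I), 0, truth$noise_sd)
    ## truth mask mirrors the masking filter's conventions exactly:
    ## exterior-connected air is not a pore, and solid shards disconnected
    ## from the main colony body (sphere-carving leftovers) are mask
    open_air <- (lab == .PH_AIR) | (!colony & !container)
    exterior <- flood_fill_3d(open_air, "boundary", 6L)
    lab[exterior] <- .PH_MASK
    nonair <- !open_air
    na_idx <- which(nonair)
    ai <- arrayInd(na_idx, d)
    cen <- colMeans(ai)
    seed_vox <- na_idx[which.min((ai[, 1] - cen[1])^2 +
                                   (ai[, 2] - cen[2])^2 +
                                   (ai[, 3] - cen[3])^2)]
    body <- flood_fill_3d(nonair, seed_vox, 6L)
    lab[(lab == .PH_SOLID | lab == .PH_MICROPORE) & !body] <- .PH_MASK
    lab[container] <- .PH_MASK
    out_truth <- truth
    out_truth$colony_z_range_vox <- c(z0, z1)
    out_truth$colony_radius_vox <- rcol
    out_truth$band_interval_mm <- truth$band_center_mm +
      c(-0.5, 0.5) * truth$band_width_mm
    fid <- sprintf("phantom-c%.3g", truth$band_center_mm)
    structure(list(
      tomogram = tomogram(I, voxel_size_um, fid),
      labels = phase_volume(lab, voxel_size_um, fid,
                            provenance = list(source = "synthetic truth")),
      truth = out_truth), class = "coral_phantom")
  })
}

#' Ground-truth vertical porosity profile of a phantom
#'
#' Counts the true phase labels in 0.9 mm slabs along Z (anchored, like the
#' porosity map, at the colony bounding box) and converts the counts to the
#' four response variables. No segmentation is involved: this is the oracle
#' against which pipeline estimates are compared.
#'
#' @param phantom A `"coral_phantom"` from [generate_phantom()], or a
#'   [phase_volume()] of ground-truth labels.
#' @param window_size_mm Slab thickness (mm).
#' @return Data frame with one row per Z slab: `z` (slab index, 0-based),
#'   `z_mm` (slab center, mm from the apical colony edge), phase counts,
#'   and `mip`, `map`, `tp`, `svf` percentages of colony voxels.
#' @export
truth_profile <- function(phantom, window_size_mm = 0.9) {
  labels <- if (inherits(phantom, "coral_phantom")) phantom$labels else phantom
  stopifnot(inherits(labels, "phase_volume"))
  lab <- labels$labels
  vox_mm <- labels$voxel_size_um / 1000
  w <- round(window_size_mm / vox_mm)
  if (w < 1L) stop("window smaller than one voxel")
  if (w > dim(lab)[3]) stop("window larger than the volume Z extent")
  idx <- which(lab != .PH_MASK)
  if (!length(idx)) stop("label volume contains no colony voxels")
  kz <- ((idx - 1L) %/% (dim(lab)[1] * dim(lab)[2])) + 1L
  z0 <- min(kz)
  slab <- (kz - z0) %/% w
  nb <- max(slab) + 1L
  v <- lab[idx]
  n_air <- tabulate(slab[v == .PH_AIR] + 1L, nb)
  n_mic <- tabulate(slab[v == .PH_MICROPORE] + 1L, nb)
  n_sol <- tabulate(slab[v == .PH_SOLID] + 1L, nb)
  tot <- n_air + n_mic + n_sol
  mip <- 100 * n_mic / tot
  map <- 100 * n_air / tot
  data.frame(z = seq_len(nb) - 1L,
             z_mm = (seq_len(nb) - 0.5) * w * vox_mm,
             n_solid = n_sol, n_micropore = n_mic, n_air = n_air,
             mip = mip, map = map, tp = mip + map,
             svf = 100 * n_sol / tot)
}
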