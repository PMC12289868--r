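#' Band-recovery study on a cohort of phantoms
#'
#' Generates a cohort of phantoms with known band centers, runs the full
#' pipeline (masking, automatic segmentation, porosity mapping, vertical
#' profile, LOESS extremum localization) on each, and measures how well the
#' microporosity peak and macroporosity valley recover the true band
#' center, plus the per-fragment microporosity/macroporosity profile
#' correlation and the cohort-level concordance between peak locations and
#' band midpoints.
#'
#' @param n_fragments Number of phantoms.
#' @param seed Seed for the whole study (band centers and phantom noise).
#' @param band_center_range_mm Band centers are drawn uniformly from this
#'   interval (mm below the apical end).
#' @param dims,voxel_size_um Phantom geometry (see [generate_phantom()]).
#' @param truth_args Named list of overrides passed to [synthetic_truth()].
#' @param span LOESS span passed to [find_band_extrema()].
#' @return List of class `"band_recovery"`: `results` (per-fragment data
#'   frame with true center, recovered peak/valley, errors, profile rho),
#'   `concordance` (a `"concordance_result"` of peaks vs true centers),
#'   and the study parameters.
#' @export
band_recovery_study <- function(n_fragments = 20L, seed = 1L,
                                band_center_range_mm = c(1.5, 4.5),
                                dims = c(120L, 120L, 300L),
                                voxel_size_um = 24.3,
                                truth_args = list(), span = 0.3) {
  rows <- with_seed(seed, function() {
    centers <- runif(n_fragments, band_center_range_mm[1],
                     band_center_range_mm[2])
    lapply(seq_len(n_fragments), function(i) {
      args <- modifyList(list(band_center_mm = centers[i], seed = NULL),
                         truth_args)
      ph <- generate_phantom(do.call(synthetic_truth, args), dims = dims,
                             voxel_size_um = voxel_size_um)
      seg <- segment_tomogram(ph$tomogram)
      pm <- compute_porosity_map(seg)
      vp <- extract_vertical_profile(pm)
      ex <- find_band_extrema(vp, span = span)
      rho <- correlate_profiles(vp$mip_mean, vp$map_mean)
      fm <- fragment_mean(pm)
      peak <- ex[ex$variable == "mip", ]
      valley <- ex[ex$variable == "map", ]
      cp_log("recovery", ph$tomogram$fragment_id,
             sprintf("truth=%.2f peak=%.2f valley=%.2f rho=%.2f",
                     centers[i], peak$location_mm, valley$location_mm,
                     rho$estimate))
      data.frame(fragment = sprintf("ph%02d", i),
                 true_center_mm = centers[i],
                 mip_peak_mm = peak$location_mm,
                 mip_peak_at_boundary = peak$at_boundary,
                 map_valley_mm = valley$location_mm,
                 map_valley_at_boundary = valley$at_boundary,
                 mip_peak_error_mm = peak$location_mm - centers[i],
                 map_valley_error_mm = valley$location_mm - centers[i],
                 mip_map_rho = rho$estimate,
                 frag_mip = fm$mean[fm$variable == "mip"],
                 frag_map = fm$mean[fm$variable == "map"],
                 frag_tp = fm$mean[fm$variable == "tp"],
                 frag_svf = fm$mean[fm$variable == "svf"])
    })
  })
  results <- do.call(rbind, rows)
  conc <- concordance_extrema_band(
    setNames(results$mip_peak_mm, results$fragment),
    setNames(results$true_center_mm, results$fragment))
  structure(list(results = results, concordance = conc,
                 n_fragments = n_fragments, seed = seed, dims = dims,
                 band_center_range_mm = band_center_range_mm),
            class = "band_recovery")
}

#' @export
print.band_recovery <- function(x, ...) {
  r <- x$results
  cat(sprintf("Band recovery over %d phantoms (centers %.1f-%.1f mm):\n",
              x$n_fragments, x$band_center_range_mm[1],
              x$band_center_range_mm[2]))
  cat(sprintf("  MiP peak  within 0.9 mm: %d/%d\n",
              sum(abs(r$mip_peak_error_mm) <= 0.9), nrow(r)))
  cat(sprintf("  MaP valley within 1.8 mm: %d/%d\n",
              sum(abs(r$map_valley_error_mm) <= 1.8), nrow(r)))
  cat(sprintf("  MiP~MaP profile rho < 0: %d/%d (mean %.2f)\n",
              sum(r$mip_map_rho < 0), nrow(r), mean(r$mip_map_rho)))
  cat(sprintf("  peak~band concordance: rho = %.2f (p = %.3g)\n",
              x$concordance$correlation$estimate,
              x$concordance$correlation$p_value))
  invisible(x)
}

#' Simulation calibration of the zone comparison
#'
#' Monte-Carlo check of [zone_anova()]: draws the three zones from normal
#' distributions (the green band optionally shifted) and records how often
#' the ANOVA rejects at level `alpha`. With `shift = 0` the rejection rate
#' estimates the type-I error; with a positive shift it estimates power.
#'
#' @param n_reps Simulation replicates.
#' @param n_per_zone Values per zone.
#' @param shift Mean shift added to the green-band zone.
#' @param sd Common standard deviation.
#' @param alpha Nominal significance level.
#' @param seed Seed.
#' @return List: `rejection_rate`, `n_reps`, `n_per_zone`, `shift`, `sd`,
#'   `alpha`.
#' @export
calibrate_zone_anova <- function(n_reps = 1000L, n_per_zone = 30L,
                                 shift = 0, sd = 1, alpha = 0.05,
                                 seed = 1L) {
  zones <- factor(rep(c("coral_tissue", "green_band", "skeleton"),
                      each = n_per_zone))
  rej <- with_seed(seed, function() {
    mu <- ifelse(zones == "green_band", shift, 0)
    vapply(seq_len(n_reps), function(r) {
      vals <- rnorm(length(zones), mean = mu, sd = sd)
      zone_anova(vals, zones, diagnostics = FALSE)$anova$p_value < alpha
    }, logical(1))
  })
  list(rejection_rate = mean(rej), n_reps = n_reps,
       n_per_zone = n_per_zone, shift = shift, sd = sd, alpha = alpha)
}
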