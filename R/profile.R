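#' Extract the vertical porosity profile of a fragment
#'
#' For every Z level of the window grid, averages each response variable
#' over the valid (X, Y) windows at that level and attaches the standard
#' error of the mean. Levels without valid windows are dropped.
#'
#' @param map A `"porosity_map"` from [compute_porosity_map()].
#' @return Data frame of class `"vertical_profile"`, one row per retained Z
#'   level: `z` (window index along Z, 0-based, apical first),
#'   `z_mm_window` (level center on the fragment's own physical scale,
#'   `(z + 0.5) * window`), `n_windows`, and `<var>_mean` / `<var>_sem`
#'   for `mip`, `map`, `tp`, `svf`. Attributes carry the fragment id and
#'   effective window size.
#' @export
extract_vertical_profile <- function(map) {
  stopifnot(inherits(map, "porosity_map"))
  ok <- map$valid
  if (!any(ok)) stop("no valid windows")
  k <- map$k[ok]
  levs <- sort(unique(k))
  if (length(levs) < 2L)
    stop("fewer than 2 usable Z levels in the porosity map")
  w_eff_mm <- attr(map, "window_vox") * attr(map, "voxel_size_um") / 1000
  vars <- c("mip", "map", "tp", "svf")
  out <- data.frame(z = levs,
                    z_mm_window = (levs + 0.5) * w_eff_mm,
                    n_windows = as.integer(table(factor(k, levels = levs))))
  for (v in vars) {
    x <- map[[v]][ok]
    out[[paste0(v, "_mean")]] <-
      as.numeric(tapply(x, factor(k, levels = levs), mean))
    out[[paste0(v, "_sem")]] <- as.numeric(
      tapply(x, factor(k, levels = levs), function(u)
        if (length(u) < 2L) 0 else sd(u) / sqrt(length(u))))
  }
  structure(out, class = c("vertical_profile", "data.frame"),
            fragment_id = attr(map, "fragment_id"),
            window_mm = w_eff_mm)
}

#' Normalize profile coordinates to a common millimeter scale
#'
#' Applies the two-step coordinate transformation used to compare fragments
#' of different sizes. First each raw vertical coordinate is normalized
#' against the Z range of the *largest* selected fragment,
#' `z_norm = (z - min(z)) / (ref_max - ref_min)` (the numerator uses the
#' fragment's own minimum, the denominator the reference fragment's range),
#' then mapped to millimeters with a conversion factor — the vertical
#' length of the largest fragment's porosity map, 8 mm by default — and a
#' correction factor of half a sampling interval (0.45 mm), because each
#' profile point represents the middle of its 0.9 mm window:
#' `z_mm = z_norm * conversion + correction`. For the largest fragment the
#' endpoints map to 0.45 mm and 8.45 mm.
#'
#' @param profile A `"vertical_profile"` (or any data frame with a `z`
#'   column).
#' @param reference_range `c(ref_min, ref_max)` of the largest fragment's
#'   raw Z coordinates; defaults to the profile's own range.
#' @param conversion_mm Conversion factor (mm).
#' @param correction_mm Correction factor (mm).
#' @return The profile with columns `z_norm` and `z_mm` added.
#' @export
normalize_coordinates <- function(profile, reference_range = NULL,
                                  conversion_mm = 8, correction_mm = 0.45) {
  if (!"z" %in% names(profile)) stop("profile must have a 'z' column")
  if (conversion_mm <= 0 || correction_mm <= 0)
    stop("conversion and correction factors must be > 0")
  if (is.null(reference_range)) reference_range <- range(profile$z)
  den <- reference_range[2] - reference_range[1]
  if (!(den > 0)) stop("reference fragment has zero Z range")
  profile$z_norm <- (profile$z - min(profile$z)) / den
  profile$z_mm <- profile$z_norm * conversion_mm + correction_mm
  profile
}

#' Conversion/correction factors reproducing a fragment's physical scale
#'
#' With the conversion factor set to the reference fragment's physical map
#' length minus one window, and the correction to half a window,
#' [normalize_coordinates()] maps window indices exactly onto window
#' centers in mm — useful when normalized locations must be compared with
#' physically measured ones (e.g. phantom ground truth).
#'
#' @param reference_profile The largest fragment's `"vertical_profile"`.
#' @return List with `conversion_mm` and `correction_mm`.
#' @export
mm_scale_from_reference <- function(reference_profile) {
  w <- attr(reference_profile, "window_mm")
  if (is.null(w)) stop("reference profile lacks a window size attribute")
  K <- diff(range(reference_profile$z))
  list(conversion_mm = w * K, correction_mm = w / 2)
}

#' Normalize a response variable within a fragment
#'
#' Rescales profile values to their within-fragment range:
#' `delta = v - min(v)`, `delta_max = max(v) - min(v)`,
#' `v_norm = delta / delta_max`. The transformation preserves the
#' intra-colonial gradient shape when profiles are pooled across fragments
#' whose raw levels differ; raw-value pooling would flatten it.
#'
#' @param v Numeric vector of profile values (one fragment).
#' @return List with `delta`, `delta_max`, `v_norm`.
#' @export
#' @examples
#' transform_variable(c(5, 7, 10))
transform_variable <- function(v) {
  if (length(v) < 2L) stop("need at least 2 values")
  if (anyNA(v)) stop("values must be non-missing")
  delta <- v - min(v)
  delta_max <- max(v) - min(v)
  if (delta_max == 0)
    stop("zero range: constant profile cannot be normalized")
  list(delta = delta, delta_max = delta_max, v_norm = delta / delta_max)
}

#' Fit a LOESS curve to profile points
#'
#' Locally weighted polynomial regression (degree 2, tricube weights)
#' evaluated on a uniform grid over the data range; no extrapolation. The
#' fit is deterministic for fixed inputs (`surface = "direct"`).
#'
#' @param x,y Profile coordinates (mm) and values; points may be pooled
#'   across fragments or species.
#' @param span LOESS span in (0, 1].
#' @param degree Local polynomial degree.
#' @param n_grid Number of evaluation points.
#' @param variable Optional variable name carried in the result.
#' @return List of class `"loess_curve"`: `grid`, `fitted`, `span`,
#'   `degree`, `n`, `variable`.
#' @export
fit_loess <- function(x, y, span = 0.3, degree = 2, n_grid = 200L,
                      variable = NULL) {
  if (!(span > 0 && span <= 1)) stop("span must be in (0, 1]")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 5L) stop("too few points for a LOESS fit (need >= 5)")
  fit <- loess(y ~ x, span = span, degree = degree, family = "gaussian",
               control = loess.control(surface = "direct"))
  grid <- seq(min(x), max(x), length.out = n_grid)
  structure(list(grid = grid, fitted = as.numeric(predict(fit, grid)),
                 span = span, degree = degree, n = length(x),
                 variable = variable),
            class = "loess_curve")
}

#' Locate the peak or valley of a fitted curve
#'
#' The peak is the grid argmax and the valley the grid argmin, with ties
#' broken towards the smallest Z (apical end). Extrema on the first or last
#' grid point are flagged `at_boundary` so callers can exclude monotone
#' profiles; with `interior = TRUE` the strongest *interior local*
#' extremum is preferred and the global one is only used when no interior
#' turning point exists.
#'
#' @param curve A `"loess_curve"`.
#' @param kind `"peak"` or `"valley"`.
#' @param interior Prefer interior local extrema over boundary ones.
#' @return List of class `"extremum"`: `kind`, `location_mm`, `value`,
#'   `at_boundary`, `variable`.
#' @export
locate_extremum <- function(curve, kind = c("peak", "valley"),
                            interior = FALSE) {
  stopifnot(inherits(curve, "loess_curve"))
  kind <- match.arg(kind)
  g <- curve$grid; p <- curve$fitted
  if (length(g) < 3L) stop("curve needs at least 3 grid points")
  s <- if (kind == "peak") p else -p
  pick <- which.max(s)                   # first max = smallest Z on ties
  if (interior) {
    n <- length(s)
    turn <- which(s > c(-Inf, s[-n]) & s >= c(s[-1], -Inf))
    turn <- turn[turn > 1L & turn < n]
    if (length(turn)) pick <- turn[which.max(s[turn])]
  }
  structure(list(kind = kind, location_mm = g[pick], value = p[pick],
                 at_boundary = pick == 1L || pick == length(g),
                 variable = curve$variable),
            class = "extremum")
}

#' Locate the microporosity peak and macroporosity valley of a profile
#'
#' Fits a LOESS curve to the per-level means of each requested variable and
#' localizes its extremum on the fragment's physical mm scale, preferring
#' interior turning points (see [locate_extremum()]). Desk-scale profiles
#' carry few Z levels, so the span is floored at `3.2 / K` (K = number of
#' levels) to keep the local quadratic identifiable; the floor is inactive
#' for the denser profiles the default span targets.
#'
#' @param profile A `"vertical_profile"`.
#' @param variables Named character vector mapping variable to extremum
#'   kind; default `c(mip = "peak", map = "valley")`, the signature of the
#'   endolithic band.
#' @param span Requested LOESS span.
#' @return Data frame: `variable`, `kind`, `location_mm`, `value`,
#'   `at_boundary`.
#' @export
find_band_extrema <- function(profile,
                              variables = c(mip = "peak", map = "valley"),
                              span = 0.3) {
  stopifnot(inherits(profile, "vertical_profile"))
  K <- nrow(profile)
  span_eff <- max(span, min(1, 3.2 / K))
  x <- profile$z_mm_window
  rows <- lapply(names(variables), function(v) {
    curve <- suppressWarnings(
      fit_loess(x, profile[[paste0(v, "_mean")]], span = span_eff,
                variable = v))
    ex <- locate_extremum(curve, variables[[v]], interior = TRUE)
    data.frame(variable = v, kind = ex$kind, location_mm = ex$location_mm,
               value = ex$value, at_boundary = ex$at_boundary)
  })
  do.call(rbind, rows)
}

#' Assign intra-colonial zones along the vertical profile
#'
#' Partitions profile coordinates into the three microenvironments using
#' the stereoscope-measured green-band interval: `z < low` is coral tissue,
#' `low <= z <= high` the green band, `z > high` skeleton (half-open at the
#' tissue edge, closed on the band).
#'
#' @param z_mm Profile coordinates (mm).
#' @param green_band_mm Interval `c(low, high)` in the same scale.
#' @return Factor with levels `coral_tissue`, `green_band`, `skeleton`.
#' @export
assign_zones <- function(z_mm, green_band_mm) {
  if (length(green_band_mm) != 2L || !(green_band_mm[1] < green_band_mm[2]))
    stop("green_band_mm must be c(low, high) with low < high")
  lo <- green_band_mm[1]; hi <- green_band_mm[2]
  if (hi < min(z_mm) || lo > max(z_mm))
    stop(sprintf(
      "green band [%g, %g] mm lies outside the profile range [%g, %g] mm",
      lo, hi, min(z_mm), max(z_mm)))
  factor(ifelse(z_mm < lo, "coral_tissue",
                ifelse(z_mm <= hi, "green_band", "skeleton")),
         levels = c("coral_tissue", "green_band", "skeleton"))
}
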