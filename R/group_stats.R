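#' Correlate two response variables along the vertical profile
#'
#' Spearman rank correlation (average ranks on ties, two-sided p from the
#' t approximation) between two per-Z series of the same fragment, e.g.
#' microporosity vs macroporosity. Z levels missing in either series are
#' dropped pairwise.
#'
#' @param v1,v2 Aligned per-Z numeric series.
#' @param method `"spearman"` (profile scale) or `"pearson"`.
#' @return List of class `"correlation_result"`: `method`, `estimate`,
#'   `p_value`, `n`.
#' @export
correlate_profiles <- function(v1, v2, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (length(v1) != length(v2)) stop("series must have equal length")
  keep <- is.finite(v1) & is.finite(v2)
  v1 <- v1[keep]; v2 <- v2[keep]
  if (length(v1) < 3L) stop("need at least 3 paired values")
  if (sd(v1) == 0 || sd(v2) == 0)
    stop("zero variance in one of the series")
  ct <- suppressWarnings(
    cor.test(v1, v2, method = method, exact = FALSE))
  structure(list(method = method, estimate = unname(ct$estimate),
                 p_value = ct$p.value, n = length(v1)),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("%s correlation: %s = %.3f, p = %.3g, n = %d\n",
              x$method, if (x$method == "spearman") "rho" else "R",
              x$estimate, x$p_value, x$n))
  invisible(x)
}

#' Concordance between profile extrema and green-band locations
#'
#' Tests whether the locations of porosity extrema (microporosity peaks or
#' macroporosity valleys) agree with the stereoscope-measured green-band
#' midpoints across fragments: a Spearman correlation between the two
#' location sets, plus a one-way ANOVA treating them as two groups (a
#' non-significant F meaning the extremum locations are indistinguishable
#' from the band locations).
#'
#' @param extrema_mm Named numeric vector of extremum locations (mm), names
#'   = fragment ids.
#' @param band_mid_mm Named numeric vector of green-band midpoints (mm),
#'   same fragment set.
#' @return List of class `"concordance_result"`: `correlation` (a
#'   `"correlation_result"`), `anova` (list `f`, `p_value`, `df`), `n`.
#' @export
concordance_extrema_band <- function(extrema_mm, band_mid_mm) {
  if (is.null(names(extrema_mm)) || is.null(names(band_mid_mm)))
    stop("both vectors must be named by fragment id")
  if (!setequal(names(extrema_mm), names(band_mid_mm)))
    stop("mismatched fragment sets between extrema and bands")
  band_mid_mm <- band_mid_mm[names(extrema_mm)]
  n <- length(extrema_mm)
  if (n < 3L) stop("need at least 3 fragments")
  corr <- correlate_profiles(unname(extrema_mm), unname(band_mid_mm),
                             "spearman")
  dat <- data.frame(
    loc = c(unname(extrema_mm), unname(band_mid_mm)),
    grp = factor(rep(c("extremum", "band"), each = n)))
  if (sd(dat$loc) == 0) {
    an <- list(f = 0, p_value = 1, df = c(1L, 2L * n - 2L))
  } else {
    fit <- aov(loc ~ grp, data = dat)
    s <- summary(fit)[[1]]
    an <- list(f = s[["F value"]][1], p_value = s[["Pr(>F)"]][1],
               df = s[["Df"]])
  }
  structure(list(correlation = corr, anova = an, n = n),
            class = "concordance_result")
}

#' Compare the three intra-colonial zones
#'
#' One-way ANOVA across the coral-tissue, green-band and skeleton zones of
#' (typically range-normalized) profile values, followed by Tukey's HSD for
#' the pairwise contrasts, with per-zone n, mean and median. Normality
#' (Shapiro-Wilk on residuals) and homoscedasticity (Levene) checks are
#' reported as diagnostics; they never switch the test.
#'
#' @param values Numeric profile values.
#' @param zones Factor from [assign_zones()] (or any grouping with >= 2
#'   levels present).
#' @param grouping Label carried in the result (e.g. a species name or
#'   `"overall"`).
#' @param diagnostics Compute the assumption checks (disable in large
#'   simulations).
#' @return List of class `"zone_stats"`: `zone_summary` (n/mean/median per
#'   zone), `anova` (`f`, `p_value`, `df`, `f_defined`), `tukey` (pairwise
#'   table with adjusted p), `diagnostics`, `grouping`.
#' @export
zone_anova <- function(values, zones, grouping = "overall",
                       diagnostics = TRUE) {
  zones <- droplevels(as.factor(zones))
  if (length(values) != length(zones))
    stop("values and zones must have equal length")
  keep <- is.finite(values) & !is.na(zones)
  values <- values[keep]; zones <- droplevels(zones[keep])
  if (nlevels(zones) < 2L) stop("empty zone: need >= 2 zones with data")
  tab <- table(zones)
  if (any(tab < 2L))
    stop(sprintf("zone '%s' has fewer than 2 values",
                 names(tab)[which(tab < 2L)[1]]))
  if (sd(values) == 0)
    stop("constant values across all zones: F undefined")
  zsum <- data.frame(
    zone = levels(zones), n = as.integer(tab),
    mean = as.numeric(tapply(values, zones, mean)),
    median = as.numeric(tapply(values, zones, median)), row.names = NULL)
  fit <- aov(values ~ zones)
  s <- summary(fit)[[1]]
  fval <- s[["F value"]][1]
  an <- list(f = fval, p_value = s[["Pr(>F)"]][1], df = s[["Df"]],
             f_defined = is.finite(fval))
  tk <- TukeyHSD(fit)$zones
  tukey <- data.frame(contrast = rownames(tk), diff = tk[, "diff"],
                      lwr = tk[, "lwr"], upr = tk[, "upr"],
                      p_adj = tk[, "p adj"], row.names = NULL)
  diag <- NULL
  if (diagnostics) {
    sw <- tryCatch(shapiro.test(stats::residuals(fit)),
                   error = function(e) NULL)
    lv <- tryCatch(car::leveneTest(values ~ zones, center = median),
                   error = function(e) NULL)
    diag <- list(
      shapiro_p = if (is.null(sw)) NA_real_ else sw$p.value,
      levene_p = if (is.null(lv)) NA_real_ else lv[1, "Pr(>F)"])
  }
  structure(list(zone_summary = zsum, anova = an, tukey = tukey,
                 diagnostics = diag, grouping = grouping),
            class = "zone_stats")
}

#' @export
print.zone_stats <- function(x, ...) {
  cat(sprintf("Zone comparison (%s): F = %.3g, p = %.3g\n", x$grouping,
              x$anova$f, x$anova$p_value))
  print(x$zone_summary, ...)
  cat("Tukey HSD:\n")
  print(x$tukey, ...)
  invisible(x)
}

#' Compare fragment means between groups (species or locations)
#'
#' For balanced species groups, one-way ANOVA with Tukey's HSD; for the
#' unbalanced Caribbean/Pacific location comparison, the non-parametric
#' Kruskal-Wallis test.
#'
#' @param values Fragment-level means of one response variable.
#' @param groups Grouping factor (>= 2 groups, each with >= 2 fragments).
#' @param test `"kruskal_wallis"` or `"anova_tukey"`.
#' @return List of class `"group_comparison"`: `test`, `statistic`,
#'   `p_value`, `df`, `group_means`, and `tukey` (for the ANOVA variant).
#' @export
compare_groups <- function(values, groups,
                           test = c("kruskal_wallis", "anova_tukey")) {
  test <- match.arg(test)
  groups <- droplevels(as.factor(groups))
  if (length(values) != length(groups))
    stop("values and groups must have equal length")
  keep <- is.finite(values) & !is.na(groups)
  values <- values[keep]; groups <- droplevels(groups[keep])
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  tab <- table(groups)
  if (any(tab < 2L))
    stop(sprintf("group '%s' has fewer than 2 fragments",
                 names(tab)[which(tab < 2L)[1]]))
  gm <- data.frame(group = levels(groups), n = as.integer(tab),
                   mean = as.numeric(tapply(values, groups, mean)),
                   row.names = NULL)
  if (test == "kruskal_wallis") {
    kw <- kruskal.test(values, groups)
    out <- list(test = test, statistic = unname(kw$statistic),
                p_value = kw$p.value, df = unname(kw$parameter),
                group_means = gm, tukey = NULL)
  } else {
    fit <- aov(values ~ groups)
    s <- summary(fit)[[1]]
    tk <- TukeyHSD(fit)$groups
    out <- list(test = test, statistic = s[["F value"]][1],
                p_value = s[["Pr(>F)"]][1], df = s[["Df"]],
                group_means = gm,
                tukey = data.frame(contrast = rownames(tk),
                                   diff = tk[, "diff"],
                                   p_adj = tk[, "p adj"], row.names = NULL))
  }
  structure(out, class = "group_comparison")
}

#' Correlate fragment means of two response variables
#'
#' Pearson correlation across fragments (inter-specific scale), e.g.
#' macroporosity vs microporosity fragment means.
#'
#' @param x,y Fragment means of the two variables (>= 3 fragments).
#' @return A `"correlation_result"` (method `"pearson"`).
#' @export
interspecific_correlation <- function(x, y) {
  correlate_profiles(x, y, method = "pearson")
}
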