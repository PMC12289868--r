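## Independent brute-force oracles used to check the package's vectorized
## implementations. These stay deliberately naive: explicit queues and
## textbook formulas, no shared code with R/.

## reference 6-connectivity flood fill: coordinate queue, scalar loops
brute_flood <- function(open, seeds = "boundary") {
  d <- dim(open)
  vis <- array(FALSE, d)
  q <- list()
  push <- function(x, y, z) q[[length(q) + 1L]] <<- c(x, y, z)
  if (identical(seeds, "boundary")) {
    for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
      if ((x == 1 || x == d[1] || y == 1 || y == d[2] ||
           z == 1 || z == d[3]) && open[x, y, z] && !vis[x, y, z]) {
        vis[x, y, z] <- TRUE; push(x, y, z)
      }
    }
  } else {
    for (s in seeds) {
      co <- arrayInd(s, d)
      if (open[co[1], co[2], co[3]]) {
        vis[co[1], co[2], co[3]] <- TRUE; push(co[1], co[2], co[3])
      }
    }
  }
  nb <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
              c(0, 0, 1), c(0, 0, -1))
  while (length(q)) {
    v <- q[[length(q)]]; q[[length(q)]] <- NULL
    for (r in 1:6) {
      p <- v + nb[r, ]
      if (all(p >= 1) && all(p <= d) && open[p[1], p[2], p[3]] &&
          !vis[p[1], p[2], p[3]]) {
        vis[p[1], p[2], p[3]] <- TRUE
        q[[length(q) + 1L]] <- p
      }
    }
  }
  vis
}

## textbook Spearman (no ties): 1 - 6*sum(d^2) / (n^3 - n)
brute_spearman <- function(x, y) {
  dr <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(dr^2) / (n^3 - n)
}

## Kruskal-Wallis H by the rank-sum formula (no tie correction needed for
## distinct values)
brute_kruskal_h <- function(values, groups) {
  r <- rank(values)
  n <- length(values)
  h <- 0
  for (g in unique(groups)) {
    rg <- r[groups == g]
    h <- h + length(rg) * (mean(rg) - (n + 1) / 2)^2
  }
  12 / (n * (n + 1)) * h
}

## Pearson R from the covariance formula
brute_pearson <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

## small phantom settings used across unit tests (fast: ~0.6 Mvoxel)
small_phantom <- function(seed, ...) {
  generate_phantom(synthetic_truth(seed = seed, ...),
                   dims = c(60L, 60L, 160L))
}

## fabricate a minimal porosity_map object from per-window phase counts
fake_map <- function(counts, k = NULL, window_vox = 5L,
                     voxel_size_um = 180) {
  n <- nrow(counts)
  if (is.null(k)) k <- seq_len(n) - 1L
  colony <- counts$n_solid + counts$n_micropore + counts$n_air
  w_eff <- window_vox * voxel_size_um / 1000
  df <- data.frame(
    i = 0L, j = 0L, k = as.integer(k),
    cx_vox = 0L, cy_vox = 0L, cz_vox = as.integer(k) * window_vox,
    cx_mm = w_eff / 2, cy_mm = w_eff / 2, cz_mm = (k + 0.5) * w_eff,
    n_solid = counts$n_solid, n_micropore = counts$n_micropore,
    n_air = counts$n_air, n_mask = counts$n_mask,
    n_total = colony + counts$n_mask,
    mip = 100 * counts$n_micropore / colony,
    map = 100 * counts$n_air / colony,
    tp = 100 * (counts$n_micropore + counts$n_air) / colony,
    svf = 100 * counts$n_solid / colony,
    colony_fraction = colony / (colony + counts$n_mask),
    valid = TRUE)
  structure(df, class = c("porosity_map", "data.frame"),
            window_size_mm = 0.9, window_vox = as.integer(window_vox),
            voxel_size_um = voxel_size_um, fragment_id = "fake",
            grid = c(1L, 1L, max(k) + 1L),
            bbox_origin_vox = c(1L, 1L, 1L))
}
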