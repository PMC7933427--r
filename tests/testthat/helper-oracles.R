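# Independent oracles used across test files.  These deliberately avoid
# the package's own implementation paths.

# Even-odd ray casting, scalar, written independently of
# point_in_polygon (different crossing formulation; boundary handling
# irrelevant for the random interior points it is used with).
oracle_point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    if ((yi > py) != (yj > py)) {
      xint <- (xj - xi) * (py - yi) / (yj - yi) + xi
      if (px < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

# Brute-force nearest-nucleus expansion: per-pixel scan over all nucleus
# pixels, ties to the lower label.
oracle_expand <- function(nuclei, max_distance) {
  out <- nuclei
  labs <- sort(unique(nuclei[nuclei > 0]))
  pix <- lapply(labs, function(k) which(nuclei == k, arr.ind = TRUE))
  for (rr in seq_len(nrow(nuclei))) {
    for (cc in seq_len(ncol(nuclei))) {
      if (nuclei[rr, cc] > 0) next
      best <- Inf; bl <- 0L
      for (ki in seq_along(labs)) {
        p <- pix[[ki]]
        d <- sqrt(min((p[, 1] - rr)^2 + (p[, 2] - cc)^2))
        if (d < best - 1e-9) { best <- d; bl <- labs[ki] }
      }
      if (best <= max_distance) out[rr, cc] <- bl
    }
  }
  out
}

# Nearest-rank percentile by explicit sort-and-index.
oracle_nearest_rank <- function(x, p) {
  s <- sort(x)
  s[max(1, ceiling(p / 100 * length(s)))]
}

# Brute-force Venn region counts from raw dots and thresholds.
oracle_venn <- function(cells, genes, thresholds, level = "any",
                        high = 20) {
  pos <- sapply(genes, function(g) {
    thr <- thresholds$threshold[thresholds$gene == g]
    d <- cells[[paste0("dots_", g)]]
    if (level == "high") d > thr & d > high else d > thr
  })
  regions <- c(genes,
               paste(genes[c(1, 1, 2)], genes[c(2, 3, 3)], sep = "&"),
               paste(genes, collapse = "&"), "none")
  counts <- setNames(integer(length(regions)), regions)
  for (i in seq_len(nrow(cells))) {
    p <- pos[i, ]
    key <- if (!any(p)) "none" else paste(genes[p], collapse = "&")
    counts[key] <- counts[key] + 1L
  }
  counts
}

# Small disc image helper: discs of given centers/radii on a zero
# background (0-based center coordinates, pixel-center convention).
disc_image <- function(dim, centers, radii, value = 1) {
  img <- matrix(0, dim[1], dim[2])
  for (i in seq_len(nrow(centers))) {
    for (rr in seq_len(dim[1])) {
      for (cc in seq_len(dim[2])) {
        if ((cc - 1 - centers[i, 1])^2 + (rr - 1 - centers[i, 2])^2 <=
            radii[i]^2) img[rr, cc] <- value
      }
    }
  }
  img
}

# A small three-population mixture shared by several statistical tests.
mixture_populations <- function(dot_mean = 60, dot_dispersion = 0.125) {
  list(
    population_spec("P1", 0.4, expr_prob = c(A = 0.9, B = 0.6, C = 0.05),
                    dot_mean = dot_mean, dot_dispersion = dot_dispersion,
                    lamina_weights = c(I = 0.30, II = 0.50, III = 0.20)),
    population_spec("P2", 0.3, expr_prob = c(A = 0.15, B = 0.9, C = 0.4),
                    dot_mean = dot_mean, dot_dispersion = dot_dispersion,
                    lamina_weights = c(II = 0.25, III = 0.55, IV = 0.20)),
    population_spec("P3", 0.3, expr_prob = c(A = 0.05, B = 0.1, C = 0.9),
                    dot_mean = dot_mean, dot_dispersion = dot_dispersion,
                    lamina_weights = c(III = 0.15, IV = 0.45, V = 0.40)))
}

# The noiseless imaging benchmark configuration: modest dot counts so
# every ground-truth dot is resolvable at the configured separation.
noiseless_config <- function(n_cells = 200, seed = 3) {
  pops <- list(
    population_spec("P1", 0.5, expr_prob = c(A = 0.8, B = 0.3, C = 0.1),
                    dot_mean = 6, dot_dispersion = 0.1,
                    lamina_weights = c(I = 0.2, II = 0.6, III = 0.2)),
    population_spec("P2", 0.5, expr_prob = c(A = 0.1, B = 0.7, C = 0.6),
                    dot_mean = 6, dot_dispersion = 0.1,
                    lamina_weights = c(III = 0.4, IV = 0.3, V = 0.3)))
  simulation_config(populations = pops, n_cells = n_cells, noise_sd = 0,
                    background_dot_rate = 0, seed = seed)
}

# Five-gene toy matrix with group means 5, 10, 11, 100, 101 in
# normalised units (library 1e7 reads, length 1 kb).
toy_cm <- function() {
  base <- c(5, 10, 11, 100, 101)
  counts <- cbind(g1 = base * 10, g2 = base * 10)   # lib 1e7, len 1e3
  rownames(counts) <- paste0("gene", 1:5)
  colnames(counts) <- c("s1", "s2")
  normalize_counts(counts,
                   gene_lengths = setNames(rep(1000, 5), rownames(counts)),
                   library_sizes = c(s1 = 1e7, s2 = 1e7),
                   groups = c(s1 = "exc", s2 = "exc"))
}

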