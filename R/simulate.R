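#' Population specification for the tissue simulator
#'
#' A population is one mixture component of the generative co-expression
#' model: cells of a population share per-gene expression probabilities,
#' per-gene dot-count distributions (negative binomial, conditional on
#' expressing) and laminar placement weights.
#'
#' @param name population label.
#' @param weight mixture proportion (weights over all populations of a
#'   config must sum to 1).
#' @param expr_prob named numeric vector, probability in `[0, 1]` that a
#'   cell of this population expresses each gene.
#' @param dot_mean named numeric vector (> 0), mean dots per cell
#'   conditional on expressing.
#' @param dot_dispersion named numeric vector (>= 0) of negative-binomial
#'   dispersions phi (variance = mu + phi * mu^2); `0` gives Poisson
#'   counts.  A scalar is recycled over genes.
#' @param lamina_weights named numeric vector of placement weights over
#'   lamina names; must sum to 1.
#' @return object of class `population_spec`.
#' @export
population_spec <- function(name, weight, expr_prob, dot_mean,
                            dot_dispersion = 0.2, lamina_weights) {
  genes <- names(expr_prob)
  stopifnot(!is.null(genes), all(nzchar(genes)))
  stopifnot(all(expr_prob >= 0 & expr_prob <= 1))
  if (length(dot_mean) == 1) dot_mean <- setNames(rep(dot_mean, length(genes)), genes)
  if (length(dot_dispersion) == 1)
    dot_dispersion <- setNames(rep(dot_dispersion, length(genes)), genes)
  stopifnot(all(genes %in% names(dot_mean)), all(genes %in% names(dot_dispersion)))
  stopifnot(all(dot_mean[genes] > 0), all(dot_dispersion[genes] >= 0))
  stopifnot(abs(sum(lamina_weights) - 1) < 1e-8, all(lamina_weights >= 0))
  structure(list(name = name, weight = weight,
                 expr_prob = expr_prob,
                 dot_mean = dot_mean[genes],
                 dot_dispersion = dot_dispersion[genes],
                 lamina_weights = lamina_weights),
            class = "population_spec")
}

#' Simulation configuration
#'
#' Bundles the tissue template, the population mixture and the imaging /
#' rendering parameters of the synthetic dorsal-horn generator.  Defaults
#' mirror the study design the pipeline was built for: 3 animals with 2
#' hemisections per animal per probe combination.
#'
#' @param template a [tissue_template()].
#' @param populations list of [population_spec()]; weights must sum to 1.
#' @param n_cells cells per hemisection.
#' @param nucleus_radius_mean,nucleus_radius_sd nucleus disc radius, px;
#'   drawn from a normal truncated below at 1.5 px.
#' @param soma_expansion soma expansion distance beyond the nucleus, px.
#' @param spot_sigma rendered spot point-spread sigma, px.
#' @param spot_amplitude rendered spot peak amplitude (image units, 0-1).
#' @param noise_sd camera noise standard deviation (image units).
#' @param background_dot_rate expected stray dots per cell-equivalent
#'   area per channel; the cell-equivalent area is
#'   `pi * (nucleus_radius_mean + soma_expansion)^2` px^2.
#' @param n_animals,hemisections_per_animal study design.
#' @param spot_min_separation minimum distance between two rendered spots
#'   of the same channel, px (keeps ground-truth dots resolvable by the
#'   detector in noiseless benchmarks).
#' @param nucleus_min_gap minimum gap between nucleus disc borders, px.
#' @param seed default RNG seed used by the generators.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(template = default_template(),
                              populations,
                              n_cells = 300,
                              nucleus_radius_mean = 4,
                              nucleus_radius_sd = 0.7,
                              soma_expansion = 4,
                              spot_sigma = 0.7,
                              spot_amplitude = 0.5,
                              noise_sd = 0.01,
                              background_dot_rate = 0.5,
                              n_animals = 3,
                              hemisections_per_animal = 2,
                              spot_min_separation = 3,
                              nucleus_min_gap = 0.5,
                              seed = 1L) {
  stopifnot(inherits(template, "tissue_template"))
  stopifnot(length(populations) >= 1,
            all(vapply(populations, inherits, TRUE, "population_spec")))
  w <- vapply(populations, `[[`, 1.0, "weight")
  if (abs(sum(w) - 1) > 1e-8) stop("population weights must sum to 1")
  genes <- unique(unlist(lapply(populations, function(p) names(p$expr_prob))))
  for (p in populations) {
    if (!all(names(p$lamina_weights) %in% names(template$laminae)))
      stop("population ", p$name, " places cells in unknown laminae")
  }
  stopifnot(n_cells > 0, nucleus_radius_mean > 0, nucleus_radius_sd >= 0,
            soma_expansion >= 0, spot_sigma > 0, background_dot_rate >= 0,
            n_animals >= 1, hemisections_per_animal >= 1,
            nucleus_min_gap >= 0)
  bb <- polygon_bbox(template$region_outline)
  dim_img <- c(ceiling(bb["ymax"] + 10), ceiling(bb["xmax"] + 10))
  structure(list(template = template, populations = populations,
                 genes = genes, n_cells = n_cells,
                 nucleus_radius_mean = nucleus_radius_mean,
                 nucleus_radius_sd = nucleus_radius_sd,
                 soma_expansion = soma_expansion,
                 spot_sigma = spot_sigma, spot_amplitude = spot_amplitude,
                 noise_sd = noise_sd,
                 background_dot_rate = background_dot_rate,
                 n_animals = n_animals,
                 hemisections_per_animal = hemisections_per_animal,
                 spot_min_separation = spot_min_separation,
                 nucleus_min_gap = nucleus_min_gap,
                 image_dim = unname(dim_img), seed = seed),
            class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("simulation_config:", length(x$populations), "populations,",
      length(x$genes), "genes (", paste(x$genes, collapse = ", "), ")\n")
  cat(sprintf("  %d cells/hemisection, %d animals x %d hemisections, image %d x %d px\n",
              x$n_cells, x$n_animals, x$hemisections_per_animal,
              x$image_dim[1], x$image_dim[2]))
  cat(sprintf("  background %.3g dots/cell-equivalent, noise sd %.3g\n",
              x$background_dot_rate, x$noise_sd))
  invisible(x)
}

# Expected soma area used to convert the per-cell background rate into a
# per-pixel Poisson intensity.
cell_equivalent_area <- function(config) {
  pi * (config$nucleus_radius_mean + config$soma_expansion)^2
}

# --- cell placement -------------------------------------------------------

.truncnorm <- function(n, mean, sd, lower) {
  x <- rnorm(n, mean, sd)
  bad <- x < lower
  tries <- 0
  while (any(bad) && tries < 50) {
    x[bad] <- rnorm(sum(bad), mean, sd)
    bad <- x < lower
    tries <- tries + 1
  }
  x[bad] <- lower
  x
}

.place_cells <- function(config, max_tries_per_cell = 400) {
  tpl <- config$template
  n <- config$n_cells
  pops <- config$populations
  w <- vapply(pops, `[[`, 1.0, "weight")
  pop_idx <- sample.int(length(pops), n, replace = TRUE, prob = w)
  H <- config$image_dim[1]; W <- config$image_dim[2]
  xs <- ys <- rs <- numeric(n)
  lam <- character(n)
  for (i in seq_len(n)) {
    p <- pops[[pop_idx[i]]]
    lw <- p$lamina_weights
    # lamina drawn once per cell so crowding cannot distort the
    # configured placement weights; only the position is retried
    li <- sample(names(lw), 1, prob = lw)
    placed <- FALSE
    tries <- 0
    while (!placed && tries < max_tries_per_cell) {
      pt <- sample_in_polygon(1, tpl$laminae[[li]])
      r <- .truncnorm(1, config$nucleus_radius_mean,
                      config$nucleus_radius_sd, lower = 1.5)
      ok <- pt[1] - r >= 1 && pt[1] + r <= W - 2 &&
        pt[2] - r >= 1 && pt[2] + r <= H - 2
      if (ok && i > 1) {
        j <- seq_len(i - 1)
        d2 <- (xs[j] - pt[1])^2 + (ys[j] - pt[2])^2
        ok <- all(d2 > (rs[j] + r + config$nucleus_min_gap)^2)
      }
      if (ok) {
        xs[i] <- pt[1]; ys[i] <- pt[2]; rs[i] <- r; lam[i] <- li
        placed <- TRUE
      }
      tries <- tries + 1
    }
    if (!placed)
      stop("could not place ", n, " non-overlapping nuclei in the template ",
           "(failed at cell ", i, "); reduce n_cells or enlarge the template")
  }
  data.frame(cell = seq_len(n), x = xs, y = ys, nucleus_radius = rs,
             population = vapply(pops[pop_idx], `[[`, "", "name"),
             lamina_true = lam, stringsAsFactors = FALSE)
}

# Render nucleus discs as a label map, then expand to somata with the
# same nearest-nucleus rule used by the segmentation stage, so that the
# simulator's ground-truth somata and the pipeline's secondary objects
# obey an identical geometry.
.cell_label_maps <- function(cells, dim, soma_expansion) {
  nuc <- matrix(0L, dim[1], dim[2])
  xs <- seq_len(dim[2]) - 1  # pixel-center x per column
  for (i in seq_len(nrow(cells))) {
    r <- cells$nucleus_radius[i]
    cx <- cells$x[i]; cy <- cells$y[i]
    rows <- max(1, floor(cy - r)):min(dim[1], ceiling(cy + r) + 1)
    cols <- max(1, floor(cx - r)):min(dim[2], ceiling(cx + r) + 1)
    for (rr in rows) {
      yy <- rr - 1
      dx2 <- r^2 - (yy - cy)^2
      if (dx2 < 0) next
      sel <- cols[abs(xs[cols] - cx) <= sqrt(dx2)]
      nuc[rr, sel] <- i
    }
  }
  soma <- expand_to_soma(nuc, soma_expansion)
  list(nuclei = nuc, somata = soma)
}

.draw_expression <- function(cells, config) {
  genes <- config$genes
  pops <- config$populations
  names(pops) <- vapply(pops, `[[`, "", "name")
  n <- nrow(cells)
  expr <- matrix(FALSE, n, length(genes), dimnames = list(NULL, genes))
  dots <- matrix(0L, n, length(genes), dimnames = list(NULL, genes))
  for (pn in names(pops)) {
    idx <- which(cells$population == pn)
    if (!length(idx)) next
    p <- pops[[pn]]
    for (g in genes) {
      pg <- if (g %in% names(p$expr_prob)) p$expr_prob[[g]] else 0
      e <- runif(length(idx)) < pg
      expr[idx, g] <- e
      ne <- sum(e)
      if (ne) {
        mu <- p$dot_mean[[g]]; phi <- p$dot_dispersion[[g]]
        dots[idx[e], g] <- if (phi > 0) rnbinom(ne, mu = mu, size = 1 / phi)
                           else rpois(ne, mu)
      }
    }
  }
  list(expr = expr, dots = dots)
}

# Place each spot inside its parent's soma such that the rounded pixel
# and its 8 neighbours all carry the parent label (so any detector
# position within ~1 px of the truth maps back to the right cell),
# respecting the same-channel minimum separation.  Random rejection
# sampling first; if a soma is too crowded for that, fall back to greedy
# farthest-point placement on the soma's interior pixel centers.  Dots
# beyond a soma's packing capacity at the configured separation are
# dropped and the cell's true count reduced accordingly (finite soma
# area bounds the number of resolvable dots); the number dropped is
# returned so callers can surface it.
.place_spots <- function(cells, dots, somata, config) {
  dimS <- dim(somata)
  sep <- config$spot_min_separation
  sep2 <- sep^2
  # interior pixels (3x3 neighbourhood uniformly labelled) per cell
  inner <- somata
  inner[] <- 0L
  core <- somata[2:(dimS[1] - 1), 2:(dimS[2] - 1)]
  uni <- core > 0
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    uni <- uni & (somata[2:(dimS[1] - 1) + dr, 2:(dimS[2] - 1) + dc] == core)
  }
  inner[2:(dimS[1] - 1), 2:(dimS[2] - 1)][uni] <- core[uni]
  cand_idx <- which(inner > 0)
  cand_lab <- inner[cand_idx]
  cand_x <- (cand_idx - 1) %/% dimS[1]   # 0-based pixel-center x
  cand_y <- (cand_idx - 1) %% dimS[1]
  ord <- order(cand_lab)
  cand_lab <- cand_lab[ord]; cand_x <- cand_x[ord]; cand_y <- cand_y[ord]
  cell_starts <- c(0, cumsum(tabulate(cand_lab, nbins = nrow(cells))))

  dropped <- 0L
  out <- vector("list", ncol(dots))
  for (gi in seq_len(ncol(dots))) {
    g <- colnames(dots)[gi]
    total <- sum(dots[, gi])
    px <- py <- numeric(total)
    pc <- integer(total)
    k <- 0L
    for (i in seq_len(nrow(cells))) {
      nd <- dots[i, gi]
      if (!nd) next
      ci <- (cell_starts[i] + 1):cell_starts[i + 1]
      if (cell_starts[i] == cell_starts[i + 1])
        stop("soma of cell ", i, " has no interior pixels; enlarge ",
             "nucleus radius or soma expansion")
      cxs <- cand_x[ci]; cys <- cand_y[ci]
      cx <- cells$x[i]; cy <- cells$y[i]
      rmax <- cells$nucleus_radius[i] + config$soma_expansion - 0.8
      placed_this_cell <- 0L
      for (s in seq_len(nd)) {
        ok <- FALSE; tries <- 0
        while (!ok && tries < 60) {
          u <- sqrt(runif(1)) * rmax
          a <- runif(1, 0, 2 * pi)
          sx <- cx + u * cos(a); sy <- cy + u * sin(a)
          r0 <- round(sy) + 1; c0 <- round(sx) + 1
          if (r0 > 1 && r0 < dimS[1] && c0 > 1 && c0 < dimS[2] &&
              inner[r0, c0] == i) {
            if (k == 0L || all((px[seq_len(k)] - sx)^2 + (py[seq_len(k)] - sy)^2 >= sep2)) {
              ok <- TRUE
            }
          }
          tries <- tries + 1
        }
        if (!ok) {
          # greedy farthest-point over the soma's interior pixel centers
          d2 <- rep(Inf, length(cxs))
          if (k > 0) {
            near <- which((px[seq_len(k)] - cx)^2 + (py[seq_len(k)] - cy)^2 <
                            (rmax + sep + 2)^2)
            for (j in near) {
              d2 <- pmin(d2, (cxs - px[j])^2 + (cys - py[j])^2)
            }
          }
          best <- which.max(d2)
          if (d2[best] < sep2) {
            # soma saturated: drop this cell's remaining dots
            dropped <- dropped + (nd - s + 1L)
            dots[i, gi] <- placed_this_cell
            break
          }
          sx <- cxs[best]; sy <- cys[best]
        }
        k <- k + 1L
        px[k] <- sx; py[k] <- sy; pc[k] <- i
        placed_this_cell <- placed_this_cell + 1L
      }
    }
    out[[gi]] <- data.frame(x = px[seq_len(k)], y = py[seq_len(k)],
                            gene = rep(g, k), cell = pc[seq_len(k)],
                            stringsAsFactors = FALSE)
  }
  list(spots = do.call(rbind, out), dots = dots, dropped = dropped)
}

.background_spots <- function(config, existing_spots = NULL) {
  H <- config$image_dim[1]; W <- config$image_dim[2]
  lambda <- config$background_dot_rate * (H * W) / cell_equivalent_area(config)
  out <- vector("list", length(config$genes))
  for (gi in seq_along(config$genes)) {
    g <- config$genes[gi]
    nb <- rpois(1, lambda)
    if (!nb) { out[[gi]] <- NULL; next }
    bx <- runif(nb, 0, W - 1); by <- runif(nb, 0, H - 1)
    out[[gi]] <- data.frame(x = bx, y = by, gene = g, cell = 0L,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

.assemble_ground_truth <- function(cells, expr, dots, spots, maps,
                                   config, animal, section) {
  genes <- config$genes
  area <- tabulate(maps$somata[maps$somata > 0], nbins = nrow(cells))
  cdf <- cells
  cdf$area <- area
  cdf$animal <- animal
  cdf$section <- section
  for (g in genes) {
    cdf[[paste0("expr_", g)]] <- expr[, g]
    cdf[[paste0("dots_", g)]] <- as.integer(dots[, g])
  }
  if (is.null(spots))
    spots <- data.frame(x = numeric(0), y = numeric(0),
                        gene = character(0), cell = integer(0))
  structure(list(cells = cdf, spots = spots,
                 nuclei = maps$nuclei, somata = maps$somata,
                 genes = genes, animal = animal, section = section),
            class = "tissue_ground_truth")
}

#' @export
print.tissue_ground_truth <- function(x, ...) {
  cat("tissue_ground_truth: ", nrow(x$cells), " cells, ",
      nrow(x$spots), " spots (", sum(x$spots$cell == 0),
      " background), genes: ", paste(x$genes, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Generate a synthetic dorsal-horn section
#'
#' Places non-overlapping nuclei inside the template's laminar bands
#' (lamina sampled from each population's placement weights, position
#' uniform within the lamina polygon), draws per-cell expression and dot
#' counts from the population mixture, places each dot inside its cell's
#' soma, adds diffuse background dots as a uniform Poisson process, and
#' optionally renders the multi-channel image (one nuclear channel plus
#' one channel per gene).
#'
#' @param config a [simulation_config()].
#' @param animal,section identifiers stored in the ground truth.
#' @param seed RNG seed (defaults to `config$seed`); identical config and
#'   seed give bit-identical output.
#' @param render if `FALSE`, skip image rendering and return `NULL` for
#'   the image stack (ground truth only; much faster).
#' @return list with elements `image` (an `image_stack` or `NULL`) and
#'   `truth` (a `tissue_ground_truth` with per-cell and per-spot records
#'   plus the ground-truth nucleus/soma label maps).
#' @export
generate_tissue <- function(config, animal = 1L, section = 1L,
                            seed = config$seed, render = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  cells <- .place_cells(config)
  maps <- .cell_label_maps(cells, config$image_dim, config$soma_expansion)
  de <- .draw_expression(cells, config)
  pl <- .place_spots(cells, de$dots, maps$somata, config)
  bg <- .background_spots(config)
  all_spots <- rbind(pl$spots, bg)
  gt <- .assemble_ground_truth(cells, de$expr, pl$dots, all_spots, maps,
                               config, animal, section)
  attr(gt, "dropped_spots") <- pl$dropped
  img <- if (render) render_image_stack(gt, config) else NULL
  list(image = img, truth = gt)
}

#' Generate a matched negative-control section
#'
#' Identical nucleus rendering and cell placement process, but the probe
#' channels contain only background dots at `background_dot_rate`; all
#' spots are marked as background in the ground truth.
#'
#' @inheritParams generate_tissue
#' @return as [generate_tissue()].
#' @export
generate_negative_control <- function(config, animal = 1L, section = 1L,
                                      seed = config$seed, render = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  cells <- .place_cells(config)
  maps <- .cell_label_maps(cells, config$image_dim, config$soma_expansion)
  genes <- config$genes
  expr <- matrix(FALSE, nrow(cells), length(genes), dimnames = list(NULL, genes))
  dots <- matrix(0L, nrow(cells), length(genes), dimnames = list(NULL, genes))
  bg <- .background_spots(config)
  gt <- .assemble_ground_truth(cells, expr, dots, bg, maps,
                               config, animal, section)
  img <- if (render) render_image_stack(gt, config) else NULL
  list(image = img, truth = gt)
}

# --- rendering ------------------------------------------------------------

#' Render an image stack from ground truth
#'
#' Nuclei are rendered as filled discs in the nuclear channel; each spot
#' adds a Gaussian blob of amplitude `spot_amplitude` and sigma
#' `spot_sigma` to its probe channel; Gaussian camera noise of sd
#' `noise_sd` is added to every channel and values are clamped to
#' `[0, 1]`.
#'
#' @param truth a `tissue_ground_truth`.
#' @param config the [simulation_config()] used to generate it.
#' @return an `image_stack`: list with `images` (named list of numeric
#'   matrices in `[0, 1]`) and `channels` (data frame of name/role).
#' @export
render_image_stack <- function(truth, config) {
  dimI <- dim(truth$nuclei)
  nuclear <- matrix(0.02, dimI[1], dimI[2])
  nuclear[truth$nuclei > 0] <- 0.65
  imgs <- list(nuclear = nuclear)
  win <- ceiling(4 * config$spot_sigma)
  for (g in truth$genes) {
    ch <- matrix(0.0, dimI[1], dimI[2])
    sp <- truth$spots[truth$spots$gene == g, , drop = FALSE]
    if (nrow(sp)) {
      for (i in seq_len(nrow(sp))) {
        cx <- sp$x[i]; cy <- sp$y[i]
        rows <- max(1, round(cy) + 1 - win):min(dimI[1], round(cy) + 1 + win)
        cols <- max(1, round(cx) + 1 - win):min(dimI[2], round(cx) + 1 + win)
        dy2 <- ((rows - 1) - cy)^2
        dx2 <- ((cols - 1) - cx)^2
        blob <- config$spot_amplitude *
          exp(-(outer(dy2, dx2, `+`)) / (2 * config$spot_sigma^2))
        ch[rows, cols] <- ch[rows, cols] + blob
      }
    }
    imgs[[g]] <- ch
  }
  if (config$noise_sd > 0) {
    imgs <- lapply(imgs, function(m)
      m + matrix(rnorm(length(m), 0, config$noise_sd), nrow(m)))
  }
  imgs <- lapply(imgs, function(m) pmin(pmax(m, 0), 1))
  channels <- data.frame(name = names(imgs),
                         role = c("nuclear", rep("probe", length(truth$genes))),
                         stringsAsFactors = FALSE)
  structure(list(images = imgs, channels = channels), class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$images[[1]])
  cat("image_stack: ", length(x$images), " channels (",
      paste(x$channels$name, collapse = ", "), "), ",
      d[1], " x ", d[2], " px\n", sep = "")
  invisible(x)
}

# --- fast measurement path ------------------------------------------------

#' Simulate a measured cell table without rendering
#'
#' Produces the cell table an ideal pipeline (ground-truth segmentation
#' plus perfect spot detection) would measure: per-cell dots equal the
#' true dot counts plus the background dots whose positions fall inside
#' the cell's soma label.  This is the fast path for statistical
#' benchmarks where rendering and re-detecting tens of thousands of spots
#' adds nothing.
#'
#' @inheritParams generate_tissue
#' @param negative_control if `TRUE`, suppress all expression so that
#'   probe channels carry background dots only.
#' @return list with `cells` (measured `CellTable`: cell, x, y, area,
#'   lamina_true, population, animal, section, `dots_<gene>` columns) and
#'   `truth` (data frame with true `expr_`/`dots_` columns), plus the
#'   soma label map.
#' @export
simulate_cell_table <- function(config, animal = 1L, section = 1L,
                                seed = config$seed,
                                negative_control = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  cells <- .place_cells(config)
  maps <- .cell_label_maps(cells, config$image_dim, config$soma_expansion)
  genes <- config$genes
  if (negative_control) {
    expr <- matrix(FALSE, nrow(cells), length(genes), dimnames = list(NULL, genes))
    dots <- matrix(0L, nrow(cells), length(genes), dimnames = list(NULL, genes))
  } else {
    de <- .draw_expression(cells, config)
    expr <- de$expr; dots <- de$dots
  }
  bg <- .background_spots(config)
  measured <- dots
  if (!is.null(bg) && nrow(bg)) {
    lab <- maps$somata[cbind(round(bg$y) + 1, round(bg$x) + 1)]
    keep <- lab > 0
    if (any(keep)) {
      tb <- table(factor(lab[keep], levels = seq_len(nrow(cells))),
                  factor(bg$gene[keep], levels = genes))
      measured <- measured + as.matrix(unclass(tb))
    }
  }
  area <- tabulate(maps$somata[maps$somata > 0], nbins = nrow(cells))
  out <- data.frame(cell = cells$cell, x = cells$x, y = cells$y,
                    area = area, population = cells$population,
                    lamina_true = cells$lamina_true,
                    animal = animal, section = section,
                    stringsAsFactors = FALSE)
  for (g in genes) out[[paste0("dots_", g)]] <- as.integer(measured[, g])
  truth <- cells
  for (g in genes) {
    truth[[paste0("expr_", g)]] <- expr[, g]
    truth[[paste0("dots_", g)]] <- as.integer(dots[, g])
  }
  list(cells = out, truth = truth, somata = maps$somata)
}

#' Simulate one probe combination across the whole study design
#'
#' Loops over `n_animals` x `hemisections_per_animal`, simulating one
#' measured cell table per hemisection, plus one matched negative-control
#' hemisection for the combination (the study hybridised one
#' negative-control hemisection per combination).
#'
#' @param config a [simulation_config()].
#' @param seed base RNG seed; hemisection s of animal a uses
#'   `seed + 97 * a + s`, the negative control uses `seed + 9001`.
#' @return list with `cells` (row-bound measured cell tables),
#'   `negctrl` (negative-control cell table) and `truth` (row-bound truth
#'   tables).
#' @export
simulate_combination <- function(config, seed = config$seed) {
  cells <- list(); truth <- list()
  for (a in seq_len(config$n_animals)) {
    for (s in seq_len(config$hemisections_per_animal)) {
      sim <- simulate_cell_table(config, animal = a, section = s,
                                 seed = seed + 97L * a + s)
      cells[[length(cells) + 1L]] <- sim$cells
      tr <- sim$truth; tr$animal <- a; tr$section <- s
      truth[[length(truth) + 1L]] <- tr
    }
  }
  nc <- simulate_cell_table(config, animal = 0L, section = 0L,
                            seed = seed + 9001L, negative_control = TRUE)
  list(cells = do.call(rbind, cells), negctrl = nc$cells,
       truth = do.call(rbind, truth))
}

# --- closed-form expectations --------------------------------------------

#' Closed-form co-expression fractions of the generative model
#'
#' Computes, from the population mixture alone, the expected fraction of
#' cells measured positive for gene `g` that are also measured positive
#' for gene `h`, when positivity is "more than `threshold` dots" and
#' measured dots are true dots plus Poisson background at the configured
#' rate.  Used as the ground-truth reference in parameter-recovery tests.
#'
#' @param config a [simulation_config()].
#' @param threshold dots-per-cell positivity threshold (strict `>`).
#' @return list with `fraction` (gene x gene matrix, percent), `p_gene`
#'   (marginal positive probabilities) and `p_joint`.
#' @export
expected_coexpression <- function(config, threshold = 20) {
  genes <- config$genes
  r <- config$background_dot_rate
  # P(NB(mu, phi) + Pois(r) > t) by convolution over the background count
  p_exceed <- function(mu, phi, t) {
    j <- 0:ceiling(max(10, r + 10 * sqrt(r + 1)))
    wbg <- dpois(j, r)
    tail_nb <- if (phi > 0) 1 - pnbinom(t - j, mu = mu, size = 1 / phi)
               else 1 - ppois(t - j, mu)
    tail_nb[t - j < 0] <- 1
    sum(wbg * tail_nb)
  }
  p_bg_only <- 1 - ppois(threshold, r)
  npop <- length(config$populations)
  ppos <- matrix(0, npop, length(genes), dimnames = list(NULL, genes))
  w <- vapply(config$populations, `[[`, 1.0, "weight")
  for (k in seq_len(npop)) {
    pop <- config$populations[[k]]
    for (g in genes) {
      pg <- if (g %in% names(pop$expr_prob)) pop$expr_prob[[g]] else 0
      pe <- if (pg > 0) p_exceed(pop$dot_mean[[g]], pop$dot_dispersion[[g]],
                                 threshold) else 0
      ppos[k, g] <- pg * pe + (1 - pg) * p_bg_only
    }
  }
  p_gene <- colSums(w * ppos)
  p_joint <- matrix(NA_real_, length(genes), length(genes),
                    dimnames = list(genes, genes))
  for (g in genes) for (h in genes) {
    p_joint[g, h] <- if (g == h) p_gene[g] else sum(w * ppos[, g] * ppos[, h])
  }
  fraction <- 100 * sweep(p_joint, 1, p_gene, "/")
  list(fraction = fraction, p_gene = p_gene, p_joint = p_joint)
}
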