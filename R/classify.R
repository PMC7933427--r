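#' Background thresholds from a negative control
#'
#' For every probe channel, the dots-per-cell distribution measured in
#' the matched negative-control section defines the background: the
#' nearest-rank percentile (default 90th) of that distribution is the
#' threshold above which a cell counts as positive.  On integer count
#' data the nearest-rank convention keeps thresholds attainable values.
#'
#' @param negctrl_cells negative-control `CellTable` with `dots_<gene>`
#'   columns.
#' @param percentile percentile in (0, 100]; the threshold is the value
#'   at sorted rank `ceiling(percentile/100 * n)`.
#' @param genes channels to calibrate; defaults to all `dots_` columns.
#' @return `threshold_set` data frame: `gene`, `threshold`, `percentile`,
#'   `n_cells`.
#' @export
background_threshold <- function(negctrl_cells, percentile = 90,
                                 genes = NULL) {
  stopifnot(is.data.frame(negctrl_cells))
  stopifnot(percentile > 0, percentile <= 100)
  if (nrow(negctrl_cells) == 0)
    stop("negative-control cell table is empty; cannot calibrate")
  if (is.null(genes)) genes <- cell_table_genes(negctrl_cells)
  if (!length(genes)) stop("no dots_<gene> columns found")
  thr <- vapply(genes, function(g) {
    x <- sort(negctrl_cells[[paste0("dots_", g)]])
    x[max(1L, ceiling(percentile / 100 * length(x)))]
  }, 0.0)
  structure(data.frame(gene = genes, threshold = unname(thr),
                       percentile = percentile,
                       n_cells = nrow(negctrl_cells),
                       stringsAsFactors = FALSE),
            class = c("threshold_set", "data.frame"))
}

#' Call cells negative / positive / high per gene
#'
#' A cell is *positive* for a gene when its dots-per-cell count is
#' strictly above the calibrated background threshold, and *high* when it
#' is additionally strictly above the high-expression threshold
#' (default 20 dots/cell).  High implies positive; calls for different
#' genes are independent.
#'
#' @param cells `CellTable` with `dots_<gene>` columns.
#' @param thresholds a [background_threshold()] result covering every
#'   gene present in `cells`.
#' @param high_threshold high-expression threshold (strict `>`).
#' @return the cell table with added `call_<gene>` factor columns
#'   (levels `negative`, `positive`, `high`), carrying the thresholds as
#'   attribute `thresholds` and class `positivity_calls`.
#' @export
call_positive <- function(cells, thresholds, high_threshold = 20) {
  genes <- cell_table_genes(cells)
  missing <- setdiff(genes, thresholds$gene)
  if (length(missing))
    stop("no background threshold for channel(s): ",
         paste(missing, collapse = ", "))
  out <- cells
  for (g in genes) {
    thr <- thresholds$threshold[thresholds$gene == g]
    d <- cells[[paste0("dots_", g)]]
    pos <- d > thr
    high <- pos & d > high_threshold
    out[[paste0("call_", g)]] <-
      factor(ifelse(high, "high", ifelse(pos, "positive", "negative")),
             levels = c("negative", "positive", "high"))
  }
  attr(out, "thresholds") <- thresholds
  attr(out, "high_threshold") <- high_threshold
  class(out) <- c("positivity_calls", "data.frame")
  out
}

# logical positivity of a calls table at a stringency level
.level_pos <- function(calls, gene, level = c("any", "high")) {
  level <- match.arg(level)
  col <- calls[[paste0("call_", gene)]]
  if (is.null(col)) stop("gene ", gene, " absent from calls")
  if (level == "any") col %in% c("positive", "high") else col == "high"
}

#' Triple-probe (co-)expression Venn counts
#'
#' Counts, per animal (hemisections of one animal pooled), the cells in
#' each of the 7 Venn regions of a 3-gene probe combination plus the
#' triple-negative remainder.  The regions partition the cells.
#'
#' @param calls a [call_positive()] result containing `animal` ids.
#' @param genes character vector of exactly 3 genes.
#' @param level `"any"` (positive or high) or `"high"`.
#' @return data frame with columns `animal`, `region` (gene names joined
#'   by `&`, or `"none"`), `count`.
#' @export
venn_counts <- function(calls, genes, level = c("any", "high")) {
  level <- match.arg(level)
  stopifnot(length(genes) == 3)
  pos <- sapply(genes, function(g) .level_pos(calls, g, level))
  regions <- c(genes,
               paste(genes[c(1, 1, 2)], genes[c(2, 3, 3)], sep = "&"),
               paste(genes, collapse = "&"), "none")
  membership <- apply(pos, 1, function(p) {
    if (!any(p)) "none" else paste(genes[p], collapse = "&")
  })
  out <- expand.grid(animal = sort(unique(calls$animal)), region = regions,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$count <- mapply(function(a, r)
    sum(calls$animal == a & membership == r), out$animal, out$region)
  out[order(out$animal, match(out$region, regions)), ]
}

#' Pairwise co-expression matrix across probe combinations
#'
#' For every gene pair observed together in at least one combination,
#' computes per animal (hemisections pooled) the number of cells
#' expressing gene g (`N_g`) and co-expressing g and h (`N_gh`), the
#' fraction `F[g,h] = 100 * N_gh / N_g`, then averages fractions
#' unweighted across animals.  At `level = "high"` both genes of a pair
#' must pass the high threshold by default (`high_rule = "both"`); the
#' asymmetric alternative (`"row"`: only the denominator gene must be
#' high, the other merely positive) is provided behind a flag.  Pairs
#' never co-hybridised are `NA`, not 0, and are listed in the
#' `missing_pairs` element with a warning.
#'
#' @param calls_list list of [call_positive()] results, one per probe
#'   combination; each must carry `animal` ids.
#' @param level `"any"` or `"high"`.
#' @param high_rule `"both"` or `"row"` (only used at `level = "high"`).
#' @param genes gene order of the matrix; defaults to order of first
#'   appearance across combinations.
#' @return object of class `coexpression_matrix`: list with `fraction`
#'   (gene x gene matrix, percent, across-animal mean), `n_g` / `n_gh`
#'   (pooled counts across animals), `per_animal` (long data frame),
#'   `level`, `n_animals`, `missing_pairs`.
#' @export
pairwise_matrix <- function(calls_list, level = c("any", "high"),
                            high_rule = c("both", "row"), genes = NULL) {
  level <- match.arg(level)
  high_rule <- match.arg(high_rule)
  if (inherits(calls_list, "data.frame")) calls_list <- list(calls_list)
  comb_genes <- lapply(calls_list, cell_table_genes)
  if (is.null(genes)) genes <- unique(unlist(comb_genes))
  ng <- length(genes)
  rows <- list()
  for (ci in seq_along(calls_list)) {
    calls <- calls_list[[ci]]
    gs <- intersect(genes, comb_genes[[ci]])
    for (a in sort(unique(calls$animal))) {
      sub <- calls[calls$animal == a, , drop = FALSE]
      for (g in gs) for (h in gs) {
        pg <- if (level == "high") .level_pos(sub, g, "high")
              else .level_pos(sub, g, "any")
        ph <- if (level == "high") {
          if (high_rule == "both" || g == h) .level_pos(sub, h, "high")
          else .level_pos(sub, h, "any")
        } else .level_pos(sub, h, "any")
        rows[[length(rows) + 1L]] <-
          data.frame(combination = ci, animal = a, gene = g, other = h,
                     n_g = sum(pg), n_gh = sum(pg & ph),
                     stringsAsFactors = FALSE)
      }
    }
  }
  long <- do.call(rbind, rows)
  # pool combinations observing the same pair within an animal
  pooled <- aggregate(cbind(n_g, n_gh) ~ animal + gene + other, long, sum)
  pooled$fraction <- ifelse(pooled$n_g > 0, 100 * pooled$n_gh / pooled$n_g, NA)
  fraction <- matrix(NA_real_, ng, ng, dimnames = list(genes, genes))
  n_g_mat <- n_gh_mat <- matrix(NA_real_, ng, ng, dimnames = list(genes, genes))
  for (g in genes) for (h in genes) {
    sel <- pooled$gene == g & pooled$other == h
    if (!any(sel)) next
    av <- per_animal_average(pooled$fraction[sel])
    fraction[g, h] <- av$mean
    n_g_mat[g, h] <- sum(pooled$n_g[sel])
    n_gh_mat[g, h] <- sum(pooled$n_gh[sel])
  }
  observed <- !is.na(n_g_mat)
  missing_pairs <- which(!observed & row(observed) != col(observed), arr.ind = TRUE)
  mp <- data.frame(gene = genes[missing_pairs[, 1]],
                   other = genes[missing_pairs[, 2]])
  if (nrow(mp))
    warning(nrow(mp), " gene pair(s) never co-hybridised; reported as NA")
  structure(list(genes = genes, fraction = fraction,
                 n_g = n_g_mat, n_gh = n_gh_mat,
                 per_animal = pooled, level = level, high_rule = high_rule,
                 n_animals = length(unique(long$animal)),
                 missing_pairs = mp),
            class = "coexpression_matrix")
}

#' @export
print.coexpression_matrix <- function(x, digits = 1, ...) {
  cat("coexpression_matrix (level =", x$level, ",", x$n_animals,
      "animals): % of row-gene cells also expressing the column gene\n")
  print(round(x$fraction, digits))
  if (nrow(x$missing_pairs))
    cat("missing (never co-hybridised):",
        paste(x$missing_pairs$gene, x$missing_pairs$other, sep = "/",
              collapse = ", "), "\n")
  invisible(x)
}

#' Unweighted per-animal average
#'
#' Ratios are computed per animal and then averaged without weighting.
#' With a single animal the mean is that animal's value and the sd is
#' reported as `NA` (not estimable from one animal).
#'
#' @param x numeric vector of per-animal statistics (NAs dropped).
#' @return list with `mean`, `sd`, `n`.
#' @export
per_animal_average <- function(x) {
  x <- x[!is.na(x)]
  list(mean = if (length(x)) mean(x) else NA_real_,
       sd = if (length(x) > 1) sd(x) else NA_real_,
       n = length(x))
}
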