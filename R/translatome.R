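#' Normalise raw counts by library size and gene length
#'
#' Normalised count of gene g in sample s =
#' `raw(g, s) / (library_size(s) / 1e6) / (length(g) / 1e3)` — reads per
#' kilobase of transcript per million mapped reads.  The "expressed"
#' (> 10) and "detectable by in situ" (> 100) thresholds shipped with
#' [count_expressed()] are interpreted on this scale.
#'
#' @param raw gene x sample matrix of non-negative integer counts with
#'   row (gene) and column (sample) names.
#' @param gene_lengths named vector of gene lengths, bp (> 0).
#' @param library_sizes named vector of total mapped reads per sample
#'   (> 0); defaults to the column sums of `raw`.
#' @param groups named character vector of group labels per sample.
#' @return object of class `count_matrix`: list with `counts`, `norm`,
#'   `gene_lengths`, `library_sizes`, `groups`.
#' @export
normalize_counts <- function(raw, gene_lengths, library_sizes = colSums(raw),
                             groups = NULL) {
  raw <- as.matrix(raw)
  stopifnot(!is.null(rownames(raw)), !is.null(colnames(raw)))
  if (any(raw < 0)) stop("counts must be non-negative")
  gene_lengths <- gene_lengths[rownames(raw)]
  library_sizes <- library_sizes[colnames(raw)]
  if (anyNA(gene_lengths) || any(gene_lengths <= 0))
    stop("gene lengths must be positive and cover every gene")
  if (anyNA(library_sizes) || any(library_sizes <= 0))
    stop("library sizes must be positive and cover every sample")
  norm <- raw / (gene_lengths / 1e3)
  norm <- sweep(norm, 2, library_sizes / 1e6, "/")
  if (!is.null(groups)) groups <- groups[colnames(raw)]
  structure(list(counts = raw, norm = norm, gene_lengths = gene_lengths,
                 library_sizes = library_sizes, groups = groups),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "genes x", ncol(x$counts), "samples")
  if (!is.null(x$groups))
    cat(" (groups:", paste(unique(x$groups), collapse = ", "), ")")
  cat("\n")
  invisible(x)
}

.group_means <- function(cm, group) {
  if (is.null(cm$groups)) stop("count matrix carries no group labels")
  sel <- cm$groups == group
  if (!any(sel)) stop("unknown group: ", group)
  rowMeans(cm$norm[, sel, drop = FALSE])
}

#' Named expressed-gene thresholds
#'
#' `expressed` (> 10 normalised counts) and `in_situ_detectable`
#' (> 100 normalised counts, three times below a gene reliably seen at
#' low levels in situ).
#' @export
expressed_thresholds <- c(expressed = 10, in_situ_detectable = 100)

#' Count expressed genes in a group
#'
#' Number of genes whose group-mean normalised count is strictly greater
#' than `threshold`; with `per_sample = TRUE` every sample of the group
#' must exceed the threshold instead.
#'
#' @param cm a [normalize_counts()] result with group labels.
#' @param group group label.
#' @param threshold normalised-count threshold (strict `>`).
#' @param per_sample use the per-sample minimum instead of the group
#'   mean.
#' @return integer count.
#' @export
count_expressed <- function(cm, group, threshold = expressed_thresholds["expressed"],
                            per_sample = FALSE) {
  stopifnot(threshold >= 0)
  if (per_sample) {
    sel <- cm$groups == group
    if (!any(sel)) stop("unknown group: ", group)
    v <- apply(cm$norm[, sel, drop = FALSE], 1, min)
  } else {
    v <- .group_means(cm, group)
  }
  sum(v > threshold)
}

#' Per-gene enrichment table for a two-group comparison
#'
#' Group-mean normalised counts, the fold ratio (group A over group B)
#' and an FDR column.  FDR values are an input: the published analyses
#' used dedicated differential-expression tools, which are outside this
#' package's scope; [nb_test_oracle()] supplies FDRs for simulated data.
#'
#' @param cm a [normalize_counts()] result.
#' @param group_a,group_b group labels (fold = mean A / mean B).
#' @param fdr named numeric vector of FDR values per gene, or `NULL`.
#' @return `enrichment_table` data frame: `gene`, `mean_a`, `mean_b`,
#'   `fold`, `fdr`.
#' @export
enrichment_table <- function(cm, group_a, group_b, fdr = NULL) {
  ma <- .group_means(cm, group_a)
  mb <- .group_means(cm, group_b)
  fold <- ifelse(ma == 0 & mb == 0, NA_real_, ma / mb)
  out <- data.frame(gene = rownames(cm$counts), mean_a = ma, mean_b = mb,
                    fold = fold, row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(fdr)) {
    if (!is.null(names(fdr))) fdr <- fdr[out$gene]
    out$fdr <- as.numeric(fdr)
  }
  structure(out, class = c("enrichment_table", "data.frame"),
            groups = c(group_a, group_b))
}

#' Filter differentially expressed genes
#'
#' Enriched-in-A genes satisfy `FDR <= fdr_max` and `fold >= min_fold`;
#' enriched-in-B genes satisfy `FDR <= fdr_max` and
#' `fold <= 1/min_fold`.  Both inequalities are inclusive.
#'
#' @param table an [enrichment_table()] with an `fdr` column.
#' @param fdr_max FDR cutoff (inclusive), default 0.05.
#' @param min_fold fold cutoff (inclusive), default 2.
#' @return list with `enriched_a`, `enriched_b` (character gene sets)
#'   and the cutoffs used.
#' @export
de_filter <- function(table, fdr_max = 0.05, min_fold = 2) {
  if (is.null(table$fdr)) stop("enrichment table has no fdr column")
  ok <- !is.na(table$fdr) & table$fdr <= fdr_max & !is.na(table$fold)
  list(enriched_a = table$gene[ok & table$fold >= min_fold],
       enriched_b = table$gene[ok & table$fold <= 1 / min_fold],
       fdr_max = fdr_max, min_fold = min_fold)
}

#' Congruence between two enriched gene sets
#'
#' @param set_a,set_b character vectors of gene ids.
#' @return list: `n_a`, `n_b`, `n_common`, `frac_a`, `frac_b`
#'   (percent of each set contained in the intersection; `NA` for an
#'   empty set).
#' @export
congruence <- function(set_a, set_b) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  common <- intersect(set_a, set_b)
  list(n_a = length(set_a), n_b = length(set_b), n_common = length(common),
       frac_a = if (length(set_a)) 100 * length(common) / length(set_a) else NA_real_,
       frac_b = if (length(set_b)) 100 * length(common) / length(set_b) else NA_real_)
}

#' Negative-binomial test oracle for simulated counts
#'
#' A per-gene negative-binomial GLM Wald test of the two-group difference
#' (log link, log library size offset), Benjamini-Hochberg corrected.
#' This is a plain reference test for simulated data with known
#' generative structure; it is not equivalent to the moderated
#' differential-expression analyses used on real sequencing data.
#'
#' @param cm a [normalize_counts()] result with group labels.
#' @param group_a,group_b groups to compare.
#' @return named vector of FDR values per gene.
#' @export
nb_test_oracle <- function(cm, group_a, group_b) {
  sel <- cm$groups %in% c(group_a, group_b)
  y <- cm$counts[, sel, drop = FALSE]
  grp <- factor(cm$groups[sel], levels = c(group_b, group_a))
  off <- log(cm$library_sizes[sel])
  pvals <- apply(y, 1, function(counts) {
    if (all(counts == counts[1])) return(1)
    p <- tryCatch({
      fit <- suppressWarnings(
        MASS::glm.nb(counts ~ grp + offset(off),
                     control = stats::glm.control(maxit = 50)))
      summary(fit)$coefficients["grp" %+% levels(grp)[2], 4]
    }, error = function(e) NA_real_)
    if (is.na(p)) {
      # quasi-Poisson fallback for degenerate dispersion estimates
      fit <- suppressWarnings(
        stats::glm(counts ~ grp + offset(off), family = stats::quasipoisson()))
      p <- summary(fit)$coefficients[2, 4]
    }
    p
  })
  p.adjust(pvals, method = "BH")
}

`%+%` <- function(a, b) paste0(a, b)

#' Generate a synthetic gene x sample count matrix with planted
#' enrichment
#'
#' Baseline per-gene expression is log-normal (in normalised-count
#' units); the expected raw count of gene g in sample s is
#' `base_g * fold(g, group(s)) * (length_g/1e3) * (library_size_s/1e6)`,
#' and counts are drawn from a negative binomial with dispersion
#' `dispersion` (variance `mu + dispersion * mu^2`).  `dispersion = 0`
#' is the deterministic limit: counts equal the rounded expectation.
#'
#' @param n_genes number of genes.
#' @param groups character vector, group label per sample (>= 2
#'   replicates per group).
#' @param enriched_sets named list (group -> integer gene indices) of
#'   planted enriched genes.
#' @param fold_changes fold change (>= 1) applied to planted genes in
#'   their group; scalar or list parallel to `enriched_sets`.
#' @param library_sizes per-sample library sizes; default 1e7.
#' @param gene_lengths per-gene lengths, bp; default 1000.
#' @param dispersion NB dispersion (>= 0; 0 = deterministic limit).
#' @param base_meanlog,base_sdlog log-normal baseline parameters.
#' @param base optional numeric vector of per-gene baseline expression
#'   (normalised-count units) overriding the log-normal draw.
#' @param seed RNG seed.
#' @return list with `cm` (a [normalize_counts()] result), `truth`
#'   (named list of planted gene ids per group) and `folds` (gene x
#'   group matrix of generative fold changes).
#' @export
generate_count_matrix <- function(n_genes, groups, enriched_sets = list(),
                                  fold_changes = 4,
                                  library_sizes = NULL, gene_lengths = NULL,
                                  dispersion = 0.05,
                                  base_meanlog = log(50), base_sdlog = 1,
                                  base = NULL, seed = 1L) {
  if (!is.null(seed)) set.seed(seed)
  if (dispersion < 0) stop("dispersion must be >= 0")
  tab <- table(groups)
  if (any(tab < 2)) stop("at least 2 replicates per group are required")
  n_samples <- length(groups)
  samples <- paste0("s", seq_len(n_samples), "_", groups)
  genes <- sprintf("gene%04d", seq_len(n_genes))
  if (is.null(library_sizes)) library_sizes <- rep(1e7, n_samples)
  if (is.null(gene_lengths)) gene_lengths <- rep(1000, n_genes)
  names(library_sizes) <- samples
  names(gene_lengths) <- genes
  if (is.null(base)) base <- rlnorm(n_genes, base_meanlog, base_sdlog)
  stopifnot(length(base) == n_genes, all(base > 0))
  ugroups <- unique(groups)
  folds <- matrix(1, n_genes, length(ugroups),
                  dimnames = list(genes, ugroups))
  if (length(enriched_sets)) {
    if (!is.list(fold_changes))
      fold_changes <- setNames(rep(list(fold_changes), length(enriched_sets)),
                               names(enriched_sets))
    for (g in names(enriched_sets)) {
      idx <- enriched_sets[[g]]
      fc <- rep(fold_changes[[g]], length.out = length(idx))
      if (any(fc < 1)) stop("planted fold changes must be >= 1")
      folds[idx, g] <- fc
    }
  }
  mu <- matrix(0, n_genes, n_samples, dimnames = list(genes, samples))
  for (s in seq_len(n_samples)) {
    mu[, s] <- base * folds[, groups[s]] *
      (gene_lengths / 1e3) * (library_sizes[s] / 1e6)
  }
  counts <- if (dispersion == 0) round(mu)
            else matrix(rnbinom(length(mu), mu = mu, size = 1 / dispersion),
                        n_genes, n_samples, dimnames = dimnames(mu))
  dimnames(counts) <- dimnames(mu)
  cm <- normalize_counts(counts, gene_lengths, library_sizes,
                         groups = setNames(groups, samples))
  truth <- lapply(enriched_sets, function(idx) genes[idx])
  list(cm = cm, truth = truth, folds = folds)
}
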