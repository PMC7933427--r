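#' Fit a landmark-based affine alignment
#'
#' Least-squares 2-D affine transform mapping section pixel coordinates
#' onto template coordinates from >= 3 non-collinear landmark pairs.
#'
#' @param landmarks_section,landmarks_template n x 2 matrices of matched
#'   points (x, y), n >= 3.
#' @return object of class `affine2d`: list with `A` (2 x 2 linear
#'   part), `b` (translation), `rms` (root-mean-square residual over the
#'   landmarks, px).
#' @export
fit_alignment <- function(landmarks_section, landmarks_template) {
  src <- as.matrix(landmarks_section); dst <- as.matrix(landmarks_template)
  stopifnot(ncol(src) == 2, ncol(dst) == 2, nrow(src) == nrow(dst))
  if (nrow(src) < 3) stop("at least 3 landmark pairs are required")
  X <- cbind(src, 1)
  if (qr(X)$rank < 3) stop("landmarks are collinear; affine fit is degenerate")
  beta <- qr.solve(X, dst)             # 3 x 2
  A <- t(beta[1:2, , drop = FALSE])
  b <- as.numeric(beta[3, ])
  pred <- X %*% beta
  rms <- sqrt(mean(rowSums((pred - dst)^2)))
  if (abs(det(A)) < 1e-12) stop("fitted linear part is singular")
  structure(list(A = A, b = b, rms = rms), class = "affine2d")
}

#' Build an affine transform from its components
#' @param A 2 x 2 linear part (invertible).
#' @param b length-2 translation.
#' @return an `affine2d`.
#' @export
affine2d <- function(A, b = c(0, 0)) {
  A <- matrix(as.numeric(A), 2, 2)
  if (abs(det(A)) < 1e-12) stop("linear part must be invertible")
  structure(list(A = A, b = as.numeric(b), rms = NA_real_), class = "affine2d")
}

#' @export
print.affine2d <- function(x, ...) {
  cat("affine2d: A =", paste(signif(t(x$A), 6), collapse = " "),
      " b =", paste(signif(x$b, 6), collapse = " "))
  if (!is.na(x$rms)) cat("  (landmark RMS ", signif(x$rms, 4), " px)", sep = "")
  cat("\n")
  invisible(x)
}

#' Apply / invert an affine transform
#' @param transform an `affine2d`.
#' @param points n x 2 matrix (x, y).
#' @return transformed n x 2 matrix (`apply_transform`) or the inverse
#'   `affine2d` (`invert_transform`).
#' @export
apply_transform <- function(transform, points) {
  pts <- matrix(as.numeric(as.matrix(points)), ncol = 2)
  out <- pts %*% t(transform$A)
  out[, 1] <- out[, 1] + transform$b[1]
  out[, 2] <- out[, 2] + transform$b[2]
  colnames(out) <- c("x", "y")
  out
}

#' @rdname apply_transform
#' @export
invert_transform <- function(transform) {
  Ai <- solve(transform$A)
  structure(list(A = Ai, b = as.numeric(-Ai %*% transform$b), rms = NA_real_),
            class = "affine2d")
}

#' Assign each cell to a lamina
#'
#' Maps cell centroids through the section-to-template transform and
#' assigns each to the first lamina polygon (dorsal-to-ventral template
#' order) containing the mapped point; on-boundary points therefore go to
#' the dorsal-most matching lamina.  Cells in no lamina get `"outside"`.
#'
#' @param cells `CellTable` with `x`, `y` columns (section frame).
#' @param template a [tissue_template()].
#' @param transform an `affine2d` mapping section to template
#'   coordinates, or `NULL` for identity.
#' @return the cell table with a `lamina` column (factor over the
#'   template's lamina names plus `"outside"`).
#' @export
assign_lamina <- function(cells, template, transform = NULL) {
  stopifnot(inherits(template, "tissue_template"))
  pts <- cbind(cells$x, cells$y)
  if (!is.null(transform)) pts <- apply_transform(transform, pts)
  lam_names <- names(template$laminae)
  assigned <- rep("outside", nrow(cells))
  unset <- rep(TRUE, nrow(cells))
  for (nm in lam_names) {
    if (!any(unset)) break
    inside <- point_in_polygon(pts[unset, 1], pts[unset, 2],
                               template$laminae[[nm]])
    idx <- which(unset)[inside]
    assigned[idx] <- nm
    unset[idx] <- FALSE
  }
  cells$lamina <- factor(assigned, levels = c(lam_names, "outside"))
  cells
}

#' Per-lamina counts of expressing cells
#'
#' Counts, per hemisection, the cells passing the requested stringency
#' level for a gene within each lamina (plus `"outside"`).  Individual
#' hemisection values are kept; use [lamina_summary()] for per-lamina
#' means over hemisections.
#'
#' @param cells a [call_positive()] result that also carries a `lamina`
#'   column (see [assign_lamina()]) and `animal` / `section` ids.
#' @param gene gene to count.
#' @param level `"any"` or `"high"`.
#' @return data frame: `gene`, `lamina`, `animal`, `section`, `count`
#'   (complete grid, zero-filled).
#' @export
lamina_counts <- function(cells, gene, level = c("any", "high")) {
  level <- match.arg(level)
  if (!paste0("call_", gene) %in% names(cells))
    stop("gene ", gene, " absent from calls")
  if (is.null(cells$lamina)) stop("cells carry no lamina assignment")
  pos <- .level_pos(cells, gene, level)
  hemis <- unique(cells[, c("animal", "section")])
  out <- merge(hemis, data.frame(lamina = levels(cells$lamina)))
  out$lamina <- factor(out$lamina, levels = levels(cells$lamina))
  out$gene <- gene
  out$count <- mapply(function(a, s, l)
    sum(pos & cells$animal == a & cells$section == s & cells$lamina == l),
    out$animal, out$section, out$lamina)
  out[order(out$animal, out$section, match(out$lamina, levels(cells$lamina))),
      c("gene", "lamina", "animal", "section", "count")]
}

#' Summarise lamina counts over hemisections
#' @param counts a [lamina_counts()] result.
#' @return data frame per (gene, lamina): `mean`, `sd`, `n` hemisections.
#' @export
lamina_summary <- function(counts) {
  agg <- aggregate(count ~ gene + lamina, counts, function(v)
    c(mean = mean(v), sd = if (length(v) > 1) sd(v) else NA_real_,
      n = length(v)))
  out <- data.frame(gene = agg$gene, lamina = agg$lamina,
                    mean = agg$count[, "mean"], sd = agg$count[, "sd"],
                    n = agg$count[, "n"])
  out[order(out$gene, match(out$lamina, levels(counts$lamina))), ]
}
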