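#' Segmentation parameters
#'
#' Parameters of the primary-object (nucleus) identification, modelled on
#' CellProfiler's `IdentifyPrimaryObjects` semantics: the automatic
#' (Otsu) threshold is multiplied by a correction factor and clipped to
#' explicit lower/upper bounds, clumped objects are optionally split by a
#' distance-transform watershed, and objects outside a diameter range are
#' discarded.
#'
#' @param smoothing_sigma Gaussian pre-smoothing sigma, px (0 = none).
#' @param threshold_method currently `"otsu"` (global).
#' @param correction_factor multiplier applied to the method threshold.
#' @param lower,upper clipping bounds on the effective threshold, in
#'   image intensity units.
#' @param declump split touching objects by distance-transform watershed?
#' @param min_diameter,max_diameter accepted object diameter range, px
#'   (objects are filtered on the equivalent-circle diameter of their
#'   area).
#' @param exclude_border drop objects touching the image border?
#' @return object of class `segmentation_params`.
#' @export
segmentation_params <- function(smoothing_sigma = 1,
                                threshold_method = "otsu",
                                correction_factor = 1,
                                lower = 0, upper = 1,
                                declump = TRUE,
                                min_diameter = 4, max_diameter = 40,
                                exclude_border = FALSE) {
  stopifnot(smoothing_sigma >= 0, correction_factor > 0, lower <= upper,
            min_diameter > 0, min_diameter < max_diameter)
  threshold_method <- match.arg(threshold_method, "otsu")
  structure(list(smoothing_sigma = smoothing_sigma,
                 threshold_method = threshold_method,
                 correction_factor = correction_factor,
                 lower = lower, upper = upper, declump = declump,
                 min_diameter = min_diameter, max_diameter = max_diameter,
                 exclude_border = exclude_border),
            class = "segmentation_params")
}

.check_image <- function(img) {
  if (!is.matrix(img) || !is.numeric(img))
    stop("expected a 2-D numeric image matrix")
  invisible(img)
}

# Global Otsu threshold on the image's own intensity range.
.otsu_threshold <- function(img) {
  rng <- range(img)
  if (diff(rng) == 0) return(Inf)   # flat image: nothing is foreground
  t01 <- EBImage::otsu(EBImage::Image(pmin(pmax((img - rng[1]) / diff(rng), 0), 1)),
                       range = c(0, 1))
  rng[1] + t01 * diff(rng)
}

# Relabel a label matrix so labels are contiguous 1..N, preserving the
# order of the original label values.
relabel_contiguous <- function(labels) {
  u <- sort(unique(labels[labels > 0]))
  if (!length(u)) return(matrix(0L, nrow(labels), ncol(labels)))
  lut <- integer(max(u))
  lut[u] <- seq_along(u)
  out <- labels
  out[labels > 0] <- lut[labels[labels > 0]]
  storage.mode(out) <- "integer"
  out
}

#' Detect nuclei as primary objects
#'
#' Smooths the nuclear channel, thresholds it at
#' `clip(method_threshold * correction_factor, lower, upper)` (strictly
#' above), labels connected foreground components and, when declumping is
#' enabled, splits touching components with a watershed on the Euclidean
#' distance transform.  Objects outside the configured diameter range are
#' removed and labels are made contiguous.  Deterministic for a fixed
#' input.
#'
#' @param nuclear_channel 2-D numeric image matrix.
#' @param params a [segmentation_params()].
#' @return integer label matrix (0 = background, labels 1..N contiguous)
#'   with attributes `provenance = "nuclei"` and `threshold` (the
#'   effective threshold used).
#' @export
detect_nuclei <- function(nuclear_channel, params = segmentation_params()) {
  .check_image(nuclear_channel)
  img <- nuclear_channel
  if (params$smoothing_sigma > 0) {
    img <- as.matrix(EBImage::gblur(EBImage::Image(img),
                                    sigma = params$smoothing_sigma))
  }
  thr <- .otsu_threshold(img) * params$correction_factor
  thr <- min(max(thr, params$lower), params$upper)
  mask <- img > thr
  if (!any(mask)) {
    out <- matrix(0L, nrow(img), ncol(img))
    attr(out, "provenance") <- "nuclei"
    attr(out, "threshold") <- thr
    return(out)
  }
  if (params$declump) {
    dm <- EBImage::distmap(EBImage::Image(mask * 1))
    ext <- max(1, round(params$min_diameter / 4))
    lab <- EBImage::watershed(dm, tolerance = 1, ext = ext)
    lab <- as.matrix(EBImage::imageData(lab))
  } else {
    lab <- as.matrix(EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask * 1))))
  }
  storage.mode(lab) <- "integer"
  min_area <- pi * (params$min_diameter / 2)^2
  max_area <- pi * (params$max_diameter / 2)^2
  out <- filter_objects(lab, min_area = min_area, max_area = max_area,
                        border_policy = if (params$exclude_border) "exclude" else "keep")
  attr(out, "provenance") <- "nuclei"
  attr(out, "threshold") <- thr
  out
}

#' Expand nuclei to somata by constrained nearest-nucleus growth
#'
#' Every background pixel whose Euclidean distance to the nearest nucleus
#' region is at most `max_distance` is assigned that nucleus's label
#' (secondary-object expansion).  Ties between equidistant nuclei go to
#' the lower label; nucleus pixels always keep their own label, so each
#' soma contains its nucleus.
#'
#' @param nuclei integer label matrix of primary objects.
#' @param max_distance maximum expansion distance in px (>= 0).
#' @return integer label matrix of somata with attribute
#'   `provenance = "soma"`; soma label k corresponds to nucleus label k.
#' @export
expand_to_soma <- function(nuclei, max_distance) {
  stopifnot(is.matrix(nuclei), max_distance >= 0)
  labs <- sort(unique(nuclei[nuclei > 0]))
  out <- nuclei
  storage.mode(out) <- "integer"
  if (max_distance == 0 || !length(labs)) {
    attr(out, "provenance") <- "soma"
    return(out)
  }
  H <- nrow(nuclei); W <- ncol(nuclei)
  best <- matrix(Inf, H, W)
  best[nuclei > 0] <- 0
  pad <- ceiling(max_distance) + 1L
  for (k in labs) {
    pos <- which(nuclei == k, arr.ind = TRUE)
    r0 <- max(1L, min(pos[, 1]) - pad); r1 <- min(H, max(pos[, 1]) + pad)
    c0 <- max(1L, min(pos[, 2]) - pad); c1 <- min(W, max(pos[, 2]) + pad)
    sub <- nuclei[r0:r1, c0:c1]
    d <- as.matrix(EBImage::distmap(EBImage::Image((sub != k) * 1)))
    upd <- which(d <= max_distance & d < best[r0:r1, c0:c1] & sub == 0)
    if (length(upd)) {
      sr <- ((upd - 1) %% nrow(sub)) + r0
      sc <- ((upd - 1) %/% nrow(sub)) + c0
      idx <- cbind(sr, sc)
      best[idx] <- d[upd]
      out[idx] <- k
    }
  }
  attr(out, "provenance") <- "soma"
  out
}

#' Filter labelled objects by area and border contact
#'
#' @param labels integer label matrix.
#' @param min_area,max_area accepted area range in px^2.
#' @param border_policy `"keep"` or `"exclude"` (drop objects touching
#'   the image edge).
#' @return relabelled (contiguous) integer label matrix.
#' @export
filter_objects <- function(labels, min_area = 0, max_area = Inf,
                           border_policy = c("keep", "exclude")) {
  stopifnot(is.matrix(labels))
  if (min_area > max_area) stop("min_area must not exceed max_area")
  border_policy <- match.arg(border_policy)
  u <- labels[labels > 0]
  if (!length(u)) return(relabel_contiguous(labels))
  areas <- tabulate(u)
  drop <- which(areas > 0 & (areas < min_area | areas > max_area))
  if (border_policy == "exclude") {
    edge <- unique(c(labels[1, ], labels[nrow(labels), ],
                     labels[, 1], labels[, ncol(labels)]))
    drop <- union(drop, edge[edge > 0])
  }
  out <- labels
  if (length(drop)) out[out %in% drop] <- 0L
  relabel_contiguous(out)
}

#' Object table of a label map
#'
#' @param labels integer label matrix.
#' @return data frame with one row per label: `label`, `x`, `y` (centroid
#'   in 0-based pixel coordinates) and `area` (px^2).
#' @export
object_table <- function(labels) {
  stopifnot(is.matrix(labels))
  n <- max(labels, 0)
  if (n == 0)
    return(data.frame(label = integer(0), x = numeric(0), y = numeric(0),
                      area = numeric(0)))
  idx <- which(labels > 0)
  lab <- labels[idx]
  rows <- ((idx - 1) %% nrow(labels))      # 0-based y
  cols <- ((idx - 1) %/% nrow(labels))     # 0-based x
  area <- tabulate(lab, nbins = n)
  data.frame(label = seq_len(n),
             x = tapply(cols, factor(lab, levels = seq_len(n)), mean),
             y = tapply(rows, factor(lab, levels = seq_len(n)), mean),
             area = area, row.names = NULL)
}
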