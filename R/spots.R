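#' Spot detection parameters
#'
#' Probe signal dots are detected as local maxima of a scale-normalised
#' Laplacian-of-Gaussian (blob) response.  As for nuclei, the automatic
#' threshold on the response is multiplied by a correction factor and
#' clipped to explicit lower/upper bounds, which is how per-slide
#' adaptation is expressed: one parameter set per image batch.
#'
#' @param log_sigma LoG scale in px, matched to the rendered/imaged spot
#'   size.
#' @param correction_factor multiplier on the automatic (Otsu) response
#'   threshold.
#' @param lower,upper clipping bounds on the effective threshold, in
#'   response units.
#' @param min_separation minimum distance between two reported spots, px;
#'   closer maxima are merged into the stronger one (non-maximum
#'   suppression).  The default 1.2 px removes axis-adjacent duplicate
#'   maxima of one blob while keeping diagonally adjacent peak pixels of
#'   two distinct dots apart.
#' @return object of class `spot_params`.
#' @export
spot_params <- function(log_sigma = 0.6, correction_factor = 1,
                        lower = 0, upper = Inf, min_separation = 1.2) {
  stopifnot(log_sigma > 0, correction_factor > 0, lower <= upper,
            min_separation >= 0)
  structure(list(log_sigma = log_sigma,
                 correction_factor = correction_factor,
                 lower = lower, upper = upper,
                 min_separation = min_separation),
            class = "spot_params")
}

# Scale-normalised negated-LoG kernel: positive response at bright blobs
# of radius ~ sigma * sqrt(2).
.log_kernel <- function(sigma) {
  half <- ceiling(3 * sigma)
  ax <- -half:half
  g <- exp(-ax^2 / (2 * sigma^2))
  G <- outer(g, g)
  r2 <- outer(ax^2, ax^2, `+`)
  k <- -(r2 / sigma^2 - 2) * G   # -sigma^2 * LoG (unnormalised)
  k - mean(k)                    # zero-sum: flat regions give 0 response
}

#' Detect probe signal dots in one channel
#'
#' Computes the LoG blob response, thresholds it at
#' `clip(otsu_response_threshold * correction_factor, lower, upper)`,
#' finds local maxima (8-neighbourhood), suppresses maxima closer than
#' `min_separation` to a stronger one, and reports one record per spot
#' with a sub-pixel position (intensity-weighted centroid of the 3x3
#' response neighbourhood).  Deterministic.
#'
#' @param probe_channel 2-D numeric image matrix.
#' @param params a [spot_params()].
#' @param gene channel/gene name stored with the spots.
#' @param animal,section identifiers stored with the spots.
#' @return `SpotTable` data frame: `x`, `y` (0-based px, sub-pixel),
#'   `gene`, `intensity` (image value at the rounded position), `parent`
#'   (NA until related to cells), `section`, `animal`.
#' @export
detect_spots <- function(probe_channel, params = spot_params(),
                         gene = "probe", animal = NA, section = NA) {
  .check_image(probe_channel)
  empty <- data.frame(x = numeric(0), y = numeric(0), gene = character(0),
                      intensity = numeric(0), parent = integer(0),
                      section = section[0], animal = animal[0])
  k <- .log_kernel(params$log_sigma)
  resp <- as.matrix(EBImage::filter2(EBImage::Image(probe_channel), k,
                                     boundary = "replicate"))
  if (diff(range(resp)) == 0) return(empty)
  thr <- .otsu_threshold(resp) * params$correction_factor
  thr <- min(max(thr, params$lower), params$upper)
  H <- nrow(resp); W <- ncol(resp)
  if (H < 3 || W < 3) return(empty)
  core <- resp[2:(H - 1), 2:(W - 1)]
  is_max <- core > thr &
    core >= resp[1:(H - 2), 2:(W - 1)] & core >= resp[3:H, 2:(W - 1)] &
    core >= resp[2:(H - 1), 1:(W - 2)] & core >= resp[2:(H - 1), 3:W] &
    core >= resp[1:(H - 2), 1:(W - 2)] & core >= resp[1:(H - 2), 3:W] &
    core >= resp[3:H, 1:(W - 2)] & core >= resp[3:H, 3:W]
  pk <- which(is_max, arr.ind = TRUE)
  if (!nrow(pk)) return(empty)
  rows <- pk[, 1] + 1L; cols <- pk[, 2] + 1L
  vals <- resp[cbind(rows, cols)]
  ord <- order(-vals, rows, cols)
  rows <- rows[ord]; cols <- cols[ord]; vals <- vals[ord]
  # greedy non-maximum suppression at min_separation
  keep <- logical(length(rows))
  kr <- kc <- numeric(0)
  min2 <- params$min_separation^2
  for (i in seq_along(rows)) {
    if (length(kr) == 0 ||
        all((kr - rows[i])^2 + (kc - cols[i])^2 >= min2)) {
      keep[i] <- TRUE
      kr <- c(kr, rows[i]); kc <- c(kc, cols[i])
    }
  }
  rows <- rows[keep]; cols <- cols[keep]
  # sub-pixel centroid on the 3x3 response neighbourhood
  sx <- sy <- numeric(length(rows))
  for (i in seq_along(rows)) {
    rr <- (rows[i] - 1):(rows[i] + 1); cc <- (cols[i] - 1):(cols[i] + 1)
    wgt <- pmax(resp[rr, cc], 0)
    s <- sum(wgt)
    if (s <= 0) { sx[i] <- cols[i] - 1; sy[i] <- rows[i] - 1; next }
    sx[i] <- sum(t(wgt) * (cc - 1)) / s
    sy[i] <- sum(wgt * (rr - 1)) / s
  }
  data.frame(x = sx, y = sy, gene = gene,
             intensity = probe_channel[cbind(rows, cols)],
             parent = NA_integer_, section = section, animal = animal,
             stringsAsFactors = FALSE)
}

#' Assign spots to the cells they lie in
#'
#' Sets each spot's `parent` to the soma label at its rounded pixel
#' position; spots over background get parent 0 and are excluded from
#' dots-per-cell counts.  The total number of spots is preserved.
#'
#' @param spots `SpotTable` data frame with `x`, `y` columns (0-based).
#' @param somata integer soma label matrix in the same pixel frame.
#' @return the spot table with `parent` filled in.
#' @export
relate_spots_to_cells <- function(spots, somata) {
  stopifnot(is.data.frame(spots), is.matrix(somata))
  if (!nrow(spots)) { spots$parent <- integer(0); return(spots) }
  r <- round(spots$y) + 1
  c <- round(spots$x) + 1
  if (any(r < 1 | r > nrow(somata) | c < 1 | c > ncol(somata)))
    stop("spot coordinates fall outside the label-map frame")
  spots$parent <- somata[cbind(r, c)]
  spots
}

#' Dots per cell
#'
#' One record per soma label with the integer dot count per gene channel
#' (0 if none); cells with zero dots in every channel are included.
#'
#' @param spots related `SpotTable` (see [relate_spots_to_cells()]); may
#'   combine several channels.
#' @param somata integer soma label matrix.
#' @param genes channels to tabulate; defaults to those present in
#'   `spots`.
#' @return `CellTable` data frame: `cell`, `x`, `y`, `area`, one
#'   `dots_<gene>` column per gene, and `animal`/`section` carried over
#'   when unique in `spots`.
#' @export
dots_per_cell <- function(spots, somata, genes = NULL) {
  stopifnot(is.matrix(somata))
  if (is.null(genes)) genes <- unique(spots$gene)
  tab <- object_table(somata)
  out <- data.frame(cell = tab$label, x = tab$x, y = tab$y, area = tab$area)
  n <- nrow(out)
  for (g in genes) out[[paste0("dots_", g)]] <- 0L
  if (nrow(spots)) {
    if (is.null(spots$parent) || anyNA(spots$parent))
      stop("spots must be related to cells first (relate_spots_to_cells)")
    sp <- spots[spots$parent > 0 & spots$gene %in% genes, , drop = FALSE]
    if (nrow(sp)) {
      tb <- table(factor(sp$parent, levels = seq_len(n)),
                  factor(sp$gene, levels = genes))
      for (g in genes)
        out[[paste0("dots_", g)]] <- as.integer(tb[, g])
    }
    for (col in c("animal", "section")) {
      v <- unique(spots[[col]])
      if (length(v) == 1 && !is.na(v)) out[[col]] <- v
    }
  }
  out
}

# Gene names carried by a CellTable's dots_ columns.
cell_table_genes <- function(cells) {
  sub("^dots_", "", grep("^dots_", names(cells), value = TRUE))
}
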