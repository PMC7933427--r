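#' Dorsal-horn tissue template
#'
#' A template describes the region outline of (half of) a dorsal horn and
#' an ordered set of laminar band polygons (dorsal to ventral, named
#' I..V).  It is used both by the tissue simulator (cell placement) and by
#' the laminar mapping stage (lamina assignment after alignment).
#'
#' @param region_outline two-column matrix (x, y) with the closed outline
#'   of the grey-matter region, in pixel coordinates (closing edge
#'   implicit).
#' @param laminae named list of two-column polygon matrices, ordered
#'   dorsal to ventral; names must be unique (conventionally `I`..`V`).
#' @param pixel_size_um physical pixel size in micrometres.
#' @return object of class `tissue_template`.
#' @details All lamina polygons must be simple and lie inside the region
#'   outline (vertex-wise check).  Laminae are treated as non-overlapping;
#'   if a mapped point falls into more than one polygon the dorsal-most
#'   lamina (earliest in the list) wins.
#' @export
tissue_template <- function(region_outline, laminae, pixel_size_um = 0.5) {
  region_outline <- as.matrix(region_outline)
  stopifnot(ncol(region_outline) == 2, nrow(region_outline) >= 3)
  stopifnot(is.list(laminae), length(laminae) >= 1)
  if (is.null(names(laminae)) || anyDuplicated(names(laminae)))
    stop("laminae must have unique names")
  if (!polygon_is_simple(region_outline))
    stop("region outline is self-intersecting")
  for (nm in names(laminae)) {
    p <- as.matrix(laminae[[nm]])
    if (!polygon_is_simple(p))
      stop("lamina polygon ", nm, " is self-intersecting")
    if (!all(point_in_polygon(p[, 1], p[, 2], region_outline)))
      stop("lamina polygon ", nm, " is not contained in the region outline")
    laminae[[nm]] <- p
  }
  stopifnot(is.numeric(pixel_size_um), pixel_size_um > 0)
  structure(list(region_outline = region_outline, laminae = laminae,
                 pixel_size_um = pixel_size_um),
            class = "tissue_template")
}

#' @export
print.tissue_template <- function(x, ...) {
  bb <- polygon_bbox(x$region_outline)
  cat("tissue_template:", length(x$laminae), "laminae (",
      paste(names(x$laminae), collapse = ", "), ")\n")
  cat(sprintf("  bbox x [%.1f, %.1f]  y [%.1f, %.1f]  pixel %.3f um\n",
              bb["xmin"], bb["xmax"], bb["ymin"], bb["ymax"],
              x$pixel_size_um))
  invisible(x)
}

#' Default half-dorsal-horn template
#'
#' A stylised half dorsal horn: a rectangular grey-matter outline with
#' five stacked laminar bands whose relative depths follow the
#' cytoarchitecture of the mouse lumbar dorsal horn (thin lamina I, thin
#' lamina II, progressively deeper laminae III-V).  Dimensions are in
#' pixels; the default fits a 260 x 300 px image with a margin that keeps
#' whole somata away from image borders.
#'
#' @param width,height outline width/height in px.
#' @param margin distance between the outline and the image border, px.
#' @param pixel_size_um physical pixel size.
#' @return a [tissue_template()].
#' @export
default_template <- function(width = 340, height = 400, margin = 10,
                             pixel_size_um = 0.5) {
  x0 <- margin; x1 <- margin + width
  y0 <- margin; y1 <- margin + height
  rect <- function(ya, yb, inset = 2) {
    cbind(x = c(x0 + inset, x1 - inset, x1 - inset, x0 + inset),
          y = c(ya, ya, yb, yb))
  }
  # relative band depths, dorsal to ventral
  depth <- c(I = 0.12, II = 0.17, III = 0.20, IV = 0.23, V = 0.28)
  edges <- y0 + height * cumsum(c(0, depth))
  laminae <- list()
  for (i in seq_along(depth)) {
    laminae[[names(depth)[i]]] <- rect(edges[i] + (i > 1) * 0.5, edges[i + 1])
  }
  outline <- cbind(x = c(x0, x1, x1, x0), y = c(y0, y0, y1, y1))
  tissue_template(outline, laminae, pixel_size_um)
}

#' Default alignment landmarks for a template
#'
#' Four canonical landmarks (dorso-medial and dorso-lateral corners of the
#' outline, plus the two ventral corners), adequate for a least-squares
#' affine fit.
#'
#' @param template a [tissue_template()].
#' @return a 4 x 2 matrix of template-frame coordinates with row names.
#' @export
default_landmarks <- function(template) {
  bb <- polygon_bbox(template$region_outline)
  m <- rbind(dorsomedial  = c(bb["xmin"], bb["ymin"]),
             dorsolateral = c(bb["xmax"], bb["ymin"]),
             ventromedial = c(bb["xmin"], bb["ymax"]),
             ventrolateral = c(bb["xmax"], bb["ymax"]))
  colnames(m) <- c("x", "y")
  m
}

#' Read / write a tissue template as GeoJSON
#'
#' The template is stored as a `FeatureCollection`: one polygon feature
#' with `name = "region"`, one polygon feature per lamina (property
#' `name` set to the lamina name, `order` giving the dorsal-to-ventral
#' rank), and optionally named point features for landmarks.
#'
#' @param template a [tissue_template()].
#' @param path file path.
#' @param landmarks optional matrix of named landmark points (x, y).
#' @return `write_template_geojson` returns `path` invisibly;
#'   `read_template_geojson` returns a list with elements `template` and
#'   `landmarks` (matrix or `NULL`).
#' @export
write_template_geojson <- function(template, path, landmarks = NULL) {
  poly_coords <- function(p) {
    ring <- rbind(p, p[1, , drop = FALSE])
    list(apply(ring, 1, function(r) c(r[[1]], r[[2]]), simplify = FALSE))
  }
  feats <- list(list(
    type = "Feature",
    properties = list(name = "region",
                      pixel_size_um = template$pixel_size_um),
    geometry = list(type = "Polygon",
                    coordinates = poly_coords(template$region_outline))))
  for (i in seq_along(template$laminae)) {
    feats[[length(feats) + 1L]] <- list(
      type = "Feature",
      properties = list(name = names(template$laminae)[i], order = i),
      geometry = list(type = "Polygon",
                      coordinates = poly_coords(template$laminae[[i]])))
  }
  if (!is.null(landmarks)) {
    for (i in seq_len(nrow(landmarks))) {
      feats[[length(feats) + 1L]] <- list(
        type = "Feature",
        properties = list(name = rownames(landmarks)[i], landmark = TRUE),
        geometry = list(type = "Point",
                        coordinates = c(landmarks[i, 1], landmarks[i, 2])))
    }
  }
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_template_geojson
#' @export
read_template_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  stopifnot(identical(gj$type, "FeatureCollection"))
  region <- NULL; pixel_size <- 0.5
  lam <- list(); lam_order <- numeric()
  landmarks <- list()
  ring_to_matrix <- function(geom) {
    ring <- geom$coordinates[[1]]
    m <- do.call(rbind, lapply(ring, function(pt) c(pt[[1]], pt[[2]])))
    # drop the repeated closing vertex
    if (nrow(m) > 1 && all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
    colnames(m) <- c("x", "y")
    m
  }
  for (f in gj$features) {
    nm <- f$properties$name
    if (identical(f$geometry$type, "Polygon")) {
      if (identical(nm, "region")) {
        region <- ring_to_matrix(f$geometry)
        if (!is.null(f$properties$pixel_size_um))
          pixel_size <- f$properties$pixel_size_um
      } else {
        lam[[nm]] <- ring_to_matrix(f$geometry)
        lam_order[nm] <- if (is.null(f$properties$order)) length(lam) else f$properties$order
      }
    } else if (identical(f$geometry$type, "Point")) {
      landmarks[[nm]] <- c(f$geometry$coordinates[[1]], f$geometry$coordinates[[2]])
    }
  }
  if (is.null(region)) stop("GeoJSON has no feature named 'region'")
  lam <- lam[names(sort(lam_order))]
  lm_mat <- NULL
  if (length(landmarks)) {
    lm_mat <- do.call(rbind, landmarks)
    colnames(lm_mat) <- c("x", "y")
  }
  list(template = tissue_template(region, lam, pixel_size),
       landmarks = lm_mat)
}
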