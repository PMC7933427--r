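# File interfaces: multi-page TIFF image stacks with a JSON sidecar
# naming channel roles, CSV tables with fixed column names, YAML
# configuration.

#' Write / read an image stack as multi-page TIFF + JSON sidecar
#'
#' One TIFF page per channel, values clamped to `[0, 1]` and stored as
#' 16-bit; `<path>.json` records channel names and roles.
#'
#' @param stack an `image_stack` (see [render_image_stack()]).
#' @param path TIFF file path.
#' @return `write_image_stack` returns `path` invisibly;
#'   `read_image_stack` returns an `image_stack`.
#' @export
write_image_stack <- function(stack, path) {
  imgs <- lapply(stack$images, function(m) pmin(pmax(m, 0), 1))
  tiff::writeTIFF(imgs, path, bits.per.sample = 16)
  jsonlite::write_json(stack$channels, paste0(path, ".json"),
                       dataframe = "rows", auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_image_stack
#' @export
read_image_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    channels <- as.data.frame(jsonlite::read_json(sidecar, simplifyVector = TRUE))
  } else {
    channels <- data.frame(name = c("nuclear", paste0("probe", seq_len(length(pages) - 1))),
                           role = c("nuclear", rep("probe", length(pages) - 1)))
  }
  names(pages) <- channels$name
  structure(list(images = pages, channels = channels), class = "image_stack")
}

#' Write / read a label map as 16-bit TIFF
#' @param labels integer label matrix.
#' @param path TIFF file path.
#' @return the label matrix (read) or `path` invisibly (write).
#' @export
write_label_map <- function(labels, path) {
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16)
  invisible(path)
}

#' @rdname write_label_map
#' @export
read_label_map <- function(path) {
  m <- tiff::readTIFF(path)
  out <- round(m * 65535)
  storage.mode(out) <- "integer"
  out
}

#' Write / read pipeline tables as CSV
#'
#' Plain CSV with the fixed column names used throughout the package
#' (`SpotTable`: x, y, gene, intensity, parent, section, animal;
#' `CellTable`: cell, x, y, area, dots_<gene>, ...).
#'
#' @param x data frame.
#' @param path CSV path.
#' @return `read_table_csv` returns a data frame.
#' @export
write_table_csv <- function(x, path) {
  write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table_csv
#' @export
read_table_csv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Write a co-expression matrix bundle as JSON
#'
#' Counts, fractions, stringency level and number of animals in one
#' machine-readable bundle.
#'
#' @param x a [pairwise_matrix()] result.
#' @param path JSON path.
#' @export
write_coexpression_json <- function(x, path) {
  jsonlite::write_json(
    list(genes = x$genes, level = x$level, n_animals = x$n_animals,
         fraction = x$fraction, n_g = x$n_g, n_gh = x$n_gh),
    path, auto_unbox = TRUE, digits = NA, na = "null", matrix = "rowmajor")
  invisible(path)
}

#' Write / read simulation parameters as YAML
#'
#' Scalar simulation parameters and the population mixture are stored as
#' YAML; the template travels separately as GeoJSON
#' ([write_template_geojson()]) and its path is recorded in the YAML.
#'
#' @param config a [simulation_config()].
#' @param path YAML path.
#' @param template_path path to the template GeoJSON written alongside.
#' @return `read_sim_config_yaml` returns a [simulation_config()].
#' @export
write_sim_config_yaml <- function(config, path,
                                  template_path = paste0(path, ".template.geojson")) {
  write_template_geojson(config$template, template_path)
  pops <- lapply(config$populations, function(p)
    list(name = p$name, weight = p$weight,
         expr_prob = as.list(p$expr_prob),
         dot_mean = as.list(p$dot_mean),
         dot_dispersion = as.list(p$dot_dispersion),
         lamina_weights = as.list(p$lamina_weights)))
  scalars <- config[c("n_cells", "nucleus_radius_mean", "nucleus_radius_sd",
                      "soma_expansion", "spot_sigma", "spot_amplitude",
                      "noise_sd", "background_dot_rate", "n_animals",
                      "hemisections_per_animal", "spot_min_separation",
                      "nucleus_min_gap", "seed")]
  yaml::write_yaml(c(scalars, list(template = template_path,
                                   populations = pops)), path)
  invisible(path)
}

#' @rdname write_sim_config_yaml
#' @export
read_sim_config_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  tpl <- read_template_geojson(y$template)$template
  pops <- lapply(y$populations, function(p)
    population_spec(p$name, p$weight,
                    expr_prob = unlist(p$expr_prob),
                    dot_mean = unlist(p$dot_mean),
                    dot_dispersion = unlist(p$dot_dispersion),
                    lamina_weights = unlist(p$lamina_weights)))
  simulation_config(template = tpl, populations = pops,
                    n_cells = y$n_cells,
                    nucleus_radius_mean = y$nucleus_radius_mean,
                    nucleus_radius_sd = y$nucleus_radius_sd,
                    soma_expansion = y$soma_expansion,
                    spot_sigma = y$spot_sigma,
                    spot_amplitude = y$spot_amplitude,
                    noise_sd = y$noise_sd,
                    background_dot_rate = y$background_dot_rate,
                    n_animals = y$n_animals,
                    hemisections_per_animal = y$hemisections_per_animal,
                    spot_min_separation = y$spot_min_separation,
                    nucleus_min_gap = y$nucleus_min_gap,
                    seed = y$seed)
}
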