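# Serialization of query and heat-map specifications to/from YAML or JSON
# config files. Every field has a CLI flag equivalent; flags override file
# values.

#' Read a run configuration from YAML or JSON
#'
#' The file may hold top-level `query:` and `heatmap:` sections whose keys
#' mirror the arguments of [query_spec()] and [heatmap_spec()]. Files ending
#' in `.json` are parsed as JSON, everything else as YAML (JSON is a YAML
#' subset, so either parser accepts both layouts).
#'
#' @param path Config file path.
#' @return Named list with elements `query` and `heatmap` (possibly empty
#'   lists).
#' @export
read_config <- function(path) {
  if (!file.exists(path)) gx_io_error(sprintf("config file not found: %s", path))
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.list(cfg)) gx_format_error(sprintf("config %s is not a mapping", path))
  unknown <- setdiff(names(cfg), c("query", "heatmap"))
  if (length(unknown) > 0L) {
    gx_validation_error(sprintf(
      "unknown config section %s (expected 'query' and/or 'heatmap')",
      sQuote(unknown[[1L]])
    ))
  }
  list(query = cfg$query %||% list(), heatmap = cfg$heatmap %||% list())
}

#' Write query and heat-map specifications to a config file
#'
#' @param path Output path; `.json` writes JSON, anything else YAML.
#' @param query A `gx_query_spec`, or `NULL`.
#' @param heatmap A `gx_heatmap_spec`, or `NULL`.
#' @return `path`, invisibly.
#' @export
write_config <- function(path, query = NULL, heatmap = NULL) {
  cfg <- list()
  if (!is.null(query)) cfg$query <- unclass(query)
  if (!is.null(heatmap)) cfg$heatmap <- unclass(heatmap)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  } else {
    yaml::write_yaml(cfg, path)
  }
  invisible(path)
}

# build a gx_query_spec from a config-section list merged with CLI overrides
spec_from_config <- function(section, overrides = list(), samples = NULL) {
  args <- utils::modifyList(section, overrides)
  if (!is.null(samples) && is.null(args$samples)) args$samples <- samples
  known <- c("samples", "abundance", "min_value", "max_value", "condition",
             "cohorts", "category", "diseases", "fill_policy")
  unknown <- setdiff(names(args), known)
  if (length(unknown) > 0L) {
    gx_validation_error(sprintf("unknown query option %s", sQuote(unknown[[1L]])))
  }
  # Inf does not survive YAML/JSON round trips as a number
  if (!is.null(args$max_value) &&
      (is.character(args$max_value) || is.null(args$max_value))) {
    args$max_value <- suppressWarnings(as.numeric(args$max_value))
    if (is.na(args$max_value)) args$max_value <- Inf
  }
  do.call(query_spec, args)
}

heatmap_spec_from_config <- function(section, overrides = list()) {
  args <- utils::modifyList(section, overrides)
  known <- c("title_header", "title_x", "title_y_left", "title_y_right",
             "gradient", "left_label_field", "right_label_field",
             "transform", "vmin", "vmax", "na_color")
  unknown <- setdiff(names(args), known)
  if (length(unknown) > 0L) {
    gx_validation_error(sprintf("unknown heatmap option %s",
                                sQuote(unknown[[1L]])))
  }
  do.call(heatmap_spec, args)
}
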