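#' Read a run configuration file
#'
#' A YAML or JSON file holding the pipeline parameters: `pixel_size`
#' (mandatory for any image run), and optional `morphology`
#' (`se`, `passes`, `dilation_passes`), `filters` (`min_area`,
#' `min_longest_axis`, `max_circularity`, `min_box_area_ratio`), `transfer`
#' (`recipient_min_area`, `punctum_max_area`, `punctum_min_area`,
#' `boundary_width`), `background` (`method`, `param`), and
#' `min_cell_area` blocks.  Unknown keys are an error so typos do not pass
#' silently.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return Named list with parsed blocks; `morphology` and `filters` are
#'   returned as ready [morphology_config()] / [protrusion_filter_config()]
#'   objects when present.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
         else if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
         else stop("config must be YAML or JSON")
  known <- c("pixel_size", "morphology", "filters", "transfer", "background",
             "min_cell_area", "connectivity")
  bad <- setdiff(names(cfg), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  if (!is.null(cfg$pixel_size)) check_pixel_size(cfg$pixel_size)
  if (!is.null(cfg$morphology))
    cfg$morphology <- do.call(morphology_config, cfg$morphology)
  if (!is.null(cfg$filters))
    cfg$filters <- do.call(protrusion_filter_config, cfg$filters)
  cfg
}
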