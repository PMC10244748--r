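#' Load an experiment configuration file
#'
#' Reads a YAML or JSON configuration record (layer sizes, controller
#' constants, integration step, plasticity constants, seeds, ...) into
#' a plain named list that the experiment runners merge over their
#' defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return Named list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("unsupported config format '.", ext, "' (use YAML or JSON)",
         call. = FALSE)
  }
}

#' Echo a configuration to JSON
#'
#' Writes the fully merged configuration actually used by a run, so
#' every experiment output directory is self-describing and rerunnable.
#'
#' @param cfg Named list.
#' @param path Output `.json` path.
#' @export
echo_config <- function(cfg, path) {
  strip_fns <- function(x) {
    if (is.list(x)) lapply(Filter(Negate(is.function), x), strip_fns) else x
  }
  cfg <- strip_fns(cfg)
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE, pretty = TRUE)
  invisible(path)
}
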