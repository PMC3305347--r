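#' Write an experiment report to disk
#'
#' Emits tidy CSV tables for every data-frame element of the report, a JSON
#' run manifest with the fully resolved configuration and seed, and (when a
#' trajectory is present) the trajectory CSV. All outputs are plain text.
#'
#' @param report A `bulb_report` from one of the `run_*` functions.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "bulb_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (nm in names(report)) {
    el <- report[[nm]]
    if (is.data.frame(el)) {
      p <- file.path(dir, paste0(nm, ".csv"))
      utils::write.csv(el, p, row.names = FALSE)
      paths <- c(paths, p)
    } else if (inherits(el, "correlation_report")) {
      p <- file.path(dir, paste0(nm, "_correlations.csv"))
      utils::write.csv(as.data.frame(el$matrix), p)
      paths <- c(paths, p)
    }
  }
  manifest <- list(experiment = report$experiment, seed = report$seed,
                   config = unclass(report$config),
                   written = format(Sys.time(), "%Y-%m-%d %H:%M:%S"))
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(c(paths, mp))
}

#' Save a network snapshot as JSON
#'
#' Serializes the connection structure (sparse index lists), synaptic
#' weights, parameters and cohort tags to a single JSON file; the companion
#' [load_network()] restores an identical `bulb_network`.
#'
#' @param net A `bulb_network`.
#' @param path Output file path.
#' @export
save_network <- function(net, path) {
  obj <- list(M = net$M, K = net$K, w = net$w, spontaneous = net$spontaneous,
              exc = net$exc, inh = net$inh, inh_w = net$inh_w,
              birth_step = net$birth_step, cohort = net$cohort)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Load a network snapshot saved by [save_network()]
#'
#' @param path JSON file path.
#' @return A `bulb_network`.
#' @export
load_network <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  net <- new_network(obj$M, obj$K, obj$w, obj$spontaneous)
  as_int_matrix <- function(x, k) matrix(as.integer(x), ncol = k)
  if (length(obj$exc)) {
    net$exc <- as_int_matrix(obj$exc, obj$K)
    net$inh <- as_int_matrix(obj$inh, obj$K)
    net$inh_w <- matrix(as.numeric(obj$inh_w), ncol = obj$K)
    net$birth_step <- as.integer(obj$birth_step)
    net$cohort <- as.character(obj$cohort)
  }
  net
}

#' Read an experiment configuration from a YAML or JSON file
#'
#' Fields mirror [experiment_config()]; unknown fields are rejected.
#'
#' @param path Config file (`.yaml`/`.yml` or `.json`).
#' @return An `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  lst <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the 'yaml' package")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  lst$experiment <- NULL
  do.call(experiment_config, lst)
}
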