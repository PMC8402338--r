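# Configuration files, delimited-text artifacts and run manifests.  All
# outputs are plain text: CSV tables with mandatory headers and floating
# values at 10 significant digits (bit-reproducible determinism checks),
# YAML for configs and manifests.

param_field_names <- function() names(formals(model_params))

#' Load a model configuration file
#'
#' Reads a YAML key-value file whose keys are [model_params()] field
#' names, applies the model defaults for absent keys and validates the
#' result.  Unknown keys are rejected with a message naming them.
#'
#' @param path Path to the YAML config (an empty file yields all
#'   defaults).
#' @return A validated `av_params` record.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  if (!is.list(cfg)) stop("config must be a YAML mapping of key: value")
  unknown <- setdiff(names(cfg), param_field_names())
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  vec_fields <- c("opinion_bounds", "committed_doctor_opinion_range",
                  "uncommitted_doctor_opinion_range")
  for (f in intersect(names(cfg), vec_fields)) {
    cfg[[f]] <- as.numeric(unlist(cfg[[f]]))
  }
  do.call(model_params, cfg)
}

#' Write a fully resolved configuration
#'
#' Serialises an `av_params` record as YAML with every field explicit
#' (no defaults left implicit).  [load_config()] of the written file
#' reproduces the record exactly.
#'
#' @param params An `av_params` record.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(params, path) {
  validate_params(params)
  yaml::write_yaml(unclass(params), path)
  invisible(path)
}

# format a data frame with numerics at 10 significant digits and write CSV
write_table10 <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.10g", out[[j]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write per-tick simulation metrics as CSV
#'
#' One row per tick with the named metric columns; floating values at 10
#' significant digits so identical runs yield byte-identical files.
#'
#' @param sim An `av_simulation` from [run_simulation()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(sim, path) {
  stopifnot(inherits(sim, "av_simulation"))
  write_table10(sim$metrics, path)
}

#' Read an activity series from delimited text
#'
#' Accepts a one-column (value) or two-column (bin, value) file with a
#' header row.
#'
#' @param path Input path.
#' @param bin_width Time units per bin.
#' @return An [av_series()].
#' @export
read_series <- function(path, bin_width = 1) {
  df <- utils::read.csv(path)
  if (ncol(df) == 1L) {
    av_series(df[[1]], bin_width = bin_width, label = basename(path))
  } else if (ncol(df) >= 2L) {
    av_series(df[[2]], bin_width = bin_width, label = basename(path))
  } else {
    stop("series file must have 1 or 2 columns")
  }
}

#' Write a run manifest
#'
#' Records tool version, command, fully resolved parameters, seed(s),
#' timestamps and an inventory of output files with MD5 digests, as YAML.
#'
#' @param path Manifest path.
#' @param command Character command label (e.g. `"simulate"`).
#' @param params An `av_params` record (or NULL).
#' @param seed Seed(s) used.
#' @param outputs Character vector of output file paths to inventory.
#' @param started POSIXct start time.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, command, params, seed, outputs,
                           started = Sys.time()) {
  inventory <- lapply(outputs, function(f) {
    list(file = f,
         md5 = unname(tools::md5sum(f)))
  })
  man <- list(
    tool = "avburst",
    version = as.character(utils::packageVersion("avburst")),
    command = command,
    seed = as.integer(seed),
    started = format(started, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    parameters = if (is.null(params)) NULL else unclass(params),
    outputs = inventory
  )
  yaml::write_yaml(man, path)
  invisible(path)
}
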