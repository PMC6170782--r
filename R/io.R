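# Configuration, snapshot and manifest plumbing.

config_defaults <- function() {
  list(
    seed = 1L,
    output = "colonymix-run",
    physics = unclass(physics_params()),
    scenario = list(name = "two-domain", adhesion = 0, n_target = 5000,
                    n_cells = 10, force_magnitude = 5,
                    adhesion_values = c(0, 0.5, 1, 2, 3),
                    displacement_target = 2,
                    metrics_every = 50L, snapshot_every = NA_integer_),
    render = list(pixel_size = 0.1, frame_interval = 10, psf_sigma = 2,
                  noise_sd = 0.02),
    flow = unclass(flow_params())
  )
}

merge_checked <- function(defaults, given, path = "") {
  unknown <- setdiff(names(given), names(defaults))
  if (length(unknown) > 0)
    stop("unknown config key(s): ",
         paste0(path, unknown, collapse = ", "))
  for (nm in names(given)) {
    if (is.list(defaults[[nm]]) && is.list(given[[nm]])) {
      defaults[[nm]] <- merge_checked(defaults[[nm]], given[[nm]],
                                      paste0(path, nm, "."))
    } else {
      defaults[[nm]] <- given[[nm]]
    }
  }
  defaults
}

#' Load a run configuration
#'
#' Reads a YAML configuration, validates it against the known schema
#' (unknown keys are rejected, naming the offending key) and fills every
#' omitted setting with its default.  `default_config()` returns the fully
#' resolved default configuration; `write_config()` writes a configuration
#' that round-trips losslessly through `load_config()`.
#'
#' @param path YAML file path.
#' @return A fully resolved configuration list of class `run_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  given <- yaml::read_yaml(path)
  if (is.null(given)) given <- list()
  cfg <- merge_checked(config_defaults(), given)
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "run_config"
  cfg
}

#' @rdname load_config
#' @export
default_config <- function() {
  cfg <- config_defaults()
  class(cfg) <- "run_config"
  cfg
}

#' @rdname load_config
#' @param config a configuration list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

snapshot_columns <- c("id", "x", "y", "dir_x", "dir_y", "length", "radius",
                      "domain_label", "adhesin", "growth_rate",
                      "division_length", "growing")

#' Write / read a colony snapshot
#'
#' One tab-separated table per time point with the full cell state at 15
#' significant digits, so a snapshot round-trips losslessly.  A `#`-prefixed
#' header line carries the simulation time.
#'
#' @param colony a [colony].
#' @param path output file.
#' @return `write_snapshot()` the path, invisibly; `read_snapshot()` a
#'   [colony] (with the supplied physics parameters attached).
#' @export
write_snapshot <- function(colony, path) {
  cl <- colony$cells
  df <- data.frame(id = cl$id,
                   x = sprintf("%.15g", cl$x), y = sprintf("%.15g", cl$y),
                   dir_x = sprintf("%.15g", cl$dx),
                   dir_y = sprintf("%.15g", cl$dy),
                   length = sprintf("%.15g", cl$length),
                   radius = sprintf("%.15g", cl$radius),
                   domain_label = cl$domain_label,
                   adhesin = sprintf("%.15g", cl$adhesin),
                   growth_rate = sprintf("%.15g", cl$growth_rate),
                   division_length = sprintf("%.15g", cl$division_length),
                   growing = as.integer(cl$growing))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# colonymix snapshot time=%.15g", colony$time), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_snapshot
#' @param path snapshot file.
#' @param params [physics_params] to attach to the rebuilt colony.
#' @export
read_snapshot <- function(path, params = physics_params()) {
  lines <- readLines(path)
  if (length(lines) < 2 || !startsWith(lines[1], "# colonymix snapshot"))
    stop("not a colonymix snapshot: ", path)
  time <- as.numeric(sub(".*time=", "", lines[1]))
  nf <- vapply(strsplit(lines[-1], "\t", fixed = TRUE), length, integer(1))
  bad <- which(nf != nf[1])
  if (length(bad) > 0)
    stop(sprintf("snapshot parse error at line %d: expected %d fields, got %d",
                 bad[1] + 1L, nf[1], nf[bad[1]]))
  df <- read.delim(text = lines[-1], sep = "\t", stringsAsFactors = FALSE,
                   colClasses = c(domain_label = "character"))
  missing <- setdiff(snapshot_columns, names(df))
  if (length(missing) > 0)
    stop("snapshot missing column(s): ", paste(missing, collapse = ", "))
  cells <- new_cells(df$id, df$x, df$y, df$dir_x, df$dir_y, df$length,
                     df$radius, df$growth_rate, df$division_length,
                     df$domain_label, df$adhesin, df$growing > 0)
  colony <- new_colony(cells, params, time = time)
  colony
}

#' Write a run manifest
#'
#' Records the fully resolved configuration, seed and package version next
#' to a run's outputs.
#'
#' @param dir run directory.
#' @param config resolved configuration list.
#' @return The manifest path, invisibly.
#' @export
write_manifest <- function(dir, config) {
  path <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(list(
    package = "colonymix",
    version = as.character(utils::packageVersion("colonymix")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = unclass(config)), path, precision = 15)
  invisible(path)
}

#' Write an image stack as multi-page TIFF
#'
#' @param frames list of numeric matrices in `[0, 1]` (clipped).
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_stack <- function(frames, path) {
  frames <- lapply(frames, function(f) pmin(pmax(f, 0), 1))
  tiff::writeTIFF(frames, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a multi-page TIFF stack
#'
#' @param path TIFF file.
#' @return List of matrices.
#' @export
read_stack <- function(path) {
  x <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(x)) x <- list(x)
  lapply(x, function(f) if (length(dim(f)) == 3) f[, , 1] else f)
}
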