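#' Write and read spike rasters as plain text
#'
#' One event per line, `time_seconds neuron_id`, sorted by time.
#'
#' @param raster data frame with columns `time` and `neuron`, or a
#'   `qif_sim`.
#' @param path file path.
#' @return `read_raster` returns the raster data frame;
#'   `write_raster` returns `path` invisibly.
#' @export
write_raster <- function(raster, path) {
  raster <- as_raster(raster)
  raster <- raster[order(raster$time), ]
  write.table(data.frame(format(raster$time, digits = 17, trim = TRUE,
                                scientific = FALSE),
                         raster$neuron),
              path, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_raster
#' @export
read_raster <- function(path) {
  x <- read.table(path, col.names = c("time", "neuron"),
                  colClasses = c("numeric", "integer"))
  if (nrow(x) > 0) {
    if (is.unsorted(x$time)) stop("malformed raster: times not sorted")
    if (any(x$neuron < 1)) stop("malformed raster: neuron ids must be >= 1")
  }
  x
}

#' Write and read weight matrices with class metadata
#'
#' Plain-text format: comment header lines carrying the matrix size and
#' the per-neuron synapse classes, followed by the dense matrix
#' (one post-synaptic row per line). Round-trips exactly at full double
#' precision.
#'
#' @param weights `N x N` weight matrix.
#' @param class_of per-neuron synapse classes (`"e"`, `"hi"`, `"ai"`).
#' @param path file path.
#' @return `read_weights` returns a list with `weights` and `class_of`;
#'   `write_weights` returns `path` invisibly.
#' @export
write_weights <- function(weights, class_of, path) {
  N <- nrow(weights)
  if (ncol(weights) != N) stop("weight matrix must be square")
  if (length(class_of) != N) stop("class_of must have length N")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# qifstdp weights N=%d", N),
               paste("# class_of:", paste(class_of, collapse = " "))), con)
  write.table(format(weights, digits = 17, trim = TRUE),
              con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_weights
#' @export
read_weights <- function(path) {
  hdr <- readLines(path, n = 2)
  if (!grepl("^# qifstdp weights N=", hdr[1]))
    stop("not a qifstdp weight file: ", path)
  N <- as.integer(sub("^# qifstdp weights N=", "", hdr[1]))
  class_of <- strsplit(sub("^# class_of: ", "", hdr[2]), " ")[[1]]
  w <- as.matrix(read.table(path, skip = 2, colClasses = "numeric"))
  dimnames(w) <- NULL
  if (nrow(w) != N || ncol(w) != N)
    stop("weight matrix shape mismatch: expected ", N, " x ", N)
  list(weights = w, class_of = class_of)
}

#' Write an indicator series as CSV
#'
#' Column names are expected to carry their units as suffixes (e.g.
#' `time_s`, `rate_hz`); they are written in the header row.
#'
#' @param series a data frame.
#' @param path file path.
#' @export
write_series <- function(series, path) {
  utils::write.csv(series, path, row.names = FALSE)
  invisible(path)
}

#' Write an experiment manifest
#'
#' Records the fully resolved configuration, the seed and the output file
#' inventory as JSON, sufficient to re-run the experiment reproducibly.
#'
#' @param config resolved configuration list.
#' @param seed integer seed.
#' @param outputs named character vector of output files.
#' @param path file path.
#' @export
write_manifest <- function(config, seed, outputs, path) {
  manifest <- list(package = "qifstdp",
                   version = as.character(utils::packageVersion("qifstdp")),
                   seed = seed, config = config,
                   outputs = as.list(outputs),
                   written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
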