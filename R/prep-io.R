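# prep module, part 3: serialization.
#
# Epoch container schema (a directory):
#   meta.json  - fs, time axis, array dims + dim order, lead metadata,
#                optional ground truth, format version
#   trials.tsv - per-trial task labels
#   data.bin   - float64 little-endian, trial-fastest ordering as written
#                by writeBin(as.numeric(data)) (R column-major order)

EPOCH_CONTAINER_VERSION <- 1L

#' Save / load an EpochSet container
#'
#' Round-trip contract: `load_epochs(save_epochs(x, path))` reproduces the
#' data and all metadata exactly.
#'
#' @param x an [epoch_set()].
#' @param path directory path for the container (created if missing).
#' @return `save_epochs` returns `path` invisibly; `load_epochs` an
#'   [epoch_set()].
#' @export
save_epochs <- function(x, path) {
  stopifnot(inherits(x, "epoch_set"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(format = "leadtime-epochs",
               version = EPOCH_CONTAINER_VERSION,
               fs = x$fs, time = x$time, dim = dim(x$data),
               dim_order = c("trial", "lead", "sample"),
               leads = x$leads)
  if (!is.null(x$ground_truth)) meta$ground_truth <- unclass(x$ground_truth)
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_trials(x$trials, file.path(path, "trials.tsv"))
  con <- file(file.path(path, "data.bin"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(x$data), con, size = 8L, endian = "little")
  invisible(path)
}

#' @rdname save_epochs
#' @export
load_epochs <- function(path) {
  mf <- file.path(path, "meta.json")
  if (!file.exists(mf)) stopf("'%s' is not an epoch container (no meta.json)", path)
  meta <- jsonlite::read_json(mf, simplifyVector = TRUE)
  for (f in c("fs", "time", "dim", "leads"))
    if (is.null(meta[[f]])) stopf("epoch container missing metadata field '%s'", f)
  if (!identical(meta$format, "leadtime-epochs"))
    stopf("unrecognized container format '%s'", meta$format %||% "<none>")
  trials <- read_trials(file.path(path, "trials.tsv"))
  con <- file(file.path(path, "data.bin"), "rb")
  on.exit(close(con))
  n <- prod(meta$dim)
  vals <- readBin(con, "numeric", n = n, size = 8L, endian = "little")
  if (length(vals) != n) stopf("data.bin truncated: expected %d values, got %d",
                               n, length(vals))
  gt <- if (!is.null(meta$ground_truth))
    structure(meta$ground_truth, class = "ground_truth") else NULL
  epoch_set(array(vals, meta$dim), meta$fs, meta$time, meta$leads, trials,
            ground_truth = gt)
}

#' Write result tables and provenance to a run directory
#'
#' Writes each element of `tables` (data.frames as TSV, other lists as
#' JSON) into `path`, plus a `provenance.json` block.
#'
#' @param tables named list of data.frames and/or lists.
#' @param path output directory (created if missing).
#' @param provenance optional named list (config echo, seeds, versions).
#' @return invisibly, the vector of files written.
#' @export
save_results <- function(tables, path, provenance = NULL) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  for (nm in names(tables)) {
    x <- tables[[nm]]
    if (is.data.frame(x)) {
      f <- file.path(path, paste0(nm, ".tsv"))
      write.table(x, f, sep = "\t", quote = FALSE, row.names = FALSE)
    } else {
      f <- file.path(path, paste0(nm, ".json"))
      jsonlite::write_json(x, f, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                           force = TRUE)
    }
    written <- c(written, f)
  }
  if (!is.null(provenance)) {
    f <- file.path(path, "provenance.json")
    provenance$package_version <- as.character(utils::packageVersion("leadtime"))
    jsonlite::write_json(provenance, f, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, force = TRUE)
    written <- c(written, f)
  }
  invisible(written)
}
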