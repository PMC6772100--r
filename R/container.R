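CONTAINER_FORMAT <- "ringmrsi-container"
CONTAINER_VERSION <- 1L

container_error <- function(msg, class) {
  stop(structure(class = c(class, "mrsi_container_error", "error",
                           "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Save a dataset bundle to a single container file
#'
#' Serializes k-space objects, trajectories, patterns, weights, maps, the
#' run configuration and a log into one versioned file (native R
#' serialization). `load_container(save_container(...))` round-trips all
#' contents bitwise.
#'
#' @param objects named list of objects to store.
#' @param path output file path.
#' @param config optional run configuration echoed into the container.
#' @param seed optional seed recorded for provenance.
#' @param log character vector of log lines to embed.
#' @return `path`, invisibly.
#' @export
save_container <- function(objects, path, config = NULL, seed = NULL,
                           log = character()) {
  stopifnot(is.list(objects))
  if (is.null(names(objects)) || any(names(objects) == ""))
    stop("all container objects must be named")
  bundle <- structure(list(
    format = CONTAINER_FORMAT,
    version = CONTAINER_VERSION,
    created = format(Sys.time(), tz = "UTC"),
    config = config, seed = seed, log = log,
    objects = objects
  ), class = "mrsi_container")
  saveRDS(bundle, path)
  invisible(path)
}

#' Load a container file
#'
#' Fails with a named integrity error (class `mrsi_container_error`) on
#' truncated/corrupt files and with a migration error on format-version
#' mismatch.
#'
#' @param path container file written by [save_container()].
#' @return the `mrsi_container` bundle (fields `objects`, `config`,
#'   `seed`, `log`, `version`).
#' @export
load_container <- function(path) {
  if (!file.exists(path))
    container_error(paste0("container file not found: ", path),
                    "mrsi_container_missing")
  bundle <- tryCatch(readRDS(path), error = function(e)
    container_error(paste0("container file ", path,
                           " is corrupt or truncated: ",
                           conditionMessage(e)),
                    "mrsi_container_corrupt"))
  if (!is.list(bundle) || !identical(bundle$format, CONTAINER_FORMAT))
    container_error(paste0(path, " is not a ", CONTAINER_FORMAT, " file"),
                    "mrsi_container_corrupt")
  if (!identical(as.integer(bundle$version), CONTAINER_VERSION))
    container_error(paste0("container version ", bundle$version,
                           " needs migration to version ",
                           CONTAINER_VERSION),
                    "mrsi_container_version")
  bundle
}

#' @export
print.mrsi_container <- function(x, ...) {
  cat(sprintf("mrsi_container v%d (created %s): %d objects\n",
              x$version, x$created, length(x$objects)))
  for (nm in names(x$objects))
    cat("  -", nm, ":", class(x$objects[[nm]])[1], "\n")
  invisible(x)
}
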