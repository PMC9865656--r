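SESSION_SCHEMA_VERSION <- 1L

#' Write / read a session container
#'
#' Sessions are stored one file per recording using R's native serialization
#' (uncompressed, for fast sequential writes of large frame cubes). The
#' container carries a `schema_version` and is validated field-by-field on
#' read, so a truncated or foreign file fails with the name of the missing
#' dataset rather than downstream.
#'
#' @param record A `session_record` (see [simulate_session()]); `frames` may
#'   be `NULL` for metadata-only containers.
#' @param path File path.
#' @return `write_session` returns `path` invisibly; `read_session` returns
#'   the `session_record`.
#' @export
write_session <- function(record, path) {
  stopifnot(inherits(record, "session_record"))
  obj <- unclass(record)
  obj$schema_version <- SESSION_SCHEMA_VERSION
  saveRDS(obj, path, compress = FALSE)
  invisible(path)
}

#' @rdname write_session
#' @export
read_session <- function(path) {
  if (!file.exists(path)) stop("session file not found: ", path)
  obj <- readRDS(path)
  if (is.null(obj$schema_version)) {
    stop("schema error in ", path, ": missing field 'schema_version'")
  }
  if (obj$schema_version > SESSION_SCHEMA_VERSION) {
    stop("schema error in ", path, ": unsupported schema_version ",
         obj$schema_version)
  }
  required <- c("belt", "user_id", "distance_class", "frame_rate",
                "duration", "cfg", "truth")
  for (f in required) {
    if (is.null(obj[[f]])) stop("schema error in ", path, ": missing field '", f, "'")
  }
  obj$schema_version <- NULL
  structure(obj, class = "session_record")
}

#' Read a dataset manifest
#'
#' @param dir Directory containing `manifest.csv` as written by
#'   [build_meta_dataset()].
#' @return The manifest `data.frame`.
#' @export
read_manifest <- function(dir) {
  path <- file.path(dir, "manifest.csv")
  if (!file.exists(path)) stop("manifest not found: ", path)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
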