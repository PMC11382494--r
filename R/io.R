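# CSV round-tripping with role validation, and a versioned JSON parameter
# archive for fitted pipelines and models.

.archive_format <- "cohortsynth-archive"
.archive_version <- 1L

#' Read a cohort table from delimited text
#'
#' Reads a header CSV, validates each declared binary column as two-valued
#' and maps it to \{0,1\} (recording the mapping), and drops rows with
#' missing values in the used columns (with a message giving the count).
#'
#' @param path CSV file with a header row.
#' @param continuous,binary Column names per type.
#' @param group,outcome Optional single column names.
#' @param sep Field separator.
#' @return Data frame restricted to the used columns, with attributes
#'   `"roles"`, `"binary_maps"` (per-column level-to-\{0,1\} maps) and
#'   `"n_dropped"`.
#' @export
read_cohort <- function(path, continuous, binary = character(0),
                        group = NULL, outcome = NULL, sep = ",") {
  stopifnot(file.exists(path))
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  cols <- c(continuous, binary, group, outcome)
  missing_cols <- setdiff(cols, names(raw))
  if (length(missing_cols) > 0L)
    stop("read_cohort: column(s) not in file: ",
         paste(missing_cols, collapse = ", "))
  df <- raw[, cols, drop = FALSE]
  maps <- list()
  for (nm in c(binary, group, outcome)) {
    v <- df[[nm]]
    lev <- sort(unique(v[!is.na(v)]))
    if (length(lev) != 2L)
      stop("read_cohort: column ", nm, " is not two-valued (levels: ",
           paste(utils::head(lev, 5), collapse = ", "), ")")
    if (!identical(as.character(lev), c("0", "1"))) {
      df[[nm]] <- as.numeric(match(v, lev) - 1L)
      maps[[nm]] <- stats::setNames(c(0, 1), as.character(lev))
      message("read_cohort: mapped ", nm, ": ", lev[1L], "->0, ", lev[2L], "->1")
    } else df[[nm]] <- as.numeric(v)
  }
  keep <- stats::complete.cases(df)
  n_dropped <- sum(!keep)
  if (n_dropped > 0L)
    message("read_cohort: dropped ", n_dropped, " row(s) with missing values")
  df <- df[keep, , drop = FALSE]
  attr(df, "roles") <- list(continuous = continuous, binary = binary,
                            group = group, outcome = outcome)
  attr(df, "binary_maps") <- maps
  attr(df, "n_dropped") <- n_dropped
  df
}

#' Write a cohort table to CSV
#'
#' @param data Data frame.
#' @param path Output file.
#' @export
write_cohort <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Save a fitted pipeline or model to a versioned JSON archive
#'
#' Serialises all fitted parameters (transform parameters, network weights,
#' configuration) to a portable text/JSON encoding at full double precision.
#' The transformed training table of a `synthvae` fit is *not* stored, so an
#' archive discloses model parameters only; after [load_archive()], prior-mode
#' generation reproduces the original fit exactly, while posterior-mode
#' generation (which needs the training rows) is unavailable.
#'
#' @param x A `synthvae`, `trained_vae`, `transform_pipeline`,
#'   `propensity_model` or `latent_grid` object.
#' @param path Output file.
#' @export
save_archive <- function(x, path) {
  if (inherits(x, "synthvae")) x$data01 <- NULL
  payload <- jsonlite::serializeJSON(x, digits = I(17))  # exact double round trip
  obj <- list(format = .archive_format, version = .archive_version,
              class = class(x)[1L], payload = payload)
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE), path)
  invisible(path)
}

#' Load an archive written by [save_archive()]
#'
#' @param path Archive file.
#' @return The restored object.
#' @export
load_archive <- function(path) {
  stopifnot(file.exists(path))
  obj <- tryCatch(jsonlite::fromJSON(readLines(path, warn = FALSE)),
                  error = function(e)
                    stop("load_archive: not a readable archive: ",
                         conditionMessage(e)))
  if (!identical(obj$format, .archive_format))
    stop("load_archive: unrecognised archive format")
  if (!identical(as.integer(obj$version), .archive_version))
    stop("load_archive: archive version ", obj$version,
         " does not match supported version ", .archive_version)
  jsonlite::unserializeJSON(obj$payload)
}
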