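#' Construct a cytometric profile
#'
#' A cytometric profile is an event-by-marker matrix of intensities together
#' with its sample and panel identity. Rows are cells (events), columns are
#' markers; marker names must be unique. Profiles start out untransformed
#' (raw ion-count scale); [arcsinh_transform()] moves them to arcsinh units
#' and flips the `transformed` flag so the transform cannot be applied twice.
#'
#' @param exprs numeric matrix (events x markers) with unique column names.
#' @param sample_id sample identifier (e.g. donor id).
#' @param panel_id antibody-panel identifier.
#' @param event_ids optional per-row identifiers; used by the synthetic-data
#'   generator to carry ground-truth cell identities. Never consulted by the
#'   matching algorithm.
#' @param transformed logical; `TRUE` if `exprs` is already in arcsinh units.
#' @return an object of class `cyto_profile`.
#' @seealso [read_profile()], [arcsinh_transform()], [subset_markers()]
#' @export
cyto_profile <- function(exprs, sample_id = NA_character_,
                         panel_id = NA_character_, event_ids = NULL,
                         transformed = FALSE) {
  exprs <- as.matrix(exprs)
  if (nrow(exprs) > 0L) storage.mode(exprs) <- "double"
  mk <- colnames(exprs)
  if (is.null(mk) || anyNA(mk) || any(mk == "")) {
    stop("every profile column must be named after a marker", call. = FALSE)
  }
  if (anyDuplicated(mk)) {
    stop("duplicate marker name(s): ",
         paste(unique(mk[duplicated(mk)]), collapse = ", "), call. = FALSE)
  }
  if (!is.null(event_ids) && length(event_ids) != nrow(exprs)) {
    stop("event_ids must have one entry per event", call. = FALSE)
  }
  structure(
    list(exprs = exprs, sample_id = sample_id, panel_id = panel_id,
         event_ids = event_ids, transformed = isTRUE(transformed)),
    class = "cyto_profile"
  )
}

#' @export
print.cyto_profile <- function(x, ...) {
  cat(sprintf("<cyto_profile> %s / %s: %d events x %d markers (%s)\n",
              x$sample_id, x$panel_id, nrow(x$exprs), ncol(x$exprs),
              if (x$transformed) "arcsinh units" else "untransformed"))
  invisible(x)
}

#' Marker names of a profile
#' @param profile a [cyto_profile()].
#' @return character vector of marker names in column order.
#' @export
profile_markers <- function(profile) colnames(profile$exprs)

#' Number of events in a profile
#' @param profile a [cyto_profile()].
#' @return integer event count.
#' @export
n_events <- function(profile) nrow(profile$exprs)

#' Arcsinh-transform a profile
#'
#' Applies the variance-stabilizing transform standard for mass cytometry,
#' `asinh(x / cofactor)`, to every intensity. The default cofactor of 5 is
#' the usual CyTOF choice. Transforming an already-transformed profile is an
#' error: all downstream stages (matching, clustering, categorization)
#' operate in arcsinh units and expect exactly one application.
#'
#' @param profile an untransformed [cyto_profile()].
#' @param cofactor positive scale divisor (default 5).
#' @return the transformed profile with its `transformed` flag set.
#' @export
#' @examples
#' p <- cyto_profile(matrix(c(0, 5), 2, 1, dimnames = list(NULL, "CD3")))
#' arcsinh_transform(p)$exprs # 0 and asinh(1) = 0.8813736
arcsinh_transform <- function(profile, cofactor = 5) {
  check_positive_scalar(cofactor, "cofactor")
  if (profile$transformed) {
    stop("profile is already arcsinh-transformed", call. = FALSE)
  }
  profile$exprs[] <- asinh(profile$exprs / cofactor)
  profile$transformed <- TRUE
  profile
}

#' Restrict a profile to a marker subset
#'
#' Columns are restricted and reordered to `markers`; rows are untouched.
#' Used to pull out backbone columns before cross-panel matching.
#'
#' @param profile a [cyto_profile()].
#' @param markers character vector; must all be present in the profile.
#' @return a profile with the requested columns, in the requested order.
#' @export
subset_markers <- function(profile, markers) {
  missing <- setdiff(markers, profile_markers(profile))
  if (length(missing)) {
    stop("unknown marker(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  profile$exprs <- profile$exprs[, markers, drop = FALSE]
  profile
}

#' Read a cytometric profile from disk
#'
#' Two on-disk formats are supported: `"tsv"`, a tab-separated event table
#' whose first row holds marker names (one event per subsequent row, decimal
#' point, no index column), and `"fcs"`, FCS 3.0/3.1 list-mode files (see
#' [read_fcs()] for the subset of the standard handled). The returned
#' profile is flagged untransformed; event order is preserved as stored.
#'
#' @param path file to read.
#' @param format `"tsv"` or `"fcs"`.
#' @param sample_id,panel_id identity to attach to the profile.
#' @return a [cyto_profile()].
#' @export
read_profile <- function(path, format = c("tsv", "fcs"),
                         sample_id = NA_character_,
                         panel_id = NA_character_) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read: ", path, call. = FALSE)
  exprs <- switch(format, tsv = read_profile_tsv(path), fcs = read_fcs(path))
  cyto_profile(exprs, sample_id = sample_id, panel_id = panel_id)
}

#' Write a cytometric profile to disk
#'
#' The TSV dialect round-trips values at full double precision; FCS output
#' is FCS 3.1 with float32 storage (round-trip error bounded by single
#' precision, about 1e-7 relative).
#'
#' @param profile a [cyto_profile()].
#' @param path destination file.
#' @param format `"tsv"` or `"fcs"`.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path, format = c("tsv", "fcs")) {
  format <- match.arg(format)
  switch(format,
    tsv = {
      ok <- tryCatch({
        utils::write.table(profile$exprs, path, sep = "\t", quote = FALSE,
                           row.names = FALSE, col.names = TRUE)
        TRUE
      }, error = function(e) FALSE, warning = function(w) FALSE)
      if (!ok) stop("cannot write: ", path, call. = FALSE)
    },
    fcs = write_fcs(profile$exprs, path)
  )
  invisible(path)
}

read_profile_tsv <- function(path) {
  header_line <- readLines(path, n = 1L)
  if (!length(header_line)) stop("empty file: ", path, call. = FALSE)
  header <- strsplit(header_line, "\t", fixed = TRUE)[[1]]
  if (anyDuplicated(header)) {
    stop("duplicate marker name(s) in ", path, ": ",
         paste(unique(header[duplicated(header)]), collapse = ", "),
         call. = FALSE)
  }
  dat <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE,
                           colClasses = rep("numeric", length(header)))
  m <- as.matrix(dat)
  if (nrow(m) == 0L) {
    m <- matrix(numeric(0), 0L, length(header),
                dimnames = list(NULL, header))
  }
  m
}
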