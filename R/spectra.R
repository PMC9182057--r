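#' Construct a spectra dataset
#'
#' The central container of the package: an absorbance matrix with its
#' wavenumber axis, per-sample reference values for one or more analytes, and
#' sample identifiers. The axis is canonicalized to strictly increasing
#' wavenumber; if it arrives in descending order (common in NIR exports, which
#' plot high wavenumber on the left) the axis and the columns of `X` are
#' reversed together.
#'
#' @param axis numeric vector of wavenumbers (cm^-1), strictly monotonic.
#' @param X numeric matrix of absorbances, one row per sample, `length(axis)`
#'   columns.
#' @param y named list (or data.frame) of reference-value vectors (% mass),
#'   one entry per analyte, each of length `nrow(X)`. May be empty.
#' @param ids character vector of unique sample labels; defaults to
#'   `"S1".."Sn"`.
#' @return An object of class `spectra_dataset` with elements `axis`, `X`,
#'   `y`, `ids`.
#' @examples
#' ds <- spectra_dataset(c(4000, 4008, 4016),
#'                       matrix(runif(6), 2, 3),
#'                       y = list(cellulose = c(40, 45)))
#' ds
#' @export
spectra_dataset <- function(axis, X, y = list(), ids = NULL) {
  axis <- as.numeric(axis)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (length(axis) != ncol(X))
    stop("axis length (", length(axis), ") != number of spectral columns (",
         ncol(X), ")")
  d <- diff(axis)
  if (length(axis) > 1 && !(all(d > 0) || all(d < 0)))
    stop("wavenumber axis must be strictly monotonic")
  if (length(axis) > 1 && all(d < 0)) {  # canonicalize to ascending
    axis <- rev(axis)
    X <- X[, rev(seq_len(ncol(X))), drop = FALSE]
  }
  if (is.data.frame(y)) y <- as.list(y)
  if (is.null(names(y)) && length(y) > 0)
    stop("analyte vectors in `y` must be named")
  y <- lapply(y, as.numeric)
  for (nm in names(y)) {
    if (length(y[[nm]]) != nrow(X))
      stop("analyte '", nm, "' has length ", length(y[[nm]]),
           ", expected ", nrow(X))
    if (any(!is.finite(y[[nm]])))
      stop("non-finite reference values in analyte '", nm, "'")
  }
  if (any(!is.finite(X)))
    stop("non-finite values in the absorbance matrix")
  if (is.null(ids)) ids <- paste0("S", seq_len(nrow(X)))
  ids <- as.character(ids)
  if (length(ids) != nrow(X)) stop("ids length must equal the sample count")
  if (anyDuplicated(ids)) stop("duplicate sample id: ",
                               ids[duplicated(ids)][1])
  dimnames(X) <- NULL
  structure(list(axis = axis, X = X, y = y, ids = ids),
            class = "spectra_dataset")
}

#' @export
print.spectra_dataset <- function(x, ...) {
  cat("spectra_dataset: ", nrow(x$X), " samples x ", ncol(x$X),
      " wavelength variables\n", sep = "")
  cat("  axis: ", format(min(x$axis)), " .. ", format(max(x$axis)),
      " cm^-1\n", sep = "")
  if (length(x$y))
    cat("  analytes: ", paste(names(x$y), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
dim.spectra_dataset <- function(x) dim(x$X)

#' Restrict a dataset to a wavelength subset
#'
#' Keeps only the given spectral columns; reference values and sample ids are
#' untouched. Indices are 1-based column positions into the (ascending) axis.
#'
#' @param ds a [spectra_dataset()].
#' @param indices integer vector of column indices (duplicates are dropped,
#'   order is made ascending).
#' @return A `spectra_dataset` on the restricted axis.
#' @export
subset_columns <- function(ds, indices) {
  stopifnot(inherits(ds, "spectra_dataset"))
  indices <- sort(unique(as.integer(indices)))
  if (length(indices) == 0) stop("empty wavelength subset: models need >= 1 variable")
  if (min(indices) < 1 || max(indices) > ncol(ds$X))
    stop("wavelength index out of range [1, ", ncol(ds$X), "]")
  spectra_dataset(ds$axis[indices], ds$X[, indices, drop = FALSE],
                  ds$y, ds$ids)
}

#' Subset samples of a dataset by row position or id
#' @param ds a [spectra_dataset()].
#' @param rows integer row positions or character ids.
#' @return A `spectra_dataset` with the selected samples.
#' @export
subset_samples <- function(ds, rows) {
  stopifnot(inherits(ds, "spectra_dataset"))
  if (is.character(rows)) rows <- match(rows, ds$ids)
  rows <- as.integer(rows)
  if (any(is.na(rows)) || any(rows < 1) || any(rows > nrow(ds$X)))
    stop("unknown sample selection")
  spectra_dataset(ds$axis, ds$X[rows, , drop = FALSE],
                  lapply(ds$y, `[`, rows), ds$ids[rows])
}

#' Read a delimited spectra table
#'
#' Expects one header row and one row per sample. Columns whose header parses
#' as a number are spectral variables (the header value is the wavenumber);
#' the remaining columns are reference analytes, except an optional id column.
#' A descending wavenumber axis is reversed to ascending at load. Missing or
#' non-numeric cells are rejected, not imputed.
#'
#' @param path file path.
#' @param sep field separator; `NULL` (default) tries comma then tab.
#' @param analytes character vector naming the analyte columns; default: every
#'   non-numeric header except `id_col`.
#' @param id_col name of the sample-id column, if present (default `"id"`).
#' @return A [spectra_dataset()].
#' @export
read_spectra_table <- function(path, sep = NULL, analytes = NULL,
                               id_col = "id") {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(sep)) {
    first <- readLines(path, n = 1L)
    sep <- if (grepl("\t", first)) "\t" else ","
  }
  tab <- read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                    colClasses = "character", stringsAsFactors = FALSE)
  hdr <- names(tab)
  num_hdr <- suppressWarnings(as.numeric(hdr))
  is_wave <- !is.na(num_hdr)
  if (!any(is_wave)) stop("format error: no numeric wavenumber headers found")
  if (is.null(analytes)) analytes <- setdiff(hdr[!is_wave], id_col)
  missing_an <- setdiff(analytes, hdr)
  if (length(missing_an))
    stop("declared analyte column(s) absent: ",
         paste(missing_an, collapse = ", "))

  parse_num <- function(col, what) {
    v <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- which(is.na(v) | !is.finite(v))
    if (length(bad))
      stop("parse error in ", what, " column '", col, "', row ", bad[1],
           ": '", tab[[col]][bad[1]], "' is not a finite number")
    v
  }
  wave_cols <- hdr[is_wave]
  X <- vapply(wave_cols, parse_num, numeric(nrow(tab)), what = "spectral")
  X <- matrix(X, nrow = nrow(tab), dimnames = NULL)
  y <- lapply(stats::setNames(analytes, analytes), parse_num,
              what = "analyte")
  ids <- if (id_col %in% hdr) tab[[id_col]] else NULL
  spectra_dataset(num_hdr[is_wave], X, y, ids)
}

#' Write a spectra table
#'
#' Inverse of [read_spectra_table()]: header = wavenumbers then analyte names
#' then `id`; values written with 15 significant digits so that a round trip
#' reproduces the data to text precision.
#'
#' @param ds a [spectra_dataset()].
#' @param path output file path.
#' @param sep field separator (default comma).
#' @return `path`, invisibly.
#' @export
write_spectra_table <- function(ds, path, sep = ",") {
  stopifnot(inherits(ds, "spectra_dataset"))
  fmt <- function(v) formatC(v, digits = 15, format = "g")
  hdr <- c(fmt(ds$axis), names(ds$y), "id")
  body <- cbind(matrix(fmt(ds$X), nrow = nrow(ds$X)),
                vapply(ds$y, fmt, character(nrow(ds$X))),
                ds$ids)
  lines <- c(paste(hdr, collapse = sep),
             apply(body, 1, paste, collapse = sep))
  writeLines(lines, path)
  invisible(path)
}
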