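#' Read a single-spectrum JCAMP-DX file
#'
#' Minimal reader for the `##XYDATA=(X++(Y..Y))` tabular form used to exchange
#' single NIR spectra. The axis is reconstructed from `FIRSTX`, `LASTX` and
#' `NPOINTS` as `FIRSTX + i * (LASTX - FIRSTX) / (NPOINTS - 1)`; ordinates are
#' multiplied by `YFACTOR`. The leading X value on each data line is a check
#' value and is not used to build the axis. Compressed (SQZ/DIF/DUP) encodings
#' and multi-block files are not supported.
#'
#' @param path file path.
#' @return A list with `axis` (numeric) and `spectrum` (numeric), both of
#'   length `NPOINTS`.
#' @export
read_jcamp_single <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  get_label <- function(label) {
    pat <- paste0("^##", label, "=")
    hit <- grep(pat, lines, ignore.case = TRUE, value = TRUE)
    if (length(hit) == 0) stop("JCAMP format error: missing ##", label, "=")
    sub(pat, "", hit[1], ignore.case = TRUE)
  }
  firstx <- as.numeric(get_label("FIRSTX"))
  lastx <- as.numeric(get_label("LASTX"))
  npoints <- as.integer(as.numeric(get_label("NPOINTS")))
  yfactor <- as.numeric(get_label("YFACTOR"))
  # XFACTOR is required by the form but only scales the per-line X check value
  xfactor <- as.numeric(get_label("XFACTOR"))
  if (any(is.na(c(firstx, lastx, npoints, yfactor, xfactor))))
    stop("JCAMP format error: non-numeric header value")
  if (npoints < 2) stop("JCAMP format error: NPOINTS must be >= 2")

  start <- grep("^##XYDATA=", lines, ignore.case = TRUE)
  if (length(start) == 0) stop("JCAMP format error: missing ##XYDATA=")
  body <- lines[(start[1] + 1):length(lines)]
  endi <- grep("^##", body)
  if (length(endi)) body <- body[seq_len(endi[1] - 1)]
  body <- trimws(body[nzchar(trimws(body))])
  yvals <- unlist(lapply(body, function(ln) {
    toks <- strsplit(ln, "[[:space:]]+")[[1]]
    if (length(toks) < 2)
      stop("JCAMP format error: data line without ordinates: '", ln, "'")
    v <- suppressWarnings(as.numeric(toks[-1]))  # first token = X check value
    if (any(is.na(v)))
      stop("JCAMP format error: non-numeric ordinate in '", ln, "'")
    v
  }), use.names = FALSE)
  if (length(yvals) != npoints)
    stop("JCAMP format error: NPOINTS=", npoints, " but ", length(yvals),
         " ordinates decoded")
  axis <- firstx + (seq_len(npoints) - 1) * (lastx - firstx) / (npoints - 1)
  list(axis = axis, spectrum = yvals * yfactor)
}
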