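# Reader/writer for columnar reduced SAS data (SASBDB-style .dat files):
# 2-4 numeric columns (q, I[, sigma_I[, sigma_q]]), '#' or free-text header
# lines, whitespace or comma delimited.

.META_KEYS <- c("label", "f_d2o", "instrument", "dq_over_q")

#' Read a columnar reduced SAS data file
#'
#' Accepts the common deposited-data dialects without configuration:
#' comment/header lines (starting with `#` or simply non-numeric) are
#' skipped, columns may be separated by whitespace or commas, and 2, 3 or 4
#' numeric columns are interpreted as q, I, sigma_I, sigma_q. Rows with
#' non-positive q or non-finite values are dropped (count recorded in
#' `metadata$n_dropped`); 2-column files get a synthesized
#' `sigma_i = 1% of I`, flagged in the metadata. q is assumed to be in
#' 1/Angstrom unless a header line declares 1/nm (e.g. `nm^-1`), in which
#' case it is converted.
#'
#' Header lines of the form `# key: value` for keys label, f_d2o,
#' instrument and dq_over_q are picked up into the curve metadata, so
#' [write_sas_ascii()] output round-trips.
#'
#' @param path Path to an ASCII file.
#' @return A [scattering_curve()].
#' @export
read_sas_ascii <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  meta <- list(source = path)

  header_mask <- logical(length(lines))
  rows <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    ln <- trimws(sub("^#+", "", lines[i]))
    toks <- strsplit(ln, "[,;[:space:]]+")[[1]]
    toks <- toks[nzchar(toks)]
    vals <- suppressWarnings(as.numeric(toks))
    # NaN/Inf tokens are numeric (a bad data row, dropped later with a
    # count); unparseable tokens mark a header line
    if (length(vals) >= 2 && all(!is.na(vals) | is.nan(vals))) {
      rows[[i]] <- vals
    } else {
      header_mask[i] <- TRUE
    }
  }
  header <- lines[header_mask]
  for (h in header) {
    m <- regmatches(h, regexec("^#\\s*([A-Za-z_0-9]+)\\s*:\\s*(.+)$", h))[[1]]
    if (length(m) == 3 && m[2] %in% .META_KEYS) {
      v <- suppressWarnings(as.numeric(m[3]))
      meta[[m[2]]] <- if (is.na(v)) trimws(m[3]) else v
    }
  }
  rows <- rows[!header_mask & !vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    stop("no numeric data rows in '", path, "'", call. = FALSE)
  }
  ncols <- vapply(rows, length, integer(1))
  tab <- table(ncols)
  nc <- min(as.integer(names(tab)[which.max(tab)]), 4L)  # modal column count
  keep_rows <- ncols >= nc
  mat <- do.call(rbind, lapply(rows[keep_rows], function(r) r[seq_len(nc)]))

  nm_unit <- any(grepl("nm\\^?\\{?-1\\}?|1\\s*/\\s*nm|\\[\\s*nm", header,
                       ignore.case = TRUE))
  if (nm_unit) {
    mat[, 1] <- mat[, 1] / 10
    meta$q_unit_converted <- "nm^-1 -> A^-1"
  }
  ok <- is.finite(mat[, 1]) & mat[, 1] > 0 &
    apply(mat, 1, function(r) all(is.finite(r)))
  if (nc >= 3) ok <- ok & mat[, 3] > 0
  n_dropped <- sum(!ok) + sum(!keep_rows)
  if (!any(ok)) stop("no usable data rows in '", path, "'", call. = FALSE)
  mat <- mat[ok, , drop = FALSE]
  meta$n_dropped <- n_dropped
  scattering_curve(
    q = mat[, 1], intensity = mat[, 2],
    sigma_i = if (nc >= 3) mat[, 3],
    sigma_q = if (nc >= 4) mat[, 4],
    metadata = meta
  )
}

#' Write a reduced SAS curve as columnar ASCII
#'
#' Emits a `#`-commented header (column names plus the label / D2O fraction
#' / instrument metadata understood by [read_sas_ascii()]) followed by 3 or
#' 4 columns at full double precision, so a write/read round trip is
#' lossless.
#'
#' @param curve A [scattering_curve()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_sas_ascii <- function(curve, path) {
  stopifnot(inherits(curve, "scattering_curve"))
  has_sq <- !is.null(curve$sigma_q)
  hdr <- c("# reduced SAS data (sanstools)",
           "# q_unit: A^-1")
  for (k in .META_KEYS) {
    v <- curve$metadata[[k]]
    if (!is.null(v) && length(v) == 1L) {
      hdr <- c(hdr, sprintf("# %s: %s", k, format(v, digits = 17)))
    }
  }
  hdr <- c(hdr, paste0("# columns: q intensity sigma_i",
                       if (has_sq) " sigma_q"))
  cols <- list(curve$q, curve$intensity, curve$sigma_i)
  if (has_sq) cols <- c(cols, list(curve$sigma_q))
  body <- do.call(paste, c(lapply(cols, function(x) {
    sprintf("%.17g", x)
  }), sep = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}
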