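#' Read and write scalar fields as plain text
#'
#' Two text formats cover exact storage and visualization-grade storage:
#'
#' * `"tsv"`: a tab-separated matrix preceded by a `# field <rows> <cols>`
#'   header, values printed with 17 significant digits — the round trip is
#'   bit-exact for doubles.
#' * `"pgm"`: a 16-bit ASCII portable graymap (`P2`) with the original
#'   min/max stored in a comment line so the field can be de-quantized on
#'   read; the round trip is exact to within `(max - min) / 65535`.
#'
#' @param field Numeric matrix.
#' @param path File path; `read_field()` dispatches on the file's magic
#'   (`P2`) or header.
#' @param format `"tsv"` (default) or `"pgm"`.
#' @return `read_field()` returns the numeric matrix; `write_field()`
#'   returns `path` invisibly.
#' @export
write_field <- function(field, path, format = c("tsv", "pgm")) {
  format <- match.arg(format)
  stopifnot(is.matrix(field), is.numeric(field), all(is.finite(field)))
  if (format == "tsv") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# field %d %d", nrow(field), ncol(field)), con)
    writeLines(apply(field, 1, function(r) paste(sprintf("%.17g", r),
                                                 collapse = "\t")), con)
  } else {
    rng <- range(field)
    q <- if (diff(rng) == 0) matrix(0L, nrow(field), ncol(field))
         else matrix(as.integer(round((field - rng[1]) / diff(rng) * 65535)),
                     nrow(field), ncol(field))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("P2",
                 sprintf("# min %.17g max %.17g", rng[1], rng[2]),
                 sprintf("%d %d", ncol(field), nrow(field)),
                 "65535"), con)
    writeLines(apply(q, 1, paste, collapse = " "), con)
  }
  invisible(path)
}

#' @rdname write_field
#' @export
read_field <- function(path) {
  first <- readLines(path, n = 1)
  if (identical(first, "P2")) {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    meta <- lines[startsWith(lines, "#")]
    body <- lines[!startsWith(lines, "#")][-1]   # drop "P2"
    dims <- as.integer(strsplit(trimws(body[1]), "\\s+")[[1]])
    maxval <- as.numeric(body[2])
    vals <- as.numeric(unlist(strsplit(trimws(body[-(1:2)]), "\\s+")))
    if (length(vals) != dims[1] * dims[2]) stop("PGM payload size mismatch")
    m <- matrix(vals, nrow = dims[2], ncol = dims[1], byrow = TRUE)
    mm <- regmatches(meta[1], gregexpr("-?[0-9.eE+-]+", meta[1]))[[1]]
    lo <- as.numeric(mm[1]); hi <- as.numeric(mm[2])
    if (hi == lo) matrix(lo, nrow(m), ncol(m)) else lo + m / maxval * (hi - lo)
  } else {
    hdr <- strsplit(trimws(sub("^#", "", first)), "\\s+")[[1]]
    if (hdr[1] != "field") stop("unrecognized field file: ", path)
    dims <- as.integer(hdr[2:3])
    m <- as.matrix(read.table(path, sep = "\t", skip = 1,
                              colClasses = "numeric"))
    dimnames(m) <- NULL
    if (!all(dim(m) == dims)) stop("field dimensions disagree with header")
    m
  }
}

#' Export diagnostics and tables as CSV
#'
#' Thin wrappers with consistent settings (no row names, no quoting).
#'
#' @param x A data.frame.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_csv_table <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Structured log line
#'
#' Writes `time | level | module | message` to `stderr`. Numeric results
#' never travel through the log; they go to CSV/TSV outputs.
#'
#' @param module Short module tag.
#' @param msg Message (sprintf-style with `...`).
#' @param ... sprintf arguments.
#' @param level One of `"info"`, `"warn"`, `"error"`.
#' @return Invisibly, the formatted line.
#' @export
log_line <- function(module, msg, ..., level = "info") {
  line <- sprintf("%s | %-5s | %s | %s",
                  format(Sys.time(), "%Y-%m-%d %H:%M:%S"), level, module,
                  sprintf(msg, ...))
  message(line)
  invisible(line)
}
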