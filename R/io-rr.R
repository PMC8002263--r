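#' Read and write the plain-text RR format
#'
#' One subject per file. The first line is a header
#' `# subject_id=<id> label=<NSR|CHF|AF>`; every following non-empty line is
#' `<seconds> <annotation-char>` separated by whitespace. The writer emits
#' intervals with six decimals, and `write_rr_text(read_rr_text(f), f2)`
#' reproduces a canonically formatted file byte for byte.
#'
#' @param path File to read or write.
#' @param series An [rr_series()] (writer only).
#' @return `read_rr_text()` returns an [rr_series()];
#'   `write_rr_text()` returns `path` invisibly.
#' @export
read_rr_text <- function(path) {
  if (!file.exists(path)) stop_invalid("no such file: ", path)
  lines <- readLines(path)
  if (!length(lines) || !grepl("^#", lines[1]))
    stop_invalid("line 1: missing '# subject_id=... label=...' header in ",
                 path)
  hdr <- lines[1]
  id <- sub(".*subject_id=(\\S+).*", "\\1", hdr)
  lab <- sub(".*label=(\\S+).*", "\\1", hdr)
  if (identical(id, hdr) || identical(lab, hdr))
    stop_invalid("line 1: malformed header: ", hdr)
  body <- lines[-1]
  body_no <- which(nzchar(trimws(body))) + 1L  # original line numbers
  body <- body[nzchar(trimws(body))]
  if (!length(body)) stop_invalid("empty data section in ", path)
  parts <- strsplit(trimws(body), "\\s+")
  bad <- which(lengths(parts) != 2)
  if (length(bad))
    stop_invalid("line ", body_no[bad[1]], ": expected '<seconds> <code>'")
  iv <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 1)))
  if (anyNA(iv))
    stop_invalid("line ", body_no[which(is.na(iv))[1]],
                 ": non-numeric interval")
  ann <- vapply(parts, `[[`, "", 2)
  rr_series(id, lab, iv, ann)
}

#' @rdname read_rr_text
#' @export
write_rr_text <- function(series, path) {
  validate_rr_series(series)
  lines <- c(
    sprintf("# subject_id=%s label=%s", series$subject_id, series$label),
    sprintf("%.6f %s", series$intervals, series$annotations))
  writeLines(lines, path)
  invisible(path)
}

#' Read and write a cohort directory
#'
#' One RR text file per subject plus a `MANIFEST` file listing the member
#' file names in order, mirroring the per-subject granularity that
#' subject-wise cross-validation splits on.
#'
#' @param cohort List of [rr_series()].
#' @param dir Directory to create/read.
#' @return `write_cohort()` returns `dir` invisibly; `read_cohort()` a list
#'   of [rr_series()].
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- vapply(cohort, function(s) paste0(s$subject_id, ".rr"),
                  character(1))
  for (i in seq_along(cohort)) {
    write_rr_text(cohort[[i]], file.path(dir, files[i]))
  }
  writeLines(files, file.path(dir, "MANIFEST"))
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  mf <- file.path(dir, "MANIFEST")
  files <- if (file.exists(mf)) readLines(mf) else
    list.files(dir, pattern = "\\.rr$")
  if (!length(files)) stop_invalid("no cohort members found in ", dir)
  lapply(file.path(dir, files), read_rr_text)
}
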