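#' Read a centroided peak list
#'
#' Reads the package's canonical peak-list interchange format: a TSV or CSV
#' file with a header line `mz<sep>intensity`, optionally preceded by
#' `# key=value` comment lines carrying metadata (`label`, `scale`).
#' Centroided mzML is also supported (via the mzR parser); profile-mode
#' scans are rejected because the standardization algorithm operates on
#' peak lists.
#'
#' @param path Path to the file.
#' @param format `"auto"` (by extension), `"tsv"`, `"csv"`, or `"mzml"`.
#' @param scans For mzML only: integer scan indices to read, or `"sum"`
#'   (default) to pool the peaks of all scans.  Pooled peaks sharing an
#'   exact m/z are merged by summing.
#' @param drop_invalid Passed to [as_spectrum()].
#' @return A `spectrum` tibble sorted ascending by m/z.
#' @seealso [write_peaklist()]
#' @export
read_peaklist <- function(path, format = c("auto", "tsv", "csv", "mzml"),
                          scans = "sum", drop_invalid = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "kneescale_io_error")
  }
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", mzml = "mzml", "tsv")
  }
  if (format == "mzml") {
    return(read_mzml(path, scans = scans, drop_invalid = drop_invalid))
  }

  meta <- read_comment_metadata(path)
  delim <- if (format == "csv") "," else "\t"
  tab <- readr::read_delim(path, delim = delim, comment = "#",
                           col_types = readr::cols(.default = readr::col_character()),
                           trim_ws = TRUE, progress = FALSE,
                           show_col_types = FALSE)
  if (ncol(tab) < 2) {
    abort(sprintf("%s: expected at least 2 columns (mz, intensity)", path),
          class = "kneescale_ingest_error")
  }
  if (!all(c("mz", "intensity") %in% names(tab))) names(tab)[1:2] <- c("mz", "intensity")
  mz <- suppressWarnings(as.numeric(tab$mz))
  it <- suppressWarnings(as.numeric(tab$intensity))
  non_num <- which(is.na(mz) | is.na(it))
  if (length(non_num) > 0 && !drop_invalid) {
    abort(sprintf("%s: non-numeric mz/intensity at data row(s) %s", path,
                  paste(head(non_num, 10), collapse = ", ")),
          class = "kneescale_ingest_error")
  }
  as_spectrum(tibble::tibble(mz = mz, intensity = it),
              label = meta$label %||% basename(path),
              scale = meta$scale %||% "raw",
              drop_invalid = drop_invalid)
}

read_comment_metadata <- function(path) {
  meta <- list()
  con <- file(path, "r"); on.exit(close(con))
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0 || !startsWith(line, "#")) break
    kv <- sub("^#\\s*", "", line)
    m <- regmatches(kv, regexec("^([^=]+)=(.*)$", kv))[[1]]
    if (length(m) == 3) meta[[trimws(m[2])]] <- trimws(m[3])
  }
  if (!is.null(meta$scale) && !meta$scale %in% c("raw", "standardized")) meta$scale <- NULL
  meta
}

read_mzml <- function(path, scans = "sum", drop_invalid = FALSE) {
  if (!requireNamespace("mzR", quietly = TRUE)) {
    abort("reading mzML requires the mzR package", class = "kneescale_io_error")
  }
  ms <- mzR::openMSfile(path)
  on.exit(mzR::close(ms))
  hdr <- mzR::header(ms)
  idx <- if (identical(scans, "sum")) seq_len(nrow(hdr)) else as.integer(scans)
  if (any(idx < 1 | idx > nrow(hdr))) {
    abort("scan index out of range", class = "kneescale_io_error")
  }
  if ("centroided" %in% names(hdr) && any(!is.na(hdr$centroided[idx]) & !hdr$centroided[idx])) {
    abort("mzML contains profile-mode scans; only centroided peak lists are supported",
          class = "kneescale_ingest_error")
  }
  pk <- mzR::peaks(ms, idx)
  if (is.matrix(pk)) pk <- list(pk)
  mat <- do.call(rbind, pk)
  suppressWarnings(
    as_spectrum(tibble::tibble(mz = mat[, 1], intensity = mat[, 2]),
                label = basename(path), scale = "raw",
                drop_invalid = drop_invalid)
  )
}

#' Write a peak list
#'
#' Writes the canonical interchange format: `# key=value` comment lines
#' with the label and scale tag, a `mz<sep>intensity` header, then one row
#' per peak in ascending m/z with intensities at 15 significant digits
#' (round-trips through [read_peaklist()] to relative error below 1e-12).
#'
#' @param spectrum A spectrum or peak data frame.
#' @param path Output path.
#' @param format `"tsv"` (default) or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_peaklist <- function(spectrum, path, format = c("tsv", "csv")) {
  format <- match.arg(format)
  s <- as_spectrum(spectrum)
  sep <- if (format == "csv") "," else "\t"
  lines <- c(
    sprintf("# label=%s", spectrum_label(s)),
    sprintf("# scale=%s", spectrum_scale(s)),
    paste0("mz", sep, "intensity"),
    sprintf("%.15g%s%.15g", s$mz, sep, s$intensity)
  )
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) abort(sprintf("cannot write to %s", path), class = "kneescale_io_error")
  invisible(path)
}
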