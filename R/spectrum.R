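#' Construct a spectrum from a peak table
#'
#' A spectrum is a tibble with two numeric columns, `mz` (mass-to-charge
#' ratio, Thomson) and `intensity` (peak height in instrument units or,
#' after standardization, dimensionless), sorted ascending by `mz`, plus a
#' free-text `label` and a `scale` tag (`"raw"` or `"standardized"`) kept
#' as attributes.  All user-facing functions in the package accept any data
#' frame with these two columns and coerce it through `as_spectrum()`.
#'
#' Validation enforces positive, finite `mz` and `intensity`.  Duplicate
#' `mz` values are merged by summing their intensities (with a warning):
#' duplicated centroids are instrument artifacts and summing preserves the
#' total ion signal.
#'
#' @param x A data frame with columns `mz` and `intensity` (or whose first
#'   two numeric columns are taken as such).
#' @param label Free-text identifier carried through the pipeline.
#' @param scale `"raw"` or `"standardized"`.
#' @param drop_invalid If `FALSE` (default) rows with non-positive or
#'   non-finite values are an error naming the offending rows; if `TRUE`
#'   they are dropped with a warning stating how many were rejected, so
#'   that `n_in = n_out + n_rejected` is always accounted for.
#' @return A `spectrum` tibble sorted ascending by `mz`.
#' @examples
#' s <- as_spectrum(data.frame(mz = c(200, 100, 150), intensity = c(2, 5, 9)))
#' s$mz
#' @export
as_spectrum <- function(x, label = NULL, scale = NULL, drop_invalid = FALSE) {
  stopifnot(is.data.frame(x))
  label <- label %||% attr(x, "label") %||% ""
  scale <- scale %||% attr(x, "scale") %||% "raw"
  scale <- match.arg(scale, c("raw", "standardized"))

  if (!all(c("mz", "intensity") %in% names(x))) {
    num <- which(vapply(x, is.numeric, logical(1)))
    if (length(num) < 2) {
      abort("need columns `mz` and `intensity` (or at least two numeric columns)",
            class = "kneescale_ingest_error")
    }
    x <- setNames(x[num[1:2]], c("mz", "intensity"))
  }
  mz <- as.numeric(x$mz)
  intensity <- as.numeric(x$intensity)

  bad <- !is.finite(mz) | !is.finite(intensity) | mz <= 0 | intensity <= 0
  if (any(bad)) {
    rows <- which(bad)
    if (drop_invalid) {
      warn(sprintf("rejected %d peak(s) with non-positive or non-numeric mz/intensity (rows %s)",
                   length(rows), paste(head(rows, 10), collapse = ", ")))
      mz <- mz[!bad]; intensity <- intensity[!bad]
    } else {
      abort(sprintf("non-positive or non-numeric mz/intensity at row(s) %s",
                    paste(head(rows, 10), collapse = ", ")),
            class = "kneescale_ingest_error")
    }
  }
  if (length(mz) == 0) {
    abort("spectrum has no valid peaks", class = "kneescale_ingest_error")
  }

  ord <- order(mz)
  mz <- mz[ord]; intensity <- intensity[ord]
  if (anyDuplicated(mz)) {
    n_dup <- sum(duplicated(mz))
    agg <- rowsum(intensity, group = mz, reorder = TRUE)
    mz_u <- as.numeric(rownames(agg))
    warn(sprintf("merged %d duplicate m/z value(s) by summing intensities", n_dup))
    mz <- mz_u; intensity <- as.numeric(agg)
  }

  new_spectrum(tibble::tibble(mz = mz, intensity = intensity), label, scale)
}

new_spectrum <- function(df, label = "", scale = "raw") {
  tibble::new_tibble(df, label = label, scale = scale,
                     class = "spectrum", nrow = nrow(df))
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("# A spectrum: %d peaks, m/z %.4g-%.4g, scale: %s%s\n",
              nrow(x), min(x$mz), max(x$mz), spectrum_scale(x),
              if (nzchar(spectrum_label(x))) paste0(", label: ", spectrum_label(x)) else ""))
  print(tibble::as_tibble(x), ...)
  invisible(x)
}

#' Spectrum metadata accessors
#'
#' @param x A spectrum (or any data frame carrying the attributes).
#' @return `spectrum_label()` the label string; `spectrum_scale()` `"raw"`
#'   or `"standardized"` (defaulting to `"raw"` when untagged).
#' @export
spectrum_label <- function(x) attr(x, "label") %||% ""

#' @rdname spectrum_label
#' @export
spectrum_scale <- function(x) attr(x, "scale") %||% "raw"

#' Multiply all intensities of a spectrum by a constant
#'
#' Convenience for constructing rescaled copies in validation experiments.
#'
#' @param spectrum A spectrum or peak data frame.
#' @param factor Positive multiplier.
#' @return A spectrum with every intensity multiplied by `factor`.
#' @export
scale_intensities <- function(spectrum, factor) {
  stopifnot(is.numeric(factor), length(factor) == 1, factor > 0)
  s <- as_spectrum(spectrum)
  new_spectrum(tibble::tibble(mz = s$mz, intensity = s$intensity * factor),
               spectrum_label(s), spectrum_scale(s))
}
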