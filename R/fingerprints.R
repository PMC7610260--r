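#' Fixed m/z grid for fingerprint extraction
#'
#' A uniform partition of the mass range into `n_bins` half-open intervals
#' `[lo, hi)`; the last bin is closed so the upper mass limit is retained.
#' The default grid (100--1000 Da, 881 bins) is the one used throughout the
#' package: every serum metabolic fingerprint (SMF) is a vector of summed
#' peak intensities on this grid.
#'
#' @param mz_min,mz_max mass range in Da.
#' @param n_bins number of bins.
#' @return An object of class `mz_grid` with elements `mz_min`, `mz_max`,
#'   `n_bins`, `width` and `centers` (bin mid-points in Da).
#' @examples
#' g <- mz_grid()
#' g$width          # 900/881 ~ 1.0215 Da
#' head(g$centers)
#' @export
mz_grid <- function(mz_min = 100, mz_max = 1000, n_bins = 881) {
  if (!is.numeric(mz_min) || !is.numeric(mz_max) || mz_min >= mz_max) {
    stop_config("mz_min/mz_max", "must satisfy mz_min < mz_max")
  }
  n_bins <- check_count(n_bins, "n_bins")
  width <- (mz_max - mz_min) / n_bins
  structure(
    list(
      mz_min = mz_min, mz_max = mz_max, n_bins = n_bins, width = width,
      centers = mz_min + (seq_len(n_bins) - 0.5) * width
    ),
    class = "mz_grid"
  )
}

#' Read a peak-list mass spectrum
#'
#' Supported dialects: `"two_column_text"` (whitespace- or tab-separated
#' m/z and intensity per line; blank lines and `#` comments skipped) and
#' `"mzml"` (centroided mzML, read through the mzR package). Peaks are
#' returned sorted by m/z; duplicate m/z entries are merged by intensity sum.
#'
#' @param path path to the spectrum file.
#' @param dialect `"two_column_text"` or `"mzml"`.
#' @param sample_id identifier attached to the spectrum; defaults to the
#'   file name without extension.
#' @return A `spectrum` object: list with `mz`, `intensity`, `sample_id`.
#' @export
load_spectrum <- function(path, dialect = c("two_column_text", "mzml"),
                          sample_id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("spectrum file not found: ", path, call. = FALSE)
  if (is.null(sample_id)) sample_id <- sub("\\.[^.]*$", "", basename(path))
  if (dialect == "two_column_text") {
    lines <- readLines(path, warn = FALSE)
    keep <- which(nzchar(trimws(lines)) & !grepl("^\\s*#", lines))
    mz <- numeric(length(keep))
    inten <- numeric(length(keep))
    for (k in seq_along(keep)) {
      ln <- keep[k]
      parts <- strsplit(trimws(lines[ln]), "[\t ]+")[[1]]
      vals <- suppressWarnings(as.numeric(parts))
      if (length(vals) < 2L || anyNA(vals[1:2])) {
        stop(sprintf("parse error in %s at line %d: expected two numeric columns",
                     path, ln), call. = FALSE)
      }
      if (vals[2] < 0) {
        stop(sprintf("parse error in %s at line %d: negative intensity", path, ln),
             call. = FALSE)
      }
      mz[k] <- vals[1]
      inten[k] <- vals[2]
    }
  } else {
    if (!requireNamespace("mzR", quietly = TRUE)) {
      stop("dialect 'mzml' requires the mzR package", call. = FALSE)
    }
    fh <- mzR::openMSfile(path)
    on.exit(mzR::close(fh), add = TRUE)
    pk <- mzR::peaks(fh, 1L)
    mz <- pk[, 1]
    inten <- pk[, 2]
    if (any(inten < 0)) stop("parse error: negative intensity in ", path, call. = FALSE)
  }
  new_spectrum(mz, inten, sample_id)
}

#' Construct a spectrum from vectors
#'
#' @param mz,intensity numeric vectors of equal length; intensities must be
#'   nonnegative. Duplicate m/z values are merged by intensity sum and peaks
#'   sorted ascending by m/z.
#' @param sample_id identifier.
#' @return A `spectrum` object.
#' @export
new_spectrum <- function(mz, intensity, sample_id = "sample") {
  stopifnot(length(mz) == length(intensity))
  if (any(intensity < 0)) stop("intensities must be nonnegative", call. = FALSE)
  if (length(mz)) {
    agg <- rowsum(intensity, group = mz) # merges duplicates, sorts keys
    mz <- as.numeric(rownames(agg))
    intensity <- as.numeric(agg[, 1])
  }
  structure(list(mz = mz, intensity = intensity, sample_id = sample_id),
            class = "spectrum")
}

#' Bin a spectrum onto a fixed m/z grid
#'
#' Each peak's intensity is added to the bin containing its m/z; peaks
#' outside the grid range are dropped and tallied. Binning conserves total
#' ion current: `sum(intensities) + dropped_intensity` equals the spectrum's
#' total intensity.
#'
#' @param spectrum a `spectrum` object.
#' @param grid an [mz_grid()].
#' @return List with `intensities` (length `n_bins`), `n_dropped` and
#'   `dropped_intensity`.
#' @export
bin_spectrum <- function(spectrum, grid) {
  stopifnot(inherits(spectrum, "spectrum"), inherits(grid, "mz_grid"))
  v <- numeric(grid$n_bins)
  mz <- spectrum$mz
  inten <- spectrum$intensity
  inside <- mz >= grid$mz_min & mz <= grid$mz_max
  idx <- floor((mz[inside] - grid$mz_min) / grid$width) + 1
  idx[idx > grid$n_bins] <- grid$n_bins # mz == mz_max: last bin is closed
  if (length(idx)) {
    agg <- rowsum(inten[inside], group = idx)
    v[as.integer(rownames(agg))] <- agg[, 1]
  }
  list(
    intensities = v,
    n_dropped = sum(!inside),
    dropped_intensity = sum(inten[!inside])
  )
}

#' Bin several spectra into a fingerprint matrix
#'
#' @param spectra list of `spectrum` objects.
#' @param grid an [mz_grid()].
#' @param normalize apply [tic_normalize()] per sample.
#' @return A numeric matrix (samples x bins) with bin centers as column
#'   names and sample ids as row names.
#' @export
bin_spectra <- function(spectra, grid, normalize = FALSE) {
  rows <- lapply(spectra, function(s) bin_spectrum(s, grid)$intensities)
  m <- rbind_list(rows)
  rownames(m) <- vapply(spectra, function(s) s$sample_id, character(1))
  colnames(m) <- format(grid$centers, trim = TRUE)
  if (anyDuplicated(rownames(m))) stop("sample ids must be unique", call. = FALSE)
  if (normalize) m <- tic_normalize(m)
  m
}

#' Total-ion-current normalization
#'
#' Divides each fingerprint by its total intensity so it sums to one,
#' removing per-sample ion-current scale. Idempotent; errors on an all-zero
#' fingerprint (an empty or failed acquisition).
#'
#' @param x nonnegative numeric vector, or matrix with samples in rows.
#' @return Object of the same shape with unit row sums.
#' @export
tic_normalize <- function(x) {
  if (is.matrix(x)) {
    tot <- rowSums(x)
    if (any(tot <= 0)) {
      stop("cannot TIC-normalize: sample(s) with zero total intensity: ",
           paste(which(tot <= 0), collapse = ", "), call. = FALSE)
    }
    return(x / tot)
  }
  if (any(x < 0)) stop("intensities must be nonnegative", call. = FALSE)
  tot <- sum(x)
  if (tot <= 0) stop("cannot TIC-normalize an all-zero fingerprint", call. = FALSE)
  x / tot
}

#' Cosine similarity between two fingerprints
#'
#' Inner product divided by the product of norms; scale-invariant and
#' symmetric, in `[0, 1]` for nonnegative fingerprints. Used as the
#' spectra-reproducibility score.
#'
#' @param a,b numeric vectors of equal length with positive norm.
#' @return Similarity score.
#' @export
cosine_similarity <- function(a, b) {
  if (length(a) != length(b)) stop("fingerprints differ in length", call. = FALSE)
  na <- sqrt(sum(a^2))
  nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) {
    stop("cosine similarity undefined for a zero-norm fingerprint", call. = FALSE)
  }
  sum(a * b) / (na * nb)
}

#' Write / read a fingerprint matrix as tab-separated text
#'
#' The header row holds bin-center m/z values; the first column holds
#' sample ids.
#'
#' @param x fingerprint matrix (samples x bins) with dimnames.
#' @param path file path.
#' @return `read_fingerprints` returns the matrix; `write_fingerprints`
#'   returns `path` invisibly.
#' @export
write_fingerprints <- function(x, path) {
  df <- data.frame(sample_id = rownames(x), x, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fingerprints
#' @export
read_fingerprints <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}
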