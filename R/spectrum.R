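#' Construct a mass spectrum
#'
#' The uniform in-memory representation flowing through the pipeline: one
#' scan with its peak list and precursor metadata. Peaks are stored sorted
#' by m/z; for centroided spectra, exact m/z ties are merged by summing
#' intensities so the ordering is strictly ascending.
#'
#' @param scan_id Unique text identifier of the scan.
#' @param ms_level Integer MS level (1 or 2).
#' @param peaks Data frame with numeric columns `mz` (thomson, > 0) and
#'   `intensity` (>= 0).
#' @param precursor_mz Precursor m/z in thomson (`NA` for MS1).
#' @param precursor_charge Positive integer charge or `NA` when the file
#'   does not record one.
#' @param retention_time Retention time in seconds, optional.
#' @param is_centroided Logical; `FALSE` marks profile-mode data.
#' @return An object of class `ms_spectrum`.
#' @examples
#' ms_spectrum("scan=1", 2, data.frame(mz = c(100, 200), intensity = c(1, 2)),
#'             precursor_mz = 500.25, precursor_charge = 2)
#' @export
ms_spectrum <- function(scan_id, ms_level = 2L,
                        peaks = data.frame(mz = numeric(),
                                           intensity = numeric()),
                        precursor_mz = NA_real_,
                        precursor_charge = NA_integer_,
                        retention_time = NA_real_,
                        is_centroided = TRUE) {
  stopifnot(is.character(scan_id), length(scan_id) == 1L)
  ms_level <- as.integer(ms_level)
  stopifnot(ms_level %in% c(1L, 2L))
  stopifnot(is.data.frame(peaks), all(c("mz", "intensity") %in% names(peaks)))
  peaks <- data.frame(mz = as.numeric(peaks$mz),
                      intensity = as.numeric(peaks$intensity))
  if (nrow(peaks)) {
    if (any(!is.finite(peaks$mz)) || any(peaks$mz <= 0))
      stop("spectrum '", scan_id, "': peak m/z must be positive and finite")
    if (any(!is.finite(peaks$intensity)) || any(peaks$intensity < 0))
      stop("spectrum '", scan_id, "': peak intensity must be non-negative")
    peaks <- peaks[order(peaks$mz), , drop = FALSE]
    if (is_centroided && anyDuplicated(peaks$mz)) {
      agg <- tapply(peaks$intensity, factor(peaks$mz, levels = unique(peaks$mz)),
                    sum)
      peaks <- data.frame(mz = unique(peaks$mz), intensity = as.numeric(agg))
    }
    rownames(peaks) <- NULL
  }
  if (!is.na(precursor_charge)) {
    precursor_charge <- as.integer(precursor_charge)
    if (precursor_charge < 1L)
      stop("spectrum '", scan_id, "': precursor charge must be positive")
  } else {
    precursor_charge <- NA_integer_
  }
  structure(
    list(scan_id = scan_id, ms_level = ms_level,
         precursor_mz = as.numeric(precursor_mz),
         precursor_charge = precursor_charge,
         retention_time = as.numeric(retention_time),
         peaks = peaks, is_centroided = isTRUE(is_centroided)),
    class = "ms_spectrum"
  )
}

#' @export
print.ms_spectrum <- function(x, ...) {
  cat("<ms_spectrum> ", x$scan_id, "  MS", x$ms_level,
      if (x$is_centroided) "  centroided" else "  profile",
      "  ", nrow(x$peaks), " peaks\n", sep = "")
  if (x$ms_level == 2L)
    cat(sprintf("  precursor m/z %.4f  charge %s\n",
                x$precursor_mz,
                if (is.na(x$precursor_charge)) "?" else x$precursor_charge))
  invisible(x)
}

#' Total ion current of a spectrum
#'
#' @param s An [ms_spectrum()].
#' @return Sum of peak intensities.
#' @export
total_ion_current <- function(s) {
  stopifnot(inherits(s, "ms_spectrum"))
  sum(s$peaks$intensity)
}

#' Centroid a profile-mode spectrum
#'
#' Replaces each contiguous profile bump (a local intensity maximum with
#' monotone flanks, delimited by local minima) with a single peak at the
#' intensity-weighted mean m/z carrying the summed intensity. Total ion
#' current is conserved. Spectra already flagged centroided are returned
#' unchanged, making the operation idempotent.
#'
#' @param s An [ms_spectrum()].
#' @return A centroided `ms_spectrum`.
#' @examples
#' prof <- ms_spectrum("s1", 2,
#'   data.frame(mz = c(500.00, 500.01, 500.02), intensity = c(1, 4, 1)),
#'   precursor_mz = 600, is_centroided = FALSE)
#' centroid_spectrum(prof)$peaks   # one peak at 500.01
#' @export
centroid_spectrum <- function(s) {
  stopifnot(inherits(s, "ms_spectrum"))
  if (s$is_centroided) return(s)
  mz <- s$peaks$mz
  int <- s$peaks$intensity
  n <- length(mz)
  if (n == 0L) {
    s$is_centroided <- TRUE
    return(s)
  }
  # split into bumps: a new bump starts when intensity rises again after
  # a fall; the valley point stays with the earlier bump
  grp <- integer(n)
  grp[1] <- 1L
  falling <- FALSE
  for (i in seq_len(n)[-1]) {
    if (int[i] > int[i - 1L] && falling) {
      grp[i] <- grp[i - 1L] + 1L
      falling <- FALSE
    } else {
      grp[i] <- grp[i - 1L]
      if (int[i] < int[i - 1L]) falling <- TRUE
    }
  }
  cmz <- vapply(split(seq_len(n), grp), function(ix) {
    w <- int[ix]
    if (sum(w) > 0) sum(mz[ix] * w) / sum(w) else mean(mz[ix])
  }, numeric(1))
  cint <- vapply(split(int, grp), sum, numeric(1))
  ms_spectrum(s$scan_id, s$ms_level,
              data.frame(mz = unname(cmz), intensity = unname(cint)),
              precursor_mz = s$precursor_mz,
              precursor_charge = s$precursor_charge,
              retention_time = s$retention_time,
              is_centroided = TRUE)
}
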