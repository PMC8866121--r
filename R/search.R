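# Core open mass-shift search: precursor selection, peak extraction,
# branched theoretical ion ladders, binomial-tail scoring, Bonferroni
# family-wise error control, and shift aggregation/annotation.

#' Select candidate conjugate spectra by precursor mass
#'
#' Keeps exactly those MS2 spectra whose precursor neutral mass is at
#' least the mass of the unconjugated Dap peptide, MS(Pept(Dap)), within
#' a small ppm slack so the unmodified (shift zero) population is not
#' lost to calibration error. Everything lighter cannot be a conjugate of
#' this peptide and is removed. Spectra without a recorded charge are
#' retained if any charge in `charge_range` would place them above the
#' bound; scoring later resolves the charge by enumeration.
#'
#' @param spectra List of [ms_spectrum()] objects.
#' @param pept The [branched_peptide()] defining MS(Pept(Dap)).
#' @param slack_ppm Allowed relative shortfall below MS(Pept(Dap)) in
#'   parts per million (default 10).
#' @param charge_range Charges assumed for spectra lacking one.
#' @return The retained subset, in input order.
#' @export
select_conjugate_spectra <- function(spectra, pept, slack_ppm = 10,
                                     charge_range = 1:3) {
  stopifnot(inherits(pept, "branched_peptide"), slack_ppm >= 0)
  bound <- peptide_mass(pept, "mono") * (1 - slack_ppm * 1e-6)
  keep <- vapply(spectra, function(s) {
    if (s$ms_level != 2L || is.na(s$precursor_mz)) return(FALSE)
    zs <- if (!is.na(s$precursor_charge)) s$precursor_charge else charge_range
    any(precursor_neutral_mass(s$precursor_mz, zs) >= bound)
  }, logical(1))
  spectra[keep]
}

#' Retain the most intense peaks per m/z window
#'
#' Within each half-open window `[i*window, (i+1)*window)` thomson, keeps
#' the `q` most intense peaks (all of them when fewer are present). Ties
#' in intensity are broken in favour of the lower m/z. Peak ordering by
#' m/z is preserved, and the operation is idempotent.
#'
#' @param s A centroided [ms_spectrum()].
#' @param q Peaks kept per window (default 10).
#' @param window Window width in thomson (default 100).
#' @return The filtered `ms_spectrum`.
#' @export
top_peaks_per_window <- function(s, q = 10L, window = 100) {
  stopifnot(inherits(s, "ms_spectrum"))
  if (q <= 0 || window <= 0) stop("q and window must be positive")
  if (!s$is_centroided) stop("top_peaks_per_window needs a centroided spectrum")
  if (nrow(s$peaks) == 0L) return(s)
  win <- floor(s$peaks$mz / window)
  keep <- unlist(lapply(split(seq_len(nrow(s$peaks)), win), function(ix) {
    if (length(ix) <= q) return(ix)
    # decreasing intensity, ties to lower mz (ix is mz-ordered)
    ix[order(-s$peaks$intensity[ix], ix)[seq_len(q)]]
  }), use.names = FALSE)
  s$peaks <- s$peaks[sort(keep), , drop = FALSE]
  rownames(s$peaks) <- NULL
  s
}

#' Conjugate mass from a precursor
#'
#' The mass of the captured entity X is the difference between the
#' observed precursor neutral mass and MS(Pept(Dap)). Values can be
#' slightly negative within the selection slack; they are reported
#' unclamped here and clamped at zero only for annotation.
#'
#' @param s An [ms_spectrum()] that passed [select_conjugate_spectra()].
#' @param pept The [branched_peptide()].
#' @param charge Charge state to use for the neutral-mass conversion.
#' @return The conjugate mass mx in daltons.
#' @export
compute_mx <- function(s, pept, charge) {
  stopifnot(inherits(s, "ms_spectrum"), inherits(pept, "branched_peptide"))
  if (is.na(s$precursor_mz)) stop("spectrum has no precursor m/z")
  precursor_neutral_mass(s$precursor_mz, charge) - peptide_mass(pept, "mono")
}

#' Theoretical fragment ions of a branched conjugate peptide
#'
#' Generates the b/y ion ladder of Pept(Dap-X): for peptide length L with
#' Dap at position d, b_j carries the conjugate mass `mx` iff `j >= d` and
#' y_j iff `j >= L - d + 1` (the fragment contains the branch point). The
#' conjugate is treated as an intact side-chain modification; the
#' backbone alone fragments. Each b/y ion is emitted at every charge in
#' `charges`, plus a water-loss variant when the fragment contains
#' S/T/E/D and an ammonia-loss variant when it contains R/K/N/Q (at most
#' one loss per ion). Ions whose m/z coincide within `dedup_tol` are
#' merged to a single entry (mean m/z) so the list size `n` never
#' double-counts coincident masses.
#'
#' @param pept The [branched_peptide()].
#' @param mx Conjugate mass in daltons (>= 0; 0 gives the plain ladder).
#' @param charges Fragment charges to emit (default 1 and 2).
#' @param losses Neutral losses to consider, subset of
#'   `c("water", "ammonia")`.
#' @param dedup_tol Merge radius in daltons for coincident theoretical
#'   masses; half the fragment match tolerance is the natural choice.
#' @return Data frame with columns `series`, `index`, `charge`, `loss`,
#'   `contains_dap`, `shifted`, `mz`, sorted by `mz`.
#' @examples
#' pept <- branched_peptide("GJG", 2)
#' theoretical_fragments(pept, mx = 147.0684, charges = 1, losses = NULL)
#' @export
theoretical_fragments <- function(pept, mx = 0, charges = c(1L, 2L),
                                  losses = c("water", "ammonia"),
                                  dedup_tol = 0.25) {
  stopifnot(inherits(pept, "branched_peptide"), mx >= 0)
  res <- pept$residues
  L <- length(res)
  if (L < 2L) stop("peptide too short to fragment (length < 2)")
  charges <- sort(unique(as.integer(charges)))
  stopifnot(all(charges >= 1L))
  losses <- if (is.null(losses)) character() else
    match.arg(losses, c("water", "ammonia"), several.ok = TRUE)
  rm_ <- residue_mass(res, "mono")
  modv <- .position_mod_deltas(pept)
  proton <- mass_proton()
  d <- pept$dap_index
  water_aa <- c("S", "T", "E", "D")
  ammonia_aa <- c("R", "K", "N", "Q")

  # per-fragment quantities for j = 1..L-1, both series
  j <- seq_len(L - 1L)
  pre <- cumsum(rm_ + modv)                     # prefix masses
  b_neutral <- pre[j]
  y_neutral <- pre[L] - pre[L - j] + mass_water("mono")
  b_dap <- j >= d
  y_dap <- j >= L - d + 1L
  can_water <- cumsum(res %in% water_aa)        # prefix counts
  can_ammonia <- cumsum(res %in% ammonia_aa)
  b_water <- can_water[j] > 0
  y_water <- (can_water[L] - can_water[L - j]) > 0
  b_ammonia <- can_ammonia[j] > 0
  y_ammonia <- (can_ammonia[L] - can_ammonia[L - j]) > 0

  base <- data.frame(
    series = rep(c("b", "y"), each = L - 1L),
    index = c(j, j),
    contains_dap = c(b_dap, y_dap),
    neutral = c(b_neutral + b_dap * mx, y_neutral + y_dap * mx),
    water_ok = c(b_water, y_water) & "water" %in% losses,
    ammonia_ok = c(b_ammonia, y_ammonia) & "ammonia" %in% losses,
    stringsAsFactors = FALSE
  )
  with_loss <- function(rows, loss, loss_mass) {
    if (nrow(rows) == 0L) return(NULL)
    cbind(rows, loss = loss, loss_mass = loss_mass)
  }
  loss_rows <- do.call(rbind, list(
    with_loss(base, "none", 0),
    with_loss(base[base$water_ok, ], "water", mass_water("mono")),
    with_loss(base[base$ammonia_ok, ], "ammonia", mass_ammonia())
  ))
  nz <- length(charges)
  nr <- nrow(loss_rows)
  idx <- rep(seq_len(nr), times = nz)
  zz <- rep(charges, each = nr)
  ions <- data.frame(
    series = loss_rows$series[idx],
    index = loss_rows$index[idx],
    charge = zz,
    loss = loss_rows$loss[idx],
    contains_dap = loss_rows$contains_dap[idx],
    shifted = loss_rows$contains_dap[idx] & mx != 0,
    mz = (loss_rows$neutral[idx] - loss_rows$loss_mass[idx] + zz * proton) / zz,
    stringsAsFactors = FALSE
  )
  # deterministic order: by mz, primary ions (no loss, low charge) first
  ions <- ions[order(ions$mz, ions$loss != "none", ions$charge,
                     ions$series, ions$index), , drop = FALSE]
  if (dedup_tol > 0 && nrow(ions) > 1L) {
    grp <- cumsum(c(TRUE, diff(ions$mz) > dedup_tol))
    first <- !duplicated(grp)
    gm <- tapply(ions$mz, grp, mean)
    ions <- ions[first, , drop = FALSE]
    ions$mz <- as.numeric(gm)
  }
  rownames(ions) <- NULL
  ions
}

#' Match observed peaks against a theoretical ion list
#'
#' Counts theoretical masses having at least one observed peak within
#' `tol` (closed interval). Each theoretical mass counts at most once no
#' matter how many peaks fall inside its window.
#'
#' @param s A centroided, window-filtered [ms_spectrum()].
#' @param ions Data frame from [theoretical_fragments()].
#' @param tol Fragment match tolerance in thomson (default 0.5, ion-trap
#'   MS2).
#' @return List with elements `k` (matched count) and `n` (list size).
#' @export
match_fragments <- function(s, ions, tol = 0.5) {
  stopifnot(inherits(s, "ms_spectrum"))
  if (tol <= 0) stop("tol must be positive")
  n <- nrow(ions)
  pk <- s$peaks$mz
  if (n == 0L || length(pk) == 0L) return(list(k = 0L, n = n))
  k <- sum(vapply(ions$mz, function(m) any(abs(pk - m) <= tol), logical(1)))
  list(k = as.integer(k), n = n)
}

#' Binomial-tail peptide-spectrum match score
#'
#' The probability that at least `k` of `n` theoretical masses are matched
#' by chance when each has independent chance `p_single`, i.e. the upper
#' binomial tail, computed in log space; the score is ten times its
#' negative decadic logarithm. `k = 0` gives tail probability 1 and score
#' 0.
#'
#' @param k Number of matched theoretical masses.
#' @param n Size of the theoretical list.
#' @param p_single Chance that a single theoretical mass is matched by a
#'   random retained peak; with `q` peaks kept per `window` thomson and
#'   match tolerance `tol`, the natural value is `q * 2 * tol / window`.
#' @return List with elements `p_tail` and `score`.
#' @examples
#' binomial_tail_score(20, 20, 0.1)   # p_tail 1e-20, score 200
#' @export
binomial_tail_score <- function(k, n, p_single) {
  stopifnot(length(k) == 1L, length(n) == 1L, length(p_single) == 1L)
  if (is.na(k) || is.na(n) || k < 0 || n < 0 || k > n)
    stop("need 0 <= k <= n")
  if (is.na(p_single) || p_single <= 0 || p_single >= 1)
    stop("p_single must lie strictly between 0 and 1")
  log_p <- stats::pbinom(k - 1, n, p_single, lower.tail = FALSE, log.p = TRUE)
  list(p_tail = exp(log_p), score = -10 * log_p / log(10))
}

#' Default single-mass chance-match probability
#'
#' @param q,window Peak retention parameters of
#'   [top_peaks_per_window()].
#' @param tol Fragment match tolerance in thomson.
#' @return `q * 2 * tol / window`, clamped to (0, 0.5].
#' @export
default_p_single <- function(q = 10, window = 100, tol = 0.5) {
  min(0.5, q * 2 * tol / window)
}

#' Bonferroni family-wise error filter
#'
#' Controls the family-wise error rate over all scored spectra at level
#' `alpha` by the Bonferroni correction: a spectrum passes iff its tail
#' probability is at most `alpha / N`, with `N` the number of spectra
#' actually scored.
#'
#' @param results Data frame of per-spectrum results with a `p_tail`
#'   column (as produced by [run_trap_search()]).
#' @param alpha Family-wise error rate, in (0, 1).
#' @param n_tests Number of tests `N`; defaults to `nrow(results)`.
#' @return The passing subset with `passes_fwer = TRUE`; the per-test
#'   threshold is attached as attribute `"threshold"`.
#' @export
bonferroni_filter <- function(results, alpha = 0.05, n_tests = nrow(results)) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (nrow(results) == 0L) stop("no scored results to filter")
  thr <- alpha / n_tests
  out <- results[results$p_tail <= thr, , drop = FALSE]
  if (nrow(out)) out$passes_fwer <- TRUE
  rownames(out) <- NULL
  attr(out, "threshold") <- thr
  out
}

#' Aggregate accepted mass shifts into clusters
#'
#' Single-linkage grouping of the mx values of passing spectra: values
#' whose sorted neighbours lie within `bin_width` join the same cluster.
#' Slightly negative mx (within the selection slack) is clamped to zero
#' before grouping, since annotation works on non-negative shifts.
#'
#' @param passing Data frame of passing results with columns `mx` and
#'   `score`.
#' @param bin_width Linkage distance in daltons (default 0.02).
#' @return Data frame with one row per cluster: `mx_centroid` (mean of
#'   member mx), `support` (spectra in the cluster), `best_score`;
#'   sorted by support, then score, descending.
#' @export
aggregate_shifts <- function(passing, bin_width = 0.02) {
  stopifnot(bin_width > 0)
  if (is.null(passing) || nrow(passing) == 0L)
    return(data.frame(mx_centroid = numeric(), support = integer(),
                      best_score = numeric()))
  mx <- pmax(passing$mx, 0)
  ord <- order(mx)
  grp <- cumsum(c(TRUE, diff(mx[ord]) > bin_width))
  out <- data.frame(
    mx_centroid = as.numeric(tapply(mx[ord], grp, mean)),
    support = as.integer(tapply(mx[ord], grp, length)),
    best_score = as.numeric(tapply(passing$score[ord], grp, max))
  )
  out <- out[order(-out$support, -out$best_score, out$mx_centroid), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Annotate mass shifts against the adduct dictionary
#'
#' Assigns each shift centroid the dictionary entry with the nearest
#' monoisotopic delta, provided it lies within `tol`; otherwise
#' `"unassigned"`. Leu and Ile are isobaric and carried as one joint
#' entry.
#'
#' @param mx_centroid Numeric vector of shift centroids in daltons.
#' @param table Adduct dictionary, see [adduct_table()].
#' @param tol Maximum absolute assignment error in daltons (default
#'   0.02).
#' @return Data frame with columns `mx_centroid`, `candidate`,
#'   `delta_da` (signed error, observed minus candidate), `delta_ppm`.
#' @examples
#' annotate_shift(c(147.068, 77.015, 58.005))
#' @export
annotate_shift <- function(mx_centroid, table = adduct_table(), tol = 0.02) {
  stopifnot(is.numeric(mx_centroid), tol > 0)
  res <- lapply(mx_centroid, function(mx) {
    err <- mx - table$delta_mono
    i <- which.min(abs(err))
    if (length(i) && abs(err[i]) <= tol)
      data.frame(mx_centroid = mx, candidate = table$name[i],
                 delta_da = err[i], delta_ppm = 1e6 * err[i] / table$delta_mono[i],
                 stringsAsFactors = FALSE)
    else
      data.frame(mx_centroid = mx, candidate = "unassigned",
                 delta_da = NA_real_, delta_ppm = NA_real_,
                 stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
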