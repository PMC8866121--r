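# Orchestration of the full open mass-shift search: read -> centroid ->
# precursor selection -> peak extraction -> mx -> branched ladder ->
# match -> binomial-tail score -> Bonferroni -> aggregate -> annotate.

#' Run the open mass-shift trap search
#'
#' Executes the whole pipeline on a set of MS2 spectra and returns a
#' report of per-spectrum matches and aggregated, annotated mass shifts.
#' For spectra without a recorded precursor charge, every charge in
#' `charge_range` is scored and the best-scoring hypothesis kept (ties to
#' the lower charge).
#'
#' @param input Spectra as a list of [ms_spectrum()] objects, or one or
#'   more file paths readable by [read_spectra()].
#' @param pept The trap [branched_peptide()].
#' @param format Input file format, `"auto"`, `"mzml"` or `"mgf"`.
#' @param fragment_tol Fragment match tolerance in thomson (default 0.5;
#'   0.8 is a common alternative preset for trap data searched loosely).
#' @param q,window Peak retention: `q` most intense peaks per `window`
#'   thomson (defaults 10 per 100).
#' @param alpha Family-wise error rate for [bonferroni_filter()].
#' @param slack_ppm Precursor selection slack, see
#'   [select_conjugate_spectra()].
#' @param charge_range Charges enumerated when a spectrum lacks one.
#' @param p_single Per-mass chance-match probability; default
#'   [default_p_single()] of `q`, `window` and `fragment_tol`.
#' @param losses Neutral losses generated in the theoretical ladder.
#' @param bin_width Shift aggregation linkage distance in daltons.
#' @param annotation_tol Maximum assignment error in daltons.
#' @param adducts Adduct dictionary for annotation.
#' @param verbose Emit stage-count messages.
#' @return A `trap_report`: list with `results` (all scored spectra),
#'   `passing` (the Bonferroni survivors), `summary` (annotated shift
#'   clusters), `counts` (stage counts) and `params`.
#' @examples
#' \donttest{
#' cfg <- simulation_config(shifts = c("Dap+Phe" = 5L), n_decoys = 20L)
#' ds <- simulate_dataset(cfg)
#' rep <- run_trap_search(ds$spectra, cfg$pept, verbose = FALSE)
#' rep$summary
#' }
#' @export
run_trap_search <- function(input, pept,
                            format = c("auto", "mzml", "mgf"),
                            fragment_tol = 0.5, q = 10L, window = 100,
                            alpha = 0.05, slack_ppm = 10,
                            charge_range = 1:3,
                            p_single = NULL,
                            losses = c("water", "ammonia"),
                            bin_width = 0.02, annotation_tol = 0.02,
                            adducts = adduct_table(),
                            verbose = TRUE) {
  format <- match.arg(format)
  stopifnot(inherits(pept, "branched_peptide"))
  if (is.null(p_single)) p_single <- default_p_single(q, window, fragment_tol)
  say <- function(...) if (verbose) message(...)

  if (is.character(input)) {
    spectra <- unlist(lapply(input, read_spectra, format = format),
                      recursive = FALSE)
  } else {
    spectra <- input
  }
  stopifnot(all(vapply(spectra, inherits, logical(1), "ms_spectrum")))
  n_read <- length(spectra)

  spectra <- lapply(spectra, centroid_spectrum)
  ms2 <- Filter(function(s) s$ms_level == 2L, spectra)
  selected <- select_conjugate_spectra(ms2, pept, slack_ppm = slack_ppm,
                                       charge_range = charge_range)
  say("trap search: ", n_read, " spectra read, ", length(ms2), " MS2, ",
      length(selected), " above MS(Pept(Dap))")

  ms_pept <- peptide_mass(pept, "mono")
  slack_da <- ms_pept * slack_ppm * 1e-6
  rows <- lapply(selected, function(s) {
    filt <- top_peaks_per_window(s, q = q, window = window)
    zs <- if (!is.na(s$precursor_charge)) s$precursor_charge else charge_range
    best <- NULL
    for (z in zs) {
      mx <- compute_mx(s, pept, z)
      if (mx < -slack_da) next
      ions <- theoretical_fragments(pept, mx = max(mx, 0),
                                    charges = c(1L, 2L), losses = losses,
                                    dedup_tol = fragment_tol / 2)
      m <- match_fragments(filt, ions, tol = fragment_tol)
      sc <- binomial_tail_score(m$k, m$n, p_single)
      if (is.null(best) || sc$score > best$score)
        best <- data.frame(scan_id = s$scan_id, charge = z, mx = mx,
                           n = m$n, k = m$k, p_single = p_single,
                           p_tail = sc$p_tail, score = sc$score,
                           passes_fwer = FALSE, stringsAsFactors = FALSE)
    }
    best
  })
  results <- do.call(rbind, rows)
  if (is.null(results))
    results <- data.frame(scan_id = character(), charge = integer(),
                          mx = numeric(), n = integer(), k = integer(),
                          p_single = numeric(), p_tail = numeric(),
                          score = numeric(), passes_fwer = logical(),
                          stringsAsFactors = FALSE)
  rownames(results) <- NULL

  if (nrow(results)) {
    passing <- bonferroni_filter(results, alpha = alpha)
    results$passes_fwer <- results$scan_id %in% passing$scan_id
  } else {
    warning("no spectra were scored; report is empty")
    passing <- results
  }
  summary <- aggregate_shifts(passing, bin_width = bin_width)
  if (nrow(summary)) {
    ann <- annotate_shift(summary$mx_centroid, table = adducts,
                          tol = annotation_tol)
    summary <- cbind(summary,
                     ann[, c("candidate", "delta_da", "delta_ppm")])
  } else {
    summary$candidate <- character()
    summary$delta_da <- numeric()
    summary$delta_ppm <- numeric()
  }
  say("trap search: ", nrow(results), " spectra scored, ", nrow(passing),
      " pass FWER ", alpha, ", ", nrow(summary), " shift cluster(s)")

  structure(
    list(results = results, passing = passing, summary = summary,
         counts = c(read = n_read, ms2 = length(ms2),
                    selected = length(selected), scored = nrow(results),
                    passing = nrow(passing)),
         params = list(peptide = pept$sequence, dap_index = pept$dap_index,
                       fragment_tol = fragment_tol, q = q, window = window,
                       alpha = alpha, slack_ppm = slack_ppm,
                       charge_range = charge_range, p_single = p_single,
                       losses = losses, bin_width = bin_width,
                       annotation_tol = annotation_tol)),
    class = "trap_report"
  )
}

#' @export
print.trap_report <- function(x, ...) {
  cat("<trap_report>\n")
  cat("  stages: ", paste(names(x$counts), x$counts, sep = "=",
                          collapse = "  "), "\n", sep = "")
  if (nrow(x$summary)) {
    cat("  shift clusters:\n")
    print(x$summary, digits = 6)
  } else {
    cat("  no shift clusters passed the family-wise error filter\n")
  }
  invisible(x)
}

#' Write a trap-search report to delimited files
#'
#' Writes `spectrum_results.tsv` (one row per scored spectrum),
#' `shift_summary.tsv` (annotated clusters) and `run_metadata.txt`
#' (parameters and stage counts). Output is deterministic: identical
#' inputs and parameters give byte-identical files.
#'
#' @param report A `trap_report` from [run_trap_search()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "trap_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fmt <- function(df) {
    num <- vapply(df, is.double, logical(1))
    df[num] <- lapply(df[num], function(x) sprintf("%.6g", x))
    df
  }
  utils::write.table(fmt(report$results),
                     file.path(dir, "spectrum_results.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(fmt(report$summary),
                     file.path(dir, "shift_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  p <- report$params
  meta <- c(
    vapply(names(p), function(k)
      paste0(k, " = ", paste(p[[k]], collapse = ",")), character(1)),
    vapply(names(report$counts), function(k)
      paste0("count_", k, " = ", report$counts[[k]]), character(1))
  )
  writeLines(meta, file.path(dir, "run_metadata.txt"))
  invisible(dir)
}

#' Plot recovered mass shifts
#'
#' Score versus shift for every spectrum passing the family-wise error
#' filter, with cluster annotations; the plot mirrors how recovered
#' shifts are usually inspected.
#'
#' @param report A `trap_report`.
#' @param ... Passed to [plot()].
#' @return Invisibly, the passing results.
#' @export
plot_shifts <- function(report, ...) {
  stopifnot(inherits(report, "trap_report"))
  p <- report$passing
  if (!nrow(p)) {
    warning("nothing to plot: no passing spectra")
    return(invisible(p))
  }
  plot(pmax(p$mx, 0), p$score, xlab = "mass shift mx (Da)",
       ylab = "score", pch = 16, col = "#00000080", ...)
  s <- report$summary
  lab <- ifelse(s$candidate == "unassigned",
                sprintf("%+.0f", s$mx_centroid),
                sprintf("%+.0f (%s)", s$mx_centroid, s$candidate))
  graphics::text(s$mx_centroid, s$best_score, lab, pos = 3, cex = 0.7)
  invisible(p)
}
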