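#' Define a Dap-containing (branched) peptide
#'
#' Describes the unconjugated Dap-containing tryptic peptide of a
#' substrate-trap enzyme. Dap is written as `"J"` in the sequence; any
#' entity later found conjugated to its side chain makes the peptide
#' branched.
#'
#' @param sequence Peptide sequence as a single string of one-letter
#'   codes (Dap = `"J"`).
#' @param dap_index 1-based position of the Dap residue.
#' @param fixed_mods Optional data frame of fixed modifications with
#'   columns `site` (an integer position, `"nterm"` or `"cterm"`) and
#'   `delta` (mass in daltons). See [mod_carbamidomethyl()].
#' @return An object of class `branched_peptide`.
#' @examples
#' branched_peptide("GJG", 2)
#' @export
branched_peptide <- function(sequence, dap_index, fixed_mods = NULL) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nzchar(sequence))
  residues <- strsplit(sequence, "")[[1]]
  bad <- setdiff(residues, residue_table()$code)
  if (length(bad))
    stop("unknown residue code(s): ", paste(unique(bad), collapse = ", "))
  dap_index <- as.integer(dap_index)
  if (length(dap_index) != 1L || is.na(dap_index) ||
      dap_index < 1L || dap_index > length(residues))
    stop("dap_index must be a position within the sequence")
  if (residues[dap_index] != "J")
    stop("residue at dap_index must be Dap ('J'), found '",
         residues[dap_index], "'")
  if (is.null(fixed_mods)) {
    fixed_mods <- data.frame(site = character(), delta = numeric(),
                             stringsAsFactors = FALSE)
  } else {
    stopifnot(is.data.frame(fixed_mods),
              all(c("site", "delta") %in% names(fixed_mods)))
    fixed_mods$site <- as.character(fixed_mods$site)
    ok <- fixed_mods$site %in% c("nterm", "cterm") |
      !is.na(suppressWarnings(as.integer(fixed_mods$site)))
    if (!all(ok))
      stop("fixed_mods$site must be integer positions, 'nterm' or 'cterm'")
    pos <- suppressWarnings(as.integer(fixed_mods$site))
    if (any(!is.na(pos) & (pos < 1L | pos > length(residues))))
      stop("fixed modification position outside the peptide")
  }
  structure(
    list(sequence = sequence, residues = residues,
         dap_index = dap_index, fixed_mods = fixed_mods),
    class = "branched_peptide"
  )
}

#' @export
print.branched_peptide <- function(x, ...) {
  cat("<branched_peptide> ", x$sequence, "  (Dap at ", x$dap_index, ")\n",
      sep = "")
  cat("  MS(Pept(Dap)) mono: ", sprintf("%.4f", peptide_mass(x)), " Da\n",
      sep = "")
  if (nrow(x$fixed_mods))
    cat("  fixed mods: ",
        paste(sprintf("%s%+.4f", x$fixed_mods$site, x$fixed_mods$delta),
              collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Carbamidomethyl-cysteine fixed modification
#'
#' Convenience constructor for the +57.0215 Da alkylation applied to every
#' cysteine, for data acquired after iodoacetamide treatment. Off by
#' default in the search.
#'
#' @param pept A [branched_peptide()].
#' @return A `fixed_mods` data frame covering all Cys positions (zero rows
#'   when the peptide has none).
#' @export
mod_carbamidomethyl <- function(pept) {
  pos <- which(pept$residues == "C")
  data.frame(site = as.character(pos),
             delta = rep(formula_mass("C2H3NO", "mono"), length(pos)),
             stringsAsFactors = FALSE)
}

#' Neutral mass of a branched peptide
#'
#' Sum of residue masses plus one water plus all fixed-modification
#' deltas. This is MS(Pept(Dap)), the reference against which conjugate
#' precursors are compared.
#'
#' @param pept A [branched_peptide()].
#' @param scale `"mono"` or `"avg"`. Fixed-mod deltas are applied as given
#'   on either scale.
#' @return Neutral peptide mass in daltons.
#' @examples
#' peptide_mass(branched_peptide("GJG", 2))   # 218.1015
#' @export
peptide_mass <- function(pept, scale = c("mono", "avg")) {
  scale <- match.arg(scale)
  stopifnot(inherits(pept, "branched_peptide"))
  sum(residue_mass(pept$residues, scale)) + mass_water(scale) +
    sum(pept$fixed_mods$delta)
}

# Per-position fixed-mod deltas (terminus mods mapped to position 1 / L,
# which is where they travel in the b / y series respectively).
.position_mod_deltas <- function(pept) {
  L <- length(pept$residues)
  d <- numeric(L)
  if (nrow(pept$fixed_mods)) {
    for (i in seq_len(nrow(pept$fixed_mods))) {
      site <- pept$fixed_mods$site[i]
      pos <- if (site == "nterm") 1L
             else if (site == "cterm") L
             else as.integer(site)
      d[pos] <- d[pos] + pept$fixed_mods$delta[i]
    }
  }
  d
}
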