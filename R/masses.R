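# Atomic masses hard-coded to keep every derived mass reproducible offline:
# monoisotopic from the IUPAC/AME tables, average from CODATA standard
# atomic weights.
.element_masses <- list(
  mono = c(C = 12.0, H = 1.0078250319, N = 14.0030740052,
           O = 15.9949146221, S = 31.97207069),
  avg  = c(C = 12.0107, H = 1.00794, N = 14.0067,
           O = 15.9994, S = 32.065)
)

# Residue (amino acid minus water) elemental compositions. "J" is the
# one-letter code this package assigns to Dap (2,3-diaminopropionic acid),
# the trap residue that replaces the catalytic Ser/Cys nucleophile.
.residue_compositions <- c(
  G = "C2H3NO",    A = "C3H5NO",    S = "C3H5NO2",  P = "C5H7NO",
  V = "C5H9NO",    T = "C4H7NO2",   C = "C3H5NOS",  L = "C6H11NO",
  I = "C6H11NO",   N = "C4H6N2O2",  D = "C4H5NO3",  Q = "C5H8N2O2",
  K = "C6H12N2O",  E = "C5H7NO3",   M = "C5H9NOS",  H = "C6H7N3O",
  F = "C9H9NO",    R = "C6H12N4O",  Y = "C9H9NO2",  W = "C11H10N2O",
  J = "C3H6N2O"
)

#' Parse a molecular formula into element counts
#'
#' Counts may be negative (e.g. `"C6H3N-1O"`), which is needed to express
#' net composition changes such as a residue-for-residue substitution.
#'
#' @param formula A single formula string over the elements C, H, N, O, S.
#' @return Named integer vector of element counts.
#' @examples
#' parse_formula("C3H6N2O")
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L, !is.na(formula))
  pat <- "([A-Z][a-z]?)(-?[0-9]*)"
  m <- regmatches(formula, gregexpr(pat, formula))[[1]]
  m <- m[nzchar(m)]
  if (!identical(paste(m, collapse = ""), formula))
    stop("cannot parse formula: ", formula)
  elem <- sub(pat, "\\1", m)
  cnt <- sub(pat, "\\2", m)
  cnt[cnt == ""] <- "1"
  counts <- as.integer(cnt)
  unknown <- setdiff(elem, names(.element_masses$mono))
  if (length(unknown))
    stop("unknown element(s) in formula: ", paste(unknown, collapse = ", "))
  tapply(counts, factor(elem, levels = unique(elem)), sum)
}

#' Mass of a molecular formula
#'
#' @param formula Formula string (see [parse_formula()]).
#' @param scale `"mono"` for monoisotopic or `"avg"` for average mass.
#' @return Mass in daltons.
#' @examples
#' formula_mass("H2O")            # 18.010565
#' formula_mass("C12H11NO6S")     # photocage net mass, ~297.03
#' @export
formula_mass <- function(formula, scale = c("mono", "avg")) {
  scale <- match.arg(scale)
  counts <- parse_formula(formula)
  sum(.element_masses[[scale]][names(counts)] * counts)
}

#' Mass constants
#'
#' `mass_water()` is both the peptide condensation water and the neutral
#' water loss; `mass_ammonia()` the neutral ammonia loss; `mass_proton()`
#' the charge carrier used in all m/z conversions.
#'
#' @param scale `"mono"` or `"avg"`.
#' @return Mass in daltons.
#' @export
mass_water <- function(scale = c("mono", "avg")) {
  formula_mass("H2O", match.arg(scale))
}

#' @rdname mass_water
#' @export
mass_proton <- function() 1.007276

#' @rdname mass_water
#' @export
mass_ammonia <- function() formula_mass("NH3", "mono")

# Residue table built once at load from the compositions above.
.residue_table_env <- new.env(parent = emptyenv())

#' Residue mass table
#'
#' The 20 canonical amino acids plus Dap (code `"J"`), with elemental
#' composition and both mass scales. Residue masses are amino-acid masses
#' minus water.
#'
#' @return A data frame with columns `code`, `composition`, `mono`, `avg`.
#' @examples
#' residue_table()
#' @export
residue_table <- function() {
  if (is.null(.residue_table_env$table)) {
    codes <- names(.residue_compositions)
    .residue_table_env$table <- data.frame(
      code = codes,
      composition = unname(.residue_compositions),
      mono = vapply(.residue_compositions, formula_mass, numeric(1),
                    scale = "mono"),
      avg = vapply(.residue_compositions, formula_mass, numeric(1),
                   scale = "avg"),
      row.names = codes,
      stringsAsFactors = FALSE
    )
  }
  .residue_table_env$table
}

#' Residue mass lookup
#'
#' @param code One-letter residue code(s); `"J"` denotes Dap.
#' @param scale `"mono"` or `"avg"`.
#' @return Residue mass(es) in daltons.
#' @examples
#' residue_mass("F")          # 147.0684, the +147 Phe conjugate shift
#' residue_mass("J")          # 86.0480, Dap
#' @export
residue_mass <- function(code, scale = c("mono", "avg")) {
  scale <- match.arg(scale)
  tab <- residue_table()
  bad <- setdiff(code, tab$code)
  if (length(bad))
    stop("unknown residue code(s): ", paste(bad, collapse = ", "))
  unname(tab[code, scale])
}

#' Neutral mass of a precursor ion
#'
#' Converts an observed precursor m/z and charge to the neutral
#' (uncharged) molecular mass, `(mz - m_proton) * z`.
#'
#' @param mz Precursor m/z in thomson.
#' @param z Positive integer charge state.
#' @return Neutral mass in daltons.
#' @examples
#' precursor_neutral_mass(500, 2)   # 997.9855
#' @export
precursor_neutral_mass <- function(mz, z) {
  if (any(is.na(z)) || any(z < 1) || any(z != as.integer(z)))
    stop("charge z must be a positive integer")
  if (any(is.na(mz)) || any(mz <= mass_proton()))
    stop("precursor m/z must exceed the proton mass")
  (mz - mass_proton()) * z
}

#' Expected mass of an intact conjugate
#'
#' Adds an adduct mass to a base molecular mass, e.g. a deconvolved
#' intact-protein mass of the Dap-containing trap enzyme plus a conjugated
#' residue. Average masses are the natural scale for deconvolved protein
#' spectra.
#'
#' @param base_mass Base neutral mass in daltons.
#' @param adduct Either a numeric mass delta in daltons or the name of an
#'   entry in `table`.
#' @param scale `"mono"` or `"avg"`; selects which delta of a named adduct
#'   is applied.
#' @param table Adduct dictionary, see [adduct_table()].
#' @return Conjugate mass in daltons.
#' @examples
#' # trap enzyme at 23,994 Da capturing one Phe -> 24,141 Da
#' round(expected_conjugate_mass(23994, "Dap+Phe", scale = "avg"))
#' @export
expected_conjugate_mass <- function(base_mass, adduct, scale = c("mono", "avg"),
                                    table = adduct_table()) {
  scale <- match.arg(scale)
  stopifnot(is.numeric(base_mass), all(base_mass > 0))
  if (is.numeric(adduct)) {
    delta <- adduct
  } else {
    idx <- match(adduct, table$name)
    if (any(is.na(idx)))
      stop("unknown adduct name(s): ",
           paste(adduct[is.na(idx)], collapse = ", "))
    delta <- if (scale == "mono") table$delta_mono[idx] else table$delta_avg[idx]
  }
  base_mass + delta
}
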