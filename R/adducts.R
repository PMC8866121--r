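# The shift dictionary used to put a chemical identity on an aggregated
# mass shift. Categories:
#   conjugated-residue      an amino acid condensed on the Dap side chain
#                           (delta = residue mass, i.e. AA minus water)
#   photocage               residual photocage on Dap (pc-Dap minus Dap)
#   photolysis-intermediate partially photolysed cage remaining on Dap
#   near-cognate-substitution a natural residue translated in place of
#                           Dap at the amber codon (delta = residue-mass
#                           difference; net composition can be negative
#                           in an element)
.adduct_env <- new.env(parent = emptyenv())

.aa3 <- c(G = "Gly", A = "Ala", S = "Ser", P = "Pro", V = "Val", T = "Thr",
          C = "Cys", N = "Asn", D = "Asp", Q = "Gln", K = "Lys", E = "Glu",
          M = "Met", H = "His", F = "Phe", R = "Arg", Y = "Tyr", W = "Trp")

.build_adduct_table <- function() {
  # Leu and Ile are isobaric and reported jointly.
  conj <- data.frame(
    name = c(paste0("Dap+", unname(.aa3)), "Dap+Leu/Ile"),
    composition = c(unname(.residue_compositions[names(.aa3)]),
                    unname(.residue_compositions["L"])),
    category = "conjugated-residue",
    stringsAsFactors = FALSE
  )
  extra <- data.frame(
    name = c("pc-Dap", "photolysis-intermediate",
             "Gln-for-Dap", "Tyr-for-Dap"),
    composition = c("C12H11NO6S", "C3H4O2S", "C2H2O", "C6H3N-1O"),
    category = c("photocage", "photolysis-intermediate",
                 "near-cognate-substitution", "near-cognate-substitution"),
    stringsAsFactors = FALSE
  )
  tab <- rbind(conj, extra)
  tab$delta_mono <- vapply(tab$composition, formula_mass, numeric(1), "mono")
  tab$delta_avg <- vapply(tab$composition, formula_mass, numeric(1), "avg")
  tab <- tab[order(tab$delta_mono), c("name", "composition",
                                      "delta_mono", "delta_avg", "category")]
  rownames(tab) <- NULL
  tab
}

#' Built-in mass-shift (adduct) dictionary
#'
#' Candidate identities for a mass shift observed at the Dap branch point:
#' each amino acid condensed on Dap (Leu/Ile merged as one isobaric
#' entry), the residual photocage (+297), the partially photolysed cage
#' intermediate (+104), and the Gln (+42) / Tyr (+77) near-cognate
#' amber-codon substitutions.
#'
#' @return Data frame with columns `name`, `composition`, `delta_mono`,
#'   `delta_avg`, `category`, sorted by monoisotopic delta.
#' @examples
#' subset(adduct_table(), name %in% c("Dap+Phe", "pc-Dap"))
#' @export
adduct_table <- function() {
  if (is.null(.adduct_env$table)) .adduct_env$table <- .build_adduct_table()
  .adduct_env$table
}

#' Read or write an adduct dictionary as delimited text
#'
#' Tab-separated with columns `name`, `composition`, `delta_mono`,
#' `delta_avg`, `category`, so users can extend the shift dictionary.
#' On read, any row with a composition has its deltas recomputed and
#' checked to 1e-3 Da; rows may omit the composition (`NA`) and give
#' deltas directly.
#'
#' @param path File path.
#' @param table Adduct data frame to write.
#' @return `read_adduct_table()` returns the adduct data frame;
#'   `write_adduct_table()` returns `path` invisibly.
#' @export
read_adduct_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "composition", "delta_mono", "delta_avg", "category")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("adduct table missing column(s): ", paste(miss, collapse = ", "))
  has_comp <- !is.na(tab$composition) & nzchar(tab$composition)
  for (i in which(has_comp)) {
    mono <- formula_mass(tab$composition[i], "mono")
    if (abs(mono - tab$delta_mono[i]) > 1e-3)
      stop("adduct '", tab$name[i],
           "': delta_mono inconsistent with composition")
  }
  tab[, need]
}

#' @rdname read_adduct_table
#' @export
write_adduct_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
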