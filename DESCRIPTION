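Package: trapshift
Title: Open Mass-Shift Search for Branched Enzyme-Substrate Conjugate
    Peptides
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies the unknown entity conjugated to the side chain of
    a 2,3-diaminopropionic acid (Dap) residue in a known tryptic peptide
    from tandem mass spectra. Substrate-trap hydrolases carry Dap in place
    of their catalytic nucleophile and capture substrate fragments as
    stable amide conjugates; the branched peptides that result show b/y
    fragment ions shifted by the conjugate mass at and beyond the branch
    point. The package reads mzML and MGF spectra, filters precursors
    against the unconjugated peptide mass, builds branched theoretical ion
    ladders with water/ammonia neutral losses, scores peptide-spectrum
    matches with a binomial-tail score, controls the family-wise error
    rate by Bonferroni correction, aggregates and annotates the recovered
    mass shifts against a residue/adduct dictionary, and supplies a
    simulator of ion-trap style MS2 spectra with planted conjugates for
    validation. Intact-protein conjugate masses are computed from average
    residue masses for orthogonal confirmation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    mzR,
    stats,
    utils
Suggests:
    optparse,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
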