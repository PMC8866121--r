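---
title: "Finding what a Dap substrate trap caught: the trapshift method"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finding what a Dap substrate trap caught: the trapshift method}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trapshift)
```

## The problem

Serine and cysteine hydrolases attack their substrates through a covalent
acyl-enzyme intermediate. When the catalytic nucleophile is replaced by
2,3-diaminopropionic acid (Dap), that intermediate is arrested as a stable
amide: the enzyme ends up carrying a fragment of its substrate — an amino
acid, a peptide, an acyl group, call it X — on the Dap side chain. After
tryptic digestion, the Dap-containing peptide of the enzyme appears in two
forms: unconjugated, `Pept(Dap)`, and branched, `Pept(Dap-X)`.

The question trapshift answers is: *what is the mass of X?* Nothing else
about X is assumed. This makes the search "open": instead of matching
spectra against a database of known modifications, every MS2 spectrum
whose precursor is at least as heavy as `Pept(Dap)` is a candidate, and
its implied shift

$$ m_x = M_{\text{precursor}} - \text{MS(Pept(Dap))} $$

is tested against the spectrum's fragment ions.

## The branched fragment model

A conjugate attached through the Dap side chain does not change how the
peptide backbone fragments; it only adds mass to the fragments that
contain the branch point. For a peptide of length $L$ with Dap at position
$d$:

* $b_j$ ions carry $+m_x$ exactly when $j \ge d$;
* $y_j$ ions carry $+m_x$ exactly when $j \ge L - d + 1$.

`theoretical_fragments()` builds this ladder with singly and doubly
protonated b/y ions, plus water-loss variants for fragments containing
S/T/E/D and ammonia-loss variants for fragments containing R/K/N/Q (at
most one loss per ion). X itself is treated as unfragmentable: cleavage
is modelled along the Pept(Dap) backbone only. Theoretical masses that
coincide within half the fragment tolerance are merged before counting,
so a shift of zero does not double-count the overlapping shifted and
unshifted ladders and inflate the score.

## Scoring and error control

Observed peaks are reduced to the ten most intense per 100 Th window
(`top_peaks_per_window()`), the standard ion-trap noise filter. A peak
matches a theoretical mass within ±0.5 Da (closed interval). With $k$ of
$n$ theoretical masses matched, the score is

$$ S = -10 \log_{10} \Pr(\text{Bin}(n, p) \ge k), $$

the upper binomial tail computed in log space (`binomial_tail_score()`),
so a fully matched 20-ion list at $p = 0.1$ scores exactly 200 rather
than underflowing. The per-mass chance probability $p$ is the
probability that a uniformly placed retained peak lands in a ±tol
window: with $q$ peaks per window $w$, $p = 2 q \cdot tol / w = 0.1$ at
the defaults. This is a deliberately simple null — retained peaks are
not uniform in real spectra — but it is *conservative* on sparse noise
(100 noise peaks spread over 1,900 Th give an empirical per-mass match
chance near 0.05), which is the direction that protects the error rate.
$p$ is configurable for instruments where the default is a poor model.

Spectra are accepted when their tail probability clears the Bonferroni
bound $\alpha / N$, where $N$ counts the spectra actually scored (not
the raw file size) and $\alpha = 0.05$ controls the family-wise error
rate. Accepted shifts are clustered by single linkage at 0.02 Da
(`aggregate_shifts()`) and each cluster centroid annotated against a
dictionary of candidate identities (`annotate_shift()`): the twenty
amino acids condensed on Dap (Leu/Ile merged, isobaric), the residual
photocage (+297.03, composition C12H11NO6S), a partially photolysed
cage intermediate (+103.99, C3H4O2S, validated against intact-mass
pair differences), and the Gln (+42.01) and Tyr (+77.02) near-cognate
substitutions at the amber codon.

## Parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| `fragment_tol` | 0.5 | Th | ion-trap MS2 accuracy; 0.8 is a common looser preset |
| `q`, `window` | 10, 100 | peaks, Th | noise filter; also defines `p_single` |
| `p_single` | 0.1 | — | `2·q·tol/window`, clamped to (0, 0.5] |
| `alpha` | 0.05 | — | family-wise error rate (Bonferroni) |
| `slack_ppm` | 10 | ppm | keeps the $m_x = 0$ population despite calibration error |
| `charge_range` | 1–3 | — | charges enumerated when a scan lacks one; best score wins, ties to lower charge |
| `bin_width` | 0.02 | Da | shift clustering radius |
| `annotation_tol` | 0.02 | Da | maximum assignment error |

Charges 1–2 are generated for fragments unconditionally; losses follow
the side-chain rules above. The "ammonium loss" wording seen for trap
instruments is implemented as ammonia (−17.0265 Da); the alternative is
a one-line change of the loss set. Carbamidomethyl-cysteine (+57.0215)
is available as a fixed modification but off by default, since the
trap search is typically run on DTT-only preparations.

Mass scales: peptide-level work is monoisotopic throughout; intact
deconvolved protein masses use average residue masses
(`expected_conjugate_mass(..., scale = "avg")`), which is what a
quadrupole deconvolution reports. Element masses are hard-coded to six
decimals so nothing depends on external tables.

## What the simulator emulates — and what it does not

`simulate_dataset()` produces ion-trap-style centroided MS2 spectra:
the precursor placed exactly at the planted conjugate mass, a random
`coverage` fraction of the branched ladder with Gaussian m/z jitter and
log-normal intensities, uniform noise peaks over the 100–2,000 Th scan
range, and noise-only decoys with precursors below (removed by
selection) or above (scored as a null) the peptide mass. The default
configuration is the package's reference condition: five hydrophobic
amino-acid conjugates (Leu/Ile, Met, Phe, Tyr, Trp) at 20 spectra each,
coverage 0.8, jitter 0.1 Th, 100 noise peaks, 500 decoys, charge 2:3
drawn 0.7:0.3 — sizes chosen so the whole validation runs in seconds on
one core while each estimate still rests on hundreds of spectra.

Not emulated: isotope envelopes, correlated (chemical) noise, precursor
m/z error, co-isolation of mixed precursors, retention-time structure,
and intensity patterns that depend on bond chemistry. Scoring uses peak
*presence* within tolerance only, so the missing intensity realism does
not touch the statistic; but passing tests on simulated data show the
pipeline's bookkeeping and error control are right, not that real trap
spectra of a particular enzyme will score as cleanly.

Determinism: one master seed; per-spectrum seeds derive from it by a
fixed integer hash of the scan ordinal, so datasets reproduce exactly
and independently of how many spectra are generated.

## Numerical choices and degenerate inputs

* Tail probabilities and scores live in log space; `k = 0` gives
  `p_tail = 1`, score 0, by construction.
* Windows are half-open `[i·w, (i+1)·w)`; match intervals are closed at
  the boundary; intensity ties in the window filter keep the lower m/z.
* `mx` may be slightly negative within the ppm slack; it is reported
  unclamped per spectrum and clamped at zero for clustering and
  annotation.
* Exact m/z ties in centroided peak lists merge by intensity summation,
  preserving strict ordering and total ion current.
* Profile centroiding splits at intensity valleys and places each bump
  at its intensity-weighted mean m/z; a spectrum is treated as profile
  only when the source file flags it so — peak spacing is never
  guessed. Any reasonable local-maximum centroider is equivalent here
  because the search consumes centroided data.
* Empty inputs (no spectra after filtering) produce an empty report
  under a warning, not an error.
* Zero-length fragment lists cannot occur (peptides shorter than two
  residues are rejected before fragmentation).

## Design decisions that were genuinely open

* **The chance-match probability.** No closed definition is forced by
  the method; we chose the uniform-peak model above, documented it, and
  exposed it. The validation checks (conservative family-wise error on
  pure noise) hold under this choice.
* **Charge handling.** Files often omit precursor charge on trap
  instruments. Enumerating 1–3 and keeping the best-scoring hypothesis
  recovers the true charge in simulation; recording the charge when the
  file has one avoids a 3× cost.
* **Bonferroni over FDR.** The search asks "is there *any* conjugate
  population here", so family-wise control over the scored spectra is
  the right guarantee; target-decoy FDR is out of scope by design.
* **Merged Leu/Ile.** The two residues are exactly isobaric; reporting
  them jointly is the only honest annotation at any tolerance.

## Limitations

* One known trap peptide per run: this is not a database search, and it
  will not find conjugates on peptides other than the one given.
* X is opaque: if the captured entity itself fragments in the trap, its
  internal ions are unmodelled and can only lower the score.
* The annotation dictionary is finite; shifts without a nearby entry
  are reported `unassigned` with their centroid, which is the honest
  output for a truly unknown conjugate.
* Average-mass arithmetic for intact proteins takes the deconvolved
  base mass as input; the package does not recompute whole-construct
  masses from sequence (tags and acetylation state live in the input).

## A worked run

```{r example}
cfg <- simulation_config(shifts = c("Dap+Phe" = 8L, "Dap+Trp" = 8L),
                         n_decoys = 100L, seed = 11L)
ds <- simulate_dataset(cfg)
report <- run_trap_search(ds$spectra, cfg$pept, verbose = FALSE)
report$summary
```

The summary lists one cluster per planted conjugate, its support (number
of passing spectra), best score, and the assigned identity with its
signed error. `write_report()` writes the per-spectrum table, the
summary, and run metadata as deterministic delimited text;
`plot_shifts()` draws score against shift with cluster labels.
```{r plot, fig.width = 6, fig.height = 4}
plot_shifts(report)
```
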