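# Synthetic ion-trap style MS2 data with known ground truth: branched
# conjugate spectra with a planted side-chain mass shift at Dap, plus
# pure-noise decoys. The defaults are the validation conditions used
# throughout the package: five hydrophobic amino-acid conjugates at 20
# spectra each, fragment coverage 0.8, m/z jitter 0.1 Th, 100 uniform
# noise peaks per spectrum over the 100-2,000 Th scan range, and 500
# decoys.

#' Example Dap-containing tryptic peptide
#'
#' A synthetic tryptic peptide with Dap (`"J"`) at position 4, used as the
#' default trap peptide in simulations and examples. It contains water-
#' and ammonia-loss eligible residues so all ion classes are exercised.
#'
#' @return A [branched_peptide()].
#' @export
example_branched_peptide <- function() {
  branched_peptide("LSGJAFDNEK", 4L)
}

#' Simulation configuration
#'
#' @param pept The trap [branched_peptide()].
#' @param shifts Named integer vector: planted shifts and their spectrum
#'   counts. Names are adduct-dictionary entries (see [adduct_table()])
#'   or literal masses in daltons (e.g. `"147.0684"`).
#' @param coverage Fraction of theoretical fragment ions emitted per
#'   spectrum, in \[0, 1\].
#' @param mz_jitter_sd Gaussian m/z error of emitted fragment peaks
#'   (thomson).
#' @param intensity_meanlog,intensity_sdlog Log-normal peak intensity
#'   parameters.
#' @param noise_peaks Uniform random noise peaks per spectrum.
#' @param mz_range Instrument scan range in thomson.
#' @param charge_probs Named probabilities of precursor charge states.
#' @param n_decoys Pure-noise decoy MS2 spectra in a dataset.
#' @param decoy_below_frac Fraction of decoys with precursor below
#'   MS(Pept(Dap)) (removed by selection); the rest sit at random masses
#'   above it and exercise the scoring null.
#' @param seed Master random seed; per-spectrum seeds derive from it.
#' @return A `sim_config` list.
#' @export
simulation_config <- function(pept = example_branched_peptide(),
                              shifts = c("Dap+Leu/Ile" = 20L, "Dap+Met" = 20L,
                                         "Dap+Phe" = 20L, "Dap+Tyr" = 20L,
                                         "Dap+Trp" = 20L),
                              coverage = 0.8,
                              mz_jitter_sd = 0.1,
                              intensity_meanlog = log(5000),
                              intensity_sdlog = 0.6,
                              noise_peaks = 100L,
                              mz_range = c(100, 2000),
                              charge_probs = c("2" = 0.7, "3" = 0.3),
                              n_decoys = 500L,
                              decoy_below_frac = 0.5,
                              seed = 1L) {
  stopifnot(inherits(pept, "branched_peptide"),
            coverage >= 0, coverage <= 1,
            mz_jitter_sd >= 0, noise_peaks >= 0,
            length(mz_range) == 2L, mz_range[1] < mz_range[2],
            n_decoys >= 0, decoy_below_frac >= 0, decoy_below_frac <= 1,
            all(shifts >= 0))
  stopifnot(!is.null(names(charge_probs)), all(charge_probs > 0))
  charge_probs <- charge_probs / sum(charge_probs)
  structure(
    list(pept = pept, shifts = shifts, coverage = coverage,
         mz_jitter_sd = mz_jitter_sd,
         intensity_meanlog = intensity_meanlog,
         intensity_sdlog = intensity_sdlog,
         noise_peaks = as.integer(noise_peaks), mz_range = mz_range,
         charge_probs = charge_probs, n_decoys = as.integer(n_decoys),
         decoy_below_frac = decoy_below_frac, seed = as.integer(seed)),
    class = "sim_config"
  )
}

# Stable per-spectrum seed from (master, ordinal); stays below 2^31.
.derive_seed <- function(master, ordinal) {
  as.integer(((as.numeric(master) %% 2147483647) * 48271 +
                as.numeric(ordinal) * 16807) %% 2147483647)
}

.resolve_shift <- function(shift_name, table = adduct_table()) {
  i <- match(shift_name, table$name)
  if (!is.na(i)) return(table$delta_mono[i])
  v <- suppressWarnings(as.numeric(shift_name))
  if (is.na(v)) stop("cannot resolve planted shift '", shift_name,
                     "': not an adduct name or a number")
  v
}

.sample_charge <- function(cfg) {
  as.integer(sample(names(cfg$charge_probs), 1L, prob = cfg$charge_probs))
}

#' Simulate one MS2 spectrum of a branched conjugate peptide
#'
#' The precursor is placed exactly at `(MS(Pept(Dap)) + shift + z *
#' m_proton) / z`; a random `coverage` fraction of the branched
#' theoretical fragment ions (charges 1-2, water/ammonia losses) is
#' emitted with Gaussian m/z jitter and log-normal intensities; uniform
#' noise peaks are added over the scan range. Fragments outside the scan
#' range are not recorded, as on a real instrument. Deterministic for a
#' given seed.
#'
#' @param cfg A [simulation_config()].
#' @param shift Planted conjugate mass in daltons (0 for the unmodified
#'   peptide).
#' @param seed Integer seed for this spectrum.
#' @param scan_id Scan identifier.
#' @param charge Precursor charge; drawn from `cfg$charge_probs` when
#'   `NULL`.
#' @return An [ms_spectrum()].
#' @export
simulate_conjugate_spectrum <- function(cfg, shift, seed,
                                        scan_id = "sim", charge = NULL) {
  stopifnot(inherits(cfg, "sim_config"), shift >= 0)
  set.seed(seed)
  z <- if (is.null(charge)) .sample_charge(cfg) else as.integer(charge)
  pmz <- (peptide_mass(cfg$pept, "mono") + shift + z * mass_proton()) / z
  ions <- theoretical_fragments(cfg$pept, mx = shift, charges = c(1L, 2L),
                                losses = c("water", "ammonia"))
  emit <- stats::runif(nrow(ions)) < cfg$coverage
  fmz <- ions$mz[emit] +
    stats::rnorm(sum(emit), 0, cfg$mz_jitter_sd)
  fint <- stats::rlnorm(sum(emit), cfg$intensity_meanlog, cfg$intensity_sdlog)
  inrange <- fmz >= cfg$mz_range[1] & fmz <= cfg$mz_range[2]
  nmz <- stats::runif(cfg$noise_peaks, cfg$mz_range[1], cfg$mz_range[2])
  nint <- stats::rlnorm(cfg$noise_peaks, cfg$intensity_meanlog,
                        cfg$intensity_sdlog)
  ms_spectrum(scan_id, 2L,
              data.frame(mz = c(fmz[inrange], nmz),
                         intensity = c(fint[inrange], nint)),
              precursor_mz = pmz, precursor_charge = z,
              is_centroided = TRUE)
}

# A decoy: noise-only MS2 spectrum at an arbitrary precursor neutral mass.
.simulate_noise_spectrum <- function(cfg, neutral_mass, seed, scan_id) {
  set.seed(seed)
  z <- .sample_charge(cfg)
  pmz <- (neutral_mass + z * mass_proton()) / z
  nmz <- stats::runif(cfg$noise_peaks, cfg$mz_range[1], cfg$mz_range[2])
  nint <- stats::rlnorm(cfg$noise_peaks, cfg$intensity_meanlog,
                        cfg$intensity_sdlog)
  ms_spectrum(scan_id, 2L, data.frame(mz = nmz, intensity = nint),
              precursor_mz = pmz, precursor_charge = z,
              is_centroided = TRUE)
}

#' Simulate a full MS2 dataset with ground truth
#'
#' Emits all planted-shift conjugate spectra plus pure-noise decoys:
#' `decoy_below_frac` of the decoys carry precursors below MS(Pept(Dap))
#' (and must be removed by precursor selection), the rest at random
#' neutral masses above it (and exercise the scoring null). Spectra are
#' shuffled deterministically and assigned sequential scan identifiers.
#'
#' @param cfg A [simulation_config()].
#' @return List with `spectra` (list of [ms_spectrum()]) and `truth`
#'   (data frame: `scan_id`, `kind`, `true_shift`, `charge`).
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  ms_pept <- peptide_mass(cfg$pept, "mono")
  shift_da <- vapply(names(cfg$shifts), .resolve_shift, numeric(1))
  plan <- data.frame(
    kind = rep("conjugate", sum(cfg$shifts)),
    shift_name = rep(names(cfg$shifts), cfg$shifts),
    true_shift = rep(shift_da, cfg$shifts),
    stringsAsFactors = FALSE
  )
  n_below <- round(cfg$n_decoys * cfg$decoy_below_frac)
  n_above <- cfg$n_decoys - n_below
  if (cfg$n_decoys > 0)
    plan <- rbind(plan,
                  data.frame(kind = c(rep("decoy_below", n_below),
                                      rep("decoy_above", n_above)),
                             shift_name = NA_character_,
                             true_shift = NA_real_,
                             stringsAsFactors = FALSE))
  n <- nrow(plan)
  # deterministic shuffle, then per-spectrum seeds by final ordinal
  set.seed(.derive_seed(cfg$seed, 0L))
  plan <- plan[sample(n), , drop = FALSE]
  decoy_mass <- stats::runif(n, ms_pept + 5, ms_pept + 350)
  decoy_mass_below <- stats::runif(n, ms_pept - 300, ms_pept - 20)
  spectra <- vector("list", n)
  ids <- sprintf("scan=%05d", seq_len(n))
  for (i in seq_len(n)) {
    sd_i <- .derive_seed(cfg$seed, i)
    spectra[[i]] <- switch(
      plan$kind[i],
      conjugate = simulate_conjugate_spectrum(cfg, plan$true_shift[i],
                                              seed = sd_i, scan_id = ids[i]),
      decoy_above = .simulate_noise_spectrum(cfg, decoy_mass[i], sd_i, ids[i]),
      decoy_below = .simulate_noise_spectrum(cfg, decoy_mass_below[i],
                                             sd_i, ids[i])
    )
  }
  truth <- data.frame(scan_id = ids, kind = plan$kind,
                      true_shift = plan$true_shift,
                      charge = vapply(spectra, `[[`, integer(1),
                                      "precursor_charge"),
                      stringsAsFactors = FALSE)
  rownames(truth) <- NULL
  list(spectra = spectra, truth = truth)
}
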