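# Core open mass-shift search operations.

pept <- example_branched_peptide()
ms_pept <- peptide_mass(pept)

spec_at <- function(neutral, z = 2L, id = "s", peaks = data.frame(
  mz = 500, intensity = 1)) {
  ms_spectrum(id, 2L, peaks, precursor_mz = (neutral + z * mass_proton()) / z,
              precursor_charge = z)
}

test_that("precursor selection keeps conjugates and the mx = 0 peptide", {
  eq <- spec_at(ms_pept)                  # exactly MS(Pept(Dap)): mx = 0
  below <- spec_at(ms_pept - 50)          # 50 Da light: impossible conjugate
  slightly <- spec_at(ms_pept * (1 - 3e-6))  # 3 ppm low: calibration slack
  above <- spec_at(ms_pept + 147.0684)
  kept <- select_conjugate_spectra(list(eq, below, slightly, above), pept,
                                   slack_ppm = 10)
  expect_length(kept, 3L)
  expect_false(any(vapply(kept, function(s)
    isTRUE(all.equal(s$precursor_mz, below$precursor_mz)), logical(1))))
  # a chargeless spectrum is kept if any enumerated charge clears the bound
  nc <- ms_spectrum("nc", 2, data.frame(mz = 500, intensity = 1),
                    precursor_mz = (ms_pept + 2 * mass_proton()) / 2)
  expect_length(select_conjugate_spectra(list(nc), pept), 1L)
  # MS1 and precursor-free MS2 never pass
  expect_length(select_conjugate_spectra(list(ms_spectrum("m1", 1)), pept), 0L)
})

test_that("windowed peak extraction keeps the q most intense per 100 Th", {
  set.seed(3)
  mz <- sort(runif(25, 200, 299.99))
  s <- ms_spectrum("w", 2, data.frame(mz = mz, intensity = sample(1:25)),
                   precursor_mz = 600)
  f <- top_peaks_per_window(s, q = 10, window = 100)
  expect_identical(nrow(f$peaks), 10L)
  expect_setequal(f$peaks$intensity, 16:25)
  expect_identical(f$peaks$mz, sort(f$peaks$mz))   # mz order preserved
  # idempotent
  expect_identical(top_peaks_per_window(f, 10, 100)$peaks, f$peaks)
  # under-filled windows keep everything
  s3 <- ms_spectrum("u", 2, data.frame(mz = c(110, 150, 190),
                                       intensity = c(1, 2, 3)),
                    precursor_mz = 600)
  expect_identical(nrow(top_peaks_per_window(s3)$peaks), 3L)
  expect_error(top_peaks_per_window(s, q = 0), "positive")
  expect_error(top_peaks_per_window(s, window = -1), "positive")
})

test_that("window boundaries are half-open and ties break to lower m/z", {
  # peak at exactly 300 counts in [300, 400), so [200, 300) is not full
  s <- ms_spectrum("b", 2,
                   data.frame(mz = c(seq(200.5, 299.5, length.out = 10), 300.0),
                              intensity = c(rep(5, 10), 1)),
                   precursor_mz = 600)
  f <- top_peaks_per_window(s, q = 10, window = 100)
  expect_identical(nrow(f$peaks), 11L)
  # equal intensities: the q lowest-m/z peaks of the window survive
  s2 <- ms_spectrum("t", 2,
                    data.frame(mz = 200 + 1:12, intensity = rep(7, 12)),
                    precursor_mz = 600)
  f2 <- top_peaks_per_window(s2, q = 10, window = 100)
  expect_identical(f2$peaks$mz, 200 + 1:10)
})

test_that("mx is the precursor neutral mass minus MS(Pept(Dap))", {
  expect_equal(compute_mx(spec_at(ms_pept), pept, 2), 0, tolerance = 1e-9)
  expect_equal(compute_mx(spec_at(ms_pept + 147.0684, 3), pept, 3),
               147.0684, tolerance = 1e-9)
  expect_equal(compute_mx(spec_at(ms_pept + 297.031), pept, 2), 297.031,
               tolerance = 1e-9)
})

test_that("branched ladders shift exactly the branch-containing fragments", {
  p <- branched_peptide("GJG", 2)
  ions <- theoretical_fragments(p, mx = 147.0684, charges = 1, losses = NULL)
  got <- setNames(ions$mz, paste0(ions$series, ions$index))
  want <- c(b1 = 58.0288, b2 = 291.1453, y1 = 76.0393, y2 = 309.1559)
  expect_equal(got[names(want)], want, tolerance = 2e-6)
  # L = 5, Dap at 3, no loss-eligible residues: 16 ions at 2 charges
  p5 <- branched_peptide("GAJVG", 3)
  i5 <- theoretical_fragments(p5, mx = 100, charges = c(1, 2),
                              losses = NULL, dedup_tol = 0)
  expect_identical(nrow(i5), 16L)
  expect_identical(sum(i5$shifted), 8L)   # b3, b4, y3, y4 at both charges
  expect_true(all(i5$shifted == i5$contains_dap))
  # positional rule: b_j shifts iff j >= d, y_j iff j >= L - d + 1
  expect_setequal(i5$index[i5$series == "b" & i5$shifted], 3:4)
  expect_setequal(i5$index[i5$series == "y" & i5$shifted], 3:4)
  expect_error(theoretical_fragments(branched_peptide("J", 1), 0),
               "too short")
})

test_that("shifted implies contains_dap across random peptides", {
  set.seed(5)
  aa <- setdiff(residue_table()$code, "J")
  for (i in 1:15) {
    L <- sample(4:12, 1)
    d <- sample(seq_len(L), 1)
    res <- sample(aa, L, replace = TRUE)
    res[d] <- "J"
    p <- branched_peptide(paste(res, collapse = ""), d)
    ions <- theoretical_fragments(p, mx = runif(1, 50, 300), dedup_tol = 0)
    expect_true(all(!ions$shifted | ions$contains_dap))
    expect_true(all(ions$mz > 0))
    # water/ammonia-loss ions only for eligible fragments
    wl <- ions[ions$loss == "water" & ions$series == "b", ]
    if (nrow(wl))
      expect_true(all(vapply(wl$index, function(jj)
        any(res[seq_len(jj)] %in% c("S", "T", "E", "D")), logical(1))))
  }
})

test_that("a zero shift collapses to the plain peptide ladder", {
  plain <- theoretical_fragments(pept, mx = 0)
  expect_false(any(plain$shifted))
  # coincident masses are merged so n is not inflated
  expect_identical(anyDuplicated(round(plain$mz / 0.25)), 0L)
})

test_that("fragment matching counts each theoretical mass at most once", {
  ions <- data.frame(mz = c(200, 300, 400))
  empty <- ms_spectrum("e", 2, precursor_mz = 500)
  expect_identical(match_fragments(empty, ions)$k, 0L)
  # saturation: every theoretical mass present exactly
  sat <- ms_spectrum("s", 2, data.frame(mz = c(200, 300, 400),
                                        intensity = c(1, 1, 1)),
                     precursor_mz = 500)
  expect_identical(match_fragments(sat, ions)$k, 3L)
  # two peaks inside one window still count once
  dbl <- ms_spectrum("d", 2, data.frame(mz = c(200.1, 200.2),
                                        intensity = c(1, 1)),
                     precursor_mz = 500)
  expect_identical(match_fragments(dbl, ions, tol = 0.5)$k, 1L)
  # closed interval at the boundary
  at_tol <- ms_spectrum("t", 2, data.frame(mz = 200.5, intensity = 1),
                        precursor_mz = 500)
  expect_identical(match_fragments(at_tol, ions, tol = 0.5)$k, 1L)
  past <- ms_spectrum("p", 2, data.frame(mz = 200.5005, intensity = 1),
                      precursor_mz = 500)
  expect_identical(match_fragments(past, ions, tol = 0.5)$k, 0L)
  expect_error(match_fragments(sat, ions, tol = 0), "positive")
})

test_that("binomial tail score matches exhaustive enumeration", {
  for (n in c(1L, 4L, 8L)) {
    for (p in c(0.1, 0.3)) {
      for (k in 0:n) {
        got <- binomial_tail_score(k, n, p)
        want <- enum_tail_prob(k, n, p)
        expect_equal(got$p_tail, want, tolerance = 1e-9)
        expect_equal(got$score, -10 * log10(want), tolerance = 1e-9)
      }
    }
  }
  # k = 2, n = 4, p = 0.1 hand value from the enumeration oracle
  expect_equal(binomial_tail_score(2, 4, 0.1)$p_tail, 0.0523,
               tolerance = 1e-3)
  expect_identical(binomial_tail_score(0, 10, 0.1)$score, 0)
  expect_equal(binomial_tail_score(20, 20, 0.1)$score, 200,
               tolerance = 1e-9)
  expect_error(binomial_tail_score(5, 4, 0.1), "k <= n")
  expect_error(binomial_tail_score(1, 4, 0), "p_single")
})

test_that("score rises with k and falls with p", {
  sc <- vapply(0:12, function(k) binomial_tail_score(k, 12, 0.1)$score,
               numeric(1))
  expect_true(all(diff(sc) > 0))
  sp <- vapply(c(0.05, 0.1, 0.2, 0.4), function(p)
    binomial_tail_score(6, 12, p)$score, numeric(1))
  expect_true(all(diff(sp) < 0))
})

test_that("Bonferroni filtering divides alpha by the scored count", {
  res <- data.frame(scan_id = sprintf("s%04d", 1:1000),
                    mx = 0, score = 0,
                    p_tail = c(4e-5, 6e-5, rep(0.5, 998)))
  out <- bonferroni_filter(res, alpha = 0.05)
  expect_equal(attr(out, "threshold"), 5e-5)
  expect_identical(out$scan_id, "s0001")       # only 4e-5 <= 5e-5
  expect_true(all(out$passes_fwer))
  one <- bonferroni_filter(res[1, ], alpha = 0.05)
  expect_equal(attr(one, "threshold"), 0.05)
  dull <- res; dull$p_tail <- 1
  expect_identical(nrow(bonferroni_filter(dull)), 0L)
  expect_error(bonferroni_filter(res, alpha = 2), "alpha")
})

test_that("shift aggregation single-links within the bin width", {
  passing <- data.frame(mx = c(147.06, 147.07, 147.07), score = c(50, 60, 55))
  agg <- aggregate_shifts(passing, bin_width = 0.02)
  expect_identical(nrow(agg), 1L)
  expect_equal(agg$mx_centroid, mean(passing$mx), tolerance = 1e-9)
  expect_identical(agg$support, 3L)
  expect_identical(agg$best_score, 60)
  two <- aggregate_shifts(data.frame(mx = c(147.07, 163.06),
                                     score = c(50, 70)), 0.02)
  expect_identical(nrow(two), 2L)
  expect_identical(nrow(aggregate_shifts(data.frame(mx = numeric(),
                                                    score = numeric()))), 0L)
})

test_that("shift annotation assigns the nearest adduct within tolerance", {
  ann <- annotate_shift(c(147.068, 77.015, 186.079, 58.005), tol = 0.02)
  expect_identical(ann$candidate,
                   c("Dap+Phe", "Tyr-for-Dap", "Dap+Trp", "unassigned"))
  expect_true(all(abs(ann$delta_da[1:3]) <= 0.02))
  expect_true(is.na(ann$delta_da[4]))
  # Leu/Ile is a single isobaric entry
  expect_identical(annotate_shift(113.084)$candidate, "Dap+Leu/Ile")
})
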