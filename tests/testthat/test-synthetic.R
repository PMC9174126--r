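test_that("study design validates the channel layout and knockdown ratio", {
  d <- study_design(seed = 3)
  expect_equal(nrow(d$channel_map), 4L)
  expect_equal(d$knockdown_ratio, 0.05)
  expect_equal(d$seed, 3L)
  bad_map <- default_channel_map()
  bad_map$condition[1] <- "other"
  expect_error(study_design(channel_map = bad_map))
  expect_error(study_design(knockdown_ratio = 0))
  expect_error(noise_model(reporter_cv = -1), ">= 0")
})

test_that("ground truth channel abundances encode the knockdown exactly", {
  # null design: no suppression anywhere
  d1 <- study_design(n_proteins = 4, knockdown_ratio = 1.0, seed = 5)
  t1 <- simulate_ground_truth(d1)
  for (e in t1$entries) {
    expect_equal(unname(e$abundance[c("130", "131")] /
                          e$abundance[c("128", "129")]), c(1, 1))
  }
  # knockdown design, noise-free by construction at the truth level
  d2 <- study_design(n_proteins = 6, knockdown_ratio = 0.05, frac_target = 1,
                     frac_transcript_shifted = 0, seed = 5)
  t2 <- simulate_ground_truth(d2)
  fuc <- Filter(function(e) e$is_core_fuc, t2$entries)
  expect_gt(length(fuc), 0)
  for (e in fuc) {
    expect_equal(unname(e$abundance[c("130", "131")] /
                          e$abundance[c("128", "129")]), c(0.05, 0.05))
  }
  # transcript ratios of stable genes stay near 1
  stable <- t2$transcript_ratios$ratio[t2$transcript_ratios$class != "transcript_shifted"]
  expect_true(all(abs(stable - 1) < 0.1))
})

test_that("a sequon-free proteome is rejected", {
  prot <- data.frame(id = "P1", description = "P1",
                     sequence = "AAAGGGWWLKAAAGGGWWLR")
  expect_error(simulate_ground_truth(study_design(n_proteins = 1, seed = 1),
                                     proteome = prot), "sequon")
})

test_that("simulated spectra are deterministic and faithful at zero noise", {
  d <- study_design(n_proteins = 4, seed = 21)
  truth <- simulate_ground_truth(d)
  sim1 <- simulate_spectra(truth, zero_noise(), seed = 21)
  sim2 <- simulate_spectra(truth, zero_noise(), seed = 21)
  p1 <- withr::local_tempfile(fileext = ".mgf")
  p2 <- withr::local_tempfile(fileext = ".mgf")
  write_mgf(sim1$spectra, p1)
  write_mgf(sim2$spectra, p2)
  expect_identical(readLines(p1), readLines(p2))  # byte-identical re-run
  for (i in seq_along(sim1$spectra)) {
    e <- truth$entries[[i]]
    ts <- theoretical_spectrum(e$glycopeptide, sim1$spectra[[i]]$charge)
    expect_equal(sim1$spectra[[i]]$precursor_mz, ts$precursor_mz,
                 tolerance = 1e-9)
  }
})

test_that("MGF writer and reader round-trip spectra", {
  d <- study_design(n_proteins = 3, seed = 13)
  sim <- simulate_spectra(simulate_ground_truth(d), noise_model(), seed = 13)
  path <- withr::local_tempfile(fileext = ".mgf")
  write_mgf(sim$spectra, path)
  back <- read_mgf(path)
  expect_equal(length(back), length(sim$spectra))
  expect_equal(back[[1]]$id, sim$spectra[[1]]$id)
  expect_equal(back[[1]]$charge, sim$spectra[[1]]$charge)
  expect_equal(back[[1]]$precursor_mz, sim$spectra[[1]]$precursor_mz,
               tolerance = 1e-6)
  expect_equal(back[[1]]$mz, sim$spectra[[1]]$mz, tolerance = 1e-6)
})

test_that("glyco spectra carry the oxonium triplet, naked spectra never do", {
  d <- study_design(n_proteins = 4, seed = 31)
  truth <- simulate_ground_truth(d)
  sim <- simulate_spectra(truth, zero_noise(), seed = 31)
  oxo <- mass_table()$oxonium
  for (i in seq_along(sim$spectra)) {
    has_oxo <- all(vapply(oxo, function(o) {
      any(abs(sim$spectra[[i]]$mz - o) < 0.01)
    }, logical(1)))
    expect_equal(has_oxo, sim$sidecar$glycan[i] != "")
  }
})

test_that("5 ppm jitter keeps nearly all true fragments inside the 20 ppm window", {
  d <- study_design(n_proteins = 8, seed = 41)
  truth <- simulate_ground_truth(d)
  nm <- noise_model(mz_jitter_ppm_sd = 5, n_noise_peaks = 0,
                    peak_dropout_prob = 0)
  sim <- simulate_spectra(truth, nm, seed = 41)
  frac_in <- vapply(seq_along(sim$spectra), function(i) {
    e <- truth$entries[[i]]
    ts <- theoretical_spectrum(e$glycopeptide, sim$spectra[[i]]$charge)
    obs <- sim$spectra[[i]]$mz
    mean(vapply(ts$ions$mz, function(t) {
      any(abs(obs - t) / t * 1e6 <= 20)
    }, logical(1)))
  }, numeric(1))
  # normal tail: P(|N(0,5)| > 20 ppm) ~ 6e-5, so >= 99% must land inside
  expect_gte(mean(frac_in), 0.99)
})

test_that("expected reporter ratio equals the knockdown ratio under noise", {
  d <- study_design(n_proteins = 50, sites_per_protein = 2, frac_target = 1,
                    frac_transcript_shifted = 0,
                    background_peptides_per_protein = 0, seed = 61)
  truth <- simulate_ground_truth(d)
  sim <- simulate_spectra(truth, noise_model(reporter_cv = 0.1), seed = 61)
  rep_mz <- tmt6_reporters()
  ratios <- unlist(lapply(seq_along(sim$spectra), function(i) {
    if (!sim$sidecar$is_core_fuc[i]) return(NULL)
    sp <- sim$spectra[[i]]
    ints <- vapply(rep_mz, function(o) sp$intensity[which.min(abs(sp$mz - o))],
                   numeric(1))
    unname(ints[c("130", "131")] / ints[c("128", "129")])
  }))
  expect_gte(length(ratios) / 2, 100)
  se <- sd(ratios) / sqrt(length(ratios))
  expect_lt(abs(mean(ratios) - 0.05), 3 * se + 1e-3)
})
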