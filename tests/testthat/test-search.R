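test_that("decoy generation reverses the sequence but keeps the C-terminus", {
  expect_equal(decoy_sequence("VCSNDNK"), "NDNSCVK")
  expect_equal(decoy_sequence("AK"), "AK")
  expect_equal(nchar(decoy_sequence("LHLDYIGPCK")), 10L)
  expect_equal(substring(decoy_sequence("LHLDYIGPCK"), 10, 10), "K")
})

test_that("candidate index size matches independent enumeration on a toy protein", {
  # AAANATAAAK: single tryptic peptide, one sequon (N4), no M/Q.
  # Variable sites: deamidation N4, protein N-terminal acetyl -> 4 combos;
  # glyco options: none, HexNAc@4, HexNAc+dHex@4 -> x3; minus the 4
  # combinations where N4 is simultaneously deamidated and glycosylated:
  # 4*3 - 4 = 8 target variants, mirrored 1:1 onto decoys -> 16.
  prot <- data.frame(id = "T1", description = "T1", sequence = "AAANATAAAK")
  idx <- build_candidate_index(prot, search_config())
  expect_equal(length(idx$records), 16L)
  expect_equal(sum(vapply(idx$records, `[[`, logical(1), "is_decoy")), 8L)
  # decoy glyco sites are mirrored onto an N of the reversed sequence
  dec <- Filter(function(r) r$is_decoy && !is.na(r$gp$glyco_site), idx$records)
  for (r in dec) {
    expect_equal(substring(r$gp$sequence, r$gp$glyco_site, r$gp$glyco_site), "N")
  }
  # peptide without N: no glyco variants at all
  prot2 <- data.frame(id = "T2", description = "T2", sequence = "AAAGATAAAK")
  idx2 <- build_candidate_index(prot2, search_config())
  expect_true(all(vapply(idx2$records,
                         function(r) is.na(r$gp$glyco_site), logical(1))))
})

test_that("zero-noise spectra are matched to their true identity and site", {
  st <- shared_study()
  sim <- simulate_spectra(st$truth, zero_noise(), seed = 70)
  take <- seq_len(20)
  psms <- search_spectra(sim$spectra[take], st$index)
  m <- merge(psms, sim$sidecar[take, ], by = "spectrum_id",
             suffixes = c("", ".true"))
  expect_equal(nrow(m), 20L)
  expect_true(all(m$sequence == m$sequence.true))
  expect_true(all(m$glycan == m$glycan.true))
  expect_true(all(!m$is_decoy))
  g <- m[m$glycan.true != "", ]
  expect_true(all(g$glyco_site == g$glyco_site.true))
})

test_that("precursors far outside the tolerance stay unidentified", {
  st <- shared_study()
  sim <- simulate_spectra(st$truth, zero_noise(), seed = 71)
  sp <- sim$spectra[[1]]
  sp$precursor_mz <- sp$precursor_mz * (1 + 50e-6)  # 50 ppm off
  expect_equal(nrow(match_spectrum(sp, st$index)), 0L)
})

test_that("random-peak spectra do not favour targets over decoys", {
  st <- shared_study()
  masses <- st$index$mass
  set.seed(404)
  wins <- c(target = 0L, decoy = 0L)
  for (i in 1:40) {
    M <- sample(masses, 1)  # precursor sits on a real candidate mass
    sp <- list(id = paste0("r", i), precursor_mz = mz(M, 2L), charge = 2L,
               mz = sort(runif(200, 100, mz(M, 2L) * 2)),
               intensity = rexp(200) * 100)
    psms <- match_spectrum(sp, st$index)
    if (!nrow(psms)) next
    best_t <- suppressWarnings(max(psms$score[!psms$is_decoy]))
    best_d <- suppressWarnings(max(psms$score[psms$is_decoy]))
    if (!is.finite(best_t) || !is.finite(best_d)) next
    if (best_t > best_d) wins["target"] <- wins["target"] + 1L
    if (best_d > best_t) wins["decoy"] <- wins["decoy"] + 1L
  }
  total <- sum(wins)
  expect_gt(total, 10)
  expect_gt(wins[["target"]] / total, 0.2)
  expect_lt(wins[["target"]] / total, 0.8)
})

test_that("q-values follow the target-decoy estimator and its oracle", {
  # full separation: every target above every decoy
  sep <- data.frame(sequence = paste0("P", 1:200),
                    score = c(200:101, 100:1),
                    is_decoy = rep(c(FALSE, TRUE), each = 100))
  out <- fdr_filter(sep, q = 0.01)
  expect_true(all(out$accepted[!out$is_decoy]))
  expect_equal(unique(out$q_value[!out$is_decoy]), 1 / 100)
  # interleaved scores: brute-force threshold minimisation
  set.seed(5)
  mixed <- data.frame(sequence = paste0("S", 1:60),
                      score = c(rnorm(30, 3), rnorm(30, 1.5)),
                      is_decoy = rep(c(FALSE, TRUE), each = 30))
  got <- fdr_filter(mixed, q = 0.05)
  want <- brute_force_qvalues(got$score, got$is_decoy)
  expect_equal(got$q_value, want, tolerance = 1e-12)
  expect_false(is.unsorted(got$q_value))  # monotone along the sorted list
  # decoy-only input: nothing accepted
  dec <- data.frame(sequence = "D", score = 5, is_decoy = TRUE)
  expect_false(any(fdr_filter(dec)$accepted))
})

test_that("site localization demands bracketing glycan-retaining evidence", {
  st <- shared_study()
  sim <- simulate_spectra(st$truth, zero_noise(), seed = 72)
  glyco_idx <- which(sim$sidecar$glycan != "")[1:10]
  psms <- search_spectra(sim$spectra[glyco_idx], st$index)
  loc <- localize_sites(psms, sim$spectra[glyco_idx], st$index)
  m <- merge(loc, sim$sidecar, by = "spectrum_id", suffixes = c("", ".true"))
  expect_true(all(m$site_localized))
  expect_true(all(m$localized_site == m$site))
  expect_true(all(nzchar(m$localization_evidence)))

  # strip all glycan-retaining peaks: localization must be withdrawn
  i <- glyco_idx[1]
  e <- st$truth$entries[[i]]
  ts <- theoretical_spectrum(e$glycopeptide, 2L)
  keep <- !ts$ions$glycan_retained | ts$ions$series == "precursor_loss"
  sp <- list(id = "stripped", precursor_mz = ts$precursor_mz, charge = 2L,
             mz = ts$ions$mz[keep], intensity = rep(1000, sum(keep)))
  psm <- match_spectrum(sp, st$index)[1, ]
  loc2 <- localize_sites(psm, list(sp), st$index)
  expect_false(loc2$site_localized)
})
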