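test_that("y1 of a TMT-labelled lysine matches the hand-summed oracle", {
  md <- mass_table()$modifications
  gp <- glycopeptide("AAK", mods = data.frame(
    position = c(0L, 3L), name = c("tmt6_nterm", "tmt6_k"),
    delta_mass = rep(md[["tmt6"]], 2)))
  ions <- by_ladder(gp, max_frag_charge = 1)
  y1 <- ions[ions$series == "y" & ions$index == 1, ]
  # K residue + water + proton + TMT6, summed independently
  expect_equal(y1$mz, 376.2758, tolerance = 1e-4)
})

test_that("b/y complement identity holds for every generated 1+ pair", {
  set.seed(9)
  p <- mass_table()$proton
  for (i in 1:8) {
    seq <- random_peptide(sample(5:15, 1))
    gp <- glycopeptide(seq)
    M <- peptide_mass(gp)
    ions <- by_ladder(gp, max_frag_charge = 1)
    n <- nchar(seq)
    for (k in seq_len(n - 1)) {
      b <- ions$mz[ions$series == "b" & ions$index == k]
      y <- ions$mz[ions$series == "y" & ions$index == n - k]
      expect_equal(b + y, M + 2 * p, tolerance = 1e-4)
    }
  }
})

test_that("starred ions sit exactly one fucosylated-GlcNAc below retained ions", {
  gp <- make_sparc_mouse_gp()
  ions <- by_ladder(gp, max_frag_charge = 2)
  cov <- ions[ions$glycan_retained, ]
  expect_gt(nrow(cov), 0)
  for (r in seq_len(nrow(cov))) {
    star <- ions[ions$series == cov$series[r] & ions$index == cov$index[r] &
                   ions$charge == cov$charge[r] & !ions$glycan_retained, ]
    expect_equal(nrow(star), 1L)
    expect_match(star$label, "\\*")
    expect_equal(star$mz, cov$mz[r] - 349.1373 / cov$charge[r],
                 tolerance = 1e-4)
  }
  # ions not spanning N6 are never starred
  expect_false(any(grepl("\\*", ions$label[ions$series == "b" & ions$index < 6])))
})

test_that("signature ions carry the precursor losses and oxonium diagnostics", {
  gp <- make_sparc_mouse_gp()
  sig <- signature_ions(gp, precursor_charge = 2)
  expect_equal(sort(sig$mz[sig$series == "oxonium"]),
               c(138.0550, 168.0655, 204.0867), tolerance = 1e-6)
  m349 <- sig[grepl("\\[M-349\\]\\(2\\+\\)", sig$label), ]
  expect_equal(m349$mz, 647.845, tolerance = 5e-4)
  expect_true(any(grepl("\\[M-146\\]", sig$label)))
  expect_equal(sort(sig$mz[sig$series == "reporter"]),
               unname(sort(tmt6_reporters())))
  # non-fucosylated remnant: no neutral-loss signature, oxonium stays
  gp2 <- glycopeptide("TANETFVLK", glyco_site = 3L,
                      glycan_comp = glycan(HexNAc = 1))
  sig2 <- signature_ions(gp2, 2)
  expect_false(any(sig2$series == "precursor_loss"))
  expect_true(any(sig2$series == "oxonium"))
  # no glycan at all: reporters only, with a warning
  gp3 <- glycopeptide("AAK", mods = data.frame(
    position = 0L, name = "tmt6_nterm",
    delta_mass = mass_table()$modifications[["tmt6"]]))
  expect_warning(sig3 <- signature_ions(gp3, 2), "no glycan")
  expect_true(all(sig3$series == "reporter"))
})

test_that("oxonium ion masses obey the HexNAc fragmentation relations", {
  tab <- mass_table()
  oxo <- tab$oxonium
  expect_equal(oxo[["HexNAc"]] - oxo[["HexNAc-2H2O"]], 2 * tab$water,
               tolerance = 1e-3)
  expect_equal(oxo[["HexNAc"]], tab$monosaccharides[["HexNAc"]] + tab$proton,
               tolerance = 1e-3)
})

test_that("theoretical spectrum combines ladders and diagnostics deterministically", {
  gp <- make_sparc_mouse_gp()
  ts <- theoretical_spectrum(gp, precursor_charge = 2)
  expect_equal(ts$precursor_mz, 822.414, tolerance = 5e-4)
  expect_false(is.unsorted(ts$ions$mz))
  expect_equal(sum(ts$ions$series == "oxonium"), 3L)
  expect_true(any(grepl("\\[M-349\\]", ts$ions$label)))
  key <- paste(ts$ions$series, ts$ions$index, ts$ions$charge,
               ts$ions$glycan_retained, round(ts$ions$neutral_loss, 4),
               ts$ions$label)
  expect_false(any(duplicated(key)))
  expect_identical(theoretical_spectrum(gp, 2)$ions, ts$ions)

  # unmodified 7-mer without glycan or TMT: pure backbone combinatorics
  plain <- glycopeptide("TADEFVL")
  ts2 <- theoretical_spectrum(plain, precursor_charge = 2, max_frag_charge = 2)
  expect_equal(nrow(ts2$ions), 2L * 6L * 2L)

  # adding the glycan only adds glyco-bearing/starred/loss/oxonium entries
  glyco <- glycopeptide("TANETFVLK", glyco_site = 3L,
                        glycan_comp = glycan(HexNAc = 1, dHex = 1,
                                             core_fucosylated = TRUE))
  naked <- glycopeptide("TANETFVLK")
  li_g <- theoretical_spectrum(glyco, 2)$ions
  li_n <- theoretical_spectrum(naked, 2)$ions
  # every naked backbone m/z persists (glycan-lost ions share the bare mass)
  expect_true(all(round(li_n$mz, 4) %in% round(li_g$mz, 4)))
  extra <- li_g[!(round(li_g$mz, 4) %in% round(li_n$mz, 4)), ]
  expect_true(all(extra$glycan_retained |
                    extra$series %in% c("precursor_loss", "oxonium")))
})
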