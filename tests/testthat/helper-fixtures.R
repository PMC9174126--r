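# Shared fixtures for the published example peptides and simulated studies.

# mouse SPARC-like glycopeptide VCSNDNK: TMT6 on N-terminus and K7,
# carbamidomethyl C2, core-fucosylated Endo F3 remnant on N6
make_sparc_mouse_gp <- function() {
  md <- mass_table()$modifications
  glycopeptide(
    "VCSNDNK",
    mods = data.frame(
      position = c(0L, 7L, 2L),
      name = c("tmt6_nterm", "tmt6_k", "carbamidomethyl"),
      delta_mass = c(md[["tmt6"]], md[["tmt6"]], md[["carbamidomethyl"]])),
    glyco_site = 6L,
    glycan_comp = glycan(HexNAc = 1L, dHex = 1L, core_fucosylated = TRUE))
}

# human SPARC tryptic peptide LHLDYIGPCK, carbamidomethyl C9, label free
make_sparc_lhl_gp <- function() {
  md <- mass_table()$modifications
  glycopeptide(
    "LHLDYIGPCK",
    mods = data.frame(position = 9L, name = "carbamidomethyl",
                      delta_mass = md[["carbamidomethyl"]]))
}

# human SPARC N116 glycopeptide VCSNDNKTFDSSCHFFATK (one missed cleavage),
# carbamidomethyl on both C, core-fucosylated remnant on N6, label free
make_sparc_human_gp <- function() {
  md <- mass_table()$modifications
  glycopeptide(
    "VCSNDNKTFDSSCHFFATK",
    mods = data.frame(position = c(2L, 13L),
                      name = rep("carbamidomethyl", 2),
                      delta_mass = rep(md[["carbamidomethyl"]], 2)),
    glyco_site = 6L,
    glycan_comp = glycan(HexNAc = 1L, dHex = 1L, core_fucosylated = TRUE),
    missed_cleavages = 1L)
}

zero_noise <- function() {
  noise_model(mz_jitter_ppm_sd = 0, reporter_cv = 0, fragment_cv = 0,
              n_noise_peaks = 0, peak_dropout_prob = 0)
}

# shared simulated study + candidate index, built once per test run
# (the index is the expensive part)
shared_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      design <- study_design(n_proteins = 30L, sites_per_protein = 2L, seed = 7L)
      truth <- simulate_ground_truth(design)
      index <- build_candidate_index(truth$proteome, search_config())
      cache <<- list(design = design, truth = truth, index = index)
    }
    cache
  }
})

# published example candidate table (protein-level TMT and transcript ratios)
table1_quant <- function() {
  data.frame(
    protein_id = c("SPARC", "LRP1", "EGFR", "EGFR", "ITGB1"),
    site = c(115L, 2345L, 578L, 653L, 50L),
    ratio_rep1 = c(0.04, 0.05, 0.256, 0.30, 0.300),
    ratio_rep2 = c(0.07, 0.05, 0.218, 0.25, 0.351),
    n_psms = c(3L, 2L, 2L, 1L, 1L),
    n_localized = c(3L, 2L, 2L, 1L, 1L),
    stringsAsFactors = FALSE)
}

table1_transcripts <- function() {
  data.frame(gene = c("Sparc", "Lrp1", "Egfr", "Itgb1"),
             ratio = c(0.88, 0.88, 0.93, 1.05), stringsAsFactors = FALSE)
}

table1_gene_map <- function() {
  data.frame(protein_id = c("SPARC", "LRP1", "EGFR", "ITGB1"),
             gene = c("Sparc", "Lrp1", "Egfr", "Itgb1"),
             stringsAsFactors = FALSE)
}

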