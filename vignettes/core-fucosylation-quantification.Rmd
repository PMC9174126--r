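---
title: "Site-specific quantification of core-fucosylated glycopeptides"
author: "corefucq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Site-specific quantification of core-fucosylated glycopeptides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corefucq)
```

## The biological question and the measurement strategy

Core-fucosylation is the transfer of fucose in alpha1-6 linkage onto the
innermost, asparagine-linked GlcNAc of an N-glycan, catalyzed in mammals by a
single enzyme, Fut8. Identifying which glycoproteins depend on Fut8 — and at
which sequon — requires site-resolved, quantitative glycoproteomics. The
measurement strategy this package implements rests on three ideas:

1. **Endo F3 simplification.** Endo F3 cleaves within the chitobiose core of
   N-glycans, leaving only the innermost GlcNAc on the peptide — together with
   the core fucose when present. A heterogeneous glycoform population
   collapses into at most two remnant species per site, `HexNAc(1)` and
   `HexNAc(1)dHex(1)`, shifting the peptide mass by 203.0794 or 349.1373 Da.
   Mass spectrometry of these simplified glycopeptides behaves almost like
   ordinary peptide MS.
2. **TMT reporter quantification.** Isobaric labeling of two control and two
   knockdown replicates on four TMT6 channels lets one MS/MS spectrum report
   the knockdown/control abundance ratio of each glycoform.
3. **A characteristic fragmentation signature.** Under stepped collision
   energy, a core-fucosylated remnant glycopeptide shows (a) precursor losses
   of fucose (−146.0579) and of the whole fucosylated GlcNAc (−349.1373),
   (b) b/y backbone ladders in glycan-retained and glycan-lost ("starred")
   forms that localize the site, and (c) the GlcNAc oxonium triplet at
   204.0867 / 168.0655 / 138.0550 that marks the spectrum as glycopeptide-
   derived.

The package models all three, plus the downstream statistics: a simplified
target-decoy search engine, q-value control, site localization,
median-normalizable reporter quantification, extracted-ion-chromatogram
(XIC) integration, and a multi-criterion ranking of candidate Fut8
substrates. A seeded synthetic-spectrum generator provides ground truth so
every stage is testable without raw instrument files.

## Mass arithmetic

All masses are monoisotopic. The constants (20 residue masses, water
18.0105646, proton 1.0072765, the four monosaccharide residues, modification
deltas, TMT6 reporter m/z values) ship as a versioned JSON table so tests can
pin exact values:

```{r}
tab <- mass_table()
c(proton = tab$proton, water = tab$water,
  HexNAc = tab$monosaccharides[["HexNAc"]],
  dHex = tab$monosaccharides[["dHex"]])
```

A glycopeptide mass is the plain additive sum: residues + water +
modification deltas + glycan remnant. The doubly charged core-fucosylated
`VCSNDNK` glycopeptide (TMT6 on the N-terminus and K7, carbamidomethyl C2,
`HexNAc(1)dHex(1)` on N6) reconstructs the published precursor:

```{r}
md <- tab$modifications
gp <- glycopeptide("VCSNDNK",
  mods = data.frame(position = c(0L, 7L, 2L),
                    name = c("tmt6_nterm", "tmt6_k", "carbamidomethyl"),
                    delta_mass = c(md[["tmt6"]], md[["tmt6"]],
                                   md[["carbamidomethyl"]])),
  glyco_site = 6L,
  glycan_comp = glycan(HexNAc = 1, dHex = 1, core_fucosylated = TRUE))
mz(peptide_mass(gp), 2L)
```

Reconstruction only succeeds with TMT on *both* the peptide N-terminus and
the lysine; this is how the package resolves the labeling ambiguity, and it
matches amine-reactive TMT chemistry. Ambiguity codes (B, Z, X, U) are
rejected rather than guessed, m/z comparisons against printed values use
±0.005 (covering 2–3 decimal rounding), and internal identities (b/y
complements, round-trips) are held to 1e-4 Da or better.

## The fragment model

`by_ladder()` emits b1..b(n−1) and y1..y(n−1) at charges 1..2. Ions spanning
the glycosite appear twice: glycan-retained, and glycan-lost with a `*`
label when the loss is the 349.1373 fucosylated-GlcNAc remnant.
`signature_ions()` adds the precursor losses (only for fucosylated
remnants; `[M-146]` keeps the GlcNAc on the peptide), the oxonium triplet,
and the active reporter ions. a-ions, internal fragments, and stacked losses
are deliberately excluded — the model covers exactly the ion types used for
sequencing and site assignment — and fragment charges are capped at
min(precursor charge, 2). Intensity is not predicted: theory space is
uniform, and simulated intensities are a property of the noise model.

## The synthetic study design

`study_design()` encodes the experiment the generator emulates: four TMT6
channels 128–131 mapped to (siCon, siFut8) x (replicate 1, 2) — the mapping
is configuration, not constant, because reagent-to-sample order is an
experimental choice — and a knockdown that suppresses core-fucosylated forms
to `knockdown_ratio` of control. The default ratio is **0.05**, the midpoint
of the strongest published example (replicate ratios 0.04 and 0.07).

Proteins are concatenations of tryptic segments with engineered, unambiguous
sequons. Each protein belongs to one of three classes:

* `target` — core-fucosylated sites suppressed to the knockdown ratio,
  transcript stable (the proteins the ranking stage must recover);
* `transcript_shifted` — the whole protein drops because its mRNA does;
  these are the decoys that criterion (ii) must reject;
* `null` — non-fucosylated remnants, unchanged abundance.

Peptide base abundances are log-normal (sdlog 0.4 around 1e5, arbitrary
units); true channel abundances are exact at the ground-truth level, so a
zero-noise simulation carries the design ratios exactly. The noise model
(defaults: 5 ppm Gaussian m/z jitter, 10% reporter CV, 30% fragment CV, 20
uniform noise peaks, 5% dropout) is applied only at spectrum synthesis.
Multiplicative noise uses mean-one log-normals, so expected reporter ratios
equal the design ratio at any CV. No acquisition-level noise statistics were
published; these defaults are stated, not fitted. The generator emits
monoisotopic sticks only — no isotope envelopes, co-isolation interference,
or chromatographic peak shapes — so passing tests demonstrate correctness of
the downstream logic, not robustness to every artifact of real data.
Retention time is a linear proxy of mass (needed only for XIC tests), and
all randomness flows from one integer seed: identical seeds give
byte-identical MGF output.

## Search, FDR, and localization

The search engine is deliberately simple and fully specified, because the
published pipeline's commercial engine is not: candidates within 6 ppm of
the precursor neutral mass are scored by the sum over matched theoretical
ions of `log(1 + I/Imax)`, with nearest-peak matching at 20 ppm, ties broken
by smallest ppm, and each observed peak allowed to satisfy one theoretical
ion (assigned greedily by peak intensity). Acceptance of the package
therefore rests on synthetic-truth recovery, not score parity with any
external engine.

Decoys are sequence reversals preserving the C-terminal residue (keeping
tryptic mass structure), generated 1:1 with glyco variants mirrored onto the
reversed positions. q-values follow the standard (decoys + 1)/targets
estimator, minimized over thresholds; they are monotone along the
score-sorted list. One PSM-level FDR is applied — whether the original
study's peptide/protein/site-level filters were applied jointly is not
recoverable, so the single filter is the package's choice. Note the
estimator's floor: with `n` PSMs the smallest attainable q is 1/n, so a 1%
cutoff needs at least ~100 target PSMs; the toy CLI configuration relaxes
the cutoff for this reason.

Site localization is conservative: a site is called only when at least one
matched glycan-retaining backbone ion and one glycan-lost or non-covering
ion bracket it, and the retained-ion constraints single out exactly one
sequon. Oxonium ions prove glycosylation but never position, and a site is
never inferred from precursor mass alone — this guards against the
asparagine-deamidation (+0.984016) confusion that the variable-modification
set would otherwise permit.

## Quantification and normalization

Reporter intensities are read within ±0.003 m/z of each channel, summed per
(protein, site) over accepted PSMs, and ratioed per replicate under the
channel map. Median normalization per channel is available and makes the
result invariant to global channel-loading differences. It assumes, however,
that most quantified species are unregulated. In a core-fucosylation-
*enriched* experiment with a strong knockdown, that assumption fails — the
regulated fraction is large, and normalizing on the enriched population
would partially cancel the very effect being measured. The package therefore
exposes `normalize` as an argument; the recovery properties are assessed
un-normalized (the simulator introduces no channel-scale distortion to
remove), while scale-invariance of the normalized path is verified
separately. With real data, normalization factors should come from the
unenriched input proteome.

`xic_area()` implements label-free comparison: a trapezoidal integral of
peaks within ±10 ppm of a target m/z over a retention-time window, which
reproduces the wild-type/knockout contrast — the naked peptide's XIC is
shared while the core-fucosylated glycopeptide's XIC vanishes in the
knockout.

## Candidate ranking

Three criteria, stated qualitatively in the source study, are made numeric
here and are configurable and recorded in the report metadata:

* **(i)** both replicate TMT ratios ≤ `max_tmt_ratio` (default 0.40, chosen
  to cover the largest passing published value, 0.351);
* **(ii)** transcript ratio within `[0.77, 1.30]` (covering the published
  passing range 0.88–1.05); proteins missing transcript evidence fail by
  default (conservative, configurable). Whether the original comparison used
  a formal statistic is unstated; a ratio band is this package's reading.
* **(iii)** at least one site-localized PSM.

Protein-level ratios use most-affected-site aggregation (minimum across
sites; the mean is available). Passing proteins are ranked by the **minimum**
of the two replicate ratios, ascending. The minimum — not the maximum — is
the default key because it is the only simple key consistent with the
published ordering of the worked example (0.04/0.07 ranking above
0.05/0.05); the alternative is exposed as `key = "max"`.

## Problem sizes and reproducibility

The shipped test suite exercises the pipeline at desk scale, chosen to keep
a full run in a few minutes while leaving the statistics meaningful: a
shared 30-protein / 60-sequon simulated study for search-based checks
(~14,000 indexed candidates after modification enumeration), 600 searched
spectra across 20 noise seeds for the empirical-FDR check, 120+
core-fucosylated sites for ratio recovery, and 20 independent designs for
ranking sensitivity/specificity. All simulations are integer-seeded with no
locale or time dependence. `scripts/acceptance.R` recomputes the printed
spectral landmarks from first principles and writes them as JSON.

## Known limitations

* Composition-only glycan model: no topology, linkage, or glycans beyond the
  Endo F3 remnant (full glycans are assumed trimmed upstream).
* No ETD/EThcD, a-/internal ions, isotope envelopes, or TMT channel
  isotope-impurity correction.
* Protein inference is "peptide maps to protein"; no grouping or parsimony.
* The sequon scan is the plain N-X(≠P)-[S/T] rule, not a glycosylation
  propensity predictor.
* The initiator methionine is not clipped by default (`clip_nterm_met`
  enables the clipped proteoform alongside the full one).
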