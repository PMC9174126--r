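#' Monoisotopic mass constants
#'
#' Loads the versioned table of monoisotopic mass constants shipped with the
#' package: amino-acid residue masses for the 20 canonical residues, water and
#' proton masses, glycan monosaccharide residue masses (Hex, HexNAc, dHex,
#' NeuAc), common modification deltas, oxonium diagnostic m/z values, and the
#' six TMT6-plex reporter ion m/z values. The table is read once per session
#' and cached.
#'
#' @return A list with elements `proton`, `water`, `residues` (named numeric),
#'   `monosaccharides`, `modifications`, `oxonium`, and `tmt6_reporters`.
#' @export
#' @examples
#' tab <- mass_table()
#' tab$proton
mass_table <- function() {
  if (!is.null(.cfq_cache$mass_table)) {
    return(.cfq_cache$mass_table)
  }
  path <- system.file("extdata", "mass_constants.json", package = "corefucq",
                      mustWork = TRUE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in c("residues", "monosaccharides", "modifications", "oxonium",
               "tmt6_reporters")) {
    raw[[nm]] <- unlist(raw[[nm]])
  }
  stopifnot(all(raw$residues > 0), length(raw$residues) == 20L,
            abs(raw$proton - 1.007276) < 1e-6)
  .cfq_cache$mass_table <- raw
  raw
}

#' Define a peptide modification
#'
#' @param name Modification name (e.g. `"carbamidomethyl"`).
#' @param delta_mass Monoisotopic mass shift in Da.
#' @param specificity Residue letter, `"N-term"` (peptide N-terminus) or
#'   `"Protein N-term"`.
#' @param kind `"fixed"` or `"variable"`.
#' @return A `modification` object (list).
#' @export
modification <- function(name, delta_mass, specificity, kind = c("fixed", "variable")) {
  kind <- match.arg(kind)
  stopifnot(is.character(name), nzchar(name), is.finite(delta_mass),
            is.character(specificity), nzchar(specificity))
  structure(list(name = name, delta_mass = delta_mass,
                 specificity = specificity, kind = kind),
            class = "modification")
}

#' Default modification set
#'
#' The standard search modification set: carbamidomethyl C (fixed), TMT6-plex
#' on the peptide N-terminus and on lysine (fixed, only when `tmt = TRUE`),
#' oxidation of M, acetylation of the protein N-terminus, deamidation of N/Q,
#' and the Endo F3 fucosylated-GlcNAc remnant (dHex-HexNAc) on N (variable).
#'
#' @param tmt Logical; include the fixed TMT6 labels.
#' @return Named list of [modification()] objects.
#' @export
default_modifications <- function(tmt = TRUE) {
  tab <- mass_table()
  md <- tab$modifications
  mods <- list(
    carbamidomethyl = modification("carbamidomethyl", md[["carbamidomethyl"]], "C", "fixed"),
    oxidation_m = modification("oxidation_m", md[["oxidation"]], "M", "variable"),
    acetyl_protein_nterm = modification("acetyl_protein_nterm", md[["acetyl"]],
                                        "Protein N-term", "variable"),
    deamidation_n = modification("deamidation_n", md[["deamidation"]], "N", "variable"),
    deamidation_q = modification("deamidation_q", md[["deamidation"]], "Q", "variable"),
    dhex_hexnac_n = modification("dhex_hexnac_n",
                                 sum(tab$monosaccharides[c("HexNAc", "dHex")]),
                                 "N", "variable")
  )
  if (tmt) {
    mods$tmt6_nterm <- modification("tmt6_nterm", md[["tmt6"]], "N-term", "fixed")
    mods$tmt6_k <- modification("tmt6_k", md[["tmt6"]], "K", "fixed")
  }
  mods
}

#' Glycan composition
#'
#' A glycan is represented by monosaccharide residue counts only (no topology
#' or linkage). An Endo F3 remnant is the special case HexNAc(1)dHex(0 or 1).
#'
#' @param HexNAc,dHex,Hex,NeuAc Non-negative integer counts.
#' @param core_fucosylated Logical; if `TRUE`, `dHex` must be >= 1.
#' @return A `glycan` object.
#' @export
#' @examples
#' glycan(HexNAc = 1, dHex = 1, core_fucosylated = TRUE)  # core-fuc remnant
glycan <- function(HexNAc = 0L, dHex = 0L, Hex = 0L, NeuAc = 0L,
                   core_fucosylated = dHex >= 1L) {
  counts <- c(Hex = as.integer(Hex), HexNAc = as.integer(HexNAc),
              dHex = as.integer(dHex), NeuAc = as.integer(NeuAc))
  if (any(is.na(counts)) || any(counts < 0L)) {
    stop("glycan counts must be non-negative integers")
  }
  if (isTRUE(core_fucosylated) && counts[["dHex"]] < 1L) {
    stop("a core-fucosylated glycan must contain at least one dHex (fucose)")
  }
  structure(list(counts = counts, core_fucosylated = isTRUE(core_fucosylated)),
            class = "glycan")
}

#' Monoisotopic mass of a glycan composition
#'
#' @param g A [glycan()] object.
#' @param table Mass table, see [mass_table()].
#' @return Mass in Da (0 for the empty composition).
#' @export
#' @examples
#' glycan_mass(glycan(HexNAc = 1, dHex = 1))  # 349.1373, nominal 349
glycan_mass <- function(g, table = mass_table()) {
  if (is.null(g)) return(0)
  stopifnot(inherits(g, "glycan"))
  sum(g$counts * table$monosaccharides[names(g$counts)])
}

#' Endo F3 remnant simplification
#'
#' Endo F3 cleaves within the chitobiose core of an N-glycan, leaving only the
#' innermost GlcNAc attached to the peptide -- together with the alpha1-6
#' core fucose when the glycan is core-fucosylated. The operation is
#' idempotent and preserves the core-fucosylation flag.
#'
#' @param g A [glycan()] object with at least one HexNAc.
#' @return The remnant: HexNAc(1) or HexNAc(1)dHex(1).
#' @export
endo_f3_simplify <- function(g) {
  stopifnot(inherits(g, "glycan"))
  if (g$counts[["HexNAc"]] < 1L) {
    stop("no N-glycan to trim: composition contains no HexNAc")
  }
  glycan(HexNAc = 1L, dHex = if (g$core_fucosylated) 1L else 0L,
         core_fucosylated = g$core_fucosylated)
}

.valid_residues <- function(sequence, table = mass_table()) {
  res <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- which(!(res %in% names(table$residues)))
  if (length(bad)) {
    stop(sprintf("unknown residue '%s' at position %d", res[bad[1]], bad[1]))
  }
  res
}

#' Construct a glycopeptide
#'
#' The central analyte: a peptide sequence plus positioned modifications, an
#' optional N-glycosylation site carrying a glycan remnant, and provenance
#' (protein, protein coordinates, missed cleavages).
#'
#' @param sequence Upper-case peptide sequence (canonical 20-letter alphabet;
#'   B/Z/X/U and other ambiguity codes are rejected).
#' @param mods `data.frame` with columns `position` (integer; 0 denotes the
#'   peptide N-terminus), `name`, `delta_mass`; or `NULL`.
#' @param glyco_site 1-based index of the glycosylated N residue, or `NA`.
#' @param glycan_comp A [glycan()] object or `NULL`.
#' @param protein_id Source protein identifier.
#' @param missed_cleavages Number of internal missed cleavage sites (0--2).
#' @param start 1-based start coordinate of the peptide in the protein.
#' @return A `glycopeptide` object.
#' @export
glycopeptide <- function(sequence, mods = NULL, glyco_site = NA_integer_,
                         glycan_comp = NULL, protein_id = NA_character_,
                         missed_cleavages = 0L, start = NA_integer_) {
  res <- .valid_residues(sequence)
  n <- length(res)
  if (is.null(mods)) {
    mods <- data.frame(position = integer(), name = character(),
                       delta_mass = numeric())
  }
  stopifnot(all(c("position", "name", "delta_mass") %in% names(mods)))
  if (nrow(mods) && (any(mods$position < 0L) || any(mods$position > n))) {
    stop("modification position out of range [0, peptide length]")
  }
  if (!is.na(glyco_site)) {
    if (glyco_site < 1L || glyco_site > n || res[glyco_site] != "N") {
      stop("glyco_site must point at an N residue within the peptide")
    }
  }
  if (missed_cleavages < 0L || missed_cleavages > 2L) {
    stop("missed_cleavages must be between 0 and 2")
  }
  structure(list(sequence = sequence, mods = mods,
                 glyco_site = as.integer(glyco_site), glycan = glycan_comp,
                 protein_id = protein_id,
                 missed_cleavages = as.integer(missed_cleavages),
                 start = as.integer(start)),
            class = "glycopeptide")
}

#' @export
print.glycopeptide <- function(x, ...) {
  gl <- if (!is.null(x$glycan)) {
    paste0(" + ", paste0(names(x$glycan$counts[x$glycan$counts > 0]),
                         x$glycan$counts[x$glycan$counts > 0], collapse = ""),
           " @N", x$glyco_site)
  } else ""
  cat(sprintf("<glycopeptide> %s%s (%d mods, %d missed cleavages, %s)\n",
              x$sequence, gl, nrow(x$mods), x$missed_cleavages, x$protein_id))
  invisible(x)
}

#' Monoisotopic mass of a (glyco)peptide
#'
#' Sum of residue masses, water, modification deltas and (when present) the
#' glycan remnant mass.
#'
#' @param gp A [glycopeptide()] object.
#' @param table Mass table.
#' @return Neutral monoisotopic mass in Da.
#' @export
#' @examples
#' peptide_mass(glycopeptide("G"))  # 75.0320
peptide_mass <- function(gp, table = mass_table()) {
  stopifnot(inherits(gp, "glycopeptide"))
  res <- .valid_residues(gp$sequence, table)
  sum(table$residues[res]) + table$water + sum(gp$mods$delta_mass) +
    glycan_mass(gp$glycan, table)
}

#' Mass-to-charge ratio of a protonated ion
#'
#' @param mass Neutral monoisotopic mass in Da (vectorized).
#' @param charge Positive integer charge state.
#' @param table Mass table.
#' @return m/z = (mass + charge * proton) / charge.
#' @export
#' @examples
#' mz(1642.8126, 2)  # 822.414
mz <- function(mass, charge, table = mass_table()) {
  if (any(charge < 1L) || any(charge != as.integer(charge))) {
    stop("charge must be a positive integer")
  }
  if (any(mass <= 0)) stop("mass must be positive")
  (mass + charge * table$proton) / charge
}

#' Neutral mass from an observed m/z
#'
#' Inverse of [mz()]: `charge * (mz - proton)`.
#'
#' @param mz_value Observed m/z.
#' @param charge Positive integer charge state.
#' @param table Mass table.
#' @return Neutral mass in Da.
#' @export
neutral_mass <- function(mz_value, charge, table = mass_table()) {
  if (any(charge < 1L)) stop("charge must be a positive integer")
  charge * (mz_value - table$proton)
}
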