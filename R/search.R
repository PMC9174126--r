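#' Search engine configuration
#'
#' Defaults follow the study's database-search settings: 6 ppm precursor and
#' 20 ppm fragment tolerance, up to two missed cleavages, minimum peptide
#' length seven, 1% FDR, carbamidomethyl C and TMT6 (peptide N-terminus and
#' K) fixed, oxidation M / protein N-terminal acetyl / deamidation N,Q and
#' the Endo F3 remnants on sequon N variable. Decoys are sequence reversals
#' preserving the C-terminal residue.
#'
#' @param precursor_tol_ppm,fragment_tol_ppm Match tolerances in ppm.
#' @param fdr_q Target-decoy q-value cutoff.
#' @param min_peptide_len,max_missed Digestion parameters.
#' @param tmt Apply the fixed TMT6 labels.
#' @param variable_mods Names of active variable modifications (subset of
#'   `"oxidation_m"`, `"acetyl_protein_nterm"`, `"deamidation_n"`,
#'   `"deamidation_q"`).
#' @param max_var_combos Cap on modification variants per peptide.
#' @param channels Active TMT reporter channels.
#' @return A `search_config` object (list).
#' @export
search_config <- function(precursor_tol_ppm = 6, fragment_tol_ppm = 20,
                          fdr_q = 0.01, min_peptide_len = 7L, max_missed = 2L,
                          tmt = TRUE,
                          variable_mods = c("oxidation_m", "acetyl_protein_nterm",
                                            "deamidation_n", "deamidation_q"),
                          max_var_combos = 64L,
                          channels = c("128", "129", "130", "131")) {
  stopifnot(precursor_tol_ppm > 0, fragment_tol_ppm > 0,
            fdr_q > 0, fdr_q < 1)
  structure(list(precursor_tol_ppm = precursor_tol_ppm,
                 fragment_tol_ppm = fragment_tol_ppm, fdr_q = fdr_q,
                 min_peptide_len = as.integer(min_peptide_len),
                 max_missed = as.integer(max_missed), tmt = isTRUE(tmt),
                 variable_mods = variable_mods,
                 max_var_combos = as.integer(max_var_combos),
                 channels = channels),
            class = "search_config")
}

#' Decoy sequence by reversal preserving the C-terminal residue
#'
#' Keeps the tryptic C-terminal K/R in place so decoys retain target-like
#' precursor mass and fragmentation properties.
#'
#' @param sequence Peptide sequence.
#' @return The decoy sequence.
#' @export
decoy_sequence <- function(sequence) {
  n <- nchar(sequence)
  if (n < 2L) return(sequence)
  res <- strsplit(sequence, "", fixed = TRUE)[[1]]
  paste0(paste(rev(res[seq_len(n - 1L)]), collapse = ""), res[n])
}

# enumerate modification/glycan variants of one peptide sequence.
# sequon_pos: peptide coordinates of glycosylatable N residues.
.peptide_variants <- function(sequence, sequon_pos, protein_nterm, config, mods) {
  res <- strsplit(sequence, "", fixed = TRUE)[[1]]
  fixed <- .fixed_mod_table(sequence,
                            if (config$tmt) mods else mods[!grepl("^tmt", names(mods))])
  var_sites <- list()
  add_site <- function(position, name) {
    var_sites[[length(var_sites) + 1L]] <<-
      list(position = position, name = name, delta = mods[[name]]$delta_mass)
  }
  vm <- config$variable_mods
  if ("oxidation_m" %in% vm) for (p in which(res == "M")) add_site(p, "oxidation_m")
  if ("deamidation_n" %in% vm) for (p in which(res == "N")) add_site(p, "deamidation_n")
  if ("deamidation_q" %in% vm) for (p in which(res == "Q")) add_site(p, "deamidation_q")
  if ("acetyl_protein_nterm" %in% vm && protein_nterm) add_site(0L, "acetyl_protein_nterm")

  ns <- length(var_sites)
  combos <- list(integer(0))
  if (ns > 0) {
    for (k in seq_len(ns)) {
      cs <- combn(ns, k, simplify = FALSE)
      combos <- c(combos, cs)
      if (length(combos) >= config$max_var_combos) break
    }
  }
  glyco_opts <- list(list(site = NA_integer_, glycan = NULL))
  for (s in sequon_pos) {
    glyco_opts <- c(glyco_opts,
                    list(list(site = s, glycan = glycan(HexNAc = 1L)),
                         list(site = s, glycan = glycan(HexNAc = 1L, dHex = 1L,
                                                        core_fucosylated = TRUE))))
  }
  out <- list()
  for (cb in combos) {
    vmods <- if (length(cb)) do.call(rbind, lapply(var_sites[cb], function(v) {
      data.frame(position = v$position, name = v$name, delta_mass = v$delta)
    })) else NULL
    for (g in glyco_opts) {
      if (!is.na(g$site) && !is.null(vmods) &&
          any(vmods$position == g$site & grepl("^deamidation", vmods$name))) {
        next  # a deamidated N cannot also carry the glycan
      }
      out[[length(out) + 1L]] <- list(mods = rbind(fixed, vmods),
                                      glyco_site = g$site, glycan = g$glycan)
      if (length(out) >= config$max_var_combos) return(out)
    }
  }
  out
}

#' Build the searchable candidate index
#'
#' Digests the proteome, enumerates every admissible fixed/variable
#' modification combination and Endo F3 remnant glycoform on sequon N
#' residues, mirrors all variants onto 1:1 reversed decoys (C-terminal
#' residue preserved, glyco sites mirrored), and keys the result by neutral
#' monoisotopic mass.
#'
#' @param proteome [read_fasta()]-style data.frame.
#' @param config A [search_config()].
#' @return A `candidate_index`: list with `records` (candidate
#'   [glycopeptide()]s plus decoy flags and sequon positions), the parallel
#'   numeric `mass` vector, sort order, and the configuration.
#' @export
build_candidate_index <- function(proteome, config = search_config()) {
  tab <- mass_table()
  mods <- default_modifications(tmt = TRUE)
  digest <- digest_proteome(proteome, max_missed = config$max_missed,
                            min_len = config$min_peptide_len)
  sequons <- do.call(rbind, lapply(seq_len(nrow(proteome)),
                                   function(i) find_sequons(proteome[i, ])))
  records <- list()
  for (r in seq_len(nrow(digest))) {
    pep <- digest[r, ]
    sq <- sequons[sequons$protein_id == pep$protein_id &
                    sequons$position >= pep$start &
                    sequons$position <= pep$end, , drop = FALSE]
    pep_sq <- sq$position - pep$start + 1L
    n <- nchar(pep$sequence)
    variants <- .peptide_variants(pep$sequence, pep_sq, pep$start == 1L,
                                  config, mods)
    for (v in variants) {
      gp <- glycopeptide(pep$sequence, mods = v$mods, glyco_site = v$glyco_site,
                         glycan_comp = v$glycan, protein_id = pep$protein_id,
                         missed_cleavages = pep$missed_cleavages,
                         start = pep$start)
      records[[length(records) + 1L]] <- list(gp = gp, is_decoy = FALSE,
                                              pep_sequons = pep_sq)
    }
    # decoy: same enumeration on the reversed sequence, glyco sites mirrored
    dseq <- decoy_sequence(pep$sequence)
    d_sq <- integer()
    if (length(pep_sq)) {
      d_sq <- ifelse(pep_sq == n, n, n - pep_sq)
      d_sq <- d_sq[substring(dseq, d_sq, d_sq) == "N"]
    }
    d_variants <- .peptide_variants(dseq, d_sq, pep$start == 1L, config, mods)
    for (v in d_variants) {
      gp <- glycopeptide(dseq, mods = v$mods, glyco_site = v$glyco_site,
                         glycan_comp = v$glycan,
                         protein_id = paste0("rev_", pep$protein_id),
                         missed_cleavages = pep$missed_cleavages,
                         start = pep$start)
      records[[length(records) + 1L]] <- list(gp = gp, is_decoy = TRUE,
                                              pep_sequons = d_sq)
    }
  }
  mass <- vapply(records, function(x) peptide_mass(x$gp, tab), numeric(1))
  ord <- order(mass)
  structure(list(records = records, mass = mass, ord = ord,
                 config = config, ion_cache = new.env(parent = emptyenv())),
            class = "candidate_index")
}

#' @export
print.candidate_index <- function(x, ...) {
  nd <- sum(vapply(x$records, `[[`, logical(1), "is_decoy"))
  cat(sprintf("<candidate_index> %d candidates (%d targets, %d decoys)\n",
              length(x$records), length(x$records) - nd, nd))
  invisible(x)
}

.candidate_ions <- function(index, id, precursor_charge) {
  key <- paste0(id, "_", precursor_charge)
  hit <- index$ion_cache[[key]]
  if (!is.null(hit)) return(hit)
  ts <- theoretical_spectrum(index$records[[id]]$gp,
                             precursor_charge = precursor_charge,
                             channels = index$config$channels)
  index$ion_cache[[key]] <- ts$ions
  ts$ions
}

# greedy peak-ion assignment: each observed peak satisfies at most one
# theoretical ion (priority: peak intensity, then smallest ppm)
.match_ions <- function(theo_mz, obs_mz, obs_int, tol_ppm) {
  nt <- length(theo_mz)
  if (!nt || !length(obs_mz)) {
    return(data.frame(theo = integer(), obs = integer(), ppm = numeric()))
  }
  j <- findInterval(theo_mz, obs_mz)
  cand <- list()
  for (i in seq_len(nt)) {
    for (jj in unique(pmin(pmax(c(j[i], j[i] + 1L), 1L), length(obs_mz)))) {
      ppm <- abs(obs_mz[jj] - theo_mz[i]) / theo_mz[i] * 1e6
      if (ppm <= tol_ppm) {
        cand[[length(cand) + 1L]] <- c(i, jj, ppm)
      }
    }
  }
  if (!length(cand)) {
    return(data.frame(theo = integer(), obs = integer(), ppm = numeric()))
  }
  m <- do.call(rbind, cand)
  o <- order(-obs_int[m[, 2]], m[, 3])
  m <- m[o, , drop = FALSE]
  used_t <- logical(length(theo_mz)); used_o <- logical(length(obs_mz))
  keep <- logical(nrow(m))
  for (r in seq_len(nrow(m))) {
    ti <- m[r, 1]; oj <- m[r, 2]
    if (!used_t[ti] && !used_o[oj]) {
      used_t[ti] <- TRUE; used_o[oj] <- TRUE; keep[r] <- TRUE
    }
  }
  m <- m[keep, , drop = FALSE]
  data.frame(theo = as.integer(m[, 1]), obs = as.integer(m[, 2]), ppm = m[, 3])
}

#' Match one spectrum against the candidate index
#'
#' Candidates within the precursor tolerance are scored with an
#' intensity-weighted matched-ion score: the sum over matched theoretical
#' ions of `log(1 + I/I_max)`, with fragment matching to the nearest observed
#' peak within the fragment tolerance (ties broken by smallest ppm; one
#' observed peak can satisfy only one theoretical ion, assigned greedily by
#' peak intensity).
#'
#' @param spectrum A spectrum record (see [simulate_spectra()] /
#'   [read_mgf()]).
#' @param index A [build_candidate_index()].
#' @param config A [search_config()] (defaults to the index's).
#' @return `data.frame` of candidate PSMs ranked by decreasing score (rank 1
#'   is the best match); zero rows if no candidate lies in the precursor
#'   window.
#' @export
match_spectrum <- function(spectrum, index, config = index$config) {
  tab <- mass_table()
  z <- spectrum$charge
  neutral <- neutral_mass(spectrum$precursor_mz, z, tab)
  tol <- config$precursor_tol_ppm * 1e-6 * neutral
  ms <- index$mass[index$ord]
  lo <- findInterval(neutral - tol, ms) + 1L
  hi <- findInterval(neutral + tol, ms)
  empty <- data.frame(spectrum_id = character(), candidate_id = integer(),
                      sequence = character(), protein_id = character(),
                      glyco_site = integer(), glycan = character(),
                      charge = integer(), score = numeric(),
                      matched_ions = integer(), precursor_ppm_error = numeric(),
                      is_decoy = logical(), rank = integer(),
                      stringsAsFactors = FALSE)
  if (hi < lo) return(empty)
  ids <- index$ord[lo:hi]
  imax <- max(spectrum$intensity, 1e-12)
  rows <- lapply(ids, function(id) {
    rec <- index$records[[id]]
    ions <- .candidate_ions(index, id, z)
    mm <- .match_ions(ions$mz, spectrum$mz, spectrum$intensity,
                      config$fragment_tol_ppm)
    score <- sum(log1p(spectrum$intensity[mm$obs] / imax))
    gl <- rec$gp$glycan
    data.frame(spectrum_id = spectrum$id, candidate_id = id,
               sequence = rec$gp$sequence, protein_id = rec$gp$protein_id,
               glyco_site = rec$gp$glyco_site,
               glycan = if (is.null(gl)) "" else
                 paste0("HexNAc", gl$counts[["HexNAc"]],
                        if (gl$counts[["dHex"]] > 0)
                          paste0("dHex", gl$counts[["dHex"]]) else ""),
               charge = z, score = score, matched_ions = nrow(mm),
               precursor_ppm_error = (neutral - index$mass[id]) /
                 index$mass[id] * 1e6,
               is_decoy = rec$is_decoy, stringsAsFactors = FALSE)
  })
  psms <- do.call(rbind, rows)
  o <- order(-psms$score, -psms$matched_ions, abs(psms$precursor_ppm_error),
             psms$sequence, psms$glycan)
  psms <- psms[o, , drop = FALSE]
  psms$rank <- seq_len(nrow(psms))
  rownames(psms) <- NULL
  psms
}

#' Search a set of spectra, keeping the best PSM per spectrum
#'
#' @param spectra List of spectrum records.
#' @param index A [build_candidate_index()].
#' @param config A [search_config()].
#' @return `data.frame` of best-per-spectrum PSMs (spectra with no candidate
#'   in the precursor window are reported unidentified, i.e. absent).
#' @export
search_spectra <- function(spectra, index, config = index$config) {
  best <- lapply(spectra, function(s) {
    psms <- match_spectrum(s, index, config)
    if (nrow(psms)) psms[1L, , drop = FALSE] else NULL
  })
  out <- do.call(rbind, best)
  if (is.null(out)) {
    out <- match_spectrum(list(id = "x", precursor_mz = 1, charge = 1L,
                               mz = numeric(), intensity = numeric()),
                          index, config)[0, ]
  }
  rownames(out) <- NULL
  out
}

#' Target-decoy FDR filtering
#'
#' Assigns each PSM the q-value `min` over score thresholds at or below its
#' score of `(#decoys + 1) / #targets`, and flags targets with
#' `q <= fdr_q` as accepted.
#'
#' @param psms Best-per-spectrum PSM `data.frame` containing both targets and
#'   decoys (columns `score`, `is_decoy`).
#' @param q q-value cutoff (default 0.01).
#' @return The PSM table sorted by decreasing score with `q_value` and
#'   `accepted` columns. With zero targets the accepted set is empty.
#' @export
fdr_filter <- function(psms, q = 0.01) {
  if (!nrow(psms)) {
    psms$q_value <- numeric(0); psms$accepted <- logical(0)
    return(psms)
  }
  o <- order(-psms$score, psms$sequence)
  psms <- psms[o, , drop = FALSE]
  cum_d <- cumsum(psms$is_decoy)
  cum_t <- cumsum(!psms$is_decoy)
  fdr <- (cum_d + 1) / pmax(cum_t, 1)
  psms$q_value <- rev(cummin(rev(fdr)))
  psms$accepted <- !psms$is_decoy & psms$q_value <= q
  if (!any(!psms$is_decoy)) psms$accepted <- rep(FALSE, nrow(psms))
  rownames(psms) <- NULL
  psms
}

#' Localize the core-fucosylation site of accepted PSMs
#'
#' A site is called localized only when (a) at least one matched
#' glycan-retaining backbone ion and (b) at least one matched glycan-lost
#' (starred) or non-covering backbone ion bracket the site, and (c) the
#' retained-ion constraints single out exactly one sequon position in the
#' peptide. Oxonium matches prove glycosylation but never position, and a
#' site is never called from precursor mass alone (guarding against N->D
#' deamidation confusion).
#'
#' @param psms PSM `data.frame` (rows with `glyco_site = NA` pass through
#'   unlocalized).
#' @param spectra List of spectrum records (source of the matched peaks).
#' @param index The [build_candidate_index()] used for the search.
#' @param config A [search_config()].
#' @return `psms` with added columns `site_localized`, `localized_site`
#'   (protein coordinate) and `localization_evidence` (comma-separated ion
#'   labels).
#' @export
localize_sites <- function(psms, spectra, index, config = index$config) {
  by_id <- setNames(spectra, vapply(spectra, `[[`, "", "id"))
  psms$site_localized <- rep(FALSE, nrow(psms))
  psms$localized_site <- rep(NA_integer_, nrow(psms))
  psms$localization_evidence <- rep("", nrow(psms))
  for (r in seq_len(nrow(psms))) {
    if (is.na(psms$glyco_site[r]) || psms$glycan[r] == "") next
    rec <- index$records[[psms$candidate_id[r]]]
    sp <- by_id[[psms$spectrum_id[r]]]
    if (is.null(sp)) next
    ions <- .candidate_ions(index, psms$candidate_id[r], psms$charge[r])
    mm <- .match_ions(ions$mz, sp$mz, sp$intensity, config$fragment_tol_ppm)
    hit <- ions[mm$theo, , drop = FALSE]
    backbone <- hit[hit$series %in% c("b", "y"), , drop = FALSE]
    retained <- backbone[backbone$glycan_retained, , drop = FALSE]
    lost_or_plain <- backbone[!backbone$glycan_retained, , drop = FALSE]
    if (!nrow(retained) || !nrow(lost_or_plain)) next
    n <- nchar(rec$gp$sequence)
    hyp <- rec$pep_sequons
    consistent <- vapply(hyp, function(s) {
      b <- retained[retained$series == "b", "index"]
      y <- retained[retained$series == "y", "index"]
      all(s <= b) && all(s >= n - y + 1L)
    }, logical(1))
    S <- hyp[consistent]
    if (length(S) == 1L) {
      psms$site_localized[r] <- TRUE
      psms$localized_site[r] <- rec$gp$start + S - 1L
      ev <- unique(c(retained$label, lost_or_plain$label))
      psms$localization_evidence[r] <- paste(ev, collapse = ",")
    }
  }
  psms
}
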