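#' Default TMT channel design
#'
#' Maps the four active TMT6 channels to (condition, replicate): 128 and 129
#' carry the two control (siCon) replicates, 130 and 131 the two knockdown
#' (siFut8) replicates. The assignment is configuration, not a constant.
#'
#' @return `data.frame` with columns `channel`, `condition`, `replicate`.
#' @export
default_channel_map <- function() {
  data.frame(channel = c("128", "129", "130", "131"),
             condition = c("siCon", "siCon", "siFut8", "siFut8"),
             replicate = c(1L, 2L, 1L, 2L), stringsAsFactors = FALSE)
}

.validate_channel_map <- function(channel_map) {
  stopifnot(all(c("channel", "condition", "replicate") %in% names(channel_map)),
            nrow(channel_map) == 4L,
            all(channel_map$condition %in% c("siCon", "siFut8")),
            all(channel_map$replicate %in% c(1L, 2L)))
  invisible(channel_map)
}

#' Study design for the synthetic knockdown experiment
#'
#' Describes the simulated experiment: two conditions (siCon, siFut8) times
#' two biological replicates on four TMT6 channels, a glycoproteome in which
#' sequon sites carry Endo F3 remnants, and a knockdown that suppresses
#' core-fucosylated forms to `knockdown_ratio` of control.
#'
#' @param channel_map See [default_channel_map()].
#' @param knockdown_ratio Expected siFut8/siCon abundance ratio of
#'   core-fucosylated forms (default 0.05).
#' @param n_proteins Number of simulated proteins.
#' @param sites_per_protein Sequon sites engineered into each protein.
#' @param frac_target Fraction of proteins that are true Fut8 targets
#'   (core-fucosylated, transcriptionally stable).
#' @param frac_transcript_shifted Fraction of proteins that are
#'   transcriptional decoys: their abundance drops by `knockdown_ratio` in
#'   siFut8 because their mRNA does, so they must be rejected by the
#'   transcript-stability criterion downstream.
#' @param background_peptides_per_protein Naked (non-glyco) peptides carried
#'   along per protein as quantification ballast.
#' @param seed Integer seed recorded in every derived output.
#' @return A `study_design` object (list).
#' @export
study_design <- function(channel_map = default_channel_map(),
                         knockdown_ratio = 0.05,
                         n_proteins = 12L,
                         sites_per_protein = 2L,
                         frac_target = 0.5,
                         frac_transcript_shifted = 0.25,
                         background_peptides_per_protein = 2L,
                         seed = 1L) {
  .validate_channel_map(channel_map)
  stopifnot(knockdown_ratio > 0, knockdown_ratio <= 1,
            n_proteins >= 1L, sites_per_protein >= 1L,
            frac_target >= 0, frac_transcript_shifted >= 0,
            frac_target + frac_transcript_shifted <= 1)
  structure(list(channel_map = channel_map,
                 knockdown_ratio = knockdown_ratio,
                 n_proteins = as.integer(n_proteins),
                 sites_per_protein = as.integer(sites_per_protein),
                 frac_target = frac_target,
                 frac_transcript_shifted = frac_transcript_shifted,
                 background_peptides_per_protein =
                   as.integer(background_peptides_per_protein),
                 seed = as.integer(seed)),
            class = "study_design")
}

#' Acquisition noise model for simulated spectra
#'
#' @param mz_jitter_ppm_sd Gaussian m/z jitter SD, in ppm (default 5).
#' @param reporter_cv Multiplicative coefficient of variation on reporter
#'   intensities (default 0.1).
#' @param fragment_cv Multiplicative CV on backbone/diagnostic fragment
#'   intensities (default 0.3).
#' @param n_noise_peaks Uniform random noise peaks added per spectrum.
#' @param noise_intensity_scale Mean intensity of noise peaks.
#' @param peak_dropout_prob Probability that a non-reporter true peak is
#'   dropped.
#' @return A `noise_model` object (list).
#' @export
noise_model <- function(mz_jitter_ppm_sd = 5, reporter_cv = 0.1,
                        fragment_cv = 0.3, n_noise_peaks = 20L,
                        noise_intensity_scale = 50,
                        peak_dropout_prob = 0.05) {
  vals <- c(mz_jitter_ppm_sd, reporter_cv, fragment_cv, n_noise_peaks,
            noise_intensity_scale, peak_dropout_prob)
  if (any(vals < 0)) stop("noise model parameters must be >= 0")
  structure(list(mz_jitter_ppm_sd = mz_jitter_ppm_sd,
                 reporter_cv = reporter_cv, fragment_cv = fragment_cv,
                 n_noise_peaks = as.integer(n_noise_peaks),
                 noise_intensity_scale = noise_intensity_scale,
                 peak_dropout_prob = peak_dropout_prob),
            class = "noise_model")
}

.aa_pool <- c("A", "S", "T", "V", "L", "I", "F", "Y", "W", "H", "D", "E",
              "G", "Q", "M", "C", "N")  # no K/R/P: cleavage controlled below

# one tryptic segment (ends in K or R); optionally with an internal sequon
.random_segment <- function(len, with_sequon = FALSE) {
  repeat {
    body <- sample(.aa_pool, len - 1L, replace = TRUE)
    if (with_sequon) {
      s <- sample(2:(len - 3L), 1L)
      body[s] <- "N"
      body[s + 1L] <- sample(setdiff(.aa_pool, c("N")), 1L)
      body[s + 2L] <- sample(c("S", "T"), 1L)
    }
    seg <- paste0(paste(body, collapse = ""), sample(c("K", "R"), 1L))
    # reject accidental extra sequons so ground truth stays unambiguous
    n_seq <- length(gregexpr("N(?=[^P][ST])", seg, perl = TRUE)[[1]] |>
                      (\(x) x[x > 0])())
    if ((with_sequon && n_seq == 1L) || (!with_sequon && n_seq == 0L)) {
      return(seg)
    }
  }
}

#' Generate a random synthetic proteome with engineered sequon sites
#'
#' Proteins are concatenations of tryptic segments (each ending in K/R), a
#' known number of which carry exactly one `N-X(!=P)-[S/T]` sequon, so the
#' fully cleaved digest recovers each glycosite in a peptide of tractable
#' length with an unambiguous site.
#'
#' @param n_proteins,sites_per_protein See [study_design()].
#' @param n_background_segments Sequon-free segments per protein.
#' @param segment_len_range Length range of each tryptic segment.
#' @param seed Integer seed.
#' @return [read_fasta()]-style `data.frame` (`id`, `description`,
#'   `sequence`).
#' @export
random_proteome <- function(n_proteins = 12L, sites_per_protein = 2L,
                            n_background_segments = 3L,
                            segment_len_range = c(8L, 14L), seed = 1L) {
  set.seed(seed)
  seen <- character()
  proteins <- lapply(seq_len(n_proteins), function(i) {
    segs <- character()
    n_seg <- sites_per_protein + n_background_segments
    glyco_idx <- sample(seq_len(n_seg), sites_per_protein)
    for (j in seq_len(n_seg)) {
      repeat {
        len <- sample(segment_len_range[1]:segment_len_range[2], 1L)
        seg <- .random_segment(len, with_sequon = j %in% glyco_idx)
        if (!(seg %in% seen)) break
      }
      seen <<- c(seen, seg)
      segs <- c(segs, seg)
    }
    data.frame(id = sprintf("PROT%03d", i),
               description = sprintf("PROT%03d synthetic protein GENE%03d", i, i),
               sequence = paste(segs, collapse = ""), stringsAsFactors = FALSE)
  })
  do.call(rbind, proteins)
}

.lognorm_factor <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate a ground-truth glycoproteome
#'
#' Emulates the wet-lab stages of the knockdown experiment: each protein is
#' assigned a class (`target`: core-fucosylated sites suppressed to
#' `knockdown_ratio` in the siFut8 channels with stable transcript;
#' `transcript_shifted`: the whole protein drops because its mRNA does;
#' `null`: non-fucosylated remnants, unchanged). Sequon sites receive Endo F3
#' remnant glycans; every peptide carries the fixed TMT and carbamidomethyl
#' modifications and true per-channel abundances. Fully reproducible from
#' `design$seed`.
#'
#' @param design A [study_design()].
#' @param proteome Optional [read_fasta()]-style data.frame; generated with
#'   [random_proteome()] when `NULL`.
#' @return A `ground_truth` object: list with `entries` (list of records,
#'   each holding a [glycopeptide()], its per-channel `abundance`, protein
#'   coordinates and class), `transcript_ratios` (`gene`, `ratio`),
#'   `proteome`, and `design`.
#' @export
simulate_ground_truth <- function(design, proteome = NULL) {
  stopifnot(inherits(design, "study_design"))
  set.seed(design$seed)
  if (is.null(proteome)) {
    proteome <- random_proteome(design$n_proteins, design$sites_per_protein,
                                seed = design$seed)
  }
  tab <- mass_table()
  mods <- default_modifications(tmt = TRUE)
  np <- nrow(proteome)
  n_target <- round(design$frac_target * np)
  n_shift <- round(design$frac_transcript_shifted * np)
  classes <- rep("null", np)
  if (n_target > 0) classes[seq_len(n_target)] <- "target"
  if (n_shift > 0) classes[n_target + seq_len(n_shift)] <- "transcript_shifted"
  classes <- sample(classes)  # class-to-protein assignment randomized
  genes <- sub("PROT", "GENE", proteome$id)

  cm <- design$channel_map
  entries <- list()
  any_sequon <- FALSE
  for (i in seq_len(np)) {
    prot <- proteome[i, ]
    sequons <- find_sequons(prot)
    digest <- tryptic_digest(prot, max_missed = 0L, min_len = 7L)
    if (nrow(sequons)) any_sequon <- TRUE
    cls <- classes[i]
    # glyco entries: the fully cleaved peptide containing each sequon
    for (s in seq_len(nrow(sequons))) {
      pos <- sequons$position[s]
      hit <- digest[digest$start <= pos & digest$end >= pos, , drop = FALSE]
      if (!nrow(hit)) next
      pep <- hit[1, ]
      site_pep <- pos - pep$start + 1L
      core_fuc <- cls %in% c("target", "transcript_shifted")
      gl <- glycan(HexNAc = 1L, dHex = if (core_fuc) 1L else 0L,
                   core_fucosylated = core_fuc)
      gp <- glycopeptide(pep$sequence, mods = .fixed_mod_table(pep$sequence, mods),
                         glyco_site = site_pep, glycan_comp = gl,
                         protein_id = prot$id, missed_cleavages = 0L,
                         start = pep$start)
      base <- rlnorm(1, meanlog = log(1e5), sdlog = 0.4)
      factor <- if ((cls == "target" && core_fuc) || cls == "transcript_shifted")
        design$knockdown_ratio else 1
      abund <- ifelse(cm$condition == "siFut8", base * factor, base)
      names(abund) <- cm$channel
      entries[[length(entries) + 1L]] <- list(
        glycopeptide = gp, abundance = abund, protein_id = prot$id,
        gene = genes[i], site = pos, class = cls, is_core_fuc = core_fuc)
    }
    # naked background peptides (reporter ballast)
    bg <- digest[!vapply(seq_len(nrow(digest)), function(r) {
      any(sequons$position >= digest$start[r] & sequons$position <= digest$end[r])
    }, logical(1)), , drop = FALSE]
    n_bg <- min(design$background_peptides_per_protein, nrow(bg))
    if (n_bg > 0) {
      bg <- bg[sample(seq_len(nrow(bg)), n_bg), , drop = FALSE]
      for (r in seq_len(nrow(bg))) {
        gp <- glycopeptide(bg$sequence[r],
                           mods = .fixed_mod_table(bg$sequence[r], mods),
                           protein_id = prot$id, missed_cleavages = 0L,
                           start = bg$start[r])
        base <- rlnorm(1, meanlog = log(1e5), sdlog = 0.4)
        factor <- if (cls == "transcript_shifted") design$knockdown_ratio else 1
        abund <- ifelse(cm$condition == "siFut8", base * factor, base)
        names(abund) <- cm$channel
        entries[[length(entries) + 1L]] <- list(
          glycopeptide = gp, abundance = abund, protein_id = prot$id,
          gene = genes[i], site = NA_integer_, class = cls,
          is_core_fuc = FALSE)
      }
    }
  }
  if (!any_sequon) stop("proteome contains no N-glycosylation sequon")
  transcript_ratios <- data.frame(
    gene = genes,
    ratio = ifelse(classes == "transcript_shifted",
                   design$knockdown_ratio * runif(np, 0.9, 1.1),
                   runif(np, 0.95, 1.05)),
    class = classes, stringsAsFactors = FALSE)
  structure(list(entries = entries, transcript_ratios = transcript_ratios,
                 proteome = proteome, design = design),
            class = "ground_truth")
}

# fixed-mod table for a sequence: TMT on N-term, TMT on each K, CAM on each C
.fixed_mod_table <- function(sequence, mods = default_modifications(tmt = TRUE)) {
  res <- strsplit(sequence, "", fixed = TRUE)[[1]]
  rows <- list()
  if (!is.null(mods$tmt6_nterm)) {
    rows[[1L]] <- data.frame(position = 0L, name = "tmt6_nterm",
                             delta_mass = mods$tmt6_nterm$delta_mass)
  }
  for (p in which(res == "K")) {
    if (!is.null(mods$tmt6_k)) {
      rows[[length(rows) + 1L]] <- data.frame(position = p, name = "tmt6_k",
                                              delta_mass = mods$tmt6_k$delta_mass)
    }
  }
  for (p in which(res == "C")) {
    rows[[length(rows) + 1L]] <- data.frame(
      position = p, name = "carbamidomethyl",
      delta_mass = mods$carbamidomethyl$delta_mass)
  }
  if (!length(rows)) {
    return(data.frame(position = integer(), name = character(),
                      delta_mass = numeric()))
  }
  do.call(rbind, rows)
}

#' Simulate MS/MS spectra from a ground truth
#'
#' One centroided MS/MS spectrum is produced per ground-truth entry per
#' charge state: theoretical fragment m/z values jittered by
#' N(0, `mz_jitter_ppm_sd`) ppm, fragment intensities with multiplicative CV,
#' reporter-region intensities carrying the true channel abundances (times
#' `reporter_cv` noise), plus uniform random noise peaks and optional peak
#' dropout. Retention time is a linear proxy of mass. Optionally a number of
#' pure-noise spectra with in-range precursors are appended.
#'
#' @param truth A [simulate_ground_truth()] object.
#' @param noise A [noise_model()].
#' @param seed Integer seed (defaults to the design seed).
#' @param charges Precursor charge states to emit per entry.
#' @param n_noise_spectra Pure random-peak spectra to append.
#' @return List with `spectra` (list of spectrum records: `id`,
#'   `precursor_mz`, `charge`, `rt`, `mz`, `intensity`) and `sidecar`
#'   (`data.frame` linking spectrum id to the true identity; noise spectra
#'   have `NA` identities).
#' @export
simulate_spectra <- function(truth, noise = noise_model(),
                             seed = truth$design$seed, charges = 2L,
                             n_noise_spectra = 0L) {
  stopifnot(inherits(truth, "ground_truth"), inherits(noise, "noise_model"))
  if (!length(truth$entries)) stop("ground truth is empty")
  set.seed(seed)
  tab <- mass_table()
  channels <- truth$design$channel_map$channel
  rep_mz <- tmt6_reporters(channels)
  spectra <- list()
  side <- list()
  k <- 0L
  for (e in truth$entries) {
    ts_cache <- NULL
    for (z in charges) {
      k <- k + 1L
      id <- sprintf("scan=%05d", k)
      ts <- theoretical_spectrum(e$glycopeptide, precursor_charge = z,
                                 channels = channels, table = tab)
      ions <- ts$ions
      is_rep <- ions$series == "reporter"
      mz_obs <- ions$mz * (1 + rnorm(nrow(ions), 0, noise$mz_jitter_ppm_sd) * 1e-6)
      int_obs <- numeric(nrow(ions))
      int_obs[!is_rep] <- 1000 * .lognorm_factor(sum(!is_rep), noise$fragment_cv)
      if (any(is_rep)) {
        ch <- sub("^TMT", "", ions$label[is_rep])
        int_obs[is_rep] <- e$abundance[ch] *
          .lognorm_factor(sum(is_rep), noise$reporter_cv)
      }
      keep <- is_rep | runif(nrow(ions)) >= noise$peak_dropout_prob
      mz_obs <- mz_obs[keep]; int_obs <- int_obs[keep]
      if (noise$n_noise_peaks > 0L) {
        nmz <- runif(noise$n_noise_peaks, 100, max(ts$precursor_mz * z, 500))
        nint <- noise$noise_intensity_scale * rexp(noise$n_noise_peaks)
        mz_obs <- c(mz_obs, nmz); int_obs <- c(int_obs, nint)
      }
      o <- order(mz_obs)
      prec <- ts$precursor_mz * (1 + rnorm(1, 0, noise$mz_jitter_ppm_sd) * 1e-6)
      M <- peptide_mass(e$glycopeptide, tab)
      spectra[[k]] <- list(id = id, precursor_mz = prec, charge = z,
                           rt = 0.3 * M + rnorm(1, 0, 5),
                           mz = mz_obs[o], intensity = int_obs[o])
      gl <- e$glycopeptide$glycan
      side[[k]] <- data.frame(
        spectrum_id = id, protein_id = e$protein_id, gene = e$gene,
        sequence = e$glycopeptide$sequence,
        glyco_site = e$glycopeptide$glyco_site, site = e$site,
        glycan = if (is.null(gl)) "" else
          paste0("HexNAc", gl$counts[["HexNAc"]],
                 if (gl$counts[["dHex"]] > 0) paste0("dHex", gl$counts[["dHex"]]) else ""),
        charge = z, is_core_fuc = e$is_core_fuc, class = e$class,
        stringsAsFactors = FALSE)
    }
  }
  masses <- vapply(truth$entries, function(e) peptide_mass(e$glycopeptide, tab),
                   numeric(1))
  for (j in seq_len(n_noise_spectra)) {
    k <- k + 1L
    id <- sprintf("scan=%05d", k)
    z <- sample(charges, 1L)
    M <- runif(1, min(masses), max(masses))
    npk <- max(noise$n_noise_peaks, 50L)
    nmz <- sort(runif(npk, 100, mz(M, z, tab) * z))
    spectra[[k]] <- list(id = id, precursor_mz = mz(M, z, tab), charge = z,
                         rt = 0.3 * M + rnorm(1, 0, 5), mz = nmz,
                         intensity = noise$noise_intensity_scale * rexp(npk))
    side[[k]] <- data.frame(spectrum_id = id, protein_id = NA_character_,
                            gene = NA_character_, sequence = NA_character_,
                            glyco_site = NA_integer_, site = NA_integer_,
                            glycan = NA_character_, charge = z,
                            is_core_fuc = FALSE, class = "noise",
                            stringsAsFactors = FALSE)
  }
  list(spectra = spectra, sidecar = do.call(rbind, side))
}

#' Write spectra to a Mascot generic format (MGF) file
#'
#' @param spectra List of spectrum records (see [simulate_spectra()]).
#' @param path Output path.
#' @return `path`, invisibly. Output is byte-stable for identical input.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (s in spectra) {
    writeLines(c("BEGIN IONS",
                 paste0("TITLE=", s$id),
                 sprintf("PEPMASS=%.6f", s$precursor_mz),
                 sprintf("CHARGE=%d+", s$charge),
                 sprintf("RTINSECONDS=%.3f", s$rt),
                 sprintf("%.6f %.4f", s$mz, s$intensity),
                 "END IONS"), con)
  }
  invisible(path)
}

#' Read a Mascot generic format (MGF) file
#'
#' @param path Path to an MGF file.
#' @return List of spectrum records (`id`, `precursor_mz`, `charge`, `rt`,
#'   `mz`, `intensity`).
#' @export
read_mgf <- function(path) {
  if (!file.exists(path)) stop(sprintf("MGF file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  begins <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(begins) != length(ends)) stop("malformed MGF: unbalanced BEGIN/END IONS")
  lapply(seq_along(begins), function(i) {
    block <- lines[(begins[i] + 1L):(ends[i] - 1L)]
    hdr <- grepl("=", block, fixed = TRUE)
    kv <- strsplit(block[hdr], "=", fixed = TRUE)
    keys <- vapply(kv, `[`, "", 1)
    vals <- vapply(kv, function(x) paste(x[-1], collapse = "="), "")
    peaks <- do.call(rbind, strsplit(trimws(block[!hdr]), "[[:space:]]+"))
    list(id = vals[keys == "TITLE"][1],
         precursor_mz = as.numeric(vals[keys == "PEPMASS"][1]),
         charge = as.integer(sub("\\+$", "", vals[keys == "CHARGE"][1])),
         rt = as.numeric(vals[keys == "RTINSECONDS"][1]),
         mz = if (is.null(peaks)) numeric() else as.numeric(peaks[, 1]),
         intensity = if (is.null(peaks)) numeric() else as.numeric(peaks[, 2]))
  })
}

#' Write the ground-truth sidecar table
#'
#' @param sim Output of [simulate_spectra()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_sidecar_tsv <- function(sim, path) {
  write.table(sim$sidecar, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Simulate an MS1 stick stream for XIC tests
#'
#' Each species elutes as a Gaussian profile of monoisotopic sticks at its
#' m/z, sampled on a regular scan grid. No isotope envelopes.
#'
#' @param species `data.frame` with columns `mz`, `rt_apex`, `intensity` and
#'   optionally `width` (Gaussian SD in seconds, default 5).
#' @param rt_range Length-2 numeric scan-time range (seconds).
#' @param dt Scan interval in seconds.
#' @return `data.frame` (`rt`, `mz`, `intensity`) sorted by `rt`.
#' @export
simulate_ms1_stream <- function(species, rt_range = c(0, 100), dt = 1) {
  if (!"width" %in% names(species)) species$width <- 5
  grid <- seq(rt_range[1], rt_range[2], by = dt)
  rows <- lapply(seq_len(nrow(species)), function(i) {
    y <- species$intensity[i] *
      exp(-(grid - species$rt_apex[i])^2 / (2 * species$width[i]^2))
    keep <- y > species$intensity[i] * 1e-4
    data.frame(rt = grid[keep], mz = species$mz[i], intensity = y[keep])
  })
  out <- do.call(rbind, rows)
  out[order(out$rt, out$mz), , drop = FALSE]
}
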