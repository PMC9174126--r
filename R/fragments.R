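#' TMT6-plex reporter ion m/z values
#'
#' @param channels Character vector of channel names (subset of
#'   `"126"`..`"131"`); defaults to the four channels of the two-condition,
#'   two-replicate design (128--131).
#' @return Named numeric vector of reporter m/z values.
#' @export
tmt6_reporters <- function(channels = c("128", "129", "130", "131")) {
  rep_mz <- mass_table()$tmt6_reporters
  bad <- setdiff(channels, names(rep_mz))
  if (length(bad)) stop("unknown TMT6 channel(s): ", paste(bad, collapse = ", "))
  rep_mz[channels]
}

.frag_label <- function(series, index, charge, star = FALSE, glyco = FALSE,
                        glycan_nominal = 0L) {
  lab <- paste0(series, index)
  if (glyco) lab <- paste0(lab, "+", glycan_nominal)
  if (star) lab <- paste0(lab, "*")
  if (charge > 1L) lab <- paste0(lab, "(", charge, "+)")
  lab
}

.ion_row <- function(series, index, charge, glycan_retained, neutral_loss,
                     mz, label) {
  data.frame(series = series, index = index, charge = charge,
             glycan_retained = glycan_retained, neutral_loss = neutral_loss,
             mz = mz, label = label, stringsAsFactors = FALSE)
}

#' Theoretical b/y fragment ladder
#'
#' Generates b1..b(n-1) and y1..y(n-1) ions at charges 1..`max_frag_charge`.
#' For ions spanning the glycosylation site, both the glycan-retained variant
#' and the glycan-lost variant are emitted; the lost variant is labelled with
#' `*` when the loss is the fucosylated GlcNAc remnant (dHex-HexNAc,
#' -349.1373 Da), the diagnostic signature of a core-fucosylated peptide.
#' N-terminal modifications travel with the b series.
#'
#' @param gp A [glycopeptide()] of length >= 2.
#' @param max_frag_charge Maximum fragment charge (default 2).
#' @param table Mass table.
#' @return `data.frame` of fragment ions with columns `series`, `index`,
#'   `charge`, `glycan_retained`, `neutral_loss`, `mz`, `label`.
#' @export
by_ladder <- function(gp, max_frag_charge = 2L, table = mass_table()) {
  stopifnot(inherits(gp, "glycopeptide"))
  res <- .valid_residues(gp$sequence, table)
  n <- length(res)
  if (n < 2L) stop("peptide must have length >= 2 to fragment")
  pos_delta <- numeric(n)
  nterm_delta <- 0
  if (nrow(gp$mods)) {
    for (r in seq_len(nrow(gp$mods))) {
      p <- gp$mods$position[r]
      if (p == 0L) nterm_delta <- nterm_delta + gp$mods$delta_mass[r]
      else pos_delta[p] <- pos_delta[p] + gp$mods$delta_mass[r]
    }
  }
  unit <- table$residues[res] + pos_delta
  prefix <- cumsum(unit)                       # residues+mods 1..i
  total <- prefix[n]
  gmass <- glycan_mass(gp$glycan, table)
  has_glycan <- !is.null(gp$glycan) && gmass > 0
  is_fuc_remnant <- has_glycan &&
    gp$glycan$counts[["HexNAc"]] == 1L && gp$glycan$counts[["dHex"]] == 1L &&
    sum(gp$glycan$counts) == 2L
  gnom <- round(gmass)
  proton <- table$proton
  rows <- vector("list", 4L * (n - 1L) * max_frag_charge)
  k <- 0L
  for (i in seq_len(n - 1L)) {
    b_neutral <- prefix[i] + nterm_delta
    y_neutral <- total - prefix[n - i] + table$water
    b_cov <- has_glycan && !is.na(gp$glyco_site) && gp$glyco_site <= i
    y_cov <- has_glycan && !is.na(gp$glyco_site) && gp$glyco_site >= n - i + 1L
    for (z in seq_len(max_frag_charge)) {
      if (b_cov) {
        k <- k + 1L
        rows[[k]] <- .ion_row("b", i, z, TRUE, 0,
                              (b_neutral + gmass + z * proton) / z,
                              .frag_label("b", i, z, glyco = TRUE,
                                          glycan_nominal = gnom))
        k <- k + 1L
        rows[[k]] <- .ion_row("b", i, z, FALSE, gmass,
                              (b_neutral + z * proton) / z,
                              .frag_label("b", i, z, star = is_fuc_remnant))
      } else {
        k <- k + 1L
        rows[[k]] <- .ion_row("b", i, z, FALSE, 0,
                              (b_neutral + z * proton) / z,
                              .frag_label("b", i, z))
      }
      if (y_cov) {
        k <- k + 1L
        rows[[k]] <- .ion_row("y", i, z, TRUE, 0,
                              (y_neutral + gmass + z * proton) / z,
                              .frag_label("y", i, z, glyco = TRUE,
                                          glycan_nominal = gnom))
        k <- k + 1L
        rows[[k]] <- .ion_row("y", i, z, FALSE, gmass,
                              (y_neutral + z * proton) / z,
                              .frag_label("y", i, z, star = is_fuc_remnant))
      } else {
        k <- k + 1L
        rows[[k]] <- .ion_row("y", i, z, FALSE, 0,
                              (y_neutral + z * proton) / z,
                              .frag_label("y", i, z))
      }
    }
  }
  do.call(rbind, rows[seq_len(k)])
}

#' Signature precursor-loss, oxonium and reporter ions
#'
#' For a core-fucosylated Endo F3 remnant glycopeptide, emits the precursor
#' signature-loss ions `[M-146]` (loss of fucose; the GlcNAc stays on the
#' peptide) and `[M-349]` (loss of the whole fucosylated GlcNAc) at the
#' precursor charge and at 1+. Any remnant-bearing glycopeptide additionally
#' yields the GlcNAc oxonium triplet (204.0867, 168.0655, 138.0550). TMT
#' reporter ions are emitted whenever the peptide carries a TMT label.
#'
#' @param gp A [glycopeptide()].
#' @param precursor_charge Precursor charge state.
#' @param channels Active TMT reporter channels (see [tmt6_reporters()]).
#' @param table Mass table.
#' @return Fragment-ion `data.frame` (see [by_ladder()]). If `gp` has no
#'   glycan, only reporter ions are returned and a warning is raised.
#' @export
signature_ions <- function(gp, precursor_charge = 2L,
                           channels = c("128", "129", "130", "131"),
                           table = mass_table()) {
  stopifnot(inherits(gp, "glycopeptide"))
  rows <- list()
  gmass <- glycan_mass(gp$glycan, table)
  has_glycan <- !is.null(gp$glycan) && gmass > 0
  proton <- table$proton
  if (has_glycan) {
    if (gp$glycan$counts[["dHex"]] >= 1L) {
      M <- peptide_mass(gp, table)
      fuc <- table$monosaccharides[["dHex"]]
      fucglcnac <- fuc + table$monosaccharides[["HexNAc"]]
      for (z in unique(c(precursor_charge, 1L))) {
        rows[[length(rows) + 1L]] <- .ion_row(
          "precursor_loss", NA_integer_, z, TRUE, fuc,
          (M - fuc + z * proton) / z,
          paste0("[M-146]", if (z > 1L) paste0("(", z, "+)") else ""))
        rows[[length(rows) + 1L]] <- .ion_row(
          "precursor_loss", NA_integer_, z, FALSE, fucglcnac,
          (M - fucglcnac + z * proton) / z,
          paste0("[M-349]", if (z > 1L) paste0("(", z, "+)") else ""))
      }
    }
    oxo <- table$oxonium
    for (i in seq_along(oxo)) {
      rows[[length(rows) + 1L]] <- .ion_row(
        "oxonium", NA_integer_, 1L, FALSE, 0, oxo[[i]],
        paste0("[", names(oxo)[i], "]+"))
    }
  } else {
    warning("glycopeptide carries no glycan: only reporter ions emitted")
  }
  has_tmt <- nrow(gp$mods) > 0 && any(grepl("^tmt", gp$mods$name))
  if (has_tmt && length(channels)) {
    rep_mz <- tmt6_reporters(channels)
    for (i in seq_along(rep_mz)) {
      rows[[length(rows) + 1L]] <- .ion_row(
        "reporter", NA_integer_, 1L, FALSE, 0, rep_mz[[i]],
        paste0("TMT", names(rep_mz)[i]))
    }
  }
  if (!length(rows)) {
    return(.ion_row(character(), integer(), integer(), logical(), numeric(),
                    numeric(), character())[0, ])
  }
  do.call(rbind, rows)
}

#' Full theoretical spectrum of a glycopeptide
#'
#' Union of the b/y ladder ([by_ladder()]) and the signature/diagnostic ions
#' ([signature_ions()]), de-duplicated on (series, index, charge,
#' glycan_retained, neutral_loss) and sorted by m/z. A pure function:
#' identical inputs give identical output.
#'
#' @param gp A [glycopeptide()].
#' @param precursor_charge Precursor charge state.
#' @param max_frag_charge Maximum backbone fragment charge; defaults to
#'   `min(precursor_charge, 2)`.
#' @param channels Active TMT reporter channels.
#' @param table Mass table.
#' @return A `theoretical_spectrum` object: list with `glycopeptide`,
#'   `precursor_mz`, `precursor_charge` and the ion `data.frame` `ions`.
#' @export
theoretical_spectrum <- function(gp, precursor_charge = 2L,
                                 max_frag_charge = min(precursor_charge, 2L),
                                 channels = c("128", "129", "130", "131"),
                                 table = mass_table()) {
  ions <- by_ladder(gp, max_frag_charge, table)
  sig <- suppressWarnings(
    signature_ions(gp, precursor_charge, channels, table))
  ions <- rbind(ions, sig)
  key <- paste(ions$series, ions$index, ions$charge, ions$glycan_retained,
               round(ions$neutral_loss, 4), ions$label)
  ions <- ions[!duplicated(key), , drop = FALSE]
  ions <- ions[order(ions$mz), , drop = FALSE]
  rownames(ions) <- NULL
  M <- peptide_mass(gp, table)
  structure(list(glycopeptide = gp,
                 precursor_mz = mz(M, precursor_charge, table),
                 precursor_charge = as.integer(precursor_charge),
                 ions = ions),
            class = "theoretical_spectrum")
}

#' @export
print.theoretical_spectrum <- function(x, ...) {
  cat(sprintf("<theoretical_spectrum> %s, precursor %.4f (%d+), %d ions\n",
              x$glycopeptide$sequence, x$precursor_mz, x$precursor_charge,
              nrow(x$ions)))
  invisible(x)
}

#' Export an annotated theoretical spectrum
#'
#' @param ts A [theoretical_spectrum()].
#' @param tsv_path,json_path Output paths (either may be `NULL`).
#' @return Invisibly, the ion table.
#' @export
export_annotated_spectrum <- function(ts, tsv_path = NULL, json_path = NULL) {
  stopifnot(inherits(ts, "theoretical_spectrum"))
  tab <- ts$ions[, c("label", "series", "charge", "mz")]
  if (!is.null(tsv_path)) {
    write.table(tab, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(peptide = ts$glycopeptide$sequence,
           precursor_mz = ts$precursor_mz,
           precursor_charge = ts$precursor_charge,
           ions = ts$ions),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(tab)
}
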