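#' Read a protein FASTA file
#'
#' Wraps [Biostrings::readAAStringSet()] and enforces the package's residue
#' policy: sequences are upper-cased and must use the canonical 20-letter
#' alphabet. Ambiguity codes (B, Z, X), selenocysteine (U) and `*` are
#' rejected rather than guessed.
#'
#' @param path Path to a FASTA file.
#' @return `data.frame` with columns `id` (first token of the header),
#'   `description` (full header) and `sequence`, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("FASTA file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (!length(nonblank)) stop(sprintf("empty FASTA file: %s", path))
  if (!startsWith(trimws(lines[nonblank[1]]), ">")) {
    stop(sprintf("malformed FASTA: line %d does not start a record header",
                 nonblank[1]))
  }
  aas <- Biostrings::readAAStringSet(path)
  if (!length(aas)) stop(sprintf("no records in FASTA file: %s", path))
  seqs <- toupper(gsub("[[:space:]]", "", as.character(aas)))
  headers <- names(aas)
  ids <- vapply(strsplit(headers, "[[:space:]]+"), `[`, "", 1)
  ok <- names(mass_table()$residues)
  for (i in seq_along(seqs)) {
    if (!nzchar(seqs[i])) stop(sprintf("record '%s' has an empty sequence", ids[i]))
    res <- strsplit(seqs[i], "")[[1]]
    bad <- which(!(res %in% ok))
    if (length(bad)) {
      stop(sprintf("record '%s': non-canonical residue '%s' at position %d",
                   ids[i], res[bad[1]], bad[1]))
    }
  }
  data.frame(id = ids, description = headers, sequence = seqs,
             stringsAsFactors = FALSE)
}

#' Write protein records to FASTA
#'
#' @param proteins `data.frame` with `id`, `sequence` and optionally
#'   `description` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path) {
  hdr <- if ("description" %in% names(proteins) &&
             any(nzchar(proteins$description))) proteins$description else proteins$id
  out <- character(2L * nrow(proteins))
  out[c(TRUE, FALSE)] <- paste0(">", hdr)
  out[c(FALSE, TRUE)] <- proteins$sequence
  writeLines(out, path)
  invisible(path)
}

# cleavage sites: C-terminal to K/R, not before P; returns end positions of
# the fully cleaved fragments (last fragment ends at nchar)
.tryptic_sites <- function(sequence) {
  res <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(res)
  cut <- which(res %in% c("K", "R"))
  cut <- cut[cut < n & res[pmin(cut + 1L, n)] != "P"]
  c(cut, n)
}

#' In-silico tryptic digestion
#'
#' Cleaves C-terminal to K/R except when the next residue is proline, and
#' enumerates all peptides with 0..`max_missed` internal missed cleavage
#' sites and length >= `min_len`.
#'
#' @param protein One row of a [read_fasta()] data.frame (or any list with
#'   `id` and `sequence`).
#' @param max_missed Maximum internal missed cleavages (default 2).
#' @param min_len Minimum peptide length in residues (default 7).
#' @param clip_nterm_met If `TRUE`, also digest the proteoform with the
#'   initiator methionine removed (off by default).
#' @return `data.frame` with columns `protein_id`, `start`, `end`,
#'   `sequence`, `missed_cleavages` (1-based protein coordinates).
#' @export
tryptic_digest <- function(protein, max_missed = 2L, min_len = 7L,
                           clip_nterm_met = FALSE) {
  seqs <- list(list(seq = protein$sequence, offset = 0L))
  if (clip_nterm_met && startsWith(protein$sequence, "M")) {
    seqs <- c(seqs, list(list(seq = substring(protein$sequence, 2L), offset = 1L)))
  }
  out <- list()
  for (s in seqs) {
    ends <- .tryptic_sites(s$seq)
    starts <- c(1L, head(ends, -1L) + 1L)
    nfrag <- length(ends)
    for (i in seq_len(nfrag)) {
      for (k in 0:max_missed) {
        j <- i + k
        if (j > nfrag) break
        a <- starts[i]; b <- ends[j]
        if (b - a + 1L < min_len) next
        out[[length(out) + 1L]] <- data.frame(
          protein_id = protein$id,
          start = a + s$offset, end = b + s$offset,
          sequence = substring(s$seq, a, b),
          missed_cleavages = k, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(protein_id = character(), start = integer(),
                      end = integer(), sequence = character(),
                      missed_cleavages = integer(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  unique(res)
}

#' Scan a protein for N-glycosylation sequons
#'
#' Reports every `N-X-[S/T]` motif with X != P (the canonical N-glycosylation
#' sequon). This is a plain motif scan, not a glycosylation-propensity
#' predictor.
#'
#' @param protein One row of a [read_fasta()] data.frame.
#' @return `data.frame` with columns `protein_id`, `position` (1-based index
#'   of the N) and `motif` (the 3-residue context).
#' @export
find_sequons <- function(protein) {
  m <- gregexpr("N(?=[^P][ST])", protein$sequence, perl = TRUE)[[1]]
  pos <- as.integer(m[m > 0])
  motif <- if (length(pos)) substring(protein$sequence, pos, pos + 2L)
           else character()
  data.frame(protein_id = rep(protein$id, length(pos)), position = pos,
             motif = motif, stringsAsFactors = FALSE)
}

#' Digest a whole proteome
#'
#' @param proteins [read_fasta()] data.frame.
#' @inheritParams tryptic_digest
#' @return Row-bound [tryptic_digest()] table over all proteins.
#' @export
digest_proteome <- function(proteins, max_missed = 2L, min_len = 7L,
                            clip_nterm_met = FALSE) {
  do.call(rbind, lapply(seq_len(nrow(proteins)), function(i) {
    tryptic_digest(proteins[i, ], max_missed, min_len, clip_nterm_met)
  }))
}

#' Write a digest table to TSV
#'
#' @param digest Output of [tryptic_digest()] / [digest_proteome()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_digest_tsv <- function(digest, path) {
  write.table(digest, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
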