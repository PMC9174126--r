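#' Ranking thresholds for candidate Fut8 targets
#'
#' The study states its three criteria qualitatively (a low knockdown/control
#' TMT ratio, an unchanged transcript, and spectral evidence for the
#' core-fucosylated glycopeptide); the numeric defaults here are the
#' package's own: a maximum TMT ratio of 0.40 and a transcript-stability
#' band of `[0.77, 1.30]`, both chosen to cover the published example rows,
#' and at least one localized PSM.
#'
#' @param max_tmt_ratio Maximum siFut8/siCon TMT ratio (both replicates).
#' @param transcript_ratio_band Length-2 inclusive band around 1 within
#'   which a transcript counts as unchanged.
#' @param min_localized_psms Minimum number of site-localized PSMs.
#' @return A `ranking_thresholds` object (list).
#' @export
ranking_thresholds <- function(max_tmt_ratio = 0.40,
                               transcript_ratio_band = c(0.77, 1.30),
                               min_localized_psms = 1L) {
  stopifnot(max_tmt_ratio > 0, max_tmt_ratio < 1,
            length(transcript_ratio_band) == 2L,
            transcript_ratio_band[1] <= 1, transcript_ratio_band[2] >= 1,
            min_localized_psms >= 0L)
  structure(list(max_tmt_ratio = max_tmt_ratio,
                 transcript_ratio_band = transcript_ratio_band,
                 min_localized_psms = as.integer(min_localized_psms)),
            class = "ranking_thresholds")
}

#' Rank candidate Fut8 target proteins
#'
#' Aggregates site-level TMT quantification per protein (most-affected-site
#' logic: the minimum site ratio per replicate), applies the three candidate
#' criteria -- (i) both replicate TMT ratios at or below `max_tmt_ratio`,
#' (ii) transcript ratio inside the stability band, (iii) at least
#' `min_localized_psms` site-localized PSMs -- and ranks the passing proteins
#' by increasing TMT ratio (deterministic tie-break by protein id).
#'
#' @param quant Site-level quantification `data.frame` (see
#'   [quantify_reporters()]): columns `protein_id`, `site`, `ratio_rep1`,
#'   `ratio_rep2`, `n_psms`; `n_localized` is used when present, otherwise
#'   `n_psms`.
#' @param transcripts Optional `data.frame` with columns `gene`, `ratio`
#'   (siFut8/siCon mRNA).
#' @param thresholds A [ranking_thresholds()].
#' @param gene_map Optional `data.frame` (`protein_id`, `gene`); by default
#'   the protein id doubles as the gene symbol.
#' @param missing_transcript `"fail"` (default, conservative) or `"pass"`:
#'   how to score criterion (ii) for proteins absent from `transcripts`.
#' @param key Ranking key across the two replicate ratios: `"min"` (default)
#'   or `"max"`, ascending.
#' @param site_aggregate Protein-level site aggregation: `"min"` (default,
#'   most affected site) or `"mean"`.
#' @return `data.frame` of candidate records: per-protein ratios, transcript
#'   ratio, spectral evidence, per-criterion pass flags, `passes_all` and
#'   `rank` (NA for failing proteins); passing rows first, in rank order.
#' @export
rank_candidates <- function(quant, transcripts = NULL,
                            thresholds = ranking_thresholds(),
                            gene_map = NULL,
                            missing_transcript = c("fail", "pass"),
                            key = c("min", "max"),
                            site_aggregate = c("min", "mean")) {
  missing_transcript <- match.arg(missing_transcript)
  key <- match.arg(key)
  site_aggregate <- match.arg(site_aggregate)
  if (!nrow(quant)) {
    return(data.frame(protein_id = character(), gene = character(),
                      sites = character(), tmt_ratio_1 = numeric(),
                      tmt_ratio_2 = numeric(), transcript_ratio = numeric(),
                      spectral_evidence = integer(), pass_tmt = logical(),
                      pass_transcript = logical(), pass_spectra = logical(),
                      passes_all = logical(), rank = integer(),
                      stringsAsFactors = FALSE))
  }
  if (!"n_localized" %in% names(quant)) quant$n_localized <- quant$n_psms
  agg <- switch(site_aggregate, min = function(x) min(x, na.rm = TRUE),
                mean = function(x) mean(x, na.rm = TRUE))
  rows <- lapply(split(quant, quant$protein_id), function(q) {
    data.frame(protein_id = q$protein_id[1],
               sites = paste(sort(q$site), collapse = ","),
               tmt_ratio_1 = agg(q$ratio_rep1), tmt_ratio_2 = agg(q$ratio_rep2),
               spectral_evidence = sum(q$n_localized),
               stringsAsFactors = FALSE)
  })
  cand <- do.call(rbind, rows)
  cand$gene <- if (!is.null(gene_map)) {
    gene_map$gene[match(cand$protein_id, gene_map$protein_id)]
  } else cand$protein_id
  cand$transcript_ratio <- if (!is.null(transcripts)) {
    transcripts$ratio[match(cand$gene, transcripts$gene)]
  } else NA_real_
  band <- thresholds$transcript_ratio_band
  cand$pass_tmt <- !is.na(cand$tmt_ratio_1) & !is.na(cand$tmt_ratio_2) &
    cand$tmt_ratio_1 <= thresholds$max_tmt_ratio &
    cand$tmt_ratio_2 <= thresholds$max_tmt_ratio
  cand$pass_transcript <- ifelse(
    is.na(cand$transcript_ratio),
    missing_transcript == "pass",
    cand$transcript_ratio >= band[1] & cand$transcript_ratio <= band[2])
  cand$pass_spectra <- cand$spectral_evidence >= thresholds$min_localized_psms
  cand$passes_all <- cand$pass_tmt & cand$pass_transcript & cand$pass_spectra
  keyfun <- switch(key, min = pmin, max = pmax)
  cand$rank_key <- keyfun(cand$tmt_ratio_1, cand$tmt_ratio_2)
  o <- order(!cand$passes_all, cand$rank_key, cand$protein_id)
  cand <- cand[o, , drop = FALSE]
  cand$rank <- NA_integer_
  cand$rank[cand$passes_all] <- seq_len(sum(cand$passes_all))
  rownames(cand) <- NULL
  cand[, c("protein_id", "gene", "sites", "tmt_ratio_1", "tmt_ratio_2",
           "transcript_ratio", "spectral_evidence", "pass_tmt",
           "pass_transcript", "pass_spectra", "passes_all", "rank")]
}

# tiny deterministic polynomial hash for run metadata (no binary deps)
.cfg_hash <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "|"))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Write the candidate report bundle
#'
#' Writes the ranked candidate table as TSV plus a run-metadata JSON (tool
#' version, seed, thresholds, config hash). Deterministic: repeated runs on
#' identical input produce byte-identical files.
#'
#' @param candidates Output of [rank_candidates()].
#' @param out_dir Output directory (created if needed).
#' @param thresholds The [ranking_thresholds()] used.
#' @param seed Seed recorded in the metadata.
#' @return Named character vector of written paths, invisibly.
#' @export
write_report <- function(candidates, out_dir, thresholds = ranking_thresholds(),
                         seed = NA_integer_) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop(sprintf("cannot create output directory: %s", out_dir))
  }
  tsv <- file.path(out_dir, "candidates.tsv")
  meta <- file.path(out_dir, "run_metadata.json")
  write.table(candidates, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- list(tool = "corefucq",
              version = as.character(packageVersion("corefucq")),
              seed = seed,
              thresholds = list(
                max_tmt_ratio = thresholds$max_tmt_ratio,
                transcript_ratio_band = thresholds$transcript_ratio_band,
                min_localized_psms = thresholds$min_localized_psms))
  cfg$config_hash <- .cfg_hash(unlist(cfg))
  jsonlite::write_json(cfg, meta, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(candidates = tsv, metadata = meta))
}
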