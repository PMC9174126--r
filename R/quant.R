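#' TMT reporter quantification of localized glycosites
#'
#' Extracts the reporter-region intensities of every PSM's spectrum (nearest
#' peak within `reporter_tol` m/z of each active channel), optionally applies
#' median normalization per channel across all quantified spectra, and
#' aggregates glyco PSMs per (protein, site) by summation. Replicate ratios
#' are siFut8/siCon under the channel map.
#'
#' @param psms PSM `data.frame` with columns `spectrum_id`, `protein_id` and
#'   the protein-coordinate glycosite in `localized_site` (or `site`); naked
#'   peptides (`NA` site) contribute to normalization but are not reported.
#' @param spectra List of spectrum records.
#' @param channel_map See [default_channel_map()].
#' @param reporter_tol Absolute m/z tolerance for reporter peaks
#'   (default 0.003).
#' @param normalize Apply per-channel median normalization (default `TRUE`).
#'   The result is then invariant to a global per-channel intensity scale.
#' @return `data.frame` with one row per (protein, site): per-channel summed
#'   intensities, `ratio_rep1`, `ratio_rep2`, `n_psms`, `n_localized`.
#'   Ratios are `NA` when a needed channel was never observed.
#' @export
quantify_reporters <- function(psms, spectra, channel_map = default_channel_map(),
                               reporter_tol = 0.003, normalize = TRUE) {
  .validate_channel_map(channel_map)
  site_col <- if ("localized_site" %in% names(psms)) "localized_site" else "site"
  by_id <- setNames(spectra, vapply(spectra, `[[`, "", "id"))
  rep_mz <- tmt6_reporters(channel_map$channel)
  n <- nrow(psms)
  I <- matrix(NA_real_, nrow = n, ncol = length(rep_mz),
              dimnames = list(NULL, names(rep_mz)))
  for (r in seq_len(n)) {
    sp <- by_id[[psms$spectrum_id[r]]]
    if (is.null(sp) || !length(sp$mz)) next
    for (c in seq_along(rep_mz)) {
      d <- abs(sp$mz - rep_mz[c])
      j <- which.min(d)
      if (d[j] <= reporter_tol) I[r, c] <- sp$intensity[j]
    }
  }
  if (normalize && n > 0) {
    med <- apply(I, 2, median, na.rm = TRUE)
    if (all(is.finite(med)) && all(med > 0)) {
      I <- sweep(I, 2, med, "/") * mean(med)
    }
  }
  glyco <- which(!is.na(psms[[site_col]]))
  if (!length(glyco)) {
    out <- data.frame(protein_id = character(), site = integer(),
                      stringsAsFactors = FALSE)
    for (ch in names(rep_mz)) out[[paste0("I_", ch)]] <- numeric(0)
    out$ratio_rep1 <- numeric(0); out$ratio_rep2 <- numeric(0)
    out$n_psms <- integer(0); out$n_localized <- integer(0)
    return(out)
  }
  key <- paste(psms$protein_id[glyco], psms[[site_col]][glyco], sep = "@")
  groups <- split(glyco, key)
  loc <- if ("site_localized" %in% names(psms)) psms$site_localized else
    rep(TRUE, n)
  ratio_of <- function(intens, repl) {
    chF <- channel_map$channel[channel_map$condition == "siFut8" &
                                 channel_map$replicate == repl]
    chC <- channel_map$channel[channel_map$condition == "siCon" &
                                 channel_map$replicate == repl]
    a <- intens[[chF]]; b <- intens[[chC]]
    if (is.na(a) || is.na(b) || b <= 0) NA_real_ else a / b
  }
  rows <- lapply(names(groups), function(k) {
    idx <- groups[[k]]
    sums <- colSums(I[idx, , drop = FALSE], na.rm = TRUE)
    sums[colSums(!is.na(I[idx, , drop = FALSE])) == 0] <- NA_real_
    intens <- as.list(sums)
    out <- data.frame(protein_id = psms$protein_id[idx[1]],
                      site = psms[[site_col]][idx[1]],
                      stringsAsFactors = FALSE)
    for (ch in names(rep_mz)) out[[paste0("I_", ch)]] <- sums[[ch]]
    out$ratio_rep1 <- ratio_of(intens, 1L)
    out$ratio_rep2 <- ratio_of(intens, 2L)
    out$n_psms <- length(idx)
    out$n_localized <- sum(loc[idx])
    out
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$protein_id, out$site), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extracted ion chromatogram area
#'
#' Trapezoidal integral over retention time of the per-scan summed intensity
#' of MS1 peaks within `tol_ppm` of `target_mz`.
#'
#' @param ms1 `data.frame` with columns `rt`, `mz`, `intensity`, sorted by
#'   `rt` (see [simulate_ms1_stream()]).
#' @param target_mz Target monoisotopic m/z.
#' @param tol_ppm Mass tolerance in ppm (default 10).
#' @param rt_window Optional length-2 retention-time window.
#' @return Integrated area (0 for an empty window).
#' @export
xic_area <- function(ms1, target_mz, tol_ppm = 10, rt_window = NULL) {
  sel <- abs(ms1$mz - target_mz) / target_mz * 1e6 <= tol_ppm
  if (!is.null(rt_window)) {
    sel <- sel & ms1$rt >= rt_window[1] & ms1$rt <= rt_window[2]
  }
  hits <- ms1[sel, , drop = FALSE]
  if (nrow(hits) < 2L) return(0)
  y <- tapply(hits$intensity, hits$rt, sum)
  t <- as.numeric(names(y))
  o <- order(t)
  t <- t[o]; y <- as.numeric(y)[o]
  if (length(t) < 2L) return(0)
  sum(diff(t) * (head(y, -1) + tail(y, -1)) / 2)
}
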