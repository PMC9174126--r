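# Independent brute-force oracles used to freeze expected values.
# These deliberately avoid the package's own code paths.

# enumerate every (start, end) window satisfying the tryptic cleavage rules
brute_force_digest <- function(sequence, max_missed = 2L, min_len = 7L) {
  res <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(res)
  is_site <- function(i) i >= 1 && i < n && res[i] %in% c("K", "R") &&
    res[i + 1] != "P"
  out <- list()
  for (a in seq_len(n)) {
    if (!(a == 1L || is_site(a - 1L))) next
    for (b in a:n) {
      if (!(b == n || is_site(b))) next
      internal <- sum(vapply(seq(a, b)[-length(seq(a, b))], is_site, logical(1)))
      if (internal > max_missed || (b - a + 1L) < min_len) next
      out[[length(out) + 1L]] <- data.frame(
        start = a, end = b, sequence = paste(res[a:b], collapse = ""),
        missed_cleavages = internal, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(), end = integer(),
                      sequence = character(), missed_cleavages = integer()))
  }
  do.call(rbind, out)
}

# position-by-position sequon scan
brute_force_sequons <- function(sequence) {
  res <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(res)
  pos <- integer()
  for (i in seq_len(max(n - 2L, 0L))) {
    if (res[i] == "N" && res[i + 1] != "P" && res[i + 2] %in% c("S", "T")) {
      pos <- c(pos, i)
    }
  }
  pos
}

# q-values by explicit minimisation over all score thresholds
brute_force_qvalues <- function(score, is_decoy) {
  vapply(score, function(s) {
    ths <- sort(unique(score[score <= s]))
    min(vapply(ths, function(t) {
      (sum(is_decoy & score >= t) + 1) / max(sum(!is_decoy & score >= t), 1)
    }, numeric(1)))
  }, numeric(1))
}

# random peptide sequence from the canonical alphabet
random_peptide <- function(len, alphabet = names(mass_table()$residues)) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}
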