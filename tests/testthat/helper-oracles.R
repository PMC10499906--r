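# Shared helpers: random sequences, brute-force digestion oracle, tiny
# fixtures built in code.

random_sequence <- function(n) {
  paste(sample(AA_ALPHABET, n, replace = TRUE), collapse = "")
}

# Brute-force full-specificity digestion oracle: enumerate every window
# (site_i, site_j) over the predicted cut positions, count internal sites,
# and filter. Independent of the package's enumeration strategy.
brute_force_full_digest <- function(isoform, rules, max_missed,
                                    length_range = c(1, Inf)) {
  sites <- sort(unique(predict_all_sites(isoform, rules)$position))
  n <- nchar(isoform$sequence)
  bounds <- c(0, sites, n)
  out <- NULL
  for (i in seq_along(bounds)) {
    for (j in seq_along(bounds)) {
      if (bounds[j] <= bounds[i]) next
      s <- bounds[i] + 1; e <- bounds[j]
      internal <- sum(sites > bounds[i] & sites < e)
      len <- e - s + 1
      if (internal <= max_missed && len >= length_range[1] &&
          len <= length_range[2])
        out <- rbind(out, data.frame(start = s, end = e))
    }
  }
  out <- unique(out)
  out[order(out$start, out$end), , drop = FALSE]
}

# Naive all-substring mapping oracle
naive_map_oracle <- function(pep, seqstr) {
  n <- nchar(seqstr); m <- nchar(pep)
  hits <- NULL
  if (m <= n) {
    for (s in 1:(n - m + 1)) {
      if (substring(seqstr, s, s + m - 1) == pep)
        hits <- rbind(hits, data.frame(start = s, end = s + m - 1))
    }
  }
  hits
}

# Dominant digestion-product intervals reported for the high-enzyme bile-salt
# digests, used for coverage and epitope-survival checks.
dominant_peptide_locations <- function() {
  data.frame(
    start = c(1, 1, 51, 50, 56, 66, 86, 53, 55),
    end = c(26, 29, 61, 79, 64, 91, 91, 72, 72))
}

with_temp_fasta <- function(lines, code) {
  f <- tempfile(fileext = ".fasta")
  writeLines(lines, f)
  on.exit(unlink(f))
  code(f)
}
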