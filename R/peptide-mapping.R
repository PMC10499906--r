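# Mapping of identified-peptide tables onto isoforms: coverage, spectral-count
# abundance, observed cleavage-site usage, epitope survival.

#' Filter an identification table by score
#'
#' Retains identifications with score strictly greater than 5 (the search
#' engine's retention rule at < 1\% FDR); the threshold is configurable.
#'
#' @param table Data frame with at least a `score` column.
#' @param min_score Retention threshold; rows with score > min_score are kept.
#' @return The filtered table. The number retained/dropped is reported via
#'   `message()`.
#' @export
filter_identifications <- function(table, min_score = 5) {
  if (!"score" %in% names(table)) stop("identification table lacks a 'score' column")
  keep <- table$score > min_score
  message(sprintf("filter_identifications: %d of %d rows retained (score > %g)",
                  sum(keep), nrow(table), min_score))
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Map peptide sequences onto isoforms
#'
#' Every match location across every isoform is reported. Under "IL"
#' equivalence isoleucine and leucine are interchangeable (tandem MS cannot
#' distinguish them) and such matches are flagged `il_ambiguous`; the default
#' is exact matching, which isoform-uniqueness claims require.
#'
#' @param peptides Character vector of peptide sequences (or a data frame with
#'   a `sequence` column; other columns are carried through).
#' @param isoforms List of `protein_isoform` objects.
#' @param equivalence "exact" or "IL".
#' @return A list with `locations` (data frame: peptide, accession, start,
#'   end, unique_to_isoform, il_ambiguous, plus carried columns) and
#'   `unmapped` (data frame of peptides matching nothing). No peptide is
#'   silently dropped.
#' @export
map_peptides <- function(peptides, isoforms, equivalence = c("exact", "IL")) {
  equivalence <- match.arg(equivalence)
  if (!length(isoforms)) stop("isoform list is empty")
  if (inherits(isoforms, "protein_isoform")) isoforms <- list(isoforms)
  carry <- NULL
  if (is.data.frame(peptides)) {
    carry <- peptides
    peptides <- peptides$sequence
  }
  canon <- function(s) if (equivalence == "IL") chartr("IL", "JJ", s) else s
  locs <- vector("list", length(peptides))
  unmapped <- integer(0)
  for (i in seq_along(peptides)) {
    pep <- toupper(peptides[i])
    hits <- NULL
    for (iso in isoforms) {
      m <- gregexpr(canon(pep), canon(iso$sequence), fixed = TRUE)[[1]]
      if (m[1] == -1L) next
      for (s in as.integer(m)) {
        e <- s + nchar(pep) - 1L
        exact_here <- substring(iso$sequence, s, e) == pep
        hits <- rbind(hits, data.frame(
          peptide = pep, accession = iso$accession, start = s, end = e,
          il_ambiguous = equivalence == "IL" && !exact_here,
          .row = i, stringsAsFactors = FALSE))
      }
    }
    if (is.null(hits)) unmapped <- c(unmapped, i) else locs[[i]] <- hits
  }
  locations <- do.call(rbind, locs)
  if (is.null(locations))
    locations <- data.frame(peptide = character(0), accession = character(0),
                            start = integer(0), end = integer(0),
                            il_ambiguous = logical(0), .row = integer(0),
                            stringsAsFactors = FALSE)
  nacc <- tapply(locations$accession, locations$peptide,
                 function(a) length(unique(a)))
  locations$unique_to_isoform <- unname(nacc[locations$peptide] == 1L)
  if (!is.null(carry)) {
    extra <- carry[locations$.row, setdiff(names(carry), "sequence"),
                   drop = FALSE]
    rownames(extra) <- NULL
    locations <- cbind(locations, extra)
  }
  locations$.row <- NULL
  unmapped_df <- if (is.null(carry)) {
    data.frame(sequence = peptides[unmapped], stringsAsFactors = FALSE)
  } else carry[unmapped, , drop = FALSE]
  rownames(locations) <- rownames(unmapped_df) <- NULL
  list(locations = locations, unmapped = unmapped_df)
}

#' Per-residue coverage of an isoform
#'
#' @param locations Data frame of peptide locations (columns start, end;
#'   optionally accession, in which case only rows matching the isoform's
#'   accession are used).
#' @param isoform A `protein_isoform`.
#' @return An object of class `coverage_map`: list with `counts` (integer per
#'   residue: number of located peptides containing it) and
#'   `coverage_fraction` = (#residues with count > 0) / length. The
#'   denominator is the full length of the supplied isoform's chain.
#' @export
coverage <- function(locations, isoform) {
  n <- nchar(isoform$sequence)
  if ("accession" %in% names(locations))
    locations <- locations[locations$accession == isoform$accession, ,
                           drop = FALSE]
  counts <- integer(n)
  for (i in seq_len(nrow(locations))) {
    s <- locations$start[i]; e <- locations$end[i]
    counts[s:e] <- counts[s:e] + 1L
  }
  structure(list(counts = counts,
                 coverage_fraction = sum(counts > 0L) / n,
                 accession = isoform$accession),
            class = "coverage_map")
}

#' @export
print.coverage_map <- function(x, ...) {
  cat(sprintf("<coverage_map> %s: %.1f%% of %d residues covered\n",
              x$accession, 100 * x$coverage_fraction, length(x$counts)))
  invisible(x)
}

#' Export a coverage map as BED-like intervals
#'
#' Three columns (accession, start-1, end) describing the maximal covered
#' intervals, half-open zero-based as in BED.
#' @param cov A `coverage_map`.
#' @return Data frame with columns accession, start0, end.
#' @export
coverage_bed <- function(cov) {
  covered <- which(cov$counts > 0L)
  if (!length(covered))
    return(data.frame(accession = character(0), start0 = integer(0),
                      end = integer(0)))
  brk <- c(0, which(diff(covered) > 1), length(covered))
  data.frame(accession = cov$accession,
             start0 = covered[brk[-length(brk)] + 1] - 1L,
             end = covered[brk[-1]])
}

#' Observed cleavage-site usage
#'
#' Each located peptide contributes observed cut events at start-1 and end;
#' chain termini (positions 0 and chain length) are excluded, so undigested
#' protein generates no usage signal. Events at predicted positions are
#' labelled with the protease, others "non-typical". Counts aggregate over
#' peptides, weighted by spectral count when a `spectral_count` column is
#' present (weight 1 otherwise).
#'
#' @param locations Data frame of locations (start, end; optional
#'   spectral_count).
#' @param predicted Data frame of predicted sites (position, protease), e.g.
#'   from [predict_all_sites()].
#' @param isoform A `protein_isoform`.
#' @return Data frame with columns position, label, n_peptides, weight,
#'   ordered by position.
#' @export
cleavage_site_usage <- function(locations, predicted, isoform) {
  n <- nchar(isoform$sequence)
  w <- if ("spectral_count" %in% names(locations))
    locations$spectral_count else rep(1, nrow(locations))
  ev <- rbind(
    data.frame(position = locations$start - 1L, weight = w),
    data.frame(position = locations$end, weight = w))
  ev <- ev[ev$position > 0L & ev$position < n, , drop = FALSE]
  if (!nrow(ev))
    return(data.frame(position = integer(0), label = character(0),
                      n_peptides = integer(0), weight = numeric(0)))
  agg_w <- tapply(ev$weight, ev$position, sum)
  agg_n <- tapply(ev$weight, ev$position, length)
  pos <- as.integer(names(agg_w))
  lab <- vapply(pos, function(p) {
    hit <- predicted$protease[predicted$position == p]
    if (length(hit)) paste(sort(unique(hit)), collapse = "+") else "non-typical"
  }, "")
  out <- data.frame(position = pos, label = lab,
                    n_peptides = as.integer(agg_n),
                    weight = as.numeric(agg_w), stringsAsFactors = FALSE)
  out[order(out$position), , drop = FALSE]
}

#' Spectral-count abundance matrix
#'
#' Rows are located peptides (ordered by start, then end), columns are
#' samples; raw spectral counts and per-sample normalised fractions (each
#' sample's fractions sum to 1 when any count is positive). Heat-map
#' abundance shading is a rendering of the normalised matrix.
#'
#' @param identifications Data frame with columns sample_id, start, end,
#'   sequence (or peptide), spectral_count.
#' @return An object of class `abundance_matrix`: list with `raw` and
#'   `normalised` matrices (rownames "start-end sequence") and `peptides`
#'   data frame.
#' @export
abundance_matrix <- function(identifications) {
  pep_col <- if ("sequence" %in% names(identifications)) "sequence" else "peptide"
  stopifnot(all(c("sample_id", "start", "end", "spectral_count") %in%
                names(identifications)))
  if (any(identifications$spectral_count < 0))
    stop("spectral counts must be non-negative")
  key <- paste0(identifications$start, "-", identifications$end, " ",
                identifications[[pep_col]])
  peps <- unique(data.frame(key = key, start = identifications$start,
                            end = identifications$end,
                            sequence = identifications[[pep_col]],
                            stringsAsFactors = FALSE))
  peps <- peps[order(peps$start, peps$end, peps$sequence), , drop = FALSE]
  samples <- sort(unique(identifications$sample_id))
  raw <- matrix(0, nrow = nrow(peps), ncol = length(samples),
                dimnames = list(peps$key, samples))
  for (i in seq_len(nrow(identifications))) {
    raw[key[i], as.character(identifications$sample_id[i])] <-
      raw[key[i], as.character(identifications$sample_id[i])] +
      identifications$spectral_count[i]
  }
  totals <- colSums(raw)
  normalised <- raw
  for (j in seq_along(totals)) {
    if (totals[j] > 0) normalised[, j] <- raw[, j] / totals[j]
    else {
      warning(sprintf("sample '%s' has zero total spectral count", samples[j]))
      normalised[, j] <- 0
    }
  }
  structure(list(raw = raw, normalised = normalised, peptides = peps),
            class = "abundance_matrix")
}

#' Classify epitope survival after digestion
#'
#' Three-state rule: an epitope is `digested` when no located peptide spans
#' its full interval; `partially_degraded` when it is spanned but some
#' observed cut event lies strictly inside the interval (bond positions
#' start..end-1); `intact` when spanned and uncut. The rule reproduces the
#' reported fate of the three Pru p 3 IgE epitopes (I31-T40 digested, A11-G20
#' and G71-K80 partially degraded). The decision is invariant to duplicate
#' peptides and to spectral counts.
#'
#' @param ep An `epitope` (or list(start, end)).
#' @param locations Data frame of peptide locations (start, end).
#' @param cut_events Integer vector of observed cut bond positions (e.g.
#'   positions from [cleavage_site_usage()], optionally combined with
#'   predicted sites).
#' @return One of "digested", "partially_degraded", "intact".
#' @export
epitope_status <- function(ep, locations, cut_events) {
  spanned <- any(locations$start <= ep$start & locations$end >= ep$end)
  if (!spanned) return("digested")
  cut <- any(cut_events >= ep$start & cut_events <= ep$end - 1L)
  if (cut) "partially_degraded" else "intact"
}
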