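# Rule-based in silico proteolysis, peptide masses, and disulphide-connected
# fragment analysis.

# Residue masses (Da). Standard tabulated values; water and hydrogen carried
# separately for terminal and disulphide arithmetic.
RESIDUE_MASS_MONO <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931)
RESIDUE_MASS_AVG <- c(
  G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132)
MASS_WATER_MONO <- 18.010565
MASS_WATER_AVG <- 18.01528
MASS_H_MONO <- 1.007825
MASS_H_AVG <- 1.00794

#' Construct a protease cleavage rule
#'
#' A rule cleaves the peptide bond C-terminal to any residue in `p1_residues`
#' unless the next residue (P1') is in `blocked_p1prime`.
#'
#' @param protease Name of the protease.
#' @param p1_residues Residues after which cleavage may occur.
#' @param blocked_p1prime Residues that block cleavage when immediately
#'   C-terminal (default proline).
#' @return An object of class `cleavage_rule`.
#' @export
cleavage_rule <- function(protease, p1_residues, blocked_p1prime = "P") {
  p1 <- unique(toupper(unlist(strsplit(p1_residues, ""))))
  bl <- unique(toupper(unlist(strsplit(blocked_p1prime, ""))))
  if (!length(p1)) stop("p1_residues must be non-empty")
  if (!all(c(p1, bl) %in% AA_ALPHABET)) stop("residues outside alphabet")
  structure(list(protease = protease, p1_residues = p1, blocked_p1prime = bl),
            class = "cleavage_rule")
}

#' Default protease rules
#'
#' Trypsin cleaves after K/R unless before P; chymotrypsin after F/Y/W/L
#' unless before P (the specificity set that yields the six predicted Pru p 3
#' sites including the L10-A11 bond); pepsin is provided (after F/L/W/Y,
#' blocked before P) but is not part of the default intestinal pipeline since
#' intact Pru p 3 resists peptic proteolysis.
#'
#' @param protease "trypsin", "chymotrypsin" or "pepsin".
#' @return A `cleavage_rule`.
#' @export
default_rule <- function(protease = c("trypsin", "chymotrypsin", "pepsin")) {
  protease <- match.arg(protease)
  switch(protease,
         trypsin = cleavage_rule("trypsin", "KR", "P"),
         chymotrypsin = cleavage_rule("chymotrypsin", "FYWL", "P"),
         pepsin = cleavage_rule("pepsin", "FLWY", "P"))
}

#' Predict specific cleavage sites
#'
#' A site at position i denotes the peptide bond between residues i and i+1.
#' The chain's final residue never yields a site.
#'
#' @param isoform A `protein_isoform`.
#' @param rule A `cleavage_rule`.
#' @return Data frame with columns position, protease, specific (all TRUE),
#'   positions ascending.
#' @examples
#' iso <- protein_isoform("X", "AKPGRG")
#' predict_cleavage_sites(iso, default_rule("trypsin"))$position  # 5
#' @export
predict_cleavage_sites <- function(isoform, rule) {
  res <- residues(isoform)
  n <- length(res)
  if (n < 2L) {
    pos <- integer(0)
  } else {
    pos <- which(res[-n] %in% rule$p1_residues &
                 !(res[-1] %in% rule$blocked_p1prime))
  }
  data.frame(position = as.integer(pos),
             protease = rep(rule$protease, length(pos)),
             specific = rep(TRUE, length(pos)),
             stringsAsFactors = FALSE)
}

#' Predicted sites for a set of rules
#' @param isoform A `protein_isoform`.
#' @param rules A `cleavage_rule` or list of rules.
#' @return Data frame of sites from all rules, ordered by position.
#' @export
predict_all_sites <- function(isoform, rules) {
  if (inherits(rules, "cleavage_rule")) rules <- list(rules)
  out <- do.call(rbind, lapply(rules, predict_cleavage_sites,
                               isoform = isoform))
  out[order(out$position), , drop = FALSE]
}

#' Monoisotopic or average peptide mass
#'
#' Sum of residue masses plus one water, plus modification deltas.
#'
#' @param sequence Peptide residue string.
#' @param mods List of `list(position, name)` pairs (position within the
#'   peptide, 1-based; name as in [modification_spec()]). Default none.
#' @param kind "mono" or "avg".
#' @return Mass in Da.
#' @examples
#' peptide_mass("G")  # 75.0320
#' @export
peptide_mass <- function(sequence, mods = list(), kind = c("mono", "avg")) {
  kind <- match.arg(kind)
  if (!nzchar(sequence)) stop("empty peptide")
  res <- strsplit(toupper(sequence), "")[[1]]
  tab <- if (kind == "mono") RESIDUE_MASS_MONO else RESIDUE_MASS_AVG
  if (any(!res %in% names(tab)))
    stop("non-canonical residue in peptide: ", sequence)
  m <- sum(tab[res]) + (if (kind == "mono") MASS_WATER_MONO else MASS_WATER_AVG)
  for (md in mods) {
    pos <- as.integer(md[[1]]); name <- md[[2]]
    spec <- modification_spec(name)
    if (pos < 1L || pos > length(res))
      stop("modification position outside peptide")
    allowed <- strsplit(spec$targets, "")[[1]]
    if (!res[pos] %in% allowed)
      stop(sprintf("%s not allowed on residue %s at position %d",
                   name, res[pos], pos))
    m <- m + if (kind == "mono") spec$delta_mono else spec$delta_avg
  }
  unname(m)
}

# internal: missed cleavages = predicted sites strictly inside [start, end-1]
.internal_sites <- function(start, end, sites) {
  sum(sites >= start & sites < end)
}

#' In silico digestion of an isoform
#'
#' Enumerates theoretical peptides from the predicted cleavage sites of the
#' active rules. Full specificity requires both termini at predicted sites (or
#' chain termini) with at most `max_missed` uncut internal sites; semi relaxes
#' exactly one terminus to any position (internal missed sites still capped);
#' none enumerates all substrings (a length bound is then mandatory on long
#' sequences, as a combinatorial guard). Peptides are filtered by length and,
#' when `mass_range_Da` is given, by monoisotopic mass. Output is ordered by
#' start, then end.
#'
#' @param isoform A `protein_isoform`.
#' @param rules A `cleavage_rule` or list of rules.
#' @param max_missed Maximum internal missed cleavages (default 2).
#' @param specificity "full", "semi" or "none".
#' @param length_range Length bounds, inclusive (default c(1, Inf)).
#' @param mass_range_Da Optional monoisotopic mass bounds, inclusive.
#' @return Data frame with columns start, end, sequence, missed_cleavages,
#'   termini_specific (2, 1 or 0), mass_mono, mass_avg.
#' @export
digest <- function(isoform, rules, max_missed = 2L,
                   specificity = c("full", "semi", "none"),
                   length_range = c(1L, Inf), mass_range_Da = NULL) {
  specificity <- match.arg(specificity)
  stopifnot(max_missed >= 0L, length_range[1] <= length_range[2])
  if (!is.null(mass_range_Da)) stopifnot(mass_range_Da[1] <= mass_range_Da[2])
  n <- nchar(isoform$sequence)
  if (specificity == "none" && !is.finite(length_range[2]) && n > 100L)
    stop("specificity 'none' on a long sequence requires a finite length bound")
  sites <- predict_all_sites(isoform, rules)$position
  sites <- sort(unique(sites))
  bounds <- c(0L, sites, n)        # allowed specific termini (post-positions)
  pairs <- NULL
  if (specificity == "full") {
    starts <- bounds[-length(bounds)] + 1L
    ends <- bounds[-1L]
    for (i in seq_along(starts)) {
      for (j in seq_along(ends)) {
        if (ends[j] < starts[i]) next
        if (.internal_sites(starts[i], ends[j], sites) > max_missed) break
        pairs <- rbind(pairs, c(starts[i], ends[j], 2L))
      }
    }
  } else if (specificity == "semi") {
    spec_start <- bounds[-length(bounds)] + 1L
    spec_end <- bounds[-1L]
    acc <- list(); k <- 0L
    for (s in spec_start) {
      for (e in s:n) {
        if (.internal_sites(s, e, sites) > max_missed) break
        k <- k + 1L
        acc[[k]] <- c(s, e, if (e %in% spec_end) 2L else 1L)
      }
    }
    for (e in spec_end) {
      for (s in e:1L) {
        if (.internal_sites(s, e, sites) > max_missed) break
        if (s %in% spec_start) next   # already enumerated with both termini
        k <- k + 1L
        acc[[k]] <- c(s, e, 1L)
      }
    }
    pairs <- do.call(rbind, acc)
  } else {
    spec_start <- bounds[-length(bounds)] + 1L
    spec_end <- bounds[-1L]
    maxlen <- min(length_range[2], n)
    acc <- list(); k <- 0L
    for (s in 1:n) {
      for (e in s:min(n, s + maxlen - 1L)) {
        k <- k + 1L
        ts <- (s %in% spec_start) + (e %in% spec_end)
        acc[[k]] <- c(s, e, ts)
      }
    }
    pairs <- do.call(rbind, acc)
  }
  if (is.null(pairs)) pairs <- matrix(integer(0), ncol = 3)
  pairs <- unique(pairs)
  len <- pairs[, 2] - pairs[, 1] + 1L
  keep <- len >= length_range[1] & len <= length_range[2]
  pairs <- pairs[keep, , drop = FALSE]
  if (nrow(pairs)) {
    seqs <- substring(isoform$sequence, pairs[, 1], pairs[, 2])
    mm <- vapply(seq_len(nrow(pairs)), function(i)
      .internal_sites(pairs[i, 1], pairs[i, 2], sites), integer(1))
    mono <- vapply(seqs, peptide_mass, numeric(1), kind = "mono",
                   USE.NAMES = FALSE)
    avg <- vapply(seqs, peptide_mass, numeric(1), kind = "avg",
                  USE.NAMES = FALSE)
  } else {
    seqs <- character(0); mm <- integer(0); mono <- avg <- numeric(0)
  }
  out <- data.frame(start = as.integer(pairs[, 1]),
                    end = as.integer(pairs[, 2]), sequence = seqs,
                    missed_cleavages = mm,
                    termini_specific = as.integer(pairs[, 3]),
                    mass_mono = mono, mass_avg = avg,
                    stringsAsFactors = FALSE)
  if (!is.null(mass_range_Da)) {
    out <- out[out$mass_mono >= mass_range_Da[1] &
               out$mass_mono <= mass_range_Da[2], , drop = FALSE]
  }
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Split a chain at cut positions and group fragments by disulphide bonds
#'
#' The chain is hydrolysed at every cut position (a cut at i severs the bond
#' between residues i and i+1); fragments whose cysteines remain paired across
#' the topology are merged into connected components. A component's mass is
#' the sum of its members' masses minus 2 H per disulphide bond contained in
#' the component (including bonds internal to one member).
#'
#' @param isoform A `protein_isoform`.
#' @param cut_positions Integer set of bond positions (1 <= i < length).
#' @param topology A `disulphide_topology` (validated against the isoform).
#' @return List of components, each a list with `members` (data frame start,
#'   end, sequence), `bridges` (matrix of cys pairs internal to the
#'   component), `mass_mono`, `mass_avg`. Components are ordered by the start
#'   of their first member and partition the fragments.
#' @export
build_fragment_components <- function(isoform, cut_positions, topology) {
  n <- nchar(isoform$sequence)
  cuts <- sort(unique(as.integer(cut_positions)))
  if (length(cuts) && (min(cuts) < 1L || max(cuts) >= n))
    stop("cut positions must satisfy 1 <= i < sequence length")
  v <- validate_topology(isoform, topology)
  if (length(v)) stop("invalid topology: ", paste(v, collapse = "; "))
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts, n)
  nf <- length(starts)
  frag_of <- function(pos) findInterval(pos, starts)
  # union-find over fragments, merged along disulphide pairs
  parent <- seq_len(nf)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  np <- nrow(topology$pairs)
  for (b in seq_len(np)) {
    f1 <- find(frag_of(topology$pairs[b, 1]))
    f2 <- find(frag_of(topology$pairs[b, 2]))
    if (f1 != f2) parent[f2] <- f1
  }
  comp_id <- vapply(seq_len(nf), find, integer(1))
  comps <- lapply(unique(comp_id[order(starts)]), function(cid) {
    idx <- which(comp_id == cid)
    members <- data.frame(start = starts[idx], end = ends[idx],
                          sequence = substring(isoform$sequence, starts[idx],
                                               ends[idx]),
                          stringsAsFactors = FALSE)
    in_comp <- if (np) vapply(seq_len(np), function(b)
      find(frag_of(topology$pairs[b, 1])) == cid, logical(1)) else logical(0)
    bridges <- topology$pairs[in_comp, , drop = FALSE]
    nb <- nrow(bridges)
    mono <- sum(vapply(members$sequence, peptide_mass, numeric(1),
                       kind = "mono", USE.NAMES = FALSE)) - 2 * nb * MASS_H_MONO
    avg <- sum(vapply(members$sequence, peptide_mass, numeric(1),
                      kind = "avg", USE.NAMES = FALSE)) - 2 * nb * MASS_H_AVG
    list(members = members, bridges = bridges, mass_mono = mono,
         mass_avg = avg)
  })
  comps
}

#' Is a peptide observable in a non-reduced digest?
#'
#' Without chemical reduction, a proteolytic peptide is released (and hence
#' observable as an independent species) only if none of its cysteines
#' participates in a disulphide bond of the topology.
#'
#' @param start,end Peptide interval on the parent chain (1-based inclusive).
#' @param isoform A `protein_isoform`.
#' @param topology A `disulphide_topology`.
#' @return TRUE iff the interval contains no paired cysteine.
#' @export
nonreduced_observable <- function(start, end, isoform, topology) {
  pc <- paired_cysteines(topology)
  !any(pc >= start & pc <= end)
}

#' Maximal intervals free of paired cysteines
#'
#' The inter-bridge regions of the chain: maximal intervals containing no
#' disulphide-paired cysteine, in sequence order. Peptides observable in
#' non-reduced digests lie entirely within these intervals.
#'
#' @param isoform A `protein_isoform`.
#' @param topology A `disulphide_topology`.
#' @return Data frame with columns start, end.
#' @export
interbridge_free_intervals <- function(isoform, topology) {
  n <- nchar(isoform$sequence)
  pc <- paired_cysteines(topology)
  free <- setdiff(seq_len(n), pc)
  if (!length(free)) return(data.frame(start = integer(0), end = integer(0)))
  brk <- c(0, which(diff(free) > 1), length(free))
  data.frame(start = free[brk[-length(brk)] + 1],
             end = free[brk[-1]])
}
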