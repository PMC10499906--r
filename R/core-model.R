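# Domain types and fixtures shared by all pipeline stages.

#' Canonical amino-acid alphabet
#'
#' The 20 standard residues; all sequences handled by the package are
#' restricted to this alphabet.
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Construct a protein isoform
#'
#' A mature protein sequence with an accession and the coordinate assigned to
#' its first residue. All peptide intervals, epitopes and disulphide positions
#' in the package are 1-based inclusive coordinates on this frame.
#'
#' @param accession Character identifier (e.g. a UniProt accession).
#' @param sequence Residue string over the 20-letter amino-acid alphabet.
#' @param label Free-text label (e.g. "Pru p 3.0101"); defaults to the
#'   accession.
#' @param numbering_origin Integer coordinate of the first residue (default 1,
#'   mature-protein numbering). N-terminally extended splice variants may carry
#'   their own origin.
#' @return An object of class `protein_isoform`.
#' @examples
#' iso <- protein_isoform("X", "ITCGQ")
#' nchar(iso$sequence)
#' @export
protein_isoform <- function(accession, sequence, label = accession,
                            numbering_origin = 1L) {
  stopifnot(is.character(accession), length(accession) == 1L, nzchar(accession))
  sequence <- toupper(as.character(sequence))
  if (!nzchar(sequence)) stop("sequence must be non-empty")
  bad <- which(!strsplit(sequence, "")[[1]] %in% AA_ALPHABET)
  if (length(bad)) {
    stop(sprintf("record '%s': non-amino-acid character '%s' at position %d",
                 accession, substr(sequence, bad[1], bad[1]), bad[1]))
  }
  numbering_origin <- as.integer(numbering_origin)
  if (is.na(numbering_origin) || numbering_origin < 1L)
    stop("numbering_origin must be >= 1")
  structure(list(accession = accession, label = label, sequence = sequence,
                 numbering_origin = numbering_origin),
            class = "protein_isoform")
}

#' @export
print.protein_isoform <- function(x, ...) {
  cat(sprintf("<protein_isoform> %s (%s), %d aa, numbering origin %d\n",
              x$accession, x$label, nchar(x$sequence), x$numbering_origin))
  invisible(x)
}

#' Residues of an isoform as a character vector
#' @param isoform A `protein_isoform`.
#' @return Character vector of single residues.
#' @export
residues <- function(isoform) strsplit(isoform$sequence, "")[[1]]

#' Read protein isoforms from a FASTA file
#'
#' The header token before the first whitespace becomes the accession; the
#' remainder (if any) becomes the label. Sequences are upper-cased and must be
#' over the canonical 20-residue alphabet; gap or unknown characters are
#' rejected with the offending record and position named.
#'
#' @param path Path to a FASTA file (wrapped or unwrapped, multi-record).
#' @return List of `protein_isoform` objects, input order preserved.
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  if (file.size(path) == 0) stop("empty FASTA file: ", path)
  set <- Biostrings::readBStringSet(path, format = "fasta")
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  lapply(seq_along(set), function(i) {
    header <- names(set)[i]
    acc <- sub("\\s.*$", "", header)
    lab <- sub("^\\S+\\s*", "", header)
    if (!nzchar(lab)) lab <- acc
    protein_isoform(acc, as.character(set[[i]]), label = lab)
  })
}

#' Write protein isoforms to a FASTA file
#' @param isoforms List of `protein_isoform` objects.
#' @param path Output path.
#' @param width Line-wrap width (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(isoforms, path, width = 60L) {
  if (inherits(isoforms, "protein_isoform")) isoforms <- list(isoforms)
  seqs <- Biostrings::BStringSet(vapply(isoforms, `[[`, "", "sequence"))
  names(seqs) <- vapply(isoforms, function(x) {
    if (identical(x$label, x$accession)) x$accession
    else paste(x$accession, x$label)
  }, "")
  Biostrings::writeXStringSet(seqs, path, width = width)
  invisible(path)
}

#' Construct a linear epitope
#'
#' @param label Text label of the form "A11-G20" (first residue letter +
#'   position, dash, last residue letter + position).
#' @param start,end 1-based inclusive coordinates; parsed from the label when
#'   omitted.
#' @return An object of class `epitope`.
#' @export
epitope <- function(label, start = NULL, end = NULL) {
  m <- regmatches(label, regexec("^([A-Z])(\\d+)-([A-Z])(\\d+)$", label))[[1]]
  if (is.null(start)) {
    if (length(m) == 0L) stop("cannot parse epitope label: ", label)
    start <- as.integer(m[3]); end <- as.integer(m[5])
  }
  stopifnot(start <= end)
  structure(list(label = label, start = as.integer(start),
                 end = as.integer(end)), class = "epitope")
}

#' Check an epitope against its parent sequence
#'
#' Verifies the interval lies within the chain and that the first/last residue
#' letters encoded in the label match the sequence.
#' @param ep An `epitope`.
#' @param isoform A `protein_isoform`.
#' @return TRUE invisibly, or an error.
#' @export
validate_epitope <- function(ep, isoform) {
  n <- nchar(isoform$sequence)
  if (ep$start < 1L || ep$end > n)
    stop(sprintf("epitope %s outside chain 1..%d", ep$label, n))
  m <- regmatches(ep$label, regexec("^([A-Z])(\\d+)-([A-Z])(\\d+)$",
                                    ep$label))[[1]]
  if (length(m)) {
    res <- residues(isoform)
    if (res[ep$start] != m[2] || res[ep$end] != m[4])
      stop(sprintf("epitope %s: label letters %s/%s do not match sequence %s/%s",
                   ep$label, m[2], m[4], res[ep$start], res[ep$end]))
  }
  invisible(TRUE)
}

#' Construct a disulphide topology
#'
#' Unordered pairs of 1-based cysteine positions. Pru p 3, like all plant
#' nsLTP1s, has eight conserved cysteines forming four intra-molecular bonds.
#'
#' @param pairs List of length-2 integer vectors, or a 2-column matrix.
#' @return An object of class `disulphide_topology` with a `pairs` matrix
#'   (rows sorted, smaller position first).
#' @export
disulphide_topology <- function(pairs) {
  if (is.matrix(pairs)) pairs <- split(pairs, row(pairs))
  if (length(pairs) == 0L) {
    m <- matrix(integer(0), ncol = 2)
  } else {
    m <- t(vapply(pairs, function(p) sort(as.integer(p)), integer(2)))
  }
  colnames(m) <- c("cys1", "cys2")
  structure(list(pairs = m), class = "disulphide_topology")
}

#' Positions participating in any disulphide pair
#' @param topology A `disulphide_topology`.
#' @return Sorted integer vector of paired cysteine positions.
#' @export
paired_cysteines <- function(topology) sort(unique(as.vector(topology$pairs)))

#' Validate a disulphide topology against an isoform
#'
#' @param isoform A `protein_isoform`.
#' @param topology A `disulphide_topology`.
#' @return Character vector of violations; empty iff every listed position is
#'   a cysteine of the sequence and no cysteine occurs in more than one pair.
#' @export
validate_topology <- function(isoform, topology) {
  res <- residues(isoform)
  out <- character(0)
  pos <- as.vector(topology$pairs)
  for (p in unique(pos)) {
    if (p < 1L || p > length(res))
      out <- c(out, sprintf("position %d outside chain", p))
    else if (res[p] != "C")
      out <- c(out, sprintf("position %d is %s, not Cys", p, res[p]))
  }
  dup <- unique(pos[duplicated(pos)])
  for (p in dup) out <- c(out, sprintf("Cys %d used in more than one pair", p))
  out
}

#' Construct a digestion-condition record
#'
#' Metadata describing one in vitro digestion test. The high and low enzyme
#' tests correspond to adult- and infant-level intestinal protease activities
#' (trypsin 34.5 vs 3.5 U/mg substrate, chymotrypsin 0.4 vs 0.04 U/mg), with
#' bile salts (sodium taurocholate + sodium glycodeoxycholate) at 4 or 1 mM
#' per salt when present. Gastric phase: pepsin 165 U/mg at pH 2.5.
#'
#' @param phase "gastric" or "intestinal".
#' @param pH Real; 2.5 (gastric), 6.5 (duodenal) or 8.0 (ileal) in the default
#'   protocol.
#' @param bile_mM Concentration per bile salt (0, 1 or 4 mM).
#' @param enzyme_level "high" or "low"; fills in default activities when the
#'   activity arguments are missing.
#' @param trypsin_U_per_mg,chymotrypsin_U_per_mg,pepsin_U_per_mg Protease
#'   activities per mg substrate.
#' @param time_min Digestion time in minutes.
#' @return An object of class `digestion_condition`.
#' @export
digestion_condition <- function(phase = c("intestinal", "gastric"),
                                pH = 6.5, bile_mM = 0,
                                enzyme_level = c("high", "low"),
                                trypsin_U_per_mg = NULL,
                                chymotrypsin_U_per_mg = NULL,
                                pepsin_U_per_mg = NULL,
                                time_min = 120) {
  phase <- match.arg(phase)
  enzyme_level <- match.arg(enzyme_level)
  if (phase == "intestinal") {
    if (is.null(trypsin_U_per_mg))
      trypsin_U_per_mg <- if (enzyme_level == "high") 34.5 else 3.5
    if (is.null(chymotrypsin_U_per_mg))
      chymotrypsin_U_per_mg <- if (enzyme_level == "high") 0.4 else 0.04
    if (is.null(pepsin_U_per_mg)) pepsin_U_per_mg <- 0
  } else {
    if (is.null(pepsin_U_per_mg)) pepsin_U_per_mg <- 165
    if (is.null(trypsin_U_per_mg)) trypsin_U_per_mg <- 0
    if (is.null(chymotrypsin_U_per_mg)) chymotrypsin_U_per_mg <- 0
  }
  vals <- c(pH, bile_mM, trypsin_U_per_mg, chymotrypsin_U_per_mg,
            pepsin_U_per_mg, time_min)
  if (any(vals < 0)) stop("activities, concentrations and times must be >= 0")
  structure(list(phase = phase, pH = pH, bile_mM = bile_mM,
                 enzyme_level = enzyme_level,
                 trypsin_U_per_mg = trypsin_U_per_mg,
                 chymotrypsin_U_per_mg = chymotrypsin_U_per_mg,
                 pepsin_U_per_mg = pepsin_U_per_mg,
                 time_min = time_min),
            class = "digestion_condition")
}

# Post-translational modification specifications. Deltas in Da; monoisotopic
# and average. Carbamidomethyl applies only to reduced-alkylated samples.
MODIFICATIONS <- data.frame(
  name = c("phospho-S", "deamidation-NQ", "oxidation-M", "carbamidomethyl-C"),
  targets = c("S", "NQ", "M", "C"),
  delta_mono = c(79.96633, 0.98402, 15.99491, 57.02146),
  delta_avg = c(79.9799, 0.9847, 15.9994, 57.0513),
  stringsAsFactors = FALSE
)

#' Look up a modification specification
#'
#' Supported: "phospho-S" (+79.9663 Da), "deamidation-NQ" (+0.9840),
#' "oxidation-M" (+15.9949), "carbamidomethyl-C" (+57.0215; fixed modification
#' for reduced-alkylated samples). Deltas are monoisotopic; average deltas are
#' carried alongside.
#'
#' @param name One of the supported modification names.
#' @return A one-row data frame with columns name, targets, delta_mono,
#'   delta_avg.
#' @export
modification_spec <- function(name) {
  i <- match(name, MODIFICATIONS$name)
  if (is.na(i)) stop("unknown modification: ", name,
                     " (supported: ", paste(MODIFICATIONS$name, collapse = ", "), ")")
  MODIFICATIONS[i, , drop = FALSE]
}

#' Load the vendored Pru p 3 fixtures
#'
#' Returns the 91-residue mature Pru p 3 chain together with its three linear
#' IgE epitopes (A11-G20, I31-T40, G71-K80) and the default disulphide
#' topology. The sequence is a vendored reconstruction of the mature chain the
#' literature maps peptides onto (accession Q9LED1, isoform Pru p 3.0102
#' numbering frame); it is gated by a self-test that checks the boundary
#' residue letters of the dominant digestion peptides, the epitope labels, the
#' phosphoserine positions 55/57/82 and the eight cysteine positions, and the
#' loader errors if any check fails. The disulphide pairing defaults to the
#' canonical plant nsLTP1 pattern C1-C6, C2-C3, C4-C7, C5-C8, i.e. pairs
#' (3,50), (13,27), (28,73), (48,87), which reproduces the disulphide-free
#' region between Cys50 and Cys73 seen in non-reduced digests; it can be
#' overridden by editing the JSON sidecar or passing a different topology
#' downstream.
#'
#' @return A list with elements `isoform` (`protein_isoform`), `epitopes`
#'   (list of `epitope`) and `topology` (`disulphide_topology`).
#' @examples
#' fx <- load_prup3_fixtures()
#' nchar(fx$isoform$sequence)  # 91
#' @export
load_prup3_fixtures <- function() {
  fa <- system.file("extdata", "prup3_mature_synthetic.fasta",
                    package = "ltpdigest", mustWork = TRUE)
  js <- system.file("extdata", "prup3_annotation.json",
                    package = "ltpdigest", mustWork = TRUE)
  iso <- read_fasta(fa)[[1]]
  ann <- jsonlite::fromJSON(js, simplifyVector = TRUE)
  eps <- lapply(ann$epitopes, epitope)
  topo <- disulphide_topology(lapply(seq_len(nrow(ann$disulphides)),
                                     function(i) ann$disulphides[i, ]))
  # self-consistency gate
  if (nchar(iso$sequence) != ann$length)
    stop("fixture sequence length mismatch")
  res <- residues(iso)
  for (ep in eps) validate_epitope(ep, iso)
  v <- validate_topology(iso, topo)
  if (length(v)) stop("fixture topology invalid: ", paste(v, collapse = "; "))
  bc <- ann$boundary_checks
  for (lab in bc) {
    m <- regmatches(lab, regexec("^([A-Z])(\\d+)-([A-Z])(\\d+)$", lab))[[1]]
    s <- as.integer(m[3]); e <- as.integer(m[5])
    if (res[s] != m[2] || res[e] != m[4])
      stop(sprintf("fixture boundary check failed for %s", lab))
  }
  for (p in ann$phosphoserines)
    if (res[p] != "S") stop(sprintf("fixture position %d is not Ser", p))
  list(isoform = iso, epitopes = eps, topology = topo)
}
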