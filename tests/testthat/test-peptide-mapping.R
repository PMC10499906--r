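fx <- load_prup3_fixtures()

test_that("identification filtering keeps scores strictly above threshold", {
  tab <- data.frame(sequence = c("a", "b", "c"), score = c(4.9, 5.0, 5.1))
  out <- suppressMessages(filter_identifications(tab))
  expect_equal(nrow(out), 1)
  expect_equal(out$score, 5.1)
  empty <- tab[0, ]
  expect_equal(nrow(suppressMessages(filter_identifications(empty))), 0)
  high <- data.frame(sequence = "x", score = 9)
  expect_equal(suppressMessages(filter_identifications(high)), high)
  expect_error(filter_identifications(data.frame(seq = "x")), "score")
})

test_that("peptides map to all locations with isoform uniqueness flags", {
  mp <- map_peptides("ITC", list(fx$isoform))
  expect_equal(mp$locations[, c("start", "end")],
               data.frame(start = 1L, end = 3L))
  expect_true(mp$locations$unique_to_isoform)
  # shared peptide across two isoforms
  iso2 <- protein_isoform("OTHER", paste0("GGG", "ITC", "GGG"))
  mp2 <- map_peptides(c("ITC", "GQV"), list(fx$isoform, iso2))
  itc <- mp2$locations[mp2$locations$peptide == "ITC", ]
  expect_equal(nrow(itc), 2)
  expect_false(any(itc$unique_to_isoform))
  gqv <- mp2$locations[mp2$locations$peptide == "GQV", ]
  expect_true(all(gqv$unique_to_isoform))
})

test_that("IL equivalence is opt-in and flagged", {
  exact <- map_peptides("LTC", list(fx$isoform))
  expect_equal(nrow(exact$locations), 0)
  expect_equal(exact$unmapped$sequence, "LTC")
  il <- map_peptides("LTC", list(fx$isoform), equivalence = "IL")
  expect_equal(il$locations[, c("start", "end")],
               data.frame(start = 1L, end = 3L))
  expect_true(il$locations$il_ambiguous)
})

test_that("every peptide is located or reported unmapped (scan oracle)", {
  set.seed(61)
  for (i in 1:15) {
    iso <- protein_isoform("R", random_sequence(sample(20:60, 1)))
    peps <- c(
      vapply(1:5, function(j) {
        s <- sample(nchar(iso$sequence) - 4, 1)
        substring(iso$sequence, s, s + sample(2:4, 1))
      }, ""),
      random_sequence(12))  # almost surely absent
    mp <- map_peptides(peps, list(iso))
    expect_equal(nrow(mp$locations) + 0L, sum(vapply(peps, function(p)
      length(gregexpr(p, iso$sequence, fixed = TRUE)[[1]][
        gregexpr(p, iso$sequence, fixed = TRUE)[[1]] > 0]), 0L)))
    for (p in unique(peps)) {
      want <- naive_map_oracle(p, iso$sequence)
      got <- mp$locations[mp$locations$peptide == p, c("start", "end")]
      got <- unique(got[order(got$start), , drop = FALSE])
      if (is.null(want)) {
        expect_true(p %in% mp$unmapped$sequence)
      } else {
        expect_equal(got, want, ignore_attr = TRUE)
      }
    }
  }
})

test_that("coverage of the dominant peptide set is 71/91 and monotone", {
  dom <- dominant_peptide_locations()
  cov <- coverage(dom, fx$isoform)
  expect_equal(cov$coverage_fraction, 71 / 91)
  expect_equal(sum(cov$counts > 0), 71)
  expect_equal(coverage(dom[0, ], fx$isoform)$coverage_fraction, 0)
  expect_equal(coverage(data.frame(start = 1, end = 91),
                        fx$isoform)$coverage_fraction, 1)
  # monotone non-decreasing as peptides accumulate
  set.seed(71)
  prev <- 0
  idx <- sample(nrow(dom))
  for (k in seq_along(idx)) {
    f <- coverage(dom[idx[seq_len(k)], , drop = FALSE],
                  fx$isoform)$coverage_fraction
    expect_gte(f, prev)
    prev <- f
  }
})

test_that("coverage BED export reproduces the covered interval union", {
  dom <- dominant_peptide_locations()
  bed <- coverage_bed(coverage(dom, fx$isoform))
  expect_equal(bed$start0, c(0, 49))
  expect_equal(bed$end, c(29, 91))
})

test_that("cleavage-site usage labels observed cuts and excludes termini", {
  predicted <- predict_all_sites(fx$isoform,
                                 list(default_rule("trypsin"),
                                      default_rule("chymotrypsin")))
  u <- cleavage_site_usage(data.frame(start = 50, end = 79), predicted,
                           fx$isoform)
  expect_equal(u$label[u$position == 79], "chymotrypsin")
  expect_equal(u$label[u$position == 49], "non-typical")
  u2 <- cleavage_site_usage(data.frame(start = 1, end = 26), predicted,
                            fx$isoform)
  expect_equal(nrow(u2), 1)  # start-1 = 0 is a chain terminus
  expect_equal(u2$position, 26L)
  expect_equal(u2$label, "non-typical")
  u3 <- cleavage_site_usage(data.frame(start = 1, end = 91), predicted,
                            fx$isoform)
  expect_equal(nrow(u3), 0)
  # spectral-count weighting aggregates
  u4 <- cleavage_site_usage(
    data.frame(start = c(50, 50), end = c(79, 79), spectral_count = c(3, 2)),
    predicted, fx$isoform)
  expect_equal(u4$weight[u4$position == 79], 5)
  expect_equal(u4$n_peptides[u4$position == 79], 2L)
})

test_that("abundance matrix normalises per sample and ignores row order", {
  ids <- data.frame(
    sample_id = c("s1", "s1", "s2", "s2"),
    sequence = c("AAA", "BBB", "AAA", "CCC"),
    start = c(1, 5, 1, 9), end = c(3, 7, 3, 11),
    spectral_count = c(3, 1, 2, 2))
  ab <- abundance_matrix(ids)
  expect_equal(unname(ab$normalised[, "s1"]),
               c(0.75, 0.25, 0))
  expect_equal(unname(colSums(ab$normalised)), c(1, 1))
  ab2 <- abundance_matrix(ids[c(3, 1, 4, 2), ])
  expect_identical(ab$raw, ab2$raw)
  expect_identical(ab$normalised, ab2$normalised)
  zero <- data.frame(sample_id = "s1", sequence = "AAA", start = 1, end = 3,
                     spectral_count = 0)
  expect_warning(abundance_matrix(zero), "zero total")
})

test_that("epitope survival reproduces the three reported outcomes", {
  dom <- dominant_peptide_locations()
  predicted <- predict_all_sites(fx$isoform,
                                 list(default_rule("trypsin"),
                                      default_rule("chymotrypsin")))
  usage <- cleavage_site_usage(dom, predicted, fx$isoform)
  cuts <- unique(c(usage$position, predicted$position))
  status <- vapply(fx$epitopes, epitope_status, "", locations = dom,
                   cut_events = cuts)
  names(status) <- vapply(fx$epitopes, `[[`, "", "label")
  expect_equal(unname(status["I31-T40"]), "digested")
  expect_equal(unname(status["A11-G20"]), "partially_degraded")
  expect_equal(unname(status["G71-K80"]), "partially_degraded")
})

test_that("epitope status follows the 3-state rule and ignores duplicates", {
  ep <- epitope("A11-G20")
  expect_equal(epitope_status(ep, data.frame(start = 1, end = 26), 16),
               "partially_degraded")
  expect_equal(epitope_status(ep, data.frame(start = 1, end = 26),
                              integer(0)), "intact")
  # a cut at the bond after the last epitope residue leaves it intact
  expect_equal(epitope_status(ep, data.frame(start = 1, end = 26), 20),
               "intact")
  expect_equal(epitope_status(ep, data.frame(start = 30, end = 60), 16),
               "digested")
  dup <- data.frame(start = c(1, 1, 1), end = c(26, 26, 26))
  expect_equal(epitope_status(ep, dup, 16), "partially_degraded")
})
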