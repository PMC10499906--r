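fx <- load_prup3_fixtures()
trypsin <- default_rule("trypsin")
chymo <- default_rule("chymotrypsin")

test_that("cleavage-site prediction applies P1/P1' rules and skips the C-terminus", {
  iso <- protein_isoform("X", "AKPGRG")
  expect_equal(predict_cleavage_sites(iso, trypsin)$position, 5L)
  # K2 blocked by P3; terminal G never a site
  iso2 <- protein_isoform("X", "AKPGRK")
  expect_equal(predict_cleavage_sites(iso2, trypsin)$position, 5L)
  # property: never a site at the final residue, each site reported once
  set.seed(21)
  for (i in 1:25) {
    iso3 <- protein_isoform("R", random_sequence(sample(2:60, 1)))
    for (rule in list(trypsin, chymo, default_rule("pepsin"))) {
      sites <- predict_cleavage_sites(iso3, rule)$position
      expect_true(all(sites < nchar(iso3$sequence)))
      expect_false(any(duplicated(sites)))
      expect_true(all(diff(sites) > 0))
    }
  }
})

test_that("the mature Pru p 3 chain has 7 tryptic and 6 chymotryptic sites", {
  tr <- predict_cleavage_sites(fx$isoform, trypsin)
  ch <- predict_cleavage_sites(fx$isoform, chymo)
  expect_equal(nrow(tr), 7)
  expect_equal(nrow(ch), 6)
  expect_true(10L %in% ch$position)  # the L10-A11 bond
})

test_that("full-specificity digestion enumerates missed-cleavage products", {
  iso <- protein_isoform("X", "AKRG")
  d0 <- digest(iso, trypsin, max_missed = 0, specificity = "full")
  expect_equal(d0$sequence, c("AK", "R", "G"))
  d1 <- digest(iso, trypsin, max_missed = 1, specificity = "full")
  expect_setequal(d1$sequence, c("AK", "AKR", "R", "RG", "G"))
  expect_equal(d1$missed_cleavages[d1$sequence == "AKR"], 1L)
})

test_that("digesting the fixture yields the dominant non-reduced interval", {
  d <- digest(fx$isoform, list(trypsin, chymo), max_missed = 2,
              specificity = "full")
  expect_true(any(d$start == 53 & d$end == 72))
  expect_true(any(d$start == 80 & d$end == 91))
  expect_true(all(d$sequence ==
                  substring(fx$isoform$sequence, d$start, d$end)))
  expect_true(!is.unsorted(d$start))
})

test_that("full digestion agrees with the brute-force window oracle", {
  set.seed(31)
  for (i in 1:20) {
    iso <- protein_isoform("R", random_sequence(sample(5:60, 1)))
    mm <- sample(0:3, 1)
    got <- digest(iso, list(trypsin, chymo), max_missed = mm,
                  specificity = "full")
    want <- brute_force_full_digest(iso, list(trypsin, chymo), mm)
    expect_equal(got[, c("start", "end")], want,
                 ignore_attr = TRUE)
  }
})

test_that("semi and non-specific digestion relax termini as defined", {
  iso <- protein_isoform("X", "AKRGW")
  semi <- digest(iso, trypsin, max_missed = 0, specificity = "semi")
  expect_true(any(semi$start == 1 & semi$end == 1))   # one specific terminus
  expect_true(all(semi$termini_specific >= 1))
  full <- digest(iso, trypsin, max_missed = 0, specificity = "full")
  expect_true(all(paste(full$start, full$end) %in%
                  paste(semi$start, semi$end)))
  none <- digest(iso, trypsin, max_missed = 0, specificity = "none",
                 length_range = c(1, 5))
  expect_equal(nrow(none), 5 * 6 / 2)  # all substrings of a 5-mer
  long <- protein_isoform("L", random_sequence(150))
  expect_error(digest(long, trypsin, specificity = "none"), "length bound")
})

test_that("peptide masses follow the residue tables and modification deltas", {
  expect_equal(peptide_mass("G"), 75.0320, tolerance = 1e-3)
  expect_error(peptide_mass(""), "empty")
  expect_equal(peptide_mass("S", mods = list(list(1, "phospho-S"))),
               peptide_mass("S") + 79.96633)
  expect_error(peptide_mass("G", mods = list(list(1, "phospho-S"))),
               "not allowed")
  expect_error(peptide_mass("SG", mods = list(list(5, "phospho-S"))),
               "outside")
  # average > monoisotopic for any real peptide
  set.seed(41)
  for (i in 1:10) {
    s <- random_sequence(sample(2:30, 1))
    expect_gt(peptide_mass(s, kind = "avg"), peptide_mass(s, kind = "mono"))
  }
})

test_that("hydrolysis conserves mass: fragments sum to parent + n_cuts waters", {
  set.seed(51)
  empty <- disulphide_topology(list())
  for (i in 1:15) {
    n <- nchar(fx$isoform$sequence)
    cuts <- sort(sample(seq_len(n - 1), sample(0:8, 1)))
    comps <- build_fragment_components(fx$isoform, cuts, empty)
    expect_length(comps, length(cuts) + 1)  # every fragment its own component
    total_mono <- sum(vapply(comps, `[[`, 0, "mass_mono"))
    total_avg <- sum(vapply(comps, `[[`, 0, "mass_avg"))
    expect_equal(total_mono,
                 peptide_mass(fx$isoform$sequence) + length(cuts) * 18.010565,
                 tolerance = 1e-6)
    expect_equal(total_avg,
                 peptide_mass(fx$isoform$sequence, kind = "avg") +
                   length(cuts) * 18.01528,
                 tolerance = 1e-6)
  }
})

test_that("disulphide bridges join fragments into components", {
  # one cut inside the Cys50..Cys73 free region: both halves stay linked
  comps <- build_fragment_components(fx$isoform, 52, fx$topology)
  expect_length(comps, 1)
  expect_equal(comps[[1]]$members$start, c(1, 53))
  expect_equal(nrow(comps[[1]]$bridges), 4)
  # cutting at 52 and 72 frees the inter-bridge peptide (53,72)
  comps2 <- build_fragment_components(fx$isoform, c(52, 72), fx$topology)
  expect_length(comps2, 2)
  sizes <- vapply(comps2, function(cp) nrow(cp$members), 0L)
  free <- comps2[[which(sizes == 1)]]
  linked <- comps2[[which(sizes == 2)]]
  expect_equal(unlist(free$members[, c("start", "end")], use.names = FALSE),
               c(53, 72))
  expect_equal(linked$members$start, c(1, 73))
  # component mass subtracts 2 H per internal disulphide
  expect_equal(linked$mass_mono,
               peptide_mass(substring(fx$isoform$sequence, 1, 52)) +
                 peptide_mass(substring(fx$isoform$sequence, 73, 91)) -
                 2 * 4 * 1.007825,
               tolerance = 1e-9)
})

test_that("component masses are invariant to bridge merge order", {
  perms <- list(c(1, 2, 3, 4), c(4, 3, 2, 1), c(2, 4, 1, 3))
  cuts <- c(20, 52, 72, 80)
  ref <- NULL
  for (p in perms) {
    topo <- disulphide_topology(lapply(p, function(i) fx$topology$pairs[i, ]))
    comps <- build_fragment_components(fx$isoform, cuts, topo)
    masses <- sort(vapply(comps, `[[`, 0, "mass_mono"))
    if (is.null(ref)) ref <- masses else expect_equal(masses, ref)
  }
})

test_that("non-reduced observability means no paired cysteine in the peptide", {
  expect_true(nonreduced_observable(53, 72, fx$isoform, fx$topology))
  expect_false(nonreduced_observable(1, 26, fx$isoform, fx$topology))
  empty <- disulphide_topology(list())
  expect_true(nonreduced_observable(1, 91, fx$isoform, empty))
})

test_that("inter-bridge free intervals cover exactly the unpaired positions", {
  iv <- interbridge_free_intervals(fx$isoform, fx$topology)
  expect_true(any(iv$start == 51 & iv$end == 72))  # between Cys50 and Cys73
  expect_true(any(iv$start == 88 & iv$end == 91))  # after the last paired Cys
  pos <- unlist(mapply(seq, iv$start, iv$end, SIMPLIFY = FALSE))
  expect_setequal(pos, setdiff(1:91, paired_cysteines(fx$topology)))
  empty <- disulphide_topology(list())
  iv0 <- interbridge_free_intervals(fx$isoform, empty)
  expect_equal(nrow(iv0), 1)
  expect_equal(c(iv0$start, iv0$end), c(1, 91))
})
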