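# Seeded generators for every pipeline input: densitometry time courses,
# peptide-identification tables, and inhibition-ELISA curves. Each output
# table draws from its own pseudo-random stream derived from the master seed,
# so regenerating one table does not disturb the others.

# internal: derive a per-table sub-seed (< 2^31) from the master seed
.sub_seed <- function(seed, offset) (as.integer(seed) + 10007L * offset) %% 2147483587L

#' Simulation configuration
#'
#' Bundles the parameters of all three generators. Defaults are the study
#' conditions the analysis assumes: first-order band decay with rate
#' constants from [reference_conditions()] on the time grid
#' {0,10,20,40,60,90,120} min with 5\% multiplicative noise and 3 replicates;
#' identification sets of 97-114 (reduced) / 21-23 (non-reduced) peptides of
#' length 6-30 and mass 500-5000 Da drawn from a semi-specific ( <= 2 missed)
#' in silico digest with dominance weights forcing the preferred products,
#' log-normal spectral counts and sprinkled modifications; 4PL inhibition
#' curves on the 7-decade grid with additive noise of sd 0.03 x upper
#' asymptote.
#'
#' @param seed Master seed (integer).
#' @param decay List: time_grid, sigma (multiplicative noise sd), replicates,
#'   conditions (data frame as [reference_conditions()]).
#' @param identifications List: n_reduced_range, n_nonreduced_range,
#'   length_range, max_missed, mass_range, dominant (character vector of
#'   dominant peptide intervals "start-end"), dominance_weight,
#'   count_meanlog, count_sdlog, phospho_prob, deamidation_prob,
#'   low_score_frac.
#' @param elisa List: grid, sigma_frac (additive noise sd as a fraction of
#'   the upper asymptote), patients (data frame patient_id, sample, a, d, b,
#'   c).
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              decay = list(),
                              identifications = list(),
                              elisa = list()) {
  dec <- utils::modifyList(list(
    time_grid = c(0, 10, 20, 40, 60, 90, 120),
    sigma = 0.05, replicates = 3L,
    conditions = reference_conditions()), decay)
  idn <- utils::modifyList(list(
    n_reduced_range = c(97L, 114L),
    n_nonreduced_range = c(21L, 23L),
    length_range = c(6L, 30L),
    max_missed = 2L,
    mass_range = c(500, 5000),
    dominant = c("1-26", "1-29", "51-61", "50-79", "56-64", "66-91",
                 "86-91", "53-72", "55-72"),
    dominance_weight = 50,
    count_meanlog = 1.0, count_sdlog = 1.0,
    dominant_count_meanlog = 3.0,
    phospho_prob = 0.3, deamidation_prob = 0.05,
    low_score_frac = 0.1), identifications)
  eli <- utils::modifyList(list(
    grid = elisa_grid(), sigma_frac = 0.03,
    patients = default_elisa_patients()), elisa)
  structure(list(seed = as.integer(seed), decay = dec,
                 identifications = idn, elisa = eli),
            class = "simulation_config")
}

#' Default simulated ELISA patient parameter sets
#'
#' Per-patient 4PL parameters emulating the observed inhibition regimes:
#' intact protein inhibits at c <= 0.01 ug/mL (one weaker responder at 0.17),
#' digests without bile salts behave similarly, and digests with bile salts
#' shift c by two to three orders of magnitude, some beyond the top of the
#' tested grid (right-censored).
#' @return Data frame: patient_id, sample, a, d, b, c.
#' @export
default_elisa_patients <- function() {
  pid <- c("P1", "P4", "P5", "P6", "P7", "P8")
  intact_c <- c(0.008, 0.006, 0.02, 0.17, 0.005, 0.01)
  digest_c <- c(0.008, 0.007, 0.25, 0.008, 0.008, 0.21)
  bile_c <- c(0.40, 3.89, 30, 1.57, 25, 40)
  data.frame(
    patient_id = rep(pid, times = 3),
    sample = rep(c("intact", "digest", "digest+bile"), each = length(pid)),
    a = 2.0, d = 0.15, b = 1.0,
    c = c(intact_c, digest_c, bile_c),
    stringsAsFactors = FALSE)
}

#' Generate densitometry time courses
#'
#' I(t) = I0 exp(-K t) (1 + eps), eps ~ Normal(0, sigma), truncated at 0.
#' Resistant conditions (K = NA in the condition table) are generated with
#' K = 0. Fragment bands are generated from the consecutive-reaction model
#' where a fragment rate constant is present (rising when fragment_class is
#' "rising", transient with k_deg = K/2 otherwise).
#'
#' @param config A `simulation_config`.
#' @return Data frame: condition_id, band, replicate, time_min,
#'   rel_intensity.
#' @export
gen_timecourse <- function(config) {
  dec <- config$decay
  set.seed(.sub_seed(config$seed, 1L))
  out <- NULL
  for (i in seq_len(nrow(dec$conditions))) {
    cond <- dec$conditions[i, ]
    K <- if (is.na(cond$K)) 0 else cond$K
    for (r in seq_len(dec$replicates)) {
      mu <- exp(-K * dec$time_grid)
      eps <- stats::rnorm(length(mu), 0, dec$sigma)
      y <- pmax(mu * (1 + eps), 0)
      out <- rbind(out, data.frame(
        condition_id = cond$condition_id, band = "parent", replicate = r,
        time_min = dec$time_grid, rel_intensity = y,
        stringsAsFactors = FALSE))
    }
    if (!is.na(cond$fragment_K) || isTRUE(cond$fragment_class == "transient")) {
      kf <- if (!is.na(cond$fragment_K)) cond$fragment_K else K
      kd <- if (isTRUE(cond$fragment_class == "transient")) K / 2 else 0
      for (r in seq_len(dec$replicates)) {
        mu <- if (kd > 0) .transient_model(dec$time_grid, 1, kf, kd)
              else 1 - exp(-kf * dec$time_grid)
        eps <- stats::rnorm(length(mu), 0, dec$sigma)
        y <- pmax(mu * (1 + eps), 0)
        out <- rbind(out, data.frame(
          condition_id = cond$condition_id, band = "fragment_7kDa",
          replicate = r, time_min = dec$time_grid, rel_intensity = y,
          stringsAsFactors = FALSE))
      }
    }
  }
  rownames(out) <- NULL
  out
}

# internal: theoretical pool for the identification generator = semi-specific
# digest union the dominant (non-typically cleaved) products
.identification_pool <- function(config, isoform, rules) {
  idn <- config$identifications
  pool <- digest(isoform, rules, max_missed = idn$max_missed,
                 specificity = "semi", length_range = idn$length_range,
                 mass_range_Da = idn$mass_range)
  dom <- do.call(rbind, lapply(strsplit(idn$dominant, "-"), function(p) {
    s <- as.integer(p[1]); e <- as.integer(p[2])
    data.frame(start = s, end = e,
               sequence = substring(isoform$sequence, s, e),
               missed_cleavages = NA_integer_, termini_specific = NA_integer_,
               mass_mono = peptide_mass(substring(isoform$sequence, s, e)),
               mass_avg = peptide_mass(substring(isoform$sequence, s, e),
                                       kind = "avg"),
               stringsAsFactors = FALSE)
  }))
  key <- paste0(pool$start, "-", pool$end)
  dom_key <- paste0(dom$start, "-", dom$end)
  pool$dominant <- key %in% dom_key
  extra <- dom[!dom_key %in% key, , drop = FALSE]
  if (nrow(extra)) {
    extra$dominant <- TRUE
    pool <- rbind(pool, extra)
  }
  pool[order(pool$start, pool$end), , drop = FALSE]
}

#' Generate a synthetic peptide-identification table
#'
#' Samples peptides without replacement from the theoretical pool (the
#' semi-specific in silico digest augmented with the dominant non-typical
#' products), with dominance weights making the preferred products
#' effectively certain to appear. Reduced samples draw a count uniform in
#' `n_reduced_range`; non-reduced samples restrict the pool to
#' [nonreduced_observable()] peptides and draw counts in
#' `n_nonreduced_range`. Spectral counts are log-normal (dominant peptides
#' with a larger meanlog); serine phosphorylation is applied at positions
#' 55/57/82 with the configured probability and deamidation sprinkled on N/Q;
#' scores are drawn so a configured fraction falls at or below the score-5
#' retention filter.
#'
#' @param config A `simulation_config`.
#' @param isoform Parent `protein_isoform`.
#' @param rules Cleavage rules for the theoretical pool.
#' @param topology `disulphide_topology` used for non-reduced observability.
#' @param n_samples Samples per reduction state (default 3, biological
#'   triplicates).
#' @return Data frame: sample_id, reduced, sequence, start, end, mods,
#'   score, spectral_count.
#' @export
gen_identifications <- function(config, isoform, rules, topology,
                                n_samples = 3L) {
  idn <- config$identifications
  set.seed(.sub_seed(config$seed, 2L))
  pool <- .identification_pool(config, isoform, rules)
  if (!nrow(pool)) stop("theoretical peptide pool is empty")
  obs <- vapply(seq_len(nrow(pool)), function(i)
    nonreduced_observable(pool$start[i], pool$end[i], isoform, topology),
    logical(1))
  phospho_sites <- c(55L, 57L, 82L)
  res <- residues(isoform)
  draw_sample <- function(sample_id, reduced) {
    p <- if (reduced) pool else pool[obs, , drop = FALSE]
    rng <- if (reduced) idn$n_reduced_range else idn$n_nonreduced_range
    n <- sample(rng[1]:rng[2], 1L)
    if (n > nrow(p))
      stop(sprintf("requested %d peptides but pool holds %d", n, nrow(p)))
    w <- ifelse(p$dominant, idn$dominance_weight, 1)
    idx <- sample(nrow(p), n, prob = w)
    # forced inclusion: dominance weights default high enough that the
    # preferred products are effectively always present; guarantee it
    domidx <- which(p$dominant)
    idx <- unique(c(domidx, idx))[seq_len(max(n, length(domidx)))]
    d <- p[idx, , drop = FALSE]
    meanlog <- ifelse(d$dominant, idn$dominant_count_meanlog,
                      idn$count_meanlog)
    d$spectral_count <- pmax(1L, as.integer(round(
      stats::rlnorm(nrow(d), meanlog, idn$count_sdlog))))
    low <- stats::runif(nrow(d)) < idn$low_score_frac
    d$score <- ifelse(low, stats::runif(nrow(d), 2, 5),
                      5 + stats::rexp(nrow(d), 1 / 4))
    d$mods <- vapply(seq_len(nrow(d)), function(i) {
      m <- character(0)
      for (ps in phospho_sites) {
        if (ps >= d$start[i] && ps <= d$end[i] &&
            stats::runif(1) < idn$phospho_prob)
          m <- c(m, sprintf("phospho-S@%d", ps - d$start[i] + 1L))
      }
      nq <- which(res[d$start[i]:d$end[i]] %in% c("N", "Q"))
      for (q in nq) if (stats::runif(1) < idn$deamidation_prob)
        m <- c(m, sprintf("deamidation-NQ@%d", q))
      paste(m, collapse = ";")
    }, "")
    data.frame(sample_id = sample_id, reduced = reduced,
               sequence = d$sequence, start = d$start, end = d$end,
               mods = d$mods, score = d$score,
               spectral_count = d$spectral_count, stringsAsFactors = FALSE)
  }
  out <- NULL
  for (s in seq_len(n_samples)) {
    out <- rbind(out, draw_sample(sprintf("red_%d", s), TRUE))
    out <- rbind(out, draw_sample(sprintf("nonred_%d", s), FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Generate synthetic inhibition-ELISA curves
#'
#' Responses from the 4PL model on the configured concentration grid plus
#' additive Gaussian noise (sd = sigma_frac x upper asymptote), truncated at
#' 0, for each patient/sample parameter set.
#'
#' @param config A `simulation_config`.
#' @return Data frame: patient_id, sample, conc_ug_per_ml, A450.
#' @export
gen_inhibition_curves <- function(config) {
  eli <- config$elisa
  set.seed(.sub_seed(config$seed, 3L))
  out <- NULL
  for (i in seq_len(nrow(eli$patients))) {
    p <- eli$patients[i, ]
    mu <- p$d + (p$a - p$d) / (1 + (eli$grid / p$c)^p$b)
    y <- pmax(mu + stats::rnorm(length(mu), 0, eli$sigma_frac * p$a), 0)
    out <- rbind(out, data.frame(
      patient_id = p$patient_id, sample = p$sample,
      conc_ug_per_ml = eli$grid, A450 = y, stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}
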