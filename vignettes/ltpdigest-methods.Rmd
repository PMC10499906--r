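---
title: "Modelling the gastrointestinal digestion of Pru p 3: methods and design notes"
author: "ltpdigest"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the gastrointestinal digestion of Pru p 3: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ltpdigest)
```

# The scientific problem

Pru p 3, the non-specific lipid transfer protein (nsLTP1) of peach, is a
9 kDa allergen whose unusual resistance to gastrointestinal proteolysis is
thought to underlie its capacity to sensitise and to trigger severe systemic
reactions. Bile salts — the biosurfactants released into the duodenum after a
meal — markedly accelerate its breakdown by trypsin and chymotrypsin, and the
digestion products remain held together as disulphide-linked aggregates that
can retain IgE reactivity. `ltpdigest` packages the computational side of
that analysis into tested, reusable components:

1. **In silico proteolysis** — rule-based cleavage-site prediction and
   theoretical digestion of the 91-residue mature chain.
2. **Peptide mapping** — locating identified peptides on isoforms, sequence
   coverage, spectral-count abundance, observed cleavage-site usage, and the
   survival of the three linear IgE epitopes (A11-G20, I31-T40, G71-K80).
3. **Disulphide connectivity** — which proteolytic fragments remain tethered
   through the four conserved bonds, and which peptides are observable
   without chemical reduction.
4. **Digestion kinetics** — a resistance gate, first-order decay fits with
   half-lives, and a consecutive-reaction model for transient fragments.
5. **Inhibition ELISA** — four-parameter logistic fits with censored IC50
   reporting.
6. **A synthetic-data generator** that emulates every wet-lab input, so the
   whole pipeline runs, and is tested, without downloads or instrument data.

# The coordinate frame and vendored fixtures

All intervals are 1-based inclusive coordinates on the mature Pru p 3 chain
(numbering origin 1 at Ile1). The packaged sequence
(`inst/extdata/prup3_mature_synthetic.fasta`) is a reconstruction of the
mature chain of the Q9LED1 / Pru p 3.0102 numbering frame, labelled
*synthetic* because it is not a certified database export. It is gated by a
self-test that `load_prup3_fixtures()` runs on every load: boundary residue
letters of the dominant digestion products (I1-A26, I1-N29, C50-Y79, L51-V61,
Q53-K72, S55-K72, A66-K91, N86-K91), the three epitope labels, the
phosphoserine positions 55/57/82, and the eight cysteines at
3, 13, 27, 28, 48, 50, 73 and 87. Splice variants with N-terminal extensions
can be represented with their own `numbering_origin`.

The disulphide pairing is not directly observed in the peptide data; the default is the canonical plant nsLTP1 pattern C1–C6, C2–C3, C4–C7,
C5–C8, i.e. pairs (3,50), (13,27), (28,73), (48,87). This choice reproduces
the experimentally observed disulphide-free window between Cys50 and Cys73
from which almost all non-reduced peptides arise. The topology is data, not
code: it can be overridden through the JSON sidecar or by passing any
`disulphide_topology` downstream.

# Protease rules

Cleavage rules are positional: cut C-terminal to any P1 residue unless the
P1' residue blocks. Defaults:

| protease | P1 | blocked P1' |
|---|---|---|
| trypsin | K, R | P |
| chymotrypsin | F, Y, W, L | P |
| pepsin (optional) | F, L, W, Y | P |

Chymotrypsin's inclusion of leucine is deliberate: it is the only standard
specificity set that yields exactly the six predicted chymotryptic sites on
the mature chain, including the L10–A11 bond. On this chain the trypsin rule
yields exactly seven sites. Pepsin is provided for completeness but is not
part of the default intestinal pipeline — intact Pru p 3 survives the
gastric phase essentially unmodified, and the observed products are
trypsin/chymotrypsin work. A "non-typical" site is any observed cut position
absent from the predicted specific set of all active rules; such sites are
reported, never predicted.

`digest()` supports full, semi- and non-specific enumeration with a
missed-cleavage cap, length bounds, and an optional monoisotopic mass window
(the 500–5000 Da profiling range). Non-specific enumeration on a long chain
demands a length bound — a combinatorial guard, not a scientific statement.

# Disulphide-linked fragments

`build_fragment_components()` splits the chain at a cut set and merges
fragments connected by disulphide pairs (union-find over the bridge
relation). A component's mass is the sum of its members' peptide masses
minus 2 × 1.007825 Da per bridge it contains — each disulphide trades two
thiol hydrogens for a bond. Two invariants anchor the arithmetic and are
enforced in the tests: hydrolysis conservation (fragment masses sum to the
parent mass plus one water per cut, monoisotopic and average separately) and
invariance of component masses to the order in which bridges are merged.

`nonreduced_observable()` encodes the observable rule for non-reduced
digests: a peptide is released as an independent species only if it contains
no disulphide-paired cysteine. With the default topology the free regions
are exactly the inter-bridge intervals, the largest being residues 51–72 —
which is where the dominant non-reduced peptide Q53-K72 lives.

# Epitope survival

Experimental reports state epitope fates, not a rule; the package defines a
three-state decision procedure and validates it by reproducing all three
observed fates:

* **digested** — no located peptide spans the full epitope interval;
* **partially degraded** — spanned, and at least one observed cut event
  falls strictly inside the interval (bond positions start … end−1);
* **intact** — spanned and internally uncut.

Observed cut events are the start−1/end bonds of located peptides, with
chain termini excluded so that undigested protein generates no proteolytic
signal. The decision is invariant to duplicate peptides and to spectral
counts. For the survival classification the predicted specific sites are
included among the cut events; the dominant products alone under-report cuts
inside A11-G20 because the site-rich N-terminal region is summarised by a
few long peptides.

# Digestion kinetics

Band intensities are fractions of the intestinal undigested control (IU) and
are used as given — no renormalisation inside the fitter.

* **Resistance gate.** A two-tailed two-sample Student's t-test
  (equal-variance, Welch by flag) between IU and final-time replicate
  intensities at α = 0.05. Non-significant series are classified resistant,
  excluded from fitting and reported with t½ = ∞.
* **Decay.** I(t) = I0·exp(−K·t) fitted by Levenberg–Marquardt damped least
  squares (`minpack.lm`), initialised from a log-linear regression on
  positive intensities — deterministic, no random restarts. Goodness of fit
  is RSE = √(SSE/(n−2)). Half-life is ln(2)/K, computed from the unrounded
  K; summary tables that round K *after* computing t½ will disagree in the
  last digit for slow conditions, and the package does not chase those
  rounded values.
* **Transient fragments.** Intermediates follow consecutive first-order
  reactions, B(t) = A·k_form/(k_deg−k_form)·(e^(−k_form·t) − e^(−k_deg·t)),
  with the analytic limit A·k·t·e^(−kt) at k_form = k_deg. When the fitted
  k_deg is indistinguishable from zero (k_deg < 1e−8 min⁻¹ or
  stderr(k_deg) ≥ k_deg) and the one-rate rising-saturation model fits no
  worse, the classification is *rising* and k_form is the fragment's
  reported rate constant; otherwise *transient*, with peak time
  ln(k_form/k_deg)/(k_form−k_deg).

Convergence uses relative tolerances of 1e−12 and a 500-iteration budget.

## What the time grid can and cannot identify

The synthetic densitometry grid is {0, 10, 20, 40, 60, 90, 120} min — the
40 and 120 min landmarks are the points at which only a trace of parent
protein remains in the bile-supplemented high-enzyme tests, and the
remaining points are a declared design choice since gel sampling times are
not otherwise recorded. On this two-hour window a slow decay is inherently
weakly identified: for K ≈ 0.0016–0.0022 min⁻¹ the signal falls by only
18–23 % over the whole experiment, and with 5 % multiplicative noise and
three replicates the information bound puts the best achievable relative
standard error of K̂ at 12–17 % — no estimator can do better on these study
conditions, and the package's fit sits essentially on that bound. Rate
constants in the 0.005–0.13 min⁻¹ range are recovered with 2–4 % median
error. The same calculus applies to the seven-decade ELISA grid: with
additive noise of 3 % of the upper asymptote, the median relative error of a
fully converged IC50 estimate at c = 0.01 µg/mL is almost exactly 10 %.
These are properties of the designs, not of the fitters, and the test suite
asserts recovery at the corresponding levels.

# Inhibition ELISA

The four-parameter logistic y = d + (a−d)/(1 + (x/c)^b) is fitted with a as
the uninhibited (upper) asymptote and IC50 ≡ c, the inflection — standard
4PL reporting, consistent with censored bounds at the grid edges.
Internally the fit runs on log(c), which keeps the problem well scaled on a
logarithmic dose axis; the declared initialisation is a = max response,
d = min response, b = 1, c = geometric mid-concentration. IC50 estimates
outside the tested range are *censored* ("< min tested" / "> max tested"),
never reported as point estimates, and censoring propagates through fold
changes as bounds ("> 40"). Fits with stderr(c)/c > 0.5 are flagged
approximate ("~"), as are fits that exhaust the iteration budget crawling
along the a–c ridge that appears when the inflection lies far outside the
grid — on that ridge the censoring classification is stable even though the
individual parameters are not. The buffer control is metadata, stored apart
from the positive-concentration series; no plate-effect correction is
applied.

# The synthetic-data generator

The generator is first-class, tested code; its defaults are the study
conditions the analysis assumes.

* **Densitometry**: I(t) = e^(−Kt)·(1+ε), ε ~ N(0, σ), σ = 0.05, truncated
  at zero, 3 replicates per time point, per-condition K from the eight
  reference digestion conditions (`reference_conditions()`); resistant
  conditions are generated flat. Multiplicative noise because band-intensity
  errors scale with signal.
* **Identifications**: peptides drawn without replacement from the
  semi-specific theoretical digest (≤ 2 missed cleavages, lengths 6–30,
  500–5000 Da) *augmented with the dominant products* — several of these
  (I1-A26 with three internal predicted sites, L51-V61 with no predicted
  terminus) have non-typical termini and exist in no rule-based digest, so
  the pool is their union and the default dominance weights force their
  inclusion. Reduced samples draw 97–114 peptides, non-reduced samples
  21–23 from the disulphide-free pool. Spectral counts are log-normal
  (dominant peptides with a higher meanlog); serine phosphorylation is
  applied at 55/57/82 with probability 0.3, deamidation sprinkled on N/Q at
  0.05; a configured fraction (default 0.1) of scores falls at or below the
  score-5 retention filter.
* **ELISA**: 4PL responses on the 1e−5–10 µg/mL grid with additive
  N(0, 0.03·a) noise, truncated at zero. Per-patient parameter sets emulate
  the three observed regimes: intact protein inhibiting at c ≤ 0.01 µg/mL
  (one weaker responder at 0.17), bile-free digests similar, and
  bile-supplemented digests shifted 100–1000-fold, some beyond the top of
  the grid.

Each output table draws from its own pseudo-random stream derived from the
master seed, so regenerating one table leaves the others untouched, and a
fixed seed reproduces every table byte-identically.

What the generator does *not* emulate — and what passing tests therefore do
not show about real data: chromatographic or spectral artefacts,
identification errors (every generated peptide is a true substring),
structure-dependent cleavage kinetics (which residues are cut *faster* is
outside scope), inter-replicate correlation, and plate effects. The
generator validates the analysis arithmetic under the assumed statistical
model; it cannot validate the model against an instrument.

# Numerical choices and degenerate inputs

* Ties and order: digestion output is sorted by (start, end); abundance rows
  by location; site tables by position. All algorithms are deterministic.
* Constant intensity series collapse to K = 0 (flagged degenerate) without
  invoking the optimiser; all-zero series are an error.
* Empty topologies are legal everywhere: every fragment becomes its own
  component, every peptide is non-reduced-observable, and the single
  inter-bridge interval is the whole chain.
* An identification that maps nowhere is recorded in an unmapped report,
  never silently dropped; I/L-equivalent matching is opt-in and flagged,
  because isoform-uniqueness claims require exact matching.
* Spectral-count normalisation is per sample by total counts; raw counts are
  always carried alongside, and both linear exports support downstream
  log-scaling, since the appropriate shading scale is a display choice.

# Problem sizes used in the test suite

The packaged checks run at desk scale: 200 simulated time courses per
digestion condition for recovery studies, 200 ELISA refits, 100 random
sequences (length ≤ 60) against a brute-force digestion oracle, and
triplicate identification tables of ~100 peptides. The full suite completes
in well under a minute on one CPU.

# Known limitations

* The vendored sequence is a verified reconstruction, not a database
  export; the self-test pins every residue the downstream analysis touches,
  but positions outside those checks carry the reconstruction's authority
  only.
* Half-lives for very slow digestions (t½ ≫ the 2-h window) are reported
  with honest, wide uncertainty; extending the time grid, not the fitter,
  is the remedy.
* The epitope rule is interval arithmetic on linear epitopes; conformational
  epitopes — which dominate residual IgE binding after digestion — are out
  of scope.
* FDR estimation, database search and PTM site localisation belong to the
  upstream search engine; the package consumes its output tables.
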