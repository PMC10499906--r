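# Pipeline orchestration: TSV I/O, run manifests, and the end-to-end driver
# that chains generation -> filtering -> mapping -> kinetics -> ELISA into one
# report. A thin command-line wrapper over these functions is shipped at
# inst/scripts/ltpdigest-cli.R.

#' Read / write the package's TSV dialect
#'
#' Plain tab-separated files with a header row, no quoting surprises.
#' @param path File path.
#' @return `read_tsv_table`: a data frame. `write_tsv_table`: `path`,
#'   invisibly.
#' @export
read_tsv_table <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' @rdname read_tsv_table
#' @param x Data frame to write.
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# internal: md5 of an R object via its canonical JSON rendering
.object_md5 <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                              force = TRUE), f)
  unname(tools::md5sum(f))
}

#' Build a run manifest
#'
#' Records the configuration hash, input-file digests, package version, seed
#' and per-stage row counts, so that a report can refuse to mix stages run
#' under different configurations. Timings are recorded but excluded from the
#' manifest hash.
#'
#' @param config A `simulation_config` (or any serialisable config object).
#' @param inputs Named character vector of input file paths (optional).
#' @param stage_rows Named integer vector of per-stage row counts (optional).
#' @param timings Named numeric vector of per-stage timings in seconds
#'   (optional).
#' @return An object of class `run_manifest`.
#' @export
run_manifest <- function(config, inputs = character(0),
                         stage_rows = integer(0), timings = numeric(0)) {
  input_md5 <- if (length(inputs)) vapply(inputs, function(p)
    unname(tools::md5sum(p)), "") else character(0)
  core <- list(config_hash = .object_md5(unclass(config)),
               input_md5 = as.list(input_md5),
               version = as.character(utils::packageVersion("ltpdigest")),
               seed = config$seed,
               stage_rows = as.list(stage_rows))
  structure(c(core, list(manifest_hash = .object_md5(core),
                         timings = as.list(timings))),
            class = "run_manifest")
}

#' Check that manifests come from the same run configuration
#' @param ... `run_manifest` objects.
#' @return TRUE invisibly; error if config hashes differ.
#' @export
check_manifests <- function(...) {
  ms <- list(...)
  h <- vapply(ms, `[[`, "", "config_hash")
  if (length(unique(h)) > 1L)
    stop("refusing to combine stages run under different configurations")
  invisible(TRUE)
}

#' Run the full digestion-analysis pipeline on synthetic inputs
#'
#' One seed, one configuration: generates time courses, identification
#' tables and inhibition curves; filters identifications; maps peptides and
#' computes coverage, abundance, cleavage-site usage and epitope survival;
#' fits digestion kinetics per condition; fits 4PL inhibition curves per
#' patient/sample with IC50 censoring and bile-salt fold changes. Reruns with
#' the same seed reproduce the report exactly.
#'
#' @param config A `simulation_config`.
#' @param fixtures As returned by [load_prup3_fixtures()] (default).
#' @return A list (class `ltpdigest_report`) with elements: kinetics (per
#'   condition K, t_half, RSE, resistance), ic50 (per patient/sample with
#'   censoring labels and fold changes), coverage (per reduction state),
#'   usage, abundance, epitopes (3-state survival), identifications,
#'   unmapped, manifest.
#' @export
run_pipeline <- function(config = simulation_config(),
                         fixtures = load_prup3_fixtures()) {
  iso <- fixtures$isoform
  topo <- fixtures$topology
  rules <- list(default_rule("trypsin"), default_rule("chymotrypsin"))
  predicted <- predict_all_sites(iso, rules)
  rows <- integer(0); timings <- numeric(0)
  tic <- function() proc.time()[["elapsed"]]
  # generate
  t0 <- tic()
  tc <- gen_timecourse(config)
  ids <- gen_identifications(config, iso, rules, topo)
  curves <- gen_inhibition_curves(config)
  timings["generate"] <- tic() - t0
  rows["timecourse"] <- nrow(tc); rows["identifications"] <- nrow(ids)
  rows["elisa_curves"] <- nrow(curves)
  # identifications -> mapping
  t0 <- tic()
  kept <- suppressMessages(filter_identifications(ids))
  mp <- map_peptides(kept, list(iso))
  loc <- mp$locations
  cov_red <- coverage(loc[loc$reduced, , drop = FALSE], iso)
  cov_nonred <- coverage(loc[!loc$reduced, , drop = FALSE], iso)
  usage <- cleavage_site_usage(loc, predicted, iso)
  ab <- abundance_matrix(loc)
  cut_events <- unique(c(usage$position, predicted$position))
  epit <- data.frame(
    epitope = vapply(fixtures$epitopes, `[[`, "", "label"),
    status = vapply(fixtures$epitopes, epitope_status, "",
                    locations = loc, cut_events = cut_events),
    stringsAsFactors = FALSE)
  timings["mapping"] <- tic() - t0
  rows["locations"] <- nrow(loc)
  # kinetics
  t0 <- tic()
  kin <- analyse_timecourses(tc)
  timings["kinetics"] <- tic() - t0
  # immunoassay
  t0 <- tic()
  ic <- NULL
  for (pid in unique(curves$patient_id)) {
    fits <- list()
    for (smp in unique(curves$sample[curves$patient_id == pid])) {
      d <- curves[curves$patient_id == pid & curves$sample == smp, ]
      fits[[smp]] <- suppressWarnings(fit_4pl(d$conc_ug_per_ml, d$A450))
    }
    for (smp in names(fits)) {
      fc <- if (smp != "intact" && "intact" %in% names(fits))
        ic50_fold_change(fits[["intact"]], fits[[smp]])
      else list(value = NA_real_, label = NA_character_)
      ic <- rbind(ic, data.frame(
        patient_id = pid, sample = smp, ic50 = fits[[smp]]$ic50,
        ic50_label = format_ic50(fits[[smp]], digits = 2),
        censored = fits[[smp]]$censored,
        fold_change_vs_intact = fc$value,
        fold_change_label = fc$label, RSE = fits[[smp]]$RSE,
        stringsAsFactors = FALSE))
    }
  }
  timings["elisa"] <- tic() - t0
  manifest <- run_manifest(config, stage_rows = rows, timings = timings)
  structure(list(kinetics = kin, ic50 = ic,
                 coverage = list(reduced = cov_red, nonreduced = cov_nonred),
                 usage = usage, abundance = ab, epitopes = epit,
                 identifications = kept, unmapped = mp$unmapped,
                 manifest = manifest),
            class = "ltpdigest_report")
}

#' @export
print.ltpdigest_report <- function(x, ...) {
  cat("<ltpdigest_report>\n")
  cat(sprintf("  kinetics: %d condition/band fits\n", nrow(x$kinetics)))
  cat(sprintf("  coverage (reduced): %.1f%%; (non-reduced): %.1f%%\n",
              100 * x$coverage$reduced$coverage_fraction,
              100 * x$coverage$nonreduced$coverage_fraction))
  cat(sprintf("  epitopes: %s\n",
              paste(x$epitopes$epitope, x$epitopes$status, collapse = "; ")))
  cat(sprintf("  IC50 rows: %d (censored: %d)\n", nrow(x$ic50),
              sum(x$ic50$censored != "none")))
  invisible(x)
}

#' Write a pipeline report to a directory of TSV files
#'
#' @param report An `ltpdigest_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv_table(report$kinetics, file.path(dir, "kinetics.tsv"))
  write_tsv_table(report$ic50, file.path(dir, "ic50.tsv"))
  write_tsv_table(report$usage, file.path(dir, "cleavage_usage.tsv"))
  write_tsv_table(report$epitopes, file.path(dir, "epitopes.tsv"))
  write_tsv_table(coverage_bed(report$coverage$reduced),
                  file.path(dir, "coverage_reduced.bed"))
  write_tsv_table(coverage_bed(report$coverage$nonreduced),
                  file.path(dir, "coverage_nonreduced.bed"))
  ab <- data.frame(peptide = rownames(report$abundance$raw),
                   report$abundance$raw, check.names = FALSE)
  write_tsv_table(ab, file.path(dir, "abundance_raw.tsv"))
  abn <- data.frame(peptide = rownames(report$abundance$normalised),
                    report$abundance$normalised, check.names = FALSE)
  write_tsv_table(abn, file.path(dir, "abundance_normalised.tsv"))
  writeLines(jsonlite::toJSON(unclass(report$manifest), auto_unbox = TRUE,
                              pretty = TRUE, digits = NA, force = TRUE),
             file.path(dir, "manifest.json"))
  invisible(dir)
}
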