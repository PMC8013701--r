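# End-to-end orchestration: load -> classify -> tally -> binomial tests ->
# dNONSENSE/dS -> JSON + text report.

#' Build a pipeline configuration
#'
#' @param landscape path to the landscape TSV.
#' @param mutations path to the evolved-line mutation TSV.
#' @param cds optional path to a CDS FASTA; when given, the
#'   nonsense/synonymous rate ratio is estimated (requires at least one
#'   observed synonymous mutation).
#' @param dialect landscape dialect, `"simple"` or `"sga-raw"`.
#' @param k_sd significance multiple for the interaction classifier
#'   (default 3).
#' @param p_expected expected beneficial probability under the landscape
#'   null for the binomial test (default 0.06).
#' @param n_boot bootstrap replicates for the ratio CI.
#' @param seed integer seed for every stochastic step.
#' @param out_dir directory receiving `report.json` and `report.txt`.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(landscape, mutations, cds = NULL,
                            dialect = "simple", k_sd = 3,
                            p_expected = 0.06, n_boot = 1000, seed = 1,
                            out_dir = ".") {
  check_number(k_sd, "k_sd", min = .Machine$double.xmin)
  check_number(p_expected, "p_expected", min = 0, max = 1)
  check_count(n_boot, "n_boot")
  seed <- check_count(seed, "seed")
  structure(list(landscape = landscape, mutations = mutations, cds = cds,
                 dialect = dialect, k_sd = k_sd, p_expected = p_expected,
                 n_boot = as.integer(n_boot), seed = seed,
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' A flat key-value document with the fields of [pipeline_config()];
#' arguments passed through `...` override the file.
#'
#' @param path YAML file path.
#' @param ... overrides (e.g. `k_sd = 2`, `seed = 7`).
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, ...) {
  if (!file.exists(path)) ec_stop("config file not found: %s", path)
  cfg <- yaml::read_yaml(path)
  dots <- list(...)
  cfg[names(dots)] <- dots
  do.call(pipeline_config, cfg)
}

#' Run the full landscape-projection analysis
#'
#' Loads the landscape and mutation tables, censuses the landscape,
#' projects the loss-of-function hits, runs the exact binomial test of the
#' observed beneficial count against `p_expected`, tabulates recurrent
#' targets, and — when a CDS FASTA is configured — estimates dNONSENSE/dS
#' with its derived beneficial multiplier and driver fraction. Writes
#' `report.json` (machine-readable; fractions rounded to 3 decimals) and
#' `report.txt` (prose summary) into the output directory. Runs are
#' deterministic for a fixed configuration and seed; partial outputs are
#' removed if any stage fails.
#'
#' @param config a `pipeline_config`.
#' @return Invisibly, a list with `report` (the report structure) and
#'   `paths` (the two files written).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(config$out_dir))
    dir.create(config$out_dir, recursive = TRUE)
  json_path <- file.path(config$out_dir, "report.json")
  txt_path <- file.path(config$out_dir, "report.txt")

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      unlink(c(json_path, txt_path))
      ec_stop("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }

  for (f in c(config$landscape, config$mutations, config$cds))
    if (!file.exists(f)) {
      unlink(c(json_path, txt_path))
      ec_stop("pipeline input file not found: %s", f)
    }

  ec_log("pipeline", "seed = %d, k_sd = %g, p_expected = %g",
         config$seed, config$k_sd, config$p_expected)
  land <- stage("load_landscape",
                read_landscape(config$landscape, config$dialect))
  muts <- stage("load_mutations", read_mutations(config$mutations))
  ec_log("pipeline", "loaded %d pairs, %d mutation records",
         nrow(land$records), nrow(muts$records))

  census <- stage("census", landscape_census(land, config$k_sd))
  tally <- stage("tally", tally_effects(muts, land, config$k_sd))
  binom <- stage("binomial", binomial_point_test(
    tally$n_beneficial, tally$n_lof_in_landscape, config$p_expected))
  excess_p <- stage("binomial", beneficial_excess_test(
    tally$n_beneficial, tally$n_lof_in_landscape, config$p_expected))
  recur <- stage("recurrence", recurrence_table(muts))

  selection <- NULL
  if (!is.null(config$cds)) {
    opp <- stage("opportunities", genome_opportunities(config$cds))
    if (sum(muts$records$mclass == "SYNONYMOUS") >= 1L) {
      selection <- stage("selection", estimate_dnonsense_ds(
        muts, opp, n_boot = config$n_boot, seed = config$seed))
    } else {
      ec_log("selection",
             "no synonymous mutations observed; dNONSENSE/dS skipped")
    }
  }

  r3 <- function(x) round(x, 3)
  report <- list(
    parameters = list(k_sd = config$k_sd, p_expected = config$p_expected,
                      n_boot = config$n_boot, seed = config$seed,
                      dialect = config$dialect),
    census = c(unclass(census),
               list(fraction_beneficial = r3(census$n_beneficial / census$n_records),
                    fraction_deleterious = r3(census$n_deleterious / census$n_records))),
    tally = {
      ta <- unclass(tally)
      attributes(ta) <- list(names = names(ta))  # drop per-hit calls attr
      ta
    },
    binomial = unclass(binom),
    beneficial_excess_p = excess_p,
    recurrence = as.data.frame(recur),
    selection = if (!is.null(selection)) {
      s <- unclass(selection)
      s$ratio <- r3(s$ratio); s$ci <- r3(s$ci)
      s$driver_fraction <- r3(s$driver_fraction)
      s$beneficial_multiplier <- r3(s$beneficial_multiplier)
      s
    })

  stage("report", {
    jsonlite::write_json(report, json_path, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
    writeLines(render_text_report(report), txt_path)
  })
  ec_log("pipeline", "wrote %s and %s", json_path, txt_path)
  invisible(list(report = report, paths = c(json = json_path, txt = txt_path)))
}

# Prose summary mirroring the analysis flow; integer percents.
render_text_report <- function(report) {
  pct <- function(x) sprintf("%d%%", round(100 * x))
  cs <- report$census; ta <- report$tally; bi <- report$binomial
  out <- c(
    "Landscape projection of compensatory loss-of-function mutations",
    "================================================================",
    sprintf("Landscape census (k_sd = %g): of %d gene pairs, %d increased fitness,",
            report$parameters$k_sd, cs$n_records, cs$n_beneficial),
    sprintf("%d decreased fitness and %d were neutral (%s beneficial, %s deleterious).",
            cs$n_deleterious, cs$n_neutral, pct(cs$n_beneficial / cs$n_records),
            pct(cs$n_deleterious / cs$n_records)),
    "",
    sprintf("Evolved lines: %d line(s), %d distinct non-silent (line, gene) hits.",
            ta$n_lines, ta$n_genes_mutated),
    sprintf("Putative loss-of-function hits: %d (%d represented in the landscape):",
            ta$n_lof, ta$n_lof_in_landscape),
    sprintf("  increasing fitness: %d; decreasing: %d; neutral: %d.",
            ta$n_beneficial, ta$n_deleterious, ta$n_neutral),
    "",
    sprintf("Binomial test of %d beneficial among %d represented hits at p = %g:",
            bi$k, bi$n, bi$p_expected),
    sprintf("  P(X = k) = %.3g; upper tail P(X >= k) = %.3g.",
            bi$p_point, report$beneficial_excess_p))
  if (!is.null(report$selection)) {
    se <- report$selection
    out <- c(out, "",
      sprintf("dNONSENSE/dS = %.3g (%d nonsense / %.1f sites vs %d synonymous / %.1f sites),",
              se$ratio, se$observed_nonsense, se$total_nonsense_sites,
              se$observed_synonymous, se$total_syn_sites),
      sprintf("beneficial truncation rate %.2g x dS; estimated driver fraction %s.",
              se$beneficial_multiplier, pct(se$driver_fraction)))
  }
  if (nrow(report$recurrence) > 0) {
    top <- head(report$recurrence, 5)
    out <- c(out, "", "Most recurrently hit genes (distinct lines):",
             sprintf("  %s: %d", top$gene, top$n_lines))
  }
  out
}
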