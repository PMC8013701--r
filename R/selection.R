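# Per-codon mutational opportunity counting under the standard genetic code
# and the opportunity-normalized nonsense/synonymous rate ratio dNONSENSE/dS.

.selection_cache <- new.env(parent = emptyenv())

# All single-nucleotide changes of the 61 non-stop codons with their class
# (SYNONYMOUS / NONSENSE / MISSENSE), built once per session from the
# standard genetic code.
codon_change_table <- function() {
  if (!is.null(.selection_cache$changes)) return(.selection_cache$changes)
  gc <- Biostrings::GENETIC_CODE
  codons <- setdiff(names(gc), .stop_codons)
  tab <- CJ(codon = codons, site = 1:3, alt = .bases)
  tab[, ref := substring(codon, site, site)]
  tab <- tab[ref != alt]
  tab[, mutant := paste0(substring(codon, 1L, site - 1L), alt,
                         substring(codon, site + 1L, 3L))]
  tab[, class := ifelse(mutant %in% .stop_codons, "NONSENSE",
                 ifelse(gc[mutant] == gc[codon], "SYNONYMOUS", "MISSENSE"))]
  setkey(tab, codon)
  .selection_cache$changes <- tab
  tab
}

# Per-codon opportunity counts (9 neighbors each).
codon_opportunity_table <- function() {
  if (!is.null(.selection_cache$opps)) return(.selection_cache$opps)
  tab <- codon_change_table()[, .(
    n_syn      = sum(class == "SYNONYMOUS"),
    n_nonsense = sum(class == "NONSENSE"),
    n_missense = sum(class == "MISSENSE")), by = codon]
  setkey(tab, codon)
  .selection_cache$opps <- tab
  tab
}

#' Classify a single-nucleotide change within a codon
#'
#' Under the standard nuclear genetic code (stops TAA/TAG/TGA), a substitution
#' is SYNONYMOUS if the encoded amino acid is unchanged, NONSENSE if the
#' mutant codon is a stop, and MISSENSE otherwise. Vectorized over all
#' arguments.
#'
#' @param codon reference codon(s), 3-letter DNA strings; stop codons are
#'   rejected.
#' @param site position(s) within the codon, 1..3.
#' @param alt substituted base(s), must differ from the reference base at
#'   `site`.
#' @return Character vector of `"SYNONYMOUS"`, `"NONSENSE"`, `"MISSENSE"`.
#' @export
#' @examples
#' classify_point_mutation("AAA", 1, "T")  # TAA -> NONSENSE
#' classify_point_mutation("AAA", 3, "G")  # AAG, Lys -> SYNONYMOUS
classify_point_mutation <- function(codon, site, alt) {
  codon <- toupper(as.character(codon))
  alt <- toupper(as.character(alt))
  site <- as.integer(site)
  n <- max(length(codon), length(site), length(alt))
  codon <- rep_len(codon, n); site <- rep_len(site, n); alt <- rep_len(alt, n)
  gc <- Biostrings::GENETIC_CODE
  if (!all(codon %in% names(gc)))
    ec_stop("invalid codon '%s'", codon[which(!codon %in% names(gc))[1L]])
  if (any(codon %in% .stop_codons))
    ec_stop("reference codon is a stop codon: %s",
            codon[which(codon %in% .stop_codons)[1L]])
  if (!all(site %in% 1:3)) ec_stop("'site' must be 1, 2 or 3")
  if (!all(alt %in% .bases)) ec_stop("'alt' must be one of A/C/G/T")
  ref <- substring(codon, site, site)
  if (any(ref == alt))
    ec_stop("alt base equals the reference base at site %d of %s",
            site[which(ref == alt)[1L]], codon[which(ref == alt)[1L]])
  mutant <- paste0(substring(codon, 1L, site - 1L), alt,
                   substring(codon, site + 1L, 3L))
  ifelse(mutant %in% .stop_codons, "NONSENSE",
         ifelse(gc[mutant] == gc[codon], "SYNONYMOUS", "MISSENSE"))
}

#' Mutational opportunities of one codon
#'
#' Enumerates the nine single-nucleotide neighbors of a non-stop codon and
#' tallies how many are synonymous, nonsense (premature stop) and missense.
#' The three counts always sum to 9.
#'
#' @param codon a single non-stop codon (3-letter DNA string).
#' @return A `codon_opportunities`: list with `codon`, `n_syn`,
#'   `n_nonsense`, `n_missense`.
#' @export
#' @examples
#' codon_opportunities("TGG")  # Trp: two neighbors are stops
codon_opportunities <- function(codon) {
  cod <- toupper(as.character(codon))
  if (length(cod) != 1L) ec_stop("'codon' must be a single codon")
  if (!cod %in% names(Biostrings::GENETIC_CODE))
    ec_stop("invalid codon '%s'", cod)
  if (cod %in% .stop_codons)
    ec_stop("reference codon is a stop codon: %s", cod)
  tab <- codon_opportunity_table()
  row <- tab[tab$codon == cod]
  structure(list(codon = cod, n_syn = row$n_syn,
                 n_nonsense = row$n_nonsense, n_missense = row$n_missense),
            class = "codon_opportunities")
}

# Split validated CDS sequences into codons, excluding each terminal stop.
# Returns data.table(gene, codon_idx, codon).
cds_codon_table <- function(cds) {
  if (is.character(cds) && length(cds) == 1L)
    cds <- Biostrings::readDNAStringSet(cds)
  if (!methods::is(cds, "DNAStringSet"))
    ec_stop("'cds' must be a DNAStringSet or a FASTA file path")
  if (length(cds) == 0L) ec_stop("CDS set is empty")
  nm <- names(cds)
  if (is.null(nm) || any(!nzchar(nm)))
    ec_stop("every CDS record must be named")
  if (anyDuplicated(nm))
    ec_stop("duplicate CDS record name: %s", nm[anyDuplicated(nm)])
  seqs <- toupper(as.character(cds))
  out <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    s <- seqs[i]; len <- nchar(s)
    if (len %% 3L != 0L)
      ec_stop("CDS '%s' length %d is not a multiple of 3", nm[i], len)
    if (len < 6L) ec_stop("CDS '%s' is too short", nm[i])
    if (grepl("[^ACGT]", s))
      ec_stop("CDS '%s' contains ambiguous or non-DNA characters", nm[i])
    starts <- seq(1L, len, by = 3L)
    codons <- substring(s, starts, starts + 2L)
    if (codons[1L] != "ATG")
      ec_stop("CDS '%s' does not start with ATG", nm[i])
    if (!codons[length(codons)] %in% .stop_codons)
      ec_stop("CDS '%s' does not end with a stop codon", nm[i])
    internal <- codons[-length(codons)]
    if (any(internal %in% .stop_codons))
      ec_stop("CDS '%s' contains an internal stop codon at codon %d",
              nm[i], which(internal %in% .stop_codons)[1L])
    out[[i]] <- data.table(gene = nm[i],
                           codon_idx = seq_along(internal), codon = internal)
  }
  rbindlist(out)
}

#' Genome-wide mutational opportunity summary
#'
#' Validates a CDS set (in-frame, ATG start, terminal stop, no internal stop,
#' unambiguous bases) and sums per-codon opportunity counts over every codon
#' except the terminal stop. Counts are divided by 3 to express synonymous
#' and nonsense opportunities in site units, the denominators of
#' dNONSENSE/dS.
#'
#' @param cds a `Biostrings::DNAStringSet` of coding sequences (one record
#'   per gene, named), or the path to a FASTA file of them (read uppercase).
#' @return An `opportunity_summary`: list with `total_syn_sites`,
#'   `total_nonsense_sites`, `total_missense_sites`, `n_codons` and a
#'   `per_gene` `data.table`.
#' @export
genome_opportunities <- function(cds) {
  codons <- cds_codon_table(cds)
  opp <- codon_opportunity_table()
  merged <- opp[codons, on = "codon"]
  per_gene <- merged[, .(
    n_codons = .N,
    syn_sites      = sum(n_syn) / 3,
    nonsense_sites = sum(n_nonsense) / 3,
    missense_sites = sum(n_missense) / 3), by = gene]
  structure(
    list(total_syn_sites      = sum(per_gene$syn_sites),
         total_nonsense_sites = sum(per_gene$nonsense_sites),
         total_missense_sites = sum(per_gene$missense_sites),
         n_codons = sum(per_gene$n_codons),
         per_gene = per_gene),
    class = "opportunity_summary")
}

#' Estimate the nonsense-to-synonymous rate ratio dNONSENSE/dS
#'
#' `ratio = (observed nonsense / nonsense sites) / (observed synonymous /
#' synonymous sites)`: under purely neutral accumulation the ratio is 1;
#' values above 1 indicate an excess of gene truncations beyond the neutral
#' expectation. Only single-nucleotide NONSENSE and SYNONYMOUS mutations
#' enter the counts (frameshifts inactivate genes but are not substitutions).
#'
#' The derived `beneficial_multiplier = max(0, ratio - 1)` expresses the
#' beneficial truncation rate in units of dS, and
#' `driver_fraction = max(0, (ratio - 1)/ratio)` the implied fraction of
#' nonsense mutations under positive selection. Uncertainty is quantified by
#' a nonparametric bootstrap over the observed mutation records (percentile
#' interval).
#'
#' @param mutations a `mutation_set` of observed mutations.
#' @param opportunities an `opportunity_summary` from
#'   [genome_opportunities()] for the CDS set the mutations occurred in.
#' @param n_boot bootstrap replicates for the ratio CI (default 1000).
#' @param conf_level CI coverage (default 0.95).
#' @param seed optional integer seed for the bootstrap; when given, the
#'   global RNG state is left untouched.
#' @return A `selection_summary`: list with `observed_nonsense`,
#'   `observed_synonymous`, `total_nonsense_sites`, `total_syn_sites`,
#'   `ratio`, `ci` (length-2 numeric), `beneficial_multiplier`,
#'   `driver_fraction`, `n_boot`, `conf_level`.
#' @export
estimate_dnonsense_ds <- function(mutations, opportunities, n_boot = 1000,
                                  conf_level = 0.95, seed = NULL) {
  stopifnot(inherits(mutations, "mutation_set"),
            inherits(opportunities, "opportunity_summary"))
  n_boot <- check_count(n_boot, "n_boot", min = 0L)
  check_number(conf_level, "conf_level", min = 0, max = 1)
  recs <- mutations$records
  n_non <- sum(recs$mclass == "NONSENSE")
  n_syn <- sum(recs$mclass == "SYNONYMOUS")
  n_other <- nrow(recs) - n_non - n_syn
  if (n_syn < 1L)
    ec_stop(paste0("no synonymous mutations observed: dNONSENSE/dS is ",
                   "undefined; collect more mutations or add a pseudo-count"))
  ns_sites <- opportunities$total_nonsense_sites
  sy_sites <- opportunities$total_syn_sites
  if (ns_sites <= 0 || sy_sites <= 0)
    ec_stop("opportunity summary has zero nonsense or synonymous sites")

  ratio_of <- function(k_non, k_syn)
    (k_non / ns_sites) / (k_syn / sy_sites)
  ratio <- ratio_of(n_non, n_syn)

  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0L) {
    # iid resampling of records: class counts are Multinomial(n, phat)
    draw <- function() {
      reps <- rmultinom(n_boot, size = nrow(recs),
                        prob = c(n_non, n_syn, n_other) / nrow(recs))
      ratio_of(reps[1L, ], reps[2L, ])
    }
    boots <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
    alpha <- (1 - conf_level) / 2
    ci <- unname(quantile(boots, c(alpha, 1 - alpha), na.rm = TRUE))
  }

  structure(
    list(observed_nonsense = n_non, observed_synonymous = n_syn,
         total_nonsense_sites = ns_sites, total_syn_sites = sy_sites,
         ratio = ratio, ci = ci,
         beneficial_multiplier = max(0, ratio - 1),
         driver_fraction = driver_fraction(ratio),
         n_boot = n_boot, conf_level = conf_level),
    class = "selection_summary")
}

#' @export
print.codon_opportunities <- function(x, ...) {
  cat(sprintf("<codon_opportunities> %s: %d synonymous, %d nonsense, %d missense (of 9)\n",
              x$codon, x$n_syn, x$n_nonsense, x$n_missense))
  invisible(x)
}

#' @export
print.opportunity_summary <- function(x, ...) {
  cat(sprintf(paste0(
    "<opportunity_summary> %d genes, %d codons\n",
    "  sites: %.2f synonymous, %.2f nonsense, %.2f missense\n"),
    nrow(x$per_gene), x$n_codons, x$total_syn_sites,
    x$total_nonsense_sites, x$total_missense_sites))
  invisible(x)
}

#' @export
print.selection_summary <- function(x, ...) {
  cat(sprintf(paste0(
    "<selection_summary> dNONSENSE/dS = %.3f (%d%% bootstrap CI %.3f-%.3f)\n",
    "  observed: %d nonsense / %.1f sites, %d synonymous / %.1f sites\n",
    "  beneficial multiplier: %.2f x dS; driver fraction: %.1f%%\n"),
    x$ratio, round(100 * x$conf_level), x$ci[1], x$ci[2],
    x$observed_nonsense, x$total_nonsense_sites,
    x$observed_synonymous, x$total_syn_sites,
    x$beneficial_multiplier, 100 * x$driver_fraction))
  invisible(x)
}
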