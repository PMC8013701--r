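# Synthetic-data generators with planted ground truth: landscapes, CDS sets,
# mutation spectra and evolved-line mutation tables. All generators are pure
# functions of their parameters and seed (withr::with_seed leaves the global
# RNG untouched).

#' Simulate a double-mutant fitness landscape with planted interactions
#'
#' Generates all `n_backgrounds x n_partners` gene pairs. Single-mutant
#' fitnesses are drawn uniformly in \[0.5, 1\] (viable deletion strains,
#' wild type = 1). Every pair receives Gaussian measurement noise with
#' standard deviation `sd` on the double-mutant fitness; a planted
#' BENEFICIAL (DELETERIOUS) pair additionally gets `+effect_size`
#' (`-effect_size`). `sd_double` is recorded as `sd`. Fitness values are
#' rounded to 6 decimals (measurement precision) and floored at 0.
#'
#' The default planted fractions (0.14 beneficial, 0.19 deleterious) echo
#' the proportions of significant calls in the genome-scale yeast census
#' (~2.6M beneficial and ~3.3M deleterious of ~18M pairs), so synthetic
#' censuses resemble the real regime. Exact planted counts are
#' `round(frac * n_pairs)`.
#'
#' @param n_backgrounds,n_partners numbers of background and partner genes.
#' @param frac_beneficial,frac_deleterious planted fractions (sum <= 1).
#' @param effect_size planted fitness effect (>= 0); the default is 10 x
#'   `sd`, far from the 3 x SD significance boundary.
#' @param sd Gaussian noise SD of the double-mutant fitness (also recorded
#'   as `sd_double`).
#' @param seed integer seed (mandatory; generation is deterministic).
#' @return List with `landscape` (a `landscape`) and `truth` (a
#'   `landscape_truth`: planted per-pair labels plus the parameters).
#' @export
sim_landscape <- function(n_backgrounds = 10, n_partners = 100,
                          frac_beneficial = 0.14, frac_deleterious = 0.19,
                          effect_size = 10 * sd, sd = 0.02, seed) {
  n_backgrounds <- check_count(n_backgrounds, "n_backgrounds", min = 1L)
  n_partners <- check_count(n_partners, "n_partners", min = 1L)
  check_number(frac_beneficial, "frac_beneficial", min = 0, max = 1)
  check_number(frac_deleterious, "frac_deleterious", min = 0, max = 1)
  if (frac_beneficial + frac_deleterious > 1)
    ec_stop("frac_beneficial + frac_deleterious must not exceed 1")
  check_number(effect_size, "effect_size", min = 0)
  check_number(sd, "sd", min = 0)
  seed <- check_count(seed, "seed")

  n_pairs <- n_backgrounds * n_partners
  n_ben <- round(frac_beneficial * n_pairs)
  n_del <- round(frac_deleterious * n_pairs)

  withr::with_seed(seed, {
    bg <- sprintf("BGENE%03d", seq_len(n_backgrounds))
    pg <- sprintf("PGENE%03d", seq_len(n_partners))
    pairs <- CJ(background_gene = bg, partner_gene = pg, sorted = FALSE)
    fit_bg <- round(runif(n_backgrounds, 0.5, 1), 6)
    fit_pg <- round(runif(n_partners, 0.5, 1), 6)
    label <- rep("NEUTRAL", n_pairs)
    slot <- sample.int(n_pairs, n_ben + n_del)
    label[slot[seq_len(n_ben)]] <- "BENEFICIAL"
    label[slot[seq_len(n_del) + n_ben]] <- "DELETERIOUS"
    pairs[, fitness_background := fit_bg[match(background_gene, bg)]]
    pairs[, fitness_partner := fit_pg[match(partner_gene, pg)]]
    shift <- ifelse(label == "BENEFICIAL", effect_size,
                    ifelse(label == "DELETERIOUS", -effect_size, 0))
    pairs[, fitness_double :=
            round(pmax(0, fitness_background + shift + rnorm(n_pairs, 0, sd)), 6)]
    pairs[, sd_double := sd]
    truth <- structure(
      list(labels = data.table(background_gene = pairs$background_gene,
                               partner_gene = pairs$partner_gene,
                               label = label),
           effect_size = effect_size, sd = sd, seed = seed),
      class = "landscape_truth")
    list(landscape = new_landscape(pairs), truth = truth)
  })
}

#' Simulate a set of coding sequences
#'
#' Each gene starts with ATG, ends with a uniformly chosen stop codon and
#' contains no internal stop. Internal bases are drawn independently with
#' `P(G) = P(C) = gc_fraction / 2` (codons hitting a stop are redrawn).
#' Lengths are sampled from multiples of 3 in `[min_len, max_len]`.
#'
#' @param n_genes number of genes.
#' @param min_len,max_len length bounds in nucleotides, multiples of 3,
#'   `min_len >= 9` (start + one internal codon + stop).
#' @param gc_fraction target GC content of internal codons, in (0, 1);
#'   default 0.4, typical of the yeast nuclear genome.
#' @param seed integer seed (mandatory).
#' @return A named `Biostrings::DNAStringSet` satisfying the
#'   [genome_opportunities()] preconditions.
#' @export
sim_cds <- function(n_genes = 20, min_len = 300, max_len = 600,
                    gc_fraction = 0.4, seed) {
  n_genes <- check_count(n_genes, "n_genes", min = 1L)
  min_len <- check_count(min_len, "min_len", min = 9L)
  max_len <- check_count(max_len, "max_len", min = min_len)
  if (min_len %% 3L != 0L || max_len %% 3L != 0L)
    ec_stop("min_len and max_len must be multiples of 3")
  check_number(gc_fraction, "gc_fraction")
  if (gc_fraction <= 0 || gc_fraction >= 1)
    ec_stop("gc_fraction must be strictly between 0 and 1")
  seed <- check_count(seed, "seed")

  base_p <- c((1 - gc_fraction) / 2, gc_fraction / 2,
              gc_fraction / 2, (1 - gc_fraction) / 2)
  withr::with_seed(seed, {
    lens <- sample(seq(min_len, max_len, by = 3L), n_genes, replace = TRUE)
    seqs <- vapply(lens, function(len) {
      n_int <- len %/% 3L - 2L
      cods <- character(n_int)
      need <- seq_len(n_int)
      while (length(need)) {
        m <- matrix(sample(.bases, 3L * length(need), replace = TRUE,
                           prob = base_p), nrow = 3L)
        cand <- paste0(m[1L, ], m[2L, ], m[3L, ])
        ok <- !cand %in% .stop_codons
        cods[need[ok]] <- cand[ok]
        need <- need[!ok]
      }
      paste0("ATG", paste(cods, collapse = ""), sample(.stop_codons, 1L))
    }, character(1))
    names(seqs) <- sprintf("GENE%03d", seq_len(n_genes))
    Biostrings::DNAStringSet(seqs)
  })
}

#' Simulate a mutation spectrum with a planted nonsense excess
#'
#' Candidate changes are all single-nucleotide substitutions over every
#' codon of the CDS set except terminal stops; candidates are sampled with
#' class-dependent weight (nonsense-creating changes weighted by
#' `nonsense_rate_multiplier`, all others 1), which plants a
#' dNONSENSE/dS of `nonsense_rate_multiplier` in expectation
#' (`1` = neutral accumulation).
#'
#' @param cds a named `DNAStringSet` (e.g. from [sim_cds()]) or FASTA path.
#' @param n_mutations number of mutations to draw (with replacement).
#' @param nonsense_rate_multiplier relative acceptance weight of
#'   nonsense-creating changes (> 0).
#' @param seed integer seed (mandatory).
#' @return List with `mutations` (a `mutation_set` whose records carry gene,
#'   CDS position, ref/alt and class) and `truth` (a `spectrum_truth`:
#'   planted multiplier, realized class counts, seed).
#' @export
sim_mutation_spectrum <- function(cds, n_mutations = 2000,
                                  nonsense_rate_multiplier = 1, seed) {
  n_mutations <- check_count(n_mutations, "n_mutations", min = 1L)
  check_number(nonsense_rate_multiplier, "nonsense_rate_multiplier",
               min = .Machine$double.xmin)
  seed <- check_count(seed, "seed")

  codons <- cds_codon_table(cds)
  changes <- codon_change_table()[codons, on = "codon",
                                  allow.cartesian = TRUE]
  changes <- changes[!is.na(site)]
  w <- ifelse(changes$class == "NONSENSE", nonsense_rate_multiplier, 1)
  withr::with_seed(seed, {
    idx <- sample.int(nrow(changes), n_mutations, replace = TRUE, prob = w)
    sel <- changes[idx]
    rec <- data.table(
      line_id = "pool", background_gene = "ancestor",
      gene = sel$gene, mclass = sel$class,
      cds_position = (sel$codon_idx - 1L) * 3L + sel$site,
      ref = sel$ref, alt = sel$alt)
    ms <- new_mutation_set(rec, provenance = "simulated spectrum")
    counts <- table(factor(rec$mclass,
                           levels = c("SYNONYMOUS", "MISSENSE", "NONSENSE")))
    truth <- structure(
      list(multiplier = nonsense_rate_multiplier,
           class_counts = as.integer(counts),
           class_names = names(counts), seed = seed),
      class = "spectrum_truth")
    list(mutations = ms, truth = truth)
  })
}

#' Simulate evolved-line loss-of-function mutation tables
#'
#' Each evolved line is assigned a background deletion drawn from the
#' landscape's background genes; its loss-of-function hits are sampled
#' without replacement from that background's partner genes, except that
#' each hit independently falls outside the landscape (a fresh `NOVELxxx`
#' gene) with probability `frac_absent`. Hit classes are NONSENSE or
#' FRAMESHIFT with equal probability.
#'
#' @param landscape a `landscape` (e.g. from [sim_landscape()]).
#' @param truth the matching `landscape_truth`; planted labels of sampled
#'   in-landscape hits are attached to the result as attribute
#'   `"planted_calls"` (`ABSENT` for novel genes).
#' @param n_lines number of evolved lines.
#' @param lof_per_line loss-of-function hits per line (>= 0).
#' @param frac_absent probability that a hit lies outside the landscape.
#' @param seed integer seed (mandatory).
#' @return A `mutation_set` loadable by the catalog functions.
#' @export
sim_evolved_lines <- function(landscape, truth, n_lines = 14,
                              lof_per_line = 2, frac_absent = 0.5, seed) {
  stopifnot(inherits(landscape, "landscape"),
            inherits(truth, "landscape_truth"))
  n_lines <- check_count(n_lines, "n_lines", min = 1L)
  lof_per_line <- check_count(lof_per_line, "lof_per_line", min = 0L)
  check_number(frac_absent, "frac_absent", min = 0, max = 1)
  seed <- check_count(seed, "seed")
  recs <- landscape$records
  if (nrow(recs) == 0L) ec_stop("landscape is empty")
  bgs <- unique(recs$background_gene)

  withr::with_seed(seed, {
    line_bg <- sample(bgs, n_lines, replace = TRUE)
    rows <- vector("list", n_lines)
    labels <- vector("list", n_lines)
    novel <- 0L
    for (i in seq_len(n_lines)) {
      partners <- recs[background_gene == line_bg[i], partner_gene]
      n_abs <- rbinom(1L, lof_per_line, frac_absent)
      n_in <- lof_per_line - n_abs
      if (n_in > length(partners))
        ec_stop("line %d requests %d in-landscape hits but background '%s' has only %d partners",
                i, n_in, line_bg[i], length(partners))
      g_in <- if (n_in > 0L) sample(partners, n_in) else character(0)
      g_abs <- if (n_abs > 0L) sprintf("NOVEL%03d", novel + seq_len(n_abs))
               else character(0)
      novel <- novel + n_abs
      genes <- c(g_in, g_abs)
      if (length(genes) == 0L) { rows[[i]] <- NULL; next }
      rows[[i]] <- data.table(
        line_id = sprintf("line%02d", i), background_gene = line_bg[i],
        gene = genes,
        mclass = sample(.lof_classes, length(genes), replace = TRUE))
      lab <- c(truth$labels[data.table(background_gene = line_bg[i],
                                       partner_gene = g_in),
                            on = c("background_gene", "partner_gene"), label],
               rep("ABSENT", n_abs))
      labels[[i]] <- data.table(line_id = sprintf("line%02d", i),
                                gene = genes, planted = lab)
    }
    rec <- rbindlist(rows)
    if (is.null(rec) || nrow(rec) == 0L)
      rec <- data.table(line_id = character(), background_gene = character(),
                        gene = character(), mclass = character())
    ms <- new_mutation_set(rec, provenance = "simulated evolved lines")
    attr(ms, "planted_calls") <- rbindlist(labels)
    ms
  })
}
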