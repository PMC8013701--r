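# Shared fixture builders. All fixtures are constructed in code.

landscape_header <- paste("background_gene", "partner_gene",
                          "fitness_background", "fitness_partner",
                          "fitness_double", "sd_double", sep = "\t")

write_landscape_file <- function(rows, path = tempfile(fileext = ".tsv")) {
  writeLines(c(landscape_header, rows), path)
  path
}

mutation_header <- paste("line_id", "background_gene", "gene",
                         "mutation_class", sep = "\t")

write_mutation_file <- function(rows, path = tempfile(fileext = ".tsv")) {
  writeLines(c(mutation_header, rows), path)
  path
}

# A small landscape data frame with calls forced far from the 3xSD boundary:
# per background gene "bgN", partner "benN" is beneficial (+0.15),
# "delN" deleterious (-0.2) and "neuN" neutral (delta 0), all at sd 0.01.
forced_landscape_df <- function(n_backgrounds = 5) {
  do.call(rbind, lapply(seq_len(n_backgrounds), function(i) {
    data.frame(
      background_gene = sprintf("bg%d", i),
      partner_gene = sprintf(c("ben%d", "del%d", "neu%d"), i),
      fitness_background = 0.8,
      fitness_partner = 0.9,
      fitness_double = c(0.95, 0.6, 0.8),
      sd_double = 0.01)
  }))
}

random_landscape_df <- function(n, seed) {
  withr::with_seed(seed, data.frame(
    background_gene = sprintf("b%03d", seq_len(n)),
    partner_gene = sprintf("p%03d", sample.int(n)),
    fitness_background = round(runif(n, 0.5, 1), 6),
    fitness_partner = round(runif(n, 0.5, 1), 6),
    fitness_double = round(runif(n, 0, 1.2), 6),
    sd_double = round(runif(n, 0, 0.05), 6)))
}

random_mutation_df <- function(n, seed) {
  withr::with_seed(seed, data.frame(
    line_id = sprintf("L%02d", sample.int(6, n, replace = TRUE)),
    background_gene = "bg0",
    gene = sprintf("g%02d", sample.int(12, n, replace = TRUE)),
    mclass = sample(c("NONSENSE", "FRAMESHIFT", "MISSENSE", "SYNONYMOUS",
                      "OTHER"), n, replace = TRUE)))
}
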