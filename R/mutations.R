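# Evolved-line mutation catalog: loader, loss-of-function filter and
# per-(line, gene) deduplication.

.mutation_cols <- c("line_id", "background_gene", "gene", "mutation_class")
.mclass_synonyms <- c("TRUNCATION" = "NONSENSE", "STOP_GAINED" = "NONSENSE")

normalize_mclass <- function(x) {
  up <- toupper(trimws(x))
  hit <- match(up, names(.mclass_synonyms))
  up[!is.na(hit)] <- .mclass_synonyms[hit[!is.na(hit)]]
  up
}

new_mutation_set <- function(records, provenance = "in-memory") {
  records <- as.data.table(records)
  need <- c("line_id", "background_gene", "gene", "mclass")
  if (!all(need %in% names(records)))
    ec_stop("mutation records lack required column(s): %s",
            paste(setdiff(need, names(records)), collapse = ", "))
  for (opt in c("cds_position", "ref", "alt"))
    if (!opt %in% names(records))
      set(records, j = opt,
          value = if (opt == "cds_position") NA_integer_ else NA_character_)
  validate_mutation_records(records)
  structure(list(records = records, provenance = provenance),
            class = "mutation_set")
}

validate_mutation_records <- function(records) {
  bad <- !records$mclass %in% .mclasses
  if (any(bad))
    ec_stop("invalid mutation class '%s'", records$mclass[which(bad)[1L]])
  if (any(!nzchar(records$line_id)) || any(!nzchar(records$gene)))
    ec_stop("line_id and gene must be non-empty strings")
  has_ba <- !is.na(records$ref) & !is.na(records$alt)
  if (any(has_ba)) {
    r <- records$ref[has_ba]; a <- records$alt[has_ba]
    if (!all(r %in% .bases) || !all(a %in% .bases))
      ec_stop("ref/alt must be single bases A/C/G/T")
    if (any(r == a)) ec_stop("ref and alt bases must differ")
  }
  invisible(records)
}

#' Build a mutation set from a data frame
#'
#' @param df data frame with columns `line_id`, `background_gene`, `gene` and
#'   either `mclass` or `mutation_class` (values among NONSENSE, FRAMESHIFT,
#'   MISSENSE, SYNONYMOUS, OTHER; `truncation` and `stop_gained` are accepted
#'   as synonyms of NONSENSE, case-insensitively). Optional columns:
#'   `cds_position` (1-based within the CDS), `ref`, `alt`.
#' @param provenance source label stored with the set.
#' @return A `mutation_set` object.
#' @export
as_mutation_set <- function(df, provenance = "in-memory") {
  df <- as.data.table(df)
  if ("mutation_class" %in% names(df) && !"mclass" %in% names(df))
    setnames(df, "mutation_class", "mclass")
  if ("mclass" %in% names(df)) df[, mclass := normalize_mclass(mclass)]
  new_mutation_set(df, provenance)
}

#' Read an evolved-line mutation table
#'
#' Expects a tab-separated file with header columns `line_id`,
#' `background_gene`, `gene`, `mutation_class` and optionally
#' `cds_position`, `ref`, `alt`. Mutation classes are matched
#' case-insensitively; `truncation` and `stop_gained` map to NONSENSE.
#'
#' @param path path to the TSV file.
#' @return A `mutation_set`; `$provenance` records the file name.
#' @seealso [filter_lof()], [unique_lof_genes()], [tally_effects()]
#' @export
read_mutations <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    ec_stop("mutation file not found: %s", path)
  raw <- fread(path, sep = "\t", header = TRUE, colClasses = "character",
               na.strings = NULL, quote = "")
  miss <- setdiff(.mutation_cols, names(raw))
  if (length(miss))
    ec_stop("mutation file %s lacks required column(s): %s", path,
            paste(miss, collapse = ", "))
  mcl <- normalize_mclass(raw$mutation_class)
  bad <- !mcl %in% .mclasses
  if (any(bad)) {
    i <- which(bad)[1L]
    ec_stop("parse error in %s: unknown mutation_class '%s' at line %d",
            path, raw$mutation_class[i], i + 1L)
  }
  rec <- data.table(line_id = raw$line_id,
                    background_gene = raw$background_gene,
                    gene = raw$gene, mclass = mcl)
  rec[, cds_position := if ("cds_position" %in% names(raw))
        suppressWarnings(as.integer(raw$cds_position)) else NA_integer_]
  for (b in c("ref", "alt"))
    set(rec, j = b, value = if (b %in% names(raw)) {
      v <- toupper(trimws(raw[[b]])); v[!nzchar(v)] <- NA_character_; v
    } else NA_character_)
  new_mutation_set(rec, provenance = basename(path))
}

#' Write a mutation set to a TSV file
#'
#' @param mutations a `mutation_set`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mutations <- function(mutations, path) {
  stopifnot(inherits(mutations, "mutation_set"))
  out <- copy(mutations$records)
  setnames(out, "mclass", "mutation_class")
  fwrite(out, path, sep = "\t", quote = FALSE, na = "")
  invisible(path)
}

#' Keep putative loss-of-function mutations
#'
#' Retains exactly the NONSENSE (truncation) and FRAMESHIFT records — the
#' classes assumed to inactivate the gene — preserving record order.
#' Idempotent.
#'
#' @param mutations a `mutation_set`.
#' @return A `mutation_set` containing only loss-of-function records.
#' @export
filter_lof <- function(mutations) {
  stopifnot(inherits(mutations, "mutation_set"))
  new_mutation_set(mutations$records[mclass %in% .lof_classes],
                   provenance = mutations$provenance)
}

#' Deduplicated loss-of-function gene hits
#'
#' Loss-of-function records collapsed so that each `(line_id, gene)` pair
#' contributes once (the counting unit of per-line mutated-gene tallies),
#' with the line's background deletion carried through.
#'
#' @param mutations a `mutation_set`.
#' @return A `data.table` with columns `line_id`, `background_gene`, `gene`,
#'   one row per unique loss-of-function (line, gene) hit.
#' @export
unique_lof_genes <- function(mutations) {
  stopifnot(inherits(mutations, "mutation_set"))
  recs <- mutations$records
  conflict <- recs[, uniqueN(background_gene), by = line_id][V1 > 1L]
  if (nrow(conflict))
    ec_stop("line '%s' is annotated with more than one background deletion",
            conflict$line_id[1L])
  lof <- recs[mclass %in% .lof_classes]
  unique(lof[, .(line_id, background_gene, gene)],
         by = c("line_id", "gene"))
}

#' @export
print.mutation_set <- function(x, ...) {
  tab <- table(x$records$mclass)
  cat(sprintf("<mutation_set> %d records across %d line(s) [%s]\n",
              nrow(x$records), uniqueN(x$records$line_id), x$provenance))
  cat(sprintf("  classes: %s\n",
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  invisible(x)
}
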