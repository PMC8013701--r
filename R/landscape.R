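# Double-mutant fitness landscape: container, loaders, and the k*SD
# interaction classifier.

.landscape_cols <- c("background_gene", "partner_gene",
                     "fitness_background", "fitness_partner",
                     "fitness_double", "sd_double")

# Published SGA table layout -> canonical column names. Strain IDs carry an
# allele/position suffix after the first underscore, stripped on read.
.sga_raw_map <- c(
  "Query Strain ID"                           = "background_gene",
  "Array Strain ID"                           = "partner_gene",
  "Query single mutant fitness (SMF)"         = "fitness_background",
  "Array SMF"                                 = "fitness_partner",
  "Double mutant fitness"                     = "fitness_double",
  "Double mutant fitness standard deviation"  = "sd_double")

new_landscape <- function(records, n_skipped = 0L, dialect = "simple") {
  records <- as.data.table(records)
  if (!all(.landscape_cols %in% names(records)))
    ec_stop("landscape records lack required columns: %s",
            paste(setdiff(.landscape_cols, names(records)), collapse = ", "))
  if (!".row" %in% names(records)) records[, ".row" := seq_len(.N)]
  validate_landscape_records(records)
  setkeyv(records, c("background_gene", "partner_gene"))
  structure(
    list(records = records, n_skipped = as.integer(n_skipped),
         dialect = dialect),
    class = "landscape")
}

validate_landscape_records <- function(records) {
  for (cl in .landscape_cols[3:5]) {
    v <- records[[cl]]
    if (any(!is.finite(v) | v < 0))
      ec_stop("column %s contains non-finite or negative fitness values", cl)
  }
  if (any(!is.finite(records$sd_double) | records$sd_double < 0))
    ec_stop("sd_double contains non-finite or negative values")
  if (any(!nzchar(records$background_gene)) || any(!nzchar(records$partner_gene)))
    ec_stop("gene identifiers must be non-empty strings")
  dup <- duplicated(records, by = c("background_gene", "partner_gene"))
  if (any(dup)) {
    i <- which(dup)[1L]
    ec_stop("duplicate (background, partner) pair: (%s, %s)",
            records$background_gene[i], records$partner_gene[i])
  }
  invisible(records)
}

#' Build a landscape from a data frame
#'
#' Wraps a data frame of gene-pair fitness measurements into a `landscape`
#' object with an index for O(log n) pair lookup. Columns required:
#' `background_gene`, `partner_gene`, `fitness_background`, `fitness_partner`,
#' `fitness_double`, `sd_double`. Fitness values are relative to wild type
#' (wild type = 1) and must be finite and non-negative; `sd_double` is the
#' standard deviation of the double-mutant fitness estimate.
#'
#' @param df data frame with the six landscape columns.
#' @return A `landscape` object.
#' @export
#' @examples
#' as_landscape(data.frame(
#'   background_gene = "RPB9", partner_gene = "WHI2",
#'   fitness_background = 0.8, fitness_partner = 0.95,
#'   fitness_double = 0.9, sd_double = 0.02))
as_landscape <- function(df) new_landscape(df)

#' Read a double-mutant fitness landscape from a TSV file
#'
#' Two dialects are supported. `"simple"` expects the canonical six columns
#' (`background_gene`, `partner_gene`, `fitness_background`,
#' `fitness_partner`, `fitness_double`, `sd_double`). `"sga-raw"` accepts the
#' published genome-scale SGA table layout (Query/Array strain IDs and their
#' single- and double-mutant fitness columns); strain identifiers are
#' truncated at the first underscore to bare gene names.
#'
#' Rows with a missing fitness or SD field are skipped (never imputed); the
#' skip count is logged and stored in the returned object.
#'
#' @param path path to a tab-separated file with a header row.
#' @param dialect `"simple"` (default) or `"sga-raw"`.
#' @return A `landscape` object; `$n_skipped` holds the skipped-row count.
#' @seealso [write_landscape()], [landscape_census()], [lookup_effect()]
#' @export
read_landscape <- function(path, dialect = c("simple", "sga-raw")) {
  if (is.character(dialect) && length(dialect) == 1L &&
      !dialect %in% c("simple", "sga-raw"))
    ec_stop("unknown landscape dialect '%s' (expected 'simple' or 'sga-raw')",
            dialect)
  dialect <- match.arg(dialect)
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    ec_stop("landscape file not found: %s", path)

  raw <- fread(path, sep = "\t", header = TRUE, colClasses = "character",
               na.strings = NULL, quote = "")
  if (dialect == "sga-raw") {
    miss <- setdiff(names(.sga_raw_map), names(raw))
    if (length(miss))
      ec_stop("sga-raw landscape file lacks column(s): %s",
              paste(miss, collapse = "; "))
    raw <- raw[, names(.sga_raw_map), with = FALSE]
    setnames(raw, names(.sga_raw_map), unname(.sga_raw_map))
    raw[, background_gene := sub("_.*$", "", background_gene)]
    raw[, partner_gene := sub("_.*$", "", partner_gene)]
  } else {
    miss <- setdiff(.landscape_cols, names(raw))
    if (length(miss))
      ec_stop("simple landscape file lacks column(s): %s",
              paste(miss, collapse = ", "))
    raw <- raw[, .landscape_cols, with = FALSE]
  }

  skip <- rep(FALSE, nrow(raw))
  for (cl in .landscape_cols[3:6]) {
    s <- trimws(raw[[cl]])
    is_missing <- !nzchar(s) | toupper(s) == "NA"
    v <- suppressWarnings(as.numeric(s))
    bad <- !is_missing & is.na(v)
    if (any(bad)) {
      i <- which(bad)[1L]
      ec_stop("parse error in %s: non-numeric value '%s' in column %s at line %d",
              path, s[i], cl, i + 1L)  # +1 for the header row
    }
    skip <- skip | is_missing
    set(raw, j = cl, value = v)
  }
  n_skipped <- sum(skip)
  if (n_skipped > 0L)
    ec_log("load_landscape", "skipped %d row(s) with missing fitness or SD in %s",
           n_skipped, path)
  new_landscape(raw[!skip], n_skipped = n_skipped, dialect = dialect)
}

#' Write a landscape to a simple-dialect TSV file
#'
#' Writes the canonical six-column tab-separated representation, preserving
#' the row order of the source file (or generation order). A file written by
#' `write_landscape()` reloads to an identical landscape and rewrites
#' field-for-field identically.
#'
#' @param landscape a `landscape` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_landscape <- function(landscape, path) {
  stopifnot(inherits(landscape, "landscape"))
  out <- copy(landscape$records)[order(.row)][, .row := NULL]
  fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

# Vectorized trichotomous call. Strict inequalities: |delta| exactly at the
# threshold is NEUTRAL.
classify_delta <- function(delta, sd_double, k_sd) {
  thr <- k_sd * sd_double
  ifelse(delta > thr, "BENEFICIAL",
         ifelse(delta < -thr, "DELETERIOUS", "NEUTRAL"))
}

new_effect_call <- function(call, delta = NA_real_, threshold = NA_real_) {
  structure(list(call = call, delta = delta, threshold = threshold),
            class = "effect_call")
}

#' Classify one gene-pair interaction by the k*SD rule
#'
#' The second deletion is called significant when the absolute difference
#' between the double-mutant fitness and the background single-mutant fitness
#' exceeds `k_sd` times the standard deviation of the double-mutant fitness:
#' `delta = fitness_double - fitness_background`, BENEFICIAL if
#' `delta > k_sd * sd_double`, DELETERIOUS if `delta < -k_sd * sd_double`,
#' NEUTRAL otherwise (ties are NEUTRAL; the inequalities are strict).
#'
#' @param record a list or one-row data frame with `fitness_background`,
#'   `fitness_double` and `sd_double` (fields as in [as_landscape()]).
#' @param k_sd positive significance multiple; default 3.
#' @return An `effect_call`: list with `call` (one of `"BENEFICIAL"`,
#'   `"DELETERIOUS"`, `"NEUTRAL"`), `delta`, and `threshold = k_sd * sd_double`.
#' @export
#' @examples
#' classify_interaction(list(fitness_background = 0.8,
#'                           fitness_double = 0.9, sd_double = 0.02))
classify_interaction <- function(record, k_sd = 3) {
  check_number(k_sd, "k_sd", min = .Machine$double.xmin)
  fb <- record[["fitness_background"]]
  fd <- record[["fitness_double"]]
  sd <- record[["sd_double"]]
  if (is.null(fb) || is.null(fd) || is.null(sd))
    ec_stop("record must carry fitness_background, fitness_double and sd_double")
  if (!all(is.finite(c(fb, fd, sd))) || sd < 0)
    ec_stop("non-finite fitness/SD values in interaction record")
  delta <- fd - fb
  new_effect_call(classify_delta(delta, sd, k_sd), delta, k_sd * sd)
}

#' Look up and classify a gene pair in a landscape
#'
#' Tries the requested `(background, partner)` orientation first; if absent,
#' tries the reversed orientation and recomputes `delta` against the fitness
#' of the single mutant that plays the requested background role. If the pair
#' is stored in neither orientation the call is `"ABSENT"` (a value, not an
#' error).
#'
#' @param landscape a `landscape` object.
#' @param background background (query) gene identifier.
#' @param partner partner (array) gene identifier.
#' @inheritParams classify_interaction
#' @return An `effect_call`; `call = "ABSENT"` carries `NA` delta/threshold.
#' @export
lookup_effect <- function(landscape, background, partner, k_sd = 3) {
  stopifnot(inherits(landscape, "landscape"))
  recs <- landscape$records
  hit <- recs[list(background, partner), nomatch = NULL]
  if (nrow(hit) == 1L) return(classify_interaction(hit, k_sd))
  rev <- recs[list(partner, background), nomatch = NULL]
  if (nrow(rev) == 1L) {
    # stored partner gene is the requested background: delta against its SMF
    delta <- rev$fitness_double - rev$fitness_partner
    return(new_effect_call(classify_delta(delta, rev$sd_double, k_sd),
                           delta, k_sd * rev$sd_double))
  }
  new_effect_call("ABSENT")
}

#' Census of interaction calls over a whole landscape
#'
#' Applies the k*SD rule to every stored pair and counts beneficial,
#' deleterious and neutral calls. The three counts always sum to the number
#' of records.
#'
#' @inheritParams lookup_effect
#' @return A `landscape_census`: list with `n_beneficial`, `n_deleterious`,
#'   `n_neutral`, `n_records`.
#' @export
landscape_census <- function(landscape, k_sd = 3) {
  stopifnot(inherits(landscape, "landscape"))
  check_number(k_sd, "k_sd", min = .Machine$double.xmin)
  recs <- landscape$records
  if (nrow(recs) == 0L) ec_stop("cannot census an empty landscape")
  calls <- classify_delta(recs$fitness_double - recs$fitness_background,
                          recs$sd_double, k_sd)
  structure(
    list(n_beneficial  = sum(calls == "BENEFICIAL"),
         n_deleterious = sum(calls == "DELETERIOUS"),
         n_neutral     = sum(calls == "NEUTRAL"),
         n_records     = nrow(recs)),
    class = "landscape_census")
}

#' Expected beneficial fraction for a set of background genes
#'
#' The fraction of `(background, partner)` records whose call is BENEFICIAL,
#' restricted to the given background genes. This is the landscape-derived
#' probability that inactivating a random partner gene benefits one of those
#' deletion backgrounds.
#'
#' @inheritParams lookup_effect
#' @param backgrounds character vector of background gene identifiers, each
#'   of which must have at least one partner in the landscape.
#' @return A single probability in \[0, 1\].
#' @export
expected_beneficial_fraction <- function(landscape, backgrounds, k_sd = 3) {
  stopifnot(inherits(landscape, "landscape"))
  backgrounds <- unique(as.character(backgrounds))
  if (length(backgrounds) == 0L) ec_stop("'backgrounds' must be non-empty")
  recs <- landscape$records
  absent <- setdiff(backgrounds, unique(recs$background_gene))
  if (length(absent))
    ec_stop("background gene '%s' has no partners in the landscape", absent[1L])
  sub <- recs[background_gene %in% backgrounds]
  calls <- classify_delta(sub$fitness_double - sub$fitness_background,
                          sub$sd_double, k_sd)
  mean(calls == "BENEFICIAL")
}

#' @export
print.landscape <- function(x, ...) {
  cat(sprintf("<landscape> %d gene pairs (%d backgrounds x %d partner genes), dialect '%s'\n",
              nrow(x$records), uniqueN(x$records$background_gene),
              uniqueN(x$records$partner_gene), x$dialect))
  if (x$n_skipped > 0L)
    cat(sprintf("  %d row(s) skipped on load (missing fitness/SD)\n", x$n_skipped))
  invisible(x)
}

#' @export
print.effect_call <- function(x, ...) {
  if (x$call == "ABSENT") {
    cat("<effect_call> ABSENT (pair not in landscape)\n")
  } else {
    cat(sprintf("<effect_call> %s (delta = %+.4f, threshold = %.4f)\n",
                x$call, x$delta, x$threshold))
  }
  invisible(x)
}

#' @export
print.landscape_census <- function(x, ...) {
  cat(sprintf(
    "<landscape_census> %d pairs: %d beneficial, %d deleterious, %d neutral\n",
    x$n_records, x$n_beneficial, x$n_deleterious, x$n_neutral))
  invisible(x)
}
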