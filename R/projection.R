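# Projection of evolved-line loss-of-function mutations onto the landscape,
# exact binomial statistics and driver-fraction arithmetic.

#' Tally landscape effects of loss-of-function mutations
#'
#' For every unique loss-of-function `(line, gene)` hit (see
#' [unique_lof_genes()]) the pair `(background deletion, mutated gene)` is
#' looked up in the landscape and classified by the k*SD rule. Hits absent
#' from the landscape count toward `n_lof` but not `n_lof_in_landscape`.
#'
#' @param mutations a `mutation_set`.
#' @param landscape a `landscape`.
#' @param k_sd positive significance multiple; default 3.
#' @return An `effect_tally`: list with `n_lines`, `n_genes_mutated`
#'   (distinct non-silent (line, gene) hits), `n_lof`, `n_lof_in_landscape`,
#'   `n_beneficial`, `n_deleterious`, `n_neutral`; the per-hit calls are
#'   attached as attribute `"calls"` (a `data.table`).
#' @export
tally_effects <- function(mutations, landscape, k_sd = 3) {
  stopifnot(inherits(mutations, "mutation_set"), inherits(landscape, "landscape"))
  recs <- mutations$records
  entries <- unique_lof_genes(mutations)
  calls <- if (nrow(entries)) {
    vapply(seq_len(nrow(entries)), function(i)
      lookup_effect(landscape, entries$background_gene[i], entries$gene[i],
                    k_sd)$call,
      character(1))
  } else character(0)
  nonsilent <- recs[mclass != "SYNONYMOUS"]
  tally <- structure(
    list(n_lines = uniqueN(recs$line_id),
         n_genes_mutated = if (nrow(nonsilent))
           nrow(unique(nonsilent[, .(line_id, gene)])) else 0L,
         n_lof = nrow(entries),
         n_lof_in_landscape = sum(calls != "ABSENT"),
         n_beneficial  = sum(calls == "BENEFICIAL"),
         n_deleterious = sum(calls == "DELETERIOUS"),
         n_neutral     = sum(calls == "NEUTRAL")),
    class = "effect_tally")
  attr(tally, "calls") <- cbind(entries, call = calls)
  tally
}

validate_binom_args <- function(k, n, p_expected) {
  k <- check_count(k, "k")
  n <- check_count(n, "n")
  check_number(p_expected, "p_expected", min = 0, max = 1)
  if (k > n) ec_stop("k (%d) must not exceed n (%d)", k, n)
  list(k = k, n = n, p = p_expected)
}

#' Exact binomial point and tail probabilities
#'
#' Computes the exact point probability `P(X = k)` and both tail
#' probabilities for `X ~ Binomial(n, p_expected)`. Probabilities are
#' evaluated in log space internally, so large `n` is handled without a
#' normal approximation.
#'
#' @param k observed number of successes.
#' @param n number of trials.
#' @param p_expected success probability under the null.
#' @return A `binomial_result`: list with `k`, `n`, `p_expected`,
#'   `p_point = P(X = k)`, `p_upper = P(X >= k)`, `p_lower = P(X <= k)`.
#'   These satisfy `p_upper + p_lower - p_point = 1`.
#' @export
#' @examples
#' # one beneficial gene among 26 landscape-represented truncations,
#' # expected beneficial probability 6%:
#' binomial_point_test(1, 26, 0.06)$p_point  # ~0.33
binomial_point_test <- function(k, n, p_expected) {
  a <- validate_binom_args(k, n, p_expected)
  p_point <- dbinom(a$k, a$n, a$p)
  p_upper <- if (a$k == 0L) 1 else
    pbinom(a$k - 1L, a$n, a$p, lower.tail = FALSE)
  p_lower <- pbinom(a$k, a$n, a$p)
  structure(list(k = a$k, n = a$n, p_expected = a$p,
                 p_point = p_point, p_upper = p_upper, p_lower = p_lower),
            class = "binomial_result")
}

#' Upper-tail test for an excess of beneficial mutations
#'
#' Returns `P(X >= k)` for `X ~ Binomial(n, p_expected)`: the probability of
#' observing at least `k_beneficial` beneficial calls if beneficial hits
#' arose at the landscape-expected rate. Small values mean the observed
#' beneficial count exceeds the landscape expectation.
#'
#' @param k_beneficial observed beneficial count.
#' @inheritParams binomial_point_test
#' @return A single probability.
#' @export
beneficial_excess_test <- function(k_beneficial, n, p_expected) {
  a <- validate_binom_args(k_beneficial, n, p_expected)
  if (a$k == 0L) 1 else pbinom(a$k - 1L, a$n, a$p, lower.tail = FALSE)
}

#' Driver fraction implied by a nonsense/synonymous rate ratio
#'
#' Under the decomposition "neutral truncations accumulate at 1 x dS and
#' beneficial ones at (ratio - 1) x dS", the fraction of nonsense mutations
#' that are genuine drivers is `(ratio - 1) / ratio`, floored at 0 (a ratio
#' below 1 implies no inferable driver excess).
#'
#' @param ratio positive dNONSENSE/dS rate ratio.
#' @return A fraction in \[0, 1\].
#' @export
#' @examples
#' driver_fraction(3.6)  # ~0.72, i.e. ~70% of truncations are drivers
driver_fraction <- function(ratio) {
  check_number(ratio, "ratio")
  if (ratio <= 0) ec_stop("'ratio' must be > 0, got %s", ratio)
  max(0, (ratio - 1) / ratio)
}

#' Recurrently mutated genes across evolved lines
#'
#' Counts, for each gene, the number of distinct evolved lines carrying a
#' non-silent (non-synonymous) mutation in it. Recurrent targets — the same
#' gene hit in parallel lines — suggest repeatable adaptive routes.
#'
#' @param mutations a `mutation_set`.
#' @return A `data.table` with columns `gene` and `n_lines`, sorted by
#'   descending `n_lines` (ties by gene name).
#' @export
recurrence_table <- function(mutations) {
  stopifnot(inherits(mutations, "mutation_set"))
  ns <- mutations$records[mclass != "SYNONYMOUS"]
  if (nrow(ns) == 0L) return(data.table(gene = character(), n_lines = integer()))
  tab <- ns[, .(n_lines = uniqueN(line_id)), by = gene]
  tab[order(-n_lines, gene)]
}

#' @export
print.effect_tally <- function(x, ...) {
  cat(sprintf(paste0(
    "<effect_tally> %d line(s); %d non-silent (line, gene) hits\n",
    "  loss-of-function hits: %d (%d represented in landscape)\n",
    "  calls: %d beneficial, %d deleterious, %d neutral\n"),
    x$n_lines, x$n_genes_mutated, x$n_lof, x$n_lof_in_landscape,
    x$n_beneficial, x$n_deleterious, x$n_neutral))
  invisible(x)
}

#' @export
print.binomial_result <- function(x, ...) {
  cat(sprintf(
    "<binomial_result> k=%d, n=%d, p=%g: P(X=k)=%.4g, P(X>=k)=%.4g, P(X<=k)=%.4g\n",
    x$k, x$n, x$p_expected, x$p_point, x$p_upper, x$p_lower))
  invisible(x)
}
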