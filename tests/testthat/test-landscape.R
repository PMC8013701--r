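test_that("simple-dialect parsing loads complete rows and skips incomplete ones", {
  f <- write_landscape_file(c(
    "g1\tp1\t0.8\t0.9\t0.85\t0.02",
    "g1\tp2\t0.8\t0.7\t0.6\t0.01",
    "g2\tp1\t0.9\t0.9\t0.95\t0.03"))
  l <- read_landscape(f)
  expect_s3_class(l, "landscape")
  expect_equal(nrow(l$records), 3L)
  expect_equal(l$n_skipped, 0L)

  f2 <- write_landscape_file(c(
    "g1\tp1\t0.8\t0.9\t0.85\t0.02",
    "g1\tp2\t0.8\t0.7\t0.6\t"))
  expect_message(l2 <- read_landscape(f2), "skipped 1")
  expect_equal(nrow(l2$records), 1L)
  expect_equal(l2$n_skipped, 1L)
})

test_that("duplicate pairs, unknown dialects and malformed numerics are rejected", {
  dup <- write_landscape_file(c(
    "g1\tp1\t0.8\t0.9\t0.85\t0.02",
    "g1\tp1\t0.8\t0.9\t0.80\t0.02"))
  expect_error(read_landscape(dup), "duplicate")

  ok <- write_landscape_file("g1\tp1\t0.8\t0.9\t0.85\t0.02")
  expect_error(read_landscape(ok, dialect = "costanzo"), "unknown landscape dialect")

  bad <- write_landscape_file(c(
    "g1\tp1\t0.8\t0.9\t0.85\t0.02",
    "g1\tp2\t0.8\t0.9\tabc\t0.02"))
  expect_error(read_landscape(bad), "line 3")
  expect_error(read_landscape(tempfile()), "not found")
})

test_that("sga-raw dialect maps the SGA columns and strips strain suffixes", {
  hdr <- paste("Query Strain ID", "Array Strain ID",
               "Query single mutant fitness (SMF)", "Array SMF",
               "Double mutant fitness",
               "Double mutant fitness standard deviation", sep = "\t")
  f <- tempfile(fileext = ".tsv")
  writeLines(c(hdr,
               "YAL002W_sn123\tYBR001C_dma45\t0.85\t0.92\t0.95\t0.015",
               "YAL003W_sn124\tYBR002C_dma46\t0.70\t0.88\t0.55\t0.020"), f)
  l <- read_landscape(f, dialect = "sga-raw")
  expect_equal(sort(l$records$background_gene), c("YAL002W", "YAL003W"))
  expect_equal(sort(l$records$partner_gene), c("YBR001C", "YBR002C"))
  eff <- lookup_effect(l, "YAL002W", "YBR001C")
  expect_equal(eff$call, "BENEFICIAL")
  expect_equal(eff$delta, 0.10)
})

test_that("the k*SD classifier applies strict inequalities around the threshold", {
  ben <- classify_interaction(list(fitness_background = 0.8,
                                   fitness_double = 0.9, sd_double = 0.02))
  expect_equal(ben$call, "BENEFICIAL")
  expect_equal(ben$delta, 0.1)
  expect_equal(ben$threshold, 0.06)

  neu <- classify_interaction(list(fitness_background = 1,
                                   fitness_double = 1, sd_double = 0.01))
  expect_equal(neu$call, "NEUTRAL")

  # |delta| exactly at k_sd * sd is NEUTRAL (strict inequality); values
  # chosen exactly representable in binary so the tie is exact
  tie <- classify_interaction(list(fitness_background = 0.5,
                                   fitness_double = 1.25,
                                   sd_double = 0.25), k_sd = 3)
  expect_equal(tie$call, "NEUTRAL")

  # sd = 0: any non-zero delta is significant, zero delta neutral
  expect_equal(classify_interaction(list(fitness_background = 0.8,
                                         fitness_double = 0.8001,
                                         sd_double = 0))$call, "BENEFICIAL")
  expect_equal(classify_interaction(list(fitness_background = 0.8,
                                         fitness_double = 0.8,
                                         sd_double = 0))$call, "NEUTRAL")
  expect_error(classify_interaction(list(fitness_background = NA_real_,
                                         fitness_double = 1, sd_double = 0.1)),
               "non-finite")
  expect_error(classify_interaction(list(fitness_background = 1,
                                         fitness_double = 1, sd_double = 0.1),
                                    k_sd = 0), "k_sd")
})

test_that("classification is antisymmetric in delta and monotone in k_sd", {
  withr::with_seed(42, {
    delta <- runif(200, -0.2, 0.2)
    sd <- runif(200, 0, 0.05)
  })
  call_of <- function(d, s, k = 3)
    classify_interaction(list(fitness_background = 1, fitness_double = 1 + d,
                              sd_double = s), k)$call
  for (i in seq_len(200)) {
    a <- call_of(delta[i], sd[i])
    b <- call_of(-delta[i], sd[i])
    expect_equal(b, switch(a, BENEFICIAL = "DELETERIOUS",
                           DELETERIOUS = "BENEFICIAL", NEUTRAL = "NEUTRAL"))
    # increasing k_sd never converts NEUTRAL into a significant call
    if (a == "NEUTRAL") expect_equal(call_of(delta[i], sd[i], 5), "NEUTRAL")
  }
})

test_that("lookup honors orientation, swaps roles for reversed pairs, else ABSENT", {
  df <- random_landscape_df(50, seed = 7)
  l <- as_landscape(df)

  # stored orientation: identical to classifying the record directly
  r <- df[17, ]
  direct <- classify_interaction(r)
  got <- lookup_effect(l, r$background_gene, r$partner_gene)
  expect_equal(got$call, direct$call)
  expect_equal(got$delta, direct$delta)

  # reversed orientation: role-swap oracle recomputes delta against the
  # single-mutant fitness of the requested background (the stored partner)
  for (i in c(1, 9, 23, 50)) {
    r <- df[i, ]
    swapped <- classify_interaction(list(
      fitness_background = r$fitness_partner,
      fitness_double = r$fitness_double, sd_double = r$sd_double))
    got <- lookup_effect(l, r$partner_gene, r$background_gene)
    expect_equal(got$call, swapped$call)
    expect_equal(got$delta, swapped$delta)
  }

  expect_equal(lookup_effect(l, "nope1", "nope2")$call, "ABSENT")
})

test_that("the census conserves record counts and handles degenerate inputs", {
  df <- random_landscape_df(200, seed = 3)
  cen <- landscape_census(as_landscape(df))
  expect_equal(cen$n_beneficial + cen$n_deleterious + cen$n_neutral,
               cen$n_records)
  expect_equal(cen$n_records, 200L)

  flat <- data.frame(background_gene = sprintf("b%d", 1:10),
                     partner_gene = "p1", fitness_background = 0.8,
                     fitness_partner = 0.9, fitness_double = 0.8,
                     sd_double = 0.01)
  cen0 <- landscape_census(as_landscape(flat))
  expect_equal(c(cen0$n_beneficial, cen0$n_deleterious, cen0$n_neutral),
               c(0L, 0L, 10L))

  empty <- as_landscape(forced_landscape_df()[0, ])
  expect_error(landscape_census(empty), "empty")
})

test_that("expected beneficial fraction equals a per-record recount", {
  # one background, 2 beneficial of 10 partners
  df <- data.frame(background_gene = "bg1",
                   partner_gene = sprintf("p%d", 1:10),
                   fitness_background = 0.8, fitness_partner = 0.9,
                   fitness_double = c(0.95, 0.95, rep(0.8, 8)),
                   sd_double = 0.01)
  expect_equal(expected_beneficial_fraction(as_landscape(df), "bg1"), 0.2)

  flat <- forced_landscape_df(4)
  flat$fitness_double <- 0.8  # all neutral
  expect_equal(expected_beneficial_fraction(as_landscape(flat),
                                            c("bg1", "bg2")), 0)

  # multi-background random landscape vs brute-force recount
  df2 <- random_landscape_df(120, seed = 9)
  df2$background_gene <- rep(sprintf("bg%d", 1:4), each = 30)
  df2$partner_gene <- sprintf("p%03d", 1:120)
  l2 <- as_landscape(df2)
  bgs <- c("bg2", "bg4")
  recount <- {
    sub <- df2[df2$background_gene %in% bgs, ]
    calls <- vapply(seq_len(nrow(sub)), function(i)
      classify_interaction(sub[i, ])$call, character(1))
    mean(calls == "BENEFICIAL")
  }
  expect_equal(expected_beneficial_fraction(l2, bgs), recount)

  expect_error(expected_beneficial_fraction(l2, c("bg1", "missing")),
               "missing")
})

test_that("write/load round-trips a simple-dialect file field-for-field", {
  sim <- sim_landscape(n_backgrounds = 4, n_partners = 25, seed = 21)
  f1 <- tempfile(fileext = ".tsv")
  write_landscape(sim$landscape, f1)
  l2 <- read_landscape(f1)
  f2 <- tempfile(fileext = ".tsv")
  write_landscape(l2, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_equal(nrow(l2$records), 100L)
})
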