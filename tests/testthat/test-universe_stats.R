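table1 <- function() {
  space_table(
    5.64e9, 2.90e9,
    region_total  = c(LC = 4.14e8, TM = 3.74e8, CC = 6.78e7, SP = 5.43e7),
    region_within = c(LC = 2.72e8, TM = 1.20e8, CC = 4.65e7, SP = 4.62e7)
  )
}

test_that("percent_table reproduces the published percentage cells", {
  pct <- percent_table(table1())
  row1 <- pct[pct$space == "total_space", ]
  row2 <- pct[pct$space == "domain_space", ]
  expect_equal(row1$all_proteins, 100)
  expect_equal(row1$LC, 7.3)
  expect_equal(row1$TM, 6.6)
  expect_equal(row1$CC, 1.2)
  expect_equal(row1$SP, 1.0)
  expect_equal(row1$all_regions, 16.1)
  expect_equal(row2$all_proteins, 51.4)
  expect_equal(row2$LC, 9.4)
  expect_equal(row2$TM, 4.1)
  expect_equal(row2$CC, 1.6)
  expect_equal(row2$SP, 1.6)
  expect_equal(row2$all_regions, 16.7)
})

test_that("percent_table handles degenerate and full-coverage inputs", {
  st <- space_table(100, 100)
  expect_equal(percent_table(st)$all_proteins[2], 100.0)
  expect_error(percent_table(space_table(100, 0)), "domain_aa")
})

test_that("darkmatter_summary arithmetic and validation", {
  s <- darkmatter_summary(5.64e9, 2.90e9, 5.09e8)
  expect_equal(s$pct_classic_dark, 48.6)
  expect_equal(s$pct_expanded_dark, 39.6)
  expect_equal(s$pct_short_linker, 9.0)

  s <- darkmatter_summary(100, 100, 0)
  expect_equal(s$pct_classic_dark, 0)
  expect_equal(s$pct_expanded_dark, 0)

  s <- darkmatter_summary(100, 40, 10)
  expect_equal(s$pct_classic_dark, 60)
  expect_equal(s$pct_expanded_dark, 50)

  expect_error(darkmatter_summary(100, 80, 30), "<= total_aa")
  expect_error(darkmatter_summary(0, 0, 0), "total_aa")
})

test_that("classic dark matter and domain coverage always sum to 100", {
  set.seed(3)
  for (i in 1:50) {
    tot <- sample(1e4:1e9, 1)
    dom <- sample.int(tot, 1)
    s <- darkmatter_summary(tot, dom, 0)
    expect_equal(s$pct_domain + s$pct_classic_dark, 100, tolerance = 0.1 / 100)
  }
})

test_that("aggregate_space handles toy proteomes", {
  # one protein, half covered
  tab <- annotation_table(tibble::tibble(seq_id = "p1", length = 100L),
                          hit_row("p1", 1, 50))
  st <- aggregate_space(tab)
  expect_equal(st$summary$total_aa, 100L)
  expect_equal(st$summary$domain_aa, 50L)
  expect_equal(st$summary$pct_domain, 50.0)

  # fully covered + fully dark protein
  tab <- annotation_table(
    tibble::tibble(seq_id = c("p1", "p2"), length = c(100L, 100L)),
    hit_row("p1", 1, 100)
  )
  st <- aggregate_space(tab)
  expect_equal(st$summary$pct_domain, 50.0)
  expect_equal(st$summary$pct_classic_dark, 50.0)
  expect_equal(st$seq_class$fraction_without_domain, 0.5)

  expect_error(aggregate_space(annotation_table(
    tibble::tibble(seq_id = character(), length = integer()))), "empty")
})

test_that("aggregate_space matches planted ground truth exactly", {
  sim <- generate_proteome(generator_config(n_proteins = 800, seed = 42,
                                            with_sequences = FALSE))
  st <- aggregate_space(sim$table)
  expect_equal(st$summary$domain_aa / st$summary$total_aa,
               sim$truth$global_coverage)
  # dark matter equals truth-side accounting from planted segments
  truth_dark <- sum(sim$truth$segments$length[
    sim$truth$segments$class == "dark_matter"])
  expect_equal(st$summary$darkmatter_aa, truth_dark)
})

test_that("aggregation is additive and scale invariant", {
  a <- generate_proteome(generator_config(n_proteins = 120, seed = 1,
                                          with_sequences = FALSE))
  b <- generate_proteome(generator_config(n_proteins = 80, seed = 2,
                                          with_sequences = FALSE))
  bt <- b$table
  bt$proteins$seq_id <- paste0("b_", bt$proteins$seq_id)
  bt$domain_hits$seq_id <- paste0("b_", bt$domain_hits$seq_id)
  bt$regions$seq_id <- paste0("b_", bt$regions$seq_id)
  ab <- annotation_table(
    dplyr::bind_rows(a$table$proteins, bt$proteins),
    dplyr::bind_rows(a$table$domain_hits, bt$domain_hits),
    dplyr::bind_rows(a$table$regions, bt$regions)
  )
  sa <- aggregate_space(a$table); sb <- aggregate_space(bt)
  sab <- aggregate_space(ab)
  expect_equal(sab$summary$total_aa, sa$summary$total_aa + sb$summary$total_aa)
  expect_equal(sab$summary$domain_aa, sa$summary$domain_aa + sb$summary$domain_aa)
  expect_equal(sab$summary$darkmatter_aa,
               sa$summary$darkmatter_aa + sb$summary$darkmatter_aa)
  expect_equal(sab$space$regions$total_aa,
               sa$space$regions$total_aa + sb$space$regions$total_aa)

  # duplicating every protein leaves percentages unchanged
  dup <- a$table
  dup$proteins$seq_id <- paste0("dup_", dup$proteins$seq_id)
  dup$domain_hits$seq_id <- paste0("dup_", dup$domain_hits$seq_id)
  dup$regions$seq_id <- paste0("dup_", dup$regions$seq_id)
  both <- annotation_table(
    dplyr::bind_rows(a$table$proteins, dup$proteins),
    dplyr::bind_rows(a$table$domain_hits, dup$domain_hits),
    dplyr::bind_rows(a$table$regions, dup$regions)
  )
  expect_equal(percent_table(aggregate_space(both)),
               percent_table(aggregate_space(a$table)))
  expect_equal(glance(aggregate_space(both))[, c("pct_domain", "pct_classic_dark",
                                                 "pct_expanded_dark")],
               glance(aggregate_space(a$table))[, c("pct_domain", "pct_classic_dark",
                                                    "pct_expanded_dark")])
})

test_that("phobius TM calls are excluded unless chosen as TM authority", {
  tab <- annotation_table(
    tibble::tibble(seq_id = "p1", length = 100L),
    regions = tibble::tibble(
      seq_id = "p1", region_type = c("TM", "TM"),
      start = c(10L, 50L), end = c(30L, 70L),
      source_tool = c("tmhmm", "phobius")
    )
  )
  st_tm <- aggregate_space(tab)
  st_ph <- aggregate_space(tab, tm_source = "phobius")
  tm_row <- function(s) s$space$regions[s$space$regions$region_type == "TM", ]
  expect_equal(tm_row(st_tm)$total_aa, 21)
  expect_equal(tm_row(st_ph)$total_aa, 21)
})

test_that("compare_releases reports deltas, dark-matter sizes and growth", {
  cmp <- compare_releases(data.frame(
    label = c("r09", "r10", "r11"),
    total_aa = c(2.8e9, 4.2e9, 5.6e9),
    pct_domain = c(47.7, 48.9, 51.4)
  ))
  expect_equal(cmp$deltas$delta_pct_domain, c(1.2, 2.5))
  expect_equal(cmp$total_growth_ratio, 2.0)
  expect_equal(cmp$snapshots$darkmatter_aa[1], 2.8e9 * 0.523)

  same <- compare_releases(data.frame(label = c("a", "b"),
                                      total_aa = c(1e9, 1e9),
                                      pct_domain = c(50, 50)))
  expect_equal(same$deltas$delta_pct_domain, 0)

  expect_error(compare_releases(data.frame(label = "a", total_aa = 1,
                                           pct_domain = 1)), "at least 2")
})

test_that("write_report emits scientific-notation cells and round-trips counts", {
  st <- table1()
  sm <- darkmatter_summary(5.64e9, 2.90e9, 5.09e8)
  d <- withr::local_tempdir()
  paths <- write_report(list(space = st, summary = sm), d)
  expect_true(all(file.exists(paths)))
  txt <- readLines(paths["text"])
  expect_true(any(grepl("2.90E\\+09", txt)))
  expect_true(any(grepl("pct_domain: 51.4", txt)))
  tsv <- readLines(paths["table"])
  expect_true(any(grepl("51.4", tsv)))
  back <- read_space_table_tsv(paths["table"])
  expect_equal(back$total_aa, st$total_aa)
  expect_equal(back$domain_aa, st$domain_aa)
  expect_equal(back$regions, st$regions)

  # empty regions render as zeros
  p2 <- write_report(list(space = space_table(100, 50),
                          summary = darkmatter_summary(100, 50, 10)),
                     d, name = "zero")
  expect_equal(read_space_table_tsv(p2["table"])$regions$total_aa,
               rep(0, 4))
})

test_that("tidy, glance and autoplot methods work on results", {
  sim <- generate_proteome(generator_config(n_proteins = 60, seed = 5,
                                            with_sequences = FALSE))
  st <- aggregate_space(sim$table)
  td <- tidy(st)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 12L)
  g <- glance(st)
  expect_equal(nrow(g), 1L)
  expect_equal(g$pct_domain + g$pct_classic_dark, 100, tolerance = 1e-6)
  expect_s3_class(autoplot(st), "ggplot")

  cmp <- compare_releases(data.frame(label = c("a", "b"),
                                     total_aa = c(1e9, 2e9),
                                     pct_domain = c(40, 45)))
  expect_s3_class(tidy(cmp), "tbl_df")
  expect_equal(glance(cmp)$total_growth_ratio, 2)
  expect_s3_class(autoplot(cmp), "ggplot")
  expect_s3_class(plot_architecture(sim$table), "ggplot")
})
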