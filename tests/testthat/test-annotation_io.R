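test_that("read_fasta counts residues and drops header descriptions", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">p1 some description", "MKV", ">p2", "MK", "VA"), f)
  p <- read_fasta(f)
  expect_equal(p$seq_id, c("p1", "p2"))
  expect_equal(p$length, c(3L, 4L))
  expect_equal(p$sequence, c("MKV", "MKVA"))
})

test_that("read_fasta warns on empty input and errors on duplicate ids", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(0), f)
  expect_warning(p <- read_fasta(f), "no FASTA records")
  expect_equal(nrow(p), 0L)

  writeLines(c(">dup", "MK", ">dup", "VA"), f)
  expect_error(read_fasta(f), "dup")
})

test_that("parse_domtblout maps fields, filters, and handles bad rows", {
  f <- withr::local_tempfile()
  pad <- function(target, query, ifrom, ito, efrom, eto, iev, score) {
    paste(target, "PF00069", 300, query, "-", 500, "1e-28", score, "0.0",
          1, 1, "1e-29", iev, score, "0.0", 1, 116, ifrom, ito, efrom, eto,
          "0.95", "desc here")
  }
  writeLines(c(
    "# comment line",
    pad("Pkinase_Tyr", "p1", 5, 120, 3, 125, "1e-30", "101.5"),
    pad("Backwards", "p1", 50, 40, 50, 40, "1e-5", "20.0")
  ), f)
  expect_warning(h <- parse_domtblout(f), "from > to")
  expect_equal(nrow(h), 1L)
  expect_equal(h$model_name, "Pkinase_Tyr")
  expect_equal(h$model_acc, "PF00069")
  expect_equal(c(h$start, h$end), c(5L, 120L))
  expect_equal(h$evalue, 1e-30)
  expect_equal(h$source, "pfam")

  # envelope coordinates on request
  expect_warning(he <- parse_domtblout(f, coords = "env"))
  expect_equal(c(he$start, he$end), c(3L, 125L))

  # comment-only file -> empty
  writeLines("# only a comment", f)
  expect_equal(nrow(parse_domtblout(f)), 0L)

  # non-numeric coordinate -> error with line number
  writeLines(pad("Bad", "p1", "x", 10, 1, 10, "1e-4", "11.0"), f)
  expect_error(parse_domtblout(f), "line 1")
})

test_that("parse_domtblout applies the optional i-Evalue post-filter", {
  sim <- generate_proteome(generator_config(n_proteins = 30, seed = 3))
  d <- withr::local_tempdir()
  emit_formats(sim, d)
  all <- parse_domtblout(file.path(d, "pfam.domtblout"))
  some <- parse_domtblout(file.path(d, "pfam.domtblout"), max_ievalue = 1e-20)
  expect_true(nrow(some) < nrow(all))
  expect_true(all(some$evalue <= 1e-20))
})

test_that("parse_rpsblast_tab maps query coordinates and normalizes swaps", {
  f <- withr::local_tempfile()
  writeLines(c(
    "p1\tgnl|CDD|223456\t40.00\t100\t55\t0\t10\t109\t1\t100\t1e-20\t95.2",
    "p2\tgnl|CDD|223457\t40.00\t100\t55\t0\t109\t10\t1\t100\t1e-8\t45.0"
  ), f)
  expect_warning(h <- parse_rpsblast_tab(f), "reversed")
  expect_equal(h$seq_id, c("p1", "p2"))
  expect_equal(h$start, c(10L, 10L))
  expect_equal(h$end, c(109L, 109L))
  expect_equal(h$evalue, c(1e-20, 1e-8))
  expect_true(all(h$source == "cdd"))

  writeLines("p1\tonly\tthree", f)
  expect_error(parse_rpsblast_tab(f), "line 1")
})

test_that("parse_tmhmm keeps TMhelix rows only", {
  f <- withr::local_tempfile()
  writeLines(c(
    "p1\tTMHMM2.0\toutside\t1\t6",
    "p1\tTMHMM2.0\tTMhelix\t7\t29",
    "p1\tTMHMM2.0\tinside\t30\t80"
  ), f)
  r <- parse_tmhmm(f)
  expect_equal(nrow(r), 1L)
  expect_equal(r$region_type, "TM")
  expect_equal(c(r$start, r$end), c(7L, 29L))
  expect_equal(r$source_tool, "tmhmm")

  writeLines(c("p1\tTMHMM2.0\tinside\t1\t50", "p1\tTMHMM2.0\toutside\t51\t99"), f)
  expect_equal(nrow(parse_tmhmm(f)), 0L)
})

test_that("parse_seg reads interval-list headers and rejects other dialects", {
  f <- withr::local_tempfile()
  writeLines(c(">p1(12-44) complexity=2.20 (12/2.20/2.50)", "aaagggsssttt"), f)
  r <- parse_seg(f)
  expect_equal(r$region_type, "LC")
  expect_equal(c(r$start, r$end), c(12L, 44L))

  writeLines(c(">p1 plain fasta header", "MKVLA"), f)
  expect_error(parse_seg(f), "seg -l")
})

test_that("parse_phobius returns SP and phobius-tagged TM features", {
  f <- withr::local_tempfile()
  writeLines(c(
    "ID   p2",
    "FT   SIGNAL        1     22",
    "FT   TRANSMEM     30     52",
    "//"
  ), f)
  r <- parse_phobius(f)
  expect_setequal(r$region_type, c("SP", "TM"))
  sp <- r[r$region_type == "SP", ]
  expect_equal(c(sp$start, sp$end), c(1L, 22L))
  expect_true(all(r$source_tool == "phobius"))

  writeLines(c("random junk", "not phobius"), f)
  expect_error(parse_phobius(f), "Phobius")
})

test_that("parse_paircoil2 merges runs above the probability threshold", {
  f <- withr::local_tempfile()
  writeLines(c(
    "# seq_id position residue p_coil",
    sprintf("p1 %d A %.2f", 1:12, c(rep(0.9, 5), 0.1, rep(0.8, 3), 0.2, 0.9, 0.9))
  ), f)
  r <- parse_paircoil2(f)
  expect_equal(nrow(r), 3L)
  expect_equal(r$start, c(1L, 7L, 11L))
  expect_equal(r$end, c(5L, 9L, 12L))
  expect_true(all(r$region_type == "CC"))
})

test_that("parser outputs are insensitive to input row order", {
  sim <- generate_proteome(generator_config(n_proteins = 25, seed = 5))
  d <- withr::local_tempdir()
  emit_formats(sim, d)
  for (fn in c("pfam.domtblout", "cdd.rpsblast.tsv", "tmhmm.txt")) {
    p <- file.path(d, fn)
    lines <- readLines(p)
    is_comment <- grepl("^#", lines)
    shuffled <- c(lines[is_comment],
                  sample(lines[!is_comment]))
    p2 <- file.path(d, paste0("shuf_", fn))
    writeLines(shuffled, p2)
    parser <- switch(fn, pfam.domtblout = parse_domtblout,
                     cdd.rpsblast.tsv = parse_rpsblast_tab,
                     tmhmm.txt = parse_tmhmm)
    a <- parser(p); b <- parser(p2)
    key <- intersect(c("seq_id", "model_name", "region_type", "start", "end"),
                     names(a))
    expect_equal(dplyr::arrange(a, dplyr::across(dplyr::all_of(key))),
                 dplyr::arrange(b, dplyr::across(dplyr::all_of(key))),
                 info = fn)
  }
})

test_that("identical duplicate hits are de-duplicated at parse time", {
  f <- withr::local_tempfile()
  row <- "p1\tgnl|CDD|1\t40.00\t50\t20\t0\t10\t59\t1\t50\t1e-20\t95.2"
  writeLines(c(row, row), f)
  expect_equal(nrow(parse_rpsblast_tab(f)), 1L)
})

test_that("unified TSV round-trips tables and rejects unknown categories", {
  sim <- generate_proteome(generator_config(n_proteins = 3, seed = 2))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_annotation_tsv(sim$table, f)
  back <- read_annotation_tsv(f)
  expect_tables_equal(sim$table, back)

  # empty table -> header-only file -> empty table
  empty <- annotation_table(tibble::tibble(seq_id = character(),
                                           length = integer()))
  write_annotation_tsv(empty, f)
  expect_equal(length(readLines(f)), 1L)
  back <- read_annotation_tsv(f)
  expect_equal(nrow(back$proteins), 0L)
  expect_equal(nrow(back$domain_hits), 0L)

  lines <- c("seq_id\tseq_len\tcategory\ttype\tname\taccession\tstart\tend\tbit_score\tevalue",
             "p1\t100\tbogus\t\t\t\t\t\t\t")
  writeLines(lines, f)
  expect_error(read_annotation_tsv(f), "line 2")

  lines[2] <- "p1\t100\tregion\tXX\tseg\t\t1\t10\t\t"
  writeLines(lines, f)
  expect_error(read_annotation_tsv(f), "unknown type")
})

test_that("a 1,000-protein synthetic table survives the TSV round trip", {
  sim <- generate_proteome(generator_config(n_proteins = 1000, seed = 42,
                                            with_sequences = FALSE))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_annotation_tsv(sim$table, f)
  expect_tables_equal(sim$table, read_annotation_tsv(f))
})

test_that("annotation_table validates lengths, ids and coordinates", {
  p <- tibble::tibble(seq_id = "p1", length = 100L)
  expect_error(annotation_table(p, hit_row("p2", 1, 10)), "unknown seq_id")
  expect_error(annotation_table(p, hit_row("p1", 1, 200)), "past protein length")
  expect_error(annotation_table(p, hit_row("p1", 0, 10)), "coordinates")
  expect_error(
    annotation_table(tibble::tibble(seq_id = c("a", "a"), length = c(5L, 6L))),
    "duplicate"
  )
  expect_error(
    annotation_table(tibble::tibble(seq_id = "a", length = 3L, sequence = "MKVA")),
    "character count"
  )
})
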