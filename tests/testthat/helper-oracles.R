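# Independent per-residue bitmap oracles and small fixture builders.

# residues covered by >= 1 interval, by explicit position marking
bitmap_covered <- function(intervals, length) {
  mask <- logical(length)
  if (!is.null(intervals) && nrow(intervals) > 0L) {
    for (i in seq_len(nrow(intervals))) {
      mask[intervals$start[i]:intervals$end[i]] <- TRUE
    }
  }
  mask
}

bitmap_union_count <- function(intervals, length) {
  sum(bitmap_covered(intervals, length))
}

# per-type within/outside-domain residue counts by bitmap
bitmap_partition <- function(regions, domains, length) {
  dom <- bitmap_covered(domains, length)
  out <- lapply(c("LC", "TM", "CC", "SP"), function(tp) {
    r <- regions[regions$region_type == tp, , drop = FALSE]
    reg <- bitmap_covered(r, length)
    data.frame(region_type = tp, total_aa = sum(reg),
               within_domain_aa = sum(reg & dom),
               outside_domain_aa = sum(reg & !dom))
  })
  do.call(rbind, out)
}

# maximal uncovered runs of a coverage bitmap
bitmap_gaps <- function(domains, length) {
  mask <- bitmap_covered(domains, length)
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[!r$values], end = ends[!r$values])
}

random_hits <- function(seq_id = "p1", n, length) {
  s <- sample.int(length, n, replace = TRUE)
  e <- pmin(length, s + sample.int(120L, n, replace = TRUE) - 1L)
  tibble::tibble(
    seq_id = seq_id,
    model_name = sprintf("m%02d", seq_len(n)),
    model_acc = NA_character_,
    start = s, end = e,
    bit_score = round(runif(n, 20, 200), 1),
    evalue = signif(10^(-runif(n, 3, 30)), 2),
    source = "pfam"
  )
}

random_regions <- function(seq_id = "p1", n, length) {
  s <- sample.int(length, n, replace = TRUE)
  e <- pmin(length, s + sample.int(40L, n, replace = TRUE) - 1L)
  tibble::tibble(
    seq_id = seq_id,
    region_type = sample(c("LC", "TM", "CC", "SP"), n, replace = TRUE),
    start = s, end = e,
    source_tool = "test"
  )
}

norm_hits <- function(h) {
  dplyr::arrange(h[, c("seq_id", "model_name", "model_acc", "start", "end",
                       "bit_score", "evalue", "source")],
                 seq_id, source, start, end, model_name)
}

norm_regions <- function(r) {
  dplyr::arrange(r[, c("seq_id", "region_type", "start", "end", "source_tool")],
                 seq_id, region_type, start, end, source_tool)
}

expect_tables_equal <- function(a, b, sequences = FALSE) {
  cols <- if (sequences) c("seq_id", "length", "sequence") else c("seq_id", "length")
  expect_equal(as.data.frame(a$proteins[, cols]), as.data.frame(b$proteins[, cols]))
  expect_equal(as.data.frame(norm_hits(a$domain_hits)),
               as.data.frame(norm_hits(b$domain_hits)))
  expect_equal(as.data.frame(norm_regions(a$regions)),
               as.data.frame(norm_regions(b$regions)))
}

hit_row <- function(seq_id, start, end, model = "m1", evalue = 1e-10,
                    source = "pfam", bit_score = 50) {
  tibble::tibble(seq_id = seq_id, model_name = model, model_acc = NA_character_,
                 start = as.integer(start), end = as.integer(end),
                 bit_score = bit_score, evalue = evalue, source = source)
}
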