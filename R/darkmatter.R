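#' Extract maximal domain-free segments of a protein
#'
#' The complement of the accepted domain residues, as maximal closed
#' intervals, each tagged with positional context: `n_terminal` (before
#' the first domain), `c_terminal` (after the last), `interdomain`
#' (between two domains), or `full_protein` when the protein has no
#' accepted domain at all.
#'
#' @param length protein length (>= 1).
#' @param resolution resolved hits for this protein ([resolve_overlaps()]
#'   output) or a data frame of accepted intervals; NULL/empty means no
#'   domains.
#' @param seq_id identifier carried into the output (taken from
#'   `resolution` when present).
#' @return tibble: `seq_id`, `start`, `end`, `length`, `context`.
#' @export
uncovered_segments <- function(length, resolution = NULL, seq_id = NA_character_) {
  if (length < 1L) abort("protein length must be >= 1")
  cov <- if (is.null(resolution) || nrow(as_tibble(resolution)) == 0L) {
    tibble(start = integer(), end = integer())
  } else if ("status" %in% names(resolution)) {
    coverage_intervals(resolution)
  } else {
    merge_intervals(resolution$start, resolution$end)
  }
  if (!is.null(resolution) && "seq_id" %in% names(resolution) &&
      nrow(as_tibble(resolution)) > 0L) {
    seq_id <- resolution$seq_id[1]
  }
  if (nrow(cov) == 0L) {
    return(tibble(seq_id = seq_id, start = 1L, end = as.integer(length),
                  length = as.integer(length), context = "full_protein"))
  }
  if (max(cov$end) > length) abort("accepted domain extends past protein length")
  bounds_s <- c(1L, cov$end + 1L)
  bounds_e <- c(cov$start - 1L, as.integer(length))
  keep <- bounds_s <= bounds_e
  gs <- bounds_s[keep]; ge <- bounds_e[keep]
  context <- dplyr::case_when(
    ge == length & gs > max(cov$end) ~ "c_terminal",
    gs == 1L & ge < min(cov$start) ~ "n_terminal",
    TRUE ~ "interdomain"
  )
  tibble(seq_id = seq_id, start = gs, end = ge,
         length = ge - gs + 1L, context = context)
}

#' Classify uncovered segments as short linkers or dark matter
#'
#' A segment is a subtractable short linker iff it is strictly shorter
#' than `linker_max` residues *and* lies between domains or between a
#' domain and a terminus. The default cutoff of 50 aa accounts for the
#' smallest domains bordered by average-size (6-8 aa) linkers; a 50-aa
#' segment is already dark matter (strict `<`). A protein with no domain
#' at all is classic dark matter over its whole length, whatever that
#' length is.
#'
#' @param segments output of [uncovered_segments()].
#' @param linker_max subtractability cutoff in aa (>= 1), default 50.
#' @return `segments` with a `class` column
#'   (`"short_linker"`/`"dark_matter"`).
#' @export
classify_segments <- function(segments, linker_max = 50) {
  if (linker_max < 1) abort("linker_max must be >= 1")
  segments |>
    mutate(class = ifelse(
      .data$length < linker_max & .data$context != "full_protein",
      "short_linker", "dark_matter"
    ))
}

#' Residue accounting for one protein
#'
#' Splits the protein's residues into accepted-domain, short-linker and
#' dark-matter counts; the three always sum to the protein length.
#'
#' @inheritParams uncovered_segments
#' @inheritParams classify_segments
#' @return one-row tibble: `seq_id`, `length`, `domain_aa`,
#'   `short_linker_aa`, `darkmatter_aa`, `has_domain`.
#' @export
account_protein <- function(length, resolution = NULL, linker_max = 50,
                            seq_id = NA_character_) {
  segs <- classify_segments(
    uncovered_segments(length, resolution, seq_id = seq_id), linker_max
  )
  dom_aa <- as.integer(length) - sum(segs$length)
  tibble(
    seq_id = segs$seq_id[1] %||% seq_id,
    length = as.integer(length),
    domain_aa = dom_aa,
    short_linker_aa = sum(segs$length[segs$class == "short_linker"]),
    darkmatter_aa = sum(segs$length[segs$class == "dark_matter"]),
    has_domain = dom_aa > 0L
  )
}

#' Residue accounting for a whole proteome
#'
#' Resolves domain overlaps per protein and applies [account_protein()]
#' to every sequence of an annotation table. Following the choice of Pfam
#' as the domain authority, only `sources = "pfam"` hits define coverage
#' by default; pass `c("pfam", "cdd")` to count both.
#'
#' @param table an [annotation_table()].
#' @param linker_max subtractability cutoff in aa, default 50.
#' @param sources domain hit sources that define coverage.
#' @param policy overlap policy, see [resolve_overlaps()].
#' @return tibble with one row per protein (columns of
#'   [account_protein()]), carrying the resolution as attribute
#'   `"resolution"`.
#' @export
account_proteome <- function(table, linker_max = 50, sources = "pfam",
                             policy = c("greedy", "union")) {
  stopifnot(inherits(table, "annotation_table"))
  policy <- match.arg(policy)
  res <- resolve_architectures(table$domain_hits, policy = policy,
                               sources = sources)
  is_acc <- res$status == "accepted"
  acc_by <- split(which(is_acc), res$seq_id[is_acc])
  ids <- table$proteins$seq_id
  lens <- table$proteins$length
  n <- length(ids)
  dom_aa <- integer(n); link_aa <- integer(n); dark_aa <- integer(n)
  for (i in seq_len(n)) {
    idx <- acc_by[[ids[i]]]
    if (is.null(idx)) {
      dark_aa[i] <- lens[i]
    } else {
      m <- merge_iv(res$start[idx], res$end[idx])
      dom_aa[i] <- sum(m$end - m$start + 1L)
      gap_len <- c(m$start, lens[i] + 1L) - c(0L, m$end) - 1L
      gap_len <- gap_len[gap_len > 0L]
      link_aa[i] <- sum(gap_len[gap_len < linker_max])
      dark_aa[i] <- sum(gap_len[gap_len >= linker_max])
    }
  }
  out <- tibble(
    seq_id = ids, length = as.integer(lens),
    domain_aa = dom_aa, short_linker_aa = link_aa, darkmatter_aa = dark_aa,
    has_domain = dom_aa > 0L
  )
  attr(out, "resolution") <- res
  out
}

#' Sequence-level coverage classes
#'
#' The classic sequence-level view: how many proteins have at least one
#' accepted domain vs none at all.
#'
#' @param accounting per-protein accounting ([account_proteome()] output).
#' @return one-row tibble: `n_proteins`, `n_with_domain`,
#'   `n_without_domain`, `fraction_with_domain`, `fraction_without_domain`.
#' @export
sequence_level_class <- function(accounting) {
  n <- nrow(accounting)
  if (n == 0L) abort("empty proteome")
  nw <- sum(accounting$has_domain)
  tibble(
    n_proteins = n, n_with_domain = nw, n_without_domain = n - nw,
    fraction_with_domain = nw / n, fraction_without_domain = (n - nw) / n
  )
}

#' Extract and classify uncovered segments for a whole proteome
#'
#' @inheritParams account_proteome
#' @return tibble: `seq_id`, `start`, `end`, `length`, `context`, `class`.
#' @export
segment_report <- function(table, linker_max = 50, sources = "pfam",
                           policy = c("greedy", "union")) {
  stopifnot(inherits(table, "annotation_table"))
  policy <- match.arg(policy)
  res <- resolve_architectures(table$domain_hits, policy = policy,
                               sources = sources)
  is_acc <- res$status == "accepted"
  acc_by <- split(which(is_acc), res$seq_id[is_acc])
  ids <- table$proteins$seq_id
  lens <- table$proteins$length
  o_id <- vector("list", length(ids)); o_s <- vector("list", length(ids))
  o_e <- vector("list", length(ids)); o_ctx <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    idx <- acc_by[[ids[i]]]
    if (is.null(idx)) {
      o_id[[i]] <- ids[i]; o_s[[i]] <- 1L; o_e[[i]] <- as.integer(lens[i])
      o_ctx[[i]] <- "full_protein"
    } else {
      m <- merge_iv(res$start[idx], res$end[idx])
      gs <- c(1L, m$end + 1L)
      ge <- c(m$start - 1L, as.integer(lens[i]))
      keep <- gs <= ge
      gs <- gs[keep]; ge <- ge[keep]
      if (length(gs) == 0L) next
      ctx <- rep("interdomain", length(gs))
      ctx[gs == 1L & ge < m$start[1]] <- "n_terminal"
      ctx[ge == lens[i] & gs > m$end[length(m$end)]] <- "c_terminal"
      o_id[[i]] <- rep(ids[i], length(gs)); o_s[[i]] <- gs; o_e[[i]] <- ge
      o_ctx[[i]] <- ctx
    }
  }
  uc <- function(x, mode) {
    v <- unlist(x, use.names = FALSE)
    if (is.null(v)) vector(mode, 0L) else v
  }
  segs <- tibble(
    seq_id = uc(o_id, "character"),
    start = uc(o_s, "integer"), end = uc(o_e, "integer"),
    length = uc(o_e, "integer") - uc(o_s, "integer") + 1L,
    context = uc(o_ctx, "character")
  )
  classify_segments(segs, linker_max)
}
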