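# Interval helpers. All intervals are 1-based closed; "overlap" means
# sharing >= 1 residue. Merging also coalesces adjacent intervals, which
# never changes residue counts or gap extraction. Internals work on plain
# start/end vectors; tibbles are built only at API boundaries.

merge_iv <- function(start, end) {
  if (length(start) == 0L) return(list(start = integer(), end = integer()))
  check_coords(start, end)
  ord <- order(start, end)
  start <- as.integer(start[ord]); end <- as.integer(end[ord])
  out_s <- integer(length(start)); out_e <- integer(length(start))
  k <- 1L; out_s[1L] <- start[1L]; out_e[1L] <- end[1L]
  for (i in seq_along(start)[-1L]) {
    if (start[i] <= out_e[k] + 1L) {
      if (end[i] > out_e[k]) out_e[k] <- end[i]
    } else {
      k <- k + 1L; out_s[k] <- start[i]; out_e[k] <- end[i]
    }
  }
  list(start = out_s[seq_len(k)], end = out_e[seq_len(k)])
}

merge_intervals <- function(start, end) {
  m <- merge_iv(start, end)
  tibble(start = m$start, end = m$end)
}

# residues shared by two disjoint-sorted interval sets
intersect_aa <- function(a_start, a_end, b_start, b_end) {
  if (length(a_start) == 0L || length(b_start) == 0L) return(0L)
  ov <- pmax(0L, outer(a_end, b_end, pmin) - outer(a_start, b_start, pmax) + 1L)
  sum(ov)
}

#' Count residues covered by at least one interval
#'
#' The coverage-sum rule generalized: for pairwise non-overlapping
#' intervals this is the plain sum of interval lengths; overlapping
#' residues are counted once.
#'
#' @param intervals data frame with `start` and `end` columns (1-based,
#'   inclusive), or NULL/empty for no intervals.
#' @param length optional protein length; if given, an interval reaching
#'   past it is an error.
#' @return integer count of distinct covered residues.
#' @export
#' @examples
#' residue_union(data.frame(start = c(1, 5), end = c(10, 20)))  # 20
residue_union <- function(intervals, length = NULL) {
  if (is.null(intervals) || nrow(intervals) == 0L) return(0L)
  if (!is.null(length) && any(intervals$end > length)) {
    abort("interval exceeds protein length")
  }
  m <- merge_iv(intervals$start, intervals$end)
  sum(m$end - m$start + 1L)
}

# greedy longest-domain selection on bare vectors; returns list(status, reason)
greedy_select <- function(start, end, evalue, model_name) {
  n <- length(start)
  hl <- end - start + 1L
  ord <- order(-hl, evalue, start, model_name, method = "radix")
  status <- character(n)
  reason <- rep(NA_character_, n)
  acc_s <- integer(0); acc_e <- integer(0); acc_lab <- character(0)
  for (i in ord) {
    clash <- which(start[i] <= acc_e & end[i] >= acc_s)
    if (length(clash) == 0L) {
      status[i] <- "accepted"
      acc_s <- c(acc_s, start[i]); acc_e <- c(acc_e, end[i])
      acc_lab <- c(acc_lab, sprintf("%s (%d-%d)", model_name[i], start[i], end[i]))
    } else {
      status[i] <- "rejected"
      reason[i] <- paste0("overlaps longer accepted hit ", acc_lab[clash[1]])
    }
  }
  list(status = status, reason = reason)
}

#' Resolve overlapping domain hits for one protein
#'
#' Greedy longest-domain rule: hits are ranked by (length descending,
#' E-value ascending, start ascending, model name ascending) and accepted
#' iff they overlap no already-accepted hit, so that whenever two hits
#' conflict the longer one wins. Every rejected hit therefore overlaps an
#' accepted hit at least as long as itself. The alternative
#' `policy = "union"` accepts every hit and lets coverage be their residue
#' union.
#'
#' @param hits tibble of domain hits for a single protein (mixed seq_ids
#'   are an error).
#' @param policy `"greedy"` (default) or `"union"`.
#' @return the input hits with added columns `hit_length`,
#'   `status` (`"accepted"`/`"rejected"`) and `reason` (NA for accepted),
#'   sorted by start.
#' @export
resolve_overlaps <- function(hits, policy = c("greedy", "union")) {
  policy <- match.arg(policy)
  hits <- complete_hit_cols(as_tibble(hits))
  if (nrow(hits) > 0L && length(unique(hits$seq_id)) > 1L) {
    abort("resolve_overlaps() expects hits for a single protein; see resolve_architectures()")
  }
  resolve_prepared(hits, policy)
}

# hits already in canonical column layout, any number of proteins
resolve_prepared <- function(hits, policy) {
  n <- nrow(hits)
  if (n == 0L) {
    return(mutate(hits, hit_length = integer(), status = character(),
                  reason = character()))
  }
  check_coords(hits$start, hits$end, "domain hit")
  hits$hit_length <- hits$end - hits$start + 1L
  if (policy == "union") {
    hits$status <- "accepted"
    hits$reason <- NA_character_
    return(arrange(hits, .data$seq_id, .data$start, .data$end))
  }
  status <- character(n); reason <- rep(NA_character_, n)
  for (idx in split(seq_len(n), hits$seq_id)) {
    g <- greedy_select(hits$start[idx], hits$end[idx], hits$evalue[idx],
                       hits$model_name[idx])
    status[idx] <- g$status
    reason[idx] <- g$reason
  }
  hits$status <- status
  hits$reason <- reason
  arrange(hits, .data$seq_id, .data$start, .data$end)
}

# disjoint sorted coverage interval list of a resolution (plain vectors)
coverage_iv <- function(resolution) {
  acc <- resolution$status == "accepted"
  merge_iv(resolution$start[acc], resolution$end[acc])
}

coverage_intervals <- function(resolution) {
  m <- coverage_iv(resolution)
  tibble(start = m$start, end = m$end)
}

#' Resolve overlaps for every protein in a hit table
#'
#' @param hits tibble of domain hits (any number of proteins), or an
#'   [annotation_table()] (its `domain_hits` are used).
#' @param policy see [resolve_overlaps()].
#' @param sources which hit sources participate (default both; dark-matter
#'   accounting uses `"pfam"` only, see [account_proteome()]).
#' @return one tibble with per-hit `status`/`reason`, all proteins.
#' @export
resolve_architectures <- function(hits, policy = c("greedy", "union"),
                                  sources = c("pfam", "cdd")) {
  policy <- match.arg(policy)
  if (inherits(hits, "annotation_table")) hits <- hits$domain_hits
  hits <- complete_hit_cols(as_tibble(hits))
  hits <- hits[hits$source %in% sources, , drop = FALSE]
  resolve_prepared(hits, policy)
}

#' Domain coverage of one protein
#'
#' @param length protein length in residues (> 0).
#' @param hits raw or resolved hits for this protein; raw hits are
#'   resolved internally with `policy`.
#' @param policy see [resolve_overlaps()].
#' @return one-row tibble: `covered_aa`, `coverage_fraction`.
#' @export
domain_coverage <- function(length, hits, policy = c("greedy", "union")) {
  if (length < 1L) abort("protein length must be >= 1")
  if (!"status" %in% names(hits)) hits <- resolve_overlaps(hits, policy)
  cov <- coverage_iv(hits)
  if (length(cov$start) > 0L && max(cov$end) > length) {
    abort("domain hit extends past protein length")
  }
  aa <- sum(cov$end - cov$start + 1L)
  tibble(covered_aa = aa, coverage_fraction = aa / length)
}

# per-type region partition on bare vectors; returns 4 x 2 count matrix
partition_counts <- function(r_type, r_start, r_end, dom) {
  out <- matrix(0L, nrow = length(REGION_TYPES), ncol = 2L,
                dimnames = list(REGION_TYPES, c("total", "within")))
  for (tp in unique(r_type)) {
    sel <- r_type == tp
    m <- merge_iv(r_start[sel], r_end[sel])
    tot <- sum(m$end - m$start + 1L)
    win <- intersect_aa(m$start, m$end, dom$start, dom$end)
    out[tp, ] <- c(tot, win)
  }
  out
}

#' Partition region residues into within- vs outside-domain counts
#'
#' Implements the domain-priority rule: a residue annotated as a region
#' that also lies inside an accepted domain counts as within-domain.
#' Within one region type residues are counted once (union); different
#' types are counted independently, so the same residue may contribute to
#' both an LC and a TM total (sum semantics across types).
#'
#' @param regions region annotations for one protein.
#' @param resolution resolved hits for the same protein (output of
#'   [resolve_overlaps()]), or a data frame of accepted intervals.
#' @return tibble with one row per region type (`LC`, `TM`, `CC`, `SP`):
#'   `total_aa`, `within_domain_aa`, `outside_domain_aa`.
#' @export
region_partition <- function(regions, resolution) {
  regions <- complete_region_cols(as_tibble(regions))
  if (nrow(regions) > 0L) check_coords(regions$start, regions$end, "region")
  dom <- if (!is.null(resolution) && "status" %in% names(resolution)) {
    coverage_iv(resolution)
  } else if (!is.null(resolution) && nrow(as_tibble(resolution)) > 0L) {
    merge_iv(resolution$start, resolution$end)
  } else {
    list(start = integer(), end = integer())
  }
  cnt <- partition_counts(regions$region_type, regions$start, regions$end, dom)
  tibble(
    region_type = REGION_TYPES,
    total_aa = unname(cnt[, "total"]),
    within_domain_aa = unname(cnt[, "within"]),
    outside_domain_aa = unname(cnt[, "total"] - cnt[, "within"])
  )
}

#' Label secondary-source hits as confirmatory or novel
#'
#' For each secondary hit (e.g. a CDD profile), the fraction of its
#' residues already inside the resolved primary (e.g. Pfam) coverage is
#' computed; hits at or above `min_overlap_frac` are confirmatory
#' (redundant), the rest contribute novel coverage.
#'
#' @param primary_hits hits of the primary source for one protein (raw;
#'   resolved internally).
#' @param secondary_hits hits of the secondary source for the same protein.
#' @param min_overlap_frac confirmatory threshold in (0, 1], default 0.75.
#' @return secondary hits with `overlap_fraction` and `label` columns.
#' @export
redundancy_assessment <- function(primary_hits, secondary_hits,
                                  min_overlap_frac = 0.75) {
  if (!is.numeric(min_overlap_frac) || min_overlap_frac <= 0 ||
      min_overlap_frac > 1) {
    abort("min_overlap_frac must be in (0, 1]")
  }
  res <- resolve_overlaps(primary_hits)
  cov <- coverage_iv(res)
  secondary_hits <- complete_hit_cols(as_tibble(secondary_hits))
  if (nrow(secondary_hits) == 0L) {
    return(mutate(secondary_hits, overlap_fraction = double(),
                  label = character()))
  }
  check_coords(secondary_hits$start, secondary_hits$end, "secondary hit")
  frac <- purrr::map2_dbl(secondary_hits$start, secondary_hits$end, function(s, e) {
    intersect_aa(s, e, cov$start, cov$end) / (e - s + 1L)
  })
  secondary_hits |>
    mutate(
      overlap_fraction = frac,
      label = ifelse(frac >= min_overlap_frac, "confirmatory", "novel")
    )
}
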