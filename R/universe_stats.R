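#' Construct a sequence-space table
#'
#' The database-scale ledger: total residues, accepted-domain residues,
#' and per region type (LC, TM, CC, SP) the total annotated residues and
#' the part lying within domain boundaries. The "all regions" cells are
#' the *sums* across the four types — a residue annotated as both LC and
#' TM counts once per type — while within one type residues are counted
#' once.
#'
#' @param total_aa total residues in the sequence space (> 0).
#' @param domain_aa residues inside accepted domains.
#' @param region_total named numeric, total region residues per type;
#'   names must cover `LC`, `TM`, `CC`, `SP` (0 allowed).
#' @param region_within named numeric, the within-domain part per type.
#' @return object of class `space_table`.
#' @export
#' @examples
#' space_table(5.64e9, 2.90e9,
#'   region_total  = c(LC = 4.14e8, TM = 3.74e8, CC = 6.78e7, SP = 5.43e7),
#'   region_within = c(LC = 2.72e8, TM = 1.20e8, CC = 4.65e7, SP = 4.62e7))
space_table <- function(total_aa, domain_aa,
                        region_total = c(LC = 0, TM = 0, CC = 0, SP = 0),
                        region_within = c(LC = 0, TM = 0, CC = 0, SP = 0)) {
  if (total_aa <= 0) abort("total_aa must be > 0")
  if (domain_aa < 0 || domain_aa > total_aa) {
    abort("need 0 <= domain_aa <= total_aa")
  }
  rt <- region_total[REGION_TYPES]
  rw <- region_within[REGION_TYPES]
  if (anyNA(rt) || anyNA(rw)) abort("region_total/region_within must name LC, TM, CC, SP")
  if (any(rw > rt)) abort("within-domain residues exceed a region total")
  regions <- tibble(
    region_type = REGION_TYPES,
    total_aa = unname(rt),
    within_domain_aa = unname(rw),
    outside_domain_aa = unname(rt - rw)
  )
  structure(
    list(total_aa = total_aa, domain_aa = domain_aa, regions = regions),
    class = "space_table"
  )
}

#' @export
print.space_table <- function(x, ...) {
  cat("<space_table>\n")
  cat(sprintf("  total %s aa, domain %s aa (%.1f%%)\n",
              formatC(x$total_aa, format = "E", digits = 2),
              formatC(x$domain_aa, format = "E", digits = 2),
              100 * x$domain_aa / x$total_aa))
  print(x$regions)
  invisible(x)
}

#' Percentage view of a sequence-space table
#'
#' Two rows of percentages mirroring the published table layout: the
#' total-space row divides every cell by the total residue count, the
#' domain-space row divides by the domain residue count (its
#' `all_proteins` cell is domain/total, i.e. the overall coverage).
#' Percentages are rounded half-up to one decimal; rounding happens only
#' here, never inside the counts.
#'
#' @param st a [space_table()], or a `dark_space_stats` object (its space
#'   table is used).
#' @return tibble with columns `space`, `all_proteins`, `LC`, `TM`, `CC`,
#'   `SP`, `all_regions`.
#' @export
percent_table <- function(st) {
  if (inherits(st, "dark_space_stats")) st <- st$space
  stopifnot(inherits(st, "space_table"))
  if (st$total_aa <= 0) abort("total_aa must be > 0 for percentages")
  rt <- setNames(st$regions$total_aa, st$regions$region_type)
  rw <- setNames(st$regions$within_domain_aa, st$regions$region_type)
  row1 <- c(all_proteins = 100,
            100 * rt / st$total_aa,
            all_regions = 100 * sum(rt) / st$total_aa)
  if (st$domain_aa <= 0) abort("domain_aa must be > 0 for domain-space percentages")
  row2 <- c(all_proteins = 100 * st$domain_aa / st$total_aa,
            100 * rw / st$domain_aa,
            all_regions = 100 * sum(rw) / st$domain_aa)
  bind_rows(
    tibble(space = "total_space", !!!as.list(round_half_up(row1, 1))),
    tibble(space = "domain_space", !!!as.list(round_half_up(row2, 1)))
  )
}

#' Dark-matter summary from residue totals
#'
#' Classic dark matter is everything outside accepted domains
#' (100 - coverage). Subtracting short interdomain/terminal linkers gives
#' the expanded estimate of the truly uncharacterized space.
#'
#' @param total_aa total residues (> 0).
#' @param domain_aa accepted-domain residues.
#' @param short_linker_aa subtractable short-linker residues;
#'   `domain_aa + short_linker_aa <= total_aa` required.
#' @return one-row tibble of class `darkmatter_summary` with the three
#'   counts, `darkmatter_aa`, and percentages `pct_domain`,
#'   `pct_classic_dark`, `pct_short_linker`, `pct_expanded_dark`
#'   (half-up, one decimal).
#' @export
#' @examples
#' darkmatter_summary(5.64e9, 2.90e9, 5.09e8)  # classic 48.6, expanded 39.6
darkmatter_summary <- function(total_aa, domain_aa, short_linker_aa) {
  if (total_aa <= 0) abort("total_aa must be > 0")
  if (domain_aa < 0 || short_linker_aa < 0 ||
      domain_aa + short_linker_aa > total_aa) {
    abort("need domain_aa + short_linker_aa <= total_aa, both >= 0")
  }
  dark <- total_aa - domain_aa - short_linker_aa
  out <- tibble(
    total_aa = total_aa, domain_aa = domain_aa,
    short_linker_aa = short_linker_aa, darkmatter_aa = dark,
    pct_domain = round_half_up(100 * domain_aa / total_aa, 1),
    pct_classic_dark = round_half_up(100 * (1 - domain_aa / total_aa), 1),
    pct_short_linker = round_half_up(100 * short_linker_aa / total_aa, 1),
    pct_expanded_dark = round_half_up(100 * dark / total_aa, 1)
  )
  class(out) <- c("darkmatter_summary", class(out))
  out
}

#' Aggregate an annotation table into database-scale statistics
#'
#' Runs the full accounting over every protein: overlap resolution,
#' uncovered-segment classification at `linker_max`, region partitioning
#' with domain priority, and the sequence-level with/without-domain split.
#'
#' @inheritParams account_proteome
#' @param tm_source which tool's TM calls populate the TM column:
#'   `"tmhmm"` (default, the TM authority) or `"phobius"`. TM annotations
#'   from the non-selected tool are dropped; TM rows from other sources
#'   (e.g. the unified TSV) are always kept.
#' @return object of class `dark_space_stats`: the [space_table()], the
#'   [darkmatter_summary()], the [sequence_level_class()] row, the
#'   per-protein accounting and the per-hit resolution.
#' @export
aggregate_space <- function(table, linker_max = 50, sources = "pfam",
                            policy = c("greedy", "union"),
                            tm_source = c("tmhmm", "phobius")) {
  stopifnot(inherits(table, "annotation_table"))
  policy <- match.arg(policy)
  tm_source <- match.arg(tm_source)
  if (nrow(table$proteins) == 0L) abort("empty proteome")

  acc <- account_proteome(table, linker_max = linker_max,
                          sources = sources, policy = policy)
  res <- attr(acc, "resolution")

  drop_tool <- if (tm_source == "tmhmm") "phobius" else "tmhmm"
  regions <- table$regions |>
    filter(!(.data$region_type == "TM" & .data$source_tool == drop_tool))

  is_acc <- res$status == "accepted"
  acc_by <- split(which(is_acc), res$seq_id[is_acc])
  reg_by <- split(seq_len(nrow(regions)), regions$seq_id)
  totals <- matrix(0, nrow = length(REGION_TYPES), ncol = 2L,
                   dimnames = list(REGION_TYPES, c("total", "within")))
  for (id in names(reg_by)) {
    ri <- reg_by[[id]]
    di <- acc_by[[id]]
    dom <- if (is.null(di)) list(start = integer(), end = integer()) else {
      merge_iv(res$start[di], res$end[di])
    }
    totals <- totals + partition_counts(regions$region_type[ri],
                                        regions$start[ri], regions$end[ri],
                                        dom)
  }

  st <- space_table(
    total_aa = sum(acc$length), domain_aa = sum(acc$domain_aa),
    region_total = totals[, "total"],
    region_within = totals[, "within"]
  )
  structure(
    list(
      space = st,
      summary = darkmatter_summary(sum(acc$length), sum(acc$domain_aa),
                                   sum(acc$short_linker_aa)),
      seq_class = sequence_level_class(acc),
      accounting = acc,
      resolution = res,
      params = list(linker_max = linker_max, sources = sources,
                    policy = policy, tm_source = tm_source)
    ),
    class = "dark_space_stats"
  )
}

#' @export
print.dark_space_stats <- function(x, ...) {
  s <- x$summary
  cat("<dark_space_stats>\n")
  cat(sprintf("  proteins: %d   residues: %s\n", x$seq_class$n_proteins,
              format(s$total_aa, big.mark = ",")))
  cat(sprintf("  domain coverage: %.1f%%   classic dark matter: %.1f%%\n",
              s$pct_domain, s$pct_classic_dark))
  cat(sprintf("  short linkers (< %d aa): %.1f%%   expanded dark matter: %.1f%%\n",
              x$params$linker_max, s$pct_short_linker, s$pct_expanded_dark))
  cat(sprintf("  proteins without any domain: %.1f%%\n",
              100 * x$seq_class$fraction_without_domain))
  invisible(x)
}

#' Compare domain coverage across database/model releases
#'
#' @param snapshots data frame with columns `label`, `total_aa`,
#'   `pct_domain`, ordered oldest first; at least two rows.
#' @return object of class `release_comparison`: the snapshots with
#'   absolute dark-matter residues added, consecutive coverage deltas in
#'   percentage points (half-up, one decimal), and the total-size ratio
#'   last/first.
#' @export
#' @examples
#' compare_releases(data.frame(
#'   label = c("Pfam22", "Pfam24", "Pfam26"),
#'   total_aa = c(2.8e9, 4.2e9, 5.6e9),
#'   pct_domain = c(47.7, 48.9, 51.4)))
compare_releases <- function(snapshots) {
  snapshots <- as_tibble(snapshots)
  if (!all(c("label", "total_aa", "pct_domain") %in% names(snapshots))) {
    abort("snapshots need columns label, total_aa, pct_domain")
  }
  if (nrow(snapshots) < 2L) abort("need at least 2 snapshots to compare")
  snapshots <- snapshots |>
    mutate(darkmatter_aa = .data$total_aa * (100 - .data$pct_domain) / 100)
  n <- nrow(snapshots)
  deltas <- tibble(
    from = snapshots$label[-n], to = snapshots$label[-1],
    delta_pct_domain = round_half_up(diff(snapshots$pct_domain), 1)
  )
  structure(
    list(snapshots = snapshots, deltas = deltas,
         total_growth_ratio = snapshots$total_aa[n] / snapshots$total_aa[1]),
    class = "release_comparison"
  )
}

#' @export
print.release_comparison <- function(x, ...) {
  cat("<release_comparison>\n")
  print(x$snapshots)
  print(x$deltas)
  cat(sprintf("  total sequence space grew %.1fx\n", x$total_growth_ratio))
  invisible(x)
}

# ---- reports ---------------------------------------------------------------

sci3 <- function(x) formatC(x, format = "E", digits = 2)

#' Write coverage and dark-matter reports
#'
#' Emits three files under `dir`: `<name>_table1.tsv` (the space table
#' with raw counts, 3-significant-digit scientific notation and
#' percentages side by side), `<name>_report.txt` (key: value lines), and
#' `<name>_report.json` (all counts, percentages and parameters).
#'
#' @param stats a `dark_space_stats` object ([aggregate_space()]), or a
#'   list with elements `space` ([space_table()]) and `summary`
#'   ([darkmatter_summary()]).
#' @param dir output directory (created if needed).
#' @param name file-name stem, default `"darkspace"`.
#' @param provenance optional named list recorded in the JSON report
#'   (input files, seed, ...).
#' @return named character vector of the written paths, invisibly.
#' @export
write_report <- function(stats, dir, name = "darkspace", provenance = list()) {
  st <- if (inherits(stats, "dark_space_stats")) stats$space else stats$space
  sm <- stats$summary
  stopifnot(inherits(st, "space_table"), !is.null(sm))
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(paste0("cannot create output directory: ", dir))
  }
  pct <- percent_table(st)
  rt <- setNames(st$regions$total_aa, st$regions$region_type)
  rw <- setNames(st$regions$within_domain_aa, st$regions$region_type)

  cells <- function(vals) {
    as.list(setNames(as.character(vals),
                     c("all_proteins", REGION_TYPES, "all_regions")))
  }
  tab <- bind_rows(
    tibble(space = "total_space", metric = "aa",
           !!!cells(sprintf("%.10g", c(st$total_aa, rt, sum(rt))))),
    tibble(space = "total_space", metric = "aa_sci",
           !!!cells(sci3(c(st$total_aa, rt, sum(rt))))),
    tibble(space = "total_space", metric = "pct",
           !!!cells(sprintf("%.1f", unlist(pct[1, -1])))),
    tibble(space = "domain_space", metric = "aa",
           !!!cells(sprintf("%.10g", c(st$domain_aa, rw, sum(rw))))),
    tibble(space = "domain_space", metric = "aa_sci",
           !!!cells(sci3(c(st$domain_aa, rw, sum(rw))))),
    tibble(space = "domain_space", metric = "pct",
           !!!cells(sprintf("%.1f", unlist(pct[2, -1]))))
  )
  tsv_path <- file.path(dir, paste0(name, "_table1.tsv"))
  readr::write_tsv(tab, tsv_path, progress = FALSE)

  txt_path <- file.path(dir, paste0(name, "_report.txt"))
  writeLines(c(
    sprintf("total_aa: %.0f (%s)", sm$total_aa, sci3(sm$total_aa)),
    sprintf("domain_aa: %.0f (%s)", sm$domain_aa, sci3(sm$domain_aa)),
    sprintf("short_linker_aa: %.0f (%s)", sm$short_linker_aa, sci3(sm$short_linker_aa)),
    sprintf("darkmatter_aa: %.0f (%s)", sm$darkmatter_aa, sci3(sm$darkmatter_aa)),
    sprintf("pct_domain: %.1f", sm$pct_domain),
    sprintf("pct_classic_dark: %.1f", sm$pct_classic_dark),
    sprintf("pct_short_linker: %.1f", sm$pct_short_linker),
    sprintf("pct_expanded_dark: %.1f", sm$pct_expanded_dark)
  ), txt_path)

  json_path <- file.path(dir, paste0(name, "_report.json"))
  payload <- list(
    space = list(total_aa = st$total_aa, domain_aa = st$domain_aa,
                 regions = st$regions),
    percentages = pct,
    summary = as.list(sm),
    params = if (inherits(stats, "dark_space_stats")) stats$params else NULL,
    provenance = provenance
  )
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(table = tsv_path, text = txt_path, json = json_path))
}

#' Re-read the counts of a written space-table TSV
#'
#' @param path a `*_table1.tsv` written by [write_report()].
#' @return the reconstructed [space_table()].
#' @export
read_space_table_tsv <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  aa <- tab |> filter(.data$metric == "aa")
  tot <- aa |> filter(.data$space == "total_space")
  dom <- aa |> filter(.data$space == "domain_space")
  space_table(
    total_aa = as.numeric(tot$all_proteins),
    domain_aa = as.numeric(dom$all_proteins),
    region_total = vapply(tot[, REGION_TYPES], as.numeric, numeric(1)),
    region_within = vapply(dom[, REGION_TYPES], as.numeric, numeric(1))
  )
}

# ---- broom-style and plotting methods -------------------------------------

#' @export
tidy.dark_space_stats <- function(x, ...) {
  st <- x$space
  bind_rows(
    tibble(space = "total_space", cell = "all_proteins",
           aa = st$total_aa, pct = 100),
    tibble(space = "total_space", cell = st$regions$region_type,
           aa = st$regions$total_aa,
           pct = round_half_up(100 * st$regions$total_aa / st$total_aa, 1)),
    tibble(space = "total_space", cell = "all_regions",
           aa = sum(st$regions$total_aa),
           pct = round_half_up(100 * sum(st$regions$total_aa) / st$total_aa, 1)),
    tibble(space = "domain_space", cell = "all_proteins",
           aa = st$domain_aa,
           pct = round_half_up(100 * st$domain_aa / st$total_aa, 1)),
    tibble(space = "domain_space", cell = st$regions$region_type,
           aa = st$regions$within_domain_aa,
           pct = round_half_up(100 * st$regions$within_domain_aa / st$domain_aa, 1)),
    tibble(space = "domain_space", cell = "all_regions",
           aa = sum(st$regions$within_domain_aa),
           pct = round_half_up(100 * sum(st$regions$within_domain_aa) / st$domain_aa, 1))
  )
}

#' @export
glance.dark_space_stats <- function(x, ...) {
  s <- x$summary
  tibble(
    n_proteins = x$seq_class$n_proteins,
    total_aa = s$total_aa, domain_aa = s$domain_aa,
    pct_domain = s$pct_domain, pct_classic_dark = s$pct_classic_dark,
    pct_short_linker = s$pct_short_linker,
    pct_expanded_dark = s$pct_expanded_dark,
    fraction_without_domain = x$seq_class$fraction_without_domain,
    linker_max = x$params$linker_max
  )
}

#' @export
tidy.release_comparison <- function(x, ...) x$snapshots

#' @export
glance.release_comparison <- function(x, ...) {
  tibble(
    n_snapshots = nrow(x$snapshots),
    first = x$snapshots$label[1],
    last = x$snapshots$label[nrow(x$snapshots)],
    total_growth_ratio = x$total_growth_ratio,
    total_delta_pct_domain = sum(x$deltas$delta_pct_domain)
  )
}

#' @export
autoplot.dark_space_stats <- function(object, ...) {
  s <- object$summary
  df <- tibble(
    component = factor(
      c("domain", "short linker", "dark matter"),
      levels = c("dark matter", "short linker", "domain")
    ),
    aa = c(s$domain_aa, s$short_linker_aa, s$darkmatter_aa)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = "proteome", y = .data$aa,
                                   fill = .data$component)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::scale_fill_manual(values = c(
      "dark matter" = "grey15", "short linker" = "grey70",
      "domain" = "#3182bd"
    )) +
    ggplot2::labs(x = NULL, y = "residues (aa)",
                  title = "Residue-level composition of the proteome") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.release_comparison <- function(object, ...) {
  df <- object$snapshots |>
    mutate(label = factor(.data$label, levels = .data$label))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$label, y = .data$pct_domain,
                                   group = 1)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = NULL, y = "domain coverage (% aa)",
                  title = "Domain coverage across releases") +
    ggplot2::theme_minimal()
}

#' Draw the domain/region architecture of selected proteins
#'
#' Domains as filled boxes on the midline, regions as thinner boxes
#' above, uncovered segments as grey (short linker) or black (dark
#' matter) lines below.
#'
#' @param table an [annotation_table()].
#' @param seq_ids proteins to draw (default: first 5).
#' @param linker_max subtractability cutoff, default 50.
#' @return a ggplot object.
#' @export
plot_architecture <- function(table, seq_ids = NULL, linker_max = 50) {
  stopifnot(inherits(table, "annotation_table"))
  seq_ids <- seq_ids %||% head(table$proteins$seq_id, 5)
  sub <- annotation_table(
    table$proteins |> filter(.data$seq_id %in% seq_ids),
    table$domain_hits |> filter(.data$seq_id %in% seq_ids),
    table$regions |> filter(.data$seq_id %in% seq_ids)
  )
  segs <- segment_report(sub, linker_max = linker_max)
  res <- resolve_architectures(sub$domain_hits)
  acc <- if (nrow(res) > 0L) filter(res, .data$status == "accepted") else res
  df <- bind_rows(
    if (nrow(acc) > 0L) tibble(seq_id = acc$seq_id, start = acc$start,
                               end = acc$end, what = "domain"),
    if (nrow(sub$regions) > 0L) tibble(seq_id = sub$regions$seq_id,
                                       start = sub$regions$start,
                                       end = sub$regions$end,
                                       what = paste0("region:", sub$regions$region_type)),
    tibble(seq_id = segs$seq_id, start = segs$start, end = segs$end,
           what = ifelse(segs$class == "short_linker", "short linker", "dark matter"))
  )
  off <- c(domain = 0, `short linker` = -0.25, `dark matter` = -0.25,
           `region:LC` = 0.25, `region:TM` = 0.25, `region:CC` = 0.25,
           `region:SP` = 0.25)
  hgt <- c(domain = 0.18, `short linker` = 0.04, `dark matter` = 0.04,
           `region:LC` = 0.10, `region:TM` = 0.10, `region:CC` = 0.10,
           `region:SP` = 0.10)
  df <- df |>
    mutate(y = match(.data$seq_id, seq_ids) + off[.data$what],
           h = hgt[.data$what])
  ggplot2::ggplot(df) +
    ggplot2::geom_rect(ggplot2::aes(
      xmin = .data$start, xmax = .data$end,
      ymin = .data$y - .data$h, ymax = .data$y + .data$h,
      fill = .data$what
    )) +
    ggplot2::scale_y_continuous(breaks = seq_along(seq_ids), labels = seq_ids) +
    ggplot2::labs(x = "residue position", y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}
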