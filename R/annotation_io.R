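#' Build a validated annotation table
#'
#' An annotation table bundles the three tidy tables the whole pipeline
#' works on: one row per protein, one row per domain hit, one row per
#' region annotation. All coordinates are 1-based and inclusive at both
#' ends, matching hmmscan alignment coordinates and TMHMM output.
#'
#' @param proteins tibble with columns `seq_id`, `length` and optionally
#'   `sequence` (NA allowed).
#' @param domain_hits tibble with columns `seq_id`, `model_name`,
#'   `model_acc`, `start`, `end`, `bit_score`, `evalue`, `source`
#'   (`"pfam"` or `"cdd"`). May be missing columns other than
#'   `seq_id`/`start`/`end`; they are filled with NA.
#' @param regions tibble with columns `seq_id`, `region_type` (one of
#'   `LC`, `TM`, `CC`, `SP`), `start`, `end`, `source_tool`.
#' @return an object of class `annotation_table`: a named list of the
#'   three tibbles, validated so that every hit and region points at a
#'   known protein and lies within its length.
#' @export
annotation_table <- function(proteins,
                             domain_hits = empty_domain_hits(),
                             regions = empty_regions()) {
  proteins <- as_tibble(proteins)
  if (!"sequence" %in% names(proteins)) proteins$sequence <- NA_character_
  proteins <- proteins |>
    mutate(seq_id = as.character(.data$seq_id), length = as.integer(.data$length)) |>
    select("seq_id", "length", "sequence")
  if (any(duplicated(proteins$seq_id))) {
    abort(paste0("duplicate seq_id: ",
                 paste(unique(proteins$seq_id[duplicated(proteins$seq_id)]), collapse = ", ")))
  }
  if (any(proteins$length < 1L)) abort("protein length must be >= 1")
  has_seq <- !is.na(proteins$sequence)
  if (any(nchar(proteins$sequence[has_seq]) != proteins$length[has_seq])) {
    abort("sequence character count must equal declared length")
  }

  domain_hits <- complete_hit_cols(as_tibble(domain_hits))
  regions <- complete_region_cols(as_tibble(regions))

  len_of <- setNames(proteins$length, proteins$seq_id)
  check_children(domain_hits, len_of, "domain hit")
  check_children(regions, len_of, "region")
  if (!all(regions$region_type %in% REGION_TYPES)) {
    abort(paste0("region_type must be one of ", paste(REGION_TYPES, collapse = "/")))
  }
  if (!all(domain_hits$source %in% c("pfam", "cdd"))) {
    abort("domain hit source must be 'pfam' or 'cdd'")
  }
  if (any(domain_hits$evalue < 0, na.rm = TRUE)) abort("evalue must be >= 0")

  structure(
    list(proteins = proteins, domain_hits = domain_hits, regions = regions),
    class = "annotation_table"
  )
}

#' @export
print.annotation_table <- function(x, ...) {
  cat(sprintf(
    "<annotation_table> %d proteins (%s aa), %d domain hits, %d region annotations\n",
    nrow(x$proteins), format(sum(x$proteins$length), big.mark = ","),
    nrow(x$domain_hits), nrow(x$regions)
  ))
  invisible(x)
}

complete_hit_cols <- function(hits) {
  tmpl <- empty_domain_hits()
  for (nm in names(tmpl)) {
    if (!nm %in% names(hits)) hits[[nm]] <- rep(tmpl[[nm]][NA_integer_], nrow(hits))
  }
  hits |>
    mutate(
      seq_id = as.character(.data$seq_id),
      model_name = as.character(.data$model_name),
      model_acc = as.character(.data$model_acc),
      start = as.integer(.data$start), end = as.integer(.data$end),
      bit_score = as.double(.data$bit_score), evalue = as.double(.data$evalue),
      source = as.character(.data$source)
    ) |>
    select(!!!names(tmpl))
}

complete_region_cols <- function(regions) {
  tmpl <- empty_regions()
  for (nm in names(tmpl)) {
    if (!nm %in% names(regions)) regions[[nm]] <- rep(tmpl[[nm]][NA_integer_], nrow(regions))
  }
  regions |>
    mutate(
      seq_id = as.character(.data$seq_id), region_type = as.character(.data$region_type),
      start = as.integer(.data$start), end = as.integer(.data$end),
      source_tool = as.character(.data$source_tool)
    ) |>
    select(!!!names(tmpl))
}

check_children <- function(tab, len_of, what) {
  if (nrow(tab) == 0L) return(invisible(TRUE))
  unknown <- setdiff(tab$seq_id, names(len_of))
  if (length(unknown) > 0L) {
    abort(paste0(what, " refers to unknown seq_id: ", paste(head(unknown, 5), collapse = ", ")))
  }
  check_coords(tab$start, tab$end, what)
  if (any(tab$end > len_of[tab$seq_id])) {
    bad <- tab$seq_id[tab$end > len_of[tab$seq_id]]
    abort(paste0(what, " extends past protein length for: ", paste(head(unique(bad), 5), collapse = ", ")))
  }
  invisible(TRUE)
}

#' Read protein identifiers and lengths from a FASTA file
#'
#' Only identifiers, lengths and residue strings are used downstream; the
#' description after the first whitespace in each header is dropped.
#'
#' @param path FASTA file.
#' @return tibble with columns `seq_id`, `length`, `sequence`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    abort("read_fasta() needs the Biostrings package")
  }
  set <- tryCatch(Biostrings::readAAStringSet(path), error = function(e) NULL)
  if (is.null(set) || length(set) == 0L) {
    warn(paste0("no FASTA records in ", path))
    return(empty_proteins())
  }
  ids <- sub("\\s.*$", "", names(set))
  if (any(duplicated(ids))) {
    abort(paste0("duplicate seq_id in FASTA: ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  tibble(seq_id = ids, length = Biostrings::width(set),
         sequence = unname(as.character(set)))
}

dedup_hits <- function(hits) {
  distinct(hits, .data$seq_id, .data$model_name, .data$start, .data$end,
           .keep_all = TRUE)
}

#' Parse an HMMER3 per-domain table (hmmscan --domtblout)
#'
#' One domain hit per row. In hmmscan output the *target* is the profile
#' and the *query* is the protein, so `seq_id` comes from the query-name
#' column and `model_name`/`model_acc` from the target columns. The
#' per-domain independent E-value (i-Evalue) becomes `evalue`. Rows are
#' expected to reflect upstream `--cut_ga` filtering and are accepted
#' as-is; use `max_ievalue` for an optional extra post-filter.
#'
#' @param path domtblout file; lines beginning `#` are comments.
#' @param source hit source tag, `"pfam"` by default.
#' @param coords which coordinate pair to use: `"ali"` (alignment,
#'   default) or `"env"` (envelope).
#' @param max_ievalue optional numeric; drop rows with i-Evalue above it.
#' @return tibble of domain hits (see [annotation_table()]). Rows whose
#'   from-coordinate exceeds the to-coordinate are rejected with a warning.
#' @export
parse_domtblout <- function(path, source = "pfam",
                            coords = c("ali", "env"), max_ievalue = NULL) {
  coords <- match.arg(coords)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0L) return(empty_domain_hits())

  fields <- strsplit(trimws(lines), "\\s+")
  nf <- lengths(fields)
  if (any(nf < 22L)) {
    abort(paste0("domtblout line ", lineno[which(nf < 22L)[1]],
                 ": expected at least 22 whitespace-separated columns"))
  }
  col <- function(i) vapply(fields, `[[`, character(1), i)
  ci <- if (coords == "ali") c(18L, 19L) else c(20L, 21L)
  from_raw <- col(ci[1]); to_raw <- col(ci[2])
  from <- suppressWarnings(as.integer(from_raw))
  to <- suppressWarnings(as.integer(to_raw))
  if (anyNA(from) || anyNA(to)) {
    abort(paste0("domtblout line ", lineno[which(is.na(from) | is.na(to))[1]],
                 ": non-numeric coordinate"))
  }
  hits <- tibble(
    seq_id = col(4), model_name = col(1),
    model_acc = dplyr::na_if(col(2), "-"),
    start = from, end = to,
    bit_score = as.double(col(14)), evalue = as.double(col(13)),
    source = source
  )
  bad <- hits$start > hits$end
  if (any(bad)) {
    warn(sprintf("rejected %d domtblout row(s) with from > to", sum(bad)))
    hits <- hits[!bad, ]
  }
  if (!is.null(max_ievalue)) hits <- filter(hits, .data$evalue <= max_ievalue)
  dedup_hits(hits)
}

#' Parse RPS-BLAST tabular hits (CDD)
#'
#' Standard 12-column BLAST tabular output (`-outfmt 6`); query
#' coordinates are columns 7-8 and become `start`/`end` (swapped and
#' flagged with a warning if reported reversed), the E-value is column 11
#' and the bit score column 12. All hits are tagged `source = "cdd"`.
#'
#' @param path tabular hits file; `#` comment lines allowed.
#' @return tibble of domain hits.
#' @export
parse_rpsblast_tab <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0L) return(empty_domain_hits())
  fields <- strsplit(trimws(lines), "\\s+")
  nf <- lengths(fields)
  if (any(nf != 12L)) {
    abort(paste0("RPS-BLAST tabular line ", lineno[which(nf != 12L)[1]],
                 ": expected 12 columns, got ", nf[which(nf != 12L)[1]]))
  }
  col <- function(i) vapply(fields, `[[`, character(1), i)
  qs <- suppressWarnings(as.integer(col(7)))
  qe <- suppressWarnings(as.integer(col(8)))
  if (anyNA(qs) || anyNA(qe)) {
    abort(paste0("RPS-BLAST tabular line ", lineno[which(is.na(qs) | is.na(qe))[1]],
                 ": non-numeric query coordinate"))
  }
  rev <- qs > qe
  if (any(rev)) {
    warn(sprintf("normalized %d RPS-BLAST row(s) with reversed query coordinates", sum(rev)))
  }
  hits <- tibble(
    seq_id = col(1), model_name = col(2), model_acc = NA_character_,
    start = pmin(qs, qe), end = pmax(qs, qe),
    bit_score = as.double(col(12)), evalue = as.double(col(11)),
    source = "cdd"
  )
  dedup_hits(hits)
}

#' Parse TMHMM2 long-format output into TM regions
#'
#' Only `TMhelix` rows become annotations; topology rows (`inside`,
#' `outside`) are ignored. Malformed lines are skipped with a warning.
#'
#' @param path TMHMM2 long-format file
#'   (`<seq_id> TMHMM2.0 <label> <start> <end>`).
#' @return tibble of TM regions with `source_tool = "tmhmm"`.
#' @export
parse_tmhmm <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) return(empty_regions())
  fields <- strsplit(trimws(lines), "\\s+")
  ok <- lengths(fields) >= 5L
  if (any(!ok)) warn(sprintf("skipped %d malformed TMHMM line(s)", sum(!ok)))
  fields <- fields[ok]
  if (length(fields) == 0L) return(empty_regions())
  lab <- vapply(fields, `[[`, character(1), 3)
  fields <- fields[lab == "TMhelix"]
  if (length(fields) == 0L) return(empty_regions())
  st <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 4)))
  en <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 5)))
  bad <- is.na(st) | is.na(en) | st > en | st < 1L
  if (any(bad)) warn(sprintf("skipped %d TMhelix line(s) with bad coordinates", sum(bad)))
  tibble(
    seq_id = vapply(fields, `[[`, character(1), 1)[!bad],
    region_type = "TM", start = st[!bad], end = en[!bad],
    source_tool = "tmhmm"
  ) |> distinct()
}

#' Parse SEG interval-list output into low-complexity regions
#'
#' Supports the interval-list dialect (`seg -l`): headers of the form
#' `>seq_id(start-end) complexity=...`; sequence lines between headers are
#' ignored. The masked-FASTA dialect is not supported.
#'
#' @param path SEG `-l` output file.
#' @return tibble of LC regions with `source_tool = "seg"`.
#' @export
parse_seg <- function(path) {
  lines <- readLines(path, warn = FALSE)
  heads <- grep("^>", lines, value = TRUE)
  if (length(heads) == 0L) {
    if (any(nzchar(trimws(lines)))) {
      abort("unrecognized SEG dialect: expected interval-list headers like '>seq_id(start-end) ...' (seg -l output)")
    }
    return(empty_regions())
  }
  m <- regmatches(heads, regexec("^>\\s*(\\S+?)\\((\\d+)-(\\d+)\\)", heads))
  bad <- lengths(m) != 4L
  if (any(bad)) {
    abort("unrecognized SEG dialect: expected interval-list headers like '>seq_id(start-end) ...' (seg -l output)")
  }
  tibble(
    seq_id = vapply(m, `[[`, character(1), 2),
    region_type = "LC",
    start = as.integer(vapply(m, `[[`, character(1), 3)),
    end = as.integer(vapply(m, `[[`, character(1), 4)),
    source_tool = "seg"
  ) |> distinct()
}

#' Parse Phobius output into SP (and Phobius TM) regions
#'
#' Reads the feature-line dialect: `ID <seq_id>` starts a record, `FT`
#' lines with `SIGNAL` or `TRANSMEM` carry intervals, `//` ends a record.
#' Signal peptides come out as `SP` regions. TRANSMEM lines are returned
#' too (tagged `source_tool = "phobius"`) but are excluded from TM totals
#' by default downstream: TMHMM is the authority for the TM column (see
#' the `tm_source` argument of [aggregate_space()]).
#'
#' @param path Phobius output file.
#' @return tibble of SP and TM regions with `source_tool = "phobius"`.
#' @export
parse_phobius <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(empty_regions())
  if (!any(grepl("^ID\\s+", lines))) {
    abort("unrecognized Phobius dialect: expected 'ID <seq_id>' records with 'FT SIGNAL/TRANSMEM <from> <to>' lines")
  }
  cur <- NA_character_
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (startsWith(ln, "ID")) {
      cur <- strsplit(ln, "\\s+")[[1]][2]
    } else if (startsWith(ln, "FT")) {
      f <- strsplit(ln, "\\s+")[[1]]
      if (length(f) >= 4L && f[2] %in% c("SIGNAL", "TRANSMEM")) {
        st <- suppressWarnings(as.integer(f[3]))
        en <- suppressWarnings(as.integer(f[4]))
        if (is.na(cur) || is.na(st) || is.na(en)) {
          warn(sprintf("skipped malformed Phobius feature line %d", i))
        } else {
          out[[i]] <- tibble(
            seq_id = cur,
            region_type = if (f[2] == "SIGNAL") "SP" else "TM",
            start = st, end = en, source_tool = "phobius"
          )
        }
      }
    }
  }
  res <- bind_rows(out)
  if (nrow(res) == 0L) return(empty_regions())
  distinct(res)
}

#' Parse PairCoil2 per-residue output into coiled-coil regions
#'
#' Expects the per-residue table (`seq_id position residue probability`);
#' maximal runs of consecutive residues whose coiled-coil probability is
#' at or above `threshold` are merged into one CC interval each.
#'
#' @param path PairCoil2 per-residue table; `#` comment lines allowed.
#' @param threshold coiled-coil probability cutoff (default 0.5, the
#'   tool's reported decision threshold).
#' @return tibble of CC regions with `source_tool = "paircoil2"`.
#' @export
parse_paircoil2 <- function(path, threshold = 0.5) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) return(empty_regions())
  fields <- strsplit(trimws(lines), "\\s+")
  if (any(lengths(fields) < 4L)) {
    abort("unrecognized PairCoil2 dialect: expected per-residue rows 'seq_id position residue probability'")
  }
  df <- tibble(
    seq_id = vapply(fields, `[[`, character(1), 1),
    pos = suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 2))),
    p = suppressWarnings(as.double(vapply(fields, `[[`, character(1), 4)))
  )
  if (anyNA(df$pos) || anyNA(df$p)) {
    abort("unrecognized PairCoil2 dialect: expected per-residue rows 'seq_id position residue probability'")
  }
  df <- df |> filter(.data$p >= threshold) |> arrange(.data$seq_id, .data$pos)
  if (nrow(df) == 0L) return(empty_regions())
  df |>
    group_by(.data$seq_id) |>
    mutate(run = cumsum(c(1L, diff(.data$pos) != 1L))) |>
    group_by(.data$seq_id, .data$run) |>
    summarise(start = min(.data$pos), end = max(.data$pos), .groups = "drop") |>
    mutate(region_type = "CC", source_tool = "paircoil2") |>
    select("seq_id", "region_type", "start", "end", "source_tool")
}

# ---- unified annotation TSV ------------------------------------------------

TSV_HEADER <- c("seq_id", "seq_len", "category", "type", "name",
                "accession", "start", "end", "bit_score", "evalue")

#' Write an annotation table to the unified TSV
#'
#' One row per protein (`category = protein`), domain hit
#' (`category = domain`, `type` pfam/cdd) and region annotation
#' (`category = region`, `type` LC/TM/CC/SP, `name` holding the source
#' tool). Inapplicable cells are empty strings; rows are sorted by
#' (seq_id, category, start). Residue strings are not stored, so the
#' round trip is lossless up to sequences.
#'
#' @param table an [annotation_table()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_annotation_tsv <- function(table, path) {
  stopifnot(inherits(table, "annotation_table"))
  len_of <- setNames(table$proteins$length, table$proteins$seq_id)
  prot <- tibble(
    seq_id = table$proteins$seq_id, seq_len = table$proteins$length,
    category = "protein", type = "", name = "", accession = "",
    start = NA_integer_, end = NA_integer_,
    bit_score = NA_real_, evalue = NA_real_
  )
  dom <- tibble(
    seq_id = table$domain_hits$seq_id,
    seq_len = unname(len_of[table$domain_hits$seq_id]),
    category = "domain", type = table$domain_hits$source,
    name = table$domain_hits$model_name,
    accession = dplyr::coalesce(table$domain_hits$model_acc, ""),
    start = table$domain_hits$start, end = table$domain_hits$end,
    bit_score = table$domain_hits$bit_score, evalue = table$domain_hits$evalue
  )
  reg <- tibble(
    seq_id = table$regions$seq_id,
    seq_len = unname(len_of[table$regions$seq_id]),
    category = "region", type = table$regions$region_type,
    name = table$regions$source_tool, accession = "",
    start = table$regions$start, end = table$regions$end,
    bit_score = NA_real_, evalue = NA_real_
  )
  all <- bind_rows(prot, dom, reg) |>
    arrange(.data$seq_id, .data$category, .data$start)
  out <- all |>
    mutate(
      start = ifelse(is.na(.data$start), "", as.character(.data$start)),
      end = ifelse(is.na(.data$end), "", as.character(.data$end)),
      bit_score = ifelse(is.na(.data$bit_score), "", sprintf("%.1f", .data$bit_score)),
      evalue = ifelse(is.na(.data$evalue), "", sprintf("%.3g", .data$evalue))
    )
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(TSV_HEADER, collapse = "\t"), con)
  if (nrow(out) > 0L) {
    writeLines(do.call(paste, c(lapply(out, as.character), sep = "\t")), con)
  }
  invisible(path)
}

#' Read the unified annotation TSV back into an annotation table
#'
#' @param path TSV written by [write_annotation_tsv()] (header row,
#'   `#` comment lines allowed).
#' @return an [annotation_table()] (sequences are NA: the TSV does not
#'   carry residue strings).
#' @export
read_annotation_tsv <- function(path) {
  raw <- readr::read_tsv(
    path, comment = "#", col_types = readr::cols(.default = readr::col_character()),
    na = character(), progress = FALSE
  )
  if (!identical(names(raw), TSV_HEADER)) {
    abort(paste0("unexpected TSV header: expected ",
                 paste(TSV_HEADER, collapse = " ")))
  }
  bad_cat <- which(!raw$category %in% c("protein", "domain", "region"))
  if (length(bad_cat) > 0L) {
    abort(paste0("line ", bad_cat[1] + 1L, ": unknown category '",
                 raw$category[bad_cat[1]], "'"))
  }
  bad_type <- which(
    (raw$category == "domain" & !raw$type %in% c("pfam", "cdd")) |
      (raw$category == "region" & !raw$type %in% REGION_TYPES)
  )
  if (length(bad_type) > 0L) {
    abort(paste0("line ", bad_type[1] + 1L, ": unknown type '",
                 raw$type[bad_type[1]], "' for category ", raw$category[bad_type[1]]))
  }
  prot <- raw |> filter(.data$category == "protein")
  dom <- raw |> filter(.data$category == "domain")
  reg <- raw |> filter(.data$category == "region")
  proteins <- tibble(
    seq_id = prot$seq_id, length = as.integer(prot$seq_len),
    sequence = NA_character_
  )
  # proteins referenced only by annotation rows (legacy two-category files)
  extra <- bind_rows(dom, reg) |>
    distinct(.data$seq_id, .data$seq_len) |>
    filter(!.data$seq_id %in% proteins$seq_id)
  if (nrow(extra) > 0L) {
    proteins <- bind_rows(proteins, tibble(
      seq_id = extra$seq_id, length = as.integer(extra$seq_len),
      sequence = NA_character_
    ))
  }
  hits <- tibble(
    seq_id = dom$seq_id, model_name = dom$name,
    model_acc = dplyr::na_if(dom$accession, ""),
    start = as.integer(dom$start), end = as.integer(dom$end),
    bit_score = as.double(dom$bit_score), evalue = as.double(dom$evalue),
    source = dom$type
  )
  regions <- tibble(
    seq_id = reg$seq_id, region_type = reg$type,
    start = as.integer(reg$start), end = as.integer(reg$end),
    source_tool = reg$name
  )
  annotation_table(proteins, hits, regions)
}
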