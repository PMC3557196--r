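#' Emit a synthetic proteome in every supported input dialect
#'
#' Writes, under `out_dir`: `proteins.fasta`, `pfam.domtblout` (hmmscan
#' per-domain table), `cdd.rpsblast.tsv` (12-column BLAST tabular),
#' `tmhmm.txt` (long format with topology filler lines), `seg.txt`
#' (interval-list dialect), `phobius.txt` (ID/FT records; SIGNAL lines
#' from the planted signal peptides, TRANSMEM lines echoing the TM
#' helices), `paircoil2.txt` (per-residue probabilities around
#' coiled-coil regions), the unified `annotations.tsv`, the ground-truth
#' tables `truth_proteins.tsv`/`truth_segments.tsv`, and `config.yaml`.
#' Re-parsing every dialect reproduces the annotation table exactly; the
#' emission itself uses no random numbers, so the same proteome always
#' writes byte-identical files.
#'
#' @param sim a `synthetic_proteome` from [generate_proteome()].
#' @param out_dir output directory (created if needed).
#' @return named character vector of written paths, invisibly.
#' @export
emit_formats <- function(sim, out_dir) {
  stopifnot(inherits(sim, "synthetic_proteome"))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(paste0("cannot create output directory: ", out_dir))
  }
  tab <- sim$table
  len_of <- setNames(tab$proteins$length, tab$proteins$seq_id)
  paths <- c(
    fasta = file.path(out_dir, "proteins.fasta"),
    domtblout = file.path(out_dir, "pfam.domtblout"),
    rpsblast = file.path(out_dir, "cdd.rpsblast.tsv"),
    tmhmm = file.path(out_dir, "tmhmm.txt"),
    seg = file.path(out_dir, "seg.txt"),
    phobius = file.path(out_dir, "phobius.txt"),
    paircoil2 = file.path(out_dir, "paircoil2.txt"),
    tsv = file.path(out_dir, "annotations.tsv"),
    truth_proteins = file.path(out_dir, "truth_proteins.tsv"),
    truth_segments = file.path(out_dir, "truth_segments.tsv"),
    config = file.path(out_dir, "config.yaml")
  )

  # FASTA, wrapped at 60 columns
  if (any(is.na(tab$proteins$sequence)) && nrow(tab$proteins) > 0L) {
    abort("proteome has no residue strings; generate with with_sequences = TRUE")
  }
  fa <- character(0)
  if (nrow(tab$proteins) > 0L) {
    fa <- unlist(purrr::map2(tab$proteins$seq_id, tab$proteins$sequence,
                             function(id, s) {
      c(paste0(">", id),
        substring(s, seq(1, nchar(s), 60), pmin(seq(1, nchar(s), 60) + 59L, nchar(s))))
    }))
  }
  writeLines(fa, paths["fasta"])

  # hmmscan --domtblout: target = model, query = protein
  ph <- tab$domain_hits |> filter(.data$source == "pfam")
  dl <- c(
    "# target name        accession   tlen query name           accession   qlen   E-value  score  bias   #  of  c-Evalue  i-Evalue  score  bias  from    to  from    to  from    to  acc description of target",
    "#------------------- ---------- ----- -------------------- ---------- ----- --------- ------ ----- --- --- --------- --------- ------ ----- ----- ----- ----- ----- ----- ----- ---- ---------------------"
  )
  if (nrow(ph) > 0L) {
    w <- ph$end - ph$start + 1L
    dl <- c(dl, sprintf(
      "%-20s %-10s %5d %-20s %-10s %5d %9.2g %6.1f %5.1f %3d %3d %9.2g %9.3g %6.1f %5.1f %5d %5d %5d %5d %5d %5d %4.2f -",
      ph$model_name, dplyr::coalesce(ph$model_acc, "-"), w,
      ph$seq_id, "-", unname(len_of[ph$seq_id]),
      ph$evalue, ph$bit_score, 0.0, 1L, 1L,
      ph$evalue, ph$evalue, ph$bit_score, 0.0,
      1L, w, ph$start, ph$end, ph$start, ph$end, 0.90
    ))
  }
  writeLines(dl, paths["domtblout"])

  # RPS-BLAST 12-column tabular
  ch <- tab$domain_hits |> filter(.data$source == "cdd")
  bl <- character(0)
  if (nrow(ch) > 0L) {
    alen <- ch$end - ch$start + 1L
    bl <- sprintf("%s\t%s\t%.2f\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%.3g\t%.1f",
                  ch$seq_id, ch$model_name, 35.00, alen,
                  as.integer(round(alen * 0.65)), 0L,
                  ch$start, ch$end, 1L, alen, ch$evalue, ch$bit_score)
  }
  writeLines(bl, paths["rpsblast"])

  # TMHMM2 long format with topology filler rows
  tm <- tab$regions |>
    filter(.data$region_type == "TM", .data$source_tool == "tmhmm") |>
    arrange(.data$seq_id, .data$start)
  tl <- character(0)
  for (id in unique(tm$seq_id)) {
    r <- tm[tm$seq_id == id, , drop = FALSE]
    L <- len_of[[id]]
    if (r$start[1] > 1L) {
      tl <- c(tl, sprintf("%s\tTMHMM2.0\toutside\t%d\t%d", id, 1L, r$start[1] - 1L))
    }
    for (j in seq_len(nrow(r))) {
      tl <- c(tl, sprintf("%s\tTMHMM2.0\tTMhelix\t%d\t%d", id, r$start[j], r$end[j]))
      nxt <- if (j < nrow(r)) r$start[j + 1] - 1L else L
      if (r$end[j] < nxt) {
        side <- if (j %% 2 == 1) "inside" else "outside"
        tl <- c(tl, sprintf("%s\tTMHMM2.0\t%s\t%d\t%d", id, side, r$end[j] + 1L, nxt))
      }
    }
  }
  writeLines(tl, paths["tmhmm"])

  # SEG -l interval list: header + lowercase segment
  lc <- tab$regions |>
    filter(.data$region_type == "LC") |>
    arrange(.data$seq_id, .data$start)
  sl <- character(0)
  if (nrow(lc) > 0L) {
    seq_of <- setNames(tab$proteins$sequence, tab$proteins$seq_id)
    sl <- unlist(purrr::map(seq_len(nrow(lc)), function(j) {
      c(sprintf(">%s(%d-%d) complexity=2.20 (12/2.20/2.50)",
                lc$seq_id[j], lc$start[j], lc$end[j]),
        tolower(substr(seq_of[[lc$seq_id[j]]], lc$start[j], lc$end[j])))
    }))
  }
  writeLines(sl, paths["seg"])

  # Phobius ID/FT records: SIGNAL from planted SPs, TRANSMEM echoes TMs
  sp <- tab$regions |> filter(.data$region_type == "SP")
  pl <- character(0)
  ids_ph <- sort(unique(c(sp$seq_id, tm$seq_id)))
  for (id in ids_ph) {
    pl <- c(pl, paste0("ID   ", id))
    s <- sp[sp$seq_id == id, , drop = FALSE]
    for (j in seq_len(nrow(s))) {
      pl <- c(pl, sprintf("FT   SIGNAL   %6d %6d", s$start[j], s$end[j]))
    }
    t <- tm[tm$seq_id == id, , drop = FALSE]
    for (j in seq_len(nrow(t))) {
      pl <- c(pl, sprintf("FT   TRANSMEM %6d %6d", t$start[j], t$end[j]))
    }
    pl <- c(pl, "//")
  }
  writeLines(pl, paths["phobius"])

  # PairCoil2 per-residue table: coil residues at 0.90, 5-residue flanks
  # at 0.02 (below the 0.5 decision threshold), so runs merge back to the
  # planted intervals exactly
  cc <- tab$regions |>
    filter(.data$region_type == "CC") |>
    arrange(.data$seq_id, .data$start)
  cl <- c("# seq_id position residue p_coil")
  if (nrow(cc) > 0L) {
    seq_of <- setNames(tab$proteins$sequence, tab$proteins$seq_id)
    cl <- c(cl, unlist(purrr::map(seq_len(nrow(cc)), function(j) {
      id <- cc$seq_id[j]; L <- len_of[[id]]
      lo <- max(1L, cc$start[j] - 5L); hi <- min(L, cc$end[j] + 5L)
      pos <- lo:hi
      p <- ifelse(pos >= cc$start[j] & pos <= cc$end[j], 0.90, 0.02)
      aa <- substring(seq_of[[id]], pos, pos)
      sprintf("%s %d %s %.2f", id, pos, aa, p)
    })))
  }
  writeLines(cl, paths["paircoil2"])

  write_annotation_tsv(tab, paths["tsv"])
  readr::write_tsv(sim$truth$proteins, paths["truth_proteins"], progress = FALSE)
  readr::write_tsv(sim$truth$segments, paths["truth_segments"], progress = FALSE)

  cfg <- sim$truth$config
  scalar <- vapply(cfg, function(v) is.atomic(v) && length(v) == 1L, logical(1))
  writeLines(sprintf("%s: %s", names(cfg)[scalar],
                     vapply(cfg[scalar], format, character(1))),
             paths["config"])
  invisible(paths)
}

#' Read back every emitted dialect into one annotation table
#'
#' The parse side of [emit_formats()]: FASTA for the protein records,
#' domtblout + RPS-BLAST for the domain hits, TMHMM/SEG/Phobius/PairCoil2
#' for the regions. Phobius TRANSMEM rows are dropped here (TMHMM is the
#' TM authority; they duplicate its helices), matching the default
#' `tm_source = "tmhmm"`.
#'
#' @param dir directory written by [emit_formats()].
#' @return an [annotation_table()].
#' @export
read_emitted_formats <- function(dir) {
  proteins <- read_fasta(file.path(dir, "proteins.fasta"))
  hits <- bind_rows(
    parse_domtblout(file.path(dir, "pfam.domtblout")),
    parse_rpsblast_tab(file.path(dir, "cdd.rpsblast.tsv"))
  )
  phob <- parse_phobius(file.path(dir, "phobius.txt"))
  regions <- bind_rows(
    parse_tmhmm(file.path(dir, "tmhmm.txt")),
    parse_seg(file.path(dir, "seg.txt")),
    phob |> filter(.data$region_type == "SP"),
    parse_paircoil2(file.path(dir, "paircoil2.txt"))
  )
  annotation_table(proteins, hits, regions)
}
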