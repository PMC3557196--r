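#' Configuration of the synthetic proteome generator
#'
#' Defaults emulate the field's reported statistics: domains of 40-700 aa
#' with a mean near 100 (length = 40 + Gamma(shape 2, scale 30), capped
#' at 700), interdomain linkers averaging ~7 aa (1 + Poisson(6)), and 28%
#' of proteins carrying no domain at all (the complement of the ~72% of
#' database sequences assignable to known families). Terminal tails are a
#' short/long mixture so that both subtractable terminal linkers and
#' large uncovered termini occur. Region densities (TM helices ~21 aa,
#' N-terminal signal peptides of 15-30 aa, low-complexity and coiled-coil
#' stretches) are plausible proteome-scale rates and freely configurable.
#'
#' @param n_proteins number of proteins to generate.
#' @param seed integer seed; the same (config, seed) always yields
#'   byte-identical output.
#' @param fraction_domain_free probability a protein has zero domains.
#' @param domain_count_p,max_domains truncated-geometric domain count for
#'   domain-bearing proteins: P(k) proportional to (1-p)^(k-1), k = 1..max.
#' @param domain_len_shape,domain_len_scale,domain_len_min,domain_len_max
#'   domain length = min(max, round(min + Gamma(shape, scale))).
#' @param linker_lambda interdomain linker length = 1 + Poisson(lambda).
#' @param tail_short_mean,tail_long_prob,tail_long_min,tail_long_mean_excess
#'   terminal tail length: with probability `tail_long_prob` it is
#'   `tail_long_min` + Geometric(mean `tail_long_mean_excess`), otherwise
#'   Geometric(mean `tail_short_mean`).
#' @param free_len_meanlog,free_len_sdlog,free_len_min,free_len_max
#'   length of domain-free proteins: clamped lognormal.
#' @param sp_prob,sp_len_min,sp_len_max signal-peptide probability and
#'   length range (placed at the N terminus only).
#' @param tm_prob,tm_count_lambda,tm_len_mean,tm_len_sd membrane-protein
#'   probability, helix count (1 + Poisson), helix length (rounded
#'   normal, clamped to 15-30 aa).
#' @param lc_prob,lc_count_lambda,lc_len_min,lc_len_mean_excess
#'   low-complexity probability, count (1 + Poisson) and length
#'   (min + geometric excess).
#' @param cc_prob,cc_len_min,cc_len_mean_excess coiled-coil probability
#'   (at most one per protein) and length.
#' @param region_in_domain_prob probability that a TM/LC/CC region is
#'   anchored on a domain-covered residue (exercises the within/outside
#'   partition); placement falls back to uniform when the protein has no
#'   covered (or no uncovered) residue.
#' @param cdd_echo_prob probability each planted Pfam hit is echoed as a
#'   redundant CDD hit with identical coordinates.
#' @param cdd_full_prob probability a domain-bearing protein additionally
#'   gets one full-length PRK-style CDD profile hit.
#' @param linker_max segment-classification cutoff recorded in the ground
#'   truth.
#' @param with_sequences generate random residue strings (needed for
#'   FASTA/SEG emission); composition is irrelevant to the pipeline.
#' @return object of class `generator_config`.
#' @export
generator_config <- function(n_proteins = 1000,
                             seed = 1L,
                             fraction_domain_free = 0.28,
                             domain_count_p = 0.45,
                             max_domains = 8L,
                             domain_len_shape = 2,
                             domain_len_scale = 30,
                             domain_len_min = 40L,
                             domain_len_max = 700L,
                             linker_lambda = 6,
                             tail_short_mean = 10,
                             tail_long_prob = 0.15,
                             tail_long_min = 50L,
                             tail_long_mean_excess = 100,
                             free_len_meanlog = log(250),
                             free_len_sdlog = 0.6,
                             free_len_min = 30L,
                             free_len_max = 2000L,
                             sp_prob = 0.30,
                             sp_len_min = 15L,
                             sp_len_max = 30L,
                             tm_prob = 0.25,
                             tm_count_lambda = 1.5,
                             tm_len_mean = 21,
                             tm_len_sd = 1.5,
                             lc_prob = 0.40,
                             lc_count_lambda = 0.7,
                             lc_len_min = 8L,
                             lc_len_mean_excess = 12,
                             cc_prob = 0.15,
                             cc_len_min = 21L,
                             cc_len_mean_excess = 20,
                             region_in_domain_prob = 0.5,
                             cdd_echo_prob = 0.8,
                             cdd_full_prob = 0.1,
                             linker_max = 50L,
                             with_sequences = TRUE) {
  cfg <- as.list(environment())
  if (cfg$n_proteins < 0) abort("n_proteins must be >= 0")
  if (cfg$fraction_domain_free < 0 || cfg$fraction_domain_free > 1) {
    abort("fraction_domain_free must be in [0, 1]")
  }
  if (cfg$domain_len_min > cfg$domain_len_max) {
    abort("infeasible config: domain_len_min > domain_len_max")
  }
  if (cfg$domain_count_p <= 0 || cfg$domain_count_p >= 1) {
    abort("domain_count_p must be in (0, 1)")
  }
  if (cfg$max_domains < 1) abort("max_domains must be >= 1")
  if (cfg$linker_max < 1) abort("linker_max must be >= 1")
  if (cfg$free_len_min > cfg$free_len_max) {
    abort("infeasible config: free_len_min > free_len_max")
  }
  structure(cfg, class = "generator_config")
}

# geometric with given mean (>= 0); mean 0 degenerates to all zeros
rgeom_mean <- function(n, m) {
  if (m <= 0) return(integer(n))
  rgeom(n, prob = 1 / (1 + m))
}

rtrunc_geom <- function(n, p, kmax) {
  w <- (1 - p)^(seq_len(kmax) - 1L)
  sample.int(kmax, n, replace = TRUE, prob = w)
}

with_preserved_rng <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic proteome with ground truth
#'
#' Architectures are built left to right: N-terminal tail, then domains
#' alternating with short linkers, then a C-terminal tail; planted
#' domains never overlap each other (use [inject_overlap_decoys()] to
#' exercise overlap resolution). Regions are placed on top and may
#' overlap domains deliberately. Every quantity the pipeline later
#' recomputes is recorded directly from the construction blueprint, not
#' by running the pipeline.
#'
#' @param config a [generator_config()].
#' @return object of class `synthetic_proteome`: list with `table` (an
#'   [annotation_table()]) and `truth` (list: per-protein tibble
#'   `proteins` with planted domain counts/coverage, tibble `segments`
#'   with contexts and classes at `config$linker_max`, scalar
#'   `global_coverage`, and the `config`).
#' @export
generate_proteome <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  cfg <- config
  with_preserved_rng(cfg$seed, {
    n <- cfg$n_proteins
    ids <- sprintf("sp%05d", seq_len(n))
    cdd_counter <- 0L

    # column accumulators (one slot per protein), combined once at the end
    prot_len <- integer(n); prot_ndom <- integer(n); prot_domaa <- integer(n)
    h_seq <- vector("list", n); h_name <- vector("list", n)
    h_acc <- vector("list", n); h_s <- vector("list", n); h_e <- vector("list", n)
    h_bs <- vector("list", n); h_ev <- vector("list", n); h_src <- vector("list", n)
    r_type <- vector("list", n); r_s <- vector("list", n); r_e <- vector("list", n)
    s_s <- vector("list", n); s_e <- vector("list", n); s_ctx <- vector("list", n)

    draw_tail <- function() {
      if (runif(1) < cfg$tail_long_prob) {
        cfg$tail_long_min + rgeom_mean(1, cfg$tail_long_mean_excess)
      } else {
        rgeom_mean(1, cfg$tail_short_mean)
      }
    }

    region_tool <- c(LC = "seg", TM = "tmhmm", CC = "paircoil2", SP = "phobius")

    for (i in seq_len(n)) {
      id <- ids[i]
      free <- runif(1) < cfg$fraction_domain_free
      if (free) {
        len <- as.integer(min(max(round(rlnorm(1, cfg$free_len_meanlog,
                                               cfg$free_len_sdlog)),
                                  cfg$free_len_min), cfg$free_len_max))
        ds <- integer(0); de <- integer(0)
        s_s[[i]] <- 1L; s_e[[i]] <- len; s_ctx[[i]] <- "full_protein"
      } else {
        k <- rtrunc_geom(1, cfg$domain_count_p, cfg$max_domains)
        dlen <- as.integer(pmin(round(cfg$domain_len_min +
                                        rgamma(k, cfg$domain_len_shape,
                                               scale = cfg$domain_len_scale)),
                                cfg$domain_len_max))
        llen <- if (k > 1) 1L + rpois(k - 1L, cfg$linker_lambda) else integer(0)
        ntail <- as.integer(draw_tail())
        ctail <- as.integer(draw_tail())
        ds <- integer(k); de <- integer(k)
        gs <- integer(0); ge <- integer(0); gctx <- character(0)
        pos <- ntail + 1L
        if (ntail > 0L) {
          gs <- 1L; ge <- ntail; gctx <- "n_terminal"
        }
        for (j in seq_len(k)) {
          ds[j] <- pos; de[j] <- pos + dlen[j] - 1L
          pos <- de[j] + 1L
          if (j < k) {
            gs <- c(gs, pos); ge <- c(ge, pos + llen[j] - 1L)
            gctx <- c(gctx, "interdomain")
            pos <- pos + llen[j]
          }
        }
        len <- de[k] + ctail
        if (ctail > 0L) {
          gs <- c(gs, de[k] + 1L); ge <- c(ge, len); gctx <- c(gctx, "c_terminal")
        }
        s_s[[i]] <- gs; s_e[[i]] <- ge; s_ctx[[i]] <- gctx
      }

      # domain hit rows (pfam) + partially redundant cdd echoes
      k <- length(ds)
      if (k > 0L) {
        midx <- sample.int(500L, k, replace = TRUE)
        h_name[[i]] <- sprintf("dom%03d", midx)
        h_acc[[i]] <- sprintf("PF%05d", midx)
        h_s[[i]] <- ds; h_e[[i]] <- de
        h_bs[[i]] <- round(runif(k, 25, 300), 1)
        h_ev[[i]] <- signif(10^(-runif(k, 5, 40)), 2)
        h_src[[i]] <- rep("pfam", k)
        echo <- runif(k) < cfg$cdd_echo_prob
        if (any(echo)) {
          m <- sum(echo)
          idx <- cdd_counter + seq_len(m)
          cdd_counter <- cdd_counter + m
          h_name[[i]] <- c(h_name[[i]], sprintf("gnl|CDD|%06d", 200000L + idx))
          h_acc[[i]] <- c(h_acc[[i]], rep(NA_character_, m))
          h_s[[i]] <- c(h_s[[i]], ds[echo]); h_e[[i]] <- c(h_e[[i]], de[echo])
          h_bs[[i]] <- c(h_bs[[i]], round(runif(m, 25, 300), 1))
          h_ev[[i]] <- c(h_ev[[i]], signif(10^(-runif(m, 5, 40)), 2))
          h_src[[i]] <- c(h_src[[i]], rep("cdd", m))
        }
        if (runif(1) < cfg$cdd_full_prob) {
          cdd_counter <- cdd_counter + 1L
          h_name[[i]] <- c(h_name[[i]], sprintf("gnl|CDD|PRK%05d", cdd_counter))
          h_acc[[i]] <- c(h_acc[[i]], NA_character_)
          h_s[[i]] <- c(h_s[[i]], 1L); h_e[[i]] <- c(h_e[[i]], len)
          h_bs[[i]] <- c(h_bs[[i]], round(runif(1, 25, 300), 1))
          h_ev[[i]] <- c(h_ev[[i]], signif(10^(-runif(1, 5, 40)), 2))
          h_src[[i]] <- c(h_src[[i]], "cdd")
        }
        h_seq[[i]] <- rep(id, length(h_s[[i]]))
      }

      # regions: anchored placement on covered/uncovered residues
      place <- function(w) {
        w <- min(w, len)
        anchor <- if (k > 0L && runif(1) < cfg$region_in_domain_prob) {
          j <- sample.int(k, 1L)
          ds[j] + sample.int(de[j] - ds[j] + 1L, 1L) - 1L
        } else {
          sample.int(len, 1L)
        }
        s <- min(max(anchor - w %/% 2L, 1L), len - w + 1L)
        c(s, s + w - 1L)
      }
      rt <- character(0); rs <- integer(0); re <- integer(0)
      if (runif(1) < cfg$sp_prob) {
        w <- min(sample(seq(cfg$sp_len_min, cfg$sp_len_max), 1L), len)
        rt <- c(rt, "SP"); rs <- c(rs, 1L); re <- c(re, as.integer(w))
      }
      if (runif(1) < cfg$tm_prob) {
        for (h in seq_len(1L + rpois(1, cfg$tm_count_lambda))) {
          w <- as.integer(min(max(round(stats::rnorm(1, cfg$tm_len_mean,
                                                     cfg$tm_len_sd)), 15), 30))
          p <- place(w)
          rt <- c(rt, "TM"); rs <- c(rs, p[1]); re <- c(re, p[2])
        }
      }
      if (runif(1) < cfg$lc_prob) {
        for (h in seq_len(1L + rpois(1, cfg$lc_count_lambda))) {
          w <- cfg$lc_len_min + rgeom_mean(1, cfg$lc_len_mean_excess)
          p <- place(w)
          rt <- c(rt, "LC"); rs <- c(rs, p[1]); re <- c(re, p[2])
        }
      }
      if (runif(1) < cfg$cc_prob) {
        w <- cfg$cc_len_min + rgeom_mean(1, cfg$cc_len_mean_excess)
        p <- place(w)
        rt <- c(rt, "CC"); rs <- c(rs, p[1]); re <- c(re, p[2])
      }
      if (length(rt) > 0L) {
        keep <- !duplicated(paste(rt, rs, re))
        r_type[[i]] <- rt[keep]; r_s[[i]] <- rs[keep]; r_e[[i]] <- re[keep]
      }

      prot_len[i] <- len
      prot_ndom[i] <- k
      prot_domaa[i] <- sum(de - ds + 1L)
    }

    uc <- function(x, mode) {
      v <- unlist(x, use.names = FALSE)
      if (is.null(v)) vector(mode, 0L) else v
    }
    truth_prot <- tibble(
      seq_id = ids, length = prot_len, n_domains = prot_ndom,
      domain_aa = prot_domaa, domain_free = prot_ndom == 0L,
      coverage = ifelse(prot_len > 0L, prot_domaa / prot_len, NA_real_)
    )
    seg_start <- uc(s_s, "integer"); seg_end <- uc(s_e, "integer")
    seg_len <- seg_end - seg_start + 1L
    seg_ctx <- uc(s_ctx, "character")
    truth_segs <- tibble(
      seq_id = rep(ids, vapply(s_s, length, integer(1))),
      start = seg_start, end = seg_end, length = seg_len, context = seg_ctx,
      class = ifelse(seg_len < cfg$linker_max & seg_ctx != "full_protein",
                     "short_linker", "dark_matter")
    )
    hits <- tibble(
      seq_id = uc(h_seq, "character"),
      model_name = uc(h_name, "character"),
      model_acc = uc(h_acc, "character"),
      start = uc(h_s, "integer"), end = uc(h_e, "integer"),
      bit_score = uc(h_bs, "double"), evalue = uc(h_ev, "double"),
      source = uc(h_src, "character")
    )
    regions <- tibble(
      seq_id = rep(ids, vapply(r_type, length, integer(1))),
      region_type = uc(r_type, "character"),
      start = uc(r_s, "integer"), end = uc(r_e, "integer"),
      source_tool = unname(region_tool[uc(r_type, "character")])
    )
    sequences <- if (cfg$with_sequences && n > 0L) {
      vapply(truth_prot$length, function(L) {
        paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                       "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"),
                     L, replace = TRUE), collapse = "")
      }, character(1))
    } else rep(NA_character_, n)

    table <- annotation_table(
      tibble(seq_id = ids, length = truth_prot$length, sequence = sequences),
      hits, regions
    )
    structure(
      list(
        table = table,
        truth = list(
          proteins = truth_prot,
          segments = truth_segs,
          global_coverage = if (n > 0L) {
            sum(truth_prot$domain_aa) / sum(truth_prot$length)
          } else NA_real_,
          config = cfg
        )
      ),
      class = "synthetic_proteome"
    )
  })
}

#' @export
print.synthetic_proteome <- function(x, ...) {
  cat(sprintf(
    "<synthetic_proteome> %d proteins, planted coverage %.3f (seed %d)\n",
    nrow(x$truth$proteins), x$truth$global_coverage, x$truth$config$seed
  ))
  invisible(x)
}

#' Analytic expectation of the planted global coverage
#'
#' The expected fraction of residues inside planted domains under a
#' configuration, computed from the configured distributions (expectation
#' of domain residues over expectation of protein length, i.e. the limit
#' of the proteome-wide ratio as n grows); no sampling involved.
#'
#' @param config a [generator_config()].
#' @return expected global coverage fraction in \[0, 1\].
#' @export
planted_coverage <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  cfg <- config
  k <- seq_len(cfg$max_domains)
  w <- (1 - cfg$domain_count_p)^(k - 1)
  e_ndom <- sum(k * w) / sum(w)
  cap <- cfg$domain_len_max - cfg$domain_len_min
  e_gam_cap <- stats::integrate(
    function(x) pmin(x, cap) * stats::dgamma(x, cfg$domain_len_shape,
                                             scale = cfg$domain_len_scale),
    0, Inf
  )$value
  e_domlen <- cfg$domain_len_min + e_gam_cap
  e_link <- 1 + cfg$linker_lambda
  e_tail <- (1 - cfg$tail_long_prob) * cfg$tail_short_mean +
    cfg$tail_long_prob * (cfg$tail_long_min + cfg$tail_long_mean_excess)
  e_len_dom <- e_ndom * e_domlen + (e_ndom - 1) * e_link + 2 * e_tail
  e_domres <- e_ndom * e_domlen
  e_len_free <- stats::integrate(
    function(x) pmin(pmax(x, cfg$free_len_min), cfg$free_len_max) *
      stats::dlnorm(x, cfg$free_len_meanlog, cfg$free_len_sdlog),
    0, Inf
  )$value
  f <- cfg$fraction_domain_free
  num <- (1 - f) * e_domres
  den <- (1 - f) * e_len_dom + f * e_len_free
  if (den == 0) return(0)
  num / den
}

#' Inject overlapping decoy hits with known expected resolution
#'
#' For each planted Pfam hit of at least 2 residues, with probability
#' `decoy_prob` a strictly shorter decoy hit lying entirely inside it is
#' added (with a worse E-value). Under the greedy longest-domain rule the
#' expected resolution is known: every decoy is rejected and coverage is
#' unchanged.
#'
#' @param sim a `synthetic_proteome` ([generate_proteome()]).
#' @param decoy_prob per-hit decoy probability.
#' @param seed seed for decoy placement.
#' @return a `synthetic_proteome` whose table contains the decoys; the
#'   decoy rows are also attached as attribute `"decoys"`. Ground truth
#'   is unchanged.
#' @export
inject_overlap_decoys <- function(sim, decoy_prob = 0.6, seed = 1L) {
  stopifnot(inherits(sim, "synthetic_proteome"))
  with_preserved_rng(seed, {
    ph <- sim$table$domain_hits |>
      filter(.data$source == "pfam", .data$end - .data$start + 1L >= 2L)
    pick <- runif(nrow(ph)) < decoy_prob
    ph <- ph[pick, , drop = FALSE]
    decoys <- if (nrow(ph) > 0L) {
      purrr::map(seq_len(nrow(ph)), function(i) {
        L <- ph$end[i] - ph$start[i] + 1L
        w <- max(1L, L - sample.int(min(20L, L - 1L), 1L))
        s <- ph$start[i] + sample.int(L - w + 1L, 1L) - 1L
        tibble(
          seq_id = ph$seq_id[i],
          model_name = paste0(ph$model_name[i], "_decoy"),
          model_acc = NA_character_,
          start = s, end = s + w - 1L,
          bit_score = round(ph$bit_score[i] / 2, 1),
          evalue = signif(pmin(ph$evalue[i] * 1e3, 10), 2),
          source = "pfam"
        )
      }) |> bind_rows()
    } else empty_domain_hits()
    table <- annotation_table(
      sim$table$proteins,
      bind_rows(sim$table$domain_hits, decoys),
      sim$table$regions
    )
    out <- sim
    out$table <- table
    attr(out, "decoys") <- decoys
    out
  })
}
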