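# Synthetic genomes with planted promoter context, so that every stage of
# the pipeline (table training, scanning, peak calling, prediction,
# evaluation) is testable end to end with known truth. The generator
# emulates the statistical structure the method assumes: an A/T-rich i.i.d.
# intergenic background, genes whose proximal window (-200..-60 by default)
# is paved with a strand-biased pool of spacer-like and REG-like octamers, a
# neutral distal window, GC-elevated CDS free of pool octamers, and a 5'UTR
# that is either compositionally distinct (Arabidopsis-like) or
# promoter-like (the rice-mode cross-talk).

#' Default planted octamer pool
#'
#' Fourteen A-rich spacer-like octamers (their preferential planting on the
#' gene strand produces the strand bias exploited by direction calling) and
#' six mixed-composition REG-like octamers. Each has planting weight 0.07:
#' the expected number of planted copies per proximal window is
#' `(enrichment - 1) * rate`, so enrichment 1 is exactly the null background
#' and enrichment 8 paves roughly half of the 141-bp window.
#'
#' @return Tibble with columns `octamer`, `rate`, `tag`.
#' @export
default_context_pool <- function() {
  spacer <- c("AAAAAAAA", "AAAAAAAT", "AAAAAATA", "AAAAATAA", "AAAATAAA",
              "AAATAAAA", "AATAAAAA", "ATAAAAAA", "TAAAAAAA", "AATAAATA",
              "ATAAATAA", "AAATAAAT", "TAAATAAA", "AATTAAAA")
  reg <- c("ACGTGGCA", "CCGACAAA", "AAGCCCAT", "GGCCCATT", "CACGTGTC",
           "AGGCCCAA")
  tibble::tibble(octamer = c(spacer, reg), rate = 0.07,
                 tag = c(rep("spacer_like", length(spacer)),
                         rep("reg_like", length(reg))))
}

#' Synthetic genome configuration
#'
#' @param n_genes Number of planted genes.
#' @param chrom_len Chromosome length (bp).
#' @param background_gc Background GC fraction (0.36 Arabidopsis-like,
#'   0.43 rice-like).
#' @param context_pool Tibble of planted octamers with per-octamer planting
#'   weight (see [default_context_pool()]).
#' @param proximal_window Inclusive relative window that receives plants.
#' @param enrichment Planting intensity; expected plants per window per pool
#'   octamer is `(enrichment - 1) * rate`, so 1 means no planting (null).
#' @param utr_mode `"distinct"` (UTR compositionally distinct from the
#'   promoter) or `"promoter_like"` (UTR planted like the proximal window,
#'   emulating the rice 5'UTR cross-talk).
#' @param utr_len_range,cds_len_range Inclusive length ranges (bp).
#' @param utr_gc,cds_gc GC fractions of the distinct-mode UTR and the CDS.
#' @param strand_mix Fraction of genes on the minus strand.
#' @param n_orphans Extra truth TSSs placed in plain background (category
#'   `"Orphan"`, no planted context, no gene model).
#' @param seed RNG seed; generation is fully deterministic given the config.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_genes = 200L, chrom_len = 2e6,
                         background_gc = 0.36,
                         context_pool = default_context_pool(),
                         proximal_window = c(-200, -60), enrichment = 8,
                         utr_mode = c("distinct", "promoter_like"),
                         utr_len_range = c(60L, 200L),
                         cds_len_range = c(300L, 900L), utr_gc = 0.45,
                         cds_gc = 0.55, strand_mix = 0.5, n_orphans = 0L,
                         seed = 1L) {
  utr_mode <- match.arg(utr_mode)
  stopifnot(enrichment >= 1, background_gc > 0, background_gc < 1,
            strand_mix >= 0, strand_mix <= 1, n_genes >= 0)
  structure(list(n_genes = as.integer(n_genes), chrom_len = as.integer(chrom_len),
                 background_gc = background_gc, context_pool = context_pool,
                 proximal_window = proximal_window, enrichment = enrichment,
                 utr_mode = utr_mode, utr_len_range = utr_len_range,
                 cds_len_range = cds_len_range, utr_gc = utr_gc,
                 cds_gc = cds_gc, strand_mix = strand_mix,
                 n_orphans = as.integer(n_orphans), seed = as.integer(seed)),
            class = "synth_config")
}

base_probs <- function(gc) {
  c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
}

random_bases <- function(n, gc) {
  sample(DNA_BASES, n, replace = TRUE, prob = base_probs(gc))
}

# Random sequence (char vector) free of pool octamers, by rejection.
random_bases_no_pool <- function(n, gc, pool) {
  pat <- paste(pool, collapse = "|")
  for (try in 1:10) {
    x <- random_bases(n, gc)
    if (!grepl(pat, paste0(x, collapse = ""))) return(x)
  }
  x
}

# Plant pool octamers into a background character vector at non-overlapping
# positions; expected copies of octamer o = (enrichment - 1) * rate_o.
plant_octamers <- function(bg, pool, enrichment) {
  W <- length(bg)
  if (enrichment <= 1 || W < 8L) return(bg)
  k <- stats::rpois(nrow(pool), (enrichment - 1) * pool$rate)
  plants <- rep(pool$octamer, k)
  if (length(plants) == 0L) return(bg)
  plants <- sample(plants)
  free <- rep(TRUE, W)
  for (p in plants) {
    starts <- which(vapply(seq_len(W - 7L),
                           function(s) all(free[s:(s + 7L)]), logical(1)))
    if (length(starts) == 0L) break
    s <- if (length(starts) == 1L) starts else sample(starts, 1L)
    bg[s:(s + 7L)] <- strsplit(p, "")[[1L]]
    free[s:(s + 7L)] <- FALSE
  }
  bg
}

#' Generate a synthetic genome with planted promoter context
#'
#' Background bases are drawn i.i.d. at `background_gc`. Each gene occupies
#' one slot of the chromosome: a 1000-bp upstream region whose proximal
#' window is paved with pool octamers on the gene strand only, a 5'UTR, and
#' a GC-elevated CDS kept free of pool octamers. Deterministic given the
#' config seed.
#'
#' @param cfg A [synth_config()].
#' @return A `synth_genome` list: `genome` (named character vector),
#'   `genes` (gene-model tibble with `gene_lo`/`gene_hi` and `cds`/`utr5`
#'   list-columns), `truth` (TSS tibble: `gene_id`, `chrom`, `pos`,
#'   `strand`, `cds_start`, `category`, `tpm`, `tss_cds_dist`), and the
#'   `config`.
#' @export
make_genome <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  upstream_len <- 1000L
  construct_max <- upstream_len + cfg$utr_len_range[2L] + cfg$cds_len_range[2L]
  if (cfg$n_genes > 0L) {
    slot <- cfg$chrom_len %/% cfg$n_genes
    required <- construct_max + 400L
    if (slot < required) {
      rlang::abort(sprintf(
        "genes do not fit: need chrom_len >= %d for %d genes",
        required * cfg$n_genes, cfg$n_genes))
    }
  }
  withr::with_seed(cfg$seed, {
    chrom <- random_bases(cfg$chrom_len, cfg$background_gc)
    genes <- list()
    truth <- list()
    pool <- cfg$context_pool
    pw <- cfg$proximal_window
    # local (gene-orientation) indices of the proximal window inside the
    # 1000-bp upstream region: relative r <= -1 sits at local 1000 + r.
    p_lo <- upstream_len + pw[1L] + 1L   # 1-based local start
    p_hi <- upstream_len + pw[2L] + 1L   # 1-based local end
    for (i in seq_len(cfg$n_genes)) {
      strand <- if (stats::runif(1) < cfg$strand_mix) "-" else "+"
      ul <- sample(cfg$utr_len_range[1L]:cfg$utr_len_range[2L], 1L)
      cl <- sample(cfg$cds_len_range[1L]:cfg$cds_len_range[2L], 1L)
      Lc <- upstream_len + ul + cl
      up <- random_bases(upstream_len, cfg$background_gc)
      up[p_lo:p_hi] <- plant_octamers(up[p_lo:p_hi], pool, cfg$enrichment)
      utr <- if (cfg$utr_mode == "promoter_like") {
        w <- random_bases(ul, cfg$background_gc)
        plant_octamers(w, pool, cfg$enrichment)
      } else {
        random_bases_no_pool(ul, cfg$utr_gc, pool$octamer)
      }
      cds <- random_bases_no_pool(cl, cfg$cds_gc, pool$octamer)
      construct <- c(up, utr, cds)
      slack <- slot - Lc - 300L
      offset <- 100L + sample.int(min(200L, slack), 1L)
      g0 <- (i - 1L) * slot + offset
      if (strand == "+") {
        tss <- g0 + upstream_len
        cds_lo <- g0 + upstream_len + ul
        cds_hi <- cds_lo + cl
        cds_start <- cds_lo
        utr_iv <- c(tss, cds_lo)
      } else {
        construct <- rev(unname(
          c(A = "T", C = "G", G = "C", T = "A")[construct]))
        tss <- g0 + ul + cl - 1L
        cds_lo <- g0
        cds_hi <- g0 + cl
        cds_start <- cds_hi - 1L
        utr_iv <- c(cds_hi, cds_hi + ul)
      }
      chrom[(g0 + 1L):(g0 + Lc)] <- construct
      gid <- sprintf("g%04d", i)
      genes[[i]] <- tibble::tibble(
        gene_id = gid, chrom = "chr1", strand = strand,
        cds_start = cds_start, tss = tss, gene_lo = g0, gene_hi = g0 + Lc,
        cds = list(matrix(c(cds_lo, cds_hi), ncol = 2L)),
        utr5 = list(matrix(utr_iv, ncol = 2L)))
      truth[[i]] <- tibble::tibble(
        gene_id = gid, chrom = "chr1", pos = tss, strand = strand,
        cds_start = cds_start, category = "GenicTop",
        tpm = stats::rlnorm(1, meanlog = 3, sdlog = 1.5),
        tss_cds_dist = ul)
    }
    if (cfg$n_orphans > 0L && cfg$n_genes > 0L) {
      slots <- sample(seq_len(cfg$n_genes), min(cfg$n_orphans, cfg$n_genes))
      for (j in seq_along(slots)) {
        pos <- slots[j] * (cfg$chrom_len %/% cfg$n_genes) - 50L
        truth[[cfg$n_genes + j]] <- tibble::tibble(
          gene_id = sprintf("orphan%03d", j), chrom = "chr1", pos = pos,
          strand = sample(c("+", "-"), 1L), cds_start = NA_real_,
          category = "Orphan",
          tpm = stats::rlnorm(1, meanlog = 1, sdlog = 1),
          tss_cds_dist = NA_real_)
      }
    }
    genome <- c(chr1 = paste0(chrom, collapse = ""))
    structure(list(genome = genome,
                   genes = dplyr::bind_rows(genes),
                   truth = dplyr::bind_rows(truth),
                   config = cfg),
              class = "synth_genome")
  })
}

#' @export
print.synth_genome <- function(x, ...) {
  cat(sprintf("<synth_genome> %d bp, %d gene(s), enrichment=%g, utr_mode=%s\n",
              x$config$chrom_len, nrow(x$genes), x$config$enrichment,
              x$config$utr_mode))
  invisible(x)
}

#' Write a synthetic genome to standard files
#'
#' Emits `genome.fa`, `genes.gff3` and `truth.tsv` under `dir`.
#'
#' @param sg A `synth_genome`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synth_genome <- function(sg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genome(sg$genome, file.path(dir, "genome.fa"))
  write_gene_models(sg$genes, file.path(dir, "genes.gff3"))
  write_tss_table(sg$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}

#' TSS-anchored promoter set from a synthetic genome
#'
#' @param sg A `synth_genome`.
#' @param n Optional number of promoters to sample.
#' @param categories Truth categories to keep (default `"GenicTop"`).
#' @param seed Optional seed for the sampling.
#' @return Promoter tibble (`gene_id`, `chrom`, `pos`, `strand`,
#'   `category`, `tpm`).
#' @export
make_promoter_set <- function(sg, n = NULL, categories = "GenicTop",
                              seed = NULL) {
  ps <- sg$truth[sg$truth$category %in% categories,
                 c("gene_id", "chrom", "pos", "strand", "category", "tpm")]
  if (!is.null(n)) {
    if (n > nrow(ps)) rlang::abort("n exceeds available promoters")
    idx <- if (is.null(seed)) sample(nrow(ps), n)
           else withr::with_seed(seed, sample(nrow(ps), n))
    ps <- ps[sort(idx), , drop = FALSE]
  }
  ps
}

#' Split a promoter set into disjoint training and test halves
#'
#' @param ps Promoter tibble.
#' @param prop Training fraction.
#' @param seed Seed for the split.
#' @return List with elements `train` and `test` (disjoint gene ids).
#' @export
split_promoter_set <- function(ps, prop = 0.5, seed = 1L) {
  n <- nrow(ps)
  idx <- withr::with_seed(seed, sample(n, floor(prop * n)))
  list(train = ps[sort(idx), , drop = FALSE],
       test = ps[setdiff(seq_len(n), idx), , drop = FALSE])
}
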