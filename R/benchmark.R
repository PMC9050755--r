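# End-to-end parameter-recovery benchmark on a synthetic genome: train
# tables on half the planted genes, predict on the other half, and measure
# gene-anchored sensitivity/precision, direction accuracy, and the
# genome-wide false-positive rate. This is the package's scaled-down
# analogue of whole-genome benchmarking.

#' Train/predict recovery benchmark on a synthetic genome
#'
#' Generates a synthetic genome, trains a PRI table on a training half of
#' the planted promoters, scans the genome, predicts TSS windows for the
#' held-out genes and evaluates them (window containment, strand-aware),
#' calls direction for every gene-anchored prediction, and counts
#' genome-wide prediction windows containing no true TSS.
#'
#' @param seed RNG seed driving the genome, the split and all sampling.
#' @param n_genes,chrom_len,enrichment,utr_mode Passed to [synth_config()].
#' @param threshold Peak threshold for prediction.
#' @param train_fraction Fraction of genes used for table training.
#' @param bin Track smoothing width.
#' @param max_search_bp Upstream search range for gene-anchored prediction.
#' @return One-row tibble: `n_test`, `n_pred`, `tp`, `sensitivity`,
#'   `precision`, `f`, `direction_accuracy`, `n_genomewide`, `fp_per_mb`.
#' @export
run_recovery_benchmark <- function(seed = 1L, n_genes = 200L,
                                   chrom_len = 2e6, enrichment = 8,
                                   utr_mode = "distinct", threshold = 0,
                                   train_fraction = 0.5, bin = 151L,
                                   max_search_bp = 3000L) {
  cfg <- synth_config(n_genes = n_genes, chrom_len = chrom_len,
                      enrichment = enrichment, utr_mode = utr_mode,
                      seed = seed)
  sg <- make_genome(cfg)
  ps <- make_promoter_set(sg)
  sp <- split_promoter_set(ps, prop = train_fraction, seed = seed + 1L)
  pri <- train_pri(sp$train, sg$genome)
  tracks <- scan_genome(pri, sg$genome, bin = bin)
  pcfg <- predictor_config(threshold = threshold,
                           max_search_bp = max_search_bp,
                           smoothing_bin = bin)
  genes_test <- sg$genes[sg$genes$gene_id %in% sp$test$gene_id, , drop = FALSE]
  preds <- predict_tss(tracks, genes_test, pcfg)
  rep <- evaluate_predictions(preds, sp$test, mode = "window",
                              directional = TRUE, by_gene = TRUE)
  dir_acc <- if (nrow(preds) > 0L) {
    100 * mean(predict_direction(tracks, preds, pcfg) == preds$strand)
  } else NA_real_
  gw <- predict_genomewide(tracks, pcfg)
  mg <- match_predictions(gw, ps, mode = "window", directional = TRUE)
  fp <- nrow(gw) - mg$tp_prec
  tibble::tibble(n_test = nrow(sp$test), n_pred = nrow(preds), tp = rep$tp,
                 sensitivity = rep$sensitivity, precision = rep$precision,
                 f = rep$f, direction_accuracy = dir_acc,
                 n_genomewide = nrow(gw),
                 fp_per_mb = fp / (chrom_len / 1e6))
}

#' Mean table score of genic region types
#'
#' Scores each gene's proximal window, distal window, 5'UTR and CDS (and a
#' sample of intergenic segments) with [score_sequence()] and averages per
#' region type: the per-region-one-number view of table specificity.
#'
#' @param sg A `synth_genome`.
#' @param table An `octamer_table`.
#' @param proximal,distal Inclusive relative windows.
#' @param n_intergenic Number of random intergenic 141-bp segments scored.
#' @param seed Seed for the intergenic sampling.
#' @return Tibble with columns `region`, `mean_score`, `sd_score`, `n`.
#' @export
score_gene_regions <- function(sg, table, proximal = c(-200, -60),
                               distal = c(-750, -450), n_intergenic = 100L,
                               seed = 1L) {
  genome <- sg$genome
  genes <- sg$genes
  seqs <- list(proximal = character(0), distal = character(0),
               utr5 = character(0), cds = character(0))
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    chrom_seq <- genome[[g$chrom]]
    tss <- sg$truth$pos[match(g$gene_id, sg$truth$gene_id)]
    px <- extract_rel_window(chrom_seq, tss, g$strand, proximal[1L],
                             proximal[2L])
    dx <- extract_rel_window(chrom_seq, tss, g$strand, distal[1L],
                             distal[2L])
    if (!is.na(px)) seqs$proximal <- c(seqs$proximal, px)
    if (!is.na(dx)) seqs$distal <- c(seqs$distal, dx)
    cm <- g$cds[[1L]]
    seqs$cds <- c(seqs$cds, extract_interval(chrom_seq, cm[1L, 1L],
                                             cm[1L, 2L], g$strand))
  }
  seqs$utr5 <- utr5_sequences(genes, genome)
  spans <- cbind(pmax(genes$gene_lo - 1100L, 0L), genes$gene_hi + 200L)
  L <- nchar(genome[[1L]])
  inter <- withr::with_seed(seed, {
    out <- character(0)
    tries <- 0L
    while (length(out) < n_intergenic && tries < 50L * n_intergenic) {
      tries <- tries + 1L
      s <- sample.int(L - 141L, 1L) - 1L
      if (!any(s < spans[, 2L] & s + 141L > spans[, 1L])) {
        out <- c(out, extract_interval(genome[[1L]], s, s + 141L))
      }
    }
    out
  })
  seqs$intergenic <- inter
  rows <- purrr::imap(seqs, function(v, nm) {
    v <- v[nchar(v) >= 8L]
    sc <- vapply(v, function(s) score_sequence(table, s), numeric(1),
                 USE.NAMES = FALSE)
    tibble::tibble(region = nm, mean_score = mean(sc),
                   sd_score = stats::sd(sc), n = length(sc))
  })
  dplyr::bind_rows(rows)
}
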