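# Hand-built smoothed tracks with known peak structure.
mk_tracks <- function(vplus, vminus = rep(-1, length(vplus)), chrom = "chr1") {
  structure(stats::setNames(list(list(
    "+" = pritss:::new_score_track(chrom, "+", vplus, smoothed = TRUE,
                                   bin = 151L),
    "-" = pritss:::new_score_track(chrom, "-", vminus, smoothed = TRUE,
                                   bin = 151L))), chrom),
    class = "track_set", bin = 151L)
}

# A track with isolated triangular peaks; `at` are the 0-based apex positions.
peaky <- function(len, at, height = 1) {
  v <- rep(-0.5, len)
  for (p in at) v[p + 1 + (-1:1)] <- c(height / 2, height, height / 2)
  v
}

test_that("gene-anchored prediction picks the first qualifying peak upstream of the CDS", {
  len <- 2000L
  gene <- tibble::tibble(gene_id = "g", chrom = "chr1", strand = "+",
                         cds_start = 1500)
  # single peak at cds_start - 270
  tr <- mk_tracks(peaky(len, 1500 - 270))
  w <- predict_gene_tss(tr, gene)
  expect_equal(w$peak_pos, 1500 - 270)
  expect_equal(c(w$start, w$end), c(1500 - 269, 1500 - 69))
  expect_equal(w$end - w$start, 200)

  # peaks at -270 and -900: the nearer one wins
  tr2 <- mk_tracks(peaky(len, c(1500 - 900, 1500 - 270)))
  expect_equal(predict_gene_tss(tr2, gene)$peak_pos, 1500 - 270)

  # no peak at or above the threshold
  cfg_hi <- predictor_config(threshold = 5)
  expect_null(predict_gene_tss(tr, gene, cfg_hi))

  # peaks beyond max_search_bp are ignored
  cfg_near <- predictor_config(max_search_bp = 200L)
  expect_null(predict_gene_tss(tr, gene, cfg_near))
})

test_that("minus-strand windows mirror the plus-strand geometry", {
  len <- 2000L
  gene <- tibble::tibble(gene_id = "g", chrom = "chr1", strand = "-",
                         cds_start = 500)
  tr <- mk_tracks(rep(-1, len), peaky(len, 500 + 270))
  w <- predict_gene_tss(tr, gene)
  expect_equal(w$peak_pos, 500 + 270)
  expect_equal(c(w$start, w$end), c(500 + 70, 500 + 270))
  expect_equal(w$end - w$start, 200)
  # window is downstream-adjacent to the peak in gene orientation
  expect_equal(w$end, w$peak_pos)
})

test_that("every predicted window has length 200 adjacent to its peak", {
  withr::with_seed(51, {
    for (rep in 1:20) {
      len <- 3000L
      st <- sample(c("+", "-"), 1)
      cds <- sample(1000:2000, 1)
      peak_at <- if (st == "+") cds - sample(50:900, 3) else
        cds + sample(50:900, 3)
      v <- peaky(len, peak_at)
      tr <- if (st == "+") mk_tracks(v) else mk_tracks(rep(-1, len), v)
      g <- tibble::tibble(gene_id = "g", chrom = "chr1", strand = st,
                          cds_start = cds)
      w <- predict_gene_tss(tr, g)
      expect_equal(w$end - w$start, 200)
      if (st == "+") {
        expect_equal(w$start, w$peak_pos + 1)
        expect_lt(w$peak_pos, cds)
      } else {
        expect_equal(w$end, w$peak_pos)
        expect_gt(w$peak_pos, cds)
      }
    }
  })
})

test_that("genome-wide prediction emits one window per above-threshold peak", {
  tr0 <- mk_tracks(rep(-1, 1000), rep(-1, 1000))
  expect_equal(nrow(predict_genomewide(tr0)), 0L)

  tr <- mk_tracks(peaky(1000, c(100, 500)), peaky(1000, 800))
  gw <- predict_genomewide(tr, predictor_config(threshold = 0.9))
  pk_n <- nrow(find_peaks(tr[["chr1"]][["+"]], 0.9)) +
    nrow(find_peaks(tr[["chr1"]][["-"]], 0.9))
  expect_equal(nrow(gw), pk_n)
  expect_equal(nrow(gw), 3L)
  expect_true(all(gw$end - gw$start == 200))
})

test_that("direction is called from the larger strand maximum, ties to the gene strand", {
  vp <- rep(0.1, 1000); vp[500] <- 0.5
  vm <- rep(0.1, 1000); vm[510] <- 0.2
  tr <- mk_tracks(vp, vm)
  w <- tibble::tibble(gene_id = "g", chrom = "chr1", strand = "-",
                      start = 500, end = 700, peak_pos = 499,
                      peak_height = 0.5)
  expect_equal(predict_direction(tr, w), "+")
  # exact tie falls back to the window's own strand
  tr_tie <- mk_tracks(rep(0.3, 1000), rep(0.3, 1000))
  expect_equal(predict_direction(tr_tie, w), "-")
  w$strand <- NA_character_
  expect_equal(predict_direction(tr_tie, w), "+")
})

test_that("the FUI filter requires a 5'UTR-like signal between peak and CDS", {
  gene <- tibble::tibble(gene_id = "g", chrom = "chr1", strand = "+",
                         cds_start = 800)
  pred <- tibble::tibble(gene_id = "g", chrom = "chr1", strand = "+",
                         start = 501, end = 701, peak_pos = 500,
                         peak_height = 1)
  fui_neg <- mk_tracks(rep(-0.2, 1000))
  expect_false(apply_fui_filter(pred, fui_neg, gene))
  v <- rep(-0.2, 1000); v[650:700] <- 0.3
  expect_true(apply_fui_filter(pred, mk_tracks(v), gene))
  # positive stretch outside the peak..CDS span does not count
  v2 <- rep(-0.2, 1000); v2[100:200] <- 0.3
  expect_false(apply_fui_filter(pred, mk_tracks(v2), gene))
})

test_that("threshold sweep rows are internally consistent", {
  len <- 3000L
  genes <- tibble::tibble(gene_id = c("a", "b"), chrom = "chr1",
                          strand = "+", cds_start = c(1000, 2500))
  truth <- tibble::tibble(gene_id = c("a", "b"), chrom = "chr1",
                          pos = c(900, 2400), strand = "+")
  tr <- mk_tracks(peaky(len, c(850, 2350), height = 1))
  expect_error(sweep_threshold(tr, genes, truth, numeric(0)), "empty")
  one <- sweep_threshold(tr, genes, truth, 0.5)
  expect_equal(nrow(one), 1L)
  sw <- sweep_threshold(tr, genes, truth, c(0, 0.5, 1, 2))
  # harmonic-mean identity holds exactly on every row
  expect_equal(sw$f * (sw$sensitivity + sw$precision),
               2 * sw$sensitivity * sw$precision)
  expect_equal(attr(sw, "best_threshold"), 0)
  expect_equal(sw$n_pred[sw$threshold == 2], 0L)
})
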