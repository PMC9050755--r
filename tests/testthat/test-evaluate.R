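test_that("window matching respects half-open boundaries and strand", {
  preds <- tibble::tibble(gene_id = "g", chrom = "chr1", strand = "+",
                          start = 270, end = 470, peak_pos = 269,
                          peak_height = 1)
  hit <- function(pos, strand = "+", directional = TRUE) {
    truth <- tibble::tibble(gene_id = "g", chrom = "chr1", pos = pos,
                            strand = strand)
    match_predictions(preds, truth, directional = directional)$tp
  }
  expect_equal(hit(300), 1L)
  expect_equal(hit(270), 1L)
  expect_equal(hit(470), 0L)   # half-open right boundary
  expect_equal(hit(269), 0L)
  expect_equal(hit(300, strand = "-"), 0L)
  expect_equal(hit(300, strand = "-", directional = FALSE), 1L)
})

test_that("point mode matches within 100 bp of the prediction point", {
  preds <- tibble::tibble(gene_id = "g", chrom = "chr1", strand = "+",
                          start = 200, end = 400, peak_pos = 199,
                          peak_height = 1)
  truth <- tibble::tibble(gene_id = "g", chrom = "chr1",
                          pos = c(250, 390, 401), strand = "+")
  m <- match_predictions(preds, truth, mode = "point100")
  # midpoint 300: 250 and 390 are within 100, 401 is not
  expect_equal(m$tp, 2L)
  preds$point <- 395
  m2 <- match_predictions(preds, truth, mode = "point100")
  expect_equal(m2$tp, 2L)
  expect_setequal(m2$truth_ids, c("g", "g"))
})

test_that("matching agrees with the all-pairs brute-force oracle", {
  withr::with_seed(61, {
    for (rep in 1:25) {
      np <- sample(1:15, 1); nt <- sample(1:15, 1)
      start <- sample(0:800, np)
      preds <- tibble::tibble(
        gene_id = NA_character_, chrom = sample(c("c1", "c2"), np, TRUE),
        strand = sample(c("+", "-"), np, TRUE),
        start = start, end = start + 200, peak_pos = start - 1,
        peak_height = 1)
      truth <- tibble::tibble(
        gene_id = sprintf("t%d", 1:nt), chrom = sample(c("c1", "c2"), nt, TRUE),
        pos = sample(0:1000, nt), strand = sample(c("+", "-"), nt, TRUE))
      for (dl in c(TRUE, FALSE)) {
        m <- match_predictions(preds, truth, directional = dl)
        orc <- oracle_match(preds, truth, directional = dl)
        expect_equal(m$tp_sens, orc$tp_sens)
        expect_equal(m$tp_prec, orc$tp_prec)
      }
    }
  })
})

test_that("matching is invariant under joint coordinate translation", {
  withr::with_seed(62, {
    start <- sample(0:500, 10)
    preds <- tibble::tibble(gene_id = NA, chrom = "c", strand = "+",
                            start = start, end = start + 200,
                            peak_pos = start - 1, peak_height = 1)
    truth <- tibble::tibble(gene_id = sprintf("t%d", 1:10), chrom = "c",
                            pos = sample(0:700, 10), strand = "+")
  })
  m0 <- match_predictions(preds, truth)
  preds2 <- dplyr::mutate(preds, start = start + 5000, end = end + 5000)
  truth2 <- dplyr::mutate(truth, pos = pos + 5000)
  m1 <- match_predictions(preds2, truth2)
  expect_equal(m0$tp_sens, m1$tp_sens)
  expect_equal(m0$tp_prec, m1$tp_prec)
})

test_that("metrics reproduce the published worked examples to two decimals", {
  m1 <- prediction_metrics(67, 94, 100)
  expect_equal(round(c(m1$sensitivity, m1$precision, m1$f), 2),
               c(67.00, 71.28, 69.07))
  m2 <- prediction_metrics(33, 61, 100)
  expect_equal(round(c(m2$sensitivity, m2$precision, m2$f), 2),
               c(33.00, 54.10, 40.99))
  m3 <- prediction_metrics(0, 10, 100)
  expect_equal(c(m3$sensitivity, m3$precision, m3$f), c(0, 0, 0))
  expect_error(prediction_metrics(1, 1, 0), "positive")
  # perfect prediction and the exact harmonic-mean identity
  expect_equal(unlist(prediction_metrics(7, 7, 7)[, c("sensitivity",
                                                      "precision", "f")]),
               c(sensitivity = 100, precision = 100, f = 100))
  m4 <- prediction_metrics(13, 29, 41)
  expect_identical(m4$f * (m4$sensitivity + m4$precision),
                   2 * m4$sensitivity * m4$precision)
})

test_that("a window spanning two TSSs counts twice for sensitivity, once for precision", {
  preds <- tibble::tibble(gene_id = NA, chrom = "c", strand = "+",
                          start = 100, end = 300, peak_pos = 99,
                          peak_height = 1)
  truth <- tibble::tibble(gene_id = c("a", "b"), chrom = "c",
                          pos = c(150, 250), strand = "+")
  rep <- evaluate_predictions(preds, truth)
  expect_equal(rep$tp, 2L)
  expect_equal(rep$tp_prec, 1L)
  expect_equal(rep$sensitivity, 100)
  expect_equal(rep$precision, 100)
})

test_that("stratified reports partition the global counts", {
  withr::with_seed(63, {
    start <- sample(0:2000, 30) * 10
    truth <- tibble::tibble(gene_id = sprintf("g%02d", 1:30), chrom = "c",
                            pos = start + sample(0:199, 30), strand = "+",
                            grp = rep(c("x", "y"), 15))
    preds <- tibble::tibble(gene_id = truth$gene_id, chrom = "c",
                            strand = "+", start = start, end = start + 200,
                            peak_pos = start - 1, peak_height = 1)
    # knock out some predictions
    preds <- preds[-sample(30, 8), ]
  })
  glob <- evaluate_predictions(preds, truth, by_gene = TRUE)
  strat <- stratified_report(preds, truth, "grp")
  expect_setequal(strat$stratum, c("x", "y"))
  expect_equal(sum(strat$tp), glob$tp)
  expect_equal(sum(strat$n_pred), nrow(preds))
  one <- stratified_report(preds, truth,
                           setNames(rep("all", 30), truth$gene_id))
  expect_equal(one$tp, glob$tp)
  expect_equal(one$f, glob$f)
})

test_that("core-type classification searches the core window, non-exclusively", {
  chrom <- strrep("C", 400)
  substr(chrom, 271, 278) <- "TATAAATA"  # 5'-most base at rel -30 of tss 300
  genome <- c(chr = chrom)
  prom <- tibble::tibble(gene_id = c("p1", "p2"), chrom = "chr",
                         pos = c(300, 100), strand = "+")
  sets <- list(TATA = "TATAAATA", YPatch = "CCCCCCCC")
  out <- classify_core_type(prom, genome, sets, core_window = c(-50, -1))
  expect_identical(out$core_labels[[1]], c("TATA", "YPatch"))
  expect_identical(out$core_type[1], "TATA+YPatch")
  expect_identical(out$core_type[2], "YPatch")
  # with a set that never occurs the promoter is coreless
  out2 <- classify_core_type(prom[2, ], genome, list(TATA = "TATAAATA"),
                             core_window = c(-50, -1))
  expect_identical(out2$core_type, "coreless")
})

test_that("expression and distance binning use the documented break points", {
  b <- bin_expression(c(1, 4, 20, 1000))
  expect_identical(as.character(b), c("<4", "4-16", "16-64", ">=256"))
  d <- bin_distance(c(50, 150, 900))
  expect_identical(as.character(d), c("<100", "100-200", ">=800"))
})
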