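test_that("count_octamers counts overlapping windows fully contained in the extract", {
  c1 <- count_octamers("ACGTACGT")
  expect_equal(c1$count[c1$octamer == "ACGTACGT"], 1)
  expect_equal(sum(c1$count), 1)
  expect_equal(attr(c1, "n_windows"), 1L)

  c2 <- count_octamers("AAAAAAAAA")
  expect_equal(c2$count[c2$octamer == "AAAAAAAA"], 2)
  expect_equal(attr(c2, "n_windows"), 2L)
})

test_that("N-containing windows are skipped but still counted in n_windows", {
  cc <- count_octamers("AAAANAAAAAAAA")  # 6 windows, only the last is clean
  expect_equal(attr(cc, "n_windows"), 6L)
  expect_equal(sum(cc$count), 1)
  expect_equal(cc$count[cc$octamer == "AAAAAAAA"], 1)
})

test_that("window extraction counts match a brute-force oracle on both strands", {
  withr::with_seed(21, {
    chrom <- random_dna(4000, gc = 0.4)
    prom <- tibble::tibble(
      gene_id = sprintf("p%02d", 1:20), chrom = "c",
      pos = sample(300:3500, 20),
      strand = sample(c("+", "-"), 20, replace = TRUE))
  })
  genome <- c(c = chrom)
  cc <- count_octamers(prom, genome, window = c(-200, -60))
  expect_equal(attr(cc, "n_windows"), 20L * 134L)
  # oracle: extract the windows by hand and enumerate substrings
  ext <- vapply(1:20, function(i) {
    if (prom$strand[i] == "+") {
      substr(chrom, prom$pos[i] - 200 + 1, prom$pos[i] - 60 + 1)
    } else {
      oracle_revcomp(substr(chrom, prom$pos[i] + 60 + 1, prom$pos[i] + 200 + 1))
    }
  }, character(1))
  orc <- oracle_count_octamers(ext)
  expect_equal(sum(cc$count), sum(unlist(orc)))
  for (o in names(orc)) {
    expect_equal(cc$count[cc$octamer == o], orc[[o]])
  }
  expect_equal(sum(cc$count[!(cc$octamer %in% names(orc))]), 0)
})

test_that("promoters whose window falls off the sequence are skipped with a warning", {
  genome <- c(c = strrep("A", 400))
  prom <- tibble::tibble(chrom = "c", pos = c(100, 300), strand = c("+", "+"))
  expect_warning(cc <- count_octamers(prom, genome, c(-200, -60)),
                 "too close")
  expect_equal(attr(cc, "n_skipped"), 1L)
  expect_equal(attr(cc, "n_windows"), 134L)
})

test_that("IGI normalization zeroes neutral octamers and matches the closed form", {
  uni <- pritss:::new_octamer_counts(rep(7, 65536), 65536L * 7L, "t")
  igi <- build_igi(uni)
  expect_identical(unique(igi$score), 0)

  # single octamer seen 15 times: closed-form oracle computed independently
  counts <- pritss:::new_octamer_counts(
    replace(numeric(65536), match("AAAAAAAA", all_octamers()), 15),
    134L, "t")
  igi2 <- build_igi(counts)
  cbar <- 15 / 65536
  expect_equal(igi2$score[igi2$octamer == "AAAAAAAA"],
               log2(16 / (1 + cbar)))
  expect_equal(igi2$score[igi2$octamer == "CCCCCCCC"],
               log2(1 / (1 + cbar)))
  expect_warning(build_igi(pritss:::new_octamer_counts(numeric(65536), 0L, "t")),
                 "all octamer counts are zero")
})

test_that("IGI normalization is mass-preserving and drift-bounded", {
  withr::with_seed(9, counts <- rpois(65536, 0.3))
  cv <- pritss:::new_octamer_counts(counts, sum(counts), "t")
  igi <- build_igi(cv)
  cbar <- mean(counts)
  # sum over octamers of 2^score * (cbar + 1) reconstructs sum(c + 1)
  expect_equal(sum(2^igi$score * (cbar + 1)), sum(counts + 1))
  # doubling all counts moves every score by less than log2(1 + 1/(cbar+1))
  igi2 <- build_igi(pritss:::new_octamer_counts(2 * counts, 2 * sum(counts), "t"))
  expect_lt(max(abs(igi2$score - igi$score)), log2(1 + 1 / (cbar + 1)))
})

test_that("table subtraction is pointwise and antisymmetric", {
  withr::with_seed(3, {
    a <- octamer_table(rnorm(65536), kind = "IGI")
    b <- octamer_table(rnorm(65536), kind = "IGI")
  })
  expect_identical(unique(subtract_tables(a, a)$score), 0)
  d <- subtract_tables(a, b)
  expect_identical(attr(d, "kind"), "PRI")
  expect_equal(d$score, a$score - b$score)
  expect_equal(subtract_tables(a, b)$score, -subtract_tables(b, a)$score)
  ab <- octamer_table(c(ACGTACGT = 1.2), kind = "IGI")
  bb <- octamer_table(c(ACGTACGT = 0.5), kind = "IGI")
  expect_equal(subtract_tables(ab, bb)$score[oct_index_of("ACGTACGT")], 0.7)
})

test_that("trained PRI ranks planted octamers in the top percentile", {
  sg <- small_synth()
  ps <- make_promoter_set(sg)
  pri <- train_pri(ps, sg$genome)
  pool <- sg$config$context_pool$octamer
  q99 <- quantile(pri$score, 0.99)
  planted_scores <- pri$score[match(pool, pri$octamer)]
  expect_true(all(planted_scores > q99))
})

test_that("null training (enrichment 1) gives pool octamers scores near zero", {
  sg0 <- make_genome(synth_config(n_genes = 60L, chrom_len = 2e5,
                                  enrichment = 1, seed = 102L))
  pri0 <- train_pri(make_promoter_set(sg0), sg0$genome)
  pool <- sg0$config$context_pool$octamer
  expect_lt(abs(mean(pri0$score[match(pool, pri0$octamer)])), 0.5)
})

test_that("identify_spacers excludes sets, breaks ties lexicographically and warns", {
  mk <- function(x) pritss:::new_octamer_counts(
    replace(numeric(65536), oct_index_of(names(x)), x), 100L, "t")
  prox <- mk(c(AAAAAAAA = 10, CCCCCCCC = 8, GGGGGGGG = 5))
  dist <- mk(c(AAAAAAAA = 2, CCCCCCCC = 4, GGGGGGGG = 7))
  out <- identify_spacers(prox, dist, exclude = list(core = "AAAAAAAA"),
                          top_n = 2)
  expect_identical(out, c("CCCCCCCC", "GGGGGGGG"))
  # tie: equal sums order lexicographically
  tie <- identify_spacers(mk(c(TTTTTTTT = 5, AAAAAAAA = 5)),
                          mk(c(TTTTTTTT = 1, AAAAAAAA = 1)), top_n = 2)
  expect_identical(tie, c("AAAAAAAA", "TTTTTTTT"))
  expect_warning(identify_spacers(prox, dist, top_n = 50), "non-excluded")
})

test_that("spacer identification recovers the planted pool on synthetic data", {
  sg <- small_synth()
  ps <- make_promoter_set(sg)
  prox <- count_octamers(ps, sg$genome, c(-200, -60))
  dist <- count_octamers(ps, sg$genome, c(-750, -450))
  top <- identify_spacers(prox, dist, top_n = 10)
  pool <- sg$config$context_pool$octamer
  expect_gte(mean(top %in% pool), 0.8)
})

test_that("compare_tables labels categories and flags overlaps", {
  withr::with_seed(4, a <- octamer_table(rnorm(65536), kind = "PRI"))
  cmp <- compare_tables(a, a)
  expect_equal(cmp$score_a, cmp$score_b)
  expect_identical(unique(cmp$category), "other")
  expect_warning(
    cmp2 <- compare_tables(a, a, categories = list(TATA = "TATAAATA",
                                                   core = c("TATAAATA", "CCAATTGG"))),
    "overlapping")
  expect_warning(compare_tables(a, a,
                                categories = list(TATA = "TATAAATA",
                                                  core = "TATAAATA")),
                 "overlapping")
  expect_identical(cmp2$category[cmp2$octamer == "TATAAATA"], "TATA")
  expect_identical(cmp2$category[cmp2$octamer == "CCAATTGG"], "core")
  expect_error(compare_tables(a, build_igi(pritss:::new_octamer_counts(
    rep(1, 65536), 65536L, "t"))), "same kind")
})

test_that("independent random tables are uncorrelated", {
  withr::with_seed(6, {
    a <- octamer_table(rnorm(65536), kind = "PRI")
    b <- octamer_table(rnorm(65536), kind = "PRI")
  })
  expect_lt(abs(cor(a$score, b$score)), 0.02)
})
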