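# Shared small fixtures, built once per test run.

# A tiny deterministic genome: one gene on each strand with an AAAAAAAA-free
# background so planted octamers can be located unambiguously.
tiny_gff3 <- function(path) {
  writeLines(c(
    "##gff-version 3",
    "chr1\ttest\tgene\t51\t400\t.\t+\t.\tID=gplus",
    "chr1\ttest\tmRNA\t51\t400\t.\t+\t.\tID=gplus.1;Parent=gplus",
    "chr1\ttest\tfive_prime_UTR\t51\t100\t.\t+\t.\tID=u1;Parent=gplus.1",
    "chr1\ttest\tCDS\t101\t200\t.\t+\t.\tID=c1;Parent=gplus.1",
    "chr1\ttest\tCDS\t301\t400\t.\t+\t.\tID=c2;Parent=gplus.1",
    "chr2\ttest\tgene\t101\t300\t.\t-\t.\tID=gminus",
    "chr2\ttest\tmRNA\t101\t300\t.\t-\t.\tID=gminus.1;Parent=gminus",
    "chr2\ttest\tCDS\t101\t200\t.\t-\t.\tID=c3;Parent=gminus.1",
    "chr3\ttest\tgene\t1\t100\t.\t+\t.\tID=nocds"
  ), path)
  path
}

# A small fast synthetic genome shared by several tests.
small_synth <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- make_genome(synth_config(n_genes = 60L, chrom_len = 2e5,
                                         seed = 101L))
    }
    cache
  }
})

oct_index_of <- function(x) match(x, all_octamers())

expect_tibble_cols <- function(x, cols) {
  expect_true(all(cols %in% colnames(x)))
}
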