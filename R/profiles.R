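# Positional occurrence profiles of octamer groups around the TSS, and
# mean-score evaluation of arbitrary sequences. Profiles use the promoter
# coordinate convention (TSS = +1, no position 0); an octamer's occurrence
# or score is assigned to its 5'-most base on the strand being read.

new_profile <- function(df, smoothing_bin, n_promoters, strand = NA_character_) {
  class(df) <- c("pri_profile", class(df))
  attr(df, "smoothing_bin") <- smoothing_bin
  attr(df, "n_promoters") <- n_promoters
  attr(df, "strand") <- strand
  df
}

check_bin <- function(bin) {
  if (!is.null(bin) && (bin %% 2L == 0L || bin < 1L)) {
    rlang::abort("smoothing bin must be odd")
  }
}

# Extract, for each promoter, the relative range padded by `pad_up` bases
# upstream and `pad_down` downstream (in gene orientation). Returns the
# character vector of extracts (NA dropped with a warning).
range_extracts <- function(promoters, genome, range, pad_up = 0L,
                           pad_down = 0L) {
  from <- rel_shift(range[1L], -pad_up)
  to <- rel_shift(range[2L], pad_down)
  seqs <- vapply(seq_len(nrow(promoters)), function(i) {
    extract_rel_window(genome[[promoters$chrom[i]]], promoters$pos[i],
                       promoters$strand[i], from, to)
  }, character(1))
  n_skipped <- sum(is.na(seqs))
  if (n_skipped > 0L) {
    rlang::warn(paste0(n_skipped, " promoter(s) not covering the range skipped"))
  }
  seqs[!is.na(seqs)]
}

#' Positional occurrence profile of an octamer set
#'
#' For each promoter-relative position r in `range`, counts how many
#' promoters carry a set-member octamer starting at r (gene orientation),
#' then applies a centered moving average of width `smoothing_bin`.
#'
#' @param promoters Promoter tibble (`chrom`, `pos` = 0-based peak TSS,
#'   `strand`).
#' @param genome Named character vector of chromosome sequences.
#' @param octamers Character vector of octamers defining the group.
#' @param range Length-2 inclusive relative range (default `c(-1000, 200)`).
#' @param smoothing_bin Odd window width (default 51) or `NULL` for raw.
#' @return A `pri_profile` tibble with columns `rel_pos`, `value` (counts,
#'   smoothed) and `frequency` (`value` per promoter).
#' @export
positional_profile <- function(promoters, genome, octamers,
                               range = c(-1000, 200), smoothing_bin = 51L) {
  check_bin(smoothing_bin)
  member <- logical(65536L)
  member[oct_index(octamers)] <- TRUE
  seqs <- range_extracts(promoters, genome, range, pad_down = 7L)
  n_pos <- rel_window_length(range[1L], range[2L])
  acc <- numeric(n_pos)
  for (s in seqs) {
    codes <- octamer_codes(s)[seq_len(n_pos)]
    hit <- member[codes + 1L]
    hit[is.na(hit)] <- FALSE
    acc <- acc + hit
  }
  value <- if (is.null(smoothing_bin)) acc else smooth_vec(acc, smoothing_bin)
  n_used <- length(seqs)
  new_profile(
    tibble::tibble(rel_pos = rel_seq(range[1L], range[2L]), value = value,
                   frequency = if (n_used > 0) value / n_used else value),
    smoothing_bin = if (is.null(smoothing_bin)) NA_integer_ else smoothing_bin,
    n_promoters = n_used)
}

#' Mean table score of a sequence
#'
#' The mean score over all L-7 octamer windows of the sequence, skipping
#' windows containing non-ACGT letters. Returning the per-window mean makes
#' sequences of different lengths comparable, which is how one number per
#' region type (CDS, 5'UTR, intergenic, ...) is produced.
#'
#' @param table An `octamer_table`.
#' @param seq A DNA string of length >= 8.
#' @return A single numeric score.
#' @export
score_sequence <- function(table, seq) {
  if (nchar(seq) < 8L) rlang::abort("sequence shorter than 8 bases")
  codes <- octamer_codes(seq)
  valid <- !is.na(codes)
  if (!any(valid)) rlang::abort("no valid octamer windows (all contain non-ACGT)")
  mean(score_vector(table)[codes[valid] + 1L])
}

#' Strand-resolved meta-profile of a score table around the TSS
#'
#' For each relative position r, the mean over promoters of the table score
#' of the octamer starting at r on the requested strand (for `strand = "-"`
#' the octamer is read 5'->3' on the reverse complement and assigned to its
#' 5'-most base on that strand), then smoothed.
#'
#' @param table An `octamer_table`.
#' @param promoters Promoter tibble.
#' @param genome Named character vector of chromosome sequences.
#' @param range Length-2 inclusive relative range (default `c(-1000, 200)`).
#' @param strand `"+"` (gene orientation) or `"-"`.
#' @param smoothing_bin Odd window width (default 151) or `NULL` for raw.
#' @return A `pri_profile` tibble with columns `rel_pos`, `value`.
#' @export
meta_profile <- function(table, promoters, genome, range = c(-1000, 200),
                         strand = "+", smoothing_bin = 151L) {
  check_bin(smoothing_bin)
  stopifnot(strand %in% c("+", "-"))
  seqs <- range_extracts(promoters, genome, range, pad_up = 7L, pad_down = 7L)
  n_pos <- rel_window_length(range[1L], range[2L])
  sv <- score_vector(table)
  acc <- numeric(n_pos)
  for (s in seqs) {
    v <- scan_values(sv, s, strand)
    acc <- acc + v[7L + seq_len(n_pos)]
  }
  n_used <- length(seqs)
  if (n_used > 0L) acc <- acc / n_used
  value <- if (is.null(smoothing_bin)) acc else smooth_vec(acc, smoothing_bin)
  new_profile(
    tibble::tibble(rel_pos = rel_seq(range[1L], range[2L]), value = value),
    smoothing_bin = if (is.null(smoothing_bin)) NA_integer_ else smoothing_bin,
    n_promoters = n_used, strand = strand)
}

#' @exportS3Method ggplot2::autoplot
autoplot.pri_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$rel_pos, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0.5, linetype = 3) +
    ggplot2::labs(x = "position relative to TSS (TSS = +1)", y = "value") +
    ggplot2::theme_minimal()
}

#' @export
plot.pri_profile <- function(x, ...) print(autoplot.pri_profile(x, ...))
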