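# Genome scanning: turn a score table plus a chromosome into strand-specific
# per-position score tracks, smooth them, and call peaks. On the plus strand
# position i carries the score of the octamer starting at i; the minus-strand
# track is obtained by scanning the reverse complement and mapping position j
# back to L-1-j, so a minus value at p covers the octamer whose 5'-most base
# on the minus strand sits at p. Negative raw scores are kept; thresholding
# happens only in peak calling.

new_score_track <- function(chrom, strand, values, smoothed = FALSE,
                            bin = NA_integer_) {
  structure(list(chrom = chrom, strand = strand, values = values,
                 smoothed = smoothed, bin = bin),
            class = "score_track")
}

#' @export
print.score_track <- function(x, ...) {
  cat(sprintf("<score_track> %s (%s) length=%d %s\n", x$chrom, x$strand,
              length(x$values),
              if (x$smoothed) paste0("smoothed bin=", x$bin) else "raw"))
  invisible(x)
}

# Core scan over a plain string given a score lookup vector (code + 1).
scan_values <- function(score_vec, seq, strand) {
  L <- nchar(seq)
  if (strand == "-") return(rev(scan_values(score_vec, revcomp(seq), "+")))
  v <- numeric(L)
  if (L >= 8L) {
    codes <- octamer_codes(seq)
    s <- score_vec[codes + 1L]
    s[is.na(s)] <- 0
    v[seq_along(s)] <- s
  }
  v
}

#' Scan a chromosome with an octamer score table
#'
#' @param table An `octamer_table`.
#' @param chrom_seq A chromosome sequence (single string).
#' @param strand `"+"` or `"-"`.
#' @param chrom Chromosome name recorded on the track.
#' @return A raw `score_track` (length equal to the chromosome; positions
#'   with no valid octamer carry 0).
#' @export
scan_track <- function(table, chrom_seq, strand = "+", chrom = "chr") {
  stopifnot(strand %in% c("+", "-"))
  new_score_track(chrom, strand, scan_values(score_vector(table), chrom_seq,
                                             strand))
}

#' Smooth a score track
#'
#' Centered simple moving average of odd width `bin`, truncated at the
#' chromosome ends (no padding, so no signal is fabricated there).
#'
#' @param track A `score_track`.
#' @param bin Odd window width (default 151).
#' @return A smoothed `score_track`.
#' @export
smooth_track <- function(track, bin = 151L) {
  if (bin %% 2L == 0L) rlang::abort("smoothing bin must be odd")
  new_score_track(track$chrom, track$strand, smooth_vec(track$values, bin),
                  smoothed = TRUE, bin = bin)
}

#' Call peaks on a smoothed score track
#'
#' A peak is a strict-or-plateau local maximum: a maximal run of equal
#' values strictly above both adjacent runs (chromosome ends count as open
#' boundaries), with value >= `threshold`. Each qualifying plateau yields one
#' peak at its leftmost position.
#'
#' @param track A smoothed `score_track`.
#' @param threshold Minimum peak height.
#' @return Tibble with columns `chrom`, `strand`, `pos` (0-based) and
#'   `height`, sorted by `pos`.
#' @export
find_peaks <- function(track, threshold) {
  v <- track$values
  empty <- tibble::tibble(chrom = character(0), strand = character(0),
                          pos = numeric(0), height = numeric(0))
  if (length(v) == 0L) return(empty)
  r <- rle(v)
  n <- length(r$values)
  left_ok <- c(TRUE, r$values[-1L] > r$values[-n])
  right_ok <- c(r$values[-n] > r$values[-1L], TRUE)
  is_peak <- left_ok & right_ok & r$values >= threshold
  if (!any(is_peak)) return(empty)
  run_start <- cumsum(c(0L, r$lengths[-n]))  # 0-based leftmost position
  tibble::tibble(chrom = track$chrom, strand = track$strand,
                 pos = run_start[is_peak], height = r$values[is_peak])
}

#' Scan a genome into smoothed strand-specific tracks
#'
#' Convenience wrapper producing, for every chromosome, smoothed `+` and `-`
#' tracks ready for peak calling and TSS prediction.
#'
#' @param table An `octamer_table`.
#' @param genome Named character vector of chromosome sequences.
#' @param bin Odd smoothing width (default 151).
#' @return A `track_set`: named list `tracks[[chrom]][[strand]]`.
#' @export
scan_genome <- function(table, genome, bin = 151L) {
  out <- lapply(names(genome), function(ch) {
    lapply(stats::setNames(c("+", "-"), c("+", "-")), function(st) {
      smooth_track(scan_track(table, genome[[ch]], st, chrom = ch), bin)
    })
  })
  names(out) <- names(genome)
  structure(out, class = "track_set", bin = bin)
}

#' @export
print.track_set <- function(x, ...) {
  cat(sprintf("<track_set> %d chromosome(s), smoothed bin=%d\n", length(x),
              attr(x, "bin")))
  invisible(x)
}

#' @exportS3Method ggplot2::autoplot
autoplot.score_track <- function(object, from = 0L,
                                 to = length(object$values), ...) {
  idx <- seq.int(from + 1L, to)
  df <- tibble::tibble(pos = idx - 1L, value = object$values[idx])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::labs(x = paste0(object$chrom, " (", object$strand, ")"),
                  y = "score") +
    ggplot2::theme_minimal()
}

#' @export
plot.score_track <- function(x, ...) print(autoplot.score_track(x, ...))
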