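# Promoter-relative coordinates follow the field's convention: the TSS is
# position +1, there is no position 0, and upstream positions are negative.
# Internally all genome coordinates are 0-based (intervals half-open); a
# relative position r maps to the genome offset r - 1 for r >= +1 and r for
# r <= -1, applied in gene orientation. On the minus strand "upstream" means
# increasing genome coordinate.

#' Convert a promoter-relative position to a 0-based genome offset
#'
#' @param r Integer vector of promoter-relative positions (no 0 allowed;
#'   the TSS itself is +1).
#' @return Integer offsets from the TSS in gene orientation.
#' @export
rel_offset <- function(r) {
  if (any(r == 0)) rlang::abort("promoter-relative coordinates have no position 0")
  ifelse(r >= 1, r - 1, r)
}

# Inverse of rel_offset.
offset_rel <- function(off) {
  ifelse(off >= 0, off + 1, off)
}

# Shift a relative position k steps downstream (k may be negative), skipping 0.
rel_shift <- function(r, k) {
  offset_rel(rel_offset(r) + k)
}

# Number of positions in the inclusive relative window from..to (0 excluded).
rel_window_length <- function(from, to) {
  stopifnot(from < to, from != 0, to != 0)
  (to - from + 1L) - as.integer(from < 0 && to > 0)
}

# The relative positions of a window, in order.
rel_seq <- function(from, to) {
  s <- seq.int(from, to)
  s[s != 0]
}

# Extract the promoter-relative window [from..to] of a promoter as a string
# read 5'->3' in gene orientation. `tss` is the 0-based genome position of the
# peak TSS. Returns NA_character_ when the window does not fit on the sequence.
extract_rel_window <- function(chrom_seq, tss, strand, from, to) {
  stopifnot(from < to)
  off_from <- rel_offset(from)
  off_to <- rel_offset(to)
  L <- nchar(chrom_seq)
  if (strand == "+") {
    g0 <- tss + off_from
    g1 <- tss + off_to
    if (g0 < 0 || g1 >= L) return(NA_character_)
    substr(chrom_seq, g0 + 1L, g1 + 1L)
  } else {
    g0 <- tss - off_to
    g1 <- tss - off_from
    if (g0 < 0 || g1 >= L) return(NA_character_)
    revcomp(substr(chrom_seq, g0 + 1L, g1 + 1L))
  }
}

# Extract a 0-based half-open genome interval as a string; gene orientation
# when strand == "-". No bounds clipping: caller guarantees validity.
extract_interval <- function(chrom_seq, lo, hi, strand = "+") {
  s <- substr(chrom_seq, lo + 1L, hi)
  if (strand == "-") revcomp(s) else s
}
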