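#' @keywords internal
"_PACKAGE"

# Shared octamer machinery. Octamers are indexed by their base-4 code
# (A=0, C=1, G=2, T=3, leftmost base most significant), which coincides with
# lexicographic order over the alphabet A < C < G < T. All score tables and
# count vectors are kept in this canonical order so that a table column can be
# used directly as a lookup vector indexed by code + 1.

.pritss_env <- new.env(parent = emptyenv())

DNA_BASES <- c("A", "C", "G", "T")

#' All 65,536 DNA octamers in canonical order
#'
#' Returns the complete set of 8-mers over {A,C,G,T} in lexicographic order
#' (A < C < G < T), which equals the order of their base-4 integer codes.
#'
#' @return Character vector of length `4^8`.
#' @export
all_octamers <- function() {
  if (is.null(.pritss_env$octamers)) {
    g <- expand.grid(rep(list(DNA_BASES), 8L),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    # expand.grid varies the first column fastest; we want the last character
    # of the octamer to vary fastest, so paste columns in reverse order.
    .pritss_env$octamers <- do.call(paste0, rev(g))
  }
  .pritss_env$octamers
}

# 1-based index of octamer strings into the canonical ordering.
oct_index <- function(octamers) {
  idx <- match(octamers, all_octamers())
  if (anyNA(idx)) {
    bad <- octamers[is.na(idx)]
    rlang::abort(paste0("not valid ACGT octamers: ",
                        paste(utils::head(bad, 3L), collapse = ", ")))
  }
  idx
}

# ASCII lookup table: base character -> 0..3, NA for anything else.
base_code_lookup <- function() {
  if (is.null(.pritss_env$base_lut)) {
    lut <- rep(NA_real_, 256L)
    lut[utf8ToInt("A") + 1L] <- 0
    lut[utf8ToInt("C") + 1L] <- 1
    lut[utf8ToInt("G") + 1L] <- 2
    lut[utf8ToInt("T") + 1L] <- 3
    .pritss_env$base_lut <- lut
  }
  .pritss_env$base_lut
}

# Per-position base codes of one sequence (0..3, NA for non-ACGT).
seq_base_codes <- function(seq) {
  base_code_lookup()[utf8ToInt(seq) + 1L]
}

# Base-4 codes of all octamer windows of `seq`, assigned to the 5'-most base.
# Length nchar(seq) - 7; windows containing non-ACGT letters are NA.
octamer_codes <- function(seq) {
  b <- seq_base_codes(seq)
  n <- length(b) - 7L
  if (n < 1L) return(numeric(0))
  out <- numeric(n)
  for (k in 0:7) {
    out <- out + b[(1L + k):(n + k)] * 4^(7L - k)
  }
  out
}

#' Reverse complement of DNA strings
#'
#' IUPAC ambiguity codes are complemented and preserved (N stays N).
#'
#' @param x Character vector of DNA strings.
#' @return Character vector of the same length.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Centered moving average with truncated windows at both ends.
smooth_vec <- function(v, bin) {
  if (bin %% 2L == 0L || bin < 1L) {
    rlang::abort("smoothing bin must be an odd positive integer")
  }
  if (bin == 1L) return(v)
  n <- length(v)
  h <- (bin - 1L) %/% 2L
  cs <- c(0, cumsum(v))
  i <- seq_len(n)
  lo <- pmax(i - h, 1L)
  hi <- pmin(i + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}
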