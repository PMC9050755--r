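# Independent brute-force oracles. These deliberately share no code with the
# package internals: plain nested loops, string operations and name lookups.

oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

random_dna <- function(n, p_n = 0, gc = 0.5) {
  probs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  x <- sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = probs)
  if (p_n > 0) x[runif(n) < p_n] <- "N"
  paste(x, collapse = "")
}

# All octamer substrings of a set of sequences, skipping non-ACGT windows.
oracle_count_octamers <- function(seqs) {
  counts <- new.env(parent = emptyenv())
  for (s in seqs) {
    L <- nchar(s)
    if (L < 8) next
    for (i in 1:(L - 7)) {
      o <- substr(s, i, i + 7)
      if (grepl("^[ACGT]{8}$", o)) {
        counts[[o]] <- (if (is.null(counts[[o]])) 0 else counts[[o]]) + 1
      }
    }
  }
  as.list(counts)
}

# Named score lookup built from an octamer_table tibble.
oracle_score_lookup <- function(table) {
  setNames(table$score, table$octamer)
}

oracle_score_sequence <- function(lookup, s) {
  vals <- c()
  for (i in 1:(nchar(s) - 7)) {
    o <- substr(s, i, i + 7)
    if (grepl("^[ACGT]{8}$", o)) vals <- c(vals, unname(lookup[o]))
  }
  mean(vals)
}

oracle_scan_plus <- function(lookup, s) {
  L <- nchar(s)
  v <- numeric(L)
  if (L >= 8) {
    for (i in 1:(L - 7)) {
      o <- substr(s, i, i + 7)
      if (grepl("^[ACGT]{8}$", o)) v[i] <- unname(lookup[o])
    }
  }
  v
}

# Minus-strand value at 0-based p is the score of the octamer whose 5'-most
# base on the minus strand sits at p (covering p-7..p on the chromosome).
oracle_scan_minus <- function(lookup, s) {
  L <- nchar(s)
  v <- numeric(L)
  for (p in 7:(L - 1)) {
    o <- oracle_revcomp(substr(s, p - 6, p + 1))
    if (grepl("^[ACGT]{8}$", o)) v[p + 1] <- unname(lookup[o])
  }
  v
}

oracle_smooth <- function(v, bin) {
  h <- (bin - 1) / 2
  n <- length(v)
  out <- numeric(n)
  for (i in 1:n) {
    out[i] <- mean(v[max(1, i - h):min(n, i + h)])
  }
  out
}

# Plateau-aware local maxima: one peak per maximal equal-value run strictly
# above both adjacent runs (ends open), at the run's leftmost 0-based index.
oracle_find_peaks <- function(v, threshold) {
  n <- length(v)
  pos <- c(); height <- c()
  i <- 1
  while (i <= n) {
    j <- i
    while (j < n && v[j + 1] == v[i]) j <- j + 1
    if ((i == 1 || v[i - 1] < v[i]) && (j == n || v[j + 1] < v[i]) &&
        v[i] >= threshold) {
      pos <- c(pos, i - 1)
      height <- c(height, v[i])
    }
    i <- j + 1
  }
  list(pos = pos, height = height)
}

# All-pairs window matching: returns truth-side and prediction-side TP.
oracle_match <- function(preds, truth, directional = FALSE) {
  det <- rep(FALSE, nrow(truth))
  mat <- rep(FALSE, nrow(preds))
  for (i in seq_len(nrow(truth))) {
    for (j in seq_len(nrow(preds))) {
      ok <- preds$chrom[j] == truth$chrom[i] &&
        preds$start[j] <= truth$pos[i] && truth$pos[i] < preds$end[j]
      if (directional) ok <- ok && preds$strand[j] == truth$strand[i]
      if (ok) {
        det[i] <- TRUE
        mat[j] <- TRUE
      }
    }
  }
  list(tp_sens = sum(det), tp_prec = sum(mat))
}
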