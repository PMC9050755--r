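# Octamer score tables. The Intergenic Index (IGI) of a TSS-relative window
# scores each octamer by its occurrence in that window across a training set
# of promoters, normalized so that octamers with neutral (mean) occurrence
# score exactly zero: score(o) = log2((c_o + pc) / (cbar + pc)) with
# cbar = sum(c) / 4^8. The Promoter Index (PRI) is the proximal-window IGI
# minus the distal-window IGI (default windows -200..-60 and -750..-450);
# the 5'UTR Index (FUI) replaces the proximal window with 5'UTR sequence.

#' Construct an octamer score table
#'
#' Builds an `octamer_table` from either a full score vector in canonical
#' octamer order (length 4^8) or a named sparse vector (unnamed octamers
#' score 0).
#'
#' @param scores Numeric vector: length 4^8 in [all_octamers()] order, or a
#'   shorter vector named by octamer.
#' @param kind Table kind label (e.g. `"IGI"`, `"PRI"`, `"FUI"`).
#' @param windows Source window label.
#' @param pseudocount Pseudocount used when the table was built, if any.
#' @return An `octamer_table` tibble (`octamer`, `score`).
#' @export
octamer_table <- function(scores, kind = "custom", windows = NA_character_,
                          pseudocount = NA_real_) {
  if (length(scores) != 65536L) {
    if (is.null(names(scores))) {
      rlang::abort("scores must be length 4^8 or named by octamer")
    }
    full <- numeric(65536L)
    full[oct_index(names(scores))] <- scores
    scores <- full
  }
  new_octamer_table(scores, kind = kind, windows = windows,
                    pseudocount = pseudocount)
}

new_octamer_counts <- function(counts, n_windows, window_label,
                               n_skipped = 0L) {
  out <- tibble::tibble(octamer = all_octamers(), count = as.numeric(counts))
  class(out) <- c("octamer_counts", class(out))
  attr(out, "n_windows") <- n_windows
  attr(out, "window_label") <- window_label
  attr(out, "n_skipped") <- n_skipped
  out
}

new_octamer_table <- function(scores, kind, windows = NA_character_,
                              pseudocount = NA_real_) {
  stopifnot(length(scores) == 65536L)
  out <- tibble::tibble(octamer = all_octamers(), score = as.numeric(scores))
  class(out) <- c("octamer_table", class(out))
  attr(out, "kind") <- kind
  attr(out, "windows") <- windows
  attr(out, "pseudocount") <- pseudocount
  out
}

# Fast lookup vector: score by octamer code + 1.
score_vector <- function(table) table$score

window_label_of <- function(window) {
  paste0(abs(window[1L]), "_", abs(window[2L]))
}

#' Count octamer occurrences in a TSS-relative promoter window
#'
#' Counts every octamer fully contained in the extracted window, read 5'->3'
#' in gene orientation; a window of L bases yields L-7 start positions per
#' promoter. Windows containing non-ACGT letters are skipped in the counts
#' but still included in `n_windows`. Promoters whose window does not fit on
#' the chromosome are dropped with a warning.
#'
#' @param promoters Either a promoter tibble (columns `chrom`, `pos` =
#'   0-based peak TSS, `strand`) with `genome` supplied, or a character
#'   vector of already-extracted window sequences.
#' @param genome Named character vector of chromosome sequences (ignored
#'   when `promoters` is a character vector).
#' @param window Length-2 integer vector, inclusive promoter-relative window
#'   in the TSS = +1 convention (default `c(-200, -60)`, a 141-base window
#'   giving 134 octamer starts).
#' @param label Window label recorded on the result; derived from `window`
#'   by default.
#' @return An `octamer_counts` tibble (`octamer`, `count`) with attributes
#'   `n_windows`, `window_label` and `n_skipped`.
#' @export
count_octamers <- function(promoters, genome = NULL, window = c(-200, -60),
                           label = NULL) {
  if (is.character(promoters)) {
    seqs <- promoters
    label <- label %||% "seq"
    n_skipped <- 0L
  } else {
    stopifnot(!is.null(genome))
    if (rel_window_length(window[1L], window[2L]) < 8L) {
      rlang::abort("window must span at least 8 bases")
    }
    label <- label %||% window_label_of(window)
    seqs <- vapply(seq_len(nrow(promoters)), function(i) {
      extract_rel_window(genome[[promoters$chrom[i]]], promoters$pos[i],
                         promoters$strand[i], window[1L], window[2L])
    }, character(1))
    n_skipped <- sum(is.na(seqs))
    if (n_skipped > 0L) {
      rlang::warn(paste0(n_skipped,
                         " promoter(s) too close to a sequence end skipped"))
    }
    seqs <- seqs[!is.na(seqs)]
  }
  seqs <- seqs[nchar(seqs) >= 8L]
  if (length(seqs) == 0L) {
    return(new_octamer_counts(numeric(65536L), 0L, label, n_skipped))
  }
  counts <- Biostrings::oligonucleotideFrequency(
    Biostrings::DNAStringSet(seqs), width = 8L, simplify.as = "collapsed")
  counts <- counts[all_octamers()]
  new_octamer_counts(unname(counts), sum(nchar(seqs) - 7L), label, n_skipped)
}

#' Build an Intergenic Index (IGI) table from octamer counts
#'
#' score(o) = log2((c_o + pseudocount) / (cbar + pseudocount)) with
#' cbar = sum(c) / 4^8, so that octamers with exactly mean occurrence score
#' zero and above-average occurrence gives a positive score.
#'
#' @param counts An `octamer_counts` tibble (counts may be non-integer, e.g.
#'   after depth rescaling).
#' @param pseudocount Additive pseudocount (default 1).
#' @return An `octamer_table` of kind `"IGI"`.
#' @export
build_igi <- function(counts, pseudocount = 1) {
  c_o <- counts$count
  if (all(c_o == 0)) rlang::warn("all octamer counts are zero; IGI is all zero")
  cbar <- sum(c_o) / length(c_o)
  scores <- log2((c_o + pseudocount) / (cbar + pseudocount))
  new_octamer_table(scores, kind = "IGI",
                    windows = attr(counts, "window_label"),
                    pseudocount = pseudocount)
}

#' Subtract one octamer table from another
#'
#' Pointwise `a - b`; used to form PRI (proximal IGI minus distal IGI) and
#' FUI (5'UTR IGI minus distal IGI).
#'
#' @param a,b `octamer_table`s over the full octamer set.
#' @param kind Kind label of the result (default `"PRI"`).
#' @return An `octamer_table`.
#' @export
subtract_tables <- function(a, b, kind = "PRI") {
  stopifnot(inherits(a, "octamer_table"), inherits(b, "octamer_table"))
  new_octamer_table(a$score - b$score, kind = kind,
                    windows = paste0(attr(a, "windows"), "-", attr(b, "windows")),
                    pseudocount = attr(a, "pseudocount"))
}

#' Train a Promoter Index (PRI) table from a promoter set
#'
#' Counts octamers in the proximal and distal TSS-relative windows, builds
#' the two IGI tables and subtracts distal from proximal. Because the two
#' windows differ in length (134 vs 294 octamer starts at the defaults), the
#' distal counts are rescaled to the proximal total before the IGI is built
#' (`match_depth = TRUE`); this removes a pseudocount artifact that would
#' otherwise give every training-unseen octamer a positive PRI on small
#' training sets while leaving well-sampled octamers essentially unchanged.
#'
#' @param promoters Promoter tibble (`chrom`, `pos`, `strand`).
#' @param genome Named character vector of chromosome sequences.
#' @param proximal,distal Inclusive promoter-relative windows.
#' @param pseudocount Pseudocount passed to [build_igi()].
#' @param match_depth Rescale distal counts to the proximal sampling depth.
#' @return An `octamer_table` of kind `"PRI"`.
#' @export
train_pri <- function(promoters, genome, proximal = c(-200, -60),
                      distal = c(-750, -450), pseudocount = 1,
                      match_depth = TRUE) {
  cp <- count_octamers(promoters, genome, proximal)
  cd <- count_octamers(promoters, genome, distal)
  if (match_depth && sum(cd$count) > 0) {
    cd$count <- cd$count * (sum(cp$count) / sum(cd$count))
  }
  subtract_tables(build_igi(cp, pseudocount), build_igi(cd, pseudocount),
                  kind = "PRI")
}

#' Train a 5'UTR Index (FUI) table
#'
#' As [train_pri()], with the proximal-window counts replaced by counts over
#' 5'UTR sequences.
#'
#' @param utr_seqs Character vector of 5'UTR sequences in gene orientation
#'   (see [utr5_sequences()]).
#' @param promoters Promoter tibble used for the distal window.
#' @param genome Named character vector of chromosome sequences.
#' @param distal Inclusive promoter-relative distal window.
#' @param pseudocount Pseudocount passed to [build_igi()].
#' @param match_depth Rescale distal counts to the 5'UTR sampling depth.
#' @return An `octamer_table` of kind `"FUI"`.
#' @export
train_fui <- function(utr_seqs, promoters, genome, distal = c(-750, -450),
                      pseudocount = 1, match_depth = TRUE) {
  cu <- count_octamers(utr_seqs, label = "utr5")
  cd <- count_octamers(promoters, genome, distal)
  if (match_depth && sum(cd$count) > 0) {
    cd$count <- cd$count * (sum(cu$count) / sum(cd$count))
  }
  subtract_tables(build_igi(cu, pseudocount), build_igi(cd, pseudocount),
                  kind = "FUI")
}

#' Extract 5'UTR sequences from gene models
#'
#' Concatenates each gene's 5'UTR intervals in gene orientation.
#'
#' @param genes Gene-model tibble with a `utr5` list-column.
#' @param genome Named character vector of chromosome sequences.
#' @return Character vector (genes without a 5'UTR are dropped).
#' @export
utr5_sequences <- function(genes, genome) {
  out <- vapply(seq_len(nrow(genes)), function(i) {
    m <- genes$utr5[[i]]
    if (is.null(m) || nrow(m) == 0L) return(NA_character_)
    parts <- vapply(seq_len(nrow(m)), function(j) {
      extract_interval(genome[[genes$chrom[i]]], m[j, 1L], m[j, 2L], "+")
    }, character(1))
    if (genes$strand[i] == "-") revcomp(paste0(rev(parts), collapse = ""))
    else paste0(parts, collapse = "")
  }, character(1))
  out[!is.na(out)]
}

#' Identify spacer octamers
#'
#' Spacers are the most frequently occurring promoter octamers that are not
#' assigned element functions: octamers are ranked by the summed proximal +
#' distal counts after removing the excluded (core/REG) sets, and the top
#' `top_n` are returned. Ties are broken lexicographically.
#'
#' @param prox,dist `octamer_counts` for the proximal and distal windows.
#' @param exclude List (or character vector) of octamer sets to exclude.
#' @param top_n Number of spacers to return (default 50).
#' @return Character vector of octamers, most frequent first.
#' @export
identify_spacers <- function(prox, dist, exclude = list(), top_n = 50L) {
  excl <- unique(unlist(exclude, use.names = FALSE))
  if (length(excl) > 0L) oct_index(excl)  # validates
  total <- prox$count + dist$count
  keep <- total > 0 & !(all_octamers() %in% excl)
  oct <- all_octamers()[keep]
  tot <- total[keep]
  ord <- order(-tot, oct)
  if (length(ord) < top_n) {
    rlang::warn(paste0("only ", length(ord),
                       " non-excluded octamers with nonzero counts"))
    top_n <- length(ord)
  }
  oct[ord][seq_len(top_n)]
}

#' Compare two octamer tables
#'
#' One row per octamer with both scores and a category label taken from the
#' first matching named octamer set (or `"other"`); used for cross-species
#' PRI scatter plots.
#'
#' @param a,b `octamer_table`s of the same kind.
#' @param categories Named list of octamer character vectors.
#' @return Tibble with columns `octamer`, `score_a`, `score_b`, `category`.
#' @export
compare_tables <- function(a, b, categories = list()) {
  stopifnot(inherits(a, "octamer_table"), inherits(b, "octamer_table"))
  if (!identical(attr(a, "kind"), attr(b, "kind"))) {
    rlang::abort("tables must be of the same kind")
  }
  category <- rep("other", 65536L)
  assigned <- logical(65536L)
  overlap <- FALSE
  for (nm in names(categories)) {
    idx <- oct_index(categories[[nm]])
    overlap <- overlap || any(assigned[idx])
    fresh <- idx[!assigned[idx]]
    category[fresh] <- nm
    assigned[fresh] <- TRUE
  }
  if (overlap) rlang::warn("overlapping categories; first-listed wins")
  tibble::tibble(octamer = all_octamers(), score_a = a$score,
                 score_b = b$score, category = category)
}

#' @exportS3Method generics::tidy
tidy.octamer_table <- function(x, ...) {
  tibble::tibble(octamer = x$octamer, score = x$score)
}

#' @exportS3Method generics::glance
glance.octamer_table <- function(x, ...) {
  tibble::tibble(kind = attr(x, "kind"), windows = attr(x, "windows"),
                 pseudocount = attr(x, "pseudocount"),
                 n_octamers = nrow(x), mean_score = mean(x$score),
                 sd_score = stats::sd(x$score), min_score = min(x$score),
                 max_score = max(x$score))
}

#' @export
print.octamer_table <- function(x, ...) {
  cat(sprintf("<octamer_table> kind=%s windows=%s pseudocount=%s\n",
              attr(x, "kind"), attr(x, "windows"),
              format(attr(x, "pseudocount"))))
  NextMethod()
}

#' Scatter plot of two octamer tables
#'
#' @param comparison Output of [compare_tables()].
#' @return A ggplot object.
#' @export
plot_table_comparison <- function(comparison) {
  highlighted <- comparison[comparison$category != "other", , drop = FALSE]
  ggplot2::ggplot(comparison,
                  ggplot2::aes(x = .data$score_a, y = .data$score_b)) +
    ggplot2::geom_point(colour = "grey80", size = 0.3) +
    ggplot2::geom_point(data = highlighted,
                        ggplot2::aes(colour = .data$category), size = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::labs(x = "score (table A)", y = "score (table B)",
                  colour = "category") +
    ggplot2::theme_minimal()
}
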