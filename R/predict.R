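# TSS prediction from PRI peaks. Gene-model-associated prediction searches
# peaks from the head of the CDS in the upstream direction and selects the
# first peak at or above the threshold; the region +1..+200 downstream of
# that peak (gene orientation) is the predicted TSS window. Genome-wide
# prediction emits one window per above-threshold peak on either strand.

#' Predictor configuration
#'
#' @param threshold Minimum smoothed peak height (species calibrations in the
#'   source data: 0.0 for Arabidopsis, 0.06 for rice PRI; 0 for FUI).
#' @param max_search_bp Upstream search range from the CDS head (default
#'   3000; 2000 reproduces the 2-kb benchmark protocol).
#' @param smoothing_bin Track smoothing width.
#' @param fui_mode Apply the 5'UTR-requiring filter ([apply_fui_filter()]).
#' @param fui_threshold Minimum smoothed FUI between peak and CDS.
#' @param flank Half-width used when comparing strand maxima in
#'   [predict_direction()].
#' @return A `predictor_config` list.
#' @export
predictor_config <- function(threshold = 0, max_search_bp = 3000L,
                             smoothing_bin = 151L, fui_mode = FALSE,
                             fui_threshold = 0, flank = 100L) {
  if (max_search_bp < 200L) rlang::abort("max_search_bp must be >= 200")
  structure(list(threshold = threshold, max_search_bp = max_search_bp,
                 smoothing_bin = smoothing_bin, fui_mode = fui_mode,
                 fui_threshold = fui_threshold, flank = flank),
            class = "predictor_config")
}

prediction_window <- function(gene_id, chrom, strand, peak_pos, peak_height) {
  if (strand == "+") {
    start <- peak_pos + 1
    end <- peak_pos + 201
  } else {
    start <- peak_pos - 200
    end <- peak_pos
  }
  tibble::tibble(gene_id = gene_id, chrom = chrom, strand = strand,
                 start = start, end = end, peak_pos = peak_pos,
                 peak_height = peak_height)
}

empty_predictions <- function() {
  tibble::tibble(gene_id = character(0), chrom = character(0),
                 strand = character(0), start = numeric(0), end = numeric(0),
                 peak_pos = numeric(0), peak_height = numeric(0))
}

select_gene_peak <- function(peaks, strand, cds_start, max_search_bp) {
  if (strand == "+") {
    cand <- peaks[peaks$pos < cds_start &
                    peaks$pos >= cds_start - max_search_bp, , drop = FALSE]
    if (nrow(cand) == 0L) return(NULL)
    cand[which.max(cand$pos), , drop = FALSE]
  } else {
    cand <- peaks[peaks$pos > cds_start &
                    peaks$pos <= cds_start + max_search_bp, , drop = FALSE]
    if (nrow(cand) == 0L) return(NULL)
    cand[which.min(cand$pos), , drop = FALSE]
  }
}

#' Gene-model-associated TSS prediction for one gene
#'
#' Peaks on the gene's strand are searched upstream of the CDS head
#' (nearest first, within `max_search_bp`); the first peak with height at or
#' above the threshold defines a 200-bp window beginning 1 bp downstream of
#' the peak in gene orientation.
#'
#' @param tracks A `track_set` of smoothed tracks (see [scan_genome()]).
#' @param gene One gene-model row (`gene_id`, `chrom`, `strand`,
#'   `cds_start`).
#' @param cfg A [predictor_config()].
#' @param peaks Optional precomputed peak tibble for the gene's chromosome
#'   and strand (at `cfg$threshold`); computed on the fly when `NULL`.
#' @return One-row prediction tibble, or `NULL` when no peak qualifies.
#' @export
predict_gene_tss <- function(tracks, gene, cfg = predictor_config(),
                             peaks = NULL) {
  if (is.null(peaks)) {
    peaks <- find_peaks(tracks[[gene$chrom]][[gene$strand]], cfg$threshold)
  }
  hit <- select_gene_peak(peaks, gene$strand, gene$cds_start,
                          cfg$max_search_bp)
  if (is.null(hit)) return(NULL)
  prediction_window(gene$gene_id, gene$chrom, gene$strand, hit$pos,
                    hit$height)
}

#' Gene-model-associated TSS prediction for a set of genes
#'
#' @param tracks A `track_set` of smoothed tracks.
#' @param genes Gene-model tibble.
#' @param cfg A [predictor_config()].
#' @return Prediction tibble, one row per gene with a qualifying peak.
#' @export
predict_tss <- function(tracks, genes, cfg = predictor_config()) {
  if (nrow(genes) == 0L) return(empty_predictions())
  keys <- unique(genes[, c("chrom", "strand")])
  peak_cache <- list()
  for (i in seq_len(nrow(keys))) {
    k <- paste0(keys$chrom[i], keys$strand[i])
    peak_cache[[k]] <- find_peaks(tracks[[keys$chrom[i]]][[keys$strand[i]]],
                                  cfg$threshold)
  }
  rows <- purrr::map(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    predict_gene_tss(tracks, g, cfg,
                     peaks = peak_cache[[paste0(g$chrom, g$strand)]])
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) empty_predictions() else out
}

#' Genome-wide TSS prediction
#'
#' Every peak at or above the threshold on either strand of every
#' chromosome yields one 200-bp window; no gene anchoring. Overlapping
#' windows from adjacent peaks are all kept.
#'
#' @param tracks A `track_set` of smoothed tracks.
#' @param cfg A [predictor_config()].
#' @return Prediction tibble (`gene_id` is `NA`).
#' @export
predict_genomewide <- function(tracks, cfg = predictor_config()) {
  rows <- purrr::map(names(tracks), function(ch) {
    purrr::map(c("+", "-"), function(st) {
      pk <- find_peaks(tracks[[ch]][[st]], cfg$threshold)
      if (nrow(pk) == 0L) return(NULL)
      tibble::tibble(
        gene_id = NA_character_, chrom = ch, strand = st,
        start = if (st == "+") pk$pos + 1 else pk$pos - 200,
        end = if (st == "+") pk$pos + 201 else pk$pos,
        peak_pos = pk$pos, peak_height = pk$height)
    })
  })
  out <- dplyr::bind_rows(unlist(rows, recursive = FALSE))
  if (nrow(out) == 0L) empty_predictions() else out
}

#' Predict promoter direction at prediction windows
#'
#' For each window, the maximum smoothed value within `peak_pos +/- flank`
#' is compared between the two strand tracks and the strand with the larger
#' maximum is returned. On an exact tie the window's own strand is returned
#' when known, else `"+"`.
#'
#' @param tracks A `track_set` of smoothed tracks.
#' @param windows Prediction tibble.
#' @param cfg A [predictor_config()] (supplies `flank`).
#' @return Character vector of `"+"`/`"-"`, one per window.
#' @export
predict_direction <- function(tracks, windows, cfg = predictor_config()) {
  vapply(seq_len(nrow(windows)), function(i) {
    w <- windows[i, ]
    v <- tracks[[w$chrom]][["+"]]$values
    L <- length(v)
    lo <- max(1L, w$peak_pos + 1L - cfg$flank)
    hi <- min(L, w$peak_pos + 1L + cfg$flank)
    max_plus <- max(tracks[[w$chrom]][["+"]]$values[lo:hi])
    max_minus <- max(tracks[[w$chrom]][["-"]]$values[lo:hi])
    if (max_plus > max_minus) "+"
    else if (max_minus > max_plus) "-"
    else if (!is.na(w$strand)) w$strand
    else "+"
  }, character(1))
}

#' 5'UTR-requiring filter for a predicted TSS
#'
#' Keeps a prediction only when some position between the source peak and
#' the CDS head (gene orientation, inclusive) has smoothed FUI at or above
#' `cfg$fui_threshold`, i.e. when a 5'UTR-like signal lies in the TSS-CDS
#' span; predictions directly upstream of a CDS with no such signal are
#' discarded by the caller.
#'
#' @param pred One-row prediction tibble.
#' @param fui_tracks A `track_set` of smoothed FUI tracks.
#' @param gene The gene-model row the prediction belongs to.
#' @param cfg A [predictor_config()].
#' @return `TRUE` to keep the prediction.
#' @export
apply_fui_filter <- function(pred, fui_tracks, gene,
                             cfg = predictor_config(fui_mode = TRUE)) {
  v <- fui_tracks[[gene$chrom]][[gene$strand]]$values
  lo <- min(pred$peak_pos, gene$cds_start)
  hi <- max(pred$peak_pos, gene$cds_start)
  lo <- max(lo, 0L)
  hi <- min(hi, length(v) - 1L)
  any(v[(lo + 1L):(hi + 1L)] >= cfg$fui_threshold)
}

#' Threshold sweep for gene-anchored TSS prediction
#'
#' Runs [predict_tss()] at every threshold in the grid, matches the
#' predictions against the true peak TSSs (window containment within the
#' same gene) and tabulates sensitivity, precision and their harmonic mean.
#'
#' @param tracks A `track_set` of smoothed tracks.
#' @param genes Gene-model tibble.
#' @param truth Truth tibble (`gene_id`, `chrom`, `pos`, `strand`).
#' @param grid Numeric vector of thresholds (non-empty).
#' @param cfg Base [predictor_config()]; its threshold is replaced per row.
#' @return Tibble with one row per threshold (`threshold`, `n_pred`, `tp`,
#'   `sensitivity`, `precision`, `f`) and attribute `best_threshold`
#'   (argmax F, lowest threshold on ties).
#' @export
sweep_threshold <- function(tracks, genes, truth, grid,
                            cfg = predictor_config()) {
  if (length(grid) == 0L) rlang::abort("threshold grid is empty")
  rows <- purrr::map(grid, function(th) {
    cfg$threshold <- th
    preds <- predict_tss(tracks, genes, cfg)
    m <- match_predictions(preds, truth, mode = "window", directional = TRUE,
                           by_gene = TRUE)
    met <- prediction_metrics(m$tp, nrow(preds), nrow(truth))
    dplyr::bind_cols(tibble::tibble(threshold = th), met)
  })
  out <- dplyr::bind_rows(rows)
  best <- out$threshold[which.max(out$f)]
  attr(out, "best_threshold") <- best
  out
}
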