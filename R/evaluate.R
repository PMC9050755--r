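# Matching predictions to true peak TSSs and computing sensitivity,
# precision and their harmonic mean F, with stratified breakdowns. A truth
# TSS counts as detected (sensitivity side) when it lies inside a prediction
# window; a prediction counts as true (precision side) when it contains at
# least one truth TSS, so a window spanning two TSSs counts twice for
# sensitivity but once for precision and both ratios stay <= 1.

truth_ids <- function(truth) {
  if (!is.null(truth$gene_id)) as.character(truth$gene_id)
  else as.character(seq_len(nrow(truth)))
}

#' Match prediction windows to true TSSs
#'
#' In `"window"` mode a truth TSS is detected when it lies inside a
#' prediction window (0-based half-open; the strand must also match when
#' `directional`). In `"point100"` mode a prediction point (the `point`
#' column when present, else the window midpoint) must lie within 100 bp of
#' the TSS. With `by_gene = TRUE` predictions are only matched against the
#' truth TSS of their own gene.
#'
#' @param preds Prediction tibble.
#' @param truth Truth tibble (`chrom`, `pos`, `strand`, optional `gene_id`).
#' @param mode `"window"` or `"point100"`.
#' @param directional Require matching strands.
#' @param by_gene Match within gene pairs (requires `gene_id` on both).
#' @return List with `tp` (= `tp_sens`, truth TSSs detected), `tp_prec`
#'   (predictions containing a truth TSS), `truth_ids` (detected) and
#'   `pred_idx` (matched prediction rows).
#' @export
match_predictions <- function(preds, truth, mode = c("window", "point100"),
                              directional = FALSE, by_gene = FALSE) {
  mode <- match.arg(mode)
  ids <- truth_ids(truth)
  if (nrow(preds) == 0L || nrow(truth) == 0L) {
    return(list(tp = 0L, tp_sens = 0L, tp_prec = 0L,
                truth_ids = character(0), pred_idx = integer(0)))
  }
  point <- if ("point" %in% colnames(preds)) preds$point
           else floor((preds$start + preds$end) / 2)
  hit <- matrix(FALSE, nrow = nrow(truth), ncol = nrow(preds))
  for (i in seq_len(nrow(truth))) {
    ok <- preds$chrom == truth$chrom[i]
    if (directional) ok <- ok & preds$strand == truth$strand[i]
    if (by_gene) ok <- ok & !is.na(preds$gene_id) &
        preds$gene_id == truth$gene_id[i]
    if (mode == "window") {
      ok <- ok & preds$start <= truth$pos[i] & truth$pos[i] < preds$end
    } else {
      ok <- ok & abs(point - truth$pos[i]) <= 100
    }
    hit[i, ] <- ok
  }
  det <- rowSums(hit) > 0
  mat <- colSums(hit) > 0
  list(tp = sum(det), tp_sens = sum(det), tp_prec = sum(mat),
       truth_ids = ids[det], pred_idx = which(mat))
}

#' Sensitivity, precision and harmonic mean from counts
#'
#' sensitivity = 100 * tp / n_pos ("true positives / positives"),
#' precision = 100 * tp / n_pred ("true positives / predictions", 0 when
#' there are no predictions), and F their harmonic mean (0 when both are 0).
#' Values are returned at full precision; the print method rounds to two
#' decimals.
#'
#' @param tp True positive count.
#' @param n_pred Number of predictions.
#' @param n_pos Number of true promoters evaluated (> 0).
#' @return One-row `eval_report` tibble (`tp`, `n_pred`, `n_pos`,
#'   `sensitivity`, `precision`, `f`).
#' @export
prediction_metrics <- function(tp, n_pred, n_pos) {
  if (n_pos <= 0L) rlang::abort("n_pos must be positive")
  sens <- 100 * tp / n_pos
  prec <- if (n_pred > 0L) 100 * tp / n_pred else 0
  f <- if (sens + prec > 0) 2 * sens * prec / (sens + prec) else 0
  out <- tibble::tibble(tp = tp, n_pred = n_pred, n_pos = n_pos,
                        sensitivity = sens, precision = prec, f = f)
  class(out) <- c("eval_report", class(out))
  out
}

#' Evaluate predictions against true TSSs
#'
#' Combines [match_predictions()] and [prediction_metrics()]. Sensitivity
#' uses the truth-side true positives and precision the prediction-side
#' ones; the two are also reported separately as `tp` and `tp_prec`.
#'
#' @inheritParams match_predictions
#' @return One-row `eval_report` tibble with an extra `tp_prec` column.
#' @export
evaluate_predictions <- function(preds, truth, mode = "window",
                                 directional = FALSE, by_gene = FALSE) {
  m <- match_predictions(preds, truth, mode = mode,
                         directional = directional, by_gene = by_gene)
  sens <- 100 * m$tp_sens / nrow(truth)
  prec <- if (nrow(preds) > 0L) 100 * m$tp_prec / nrow(preds) else 0
  f <- if (sens + prec > 0) 2 * sens * prec / (sens + prec) else 0
  out <- tibble::tibble(tp = m$tp_sens, tp_prec = m$tp_prec,
                        n_pred = nrow(preds), n_pos = nrow(truth),
                        sensitivity = sens, precision = prec, f = f)
  class(out) <- c("eval_report", class(out))
  out
}

#' @export
print.eval_report <- function(x, ...) {
  y <- tibble::as_tibble(x)
  y$sensitivity <- round(y$sensitivity, 2)
  y$precision <- round(y$precision, 2)
  y$f <- round(y$f, 2)
  print(y)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.eval_report <- function(x, ...) tibble::as_tibble(x)

#' @exportS3Method generics::glance
glance.eval_report <- function(x, ...) {
  tibble::as_tibble(x)[, c("sensitivity", "precision", "f")]
}

#' Stratified evaluation report
#'
#' Computes per-stratum metrics, the strata being a labelling of the truth
#' TSSs (core type, expression bin, TSS-CDS distance bin, REG presence,
#' promoter category, ...). Predictions carrying a `gene_id` are assigned to
#' the stratum of their gene; unlabeled truth records form an `"unlabeled"`
#' bucket.
#'
#' @param preds Prediction tibble with `gene_id`.
#' @param truth Truth tibble with `gene_id`.
#' @param strata Either the name of a label column in `truth`, or a named
#'   character vector mapping truth `gene_id` to label.
#' @param mode,directional Passed to [match_predictions()].
#' @return Tibble of per-stratum `eval_report` rows with a `stratum` column.
#' @export
stratified_report <- function(preds, truth, strata, mode = "window",
                              directional = FALSE) {
  labels <- if (is.character(strata) && length(strata) == 1L &&
                strata %in% names(truth)) {
    as.character(truth[[strata]])
  } else {
    unname(strata[truth_ids(truth)])
  }
  labels[is.na(labels)] <- "unlabeled"
  rows <- purrr::map(unique(labels), function(lb) {
    tr <- truth[labels == lb, , drop = FALSE]
    pr <- preds[!is.na(preds$gene_id) &
                  preds$gene_id %in% tr$gene_id, , drop = FALSE]
    rep <- evaluate_predictions(pr, tr, mode = mode,
                                directional = directional, by_gene = TRUE)
    dplyr::bind_cols(tibble::tibble(stratum = lb), rep)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("eval_report", class(out))
  out
}

#' Classify promoters by core promoter element content
#'
#' A core label (TATA, Y Patch, GA, CA, ...) applies when any octamer of its
#' set occurs fully within the TSS-proximal core window; promoters matching
#' no set are `"coreless"`. Labels are not exclusive.
#'
#' @param promoters Promoter tibble (`chrom`, `pos`, `strand`).
#' @param genome Named character vector of chromosome sequences.
#' @param core_sets Named list of octamer character vectors.
#' @param core_window Inclusive relative window searched (default
#'   `c(-50, 10)`; configurable to match the provenance of the octamer
#'   sets).
#' @return `promoters` with list-column `core_labels` and string column
#'   `core_type` (labels joined with `+`, or `"coreless"`).
#' @export
classify_core_type <- function(promoters, genome, core_sets,
                               core_window = c(-50, 10)) {
  sets_idx <- lapply(core_sets, oct_index)
  labs <- purrr::map(seq_len(nrow(promoters)), function(i) {
    s <- extract_rel_window(genome[[promoters$chrom[i]]], promoters$pos[i],
                            promoters$strand[i], core_window[1L],
                            core_window[2L])
    if (is.na(s)) return(character(0))
    codes <- octamer_codes(s)
    codes <- codes[!is.na(codes)] + 1L
    names(core_sets)[vapply(sets_idx, function(ix) any(codes %in% ix),
                            logical(1))]
  })
  promoters$core_labels <- labs
  promoters$core_type <- vapply(labs, function(x) {
    if (length(x) == 0L) "coreless" else paste(x, collapse = "+")
  }, character(1))
  promoters
}

#' Bin expression levels (tpm)
#'
#' Default bins follow a lowest bin below 4 tpm with log2-spaced bins above.
#'
#' @param tpm Numeric vector of expression values.
#' @param breaks Increasing break points (default `c(4, 16, 64, 256)`).
#' @return Factor of bin labels.
#' @export
bin_expression <- function(tpm, breaks = c(4, 16, 64, 256)) {
  cut(tpm, breaks = c(-Inf, breaks, Inf),
      labels = c(paste0("<", breaks[1L]),
                 paste0(utils::head(breaks, -1L), "-", breaks[-1L]),
                 paste0(">=", breaks[length(breaks)])),
      right = FALSE)
}

#' Bin TSS-CDS distances
#'
#' @param d Numeric vector of distances (bp).
#' @param breaks Increasing break points (default `c(100, 200, 400, 800)`).
#' @return Factor of bin labels.
#' @export
bin_distance <- function(d, breaks = c(100, 200, 400, 800)) {
  cut(d, breaks = c(-Inf, breaks, Inf),
      labels = c(paste0("<", breaks[1L]),
                 paste0(utils::head(breaks, -1L), "-", breaks[-1L]),
                 paste0(">=", breaks[length(breaks)])),
      right = FALSE)
}

#' Bar chart of a stratified evaluation report
#'
#' @param report Output of [stratified_report()].
#' @return A ggplot object.
#' @export
plot_eval_report <- function(report) {
  long <- tidyr::pivot_longer(tibble::as_tibble(report),
                              c("sensitivity", "precision", "f"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$stratum, y = .data$value,
                                     fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "%", fill = NULL) +
    ggplot2::theme_minimal()
}
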