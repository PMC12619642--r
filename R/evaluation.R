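# Scoring detection output against ground truth, plus the diagnostic
# summaries used to investigate chimera formation patterns and database
# completeness (gene-pair recombination counts and their normalization).

#' ROC curve and AUC
#'
#' Curve over all distinct score thresholds with tied scores grouped (all
#' ties enter/leave together); AUC by the trapezoidal rule, which under tie
#' grouping equals the Mann-Whitney statistic with half-credit for ties.
#'
#' @param labels Logical (or 0/1) ground-truth labels; both classes must be
#'   present.
#' @param scores Numeric scores, higher = more likely positive.
#' @return A list with `curve` (data.frame `threshold`, `tpr`, `fpr`,
#'   beginning at the all-negative point) and `auc`.
#' @export
roc_auc <- function(labels, scores) {
  labels <- as.logical(labels)
  if (length(labels) != length(scores)) {
    stop_evaluation("labels and scores have different lengths")
  }
  if (any(is.na(labels)) || any(is.na(scores))) {
    stop_evaluation("labels and scores must not contain NA")
  }
  P <- sum(labels); N <- sum(!labels)
  if (P == 0L || N == 0L) {
    stop_evaluation("both classes must be present to compute a ROC curve")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  last <- c(which(diff(s) != 0), length(s))  # last index of each tie group
  tpr <- cumsum(y)[last] / P
  fpr <- cumsum(!y)[last] / N
  curve <- data.frame(threshold = c(Inf, s[last]), tpr = c(0, tpr),
                      fpr = c(0, fpr))
  auc <- sum(diff(curve$fpr) * (head(curve$tpr, -1) + tail(curve$tpr, -1)) / 2)
  list(curve = curve, auc = auc)
}

#' Confusion counts at a detection threshold
#'
#' A positive call is `score > threshold` (strict, matching
#' [posterior_threshold()]).
#'
#' @inheritParams roc_auc
#' @param threshold Probability threshold.
#' @return List with `tp`, `fp`, `tn`, `fn` (they sum to `length(labels)`).
#' @export
confusion_at_threshold <- function(labels, scores, threshold) {
  labels <- as.logical(labels)
  if (length(labels) != length(scores)) {
    stop_evaluation("labels and scores have different lengths")
  }
  pos <- scores > threshold
  list(tp = sum(pos & labels), fp = sum(pos & !labels),
       tn = sum(!pos & !labels), fn = sum(!pos & labels))
}

# Events of calls that are flagged and have exactly one recombination event.
single_event_calls <- function(calls) {
  stopifnot(is.data.frame(calls), "events" %in% names(calls))
  n_ev <- vapply(calls$events, nrow, integer(1L))
  idx <- which(calls$chimeric & n_ev == 1L)
  do.call(rbind, c(calls$events[idx],
                   list(data.frame(from_allele = character(0),
                                   to_allele = character(0),
                                   breakpoint_column = integer(0)))))
}

#' Gene-pair recombination count matrix
#'
#' Tallies gene (not allele) pairs for flagged calls with exactly one
#' recombination event; multi-event chimeras are excluded. Rows are the gene
#' on the left (pre-breakpoint) side, columns the right side.
#'
#' @param calls Calls data.frame from [run_detection()] (must carry the
#'   `events` list-column, i.e. Viterbi output).
#' @param genes Optional gene label vector fixing the matrix axes; defaults
#'   to the sorted union of genes observed in the events.
#' @return An integer matrix with gene dimnames; its total equals the number
#'   of single-event chimeras tallied.
#' @export
recombination_counts <- function(calls, genes = NULL) {
  ev <- single_event_calls(calls)
  left <- sub("\\*.*$", "", ev$from_allele)
  right <- sub("\\*.*$", "", ev$to_allele)
  if (is.null(genes)) genes <- sort(unique(c(left, right)))
  counts <- matrix(0L, length(genes), length(genes),
                   dimnames = list(genes, genes))
  for (i in seq_along(left)) {
    counts[left[i], right[i]] <- counts[left[i], right[i]] + 1L
  }
  counts
}

#' Normalized recombination counts (observed / expected)
#'
#' Divides each cell by its expectation under independent participation of
#' the two genes: `freq_left * freq_right * total single-event chimeras`.
#' Missing database alleles show up as overrepresented (ratio >> 1) cells.
#' Cells with zero expectation are `NA`.
#'
#' @param counts Matrix from [recombination_counts()].
#' @param gene_frequencies Named numeric vector of gene frequencies; must be
#'   positive for every gene appearing in `counts`.
#' @return Numeric matrix of observed/expected ratios.
#' @export
normalized_recombination_counts <- function(counts, gene_frequencies) {
  genes <- rownames(counts)
  if (length(genes) == 0L) return(counts + 0)
  freq <- gene_frequencies[genes]
  used <- rowSums(counts) + colSums(counts) > 0
  if (any(used & (is.na(freq) | freq <= 0))) {
    stop_evaluation("gene_frequencies must be positive for every gene with counts")
  }
  total <- sum(counts)
  expected <- outer(freq, freq) * total
  out <- counts / expected
  out[expected == 0] <- NA_real_
  dimnames(out) <- dimnames(counts)
  out
}

#' Histogram of recombination breakpoint positions
#'
#' Bins the breakpoint columns of flagged single-event chimeras over the MSA
#' columns `1..L`; bins partition the range exactly once (the last bin may
#' be short).
#'
#' @param calls Calls data.frame with the `events` list-column.
#' @param bin_width Positive integer bin width in MSA columns.
#' @param L MSA column count.
#' @return Data.frame with `bin_start`, `bin_end`, `count`.
#' @export
breakpoint_histogram <- function(calls, bin_width, L) {
  if (!is_count(bin_width) || bin_width < 1L) {
    stop_parameter("`bin_width` must be a positive integer")
  }
  ev <- single_event_calls(calls)
  starts <- seq(1L, L, by = bin_width)
  ends <- pmin(starts + bin_width - 1L, L)
  bin <- findInterval(ev$breakpoint_column, starts)
  count <- tabulate(bin, nbins = length(starts))
  data.frame(bin_start = starts, bin_end = ends, count = count)
}
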