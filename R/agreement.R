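# Inter-scorer agreement on binarized spindle timelines, and event-level
# consensus matching.

#' Binarize an event list onto a fixed-resolution timeline
#'
#' A bin is TRUE if any event overlaps it by any amount. Bins are
#' half-open intervals `[k*resolution, (k+1)*resolution)` and events
#' are half-open `[onset, offset)`.
#'
#' @param events data.frame with `onset`, `offset` in seconds.
#' @param duration timeline length in seconds.
#' @param resolution bin width in seconds.
#' @return logical vector of `floor(duration / resolution)` bins.
#' @export
binarize_timeline <- function(events, duration, resolution = 0.1) {
  stopifnot(duration > 0, resolution > 0)
  n <- floor(duration / resolution + 1e-9)
  out <- rep(FALSE, n)
  if (!is.null(events) && nrow(events)) {
    for (i in seq_len(nrow(events))) {
      lo <- max(0L, floor(events$onset[i] / resolution + 1e-9))
      hi <- min(n - 1L, ceiling(events$offset[i] / resolution - 1e-9) - 1L)
      if (hi >= lo) out[(lo:hi) + 1L] <- TRUE
    }
  }
  out
}

#' Agreement statistics between two binary timelines
#'
#' Confusion counts treat `a` as the reference: TP = both TRUE,
#' FN = only `a`, FP = only `b`, TN = neither. Derived statistics:
#' sensitivity TP/(TP+FN), specificity TN/(TN+FP), precision
#' TP/(TP+FP), Cohen's kappa `(p_o - p_e)/(1 - p_e)`, Matthews
#' correlation `(TP*TN - FP*FN)/sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`
#' (identical to the Pearson correlation of the two binary vectors),
#' and the adjusted G-mean for imbalanced classes:
#' `AGm = (Gm + specificity * N_n) / (1 + N_n)` where
#' `Gm = sqrt(sensitivity * specificity)` and `N_n` is the proportion
#' of negative (reference-FALSE) bins, defined as 0 when sensitivity
#' is 0.
#'
#' @param a,b logical vectors of equal positive length.
#' @return object of class `agreement_result`: list with `TP`, `FP`,
#'   `FN`, `TN`, `sensitivity`, `specificity`, `precision`, `kappa`,
#'   `matthews`, `adjusted_gmean`, `kappa_label`.
#' @export
agreement_stats <- function(a, b) {
  if (!is.logical(a) || !is.logical(b))
    stop("timelines must be logical vectors")
  if (!length(a) || length(a) != length(b))
    stop("timelines must be non-empty and of equal length")
  n <- length(a)
  tp <- sum(a & b); fn <- sum(a & !b)
  fp <- sum(!a & b); tn <- sum(!a & !b)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  p_o <- (tp + tn) / n
  p_e <- ((tp + fn) * (tp + fp) + (fp + tn) * (fn + tn)) / n^2
  kappa <- if (abs(1 - p_e) < 1e-15) {
    if (p_o >= 1) 1 else 0     # degenerate marginals
  } else (p_o - p_e) / (1 - p_e)
  denom <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (denom > 0) (tp * tn - fp * fn) / denom else NA_real_
  n_n <- (fp + tn) / n
  agm <- if (is.na(sens) || sens == 0) 0 else
    (sqrt(sens * spec) + spec * n_n) / (1 + n_n)
  structure(list(TP = tp, FP = fp, FN = fn, TN = tn,
                 sensitivity = sens, specificity = spec,
                 precision = prec, kappa = kappa, matthews = mcc,
                 adjusted_gmean = agm,
                 kappa_label = landis_koch_label(kappa)),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf(
    "<agreement_result> TP=%d FP=%d FN=%d TN=%d\n  sens=%.3f spec=%.3f prec=%.3f kappa=%.3f (%s) MCC=%.3f AGm=%.3f\n",
    x$TP, x$FP, x$FN, x$TN, x$sensitivity, x$specificity, x$precision,
    x$kappa, x$kappa_label, x$matthews, x$adjusted_gmean))
  invisible(x)
}

#' Landis-Koch benchmark label for a kappa (or ICC) value
#'
#' 0-0.2 slight, 0.21-0.40 fair, 0.41-0.60 moderate, 0.61-0.80
#' substantial, 0.81-1 almost perfect; values below 0 are labelled
#' `"poor"`.
#'
#' @param kappa numeric value in `[-1, 1]`.
#' @return character label.
#' @export
landis_koch_label <- function(kappa) {
  if (is.na(kappa)) return(NA_character_)
  if (kappa < 0) "poor"
  else if (kappa <= 0.20) "slight"
  else if (kappa <= 0.40) "fair"
  else if (kappa <= 0.60) "moderate"
  else if (kappa <= 0.80) "substantial"
  else "almost perfect"
}

#' Event-level consensus by minimum temporal overlap
#'
#' Two events agree when their intersection lasts at least
#' `min_overlap` seconds. Matching is greedy one-to-one by decreasing
#' overlap; unmatched events are reported per scorer.
#'
#' @param events_a,events_b event data.frames with `onset`, `offset`.
#' @param min_overlap minimum overlap in seconds.
#' @return list with `consensus` (data.frame of `index_a`, `index_b`,
#'   `overlap`), `only_a`, `only_b` (integer row indices).
#' @export
event_overlap_sets <- function(events_a, events_b, min_overlap = 0.3) {
  na <- nrow(events_a); nb <- nrow(events_b)
  pairs <- list()
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      ov <- min(events_a$offset[i], events_b$offset[j]) -
        max(events_a$onset[i], events_b$onset[j])
      if (ov >= min_overlap - 1e-9)
        pairs[[length(pairs) + 1L]] <-
          data.frame(index_a = i, index_b = j, overlap = ov)
    }
  }
  cons <- data.frame(index_a = integer(0), index_b = integer(0),
                     overlap = numeric(0))
  if (length(pairs)) {
    cand <- do.call(rbind, pairs)
    cand <- cand[order(-cand$overlap), , drop = FALSE]
    used_a <- logical(na); used_b <- logical(nb)
    for (r in seq_len(nrow(cand))) {
      i <- cand$index_a[r]; j <- cand$index_b[r]
      if (!used_a[i] && !used_b[j]) {
        cons <- rbind(cons, cand[r, , drop = FALSE])
        used_a[i] <- TRUE; used_b[j] <- TRUE
      }
    }
  }
  list(consensus = cons,
       only_a = setdiff(seq_len(na), cons$index_a),
       only_b = setdiff(seq_len(nb), cons$index_b))
}

#' Weighted average across recordings
#'
#' Used to pool per-recording agreement statistics with each
#' recording's number of investigated sleep epochs as the weight.
#'
#' @param values numeric vector.
#' @param weights non-negative weights, same length.
#' @return scalar weighted mean.
#' @export
weighted_average <- function(values, weights = rep(1, length(values))) {
  stopifnot(length(values) == length(weights), all(weights >= 0),
            sum(weights) > 0)
  sum(values * weights) / sum(weights)
}

#' Pearson correlation of two numeric vectors
#'
#' Thin wrapper over [stats::cor()] used for subject-wise spindle
#' density agreement between scorers.
#' @param x,y numeric vectors of equal length.
#' @export
pearson <- function(x, y) stats::cor(x, y, method = "pearson")
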