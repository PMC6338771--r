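# ROC construction from scored, gel-labeled primer pairs: threshold sweep,
# trapezoidal AUC, and the dimer-free discrimination threshold.

.normalise_labels <- function(labels) {
  lab <- tolower(gsub("[ -]", "_", trimws(as.character(labels))))
  ok <- c("dimer", "dimer_free", "ambiguous")
  bad <- setdiff(unique(lab), ok)
  if (length(bad) > 0L) {
    stop("unknown dimer label(s): ", paste(bad, collapse = ", "),
         " (expected dimer / dimer_free / ambiguous)", call. = FALSE)
  }
  lab
}

#' Build a ROC curve from dimer scores and gel labels
#'
#' Scores paired with dimer status are arranged from most positive to most
#' negative; each distinct score (plus a sentinel above the maximum) is set
#' in turn as the discrimination threshold. A pair is classified
#' dimer-forming when its score is strictly below the threshold and
#' dimer-free when at or above it. TPR and FPR at each threshold give the
#' curve; the area is accumulated by the trapezoid rule, which handles
#' cross-class ties as diagonal segments (equivalent to half-weighting in
#' the Mann-Whitney statistic).
#'
#' @param scores numeric dimer scores (more negative = more dimer-prone).
#' @param labels labels, one of "dimer", "dimer_free", "ambiguous".
#' @param ambiguous_mode "exclude" drops ambiguous pairs from the analysis;
#'   "as_dimer" reclassifies them as dimer-forming (the stringent mode).
#' @param threshold_rule passed to \code{\link{dimer_free_threshold}}.
#' @return an object of class \code{roc_curve}: \code{points} (data frame of
#'   threshold, tpr, fpr, partial_auc in descending threshold order),
#'   \code{auc}, \code{dimer_free_threshold}, \code{tnr_at_threshold},
#'   \code{n_positive}, \code{n_negative}, \code{n_excluded}.
#' @export
build_roc <- function(scores, labels, ambiguous_mode = c("exclude", "as_dimer"),
                      threshold_rule = c("above_worst_dimer", "worst_dimer")) {
  ambiguous_mode <- match.arg(ambiguous_mode)
  threshold_rule <- match.arg(threshold_rule)
  if (length(scores) != length(labels)) {
    stop("scores and labels differ in length", call. = FALSE)
  }
  if (any(!is.finite(scores))) {
    stop("non-finite dimer score in input", call. = FALSE)
  }
  lab <- .normalise_labels(labels)
  amb <- lab == "ambiguous"
  n_excluded <- 0L
  if (ambiguous_mode == "exclude") {
    n_excluded <- sum(amb)
    scores <- scores[!amb]
    lab <- lab[!amb]
  } else {
    lab[amb] <- "dimer"
  }
  pos <- lab == "dimer"
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L) {
    stop("ROC undefined: need at least one dimer and one dimer-free pair",
         call. = FALSE)
  }
  thresholds <- c(max(scores) + 1, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thresholds, function(t) sum(scores[pos] < t) / n_pos,
                numeric(1))
  fpr <- vapply(thresholds, function(t) sum(scores[!pos] < t) / n_neg,
                numeric(1))
  partial <- c(0, (fpr[-length(fpr)] - fpr[-1]) *
                 (tpr[-length(tpr)] + tpr[-1]) / 2)
  thr <- dimer_free_threshold(scores, lab, rule = threshold_rule)
  structure(list(
    points = data.frame(threshold = thresholds, tpr = tpr, fpr = fpr,
                        partial_auc = partial),
    auc = sum(partial),
    dimer_free_threshold = thr$threshold,
    tnr_at_threshold = thr$tnr,
    threshold_vacuous = thr$vacuous,
    n_positive = n_pos,
    n_negative = n_neg,
    n_excluded = n_excluded
  ), class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.4f over %d dimer / %d dimer-free pairs",
              x$auc, x$n_positive, x$n_negative))
  if (x$n_excluded > 0) cat(sprintf(" (%d ambiguous excluded)", x$n_excluded))
  cat("\n")
  if (is.na(x$dimer_free_threshold)) {
    cat("Dimer-free threshold: undefined (no score above the worst dimer)\n")
  } else {
    cat(sprintf("Dimer-free threshold = %.4f, TNR = %.4f%s\n",
                x$dimer_free_threshold, x$tnr_at_threshold,
                if (isTRUE(x$threshold_vacuous)) " (vacuous: no dimers)" else ""))
  }
  invisible(x)
}

#' Dimer-free discrimination threshold
#'
#' The threshold below which the first dimer forms: with the "score >=
#' threshold implies dimer-free" rule, it is the lowest observed score that
#' still sits strictly above every dimer-labeled score, so the false
#' negative count is zero by construction. \code{rule = "worst_dimer"}
#' instead reports the worst (most positive) dimer score itself.
#'
#' @param scores numeric dimer scores.
#' @param labels dimer labels ("ambiguous" entries are ignored here; handle
#'   them upstream).
#' @param rule threshold reporting convention.
#' @return list with \code{threshold} (NA when undefined), \code{tnr}
#'   (fraction of dimer-free pairs at or above the threshold) and
#'   \code{vacuous} (TRUE when there are no dimer-labeled pairs).
#' @export
dimer_free_threshold <- function(scores, labels,
                                 rule = c("above_worst_dimer", "worst_dimer")) {
  rule <- match.arg(rule)
  lab <- .normalise_labels(labels)
  keep <- lab != "ambiguous"
  scores <- scores[keep]
  lab <- lab[keep]
  pos <- lab == "dimer"
  neg_scores <- scores[!pos]
  if (!any(pos)) {
    return(list(threshold = min(scores), tnr = 1.0, vacuous = TRUE))
  }
  s_max <- max(scores[pos])
  if (rule == "worst_dimer") {
    thr <- s_max
    tnr <- if (length(neg_scores) == 0L) 0 else mean(neg_scores > thr)
    return(list(threshold = thr, tnr = tnr, vacuous = FALSE))
  }
  above <- scores[scores > s_max]
  if (length(above) == 0L) {
    return(list(threshold = NA_real_, tnr = 0, vacuous = FALSE))
  }
  thr <- min(above)
  tnr <- if (length(neg_scores) == 0L) 0 else mean(neg_scores >= thr)
  list(threshold = thr, tnr = tnr, vacuous = FALSE)
}

#' Score and evaluate a labeled primer-pair dataset
#'
#' Computes the dimer score of every pair, then builds the ROC curve from
#' the scores and the empirical labels.
#'
#' @param pairs a pair table (data frame with columns pair_id, forward,
#'   reverse, dimer_status) or a list of \code{\link{primer_pair}} objects.
#' @param params a \code{\link{thermo_params}}.
#' @param config a \code{\link{scoring_config}}.
#' @param ambiguous_mode,threshold_rule passed to \code{\link{build_roc}}.
#' @param use_adjusted evaluate on length/GC adjusted scores (default) or
#'   raw scores.
#' @return list with \code{curve} (a \code{roc_curve}) and \code{scores}
#'   (data frame: pair_id, raw_ds, adjusted_ds, best_pairing, label).
#' @export
evaluate_dataset <- function(pairs, params, config = scoring_config(),
                             ambiguous_mode = c("exclude", "as_dimer"),
                             threshold_rule = c("above_worst_dimer",
                                                "worst_dimer"),
                             use_adjusted = TRUE) {
  pl <- .as_pair_list(pairs)
  scored <- lapply(pl, dimer_score_pair, params = params, config = config)
  tab <- data.frame(
    pair_id = vapply(pl, `[[`, character(1), "pair_id"),
    raw_ds = vapply(scored, `[[`, numeric(1), "raw_ds"),
    adjusted_ds = vapply(scored, `[[`, numeric(1), "adjusted_ds"),
    best_pairing = vapply(scored, `[[`, character(1), "best_pairing"),
    label = vapply(pl, `[[`, character(1), "label"),
    stringsAsFactors = FALSE
  )
  if (any(tab$label == "unlabeled")) {
    stop("evaluate_dataset needs labeled pairs (dimer / dimer_free / ",
         "ambiguous)", call. = FALSE)
  }
  sc <- if (use_adjusted) tab$adjusted_ds else tab$raw_ds
  curve <- build_roc(sc, tab$label, ambiguous_mode = ambiguous_mode,
                     threshold_rule = threshold_rule)
  list(curve = curve, scores = tab)
}

# coerce a pair table data frame or list of primer_pair into a list of
# primer_pair objects
.as_pair_list <- function(pairs) {
  if (is.data.frame(pairs)) {
    need <- c("pair_id", "forward", "reverse")
    if (!all(need %in% names(pairs))) {
      stop("pair table must have columns pair_id, forward, reverse",
           call. = FALSE)
    }
    lab <- if ("dimer_status" %in% names(pairs)) {
      pairs$dimer_status
    } else {
      rep("unlabeled", nrow(pairs))
    }
    lapply(seq_len(nrow(pairs)), function(i) {
      primer_pair(pairs$pair_id[i], pairs$forward[i], pairs$reverse[i],
                  label = lab[i])
    })
  } else if (is.list(pairs) && all(vapply(pairs, inherits, logical(1),
                                          "primer_pair"))) {
    pairs
  } else {
    stop("pairs must be a pair table or a list of primer_pair objects",
         call. = FALSE)
  }
}
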