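# Greedy dimer-aware multiplex pool construction from externally supplied
# per-region candidate primer pairs, plus an exhaustive post-hoc audit.

#' A target region with its candidate primer pairs
#'
#' Candidate generation (design against a genomic target) is out of scope;
#' callers supply pre-designed candidates per region.
#'
#' @param region_id identifier string.
#' @param candidates list of \code{\link{primer_pair}} objects (may be
#'   empty; the region is then reported as a dropout).
#' @return an object of class \code{region}.
#' @export
region <- function(region_id, candidates = list()) {
  stopifnot(all(vapply(candidates, inherits, logical(1), "primer_pair")))
  structure(list(region_id = as.character(region_id),
                 candidates = candidates),
            class = "region")
}

#' Worst interaction score of a candidate pair against a primer pool
#'
#' Pairs the candidate's two primers with every oligo already in the pool,
#' plus the candidate's own three pairings, and returns the most negative
#' length/GC-adjusted dimer score among all these interactions. With an
#' empty pool this reduces to the candidate's own dimer score.
#'
#' @param candidate a \code{\link{primer_pair}}.
#' @param pool_primers character vector of pool oligo sequences.
#' @param params a \code{\link{thermo_params}}.
#' @param config a \code{\link{scoring_config}}.
#' @return the minimum adjusted dimer score (score units).
#' @export
cross_pool_min_score <- function(candidate, pool_primers, params,
                                 config = scoring_config()) {
  stopifnot(inherits(candidate, "primer_pair"))
  own <- dimer_score_pair(candidate, params, config)$adjusted_ds
  if (length(pool_primers) == 0L) return(own)
  cross <- vapply(pool_primers, function(oligo) {
    min(.oligo_pairing_score(candidate$forward, oligo, params, config),
        .oligo_pairing_score(candidate$reverse, oligo, params, config))
  }, numeric(1))
  min(own, cross)
}

#' Greedy construction of a dimer-free multiplex pool
#'
#' Regions are processed from fewest to most candidates (ties broken by
#' region id); for each region, candidates whose worst interaction with the
#' growing pool stays at or above the dimer-free threshold are retained, and
#' the retained candidate with the highest (least negative) score is added
#' to the pool. Regions with no surviving candidate are recorded as
#' dropouts. Earlier acceptances are never revisited.
#'
#' @param regions list of \code{\link{region}} objects.
#' @param threshold dimer-free cutoff on the adjusted score scale. The
#'   default, -4.43, is the length/GC-adjusted cutoff calibrated on gel
#'   data under one specific set of PCR conditions; it is condition-specific
#'   and should be re-derived (via \code{\link{build_roc}}) for other
#'   chemistries.
#' @param params a \code{\link{thermo_params}}.
#' @param config a \code{\link{scoring_config}}.
#' @return an object of class \code{multiplex_pool}: \code{accepted} (data
#'   frame: region_id, pair_id, forward, reverse, worst_cross_score, in
#'   acceptance order), \code{threshold}, \code{dropouts}, \code{n_primers},
#'   \code{pool_oligos}.
#' @export
build_pool <- function(regions, threshold = -4.43, params,
                       config = scoring_config()) {
  stopifnot(all(vapply(regions, inherits, logical(1), "region")))
  if (!is.finite(threshold)) stop("threshold must be finite", call. = FALSE)
  n_cand <- vapply(regions, function(r) length(r$candidates), integer(1))
  ids <- vapply(regions, `[[`, character(1), "region_id")
  ord <- order(n_cand, ids)
  pool <- character(0)
  accepted <- list()
  dropouts <- character(0)
  for (r in regions[ord]) {
    if (length(r$candidates) == 0L) {
      dropouts <- c(dropouts, r$region_id)
      next
    }
    scores <- vapply(r$candidates, cross_pool_min_score, numeric(1),
                     pool_primers = pool, params = params, config = config)
    ok <- which(scores >= threshold)
    if (length(ok) == 0L) {
      dropouts <- c(dropouts, r$region_id)
      next
    }
    best <- ok[which.max(scores[ok])]  # ties: first by input order
    cand <- r$candidates[[best]]
    accepted[[length(accepted) + 1L]] <- data.frame(
      region_id = r$region_id, pair_id = cand$pair_id,
      forward = cand$forward, reverse = cand$reverse,
      worst_cross_score = scores[best], stringsAsFactors = FALSE)
    pool <- c(pool, cand$forward, cand$reverse)
  }
  acc <- if (length(accepted) > 0L) {
    do.call(rbind, accepted)
  } else {
    data.frame(region_id = character(0), pair_id = character(0),
               forward = character(0), reverse = character(0),
               worst_cross_score = numeric(0))
  }
  structure(list(accepted = acc, threshold = threshold, dropouts = dropouts,
                 n_primers = length(pool), pool_oligos = pool),
            class = "multiplex_pool")
}

#' @export
print.multiplex_pool <- function(x, ...) {
  cat(sprintf("Multiplex pool: %d regions accepted (%d primers), %d dropout(s), threshold %.3f\n",
              nrow(x$accepted), x$n_primers, length(x$dropouts), x$threshold))
  if (length(x$dropouts) > 0) {
    cat("  dropouts:", paste(x$dropouts, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Exhaustive post-hoc audit of a multiplex pool
#'
#' Rescores every distinct primer-primer combination in the final pool,
#' homodimers included: for n pool primers that is (n^2 + n)/2 interactions.
#'
#' @param pool a \code{\link{build_pool}} result.
#' @param params a \code{\link{thermo_params}}.
#' @param config a \code{\link{scoring_config}}.
#' @return list with \code{n_interactions}, \code{min_score},
#'   \code{all_pass} (no interaction below the pool threshold) and
#'   \code{scores} (matrix of pairwise adjusted scores, upper triangle).
#' @export
verify_pool <- function(pool, params, config = scoring_config()) {
  stopifnot(inherits(pool, "multiplex_pool"))
  oligos <- pool$pool_oligos
  n <- length(oligos)
  scores <- matrix(NA_real_, n, n)
  count <- 0L
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (n == 0L) break
      scores[i, j] <- .oligo_pairing_score(oligos[i], oligos[j], params,
                                           config)
      count <- count + 1L
    }
  }
  min_score <- if (count > 0L) min(scores, na.rm = TRUE) else Inf
  list(n_interactions = count, min_score = min_score,
       all_pass = min_score >= pool$threshold, scores = scores)
}
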