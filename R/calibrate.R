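# Bonus/penalty calibration: exhaustive grid search over scoring-config
# fields maximising the mean dimer-free TNR across training sets, with mean
# AUC as the tie-break.

.GRID_FIELDS <- c("gc_full_span_bonus", "compound_end_penalty",
                  "double_mismatch_penalty",
                  paste0("penalty_pos", 1:5))

#' Candidate grid for scoring-parameter calibration
#'
#' @param ... named candidate value vectors. Allowed names:
#'   \code{gc_full_span_bonus}, \code{compound_end_penalty},
#'   \code{double_mismatch_penalty}, and \code{penalty_pos1} ..
#'   \code{penalty_pos5} (the per-position 3' mismatch penalties).
#'   Enumeration is lexicographic over the declared parameter order (the
#'   first declared parameter varies slowest).
#' @return an object of class \code{parameter_grid}.
#' @examples
#' parameter_grid(gc_full_span_bonus = c(0, -1, -2),
#'                compound_end_penalty = c(1, 2))
#' @export
parameter_grid <- function(...) {
  values <- list(...)
  if (length(values) == 0L) stop("empty parameter grid", call. = FALSE)
  bad <- setdiff(names(values), .GRID_FIELDS)
  if (is.null(names(values)) || any(names(values) == "") || length(bad) > 0L) {
    stop("grid parameters must be named from: ",
         paste(.GRID_FIELDS, collapse = ", "), call. = FALSE)
  }
  if (any(vapply(values, length, integer(1)) == 0L)) {
    stop("every grid parameter needs at least one candidate value",
         call. = FALSE)
  }
  structure(list(values = values), class = "parameter_grid")
}

# cartesian product in declared lexicographic order: first parameter
# outermost (varies slowest)
.grid_rows <- function(grid) {
  g <- expand.grid(rev(grid$values), KEEP.OUT.ATTRS = FALSE)
  g[, rev(seq_along(g)), drop = FALSE]
}

# apply one grid row to a scoring config
.apply_grid_row <- function(config, row) {
  for (nm in names(row)) {
    v <- row[[nm]]
    if (startsWith(nm, "penalty_pos")) {
      i <- as.integer(sub("penalty_pos", "", nm))
      config$three_prime_mismatch_penalties[i] <- v
    } else {
      config[[nm]] <- v
    }
  }
  do.call(scoring_config, unclass(config)[names(formals(scoring_config))])
}

# objective for one training set under a feature representation:
# features recomputed per pair only when double_mismatch_penalty changes.
.set_objective <- function(feats_by_pair, meta, labels, config) {
  scores <- vapply(seq_along(feats_by_pair), function(i) {
    fm <- feats_by_pair[[i]]
    sc <- .combine_features(fm$features, config)
    j <- which.min(sc)
    if (config$use_length_gc_adjustment) {
      ds1 <- sc[j] / config$length_norm_divisor * fm$lensum[j]
      (ds1 + ds1 * fm$gcavg[j] * config$gc_coefficient) / config$final_divisor
    } else {
      sc[j]
    }
  }, numeric(1))
  thr <- dimer_free_threshold(scores, labels)
  curve <- build_roc(scores, labels)
  c(tnr = thr$tnr, auc = curve$auc)
}

# per-pair feature matrices for all structures of all three pairings
.pair_feature_set <- function(pair, params, config) {
  pairings <- list(c(pair$forward, pair$reverse),
                   c(pair$forward, pair$forward),
                   c(pair$reverse, pair$reverse))
  mats <- list(); lensum <- numeric(0); gcavg <- numeric(0)
  for (sq in pairings) {
    pf <- .pairing_features(sq[1], sq[2], params, config)
    mats[[length(mats) + 1L]] <- pf$features
    n <- nrow(pf$features)
    lensum <- c(lensum, rep(nchar(sq[1]) + nchar(sq[2]), n))
    gcavg <- c(gcavg, rep((.gc_fraction(toupper(sq[1])) +
                             .gc_fraction(toupper(sq[2]))) / 2, n))
  }
  list(features = do.call(rbind, mats), lensum = lensum, gcavg = gcavg)
}

#' Grid search for bonus/penalty values
#'
#' Exhaustively evaluates every candidate configuration on one or more
#' labeled training sets. The objective is the mean dimer-free true negative
#' rate across sets; ties are broken by the mean AUC, and remaining ties by
#' enumeration order. Structure free energies are computed once per
#' double-mismatch-penalty value and reused across the penalty/bonus grid,
#' so large grids stay cheap.
#'
#' @param grid a \code{\link{parameter_grid}}.
#' @param training_sets list of labeled pair tables (or lists of
#'   \code{\link{primer_pair}}); every set needs both classes.
#' @param params a \code{\link{thermo_params}}.
#' @param config base \code{\link{scoring_config}}; grid fields override it.
#' @return list with \code{config} (winning full configuration),
#'   \code{report} (data frame: one row per candidate with mean_tnr and
#'   mean_auc) and \code{best_index}.
#' @export
grid_search <- function(grid, training_sets, params,
                        config = scoring_config()) {
  stopifnot(inherits(grid, "parameter_grid"))
  if (length(training_sets) == 0L) {
    stop("no training sets supplied", call. = FALSE)
  }
  sets <- lapply(training_sets, .as_pair_list)
  set_names <- if (is.null(names(training_sets))) {
    paste0("set", seq_along(sets))
  } else {
    names(training_sets)
  }
  for (i in seq_along(sets)) {
    lab <- vapply(sets[[i]], `[[`, character(1), "label")
    lab <- lab[lab != "ambiguous"]
    if (!all(c("dimer", "dimer_free") %in% lab)) {
      stop("degenerate training set '", set_names[i],
           "': needs both dimer and dimer-free pairs", call. = FALSE)
    }
  }
  labels <- lapply(sets, function(s) vapply(s, `[[`, character(1), "label"))

  rows <- .grid_rows(grid)
  # feature matrices depend on the thermodynamic base values, hence on the
  # double-mismatch penalty; cache one feature set per distinct value
  dmp_values <- if ("double_mismatch_penalty" %in% names(rows)) {
    unique(rows$double_mismatch_penalty)
  } else {
    config$double_mismatch_penalty
  }
  feat_cache <- lapply(dmp_values, function(dmp) {
    cfg <- config
    cfg$double_mismatch_penalty <- dmp
    lapply(sets, function(s) {
      lapply(s, .pair_feature_set, params = params, config = cfg)
    })
  })
  names(feat_cache) <- as.character(dmp_values)

  n_cfg <- nrow(rows)
  mean_tnr <- numeric(n_cfg)
  mean_auc <- numeric(n_cfg)
  for (r in seq_len(n_cfg)) {
    cfg_r <- .apply_grid_row(config, rows[r, , drop = FALSE])
    fc <- feat_cache[[as.character(cfg_r$double_mismatch_penalty)]]
    obj <- vapply(seq_along(sets), function(i) {
      .set_objective(fc[[i]], NULL, labels[[i]], cfg_r)
    }, numeric(2))
    mean_tnr[r] <- mean(obj["tnr", ])
    mean_auc[r] <- mean(obj["auc", ])
  }
  report <- cbind(rows, mean_tnr = mean_tnr, mean_auc = mean_auc)
  eps <- 1e-12
  best_tnr <- max(mean_tnr)
  cand <- which(mean_tnr >= best_tnr - eps)
  best_auc <- max(mean_auc[cand])
  cand <- cand[mean_auc[cand] >= best_auc - eps]
  best <- min(cand)
  list(config = .apply_grid_row(config, rows[best, , drop = FALSE]),
       report = report, best_index = best)
}
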