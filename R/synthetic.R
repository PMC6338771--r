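# Synthetic labeled primer-pair datasets and multiplex fixtures. Dimer-prone
# pairs carry a planted mutual 3'-complementary block (either spanning both
# 3' ends or anchored at a single 3' end with a 5' overhang, the two
# extensible artefact geometries seen in sequenced dimers); dimer-free pairs
# are rejection-sampled so no pairing shows 3'-anchored complementarity of
# four or more bases.

.rand_seq <- function(len, gc) {
  paste(sample(.BASES, len, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

.flip_base <- function(base) sample(setdiff(.BASES, base), 1L)

# longest complementary run anchored at the 3' terminus of `a` against any
# position of `b`
.end_run_one <- function(a, b) {
  la <- nchar(a)
  k <- 0L
  while (k < la) {
    probe <- reverse_complement(substr(a, la - k, la))
    if (!grepl(probe, b, fixed = TRUE)) break
    k <- k + 1L
  }
  k
}

# worst 3'-anchored complementarity over the three pairings of (f, r)
.max_end_complement <- function(f, r) {
  max(.end_run_one(f, r), .end_run_one(r, f),
      .end_run_one(f, f), .end_run_one(r, r))
}

# TRUE when some complementary run of >= k bases exists anywhere between a
# and b (any ungapped alignment, any position)
.has_complement_run <- function(a, b, k = 4L) {
  la <- nchar(a)
  if (la < k) return(FALSE)
  for (i in 1:(la - k + 1L)) {
    if (grepl(reverse_complement(substr(a, i, i + k - 1L)), b,
              fixed = TRUE)) {
      return(TRUE)
    }
  }
  FALSE
}

# worst-case complementarity over the three pairings, any position
.has_any_complement <- function(f, r, k = 4L) {
  .has_complement_run(f, r, k) || .has_complement_run(f, f, k) ||
    .has_complement_run(r, r, k)
}

#' Specification for a synthetic labeled dataset
#'
#' @param n_pairs number of primer pairs.
#' @param dimer_fraction fraction of pairs (exact count, rounded) that carry
#'   a planted dimer motif and the "dimer" label.
#' @param length_range primer length range, bases.
#' @param gc_range G+C fraction range for random sequence.
#' @param complement_range planted 3'-complementary block length range for
#'   dimer pairs.
#' @param mismatch_rate per-base probability of injecting a mismatch into
#'   the planted block.
#' @param label_noise probability of flipping each final label.
#' @param seed integer seed; generation is deterministic given the seed.
#' @param max_attempts rejection-sampling cap per pair before failing.
#' @param dimer_score_ceiling dimer-class pairs must score at or below this
#'   adjusted dimer score (the planted motif must actually be stable, as a
#'   gel-visible artefact would be).
#' @param free_score_floor dimer-free pairs must score at or above this
#'   adjusted score, leaving a margin between the two classes.
#' @return an object of class \code{sim_spec}.
#' @export
sim_spec <- function(n_pairs = 200, dimer_fraction = 0.3,
                     length_range = c(18, 24), gc_range = c(0.35, 0.65),
                     complement_range = c(8, 12), mismatch_rate = 0,
                     label_noise = 0, seed = 1, max_attempts = 10000,
                     dimer_score_ceiling = -5, free_score_floor = -4) {
  stopifnot(n_pairs >= 1, dimer_fraction >= 0, dimer_fraction <= 1,
            length_range[1] >= 8, length_range[2] >= length_range[1],
            gc_range[1] > 0, gc_range[2] < 1, gc_range[2] >= gc_range[1],
            complement_range[1] >= 2,
            complement_range[2] >= complement_range[1],
            mismatch_rate >= 0, mismatch_rate < 1,
            label_noise >= 0, label_noise <= 1, max_attempts >= 1,
            !(is.finite(dimer_score_ceiling) && is.finite(free_score_floor)) ||
              dimer_score_ceiling <= free_score_floor)
  structure(list(n_pairs = as.integer(n_pairs),
                 dimer_fraction = dimer_fraction,
                 length_range = as.integer(length_range),
                 gc_range = gc_range,
                 complement_range = as.integer(complement_range),
                 mismatch_rate = mismatch_rate, label_noise = label_noise,
                 seed = as.integer(seed),
                 max_attempts = as.integer(max_attempts),
                 dimer_score_ceiling = dimer_score_ceiling,
                 free_score_floor = free_score_floor),
            class = "sim_spec")
}

.sample_gc <- function(spec) stats::runif(1, spec$gc_range[1], spec$gc_range[2])
.sample_len <- function(spec) {
  sample(spec$length_range[1]:spec$length_range[2], 1L)
}

# one dimer-prone pair: plant a mutual 3'-complementary block and keep only
# pairs whose adjusted score confirms the motif is stable enough to show as
# a gel artefact
.make_dimer_pair <- function(spec, params, config) {
  for (i in seq_len(spec$max_attempts)) {
    motif <- sample(c("double", "single"), 1L)
    gc <- .sample_gc(spec)
    lf <- .sample_len(spec)
    lr <- .sample_len(spec)
    bl <- sample(spec$complement_range[1]:spec$complement_range[2], 1L)
    bl <- min(bl, lf - 2L, lr - 5L)
    fwd <- .rand_seq(lf, gc)
    block <- reverse_complement(substr(fwd, lf - bl + 1L, lf))
    if (spec$mismatch_rate > 0) {
      ch <- strsplit(block, "")[[1]]
      hit <- stats::runif(length(ch)) < spec$mismatch_rate
      for (j in which(hit)) ch[j] <- .flip_base(ch[j])
      block <- paste(ch, collapse = "")
    }
    if (motif == "double") {
      rev <- paste0(.rand_seq(lr - bl, gc), block)
    } else {
      tail_len <- sample(3:5, 1L)
      pre_len <- lr - bl - tail_len
      if (pre_len < 0L) { tail_len <- tail_len + pre_len; pre_len <- 0L }
      rev <- paste0(.rand_seq(pre_len, gc), block,
                    .rand_seq(max(tail_len, 0L), gc))
    }
    sc <- dimer_score_pair(primer_pair("cand", fwd, rev), params,
                           config)$adjusted_ds
    if (sc <= spec$dimer_score_ceiling) {
      return(list(forward = fwd, reverse = rev, motif = motif,
                  planted_len = bl))
    }
  }
  stop("rejection sampling failed after ", spec$max_attempts,
       " attempts; spec is infeasible (dimer class)", call. = FALSE)
}

# one dimer-free pair: no pairing shows a complementary run of 4+ bases at
# any position, and the adjusted score stays above the class floor
.make_free_pair <- function(spec, params, config) {
  for (i in seq_len(spec$max_attempts)) {
    gc <- .sample_gc(spec)
    fwd <- .rand_seq(.sample_len(spec), gc)
    rev <- .rand_seq(.sample_len(spec), gc)
    if (!.has_any_complement(fwd, rev, 4L)) {
      sc <- dimer_score_pair(primer_pair("cand", fwd, rev), params,
                             config)$adjusted_ds
      if (sc >= spec$free_score_floor) {
        return(list(forward = fwd, reverse = rev, motif = NA_character_,
                    planted_len = NA_integer_))
      }
    }
  }
  stop("rejection sampling failed after ", spec$max_attempts,
       " attempts; spec is infeasible (dimer-free class)", call. = FALSE)
}

#' Generate a labeled synthetic primer-pair dataset
#'
#' Emulates a gel-labeled primer set: the requested fraction of pairs carry
#' a planted mutual 3'-complementary block (the "dimer" class; motif
#' "double" spans both 3' ends, motif "single" anchors one 3' end against an
#' internal block with a 5' overhang); the remainder are rejection-sampled
#' to be free of 3'-anchored complementarity of 4+ bases across all three
#' pairings. Labels are then flipped at the specified noise rate. Output is
#' deterministic for a given spec.
#'
#' @param spec a \code{\link{sim_spec}}.
#' @param params \code{\link{thermo_params}} used for the class score guards.
#' @param config \code{\link{scoring_config}} used for the class score
#'   guards; datasets for calibration experiments are generated under the
#'   planted configuration.
#' @return a \code{pair_table} data frame with columns pair_id, forward,
#'   reverse, dimer_status, planted_motif, planted_len.
#' @export
generate_dataset <- function(spec, params = thermo_params(),
                             config = scoring_config()) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed)
  n_dimer <- round(spec$n_pairs * spec$dimer_fraction)
  make <- c(rep(TRUE, n_dimer), rep(FALSE, spec$n_pairs - n_dimer))
  make <- sample(make)  # interleave the classes
  rows <- lapply(seq_along(make), function(i) {
    p <- if (make[i]) .make_dimer_pair(spec, params, config) else
      .make_free_pair(spec, params, config)
    data.frame(pair_id = sprintf("sim_%04d", i),
               forward = p$forward, reverse = p$reverse,
               dimer_status = if (make[i]) "dimer" else "dimer_free",
               planted_motif = p$motif, planted_len = p$planted_len,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (spec$label_noise > 0) {
    flip <- stats::runif(nrow(out)) < spec$label_noise
    out$dimer_status[flip] <- ifelse(out$dimer_status[flip] == "dimer",
                                     "dimer_free", "dimer")
  }
  class(out) <- c("pair_table", "data.frame")
  out
}

#' Generate a labeled set for scoring-parameter recovery experiments
#'
#' Builds a primer-pair set whose labels are, by construction, perfectly
#' separated by the dimer score computed under a chosen ("planted")
#' configuration: pairs are scored under \code{planted_config} and labeled
#' dimer exactly when the score falls below a cutoff placed in the score gap
#' nearest the median. A grid search over candidate configurations can then
#' only reach a perfect objective at (or ordinally equivalent to) the
#' planted values. The set mixes three sensitive pair designs:
#' \itemize{
#'   \item full-span probes: an intact planted 3'-3' block, whose best
#'     structure carries the full-span G/C bonus;
#'   \item compound probes: a single-3'-end block with mismatches planted at
#'     positions 2 and 4 from the scored end, whose best structure incurs
#'     positional and compound end penalties;
#'   \item clean pairs with no complementary run of 4+ bases anywhere.
#' }
#' 3'-terminal self- and cross-pairing of the random portions is rejected so
#' the probe structures, not incidental micro-overlaps, decide each score.
#'
#' @param n_pairs number of pairs (split roughly equally across designs).
#' @param planted_config the \code{\link{scoring_config}} whose penalty and
#'   bonus values define the labels.
#' @param params a \code{\link{thermo_params}}.
#' @param seed integer seed.
#' @param guard_configs list of competitor \code{scoring_config}s the label
#'   cutoff must defeat: the cutoff is placed so that each of them
#'   misorders at least one pair (objective strictly below perfect). By
#'   default, single-axis perturbations of the planted bonus (+/- 1) and
#'   compound penalty (+/- 1.5); a pair's score is monotone in each penalty
#'   coefficient, so defeating the nearest perturbation defeats any larger
#'   one on the same side.
#' @return a \code{pair_table} with dimer_status labels; the cutoff used is
#'   attached as attribute \code{"cutoff"}.
#' @export
generate_calibration_set <- function(n_pairs = 150, planted_config,
                                     params = thermo_params(), seed = 1,
                                     guard_configs = NULL) {
  # whether an identifiable cutoff exists depends on where the probe scores
  # happen to fall; redraw (deterministically) until one does
  last_err <- NULL
  for (attempt in 0:9) {
    res <- tryCatch(
      .calibration_set_once(n_pairs, planted_config, params,
                            seed + attempt * 7919L, guard_configs),
      error = function(e) e)
    if (!inherits(res, "error")) return(res)
    last_err <- res
  }
  stop(conditionMessage(last_err), " (after 10 redraws)", call. = FALSE)
}

.calibration_set_once <- function(n_pairs, planted_config, params, seed,
                                  guard_configs) {
  set.seed(seed)
  rs <- function(n) paste(sample(.BASES, n, replace = TRUE), collapse = "")
  clean_ends <- function(f, r = NULL) {
    if (.has_complement_run(f, f, 4L) || .end_run_one(f, f) > 1L) {
      return(FALSE)
    }
    if (!is.null(r)) {
      if (.has_complement_run(r, r, 4L) || .end_run_one(r, r) > 1L ||
          .end_run_one(r, f) > 1L) {
        return(FALSE)
      }
    }
    TRUE
  }
  make_span <- function() {
    repeat {
      lf <- sample(18:24, 1L)
      bl <- sample(4:8, 1L)
      f <- rs(lf)
      if (!clean_ends(f)) next
      block <- reverse_complement(substr(f, lf - bl + 1L, lf))
      r <- paste0(rs(sample(18:24, 1L) - bl), block)
      if (.has_complement_run(substr(r, 1, nchar(r) - bl), r, 4L)) next
      return(c(f, r))
    }
  }
  make_compound <- function() {
    repeat {
      lf <- sample(18:24, 1L)
      bl <- 10L
      f <- rs(lf)
      if (!clean_ends(f)) next
      block <- strsplit(reverse_complement(substr(f, lf - bl + 1L, lf)),
                        "")[[1]]
      for (j in c(2L, 4L)) block[j] <- .flip_base(block[j])
      r <- paste0(rs(8L), paste(block, collapse = ""), rs(3L))
      if (!clean_ends(f, r)) next
      return(c(f, r))
    }
  }
  make_clean <- function() {
    repeat {
      f <- rs(sample(18:24, 1L))
      r <- rs(sample(18:24, 1L))
      if (!.has_any_complement(f, r, 4L)) return(c(f, r))
    }
  }
  kinds <- rep(c("span", "compound", "compound", "clean"),
               length.out = n_pairs)
  rows <- lapply(seq_len(n_pairs), function(i) {
    sq <- switch(kinds[i], span = make_span(), compound = make_compound(),
                 clean = make_clean())
    data.frame(pair_id = sprintf("cal_%04d", i), forward = sq[1],
               reverse = sq[2], kind = kinds[i], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(guard_configs)) {
    perturb <- function(field, delta) {
      cfg <- planted_config
      cfg[[field]] <- cfg[[field]] + delta
      cfg
    }
    guard_configs <- list(perturb("gc_full_span_bonus", 1),
                          perturb("gc_full_span_bonus", -1),
                          perturb("compound_end_penalty", 1.5),
                          perturb("compound_end_penalty", -1.5))
  }
  feats <- lapply(seq_len(nrow(out)), function(i) {
    .pair_feature_set(primer_pair(out$pair_id[i], out$forward[i],
                                  out$reverse[i]), params, planted_config)
  })
  score_under <- function(cfg) {
    vapply(feats, function(fm) {
      scv <- .combine_features(fm$features, cfg)
      j <- which.min(scv)
      ds1 <- scv[j] / cfg$length_norm_divisor * fm$lensum[j]
      (ds1 + ds1 * fm$gcavg[j] * cfg$gc_coefficient) / cfg$final_divisor
    }, numeric(1))
  }
  sc <- score_under(planted_config)
  guard_scores <- lapply(guard_configs, score_under)
  o <- sort(unique(sc))
  gaps <- which(diff(o) > 1e-9)
  centers <- (o[gaps] + o[gaps + 1]) / 2
  centers <- centers[order(abs(centers - stats::median(sc)))]
  # place the cutoff so that every guard configuration misorders at least
  # one pair relative to the labels (its dimer-free TNR or AUC falls below
  # the planted configuration's perfect 1.0)
  breaks_all <- function(ctr) {
    labels <- ifelse(sc < ctr, "dimer", "dimer_free")
    if (length(unique(labels)) < 2L) return(FALSE)
    all(vapply(guard_scores, function(gsc) {
      thr <- dimer_free_threshold(gsc, labels)
      if (thr$tnr < 1) return(TRUE)
      build_roc(gsc, labels)$auc < 1 - 1e-12
    }, logical(1)))
  }
  cutoff <- NA_real_
  for (ctr in centers) {
    if (breaks_all(ctr)) { cutoff <- ctr; break }
  }
  if (is.na(cutoff)) {
    stop("could not place an identifiable label cutoff; increase n_pairs",
         call. = FALSE)
  }
  out$dimer_status <- ifelse(sc < cutoff, "dimer", "dimer_free")
  attr(out, "cutoff") <- cutoff
  class(out) <- c("pair_table", "data.frame")
  out
}

#' Generate a multiplex fixture of candidate regions
#'
#' \code{orthogonality = "full"} rejection-samples every candidate pair so
#' that all of its interactions (its own three pairings, its region mates,
#' and every primer generated before it) score above the dimer-free cutoff
#' plus a safety margin - the fixture is orthogonal by construction, for any
#' seed. \code{orthogonality = "adversarial"} makes the final region's sole
#' candidate strongly complementary to the first region's forward primer, so
#' pool construction must drop it.
#'
#' @param n_regions number of regions.
#' @param candidates_per_region candidates per region.
#' @param orthogonality "full" or "adversarial".
#' @param seed integer seed.
#' @param params a \code{\link{thermo_params}}.
#' @param config a \code{\link{scoring_config}}.
#' @param threshold dimer-free cutoff the fixture is built against.
#' @param margin safety margin above the cutoff for "full" orthogonality.
#' @return list of \code{\link{region}} objects.
#' @export
generate_multiplex_fixture <- function(n_regions, candidates_per_region = 3,
                                       orthogonality = c("full",
                                                         "adversarial"),
                                       seed = 1,
                                       params = thermo_params(),
                                       config = scoring_config(),
                                       threshold = -4.43, margin = 0.5) {
  orthogonality <- match.arg(orthogonality)
  if (n_regions == 0L) return(list())
  set.seed(seed)
  spec <- sim_spec(n_pairs = 1, seed = seed)  # reuse length/GC defaults
  floor_score <- threshold + margin
  all_oligos <- character(0)
  regions <- vector("list", n_regions)
  for (r in seq_len(n_regions)) {
    cands <- vector("list", candidates_per_region)
    for (cix in seq_len(candidates_per_region)) {
      adversary <- orthogonality == "adversarial" &&
        r == n_regions && cix == candidates_per_region && r > 1L
      if (adversary) {
        target <- regions[[1]]$candidates[[1]]$forward
        lt <- nchar(target)
        block <- reverse_complement(substr(target, lt - 9L, lt))
        gc <- .sample_gc(spec)
        fwd <- paste0(.rand_seq(10, gc), block)
        rev <- .rand_seq(.sample_len(spec), gc)
        cands[[cix]] <- primer_pair(sprintf("R%02d_c%d", r, cix), fwd, rev)
        next
      }
      found <- FALSE
      for (att in seq_len(spec$max_attempts)) {
        gc <- .sample_gc(spec)
        fwd <- .rand_seq(.sample_len(spec), gc)
        rev <- .rand_seq(.sample_len(spec), gc)
        if (.max_end_complement(fwd, rev) > 3L) next
        prior <- c(all_oligos,
                   unlist(lapply(cands[seq_len(cix - 1L)], function(p) {
                     c(p$forward, p$reverse)
                   })))
        # a loose pre-filter against the accumulated oligos (anchored runs
        # of 5+); the dimer-score check below is the binding criterion, and
        # a stricter run cap here becomes unsatisfiable as the pool grows
        if (length(prior) > 0L &&
            any(vapply(prior, function(o) {
              max(.end_run_one(fwd, o), .end_run_one(o, fwd),
                  .end_run_one(rev, o), .end_run_one(o, rev)) > 4L
            }, logical(1)))) next
        cand <- primer_pair(sprintf("R%02d_c%d", r, cix), fwd, rev)
        sc <- cross_pool_min_score(cand, prior, params, config)
        if (sc >= floor_score) {
          cands[[cix]] <- cand
          found <- TRUE
          break
        }
      }
      if (!found) {
        stop("could not generate an orthogonal candidate for region ", r,
             " after ", spec$max_attempts, " attempts", call. = FALSE)
      }
    }
    regions[[r]] <- region(sprintf("R%02d", r), cands)
    all_oligos <- c(all_oligos,
                    unlist(lapply(cands, function(p) c(p$forward, p$reverse))))
  }
  regions
}
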