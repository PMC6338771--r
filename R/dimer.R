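# Dimer scoring: alignment enumeration over all sliding offsets, the
# 3'-anchored prefix-minimum base value, positional penalties/bonuses, and
# the length/GC adjustment.

#' Scoring configuration
#'
#' Holds every bonus, penalty and adjustment constant of the dimer scorer.
#' Penalties use the destabilising (non-negative) convention and the
#' full-span G/C bonus the stabilising (non-positive) one. The length/GC
#' adjustment constants 20, 2.25 and 4.4 follow the published adjustment
#' pseudocode; the positional penalty magnitudes default to values
#' re-derivable with \code{\link{grid_search}}.
#'
#' @param sentinel_start starting dimer score before any structure is seen
#'   (an arbitrary value greater than the maximum meaningful score of 0).
#' @param min_overlap smallest overlap worth scoring, bases (>= 2; one
#'   nearest-neighbour step is the smallest scoreable structure).
#' @param three_prime_window how many overlap positions from the 3' end
#'   attract per-position mismatch penalties.
#' @param three_prime_mismatch_penalties penalty (score units) per mismatch
#'   at positions 1..window from the scored 3' end.
#' @param compound_end_penalty extra penalty when position 1 or 2 is a
#'   mismatch and at least one more mismatch lies within the first 5.
#' @param double_mismatch_penalty per-step value for doubly mismatched
#'   nearest-neighbour steps, kcal/mol-equivalent.
#' @param gc_full_span_bonus bonus (<= 0) for a perfectly matched structure
#'   spanning both 3' ends whose scored terminal base is C or G.
#' @param length_norm_divisor,gc_coefficient,final_divisor length/GC
#'   adjustment constants.
#' @param use_length_gc_adjustment apply the length/GC adjustment to the
#'   returned score.
#' @param use_overhangs add 5' dangling-end free energies.
#' @return an object of class \code{scoring_config}.
#' @export
scoring_config <- function(sentinel_start = 100,
                           min_overlap = 2,
                           three_prime_window = 5,
                           three_prime_mismatch_penalties = c(3, 3, 2, 1, 1),
                           compound_end_penalty = 2,
                           double_mismatch_penalty = 1,
                           gc_full_span_bonus = -1,
                           length_norm_divisor = 20,
                           gc_coefficient = 2.25,
                           final_divisor = 4.4,
                           use_length_gc_adjustment = TRUE,
                           use_overhangs = TRUE) {
  cfg <- list(sentinel_start = sentinel_start,
              min_overlap = as.integer(min_overlap),
              three_prime_window = as.integer(three_prime_window),
              three_prime_mismatch_penalties = three_prime_mismatch_penalties,
              compound_end_penalty = compound_end_penalty,
              double_mismatch_penalty = double_mismatch_penalty,
              gc_full_span_bonus = gc_full_span_bonus,
              length_norm_divisor = length_norm_divisor,
              gc_coefficient = gc_coefficient,
              final_divisor = final_divisor,
              use_length_gc_adjustment = isTRUE(use_length_gc_adjustment),
              use_overhangs = isTRUE(use_overhangs))
  if (cfg$min_overlap < 2L) stop("min_overlap must be >= 2", call. = FALSE)
  if (cfg$three_prime_window < 2L) {
    stop("three_prime_window must be >= 2", call. = FALSE)
  }
  if (length(cfg$three_prime_mismatch_penalties) != cfg$three_prime_window) {
    stop("need one positional penalty per window position", call. = FALSE)
  }
  if (any(cfg$three_prime_mismatch_penalties < 0) ||
      cfg$compound_end_penalty < 0 || cfg$double_mismatch_penalty < 0) {
    stop("penalties must be >= 0 (destabilising convention)", call. = FALSE)
  }
  if (cfg$gc_full_span_bonus > 0) {
    stop("gc_full_span_bonus must be <= 0 (stabilising convention)",
         call. = FALSE)
  }
  if (cfg$length_norm_divisor <= 0 || cfg$final_divisor <= 0) {
    stop("divisors must be > 0", call. = FALSE)
  }
  structure(cfg, class = "scoring_config")
}

#' @export
print.scoring_config <- function(x, ...) {
  cat("Dimer scoring configuration\n")
  for (k in names(x)) {
    cat(sprintf("  %-32s %s\n", k, paste(format(x[[k]]), collapse = " ")))
  }
  invisible(x)
}

#' A primer pair with an optional empirical dimer label
#'
#' @param pair_id identifier string.
#' @param forward,reverse primer sequences, 5'->3'.
#' @param label one of "dimer", "dimer_free", "ambiguous", "unlabeled";
#'   typically the gel-electrophoresis call for the pair.
#' @return an object of class \code{primer_pair}.
#' @export
primer_pair <- function(pair_id, forward, reverse, label = "unlabeled") {
  label <- match.arg(label, c("dimer", "dimer_free", "ambiguous", "unlabeled"))
  structure(list(pair_id = as.character(pair_id),
                 forward = validate_sequence(forward, "forward primer"),
                 reverse = validate_sequence(reverse, "reverse primer"),
                 label = label),
            class = "primer_pair")
}

# Build one alignment at a given offset. top is 5'->3'; bchars is the
# shorter oligo reversed to 3'->5'. Offset k places bottom position j over
# top position k + j.
.make_structure <- function(tchars, bchars, k, comp_t) {
  lt <- length(tchars)
  lb <- length(bchars)
  n <- min(lb, lt - k)
  idx <- (k + 1L):(k + n)
  states <- comp_t[idx] == bchars[seq_len(n)]
  structure(list(
    top = paste(tchars, collapse = ""),
    bottom = paste(bchars, collapse = ""),
    offset = k,
    overlap_start = k + 1L,
    overlap_len = n,
    states = unname(states),
    left_dangle = if (k >= 1L) tchars[k] else NA_character_,
    right_dangle = if (k + lb > lt) bchars[n + 1L] else NA_character_,
    spans_both = (k + lb >= lt)
  ), class = "dimer_structure")
}

#' Enumerate all sliding dimer alignments of two oligos
#'
#' The longer oligo is the "top" (ties: the first argument); the shorter is
#' the "bottom" and is reversed into 3'->5' orientation. The bottom's 3' end
#' starts paired to the top's 5' end (a single 3' overhang unless lengths are
#' equal) and slides rightwards, producing every structure with 5' overhangs
#' down to an overlap of \code{config$min_overlap} bases. The bottom's 3'
#' terminal base is paired in every structure; only extensible geometries are
#' enumerated.
#'
#' @param seq_a,seq_b oligo sequences, 5'->3'.
#' @param config a \code{\link{scoring_config}}.
#' @return list of \code{dimer_structure} objects, ordered by offset.
#' @export
enumerate_alignments <- function(seq_a, seq_b, config = scoring_config()) {
  a <- validate_sequence(seq_a, "first oligo")
  b <- validate_sequence(seq_b, "second oligo")
  if (nchar(a) < config$min_overlap || nchar(b) < config$min_overlap) {
    stop("degenerate input: oligo shorter than min_overlap", call. = FALSE)
  }
  if (nchar(b) > nchar(a)) { tmp <- a; a <- b; b <- tmp }
  tchars <- strsplit(a, "")[[1]]
  bchars <- rev(strsplit(b, "")[[1]])
  comp_t <- unname(.COMP[tchars])
  lapply(0:(length(tchars) - config$min_overlap), function(k) {
    .make_structure(tchars, bchars, k, comp_t)
  })
}

#' @export
print.dimer_structure <- function(x, ...) {
  cat(render_structure(x), sep = "\n")
  invisible(x)
}

#' Render a dimer structure as alignment text
#'
#' Three lines: top strand 5'->3', pairing marks (| match, . mismatch),
#' bottom strand 3'->5'. Coordinates in downstream reports are 1-based and
#' inclusive.
#'
#' @param structure a \code{dimer_structure}.
#' @return character vector of three lines.
#' @export
render_structure <- function(structure) {
  s <- structure
  marks <- paste(ifelse(s$states, "|", "."), collapse = "")
  c(paste0("   5'-", s$top, "-3'"),
    paste0("      ", strrep(" ", s$offset), marks),
    paste0("   ", strrep(" ", s$offset), "3'-", s$bottom, "-5'"))
}

# Compute the score and its decomposition for one structure.
# Returns a named numeric vector: base, mm1..mmW, compound, overhang,
# fullspan, total_dg, score.
.structure_features <- function(s, params, config) {
  n <- s$overlap_len
  if (n < 2L) stop("degenerate structure: overlap < 2", call. = FALSE)
  tchars <- strsplit(s$top, "")[[1]]
  bchars <- strsplit(s$bottom, "")[[1]]
  idx <- s$overlap_start:(s$overlap_start + n - 1L)
  tw <- tchars[idx]
  bw <- bchars[seq_len(n)]
  dgs <- .step_dgs(tw, bw, params, config$double_mismatch_penalty)
  csL <- cumsum(dgs)
  csR <- cumsum(rev(dgs))
  minL <- min(csL)
  minR <- min(csR)
  # scan inward from each 3'-terminal overlap position independently; the
  # more negative prefix minimum wins (ties: the bottom's 3' end, i.e. left)
  from_left <- minL <= minR
  base <- min(minL, minR)

  w <- config$three_prime_window
  k <- min(w, n)
  ord <- if (from_left) seq_len(k) else n - seq_len(k) + 1L
  mm <- numeric(w)
  mm[seq_len(k)] <- as.numeric(!s$states[ord])
  k5 <- min(5L, n)
  ord5 <- if (from_left) seq_len(k5) else n - seq_len(k5) + 1L
  mm5 <- !s$states[ord5]
  compound <- as.numeric((mm5[1] || (k5 >= 2 && mm5[2])) && sum(mm5) >= 2)

  overhang <- 0
  if (!is.na(s$left_dangle) && s$states[1]) {
    overhang <- overhang + params$dangling[[paste0(s$left_dangle, tw[1])]]
  }
  if (!is.na(s$right_dangle) && s$states[n]) {
    overhang <- overhang + params$dangling[[paste0(s$right_dangle, bw[n])]]
  }

  term_base <- if (from_left) bw[1] else tw[n]
  fullspan <- as.numeric(s$spans_both && all(s$states) &&
                           term_base %in% c("C", "G"))

  feats <- c(base = base, stats::setNames(mm, paste0("mm", seq_len(w))),
             compound = compound, overhang = overhang, fullspan = fullspan,
             total_dg = sum(dgs))
  feats["score"] <- .combine_features(feats, config)
  feats
}

# assemble a score from a feature decomposition under a config (vectorised
# over rows when given a matrix)
.combine_features <- function(feats, config) {
  w <- config$three_prime_window
  if (is.matrix(feats)) {
    mm <- feats[, paste0("mm", seq_len(w)), drop = FALSE]
    feats[, "base"] +
      as.vector(mm %*% config$three_prime_mismatch_penalties) +
      feats[, "compound"] * config$compound_end_penalty +
      (if (config$use_overhangs) feats[, "overhang"] else 0) +
      feats[, "fullspan"] * config$gc_full_span_bonus
  } else {
    feats[["base"]] +
      sum(feats[paste0("mm", seq_len(w))] *
            config$three_prime_mismatch_penalties) +
      feats[["compound"]] * config$compound_end_penalty +
      (if (config$use_overhangs) feats[["overhang"]] else 0) +
      feats[["fullspan"]] * config$gc_full_span_bonus
  }
}

#' Score one dimer structure
#'
#' The base value is the minimum running prefix sum of nearest-neighbour step
#' free energies scanned inward from each of the two 3'-terminal overlap
#' positions (the more negative of the two scans). To it are added, in order:
#' per-position penalties for mismatches within the 3' window, the compound
#' end penalty, 5' dangling-end free energies for overhangs adjacent to a
#' terminal matched pair, and the full-span G/C bonus.
#'
#' @param structure a \code{dimer_structure} from
#'   \code{\link{enumerate_alignments}}.
#' @param params a \code{\link{thermo_params}}.
#' @param config a \code{\link{scoring_config}}.
#' @return the structure's score (kcal/mol-comparable score units).
#' @export
score_structure <- function(structure, params, config = scoring_config()) {
  unname(.structure_features(structure, params, config)["score"])
}

# all structures of one oligo-oligo pairing -> feature matrix (+ structures)
.pairing_features <- function(seq_a, seq_b, params, config,
                              keep_structures = FALSE) {
  structs <- enumerate_alignments(seq_a, seq_b, config)
  feats <- t(vapply(structs, .structure_features,
                    numeric(config$three_prime_window + 6L),
                    params = params, config = config))
  list(features = feats, structures = if (keep_structures) structs else NULL)
}

# min raw score of one pairing
.pairing_min <- function(seq_a, seq_b, params, config) {
  pf <- .pairing_features(seq_a, seq_b, params, config,
                          keep_structures = TRUE)
  i <- which.min(pf$features[, "score"])
  list(raw = pf$features[i, "score"], structure = pf$structures[[i]])
}

#' Length/GC adjustment of a dimer score
#'
#' Normalises a raw score for the combined primer length and average G+C
#' fraction, then rescales to remain comparable to a free energy:
#' \code{ds/20 * (len_top + len_bottom)}, then \code{+ ds * gc_avg * 2.25},
#' then \code{/ 4.4}. \code{gc_avg} is the mean of the two primers' G+C
#' proportions.
#'
#' @param ds raw dimer score.
#' @param top,bottom the two primer sequences involved.
#' @param config a \code{\link{scoring_config}} (supplies the constants).
#' @return adjusted dimer score.
#' @export
adjust_length_gc <- function(ds, top, bottom, config = scoring_config()) {
  top <- validate_sequence(top, "top primer")
  bottom <- validate_sequence(bottom, "bottom primer")
  gc_avg <- (.gc_fraction(top) + .gc_fraction(bottom)) / 2
  ds1 <- ds / config$length_norm_divisor * (nchar(top) + nchar(bottom))
  ds2 <- ds1 + ds1 * gc_avg * config$gc_coefficient
  ds2 / config$final_divisor
}

#' Dimer score of a primer pair
#'
#' Evaluates the three possible primer-primer pairings (forward-reverse
#' hetero plus the two homodimers), scoring every sliding alignment of each,
#' and returns the most negative value found, starting from the sentinel.
#' The length/GC adjustment, when enabled, is applied to the best raw score
#' using the best structure's two primers.
#'
#' @param pair a \code{\link{primer_pair}}.
#' @param params a \code{\link{thermo_params}}.
#' @param config a \code{\link{scoring_config}}.
#' @return an object of class \code{scored_pair} with elements \code{pair},
#'   \code{raw_ds}, \code{adjusted_ds}, \code{best_structure},
#'   \code{best_pairing} ("FR", "FF" or "RR").
#' @export
dimer_score_pair <- function(pair, params, config = scoring_config()) {
  stopifnot(inherits(pair, "primer_pair"))
  pairings <- list(FR = c(pair$forward, pair$reverse),
                   FF = c(pair$forward, pair$forward),
                   RR = c(pair$reverse, pair$reverse))
  raw <- config$sentinel_start
  best_structure <- NULL
  best_pairing <- NA_character_
  best_seqs <- NULL
  for (nm in names(pairings)) {
    sq <- pairings[[nm]]
    if (nchar(sq[1]) < config$min_overlap || nchar(sq[2]) < config$min_overlap) {
      next
    }
    pm <- .pairing_min(sq[1], sq[2], params, config)
    if (pm$raw < raw) {
      raw <- pm$raw
      best_structure <- pm$structure
      best_pairing <- nm
      best_seqs <- sq
    }
  }
  adjusted <- if (is.null(best_structure)) {
    raw  # no scoreable structure: sentinel, no adjustment
  } else if (config$use_length_gc_adjustment) {
    adjust_length_gc(raw, best_seqs[1], best_seqs[2], config)
  } else {
    raw
  }
  structure(list(pair = pair, raw_ds = unname(raw),
                 adjusted_ds = unname(adjusted),
                 best_structure = best_structure,
                 best_pairing = best_pairing),
            class = "scored_pair")
}

#' @export
print.scored_pair <- function(x, ...) {
  cat(sprintf("Primer pair %s: raw dS = %.3f, adjusted dS = %.3f (%s)\n",
              x$pair$pair_id, x$raw_ds, x$adjusted_ds, x$best_pairing))
  if (!is.null(x$best_structure)) print(x$best_structure)
  invisible(x)
}

# adjusted score of a single oligo-oligo pairing (used by the multiplex
# builder, where cross interactions are between arbitrary pool oligos)
.oligo_pairing_score <- function(seq_a, seq_b, params, config) {
  pm <- .pairing_min(seq_a, seq_b, params, config)
  if (config$use_length_gc_adjustment) {
    a <- toupper(seq_a); b <- toupper(seq_b)
    top <- if (nchar(b) > nchar(a)) b else a
    bot <- if (nchar(b) > nchar(a)) a else b
    adjust_length_gc(pm$raw, top, bot, config)
  } else {
    pm$raw
  }
}
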