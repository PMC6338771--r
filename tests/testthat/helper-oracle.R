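# Independent brute-force re-implementation of the dimer scorer, written
# with explicit loops and its own table handling, used only as a test
# oracle. It re-reads the shipped parameter files directly.

oracle_tables <- local({
  ext <- function(f) system.file("extdata", f, package = "oligodimer",
                                 mustWork = TRUE)
  match_tab <- read.delim(ext("nn_match.tsv"), stringsAsFactors = FALSE)
  mm_tab <- read.delim(ext("nn_mismatch.tsv"), stringsAsFactors = FALSE)
  dang_tab <- read.delim(ext("nn_dangling5.tsv"), stringsAsFactors = FALSE)
  list(match = setNames(match_tab$dg37, match_tab$step),
       match_dh = setNames(match_tab$dh, match_tab$step),
       match_ds = setNames(match_tab$ds, match_tab$step),
       mism = setNames(mm_tab$dg37, mm_tab$step),
       dang = setNames(dang_tab$dg37, dang_tab$context))
})

oracle_comp <- function(b) {
  switch(b, A = "T", T = "A", C = "G", G = "C")
}

oracle_rev <- function(x) paste(rev(strsplit(x, "")[[1]]), collapse = "")

# one nearest-neighbour step, read straight off the tables
oracle_step <- function(t1, t2, b1, b2, dbl_penalty) {
  m1 <- oracle_comp(t1) == b1
  m2 <- oracle_comp(t2) == b2
  key <- paste0(t1, t2, "/", b1, b2)
  if (m1 && m2) return(unname(oracle_tables$match[key]))
  if (!m1 && !m2) return(dbl_penalty)
  v <- oracle_tables$mism[key]
  if (is.na(v)) {
    v <- oracle_tables$mism[paste0(b2, b1, "/", t2, t1)]
  }
  if (is.na(v)) v <- 0
  unname(v)
}

# score every alignment of one oligo-oligo pairing; returns min raw score
oracle_pairing_min <- function(seq_a, seq_b, cfg) {
  a <- toupper(seq_a); b <- toupper(seq_b)
  if (nchar(b) > nchar(a)) { tmp <- a; a <- b; b <- tmp }
  top <- strsplit(a, "")[[1]]
  bot <- strsplit(oracle_rev(b), "")[[1]]
  nt <- length(top); nb <- length(bot)
  pen <- cfg$three_prime_mismatch_penalties
  w <- cfg$three_prime_window
  best <- Inf
  for (k in 0:(nt - cfg$min_overlap)) {
    n <- min(nb, nt - k)
    tw <- top[(k + 1):(k + n)]
    bw <- bot[1:n]
    st <- logical(n)
    for (i in 1:n) st[i] <- oracle_comp(tw[i]) == bw[i]
    dg <- numeric(n - 1)
    for (i in 1:(n - 1)) {
      dg[i] <- oracle_step(tw[i], tw[i + 1], bw[i], bw[i + 1],
                           cfg$double_mismatch_penalty)
    }
    # prefix scans from each 3'-terminal end of the overlap
    minL <- min(cumsum(dg))
    minR <- min(cumsum(rev(dg)))
    from_left <- minL <= minR
    base <- min(minL, minR)
    mm01 <- numeric(w)
    for (p in 1:min(w, n)) {
      pos <- if (from_left) p else n - p + 1
      mm01[p] <- as.numeric(!st[pos])
    }
    nmm5 <- 0; mm1 <- FALSE; mm2 <- FALSE
    for (p in 1:min(5, n)) {
      pos <- if (from_left) p else n - p + 1
      if (!st[pos]) {
        nmm5 <- nmm5 + 1
        if (p == 1) mm1 <- TRUE
        if (p == 2) mm2 <- TRUE
      }
    }
    compound <- as.numeric((mm1 || mm2) && nmm5 >= 2)
    ov <- 0
    if (k >= 1 && st[1]) {
      ov <- ov + oracle_tables$dang[[paste0(top[k], tw[1])]]
    }
    if (k + nb > nt && st[n]) {
      ov <- ov + oracle_tables$dang[[paste0(bot[n + 1], bw[n])]]
    }
    fullspan <- 0
    if (k + nb >= nt && all(st)) {
      term <- if (from_left) bw[1] else tw[n]
      if (term == "C" || term == "G") fullspan <- 1
    }
    score <- base + sum(mm01 * pen) + compound * cfg$compound_end_penalty +
      (if (cfg$use_overhangs) ov else 0) + fullspan * cfg$gc_full_span_bonus
    if (score < best) best <- score
  }
  best
}

oracle_adjust <- function(ds, a, b, cfg) {
  gcfrac <- function(x) {
    ch <- strsplit(toupper(x), "")[[1]]
    sum(ch == "G" | ch == "C") / length(ch)
  }
  ds1 <- ds / cfg$length_norm_divisor * (nchar(a) + nchar(b))
  ds2 <- ds1 + ds1 * (gcfrac(a) + gcfrac(b)) / 2 * cfg$gc_coefficient
  ds2 / cfg$final_divisor
}

# full pair score: three pairings, sentinel start, optional adjustment
oracle_score_pair <- function(fwd, rev, cfg) {
  raw <- cfg$sentinel_start
  best_seqs <- NULL
  for (pr in list(c(fwd, rev), c(fwd, fwd), c(rev, rev))) {
    if (nchar(pr[1]) < cfg$min_overlap || nchar(pr[2]) < cfg$min_overlap) next
    v <- oracle_pairing_min(pr[1], pr[2], cfg)
    if (v < raw) { raw <- v; best_seqs <- pr }
  }
  adj <- if (is.null(best_seqs) || !cfg$use_length_gc_adjustment) {
    raw
  } else {
    oracle_adjust(raw, best_seqs[1], best_seqs[2], cfg)
  }
  list(raw = raw, adjusted = adj)
}

# direct tie-corrected Mann-Whitney AUC: mean over all (pos, neg) pairs of
# 1[neg score > pos score] + 0.5 * 1[equal]  (more negative = more
# dimer-prone, so a correctly ordered pair has the negative above)
oracle_mw_auc <- function(scores, labels) {
  pos <- scores[labels == "dimer"]
  neg <- scores[labels == "dimer_free"]
  tot <- 0
  for (p in pos) {
    for (q in neg) {
      tot <- tot + (q > p) + 0.5 * (q == p)
    }
  }
  tot / (length(pos) * length(neg))
}

# direct-counting dimer-free threshold
oracle_threshold <- function(scores, labels) {
  pos <- scores[labels == "dimer"]
  neg <- scores[labels == "dimer_free"]
  s_max <- max(pos)
  above <- scores[scores > s_max]
  if (length(above) == 0) return(list(threshold = NA_real_, tnr = 0))
  thr <- min(above)
  list(threshold = thr, tnr = sum(neg >= thr) / length(neg))
}

.sym_key_for_test <- function(key) {
  paste0(oracle_rev(substr(key, 4, 5)), "/", oracle_rev(substr(key, 1, 2)))
}

random_primer <- function(len, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}
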