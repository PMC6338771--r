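test_that("alignment enumeration produces every sliding offset", {
  a <- random_primer(20)
  b <- random_primer(20)
  st <- enumerate_alignments(a, b, CONFIG)
  expect_length(st, 19)  # overlaps 20 down to min_overlap = 2
  expect_equal(vapply(st, `[[`, integer(1), "offset"), 0:18)
  # equal lengths at offset 0: full overlap, spans both 3' ends, no overhang
  expect_true(st[[1]]$spans_both)
  expect_true(is.na(st[[1]]$left_dangle) && is.na(st[[1]]$right_dangle))

  st2 <- enumerate_alignments(random_primer(20), random_primer(18), CONFIG)
  expect_length(st2, 19)
  # offset 0 with a shorter bottom: single 3' overhang of the top, so the
  # structure does not span the top's 3' end and has no 5' overhang
  expect_false(st2[[1]]$spans_both)
  expect_true(is.na(st2[[1]]$left_dangle) && is.na(st2[[1]]$right_dangle))
  # last offset: maximal 5' overhangs on both sides
  expect_false(is.na(st2[[19]]$left_dangle))
  expect_false(is.na(st2[[19]]$right_dangle))

  expect_error(enumerate_alignments("A", "ACGT", CONFIG), "degenerate")
})

test_that("length/GC adjustment matches the printed pseudocode arithmetic", {
  expect_equal(adjust_length_gc(0, "ATATATATAT", "TATATATATA", CONFIG), 0)
  # -4.4, two 10-mers, zero GC: length factor 1, GC term 0, /4.4 -> -1
  expect_equal(adjust_length_gc(-4.4, "ATATATATAT", "TATATATATA", CONFIG),
               -1.0)
  # -4.4, two 20-mers at 50% GC: -8.8 + (-8.8 * 0.5 * 2.25) = -18.7; /4.4
  expect_equal(adjust_length_gc(-4.4, strrep("AC", 10), strrep("GT", 10),
                                CONFIG), -18.7 / 4.4)
  # adjustment is linear in the score
  set.seed(11)
  for (i in 1:10) {
    a <- random_primer(sample(15:25, 1))
    b <- random_primer(sample(15:25, 1))
    ds <- runif(1, -20, 0)
    k <- runif(1, 0.1, 5)
    expect_equal(adjust_length_gc(k * ds, a, b, CONFIG),
                 k * adjust_length_gc(ds, a, b, CONFIG), tolerance = 1e-12)
  }
})

test_that("a single-step structure scores its step dG plus overhang terms", {
  # 21-mer vs 20-mer at the last offset: overlap of exactly 2 with a 5'
  # overhang on each side
  a <- random_primer(21)
  b <- random_primer(20)
  st <- enumerate_alignments(a, b, CONFIG)
  last <- st[[length(st)]]
  expect_equal(last$overlap_len, 2L)
  sc <- score_structure(last, PARAMS, CONFIG)
  expect_true(is.finite(sc))
  # disabling overhangs changes the score only by the dangling terms
  cfg2 <- scoring_config(use_overhangs = FALSE)
  sc2 <- score_structure(last, PARAMS, cfg2)
  tch <- strsplit(last$top, "")[[1]]
  bch <- strsplit(last$bottom, "")[[1]]
  n0 <- last$overlap_start
  dang <- 0
  if (last$states[1]) {
    dang <- dang + oracle_tables$dang[[paste0(tch[n0 - 1], tch[n0])]]
  }
  if (last$states[2]) {
    dang <- dang + oracle_tables$dang[[paste0(bch[3], bch[2])]]
  }
  expect_equal(sc - sc2, dang)
})

test_that("pair scoring matches the exhaustive brute-force oracle", {
  set.seed(101)
  n_checked <- 0
  for (i in 1:150) {
    f <- random_primer(sample(4:10, 1), gc = runif(1, 0.25, 0.75))
    r <- random_primer(sample(4:10, 1), gc = runif(1, 0.25, 0.75))
    got <- dimer_score_pair(primer_pair("x", f, r), PARAMS, CONFIG)
    want <- oracle_score_pair(f, r, CONFIG)
    expect_identical(got$raw_ds, want$raw)
    expect_identical(got$adjusted_ds, want$adjusted)
    n_checked <- n_checked + 1
  }
  expect_equal(n_checked, 150)
})

test_that("oracle agreement holds under a non-default configuration", {
  cfg <- scoring_config(three_prime_mismatch_penalties = c(4, 2, 2, 0.5, 0.5),
                        compound_end_penalty = 3.5,
                        double_mismatch_penalty = 0.7,
                        gc_full_span_bonus = -2,
                        use_overhangs = TRUE)
  set.seed(202)
  for (i in 1:60) {
    f <- random_primer(sample(4:10, 1))
    r <- random_primer(sample(4:10, 1))
    got <- dimer_score_pair(primer_pair("x", f, r), PARAMS, cfg)
    expect_identical(got$raw_ds, oracle_score_pair(f, r, cfg)$raw)
  }
})

test_that("a perfectly complementary pair scores the full duplex", {
  f <- "ACGGTCAGTCAGGCAT"
  r <- reverse_complement(f)
  sp <- dimer_score_pair(primer_pair("pc", f, r), PARAMS, CONFIG)
  expect_equal(sp$best_pairing, "FR")
  expect_true(sp$best_structure$spans_both)
  expect_true(all(sp$best_structure$states))
  # full-length duplex dG plus the G/C full-span bonus (terminal T at the
  # bottom 3' end loses the bonus only if neither scan ends on C/G; here the
  # top 3' base is T, bottom 3' base is A -> check against oracle instead)
  expect_identical(sp$raw_ds, oracle_score_pair(f, r, CONFIG)$raw)
  full_dg <- duplex_dg(f, paste(vapply(strsplit(f, "")[[1]], oracle_comp,
                                       character(1)), collapse = ""),
                       PARAMS, CONFIG)
  expect_lte(sp$raw_ds, full_dg)
})

test_that("homopolymer pairs have no stabilising structure", {
  sp <- dimer_score_pair(primer_pair("pa", strrep("A", 20), strrep("A", 20)),
                         PARAMS, CONFIG)
  expect_gte(sp$raw_ds, 0)
  expect_identical(sp$raw_ds,
                   oracle_score_pair(strrep("A", 20), strrep("A", 20),
                                     CONFIG)$raw)
})

test_that("scoring is symmetric in forward/reverse and deterministic", {
  set.seed(303)
  for (i in 1:20) {
    f <- random_primer(sample(12:22, 1))
    r <- random_primer(sample(12:22, 1))
    s1 <- dimer_score_pair(primer_pair("a", f, r), PARAMS, CONFIG)
    s2 <- dimer_score_pair(primer_pair("b", r, f), PARAMS, CONFIG)
    expect_identical(s1$raw_ds, s2$raw_ds)
    expect_identical(s1$adjusted_ds, s2$adjusted_ds)
    s3 <- dimer_score_pair(primer_pair("a", f, r), PARAMS, CONFIG)
    expect_identical(s1$raw_ds, s3$raw_ds)
    expect_identical(s1$best_structure$offset, s3$best_structure$offset)
  }
})

test_that("growing a perfect duplex with G/C steps monotonically stabilises it", {
  # extending a fully complementary hetero-pairing by one matched C/G pair
  # appends a step whose stabilisation exceeds the full-span bonus, so the
  # pairing's score strictly decreases with length
  set.seed(404)
  for (rep in 1:10) {
    f <- random_primer(8)
    prev <- oligodimer:::.pairing_min(f, reverse_complement(f), PARAMS,
                                      CONFIG)$raw
    for (k in 1:8) {
      f <- paste0(f, sample(c("C", "G"), 1))
      cur <- oligodimer:::.pairing_min(f, reverse_complement(f), PARAMS,
                                       CONFIG)$raw
      expect_lt(cur, prev)
      prev <- cur
    }
  }
})

test_that("pairs too short to form a scoreable structure keep the sentinel", {
  sp <- dimer_score_pair(primer_pair("tiny", "A", "T"), PARAMS, CONFIG)
  expect_equal(sp$raw_ds, CONFIG$sentinel_start)
  expect_equal(sp$adjusted_ds, CONFIG$sentinel_start)
  expect_true(is.null(sp$best_structure))
})

test_that("structure rendering aligns the bottom strand at its offset", {
  st <- enumerate_alignments("ACGTACGTAC", "ACGTACGT", CONFIG)
  txt <- render_structure(st[[3]])
  expect_length(txt, 3)
  expect_match(txt[1], "5'-ACGTACGTAC-3'")
  expect_match(txt[3], "3'-")
  # bottom line shifted by the offset
  expect_equal(regexpr("3'-", txt[3])[1] - regexpr("5'-", txt[1])[1],
               st[[3]]$offset)
})
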