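test_that("all 16 WC steps resolve and reconstruct dG37 from dH/dS", {
  wc_keys <- as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                             function(a, b) {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    paste0(a, b, "/", comp[a], comp[b])
  }))
  expect_length(wc_keys, 16)
  expect_true(all(wc_keys %in% names(PARAMS$match$dg37)))
  expect_true(all(PARAMS$match$dg37 < 0))
  recon <- dg_at_temperature(PARAMS$match$dh, PARAMS$match$ds, 37)
  expect_true(all(abs(recon - PARAMS$match$dg37) <= 0.05))
})

test_that("nn_step_dg dispatches between match, mismatch and double-mismatch", {
  expect_equal(nn_step_dg("AA", "TT", PARAMS, CONFIG),
               PARAMS$match$dg37[["AA/TT"]])
  # GC/CG stacks more strongly than AA/TT
  expect_lt(nn_step_dg("GC", "CG", PARAMS, CONFIG),
            nn_step_dg("AA", "TT", PARAMS, CONFIG))
  # double mismatch is a config passthrough
  cfg <- scoring_config(double_mismatch_penalty = 1.0)
  expect_equal(nn_step_dg("AA", "AA", PARAMS, cfg), 1.0)
  # single mismatch comes from the mismatch table (A.C pair right position)
  expect_equal(nn_step_dg("AA", "TC", PARAMS, CONFIG),
               unname(PARAMS$mismatch$dg37[["AA/TC"]]))
  expect_error(nn_step_dg("AX", "TT", PARAMS, CONFIG), "invalid base")
})

test_that("temperature response follows dG = dH - T dS", {
  expect_equal(dg_at_temperature(0, 0, 55), 0)
  aatt <- dg_at_temperature(PARAMS$match$dh[["AA/TT"]],
                            PARAMS$match$ds[["AA/TT"]], 37)
  expect_lt(abs(aatt - PARAMS$match$dg37[["AA/TT"]]), 0.05)
  # negative dS: colder is more stable (the 17-67 degC sweep direction)
  expect_lt(dg_at_temperature(-7.9, -22.2, 17),
            dg_at_temperature(-7.9, -22.2, 67))
  expect_error(dg_at_temperature(NA_real_, 1, 37), "non-finite")
})

test_that("sodium correction acts on entropy per phosphate", {
  expect_equal(sodium_correct_entropy(-22.2, 2, 1.0), -22.2)
  expect_equal(sodium_correct_entropy(-22.2, 2, 0.5),
               -22.2 + 0.368 * log(0.5), tolerance = 1e-12)
  # high salt (10 M end of the sweep) makes dS less negative
  expect_gt(sodium_correct_entropy(-22.2, 2, 10), -22.2)
  expect_error(sodium_correct_entropy(-22.2, 2, 0), "sodium")
})

test_that("magnesium folds into a sodium-equivalent concentration", {
  expect_equal(na_equivalent(1.0, 0, 0), 1.0)
  expect_equal(na_equivalent(0.05, 0.0045, 0),
               0.05 + 0.120 * sqrt(0.0045), tolerance = 1e-12)
  # dNTPs chelate magnesium stoichiometrically
  expect_equal(na_equivalent(0, 0.0045, 0.0045), 0)
  expect_error(na_equivalent(-0.1, 0, 0), "non-negative")
  # monotone in each cation, non-increasing in dNTPs
  expect_gte(na_equivalent(0.1, 0.004, 0), na_equivalent(0.05, 0.004, 0))
  expect_gte(na_equivalent(0.05, 0.006, 0), na_equivalent(0.05, 0.004, 0))
  expect_lte(na_equivalent(0.05, 0.004, 0.002), na_equivalent(0.05, 0.004, 0))
})

test_that("duplex dG equals the brute-force sum of step entries", {
  # single step window
  expect_equal(duplex_dg("AC", "TG", PARAMS, CONFIG),
               unname(PARAMS$match$dg37[["AC/TG"]]))
  set.seed(7)
  for (rep in 1:25) {
    len <- sample(2:12, 1)
    top <- random_primer(len)
    bot <- paste(vapply(strsplit(top, "")[[1]], oracle_comp, character(1)),
                 collapse = "")
    expected <- 0
    tch <- strsplit(top, "")[[1]]
    bch <- strsplit(bot, "")[[1]]
    for (i in 1:(len - 1)) {
      expected <- expected + oracle_tables$match[[paste0(
        tch[i], tch[i + 1], "/", bch[i], bch[i + 1])]]
    }
    expect_equal(duplex_dg(top, bot, PARAMS, CONFIG), expected)
    # simultaneous reversal of both strands reads the same duplex backwards
    expect_equal(duplex_dg(oracle_rev(bot), oracle_rev(top), PARAMS, CONFIG),
                 expected)
  }
})

test_that("off-standard conditions recompute dG from dH/dS with salt", {
  p_cold <- thermo_params(temperature_c = 17)
  p_hot <- thermo_params(temperature_c = 67)
  top <- "ACGTGCAT"
  bot <- paste(vapply(strsplit(top, "")[[1]], oracle_comp, character(1)),
               collapse = "")
  expect_lt(duplex_dg(top, bot, p_cold, CONFIG),
            duplex_dg(top, bot, p_hot, CONFIG))
  # low salt destabilises (dS more negative, dG less negative)
  p_lowsalt <- thermo_params(sodium_m = 0.05)
  expect_gt(duplex_dg(top, bot, p_lowsalt, CONFIG),
            duplex_dg(top, bot, PARAMS, CONFIG))
  # hand-check one step at 50 degC, 0.5 M Na
  p <- thermo_params(temperature_c = 50, sodium_m = 0.5)
  ds_corr <- -22.2 + 0.368 * log(0.5)
  expect_equal(nn_step_dg("AA", "TT", p, CONFIG),
               -7.9 - (50 + 273.15) * ds_corr / 1000, tolerance = 1e-12)
})

test_that("missing mismatch entries fall back to 0 with a warning", {
  # truncate the mismatch table to force a missing step
  full <- read.delim(system.file("extdata", "nn_mismatch.tsv",
                                 package = "oligodimer"))
  keep <- full[full$step != "AA/TC" &
                 full$step != .sym_key_for_test("AA/TC"), ]
  tmp <- tempfile(fileext = ".tsv")
  write.table(keep, tmp, sep = "\t", row.names = FALSE, quote = FALSE)
  p <- thermo_params(mismatch_file = tmp)
  expect_warning(v <- nn_step_dg("AA", "TC", p, CONFIG),
                 "no published mismatch parameters")
  expect_equal(v, 0)
  # warning fires once per key
  expect_silent(nn_step_dg("AA", "TC", p, CONFIG))
})

test_that("parameter validation rejects bad conditions and tables", {
  expect_error(thermo_params(temperature_c = 150), "0-100")
  expect_error(thermo_params(sodium_m = 0), "> 0")
  full <- read.delim(system.file("extdata", "nn_match.tsv",
                                 package = "oligodimer"))
  tmp <- tempfile(fileext = ".tsv")
  write.table(full[-1, ], tmp, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(thermo_params(match_file = tmp), "incomplete")
})
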