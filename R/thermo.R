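# Nearest-neighbour thermodynamics: parameter tables, temperature and salt
# adjustment, and duplex free-energy computation.
#
# The parameter files shipped under inst/extdata hold the published unified
# Watson-Crick duplex set, the internal single-mismatch compilations, and the
# 5' dangling-end set. Step keys read top-dinucleotide (5'->3') "/"
# bottom-dinucleotide (3'->5'), aligned position by position, e.g. "AC/TG"
# is 5'-AC-3' paired with 3'-TG-5'.

.read_nn_table <- function(path, dangling = FALSE) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (dangling) {
    stats::setNames(tab$dg37, tab$context)
  } else {
    list(dg37 = stats::setNames(tab$dg37, tab$step),
         dh   = stats::setNames(tab$dh, tab$step),
         ds   = stats::setNames(tab$ds, tab$step))
  }
}

# 180-degree rotation of a step key: "XY/ZW" -> "WZ/YX" (same duplex read
# from the other strand)
.sym_key <- function(key) {
  t2 <- substr(key, 1, 2)
  b2 <- substr(key, 4, 5)
  paste0(.revseq(b2), "/", .revseq(t2))
}

# augment a keyed table with symmetric images so lookups are single-shot
.augment_sym <- function(v) {
  extra <- vapply(names(v), .sym_key, character(1))
  new <- !(extra %in% names(v))
  c(v, stats::setNames(v[new], extra[new]))
}

#' Thermodynamic parameter set
#'
#' Loads the nearest-neighbour parameter tables and fixes the solution
#' conditions under which step free energies are evaluated. At the standard
#' condition (37 degrees C, 1 M monovalent cation) the tabulated
#' \eqn{\Delta G^\circ_{37}} values are used directly; at any other
#' temperature or salt, \eqn{\Delta G} is recomputed from the tabulated
#' \eqn{(\Delta H, \Delta S)} with the entropic salt correction applied
#' (see \code{\link{sodium_correct_entropy}}). Magnesium is folded into an
#' equivalent monovalent concentration via \code{\link{na_equivalent}}.
#'
#' @param temperature_c temperature in degrees Celsius (0-100).
#' @param sodium_m total monovalent cation concentration, mol/L (> 0).
#' @param magnesium_m free magnesium concentration, mol/L.
#' @param dntp_m total dNTP concentration, mol/L (chelates magnesium).
#' @param match_file,mismatch_file,dangling_file optional paths to
#'   alternative tab-separated parameter tables in the shipped format.
#' @return an object of class \code{thermo_params}.
#' @examples
#' p <- thermo_params()
#' p$match$dg37[["AA/TT"]]
#' @export
thermo_params <- function(temperature_c = 37, sodium_m = 1.0,
                          magnesium_m = 0, dntp_m = 0,
                          match_file = NULL, mismatch_file = NULL,
                          dangling_file = NULL) {
  if (!is.finite(temperature_c) || temperature_c < 0 || temperature_c > 100) {
    stop("temperature_c must be within 0-100 degrees C", call. = FALSE)
  }
  if (!is.finite(sodium_m) || sodium_m <= 0) {
    stop("sodium_m must be > 0", call. = FALSE)
  }
  if (magnesium_m < 0 || dntp_m < 0) {
    stop("concentrations must be non-negative", call. = FALSE)
  }
  pick <- function(user, default) {
    if (is.null(user)) system.file("extdata", default, package = "oligodimer",
                                   mustWork = TRUE) else user
  }
  match_tab <- .read_nn_table(pick(match_file, "nn_match.tsv"))
  mm_tab <- .read_nn_table(pick(mismatch_file, "nn_mismatch.tsv"))
  dangling <- .read_nn_table(pick(dangling_file, "nn_dangling5.tsv"),
                             dangling = TRUE)

  wc_keys <- as.vector(outer(.BASES, .BASES, function(a, b) {
    paste0(a, b, "/", .COMP[a], .COMP[b])
  }))
  missing_wc <- setdiff(wc_keys, names(match_tab$dg37))
  if (length(missing_wc) > 0L) {
    stop("match table incomplete; missing step(s): ",
         paste(missing_wc, collapse = ", "), call. = FALSE)
  }
  if (any(match_tab$dg37 >= 0)) {
    stop("all Watson-Crick step dG37 values must be negative", call. = FALSE)
  }
  recon <- match_tab$dh - 310.15 * match_tab$ds / 1000
  if (any(abs(recon - match_tab$dg37) > 0.05)) {
    stop("match table inconsistent: dH - 310.15*dS/1000 deviates from dG37 ",
         "by more than 0.05 kcal/mol", call. = FALSE)
  }

  na_eff <- na_equivalent(sodium_m, magnesium_m, dntp_m)
  standard <- (temperature_c == 37 && na_eff == 1)
  eff <- function(tab) {
    if (standard) {
      tab$dg37
    } else {
      ds_corr <- sodium_correct_entropy(tab$ds, n_phosphates = 2,
                                        sodium_m = na_eff)
      dg_at_temperature(tab$dh, ds_corr, temperature_c)
    }
  }
  obj <- list(
    match = match_tab,
    mismatch = list(dg37 = .augment_sym(mm_tab$dg37),
                    dh = .augment_sym(mm_tab$dh),
                    ds = .augment_sym(mm_tab$ds)),
    dangling = dangling,
    temperature_c = temperature_c,
    sodium_m = sodium_m,
    magnesium_m = magnesium_m,
    dntp_m = dntp_m,
    na_eff = na_eff,
    standard = standard,
    warned = new.env(parent = emptyenv())
  )
  obj$match_eff <- eff(match_tab)
  obj$mismatch_eff <- eff(obj$mismatch)
  class(obj) <- "thermo_params"
  obj
}

#' @export
print.thermo_params <- function(x, ...) {
  cat("Nearest-neighbour thermodynamic parameters\n")
  cat(sprintf("  %d WC steps, %d mismatch steps, %d dangling-end contexts\n",
              length(x$match$dg37), length(x$mismatch$dg37),
              length(x$dangling)))
  cat(sprintf("  conditions: %g degC, [Na+] %g M, [Mg2+] %g M, [dNTP] %g M",
              x$temperature_c, x$sodium_m, x$magnesium_m, x$dntp_m))
  cat(sprintf(" (Na+ equivalent %.4g M)\n", x$na_eff))
  invisible(x)
}

#' Free energy at an arbitrary temperature
#'
#' \eqn{\Delta G = \Delta H - T \Delta S / 1000} with \eqn{T} in kelvin.
#' Units: \code{dh} kcal/mol, \code{ds} cal/(mol K), result kcal/mol.
#'
#' @param dh enthalpy change, kcal/mol.
#' @param ds entropy change, cal/(mol K).
#' @param temperature_c temperature, degrees Celsius.
#' @return free energy change, kcal/mol.
#' @export
dg_at_temperature <- function(dh, ds, temperature_c) {
  if (any(!is.finite(dh)) || any(!is.finite(ds)) ||
      any(!is.finite(temperature_c))) {
    stop("non-finite input to dg_at_temperature", call. = FALSE)
  }
  dh - (temperature_c + 273.15) * ds / 1000
}

#' Entropic salt correction
#'
#' Applies the per-phosphate monovalent-cation correction
#' \eqn{\Delta S[Na^+] = \Delta S[1M] + 0.368 (N/2) \ln[Na^+]},
#' where \eqn{N} is the number of phosphates contributing (2 per
#' nearest-neighbour step).
#'
#' @param ds entropy change at 1 M Na+, cal/(mol K).
#' @param n_phosphates number of phosphates in the stretch being corrected.
#' @param sodium_m total monovalent cation (equivalent) concentration, mol/L.
#' @return corrected entropy, cal/(mol K).
#' @export
sodium_correct_entropy <- function(ds, n_phosphates, sodium_m) {
  if (any(!is.finite(sodium_m)) || any(sodium_m <= 0)) {
    stop("sodium_m must be > 0", call. = FALSE)
  }
  if (any(n_phosphates < 0)) stop("n_phosphates must be >= 0", call. = FALSE)
  ds + 0.368 * (n_phosphates / 2) * log(sodium_m)
}

#' Sodium-equivalent concentration of a divalent-containing buffer
#'
#' Converts free magnesium into an equivalent monovalent concentration,
#' \eqn{[Na^+]_{eq} = [Na^+] + 120\sqrt{[Mg^{2+}]_{free}}} (concentrations
#' in mM inside the square root; here everything is kept in mol/L, hence the
#' factor 0.120). dNTPs chelate magnesium stoichiometrically, so free
#' magnesium is \code{max(magnesium_m - dntp_m, 0)}.
#'
#' @param sodium_m monovalent cations, mol/L.
#' @param magnesium_m total magnesium, mol/L.
#' @param dntp_m total dNTPs, mol/L.
#' @return sodium-equivalent concentration, mol/L.
#' @export
na_equivalent <- function(sodium_m, magnesium_m = 0, dntp_m = 0) {
  if (sodium_m < 0 || magnesium_m < 0 || dntp_m < 0) {
    stop("concentrations must be non-negative", call. = FALSE)
  }
  sodium_m + 0.120 * sqrt(max(magnesium_m - dntp_m, 0))
}

# effective per-step free energies for an aligned window.
# tchars: top bases 5'->3'; bchars: bottom bases 3'->5' (positionwise).
# Returns the vector of n-1 step dG values under params' conditions, with a
# configurable penalty standing in for steps where both positions mismatch
# and a neutral 0 (with a one-time warning) for single-mismatch steps absent
# from the published compilations.
.step_dgs <- function(tchars, bchars, params, double_mismatch_penalty) {
  n <- length(tchars)
  states <- .COMP[tchars] == bchars
  keys <- paste0(tchars[-n], tchars[-1], "/", bchars[-n], bchars[-1])
  nmatch <- states[-n] + states[-1]
  dgs <- numeric(n - 1L)
  i2 <- nmatch == 2L
  if (any(i2)) dgs[i2] <- params$match_eff[keys[i2]]
  i1 <- nmatch == 1L
  if (any(i1)) {
    v <- params$mismatch_eff[keys[i1]]
    if (anyNA(v)) {
      miss <- unique(keys[i1][is.na(v)])
      new <- miss[!vapply(miss, exists, logical(1), envir = params$warned)]
      if (length(new) > 0L) {
        for (k in new) assign(k, TRUE, envir = params$warned)
        warning("no published mismatch parameters for step(s) ",
                paste(new, collapse = ", "), "; using 0 kcal/mol",
                call. = FALSE)
      }
      v[is.na(v)] <- 0
    }
    dgs[i1] <- v
  }
  i0 <- nmatch == 0L
  if (any(i0)) dgs[i0] <- double_mismatch_penalty
  unname(dgs)
}

#' Free energy of one nearest-neighbour step
#'
#' Looks up a single step (two adjacent aligned base pairs). Watson-Crick
#' steps use the duplex table, steps with exactly one mismatched position use
#' the single-mismatch table, and doubly mismatched steps are assigned the
#' configured destabilising penalty.
#'
#' @param top two top-strand bases, 5'->3' (string or character vector).
#' @param bottom two bottom-strand bases, 3'->5', aligned positionwise.
#' @param params a \code{\link{thermo_params}} object.
#' @param config a \code{\link{scoring_config}} object (supplies the
#'   double-mismatch penalty).
#' @return step free energy, kcal/mol (score units for double mismatches).
#' @export
nn_step_dg <- function(top, bottom, params, config = scoring_config()) {
  tchars <- if (length(top) == 1L) strsplit(validate_sequence(top), "")[[1]] else top
  bchars <- if (length(bottom) == 1L) strsplit(validate_sequence(bottom), "")[[1]] else bottom
  if (length(tchars) != 2L || length(bchars) != 2L) {
    stop("a step is exactly two aligned base pairs", call. = FALSE)
  }
  .step_dgs(tchars, bchars, params, config$double_mismatch_penalty)
}

#' Free energy of an aligned duplex window
#'
#' Sums nearest-neighbour step free energies over a gap-free aligned window,
#' each step evaluated under the temperature/salt conditions carried by
#' \code{params}.
#'
#' @param top_window top-strand window, 5'->3'.
#' @param bottom_window bottom-strand window, 3'->5', same length.
#' @param params a \code{\link{thermo_params}} object.
#' @param config a \code{\link{scoring_config}} object.
#' @return window free energy, kcal/mol.
#' @export
duplex_dg <- function(top_window, bottom_window, params,
                      config = scoring_config()) {
  t <- strsplit(validate_sequence(top_window, "top window"), "")[[1]]
  b <- strsplit(validate_sequence(bottom_window, "bottom window"), "")[[1]]
  if (length(t) != length(b)) {
    stop("windows must have equal length", call. = FALSE)
  }
  if (length(t) < 2L) {
    stop("degenerate structure: window shorter than 2 bases", call. = FALSE)
  }
  sum(.step_dgs(t, b, params, config$double_mismatch_penalty))
}
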