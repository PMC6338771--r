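# Readers/writers for primer tables, FASTA input, key-value configuration
# files, and run reports.

.HEADER_SYNONYMS <- list(
  pair_id = c("pair_id", "pair", "id", "name", "pair_name"),
  forward = c("forward", "forward_primer", "fwd", "f", "forward_sequence"),
  reverse = c("reverse", "reverse_primer", "rev", "r", "reverse_sequence"),
  dimer_status = c("dimer_status", "status", "label", "dimer",
                   "dimer_band_status")
)

.map_headers <- function(nms) {
  key <- tolower(gsub("[ .-]+", "_", trimws(nms)))
  out <- nms
  for (canon in names(.HEADER_SYNONYMS)) {
    hit <- which(key %in% .HEADER_SYNONYMS[[canon]])
    if (length(hit) > 1L) {
      stop("multiple columns map to '", canon, "'", call. = FALSE)
    }
    if (length(hit) == 1L) out[hit] <- canon
  }
  out
}

#' Read a delimited primer-pair table
#'
#' Expects columns pair_id, forward, reverse and optionally dimer_status
#' (header synonyms such as "Forward Primer" are recognised). Sequences are
#' trimmed, uppercased and validated; dimer_status is parsed
#' case-insensitively into dimer / dimer_free / ambiguous. Errors name the
#' offending data row.
#'
#' @param path file path.
#' @param sep field delimiter; default guesses from the extension (.tsv/.txt
#'   tab, otherwise comma).
#' @return a data frame of class \code{pair_table}.
#' @export
read_pair_table <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep)) {
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  raw <- utils::read.table(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE, colClasses = "character",
                           check.names = FALSE, quote = "\"",
                           comment.char = "")
  names(raw) <- .map_headers(names(raw))
  need <- c("pair_id", "forward", "reverse")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0L) {
    stop("pair table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  out <- data.frame(pair_id = trimws(raw$pair_id),
                    forward = NA_character_, reverse = NA_character_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(raw))) {
    out$forward[i] <- tryCatch(
      validate_sequence(raw$forward[i], "forward primer"),
      error = function(e) stop("row ", i, ": ", conditionMessage(e),
                               call. = FALSE))
    out$reverse[i] <- tryCatch(
      validate_sequence(raw$reverse[i], "reverse primer"),
      error = function(e) stop("row ", i, ": ", conditionMessage(e),
                               call. = FALSE))
  }
  dup <- duplicated(out$pair_id)
  if (any(dup)) {
    stop("duplicate pair_id at row(s) ",
         paste(which(dup), collapse = ", "), call. = FALSE)
  }
  if ("dimer_status" %in% names(raw)) {
    st <- tolower(gsub("[ -]", "_", trimws(raw$dimer_status)))
    ok <- st %in% c("dimer", "dimer_free", "ambiguous")
    if (any(!ok)) {
      stop("unknown dimer_status at row(s) ",
           paste(which(!ok), collapse = ", "), ": ",
           paste(unique(raw$dimer_status[!ok]), collapse = ", "),
           call. = FALSE)
    }
    out$dimer_status <- st
  }
  attr(out, "row_numbers") <- seq_len(nrow(out))
  class(out) <- c("pair_table", "data.frame")
  out
}

#' Write a primer-pair table
#'
#' Plain CSV/TSV writer; \code{read_pair_table} of the written file
#' round-trips the content exactly.
#'
#' @param x pair table data frame.
#' @param path output path; delimiter guessed from the extension.
#' @export
write_pair_table <- function(x, path) {
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(as.data.frame(x)[, intersect(
    c("pair_id", "forward", "reverse", "dimer_status"), names(x))],
    path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read primer pairs from FASTA
#'
#' Two pairing conventions: \code{"suffix"} pairs records named
#' \code{<id>_F} / \code{<id>_R}; \code{"interleaved"} pairs consecutive
#' records (odd = forward, even = reverse).
#'
#' @param path FASTA file.
#' @param pairing "suffix" or "interleaved".
#' @return a \code{pair_table} data frame (no dimer_status column).
#' @export
read_primer_fasta <- function(path, pairing = c("suffix", "interleaved")) {
  pairing <- match.arg(pairing)
  seqs <- Biostrings::readDNAStringSet(path)
  nms <- names(seqs)
  sq <- toupper(as.character(seqs))
  if (pairing == "interleaved") {
    if (length(sq) %% 2 != 0L) {
      stop("interleaved FASTA needs an even record count", call. = FALSE)
    }
    fwd <- sq[seq(1, length(sq), by = 2)]
    rev <- sq[seq(2, length(sq), by = 2)]
    ids <- sub("_F$", "", nms[seq(1, length(sq), by = 2)])
  } else {
    is_f <- grepl("_F$", nms)
    is_r <- grepl("_R$", nms)
    if (!all(is_f | is_r)) {
      stop("suffix pairing needs every record named <id>_F or <id>_R",
           call. = FALSE)
    }
    fid <- sub("_F$", "", nms[is_f])
    rid <- sub("_R$", "", nms[is_r])
    if (!setequal(fid, rid) || anyDuplicated(fid) || anyDuplicated(rid)) {
      stop("forward/reverse records do not pair up one-to-one",
           call. = FALSE)
    }
    fwd <- sq[is_f][order(fid)]
    rev <- sq[is_r][order(rid)]
    ids <- sort(fid)
  }
  out <- data.frame(pair_id = ids,
                    forward = vapply(fwd, validate_sequence, character(1)),
                    reverse = vapply(rev, validate_sequence, character(1)),
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("pair_table", "data.frame")
  out
}

.CONFIG_THERMO_KEYS <- c("temperature_c", "sodium_m", "magnesium_m", "dntp_m")

#' Load scoring and thermodynamic settings from a key-value file
#'
#' Lines of the form \code{key = value} (or \code{key: value}; \code{#}
#' comments allowed). Keys are \code{\link{scoring_config}} arguments
#' (vector-valued ones comma-separated) plus the condition keys
#' \code{temperature_c}, \code{sodium_m}, \code{magnesium_m},
#' \code{dntp_m}. Unknown keys are rejected.
#'
#' @param path config file; an empty or absent-key file yields all defaults.
#' @return list with \code{config} (\code{scoring_config}) and \code{params}
#'   (\code{thermo_params}).
#' @export
load_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  cfg_args <- list()
  thermo_args <- list()
  known_cfg <- names(formals(scoring_config))
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z0-9_]+)\\s*[=:]\\s*(.*)$", ln))[[1]]
    if (length(m) != 3L) stop("malformed config line: ", ln, call. = FALSE)
    key <- m[2]; val <- trimws(m[3])
    parse_num <- function(v) {
      x <- suppressWarnings(as.numeric(strsplit(v, ",")[[1]]))
      if (anyNA(x)) {
        stop("malformed numeric value for key '", key, "': ", v,
             call. = FALSE)
      }
      x
    }
    if (key %in% c("use_length_gc_adjustment", "use_overhangs")) {
      cfg_args[[key]] <- toupper(val) %in% c("TRUE", "T", "YES", "1")
    } else if (key %in% known_cfg) {
      cfg_args[[key]] <- parse_num(val)
    } else if (key %in% .CONFIG_THERMO_KEYS) {
      thermo_args[[key]] <- parse_num(val)
    } else {
      stop("unknown config key: ", key, call. = FALSE)
    }
  }
  list(config = do.call(scoring_config, cfg_args),
       params = do.call(thermo_params, thermo_args))
}

#' Write analysis reports
#'
#' Emits a score table CSV, a ROC curve CSV, a plain-text summary and a run
#' log (configuration values, seed, package version, input checksum) -
#' enough to reproduce the run bit-exactly.
#'
#' @param results an \code{\link{evaluate_dataset}} result (or a list with a
#'   \code{scores} data frame and optionally a \code{curve}).
#' @param out_dir output directory (created if needed).
#' @param seed integer seed used for the run, if any.
#' @param input_path path of the primary input, hashed into the log.
#' @param config the \code{scoring_config} used.
#' @return invisibly, the paths written.
#' @export
write_reports <- function(results, out_dir, seed = NULL, input_path = NULL,
                          config = scoring_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  if (!is.null(results$scores)) {
    p <- file.path(out_dir, "scores.csv")
    utils::write.csv(results$scores, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  if (!is.null(results$curve)) {
    p <- file.path(out_dir, "roc_curve.csv")
    utils::write.csv(results$curve$points, p, row.names = FALSE)
    paths <- c(paths, p)
    p <- file.path(out_dir, "summary.txt")
    con <- file(p, "w")
    writeLines(c(
      sprintf("auc: %.6f", results$curve$auc),
      sprintf("dimer_free_threshold: %s",
              format(results$curve$dimer_free_threshold)),
      sprintf("tnr_at_threshold: %.6f", results$curve$tnr_at_threshold),
      sprintf("n_positive: %d", results$curve$n_positive),
      sprintf("n_negative: %d", results$curve$n_negative),
      sprintf("n_excluded: %d", results$curve$n_excluded)
    ), con)
    close(con)
    paths <- c(paths, p)
  }
  logp <- file.path(out_dir, "run_log.txt")
  cfg_lines <- vapply(names(config), function(k) {
    sprintf("config.%s: %s", k, paste(format(config[[k]]), collapse = ","))
  }, character(1))
  writeLines(c(
    sprintf("package: oligodimer %s",
            as.character(utils::packageVersion("oligodimer"))),
    sprintf("timestamp: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    sprintf("seed: %s", if (is.null(seed)) "none" else format(seed)),
    sprintf("input: %s", if (is.null(input_path)) "none" else input_path),
    sprintf("input_md5: %s",
            if (is.null(input_path)) "none" else
              unname(tools::md5sum(input_path))),
    cfg_lines
  ), logp)
  invisible(c(paths, logp))
}
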