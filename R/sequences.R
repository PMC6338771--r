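#' @keywords internal
"_PACKAGE"

.BASES <- c("A", "C", "G", "T")
.COMP <- c(A = "T", C = "G", G = "C", T = "A")

#' Validate and normalise a DNA sequence
#'
#' Uppercases the input and rejects anything outside A/C/G/T. The
#' nearest-neighbour tables are defined only on the four unambiguous bases,
#' so IUPAC degeneracy codes (including N) are errors, not wildcards.
#'
#' @param x single character string, a DNA sequence written 5'->3'.
#' @param what label used in error messages (e.g. "forward primer").
#' @return the validated, uppercased sequence.
#' @export
validate_sequence <- function(x, what = "sequence") {
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    stop(what, " must be a single character string", call. = FALSE)
  }
  x <- toupper(trimws(x))
  if (nchar(x) == 0L) stop(what, " is empty", call. = FALSE)
  bad <- setdiff(unique(strsplit(x, "")[[1]]), .BASES)
  if (length(bad) > 0L) {
    stop(what, " contains invalid base(s): ", paste(bad, collapse = ", "),
         " (only A/C/G/T are allowed)", call. = FALSE)
  }
  x
}

# reverse of a sequence string
.revseq <- function(x) {
  paste(rev(strsplit(x, "")[[1]]), collapse = "")
}

#' Reverse complement of a DNA sequence
#' @param x DNA sequence string (A/C/G/T).
#' @return reverse complement, 5'->3'.
#' @export
reverse_complement <- function(x) {
  .revseq(chartr("ACGT", "TGCA", toupper(x)))
}

# fraction of G+C bases
.gc_fraction <- function(x) {
  ch <- strsplit(x, "")[[1]]
  mean(ch %in% c("G", "C"))
}
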