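#' Reverse complement of a nucleotide string
#'
#' Works on plain character vectors over the \{A,C,G,T,N\} alphabet.
#' N maps to N.
#'
#' @param x character vector of nucleotide strings.
#' @return character vector of reverse complements.
#' @export
#' @examples
#' revcomp("ACGTN")
revcomp <- function(x) {
  stopifnot(is.character(x))
  vapply(x, function(s) {
    if (nchar(s) == 0L) return("")
    comp <- chartr("ACGTNacgtn", "TGCANtgcan", s)
    paste(rev(strsplit(comp, "", fixed = TRUE)[[1L]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Round half away from zero at a fixed number of decimals
#'
#' `base::round()` rounds half to even; printed report figures here use
#' the conventional round-half-up (12.615 -> 12.62).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Percentage of a total at a stated precision
#'
#' @param count numerator count(s).
#' @param total denominator.
#' @param digits decimal places of the printed percent (round-half-up).
#' @return numeric percent value(s), e.g. 48.7 for 19008/39027 at 1 dp.
#' @export
#' @examples
#' percent_of(19008, 39027, digits = 1)
percent_of <- function(count, total, digits = 2) {
  stopifnot(is.numeric(count), is.numeric(total), total > 0)
  round_half_up(count / total * 100, digits)
}

# Validate a nucleotide string vector against the {A,C,G,T,N} alphabet.
check_alphabet <- function(x, allow_n = TRUE, what = "sequence") {
  pat <- if (allow_n) "^[ACGTN]*$" else "^[ACGT]*$"
  bad <- !grepl(pat, x)
  if (any(bad)) {
    stop(sprintf("%s contains characters outside {A,C,G,T%s}: first offender '%s'",
                 what, if (allow_n) ",N" else "", x[which(bad)[1L]]),
         call. = FALSE)
  }
  invisible(TRUE)
}
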