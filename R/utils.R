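#' @keywords internal
"_PACKAGE"

## Sequence alphabet helpers. Genome and FASTQ use DNA (T); mature miRNAs are
## stored as RNA (U). All sequence comparisons are T/U-normalized.

#' Convert a DNA string to RNA (T -> U)
#' @param x character vector of sequences
#' @return character vector in RNA alphabet
#' @export
dna_to_rna <- function(x) chartr("Tt", "Uu", x)

#' Convert an RNA string to DNA (U -> T)
#' @param x character vector of sequences
#' @return character vector in DNA alphabet
#' @export
rna_to_dna <- function(x) chartr("Uu", "Tt", x)

#' Reverse complement (alphabet-preserving)
#'
#' Complements A/C/G/T-or-U and reverses. RNA input yields RNA output.
#' @param x character vector of sequences
#' @return character vector of reverse complements
#' @export
revcomp <- function(x) {
  is_rna <- grepl("U", x, fixed = TRUE) | grepl("u", x, fixed = TRUE)
  xd <- rna_to_dna(toupper(x))
  rc <- vapply(xd, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
  ifelse(is_rna, dna_to_rna(rc), rc)
}

split_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

## Watson-Crick + wobble pairing on the RNA alphabet.
.pair_ok <- local({
  tab <- matrix(FALSE, 4, 4, dimnames = list(c("A", "C", "G", "U"),
                                             c("A", "C", "G", "U")))
  tab["A", "U"] <- tab["U", "A"] <- TRUE
  tab["G", "C"] <- tab["C", "G"] <- TRUE
  tab["G", "U"] <- tab["U", "G"] <- TRUE
  tab
})

can_pair <- function(a, b) {
  ok <- .pair_ok[cbind(a, b)]
  ok[is.na(ok)] <- FALSE
  ok
}

is_wc_pair <- function(a, b) {
  (a == "A" & b == "U") | (a == "U" & b == "A") |
    (a == "G" & b == "C") | (a == "C" & b == "G")
}

is_gu_pair <- function(a, b) {
  (a == "G" & b == "U") | (a == "U" & b == "G")
}

#' Phred quality from an error probability
#'
#' Q = -10 * log10(error_ratio), the standard Phred transform used when
#' filtering reads whose 3' end falls below Q20.
#'
#' @param error_ratio base-call error probability in (0, 1]
#' @return Phred quality in phred units
#' @examples
#' phred_q(0.01) # 20
#' @export
phred_q <- function(error_ratio) {
  if (any(!is.finite(error_ratio)) || any(error_ratio <= 0) ||
      any(error_ratio > 1)) {
    stop("error_ratio must be in (0, 1]")
  }
  -10 * log10(error_ratio)
}

## Phred+33 encoding helpers for FASTQ qualities.
phred_to_chars <- function(q) {
  vapply(q, function(v) intToUtf8(as.integer(v) + 33L, multiple = FALSE),
         character(1))
}

chars_to_phred <- function(s) {
  lapply(s, function(x) utf8ToInt(x) - 33L)
}

## Deterministic seed derivation: keep derived seeds below 2^31.
derive_seed <- function(seed, salt) {
  (as.integer(seed) * 1103L + as.integer(salt) * 12289L) %% 2147483399L
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}
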