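#' @keywords internal
"_PACKAGE"

## Shared alphabet constants. Codon order follows the conventional
## TCAG-by-position enumeration (same order as Biostrings::GENETIC_CODE).
BASES <- c("T", "C", "A", "G")
CODONS <- paste0(
  rep(BASES, each = 16L),
  rep(rep(BASES, each = 4L), times = 4L),
  rep(BASES, times = 16L)
)

## Normalize a nucleotide string to the internal DNA alphabet: uppercase, U -> T.
normalize_dna <- function(seq) {
  gsub("U", "T", toupper(seq), fixed = TRUE)
}

## Validate that a string is ACGT-only; error names the first offending position.
check_dna <- function(seq, what = "sequence") {
  bad <- regexpr("[^ACGT]", seq)
  if (bad != -1L) {
    stop(sprintf("invalid %s: non-ACGT character '%s' at position %d",
                 what, substr(seq, bad, bad), bad), call. = FALSE)
  }
  invisible(seq)
}

#' Genetic code for the standard or vertebrate mitochondrial table
#'
#' Builds the codon-to-amino-acid map plus start/stop codon sets for NCBI
#' translation table 1 (standard) or 2 (vertebrate mitochondrial). The two
#' tables differ at exactly four codons: TGA (stop vs. Trp), AGA and AGG
#' (Arg vs. stop), and ATA (Ile vs. Met). Table 1 uses ATG as the start
#' codon; table 2 additionally admits ATA.
#'
#' @param table_id Integer, 1 or 2.
#' @return An object of class `genetic_code`: a list with `table_id`,
#'   `codon_to_aa` (named character vector over all 64 codons, `"*"` for
#'   stops), `start_codons` and `stop_codons`.
#' @examples
#' genetic_code(2)$codon_to_aa[["TGA"]]  # "W"
#' @export
genetic_code <- function(table_id = 1L) {
  table_id <- as.integer(table_id)
  if (length(table_id) != 1L || !table_id %in% c(1L, 2L)) {
    stop("only NCBI translation tables 1 and 2 are supported")
  }
  map <- Biostrings::getGeneticCode(as.character(table_id))
  map <- stats::setNames(as.character(map), names(map))[CODONS]
  starts <- if (table_id == 1L) "ATG" else c("ATA", "ATG")
  structure(
    list(table_id = table_id,
         codon_to_aa = map,
         start_codons = starts,
         stop_codons = names(map)[map == "*"]),
    class = "genetic_code"
  )
}

#' @export
print.genetic_code <- function(x, ...) {
  cat(sprintf("<genetic_code> NCBI table %d; starts: %s; stops: %s\n",
              x$table_id,
              paste(x$start_codons, collapse = ","),
              paste(x$stop_codons, collapse = ",")))
  invisible(x)
}

## Split a sequence into in-frame codons; trailing partial codon dropped.
## Returns a character vector (possibly empty).
frame_codons <- function(seq, frame = 1L) {
  n <- nchar(seq)
  n_cod <- (n - frame + 1L) %/% 3L
  if (n_cod < 1L) return(character(0))
  starts <- seq.int(frame, by = 3L, length.out = n_cod)
  substring(seq, starts, starts + 2L)
}

#' Translate a nucleotide sequence in a given reading frame
#'
#' Full-frame translation: stop codons are rendered as `"*"` and translation
#' does not terminate at them. The trailing partial codon, if any, is
#' ignored. Frame `k` (1, 2 or 3) starts codons at nucleotide `k` (1-based).
#'
#' @param seq Nucleotide string (`U` is normalized to `T`).
#' @param code A [genetic_code()] object.
#' @param frame Integer in 1..3.
#' @return Amino-acid string of length `floor((nchar(seq) - frame + 1)/3)`.
#' @examples
#' translate_dna("TGA", genetic_code(2))  # "W"
#' translate_dna("TGA", genetic_code(1))  # "*"
#' @export
translate_dna <- function(seq, code = genetic_code(1L), frame = 1L) {
  stopifnot(inherits(code, "genetic_code"), frame %in% 1:3)
  seq <- normalize_dna(seq)
  check_dna(seq)
  codons <- frame_codons(seq, frame)
  if (!length(codons)) return("")
  paste(unname(code$codon_to_aa[codons]), collapse = "")
}

#' Locate the first in-frame stop codon
#'
#' @inheritParams translate_dna
#' @return Integer vector `c(start, end)` giving the 1-based inclusive
#'   nucleotide span of the leftmost in-frame stop codon, or `NULL` when the
#'   frame is stop-free.
#' @examples
#' first_stop("AAATAAAAA", genetic_code(1))  # c(4, 6)
#' first_stop("AGAAGA", genetic_code(2))     # c(1, 3): AGA is a stop in table 2
#' @export
first_stop <- function(seq, code = genetic_code(1L), frame = 1L) {
  stopifnot(inherits(code, "genetic_code"), frame %in% 1:3)
  seq <- normalize_dna(seq)
  check_dna(seq)
  codons <- frame_codons(seq, frame)
  hit <- which(codons %in% code$stop_codons)
  if (!length(hit)) return(NULL)
  p <- frame + 3L * (hit[1L] - 1L)
  c(p, p + 2L)
}

#' Is a codon a start codon under a genetic code?
#'
#' @param codon A 3-letter ACGT string (`U` normalized to `T`).
#' @param code A [genetic_code()] object.
#' @return Logical.
#' @export
is_start_codon <- function(codon, code = genetic_code(1L)) {
  stopifnot(inherits(code, "genetic_code"))
  codon <- normalize_dna(codon)
  if (nchar(codon) != 3L) stop("codon must be a trinucleotide")
  check_dna(codon, "codon")
  codon %in% code$start_codons
}
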