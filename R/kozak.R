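KOZAK_LEVELS <- c("optimal", "strong", "adequate", "weak", "undetermined")

#' Extract the Kozak context around a nested-ORF start codon
#'
#' Pulls the up to six bases immediately 5' of the ATG (positions -6..-1)
#' and the base immediately 3' of it (position +4). The strength class is
#' left unset; see [classify_kozak()].
#'
#' @param host_seq Host CDS nucleotide string.
#' @param orf_start_nt 1-based position of the A of the ATG on the host.
#' @return An object of class `kozak_context`: list with `upstream`,
#'   `minus3` (the purine/pyrimidine-determining base, `NA` when fewer than
#'   three upstream bases exist), and `plus4` (`NA` when the ATG ends the
#'   sequence).
#' @export
extract_kozak <- function(host_seq, orf_start_nt) {
  host_seq <- normalize_dna(host_seq)
  check_dna(host_seq, "host sequence")
  s <- as.integer(orf_start_nt)
  if (s < 1L || s + 2L > nchar(host_seq)) stop("orf_start_nt out of range")
  if (substr(host_seq, s, s + 2L) != "ATG") {
    stop(sprintf("contract violation: codon at position %d is '%s', not ATG",
                 s, substr(host_seq, s, s + 2L)))
  }
  upstream <- if (s > 1L) substr(host_seq, max(1L, s - 6L), s - 1L) else ""
  minus3 <- if (s >= 4L) substr(host_seq, s - 3L, s - 3L) else NA_character_
  plus4 <- if (s + 3L <= nchar(host_seq)) substr(host_seq, s + 3L, s + 3L) else NA_character_
  structure(list(upstream = upstream, minus3 = minus3, plus4 = plus4),
            class = "kozak_context")
}

#' Classify Kozak initiation strength
#'
#' Four tiers, decided by the -3 and +4 positions (R = purine), with the
#' full `GCCRCC` upstream motif additionally required for the top tier:
#' * optimal: `GCCRCC ATG G`
#' * strong: `NNNRNN ATG G`
#' * adequate: `NNNRNN ATG (A/C/T)` or `NNN(C/T)NN ATG G`
#' * weak: `NNN(C/T)NN ATG (A/C/T)`
#'
#' Tiers are nested; the most specific matching pattern wins (a context
#' matching both "optimal" and "strong" is optimal). Contexts lacking a -3
#' or +4 base are `"undetermined"` and excluded from tallies.
#'
#' @param upstream Either a `kozak_context` object or a character vector of
#'   upstream (-6..-1) base strings.
#' @param plus4 Character vector of +4 bases (ignored when `upstream` is a
#'   `kozak_context`).
#' @return Character vector of strength classes.
#' @examples
#' classify_kozak("GCCACC", "G")  # "optimal"
#' classify_kozak("TTTCTT", "C")  # "weak"
#' @export
classify_kozak <- function(upstream, plus4 = NULL) {
  if (inherits(upstream, "kozak_context")) {
    plus4 <- upstream$plus4
    upstream <- upstream$upstream
  }
  upstream <- normalize_dna(upstream)
  plus4 <- normalize_dna(plus4)
  n <- nchar(upstream)
  minus3 <- ifelse(n >= 3L, substr(upstream, n - 2L, n - 2L), NA_character_)
  und <- is.na(minus3) | is.na(plus4) | !minus3 %in% BASES | !plus4 %in% BASES
  purine <- minus3 %in% c("A", "G")
  g4 <- !is.na(plus4) & plus4 == "G"
  optimal <- n == 6L & grepl("^GCC[AG]CC$", upstream) & g4
  ifelse(und, "undetermined",
    ifelse(optimal, "optimal",
      ifelse(purine & g4, "strong",
        ifelse(purine | g4, "adequate", "weak"))))
}

#' Kozak contexts for a set of nested ORFs
#'
#' Joins nested ORFs to their host sequences, extracts each start-codon
#' context, and classifies it.
#'
#' @param records Host CDS records (data.frame with `id`, `seq`).
#' @param orfs Nested-ORF data.frame (columns `host_id`, `start_nt`).
#' @return A data.frame with `host_id`, `upstream`, `minus3`, `plus4`,
#'   `strength`.
#' @export
kozak_contexts <- function(records, orfs) {
  records <- as_cds_records(records)
  m <- match(orfs$host_id, records$id)
  if (anyNA(m)) stop("host_id(s) missing from records: ",
                     paste(unique(orfs$host_id[is.na(m)]), collapse = ", "))
  n <- nrow(orfs)
  out <- data.frame(host_id = orfs$host_id, upstream = character(n),
                    minus3 = NA_character_, plus4 = NA_character_,
                    strength = character(n), stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    ctx <- extract_kozak(records$seq[m[i]], orfs$start_nt[i])
    out$upstream[i] <- ctx$upstream
    out$minus3[i] <- ctx$minus3
    out$plus4[i] <- ctx$plus4
    out$strength[i] <- classify_kozak(ctx)
  }
  out
}

#' Tally Kozak base composition and strength classes
#'
#' Counts the bases observed at the -3 and +4 positions (over contexts where
#' the position exists) and the strength classes over all inputs.
#' Undetermined contexts are excluded from the per-position tallies and
#' reported in the class tally.
#'
#' @param contexts Data.frame from [kozak_contexts()] (or any data.frame
#'   with `minus3`, `plus4`, `strength` columns).
#' @return A list with integer tables `minus3`, `plus4`, `strength`.
#' @export
tally_kozak <- function(contexts) {
  det <- contexts$strength != "undetermined"
  list(
    minus3 = table(factor(contexts$minus3[det], levels = BASES)),
    plus4 = table(factor(contexts$plus4[det], levels = BASES)),
    strength = table(factor(contexts$strength, levels = KOZAK_LEVELS))
  )
}
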