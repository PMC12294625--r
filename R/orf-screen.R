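## Coerce records input: accepts a data.frame with columns id/seq or a named
## character vector of sequences.
as_cds_records <- function(records) {
  if (is.character(records)) {
    if (is.null(names(records))) stop("sequences must be named by record id")
    records <- data.frame(id = names(records), seq = unname(records),
                          stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(records), all(c("id", "seq") %in% names(records)))
  records$seq <- normalize_dna(records$seq)
  records
}

empty_orf_frame <- function() {
  data.frame(host_id = character(0), frame = integer(0), start_nt = integer(0),
             end_nt = integer(0), length_codons = integer(0),
             nt_seq = character(0), aa_seq = character(0), complete = logical(0),
             stringsAsFactors = FALSE)
}

## Scan one sequence in one frame; returns rows for the 5'-most ATG of every
## stop-bounded segment meeting the length threshold.
.scan_one_frame <- function(seq, host_id, code, frame, min_codons, include_incomplete) {
  codons <- frame_codons(seq, frame)
  n_cod <- length(codons)
  if (!n_cod) return(empty_orf_frame())
  stop_idx <- which(codons %in% code$stop_codons)
  seg_lo <- c(1L, stop_idx + 1L)
  seg_stop <- c(stop_idx, NA_integer_)  # NA: segment runs off the 3' end
  rows <- vector("list", length(seg_lo))
  for (k in seq_along(seg_lo)) {
    lo <- seg_lo[k]
    st <- seg_stop[k]
    hi <- if (is.na(st)) n_cod else st - 1L
    if (lo > hi) next
    if (is.na(st) && !include_incomplete) next
    a <- which(codons[lo:hi] == "ATG")
    if (!length(a)) next
    ai <- lo + a[1L] - 1L
    len <- hi - ai + 1L  # codons excluding the stop
    if (len < min_codons) next
    start_nt <- frame + 3L * (ai - 1L)
    end_cod <- if (is.na(st)) n_cod else st
    end_nt <- frame + 3L * end_cod - 1L
    rows[[k]] <- data.frame(
      host_id = host_id, frame = frame, start_nt = start_nt, end_nt = end_nt,
      length_codons = len,
      nt_seq = substr(seq, start_nt, end_nt),
      aa_seq = paste(unname(code$codon_to_aa[codons[ai:hi]]), collapse = ""),
      complete = !is.na(st), stringsAsFactors = FALSE)
  }
  do.call(rbind, c(rows[!vapply(rows, is.null, TRUE)], list(empty_orf_frame())))
}

#' Scan host CDSs for nested open reading frames
#'
#' Finds ATG-initiated open reading frames in the shifted (+2/+3) reading
#' frames of each host CDS under the supplied genetic code. Within each
#' stop-bounded segment the 5'-most ATG is reported (the longest variant);
#' internal ATGs are not listed separately. ORFs lacking an in-frame stop
#' before the end of the host CDS are excluded unless
#' `include_incomplete = TRUE`. Only ATG is accepted as an initiator, under
#' either code: the downstream Kozak analysis presumes an AUG start.
#'
#' @param records A data.frame with columns `id` and `seq`, or a named
#'   character vector of sequences.
#' @param code A [genetic_code()]; the standard code (table 1) for the
#'   cytosolic scan, table 2 for the mitochondrial control scan.
#' @param frames Subset of `c(2, 3)`; the host (+1) frame is never scanned.
#' @param min_codons Minimum ORF length in codons, excluding the stop codon.
#' @param include_incomplete Keep ORFs running off the 3' end?
#' @return A data.frame with columns `host_id`, `frame`, `start_nt`,
#'   `end_nt`, `length_codons`, `nt_seq`, `aa_seq`, `complete`
#'   (1-based inclusive nucleotide coordinates on the host).
#' @export
scan_nested_orfs <- function(records, code = genetic_code(1L), frames = c(2L, 3L),
                             min_codons = 150L, include_incomplete = FALSE) {
  stopifnot(inherits(code, "genetic_code"))
  frames <- as.integer(frames)
  if (!length(frames) || !all(frames %in% c(2L, 3L))) {
    stop("frames must be a non-empty subset of {2, 3}")
  }
  if (min_codons < 1L) stop("min_codons must be >= 1")
  records <- as_cds_records(records)
  out <- vector("list", nrow(records) * length(frames))
  k <- 0L
  for (i in seq_len(nrow(records))) {
    check_dna(records$seq[i], paste0("sequence '", records$id[i], "'"))
    for (f in sort(frames)) {
      k <- k + 1L
      out[[k]] <- .scan_one_frame(records$seq[i], records$id[i], code, f,
                                  min_codons, include_incomplete)
    }
  }
  res <- do.call(rbind, c(out[seq_len(k)], list(empty_orf_frame())))
  rownames(res) <- NULL
  res
}

#' Keep the longest nested ORF per host and reading frame
#'
#' When several candidates share a host and frame, the longest is retained;
#' ties are broken towards the smallest start coordinate.
#'
#' @param orfs Output of [scan_nested_orfs()].
#' @return A data.frame with at most one row per `(host_id, frame)` pair.
#' @export
longest_per_frame <- function(orfs) {
  if (!nrow(orfs)) return(orfs)
  key <- paste(orfs$host_id, orfs$frame, sep = "\r")
  keep <- unlist(lapply(split(seq_len(nrow(orfs)), key), function(idx) {
    sub <- orfs[idx, ]
    idx[order(-sub$length_codons, sub$start_nt)][1L]
  }), use.names = FALSE)
  res <- orfs[sort(keep), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Consolidate identical nested-ORF sequences
#'
#' Groups ORFs by exact nucleotide identity and keeps one representative per
#' group (the lexicographically smallest `host_id`), so that downstream
#' codon-usage statistics are not inflated by redundant sequences.
#'
#' @param orfs A data.frame of nested ORFs.
#' @return A list with `unique` (the de-duplicated data.frame, original row
#'   order of representatives) and `duplicate_groups` (a named list mapping
#'   each representative `host_id` to the sorted ids it absorbed; only
#'   groups of size > 1 are listed).
#' @export
dedupe_orfs <- function(orfs) {
  if (!nrow(orfs)) return(list(unique = orfs, duplicate_groups = list()))
  groups <- split(seq_len(nrow(orfs)), orfs$nt_seq)
  rep_rows <- integer(length(groups))
  dup <- list()
  for (k in seq_along(groups)) {
    idx <- groups[[k]]
    rep_host <- min(orfs$host_id[idx])
    rep_rows[k] <- idx[orfs$host_id[idx] == rep_host][1L]
    if (length(idx) > 1L) {
      dup[[rep_host]] <- sort(orfs$host_id[idx])
    }
  }
  res <- orfs[sort(rep_rows), , drop = FALSE]
  rownames(res) <- NULL
  list(unique = res, duplicate_groups = dup)
}

#' Premature-termination-codon scan of the host reading frame
#'
#' Translates each host CDS in its own (+1) frame under the standard code,
#' reports the leftmost stop codon (the premature termination codon a
#' cytosolic ribosome would hit), and then looks for ATG codons on the +1
#' grid strictly downstream of that stop, recording the longest ATG-initiated
#' ORF they could start (stop-terminated, or running to the sequence end).
#'
#' @param records A data.frame with `id`/`seq` columns or named sequences.
#' @param min_downstream_codons Threshold (strictly exceeded) for flagging a
#'   downstream ORF as long. Default 50.
#' @param code Genetic code used for the scan; the standard code by default.
#' @return A data.frame with columns `host_id`, `first_stop_start`,
#'   `first_stop_end`, `first_stop_codon`, `longest_downstream_orf_codons`,
#'   `downstream_long_orf`.
#' @export
ptc_scan <- function(records, min_downstream_codons = 50L, code = genetic_code(1L)) {
  records <- as_cds_records(records)
  n <- nrow(records)
  out <- data.frame(host_id = records$id,
                    first_stop_start = NA_integer_, first_stop_end = NA_integer_,
                    first_stop_codon = NA_character_,
                    longest_downstream_orf_codons = 0L,
                    downstream_long_orf = FALSE, stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    seq <- records$seq[i]
    check_dna(seq, paste0("sequence '", records$id[i], "'"))
    codons <- frame_codons(seq, 1L)
    n_cod <- length(codons)
    stops <- which(codons %in% code$stop_codons)
    from <- 1L
    if (length(stops)) {
      s1 <- stops[1L]
      out$first_stop_start[i] <- 3L * s1 - 2L
      out$first_stop_end[i] <- 3L * s1
      out$first_stop_codon[i] <- codons[s1]
      from <- s1 + 1L
    }
    atg <- which(codons == "ATG")
    atg <- atg[atg >= from]
    longest <- 0L
    for (a in atg) {
      nxt <- stops[stops > a]
      len <- if (length(nxt)) nxt[1L] - a else n_cod - a + 1L
      if (len > longest) longest <- len
    }
    out$longest_downstream_orf_codons[i] <- longest
    out$downstream_long_orf[i] <- longest > min_downstream_codons
  }
  out
}
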