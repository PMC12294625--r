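#' Read CDS records from a FASTA file
#'
#' Headers are parsed as `accession [species] [group]` on whitespace; a
#' sidecar metadata TSV (columns `id`, `species`, `group`) overrides header
#' tokens when supplied. Sequences are uppercased and `U` is normalized to
#' `T`. With `clean = TRUE` (the default) records containing any remaining
#' non-ACGT base are dropped, and the number of removals is reported via
#' `message()` — this mirrors the ambiguity filter applied to GenBank
#' downloads before screening.
#'
#' @param path FASTA file (wrapped or unwrapped, multi-record).
#' @param metadata Optional path to a TSV with columns `id`, `species`,
#'   `group`.
#' @param clean Drop records with ambiguous bases? If `FALSE`, such records
#'   are kept verbatim and downstream functions will reject them.
#' @return A data.frame with columns `id`, `species`, `group`, `seq`. The
#'   number of dropped records is attached as attribute `n_removed`.
#' @export
read_cds_fasta <- function(path, metadata = NULL, clean = TRUE) {
  ss <- Biostrings::readBStringSet(path)
  if (!length(ss)) stop("empty FASTA file: ", path)
  headers <- names(ss)
  toks <- strsplit(trimws(headers), "\\s+")
  ## header convention: "accession species group"; trailing tokens ignored
  id <- vapply(toks, `[`, "", 1L)
  species <- vapply(toks, `[`, "", 2L)
  group <- vapply(toks, `[`, "", 3L)
  if (anyDuplicated(id)) {
    stop("duplicate FASTA ids: ", paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  seqs <- normalize_dna(as.character(ss))
  rec <- data.frame(id = id, species = species, group = group, seq = unname(seqs),
                    stringsAsFactors = FALSE)
  if (!is.null(metadata)) {
    md <- utils::read.delim(metadata, stringsAsFactors = FALSE)
    m <- match(rec$id, md$id)
    for (col in intersect(c("species", "group", "family", "genus"), names(md))) {
      rec[[col]] <- md[[col]][m]
    }
  }
  n_removed <- 0L
  if (clean) {
    ok <- !grepl("[^ACGT]", rec$seq)
    n_removed <- sum(!ok)
    if (n_removed > 0L) {
      message(sprintf("read_cds_fasta: removed %d record(s) with ambiguous (non-ACGT) bases", n_removed))
      rec <- rec[ok, , drop = FALSE]
      rownames(rec) <- NULL
    }
    if (!nrow(rec)) stop("no records left after removing ambiguous sequences")
  }
  attr(rec, "n_removed") <- n_removed
  rec
}

#' Write CDS records to FASTA
#'
#' @param records A data.frame as returned by [read_cds_fasta()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_cds_fasta <- function(records, path) {
  stopifnot(all(c("id", "seq") %in% names(records)))
  hdr <- records$id
  if (!is.null(records$species)) {
    extra <- ifelse(is.na(records$species), "", paste0(" ", records$species))
    if (!is.null(records$group)) {
      extra <- paste0(extra, ifelse(is.na(records$group), "", paste0(" ", records$group)))
    }
    hdr <- paste0(hdr, extra)
  }
  ss <- Biostrings::BStringSet(stats::setNames(records$seq, hdr))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Construct a codon-usage table
#'
#' The package's in-memory representation of a species-level codon usage
#' table for a gene set (nuclear or mitochondrial). Counts are stored over
#' all 64 codons; codons absent from the input are filled with zero.
#'
#' @param counts Named numeric vector of codon counts (DNA alphabet; RNA
#'   codons are normalized). Missing codons are zero-filled.
#' @param gene_set `"nuclear"`, `"mitochondrial"`, or `NA`.
#' @param n_cds Number of coding sequences behind the table (metadata).
#' @param avg_cds_len_codons Average CDS length in codons (metadata).
#' @param species Species label.
#' @return An object of class `codon_usage_table`.
#' @export
codon_usage_table <- function(counts, gene_set = NA_character_, n_cds = NA_real_,
                              avg_cds_len_codons = NA_real_, species = NA_character_) {
  if (is.null(names(counts))) stop("counts must be a named vector of codons")
  names(counts) <- normalize_dna(names(counts))
  unknown <- setdiff(names(counts), CODONS)
  if (length(unknown)) stop("unknown codon token(s): ", paste(unknown, collapse = ", "))
  if (any(counts < 0)) stop("codon counts must be non-negative")
  full <- stats::setNames(numeric(64L), CODONS)
  full[names(counts)] <- as.numeric(counts)
  if (sum(full) <= 0) stop("codon usage table has no positive counts")
  if (length(counts) < 64L) {
    warning(sprintf("codon table missing %d codon(s); filled with zeros",
                    64L - length(counts)))
  }
  structure(
    list(codon_counts = full, gene_set = gene_set, n_cds = as.numeric(n_cds),
         avg_cds_len_codons = as.numeric(avg_cds_len_codons), species = species),
    class = "codon_usage_table"
  )
}

#' @export
print.codon_usage_table <- function(x, ...) {
  cat(sprintf("<codon_usage_table> %s / %s: %s codons from %s CDSs (avg %s codons)\n",
              x$species, x$gene_set, format(sum(x$codon_counts)),
              format(x$n_cds), format(x$avg_cds_len_codons)))
  invisible(x)
}

#' Read a codon-usage table
#'
#' Three dialects are supported:
#' * `canonical_tsv` — the package interchange format: `#`-prefixed metadata
#'   lines (`# species:`, `# gene_set:`, `# n_cds:`, `# avg_cds_len_codons:`)
#'   followed by two tab-separated columns `codon<TAB>count`.
#' * `cocoputs_tsv` — a one-row TSV export with one column per codon plus
#'   metadata columns (`Species`, `# CDS`, `# Codons`).
#' * `kazusa_text` — the classic Kazusa block layout of tokens like
#'   `UUU 17.6( 714298)`; the parenthesized integer is taken as the count.
#'
#' RNA codons are normalized to DNA; missing codons are zero-filled with a
#' warning.
#'
#' @param path Input file.
#' @param dialect One of `"canonical_tsv"`, `"cocoputs_tsv"`, `"kazusa_text"`.
#' @param gene_set,species Metadata overrides for dialects that do not carry
#'   them in-file.
#' @return A [codon_usage_table()].
#' @export
read_codon_table <- function(path,
                             dialect = c("canonical_tsv", "cocoputs_tsv", "kazusa_text"),
                             gene_set = NULL, species = NULL) {
  dialect <- match.arg(dialect)
  tab <- switch(dialect,
    canonical_tsv = .read_canonical_tsv(path),
    cocoputs_tsv = .read_cocoputs_tsv(path),
    kazusa_text = .read_kazusa_text(path)
  )
  if (!is.null(gene_set)) tab$gene_set <- gene_set
  if (!is.null(species)) tab$species <- species
  tab
}

.read_canonical_tsv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ml in meta_lines) {
    kv <- sub("^#\\s*", "", ml)
    key <- trimws(sub(":.*$", "", kv))
    val <- trimws(sub("^[^:]*:", "", kv))
    meta[[key]] <- val
  }
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  parts <- strsplit(body, "\t", fixed = TRUE)
  codons <- vapply(parts, `[`, "", 1L)
  counts <- as.numeric(vapply(parts, `[`, "", 2L))
  if (anyNA(counts)) stop("malformed count in canonical codon TSV: ", path)
  codon_usage_table(
    stats::setNames(counts, codons),
    gene_set = if (!is.null(meta$gene_set)) meta$gene_set else NA_character_,
    n_cds = if (!is.null(meta$n_cds)) as.numeric(meta$n_cds) else NA_real_,
    avg_cds_len_codons = if (!is.null(meta$avg_cds_len_codons)) as.numeric(meta$avg_cds_len_codons) else NA_real_,
    species = if (!is.null(meta$species)) meta$species else NA_character_
  )
}

.read_cocoputs_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) < 1L) stop("empty CoCoPUTs-style table: ", path)
  row <- df[1L, , drop = FALSE]
  cods <- names(row)[normalize_dna(names(row)) %in% CODONS]
  if (!length(cods)) stop("no codon columns found in ", path)
  counts <- stats::setNames(as.numeric(row[1L, cods]), normalize_dna(cods))
  n_cds <- if ("# CDS" %in% names(row)) as.numeric(row[["# CDS"]]) else NA_real_
  n_codons <- if ("# Codons" %in% names(row)) as.numeric(row[["# Codons"]]) else sum(counts)
  codon_usage_table(
    counts,
    n_cds = n_cds,
    avg_cds_len_codons = if (!is.na(n_cds) && n_cds > 0) n_codons / n_cds else NA_real_,
    species = if ("Species" %in% names(row)) row[["Species"]] else NA_character_
  )
}

.read_kazusa_text <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = " ")
  m <- gregexpr("([ACGTUacgtu]{3})\\s+[0-9.]+\\s*\\(\\s*([0-9]+)\\s*\\)", txt)
  hits <- regmatches(txt, m)[[1L]]
  if (!length(hits)) stop("no Kazusa-style codon entries found in ", path)
  codons <- normalize_dna(sub("^([ACGTUacgtu]{3}).*$", "\\1", hits))
  counts <- as.numeric(sub("^.*\\(\\s*([0-9]+)\\s*\\)$", "\\1", hits))
  codon_usage_table(stats::setNames(counts, codons))
}

#' Write a codon-usage table in the canonical TSV dialect
#'
#' @param table A [codon_usage_table()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_codon_table <- function(table, path) {
  stopifnot(inherits(table, "codon_usage_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# species: ", table$species),
    paste0("# gene_set: ", table$gene_set),
    paste0("# n_cds: ", format(table$n_cds, scientific = FALSE)),
    paste0("# avg_cds_len_codons: ", format(table$avg_cds_len_codons, scientific = FALSE))
  ), con)
  writeLines(paste(CODONS, format(table$codon_counts, scientific = FALSE, trim = TRUE),
                   sep = "\t"), con)
  invisible(path)
}

#' Is a reference codon-usage table robust enough to use?
#'
#' A nuclear reference table qualifies when it was built from at least
#' `min_cds` coding sequences whose average length strictly exceeds
#' `min_avg_len` codons. Missing metadata yields `NA` (indeterminate), never
#' a silent `TRUE`.
#'
#' @param table A [codon_usage_table()].
#' @param min_cds Minimum number of CDSs (inclusive). Default 30.
#' @param min_avg_len Average CDS length threshold in codons (strictly
#'   exceeded). Default 100.
#' @return `TRUE`, `FALSE`, or `NA` when metadata is missing.
#' @export
table_is_robust <- function(table, min_cds = 30, min_avg_len = 100) {
  stopifnot(inherits(table, "codon_usage_table"))
  if (is.na(table$n_cds) || is.na(table$avg_cds_len_codons)) return(NA)
  table$n_cds >= min_cds && table$avg_cds_len_codons > min_avg_len
}
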