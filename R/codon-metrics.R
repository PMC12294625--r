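#' Count codons of an in-frame coding sequence
#'
#' @param seq Nucleotide string whose length is divisible by 3 (the frame is
#'   resolved by the caller). Stop codons are counted here; metric functions
#'   exclude them as appropriate.
#' @param source_id Optional label attached as an attribute.
#' @return Named integer vector over all 64 codons.
#' @export
codon_counts <- function(seq, source_id = NULL) {
  seq <- normalize_dna(seq)
  check_dna(seq)
  if (nchar(seq) %% 3L != 0L) {
    stop("sequence length (", nchar(seq), ") is not divisible by 3")
  }
  codons <- frame_codons(seq, 1L)
  counts <- table(factor(codons, levels = CODONS))
  out <- stats::setNames(as.integer(counts), CODONS)
  attr(out, "source_id") <- source_id
  out
}

## Coerce counts input for RSCU/adaptation functions: codon_usage_table,
## named numeric vector, or in-frame sequence string.
as_codon_count_vector <- function(x) {
  if (inherits(x, "codon_usage_table")) return(x$codon_counts)
  if (is.character(x) && length(x) == 1L) {
    cc <- codon_counts(x)
    return(stats::setNames(as.numeric(cc), names(cc)))
  }
  if (is.numeric(x)) {
    if (is.null(names(x))) stop("codon counts must be named by codon")
    full <- stats::setNames(numeric(64L), CODONS)
    nm <- normalize_dna(names(x))
    unknown <- setdiff(nm, CODONS)
    if (length(unknown)) stop("unknown codon(s): ", paste(unknown, collapse = ", "))
    full[nm] <- as.numeric(x)
    return(full)
  }
  stop("cannot interpret object of class ", paste(class(x), collapse = "/"),
       " as codon counts")
}

#' Synonymous-codon families of a genetic code
#'
#' @param code_basis Translation table id defining the families (default 1).
#' @param min_size Keep only families with at least this many codons.
#' @return Named list (by amino acid) of codon character vectors; stop
#'   codons are never included.
#' @export
codon_families <- function(code_basis = 1L, min_size = 1L) {
  code <- genetic_code(code_basis)
  aa <- code$codon_to_aa
  sense <- names(aa)[aa != "*"]
  fams <- split(sense, aa[sense])
  fams[lengths(fams) >= min_size]
}

#' Default included codon set for RSCU and CAI
#'
#' All sense codons of the basis code belonging to synonymous families of
#' size at least two. Under the standard code this is the conventional
#' 59-codon set: the 61 sense codons minus ATG (Met) and TGG (Trp), whose
#' single-codon families carry no usage information.
#'
#' @inheritParams codon_families
#' @return Character vector of codons, in canonical order.
#' @export
included_codons <- function(code_basis = 1L) {
  fams <- codon_families(code_basis, min_size = 2L)
  intersect(CODONS, unlist(fams, use.names = FALSE))
}

#' Relative synonymous codon usage (RSCU)
#'
#' For codon `c` in synonymous family `F(c)`,
#' `RSCU_c = n_c * |F(c)| / sum(n_{c'} for c' in F(c))`: the observed count
#' divided by the mean count of the family. Unbiased usage gives RSCU 1 for
#' every codon. Families with zero total count receive the neutral value 1
#' for all members and are flagged (with a warning), rather than NaN.
#'
#' @param x A [codon_usage_table()], a named codon-count vector (e.g. from
#'   [codon_counts()]), or an in-frame nucleotide string.
#' @param code_basis Translation table defining synonym families. The
#'   default (table 1) is used for every vector, including mitochondrial
#'   reference tables, so that gene and reference vectors remain
#'   commensurable; pass 2 for a sensitivity analysis under mitochondrial
#'   families.
#' @param included Codon subset to report (default [included_codons()]).
#' @return An object of class `rscu_vector`: list with `values` (named
#'   numeric over `included`), `code_basis`, `included`, `zero_families`.
#' @examples
#' rscu(c(TTT = 3, TTC = 1))$values[c("TTT", "TTC")]  # 1.5, 0.5
#' @export
rscu <- function(x, code_basis = 1L, included = NULL) {
  if (is.character(x) && length(x) == 1L) x <- codon_counts(x)
  counts <- as_codon_count_vector(x)
  fams <- codon_families(code_basis, min_size = 1L)
  if (is.null(included)) {
    included <- included_codons(code_basis)
  } else {
    included <- normalize_dna(included)
    sense <- unlist(fams, use.names = FALSE)
    if (!all(included %in% sense)) {
      stop("included codons must be sense codons of the basis code")
    }
    included <- intersect(CODONS, included)
  }
  values <- stats::setNames(numeric(64L), CODONS)
  zero_fams <- character(0)
  for (aa in names(fams)) {
    fam <- fams[[aa]]
    tot <- sum(counts[fam])
    if (tot > 0) {
      values[fam] <- counts[fam] * length(fam) / tot
    } else {
      values[fam] <- 1
      zero_fams <- c(zero_fams, aa)
    }
  }
  zero_fams <- intersect(zero_fams,
                         names(fams)[vapply(fams, function(f) any(f %in% included), TRUE)])
  if (length(zero_fams)) {
    warning("zero-count synonym families set to neutral RSCU 1: ",
            paste(zero_fams, collapse = ", "))
  }
  structure(list(values = values[included], code_basis = as.integer(code_basis),
                 included = included, zero_families = zero_fams),
            class = "rscu_vector")
}

#' @export
print.rscu_vector <- function(x, ...) {
  cat(sprintf("<rscu_vector> %d codons (basis table %d)%s\n",
              length(x$included), x$code_basis,
              if (length(x$zero_families))
                paste0("; neutral families: ", paste(x$zero_families, collapse = ","))
              else ""))
  print(round(x$values, 3))
  invisible(x)
}
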