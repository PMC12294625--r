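#' Cosine similarity of two codon-usage vectors
#'
#' `R(A, B) = sum(a*b) / (||a|| * ||b||)`, in `[-1, 1]` (and `[0, 1]` for
#' non-negative RSCU vectors). Both arguments must be over the same included
#' codon set and ordering.
#'
#' @param a,b [rscu()] vectors, or plain numeric vectors of equal length
#'   (names, when present, must match).
#' @return Cosine similarity.
#' @export
cosine_similarity <- function(a, b) {
  if (inherits(a, "rscu_vector") && inherits(b, "rscu_vector")) {
    if (!identical(a$included, b$included)) {
      stop("mismatched codon sets between RSCU vectors")
    }
    a <- a$values
    b <- b$values
  }
  a <- as.numeric(a)
  b <- as.numeric(b)
  if (length(a) != length(b)) stop("vectors differ in length")
  na <- sqrt(sum(a^2))
  nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("cosine similarity undefined for a zero vector")
  sum(a * b) / (na * nb)
}

#' Cosine dissimilarity D(A, B) = (1 - R(A, B)) / 2
#'
#' Reported for reference only; the cosine similarity itself is the
#' recommended comparison statistic.
#'
#' @inheritParams cosine_similarity
#' @return Value in `[0, 1]`.
#' @export
cosine_dissimilarity <- function(a, b) {
  (1 - cosine_similarity(a, b)) / 2
}

#' Per-species codon-usage similarity table
#'
#' For every nested ORF whose species has a robust nuclear reference table
#' and a mitochondrial reference table, computes four RSCU cosine
#' similarities: nested ORF and host CDS, each against the nuclear and the
#' mitochondrial reference set. The robustness filter
#' ([table_is_robust()]) is applied to nuclear tables only; mitochondrial
#' gene sets are small by nature and need only be present. Skipped species
#' are recorded in the `skipped` attribute.
#'
#' @param orfs Nested-ORF data.frame (after de-duplication), columns
#'   `host_id`, `nt_seq`.
#' @param records Host CDS records with `id`, `species`, `seq`.
#' @param nuclear_tables,mito_tables Named lists of [codon_usage_table()]s,
#'   keyed by species.
#' @param min_cds,min_avg_len Robustness thresholds for nuclear tables.
#' @return Data.frame with columns `species`, `host_id`,
#'   `sim_ncytb_nuclear`, `sim_ncytb_mito`, `sim_cytb_nuclear`,
#'   `sim_cytb_mito`; skipped species in `attr(, "skipped")`.
#' @export
build_similarity_table <- function(orfs, records, nuclear_tables, mito_tables,
                                   min_cds = 30, min_avg_len = 100) {
  records <- as_cds_records(records)
  rows <- list()
  skipped <- list()
  for (i in seq_len(nrow(orfs))) {
    host_id <- orfs$host_id[i]
    m <- match(host_id, records$id)
    if (is.na(m)) stop("host_id missing from records: ", host_id)
    species <- records$species[m]
    nt <- nuclear_tables[[species]]
    mt <- mito_tables[[species]]
    if (is.null(nt) || !isTRUE(table_is_robust(nt, min_cds, min_avg_len))) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(species = species, host_id = host_id,
                   reason = if (is.null(nt)) "no_nuclear_table" else "nuclear_table_not_robust")
      next
    }
    if (is.null(mt)) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(species = species, host_id = host_id, reason = "no_mito_table")
      next
    }
    trim3 <- function(s) substr(s, 1L, 3L * (nchar(s) %/% 3L))
    r_orf <- rscu(codon_counts(trim3(orfs$nt_seq[i])))
    r_host <- rscu(codon_counts(trim3(records$seq[m])))
    r_nuc <- rscu(nt)
    r_mit <- rscu(mt)
    rows[[length(rows) + 1L]] <- data.frame(
      species = species, host_id = host_id,
      sim_ncytb_nuclear = cosine_similarity(r_orf, r_nuc),
      sim_ncytb_mito = cosine_similarity(r_orf, r_mit),
      sim_cytb_nuclear = cosine_similarity(r_host, r_nuc),
      sim_cytb_mito = cosine_similarity(r_host, r_mit),
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(species = character(0), host_id = character(0),
               sim_ncytb_nuclear = numeric(0), sim_ncytb_mito = numeric(0),
               sim_cytb_nuclear = numeric(0), sim_cytb_mito = numeric(0))
  rownames(out) <- NULL
  attr(out, "skipped") <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(species = character(0), host_id = character(0), reason = character(0))
  out
}

#' Paired Wilcoxon signed-rank test
#'
#' Zero differences are dropped (signed-rank convention). The exact null
#' distribution is used whenever the effective sample size is at most 25
#' and the absolute differences carry no ties; otherwise the normal
#' approximation with continuity and tie correction applies.
#'
#' @param x,y Paired numeric vectors of equal length. Alternatively `y` may
#'   be omitted and `x` taken as the differences.
#' @param alternative `"greater"` (x tends to exceed y), `"less"`, or
#'   `"two.sided"`.
#' @param comparison Optional label carried into the result.
#' @return One-row data.frame: `comparison`, `n` (effective pairs),
#'   `statistic` (V), `p_value`, `alternative`, `method`.
#' @examples
#' # 12 uniformly positive differences: one-tailed p = 1/4096
#' wilcoxon_signed_rank(1:12 + 10, 1:12, alternative = "greater")$p_value
#' @export
wilcoxon_signed_rank <- function(x, y = NULL,
                                 alternative = c("greater", "less", "two.sided"),
                                 comparison = NA_character_) {
  alternative <- match.arg(alternative)
  d <- if (is.null(y)) as.numeric(x) else {
    if (length(x) != length(y)) stop("x and y must be paired (equal length)")
    as.numeric(x) - as.numeric(y)
  }
  d <- d[d != 0]
  if (!length(d)) stop("all differences are zero; signed-rank test undefined")
  n <- length(d)
  ties <- any(duplicated(abs(d)))
  exact <- n <= 25L && !ties
  ht <- suppressWarnings(stats::wilcox.test(d, alternative = alternative,
                                            exact = exact, correct = TRUE))
  data.frame(comparison = comparison, n = n,
             statistic = unname(ht$statistic), p_value = ht$p.value,
             alternative = alternative,
             method = if (exact) "exact" else "normal_approx",
             stringsAsFactors = FALSE)
}

#' Spearman rank correlation
#'
#' Rho is the Pearson correlation of the (average-tie) ranks; the p-value
#' uses the t approximation.
#'
#' @param x,y Numeric vectors of equal length, at least 3 values.
#' @return List with `rho`, `p_value`, `n`.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant input vector")
  ht <- suppressWarnings(stats::cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ht$estimate), p_value = ht$p.value, n = length(x))
}

## Default similar-residue groups (conservative substitution classes).
SIMILAR_GROUPS <- c("GAVLI", "FYW", "CM", "ST", "KRH", "DENQ", "P")

#' Pairwise identity and similarity of two aligned protein sequences
#'
#' Columns where both sequences carry a gap are ignored. Identity counts
#' columns with identical residues; similarity additionally counts columns
#' whose residues fall in the same substitution group. Both are percentages
#' of the columns holding at least one residue, so a column aligned against
#' a gap counts against both scores.
#'
#' @param aligned_a,aligned_b Gapped amino-acid strings of equal length
#'   (`-` for gaps).
#' @param similar_groups Character vector of residue groups.
#' @return Named numeric `c(identity=, similarity=)` in percent.
#' @examples
#' pairwise_identity_similarity("KR", "RK")  # identity 0, similarity 100
#' @export
pairwise_identity_similarity <- function(aligned_a, aligned_b,
                                         similar_groups = SIMILAR_GROUPS) {
  if (nchar(aligned_a) != nchar(aligned_b)) {
    stop("aligned sequences differ in length")
  }
  a <- strsplit(toupper(aligned_a), "")[[1L]]
  b <- strsplit(toupper(aligned_b), "")[[1L]]
  grp <- integer(0)
  for (g in seq_along(similar_groups)) {
    letters_g <- strsplit(similar_groups[g], "")[[1L]]
    grp[letters_g] <- g
  }
  keep <- !(a == "-" & b == "-")
  a <- a[keep]
  b <- b[keep]
  if (!length(a)) stop("alignment has no residue-bearing columns")
  both <- a != "-" & b != "-"
  ident <- both & a == b
  ga <- grp[a]
  gb <- grp[b]
  simil <- ident | (both & !is.na(ga) & !is.na(gb) & ga == gb)
  c(identity = 100 * sum(ident) / length(a),
    similarity = 100 * sum(simil) / length(a))
}
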