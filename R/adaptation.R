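## Run code with a temporarily fixed RNG state when seed is given; the
## caller's RNG stream is restored afterwards.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Relative adaptiveness weights from a reference codon-usage table
#'
#' Within each synonymous family the weight of a codon is its count divided
#' by the count of the family's most frequent codon, so the preferred codon
#' gets weight 1. Zero-count codons receive a 0.5 pseudocount before
#' normalization, keeping every weight strictly positive. Stop codons and
#' the single-codon families (ATG, TGG under the standard code) are
#' excluded: their weights would always be 1 and only dilute the index.
#'
#' @param ref A [codon_usage_table()] or named codon-count vector with a
#'   positive total.
#' @param code_basis Translation table defining families (default 1).
#' @return Object of class `relative_adaptiveness`: list with `w` (named
#'   weights over the included codons), `reference_id`, `excluded`.
#' @export
relative_adaptiveness <- function(ref, code_basis = 1L) {
  counts <- as_codon_count_vector(ref)
  if (sum(counts) <= 0) stop("reference table has no positive counts")
  fams <- codon_families(code_basis, min_size = 2L)
  included <- included_codons(code_basis)
  w <- stats::setNames(numeric(64L), CODONS)
  for (fam in fams) {
    n <- counts[fam]
    n[n == 0] <- 0.5
    w[fam] <- n / max(n)
  }
  structure(
    list(w = w[included],
         reference_id = if (inherits(ref, "codon_usage_table")) ref$species else NA_character_,
         excluded = setdiff(CODONS, included),
         code_basis = as.integer(code_basis)),
    class = "relative_adaptiveness"
  )
}

#' Codon adaptation index (CAI)
#'
#' Geometric mean of the relative adaptiveness weights of a gene's codons,
#' taken over the codons in the weight set (stops and single-codon families
#' excluded). Ranges in (0, 1]; 1 means every codon is the
#' reference-preferred one.
#'
#' @param seq In-frame nucleotide string (length divisible by 3), or a named
#'   codon-count vector.
#' @param w A [relative_adaptiveness()] object (or a reference table, which
#'   is converted).
#' @return CAI value in (0, 1].
#' @export
cai <- function(seq, w) {
  if (!inherits(w, "relative_adaptiveness")) w <- relative_adaptiveness(w)
  counts <- if (is.character(seq)) codon_counts(seq) else as_codon_count_vector(seq)
  n <- counts[names(w$w)]
  L <- sum(n)
  if (L == 0) stop("sequence contains no codons outside the excluded set")
  exp(sum(n * log(w$w)) / L)
}

#' Generate one composition-matched mock coding sequence
#'
#' Builds an in-frame sequence with exactly the requested amino-acid
#' composition, sampling each amino acid's codon from its synonymous family
#' with probability proportional to the product of the supplied per-base
#' frequencies over the codon's three positions (renormalized within the
#' family). This is the null model behind eCAI/eRCDI: amino-acid bias is
#' preserved exactly and base bias approximately.
#'
#' @param aa_profile Character vector of single-letter amino acids (repeats
#'   allowed; order irrelevant), or a named count vector/table.
#' @param base_freqs Named numeric `c(A=,C=,G=,T=)` summing to 1.
#' @param code_basis Translation table supplying the families.
#' @return Nucleotide string of length `3 * sum(profile)`.
#' @export
generate_mock <- function(aa_profile, base_freqs, code_basis = 1L) {
  if (is.table(aa_profile) || !is.null(names(aa_profile))) {
    prof <- stats::setNames(as.integer(aa_profile), names(aa_profile))
  } else {
    tb <- table(aa_profile)
    prof <- stats::setNames(as.integer(tb), names(tb))
  }
  prof <- prof[prof > 0L]
  names(base_freqs) <- normalize_dna(names(base_freqs))
  if (!all(c("A", "C", "G", "T") %in% names(base_freqs)) ||
      abs(sum(base_freqs) - 1) > 1e-8 || any(base_freqs < 0)) {
    stop("base_freqs must be named A/C/G/T probabilities summing to 1")
  }
  fams <- codon_families(code_basis, min_size = 1L)
  bad <- setdiff(names(prof), names(fams))
  if (length(bad)) stop("amino acid(s) with no codon under this code: ",
                        paste(bad, collapse = ", "))
  pieces <- character(0)
  for (aa in names(prof)) {
    fam <- fams[[aa]]
    p <- vapply(strsplit(fam, ""), function(b) prod(base_freqs[b]), 0)
    if (sum(p) <= 0) {
      stop("base frequencies give zero probability to every codon of ", aa)
    }
    pieces <- c(pieces, sample(fam, prof[[aa]], replace = TRUE, prob = p))
  }
  paste(pieces, collapse = "")
}

## Amino-acid profile and mononucleotide frequencies of a query sequence;
## stops are dropped from the profile (mocks model the coding residues).
.query_composition <- function(seq, code_basis) {
  seq <- normalize_dna(seq)
  aa <- strsplit(translate_dna(seq, genetic_code(code_basis), 1L), "")[[1L]]
  aa <- aa[aa != "*"]
  if (!length(aa)) stop("sequence encodes no amino acids")
  chars <- strsplit(seq, "")[[1L]]
  bf <- table(factor(chars, levels = c("A", "C", "G", "T")))
  list(profile = aa, base_freqs = stats::setNames(as.numeric(bf) / sum(bf), names(bf)))
}

.mc_adaptation <- function(statistic, mock_stat_fun, metric, n_random, alpha,
                           method, seed, verdicts) {
  if (n_random < 2) stop("n_random must be >= 2")
  mocks <- with_seed(seed, vapply(seq_len(n_random), function(i) mock_stat_fun(), 0))
  expected <- mean(mocks)
  s <- stats::sd(mocks)
  upper <- if (method == "normal") expected + stats::qnorm(1 - alpha) * s
           else unname(stats::quantile(mocks, 1 - alpha))
  lower <- 2 * expected - upper
  verdict <- if (statistic > upper) verdicts[["above"]]
             else if (statistic < lower) verdicts[["below"]]
             else verdicts[["inside"]]
  structure(
    list(metric = metric, statistic = statistic, expected = expected, sd = s,
         upper = upper, lower = lower, verdict = verdict,
         n_random = as.integer(n_random), alpha = alpha, method = method,
         seed = seed),
    class = "adaptation_result"
  )
}

#' @export
print.adaptation_result <- function(x, ...) {
  cat(sprintf("<adaptation_result> %s = %.4f; expected %.4f [%.4f, %.4f] (n_random = %d, %s) -> %s\n",
              x$metric, x$statistic, x$expected, x$lower, x$upper,
              x$n_random, x$method, x$verdict))
  invisible(x)
}

#' CAI with Monte-Carlo expected value (eCAI)
#'
#' Computes the query's CAI against a reference table, then simulates
#' `n_random` mock sequences preserving the query's amino-acid composition
#' exactly and its global mononucleotide frequencies approximately, and
#' derives the expected CAI with a one-sided 95% limit. The lower limit is
#' `2 * expected - upper` (the upper limit reflected about the mean). A CAI
#' above the upper limit indicates positive adaptation to the reference,
#' below the lower limit negative adaptation, and anything inside the
#' interval is statistically indistinguishable from composition-matched
#' random sequences.
#'
#' @param seq In-frame nucleotide string.
#' @param ref Reference [codon_usage_table()] (or counts) for the weights.
#' @param n_random Number of mock sequences (default 500).
#' @param alpha One-sided significance level (default 0.05; the normal
#'   method uses `z = qnorm(1 - alpha) = 1.6449` at the default).
#' @param method `"normal"` (mean + z * sd) or `"percentile"` (empirical
#'   quantile of the mock CAIs).
#' @param seed Optional integer; fixes the mock ensemble reproducibly
#'   without disturbing the caller's RNG stream.
#' @return An `adaptation_result` with verdict one of
#'   `"positive_adaptation"`, `"negative_adaptation"`,
#'   `"indistinguishable"`.
#' @export
ecai <- function(seq, ref, n_random = 500L, alpha = 0.05,
                 method = c("normal", "percentile"), seed = NULL) {
  method <- match.arg(method)
  w <- relative_adaptiveness(ref)
  statistic <- cai(seq, w)
  comp <- .query_composition(seq, code_basis = 1L)
  .mc_adaptation(
    statistic,
    function() cai(generate_mock(comp$profile, comp$base_freqs), w),
    metric = "CAI", n_random = n_random, alpha = alpha, method = method,
    seed = seed,
    verdicts = c(above = "positive_adaptation", below = "negative_adaptation",
                 inside = "indistinguishable")
  )
}

#' Relative codon deoptimization index (RCDI)
#'
#' Compares the within-amino-acid codon frequencies of a query gene with a
#' reference gene set:
#' `RCDI = (1/N) * sum_c n_c * CiF_q(c) / CiF_r(c)` over the sense codons
#' of the basis code present in the query, where `CiF` is a codon's
#' relative frequency within its synonymous family and `N` the number of
#' counted codons. RCDI is 1 exactly when the query's family frequencies
#' match the reference's, and grows with deoptimization. Reference families
#' containing zero-count codons are smoothed with a 0.5 pseudocount on the
#' zeros.
#'
#' @param seq In-frame nucleotide string (or named codon counts).
#' @param ref Reference [codon_usage_table()] or counts.
#' @param code_basis Translation table defining families (default 1).
#' @return RCDI value `>= 1` (up to floating tolerance).
#' @export
rcdi <- function(seq, ref, code_basis = 1L) {
  q <- if (is.character(seq)) codon_counts(seq) else as_codon_count_vector(seq)
  r <- as_codon_count_vector(ref)
  fams <- codon_families(code_basis, min_size = 1L)
  acc <- 0
  N <- 0
  for (fam in fams) {
    nq <- q[fam]
    tq <- sum(nq)
    if (tq == 0) next
    nr <- r[fam]
    if (any(nr == 0)) nr[nr == 0] <- 0.5
    fr <- nr / sum(nr)
    fq <- nq / tq
    acc <- acc + sum(nq * fq / fr)
    N <- N + tq
  }
  if (N == 0) stop("sequence contains no sense codons to count")
  acc / N
}

#' RCDI with Monte-Carlo expected value (eRCDI)
#'
#' The null ensemble is the same composition-matched mock model as in
#' [ecai()]. An RCDI above the upper limit marks codon usage significantly
#' more deoptimized than composition alone explains (`"deoptimized"`),
#' below the lower limit significantly closer to the reference than random
#' (`"over_adapted"`), and inside the interval usage explained by amino
#' acid composition and base content (`"composition_driven"`).
#'
#' @inheritParams ecai
#' @return An `adaptation_result`.
#' @export
ercdi <- function(seq, ref, n_random = 500L, alpha = 0.05,
                  method = c("normal", "percentile"), seed = NULL) {
  method <- match.arg(method)
  statistic <- rcdi(seq, ref)
  comp <- .query_composition(seq, code_basis = 1L)
  .mc_adaptation(
    statistic,
    function() rcdi(generate_mock(comp$profile, comp$base_freqs), ref),
    metric = "RCDI", n_random = n_random, alpha = alpha, method = method,
    seed = seed,
    verdicts = c(above = "deoptimized", below = "over_adapted",
                 inside = "composition_driven")
  )
}
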