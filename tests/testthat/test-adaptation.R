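ref_counts <- function(...) {
  x <- c(...)
  full <- stats::setNames(numeric(64), naltorf:::CODONS)
  full[names(x)] <- x
  full
}

test_that("relative adaptiveness normalizes within families with 0.5 pseudocounts", {
  w <- relative_adaptiveness(ref_counts(AAA = 80, AAG = 20))
  expect_equal(unname(w$w[c("AAA", "AAG")]), c(1, 0.25))
  w2 <- relative_adaptiveness(ref_counts(AAA = 10, AAG = 0))
  expect_equal(unname(w2$w[c("AAA", "AAG")]), c(1, 0.05))  # 0.5 / 10
  # uniform table: every weight 1
  w3 <- relative_adaptiveness(stats::setNames(rep(5, 64), naltorf:::CODONS))
  expect_true(all(w3$w == 1))
  expect_length(w3$w, 59)
  expect_error(relative_adaptiveness(ref_counts(AAA = 0)), "no positive")
})

test_that("CAI closed forms and log-domain oracle agree", {
  ref <- ref_counts(AAA = 80, AAG = 20, TTT = 90, TTC = 10)
  w <- relative_adaptiveness(ref)
  expect_equal(cai(strrep("AAA", 20), w), 1)
  # alternating preferred / half-preferred codons (w = 1 and 0.5)
  ref2 <- ref_counts(AAA = 80, AAG = 40)
  w2 <- relative_adaptiveness(ref2)
  expect_equal(cai(strrep("AAAAAG", 30), w2), sqrt(0.5), tolerance = 1e-12)
  # random gene vs oracle
  set.seed(60)
  wfull <- relative_adaptiveness(stats::setNames(rpois(64, 40) + 1, naltorf:::CODONS))
  gene <- paste(sample(names(wfull$w), 300, replace = TRUE), collapse = "")
  expect_equal(cai(gene, wfull), oracle_cai(gene, wfull$w), tolerance = 1e-12)
  # monotonicity: swapping in a more-preferred synonym never lowers CAI
  g2 <- sub("AAG", "AAA", strrep("AAG", 10))
  expect_true(cai(g2, w2) >= cai(strrep("AAG", 10), w2))
  expect_error(cai("ATGTGG", w2), "excluded")
})

test_that("generate_mock preserves amino-acid composition and follows base bias", {
  set.seed(61)
  uf <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  mock <- generate_mock(c(K = 5, F = 3, W = 1), uf)
  expect_identical(nchar(mock), 27L)
  aa <- strsplit(translate_dna(mock, genetic_code(1)), "")[[1]]
  expect_identical(sort(table(aa), decreasing = TRUE),
                   sort(table(rep(c("K", "F", "W"), c(5, 3, 1))), decreasing = TRUE),
                   ignore_attr = TRUE)
  # degenerate base law: Lys must always be AAA
  mock2 <- generate_mock(rep("K", 20), c(A = 1, C = 0, G = 0, T = 0))
  expect_identical(mock2, strrep("AAA", 20))
  # impossible family under a degenerate law errors
  expect_error(generate_mock("F", c(A = 1, C = 0, G = 0, T = 0)), "zero probability")
  # GC of the mock population tracks the GC of the base law monotonically
  gc_of <- function(s) mean(strsplit(s, "")[[1]] %in% c("G", "C"))
  prof <- rep(c("A", "L", "R", "G", "P", "S", "T", "V"), 25)
  gcs <- vapply(c(0.2, 0.5, 0.8), function(gc) {
    bf <- c(A = (1 - gc) / 2, T = (1 - gc) / 2, G = gc / 2, C = gc / 2)
    mean(vapply(1:20, function(i) gc_of(generate_mock(prof, bf)), 0))
  }, 0)
  expect_true(all(diff(gcs) > 0))
  # uniform base law makes synonymous codons equiprobable
  draws <- table(substring(paste(replicate(400, generate_mock("K", uf)),
                                 collapse = ""), seq(1, 1198, 3), seq(3, 1200, 3)))
  expect_true(abs(draws[["AAA"]] - draws[["AAG"]]) < 4 * sqrt(400 * 0.25))
})

test_that("eCAI contracts: limits, determinism, degenerate null, verdicts", {
  set.seed(62)
  skewed <- stats::setNames(rpois(64, 10) + 1, naltorf:::CODONS)
  skewed[c("AAA", "TTT", "GGC", "CCC")] <- 400
  gene <- paste(c("ATG", sample(included_codons(1), 150, replace = TRUE)),
                collapse = "")
  r <- ecai(gene, skewed, n_random = 200, seed = 17)
  expect_equal(r$lower, 2 * r$expected - r$upper, tolerance = 1e-15)
  expect_true(r$lower <= r$expected && r$expected <= r$upper)
  # bit-identical reproduction under the same seed
  r2 <- ecai(gene, skewed, n_random = 200, seed = 17)
  expect_identical(r[c("statistic", "expected", "upper", "lower")],
                   r2[c("statistic", "expected", "upper", "lower")])
  # percentile method obeys the same reflection identity
  rp <- ecai(gene, skewed, n_random = 200, method = "percentile", seed = 17)
  expect_equal(rp$lower, 2 * rp$expected - rp$upper, tolerance = 1e-15)
  # alpha -> 0.5 collapses the normal upper limit to the expectation
  r5 <- ecai(gene, skewed, n_random = 200, alpha = 0.5, seed = 17)
  expect_equal(r5$upper, r5$expected, tolerance = 1e-12)
  # degenerate uniform reference: all mock CAIs 1, sd 0, indistinguishable
  unif <- stats::setNames(rep(3, 64), naltorf:::CODONS)
  rd <- ecai(gene, unif, n_random = 100, seed = 1)
  expect_identical(rd$sd, 0)
  expect_identical(c(rd$expected, rd$upper, rd$lower), c(1, 1, 1))
  expect_identical(rd$verdict, "indistinguishable")
  # a fully preferred-codon gene against a skewed reference is positively adapted
  w <- relative_adaptiveness(skewed)
  best <- names(w$w)[w$w == 1]
  gene_best <- paste(sample(best, 200, replace = TRUE), collapse = "")
  rb <- ecai(gene_best, skewed, n_random = 200, seed = 3)
  expect_identical(rb$statistic, 1)
  expect_identical(rb$verdict, "positive_adaptation")
  expect_error(ecai(gene, skewed, n_random = 1), "n_random")
})

test_that("RCDI closed forms, floor at 1, and smoothing", {
  # frequency-matched query: exactly 1
  ref <- ref_counts(AAA = 60, AAG = 20, TTT = 30, TTC = 10)
  q <- paste(c(rep("AAA", 6), rep("AAG", 2), rep("TTT", 3), "TTC"), collapse = "")
  expect_equal(rcdi(q, ref), 1, tolerance = 1e-12)
  # two-codon family (0.8, 0.2), query all codon 1: 1/0.8 = 1.25
  expect_equal(rcdi(strrep("AAA", 10), ref_counts(AAA = 80, AAG = 20)), 1.25)
  # >= 1 on random instances (Cauchy-Schwarz floor)
  set.seed(63)
  for (i in 1:200) {
    qc <- stats::setNames(rpois(64, 5), naltorf:::CODONS)
    rc <- stats::setNames(rpois(64, 5) + 1, naltorf:::CODONS)
    if (sum(qc) == 0) next
    expect_true(rcdi(qc, rc) >= 1 - 1e-12)
  }
  expect_error(rcdi(stats::setNames(numeric(64), naltorf:::CODONS), ref), "no sense codons")
})

test_that("eRCDI verdicts separate composition-driven from deoptimized usage", {
  set.seed(64)
  # reference sharply prefers one codon per family; query uses the rare ones
  pref <- stats::setNames(rep(1, 64), naltorf:::CODONS)
  for (fam in codon_families(1, min_size = 2)) pref[fam[1]] <- 500
  rare <- unlist(lapply(codon_families(1, min_size = 2), function(f) f[length(f)]))
  gene_rare <- paste(sample(rare, 200, replace = TRUE), collapse = "")
  rr <- ercdi(gene_rare, pref, n_random = 200, seed = 5)
  expect_identical(rr$verdict, "deoptimized")
  expect_true(rr$statistic > rr$upper)
  # self-consistent query: one draw from the null ensemble itself (a mock
  # under uniform base frequencies) scored against a uniform reference
  unif <- stats::setNames(rep(10, 64), naltorf:::CODONS)
  prof <- rep(c("A", "L", "R", "S", "V", "P", "T", "G", "K", "F"), 30)
  gene_u <- generate_mock(prof, c(A = 0.25, C = 0.25, G = 0.25, T = 0.25))
  ru <- ercdi(gene_u, unif, n_random = 200, seed = 6)
  expect_identical(ru$verdict, "composition_driven")
  # determinism and the reflection identity
  ru2 <- ercdi(gene_u, unif, n_random = 200, seed = 6)
  expect_identical(ru[c("statistic", "expected", "upper", "lower")],
                   ru2[c("statistic", "expected", "upper", "lower")])
  expect_equal(ru$lower, 2 * ru$expected - ru$upper, tolerance = 1e-15)
})
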