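test_that("scanner finds a constructed frame-2 ORF with exact coordinates", {
  host <- paste0("C", "ATG", strrep("TTT", 150), "TAA", strrep("A", 30))
  orfs <- scan_nested_orfs(c(H = host), min_codons = 150)
  expect_identical(nrow(orfs), 1L)
  expect_identical(orfs$frame, 2L)
  expect_identical(orfs$start_nt, 2L)
  expect_identical(orfs$length_codons, 151L)  # ATG + 150 Phe codons, stop excluded
  expect_identical(orfs$end_nt, 2L + 3L * 152L - 1L)
  expect_match(orfs$nt_seq, "^ATG")
  expect_match(orfs$nt_seq, "TAA$")
  expect_identical(orfs$aa_seq, paste0("M", strrep("F", 150)))
  # poly-A host: no ATG, no ORFs
  expect_identical(nrow(scan_nested_orfs(c(H = strrep("A", 1140)))), 0L)
  expect_error(scan_nested_orfs(c(H = host), min_codons = 0), "min_codons")
  expect_error(scan_nested_orfs(c(H = host), frames = 1L), "subset")
})

test_that("scanner output matches the brute-force enumerator on random sequences", {
  set.seed(310)
  for (i in 1:200) {
    s <- random_dna(sample(300:2000, 1))
    min_c <- sample(c(5L, 10L, 25L), 1)
    got <- scan_nested_orfs(c(S = s), min_codons = min_c)
    want <- oracle_scan(s, min_codons = min_c)
    expect_identical(nrow(got), nrow(want))
    if (nrow(got)) {
      got <- got[order(got$frame, got$start_nt), ]
      expect_equal(got$frame, want$frame, ignore_attr = TRUE)
      expect_equal(got$start_nt, want$start_nt, ignore_attr = TRUE)
      expect_equal(got$end_nt, want$end_nt, ignore_attr = TRUE)
      expect_equal(got$length_codons, want$length_codons, ignore_attr = TRUE)
    }
  }
})

test_that("every reported ORF satisfies its structural invariants", {
  set.seed(311)
  for (i in 1:50) {
    s <- random_dna(sample(600:1500, 1))
    orfs <- scan_nested_orfs(c(S = s), min_codons = 10)
    for (k in seq_len(nrow(orfs))) {
      expect_match(orfs$nt_seq[k], "^ATG")
      expect_true(substr(orfs$nt_seq[k], nchar(orfs$nt_seq[k]) - 2,
                         nchar(orfs$nt_seq[k])) %in% c("TAA", "TAG", "TGA"))
      expect_identical(orfs$length_codons[k], nchar(orfs$aa_seq[k]))
      expect_identical(orfs$length_codons[k],
                       (orfs$end_nt[k] - orfs$start_nt[k] + 1L) %/% 3L - 1L)
      expect_identical((orfs$start_nt[k] - orfs$frame[k]) %% 3L, 0L)
      expect_false(grepl("*", orfs$aa_seq[k], fixed = TRUE))
    }
  }
})

test_that("raising min_codons never adds ORFs (monotonicity)", {
  set.seed(312)
  for (i in 1:20) {
    s <- random_dna(1200)
    lo <- scan_nested_orfs(c(S = s), min_codons = 5)
    hi <- scan_nested_orfs(c(S = s), min_codons = 20)
    expect_true(nrow(hi) <= nrow(lo))
    key <- function(d) paste(d$frame, d$start_nt, d$end_nt)
    expect_true(all(key(hi) %in% key(lo)))
  }
})

test_that("longest_per_frame keeps the longest candidate, ties to smallest start", {
  orfs <- data.frame(
    host_id = "H", frame = c(3L, 3L), start_nt = c(6L, 90L),
    end_nt = c(6L + 3L * 161L - 1L, 90L + 3L * 152L - 1L),
    length_codons = c(160L, 151L), nt_seq = c("a", "b"), aa_seq = c("a", "b"),
    complete = TRUE)
  expect_identical(longest_per_frame(orfs)$length_codons, 160L)
  expect_identical(nrow(longest_per_frame(orfs[0, ])), 0L)
  ties <- data.frame(
    host_id = "H", frame = 3L, start_nt = c(30L, 6L),
    end_nt = c(30L + 482L, 6L + 482L), length_codons = c(160L, 160L),
    nt_seq = c("a", "b"), aa_seq = c("a", "b"), complete = TRUE)
  expect_identical(longest_per_frame(ties)$start_nt, 6L)
  # oracle: enumerate both and pick by (length desc, start asc)
  ord <- ties[order(-ties$length_codons, ties$start_nt), ][1, ]
  expect_identical(longest_per_frame(ties)$start_nt, ord$start_nt)
})

test_that("dedupe consolidates identical nucleotide sequences", {
  mk <- function(host, nt) data.frame(host_id = host, frame = 3L, start_nt = 1L,
                                      end_nt = 3L, length_codons = 1L,
                                      nt_seq = nt, aa_seq = "M", complete = TRUE)
  orfs <- do.call(rbind, c(
    lapply(c("B2", "A1", "C3"), mk, nt = "SHARED"),
    lapply(sprintf("D%02d", 1:28), function(h) mk(h, paste0("U", h)))
  ))
  ded <- dedupe_orfs(orfs)
  expect_identical(nrow(ded$unique), 29L)
  expect_identical(names(ded$duplicate_groups), "A1")
  expect_identical(ded$duplicate_groups$A1, c("A1", "B2", "C3"))
  # all-distinct input is returned unchanged
  all_d <- dedupe_orfs(orfs[4:31, ])
  expect_identical(all_d$unique, { x <- orfs[4:31, ]; rownames(x) <- NULL; x })
  expect_length(all_d$duplicate_groups, 0)
})

test_that("ptc_scan reports first stop span, codon and downstream ORFs", {
  # no frame-1 stop: downstream scan covers the whole sequence
  s_clean <- paste(rep("AAA", 100), collapse = "")
  r <- ptc_scan(c(X = s_clean))
  expect_true(is.na(r$first_stop_start))
  expect_identical(r$longest_downstream_orf_codons, 0L)
  # stop at codon 4; ATG right after with 60 codons then TAA
  s <- paste0("ATGAAAAAA", "TGA", "ATG", strrep("GGG", 60), "TAA", "CCC")
  r2 <- ptc_scan(c(X = s), min_downstream_codons = 50)
  expect_identical(r2$first_stop_start, 10L)
  expect_identical(r2$first_stop_end, 12L)
  expect_identical(r2$first_stop_codon, "TGA")
  expect_identical(r2$longest_downstream_orf_codons, 61L)
  expect_true(r2$downstream_long_orf)
  # verify the downstream length with the translation oracle
  aa <- translate_dna(substr(s, 13, nchar(s)), genetic_code(1))
  expect_identical(as.integer(regexpr("*", substr(aa, 2, nchar(aa)), fixed = TRUE)),
                   r2$longest_downstream_orf_codons)
  # an ATG-initiated ORF running to the sequence end is counted
  s3 <- paste0("AAA", "TAA", "ATG", strrep("CCC", 10))
  r3 <- ptc_scan(c(X = s3), min_downstream_codons = 5)
  expect_identical(r3$longest_downstream_orf_codons, 11L)
  expect_true(r3$downstream_long_orf)
})
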