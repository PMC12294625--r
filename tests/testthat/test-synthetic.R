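test_that("spec validation rejects impossible configurations", {
  expect_error(synthetic_spec(host_len_nt = 1000), "divisible by 3")
  expect_error(synthetic_spec(orf_len_codons = c(400, 400)), "does not fit")
  expect_error(synthetic_spec(orf_frame = 1), "orf_frame")
  expect_error(synthetic_spec(kozak_class = "great"), "kozak_class")
  expect_error(synthetic_spec(n_duplicates = 2), "duplicates require positives")
})

test_that("positive hosts round-trip through scanner, PTC scan and Kozak classifier", {
  spec <- synthetic_spec(n_positive = 12, kozak_class = c("optimal", "strong",
                                                          "adequate", "weak"),
                         seed = 91)
  out <- generate_hosts(spec)
  man <- out$manifest
  expect_identical(nrow(out$records), 12L)
  orfs <- longest_per_frame(scan_nested_orfs(out$records))
  expect_identical(nrow(orfs), 12L)
  m <- match(man$id, orfs$host_id)
  expect_false(anyNA(m))
  expect_identical(orfs$start_nt[m], man$orf_start_nt)
  expect_identical(orfs$end_nt[m], man$orf_end_nt)
  expect_identical(orfs$frame[m], man$orf_frame)
  expect_identical(orfs$length_codons[m], man$orf_len_codons)
  koz <- kozak_contexts(out$records, orfs[m, ])
  expect_identical(koz$strength, man$kozak_class)
  ptc <- ptc_scan(out$records)
  expect_true(all(ptc$first_stop_start == 88L & ptc$first_stop_end == 90L))
  expect_true(all(vapply(out$records$seq, function(s)
    substr(s, 88, 90) == "TGA", TRUE)))
  # hosts are clean mitochondrial CDSs: ATG start, no internal table-2 stop
  for (s in out$records$seq) {
    expect_identical(substr(s, 1, 3), "ATG")
    expect_null(first_stop(s, genetic_code(2), 1))
  }
})

test_that("negative hosts yield no qualifying ORFs; unplanted hosts have no PTC", {
  spec <- synthetic_spec(n_negative = 8, seed = 92)
  out <- generate_hosts(spec)
  expect_identical(nrow(scan_nested_orfs(out$records)), 0L)
  spec2 <- synthetic_spec(n_positive = 2, plant_early_tga = FALSE, seed = 93)
  out2 <- generate_hosts(spec2)
  ptc <- ptc_scan(out2$records)
  expect_true(all(is.na(ptc$first_stop_start)))
})

test_that("duplicates copy sequences and are consolidated downstream", {
  spec <- synthetic_spec(n_positive = 3, n_duplicates = 2, seed = 94)
  out <- generate_hosts(spec)
  expect_identical(nrow(out$records), 5L)
  dup_rows <- out$manifest[!is.na(out$manifest$duplicate_of), ]
  expect_identical(nrow(dup_rows), 2L)
  for (k in seq_len(nrow(dup_rows))) {
    src_seq <- out$records$seq[out$records$id == dup_rows$duplicate_of[k]]
    expect_identical(out$records$seq[out$records$id == dup_rows$id[k]], src_seq)
  }
  ded <- dedupe_orfs(longest_per_frame(scan_nested_orfs(out$records)))
  expect_identical(nrow(ded$unique), 3L)
  expect_length(ded$duplicate_groups, 2L)
})

test_that("generation is seed-deterministic and seed-sensitive", {
  spec <- synthetic_spec(n_positive = 2, n_negative = 2, seed = 95)
  a <- generate_hosts(spec)
  b <- generate_hosts(spec)
  expect_identical(a, b)
  spec2 <- spec
  spec2$seed <- 96
  expect_false(identical(generate_hosts(spec2)$records$seq, a$records$seq))
})

test_that("synthetic usage tables follow their law and metadata contract", {
  set.seed(97)
  tab <- generate_usage_table("uniform", n_cds = 100, avg_len_codons = 300)
  expect_s3_class(tab, "codon_usage_table")
  n_sense <- sum(codon_bias_profile("uniform") > 0)
  expected <- sum(tab$codon_counts) / n_sense
  # multinomial concentration: every sense count within 4 sd of uniform
  sdv <- sqrt(sum(tab$codon_counts) * (1 / n_sense) * (1 - 1 / n_sense))
  sense <- names(codon_bias_profile("uniform"))[codon_bias_profile("uniform") > 0]
  expect_true(all(abs(tab$codon_counts[sense] - expected) < 4 * sdv))
  expect_true(all(tab$codon_counts[setdiff(naltorf:::CODONS, sense)] == 0))
  # shallow table fails the robustness gate
  shallow <- generate_usage_table("uniform", n_cds = 29, avg_len_codons = 300)
  expect_false(table_is_robust(shallow))
  # genes built from a law concentrated on family-best codons score CAI near 1
  pref <- stats::setNames(rep(0.01, 64), naltorf:::CODONS)
  best <- vapply(codon_families(1, min_size = 2), `[`, "", 1L)
  pref[best] <- 100
  tab2 <- generate_usage_table(pref, 50, 300)
  gene <- paste(sample(best, 200, replace = TRUE), collapse = "")
  expect_gt(cai(gene, tab2), 0.95)
})

test_that("the mito-like profile respects mitochondrial coding constraints", {
  w <- codon_bias_profile("mito_like")
  expect_true(all(w[c("AGA", "AGG", "TAA", "TAG")] == 0))
  expect_gt(w[["TGA"]], 0)
  # third-position bias ordering A > C > T > G within a family
  expect_true(w[["GCA"]] > w[["GCC"]] && w[["GCC"]] > w[["GCT"]] &&
                w[["GCT"]] > w[["GCG"]])
})

test_that("frameshift law preserves host positional marginals", {
  law <- frameshift_law("mito_like", 3)
  # +3-frame first base inherits the host third-base bias ordering
  m <- vapply(split(law, substr(names(law), 1, 1)), sum, 0)
  expect_true(m[["A"]] > m[["C"]] && m[["C"]] > m[["T"]] && m[["T"]] > m[["G"]])
  # +3-frame third base is near-neutral (host second-base marginal)
  m3 <- vapply(split(law, substr(names(law), 3, 3)), sum, 0)
  expect_lt(max(m3) / min(m3), 1.6)
  expect_equal(sum(law), 1, tolerance = 1e-12)
})

test_that("generate_study_set writes a consistent, reproducible fixture tree", {
  specs <- list(Alpha = synthetic_spec(n_positive = 2, n_negative = 2,
                                       n_duplicates = 1, id_prefix = "A"),
                Beta = synthetic_spec(n_positive = 2, id_prefix = "B"))
  d1 <- file.path(tempdir(), "fix1")
  d2 <- file.path(tempdir(), "fix2")
  unlink(c(d1, d2), recursive = TRUE)
  cfg1 <- generate_study_set(specs, d1, n_robust_nuclear = 2, seed = 98)
  cfg2 <- generate_study_set(specs, d2, n_robust_nuclear = 2, seed = 98)
  expect_s3_class(cfg1, "pipeline_config")
  for (f in c("alpha.fa", "beta.fa", "manifest.tsv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  expect_identical(sort(list.files(file.path(d1, "tables"))),
                   sort(list.files(file.path(d2, "tables"))))
  man <- utils::read.delim(file.path(d1, "manifest.tsv"))
  expect_identical(nrow(man), 7L)
  recs <- read_cds_fasta(file.path(d1, "alpha.fa"))
  expect_identical(recs$group, rep("Alpha", 5))
  # a different seed produces different sequences
  d3 <- file.path(tempdir(), "fix3")
  unlink(d3, recursive = TRUE)
  generate_study_set(specs, d3, n_robust_nuclear = 2, seed = 99)
  expect_false(identical(readLines(file.path(d1, "alpha.fa")),
                         readLines(file.path(d3, "alpha.fa"))))
})
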