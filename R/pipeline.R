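## Round half away from zero, as in the conventional percentage formatting.
round_half_up <- function(x, digits = 2L) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Configuration for the end-to-end analysis pipeline
#'
#' @param fasta Named character vector of FASTA paths; names are group
#'   labels (e.g. `c(Primates = "primates.fa")`).
#' @param table_dir Directory of canonical codon-table TSVs named
#'   `<species>_nuclear.tsv` / `<species>_mito.tsv`.
#' @param out_dir Optional directory for per-stage TSVs and the summary
#'   JSON; `NULL` keeps everything in memory.
#' @param min_codons Nested-ORF length threshold (codons, stop excluded).
#' @param downstream_min Downstream-ORF length threshold for the PTC scan.
#' @param n_random Mock-ensemble size for eCAI/eRCDI.
#' @param alpha One-sided significance level.
#' @param seed Integer seed from which all pipeline randomness derives.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(fasta, table_dir = NULL, out_dir = NULL,
                            min_codons = 150L, downstream_min = 50L,
                            n_random = 500L, alpha = 0.05, seed = 1L) {
  if (is.null(names(fasta)) || any(!nzchar(names(fasta)))) {
    stop("fasta paths must be named by group")
  }
  missing <- fasta[!file.exists(fasta)]
  if (length(missing)) stop("missing FASTA file(s): ", paste(missing, collapse = ", "))
  if (!is.null(table_dir) && !dir.exists(table_dir)) {
    stop("table_dir does not exist: ", table_dir)
  }
  stopifnot(min_codons >= 1L, downstream_min >= 1L, n_random >= 2L,
            alpha > 0, alpha < 1)
  structure(list(fasta = fasta, table_dir = table_dir, out_dir = out_dir,
                 min_codons = as.integer(min_codons),
                 downstream_min = as.integer(downstream_min),
                 n_random = as.integer(n_random), alpha = alpha,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Load per-species reference tables from a directory
#'
#' @param table_dir Directory of canonical TSVs named
#'   `<species>_nuclear.tsv` and `<species>_mito.tsv`.
#' @return List with named lists `nuclear` and `mito`, keyed by species.
#' @export
load_reference_tables <- function(table_dir) {
  out <- list(nuclear = list(), mito = list())
  for (f in list.files(table_dir, pattern = "\\.tsv$", full.names = TRUE)) {
    base <- sub("\\.tsv$", "", basename(f))
    kind <- if (grepl("_nuclear$", base)) "nuclear"
            else if (grepl("_mito$", base)) "mito"
            else next
    tab <- read_codon_table(f, "canonical_tsv")
    sp <- if (!is.na(tab$species)) tab$species else sub("_(nuclear|mito)$", "", base)
    out[[kind]][[sp]] <- tab
  }
  out
}

#' Prevalence of nested-ORF-positive records per group
#'
#' @param records CDS records with a `group` column.
#' @param orfs Nested-ORF table (`host_id` column) from the scan.
#' @return Data.frame: `group`, `n_records`, `n_positive`, `pct_positive`
#'   (percentage, rounded half-up to 2 decimals).
#' @export
summarize_prevalence <- function(records, orfs) {
  if (!nrow(records)) stop("no records to summarize")
  pos_ids <- unique(orfs$host_id)
  groups <- unique(records$group)
  do.call(rbind, lapply(groups, function(g) {
    sub <- records[records$group %in% g, ]
    npos <- sum(sub$id %in% pos_ids)
    data.frame(group = g, n_records = nrow(sub), n_positive = npos,
               pct_positive = round_half_up(100 * npos / nrow(sub), 2L),
               stringsAsFactors = FALSE)
  }))
}

.write_stage <- function(df, out_dir, name) {
  if (is.null(out_dir)) return(invisible(NULL))
  utils::write.table(df, file.path(out_dir, paste0(name, ".tsv")), sep = "\t",
                     quote = FALSE, row.names = FALSE)
}

#' Run the full nested-ORF analysis pipeline
#'
#' Orchestrates, per group: ambiguity-cleaned FASTA input; the
#' standard-code nested-ORF scan of frames +2/+3 with longest-per-frame
#' selection, plus the mitochondrial-code control scan; duplicate
#' consolidation; Kozak context extraction, classification and tallies on
#' the unique set; the host-frame PTC scan of positive hosts; CAI/eCAI and
#' RCDI/eRCDI verdicts against each species' robust nuclear table; and the
#' RSCU cosine-similarity table with the four one-tailed Wilcoxon
#' signed-rank comparisons. All randomness derives from `config$seed`.
#'
#' @param config A [pipeline_config()].
#' @return A list with one entry per group (stage data.frames) plus
#'   `summary`, the nested summary list also written as JSON when
#'   `out_dir` is set.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  }
  tables <- if (!is.null(config$table_dir)) load_reference_tables(config$table_dir)
            else list(nuclear = list(), mito = list())
  result <- list()
  summary <- list(seed = config$seed,
                  parameters = list(min_codons = config$min_codons,
                                    downstream_min = config$downstream_min,
                                    n_random = config$n_random,
                                    alpha = config$alpha))
  for (g in names(config$fasta)) {
    recs <- read_cds_fasta(config$fasta[[g]])
    scan1 <- scan_nested_orfs(recs, genetic_code(1L), c(2L, 3L), config$min_codons)
    best <- longest_per_frame(scan1)
    scan2 <- scan_nested_orfs(recs, genetic_code(2L), c(2L, 3L), config$min_codons)
    prev <- summarize_prevalence(transform(recs, group = g), best)
    ded <- dedupe_orfs(best)
    uniq <- ded$unique
    koz <- kozak_contexts(recs, uniq)
    tk <- tally_kozak(koz)
    pos_hosts <- recs[recs$id %in% uniq$host_id, , drop = FALSE]
    ptc <- if (nrow(pos_hosts)) ptc_scan(pos_hosts, config$downstream_min) else
      ptc_scan(recs[0, , drop = FALSE], config$downstream_min)

    ## adaptation verdicts against robust nuclear tables
    adapt_rows <- list()
    for (i in seq_len(nrow(uniq))) {
      sp <- recs$species[match(uniq$host_id[i], recs$id)]
      ntab <- tables$nuclear[[sp]]
      if (is.null(ntab) || !isTRUE(table_is_robust(ntab))) next
      e1 <- ecai(uniq$nt_seq[i], ntab, n_random = config$n_random,
                 alpha = config$alpha)
      e2 <- ercdi(uniq$nt_seq[i], ntab, n_random = config$n_random,
                  alpha = config$alpha)
      adapt_rows[[length(adapt_rows) + 1L]] <- data.frame(
        host_id = uniq$host_id[i], species = sp,
        cai = e1$statistic, ecai = e1$expected, cai_upper = e1$upper,
        cai_lower = e1$lower, cai_verdict = e1$verdict,
        rcdi = e2$statistic, ercdi = e2$expected, rcdi_upper = e2$upper,
        rcdi_lower = e2$lower, rcdi_verdict = e2$verdict,
        stringsAsFactors = FALSE)
    }
    adapt <- if (length(adapt_rows)) do.call(rbind, adapt_rows) else
      data.frame(host_id = character(0), species = character(0),
                 cai = numeric(0), ecai = numeric(0), cai_upper = numeric(0),
                 cai_lower = numeric(0), cai_verdict = character(0),
                 rcdi = numeric(0), ercdi = numeric(0), rcdi_upper = numeric(0),
                 rcdi_lower = numeric(0), rcdi_verdict = character(0))

    simtab <- build_similarity_table(uniq, recs, tables$nuclear, tables$mito)
    tests <- if (nrow(simtab) >= 2L) {
      rbind(
        wilcoxon_signed_rank(simtab$sim_cytb_mito, simtab$sim_cytb_nuclear,
                             "greater", "cytb_mito_gt_cytb_nuclear"),
        wilcoxon_signed_rank(simtab$sim_cytb_nuclear, simtab$sim_ncytb_nuclear,
                             "greater", "cytb_nuclear_gt_ncytb_nuclear"),
        wilcoxon_signed_rank(simtab$sim_cytb_mito, simtab$sim_ncytb_mito,
                             "greater", "cytb_mito_gt_ncytb_mito"),
        wilcoxon_signed_rank(simtab$sim_ncytb_nuclear, simtab$sim_ncytb_mito,
                             "greater", "ncytb_nuclear_gt_ncytb_mito"))
    } else {
      data.frame(comparison = character(0), n = integer(0), statistic = numeric(0),
                 p_value = numeric(0), alternative = character(0), method = character(0))
    }

    gl <- tolower(g)
    .write_stage(best, config$out_dir, paste0("orfs_", gl))
    .write_stage(uniq, config$out_dir, paste0("orfs_unique_", gl))
    .write_stage(koz, config$out_dir, paste0("kozak_", gl))
    .write_stage(ptc, config$out_dir, paste0("ptc_", gl))
    .write_stage(adapt, config$out_dir, paste0("adaptation_", gl))
    .write_stage(simtab, config$out_dir, paste0("similarity_", gl))
    .write_stage(tests, config$out_dir, paste0("tests_", gl))

    summary$groups[[g]] <- list(
      n_records = nrow(recs),
      n_removed_ambiguous = attr(recs, "n_removed"),
      n_positive = prev$n_positive,
      pct_positive = prev$pct_positive,
      frame_counts = as.list(table(factor(best$frame, levels = 2:3))),
      table2_scan_orfs = nrow(scan2),
      n_unique = nrow(uniq),
      n_duplicate_groups = length(ded$duplicate_groups),
      kozak = list(strength = as.list(tk$strength),
                   minus3 = as.list(tk$minus3),
                   plus4 = as.list(tk$plus4)),
      ptc = list(
        n_scanned = nrow(ptc),
        n_first_stop_88_90 = sum(ptc$first_stop_start == 88L &
                                   ptc$first_stop_end == 90L, na.rm = TRUE),
        n_no_stop = sum(is.na(ptc$first_stop_start)),
        n_downstream_long_orf = sum(ptc$downstream_long_orf)),
      adaptation = list(
        n_genes = nrow(adapt),
        cai_outside_ci = sum(adapt$cai_verdict != "indistinguishable"),
        rcdi_outside_ci = sum(adapt$rcdi_verdict != "composition_driven")),
      similarity = list(
        n_species = nrow(simtab),
        n_skipped = nrow(attr(simtab, "skipped")),
        mean_sim = if (nrow(simtab)) lapply(simtab[, grep("^sim_", names(simtab))], mean)
                   else NULL,
        tests = if (nrow(tests)) tests else NULL)
    )
    result[[g]] <- list(records = recs, orfs = best, orfs_table2 = scan2,
                        unique = uniq, duplicate_groups = ded$duplicate_groups,
                        kozak = koz, ptc = ptc, adaptation = adapt,
                        similarity = simtab, tests = tests)
  }
  if (!is.null(config$out_dir)) {
    jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
  }
  result$summary <- summary
  result
}
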