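## Codons that must never appear on the host (+1) codon grid: the stop
## codons shared with or specific to the vertebrate mitochondrial code.
## TGA (Trp in the organelle, a cytosolic stop) is handled positionally:
## forbidden before codon 30 so the planted PTC is the first standard-code
## stop, allowed downstream (real cytb carries many TGA Trp codons, which
## keep chance downstream ORFs short).
FORBIDDEN_F1 <- c("TAA", "TAG", "AGA", "AGG")

## Is codon `cod` acceptable at host-frame codon index j?
.host_codon_ok <- function(cod, j, plant) {
  if (cod %in% FORBIDDEN_F1) return(FALSE)
  if (cod == "TGA") {
    if (!plant) return(FALSE)
    return(j >= 30L)  # the planted PTC or a downstream Trp
  }
  TRUE
}

#' Built-in codon-bias profiles for the synthetic generator
#'
#' Weight vectors over the 64 codons used as sampling laws and as the basis
#' of synthetic reference tables. Bias acts on the third codon position:
#' `"mito_like"` mimics the strong A-ending preference of mammalian
#' mitochondrial protein genes (A:C:T:G = 8:4:2:1), `"nuclear_like"` a
#' milder bias in the same direction (4:3:2:1), and `"uniform"` weights all
#' sense codons equally. Sense codons are taken under the code the gene set
#' is translated with: the mito-like profile puts zero weight on AGA and
#' AGG (mitochondrial stop codons, absent from real organellar gene sets)
#' while keeping TGA (mitochondrial Trp); the other profiles zero the three
#' standard-code stops.
#'
#' @param kind `"uniform"`, `"mito_like"`, or `"nuclear_like"`.
#' @return Named numeric vector of 64 weights.
#' @export
codon_bias_profile <- function(kind = c("uniform", "mito_like", "nuclear_like")) {
  kind <- match.arg(kind)
  basis <- genetic_code(if (kind == "mito_like") 2L else 1L)
  sense <- names(basis$codon_to_aa)[basis$codon_to_aa != "*"]
  w <- stats::setNames(numeric(64L), CODONS)
  if (kind == "uniform") {
    w[sense] <- 1
  } else {
    w3 <- switch(kind,
                 mito_like = c(A = 8, C = 4, T = 2, G = 1),
                 nuclear_like = c(A = 4, C = 3, T = 2, G = 1))
    third <- substr(sense, 3L, 3L)
    w[sense] <- w3[third]
  }
  w
}

#' Codon law induced in a shifted reading frame
#'
#' Distribution of shifted-frame codons when host-frame codons are sampled
#' from `host_law` (restricted to the codons the generator may place). A
#' +3-frame codon reads (base 3 of host codon j, bases 1-2 of host codon
#' j+1); a +2-frame codon reads (bases 2-3 of j, base 1 of j+1). The law is
#' the product of the corresponding positional base marginals of the host
#' law, so sampling nested-ORF codons from it leaves the host's frame-1
#' base composition — and hence its codon bias — intact across the ORF
#' window, while the nested ORF's own third positions are essentially
#' neutral under a third-position-biased host law. This mirrors real nested
#' ORFs, whose codon usage is dictated by the host frame, and it is the
#' generator's default law for nested-ORF interiors.
#'
#' @param host_law Profile name or named weight vector (see
#'   [codon_bias_profile()]).
#' @param frame 2 or 3.
#' @return Named numeric vector of 64 codon weights.
#' @export
frameshift_law <- function(host_law, frame) {
  stopifnot(frame %in% c(2L, 3L))
  w <- resolve_codon_law(host_law)
  allowed <- setdiff(CODONS, c(FORBIDDEN_F1, "TGA"))
  p <- w[allowed] / sum(w[allowed])
  m <- lapply(1:3, function(k) vapply(split(p, substr(allowed, k, k)), sum, 0))
  ## positional marginals seen by the shifted frame
  ord <- if (frame == 3L) c(3L, 1L, 2L) else c(2L, 3L, 1L)
  stats::setNames(
    m[[ord[1L]]][substr(CODONS, 1L, 1L)] *
      m[[ord[2L]]][substr(CODONS, 2L, 2L)] *
      m[[ord[3L]]][substr(CODONS, 3L, 3L)],
    CODONS
  )
}

## Resolve a law argument (profile name or named weight vector) into a
## 64-long weight vector.
resolve_codon_law <- function(law) {
  if (is.character(law) && length(law) == 1L) return(codon_bias_profile(law))
  if (is.numeric(law)) {
    if (any(law < 0) || sum(law) <= 0) stop("codon law weights must be >= 0, not all zero")
    return(as_codon_count_vector(law))
  }
  stop("codon law must be a profile name or a named weight vector")
}

#' Specification for a synthetic cytb-like cohort
#'
#' Captures the study conditions a generated cohort emulates: host length
#' (1,140 nt, the mammalian cytb CDS length), nested-ORF frame and length
#' range (frame +3, 150-239 codons, matching the observed nested ORFs), the
#' planted early host-frame TGA at nucleotides 88-90, and the codon laws for
#' host and nested-ORF codons.
#'
#' @param n_positive Number of distinct hosts carrying a planted nested ORF.
#' @param n_negative Number of hosts guaranteed to carry none.
#' @param n_duplicates Extra positives emitted as exact copies of earlier
#'   positives (under new ids/species), to exercise duplicate consolidation.
#' @param host_len_nt Host CDS length (divisible by 3). Default 1140.
#' @param orf_len_codons Length range (inclusive, stop excluded) for planted
#'   ORFs. Default `c(150, 239)`.
#' @param orf_frame 2 or 3. Default 3.
#' @param kozak_class Target Kozak classes for the positives, recycled.
#' @param plant_early_tga Plant a host-frame TGA at codon 30 (nt 88-90)?
#' @param codon_law Sampling law for host codons (profile name or weights).
#' @param orf_codon_law Law for nested-ORF interior codons. The default
#'   `"frameshift"` uses the law the host's own shifted frame induces (see
#'   [frameshift_law()]), which keeps the host's frame-1 usage faithful to
#'   `codon_law` across the ORF window while leaving the nested ORF's
#'   silent positions essentially neutral — the situation observed for
#'   real nested ORFs, whose codon usage is dictated by the host.
#' @param min_codons Scanner threshold the cohort is generated against.
#' @param group Group label (e.g. `"Primates"`).
#' @param id_prefix Record id prefix.
#' @param seed Optional integer seed making the cohort reproducible.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_positive = 0L, n_negative = 0L, n_duplicates = 0L,
                           host_len_nt = 1140L, orf_len_codons = c(150L, 239L),
                           orf_frame = 3L, kozak_class = "adequate",
                           plant_early_tga = TRUE,
                           codon_law = "mito_like", orf_codon_law = "frameshift",
                           min_codons = 150L, group = "Synthetic",
                           id_prefix = "SYN", seed = NULL) {
  stopifnot(n_positive >= 0L, n_negative >= 0L, n_duplicates >= 0L)
  if (n_duplicates > 0L && n_positive == 0L) stop("duplicates require positives")
  if (host_len_nt %% 3L != 0L) stop("host_len_nt must be divisible by 3")
  if (!orf_frame %in% c(2L, 3L)) stop("orf_frame must be 2 or 3")
  orf_len_codons <- as.integer(orf_len_codons)
  if (length(orf_len_codons) == 1L) orf_len_codons <- rep(orf_len_codons, 2L)
  if (orf_len_codons[1L] > orf_len_codons[2L] || orf_len_codons[1L] < 1L) {
    stop("invalid orf_len_codons range")
  }
  if (!all(kozak_class %in% c("optimal", "strong", "adequate", "weak"))) {
    stop("kozak_class must be optimal/strong/adequate/weak")
  }
  smin <- if (plant_early_tga) 97L else 13L
  if (smin + 3L * (orf_len_codons[1L] + 1L) - 1L > host_len_nt) {
    stop("unsatisfiable spec: nested ORF does not fit in the host")
  }
  structure(
    list(n_positive = as.integer(n_positive), n_negative = as.integer(n_negative),
         n_duplicates = as.integer(n_duplicates), host_len_nt = as.integer(host_len_nt),
         orf_len_codons = orf_len_codons, orf_frame = as.integer(orf_frame),
         kozak_class = kozak_class, plant_early_tga = isTRUE(plant_early_tga),
         codon_law = codon_law, orf_codon_law = orf_codon_law,
         min_codons = as.integer(min_codons), group = group,
         id_prefix = id_prefix, seed = seed),
    class = "synthetic_spec"
  )
}

## Target Kozak bases for a class: 6 upstream bases (-6..-1) and the +4 base.
## Non-optimal classes use a TTT/TT shell so the full optimal motif cannot
## match by accident; all shells avoid creating host-frame stop codons.
.kozak_target <- function(class) {
  r <- sample(c("A", "G"), 1L)
  y <- sample(c("C", "T"), 1L)
  not_g <- sample(c("A", "C", "T"), 1L)
  switch(class,
    optimal = list(upstream = paste0("GCC", r, "CC"), plus4 = "G"),
    strong = list(upstream = paste0("TTT", r, "TT"), plus4 = "G"),
    adequate = if (sample(2L, 1L) == 1L)
        list(upstream = paste0("TTT", r, "TT"), plus4 = not_g)
      else
        list(upstream = paste0("TTT", y, "TT"), plus4 = "G"),
    weak = list(upstream = paste0("TTT", y, "TT"), plus4 = not_g),
    stop("unknown kozak class: ", class)
  )
}

## Repair host-frame (+1) stop codons created by splicing the nested-ORF
## window into the host. Editable material: nested-ORF codons 2..L+1
## (codon 2 keeps its first base, the +4 position; the final codon stays a
## standard-code stop) and host bases outside both the ORF window and the
## protected positions. Returns the repaired base vector or NULL.
.repair_frame1 <- function(nt, s, L, protected, plant, sense1) {
  W <- s:(s + 3L * (L + 1L) - 1L)
  n_cod <- length(nt) %/% 3L
  f1 <- function(j) paste(nt[(3L * j - 2L):(3L * j)], collapse = "")
  allowed <- function(j) .host_codon_ok(f1(j), j, plant)
  bad <- which(!vapply(seq_len(n_cod), allowed, TRUE))
  for (j in bad) {
    if (allowed(j)) next  # fixed as a side effect of an earlier repair
    pos <- (3L * j - 2L):(3L * j)
    in_w <- pos[pos %in% W]
    success <- FALSE
    if (length(in_w)) {
      ms <- unique((in_w - s) %/% 3L + 1L)
      for (m in ms) {
        if (m == 1L) next  # the ORF ATG is immutable
        repl <- if (m == L + 1L) c("TAA", "TAG", "TGA") else sense1
        if (m == 2L) repl <- repl[substr(repl, 1L, 1L) == nt[s + 3L]]
        span <- (s + 3L * (m - 1L)):(s + 3L * m - 1L)
        touched <- unique(ceiling(span / 3))
        touched <- touched[touched >= 1L & touched <= n_cod]
        was_bad <- !vapply(touched, allowed, TRUE)
        old <- nt[span]
        for (r in sample(repl)) {
          nt[span] <- strsplit(r, "")[[1L]]
          now_ok <- vapply(touched, allowed, TRUE)
          if (allowed(j) && all(now_ok | was_bad)) {
            success <- TRUE
            break
          }
        }
        if (success) break
        nt[span] <- old
      }
    }
    if (!success) {
      editable <- pos[!(pos %in% W) & !(pos %in% protected)]
      if (length(editable)) {
        combos <- expand.grid(rep(list(BASES), length(editable)), stringsAsFactors = FALSE)
        for (k in sample(nrow(combos))) {
          old <- nt[editable]
          nt[editable] <- unlist(combos[k, ], use.names = FALSE)
          if (allowed(j)) {
            success <- TRUE
            break
          }
          nt[editable] <- old
        }
      }
    }
    if (!success) return(NULL)
  }
  if (!all(vapply(seq_len(n_cod), allowed, TRUE))) return(NULL)
  nt
}

## One construction attempt; returns list(seq, truth) or NULL.
.build_host_attempt <- function(spec, positive, kozak_class) {
  host_len <- spec$host_len_nt
  n_cod <- host_len %/% 3L
  law <- resolve_codon_law(spec$codon_law)
  no_tga <- setdiff(CODONS, c(FORBIDDEN_F1, "TGA"))
  with_tga <- setdiff(CODONS, FORBIDDEN_F1)
  if (sum(law[no_tga]) <= 0) stop("host codon law puts no mass on allowed codons")
  sense1 <- names(genetic_code(1L)$codon_to_aa)[genetic_code(1L)$codon_to_aa != "*"]
  orf_law <- if (identical(spec$orf_codon_law, "frameshift")) {
    frameshift_law(spec$codon_law, spec$orf_frame)
  } else {
    resolve_codon_law(spec$orf_codon_law)
  }

  ## TGA is kept out of the 5' region so the planted PTC is the first
  ## standard-code stop; downstream it is sampled as a normal Trp codon.
  cods <- sample(no_tga, n_cod, replace = TRUE, prob = law[no_tga])
  if (spec$plant_early_tga && n_cod > 30L) {
    down <- 31L:n_cod
    cods[down] <- sample(with_tga, length(down), replace = TRUE, prob = law[with_tga])
  }
  cods[1L] <- "ATG"
  if (spec$plant_early_tga) cods[30L] <- "TGA"
  nt <- strsplit(paste(cods, collapse = ""), "")[[1L]]

  s <- NA_integer_
  L <- NA_integer_
  if (positive) {
    L <- if (spec$orf_len_codons[1L] == spec$orf_len_codons[2L]) spec$orf_len_codons[1L]
         else sample(seq(spec$orf_len_codons[1L], spec$orf_len_codons[2L]), 1L)
    f <- spec$orf_frame
    smin <- if (spec$plant_early_tga) 97L else 13L
    cand <- seq.int(f, host_len, by = 3L)
    cand <- cand[cand >= smin & cand + 3L * (L + 1L) - 1L <= host_len]
    if (!length(cand)) stop("unsatisfiable spec: ORF of ", L, " codons does not fit")
    s <- if (length(cand) == 1L) cand else sample(cand, 1L)
    tgt <- .kozak_target(kozak_class)
    oc <- character(L + 1L)
    oc[1L] <- "ATG"
    second <- sense1[substr(sense1, 1L, 1L) == tgt$plus4]
    p2 <- orf_law[second]
    oc[2L] <- if (sum(p2) > 0) sample(second, 1L, prob = p2) else sample(second, 1L)
    if (L >= 3L) {
      pi <- orf_law[sense1]
      oc[3L:L] <- if (sum(pi) > 0) sample(sense1, L - 2L, replace = TRUE, prob = pi)
                  else sample(sense1, L - 2L, replace = TRUE)
    }
    oc[L + 1L] <- sample(c("TAA", "TAG", "TGA"), 1L)
    nt[s:(s + 3L * (L + 1L) - 1L)] <- strsplit(paste(oc, collapse = ""), "")[[1L]]
    nt[(s - 6L):(s - 1L)] <- strsplit(tgt$upstream, "")[[1L]]
    protected <- c(1:3, if (spec$plant_early_tga) 88:90, (s - 6L):(s + 3L))
    nt <- .repair_frame1(nt, s, L, protected, spec$plant_early_tga, sense1)
    if (is.null(nt)) return(NULL)
  }

  seqstr <- paste(nt, collapse = "")

  ## self-verification through the package's own analysis path
  if (substr(seqstr, 1L, 3L) != "ATG") return(NULL)
  if (!is.null(first_stop(seqstr, genetic_code(2L), 1L))) return(NULL)
  fs <- first_stop(seqstr, genetic_code(1L), 1L)
  if (spec$plant_early_tga) {
    if (!identical(fs, c(88L, 90L)) || substr(seqstr, 88L, 90L) != "TGA") return(NULL)
  } else if (!is.null(fs)) {
    return(NULL)
  }
  found <- scan_nested_orfs(c(x = seqstr), genetic_code(1L), frames = c(2L, 3L),
                            min_codons = spec$min_codons)
  if (positive) {
    if (nrow(found) != 1L) return(NULL)
    if (found$frame != spec$orf_frame || found$start_nt != s ||
        found$length_codons != L ||
        found$end_nt != s + 3L * (L + 1L) - 1L) return(NULL)
    if (classify_kozak(extract_kozak(seqstr, s)) != kozak_class) return(NULL)
  } else if (nrow(found) != 0L) {
    return(NULL)
  }

  truth <- data.frame(
    has_orf = positive,
    orf_start_nt = s, orf_end_nt = if (positive) s + 3L * (L + 1L) - 1L else NA_integer_,
    orf_frame = if (positive) spec$orf_frame else NA_integer_,
    orf_len_codons = L,
    kozak_class = if (positive) kozak_class else NA_character_,
    first_stop_start = if (is.null(fs)) NA_integer_ else fs[1L],
    first_stop_end = if (is.null(fs)) NA_integer_ else fs[2L],
    stringsAsFactors = FALSE)
  list(seq = seqstr, truth = truth)
}

#' Generate one cytb-like host CDS
#'
#' Builds a host sequence translatable end-to-end under the vertebrate
#' mitochondrial code (ATG start, no internal stop), optionally carrying the
#' early standard-code TGA at nucleotides 88-90 and, for positives, an
#' embedded standard-code nested ORF with the requested frame, length and
#' Kozak class. The construction proposes, locally repairs host-frame stop
#' codons, and then verifies itself by running the package's own scanner,
#' PTC scan and Kozak classifier; failed attempts are resampled up to
#' `max_attempts` times.
#'
#' @param spec A [synthetic_spec()].
#' @param positive Embed a nested ORF?
#' @param kozak_class Target class for this record.
#' @param id Record id written into the truth row.
#' @param max_attempts Bounded resampling cap (default 1000).
#' @return List with `record` (one-row data.frame: `id`, `species`, `group`,
#'   `seq`) and `truth` (one-row manifest data.frame).
#' @export
generate_host <- function(spec, positive = TRUE,
                          kozak_class = spec$kozak_class[1L],
                          id = spec$id_prefix, max_attempts = 1000L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  for (attempt in seq_len(max_attempts)) {
    res <- .build_host_attempt(spec, positive, kozak_class)
    if (!is.null(res)) {
      record <- data.frame(id = id, species = paste0("sp_", id),
                           group = spec$group, seq = res$seq,
                           stringsAsFactors = FALSE)
      truth <- cbind(data.frame(id = id, stringsAsFactors = FALSE), res$truth,
                     data.frame(duplicate_of = NA_character_, stringsAsFactors = FALSE))
      return(list(record = record, truth = truth))
    }
  }
  stop("failed to generate a satisfying host in ", max_attempts, " attempts")
}

#' Generate a full synthetic cohort with its truth manifest
#'
#' Emits `n_positive` hosts with planted nested ORFs (Kozak classes recycled
#' from `spec$kozak_class`), `n_duplicates` exact copies of earlier
#' positives under fresh ids/species, and `n_negative` ORF-free hosts.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `records` (data.frame `id`, `species`, `group`, `seq`)
#'   and `manifest` (one truth row per record).
#' @export
generate_hosts <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    classes <- if (spec$n_positive > 0L) rep_len(spec$kozak_class, spec$n_positive) else character(0)
    recs <- list()
    truths <- list()
    for (i in seq_len(spec$n_positive)) {
      g <- generate_host(spec, positive = TRUE, kozak_class = classes[i],
                         id = sprintf("%sP%03d", spec$id_prefix, i))
      recs[[length(recs) + 1L]] <- g$record
      truths[[length(truths) + 1L]] <- g$truth
    }
    for (i in seq_len(spec$n_duplicates)) {
      src <- ((i - 1L) %% spec$n_positive) + 1L
      id <- sprintf("%sX%03d", spec$id_prefix, i)
      rec <- recs[[src]]
      tr <- truths[[src]]
      rec$id <- id
      rec$species <- paste0("sp_", id)
      tr$id <- id
      tr$duplicate_of <- truths[[src]]$id
      recs[[length(recs) + 1L]] <- rec
      truths[[length(truths) + 1L]] <- tr
    }
    for (i in seq_len(spec$n_negative)) {
      g <- generate_host(spec, positive = FALSE,
                         id = sprintf("%sN%03d", spec$id_prefix, i))
      recs[[length(recs) + 1L]] <- g$record
      truths[[length(truths) + 1L]] <- g$truth
    }
    list(records = do.call(rbind, recs), manifest = do.call(rbind, truths))
  })
}

#' Generate a synthetic codon-usage reference table
#'
#' Counts are a single multinomial draw of size `n_cds * avg_len_codons`
#' from the normalized bias weights, so empirical frequencies concentrate
#' around the law as the table deepens.
#'
#' @param bias Profile name (see [codon_bias_profile()]) or named weights.
#' @param n_cds,avg_len_codons Metadata (and draw size).
#' @param gene_set `"nuclear"` or `"mitochondrial"`.
#' @param species Species label.
#' @return A [codon_usage_table()].
#' @export
generate_usage_table <- function(bias = "uniform", n_cds = 50, avg_len_codons = 300,
                                 gene_set = "nuclear", species = "synthetic") {
  w <- resolve_codon_law(bias)
  total <- round(n_cds * avg_len_codons)
  counts <- stats::rmultinom(1L, total, prob = w / sum(w))[, 1L]
  codon_usage_table(stats::setNames(as.numeric(counts), CODONS),
                    gene_set = gene_set, n_cds = n_cds,
                    avg_cds_len_codons = avg_len_codons, species = species)
}

#' Generate a complete on-disk study fixture
#'
#' Writes, for each group spec, a FASTA of host CDSs, per-species nuclear
#' and mitochondrial codon-usage tables for all positive species (the first
#' `n_robust_nuclear` positives get deep nuclear tables passing the
#' robustness filter; the rest get shallow, non-robust ones), and a combined
#' truth manifest — everything [run_all()] needs.
#'
#' @param specs Named list of [synthetic_spec()]s; names are group labels.
#' @param dir Output directory (created).
#' @param n_robust_nuclear Named integer (per group) or single number:
#'   positives given robust nuclear tables. `NULL` means all.
#' @param nuclear_bias,mito_bias Laws behind the reference tables.
#' @param seed Integer seed for the whole fixture tree.
#' @return Invisibly, a [pipeline_config()] pointing at the fixture.
#' @export
generate_study_set <- function(specs, dir, n_robust_nuclear = NULL,
                               nuclear_bias = "nuclear_like", mito_bias = "mito_like",
                               seed = 1L) {
  stopifnot(is.list(specs), !is.null(names(specs)))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "tables"), showWarnings = FALSE)
  fasta <- character(0)
  manifests <- list()
  with_seed(seed, {
    for (g in names(specs)) {
      spec <- specs[[g]]
      spec$group <- g
      spec$seed <- NULL  # the fixture-level seed governs everything
      hosts <- generate_hosts(spec)
      fa <- file.path(dir, paste0(tolower(g), ".fa"))
      write_cds_fasta(hosts$records, fa)
      fasta[g] <- fa
      man <- hosts$manifest
      man$group <- g
      manifests[[g]] <- man
      pos <- hosts$records[hosts$manifest$has_orf & is.na(hosts$manifest$duplicate_of), ]
      n_rob <- if (is.null(n_robust_nuclear)) nrow(pos)
               else if (!is.null(names(n_robust_nuclear))) n_robust_nuclear[[g]]
               else n_robust_nuclear
      dup_pos <- hosts$records[hosts$manifest$has_orf & !is.na(hosts$manifest$duplicate_of), ]
      all_pos <- rbind(pos, dup_pos)
      for (k in seq_len(nrow(all_pos))) {
        sp <- all_pos$species[k]
        robust <- k <= n_rob && k <= nrow(pos)
        nuc <- generate_usage_table(nuclear_bias,
                                    n_cds = if (robust) 50 else 20,
                                    avg_len_codons = if (robust) 300 else 80,
                                    gene_set = "nuclear", species = sp)
        mit <- generate_usage_table(mito_bias, n_cds = 13, avg_len_codons = 300,
                                    gene_set = "mitochondrial", species = sp)
        write_codon_table(nuc, file.path(dir, "tables", paste0(sp, "_nuclear.tsv")))
        write_codon_table(mit, file.path(dir, "tables", paste0(sp, "_mito.tsv")))
      }
    }
  })
  manifest <- do.call(rbind, manifests)
  rownames(manifest) <- NULL
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(pipeline_config(fasta = fasta, table_dir = file.path(dir, "tables"),
                            seed = seed))
}
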