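# Independent brute-force oracles used to validate the implementation.
# These deliberately re-derive results from first principles (regex walks,
# exhaustive enumeration, log-domain arithmetic) and never call the code
# paths they check.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Enumerate every ATG..stop span in the requested frames by walking the
# codon grid from each ATG; keep the 5'-most ATG per stop, then filter by
# length. Complete ORFs only.
oracle_scan <- function(seq, frames = c(2L, 3L), min_codons = 150L,
                        stops = c("TAA", "TAG", "TGA")) {
  n <- nchar(seq)
  rows <- list()
  for (f in frames) {
    atg <- as.integer(gregexpr("(?=ATG)", seq, perl = TRUE)[[1L]])
    atg <- atg[atg > 0 & (atg - f) %% 3L == 0L]
    spans <- list()
    for (a in atg) {
      p <- a + 3L
      end <- NA_integer_
      while (p + 2L <= n) {
        if (substr(seq, p, p + 2L) %in% stops) {
          end <- p + 2L
          break
        }
        p <- p + 3L
      }
      if (!is.na(end)) spans[[length(spans) + 1L]] <- c(a, end)
    }
    if (!length(spans)) next
    sp <- do.call(rbind, spans)
    for (e in sort(unique(sp[, 2L]))) {
      a <- min(sp[sp[, 2L] == e, 1L])
      len <- (e - a + 1L) %/% 3L - 1L
      if (len >= min_codons) {
        rows[[length(rows) + 1L]] <-
          data.frame(frame = f, start_nt = a, end_nt = e, length_codons = len)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(frame = integer(0), start_nt = integer(0),
                      end_nt = integer(0), length_codons = integer(0)))
  }
  out <- do.call(rbind, rows)
  out[order(out$frame, out$start_nt), , drop = FALSE]
}

# Regex implementation of the four published Kozak patterns, in precedence
# order, on the context string upstream + "ATG" + plus4.
oracle_kozak <- function(upstream, plus4) {
  ctx <- paste0(upstream, "ATG", plus4)
  if (nchar(upstream) < 3L || is.na(plus4) || !plus4 %in% c("A", "C", "G", "T")) {
    return("undetermined")
  }
  if (grepl("^GCC[AG]CCATGG$", ctx)) return("optimal")
  if (grepl("[AG]..ATGG$", ctx)) return("strong")
  if (grepl("[AG]..ATG[ACT]$", ctx) || grepl("[CT]..ATGG$", ctx)) return("adequate")
  if (grepl("[CT]..ATG[ACT]$", ctx)) return("weak")
  "undetermined"
}

# Log-domain CAI recomputation by explicit codon walk.
oracle_cai <- function(seq, w) {
  codons <- substring(seq, seq(1L, nchar(seq) - 2L, by = 3L),
                      seq(3L, nchar(seq), by = 3L))
  lw <- 0
  L <- 0L
  for (cod in codons) {
    if (cod %in% names(w)) {
      lw <- lw + log(w[[cod]])
      L <- L + 1L
    }
  }
  exp(lw / L)
}

# Exact one-sided signed-rank p by full 2^n sign-flip enumeration.
oracle_wilcoxon_exact <- function(d, alternative = "greater") {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0L, 1L)), n))
  v_all <- as.matrix(signs) %*% r
  switch(alternative,
         greater = mean(v_all >= v_obs),
         less = mean(v_all <= v_obs),
         two.sided = min(1, 2 * min(mean(v_all >= v_obs), mean(v_all <= v_obs))))
}

# RSCU by direct definition loop over table-1 families.
oracle_rscu <- function(counts, included) {
  aa_map <- naltorf::genetic_code(1L)$codon_to_aa
  out <- numeric(0)
  for (cod in included) {
    fam <- names(aa_map)[aa_map == aa_map[[cod]]]
    tot <- sum(counts[fam])
    out[cod] <- if (tot > 0) counts[[cod]] * length(fam) / tot else 1
  }
  out
}
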