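## Independent oracles and small in-code fixtures shared across tests.

## Brute-force reference clumping: plain repeat-loop with per-pair r2
## queries, structurally independent of ld_clump's vectorized path.
clump_bruteforce <- function(records, panel, p_index, r2_max, window_kb) {
  records <- as.data.frame(records)
  cand <- records[is.finite(records$p) & records$p <= p_index, , drop = FALSE]
  cand <- cand[cand$snp_id %in% panel$map$snp_id, , drop = FALSE]
  if (nrow(cand) > 0L) {
    mono <- panel$map$monomorphic[match(cand$snp_id, panel$map$snp_id)]
    cand <- cand[!mono, , drop = FALSE]
  }
  if (nrow(cand) == 0L) return(character())
  pm <- panel$map[match(cand$snp_id, panel$map$snp_id), ]
  if (is.null(cand$chrom)) cand$chrom <- NA
  if (is.null(cand$bp)) cand$bp <- NA
  cand$chrom <- ifelse(is.na(cand$chrom), pm$chrom, cand$chrom)
  cand$bp <- ifelse(is.na(cand$bp), pm$bp, cand$bp)
  kept <- character()
  repeat {
    if (nrow(cand) == 0L) break
    ord <- order(cand$p, cand$bp, cand$snp_id)
    idx <- ord[1L]
    index_snp <- cand$snp_id[idx]
    kept <- c(kept, index_snp)
    drop <- rep(FALSE, nrow(cand))
    drop[idx] <- TRUE
    for (j in seq_len(nrow(cand))) {
      if (j == idx) next
      if (cand$chrom[j] == cand$chrom[idx] &&
          abs(cand$bp[j] - cand$bp[idx]) <= window_kb * 1000 &&
          ld_r2(panel, cand$snp_id[j], index_snp) >= r2_max) {
        drop[j] <- TRUE
      }
    }
    cand <- cand[!drop, , drop = FALSE]
  }
  kept
}

## Inverse-variance-weighted mean oracle (independent instruments).
ivw_oracle <- function(bxy, v) {
  w <- 1 / v
  list(b = sum(w * bxy) / sum(w), se = sqrt(1 / sum(w)))
}

## Quick sumstats builder with consistent p-values.
make_records <- function(snp_id, beta, se, a1 = "A", a2 = "G",
                         freq = 0.3, n = 10000, chrom = "1",
                         bp = seq_along(snp_id) * 1000L) {
  data.frame(snp_id = snp_id, chrom = chrom, bp = as.integer(bp),
             a1 = a1, a2 = a2, freq = freq, beta = beta, se = se,
             p = pmin(pmax(2 * pnorm(-abs(beta / se)), 1e-300), 1), n = n)
}

## Small panel with tunable LD: columns within a cluster are noisy copies.
toy_panel <- function(n = 80, clusters = list(3, 2, 1), maf = 0.3,
                      chrom_per_cluster = NULL, spacing = 1e4) {
  m <- sum(unlist(clusters))
  G <- matrix(NA_real_, n, m)
  ids <- sprintf("snp%02d", seq_len(m))
  chrom <- character(m); bp <- integer(m)
  col <- 0L
  for (ci in seq_along(clusters)) {
    k <- clusters[[ci]]
    base <- rbinom(n, 2, maf)
    for (j in seq_len(k)) {
      col <- col + 1L
      g <- base
      swap <- runif(n) < 0.12 * (j - 1)
      g[swap] <- rbinom(sum(swap), 2, maf)
      G[, col] <- g
      chrom[col] <- if (is.null(chrom_per_cluster)) "1"
        else chrom_per_cluster[ci]
      bp[col] <- as.integer(1e6 + (col - 1L) * spacing)
    }
  }
  ld_panel(G, ids, chrom, bp, a1 = rep("A", m), a2 = rep("G", m))
}

## tiny scenario used for pipeline mechanics (fast, all stages reachable)
small_spec <- function(seed = 7L) {
  scenario_spec(n_mqtl_disc = 1500L, n_mqtl_repl = 800L, n_eqtl = 2000L,
                n_gwas = 8000L, n_mediation = 2L, n_pleiotropy = 2L,
                n_linkage = 2L, n_reverse = 2L, n_null = 10L,
                n_traits = 2L, n_support_per_trait = 2L,
                n_decoy_genes = 6L, n_null_blocks = 6L, seed = seed)
}
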