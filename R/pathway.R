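## Pathway-level test: do SNPs that perturb a gene set's expression also
## perturb the trait? Pooled significant eQTLs across the set's genes are
## pruned to linkage equilibrium, then |Z| of the eQTL association is rank-
## correlated with |Z| of the GWAS association. Absolute values are used
## because member genes may act in inhibitory or activatory directions.

#' Build the pruned eQTL SNP panel for a gene set
#'
#' Pools all eQTL records with `p <= p_eqtl` across the pathway's genes;
#' when one SNP is an eQTL for several member genes its largest `|z|` is
#' kept; the pooled SNPs are then clumped at `r2 < r2_pathway` (index p =
#' the pooled eQTL p) so the retained SNPs are in approximate linkage
#' equilibrium.
#'
#' @param genes Character vector of gene ids.
#' @param eqtl_store Named list mapping gene id to [qtl_probe_set()].
#' @param panel An [ld_panel()].
#' @param config A [pipeline_config()].
#' @return data.table `snp_id, gene, z_eqtl_abs, p_eqtl`; zero rows when no
#'   eQTL qualifies.
#' @export
pathway_snp_panel <- function(genes, eqtl_store, panel,
                              config = pipeline_config()) {
  pools <- list()
  for (g in sort(unique(genes))) {   # gene-order invariant
    ps <- eqtl_store[[g]]
    if (is.null(ps)) next
    rec <- data.table::as.data.table(ps$records)
    rec <- rec[is.finite(p) & p <= config$p_eqtl]
    if (nrow(rec) == 0L) next
    pools[[length(pools) + 1L]] <- data.table::data.table(
      snp_id = rec$snp_id, gene = g, z_eqtl_abs = abs(rec$beta / rec$se),
      p_eqtl = rec$p, chrom = rec$chrom, bp = rec$bp)
  }
  empty <- data.table::data.table(snp_id = character(), gene = character(),
                                  z_eqtl_abs = numeric(), p_eqtl = numeric(),
                                  chrom = character(), bp = integer())
  if (length(pools) == 0L) return(empty)
  pool <- data.table::rbindlist(pools)
  ## shared SNPs: keep the strongest |z| across member genes
  data.table::setorder(pool, snp_id, -z_eqtl_abs)
  pool <- pool[!duplicated(pool$snp_id)]
  kept <- ld_clump(pool[, .(snp_id, chrom, bp, p = p_eqtl)], panel,
                   p_index = config$p_eqtl, r2_max = config$r2_pathway,
                   window_kb = config$window_kb_pathway)
  if (length(kept) == 0L) return(empty)
  out <- pool[match(sort(kept), pool$snp_id)]
  out[]
}

#' Rank correlation of |Z| between a SNP panel and a trait
#'
#' Pairs each panel SNP's `|z_eqtl|` with the trait's `|z_gwas|` (matched on
#' `snp_id`; absolute Z-scores are allele-orientation free, so no
#' harmonization is needed) and computes Spearman's rho with average ranks
#' for ties. The p-value is two-sided: a t approximation for `n >= 30`, an
#' exact permutation p (`perm_B` permutations drawn from the current RNG
#' stream; set a seed for reproducibility) below that.
#'
#' @param snp_panel Output of [pathway_snp_panel()].
#' @param gwas Sumstats table for the trait.
#' @param config A [pipeline_config()].
#' @param set_id,trait_id,gene_indicator Labels carried into the result.
#' @return One-row data.table `set_id, gene_indicator, trait_id, n_snps,
#'   rho, p, method`; `rho`/`p` are `NA` with `method = "insufficient-data"`
#'   when fewer than `pathway_min_snps` SNPs overlap.
#' @export
pathway_trait_correlation <- function(snp_panel, gwas,
                                      config = pipeline_config(),
                                      set_id = "set", trait_id = "trait",
                                      gene_indicator = "") {
  gwas <- data.table::as.data.table(gwas)
  m <- match(snp_panel$snp_id, gwas$snp_id)
  keep <- !is.na(m)
  zx <- snp_panel$z_eqtl_abs[keep]
  zy <- abs(gwas$beta[m[keep]] / gwas$se[m[keep]])
  n <- length(zx)
  if (n < config$pathway_min_snps) {
    return(data.table::data.table(
      set_id = set_id, gene_indicator = gene_indicator, trait_id = trait_id,
      n_snps = n, rho = NA_real_, p = NA_real_,
      method = "insufficient-data"))
  }
  rho <- stats::cor(zx, zy, method = "spearman")
  if (n >= 30L) {
    tt <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
    pv <- .clamp_p(2 * stats::pt(-abs(tt), df = n - 2))
    method <- "t-approximation"
  } else {
    ## exact-style permutation on ranks; Pearson-on-ranks equals Spearman
    rx <- rank(zx); ry <- rank(zy)
    rx <- (rx - mean(rx)) / stats::sd(rx)
    ry <- (ry - mean(ry)) / stats::sd(ry)
    B <- config$perm_B
    perm <- matrix(0, n, B)
    for (b in seq_len(B)) perm[, b] <- sample(rx)
    rho_perm <- as.vector(crossprod(perm, ry)) / (n - 1)
    pv <- (sum(abs(rho_perm) >= abs(rho) - 1e-12) + 1) / (B + 1)
    method <- "permutation"
  }
  data.table::data.table(
    set_id = set_id, gene_indicator = gene_indicator, trait_id = trait_id,
    n_snps = n, rho = rho, p = pv, method = method)
}

#' Scan all gene sets containing an indicator gene
#'
#' Filters the supplied sets to those containing `gene_indicator`, builds
#' each set's pruned eQTL panel, computes the |Z| rank correlation against
#' the trait, sorts by ascending p and appends a Benjamini-Hochberg q-value
#' across the tested sets (an addition beyond the raw per-set p).
#'
#' @param gene_indicator Gene of interest.
#' @param gene_sets List of [gene_set()] objects.
#' @param eqtl_store Named list mapping gene id to [qtl_probe_set()].
#' @param gwas Sumstats table for the trait.
#' @param panel An [ld_panel()].
#' @param config A [pipeline_config()].
#' @param trait_id Label.
#' @return data.table of per-set results (tested sets only), with a
#'   `skipped` attribute listing sets that had no usable SNP panel.
#' @export
pathway_scan <- function(gene_indicator, gene_sets, eqtl_store, gwas, panel,
                         config = pipeline_config(), trait_id = "trait") {
  rows <- list()
  skipped <- list()
  for (s in gene_sets) {
    if (!(gene_indicator %in% s$genes)) next
    pan <- pathway_snp_panel(s$genes, eqtl_store, panel, config)
    if (nrow(pan) == 0L) {
      skipped[[length(skipped) + 1L]] <- data.table::data.table(
        set_id = s$set_id, reason = "no-qualifying-eqtls")
      next
    }
    res <- pathway_trait_correlation(pan, gwas, config, s$set_id, trait_id,
                                     gene_indicator)
    if (res$method == "insufficient-data") {
      skipped[[length(skipped) + 1L]] <- data.table::data.table(
        set_id = s$set_id, reason = "insufficient-data")
      next
    }
    res[, description := s$description]
    rows[[length(rows) + 1L]] <- res
  }
  out <- if (length(rows) > 0L) data.table::rbindlist(rows) else
    data.table::data.table(set_id = character(), gene_indicator = character(),
                           trait_id = character(), n_snps = integer(),
                           rho = numeric(), p = numeric(),
                           method = character(), description = character())
  if (nrow(out) > 0L) {
    out[, q := stats::p.adjust(p, method = "BH")]
    data.table::setorder(out, p, set_id)
  } else {
    out[, q := numeric()]
  }
  attr(out, "skipped") <- if (length(skipped) > 0L)
    data.table::rbindlist(skipped) else
    data.table::data.table(set_id = character(), reason = character())
  out
}
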