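## SMR co-localization test and HEIDI pleiotropy-vs-linkage test.
##
## SMR uses the top cis-QTL SNP as the instrument for a molecular probe and
## asks whether the probe and a complex trait share the association signal:
##   T_SMR = z_gwas^2 z_qtl^2 / (z_gwas^2 + z_qtl^2)  ~  chi^2_1 under H0,
##   b_smr = b_gwas / b_qtl (Wald ratio),
##   se_smr by the delta method.
## HEIDI tests heterogeneity of the ratio estimate across SNPs in LD with
## the top SNP: under pleiotropy (one shared causal variant) the per-SNP
## b_xy are homogeneous; heterogeneity indicates linkage (distinct causal
## variants).

## vectorized core: T statistic from the two z-scores
.smr_stat <- function(z_qtl, z_gwas) {
  zq2 <- z_qtl^2
  zg2 <- z_gwas^2
  t <- zq2 * zg2 / (zq2 + zg2)
  t[zg2 == 0] <- 0
  t
}

#' SMR test at a single (top) SNP
#'
#' Both records must already be harmonized to the same effect allele (see
#' [harmonize_sumstats()]).
#'
#' @param qtl,gwas Single sumstats records (1-row data.frames or lists) for
#'   the same SNP: the probe's QTL association and the trait's GWAS
#'   association.
#' @return `list(b_smr, se_smr, p_smr, t_smr)`.
#' @export
smr_test <- function(qtl, gwas) {
  b_q <- qtl$beta; se_q <- qtl$se
  b_g <- gwas$beta; se_g <- gwas$se
  if (b_q == 0) stop("undefined ratio: QTL effect is zero at the top SNP")
  z_q <- b_q / se_q
  z_g <- b_g / se_g
  t <- .smr_stat(z_q, z_g)
  b_smr <- b_g / b_q
  ## delta-method variance of b_g/b_q (valid at b_g = 0 too)
  se_smr <- sqrt(se_g^2 / b_q^2 + b_g^2 * se_q^2 / b_q^4)
  p_smr <- .clamp_p(stats::pchisq(t, df = 1, lower.tail = FALSE))
  list(b_smr = b_smr, se_smr = se_smr, p_smr = p_smr, t_smr = t)
}

## delta-method covariance of Wald ratios b_xy(i) = bg_i/bq_i across SNPs,
## for two independent samples (QTL and GWAS), LD correlation r between SNPs:
##   cov(bxy_i, bxy_j) = r_ij seg_i seg_j / (bq_i bq_j)
##                     + bg_i bg_j r_ij seq_i seq_j / (bq_i^2 bq_j^2)
.bxy_cov <- function(bq, seq_, bg, seg, r) {
  outer_seg <- outer(seg, seg)
  outer_bq <- outer(bq, bq)
  outer_bg <- outer(bg, bg)
  outer_seq <- outer(seq_, seq_)
  r * outer_seg / outer_bq + outer_bg * r * outer_seq / outer_bq^2
}

#' HEIDI test: heterogeneity in dependent instruments
#'
#' Selects cis SNPs around the top QTL SNP (QTL `p < heidi_snp_p`, r2 to the
#' top SNP within `[heidi_r2_min, heidi_r2_max]`, capped at
#' `heidi_max_snps` strongest by QTL p) and tests whether their Wald ratios
#' `b_xy(i) = b_gwas(i)/b_qtl(i)` differ from the top SNP's. The statistic
#' is the sum of squared standardized differences `z_d(i)`; its null
#' distribution is a weighted chi-square sum with weights the eigenvalues of
#' the correlation matrix of the `z_d`, evaluated by [p_quadform()].
#'
#' Records are aligned to the panel's counted alleles internally, so the
#' signed LD correlations and effect signs refer to the same alleles.
#'
#' @param qtl_set A [qtl_probe_set()].
#' @param gwas Sumstats table for the trait.
#' @param panel An [ld_panel()].
#' @param config A [pipeline_config()] (supplies the selection constants).
#' @param top_snp Optional SNP id to use as the top SNP; default is the
#'   smallest QTL p among panel-aligned records.
#' @return `list(p_heidi, n_heidi_snps, top_snp, method)`; `p_heidi` is `NA`
#'   when fewer than `heidi_min_snps` SNPs qualify.
#' @export
heidi_test <- function(qtl_set, gwas, panel, config = pipeline_config(),
                       top_snp = NULL) {
  aq <- align_to_panel(qtl_set$records, panel,
                       config$palindrome_maf_limit)$aligned
  ag <- align_to_panel(gwas, panel, config$palindrome_maf_limit)$aligned
  .heidi_core(aq, ag, panel, config, top_snp)
}

## core on panel-aligned inputs (shared with the co-localization screen)
.heidi_core <- function(aq, ag, panel, config, top_snp = NULL) {
  if (nrow(aq) == 0L) {
    return(list(p_heidi = NA_real_, n_heidi_snps = 0L,
                top_snp = NA_character_, method = NA_character_))
  }
  mg <- match(aq$snp_id, ag$snp_id)
  keep <- !is.na(mg)
  aq <- aq[keep]; ag <- ag[mg[keep]]
  if (nrow(aq) == 0L) {
    return(list(p_heidi = NA_real_, n_heidi_snps = 0L,
                top_snp = NA_character_, method = NA_character_))
  }
  if (is.null(top_snp)) {
    ord <- order(aq$p, aq$bp, aq$snp_id)
    top_snp <- aq$snp_id[ord[1L]]
  }
  ti <- match(top_snp, aq$snp_id)
  if (is.na(ti)) stop("top SNP ", top_snp, " not among aligned records")
  cand <- which(aq$p < config$heidi_snp_p & seq_len(nrow(aq)) != ti)
  ## monomorphic SNPs cannot enter the LD computation
  mono <- panel$map$monomorphic[match(aq$snp_id, panel$map$snp_id)]
  cand <- cand[!mono[cand]]
  if (mono[ti] || length(cand) == 0L) {
    return(list(p_heidi = NA_real_, n_heidi_snps = 0L, top_snp = top_snp,
                method = NA_character_))
  }
  r_top <- ld_r(panel, c(aq$snp_id[ti], aq$snp_id[cand]))[1L, -1L]
  ok <- r_top^2 >= config$heidi_r2_min & r_top^2 <= config$heidi_r2_max
  cand <- cand[ok]
  if (length(cand) > config$heidi_max_snps) {
    cand <- cand[order(aq$p[cand])][seq_len(config$heidi_max_snps)]
  }
  if (length(cand) < config$heidi_min_snps) {
    return(list(p_heidi = NA_real_, n_heidi_snps = length(cand),
                top_snp = top_snp, method = NA_character_))
  }
  sel <- c(ti, sort(cand))  # sort: result must not depend on input order
  r <- ld_r(panel, aq$snp_id[sel])
  bq <- aq$beta[sel]; seq_ <- aq$se[sel]
  bg <- ag$beta[sel]; seg <- ag$se[sel]
  bxy <- bg / bq
  C <- .bxy_cov(bq, seq_, bg, seg, r)
  k <- length(sel) - 1L
  d <- bxy[-1L] - bxy[1L]
  ## cov(d_i, d_j) = C_ij - C_i1 - C_j1 + C_11
  Cd <- C[-1L, -1L, drop = FALSE] -
    outer(C[-1L, 1L], rep(1, k)) - outer(rep(1, k), C[1L, -1L]) + C[1L, 1L]
  vd <- diag(Cd)
  if (any(vd <= 0)) {
    ## numerically degenerate variance; regularize
    vd <- pmax(vd, 1e-12)
  }
  z_d <- d / sqrt(vd)
  R <- Cd / sqrt(outer(vd, vd))
  if (any(!is.finite(R))) {
    warning("singular LD correlation structure in HEIDI; ridge applied")
    R[!is.finite(R)] <- 0
    diag(R) <- 1
  }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-6) {
    warning("HEIDI z_d correlation matrix not PSD; ridge applied")
    eps <- -min(ev) + 1e-8
    R <- (R + diag(eps, k)) / (1 + eps)
    ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  }
  q <- sum(z_d^2)
  p <- p_quadform(q, ev)
  list(p_heidi = as.numeric(p), n_heidi_snps = k, top_snp = top_snp,
       method = attr(p, "method"))
}

#' Co-localization screen across probes
#'
#' For each probe whose top cis-QTL association reaches the instrument
#' significance threshold, runs the SMR test at the top SNP (after
#' harmonizing the GWAS record onto the QTL effect allele) and the HEIDI
#' test, and flags `pass_smr = (p_smr < p_colocalization)` and
#' `pass_heidi = (p_heidi >= heidi_keep_p)`. An undefined HEIDI p (too few
#' SNPs) is treated as passing by default (`heidi_na_pass`): pleiotropy
#' cannot be rejected.
#'
#' @param probes List of [qtl_probe_set()] objects.
#' @param gwas Sumstats table for one trait.
#' @param panel An [ld_panel()].
#' @param config A [pipeline_config()].
#' @param trait_id Label recorded in the output.
#' @return data.table with one row per tested probe: `probe_id, trait_id,
#'   top_snp, b_smr, se_smr, p_smr, n_heidi_snps, p_heidi, heidi_method,
#'   pass_smr, pass_heidi`. Probes with no qualifying instrument are
#'   recorded in the `skipped` attribute with a reason.
#' @export
colocalization_screen <- function(probes, gwas, panel,
                                  config = pipeline_config(),
                                  trait_id = "trait") {
  rows <- list()
  skipped <- list()
  ## align the trait once; probe records are aligned per probe, after which
  ## both sides share the panel's counted alleles and match by snp_id
  ag <- align_to_panel(gwas, panel, config$palindrome_maf_limit)$aligned
  for (ps in probes) {
    aq <- align_to_panel(ps$records, panel,
                         config$palindrome_maf_limit)$aligned
    mg <- match(aq$snp_id, ag$snp_id)
    keep <- !is.na(mg)
    if (!any(keep)) {
      skipped[[length(skipped) + 1L]] <- data.table::data.table(
        probe_id = ps$probe_id, reason = "no-overlap")
      next
    }
    aq2 <- aq[keep]; hg <- ag[mg[keep]]
    ord <- order(aq2$p, aq2$bp, aq2$snp_id)
    top <- ord[1L]
    if (aq2$p[top] > config$p_instrument) {
      skipped[[length(skipped) + 1L]] <- data.table::data.table(
        probe_id = ps$probe_id, reason = "no-instrument")
      next
    }
    st <- smr_test(aq2[top], hg[top])
    hd <- .heidi_core(aq, ag, panel, config, top_snp = aq2$snp_id[top])
    rows[[length(rows) + 1L]] <- data.table::data.table(
      probe_id = ps$probe_id, trait_id = trait_id,
      top_snp = aq2$snp_id[top],
      b_smr = st$b_smr, se_smr = st$se_smr, p_smr = st$p_smr,
      n_heidi_snps = hd$n_heidi_snps, p_heidi = hd$p_heidi,
      heidi_method = hd$method %||% NA_character_,
      pass_smr = st$p_smr < config$p_colocalization,
      pass_heidi = if (is.na(hd$p_heidi)) config$heidi_na_pass
                   else hd$p_heidi >= config$heidi_keep_p)
  }
  out <- if (length(rows) > 0L) data.table::rbindlist(rows) else
    data.table::data.table(
      probe_id = character(), trait_id = character(), top_snp = character(),
      b_smr = numeric(), se_smr = numeric(), p_smr = numeric(),
      n_heidi_snps = integer(), p_heidi = numeric(),
      heidi_method = character(), pass_smr = logical(), pass_heidi = logical())
  attr(out, "skipped") <- if (length(skipped) > 0L)
    data.table::rbindlist(skipped) else
    data.table::data.table(probe_id = character(), reason = character())
  out
}
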