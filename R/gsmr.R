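## Multi-instrument summary-based MR (GSMR-style): instrument selection by
## exposure significance + LD clumping, HEIDI-style pleiotropy-outlier
## removal, and GLS combination of per-SNP Wald ratios with LD-aware
## covariance.

#' Construct an instrument set
#'
#' @param exposure_id,outcome_id Labels.
#' @param snps data.table with one row per instrument: `snp_id, b_exp,
#'   se_exp, b_out, se_out` (effects on the same allele).
#' @param ld_corr Signed LD correlation matrix over the instruments (order
#'   of `snps`); defaults to the identity (independent instruments).
#' @param removed data.table(snp_id, reason) of instruments excluded on the
#'   way to this set.
#' @return Object of class `instrument_set`.
#' @export
instrument_set <- function(exposure_id, outcome_id, snps,
                           ld_corr = NULL, removed = NULL) {
  snps <- data.table::as.data.table(snps)
  k <- nrow(snps)
  if (is.null(ld_corr)) ld_corr <- diag(1, k)
  if (!is.null(dim(ld_corr)) && any(dim(ld_corr) != k)) {
    stop("ld_corr dimension does not match number of instruments")
  }
  structure(list(exposure_id = as.character(exposure_id),
                 outcome_id = as.character(outcome_id),
                 snps = snps,
                 ld_corr = ld_corr,
                 removed = removed %||% data.table::data.table(
                   snp_id = character(), reason = character())),
            class = "instrument_set")
}

#' @export
print.instrument_set <- function(x, ...) {
  cat("<instrument_set> ", x$exposure_id, " -> ", x$outcome_id, ": ",
      nrow(x$snps), " instruments (", nrow(x$removed), " removed)\n",
      sep = "")
  invisible(x)
}

#' Select MR instruments for an exposure
#'
#' Implements the three instrument criteria: (1) association with the
#' exposure at `p <= p_instrument` (genome-wide significance by default);
#' (2) mutual linkage equilibrium, enforced by greedy clumping at
#' `r2 < r2_instruments`; (3) availability of a harmonized outcome record
#' (SNPs without one are dropped with reason `"no-outcome-record"`).
#' Exposure and outcome records are aligned to the panel's counted alleles
#' so the signed LD correlation matrix refers to the same alleles as the
#' effects.
#'
#' @param exposure A [qtl_probe_set()] (or sumstats table) for the exposure.
#' @param outcome Sumstats table for the outcome.
#' @param panel An [ld_panel()].
#' @param config A [pipeline_config()].
#' @param exposure_id,outcome_id Labels (default from the probe set).
#' @return An [instrument_set()]; zero rows signal "not testable".
#' @export
select_instruments <- function(exposure, outcome, panel,
                               config = pipeline_config(),
                               exposure_id = NULL, outcome_id = "outcome") {
  if (inherits(exposure, "qtl_probe_set")) {
    exposure_id <- exposure_id %||% exposure$probe_id
    exp_rec <- exposure$records
  } else {
    exposure_id <- exposure_id %||% "exposure"
    exp_rec <- data.table::as.data.table(exposure)
  }
  ae <- align_to_panel(exp_rec, panel, config$palindrome_maf_limit)
  ao <- align_to_panel(outcome, panel, config$palindrome_maf_limit)
  removed <- list(ae$exclusions)
  ex <- ae$aligned[p <= config$p_instrument]
  if (nrow(ex) == 0L) {
    return(instrument_set(exposure_id, outcome_id,
                          data.table::data.table(
                            snp_id = character(), b_exp = numeric(),
                            se_exp = numeric(), b_out = numeric(),
                            se_out = numeric()),
                          removed = data.table::rbindlist(removed)))
  }
  mo <- match(ex$snp_id, ao$aligned$snp_id)
  if (any(is.na(mo))) {
    removed[[length(removed) + 1L]] <- data.table::data.table(
      snp_id = ex$snp_id[is.na(mo)], reason = "no-outcome-record")
    ex <- ex[!is.na(mo)]
    mo <- mo[!is.na(mo)]
  }
  if (nrow(ex) == 0L) {
    return(instrument_set(exposure_id, outcome_id,
                          data.table::data.table(
                            snp_id = character(), b_exp = numeric(),
                            se_exp = numeric(), b_out = numeric(),
                            se_out = numeric()),
                          removed = data.table::rbindlist(removed)))
  }
  kept <- ld_clump(ex, panel, p_index = config$p_instrument,
                   r2_max = config$r2_instruments,
                   window_kb = config$window_kb_mr)
  clumped_away <- setdiff(ex$snp_id, kept)
  if (length(clumped_away) > 0L) {
    removed[[length(removed) + 1L]] <- data.table::data.table(
      snp_id = clumped_away, reason = "ld-clumped")
  }
  kept <- sort(kept)  # fit is order-invariant; fix a canonical order
  ke <- ex[match(kept, ex$snp_id)]
  ko <- ao$aligned[match(kept, ao$aligned$snp_id)]
  snps <- data.table::data.table(
    snp_id = kept, b_exp = ke$beta, se_exp = ke$se, p_exp = ke$p,
    b_out = ko$beta, se_out = ko$se, p_out = ko$p,
    chrom = ke$chrom, bp = ke$bp)
  R <- if (nrow(snps) > 0L) ld_r(panel, kept) else diag(0)
  instrument_set(exposure_id, outcome_id, snps, ld_corr = R,
                 removed = data.table::rbindlist(removed))
}

## per-SNP Wald ratio and delta-method variance
.ratio_and_var <- function(snps) {
  bxy <- snps$b_out / snps$b_exp
  v <- snps$se_out^2 / snps$b_exp^2 +
    snps$b_out^2 * snps$se_exp^2 / snps$b_exp^4
  list(bxy = bxy, var = v)
}

#' HEIDI-style pleiotropy-outlier removal
#'
#' Iteratively: compute a robust provisional causal estimate (median of the
#' per-SNP Wald ratios), standardize each SNP's deviation from it by the
#' delta-method SE, and remove SNPs whose two-sided heterogeneity p-value
#' falls below `p_heidi_outlier` (0.01). Repeats until a fixed point or
#' `max_iter`. With fewer than `min_instruments_filter` instruments the
#' filter is skipped with a warning (the provisional estimate would not be
#' robust).
#'
#' @param inst An [instrument_set()].
#' @param config A [pipeline_config()].
#' @param max_iter Maximum iterations (default 10).
#' @return The filtered [instrument_set()]; removed SNPs carry reason
#'   `"heidi-outlier"`.
#' @export
gsmr_outlier_filter <- function(inst, config = pipeline_config(),
                                max_iter = 10L) {
  if (nrow(inst$snps) < config$min_instruments_filter) {
    warning("fewer than ", config$min_instruments_filter,
            " instruments; pleiotropy-outlier filter skipped")
    return(inst)
  }
  snps <- inst$snps
  R <- inst$ld_corr
  removed <- inst$removed
  for (it in seq_len(max_iter)) {
    rv <- .ratio_and_var(snps)
    b_med <- stats::median(rv$bxy)
    ## the provisional estimate is itself noisy; its asymptotic variance
    ## (median of ~normals) enters the difference's SE
    var_med <- (pi / 2) * mean(rv$var) / length(rv$bxy)
    z_d <- (rv$bxy - b_med) / sqrt(rv$var + var_med)
    p_d <- .z2p(z_d)
    out <- p_d < config$p_heidi_outlier
    if (!any(out)) break
    removed <- data.table::rbindlist(list(
      removed,
      data.table::data.table(snp_id = snps$snp_id[out],
                             reason = "heidi-outlier")))
    keep <- !out
    snps <- snps[keep]
    R <- R[keep, keep, drop = FALSE]
    if (nrow(snps) == 0L) break
  }
  instrument_set(inst$exposure_id, inst$outcome_id, snps, R, removed)
}

#' GLS causal-effect estimate from an instrument set
#'
#' Combines the per-SNP Wald ratios `b_xy(i) = b_out(i)/b_exp(i)` by
#' generalized least squares with covariance
#' `V_ij = r_ij * sqrt(var_i * var_j)` (delta-method variances, LD
#' correlation `r` between instruments):
#' `b_xy = (1' V^-1 b) / (1' V^-1 1)`, `var(b_xy) = 1 / (1' V^-1 1)`,
#' two-sided normal p. With independent instruments this reduces to the
#' inverse-variance-weighted mean; with one instrument, to the Wald ratio
#' with its delta-method SE. A ridge (`ridge_eps` on the correlation
#' factor) is applied when `V` is ill-conditioned.
#'
#' @param inst An [instrument_set()].
#' @param config A [pipeline_config()].
#' @param direction Recorded in the result (`"forward"`/`"reverse"`).
#' @return `mr_result` list: `exposure_id, outcome_id, b_xy, se_xy, p_xy,
#'   n_instruments, removed, direction, testable`.
#' @export
gsmr_fit <- function(inst, config = pipeline_config(),
                     direction = "forward") {
  k <- nrow(inst$snps)
  if (k == 0L) {
    return(structure(list(exposure_id = inst$exposure_id,
                          outcome_id = inst$outcome_id,
                          b_xy = NA_real_, se_xy = NA_real_, p_xy = NA_real_,
                          n_instruments = 0L, removed = inst$removed,
                          direction = direction, testable = FALSE),
                     class = "mr_result"))
  }
  rv <- .ratio_and_var(inst$snps)
  R <- inst$ld_corr
  if (is.null(dim(R))) R <- matrix(R, 1L, 1L)
  kap <- kappa(R, exact = FALSE)
  if (!is.finite(kap) || kap > 1e8) {
    R <- (R + diag(config$ridge_eps, k)) / (1 + config$ridge_eps)
  }
  sdv <- sqrt(rv$var)
  V <- R * outer(sdv, sdv)
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) {
    R <- (R + diag(1e-3, k)) / (1 + 1e-3)
    V <- R * outer(sdv, sdv)
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) stop("singular instrument covariance after regularization")
  }
  ones <- rep(1, k)
  Vi1 <- backsolve(ch, forwardsolve(t(ch), ones))
  denom <- sum(Vi1)
  b <- sum(Vi1 * rv$bxy) / denom
  se <- sqrt(1 / denom)
  structure(list(exposure_id = inst$exposure_id,
                 outcome_id = inst$outcome_id,
                 b_xy = b, se_xy = se, p_xy = .z2p(b / se),
                 n_instruments = k, removed = inst$removed,
                 direction = direction, testable = TRUE),
            class = "mr_result")
}

#' @export
print.mr_result <- function(x, ...) {
  if (!x$testable) {
    cat("<mr_result> ", x$exposure_id, " -> ", x$outcome_id,
        " (", x$direction, "): not testable\n", sep = "")
  } else {
    cat("<mr_result> ", x$exposure_id, " -> ", x$outcome_id,
        " (", x$direction, "): b = ", signif(x$b_xy, 4),
        " (se ", signif(x$se_xy, 3), "), p = ", format(x$p_xy, digits = 3),
        ", ", x$n_instruments, " instruments\n", sep = "")
  }
  invisible(x)
}

#' Bidirectional MR with reverse-causation screen
#'
#' Runs forward MR (exposure -> outcome, exposure-associated instruments)
#' and reverse MR (outcome -> exposure, outcome-associated instruments),
#' each with instrument selection and pleiotropy-outlier removal. The
#' reverse direction is "not testable" when the outcome has no qualifying
#' instruments with exposure-side records; per the screening rule this
#' counts as passing the reverse-causation check (`reverse_ok`).
#'
#' @param exposure_qtl A [qtl_probe_set()] for the exposure.
#' @param outcome Sumstats table for the outcome (e.g. trait GWAS).
#' @param panel An [ld_panel()].
#' @param config A [pipeline_config()].
#' @param exposure_id,outcome_id Labels.
#' @return `list(forward = mr_result, reverse = mr_result, reverse_ok)`.
#' @export
gsmr_bidirectional <- function(exposure_qtl, outcome, panel,
                               config = pipeline_config(),
                               exposure_id = NULL, outcome_id = "outcome") {
  exposure_id <- exposure_id %||%
    if (inherits(exposure_qtl, "qtl_probe_set")) exposure_qtl$probe_id
    else "exposure"
  fwd_inst <- select_instruments(exposure_qtl, outcome, panel, config,
                                 exposure_id, outcome_id)
  if (nrow(fwd_inst$snps) >= config$min_instruments_filter) {
    fwd_inst <- gsmr_outlier_filter(fwd_inst, config)
  }
  forward <- gsmr_fit(fwd_inst, config, "forward")
  exp_rec <- if (inherits(exposure_qtl, "qtl_probe_set"))
    exposure_qtl$records else exposure_qtl
  rev_inst <- select_instruments(outcome, exp_rec, panel, config,
                                 exposure_id = outcome_id,
                                 outcome_id = exposure_id)
  if (nrow(rev_inst$snps) >= config$min_instruments_filter) {
    rev_inst <- gsmr_outlier_filter(rev_inst, config)
  }
  reverse <- gsmr_fit(rev_inst, config, "reverse")
  reverse_ok <- !reverse$testable || reverse$p_xy >= config$p_reverse
  list(forward = forward, reverse = reverse, reverse_ok = reverse_ok)
}
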