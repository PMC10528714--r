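## End-to-end orchestration: candidate CpGs -> co-localization (SMR + HEIDI)
## -> bidirectional MR with outlier removal (discovery) -> replication in a
## second mQTL cohort -> expression-mediation chaining -> pathway scans.
## Stage ordering is strict and audited: no MR without a co-localization
## pass, no replication without a discovery pass, no mediation without
## final_pass.

#' Pipeline configuration
#'
#' Houses every threshold of the screen. Defaults follow the published
#' screening rules: co-localization and MR significance at genome-wide
#' level (5e-8), instrument LD r2 < 0.2, pleiotropy-outlier HEIDI p < 0.01,
#' reverse-causation exclusion at p < 0.05, and pathway pruning at r2 <
#' 0.05 with eQTL p < 5e-8. The HEIDI selection constants and windows are
#' implementation defaults (the screening rules state only the thresholds
#' above) and are all configurable.
#'
#' @param p_colocalization SMR pass threshold (P_SMR below this
#'   co-localizes).
#' @param p_instrument Exposure-association threshold for instruments and
#'   for testing a probe at all.
#' @param p_mr Causal-contribution significance threshold (forward MR,
#'   replication, and both mediation links).
#' @param p_reverse Reverse-causation exclusion threshold.
#' @param r2_instruments Max LD r2 among MR instruments.
#' @param p_heidi_outlier Per-SNP heterogeneity p below which an instrument
#'   is removed as pleiotropic.
#' @param heidi_keep_p Probe-level HEIDI threshold: `p_heidi` below this
#'   indicates linkage rather than pleiotropy.
#' @param heidi_gate Apply `heidi_keep_p` as a hard filter at the
#'   co-localization stage (default TRUE); with FALSE, HEIDI is reported
#'   but pairs proceed regardless.
#' @param heidi_na_pass Treat an undefined HEIDI p (too few SNPs) as a pass
#'   (pleiotropy cannot be rejected).
#' @param heidi_snp_p,heidi_r2_min,heidi_r2_max,heidi_max_snps,heidi_min_snps
#'   HEIDI SNP-selection constants.
#' @param r2_pathway,p_eqtl,window_kb_pathway,pathway_min_snps Pathway-stage
#'   settings.
#' @param cis_window_kb Cis window half-width (kb) for locus definitions.
#' @param window_kb_mr Clump window (kb) for instrument selection.
#' @param min_instruments_filter Minimum instruments for the outlier filter.
#' @param palindrome_maf_limit See [harmonize_sumstats()].
#' @param perm_B Permutations for small-n pathway p-values.
#' @param ridge_eps Ridge added to ill-conditioned LD correlation factors.
#' @param seed Seed set at the start of [run_pipeline()].
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(p_colocalization = 5e-8,
                            p_instrument = 5e-8,
                            p_mr = 5e-8,
                            p_reverse = 0.05,
                            r2_instruments = 0.2,
                            p_heidi_outlier = 0.01,
                            heidi_keep_p = 0.01,
                            heidi_gate = TRUE,
                            heidi_na_pass = TRUE,
                            heidi_snp_p = 1.6e-3,
                            heidi_r2_min = 0.05,
                            heidi_r2_max = 0.9,
                            heidi_max_snps = 20L,
                            heidi_min_snps = 3L,
                            r2_pathway = 0.05,
                            p_eqtl = 5e-8,
                            window_kb_pathway = 250,
                            pathway_min_snps = 10L,
                            cis_window_kb = 1000,
                            window_kb_mr = 10000,
                            min_instruments_filter = 3L,
                            palindrome_maf_limit = 0.4,
                            perm_B = 10000L,
                            ridge_eps = 1e-6,
                            seed = 1L) {
  cfg <- as.list(environment())
  probs <- c("p_colocalization", "p_instrument", "p_mr", "p_reverse",
             "p_heidi_outlier", "heidi_keep_p", "heidi_snp_p", "p_eqtl")
  for (nm in probs) {
    if (!is.finite(cfg[[nm]]) || cfg[[nm]] <= 0 || cfg[[nm]] >= 1) {
      stop(nm, " must lie in (0, 1)")
    }
  }
  for (nm in c("r2_instruments", "r2_pathway")) {
    if (!is.finite(cfg[[nm]]) || cfg[[nm]] <= 0 || cfg[[nm]] >= 1) {
      stop(nm, " must lie in (0, 1)")
    }
  }
  structure(cfg, class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config> P_SMR<", x$p_colocalization, ", MR p<", x$p_mr,
      ", reverse p<", x$p_reverse, ", instrument r2<", x$r2_instruments,
      ", HEIDI outlier p<", x$p_heidi_outlier, ", pathway r2<",
      x$r2_pathway, "\n", sep = "")
  invisible(x)
}

.removed_str <- function(removed) {
  if (is.null(removed) || nrow(removed) == 0L) return("")
  paste(paste0(removed$snp_id, ":", removed$reason), collapse = ";")
}

.empty_records <- function() {
  data.table::data.table(
    cpg_id = character(), trait_id = character(), top_snp = character(),
    b_smr = numeric(), se_smr = numeric(), p_smr = numeric(),
    n_heidi_snps = integer(), p_heidi = numeric(), pass_smr = logical(),
    pass_heidi = logical(), disc_b = numeric(), disc_se = numeric(),
    disc_p = numeric(), disc_n_inst = integer(), disc_removed = character(),
    rev_b = numeric(), rev_se = numeric(), rev_p = numeric(),
    rev_n_inst = integer(), reverse_ok = logical(), status = character())
}

#' Discovery stage: co-localization then bidirectional MR
#'
#' For every candidate CpG x trait pair: runs the co-localization screen
#' (probe tested only if its top QTL association reaches `p_instrument`);
#' pairs with `p_smr < p_colocalization` (and, when `heidi_gate`, a HEIDI
#' pass) proceed to bidirectional MR with pleiotropy-outlier removal.
#' Pairs are excluded when the forward MR misses `p_mr` or the reverse MR
#' shows reverse causation (`p < p_reverse`). Per-pair failures are
#' recorded with reason codes and never abort the run.
#'
#' @param candidate_cpgs Named list of [qtl_probe_set()] (the EWAS
#'   candidate CpGs).
#' @param traits Named list of per-trait GWAS sumstats tables.
#' @param panel An [ld_panel()].
#' @param config A [pipeline_config()].
#' @return `list(records = data.table, audit = data.table)`.
#' @export
run_discovery <- function(candidate_cpgs, traits, panel,
                          config = pipeline_config()) {
  rows <- list(); audit <- list()
  note <- function(stage, cpg, trait, action) {
    audit[[length(audit) + 1L]] <<- data.table::data.table(
      stage = stage, cpg_id = cpg, trait_id = trait, action = action)
  }
  for (tr in names(traits)) {
    scr <- colocalization_screen(candidate_cpgs, traits[[tr]], panel,
                                 config, trait_id = tr)
    skipped <- attr(scr, "skipped")
    if (nrow(skipped) > 0L) {
      for (i in seq_len(nrow(skipped))) {
        note("colocalization", skipped$probe_id[i], tr,
             paste0("skipped:", skipped$reason[i]))
        rows[[length(rows) + 1L]] <- data.table::data.table(
          cpg_id = skipped$probe_id[i], trait_id = tr,
          top_snp = NA_character_, b_smr = NA_real_, se_smr = NA_real_,
          p_smr = NA_real_, n_heidi_snps = NA_integer_, p_heidi = NA_real_,
          pass_smr = FALSE, pass_heidi = NA, disc_b = NA_real_,
          disc_se = NA_real_, disc_p = NA_real_, disc_n_inst = NA_integer_,
          disc_removed = "", rev_b = NA_real_, rev_se = NA_real_,
          rev_p = NA_real_, rev_n_inst = NA_integer_, reverse_ok = NA,
          status = skipped$reason[i])
      }
    }
    for (i in seq_len(nrow(scr))) {
      r <- scr[i]
      note("colocalization", r$probe_id, tr, "tested")
      base <- data.table::data.table(
        cpg_id = r$probe_id, trait_id = tr, top_snp = r$top_snp,
        b_smr = r$b_smr, se_smr = r$se_smr, p_smr = r$p_smr,
        n_heidi_snps = r$n_heidi_snps, p_heidi = r$p_heidi,
        pass_smr = r$pass_smr, pass_heidi = r$pass_heidi,
        disc_b = NA_real_, disc_se = NA_real_, disc_p = NA_real_,
        disc_n_inst = NA_integer_, disc_removed = "", rev_b = NA_real_,
        rev_se = NA_real_, rev_p = NA_real_, rev_n_inst = NA_integer_,
        reverse_ok = NA, status = "")
      if (!r$pass_smr) {
        base$status <- "smr-fail"
        rows[[length(rows) + 1L]] <- base
        next
      }
      if (config$heidi_gate && !r$pass_heidi) {
        base$status <- "heidi-fail"
        rows[[length(rows) + 1L]] <- base
        next
      }
      note("mr", r$probe_id, tr, "bidirectional")
      bid <- gsmr_bidirectional(candidate_cpgs[[r$probe_id]], traits[[tr]],
                                panel, config, exposure_id = r$probe_id,
                                outcome_id = tr)
      fw <- bid$forward; rv <- bid$reverse
      base[, `:=`(disc_b = fw$b_xy, disc_se = fw$se_xy, disc_p = fw$p_xy,
                  disc_n_inst = fw$n_instruments,
                  disc_removed = .removed_str(fw$removed),
                  rev_b = rv$b_xy, rev_se = rv$se_xy, rev_p = rv$p_xy,
                  rev_n_inst = rv$n_instruments,
                  reverse_ok = bid$reverse_ok)]
      base$status <- if (!fw$testable || is.na(fw$p_xy)) "mr-fail"
        else if (fw$p_xy >= config$p_mr) "mr-fail"
        else if (!bid$reverse_ok) "reverse-fail"
        else "pass-discovery"
      rows[[length(rows) + 1L]] <- base
    }
  }
  records <- if (length(rows) > 0L) data.table::rbindlist(rows) else
    .empty_records()
  data.table::setorder(records, trait_id, cpg_id)
  list(records = records,
       audit = if (length(audit) > 0L) data.table::rbindlist(audit) else
         data.table::data.table(stage = character(), cpg_id = character(),
                                trait_id = character(), action = character()))
}

#' Replication stage
#'
#' Re-runs the forward MR for every pair that passed discovery, using the
#' replication cohort's mQTLs against the same trait GWAS, and sets
#' `final_pass` (discovery pass AND replication `p < p_mr` AND reverse
#' check ok). Replication filters on p only; a significant but
#' sign-discordant replication still passes and is flagged
#' `sign_discordant`. CpGs absent from the replication cohort fail with
#' reason `"not-in-replication"`.
#'
#' @param discovery Output of [run_discovery()].
#' @param replication_mqtl Named list of replication-cohort
#'   [qtl_probe_set()].
#' @param traits Named list of per-trait GWAS sumstats.
#' @param panel An [ld_panel()].
#' @param config A [pipeline_config()].
#' @return `list(records, audit)` with replication columns appended.
#' @export
run_replication <- function(discovery, replication_mqtl, traits, panel,
                            config = pipeline_config()) {
  records <- data.table::copy(discovery$records)
  audit <- data.table::copy(discovery$audit)
  records[, `:=`(repl_b = NA_real_, repl_se = NA_real_, repl_p = NA_real_,
                 repl_n_inst = NA_integer_, repl_status = "",
                 sign_discordant = NA, final_pass = FALSE)]
  idx <- which(records$status == "pass-discovery")
  for (i in idx) {
    cpg <- records$cpg_id[i]; tr <- records$trait_id[i]
    audit <- data.table::rbindlist(list(audit, data.table::data.table(
      stage = "replication", cpg_id = cpg, trait_id = tr,
      action = "forward-mr")))
    ps <- replication_mqtl[[cpg]]
    if (is.null(ps)) {
      records[i, `:=`(repl_status = "not-in-replication",
                      final_pass = FALSE)]
      next
    }
    inst <- select_instruments(ps, traits[[tr]], panel, config,
                               exposure_id = cpg, outcome_id = tr)
    if (nrow(inst$snps) >= config$min_instruments_filter) {
      inst <- gsmr_outlier_filter(inst, config)
    }
    fit <- gsmr_fit(inst, config, "forward")
    if (!fit$testable || is.na(fit$p_xy)) {
      records[i, `:=`(repl_status = "not-testable", final_pass = FALSE)]
      next
    }
    ok <- fit$p_xy < config$p_mr
    records[i, `:=`(repl_b = fit$b_xy, repl_se = fit$se_xy,
                    repl_p = fit$p_xy, repl_n_inst = fit$n_instruments,
                    repl_status = if (ok) "pass" else "replication-fail",
                    sign_discordant = ok &&
                      sign(fit$b_xy) != sign(records$disc_b[i]),
                    final_pass = ok)]
  }
  list(records = records, audit = audit)
}

#' Expression-mediation chaining for one replicated CpG-trait pair
#'
#' For each gene whose top eQTL SNP lies within `cis_window_kb` of the CpG
#' (same chromosome): runs MR of CpG -> expression (mQTL instruments,
#' eQTL outcome) and expression -> trait (eQTL instruments, GWAS outcome).
#' A gene link is reported when both are significant at `p_mr`; the sign of
#' the chain product is checked against the direct CpG -> trait estimate
#' and flagged `"sign-inconsistent-chain"` on disagreement.
#'
#' @param record One row of the replication-stage records (must have
#'   `final_pass == TRUE`).
#' @param mqtl_probe The CpG's discovery [qtl_probe_set()].
#' @param eqtl_store Named list of gene [qtl_probe_set()].
#' @param gwas The trait's sumstats table.
#' @param panel An [ld_panel()].
#' @param config A [pipeline_config()].
#' @return data.table of gene links (possibly zero rows).
#' @export
mediate_expression <- function(record, mqtl_probe, eqtl_store, gwas, panel,
                               config = pipeline_config()) {
  stopifnot(isTRUE(record$final_pass))
  links <- list()
  win <- config$cis_window_kb * 1000
  for (g in names(eqtl_store)) {
    ps <- eqtl_store[[g]]
    top <- ps$records[which.min(ps$records$p)]
    if (nrow(top) == 0L || is.na(top$chrom)) next
    cpg_chrom <- mqtl_probe$probe_chrom
    cpg_bp <- mqtl_probe$probe_bp
    if (top$chrom != cpg_chrom || abs(top$bp - cpg_bp) > win) next
    ## CpG -> expression
    i1 <- select_instruments(mqtl_probe, ps$records, panel, config,
                             exposure_id = record$cpg_id, outcome_id = g)
    if (nrow(i1$snps) >= config$min_instruments_filter) {
      i1 <- gsmr_outlier_filter(i1, config)
    }
    f1 <- gsmr_fit(i1, config, "forward")
    if (!f1$testable || is.na(f1$p_xy) || f1$p_xy >= config$p_mr) next
    ## expression -> trait
    i2 <- select_instruments(ps, gwas, panel, config, exposure_id = g,
                             outcome_id = record$trait_id)
    if (nrow(i2$snps) >= config$min_instruments_filter) {
      i2 <- gsmr_outlier_filter(i2, config)
    }
    f2 <- gsmr_fit(i2, config, "forward")
    if (!f2$testable || is.na(f2$p_xy) || f2$p_xy >= config$p_mr) next
    links[[length(links) + 1L]] <- data.table::data.table(
      cpg_id = record$cpg_id, trait_id = record$trait_id, gene_id = g,
      cg_b = f1$b_xy, cg_se = f1$se_xy, cg_p = f1$p_xy,
      gt_b = f2$b_xy, gt_se = f2$se_xy, gt_p = f2$p_xy,
      flag = if (sign(f1$b_xy * f2$b_xy) == sign(record$disc_b)) ""
             else "sign-inconsistent-chain")
  }
  if (length(links) > 0L) data.table::rbindlist(links) else
    data.table::data.table(cpg_id = character(), trait_id = character(),
                           gene_id = character(), cg_b = numeric(),
                           cg_se = numeric(), cg_p = numeric(),
                           gt_b = numeric(), gt_se = numeric(),
                           gt_p = numeric(), flag = character())
}

#' Run the full pipeline on a simulated or assembled study
#'
#' Discovery, replication, expression mediation, and a pathway scan for
#' every mediating gene found. The config seed is set at the start, so
#' identical study + config give byte-identical exported tables.
#'
#' @param study A `methmr_study` (from [simulate_study()]) or a list with
#'   the same elements (`mqtl_disc`, `mqtl_repl`, `eqtl`, `gwas`, `panel`,
#'   `gene_sets`).
#' @param config A [pipeline_config()].
#' @return Object of class `methmr_results`: `records`, `gene_links`,
#'   `pathways`, `audit`, `config`.
#' @export
run_pipeline <- function(study, config = pipeline_config()) {
  set.seed(config$seed)
  disc <- run_discovery(study$mqtl_disc, study$gwas, study$panel, config)
  repl <- run_replication(disc, study$mqtl_repl, study$gwas, study$panel,
                          config)
  records <- repl$records
  audit <- repl$audit
  links <- list()
  for (i in which(records$final_pass)) {
    audit <- data.table::rbindlist(list(audit, data.table::data.table(
      stage = "mediation", cpg_id = records$cpg_id[i],
      trait_id = records$trait_id[i], action = "gene-scan")))
    links[[length(links) + 1L]] <- mediate_expression(
      records[i], study$mqtl_disc[[records$cpg_id[i]]], study$eqtl,
      study$gwas[[records$trait_id[i]]], study$panel, config)
  }
  gene_links <- if (length(links) > 0L) data.table::rbindlist(links) else
    data.table::data.table(cpg_id = character(), trait_id = character(),
                           gene_id = character(), cg_b = numeric(),
                           cg_se = numeric(), cg_p = numeric(),
                           gt_b = numeric(), gt_se = numeric(),
                           gt_p = numeric(), flag = character())
  data.table::setorder(gene_links, trait_id, cpg_id, gene_id)
  pathways <- list()
  if (nrow(gene_links) > 0L && length(study$gene_sets) > 0L) {
    for (i in seq_len(nrow(gene_links))) {
      g <- gene_links$gene_id[i]; tr <- gene_links$trait_id[i]
      audit <- data.table::rbindlist(list(audit, data.table::data.table(
        stage = "pathway", cpg_id = gene_links$cpg_id[i], trait_id = tr,
        action = paste0("scan:", g))))
      pathways[[length(pathways) + 1L]] <- pathway_scan(
        g, study$gene_sets, study$eqtl, study$gwas[[tr]], study$panel,
        config, trait_id = tr)
    }
  }
  pathway_tab <- if (length(pathways) > 0L)
    data.table::rbindlist(pathways) else
    data.table::data.table(set_id = character(), gene_indicator = character(),
                           trait_id = character(), n_snps = integer(),
                           rho = numeric(), p = numeric(),
                           method = character(), description = character(),
                           q = numeric())
  structure(list(records = records, gene_links = gene_links,
                 pathways = pathway_tab, audit = audit, config = config),
            class = "methmr_results")
}

#' @export
print.methmr_results <- function(x, ...) {
  cat("<methmr_results> ", nrow(x$records), " CpG-trait pairs screened; ",
      sum(x$records$final_pass), " passed discovery+replication; ",
      nrow(x$gene_links), " gene mediation links\n", sep = "")
  invisible(x)
}

#' Export pipeline results as TSV tables
#'
#' Writes `mediation_records.tsv`, `gene_links.tsv`, `pathway_results.tsv`
#' and `audit_log.tsv` with deterministic column and row order (trait, then
#' CpG). Betas and SEs are written at full precision; display-rounded
#' copies (3 significant digits) are appended for the main effect columns.
#'
#' @param results A `methmr_results`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
export_results <- function(results, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rec <- data.table::copy(results$records)
  data.table::setorder(rec, trait_id, cpg_id)
  for (cl in c("b_smr", "p_smr", "disc_b", "disc_p", "repl_b", "repl_p")) {
    if (!is.null(rec[[cl]])) rec[[paste0(cl, "_rounded")]] <- signif(rec[[cl]], 3)
  }
  data.table::fwrite(rec, file.path(dir, "mediation_records.tsv"),
                     sep = "\t", quote = FALSE)
  gl <- data.table::copy(results$gene_links)
  if (nrow(gl) > 0L) data.table::setorder(gl, trait_id, cpg_id, gene_id)
  data.table::fwrite(gl, file.path(dir, "gene_links.tsv"), sep = "\t",
                     quote = FALSE)
  data.table::fwrite(results$pathways, file.path(dir, "pathway_results.tsv"),
                     sep = "\t", quote = FALSE)
  data.table::fwrite(results$audit, file.path(dir, "audit_log.tsv"),
                     sep = "\t", quote = FALSE)
  invisible(dir)
}

#' Score pipeline results against a study's ground truth
#'
#' Uses the generator's manifest: a true positive is a `final_pass` pair
#' matching a planted mediation (CpG, trait); any other `final_pass` pair
#' is a false positive. Also reports how often linkage/reverse CpGs that
#' passed the SMR stage were caught by the HEIDI gate or the
#' reverse-causation filter.
#'
#' @param results A `methmr_results`.
#' @param study The `methmr_study` the results came from (or its manifest).
#' @return `list(n_true, tp, fp, fn, tpr, confound_occurrences,
#'   confound_caught, catch_rate)`.
#' @export
score_results <- function(results, study) {
  manifest <- if (inherits(study, "methmr_study")) study$manifest else study
  truth_pairs <- data.table::as.data.table(manifest$true_pairs)
  rec <- results$records
  key <- function(c_, t_) paste(c_, t_, sep = "|")
  true_keys <- key(truth_pairs$cpg_id, truth_pairs$trait_id)
  pass_keys <- key(rec$cpg_id[rec$final_pass], rec$trait_id[rec$final_pass])
  tp <- sum(pass_keys %in% true_keys)
  fp <- sum(!(pass_keys %in% true_keys))
  fn <- sum(!(true_keys %in% pass_keys))
  cpgs <- data.table::as.data.table(manifest$cpgs)
  confound <- cpgs[topology %in% c("linkage", "reverse")]
  conf <- rec[cpg_id %in% confound$cpg_id & pass_smr %in% TRUE]
  ## only the CpG's own trait pairing is a meaningful confounding occurrence
  conf <- conf[key(cpg_id, trait_id) %in%
                 key(confound$cpg_id, confound$trait_id)]
  caught <- conf$status %in% c("heidi-fail", "reverse-fail")
  list(n_true = length(true_keys), tp = tp, fp = fp, fn = fn,
       tpr = if (length(true_keys) > 0L) tp / length(true_keys) else NA_real_,
       confound_occurrences = nrow(conf), confound_caught = sum(caught),
       catch_rate = if (nrow(conf) > 0L) mean(caught) else NA_real_)
}
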