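## Synthetic-data generator: block-LD genotypes, an explicit causal model
## (exposure EWAS CpGs -> genes -> traits, plus pleiotropy / linkage /
## reverse / null topologies), per-cohort individual-level simulation, and
## per-SNP summary statistics — everything the pipeline consumes, with a
## ground-truth manifest.
##
## Summary statistics are generated from explicit individual-level
## simulation (not from a multivariate normal of Z-scores) so that LD,
## allele frequency and delta-method behavior are internally consistent.

.NONPAL_PAIRS <- matrix(c("A", "G", "A", "C", "T", "G", "T", "C",
                          "G", "A", "C", "A", "G", "T", "C", "T"),
                        ncol = 2, byrow = TRUE)

#' Scenario specification for the synthetic study
#'
#' Defines the study conditions: cohort sample sizes, the block-LD panel
#' structure, the causal-topology census across CpGs, and effect sizes.
#' Defaults are a desk-scale emulation of the real data sources: the
#' discovery mQTL cohort mirrors an ~2000-subject methylation study, the
#' replication cohort an ~1000-subject one, with eQTL and GWAS cohorts as
#' larger consortium-style samples, and a 500-individual genotype reference
#' panel.
#'
#' @param n_ref Reference-panel individuals.
#' @param n_mqtl_disc,n_mqtl_repl Discovery/replication mQTL cohort sizes.
#' @param n_eqtl,n_gwas eQTL and GWAS cohort sizes.
#' @param snps_per_block SNPs per LD block.
#' @param within_block_rho Latent exchangeable correlation within a block
#'   (genotype-scale r is somewhat attenuated by dosage thresholding).
#' @param n_mediation,n_pleiotropy,n_linkage,n_reverse,n_null CpG counts by
#'   causal topology.
#' @param n_traits Number of quantitative traits.
#' @param n_support_per_trait Trait-affecting "pathway support" genes per
#'   trait (expression affects the trait directly, not via a CpG).
#' @param n_decoy_genes Genes with cis eQTLs but no trait effect (decoy
#'   pathway).
#' @param n_null_blocks LD blocks shared by the null CpGs (decoy genes are
#'   overlaid on the same blocks).
#' @param b_snp_cpg_range Range of per-SNP cis effects on CpG methylation.
#' @param b_cpg_gene CpG -> gene-expression effect (mediation chain).
#' @param b_gene_trait Gene-expression -> trait effect (mediation chain).
#' @param b_pleiotropy Direct SNP -> trait effect of the planted pleiotropic
#'   mQTL SNP.
#' @param b_pleio_snp_cpg CpG effect of the pleiotropic SNP (kept below the
#'   clean cis effects so it is rarely the top mQTL).
#' @param b_linkage Direct SNP -> trait effect of the linkage partner SNP.
#' @param b_null_range Cis effect range for null CpGs.
#' @param b_trait_snp_range Per-SNP effects of each trait's own loci.
#' @param b_trait_cpg Trait -> CpG effect for reverse-topology CpGs.
#' @param b_support_eqtl_range Cis eQTL effect range for support and decoy
#'   genes (the spread drives the pathway rank correlation).
#' @param b_support_trait Expression -> trait effect of support genes.
#' @param maf_range Allele-frequency range of the effect allele.
#' @param noise_sd Residual SD of every phenotype layer.
#' @param smoke_prev,b_smoke_range Exposure (smoking) prevalence and CpG
#'   effect range; used only for the EWAS-style candidate table.
#' @param simulate_smoking Include the exposure variable.
#' @param cis_window_kb Cis window half-width used for probe coverage.
#' @param orient_frac Fraction of emitted records with randomized allele
#'   orientation (exercises harmonization downstream).
#' @param seed RNG seed for the whole study.
#' @return Object of class `scenario_spec`.
#' @export
scenario_spec <- function(n_ref = 500L,
                          n_mqtl_disc = 2000L, n_mqtl_repl = 1000L,
                          n_eqtl = 3000L, n_gwas = 10000L,
                          snps_per_block = 40L, within_block_rho = 0.9,
                          n_mediation = 5L, n_pleiotropy = 5L,
                          n_linkage = 5L, n_reverse = 5L, n_null = 80L,
                          n_traits = 3L, n_support_per_trait = 4L,
                          n_decoy_genes = 12L, n_null_blocks = 12L,
                          b_snp_cpg_range = c(0.5, 0.9),
                          b_cpg_gene = 0.7, b_gene_trait = 0.45,
                          b_pleiotropy = 0.35, b_pleio_snp_cpg = 0.5,
                          b_linkage = 0.45,
                          b_null_range = c(0.4, 0.8),
                          b_trait_snp_range = c(0.4, 0.7),
                          b_trait_cpg = 0.9,
                          b_support_eqtl_range = c(0.3, 0.9),
                          b_support_trait = 0.45,
                          maf_range = c(0.05, 0.5),
                          noise_sd = 1,
                          smoke_prev = 0.25, b_smoke_range = c(0.1, 0.3),
                          simulate_smoking = TRUE,
                          cis_window_kb = 1000,
                          orient_frac = 0.4,
                          seed = 1L) {
  spec <- as.list(environment())
  stopifnot(noise_sd > 0, all(is.finite(unlist(spec[grepl("^b_", names(spec))]))),
            within_block_rho >= 0, within_block_rho < 1,
            maf_range[1] > 0, maf_range[2] <= 0.5)
  spec$n_blocks <- with(spec, 2L * n_mediation + 3L * n_pleiotropy +
                          n_linkage + 3L * n_traits +
                          2L * n_support_per_trait * n_traits +
                          n_null_blocks)
  structure(spec, class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat("<scenario_spec> ", x$n_blocks, " blocks x ", x$snps_per_block,
      " SNPs; cohorts ref=", x$n_ref, " mQTL=", x$n_mqtl_disc, "/",
      x$n_mqtl_repl, " eQTL=", x$n_eqtl, " GWAS=", x$n_gwas,
      "; CpGs med/pleio/link/rev/null = ", x$n_mediation, "/",
      x$n_pleiotropy, "/", x$n_linkage, "/", x$n_reverse, "/", x$n_null,
      "; seed ", x$seed, "\n", sep = "")
  invisible(x)
}

## ---- layout & ground truth --------------------------------------------

## Pack block groups onto chromosomes (4 slots per chromosome, 0.5 Mb
## apart, blocks of a group on consecutive slots so a cis window can span
## a multi-signal architecture).
.pack_blocks <- function(group_sizes) {
  chrom <- integer(0); slot <- integer(0); group <- integer(0)
  cur_chrom <- 1L; cur_slot <- 0L
  for (gi in seq_along(group_sizes)) {
    sz <- group_sizes[gi]
    if (cur_slot + sz > 4L) { cur_chrom <- cur_chrom + 1L; cur_slot <- 0L }
    chrom <- c(chrom, rep(cur_chrom, sz))
    slot <- c(slot, cur_slot + seq_len(sz) - 1L)
    group <- c(group, rep(gi, sz))
    cur_slot <- cur_slot + sz
  }
  data.table::data.table(chrom = as.character(chrom), slot = slot,
                         group = group)
}

.build_truth <- function(spec) {
  with(spec, {
    ## group roster: one row per block group
    groups <- data.table::data.table(
      role = c(rep("mediation", n_mediation), rep("pleiotropy", n_pleiotropy),
               rep("linkage", n_linkage), rep("trait", n_traits),
               rep("support", n_support_per_trait * n_traits),
               rep("null", n_null_blocks)),
      size = c(rep(2L, n_mediation), rep(3L, n_pleiotropy),
               rep(1L, n_linkage), rep(3L, n_traits),
               rep(2L, n_support_per_trait * n_traits),
               rep(1L, n_null_blocks)))
    groups[, group := .I]
    packed <- .pack_blocks(groups$size)
    blocks <- packed[, .(block = .I, chrom, slot, group)]
    blocks[, start := 1e6 + slot * 5e5]
    blocks <- merge(blocks, groups[, .(group, role)], by = "group")
    data.table::setorder(blocks, block)

    ## SNP map
    m <- snps_per_block
    snp_map <- blocks[, .(block = rep(block, each = m),
                          chrom = rep(chrom, each = m),
                          bp = as.integer(rep(start, each = m) +
                                            5000 * (seq_len(m) - 1L)))]
    nsnp <- nrow(snp_map)
    snp_map[, snp_id := sprintf("rs%06d", 100000L + .I)]
    pair <- .NONPAL_PAIRS[sample.int(nrow(.NONPAL_PAIRS), nsnp,
                                     replace = TRUE), , drop = FALSE]
    snp_map[, `:=`(a1 = pair[, 1], a2 = pair[, 2],
                   freq = runif(nsnp, maf_range[1], maf_range[2]))]
    data.table::setcolorder(snp_map, c("snp_id", "chrom", "bp", "a1", "a2",
                                       "freq", "block"))

    traits <- paste0("trait", seq_len(n_traits))
    rr_trait <- function(i) traits[(i - 1L) %% n_traits + 1L]
    blk_of_group <- split(blocks$block, blocks$group)
    snp_of_block <- split(snp_map$snp_id, snp_map$block)
    mid_bp <- function(blks) {
      s <- snp_map[block %in% blks]
      as.integer(round(mean(range(s$bp))))
    }
    chrom_of <- function(blk) blocks$chrom[match(blk, blocks$block)]

    cpg_ids <- sprintf("cg%08d", sample.int(99999999L,
                                            n_mediation + n_pleiotropy +
                                              n_linkage + n_reverse + n_null))
    cpgs <- list(); cpg_eff <- list(); trait_snp_eff <- list()
    genes <- list(); gene_eqtl_eff <- list(); gene_from_cpg <- list()
    gene_trait_eff <- list(); rev_eff <- list()
    ci <- 0L; gi_med <- 0L
    g_role <- groups$role

    ## mediation CpGs: 2 cis blocks, 2 causal SNPs per block; chain
    ## CpG -> gene -> trait with alternating signs
    for (i in seq_len(n_mediation)) {
      ci <- ci + 1L; gi_med <- gi_med + 1L
      grp <- which(g_role == "mediation")[i]
      blks <- blk_of_group[[grp]]
      snps <- unlist(lapply(snp_of_block[as.character(blks)],
                            function(s) s[c(5L, 25L)]))
      gene_id <- sprintf("GENE%03d", gi_med)
      tr <- rr_trait(i)
      b2 <- b_cpg_gene * ifelse(i %% 2L == 0L, -1, 1)
      b3 <- b_gene_trait * ifelse(i %% 3L == 0L, -1, 1)
      cpgs[[ci]] <- data.table::data.table(
        cpg_id = cpg_ids[ci], chrom = chrom_of(blks[1]), bp = mid_bp(blks),
        topology = "mediation", trait_id = tr, gene_id = gene_id)
      cpg_eff[[ci]] <- data.table::data.table(
        cpg_id = cpg_ids[ci], snp_id = snps,
        beta = runif(length(snps), b_snp_cpg_range[1], b_snp_cpg_range[2]))
      genes[[length(genes) + 1L]] <- data.table::data.table(
        gene_id = gene_id, role = "mediator", chrom = chrom_of(blks[1]),
        bp = mid_bp(blks), trait_id = tr, cpg_id = cpg_ids[ci])
      gene_from_cpg[[length(gene_from_cpg) + 1L]] <- data.table::data.table(
        gene_id = gene_id, cpg_id = cpg_ids[ci], beta = b2)
      gene_trait_eff[[length(gene_trait_eff) + 1L]] <- data.table::data.table(
        gene_id = gene_id, trait_id = tr, beta = b3)
    }

    ## pleiotropy CpGs: 3 cis blocks; one cis SNP additionally has a direct
    ## trait effect (exposure <- SNP -> outcome)
    for (i in seq_len(n_pleiotropy)) {
      ci <- ci + 1L
      grp <- which(g_role == "pleiotropy")[i]
      blks <- blk_of_group[[grp]]
      snps <- unlist(lapply(snp_of_block[as.character(blks)],
                            function(s) s[c(5L, 25L)]))
      tr <- rr_trait(i)
      b <- runif(length(snps), b_snp_cpg_range[1], b_snp_cpg_range[2])
      b[1L] <- b_pleio_snp_cpg
      cpgs[[ci]] <- data.table::data.table(
        cpg_id = cpg_ids[ci], chrom = chrom_of(blks[1]), bp = mid_bp(blks),
        topology = "pleiotropy", trait_id = tr, gene_id = NA_character_)
      cpg_eff[[ci]] <- data.table::data.table(
        cpg_id = cpg_ids[ci], snp_id = snps, beta = b)
      trait_snp_eff[[length(trait_snp_eff) + 1L]] <- data.table::data.table(
        trait_id = tr, snp_id = snps[1L], beta = b_pleiotropy)
    }

    ## linkage CpGs: one block, SNP A -> CpG, distinct SNP B -> trait
    for (i in seq_len(n_linkage)) {
      ci <- ci + 1L
      grp <- which(g_role == "linkage")[i]
      blks <- blk_of_group[[grp]]
      s <- snp_of_block[[as.character(blks[1])]]
      tr <- rr_trait(i)
      cpgs[[ci]] <- data.table::data.table(
        cpg_id = cpg_ids[ci], chrom = chrom_of(blks[1]), bp = mid_bp(blks),
        topology = "linkage", trait_id = tr, gene_id = NA_character_)
      cpg_eff[[ci]] <- data.table::data.table(
        cpg_id = cpg_ids[ci], snp_id = s[5L], beta = 0.8)
      trait_snp_eff[[length(trait_snp_eff) + 1L]] <- data.table::data.table(
        trait_id = tr, snp_id = s[25L], beta = b_linkage)
    }

    ## trait-own loci
    trait_groups <- which(g_role == "trait")
    for (t in seq_len(n_traits)) {
      blks <- blk_of_group[[trait_groups[t]]]
      snps <- unlist(lapply(snp_of_block[as.character(blks)],
                            function(s) s[c(5L, 25L)]))
      trait_snp_eff[[length(trait_snp_eff) + 1L]] <- data.table::data.table(
        trait_id = traits[t], snp_id = snps,
        beta = runif(length(snps), b_trait_snp_range[1],
                     b_trait_snp_range[2]))
    }

    ## reverse CpGs: no cis SNPs of their own; probe sits at the middle of
    ## a trait's own locus group, methylation = b * trait + noise
    for (i in seq_len(n_reverse)) {
      ci <- ci + 1L
      tr_i <- (i - 1L) %% n_traits + 1L
      blks <- blk_of_group[[trait_groups[tr_i]]]
      cpgs[[ci]] <- data.table::data.table(
        cpg_id = cpg_ids[ci], chrom = chrom_of(blks[1]),
        bp = mid_bp(blks) + 1000L * i, topology = "reverse",
        trait_id = traits[tr_i], gene_id = NA_character_)
      rev_eff[[length(rev_eff) + 1L]] <- data.table::data.table(
        cpg_id = cpg_ids[ci], trait_id = traits[tr_i], beta = b_trait_cpg)
    }

    ## null CpGs share the null blocks (several CpGs per block)
    null_groups <- which(g_role == "null")
    for (i in seq_len(n_null)) {
      ci <- ci + 1L
      grp <- null_groups[(i - 1L) %% n_null_blocks + 1L]
      blks <- blk_of_group[[grp]]
      s <- snp_of_block[[as.character(blks[1])]]
      picks <- s[sample.int(length(s), 2L)]
      cpgs[[ci]] <- data.table::data.table(
        cpg_id = cpg_ids[ci], chrom = chrom_of(blks[1]),
        bp = mid_bp(blks) + 100L * i, topology = "null",
        trait_id = NA_character_, gene_id = NA_character_)
      cpg_eff[[ci]] <- data.table::data.table(
        cpg_id = cpg_ids[ci], snp_id = picks,
        beta = runif(2L, b_null_range[1], b_null_range[2]))
    }

    ## support genes: own cis eQTLs (2 blocks), expression affects the trait
    support_groups <- which(g_role == "support")
    gi <- gi_med
    for (t in seq_len(n_traits)) {
      for (k in seq_len(n_support_per_trait)) {
        gi <- gi + 1L
        grp <- support_groups[(t - 1L) * n_support_per_trait + k]
        blks <- blk_of_group[[grp]]
        snps <- unlist(lapply(snp_of_block[as.character(blks)],
                              function(s) s[c(5L, 25L)]))
        gene_id <- sprintf("GENE%03d", gi)
        genes[[length(genes) + 1L]] <- data.table::data.table(
          gene_id = gene_id, role = "support", chrom = chrom_of(blks[1]),
          bp = mid_bp(blks), trait_id = traits[t], cpg_id = NA_character_)
        gene_eqtl_eff[[length(gene_eqtl_eff) + 1L]] <- data.table::data.table(
          gene_id = gene_id, snp_id = snps,
          beta = runif(length(snps), b_support_eqtl_range[1],
                       b_support_eqtl_range[2]))
        gene_trait_eff[[length(gene_trait_eff) + 1L]] <- data.table::data.table(
          gene_id = gene_id, trait_id = traits[t],
          beta = b_support_trait * sample(c(-1, 1), 1L))
      }
    }

    ## decoy genes: cis eQTLs on the null blocks, no trait effect
    for (k in seq_len(n_decoy_genes)) {
      gi <- gi + 1L
      grp <- null_groups[(k - 1L) %% n_null_blocks + 1L]
      blks <- blk_of_group[[grp]]
      s <- snp_of_block[[as.character(blks[1])]]
      gene_id <- sprintf("GENE%03d", gi)
      genes[[length(genes) + 1L]] <- data.table::data.table(
        gene_id = gene_id, role = "decoy", chrom = chrom_of(blks[1]),
        bp = mid_bp(blks) + 500L * k, trait_id = NA_character_,
        cpg_id = NA_character_)
      gene_eqtl_eff[[length(gene_eqtl_eff) + 1L]] <- data.table::data.table(
        gene_id = gene_id, snp_id = s[c(10L, 30L)],
        beta = runif(2L, b_support_eqtl_range[1], b_support_eqtl_range[2]))
    }

    cpgs <- data.table::rbindlist(cpgs)
    genes <- data.table::rbindlist(genes)
    smoke_eff <- data.table::data.table(
      cpg_id = cpgs$cpg_id,
      beta = if (simulate_smoking)
        runif(nrow(cpgs), b_smoke_range[1], b_smoke_range[2]) *
          sample(c(-1, 1), nrow(cpgs), replace = TRUE) else 0)

    ## pathway gene sets: per-trait causal set (mediator + support genes),
    ## one decoy set, plus mixed filler sets
    sets <- list(); set_truth <- list(); si <- 0L
    for (t in seq_len(n_traits)) {
      si <- si + 1L
      gset <- c(genes[role == "mediator" & trait_id == traits[t], gene_id],
                genes[role == "support" & trait_id == traits[t], gene_id])
      sets[[si]] <- gene_set(sprintf("M%04d", 1000L + si),
                             paste0("synthetic causal pathway for ",
                                    traits[t]), gset)
      set_truth[[si]] <- data.table::data.table(
        set_id = sets[[si]]$set_id, type = "causal", trait_id = traits[t])
    }
    si <- si + 1L
    sets[[si]] <- gene_set(sprintf("M%04d", 1000L + si),
                           "synthetic decoy pathway (no trait effect)",
                           genes[role == "decoy", gene_id])
    set_truth[[si]] <- data.table::data.table(
      set_id = sets[[si]]$set_id, type = "decoy", trait_id = NA_character_)
    for (t in seq_len(n_traits)) {
      ## mixed set: this trait's mediator + decoys (mostly-null membership)
      si <- si + 1L
      gset <- c(genes[role == "mediator" & trait_id == traits[t], gene_id][1L],
                genes[role == "decoy", gene_id])
      sets[[si]] <- gene_set(sprintf("M%04d", 1000L + si),
                             "synthetic mixed pathway", gset)
      set_truth[[si]] <- data.table::data.table(
        set_id = sets[[si]]$set_id, type = "mixed", trait_id = traits[t])
    }
    names(sets) <- vapply(sets, `[[`, character(1), "set_id")

    list(snp_map = snp_map, blocks = blocks, cpgs = cpgs,
         cpg_eff = data.table::rbindlist(cpg_eff),
         rev_eff = data.table::rbindlist(rev_eff),
         genes = genes,
         gene_eqtl_eff = data.table::rbindlist(gene_eqtl_eff),
         gene_from_cpg = data.table::rbindlist(gene_from_cpg),
         gene_trait_eff = data.table::rbindlist(gene_trait_eff),
         trait_snp_eff = data.table::rbindlist(trait_snp_eff),
         smoke_eff = smoke_eff, traits = traits,
         gene_sets = sets,
         set_truth = data.table::rbindlist(set_truth))
  })
}

## ---- genotypes & phenotypes -------------------------------------------

## block-LD genotypes: per block and haplotype, a latent Gaussian with
## exchangeable correlation rho is thresholded at qnorm(freq), giving
## Hardy-Weinberg dosages of the a1 allele
.sim_genotypes <- function(n, snp_map, rho) {
  nsnp <- nrow(snp_map)
  G <- matrix(0, n, nsnp, dimnames = list(NULL, snp_map$snp_id))
  sr <- sqrt(rho); se <- sqrt(1 - rho)
  for (b in unique(snp_map$block)) {
    idx <- which(snp_map$block == b)
    m <- length(idx)
    thr <- rep(qnorm(snp_map$freq[idx]), each = n)
    dose <- 0L
    for (h in 1:2) {
      lat <- sr * rnorm(n) + se * matrix(rnorm(n * m), n, m)
      dose <- dose + (lat < thr)
    }
    G[, idx] <- dose
  }
  G
}

#' Simulate a block-LD genotype reference panel
#'
#' @param spec A [scenario_spec()].
#' @param snp_map Optional SNP map (from an existing study's truth); when
#'   omitted, the spec's layout is built under its seed.
#' @param n Number of individuals (default `spec$n_ref`).
#' @return An [ld_panel()].
#' @export
simulate_panel <- function(spec, snp_map = NULL, n = spec$n_ref) {
  if (is.null(snp_map)) {
    set.seed(spec$seed)
    snp_map <- .build_truth(spec)$snp_map
  }
  G <- .sim_genotypes(n, snp_map, spec$within_block_rho)
  ld_panel(G, snp_map$snp_id, snp_map$chrom, snp_map$bp,
           snp_map$a1, snp_map$a2)
}

## dense effect matrix from a long table (rows = ids1, cols = ids2)
.eff_matrix <- function(eff, row_ids, col_ids, row_col, col_col) {
  M <- matrix(0, length(row_ids), length(col_ids),
              dimnames = list(row_ids, col_ids))
  if (nrow(eff) > 0L) {
    M[cbind(match(eff[[row_col]], row_ids), match(eff[[col_col]], col_ids))] <-
      eff$beta
  }
  M
}

#' Simulate all phenotype layers for one cohort
#'
#' Applies the causal model to a genotype matrix: CpG methylation from cis
#' SNPs (plus the exposure), gene expression from its own eQTLs and/or its
#' mediating CpG, traits from expression, direct SNP effects, and noise;
#' reverse-topology CpGs are generated from the trait. Gaussian noise
#' (`noise_sd`) at every layer; each cohort is an independent draw.
#'
#' @param G Genotype matrix from [.sim_genotypes()]/[simulate_panel()].
#' @param truth Ground-truth object (internal; from `simulate_study`).
#' @param spec A [scenario_spec()].
#' @return `list(cpg, expr, trait, smoke)` with column names the entity ids.
#' @keywords internal
.simulate_phenotypes <- function(G, truth, spec) {
  n <- nrow(G)
  cpg_ids <- truth$cpgs$cpg_id
  gene_ids <- truth$genes$gene_id
  traits <- truth$traits
  smoke <- if (spec$simulate_smoking)
    rbinom(n, 1L, spec$smoke_prev) else rep(0L, n)

  ## CpG layer (reverse CpGs filled after traits)
  snps_c <- unique(truth$cpg_eff$snp_id)
  Bc <- .eff_matrix(truth$cpg_eff, snps_c, cpg_ids, "snp_id", "cpg_id")
  cpg <- G[, snps_c, drop = FALSE] %*% Bc
  cpg <- cpg + outer(smoke, truth$smoke_eff$beta[match(cpg_ids,
                                                       truth$smoke_eff$cpg_id)])
  cpg <- cpg + matrix(rnorm(n * length(cpg_ids), sd = spec$noise_sd),
                      n, length(cpg_ids))
  colnames(cpg) <- cpg_ids

  ## expression layer
  snps_g <- unique(truth$gene_eqtl_eff$snp_id)
  Bg <- .eff_matrix(truth$gene_eqtl_eff, snps_g, gene_ids,
                    "snp_id", "gene_id")
  M2 <- .eff_matrix(truth$gene_from_cpg, cpg_ids, gene_ids,
                    "cpg_id", "gene_id")
  expr <- G[, snps_g, drop = FALSE] %*% Bg + cpg %*% M2 +
    matrix(rnorm(n * length(gene_ids), sd = spec$noise_sd),
           n, length(gene_ids))
  colnames(expr) <- gene_ids

  ## trait layer
  snps_t <- unique(truth$trait_snp_eff$snp_id)
  Bt <- .eff_matrix(truth$trait_snp_eff, snps_t, traits,
                    "snp_id", "trait_id")
  B3 <- .eff_matrix(truth$gene_trait_eff, gene_ids, traits,
                    "gene_id", "trait_id")
  trait <- expr %*% B3 + G[, snps_t, drop = FALSE] %*% Bt +
    matrix(rnorm(n * length(traits), sd = spec$noise_sd), n, length(traits))
  colnames(trait) <- traits

  ## reverse CpGs
  if (nrow(truth$rev_eff) > 0L) {
    for (i in seq_len(nrow(truth$rev_eff))) {
      cid <- truth$rev_eff$cpg_id[i]
      cpg[, cid] <- cpg[, cid] +
        truth$rev_eff$beta[i] * trait[, truth$rev_eff$trait_id[i]]
    }
  }
  list(cpg = cpg, expr = expr, trait = trait, smoke = smoke)
}

## ---- summary statistics -----------------------------------------------

#' Per-SNP association scan (simple linear regression)
#'
#' Regresses a phenotype on each SNP's dosage separately and returns the
#' univariate-GWAS summary statistics: `beta`, `se`, two-sided Student-t
#' p-value (df `n - 2`), allele frequency of the counted allele, and `n`.
#' Monomorphic SNPs are skipped with a warning.
#'
#' @param G Genotype (dosage) matrix with SNP ids as column names.
#' @param y Phenotype vector (`length(y) == nrow(G)`, `n >= 30` expected).
#' @param snp_map data.frame with `snp_id, chrom, bp, a1, a2` for the
#'   scanned SNPs.
#' @param chunk Columns per block of the vectorized computation.
#' @return A sumstats `data.table` in `snp_map` order.
#' @export
assoc_scan <- function(G, y, snp_map, chunk = 1024L) {
  snp_map <- data.table::as.data.table(snp_map)
  stopifnot(nrow(G) == length(y))
  if (!identical(colnames(G), snp_map$snp_id)) {
    G <- G[, snp_map$snp_id, drop = FALSE]
  }
  n <- length(y)
  ym <- mean(y)
  Syy <- sum((y - ym)^2)
  nsnp <- ncol(G)
  beta <- se <- freq <- sxx_all <- numeric(nsnp)
  for (s in seq.int(1L, nsnp, by = chunk)) {
    e <- min(s + chunk - 1L, nsnp)
    g <- G[, s:e, drop = FALSE]
    gm <- colMeans(g)
    Sxx <- colSums(g * g) - n * gm^2
    Sxy <- as.vector(crossprod(g, y)) - n * gm * ym
    b <- Sxy / Sxx
    sigma2 <- pmax(Syy - b * Sxy, 0) / (n - 2L)
    beta[s:e] <- b
    se[s:e] <- sqrt(sigma2 / Sxx)
    freq[s:e] <- unname(gm) / 2
    sxx_all[s:e] <- Sxx
  }
  ## genotype variance of zero means monomorphic (a zero-residual fit is
  ## legitimate and keeps se = 0 with p at the floor)
  mono <- !(sxx_all > 1e-12) | !is.finite(beta)
  out <- data.table::data.table(
    snp_id = snp_map$snp_id, chrom = snp_map$chrom, bp = snp_map$bp,
    a1 = snp_map$a1, a2 = snp_map$a2, freq = freq, beta = beta, se = se,
    p = .clamp_p(2 * stats::pt(-abs(beta / se), df = n - 2L)), n = n)
  if (any(mono)) {
    warning(sum(mono), " monomorphic SNP(s) skipped in scan: ",
            .fmt_ids(snp_map$snp_id[mono]))
    out <- out[!mono]
  }
  out[]
}

## scan of many outcomes against one regressor (EWAS-style)
.outcome_scan <- function(x, Y) {
  n <- length(x)
  xm <- mean(x)
  Sxx <- sum((x - xm)^2)
  ym <- colMeans(Y)
  Sxy <- as.vector(crossprod(Y, x - xm))
  Syy <- colSums(Y * Y) - n * ym^2
  beta <- Sxy / Sxx
  sigma2 <- pmax(Syy - beta * Sxy, 0) / (n - 2L)
  se <- sqrt(sigma2 / Sxx)
  data.table::data.table(
    id = colnames(Y), beta = beta, se = se,
    p = .clamp_p(2 * stats::pt(-abs(beta / se), df = n - 2L)), n = n)
}

## randomize allele orientation of a fraction of emitted records; the
## information content is unchanged and downstream code must harmonize
.randomize_orientation <- function(rec, frac) {
  if (frac <= 0 || nrow(rec) == 0L) return(rec)
  flip <- runif(nrow(rec)) < frac
  rec[flip, `:=`(a1 = a2, a2 = a1, beta = -beta, freq = 1 - freq)]
  rec
}

## ---- the study bundle --------------------------------------------------

#' Simulate a complete synthetic study
#'
#' Generates, under the spec's seed, everything the pipeline consumes: the
#' LD reference panel, an EWAS-style candidate-CpG table, discovery and
#' replication mQTL probe sets (independent cohorts, shared ground truth),
#' an eQTL store, per-trait GWAS summary statistics, pathway gene sets, and
#' a ground-truth manifest sufficient to score any pipeline output.
#'
#' Each probe's mQTL records cover its cis window plus all SNPs reaching
#' genome-wide significance for any study trait (a GWAS-hit lookup, which
#' is what gives the reverse-causation MR its instruments).
#'
#' @param spec A [scenario_spec()].
#' @return Object of class `methmr_study`.
#' @export
simulate_study <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  set.seed(spec$seed)
  truth <- .build_truth(spec)
  map <- truth$snp_map

  panel <- {
    G <- .sim_genotypes(spec$n_ref, map, spec$within_block_rho)
    ld_panel(G, map$snp_id, map$chrom, map$bp, map$a1, map$a2)
  }

  ## GWAS cohort
  G <- .sim_genotypes(spec$n_gwas, map, spec$within_block_rho)
  ph <- .simulate_phenotypes(G, truth, spec)
  gwas <- list()
  gw_sig <- character()
  for (t in truth$traits) {
    sc <- assoc_scan(G, ph$trait[, t], map)
    gw_sig <- union(gw_sig, sc$snp_id[sc$p <= 5e-8])
    gwas[[t]] <- .randomize_orientation(sc, spec$orient_frac)
  }
  rm(G, ph)

  ## probe coverage: cis window plus GWAS hits (lookup)
  win <- spec$cis_window_kb * 1000
  cov_ids <- lapply(seq_len(nrow(truth$cpgs)), function(i) {
    cis <- map[chrom == truth$cpgs$chrom[i] &
                 abs(bp - truth$cpgs$bp[i]) <= win, snp_id]
    union(cis, gw_sig)
  })

  mk_mqtl <- function(n_cohort) {
    G <- .sim_genotypes(n_cohort, map, spec$within_block_rho)
    ph <- .simulate_phenotypes(G, truth, spec)
    out <- vector("list", nrow(truth$cpgs))
    names(out) <- truth$cpgs$cpg_id
    for (i in seq_len(nrow(truth$cpgs))) {
      ids <- cov_ids[[i]]
      sub <- map[match(ids, map$snp_id)]
      sc <- assoc_scan(G[, ids, drop = FALSE],
                       ph$cpg[, truth$cpgs$cpg_id[i]], sub)
      sc <- .randomize_orientation(sc, spec$orient_frac)
      out[[i]] <- qtl_probe_set(truth$cpgs$cpg_id[i], truth$cpgs$chrom[i],
                                truth$cpgs$bp[i], "", sc)
    }
    list(probes = out, G = G, ph = ph)
  }

  disc <- mk_mqtl(spec$n_mqtl_disc)
  ## EWAS-style candidate table from the discovery cohort
  if (spec$simulate_smoking && stats::var(disc$ph$smoke) > 0) {
    ew <- .outcome_scan(disc$ph$smoke, disc$ph$cpg)
    candidates <- data.table::data.table(
      cpg_id = ew$id, chrom = truth$cpgs$chrom, bp = truth$cpgs$bp,
      beta = ew$beta, se = ew$se, p = ew$p,
      direction = ifelse(ew$beta >= 0, "hypermethylated", "hypomethylated"))
  } else {
    candidates <- data.table::data.table(
      cpg_id = truth$cpgs$cpg_id, chrom = truth$cpgs$chrom,
      bp = truth$cpgs$bp, beta = NA_real_, se = NA_real_, p = NA_real_,
      direction = NA_character_)
  }
  mqtl_disc <- disc$probes
  rm(disc)

  mqtl_repl <- mk_mqtl(spec$n_mqtl_repl)$probes

  ## eQTL cohort: per-gene cis scans
  G <- .sim_genotypes(spec$n_eqtl, map, spec$within_block_rho)
  ph <- .simulate_phenotypes(G, truth, spec)
  eqtl <- vector("list", nrow(truth$genes))
  names(eqtl) <- truth$genes$gene_id
  for (i in seq_len(nrow(truth$genes))) {
    cis <- map[chrom == truth$genes$chrom[i] &
                 abs(bp - truth$genes$bp[i]) <= win]
    sc <- assoc_scan(G[, cis$snp_id, drop = FALSE],
                     ph$expr[, truth$genes$gene_id[i]], cis)
    sc <- .randomize_orientation(sc, spec$orient_frac)
    eqtl[[i]] <- qtl_probe_set(truth$genes$gene_id[i], truth$genes$chrom[i],
                               truth$genes$bp[i], truth$genes$gene_id[i], sc)
  }
  rm(G, ph)

  manifest <- list(
    seed = spec$seed,
    sizes = spec[c("n_ref", "n_mqtl_disc", "n_mqtl_repl", "n_eqtl",
                   "n_gwas", "n_blocks", "snps_per_block")],
    topology_counts = as.list(table(truth$cpgs$topology)),
    cpgs = as.data.frame(truth$cpgs),
    true_pairs = as.data.frame(
      truth$cpgs[topology == "mediation",
                 .(cpg_id, trait_id, gene_id)]),
    gene_roles = as.data.frame(truth$genes[, .(gene_id, role, trait_id)]),
    set_truth = as.data.frame(truth$set_truth),
    effects = list(
      cpg_eff = as.data.frame(truth$cpg_eff),
      gene_from_cpg = as.data.frame(truth$gene_from_cpg),
      gene_trait_eff = as.data.frame(truth$gene_trait_eff),
      trait_snp_eff = as.data.frame(truth$trait_snp_eff),
      rev_eff = as.data.frame(truth$rev_eff)))

  structure(list(spec = spec, truth = truth, panel = panel,
                 candidates = candidates, mqtl_disc = mqtl_disc,
                 mqtl_repl = mqtl_repl, eqtl = eqtl, gwas = gwas,
                 gene_sets = truth$gene_sets, manifest = manifest),
            class = "methmr_study")
}

#' @export
print.methmr_study <- function(x, ...) {
  cat("<methmr_study> seed ", x$spec$seed, ": ",
      length(x$mqtl_disc), " CpG probes, ", length(x$eqtl), " genes, ",
      length(x$gwas), " traits, ", nrow(x$panel$map), " panel SNPs\n",
      sep = "")
  invisible(x)
}

#' Write a simulated study to disk
#'
#' Emits the study as the pipeline's external file formats: panel genotype
#' and map TSVs (optionally also PLINK bed/bim/fam), discovery and
#' replication mQTL tables, the eQTL table, one COJO `.ma` file per trait,
#' the EWAS-style candidate table, the pathway GMT, and a ground-truth
#' `manifest.json`. Identical spec + seed give byte-identical bundles.
#'
#' @param study A `methmr_study` (or a [scenario_spec()], which is
#'   simulated first).
#' @param outdir Output directory.
#' @param force Overwrite an existing non-empty directory.
#' @param plink Also write the panel in PLINK binary format.
#' @return `outdir`, invisibly.
#' @export
emit_study <- function(study, outdir, force = FALSE, plink = FALSE) {
  if (inherits(study, "scenario_spec")) study <- simulate_study(study)
  stopifnot(inherits(study, "methmr_study"))
  if (dir.exists(outdir) && length(dir(outdir)) > 0L && !force) {
    stop("output directory ", outdir, " is not empty; use force = TRUE")
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(outdir, ...)
  write_ld_panel_tsv(study$panel, fp("panel_geno.tsv"), fp("panel_map.tsv"))
  if (plink) write_plink_panel(study$panel, fp("panel"))
  write_qtl_table(study$mqtl_disc, fp("mqtl_discovery.tsv"))
  write_qtl_table(study$mqtl_repl, fp("mqtl_replication.tsv"))
  write_qtl_table(study$eqtl, fp("eqtl.tsv"))
  for (t in names(study$gwas)) {
    write_gwas_ma(study$gwas[[t]], fp(paste0("gwas_", t, ".ma")))
  }
  data.table::fwrite(study$candidates, fp("candidates.tsv"), sep = "\t",
                     quote = FALSE)
  write_gmt(study$gene_sets, fp("pathways.gmt"))
  jsonlite::write_json(study$manifest, fp("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}

## ---- focused scenario generators (single-locus / summary-level) --------

#' Simulate a single-locus SMR/HEIDI scenario
#'
#' One LD block. Under `"pleiotropy"`, a single causal SNP drives both the
#' methylation probe and the trait (HEIDI's null). Under `"linkage"`, two
#' distinct causal SNPs in LD drive the probe and the trait separately
#' (HEIDI's alternative). Returns the pieces [heidi_test()] consumes.
#'
#' @param topology `"pleiotropy"` or `"linkage"`.
#' @param n_qtl,n_gwas,n_ref Cohort sizes.
#' @param m_snps Block size.
#' @param rho Latent within-block correlation; default 0.9 for pleiotropy
#'   and 0.78 for linkage (genotype-scale r2 near 0.5 between the causal
#'   pair).
#' @param b_qtl,b_gwas Causal effect sizes.
#' @return `list(qtl_set, gwas, panel, topology)`.
#' @export
simulate_smr_scenario <- function(topology = c("pleiotropy", "linkage"),
                                  n_qtl = 3000L, n_gwas = 8000L,
                                  n_ref = 500L, m_snps = 30L, rho = NULL,
                                  b_qtl = 0.8, b_gwas = 0.35) {
  topology <- match.arg(topology)
  rho <- rho %||% if (topology == "pleiotropy") 0.9 else 0.78
  map <- data.table::data.table(
    snp_id = sprintf("rs%04d", seq_len(m_snps)), chrom = "1",
    bp = as.integer(1e6 + 5000 * (seq_len(m_snps) - 1L)),
    a1 = "A", a2 = "G",
    freq = runif(m_snps, 0.1, 0.5), block = 1L)
  c1 <- 5L; c2 <- 20L
  panel <- ld_panel(.sim_genotypes(n_ref, map, rho), map$snp_id, map$chrom,
                    map$bp, map$a1, map$a2)
  Gq <- .sim_genotypes(n_qtl, map, rho)
  meth <- b_qtl * Gq[, c1] + rnorm(n_qtl)
  qtl <- assoc_scan(Gq, meth, map)
  Gg <- .sim_genotypes(n_gwas, map, rho)
  causal_g <- if (topology == "pleiotropy") c1 else c2
  y <- b_gwas * Gg[, causal_g] + rnorm(n_gwas)
  gwas <- assoc_scan(Gg, y, map)
  list(qtl_set = qtl_probe_set("cg_sim", "1", map$bp[c1], "", qtl),
       gwas = gwas, panel = panel, topology = topology)
}

#' Simulate a two-sample multi-instrument MR scenario
#'
#' Independent instruments (no LD): an exposure with `k` causal SNPs and an
#' outcome affected by the exposure with causal effect `b_xy`, each
#' measured in its own cohort. Returns a ready [instrument_set()] (identity
#' LD correlation, matching the generating independence).
#'
#' @param k Number of instruments.
#' @param n_exp,n_out Cohort sizes.
#' @param b_xy True causal effect.
#' @param b_exp_range Per-SNP exposure effect range.
#' @param maf_range Allele-frequency range.
#' @return `list(inst, b_xy)`.
#' @export
simulate_mr_scenario <- function(k = 20L, n_exp = 20000L, n_out = 20000L,
                                 b_xy = 0.3, b_exp_range = c(0.2, 0.45),
                                 maf_range = c(0.1, 0.5)) {
  f <- runif(k, maf_range[1], maf_range[2])
  b <- runif(k, b_exp_range[1], b_exp_range[2])
  ids <- sprintf("rs%04d", seq_len(k))
  Ge <- matrix(rbinom(n_exp * k, 2L, rep(f, each = n_exp)), n_exp, k,
               dimnames = list(NULL, ids))
  x <- Ge %*% b + rnorm(n_exp)
  map <- data.table::data.table(snp_id = ids, chrom = "1",
                                bp = as.integer(1e6 + 1e6 * seq_len(k)),
                                a1 = "A", a2 = "G")
  exp_rec <- assoc_scan(Ge, as.vector(x), map)
  Go <- matrix(rbinom(n_out * k, 2L, rep(f, each = n_out)), n_out, k,
               dimnames = list(NULL, ids))
  x2 <- Go %*% b + rnorm(n_out)
  y <- b_xy * x2 + rnorm(n_out)
  out_rec <- assoc_scan(Go, as.vector(y), map)
  snps <- data.table::data.table(
    snp_id = ids, b_exp = exp_rec$beta, se_exp = exp_rec$se,
    p_exp = exp_rec$p, b_out = out_rec$beta, se_out = out_rec$se,
    p_out = out_rec$p)
  list(inst = instrument_set("exposure", "outcome", snps), b_xy = b_xy)
}

#' Simulate an instrument set with a planted pleiotropic outlier
#'
#' Summary-level draws: `n_concordant` instruments share the Wald ratio
#' `ratio`; one planted SNP has ratio `outlier_ratio` (direct pleiotropy)
#' with small SEs. Used to validate the outlier filter.
#'
#' @param n_concordant Number of concordant instruments.
#' @param ratio,outlier_ratio Wald ratios.
#' @param b_exp_range True exposure effect range.
#' @param se_exp,se_out Summary-statistic standard errors.
#' @return `list(inst, planted)` with the planted SNP's id.
#' @export
simulate_outlier_scenario <- function(n_concordant = 9L, ratio = 0.3,
                                      outlier_ratio = 3.0,
                                      b_exp_range = c(0.3, 0.6),
                                      se_exp = 0.02, se_out = 0.02) {
  k <- n_concordant + 1L
  ids <- sprintf("rs%04d", seq_len(k))
  b_true <- runif(k, b_exp_range[1], b_exp_range[2])
  r_true <- c(rep(ratio, n_concordant), outlier_ratio)
  b_exp <- b_true + rnorm(k, sd = se_exp)
  b_out <- r_true * b_true + rnorm(k, sd = se_out)
  snps <- data.table::data.table(
    snp_id = ids, b_exp = b_exp, se_exp = se_exp,
    p_exp = .z2p(b_exp / se_exp), b_out = b_out, se_out = se_out,
    p_out = .z2p(b_out / se_out))
  list(inst = instrument_set("exposure", "outcome", snps),
       planted = ids[k])
}

#' Simulate a pathway scenario (causal or decoy)
#'
#' One independent eQTL SNP per gene; expression driven by it with effects
#' spread over `b_eqtl_range`. Under the causal scenario each gene's
#' expression also affects the trait (`b_gene_trait`), inducing the |Z|
#' rank correlation; under the decoy scenario the trait is pure noise.
#'
#' @param causal Logical.
#' @param n_genes Number of pathway genes (one SNP each).
#' @param n_eqtl,n_gwas,n_ref Cohort sizes.
#' @param b_eqtl_range,b_gene_trait Effect sizes.
#' @return `list(eqtl_store, gwas, panel, set)`.
#' @export
simulate_pathway_scenario <- function(causal = TRUE, n_genes = 12L,
                                      n_eqtl = 3000L, n_gwas = 10000L,
                                      n_ref = 500L,
                                      b_eqtl_range = c(0.3, 0.9),
                                      b_gene_trait = 0.45) {
  f <- runif(n_genes, 0.1, 0.5)
  ids <- sprintf("rs%04d", seq_len(n_genes))
  genes <- sprintf("PGENE%03d", seq_len(n_genes))
  map <- data.table::data.table(snp_id = ids, chrom = "1",
                                bp = as.integer(1e6 + 1e6 * seq_len(n_genes)),
                                a1 = "A", a2 = "G")
  b_e <- runif(n_genes, b_eqtl_range[1], b_eqtl_range[2])
  panel <- ld_panel(matrix(rbinom(n_ref * n_genes, 2L, rep(f, each = n_ref)),
                           n_ref, n_genes, dimnames = list(NULL, ids)),
                    ids, map$chrom, map$bp, map$a1, map$a2)
  Ge <- matrix(rbinom(n_eqtl * n_genes, 2L, rep(f, each = n_eqtl)),
               n_eqtl, n_genes, dimnames = list(NULL, ids))
  eqtl_store <- vector("list", n_genes)
  names(eqtl_store) <- genes
  for (g in seq_len(n_genes)) {
    expr <- b_e[g] * Ge[, g] + rnorm(n_eqtl)
    eqtl_store[[g]] <- qtl_probe_set(genes[g], "1", map$bp[g], genes[g],
                                     assoc_scan(Ge, expr, map))
  }
  Gg <- matrix(rbinom(n_gwas * n_genes, 2L, rep(f, each = n_gwas)),
               n_gwas, n_genes, dimnames = list(NULL, ids))
  expr_g <- Gg %*% diag(b_e) +
    matrix(rnorm(n_gwas * n_genes), n_gwas, n_genes)
  y <- if (causal) as.vector(expr_g %*% rep(b_gene_trait, n_genes)) +
    rnorm(n_gwas) else rnorm(n_gwas)
  gwas <- assoc_scan(Gg, y, map)
  list(eqtl_store = eqtl_store, gwas = gwas, panel = panel,
       set = gene_set("M_SIM", if (causal) "causal" else "decoy", genes))
}
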