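test_that("association scan matches the regression definition", {
  set.seed(26)
  n <- 200
  G <- matrix(rbinom(n * 3, 2, 0.4), n, 3,
              dimnames = list(NULL, paste0("rs", 1:3)))
  map <- data.frame(snp_id = paste0("rs", 1:3), chrom = "1",
                    bp = 1:3 * 1000L, a1 = "A", a2 = "G")
  ## noiseless phenotype: beta recovered exactly
  y <- 2 * G[, 1]
  sc <- assoc_scan(G, y, map)
  expect_equal(sc$beta[1], 2, tolerance = 1e-12)
  expect_lt(sc$p[1], 1e-100)
  ## definitional check against lm() on a noisy phenotype
  y2 <- 0.5 * G[, 2] + rnorm(n)
  sc2 <- assoc_scan(G, y2, map)
  fit <- summary(lm(y2 ~ G[, 2]))$coefficients[2, ]
  expect_equal(sc2$beta[2], unname(fit["Estimate"]), tolerance = 1e-10)
  expect_equal(sc2$se[2], unname(fit["Std. Error"]), tolerance = 1e-10)
  expect_equal(sc2$p[2], unname(fit["Pr(>|t|)"]), tolerance = 1e-10)
  ## p = 2 * t tail at beta/se with df = n - 2, and freq is dosage mean / 2
  expect_equal(sc2$p, 2 * pt(-abs(sc2$beta / sc2$se), df = n - 2))
  expect_equal(sc2$freq, unname(colMeans(G)) / 2)
  ## monomorphic SNP skipped with a warning
  G2 <- cbind(G, rs4 = 1)
  map2 <- rbind(map, data.frame(snp_id = "rs4", chrom = "1", bp = 4000L,
                                a1 = "A", a2 = "G"))
  expect_warning(sc3 <- assoc_scan(G2, y2, map2), "monomorphic")
  expect_false("rs4" %in% sc3$snp_id)
})

test_that("null scan p-values are uniform", {
  set.seed(27)
  n <- 400; m <- 800
  G <- matrix(rbinom(n * m, 2, 0.3), n, m,
              dimnames = list(NULL, sprintf("rs%04d", 1:m)))
  map <- data.frame(snp_id = colnames(G), chrom = "1",
                    bp = seq_len(m) * 1000L, a1 = "A", a2 = "G")
  y <- rnorm(n)  # unrelated phenotype
  sc <- assoc_scan(G, y, map)
  expect_gt(ks.test(sc$p, "punif")$p.value, 0.01)
})

test_that("panel LD structure follows the block model", {
  spec0 <- scenario_spec(within_block_rho = 0, n_ref = 400, seed = 3)
  p0 <- simulate_panel(spec0)
  ## null within-block correlation: mean off-diagonal r2 near 1/n
  g <- p0$geno[, 1:40]
  r2 <- cor(g)^2
  off <- r2[upper.tri(r2)]
  expect_lt(abs(mean(off) - 1 / 400), 3 / 400)

  spec9 <- scenario_spec(within_block_rho = 0.9, n_ref = 400, seed = 3)
  p9 <- simulate_panel(spec9)
  g9 <- p9$geno[, 1:40]
  r29 <- cor(g9)^2
  expect_gt(median(r29[upper.tri(r29)]), 0.2)
  ## cross-block r2 stays at noise level
  g_cross <- p9$geno[, c(1:20, 41:60)]
  rc <- (cor(g_cross)^2)[1:20, 21:40]
  expect_lt(median(rc), 0.02)
  ## allele frequencies respect the configured range (with sampling noise)
  expect_true(all(p9$map$freq > 0.01 & p9$map$freq < 0.6))
})

test_that("effect sizes are recovered by the scan within 2 SE", {
  set.seed(29)
  ok <- replicate(200, {
    n <- 2000
    g <- rbinom(n, 2, 0.3)
    b <- 0.6
    y <- b * g + rnorm(n)
    m <- data.frame(snp_id = "rs1", chrom = "1", bp = 1L, a1 = "A",
                    a2 = "G")
    sc <- assoc_scan(matrix(g, ncol = 1, dimnames = list(NULL, "rs1")), y, m)
    abs(sc$beta - b) <= 2 * sc$se
  })
  expect_gte(mean(ok), 0.93)
})

test_that("study bundle is deterministic, complete, and round-trips", {
  spec <- small_spec(seed = 99)
  study <- simulate_study(spec)
  ## manifest topology counts match the spec census
  tc <- study$manifest$topology_counts
  expect_equal(tc$mediation, spec$n_mediation)
  expect_equal(tc$pleiotropy, spec$n_pleiotropy)
  expect_equal(tc$linkage, spec$n_linkage)
  expect_equal(tc$reverse, spec$n_reverse)
  expect_equal(tc$null, spec$n_null)
  expect_equal(length(study$mqtl_disc), nrow(study$manifest$cpgs))

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  emit_study(study, d1, force = TRUE)
  emit_study(simulate_study(small_spec(seed = 99)), d2, force = TRUE)
  f1 <- sort(dir(d1)); f2 <- sort(dir(d2))
  expect_equal(f1, f2)
  for (f in f1) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
  }
  ## refuses to overwrite without force
  expect_error(emit_study(study, d1), "force")

  ## the bundle reads back losslessly through the package readers
  back_gwas <- read_gwas_ma(file.path(d1, "gwas_trait1.ma"))
  expect_equal(nrow(back_gwas), nrow(study$gwas$trait1))
  back_mqtl <- read_qtl_table(file.path(d1, "mqtl_discovery.tsv"))
  expect_equal(length(back_mqtl), length(study$mqtl_disc))
  one <- study$mqtl_disc[[1]]
  expect_equal(nrow(back_mqtl[[one$probe_id]]$records), nrow(one$records))
  back_panel <- read_ld_panel_tsv(file.path(d1, "panel_geno.tsv"),
                                  file.path(d1, "panel_map.tsv"))
  expect_equal(unname(back_panel$geno), unname(study$panel$geno))
  sets <- read_gmt(file.path(d1, "pathways.gmt"))
  expect_equal(length(sets), length(study$gene_sets))
  mani <- jsonlite::read_json(file.path(d1, "manifest.json"),
                              simplifyVector = TRUE)
  expect_equal(nrow(mani$true_pairs), spec$n_mediation)
})

test_that("discovery and replication cohorts have independent noise", {
  spec <- small_spec(seed = 55)
  study <- simulate_study(spec)
  nulls <- study$manifest$cpgs$cpg_id[study$manifest$cpgs$topology == "null"]
  ## per null CpG, correlate disc vs repl betas over its null cis SNPs:
  ## shared ground truth (zero effects elsewhere) but independent sampling
  cors <- sapply(nulls, function(cg) {
    ps <- study$mqtl_disc[[cg]]
    d <- ps$records
    r <- study$mqtl_repl[[cg]]$records
    ## true beta is exactly zero off the probe's chromosome (no cis LD)
    shared <- intersect(d$snp_id[d$chrom != ps$probe_chrom], r$snp_id)
    bd <- d$beta[match(shared, d$snp_id)] *
      ifelse(d$a1[match(shared, d$snp_id)] ==
               r$a1[match(shared, r$snp_id)], 1, -1)
    cor(bd, r$beta[match(shared, r$snp_id)])
  })
  expect_lt(abs(mean(cors)), 0.15)
})

test_that("mediation chain effects are recovered by MR within 2 SE", {
  spec <- small_spec(seed = 31)
  study <- simulate_study(spec)
  cfg <- pipeline_config()
  tp <- study$manifest$true_pairs
  eff <- study$manifest$effects
  for (i in seq_len(nrow(tp))) {
    b2 <- eff$gene_from_cpg$beta[eff$gene_from_cpg$cpg_id == tp$cpg_id[i]]
    b3 <- eff$gene_trait_eff$beta[eff$gene_trait_eff$gene_id ==
                                    tp$gene_id[i]]
    implied <- b2 * b3  # path product: CpG -> gene -> trait
    inst <- select_instruments(study$mqtl_disc[[tp$cpg_id[i]]],
                               study$gwas[[tp$trait_id[i]]],
                               study$panel, cfg)
    f <- gsmr_fit(inst)
    expect_true(f$testable)
    expect_lt(abs(f$b_xy - implied), 2.5 * f$se_xy + 0.02)
  }
})
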