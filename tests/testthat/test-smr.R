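test_that("SMR statistic and p-value match their defining formulas", {
  ## z_qtl = z_gwas = 2: T = 2, p = upper chi-square(1) tail at 2
  st <- smr_test(list(beta = 0.2, se = 0.1), list(beta = 0.2, se = 0.1))
  expect_equal(st$t_smr, 2)
  expect_equal(st$p_smr, pchisq(2, 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(st$b_smr, 1)

  ## z_gwas = 0: T = 0, p = 1
  st0 <- smr_test(list(beta = 0.2, se = 0.1), list(beta = 0, se = 0.1))
  expect_equal(st0$t_smr, 0)
  expect_equal(st0$p_smr, 1)

  ## strong instrument limit: T approaches z_gwas^2 from below
  st2 <- smr_test(list(beta = 100, se = 1), list(beta = 3, se = 1))
  expect_equal(st2$t_smr, 1e4 * 9 / (1e4 + 9), tolerance = 1e-12)
  expect_lt(st2$t_smr, 9)

  ## delta-method SE at the top SNP
  st3 <- smr_test(list(beta = 0.5, se = 0.05), list(beta = 0.15, se = 0.02))
  expect_equal(st3$b_smr, 0.3)
  expect_equal(st3$se_smr, 0.05)

  expect_error(smr_test(list(beta = 0, se = 0.1), list(beta = 1, se = 0.1)),
               "zero")
})

test_that("T_SMR never exceeds min(z^2) across a z grid", {
  zs <- seq(-6, 6, by = 0.75)
  for (zq in zs[zs != 0]) for (zg in zs) {
    st <- smr_test(list(beta = zq * 0.1, se = 0.1),
                   list(beta = zg * 0.1, se = 0.1))
    expect_lte(st$t_smr, min(zq^2, zg^2) + 1e-12)
    expect_equal(st$p_smr, pchisq(st$t_smr, 1, lower.tail = FALSE),
                 tolerance = 1e-12)
  }
})

test_that("SMR is invariant under simultaneous allele flips", {
  st1 <- smr_test(list(beta = 0.4, se = 0.1), list(beta = -0.1, se = 0.04))
  st2 <- smr_test(list(beta = -0.4, se = 0.1), list(beta = 0.1, se = 0.04))
  expect_equal(st1$b_smr, st2$b_smr)
  expect_equal(st1$se_smr, st2$se_smr)
  expect_equal(st1$p_smr, st2$p_smr)
})

test_that("weighted chi-square tail matches exact cases and simulation", {
  expect_equal(as.numeric(p_quadform(3.84, 1)),
               pchisq(3.84, 1, lower.tail = FALSE))
  for (q in c(1, 5, 12)) {
    expect_equal(as.numeric(p_quadform(q, c(1, 1, 1))),
                 pchisq(q, 3, lower.tail = FALSE), tolerance = 1e-6)
  }
  expect_equal(as.numeric(p_quadform(0, c(2, 1))), 1)
  ## unequal weights against a semi-analytic mixture
  set.seed(8)
  lam <- c(2, 1, 0.5)
  B <- rchisq(4e5, 1); C <- rchisq(4e5, 1)
  for (q in c(5, 15)) {
    truth <- mean(pchisq((q - B - 0.5 * C) / 2, 1, lower.tail = FALSE))
    ## the semi-analytic reference has Monte Carlo error of its own
    expect_lt(abs(as.numeric(p_quadform(q, lam)) - truth), 5e-4)
  }
  ## satterthwaite fallback is a valid probability of similar magnitude
  ps <- p_quadform(15, lam, method = "satterthwaite")
  expect_equal(attr(ps, "method"), "satterthwaite")
  expect_gt(as.numeric(ps), 0)
})

## a small single-locus fixture with a genuinely shared causal variant
local_pleio_fixture <- function(seed) {
  set.seed(seed)
  simulate_smr_scenario("pleiotropy", n_qtl = 2000, n_gwas = 4000,
                        n_ref = 400, m_snps = 20)
}

test_that("HEIDI returns p = 1 when all ratios are exactly equal", {
  set.seed(21)
  panel <- toy_panel(n = 300, clusters = list(6), spacing = 5e3)
  ids <- panel$map$snp_id
  b_q <- c(0.8, 0.7, 0.65, 0.6, 0.55, 0.5)
  qtl <- make_records(ids, beta = b_q, se = 0.02,
                      chrom = panel$map$chrom, bp = panel$map$bp)
  gwas <- make_records(ids, beta = 0.3 * b_q, se = 0.02,
                       chrom = panel$map$chrom, bp = panel$map$bp)
  ps <- qtl_probe_set("cg1", "1", panel$map$bp[1], "", qtl)
  h <- heidi_test(ps, gwas, panel, pipeline_config())
  expect_gte(h$n_heidi_snps, 3L)
  expect_equal(h$p_heidi, 1)
})

test_that("HEIDI p is invariant to SNP input order", {
  sc <- local_pleio_fixture(101)
  cfg <- pipeline_config()
  h1 <- heidi_test(sc$qtl_set, sc$gwas, sc$panel, cfg)
  set.seed(5)
  perm <- sample(nrow(sc$qtl_set$records))
  ps2 <- qtl_probe_set("cg_sim", "1", sc$qtl_set$probe_bp, "",
                       sc$qtl_set$records[perm])
  h2 <- heidi_test(ps2, sc$gwas[sample(nrow(sc$gwas))], sc$panel, cfg)
  expect_equal(h1$p_heidi, h2$p_heidi)
  expect_equal(h1$n_heidi_snps, h2$n_heidi_snps)
})

test_that("HEIDI is undefined with too few qualifying SNPs", {
  set.seed(3)
  panel <- toy_panel(n = 300, clusters = list(2), spacing = 5e3)
  qtl <- make_records(panel$map$snp_id, beta = c(0.8, 0.7), se = 0.02,
                      chrom = panel$map$chrom, bp = panel$map$bp)
  gwas <- make_records(panel$map$snp_id, beta = c(0.2, 0.2), se = 0.02,
                       chrom = panel$map$chrom, bp = panel$map$bp)
  ps <- qtl_probe_set("cg1", "1", panel$map$bp[1], "", qtl)
  h <- heidi_test(ps, gwas, panel, pipeline_config())
  expect_true(is.na(h$p_heidi))
  expect_lt(h$n_heidi_snps, 3L)
})

test_that("co-localization screen flags and skips per the thresholds", {
  sc <- local_pleio_fixture(202)
  cfg <- pipeline_config()
  scr <- colocalization_screen(list(sc$qtl_set), sc$gwas, sc$panel, cfg,
                               trait_id = "t")
  expect_equal(nrow(scr), 1L)
  expect_true(scr$pass_smr)      # strong shared signal by construction
  expect_true(scr$pass_heidi)    # single shared causal variant
  expect_equal(scr$trait_id, "t")

  ## a probe with no genome-wide-significant QTL SNP is skipped
  weak <- sc$qtl_set
  weak$records$beta <- weak$records$beta * 0.02
  weak$records$p <- pmin(1, 2 * pnorm(-abs(weak$records$beta /
                                             weak$records$se)))
  scr2 <- colocalization_screen(list(weak), sc$gwas, sc$panel, cfg)
  expect_equal(nrow(scr2), 0L)
  expect_equal(attr(scr2, "skipped")$reason, "no-instrument")

  ## no overlapping SNPs at all
  gw3 <- sc$gwas
  gw3$snp_id <- paste0("other_", gw3$snp_id)
  scr3 <- colocalization_screen(list(sc$qtl_set), gw3, sc$panel, cfg)
  expect_equal(attr(scr3, "skipped")$reason, "no-overlap")
})
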