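test_that("single-instrument fit reduces to the Wald ratio", {
  inst <- instrument_set("cpg", "trait",
                         data.frame(snp_id = "rs1", b_exp = 0.5,
                                    se_exp = 0.05, b_out = 0.15,
                                    se_out = 0.02))
  f <- gsmr_fit(inst)
  expect_equal(f$b_xy, 0.3)
  ## hand delta-method: sqrt((0.02/0.5)^2 + (0.15*0.05/0.25)^2) = 0.05
  expect_equal(f$se_xy, 0.05, tolerance = 1e-12)
  expect_equal(f$n_instruments, 1L)
})

test_that("identical ratios with independent instruments give the ratio", {
  inst <- instrument_set("e", "o",
                         data.frame(snp_id = paste0("rs", 1:5),
                                    b_exp = c(0.5, 0.4, 0.3, 0.6, 0.45),
                                    se_exp = 0.03,
                                    b_out = 0.25 * c(0.5, 0.4, 0.3, 0.6, 0.45),
                                    se_out = 0.02))
  f <- gsmr_fit(inst)
  expect_equal(f$b_xy, 0.25, tolerance = 1e-10)
})

test_that("GLS with diagonal covariance equals the IVW oracle", {
  set.seed(13)
  for (i in 1:25) {
    k <- sample(2:15, 1)
    snps <- data.frame(snp_id = paste0("rs", seq_len(k)),
                       b_exp = runif(k, 0.2, 0.8) * sample(c(-1, 1), k, TRUE),
                       se_exp = runif(k, 0.01, 0.08),
                       b_out = rnorm(k, 0, 0.2),
                       se_out = runif(k, 0.01, 0.08))
    inst <- instrument_set("e", "o", snps)
    f <- gsmr_fit(inst)
    bxy <- snps$b_out / snps$b_exp
    v <- snps$se_out^2 / snps$b_exp^2 +
      snps$b_out^2 * snps$se_exp^2 / snps$b_exp^4
    want <- ivw_oracle(bxy, v)
    expect_equal(f$b_xy, want$b, tolerance = 1e-10)
    expect_equal(f$se_xy, want$se, tolerance = 1e-10)
  }
})

test_that("fit is invariant to instrument order and allele flips", {
  set.seed(14)
  k <- 8
  snps <- data.table::data.table(
    snp_id = paste0("rs", 1:k), b_exp = runif(k, 0.3, 0.7),
    se_exp = 0.04, b_out = rnorm(k, 0.1, 0.05), se_out = 0.03)
  R <- diag(k); R[1, 2] <- R[2, 1] <- 0.4
  f1 <- gsmr_fit(instrument_set("e", "o", snps, R))
  perm <- sample(k)
  f2 <- gsmr_fit(instrument_set("e", "o", snps[perm],
                                R[perm, perm]))
  expect_equal(f1$b_xy, f2$b_xy, tolerance = 1e-12)
  expect_equal(f1$se_xy, f2$se_xy, tolerance = 1e-12)
  ## flip the measured allele of instrument 3 in both studies: the signed
  ## LD row flips too, and the estimate is unchanged
  snps3 <- data.table::copy(snps)
  snps3[3, `:=`(b_exp = -b_exp, b_out = -b_out)]
  R3 <- R; R3[3, ] <- -R3[3, ]; R3[, 3] <- -R3[, 3]; diag(R3) <- 1
  f3 <- gsmr_fit(instrument_set("e", "o", snps3, R3))
  expect_equal(f1$b_xy, f3$b_xy, tolerance = 1e-12)
  expect_equal(f1$se_xy, f3$se_xy, tolerance = 1e-12)
})

test_that("adding an identical-ratio instrument never increases the SE", {
  set.seed(15)
  for (i in 1:10) {
    k <- sample(2:10, 1)
    b_exp <- runif(k, 0.3, 0.8)
    snps <- data.frame(snp_id = paste0("rs", seq_len(k)),
                       b_exp = b_exp, se_exp = runif(k, 0.01, 0.05),
                       b_out = 0.3 * b_exp, se_out = runif(k, 0.01, 0.05))
    f_all <- gsmr_fit(instrument_set("e", "o", snps))
    f_less <- gsmr_fit(instrument_set("e", "o", snps[-k, ]))
    expect_lte(f_all$se_xy, f_less$se_xy + 1e-12)
  }
})

test_that("outlier filter removes nothing when ratios agree", {
  b_exp <- c(0.5, 0.4, 0.6, 0.45)
  inst <- instrument_set("e", "o",
                         data.frame(snp_id = paste0("rs", 1:4),
                                    b_exp = b_exp, se_exp = 0.02,
                                    b_out = 0.3 * b_exp, se_out = 0.02))
  out <- gsmr_outlier_filter(inst)
  expect_equal(nrow(out$snps), 4L)
  expect_equal(nrow(out$removed), 0L)
})

test_that("outlier filter is skipped below the instrument minimum", {
  inst <- instrument_set("e", "o",
                         data.frame(snp_id = c("rs1", "rs2"),
                                    b_exp = c(0.5, 0.4), se_exp = 0.02,
                                    b_out = c(0.15, 0.4), se_out = 0.02))
  expect_warning(out <- gsmr_outlier_filter(inst), "skipped")
  expect_equal(nrow(out$snps), 2L)
})

test_that("a planted pleiotropic instrument is removed", {
  set.seed(16)
  hits <- logical(40); clean <- logical(40)
  for (i in 1:40) {
    sc <- simulate_outlier_scenario()
    out <- gsmr_outlier_filter(sc$inst)
    hits[i] <- sc$planted %in% out$removed$snp_id
    clean[i] <- !any(setdiff(sc$inst$snps$snp_id, sc$planted) %in%
                       out$removed$snp_id)
  }
  expect_gt(mean(hits), 0.9)
  expect_gt(mean(clean), 0.8)
})

test_that("instrument selection applies the three criteria", {
  set.seed(17)
  panel <- toy_panel(n = 400, clusters = list(2, 1, 1), spacing = 5e3)
  ids <- panel$map$snp_id
  cfg <- pipeline_config()
  ## significance: p-values [1e-9, 1e-7] keep only the first
  exp_rec <- make_records(ids, beta = c(0.62, 0.60, 0.58, 0.05), se = 0.1,
                          chrom = panel$map$chrom, bp = panel$map$bp)
  out_rec <- make_records(ids, beta = 0.1, se = 0.05,
                          chrom = panel$map$chrom, bp = panel$map$bp)
  ps <- qtl_probe_set("cg1", "1", panel$map$bp[1], "", exp_rec)
  inst <- select_instruments(ps, out_rec, panel, cfg)
  expect_true(all(inst$snps$p_exp <= 5e-8))
  expect_false(ids[4] %in% inst$snps$snp_id)
  ## LD: the correlated pair collapses to its lower-p member
  expect_false(all(c(ids[1], ids[2]) %in% inst$snps$snp_id))
  expect_true(ids[1] %in% inst$snps$snp_id)
  ## pairwise r2 of what remains is below the threshold
  if (nrow(inst$snps) > 1) {
    R2 <- inst$ld_corr^2
    expect_lt(max(R2[upper.tri(R2)]), cfg$r2_instruments)
  }
  ## missing outcome record -> dropped with its reason
  out_miss <- out_rec[out_rec$snp_id != ids[3], ]
  inst2 <- select_instruments(ps, out_miss, panel, cfg)
  expect_true(any(inst2$removed$reason == "no-outcome-record" &
                    inst2$removed$snp_id == ids[3]))
  expect_false(ids[3] %in% inst2$snps$snp_id)
})

test_that("reverse direction without instruments counts as not testable", {
  set.seed(18)
  panel <- toy_panel(n = 400, clusters = list(1, 1, 1), spacing = 5e3)
  ids <- panel$map$snp_id
  exp_rec <- make_records(ids, beta = c(0.7, 0.65, 0.6), se = 0.08,
                          chrom = panel$map$chrom, bp = panel$map$bp)
  ## outcome has no genome-wide-significant SNP of its own
  out_rec <- make_records(ids, beta = c(0.21, 0.20, 0.18), se = 0.05,
                          chrom = panel$map$chrom, bp = panel$map$bp)
  out_rec$p <- pmax(out_rec$p, 1e-6)
  ps <- qtl_probe_set("cg1", "1", panel$map$bp[1], "", exp_rec)
  bid <- gsmr_bidirectional(ps, out_rec, panel, pipeline_config(),
                            outcome_id = "trait")
  expect_true(bid$forward$testable)
  expect_false(bid$reverse$testable)
  expect_true(bid$reverse_ok)
})
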