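test_that("COJO .ma files parse to validated records", {
  f <- withr::local_tempfile(fileext = ".ma")
  writeLines(c("SNP A1 A2 freq b se p N",
               "rs1 A G 0.3 0.1 0.02 5.7e-7 10000",
               "rs2 T C 0.10 -0.05 0.01 6.0e-7 9000"), f)
  rec <- read_gwas_ma(f)
  expect_equal(nrow(rec), 2L)
  expect_equal(rec$beta[1] / rec$se[1], 5)
  expect_equal(rec$snp_id, c("rs1", "rs2"))
  expect_equal(rec$a1[2], "T")

  ## se = 0 violates the record invariants
  writeLines(c("SNP A1 A2 freq b se p N",
               "rs1 A G 0.3 0.1 0 5.7e-7 10000"), f)
  expect_error(read_gwas_ma(f), "invariant")

  ## drop mode: 3 rows, one bad -> 2 records plus a warning
  writeLines(c("SNP A1 A2 freq b se p N",
               "rs1 A G 0.3 0.1 0.02 5.7e-7 10000",
               "rs2 A G 0.3 0.1 0 1e-4 10000",
               "rs3 T C 0.2 0.2 0.05 6e-5 10000"), f)
  expect_warning(rec <- read_gwas_ma(f, on_invalid = "drop"), "dropped")
  expect_equal(rec$snp_id, c("rs1", "rs3"))
})

test_that(".ma format errors are specific", {
  f <- withr::local_tempfile(fileext = ".ma")
  writeLines(c("SNP A1 A2 freq b se N",
               "rs1 A G 0.3 0.1 0.02 10000"), f)
  expect_error(read_gwas_ma(f), "P")
  writeLines(c("SNP A1 A2 freq b se p N",
               "rs1 A G 0.3 0.1 0.02 5.7e-7 10000",
               "rs2 A G 0.3 oops 0.02 5.7e-7 10000"), f)
  expect_error(read_gwas_ma(f), "line 3")
  ## extra columns are ignored with a warning
  writeLines(c("SNP A1 A2 freq b se p N extra",
               "rs1 A G 0.3 0.1 0.02 5.7e-7 10000 x"), f)
  expect_warning(rec <- read_gwas_ma(f), "extra")
  expect_equal(nrow(rec), 1L)
})

test_that("write/read round-trip preserves fields, including gzip", {
  set.seed(5)
  rec <- make_records(sprintf("rs%d", 1:20), beta = rnorm(20),
                      se = runif(20, 0.01, 0.1))
  for (ext in c(".ma", ".ma.gz")) {
    f <- withr::local_tempfile(fileext = ext)
    write_gwas_ma(rec, f)
    back <- read_gwas_ma(f)
    expect_equal(back$beta, rec$beta, tolerance = 1e-12)
    expect_equal(back$se, rec$se, tolerance = 1e-12)
    expect_equal(back$p, rec$p, tolerance = 1e-12)
    expect_equal(back$n, rec$n)
    expect_equal(back$a1, rec$a1)
  }
})

test_that("QTL tables group by probe and reject duplicates", {
  f <- withr::local_tempfile(fileext = ".tsv")
  rec <- make_records(c("rs1", "rs2", "rs1", "rs3"),
                      beta = c(0.5, 0.4, 0.3, 0.2), se = 0.05)
  tab <- cbind(data.frame(probe_id = c("cg1", "cg1", "cg2", "cg2"),
                          probe_chrom = "1", probe_bp = 500L, gene = ""),
               rec)
  data.table::fwrite(tab, f, sep = "\t")
  ps <- read_qtl_table(f)
  expect_length(ps, 2L)
  expect_equal(names(ps), c("cg1", "cg2"))
  expect_equal(nrow(ps$cg1$records), 2L)
  expect_s3_class(ps$cg1, "qtl_probe_set")

  tab2 <- tab; tab2$snp_id <- c("rs1", "rs1", "rs1", "rs3")
  data.table::fwrite(tab2, f, sep = "\t")
  expect_error(read_qtl_table(f), "duplicate")

  data.table::fwrite(tab[0, ], f, sep = "\t")
  expect_length(read_qtl_table(f), 0L)

  ## probe-set round trip
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_qtl_table(ps, f2)
  back <- read_qtl_table(f2)
  expect_equal(back$cg2$records$beta, ps$cg2$records$beta)
})

test_that("GMT files parse, dedupe, and reject short lines", {
  f <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("M1920\tdesc\tRAB29\tLRRK2"), f)
  gs <- read_gmt(f)
  expect_equal(gs$M1920$genes, c("RAB29", "LRRK2"))
  writeLines("X\tdesc", f)
  expect_error(read_gmt(f), "line 1")
  writeLines("S\td\tA\tA\tB", f)
  expect_warning(gs <- read_gmt(f), "duplicate")
  expect_equal(gs$S$genes, c("A", "B"))
})

test_that("harmonization aligns alleles, flips signs, excludes palindromes", {
  ref <- make_records("rs1", 0.1, 0.05, a1 = "A", a2 = "G", freq = 0.3)
  same <- make_records("rs1", 0.2, 0.05, a1 = "A", a2 = "G", freq = 0.3)
  h <- harmonize_record(ref, same)
  expect_false(h$excluded)
  expect_equal(h$record$beta, 0.2)

  swapped <- make_records("rs1", 0.2, 0.05, a1 = "G", a2 = "A", freq = 0.3)
  h <- harmonize_record(ref, swapped)
  expect_equal(h$record$beta, -0.2)
  expect_equal(h$record$freq, 0.7)
  expect_equal(h$record$a1, "A")

  ## strand flip resolves to the same cases
  strand <- make_records("rs1", 0.2, 0.05, a1 = "T", a2 = "C", freq = 0.3)
  h <- harmonize_record(ref, strand)
  expect_equal(h$record$beta, 0.2)
  strand_swap <- make_records("rs1", 0.2, 0.05, a1 = "C", a2 = "T",
                              freq = 0.7)
  h <- harmonize_record(ref, strand_swap)
  expect_equal(h$record$beta, -0.2)

  ## ambiguous palindrome excluded
  ref_at <- make_records("rs1", 0.1, 0.05, a1 = "A", a2 = "T", freq = 0.5)
  oth_at <- make_records("rs1", 0.2, 0.05, a1 = "A", a2 = "T", freq = 0.5)
  h <- harmonize_record(ref_at, oth_at)
  expect_true(h$excluded)
  expect_equal(h$reason, "palindromic-ambiguous")

  ## low-MAF palindrome aligned by frequency
  ref_cg <- make_records("rs1", 0.1, 0.05, a1 = "C", a2 = "G", freq = 0.1)
  oth_cg <- make_records("rs1", 0.2, 0.05, a1 = "C", a2 = "G", freq = 0.88)
  h <- harmonize_record(ref_cg, oth_cg)
  expect_false(h$excluded)
  expect_equal(h$record$beta, -0.2)

  ## irreconcilable alleles
  mism <- make_records("rs1", 0.2, 0.05, a1 = "A", a2 = "C")
  h <- harmonize_record(ref, mism)
  expect_true(h$excluded)
  expect_equal(h$reason, "allele-mismatch")
})

test_that("harmonization is idempotent and preserves |beta|, se, p, n", {
  set.seed(42)
  pairs <- matrix(c("A","G","T","C","G","A","C","T"), ncol = 2, byrow = TRUE)
  for (i in 1:30) {
    pr <- pairs[sample(4, 1), ]
    ref <- make_records("rs1", rnorm(1), runif(1, 0.01, 0.2),
                        a1 = pr[1], a2 = pr[2], freq = runif(1))
    orient <- sample(c("same", "swap", "strand"), 1)
    oth <- make_records("rs1", rnorm(1), runif(1, 0.01, 0.2),
                        a1 = switch(orient, same = pr[1], swap = pr[2],
                                    strand = chartr("ACGT", "TGCA", pr[1])),
                        a2 = switch(orient, same = pr[2], swap = pr[1],
                                    strand = chartr("ACGT", "TGCA", pr[2])),
                        freq = runif(1))
    h1 <- harmonize_record(ref, oth)
    expect_false(h1$excluded)
    expect_equal(abs(h1$record$beta), abs(oth$beta))
    expect_equal(h1$record$se, oth$se)
    expect_equal(h1$record$p, oth$p)
    expect_equal(h1$record$n, oth$n)
    h2 <- harmonize_record(ref, h1$record)
    expect_equal(h2$record$beta, h1$record$beta)
    expect_equal(h2$record$freq, h1$record$freq)
  }
})

test_that("p/z inconsistency warns rather than errors", {
  rec <- make_records("rs1", 0.5, 0.05)
  rec$p <- 0.5  # wildly inconsistent with z = 10
  expect_warning(validate_sumstats(rec), "inconsistent")
})
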