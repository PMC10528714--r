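## Summary-statistics containers and flat-file IO.
##
## A summary-statistics table ("sumstats") is a data.table with one row per
## SNP-association: snp_id, chrom, bp, a1 (effect allele), a2 (other allele),
## freq (frequency of a1), beta (effect per a1 allele), se, p, n.
## chrom/bp may be NA when the source file lacks them (COJO .ma); they can be
## filled from an LD panel's SNP map.

.SUMSTAT_COLS <- c("snp_id", "chrom", "bp", "a1", "a2",
                   "freq", "beta", "se", "p", "n")

.read_lines_maybe_gz <- function(path) {
  if (grepl("\\.gz$", path)) {
    con <- gzfile(path, open = "rt")
    on.exit(close(con))
    readLines(con)
  } else {
    readLines(path)
  }
}

.fread_maybe_gz <- function(path, ...) {
  if (grepl("\\.gz$", path)) {
    data.table::fread(text = .read_lines_maybe_gz(path), ...)
  } else {
    data.table::fread(path, ...)
  }
}

#' Validate a summary-statistics table
#'
#' Checks the record invariants: `se > 0`, `freq` in `[0, 1]`, `a1 != a2`,
#' finite `beta/se`, `p` in `(0, 1]`, `n >= 1`. Optionally cross-checks the
#' reported p-value against the two-sided normal approximation
#' `2 * pnorm(-|beta/se|)`; because published files round both `p` and `se`,
#' disagreement within a relative factor (default 10x) is tolerated and
#' larger disagreement raises a warning, not an error.
#'
#' @param x data.frame-like with the sumstats columns.
#' @param on_invalid `"error"` to stop at the first invalid row, `"drop"` to
#'   remove invalid rows with a warning.
#' @param check_pz Logical; cross-check `p` against `beta/se`.
#' @param pz_rel_tol Tolerated relative factor between reported and
#'   recomputed p-values.
#' @return A validated `data.table` (invisibly reordered columns).
#' @export
validate_sumstats <- function(x, on_invalid = c("error", "drop"),
                              check_pz = TRUE, pz_rel_tol = 10) {
  on_invalid <- match.arg(on_invalid)
  x <- data.table::as.data.table(x)
  missing_cols <- setdiff(.SUMSTAT_COLS, names(x))
  if ("chrom" %in% missing_cols) x[, chrom := NA_character_]
  if ("bp" %in% missing_cols) x[, bp := NA_integer_]
  missing_cols <- setdiff(.SUMSTAT_COLS, names(x))
  if (length(missing_cols) > 0L) {
    stop("sumstats table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  x <- x[, .SUMSTAT_COLS, with = FALSE]
  bad <- !is.finite(x$se) | x$se <= 0
  bad <- bad | !is.finite(x$freq) | x$freq < 0 | x$freq > 1
  bad <- bad | is.na(x$a1) | is.na(x$a2) | toupper(x$a1) == toupper(x$a2)
  bad <- bad | !is.finite(x$beta)
  bad <- bad | !is.finite(x$p) | x$p <= 0 | x$p > 1
  bad <- bad | !is.finite(x$n) | x$n < 1
  if (any(bad)) {
    if (on_invalid == "error") {
      i <- which(bad)[1L]
      stop("invalid summary-statistic record at row ", i,
           " (snp ", x$snp_id[i], "): violates record invariants")
    }
    warning(sum(bad), " invalid record(s) dropped: ",
            .fmt_ids(x$snp_id[bad]))
    x <- x[!bad]
  }
  if (check_pz && nrow(x) > 0L) {
    p_theory <- .z2p(x$beta / x$se)
    ratio <- x$p / p_theory
    ## deep tails are dominated by the t-vs-normal approximation gap, not
    ## by rounding; only meaningful magnitudes are checked
    off <- is.finite(ratio) & (ratio > pz_rel_tol | ratio < 1 / pz_rel_tol) &
      pmax(x$p, p_theory) > 1e-15
    if (any(off)) {
      warning(sum(off), " record(s) have p inconsistent with beta/se ",
              "beyond the ", pz_rel_tol, "x tolerance: ",
              .fmt_ids(x$snp_id[off]))
    }
  }
  x[]
}

#' Read GWAS summary statistics in COJO ".ma" format
#'
#' The COJO dialect is whitespace- or tab-delimited with header columns
#' `SNP A1 A2 freq b se p N` (case-insensitive). Extra columns are ignored
#' with a warning. Chromosome and position are absent from this format and
#' are returned as `NA` unless a `snp_map` (e.g. an [ld_panel()] `$map`) is
#' supplied to fill them. Gzipped files are accepted.
#'
#' @param path Path to the `.ma` file (optionally `.gz`).
#' @param on_invalid Passed to [validate_sumstats()]: `"error"` (default) or
#'   `"drop"` rows failing the record invariants.
#' @param snp_map Optional data.frame with `snp_id`, `chrom`, `bp` used to
#'   fill positions.
#' @return A sumstats `data.table` in file order.
#' @export
read_gwas_ma <- function(path, on_invalid = c("error", "drop"),
                         snp_map = NULL) {
  on_invalid <- match.arg(on_invalid)
  raw <- .fread_maybe_gz(path, header = TRUE, colClasses = list(character = 1))
  nm <- tolower(names(raw))
  wanted <- c(snp = "snp", a1 = "a1", a2 = "a2", freq = "freq",
              b = "b", se = "se", p = "p", n = "n")
  idx <- match(wanted, nm)
  if (anyNA(idx)) {
    stop("missing required column(s) in ", path, ": ",
         paste(toupper(wanted[is.na(idx)]), collapse = ", "))
  }
  extra <- setdiff(names(raw), names(raw)[idx])
  if (length(extra) > 0L) {
    warning("ignoring extra column(s) in ", path, ": ",
            paste(extra, collapse = ", "))
  }
  out <- data.table::data.table(
    snp_id = as.character(raw[[idx[1]]]),
    chrom = NA_character_, bp = NA_integer_,
    a1 = toupper(as.character(raw[[idx[2]]])),
    a2 = toupper(as.character(raw[[idx[3]]]))
  )
  num_cols <- c("freq", "beta", "se", "p", "n")
  for (k in seq_along(num_cols)) {
    v <- raw[[idx[3 + k]]]
    vn <- suppressWarnings(as.numeric(v))
    bad <- is.na(vn) & !is.na(v) & v != "NA"
    if (any(bad)) {
      line <- which(bad)[1L] + 1L  # + header
      if (on_invalid == "error") {
        stop("unparseable numeric value '", v[which(bad)[1L]], "' in column ",
             toupper(names(wanted)[3 + k]), " at line ", line, " of ", path)
      }
      vn[bad] <- NA_real_
    }
    out[[num_cols[k]]] <- vn
  }
  if (!is.null(snp_map)) {
    snp_map <- data.table::as.data.table(snp_map)
    m <- match(out$snp_id, snp_map$snp_id)
    out[!is.na(m), `:=`(chrom = as.character(snp_map$chrom[m[!is.na(m)]]),
                        bp = as.integer(snp_map$bp[m[!is.na(m)]]))]
  }
  validate_sumstats(out, on_invalid = on_invalid)
}

#' Write GWAS summary statistics in COJO ".ma" format
#'
#' @param x A sumstats table.
#' @param path Output path.
#' @export
write_gwas_ma <- function(x, path) {
  x <- data.table::as.data.table(x)
  out <- x[, .(SNP = snp_id, A1 = a1, A2 = a2, freq = freq,
               b = beta, se = se, p = p, N = n)]
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Construct a cis-QTL probe set
#'
#' A probe set holds all cis-window summary statistics for one molecular
#' probe: a methylation CpG (mQTL) or a gene (eQTL).
#'
#' @param probe_id Probe identifier (e.g. `cg05228408` or a gene id).
#' @param probe_chrom,probe_bp Probe location.
#' @param gene Annotated gene name (may be `""`).
#' @param records Sumstats table of cis SNP associations; must be non-empty
#'   with unique `snp_id`.
#' @return An object of class `qtl_probe_set`.
#' @export
qtl_probe_set <- function(probe_id, probe_chrom, probe_bp, gene = "",
                          records) {
  records <- data.table::as.data.table(records)
  if (nrow(records) == 0L) stop("probe ", probe_id, ": records must be non-empty")
  if (anyDuplicated(records$snp_id)) {
    stop("probe ", probe_id, ": duplicate snp_id in records")
  }
  structure(list(probe_id = as.character(probe_id),
                 probe_chrom = as.character(probe_chrom),
                 probe_bp = as.integer(probe_bp),
                 gene = as.character(gene),
                 records = records),
            class = "qtl_probe_set")
}

#' @export
print.qtl_probe_set <- function(x, ...) {
  cat("<qtl_probe_set> ", x$probe_id,
      " (", x$probe_chrom, ":", x$probe_bp, ")",
      if (nzchar(x$gene)) paste0(" gene=", x$gene) else "",
      " — ", nrow(x$records), " SNP records\n", sep = "")
  invisible(x)
}

#' Read a long-format QTL table into probe sets
#'
#' Expects a TSV with columns `probe_id, probe_chrom, probe_bp, gene,
#' snp_id, chrom, bp, a1, a2, freq, beta, se, p, n`. Rows are grouped by
#' `probe_id` preserving file order. A duplicated `(probe_id, snp_id)` pair
#' is a format error. A BESD-derived text export (SMR `--query` output)
#' maps onto this schema directly: Probe/Probe_Chr/Probe_bp/Gene and
#' SNP/Chr/BP/A1/A2/Freq/b/SE/p plus a constant N column.
#'
#' @param path Path to the TSV (optionally gzipped).
#' @param on_invalid Passed to [validate_sumstats()].
#' @return Named list of [qtl_probe_set()] objects, in first-appearance order.
#' @export
read_qtl_table <- function(path, on_invalid = c("error", "drop")) {
  on_invalid <- match.arg(on_invalid)
  raw <- .fread_maybe_gz(path, header = TRUE)
  need <- c("probe_id", "probe_chrom", "probe_bp", "gene", .SUMSTAT_COLS)
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0L) {
    stop("missing required column(s) in ", path, ": ",
         paste(miss, collapse = ", "))
  }
  if (nrow(raw) == 0L) return(list())
  dup <- duplicated(raw[, .(probe_id, snp_id)])
  if (any(dup)) {
    stop("duplicate (probe_id, snp_id) pair(s) in ", path, ": ",
         .fmt_ids(paste0(raw$probe_id[dup], "/", raw$snp_id[dup])))
  }
  raw[, probe_id := as.character(probe_id)]
  ids <- unique(raw$probe_id)
  out <- vector("list", length(ids))
  names(out) <- ids
  for (pid in ids) {
    g <- raw[probe_id == pid]
    rec <- validate_sumstats(g[, .SUMSTAT_COLS, with = FALSE],
                             on_invalid = on_invalid)
    out[[pid]] <- qtl_probe_set(pid, g$probe_chrom[1L], g$probe_bp[1L],
                                g$gene[1L], rec)
  }
  out
}

#' Write probe sets as a long-format QTL table
#'
#' @param probes List of [qtl_probe_set()] objects.
#' @param path Output path.
#' @export
write_qtl_table <- function(probes, path) {
  rows <- lapply(probes, function(ps) {
    cbind(data.table::data.table(probe_id = ps$probe_id,
                                 probe_chrom = ps$probe_chrom,
                                 probe_bp = ps$probe_bp,
                                 gene = ps$gene),
          ps$records)
  })
  data.table::fwrite(data.table::rbindlist(rows), path, sep = "\t",
                     quote = FALSE)
  invisible(path)
}

#' Construct a gene set
#' @param set_id Set identifier (e.g. an MSigDB id).
#' @param description Free-text description.
#' @param genes Character vector of member gene names (non-empty, unique).
#' @export
gene_set <- function(set_id, description = "", genes) {
  genes <- as.character(genes)
  if (length(genes) == 0L) stop("gene set ", set_id, ": genes must be non-empty")
  if (anyDuplicated(genes)) stop("gene set ", set_id, ": duplicate genes")
  structure(list(set_id = as.character(set_id),
                 description = as.character(description),
                 genes = genes),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat("<gene_set> ", x$set_id, " — ", length(x$genes), " genes\n", sep = "")
  invisible(x)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT dialect: one set per line, tab-separated fields
#' `name<TAB>description<TAB>gene1<TAB>gene2...`. Lines with fewer than three
#' fields are a format error; duplicate genes within a line are deduplicated
#' with a warning.
#'
#' @param path Path to the GMT file (optionally gzipped).
#' @return List of [gene_set()] objects.
#' @export
read_gmt <- function(path) {
  lines <- .read_lines_maybe_gz(path)
  lines <- lines[nzchar(lines)]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L) {
      stop("GMT format error at line ", i, " of ", path,
           ": fewer than 3 tab-separated fields")
    }
    genes <- f[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      warning("duplicate gene(s) in set ", f[1L], " at line ", i,
              "; deduplicated")
      genes <- unique(genes)
    }
    out[[i]] <- gene_set(f[1L], f[2L], genes)
  }
  names(out) <- vapply(out, `[[`, character(1), "set_id")
  out
}

#' Write gene sets to a GMT file
#' @param sets List of [gene_set()] objects.
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(sets, function(s) {
    paste(c(s$set_id, s$description, s$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

## ---- allele harmonization ---------------------------------------------

## classify how `other`'s alleles relate to `reference`'s
## returns one of: same, swap, strand, strand_swap, mismatch
.allele_class <- function(ref_a1, ref_a2, oth_a1, oth_a2) {
  n <- length(ref_a1)
  cls <- rep("mismatch", n)
  cls[oth_a1 == ref_a1 & oth_a2 == ref_a2] <- "same"
  cls[oth_a1 == ref_a2 & oth_a2 == ref_a1] <- "swap"
  c1 <- .complement(oth_a1); c2 <- .complement(oth_a2)
  strand <- c1 == ref_a1 & c2 == ref_a2 & cls == "mismatch"
  cls[strand] <- "strand"
  sswap <- c1 == ref_a2 & c2 == ref_a1 & cls == "mismatch"
  cls[sswap] <- "strand_swap"
  cls
}

#' Harmonize summary statistics onto a reference's effect alleles
#'
#' Expresses `other`'s records on the same effect allele as `reference`,
#' SNP by SNP (matched on `snp_id`): identical alleles are kept unchanged;
#' swapped `a1/a2` negates `beta` and reflects `freq`; a strand flip
#' (complementary alleles) resolves to one of those two cases. Palindromic
#' SNPs (A/T or C/G) are aligned by allele frequency, and excluded as
#' ambiguous when either source's minor-allele frequency exceeds
#' `palindrome_maf_limit` (near 0.5 the frequencies carry no orientation
#' information). Irreconcilable allele sets are excluded. Harmonization
#' never changes `|beta|`, `se`, `p`, or `n`, and is idempotent.
#'
#' @param reference,other Sumstats tables.
#' @param palindrome_maf_limit MAF above which palindromic SNPs are excluded
#'   (default 0.4, standard two-sample MR practice).
#' @return `list(harmonized = <sumstats for shared SNPs, reference order>,
#'   exclusions = data.table(snp_id, reason))`. Reasons are
#'   `"palindromic-ambiguous"`, `"allele-mismatch"`, or `"not-in-other"`.
#' @export
harmonize_sumstats <- function(reference, other, palindrome_maf_limit = 0.4) {
  reference <- data.table::as.data.table(reference)
  other <- data.table::as.data.table(other)
  m <- match(reference$snp_id, other$snp_id)
  excl <- list()
  absent <- is.na(m)
  if (any(absent)) {
    excl[[length(excl) + 1L]] <- data.table::data.table(
      snp_id = reference$snp_id[absent], reason = "not-in-other")
  }
  ref <- reference[!absent]
  oth <- other[m[!absent]]
  if (nrow(ref) == 0L) {
    exclusions <- if (length(excl) > 0L) data.table::rbindlist(excl) else
      data.table::data.table(snp_id = character(), reason = character())
    return(list(harmonized = oth, exclusions = exclusions))
  }
  ra1 <- toupper(ref$a1); ra2 <- toupper(ref$a2)
  oa1 <- toupper(oth$a1); oa2 <- toupper(oth$a2)
  cls <- .allele_class(ra1, ra2, oa1, oa2)
  pal <- .is_palindromic(oa1, oa2)
  drop <- cls == "mismatch"
  flip <- rep(FALSE, nrow(oth))
  ## palindromic: strand state unknowable; align by frequency, or exclude
  ## when either side's MAF is too close to 0.5 to be informative
  if (any(pal & !drop)) {
    amb <- pal & !drop &
      (pmin(ref$freq, 1 - ref$freq) > palindrome_maf_limit |
       pmin(oth$freq, 1 - oth$freq) > palindrome_maf_limit)
    keep_pal <- pal & !drop & !amb
    flip[keep_pal] <- abs(oth$freq[keep_pal] - ref$freq[keep_pal]) >
      abs((1 - oth$freq[keep_pal]) - ref$freq[keep_pal])
    if (any(amb)) {
      excl[[length(excl) + 1L]] <- data.table::data.table(
        snp_id = oth$snp_id[amb], reason = "palindromic-ambiguous")
      drop <- drop | amb
    }
  }
  flip[!pal & cls %in% c("swap", "strand_swap")] <- TRUE
  if (any(cls == "mismatch")) {
    excl[[length(excl) + 1L]] <- data.table::data.table(
      snp_id = oth$snp_id[cls == "mismatch"], reason = "allele-mismatch")
  }
  out <- data.table::copy(oth)
  out[flip, `:=`(beta = -beta, freq = 1 - freq)]
  out[, `:=`(a1 = ref$a1, a2 = ref$a2)]
  out <- out[!drop]
  exclusions <- if (length(excl) > 0L) data.table::rbindlist(excl) else
    data.table::data.table(snp_id = character(), reason = character())
  list(harmonized = out, exclusions = exclusions)
}

#' Harmonize a single record onto a reference record
#'
#' Single-SNP convenience wrapper around [harmonize_sumstats()]; both inputs
#' must share `snp_id`.
#'
#' @inheritParams harmonize_sumstats
#' @return `list(record = <1-row sumstats or NULL>, excluded = logical,
#'   reason = character or NA)`.
#' @export
harmonize_record <- function(reference, other, palindrome_maf_limit = 0.4) {
  reference <- data.table::as.data.table(reference)
  other <- data.table::as.data.table(other)
  stopifnot(nrow(reference) == 1L, nrow(other) == 1L)
  if (reference$snp_id != other$snp_id) {
    stop("harmonize_record requires matching snp_id")
  }
  h <- harmonize_sumstats(reference, other, palindrome_maf_limit)
  if (nrow(h$harmonized) == 1L) {
    list(record = h$harmonized, excluded = FALSE, reason = NA_character_)
  } else {
    list(record = NULL, excluded = TRUE, reason = h$exclusions$reason[1L])
  }
}
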