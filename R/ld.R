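## LD reference panel: genotype dosages plus a SNP map, supporting pairwise
## r2 queries and greedy p-value clumping (PLINK --clump semantics).

#' Construct an LD reference panel
#'
#' @param genotypes `n_individuals x n_snps` matrix of a1-allele dosages
#'   (0/1/2, `NA` allowed). Column order must match `snp_id`.
#' @param snp_id,chrom,bp,a1,a2 Per-SNP map vectors; `a1` is the counted
#'   allele of the dosage matrix.
#' @return Object of class `ld_panel` with elements `geno`, `map` (a
#'   data.table with a `monomorphic` flag: fewer than two distinct observed
#'   genotype values, for which r2 is undefined).
#' @export
ld_panel <- function(genotypes, snp_id, chrom, bp, a1, a2 = NA_character_) {
  genotypes <- as.matrix(genotypes)
  snp_id <- as.character(snp_id)
  if (ncol(genotypes) != length(snp_id)) {
    stop("genotypes has ", ncol(genotypes), " columns but ", length(snp_id),
         " snp ids were given")
  }
  if (anyDuplicated(snp_id)) stop("snp_id must be unique")
  colnames(genotypes) <- snp_id
  mono <- apply(genotypes, 2L, function(g) {
    length(unique(g[!is.na(g)])) < 2L
  })
  map <- data.table::data.table(
    snp_id = snp_id, chrom = as.character(chrom), bp = as.integer(bp),
    a1 = toupper(as.character(a1)), a2 = toupper(as.character(a2)),
    freq = colMeans(genotypes, na.rm = TRUE) / 2,
    monomorphic = mono)
  structure(list(geno = genotypes, map = map), class = "ld_panel")
}

#' @export
print.ld_panel <- function(x, ...) {
  cat("<ld_panel> ", nrow(x$geno), " individuals x ", ncol(x$geno),
      " SNPs (", sum(x$map$monomorphic), " monomorphic)\n", sep = "")
  invisible(x)
}

.panel_idx <- function(panel, ids) {
  i <- match(ids, panel$map$snp_id)
  if (anyNA(i)) {
    stop("SNP(s) not present in LD panel: ", .fmt_ids(ids[is.na(i)]))
  }
  i
}

#' Signed LD correlation between SNPs in a panel
#'
#' Pearson correlation of a1-allele dosages over pairwise-complete
#' individuals. The sign refers to the panel's counted (`a1`) alleles;
#' summary statistics must be aligned to the panel (see
#' [align_to_panel()]) before signed correlations are meaningful.
#'
#' @param panel An [ld_panel()].
#' @param ids Character vector of SNP ids.
#' @return Symmetric correlation matrix over `ids`.
#' @export
ld_r <- function(panel, ids) {
  i <- .panel_idx(panel, ids)
  if (any(panel$map$monomorphic[i])) {
    stop("LD undefined for monomorphic SNP(s): ",
         .fmt_ids(ids[panel$map$monomorphic[i]]))
  }
  g <- panel$geno[, i, drop = FALSE]
  if (anyNA(g)) {
    nn <- crossprod(!is.na(g))
    if (any(nn < 3)) stop("fewer than 3 pairwise-complete individuals")
    r <- suppressWarnings(stats::cor(g, use = "pairwise.complete.obs"))
  } else {
    if (nrow(g) < 3) stop("fewer than 3 pairwise-complete individuals")
    r <- stats::cor(g)
  }
  dimnames(r) <- list(ids, ids)
  r
}

#' Pairwise r-squared between two panel SNPs
#'
#' @param panel An [ld_panel()].
#' @param snp_a,snp_b SNP ids.
#' @return Squared Pearson correlation in `[0, 1]`.
#' @export
ld_r2 <- function(panel, snp_a, snp_b) {
  unname(ld_r(panel, c(snp_a, snp_b))[1L, 2L]^2)
}

#' Greedy p-value LD clumping
#'
#' PLINK-clump semantics: among records with `p <= p_index`, repeatedly take
#' the best remaining SNP (ascending p; ties broken by ascending bp, then
#' lexicographic snp_id) as an index SNP and remove all remaining candidates
#' on the same chromosome within `window_kb` of it whose r2 with it is
#' `>= r2_max`. SNPs absent from the panel (or monomorphic there) are
#' dropped with a warning. Missing `chrom`/`bp` are filled from the panel
#' map.
#'
#' @param records Sumstats table (needs `snp_id`, `p`; `chrom`/`bp` used if
#'   present).
#' @param panel An [ld_panel()].
#' @param p_index Index-SNP significance threshold.
#' @param r2_max r2 at or above which a nearby SNP is clumped away.
#' @param window_kb Window half-width in kilobases.
#' @return Character vector of retained index SNP ids, in selection order.
#' @export
ld_clump <- function(records, panel, p_index = 5e-8, r2_max = 0.2,
                     window_kb = 10000) {
  records <- data.table::as.data.table(records)
  cand <- records[is.finite(p) & p <= p_index]
  if (nrow(cand) == 0L) return(character())
  in_panel <- cand$snp_id %in% panel$map$snp_id
  if (!all(in_panel)) {
    warning(sum(!in_panel), " candidate SNP(s) absent from LD panel, dropped: ",
            .fmt_ids(cand$snp_id[!in_panel]))
    cand <- cand[in_panel]
  }
  if (nrow(cand) == 0L) return(character())
  pi_ <- .panel_idx(panel, cand$snp_id)
  mono <- panel$map$monomorphic[pi_]
  if (any(mono)) {
    warning(sum(mono), " monomorphic candidate SNP(s) dropped: ",
            .fmt_ids(cand$snp_id[mono]))
    cand <- cand[!mono]
  }
  if (nrow(cand) == 0L) return(character())
  ## fill chrom/bp from the panel map where absent
  pi_ <- .panel_idx(panel, cand$snp_id)
  if (!("chrom" %in% names(cand))) cand[, chrom := NA_character_]
  if (!("bp" %in% names(cand))) cand[, bp := NA_integer_]
  fill <- is.na(cand$chrom) | is.na(cand$bp)
  if (any(fill)) {
    cand[fill, `:=`(chrom = panel$map$chrom[pi_[fill]],
                    bp = panel$map$bp[pi_[fill]])]
  }
  data.table::setorder(cand, p, bp, snp_id)
  r2m <- ld_r(panel, cand$snp_id)^2
  win <- window_kb * 1000
  alive <- rep(TRUE, nrow(cand))
  kept <- character()
  for (i in seq_len(nrow(cand))) {
    if (!alive[i]) next
    kept <- c(kept, cand$snp_id[i])
    alive[i] <- FALSE
    hit <- alive & cand$chrom == cand$chrom[i] &
      abs(cand$bp - cand$bp[i]) <= win & r2m[i, ] >= r2_max
    alive[hit] <- FALSE
  }
  kept
}

## ---- panel IO ----------------------------------------------------------

#' Read an LD panel from TSV genotype + map files
#'
#' The genotype file has individuals as rows and SNPs as columns, with a
#' header of SNP ids (an optional first `iid` column is ignored); dosages
#' count the map's `a1` allele. The sidecar map TSV has columns
#' `snp_id, chrom, bp, a1, a2`.
#'
#' @param geno_path,map_path File paths (optionally gzipped).
#' @return An [ld_panel()].
#' @export
read_ld_panel_tsv <- function(geno_path, map_path) {
  g <- .fread_maybe_gz(geno_path, header = TRUE)
  if (tolower(names(g)[1L]) %in% c("iid", "id", "individual")) {
    g <- g[, -1L, with = FALSE]
  }
  map <- .fread_maybe_gz(map_path, header = TRUE)
  need <- c("snp_id", "chrom", "bp", "a1", "a2")
  miss <- setdiff(need, names(map))
  if (length(miss) > 0L) {
    stop("missing required column(s) in ", map_path, ": ",
         paste(miss, collapse = ", "))
  }
  if (!setequal(names(g), map$snp_id)) {
    stop("genotype columns and map snp_id disagree")
  }
  g <- g[, match(map$snp_id, names(g)), with = FALSE]
  ld_panel(as.matrix(g), map$snp_id, map$chrom, map$bp, map$a1, map$a2)
}

#' Write an LD panel as TSV genotype + map files
#' @param panel An [ld_panel()].
#' @param geno_path,map_path Output paths.
#' @export
write_ld_panel_tsv <- function(panel, geno_path, map_path) {
  data.table::fwrite(data.table::as.data.table(panel$geno), geno_path,
                     sep = "\t", quote = FALSE)
  data.table::fwrite(panel$map[, .(snp_id, chrom, bp, a1, a2)], map_path,
                     sep = "\t", quote = FALSE)
  invisible(c(geno_path, map_path))
}

## PLINK 1 binary genotypes, SNP-major v1.00.
## 2-bit codes (within each byte, low bits first):
##   00 = homozygous A1 (dosage 2), 01 = missing, 10 = het, 11 = hom A2.
.plink_decode <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      dec <- matrix(0L, nrow = 256, ncol = 4)
      code2dose <- c(`0` = 2L, `1` = NA_integer_, `2` = 1L, `3` = 0L)
      for (b in 0:255) {
        for (k in 0:3) {
          code <- bitwAnd(bitwShiftR(b, 2L * k), 3L)
          dec[b + 1L, k + 1L] <- code2dose[[as.character(code)]]
        }
      }
      tab <<- dec
    }
    tab
  }
})

#' Read an LD panel from PLINK bed/bim/fam files
#'
#' Minimal reader for the PLINK 1 binary format (SNP-major). Dosages count
#' the bim file's A1 allele.
#'
#' @param prefix Path prefix; `<prefix>.bed/.bim/.fam` must exist.
#' @return An [ld_panel()].
#' @export
read_plink_panel <- function(prefix) {
  bim <- data.table::fread(paste0(prefix, ".bim"), header = FALSE,
                           col.names = c("chrom", "snp_id", "cm", "bp",
                                         "a1", "a2"))
  fam <- data.table::fread(paste0(prefix, ".fam"), header = FALSE)
  n <- nrow(fam); m <- nrow(bim)
  con <- file(paste0(prefix, ".bed"), "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 3L)
  if (!identical(as.integer(magic), c(108L, 27L, 1L))) {
    stop("not a SNP-major PLINK v1.00 .bed file: ", prefix, ".bed")
  }
  bpsnp <- ceiling(n / 4)
  raw <- readBin(con, "raw", bpsnp * m)
  dec <- .plink_decode()
  ## decode all bytes at once: (bpsnp*m) x 4 dosage values, column-major per byte
  vals <- dec[as.integer(raw) + 1L, , drop = FALSE]
  geno <- matrix(t(vals), nrow = bpsnp * 4L)[seq_len(n), , drop = FALSE]
  dim(geno) <- c(n, m)
  ld_panel(geno, bim$snp_id, bim$chrom, bim$bp, bim$a1, bim$a2)
}

#' Write an LD panel as PLINK bed/bim/fam files
#' @param panel An [ld_panel()].
#' @param prefix Output path prefix.
#' @export
write_plink_panel <- function(panel, prefix) {
  g <- panel$geno
  n <- nrow(g); m <- ncol(g)
  map <- panel$map
  data.table::fwrite(data.table::data.table(
    map$chrom, map$snp_id, 0L, map$bp, map$a1,
    ifelse(is.na(map$a2), "0", map$a2)),
    paste0(prefix, ".bim"), sep = "\t", quote = FALSE, col.names = FALSE)
  data.table::fwrite(data.table::data.table(
    paste0("F", seq_len(n)), paste0("I", seq_len(n)), 0L, 0L, 0L, -9L),
    paste0(prefix, ".fam"), sep = "\t", quote = FALSE, col.names = FALSE)
  dose2code <- function(d) {
    code <- integer(length(d))          # dosage 2 -> 00
    code[is.na(d)] <- 1L
    code[!is.na(d) & d == 1] <- 2L
    code[!is.na(d) & d == 0] <- 3L
    code
  }
  bpsnp <- ceiling(n / 4)
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  pad <- bpsnp * 4L - n
  for (j in seq_len(m)) {
    code <- c(dose2code(g[, j]), rep(3L, pad))  # pad codes are ignored on read
    b <- code[c(TRUE, FALSE, FALSE, FALSE)] +
      bitwShiftL(code[c(FALSE, TRUE, FALSE, FALSE)], 2L) +
      bitwShiftL(code[c(FALSE, FALSE, TRUE, FALSE)], 4L) +
      bitwShiftL(code[c(FALSE, FALSE, FALSE, TRUE)], 6L)
    writeBin(as.raw(b), con)
  }
  invisible(prefix)
}

#' Align summary statistics to a panel's counted alleles
#'
#' Flips `beta`/`freq` of records whose allele orientation is swapped (or
#' strand-flipped) relative to the panel's `a1`/`a2`, so that effect signs
#' and signed LD correlations refer to the same alleles. Records for SNPs
#' absent from the panel or with irreconcilable alleles are dropped.
#'
#' @param records Sumstats table.
#' @param panel An [ld_panel()].
#' @param palindrome_maf_limit Passed to [harmonize_sumstats()].
#' @return `list(aligned = sumstats, exclusions = data.table)`.
#' @export
align_to_panel <- function(records, panel, palindrome_maf_limit = 0.4) {
  records <- data.table::as.data.table(records)
  m <- match(records$snp_id, panel$map$snp_id)
  keep <- !is.na(m)
  excl <- NULL
  if (!all(keep)) {
    excl <- data.table::data.table(snp_id = records$snp_id[!keep],
                                   reason = "not-in-panel")
  }
  rec <- records[keep]
  pm <- panel$map[m[keep]]
  ref <- data.table::data.table(snp_id = pm$snp_id, chrom = pm$chrom,
                                bp = pm$bp, a1 = pm$a1, a2 = pm$a2,
                                freq = pm$freq, beta = 0, se = 1, p = 1,
                                n = nrow(panel$geno))
  h <- harmonize_sumstats(ref, rec, palindrome_maf_limit)
  ## fill positions from the panel map
  hm <- match(h$harmonized$snp_id, pm$snp_id)
  h$harmonized[, `:=`(chrom = pm$chrom[hm], bp = pm$bp[hm])]
  exclusions <- data.table::rbindlist(list(excl, h$exclusions), fill = TRUE)
  list(aligned = h$harmonized, exclusions = exclusions)
}
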