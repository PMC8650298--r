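#' @useDynLib herdmix, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor optimize rbeta rbinom rpois runif sd setNames
#'   quantile weighted.mean complete.cases
#' @importFrom utils read.table write.table head tail
NULL

#' Variant table
#'
#' A data frame describing the markers of a genotype matrix: one row per
#' SNP with identifier, chromosome label, 1-based physical position,
#' genetic position in centimorgans and the two alleles. Genetic
#' positions must be non-decreasing within a chromosome; intervals built
#' from them are half-open `[start, end)`.
#'
#' @param snp_id character vector of unique marker names.
#' @param chrom chromosome labels (autosomes by number, `"X"` for the X).
#' @param pos_bp integer physical positions (1-based).
#' @param pos_cM numeric genetic positions in centimorgans.
#' @param ref_allele,alt_allele single-character nucleotide codes; the
#'   genotype matrix counts copies of `alt_allele`.
#' @return a `data.frame` of class `variant_table`.
#' @export
variant_table <- function(snp_id, chrom, pos_bp, pos_cM, ref_allele, alt_allele) {
  vt <- data.frame(snp_id = as.character(snp_id), chrom = as.character(chrom),
                   pos_bp = as.integer(pos_bp), pos_cM = as.numeric(pos_cM),
                   ref_allele = as.character(ref_allele),
                   alt_allele = as.character(alt_allele),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(vt$snp_id)) stop("duplicate snp_id in variant table")
  if (any(vt$ref_allele == vt$alt_allele))
    stop("ref and alt alleles must differ")
  for (ch in unique(vt$chrom)) {
    p <- vt$pos_cM[vt$chrom == ch]
    if (is.unsorted(p)) stop("pos_cM not non-decreasing on chromosome ", ch)
  }
  class(vt) <- c("variant_table", "data.frame")
  vt
}

#' Sample sheet
#'
#' Per-individual metadata: unique id, population label, sampling site and
#' genetic sex. Sex is required for any individual whose X-chromosome
#' genotypes are used (it sets the X ploidy).
#'
#' @param individual_id unique ids.
#' @param population population labels.
#' @param sampling_site sampling-site labels (defaults to the population).
#' @param genetic_sex one of `"female"`, `"male"`, `"unknown"` per individual.
#' @return a `data.frame` of class `sample_sheet`.
#' @export
sample_sheet <- function(individual_id, population,
                         sampling_site = population,
                         genetic_sex = "unknown") {
  sex <- rep_len(as.character(genetic_sex), length(individual_id))
  if (!all(sex %in% c("female", "male", "unknown")))
    stop("genetic_sex must be female, male or unknown")
  sh <- data.frame(individual_id = as.character(individual_id),
                   population = as.character(population),
                   sampling_site = as.character(sampling_site),
                   genetic_sex = sex, stringsAsFactors = FALSE)
  if (anyDuplicated(sh$individual_id)) stop("duplicate individual ids")
  class(sh) <- c("sample_sheet", "data.frame")
  sh
}

#' Genotype matrix container
#'
#' Bundles an individuals-by-SNPs matrix of alternate-allele counts with
#' its variant table and sample sheet. Missing calls are `NA`; valid calls
#' lie in `0..ploidy`, where ploidy is 2 on autosomes and on the X of
#' females, and 1 on the male X. Heterozygous male X input must be
#' resolved (to missing) before construction.
#'
#' @param calls integer matrix, rows = individuals (rownames = ids),
#'   columns = SNPs (colnames = snp ids).
#' @param variants a [variant_table()].
#' @param samples a [sample_sheet()].
#' @return an object of class `geno_matrix`.
#' @export
geno_matrix <- function(calls, variants, samples) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (is.null(rownames(calls))) rownames(calls) <- samples$individual_id
  if (is.null(colnames(calls))) colnames(calls) <- variants$snp_id
  if (!identical(colnames(calls), variants$snp_id))
    stop("calls columns do not match variant table")
  if (!identical(rownames(calls), samples$individual_id))
    stop("calls rows do not match sample sheet")
  gm <- structure(list(calls = calls, variants = variants, samples = samples),
                  class = "geno_matrix")
  pl <- ploidy_matrix(gm)
  bad <- which(!is.na(calls) & (calls < 0L | calls > pl), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("call exceeds ploidy at individual ", rownames(calls)[bad[1, 1]],
         ", snp ", colnames(calls)[bad[1, 2]])
  x_used <- variants$chrom == "X" & colSums(!is.na(calls)) > 0
  if (any(x_used)) {
    carriers <- rowSums(!is.na(calls[, x_used, drop = FALSE])) > 0
    if (any(samples$genetic_sex[carriers] == "unknown"))
      stop("X genotypes present for individuals of unknown sex")
  }
  gm
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat("geno_matrix:", nrow(x$calls), "individuals x", ncol(x$calls), "SNPs\n")
  cat("  chromosomes:", paste(unique(x$variants$chrom), collapse = ", "), "\n")
  cat("  missing calls:", sum(is.na(x$calls)), "\n")
  invisible(x)
}

#' Per-call ploidy matrix
#'
#' Ploidy of each (individual, SNP) cell: 2 everywhere except the male X,
#' which is 1.
#'
#' @param gm a [geno_matrix()].
#' @return integer matrix with the dimensions of `gm$calls`.
#' @export
ploidy_matrix <- function(gm) {
  pl <- matrix(2L, nrow(gm$calls), ncol(gm$calls),
               dimnames = dimnames(gm$calls))
  male <- gm$samples$genetic_sex == "male"
  on_x <- gm$variants$chrom == "X"
  if (any(male) && any(on_x)) pl[male, on_x] <- 1L
  pl
}

subset_geno <- function(gm, ind = NULL, snp = NULL) {
  calls <- gm$calls
  samples <- gm$samples
  variants <- gm$variants
  if (!is.null(ind)) {
    calls <- calls[ind, , drop = FALSE]
    samples <- samples[ind, , drop = FALSE]
    rownames(samples) <- NULL
  }
  if (!is.null(snp)) {
    calls <- calls[, snp, drop = FALSE]
    variants <- variants[snp, , drop = FALSE]
    rownames(variants) <- NULL
  }
  structure(list(calls = calls, variants = variants, samples = samples),
            class = "geno_matrix")
}

#' Read genotypes with sample metadata
#'
#' Reads a VCF (GT field only) or a genotype TSV into a [geno_matrix()].
#' The TSV dialect is: a header row of snp ids, then one row per
#' individual (first column the id), cells in `{0, 1, 2, NA}`. Male X
#' genotypes are coerced to haploid counts; a heterozygous male X call is
#' set missing and counted in the returned report.
#'
#' @param path file to read.
#' @param format `"vcf"` or `"tsv"`.
#' @param sample_sheet a [sample_sheet()] covering the file's individuals.
#' @param variants for `format = "tsv"`, a [variant_table()] describing
#'   the columns (a TSV carries no positions or alleles itself).
#' @return a list with elements `geno` ([geno_matrix()]) and `report`
#'   (list with `male_x_het_set_missing` count).
#' @export
read_genotypes <- function(path, format = c("vcf", "tsv"), sample_sheet,
                           variants = NULL) {
  format <- match.arg(format)
  if (format == "vcf") {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(v)
    ids <- fix[, "ID"]
    ids[is.na(ids)] <- paste0(fix[is.na(ids), "CHROM"], "_", fix[is.na(ids), "POS"])
    cm <- suppressWarnings(as.numeric(vcfR::extract.info(v, "CM")))
    if (all(is.na(cm))) cm <- as.numeric(fix[, "POS"]) / 1e6
    vt <- variant_table(ids, fix[, "CHROM"], as.integer(fix[, "POS"]), cm,
                        fix[, "REF"], fix[, "ALT"])
    gt <- vcfR::extract.gt(v, element = "GT")
    samp <- colnames(gt)
    sheet <- sample_sheet[match(samp, sample_sheet$individual_id), ,
                          drop = FALSE]
    if (anyNA(sheet$individual_id))
      stop("sample(s) in VCF absent from sample sheet: ",
           paste(samp[is.na(sheet$individual_id)], collapse = ", "))
    rownames(sheet) <- NULL
    class(sheet) <- c("sample_sheet", "data.frame")
    parse_gt <- function(g) {
      al <- strsplit(gsub("|", "/", g, fixed = TRUE), "/", fixed = TRUE)
      cnt <- vapply(al, function(a) {
        if (length(a) == 0 || any(a == ".") || anyNA(a)) return(NA_integer_)
        sum(a != "0")
      }, integer(1))
      nal <- vapply(al, length, integer(1))
      list(cnt = cnt, nal = nal)
    }
    parsed <- apply(gt, 1, parse_gt, simplify = FALSE)
    calls <- do.call(rbind, lapply(parsed, `[[`, "cnt"))
    n_alleles <- do.call(rbind, lapply(parsed, `[[`, "nal"))
    dimnames(calls) <- dimnames(n_alleles) <- list(vt$snp_id, samp)
    calls <- t(calls)
    n_alleles <- t(n_alleles)
  } else {
    tab <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                      row.names = 1, stringsAsFactors = FALSE)
    calls <- as.matrix(tab)
    if (is.null(variants))
      stop("genotype-tsv input needs a variant table for positions/alleles")
    vt <- variants
    calls <- calls[, vt$snp_id, drop = FALSE]
    sheet <- sample_sheet[match(rownames(calls), sample_sheet$individual_id), ,
                          drop = FALSE]
    if (anyNA(sheet$individual_id)) stop("individual(s) missing from sample sheet")
    rownames(sheet) <- NULL
    class(sheet) <- c("sample_sheet", "data.frame")
  }
  storage.mode(calls) <- "integer"

  # haploidize the male X; VCF encodes male X as diploid GT, so "0/1" is
  # impossible for a haploid chromosome and becomes missing, while "1/1"
  # collapses to one alternate copy. The TSV dialect already stores
  # haploid counts, so a male X cell of 2 there is a ploidy error caught
  # by the container below.
  n_het_fix <- 0L
  male <- sheet$genetic_sex == "male"
  on_x <- vt$chrom == "X"
  if (any(on_x) && any(!is.na(calls[, on_x, drop = FALSE]))) {
    if (any(sheet$genetic_sex == "unknown" &
            rowSums(!is.na(calls[, on_x, drop = FALSE])) > 0))
      stop("X genotypes present for individuals of unknown sex")
    if (any(male) && format == "vcf") {
      mx <- calls[male, on_x, drop = FALSE]
      dip <- n_alleles[male, on_x, drop = FALSE] == 2L
      het <- !is.na(mx) & dip & mx == 1L
      n_het_fix <- sum(het)
      if (n_het_fix > 0)
        warning(n_het_fix, " heterozygous male X call(s) set to missing")
      mx[het] <- NA_integer_
      mx[!is.na(mx) & dip & mx == 2L] <- 1L
      calls[male, on_x] <- mx
    }
  }
  list(geno = geno_matrix(calls, vt, sheet),
       report = list(male_x_het_set_missing = n_het_fix))
}

#' Write genotypes
#'
#' Writes a [geno_matrix()] as VCF 4.2 (GT only; male X emitted as a
#' single haploid allele) or as the genotype TSV dialect read by
#' [read_genotypes()].
#'
#' @param gm a [geno_matrix()].
#' @param path output file (`.vcf` is written uncompressed).
#' @param format `"vcf"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(gm, path, format = c("vcf", "tsv")) {
  format <- match.arg(format)
  if (format == "tsv") {
    tab <- cbind(individual_id = rownames(gm$calls),
                 as.data.frame(gm$calls, check.names = FALSE))
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  vt <- gm$variants
  pl <- ploidy_matrix(gm)
  gt_of <- function(g, p) {
    out <- character(length(g))
    dip <- p == 2L
    out[dip] <- c("0/0", "0/1", "1/1")[g[dip] + 1L]
    out[!dip] <- c("0", "1")[g[!dip] + 1L]
    out[is.na(g)] <- ifelse(dip[is.na(g)], "./.", ".")
    out
  }
  body <- vapply(seq_len(nrow(vt)), function(j) {
    paste(gt_of(gm$calls[, j], pl[, j]), collapse = "\t")
  }, character(1))
  lines <- c("##fileformat=VCFv4.2",
             sprintf("##INFO=<ID=CM,Number=1,Type=Float,Description=\"Genetic position (cM)\">"),
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", rownames(gm$calls)), collapse = "\t"),
             paste(vt$chrom, vt$pos_bp, vt$snp_id, vt$ref_allele, vt$alt_allele,
                   ".", ".", sprintf("CM=%.6g", vt$pos_cM), "GT", body,
                   sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a sample sheet from TSV
#'
#' Expects columns `individual_id`, `population`, `sampling_site`,
#' `genetic_sex`.
#' @param path tab-separated file.
#' @return a [sample_sheet()].
#' @export
read_sample_sheet <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  sample_sheet(tab$individual_id, tab$population, tab$sampling_site,
               tab$genetic_sex)
}
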