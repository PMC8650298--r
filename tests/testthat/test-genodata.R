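test_that("VCF round-trip preserves calls, male X read back haploid", {
  gm <- toy_geno(n_ind = 3, n_aut = 3, n_x = 2, seed = 4)
  path <- tempfile(fileext = ".vcf")
  write_genotypes(gm, path, format = "vcf")
  back <- read_genotypes(path, format = "vcf", sample_sheet = gm$samples)
  expect_identical(unname(back$geno$calls), unname(gm$calls))
  expect_identical(back$geno$variants$snp_id, gm$variants$snp_id)
  expect_identical(back$report$male_x_het_set_missing, 0L)
  expect_equal(back$geno$variants$pos_cM, gm$variants$pos_cM,
               tolerance = 1e-6)
})

test_that("TSV round-trip is the identity", {
  gm <- toy_geno(seed = 5)
  gm$calls[2, 3] <- NA
  gm <- geno_matrix(gm$calls, gm$variants, gm$samples)
  path <- tempfile(fileext = ".tsv")
  write_genotypes(gm, path, format = "tsv")
  back <- read_genotypes(path, format = "tsv", sample_sheet = gm$samples,
                         variants = gm$variants)
  expect_identical(unname(back$geno$calls), unname(gm$calls))
})

test_that("heterozygous male X calls are set missing and counted", {
  vt <- variant_table(c("a1", "x1"), c("1", "X"), c(100L, 200L),
                      c(0.1, 0.2), c("A", "C"), c("G", "T"))
  sh <- sample_sheet(c("f1", "m1"), "P", genetic_sex = c("female", "male"))
  lines <- c("##fileformat=VCFv4.2",
             "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tf1\tm1",
             "1\t100\ta1\tA\tG\t.\t.\t.\tGT\t0/1\t1/1",
             "X\t200\tx1\tC\tT\t.\t.\t.\tGT\t0/1\t0/1")
  path <- tempfile(fileext = ".vcf")
  writeLines(lines, path)
  expect_warning(res <- read_genotypes(path, "vcf", sh), "heterozygous male X")
  expect_identical(res$report$male_x_het_set_missing, 1L)
  expect_true(is.na(res$geno$calls["m1", "x1"]))
  expect_identical(res$geno$calls["f1", "x1"], 1L)
  expect_identical(res$geno$calls["m1", "a1"], 2L)
})

test_that("X genotypes with unknown sex are rejected", {
  gm <- toy_geno(n_ind = 2, sexes = c("female", "male"))
  sheet_bad <- gm$samples
  sheet_bad$genetic_sex[2] <- "unknown"
  expect_error(geno_matrix(gm$calls, gm$variants, sheet_bad), "unknown sex")
})

test_that("missingness filter removes SNPs first, then individuals", {
  set.seed(11)
  calls <- matrix(sample(0:2, 100 * 20, replace = TRUE), 100, 20)
  calls[sample(100, 6), 3] <- NA          # snp 3: 6% missing -> out at 0.05
  calls[sample(100, 5), 7] <- NA          # snp 7: exactly 5% -> kept
  gm <- geno_from_calls(calls)
  res <- filter_missingness(gm, per_snp_max = 0.05, per_ind_max = 0.05)
  expect_identical(res$report$snps_removed$snp_id, "s003")
  expect_true("s007" %in% colnames(res$geno$calls))
  # brute-force check of the removal set on a planted matrix
  calls2 <- matrix(sample(0:2, 50 * 20, replace = TRUE), 50, 20)
  for (j in 1:20) calls2[seq_len(j - 1), j] <- NA
  gm2 <- geno_from_calls(calls2)
  res2 <- filter_missingness(gm2, per_snp_max = 0.10, per_ind_max = 1)
  manual <- colnames(gm2$calls)[colMeans(is.na(calls2)) > 0.10]
  expect_identical(res2$report$snps_removed$snp_id, manual)
  # no missing data -> identity
  res3 <- filter_missingness(gm, per_snp_max = 1, per_ind_max = 1)
  expect_identical(res3$geno$calls, gm$calls)
  # idempotence
  res4 <- filter_missingness(res$geno, 0.05, 0.05)
  expect_identical(res4$geno$calls, res$geno$calls)
})

test_that("exact HWE p-values match the enumeration oracle", {
  expect_equal(hwe_exact_test(5, 0, 0), 1)     # monomorphic
  expect_equal(hwe_exact_test(1, 18, 1), hwe_oracle(1, 18, 1),
               tolerance = 1e-10)
  set.seed(21)
  for (rep in 1:100) {
    n <- sample(5:50, 1)
    naa <- sample(0:n, 1)
    nab <- sample(0:(n - naa), 1)
    nbb <- n - naa - nab
    expect_equal(hwe_exact_test(naa, nab, nbb), hwe_oracle(naa, nab, nbb),
                 tolerance = 1e-9)
  }
})

test_that("HWE filter removes a SNP only when it fails in every group", {
  set.seed(31)
  # snp 1: extreme heterozygote excess in both sites; snp 2: only site A;
  # snp 3: in equilibrium everywhere
  mk_site <- function(bad1, bad2) {
    cbind(if (bad1) rep(1L, 30) else rbinom(30, 2, 0.5),
          if (bad2) rep(1L, 30) else rbinom(30, 2, 0.5),
          rbinom(30, 2, 0.5))
  }
  calls <- rbind(mk_site(TRUE, TRUE), mk_site(TRUE, FALSE))
  vt <- variant_table(c("s1", "s2", "s3"), rep("1", 3), 1:3 * 100L,
                      1:3 * 0.1, rep("A", 3), rep("G", 3))
  sh <- sample_sheet(sprintf("i%02d", 1:60), "P",
                     sampling_site = rep(c("A", "B"), each = 30))
  gm <- geno_matrix(calls, vt, sh)
  res <- hwe_exact_filter(gm, alpha = 0.005)
  expect_identical(res$report$snp_id, "s1")
  expect_identical(colnames(res$geno$calls), c("s2", "s3"))
  # idempotent
  res2 <- hwe_exact_filter(res$geno, alpha = 0.005)
  expect_identical(res2$geno$calls, res$geno$calls)
})

test_that("strand-ambiguous SNPs are dropped symmetrically", {
  # A/T and C/G pairs out in either allele order; A/G and T/C stay
  vt <- variant_table(paste0("s", 1:6), rep("1", 6), 1:6 * 100L, 1:6 * 0.1,
                      c("A", "A", "G", "T", "C", "T"),
                      c("T", "G", "C", "A", "G", "C"))
  sh <- sample_sheet(c("i1", "i2"), "P")
  gm <- geno_matrix(matrix(1L, 2, 6), vt, sh)
  out <- drop_ambiguous(gm)
  expect_identical(out$variants$snp_id, c("s2", "s6"))
  expect_identical(drop_ambiguous(out)$variants$snp_id, c("s2", "s6"))
})

test_that("IBS relatedness flags duplicates and kin, not unrelated", {
  sim <- small_pulse_sim(n_out = 40, n_snp_aut = 600, n_snp_x = 0,
                         map = c("1" = 150), seed = 13)
  calls <- sim$geno$calls
  # plant a duplicate and a synthetic parent-offspring pair
  calls <- rbind(calls, dup = calls[1, ])
  set.seed(3)
  freqs <- colMeans(sim$geno$calls) / 2
  parent <- calls[2, ]
  child <- rbinom(ncol(calls), 1, parent / 2) + rbinom(ncol(calls), 1, freqs)
  calls <- rbind(calls, child = child)
  rownames(calls) <- sprintf("i%03d", seq_len(nrow(calls)))
  gm <- geno_from_calls(calls)
  res <- ibs_relatedness(gm)
  dup_row <- res$pairs[res$pairs$id1 == "i001" & res$pairs$id2 == "i041", ]
  expect_identical(dup_row$degree, "first")
  expect_gt(dup_row$kinship_like, 0.9)
  po_row <- res$pairs[res$pairs$id1 == "i002" & res$pairs$id2 == "i042", ]
  unrelated <- res$pairs$kinship_like[res$pairs$degree == "unrelated"]
  expect_gt(po_row$kinship_like, max(unrelated))
  expect_true("i041" %in% res$exclude | "i001" %in% res$exclude)
})

test_that("unrelated panel yields an empty exclusion list", {
  set.seed(17)
  calls <- matrix(rbinom(30 * 500, 2, runif(500, 0.1, 0.9)),
                  30, 500, byrow = TRUE)
  gm <- geno_from_calls(calls)
  res <- ibs_relatedness(gm)
  expect_length(res$exclude, 0)
})

test_that("population down-sampling caps and is seed-reproducible", {
  sh <- sample_sheet(sprintf("i%03d", 1:47),
                     population = rep(c("A", "B"), c(12, 35)))
  k1 <- downsample_population(sh, max_n = 20, seed = 5)
  k2 <- downsample_population(sh, max_n = 20, seed = 5)
  expect_identical(k1, k2)
  expect_identical(sum(startsWith(k1, "i0") &
                         k1 %in% sh$individual_id[sh$population == "A"]), 12L)
  expect_identical(sum(k1 %in% sh$individual_id[sh$population == "B"]), 20L)
  k3 <- downsample_population(sh, max_n = 20, seed = 6)
  expect_false(identical(k1, k3))
})

test_that("LD pruning leaves no within-window pair above the r2 cap", {
  set.seed(41)
  n <- 60
  # planted LD blocks: groups of 4 highly correlated SNPs
  base <- matrix(rbinom(n * 30, 2, 0.5), n, 30)
  calls <- matrix(0L, n, 120)
  for (j in 1:120) {
    src <- base[, ceiling(j / 4)]
    flip <- rbinom(n, 1, 0.05)
    calls[, j] <- ifelse(flip == 1, sample(0:2, n, TRUE), src)
  }
  gm <- geno_from_calls(calls)
  kept <- ld_prune(gm, window_snps = 50, step_snps = 10, r2_max = 0.4)
  idx <- match(kept, colnames(gm$calls))
  # exhaustive within-window verification over every window position
  for (s in seq(1, ncol(calls) - 1, by = 10)) {
    win <- idx[idx >= s & idx < s + 50]
    if (length(win) < 2) next
    r2 <- cor(calls[, win])^2
    diag(r2) <- 0
    expect_lte(max(r2, na.rm = TRUE), 0.4)
  }
  # duplicated column: one of the two goes
  dup <- cbind(calls[, 1:10], calls[, 5])
  gm2 <- geno_from_calls(dup)
  kept2 <- ld_prune(gm2, window_snps = 20, step_snps = 5, r2_max = 0.4)
  expect_false(all(c("s005", "s011") %in% kept2))
  # independent SNPs all keep; pruning is idempotent
  indep <- matrix(rbinom(200 * 40, 2, 0.5), 200, 40)
  gm3 <- geno_from_calls(indep)
  kept3 <- ld_prune(gm3)
  expect_identical(kept3, colnames(gm3$calls))
  sub <- herdmix:::subset_geno(gm, snp = match(kept, colnames(gm$calls)))
  expect_identical(ld_prune(sub, 50, 10, 0.4), kept)
})

test_that("ancestral-allele polarization follows the 2-of-3 ape rule", {
  vt <- variant_table(paste0("s", 1:6), rep("1", 6), 1:6 * 100L, 1:6 * 0.1,
                      rep("A", 6), rep("G", 6))
  apes <- data.frame(
    snp_id = paste0("s", 1:6),
    chimp = c("A", "A", "A", "C", "A", NA),
    gorilla = c("A", "A", "C", "C", NA, NA),
    orangutan = c("G", "A", "G", "C", "A", "A"),
    stringsAsFactors = FALSE)
  res <- polarize_ancestral(vt, apes)
  # s1: 2-of-3 agree on A; s2: all three agree; s5: two calls agree on A
  expect_identical(res$ancestral$snp_id, c("s1", "s2", "s5"))
  expect_identical(res$ancestral$ancestral_allele, c("A", "A", "A"))
  # s3: no majority; s4: majority allele C not a human allele; s6: 1 call
  expect_setequal(res$excluded, c("s3", "s4", "s6"))
})

test_that("panel merging harmonizes swapped alleles and preserves frequencies", {
  gm <- toy_geno(n_ind = 8, n_aut = 10, n_x = 0, seed = 51)
  # self-merge is the identity on calls
  m0 <- merge_panels(gm, gm)
  expect_identical(unname(m0$geno$calls),
                   unname(rbind(gm$calls, gm$calls)))
  # swapped ref/alt panel: counts complemented back on merge
  vt_swap <- gm$variants
  tmp <- vt_swap$ref_allele
  vt_swap$ref_allele <- vt_swap$alt_allele
  vt_swap$alt_allele <- tmp
  sh2 <- sample_sheet(paste0("j", 1:8), "P2")
  calls_swap <- 2L - gm$calls
  rownames(calls_swap) <- sh2$individual_id
  gm_swap <- geno_matrix(calls_swap, vt_swap, sh2)
  m1 <- merge_panels(gm, gm_swap)
  expect_identical(m1$report$flipped_per_panel[2], ncol(gm$calls))
  f_orig <- colMeans(gm$calls) / 2
  f_merged <- colMeans(m1$geno$calls[9:16, , drop = FALSE]) / 2
  expect_equal(unname(f_merged), unname(f_orig))
  # disjoint SNP sets -> error
  vt_other <- gm$variants
  vt_other$snp_id <- paste0("z", seq_len(nrow(vt_other)))
  calls_other <- gm$calls
  dimnames(calls_other) <- list(sh2$individual_id, vt_other$snp_id)
  gm_other <- geno_matrix(calls_other, vt_other, sh2)
  expect_error(merge_panels(gm, gm_other), "no overlapping")
})
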