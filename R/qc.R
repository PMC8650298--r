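#' Missingness filter
#'
#' Removes SNPs whose missing-call fraction exceeds `per_snp_max`, then
#' individuals whose missing fraction (over the surviving SNPs) exceeds
#' `per_ind_max`. SNPs are filtered first, so a badly typed marker does
#' not drag down otherwise good samples.
#'
#' @param gm a [geno_matrix()].
#' @param per_snp_max maximum tolerated per-SNP missing fraction
#'   (default 0.05).
#' @param per_ind_max maximum tolerated per-individual missing fraction
#'   (default 0.05).
#' @return list with `geno` (filtered) and `report` (data frames
#'   `snps_removed`, `individuals_removed` with their missing fractions).
#' @export
filter_missingness <- function(gm, per_snp_max = 0.05, per_ind_max = 0.05) {
  stopifnot(per_snp_max >= 0, per_snp_max <= 1,
            per_ind_max >= 0, per_ind_max <= 1)
  snp_miss <- colMeans(is.na(gm$calls))
  drop_snp <- snp_miss > per_snp_max
  gm2 <- subset_geno(gm, snp = !drop_snp)
  ind_miss <- rowMeans(is.na(gm2$calls))
  if (ncol(gm2$calls) == 0) ind_miss <- rep(0, nrow(gm2$calls))
  drop_ind <- ind_miss > per_ind_max
  gm2 <- subset_geno(gm2, ind = !drop_ind)
  if (ncol(gm2$calls) == 0 || nrow(gm2$calls) == 0)
    stop("missingness filter removed all SNPs or all individuals")
  list(geno = gm2,
       report = list(
         snps_removed = data.frame(
           snp_id = colnames(gm$calls)[drop_snp],
           missing_fraction = unname(snp_miss[drop_snp])),
         individuals_removed = data.frame(
           individual_id = rownames(gm$calls)[drop_ind],
           missing_fraction = unname(ind_miss[drop_ind]))))
}

#' Exact Hardy-Weinberg test
#'
#' Exact two-sided test for departure from Hardy-Weinberg proportions at
#' a biallelic diploid site, from genotype counts. The p-value is the sum
#' of probabilities, over all heterozygote counts compatible with the
#' observed allele counts, that do not exceed the probability of the
#' observed configuration (no mid-p correction). Computed with the
#' standard recurrence over heterozygote counts.
#'
#' @param n_hom_ref,n_het,n_hom_alt genotype counts (vectorized).
#' @return numeric vector of p-values.
#' @export
hwe_exact_test <- function(n_hom_ref, n_het, n_hom_alt) {
  mapply(function(naa, nab, nbb) {
    n <- naa + nab + nbb
    if (n == 0) return(1)
    n_a <- 2 * naa + nab          # minor/major orientation is irrelevant
    n_b <- 2 * nbb + nab
    rare <- min(n_a, n_b)
    # parity of the heterozygote count is fixed by the allele counts
    hets <- seq(rare %% 2, rare, by = 2)
    if (length(hets) == 1) return(1)
    # recurrence: P(h+2)/P(h) = 4*na(h)*nb(h) / ((h+2)*(h+1))
    # with na(h) = (rare - h)/2 available rare-allele homozygote copies
    probs <- numeric(length(hets))
    probs[1] <- 1  # un-normalized, rescaled below
    for (i in seq_along(hets)[-1]) {
      h <- hets[i - 1]
      hom_rare <- (rare - h) / 2
      hom_common <- n - h - hom_rare
      probs[i] <- probs[i - 1] * 4 * hom_rare * hom_common /
        ((h + 2) * (h + 1))
    }
    probs <- probs / sum(probs)
    obs <- probs[match(nab, hets)]
    sum(probs[probs <= obs * (1 + 1e-9)])
  }, n_hom_ref, n_het, n_hom_alt)
}

#' Hardy-Weinberg filter per site group
#'
#' Applies the exact Hardy-Weinberg test per SNP within each group of a
#' site partition (e.g. sampling locations). A SNP is removed only when
#' it fails (`p < alpha`) in every evaluable group, so that true
#' population structure across sites does not eliminate markers that a
#' genotyping artifact would fail everywhere. Groups with fewer than 5
#' genotyped diploids at a SNP are skipped for that SNP; male X calls
#' (haploid) never enter the test.
#'
#' @param gm a [geno_matrix()].
#' @param groups factor/character vector partitioning individuals
#'   (default: the sample sheet's `sampling_site`).
#' @param alpha per-test significance threshold (default 0.005).
#' @param min_group_n minimum genotyped diploids per group (default 5).
#' @return list with `geno` (filtered) and `report` (data frame of
#'   removed SNPs with their per-group p-values collapsed to the maximum).
#' @export
hwe_exact_filter <- function(gm, groups = gm$samples$sampling_site,
                             alpha = 0.005, min_group_n = 5) {
  groups <- as.character(groups)
  stopifnot(length(groups) == nrow(gm$calls))
  pl <- ploidy_matrix(gm)
  fails_everywhere <- rep(TRUE, ncol(gm$calls))
  evaluated <- rep(FALSE, ncol(gm$calls))
  max_p <- rep(NA_real_, ncol(gm$calls))
  for (grp in unique(groups)) {
    rows <- groups == grp
    calls <- gm$calls[rows, , drop = FALSE]
    dip <- pl[rows, , drop = FALSE] == 2L & !is.na(calls)
    n0 <- colSums(dip & calls == 0L)
    n1 <- colSums(dip & calls == 1L)
    n2 <- colSums(dip & calls == 2L)
    n <- n0 + n1 + n2
    ok <- n >= min_group_n
    if (!any(ok)) {
      warning("group ", grp, " has <", min_group_n,
              " genotyped diploids everywhere; skipped")
      next
    }
    p <- rep(NA_real_, length(n))
    p[ok] <- hwe_exact_test(n0[ok], n1[ok], n2[ok])
    evaluated <- evaluated | ok
    fails_everywhere[ok] <- fails_everywhere[ok] & (p[ok] < alpha)
    max_p <- pmax(max_p, p, na.rm = TRUE)
  }
  drop <- evaluated & fails_everywhere
  list(geno = subset_geno(gm, snp = !drop),
       report = data.frame(snp_id = colnames(gm$calls)[drop],
                           max_group_p = max_p[drop]))
}

#' Remove strand-ambiguous SNPs
#'
#' Drops A/T and C/G SNPs (in either allele order), whose strand cannot
#' be resolved when merging datasets genotyped on different strands.
#'
#' @param gm a [geno_matrix()].
#' @return filtered [geno_matrix()].
#' @export
drop_ambiguous <- function(gm) {
  pair <- paste(pmin(gm$variants$ref_allele, gm$variants$alt_allele),
                pmax(gm$variants$ref_allele, gm$variants$alt_allele))
  subset_geno(gm, snp = !(pair %in% c("A T", "C G")))
}

#' IBS relatedness screen
#'
#' Computes a kinship-like proportion for every pair of individuals from
#' identity by state: one minus the ratio of the mean absolute genotype
#' difference to its expectation under Hardy-Weinberg independence at the
#' sample allele frequencies. Unrelated pairs score near 0, duplicates
#' score 1, first-degree relatives near 0.5. Pairs above the cuts are
#' flagged and one member of each flagged pair is excluded (the one with
#' more missingness; ties go against the later id in sort order).
#'
#' @param gm a [geno_matrix()] (autosomal SNPs are used).
#' @param first_degree_cut flag at or above this as first degree
#'   (default 0.45).
#' @param second_degree_cut flag at or above this as second degree
#'   (default 0.20).
#' @return list with `pairs` (data frame id1, id2, kinship_like, degree)
#'   and `exclude` (character vector of ids to drop).
#' @export
ibs_relatedness <- function(gm, first_degree_cut = 0.45,
                            second_degree_cut = 0.20) {
  stopifnot(nrow(gm$calls) >= 2)
  aut <- gm$variants$chrom != "X"
  g <- gm$calls[, aut, drop = FALSE]
  n <- nrow(g)
  freq <- colMeans(g, na.rm = TRUE) / 2
  # E|gi - gj| for two independent HW genotypes at frequency q:
  # unordered pairs (0,1) and (1,2) differ by 1, (0,2) by 2
  p0 <- (1 - freq)^2; p1 <- 2 * freq * (1 - freq); p2 <- freq^2
  e_diff <- 2 * p0 * p1 + 2 * p1 * p2 + 4 * p0 * p2
  ids <- rownames(g)
  res <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      both <- !is.na(g[i, ]) & !is.na(g[j, ])
      if (!any(both)) next
      obs <- mean(abs(g[i, both] - g[j, both]))
      expd <- mean(e_diff[both])
      res[[length(res) + 1]] <- data.frame(
        id1 = ids[i], id2 = ids[j],
        kinship_like = 1 - obs / expd, stringsAsFactors = FALSE)
    }
  }
  pairs <- do.call(rbind, res)
  pairs$degree <- ifelse(pairs$kinship_like >= first_degree_cut, "first",
                  ifelse(pairs$kinship_like >= second_degree_cut, "second",
                         "unrelated"))
  flagged <- pairs[pairs$degree != "unrelated", , drop = FALSE]
  exclude <- character(0)
  miss <- rowMeans(is.na(gm$calls))
  names(miss) <- rownames(gm$calls)
  if (nrow(flagged) > 0) {
    for (r in seq_len(nrow(flagged))) {
      a <- flagged$id1[r]; b <- flagged$id2[r]
      if (a %in% exclude || b %in% exclude) next
      drop <- if (miss[a] > miss[b]) a
              else if (miss[b] > miss[a]) b
              else max(a, b)  # tie: later id
      exclude <- c(exclude, drop)
    }
  }
  list(pairs = pairs, exclude = exclude)
}

#' Random down-sampling of populations
#'
#' Caps each population at `max_n` individuals by seeded random
#' selection; populations at or below the cap are untouched.
#'
#' @param sheet a [sample_sheet()].
#' @param max_n maximum individuals per population (default 20).
#' @param seed integer seed making the selection reproducible.
#' @return character vector of kept individual ids, in sheet order.
#' @export
downsample_population <- function(sheet, max_n = 20, seed) {
  keep <- character(0)
  with_seed(seed, {
    for (pop in unique(sheet$population)) {
      ids <- sheet$individual_id[sheet$population == pop]
      if (length(ids) > max_n) ids <- sample(ids, max_n)
      keep <- c(keep, ids)
    }
  })
  sheet$individual_id[sheet$individual_id %in% keep]
}

#' Sliding-window LD pruning
#'
#' Greedy genotype-correlation pruning in the PLINK
#' `--indep-pairwise`-style scheme: within each window of `window_snps`
#' consecutive SNPs (per chromosome), while any surviving pair has
#' squared correlation above `r2_max`, the pair with the highest r2 is
#' resolved by removing its lower-minor-allele-frequency member (ties
#' remove the later position); the window then advances by `step_snps`.
#'
#' @param gm a [geno_matrix()].
#' @param window_snps window width in SNPs (default 200).
#' @param step_snps step size in SNPs (default 25).
#' @param r2_max maximum tolerated pairwise r2 (default 0.4).
#' @return character vector of kept snp ids.
#' @export
ld_prune <- function(gm, window_snps = 200, step_snps = 25, r2_max = 0.4) {
  keep <- rep(TRUE, ncol(gm$calls))
  names(keep) <- colnames(gm$calls)
  g_all <- gm$calls
  maf_all <- pmin(colMeans(g_all, na.rm = TRUE) / 2,
                  1 - colMeans(g_all, na.rm = TRUE) / 2)
  for (ch in unique(gm$variants$chrom)) {
    idx <- which(gm$variants$chrom == ch)
    starts <- seq(1, max(1, length(idx) - 1), by = step_snps)
    for (s in starts) {
      win <- idx[s:min(s + window_snps - 1, length(idx))]
      win <- win[keep[win]]
      if (length(win) < 2) next
      r2 <- suppressWarnings(
        cor(g_all[, win, drop = FALSE], use = "pairwise.complete.obs"))^2
      r2[!is.finite(r2)] <- 0
      diag(r2) <- 0
      repeat {
        m <- which.max(r2)
        if (r2[m] <= r2_max) break
        ij <- arrayInd(m, dim(r2))
        a <- win[ij[1]]; b <- win[ij[2]]
        drop <- if (maf_all[a] < maf_all[b]) a
                else if (maf_all[b] < maf_all[a]) b
                else max(a, b)  # tie: later position
        keep[drop] <- FALSE
        d <- which(win == drop)
        r2[d, ] <- 0; r2[, d] <- 0
      }
    }
  }
  names(keep)[keep]
}

#' Ancestral-allele polarization
#'
#' Assigns the ancestral allele of each SNP by majority vote over
#' chimpanzee, gorilla and orangutan calls: at least two of the three
#' apes must carry the same allele, and that allele must be one of the
#' SNP's two human alleles; otherwise the SNP is excluded.
#'
#' @param variants a [variant_table()].
#' @param apes data frame with columns `snp_id`, `chimp`, `gorilla`,
#'   `orangutan` (single nucleotide codes or `NA`).
#' @return list with `ancestral` (data frame snp_id, ancestral_allele)
#'   and `excluded` (snp ids without a usable ancestral state).
#' @export
polarize_ancestral <- function(variants, apes) {
  apes <- apes[match(variants$snp_id, apes$snp_id), , drop = FALSE]
  anc <- rep(NA_character_, nrow(variants))
  for (i in seq_len(nrow(variants))) {
    calls <- c(apes$chimp[i], apes$gorilla[i], apes$orangutan[i])
    calls <- calls[!is.na(calls)]
    if (length(calls) < 2) next
    tab <- table(calls)
    top <- names(tab)[which.max(tab)]
    if (max(tab) < 2) next
    if (top %in% c(variants$ref_allele[i], variants$alt_allele[i]))
      anc[i] <- top
  }
  ok <- !is.na(anc)
  list(ancestral = data.frame(snp_id = variants$snp_id[ok],
                              ancestral_allele = anc[ok],
                              stringsAsFactors = FALSE),
       excluded = variants$snp_id[!ok])
}

#' Merge genotype panels
#'
#' Intersects datasets on snp id (after strand-ambiguous removal),
#' harmonizes alleles by complementing alternate-allele counts where
#' ref/alt are swapped relative to the first panel, drops SNPs whose
#' allele pairs conflict, and stacks individuals.
#'
#' @param ... two or more [geno_matrix()] objects.
#' @return list with `geno` (merged) and `report` (data frame of
#'   dropped snp ids with reason; count of flipped SNPs per panel).
#' @export
merge_panels <- function(...) {
  panels <- list(...)
  stopifnot(length(panels) >= 2)
  panels <- lapply(panels, drop_ambiguous)
  common <- Reduce(intersect, lapply(panels, function(p) p$variants$snp_id))
  if (length(common) == 0) stop("no overlapping SNPs between panels")
  base <- subset_geno(panels[[1]],
                      snp = match(common, panels[[1]]$variants$snp_id))
  vt <- base$variants
  conflict <- rep(FALSE, length(common))
  flipped <- integer(length(panels))
  pieces <- list(base$calls)
  sheets <- list(base$samples)
  for (p in seq_along(panels)[-1]) {
    gm <- subset_geno(panels[[p]],
                      snp = match(common, panels[[p]]$variants$snp_id))
    same <- gm$variants$ref_allele == vt$ref_allele &
            gm$variants$alt_allele == vt$alt_allele
    swap <- gm$variants$ref_allele == vt$alt_allele &
            gm$variants$alt_allele == vt$ref_allele
    conflict <- conflict | (!same & !swap)
    calls <- gm$calls
    if (any(swap)) {
      pl <- ploidy_matrix(gm)
      calls[, swap] <- pl[, swap, drop = FALSE] - calls[, swap, drop = FALSE]
    }
    flipped[p] <- sum(swap)
    pieces[[p]] <- calls
    sheets[[p]] <- gm$samples
  }
  keep <- !conflict
  calls <- do.call(rbind, lapply(pieces, function(x) x[, keep, drop = FALSE]))
  sheet <- do.call(rbind, sheets)
  rownames(sheet) <- NULL
  class(sheet) <- c("sample_sheet", "data.frame")
  vt2 <- vt[keep, , drop = FALSE]
  rownames(vt2) <- NULL
  list(geno = geno_matrix(calls, vt2, sheet),
       report = list(dropped_conflicting = common[conflict],
                     flipped_per_panel = flipped))
}

# evaluate `code` under a temporary RNG state seeded with `seed`
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  eval.parent(substitute(code))
}
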