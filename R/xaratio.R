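#' Autosomal surrogate segments for the X
#'
#' Builds the nine autosomal segments used as X-comparable surrogates:
#' chromosomes 1-7 restricted to their first 180 cM, chromosomes 10 and
#' 12 whole (they are already approximately X-length), plus the X
#' itself. With `strict = TRUE` all nine autosomes are trimmed to
#' `[0, 180)` cM; a chromosome shorter than the trim length is kept whole
#' with a warning.
#'
#' @param variants a [variant_table()] covering chromosomes 1-7, 10, 12
#'   and X.
#' @param trim_cM trim length in cM (default 180, the X genetic length).
#' @param strict trim chromosomes 10 and 12 as well (default `FALSE`).
#' @return data frame: chrom, start_cM, end_cM (NA = whole), is_x.
#' @export
build_surrogates <- function(variants, trim_cM = 180, strict = FALSE) {
  need <- c(as.character(1:7), "10", "12", "X")
  have <- unique(variants$chrom)
  if (!all(need %in% have))
    stop("variant table lacks chromosome(s): ",
         paste(setdiff(need, have), collapse = ", "))
  trim_set <- if (strict) c(as.character(1:7), "10", "12")
              else as.character(1:7)
  specs <- lapply(setdiff(need, "X"), function(ch) {
    len <- max(variants$pos_cM[variants$chrom == ch])
    if (ch %in% trim_set) {
      if (len < trim_cM) {
        warning("chromosome ", ch, " is shorter than ", trim_cM,
                " cM; kept whole")
        data.frame(chrom = ch, start_cM = 0, end_cM = NA_real_)
      } else data.frame(chrom = ch, start_cM = 0, end_cM = trim_cM)
    } else data.frame(chrom = ch, start_cM = 0, end_cM = NA_real_)
  })
  out <- do.call(rbind, specs)
  out <- rbind(out, data.frame(chrom = "X", start_cM = 0, end_cM = NA_real_))
  out$is_x <- out$chrom == "X"
  out
}

segment_snps <- function(variants, spec_row) {
  sel <- variants$chrom == spec_row$chrom &
    variants$pos_cM >= spec_row$start_cM
  if (!is.na(spec_row$end_cM)) sel <- sel & variants$pos_cM < spec_row$end_cM
  which(sel)
}

#' Down-sample autosomal SNPs to the X count
#'
#' Randomly reduces each autosomal surrogate's SNP set to exactly the
#' number of SNPs on the X, equalizing resolution across segments. A
#' segment with fewer SNPs than the X keeps them all, with a warning.
#'
#' @param segment_snp_ids list of character vectors of snp ids, one per
#'   autosomal segment.
#' @param x_snp_count number of SNPs on the X.
#' @param seed integer seed.
#' @return list of down-sampled snp-id vectors (input order preserved).
#' @export
downsample_to_x <- function(segment_snp_ids, x_snp_count, seed) {
  with_seed(seed, {
    out <- lapply(segment_snp_ids, function(ids) {
      if (length(ids) <= x_snp_count) {
        if (length(ids) < x_snp_count)
          warning("segment has fewer SNPs (", length(ids),
                  ") than the X (", x_snp_count, "); kept all")
        ids
      } else sort(sample(ids, x_snp_count))
    })
  })
  out
}

#' X/autosome ancestry ratios
#'
#' The sex-bias procedure: run supervised ancestry estimation separately
#' on each of the nine X-length autosomal surrogates and on the X
#' (males haploid), average the fractions over the target individuals,
#' form the X-over-autosome ratio per ancestry against each surrogate
#' independently and average the nine ratios, and attach a bootstrap SD
#' from resampling individuals. Ancestries whose point estimate is below
#' `min_ancestry` on either the autosomal or the X side are reported but
#' flagged `not-evaluated` (a tiny fraction can vanish from a single
#' chromosome by chance, which makes its ratio wild).
#'
#' @param gm a [geno_matrix()] with chromosomes 1-7, 10, 12 and X.
#' @param f_panels K x M matrix of supervised source frequencies for all
#'   SNPs of `gm`, rows named by ancestry.
#' @param target_ids individuals (default: everyone in `gm`) whose mean
#'   fractions enter the ratio.
#' @param min_ancestry evaluation gate on the mean fraction
#'   (default 0.02).
#' @param n_boot bootstrap resamples of individuals (default 100).
#' @param seed integer seed (SNP down-sampling and bootstrap).
#' @param strict trim chromosomes 10 and 12 too (see
#'   [build_surrogates()]).
#' @param tol,max_iter EM controls passed to [supervised_q()].
#' @return object of class `xa_ratio`: data frame with per-ancestry X
#'   mean, mean autosomal fraction, mean-of-ratios `ratio`, ratio of
#'   means `ratio_of_means`, bootstrap mean and SD, flag; attributes
#'   carry the per-segment fractions and `n_boot`.
#' @export
xa_ratios <- function(gm, f_panels, target_ids = gm$samples$individual_id,
                      min_ancestry = 0.02, n_boot = 100, seed = 1,
                      strict = FALSE, tol = 1e-5, max_iter = 500) {
  if (length(target_ids) < 10)
    stop("need at least 10 target individuals")
  if (is.null(rownames(f_panels))) stop("f_panels must have ancestry rownames")
  specs <- build_surrogates(gm$variants, strict = strict)
  x_snps <- segment_snps(gm$variants, specs[specs$is_x, ])
  aut_specs <- specs[!specs$is_x, ]
  aut_snp_ids <- lapply(seq_len(nrow(aut_specs)), function(r)
    gm$variants$snp_id[segment_snps(gm$variants, aut_specs[r, ])])
  aut_snp_ids <- downsample_to_x(aut_snp_ids, length(x_snps), seed)

  rows <- match(target_ids, gm$samples$individual_id)
  if (anyNA(rows)) stop("unknown target individual id(s)")
  K <- nrow(f_panels)
  segments <- c(lapply(aut_snp_ids, function(ids)
    match(ids, gm$variants$snp_id)), list(x_snps))
  seg_names <- c(aut_specs$chrom, "X")

  # per-segment supervised Q for the target individuals
  q_seg <- array(NA_real_, c(length(rows), K, length(segments)),
                 dimnames = list(target_ids, rownames(f_panels), seg_names))
  for (s in seq_along(segments)) {
    sub <- subset_geno(gm, ind = rows, snp = segments[[s]])
    fit <- supervised_q(sub, f_panels[, segments[[s]], drop = FALSE],
                        tol = tol, max_iter = max_iter,
                        track_loglik = FALSE)
    q_seg[, , s] <- fit$Q
  }

  n_aut <- length(segments) - 1
  stat_from <- function(idx) {
    means <- apply(q_seg[idx, , , drop = FALSE], c(2, 3), mean)
    x_mean <- means[, n_aut + 1]
    a_means <- means[, seq_len(n_aut), drop = FALSE]
    ratio_each <- x_mean / a_means  # recycles x_mean down columns
    list(x = x_mean, a = rowMeans(a_means),
         ratio = rowMeans(ratio_each),
         ratio_of_means = x_mean / rowMeans(a_means))
  }
  pt <- stat_from(seq_along(rows))
  boot <- with_seed(seed + 1L, {
    replicate(n_boot, {
      st <- stat_from(sample(seq_along(rows), replace = TRUE))
      st$ratio
    })
  })
  if (is.null(dim(boot))) boot <- matrix(boot, nrow = 1)
  flag <- ifelse(pt$x >= min_ancestry & pt$a >= min_ancestry,
                 "evaluated", "not-evaluated")
  out <- data.frame(ancestry = rownames(f_panels),
                    x_mean = pt$x, autosome_mean = pt$a,
                    ratio = pt$ratio, ratio_of_means = pt$ratio_of_means,
                    boot_mean = rowMeans(boot),
                    boot_sd = apply(boot, 1, sd),
                    flag = flag, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("xa_ratio", "data.frame"),
            segment_fractions = q_seg, n_boot = n_boot, seed = seed)
}

#' Invert an X/A ratio to sex-specific contributions
#'
#' Interpretation layer: under a single founding pulse with female share
#' `p_f` of the source's contribution, the autosomal fraction is
#' proportional to `(s_f + s_m) / 2` and the X fraction to
#' `(2 s_f + s_m) / 3`, so the X/A ratio equals `(2/3)(1 + p_f)` and
#' `p_f = 3 r / 2 - 1`. Ratios below the all-male floor of 2/3 are
#' flagged (consistent with ongoing male-biased gene flow rather than a
#' single pulse); ratios above the all-female ceiling of 4/3 likewise.
#'
#' @param r positive X/A ratio (vectorized).
#' @return data frame: ratio, p_female (NA outside `[2/3, 4/3]`), flag in
#'   `{in-range, below-single-pulse-floor, above-single-pulse-ceiling}`.
#' @export
infer_sex_fractions <- function(r) {
  if (any(r <= 0)) stop("ratio must be positive")
  p_f <- 3 * r / 2 - 1
  flag <- ifelse(r < 2 / 3, "below-single-pulse-floor",
          ifelse(r > 4 / 3, "above-single-pulse-ceiling", "in-range"))
  data.frame(ratio = r,
             p_female = ifelse(flag == "in-range", p_f, NA_real_),
             flag = flag, stringsAsFactors = FALSE)
}

#' Cohort filter on typical ancestry profiles
#'
#' Keeps individuals whose ancestry fractions lie within plus or minus
#' one standard deviation of the group mean for every ancestry - a way
#' to form a homogeneous "meta-group" that damps the signal of very
#' recent admixture before tract-based dating.
#'
#' @param q n x K ancestry-fraction matrix with individual rownames.
#' @param n_sd width of the band in SDs (default 1).
#' @return character vector of kept individual ids.
#' @export
meta_group_filter <- function(q, n_sd = 1) {
  mu <- colMeans(q)
  s <- apply(q, 2, sd)
  ok <- rep(TRUE, nrow(q))
  for (k in seq_len(ncol(q)))
    ok <- ok & q[, k] >= mu[k] - n_sd * s[k] & q[, k] <= mu[k] + n_sd * s[k]
  rownames(q)[ok]
}
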