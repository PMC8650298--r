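#' Local-ancestry tract set
#'
#' Long-format table of phased local-ancestry segments in genetic-map
#' coordinates: columns `individual`, `hap` (1/2), `chrom`, `start_cM`,
#' `end_cM` (half-open interval), `ancestry`. Per haplotype per
#' chromosome the segments must be sorted, non-overlapping and
#' contiguous.
#'
#' @param df data frame with the six columns above.
#' @return the validated data frame with class `tract_set`.
#' @export
tract_set <- function(df) {
  need <- c("individual", "hap", "chrom", "start_cM", "end_cM", "ancestry")
  if (!all(need %in% names(df))) stop("tract table lacks required columns")
  if (any(df$end_cM <= df$start_cM)) stop("empty or inverted tract")
  key <- paste(df$individual, df$hap, df$chrom, sep = "|")
  for (idx in split(seq_len(nrow(df)), key)) {
    s <- df$start_cM[idx]; e <- df$end_cM[idx]
    if (is.unsorted(s, strictly = TRUE) ||
        any(abs(e[-length(e)] - s[-1]) > 1e-9))
      stop("tracts not contiguous for ", key[idx[1]])
  }
  class(df) <- c("tract_set", "data.frame")
  df
}

#' Read/write tract tables
#'
#' Tab-separated exchange format for [tract_set()] tables.
#' @param path file path.
#' @return `read_tracts`: a [tract_set()]; `write_tracts`: `path`.
#' @export
read_tracts <- function(path) {
  tract_set(read.table(path, header = TRUE, sep = "\t",
                       stringsAsFactors = FALSE,
                       colClasses = c(chrom = "character")))
}

#' @rdname read_tracts
#' @param tracts a [tract_set()].
#' @export
write_tracts <- function(tracts, path) {
  write.table(tracts, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Window-based local-ancestry calling
#'
#' A deliberately simple local-ancestry caller so the dating pipeline can
#' run from genotypes: each phased haplotype is cut into fixed-width
#' genetic windows and each window is assigned the source maximizing the
#' window log-likelihood `sum_j log(f_kj)` or `log(1 - f_kj)` over its
#' SNPs. Optional majority smoothing over 3-window neighborhoods is
#' applied `smoothing_passes` times, ties in the argmax break by source
#' order (flagged low-confidence), windows without SNPs inherit the left
#' neighbor's label, and adjacent same-label windows merge into tracts.
#'
#' @param haps haplotype allele matrix (rows = haplotypes, 0/1, NA where
#'   a haplotype does not exist, e.g. male X).
#' @param hap_index data frame `individual`, `hap` describing the rows.
#' @param variants a [variant_table()] for the columns.
#' @param f_panels K x M source frequencies, rows named by ancestry.
#' @param window_cM window width (default 1 cM).
#' @param smoothing_passes majority-smoothing passes (default 1).
#' @param chrom_lengths optional named cM lengths (default: max SNP
#'   position per chromosome).
#' @return a [tract_set()].
#' @export
call_local_ancestry <- function(haps, hap_index, variants, f_panels,
                                window_cM = 1, smoothing_passes = 1,
                                chrom_lengths = NULL) {
  f <- clamp_freq(as.matrix(f_panels))
  K <- nrow(f)
  lf1 <- log(f); lf0 <- log1p(-f)
  out <- list()
  for (ch in unique(variants$chrom)) {
    cols <- which(variants$chrom == ch)
    pos <- variants$pos_cM[cols]
    len <- if (!is.null(chrom_lengths)) chrom_lengths[[ch]] else max(pos)
    brk <- seq(0, len + window_cM, by = window_cM)
    win_of <- findInterval(pos, brk)
    nwin <- max(win_of)
    for (r in seq_len(nrow(haps))) {
      al <- haps[r, cols]
      if (all(is.na(al))) next
      # window log-likelihood per source
      obs <- !is.na(al)
      contrib <- lf1[, cols, drop = FALSE] * rep(al == 1L & obs, each = K) +
                 lf0[, cols, drop = FALSE] * rep(al == 0L & obs, each = K)
      sums <- rowsum(t(contrib), win_of)        # windows present x K
      ll <- matrix(0, K, nwin)
      ll[, as.integer(rownames(sums))] <- t(sums)
      lab <- apply(ll, 2, which.max)
      empty <- tabulate(win_of[obs], nwin) == 0
      for (w in which(empty)) lab[w] <- if (w > 1) lab[w - 1] else lab[which(!empty)[1]]
      for (pass in seq_len(smoothing_passes)) {
        if (nwin >= 3) {
          sm <- lab
          for (w in 2:(nwin - 1)) {
            tri <- lab[(w - 1):(w + 1)]
            tab <- tabulate(tri, K)
            if (max(tab) >= 2) sm[w] <- which.max(tab)
          }
          lab <- sm
        }
      }
      # merge adjacent same-label windows
      run_end <- c(which(diff(lab) != 0), nwin)
      run_start <- c(1, head(run_end, -1) + 1)
      out[[length(out) + 1]] <- data.frame(
        individual = hap_index$individual[r], hap = hap_index$hap[r],
        chrom = ch,
        start_cM = pmin(brk[run_start], len),
        end_cM = pmin(brk[run_end + 1], len),
        ancestry = rownames(f)[lab[run_start]],
        stringsAsFactors = FALSE)
    }
  }
  tr <- do.call(rbind, out)
  tr <- tr[tr$end_cM > tr$start_cM, , drop = FALSE]
  rownames(tr) <- NULL
  tract_set(tr)
}

# Sample tract ancestries on a regular grid and accumulate ordered-pair
# counts per grid lag, per individual (bootstrap unit).
lag_count_table <- function(tracts, labels, grid_cM, max_lag) {
  K <- length(labels)
  lab_int <- match(tracts$ancestry, labels)
  if (anyNA(lab_int)) stop("tract ancestry not in label set")
  inds <- unique(tracts$individual)
  key <- paste(tracts$individual, tracts$hap, tracts$chrom, sep = "|")
  per_ind <- lapply(inds, function(x) {
    list(joint = array(0L, c(K, K, max_lag)), marg = integer(K), total = 0L)
  })
  names(per_ind) <- inds
  for (idx in split(seq_len(nrow(tracts)), key)) {
    ind <- tracts$individual[idx[1]]
    s <- tracts$start_cM[idx]
    e_last <- tracts$end_cM[idx[length(idx)]]
    pts <- seq(s[1], e_last - 1e-9, by = grid_cM)
    g <- lab_int[idx][findInterval(pts, s)]
    acc <- per_ind[[ind]]
    acc$joint <- acc$joint + .lag_pair_counts(g, K, max_lag)
    acc$marg <- acc$marg + tabulate(g, K)
    acc$total <- acc$total + length(g)
    per_ind[[ind]] <- acc
  }
  list(per_ind = per_ind, K = K, labels = labels, grid_cM = grid_cM)
}

curve_from_counts <- function(counts, which_ind, pair, bin_cM, d_min, d_max,
                              normalize = c("product", "covariance")) {
  normalize <- match.arg(normalize)
  labels <- counts$labels
  a <- match(pair[1], labels); b <- match(pair[2], labels)
  if (is.na(a) || is.na(b))
    stop("ancestry absent from tracts: ", pair[is.na(c(a, b))][1])
  grid <- counts$grid_cM
  max_lag <- dim(counts$per_ind[[1]]$joint)[3]
  joint <- array(0, dim(counts$per_ind[[1]]$joint))
  pairs_tot <- matrix(0, length(labels)^2, max_lag)
  marg <- numeric(length(labels)); total <- 0
  for (ind in which_ind) {
    acc <- counts$per_ind[[ind]]
    joint <- joint + acc$joint
    marg <- marg + acc$marg
    total <- total + acc$total
  }
  pa <- marg[a] / total; pb <- marg[b] / total
  if (pa == 0 || pb == 0)
    stop("ancestry absent from tracts: ", pair[c(pa, pb) == 0][1])
  lag_d <- seq_len(max_lag) * grid
  use <- lag_d >= d_min & lag_d <= d_max
  bins <- seq(d_min, d_max, by = bin_cM)
  bin_of <- findInterval(lag_d, bins, rightmost.closed = TRUE)
  n_ab <- vapply(seq_len(max_lag), function(l) sum(joint[a, b, l]), 0)
  n_all <- vapply(seq_len(max_lag), function(l) sum(joint[, , l]), 0)
  mids <- vals <- npairs <- numeric(0)
  for (bn in unique(bin_of[use])) {
    sel <- use & bin_of == bn
    tot <- sum(n_all[sel])
    if (tot == 0) next
    p_ab <- sum(n_ab[sel]) / tot
    v <- if (normalize == "product") p_ab / (pa * pb) else p_ab - pa * pb
    mids <- c(mids, mean(lag_d[sel]))
    vals <- c(vals, v)
    npairs <- c(npairs, tot)
  }
  structure(list(pair = pair, bins_cM = mids, values = vals,
                 pair_counts = npairs, p_a = pa, p_b = pb,
                 normalize = normalize),
            class = "coancestry_curve")
}

#' Pairwise coancestry curve
#'
#' Estimates, as a function of genetic distance `d`, the joint
#' probability that two positions on the same haplotype carry the ordered
#' ancestry pair `(A, B)`, relative to the product of the marginal
#' ancestry proportions. After an admixture pulse `g` generations ago the
#' curve approaches its asymptote like `exp(-g d)` (d in Morgans), which
#' is what [fit_exponential()] exploits. Positions are sampled on a
#' regular genetic grid over the tracts and all intra-haplotype pairs
#' with `d_min <= d <= d_max` are binned.
#'
#' @param tracts a [tract_set()].
#' @param pair length-2 character vector `(A, B)` of ancestry labels.
#' @param bin_cM distance bin width (default 0.5).
#' @param d_min,d_max distance range in cM (defaults 0.5 and 30;
#'   distances below ~0.5 cM carry background LD).
#' @param grid_cM grid spacing for sampling tract labels (default 0.2).
#' @param normalize `"product"` (relative rate, default) or
#'   `"covariance"`.
#' @return object of class `coancestry_curve`: bins (cM midpoints),
#'   values, pair counts, marginal proportions.
#' @export
coancestry_curve <- function(tracts, pair, bin_cM = 0.5, d_min = 0.5,
                             d_max = 30, grid_cM = 0.2,
                             normalize = c("product", "covariance")) {
  labels <- sort(unique(tracts$ancestry))
  max_lag <- ceiling(d_max / grid_cM)
  counts <- lag_count_table(tracts, labels, grid_cM, max_lag)
  curve_from_counts(counts, unique(tracts$individual), pair, bin_cM,
                    d_min, d_max, normalize)
}

#' @export
print.coancestry_curve <- function(x, ...) {
  cat("coancestry_curve", paste0("(", x$pair[1], ",", x$pair[2], "):"),
      length(x$bins_cM), "bins,",
      sprintf("marginals %.3f x %.3f\n", x$p_a, x$p_b))
  invisible(x)
}

#' Exponential decay fit of a coancestry curve
#'
#' Weighted least squares of `value(d) = a exp(-lambda u(d)) + c` with
#' weights the per-bin pair counts, where `u(d)` is the per-meiosis
#' log-survival distance. With `map_function = "haldane"` (default),
#' `u(d) = -log(1 - r(d))` with `r(d) = (1 - exp(-2 d / 100)) / 2` the
#' Haldane recombination fraction: the probability that two loci stay on
#' the same parental haplotype through one meiosis is `1 - r`, so a pair
#' decorrelates over `lambda` meioses like `exp(-lambda u)`. With
#' `map_function = "linear"`, `u(d) = d / 100` (the small-distance
#' approximation most ancestry-LD software uses; it underestimates
#' `lambda` slightly when fitting out to tens of cM). `lambda` counts
#' ancestry-switching meioses; because the very first post-admixture
#' meiosis recombines two same-ancestry founder chromosomes and cannot
#' switch ancestry, the reported date in generations is
#' `lambda + meiosis_offset` with `meiosis_offset = 1` by default (set 0
#' to report the raw rate). For fixed `lambda` the model is linear in
#' `(a, c)`, so `lambda` is profiled by Brent search over several
#' brackets and the best weighted SSE wins.
#'
#' @param curve a [coancestry_curve()].
#' @param weights per-bin weights (default the curve's pair counts).
#' @param lambda_starts centers of the search brackets (default
#'   `c(5, 20, 50, 100, 200)`).
#' @param lambda_max upper box bound (default 600); an estimate at a box
#'   bound is flagged unreliable.
#' @param map_function `"haldane"` (default) or `"linear"` distance
#'   coordinate.
#' @param meiosis_offset added to `lambda` when reporting generations
#'   (default 1).
#' @return object of class `decay_fit`: `a`, `lambda`, `c`,
#'   `generations` (= lambda + meiosis_offset), `years`, `sse`, `flag`
#'   in `{ok, at-bound, flat}`, plus the fit settings.
#' @export
fit_exponential <- function(curve, weights = curve$pair_counts,
                            lambda_starts = c(5, 20, 50, 100, 200),
                            lambda_max = 600,
                            map_function = c("haldane", "linear"),
                            meiosis_offset = 1) {
  map_function <- match.arg(map_function)
  d <- curve$bins_cM; y <- curve$values
  ok <- is.finite(y) & weights > 0
  d <- d[ok]; y <- y[ok]; w <- weights[ok]
  if (length(d) < 10) stop("need at least 10 usable bins")
  u <- if (map_function == "haldane") -log1p(-(1 - exp(-2 * d / 100)) / 2)
       else d / 100
  wls <- function(lambda) {
    x <- exp(-lambda * u)
    X <- cbind(x, 1)
    fit <- stats::lm.wfit(X, y, w)
    sse <- sum(w * fit$residuals^2)
    list(sse = sse, a = fit$coefficients[1], c = fit$coefficients[2])
  }
  lo_all <- 1e-3
  best <- NULL
  brackets <- cbind(c(lo_all, head(lambda_starts, -1)),
                    c(lambda_starts[-1], lambda_max))
  for (r in seq_len(nrow(brackets))) {
    opt <- optimize(function(l) wls(l)$sse, brackets[r, ])
    if (is.null(best) || opt$objective < best$objective) best <- opt
  }
  sol <- wls(best$minimum)
  lambda <- best$minimum
  flag <- "ok"
  level <- weighted.mean(y, w)
  if (abs(sol$a) < 0.02 * max(abs(level), 0.1)) flag <- "flat"
  else if (lambda > lambda_max * 0.99 || lambda < lo_all * 2) flag <- "at-bound"
  gens <- if (flag == "flat") NA_real_ else lambda + meiosis_offset
  structure(list(a = unname(sol$a), lambda = lambda, c = unname(sol$c),
                 generations = gens,
                 years = if (is.na(gens)) NA_real_
                         else generations_to_years(gens),
                 sse = best$objective, n_bins = length(d), flag = flag,
                 map_function = map_function,
                 meiosis_offset = meiosis_offset),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf(
    "decay_fit: a=%.4g lambda=%.2f c=%.4g (%s)\n", x$a, x$lambda, x$c, x$flag))
  if (!is.na(x$generations))
    cat(sprintf("  date: %.1f generations ~ %.0f years\n",
                x$generations, x$years))
  invisible(x)
}

#' Bootstrap admixture-date confidence interval
#'
#' Resamples individuals with replacement `n_boot` times, rebuilds the
#' coancestry curve from the resampled tract sets and refits the decay,
#' returning the point fit with a percentile confidence interval on the
#' date.
#'
#' @inheritParams coancestry_curve
#' @param n_boot bootstrap resamples (default 100).
#' @param seed integer seed.
#' @param conf confidence level (default 0.95, percentile CI).
#' @param ... passed on to [fit_exponential()].
#' @return a `decay_fit` with extra fields `ci_lower`, `ci_upper`
#'   (generations), `ci_years`, `boot_generations`, `n_boot`.
#' @export
bootstrap_dates <- function(tracts, pair, n_boot = 100, seed = 1,
                            bin_cM = 0.5, d_min = 0.5, d_max = 30,
                            grid_cM = 0.2, conf = 0.95, ...) {
  labels <- sort(unique(tracts$ancestry))
  max_lag <- ceiling(d_max / grid_cM)
  counts <- lag_count_table(tracts, labels, grid_cM, max_lag)
  inds <- unique(tracts$individual)
  point <- fit_exponential(curve_from_counts(counts, inds, pair, bin_cM,
                                             d_min, d_max), ...)
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      take <- sample(inds, replace = TRUE)
      cv <- tryCatch(curve_from_counts(counts, take, pair, bin_cM,
                                       d_min, d_max),
                     error = function(e) NULL)
      if (is.null(cv)) return(NA_real_)
      fit_exponential(cv, ...)$generations
    }, 0)
  })
  alpha <- (1 - conf) / 2
  ci <- quantile(boots, c(alpha, 1 - alpha), na.rm = TRUE, names = FALSE)
  point$ci_lower <- ci[1]
  point$ci_upper <- ci[2]
  point$ci_years <- generations_to_years(ci)
  point$boot_generations <- boots
  point$n_boot <- n_boot
  point
}

#' Convert generations to years
#'
#' @param g generations (vectorized).
#' @param years_per_generation generation time (default 30 years).
#' @return years.
#' @export
generations_to_years <- function(g, years_per_generation = 30) {
  g * years_per_generation
}

#' Classify coancestry-curve shape
#'
#' Diagnostic for spurious or multi-pulse signals: a clean single pulse
#' gives a monotone exponential approach to the asymptote
#' (`classic-decay`); a hump or dip (`non-monotone`) suggests multiple
#' admixture events at different times; `flat` means no usable decay.
#' The curve is smoothed with a short running mean and classified by the
#' sign pattern of its slopes.
#'
#' @param curve a [coancestry_curve()].
#' @param flat_tol relative amplitude below which the curve counts as
#'   flat (default 0.02 of the mean level, with an absolute floor).
#' @return one of `"classic-decay"`, `"non-monotone"`, `"flat"`.
#' @export
diagnose_curve_shape <- function(curve, flat_tol = 0.02) {
  y <- curve$values
  k <- min(5, length(y))
  sm <- stats::filter(y, rep(1 / k, k), sides = 2)
  sm <- as.numeric(sm[!is.na(sm)])
  if (length(sm) < 3) sm <- y
  rng <- diff(range(sm))
  if (rng < max(flat_tol * abs(mean(sm)), 1e-8)) return("flat")
  slopes <- diff(sm)
  eps <- 0.02 * rng
  up <- any(slopes > eps); down <- any(slopes < -eps)
  if (up && down) "non-monotone" else "classic-decay"
}
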