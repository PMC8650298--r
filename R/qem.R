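#' Admixture model log-likelihood
#'
#' Log-likelihood of ancestry fractions `q` given source allele
#' frequencies, genotypes and per-call ploidy under the standard
#' admixture model: for SNP `j` with ploidy `c` and alternate count `g`,
#' the contribution is `g log(sum_k q_k f_kj) + (c - g) log(sum_k q_k (1
#' - f_kj))`. Missing genotypes are skipped; frequencies are clamped
#' away from 0 and 1 (at 1e-6) so the value is always finite.
#'
#' @param q length-K simplex vector, or an n x K matrix (one row per
#'   individual).
#' @param f K x M source allele-frequency matrix.
#' @param g length-M genotype vector, or n x M matrix, alternate-allele
#'   counts with `NA` missing.
#' @param ploidy matching vector/matrix of ploidies (2, or 1 on male X).
#' @return total log-likelihood (summed over individuals if matrices).
#' @export
admix_loglik <- function(q, f, g, ploidy) {
  if (is.null(dim(g))) g <- matrix(g, nrow = 1)
  if (is.null(dim(q))) q <- matrix(q, nrow = 1)
  if (is.null(dim(ploidy))) ploidy <- matrix(ploidy, nrow = 1)
  f <- clamp_freq(f)
  p <- q %*% f
  miss <- is.na(g)
  g[miss] <- 0L
  ploidy[miss] <- 0L
  sum(g * log(p) + (ploidy - g) * log1p(-p))
}

clamp_freq <- function(f, eps = 1e-6) pmin(pmax(f, eps), 1 - eps)

em_q_update <- function(q, f, g, cpl) {
  # one EM sweep on Q with F fixed; g, cpl have 0 at missing cells.
  # qnew_ik  proportional to  q_ik [ (g/p) f_k' + ((c-g)/(1-p)) (1-f_k)' ]
  p <- q %*% f
  qnew <- q * ((g / p) %*% t(f) + ((cpl - g) / (1 - p)) %*% t(1 - f))
  qnew <- qnew / pmax(rowSums(cpl), .Machine$double.eps)
  # exact simplex renormalization (guards the log-likelihood's log1p)
  qnew / rowSums(qnew)
}

#' Supervised ancestry-fraction estimation
#'
#' EM estimation of per-individual ancestry fractions with the source
#' allele frequencies held fixed (supervised admixture). Each allele copy
#' is assigned a responsibility over sources and the fractions are
#' re-normalized on the simplex; iteration stops when no coordinate
#' moves more than `tol`. The log-likelihood is non-decreasing across
#' iterations. Male X genotypes enter with ploidy 1.
#'
#' @param gm a [geno_matrix()], or a plain genotype matrix.
#' @param f_panel K x M matrix of fixed source frequencies, rows named by
#'   source; columns must match the SNP columns of `gm`.
#' @param ploidy optional ploidy matrix (derived from `gm` when it is a
#'   [geno_matrix()]; defaults to 2 otherwise).
#' @param tol convergence tolerance on max |delta q| (default 1e-6).
#' @param max_iter iteration cap (default 2000).
#' @param q0 optional n x K start matrix (default uniform).
#' @param track_loglik evaluate the log-likelihood every iteration
#'   (default `TRUE`; turning it off speeds up large fits, and the final
#'   log-likelihood is still reported).
#' @return object of class `admix_fit`: list with `Q` (n x K), `loglik`,
#'   `loglik_trace`, `iterations`, `converged`.
#' @export
supervised_q <- function(gm, f_panel, ploidy = NULL, tol = 1e-6,
                         max_iter = 2000, q0 = NULL, track_loglik = TRUE) {
  g <- if (inherits(gm, "geno_matrix")) gm$calls else as.matrix(gm)
  if (is.null(ploidy))
    ploidy <- if (inherits(gm, "geno_matrix")) ploidy_matrix(gm)
              else matrix(2L, nrow(g), ncol(g))
  f <- clamp_freq(as.matrix(f_panel))
  K <- nrow(f)
  if (K < 2) stop("need at least two sources")
  if (ncol(f) != ncol(g)) stop("panel and genotypes disagree on SNP count")
  n <- nrow(g)
  miss <- is.na(g)
  g2 <- g; g2[miss] <- 0L
  cpl <- ploidy; cpl[miss] <- 0L
  storage.mode(g2) <- "double"; storage.mode(cpl) <- "double"
  q <- if (is.null(q0)) matrix(1 / K, n, K) else as.matrix(q0)
  ll_trace <- numeric(0)
  converged <- FALSE
  it <- 0
  ll_quick <- function(q) {
    p <- q %*% f
    sum(g2 * log(p) + (cpl - g2) * log1p(-p))
  }
  while (it < max_iter) {
    it <- it + 1
    qnew <- em_q_update(q, f, g2, cpl)
    if (track_loglik) {
      ll_trace[it] <- ll_quick(qnew)
      if (!is.finite(ll_trace[it])) stop("non-finite likelihood")
    }
    delta <- max(abs(qnew - q))
    q <- qnew
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!track_loglik) {
    ll_trace <- ll_quick(q)
    if (!is.finite(ll_trace)) stop("non-finite likelihood")
  }
  dimnames(q) <- list(rownames(g), rownames(f))
  structure(list(Q = q, F = f, loglik = ll_trace[length(ll_trace)],
                 loglik_trace = ll_trace, iterations = it,
                 converged = converged, supervised = TRUE),
            class = "admix_fit")
}

#' Unsupervised admixture estimation
#'
#' Joint EM estimation of ancestry fractions Q and source frequencies F
#' (FRAPPE-style alternating updates), replicated from random starts; the
#' replicate with the best log-likelihood is returned along with the full
#' replicate likelihood table. Source labels are arbitrary
#' ("label switching"): any alignment to external labels is left to the
#' caller.
#'
#' @param gm a [geno_matrix()] (LD-pruned markers recommended).
#' @param K number of clusters.
#' @param seed integer seed for the random starts.
#' @param replicates number of random restarts (default 3).
#' @param tol,max_iter EM controls (defaults 1e-6 on Q and F, 2000).
#' @return `admix_fit` with `Q`, `F`, `loglik`, `replicate_logliks`,
#'   `iterations`, `converged`, `seed`.
#' @export
unsupervised_qf <- function(gm, K, seed, replicates = 3, tol = 1e-6,
                            max_iter = 2000) {
  g <- if (inherits(gm, "geno_matrix")) gm$calls else as.matrix(gm)
  ploidy <- if (inherits(gm, "geno_matrix")) ploidy_matrix(gm)
            else matrix(2L, nrow(g), ncol(g))
  n <- nrow(g); M <- ncol(g)
  if (K > n) warning("K exceeds the number of individuals")
  miss <- is.na(g)
  g2 <- g; g2[miss] <- 0L
  cpl <- ploidy; cpl[miss] <- 0L
  storage.mode(g2) <- "double"; storage.mode(cpl) <- "double"
  obs_freq <- colSums(g2) / pmax(colSums(cpl), 1)

  run_once <- function(rep_seed) {
    with_seed(rep_seed, {
      q <- matrix(stats::rgamma(n * K, 1), n, K)
      q <- q / rowSums(q)
      f <- clamp_freq(matrix(rep(obs_freq, each = K), K, M) *
                        matrix(runif(K * M, 0.5, 1.5), K, M))
    })
    if (K == 1) {
      q <- matrix(1, n, 1)
      f <- matrix(clamp_freq(obs_freq), 1, M)
      return(list(Q = q, F = f, loglik = admix_loglik(q, f, g, ploidy),
                  trace = numeric(0), iterations = 0L, converged = TRUE))
    }
    trace <- numeric(0); converged <- FALSE; it <- 0
    while (it < max_iter) {
      it <- it + 1
      p <- q %*% f
      a_term <- g2 / p
      r_term <- (cpl - g2) / (1 - p)
      fnew <- f
      for (k in seq_len(K)) {
        alt_kj <- colSums(a_term * q[, k]) * f[k, ]
        ref_kj <- colSums(r_term * q[, k]) * (1 - f[k, ])
        fnew[k, ] <- alt_kj / pmax(alt_kj + ref_kj, 1e-300)
      }
      fnew <- clamp_freq(fnew)
      qnew <- em_q_update(q, f, g2, cpl)  # responsibilities under current f
      delta <- max(max(abs(qnew - q)), max(abs(fnew - f)))
      q <- qnew; f <- fnew
      trace[it] <- admix_loglik(q, f, g, ploidy)
      if (delta < tol) { converged <- TRUE; break }
    }
    list(Q = q, F = f, loglik = trace[length(trace)], trace = trace,
         iterations = it, converged = converged)
  }

  rep_seeds <- seed + seq_len(replicates) - 1L
  fits <- lapply(rep_seeds, run_once)
  lls <- vapply(fits, `[[`, 0, "loglik")
  best <- fits[[which.max(lls)]]
  dimnames(best$Q) <- list(rownames(g), paste0("K", seq_len(K)))
  rownames(best$F) <- paste0("K", seq_len(K))
  structure(list(Q = best$Q, F = best$F, loglik = best$loglik,
                 loglik_trace = best$trace,
                 replicate_logliks = data.frame(seed = rep_seeds,
                                                loglik = lls),
                 iterations = best$iterations, converged = best$converged,
                 supervised = FALSE, seed = seed),
            class = "admix_fit")
}

#' @export
print.admix_fit <- function(x, ...) {
  cat("admix_fit:", nrow(x$Q), "individuals, K =", ncol(x$Q),
      if (isTRUE(x$supervised)) "(supervised)" else "(unsupervised)", "\n")
  cat("  loglik:", format(x$loglik), "; iterations:", x$iterations,
      "; converged:", x$converged, "\n")
  invisible(x)
}

#' Group-mean ancestry fractions
#'
#' Arithmetic mean of the Q matrix within groups (e.g. populations or
#' sampling sites), the quantity shown as per-population pie charts in
#' cluster analyses.
#'
#' @param fit an `admix_fit` (or a bare Q matrix).
#' @param sheet a [sample_sheet()] aligned with the rows of Q.
#' @param group_by column of `sheet` to group on (default `"population"`).
#' @return data frame: group, n, one column per source; rows sum to 1.
#' @export
cluster_mean_fractions <- function(fit, sheet, group_by = "population") {
  q <- if (inherits(fit, "admix_fit")) fit$Q else as.matrix(fit)
  groups <- sheet[[group_by]]
  stopifnot(length(groups) == nrow(q))
  out <- lapply(unique(groups), function(grp) {
    rows <- groups == grp
    data.frame(group = grp, n = sum(rows),
               t(colMeans(q[rows, , drop = FALSE])),
               check.names = FALSE, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Align unsupervised clusters to reference labels
#'
#' Greedy matching of estimated clusters to truth by correlation of the
#' source-frequency rows (used only in evaluation, never inside the
#' fitter).
#'
#' @param f_est,f_true K x M frequency matrices.
#' @return integer permutation: estimated cluster `i` corresponds to true
#'   source `perm[i]`.
#' @export
align_clusters <- function(f_est, f_true) {
  K <- nrow(f_est)
  cc <- cor(t(f_est), t(f_true))
  cc[!is.finite(cc)] <- -Inf
  perm <- integer(K)
  for (step in seq_len(K)) {
    m <- arrayInd(which.max(cc), dim(cc))
    perm[m[1]] <- m[2]
    cc[m[1], ] <- -Inf
    cc[, m[2]] <- -Inf
  }
  perm
}
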