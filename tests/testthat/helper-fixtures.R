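# Shared fixture builders: everything is generated in code at test time.

# a small diploid genotype container on two chromosomes (one autosome, X)
toy_geno <- function(n_ind = 6, n_aut = 8, n_x = 4, seed = 1,
                     sexes = rep(c("female", "male"), length.out = n_ind)) {
  set.seed(seed)
  M <- n_aut + n_x
  vt <- variant_table(
    snp_id = sprintf("s%02d", 1:M),
    chrom = c(rep("1", n_aut), rep("X", n_x)),
    pos_bp = c(seq_len(n_aut) * 1000L, seq_len(n_x) * 1000L),
    pos_cM = c(seq_len(n_aut) * 0.5, seq_len(n_x) * 0.5),
    ref_allele = rep("A", M), alt_allele = rep("G", M))
  sh <- sample_sheet(sprintf("i%02d", 1:n_ind), population = "P1",
                     genetic_sex = sexes)
  calls <- matrix(sample(0:2, n_ind * M, replace = TRUE), n_ind, M)
  male <- sh$genetic_sex == "male"
  calls[male, vt$chrom == "X"] <-
    sample(0:1, sum(male) * n_x, replace = TRUE)
  geno_matrix(calls, vt, sh)
}

# autosome-only genotype container from an explicit call matrix
geno_from_calls <- function(calls, ref = "A", alt = "G",
                            pop = "P1", site = pop) {
  dimnames(calls) <- NULL
  n <- nrow(calls); M <- ncol(calls)
  vt <- variant_table(sprintf("s%03d", 1:M), rep("1", M),
                      seq_len(M) * 1000L, seq_len(M) * 0.5,
                      rep_len(ref, M), rep_len(alt, M))
  sh <- sample_sheet(sprintf("i%03d", 1:n), population = rep_len(pop, n),
                     sampling_site = rep_len(site, n))
  geno_matrix(calls, vt, sh)
}

# independent exact Hardy-Weinberg oracle: direct closed-form enumeration
# over heterozygote counts with log-factorials
hwe_oracle <- function(naa, nab, nbb) {
  n <- naa + nab + nbb
  na <- 2 * naa + nab
  nb <- 2 * nbb + nab
  rare <- min(na, nb)
  hets <- seq(rare %% 2, rare, by = 2)
  logp <- vapply(hets, function(h) {
    hr <- (rare - h) / 2
    hc <- n - h - hr
    lgamma(n + 1) - lgamma(hr + 1) - lgamma(h + 1) - lgamma(hc + 1) +
      h * log(2) + lgamma(na + 1) + lgamma(nb + 1) - lgamma(2 * n + 1)
  }, 0)
  probs <- exp(logp - max(logp))
  probs <- probs / sum(probs)
  obs <- probs[match(nab, hets)]
  sum(probs[probs <= obs * (1 + 1e-9)])
}

# Hudson-style FST from two allele-frequency vectors (no sampling noise)
hudson_fst <- function(p1, p2) {
  num <- (p1 - p2)^2
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  sum(num) / sum(den)
}

# a tiny two-source single-pulse simulated dataset reused by tests
small_pulse_sim <- function(g = 10, frac_f = 0.25, frac_m = 0.25,
                            n_out = 120, n_snp_aut = 400, n_snp_x = 150,
                            fst = 0.3, seed = 9, pool = 400,
                            map = c("1" = 150, "X" = 130)) {
  sch <- single_pulse_schedule(g, frac_f, frac_m)
  nsnp <- round(map / sum(map) * (n_snp_aut + n_snp_x))
  vt <- make_map_variants(map, nsnp, seed)
  src <- make_source_freqs(nrow(vt), 2, fst, seed + 1,
                           labels = c("BASE", "PULSE"))
  co <- simulate_admixture(src, sch, n_out, map, seed + 2, pool_size = pool)
  em <- emit_genotypes(co, src, vt, seed + 3, haplotypes = TRUE)
  f <- src$freqs
  colnames(f) <- vt$snp_id
  list(schedule = sch, variants = vt, sources = src, cohort = co,
       geno = em$geno, haps = em$haps, hap_index = em$hap_index, f = f)
}
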