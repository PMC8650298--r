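#' Balding-Nichols source allele frequencies
#'
#' Draws per-source allele frequencies around shared ancestral
#' frequencies under the Balding-Nichols model: the frequency of source
#' `k` at a SNP with ancestral frequency `p` is
#' `Beta(p (1 - F) / F, (1 - p)(1 - F) / F)` with `F` the source's drift
#' parameter. Ancestral frequencies are uniform on `p_range`; drawn
#' frequencies are clamped away from 0 and 1.
#'
#' @param M number of SNPs.
#' @param K number of sources.
#' @param fst per-source drift parameter(s) in `[0, 1)`, recycled to
#'   length `K`. `fst = 0` gives sources identical to the ancestral.
#' @param seed integer seed.
#' @param labels source labels (default `S1..SK`).
#' @param p_range range of ancestral frequencies (default `c(0.05, 0.95)`).
#' @param clamp frequencies forced into `[clamp, 1 - clamp]`
#'   (default 1/200, i.e. `1/(2 n_ref)` for a nominal 100-sample panel).
#' @return object of class `source_model`: list with `freqs` (K x M
#'   matrix), `ancestral`, `labels`, `fst`.
#' @export
make_source_freqs <- function(M, K, fst, seed, labels = paste0("S", seq_len(K)),
                              p_range = c(0.05, 0.95), clamp = 1 / 200) {
  fst <- rep_len(fst, K)
  if (any(fst < 0) || any(fst >= 1)) stop("fst must lie in [0, 1)")
  with_seed(seed, {
    p <- runif(M, p_range[1], p_range[2])
    f <- matrix(NA_real_, K, M, dimnames = list(labels, NULL))
    for (k in seq_len(K)) {
      if (fst[k] == 0) {
        f[k, ] <- p
      } else {
        shape <- (1 - fst[k]) / fst[k]
        f[k, ] <- rbeta(M, p * shape, (1 - p) * shape)
      }
    }
  })
  f <- pmin(pmax(f, clamp), 1 - clamp)
  structure(list(freqs = f, ancestral = p, labels = labels, fst = fst),
            class = "source_model")
}

#' Admixture schedule
#'
#' Per-generation, per-sex fresh contribution fractions. Row `g` gives,
#' for each source, the fraction of that generation's mothers (`sf`) and
#' fathers (`sm`) drawn fresh from the source; the remainder come from
#' the existing admixed pool. Row 0 founds the population and must sum
#' to 1 per sex; later rows must sum to at most 1.
#'
#' @param sf,sm numeric matrices, `(G + 1)` rows by `K` source columns.
#' @param labels source labels (default column names of `sf`).
#' @return object of class `admixture_schedule`.
#' @export
admixture_schedule <- function(sf, sm, labels = colnames(sf)) {
  sf <- as.matrix(sf); sm <- as.matrix(sm)
  if (!identical(dim(sf), dim(sm))) stop("sf and sm must have equal dimensions")
  if (is.null(labels)) labels <- paste0("S", seq_len(ncol(sf)))
  if (any(sf < 0) || any(sm < 0)) stop("negative contribution fraction")
  if (abs(sum(sf[1, ]) - 1) > 1e-9 || abs(sum(sm[1, ]) - 1) > 1e-9)
    stop("generation-0 fractions must sum to 1 per sex")
  if (any(rowSums(sf) > 1 + 1e-9) || any(rowSums(sm) > 1 + 1e-9))
    stop("fresh fractions exceed 1 in some generation")
  colnames(sf) <- colnames(sm) <- labels
  structure(list(sf = sf, sm = sm, labels = labels,
                 generations = nrow(sf) - 1L),
            class = "admixture_schedule")
}

#' Single-pulse schedule helper
#'
#' Convenience constructor: the population is founded from `base` source
#' `g` generations ago with an immediate pulse from source `pulse` of
#' female fraction `frac_f` and male fraction `frac_m`, then mates
#' randomly with no further gene flow.
#'
#' @param g generations since the pulse.
#' @param frac_f,frac_m female/male founding fractions of the pulse source.
#' @param labels length-2 source labels, base first.
#' @return an [admixture_schedule()] with sources `(base, pulse)`.
#' @export
single_pulse_schedule <- function(g, frac_f, frac_m,
                                  labels = c("BASE", "PULSE")) {
  sf <- matrix(0, g + 1, 2, dimnames = list(NULL, labels))
  sm <- sf
  sf[1, ] <- c(1 - frac_f, frac_f)
  sm[1, ] <- c(1 - frac_m, frac_m)
  admixture_schedule(sf, sm, labels)
}

#' Expected ancestry fractions under a schedule
#'
#' Deterministic recursion for the expected autosomal and X-chromosome
#' ancestry fractions of the final generation, ignoring drift. Autosomes:
#' each generation is the sexes' average of fresh contributions plus the
#' diluted pool. X: females carry one maternal (pool or fresh mother) and
#' one paternal X; males carry a maternal X only; the returned X value is
#' the expectation for an individual of random sex (2/3 female-weighted).
#'
#' Matriline (mtDNA) and patriline (Y) expectations follow the female
#' and male fresh-contribution chains alone. All four ignore drift,
#' which for the uniparental systems can be substantial over many
#' generations (single-locus effective size).
#'
#' @param schedule an [admixture_schedule()].
#' @return list with `autosomal`, `x`, `mt` and `y` expected fraction
#'   vectors.
#' @export
expected_fractions <- function(schedule) {
  sf <- schedule$sf; sm <- schedule$sm
  # founders are unadmixed migrants, so generation 0 is sex-structured
  a_fem <- sf[1, ]; a_mal <- sm[1, ]
  x_fem <- sf[1, ]; x_mal <- sm[1, ]
  mt <- sf[1, ]; y <- sm[1, ]
  G <- nrow(sf) - 1
  for (g in seq_len(G)) {
    keep_f <- 1 - sum(sf[g + 1, ]); keep_m <- 1 - sum(sm[g + 1, ])
    mother_a <- sf[g + 1, ] + keep_f * a_fem
    father_a <- sm[g + 1, ] + keep_m * a_mal
    a_fem <- a_mal <- (mother_a + father_a) / 2
    mother_x <- sf[g + 1, ] + keep_f * x_fem
    father_x <- sm[g + 1, ] + keep_m * x_mal
    x_fem_new <- (mother_x + father_x) / 2
    x_mal <- mother_x
    x_fem <- x_fem_new
    mt <- sf[g + 1, ] + keep_f * mt
    y <- sm[g + 1, ] + keep_m * y
  }
  list(autosomal = (a_fem + a_mal) / 2, x = (2 * x_fem + x_mal) / 3,
       mt = mt, y = y)
}

#' Forward-time admixture simulation
#'
#' Simulates a sex-structured admixing population forward in time on a
#' centimorgan map: discrete non-overlapping generations at constant pool
#' size, random mating given the schedule, Poisson crossovers (Haldane,
#' no interference), X recombining in females only and transmitted intact
#' father-to-daughter, Y following the patriline and mtDNA the matriline.
#' Fresh migrants are unadmixed single-source individuals. Founders carry
#' single-source chromosomes.
#'
#' @param source_model a [make_source_freqs()] model (supplies labels; the
#'   frequencies are used later by [emit_genotypes()]).
#' @param schedule an [admixture_schedule()] with matching sources.
#' @param n_out cohort size to sample from the final generation.
#' @param map named numeric vector of chromosome lengths in cM; a
#'   component named `"X"` is treated as the X chromosome.
#' @param seed integer seed.
#' @param pool_size constant population size per generation (default
#'   2000; must be at least `2 * n_out`).
#' @return object of class `sim_cohort`: sample sheet with sexes, a
#'   [tract_set()] of true ancestry segments (chromosome `"X"` included),
#'   true per-individual autosomal and X fractions, mtDNA and Y source
#'   labels, parental uniparental labels, the map and the seed.
#' @export
simulate_admixture <- function(source_model, schedule, n_out, map, seed,
                               pool_size = 2000) {
  stopifnot(inherits(schedule, "admixture_schedule"))
  if (pool_size < 2 * n_out)
    stop("pool_size must be at least 2 * n_out")
  if (!identical(source_model$labels, schedule$labels))
    stop("source model and schedule disagree on source labels")
  x_len <- if ("X" %in% names(map)) unname(map[["X"]]) else NA_real_
  aut <- map[names(map) != "X"]
  if (length(aut) < 1) stop("need at least one autosome in the map")
  core <- with_seed(seed, {
    .sim_admixture_core(unname(aut), x_len, schedule$sf, schedule$sm,
                        as.integer(pool_size), as.integer(n_out))
  })
  labels <- schedule$labels
  ids <- sprintf("sim%04d", seq_len(n_out))
  sheet <- sample_sheet(ids, population = "SIM",
                        genetic_sex = c("female", "male")[core$sex])
  chrom_names <- c("X", names(aut))[core$tract_chr + 1L]
  tracts <- tract_set(data.frame(
    individual = ids[core$tract_ind], hap = core$tract_hap,
    chrom = chrom_names, start_cM = core$tract_start,
    end_cM = core$tract_end, ancestry = labels[core$tract_lab],
    stringsAsFactors = FALSE))
  dimnames(core$frac_aut) <- list(ids, labels)
  dimnames(core$frac_x) <- list(ids, labels)
  structure(list(
    samples = sheet, tracts = tracts,
    frac_autosomal = core$frac_aut,
    frac_x = if (!is.na(x_len)) core$frac_x else NULL,
    mt = setNames(labels[core$mt], ids),
    y = setNames(ifelse(is.na(core$y), NA_character_, labels[core$y]), ids),
    mother_mt = setNames(labels[core$mother_mt], ids),
    father_y = setNames(labels[core$father_y], ids),
    map = map, labels = labels, seed = seed, schedule = schedule),
    class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("sim_cohort:", nrow(x$samples), "individuals,",
      length(x$map), "chromosomes, sources:",
      paste(x$labels, collapse = ", "), "\n")
  cat("  mean autosomal fractions:",
      paste(sprintf("%s=%.3f", x$labels, colMeans(x$frac_autosomal)),
            collapse = ", "), "\n")
  invisible(x)
}

#' Place SNPs on a genetic map
#'
#' Generates a [variant_table()] with SNPs at uniform random cM positions
#' along each chromosome (sorted), physical positions at 1 Mb/cM, and
#' random non-ambiguous allele pairs.
#'
#' @param map named numeric vector of chromosome lengths in cM.
#' @param snps_per_chrom integer vector (recycled) of SNP counts.
#' @param seed integer seed.
#' @return a [variant_table()].
#' @export
make_map_variants <- function(map, snps_per_chrom, seed) {
  snps_per_chrom <- rep_len(snps_per_chrom, length(map))
  pairs <- list(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"))
  with_seed(seed, {
    out <- lapply(seq_along(map), function(i) {
      n <- snps_per_chrom[i]
      pos <- sort(runif(n, 0, map[i]))
      al <- pairs[sample.int(4, n, replace = TRUE)]
      data.frame(chrom = names(map)[i],
                 pos_cM = pos,
                 pos_bp = as.integer(round(pos * 1e6) + 1),
                 ref_allele = vapply(al, `[`, "", 1),
                 alt_allele = vapply(al, `[`, "", 2),
                 stringsAsFactors = FALSE)
    })
  })
  tab <- do.call(rbind, out)
  variant_table(sprintf("snp%06d", seq_len(nrow(tab))), tab$chrom,
                tab$pos_bp, tab$pos_cM, tab$ref_allele, tab$alt_allele)
}

#' Emit genotypes from a simulated cohort
#'
#' Draws alleles for each haplotype: at SNP `j` on a tract of ancestry
#' `k`, the alternate allele appears with probability `f[k, j]` from the
#' source model. Males get a single X draw. Optionally returns the phased
#' haplotypes for local-ancestry work.
#'
#' @param cohort a [simulate_admixture()] cohort.
#' @param source_model the matching [make_source_freqs()] model.
#' @param variants a [variant_table()] on the cohort's map (e.g. from
#'   [make_map_variants()]); must have exactly `ncol(freqs)` SNPs.
#' @param seed integer seed.
#' @param haplotypes if `TRUE`, also return the per-haplotype allele
#'   matrix and its (individual, hap) index.
#' @return list with `geno` (a [geno_matrix()]) and, if requested,
#'   `haps` (matrix of 0/1 alleles, one row per haplotype) and
#'   `hap_index` (data frame individual, hap).
#' @export
emit_genotypes <- function(cohort, source_model, variants, seed,
                           haplotypes = FALSE) {
  f <- source_model$freqs
  if (ncol(f) != nrow(variants))
    stop("source model and variant table disagree on SNP count")
  K <- nrow(f)
  ids <- cohort$samples$individual_id
  n <- length(ids)
  calls <- matrix(NA_integer_, n, nrow(variants),
                  dimnames = list(ids, variants$snp_id))
  hap_rows <- list()
  tr <- cohort$tracts
  lab_int <- match(tr$ancestry, cohort$labels)
  tract_idx <- split(seq_len(nrow(tr)),
                     paste(tr$individual, tr$hap, tr$chrom, sep = "|"))
  with_seed(seed, {
    for (ch in unique(variants$chrom)) {
      snp_cols <- which(variants$chrom == ch)
      pos <- variants$pos_cM[snp_cols]
      for (i in seq_len(n)) {
        sexf <- cohort$samples$genetic_sex[i] == "female"
        nhap <- if (ch == "X" && !sexf) 1L else 2L
        acc <- integer(length(snp_cols))
        for (hp in seq_len(nhap)) {
          sel <- tract_idx[[paste(ids[i], hp, ch, sep = "|")]]
          if (is.null(sel)) stop("missing tracts for ", ids[i], " chrom ", ch)
          k_at <- lab_int[sel][findInterval(pos, tr$start_cM[sel])]
          p <- f[cbind(k_at, snp_cols)]
          al <- rbinom(length(p), 1L, p)
          acc <- acc + al
          if (haplotypes) {
            hap_rows[[length(hap_rows) + 1L]] <- list(i = i, hp = hp,
                                                      ch = ch, al = al)
          }
        }
        calls[i, snp_cols] <- acc
      }
    }
  })
  geno <- geno_matrix(calls, variants, cohort$samples)
  out <- list(geno = geno)
  if (haplotypes) {
    # assemble per-(individual, hap) rows across chromosomes; the male X
    # exists only as hap 1
    keymap <- new.env()
    for (r in hap_rows) {
      key <- paste(r$i, r$hp, sep = "_")
      cur <- keymap[[key]]
      if (is.null(cur)) cur <- rep(NA_integer_, nrow(variants))
      cur[variants$chrom == r$ch] <- r$al
      keymap[[key]] <- cur
    }
    keys <- ls(keymap)
    parts <- strsplit(keys, "_")
    ord <- order(as.integer(vapply(parts, `[`, "", 1)),
                 as.integer(vapply(parts, `[`, "", 2)))
    keys <- keys[ord]; parts <- parts[ord]
    haps <- do.call(rbind, lapply(keys, function(k) keymap[[k]]))
    colnames(haps) <- variants$snp_id
    out$haps <- haps
    out$hap_index <- data.frame(
      individual = ids[as.integer(vapply(parts, `[`, "", 1))],
      hap = as.integer(vapply(parts, `[`, "", 2)),
      stringsAsFactors = FALSE)
  }
  out
}
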