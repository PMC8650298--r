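#' Default pipeline configuration
#'
#' A complete synthetic-mode configuration for [run_pipeline()], small
#' enough for a quick end-to-end run. Every stochastic stage derives its
#' seed from the single top-level `seed` by a fixed counter scheme
#' (`seed + stage offset`), so stages are independently reproducible.
#'
#' @param seed top-level integer seed.
#' @param out_dir output directory.
#' @return nested configuration list.
#' @export
default_config <- function(seed = 1, out_dir = "herdmix_run") {
  list(
    seed = seed,
    out_dir = out_dir,
    stages = c("sim", "qc", "admix", "xa", "date", "uniparental",
               "popstats"),
    sim = list(n_out = 120, pool_size = 400, density = 2),
    qc = list(per_snp_max = 0.05, per_ind_max = 0.05, hwe_alpha = 0.005),
    admix = list(tol = 1e-4, max_iter = 300),
    xa = list(n_boot = 50, min_ancestry = 0.02),
    date = list(pair = c("SAN", "EAF"), n_boot = 25, d_max = 30),
    uniparental = list(),
    popstats = list(variant = NULL)
  )
}

stage_seed <- function(config, stage) {
  offsets <- c(sim = 101L, qc = 202L, admix = 303L, xa = 404L,
               date = 505L, uniparental = 606L, popstats = 707L)
  as.integer(config$seed) + offsets[[stage]]
}

validate_config <- function(config) {
  if (is.null(config$seed)) stop("config validation: missing seed")
  if (is.null(config$out_dir)) stop("config validation: missing out_dir")
  config$stages <- unlist(config$stages)
  bad <- setdiff(config$stages,
                 c("sim", "qc", "admix", "xa", "date", "uniparental",
                   "popstats"))
  if (length(bad)) stop("config validation: unknown stage ", bad[1])
  config
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full synthetic analysis pipeline
#'
#' Orchestrates the stages sim (simulate a five-source sex-biased
#' cohort), qc (missingness, Hardy-Weinberg, strand-ambiguous and LD
#' filters), admix (supervised ancestry fractions), xa (X/autosome
#' ratios), date (coancestry-curve admixture dating), uniparental
#' (haplogroup tallies and the four-system composition) and popstats
#' (ancestry ratios). Each stage writes tab-separated tables into the
#' run directory; a manifest with md5 checksums of all products is
#' written last. A stage failure halts the run with a stage-named error,
#' retaining earlier outputs.
#'
#' @param config a configuration list, path to a YAML file with the same
#'   structure, or the output of [default_config()].
#' @return the run directory path, invisibly; the manifest lists the
#'   produced files.
#' @export
run_pipeline <- function(config = default_config()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- validate_config(config)
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out, "run.log")
  logf <- function(stage, ...) {
    cat(sprintf("[%s] %s\n", stage, paste0(...)), file = log_path,
        append = TRUE)
  }
  cat("# herdmix run log\n", file = log_path)
  cat("# config:\n", file = log_path, append = TRUE)
  cat(paste0("#   ", strsplit(yaml::as.yaml(config), "\n")[[1]],
             collapse = "\n"),
      "\n", file = log_path, append = TRUE)
  state <- new.env()
  run_stage <- function(stage, fun) {
    if (!stage %in% config$stages) return(invisible(NULL))
    logf(stage, "start, seed=", stage_seed(config, stage))
    tryCatch(fun(), error = function(e)
      stop("stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
    logf(stage, "done")
  }

  run_stage("sim", function() {
    seed <- stage_seed(config, "sim")
    preset <- hessequa_preset(seed, density = config$sim$density)
    cohort <- simulate_admixture(preset$sources, preset$schedule,
                                 config$sim$n_out, preset$map, seed + 1L,
                                 pool_size = config$sim$pool_size)
    em <- emit_genotypes(cohort, preset$sources, preset$variants,
                         seed + 2L)
    state$preset <- preset; state$cohort <- cohort; state$geno <- em$geno
    write_tsv(cohort$samples, file.path(out, "sim_samples.tsv"))
    write_tracts(cohort$tracts, file.path(out, "sim_tracts.tsv"))
    write_tsv(data.frame(individual_id = rownames(cohort$frac_autosomal),
                         cohort$frac_autosomal, check.names = FALSE),
              file.path(out, "sim_true_fractions.tsv"))
    write_tsv(data.frame(individual_id = names(cohort$mt),
                         mtDNA = cohort$mt, Y = cohort$y),
              file.path(out, "sim_uniparental.tsv"))
    write_genotypes(state$geno, file.path(out, "sim_genotypes.tsv"),
                    format = "tsv")
  })

  run_stage("qc", function() {
    fm <- filter_missingness(state$geno, config$qc$per_snp_max,
                             config$qc$per_ind_max)
    hw <- hwe_exact_filter(fm$geno, alpha = config$qc$hwe_alpha)
    gm <- drop_ambiguous(hw$geno)
    kept <- ld_prune(gm)
    state$geno_qc <- gm
    state$pruned <- kept
    write_tsv(data.frame(
      step = c("input_snps", "after_missingness", "after_hwe",
               "after_ambiguous", "ld_pruned_kept"),
      n = c(ncol(state$geno$calls), ncol(fm$geno$calls),
            ncol(hw$geno$calls), ncol(gm$calls), length(kept))),
      file.path(out, "qc_report.tsv"))
  })

  run_stage("admix", function() {
    f <- state$preset$sources$freqs
    colnames(f) <- state$preset$variants$snp_id
    keep <- match(colnames(state$geno_qc$calls), colnames(f))
    fit <- supervised_q(state$geno_qc, f[, keep, drop = FALSE],
                        tol = config$admix$tol,
                        max_iter = config$admix$max_iter)
    state$fit <- fit
    write_tsv(data.frame(individual_id = rownames(fit$Q), fit$Q,
                         check.names = FALSE),
              file.path(out, "admix_Q.tsv"))
  })

  run_stage("xa", function() {
    f <- state$preset$sources$freqs
    colnames(f) <- state$preset$variants$snp_id
    keep <- match(colnames(state$geno_qc$calls), colnames(f))
    xa <- xa_ratios(state$geno_qc, f[, keep, drop = FALSE],
                    min_ancestry = config$xa$min_ancestry,
                    n_boot = config$xa$n_boot,
                    seed = stage_seed(config, "xa"))
    state$xa <- xa
    write_tsv(as.data.frame(xa), file.path(out, "xa_ratios.tsv"))
  })

  run_stage("date", function() {
    aut <- state$cohort$tracts[state$cohort$tracts$chrom != "X", ,
                               drop = FALSE]
    fit <- bootstrap_dates(tract_set(aut), unlist(config$date$pair),
                           n_boot = config$date$n_boot,
                           seed = stage_seed(config, "date"),
                           d_max = config$date$d_max)
    state$date <- fit
    write_tsv(data.frame(pair = paste(config$date$pair, collapse = "-"),
                         amplitude = fit$a, lambda = fit$lambda,
                         offset = fit$c, generations = fit$generations,
                         years = fit$years, ci_lower_gen = fit$ci_lower,
                         ci_upper_gen = fit$ci_upper, flag = fit$flag),
              file.path(out, "date_fit.tsv"))
  })

  run_stage("uniparental", function() {
    lab_map <- c(SAN = "San", EAF = "East African", WAF = "West African",
                 EUR = "European", SEA = "Asian")
    co <- state$cohort
    mt_calls <- data.frame(individual_id = names(co$mt), system = "mtDNA",
                           haplogroup = unname(lab_map[co$mt]))
    males <- !is.na(co$y)
    y_calls <- data.frame(individual_id = names(co$y)[males], system = "Y",
                          haplogroup = unname(lab_map[co$y[males]]))
    id_map <- ancestry_map(unname(lab_map), unname(lab_map))
    calls <- assign_ancestry(rbind(mt_calls, y_calls), id_map)
    mt_tab <- tally_haplogroups(calls, "mtDNA")
    y_tab <- tally_haplogroups(calls, "Y")
    q_mean <- colMeans(state$fit$Q)
    x_mean <- attr(state$xa, "segment_fractions")
    x_mean <- apply(x_mean[, , dim(x_mean)[3], drop = FALSE], 2, mean)
    names(q_mean) <- names(x_mean) <- unname(lab_map[state$cohort$labels])
    rep <- composition_report(autosomal = q_mean, x = x_mean,
                              mtdna = mt_tab, y = y_tab)
    state$composition <- rep
    write_tsv(rep, file.path(out, "uniparental_composition.tsv"))
  })

  run_stage("popstats", function() {
    means <- cluster_mean_fractions(state$fit, state$geno_qc$samples)
    rat <- ea_san_ratio(means)
    state$ea_san <- rat
    write_tsv(rat, file.path(out, "popstats_ea_san_ratio.tsv"))
    if (!is.null(config$popstats$variant)) {
      write_tsv(allele_frequency(state$geno_qc, config$popstats$variant),
                file.path(out, "popstats_variant_freq.tsv"))
    }
  })

  # product tables only: the log echoes the (path-bearing) config
  files <- setdiff(list.files(out), c("manifest.tsv", "run.log"))
  manifest <- data.frame(file = files,
                         md5 = unname(tools::md5sum(file.path(out, files))))
  write_tsv(manifest, file.path(out, "manifest.tsv"))
  invisible(out)
}
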