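#' Ploidy-aware allele frequency of a target variant
#'
#' Frequency of a chosen allele at one variant, counting over non-missing
#' calls with per-individual ploidy (male X counts one allele). Useful
#' for trait-associated variants such as the lactase-persistence
#' regulatory alleles, where the frequency is read off the raw data
#' rather than a merged panel.
#'
#' @param gm a [geno_matrix()].
#' @param variant_id snp id to look up.
#' @param allele `"alt"` (default) or `"ref"`: which allele to count.
#' @return data frame: variant_id, allele (nucleotide), count,
#'   total_alleles, frequency.
#' @export
allele_frequency <- function(gm, variant_id, allele = c("alt", "ref")) {
  allele <- match.arg(allele)
  j <- match(variant_id, gm$variants$snp_id)
  if (is.na(j)) stop("variant ", variant_id, " not found")
  g <- gm$calls[, j]
  pl <- ploidy_matrix(gm)[, j]
  ok <- !is.na(g)
  total <- sum(pl[ok])
  cnt <- if (allele == "alt") sum(g[ok]) else total - sum(g[ok])
  nuc <- if (allele == "alt") gm$variants$alt_allele[j]
         else gm$variants$ref_allele[j]
  data.frame(variant_id = variant_id, allele = nuc, count = cnt,
             total_alleles = total,
             frequency = if (total > 0) cnt / total else NA_real_,
             stringsAsFactors = FALSE)
}

#' Lactase-persistence variant identifiers
#'
#' Lookup table shipped with the package linking common names of
#' lactase-persistence regulatory variants to rs identifiers, so
#' variants are addressed by id rather than by build-dependent
#' coordinates.
#'
#' @return data frame: name, rs_id, associated_region.
#' @export
lp_variant_table <- function() {
  path <- system.file("extdata", "lp_variants.tsv", package = "herdmix")
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' East-African-to-San ancestry ratio
#'
#' For each group, the East African fraction relative to the combined
#' East African plus San (autochthonous) ancestry:
#' `ratio = EA / (EA + San)`. Under a single early East African pulse
#' into a San background, later immigrant ancestries dilute both terms
#' equally, so the ratio tracks the original mixing proportion.
#'
#' @param q_table data frame of group mean fractions (e.g. from
#'   [cluster_mean_fractions()]) with a `group` column and ancestry
#'   columns.
#' @param ea_label,san_label column names of the two ancestries.
#' @return data frame: group, ea_fraction, san_fraction, ratio (in
#'   `[0, 1]`, NA with a flag when both fractions are 0).
#' @export
ea_san_ratio <- function(q_table, ea_label = "EAF", san_label = "SAN") {
  stopifnot(all(c(ea_label, san_label) %in% names(q_table)))
  ea <- q_table[[ea_label]]
  san <- q_table[[san_label]]
  denom <- ea + san
  data.frame(group = q_table$group,
             ea_fraction = ea, san_fraction = san,
             ratio = ifelse(denom > 0, ea / denom, NA_real_),
             flag = ifelse(denom > 0, "ok", "undefined"),
             stringsAsFactors = FALSE)
}
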