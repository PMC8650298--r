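#' Five-source Khoe-San descendant scenario
#'
#' A documented simulation scenario emulating the admixture history of a
#' southern Cape Khoe-San descendant cohort: an autochthonous San
#' foundation receiving an old, strongly male-biased East African
#' pastoralist pulse (~32 generations before present), followed by a
#' colonial-era three-source pulse (West African, European, Southeast
#' Asian) 6-7 generations before present with a male-biased European
#' component. Expected final fractions (by [expected_fractions()]):
#' roughly 34% San, 3% East African, 25% West African, 26% European, 12%
#' Southeast Asian, with an East African X/A ratio below 1 and a San X/A
#' ratio above 1.
#'
#' The recommended mating-pool size is 20,000: over the ~32 generations
#' separating the pastoralist pulse from the present, single-chromosome
#' drift in a small pool would swamp the X/autosome contrast of a 3%
#' ancestry component, while human population sizes on this timescale
#' keep that drift minor.
#'
#' @param seed integer seed for the source-frequency draw and marker
#'   placement.
#' @param density SNPs per cM (default 6).
#' @return list with `sources` (a [make_source_freqs()] model), `schedule`
#'   (an [admixture_schedule()]), `map` (chromosomes 1-7, 10, 12 and X,
#'   lengths in cM), `variants` (a [variant_table()] on that map) and
#'   `pool_size` (recommended mating-pool size).
#' @export
hessequa_preset <- function(seed, density = 6) {
  labels <- c("SAN", "EAF", "WAF", "EUR", "SEA")
  G <- 32L  # ~960 years at 30 y/generation
  sf <- matrix(0, G + 1, 5, dimnames = list(NULL, labels))
  sm <- sf
  # founding: San base plus a strongly male-biased East African pulse
  # (~93% male; the X/A ratios observed for this ancestry sit far below
  # the all-male single-pulse floor, so the pulse is modeled near the
  # male extreme)
  sf[1, ] <- c(0.9874, 0.0126, 0, 0, 0)
  sm[1, ] <- c(0.8326, 0.1674, 0, 0, 0)
  # colonial pulse split over generations 25 and 26 (7 and 6 before
  # present); European arrivals 80% male, others sex-balanced
  colonial <- function(waf, eur, sea, w_eur = 0.20) {
    rbind(f = c(0, 0, waf, 2 * w_eur * eur, sea),
          m = c(0, 0, waf, 2 * (1 - w_eur) * eur, sea))
  }
  c1 <- colonial(0.160, 0.165, 0.075)
  c2 <- colonial(0.153, 0.159, 0.073)
  sf[26, ] <- c1["f", ]; sm[26, ] <- c1["m", ]
  sf[27, ] <- c2["f", ]; sm[27, ] <- c2["m", ]
  schedule <- admixture_schedule(sf, sm, labels)

  map <- c("1" = 286, "2" = 268, "3" = 223, "4" = 214, "5" = 204,
           "6" = 192, "7" = 187, "10" = 181, "12" = 174, "X" = 180)
  variants <- make_map_variants(map, round(map * density), seed)
  sources <- make_source_freqs(nrow(variants), 5,
                               fst = c(0.20, 0.15, 0.15, 0.15, 0.18),
                               seed = seed + 1L, labels = labels)
  list(sources = sources, schedule = schedule, map = map,
       variants = variants, pool_size = 20000L)
}
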