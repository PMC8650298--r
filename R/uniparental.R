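#' Haplogroup-to-ancestry map
#'
#' An ordered prefix-rule table mapping haplogroup names to continental
#' ancestry labels, matched by longest prefix; unmatched haplogroups are
#' `"unclassified"`. Nomenclature is matched as plain string prefixes
#' (no phylotree traversal), which is sufficient for coarse continental
#' bins but cannot express exceptions inside a clade beyond longer
#' prefixes.
#'
#' @param prefix character vector of haplogroup prefixes (unique).
#' @param ancestry ancestry label per prefix.
#' @return data frame of class `ancestry_map`.
#' @export
ancestry_map <- function(prefix, ancestry) {
  if (anyDuplicated(prefix)) stop("duplicate prefixes in ancestry map")
  m <- data.frame(prefix = as.character(prefix),
                  ancestry = as.character(ancestry),
                  stringsAsFactors = FALSE)
  class(m) <- c("ancestry_map", "data.frame")
  m
}

#' Default Khoe-San descendant haplogroup assignments
#'
#' The continental assignments used for the Hessequa-descendant style
#' cohort: L0d (mtDNA) and A1b (Y) are autochthonous San lineages; L4b
#' and L5a mtDNA and E1b1b Y are East African pastoralist-associated;
#' L0a/L1b/L2a/L3d/L3e mtDNA mark the West African Bantu expansion;
#' B/E/M/U7a mtDNA are Asian; H and J mtDNA European; U2a1a is left
#' unclassified (its central-Eurasian distribution does not separate an
#' Asian from a European origin). Y haplogroups R and I are European,
#' O/C/L/H Asian, E1b1a West African.
#'
#' @param system `"mtDNA"` or `"Y"`.
#' @return an [ancestry_map()].
#' @export
default_haplogroup_map <- function(system = c("mtDNA", "Y")) {
  system <- match.arg(system)
  if (system == "mtDNA") {
    ancestry_map(
      prefix = c("L0d", "L4b", "L5a", "L0a", "L1b", "L2a", "L3d", "L3e",
                 "B", "E", "M", "U7a", "H", "J", "U2a1a"),
      ancestry = c("San", "East African", "East African", "West African",
                   "West African", "West African", "West African",
                   "West African", "Asian", "Asian", "Asian", "Asian",
                   "European", "European", "unclassified"))
  } else {
    ancestry_map(
      prefix = c("A1b", "E1b1b", "E1b1a", "E2", "R", "I", "G", "O", "C",
                 "L", "H", "J", "T"),
      ancestry = c("San", "East African", "West African", "West African",
                   "European", "European", "European", "Asian", "Asian",
                   "Asian", "Asian", "Asian", "Asian"))
  }
}

#' Assign ancestries to haplogroup calls
#'
#' Longest-prefix match of each haplogroup against the map; unmatched
#' calls become `"unclassified"`. The match is canonical: rule order in
#' the map never changes the result.
#'
#' @param calls data frame with columns `individual_id`, `system`
#'   (`"mtDNA"`/`"Y"`), `haplogroup`.
#' @param map an [ancestry_map()].
#' @return `calls` with an added `ancestry` column.
#' @export
assign_ancestry <- function(calls, map) {
  stopifnot(all(c("individual_id", "system", "haplogroup") %in% names(calls)))
  if (any(!nzchar(calls$haplogroup))) stop("empty haplogroup string")
  calls$ancestry <- vapply(calls$haplogroup, function(hg) {
    hit <- map$prefix[startsWith(hg, map$prefix)]
    if (length(hit) == 0) return("unclassified")
    map$ancestry[map$prefix == hit[which.max(nchar(hit))]]
  }, "", USE.NAMES = FALSE)
  calls
}

#' Tally haplogroup ancestries
#'
#' Fractions of each ancestry among the calls of one marker system. The
#' denominator is all calls in the system (unclassified included);
#' fractions are exact before rounding and percentages are rounded
#' half-up to one decimal for presentation.
#'
#' @param calls output of [assign_ancestry()].
#' @param system `"mtDNA"` or `"Y"`.
#' @return data frame: ancestry, count, denominator, fraction, percent.
#' @export
tally_haplogroups <- function(calls, system) {
  sub <- calls[calls$system == system, , drop = FALSE]
  if (nrow(sub) == 0) stop("no calls for system ", system)
  tab <- table(sub$ancestry)
  denom <- nrow(sub)
  out <- data.frame(ancestry = names(tab),
                    count = as.integer(tab),
                    denominator = denom,
                    fraction = as.numeric(tab) / denom,
                    stringsAsFactors = FALSE)
  out$percent <- round_half_up(100 * out$fraction, 1)
  rownames(out) <- NULL
  out
}

# round half away from zero (R's round() is banker's rounding)
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Four-marker-system ancestry composition
#'
#' Aligns ancestry fractions from autosomes, the X chromosome, mtDNA and
#' the Y chromosome over a shared ancestry label set - the object behind
#' "ancestry by marker system" comparisons. Missing systems are allowed;
#' each supplied row sums to 1 over ancestries plus `unclassified`.
#'
#' @param autosomal,x named numeric vectors of mean ancestry fractions
#'   (may be `NULL`).
#' @param mtdna,y tally tables from [tally_haplogroups()] (may be
#'   `NULL`).
#' @return data frame of class `composition_report`: one row per marker
#'   system, one column per ancestry plus `unclassified`.
#' @export
composition_report <- function(autosomal = NULL, x = NULL, mtdna = NULL,
                               y = NULL) {
  as_vec <- function(tab) setNames(tab$fraction, tab$ancestry)
  systems <- list(autosomal = autosomal, X = x,
                  mtDNA = if (!is.null(mtdna)) as_vec(mtdna),
                  Y = if (!is.null(y)) as_vec(y))
  systems <- Filter(Negate(is.null), systems)
  if (length(systems) == 0) stop("no marker system supplied")
  ancestries <- unique(c(unlist(lapply(systems, names))))
  ancestries <- c(setdiff(ancestries, "unclassified"), "unclassified")
  rows <- lapply(names(systems), function(s) {
    v <- systems[[s]][ancestries]
    v[is.na(v)] <- 0
    names(v) <- ancestries
    data.frame(system = s, t(v), check.names = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("composition_report", "data.frame")
  out
}

#' Read haplogroup calls from TSV
#'
#' Expects columns `individual_id`, `system`, `haplogroup`.
#' @param path tab-separated file.
#' @return data frame of calls.
#' @export
read_haplogroup_calls <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  stopifnot(all(c("individual_id", "system", "haplogroup") %in% names(tab)))
  tab
}
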