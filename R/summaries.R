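.CONF_RANK <- c(high = 3L, medium = 2L, low = 1L)

#' COG functional-category enrichment between ancestral and HGT genes
#'
#' Compares the COG category composition of the ancestral and
#' horizontally transferred gene sets. For each category a 2x2 table
#' (in-category vs not x ancestral vs hgt) is tested with a two-sided
#' Fisher's exact test and Benjamini-Hochberg adjusted across
#' categories. Genes without a COG assignment are excluded from the
#' tables but counted in the `no_cog` attribute.
#'
#' @param calls ancestry calls from [classifyGenome()].
#' @param cogMap data.frame from [readCogMap()] (`gene_id`, `category`).
#' @param confidenceFloor lowest confidence retained: `"high"` (default,
#'   the firm-proportion convention), `"medium"` or `"low"`.
#' @param alpha FDR threshold recorded in the result (default 0.05).
#' @return a data.frame with one row per category present in either set:
#'   `category`, `count_ancestral`, `count_hgt`, `odds_ratio` (sample
#'   odds ratio; `Inf`/0 sentinels when a margin is empty), `p_value`,
#'   `q_value`, `direction` (`ancestral-enriched`, `hgt-enriched` or
#'   `none`). Attributes `no_cog` (genes dropped per set for lacking a
#'   COG) and `alpha`.
#' @export
cogEnrichment <- function(calls, cogMap, confidenceFloor = "high",
                          alpha = 0.05) {
  calls <- as.data.frame(calls)
  stopifnot(confidenceFloor %in% names(.CONF_RANK))
  floorRank <- .CONF_RANK[[confidenceFloor]]
  keep <- calls$category %in% c("ancestral", "hgt") &
    .CONF_RANK[calls$confidence] >= floorRank
  calls <- calls[which(keep), , drop = FALSE]
  cat4gene <- setNames(cogMap$category, cogMap$gene_id)
  calls$cog <- cat4gene[calls$query_id]
  noCog <- c(
    ancestral = sum(calls$category == "ancestral" & is.na(calls$cog)),
    hgt = sum(calls$category == "hgt" & is.na(calls$cog))
  )
  calls <- calls[!is.na(calls$cog), , drop = FALSE]
  nAnc <- sum(calls$category == "ancestral")
  nHgt <- sum(calls$category == "hgt")
  if (nAnc == 0L || nHgt == 0L)
    stop("one of the ancestral/hgt sets is empty after filtering; ",
         "try a lower confidenceFloor")

  cats <- sort(unique(calls$cog))
  rows <- lapply(cats, function(cc) {
    a <- sum(calls$category == "ancestral" & calls$cog == cc)
    b <- sum(calls$category == "hgt" & calls$cog == cc)
    tab <- matrix(c(a, nAnc - a, b, nHgt - b), nrow = 2L)
    p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
    oddsNum <- a / (nAnc - a)
    oddsDen <- b / (nHgt - b)
    or <- oddsNum / oddsDen  # Inf / 0 sentinels propagate naturally
    data.frame(category = cc, count_ancestral = a, count_hgt = b,
               odds_ratio = or, p_value = p)
  })
  out <- do.call(rbind, rows)
  out$q_value <- p.adjust(out$p_value, method = "BH")
  out$direction <- ifelse(is.nan(out$odds_ratio) | out$odds_ratio == 1 |
                            out$p_value >= 1, "none",
                          ifelse(out$odds_ratio > 1, "ancestral-enriched",
                                 "hgt-enriched"))
  attr(out, "no_cog") <- noCog
  attr(out, "alpha") <- alpha
  attr(out, "test") <- "two-sided Fisher exact, BH-adjusted"
  out
}

#' Taxonomic distribution of best eligible hits for HGT genes
#'
#' For every gene called horizontally transferred, takes its first hit to
#' a species that is neither the query's own species nor in the focal
#' genus -- the best eligible hit, the proxy for the donor lineage -- and
#' tabulates the chosen taxonomy level. HGT genes with no eligible hit
#' are reported in an `unresolved` bin rather than dropped.
#'
#' @param hitTables named list of per-query hit tables.
#' @param calls ancestry calls from [classifyGenome()].
#' @param taxonomy taxonomy data.frame from [readTaxonomyTable()].
#' @param groupLevel taxonomy column to group by: `"order"` (default),
#'   `"family"` or `"genus"` (the levels the taxonomy table carries).
#' @param config an [AncestryConfig-class] (for self species and focal
#'   genus).
#' @param confidenceFloor lowest confidence retained (default `"high"`).
#' @return a data.frame (`group`, `n`, `fraction`); fractions include
#'   the unresolved bin and sum to 1. Zero rows when no HGT genes pass.
#' @export
bestHitTaxonomy <- function(hitTables, calls, taxonomy,
                            groupLevel = c("order", "family", "genus"),
                            config = ancestryConfig(),
                            confidenceFloor = "high") {
  groupLevel <- match.arg(groupLevel)
  calls <- as.data.frame(calls)
  floorRank <- .CONF_RANK[[confidenceFloor]]
  hgtIds <- calls$query_id[calls$category == "hgt" &
                             .CONF_RANK[calls$confidence] >= floorRank]
  if (!length(hgtIds))
    return(data.frame(group = character(0), n = integer(0),
                      fraction = numeric(0)))
  groups <- vapply(hgtIds, function(q) {
    h <- hitTables[[q]]
    if (is.null(h) || !nrow(h)) return("unresolved")
    idx <- match(h$subject_id, taxonomy$subject_key)
    ok <- !is.na(idx)
    idx <- idx[ok]
    eligible <- taxonomy$species[idx] != config@selfSpecies &
      taxonomy$genus[idx] != config@focalGenus
    if (!any(eligible)) return("unresolved")
    taxonomy[[groupLevel]][idx[which(eligible)[1L]]]
  }, character(1L))
  tab <- sort(table(groups), decreasing = TRUE)
  out <- data.frame(group = names(tab), n = as.integer(tab))
  out$fraction <- out$n / sum(out$n)
  rownames(out) <- NULL
  out
}

#' Divergence time from 16S rRNA divergence
#'
#' Converts a pairwise 16S rRNA divergence into a rough divergence-time
#' interval using the 1--2% per 50 Myr molecular-clock calibration. The
#' fast rate (2%/50 Myr) gives the minimum age, the slow rate (1%/50 Myr)
#' the maximum: a lineage pair 8% apart is dated 200--400 Myr.
#'
#' @param divergencePercent observed 16S divergence, in percent (>= 0).
#' @param cal a [ClockCalibration-class] (default: 1--2% per 50 Myr).
#' @return named numeric of length 2: `t_min_myr`, `t_max_myr`.
#' @examples
#' estimateDivergenceTime(8)   # 200-400 Myr
#' @export
estimateDivergenceTime <- function(divergencePercent,
                                   cal = clockCalibration()) {
  if (!is.numeric(divergencePercent) || any(divergencePercent < 0))
    stop("divergencePercent must be >= 0")
  c(t_min_myr = divergencePercent / cal@percentHigh * cal@myrPerUnit,
    t_max_myr = divergencePercent / cal@percentLow * cal@myrPerUnit)
}
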