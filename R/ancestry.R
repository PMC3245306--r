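## Internal membership codes for a neighborhood position:
##   1 = G: other focal-genus species (e.g. another Azospirillum)
##   2 = F: focal-family species outside the focal genus
##   3 = O: focal-order species outside the focal family
##   4 = X: species outside the focal order
.MEMBERSHIP_LETTERS <- c("G", "F", "O", "X")

.membershipCodes <- function(genus, family, order, config) {
  code <- rep.int(4L, length(genus))
  code[order == config@focalOrder] <- 3L
  code[family == config@focalFamily] <- 2L
  code[genus == config@focalGenus] <- 1L
  code
}

## Count members of `codes` among the top-k positions, either of the full
## sequence or after removing focal-genus (code 1) positions.
.countTop <- function(memb, k, codes) {
  sum(head(memb, k) %in% codes)
}

## The rule engine. `memb` is an integer membership vector (codes above)
## for one query, in neighborhood order. Returns category/confidence/
## rule/evidence. Total on any input.
.classifyMembershipCore <- function(memb, config) {
  n <- length(memb)
  prefilter <- config@genusExclusion == "prefilter"
  gRem <- memb[memb != 1L]
  m <- length(gRem)

  countEx <- if (prefilter) {
    function(k, codes) sum(head(gRem, k) %in% codes)
  } else {
    function(k, codes) sum(head(memb, k) %in% setdiff(codes, 1L))
  }

  ordCodes <- if (config@countFocalGenusInAncestral) c(1L, 2L, 3L) else c(2L, 3L)
  famCodes <- if (config@countFocalGenusInAncestral) c(1L, 2L) else 2L

  evid <- function(...) list(n_species = n, n_nongenus = m, ...)

  # no informative hits: nothing outside the focal genus survived
  if (m == 0L)
    return(list(category = "unassigned", confidence = "none",
                rule = "no_informative_hits", evidence = evid()))

  # ancestral-high: >= 6 focal-order species in the top 8, or all but 1
  # when fewer than 8 species were hit
  wHigh <- min(n, config@windowHighAnc)
  ordHigh <- .countTop(memb, config@windowHighAnc, ordCodes)
  needHigh <- if (n >= config@windowHighAnc) config@thresholdHighAnc
              else max(1L, n - 1L)
  if (ordHigh >= needHigh)
    return(list(category = "ancestral", confidence = "high",
                rule = "ancestral_high",
                evidence = evid(order_in_window = ordHigh,
                                window = wHigh, needed = needHigh)))

  # hgt-high: 0 focal-order species in the top 10, focal genus excluded
  ordTop10 <- countEx(config@windowHighHgt, c(2L, 3L))
  if (ordTop10 == 0L)
    return(list(category = "hgt", confidence = "high", rule = "hgt_high",
                evidence = evid(order_in_window = ordTop10,
                                window = config@windowHighHgt)))

  ancMed <- .countTop(memb, config@windowMedAnc, famCodes)
  hgtMed <- countEx(config@windowMedHgt, c(2L, 3L))
  ancLow <- countEx(config@windowLowAnc, 2L)

  # conflict: simultaneously hgt-medium and (ancestral-medium or -low)
  if (hgtMed == 0L && (ancMed >= config@thresholdMedAnc || ancLow >= 1L))
    return(list(category = "unassigned", confidence = "none",
                rule = "conflict_hgt_medium_vs_ancestral",
                evidence = evid(family_in_med_window = ancMed,
                                family_in_low_window = ancLow,
                                order_in_hgt_med_window = hgtMed)))

  # ancestral-medium: >= 4 focal-family species in the top 8
  if (ancMed >= config@thresholdMedAnc)
    return(list(category = "ancestral", confidence = "medium",
                rule = "ancestral_medium",
                evidence = evid(family_in_window = ancMed,
                                window = config@windowMedAnc,
                                needed = config@thresholdMedAnc)))

  # hgt-medium: 0 focal-order species in the top 5, focal genus excluded
  if (hgtMed == 0L)
    return(list(category = "hgt", confidence = "medium", rule = "hgt_medium",
                evidence = evid(order_in_window = hgtMed,
                                window = config@windowMedHgt)))

  # ancestral-low: >= 1 focal-family species in the top 8, genus excluded
  if (ancLow >= 1L)
    return(list(category = "ancestral", confidence = "low",
                rule = "ancestral_low",
                evidence = evid(family_in_window = ancLow,
                                window = config@windowLowAnc)))

  # hgt-low: 0 focal-family species in the top 8, genus excluded
  famLow <- countEx(config@windowLowHgt, 2L)
  if (famLow == 0L)
    return(list(category = "hgt", confidence = "low", rule = "hgt_low",
                evidence = evid(family_in_window = famLow,
                                window = config@windowLowHgt)))

  list(category = "unassigned", confidence = "none", rule = "no_rule_fired",
       evidence = evid())
}

#' Classify a membership sequence
#'
#' Low-level entry to the rule engine: classifies an ordered sequence of
#' lineage memberships, one letter per distinct species in a query's hit
#' neighborhood. Letters: `G` other focal-genus species, `F` focal-family
#' species outside the genus, `O` focal-order species outside the family,
#' `X` species outside the order. Rules are evaluated high-confidence
#' first (ancestral-high, hgt-high), then the published conflict clause
#' (simultaneously hgt-medium and ancestral-medium-or-low is unassigned),
#' then medium and low tiers.
#'
#' @param membership character vector over `G`,`F`,`O`,`X` (or the integer
#'   codes 1--4), in neighborhood order. May be empty.
#' @param config an [AncestryConfig-class]; defaults apply otherwise.
#' @return a list with `category` (`ancestral`/`hgt`/`unassigned`),
#'   `confidence` (`high`/`medium`/`low`/`none`), `rule` and `evidence`.
#' @examples
#' classifyMembership(c("F","F","F","F","F","F","X","X"))$confidence  # high
#' classifyMembership(rep("X", 10))$category                          # hgt
#' @export
classifyMembership <- function(membership, config = ancestryConfig()) {
  if (is.character(membership)) {
    memb <- match(membership, .MEMBERSHIP_LETTERS)
    if (anyNA(memb))
      stop("membership letters must be among G, F, O, X")
  } else {
    memb <- as.integer(membership)
    if (length(memb) && (anyNA(memb) || any(memb < 1L) || any(memb > 4L)))
      stop("membership codes must be integers in 1..4")
  }
  .classifyMembershipCore(memb, config)
}

#' Build a query's taxonomic neighborhood
#'
#' Maps a query's ordered BLAST hits to species via the taxonomy table,
#' removes hits to the query's own species, keeps only the first
#' occurrence of each species, and preserves the original hit order. The
#' resulting [Neighborhood-class] is the classifier's sole input.
#'
#' @param hits a per-query hit data.frame as produced by [readBlastTab()]
#'   (needs `subject_id`; `query_id` if `queryId` is not given). Hits are
#'   assumed already e-value-filtered and in BLAST output order.
#' @param taxonomy a taxonomy data.frame from [readTaxonomyTable()].
#' @param config an [AncestryConfig-class] providing `selfSpecies`.
#' @param queryId query identifier, required when `hits` has no rows.
#' @param lenient if TRUE, subject ids missing from the taxonomy are
#'   skipped with a warning instead of raising an error.
#' @return a [Neighborhood-class].
#' @examples
#' tax <- data.frame(
#'   subject_key = c("s1", "s2", "s3"),
#'   species = c("Azospirillum lipoferum", "Rhodospirillum rubrum",
#'               "Escherichia coli"),
#'   genus = c("Azospirillum", "Rhodospirillum", "Escherichia"),
#'   family = c("Rhodospirillaceae", "Rhodospirillaceae",
#'              "Enterobacteriaceae"),
#'   order = c("Rhodospirillales", "Rhodospirillales", "Enterobacterales"))
#' rownames(tax) <- tax$subject_key
#' hits <- data.frame(query_id = "g1",
#'                    subject_id = c("s1", "s2", "s2", "s3"))
#' buildNeighborhood(hits, tax)   # self removed, s2 deduplicated
#' @export
buildNeighborhood <- function(hits, taxonomy, config = ancestryConfig(),
                              queryId = NULL, lenient = FALSE) {
  if (is.null(queryId)) {
    if (!nrow(hits)) stop("queryId is required for an empty hit table")
    queryId <- hits$query_id[1L]
  }
  idx <- match(hits$subject_id, taxonomy$subject_key)
  if (anyNA(idx)) {
    missing <- unique(hits$subject_id[is.na(idx)])
    if (!lenient)
      stop("subject id(s) not in taxonomy table: ",
           paste(missing, collapse = ", "))
    warning("skipping subject id(s) not in taxonomy table: ",
            paste(missing, collapse = ", "))
    idx <- idx[!is.na(idx)]
  }
  species <- taxonomy$species[idx]
  keep <- species != config@selfSpecies & !duplicated(species)
  new("Neighborhood",
      queryId = queryId,
      species = species[keep],
      genus = taxonomy$genus[idx][keep],
      family = taxonomy$family[idx][keep],
      order = taxonomy$order[idx][keep])
}

#' Classify one gene from its neighborhood
#'
#' Applies the tiered neighborhood rules to a [Neighborhood-class] and
#' returns the per-gene verdict: ancestral or horizontally transferred at
#' high/medium/low confidence, or unassigned. See [classifyMembership()]
#' for the rule set and its evaluation order.
#'
#' @param nb a [Neighborhood-class] from [buildNeighborhood()].
#' @param config an [AncestryConfig-class].
#' @return a named list: `query_id`, `category`, `confidence`,
#'   `rule_fired`, and `evidence` (the counts the winning rule used).
#' @export
classifyAncestry <- function(nb, config = ancestryConfig()) {
  stopifnot(is(nb, "Neighborhood"))
  memb <- .membershipCodes(nb@genus, nb@family, nb@order, config)
  res <- .classifyMembershipCore(memb, config)
  list(query_id = nb@queryId, category = res$category,
       confidence = res$confidence, rule_fired = res$rule,
       evidence = res$evidence)
}

.evidenceJson <- function(ev) {
  vals <- vapply(ev, function(v) as.character(v), character(1L))
  paste0("{", paste0('"', names(ev), '":', vals, collapse = ","), "}")
}

#' Classify every gene of a genome
#'
#' Runs [buildNeighborhood()] plus the rule engine over a full set of
#' per-query hit tables. Queries listed in `queryIds` but absent from
#' `hitTables` (no BLAST hits at all) are reported unassigned, as are
#' queries whose neighborhoods are empty after self-exclusion and
#' focal-genus removal.
#'
#' @param hitTables named list of per-query hit data.frames, as returned
#'   by [readBlastTab()] or [simulateHitTables()].
#' @param taxonomy taxonomy data.frame from [readTaxonomyTable()].
#' @param config an [AncestryConfig-class].
#' @param queryIds queries to classify; defaults to `names(hitTables)`.
#'   Extra ids without a hit table get an unassigned call.
#' @param lenient passed to [buildNeighborhood()].
#' @return a `DataFrame` with one row per query: `query_id`, `category`,
#'   `confidence`, `rule_fired`, `evidence_json`.
#' @export
classifyGenome <- function(hitTables, taxonomy, config = ancestryConfig(),
                           queryIds = names(hitTables), lenient = FALSE) {
  if (is.null(queryIds)) queryIds <- character(0)
  nq <- length(queryIds)
  category <- character(nq); confidence <- character(nq)
  rule <- character(nq); evjson <- character(nq)
  taxKey <- taxonomy$subject_key
  taxSpecies <- taxonomy$species
  taxCodes <- .membershipCodes(taxonomy$genus, taxonomy$family,
                               taxonomy$order, config)
  selfSpecies <- config@selfSpecies
  for (i in seq_len(nq)) {
    q <- queryIds[i]
    h <- hitTables[[q]]
    if (is.null(h) || !nrow(h)) {
      res <- .classifyMembershipCore(integer(0), config)
      if (is.null(h)) res$rule <- "no_blast_hits"
    } else {
      idx <- match(h$subject_id, taxKey)
      if (anyNA(idx)) {
        missing <- unique(h$subject_id[is.na(idx)])
        if (!lenient)
          stop("query ", q, ": subject id(s) not in taxonomy table: ",
               paste(missing, collapse = ", "))
        warning("query ", q, ": skipping unknown subject id(s)")
        idx <- idx[!is.na(idx)]
      }
      sp <- taxSpecies[idx]
      keep <- sp != selfSpecies & !duplicated(sp)
      res <- .classifyMembershipCore(taxCodes[idx][keep], config)
    }
    category[i] <- res$category
    confidence[i] <- res$confidence
    rule[i] <- res$rule
    evjson[i] <- .evidenceJson(res$evidence)
  }
  DataFrame(query_id = queryIds, category = category,
            confidence = confidence, rule_fired = rule,
            evidence_json = evjson)
}

#' Tabulate ancestry calls
#'
#' Counts and fractions of calls by category and confidence, plus the
#' high-confidence-only view used when reporting firm proportions.
#'
#' @param calls a `DataFrame`/data.frame of calls from [classifyGenome()].
#' @return a list with three data.frames: `full` (category x confidence
#'   counts and fractions of all calls), `byCategory` (collapsed over
#'   confidence), and `highConfidence` (counts and fractions among
#'   high-confidence calls only).
#' @export
summarizeProportions <- function(calls) {
  calls <- as.data.frame(calls)
  if (!nrow(calls)) stop("cannot summarize an empty call list")
  catLev <- c("ancestral", "hgt", "unassigned")
  confLev <- c("high", "medium", "low", "none")
  tab <- table(factor(calls$category, levels = catLev),
               factor(calls$confidence, levels = confLev))
  full <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(full) <- c("category", "confidence", "n")
  full <- full[order(match(full$category, catLev),
                     match(full$confidence, confLev)), ]
  # the 7 reachable category x confidence combinations
  full <- full[(full$category %in% c("ancestral", "hgt") &
                  full$confidence %in% c("high", "medium", "low")) |
                 (full$category == "unassigned" & full$confidence == "none"), ]
  full$fraction <- full$n / nrow(calls)
  rownames(full) <- NULL
  byCat <- aggregate(n ~ category, data = full, FUN = sum)
  byCat <- byCat[match(catLev, byCat$category), ]
  byCat$fraction <- byCat$n / nrow(calls)
  rownames(byCat) <- NULL
  hi <- calls[calls$confidence == "high", , drop = FALSE]
  highConfidence <- data.frame(
    category = c("ancestral", "hgt"),
    n = c(sum(hi$category == "ancestral"), sum(hi$category == "hgt"))
  )
  highConfidence$fraction <- if (nrow(hi))
    highConfidence$n / nrow(hi) else NA_real_
  list(full = full, byCategory = byCat, highConfidence = highConfidence)
}
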