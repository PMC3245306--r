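#' @include azohgt-package.R
NULL

## ---------------------------------------------------------------------------
## AncestryConfig
## ---------------------------------------------------------------------------

#' Classifier configuration
#'
#' Holds the focal-lineage labels and the window/threshold constants of the
#' neighborhood classifier. The defaults encode the published rule set:
#' ancestral-high needs at least 6 of the top 8 species in the focal order
#' (or all but 1 when fewer than 8 species were hit); ancestral-medium at
#' least 4 focal-family species in the top 8; ancestral-low at least 1
#' focal-family species in the top 8 after removing other focal-genus
#' species; hgt-high/medium/low need 0 focal-order (or, for low, focal
#' family) species in the top 10/5/8 after removing focal-genus species.
#'
#' @slot selfSpecies binomial species name of the query organism; its own
#'   hits are discarded before any rule is applied.
#' @slot focalGenus,focalFamily,focalOrder lineage labels the rules test.
#' @slot windowHighAnc,thresholdHighAnc window and minimum focal-order
#'   count for the ancestral-high rule (defaults 8 and 6).
#' @slot windowMedAnc,thresholdMedAnc window and minimum focal-family
#'   count for ancestral-medium (defaults 8 and 4).
#' @slot windowLowAnc window for ancestral-low (default 8; threshold 1).
#' @slot windowHighHgt,windowMedHgt,windowLowHgt windows in which zero
#'   focal-order (high/medium) or focal-family (low) species are required
#'   (defaults 10, 5, 8).
#' @slot countFocalGenusInAncestral logical; whether other focal-genus
#'   species count toward the ancestral-high and ancestral-medium tallies
#'   (default TRUE: the family inventory backing the top-8 window counts
#'   the focal-genus genomes among family members).
#' @slot genusExclusion either "prefilter" (focal-genus species are removed
#'   from the ordered list before a top-k window is taken; default) or
#'   "inwindow" (they keep their slots but are not counted).
#' @slot evalueCutoff BLAST e-value cutoff applied upstream (default 1e-4).
#'
#' @seealso [ancestryConfig()] for the user-facing constructor.
#' @exportClass AncestryConfig
setClass("AncestryConfig",
  representation(
    selfSpecies = "character",
    focalGenus = "character",
    focalFamily = "character",
    focalOrder = "character",
    windowHighAnc = "integer",
    thresholdHighAnc = "integer",
    windowMedAnc = "integer",
    thresholdMedAnc = "integer",
    windowLowAnc = "integer",
    windowHighHgt = "integer",
    windowMedHgt = "integer",
    windowLowHgt = "integer",
    countFocalGenusInAncestral = "logical",
    genusExclusion = "character",
    evalueCutoff = "numeric"
  ),
  prototype(
    selfSpecies = "Azospirillum lipoferum",
    focalGenus = "Azospirillum",
    focalFamily = "Rhodospirillaceae",
    focalOrder = "Rhodospirillales",
    windowHighAnc = 8L,
    thresholdHighAnc = 6L,
    windowMedAnc = 8L,
    thresholdMedAnc = 4L,
    windowLowAnc = 8L,
    windowHighHgt = 10L,
    windowMedHgt = 5L,
    windowLowHgt = 8L,
    countFocalGenusInAncestral = TRUE,
    genusExclusion = "prefilter",
    evalueCutoff = 1e-4
  )
)

setValidity("AncestryConfig", function(object) {
  msg <- character(0)
  win <- c(object@windowHighAnc, object@windowMedAnc, object@windowLowAnc,
           object@windowHighHgt, object@windowMedHgt, object@windowLowHgt)
  if (any(is.na(win)) || any(win < 1L))
    msg <- c(msg, "all windows must be >= 1")
  if (object@thresholdHighAnc > object@windowHighAnc)
    msg <- c(msg, "thresholdHighAnc must not exceed windowHighAnc")
  if (object@thresholdMedAnc > object@windowMedAnc)
    msg <- c(msg, "thresholdMedAnc must not exceed windowMedAnc")
  for (s in c("selfSpecies", "focalGenus", "focalFamily", "focalOrder"))
    if (length(slot(object, s)) != 1L || !nzchar(slot(object, s)))
      msg <- c(msg, sprintf("%s must be a single non-empty string", s))
  if (!object@genusExclusion %in% c("prefilter", "inwindow"))
    msg <- c(msg, "genusExclusion must be 'prefilter' or 'inwindow'")
  if (!is.finite(object@evalueCutoff) || object@evalueCutoff <= 0)
    msg <- c(msg, "evalueCutoff must be > 0")
  if (length(msg)) msg else TRUE
})

#' Create a classifier configuration
#'
#' @param selfSpecies binomial name of the organism whose genes are being
#'   classified; hits to it are removed before any rule applies.
#' @param ... any `AncestryConfig` slot to override, e.g.
#'   `countFocalGenusInAncestral = FALSE` or `windowHighHgt = 12L`.
#' @return a validated [AncestryConfig-class] object.
#' @examples
#' cfg <- ancestryConfig(selfSpecies = "Azospirillum brasilense")
#' cfg
#' @export
ancestryConfig <- function(selfSpecies = "Azospirillum lipoferum", ...) {
  args <- list(...)
  intSlots <- c("windowHighAnc", "thresholdHighAnc", "windowMedAnc",
                "thresholdMedAnc", "windowLowAnc", "windowHighHgt",
                "windowMedHgt", "windowLowHgt")
  for (s in intersect(names(args), intSlots)) args[[s]] <- as.integer(args[[s]])
  do.call(new, c(list("AncestryConfig", selfSpecies = selfSpecies), args))
}

setMethod("show", "AncestryConfig", function(object) {
  cat("AncestryConfig\n")
  cat("  self species :", object@selfSpecies, "\n")
  cat("  focal lineage:", object@focalGenus, "<", object@focalFamily,
      "<", object@focalOrder, "\n")
  cat(sprintf("  ancestral    : high >=%d/%d order, medium >=%d/%d family, low >=1/%d family (genus excluded)\n",
              object@thresholdHighAnc, object@windowHighAnc,
              object@thresholdMedAnc, object@windowMedAnc,
              object@windowLowAnc))
  cat(sprintf("  hgt          : high 0 order/top %d, medium 0 order/top %d, low 0 family/top %d (genus excluded)\n",
              object@windowHighHgt, object@windowMedHgt, object@windowLowHgt))
  cat("  genus counts in ancestral tallies:",
      object@countFocalGenusInAncestral, "\n")
  cat("  e-value cutoff:", object@evalueCutoff, "\n")
  invisible(object)
})

## ---------------------------------------------------------------------------
## Neighborhood
## ---------------------------------------------------------------------------

#' A query's taxonomic hit neighborhood
#'
#' The ordered list of distinct species among a query's BLAST hits after
#' the e-value cutoff, removal of hits to the query's own species, and
#' first-occurrence-per-species deduplication. This is the classifier's
#' sole input: the rules only look at the rank order of lineage
#' memberships, never at scores.
#'
#' @slot queryId the query gene/protein identifier.
#' @slot species,genus,family,order parallel character vectors giving the
#'   lineage of each retained species, in hit order.
#' @seealso [buildNeighborhood()], [classifyAncestry()]
#' @exportClass Neighborhood
setClass("Neighborhood",
  representation(
    queryId = "character",
    species = "character",
    genus = "character",
    family = "character",
    order = "character"
  )
)

setValidity("Neighborhood", function(object) {
  msg <- character(0)
  n <- length(object@species)
  if (length(object@queryId) != 1L || !nzchar(object@queryId))
    msg <- c(msg, "queryId must be a single non-empty string")
  if (length(object@genus) != n || length(object@family) != n ||
      length(object@order) != n)
    msg <- c(msg, "lineage vectors must be parallel to species")
  if (anyDuplicated(object@species))
    msg <- c(msg, "species must be deduplicated (first occurrence only)")
  if (length(msg)) msg else TRUE
})

setMethod("show", "Neighborhood", function(object) {
  n <- length(object@species)
  cat(sprintf("Neighborhood for query '%s': %d species\n", object@queryId, n))
  if (n) {
    shown <- head(seq_len(n), 10L)
    cat(paste0(sprintf("  %2d. %s [%s]", shown, object@species[shown],
                       object@order[shown]), collapse = "\n"), "\n")
    if (n > 10L) cat("  ...\n")
  }
  invisible(object)
})

#' @describeIn Neighborhood-class number of distinct species retained.
#' @param x a `Neighborhood`.
#' @export
setMethod("length", "Neighborhood", function(x) length(x@species))

#' Accessors for Neighborhood
#'
#' @param nb a [Neighborhood-class] object.
#' @return `queryId()` the query identifier; `speciesSeq()` a `DataFrame`
#'   with one row per retained species (columns species, genus, family,
#'   order) in hit order.
#' @export
queryId <- function(nb) {
  stopifnot(is(nb, "Neighborhood"))
  nb@queryId
}

#' @rdname queryId
#' @export
speciesSeq <- function(nb) {
  stopifnot(is(nb, "Neighborhood"))
  DataFrame(species = nb@species, genus = nb@genus,
            family = nb@family, order = nb@order)
}

## ---------------------------------------------------------------------------
## GenomeRecord
## ---------------------------------------------------------------------------

#' An annotated replicon
#'
#' One replicon sequence plus its typed features (CDS, tRNA, rRNA, other)
#' as a `GRanges` with 1-based inclusive coordinates, the flat-file
#' convention. Built by [readGenomeFlatfile()], [genomeRecord()] or
#' [simulateGenomeWithPrimers()].
#'
#' @slot repliconId replicon identifier (accession or locus name).
#' @slot sequence a [Biostrings::DNAString]; ambiguous IUPAC letters are
#'   retained.
#' @slot features a `GRanges` on this replicon with a `type` metadata
#'   column in {CDS, tRNA, rRNA, other}.
#' @exportClass GenomeRecord
setClass("GenomeRecord",
  representation(
    repliconId = "character",
    sequence = "DNAString",
    features = "GRanges"
  )
)

setValidity("GenomeRecord", function(object) {
  msg <- character(0)
  if (length(object@repliconId) != 1L || !nzchar(object@repliconId))
    msg <- c(msg, "repliconId must be a single non-empty string")
  if (length(object@features)) {
    if (is.null(mcols(object@features)$type))
      msg <- c(msg, "features must carry a 'type' metadata column")
    if (any(start(object@features) < 1L) ||
        any(end(object@features) > length(object@sequence)))
      msg <- c(msg, "feature coordinates must lie within the sequence")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GenomeRecord
#'
#' @param repliconId replicon identifier.
#' @param sequence nucleotide sequence (character or `DNAString`);
#'   upper-cased on input.
#' @param features a data.frame with columns `type`, `start`, `end`,
#'   `strand` (1-based inclusive; strand "+", "-" or "*"), or a `GRanges`
#'   with a `type` metadata column. May be empty.
#' @return a validated [GenomeRecord-class].
#' @examples
#' gr <- genomeRecord("chr", strrep("ACGT", 25),
#'                    data.frame(type = "CDS", start = 1, end = 60,
#'                               strand = "+"))
#' gr
#' @export
genomeRecord <- function(repliconId, sequence, features = NULL) {
  seq <- DNAString(toupper(as.character(sequence)))
  if (is.null(features)) {
    feats <- GRanges(seqnames = character(0), ranges = IRanges(),
                     strand = character(0))
    mcols(feats)$type <- character(0)
  } else if (is(features, "GRanges")) {
    feats <- features
  } else {
    features <- as.data.frame(features)
    if (nrow(features) == 0L) {
      feats <- GRanges(seqnames = character(0), ranges = IRanges(),
                       strand = character(0))
      mcols(feats)$type <- character(0)
    } else {
      feats <- GRanges(
        seqnames = repliconId,
        ranges = IRanges(start = as.integer(features$start),
                         end = as.integer(features$end)),
        strand = if (is.null(features$strand)) "*" else features$strand
      )
      mcols(feats)$type <- as.character(features$type)
    }
  }
  new("GenomeRecord", repliconId = repliconId, sequence = seq,
      features = feats)
}

setMethod("show", "GenomeRecord", function(object) {
  tab <- table(factor(mcols(object@features)$type,
                      levels = c("CDS", "tRNA", "rRNA", "other")))
  cat(sprintf("GenomeRecord '%s': %s bp; %d CDS, %d tRNA, %d rRNA, %d other\n",
              object@repliconId,
              format(length(object@sequence), big.mark = ","),
              tab[["CDS"]], tab[["tRNA"]], tab[["rRNA"]], tab[["other"]]))
  invisible(object)
})

#' @describeIn GenomeRecord-class sequence length in bp.
#' @param x a `GenomeRecord`.
#' @export
setMethod("length", "GenomeRecord", function(x) length(x@sequence))

#' Accessors for GenomeRecord
#'
#' @param x a [GenomeRecord-class].
#' @return `repliconId()` the identifier; `genomeSequence()` the
#'   `DNAString`; `genomeFeatures()` the feature `GRanges`.
#' @export
repliconId <- function(x) {
  stopifnot(is(x, "GenomeRecord"))
  x@repliconId
}

#' @rdname repliconId
#' @export
genomeSequence <- function(x) {
  stopifnot(is(x, "GenomeRecord"))
  x@sequence
}

#' @rdname repliconId
#' @export
genomeFeatures <- function(x) {
  stopifnot(is(x, "GenomeRecord"))
  x@features
}

## ---------------------------------------------------------------------------
## ClockCalibration
## ---------------------------------------------------------------------------

#' 16S rRNA molecular-clock calibration
#'
#' The rule-of-thumb calibration that 1--2% divergence in the 16S rRNA
#' gene corresponds to 50 Myr of separation. The 2%/50 Myr end is the fast
#' rate and yields the minimum age; 1%/50 Myr is the slow rate and yields
#' the maximum.
#'
#' @slot percentLow slow-rate bound, % divergence per `myrPerUnit` (1.0).
#' @slot percentHigh fast-rate bound (2.0).
#' @slot myrPerUnit Myr corresponding to one calibration unit (50).
#' @seealso [estimateDivergenceTime()]
#' @exportClass ClockCalibration
setClass("ClockCalibration",
  representation(percentLow = "numeric", percentHigh = "numeric",
                 myrPerUnit = "numeric"),
  prototype(percentLow = 1.0, percentHigh = 2.0, myrPerUnit = 50.0)
)

setValidity("ClockCalibration", function(object) {
  if (!(object@percentLow > 0 && object@percentLow <= object@percentHigh))
    return("need 0 < percentLow <= percentHigh")
  if (object@myrPerUnit <= 0) return("myrPerUnit must be > 0")
  TRUE
})

#' @rdname ClockCalibration-class
#' @param percentLow,percentHigh,myrPerUnit see slots.
#' @export
clockCalibration <- function(percentLow = 1.0, percentHigh = 2.0,
                             myrPerUnit = 50.0) {
  new("ClockCalibration", percentLow = percentLow,
      percentHigh = percentHigh, myrPerUnit = myrPerUnit)
}

## ---------------------------------------------------------------------------
## PsmFilterConfig
## ---------------------------------------------------------------------------

#' PSM filter thresholds
#'
#' Charge-dependent XCorr minima, a delta-CN minimum, a tryptic-status
#' requirement and a distinct-peptides-per-protein minimum, in the
#' DTASelect style. All thresholds are inclusive (a PSM exactly at a
#' threshold passes). Charges above +3 are filtered with the +3 XCorr
#' threshold.
#'
#' @slot xcorrMinByCharge numeric vector of XCorr minima for charges
#'   +1, +2, +3 (defaults 1.8, 2.5, 3.5).
#' @slot deltaCnMin minimum delta CN (default 0.08).
#' @slot minPeptidesPerProtein distinct passing peptide sequences needed
#'   to call a protein identified (default 2).
#' @slot trypticRequirement "semi-or-better" (fully or semi pass; default)
#'   or "fully" (only fully tryptic pass).
#' @seealso [filterPsms()]
#' @exportClass PsmFilterConfig
setClass("PsmFilterConfig",
  representation(xcorrMinByCharge = "numeric", deltaCnMin = "numeric",
                 minPeptidesPerProtein = "integer",
                 trypticRequirement = "character"),
  prototype(xcorrMinByCharge = c(`1` = 1.8, `2` = 2.5, `3` = 3.5),
            deltaCnMin = 0.08, minPeptidesPerProtein = 2L,
            trypticRequirement = "semi-or-better")
)

setValidity("PsmFilterConfig", function(object) {
  msg <- character(0)
  if (length(object@xcorrMinByCharge) != 3L ||
      any(object@xcorrMinByCharge <= 0))
    msg <- c(msg, "xcorrMinByCharge must be 3 positive values (charges 1:3)")
  if (object@deltaCnMin < 0) msg <- c(msg, "deltaCnMin must be >= 0")
  if (object@minPeptidesPerProtein < 1L)
    msg <- c(msg, "minPeptidesPerProtein must be >= 1")
  if (!object@trypticRequirement %in% c("semi-or-better", "fully"))
    msg <- c(msg, "trypticRequirement must be 'semi-or-better' or 'fully'")
  if (length(msg)) msg else TRUE
})

#' @rdname PsmFilterConfig-class
#' @param xcorrMinByCharge,deltaCnMin,minPeptidesPerProtein,trypticRequirement
#'   see slots.
#' @export
psmFilterConfig <- function(xcorrMinByCharge = c(1.8, 2.5, 3.5),
                            deltaCnMin = 0.08,
                            minPeptidesPerProtein = 2L,
                            trypticRequirement = "semi-or-better") {
  new("PsmFilterConfig", xcorrMinByCharge = xcorrMinByCharge,
      deltaCnMin = deltaCnMin,
      minPeptidesPerProtein = as.integer(minPeptidesPerProtein),
      trypticRequirement = trypticRequirement)
}
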