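## Run code under a fixed seed without disturbing the caller's RNG stream.
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(expr)
}

#' Simulation configuration
#'
#' Parameters of the synthetic-data generators. The taxonomy shape
#' defaults mirror the family inventory the classifier's top-8 window is
#' built on: besides the query organism, 2 other *Azospirillum* genomes
#' and 6 further *Rhodospirillaceae* (3 *Magnetospirillum*, 2
#' *Rhodospirillum*, *Nisaea*), 3 order-level *Rhodospirillales* outside
#' the family, and 8 outside-order species in each of three donor groups
#' (*Rhizobiales*, *Burkholderiales*, other). All generation is a pure
#' function of the configuration, including its seed.
#'
#' @slot seed RNG seed (integer).
#' @slot nGenes number of genes to simulate hit tables for.
#' @slot hgtFraction probability a gene is horizontally transferred.
#' @slot familyRetention probability each eligible close-relative species
#'   appears among an ancestral gene's leading hits (rho).
#' @slot donorGroupProbs named multinomial over donor groups for HGT
#'   genes.
#' @slot nFocalGenusOther,nFamilyOther,nOrderNonfamily,nOutsidePerGroup
#'   taxonomy shape counts.
#' @slot duplicateRate probability a species contributes a second,
#'   consecutive hit (exercises first-occurrence deduplication).
#' @slot nPsms number of PSMs for [simulatePsmTable()].
#' @slot genomeLength,ampliconLength,gcContent genome-simulation shape
#'   for [simulateGenomeWithPrimers()].
#' @slot fwdPrimer,revPrimer primer pair planted in the simulated genome
#'   (defaults: the 19-mers whose product on the *cpaB* fragment is
#'   211 bp).
#' @exportClass SimConfig
setClass("SimConfig",
  representation(
    seed = "integer", nGenes = "integer", hgtFraction = "numeric",
    familyRetention = "numeric", donorGroupProbs = "numeric",
    nFocalGenusOther = "integer", nFamilyOther = "integer",
    nOrderNonfamily = "integer", nOutsidePerGroup = "integer",
    duplicateRate = "numeric", nPsms = "integer",
    genomeLength = "integer", ampliconLength = "integer",
    gcContent = "numeric", fwdPrimer = "character",
    revPrimer = "character"
  ),
  prototype(
    seed = 1L, nGenes = 100L, hgtFraction = 0.5, familyRetention = 0.9,
    donorGroupProbs = c(Rhizobiales = 0.4, Burkholderiales = 0.35,
                        other = 0.25),
    nFocalGenusOther = 2L, nFamilyOther = 6L, nOrderNonfamily = 3L,
    nOutsidePerGroup = 8L, duplicateRate = 0.2, nPsms = 500L,
    genomeLength = 5000L, ampliconLength = 211L, gcContent = 0.65,
    fwdPrimer = "GCGTGGACCTGATCCTGAC", revPrimer = "GTGACCGTCTCGCTCTGAC"
  )
)

setValidity("SimConfig", function(object) {
  msg <- character(0)
  if (object@hgtFraction < 0 || object@hgtFraction > 1)
    msg <- c(msg, "hgtFraction must be in [0, 1]")
  if (object@familyRetention < 0 || object@familyRetention > 1)
    msg <- c(msg, "familyRetention must be in [0, 1]")
  if (any(object@donorGroupProbs < 0) ||
      abs(sum(object@donorGroupProbs) - 1) > 1e-9)
    msg <- c(msg, "donorGroupProbs must be non-negative and sum to 1")
  counts <- c(object@nGenes, object@nFocalGenusOther, object@nFamilyOther,
              object@nOrderNonfamily, object@nOutsidePerGroup,
              object@nPsms)
  if (any(counts < 0L)) msg <- c(msg, "counts must be >= 0")
  if (object@duplicateRate < 0 || object@duplicateRate > 1)
    msg <- c(msg, "duplicateRate must be in [0, 1]")
  if (object@ampliconLength >
      object@genomeLength)
    msg <- c(msg, "ampliconLength must not exceed genomeLength")
  if (object@ampliconLength <
      nchar(object@fwdPrimer) + nchar(object@revPrimer))
    msg <- c(msg, "ampliconLength must fit both primers")
  if (length(msg)) msg else TRUE
})

#' @rdname SimConfig-class
#' @param seed,... slot values to override (see slots).
#' @export
simConfig <- function(seed = 1L, ...) {
  args <- list(...)
  intSlots <- c("nGenes", "nFocalGenusOther", "nFamilyOther",
                "nOrderNonfamily", "nOutsidePerGroup", "nPsms",
                "genomeLength", "ampliconLength")
  for (s in intersect(names(args), intSlots)) args[[s]] <- as.integer(args[[s]])
  do.call(new, c(list("SimConfig", seed = as.integer(seed)), args))
}

## Fixed species catalog the taxonomy simulator draws from, in canonical
## order. Extra species beyond the catalog get synthesized names.
.SPECIES_CATALOG <- list(
  self = c("Azospirillum lipoferum"),
  genus_other = c("Azospirillum brasilense", "Azospirillum sp. B510"),
  family_other = c("Magnetospirillum magneticum",
                   "Magnetospirillum gryphiswaldense",
                   "Magnetospirillum magnetotacticum",
                   "Rhodospirillum rubrum", "Rhodospirillum centenum",
                   "Nisaea sp. BAL199"),
  order_nonfamily = c("Acetobacter pasteurianus", "Gluconobacter oxydans",
                      "Granulibacter bethesdensis"),
  Rhizobiales = c("Rhizobium etli", "Rhizobium leguminosarum",
                  "Sinorhizobium meliloti", "Bradyrhizobium japonicum",
                  "Mesorhizobium loti", "Agrobacterium tumefaciens",
                  "Ochrobactrum anthropi", "Methylobacterium extorquens"),
  Burkholderiales = c("Burkholderia xenovorans", "Burkholderia cenocepacia",
                      "Cupriavidus necator", "Ralstonia solanacearum",
                      "Bordetella pertussis", "Variovorax paradoxus",
                      "Acidovorax citrulli", "Herbaspirillum seropedicae"),
  other = c("Escherichia coli", "Pseudomonas fluorescens",
            "Bacillus subtilis", "Streptomyces coelicolor",
            "Xanthomonas campestris", "Vibrio cholerae",
            "Clostridium acetobutylicum", "Mycobacterium tuberculosis")
)

.pickSpecies <- function(pool, n, stem) {
  if (n <= length(pool)) return(pool[seq_len(n)])
  c(pool, sprintf("%s sim-sp. %d", stem, seq_len(n - length(pool))))
}

#' Simulate a taxonomy universe
#'
#' Builds a taxonomy table whose shape mirrors the database composition
#' the classifier's windows assume: the query species, other focal-genus
#' genomes, further focal-family species, order-level relatives, and
#' outside-order species partitioned into donor groups. Each species
#' contributes two subject keys (two strains) so that first-occurrence
#' species deduplication is exercised. Deterministic: no randomness is
#' involved, only the shape counts.
#'
#' @param cfg a [SimConfig-class].
#' @return a taxonomy data.frame in the [readTaxonomyTable()] schema,
#'   with a `group` attribute mapping each outside-order species to its
#'   donor group.
#' @export
simulateTaxonomy <- function(cfg = simConfig()) {
  stopifnot(is(cfg, "SimConfig"))
  cat <- .SPECIES_CATALOG
  mk <- function(species, genus, family, order) {
    if (!length(species)) return(NULL)
    data.frame(species = species,
               genus = if (length(genus) == 1L)
                 rep(genus, length(species)) else genus,
               family = family, order = order)
  }
  genusOther <- .pickSpecies(cat$genus_other, cfg@nFocalGenusOther,
                             "Azospirillum")
  famOther <- .pickSpecies(cat$family_other, cfg@nFamilyOther,
                           "Rhodospirillaceae")
  ordNonfam <- .pickSpecies(cat$order_nonfamily, cfg@nOrderNonfamily,
                            "Acetobacteraceae")
  firstWord <- function(x) vapply(strsplit(x, " "), `[`, character(1L), 1L)
  rows <- rbind(
    mk(cat$self, "Azospirillum", "Rhodospirillaceae", "Rhodospirillales"),
    mk(genusOther, "Azospirillum", "Rhodospirillaceae", "Rhodospirillales"),
    mk(famOther, firstWord(famOther), "Rhodospirillaceae",
       "Rhodospirillales"),
    mk(ordNonfam, firstWord(ordNonfam), "Acetobacteraceae",
       "Rhodospirillales")
  )
  groups <- names(cfg@donorGroupProbs)
  outsideOrders <- c(Rhizobiales = "Rhizobiales",
                     Burkholderiales = "Burkholderiales",
                     other = "Enterobacterales")
  groupOf <- character(0)
  for (g in groups) {
    pool <- if (g %in% names(cat)) cat[[g]] else character(0)
    sp <- .pickSpecies(pool, cfg@nOutsidePerGroup, g)
    ord <- if (g %in% names(outsideOrders)) outsideOrders[[g]] else g
    rows <- rbind(rows, mk(sp, firstWord(sp), paste0(ord, "_family"), ord))
    groupOf <- c(groupOf, setNames(rep(g, length(sp)), sp))
  }
  # two strains (subject keys) per species
  tax <- rows[rep(seq_len(nrow(rows)), each = 2L), , drop = FALSE]
  tax$subject_key <- paste0(gsub("[ .]+", "_", tax$species), "|",
                            rep(c("a", "b"), nrow(rows)))
  tax <- tax[, c("subject_key", "species", "genus", "family", "order")]
  rownames(tax) <- tax$subject_key
  attr(tax, "group") <- groupOf
  attr(tax, "self_species") <- cat$self
  tax
}

## Expand an ordered species vector into BLAST-hit rows for one query:
## pick a strain per species, occasionally duplicate a species
## (consecutive second strain), and assign rank-decreasing scores with
## e-values 10^(-100 + rank) so values never cross the default cutoff.
.speciesToHits <- function(geneId, speciesSeq, taxBySpecies, dupRate) {
  dup <- runif(length(speciesSeq)) < dupRate
  expanded <- rep(speciesSeq, times = 1L + dup)
  strainPick <- unlist(lapply(seq_along(speciesSeq), function(i) {
    keys <- taxBySpecies[[speciesSeq[i]]]
    if (dup[i]) keys[1:2] else sample(keys, 1L)
  }), use.names = FALSE)
  nh <- length(expanded)
  rank <- seq_len(nh)
  data.frame(
    query_id = geneId,
    subject_id = strainPick,
    percent_identity = pmax(35, 95 - 1.5 * rank + round(runif(nh, -2, 2), 1)),
    aln_length = 250L,
    evalue = 10^(-100 + pmin(rank, 90)),
    bitscore = pmax(50, 500 - 10 * rank),
    rank = rank
  )
}

#' Simulate per-gene BLAST hit tables with known ancestry labels
#'
#' Generates one hit table per gene under a known ancestral/HGT label.
#' Ancestral genes draw their leading hits from the non-self
#' focal-family species (each retained with probability
#' `familyRetention`, catalog order preserved), then order-level
#' relatives, then outside species. HGT genes draw a donor group from
#' `donorGroupProbs` and lead with that group's species; their first 10
#' distinct non-genus species are always outside the focal order, with
#' family hits (if any) only beyond rank 10. Every gene also best-hits
#' its own genome, and species may contribute duplicate strain hits, so
#' self-exclusion and deduplication are exercised. E-values are a
#' deterministic decreasing function of rank; the rules never read them
#' beyond the cutoff.
#'
#' @param cfg a [SimConfig-class] (`nGenes`, `hgtFraction`,
#'   `familyRetention`, `donorGroupProbs`, `duplicateRate`, `seed`).
#' @param taxonomy a taxonomy from [simulateTaxonomy()]; defaults to
#'   `simulateTaxonomy(cfg)`.
#' @return a list: `hit_tables` (named list of per-gene hit
#'   data.frames), `labels` (named `"ancestral"`/`"hgt"` ground truth),
#'   `donor_groups` (named donor group per HGT gene), `taxonomy`.
#' @export
simulateHitTables <- function(cfg = simConfig(),
                              taxonomy = simulateTaxonomy(cfg)) {
  stopifnot(is(cfg, "SimConfig"))
  groupOf <- attr(taxonomy, "group")
  selfSpecies <- attr(taxonomy, "self_species")
  allSpecies <- unique(taxonomy$species)
  famSpecies <- setdiff(
    allSpecies[taxonomy$family[match(allSpecies, taxonomy$species)] ==
                 "Rhodospirillaceae"], selfSpecies)
  ordSpecies <- allSpecies[
    taxonomy$order[match(allSpecies, taxonomy$species)] ==
      "Rhodospirillales" &
      taxonomy$family[match(allSpecies, taxonomy$species)] !=
        "Rhodospirillaceae"]
  outSpecies <- names(groupOf)
  groups <- names(cfg@donorGroupProbs)

  if (cfg@hgtFraction < 1 && length(famSpecies) == 0L)
    stop("impossible simulation shape: ancestral genes requested but ",
         "the taxonomy has no non-self focal-family species")
  if (cfg@hgtFraction > 0 && length(outSpecies) < 10L)
    stop("impossible simulation shape: HGT genes need at least 10 ",
         "outside-order species")

  taxBySpecies <- split(taxonomy$subject_key, taxonomy$species)

  .withSeed(cfg@seed, {
    n <- cfg@nGenes
    geneIds <- sprintf("AZOLI_%05d", seq_len(n))
    isHgt <- runif(n) < cfg@hgtFraction
    labels <- setNames(ifelse(isHgt, "hgt", "ancestral"), geneIds)
    donors <- setNames(rep(NA_character_, n), geneIds)
    hitTables <- vector("list", n)
    names(hitTables) <- geneIds
    rho <- cfg@familyRetention
    for (i in seq_len(n)) {
      if (isHgt[i]) {
        g <- sample(groups, 1L, prob = cfg@donorGroupProbs)
        donors[i] <- g
        donorSp <- sample(outSpecies[groupOf == g])
        donorSp <- donorSp[runif(length(donorSp)) < rho]
        fill <- sample(setdiff(outSpecies, donorSp))
        lead <- c(donorSp, fill)
        # first 10 outside-order species, then optionally trailing
        # family hits at rank > 10
        lead <- lead[seq_len(max(10L, length(donorSp)))]
        trail <- if (runif(1) < 0.3)
          sample(famSpecies, min(2L, length(famSpecies))) else character(0)
        speciesSeq <- c(selfSpecies, lead, trail)
      } else {
        fam <- famSpecies[runif(length(famSpecies)) < rho]
        ord <- ordSpecies[runif(length(ordSpecies)) < rho]
        outside <- sample(outSpecies, min(6L, length(outSpecies)))
        speciesSeq <- c(selfSpecies, fam, ord, outside)
      }
      hitTables[[i]] <- .speciesToHits(geneIds[i], speciesSeq,
                                       taxBySpecies, cfg@duplicateRate)
    }
    list(hit_tables = hitTables, labels = labels,
         donor_groups = donors[isHgt], taxonomy = taxonomy)
  })
}

.AMINO_ACIDS <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]

#' Simulate a PSM table with ground-truth filter labels
#'
#' Draws PSMs with charge, XCorr, delta CN, tryptic status and decoy
#' flags spanning the filter thresholds, and records for each PSM
#' whether it should pass the default DTASelect-style filter -- computed
#' here by a direct, separate transcription of the thresholds so
#' [filterPsms()] can be checked against recorded truth.
#'
#' @param cfg a [SimConfig-class] (`nPsms`, `seed`).
#' @return a list: `psms` (data.frame in the [readPsmTable()] schema),
#'   `truth` (logical pass label per PSM), `protein_lengths` (named
#'   residue lengths for NSAF downstream).
#' @export
simulatePsmTable <- function(cfg = simConfig()) {
  stopifnot(is(cfg, "SimConfig"))
  .withSeed(cfg@seed, {
    n <- cfg@nPsms
    nProt <- 50L
    prot <- sprintf("P%03d", seq_len(nProt))
    lens <- setNames(sample(100:600, nProt, replace = TRUE), prot)
    isDecoyProt <- c(rep(FALSE, nProt - 10L), rep(TRUE, 10L))
    prot[isDecoyProt] <- paste0("rev_", prot[isDecoyProt])
    names(lens) <- prot
    pick <- sample.int(nProt, n, replace = TRUE)
    peptide <- vapply(seq_len(n), function(i)
      paste(sample(.AMINO_ACIDS, sample(8:14, 1L), replace = TRUE),
            collapse = ""), character(1L))
    # reuse some peptides within a protein so distinct-peptide counting
    # differs from PSM counting
    for (i in which(runif(n) < 0.3)) {
      earlier <- which(pick[seq_len(i - 1L)] == pick[i])
      if (length(earlier)) peptide[i] <- peptide[earlier[1L]]
    }
    charge <- sample(1:4, n, replace = TRUE, prob = c(0.2, 0.45, 0.3, 0.05))
    xcorr <- round(runif(n, 0.5, 5.0), 3)
    deltaCn <- round(runif(n, 0, 0.3), 3)
    tryptic <- sample(c("fully", "semi", "non"), n, replace = TRUE,
                      prob = c(0.6, 0.25, 0.15))
    psms <- data.frame(
      peptide = peptide, protein_id = prot[pick], charge = charge,
      xcorr = xcorr, delta_cn = deltaCn, tryptic_status = tryptic,
      is_decoy = isDecoyProt[pick]
    )
    # ground truth by direct transcription of the filter thresholds
    xcorrNeeded <- ifelse(charge == 1, 1.8, ifelse(charge == 2, 2.5, 3.5))
    truth <- xcorr >= xcorrNeeded & deltaCn >= 0.08 & tryptic != "non"
    list(psms = psms, truth = truth, protein_lengths = lens)
  })
}

#' Simulate a genome record with planted features and primer sites
#'
#' Builds a random-background replicon carrying planted CDS/tRNA/rRNA
#' features at recorded coordinates and one planted primer pair whose
#' amplicon has a known length (default 211 bp, the *cpaB* internal
#' fragment size), so genome statistics and in-silico PCR can be checked
#' against ground truth. The generator verifies that neither primer site
#' occurs anywhere else in the sequence and re-draws the background (new
#' derived seed) in the astronomically rare collision case.
#'
#' @param cfg a [SimConfig-class] (`genomeLength`, `ampliconLength`,
#'   `gcContent`, `fwdPrimer`, `revPrimer`, `seed`).
#' @return a list: `record` (a [GenomeRecord-class]), `truth` (list with
#'   `amplicon_start`, `amplicon_end`, `amplicon_length` and the planted
#'   `features` data.frame).
#' @export
simulateGenomeWithPrimers <- function(cfg = simConfig()) {
  stopifnot(is(cfg, "SimConfig"))
  L <- cfg@genomeLength
  fwd <- cfg@fwdPrimer
  rev <- cfg@revPrimer
  ampLen <- cfg@ampliconLength
  if (ampLen > L)
    stop("impossible simulation shape: amplicon longer than the sequence")
  revSite <- as.character(reverseComplement(DNAString(rev)))

  for (attempt in 0:20) {
    seqChars <- .withSeed(cfg@seed + attempt, {
      p <- cfg@gcContent / 2
      sample(c("A", "C", "G", "T"), L, replace = TRUE,
             prob = c((1 - cfg@gcContent) / 2, p, p, (1 - cfg@gcContent) / 2))
    })
    ampStart <- max(1L, (L - ampLen) %/% 3L)
    ampEnd <- ampStart + ampLen - 1L
    seqChars[ampStart:(ampStart + nchar(fwd) - 1L)] <-
      strsplit(fwd, "")[[1L]]
    seqChars[(ampEnd - nchar(rev) + 1L):ampEnd] <-
      strsplit(revSite, "")[[1L]]
    seqStr <- paste(seqChars, collapse = "")
    counts <- vapply(c(fwd, revSite, rev,
                       as.character(reverseComplement(DNAString(fwd)))),
                     function(p) length(gregexpr(p, seqStr, fixed = TRUE)[[1L]][
                       gregexpr(p, seqStr, fixed = TRUE)[[1L]] > 0]),
                     numeric(1L))
    if (counts[1L] == 1L && counts[2L] == 1L && counts[3L] == 0L &&
        counts[4L] == 0L) break
  }

  # planted features on fixed length fractions, disjoint by construction
  feat <- data.frame(
    type = c("CDS", "CDS", "CDS", "tRNA", "tRNA", "rRNA"),
    start = pmax(1L, as.integer(L * c(0.02, 0.25, 0.55, 0.78, 0.82, 0.88))),
    end = as.integer(L * c(0.18, 0.45, 0.70, 0.79, 0.83, 0.93)),
    strand = c("+", "-", "+", "+", "-", "+")
  )
  record <- genomeRecord("sim_replicon", seqStr, feat)
  list(record = record,
       truth = list(amplicon_start = ampStart, amplicon_end = ampEnd,
                    amplicon_length = ampLen, features = feat))
}
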