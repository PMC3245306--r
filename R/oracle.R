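#' Literal reference transcription of the ancestry rules
#'
#' A deliberately naive, sentence-by-sentence transcription of the
#' neighborhood rules, kept independent of the production rule engine so
#' the two can be compared exhaustively. Each published sentence becomes
#' one predicate over the ordered membership letters; tiers are evaluated
#' high-confidence first, with the conflict clause (simultaneously
#' hgt-medium and ancestral-medium-or-low) checked before the medium
#' tiers. This function trades speed for transparency; use
#' [classifyMembership()] for real work.
#'
#' @param membership character vector over `G` (other focal-genus
#'   species), `F` (focal-family, non-genus), `O` (focal-order,
#'   non-family), `X` (outside the order), in neighborhood order.
#' @param countGenusInAncestral whether focal-genus species count toward
#'   the ancestral tallies (default TRUE, as in the default
#'   [ancestryConfig()]).
#' @return a list with `category` and `confidence`, coded as in
#'   [classifyMembership()].
#' @export
literalAncestryOracle <- function(membership, countGenusInAncestral = TRUE) {
  stopifnot(all(membership %in% c("G", "F", "O", "X")))

  in_order <- function(letter) {
    if (countGenusInAncestral) letter %in% c("G", "F", "O")
    else letter %in% c("F", "O")
  }
  in_family <- function(letter) {
    if (countGenusInAncestral) letter %in% c("G", "F") else letter == "F"
  }

  # "excluding hits to other Azospirillum genomes"
  without_genus <- membership[membership != "G"]

  # "Unassigned proteins either have no BLAST hits outside Azospirillum..."
  if (length(without_genus) == 0) {
    return(list(category = "unassigned", confidence = "none"))
  }

  n_species <- length(membership)

  # "High confidence ancestral proteins have at least 6 of the top 8
  #  species belonging to Rhodospirillales or all but 1, if the BLAST
  #  result had less than 8 species."
  count <- 0
  for (i in seq_len(min(8, n_species))) {
    if (in_order(membership[i])) count <- count + 1
  }
  ancestral_high <- if (n_species >= 8) {
    count >= 6
  } else {
    count >= n_species - 1 && count >= 1
  }
  if (ancestral_high) {
    return(list(category = "ancestral", confidence = "high"))
  }

  # "High confidence horizontally transferred proteins have 0 hits to
  #  Rhodospirillales in the top 10, excluding hits to other
  #  Azospirillum genomes."
  count <- 0
  for (i in seq_len(min(10, length(without_genus)))) {
    if (without_genus[i] %in% c("F", "O")) count <- count + 1
  }
  hgt_high <- count == 0
  if (hgt_high) {
    return(list(category = "hgt", confidence = "high"))
  }

  # "Medium confidence ancestral proteins have at least 4
  #  Rhodospirillaceae in the top 8."
  count <- 0
  for (i in seq_len(min(8, n_species))) {
    if (in_family(membership[i])) count <- count + 1
  }
  ancestral_medium <- count >= 4

  # "Medium confidence horizontally transferred proteins have 0 hits to
  #  Rhodospirillales in the top 5, excluding hits to other
  #  Azospirillum genomes."
  count <- 0
  for (i in seq_len(min(5, length(without_genus)))) {
    if (without_genus[i] %in% c("F", "O")) count <- count + 1
  }
  hgt_medium <- count == 0

  # "Low confidence ancestral proteins have at least 1 Rhodospirillaceae
  #  in the top 8, excluding hits to other Azospirillum genomes."
  count <- 0
  for (i in seq_len(min(8, length(without_genus)))) {
    if (without_genus[i] == "F") count <- count + 1
  }
  ancestral_low <- count >= 1

  # "... or simultaneously classify as medium confidence horizontally
  #  transferred and medium or low confidence ancestral."
  if (hgt_medium && (ancestral_medium || ancestral_low)) {
    return(list(category = "unassigned", confidence = "none"))
  }
  if (ancestral_medium) {
    return(list(category = "ancestral", confidence = "medium"))
  }
  if (hgt_medium) {
    return(list(category = "hgt", confidence = "medium"))
  }
  if (ancestral_low) {
    return(list(category = "ancestral", confidence = "low"))
  }

  # "Low confidence horizontally transferred proteins have 0 hits to
  #  Rhodospirillaceae in the top 8, excluding hits to other
  #  Azospirillum genomes."
  count <- 0
  for (i in seq_len(min(8, length(without_genus)))) {
    if (without_genus[i] == "F") count <- count + 1
  }
  if (count == 0) {
    return(list(category = "hgt", confidence = "low"))
  }

  list(category = "unassigned", confidence = "none")
}

#' Enumerate all membership sequences up to a length
#'
#' Generates every sequence over the membership alphabet `G`,`F`,`O`,`X`
#' of lengths `0..maxLen` as an integer-coded matrix per length, for
#' exhaustive rule-engine sweeps.
#'
#' @param len sequence length (a single non-negative integer).
#' @return an integer matrix with `4^len` rows and `len` columns, values
#'   1--4 coding `G`,`F`,`O`,`X`; for `len = 0` a 1x0 matrix.
#' @export
enumerateMemberships <- function(len) {
  stopifnot(len >= 0, len <= 12)
  if (len == 0) return(matrix(integer(0), nrow = 1L, ncol = 0L))
  m <- as.matrix(expand.grid(rep(list(1:4), len), KEEP.OUT.ATTRS = FALSE))
  dimnames(m) <- NULL
  storage.mode(m) <- "integer"
  m
}
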