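#' Batch-classify membership sequences of equal length
#'
#' Vectorized form of [classifyMembership()] for a matrix of
#' integer-coded membership sequences (one row per query, columns in
#' neighborhood order; codes 1 = `G`, 2 = `F`, 3 = `O`, 4 = `X`). Used
#' for exhaustive sweeps over the rule space, where classifying millions
#' of sequences one at a time would be slow. Agrees with
#' [classifyMembership()] row for row; only the default
#' `genusExclusion = "prefilter"` mode is supported.
#'
#' @param m an integer matrix as produced by [enumerateMemberships()].
#' @param config an [AncestryConfig-class].
#' @return a data.frame with one row per input row: `category`,
#'   `confidence`, `rule_fired`.
#' @export
classifyMembershipMatrix <- function(m, config = ancestryConfig()) {
  stopifnot(is.matrix(m))
  if (config@genusExclusion != "prefilter")
    stop("classifyMembershipMatrix supports genusExclusion = 'prefilter' only")
  nR <- nrow(m)
  n <- ncol(m)

  if (n == 0L) {
    res <- rep.int(8L, nR)
  } else {
    isG <- m == 1L
    isF <- m == 2L
    isFO <- m <= 3L & !isG
    # cumulative non-genus count: position j is among the first k species
    # "excluding hits to other Azospirillum genomes" iff csNG[, j] <= k
    U <- matrix(0L, n, n)
    U[upper.tri(U, diag = TRUE)] <- 1L
    csNG <- (!isG) %*% U
    mNG <- csNG[, n]

    countEx <- function(k, fam) {
      sel <- if (fam) isF else isFO
      rowSums(sel & (csNG <= k))
    }
    countTop <- function(k, codes) {
      cols <- seq_len(min(k, n))
      rowSums(matrix(m[, cols] %in% codes, nrow = nR))
    }

    ordCodes <- if (config@countFocalGenusInAncestral) c(1L, 2L, 3L)
                else c(2L, 3L)
    famCodes <- if (config@countFocalGenusInAncestral) c(1L, 2L) else 2L

    needHigh <- if (n >= config@windowHighAnc) config@thresholdHighAnc
                else max(1L, n - 1L)
    ancHigh <- countTop(config@windowHighAnc, ordCodes) >= needHigh
    hgtHigh <- countEx(config@windowHighHgt, fam = FALSE) == 0L
    ancMed <- countTop(config@windowMedAnc, famCodes) >=
      config@thresholdMedAnc
    hgtMed <- countEx(config@windowMedHgt, fam = FALSE) == 0L
    ancLow <- countEx(config@windowLowAnc, fam = TRUE) >= 1L
    hgtLow <- countEx(config@windowLowHgt, fam = TRUE) == 0L

    res <- integer(nR)
    decided <- mNG == 0L
    res[decided] <- 8L
    step <- function(cond, code) {
      sel <- !decided & cond
      res[sel] <<- code
      decided <<- decided | sel
    }
    step(ancHigh, 1L)
    step(hgtHigh, 2L)
    step(hgtMed & (ancMed | ancLow), 3L)
    step(ancMed, 4L)
    step(hgtMed, 5L)
    step(ancLow, 6L)
    step(hgtLow, 7L)
    res[!decided] <- 8L
  }

  outcomes <- data.frame(
    category = c("ancestral", "hgt", "unassigned", "ancestral", "hgt",
                 "ancestral", "hgt", "unassigned"),
    confidence = c("high", "high", "none", "medium", "medium", "low",
                   "low", "none"),
    rule_fired = c("ancestral_high", "hgt_high",
                   "conflict_hgt_medium_vs_ancestral", "ancestral_medium",
                   "hgt_medium", "ancestral_low", "hgt_low",
                   "no_informative_hits")
  )
  out <- outcomes[res, , drop = FALSE]
  rownames(out) <- NULL
  out
}
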