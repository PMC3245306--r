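#' Filter peptide-spectrum matches and identify proteins
#'
#' DTASelect-style filtering: a PSM passes if its XCorr meets the
#' charge-specific minimum (1.8/2.5/3.5 for +1/+2/+3; charges above +3
#' use the +3 threshold and are flagged), its delta CN is at least 0.08,
#' and it is at least semi-tryptic. All thresholds are inclusive. A
#' protein is identified when at least `minPeptidesPerProtein` distinct
#' passing peptide sequences map to it; shared peptides count toward
#' every protein they map to.
#'
#' @param psms PSM data.frame from [readPsmTable()] or
#'   [simulatePsmTable()].
#' @param cfg a [PsmFilterConfig-class].
#' @return a list: `accepted` (the passing PSMs, with a
#'   `charge_above_3` flag column), `proteins` (data.frame `protein_id`,
#'   `n_peptides`, `spc`, `is_decoy` for identified proteins, decoys
#'   included so downstream decoy accounting stays possible).
#' @export
filterPsms <- function(psms, cfg = psmFilterConfig()) {
  psms <- as.data.frame(psms)
  if (!nrow(psms))
    return(list(accepted = psms,
                proteins = data.frame(protein_id = character(0),
                                      n_peptides = integer(0),
                                      spc = integer(0),
                                      is_decoy = logical(0))))
  if (any(psms$charge < 1L))
    stop("PSM record error: charge must be >= 1")
  chargeIdx <- pmin(psms$charge, 3L)
  xcorrMin <- cfg@xcorrMinByCharge[chargeIdx]
  trypticOk <- if (cfg@trypticRequirement == "fully")
    psms$tryptic_status == "fully"
  else psms$tryptic_status %in% c("fully", "semi")
  pass <- psms$xcorr >= xcorrMin &
    psms$delta_cn >= cfg@deltaCnMin &
    trypticOk
  accepted <- psms[pass, , drop = FALSE]
  accepted$charge_above_3 <- accepted$charge > 3L
  rownames(accepted) <- NULL

  if (nrow(accepted)) {
    byProt <- split(accepted$peptide, accepted$protein_id)
    nPep <- vapply(byProt, function(p) length(unique(p)), integer(1L))
    spc <- vapply(byProt, length, integer(1L))
    ident <- nPep >= cfg@minPeptidesPerProtein
    decoy <- vapply(split(accepted$is_decoy, accepted$protein_id),
                    function(d) any(d), logical(1L))
    proteins <- data.frame(protein_id = names(byProt)[ident],
                           n_peptides = unname(nPep[ident]),
                           spc = unname(spc[ident]),
                           is_decoy = unname(decoy[ident]))
  } else {
    proteins <- data.frame(protein_id = character(0),
                           n_peptides = integer(0), spc = integer(0),
                           is_decoy = logical(0))
  }
  list(accepted = accepted, proteins = proteins)
}

#' Reverse-decoy false-positive rate
#'
#' Percent false positives estimated from reverse-database matches:
#' `%FP = 2 * nReverse / (nReverse + nReal) * 100`. The factor 2 reflects
#' that a decoy match pairs with an expected equal number of incorrect
#' forward matches. Bounded in `[0, 200]`; equals 100% when reverse and
#' real identifications are equally frequent.
#'
#' @param nReverse count of reverse (decoy) identifications.
#' @param nReal count of forward (real) identifications.
#' @return the false-positive rate in percent.
#' @examples
#' fpRate(10, 990)   # 2.0
#' @export
fpRate <- function(nReverse, nReal) {
  stopifnot(nReverse >= 0, nReal >= 0)
  if (nReverse + nReal == 0)
    stop("undefined false-positive rate: no identifications at all")
  200 * nReverse / (nReverse + nReal)
}

#' Normalized spectral abundance factors
#'
#' Converts protein spectral counts into relative abundances:
#' `NSAF_k = (SpC/L)_k / sum_n (SpC/L)_n`, where SpC is the total
#' spectral count of protein k and L its length in residues. NSAF values
#' sum to 1 over the sample and are invariant to rescaling all spectral
#' counts by a constant.
#'
#' @param identifications data.frame with columns `protein_id`, `spc`
#'   (total spectral count, >= 0) and `length` (residues, > 0).
#' @return a data.frame (`protein_id`, `spc`, `length`, `saf`, `nsaf`)
#'   sorted by decreasing `nsaf`.
#' @examples
#' nsaf(data.frame(protein_id = c("a", "b"), spc = c(10, 30),
#'                 length = c(100, 300)))
#' @export
nsaf <- function(identifications) {
  df <- as.data.frame(identifications)
  needed <- c("protein_id", "spc", "length")
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop("identifications need column(s): ", paste(missing, collapse = ", "))
  if (any(df$length <= 0))
    stop("domain error: protein length must be > 0")
  if (any(df$spc < 0))
    stop("domain error: spectral counts must be >= 0")
  if (!nrow(df) || all(df$spc == 0))
    stop("undefined NSAF: all spectral counts are zero")
  df$saf <- df$spc / df$length
  df$nsaf <- df$saf / sum(df$saf)
  df <- df[order(-df$nsaf), c("protein_id", "spc", "length", "saf", "nsaf")]
  rownames(df) <- NULL
  df
}
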