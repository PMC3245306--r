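#' Genome-record statistics
#'
#' Recomputes flat-file-level genome statistics from one or more
#' [GenomeRecord-class] replicons: total length, GC content, CDS and RNA
#' feature counts, and the protein-coding fraction. GC is computed over
#' unambiguous bases only (N and other IUPAC codes are excluded from both
#' numerator and denominator) and rounded half-even to 2 decimals. The
#' coding fraction is reported twice: `coding_percent` merges overlapping
#' CDS intervals per replicon (per-base union) and `coding_percent_raw`
#' sums raw CDS lengths, since annotation pipelines differ on this.
#'
#' @param records a [GenomeRecord-class] or list of them (one per
#'   replicon).
#' @return a one-row data.frame: `n_replicons`, `total_length_bp`,
#'   `gc_percent`, `n_cds`, `coding_percent`, `coding_percent_raw`,
#'   `n_trna`, `n_rrna_genes`.
#' @export
computeGenomeStats <- function(records) {
  if (is(records, "GenomeRecord")) records <- list(records)
  if (!length(records)) stop("need at least one GenomeRecord")
  stopifnot(all(vapply(records, is, logical(1L), "GenomeRecord")))

  lens <- vapply(records, function(r) length(r@sequence), numeric(1L))
  freq <- vapply(records, function(r)
    letterFrequency(r@sequence, c("A", "C", "G", "T")), numeric(4L))
  gcNum <- sum(freq[c("C", "G"), ])
  acgt <- sum(freq)
  gc <- if (acgt > 0) round(100 * gcNum / acgt, 2L) else NA_real_

  featCounts <- vapply(records, function(r) {
    ty <- mcols(r@features)$type
    c(cds = sum(ty == "CDS"), trna = sum(ty == "tRNA"),
      rrna = sum(ty == "rRNA"))
  }, numeric(3L))

  codingUnion <- sum(vapply(records, function(r) {
    cds <- r@features[mcols(r@features)$type == "CDS"]
    if (!length(cds)) return(0)
    sum(width(reduce(ranges(cds))))
  }, numeric(1L)))
  codingRaw <- sum(vapply(records, function(r) {
    cds <- r@features[mcols(r@features)$type == "CDS"]
    if (!length(cds)) return(0)
    sum(width(cds))
  }, numeric(1L)))

  total <- sum(lens)
  data.frame(
    n_replicons = length(records),
    total_length_bp = total,
    gc_percent = gc,
    n_cds = sum(featCounts["cds", ]),
    coding_percent = 100 * codingUnion / total,
    coding_percent_raw = 100 * codingRaw / total,
    n_trna = sum(featCounts["trna", ]),
    n_rrna_genes = sum(featCounts["rrna", ])
  )
}

.pairPrimerSites <- function(fwdStarts, fwdLen, revEnds, revLen,
                             maxProduct) {
  ## exhaustive pairing: every forward site with every reverse site
  ## downstream on the same strand, non-overlapping, within maxProduct
  out <- list()
  for (s in fwdStarts) {
    for (e in revEnds) {
      len <- e - s + 1
      if (len >= fwdLen + revLen && len <= maxProduct)
        out[[length(out) + 1L]] <- c(start = s, end = e, length_bp = len)
    }
  }
  out
}

#' In-silico PCR
#'
#' Locates a primer pair on genome records and reports every implied
#' amplicon. A product is an exact occurrence of the forward primer
#' paired with an exact occurrence of the reverse complement of the
#' reverse primer downstream on the same strand, within `maxProduct` bp;
#' both orientations (the roles of `fwd` and `rev` swapped, i.e. the
#' forward primer annealing to the minus strand) are searched. Product
#' coordinates are 1-based inclusive and include both primers. Exact
#' matching only; degenerate bases in primers are not supported.
#'
#' @param records a [GenomeRecord-class] or list of them.
#' @param fwd,rev primer sequences, 5'->3', over A/C/G/T.
#' @param maxProduct maximum product length in bp (default 10000).
#' @return a data.frame (`replicon_id`, `start`, `end`, `length_bp`,
#'   `fwd_strand`) with one row per product; zero rows when the primers
#'   find no product.
#' @examples
#' gr <- genomeRecord("amp", paste0(strrep("A", 40), "GCGTGGACC",
#'                                  strrep("T", 40), "CGCTCTGAC",
#'                                  strrep("A", 40)))
#' insilicoPcr(gr, "GCGTGGACC", "GTCAGAGCG")   # one 58-bp product
#' @export
insilicoPcr <- function(records, fwd, rev, maxProduct = 10000) {
  if (is(records, "GenomeRecord")) records <- list(records)
  stopifnot(nzchar(fwd), nzchar(rev))
  fwd <- toupper(fwd); rev <- toupper(rev)
  if (grepl("[^ACGT]", fwd) || grepl("[^ACGT]", rev))
    stop("primers must be plain A/C/G/T sequences")
  fwdP <- DNAString(fwd)
  revP <- DNAString(rev)

  rows <- list()
  for (r in records) {
    subject <- r@sequence
    # orientation 1: fwd on plus strand, revcomp(rev) downstream
    # orientation 2: rev on plus strand, revcomp(fwd) downstream
    #                (the forward primer anneals to the minus strand)
    for (orient in 1:2) {
      p1 <- if (orient == 1L) fwdP else revP
      p2 <- if (orient == 1L) revP else fwdP
      s1 <- start(matchPattern(p1, subject))
      e2 <- end(matchPattern(reverseComplement(p2), subject))
      prods <- .pairPrimerSites(s1, length(p1), e2, length(p2), maxProduct)
      for (p in prods)
        rows[[length(rows) + 1L]] <- data.frame(
          replicon_id = r@repliconId, start = p[["start"]],
          end = p[["end"]], length_bp = p[["length_bp"]],
          fwd_strand = if (orient == 1L) "+" else "-")
    }
  }
  if (!length(rows))
    return(data.frame(replicon_id = character(0), start = integer(0),
                      end = integer(0), length_bp = integer(0),
                      fwd_strand = character(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$replicon_id, out$start, out$end), , drop = FALSE]
}
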