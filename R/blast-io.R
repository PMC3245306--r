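#' Read a tabular BLAST hit file (outfmt-6 dialect)
#'
#' Parses a 12-column tab-separated BLAST table (qseqid sseqid pident
#' length mismatch gapopen qstart qend sstart send evalue bitscore),
#' drops hits with e-value above the cutoff, and returns the surviving
#' hits grouped by query. Within a query the file order is preserved and
#' recorded as `rank`; BLAST emits hits in descending bitscore order and
#' that order -- not a re-sort -- defines the classifier's windows.
#'
#' @param path path to the tab-separated hit file. Lines starting with
#'   `#` are ignored. An empty file yields an empty list.
#' @param evalueCutoff hits with e-value strictly above this are removed
#'   (default 1e-4, the cutoff used for ancestry assignment).
#' @return a named list, one element per query (in order of first
#'   appearance), each a data.frame with columns `query_id`, `subject_id`,
#'   `percent_identity`, `aln_length`, `evalue`, `bitscore`, `rank`.
#'   Queries whose hits are all filtered out map to a zero-row data.frame.
#' @examples
#' f <- tempfile()
#' writeLines(c("g1\tsubA\t90\t100\t5\t0\t1\t100\t1\t100\t1e-30\t200",
#'              "g1\tsubB\t80\t100\t9\t0\t1\t100\t1\t100\t2e-3\t80"), f)
#' readBlastTab(f)          # subB removed by the 1e-4 cutoff
#' @export
readBlastTab <- function(path, evalueCutoff = 1e-4) {
  stopifnot(is.numeric(evalueCutoff), length(evalueCutoff) == 1L,
            evalueCutoff > 0)
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  lineNo <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) return(setNames(list(), character(0)))

  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 12L)) {
    bad <- lineNo[which(nf < 12L)[1L]]
    stop(sprintf("malformed BLAST row at line %d: expected >= 12 tab-separated columns, got %d",
                 bad, nf[which(nf < 12L)[1L]]))
  }
  m <- vapply(parts, function(p) p[1:12], character(12L))
  query <- m[1L, ]
  evalue <- suppressWarnings(as.numeric(m[11L, ]))
  if (anyNA(evalue)) {
    bad <- lineNo[which(is.na(evalue))[1L]]
    stop(sprintf("malformed BLAST row at line %d: non-numeric e-value '%s'",
                 bad, m[11L, which(is.na(evalue))[1L]]))
  }
  pident <- suppressWarnings(as.numeric(m[3L, ]))
  alen <- suppressWarnings(as.integer(m[4L, ]))
  bits <- suppressWarnings(as.numeric(m[12L, ]))
  if (anyNA(pident) || anyNA(alen) || anyNA(bits)) {
    bad <- lineNo[which(is.na(pident) | is.na(alen) | is.na(bits))[1L]]
    stop(sprintf("malformed BLAST row at line %d: non-numeric field", bad))
  }
  if (any(!nzchar(query)))
    stop(sprintf("malformed BLAST row at line %d: empty query id",
                 lineNo[which(!nzchar(query))[1L]]))

  hits <- data.frame(
    query_id = query, subject_id = m[2L, ], percent_identity = pident,
    aln_length = alen, evalue = evalue, bitscore = bits,
    stringsAsFactors = FALSE
  )
  queries <- unique(query)
  pass <- hits$evalue <= evalueCutoff
  out <- lapply(queries, function(q) {
    h <- hits[hits$query_id == q & pass, , drop = FALSE]
    h$rank <- seq_len(nrow(h))
    rownames(h) <- NULL
    h
  })
  names(out) <- queries
  out
}

#' Write hit tables as a tabular BLAST file
#'
#' Emits the 12-column outfmt-6 dialect that [readBlastTab()] consumes.
#' Fields the in-memory representation does not carry (mismatches, gap
#' opens, coordinates) are filled with consistent placeholders derived
#' from the alignment length.
#'
#' @param hitTables a named list of per-query hit data.frames as returned
#'   by [readBlastTab()] or [simulateHitTables()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeBlastTab <- function(hitTables, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (h in hitTables) {
    if (!nrow(h)) next
    mm <- round(h$aln_length * (100 - h$percent_identity) / 100)
    rows <- sprintf("%s\t%s\t%.2f\t%d\t%d\t0\t1\t%d\t1\t%d\t%s\t%.1f",
                    h$query_id, h$subject_id, h$percent_identity,
                    h$aln_length, as.integer(mm), h$aln_length,
                    h$aln_length, format(h$evalue, scientific = TRUE),
                    h$bitscore)
    writeLines(rows, con)
  }
  invisible(path)
}
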