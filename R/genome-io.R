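## Resolve a flat-file location string ("complement(join(10..20,30..40))",
## "<1..>200", "join(5..10,20..30)") to (start, end, strand). Compound
## locations collapse to their min-start/max-end envelope.
.parseLocation <- function(loc) {
  strand <- if (grepl("complement", loc, fixed = TRUE)) "-" else "+"
  clean <- gsub("[<>]", "", loc)
  nums <- regmatches(clean, gregexpr("[0-9]+", clean))[[1L]]
  if (!length(nums)) return(NULL)
  pos <- suppressWarnings(as.numeric(nums))
  if (anyNA(pos)) return(NULL)
  list(start = min(pos), end = max(pos), strand = strand)
}

.FEATURE_TYPES <- c(CDS = "CDS", tRNA = "tRNA", rRNA = "rRNA")

#' Read an annotated genome flat file (GenBank or EMBL dialect)
#'
#' Parses one record from a GenBank- (`LOCUS`/`FEATURES`/`ORIGIN`) or
#' EMBL-style (`ID`/`FT`/`SQ`) flat file into a [GenomeRecord-class].
#' CDS, tRNA and rRNA features are typed as such; any other feature key
#' except the full-length `source` feature becomes `other`. Compound
#' locations (`join`, `order`, `complement`) are resolved to their
#' min-start/max-end envelope with strand from `complement`. Coordinates
#' are 1-based inclusive. A feature whose location cannot be parsed is
#' skipped with a warning; a record with no sequence block is an error.
#'
#' @param path path to the flat file. Only the first record of a
#'   multi-record file is read (with a warning).
#' @return a [GenomeRecord-class] with upper-cased sequence.
#' @export
readGenomeFlatfile <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) stop("flat-file format error: empty file")
  first <- lines[nzchar(trimws(lines))][1L]
  dialect <- if (startsWith(first, "LOCUS")) "genbank"
             else if (startsWith(first, "ID")) "embl"
             else stop("flat-file format error: expected a LOCUS (GenBank) or ID (EMBL) header line")

  recEnd <- which(trimws(lines) == "//")
  if (length(recEnd) > 1L)
    warning("multi-record flat file: only the first record is read")
  if (length(recEnd)) lines <- lines[seq_len(recEnd[1L])]

  if (dialect == "genbank") {
    id <- strsplit(trimws(first), "[[:space:]]+")[[1L]][2L]
    featStart <- grep("^FEATURES", lines)
    seqStart <- grep("^ORIGIN", lines)
    if (!length(seqStart))
      stop("flat-file format error: missing ORIGIN sequence block")
    featLines <- if (length(featStart))
      lines[(featStart[1L] + 1L):(seqStart[1L] - 1L)] else character(0)
    seqLines <- lines[(seqStart[1L] + 1L):length(lines)]
    isFeat <- grepl("^ {5}\\S", featLines)
    contOk <- grepl("^ {21}", featLines) & !grepl("^ *\\/", trimws(featLines))
  } else {
    id <- strsplit(trimws(first), "[[:space:]]+")[[1L]][2L]
    id <- sub(";$", "", id)
    seqStart <- grep("^SQ", lines)
    if (!length(seqStart))
      stop("flat-file format error: missing SQ sequence block")
    featLines <- grep("^FT", lines, value = TRUE)
    featLines <- substring(featLines, 3L)  # strip the FT tag, keep spacing
    seqLines <- lines[(seqStart[1L] + 1L):length(lines)]
    isFeat <- grepl("^ {3}\\S", featLines)
    contOk <- grepl("^ {10,}", featLines) & !grepl("^\\/", trimws(featLines))
  }

  seqChars <- gsub("[^A-Za-z]", "", paste(seqLines, collapse = ""))
  if (!nzchar(seqChars))
    stop("flat-file format error: empty sequence block")

  types <- character(0); starts <- numeric(0); ends <- numeric(0)
  strands <- character(0)
  i <- 1L
  n <- length(featLines)
  while (i <= n) {
    if (isFeat[i]) {
      fields <- strsplit(trimws(featLines[i]), "[[:space:]]+")[[1L]]
      key <- fields[1L]
      loc <- if (length(fields) > 1L)
        paste(fields[-1L], collapse = "") else ""
      j <- i + 1L
      # a location continues onto the next line while its parentheses are
      # unbalanced or it ends with a comma; qualifier lines never qualify
      unbalanced <- function(s) {
        chars <- strsplit(s, "")[[1L]]
        sum(chars == "(") != sum(chars == ")") || grepl(",$", s)
      }
      while (j <= n && !isFeat[j] && contOk[j] && unbalanced(loc)) {
        loc <- paste0(loc, trimws(featLines[j]))
        j <- j + 1L
      }
      # skip this feature's qualifier lines
      while (j <= n && !isFeat[j]) j <- j + 1L
      if (key != "source") {
        parsed <- .parseLocation(loc)
        if (is.null(parsed)) {
          warning(sprintf("skipping feature '%s' with unparseable location '%s'",
                          key, loc))
        } else {
          types <- c(types, if (key %in% names(.FEATURE_TYPES))
            .FEATURE_TYPES[[key]] else "other")
          starts <- c(starts, parsed$start)
          ends <- c(ends, parsed$end)
          strands <- c(strands, parsed$strand)
        }
      }
      i <- j
    } else {
      i <- i + 1L
    }
  }

  feats <- if (length(types))
    data.frame(type = types, start = starts, end = ends, strand = strands)
  else NULL
  genomeRecord(repliconId = id, sequence = seqChars, features = feats)
}
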