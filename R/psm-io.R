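.TRYPTIC_LEVELS <- c("fully", "semi", "non")

#' Read a peptide-spectrum-match (PSM) table
#'
#' Loads a TSV with columns `peptide`, `protein_id`, `charge`, `xcorr`,
#' `delta_cn`, `tryptic_status`, `is_decoy`. `tryptic_status` must be one
#' of `fully`, `semi`, `non`; `is_decoy` is `TRUE`/`FALSE`. A missing
#' `tryptic_status` column is an error unless `defaultTryptic = TRUE`, in
#' which case every PSM is taken as fully tryptic -- note the semi-tryptic
#' filter is then vacuous, which is why defaulting is opt-in.
#'
#' @param path path to the TSV file.
#' @param defaultTryptic allow a missing `tryptic_status` column,
#'   defaulting it to `"fully"` (default FALSE).
#' @return a data.frame of PSM records.
#' @export
readPsmTable <- function(path, defaultTryptic = FALSE) {
  tab <- read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
  needed <- c("peptide", "protein_id", "charge", "xcorr", "delta_cn",
              "is_decoy")
  missing <- setdiff(needed, names(tab))
  if (length(missing))
    stop("PSM table schema error: missing column(s) ",
         paste(missing, collapse = ", "))
  if (!"tryptic_status" %in% names(tab)) {
    if (!defaultTryptic)
      stop("PSM table schema error: missing tryptic_status column ",
           "(set defaultTryptic = TRUE to assume fully tryptic)")
    tab$tryptic_status <- "fully"
  }
  bad <- setdiff(unique(tab$tryptic_status), .TRYPTIC_LEVELS)
  if (length(bad))
    stop("PSM table schema error: unknown tryptic_status token(s): ",
         paste(bad, collapse = ", "))
  tab$charge <- as.integer(tab$charge)
  tab$xcorr <- as.numeric(tab$xcorr)
  tab$delta_cn <- as.numeric(tab$delta_cn)
  tab$is_decoy <- as.logical(tab$is_decoy)
  if (any(tab$charge < 1L, na.rm = TRUE) || anyNA(tab$charge))
    stop("PSM table record error: charge must be an integer >= 1")
  if (any(tab$delta_cn < 0, na.rm = TRUE))
    stop("PSM table record error: delta_cn must be >= 0")
  tab[, c("peptide", "protein_id", "charge", "xcorr", "delta_cn",
          "tryptic_status", "is_decoy"), drop = FALSE]
}

#' @rdname readPsmTable
#' @param psms a PSM data.frame as returned by `readPsmTable()`.
#' @export
writePsmTable <- function(psms, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("# azohgt PSM table", con)
  suppressWarnings(write.table(psms, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  invisible(path)
}

#' Write and read ancestry call tables
#'
#' Persists the per-gene ancestry calls of [classifyGenome()] as a TSV
#' with commented header lines, columns `query_id`, `category`,
#' `confidence`, `rule_fired`, `evidence_json`. `readCallsTable()`
#' round-trips the file back into the same `DataFrame` layout.
#'
#' @param calls a `DataFrame`/data.frame of ancestry calls.
#' @param path output (or input) path.
#' @return `writeCallsTable()` returns `path` invisibly;
#'   `readCallsTable()` returns a `DataFrame` of calls.
#' @export
writeCallsTable <- function(calls, path) {
  calls <- as.data.frame(calls)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c("# azohgt ancestry calls",
               "# category: ancestral | hgt | unassigned; confidence: high | medium | low | none"),
             con)
  suppressWarnings(write.table(calls, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  invisible(path)
}

#' @rdname writeCallsTable
#' @export
readCallsTable <- function(path) {
  tab <- read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                    quote = "", stringsAsFactors = FALSE)
  needed <- c("query_id", "category", "confidence", "rule_fired")
  missing <- setdiff(needed, names(tab))
  if (length(missing))
    stop("calls table schema error: missing column(s) ",
         paste(missing, collapse = ", "))
  DataFrame(tab)
}
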