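#' Read a subject-to-taxonomy mapping table
#'
#' Loads a tab-separated table with header columns `subject_key`,
#' `species`, `genus`, `family`, `order` mapping each BLAST subject
#' identifier (or species) to its lineage labels. Species names are
#' binomial: strains of one species share a species label and collapse
#' during neighborhood deduplication.
#'
#' @param path path to the TSV file. Lines starting with `#` before the
#'   header are ignored.
#' @return a data.frame keyed by `subject_key` (also its rownames) with
#'   the five schema columns.
#' @examples
#' f <- tempfile()
#' writeLines(c("subject_key\tspecies\tgenus\tfamily\torder",
#'              "s1\tRhodospirillum rubrum\tRhodospirillum\tRhodospirillaceae\tRhodospirillales"),
#'            f)
#' readTaxonomyTable(f)
#' @export
readTaxonomyTable <- function(path) {
  tab <- read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, colClasses = "character")
  needed <- c("subject_key", "species", "genus", "family", "order")
  missing <- setdiff(needed, names(tab))
  if (length(missing))
    stop("taxonomy table schema error: missing column(s) ",
         paste(missing, collapse = ", "))
  tab <- tab[, needed, drop = FALSE]
  if (nrow(tab)) {
    dup <- tab$subject_key[duplicated(tab$subject_key)]
    if (length(dup))
      stop("duplicate subject_key in taxonomy table: ",
           paste(unique(dup), collapse = ", "))
    empty <- which(apply(tab == "" | is.na(tab), 1L, any))
    if (length(empty))
      stop("taxonomy table row ", empty[1L], " has an empty lineage field")
    rownames(tab) <- tab$subject_key
  }
  tab
}

## The classical 25 one-letter COG functional categories.
.COG_ALPHABET <- c("J", "A", "K", "L", "B", "D", "Y", "V", "T", "M", "N",
                   "Z", "W", "U", "O", "C", "G", "E", "F", "H", "I", "P",
                   "Q", "R", "S")

#' Read a gene-to-COG-category map
#'
#' Loads a two-column TSV (`gene_id`, `category`) assigning each gene a
#' one-letter COG functional category. Categories outside the 25-letter
#' COG alphabet are rejected.
#'
#' @param path path to the TSV file (header required).
#' @return a data.frame with columns `gene_id` and `category`.
#' @export
readCogMap <- function(path) {
  tab <- read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, colClasses = "character")
  missing <- setdiff(c("gene_id", "category"), names(tab))
  if (length(missing))
    stop("COG map schema error: missing column(s) ",
         paste(missing, collapse = ", "))
  bad <- setdiff(unique(tab$category), .COG_ALPHABET)
  if (length(bad))
    stop("COG map contains non-COG category letter(s): ",
         paste(bad, collapse = ", "))
  tab[, c("gene_id", "category"), drop = FALSE]
}
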