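#' Assign a chemotaxis class from CheA model scores
#'
#' Given one sequence's scores against class-specific CheA models (F5,
#' F7, F8, F9, ACF, ...) and against the all-CheA model, assigns the
#' class of the top-scoring class model, or `"Unc"` (unclassified) when
#' the full-set model strictly outscores every class model. Ties among
#' class scores are broken lexicographically with a warning. Scores must
#' share one scale where higher is better (e.g. HMM bit scores).
#'
#' @param classScores named numeric vector of class-model scores; at
#'   least one score required.
#' @param fullSetScore score against the all-CheA model.
#' @return a single class label, or `"Unc"`.
#' @examples
#' classifyChea(c(F7 = 310.2, F5 = 120.0), fullSetScore = 250.0)  # "F7"
#' classifyChea(c(F7 = 100), fullSetScore = 150)                  # "Unc"
#' @export
classifyChea <- function(classScores, fullSetScore) {
  if (!length(classScores)) stop("need at least one class score")
  if (is.null(names(classScores)) || any(!nzchar(names(classScores))))
    stop("class scores must be named with class labels")
  best <- max(classScores)
  if (fullSetScore > best) return("Unc")
  winners <- sort(names(classScores)[classScores == best])
  if (length(winners) > 1L)
    warning("tie among class models (", paste(winners, collapse = ", "),
            "); choosing '", winners[1L], "' lexicographically")
  winners[1L]
}

#' Classify a CheA score table
#'
#' Applies [classifyChea()] to every row of a score table with one
#' column per model.
#'
#' @param scores data.frame with a `sequence_id` column, one numeric
#'   column per class model, and a full-set column.
#' @param fullSetColumn name of the all-CheA model column (default
#'   `"full_set"`).
#' @return a data.frame (`sequence_id`, `assigned_class`).
#' @export
classifyCheaTable <- function(scores, fullSetColumn = "full_set") {
  stopifnot("sequence_id" %in% names(scores))
  if (!fullSetColumn %in% names(scores))
    stop("full-set score column '", fullSetColumn, "' not found")
  classCols <- setdiff(names(scores), c("sequence_id", fullSetColumn))
  if (!length(classCols)) stop("no class-model score columns found")
  assigned <- vapply(seq_len(nrow(scores)), function(i) {
    cs <- unlist(scores[i, classCols, drop = FALSE])
    classifyChea(setNames(as.numeric(cs), classCols),
                 as.numeric(scores[[fullSetColumn]][i]))
  }, character(1L))
  data.frame(sequence_id = scores$sequence_id, assigned_class = assigned)
}

#' @rdname classifyCheaTable
#' @param path path to a TSV score table with header.
#' @export
readCheaScores <- function(path) {
  tab <- read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
  if (!"sequence_id" %in% names(tab))
    stop("CheA score table schema error: missing sequence_id column")
  tab
}
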