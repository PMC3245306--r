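# Shared fixture builders: everything is generated in code at test time.

# A small taxonomy data.frame keyed the way readTaxonomyTable() returns it.
makeTaxonomy <- function() {
  tax <- data.frame(
    subject_key = c("self", "azo2", "mag1", "mag2", "mag3", "rho1", "rho2",
                    "nis1", "ace1", "rhizo1", "burk1", "eco1"),
    species = c("Azospirillum lipoferum", "Azospirillum brasilense",
                "Magnetospirillum magneticum",
                "Magnetospirillum gryphiswaldense",
                "Magnetospirillum magnetotacticum",
                "Rhodospirillum rubrum", "Rhodospirillum centenum",
                "Nisaea sp. BAL199", "Acetobacter pasteurianus",
                "Rhizobium etli", "Burkholderia xenovorans",
                "Escherichia coli"),
    genus = c("Azospirillum", "Azospirillum", "Magnetospirillum",
              "Magnetospirillum", "Magnetospirillum", "Rhodospirillum",
              "Rhodospirillum", "Nisaea", "Acetobacter", "Rhizobium",
              "Burkholderia", "Escherichia"),
    family = c(rep("Rhodospirillaceae", 8), "Acetobacteraceae",
               "Rhizobiaceae", "Burkholderiaceae", "Enterobacteriaceae"),
    order = c(rep("Rhodospirillales", 9), "Rhizobiales", "Burkholderiales",
              "Enterobacterales")
  )
  rownames(tax) <- tax$subject_key
  tax
}

# Minimal hit table for one query over the given subject keys.
makeHits <- function(queryId, subjectKeys) {
  n <- length(subjectKeys)
  data.frame(
    query_id = rep(queryId, n), subject_id = subjectKeys,
    percent_identity = 90 - seq_len(n), aln_length = 200L,
    evalue = 10^(-50 + seq_len(n)), bitscore = 400 - 10 * seq_len(n),
    rank = seq_len(n)
  )
}

# Write a 12-column outfmt-6 line.
blastLine <- function(q, s, evalue, bits = 200, pident = 90) {
  sprintf("%s\t%s\t%.1f\t150\t10\t0\t1\t150\t1\t150\t%s\t%.1f",
          q, s, pident, format(evalue, scientific = TRUE), bits)
}

# A minimal GenBank-dialect record as a character vector of lines.
makeGenbankLines <- function(id = "TESTREC", seq = strrep("acgt", 30),
                             featureLines = character(0)) {
  n <- nchar(seq)
  c(sprintf("LOCUS       %s             %d bp    DNA     linear   BCT", id, n),
    "DEFINITION  synthetic test record.",
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", n),
    featureLines,
    "ORIGIN",
    vapply(seq(1L, n, by = 60L), function(i) {
      sprintf("%9d %s", i, substr(seq, i, min(i + 59L, n)))
    }, character(1L)),
    "//")
}

# Independent two-sided Fisher p-value by exhaustive hypergeometric
# enumeration over all tables with the observed margins.
enumFisherP <- function(a, b, c, d) {
  m <- a + b          # row 1 total
  n <- c + d          # row 2 total
  k <- a + c          # column 1 total
  lo <- max(0L, k - n)
  hi <- min(k, m)
  probs <- vapply(lo:hi, function(x)
    choose(m, x) * choose(n, k - x) / choose(m + n, k), numeric(1L))
  pObs <- probs[a - lo + 1L]
  sum(probs[probs <= pObs * (1 + 1e-7)])
}
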