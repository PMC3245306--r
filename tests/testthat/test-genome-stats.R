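test_that("computeGenomeStats on constructed records", {
  gr <- genomeRecord("r1", strrep("ATGC", 25),
                     data.frame(type = "CDS", start = 1, end = 60,
                                strand = "+"))
  st <- computeGenomeStats(gr)
  expect_equal(st$total_length_bp, 100)
  expect_equal(st$gc_percent, 50.00)
  expect_equal(st$coding_percent, 60.0)
  expect_equal(st$n_cds, 1L)

  # overlapping CDS merge to their union, raw sum reported separately
  gr <- genomeRecord("r1", strrep("ATGC", 25),
                     data.frame(type = c("CDS", "CDS"),
                                start = c(1, 41), end = c(50, 90),
                                strand = "+"))
  st <- computeGenomeStats(gr)
  expect_equal(st$coding_percent, 90.0)
  expect_equal(st$coding_percent_raw, 100.0)

  # N excluded from both GC numerator and denominator
  gr <- genomeRecord("r1", strrep("ATGCN", 20))
  expect_equal(computeGenomeStats(gr)$gc_percent, 50.00)

  expect_error(computeGenomeStats(list()), "at least one")
})

test_that("stats over a record list equal the merge of per-record stats", {
  g <- simulateGenomeWithPrimers(simConfig(seed = 3))
  r1 <- g$record
  r2 <- genomeRecord("r2", strrep("GGCC", 500),
                     data.frame(type = c("CDS", "tRNA"),
                                start = c(1, 1001), end = c(800, 1080),
                                strand = "+"))
  both <- computeGenomeStats(list(r1, r2))
  s1 <- computeGenomeStats(r1); s2 <- computeGenomeStats(r2)
  expect_equal(both$total_length_bp, s1$total_length_bp + s2$total_length_bp)
  expect_equal(both$n_cds, s1$n_cds + s2$n_cds)
  expect_equal(both$n_trna, s1$n_trna + s2$n_trna)
  # GC merges via base counts, not averaged percentages
  gc1 <- s1$gc_percent * s1$total_length_bp
  gc2 <- s2$gc_percent * s2$total_length_bp
  expect_equal(both$gc_percent,
               round((gc1 + gc2) / both$total_length_bp, 2))
  # coding union merges additively across replicons
  expect_equal(both$coding_percent * both$total_length_bp,
               s1$coding_percent * s1$total_length_bp +
                 s2$coding_percent * s2$total_length_bp,
               tolerance = 1e-9)
})

test_that("coding union equals a per-base occupancy scan", {
  set.seed(41)
  for (rep in 1:5) {
    L <- 2000L
    nCds <- sample(3:8, 1)
    starts <- sort(sample(seq_len(L - 100L), nCds))
    ends <- pmin(L, starts + sample(50:400, nCds, replace = TRUE))
    gr <- genomeRecord("r", paste(sample(c("A", "C", "G", "T"), L,
                                         replace = TRUE), collapse = ""),
                       data.frame(type = "CDS", start = starts, end = ends,
                                  strand = "+"))
    st <- computeGenomeStats(gr)
    covered <- logical(L)
    for (i in seq_len(nCds)) covered[starts[i]:ends[i]] <- TRUE
    expect_equal(st$coding_percent, 100 * sum(covered) / L)
  }
})

test_that("insilicoPcr finds planted products and exhausts pairings", {
  fwd <- "GCGTGGACCTGATCCTGAC"
  rev <- "GTGACCGTCTCGCTCTGAC"
  revSite <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(rev)))
  # plant fwd at 41..59, reverse site ending at 251: product length 211
  seq <- paste(rep("A", 300), collapse = "")
  substr(seq, 41, 59) <- fwd
  substr(seq, 233, 251) <- revSite
  gr <- genomeRecord("amp", seq)
  prod <- insilicoPcr(gr, fwd, rev)
  expect_equal(nrow(prod), 1L)
  expect_equal(prod$start, 41)
  expect_equal(prod$end, 251)
  expect_equal(prod$length_bp, 211)
  expect_equal(prod$fwd_strand, "+")

  # absent primers -> empty
  expect_equal(nrow(insilicoPcr(gr, "ACACACACACAC", rev)), 0L)

  # two forward sites upstream of one reverse site -> two products
  seq2 <- paste0(strrep("T", 10), fwd, strrep("T", 30), fwd,
                 strrep("T", 30), revSite, strrep("T", 10))
  prod2 <- insilicoPcr(genomeRecord("amp2", seq2), fwd, rev)
  expect_equal(nrow(prod2), 2L)
  expect_equal(sort(prod2$start), c(11, 60))
  expect_equal(unique(prod2$end), 127)

  # products farther apart than maxProduct are not reported
  expect_equal(nrow(insilicoPcr(gr, fwd, rev, maxProduct = 100)), 0L)
})

test_that("reverse-complementing a record mirrors PCR products, keeps stats", {
  g <- simulateGenomeWithPrimers(simConfig(seed = 19))
  rec <- g$record
  fwd <- "GCGTGGACCTGATCCTGAC"; rev <- "GTGACCGTCTCGCTCTGAC"
  st <- computeGenomeStats(rec)
  p <- insilicoPcr(rec, fwd, rev)

  L <- length(rec)
  rcSeq <- as.character(Biostrings::reverseComplement(genomeSequence(rec)))
  ft <- as.data.frame(genomeFeatures(rec))
  rcFeat <- data.frame(type = ft$type, start = L - ft$end + 1L,
                       end = L - ft$start + 1L,
                       strand = ifelse(ft$strand == "+", "-", "+"))
  rcRec <- genomeRecord(repliconId(rec), rcSeq, rcFeat)
  rcSt <- computeGenomeStats(rcRec)
  expect_equal(rcSt$total_length_bp, st$total_length_bp)
  expect_equal(rcSt$gc_percent, st$gc_percent)
  expect_equal(rcSt$n_cds, st$n_cds)

  rcP <- insilicoPcr(rcRec, fwd, rev)
  expect_equal(nrow(rcP), nrow(p))
  expect_equal(rcP$length_bp, p$length_bp)
  expect_equal(sort(L - p$end + 1L), sort(rcP$start))
})
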