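psm <- function(peptide = "PEPTIDEK", protein = "P1", charge = 2L,
                xcorr = 3, deltaCn = 0.2, tryptic = "fully",
                decoy = FALSE) {
  data.frame(peptide = peptide, protein_id = protein, charge = charge,
             xcorr = xcorr, delta_cn = deltaCn, tryptic_status = tryptic,
             is_decoy = decoy)
}

test_that("PSM filter thresholds are inclusive and charge-aware", {
  # exactly at every threshold for +2, semi-tryptic: passes
  atBoundary <- psm(charge = 2L, xcorr = 2.5, deltaCn = 0.08,
                    tryptic = "semi")
  expect_equal(nrow(filterPsms(atBoundary)$accepted), 1L)
  # each criterion just below threshold: fails
  expect_equal(nrow(filterPsms(psm(charge = 1L, xcorr = 1.79))$accepted), 0L)
  expect_equal(nrow(filterPsms(psm(xcorr = 2.49, charge = 2L))$accepted), 0L)
  expect_equal(nrow(filterPsms(psm(deltaCn = 0.079))$accepted), 0L)
  expect_equal(nrow(filterPsms(psm(tryptic = "non"))$accepted), 0L)
  # per-charge minima
  expect_equal(nrow(filterPsms(psm(charge = 1L, xcorr = 1.8))$accepted), 1L)
  expect_equal(nrow(filterPsms(psm(charge = 3L, xcorr = 3.49))$accepted), 0L)
  expect_equal(nrow(filterPsms(psm(charge = 3L, xcorr = 3.5))$accepted), 1L)
  # charges above +3 use the +3 threshold and are flagged
  res <- filterPsms(psm(charge = 4L, xcorr = 3.5))
  expect_equal(nrow(res$accepted), 1L)
  expect_true(res$accepted$charge_above_3)
  expect_error(filterPsms(psm(charge = 0L)), "charge")
})

test_that("a protein needs two distinct passing peptides", {
  one <- psm()
  expect_equal(nrow(filterPsms(one)$proteins), 0L)
  # two PSMs of the SAME peptide still count once
  two_same <- rbind(psm(), psm())
  expect_equal(nrow(filterPsms(two_same)$proteins), 0L)
  two_diff <- rbind(psm(), psm(peptide = "OTHERPEPK"))
  prot <- filterPsms(two_diff)$proteins
  expect_equal(prot$protein_id, "P1")
  expect_equal(prot$n_peptides, 2L)
  expect_equal(prot$spc, 2L)
})

test_that("filterPsms reproduces generator truth and is idempotent", {
  sim <- simulatePsmTable(simConfig(seed = 8, nPsms = 500))
  res <- filterPsms(sim$psms)
  expect_equal(nrow(res$accepted), sum(sim$truth))
  expect_equal(res$accepted$peptide, sim$psms$peptide[sim$truth])
  # idempotence: filtering the accepted set changes nothing
  again <- filterPsms(res$accepted[, names(sim$psms)])
  expect_equal(again$accepted[, names(sim$psms)],
               res$accepted[, names(sim$psms)])
})

test_that("fpRate implements the doubled decoy fraction", {
  expect_equal(fpRate(10, 990), 2.0)
  expect_equal(fpRate(0, 500), 0.0)
  fp <- fpRate(21, 979)
  expect_equal(fp, 4.2)
  expect_true(fp >= 1.4 && fp <= 4.3)   # inside the reported range
  expect_equal(fpRate(50, 50), 100)
  expect_equal(fpRate(5, 0), 200)       # upper bound
  expect_error(fpRate(0, 0), "undefined")
})

test_that("decoys that fail the filter contribute nothing to the FP rate", {
  sim <- simulatePsmTable(simConfig(seed = 30, nPsms = 300))
  psms <- sim$psms
  psms$xcorr[psms$is_decoy] <- 0.1   # force every decoy below threshold
  acc <- filterPsms(psms)$accepted
  expect_equal(fpRate(sum(acc$is_decoy), sum(!acc$is_decoy)), 0)
})

test_that("NSAF normalizes, sorts, and matches a two-pass oracle", {
  res <- nsaf(data.frame(protein_id = c("a", "b"), spc = c(10, 30),
                         length = c(100, 300)))
  expect_equal(res$nsaf, c(0.5, 0.5))

  expect_equal(nsaf(data.frame(protein_id = "only", spc = 5,
                               length = 123))$nsaf, 1.0)

  set.seed(12)
  ids <- data.frame(protein_id = sprintf("P%02d", 1:50),
                    spc = rpois(50, 20), length = sample(80:900, 50))
  ids$spc[1] <- max(ids$spc) + 5   # ensure a nonzero and a clear max
  res <- nsaf(ids)
  expect_equal(sum(res$nsaf), 1, tolerance = 1e-9)
  expect_true(all(diff(res$nsaf) <= 1e-12))
  # independent two-pass computation
  saf <- ids$spc / ids$length
  want <- (saf / sum(saf))[match(res$protein_id, ids$protein_id)]
  expect_equal(res$nsaf, want, tolerance = 1e-12)
  # scale invariance
  ids2 <- ids; ids2$spc <- ids2$spc * 7
  expect_equal(nsaf(ids2)$nsaf, res$nsaf, tolerance = 1e-12)

  expect_error(nsaf(data.frame(protein_id = "x", spc = 1, length = 0)),
               "length")
  expect_error(nsaf(data.frame(protein_id = "x", spc = 0, length = 10)),
               "zero")
})
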