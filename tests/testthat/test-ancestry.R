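# Rule-by-rule cases: each row is (membership string, category, confidence),
# with G = other focal-genus, F = family non-genus, O = order non-family,
# X = outside the order.
ruleCases <- list(
  list("FFFFFFXX", "ancestral", "high"),    # 6 of top 8 in the order
  list("OOOFFFXX", "ancestral", "high"),
  list("XXXXXXXXXX", "hgt", "high"),        # 0 order in top 10
  list("OOOX", "ancestral", "high"),        # all but 1 on a short list
  list("XXXXXFXX", "unassigned", "none"),   # hgt-medium + ancestral-low
  list("FFFFXXXX", "ancestral", "medium"),  # 4 family in top 8
  list("XXXXXXXXXF", "hgt", "medium"),      # F at rank 10 blocks hgt-high
  list("XXXXOXXX", "hgt", "low"),           # order blocks hgt-med, no family
  list("", "unassigned", "none"),
  list("GGG", "unassigned", "none"),        # nothing outside the focal genus
  list("XXXXOFXX", "ancestral", "low")      # family at rank 6, order at 5
)

test_that("classifyMembership reproduces the published rule outcomes", {
  for (case in ruleCases) {
    memb <- strsplit(case[[1]], "")[[1]]
    got <- classifyMembership(memb)
    expect_equal(got$category, case[[2]], label = case[[1]])
    expect_equal(got$confidence, case[[3]], label = case[[1]])
  }
})

test_that("genus hits are excluded before windowing in hgt/low rules", {
  # 5 genus hits then a family hit. With genus counting disabled the
  # short-list ancestral-high rule fails, and after prefilter removal the
  # family hit sits at genus-excluded rank 1, blocking every hgt rule:
  # the call is ancestral-low, not hgt
  cfgNoG <- ancestryConfig(countFocalGenusInAncestral = FALSE)
  got <- classifyMembership(c("G", "G", "G", "G", "G", "F"), cfgNoG)
  expect_equal(got$category, "ancestral")
  expect_equal(got$confidence, "low")
  # under the default, genus species count toward the ancestral tally
  # and the same list is ancestral-high (6 of 6, all but 1 satisfied)
  expect_equal(classifyMembership(c("G", "G", "G", "G", "G", "F"))$confidence,
               "high")
})

test_that("the genus-counting flag flips ancestral tallies", {
  memb <- c("G", "G", "F", "F", "X", "X", "X", "X")
  withG <- classifyMembership(memb)                 # 4 family in top 8
  expect_equal(withG$confidence, "medium")
  noG <- classifyMembership(memb,
    ancestryConfig(countFocalGenusInAncestral = FALSE))
  expect_false(identical(noG$rule, "ancestral_medium"))
})

test_that("the medium/medium conflict is unassigned", {
  # 4 genus hits satisfy ancestral-medium (genus counts by default) while
  # the genus-excluded top 5 holds no order member: simultaneous
  # hgt-medium and ancestral-medium must be unassigned. The order member
  # at genus-excluded rank 6 keeps hgt-high from firing first.
  got <- classifyMembership(c("G", "G", "G", "G", "X", "X", "X", "X",
                              "X", "O"))
  expect_equal(got$category, "unassigned")
  expect_equal(got$rule, "conflict_hgt_medium_vs_ancestral")
})

test_that("buildNeighborhood removes self and deduplicates species", {
  tax <- makeTaxonomy()
  nb <- buildNeighborhood(makeHits("g1", c("self", "mag1", "mag1", "rho1")),
                          tax)
  expect_equal(speciesSeq(nb)$species,
               c("Magnetospirillum magneticum", "Rhodospirillum rubrum"))

  # all hits to self -> empty neighborhood, call unassigned
  nb <- buildNeighborhood(makeHits("g1", c("self", "self")), tax)
  expect_length(nb, 0L)
  expect_equal(classifyAncestry(nb)$category, "unassigned")

  # unresolvable subject ids error (or warn under lenient)
  expect_error(buildNeighborhood(makeHits("g1", c("self", "nope")), tax),
               "nope")
  expect_warning(
    nb <- buildNeighborhood(makeHits("g1", c("mag1", "nope")), tax,
                            lenient = TRUE), "nope")
  expect_length(nb, 1L)
})

test_that("buildNeighborhood matches a brute-force first-occurrence scan", {
  set.seed(99)
  tax <- makeTaxonomy()
  for (rep in 1:20) {
    keys <- sample(tax$subject_key, 50, replace = TRUE)
    nb <- buildNeighborhood(makeHits("q", keys), tax)
    # independent one-pass set-based oracle
    seen <- character(0)
    for (k in keys) {
      sp <- tax[k, "species"]
      if (sp != "Azospirillum lipoferum" && !(sp %in% seen))
        seen <- c(seen, sp)
    }
    expect_equal(speciesSeq(nb)$species, seen)
  }
})

test_that("classifyGenome covers hit-less queries and is order-independent", {
  tax <- makeTaxonomy()
  tables <- list(
    anc = makeHits("anc", c("self", "azo2", "mag1", "mag2", "mag3",
                            "rho1", "rho2", "nis1")),
    out = makeHits("out", rep(c("rhizo1", "burk1", "eco1"), 4)),
    selfonly = makeHits("selfonly", "self")
  )
  calls <- classifyGenome(tables, tax,
                          queryIds = c("anc", "out", "selfonly", "nohits"))
  expect_equal(calls$category,
               c("ancestral", "hgt", "unassigned", "unassigned"))
  expect_equal(calls$confidence[1:2], c("high", "high"))
  expect_equal(calls$rule_fired[4], "no_blast_hits")

  # permuting query order permutes rows, not verdicts
  calls2 <- classifyGenome(tables, tax,
                           queryIds = c("nohits", "selfonly", "out", "anc"))
  m <- match(calls$query_id, calls2$query_id)
  expect_equal(calls2$category[m], calls$category)
  expect_equal(calls2$confidence[m], calls$confidence)

  expect_equal(nrow(classifyGenome(list(), tax)), 0L)
})

test_that("monotonicity: prepending a family species never demotes toward hgt", {
  set.seed(7)
  rank <- c(hgt = 0, unassigned = 1, ancestral = 2)
  for (rep in 1:500) {
    memb <- sample(c("G", "F", "O", "X"), sample(0:9, 1), replace = TRUE)
    before <- classifyMembership(memb)$category
    after <- classifyMembership(c("F", memb))$category
    expect_gte(rank[[after]], rank[[before]])
  }
})

test_that("classification is deterministic", {
  set.seed(11)
  for (rep in 1:50) {
    memb <- sample(c("G", "F", "O", "X"), sample(0:10, 1), replace = TRUE)
    expect_identical(classifyMembership(memb), classifyMembership(memb))
  }
})

test_that("summarizeProportions counts, fractions and high-confidence view", {
  calls <- S4Vectors::DataFrame(
    query_id = sprintf("g%d", 1:6),
    category = c("ancestral", "ancestral", "hgt", "hgt", "hgt", "unassigned"),
    confidence = c("high", "low", "high", "high", "medium", "none"),
    rule_fired = "x", evidence_json = "{}")
  s <- summarizeProportions(calls)
  expect_equal(sum(s$full$n), 6L)
  expect_equal(sum(s$full$fraction), 1, tolerance = 1e-12)
  expect_equal(s$byCategory$n, c(2L, 3L, 1L))
  expect_equal(s$highConfidence$n, c(1L, 2L))
  expect_equal(sum(s$highConfidence$fraction), 1)

  # all-unassigned input
  calls$category <- "unassigned"; calls$confidence <- "none"
  s <- summarizeProportions(calls)
  expect_equal(s$byCategory$fraction, c(0, 0, 1))

  expect_error(summarizeProportions(calls[0, ]), "empty")
})

test_that("summary fractions equal brute-force tallies on simulated calls", {
  sim <- simulateHitTables(simConfig(seed = 21, nGenes = 500,
                                     hgtFraction = 0.4))
  calls <- classifyGenome(sim$hit_tables, sim$taxonomy)
  s <- summarizeProportions(calls)
  df <- as.data.frame(calls)
  for (i in seq_len(nrow(s$full))) {
    expect_equal(s$full$n[i],
                 sum(df$category == s$full$category[i] &
                       df$confidence == s$full$confidence[i]))
  }
})
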