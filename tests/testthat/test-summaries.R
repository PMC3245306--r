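makeCalls <- function(ids, category, confidence = "high") {
  S4Vectors::DataFrame(query_id = ids, category = category,
                       confidence = confidence, rule_fired = "x",
                       evidence_json = "{}")
}

test_that("cogEnrichment matches the disjoint-category exact case", {
  calls <- makeCalls(sprintf("g%02d", 1:20),
                     rep(c("ancestral", "hgt"), each = 10))
  cog <- data.frame(gene_id = sprintf("g%02d", 1:20),
                    category = rep(c("J", "V"), each = 10))
  res <- cogEnrichment(calls, cog)
  # 10/0 vs 0/10 split: two-sided hypergeometric p = 2/C(20,10) = 1/92378
  expect_equal(res$p_value[res$category == "J"], 2 / choose(20, 10),
               tolerance = 1e-12)
  expect_equal(res$p_value[res$category == "V"], 2 / choose(20, 10),
               tolerance = 1e-12)
  expect_equal(res$direction[res$category == "J"], "ancestral-enriched")
  expect_equal(res$direction[res$category == "V"], "hgt-enriched")
})

test_that("cogEnrichment p-values equal exhaustive hypergeometric enumeration", {
  set.seed(31)
  for (rep in 1:10) {
    nA <- sample(5:15, 1); nH <- sample(5:15, 1)
    catA <- sample(c("J", "K", "E"), nA, replace = TRUE)
    catH <- sample(c("J", "K", "E"), nH, replace = TRUE)
    calls <- makeCalls(sprintf("g%03d", seq_len(nA + nH)),
                       rep(c("ancestral", "hgt"), c(nA, nH)))
    cog <- data.frame(gene_id = calls$query_id, category = c(catA, catH))
    res <- cogEnrichment(calls, cog)
    for (i in seq_len(nrow(res))) {
      a <- res$count_ancestral[i]; b <- res$count_hgt[i]
      expect_equal(res$p_value[i],
                   enumFisherP(a, nA - a, b, nH - b),
                   tolerance = 1e-9, label = res$category[i])
    }
  }
})

test_that("identical category distributions give p = 1 and direction none", {
  calls <- makeCalls(sprintf("g%02d", 1:20),
                     rep(c("ancestral", "hgt"), each = 10))
  cog <- data.frame(gene_id = sprintf("g%02d", 1:20),
                    category = rep(rep(c("J", "K"), each = 5), 2))
  res <- cogEnrichment(calls, cog)
  expect_true(all(res$p_value == 1))
  expect_true(all(res$direction == "none"))
})

test_that("cogEnrichment degenerate/edge behavior", {
  # single category present: one row, odds ratio NaN-guarded to 'none'
  calls <- makeCalls(c("a", "b"), c("ancestral", "hgt"))
  cog <- data.frame(gene_id = c("a", "b"), category = c("J", "J"))
  res <- cogEnrichment(calls, cog)
  expect_equal(nrow(res), 1L)
  expect_equal(res$direction, "none")

  # genes without a COG are excluded but counted
  calls <- makeCalls(c("a", "b", "c"), c("ancestral", "hgt", "hgt"))
  cog <- data.frame(gene_id = c("a", "b"), category = c("J", "K"))
  res <- cogEnrichment(calls, cog)
  expect_equal(unname(attr(res, "no_cog")["hgt"]), 1L)

  # one empty set advises lowering the floor
  calls <- makeCalls(c("a", "b"), c("ancestral", "hgt"),
                     confidence = c("high", "low"))
  cog <- data.frame(gene_id = c("a", "b"), category = c("J", "K"))
  expect_error(cogEnrichment(calls, cog, confidenceFloor = "high"),
               "confidenceFloor")
  expect_equal(nrow(cogEnrichment(calls, cog, confidenceFloor = "low")), 2L)
})

test_that("BH q-values are monotone in p-rank and bound p from above", {
  set.seed(17)
  calls <- makeCalls(sprintf("g%03d", 1:60),
                     rep(c("ancestral", "hgt"), each = 30))
  cog <- data.frame(gene_id = calls$query_id,
                    category = sample(c("J", "K", "E", "P", "C"), 60,
                                      replace = TRUE))
  res <- cogEnrichment(calls, cog)
  o <- order(res$p_value)
  expect_true(all(diff(res$q_value[o]) >= -1e-12))
  expect_true(all(res$q_value >= res$p_value - 1e-12))
})

test_that("bestHitTaxonomy picks the first eligible hit per HGT gene", {
  tax <- makeTaxonomy()
  tables <- list(
    h1 = makeHits("h1", c("self", "azo2", "rhizo1", "burk1")),
    h2 = makeHits("h2", c("rhizo1", "eco1")),
    h3 = makeHits("h3", c("burk1")),
    h4 = makeHits("h4", c("self", "azo2"))   # no eligible hit
  )
  calls <- makeCalls(c("h1", "h2", "h3", "h4"), "hgt")
  res <- bestHitTaxonomy(tables, calls, tax)
  expect_equal(res$group[res$n == 2], "Rhizobiales")
  expect_equal(sum(res$fraction), 1, tolerance = 1e-12)
  expect_true("unresolved" %in% res$group)

  # counting example: two Rhizobiales + one Burkholderiales
  res <- bestHitTaxonomy(tables[1:3], calls[1:3, ], tax)
  expect_equal(res$fraction[match(c("Rhizobiales", "Burkholderiales"),
                                  res$group)], c(2 / 3, 1 / 3))

  # empty hgt set
  empty <- bestHitTaxonomy(tables, makeCalls("h1", "ancestral"), tax)
  expect_equal(nrow(empty), 0L)
})

test_that("bestHitTaxonomy recovers the donor-group multinomial", {
  probs <- c(Rhizobiales = 0.5, Burkholderiales = 0.3, other = 0.2)
  sim <- simulateHitTables(simConfig(seed = 13, nGenes = 200,
                                     hgtFraction = 1,
                                     donorGroupProbs = probs))
  calls <- classifyGenome(sim$hit_tables, sim$taxonomy)
  res <- bestHitTaxonomy(sim$hit_tables, calls, sim$taxonomy,
                         groupLevel = "order")
  groupOrder <- c(Rhizobiales = "Rhizobiales",
                  Burkholderiales = "Burkholderiales",
                  other = "Enterobacterales")
  n <- sum(res$n)
  for (g in names(probs)) {
    frac <- res$fraction[res$group == groupOrder[[g]]]
    ci <- 1.96 * sqrt(probs[[g]] * (1 - probs[[g]]) / n)
    expect_lt(abs(frac - probs[[g]]), ci + 0.01, label = g)
  }
})

test_that("divergence-clock mapping and linearity", {
  expect_equal(estimateDivergenceTime(8),
               c(t_min_myr = 200, t_max_myr = 400))
  expect_equal(estimateDivergenceTime(0),
               c(t_min_myr = 0, t_max_myr = 0))
  expect_equal(estimateDivergenceTime(1),
               c(t_min_myr = 25, t_max_myr = 50))
  # linearity
  expect_equal(estimateDivergenceTime(4.6) * 2, estimateDivergenceTime(9.2))
  # bounds ordered
  t <- estimateDivergenceTime(3.7)
  expect_lte(t[["t_min_myr"]], t[["t_max_myr"]])
  expect_error(estimateDivergenceTime(-1), ">= 0")
})
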