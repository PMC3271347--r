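test_that("name normalization folds case, spacing and punctuation only", {
  expect_equal(normalizeName("Acetyl-CoA"), "acetylcoa")
  expect_equal(normalizeName("acetyl CoA"), "acetylcoa")
  expect_equal(normalizeName("D-Glucose 6-phosphate"),
               normalizeName("D-glucose-6-phosphate"))
  # no transliteration: Greek alpha stays distinct from "alpha"
  expect_false(normalizeName("α-D-Glucose") ==
                 normalizeName("alpha-D-glucose"))
  # NFKC folds typographic variants (en dash, superscript plus)
  expect_equal(normalizeName("NAD⁺"), normalizeName("NAD+"))
  expect_equal(normalizeName("oxo–glutarate"),
               normalizeName("oxo-glutarate"))
})

mrec <- function(...) metTable(list(local_id = "x", ...))

test_that("the match cascade decides every route correctly", {
  cfg <- matchConfig()
  m <- function(a, b, cfg. = cfg, ...)
    metabolitesMatch(a, b, cfg., ...)

  glc1 <- mrec(names = "alpha-D-glucose", kegg_compound = "C00031")
  glc2 <- mrec(names = "a-D-glc", kegg_compound = "C00031")
  expect_equal(m(glc1, glc2)$route, "kegg_compound")

  # kegg stop rule: differing primary ids block even agreeing secondaries
  a <- mrec(names = "lipoamide-E", kegg_compound = "C15972",
            cas = "940-69-2")
  b <- mrec(names = "lipoamide", kegg_compound = "C00248",
            cas = "940-69-2")
  expect_false(m(a, b)$match)

  # ... unless the pair is hand-curated as an override
  tca <- matchConfig(override_pairs = data.frame(
    a = "kegg_compound:C15972", b = "kegg_compound:C00248"))
  expect_equal(m(a, b, tca)$route, "override")

  # secondary identifiers step in when a primary id is missing on one side
  c1 <- mrec(names = "thing one", cas = "50-00-0")
  c2 <- mrec(names = "thing two", kegg_compound = "C11111",
             cas = "50-00-0")
  expect_equal(m(c1, c2)$route, "secondary_id:cas")
  g1 <- mrec(names = "gly one", kegg_glycan = "G00001")
  g2 <- mrec(names = "gly two", kegg_glycan = "G00001")
  expect_equal(m(g1, g2)$route, "secondary_id:kegg_glycan")

  # name route needs both formulas present and equal
  n1 <- mrec(names = "citrate", formula = "C6H8O7")
  n2 <- mrec(names = c("Citrate", "citric acid"), formula = "C6H8O7")
  expect_equal(m(n1, n2)$route, "name+formula")
  n3 <- mrec(names = "citrate")  # no formula
  expect_false(m(n1, n3)$match)
  n4 <- mrec(names = "citrate", formula = "C6H9O7")
  expect_false(m(n1, n4)$match)

  # H-tolerant formulas absorb protonation differences
  htol <- matchConfig(h_tolerant_formula = TRUE)
  expect_true(m(n1, n4, htol)$match)
  n5 <- mrec(names = "citrate", formula = "C5H8O7")
  expect_false(m(n1, n5, htol)$match)   # only H may differ

  # name alone suffices when the formula requirement is relaxed
  loose <- matchConfig(name_requires_formula = FALSE)
  expect_true(m(n1, n3, loose)$match)

  # generic/specific guard
  gen <- mrec(names = "an alcohol", is_generic = TRUE,
              kegg_compound = "C00069")
  eth <- mrec(names = "ethanol", kegg_compound = "C00069")
  expect_false(m(gen, eth)$match)
  off <- matchConfig(generic_specific_guard = FALSE)
  expect_true(m(gen, eth, off)$match)
  gen2 <- mrec(names = "an alcohol", is_generic = TRUE,
               kegg_compound = "C00069")
  expect_true(m(gen, gen2)$match)   # generic-generic is allowed

  # quarantined names never match by name
  expect_false(m(n1, n2, quarantine = "citrate")$match)
})

test_that("matching is symmetric", {
  for (seed in 1:5) {
    snaps <- randomMetaboliteSnapshots(seed, n_snapshots = 1,
                                       n_per_snapshot = 12)
    m <- metabolites(snaps[[1]])
    cfg <- matchConfig()
    for (i in 1:(nrow(m) - 1)) {
      for (j in (i + 1):nrow(m)) {
        expect_equal(metabolitesMatch(m[i, ], m[j, ], cfg)$match,
                     metabolitesMatch(m[j, ], m[i, ], cfg)$match)
      }
    }
  }
})

test_that("transitive closure chains matches across databases", {
  A <- databaseSnapshot("A", metabolites = metTable(
    list(local_id = "x", names = "alpha", cas = "50-00-0")))
  B <- databaseSnapshot("B", metabolites = metTable(
    list(local_id = "y", names = "beta", cas = "50-00-0",
         chebi = "CHEBI:1")))
  C <- databaseSnapshot("C", metabolites = metTable(
    list(local_id = "z", names = "gamma", chebi = "CHEBI:1")))
  part <- buildMetabolitePartition(list(A, B, C))
  mb <- membership(part)
  expect_equal(length(unique(mb$class_id)), 1)
  routes <- sort(evidence(part)$route)
  expect_true("secondary_id:cas" %in% routes)
  expect_true("secondary_id:chebi" %in% routes)
})

test_that("non-matching metabolites stay singletons", {
  A <- databaseSnapshot("A", metabolites = metTable(
    list(local_id = "x", names = "one", kegg_compound = "C00001"),
    list(local_id = "y", names = "two", kegg_compound = "C00002")))
  B <- databaseSnapshot("B", metabolites = metTable(
    list(local_id = "z", names = "three", kegg_compound = "C00003")))
  part <- buildMetabolitePartition(list(A, B))
  expect_equal(length(unique(membership(part)$class_id)), 3)
  expect_equal(nrow(evidence(part)), 0)
})

test_that("ambiguous names are quarantined from the name route", {
  # within one snapshot "tartrate" labels two different formulas
  A <- databaseSnapshot("A", metabolites = metTable(
    list(local_id = "m1", names = "tartrate", formula = "C4H6O6"),
    list(local_id = "m2", names = "tartrate", formula = "C4H4O6")))
  B <- databaseSnapshot("B", metabolites = metTable(
    list(local_id = "m1", names = "tartrate", formula = "C4H6O6")))
  part <- buildMetabolitePartition(list(A, B))
  expect_equal(length(unique(membership(part)$class_id)), 3)
  expect_true("tartrate" %in% attr(part, "quarantined_names"))
})

test_that("the partition equals the brute-force all-pairs closure", {
  cfg <- matchConfig()
  for (seed in 1:10) {
    snaps <- randomMetaboliteSnapshots(seed)
    got <- partitionClasses(buildMetabolitePartition(snaps, cfg))
    want <- canonicalClasses(bruteForceMetabolitePartition(snaps, cfg))
    expect_identical(got, want)
  }
})

test_that("no class mixes generic and specific metabolites under the guard", {
  for (seed in 11:20) {
    snaps <- randomMetaboliteSnapshots(seed)
    part <- buildMetabolitePartition(snaps, matchConfig())
    mb <- membership(part)
    flags <- unlist(lapply(snaps, function(s) {
      m <- metabolites(s)
      stats::setNames(m$is_generic,
                      paste0(snapshotName(s), "::", m$local_id))
    }))
    mixed <- tapply(flags[mb$key], mb$class_id,
                    function(x) length(unique(x)) > 1)
    expect_false(any(mixed))
  }
})
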