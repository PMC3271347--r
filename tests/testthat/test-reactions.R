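# two snapshots over shared chemistry used throughout the reaction tests
reactionFixture <- function() {
  mets <- metTable(
    list(local_id = "a", names = "compound a", kegg_compound = "C00101"),
    list(local_id = "b", names = "compound b", kegg_compound = "C00102"),
    list(local_id = "h2o", names = "H2O", kegg_compound = "C00001"),
    list(local_id = "h", names = "H+", kegg_compound = "C00080"),
    list(local_id = "h2o_m", names = "H2O", kegg_compound = "C00001",
         compartment = "m"))
  A <- databaseSnapshot("A", metabolites = mets, reactions = rxnTable(
    list(local_id = "r1", side_a = c(a = 1, h2o = 1), side_b = c(b = 1)),
    list(local_id = "r2", side_a = c(a = 1), side_b = c(b = 1, h = 1)),
    list(local_id = "r3", side_a = c(h2o = 1), side_b = c(h2o_m = 1))))
  B <- databaseSnapshot("B", metabolites = mets, reactions = rxnTable(
    list(local_id = "s1", side_a = c(b = 1), side_b = c(a = 1)),
    list(local_id = "s2", side_a = c(a = 1), side_b = c(b = 1))))
  list(A = A, B = B)
}

test_that("signatures ignore direction and the configured currency set", {
  fx <- reactionFixture()
  cfg <- matchConfig()   # relaxed: e-, H+, H2O ignored
  part <- buildMetabolitePartition(list(fx$A, fx$B), cfg)
  sigA1 <- reactionSignature(reactions(fx$A)[1, ], "A", part, cfg,
    ignore_classes = PathCompare:::ignoreClassIds(part, list(fx$A, fx$B),
                                                  cfg))
  sigB1 <- reactionSignature(reactions(fx$B)[1, ], "B", part, cfg,
    ignore_classes = PathCompare:::ignoreClassIds(part, list(fx$A, fx$B),
                                                  cfg))
  expect_equal(as.character(sigA1), as.character(sigB1))
})

test_that("strict and relaxed modes differ exactly on currency species", {
  fx <- reactionFixture()
  strict <- matchConfig(ignore_metabolites = character(0))
  relaxed <- matchConfig()
  cmp_s <- compareSnapshots(list(fx$A, fx$B), strict)
  cmp_r <- compareSnapshots(list(fx$A, fx$B), relaxed)
  # strict: r1 (a+h2o->b), r2 (a->b+h), s1/s2 (a<->b) all distinct except
  # s1==s2; relaxed: r1==r2==s1==s2
  expect_equal(cmp_s$results$reaction@consensus_count, 0L)
  expect_equal(cmp_r$results$reaction@consensus_count, 1L)
})

test_that("a transport of an ignored species degenerates and is excluded", {
  fx <- reactionFixture()
  cfg <- matchConfig()
  part <- buildMetabolitePartition(list(fx$A, fx$B), cfg)
  rpart <- buildReactionPartition(list(fx$A, fx$B), part, cfg)
  mb <- membership(rpart)
  r3 <- mb[mb$key == "A::r3", ]
  expect_equal(r3$excluded_reason, "degenerate")
  sets <- entitySets(rpart)
  expect_false(r3$class_id %in% unlist(sets))
  expect_equal(unname(attr(sets, "excluded")["degenerate"]), 1L)
})

test_that("a reaction written in both directions counts once per snapshot", {
  fx <- reactionFixture()
  cfg <- matchConfig()
  part <- buildMetabolitePartition(list(fx$B), cfg)
  rpart <- buildReactionPartition(list(fx$B), part, cfg)
  sets <- entitySets(rpart)
  expect_equal(length(sets$B), 1)   # s1 and s2 collapse
})

test_that("every strict class is contained in a relaxed class", {
  truth <- generateGroundTruth(50, 5, seed = 21)
  prof <- function(s) perturbationProfile(p_cov = 0.9,
                                          p_balance_h2o_hplus = 0.5,
                                          p_flip_direction = 0.3, seed = s)
  snaps <- list(deriveSnapshot(truth, prof(1), "A")$snapshot,
                deriveSnapshot(truth, prof(2), "B")$snapshot)
  strict <- compareSnapshots(snaps, matchConfig(
    ignore_metabolites = character(0)))
  relaxed <- compareSnapshots(snaps, matchConfig())
  s_cl <- partitionClasses(strict$partitions$reaction,
                           countable_only = TRUE)
  r_cl <- partitionClasses(relaxed$partitions$reaction,
                           countable_only = TRUE)
  r_of <- membership(relaxed$partitions$reaction)
  r_map <- stats::setNames(r_of$class_id, r_of$key)
  for (cl in s_cl) {
    expect_equal(length(unique(r_map[cl])), 1)
  }
  # relaxed matching can only add cross-snapshot matches
  crossMatches <- function(cmp) {
    mb <- membership(cmp$partitions$reaction)
    mb <- mb[is.na(mb$excluded_reason), ]
    sum(tapply(mb$snapshot, mb$class_id,
               function(s) length(unique(s))) > 1)
  }
  expect_gte(crossMatches(relaxed), crossMatches(strict))
  expect_lte(relaxed$results$reaction@union_size,
             strict$results$reaction@union_size)
})

test_that("growing the ignore set never shrinks cross-snapshot matches", {
  truth <- generateGroundTruth(40, 4, seed = 31)
  snaps <- lapply(1:2, function(i) deriveSnapshot(
    truth, perturbationProfile(p_cov = 0.85, p_balance_h2o_hplus = 0.6,
                               seed = 40 + i),
    sprintf("S%d", i))$snapshot)
  cfgs <- list(matchConfig(ignore_metabolites = character(0)),
               matchConfig(ignore_metabolites = "H+"),
               matchConfig(ignore_metabolites = c("H+", "H2O")),
               matchConfig())
  stats_by_cfg <- lapply(cfgs, function(cfg) {
    cmp <- compareSnapshots(snaps, cfg)
    mb <- membership(cmp$partitions$reaction)
    mb <- mb[is.na(mb$excluded_reason), ]
    list(cross = sum(tapply(mb$snapshot, mb$class_id,
                            function(s) length(unique(s))) > 1),
         union = cmp$results$reaction@union_size)
  })
  for (i in 2:length(stats_by_cfg)) {
    expect_gte(stats_by_cfg[[i]]$cross, stats_by_cfg[[i - 1]]$cross)
    expect_lte(stats_by_cfg[[i]]$union, stats_by_cfg[[i - 1]]$union)
  }
})
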