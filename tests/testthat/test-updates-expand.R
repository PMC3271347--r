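test_that("transferred identifiers are replaced, obsolete ones removed", {
  s <- databaseSnapshot(
    "d", genes = data.frame(local_id = c("g1", "g2"),
                            gene_id = c("123", "999")),
    metabolites = metTable(
      list(local_id = "m1", names = "water", kegg_compound = "C00001"),
      list(local_id = "m2", names = "x", kegg_compound = "C55555")),
    reactions = rxnTable(list(local_id = "r1", side_a = c(m1 = 1),
                              side_b = c(m2 = 1),
                              ecs = c("1.1.1.1", "2.2.2.2"))))
  upd <- updateTables(
    transferred = list(gene = c("123" = "456"),
                       ec = c("2.2.2.2" = "2.2.2.3")),
    obsolete = list(kegg_compound = "C00001", ec = "1.1.1.1"))
  s2 <- applyIdentifierUpdates(s, upd)
  expect_equal(genes(s2)$gene_id, c("456", "999"))
  expect_true(is.na(metabolites(s2)$kegg_compound[1]))
  # record retained even though its identifier is gone
  expect_equal(nrow(metabolites(s2)), 2)
  expect_equal(metabolites(s2)$kegg_compound[2], "C55555")
  expect_equal(reactions(s2)$ecs[[1]], "2.2.2.3")
  summ <- attr(s2, "update_summary")
  expect_equal(unname(summ$gene["replaced"]), 1)
  expect_equal(unname(summ$kegg_compound["removed"]), 1)
})

test_that("updates with empty tables are the identity and idempotent", {
  truth <- generateGroundTruth(30, 3, seed = 2)
  snap <- deriveSnapshot(truth, perturbationProfile(seed = 5),
                         "idm")$snapshot
  s_id <- applyIdentifierUpdates(snap, updateTables())
  expect_identical(PathCompare:::snapshotToList(s_id),
                   PathCompare:::snapshotToList(snap))
  upd <- truth@update_tables
  once <- applyIdentifierUpdates(snap, upd)
  twice <- applyIdentifierUpdates(once, upd)
  expect_identical(PathCompare:::snapshotToList(once),
                   PathCompare:::snapshotToList(twice))
})

generic_snap <- function(instances_alc = c("et", "prop"),
                         instances_ald = c("acet", "propa")) {
  databaseSnapshot(
    "g",
    metabolites = metTable(
      list(local_id = "alc", names = "an alcohol", is_generic = TRUE,
           instance_ids = instances_alc),
      list(local_id = "ald", names = "an aldehyde", is_generic = TRUE,
           instance_ids = instances_ald),
      list(local_id = "et", names = "ethanol", formula = "C2H6O"),
      list(local_id = "prop", names = "propanol", formula = "C3H8O"),
      list(local_id = "acet", names = "acetaldehyde", formula = "C2H4O"),
      list(local_id = "propa", names = "propanal", formula = "C3H6O"),
      list(local_id = "nad", names = "NAD+", kegg_compound = "C00003"),
      list(local_id = "nadh", names = "NADH", kegg_compound = "C00004")),
    reactions = rxnTable(
      list(local_id = "r1", side_a = c(alc = 1, nad = 1),
           side_b = c(ald = 1, nadh = 1), is_set_reaction = TRUE),
      list(local_id = "r2", side_a = c(et = 1), side_b = c(acet = 1))))
}

test_that("first-member expansion instantiates positionally", {
  s <- expandGenericReactions(generic_snap(), mode = "first_member")
  r1 <- reactions(s)[reactions(s)$local_id == "r1", ]
  expect_equal(r1$side_a[[1]], c(et = 1, nad = 1))
  expect_equal(r1$side_b[[1]], c(acet = 1, nadh = 1))
  expect_false(r1$expansion_flagged)
  # the non-generic reaction is untouched
  r2 <- reactions(s)[reactions(s)$local_id == "r2", ]
  expect_equal(r2$side_a[[1]], c(et = 1))
})

test_that("all-members expansion emits one reaction per paired index", {
  s <- expandGenericReactions(generic_snap(), mode = "all_members")
  r <- reactions(s)
  expect_setequal(r$local_id, c("r1__1", "r1__2", "r2"))
  expect_equal(r$side_a[[match("r1__2", r$local_id)]],
               c(nad = 1, prop = 1))
})

test_that("mode none is the identity", {
  s0 <- generic_snap()
  expect_identical(PathCompare:::snapshotToList(
    expandGenericReactions(s0, "none")),
    PathCompare:::snapshotToList(s0))
})

test_that("classes without instances or unpaired sides flag the reaction", {
  s_empty <- generic_snap(instances_alc = character(0),
                          instances_ald = character(0))
  e <- expandGenericReactions(s_empty, "first_member")
  r1 <- reactions(e)[reactions(e)$local_id == "r1", ]
  expect_equal(r1$side_a[[1]], c(alc = 1, nad = 1))  # unchanged
  expect_true(r1$expansion_flagged)

  s_unpaired <- generic_snap(instances_ald = character(0))
  u <- expandGenericReactions(s_unpaired, "first_member")
  r1 <- reactions(u)[reactions(u)$local_id == "r1", ]
  expect_equal(r1$side_a[[1]], c(alc = 1, nad = 1))
  expect_true(r1$expansion_flagged)
})

test_that("expansion never changes the number of non-generic reactions", {
  truth <- generateGroundTruth(40, 4, seed = 9)
  snap <- deriveSnapshot(truth, perturbationProfile(p_generic = 0.5,
                                                    seed = 4),
                         "exp")$snapshot
  before <- reactions(snap)
  n_plain <- sum(!before$is_set_reaction)
  after <- reactions(expandGenericReactions(snap, "first_member"))
  plain_ids <- before$local_id[!before$is_set_reaction]
  expect_true(all(plain_ids %in% after$local_id))
  for (id in plain_ids) {
    expect_identical(after$side_a[[match(id, after$local_id)]],
                     before$side_a[[match(id, before$local_id)]])
  }
})
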