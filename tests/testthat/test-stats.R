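test_that("consensus reproduces hand-enumerated memberships", {
  sets <- list(A = c("x", "y", "w"), B = c("x", "z"), C = c("x", "y"))
  res <- consensus(sets)
  expect_equal(unionSize(res), 4)
  expect_equal(res@consensus_count, 1L)           # x
  expect_equal(occurrenceHistogram(res),
               c("1" = 2L, "2" = 1L, "3" = 1L))   # w,z | y | x
  expect_equal(uniqueCounts(res), c(A = 1L, B = 1L, C = 0L))
  expect_equal(consensusPct(res), 25L)
  # order invariance
  res2 <- consensus(sets[c(3, 1, 2)])
  expect_equal(occurrenceHistogram(res2), occurrenceHistogram(res))
  expect_equal(consensusPct(res2), consensusPct(res))
})

test_that("identical sets give full consensus and no uniques", {
  sets <- list(A = c("x", "y"), B = c("x", "y"), C = c("x", "y"),
               D = c("x", "y"), E = c("x", "y"))
  res <- consensus(sets)
  expect_equal(consensusPct(res), 100L)
  expect_equal(sum(uniqueCounts(res)), 0L)
  expect_equal(majorityPct(res), 100L)
})

test_that("consensus errors on an empty union", {
  expect_error(consensus(list(A = character(0), B = character(0))),
               "empty union")
})

test_that("consensus matches a brute-force membership oracle on fuzz", {
  for (seed in 1:20) {
    set.seed(seed)
    n_snap <- sample(2:5, 1)
    universe <- sprintf("e%02d", 1:15)
    sets <- stats::setNames(lapply(seq_len(n_snap), function(i)
      sort(sample(universe, sample(3:12, 1)))),
      sprintf("S%d", seq_len(n_snap)))
    if (length(unique(unlist(sets))) == 0) next
    res <- consensus(sets)
    # oracle: count element-by-element
    occ <- vapply(unique(unlist(sets)), function(e)
      sum(vapply(sets, function(s) e %in% s, logical(1))), integer(1))
    expect_equal(unionSize(res), length(occ))
    expect_equal(res@consensus_count, sum(occ == n_snap))
    expect_equal(res@majority_count,
                 sum(occ >= min(3, n_snap)))
    for (k in seq_len(n_snap))
      expect_equal(unname(occurrenceHistogram(res)[k]), sum(occ == k))
  }
})

test_that("majority thresholds behave as bounds of the consensus", {
  set.seed(3)
  sets <- stats::setNames(lapply(1:5, function(i)
    sort(sample(sprintf("e%02d", 1:20), sample(5:15, 1)))),
    sprintf("S%d", 1:5))
  expect_equal(majority(sets, 1)$pct, 100L)
  res <- consensus(sets)
  expect_equal(majority(sets, 5)$count, res@consensus_count)
  prev <- Inf
  for (thr in 1:5) {
    cur <- majority(sets, thr)$count
    expect_lte(cur, prev)
    prev <- cur
  }
  expect_lte(consensusPct(res), majorityPct(res))
})

test_that("pairwise table follows the two-way set formula", {
  sets <- list(A = c("a", "b"), B = c("c", "d"), C = c("a", "b", "c", "d"))
  pm <- pairwiseTable(sets)
  expect_equal(pm["A", "B"], 0L)                    # disjoint
  expect_equal(pm["A", "C"], 50L)                   # nested: 2 of 4
  expect_equal(pm["A", "A"], 100L)
  expect_true(isSymmetric(pm))
  # every pairwise overlap is at least the N-way consensus ratio
  res <- consensus(sets)
  off <- pm[upper.tri(pm)]
  expect_true(all(off >= consensusPct(res) - 1))
})

test_that("pairwise comparison rebuilds partitions without bridging", {
  # B bridges A and C: A-B match on cas, B-C on chebi. In the 3-way
  # partition A and C share a class, but pairwise A-C must not match.
  A <- databaseSnapshot("A", metabolites = metTable(
    list(local_id = "x", names = "one", cas = "50-00-0")))
  B <- databaseSnapshot("B", metabolites = metTable(
    list(local_id = "y", names = "two", cas = "50-00-0",
         chebi = "CHEBI:1")))
  C <- databaseSnapshot("C", metabolites = metTable(
    list(local_id = "z", names = "three", chebi = "CHEBI:1")))
  part3 <- buildMetabolitePartition(list(A, B, C))
  expect_equal(length(unique(membership(part3)$class_id)), 1)
  pm <- pairwiseCompare(list(A, B, C), "metabolite")
  expect_equal(pm["A", "B"], 100L)
  expect_equal(pm["B", "C"], 100L)
  expect_equal(pm["A", "C"], 0L)
})

test_that("gene/EC combination recovers planted agreement patterns", {
  mets <- metTable(list(local_id = "a", names = "a"),
                   list(local_id = "b", names = "b"))
  mk <- function(name, ecs_g1, ecs_g2) {
    databaseSnapshot(name,
      genes = data.frame(local_id = c("g1", "g2"),
                         gene_id = c("100", "200")),
      metabolites = mets,
      reactions = rxnTable(
        list(local_id = "r1", side_a = c(a = 1), side_b = c(b = 1),
             genes = "g1", ecs = ecs_g1),
        list(local_id = "r2", side_a = c(b = 1), side_b = c(a = 1),
             genes = "g2", ecs = ecs_g2)))
  }
  # gene 100: same single EC everywhere -> all agree
  # gene 200: overlapping but unequal EC sets -> at least one
  snaps <- list(mk("A", "1.1.1.1", c("2.2.2.2", "3.3.3.3")),
                mk("B", "1.1.1.1", "2.2.2.2"))
  gp <- buildGenePartition(snaps)
  ep <- buildECPartition(snaps, 4)
  out <- combinationGeneEC(snaps, gp, ep)
  expect_equal(out$n_consensus_genes, 2)
  expect_equal(out$all_ec_agree, 1)
  expect_equal(out$at_least_one, 2)
  expect_equal(out$none, 0)
  expect_equal(out$pct_all_ec_agree, 50L)
})

test_that("three-level combination classifies planted reaction patterns", {
  mets <- metTable(
    list(local_id = "a", names = "a", kegg_compound = "C00101"),
    list(local_id = "b", names = "b", kegg_compound = "C00102"),
    list(local_id = "c", names = "c", kegg_compound = "C00103"),
    list(local_id = "d", names = "d", kegg_compound = "C00104"))
  mk <- function(name, g_r1, ec_r2) {
    databaseSnapshot(name,
      genes = data.frame(local_id = sprintf("g%d", 1:3),
                         gene_id = c("100", "200", "300")),
      metabolites = mets,
      reactions = rxnTable(
        list(local_id = "r1", side_a = c(a = 1), side_b = c(b = 1),
             genes = g_r1, ecs = "1.1.1.1"),
        list(local_id = "r2", side_a = c(c = 1), side_b = c(d = 1),
             genes = "g3", ecs = ec_r2)))
  }
  # r1: full EC agreement; genes: B adds g2 on top of A's {g1} -> tagged
  # r2: same gene everywhere, disjoint ECs -> gene_only + no_common_ec
  snaps <- list(mk("A", "g1", "4.4.4.4"), mk("B", c("g1", "g2"), "5.5.5.5"))
  cmp <- compareSnapshots(snaps)
  out <- combinationReactionGeneEC(snaps, cmp$partitions)
  expect_equal(out$n_consensus_reactions, 2)
  expect_equal(out$full_agreement, 0)
  expect_equal(out$ec_only, 1)
  expect_equal(out$gene_only, 1)
  expect_equal(out$no_common_ec, 1)
  expect_equal(out$no_common_gene, 0)
  expect_equal(out$additional_genes, 1)
})

test_that("restricting to the whole database changes nothing", {
  truth <- generateGroundTruth(30, 3, seed = 12)
  snaps <- lapply(1:2, function(i) deriveSnapshot(
    truth, perturbationProfile(p_cov = 0.9, seed = i), sprintf("S%d", i)))
  ss <- lapply(snaps, `[[`, "snapshot")
  full <- compareSnapshots(ss)
  all_cats <- categoryLabels()
  rest <- restrictedCompare(ss, categories = all_cats,
                            drop_transport = FALSE)
  # every reaction is in a pathway with a category, so scope = everything
  expect_equal(consensusPct(rest$results$reaction),
               consensusPct(full$results$reaction))
  expect_equal(unionSize(rest$results$gene),
               unionSize(full$results$gene))
})

test_that("an empty scope names the snapshots lacking it", {
  truth <- generateGroundTruth(20, 2, seed = 13)
  ss <- lapply(1:2, function(i) deriveSnapshot(
    truth, perturbationProfile(seed = i), sprintf("S%d", i))$snapshot)
  expect_error(restrictedCompare(ss, pathway = "no such pathway"),
               "empty in snapshot")
})
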