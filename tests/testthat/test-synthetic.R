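test_that("ground truth and derivation are deterministic under a seed", {
  t1 <- generateGroundTruth(40, 4, seed = 5)
  t2 <- generateGroundTruth(40, 4, seed = 5)
  expect_identical(PathCompare:::snapshotToList(truthSnapshot(t1)),
                   PathCompare:::snapshotToList(truthSnapshot(t2)))
  p <- perturbationProfile(p_cov = 0.7, p_id_drop = 0.3,
                           p_name_variant = 0.2, seed = 9)
  d1 <- deriveSnapshot(t1, p, "X")
  d2 <- deriveSnapshot(t2, p, "X")
  expect_identical(PathCompare:::snapshotToList(d1$snapshot),
                   PathCompare:::snapshotToList(d2$snapshot))
  expect_identical(truthEntries(d1$ledger), truthEntries(d2$ledger))
})

test_that("the identity profile reproduces the truth up to relabeling", {
  truth <- generateGroundTruth(30, 3, seed = 6)
  d <- deriveSnapshot(truth, perturbationProfile(seed = 1), "copy")
  ts <- truthSnapshot(truth)
  expect_equal(nrow(reactions(d$snapshot)), nrow(reactions(ts)))
  e <- truthEntries(d$ledger)
  expect_setequal(e$truth_id[e$entity_class == "reaction"],
                  reactions(ts)$local_id)
  expect_true(all(e$tags == ""))
  # two identity-profile snapshots agree 100% everywhere
  d2 <- deriveSnapshot(truth, perturbationProfile(seed = 2), "copy2")
  cmp <- compareSnapshots(list(d$snapshot, d2$snapshot))
  for (res in cmp$results) expect_equal(consensusPct(res), 100L)
})

test_that("currency metabolites are hubs of the truth network", {
  over_median <- vapply(1:10, function(seed) {
    ts <- truthSnapshot(generateGroundTruth(50, 5, seed = seed))
    deg <- table(unlist(lapply(c(reactions(ts)$side_a,
                                 reactions(ts)$side_b), names)))
    cur <- grep("^cur_", names(deg), value = TRUE)
    mean(deg[cur]) > stats::median(deg)
  }, logical(1))
  expect_true(all(over_median))
})

test_that("lumping a fully covered route yields its symbolic net reaction", {
  truth <- generateGroundTruth(40, 4, seed = 8)
  d <- deriveSnapshot(truth, perturbationProfile(p_lump = 1, seed = 3),
                      "lumped")
  e <- truthEntries(d$ledger)
  lumped <- e[e$entity_class == "reaction" & grepl("lump", e$tags), ]
  expect_gt(nrow(lumped), 0)
  ts <- truthSnapshot(truth)
  tm <- metabolites(ts)
  # ledger maps each lumped reaction to its route group id
  expect_true(all(lumped$truth_id %in% truth@routes$route_id))
  for (k in seq_len(nrow(lumped))) {
    route_id <- lumped$truth_id[k]
    members <- truth@routes$reaction_ids[[
      match(route_id, truth@routes$route_id)]]
    rows <- reactions(ts)[match(members, reactions(ts)$local_id), ]
    # independent symbolic oracle: count species on both sides and cancel
    all_a <- unlist(lapply(rows$side_a, names))
    all_b <- unlist(lapply(rows$side_b, names))
    expected_a <- character(0); expected_b <- character(0)
    for (sp in unique(c(all_a, all_b))) {
      bal <- sum(all_a == sp) - sum(all_b == sp)
      if (bal > 0) expected_a <- c(expected_a, sp)
      if (bal < 0) expected_b <- c(expected_b, sp)
    }
    dr <- reactions(d$snapshot)
    row <- dr[match(lumped$local_id[k], dr$local_id), ]
    led_m <- e[e$entity_class == "metabolite", ]
    truth_of <- stats::setNames(led_m$truth_id, led_m$local_id)
    got_a <- sort(unname(truth_of[names(row$side_a[[1]])]))
    got_b <- sort(unname(truth_of[names(row$side_b[[1]])]))
    expect_true(setequal(got_a, expected_a) && setequal(got_b, expected_b) ||
                setequal(got_a, expected_b) && setequal(got_b, expected_a))
    # chain intermediates are gone
    intermediates <- intersect(all_a, all_b)
    expect_false(any(intermediates %in% c(got_a, got_b)))
  }
})

test_that("identifier dropout with intact names still matches by name", {
  truth <- generateGroundTruth(20, 2, seed = 10)
  drop_all <- stats::setNames(rep(1, 6),
                              c(PathCompare:::metNamespaces(), "gene"))
  drop_all["gene"] <- 0
  d1 <- deriveSnapshot(truth, perturbationProfile(p_id_drop = drop_all,
                                                  seed = 1), "noid")
  d2 <- deriveSnapshot(truth, perturbationProfile(seed = 2), "full")
  expect_true(all(is.na(metabolites(d1$snapshot)$kegg_compound)))
  cmp <- compareSnapshots(list(d1$snapshot, d2$snapshot))
  expect_equal(consensusPct(cmp$results$metabolite), 100L)
  ev <- evidence(cmp$partitions$metabolite)
  expect_true(all(ev$route == "name+formula"))
})

test_that("hard synonyms and proton shifts degrade matching as designed", {
  truth <- generateGroundTruth(20, 2, seed = 11)
  drop_all <- stats::setNames(rep(1, 5), PathCompare:::metNamespaces())
  base <- list(p_id_drop = drop_all)
  mk <- function(extra, name, seed) {
    args <- c(base, extra, list(seed = seed))
    deriveSnapshot(truth, do.call(perturbationProfile, args), name)
  }
  plain <- mk(list(), "plain", 1)
  shifted <- mk(list(p_proton_shift = 1), "shifted", 2)
  # without identifiers a proton-shifted partner matches only H-tolerantly
  strictF <- compareSnapshots(list(plain$snapshot, shifted$snapshot),
                              matchConfig())
  tolerant <- compareSnapshots(list(plain$snapshot, shifted$snapshot),
                               matchConfig(h_tolerant_formula = TRUE))
  expect_lt(consensusPct(strictF$results$metabolite), 50L)
  expect_equal(consensusPct(tolerant$results$metabolite), 100L)
  # hard synonyms are unrecoverable by construction
  hard <- mk(list(p_name_variant = 1), "hard", 3)
  cmp_hard <- compareSnapshots(list(plain$snapshot, hard$snapshot))
  expect_lt(consensusPct(cmp_hard$results$metabolite), 100L)
})

test_that("generic substitution never creates truth-level false merges", {
  truth <- generateGroundTruth(40, 4, seed = 14)
  d1 <- deriveSnapshot(truth, perturbationProfile(p_generic = 0.5,
                                                  p_alt_substrate = 0.5,
                                                  seed = 5), "A")
  d2 <- deriveSnapshot(truth, perturbationProfile(p_generic = 0.3,
                                                  p_lump = 0.5, seed = 6),
                       "B")
  cmp <- compareSnapshots(list(d1$snapshot, d2$snapshot))
  mb <- membership(cmp$partitions$reaction)
  truth_of <- do.call(rbind, lapply(list(d1$ledger, d2$ledger), function(l) {
    e <- truthEntries(l)
    e <- e[e$entity_class == "reaction", ]
    data.frame(key = paste0(l@snapshot, "::", e$local_id),
               truth_id = e$truth_id, stringsAsFactors = FALSE)
  }))
  tmap <- stats::setNames(truth_of$truth_id, truth_of$key)
  mb <- mb[is.na(mb$excluded_reason), ]
  # no class may span two different truth identities (mis-merge count 0)
  mis <- tapply(tmap[mb$key], mb$class_id,
                function(x) length(unique(x)) > 1)
  expect_false(any(mis))
})

test_that("true overlap refuses mixed ground truths", {
  t1 <- generateGroundTruth(20, 2, seed = 1)
  t2 <- generateGroundTruth(20, 2, seed = 2)
  l1 <- deriveSnapshot(t1, perturbationProfile(seed = 1), "A")$ledger
  l2 <- deriveSnapshot(t2, perturbationProfile(seed = 1), "B")$ledger
  expect_error(trueOverlap(list(l1, l2), "reaction"), "different ground")
  sets <- trueOverlap(list(l1), "reaction")
  expect_equal(length(sets$A), 20)
})

test_that("perturbation profiles reject invalid rates and read from YAML", {
  expect_error(perturbationProfile(p_cov = 1.2), "0, 1")
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("p_cov: 0.5", "p_lump: 0.25", "seed: 42",
               "p_id_drop:", "  kegg_compound: 0.8"), f)
  p <- perturbationProfileFromYAML(f)
  expect_equal(p@p_cov, 0.5)
  expect_equal(p@p_lump, 0.25)
  expect_equal(unname(p@p_id_drop["kegg_compound"]), 0.8)
  expect_equal(unname(p@p_id_drop["cas"]), 0)
  expect_equal(p@seed, 42L)
})
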