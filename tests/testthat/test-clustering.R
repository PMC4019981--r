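test_that("bait-relative abundance averages per-run ratios with zeros", {
  ds <- toy_dataset()
  nsaf <- compute_nsaf(ds, "bait")
  rel <- relative_abundance(nsaf, ds)
  expect_equal(unname(rel["BAITX", "BAITX"]), 1)
  manual <- mean(nsaf[c("r1", "r2"), "PREYA"] / nsaf[c("r1", "r2"), "BAITX"])
  expect_equal(unname(rel["PREYA", "BAITX"]), manual)
  # CONTZ undetected in r2 contributes a zero ratio
  expect_equal(unname(rel["CONTZ", "BAITX"]),
               mean(c(nsaf["r1", "CONTZ"] / nsaf["r1", "BAITX"], 0)))
  # a bait missing from its own run is an error naming the run
  nsaf0 <- nsaf
  nsaf0["r1", "BAITX"] <- 0
  expect_error(relative_abundance(nsaf0, ds), "r1")
})

test_that("uncentered Pearson distance satisfies its closed form and bounds", {
  m <- rbind(x = c(1, 2), y = c(2, 1), same = c(2, 4), ortho = c(0, 3))
  d <- gene_distance_matrix(m)
  expect_equal(unname(d["x", "y"]), 0.2)        # 1 - 4/5
  expect_equal(unname(d["x", "same"]), 0)       # identical direction
  expect_equal(unname(d["y", "ortho"]), 1 - 1 / sqrt(5))
  expect_equal(d, t(d))
  expect_true(all(d >= 0 & d <= 1))
  expect_true(all(diag(d) == 0))
  expect_equal(unname(gene_distance_matrix(
    rbind(a = c(1, 0, 0), b = c(0, 1, 0)))["a", "b"]), 1)
  expect_warning(gene_distance_matrix(rbind(a = c(1, 1), b = c(1, 2),
                                            z = c(0, 0))), "all-zero")
  expect_error(gene_distance_matrix(rbind(a = c(1, 1))), "two")
})

test_that("average-linkage merges match the brute-force oracle on 3 profiles", {
  m <- rbind(a = c(1, 0.2, 0), b = c(0.9, 0.4, 0.1), c = c(0, 0.3, 1))
  d <- gene_distance_matrix(m)
  mod <- hierarchical_modules(d, 1L)
  tree <- mod$tree
  # oracle: merge the closest pair first, then average linkage to the third
  pairs <- list(c("a", "b"), c("a", "c"), c("b", "c"))
  dv <- vapply(pairs, function(p) d[p[1], p[2]], numeric(1))
  first <- pairs[[which.min(dv)]]
  third <- setdiff(rownames(m), first)
  h1 <- min(dv)
  h2 <- mean(c(d[first[1], third], d[first[2], third]))
  expect_equal(tree$height, c(h1, h2))
  expect_equal(sort(rownames(m)[-tree$merge[1, ]]), sort(first))
})

test_that("module cutting recovers separable blocks deterministically", {
  m <- rbind(a1 = c(1, 1, 0, 0), a2 = c(2, 2, 0, 0), a3 = c(1, 2, 0, 0),
             b1 = c(0, 0, 1, 1), b2 = c(0, 0, 2, 1))
  d <- gene_distance_matrix(m)
  mod <- hierarchical_modules(d, 2L)
  expect_equal(unname(mod$labels[c("a1", "a2", "a3")]), rep(1L, 3L))
  expect_equal(unname(mod$labels[c("b1", "b2")]), rep(2L, 2L))
  # determinism: identical input, identical result
  expect_identical(mod, hierarchical_modules(d, 2L))
  # as many clusters as proteins: all singletons
  expect_equal(sort(unname(hierarchical_modules(d, 5L)$labels)), 1:5)
  expect_error(hierarchical_modules(d, 6L), "exceeds")
})

test_that("profile-correlated sub-threshold preys are rescued, others not", {
  # 4-protein toy: hub passes both filters, friend correlates with hub,
  # loner is orthogonal to every HCIP of the bait
  enr <- data.frame(bait = "B", prey = c("hub", "friend", "loner", "out"),
                    xbar = 0.1, control_value = 1e-4,
                    enrichment = c(100, 100, 100, 1),
                    passed = c(TRUE, TRUE, TRUE, FALSE))
  wd <- data.frame(bait = "B", prey = c("hub", "friend", "loner", "out"),
                   xbar = 0.1, f = 1L, omega = 1, n = 2L,
                   wd = c(2, 0.5, 0.5, 0.5), wdn = c(2, 0.5, 0.5, 0.5),
                   passed = c(TRUE, FALSE, FALSE, FALSE))
  m <- rbind(hub = c(1, 0.5, 0), friend = c(0.8, 0.6, 0),
             loner = c(0, 0, 1), out = c(1, 0, 0))
  gdm <- gene_distance_matrix(m)
  hcip <- data.frame(bait = "B", prey = "hub")
  res <- rescue_subthreshold(enr, wd, gdm, hcip)
  expect_equal(res$prey, c("friend", "loner"))  # enrichment-passing only
  expect_true(res$rescued[res$prey == "friend"])
  expect_gt(res$max_similarity[res$prey == "friend"], 0)
  expect_false(res$rescued[res$prey == "loner"])
  # prey with no profile in the GDM is never rescued
  gdm2 <- gdm[c("hub", "loner"), c("hub", "loner")]
  res2 <- rescue_subthreshold(enr, wd, gdm2, hcip)
  expect_false(res2$rescued[res2$prey == "friend"])
})

test_that("network assembly unions passing and rescued edges and dedups", {
  enr <- data.frame(bait = c("A", "A", "A", "B", "B"),
                    prey = c("P1", "P2", "P3", "A", "P1"),
                    xbar = 0.1, control_value = 1e-3,
                    enrichment = 100, passed = TRUE)
  wd <- data.frame(bait = c("A", "A", "A", "B", "B"),
                   prey = c("P1", "P2", "P3", "A", "P1"),
                   xbar = 0.1, f = 1L, omega = 1, n = 2L, wd = 1,
                   wdn = c(2, 2, 0.4, 1.5, 0.2),
                   passed = c(TRUE, TRUE, FALSE, TRUE, FALSE))
  rescued <- data.frame(bait = "A", prey = "P3", max_similarity = 0.5,
                        rescued = TRUE)
  net <- assemble_network(enr, wd, rescued)
  expect_s3_class(net, "interaction_network")
  expect_equal(nrow(net$edges), 4L)  # A-P1, A-P2, B-A, rescued A-P3
  expect_equal(sum(net$edges$rescued), 1L)
  # bait-bait pair scored from both directions collapses to one edge
  wd2 <- wd
  wd2$passed[wd2$bait == "B" & wd2$prey == "P1"] <- TRUE
  enr2 <- rbind(enr, data.frame(bait = "A", prey = "B", xbar = 0.1,
                                control_value = 1e-3, enrichment = 100,
                                passed = TRUE))
  wd3 <- rbind(wd2, data.frame(bait = "A", prey = "B", xbar = 0.1, f = 1L,
                               omega = 1, n = 2L, wd = 1, wdn = 1.2,
                               passed = TRUE))
  net2 <- assemble_network(enr2, wd3, rescued)
  keyed <- edge_key(net2$edges$bait, net2$edges$prey)
  expect_equal(anyDuplicated(keyed), 0L)
  ab <- net2$edges[keyed == edge_key("A", "B"), ]
  expect_equal(nrow(ab), 1L)
  expect_equal(ab$bait, "A")         # canonical direction kept
  expect_equal(ab$wdn, 1.2)
  expect_equal(ab$wdn_reverse, 1.5)  # reverse direction retained
  # empty network allowed with a warning
  enr0 <- enr[0, ]; wd0 <- wd[0, ]
  expect_warning(assemble_network(enr0, wd0), "empty")
})

test_that("rescue only ever adds edges on synthetic data", {
  scored <- default_scored()
  strict <- assemble_network(scored$enrichment, scored$wd)
  final_keys <- edge_key(scored$network$edges$bait,
                         scored$network$edges$prey)
  strict_keys <- edge_key(strict$edges$bait, strict$edges$prey)
  expect_true(all(strict_keys %in% final_keys))
  expect_gte(nrow(scored$network$edges), nrow(strict$edges))
})

test_that("recall against a reference stratum is plain set arithmetic", {
  net <- interaction_network(
    data.frame(bait = c("A", "A", "B", "C"),
               prey = c("P1", "P2", "P3", "P4")))
  ref <- data.frame(protein_a = c("A", "A", "P3", "A", "X", "Y", "Z", "Q",
                                  "R", "S"),
                    protein_b = c("P1", "P2", "B", "P9", "X2", "Y2", "Z2",
                                  "Q2", "R2", "S2"),
                    n_publications = c(2L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L,
                                       1L))
  expect_equal(recall_vs_reference(net, ref, 1L), 0.3)
  expect_equal(recall_vs_reference(net, ref, 2L), 1)
  # 4 of 10 present -> 0.4
  ref$n_publications <- 1L
  ref$protein_a[4] <- "C"; ref$protein_b[4] <- "P4"
  expect_equal(recall_vs_reference(net, ref, 1L), 0.4)
  expect_equal(recall_vs_reference(
    interaction_network(ref[, 1:2] |>
                          stats::setNames(c("bait", "prey"))), ref, 1L), 1)
  empty <- suppressWarnings(interaction_network(
    data.frame(bait = character(0), prey = character(0))))
  expect_equal(recall_vs_reference(empty, ref, 1L), 0)
  expect_error(recall_vs_reference(net, ref, 99L), "empty")
})

test_that("family dimer enumeration counts unordered linked pairs", {
  net <- interaction_network(data.frame(bait = c("a", "a"),
                                        prey = c("b", "c")))
  expect_equal(enumerate_family_dimers(net, c("a", "b", "c")), 2L)
  empty <- suppressWarnings(interaction_network(
    data.frame(bait = character(0), prey = character(0))))
  expect_equal(enumerate_family_dimers(empty, c("a", "b")), 0L)
  # family members outside the network contribute nothing
  expect_equal(enumerate_family_dimers(net, c("a", "b", "zz")), 1L)
})

test_that("the SARAH selectivity pattern implies 15 pairwise sub-complexes", {
  net <- sarah_selectivity_network()
  expect_equal(nrow(net$edges), 15L)
  expect_equal(enumerate_family_dimers(net, sarah_family()), 15L)
  # no RASSF-RASSF or RASSF-SAV1 pairs
  rasf <- grep("^RASF", sarah_family(), value = TRUE)
  expect_equal(enumerate_family_dimers(net, c(rasf, "SAV1")), 0L)
})
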