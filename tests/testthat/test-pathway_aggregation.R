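test_that("enrichment score hits its analytic extremes", {
  scores <- setNames(seq(10, 1), sprintf("g%d", 1:10))
  res <- prerankedGsea(scores, list(top = c("g1", "g2", "g3")), nPerm = 50,
                       seed = 1)
  expect_equal(res$ES, 1)   # peak before any miss
  expect_setequal(res$leadingEdge[[1]], c("g1", "g2", "g3"))

  # ES bounded and antisymmetric under score negation
  set.seed(3)
  sc <- setNames(rnorm(40), sprintf("h%d", 1:40))
  sets <- list(s1 = sprintf("h%d", c(1, 5, 9, 22)),
               s2 = sprintf("h%d", c(30, 33, 38)))
  a <- prerankedGsea(sc, sets, nPerm = 20, seed = 1)
  b <- prerankedGsea(-sc, sets, nPerm = 20, seed = 1)
  expect_true(all(abs(a$ES) <= 1))
  expect_equal(a$ES, -b$ES, tolerance = 1e-12)

  expect_error(prerankedGsea(sc, list(all = names(sc)), nPerm = 20),
               "whole ranked list")
  expect_warning(prerankedGsea(sc, list(out = "nope", s1 = sets$s1),
                               nPerm = 20), "skipped")
})

test_that("enrichment scores agree with an independent implementation", {
  skip_if_not_installed("fgsea")
  fx <- generateGseaFixture(gseaConfig(seed = 12, listLength = 500,
                                       nNullSets = 6, blocks = 0))
  stats <- setNames(fx$ranked$score, fx$ranked$gene)
  ours <- prerankedGsea(fx$ranked, fx$sets, nPerm = 50, seed = 1)
  for (nm in ours$pathway) {
    ref <- fgsea::calcGseaStat(stats, which(names(stats) %in% fx$sets[[nm]]))
    expect_equal(ours$ES[ours$pathway == nm], ref, tolerance = 1e-9)
  }
})

test_that("nominal p matches exhaustive same-size enumeration", {
  set.seed(21)
  scores <- setNames(sort(rnorm(6), decreasing = TRUE), sprintf("e%d", 1:6))
  set_ <- names(scores)[c(1, 3)]
  nPerm <- 2000
  res <- prerankedGsea(scores, list(s = set_), nPerm = nPerm, seed = 2)
  allES <- allSubsetES(unname(scores), 2)
  if (res$ES >= 0) {
    same <- allES[allES >= 0]
    pExact <- mean(same >= res$ES - 1e-12)
  } else {
    same <- allES[allES < 0]
    pExact <- mean(same <= res$ES + 1e-12)
  }
  se <- sqrt(pExact * (1 - pExact) / nPerm)
  expect_lt(abs(res$p - pExact), 3 * se + 2 / nPerm)
})

test_that("null-fixture p-values are uniform", {
  set.seed(33)
  genes <- sprintf("n%d", 1:800)
  scores <- setNames(rnorm(800), genes)
  sets <- lapply(1:200, function(i) sample(genes, 25))
  names(sets) <- sprintf("rand%03d", 1:200)
  res <- prerankedGsea(scores, sets, nPerm = 400, seed = 7)
  ks <- suppressWarnings(stats::ks.test(res$p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("enrichment filtering and merging follow the stated rules", {
  rec <- data.frame(pathway = c("a", "b", "c"), NES = c(0.5, -0.8, 2),
                    q = c(0.01, 0.01, 0.05))
  kept <- filterEnriched(rec)
  expect_identical(kept$pathway, "b")  # NES=0.5 and q=0.05 are excluded

  sets <- list(P1 = sprintf("x%d", 1:6), P2 = sprintf("y%d", 1:4))
  records <- data.frame(contrast = c("c1", "c2", "c1"),
                        pathway = c("P1", "P1", "P2"),
                        NES = c(2, 1, 0.7), q = c(0.01, 0.03, 0.2),
                        stringsAsFactors = FALSE)
  records$leadingEdge <- list(c("x1", "x2"), c("x2", "x3"), c("y1"))
  merged <- mergeRedundant(records, sets)
  p1 <- merged[merged$pathway == "P1", ]
  expect_equal(p1$mean_NES, 1.5)
  expect_equal(p1$gene_coverage, 3 / 6)
  p2 <- merged[merged$pathway == "P2", ]
  expect_equal(p2$mean_NES, 0.7)       # single contrast passes through
  expect_equal(p2$mean_FDR, 0.2)
  expect_error(mergeRedundant(transform(records, pathway = "ghost"), sets),
               "absent from the collection")
})

test_that("Jaccard matrix is exact, symmetric, and validates input", {
  sets <- list(s1 = c("A", "B"), s2 = c("B", "C"), s3 = c("A", "B"),
               s4 = c("D"))
  J <- jaccardMatrix(sets)
  expect_equal(J["s1", "s2"], 1 / 3)
  expect_equal(J["s1", "s3"], 1)
  expect_equal(J["s1", "s4"], 0)
  expect_true(isSymmetric(J))
  expect_equal(diag(J), setNames(rep(1, 4), names(sets)))
  expect_error(jaccardMatrix(list(a = "X")), "at least 2")
  expect_error(jaccardMatrix(list(a = "X", b = character())), "empty")
})

test_that("superpathway clustering recovers planted blocks exactly", {
  sets <- list(d1 = c("A", "B"), d2 = c("A", "B"), far = c("Q", "R"))
  cl <- clusterSuperpathways(jaccardMatrix(sets))
  expect_identical(cl[["d1"]], cl[["d2"]])
  expect_false(cl[["far"]] == cl[["d1"]])

  disjoint <- list(u = c("A"), v = c("B"), w = c("C"))
  expect_identical(unname(clusterSuperpathways(jaccardMatrix(disjoint))),
                   1:3)

  fx <- generateGseaFixture(gseaConfig(seed = 18))
  blockSets <- fx$sets[names(fx$truth$blockMembership)]
  J <- jaccardMatrix(blockSets)
  cl2 <- clusterSuperpathways(J)
  skip_if_not_installed("mclust")
  ari <- mclust::adjustedRandIndex(cl2, fx$truth$blockMembership)
  expect_equal(ari, 1.0)
  # agrees with the brute-force agglomeration oracle
  oracle <- bruteFlatClusters(1 - J, "average", 0.8)
  expect_equal(mclust::adjustedRandIndex(cl2, oracle), 1.0)
  # invariant to input permutation
  perm <- c(4, 2, 6, 1, 3, 5)
  clP <- clusterSuperpathways(J[perm, perm])
  expect_equal(mclust::adjustedRandIndex(cl2, clP[names(cl2)]), 1.0)
  expect_error(clusterSuperpathways(matrix(c(1, 0.2, 0.5, 1), 2)),
               "symmetric")
})

test_that("superpathway summaries and labels are deterministic", {
  sets <- list(A = c("g1", "g2"), B = c("g1", "g3"), C = c("z1", "z2"))
  merged <- data.frame(pathway = c("A", "B", "C"), n_contrasts = 1,
                       mean_NES = c(1, 3, -2), mean_FDR = c(0.01, 0.03, 0.2),
                       gene_coverage = c(0.5, 0.5, 1),
                       stringsAsFactors = FALSE)
  merged$contrasts <- list("c1", "c1", "c1")
  merged$leadingUnion <- list("g1", "g1", "z1")
  clusters <- c(A = 1L, B = 1L, C = 2L)
  sp <- summarizeSuperpathways(clusters, merged, sets)
  expect_equal(sp$mean_NES[sp$cluster == 1], 2)    # mean of 1 and 3
  expect_equal(sp$mean_NES[sp$cluster == 2], -2)   # singleton passes through
  expect_setequal(sp$genes[[1]], c("g1", "g2", "g3"))

  # member order does not change the metrics
  sp2 <- summarizeSuperpathways(clusters[c(2, 1, 3)], merged[c(2, 1, 3), ],
                                sets)
  expect_equal(sp2$mean_NES, sp$mean_NES)

  lab <- labelSuperpathway("myelin assembly")
  expect_identical(lab, c("myelin assembly", "assembly"))
  expect_identical(labelSuperpathway(rep("myelin assembly", 3)), lab)
  expect_error(labelSuperpathway(character()), "empty cluster")
  # stopword-only names fall back to the most frequent raw token
  expect_identical(labelSuperpathway("of the"), "of")
})
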