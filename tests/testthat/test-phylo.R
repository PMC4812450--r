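test_that("allele-sharing distance follows IBS counting", {
  # identical vectors -> 0; opposite homozygotes -> 1; hom vs het -> 0.5
  x <- vt(cbind(A = c(0L, 1L, 2L), B = c(0L, 1L, 2L)))
  expect_equal(allele_sharing_distance(x)$dist["A", "B"], 0)
  y <- vt(cbind(A = c(0L, 2L), B = c(2L, 0L)))
  expect_equal(allele_sharing_distance(y)$dist["A", "B"], 1)
  z <- vt(cbind(A = 0L, B = 1L))
  expect_equal(allele_sharing_distance(z)$dist["A", "B"], 0.5)
})

test_that("the distance is a semimetric computed over shared called sites", {
  set.seed(5)
  g <- matrix(sample(c(0L, 1L, 2L, NA), 300, TRUE), 100, 3,
              dimnames = list(NULL, c("A", "B", "C")))
  x <- vt(g)
  dm <- allele_sharing_distance(x)
  expect_equal(dm$dist, t(dm$dist))
  expect_equal(diag(dm$dist), c(A = 0, B = 0, C = 0))
  expect_true(all(dm$dist >= 0 & dm$dist <= 1))
  ok <- !is.na(g[, "A"]) & !is.na(g[, "B"])
  expect_equal(dm$n_sites["A", "B"], sum(ok))
  none <- vt(cbind(A = c(1L, NA), B = c(NA, 1L)))
  expect_error(allele_sharing_distance(none), "no comparable")
})

test_that("three-taxon NJ solves the closed-form pendant lengths", {
  d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tree <- neighbor_joining(d)
  bl <- setNames(tree$edge.length[tree$edge[, 2] <= 3],
                 tree$tip.label[tree$edge[tree$edge[, 2] <= 3, 2]])
  expect_equal(bl[c("A", "B", "C")], c(A = 1, B = 1, C = 3))
  expect_error(neighbor_joining(d[1:2, 1:2]), "at least 3")
})

test_that("NJ reproduces additive matrices exactly (random trees)", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(4:8, 1)
    ref <- ape::rtree(n, rooted = FALSE,
                      br = function(k) runif(k, 0.1, 2))
    d <- stats::cophenetic(ref)
    tree <- neighbor_joining(d)
    got <- stats::cophenetic(tree)[rownames(d), colnames(d)]
    expect_lt(max(abs(got - d)), 1e-9, label = paste("seed", seed))
    # independent route: ape's NJ on the same matrix
    ape_d <- stats::cophenetic(ape::nj(d))[rownames(d), colnames(d)]
    expect_lt(max(abs(got - ape_d)), 1e-8)
  }
})

test_that("equal distances resolve deterministically with no negatives", {
  d <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(d) <- 0
  t1 <- neighbor_joining(d)
  t2 <- neighbor_joining(d)
  expect_equal(ape::write.tree(t1), ape::write.tree(t2))
  expect_true(all(t1$edge.length >= 0))
})

test_that("midpoint rooting halves the longest leaf-to-leaf path", {
  two <- ape::read.tree(text = "(A:1,B:3);")
  r <- midpoint_root(two)
  h <- stats::cophenetic(r)
  expect_equal(h["A", "B"], 4)
  depths <- ape::node.depth.edgelength(r)
  expect_equal(depths[match(c("A", "B"), r$tip.label)], c(2, 2))
  # symmetric quartet: root lands on the central edge
  quartet <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  rq <- midpoint_root(ape::unroot(quartet))
  dq <- ape::node.depth.edgelength(rq)
  expect_equal(unname(dq[seq_len(4)]), rep(2, 4))
})

test_that("midpoint rooting matches brute force on a chain and phangorn", {
  chain <- ape::read.tree(text = "(((A:4,B:1):2,C:1):3,D:1);")
  r <- midpoint_root(ape::unroot(chain))
  dmat <- stats::cophenetic(chain)
  expect_equal(max(dmat), dmat["A", "D"])
  depths <- ape::node.depth.edgelength(r)
  expect_equal(depths[match("A", r$tip.label)], max(dmat) / 2)
  for (seed in 1:10) {
    set.seed(seed)
    tr <- ape::rtree(6, rooted = FALSE,
                     br = function(k) runif(k, 0.1, 2))
    mine <- stats::cophenetic(midpoint_root(tr))
    ref <- stats::cophenetic(phangorn::midpoint(tr))
    expect_lt(max(abs(mine[rownames(ref), colnames(ref)] - ref)), 1e-8)
    # leaf set unchanged
    expect_setequal(midpoint_root(tr)$tip.label, tr$tip.label)
  }
})

test_that("island-private variation groups each island into a clade", {
  for (seed in c(2, 4, 6)) {
    co <- simulate_cohort(5, 2, 400, 60, 40, seed = seed)
    dm <- allele_sharing_distance(co$variants)
    tree <- midpoint_root(neighbor_joining(dm$dist))
    panay <- names(co$island_map)[co$island_map == "panay"]
    negros <- names(co$island_map)[co$island_map == "negros"]
    expect_true(ape::is.monophyletic(tree, panay), info = seed)
    expect_true(ape::is.monophyletic(tree, negros), info = seed)
  }
})
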