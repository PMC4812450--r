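test_that("fixed differences and invariant sites are removed", {
  g <- rbind(rep(2L, 7),                 # fixed difference: all hom alt
             c(rep(2L, 6), 1L),         # one het: retained
             rep(0L, 7),                # not a variant
             c(rep(2L, 6), NA))         # missing does not break fixation
  x <- vt(g)
  y <- remove_fixed_differences(x)
  expect_equal(y$sites$pos, x$sites$pos[2])
})

test_that("the MAC filter counts haplotypes (het = 1, hom = 2)", {
  g <- rbind(c(1L, rep(0L, 6)),          # singleton het: MAC 1, removed
             c(1L, 1L, rep(0L, 5)),      # two hets: MAC 2, kept
             c(2L, rep(0L, 6)))          # one hom alt: MAC 2, kept
  x <- vt(g)
  y <- mac_filter(x, 2)
  expect_equal(y$sites$pos, x$sites$pos[2:3])
})

test_that("MAC counts the minor allele even when alt is the major allele", {
  # 6 hom alt + 1 het: alt = 13 of 14 haplotypes, minor (ref) count 1
  x <- vt(rbind(c(rep(2L, 6), 1L)))
  expect_equal(n_sites(mac_filter(x, 2)), 0)
})

test_that("fixed-difference and MAC filters commute", {
  set.seed(12)
  for (rep in 1:5) {
    g <- matrix(sample(c(0L, 1L, 2L, NA), 200 * 7, TRUE,
                       prob = c(0.5, 0.2, 0.2, 0.1)), 200, 7)
    colnames(g) <- paste0("S", 1:7)
    x <- vt(g)
    a <- mac_filter(remove_fixed_differences(x))
    b <- remove_fixed_differences(mac_filter(x))
    expect_equal(a$sites, b$sites)
    expect_equal(a$gt, b$gt)
  }
})

test_that("island partition classifies private and shared minor alleles", {
  map <- c(P1 = "panay", P2 = "panay", N1 = "negros")
  g <- rbind(c(1L, 1L, 0L),   # minor allele only in panay
             c(0L, 0L, 2L),   # minor allele only in negros
             c(1L, 0L, 1L))   # one het on each island: shared
  x <- vt(g)
  colnames(x$gt) <- colnames(x$dp) <- names(map)
  part <- partition_by_island(x, map)
  expect_equal(as.character(part$category),
               c("panay_private", "negros_private", "shared"))
  expect_error(partition_by_island(x, map[1:2]), "island map")
})

test_that("cohort partition recovers planted counts exactly over seeds", {
  for (seed in c(3, 14, 15)) {
    co <- simulate_cohort(4, 3, 200, 40, 25, seed = seed)
    part <- partition_by_island(co$variants, co$island_map)
    expect_equal(unname(part$counts[c("shared", "panay_private",
                                      "negros_private")]),
                 c(200L, 40L, 25L), info = seed)
  }
})

test_that("partition accounting: categories sum to the class total", {
  co <- simulate_cohort(5, 2, 300, 50, 20, seed = 9)
  annot <- data.frame(
    chrom = co$variants$sites$chrom,
    pos = co$variants$sites$pos,
    consequence = sample(c("synonymous", "nonsynonymous", "other"),
                         n_sites(co$variants), TRUE),
    sift_score = NA_real_)
  ns <- annot$consequence == "nonsynonymous"
  set.seed(1); annot$sift_score[ns] <- runif(sum(ns))
  res <- partition_table(co$variants, co$island_map, annot = annot)
  tab <- res$table
  cat_cols <- c("shared", "panay_private", "negros_private")
  expect_equal(rowSums(tab[, cat_cols]), tab$total)
  expect_equal(tab$total[tab$class == "all"], 370)
})

test_that("SIFT classification splits tolerated from not-tolerated at 0.05", {
  annot <- data.frame(chrom = "chr1", pos = 1:5,
                      consequence = c("nonsynonymous", "nonsynonymous",
                                      "nonsynonymous", "synonymous",
                                      "other"),
                      sift_score = c(0, 1, 0.05, NA, NA))
  cls <- classify_sift(annot)
  expect_equal(cls$class,
               c("nonsyn_not_tolerated", "nonsyn_tolerated",
                 "nonsyn_tolerated", "synonymous", "other"))
  bad <- annot; bad$sift_score[1] <- 1.2
  expect_error(classify_sift(bad), "outside")
})

test_that("het/hom ratios handle the zero-homozygote case", {
  g <- rbind(matrix(1L, 5, 2), matrix(2L, 2, 2),  # class a: 10 het, 4 hom
             matrix(1L, 3, 2))                    # class b: 6 het, 0 hom
  x <- vt(g)
  cls <- c(rep("a", 7), rep("b", 3))
  r <- het_hom_ratio(x, cls)
  expect_equal(r$ratio[r$class == "a"], 2.5)
  expect_true(is.na(r$ratio[r$class == "b"]))
  expect_false(r$defined[r$class == "b"])
  expect_equal(r$ratio[r$class == "a"],
               r$n_het[r$class == "a"] / r$n_hom[r$class == "a"])
})
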