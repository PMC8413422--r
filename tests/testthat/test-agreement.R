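test_that("spearman_correlation matches hand-computed and boundary cases", {
  x <- c(1, 2, 3, 4)
  expect_equal(spearman_correlation(x, c(2, 1, 4, 3)), 0.6)
  expect_equal(spearman_correlation(x, exp(x)), 1.0)   # monotone transform
  expect_equal(spearman_correlation(x, -x), -1.0)
  expect_true(is.na(spearman_correlation(x, rep(2, 4))))
  expect_error(spearman_correlation(x, 1:3), "equal length")
  expect_error(spearman_correlation(1:2, 2:3), "at least 3")
  expect_error(spearman_correlation(c(1, NA, 3), 1:3), "finite")
})

test_that("spearman_correlation is invariant under monotone transforms", {
  set.seed(31)
  for (i in 1:20) {
    x <- rnorm(50); y <- rnorm(50)
    r <- spearman_correlation(x, y)
    expect_equal(spearman_correlation(exp(x), y), r)
    expect_equal(spearman_correlation(x, y^3 + 5 * y), r)
  }
})

test_that("ternary_jaccard matches its displayed-formula semantics", {
  a <- c(1, -1, 0, 1); b <- c(1, 1, 0, 0)
  expect_equal(ternary_jaccard(a, b), 1 / 3)
  expect_equal(ternary_jaccard(a, a), 1.0)
  expect_equal(ternary_jaccard(c(0, 0), c(0, 0)), 0.0)  # empty case is 0, not 1
  # sign-flipped overlap: counts in the denominator, never the numerator
  expect_equal(ternary_jaccard(c(1, 0), c(-1, 0)), 0.0)
  expect_error(ternary_jaccard(c(2, 0), c(0, 0)), "ternary")
})

test_that("ternary_jaccard is symmetric, bounded, and 1 only on nonzero self-match", {
  set.seed(12)
  for (i in 1:50) {
    a <- random_ternary(30); b <- random_ternary(30)
    j <- ternary_jaccard(a, b)
    expect_gte(j, 0); expect_lte(j, 1)
    expect_equal(j, ternary_jaccard(b, a))
    expect_equal(ternary_jaccard(a, a), as.numeric(any(a != 0)))
  }
})

test_that("within-dataset agreement scores all replicate pairs and takes the max", {
  set.seed(7)
  vals <- matrix(rnorm(30), nrow = 10,
                 dimnames = list(sprintf("G%02d", 1:10), c("r1", "r2", "r3")))
  vals[1:4, ] <- vals[1:4, ] + 3  # some shared DE
  prof <- make_profiles(vals, rep("x", 3), 10, "MCF7")
  res <- within_dataset_agreement(prof, "spearman")
  expect_equal(nrow(res$pairs), choose(3, 2))
  expect_equal(res$summary$max_value, max(res$pairs$value))
  expect_equal(res$summary$n_pairs, 3L)
  # lesser DE count per pair equals the min of the two ternarized counts
  counts <- count_de_genes(ternarize(prof))
  i1 <- match(res$pairs$profile_1, prof$meta$profile_id)
  i2 <- match(res$pairs$profile_2, prof$meta$profile_id)
  expect_equal(res$pairs$lesser_de_count, pmin(counts[i1], counts[i2]),
               ignore_attr = TRUE)
})

test_that("single-profile conditions are excluded; filters apply", {
  vals <- matrix(rnorm(40), nrow = 10,
                 dimnames = list(sprintf("G%02d", 1:10), paste0("p", 1:4)))
  prof <- make_profiles(vals, c("x", "x", "y", "z"),
                        10, c("MCF7", "MCF7", "MCF7", "PC3"))
  res <- within_dataset_agreement(prof, "spearman")
  expect_equal(unique(sapply(strsplit(res$pairs$condition, "|", fixed = TRUE),
                             `[`, 1)), "x")
  res_pc3 <- suppressMessages(
    within_dataset_agreement(prof, "spearman", cell_lines = "PC3"))
  expect_equal(nrow(res_pc3$pairs), 0L)
})

test_that("identical replicates give maximal agreement 1", {
  vals <- matrix(rep(rnorm(10), 2), nrow = 10,
                 dimnames = list(sprintf("G%02d", 1:10), c("a", "b")))
  prof <- make_profiles(vals, c("x", "x"), 10, "MCF7")
  res <- within_dataset_agreement(prof, "spearman")
  expect_equal(res$summary$max_value, 1.0)
})

test_that("harmonization matches exactly or within relative concentration tolerance", {
  g <- sprintf("G%02d", 1:12)
  va <- matrix(rnorm(36), nrow = 12, dimnames = list(g, c("a1", "a2", "a3")))
  vb <- matrix(rnorm(36), nrow = 12, dimnames = list(g, c("b1", "b2", "b3")))
  pa <- make_profiles(va, c("x", "y", "z"), c(10, 10, 10), "MCF7")
  pb <- make_profiles(vb, c("x", "y", "z"), c(10, 14, 20), "MCF7")
  exact <- harmonize(pa, pb, conc_tolerance = 0)
  expect_equal(length(exact$pairs), 1L)
  expect_setequal(exact$unmatched, pa$meta$condition[2:3])
  tol <- harmonize(pa, pb, conc_tolerance = 0.5)
  # |10-14|/10 = 0.4 < 0.5 matches; |10-20|/10 = 1.0 does not
  expect_equal(length(tol$pairs), 2L)
  expect_setequal(tol$unmatched, pa$meta$condition[3])
})

test_that("cross-dataset agreement is 1 for identical profiles and respects the universe", {
  g <- sprintf("G%02d", 1:30)
  va <- matrix(rnorm(30), nrow = 30, dimnames = list(g, "a1"))
  pa <- make_profiles(va, "x", 10, "MCF7")
  pb <- make_profiles(va, "x", 10, "MCF7")
  pb$meta$profile_id <- pb$meta$replicate_group <- "b1"
  colnames(pb$values) <- "b1"
  harm <- harmonize(pa, pb)
  res <- cross_dataset_agreement(harm, "spearman", "all")
  expect_equal(res$value, 1.0)
  lm_ids <- g[1:15]
  res_lm <- cross_dataset_agreement(harm, "spearman", "landmark",
                                    landmark_ids = lm_ids)
  expect_equal(res_lm$n_shared_genes, 15L)
  # a too-small landmark set skips the pair with a reason
  res_skip <- cross_dataset_agreement(harm, "spearman", "landmark",
                                      landmark_ids = g[1:5])
  expect_true(is.na(res_skip$value))
  expect_equal(res_skip$skipped, "shared_gene_index_below_minimum")
})

test_that("in-replicate agreement is the min of within-replicate maxima", {
  set.seed(9)
  g <- 40
  m1 <- matrix(rnorm(g * 3), nrow = g)
  m2 <- matrix(rnorm(g * 4), nrow = g)
  got <- in_replicate_sample_agreement(m1, m2)
  brute_max <- function(m) {
    best <- -Inf
    for (i in seq_len(ncol(m) - 1)) for (j in seq(i + 1, ncol(m)))
      best <- max(best, spearman_correlation(m[, i], m[, j]))
    best
  }
  expect_equal(got, min(brute_max(m1), brute_max(m2)))
  # duplicated identical samples saturate at 1
  dup <- cbind(m1[, 1], m1[, 1])
  expect_equal(in_replicate_sample_agreement(dup, dup), 1.0)
  # a replicate with one sample yields a missing value with a reason
  one <- m1[, 1, drop = FALSE]
  res <- in_replicate_sample_agreement(one, m2)
  expect_true(is.na(res))
  expect_match(attr(res, "reason"), "fewer_than_2")
})

test_that("cross-replicate agreement is the max over all cross pairs", {
  set.seed(10)
  g <- 40
  m1 <- matrix(rnorm(g * 3), nrow = g)
  m2 <- matrix(rnorm(g * 2), nrow = g)
  got <- cross_replicate_sample_agreement(m1, m2)
  vals <- c()
  for (i in 1:3) for (j in 1:2)
    vals <- c(vals, spearman_correlation(m1[, i], m2[, j]))
  expect_equal(got, max(vals))
  # a copied sample gives exactly 1
  expect_equal(cross_replicate_sample_agreement(m1, m1[, 2, drop = FALSE]), 1.0)
  # independent random samples at 1000 genes correlate near zero
  set.seed(11)
  big1 <- matrix(rnorm(1000), ncol = 1); big2 <- matrix(rnorm(1000), ncol = 1)
  expect_lt(abs(cross_replicate_sample_agreement(big1, big2)), 0.1)
})
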