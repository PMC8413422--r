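test_that("collapse_probes keeps the greatest-magnitude probe per gene per profile", {
  m <- rbind(pA = c(0.5, 3.0), pB = c(-2.0, 0.1), pC = c(1.0, -4.0))
  map <- data.frame(probe_id = c("pA", "pB", "pC"),
                    gene_id = c("G1", "G1", "G2"))
  out <- collapse_probes(m, map)
  # per profile independently: G1 takes -2.0 then +3.0
  expect_equal(out["G1", ], c(-2.0, 3.0))
  expect_equal(out["G2", ], c(1.0, -4.0))
})

test_that("probes mapping to multiple genes are removed regardless of value", {
  m <- rbind(pA = c(100, 100), pB = c(0.2, 0.3))
  map <- data.frame(probe_id = c("pA", "pA", "pB"),
                    gene_id = c("G1", "G2", "G1"))
  out <- collapse_probes(m, map)
  expect_equal(rownames(out), "G1")
  expect_equal(out["G1", ], c(0.2, 0.3))
})

test_that("collapse_probes is the identity for one probe per gene, and idempotent", {
  set.seed(3)
  m <- matrix(rnorm(12), nrow = 4,
              dimnames = list(paste0("p", 1:4), paste0("s", 1:3)))
  map <- data.frame(probe_id = paste0("p", 1:4), gene_id = paste0("G", 1:4))
  out <- collapse_probes(m, map)
  expect_equal(out[order(rownames(out)), ],
               {mm <- m; rownames(mm) <- paste0("G", 1:4); mm[order(rownames(mm)), ]})
  idmap <- data.frame(probe_id = rownames(out), gene_id = rownames(out))
  expect_equal(collapse_probes(out, idmap), out)
  expect_error(collapse_probes(m, map[0, ]), "empty")
})

test_that("representative-profile selection is seeded and valid", {
  vals <- matrix(rnorm(50), nrow = 5,
                 dimnames = list(paste0("G", 1:5), paste0("r", 1:10)))
  prof <- make_profiles(vals, compound = rep(c("a", "b"), each = 5),
                        concentration_uM = 10, cell_line = "MCF7")
  r1 <- select_representative_profiles(prof, seed = 4)
  r2 <- select_representative_profiles(prof, seed = 4)
  expect_identical(r1$values, r2$values)
  expect_equal(ncol(r1$values), 2L)
  expect_setequal(r1$meta$condition, unique(prof$meta$condition))
  # all picks are members of the duplicate set
  expect_true(all(r1$meta$profile_id %in% prof$meta$profile_id))
  # single-profile condition returns that profile
  single <- subset_profiles(prof, 1)
  expect_identical(select_representative_profiles(single, 9)$values, single$values)
})

test_that("fold-change profiles are exact group-mean differences", {
  genes <- c("G1", "G2")
  vals <- cbind(t1 = c(5, 1), t2 = c(5, 2), c1 = c(3, 0), c2 = c(3, 1))
  rownames(vals) <- genes
  meta <- data.frame(
    sample_id = colnames(vals), compound = c("x", "x", "DMSO", "DMSO"),
    concentration_uM = c(10, 10, NA, NA), cell_line = "MCF7", duration_h = 6,
    role = c("treatment", "treatment", "control", "control"),
    plate_pool = "p1", replicate_group = c("t", "t", "c", "c"),
    stringsAsFactors = FALSE)
  corpus <- structure(list(values = vals,
                           gene_info = data.frame(gene_id = genes,
                                                  landmark = c(TRUE, FALSE)),
                           sample_meta = meta, platform = "A"),
                      class = "expr_corpus")
  de <- compute_fc_profiles(corpus, seed = 1)
  expect_equal(ncol(de$values), 1L)
  expect_equal(unname(de$values[, 1]), c(2.0, 1.0))
  expect_equal(de$meta$n_contributing_replicates, 2L)
})

test_that("undersized and control-less groups are skipped with reasons", {
  genes <- paste0("G", 1:3)
  vals <- matrix(rnorm(18), nrow = 3, dimnames = list(genes, paste0("s", 1:6)))
  meta <- data.frame(
    sample_id = colnames(vals),
    compound = c("x", "DMSO", "DMSO", "y", "y", "y"),
    concentration_uM = c(10, NA, NA, 5, 5, 5), cell_line = "MCF7",
    duration_h = 6,
    role = c("treatment", "control", "control",
             "treatment", "treatment", "treatment"),
    plate_pool = c("p1", "p1", "p1", "p2", "p2", "p2"),
    replicate_group = c("tx", "cx", "cx", "ty", "ty", "ty"),
    stringsAsFactors = FALSE)
  corpus <- structure(list(values = vals,
                           gene_info = data.frame(gene_id = genes,
                                                  landmark = TRUE),
                           sample_meta = meta, platform = "A"),
                      class = "expr_corpus")
  de <- compute_fc_profiles(corpus, seed = 1)
  expect_equal(ncol(de$values), 0L)
  expect_setequal(de$exclusions$replicate_group, c("tx", "ty"))
  expect_match(de$exclusions$reason[de$exclusions$replicate_group == "tx"],
               "below_minimum")
  expect_match(de$exclusions$reason[de$exclusions$replicate_group == "ty"],
               "no_plate_matched_control")
})

test_that("oversized groups are subsampled to a common size within bounds", {
  genes <- paste0("G", 1:2)
  n_t <- 25; n_c <- 4
  vals <- matrix(rnorm(2 * (n_t + n_c)), nrow = 2,
                 dimnames = list(genes, c(paste0("t", 1:n_t), paste0("c", 1:n_c))))
  meta <- data.frame(
    sample_id = colnames(vals),
    compound = c(rep("x", n_t), rep("DMSO", n_c)),
    concentration_uM = c(rep(10, n_t), rep(NA, n_c)), cell_line = "MCF7",
    duration_h = 6, role = c(rep("treatment", n_t), rep("control", n_c)),
    plate_pool = "p1", replicate_group = c(rep("t", n_t), rep("c", n_c)),
    stringsAsFactors = FALSE)
  corpus <- structure(list(values = vals,
                           gene_info = data.frame(gene_id = genes, landmark = TRUE),
                           sample_meta = meta, platform = "A"),
                      class = "expr_corpus")
  de <- compute_fc_profiles(corpus, seed = 2)
  expect_equal(de$meta$n_contributing_replicates, 4L)
  expect_lte(de$meta$n_contributing_replicates, 20L)
})

test_that("noiseless fold changes recover scaled planted effect vectors", {
  spec <- noiseless_spec()
  truth <- generate_ground_truth(spec)
  corpus <- simulate_corpus(truth, spec, "A")
  de <- compute_fc_profiles(corpus, seed = 3)
  for (j in c(1L, ncol(de$values))) {
    m <- de$meta[j, ]
    key <- paste(m$compound, m$cell_line, sep = "|")
    scl <- dose_scaling(m$concentration_uM, truth$ec50[[m$compound]],
                        truth$hill[[m$compound]]) *
      truth$responsiveness[m$compound, m$cell_line]
    expect_equal(unname(de$values[, j]), unname(scl * truth$effects_a[, key]),
                 tolerance = 1e-10)
  }
})

test_that("de-standardization multiplies by sqrt(n) and checks kind", {
  vals <- matrix(c(1.5, 0, -1.5), ncol = 1,
                 dimnames = list(paste0("G", 1:3), "p1"))
  prof <- make_profiles(vals, "x", 10, "MCF7", kind = "MZS", n_reps = 4L)
  out <- destandardize_mzs(prof)
  expect_equal(unname(out$values[, 1]), c(3.0, 0, -3.0))
  n1 <- make_profiles(vals, "x", 10, "MCF7", kind = "MZS", n_reps = 1L)
  expect_equal(destandardize_mzs(n1)$values, n1$values)
  fc <- make_profiles(vals, "x", 10, "MCF7", kind = "FC")
  expect_error(destandardize_mzs(fc), "MZS")
})

test_that("ternarize applies inclusive cutoffs per kind", {
  expect_equal(ternarize(c(1.2, -0.5, -1.0)), c(1L, 0L, -1L))
  expect_equal(ternarize(c(0, 0, 0)), c(0L, 0L, 0L))
  # z = 1.1 with n = 4 de-standardizes to 2.2 >= 2
  expect_equal(ternarize(1.1, kind = "MZS", n = 4), 1L)
  expect_equal(ternarize(0.9, kind = "MZS", n = 4), 0L)
  # boundary values count as DE
  expect_equal(ternarize(c(1, -1)), c(1L, -1L))
})

test_that("ternarizing MZS commutes with explicit de-standardization", {
  set.seed(42)
  vals <- matrix(rnorm(60), nrow = 20,
                 dimnames = list(sprintf("G%02d", 1:20), paste0("p", 1:3)))
  prof <- make_profiles(vals, rep("x", 3), 10, "MCF7", kind = "MZS", n_reps = 5L)
  t1 <- ternarize(prof)
  direct <- apply(destandardize_mzs(prof)$values, 2, function(v)
    (v >= 2) - (v <= -2))
  expect_equal(unname(t1$values), unname(direct))
})

test_that("count_de_genes matches brute-force enumeration", {
  expect_equal(count_de_genes(c(1L, 0L, -1L, 0L)), 2)
  expect_equal(count_de_genes(integer(4)), 0)
  set.seed(8)
  for (i in 1:20) {
    v <- random_ternary(40)
    expect_equal(count_de_genes(v), sum(v == 1) + sum(v == -1))
  }
  expect_error(count_de_genes(c(2L, 0L)), "ternary")
})
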