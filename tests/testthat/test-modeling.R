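test_that("regression input takes Y, X1, X2, X3 from the max pair", {
  sm <- data.frame(condition = c("c1", "c2", "c3"),
                   max_value = c(0.8, 0.5, NA),
                   n_pairs = 3L, best_profile_1 = "p1", best_profile_2 = "p2",
                   lesser_de_count = c(45, 120, 10),
                   in_replicate = c(0.9, NA, 0.8),
                   cross_replicate = c(0.7, 0.6, 0.5),
                   stringsAsFactors = FALSE)
  input <- build_regression_input(list(summary = sm))
  expect_equal(nrow(input$data), 1L)       # rows with missing parts dropped
  expect_equal(input$n_excluded, 2L)
  expect_equal(input$data$X1, 45)          # lesser DE count of the pair
  expect_equal(input$data$Y, 0.8)
  expect_error(build_regression_input(list(summary = sm[, 1:3])),
               "sample agreements")
})

test_that("noiseless planted coefficients are recovered to high precision", {
  set.seed(17)
  n <- 200
  X <- matrix(rnorm(3 * n), ncol = 3)
  z <- scale(X)
  y <- 0.60 * z[, 1] + 0.13 * z[, 2] + 0.19 * z[, 3]
  df <- data.frame(Y = y, X1 = X[, 1], X2 = X[, 2], X3 = X[, 3])
  fit <- suppressWarnings(standardized_linear_fit(df))  # perfect-fit notice
  # noiseless OLS identity: coefficients on z-scored variables, up to the
  # rescaling of Y by its own sd
  b <- fit$standardized_coefficients * sd(y)
  expect_equal(unname(b), c(0.60, 0.13, 0.19), tolerance = 1e-6)
  expect_equal(fit$r_squared, 1.0, tolerance = 1e-10)
})

test_that("orthogonal standardized predictors give coefficients equal to simple correlations", {
  set.seed(18)
  n <- 2000
  X <- matrix(rnorm(3 * n), ncol = 3)
  X <- qr.Q(qr(X)) * sqrt(n)  # exactly orthogonal columns
  y <- 0.5 * X[, 1] - 0.2 * X[, 2] + rnorm(n, 0, 0.5)
  df <- data.frame(Y = y, X1 = X[, 1], X2 = X[, 2], X3 = X[, 3])
  fit <- standardized_linear_fit(df)
  simple_r <- c(cor(y, X[, 1]), cor(y, X[, 2]), cor(y, X[, 3]))
  expect_equal(unname(fit$standardized_coefficients), simple_r,
               tolerance = 1e-2)
})

test_that("the OLS engine matches a normal-equations oracle", {
  set.seed(19)
  for (i in 1:10) {
    n <- sample(15:50, 1)
    df <- data.frame(Y = rnorm(n), X1 = rnorm(n), X2 = rnorm(n), X3 = rnorm(n))
    fit <- standardized_linear_fit(df)
    z <- scale(as.matrix(df))
    X <- cbind(1, z[, c("X1", "X2", "X3")])
    beta <- solve(t(X) %*% X, t(X) %*% z[, "Y"])
    expect_equal(unname(fit$standardized_coefficients),
                 unname(beta[2:4, 1]), tolerance = 1e-8)
  }
})

test_that("collinear designs raise an error naming the problem", {
  set.seed(20)
  x <- rnorm(30)
  df <- data.frame(Y = rnorm(30), X1 = x, X2 = 2 * x, X3 = rnorm(30))
  expect_error(standardized_linear_fit(df), "collinear")
  expect_error(standardized_linear_fit(df[1:5, ]), "at least 10")
})

test_that("null simulations show no spurious standardized effects", {
  set.seed(23)
  hits <- 0L
  for (s in 1:20) {
    df <- data.frame(Y = rnorm(2000), X1 = rnorm(2000), X2 = rnorm(2000),
                     X3 = rnorm(2000))  # response independent of predictors
    fit <- standardized_linear_fit(df)
    if (all(abs(fit$standardized_coefficients) < 0.07)) hits <- hits + 1L
  }
  expect_gte(hits, 19L)
})

test_that("dose_trend applies both eligibility filters", {
  # conditions: compound 'good' at 3 concentrations x 3 replicates;
  # compound 'few_conc' at 2 concentrations; condition with 2 replicates
  g <- sprintf("G%02d", 1:20)
  mk_cols <- function(n, shift) matrix(rnorm(20 * n) + shift, nrow = 20)
  vals <- cbind(mk_cols(3, 0), mk_cols(3, 1), mk_cols(3, 2),
                mk_cols(3, 0), mk_cols(3, 1), mk_cols(2, 0))
  colnames(vals) <- sprintf("p%02d", seq_len(ncol(vals)))
  rownames(vals) <- g
  prof <- make_profiles(
    vals,
    compound = c(rep("good", 9), rep("few_conc", 6), rep("two_reps", 2)),
    concentration_uM = c(rep(c(1, 5, 25), each = 3), rep(c(1, 5), each = 3),
                         rep(1, 2)),
    cell_line = "MCF7")
  within <- within_dataset_agreement(prof, "spearman")
  dt <- dose_trend(within, prof, min_replicates = 3, min_concentrations = 3)
  expect_equal(dt$records$compound, "good")
  expect_true(any(grepl("few_conc", dt$ineligible$group)))
  # the two-replicate condition contributes no pairs at all
  expect_false(any(dt$points$compound == "two_reps"))
})

test_that("dose_trend is exactly +1 on a strictly monotone noiseless relationship", {
  g <- sprintf("G%02d", 1:20)
  set.seed(22)
  # one replicate pair per dose, with agreement a strictly increasing
  # function of dose: shared signal grows while replicate noise shrinks
  concs <- c(0.5, 2, 8, 32, 128)
  base <- rnorm(20)
  cols <- list(); cc <- c()
  for (i in seq_along(concs)) {
    shared <- base * i
    cols[[length(cols) + 1]] <- shared + rnorm(20, 0, 3 / i^2)
    cols[[length(cols) + 1]] <- shared + rnorm(20, 0, 3 / i^2)
    cc <- c(cc, rep(concs[i], 2))
  }
  vals <- do.call(cbind, cols)
  dimnames(vals) <- list(g, sprintf("p%02d", seq_len(ncol(vals))))
  prof <- make_profiles(vals, "x", cc, "MCF7")
  within <- within_dataset_agreement(prof, "spearman")
  conc <- as.numeric(sapply(strsplit(within$pairs$condition, "|", fixed = TRUE),
                            `[`, 2))
  stopifnot(all(diff(within$pairs$value[order(conc)]) > 0))  # construction sanity
  dt <- dose_trend(within, prof, min_replicates = 2)
  expect_equal(dt$records$trend_statistic, 1.0)
})

test_that("DE counts per dose reflect the planted dose-response", {
  spec <- noiseless_spec(compounds = c("drugA", "drugB"),
                         concentrations = c(0.05, 0.5, 5, 50),
                         cell_lines = "MCF7",
                         n_replicate_profiles = 1L,
                         frac_de_genes = 0.3)
  truth <- generate_ground_truth(
    spec,
    responsiveness = matrix(c(1, 0), 2, 1,
                            dimnames = list(c("drugA", "drugB"), "MCF7")),
    ec50 = c(drugA = 1, drugB = 1), hill = c(drugA = 1.5, drugB = 1.5))
  corpus <- simulate_corpus(truth, spec, "A")
  de <- compute_fc_profiles(corpus, seed = 2)
  tab <- de_count_vs_dose(de)
  a <- tab[tab$compound == "drugA", ]
  expect_true(all(diff(a$de_count) >= 0))      # nondecreasing in dose
  # at saturation the count equals the planted genes clearing the cutoff
  scl <- dose_scaling(50, 1, 1.5)
  expected <- sum(abs(scl * truth$effects_a[, "drugA|MCF7"]) >= 1)
  expect_equal(a$de_count[a$concentration_uM == 50], expected)
  b <- tab[tab$compound == "drugB", ]
  expect_true(all(b$de_count == 0))            # unresponsive: no DE at any dose
})
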