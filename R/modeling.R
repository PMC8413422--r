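# Explanatory analyses: the three-predictor standardized regression of
# within-dataset DE agreement, and dose-trend analysis under replicate and
# concentration eligibility filters.

#' Build the regression input table
#'
#' One row per condition: the response `Y` is the condition's maximal
#' pairwise DE agreement; `X1` is the lesser DE-gene count of the pair that
#' achieved the maximum (the limiting profile's strength); `X2` and `X3`
#' are the in-replicate and cross-replicate sample agreements of that same
#' pair. Rows with any missing component are excluded and counted.
#'
#' @param within result of [within_dataset_agreement()] passed through
#'   [add_sample_agreement()].
#' @return list with `data` (data frame: condition, Y, X1, X2, X3) and
#'   `n_excluded`.
#' @export
build_regression_input <- function(within) {
  sm <- within$summary
  needed <- c("max_value", "lesser_de_count", "in_replicate", "cross_replicate")
  if (!all(needed %in% names(sm)))
    stop("summary lacks sample agreements; run add_sample_agreement() first")
  df <- data.frame(condition = sm$condition, Y = sm$max_value,
                   X1 = sm$lesser_de_count, X2 = sm$in_replicate,
                   X3 = sm$cross_replicate, stringsAsFactors = FALSE)
  ok <- stats::complete.cases(df)
  list(data = df[ok, , drop = FALSE], n_excluded = sum(!ok))
}

#' Standardized three-predictor linear fit
#'
#' Ordinary least squares of `Y` on `(X1, X2, X3)` after z-scoring the
#' response and every predictor, so the reported coefficients are
#' standardized regression coefficients. An intercept is retained for
#' numerical stability (it is ~0 on standardized data).
#'
#' @param input result of [build_regression_input()], or a data frame with
#'   columns `Y`, `X1`, `X2`, `X3`.
#' @return a `regression_fit`: `standardized_coefficients` (named length-3),
#'   `adjusted_r_squared`, `r_squared`, `f_statistic` (with `df1`, `df2`),
#'   `coefficient_p_values`, `n_used`.
#' @export
standardized_linear_fit <- function(input) {
  df <- if (is.data.frame(input)) input else input$data
  if (!all(c("Y", "X1", "X2", "X3") %in% names(df)))
    stop("input must contain columns Y, X1, X2, X3")
  df <- df[stats::complete.cases(df[, c("Y", "X1", "X2", "X3")]), , drop = FALSE]
  n <- nrow(df)
  if (n < 10) stop("need at least 10 complete rows")
  zs <- function(v) {
    s <- stats::sd(v)
    if (s == 0) return(rep(0, length(v)))
    (v - mean(v)) / s
  }
  z <- data.frame(Y = zs(df$Y), X1 = zs(df$X1), X2 = zs(df$X2), X3 = zs(df$X3))
  X <- cbind(1, as.matrix(z[, c("X1", "X2", "X3")]))
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[-(qx$pivot[seq_len(qx$rank)])]
    stop(sprintf("rank-deficient design; collinear column(s): %s",
                 paste(bad, collapse = ", ")))
  }
  fit <- stats::lm(Y ~ X1 + X2 + X3, data = z)
  sm <- summary(fit)
  coefs <- stats::coef(fit)[c("X1", "X2", "X3")]
  pvals <- sm$coefficients[c("X1", "X2", "X3"), "Pr(>|t|)"]
  structure(list(
    standardized_coefficients = coefs,
    r_squared = sm$r.squared,
    adjusted_r_squared = sm$adj.r.squared,
    f_statistic = unname(sm$fstatistic["value"]),
    df1 = unname(sm$fstatistic["numdf"]), df2 = unname(sm$fstatistic["dendf"]),
    coefficient_p_values = pvals,
    n_used = n, lm_fit = fit), class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf(
    "regression_fit: B = (%.3f, %.3f, %.3f), adj-R2 = %.3f, F(%d, %d) = %.1f, n = %d\n",
    x$standardized_coefficients[1], x$standardized_coefficients[2],
    x$standardized_coefficients[3], x$adjusted_r_squared,
    x$df1, x$df2, x$f_statistic, x$n_used))
  invisible(x)
}

#' Simulate data from the three-predictor agreement model
#'
#' Generates data in which `beta` are the true *standardized* regression
#' coefficients: predictors and response all have unit population
#' variance, so a z-scored fit estimates `beta` directly. With three
#' coefficients the population R-squared is `b' R b` (with `R` the
#' predictor correlation matrix); a common pairwise predictor correlation
#' is solved for analytically so that the population R-squared equals
#' `r_squared`, and the residual variance is `1 - r_squared`.
#'
#' @param n number of rows.
#' @param beta length-3 standardized coefficients.
#' @param r_squared target population R-squared in (0, 1). Must be
#'   attainable: with a common predictor correlation `r > -0.5` this
#'   requires `r_squared` reachable from `sum(beta^2)` through the
#'   cross-terms of `beta`.
#' @param seed integer seed.
#' @return data frame with columns `Y`, `X1`, `X2`, `X3`.
#' @export
simulate_regression_data <- function(n, beta = c(0.60, 0.13, 0.19),
                                     r_squared = 0.37, seed = 1L) {
  stopifnot(length(beta) == 3, r_squared > 0, r_squared < 1)
  s2 <- sum(beta^2)
  cross <- beta[1] * beta[2] + beta[1] * beta[3] + beta[2] * beta[3]
  if (abs(r_squared - s2) < 1e-12) {
    r <- 0
  } else {
    if (abs(cross) < 1e-12)
      stop("r_squared != sum(beta^2) requires nonzero coefficient cross-terms")
    r <- (r_squared - s2) / (2 * cross)
  }
  if (r <= -0.5 || r >= 1)
    stop("target r_squared is not attainable with a common predictor correlation")
  R <- matrix(r, 3, 3); diag(R) <- 1
  L <- chol(R)
  resid_sd <- sqrt(1 - r_squared)
  with_seed(seed, {
    X <- matrix(stats::rnorm(3 * n), ncol = 3) %*% L
    Y <- as.numeric(X %*% beta) + stats::rnorm(n, 0, resid_sd)
  })
  data.frame(Y = Y, X1 = X[, 1], X2 = X[, 2], X3 = X[, 3])
}

# parse condition keys back into their four fields
split_condition <- function(cond) {
  parts <- strsplit(cond, "|", fixed = TRUE)
  data.frame(compound = vapply(parts, `[`, "", 1),
             concentration_uM = as.numeric(vapply(parts, `[`, "", 2)),
             cell_line = vapply(parts, `[`, "", 3),
             duration_h = as.numeric(vapply(parts, `[`, "", 4)),
             stringsAsFactors = FALSE)
}

#' Dose-trend analysis of within-dataset agreement
#'
#' Restricts the pairwise agreement values to conditions with at least
#' `min_replicates` replicate profiles and to (compound, cell line) groups
#' spanning at least `min_concentrations` distinct concentrations, then
#' summarizes each group's dose trend as the Spearman correlation of the
#' pooled pairwise agreement values against log10 concentration.
#'
#' @param within result of [within_dataset_agreement()].
#' @param profiles the `de_profiles` the agreement was computed from (used
#'   to count replicate profiles per condition).
#' @param min_replicates minimum replicate profiles per condition
#'   (default 3).
#' @param min_concentrations minimum distinct concentrations per
#'   (compound, cell line) (default 3).
#' @param n_perm number of condition-level permutations for the trend
#'   p-value. The pooled pairwise values within a condition share
#'   profiles and are therefore not independent, which makes the
#'   asymptotic rank-correlation p-value anti-conservative; permuting the
#'   concentration labels across conditions (keeping each condition's
#'   pairs together) gives a calibrated two-sided p. `0` (default) reports
#'   the asymptotic p-value instead.
#' @param perm_seed seed for the permutation draw.
#' @return list with `records` (one row per eligible group: compound,
#'   cell_line, trend_statistic, trend_p_value, n_pairs,
#'   n_concentrations) and `points` (the underlying pooled pairs:
#'   compound, cell_line, log10_concentration, value) and `ineligible`
#'   (groups failing the filters, with reasons).
#' @export
dose_trend <- function(within, profiles, min_replicates = 3L,
                       min_concentrations = 3L, n_perm = 0L,
                       perm_seed = 1L) {
  reps_per_cond <- table(profiles$meta$condition)
  pr <- within$pairs
  pr <- pr[!is.na(pr$value), , drop = FALSE]
  eligible_cond <- names(reps_per_cond)[reps_per_cond >= min_replicates]
  pr <- pr[pr$condition %in% eligible_cond, , drop = FALSE]
  cond <- split_condition(pr$condition)
  pts <- cbind(cond, data.frame(log10_concentration = log10(cond$concentration_uM),
                                value = pr$value))

  groups <- split(pts, paste(pts$compound, pts$cell_line, sep = "|"))
  rec <- list(); inel <- list()
  for (g in sort(names(groups))) {
    d <- groups[[g]]
    ncc <- length(unique(d$concentration_uM))
    if (ncc < min_concentrations) {
      inel[[g]] <- data.frame(group = g,
                              reason = sprintf("concentrations_%d_below_%d",
                                               ncc, min_concentrations),
                              stringsAsFactors = FALSE)
      next
    }
    ct <- suppressWarnings(
      stats::cor.test(d$value, d$log10_concentration, method = "spearman"))
    pval <- ct$p.value
    if (n_perm > 0) {
      obs <- unname(ct$estimate)
      uc <- sort(unique(d$concentration_uM))
      perm_stats <- with_seed(substream_seed(perm_seed, paste0("trend_", g)), {
        vapply(seq_len(n_perm), function(b) {
          newc <- stats::setNames(sample(uc), uc)
          suppressWarnings(stats::cor(
            d$value, log10(newc[as.character(d$concentration_uM)]),
            method = "spearman"))
        }, numeric(1))
      })
      pval <- if (is.na(obs)) NA_real_ else
        (1 + sum(abs(perm_stats) >= abs(obs) - 1e-12, na.rm = TRUE)) /
          (n_perm + 1)
    }
    rec[[g]] <- data.frame(compound = d$compound[1], cell_line = d$cell_line[1],
                           trend_statistic = unname(ct$estimate),
                           trend_p_value = pval,
                           n_pairs = nrow(d), n_concentrations = ncc,
                           stringsAsFactors = FALSE)
  }
  records <- if (length(rec)) do.call(rbind, rec) else
    data.frame(compound = character(), cell_line = character(),
               trend_statistic = numeric(), trend_p_value = numeric(),
               n_pairs = integer(), n_concentrations = integer(),
               stringsAsFactors = FALSE)
  ineligible <- if (length(inel)) do.call(rbind, inel) else
    data.frame(group = character(), reason = character(),
               stringsAsFactors = FALSE)
  rownames(records) <- rownames(ineligible) <- NULL
  list(records = records, points = pts, ineligible = ineligible)
}

#' DE-gene counts against dose
#'
#' Counts differentially expressed genes in each profile's ternarization
#' and groups the counts by (compound, cell line), sorted by
#' concentration.
#'
#' @param profiles a `de_profiles` object.
#' @return data frame: compound, cell_line, concentration_uM,
#'   log10_concentration, profile_id, de_count; sorted within group by
#'   concentration.
#' @export
de_count_vs_dose <- function(profiles) {
  counts <- count_de_genes(ternarize(profiles))
  m <- profiles$meta
  out <- data.frame(compound = m$compound, cell_line = m$cell_line,
                    concentration_uM = m$concentration_uM,
                    log10_concentration = log10(m$concentration_uM),
                    profile_id = m$profile_id,
                    de_count = as.integer(counts[m$profile_id]),
                    stringsAsFactors = FALSE)
  out[order(out$compound, out$cell_line, out$concentration_uM,
            out$profile_id), , drop = FALSE]
}
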