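# Reproducibility statistics: Spearman rank correlation, ternary Jaccard,
# within- and cross-dataset DE agreement, harmonization, and sample-level
# in-/cross-replicate agreement.

#' Spearman rank correlation
#'
#' Pearson correlation of average-ranked values (ties receive their average
#' rank). A constant vector has no rank variance; the correlation is then
#' undefined and returned as `NA` rather than coerced to 0.
#'
#' @param x,y numeric vectors of equal length (at least 3), finite values.
#' @return correlation in `[-1, 1]`, or `NA_real_` if either vector is
#'   constant.
#' @export
#' @examples
#' spearman_correlation(c(1, 2, 3, 4), c(2, 1, 4, 3))  # 0.6
spearman_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("values must be finite")
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) return(NA_real_)
  stats::cor(rx, ry)
}

#' Ternary Jaccard similarity of DE calls
#'
#' A Jaccard index adapted to ternary (-1/0/+1) differential-expression
#' calls: the numerator counts genes called differentially expressed in the
#' same direction in both vectors; the denominator counts genes called in
#' either. Two all-zero vectors score 0 (not 1): agreeing on "nothing is
#' differentially expressed" is not evidence of signature agreement.
#'
#' @param a,b ternary vectors (values in -1, 0, 1) on the same gene index.
#' @return similarity in `[0, 1]`.
#' @export
#' @examples
#' ternary_jaccard(c(1, -1, 0, 1), c(1, 1, 0, 0))  # 1/3
ternary_jaccard <- function(a, b) {
  if (length(a) != length(b)) stop("a and b must have equal length")
  if (!all(a %in% c(-1, 0, 1)) || !all(b %in% c(-1, 0, 1)))
    stop("inputs must be ternary (-1, 0, 1)")
  num <- sum(a == b & a != 0)
  den <- sum(a != 0 | b != 0)
  if (den == 0) return(0)
  num / den
}

# dispatch on the metric name used throughout the module
pair_metric <- function(metric, va, vb, ta = NULL, tb = NULL) {
  if (metric == "spearman") spearman_correlation(va, vb)
  else ternary_jaccard(ta, tb)
}

#' Within-dataset agreement of replicate DE profiles
#'
#' Retains conditions for the requested cell lines and duration with at
#' least two replicate profiles; scores every unordered replicate pair with
#' the chosen metric; summarizes each condition by its maximal ("best
#' case") pairwise value. Each pair also records the lesser of the two
#' profiles' DE-gene counts (the "limiting profile" strength).
#'
#' @param profiles a `de_profiles` object with duplicate conditions
#'   retained.
#' @param metric `"spearman"` or `"ternary_jaccard"`.
#' @param cell_lines cell lines retained (default: all present).
#' @param duration_h duration retained (default: all present).
#' @return list with `pairs` (one row per replicate pair: condition,
#'   profile ids, metric value, `lesser_de_count`) and `summary` (one row
#'   per condition: `max_value`, `n_pairs`, and the pair achieving the
#'   max).
#' @export
within_dataset_agreement <- function(profiles,
                                     metric = c("spearman", "ternary_jaccard"),
                                     cell_lines = NULL, duration_h = NULL) {
  metric <- match.arg(metric)
  meta <- profiles$meta
  keep <- rep(TRUE, nrow(meta))
  if (!is.null(cell_lines)) keep <- keep & meta$cell_line %in% cell_lines
  if (!is.null(duration_h)) keep <- keep & meta$duration_h %in% duration_h
  prof <- subset_profiles(profiles, which(keep))
  tern <- ternarize(prof)
  de_counts <- count_de_genes(tern)

  groups <- split(seq_len(nrow(prof$meta)), prof$meta$condition)
  groups <- groups[vapply(groups, length, integer(1)) >= 2]
  groups <- groups[order(names(groups))]
  if (length(groups) == 0) {
    message("within_dataset_agreement: no condition with >= 2 replicates")
  }

  pair_rows <- list()
  for (cond in names(groups)) {
    ix <- groups[[cond]]
    ix <- ix[order(prof$meta$profile_id[ix])]  # deterministic pair order
    cmb <- utils::combn(ix, 2)
    for (p in seq_len(ncol(cmb))) {
      i <- cmb[1, p]; j <- cmb[2, p]
      val <- pair_metric(metric, prof$values[, i], prof$values[, j],
                         tern$values[, i], tern$values[, j])
      pair_rows[[length(pair_rows) + 1L]] <- data.frame(
        condition = cond,
        profile_1 = prof$meta$profile_id[i],
        profile_2 = prof$meta$profile_id[j],
        value = val,
        lesser_de_count = min(de_counts[i], de_counts[j]),
        stringsAsFactors = FALSE)
    }
  }
  pairs <- if (length(pair_rows)) do.call(rbind, pair_rows) else
    data.frame(condition = character(), profile_1 = character(),
               profile_2 = character(), value = numeric(),
               lesser_de_count = numeric(), stringsAsFactors = FALSE)
  rownames(pairs) <- NULL

  summary <- do.call(rbind, lapply(split(pairs, pairs$condition), function(df) {
    ok <- !is.na(df$value)
    if (!any(ok)) {
      return(data.frame(condition = df$condition[1], max_value = NA_real_,
                        n_pairs = nrow(df), best_profile_1 = NA_character_,
                        best_profile_2 = NA_character_,
                        lesser_de_count = NA_real_, stringsAsFactors = FALSE))
    }
    best <- which(df$value == max(df$value[ok]) & ok)[1]
    data.frame(condition = df$condition[1], max_value = df$value[best],
               n_pairs = nrow(df), best_profile_1 = df$profile_1[best],
               best_profile_2 = df$profile_2[best],
               lesser_de_count = df$lesser_de_count[best],
               stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL
  list(pairs = pairs, summary = summary, metric = metric)
}

#' Match conditions across two DE corpora
#'
#' Two conditions are the same when compound, cell line and duration are
#' equal and the concentrations match: exactly (tolerance 0) or within a
#' relative tolerance `|c_a - c_b| / c_a < conc_tolerance` (the corpus-A
#' concentration is the reference). When several corpus-B conditions
#' qualify, the nearest concentration wins. Each corpus is expected to
#' carry one profile per condition (see
#' [select_representative_profiles()]).
#'
#' @param profiles_a,profiles_b `de_profiles` objects.
#' @param conc_tolerance relative concentration tolerance (default 0 =
#'   exact matching).
#' @return list with `pairs` — a list of harmonized pairs, each carrying
#'   `condition`, the two profile columns, kinds, replicate counts and the
#'   shared gene index — and `unmatched` (corpus-A conditions with no
#'   match).
#' @export
harmonize <- function(profiles_a, profiles_b, conc_tolerance = 0) {
  ma <- profiles_a$meta; mb <- profiles_b$meta
  shared_genes <- intersect(rownames(profiles_a$values),
                            rownames(profiles_b$values))
  pairs <- list(); unmatched <- character()
  for (i in seq_len(nrow(ma))) {
    cand <- which(mb$compound == ma$compound[i] &
                  mb$cell_line == ma$cell_line[i] &
                  mb$duration_h == ma$duration_h[i])
    if (conc_tolerance == 0) {
      cand <- cand[mb$concentration_uM[cand] == ma$concentration_uM[i]]
    } else {
      rel <- abs(ma$concentration_uM[i] - mb$concentration_uM[cand]) /
        ma$concentration_uM[i]
      cand <- cand[rel < conc_tolerance]
    }
    if (length(cand) == 0) {
      unmatched <- c(unmatched, ma$condition[i])
      next
    }
    if (length(cand) > 1) {
      d <- abs(mb$concentration_uM[cand] - ma$concentration_uM[i])
      cand <- cand[order(d, mb$concentration_uM[cand])][1]
    }
    pairs[[length(pairs) + 1L]] <- list(
      condition = ma$condition[i],
      condition_b = mb$condition[cand],
      values_a = profiles_a$values[shared_genes, i],
      values_b = profiles_b$values[shared_genes, cand],
      kind_a = profiles_a$kind, kind_b = profiles_b$kind,
      n_a = ma$n_contributing_replicates[i],
      n_b = mb$n_contributing_replicates[cand],
      shared_gene_index = shared_genes)
  }
  list(pairs = pairs, unmatched = unmatched)
}

#' Cross-dataset agreement of harmonized condition pairs
#'
#' One agreement value per harmonized condition pair, over all shared
#' genes or the landmark subset. For the ternary Jaccard metric each
#' profile is ternarized under the thresholds of its own kind
#' (fold change: 1.0; de-standardized z: 2.0).
#'
#' @param harmonized result of [harmonize()].
#' @param metric `"spearman"` or `"ternary_jaccard"`.
#' @param universe `"all"` or `"landmark"`.
#' @param landmark_ids landmark gene ids (required for
#'   `universe = "landmark"`).
#' @param min_shared minimum shared-gene count below which a pair is
#'   skipped (rank statistics on very short vectors are uninformative).
#' @return data frame: condition, value, n_shared_genes, skipped reason.
#' @export
cross_dataset_agreement <- function(harmonized,
                                    metric = c("spearman", "ternary_jaccard"),
                                    universe = c("all", "landmark"),
                                    landmark_ids = NULL, min_shared = 10L) {
  metric <- match.arg(metric)
  universe <- match.arg(universe)
  rows <- lapply(harmonized$pairs, function(p) {
    genes <- p$shared_gene_index
    if (universe == "landmark") {
      if (is.null(landmark_ids)) stop("landmark_ids required")
      genes <- intersect(genes, landmark_ids)
    }
    if (length(genes) < min_shared) {
      return(data.frame(condition = p$condition, value = NA_real_,
                        n_shared_genes = length(genes),
                        skipped = "shared_gene_index_below_minimum",
                        stringsAsFactors = FALSE))
    }
    va <- p$values_a[genes]; vb <- p$values_b[genes]
    val <- if (metric == "spearman") {
      spearman_correlation(va, vb)
    } else {
      ternary_jaccard(ternarize(va, kind = p$kind_a, n = p$n_a),
                      ternarize(vb, kind = p$kind_b, n = p$n_b))
    }
    data.frame(condition = p$condition, value = val,
               n_shared_genes = length(genes), skipped = NA_character_,
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(condition = character(), value = numeric(),
               n_shared_genes = integer(), skipped = character(),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' In-replicate ("limiting") sample-level agreement
#'
#' For each of two replicate groups, the maximal pairwise Spearman
#' correlation of gene expression among its constituent samples is taken;
#' the pair's representative value is the smaller of the two maxima — the
#' noisier replicate caps the agreement the DE pair can attain.
#'
#' @param samples_rep1,samples_rep2 gene x sample numeric matrices (at
#'   least 2 samples each).
#' @return correlation in `[-1, 1]`, or `NA_real_` (with a reason
#'   attribute) when a replicate has fewer than 2 samples.
#' @export
in_replicate_sample_agreement <- function(samples_rep1, samples_rep2) {
  max_within <- function(m) {
    if (is.null(dim(m)) || ncol(m) < 2)
      return(NA_real_)
    cmb <- utils::combn(ncol(m), 2)
    max(vapply(seq_len(ncol(cmb)), function(p)
      spearman_correlation(m[, cmb[1, p]], m[, cmb[2, p]]), numeric(1)),
      na.rm = TRUE)
  }
  m1 <- max_within(samples_rep1); m2 <- max_within(samples_rep2)
  if (is.na(m1) || is.na(m2)) {
    out <- NA_real_
    attr(out, "reason") <- "replicate_with_fewer_than_2_samples"
    return(out)
  }
  min(m1, m2)
}

#' Cross-replicate sample-level agreement
#'
#' Maximal Spearman correlation over all sample pairs formed by taking one
#' sample from each replicate group: the best-case cross-replicate
#' expression agreement.
#'
#' @param samples_rep1,samples_rep2 gene x sample numeric matrices (at
#'   least 1 sample each).
#' @return correlation in `[-1, 1]`, or `NA_real_` for an empty replicate.
#' @export
cross_replicate_sample_agreement <- function(samples_rep1, samples_rep2) {
  m1 <- as.matrix(samples_rep1); m2 <- as.matrix(samples_rep2)
  if (ncol(m1) < 1 || ncol(m2) < 1) {
    out <- NA_real_
    attr(out, "reason") <- "empty_replicate"
    return(out)
  }
  vals <- numeric(0)
  for (i in seq_len(ncol(m1)))
    for (j in seq_len(ncol(m2)))
      vals <- c(vals, spearman_correlation(m1[, i], m2[, j]))
  if (all(is.na(vals))) return(NA_real_)
  max(vals, na.rm = TRUE)
}

#' Attach sample-level agreements to within-dataset DE pairs
#'
#' For each replicate DE pair of a [within_dataset_agreement()] result,
#' computes the in-replicate and cross-replicate sample agreements from
#' the constituent samples of the two replicate groups. Fold-change
#' profiles contribute both treatment and control samples; moderated
#' z-score profiles contribute treatment samples only.
#'
#' @param within result of [within_dataset_agreement()].
#' @param corpus the `expr_corpus` the profiles were computed from.
#' @param kind `"FC"` or `"MZS"` (selects the constituent-sample rule).
#' @return the `within` list with `in_replicate` and `cross_replicate`
#'   columns added to `$pairs` and to `$summary` (values of the max pair).
#' @export
add_sample_agreement <- function(within, corpus, kind = c("FC", "MZS")) {
  kind <- match.arg(kind)
  meta <- corpus$sample_meta
  group_samples <- function(grp) {
    rows_t <- which(meta$replicate_group == grp)
    if (kind == "FC") {
      plate <- meta$plate_pool[rows_t[1]]
      rows_c <- which(meta$role == "control" & meta$plate_pool == plate)
      rows_t <- c(rows_t, rows_c)
    }
    corpus$values[, rows_t, drop = FALSE]
  }
  pr <- within$pairs
  pr$in_replicate <- NA_real_
  pr$cross_replicate <- NA_real_
  for (i in seq_len(nrow(pr))) {
    s1 <- group_samples(pr$profile_1[i])
    s2 <- group_samples(pr$profile_2[i])
    pr$in_replicate[i] <- in_replicate_sample_agreement(s1, s2)
    pr$cross_replicate[i] <- cross_replicate_sample_agreement(s1, s2)
  }
  within$pairs <- pr
  sm <- within$summary
  key <- paste(pr$condition, pr$profile_1, pr$profile_2)
  skey <- paste(sm$condition, sm$best_profile_1, sm$best_profile_2)
  ix <- match(skey, key)
  sm$in_replicate <- pr$in_replicate[ix]
  sm$cross_replicate <- pr$cross_replicate[ix]
  within$summary <- sm
  within
}
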