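# Differential-expression engine: probe collapsing, plate-matched
# fold-change computation with group-size constraints, moderated z-scores
# with de-standardization, and ternarization.

#' Construct a DE profile set
#' @keywords internal
new_de_profiles <- function(values, meta, kind, exclusions = NULL) {
  stopifnot(is.matrix(values), nrow(meta) == ncol(values),
            kind %in% c("FC", "MZS"))
  if (is.null(exclusions)) {
    exclusions <- data.frame(replicate_group = character(),
                             reason = character(), stringsAsFactors = FALSE)
  }
  structure(list(values = values, meta = meta, kind = kind,
                 exclusions = exclusions),
            class = "de_profiles")
}

#' @export
print.de_profiles <- function(x, ...) {
  cat(sprintf("de_profiles (%s): %d genes x %d profiles, %d conditions, %d exclusions\n",
              x$kind, nrow(x$values), ncol(x$values),
              length(unique(x$meta$condition)), nrow(x$exclusions)))
  invisible(x)
}

#' Subset a DE profile set by profile index
#' @param profiles a `de_profiles` object.
#' @param idx integer or logical index over profiles (columns).
#' @return a `de_profiles` object.
#' @export
subset_profiles <- function(profiles, idx) {
  new_de_profiles(profiles$values[, idx, drop = FALSE],
                  profiles$meta[idx, , drop = FALSE],
                  profiles$kind, profiles$exclusions)
}

#' Collapse a probe-level matrix to gene level
#'
#' Probes mapping to more than one gene are removed. For each remaining
#' gene and each profile independently, the probe value with the greatest
#' absolute magnitude is selected (sign preserved). Genes with no surviving
#' probe are absent from the output.
#'
#' @param probe_matrix probe x profile numeric matrix with probe ids as
#'   row names.
#' @param map data frame with columns `probe_id` and `gene_id`; a probe
#'   mapping to several genes appears on several rows.
#' @return gene x profile numeric matrix, genes sorted lexicographically.
#' @export
#' @examples
#' m <- rbind(p1 = c(0.5, 1), p2 = c(-2, 0.1))
#' collapse_probes(m, data.frame(probe_id = c("p1", "p2"),
#'                               gene_id = c("G1", "G1")))
collapse_probes <- function(probe_matrix, map) {
  if (!is.matrix(probe_matrix) || is.null(rownames(probe_matrix)))
    stop("probe_matrix must be a matrix with probe ids as row names")
  if (nrow(map) == 0) stop("empty probe map")
  stopifnot(all(c("probe_id", "gene_id") %in% names(map)))
  map <- unique(map[, c("probe_id", "gene_id")])
  n_targets <- table(map$probe_id)
  multi <- names(n_targets)[n_targets > 1]
  map <- map[!(map$probe_id %in% multi), , drop = FALSE]
  map <- map[map$probe_id %in% rownames(probe_matrix), , drop = FALSE]
  if (nrow(map) == 0) stop("no probe maps uniquely to a gene")

  m <- probe_matrix[map$probe_id, , drop = FALSE]
  gene <- map$gene_id
  genes <- sort(unique(gene))
  out <- matrix(NA_real_, nrow = length(genes), ncol = ncol(m),
                dimnames = list(genes, colnames(m)))
  for (j in seq_len(ncol(m))) {
    o <- order(-abs(m[, j]), rownames(m))  # probe id breaks magnitude ties
    sel <- o[!duplicated(gene[o])]
    out[gene[sel], j] <- m[sel, j]
  }
  out
}

#' Keep one representative profile per condition
#'
#' Where a corpus contains duplicate profiles of the same condition
#' (the same treatment-control condition tested multiple times), a single
#' representative is selected uniformly at random, deterministically under
#' the seed.
#'
#' @param profiles a `de_profiles` object.
#' @param seed integer seed.
#' @return a `de_profiles` object with exactly one profile per condition.
#' @export
select_representative_profiles <- function(profiles, seed) {
  groups <- split(seq_len(nrow(profiles$meta)), profiles$meta$condition)
  groups <- groups[order(names(groups))]
  keep <- with_seed(substream_seed(seed, "representative"), {
    vapply(groups, function(ix) {
      if (length(ix) == 1L) ix else ix[sample.int(length(ix), 1L)]
    }, integer(1))
  })
  subset_profiles(profiles, sort(unname(keep)))
}

# Shared driver for FC / MZS computation: pairs every treatment replicate
# group with the largest control group on its plate pool, subsamples both
# to a common size within group_bounds, and applies `stat_fun`.
compute_group_profiles <- function(corpus, group_bounds, seed, stat_fun, kind) {
  meta <- corpus$sample_meta
  lo <- group_bounds[1]; hi <- group_bounds[2]
  trt_groups <- sort(unique(meta$replicate_group[meta$role == "treatment"]))

  prof_cols <- list(); prof_meta <- list(); excl <- list()
  for (grp in trt_groups) {
    rows_t <- which(meta$replicate_group == grp)
    plate <- meta$plate_pool[rows_t[1]]
    ctl_groups <- unique(meta$replicate_group[meta$role == "control" &
                                              meta$plate_pool == plate])
    if (length(ctl_groups) == 0) {
      excl[[grp]] <- "no_plate_matched_control"
      next
    }
    ctl_sizes <- vapply(ctl_groups, function(g)
      sum(meta$replicate_group == g), integer(1))
    # largest eligible control group; ties broken by lexicographic label
    o <- order(-ctl_sizes, ctl_groups)
    ctl <- ctl_groups[o[1]]
    rows_c <- which(meta$replicate_group == ctl)

    n_use <- min(length(rows_t), length(rows_c), hi)
    if (n_use < lo) {
      excl[[grp]] <- sprintf("group_size_%d_below_minimum_%d", n_use, lo)
      next
    }
    sub <- with_seed(substream_seed(seed, paste0("subsample_", grp)), {
      list(t = sort(sample(rows_t, n_use)), c = sort(sample(rows_c, n_use)))
    })
    prof_cols[[grp]] <- stat_fun(corpus$values[, sub$t, drop = FALSE],
                                 corpus$values[, sub$c, drop = FALSE])
    m1 <- meta[rows_t[1], ]
    prof_meta[[grp]] <- data.frame(
      profile_id = grp, compound = m1$compound,
      concentration_uM = m1$concentration_uM, cell_line = m1$cell_line,
      duration_h = m1$duration_h, replicate_group = grp,
      n_contributing_replicates = n_use,
      condition = condition_key(m1$compound, m1$concentration_uM,
                                m1$cell_line, m1$duration_h),
      stringsAsFactors = FALSE
    )
  }

  exclusions <- if (length(excl)) {
    data.frame(replicate_group = names(excl), reason = unlist(excl),
               stringsAsFactors = FALSE, row.names = NULL)
  } else NULL
  if (length(prof_cols) == 0) {
    values <- matrix(numeric(0), nrow = nrow(corpus$values), ncol = 0,
                     dimnames = list(rownames(corpus$values), NULL))
    meta_df <- data.frame(profile_id = character(), compound = character(),
                          concentration_uM = numeric(), cell_line = character(),
                          duration_h = numeric(), replicate_group = character(),
                          n_contributing_replicates = integer(),
                          condition = character(), stringsAsFactors = FALSE)
    return(new_de_profiles(values, meta_df, kind, exclusions))
  }
  values <- do.call(cbind, prof_cols)
  meta_df <- do.call(rbind, prof_meta)
  rownames(meta_df) <- NULL
  colnames(values) <- meta_df$profile_id
  new_de_profiles(values, meta_df, kind, exclusions)
}

#' Compute plate-matched log2 fold-change profiles
#'
#' One profile is produced per treatment replicate group: the per-gene
#' difference of mean log2 expression between the treatment group and its
#' plate-matched control group. Both groups are subsampled (uniformly,
#' seeded) to a common size within `group_bounds`; groups that cannot reach
#' the minimum are skipped and reported in the exclusion table.
#'
#' @param corpus an `expr_corpus`.
#' @param group_bounds length-2 integer vector, minimum and maximum group
#'   size (default `c(2, 20)`).
#' @param seed integer seed driving the subsampling.
#' @return a `de_profiles` object of kind `"FC"`; `$exclusions` lists
#'   skipped replicate groups with reasons.
#' @export
compute_fc_profiles <- function(corpus, group_bounds = c(2L, 20L), seed = 1L) {
  compute_group_profiles(corpus, group_bounds, seed,
                         function(t, c) rowMeans(t) - rowMeans(c), "FC")
}

#' Compute moderated z-score profiles
#'
#' Per-gene z statistic `(mean treatment - mean control) / pooled standard
#' error`, with a small variance floor guarding against degenerate
#' gene-level variance estimates. Group pairing, subsampling and exclusion
#' rules are identical to [compute_fc_profiles()]. The recorded
#' `n_contributing_replicates` is the per-group sample size used, which is
#' the `n` consumed by [destandardize_mzs()].
#'
#' @inheritParams compute_fc_profiles
#' @param var_floor minimum admissible pooled per-gene variance.
#' @return a `de_profiles` object of kind `"MZS"`.
#' @export
compute_mzs_profiles <- function(corpus, group_bounds = c(2L, 20L), seed = 1L,
                                 var_floor = 0.01) {
  stat <- function(t, c) {
    n <- ncol(t)
    sp2 <- (apply(t, 1, stats::var) + apply(c, 1, stats::var)) / 2
    sp2 <- pmax(sp2, var_floor)
    (rowMeans(t) - rowMeans(c)) / sqrt(sp2 * (2 / n))
  }
  compute_group_profiles(corpus, group_bounds, seed, stat, "MZS")
}

#' De-standardize moderated z-score profiles
#'
#' Multiplies each moderated z-score vector by the square root of its
#' contributing replicate count, restoring a magnitude comparable across
#' profiles built from different numbers of samples.
#'
#' @param profiles a `de_profiles` object of kind `"MZS"`.
#' @return a `de_profiles` object of kind `"MZS"` whose values are
#'   `z * sqrt(n)` (marked de-standardized).
#' @export
destandardize_mzs <- function(profiles) {
  if (!inherits(profiles, "de_profiles") || profiles$kind != "MZS")
    stop("destandardize_mzs() requires de_profiles of kind MZS", call. = FALSE)
  n <- profiles$meta$n_contributing_replicates
  if (any(n < 1)) stop("n_contributing_replicates must be >= 1", call. = FALSE)
  out <- profiles
  out$values <- sweep(profiles$values, 2, sqrt(n), "*")
  attr(out, "destandardized") <- TRUE
  out
}

#' Ternarize DE profiles
#'
#' Maps each value to -1 (under-expressed), 0 (unchanged) or +1
#' (over-expressed). Fold-change profiles use cutoffs of -1.0 / +1.0;
#' moderated z-score profiles are first de-standardized
#' (`z * sqrt(n)`) and then cut at -2.0 / +2.0. Values exactly at a cutoff
#' count as differentially expressed.
#'
#' @param profiles a `de_profiles` object, or a plain numeric vector
#'   (treated as fold-change scale unless `kind` says otherwise).
#' @param fc_cutoff cutoff magnitude for fold-change values.
#' @param mzs_cutoff cutoff magnitude for de-standardized z values.
#' @param kind for numeric input: `"FC"` or `"MZS"`.
#' @param n for numeric `"MZS"` input: contributing replicate count.
#' @return a `ternary_profiles` object (gene x profile integer matrix in
#'   `{-1, 0, 1}` plus metadata), or an integer vector for vector input.
#' @export
#' @examples
#' ternarize(c(1.2, -0.5, -1.0))
ternarize <- function(profiles, fc_cutoff = 1, mzs_cutoff = 2,
                      kind = "FC", n = 1L) {
  if (is.numeric(profiles) && !is.matrix(profiles)) {
    v <- if (kind == "MZS") profiles * sqrt(n) else profiles
    cut <- if (kind == "MZS") mzs_cutoff else fc_cutoff
    out <- (v >= cut) - (v <= -cut)
    return(as.integer(out))
  }
  if (!inherits(profiles, "de_profiles"))
    stop("ternarize() requires a de_profiles object or numeric vector")
  if (profiles$kind == "MZS" && !isTRUE(attr(profiles, "destandardized"))) {
    profiles <- destandardize_mzs(profiles)
  }
  cut <- if (profiles$kind == "MZS") mzs_cutoff else fc_cutoff
  tern <- (profiles$values >= cut) - (profiles$values <= -cut)
  storage.mode(tern) <- "integer"
  structure(list(values = tern, meta = profiles$meta,
                 source_kind = profiles$kind,
                 thresholds_used = c(lower = -cut, upper = cut)),
            class = "ternary_profiles")
}

#' Count differentially expressed genes
#'
#' @param t a `ternary_profiles` object, a ternary integer matrix, or a
#'   single ternary vector.
#' @return per-profile nonzero counts (named vector for matrices, scalar
#'   for vectors).
#' @export
count_de_genes <- function(t) {
  v <- if (inherits(t, "ternary_profiles")) t$values else t
  if (!all(v %in% c(-1L, 0L, 1L))) stop("values must be ternary (-1, 0, 1)")
  if (is.matrix(v)) colSums(v != 0) else sum(v != 0)
}
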