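# Signature-query engine and retrieval benchmark: two-sided KS enrichment
# scoring against a DE corpus, compound ranking on a shared universe,
# decile-success and median-rank metrics, and meta-rankings.

#' Kolmogorov-Smirnov enrichment score of a gene list in a ranked profile
#'
#' Unweighted two-sided running-sum statistic: walking the profile from the
#' most up-regulated gene down, the sum increases by `1/|list|` at list
#' members and decreases by `1/(N - |list|)` elsewhere; the score is the
#' extreme deviation reached, signed (positive when the list concentrates
#' at the top of the ranking, negative at the bottom).
#'
#' @param gene_list character vector of gene ids (nonempty, all present in
#'   the profile).
#' @param ranked_genes character vector of all gene ids ordered by
#'   descending DE value.
#' @return score in `[-1, 1]`.
#' @export
enrichment_score <- function(gene_list, ranked_genes) {
  nh <- length(gene_list)
  N <- length(ranked_genes)
  if (nh == 0) stop("gene_list must be nonempty")
  if (nh >= N) stop("gene_list must be smaller than the profile")
  hit <- ranked_genes %in% gene_list
  if (sum(hit) < nh) stop("gene_list contains ids absent from the profile")
  step <- ifelse(hit, 1 / nh, -1 / (N - nh))
  running <- cumsum(step)
  hi <- max(running); lo <- min(running)
  if (hi >= -lo) hi else lo
}

#' Combined connectivity score of a signature against a profile
#'
#' Enrichment of the up-list and of the down-list are combined by the
#' standard convention: when both enrichments share a sign the evidence is
#' contradictory and the score is 0; otherwise the score is
#' `(es_up - es_down) / 2`. Positive scores mean the profile mimics the
#' query signature; negative scores mean it reverses it.
#'
#' @param sig a `cmap_signature`.
#' @param profile a single-profile `de_profiles` object or gene-named
#'   numeric vector of DE values.
#' @return list with `value`, `es_up`, `es_down`.
#' @export
connectivity_score <- function(sig, profile) {
  v <- as_profile_vector(profile)
  ranked <- names(v)[order(-v, names(v))]
  es_up <- enrichment_score(sig$up_genes, ranked)
  es_down <- enrichment_score(sig$down_genes, ranked)
  value <- if (es_up * es_down > 0) 0 else (es_up - es_down) / 2
  list(value = value, es_up = es_up, es_down = es_down)
}

#' Query a DE corpus with a signature
#'
#' Scores every corpus profile passing the cell-line filter, aggregates
#' scores to the compound level, restricts the ranking to a shared compound
#' universe, and ranks compounds by descending score (competition ranking;
#' equal scores ordered by compound id). Reports the rank and the inverse
#' rank (`K + 1 - rank`, the position from the bottom used for
#' signature-reversing queries) of a target compound.
#'
#' @param sig a `cmap_signature`.
#' @param corpus a `de_profiles` object.
#' @param target_compound compound whose retrieval is being benchmarked.
#' @param cell_line_filter optional cell line label restricting the corpus.
#' @param compound_universe optional compound set to rank (default: all
#'   compounds present after filtering).
#' @param aggregate `"max"` (default) or `"median"` over a compound's
#'   profile scores.
#' @return a `retrieval_result`: `ranked_compounds` (data frame compound,
#'   score, rank), `rank_of_target`, `inverse_rank_of_target`,
#'   `corpus_compound_count`, or a result with
#'   `reason = "target-not-in-universe"`.
#' @export
query_corpus <- function(sig, corpus, target_compound,
                         cell_line_filter = NULL, compound_universe = NULL,
                         aggregate = c("max", "median")) {
  aggregate <- match.arg(aggregate)
  meta <- corpus$meta
  keep <- rep(TRUE, nrow(meta))
  if (!is.null(cell_line_filter)) keep <- keep & meta$cell_line %in% cell_line_filter
  if (!any(keep)) stop("no corpus profiles left after cell-line filter")
  vals <- corpus$values[, keep, drop = FALSE]
  cpds <- meta$compound[keep]
  if (is.null(compound_universe)) compound_universe <- sort(unique(cpds))
  in_uni <- cpds %in% compound_universe
  if (!any(in_uni)) stop("no corpus profiles for the compound universe")
  vals <- vals[, in_uni, drop = FALSE]; cpds <- cpds[in_uni]

  scores <- vapply(seq_len(ncol(vals)), function(j)
    connectivity_score(sig, stats::setNames(vals[, j], rownames(vals)))$value,
    numeric(1))
  agg_fun <- if (aggregate == "max") max else stats::median
  by_cpd <- tapply(scores, cpds, agg_fun)
  cpd_ids <- sort(names(by_cpd))
  score <- as.numeric(by_cpd[cpd_ids])

  o <- order(-score, cpd_ids)
  ranked <- data.frame(compound = cpd_ids[o], score = score[o],
                       stringsAsFactors = FALSE)
  ranked$rank <- rank(-ranked$score, ties.method = "min")
  K <- nrow(ranked)

  if (!(target_compound %in% ranked$compound)) {
    return(structure(list(target_compound = target_compound,
                          ranked_compounds = ranked,
                          rank_of_target = NA_integer_,
                          inverse_rank_of_target = NA_integer_,
                          corpus_compound_count = K,
                          cell_line_filter = cell_line_filter,
                          reason = "target-not-in-universe"),
                     class = "retrieval_result"))
  }
  r <- ranked$rank[ranked$compound == target_compound]
  structure(list(target_compound = target_compound, ranked_compounds = ranked,
                 rank_of_target = as.integer(r),
                 inverse_rank_of_target = as.integer(K + 1L - r),
                 corpus_compound_count = K,
                 cell_line_filter = cell_line_filter, reason = NA_character_),
            class = "retrieval_result")
}

#' @export
print.retrieval_result <- function(x, ...) {
  cat(sprintf("retrieval_result: target %s rank %s of %d compounds\n",
              x$target_compound, x$rank_of_target, x$corpus_compound_count))
  invisible(x)
}

#' Was the target retrieved in the top decile?
#'
#' The cutoff is computed from the ranked universe size as
#' `ceiling(0.1 * K)`, so universes of any size are supported.
#'
#' @param result a `retrieval_result`.
#' @return logical (`NA` if the target was not in the universe).
#' @export
success_at_decile <- function(result) {
  if (is.na(result$rank_of_target)) return(NA)
  result$rank_of_target <= ceiling(0.1 * result$corpus_compound_count)
}

#' Median retrieval rank over a set of queries
#' @param results list of `retrieval_result` objects.
#' @return median of the target ranks (average of the middle two for even
#'   counts); `NA` ranks (target not in universe) are dropped.
#' @export
median_rank <- function(results) {
  if (length(results) == 0) stop("results must be nonempty")
  ranks <- vapply(results, function(r) as.numeric(r$rank_of_target), numeric(1))
  stats::median(ranks[!is.na(ranks)])
}

check_rank_lists <- function(rank_lists) {
  cpds <- sort(unique(unlist(lapply(rank_lists, names))))
  for (i in seq_along(rank_lists)) {
    missing <- setdiff(cpds, names(rank_lists[[i]]))
    if (length(missing))
      stop(sprintf("compound '%s' missing from rank list %d", missing[1], i))
  }
  cpds
}

#' Rank-product meta-ranking
#'
#' Orders compounds by the geometric mean of their ranks across query
#' lists (ascending); ties broken by compound id.
#'
#' @param rank_lists list of named numeric vectors (compound -> rank); all
#'   lists must rank every compound.
#' @return data frame: compound, rank_product, meta_rank.
#' @export
meta_rank_product <- function(rank_lists) {
  cpds <- check_rank_lists(rank_lists)
  rp <- vapply(cpds, function(cp)
    exp(mean(log(vapply(rank_lists, function(l) l[[cp]], numeric(1))))),
    numeric(1))
  o <- order(rp, cpds)
  data.frame(compound = cpds[o], rank_product = rp[o],
             meta_rank = seq_along(cpds), stringsAsFactors = FALSE)
}

#' Percentile-ordering meta-ranking
#'
#' Orders compounds by a percentile (default the 75th, linear
#' interpolation) of their ranks across query lists; ties broken by
#' compound id.
#'
#' @inheritParams meta_rank_product
#' @param percentile percentile in (0, 100), default 75.
#' @return data frame: compound, percentile_rank, meta_rank.
#' @export
meta_rank_percentile <- function(rank_lists, percentile = 75) {
  cpds <- check_rank_lists(rank_lists)
  q <- vapply(cpds, function(cp)
    as.numeric(stats::quantile(
      vapply(rank_lists, function(l) l[[cp]], numeric(1)),
      probs = percentile / 100, type = 7)),
    numeric(1))
  o <- order(q, cpds)
  data.frame(compound = cpds[o], percentile_rank = q[o],
             meta_rank = seq_along(cpds), stringsAsFactors = FALSE)
}
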