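# Query-signature generation: fixed-cutoff, hybrid, and top-k thresholding
# with the 10-150 genes-per-direction query-size contract.

SIG_MIN <- 10L
SIG_MAX <- 150L

new_signature <- function(up, down, method, condition = NA_character_,
                          universe = "all") {
  structure(list(up_genes = up, down_genes = down, method = method,
                 source_condition = condition, gene_universe = universe),
            class = "cmap_signature")
}

disqualified <- function(reason, condition = NA_character_, method = NA_character_) {
  structure(list(reason = reason, source_condition = condition,
                 method = method),
            class = "signature_disqualified")
}

#' Is a signature result a disqualification?
#' @param x result of a signature constructor.
#' @return logical.
#' @export
is_disqualified <- function(x) inherits(x, "signature_disqualified")

#' @export
print.cmap_signature <- function(x, ...) {
  cat(sprintf("cmap_signature [%s]: %d up / %d down (%s genes) for %s\n",
              x$method, length(x$up_genes), length(x$down_genes),
              x$gene_universe, x$source_condition))
  invisible(x)
}

#' @export
print.signature_disqualified <- function(x, ...) {
  cat(sprintf("signature disqualified (%s) for %s\n", x$reason,
              x$source_condition))
  invisible(x)
}

# profile input: named numeric vector of DE values (FC scale, or
# de-standardized z-scores with cutoff 2).
as_profile_vector <- function(profile) {
  if (inherits(profile, "de_profiles")) {
    if (ncol(profile$values) != 1L)
      stop("expected a single profile; subset first", call. = FALSE)
    stats::setNames(profile$values[, 1L], rownames(profile$values))
  } else {
    if (is.null(names(profile))) stop("profile vector must be gene-named")
    profile
  }
}

# order gene ids by decreasing magnitude, gene id as deterministic tie-break
order_by_magnitude <- function(v) names(v)[order(-abs(v), names(v))]

#' Fixed-cutoff query signature
#'
#' Over-expressed genes are those with values at or above `+cutoff`,
#' under-expressed at or below `-cutoff`, each list ordered by descending
#' magnitude. A condition whose lists fall outside the query-size contract
#' (`size_bounds` genes per direction) is disqualified; the disqualification
#' is returned as a value, not raised.
#'
#' @param profile a single-profile `de_profiles` object or a gene-named
#'   numeric vector on the log2 fold-change scale (use cutoff 2 for
#'   de-standardized z-scores).
#' @param cutoff positive cutoff magnitude (default 1.0).
#' @param size_bounds admissible per-direction list size, default
#'   `c(10, 150)`.
#' @param condition condition label carried into the signature.
#' @return a `cmap_signature` or a `signature_disqualified`.
#' @export
fixed_cutoff_signature <- function(profile, cutoff = 1, size_bounds = c(SIG_MIN, SIG_MAX),
                                   condition = NA_character_) {
  v <- as_profile_vector(profile)
  if (cutoff <= 0) stop("cutoff must be positive")
  up <- v[v >= cutoff]; down <- v[v <= -cutoff]
  for (side in list(c("up", length(up)), c("down", length(down)))) {
    k <- as.integer(side[2])
    if (k < size_bounds[1])
      return(disqualified(sprintf("%s<%d", side[1], size_bounds[1]),
                          condition, "fixed_cutoff"))
    if (k > size_bounds[2])
      return(disqualified(sprintf("%s>%d", side[1], size_bounds[2]),
                          condition, "fixed_cutoff"))
  }
  new_signature(order_by_magnitude(up), order_by_magnitude(down),
                "fixed_cutoff", condition)
}

#' Hybrid-threshold query signature
#'
#' Applies the fixed cutoff first; a direction list exceeding the upper
#' size bound is truncated to the `size_bounds[2]` genes of greatest
#' magnitude (per direction independently), while a list below the lower
#' bound disqualifies the condition.
#'
#' @inheritParams fixed_cutoff_signature
#' @return a `cmap_signature` or a `signature_disqualified`.
#' @export
hybrid_threshold_signature <- function(profile, cutoff = 1,
                                       size_bounds = c(SIG_MIN, SIG_MAX),
                                       condition = NA_character_) {
  v <- as_profile_vector(profile)
  up <- v[v >= cutoff]; down <- v[v <= -cutoff]
  if (length(up) < size_bounds[1])
    return(disqualified(sprintf("up<%d", size_bounds[1]), condition, "hybrid"))
  if (length(down) < size_bounds[1])
    return(disqualified(sprintf("down<%d", size_bounds[1]), condition, "hybrid"))
  up_ids <- utils::head(order_by_magnitude(up), size_bounds[2])
  down_ids <- utils::head(order_by_magnitude(down), size_bounds[2])
  new_signature(up_ids, down_ids, "hybrid", condition)
}

#' Top-k query signature
#'
#' Selects the `k` most positive and `k` most negative genes (ranked by
#' magnitude within direction; gene-id tie-break). `k = 50` over the
#' landmark universe gives the classic 100-gene signature; `k = 10` / `150`
#' over all genes give 20- and 300-gene signatures. Genes with value
#' exactly 0 never enter either list; a profile with fewer than `k`
#' strictly positive or strictly negative genes is disqualified.
#'
#' @inheritParams fixed_cutoff_signature
#' @param k genes per direction.
#' @param universe `"all"` or `"landmark"`.
#' @param landmark_ids gene ids of the landmark subset (required when
#'   `universe = "landmark"`).
#' @return a `cmap_signature` or a `signature_disqualified`.
#' @export
top_k_signature <- function(profile, k, universe = c("all", "landmark"),
                            landmark_ids = NULL, condition = NA_character_) {
  universe <- match.arg(universe)
  v <- as_profile_vector(profile)
  if (k < 1) stop("k must be a positive count")
  if (universe == "landmark") {
    if (is.null(landmark_ids)) stop("landmark_ids required for landmark universe")
    v <- v[names(v) %in% landmark_ids]
  }
  pos <- v[v > 0]; neg <- v[v < 0]
  method <- sprintf("top%d", 2L * as.integer(k))
  if (length(pos) < k)
    return(disqualified(sprintf("positive<%d", k), condition, method))
  if (length(neg) < k)
    return(disqualified(sprintf("negative<%d", k), condition, method))
  new_signature(utils::head(order_by_magnitude(pos), k),
                utils::head(order_by_magnitude(neg), k),
                method, condition, universe)
}

#' Restrict a profile to a gene universe
#'
#' Intersects the profile's gene index with `gene_set`, preserving the
#' original index order (used e.g. to drop non-harmonized genes or keep
#' landmark genes only).
#'
#' @param profile a `de_profiles` object or gene-named numeric vector.
#' @param gene_set nonempty character vector of gene ids.
#' @return same type as the input, restricted to the intersection.
#' @export
restrict_to_universe <- function(profile, gene_set) {
  if (length(gene_set) == 0) stop("gene_set must be nonempty")
  if (inherits(profile, "de_profiles")) {
    keep <- rownames(profile$values) %in% gene_set
    if (!any(keep)) stop("empty intersection with gene_set")
    out <- profile
    out$values <- profile$values[keep, , drop = FALSE]
    return(out)
  }
  keep <- names(profile) %in% gene_set
  if (!any(keep)) stop("empty intersection with gene_set")
  profile[keep]
}

#' Build signatures for every profile of a DE set
#'
#' Applies one thresholding method to each profile and returns the eligible
#' signatures together with a manifest of sizes and disqualifications.
#'
#' @param profiles a `de_profiles` object (FC scale; MZS profiles are
#'   de-standardized and cut at 2.0).
#' @param method one of `"hybrid"`, `"fixed_cutoff"`, `"top100"`,
#'   `"top20"`, `"top300"`.
#' @param landmark_ids landmark gene ids (needed for `"top100"`).
#' @return list with `signatures` (named list of `cmap_signature`) and
#'   `manifest` (data frame: condition, profile_id, method, n_up, n_down,
#'   disqualification reason or NA).
#' @export
build_signatures <- function(profiles, method = c("hybrid", "fixed_cutoff",
                                                  "top100", "top20", "top300"),
                             landmark_ids = NULL) {
  method <- match.arg(method)
  vals <- profiles$values
  cutoff <- if (profiles$kind == "MZS") 2 else 1
  if (profiles$kind == "MZS" && !isTRUE(attr(profiles, "destandardized")))
    vals <- destandardize_mzs(profiles)$values
  sigs <- list(); rows <- list()
  for (j in seq_len(ncol(vals))) {
    v <- stats::setNames(vals[, j], rownames(vals))
    cond <- profiles$meta$condition[j]
    pid <- profiles$meta$profile_id[j]
    s <- switch(method,
      hybrid = hybrid_threshold_signature(v, cutoff = cutoff, condition = cond),
      fixed_cutoff = fixed_cutoff_signature(v, cutoff = cutoff, condition = cond),
      top100 = top_k_signature(v, 50L, "landmark", landmark_ids, condition = cond),
      top20 = top_k_signature(v, 10L, "all", condition = cond),
      top300 = top_k_signature(v, 150L, "all", condition = cond))
    if (is_disqualified(s)) {
      rows[[pid]] <- data.frame(condition = cond, profile_id = pid,
                                method = method, n_up = NA_integer_,
                                n_down = NA_integer_, disqualified = s$reason,
                                stringsAsFactors = FALSE)
    } else {
      sigs[[pid]] <- s
      rows[[pid]] <- data.frame(condition = cond, profile_id = pid,
                                method = method, n_up = length(s$up_genes),
                                n_down = length(s$down_genes),
                                disqualified = NA_character_,
                                stringsAsFactors = FALSE)
    }
  }
  manifest <- if (length(rows)) do.call(rbind, rows) else
    data.frame(condition = character(), profile_id = character(),
               method = character(), n_up = integer(), n_down = integer(),
               disqualified = character(), stringsAsFactors = FALSE)
  rownames(manifest) <- NULL
  list(signatures = sigs, manifest = manifest)
}
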