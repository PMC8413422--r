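# Synthetic perturbation-corpus generator.
#
# Emulates a pair of connectivity-map-style compendia ("platform A" /
# "platform B"): replicated compound x concentration x cell line conditions,
# plate-matched vehicle controls, saturating (Hill) dose-response, cell-line
# responsiveness, and a tunable cross-platform concordance of the planted
# per-gene effect vectors. Every downstream stage of the package is testable
# against this planted ground truth.

#' Specification of a synthetic perturbation corpus
#'
#' Collects every tunable of the generator in one validated object. The
#' defaults describe a small two-cell-line compendium: 20 compounds at four
#' concentrations spanning typical potencies, three replicate
#' treatment-control groups per condition, and log2-scale expression noise.
#'
#' @param n_genes number of genes on the (shared) gene index.
#' @param n_landmark number of genes flagged as directly measured landmarks
#'   (the remainder play the role of inferred genes); must be `<= n_genes`.
#' @param compounds character vector of compound labels.
#' @param concentrations positive concentrations in micromolar applied to
#'   every compound.
#' @param cell_lines character vector of cell line labels.
#' @param duration_h treatment duration in hours (single value).
#' @param n_replicate_profiles number of independent replicate
#'   treatment-control groups (each on its own plate pool) per condition.
#' @param n_samples_per_group samples per treatment group and per control
#'   group; must lie in `[2, 20]`, the group-size constraint enforced by the
#'   differential-expression engine.
#' @param sample_noise_sd per-gene, per-sample Gaussian noise (log2 units).
#' @param platform_noise_sd standard deviation of the fixed per-gene
#'   platform distortion added to treatment samples of each
#'   (compound, cell line) on each platform; models systematic
#'   platform-specific artefacts that do not average out over samples.
#' @param plate_effect_sd standard deviation of the scalar per-plate offset
#'   (shared by all genes on a plate, so it cancels in plate-matched
#'   fold changes).
#' @param concordance_rho target Pearson correlation, in `[0, 1]`, between
#'   the platform A and platform B effect vectors of each
#'   (compound, cell line).
#' @param frac_de_genes fraction of genes, in `(0, 1]`, with a nonzero
#'   planted effect per (compound, cell line).
#' @param effect_scale standard deviation (log2 units) of nonzero planted
#'   effects.
#' @param seed integer master seed; expanded into per-stage substreams.
#'
#' @return an object of class `corpus_spec`.
#' @export
#' @examples
#' spec <- corpus_spec(n_genes = 200, compounds = paste0("cpd", 1:5))
#' spec$n_genes
corpus_spec <- function(n_genes = 1000L,
                        n_landmark = 200L,
                        compounds = sprintf("cpd%02d", 1:20),
                        concentrations = c(0.08, 0.4, 2, 10),
                        cell_lines = c("MCF7", "PC3"),
                        duration_h = 6,
                        n_replicate_profiles = 3L,
                        n_samples_per_group = 4L,
                        sample_noise_sd = 0.5,
                        platform_noise_sd = 0.25,
                        plate_effect_sd = 0.3,
                        concordance_rho = 0.7,
                        frac_de_genes = 0.15,
                        effect_scale = 2,
                        seed = 1L) {
  spec <- list(
    n_genes = as.integer(n_genes), n_landmark = as.integer(n_landmark),
    compounds = as.character(compounds),
    concentrations = as.numeric(concentrations),
    cell_lines = as.character(cell_lines), duration_h = as.numeric(duration_h),
    n_replicate_profiles = as.integer(n_replicate_profiles),
    n_samples_per_group = as.integer(n_samples_per_group),
    sample_noise_sd = as.numeric(sample_noise_sd),
    platform_noise_sd = as.numeric(platform_noise_sd),
    plate_effect_sd = as.numeric(plate_effect_sd),
    concordance_rho = as.numeric(concordance_rho),
    frac_de_genes = as.numeric(frac_de_genes),
    effect_scale = as.numeric(effect_scale),
    seed = as.integer(seed)
  )
  class(spec) <- "corpus_spec"
  validate_corpus_spec(spec)
  spec
}

#' @keywords internal
validate_corpus_spec <- function(spec) {
  if (!inherits(spec, "corpus_spec")) stop("not a corpus_spec", call. = FALSE)
  with(spec, {
    if (is.na(n_genes) || n_genes < 1) stop_field("n_genes", "must be a positive count")
    if (is.na(n_landmark) || n_landmark < 1 || n_landmark > n_genes)
      stop_field("n_landmark", "must be a positive count <= n_genes")
    if (length(compounds) < 1 || anyDuplicated(compounds))
      stop_field("compounds", "must be a nonempty set of unique labels")
    if (length(concentrations) < 1 || any(!is.finite(concentrations)) ||
        any(concentrations <= 0))
      stop_field("concentrations", "must all be positive")
    if (length(cell_lines) < 1 || anyDuplicated(cell_lines))
      stop_field("cell_lines", "must be a nonempty set of unique labels")
    if (length(duration_h) != 1 || duration_h <= 0)
      stop_field("duration_h", "must be a single positive value")
    if (n_replicate_profiles < 1)
      stop_field("n_replicate_profiles", "must be a positive count")
    if (n_samples_per_group < 2 || n_samples_per_group > 20)
      stop_field("n_samples_per_group", "must lie in [2, 20]")
    if (sample_noise_sd < 0) stop_field("sample_noise_sd", "must be nonnegative")
    if (platform_noise_sd < 0) stop_field("platform_noise_sd", "must be nonnegative")
    if (plate_effect_sd < 0) stop_field("plate_effect_sd", "must be nonnegative")
    if (!is.finite(concordance_rho) || concordance_rho < 0 || concordance_rho > 1)
      stop_field("concordance_rho", "must lie in [0, 1]")
    if (!is.finite(frac_de_genes) || frac_de_genes <= 0 || frac_de_genes > 1)
      stop_field("frac_de_genes", "must lie in (0, 1]")
    if (!is.finite(effect_scale) || effect_scale <= 0)
      stop_field("effect_scale", "must be positive")
    if (is.na(seed)) stop_field("seed", "must be an integer")
  })
  invisible(spec)
}

#' Saturating Hill dose-response scaling
#'
#' Fraction of the maximal transcriptional effect attained at concentration
#' `d`: `d^h / (ec50^h + d^h)`. Strictly increasing in `d`, 0.5 at
#' `d = ec50`, and saturating at 1.
#'
#' @param d concentration in micromolar (positive).
#' @param ec50 half-maximal concentration in micromolar (positive).
#' @param hill Hill coefficient (positive).
#' @return a value in `(0, 1)`, vectorized over `d`.
#' @export
#' @examples
#' dose_scaling(10, ec50 = 5, hill = 2)  # 0.8
dose_scaling <- function(d, ec50, hill) {
  if (any(!is.finite(d)) || any(d <= 0)) stop("d must be positive", call. = FALSE)
  if (!is.finite(ec50) || ec50 <= 0) stop("ec50 must be positive", call. = FALSE)
  if (!is.finite(hill) || hill <= 0) stop("hill must be positive", call. = FALSE)
  # work on the log scale to avoid overflow at extreme d/ec50 ratios
  r <- (log(d) - log(ec50)) * hill
  stats::plogis(r)
}

#' Generate the planted ground truth of a synthetic corpus
#'
#' Draws, for every (compound, cell line), a sparse gene-indexed effect
#' vector for platform A; the platform B vector is the mixture
#' `rho * theta + sqrt(1 - rho^2) * eps` with `eps` an independent draw of
#' the same marginal distribution, so that its expected correlation with
#' the platform A vector equals `concordance_rho`. Per-compound Hill
#' dose-response parameters and per-(compound, cell line) responsiveness
#' complete the truth. The random draws do not depend on `concordance_rho`,
#' so corpora generated at different concordance levels under the same seed
#' share the same underlying effect and noise components.
#'
#' @param spec a [corpus_spec()].
#' @param responsiveness optional compounds x cell lines matrix in `[0, 1]`
#'   overriding the drawn responsiveness (e.g. zero rows to plant
#'   unresponsive conditions).
#' @param ec50 optional named vector (per compound) of EC50 values in
#'   micromolar overriding the drawn values.
#' @param hill optional named vector (per compound) of Hill coefficients.
#' @return an object of class `ground_truth` with elements
#'   `effects_a`, `effects_b` (gene x condition-key matrices),
#'   `ec50`, `hill` (named per compound),
#'   `responsiveness` (compounds x cell lines matrix), and `gene_ids`.
#' @export
generate_ground_truth <- function(spec, responsiveness = NULL,
                                  ec50 = NULL, hill = NULL) {
  validate_corpus_spec(spec)
  n_cpd <- length(spec$compounds)
  n_cell <- length(spec$cell_lines)
  keys <- as.vector(outer(spec$compounds, spec$cell_lines, paste, sep = "|"))
  gene_ids <- sprintf("G%05d", seq_len(spec$n_genes))

  with_seed(substream_seed(spec$seed, "ground_truth"), {
    draw_sparse <- function() {
      mask <- matrix(stats::rbinom(spec$n_genes * length(keys), 1L,
                                   spec$frac_de_genes),
                     nrow = spec$n_genes)
      eff <- matrix(stats::rnorm(spec$n_genes * length(keys), 0,
                                 spec$effect_scale),
                    nrow = spec$n_genes)
      out <- mask * eff
      dimnames(out) <- list(gene_ids, keys)
      out
    }
    theta <- draw_sparse()
    eps <- draw_sparse()
    drawn_ec50 <- stats::setNames(10^stats::runif(n_cpd, -0.5, 1), spec$compounds)
    drawn_hill <- stats::setNames(stats::runif(n_cpd, 1, 2), spec$compounds)
    drawn_resp <- matrix(stats::runif(n_cpd * n_cell, 0.25, 1),
                         nrow = n_cpd,
                         dimnames = list(spec$compounds, spec$cell_lines))
  })

  rho <- spec$concordance_rho
  effects_b <- rho * theta + sqrt(1 - rho^2) * eps

  if (!is.null(ec50)) {
    if (!all(spec$compounds %in% names(ec50)))
      stop_field("ec50", "must name every compound")
    drawn_ec50 <- ec50[spec$compounds]
  }
  if (!is.null(hill)) {
    if (!all(spec$compounds %in% names(hill)))
      stop_field("hill", "must name every compound")
    drawn_hill <- hill[spec$compounds]
  }
  if (!is.null(responsiveness)) {
    if (!all(dim(responsiveness) == c(n_cpd, n_cell)))
      stop_field("responsiveness", "must be a compounds x cell_lines matrix")
    if (any(responsiveness < 0 | responsiveness > 1))
      stop_field("responsiveness", "values must lie in [0, 1]")
    drawn_resp <- responsiveness
    dimnames(drawn_resp) <- list(spec$compounds, spec$cell_lines)
  }
  if (any(drawn_ec50 <= 0)) stop_field("ec50", "must be positive")
  if (any(drawn_hill <= 0)) stop_field("hill", "must be positive")

  structure(list(effects_a = theta, effects_b = effects_b,
                 ec50 = drawn_ec50, hill = drawn_hill,
                 responsiveness = drawn_resp, gene_ids = gene_ids),
            class = "ground_truth")
}

#' Simulate an expression corpus for one platform
#'
#' Builds a gene x sample log2 expression matrix with complete sample
#' metadata. Every condition receives `n_replicate_profiles` independent
#' replicate groups, each consisting of one treatment group and one
#' plate-matched control group on a dedicated plate pool. Control samples
#' are baseline + scalar plate offset + per-gene noise; treatment samples
#' additionally receive `dose_scaling * responsiveness * effect_vector`
#' plus the fixed per-(compound, cell line) platform distortion.
#'
#' @param truth a [generate_ground_truth()] result.
#' @param spec the [corpus_spec()] used to build `truth`.
#' @param platform `"A"` or `"B"`; selects the effect-vector set and the
#'   platform-specific random substream.
#' @return an object of class `expr_corpus`: a list with `values`
#'   (gene x sample matrix), `gene_info` (`gene_id`, `landmark`), and
#'   `sample_meta` (one row per sample: `sample_id`, `compound`,
#'   `concentration_uM`, `cell_line`, `duration_h`, `role`, `plate_pool`,
#'   `replicate_group`).
#' @export
simulate_corpus <- function(truth, spec, platform = c("A", "B")) {
  platform <- match.arg(platform)
  validate_corpus_spec(spec)
  if (!inherits(truth, "ground_truth")) stop("truth must be a ground_truth")

  effects <- if (platform == "A") truth$effects_a else truth$effects_b
  gene_ids <- truth$gene_ids
  n_genes <- spec$n_genes
  npg <- spec$n_samples_per_group

  grid <- expand.grid(replicate = seq_len(spec$n_replicate_profiles),
                      concentration_uM = spec$concentrations,
                      cell_line = spec$cell_lines,
                      compound = spec$compounds,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  # deterministic ordering of samples
  grid <- grid[order(grid$compound, grid$cell_line, grid$concentration_uM,
                     grid$replicate), , drop = FALSE]

  meta_list <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    plate <- sprintf("plate_%s_%s_%s_r%d", g$compound,
                     format(g$concentration_uM, trim = TRUE, scientific = FALSE),
                     g$cell_line, g$replicate)
    trt_grp <- paste0(plate, "_trt")
    ctl_grp <- paste0(plate, "_ctl")
    meta_list[[i]] <- data.frame(
      sample_id = c(sprintf("%s_s%02d", trt_grp, seq_len(npg)),
                    sprintf("%s_s%02d", ctl_grp, seq_len(npg))),
      compound = c(rep(g$compound, npg), rep("DMSO", npg)),
      concentration_uM = c(rep(g$concentration_uM, npg), rep(NA_real_, npg)),
      cell_line = g$cell_line,
      duration_h = spec$duration_h,
      role = rep(c("treatment", "control"), each = npg),
      plate_pool = plate,
      replicate_group = rep(c(trt_grp, ctl_grp), each = npg),
      treated_compound = g$compound,
      treated_concentration_uM = g$concentration_uM,
      stringsAsFactors = FALSE
    )
  }
  meta <- do.call(rbind, meta_list)
  rownames(meta) <- NULL
  n_samples <- nrow(meta)
  plates <- unique(meta$plate_pool)

  with_seed(substream_seed(spec$seed, paste0("corpus_", platform)), {
    baseline <- stats::runif(n_genes, 4, 12)
    plate_eff <- stats::setNames(
      stats::rnorm(length(plates), 0, spec$plate_effect_sd), plates)
    distort <- matrix(stats::rnorm(n_genes * ncol(effects), 0,
                                   spec$platform_noise_sd),
                      nrow = n_genes, dimnames = dimnames(effects))
    noise <- matrix(stats::rnorm(n_genes * n_samples, 0, spec$sample_noise_sd),
                    nrow = n_genes)
  })

  values <- matrix(baseline, nrow = n_genes, ncol = n_samples) + noise
  values <- sweep(values, 2, plate_eff[meta$plate_pool], "+")

  trt_idx <- which(meta$role == "treatment")
  if (length(trt_idx)) {
    key <- paste(meta$treated_compound[trt_idx], meta$cell_line[trt_idx],
                 sep = "|")
    scl <- vapply(trt_idx, function(j) {
      cpd <- meta$treated_compound[j]
      dose_scaling(meta$treated_concentration_uM[j],
                   truth$ec50[[cpd]], truth$hill[[cpd]]) *
        truth$responsiveness[cpd, meta$cell_line[j]]
    }, numeric(1))
    values[, trt_idx] <- values[, trt_idx] +
      sweep(effects[, key, drop = FALSE], 2, scl, "*") +
      distort[, key, drop = FALSE]
  }

  dimnames(values) <- list(gene_ids, meta$sample_id)
  meta$treated_compound <- NULL
  meta$treated_concentration_uM <- NULL
  structure(list(
    values = values,
    gene_info = data.frame(gene_id = gene_ids,
                           landmark = seq_len(n_genes) <= spec$n_landmark,
                           stringsAsFactors = FALSE),
    sample_meta = meta,
    platform = platform
  ), class = "expr_corpus")
}

#' @export
print.expr_corpus <- function(x, ...) {
  cat(sprintf("expr_corpus (platform %s): %d genes x %d samples, %d plate pools\n",
              x$platform, nrow(x$values), ncol(x$values),
              length(unique(x$sample_meta$plate_pool))))
  invisible(x)
}

#' Landmark gene identifiers of a corpus
#' @param corpus an `expr_corpus`.
#' @return character vector of landmark gene ids.
#' @export
landmark_genes <- function(corpus) {
  corpus$gene_info$gene_id[corpus$gene_info$landmark]
}
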