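# Shared fixtures: small corpus specs and hand-built DE profile sets.

small_spec <- function(...) {
  args <- list(n_genes = 300L, n_landmark = 60L,
               compounds = sprintf("cpd%02d", 1:6),
               concentrations = c(0.5, 10),
               cell_lines = c("MCF7", "PC3"),
               n_replicate_profiles = 2L, n_samples_per_group = 4L,
               seed = 11L)
  args[names(list(...))] <- list(...)
  do.call(corpus_spec, args)
}

noiseless_spec <- function(...) {
  small_spec(sample_noise_sd = 0, platform_noise_sd = 0, plate_effect_sd = 0,
             ...)
}

# de_profiles object built directly from a value matrix and a condition
# layout; replicate ids are appended per duplicated condition
make_profiles <- function(values, compound, concentration_uM, cell_line,
                          duration_h = 6, kind = "FC", n_reps = 2L) {
  meta <- data.frame(
    profile_id = colnames(values), compound = compound,
    concentration_uM = concentration_uM, cell_line = cell_line,
    duration_h = duration_h, replicate_group = colnames(values),
    n_contributing_replicates = n_reps,
    condition = paste(compound, format(concentration_uM, trim = TRUE,
                                       scientific = FALSE),
                      cell_line, duration_h, sep = "|"),
    stringsAsFactors = FALSE)
  sigrepro:::new_de_profiles(values, meta, kind)
}

random_ternary <- function(n) sample(c(-1L, 0L, 1L), n, replace = TRUE)

# set-enumeration oracle for the ternary Jaccard index
ternary_jaccard_oracle <- function(a, b) {
  up_a <- which(a == 1); dn_a <- which(a == -1)
  up_b <- which(b == 1); dn_b <- which(b == -1)
  num <- length(intersect(up_a, up_b)) + length(intersect(dn_a, dn_b))
  den <- length(union(c(up_a, dn_a), c(up_b, dn_b)))
  if (den == 0) 0 else num / den
}

# textbook tie-corrected Spearman formula (sums over tie groups)
spearman_tie_formula <- function(x, y) {
  n <- length(x)
  tie_term <- function(v) {
    t <- table(v)
    sum(t^3 - t) / 12
  }
  rx <- rank(x); ry <- rank(y)
  Sx <- (n^3 - n) / 12 - tie_term(x)
  Sy <- (n^3 - n) / 12 - tie_term(y)
  d2 <- sum((rx - ry)^2)
  (Sx + Sy - d2) / (2 * sqrt(Sx * Sy))
}
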