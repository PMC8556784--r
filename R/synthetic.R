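#' Configuration for the planted-block synthetic generator
#'
#' The generator emulates the statistical structure the prediction method
#' relies on: drugs come in groups, each drug group preferentially treats one
#' disease group, drugs within a group share a feature fingerprint and a
#' side-effect profile, and a fraction of disease labels double as
#' side-effect labels so that side-effect marking has something to mark.
#'
#' Defaults emulate the real corpus the method was designed for at one
#' quarter scale (134 drugs x 145 diseases, 414 feature bits, 346 side
#' effects) with cell probabilities chosen so that realized sparsities land
#' near 0.99 (associations), 0.92 (features) and 0.95 (side effects).
#'
#' @param n_drugs,n_diseases,n_features,n_side_effects entity counts
#' @param n_drug_groups,n_disease_groups planted group counts (drug group g
#'   is mapped to disease group `((g - 1) %% n_disease_groups) + 1`)
#' @param p_assoc_in_group probability of a treatment link inside a mapped
#'   drug-group/disease-group block
#' @param p_assoc_background probability of a treatment link elsewhere
#' @param p_feature_in_group density of a drug group's prototype fingerprint
#' @param p_side_in_group density of a drug group's prototype side-effect set
#' @param feature_flip_noise per-drug, per-bit flip probability applied to
#'   the group prototypes (features and side effects alike)
#' @param overlap_fraction fraction of disease labels reused as side-effect
#'   labels
#' @param seed integer seed; the generated triple is a pure function of the
#'   config
#' @return a list of class `synth_config`
#' @export
synth_config <- function(n_drugs = 134, n_diseases = 145, n_features = 414,
                         n_side_effects = 346, n_drug_groups = 12,
                         n_disease_groups = 12, p_assoc_in_group = 0.08,
                         p_assoc_background = 8e-4,
                         p_feature_in_group = 0.07, p_side_in_group = 0.05,
                         feature_flip_noise = 0.008,
                         overlap_fraction = 0.25, seed = 1L) {
  cfg <- list(n_drugs = n_drugs, n_diseases = n_diseases,
              n_features = n_features, n_side_effects = n_side_effects,
              n_drug_groups = n_drug_groups,
              n_disease_groups = n_disease_groups,
              p_assoc_in_group = p_assoc_in_group,
              p_assoc_background = p_assoc_background,
              p_feature_in_group = p_feature_in_group,
              p_side_in_group = p_side_in_group,
              feature_flip_noise = feature_flip_noise,
              overlap_fraction = overlap_fraction, seed = as.integer(seed))
  counts <- cfg[c("n_drugs", "n_diseases", "n_features", "n_side_effects",
                  "n_drug_groups", "n_disease_groups")]
  if (any(unlist(counts) < 1))
    stop("all entity and group counts must be positive", call. = FALSE)
  probs <- cfg[c("p_assoc_in_group", "p_assoc_background",
                 "p_feature_in_group", "p_side_in_group",
                 "feature_flip_noise", "overlap_fraction")]
  if (any(unlist(probs) < 0 | unlist(probs) > 1))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (n_drug_groups > n_drugs || n_disease_groups > n_diseases)
    stop("group counts cannot exceed entity counts", call. = FALSE)
  if (round(overlap_fraction * n_diseases) > n_side_effects)
    stop("overlap_fraction implies more shared labels than side effects",
         call. = FALSE)
  structure(cfg, class = "synth_config")
}

# Run expr with a private RNG stream; caller's .Random.seed is untouched.
with_rng <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

pad_labels <- function(prefix, n) sprintf("%s%0*d", prefix, nchar(n), seq_len(n))

# Contiguous, balanced group assignment (sizes differ by at most 1).
assign_groups <- function(n, g) sort(rep_len(seq_len(g), n))

#' Generate a synthetic association / feature / side-effect triple
#'
#' Implements the planted-block model described in [synth_config()].  Given
#' the same config the output is bit-identical across calls.
#'
#' @param config a [synth_config()]
#' @return a list with labeled matrices `assoc` (drug x disease, 0/1),
#'   `features` (drug x feature, 0/1), `side_effects` (drug x side effect,
#'   0/1), plus ground-truth vectors `drug_groups`, `disease_groups` and the
#'   `config`
#' @export
synth_generate <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  with_rng(config$seed, {
    drugs <- pad_labels("drug", config$n_drugs)
    diseases <- pad_labels("disease", config$n_diseases)
    features <- pad_labels("feat", config$n_features)
    n_overlap <- round(config$overlap_fraction * config$n_diseases)
    sides <- c(diseases[seq_len(n_overlap)],
               pad_labels("side", config$n_side_effects - n_overlap))

    dg <- assign_groups(config$n_drugs, config$n_drug_groups)
    eg <- assign_groups(config$n_diseases, config$n_disease_groups)
    mapped <- ((dg - 1L) %% config$n_disease_groups) + 1L

    in_block <- outer(mapped, eg, `==`)
    p <- ifelse(in_block, config$p_assoc_in_group, config$p_assoc_background)
    assoc <- matrix(as.double(stats::runif(length(p)) < p), nrow(p),
                    dimnames = list(drugs, diseases))

    flip_from_prototype <- function(proto_p, n_cols, labels) {
      proto <- matrix(
        as.double(stats::runif(config$n_drug_groups * n_cols) < proto_p),
        config$n_drug_groups, n_cols)
      m <- proto[dg, , drop = FALSE]
      flips <- stats::runif(length(m)) < config$feature_flip_noise
      m[flips] <- 1 - m[flips]
      dimnames(m) <- list(drugs, labels)
      m
    }
    feats <- flip_from_prototype(config$p_feature_in_group,
                                 config$n_features, features)
    side <- flip_from_prototype(config$p_side_in_group,
                                config$n_side_effects, sides)

    list(assoc = labeled_matrix(assoc), features = labeled_matrix(feats),
         side_effects = labeled_matrix(side), drug_groups = dg,
         disease_groups = eg, config = config)
  })
}

#' Sparse degree of a matrix
#'
#' Fraction of zero-valued cells, the "sparse degree" used to characterize
#' the input corpora (about 0.99 for associations, 0.92 for drug features,
#' 0.95 for side effects at full scale).
#'
#' @param x labeled numeric matrix
#' @return fraction of zeros in `[0, 1]`
#' @export
sparsity <- function(x) {
  if (!is.matrix(x) || length(x) == 0L)
    stop("sparsity() needs a non-empty matrix", call. = FALSE)
  mean(x == 0)
}
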