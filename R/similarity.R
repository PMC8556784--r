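#' Similarity matrices
#'
#' Three similarity notions feed the neighbor predictor: cosine similarity
#' over the autoencoder codes for drug-feature similarity, the Tanimoto
#' coefficient over side-effect profiles for drug side-effect similarity, and
#' the Tanimoto coefficient over treatment profiles (which drugs treat a
#' disease) for disease similarity.  All outputs are symmetric square
#' matrices with values in `[0, 1]`.
#'
#' Entities with an empty profile (all-zero code vector, no side effects, no
#' treating drugs) get similarity 0 to everything *including themselves*: the
#' Tanimoto ratio is 0/0 there, and the zero convention keeps them inert as
#' neighbors.
#'
#' @name similarity
NULL

#' Cosine similarity between drugs from encoded features
#'
#' `sim(d, d*) = sum(f_d * f_d*) / (||f_d|| * ||f_d*||)` with the zero-norm
#' convention of [similarity].
#'
#' @param encoded drugs x code real matrix with non-negative entries (ReLU
#'   codes), row labels = drug labels
#' @return symmetric drugs x drugs similarity matrix
#' @export
cosine_drug_similarity <- function(encoded) {
  x <- as.matrix(encoded)
  norms <- sqrt(rowSums(x^2))
  s <- tcrossprod(x)
  denom <- outer(norms, norms)
  s <- ifelse(denom > 0, s / denom, 0)
  # guard rounding: clamp into [0,1] for non-negative inputs
  s[s > 1] <- 1
  s[s < 0] <- 0
  dimnames(s) <- list(rownames(encoded), rownames(encoded))
  s
}

# Tanimoto over the rows of a binary matrix; empty profiles -> 0 everywhere.
tanimoto_rows <- function(x) {
  inter <- tcrossprod(x)
  sizes <- rowSums(x)
  union <- outer(sizes, sizes, `+`) - inter
  s <- ifelse(union > 0, inter / union, 0)
  dimnames(s) <- list(rownames(x), rownames(x))
  s
}

#' Tanimoto similarity between drugs from side-effect profiles
#'
#' `sim(d, d*) = |I_dd*| / (|I_d| + |I_d*| - |I_dd*|)` where `I_dd*` counts
#' shared side effects and `I_d` the side effects of drug d.
#'
#' @param side_effects binary drugs x side-effect matrix
#' @return symmetric drugs x drugs similarity matrix
#' @export
tanimoto_drug_similarity <- function(side_effects) {
  validate_labeled_matrix(side_effects, binary = TRUE, what = "side_effects")
  tanimoto_rows(as.matrix(side_effects))
}

#' Tanimoto similarity between diseases from treatment profiles
#'
#' `sim(e, e*) = |I_ee*| / (|I_e| + |I_e*| - |I_ee*|)` where `I_ee*` counts
#' drugs treating both diseases.  Only association cells equal to 1 count as
#' "treats": the -1 cells introduced by [mark_side_effects()] are treated as
#' non-treatments.
#'
#' @param assoc drug x disease association matrix over \{-1, 0, 1\}
#' @return symmetric diseases x diseases similarity matrix
#' @export
tanimoto_disease_similarity <- function(assoc) {
  validate_labeled_matrix(assoc, what = "assoc")
  if (!all(assoc %in% c(-1, 0, 1)))
    stop("assoc values must lie in {-1, 0, 1}", call. = FALSE)
  treats <- t(assoc == 1) * 1   # diseases x drugs indicator
  tanimoto_rows(treats)
}
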