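#' Mark known side effects into the association matrix
#'
#' Some side-effect labels are disease labels.  Where a drug is known to
#' *cause* a disease as a side effect, the drug-disease cell is flipped from
#' 0 to -1 so the neighbor predictor can use "causes" as negative evidence.
#' Cells equal to 1 (known treatments) are never overwritten.  Labels are
#' matched by exact string equality.
#'
#' @param assoc drug x disease matrix over \{0, 1\}
#' @param side_effects binary drug x side-effect matrix (same drug axis)
#' @return the association matrix with some 0 cells set to -1
#' @export
mark_side_effects <- function(assoc, side_effects) {
  validate_labeled_matrix(assoc, binary = TRUE, what = "assoc")
  validate_labeled_matrix(side_effects, binary = TRUE, what = "side_effects")
  if (!identical(rownames(assoc), rownames(side_effects)))
    stop("assoc and side_effects must share the drug axis (run align_inputs)",
         call. = FALSE)
  shared <- intersect(colnames(assoc), colnames(side_effects))
  out <- assoc
  for (lab in shared) {
    hit <- side_effects[, lab] == 1 & out[, lab] == 0
    out[hit, lab] <- -1
  }
  out
}

# Self-inclusive top-k neighbor weights: one row per entity, W[i, j] = sim if
# j is among i's top_k neighbors (ranked by similarity, ties by label), plus
# W[i, i] = 1.  Rows of the returned matrix sum to >= 1.
neighbor_weights <- function(sim, top_k) {
  n <- nrow(sim)
  labs <- rownames(sim)
  if (top_k < 1) stop("top_k must be >= 1", call. = FALSE)
  w <- matrix(0, n, n, dimnames = dimnames(sim))
  k <- min(top_k, n - 1L)
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    ranked <- others[order(-sim[i, others], labs[others])]
    nn <- ranked[seq_len(k)]
    w[i, nn] <- sim[i, nn]
    w[i, i] <- 1
  }
  w
}

#' Predict associations from drug similarity
#'
#' For each drug d and disease e the score is the similarity-weighted mean of
#' the (marked) association values over `NN' = {d} union (top-k most similar
#' drugs)`, with the drug itself included at similarity 1:
#' `P(d,e) = sum_{d* in NN'} sim(d,d*) s(d*,e) / sum_{d* in NN'} sim(d,d*)`.
#' Self-inclusion anchors the prediction to known information and keeps the
#' denominator at least 1, so sparse similarity rows cannot collapse the
#' ratio.  Ties at the top-k boundary are broken by drug label order.
#'
#' @param assoc_marked drug x disease matrix over \{-1, 0, 1\}
#' @param drug_sim symmetric drug similarity matrix aligned with `assoc_marked`
#' @param top_k number of neighbors (ranked positions; zero-similarity
#'   neighbors still occupy positions), default 50
#' @return drug x disease real score matrix in `[-1, 1]`
#' @export
predict_by_drug <- function(assoc_marked, drug_sim, top_k = 50L) {
  stopifnot(identical(rownames(assoc_marked), rownames(drug_sim)))
  w <- neighbor_weights(drug_sim, top_k)
  p <- (w %*% assoc_marked) / rowSums(w)
  dimnames(p) <- dimnames(assoc_marked)
  p
}

#' Predict associations from disease similarity
#'
#' Column-wise counterpart of [predict_by_drug()]: scores are weighted means
#' of association values over each disease's self-inclusive top-k neighbor
#' set, `P(d,e) = sum_{e* in NN'} sim(e,e*) s(d,e*) / sum sim(e,e*)`.
#'
#' @param assoc_marked drug x disease matrix over \{-1, 0, 1\}
#' @param disease_sim symmetric disease similarity matrix aligned with the
#'   columns of `assoc_marked`
#' @inheritParams predict_by_drug
#' @return drug x disease real score matrix in `[-1, 1]`
#' @export
predict_by_disease <- function(assoc_marked, disease_sim, top_k = 50L) {
  stopifnot(identical(colnames(assoc_marked), rownames(disease_sim)))
  w <- neighbor_weights(disease_sim, top_k)
  p <- assoc_marked %*% t(w)
  p <- sweep(p, 2, rowSums(w), `/`)
  dimnames(p) <- dimnames(assoc_marked)
  p
}

#' Per-source prediction matrices
#'
#' Wires the three data sources into prediction matrices: source `"assoc"`
#' uses disease Tanimoto similarity (disease-side prediction), source
#' `"feature"` uses cosine similarity over the autoencoder codes, and source
#' `"side"` uses Tanimoto similarity over side-effect profiles (both
#' drug-side predictions).
#'
#' @param assoc_marked marked association matrix
#' @param encoded autoencoder code matrix (drug rows)
#' @param side_effects binary drug x side-effect matrix
#' @param top_k neighbor count
#' @return named list of three prediction matrices (`assoc`, `feature`,
#'   `side`)
#' @export
predict_sources <- function(assoc_marked, encoded, side_effects, top_k = 50L) {
  list(
    assoc = predict_by_disease(assoc_marked,
                               tanimoto_disease_similarity(assoc_marked),
                               top_k),
    feature = predict_by_drug(assoc_marked, cosine_drug_similarity(encoded),
                              top_k),
    side = predict_by_drug(assoc_marked,
                           tanimoto_drug_similarity(side_effects), top_k))
}
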