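#' Default encoder configuration scaled to the data
#'
#' The reference network tapers 1656 -> 1024 -> 640 -> 400; expressed as
#' ratios of the input width that is roughly x0.62, x0.39, x0.24.  This
#' helper applies the same taper to an arbitrary feature count so the
#' quarter-scale synthetic fixture (414 features) gets a proportionate
#' 414 -> 256 -> 160 -> 100 network.
#'
#' @param input_dim number of feature columns
#' @param ... further arguments passed to [encoder_config()]
#' @return an [encoder_config()]
#' @export
default_encoder_config <- function(input_dim, ...) {
  encoder_config(input_dim = input_dim,
                 hidden_dims = pmax(4L, as.integer(round(input_dim * c(0.62, 0.39)))),
                 code_dim = max(2L, as.integer(round(input_dim * 0.24))),
                 ...)
}

#' Run the full prediction pipeline
#'
#' Executes the end-to-end flow: align the three inputs on the drug axis,
#' mark side effects into the association matrix, train the autoencoder and
#' encode the drug features, compute the three similarity matrices, the three
#' per-source predictions, optimize the fusion weights and fuse.  Optionally
#' every intermediate matrix and a run manifest are written to `out_dir`.
#'
#' @param assoc,features,side_effects labeled input matrices (see
#'   [read_labeled_matrix()]), or `NULL` to generate them from `synth`
#' @param synth a [synth_config()] used when the three matrices are not given
#' @param encoder an [encoder_config()]; default [default_encoder_config()]
#'   on the aligned feature matrix with the global `seed`
#' @param top_k neighbor count (default 50)
#' @param fusion `"adaptive"` (optimized weights) or `"uniform"`
#' @param epsilon weight floor for [optimize_weights()]
#' @param seed global seed, forwarded to every stochastic stage that has no
#'   explicit seed of its own
#' @param out_dir if non-`NULL`, artifacts (CSV matrices, weight report,
#'   manifest JSON) are written there
#' @param verbose log stage progress and matrix shapes via [message()]
#' @return a list bundle: aligned inputs, `marked`, `encoded`,
#'   `similarities` (3), `predictions` (3), `weights`, `fused`, and `manifest`
#' @export
run_all <- function(assoc = NULL, features = NULL, side_effects = NULL,
                    synth = NULL, encoder = NULL, top_k = 50L,
                    fusion = c("adaptive", "uniform"), epsilon = 1e-4,
                    seed = 1L, out_dir = NULL, verbose = TRUE) {
  fusion <- match.arg(fusion)
  say <- function(...) if (verbose) message("[drfuse] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  if (is.null(assoc)) {
    if (is.null(synth)) synth <- synth_config(seed = seed)
    say("simulate: generating synthetic inputs (seed ", synth$seed, ")")
    sim <- stage("simulate", synth_generate(synth))
    assoc <- sim$assoc; features <- sim$features
    side_effects <- sim$side_effects
  }

  say("align: ", nrow(assoc), " x ", ncol(assoc), " associations")
  aligned <- stage("align", align_inputs(assoc, features, side_effects))
  if (any(aligned$dropped > 0))
    say("align: dropped drugs ", paste(aligned$dropped, collapse = "/"))

  marked <- stage("mark", mark_side_effects(aligned$assoc,
                                            aligned$side_effects))
  say("mark: ", sum(marked == -1), " cells set to -1")

  if (is.null(encoder))
    encoder <- default_encoder_config(ncol(aligned$features), seed = seed)
  say("encode: ", paste(c(encoder$input_dim, encoder$hidden_dims,
                          encoder$code_dim), collapse = " -> "))
  model <- stage("encode", fit_autoencoder(build_autoencoder(encoder),
                                           aligned$features))
  encoded <- encode(model, aligned$features)
  say("encode: final training MSE ",
      signif(model$loss_history[length(model$loss_history)], 4),
      " after ", length(model$loss_history), " epochs")

  sims <- stage("similarity", list(
    disease = tanimoto_disease_similarity(marked),
    feature = cosine_drug_similarity(encoded),
    side = tanimoto_drug_similarity(aligned$side_effects)))

  say("predict: top_k = ", top_k)
  preds <- stage("predict", list(
    assoc = predict_by_disease(marked, sims$disease, top_k),
    feature = predict_by_drug(marked, sims$feature, top_k),
    side = predict_by_drug(marked, sims$side, top_k)))

  if (fusion == "adaptive") {
    weights <- stage("fuse", suppressWarnings(
      optimize_weights(marked, preds, epsilon)))
    say("fuse: weights ", paste(signif(weights$weights, 4), collapse = ", "))
  } else {
    k <- length(preds)
    weights <- structure(list(weights = stats::setNames(rep(1 / k, k),
                                                        names(preds)),
                              coefficients = fusion_coefficients(marked, preds),
                              value = NA_real_),
                         class = "fusion_weights")
    say("fuse: uniform weights")
  }
  fused <- fuse_predictions(preds, weights)

  manifest <- list(
    package = "drfuse",
    version = as.character(utils::packageVersion("drfuse")),
    seed = seed, top_k = top_k, fusion = fusion, epsilon = epsilon,
    encoder = unclass(encoder),
    synth = if (!is.null(synth)) unclass(synth),
    weights = as.list(weights$weights),
    n_drugs = nrow(marked), n_diseases = ncol(marked))

  bundle <- list(assoc = aligned$assoc, features = aligned$features,
                 side_effects = aligned$side_effects, marked = marked,
                 model = model, encoded = encoded, similarities = sims,
                 predictions = preds, weights = weights, fused = fused,
                 manifest = manifest)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    w <- function(m, name)
      write_labeled_matrix(m, file.path(out_dir, paste0(name, ".csv")))
    w(aligned$assoc, "assoc"); w(marked, "assoc_marked")
    w(encoded, "encoded")
    w(sims$disease, "sim_disease"); w(sims$feature, "sim_feature")
    w(sims$side, "sim_side")
    for (nm in names(preds)) w(preds[[nm]], paste0("pred_", nm))
    w(fused, "fused")
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    say("artifacts written to ", out_dir)
  }
  bundle
}

#' Rank candidate drugs for a disease
#'
#' Top-`n` drugs by fused score for one disease.  With `novel_only = TRUE`,
#' drugs already known to treat the disease (association value 1) are
#' excluded, leaving repositioning candidates only.
#'
#' @param fused fused prediction matrix
#' @param assoc the (unmarked) association matrix, for the `novel_only`
#'   filter
#' @param disease disease label
#' @param n list length
#' @param novel_only drop known treatments first
#' @return data frame with columns `drug`, `score`, `known` (association
#'   value), sorted by decreasing score
#' @export
rank_candidates <- function(fused, assoc, disease, n = 10L,
                            novel_only = FALSE) {
  if (!disease %in% colnames(fused))
    stop("unknown disease label: ", disease, call. = FALSE)
  scores <- fused[, disease]
  known <- assoc[, disease]
  keep <- if (novel_only) known != 1 else rep(TRUE, length(scores))
  ord <- order(-scores[keep], rownames(fused)[keep])
  sel <- which(keep)[ord][seq_len(min(n, sum(keep)))]
  data.frame(drug = rownames(fused)[sel], score = scores[sel],
             known = known[sel], row.names = NULL)
}
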