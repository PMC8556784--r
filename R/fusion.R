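#' Per-source penalty coefficients
#'
#' For each prediction matrix the coefficient
#' `c_k = sum_{s=1} (s - P_k)^2 - sum_{s=0} (s - P_k)^2`
#' rewards sources whose scores sit near 1 on known treatments and pushes
#' scores on unknown (s = 0) cells upward — the second sum enters with a
#' minus sign because new indications are what the method is after.  Cells
#' marked -1 by [mark_side_effects()] belong to neither stratum and are
#' excluded.
#'
#' @param assoc drug x disease matrix over \{-1, 0, 1\} (training data)
#' @param preds list of prediction matrices, same shape as `assoc`
#' @return numeric vector `c_k`, one per source
#' @export
fusion_coefficients <- function(assoc, preds) {
  stopifnot(is.list(preds), length(preds) >= 1L)
  pos <- assoc == 1
  neg <- assoc == 0
  vapply(preds, function(p) {
    if (!identical(dim(p), dim(assoc)))
      stop("prediction matrix shape does not match the association matrix",
           call. = FALSE)
    sum((1 - p[pos])^2) - sum(p[neg]^2)
  }, numeric(1))
}

#' Fusion objective
#'
#' The weighted penalty `L(beta) = sum_k beta_k^2 c_k` with `c_k` from
#' [fusion_coefficients()]; minimized over the probability simplex to obtain
#' the fusion weights.
#'
#' @param weights numeric weight vector (one per source)
#' @inheritParams fusion_coefficients
#' @return scalar objective value
#' @export
fusion_objective <- function(weights, assoc, preds) {
  if (length(weights) != length(preds))
    stop("one weight per source required", call. = FALSE)
  sum(weights^2 * fusion_coefficients(assoc, preds))
}

#' Optimize fusion weights on the simplex
#'
#' Minimizes `sum_k beta_k^2 c_k` subject to `sum beta_k = 1` and
#' `beta_k >= epsilon` (the strict positivity constraint realized as a small
#' floor).  When every `c_k` is positive the problem is a convex quadratic
#' with closed form `beta_k proportional to 1/c_k`, solved by an active-set
#' sweep against the floor.  When some `c_k <= 0` the objective rewards
#' concentrating mass on the most negative coefficient; the floor keeps the
#' problem bounded and a warning is issued.  In that regime the optimum is
#' found by comparing the floor-vertices with a deterministic local search
#' (projected BFGS from the uniform start).
#'
#' @param assoc training drug x disease matrix over \{-1, 0, 1\}
#' @param preds list of K >= 2 prediction matrices
#' @param epsilon lower bound standing in for strict positivity (default 1e-4)
#' @return a list of class `fusion_weights` with `weights` (named if `preds`
#'   is named; sums to 1, all `>= epsilon`), `coefficients` (the `c_k`) and
#'   `value` (objective at the optimum)
#' @export
optimize_weights <- function(assoc, preds, epsilon = 1e-4) {
  k <- length(preds)
  if (k < 2L) stop("need at least two sources to fuse", call. = FALSE)
  if (epsilon <= 0 || k * epsilon >= 1)
    stop("epsilon must satisfy 0 < K * epsilon < 1", call. = FALSE)
  cc <- fusion_coefficients(assoc, preds)

  obj <- function(beta) sum(beta^2 * cc)

  if (all(cc > 0)) {
    # beta ~ 1/c_k, with coordinates hitting the floor pinned there
    free <- rep(TRUE, k)
    beta <- numeric(k)
    repeat {
      mass <- 1 - sum(!free) * epsilon
      beta[free] <- mass * (1 / cc[free]) / sum(1 / cc[free])
      beta[!free] <- epsilon
      low <- free & beta < epsilon
      if (!any(low)) break
      free[low] <- FALSE
    }
  } else {
    warning("non-positive penalty coefficient(s); objective favors ",
            "concentrating weight (floor keeps it bounded)", call. = FALSE)
    vertices <- lapply(seq_len(k), function(i) {
      v <- rep(epsilon, k)
      v[i] <- 1 - (k - 1) * epsilon
      v
    })
    local <- simplex_local_search(cc, epsilon)
    cand <- c(vertices, list(local, rep(1 / k, k)))
    beta <- cand[[which.min(vapply(cand, obj, numeric(1)))]]
  }
  structure(list(weights = stats::setNames(beta, names(preds)),
                 coefficients = stats::setNames(cc, names(preds)),
                 value = obj(beta)),
            class = "fusion_weights")
}

# Deterministic constrained local search from the uniform start: the last
# coordinate is eliminated via the simplex equality, the floors become linear
# inequalities for constrOptim.
simplex_local_search <- function(cc, epsilon) {
  k <- length(cc)
  f <- function(b) {
    beta <- c(b, 1 - sum(b))
    sum(beta^2 * cc)
  }
  g <- function(b) 2 * b * cc[-k] - 2 * (1 - sum(b)) * cc[k]
  ui <- rbind(diag(k - 1L), rep(-1, k - 1L))
  ci <- c(rep(epsilon, k - 1L), epsilon - 1)
  start <- rep(1 / k, k - 1L)
  res <- tryCatch(
    stats::constrOptim(start, f, g, ui = ui, ci = ci, method = "BFGS",
                       outer.iterations = 200),
    error = function(e) list(par = start))
  beta <- c(res$par, 1 - sum(res$par))
  pmax(beta, epsilon) / sum(pmax(beta, epsilon))
}

#' Fuse per-source predictions
#'
#' Elementwise weighted sum `P* = sum_k beta_k P_k`.
#'
#' @param preds list of prediction matrices with identical shapes
#' @param weights a [optimize_weights()] result or a numeric vector of the
#'   same length as `preds`
#' @return fused prediction matrix
#' @export
fuse_predictions <- function(preds, weights) {
  if (inherits(weights, "fusion_weights")) weights <- weights$weights
  if (length(weights) != length(preds))
    stop("length(weights) must equal length(preds)", call. = FALSE)
  out <- 0
  for (i in seq_along(preds)) out <- out + weights[i] * preds[[i]]
  dimnames(out) <- dimnames(preds[[1]])
  out
}

#' Simple-average fusion baseline
#'
#' Fuses sources with uniform weights `1/K`; the baseline the adaptive
#' weights are compared against.
#'
#' @param preds non-empty list of prediction matrices
#' @return fused prediction matrix
#' @export
simple_average_fuse <- function(preds) {
  if (length(preds) == 0L) stop("no sources to fuse", call. = FALSE)
  fuse_predictions(preds, rep(1 / length(preds), length(preds)))
}
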