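#' Microstate template set
#'
#' @param maps channels x k matrix; each column is zero-mean and unit-norm.
#' @param polarity `"invariant"` (a map and its sign-flip are the same state;
#'   resting analysis) or `"variant"` (polarity respected; task analysis).
#' @param level `"individual"` or `"group"`.
#' @return object of class `"microstate_set"`.
#' @export
microstate_set <- function(maps, polarity = c("invariant", "variant"),
                           level = c("individual", "group")) {
  polarity <- match.arg(polarity)
  level <- match.arg(level)
  maps <- as.matrix(maps)
  dimnames(maps) <- NULL
  maps <- sweep(maps, 2L, colMeans(maps))
  nrm <- sqrt(colSums(maps^2))
  if (any(nrm == 0)) stop("zero-norm template map")
  maps <- sweep(maps, 2L, nrm, "/")
  structure(list(maps = maps, polarity = polarity, level = level,
                 k = ncol(maps)), class = "microstate_set")
}

#' @export
print.microstate_set <- function(x, ...) {
  cat(sprintf("<microstate_set: k = %d, %d channels, polarity-%s, %s level>\n",
              x$k, nrow(x$maps), x$polarity, x$level))
  invisible(x)
}

#' Spatial correlation between two topographies
#'
#' Cosine similarity of the two zero-mean potential vectors (their spatial
#' Pearson correlation); with `polarity_invariant` the absolute value is
#' returned.
#'
#' @param a,b average-referenced numeric vectors, same length.
#' @param polarity_invariant ignore polarity (default TRUE).
#' @return scalar in [-1, 1] (or [0, 1] when invariant).
#' @export
spatial_correlation <- function(a, b, polarity_invariant = TRUE) {
  if (length(a) != length(b)) stop("channel counts differ")
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("zero-norm topography")
  r <- sum(a * b) / (na * nb)
  if (polarity_invariant) abs(r) else r
}

# Zero-mean and unit-normalize topography columns. Zero-norm columns error
# unless drop_zero, in which case they are removed (with attribute "kept").
normalize_maps <- function(x, drop_zero = FALSE) {
  x <- as.matrix(x)
  x <- sweep(x, 2L, colMeans(x))
  nrm <- sqrt(colSums(x^2))
  if (any(nrm == 0)) {
    if (!drop_zero) stop("zero-norm (flat) topography")
    keep <- nrm > 0
    x <- x[, keep, drop = FALSE]; nrm <- nrm[keep]
    x <- sweep(x, 2L, nrm, "/")
    attr(x, "kept") <- which(keep)
    return(x)
  }
  sweep(x, 2L, nrm, "/")
}

# Evaluate RNG-dependent code under a temporary seed, restoring global state.
local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Modified k-means clustering of topographies
#'
#' Alternates assignment and template update until label stability (or a
#' relative explained-variance change below `tol`). Assignment maximizes the
#' squared spatial correlation (invariant mode) or the signed spatial
#' correlation (variant mode) with the templates. The update is the principal
#' eigenvector of the assigned maps' outer-product sum (invariant) or their
#' normalized mean (variant). The best of `n_restarts` seeded restarts by the
#' mode's objective is returned; empty clusters are re-seeded from the
#' worst-fit sample.
#'
#' @param maps channels x n matrix of topographies (average-referenced).
#' @param k number of clusters (<= n).
#' @param polarity `"invariant"` or `"variant"`.
#' @param n_restarts random restarts (default 20).
#' @param seed integer seed; the fit is bit-for-bit reproducible.
#' @param tol relative objective-change tolerance (default 1e-6).
#' @param max_iter iteration cap per restart (default 1000).
#' @return `microstate_set` with attributes `assignment` (per-sample template
#'   index), `corr` (per-sample correlation with the assigned template, signed
#'   in variant mode), `objective` (mode-specific restart objective) and `ev`
#'   (mean squared correlation of samples with their assigned template).
#' @export
modified_kmeans <- function(maps, k, polarity = c("invariant", "variant"),
                            n_restarts = 20, seed = 1, tol = 1e-6,
                            max_iter = 1000) {
  polarity <- match.arg(polarity)
  X <- normalize_maps(maps)
  n <- ncol(X)
  if (k > n) stop("k exceeds number of topographies")
  if (k < 1) stop("k must be >= 1")

  update_template <- function(members, fallback) {
    if (ncol(members) == 0L) return(fallback)
    if (polarity == "invariant") return(principal_direction(members))
    v <- rowMeans(members)
    nv <- sqrt(sum(v^2))
    if (nv == 0) members[, 1L] else v / nv
  }

  objective_of <- function(Tm, assign) {
    C <- crossprod(Tm, X)
    score <- if (polarity == "invariant") C^2 else C
    sum(score[cbind(assign, seq_len(n))])
  }

  run_once <- function(init_idx) {
    Tm <- X[, init_idx, drop = FALSE]
    assign_prev <- rep(0L, n)
    obj_prev <- -Inf
    obj_trace <- numeric(0)
    for (it in seq_len(max_iter)) {
      C <- crossprod(Tm, X)                       # k x n correlations
      score <- if (polarity == "invariant") C^2 else C
      assign <- max.col(t(score), ties.method = "first")
      win <- score[cbind(assign, seq_len(n))]
      # re-seed empty clusters from the worst-fit sample
      empty <- setdiff(seq_len(k), unique(assign))
      if (length(empty)) {
        worst <- order(win)
        for (j in seq_along(empty)) {
          t_idx <- worst[j]
          assign[t_idx] <- empty[j]
          Tm[, empty[j]] <- X[, t_idx]
        }
        C <- crossprod(Tm, X)
        score <- if (polarity == "invariant") C^2 else C
        win <- score[cbind(assign, seq_len(n))]
      }
      obj <- sum(win)
      obj_trace <- c(obj_trace, obj)
      if (all(assign == assign_prev) ||
          (is.finite(obj_prev) && abs(obj - obj_prev) <= tol * max(abs(obj), 1)))
        break
      assign_prev <- assign; obj_prev <- obj
      for (j in seq_len(k))
        Tm[, j] <- update_template(X[, assign == j, drop = FALSE], Tm[, j])
    }
    # Hartigan-style polish on small instances: exhaustive single-point
    # relocations escape the shallow basins of the alternating scheme
    if (n * k <= 240L) {
      C <- crossprod(Tm, X)
      score <- if (polarity == "invariant") C^2 else C
      assign <- max.col(t(score), ties.method = "first")
      obj <- sum(score[cbind(assign, seq_len(n))])
      repeat {
        improved <- FALSE
        for (t_i in seq_len(n)) {
          from <- assign[t_i]
          if (sum(assign == from) <= 1L) next
          for (to in seq_len(k)) {
            if (to == from) next
            cand <- assign
            cand[t_i] <- to
            Tc <- Tm
            Tc[, from] <- update_template(X[, cand == from, drop = FALSE],
                                          Tm[, from])
            Tc[, to] <- update_template(X[, cand == to, drop = FALSE],
                                        Tm[, to])
            o <- objective_of(Tc, cand)
            if (o > obj + 1e-12) {
              assign <- cand; Tm <- Tc; obj <- o
              improved <- TRUE
              break
            }
          }
          if (improved) break
        }
        if (!improved) break
      }
      # settle back to an assignment-consistent fixed point
      for (it in seq_len(max_iter)) {
        C <- crossprod(Tm, X)
        score <- if (polarity == "invariant") C^2 else C
        new_assign <- max.col(t(score), ties.method = "first")
        if (all(new_assign == assign)) break
        assign <- new_assign
        for (j in seq_len(k))
          Tm[, j] <- update_template(X[, assign == j, drop = FALSE], Tm[, j])
      }
    }
    C <- crossprod(Tm, X)
    score <- if (polarity == "invariant") C^2 else C
    assign <- max.col(t(score), ties.method = "first")
    corr <- C[cbind(assign, seq_len(n))]
    list(templates = Tm, assign = assign, corr = corr,
         objective = sum(score[cbind(assign, seq_len(n))]),
         ev = mean(corr^2), objective_trace = obj_trace)
  }

  # k-means++-style seeding: subsequent seeds drawn with probability
  # proportional to their residual (unexplained) variance under the seeds
  # chosen so far, in the mode's own fit metric
  seed_init <- function() {
    init <- sample.int(n, 1L)
    if (k > 1L) for (j in 2:k) {
      C <- crossprod(X[, init, drop = FALSE], X)
      fitv <- if (polarity == "invariant") C^2 else pmax(C, 0)
      resid <- pmax(0, 1 - apply(fitv, 2L, max))
      resid[init] <- 0
      if (sum(resid) <= 0) resid <- as.numeric(!(seq_len(n) %in% init))
      init <- c(init, sample.int(n, 1L, prob = resid))
    }
    init
  }
  best <- local_seed(seed, {
    res <- NULL
    for (r in seq_len(n_restarts)) {
      fit <- run_once(seed_init())
      if (is.null(res) || fit$objective > res$objective) res <- fit
    }
    res
  })

  out <- microstate_set(best$templates, polarity = polarity)
  attr(out, "assignment") <- best$assign
  attr(out, "corr") <- best$corr
  attr(out, "objective") <- best$objective
  attr(out, "ev") <- best$ev
  attr(out, "objective_trace") <- best$objective_trace
  out
}

# Leading eigenvector of the outer-product sum M %*% t(M) (channels are few,
# so the symmetric eigenproblem is cheap regardless of cluster size); sign
# fixed so the largest-magnitude entry is positive.
principal_direction <- function(M) {
  if (ncol(M) == 1L) {
    v <- M[, 1L]
  } else {
    S <- tcrossprod(M)
    v <- eigen(S, symmetric = TRUE)$vectors[, 1L]
  }
  v <- v / sqrt(sum(v^2))
  if (v[which.max(abs(v))] < 0) v <- -v
  v
}
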