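#' Cluster-number selection by an aggregate of seven validity criteria
#'
#' Runs [modified_kmeans()] for every candidate k, scores each solution with
#' seven cluster-validity criteria (Silhouette, Davies-Bouldin negated, Dunn,
#' point-biserial, Calinski-Harabasz, Krzanowski-Lai, and the closed-form
#' cross-validation criterion negated — all oriented so larger is better),
#' and lets [meta_criterion()] pick the winning k by median vote.
#'
#' Distances between topographies are 1 - C^2 (invariant) or 1 - C (variant),
#' with C the spatial correlation. Pairwise-distance criteria (Silhouette,
#' Dunn, point-biserial) are computed on a seeded subsample of at most
#' `max_pairwise` points to bound memory; centroid-based criteria use all
#' points.
#'
#' @param maps channels x n matrix of topographies.
#' @param k_range inclusive candidate range, e.g. `c(1, 12)`. k = 1 never
#'   receives votes (most criteria are undefined there).
#' @param polarity `"invariant"` or `"variant"`.
#' @param n_restarts restarts per k.
#' @param seed integer seed.
#' @param max_pairwise subsample cap for pairwise criteria (default 1000).
#' @return list with `profile` (a `criterion_profile`), `solutions` (one
#'   `microstate_set` per k) and `best` (the solution at the selected k).
#' @export
select_k <- function(maps, k_range = c(1, 12),
                     polarity = c("invariant", "variant"),
                     n_restarts = 20, seed = 1, max_pairwise = 1000) {
  polarity <- match.arg(polarity)
  X <- normalize_maps(maps)
  n <- ncol(X); p <- nrow(X)
  ks <- seq.int(k_range[1], k_range[2])
  ks <- ks[ks >= 1 & ks <= n]
  if (length(ks) < 2L) stop("need at least 2 candidate k values")

  seeds <- local_seed(seed, sample.int(.Machine$integer.max, length(ks) + 1L))
  solutions <- vector("list", length(ks))
  names(solutions) <- as.character(ks)
  for (i in seq_along(ks))
    solutions[[i]] <- modified_kmeans(X, ks[i], polarity = polarity,
                                      n_restarts = n_restarts,
                                      seed = seeds[i])

  crit <- criterion_matrix(X, solutions, ks, polarity,
                           subsample_seed = seeds[length(seeds)],
                           max_pairwise = max_pairwise)
  profile <- meta_criterion(crit, k_values = ks)
  list(profile = profile,
       solutions = solutions,
       best = solutions[[as.character(profile$meta_k)]])
}

# Criterion scores (rows = criteria, larger is better) for precomputed
# solutions at candidate ks.
criterion_matrix <- function(X, solutions, ks, polarity,
                             subsample_seed = 1, max_pairwise = 1000) {
  n <- ncol(X); p <- nrow(X)
  invariant <- polarity == "invariant"

  # aligned Euclidean embedding: flip each sample to its assigned template's
  # polarity (invariant mode) so sums-of-squares criteria make sense
  aligned <- function(sol) {
    a <- attr(sol, "assignment"); C <- attr(sol, "corr")
    Xa <- X
    if (invariant) {
      fl <- C < 0
      Xa[, fl] <- -Xa[, fl]
    }
    list(X = Xa, assign = a)
  }

  # within-cluster sum of squares in the aligned embedding
  wss <- vapply(seq_along(ks), function(i) {
    al <- aligned(solutions[[i]])
    w <- 0
    for (j in unique(al$assign)) {
      M <- al$X[, al$assign == j, drop = FALSE]
      ctr <- rowMeans(M)
      w <- w + sum(sweep(M, 1L, ctr)^2)
    }
    w
  }, numeric(1))

  sub <- if (n > max_pairwise)
    local_seed(subsample_seed, sort(sample.int(n, max_pairwise)))
  else seq_len(n)
  Cs <- crossprod(X[, sub, drop = FALSE])
  D <- if (invariant) 1 - Cs^2 else 1 - Cs
  D[D < 0] <- 0
  diag(D) <- 0

  crit <- matrix(NA_real_, 7L, length(ks),
                 dimnames = list(c("silhouette", "neg_davies_bouldin", "dunn",
                                   "point_biserial", "calinski_harabasz",
                                   "krzanowski_lai", "neg_cross_validation"),
                                 as.character(ks)))
  for (i in seq_along(ks)) {
    k <- ks[i]
    sol <- solutions[[i]]
    a_full <- attr(sol, "assignment")
    a <- a_full[sub]
    corr <- attr(sol, "corr")
    Tm <- sol$maps
    kk <- length(unique(a_full))
    if (kk < k) next   # degenerate solution (collapsed clusters): disqualify

    if (k >= 2L) {
      crit["silhouette", i] <- mean_silhouette(D, a)
      crit["neg_davies_bouldin", i] <- -davies_bouldin(X, a_full, Tm, invariant)
      crit["dunn", i] <- dunn_index(D, a)
      crit["point_biserial", i] <- point_biserial(D, a)
      al <- aligned(sol)
      crit["calinski_harabasz", i] <-
        calinski_harabasz(al$X, al$assign, wss[i])
    }
    if (k < p - 1L)
      crit["neg_cross_validation", i] <-
        -mean(1 - corr^2) * ((p - 1) / (p - 1 - k))^2
  }
  # Krzanowski-Lai needs W at k-1 and k+1 (all three non-degenerate)
  degen <- vapply(seq_along(ks), function(i)
    length(unique(attr(solutions[[i]], "assignment"))) < ks[i], logical(1))
  for (i in seq_along(ks)) {
    k <- ks[i]
    if (i == 1L || i == length(ks) || k < 2L) next
    if (any(degen[(i - 1L):(i + 1L)])) next
    diff_k <- (k - 1)^(2 / p) * wss[i - 1L] - k^(2 / p) * wss[i]
    diff_k1 <- k^(2 / p) * wss[i] - (k + 1)^(2 / p) * wss[i + 1L]
    if (abs(diff_k1) > 1e-12)
      crit["krzanowski_lai", i] <- abs(diff_k) / abs(diff_k1)
  }
  crit
}

mean_silhouette <- function(D, a) {
  n <- length(a)
  lev <- sort(unique(a))
  ind <- vapply(lev, function(j) as.numeric(a == j), numeric(n))
  sums <- D %*% ind                       # n x k: total distance to cluster j
  sizes <- colSums(ind)
  j <- match(a, lev)
  own <- cbind(seq_len(n), j)
  a_t <- sums[own] / (sizes[j] - 1)       # Inf-safe below for singletons
  means <- sweep(sums, 2L, sizes, "/")
  means[own] <- Inf
  b_t <- do.call(pmin, lapply(seq_along(lev), function(c) means[, c]))
  denom <- pmax(a_t, b_t)
  s <- ifelse(denom > 0, (b_t - a_t) / denom, 0)
  s[sizes[j] <= 1] <- 0
  mean(s)
}

davies_bouldin <- function(X, a, Tm, invariant) {
  lev <- sort(unique(a))
  k <- length(lev)
  dist_pt <- function(C) if (invariant) 1 - C^2 else 1 - C
  S <- vapply(seq_along(lev), function(j) {
    M <- X[, a == lev[j], drop = FALSE]
    mean(dist_pt(crossprod(Tm[, lev[j], drop = FALSE], M)))
  }, numeric(1))
  Ct <- crossprod(Tm[, lev, drop = FALSE])
  M <- dist_pt(Ct)
  r <- numeric(k)
  for (i in seq_len(k)) {
    ratio <- (S[i] + S[-i]) / pmax(M[i, -i], 1e-12)
    r[i] <- max(ratio)
  }
  mean(r)
}

dunn_index <- function(D, a) {
  lev <- sort(unique(a))
  diam <- max(vapply(lev, function(j) {
    d <- D[a == j, a == j, drop = FALSE]
    if (length(d) <= 1) 0 else max(d)
  }, numeric(1)))
  between <- outer(a, a, `!=`)
  if (!any(between) || diam <= 0) return(NA_real_)
  min(D[between]) / diam
}

point_biserial <- function(D, a) {
  same <- outer(a, a, `==`)
  ut <- upper.tri(D)
  d <- D[ut]; between <- as.numeric(!same[ut])
  if (stats::sd(d) == 0 || stats::sd(between) == 0) return(NA_real_)
  stats::cor(d, between)
}

calinski_harabasz <- function(Xa, a, W) {
  n <- ncol(Xa)
  lev <- sort(unique(a))
  k <- length(lev)
  if (k < 2L || n <= k) return(NA_real_)
  m <- rowMeans(Xa)
  B <- 0
  for (j in lev) {
    M <- Xa[, a == j, drop = FALSE]
    B <- B + ncol(M) * sum((rowMeans(M) - m)^2)
  }
  if (W <= 0) return(NA_real_)
  (B / (k - 1)) / (W / (n - k))
}

#' Meta-criterion: median vote over cluster-validity criteria
#'
#' Every criterion votes for its best k (larger score is better); the selected
#' k is the median of the votes, with ties broken toward the smaller k (lower
#' median). Criteria that are constant across k, or entirely undefined,
#' abstain. k = 1 is excluded from voting.
#'
#' @param criterion_matrix criteria x k matrix of scores, larger = better;
#'   column names give k unless `k_values` is supplied.
#' @param k_values integer candidate ks matching the columns.
#' @return object of class `"criterion_profile"`: list with `k_values`,
#'   `criterion_matrix`, `votes` (named per criterion, NA = abstained) and
#'   `meta_k`.
#' @export
meta_criterion <- function(criterion_matrix, k_values = NULL) {
  cm <- as.matrix(criterion_matrix)
  if (is.null(k_values)) k_values <- as.integer(colnames(cm))
  if (length(k_values) != ncol(cm) || anyNA(k_values))
    stop("k_values must match criterion matrix columns")
  if (ncol(cm) < 2L || nrow(cm) < 2L)
    stop("need at least 2 candidate k values and 2 criteria")
  votable <- k_values >= 2L
  votes <- apply(cm, 1L, function(row) {
    r <- row[votable]
    ok <- is.finite(r)
    if (sum(ok) == 0L) return(NA_integer_)
    # numerically constant across >1 candidates carries no information
    if (sum(ok) > 1L &&
        max(r[ok]) - min(r[ok]) <= 1e-10 * max(abs(r[ok]), 1))
      return(NA_integer_)
    k_values[votable][which.max(replace(r, !ok, -Inf))]
  })
  v <- votes[!is.na(votes)]
  if (length(v) == 0L) stop("all criteria abstained; cannot select k")
  sv <- sort(v)
  meta_k <- sv[ceiling(length(sv) / 2)]    # lower median: ties to smaller k
  structure(list(k_values = k_values, criterion_matrix = cm,
                 votes = votes, meta_k = as.integer(meta_k)),
            class = "criterion_profile")
}

#' @export
print.criterion_profile <- function(x, ...) {
  cat(sprintf("<criterion_profile: k in [%d, %d], meta_k = %d>\n",
              min(x$k_values), max(x$k_values), x$meta_k))
  print(x$votes)
  invisible(x)
}

#' Resampled clustering of GFP-peak topographies
#'
#' The individual-level stage of the two-stage scheme: each of `n_epochs`
#' resampling epochs draws `n_samples_per_epoch` topographies without
#' replacement, clusters them at every candidate k, and keeps the solution at
#' the epoch's meta-criterion k. Rest-side defaults follow the study design
#' (50 epochs of 833 subsamples, k 1-12).
#'
#' @param peak_maps channels x n matrix (e.g. GFP-peak topographies).
#' @param n_epochs resampling epochs (default 50).
#' @param n_samples_per_epoch subsample size (default 833).
#' @param k_range candidate k range (default `c(1, 12)`).
#' @param n_restarts restarts per k per epoch (default 50).
#' @param seed integer seed; output is bit-for-bit reproducible.
#' @param polarity `"invariant"` or `"variant"`.
#' @return list of `n_epochs` winning `microstate_set`s, each with its
#'   epoch's `criterion_profile` attached as attribute `"profile"`.
#' @export
resample_cluster <- function(peak_maps, n_epochs = 50,
                             n_samples_per_epoch = 833,
                             k_range = c(1, 12), n_restarts = 50, seed = 1,
                             polarity = c("invariant", "variant")) {
  polarity <- match.arg(polarity)
  X <- as.matrix(peak_maps)
  n <- ncol(X)
  if (n_samples_per_epoch > n)
    stop("n_samples_per_epoch exceeds available topographies")
  if (n_restarts < 1) stop("n_restarts must be >= 1")
  plan <- local_seed(seed, list(
    idx = replicate(n_epochs, sample.int(n, n_samples_per_epoch),
                    simplify = FALSE),
    seeds = sample.int(.Machine$integer.max, n_epochs)))
  out <- vector("list", n_epochs)
  for (e in seq_len(n_epochs)) {
    sel <- select_k(X[, plan$idx[[e]], drop = FALSE], k_range = k_range,
                    polarity = polarity, n_restarts = n_restarts,
                    seed = plan$seeds[e])
    win <- sel$best
    attr(win, "profile") <- sel$profile
    out[[e]] <- win
  }
  out
}

#' Group-level aggregation of individual microstate sets
#'
#' Stage 2 pools the template maps of all individual winning sets and, in
#' each of `n_epochs` epochs, clusters the maps of `n_sets` randomly drawn
#' sets (meta-criterion k per epoch). Stage 3 pools the stage-2 winners' maps
#' and runs one final clustering with meta-criterion selection. Defaults
#' mirror the study design (100 epochs x 1000 sets, k 1-15, 100 restarts).
#'
#' @param individual_sets list of `microstate_set`s (all participants' epoch
#'   winners pooled).
#' @param n_epochs,n_sets stage-2 resampling design.
#' @param k_range candidate k range for both stages (default `c(1, 15)`).
#' @param n_restarts restarts (default 100).
#' @param seed integer seed.
#' @param polarity `"invariant"` or `"variant"`.
#' @return group-level `microstate_set` with the final `criterion_profile`
#'   attached as attribute `"profile"`.
#' @export
group_aggregate <- function(individual_sets, n_epochs = 100, n_sets = 1000,
                            k_range = c(1, 15), n_restarts = 100, seed = 1,
                            polarity = c("invariant", "variant")) {
  polarity <- match.arg(polarity)
  if (length(individual_sets) == 0L) stop("no individual sets supplied")
  n_avail <- length(individual_sets)
  n_sets <- min(n_sets, n_avail)
  plan <- local_seed(seed, list(
    idx = replicate(n_epochs, sample.int(n_avail, n_sets), simplify = FALSE),
    seeds = sample.int(.Machine$integer.max, n_epochs + 1L)))
  stage2 <- vector("list", n_epochs)
  for (e in seq_len(n_epochs)) {
    pooled <- do.call(cbind, lapply(individual_sets[plan$idx[[e]]],
                                    function(s) s$maps))
    sel <- select_k(pooled, k_range = k_range, polarity = polarity,
                    n_restarts = n_restarts, seed = plan$seeds[e])
    stage2[[e]] <- sel$best
  }
  pooled <- do.call(cbind, lapply(stage2, function(s) s$maps))
  sel <- select_k(pooled, k_range = k_range, polarity = polarity,
                  n_restarts = n_restarts, seed = plan$seeds[n_epochs + 1L])
  out <- sel$best
  out$level <- "group"
  attr(out, "profile") <- sel$profile
  out
}
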