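# Shared fixtures, all built in code at test time.

# random average-referenced topography matrix
random_maps <- function(n_channels, n, seed = 1) {
  withr::with_seed(seed,
    average_reference(matrix(rnorm(n_channels * n), n_channels, n)))
}

# hand-built neighbor graph (arbitrary neighbor sets, for operator tests)
manual_graph <- function(neighbors) {
  structure(list(neighbors = neighbors, k = ncol(neighbors)),
            class = "neighbor_graph")
}

# complete graph on n channels (every other channel is a neighbor)
complete_graph <- function(n) {
  nb <- t(vapply(seq_len(n), function(i) setdiff(seq_len(n), i),
                 integer(n - 1L)))
  manual_graph(nb)
}

# segmentation object assembled directly, for arithmetic-level tests
make_seg <- function(labels, fit_corr, sr = 250, gfp_trace = NULL,
                     polarity = "invariant", analyzed = NULL) {
  n <- length(labels)
  k <- nrow(fit_corr)
  if (is.null(gfp_trace)) gfp_trace <- rep(1, n)
  if (is.null(analyzed)) analyzed <- rep(TRUE, n)
  corr <- rep(NA_real_, n)
  ok <- !is.na(labels)
  v <- fit_corr[cbind(labels[ok], which(ok))]
  corr[ok] <- if (polarity == "invariant") abs(v) else v
  structure(list(labels = as.integer(labels), corr = corr,
                 gfp_trace = gfp_trace, sr = sr,
                 time_ms = (seq_len(n) - 1) * 1000 / sr,
                 analyzed = analyzed, window = NULL, fit_corr = fit_corr,
                 polarity = polarity, k = k, min_corr = 0),
            class = "segmentation")
}

# enumerate all assignments of n items into exactly the labels 1..k that use
# every label at least once (brute-force clustering oracle support)
all_partitions <- function(n, k) {
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), n)))
  keep <- apply(grid, 1L, function(a) length(unique(a)) == k)
  grid <- grid[keep, , drop = FALSE]
  # canonical form: first occurrences in increasing label order
  canon <- apply(grid, 1L, function(a)
    paste(match(a, unique(a)), collapse = ","))
  grid[!duplicated(canon), , drop = FALSE]
}

# brute-force optimum of the modified k-means objective over all partitions
brute_force_kmeans <- function(X, k, polarity = "invariant") {
  X <- microstatr:::normalize_maps(X)
  parts <- all_partitions(ncol(X), k)
  best <- -Inf
  for (r in seq_len(nrow(parts))) {
    a <- parts[r, ]
    obj <- 0
    for (j in seq_len(k)) {
      M <- X[, a == j, drop = FALSE]
      if (polarity == "invariant") {
        tpl <- microstatr:::principal_direction(M)
        obj <- obj + sum(crossprod(tpl, M)^2)
      } else {
        tpl <- rowMeans(M)
        nt <- sqrt(sum(tpl^2))
        if (nt == 0) next
        tpl <- tpl / nt
        obj <- obj + sum(crossprod(tpl, M))
      }
    }
    if (obj > best) best <- obj
  }
  best
}

# greedy one-to-one matching of recovered templates to planted maps by
# absolute spatial correlation; returns the matched correlations
match_maps <- function(recovered, planted) {
  C <- abs(crossprod(recovered, planted))
  out <- numeric(ncol(planted))
  for (i in seq_len(ncol(planted))) {
    idx <- arrayInd(which.max(C), dim(C))
    out[idx[2]] <- C[idx[1], idx[2]]
    C[idx[1], ] <- -Inf
    C[, idx[2]] <- -Inf
  }
  out
}
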