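#' Read a channel adjacency graph
#'
#' @param path YAML file with fields `n_channels` and `edges` (list of
#'   two-element channel index pairs); defaults to the packaged illustrative
#'   44-channel layout.
#' @return Symmetric, irreflexive logical adjacency matrix.
#' @export
read_adjacency <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "adjacency.yaml", package = "natfnirs",
                        mustWork = TRUE)
  y <- yaml::read_yaml(path)
  n <- as.integer(y$n_channels)
  adj <- matrix(FALSE, n, n)
  for (e in y$edges) {
    assert_that(length(e) == 2 && all(e >= 1) && all(e <= n),
                "bad edge in adjacency file")
    adj[e[1], e[2]] <- TRUE
    adj[e[2], e[1]] <- TRUE
  }
  diag(adj) <- FALSE
  adj
}

#' Form supra-threshold clusters on the channel graph
#'
#' Connected components (via the channel adjacency) of the set of channels
#' whose t-value exceeds the cluster-forming threshold; the cluster mass is
#' the sum of member t-values. One-sided: only positive excursions form
#' clusters.
#'
#' @param tvals Per-channel t-values (`NA` = untestable channel).
#' @param adjacency Symmetric logical adjacency matrix.
#' @param threshold Cluster-forming threshold (t > 2.0 in the protocol).
#' @return List of clusters, each `list(channels, mass)`, sorted by
#'   decreasing mass; empty list when nothing is supra-threshold.
#' @export
form_clusters <- function(tvals, adjacency, threshold = 2.0) {
  assert_that(nrow(adjacency) == length(tvals),
              "adjacency size does not match the t vector")
  sup <- which(!is.na(tvals) & tvals > threshold)
  if (!length(sup)) return(list())
  # connected components of the supra-threshold subgraph (breadth-first)
  sub <- adjacency[sup, sup, drop = FALSE]
  m <- length(sup)
  comp <- integer(m)
  k <- 0L
  for (s in seq_len(m)) {
    if (comp[s]) next
    k <- k + 1L
    frontier <- s
    comp[s] <- k
    while (length(frontier)) {
      reach <- colSums(matrix(sub[frontier, ], nrow = length(frontier)))
      nb <- which(reach > 0)
      nb <- nb[comp[nb] == 0L]
      comp[nb] <- k
      frontier <- nb
    }
  }
  out <- lapply(seq_len(k), function(kk) {
    ch <- sup[comp == kk]
    list(channels = ch, mass = sum(tvals[ch]))
  })
  out[order(vapply(out, `[[`, numeric(1), "mass"), decreasing = TRUE)]
}

# column t statistics of a participants x channels matrix (greater tail),
# degenerate columns -> 0
col_tstats <- function(X) {
  n <- nrow(X)
  m <- colMeans(X)
  v <- (colSums(X^2) - n * m^2) / (n - 1)
  t <- ifelse(v > 0, m / sqrt(v / n), 0)
  t
}

#' Sign-flip null distribution of the maximum cluster mass
#'
#' Each iteration flips whole participants with probability one half (the
#' full channel vector flips together, preserving spatial correlation),
#' recomputes channel t-values and cluster masses, and records the maximum
#' mass (zero when no cluster forms). When the statistic involves a
#' data-dependent peak window, pass `rminus` so a flipped participant
#' contributes `-rminus[i, ]` — the peak-window statistic of the
#' sign-flipped trace — and the selection step is thereby recomputed inside
#' every iteration. With `2^n <= 4096` all sign patterns are enumerated
#' exhaustively instead of sampled.
#'
#' @param rplus Participants x channels response matrix (unflipped).
#' @param rminus Response matrix of the sign-flipped traces; defaults to
#'   `rplus` (plain response-vector flipping).
#' @param adjacency Adjacency matrix.
#' @param threshold Cluster-forming threshold.
#' @param n_perm Monte-Carlo iterations (ignored in exhaustive mode).
#' @param seed RNG seed for the Monte-Carlo mode.
#' @param exhaustive Force (`TRUE`)/suppress (`FALSE`) exhaustive
#'   enumeration; default auto.
#' @return List with `max_mass` (the null draws), `exhaustive`, `n`.
#' @export
signflip_null <- function(rplus, rminus = rplus, adjacency, threshold = 2.0,
                          n_perm = 1000, seed = 1L, exhaustive = NULL) {
  n <- nrow(rplus)
  assert_that(n >= 2, "need at least two participants")
  assert_that(all(dim(rplus) == dim(rminus)), "rplus/rminus shape mismatch")
  if (any(apply(rplus, 2, function(v) stats::sd(v, na.rm = TRUE)) == 0, na.rm = TRUE))
    stopf("degenerate (zero-variance) channel responses: sign-flip null undefined")
  # missing responses cannot enter the vectorised t; require complete rows
  rplus[is.na(rplus)] <- 0
  rminus[is.na(rminus)] <- 0
  if (is.null(exhaustive)) exhaustive <- 2^n <= 4096
  flips <- if (exhaustive) {
    m <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
    dimnames(m) <- NULL
    m
  } else {
    with_seed(derive_seed(seed, 4L),
              matrix(stats::runif(n_perm * n) < 0.5, n_perm, n))
  }
  max_mass <- apply(flips, 1, function(fl) {
    X <- rplus
    if (any(fl)) X[fl, ] <- -rminus[fl, , drop = FALSE]
    cl <- form_clusters(col_tstats(X), adjacency, threshold)
    if (length(cl)) cl[[1]]$mass else 0
  })
  list(max_mass = as.numeric(max_mass), exhaustive = exhaustive,
       n = nrow(flips))
}

#' Permutation p-value of an observed cluster mass
#'
#' Add-one convention: `p = (1 + #\{null >= observed\}) / (1 + n_perm)`.
#'
#' @param observed_mass Observed cluster mass.
#' @param null Vector of null maximum masses.
#' @export
cluster_pvalue <- function(observed_mass, null) {
  assert_that(length(null) > 0, "empty null distribution")
  (1 + sum(null >= observed_mass)) / (1 + length(null))
}

#' Cluster-mass sign-flip permutation test
#'
#' One-sided cluster test of an HbO increase over the channel graph:
#' channel t-values are thresholded at `threshold`, spatially adjacent
#' supra-threshold channels are grouped, each cluster's mass is the sum of
#' its t-values, and significance is assessed against the max-mass null
#' distribution built by randomly sign-flipping participants.
#'
#' Two flipping modes are available. `"trace"` (default) flips each
#' participant's block-average time course and recomputes the peak-window
#' response inside every iteration, which keeps the permutation test exact
#' even though the peak window is selected from the data. `"response"`
#' flips the already-extracted response vectors.
#'
#' @param x For `flip = "trace"`: a list of `attn_blocks`/`attn_blockavg`
#'   (one per participant). For `flip = "response"`: a participants x
#'   channels response matrix.
#' @param adjacency Adjacency matrix (see [read_adjacency()]).
#' @param params [epoch_params()] (trace mode).
#' @param threshold Cluster-forming threshold.
#' @param n_perm Permutation count.
#' @param seed RNG seed.
#' @param flip `"trace"` or `"response"`.
#' @param exhaustive Passed to [signflip_null()] (default auto).
#' @return Object of class `cluster_test`: `t` (observed channel t-values),
#'   `clusters` (with per-cluster `p`), `null_max_mass`, `n_perm`,
#'   `exhaustive`.
#' @export
cluster_permutation_test <- function(x, adjacency, params = epoch_params(),
                                     threshold = 2.0, n_perm = 1000,
                                     seed = 1L, flip = c("trace", "response"),
                                     exhaustive = NULL) {
  flip <- match.arg(flip)
  if (flip == "trace") {
    avgs <- lapply(x, function(b)
      if (inherits(b, "attn_blocks")) block_average(b) else b)
    avgs <- Filter(function(b) b$n_blocks > 0, avgs)
    direction <- peak_direction(params, "hbo")
    resp_of <- function(avg, sgn) {
      tr <- sgn * avg$hbo
      vapply(seq_len(nrow(tr)), function(ch) {
        if (!avg$channel_ok[ch]) return(NA_real_)
        peak_response_trace(tr[ch, ], avg$rel_time, params, direction)
      }, numeric(1))
    }
    rplus <- t(vapply(avgs, resp_of, numeric(nrow(avgs[[1]]$hbo)), sgn = 1))
    # statistic of a flipped trace: -(peak response of the negated series);
    # with the sign-symmetric "abs" peak this equals rplus exactly
    rminus <- if (direction == "abs") rplus else
      -t(vapply(avgs, resp_of, numeric(nrow(avgs[[1]]$hbo)), sgn = -1))
  } else {
    rplus <- x
    rminus <- x
  }
  tvals <- col_tstats(ifelse(is.na(rplus), 0, rplus))
  tvals[colSums(!is.na(rplus)) < 2] <- NA
  clusters <- form_clusters(tvals, adjacency, threshold)
  null <- signflip_null(rplus, rminus, adjacency, threshold, n_perm, seed,
                        exhaustive = exhaustive)
  clusters <- lapply(clusters, function(cl) {
    cl$p <- cluster_pvalue(cl$mass, null$max_mass)
    cl
  })
  structure(list(t = tvals, clusters = clusters,
                 null_max_mass = null$max_mass, n_perm = null$n,
                 exhaustive = null$exhaustive, threshold = threshold),
            class = "cluster_test")
}

#' @export
print.cluster_test <- function(x, ...) {
  cat(sprintf("<cluster_test> threshold t > %g, %d permutations%s\n",
              x$threshold, x$n_perm,
              if (x$exhaustive) " (exhaustive)" else ""))
  if (!length(x$clusters)) {
    cat("  no supra-threshold cluster\n")
  } else {
    for (cl in x$clusters) {
      cat(sprintf("  channels {%s}: mass %.2f, p = %.4g\n",
                  paste(cl$channels, collapse = ", "), cl$mass, cl$p))
    }
  }
  invisible(x)
}
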