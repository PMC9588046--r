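# Independent brute-force oracles. These deliberately share no code with the
# implementation: the clustering oracle works on raw points via the textbook
# definition (core set + connected components of the core graph), prefix
# means are recomputed by filtering, and softmax values come from the
# unnormalized closed form.

# DBSCAN oracle: returns list(labels, border_candidates). Border points
# adjacent to several clusters are genuinely ambiguous, so the comparison
# checks membership in the candidate set instead of exact equality there.
dbscan_oracle <- function(points, eps, min_pts) {
  pts <- as.matrix(points)
  n <- nrow(pts)
  if (n == 0) return(list(labels = integer(0), candidates = list()))
  d <- as.matrix(stats::dist(pts))
  within <- d <= eps + 1e-300
  core <- rowSums(within) >= min_pts
  labels <- integer(n)
  candidates <- vector("list", n)
  if (any(core)) {
    core_idx <- which(core)
    adj <- within[core_idx, core_idx, drop = FALSE]
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                             diag = FALSE)
    comp <- igraph::components(g)$membership
    labels[core_idx] <- comp
    for (i in which(!core)) {
      adj_cores <- core_idx[within[i, core_idx]]
      if (length(adj_cores) > 0) {
        cand <- unique(labels[adj_cores])
        labels[i] <- cand[1]
        candidates[[i]] <- cand
      }
    }
  }
  list(labels = labels, candidates = candidates)
}

# compare an implementation labeling to the oracle up to label permutation
expect_dbscan_equivalent <- function(impl, oracle_out) {
  oracle <- oracle_out$labels
  expect_identical(impl == 0L, oracle == 0L) # same noise set
  if (all(impl == 0L)) return(invisible(TRUE))
  # bijection between cluster ids, built from (any) points; border points with
  # several candidate clusters are checked by membership below
  fixed <- which(impl > 0 &
                   vapply(seq_along(impl), function(i) {
                     is.null(oracle_out$candidates[[i]]) ||
                       length(oracle_out$candidates[[i]]) == 1
                   }, logical(1)))
  map <- tapply(oracle[fixed], impl[fixed], function(x) unique(x))
  expect_true(all(lengths(map) == 1),
              label = "each implementation cluster maps to one oracle cluster")
  map <- vapply(map, identity, numeric(1))
  expect_equal(length(unique(map)), length(map),
               label = "cluster mapping is a bijection")
  for (i in seq_along(impl)) {
    cand <- oracle_out$candidates[[i]]
    if (!is.null(cand) && length(cand) > 1) {
      expect_true(map[[as.character(impl[i])]] %in% cand)
    }
  }
  invisible(TRUE)
}

# strict-prefix leave-one-out mean by direct filtering
prefix_mean_oracle <- function(reviews, t, exclude_id = NULL) {
  keep <- reviews$timestamp < t
  if (!is.null(exclude_id)) keep <- keep & reviews$review_id != exclude_id
  if (!any(keep)) return(list(raw_prior_mean = NA_real_, n_reviews = 0L))
  list(raw_prior_mean = mean(reviews$stars[keep]), n_reviews = sum(keep))
}
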