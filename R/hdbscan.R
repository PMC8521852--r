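# Hierarchical density-based clustering (HDBSCAN-style) on a precomputed
# distance matrix. The algorithm follows the standard construction: core
# distances smooth the metric into a mutual-reachability distance, a minimum
# spanning tree gives the single-linkage hierarchy of density levels, the
# hierarchy is condensed with a minimum cluster size, and the flat clustering
# maximizing total stability (excess of mass) is extracted. Points never
# inside a selected cluster are labeled noise (-1).

#' Density-based hierarchical clustering with noise
#'
#' Groups observations lying in dense regions while marking observations in
#' sparse regions as noise. Works on any precomputed distance matrix; the
#' density scale at each point is its core distance (distance to the
#' `min_samples`-th nearest neighbour, the point itself included), clusters
#' are extracted from the condensed single-linkage hierarchy of the
#' mutual-reachability distance by maximizing stability, and a cluster must
#' contain at least `min_cluster_size` points.
#'
#' @param d Symmetric distance matrix (or `dist`).
#' @param min_cluster_size Minimum number of points a cluster may contain
#'   (>= 2).
#' @param min_samples Neighbourhood size for core distances; defaults to
#'   `min_cluster_size`.
#' @return Integer labels, `1..k` for clusters and `-1` for noise.
#' @export
hdbscan_dist <- function(d, min_cluster_size, min_samples = min_cluster_size) {
  d <- as.matrix(d)
  n <- nrow(d)
  min_cluster_size <- max(2L, as.integer(min_cluster_size))
  min_samples <- max(2L, min(as.integer(min_samples), n))
  if (n < 2 * min_cluster_size) return(rep(-1L, n))

  core <- vapply(seq_len(n), function(i) sort(d[i, ])[min_samples], numeric(1))
  mr <- pmax(d, outer(core, core, pmax))

  # Prim's MST on the mutual-reachability graph
  in_tree <- logical(n)
  best_w <- rep(Inf, n)
  best_from <- integer(n)
  in_tree[1] <- TRUE
  best_w <- mr[1, ]
  best_from[] <- 1L
  edges <- matrix(0, n - 1, 3)            # from, to, weight
  for (e in seq_len(n - 1)) {
    cand <- which(!in_tree)
    v <- cand[which.min(best_w[cand])]
    edges[e, ] <- c(best_from[v], v, best_w[v])
    in_tree[v] <- TRUE
    upd <- !in_tree & mr[v, ] < best_w
    best_w[upd] <- mr[v, upd]
    best_from[upd] <- v
  }
  edges <- edges[order(edges[, 3]), , drop = FALSE]

  # single-linkage hierarchy via union-find; internal nodes n+1 .. 2n-1
  parent_uf <- seq_len(2L * n - 1L)
  find <- function(i) {
    while (parent_uf[i] != i) i <- parent_uf[i]
    i
  }
  comp_node <- seq_len(n)                 # current tree node of each root
  child_l <- integer(2L * n - 1L); child_r <- integer(2L * n - 1L)
  height <- numeric(2L * n - 1L)
  size <- c(rep(1L, n), integer(n - 1L))
  nxt <- n
  for (e in seq_len(n - 1)) {
    ra <- find(edges[e, 1]); rb <- find(edges[e, 2])
    na <- comp_node[ra]; nb <- comp_node[rb]
    nxt <- nxt + 1L
    child_l[nxt] <- na; child_r[nxt] <- nb
    height[nxt] <- edges[e, 3]
    size[nxt] <- size[na] + size[nb]
    parent_uf[ra] <- nxt; parent_uf[rb] <- nxt
    parent_uf[nxt] <- nxt
    comp_node[nxt] <- nxt
  }
  root <- nxt

  subtree_points <- function(node) {
    out <- integer(0); stack <- node
    while (length(stack) > 0) {
      nd <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (nd <= n) out <- c(out, nd) else stack <- c(stack, child_l[nd], child_r[nd])
    }
    out
  }

  # condense the hierarchy: walk each cluster down from its birth node
  cl_parent <- integer(0); cl_birth <- numeric(0); cl_stab <- numeric(0)
  cl_children <- list()
  new_cluster <- function(parent, birth) {
    cl_parent[length(cl_parent) + 1L] <<- parent
    cl_birth[length(cl_birth) + 1L] <<- birth
    cl_stab[length(cl_stab) + 1L] <<- 0
    cl_children[[length(cl_parent)]] <<- integer(0)
    if (parent > 0) {
      cl_children[[parent]] <<- c(cl_children[[parent]], length(cl_parent))
    }
    length(cl_parent)
  }
  point_cluster <- integer(n)

  queue <- list(list(node = root, cid = new_cluster(0L, 0)))
  while (length(queue) > 0) {
    item <- queue[[length(queue)]]; queue[[length(queue)]] <- NULL
    node <- item$node; cid <- item$cid
    repeat {
      if (node <= n) {            # singleton branch: point leaves here
        point_cluster[node] <- cid
        break
      }
      lam <- 1 / max(height[node], 1e-12)
      a <- child_l[node]; b <- child_r[node]
      big_a <- size[a] >= min_cluster_size
      big_b <- size[b] >= min_cluster_size
      if (big_a && big_b) {       # true split: cluster dies, two children born
        cl_stab[cid] <- cl_stab[cid] + size[node] * (lam - cl_birth[cid])
        queue[[length(queue) + 1L]] <- list(node = a, cid = new_cluster(cid, lam))
        queue[[length(queue) + 1L]] <- list(node = b, cid = new_cluster(cid, lam))
        break
      }
      if (!big_a && !big_b) {     # cluster dissolves: all points leave
        pts <- subtree_points(node)
        point_cluster[pts] <- cid
        cl_stab[cid] <- cl_stab[cid] + length(pts) * (lam - cl_birth[cid])
        break
      }
      small <- if (big_a) b else a
      pts <- subtree_points(small)
      point_cluster[pts] <- cid   # side branch falls out as in-cluster noise
      cl_stab[cid] <- cl_stab[cid] + length(pts) * (lam - cl_birth[cid])
      node <- if (big_a) a else b
    }
  }

  n_cl <- length(cl_parent)
  if (n_cl <= 1) return(rep(-1L, n))

  # excess-of-mass selection; the root (id 1) is never selected
  selected <- logical(n_cl)
  score <- numeric(n_cl)
  for (cid in rev(seq_len(n_cl))) {
    kids <- cl_children[[cid]]
    if (length(kids) == 0) {
      selected[cid] <- cid != 1L
      score[cid] <- cl_stab[cid]
    } else if (cid != 1L && cl_stab[cid] >= sum(score[kids])) {
      selected[cid] <- TRUE
      score[cid] <- cl_stab[cid]
      deselect <- kids
      while (length(deselect) > 0) {
        selected[deselect] <- FALSE
        deselect <- unlist(cl_children[deselect])
      }
    } else {
      score[cid] <- sum(score[kids])
    }
  }

  labels <- rep(-1L, n)
  sel_ids <- which(selected)
  if (length(sel_ids) == 0) return(labels)
  relabel <- setNames(seq_along(sel_ids), sel_ids)
  for (p in seq_len(n)) {
    cid <- point_cluster[p]
    while (cid > 0 && !selected[cid]) cid <- cl_parent[cid]
    if (cid > 0) labels[p] <- relabel[[as.character(cid)]]
  }
  labels
}

#' Pearson-correlation distance between proportion rows
#'
#' 1 minus the Pearson correlation of each pair of rows. Rows constant
#' across columns (e.g. a user with exactly equal day-type proportions)
#' have undefined correlation and are placed at distance 1 from everything.
#'
#' @param x Numeric matrix, rows compared.
#' @return A symmetric distance matrix with zero diagonal.
#' @export
correlation_distance <- function(x) {
  xc <- x - rowMeans(x)
  nrm <- sqrt(rowSums(xc^2))
  r <- (xc %*% t(xc)) / outer(nrm, nrm)
  r[!is.finite(r)] <- 0
  r <- pmin(pmax(r, -1), 1)
  d <- 1 - r
  diag(d) <- 0
  d
}
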