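#' Weighted modularity of a partition
#'
#' `Q = sum_c [ W_c / m - gamma * (K_c / 2m)^2 ]` where `W_c` is the
#' intra-community edge weight (each edge once, self-loops once), `K_c` the
#' summed weighted degree of the community (self-loops counting twice),
#' `m` the total edge weight, and `gamma` the resolution. A graph without
#' edges has `Q = 0` by convention.
#'
#' @param graph an undirected `igraph`; edge attribute `weight` is used if
#'   present, otherwise unit weights
#' @param membership integer/character vector of community labels, one per
#'   vertex
#' @param resolution resolution parameter `gamma`
#' @return numeric modularity
#' @export
modularity_weighted <- function(graph, membership, resolution = 1.0) {
  stopifnot(length(membership) == igraph::vcount(graph))
  w <- igraph::edge_attr(graph, "weight")
  if (is.null(w)) w <- rep(1, igraph::ecount(graph))
  if (length(w) == 0L || sum(w) == 0) return(0)
  el <- igraph::as_edgelist(graph, names = FALSE)
  m <- sum(w)
  comm <- as.integer(factor(membership))
  intra <- comm[el[, 1L]] == comm[el[, 2L]]
  W_c <- tapply(w[intra], comm[el[intra, 1L]], sum)
  deg <- numeric(igraph::vcount(graph))
  for (e in seq_along(w)) {
    deg[el[e, 1L]] <- deg[el[e, 1L]] + w[e]
    deg[el[e, 2L]] <- deg[el[e, 2L]] + w[e]
  }
  K_c <- tapply(deg, comm, sum)
  sum(W_c / m) - resolution * sum((K_c / (2 * m))^2)
}

# One local-moving + aggregation round on an edge-list representation.
# Nodes 1..n; `self` holds self-loop weight per node (aggregated intra
# weight). Returns membership, whether any node moved, and the Q trace
# (one value per completed sweep).
.louvain_level <- function(n, ei, ej, ew, self, gamma, order) {
  m <- sum(ew) + sum(self)
  k <- numeric(n)
  for (e in seq_along(ew)) {
    k[ei[e]] <- k[ei[e]] + ew[e]
    k[ej[e]] <- k[ej[e]] + ew[e]
  }
  k <- k + 2 * self
  nbr <- vector("list", n)
  nbw <- vector("list", n)
  for (v in seq_len(n)) {
    nbr[[v]] <- integer(0)
    nbw[[v]] <- numeric(0)
  }
  for (e in seq_along(ew)) {
    nbr[[ei[e]]] <- c(nbr[[ei[e]]], ej[e])
    nbw[[ei[e]]] <- c(nbw[[ei[e]]], ew[e])
    nbr[[ej[e]]] <- c(nbr[[ej[e]]], ei[e])
    nbw[[ej[e]]] <- c(nbw[[ej[e]]], ew[e])
  }
  comm <- seq_len(n)
  tot <- k
  q_of <- function() {
    cf <- comm
    intra <- sum(ew[cf[ei] == cf[ej]]) + sum(self)
    K_c <- tapply(k, cf, sum)
    intra / m - gamma * sum((K_c / (2 * m))^2)
  }
  trace <- numeric(0)
  moved_any <- FALSE
  repeat {
    moved <- FALSE
    for (v in order) {
      c_old <- comm[v]
      tot[c_old] <- tot[c_old] - k[v]
      # weight from v to each neighbouring community (self-loop excluded:
      # it stays internal wherever v goes, so it cancels in the comparison)
      if (length(nbr[[v]])) {
        wvc <- tapply(nbw[[v]], comm[nbr[[v]]], sum)
        cand <- as.integer(names(wvc))
        wvc <- as.numeric(wvc)
      } else {
        wvc <- numeric(0)
        cand <- integer(0)
      }
      if (!c_old %in% cand) {
        cand <- c(cand, c_old)
        wvc <- c(wvc, 0)
      }
      gain <- wvc / m - gamma * tot[cand] * k[v] / (2 * m^2)
      best <- max(gain)
      pick <- cand[gain >= best - 1e-13]
      c_new <- if (c_old %in% pick) c_old else min(pick)
      comm[v] <- c_new
      tot[c_new] <- tot[c_new] + k[v]
      if (c_new != c_old) {
        moved <- TRUE
        moved_any <- TRUE
      }
    }
    trace <- c(trace, q_of())
    if (!moved) break
  }
  list(membership = comm, moved = moved_any, trace = trace)
}

#' Louvain community detection on a weighted undirected graph
#'
#' Standard two-phase Louvain: greedy local moving of nodes between
#' communities to maximize weighted modularity (at the given resolution),
#' followed by aggregation of communities into supernodes, repeated until no
#' further gain. The node visiting order is shuffled by a seeded RNG, so a
#' fixed seed gives a byte-identical partition. Isolated nodes end up as
#' singleton communities.
#'
#' @param graph undirected `igraph`; edge attribute `weight` used if present
#' @param resolution resolution parameter (default 1)
#' @param seed integer seed for the node-order shuffle
#' @return a list with `membership` (integer vector named by vertex name,
#'   community ids 1..k), `modularity` (Q of the returned partition) and
#'   `q_trace` (Q after each completed local-moving sweep; non-decreasing)
#' @export
louvain_partition <- function(graph, resolution = 1.0, seed = 1L) {
  n <- igraph::vcount(graph)
  vnames <- igraph::V(graph)$name
  if (is.null(vnames)) vnames <- as.character(seq_len(n))
  if (n == 0L) {
    return(list(membership = stats::setNames(integer(0), character(0)),
                modularity = 0, q_trace = numeric(0)))
  }
  w <- igraph::edge_attr(graph, "weight")
  if (is.null(w)) w <- rep(1, igraph::ecount(graph))
  el <- igraph::as_edgelist(graph, names = FALSE)
  keep <- el[, 1L] != el[, 2L]
  ei <- el[keep, 1L]
  ej <- el[keep, 2L]
  ew <- w[keep]
  if (length(ew) == 0L || sum(ew) == 0) {
    memb <- stats::setNames(seq_len(n), vnames)
    return(list(membership = memb, modularity = 0, q_trace = numeric(0)))
  }
  rng <- .seeded_rng(seed)
  assign_orig <- seq_len(n)      # original node -> current community label
  cur_n <- n
  cur_ei <- ei; cur_ej <- ej; cur_ew <- ew
  cur_self <- numeric(n)
  q_trace <- numeric(0)
  repeat {
    order <- rng$shuffle(cur_n)
    lev <- .louvain_level(cur_n, cur_ei, cur_ej, cur_ew, cur_self,
                          resolution, order)
    q_trace <- c(q_trace, lev$trace)
    relab <- as.integer(factor(lev$membership))
    assign_orig <- relab[assign_orig]
    if (!lev$moved) break
    # aggregate: communities become supernodes
    nc <- max(relab)
    a <- relab[cur_ei]
    b <- relab[cur_ej]
    new_self <- tapply(c(cur_self, cur_ew[a == b]),
                       c(relab, a[a == b]), sum)
    cur_self <- numeric(nc)
    cur_self[as.integer(names(new_self))] <- new_self
    inter <- a != b
    if (any(inter)) {
      lo <- pmin(a[inter], b[inter])
      hi <- pmax(a[inter], b[inter])
      key <- paste(lo, hi)
      agg <- tapply(cur_ew[inter], key, sum)
      parts <- do.call(rbind, strsplit(names(agg), " ", fixed = TRUE))
      cur_ei <- as.integer(parts[, 1L])
      cur_ej <- as.integer(parts[, 2L])
      cur_ew <- as.numeric(agg)
    } else {
      cur_ei <- integer(0)
      cur_ej <- integer(0)
      cur_ew <- numeric(0)
    }
    cur_n <- nc
    if (cur_n == 1L) break
  }
  memb <- as.integer(factor(assign_orig, levels = unique(assign_orig)))
  final_q <- modularity_weighted(graph,
                                 memb, resolution = resolution)
  list(membership = stats::setNames(memb, vnames), modularity = final_q,
       q_trace = q_trace)
}
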