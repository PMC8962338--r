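# Topological descriptors: spectral moments of the property-weighted bond
# adjacency matrix, Kier-Hall simple/valence connectivity indices, and edge
# (bond) connectivity indices evaluated on the line graph.
#
# Subgraph enumeration is exact: connected o-edge subgraphs are enumerated
# once each with the ESU algorithm applied to the line graph (a set of edges
# is connected exactly when the corresponding line-graph vertex set induces a
# connected subgraph). Exactness is what lets brute-force oracles check every
# index in the test suite.

#' Property-weighted bond adjacency matrix
#'
#' Square matrix indexed by bonds: off-diagonal entry 1 when two bonds share
#' an atom; diagonal entry the bond weight
#' \eqn{w(i,j) = p_i/\delta_i + p_j/\delta_j} (atomic property over
#' heavy-atom degree, summed over the bond's two atoms). With
#' `property = "none"` the diagonal is zero.
#'
#' @param g a `mol_graph`.
#' @param property property code (see [assign_properties()]) or `"none"`.
#' @return `nB x nB` symmetric numeric matrix.
#' @export
#' @examples
#' bond_adjacency(parse_smiles("CCC"), "none")  # [[0,1],[1,0]]
bond_adjacency <- function(g, property = "none") {
  stopifnot(inherits(g, "mol_graph"), g$nB >= 1)
  nB <- g$nB
  B <- matrix(0, nB, nB)
  if (nB > 1) {
    for (a in seq_len(nB - 1)) {
      for (b in (a + 1):nB) {
        if (length(intersect(g$bonds[a, c("i", "j")],
                             g$bonds[b, c("i", "j")]))) {
          B[a, b] <- B[b, a] <- 1
        }
      }
    }
  }
  if (!identical(property, "none")) {
    p <- assign_properties(g, property)
    d <- g$degree
    w <- p[g$bonds[, "i"]] / d[g$bonds[, "i"]] +
         p[g$bonds[, "j"]] / d[g$bonds[, "j"]]
    diag(B) <- w
  }
  B
}

#' Spectral moment of a bond adjacency matrix
#'
#' Trace of the k-th matrix power; order 0 returns the matrix dimension (the
#' bond count nB).
#'
#' @param B matrix from [bond_adjacency()].
#' @param k non-negative integer order.
#' @return The spectral moment (a single number).
#' @export
spectral_moment <- function(B, k) {
  stopifnot(is.matrix(B), k >= 0, k == round(k))
  if (k == 0) return(nrow(B))
  M <- B
  if (k > 1) for (t in seq_len(k - 1)) M <- M %*% B
  sum(diag(M))
}

# ---- exact connected-subgraph enumeration (ESU) ----------------------------

# adjacency list from an edge matrix over nv vertices
edges_to_adj <- function(nv, edges) {
  adj <- rep(list(integer(0)), nv)
  if (nrow(edges)) {
    for (e in seq_len(nrow(edges))) {
      i <- edges[e, 1]; j <- edges[e, 2]
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
  }
  adj
}

# All connected vertex subsets of size k (each exactly once), ESU algorithm.
esu_subsets <- function(adj, k) {
  nv <- length(adj)
  out <- vector("list", 0L)
  if (k < 1 || nv < k) return(out)
  if (k == 1) return(lapply(seq_len(nv), identity))
  res <- new.env(parent = emptyenv())
  res$n <- 0L
  res$items <- vector("list", 64L)
  push <- function(sub) {
    res$n <- res$n + 1L
    if (res$n > length(res$items)) {
      res$items <- c(res$items, vector("list", length(res$items)))
    }
    res$items[[res$n]] <- sub
  }
  extend <- function(sub, ext, root, in_nbr) {
    if (length(sub) == k) { push(sub); return(invisible()) }
    while (length(ext)) {
      w <- ext[1]
      ext <- ext[-1]
      new_nbr <- in_nbr
      cand <- adj[[w]]
      excl <- cand[cand > root & !in_nbr[cand]]
      new_nbr[cand] <- TRUE
      extend(c(sub, w), c(ext, setdiff(excl, w)), root, new_nbr)
    }
    invisible()
  }
  for (v in seq_len(nv)) {
    in_nbr <- logical(nv)
    in_nbr[v] <- TRUE
    in_nbr[adj[[v]]] <- TRUE
    extend(v, adj[[v]][adj[[v]] > v], v, in_nbr)
  }
  res$items[seq_len(res$n)]
}

# line-graph structure of a graph given its edge matrix (cols i, j):
# vertices = edges of the input; edge list pairs edges sharing an endpoint
line_graph_edges <- function(edges) {
  ne <- nrow(edges)
  if (ne < 2) return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("i", "j"))))
  pairs <- utils::combn(ne, 2)
  share <- vapply(seq_len(ncol(pairs)), function(c) {
    a <- pairs[1, c]; b <- pairs[2, c]
    length(intersect(edges[a, 1:2], edges[b, 1:2])) > 0
  }, logical(1))
  m <- t(pairs[, share, drop = FALSE])
  colnames(m) <- c("i", "j")
  m
}

# classify a connected edge subset of a graph (edges given as endpoint
# matrix): Ch if it contains a cycle; else P (no branch vertex), C (branched,
# no degree-2 vertex), or PC (both)
classify_edge_subset <- function(edge_endpoints) {
  atoms <- unique(as.vector(edge_endpoints))
  ne <- nrow(edge_endpoints)
  if (ne >= length(atoms)) return("Ch")
  deg <- table(factor(as.vector(edge_endpoints), levels = atoms))
  if (max(deg) <= 2) "P"
  else if (!any(deg == 2)) "C"
  else "PC"
}

#' Enumerate connected subgraphs of a molecule by type and order
#'
#' Returns every connected subgraph with `o` bonds exactly once, classified by
#' the Kier-Hall rules: `Ch` (chain) contains a cycle; among acyclic
#' subgraphs, `P` (path) has no vertex of subgraph degree 3 or more, `C`
#' (cluster) has branching but no degree-2 vertex, and `PC` (path-cluster)
#' mixes both.
#'
#' @param g a `mol_graph`.
#' @param s subgraph type: `"P"`, `"C"`, `"PC"`, `"Ch"`, or `"all"`.
#' @param o order (number of bonds in the subgraph), >= 1.
#' @return List of integer vectors of bond indices (rows of `g$bonds`).
#' @export
#' @examples
#' length(enumerate_subgraphs(parse_smiles("CCCC"), "P", 2))  # 2
enumerate_subgraphs <- function(g, s = "all", o) {
  stopifnot(inherits(g, "mol_graph"), o >= 1)
  s <- match.arg(s, c("P", "C", "PC", "Ch", "all"))
  ladj <- edges_to_adj(g$nB, line_graph_edges(g$bonds))
  subs <- esu_subsets(ladj, o)
  if (identical(s, "all")) return(subs)
  keep <- vapply(subs, function(bi) {
    classify_edge_subset(g$bonds[bi, c("i", "j"), drop = FALSE]) == s
  }, logical(1))
  subs[keep]
}

#' Kier-Hall valence delta values
#'
#' \eqn{\delta^v = Z^v - h} for second-row atoms and
#' \eqn{(Z^v - h)/(Z - Z^v - 1)} beyond, with \eqn{Z^v} the valence-electron
#' count, \eqn{h} the attached hydrogens and \eqn{Z} the atomic number.
#'
#' @param g a `mol_graph`.
#' @return Numeric vector of valence deltas (one per heavy atom).
#' @export
valence_delta <- function(g) {
  et <- element_table()
  missing_el <- setdiff(g$element, rownames(et))
  if (length(missing_el)) {
    stop("no valence-delta entry for element(s): ",
         paste(missing_el, collapse = ", "))
  }
  zv <- et[g$element, "valence_electrons"]
  z <- et[g$element, "atomic_number"]
  dv <- ifelse(z <= 10, zv - g$hcount, (zv - g$hcount) / (z - zv - 1))
  bad <- which(dv <= 0)
  if (length(bad)) {
    stop("non-positive valence delta for atom(s) ",
         paste(bad, collapse = ", "), " (", paste(g$element[bad], collapse = ", "),
         ") in '", g$id, "'")
  }
  dv
}

#' Kier-Hall connectivity index
#'
#' Sum over connected subgraphs of type `s` with `o` bonds of the product,
#' over the subgraph's atoms, of \eqn{\delta^{-1/2}}; `variant = "simple"`
#' uses the heavy-atom degree, `"valence"` uses [valence_delta()].
#'
#' @param g a `mol_graph`.
#' @param s subgraph type (`"P"`, `"C"`, `"PC"`, `"Ch"`).
#' @param o order (bonds per subgraph).
#' @param variant `"simple"` or `"valence"`.
#' @param cache optional per-molecule cache environment.
#' @return The index value (0 when no subgraph of that type/order exists).
#' @export
#' @examples
#' connectivity_index(parse_smiles("C1CCCCC1"), "Ch", 6)  # 0.125
connectivity_index <- function(g, s, o, variant = c("simple", "valence"),
                               cache = NULL) {
  variant <- match.arg(variant)
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  delta <- if (variant == "simple") {
    d <- g$degree
    if (any(d <= 0)) stop("isolated atom (degree 0) in '", g$id, "'")
    d
  } else {
    cached(cache, "valence_delta", valence_delta(g))
  }
  subs <- cached(cache, paste0("esu_atom_", o), {
    ladj <- edges_to_adj(g$nB, cached(cache, "lg_edges",
                                      line_graph_edges(g$bonds)))
    esu_subsets(ladj, o)
  })
  total <- 0
  for (bi in subs) {
    ep <- g$bonds[bi, c("i", "j"), drop = FALSE]
    if (classify_edge_subset(ep) != s) next
    atoms <- unique(as.vector(ep))
    total <- total + prod(delta[atoms])^(-0.5)
  }
  total
}

#' Edge (bond) connectivity index
#'
#' The connectivity-index construction evaluated on the line graph: vertices
#' are the molecule's bonds, a vertex degree is the number of adjacent bonds,
#' and subgraphs are classified within the line graph.
#'
#' @inheritParams connectivity_index
#' @return The index value.
#' @export
#' @examples
#' edge_connectivity_index(parse_smiles("c1ccccc1"), "Ch", 6)  # 0.125
edge_connectivity_index <- function(g, s, o, cache = NULL) {
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  lg <- cached(cache, "lg_edges", line_graph_edges(g$bonds))
  deg_l <- tabulate(as.vector(lg), nbins = g$nB)
  subs <- cached(cache, paste0("esu_line_", o), {
    lladj <- edges_to_adj(nrow(lg), line_graph_edges(lg))
    esu_subsets(lladj, o)
  })
  total <- 0
  for (ei in subs) {
    ep <- lg[ei, c("i", "j"), drop = FALSE]
    if (classify_edge_subset(ep) != s) next
    verts <- unique(as.vector(ep))
    if (any(deg_l[verts] <= 0)) stop("degree-0 line-graph vertex")
    total <- total + prod(deg_l[verts])^(-0.5)
  }
  total
}
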