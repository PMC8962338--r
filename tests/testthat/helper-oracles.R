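# Independent brute-force oracles for the descriptor machinery. These stay
# deliberately naive (recursive walk enumeration, combn over edge subsets)
# so they share no code path with the package implementations they check.

# sum over closed weighted walks of length k on a matrix M (diagonal entries
# act as self-loop weights), by explicit recursive enumeration
oracle_closed_walks <- function(M, k) {
  n <- nrow(M)
  if (k == 0) return(n)
  total <- 0
  step <- function(v0, v, remaining, w) {
    if (remaining == 0) {
      if (v == v0) total <<- total + w
      return(invisible())
    }
    for (u in seq_len(n)) {
      if (M[v, u] != 0) step(v0, u, remaining - 1, w * M[v, u])
    }
  }
  for (v in seq_len(n)) step(v, v, k, 1)
  total
}

# all connected o-edge subgraphs via combn + connectivity check
oracle_edge_subsets <- function(edges, o) {
  ne <- nrow(edges)
  if (o > ne) return(list())
  if (o == ne) cands <- matrix(seq_len(ne), ncol = 1)
  else cands <- utils::combn(ne, o)
  out <- list()
  for (c in seq_len(ncol(cands))) {
    sel <- cands[, c]
    ep <- edges[sel, , drop = FALSE]
    atoms <- unique(as.vector(ep[, 1:2]))
    # connectivity by label propagation
    lab <- stats::setNames(seq_along(atoms), atoms)
    repeat {
      changed <- FALSE
      for (r in seq_len(nrow(ep))) {
        a <- as.character(ep[r, 1]); b <- as.character(ep[r, 2])
        m <- min(lab[a], lab[b])
        if (lab[a] != m || lab[b] != m) {
          lab[a] <- lab[b] <- m
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    if (length(unique(lab)) == 1) out[[length(out) + 1]] <- sort(sel)
  }
  out
}

# Kier-Hall classification of an edge subset (independent restatement)
oracle_classify <- function(ep) {
  atoms <- unique(as.vector(ep[, 1:2]))
  if (nrow(ep) >= length(atoms)) return("Ch")
  deg <- table(factor(as.vector(ep[, 1:2]), levels = atoms))
  if (max(deg) <= 2) return("P")
  if (!any(deg == 2)) return("C")
  "PC"
}

# connectivity index by brute force over subsets
oracle_connectivity <- function(g, s, o, delta) {
  subs <- oracle_edge_subsets(g$bonds, o)
  total <- 0
  for (sel in subs) {
    ep <- g$bonds[sel, , drop = FALSE]
    if (oracle_classify(ep) != s) next
    atoms <- unique(as.vector(ep[, 1:2]))
    total <- total + 1 / sqrt(prod(delta[atoms]))
  }
  total
}

# line graph as an edge matrix (vertices = bond indices of g)
oracle_line_graph <- function(g) {
  nb <- nrow(g$bonds)
  out <- NULL
  if (nb >= 2) {
    for (a in seq_len(nb - 1)) {
      for (b in (a + 1):nb) {
        if (length(intersect(g$bonds[a, 1:2], g$bonds[b, 1:2]))) {
          out <- rbind(out, c(a, b))
        }
      }
    }
  }
  if (is.null(out)) out <- matrix(integer(0), ncol = 2)
  colnames(out) <- c("i", "j")
  out
}

oracle_edge_connectivity <- function(g, s, o) {
  lg <- oracle_line_graph(g)
  nb <- nrow(g$bonds)
  deg_l <- tabulate(as.vector(lg), nbins = nb)
  subs <- oracle_edge_subsets(lg, o)
  total <- 0
  for (sel in subs) {
    ep <- lg[sel, , drop = FALSE]
    if (oracle_classify(ep) != s) next
    verts <- unique(as.vector(ep[, 1:2]))
    total <- total + 1 / sqrt(prod(deg_l[verts]))
  }
  total
}

# [S^m]_ij by enumerating length-m walks with product of 1/degree weights
oracle_stochastic_entry <- function(g, m, i, j) {
  adj <- lapply(seq_len(g$n_atoms), function(v) {
    unique(c(g$bonds[g$bonds[, "i"] == v, "j"],
             g$bonds[g$bonds[, "j"] == v, "i"]))
  })
  deg <- lengths(adj)
  total <- 0
  walk <- function(v, remaining, w) {
    if (remaining == 0) {
      if (v == j) total <<- total + w
      return(invisible())
    }
    for (u in adj[[v]]) walk(u, remaining - 1, w / deg[v])
  }
  if (m == 0) return(as.numeric(i == j))
  walk(i, m, 1)
  total
}

# small molecule panel used by the oracle-equivalence tests (<= 8 bonds)
oracle_panel <- function() {
  c(ethane = "CC", propane = "CCC", butane = "CCCC", isobutane = "CC(C)C",
    neopentane = "CC(C)(C)C", cyclohexane = "C1CCCCC1",
    benzene = "c1ccccc1", ethanol = "CCO", acetone = "CC(C)=O",
    mecyclopentane = "CC1CCCC1", fluoroethane = "CCF",
    dimethylamine = "CNC")
}
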