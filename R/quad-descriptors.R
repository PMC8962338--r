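# Atom-based local stochastic quadratic indices.
#
# The atom adjacency matrix is row-normalized by the heavy-atom degree so each
# row is a probability distribution over neighbors; the m-th power spreads a
# property vector over length-m walks. The local index restricts the quadratic
# form to one typed atom group.

#' Row-stochastic atom adjacency matrix
#'
#' Adjacency of the hydrogen-suppressed graph with each row divided by the
#' atom's degree. Rows sum to one, and every power of the matrix is again
#' row-stochastic.
#'
#' @param g a `mol_graph` (at least two heavy atoms; an isolated heavy atom
#'   has a zero row and is rejected).
#' @return `n x n` matrix.
#' @export
#' @examples
#' stochastic_matrix(parse_smiles("CCC"))[2, ]  # 0.5 0 0.5
stochastic_matrix <- function(g) {
  stopifnot(inherits(g, "mol_graph"))
  n <- g$n_atoms
  if (any(g$degree == 0)) {
    stop("isolated heavy atom in '", g$id, "': cannot row-normalize")
  }
  S <- matrix(0, n, n)
  for (b in seq_len(g$nB)) {
    i <- g$bonds[b, "i"]; j <- g$bonds[b, "j"]
    S[i, j] <- 1; S[j, i] <- 1
  }
  S / g$degree
}

# m-th power of the stochastic matrix, cached per molecule
stochastic_power <- function(g, m, cache = NULL) {
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  if (m == 0) return(diag(g$n_atoms))
  key <- paste0("Spow_", m)
  if (is.null(cache[[key]])) {
    S <- cached(cache, "Spow_1", stochastic_matrix(g))
    M <- S
    if (m > 1) for (t in seq_len(m - 1)) M <- M %*% S
    cache[[key]] <- M
  }
  cache[[key]]
}

#' Local stochastic quadratic index
#'
#' \eqn{q = \sum_{i \in T} x_i \, [S^m x]_i}: the property value of each atom
#' in group `T` multiplied by the property mass reachable from it in `m`
#' stochastic steps, summed over the group. Order 0 degenerates to
#' \eqn{\sum_{i \in T} x_i^2}; an empty group gives 0.
#'
#' @param g a `mol_graph`.
#' @param x per-atom property vector (length `g$n_atoms`).
#' @param m walk length, 0..6.
#' @param group group code (`"G"`, `"Y"`, `"C"`, `"M"`, `"A"`) or an integer
#'   vector of atom indices.
#' @param cache optional per-molecule cache environment.
#' @return The index value.
#' @export
#' @examples
#' g <- parse_smiles("CC")
#' local_quadratic_index(g, c(2, 3), 1, 1L)  # 2*3 = 6
local_quadratic_index <- function(g, x, m, group, cache = NULL) {
  stopifnot(inherits(g, "mol_graph"), length(x) == g$n_atoms,
            m >= 0, m <= 6)
  idx <- if (is.character(group)) {
    grp <- if (!is.null(cache)) cached(cache, "groups", atom_groups(g))
           else atom_groups(g)
    if (!group %in% names(grp)) stop("unknown atom group code: ", group)
    grp[[group]]
  } else {
    as.integer(group)
  }
  if (!length(idx)) return(0)
  Sx <- as.vector(stochastic_power(g, m, cache) %*% x)
  sum(x[idx] * Sx[idx])
}
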