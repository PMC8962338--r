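# Hydrogen-suppressed molecular graphs.
#
# Parsing and aromatic perception are delegated to OpenBabel through
# ChemmineR/ChemmineOB; everything downstream (descriptors, typing) works on
# the plain `mol_graph` structure built here, so the object is the single
# chemistry contract of the package.

# SDF charge-code column (field 2 after the element symbol): 1..7 codes.
.sdf_charge <- c(`0` = 0, `1` = 3, `2` = 2, `3` = 1, `4` = 0, `5` = -1,
                 `6` = -2, `7` = -3)

# Lowest standard valences per element; hypervalent states picked as the
# smallest allowed valence >= bond-order sum.
.valences <- list(B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4, P = c(3, 5),
                  S = c(2, 4, 6), Cl = 1, Se = c(2, 4, 6), Br = 1, I = 1,
                  Na = 0, K = 0, H = 1)

#' Parse a SMILES string into a hydrogen-suppressed molecular graph
#'
#' Builds a `mol_graph`: heavy atoms with element symbol, formal charge,
#' aromatic flag and implicit-hydrogen count; bonds with order; ring
#' membership of atoms and bonds; and `nB`, the bond count ignoring bond
#' multiplicity. Aromaticity is perceived on rings (OpenBabel perception via
#' ChemmineR). Multi-component (dot-disconnected) inputs keep the largest
#' component with a warning, or fail when `keep_largest = FALSE`. Molecules
#' with fewer than two heavy atoms are rejected: the size normalization of the
#' descriptor layer divides by `nB`.
#'
#' @param smiles single SMILES string.
#' @param id optional molecule identifier (defaults to the SMILES).
#' @param keep_largest keep the largest connected component of
#'   multi-component inputs (`TRUE`, default) or raise an error.
#' @return An object of class `mol_graph`.
#' @export
#' @examples
#' g <- parse_smiles("CCO")
#' g$n_atoms  # 3
#' g$nB       # 2
parse_smiles <- function(smiles, id = NULL, keep_largest = TRUE) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      !nzchar(trimws(smiles))) {
    stop("'smiles' must be a single non-empty string")
  }
  smiles <- trimws(smiles)
  if (is.null(id)) id <- smiles
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(stats::setNames(smiles, id))),
    error = function(e) {
      stop("SMILES parse error for '", smiles, "': ", conditionMessage(e),
           call. = FALSE)
    })
  if (!methods::is(sdf, "SDFset") || length(sdf) < 1L) {
    stop("SMILES parse error for '", smiles, "': invalid structure",
         call. = FALSE)
  }
  if (!isTRUE(suppressWarnings(ChemmineR::validSDF(sdf))[1L])) {
    ab <- tryCatch(ChemmineR::atomblock(sdf[[1]]), error = function(e) NULL)
    if (!is.null(ab) && nrow(ab) < 2L) {
      stop("molecule '", id, "' has fewer than 2 heavy atoms; ",
           "size normalization (division by nB) is undefined", call. = FALSE)
    }
    stop("SMILES parse error for '", smiles, "': invalid structure",
         call. = FALSE)
  }
  g <- mol_graph_from_sdf(sdf[[1]], id = id, smiles = smiles,
                          keep_largest = keep_largest)
  g
}

#' Read a .smi file (one SMILES and optional id per line)
#'
#' @param path file path; each non-empty line is `SMILES[ \t]id`.
#' @param keep_largest passed to [parse_smiles()].
#' @return A named list of `mol_graph` objects.
#' @export
read_smi <- function(path, keep_largest = TRUE) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    warning("no molecules in ", path)
    return(list())
  }
  parts <- strsplit(lines, "[ \t]+")
  smiles <- vapply(parts, `[[`, "", 1L)
  ids <- vapply(seq_along(parts), function(i) {
    if (length(parts[[i]]) > 1L) parts[[i]][[2L]] else paste0("mol", i)
  }, "")
  out <- Map(parse_smiles, smiles, ids, keep_largest = keep_largest)
  names(out) <- ids
  out
}

#' Read an SDF (V2000) file into molecular graphs
#'
#' @param path SDF file path.
#' @param keep_largest passed through to component handling.
#' @return A named list of `mol_graph` objects.
#' @export
read_sdf <- function(path, keep_largest = TRUE) {
  sdfset <- ChemmineR::read.SDFset(path)
  ok <- ChemmineR::validSDF(sdfset)
  if (any(!ok)) warning(sum(!ok), " invalid SDF record(s) skipped")
  sdfset <- sdfset[ok]
  ids <- ChemmineR::sdfid(sdfset)
  ids[!nzchar(ids)] <- paste0("mol", which(!nzchar(ids)))
  out <- lapply(seq_along(sdfset), function(i) {
    mol_graph_from_sdf(sdfset[[i]], id = ids[i], smiles = NA_character_,
                       keep_largest = keep_largest)
  })
  names(out) <- ids
  out
}

#' Canonicalize SMILES strings
#'
#' @param smiles character vector of SMILES.
#' @return Character vector of canonical SMILES (`NA` where conversion
#'   failed, with a warning).
#' @export
canonical_smiles <- function(smiles) {
  if (!length(smiles)) return(character())
  src <- paste0(smiles, " m", seq_along(smiles), "\n", collapse = "")
  out <- tryCatch(ChemmineOB::convertFormat("SMI", "CAN", source = src),
                  error = function(e) "")
  lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
  res <- rep(NA_character_, length(smiles))
  if (length(lines)) {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    can <- vapply(parts, `[[`, "", 1L)
    idx <- as.integer(sub("^m", "", vapply(parts, function(p) {
      if (length(p) > 1L) p[[2L]] else ""
    }, "")))
    keep <- !is.na(idx)
    res[idx[keep]] <- can[keep]
  }
  if (anyNA(res)) {
    warning(sum(is.na(res)), " SMILES failed canonicalization")
  }
  res
}

# Build a mol_graph from a ChemmineR SDF object.
mol_graph_from_sdf <- function(sdf, id, smiles, keep_largest = TRUE) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  n <- nrow(ab)
  element <- sub("_.*$", "", rownames(ab))
  charge_code <- if ("C6" %in% colnames(ab)) ab[, "C6"] else rep(0, n)
  charge <- unname(.sdf_charge[as.character(charge_code)])
  charge[is.na(charge)] <- 0L

  bonds <- if (is.null(bb) || nrow(bb) == 0L) {
    matrix(numeric(0), ncol = 3, dimnames = list(NULL, c("i", "j", "order")))
  } else {
    cbind(i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
          order = as.numeric(bb[, 3]))
  }

  # connected components (heavy-atom BFS)
  comp <- graph_components(n, bonds)
  if (max(comp) > 1L) {
    if (!keep_largest) {
      stop("multi-component structure for '", id,
           "' (", max(comp), " components)")
    }
    keep_comp <- which.max(tabulate(comp))
    keep <- which(comp == keep_comp)
    warning("'", id, "': multi-component input, keeping largest component (",
            length(keep), " of ", n, " atoms)")
    remap <- match(seq_len(n), keep)
    bkeep <- bonds[, "i"] %in% keep & bonds[, "j"] %in% keep
    bonds <- bonds[bkeep, , drop = FALSE]
    bonds[, "i"] <- remap[bonds[, "i"]]
    bonds[, "j"] <- remap[bonds[, "j"]]
    element <- element[keep]
    charge <- charge[keep]
    ab <- ab[keep, , drop = FALSE]
    n <- length(keep)
  }

  if (n < 2L) {
    stop("molecule '", id, "' has fewer than 2 heavy atoms; ",
         "size normalization (division by nB) is undefined")
  }

  degree <- tabulate(c(bonds[, "i"], bonds[, "j"]), nbins = n)

  # aromaticity + ring membership from ring perception
  aromatic <- logical(n)
  ring_atom <- logical(n)
  rng <- tryCatch(
    suppressWarnings(ChemmineR::rings(sdf, upper = 14, type = "all",
                                      arom = TRUE)),
    error = function(e) list(RINGS = list(), AROMATIC = logical()))
  ring_list <- lapply(rng$RINGS, function(r) as.integer(sub("^.*_", "", r)))
  if (max(graph_components(n, bonds)) == 1L && length(ring_list)) {
    for (k in seq_along(ring_list)) {
      atoms_k <- ring_list[[k]]
      atoms_k <- atoms_k[atoms_k <= n & atoms_k >= 1]  # post-component remap
      ring_atom[atoms_k] <- TRUE
      if (isTRUE(rng$AROMATIC[k])) aromatic[atoms_k] <- TRUE
    }
  }
  # only carbon and classic heteroatoms can be aromatic
  aromatic <- aromatic & element %in% c("C", "N", "O", "S", "Se", "P", "B")

  # ring bonds: non-bridge bonds (removal keeps endpoints connected)
  nB <- nrow(bonds)
  ring_bond <- logical(nB)
  if (nB) {
    for (b in seq_len(nB)) {
      rest <- bonds[-b, , drop = FALSE]
      comp_b <- graph_components(n, rest)
      ring_bond[b] <- comp_b[bonds[b, "i"]] == comp_b[bonds[b, "j"]]
    }
  }

  hcount <- implicit_h(element, charge, bonds, n)

  structure(list(id = id, smiles = smiles, n_atoms = n, element = element,
                 aromatic = aromatic, charge = as.integer(charge),
                 hcount = hcount, bonds = bonds, degree = degree,
                 ring_atom = ring_atom, ring_bond = ring_bond, nB = nB),
            class = "mol_graph")
}

# implicit hydrogen counts from standard valences
implicit_h <- function(element, charge, bonds, n) {
  bosum <- numeric(n)
  if (nrow(bonds)) {
    for (b in seq_len(nrow(bonds))) {
      bosum[bonds[b, "i"]] <- bosum[bonds[b, "i"]] + bonds[b, "order"]
      bosum[bonds[b, "j"]] <- bosum[bonds[b, "j"]] + bonds[b, "order"]
    }
  }
  vapply(seq_len(n), function(i) {
    vals <- .valences[[element[i]]]
    if (is.null(vals)) return(0L)
    ch <- charge[i]
    # cations of N/P/O/S gain a bonding site, anions and carbocations lose one
    vals <- if (ch > 0 && element[i] %in% c("N", "P", "O", "S")) {
      vals + ch
    } else if (ch != 0) {
      vals - abs(ch)
    } else {
      vals
    }
    v <- vals[vals >= bosum[i]]
    if (!length(v)) return(0L)
    as.integer(min(v) - bosum[i])
  }, integer(1))
}

# connected components of a graph given bonds; returns component id per atom
graph_components <- function(n, bonds) {
  comp <- integer(n)
  if (!n) return(comp)
  adj <- vector("list", n)
  if (nrow(bonds)) {
    for (b in seq_len(nrow(bonds))) {
      i <- bonds[b, "i"]; j <- bonds[b, "j"]
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
  }
  cid <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (u in adj[[v]]) {
        if (comp[u] == 0L) { comp[u] <- cid; queue <- c(queue, u) }
      }
    }
  }
  comp
}

# adjacency list of heavy atoms
atom_adjacency_list <- function(g) {
  adj <- vector("list", g$n_atoms)
  if (g$nB) {
    for (b in seq_len(g$nB)) {
      i <- g$bonds[b, "i"]; j <- g$bonds[b, "j"]
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
  }
  adj
}

#' @export
print.mol_graph <- function(x, ...) {
  cat("mol_graph '", x$id, "': ", x$n_atoms, " heavy atoms, ", x$nB,
      " bonds (", sum(x$aromatic), " aromatic atoms)\n", sep = "")
  invisible(x)
}

#' Typed atom groups of a molecular graph
#'
#' Classifies every heavy atom into the groups used by the local quadratic
#' indices: `G` halogens (F, Cl, Br, I), `Y` heteroatoms (N, O, S, P, Se),
#' `A` aromatic carbons, `C` aliphatic carbons, and `M` methyl carbons
#' (aliphatic carbon with exactly one heavy neighbor and at least three
#' hydrogens; `M` is a subset of `C`).
#'
#' @param g a `mol_graph`.
#' @return A list of integer index vectors `G`, `Y`, `C`, `M`, `A`.
#' @export
#' @examples
#' atom_groups(parse_smiles("Cc1ccccc1"))  # toluene: 6 in A, 1 in C and M
atom_groups <- function(g) {
  stopifnot(inherits(g, "mol_graph"))
  el <- g$element
  G <- which(el %in% c("F", "Cl", "Br", "I"))
  Y <- which(el %in% c("N", "O", "S", "P", "Se"))
  A <- which(el == "C" & g$aromatic)
  C <- which(el == "C" & !g$aromatic)
  M <- C[g$degree[C] == 1L & g$hcount[C] >= 3L]
  list(G = G, Y = Y, C = C, M = M, A = A)
}
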