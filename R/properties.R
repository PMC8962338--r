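# Atomic physicochemical property schemes.
#
# All table-driven schemes resolve through the versioned CSVs under
# inst/extdata. Hydrogen contributions (logP/MR increments of attached
# hydrogens) are folded into the heavy atom carrying them, so each scheme
# yields exactly one value per heavy atom.

.property_codes <- c("Hyd", "Psa", "Mol", "Gas", "Ato", "Aw", "E", "Pol", "Ku")

#' Per-atom physicochemical property vector
#'
#' Returns one value per heavy atom for the requested scheme:
#' \describe{
#'   \item{Hyd}{hydrophobicity: atomic logP contributions
#'     (Ghose-Crippen-style table, hydrogens folded in).}
#'   \item{Mol}{molar refractivity contributions from the same typing.}
#'   \item{Psa}{polar-surface-area increments (Ertl-type fragment scheme
#'     mapped to atoms; apolar atoms contribute 0).}
#'   \item{Gas}{Gasteiger-Marsili partial charges by damped iterative
#'     electronegativity equalization (hydrogen charges folded in, so the
#'     vector sums to the net formal charge).}
#'   \item{Ato, Aw}{standard atomic weight (two aliases of the same scheme).}
#'   \item{E}{Pauling electronegativity.}
#'   \item{Pol}{atomic polarizability (angstrom^3).}
#'   \item{Ku}{Kupchik vertex degree
#'     \eqn{(r_{Csp3}/r_i)\,(Z^v_i - h_i)}: valence-electron count minus
#'     attached hydrogens, scaled by the covalent-radius ratio to sp3 carbon.}
#' }
#'
#' @param g a `mol_graph`.
#' @param scheme one of `"Hyd"`, `"Psa"`, `"Mol"`, `"Gas"`, `"Ato"`, `"Aw"`,
#'   `"E"`, `"Pol"`, `"Ku"`.
#' @return Numeric vector of length `g$n_atoms`.
#' @export
#' @examples
#' assign_properties(parse_smiles("CCO"), "Ato")
assign_properties <- function(g, scheme) {
  stopifnot(inherits(g, "mol_graph"))
  scheme <- match.arg(scheme, .property_codes)
  el <- g$element
  et <- element_table()
  missing_el <- setdiff(el, rownames(et))
  lookup <- function(col) {
    if (length(missing_el)) {
      stop("no ", scheme, " entry for element(s): ",
           paste(missing_el, collapse = ", "))
    }
    unname(et[el, col])
  }
  out <- switch(scheme,
    Ato = ,
    Aw = lookup("weight"),
    E = lookup("en_pauling"),
    Pol = lookup("polarizability"),
    Ku = {
      zv <- lookup("valence_electrons")
      r <- lookup("covalent_radius")
      (0.772 / r) * (zv - g$hcount)
    },
    Hyd = crippen_values(g, "hyd"),
    Mol = crippen_values(g, "mr"),
    Psa = psa_values(g),
    Gas = gasteiger_charges(g))
  if (any(!is.finite(out))) {
    stop("non-finite ", scheme, " value for molecule '", g$id, "'")
  }
  out
}

# ---- Crippen-style typing (Hyd / Mol) --------------------------------------

# reduced atom-typing dialect; returns a type id per heavy atom
crippen_type <- function(g, i) {
  el <- g$element[i]
  adj <- which(g$bonds[, "i"] == i | g$bonds[, "j"] == i)
  nbrs <- setdiff(as.vector(g$bonds[adj, c("i", "j")]), i)
  orders <- g$bonds[adj, "order"]
  has_het_nbr <- any(!g$element[nbrs] %in% c("C", "H"))
  max_order <- if (length(orders)) max(orders) else 0
  dbl_nbrs <- nbrs[orders >= 2]
  switch(el,
    C = {
      if (g$aromatic[i]) {
        nonring <- adj[!g$ring_bond[adj]]
        subs <- setdiff(as.vector(g$bonds[nonring, c("i", "j")]), i)
        if (g$hcount[i] > 0) "C_ar_h"
        else if (!length(subs)) "C_ar_ar"                 # ring-fusion carbon
        else if (any(g$element[subs] != "C")) "C_ar_x"
        else if (any(g$aromatic[subs])) "C_ar_ar"         # biaryl link
        else "C_ar_c"
      } else if (max_order >= 3 || sum(orders >= 2) >= 2) {
        "C_sp"
      } else if (max_order == 2) {
        if (any(!g$element[dbl_nbrs] %in% "C")) "C_sp2_x" else "C_sp2_c"
      } else if (g$degree[i] <= 2) {
        if (has_het_nbr) "C_sp3_ps_x" else "C_sp3_ps"
      } else {
        if (has_het_nbr) "C_sp3_tq_x" else "C_sp3_tq"
      }
    },
    N = {
      carbonyl_nbr <- any(vapply(nbrs, function(u) {
        if (g$element[u] != "C") return(FALSE)
        badj <- which(g$bonds[, "i"] == u | g$bonds[, "j"] == u)
        others <- setdiff(as.vector(g$bonds[badj, c("i", "j")]), u)
        any(g$bonds[badj, "order"] >= 2 & g$element[others] %in% c("O", "S"))
      }, logical(1)))
      n_dbl_o <- sum(g$element[dbl_nbrs] == "O")
      if (g$charge[i] > 0) "N_plus"
      else if (n_dbl_o >= 2) "N_nitro"
      else if (g$aromatic[i]) "N_ar"
      else if (max_order >= 3) "N_sp"
      else if (max_order == 2) "N_sp2"
      else if (carbonyl_nbr) "N_amide"
      else if (g$hcount[i] >= 2) "N_prim"
      else if (g$hcount[i] == 1) "N_sec"
      else "N_tert"
    },
    O = {
      if (g$charge[i] < 0) "O_minus"
      else if (g$aromatic[i]) "O_ar"
      else if (max_order >= 2) "O_dbl"
      else if (g$hcount[i] >= 1) "O_oh"
      else "O_ether"
    },
    S = {
      if (any(g$element[dbl_nbrs] == "O")) "S_ox"
      else if (g$aromatic[i]) "S_ar"
      else "S_any"
    },
    P = "P_any", F = "F_any", Cl = "Cl_any", Br = "Br_any", I = "I_any",
    Se = "Se_any", B = "B_any",
    stop("no Hyd/Mol contribution entry for element ", el))
}

crippen_values <- function(g, col) {
  tbl <- crippen_table()
  vapply(seq_len(g$n_atoms), function(i) {
    ty <- crippen_type(g, i)
    if (!ty %in% rownames(tbl)) {
      stop("no contribution-table entry for type ", ty)
    }
    h_ty <- if (g$element[i] == "C") "h_on_c" else "h_on_het"
    tbl[ty, col] + g$hcount[i] * tbl[h_ty, col]
  }, numeric(1))
}

# ---- PSA typing ------------------------------------------------------------

psa_type <- function(g, i) {
  el <- g$element[i]
  if (!el %in% c("N", "O", "S", "P")) return(NA_character_)
  adj <- which(g$bonds[, "i"] == i | g$bonds[, "j"] == i)
  orders <- g$bonds[adj, "order"]
  nbrs <- setdiff(as.vector(g$bonds[adj, c("i", "j")]), i)
  max_order <- if (length(orders)) max(orders) else 0
  h <- g$hcount[i]
  n_dbl_o <- sum(g$element[nbrs[orders >= 2]] == "O")
  switch(el,
    N = {
      if (g$charge[i] > 0) {
        switch(as.character(min(h, 3)), `0` = "N_plus", `1` = "N_plus_h",
               `2` = "N_plus_h2", `3` = "N_plus_h3")
      } else if (n_dbl_o >= 2) "N_nitro"
      else if (g$aromatic[i]) { if (h > 0) "N_ar_h" else "N_ar" }
      else if (max_order >= 3) "N_triple"
      else if (max_order == 2) "N_dbl"
      else if (h >= 2) "N_h2"
      else if (h == 1) "N_h_single"
      else "N_3single"
    },
    O = {
      if (g$charge[i] < 0) "O_minus"
      else if (g$aromatic[i]) "O_ar"
      else if (max_order >= 2) "O_dbl"
      else if (h >= 1) "O_h"
      else "O_single"
    },
    S = {
      if (n_dbl_o >= 2) "S_sulfone"
      else if (n_dbl_o == 1) "S_sulfoxide"
      else if (g$aromatic[i]) "S_ar"
      else if (max_order >= 2) "S_dbl"
      else "S_single"
    },
    P = if (n_dbl_o >= 1 || max_order >= 2) "P_oxide" else "P_3single")
}

psa_values <- function(g) {
  tbl <- psa_table()
  vapply(seq_len(g$n_atoms), function(i) {
    ty <- psa_type(g, i)
    if (is.na(ty)) 0 else tbl[ty, "psa"]
  }, numeric(1))
}

# ---- Gasteiger-Marsili charges ---------------------------------------------

gasteiger_hyb <- function(g, i) {
  # halogens and (hyper)valent S/P/Se use their single parameter triple
  if (g$element[i] %in% c("F", "Cl", "Br", "I", "S", "P", "Se")) return("sp3")
  adj <- which(g$bonds[, "i"] == i | g$bonds[, "j"] == i)
  orders <- g$bonds[adj, "order"]
  if (any(orders >= 3) || sum(orders >= 2) >= 2) "sp"
  else if (g$aromatic[i] || any(orders >= 2)) "sp2"
  else "sp3"
}

#' Gasteiger-Marsili partial charges
#'
#' Damped iterative partial equalization of orbital electronegativities
#' (PEOE). Hydrogens are included in the iteration as explicit pseudo-atoms
#' and their converged charges are folded into the heavy atom they sit on, so
#' the returned vector sums to the molecule's net formal charge. The result
#' carries attributes `iterations` and `max_delta` (largest per-atom charge
#' change in the final sweep).
#'
#' @param g a `mol_graph`.
#' @param iterations damping sweeps (default 8; the damping factor 0.5^t makes
#'   later sweeps geometrically small).
#' @param damping per-sweep damping base (default 0.5).
#' @return Numeric vector of length `g$n_atoms` of partial charges.
#' @export
gasteiger_charges <- function(g, iterations = 8, damping = 0.5) {
  stopifnot(inherits(g, "mol_graph"))
  gp <- gasteiger_table()
  # expand: heavy atoms 1..n, then hydrogens appended with their anchor
  n <- g$n_atoms
  key <- vapply(seq_len(n), function(i) {
    el <- g$element[i]
    k <- if (el == "H") "H_s" else paste0(el, "_", gasteiger_hyb(g, i))
    if (!k %in% rownames(gp)) {
      stop("no PEOE parameters for atom ", i, " (", k, ") in '", g$id, "'")
    }
    k
  }, "")
  edges <- g$bonds[, c("i", "j"), drop = FALSE]
  anchor <- integer(0)
  for (i in seq_len(n)) {
    nh <- g$hcount[i]
    if (nh > 0) {
      hidx <- length(key) + seq_len(nh)
      key <- c(key, rep("H_s", nh))
      edges <- rbind(edges, cbind(i = rep(i, nh), j = hidx))
      anchor <- c(anchor, rep(i, nh))
    }
  }
  ntot <- length(key)
  a <- gp[key, "a"]; b <- gp[key, "b"]; cc <- gp[key, "c"]
  chi_plus <- ifelse(key == "H_s", 20.02, a + b + cc)
  q <- c(as.numeric(g$charge), rep(0, ntot - n))
  max_delta <- Inf
  for (t in seq_len(iterations)) {
    chi <- a + b * q + cc * q^2
    dq <- numeric(ntot)
    f <- damping^t
    for (e in seq_len(nrow(edges))) {
      i <- edges[e, 1]; j <- edges[e, 2]
      if (chi[i] == chi[j]) next
      lo <- if (chi[i] < chi[j]) i else j
      hi <- if (chi[i] < chi[j]) j else i
      amt <- (chi[hi] - chi[lo]) / chi_plus[lo] * f
      dq[lo] <- dq[lo] + amt   # donor becomes more positive
      dq[hi] <- dq[hi] - amt
    }
    q <- q + dq
    max_delta <- max(abs(dq))
  }
  heavy <- q[seq_len(n)]
  if (length(anchor)) {
    for (k in seq_along(anchor)) {
      heavy[anchor[k]] <- heavy[anchor[k]] + q[n + k]
    }
  }
  structure(heavy, iterations = iterations, max_delta = max_delta)
}
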