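# Global physicochemical properties and drug-likeness filters (Lipinski,
# Ghose, Veber).

# topological distance matrix (BFS; unweighted heavy-atom graph)
topo_distances <- function(g) {
  n <- g$n_atoms
  adj <- atom_adjacency_list(g)
  D <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    D[s, s] <- 0
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (u in adj[[v]]) {
        if (is.infinite(D[s, u])) {
          D[s, u] <- D[s, v] + 1
          queue <- c(queue, u)
        }
      }
    }
  }
  D
}

# count of nitro groups (N doubly bonded to two O)
count_nitro <- function(g) {
  sum(vapply(seq_len(g$n_atoms), function(i) {
    if (g$element[i] != "N") return(FALSE)
    adj <- which(g$bonds[, "i"] == i | g$bonds[, "j"] == i)
    nbrs <- setdiff(as.vector(g$bonds[adj, c("i", "j")]), i)
    sum(g$element[nbrs[g$bonds[adj, "order"] >= 2]] == "O") >= 2
  }, logical(1)))
}

# Moriguchi-style logP from graph-derivable terms; the rare NCS/BLM/HB
# correction flags are taken as 0 (documented simplification)
moriguchi_logp <- function(g) {
  el <- g$element
  hal_w <- c(F = 0.5, Cl = 1.0, Br = 1.5, I = 2.0)
  cx <- sum(el == "C") + sum(hal_w[el[el %in% names(hal_w)]])
  no <- sum(el %in% c("N", "O"))
  D <- topo_distances(g)
  no_idx <- which(el %in% c("N", "O"))
  prx <- 0
  if (length(no_idx) > 1) {
    for (a in seq_len(length(no_idx) - 1)) {
      for (b in (a + 1):length(no_idx)) {
        d <- D[no_idx[a], no_idx[b]]
        if (d == 1) prx <- prx + 2
        else if (d == 2) prx <- prx + 1
      }
    }
  }
  arom_bond <- g$aromatic[g$bonds[, "i"]] & g$aromatic[g$bonds[, "j"]] &
    g$ring_bond
  ub <- sum(g$bonds[, "order"] >= 2 & !arom_bond)
  rng <- as.numeric(any(g$ring_atom))
  # polar substituents on aromatic rings
  pol <- 0
  for (b in seq_len(g$nB)) {
    i <- g$bonds[b, "i"]; j <- g$bonds[b, "j"]
    if (g$aromatic[i] && !g$aromatic[j] && el[j] %in% c("N", "O", "S", "P") ||
        g$aromatic[j] && !g$aromatic[i] && el[i] %in% c("N", "O", "S", "P")) {
      pol <- pol + 1
    }
  }
  alk <- as.numeric(all(el == "C") && all(g$bonds[, "order"] == 1) &&
                    !any(g$ring_atom))
  qn <- sum(el == "N" & (g$degree == 4 | g$charge > 0))
  nno2 <- count_nitro(g)
  has_acid <- any(vapply(seq_len(g$n_atoms), function(i) {
    if (el[i] != "C") return(FALSE)
    adj <- which(g$bonds[, "i"] == i | g$bonds[, "j"] == i)
    nbrs <- setdiff(as.vector(g$bonds[adj, c("i", "j")]), i)
    oh <- any(el[nbrs] == "O" & g$hcount[nbrs] >= 1)
    dbl_o <- any(el[nbrs[g$bonds[adj, "order"] >= 2]] == "O")
    oh && dbl_o
  }, logical(1)))
  has_amine <- any(el == "N" & g$hcount >= 1 & !g$aromatic)
  amp <- as.numeric(has_acid && has_amine)
  -1.014 + 1.244 * cx^0.6 - 1.017 * no^0.9 + 0.406 * prx -
    0.145 * ub^0.8 + 0.268 * pol - 2.215 * amp + 0.912 * alk -
    0.392 * rng - 3.684 * qn + 0.474 * nno2
}

# rotatable bonds: non-ring single bonds between two non-terminal heavy
# atoms, amide C-N excluded
count_rotatable <- function(g) {
  if (!g$nB) return(0L)
  rbn <- 0L
  for (b in seq_len(g$nB)) {
    if (g$ring_bond[b] || g$bonds[b, "order"] != 1) next
    i <- g$bonds[b, "i"]; j <- g$bonds[b, "j"]
    if (g$degree[i] < 2 || g$degree[j] < 2) next
    amide <- function(c_at, n_at) {
      g$element[c_at] == "C" && g$element[n_at] == "N" && {
        adj <- which(g$bonds[, "i"] == c_at | g$bonds[, "j"] == c_at)
        nbrs <- setdiff(as.vector(g$bonds[adj, c("i", "j")]), c_at)
        any(g$bonds[adj, "order"] >= 2 & g$element[nbrs] == "O")
      }
    }
    if (amide(i, j) || amide(j, i)) next
    rbn <- rbn + 1L
  }
  rbn
}

#' Global physicochemical profile and drug-likeness verdicts
#'
#' Computes H-bond donor/acceptor counts, molecular weight, Moriguchi and
#' Ghose-Crippen-style logP estimates, molar refractivity, atom count,
#' rotatable-bond count and polar surface area from the molecular graph and
#' the bundled property tables, then applies three filters: Lipinski's rule
#' of five (MW <= 500, MlogP <= 4.15 with AlogP <= 5 as configurable
#' fallback, nHDon <= 5, nHAcc <= 10), the Ghose filter (160 <= MW <= 480,
#' -0.4 <= AlogP <= 5.6, 40 <= MR <= 130, 20 <= nAT <= 70) and Veber's
#' guidelines (RBN <= 10, PSA <= 140).
#'
#' @param g a `mol_graph` (or SMILES string).
#' @param lipinski_logp which logP estimate Lipinski uses: `"mlogp"`
#'   (default, threshold 4.15) or `"alogp"` (threshold 5).
#' @return A list of class `drug_likeness` with the properties and logical
#'   `lipinski`, `ghose`, `veber` verdicts.
#' @export
#' @examples
#' drug_likeness("CCO")$lipinski  # TRUE
drug_likeness <- function(g, lipinski_logp = c("mlogp", "alogp")) {
  lipinski_logp <- match.arg(lipinski_logp)
  if (is.character(g)) g <- parse_smiles(g)
  stopifnot(inherits(g, "mol_graph"))
  el <- g$element
  et <- element_table()
  nhdon <- sum(el %in% c("N", "O") & g$hcount >= 1)
  nhacc <- sum(el %in% c("N", "O"))
  mw <- sum(et[el, "weight"]) + sum(g$hcount) * et["H", "weight"]
  alogp <- sum(assign_properties(g, "Hyd"))
  mr <- sum(assign_properties(g, "Mol"))
  psa <- sum(assign_properties(g, "Psa"))
  nat <- g$n_atoms + sum(g$hcount)
  rbn <- count_rotatable(g)
  mlogp <- moriguchi_logp(g)
  logp_ok <- if (lipinski_logp == "mlogp") mlogp <= 4.15 else alogp <= 5
  out <- list(id = g$id, nHDon = nhdon, nHAcc = nhacc, MW = mw,
              MlogP = mlogp, AlogP = alogp, MR = mr, nAT = nat, RBN = rbn,
              PSA = psa,
              lipinski = mw <= 500 && logp_ok && nhdon <= 5 && nhacc <= 10,
              ghose = mw >= 160 && mw <= 480 && alogp >= -0.4 &&
                alogp <= 5.6 && mr >= 40 && mr <= 130 && nat >= 20 &&
                nat <= 70,
              veber = rbn <= 10 && psa <= 140)
  class(out) <- "drug_likeness"
  out
}

#' @export
print.drug_likeness <- function(x, ...) {
  cat(sprintf(
    "drug_likeness '%s': MW=%.2f MlogP=%.3f AlogP=%.3f MR=%.2f nHDon=%d nHAcc=%d nAT=%d RBN=%d PSA=%.2f\n",
    x$id, x$MW, x$MlogP, x$AlogP, x$MR, x$nHDon, x$nHAcc, x$nAT, x$RBN,
    x$PSA))
  cat(sprintf("  Lipinski: %s | Ghose: %s | Veber: %s\n",
              ifelse(x$lipinski, "pass", "fail"),
              ifelse(x$ghose, "pass", "fail"),
              ifelse(x$veber, "pass", "fail")))
  invisible(x)
}
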