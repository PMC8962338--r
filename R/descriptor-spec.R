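# Descriptor naming grammar.
#
# A spec string names one raw graph-theoretical invariant (GTI):
#   [N]SM(<prop>)<k>     spectral moment of the property-weighted bond
#                        adjacency matrix, order k  (N = divided by nB)
#   [N]X(<s>)<o>         Kier-Hall simple connectivity index, subgraph type
#                        s in {P,C,PC,Ch}, order o
#   [N]Xv(<s>)<o>        valence connectivity index
#   [N]e(<s>)<o>         edge (bond) connectivity index on the line graph
#   ASq<m>(<prop>)<T>    local stochastic quadratic index, power m, property
#                        prop, atom group T in {G,Y,C,M,A}

#' Parse a descriptor specification string
#'
#' @param spec a single spec string, e.g. `"NSM(Hyd)3"`, `"Xv(Ch)6"`,
#'   `"Ne(PC)6"`, `"ASq4(Hyd)G"`.
#' @return A list with elements `family` (`"SM"`, `"X"`, `"Xv"`, `"e"` or
#'   `"ASq"`), `normalized`, `property`, `stype`, `order`, `group`, `string`.
#' @export
#' @examples
#' parse_descriptor_spec("NSM(Hyd)3")
parse_descriptor_spec <- function(spec) {
  stopifnot(is.character(spec), length(spec) == 1L)
  m <- regmatches(spec, regexec("^(N?)(SM)\\(([A-Za-z]+)\\)([0-9]+)$", spec))[[1]]
  if (length(m)) {
    prop <- match.arg(m[4], .property_codes)
    return(list(family = "SM", normalized = m[2] == "N", property = prop,
                stype = NA_character_, order = as.integer(m[5]),
                group = NA_character_, string = spec))
  }
  m <- regmatches(spec, regexec("^(N?)(Xv|X|e)\\((P|C|PC|Ch)\\)([0-9]+)$",
                                spec))[[1]]
  if (length(m)) {
    return(list(family = m[3], normalized = m[2] == "N",
                property = NA_character_, stype = m[4],
                order = as.integer(m[5]), group = NA_character_,
                string = spec))
  }
  m <- regmatches(spec, regexec("^ASq([0-9])\\(([A-Za-z]+)\\)(G|Y|C|M|A)$",
                                spec))[[1]]
  if (length(m)) {
    prop <- match.arg(m[3], .property_codes)
    return(list(family = "ASq", normalized = FALSE, property = prop,
                stype = NA_character_, order = as.integer(m[2]),
                group = m[4], string = spec))
  }
  stop("cannot parse descriptor spec: '", spec, "'")
}

#' Format a parsed descriptor spec back to its string form
#' @param x a parsed spec (list as returned by [parse_descriptor_spec()]).
#' @return The spec string.
#' @export
format_descriptor_spec <- function(x) {
  if (x$family == "ASq") {
    sprintf("ASq%d(%s)%s", x$order, x$property, x$group)
  } else if (x$family == "SM") {
    sprintf("%sSM(%s)%d", if (x$normalized) "N" else "", x$property, x$order)
  } else {
    sprintf("%s%s(%s)%d", if (x$normalized) "N" else "", x$family, x$stype,
            x$order)
  }
}

#' Compute one raw descriptor value for a molecule
#'
#' @param g a `mol_graph`.
#' @param spec a spec string or parsed spec.
#' @param cache optional environment reused across specs of the same molecule
#'   (caches property vectors, subgraph enumerations and matrix powers).
#' @return A single numeric value.
#' @export
#' @examples
#' calc_descriptor(parse_smiles("CCCC"), "X(P)1")  # 1.9142
calc_descriptor <- function(g, spec, cache = NULL) {
  if (is.character(spec)) spec <- parse_descriptor_spec(spec)
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  val <- switch(spec$family,
    SM = {
      B <- cached(cache, paste0("B_", spec$property),
                  bond_adjacency(g, spec$property))
      spectral_moment(B, spec$order)
    },
    X = connectivity_index(g, spec$stype, spec$order, variant = "simple",
                           cache = cache),
    Xv = connectivity_index(g, spec$stype, spec$order, variant = "valence",
                            cache = cache),
    e = edge_connectivity_index(g, spec$stype, spec$order, cache = cache),
    ASq = {
      x <- cached(cache, paste0("prop_", spec$property),
                  assign_properties(g, spec$property))
      grp <- cached(cache, "groups", atom_groups(g))
      local_quadratic_index(g, x, spec$order, spec$group, cache = cache)
    })
  if (spec$normalized) val <- normalize_descriptor(val, g$nB)
  val
}

cached <- function(cache, key, value) {
  if (is.null(cache[[key]])) cache[[key]] <- value
  cache[[key]]
}

#' Size normalization of a topological descriptor
#'
#' Divides a raw invariant by the number of bonds (ignoring multiplicity),
#' producing a size-independent descriptor.
#'
#' @param ti raw descriptor value.
#' @param nB bond count; must be >= 1.
#' @return `ti / nB`.
#' @export
normalize_descriptor <- function(ti, nB) {
  if (!is.numeric(nB) || length(nB) != 1L || nB < 1) {
    stop("size normalization undefined: nB must be >= 1")
  }
  ti / nB
}

#' Compute a descriptor matrix for a set of molecules
#'
#' @param graphs list of `mol_graph` objects (or a character vector of SMILES,
#'   parsed on the fly).
#' @param specs character vector of spec strings (defaults to the raw
#'   invariants of bundled Model 1).
#' @return Numeric matrix, molecules x specs, with molecule ids as row names.
#' @export
#' @examples
#' compute_descriptors("CCO", c("X(P)1", "NSM(Ato)1"))
compute_descriptors <- function(graphs, specs = model_descriptor_set(1)$spec) {
  if (is.character(graphs)) {
    graphs <- lapply(graphs, parse_smiles)
  }
  if (inherits(graphs, "mol_graph")) graphs <- list(graphs)
  parsed <- lapply(specs, parse_descriptor_spec)
  out <- matrix(NA_real_, nrow = length(graphs), ncol = length(specs),
                dimnames = list(vapply(graphs, `[[`, "", "id"), specs))
  for (i in seq_along(graphs)) {
    cache <- new.env(parent = emptyenv())
    for (j in seq_along(parsed)) {
      out[i, j] <- calc_descriptor(graphs[[i]], parsed[[j]], cache = cache)
    }
  }
  out
}
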