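# The two-step Box-Jenkins (moving-average deviation) transform.
#
# Step 1: for every value e of every condition element (ma, tg, ei,
# separately), average each raw descriptor over the *training actives*
# assayed under e. Step 2: re-express each case's raw descriptor as
#   D = (GTI - avg(GTI)_e) / (std(GTI) * ps(e))
# where std(GTI) is the (sample) standard deviation of the descriptor over
# the whole training set and ps(e) = n(e)/NT(e) is the a-priori probability
# of an active among the training cases of e. D measures how much a chemical
# deviates, structurally and physicochemically, from the chemicals assayed
# under the same condition element, on a scale that shrinks as the element
# gets easier (higher active prevalence).

.element_kinds <- c("ma", "tg", "ei")

#' Fit the condition-element statistics of the Box-Jenkins transform
#'
#' Computes, per condition-element value: the per-descriptor average over
#' training actives, the active count `n`, total count `NT` and prior
#' `ps = n/NT`; plus the per-descriptor standard deviation over all training
#' cases (sample formula, n-1 denominator). Fails when an element value has
#' zero training actives (ps would be 0) or a descriptor is constant on the
#' training set (std 0).
#'
#' @param records training records (annotated with `ia`).
#' @param gti numeric matrix of raw descriptors, one row per record (row
#'   order must match `records`).
#' @return An object of class `bj_stats`.
#' @export
fit_box_jenkins <- function(records, gti) {
  stopifnot(nrow(records) == nrow(gti))
  if (is.null(records$ia)) stop("records must be annotated (column 'ia')")
  if (nrow(records) < 2L) stop("need at least 2 training cases")
  gti <- as.matrix(gti)
  std <- apply(gti, 2, stats::sd)
  zero <- std <= 0 | !is.finite(std)
  if (any(zero)) {
    stop("zero/undefined training standard deviation for descriptor(s): ",
         paste(colnames(gti)[zero], collapse = ", "))
  }
  elements <- lapply(.element_kinds, function(kind) {
    vals <- unique(records[[kind]])
    avg <- matrix(NA_real_, length(vals), ncol(gti),
                  dimnames = list(vals, colnames(gti)))
    n <- NT <- stats::setNames(integer(length(vals)), vals)
    for (v in vals) {
      in_e <- records[[kind]] == v
      act <- in_e & records$ia == 1L
      n[v] <- sum(act)
      NT[v] <- sum(in_e)
      if (n[v] == 0L) {
        stop("element '", v, "' of kind '", kind,
             "' has zero training actives (ps = 0)")
      }
      avg[v, ] <- colMeans(gti[act, , drop = FALSE])
    }
    list(values = vals, avg = avg, n = n, NT = NT, ps = n / NT)
  })
  names(elements) <- .element_kinds
  structure(list(std = std, elements = elements, specs = colnames(gti),
                 n_train = nrow(records)),
            class = "bj_stats")
}

#' @export
print.bj_stats <- function(x, ...) {
  cat("Box-Jenkins statistics: ", length(x$specs), " descriptors, fitted on ",
      x$n_train, " training cases\n", sep = "")
  for (kind in .element_kinds) {
    cat("  ", kind, ": ", length(x$elements[[kind]]$values),
        " element value(s)\n", sep = "")
  }
  invisible(x)
}

#' Apply the Box-Jenkins deviation transform
#'
#' Produces the feature matrix of deviation descriptors. Each configured
#' (spec, suffix) pair contributes one column, named
#' `D(<spec>)<suffix>`; the deviation of a record is taken against the
#' statistics of the record's own value of that condition element. Element
#' values unseen at fitting time are an error (no silent imputation).
#'
#' @param records records to transform (any split).
#' @param gti raw descriptor matrix aligned with `records`.
#' @param stats fitted `bj_stats`.
#' @param feature_map data frame with columns `spec` and `suffix` (e.g. a
#'   bundled set from [model_descriptor_set()]). Defaults to every descriptor
#'   crossed with every element kind.
#' @return Numeric feature matrix, rows aligned with `records`.
#' @export
bj_transform <- function(records, gti, stats,
                         feature_map = NULL) {
  stopifnot(inherits(stats, "bj_stats"), nrow(records) == nrow(gti))
  gti <- as.matrix(gti)
  if (is.null(feature_map)) {
    feature_map <- expand.grid(spec = stats$specs, suffix = .element_kinds,
                               stringsAsFactors = FALSE)
  }
  bad <- setdiff(feature_map$spec, stats$specs)
  if (length(bad)) stop("descriptor(s) not in fitted stats: ",
                        paste(bad, collapse = ", "))
  out <- matrix(NA_real_, nrow(records), nrow(feature_map))
  colnames(out) <- paste0("D(", feature_map$spec, ")", feature_map$suffix)
  for (f in seq_len(nrow(feature_map))) {
    spec <- feature_map$spec[f]
    kind <- feature_map$suffix[f]
    el <- stats$elements[[kind]]
    ev <- records[[kind]]
    idx <- match(ev, el$values)
    if (anyNA(idx)) {
      stop("unseen ", kind, " element value(s): ",
           paste(unique(ev[is.na(idx)]), collapse = ", "))
    }
    out[, f] <- (gti[, spec] - el$avg[idx, spec]) /
      (stats$std[spec] * el$ps[idx])
  }
  out
}
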