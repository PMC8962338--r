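# Model interpretation (class propensities, sensitivity values) and
# multi-condition screening of candidate molecules.

#' Class-based descriptor means and propensity directions
#'
#' Per feature: the mean over actives, the mean over inactives, and the
#' propensity — `Increase` when the active mean exceeds the inactive mean
#' (raising the descriptor should favor activity), `Decrease` when it is
#' lower, `Tie` when equal.
#'
#' @param features feature matrix.
#' @param labels 1/-1 labels; both classes must be present.
#' @param feature_names columns to report (default all).
#' @return Data frame with columns `feature`, `mean_active`,
#'   `mean_inactive`, `propensity`.
#' @export
class_propensities <- function(features, labels,
                               feature_names = colnames(features)) {
  features <- as.matrix(features)
  if (!any(labels == 1) || !any(labels == -1)) {
    stop("both classes must be present")
  }
  ma_ <- colMeans(features[labels == 1, feature_names, drop = FALSE])
  mi_ <- colMeans(features[labels == -1, feature_names, drop = FALSE])
  data.frame(feature = feature_names, mean_active = unname(ma_),
             mean_inactive = unname(mi_),
             propensity = propensity_direction(ma_, mi_),
             stringsAsFactors = FALSE)
}

#' Propensity sign rule
#'
#' @param mean_active,mean_inactive class-based means (vectorized).
#' @return `"Increase"`, `"Decrease"` or `"Tie"` per pair.
#' @export
propensity_direction <- function(mean_active, mean_inactive) {
  ifelse(mean_active > mean_inactive, "Increase",
         ifelse(mean_active < mean_inactive, "Decrease", "Tie"))
}

#' Descriptor sensitivity values by mean-substitution
#'
#' The importance of each feature is the ratio of the classification error
#' obtained after clamping that feature's column to its training mean over
#' the baseline error (errors measured on the supplied data). Uninformative
#' features give SV near 1; larger SV means the model leans on the feature.
#' With a zero baseline error the ratio is undefined: SVs are returned as
#' `NA`, ranking falls back to the perturbed error, and the report is
#' flagged.
#'
#' @param model a `ptml_classifier`.
#' @param features feature matrix (training data for the reference usage).
#' @param labels true 1/-1 labels.
#' @return Data frame with columns `feature`, `sv`, `perturbed_error`,
#'   `rank`, plus attributes `baseline_error` and `baseline_zero`.
#' @export
sensitivity_values <- function(model, features, labels) {
  features <- as.matrix(features)
  base_err <- mean(predict(model, features)$label != labels)
  perr <- vapply(model$features, function(f) {
    Xp <- features
    Xp[, f] <- model$feature_means[f]
    mean(predict(model, Xp)$label != labels)
  }, numeric(1))
  sv <- if (base_err > 0) perr / base_err else rep(NA_real_, length(perr))
  out <- data.frame(feature = model$features, sv = unname(sv),
                    perturbed_error = unname(perr), stringsAsFactors = FALSE)
  ord <- if (base_err > 0) order(-out$sv, out$feature)
         else order(-out$perturbed_error, out$feature)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "baseline_error") <- base_err
  attr(out, "baseline_zero") <- base_err == 0
  out
}

# feature map (spec + suffix) recovered from D(<spec>)<suffix> feature names
feature_map_from_names <- function(feature_names) {
  m <- regmatches(feature_names,
                  regexec("^D\\((.+)\\)(ma|tg|ei)$", feature_names))
  bad <- lengths(m) == 0
  if (any(bad)) stop("not deviation-feature name(s): ",
                     paste(feature_names[bad], collapse = ", "))
  data.frame(spec = vapply(m, `[[`, "", 2),
             suffix = vapply(m, `[[`, "", 3), stringsAsFactors = FALSE)
}

#' Screen candidate molecules across experimental conditions
#'
#' Computes each molecule's raw descriptors once, deviates them against every
#' condition in the table with the fitted Box-Jenkins statistics, and scores
#' each (molecule, condition) case with the classifier. The applicability
#' domain is evaluated per case; out-of-domain predictions are still
#' reported, flagged. A second classifier can be attached as a concordance
#' filter: its probability and label are reported alongside.
#'
#' @param molecules character vector of SMILES or list of `mol_graph`s.
#' @param model a `ptml_classifier` trained on deviation features.
#' @param stats the `bj_stats` the model's features were built with.
#' @param conditions condition table (default the bundled 44-condition
#'   panel).
#' @param filter_model optional second `ptml_classifier` (with `filter_stats`
#'   its own `bj_stats`, defaulting to `stats`).
#' @param filter_stats see `filter_model`.
#' @return Data frame with one row per molecule x condition: `id`, `ma`,
#'   `tg`, `ei`, `prob_active`, `label`, `tsad`, `in_ad` (and
#'   `filter_prob`/`filter_label`/`filter_in_ad` when a filter model is
#'   given); attribute `summary` holds the per-molecule fraction of
#'   conditions predicted active.
#' @export
screen_molecules <- function(molecules, model, stats,
                             conditions = ptml_conditions(),
                             filter_model = NULL, filter_stats = stats) {
  if (is.character(molecules)) molecules <- lapply(molecules, parse_smiles)
  if (inherits(molecules, "mol_graph")) molecules <- list(molecules)
  if (!nrow(conditions)) stop("empty condition table")
  fmap <- feature_map_from_names(model$features)
  gti <- compute_descriptors(molecules, unique(fmap$spec))
  fmap_f <- gti_f <- NULL
  if (!is.null(filter_model)) {
    fmap_f <- feature_map_from_names(filter_model$features)
    gti_f <- compute_descriptors(molecules, unique(fmap_f$spec))
  }
  res <- vector("list", length(molecules))
  for (i in seq_along(molecules)) {
    id <- molecules[[i]]$id
    pseudo <- conditions[, c("ma", "tg", "ei")]
    X <- bj_transform(pseudo, gti[rep(i, nrow(pseudo)), , drop = FALSE],
                      stats, feature_map = fmap)
    pr <- predict(model, X)
    ad <- tsad(model, X)
    row <- data.frame(id = id, pseudo, prob_active = pr$prob_active,
                      label = pr$label, tsad = ad$tsad, in_ad = ad$in_ad,
                      stringsAsFactors = FALSE)
    if (!is.null(filter_model)) {
      Xf <- bj_transform(pseudo, gti_f[rep(i, nrow(pseudo)), , drop = FALSE],
                         filter_stats, feature_map = fmap_f)
      prf <- predict(filter_model, Xf)
      adf <- tsad(filter_model, Xf)
      row$filter_prob <- prf$prob_active
      row$filter_label <- prf$label
      row$filter_in_ad <- adf$in_ad
    }
    res[[i]] <- row
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  summ <- aggregate(label ~ id, out, function(l) mean(l == 1))
  names(summ)[2] <- "fraction_active"
  attr(out, "summary") <- summ
  out
}
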