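# Feature ranking and selection, MLP/LDA classifiers, global and
# per-condition metrics, and the range-based applicability domain (TSAD).

# entropy of a probability vector (natural log); 0*log(0) = 0
shannon_entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

# Jeffreys divergence between two discrete distributions
jeffreys_divergence <- function(p, q) {
  keep <- p > 0 | q > 0
  p <- p[keep]; q <- q[keep]
  if (any(p == 0) || any(q == 0)) return(Inf)
  sum((p - q) * log(p / q))
}

# MI-DSE: mutual information between class and bin under equal class priors,
# written as a differential Shannon entropy H(mix) - mean of class entropies
mi_dse <- function(p, q) {
  shannon_entropy((p + q) / 2) - (shannon_entropy(p) + shannon_entropy(q)) / 2
}

#' Rank deviation descriptors by class-discrimination
#'
#' For each feature, class-conditional histograms (equal-width bins over the
#' pooled range, Laplace-smoothed) are compared between actives and
#' inactives with two entropy criteria: the mutual-information differential
#' Shannon entropy (MI-DSE, primary key) and the Jeffreys divergence
#' \eqn{\sum (p-q)\ln(p/q)} (tie-break). Constant features score 0.
#'
#' @param features numeric feature matrix.
#' @param labels vector of 1/-1 labels.
#' @param bins histogram bins (default 24).
#' @param alpha Laplace smoothing pseudo-count (default 1).
#' @return An object of class `feature_ranking`: a data frame with columns
#'   `feature`, `mi_dse`, `jeffreys`, `rank`, ordered by rank.
#' @export
rank_features <- function(features, labels, bins = 24, alpha = 1) {
  features <- as.matrix(features)
  stopifnot(nrow(features) == length(labels))
  act <- labels == 1
  if (sum(act) < 2 || sum(!act) < 2) {
    stop("need at least 2 cases per class")
  }
  scores <- t(vapply(seq_len(ncol(features)), function(j) {
    x <- features[, j]
    rng <- range(x)
    if (diff(rng) == 0) return(c(0, 0))
    breaks <- seq(rng[1], rng[2], length.out = bins + 1)
    bin <- pmin(pmax(findInterval(x, breaks, rightmost.closed = TRUE), 1L),
                bins)
    ca <- tabulate(bin[act], nbins = bins)
    ci <- tabulate(bin[!act], nbins = bins)
    p <- (ca + alpha) / (sum(ca) + alpha * bins)
    q <- (ci + alpha) / (sum(ci) + alpha * bins)
    c(mi_dse(p, q), jeffreys_divergence(p, q))
  }, numeric(2)))
  out <- data.frame(feature = colnames(features), mi_dse = scores[, 1],
                    jeffreys = scores[, 2], stringsAsFactors = FALSE)
  ord <- order(-out$mi_dse, -out$jeffreys, out$feature)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("feature_ranking", "data.frame")
  out
}

feature_suffix <- function(feature) {
  m <- regmatches(feature, regexec("\\)(ma|tg|ei)$", feature))
  vapply(m, function(x) if (length(x)) x[2] else NA_character_, "")
}

#' Greedy non-redundant feature selection
#'
#' Walks the ranking in order, admitting a feature only when its absolute
#' Pearson correlation with every already-admitted feature stays below
#' `pcc_bound`, up to `size` features. Features carry a condition-element
#' suffix (`ma`/`tg`/`ei`); having at least one feature per element kind is
#' mandatory, so under-represented kinds displace the lowest-ranked
#' redundant admissions if needed.
#'
#' @param ranking a `feature_ranking` from [rank_features()].
#' @param features the feature matrix the ranking was computed on.
#' @param size target number of features (default 15).
#' @param pcc_bound redundancy bound on |PCC| (default 0.7).
#' @param require_suffixes element kinds that must be represented (default
#'   `ma`, `tg`, `ei`; kinds absent from all feature names are not required).
#' @return Character vector of selected feature names (rank order).
#' @export
select_features <- function(ranking, features, size = 15, pcc_bound = 0.7,
                            require_suffixes = c("ma", "tg", "ei")) {
  features <- as.matrix(features)
  feats <- ranking$feature
  sfx <- feature_suffix(feats)
  absent <- setdiff(require_suffixes, sfx)
  if (length(absent)) {
    stop("cannot satisfy the mandatory per-element constraint: no candidate ",
         "features for kind(s) ", paste(absent, collapse = ", "))
  }
  admissible <- function(cand, sel) {
    !length(sel) ||
      all(abs(suppressWarnings(
        stats::cor(features[, cand], features[, sel, drop = FALSE])
      )) < pcc_bound, na.rm = FALSE)
  }
  sel <- character(0)
  for (f in feats) {
    if (length(sel) >= size) break
    ok <- admissible(f, sel)
    if (isTRUE(ok) && !is.na(ok)) sel <- c(sel, f)
  }
  # enforce the mandatory per-element-kind representation
  for (kind in require_suffixes) {
    if (kind %in% feature_suffix(sel)) next
    cands <- feats[sfx == kind & !feats %in% sel]
    placed <- FALSE
    for (cand in cands) {
      sel_try <- sel
      if (length(sel_try) >= size) {
        # displace the lowest-ranked feature of an over-represented kind
        sfx_sel <- feature_suffix(sel_try)
        counts <- table(sfx_sel)
        redundant <- which(counts[sfx_sel] > 1 | is.na(sfx_sel))
        drop_idx <- if (length(redundant)) max(redundant) else length(sel_try)
        sel_try <- sel_try[-drop_idx]
      }
      if (isTRUE(admissible(cand, sel_try))) {
        sel <- c(sel_try, cand)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop("cannot satisfy the mandatory per-element constraint for kind(s): ",
           kind)
    }
  }
  sel[order(match(sel, feats))]
}

#' Classification metrics from per-class counts
#'
#' Sensitivity, specificity, accuracy (percent) and the Matthews correlation
#' coefficient from the numbers of active/inactive cases and how many of each
#' were correctly classified. The MCC denominator-zero case returns 0.
#'
#' @param n_active,ccc_active actives and correctly classified actives.
#' @param n_inactive,ccc_inactive inactives and correctly classified
#'   inactives.
#' @return List with `n_active`, `ccc_active`, `n_inactive`, `ccc_inactive`,
#'   `sn`, `sp`, `ac` (percent) and `mcc`.
#' @export
#' @examples
#' metrics_from_counts(3010, 2495, 4273, 3817)
metrics_from_counts <- function(n_active, ccc_active, n_inactive,
                                ccc_inactive) {
  stopifnot(ccc_active <= n_active, ccc_inactive <= n_inactive,
            ccc_active >= 0, ccc_inactive >= 0)
  tp <- ccc_active; fn <- n_active - ccc_active
  tn <- ccc_inactive; fp <- n_inactive - ccc_inactive
  denom <- sqrt((tp + fp)) * sqrt((tp + fn)) * sqrt((tn + fp)) *
    sqrt((tn + fn))
  mcc <- if (denom == 0) 0 else (tp * tn - fp * fn) / denom
  list(n_active = n_active, ccc_active = ccc_active,
       n_inactive = n_inactive, ccc_inactive = ccc_inactive,
       sn = 100 * tp / n_active, sp = 100 * tn / n_inactive,
       ac = 100 * (tp + tn) / (n_active + n_inactive), mcc = mcc)
}

#' Train an MLP or LDA classifier with a range applicability domain
#'
#' The MLP is a single-hidden-layer perceptron (logistic hidden units,
#' softmax/cross-entropy output, full-batch BFGS optimization via
#' \pkg{nnet}), deterministic for a given seed; the LDA baseline
#' (\pkg{MASS}) is fitted on the same features. The training ranges
#' (closed `[min, max]` per feature) are stored as the model's applicability
#' domain, and the training means are kept for sensitivity analysis.
#'
#' @param features numeric feature matrix (selected features only).
#' @param labels 1/-1 labels; both classes must be present.
#' @param algorithm `"mlp"` or `"lda"`.
#' @param hidden hidden-layer width for the MLP (default 45).
#' @param seed integer seed controlling weight initialization.
#' @param maxit maximum optimizer iterations (default 500).
#' @param decay weight decay for the MLP (default 1e-3).
#' @return An object of class `ptml_classifier`.
#' @export
train_classifier <- function(features, labels,
                             algorithm = c("mlp", "lda"), hidden = 45,
                             seed = 101L, maxit = 500, decay = 1e-3) {
  algorithm <- match.arg(algorithm)
  features <- as.matrix(features)
  stopifnot(nrow(features) == length(labels))
  if (length(unique(labels)) < 2) {
    stop("training labels contain a single class")
  }
  if (algorithm == "mlp" && (!is.numeric(hidden) || hidden < 1)) {
    stop("hidden-layer width must be >= 1")
  }
  yf <- factor(ifelse(labels == 1, "active", "inactive"),
               levels = c("inactive", "active"))
  fit <- if (algorithm == "mlp") {
    withr::with_seed(as.integer(seed), {
      nnet::nnet(x = features, y = nnet::class.ind(yf), size = hidden,
                 softmax = TRUE, maxit = maxit, decay = decay,
                 trace = FALSE, MaxNWts = 1e5)
    })
  } else {
    MASS::lda(features, grouping = yf)
  }
  structure(list(algorithm = algorithm, fit = fit,
                 features = colnames(features), hidden = hidden,
                 seed = as.integer(seed),
                 ad = rbind(min = apply(features, 2, min),
                            max = apply(features, 2, max)),
                 feature_means = colMeans(features)),
            class = "ptml_classifier")
}

#' @export
print.ptml_classifier <- function(x, ...) {
  d <- length(x$features)
  topo <- if (x$algorithm == "mlp") {
    paste0("MLP ", d, "-", x$hidden, "-2")
  } else {
    paste0("LDA on ", d, " features")
  }
  cat("ptml_classifier: ", topo, "\n", sep = "")
  invisible(x)
}

#' Predict active-class probabilities and labels
#'
#' @param object a `ptml_classifier`.
#' @param newdata feature matrix with the model's feature columns.
#' @param ... unused.
#' @return Data frame with columns `prob_active` and `label` (1/-1 at the
#'   0.5 probability threshold).
#' @export
predict.ptml_classifier <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  miss <- setdiff(object$features, colnames(newdata))
  if (length(miss)) stop("missing feature column(s): ",
                         paste(miss, collapse = ", "))
  X <- newdata[, object$features, drop = FALSE]
  prob <- if (object$algorithm == "mlp") {
    stats::predict(object$fit, X)[, "active"]
  } else {
    stats::predict(object$fit, X)$posterior[, "active"]
  }
  data.frame(prob_active = as.numeric(prob),
             label = ifelse(prob >= 0.5, 1L, -1L))
}

#' Evaluate a classifier globally and per condition element
#'
#' Global sensitivity/specificity/accuracy/MCC plus, when `conditions` is
#' given, local Sn/Sp tables computed on the subset of cases sharing each
#' value of each condition element (ma, tg, ei). Element values lacking
#' cases of the relevant class get `NA` there.
#'
#' @param model a `ptml_classifier`.
#' @param features evaluation feature matrix.
#' @param labels true 1/-1 labels.
#' @param conditions optional data frame with columns `ma`, `tg`, `ei`
#'   aligned with `features`.
#' @return An object of class `ptml_report`: list with `global` (see
#'   [metrics_from_counts()]) and `local` (per-kind data frames or `NULL`).
#' @export
evaluate_model <- function(model, features, labels, conditions = NULL) {
  if (!nrow(as.matrix(features))) stop("empty evaluation set")
  pred <- predict(model, features)$label
  rep_counts <- function(obs, prd) {
    metrics_from_counts(sum(obs == 1), sum(obs == 1 & prd == 1),
                        sum(obs == -1), sum(obs == -1 & prd == -1))
  }
  global <- rep_counts(labels, pred)
  local <- NULL
  if (!is.null(conditions)) {
    local <- lapply(.element_kinds, function(kind) {
      vals <- unique(conditions[[kind]])
      do.call(rbind, lapply(vals, function(v) {
        in_e <- conditions[[kind]] == v
        na_ <- sum(labels[in_e] == 1)
        ni_ <- sum(labels[in_e] == -1)
        data.frame(
          value = v, n_active = na_, n_inactive = ni_,
          sn = if (na_ > 0) 100 * sum(in_e & labels == 1 & pred == 1) / na_
               else NA_real_,
          sp = if (ni_ > 0) 100 * sum(in_e & labels == -1 & pred == -1) / ni_
               else NA_real_,
          stringsAsFactors = FALSE)
      }))
    })
    names(local) <- .element_kinds
  }
  structure(list(global = global, local = local,
                 algorithm = model$algorithm), class = "ptml_report")
}

#' @export
print.ptml_report <- function(x, ...) {
  g <- x$global
  cat(sprintf(
    "ptml_report (%s): N_a=%d CCC_a=%d N_i=%d CCC_i=%d | Sn=%.2f%% Sp=%.2f%% Ac=%.2f%% MCC=%.3f\n",
    x$algorithm, g$n_active, g$ccc_active, g$n_inactive, g$ccc_inactive,
    g$sn, g$sp, g$ac, g$mcc))
  invisible(x)
}

#' Total score of the applicability domain (TSAD)
#'
#' Counts, per case, how many of the model's features fall inside their
#' closed training `[min, max]` interval. A case is inside the applicability
#' domain exactly when its TSAD equals the number of features.
#'
#' @param model a `ptml_classifier` (carries the training ranges).
#' @param features feature matrix to score.
#' @return Data frame with columns `tsad` and `in_ad`.
#' @export
tsad <- function(model, features) {
  features <- as.matrix(features)
  miss <- setdiff(model$features, colnames(features))
  if (length(miss)) stop("missing feature column(s): ",
                         paste(miss, collapse = ", "))
  X <- features[, model$features, drop = FALSE]
  d <- length(model$features)
  inside <- sweep(X, 2, model$ad["min", ], ">=") &
    sweep(X, 2, model$ad["max", ], "<=")
  score <- rowSums(inside)
  data.frame(tsad = as.integer(score), in_ad = score == d)
}
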