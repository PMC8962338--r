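# End-to-end pipeline: curation -> descriptors -> deviation features ->
# feature selection -> MLP + LDA -> evaluation, AD and interpretation.

#' Run the full modeling pipeline
#'
#' Chains every stage on a bioactivity table: curation (dedup, labeling,
#' stratified split), raw-descriptor computation for the chosen bundled
#' descriptor model, Box-Jenkins deviation features fitted on the training
#' series, MI-DSE/Jeffreys ranking with PCC-bounded selection, MLP and LDA
#' training, evaluation with global and per-condition-element metrics, and
#' applicability-domain scoring. Stage logs (drop counts, split sizes,
#' selected features, metrics) are emitted as messages.
#'
#' @param records bioactivity data frame (or a file path readable by
#'   [read_bioactivity()]).
#' @param model bundled descriptor model, 1 (topological) or 2 (stochastic
#'   quadratic; default — polynomial cost in molecule size, where the
#'   Model-1 subgraph enumeration grows exponentially with subgraph order).
#' @param conditions condition/cutoff table (default the bundled panel).
#' @param test_fraction held-out fraction (default 0.25).
#' @param split_seed,train_seed seeds for the split and the MLP weights.
#' @param hidden MLP hidden-layer width (default 45).
#' @param select_size target feature count (default: the full descriptor
#'   set of the chosen model).
#' @param pcc_bound redundancy bound (default 0.7).
#' @param maxit,decay MLP optimizer settings.
#' @return A list of class `ptml_pipeline` with elements `records`, `gti`,
#'   `stats`, `features`, `ranking`, `selected`, `models` (mlp, lda),
#'   `reports` (per algorithm and split) and `ad` (training TSAD table).
#' @export
run_ptml_pipeline <- function(records, model = 2,
                              conditions = ptml_conditions(),
                              test_fraction = 0.25, split_seed = 2021L,
                              train_seed = 101L, hidden = 45,
                              select_size = NULL, pcc_bound = 0.7,
                              maxit = 500, decay = 1e-3) {
  if (is.character(records) && length(records) == 1L) {
    records <- read_bioactivity(records)
  } else if (is.null(records$canonical_smiles)) {
    records <- curate_bioactivity(records)
  }
  mset <- model_descriptor_set(model)
  if (is.null(select_size)) select_size <- nrow(mset)

  records <- deduplicate_records(records)
  records <- annotate_activity(records, cutoff_table(conditions))
  records <- split_dataset(records, test_fraction, seed = split_seed)
  train <- records$split == "train"
  message("split: ", sum(train), " training / ", sum(!train), " test cases (",
          sum(records$ia == 1), " actives overall)")

  # raw descriptors per distinct structure, expanded to cases
  uniq <- unique(records$canonical_smiles)
  graphs <- lapply(uniq, parse_smiles)
  gti_u <- compute_descriptors(graphs, mset$spec)
  gti <- gti_u[match(records$canonical_smiles, uniq), , drop = FALSE]
  rownames(gti) <- records$compound_id
  message("descriptors: ", ncol(gti), " invariants for ", length(uniq),
          " distinct structures")

  stats <- fit_box_jenkins(records[train, , drop = FALSE],
                           gti[train, , drop = FALSE])
  fmap <- mset[, c("spec", "suffix")]
  features <- bj_transform(records, gti, stats, feature_map = fmap)

  ranking <- rank_features(features[train, , drop = FALSE],
                           records$ia[train])
  selected <- select_features(ranking, features[train, , drop = FALSE],
                              size = select_size, pcc_bound = pcc_bound)
  message("selected ", length(selected), " features: ",
          paste(selected, collapse = ", "))

  Xtr <- features[train, selected, drop = FALSE]
  Xte <- features[!train, selected, drop = FALSE]
  ytr <- records$ia[train]
  yte <- records$ia[!train]
  mlp <- train_classifier(Xtr, ytr, "mlp", hidden = hidden,
                          seed = train_seed, maxit = maxit, decay = decay)
  lda <- train_classifier(Xtr, ytr, "lda")
  cond_cols <- records[, c("ma", "tg", "ei")]
  reports <- list(
    mlp_train = evaluate_model(mlp, Xtr, ytr, cond_cols[train, ]),
    mlp_test = evaluate_model(mlp, Xte, yte, cond_cols[!train, ]),
    lda_train = evaluate_model(lda, Xtr, ytr),
    lda_test = evaluate_model(lda, Xte, yte))
  for (nm in c("mlp_train", "mlp_test", "lda_train", "lda_test")) {
    g <- reports[[nm]]$global
    message(sprintf("%s: Sn=%.2f%% Sp=%.2f%% Ac=%.2f%% MCC=%.3f", nm,
                    g$sn, g$sp, g$ac, g$mcc))
  }
  structure(list(records = records, gti = gti, stats = stats,
                 features = features, ranking = ranking, selected = selected,
                 models = list(mlp = mlp, lda = lda), reports = reports,
                 ad = tsad(mlp, Xtr)),
            class = "ptml_pipeline")
}

#' @export
print.ptml_pipeline <- function(x, ...) {
  cat("ptml_pipeline: ", nrow(x$records), " cases, ",
      length(x$selected), " selected features\n", sep = "")
  for (nm in names(x$reports)) {
    g <- x$reports[[nm]]$global
    cat(sprintf("  %-9s Sn=%6.2f%% Sp=%6.2f%% Ac=%6.2f%% MCC=%.3f\n", nm,
                g$sn, g$sp, g$ac, g$mcc))
  }
  invisible(x)
}
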