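# Bioactivity-table curation: loading, deduplication, activity labeling and
# train/test splitting. A case is a chemical tested under one experimental
# condition, the triple (ma = activity measure, tg = target, ei = assay
# information); labels are dichotomous (1 active, -1 inactive) against a
# cutoff resolved per (ma, tg).

.bio_cols <- c("compound_id", "smiles", "ma", "tg", "ei", "value", "units")

#' Read and curate a bioactivity table
#'
#' Reads a CSV/TSV with columns `compound_id`, `smiles`, `ma`, `tg`, `ei`,
#' `value`, `units`. Rows missing SMILES, value or units, and rows with
#' non-positive values, are dropped and counted (see the `drop_counts`
#' attribute and the log message). Values must be in nM; a row with any other
#' non-missing unit is an error. SMILES are canonicalized into a
#' `canonical_smiles` column.
#'
#' @param path file path (delimiter inferred from the extension; `.tsv`/`.txt`
#'   read as tab-separated).
#' @param canonicalize add canonical SMILES (default `TRUE`).
#' @return Data frame of curated records with attribute `drop_counts`.
#' @export
read_bioactivity <- function(path, canonicalize = TRUE) {
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- tryCatch(
    utils::read.csv(path, sep = sep, stringsAsFactors = FALSE),
    error = function(e) stop("cannot read bioactivity table '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (nrow(df) == 0L) {
    warning("empty bioactivity table: ", path)
    df <- as.data.frame(stats::setNames(
      c(list(character(), character(), character(), character(), character()),
        list(numeric(), character())), .bio_cols))
    attr(df, "drop_counts") <- c(missing_smiles = 0L, missing_value = 0L,
                                 missing_units = 0L, nonpositive_value = 0L)
    return(df)
  }
  miss <- setdiff(.bio_cols, names(df))
  if (length(miss)) stop("bioactivity table lacks column(s): ",
                         paste(miss, collapse = ", "))
  curate_bioactivity(df, canonicalize = canonicalize)
}

#' Curate an in-memory bioactivity data frame
#'
#' Applies the same dropping/canonicalization rules as [read_bioactivity()].
#'
#' @param df data frame with the bioactivity schema.
#' @param canonicalize add canonical SMILES (default `TRUE`).
#' @return Curated data frame with attribute `drop_counts`.
#' @export
curate_bioactivity <- function(df, canonicalize = TRUE) {
  blank <- function(x) is.na(x) | !nzchar(trimws(as.character(x)))
  n0 <- nrow(df)
  m_smiles <- blank(df$smiles)
  m_value <- is.na(suppressWarnings(as.numeric(df$value)))
  m_units <- blank(df$units)
  keep <- !(m_smiles | m_value | m_units)
  bad_units <- keep & toupper(trimws(df$units)) != "NM"
  if (any(bad_units)) {
    stop("unknown units (only nM accepted): ",
         paste(unique(df$units[bad_units]), collapse = ", "))
  }
  df <- df[keep, , drop = FALSE]
  df$value <- as.numeric(df$value)
  nonpos <- df$value <= 0
  df <- df[!nonpos, , drop = FALSE]
  drops <- c(missing_smiles = sum(m_smiles),
             missing_value = sum(m_value & !m_smiles),
             missing_units = sum(m_units & !m_smiles & !m_value),
             nonpositive_value = sum(nonpos))
  if (canonicalize && nrow(df)) {
    df$canonical_smiles <- canonical_smiles(df$smiles)
  } else if (nrow(df)) {
    df$canonical_smiles <- df$smiles
  }
  rownames(df) <- NULL
  message("curated bioactivity table: kept ", nrow(df), " of ", n0,
          " rows (dropped ", n0 - nrow(df), ")")
  attr(df, "drop_counts") <- drops
  df
}

#' Remove duplicate cases, keeping the lowest activity value
#'
#' Among records sharing the same chemical (canonical SMILES) and experimental
#' condition, only the record with the minimum activity value survives; ties
#' keep the first-seen record.
#'
#' @param records curated bioactivity data frame (needs `canonical_smiles`).
#' @return Deduplicated data frame.
#' @export
deduplicate_records <- function(records) {
  if (!nrow(records)) return(records)
  if (is.null(records$canonical_smiles)) {
    records$canonical_smiles <- canonical_smiles(records$smiles)
  }
  key <- paste(records$canonical_smiles, records$ma, records$tg, records$ei,
               sep = "\r")
  pos <- seq_len(nrow(records))
  ord <- order(key, records$value, pos)  # stable first-seen tie-break
  keep_pos <- sort(pos[ord][!duplicated(key[ord])])
  out <- records[keep_pos, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cutoff table from a condition table
#'
#' @param conditions condition table (default the bundled 44-condition panel);
#'   must have columns `ma`, `tg`, `cutoff_nM`.
#' @return Data frame with one cutoff per (ma, tg) pair.
#' @export
cutoff_table <- function(conditions = ptml_conditions()) {
  ct <- unique(conditions[, c("ma", "tg", "cutoff_nM")])
  dup <- duplicated(ct[, c("ma", "tg")])
  if (any(dup)) stop("conflicting cutoffs for: ",
                     paste(ct$tg[dup], collapse = ", "))
  ct
}

#' Label cases active/inactive against activity cutoffs
#'
#' A case is active (`ia = 1`) when its value is less than or equal to the
#' cutoff resolved for its (ma, tg) pair, inactive (`ia = -1`) otherwise. The
#' boundary is inclusive.
#'
#' @param records curated bioactivity data frame.
#' @param cutoffs cutoff table from [cutoff_table()].
#' @return The records with an added integer column `ia`.
#' @export
annotate_activity <- function(records, cutoffs = cutoff_table()) {
  idx <- match(paste(records$ma, records$tg, sep = "\r"),
               paste(cutoffs$ma, cutoffs$tg, sep = "\r"))
  if (anyNA(idx)) {
    miss <- unique(paste0("(", records$ma[is.na(idx)], ", ",
                          records$tg[is.na(idx)], ")"))
    stop("no activity cutoff for condition(s): ", paste(miss, collapse = "; "))
  }
  records$ia <- ifelse(records$value <= cutoffs$cutoff_nM[idx], 1L, -1L)
  records
}

#' Stratified train/test split
#'
#' Assigns each record to the training or test series, stratifying by label
#' within each experimental condition (falling back to coarser strata when a
#' stratum is a single record). Reproducible for a given seed. Fails if any
#' condition-element value ends up with zero training actives, since the
#' deviation transform could not be fitted.
#'
#' @param records annotated data frame (needs `ia`).
#' @param test_fraction fraction of cases held out, in (0, 1); default 0.25.
#' @param seed integer seed.
#' @return The records with an added character column `split`
#'   (`"train"`/`"test"`).
#' @export
split_dataset <- function(records, test_fraction = 0.25, seed = 1L) {
  if (!is.numeric(test_fraction) || test_fraction <= 0 || test_fraction >= 1) {
    stop("test_fraction must be strictly between 0 and 1")
  }
  if (is.null(records$ia)) stop("records must be annotated (column 'ia')")
  n <- nrow(records)
  strata <- paste(records$ma, records$tg, records$ei, records$ia, sep = "\r")
  split <- rep("train", n)
  withr::with_seed(as.integer(seed), {
    for (s in unique(strata)) {
      idx <- which(strata == s)
      n_test <- floor(length(idx) * test_fraction + 0.5)
      n_test <- min(n_test, length(idx) - 1L)  # keep >= 1 in training
      if (n_test > 0) {
        split[sample(idx, n_test)] <- "test"
      }
    }
  })
  records$split <- split
  train <- records[records$split == "train", , drop = FALSE]
  for (kind in c("ma", "tg", "ei")) {
    vals <- unique(records[[kind]])
    n_act <- vapply(vals, function(v) {
      sum(train[[kind]] == v & train$ia == 1L)
    }, integer(1))
    if (any(n_act == 0L)) {
      stop("condition element(s) with zero training actives after split (",
           kind, ": ", paste(vals[n_act == 0L], collapse = ", "),
           "); re-split with another seed or merge elements")
    }
  }
  records
}
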