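# Reproducible synthetic multi-condition bioactivity data with planted
# structure-activity signal.
#
# Active-type molecules are assembled from heteroatom-rich motifs known to
# matter for the bundled models' descriptors (2-aminopyrimidine and
# 2-aminotriazine heads, urea/carbamide links, glycine-like chains,
# 4-halophenyl tails); inactive-type molecules are carbon-rich (alkyl chains,
# plain rings). Activity values are drawn log-normally around
# cutoff*(1 -/+ margin) on the correct side of the cutoff, with a hard
# margin so the cutoff labeling always recovers the planted label.

#' Default condition panel of the synthetic generator
#'
#' A compact subset of the bundled 44-condition table: three target proteins
#' under protein-format assays plus three pancreatic cell lines, spanning
#' both activity measures and four assay-information labels.
#'
#' @return Data frame with columns `ma`, `tg`, `ei`, `cutoff_nM`.
#' @export
synthetic_conditions <- function() {
  all44 <- ptml_conditions()
  pick <- rbind(
    c("IC50(nM)p", "Caspase-1", "B (single protein format)"),
    c("IC50(nM)p", "TNF-alpha", "B (single protein format)"),
    c("IC50(nM)p", "TNF-alpha", "F (assay format)"),
    c("IC50(nM)p", "IGF1R", "B (single protein format)"),
    c("IC50(nM)p", "IGF1R", "B (cell-based format)"),
    c("IC50(nM)c", "PSN1", "F (cell-based format)"),
    c("IC50(nM)c", "MIA-PaCa-2", "F (cell-based format)"),
    c("IC50(nM)c", "BxPC-3", "F (cell-based format)"))
  idx <- match(paste(pick[, 1], pick[, 2], pick[, 3]),
               paste(all44$ma, all44$tg, all44$ei))
  all44[idx, , drop = FALSE]
}

# fragment-grammar molecule pools (class-pure, chemically valid by assembly)
synthetic_pools <- function() {
  tails <- c("CCO", "CCN", "CO", "CN", "CCOC", "CCNC", "CC(C)O", "CCCO",
             "CCCN", "CCN(C)C")
  tails <- c(tails, paste0(tails, "C"))
  hal <- c("F", "Cl", "Br", "I")
  active <- c(
    sprintf("Nc1nc(N%s)ccn1", tails),                 # pyrimidin-2-amine
    as.vector(outer(tails, hal, function(t, h)
      sprintf("O=C(N%s)Nc1ccc(%s)cc1", t, h))),       # urea + 4-halophenyl
    sprintf("OC(=O)CN%s", tails),                     # glycine-like
    sprintf("Nc1nc(%s)nc(N)n1", tails),               # triazin-2-amine
    sprintf("NC(=O)N%s", tails),                      # carbamide tail
    sprintf("NNC(=O)%s", tails),                      # hydrazide
    sprintf("ONC(=O)%s", tails),                      # hydroxamic acid
    sprintf("NS(=O)(=O)c1ccc(%s)cc1", hal),           # 4-halobenzenesulfonamide
    sprintf("Nc1ccc(%s)cc1", hal))                    # 4-haloaniline
  inactive <- c(
    vapply(4:14, function(k) strrep("C", k), ""),
    sprintf("CC(C)%s", vapply(3:10, function(k) strrep("C", k), "")),
    sprintf("c1ccccc1%s", vapply(2:9, function(k) strrep("C", k), "")),
    sprintf("C1CCCCC1%s", vapply(2:9, function(k) strrep("C", k), "")),
    sprintf("CC(C)(C)%s", vapply(2:9, function(k) strrep("C", k), "")),
    sprintf("C=C%s", vapply(3:10, function(k) strrep("C", k), "")))
  list(active = unique(active), inactive = unique(inactive))
}

#' Synthetic-dataset configuration
#'
#' @param n_cases total number of cases (chemical-in-condition rows); spread
#'   as evenly as possible over the conditions. Chemicals may recur across
#'   conditions (as in real multi-condition panels) but never within one.
#' @param seed integer seed; fully determines the output.
#' @param conditions condition table with `cutoff_nM` (default
#'   [synthetic_conditions()]).
#' @param active_fraction per-condition fraction of planted actives, in
#'   (0, 1); default 0.4.
#' @param log_sigma log-scale spread of the activity-value noise (default
#'   0.25).
#' @param margin minimum relative distance of any value from its cutoff
#'   (default 0.2), so labels are stable under the noise model.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_cases = 200, seed = 42L,
                             conditions = synthetic_conditions(),
                             active_fraction = 0.4, log_sigma = 0.25,
                             margin = 0.2) {
  if (is.null(conditions) || !nrow(conditions)) {
    stop("synthetic config needs at least one condition")
  }
  if (active_fraction <= 0 || active_fraction >= 1) {
    stop("active_fraction must be in (0, 1)")
  }
  if (margin <= 0 || margin >= 1) stop("margin must be in (0, 1)")
  structure(list(n_cases = n_cases, seed = as.integer(seed),
                 conditions = conditions, active_fraction = active_fraction,
                 log_sigma = log_sigma, margin = margin),
            class = "synthetic_config")
}

#' Generate a synthetic multi-condition bioactivity table
#'
#' Deterministic for a given seed. Every condition receives at least two
#' planted actives and two planted inactives; the value noise never crosses
#' the cutoff, so [annotate_activity()] recovers the planted labels exactly.
#' The planted labels are attached as attribute `truth`.
#'
#' @param config a [synthetic_config()].
#' @return Bioactivity data frame (`compound_id`, `smiles`, `ma`, `tg`,
#'   `ei`, `value`, `units`) with attribute `truth`.
#' @export
#' @examples
#' head(generate_bioactivity(synthetic_config(n_cases = 40)))
generate_bioactivity <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  cond <- config$conditions
  nc <- nrow(cond)
  base <- config$n_cases %/% nc
  extra <- config$n_cases %% nc
  n_per <- rep(base, nc) + c(rep(1L, extra), rep(0L, nc - extra))
  n_act <- round(n_per * config$active_fraction)
  if (any(n_act < 2L) || any(n_per - n_act < 2L)) {
    stop("infeasible size/fraction: every condition needs >= 2 planted ",
         "actives and >= 2 planted inactives (smallest condition has ",
         min(n_per), " cases)")
  }
  pools <- synthetic_pools()
  if (max(n_act) > length(pools$active) ||
      max(n_per - n_act) > length(pools$inactive)) {
    stop("requested per-condition count exceeds the fragment-grammar pool")
  }
  rows <- vector("list", nc)
  withr::with_seed(config$seed, {
    for (k in seq_len(nc)) {
      act_smis <- sample(pools$active, n_act[k])
      inact_smis <- sample(pools$inactive, n_per[k] - n_act[k])
      cutoff <- cond$cutoff_nM[k]
      v_act <- cutoff * (1 - config$margin) *
        exp(-abs(stats::rnorm(n_act[k], 0, config$log_sigma)))
      v_inact <- cutoff * (1 + config$margin) *
        exp(abs(stats::rnorm(n_per[k] - n_act[k], 0, config$log_sigma)))
      rows[[k]] <- data.frame(
        smiles = c(act_smis, inact_smis),
        ma = cond$ma[k], tg = cond$tg[k], ei = cond$ei[k],
        value = c(v_act, v_inact), units = "nM",
        planted = rep(c(1L, -1L), c(n_act[k], n_per[k] - n_act[k])),
        stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  # stable chemical registry: one id per distinct structure
  uniq <- unique(out$smiles)
  out$compound_id <- sprintf("CHEM%04d", match(out$smiles, uniq))
  out <- out[, c("compound_id", "smiles", "ma", "tg", "ei", "value", "units",
                 "planted")]
  rownames(out) <- NULL
  truth <- out[, c("compound_id", "smiles", "ma", "tg", "ei", "planted")]
  out$planted <- NULL
  attr(out, "truth") <- truth
  out
}

#' Hand-checked micro dataset
#'
#' Eight tiny molecules over two experimental conditions, built for end-to-end
#' verification of the descriptor, labeling and deviation-transform
#' arithmetic. Every number it implies (path-connectivity values, training
#' standard deviation, element averages, priors and deviation features) was
#' derived by hand and frozen in the companion file
#' `inst/extdata/micro_expected.csv`.
#'
#' @return List with `records` (bioactivity data frame) and `expected` (the
#'   companion table of hand-derived values).
#' @export
generate_micro_dataset <- function() {
  records <- data.frame(
    compound_id = paste0("M", 1:8),
    smiles = c("CC", "CCC", "CCCC", "CC(C)C", "CCO", "CCCO", "CCN",
               "C1CCCCC1"),
    ma = rep(c("IC50(nM)p", "IC50(nM)c"), each = 4),
    tg = rep(c("IGF1R", "PSN1"), each = 4),
    ei = rep(c("B (single protein format)", "F (cell-based format)"),
             each = 4),
    value = c(10, 25, 200, 500, 1000, 2000, 20000, 50000),
    units = "nM", stringsAsFactors = FALSE)
  expected <- utils::read.csv(ptml_extdata("micro_expected.csv"),
                              comment.char = "#", stringsAsFactors = FALSE)
  list(records = records, expected = expected)
}
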