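make_table <- function(df) {
  path <- tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  path
}

test_that("curation drops incomplete rows and counts them", {
  df <- data.frame(
    compound_id = c("a", "b", "c"),
    smiles = c("CCO", "CCN", "CCC"),
    ma = "IC50(nM)p", tg = "IGF1R", ei = "B (single protein format)",
    value = c(10, 20, 30), units = c("nM", "", "nM"),
    stringsAsFactors = FALSE)
  rec <- suppressMessages(read_bioactivity(make_table(df)))
  expect_equal(nrow(rec), 2L)
  expect_equal(sum(attr(rec, "drop_counts")), 1L)
  expect_equal(unname(attr(rec, "drop_counts")["missing_units"]), 1L)

  # non-positive concentration rejected
  df$units <- "nM"; df$value[2] <- -5
  rec2 <- suppressMessages(read_bioactivity(make_table(df)))
  expect_equal(nrow(rec2), 2L)
  expect_equal(unname(attr(rec2, "drop_counts")["nonpositive_value"]), 1L)

  # unknown units are an error, not a silent drop
  df$value[2] <- 5; df$units[2] <- "uM"
  expect_error(suppressMessages(read_bioactivity(make_table(df))), "units")

  # empty file: empty record list plus a warning
  empty <- make_table(df[0, ])
  expect_warning(rec3 <- suppressMessages(read_bioactivity(empty)), "empty")
  expect_equal(nrow(rec3), 0L)
})

test_that("deduplication keeps the lowest value with stable tie-break", {
  df <- data.frame(
    compound_id = c("x1", "x2", "y1", "y2", "y3", "z"),
    smiles = c("CCO", "OCC", "CCN", "NCC", "CCN", "CCC"),
    ma = "IC50(nM)p", tg = "IGF1R", ei = "B (single protein format)",
    value = c(100, 50, 80, 20, 20, 10), units = "nM",
    stringsAsFactors = FALSE)
  rec <- suppressMessages(curate_bioactivity(df))
  dd <- deduplicate_records(rec)
  expect_equal(nrow(dd), 3L)
  expect_equal(dd$value[dd$canonical_smiles ==
                          canonical_smiles("CCO")], 50)
  # tie 20/20: first-seen record (compound y2) survives
  expect_equal(dd$compound_id[dd$canonical_smiles ==
                                canonical_smiles("CCN")], "y2")
  # single records pass through unchanged
  expect_equal(dd$value[dd$compound_id == "z"], 10)
})

test_that("activity labeling is boundary-inclusive per the cutoff table", {
  df <- data.frame(
    compound_id = c("a", "b", "c", "d"),
    smiles = "CCO",
    ma = c("IC50(nM)p", "IC50(nM)p", "IC50(nM)c", "IC50(nM)c"),
    tg = c("IGF1R", "IGF1R", "PSN1", "PSN1"),
    ei = c("B (single protein format)", "B (single protein format)",
           "F (cell-based format)", "F (cell-based format)"),
    value = c(50, 51, 6449.735, 6449.736), units = "nM",
    stringsAsFactors = FALSE)
  rec <- annotate_activity(suppressMessages(curate_bioactivity(df)))
  expect_equal(rec$ia, c(1L, -1L, 1L, -1L))
  # unknown (ma, tg) combination fails
  df$tg[1] <- "NotATarget"
  expect_error(annotate_activity(suppressMessages(curate_bioactivity(df))),
               "cutoff")
})

test_that("splitting is reproducible, stratified, and validates fractions", {
  bio <- generate_bioactivity(synthetic_config(n_cases = 120, seed = 11L))
  rec <- annotate_activity(suppressMessages(curate_bioactivity(bio)))
  s1 <- split_dataset(rec, 0.25, seed = 99L)
  s2 <- split_dataset(rec, 0.25, seed = 99L)
  expect_identical(s1$split, s2$split)
  expect_lt(abs(mean(s1$split == "test") - 0.25), 0.06)
  # per-stratum train proportions stay within one case of the overall split
  strata <- paste(rec$ma, rec$tg, rec$ei, rec$ia)
  for (st in unique(strata)) {
    idx <- strata == st
    n_test <- sum(s1$split[idx] == "test")
    expect_lte(abs(n_test - 0.25 * sum(idx)), 1)
  }
  expect_error(split_dataset(rec, 1.0), "between 0 and 1")
  expect_error(split_dataset(rec, 0), "between 0 and 1")
})

test_that("Box-Jenkins statistics follow the defining formulas", {
  rec <- data.frame(
    compound_id = paste0("m", 1:10), smiles = "CCO",
    ma = "IC50(nM)p", tg = rep(c("IGF1R", "TNF-alpha"), each = 5),
    ei = "B (single protein format)",
    value = 1, units = "nM",
    ia = c(1L, 1L, 1L, -1L, -1L, 1L, 1L, -1L, -1L, -1L),
    stringsAsFactors = FALSE)
  gti <- matrix(c(1, 3, 2, 10, 20, 1, 2, 3, 4, 30), ncol = 1,
                dimnames = list(NULL, "X(P)1"))
  st <- fit_box_jenkins(rec, gti)
  # ps: 3 actives of 5 / 2 of 5 per target; 5 of 10 for the shared ma
  expect_equal(unname(st$elements$tg$ps), c(3 / 5, 2 / 5))
  expect_equal(unname(st$elements$ma$ps), 0.5)
  # avg over actives: (1+3+2)/3 = 2 for IGF1R
  expect_equal(unname(st$elements$tg$avg["IGF1R", 1]), 2)
  # std over all training cases, sample formula
  expect_equal(unname(st$std), sd(gti[, 1]))
  # hand case from {1,2,3,4}
  rec4 <- rec[1:4, ]; rec4$tg <- "IGF1R"
  gti4 <- matrix(1:4, ncol = 1, dimnames = list(NULL, "g"))
  st4 <- fit_box_jenkins(rec4, gti4)
  expect_equal(unname(st4$std), 1.2909944487358056, tolerance = 1e-12)
})

test_that("the deviation transform matches Eq-style hand arithmetic", {
  rec <- data.frame(
    compound_id = paste0("m", 1:4), smiles = "CCO",
    ma = "A", tg = "T", ei = "E", value = 1, units = "nM",
    ia = c(1L, 1L, -1L, -1L), stringsAsFactors = FALSE)
  gti <- matrix(c(1, 3, 2, 4), ncol = 1, dimnames = list(NULL, "g"))
  st <- fit_box_jenkins(rec, gti)
  fm <- data.frame(spec = "g", suffix = "ma")
  D <- bj_transform(rec, gti, st, fm)
  # avg over actives = 2, std = 1.2910, ps = 0.5: case with GTI = 4 ->
  # (4-2)/(1.2910*0.5) = 3.0984; case with GTI = avg -> 0
  expect_equal(unname(D[4, 1]), 2 / (sd(c(1, 3, 2, 4)) * 0.5),
               tolerance = 1e-12)
  expect_equal(unname(round(D[4, 1], 4)), 3.0984)
  expect_equal(unname(D[3, 1]), 0)
  # unseen element value: hard error
  rec_new <- rec[1, ]; rec_new$tg <- "UNSEEN"
  fm_tg <- data.frame(spec = "g", suffix = "tg")
  expect_error(bj_transform(rec_new, gti[1, , drop = FALSE], st, fm_tg),
               "unseen")
})

test_that("deviations of training actives average to zero per element", {
  bio <- generate_bioactivity(synthetic_config(n_cases = 160, seed = 5L))
  rec <- annotate_activity(suppressMessages(curate_bioactivity(bio)))
  gti <- compute_descriptors(rec$smiles, c("ASq0(Hyd)Y", "ASq1(Aw)C"))
  st <- fit_box_jenkins(rec, gti)
  D <- bj_transform(rec, gti, st)
  for (kind in c("ma", "tg", "ei")) {
    for (v in unique(rec[[kind]])) {
      act <- rec[[kind]] == v & rec$ia == 1L
      cols <- grepl(paste0("\\)", kind, "$"), colnames(D))
      expect_lt(max(abs(colMeans(D[act, cols, drop = FALSE]))), 1e-9)
    }
  }
  # refitting on the same training data leaves the statistics unchanged
  st2 <- fit_box_jenkins(rec, gti)
  expect_equal(st2$std, st$std)
  expect_equal(st2$elements$tg$avg, st$elements$tg$avg)
})

test_that("micro fixture reproduces its hand-derived companion values", {
  md <- generate_micro_dataset()
  rec <- annotate_activity(suppressMessages(curate_bioactivity(md$records)))
  expect_identical(rec$ia, md$expected$ia)
  gti <- compute_descriptors(rec$smiles, "X(P)1")
  expect_equal(unname(gti[, 1]), md$expected$xp1, tolerance = 1e-12)
  st <- fit_box_jenkins(rec, gti)
  expect_equal(unname(st$std), 0.59912634870335235, tolerance = 1e-12)
  expect_true(all(unlist(lapply(st$elements, `[[`, "ps")) == 0.5))
  fm <- data.frame(spec = "X(P)1", suffix = c("ma", "tg", "ei"))
  D <- bj_transform(rec, gti, st, fm)
  for (j in 1:3) {
    expect_equal(unname(D[, j]), md$expected$d_value, tolerance = 1e-9)
  }
  # deviation is zero exactly where the raw value equals the element average
  expect_equal(which(abs(D[, 1]) < 1e-12),
               which(abs(md$expected$xp1 - md$expected$avg_element) < 1e-12))
})
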