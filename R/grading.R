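disease_levels <- c("NORMAL", "LOW", "HIGH")
histo_levels <- c("NORMAL", "CIN1", "CIN2", "CIN3")

disease_factor <- function(x) factor(x, levels = disease_levels, ordered = TRUE)

#' Three-class grading from the ENC ratio
#'
#' Applies the published threshold rule: NORMAL below 0.08, LOW between 0.08
#' and 0.18, HIGH above 0.18. The published bands are open at the cut points
#' (no case falls exactly on one); boundary values are assigned to the
#' higher-risk side, the clinically conservative choice. Both cut points are
#' configurable.
#'
#' @param enc Numeric vector of ENC ratios, each in (0, 1).
#' @param low_cut,high_cut Band edges (defaults 0.08 and 0.18).
#' @return Ordered factor with levels NORMAL < LOW < HIGH.
#' @export
classify_enc <- function(enc, low_cut = 0.08, high_cut = 0.18) {
  if (any(!is.finite(enc)) || any(enc <= 0 | enc >= 1)) {
    stop_validation("ENC ratio must lie in (0, 1)")
  }
  disease_factor(ifelse(enc < low_cut, "NORMAL",
                        ifelse(enc < high_cut, "LOW", "HIGH")))
}

#' Three-class grading from the 3NDND
#'
#' Published rule: NORMAL above 25 um, LOW between 21 and 25 um (inclusive,
#' following the published wording), HIGH below 21 um.
#'
#' @param d_um Numeric vector of 3NDND values (um, > 0).
#' @param low_cut,high_cut Band edges in um (defaults 21 and 25).
#' @return Ordered factor with levels NORMAL < LOW < HIGH.
#' @export
classify_nddn3 <- function(d_um, low_cut = 21, high_cut = 25) {
  if (any(!is.finite(d_um)) || any(d_um <= 0)) {
    stop_validation("3NDND must be > 0")
  }
  disease_factor(ifelse(d_um > high_cut, "NORMAL",
                        ifelse(d_um >= low_cut, "LOW", "HIGH")))
}

#' Collapse a histopathology grade to a disease group
#'
#' NORMAL stays NORMAL, CIN1 is low grade, CIN2 and CIN3 are high grade.
#' (Reactive atypia, when present in source data, should be recoded NORMAL
#' before calling.)
#'
#' @param g Character/factor vector of grades among NORMAL, CIN1, CIN2, CIN3
#'   (NORMAL/LOW/HIGH pass through unchanged).
#' @return Ordered factor with levels NORMAL < LOW < HIGH.
#' @export
collapse_grade <- function(g) {
  g <- as.character(g)
  map <- c(NORMAL = "NORMAL", CIN1 = "LOW", CIN2 = "HIGH", CIN3 = "HIGH",
           LOW = "LOW", HIGH = "HIGH")
  bad <- setdiff(unique(g), names(map))
  if (length(bad) > 0) stop_validation("unknown grade(s): %s", paste(bad, collapse = ", "))
  disease_factor(unname(map[g]))
}

#' Impression-by-histopathology contingency table
#'
#' A 3 x k count matrix with rows the predicted/impression group
#' (NORMAL/LOW/HIGH) and columns the histopathology grade — either the full
#' NORMAL/CIN1/CIN2/CIN3 ladder or an already collapsed NORMAL/LOW/HIGH set.
#'
#' @param counts Non-negative integer matrix with dimnames, rows named
#'   NORMAL/LOW/HIGH.
#' @return An object of class `contingency_table`.
#' @export
contingency_table <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop_validation("counts must be non-negative integers")
  }
  if (sum(counts) == 0) stop_validation("contingency table is empty")
  if (is.null(rownames(counts)) || !identical(rownames(counts), disease_levels)) {
    stop_validation("rows must be named NORMAL, LOW, HIGH (in order)")
  }
  cols_ok <- identical(colnames(counts), histo_levels) ||
    identical(colnames(counts), disease_levels)
  if (!cols_ok) {
    stop_validation("columns must be NORMAL/CIN1/CIN2/CIN3 or NORMAL/LOW/HIGH")
  }
  structure(counts, class = c("contingency_table", "matrix"))
}

#' @rdname contingency_table
#' @param predicted,truth Equal-length vectors of disease groups (predicted)
#'   and histopathology grades (truth); tabulated into a table.
#' @export
contingency_from_labels <- function(predicted, truth) {
  predicted <- disease_factor(as.character(predicted))
  truth <- as.character(truth)
  lv <- if (all(truth %in% histo_levels) && any(truth %in% c("CIN1", "CIN2", "CIN3"))) {
    histo_levels
  } else {
    disease_levels
  }
  truth <- factor(truth, levels = lv)
  if (anyNA(predicted) || anyNA(truth)) stop_validation("unknown labels in predicted/truth")
  contingency_table(unclass(table(predicted, truth)))
}

#' @export
print.contingency_table <- function(x, ...) {
  cat("<contingency_table> impression/prediction rows x histopathology columns\n")
  print(unclass(x))
  invisible(x)
}

#' The published colposcopy-by-histopathology contingency table
#'
#' Counts of 46 cervical biopsies cross-classified by colposcopic impression
#' (normal / low grade / high grade) and histopathological diagnosis
#' (normal / CIN1 / CIN2 / CIN3), shipped as a plain-text fixture. This is
#' the reference input for the colposcopy diagnostic benchmark and the
#' ordinal correlation.
#'
#' @return A [contingency_table()] (3 x 4).
#' @export
colposcopy_table <- function() {
  path <- system.file("extdata", "colposcopy_histology_counts.csv",
                      package = "qtpcervix", mustWork = TRUE)
  df <- read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  contingency_table(m)
}

# Binarize a contingency table for one detection task. Columns are mapped to
# disease groups via collapse_grade; rows are already groups.
binarize_table <- function(tab, task) {
  col_group <- as.character(collapse_grade(colnames(tab)))
  truth_pos <- if (task == "high_grade") col_group == "HIGH" else col_group != "NORMAL"
  pred_pos <- if (task == "high_grade") {
    rownames(tab) == "HIGH"
  } else {
    rownames(tab) != "NORMAL"
  }
  list(
    tp = sum(tab[pred_pos, truth_pos]),
    fn = sum(tab[!pred_pos, truth_pos]),
    tn = sum(tab[!pred_pos, !truth_pos]),
    fp = sum(tab[pred_pos, !truth_pos])
  )
}

#' Diagnostic sensitivity and specificity from a contingency table
#'
#' Binarizes the three-group prediction and the histopathology truth for one
#' detection task — `"high_grade"` (CIN2/CIN3 positive, HIGH prediction
#' positive) or `"any_lesion"` (any CIN positive, LOW or HIGH prediction
#' positive) — and reports the confusion counts with sensitivity and
#' specificity as truncated integer percents, `floor(100 * ratio)`, the
#' convention under which the published colposcopy values reproduce exactly.
#'
#' @param tab A [contingency_table()].
#' @param task `"high_grade"` or `"any_lesion"`.
#' @return One-row tibble: `task`, `tp`, `fn`, `tn`, `fp`,
#'   `sensitivity_pct`, `specificity_pct`.
#' @export
diagnostic_metrics <- function(tab, task = c("high_grade", "any_lesion")) {
  task <- match.arg(task)
  if (!inherits(tab, "contingency_table")) tab <- contingency_table(tab)
  b <- binarize_table(tab, task)
  if (b$tp + b$fn == 0) stop_insufficient("no positive cases: sensitivity undefined")
  if (b$tn + b$fp == 0) stop_insufficient("no negative cases: specificity undefined")
  tibble(
    task = task, tp = b$tp, fn = b$fn, tn = b$tn, fp = b$fp,
    sensitivity_pct = trunc(100 * b$tp / (b$tp + b$fn)),
    specificity_pct = trunc(100 * b$tn / (b$tn + b$fp))
  )
}

#' Ordinal Spearman correlation from a contingency table
#'
#' Expands the table into paired ordinal observations (one pair per counted
#' biopsy), optionally collapsing the histopathology margin to the
#' three-level NORMAL/LOW/HIGH ladder, assigns mid-ranks to ties and returns
#' the Pearson correlation of the rank vectors. The published coefficient
#' (0.43) corresponds to `collapse = TRUE`; the full four-level coding is
#' also available.
#'
#' @param tab A [contingency_table()].
#' @param collapse Collapse histopathology to three levels first?
#' @return Scalar rank correlation.
#' @export
spearman_ordinal <- function(tab, collapse = TRUE) {
  if (!inherits(tab, "contingency_table")) tab <- contingency_table(tab)
  if (sum(tab) < 2) stop_validation("need at least 2 observations")
  col_code <- if (collapse) {
    as.integer(collapse_grade(colnames(tab)))
  } else {
    seq_len(ncol(tab))
  }
  row_code <- seq_len(nrow(tab))
  idx <- which(tab > 0, arr.ind = TRUE)
  x <- rep(row_code[idx[, 1]], tab[idx])
  y <- rep(col_code[idx[, 2]], tab[idx])
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    stop_insufficient("a margin is constant: rank correlation undefined")
  }
  cor(rank(x), rank(y))
}

#' One-way ANOVA with Fisher's LSD post hoc test
#'
#' Fits a one-way ANOVA of a feature on a grouping (disease group or
#' histopathology grade) and computes all pairwise Fisher least-significant-
#' difference comparisons: t statistics from the pooled within-group mean
#' square on its residual degrees of freedom, with no multiplicity
#' adjustment (LSD is unadjusted by definition). With two groups the LSD
#' p-value equals the pooled-variance two-sample t-test.
#'
#' @param data Data frame with the feature and group columns.
#' @param value,group Column names (tidy-eval) of the numeric feature and the
#'   grouping variable.
#' @return Object of class `qtp_anova`; see [tidy.qtp_anova()] and
#'   [glance.qtp_anova()].
#' @export
anova_lsd <- function(data, value, group) {
  v <- rlang::eval_tidy(rlang::enquo(value), data)
  g <- factor(rlang::eval_tidy(rlang::enquo(group), data))
  ok <- is.finite(v) & !is.na(g)
  v <- v[ok]; g <- droplevels(g[ok])
  ns <- table(g)
  if (length(ns) < 2) stop_validation("need >= 2 groups")
  if (any(ns < 2)) {
    stop_validation("every group needs >= 2 observations (violated: %s)",
                    paste(names(ns)[ns < 2], collapse = ", "))
  }
  fit <- aov(v ~ g)
  an <- summary(fit)[[1]]
  mse <- an["Residuals", "Mean Sq"]
  df_res <- an["Residuals", "Df"]
  means <- tapply(v, g, mean)
  pairs <- utils::combn(names(ns), 2)
  pw <- purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    se <- sqrt(mse * (1 / ns[[a]] + 1 / ns[[b]]))
    tstat <- (means[[a]] - means[[b]]) / se
    tibble(group1 = a, group2 = b, diff = means[[a]] - means[[b]],
           se = se, t = tstat, df = df_res,
           p_value = 2 * pt(-abs(tstat), df_res))
  })
  structure(
    list(f_statistic = an["g", "F value"], p_value = an["g", "Pr(>F)"],
         df_between = an["g", "Df"], df_within = df_res, mse = mse,
         group_means = tibble(group = names(ns), n = as.integer(ns),
                              mean = as.numeric(means[names(ns)])),
         pairwise = pw),
    class = "qtp_anova"
  )
}

#' @export
print.qtp_anova <- function(x, ...) {
  cat(sprintf("<qtp_anova> F(%d, %d) = %.3f, p = %.3g\n",
              x$df_between, x$df_within, x$f_statistic, x$p_value))
  print(x$pairwise)
  invisible(x)
}

#' @describeIn anova_lsd Pairwise LSD comparisons as a tibble.
#' @param x A `qtp_anova` object.
#' @param ... Unused.
#' @export
tidy.qtp_anova <- function(x, ...) x$pairwise

#' @describeIn anova_lsd One-row ANOVA summary.
#' @export
glance.qtp_anova <- function(x, ...) {
  tibble(f_statistic = x$f_statistic, p_value = x$p_value,
         df_between = x$df_between, df_within = x$df_within, mse = x$mse)
}

#' Classify specimens from their QTP features
#'
#' Adds the ENC-ratio and 3NDND threshold classifications to a feature table
#' (as produced by [compute_qtp()] rows).
#'
#' @param features Data frame with `enc_ratio` and `nddn3_um` columns.
#' @param enc_low_cut,enc_high_cut ENC band edges; see [classify_enc()].
#' @param nddn3_low_cut,nddn3_high_cut 3NDND band edges (um); see
#'   [classify_nddn3()].
#' @return The input with `enc_class` and `nddn3_class` columns appended.
#' @export
classify_specimens <- function(features, enc_low_cut = 0.08, enc_high_cut = 0.18,
                               nddn3_low_cut = 21, nddn3_high_cut = 25) {
  dplyr::mutate(
    features,
    enc_class = classify_enc(.data$enc_ratio, enc_low_cut, enc_high_cut),
    nddn3_class = classify_nddn3(.data$nddn3_um, nddn3_low_cut, nddn3_high_cut)
  )
}

#' Per-depth diagnostic performance of the QTP classifiers
#'
#' For every acquisition depth present, classifies each specimen by ENC
#' ratio and by 3NDND, cross-tabulates against the histopathology truth and
#' reports sensitivity/specificity for both detection tasks — the
#' depth-comparison report layout.
#'
#' @param features Data frame with `specimen_id`, `depth_um`, `enc_ratio`,
#'   `nddn3_um` and a `truth` column of histopathology grades or disease
#'   groups.
#' @return Tibble with one row per depth x feature x task:
#'   `depth_um`, `feature`, `task`, counts and truncated percents.
#' @export
evaluate_depths <- function(features) {
  need <- c("specimen_id", "depth_um", "enc_ratio", "nddn3_um", "truth")
  miss <- setdiff(need, names(features))
  if (length(miss) > 0) stop_validation("missing columns: %s", paste(miss, collapse = ", "))
  no_truth <- features$specimen_id[is.na(features$truth)]
  if (length(no_truth) > 0) {
    stop_validation("missing truth label for specimen(s): %s",
                    paste(unique(no_truth), collapse = ", "))
  }
  cls <- classify_specimens(features)
  cls$.depth_key <- ifelse(is.na(cls$depth_um), "<none>", as.character(cls$depth_um))
  purrr::map_dfr(split(cls, cls$.depth_key), function(d) {
    purrr::map_dfr(c(enc_ratio = "enc_class", nddn3 = "nddn3_class"), function(col) {
      tab <- contingency_from_labels(d[[col]], d$truth)
      dplyr::bind_rows(
        diagnostic_metrics(tab, "high_grade"),
        diagnostic_metrics(tab, "any_lesion")
      )
    }, .id = "feature") |>
      dplyr::mutate(depth_um = d$depth_um[1], .before = 1)
  })
}
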