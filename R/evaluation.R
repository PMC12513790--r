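# Discrimination analysis: ROC AUC and rank-sum comparisons.

#' ROC area under the curve via the rank statistic
#'
#' AUC computed as the Mann-Whitney U statistic normalised by
#' `n_pathogenic * n_benign`, with tied scores counted 1/2 through
#' midranks. This equals the probability that a randomly chosen
#' pathogenic variant outscores a randomly chosen benign one, which makes
#' it robust to class imbalance. For `lower_pathogenic` predictors the
#' score order is reversed first, so a well-behaved SPDV yields AUC above
#' 0.5.
#'
#' @param scores Numeric scores; `NA`s are dropped pairwise with their
#'   labels.
#' @param labels Logical (or 0/1) vector, `TRUE` for pathogenic.
#' @param orientation `"higher_pathogenic"` (default) or
#'   `"lower_pathogenic"`.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels,
                    orientation = c("higher_pathogenic", "lower_pathogenic")) {
  orientation <- match.arg(orientation)
  stopifnot(length(scores) == length(labels))
  labels <- as.logical(labels)
  ok <- !is.na(scores) & !is.na(labels)
  s <- scores[ok]
  y <- labels[ok]
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0 || n0 == 0) {
    stop("both classes must be represented among non-missing scores")
  }
  if (orientation == "lower_pathogenic") s <- -s
  r <- rank(s, ties.method = "average")
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve coordinates
#'
#' Per-threshold false and true positive rates, suitable for plotting or
#' TSV export.
#'
#' @inheritParams roc_auc
#' @return Data frame with columns `threshold`, `fpr`, `tpr`.
#' @export
roc_curve <- function(scores, labels,
                      orientation = c("higher_pathogenic", "lower_pathogenic")) {
  orientation <- match.arg(orientation)
  labels <- as.logical(labels)
  ok <- !is.na(scores) & !is.na(labels)
  s <- scores[ok]; y <- labels[ok]
  if (orientation == "lower_pathogenic") s <- -s
  o <- order(s, decreasing = TRUE)
  s <- s[o]; y <- y[o]
  keep <- c(diff(s) != 0, TRUE)  # one point per distinct threshold
  data.frame(threshold = s[keep],
             tpr = cumsum(y)[keep] / sum(y),
             fpr = cumsum(!y)[keep] / sum(!y))
}

default_comparisons <- function() {
  c(list(list(label = "dominant vs benign", pathogenic = DOMINANT_LABELS)),
    lapply(DOMINANT_LABELS, function(l) {
      list(label = paste(l, "vs benign"), pathogenic = l)
    }))
}

#' Benchmark predictors against labelled variants
#'
#' One ROC AUC per predictor per comparison. The default comparisons are
#' all dominant phenotypes pooled against benign, plus each dominant
#' phenotype (MH, CCD, RRD) separately against benign; recessive variants
#' are excluded by default since they are frequently carried
#' heterozygously in the healthy population. Variants missing a
#' predictor's score are dropped for that predictor only (pairwise
#' deletion), so counts can differ between predictors.
#'
#' @param score_table A [score_table()].
#' @param variants A [variant_table()].
#' @param comparisons List of `list(label =, pathogenic =, benign =)`
#'   where `pathogenic`/`benign` are label subsets; `benign` defaults to
#'   `"benign"`. `NULL` uses the default set described above.
#' @return Data frame of class `EvaluationResult` with columns
#'   `predictor`, `comparison`, `n_pathogenic`, `n_benign`, `roc_auc`.
#' @export
evaluate_predictors <- function(score_table, variants, comparisons = NULL) {
  if (is.null(comparisons)) comparisons <- default_comparisons()
  variants <- as.data.frame(variants)
  st <- as.data.frame(score_table)
  rows <- list()
  for (pred in unique(st$predictor)) {
    ps <- st[st$predictor == pred, , drop = FALSE]
    ori <- ps$orientation[1]
    sc <- ps$score[match(variants$variant, ps$variant)]
    for (cmp in comparisons) {
      ben <- if (is.null(cmp$benign)) "benign" else cmp$benign
      in_p <- variants$label %in% cmp$pathogenic & !is.na(sc)
      in_b <- variants$label %in% ben & !is.na(sc)
      if (!any(in_p) || !any(in_b)) {
        warning("comparison '", cmp$label, "' has an empty side for ",
                pred, "; skipped")
        next
      }
      use <- in_p | in_b
      rows[[length(rows) + 1]] <- data.frame(
        predictor = pred, comparison = cmp$label,
        n_pathogenic = sum(in_p), n_benign = sum(in_b),
        roc_auc = roc_auc(sc[use], in_p[use], orientation = ori),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("EvaluationResult", "data.frame")
  out
}

#' Two-sided Wilcoxon rank-sum comparison
#'
#' Thin wrapper around [stats::wilcox.test()] using the
#' normal approximation with tie correction, for comparing a score (e.g.
#' predicted stability change magnitude) between two variant classes.
#'
#' @param values_a,values_b Numeric vectors (non-empty; `NA` dropped).
#' @return List with `statistic` (the rank-sum U for `values_a`) and
#'   `p_value`.
#' @export
ranksum_compare <- function(values_a, values_b) {
  values_a <- values_a[!is.na(values_a)]
  values_b <- values_b[!is.na(values_b)]
  if (length(values_a) == 0 || length(values_b) == 0) {
    stop("both samples must be non-empty")
  }
  if (length(unique(c(values_a, values_b))) == 1) {
    # degenerate all-tied case: the normal approximation has zero variance
    return(list(statistic = length(values_a) * length(values_b) / 2,
                p_value = 1))
  }
  ht <- wilcox.test(values_a, values_b, alternative = "two.sided",
                    exact = FALSE, correct = FALSE)
  list(statistic = unname(ht$statistic), p_value = ht$p.value)
}
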