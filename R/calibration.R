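# Gene-specific ACMG/AMP PP3/BP4 evidence from kernel-density likelihood
# ratios.
#
# The positive likelihood ratio at a score s is the ratio of the
# pathogenic-reference to the benign-reference score density at s. The
# evidence ladder converts a prior probability of pathogenicity into odds
# thresholds: the very-strong threshold is the posterior/prior odds
# ratio, and each weaker level is the square root of the previous one, so
# supporting^8 = very_strong. Benign thresholds are exact reciprocals.

EVIDENCE_LEVELS <- c("BP4_very_strong", "BP4_strong", "BP4_moderate",
                     "BP4_supporting", "indeterminate", "PP3_supporting",
                     "PP3_moderate", "PP3_strong", "PP3_very_strong")

#' Prior-derived PP3/BP4 evidence ladder
#'
#' Converts a prior probability of pathogenicity and a target posterior
#' for very-strong evidence into the ladder of likelihood-ratio
#' thresholds. The very-strong odds of pathogenicity is
#' `odds(posterior_vs) / odds(prior)`; strong, moderate and supporting
#' thresholds are its successive square roots (powers 1/2, 1/4, 1/8), and
#' benign thresholds are the reciprocals of the pathogenic ones.
#'
#' @param prior Prior probability of pathogenicity in (0, 1); the default
#'   0.1 is a pragmatic choice for genes with mixed inheritance and high
#'   VUS rates.
#' @param posterior_vs Posterior probability defining very-strong
#'   evidence (default 0.99).
#' @return Object of class `EvidenceLadder`: list with `prior`,
#'   `posterior_vs`, `op_vs`, and named threshold vectors `pathogenic`
#'   (meet with lr >= threshold) and `benign` (meet with lr <=
#'   threshold), each over supporting/moderate/strong/very_strong.
#' @export
evidence_ladder <- function(prior = 0.1, posterior_vs = 0.99) {
  if (prior <= 0 || prior >= 1) stop("prior must be in (0, 1)")
  if (posterior_vs <= prior || posterior_vs >= 1) {
    stop("posterior_vs must be in (prior, 1)")
  }
  op_vs <- (posterior_vs / (1 - posterior_vs)) / (prior / (1 - prior))
  pathogenic <- c(supporting = op_vs^(1 / 8), moderate = op_vs^(1 / 4),
                  strong = op_vs^(1 / 2), very_strong = op_vs)
  structure(list(prior = prior, posterior_vs = posterior_vs, op_vs = op_vs,
                 pathogenic = pathogenic, benign = 1 / pathogenic),
            class = "EvidenceLadder")
}

#' @export
print.EvidenceLadder <- function(x, ...) {
  cat(sprintf("EvidenceLadder (prior %.3g, posterior %.3g): OP_vs = %.4g\n",
              x$prior, x$posterior_vs, x$op_vs))
  cat("  pathogenic lr+ >=:",
      paste(sprintf("%s %.4g", names(x$pathogenic), x$pathogenic),
            collapse = ", "), "\n")
  cat("  benign lr+ <=:   ",
      paste(sprintf("%s %.4g", names(x$benign), x$benign),
            collapse = ", "), "\n")
  invisible(x)
}

kde_on_grid <- function(x, grid, bw) {
  d <- density(x, bw = bw, from = grid[1], to = grid[length(grid)],
               n = length(grid))
  d$y
}

resolve_bw <- function(bandwidth, x) {
  if (is.numeric(bandwidth)) return(bandwidth)
  if (identical(bandwidth, "nrd0")) return(bw.nrd0(x))
  stop("bandwidth must be numeric or \"nrd0\" (Silverman's rule)")
}

#' Fit a bootstrap kernel-density likelihood-ratio curve
#'
#' Estimates the positive likelihood ratio `lr+(s) = f_path(s) /
#' f_benign(s)` across the span of the pooled reference scores, where the
#' densities are Gaussian kernel density estimates of the pathogenic and
#' benign reference score distributions. `n_boot` bootstrap refits
#' (resampling each reference set with replacement, re-applying the
#' bandwidth rule) give a percentile band; downstream classification uses
#' the conservative band edge — lower for pathogenic evidence, upper for
#' benign — so evidence strength is never overstated by sampling noise.
#'
#' @param path_scores Scores of reference pathogenic (P/LP) variants.
#' @param benign_scores Scores of reference benign (B/LB) variants.
#' @param bandwidth `"nrd0"` (Silverman's rule, per reference set,
#'   default) or a fixed numeric bandwidth.
#' @param n_boot Number of bootstrap refits (default 1000).
#' @param band Percentile band probabilities (default `c(0.05, 0.95)`).
#' @param seed Integer seed for the bootstrap resampling.
#' @param min_n Minimum reference-set size (default 10).
#' @param lr_ceiling Cap applied where the benign density underflows
#'   (default 1e6).
#' @param predictor,orientation Metadata recorded in the model.
#' @param grid_n Number of evaluation grid points (default 512).
#' @return Object of class `LrModel`: grid, point `lr`, band `lr_lo` /
#'   `lr_hi`, reference spans and fitting metadata.
#' @export
fit_lr_curve <- function(path_scores, benign_scores, bandwidth = "nrd0",
                         n_boot = 1000, band = c(0.05, 0.95), seed = 1,
                         min_n = 10, lr_ceiling = 1e6,
                         predictor = "score",
                         orientation = "higher_pathogenic", grid_n = 512) {
  path_scores <- path_scores[!is.na(path_scores)]
  benign_scores <- benign_scores[!is.na(benign_scores)]
  if (length(path_scores) < min_n || length(benign_scores) < min_n) {
    stop("each reference set needs at least ", min_n, " scores (got ",
         length(path_scores), " pathogenic, ", length(benign_scores),
         " benign)")
  }
  span <- range(c(path_scores, benign_scores))
  grid <- seq(span[1], span[2], length.out = grid_n)

  lr_once <- function(p, b) {
    fp <- kde_on_grid(p, grid, resolve_bw(bandwidth, p))
    fb <- kde_on_grid(b, grid, resolve_bw(bandwidth, b))
    underflow <- fb <= .Machine$double.xmin
    lr <- fp / pmax(fb, .Machine$double.xmin)
    lr[underflow] <- lr_ceiling
    pmin(lr, lr_ceiling)
  }
  lr_point <- lr_once(path_scores, benign_scores)

  # each reference set gets its own index stream seeded identically, and
  # the band edges are symmetric order statistics; together these make
  # the fitted band exactly reciprocal when the reference sets are
  # swapped (so PP3/BP4 calls swap too)
  np <- length(path_scores); nb <- length(benign_scores)
  ip <- withr::with_seed(seed, matrix(
    sample.int(np, np * n_boot, replace = TRUE), ncol = n_boot))
  ib <- withr::with_seed(seed, matrix(
    sample.int(nb, nb * n_boot, replace = TRUE), ncol = n_boot))
  boot <- vapply(seq_len(n_boot), function(b) {
    lr_once(path_scores[ip[, b]], benign_scores[ib[, b]])
  }, numeric(grid_n))
  k_lo <- max(1L, round(band[1] * n_boot))
  k_hi <- n_boot + 1L - k_lo
  sorted <- apply(boot, 1, sort)
  qs <- rbind(sorted[k_lo, ], sorted[k_hi, ])

  structure(list(predictor = predictor, orientation = orientation,
                 grid = grid, lr = lr_point,
                 lr_lo = qs[1, ], lr_hi = qs[2, ],
                 span = span, bandwidth = bandwidth, n_boot = n_boot,
                 band = band, seed = seed, lr_ceiling = lr_ceiling,
                 n_path = length(path_scores),
                 n_benign = length(benign_scores)),
            class = "LrModel")
}

#' @export
print.LrModel <- function(x, ...) {
  cat(sprintf(
    "LrModel for '%s' (%s): %d P/LP vs %d B/LB refs, span [%.3g, %.3g], %d bootstraps\n",
    x$predictor, x$orientation, x$n_path, x$n_benign,
    x$span[1], x$span[2], x$n_boot))
  invisible(x)
}

#' Evaluate a fitted likelihood-ratio curve at new scores
#'
#' Scores outside the fitted span are clamped to the span boundary (the
#' KDE tails beyond the reference data are unreliable, so the boundary
#' lr is extended flat); clamping is reported via the `clamped` column.
#'
#' @param model An `LrModel`.
#' @param scores Numeric scores.
#' @return Data frame with `score`, `lr`, `lr_lo`, `lr_hi`, `clamped`.
#' @export
predict_lr <- function(model, scores) {
  stopifnot(inherits(model, "LrModel"))
  clamped <- !is.na(scores) & (scores < model$span[1] | scores > model$span[2])
  s <- pmin(pmax(scores, model$span[1]), model$span[2])
  data.frame(
    score = scores,
    lr = approx(model$grid, model$lr, xout = s, rule = 2)$y,
    lr_lo = approx(model$grid, model$lr_lo, xout = s, rule = 2)$y,
    lr_hi = approx(model$grid, model$lr_hi, xout = s, rule = 2)$y,
    clamped = clamped
  )
}

#' Assign PP3/BP4 evidence levels to variants
#'
#' Each variant's conservative likelihood ratio is compared against the
#' ladder: the call is the strongest pathogenic level whose threshold the
#' lower band edge meets, otherwise the strongest benign level whose
#' threshold the upper band edge meets, otherwise indeterminate.
#'
#' @param model An `LrModel` from [fit_lr_curve()].
#' @param ladder An [evidence_ladder()].
#' @param scores A [score_table()] subset (or data frame with `variant`
#'   and `score`) for the model's predictor.
#' @return Data frame of class `EvidenceCall` with `variant`, `score`,
#'   `lr`, `lr_lo`, `lr_hi`, `level` (ordered factor from
#'   `BP4_very_strong` to `PP3_very_strong`).
#' @export
classify_variants <- function(model, ladder, scores) {
  stopifnot(inherits(model, "LrModel"), inherits(ladder, "EvidenceLadder"))
  scores <- as.data.frame(scores)
  if ("predictor" %in% names(scores)) {
    if (!all(scores$predictor == model$predictor)) {
      stop("score table contains predictors other than '", model$predictor, "'")
    }
    if ("orientation" %in% names(scores) &&
          !all(scores$orientation == model$orientation)) {
      stop("score orientation disagrees with the model's")
    }
  }
  pl <- predict_lr(model, scores$score)
  if (any(pl$clamped)) {
    message(sum(pl$clamped),
            " score(s) outside the fitted span; lr clamped to the boundary")
  }
  strengths <- c("very_strong", "strong", "moderate", "supporting")
  level <- rep("indeterminate", nrow(pl))
  for (s in strengths) {  # strongest first; first hit wins
    hit <- level == "indeterminate" & pl$lr_lo >= ladder$pathogenic[[s]]
    level[hit] <- paste0("PP3_", s)
  }
  for (s in strengths) {
    hit <- level == "indeterminate" & pl$lr_hi <= ladder$benign[[s]]
    level[hit] <- paste0("BP4_", s)
  }
  out <- data.frame(variant = scores$variant, score = scores$score,
                    lr = pl$lr, lr_lo = pl$lr_lo, lr_hi = pl$lr_hi,
                    level = factor(level, levels = EVIDENCE_LEVELS,
                                   ordered = TRUE),
                    stringsAsFactors = FALSE)
  class(out) <- c("EvidenceCall", "data.frame")
  out
}

#' Evidence-class composition per variant category
#'
#' Fraction of variants at each evidence level within each category
#' (e.g. gnomAD / ClinVar VUS / phenotype groups); fractions sum to 1 per
#' category.
#'
#' @param calls An `EvidenceCall` data frame from [classify_variants()].
#' @param categories Either a character vector parallel to `calls`, or a
#'   data frame with `variant` and `category` columns covering every
#'   called variant.
#' @return Data frame with one row per (category, level) and a `fraction`
#'   column.
#' @export
summarise_calls <- function(calls, categories) {
  if (is.data.frame(categories)) {
    cat_vec <- categories$category[match(calls$variant, categories$variant)]
    if (anyNA(cat_vec)) {
      stop("no category for variants: ",
           paste(unique(calls$variant[is.na(cat_vec)]), collapse = ", "))
    }
  } else {
    stopifnot(length(categories) == nrow(calls))
    cat_vec <- categories
  }
  tab <- table(category = cat_vec,
               level = factor(calls$level, levels = EVIDENCE_LEVELS))
  frac <- prop.table(tab, margin = 1)
  out <- as.data.frame(frac, responseName = "fraction",
                       stringsAsFactors = FALSE)
  out$level <- factor(out$level, levels = EVIDENCE_LEVELS, ordered = TRUE)
  out[order(out$category, out$level), c("category", "level", "fraction")]
}
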