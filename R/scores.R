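# Variant datasets and predictor score tracks.

VARIANT_LABELS <- c("MH", "CCD", "RRD", "recessive", "benign")
DOMINANT_LABELS <- c("MH", "CCD", "RRD")

AA3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
         E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
         M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
         Y = "Tyr", V = "Val")

#' Canonical variant key
#'
#' Formats variants as `p.<ref><pos><alt>` with 1-letter codes, e.g.
#' `p.R614C`.
#'
#' @param ref_aa,alt_aa 1-letter amino acid codes.
#' @param human_pos 1-based human sequence position.
#' @return Character vector of keys.
#' @export
variant_key <- function(ref_aa, human_pos, alt_aa) {
  sprintf("p.%s%d%s", ref_aa, as.integer(human_pos), alt_aa)
}

#' Parse variant keys
#'
#' Accepts `p.R614C` and 3-letter `p.Arg614Cys` forms (the `p.` prefix is
#' optional).
#'
#' @param keys Character vector of protein-level variant notations.
#' @return Data frame with `ref_aa`, `human_pos`, `alt_aa` (1-letter).
#' @export
parse_variant_key <- function(keys) {
  x <- sub("^p\\.", "", keys)
  m1 <- regmatches(x, regexec("^([A-Z])([0-9]+)([A-Z])$", x))
  m3 <- regmatches(x, regexec("^([A-Z][a-z]{2})([0-9]+)([A-Z][a-z]{2})$", x))
  to1 <- function(aa) {
    out <- names(AA3)[match(aa, AA3)]
    if (anyNA(out)) stop("unknown 3-letter amino acid code: ",
                         paste(unique(aa[is.na(out)]), collapse = ", "))
    out
  }
  parse_one <- function(a, b) {
    if (length(a) == 4) list(ref = a[2], pos = as.integer(a[3]), alt = a[4])
    else if (length(b) == 4) list(ref = to1(b[2]), pos = as.integer(b[3]),
                                  alt = to1(b[4]))
    else stop("cannot parse variant notation: '", paste(a, b), "'")
  }
  parsed <- Map(function(a, b, orig) {
    if (length(a) != 4 && length(b) != 4) {
      stop("cannot parse variant notation: '", orig, "'")
    }
    parse_one(a, b)
  }, m1, m3, keys)
  data.frame(ref_aa = vapply(parsed, `[[`, "", "ref"),
             human_pos = vapply(parsed, `[[`, 1L, "pos"),
             alt_aa = vapply(parsed, `[[`, "", "alt"),
             stringsAsFactors = FALSE)
}

#' Construct a labelled variant table
#'
#' @param human_pos Integer human sequence positions (1-based).
#' @param ref_aa,alt_aa 1-letter reference and alternate amino acids.
#' @param label Phenotype/benign label, one of `MH`, `CCD`, `RRD`,
#'   `recessive`, `benign`.
#' @param source Free-text provenance (default `""`).
#' @return Data frame of class `VariantTable` with a `variant` key column.
#' @export
variant_table <- function(human_pos, ref_aa, alt_aa, label, source = "") {
  label <- as.character(label)
  bad <- setdiff(unique(label), VARIANT_LABELS)
  if (length(bad) > 0) {
    stop("unknown labels: ", paste(bad, collapse = ", "),
         " (expected ", paste(VARIANT_LABELS, collapse = "/"), ")")
  }
  out <- data.frame(variant = variant_key(ref_aa, human_pos, alt_aa),
                    human_pos = as.integer(human_pos),
                    ref_aa = ref_aa, alt_aa = alt_aa, label = label,
                    source = rep_len(source, length(human_pos)),
                    stringsAsFactors = FALSE)
  class(out) <- c("VariantTable", "data.frame")
  out
}

#' Read a variant table from TSV/CSV
#'
#' Expects columns `human_pos`, `ref_aa`, `alt_aa`, `label` and
#' optionally `source`; alternatively a `variant` column in `p.R614C` /
#' `p.Arg614Cys` notation plus `label`. Column names can be remapped via
#' `col_map`.
#'
#' @param path File path (tab- or comma-separated, sniffed from the
#'   extension).
#' @param col_map Optional named character vector mapping the expected
#'   names to the file's header names, e.g.
#'   `c(human_pos = "position", label = "phenotype")`.
#' @return A [variant_table()].
#' @export
read_variant_table <- function(path, col_map = NULL) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- read.delim(path, sep = sep, stringsAsFactors = FALSE)
  if (!is.null(col_map)) {
    for (std in names(col_map)) {
      names(df)[names(df) == col_map[[std]]] <- std
    }
  }
  if (!all(c("human_pos", "ref_aa", "alt_aa") %in% names(df)) &&
        "variant" %in% names(df)) {
    df <- cbind(df[setdiff(names(df), c("human_pos", "ref_aa", "alt_aa"))],
                parse_variant_key(df$variant))
  }
  need <- c("human_pos", "ref_aa", "alt_aa", "label")
  if (!all(need %in% names(df))) {
    stop("variant file lacks columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  if (!"source" %in% names(df)) df$source <- ""
  variant_table(df$human_pos, df$ref_aa, df$alt_aa, df$label, df$source)
}

#' Assemble mutually exclusive pathogenic and benign variant sets
#'
#' Deduplicates the disease table (erroring if one variant carries
#' conflicting phenotype labels), labels the population table benign, and
#' removes from the benign side any variant already present in the
#' disease set, so the pathogenic and putatively benign subsets are
#' disjoint by construction.
#'
#' @param disease [variant_table()] of disease-associated variants
#'   (labels `MH`/`CCD`/`RRD`/`recessive`).
#' @param population [variant_table()] of population variants (any label;
#'   relabelled `benign`).
#' @return A combined [variant_table()].
#' @export
assemble_datasets <- function(disease, population) {
  disease <- as.data.frame(disease)
  population <- as.data.frame(population)
  if (any(disease$label == "benign")) {
    stop("disease table contains rows labelled 'benign'")
  }
  lab_by_var <- tapply(disease$label, disease$variant,
                       function(l) length(unique(l)))
  conflicts <- names(lab_by_var)[lab_by_var > 1]
  if (length(conflicts) > 0) {
    stop("conflicting phenotype labels within the disease table for: ",
         paste(conflicts, collapse = ", "))
  }
  disease <- disease[!duplicated(disease$variant), , drop = FALSE]
  population$label <- "benign"
  population <- population[!duplicated(population$variant), , drop = FALSE]
  population <- population[!(population$variant %in% disease$variant), ,
                           drop = FALSE]
  out <- rbind(disease, population)
  rownames(out) <- NULL
  class(out) <- c("VariantTable", "data.frame")
  out
}

#' Split a sequence into fixed-length overlapping segments
#'
#' Segment k (0-based) starts at `1 + k * (segment_length - overlap)`;
#' the final segment is truncated at `length`. Every position is covered
#' and consecutive segments overlap by exactly `overlap` positions except
#' possibly the last. A trailing segment that would add no new positions
#' is dropped.
#'
#' @param length Sequence length.
#' @param segment_length Nominal segment length.
#' @param overlap Number of positions shared by consecutive segments.
#' @return Data frame with columns `segment`, `start`, `end` (1-based,
#'   closed intervals).
#' @export
segment_sequence <- function(length, segment_length, overlap) {
  stopifnot(length >= 1, segment_length >= 1)
  if (overlap < 0 || overlap >= segment_length) {
    stop("overlap must satisfy 0 <= overlap < segment_length")
  }
  starts <- seq.int(1L, length, by = segment_length - overlap)
  ends <- pmin(starts + segment_length - 1L, length)
  keep <- c(TRUE, ends[-1] > ends[-length(ends)])
  starts <- starts[keep]; ends <- ends[keep]
  data.frame(segment = seq_along(starts), start = starts, end = ends)
}

#' Merge per-segment score tracks into one per-position track
#'
#' Positions covered by a single segment keep their score; positions in
#' segment overlaps get the arithmetic mean of the covering scores.
#' Missing values are ignored in the mean; a position missing in every
#' covering segment stays missing.
#'
#' @param segments List of `list(interval = c(start, end), scores =
#'   numeric)` as produced by scoring the output of [segment_sequence()].
#' @param length Total track length; defaults to the largest segment end.
#' @return Numeric vector of length `length`.
#' @export
merge_segment_scores <- function(segments, length = NULL) {
  ends <- vapply(segments, function(s) s$interval[2], 1)
  if (is.null(length)) length <- max(ends)
  sums <- numeric(length)
  counts <- integer(length)
  for (s in segments) {
    iv <- s$interval
    n <- iv[2] - iv[1] + 1
    if (base::length(s$scores) != n) {
      stop("segment [", iv[1], ",", iv[2], "] expects ", n,
           " scores but got ", base::length(s$scores))
    }
    pos <- iv[1]:iv[2]
    ok <- !is.na(s$scores)
    sums[pos[ok]] <- sums[pos[ok]] + s$scores[ok]
    counts[pos[ok]] <- counts[pos[ok]] + 1L
  }
  out <- sums / counts
  out[counts == 0L] <- NA_real_
  out
}

#' Rank-normalise a score vector to (0, 1]
#'
#' Ascending midranks of the finite values divided by the number of
#' finite values; the largest value maps to 1. Ties share their midrank.
#' Missing values stay missing.
#'
#' @param values Numeric vector.
#' @return Numeric vector of the same length in `(0, 1]` (NA preserved).
#' @export
rank_normalise <- function(values) {
  finite <- is.finite(values)
  if (!any(finite)) stop("rank_normalise needs at least one finite value")
  out <- rep(NA_real_, length(values))
  out[finite] <- rank(values[finite], ties.method = "average") / sum(finite)
  out
}

#' Construct a long-format predictor score table
#'
#' One row per (variant, predictor) with the predictor's orientation:
#' `higher_pathogenic` when larger scores indicate pathogenicity,
#' `lower_pathogenic` otherwise (e.g. SPDV). Missing scores are simply
#' absent rows, never zero-filled.
#'
#' @param variant Variant keys (see [variant_key()]).
#' @param predictor Predictor names.
#' @param score Numeric scores.
#' @param orientation `"higher_pathogenic"` or `"lower_pathogenic"`,
#'   recycled per row; must be constant within a predictor.
#' @return Data frame of class `ScoreTable`.
#' @export
score_table <- function(variant, predictor, score,
                        orientation = "higher_pathogenic") {
  orientation <- rep_len(orientation, length(variant))
  bad <- setdiff(unique(orientation),
                 c("higher_pathogenic", "lower_pathogenic"))
  if (length(bad) > 0) stop("unknown orientation: ", paste(bad, collapse = ", "))
  out <- data.frame(variant = variant, predictor = predictor,
                    score = as.numeric(score), orientation = orientation,
                    stringsAsFactors = FALSE)
  out <- out[!is.na(out$score), , drop = FALSE]
  if (anyDuplicated(out[c("variant", "predictor")])) {
    stop("more than one score for the same (variant, predictor) pair")
  }
  per_pred <- tapply(out$orientation, out$predictor,
                     function(o) length(unique(o)))
  if (any(per_pred > 1)) {
    stop("orientation must be constant within a predictor: ",
         paste(names(per_pred)[per_pred > 1], collapse = ", "))
  }
  rownames(out) <- NULL
  class(out) <- c("ScoreTable", "data.frame")
  out
}

#' Read a wide predictor score matrix into a ScoreTable
#'
#' Expects a `variant` column plus one column per predictor. Empty cells
#' become absent rows.
#'
#' @param path TSV/CSV path.
#' @param orientation Named character vector giving each predictor's
#'   orientation; unnamed scalar applies to all (default
#'   `"higher_pathogenic"`).
#' @return A [score_table()].
#' @export
read_score_table <- function(path, orientation = "higher_pathogenic") {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- read.delim(path, sep = sep, stringsAsFactors = FALSE,
                   check.names = FALSE)
  if (!"variant" %in% names(df)) stop("score file needs a 'variant' column")
  preds <- setdiff(names(df), "variant")
  if (length(preds) == 0) stop("score file has no predictor columns")
  long <- do.call(rbind, lapply(preds, function(p) {
    ori <- if (!is.null(names(orientation)) && p %in% names(orientation)) {
      orientation[[p]]
    } else if (is.null(names(orientation))) orientation[[1]]
    else "higher_pathogenic"
    data.frame(variant = df$variant, predictor = p,
               score = suppressWarnings(as.numeric(df[[p]])),
               orientation = ori, stringsAsFactors = FALSE)
  }))
  score_table(long$variant, long$predictor, long$score, long$orientation)
}
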