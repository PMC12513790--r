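# SPDV and EDC: spatial clustering metrics over C-alpha coordinates.
#
# SPDV_K(query) = mean of the K smallest Euclidean distances from the
# query residue's C-alpha to the C-alphas of known disease-variant sites,
# with the query itself excluded from the site set. Lower values mean the
# residue sits closer to the disease cluster, so SPDV is a
# "lower = more pathogenic" score.
#
# EDC = (mean over ALL residues of the distance to the nearest site other
# than the residue itself) / (mean over site residues of the distance to
# the nearest other site). Randomly dispersed sites give values near 1;
# clustered sites give values above 1.

#' Define a set of disease-variant sites
#'
#' A `SiteSet` holds the unique structure positions harbouring known
#' disease variants for one model (e.g. all pathogenic sites, or one
#' phenotype's sites).
#'
#' @param label Model label, e.g. `"all"`, `"MH"`, `"CCD"`.
#' @param chain Character vector of chain ids.
#' @param resno Integer author residue numbers.
#' @param ins Insertion codes (`""` when absent).
#' @param human_pos Optional human sequence positions carried along for
#'   reporting.
#' @return Object of class `SiteSet`.
#' @export
site_set <- function(label, chain, resno, ins = "", human_pos = NA_integer_) {
  sites <- data.frame(chain = chain, resno = resno,
                      ins = rep_len(ifelse(is.na(ins) | ins == " ", "", ins),
                                    length(chain)),
                      human_pos = rep_len(human_pos, length(chain)),
                      stringsAsFactors = FALSE)
  sites <- sites[!duplicated(residue_key(sites$chain, sites$resno, sites$ins)), ,
                 drop = FALSE]
  if (nrow(sites) == 0) stop("a SiteSet must contain at least one site")
  structure(list(label = label, sites = sites), class = "SiteSet")
}

#' @export
print.SiteSet <- function(x, ...) {
  cat(sprintf("SiteSet '%s': %d sites on chains %s\n", x$label,
              nrow(x$sites), paste(unique(x$sites$chain), collapse = ",")))
  invisible(x)
}

# residues of `structure` with C-alpha, as coord matrix + keys
ca_table <- function(structure) {
  r <- structure$residues[structure$residues$has_ca, , drop = FALSE]
  list(key = residue_key(r$chain, r$resno, r$ins),
       chain = r$chain, resno = r$resno, ins = r$ins,
       xyz = as.matrix(r[, c("x", "y", "z")]))
}

# Euclidean cross-distance between two coordinate matrices (n x 3, m x 3)
cross_dist <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

resolve_site_coords <- function(structure, sites) {
  ca <- ca_table(structure)
  skey <- residue_key(sites$sites$chain, sites$sites$resno, sites$sites$ins)
  idx <- match(skey, ca$key)
  if (anyNA(idx)) {
    missing <- skey[is.na(idx)]
    warning("dropping ", length(missing),
            " site(s) without a C-alpha in the structure: ",
            paste(head(missing, 5), collapse = ", "),
            if (length(missing) > 5) ", ..." else "")
    idx <- idx[!is.na(idx)]
  }
  if (length(idx) == 0) stop("no site has a C-alpha in this structure")
  list(ca = ca, idx = idx)
}

#' Spatial Proximity to Disease Variants for one residue
#'
#' Mean of the K smallest C-alpha Euclidean distances from the query
#' residue to the disease-variant sites. A query that is itself a site is
#' excluded from the site set before ranking, so scoring a known
#' pathogenic position never sees its own site. In `intra` mode only
#' sites on the query's chain are eligible; `inter` mode pools sites on
#' all chains.
#'
#' @param structure A [structure_model()].
#' @param sites A [site_set()].
#' @param query Residue key: either a string `"chain:resno:ins"` or a
#'   list/vector with elements `chain`, `resno` and optionally `ins`.
#' @param K Number of nearest site distances to average.
#' @param mode `"intra"` or `"inter"`.
#' @return SPDV_K in Angstroms, or `NA` if fewer than `K` eligible sites
#'   remain after self-exclusion.
#' @export
spdv <- function(structure, sites, query, K, mode = c("intra", "inter")) {
  mode <- match.arg(mode)
  stopifnot(inherits(sites, "SiteSet"), K >= 1)
  qk <- if (is.character(query) && length(query) == 1) query
        else residue_key(query[["chain"]], query[["resno"]],
                         if (is.null(query[["ins"]])) "" else query[["ins"]])
  res <- resolve_site_coords(structure, sites)
  ca <- res$ca
  qi <- match(qk, ca$key)
  if (is.na(qi)) stop("query residue '", qk, "' has no C-alpha in the structure")
  sidx <- res$idx
  if (mode == "intra") sidx <- sidx[ca$chain[sidx] == ca$chain[qi]]
  sidx <- sidx[sidx != qi]  # self-exclusion
  if (length(sidx) == 0) {
    warning("no eligible sites for query '", qk, "' in ", mode, " mode")
    return(NA_real_)
  }
  d <- sqrt(colSums((t(ca$xyz[sidx, , drop = FALSE]) - ca$xyz[qi, ])^2))
  if (length(d) < K) return(NA_real_)
  mean(sort(d)[seq_len(K)])
}

#' SPDV profile over all residues for a set of K values
#'
#' Computes SPDV_K for every residue with a C-alpha, for each K, sharing
#' the distance computation across K. Site residues are scored
#' leave-self-out. Residues with fewer than K eligible sites get `NA`.
#'
#' @inheritParams spdv
#' @param K_set Integer vector of K values (e.g. `1:8`).
#' @return Object of class `SpdvProfile`: a data frame with columns
#'   `chain`, `resno`, `ins`, `K`, `spdv` plus attributes `model_label`,
#'   `mode` and `orientation = "lower_pathogenic"`.
#' @export
spdv_profile <- function(structure, sites, K_set, mode = c("intra", "inter")) {
  mode <- match.arg(mode)
  stopifnot(inherits(sites, "SiteSet"), length(K_set) >= 1, all(K_set >= 1))
  K_set <- sort(unique(as.integer(K_set)))
  res <- resolve_site_coords(structure, sites)
  ca <- res$ca
  n <- length(ca$key)
  Kmax <- max(K_set)

  # per residue: ascending distances to eligible sites (self excluded)
  smallest <- matrix(NA_real_, nrow = n, ncol = Kmax)
  chains <- if (mode == "intra") unique(ca$chain) else "__all__"
  for (ch in chains) {
    ri <- if (mode == "intra") which(ca$chain == ch) else seq_len(n)
    si <- if (mode == "intra") res$idx[ca$chain[res$idx] == ch] else res$idx
    if (length(si) == 0) next
    D <- cross_dist(ca$xyz[ri, , drop = FALSE], ca$xyz[si, , drop = FALSE])
    self <- outer(ri, si, "==")
    D[self] <- NA
    for (j in seq_along(ri)) {
      d <- sort(D[j, ])  # drops NA (the self column)
      k <- min(length(d), Kmax)
      if (k > 0) smallest[ri[j], seq_len(k)] <- d[seq_len(k)]
    }
  }

  csum <- smallest
  for (k in seq_len(Kmax)[-1]) csum[, k] <- csum[, k - 1] + smallest[, k]
  out <- do.call(rbind, lapply(K_set, function(k) {
    data.frame(chain = ca$chain, resno = ca$resno, ins = ca$ins,
               K = k, spdv = csum[, k] / k, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  structure(out, model_label = sites$label, mode = mode,
            orientation = "lower_pathogenic",
            class = c("SpdvProfile", "data.frame"))
}

#' 1D sequence analog of SPDV
#'
#' Same construction as [spdv()] but with distance measured along the
#' primary sequence (in residues) instead of through space.
#'
#' @param seq_length Length of the sequence.
#' @param sites Integer vector of site positions.
#' @param query Query position (1-based).
#' @param K Number of nearest site distances to average.
#' @return Mean of the K smallest sequence separations, or `NA` if fewer
#'   than `K` sites remain after self-exclusion.
#' @export
spdv_1d <- function(seq_length, sites, query, K) {
  stopifnot(query >= 1, query <= seq_length, K >= 1)
  sites <- unique(as.integer(sites))
  if (any(sites < 1 | sites > seq_length)) {
    stop("site positions outside [1, ", seq_length, "]")
  }
  sites <- sites[sites != query]  # self-exclusion
  if (length(sites) == 0) {
    warning("no eligible sites for query ", query)
    return(NA_real_)
  }
  d <- abs(query - sites)
  if (length(d) < K) return(NA_real_)
  mean(sort(d)[seq_len(K)])
}

#' Extent of Disease Clustering
#'
#' Ratio of the mean nearest-site distance taken over all residues to the
#' mean nearest-other-site distance taken over the site residues
#' themselves. Sites scattered uniformly give EDC near 1; sites packed
#' together give EDC above 1 (every site is close to another site, while
#' the average residue is not).
#'
#' @inheritParams spdv
#' @return Object of class `EdcResult`: list with `edc`, `n_sites`,
#'   `n_residues`, `numerator_mean` and `denominator_mean` (both in
#'   Angstroms).
#' @export
edc <- function(structure, sites, mode = c("intra", "inter")) {
  mode <- match.arg(mode)
  stopifnot(inherits(sites, "SiteSet"))
  res <- resolve_site_coords(structure, sites)
  ca <- res$ca
  n <- length(ca$key)
  if (length(res$idx) < 2) stop("EDC needs at least 2 sites with C-alpha")

  nearest <- rep(NA_real_, n)
  chains <- if (mode == "intra") unique(ca$chain) else "__all__"
  for (ch in chains) {
    ri <- if (mode == "intra") which(ca$chain == ch) else seq_len(n)
    si <- if (mode == "intra") res$idx[ca$chain[res$idx] == ch] else res$idx
    if (length(si) == 0) next
    D <- cross_dist(ca$xyz[ri, , drop = FALSE], ca$xyz[si, , drop = FALSE])
    D[outer(ri, si, "==")] <- NA  # a residue is never its own nearest site
    nearest[ri] <- apply(D, 1, function(d) {
      if (all(is.na(d))) NA_real_ else min(d, na.rm = TRUE)
    })
  }

  is_site <- seq_len(n) %in% res$idx
  den <- nearest[is_site]
  if (anyNA(den)) stop("EDC needs at least 2 sites per evaluated chain")
  num <- nearest[!is.na(nearest)]
  out <- list(edc = mean(num) / mean(den),
              n_sites = sum(is_site), n_residues = length(num),
              numerator_mean = mean(num), denominator_mean = mean(den))
  class(out) <- "EdcResult"
  out
}

#' @export
print.EdcResult <- function(x, ...) {
  cat(sprintf("EDC = %.3f (%d sites, %d residues; num %.2f A / den %.2f A)\n",
              x$edc, x$n_sites, x$n_residues,
              x$numerator_mean, x$denominator_mean))
  invisible(x)
}
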