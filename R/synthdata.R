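# Synthetic structures, planted disease-site sets and score
# distributions, so the full analysis path (structure in, evidence out)
# can be exercised and calibrated without any external data.

#' Specification for a synthetic structure study
#'
#' Captures everything needed to build a reproducible synthetic instance:
#' geometry, number of residues, how many disease sites to plant and
#' whether they cluster, and the per-class score model.
#'
#' @param n_residues Number of residues (>= 2).
#' @param geometry `"line"` (extended chain, 3.8 A C-alpha spacing),
#'   `"helix"` (ideal alpha-helix: 1.5 A rise, 100 degree twist, 2.3 A
#'   radius) or `"random_globule"` (uniform points in a sphere at ~0.6
#'   residues/nm^3 packing).
#' @param site_count Number of disease sites to plant
#'   (<= `n_residues`).
#' @param cluster_centers Residue indices acting as cluster centres
#'   (used when `cluster_spread` is finite).
#' @param cluster_spread Standard deviation (Angstroms) of the Gaussian
#'   planting kernel around the nearest centre; `Inf` plants uniformly.
#' @param score_model List with `path = c(mean, sd)` and
#'   `benign = c(mean, sd)` for [simulate_scores()].
#' @param seed Integer seed; every random draw for this spec flows from
#'   it.
#' @return Object of class `SyntheticSpec`.
#' @export
synthetic_spec <- function(n_residues = 200,
                           geometry = c("random_globule", "line", "helix"),
                           site_count = 20,
                           cluster_centers = NULL,
                           cluster_spread = Inf,
                           score_model = list(path = c(mean = 2, sd = 1),
                                              benign = c(mean = 0, sd = 1)),
                           seed) {
  geometry <- match.arg(geometry)
  if (missing(seed)) stop("a seed is mandatory for a SyntheticSpec")
  if (n_residues < 2) stop("n_residues must be >= 2")
  if (site_count > n_residues) stop("site_count cannot exceed n_residues")
  if (site_count < 1) stop("site_count must be >= 1")
  if (!(is.infinite(cluster_spread) || cluster_spread > 0)) {
    stop("cluster_spread must be > 0 or Inf")
  }
  if (is.finite(cluster_spread) && is.null(cluster_centers)) {
    stop("finite cluster_spread needs cluster_centers")
  }
  structure(list(n_residues = as.integer(n_residues), geometry = geometry,
                 site_count = as.integer(site_count),
                 cluster_centers = cluster_centers,
                 cluster_spread = cluster_spread,
                 score_model = score_model, seed = as.integer(seed)),
            class = "SyntheticSpec")
}

#' Build a synthetic structure
#'
#' Deterministic for a given spec (the seed drives the globule
#' coordinates). The structure is a single chain `"A"` of alanines with
#' every C-alpha resolved; [write_structure()] emits it as a minimal
#' valid PDB so file-reading code paths can be exercised rather than
#' bypassed.
#'
#' @param spec A [synthetic_spec()].
#' @return A [structure_model()].
#' @export
make_structure <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  n <- spec$n_residues
  xyz <- switch(spec$geometry,
    line = cbind(x = 3.8 * (seq_len(n) - 1), y = 0, z = 0),
    helix = {
      i <- seq_len(n) - 1
      t <- i * 100 * pi / 180
      cbind(x = 2.3 * cos(t), y = 2.3 * sin(t), z = 1.5 * i)
    },
    random_globule = {
      # uniform points in a ball sized for ~0.6 residues per nm^3
      radius <- (3 * n / (4 * pi * 6e-4))^(1 / 3)
      withr::with_seed(spec$seed, {
        u <- matrix(rnorm(3 * n), ncol = 3)
        u <- u / sqrt(rowSums(u^2))
        r <- radius * runif(n)^(1 / 3)
        u * r
      })
    })
  residues <- data.frame(chain = "A", resno = seq_len(n), ins = "",
                         resid = "ALA", aa = "A",
                         x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                         stringsAsFactors = FALSE)
  structure_model(sprintf("synthetic_%s_%d", spec$geometry, spec$seed),
                  residues)
}

#' Plant disease sites on a synthetic structure
#'
#' With infinite `cluster_spread` the sites are a uniform sample of
#' residue positions without replacement (the dispersed regime, EDC near
#' 1). With finite spread, residues are sampled without replacement with
#' probability proportional to a Gaussian kernel of their C-alpha
#' distance to the nearest cluster centre (the clustered regime, EDC
#' above 1).
#'
#' @param struct A [structure_model()] built from `spec`.
#' @param spec The [synthetic_spec()].
#' @param label Label for the returned [site_set()] (default
#'   `"planted"`).
#' @return A [site_set()].
#' @export
plant_sites <- function(struct, spec, label = "planted") {
  stopifnot(inherits(struct, "StructureModel"), inherits(spec, "SyntheticSpec"))
  r <- struct$residues
  n <- nrow(r)
  if (spec$site_count > n) stop("site_count exceeds the number of residues")
  idx <- withr::with_seed(spec$seed + 1L, {
    if (is.infinite(spec$cluster_spread)) {
      sample.int(n, spec$site_count)
    } else {
      centers <- as.matrix(r[spec$cluster_centers, c("x", "y", "z")])
      d2 <- sapply(seq_len(nrow(centers)), function(ci) {
        (r$x - centers[ci, 1])^2 + (r$y - centers[ci, 2])^2 +
          (r$z - centers[ci, 3])^2
      })
      dmin2 <- if (is.matrix(d2)) apply(d2, 1, min) else d2
      w <- exp(-dmin2 / (2 * spec$cluster_spread^2))
      sample.int(n, spec$site_count, prob = w)
    }
  })
  idx <- sort(idx)
  site_set(label, chain = r$chain[idx], resno = r$resno[idx],
           ins = r$ins[idx], human_pos = r$resno[idx])
}

#' Simulate two-component predictor scores with truth labels
#'
#' Gaussian score draws per class (pathogenic vs benign), the standard
#' testbed for score calibration: the analytic likelihood ratio and ROC
#' AUC of the two-Gaussian model are known in closed form.
#'
#' @param n_path,n_benign Number of variants per class (positive).
#' @param path_mean,path_sd,benign_mean,benign_sd Class score
#'   distributions (defaults N(2,1) vs N(0,1)).
#' @param seed Integer seed.
#' @param predictor Predictor name recorded in the score table.
#' @return List with `scores` (a [score_table()]) and `truth` (data frame
#'   `variant`, `label` in `pathogenic`/`benign`).
#' @export
simulate_scores <- function(n_path, n_benign, path_mean = 2, path_sd = 1,
                            benign_mean = 0, benign_sd = 1, seed,
                            predictor = "synthetic") {
  if (n_path < 1 || n_benign < 1) stop("both class sizes must be positive")
  if (path_sd <= 0 || benign_sd <= 0) stop("class sds must be positive")
  if (missing(seed)) stop("a seed is mandatory")
  draws <- withr::with_seed(seed, {
    list(p = rnorm(n_path, path_mean, path_sd),
         b = rnorm(n_benign, benign_mean, benign_sd))
  })
  variant <- c(sprintf("path_%d", seq_len(n_path)),
               sprintf("benign_%d", seq_len(n_benign)))
  list(scores = score_table(variant, predictor,
                            c(draws$p, draws$b), "higher_pathogenic"),
       truth = data.frame(variant = variant,
                          label = rep(c("pathogenic", "benign"),
                                      c(n_path, n_benign)),
                          stringsAsFactors = FALSE))
}
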