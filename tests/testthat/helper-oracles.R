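# Independent brute-force oracles and tiny fixture builders used across
# the suite. The oracles deliberately share no code with the package:
# they enumerate every pairwise quantity directly.

# mean of the K smallest Euclidean distances from `query_xyz` (length-3)
# to the rows of `site_xyz`, NA if fewer than K rows
brute_spdv <- function(query_xyz, site_xyz, K) {
  if (nrow(site_xyz) < K) return(NA_real_)
  d <- apply(site_xyz, 1, function(s) sqrt(sum((s - query_xyz)^2)))
  mean(sort(d)[seq_len(K)])
}

brute_spdv_1d <- function(query, sites, K) {
  sites <- sites[sites != query]
  if (length(sites) < K) return(NA_real_)
  mean(sort(abs(sites - query))[seq_len(K)])
}

# EDC by direct enumeration over a coordinate matrix and site indices
brute_edc <- function(xyz, site_idx) {
  n <- nrow(xyz)
  nearest <- vapply(seq_len(n), function(i) {
    others <- setdiff(site_idx, i)
    min(apply(xyz[others, , drop = FALSE], 1,
              function(s) sqrt(sum((s - xyz[i, ])^2))))
  }, 1)
  mean(nearest) / mean(nearest[site_idx])
}

# AUC by exhaustive pair counting, ties worth 1/2
brute_auc <- function(path_scores, benign_scores) {
  wins <- 0
  for (p in path_scores) {
    wins <- wins + sum(p > benign_scores) + 0.5 * sum(p == benign_scores)
  }
  wins / (length(path_scores) * length(benign_scores))
}

# uniformly random rotation matrix (QR of a Gaussian matrix, det fixed +1)
random_rotation <- function() {
  qr_dec <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_dec)
  Q %*% diag(c(1, 1, det(Q)))
}

apply_rigid <- function(model, R, t) {
  r <- model$residues
  xyz <- as.matrix(r[, c("x", "y", "z")]) %*% t(R)
  r$x <- xyz[, 1] + t[1]; r$y <- xyz[, 2] + t[2]; r$z <- xyz[, 3] + t[3]
  structure_model(model$structure_id, r[, setdiff(names(r), "has_ca")])
}

# StructureModel straight from a coordinate matrix (single chain A)
model_from_xyz <- function(xyz, chain = "A", resno = seq_len(nrow(xyz))) {
  structure_model("test", data.frame(
    chain = chain, resno = resno, ins = "", resid = "ALA", aa = "A",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], stringsAsFactors = FALSE))
}

# minimal PDB ATOM record text for C-alpha-only fixtures
pdb_atom_line <- function(serial, x, y, z, resno, chain = "A",
                          resid = "ALA", altloc = "", ins = "",
                          name = " CA ") {
  sprintf("ATOM  %5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f",
          serial, name, altloc, resid, chain, resno, ins, x, y, z, 1, 0)
}

write_pdb_fixture <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}
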