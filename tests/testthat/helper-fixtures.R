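# Shared fixtures and independent brute-force oracles.  Oracles are kept
# deliberately naive (double loops, bounding-box scans) so they stay
# independent of the implementation paths they check.

# minimal hand-written PDB: 3 residues x 4 backbone atoms + a 2-atom
# hetero group
write_tiny_pdb <- function(path) {
  lines <- c(
    "ATOM      1  N   LEU A 104      10.000  10.000  10.000  1.00  0.00           N",
    "ATOM      2  CA  LEU A 104      11.000  10.000  10.000  1.00  0.00           C",
    "ATOM      3  C   LEU A 104      12.000  10.000  10.000  1.00  0.00           C",
    "ATOM      4  O   LEU A 104      13.000  10.000  10.000  1.00  0.00           O",
    "ATOM      5  N   GLY A 105      10.000  12.000  10.000  1.00  0.00           N",
    "ATOM      6  CA  GLY A 105      11.000  12.000  10.000  1.00  0.00           C",
    "ATOM      7  C   GLY A 105      12.000  12.000  10.000  1.00  0.00           C",
    "ATOM      8  O   GLY A 105      13.000  12.000  10.000  1.00  0.00           O",
    "ATOM      9  N   ALA A 106      10.000  14.000  10.000  1.00  0.00           N",
    "ATOM     10  CA  ALA A 106      11.000  14.000  10.000  1.00  0.00           C",
    "ATOM     11  C   ALA A 106      12.000  14.000  10.000  1.00  0.00           C",
    "ATOM     12  O   ALA A 106      13.000  14.000  10.000  1.00  0.00           O",
    "HETATM   13  C1  LIG A 900       5.000   5.000   5.000  1.00  0.00           C",
    "HETATM   14  C2  LIG A 900       6.000   5.000   5.000  1.00  0.00           C",
    "END")
  writeLines(lines, path)
  path
}

model_xyz <- function(x) pocketforge:::as_xyz(x)

# brute-force residue selection: all-pairs distance double loop
bf_select_within <- function(model, centers, radius) {
  centers <- pocketforge:::as_xyz(centers)
  keys <- pocketforge:::atom_res_keys(model$atoms)
  hit <- character(0)
  for (i in seq_len(nrow(model$atoms))) {
    p <- as.numeric(model$atoms[i, c("x", "y", "z")])
    for (j in seq_len(nrow(centers))) {
      if (sqrt(sum((p - centers[j, ])^2)) <= radius) {
        hit <- c(hit, keys[i]); break
      }
    }
  }
  pocketforge:::sort_residue_keys(unique(hit))
}

# brute-force monitor distance
bf_monitor <- function(pose, model, resA, resB) {
  ca <- function(k) {
    a <- model$atoms
    i <- which(pocketforge:::atom_res_keys(a) == k & a$name == "CA")
    as.numeric(a[i[1], c("x", "y", "z")])
  }
  lig <- colMeans(model_xyz(pose))
  sqrt(sum((lig - (ca(resA) + ca(resB)) / 2)^2))
}

# brute-force occupied-voxel count by scanning the padded bounding box
bf_voxel_count <- function(xyz, spacing, radius, origin = c(0, 0, 0)) {
  xyz <- matrix(xyz, ncol = 3)
  lo <- floor((apply(xyz, 2, min) - origin - radius) / spacing) - 1
  hi <- ceiling((apply(xyz, 2, max) - origin + radius) / spacing) + 1
  count <- 0
  for (i in lo[1]:hi[1]) for (j in lo[2]:hi[2]) for (k in lo[3]:hi[3]) {
    ctr <- origin + (c(i, j, k) + 0.5) * spacing
    d2 <- min(colSums((t(xyz) - ctr)^2))
    if (d2 <= radius^2) count <- count + 1
  }
  count
}

# tie-corrected Mann-Whitney AUC for lower-is-better scores, with
# undocked compounds ranked jointly worst
bf_rank_auc <- function(label, score) {
  worst <- max(score, na.rm = TRUE) + 1
  score[is.na(score)] <- worst
  r <- rank(score)  # ties -> average rank
  act <- label == "active"
  n_a <- sum(act); n_i <- sum(!act)
  u_worse <- sum(r[act]) - n_a * (n_a + 1) / 2  # pairs where active ranks worse
  1 - u_worse / (n_a * n_i)
}

# random rigid transform
random_transform <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  R <- rbind(
    c(1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] - q[1] * q[4]),
      2 * (q[2] * q[4] + q[1] * q[3])),
    c(2 * (q[2] * q[3] + q[1] * q[4]), 1 - 2 * (q[2]^2 + q[4]^2),
      2 * (q[3] * q[4] - q[1] * q[2])),
    c(2 * (q[2] * q[4] - q[1] * q[3]), 2 * (q[3] * q[4] + q[1] * q[2]),
      1 - 2 * (q[2]^2 + q[3]^2)))
  list(rotation = R, translation = rnorm(3, sd = 5))
}

apply_rigid <- function(tf, m) sweep(m %*% t(tf$rotation), 2, tf$translation, "+")

# a pose complex cloud over copies of the toy receptor, poses scattered
# around the pocket so some pass and some fail the 4 A filter
toy_complex_cloud <- function(n, seed, spread = 4) {
  toy <- make_toy_receptor(50, seed = 7)
  lapply(seq_len(n), function(i) {
    xyz <- pocketforge:::with_seed(pocketforge::split_seed(seed, i), {
      ctr <- rnorm(3, sd = spread)
      sweep(matrix(rnorm(18, sd = 0.6), 6, 3), 2, ctr, "+")
    })
    pose <- ligand_pose(sprintf("p%03d", i), toy$model$id, xyz)
    pose_complex(toy$model, pose, metrics = list(score = -i))
  })
}
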