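#' Kabsch superposition
#'
#' Least-squares rigid-body superposition of `mobile` onto `reference`
#' via singular value decomposition, with the determinant correction that
#' excludes reflections.  Returns the optimal transform and the minimised
#' RMSD.
#'
#' @param mobile,reference `n x 3` coordinate matrices (or objects
#'   accepted by the package's coordinate accessors), equal `n >= 3`.
#' @return list with `rotation` (3 x 3, det +1), `translation`
#'   (3-vector), and `rmsd` (Angstrom).  Apply with [apply_transform()].
#' @export
kabsch_superpose <- function(mobile, reference) {
  P <- as_xyz(mobile); Q <- as_xyz(reference)
  if (nrow(P) != nrow(Q)) stop("point sets differ in size")
  if (nrow(P) < 3) stop("need at least 3 points for superposition")
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  s <- svd(crossprod(Pc, Qc))           # H = P^T Q = U D V^T
  d <- sign(det(tcrossprod(s$v, s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  fitted <- Pc %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - Qc)^2)))
  list(rotation = R, translation = as.numeric(cq - R %*% cp), rmsd = rmsd)
}

#' Apply a rigid transform to coordinates
#'
#' @param transform result of [kabsch_superpose()].
#' @param x coordinates (`n x 3` matrix or model/pose object; matrices
#'   are returned as matrices, models/poses with coordinates replaced).
#' @return transformed object of the same kind as `x`.
#' @export
apply_transform <- function(transform, x) {
  move <- function(m) sweep(m %*% t(transform$rotation), 2,
                            transform$translation, "+")
  if (inherits(x, c("structure_model", "ligand_pose"))) {
    xyz <- move(as_xyz(x))
    x$atoms$x <- xyz[, 1]; x$atoms$y <- xyz[, 2]; x$atoms$z <- xyz[, 3]
    if (inherits(x, "structure_model") && length(x$ligands))
      x$ligands <- lapply(x$ligands, function(l) apply_transform(transform, l))
    return(x)
  }
  move(as_xyz(x))
}

#' Root-mean-square deviation between paired point sets
#'
#' @param a,b equal-size coordinate sets.
#' @param fit if `TRUE`, `a` is Kabsch-superposed onto `b` first
#'   (minimised RMSD); if `FALSE` the deviation is taken in the given
#'   frame.
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(a, b, fit = FALSE) {
  A <- as_xyz(a); B <- as_xyz(b)
  if (nrow(A) != nrow(B)) stop("point sets differ in size")
  if (fit) return(kabsch_superpose(A, B)$rmsd)
  sqrt(mean(rowSums((A - B)^2)))
}

#' Geometric centroid of a point set
#'
#' Unweighted arithmetic mean of heavy-atom coordinates (no mass
#' weighting), the convention used for ligand centroids in the
#' monitor-distance filter.
#'
#' @param x coordinates (matrix, [ligand_pose()], ...).
#' @return 3-vector (Angstrom).
#' @export
centroid <- function(x) {
  m <- as_xyz(x)
  if (nrow(m) < 1) stop("empty point set")
  colMeans(m)
}

#' Monitor distance of a pose
#'
#' Distance between the ligand heavy-atom centroid and the midpoint of
#' the C-alpha atoms of two designated residues (for OR5K1, the
#' mutagenesis-identified leucines 3.32 and 6.51).  This is the quantity
#' the 0.4 nm (4.0 Angstrom) pose filter acts on.
#'
#' @param pose a [ligand_pose()].
#' @param model the receptor [structure_model()].
#' @param resA,resB residue keys of the two anchor residues (symmetric).
#' @return distance in Angstrom.
#' @export
monitor_distance <- function(pose, model, resA, resB) {
  ca <- lapply(c(resA, resB), function(k) {
    v <- residue_atom_xyz(model, k, "CA")
    if (is.null(v)) stop("residue ", k, " has no CA atom in model ", model$id)
    v
  })
  mid <- (ca[[1]] + ca[[2]]) / 2
  sqrt(sum((centroid(pose) - mid)^2))
}

#' Per-residue C-alpha distances between two models
#'
#' The per-residue distance profile used to localise where two receptor
#' models disagree (loops, helix ends).  With `prealign = TRUE` the first
#' model is Kabsch-superposed onto the second over the paired C-alpha set
#' before distances are measured, so rigid-body offsets do not register.
#'
#' @param modelA,modelB [structure_model()] objects.
#' @param pairing data frame with columns `keyA`, `keyB` (or a character
#'   vector of keys shared by both models).  Default: all residues common
#'   to both models that carry a CA atom.
#' @param prealign superpose before measuring (default `TRUE`).
#' @return data frame (`key`, `distance`) in pairing order.
#' @export
per_residue_ca_distance <- function(modelA, modelB, pairing = NULL,
                                    prealign = TRUE) {
  if (is.null(pairing)) {
    common <- intersect(residue_keys(modelA), residue_keys(modelB))
    pairing <- data.frame(keyA = common, keyB = common,
                          stringsAsFactors = FALSE)
  } else if (is.character(pairing)) {
    pairing <- data.frame(keyA = pairing, keyB = pairing,
                          stringsAsFactors = FALSE)
  }
  if (nrow(pairing) == 0) stop("empty pairing")
  A <- atom_coords_by_key(modelA, pairing$keyA, "CA")
  B <- atom_coords_by_key(modelB, pairing$keyB, "CA")
  if (prealign && nrow(A) >= 3) A <- apply_transform(kabsch_superpose(A, B), A)
  data.frame(key = pairing$keyA, distance = sqrt(rowSums((A - B)^2)),
             stringsAsFactors = FALSE)
}

#' Root-mean-square fluctuation over an ensemble
#'
#' Per-residue RMSF of a named atom across an ensemble of conformations.
#' Frames are first superposed onto the first frame over the selection,
#' the coordinate mean is taken, each frame is superposed once more onto
#' that mean (a single iteration of the mean-fitting loop), and
#' `RMSF_i = sqrt(mean_t |x_i(t) - <x_i>|^2)`.
#'
#' @param ensemble list of [structure_model()] frames (>= 2).
#' @param selection residue keys; default all residues of frame 1 that
#'   carry `atom`.
#' @param atom atom name (default `"CA"`).
#' @return data frame (`key`, `rmsf`) in Angstrom.
#' @export
rmsf <- function(ensemble, selection = NULL, atom = "CA") {
  if (length(ensemble) < 2) stop("need at least 2 frames")
  if (is.null(selection)) {
    selection <- Filter(function(k) !is.null(residue_atom_xyz(ensemble[[1]], k, atom)),
                        residue_keys(ensemble[[1]]))
  }
  frames <- lapply(ensemble, atom_coords_by_key, keys = selection,
                   atom = atom)
  n <- length(frames)
  frames <- c(frames[1], lapply(frames[-1], function(f)
    apply_transform(kabsch_superpose(f, frames[[1]]), f)))
  mean_xyz <- Reduce(`+`, frames) / n
  frames <- lapply(frames, function(f)
    apply_transform(kabsch_superpose(f, mean_xyz), f))
  mean_xyz <- Reduce(`+`, frames) / n
  dev2 <- Reduce(`+`, lapply(frames, function(f) rowSums((f - mean_xyz)^2))) / n
  data.frame(key = selection, rmsf = sqrt(dev2), stringsAsFactors = FALSE)
}
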