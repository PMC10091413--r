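#' Mutagenesis-informed distance criterion
#'
#' A pair of anchor residues plus a threshold on the
#' [monitor_distance()] between the ligand centroid and the midpoint of
#' their C-alpha atoms.  The default threshold is 4.0 Angstrom (0.4 nm),
#' the cutoff used to keep only poses engaging the two leucines
#' identified by alanine mutagenesis.
#'
#' @param resA,resB residue keys.
#' @param threshold Angstrom (> 0, default 4.0).
#' @return object of class `distance_criterion`.
#' @export
distance_criterion <- function(resA, resB, threshold = 4.0) {
  if (threshold <= 0) stop("threshold must be positive")
  structure(list(resA = resA, resB = resB, threshold = threshold),
            class = "distance_criterion")
}

#' Receptor-ligand complex with attached metrics
#'
#' @param model receptor [structure_model()].
#' @param pose [ligand_pose()] belonging to that model.
#' @param metrics named list of per-complex quantities (e.g. `auc`,
#'   `score`, `monitor_distance`).
#' @param parent id of the model this complex was refined from (lineage).
#' @return object of class `pose_complex`.
#' @export
pose_complex <- function(model, pose, metrics = list(), parent = NA_character_) {
  if (!identical(pose$model_id, model$id))
    stop("pose ", pose$pose_id, " belongs to model ", pose$model_id,
         ", not ", model$id)
  structure(list(model = model, pose = pose, metrics = metrics,
                 parent = parent),
            class = "pose_complex")
}

#' Filter pose complexes by the monitor-distance criterion
#'
#' Keeps complexes whose [monitor_distance()] is strictly below the
#' criterion threshold ("below 0.4 nm"), preserving input order.
#' Idempotent.
#'
#' @param complexes list of [pose_complex()].
#' @param criterion a [distance_criterion()].
#' @return filtered list; each survivor gains
#'   `metrics$monitor_distance`.
#' @export
filter_poses <- function(complexes, criterion) {
  stopifnot(inherits(criterion, "distance_criterion"))
  kept <- list()
  for (cx in complexes) {
    d <- tryCatch(
      monitor_distance(cx$pose, cx$model, criterion$resA, criterion$resB),
      error = function(e) stop("complex ", cx$pose$pose_id, ": ",
                               conditionMessage(e), call. = FALSE))
    if (d < criterion$threshold) {
      cx$metrics$monitor_distance <- d
      kept[[length(kept) + 1]] <- cx
    }
  }
  kept
}

#' Binding-shell residues around a ligand pose
#'
#' Residues with any heavy atom within `radius` of the ligand centroid
#' (default 7 Angstrom), the shell used to build pairwise pose RMSD
#' matrices.  Sorted by chain and residue number.
#'
#' @param model receptor [structure_model()].
#' @param pose [ligand_pose()].
#' @param radius Angstrom (> 0, default 7.0).
#' @return character vector of residue keys.
#' @export
binding_shell <- function(model, pose, radius = 7.0) {
  if (nrow(pose$atoms) == 0) stop("empty pose")
  ctr <- centroid(pose)
  heavy <- model$atoms$element != "H"
  sub <- model$atoms[heavy, , drop = FALSE]
  d2 <- cross_dist2(as_xyz(sub), matrix(ctr, 1, 3))
  hit <- d2[, 1] <= radius^2 + 1e-12
  sort_residue_keys(unique(atom_res_keys(sub)[hit]))
}

# correspondence coordinates of one complex: shell residue heavy atoms
# (matched by residue key + atom name) followed by ligand atoms
complex_coords <- function(cx, shell, include_ligand = TRUE, template = NULL) {
  at <- cx$model$atoms[cx$model$atoms$element != "H", , drop = FALSE]
  keys <- atom_res_keys(at)
  rows <- NULL
  for (k in shell) {
    i <- which(keys == k)
    if (!length(i))
      stop("complex ", cx$pose$pose_id, ": shell residue ", k, " missing")
    i <- i[order(at$name[i], method = "radix")]
    rows <- rbind(rows, data.frame(key = k, name = at$name[i],
                                   x = at$x[i], y = at$y[i], z = at$z[i]))
  }
  if (include_ligand) {
    la <- cx$pose$atoms
    rows <- rbind(rows, data.frame(key = "__ligand__", name = la$name,
                                   x = la$x, y = la$y, z = la$z))
  }
  if (!is.null(template)) {
    want <- paste(template$key, template$name)
    have <- paste(rows$key, rows$name)
    idx <- match(want, have)
    if (anyNA(idx)) {
      miss <- template[is.na(idx), ]
      stop("complex ", cx$pose$pose_id, ": no atom ", miss$name[1],
           " in residue ", miss$key[1])
    }
    rows <- rows[idx, , drop = FALSE]
  }
  rows
}

#' Pairwise RMSD matrix over a pose ensemble
#'
#' Heavy-atom RMSD between all pairs of complexes over the binding-shell
#' residues plus (by default) the ligand, with atoms matched by residue
#' key and atom name.  By default the RMSD is taken in the shared frame
#' (complexes from one refinement share the receptor frame and are
#' assumed pre-superposed); `refit = TRUE` Kabsch-fits each pair first.
#'
#' @param complexes list of [pose_complex()] with unique pose ids.
#' @param shell residue keys (e.g. from [binding_shell()]).
#' @param include_ligand include ligand atoms (default `TRUE`).
#' @param refit superpose each pair before the RMSD (default `FALSE`).
#' @return symmetric matrix (Angstrom) with pose ids as dimnames.
#' @export
pairwise_pose_rmsd <- function(complexes, shell, include_ligand = TRUE,
                               refit = FALSE) {
  n <- length(complexes)
  stopifnot(n >= 2)
  ids <- vapply(complexes, function(cx) cx$pose$pose_id, "")
  if (anyDuplicated(ids)) stop("pose ids must be unique")
  template <- complex_coords(complexes[[1]], shell, include_ligand)
  coords <- lapply(complexes, function(cx)
    as.matrix(complex_coords(cx, shell, include_ligand,
                             template)[, c("x", "y", "z")]))
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    m[i, j] <- m[j, i] <- rmsd(coords[[i]], coords[[j]], fit = refit)
  }
  m
}

#' Average-linkage dendrogram levels
#'
#' Unweighted average-linkage (UPGMA) agglomeration of a pairwise
#' distance matrix via [stats::hclust()], unrolled into one level per
#' cluster count `k = N .. 1` with the flat assignment and the merge
#' height at which that level appears.
#'
#' @param matrix symmetric non-negative matrix with zero diagonal and
#'   dimnames identifying the items.
#' @return list of class `linkage_levels` with elements `hclust` and
#'   `levels` (per `k`: `k`, `assignment` named by item id,
#'   `merge_height`).
#' @export
average_linkage <- function(matrix) {
  if (any(!is.finite(matrix))) stop("distance matrix contains non-finite values")
  if (!isSymmetric(unname(matrix), tol = 1e-8)) stop("distance matrix must be symmetric")
  if (any(diag(matrix) != 0)) stop("distance matrix must have a zero diagonal")
  n <- nrow(matrix)
  if (is.null(dimnames(matrix)))
    dimnames(matrix) <- list(seq_len(n), seq_len(n))
  hc <- hclust(as.dist(matrix), method = "average")
  levels <- lapply(n:1, function(k) {
    list(k = k,
         assignment = cutree(hc, k = k),
         merge_height = if (k == n) 0 else hc$height[n - k])
  })
  structure(list(hclust = hc, levels = levels, n = n),
            class = "linkage_levels")
}

# flat assignment at a given cluster count
level_assignment <- function(linkage, k) {
  linkage$levels[[linkage$n - k + 1]]$assignment
}

# index (into a profile vector) of the second local minimum scanning
# left to right; falls back to the global minimum when fewer than two
# local minima exist
second_local_min <- function(p) {
  n <- length(p)
  is_min <- vapply(seq_len(n), function(i)
    (i == 1 || p[i] < p[i - 1]) && (i == n || p[i] < p[i + 1]), logical(1))
  mins <- which(is_min)
  if (length(mins) >= 2) mins[2] else which.min(p)
}

#' Kelley-penalty dendrogram level selection
#'
#' Kelley-Gardner-Sutcliffe penalty for choosing the number of clusters:
#' for each level `k` in `2..N-1` the average within-cluster spread
#' (mean pairwise distance of clusters of size >= 2) is min-max
#' normalised across levels onto `[1, N-1]` and added to `k`.  The
#' selected level is the *second local minimum* of the penalty scanning
#' `k` upward — the convention used when cutting pose dendrograms — or
#' the global minimum when fewer than two local minima exist.  The
#' selection is invariant under uniform scaling of the distance matrix.
#'
#' @param linkage a [average_linkage()] result.
#' @param matrix the distance matrix the linkage was built from.
#' @return list of class `kelley_profile`: `k` (levels scanned),
#'   `penalty`, `normalized_spread`, `selected_k`.
#' @export
kelley_select <- function(linkage, matrix) {
  n <- linkage$n
  if (n < 4) stop("need at least 4 items for a Kelley profile")
  ks <- 2:(n - 1)
  spread <- vapply(ks, function(k) {
    assign <- level_assignment(linkage, k)
    sizes <- table(assign)
    cl <- names(sizes)[sizes >= 2]
    if (!length(cl)) return(NA_real_)
    mean(vapply(cl, function(c0) {
      idx <- which(assign == as.integer(c0))
      sub <- matrix[idx, idx, drop = FALSE]
      mean(sub[upper.tri(sub)])
    }, 0))
  }, 0)
  if (all(is.na(spread))) stop("degenerate levels: no cluster of size >= 2")
  rng <- range(spread, na.rm = TRUE)
  norm <- if (diff(rng) < 1e-12) rep(1, length(spread)) else
    1 + (spread - rng[1]) / diff(rng) * (n - 2)
  norm[is.na(norm)] <- n - 1  # all-singleton levels carry maximal spread
  penalty <- norm + ks
  structure(list(k = ks, penalty = penalty, normalized_spread = norm,
                 selected_k = ks[second_local_min(penalty)]),
            class = "kelley_profile")
}

#' Best complex per cluster
#'
#' Per cluster, the complex maximising `key_metric` (default `"auc"`),
#' with deterministic lexicographic tie-breaking on pose id.
#'
#' @param assignment named integer vector: pose id -> cluster index
#'   (e.g. a level assignment from [average_linkage()]).
#' @param complexes list of [pose_complex()]; each must carry the metric.
#' @param key_metric metric name in `metrics` (default `"auc"`).
#' @return named list: cluster index (as character) -> `pose_complex`.
#' @export
cluster_representatives <- function(assignment, complexes,
                                    key_metric = "auc") {
  ids <- vapply(complexes, function(cx) cx$pose$pose_id, "")
  vals <- vapply(complexes, function(cx) {
    v <- cx$metrics[[key_metric]]
    if (is.null(v)) stop("complex ", cx$pose$pose_id, " lacks metric '",
                         key_metric, "'")
    as.numeric(v)
  }, 0)
  if (!all(ids %in% names(assignment)))
    stop("assignment lacks pose id(s): ",
         paste(setdiff(ids, names(assignment)), collapse = ", "))
  cl <- assignment[ids]
  out <- list()
  for (c0 in sort(unique(cl))) {
    in_cl <- which(cl == c0)
    best <- in_cl[order(-vals[in_cl], ids[in_cl], method = "radix")][1]
    out[[as.character(c0)]] <- complexes[[best]]
  }
  out
}
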