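#' Backbone segment container
#'
#' An ordered run of backbone heavy atoms (N, CA, C, O per residue,
#' N- to C-terminus) extracted from one model or trajectory frame —
#' typically an extracellular loop whose fold is being compared across
#' an ensemble.  Structures must already share a common frame
#' (superpose receptors first; see [kabsch_superpose()]).
#'
#' @param segment_id unique tag.
#' @param atoms data frame with `name`, `x`, `y`, `z` (ordered), or an
#'   `n x 3` matrix.
#' @param source model/frame tag the segment came from.
#' @return object of class `backbone_segment`.
#' @export
backbone_segment <- function(segment_id, atoms, source = "") {
  if (is.matrix(atoms))
    atoms <- data.frame(name = rep_len(c("N", "CA", "C", "O"), nrow(atoms)),
                        x = atoms[, 1], y = atoms[, 2], z = atoms[, 3])
  if (nrow(atoms) < 1) stop("empty segment")
  structure(list(segment_id = segment_id, atoms = atoms, source = source),
            class = "backbone_segment")
}

#' Extract a backbone segment from a model
#'
#' @param model a [structure_model()].
#' @param chain chain id.
#' @param first,last first and last residue number (inclusive).
#' @param segment_id tag; default `"<model id>:<chain>:<first>-<last>"`.
#' @return a [backbone_segment()] of the N, CA, C, O atoms in residue
#'   order.
#' @export
extract_segment <- function(model, chain, first, last, segment_id = NULL) {
  a <- model$atoms
  sel <- a$chain == chain & a$resnum >= first & a$resnum <= last &
    a$name %in% c("N", "CA", "C", "O")
  if (!any(sel)) stop("no backbone atoms in ", chain, ":", first, "-", last)
  a <- a[sel, , drop = FALSE]
  a <- a[order(a$resnum, match(a$name, c("N", "CA", "C", "O"))), , drop = FALSE]
  if (is.null(segment_id))
    segment_id <- paste0(model$id, ":", chain, ":", first, "-", last)
  backbone_segment(segment_id, a[, c("name", "x", "y", "z")], source = model$id)
}

#' Voxelise a backbone segment
#'
#' Occupancy grid on a fixed lattice: voxel `(i, j, k)` covers
#' `origin + [i, i+1) * spacing` per axis and is occupied iff its centre
#' lies within `atom_radius` of any segment atom.  Because the lattice is
#' anchored at `origin` (not at the data), grids of different segments
#' are directly comparable, and translating a segment by an exact
#' multiple of the spacing shifts the occupied set without changing its
#' size.
#'
#' @param segment a [backbone_segment()] (or coordinate matrix).
#' @param spacing voxel edge in Angstrom (default 1.0).
#' @param atom_radius atom radius in Angstrom (default 2.0).
#' @param origin lattice origin (default `c(0, 0, 0)`).
#' @return object of class `voxel_grid`: `origin`, `spacing`,
#'   `occupied` (integer index matrix), `keys` (index strings).
#' @export
voxelize <- function(segment, spacing = 1.0, atom_radius = 2.0,
                     origin = c(0, 0, 0)) {
  xyz <- as_xyz(if (inherits(segment, "backbone_segment")) segment$atoms else segment)
  if (nrow(xyz) == 0) stop("empty segment")
  if (spacing <= 0) stop("spacing must be positive")
  occ <- new.env(hash = TRUE)
  r2 <- atom_radius^2
  for (i in seq_len(nrow(xyz))) {
    p <- (xyz[i, ] - origin) / spacing
    lo <- floor(p - atom_radius / spacing - 1)
    hi <- ceiling(p + atom_radius / spacing + 1)
    gx <- lo[1]:hi[1]; gy <- lo[2]:hi[2]; gz <- lo[3]:hi[3]
    ctr <- expand.grid(ix = gx, iy = gy, iz = gz)
    cx <- (ctr$ix + 0.5) * spacing + origin[1]
    cy <- (ctr$iy + 0.5) * spacing + origin[2]
    cz <- (ctr$iz + 0.5) * spacing + origin[3]
    d2 <- (cx - xyz[i, 1])^2 + (cy - xyz[i, 2])^2 + (cz - xyz[i, 3])^2
    inside <- which(d2 <= r2)
    for (j in inside) {
      key <- paste(ctr$ix[j], ctr$iy[j], ctr$iz[j], sep = ",")
      assign(key, c(ctr$ix[j], ctr$iy[j], ctr$iz[j]), envir = occ)
    }
  }
  keys <- ls(occ)
  idx <- if (length(keys)) t(vapply(keys, function(k) get(k, envir = occ),
                                    numeric(3))) else matrix(0, 0, 3)
  structure(list(origin = origin, spacing = spacing,
                 occupied = unname(idx), keys = keys,
                 id = if (inherits(segment, "backbone_segment"))
                   segment$segment_id else NULL),
            class = "voxel_grid")
}

#' Volume overlap of two voxel grids
#'
#' Normalised shared volume `n` in `[0, 1]`.  Default normalisation is
#' by the smaller volume (`|A & B| / min(|A|, |B|)`), so self-overlap
#' and containment are exactly 1 and the derived dissimilarity `1 - n`
#' spans `[0, 1]`; `"tanimoto"` normalises by the union instead.
#'
#' @param a,b [voxelize()] results sharing origin and spacing.
#' @param normalize `"min"` (default) or `"tanimoto"`.
#' @return overlap value in `[0, 1]`.
#' @export
overlap <- function(a, b, normalize = c("min", "tanimoto")) {
  normalize <- match.arg(normalize)
  if (max(abs(a$origin - b$origin)) > 1e-9 ||
      abs(a$spacing - b$spacing) > 1e-9)
    stop("voxel grids are on different lattices (origin/spacing mismatch)")
  inter <- length(intersect(a$keys, b$keys))
  denom <- switch(normalize,
                  min = min(length(a$keys), length(b$keys)),
                  tanimoto = length(union(a$keys, b$keys)))
  if (denom == 0) stop("cannot overlap empty grids")
  inter / denom
}

#' Pairwise 1 - overlap dissimilarity matrix
#'
#' Voxelises every segment on a common lattice and assembles the
#' symmetric matrix of `1 - n` values (zero diagonal) that defines the
#' loop shape space.
#'
#' @param segments list of [backbone_segment()] in a common frame.
#' @param spacing,atom_radius,origin lattice parameters, see
#'   [voxelize()].
#' @param normalize overlap normalisation, see [overlap()].
#' @return symmetric matrix in `[0, 1]` with segment ids as dimnames.
#' @export
dissimilarity_matrix <- function(segments, spacing = 1.0, atom_radius = 2.0,
                                 origin = c(0, 0, 0),
                                 normalize = c("min", "tanimoto")) {
  normalize <- match.arg(normalize)
  if (length(segments) < 2) stop("need at least 2 segments")
  ids <- vapply(segments, function(s) s$segment_id, "")
  if (anyDuplicated(ids)) stop("segment ids must be unique")
  grids <- lapply(segments, voxelize, spacing = spacing,
                  atom_radius = atom_radius, origin = origin)
  n <- length(grids)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    m[i, j] <- m[j, i] <- 1 - overlap(grids[[i]], grids[[j]], normalize)
  }
  m
}

#' 2D embedding of a shape-space dissimilarity matrix
#'
#' t-distributed stochastic neighbour embedding of the `1 - n` matrix
#' (exact gradient, suitable for the ensemble sizes loop analyses use),
#' deterministic for a fixed seed.  When `N - 1 < 3 * perplexity` the
#' perplexity is reduced to `floor((N - 1) / 3)` with a warning, and the
#' value actually used is recorded.
#'
#' @param matrix symmetric dissimilarity matrix with id dimnames.
#' @param perplexity target perplexity (default 25).
#' @param angle kept for provenance; 0 selects the exact gradient, which
#'   is what this implementation computes for any value.
#' @param max_iter gradient-descent iterations (default 1000).
#' @param seed RNG seed for the initial layout.
#' @return data frame (`id`, `x`, `y`) with the parameters used attached
#'   as attribute `params`.
#' @export
embed_shapespace <- function(matrix, perplexity = 25, angle = 0,
                             max_iter = 1000, seed = 0) {
  if (!is.matrix(matrix) || nrow(matrix) != ncol(matrix))
    stop("need a square dissimilarity matrix")
  if (any(!is.finite(matrix))) stop("dissimilarity matrix contains non-finite values")
  n <- nrow(matrix)
  used_perplexity <- perplexity
  if (n - 1 < 3 * perplexity) {
    used_perplexity <- max(1, floor((n - 1) / 3))
    warning("perplexity ", perplexity, " too large for N = ", n,
            "; reduced to ", used_perplexity)
  }
  coords <- tsne_exact(matrix, perplexity = used_perplexity,
                       max_iter = max_iter, seed = seed)
  ids <- rownames(matrix) %||% as.character(seq_len(n))
  out <- data.frame(id = ids, x = coords[, 1], y = coords[, 2],
                    stringsAsFactors = FALSE)
  attr(out, "params") <- list(perplexity = used_perplexity, angle = angle,
                              max_iter = max_iter, seed = seed)
  out
}

#' Representative segments of a conformational ensemble
#'
#' Average-linkage clustering of the `1 - n` dissimilarity matrix cut at
#' `k = count` clusters; per cluster the medoid (minimum mean
#' dissimilarity to the other members) is returned, with deterministic
#' lexicographic tie-breaking on segment id.  This is how a handful of
#' representative loop folds (e.g. 10 per trajectory replica) is
#' distilled from a frame ensemble.
#'
#' @param segments list of [backbone_segment()].
#' @param count number of representatives (default 10, `<= N`).
#' @param ... lattice parameters passed to [dissimilarity_matrix()].
#' @return list of `count` segments, ordered by cluster index.
#' @export
ensemble_representatives <- function(segments, count = 10, ...) {
  n <- length(segments)
  if (count > n) stop("count exceeds the number of segments")
  if (count == n) return(segments)
  ids <- vapply(segments, function(s) s$segment_id, "")
  d <- dissimilarity_matrix(segments, ...)
  linkage <- average_linkage(d)
  assign <- level_assignment(linkage, count)
  out <- list()
  for (c0 in sort(unique(assign))) {
    idx <- which(assign == c0)
    mean_d <- vapply(idx, function(i) mean(d[i, idx]), 0)
    best <- idx[order(mean_d, ids[idx], method = "radix")][1]
    out[[length(out) + 1]] <- segments[[best]]
  }
  out
}
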