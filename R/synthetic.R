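# Synthetic study systems: toy receptors with a defined pocket, pose
# clouds with planted clusters, screening tables with calibrated AUC,
# and loop families with planted folds.  Everything is deterministic for
# a fixed seed, and one master seed can be fanned out with split_seed().

# deterministic compact ligand: `size` pseudo-atoms in a ball of radius
# `extent` around `center`
synthetic_ligand <- function(compound_id, model_id, center = c(0, 0, 0),
                             size = 8, extent = 1.2, seed = 1,
                             score = NULL) {
  xyz <- with_seed(seed, {
    m <- matrix(rnorm(size * 3), size, 3)
    m <- m / sqrt(rowSums(m^2)) * runif(size, 0, extent)
    sweep(m, 2, center, "+")
  })
  ligand_pose(pose_id = compound_id, model_id = model_id, atoms = xyz,
              score = score)
}

#' Generate a toy receptor with a defined binding pocket
#'
#' Residues are arranged on a cylindrical shell around a pocket centred
#' at the origin: backbone atoms (N, CA, C, O) on the outer wall,
#' side-chain pseudo-atoms pointing inward.  Two key residues (full
#' leucines, 8 heavy atoms) sit diametrically opposite on the central
#' ring so that the midpoint of their C-alpha atoms is exactly the
#' pocket centre — the toy analogue of the mutagenesis-identified
#' leucine pair flanking an orthosteric site.  The remaining central-ring
#' residues are pocket-lining leucines; outer rings mix ALA/GLY/SER/VAL.
#'
#' @param n_residues number of residues (>= 10, default 50).
#' @param pocket_radius pocket radius in Angstrom (default 6).
#' @param seed RNG seed (controls small deterministic jitter).
#' @return list: `model` ([structure_model()]), `pocket`
#'   ([pocket_definition()] whose `points` fill the pocket sphere), and
#'   `key_residues` (two residue keys).
#' @export
make_toy_receptor <- function(n_residues = 50, pocket_radius = 6,
                              seed = 7) {
  if (n_residues < 10) stop("need at least 10 residues")
  ring_size <- 16
  n_rings <- ceiling(n_residues / ring_size)
  r_ca <- pocket_radius + 2.5
  rows <- list()
  serial <- 0
  add_atom <- function(res, name, element, xyz) {
    serial <<- serial + 1
    data.frame(serial = serial, name = name, element = element,
               resname = res$resname, chain = "A", resnum = res$resnum,
               insert = "", x = xyz[1], y = xyz[2], z = xyz[3],
               stringsAsFactors = FALSE)
  }
  jit <- with_seed(seed, matrix(rnorm(n_residues * 3, sd = 0.05),
                                n_residues, 3))
  central_ring <- ceiling(n_rings / 2)
  # key residues: positions 1 and 1 + ring_size/2 of the central ring
  first_central <- (central_ring - 1) * ring_size + 1
  key_idx <- c(first_central, first_central + ring_size %/% 2)
  key_idx <- pmin(key_idx, n_residues)
  if (key_idx[1] == key_idx[2]) key_idx[2] <- key_idx[1] + 1
  res_counter <- 0
  for (ring in seq_len(n_rings)) {
    z0 <- (ring - central_ring) * 4
    in_ring <- min(ring_size, n_residues - (ring - 1) * ring_size)
    for (p in seq_len(in_ring)) {
      res_counter <- res_counter + 1
      i <- res_counter
      theta <- 2 * pi * (p - 1) / ring_size
      is_key <- i %in% key_idx
      central <- ring == central_ring
      resname <- if (central) "LEU" else
        c("ALA", "GLY", "SER", "VAL")[(p - 1) %% 4 + 1]
      res <- list(resnum = i, resname = resname)
      radial <- c(cos(theta), sin(theta), 0)
      tang <- c(-sin(theta), cos(theta), 0)
      axis <- c(0, 0, 1)
      ca <- if (is_key) r_ca * radial + c(0, 0, z0)  # exact: midpoint = centre
            else r_ca * radial + c(0, 0, z0) + jit[i, ]
      # N and C sit off the CA-tangent line so the backbone is never
      # collinear (ideal C-beta construction needs a defined bisector)
      rows[[length(rows) + 1]] <- add_atom(res, "N", "N",
                                           ca + 1.4 * tang + 0.5 * axis)
      rows[[length(rows) + 1]] <- add_atom(res, "CA", "C", ca)
      rows[[length(rows) + 1]] <- add_atom(res, "C", "C",
                                           ca - 1.4 * tang + 0.5 * axis)
      rows[[length(rows) + 1]] <- add_atom(res, "O", "O",
                                           ca - 1.4 * tang + 0.5 * axis +
                                             1.23 * radial)
      if (resname != "GLY") {
        cb <- ca - 1.5 * radial
        rows[[length(rows) + 1]] <- add_atom(res, "CB", "C", cb)
        if (resname == "LEU") {
          cg <- ca - (r_ca - pocket_radius + 1) * radial
          rows[[length(rows) + 1]] <- add_atom(res, "CG", "C", cg)
          rows[[length(rows) + 1]] <-
            add_atom(res, "CD1", "C", cg - 0.8 * radial + 0.9 * tang)
          rows[[length(rows) + 1]] <-
            add_atom(res, "CD2", "C", cg - 0.8 * radial - 0.9 * tang)
        }
        if (resname == "SER")
          rows[[length(rows) + 1]] <- add_atom(res, "OG", "O",
                                               cb - 1.0 * radial)
        if (resname == "VAL")
          rows[[length(rows) + 1]] <- add_atom(res, "CG1", "C",
                                               cb + 1.2 * tang)
      }
    }
  }
  atoms <- do.call(rbind, rows)
  model <- structure_model("toy", atoms,
                           provenance = sprintf("synthetic toy receptor (seed %d)", seed))
  # pocket points: lattice filling the pocket sphere
  g <- seq(-pocket_radius, pocket_radius, by = 2)
  pts <- as.matrix(expand.grid(x = g, y = g, z = g))
  pts <- pts[rowSums(pts^2) <= pocket_radius^2, , drop = FALSE]
  keys <- residue_key("A", key_idx)
  list(model = model,
       pocket = pocket_definition(c(0, 0, 0), box_edge = 2 * pocket_radius,
                                  points = pts),
       key_residues = keys)
}

#' Generate a pose cloud with planted clusters
#'
#' `k` cluster centres separated by at least `between_sep` (placed on a
#' lattice of that spacing), each populated with `n_per_cluster` copies
#' of a common ligand template jittered isotropically with standard
#' deviation `within_sigma` per coordinate.
#'
#' @param k number of planted clusters.
#' @param n_per_cluster poses per cluster.
#' @param within_sigma within-cluster jitter (Angstrom).
#' @param between_sep minimal centre separation (> 0, Angstrom).
#' @param seed RNG seed.
#' @param model_id receptor tag attached to the poses.
#' @return list: `poses` (list of [ligand_pose()]) and `labels` (true
#'   cluster index per pose).
#' @export
make_pose_cloud <- function(k = 5, n_per_cluster = 10, within_sigma = 0.5,
                            between_sep = 10, seed = 1,
                            model_id = "cloud") {
  if (between_sep <= 0) stop("between_sep must be positive")
  side <- ceiling(k^(1 / 3))
  grid <- as.matrix(expand.grid(0:(side), 0:(side), 0:(side))) * between_sep
  centers <- grid[seq_len(k), , drop = FALSE]
  template <- as_xyz(synthetic_ligand("template", model_id,
                                      seed = split_seed(seed, 0)))
  poses <- list(); labels <- integer(0)
  idx <- 0
  for (c0 in seq_len(k)) {
    for (m in seq_len(n_per_cluster)) {
      idx <- idx + 1
      xyz <- with_seed(split_seed(seed, idx), {
        sweep(template, 2, centers[c0, ], "+") +
          matrix(rnorm(length(template), sd = within_sigma),
                 nrow(template), 3)
      })
      poses[[idx]] <- ligand_pose(sprintf("pose_%03d", idx), model_id, xyz)
      labels[idx] <- c0
    }
  }
  list(poses = poses, labels = labels)
}

#' Generate a screening table with a calibrated AUC
#'
#' Binormal construction: active scores are drawn from
#' `N(-delta, 1)` and inactive scores from `N(0, 1)` (lower is better)
#' with `delta = sqrt(2) * qnorm(target_auc)`, so the population AUC is
#' exactly `target_auc` and the empirical AUC converges to it as the
#' library grows.
#'
#' @param n_actives,n_inactives library composition.
#' @param target_auc population AUC, strictly between 0.5 and 1.
#' @param seed RNG seed.
#' @return a [screen_records()] table (all compounds docked).
#' @export
make_screen_scores <- function(n_actives = 13, n_inactives = 131,
                               target_auc = 0.85, seed = 1) {
  if (target_auc <= 0.5 || target_auc >= 1)
    stop("target_auc must lie strictly between 0.5 and 1")
  delta <- sqrt(2) * qnorm(target_auc)
  with_seed(seed, {
    screen_records(
      compound_id = c(sprintf("ACT%04d", seq_len(n_actives)),
                      sprintf("INA%04d", seq_len(n_inactives))),
      label = rep(c("active", "inactive"), c(n_actives, n_inactives)),
      score = c(rnorm(n_actives, mean = -delta), rnorm(n_inactives)))
  })
}

# parametric backbone templates for loop families: CA trace along a
# curve, with N/C/O offset from the local tangent
loop_template <- function(family, n_residues = 12) {
  i <- seq_len(n_residues)
  ca <- switch(((family - 1) %% 3) + 1,
    # extended strand
    cbind(3.3 * i, 0 * i, 0 * i),
    # hairpin: out along +x, turn, back shifted in y
    {
      half <- ceiling(n_residues / 2)
      out <- cbind(3.3 * seq_len(half), 0, 0)
      back <- cbind(3.3 * rev(seq_len(n_residues - half)), 4.8, 0)
      rbind(out, back)
    },
    # helical arc
    cbind(2.3 * cos(100 * pi / 180 * i), 2.3 * sin(100 * pi / 180 * i),
          1.5 * i))
  # distinct higher-order families: tilt the template
  tilt <- (family - 1) %/% 3
  if (tilt > 0) {
    ang <- tilt * pi / 5
    R <- rbind(c(cos(ang), 0, sin(ang)), c(0, 1, 0),
               c(-sin(ang), 0, cos(ang)))
    ca <- ca %*% t(R)
  }
  rows <- NULL
  for (r in seq_len(n_residues)) {
    nxt <- ca[min(r + 1, n_residues), ] - ca[max(r - 1, 1), ]
    t0 <- unit3(nxt)
    perp <- unit3(cross3(t0, c(0, 0, 1) + 1e-3))
    rows <- rbind(rows,
                  cbind(c("N", "CA", "C", "O"),
                        rbind(ca[r, ] - 1.2 * t0, ca[r, ],
                              ca[r, ] + 1.2 * t0,
                              ca[r, ] + 1.2 * t0 + 1.23 * perp)))
  }
  data.frame(name = rows[, 1], x = as.numeric(rows[, 2]),
             y = as.numeric(rows[, 3]), z = as.numeric(rows[, 4]),
             stringsAsFactors = FALSE)
}

#' Generate backbone loop families with planted folds
#'
#' Each family is a distinct parametric backbone template (extended
#' strand, hairpin, helical arc, and tilted variants beyond three
#' families); members are the template plus isotropic Gaussian noise.
#' All families share a common frame, emulating loops extracted from
#' superposed receptor models.
#'
#' @param n_families number of families (>= 2).
#' @param members members per family.
#' @param noise_sigma per-coordinate noise (Angstrom).
#' @param seed RNG seed.
#' @param n_residues residues per loop (default 12).
#' @return list: `segments` (list of [backbone_segment()]) and `labels`
#'   (family index per segment).
#' @export
make_loop_families <- function(n_families = 3, members = 10,
                               noise_sigma = 0.3, seed = 1,
                               n_residues = 12) {
  if (n_families < 2) stop("need at least 2 families")
  segments <- list(); labels <- integer(0)
  idx <- 0
  for (f in seq_len(n_families)) {
    template <- loop_template(f, n_residues)
    txyz <- as.matrix(template[, c("x", "y", "z")])
    for (m in seq_len(members)) {
      idx <- idx + 1
      xyz <- with_seed(split_seed(seed, idx),
                       txyz + matrix(rnorm(length(txyz), sd = noise_sigma),
                                     nrow(txyz), 3))
      atoms <- template
      atoms[, c("x", "y", "z")] <- xyz
      segments[[idx]] <- backbone_segment(sprintf("fam%d_m%02d", f, m),
                                          atoms,
                                          source = sprintf("family%d", f))
      labels[idx] <- f
    }
  }
  list(segments = segments, labels = labels)
}
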