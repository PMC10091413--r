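#' Deterministic mock docking engine
#'
#' Reference implementation of the [docking_engine()] contract for
#' testing and protocol development.  Scoring is a transparent contact
#' count rather than a physical potential, which makes it exactly
#' invertible for oracle checks:
#' `score = -(receptor heavy atoms within contact_cutoff of the ligand)
#'  + 10 * (receptor heavy atoms within clash_cutoff)`.
#' Consequently truncating a residue that contributes `c` contact atoms
#' raises the score by exactly `c`, and mutating a residue far from the
#' pose changes nothing.
#'
#' `dock()` places a deterministic pseudo-ligand (seeded per compound
#' and model) near the pocket centre; `refine()` jitters only the
#' side-chain atoms of the flexible residues and the ligand, honouring
#' the contract that everything else stays fixed.  An optional
#' `score_fun(compound_id, model_id)` overrides docking scores (return
#' `NA` for an undocked compound), which lets tests rig perfect, random,
#' or paper-shaped rankings.
#'
#' @param contact_cutoff contact distance (Angstrom, default 4.0).
#' @param clash_cutoff clash distance (Angstrom, default 1.5).
#' @param jitter standard deviation of refinement moves (default 0.3).
#' @param n_poses poses generated per `refine()`/`dock()` call
#'   (default 5, capped by `max_poses`).
#' @param max_poses retention cap per refinement (default 20).
#' @param score_fun optional score override, see above.
#' @param seed engine seed (combined with per-call seeds).
#' @return a [docking_engine()].
#' @export
mock_engine <- function(contact_cutoff = 4.0, clash_cutoff = 1.5,
                        jitter = 0.3, n_poses = 5, max_poses = 20,
                        score_fun = NULL, seed = 1) {
  heavy_xyz <- function(model)
    as_xyz(model$atoms[model$atoms$element != "H", , drop = FALSE])

  score_in_place <- function(model, pose) {
    d2 <- cross_dist2(heavy_xyz(model), as_xyz(pose))
    mind <- sqrt(apply(d2, 1, min))
    -sum(mind <= contact_cutoff) + 10 * sum(mind <= clash_cutoff)
  }

  dock <- function(model, compound, pocket) {
    cid <- as.character(compound)
    base_seed <- split_seed(seed, hash31(paste(cid, model$id)))
    if (!is.null(score_fun)) {
      s <- score_fun(cid, model$id)
      if (is.na(s)) return(list())
      pose <- synthetic_ligand(paste0(cid, "@", model$id), model$id,
                               center = pocket$center, seed = base_seed,
                               score = s)
      return(list(pose))
    }
    poses <- lapply(seq_len(n_poses), function(p) {
      shift <- with_seed(split_seed(base_seed, p),
                         rnorm(3, sd = jitter))
      pose <- synthetic_ligand(sprintf("%s@%s.p%d", cid, model$id, p),
                               model$id, center = pocket$center + shift,
                               seed = base_seed)
      pose$score <- score_in_place(model, pose)
      pose
    })
    poses[order(vapply(poses, function(p) p$score, 0),
                vapply(poses, function(p) p$pose_id, ""))]
  }

  refine <- function(model, compound, pocket, flexible, seed) {
    cid <- as.character(compound)
    backbone <- c("N", "CA", "C", "O", "OXT")
    keys <- atom_res_keys(model$atoms)
    movable <- which(keys %in% flexible & !(model$atoms$name %in% backbone))
    n_out <- min(n_poses, max_poses)
    lapply(seq_len(n_out), function(p) {
      child <- split_seed(seed, p)
      new_model <- model
      new_model$id <- sprintf("%s.s%d.p%d", model$id, seed %% 100000L, p)
      if (length(movable)) {
        moves <- with_seed(child, matrix(rnorm(length(movable) * 3,
                                               sd = jitter),
                                         length(movable), 3))
        new_model$atoms[movable, c("x", "y", "z")] <-
          new_model$atoms[movable, c("x", "y", "z")] + moves
      }
      shift <- with_seed(split_seed(child, 7), rnorm(3, sd = jitter))
      pose <- synthetic_ligand(paste0(new_model$id, ".", cid),
                               new_model$id,
                               center = pocket$center + shift,
                               seed = split_seed(child, 11))
      pose$score <- score_in_place(new_model, pose)
      pose$round <- NULL
      pose_complex(new_model, pose,
                   metrics = list(score = pose$score))
    })
  }

  docking_engine(dock = dock, refine = refine,
                 score_in_place = score_in_place, name = "mock")
}
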