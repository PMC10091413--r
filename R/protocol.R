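#' Docking pocket definition
#'
#' The protocol never detects pockets itself: a pocket is a user-supplied
#' centre (either explicit pocket points, whose centroid defines the
#' grid centre, or the centroid of a reference docked ligand) plus a box
#' edge.
#'
#' @param center 3-vector (Angstrom).
#' @param box_edge docking box edge (> 0, default 10).
#' @param points optional `n x 3` matrix of pocket-filling points (used
#'   by the `pocket_shell` flexible-residue policy).
#' @return object of class `pocket_definition`.
#' @export
pocket_definition <- function(center, box_edge = 10, points = NULL) {
  if (box_edge <= 0) stop("box_edge must be positive")
  stopifnot(length(center) == 3, all(is.finite(center)))
  structure(list(center = as.numeric(center), box_edge = box_edge,
                 points = points),
            class = "pocket_definition")
}

#' Pocket centred on a reference ligand pose
#'
#' @param pose a [ligand_pose()]; the pocket centre is its centroid.
#' @param box_edge box edge (default 10).
#' @return a [pocket_definition()].
#' @export
pocket_from_pose <- function(pose, box_edge = 10) {
  pocket_definition(centroid(pose), box_edge = box_edge,
                    points = as_xyz(pose))
}

#' Specification of one induced-fit refinement round
#'
#' Each round declares which receptor side chains the engine may move:
#' `pocket_shell` (residues within `radius`, default 3 Angstrom, of the
#' pocket points — the opening round over the whole extracellular
#' pocket), `ligand_shell` (residues within `radius`, default 4
#' Angstrom, of the current ligand pose — the focusing round), or
#' `named` (an explicit residue list — the final round sampling only the
#' key residues).  The shrinking flexible set is the heart of the
#' iterative protocol.
#'
#' @param name round label (`"IFD1"`, `"IFD2"`, `"IFD3"`, or custom).
#' @param flexible_policy `"pocket_shell"`, `"ligand_shell"` or
#'   `"named"`.
#' @param radius shell radius (defaults: 3.0 for `pocket_shell`, 4.0 for
#'   `ligand_shell`).
#' @param residues residue keys for the `named` policy.
#' @param probe_ligands compound ids docked/refined in this round.
#' @return object of class `round_spec`.
#' @export
round_spec <- function(name = c("IFD1", "IFD2", "IFD3", "custom"),
                       flexible_policy = c("pocket_shell", "ligand_shell",
                                           "named"),
                       radius = NULL, residues = NULL,
                       probe_ligands = "probe") {
  name <- match.arg(name)
  flexible_policy <- match.arg(flexible_policy)
  if (is.null(radius))
    radius <- switch(flexible_policy, pocket_shell = 3.0,
                     ligand_shell = 4.0, named = NA_real_)
  if (flexible_policy != "named" && radius <= 0) stop("radius must be positive")
  if (flexible_policy == "named" && !length(residues))
    stop("named policy needs a non-empty residue list")
  structure(list(name = name, flexible_policy = flexible_policy,
                 radius = radius, residues = residues,
                 probe_ligands = probe_ligands),
            class = "round_spec")
}

#' Survival gate for refined models
#'
#' A refined complex survives a round iff its screening AUC exceeds
#' `min_auc` (strict `>` by default, configurable) and its
#' [monitor_distance()] is strictly below `max_monitor_distance`
#' (0.4 nm = 4.0 Angstrom by default).
#'
#' @param criterion a [distance_criterion()] naming the two anchor
#'   residues.
#' @param min_auc AUC threshold in `[0, 1]` (default 0.8); `NULL`
#'   disables the AUC gate.
#' @param max_monitor_distance Angstrom (default 4.0).
#' @param strict_auc require `auc > min_auc` (default) rather than `>=`.
#' @return object of class `model_gate`.
#' @export
model_gate <- function(criterion, min_auc = 0.8, max_monitor_distance = 4.0,
                       strict_auc = TRUE) {
  stopifnot(inherits(criterion, "distance_criterion"))
  if (!is.null(min_auc) && (min_auc < 0 || min_auc > 1))
    stop("min_auc must lie in [0, 1]")
  structure(list(criterion = criterion, min_auc = min_auc,
                 max_monitor_distance = max_monitor_distance,
                 strict_auc = strict_auc),
            class = "model_gate")
}

gate_passes <- function(gate, auc_value, dist_value) {
  ok_auc <- if (is.null(gate$min_auc)) TRUE
            else if (is.na(auc_value)) FALSE
            else if (gate$strict_auc) auc_value > gate$min_auc
            else auc_value >= gate$min_auc
  ok_auc && dist_value < gate$max_monitor_distance
}

#' Pluggable docking engine contract
#'
#' The conformational search itself (commercial induced-fit docking) is
#' out of scope; the protocol talks to any backend providing three
#' deterministic operations:
#' \describe{
#'   \item{`dock(model, compound, pocket)`}{list of scored
#'     [ligand_pose()], empty when the compound cannot be docked.}
#'   \item{`refine(model, compound, pocket, flexible, seed)`}{list of
#'     [pose_complex()]; must move only the ligand and atoms of the
#'     `flexible` residues.}
#'   \item{`score_in_place(model, pose)`}{finite score in kcal/mol,
#'     lower is better.}
#' }
#' [mock_engine()] is the reference implementation.
#'
#' @param dock,refine,score_in_place backend functions as above.
#' @param name backend tag.
#' @return object of class `docking_engine`.
#' @export
docking_engine <- function(dock, refine, score_in_place, name = "engine") {
  stopifnot(is.function(dock), is.function(refine),
            is.function(score_in_place))
  structure(list(dock = dock, refine = refine,
                 score_in_place = score_in_place, name = name),
            class = "docking_engine")
}

#' Flexible residues of a refinement round
#'
#' Resolves a [round_spec()] policy into a concrete residue set:
#' `pocket_shell` selects residues within the round radius of the pocket
#' points, `ligand_shell` within the radius of a ligand pose, `named`
#' returns the declared list after checking existence.
#'
#' @param model a [structure_model()].
#' @param spec a [round_spec()].
#' @param context pocket points (matrix or [pocket_definition()]) for
#'   `pocket_shell`; a [ligand_pose()] for `ligand_shell`; ignored for
#'   `named`.
#' @return character vector of residue keys (sorted).
#' @export
flexible_residues <- function(model, spec, context = NULL) {
  switch(spec$flexible_policy,
    pocket_shell = {
      pts <- if (inherits(context, "pocket_definition"))
        context$points %||% matrix(context$center, 1, 3) else as_xyz(context)
      select_within(model, pts, spec$radius)
    },
    ligand_shell = {
      if (!inherits(context, "ligand_pose"))
        stop("ligand_shell policy needs a ligand_pose context")
      select_within(model, context, spec$radius)
    },
    named = {
      missing <- setdiff(spec$residues, residue_keys(model))
      if (length(missing))
        stop("named residue(s) absent from model ", model$id, ": ",
             paste(missing, collapse = ", "))
      sort_residue_keys(spec$residues)
    })
}

#' Evaluate one receptor model by screening enrichment
#'
#' Docks every library compound with the engine, ranks the outcomes
#' (undocked compounds ranked worst), and computes the ROC AUC and the
#' top-fraction enrichment factor.  An engine failure on a compound is
#' recorded as undocked, never as an error.
#'
#' @param model a [structure_model()].
#' @param library data frame with columns `compound_id` and `label`
#'   (`"active"`/`"inactive"`).
#' @param engine a [docking_engine()].
#' @param pocket a [pocket_definition()].
#' @param fraction EF fraction (default 0.15).
#' @return list: `auc`, `ef`, `ef_max`, `records` (the
#'   [screen_records()] with per-compound best scores), `ranking`.
#' @export
evaluate_model <- function(model, library, engine, pocket,
                           fraction = 0.15) {
  stopifnot(all(c("compound_id", "label") %in% names(library)))
  scores <- vapply(library$compound_id, function(cid) {
    poses <- tryCatch(engine$dock(model, cid, pocket),
                      error = function(e) list())
    if (!length(poses)) return(NA_real_)
    min(vapply(poses, function(p) p$score, 0))
  }, 0)
  records <- screen_records(library$compound_id, library$label,
                            unname(scores))
  ranking <- build_ranking(records)
  m <- screen_metrics(ranking, fraction)
  list(auc = m$auc, ef = m$ef, ef_max = m$ef_max, records = records,
       ranking = ranking)
}

#' Initial refinement state
#'
#' @param models list of starting [structure_model()] objects (the
#'   candidate pool roots).
#' @param pocket a [pocket_definition()].
#' @return object of class `refinement_state` holding the candidate
#'   pool, the survivor set (initially all starting models), the round
#'   history, and the lineage of every pool entry.
#' @export
refinement_state <- function(models, pocket) {
  stopifnot(length(models) >= 1, inherits(pocket, "pocket_definition"))
  pool <- list()
  for (m in models) {
    pool[[m$id]] <- list(id = m$id, model = m, pose = NULL,
                         metrics = list(), parent = NA_character_,
                         round = "start")
  }
  structure(list(pool = pool, survivors = names(pool), rounds = list(),
                 pocket = pocket),
            class = "refinement_state")
}

#' @export
print.refinement_state <- function(x, ...) {
  cat("refinement_state: ", length(x$pool), " pool entries, ",
      length(x$survivors), " current survivor(s), ",
      length(x$rounds), " round(s) run\n", sep = "")
  invisible(x)
}

# best AUC seen anywhere in the pool (NA if none evaluated yet)
pool_max_auc <- function(state) {
  v <- vapply(state$pool, function(e) e$metrics$auc %||% NA_real_, 0)
  if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE)
}

#' Run one refinement round
#'
#' For every surviving candidate the round's flexible-residue set is
#' resolved, the engine generates refined receptor-ligand complexes for
#' each probe ligand, every complex is measured (monitor distance
#' always; screening AUC/EF when the gate requires and a library is
#' given), and the gate is applied.  All generated complexes enter the
#' pool with their parent recorded, and parents are retained, so the
#' best AUC in the pool never decreases across rounds.  A round with
#' zero survivors issues a warning and leaves the survivor set empty
#' (not an error).
#'
#' @param state a [refinement_state()].
#' @param spec the round's [round_spec()].
#' @param engine a [docking_engine()].
#' @param gate a [model_gate()].
#' @param library screening library (`compound_id`, `label`) or `NULL`
#'   to skip the AUC gate.
#' @param seed round seed; every engine call receives a deterministic
#'   child seed ([split_seed()]), so rounds are bit-reproducible.
#' @return the updated `refinement_state`.
#' @export
run_round <- function(state, spec, engine, gate, library = NULL, seed = 1) {
  stopifnot(inherits(state, "refinement_state"),
            inherits(spec, "round_spec"),
            inherits(engine, "docking_engine"),
            inherits(gate, "model_gate"))
  if (!length(state$survivors)) stop("no surviving candidates to refine")
  survivors_new <- character(0)
  flex_sizes <- integer(0)
  n_generated <- 0L
  for (ci in seq_along(state$survivors)) {
    ent <- state$pool[[state$survivors[ci]]]
    context <- switch(spec$flexible_policy,
      pocket_shell = state$pocket,
      ligand_shell = {
        if (!is.null(ent$pose)) ent$pose else {
          poses <- engine$dock(ent$model, spec$probe_ligands[1],
                               state$pocket)
          if (!length(poses))
            stop("cannot derive a ligand shell: probe ligand ",
                 spec$probe_ligands[1], " does not dock into ", ent$id)
          poses[[1]]
        }
      },
      named = NULL)
    flex <- flexible_residues(ent$model, spec, context)
    flex_sizes[ent$id] <- length(flex)
    for (pi in seq_along(spec$probe_ligands)) {
      child_seed <- split_seed(seed, (ci - 1) * 1000 + pi)
      cxs <- engine$refine(ent$model, spec$probe_ligands[pi], state$pocket,
                           flex, seed = child_seed)
      for (cx in cxs) {
        n_generated <- n_generated + 1L
        d <- monitor_distance(cx$pose, cx$model, gate$criterion$resA,
                              gate$criterion$resB)
        cx$metrics$monitor_distance <- d
        if (!is.null(library) && !is.null(gate$min_auc)) {
          ev <- evaluate_model(cx$model, library, engine, state$pocket)
          cx$metrics$auc <- ev$auc
          cx$metrics$ef <- ev$ef
        }
        entry <- list(id = cx$model$id, model = cx$model, pose = cx$pose,
                      metrics = cx$metrics, parent = ent$id,
                      round = spec$name)
        state$pool[[entry$id]] <- entry
        if (gate_passes(gate, cx$metrics$auc %||% NA_real_, d))
          survivors_new <- c(survivors_new, entry$id)
      }
    }
  }
  state$rounds[[length(state$rounds) + 1]] <- list(
    name = spec$name, flexible_sizes = flex_sizes,
    n_generated = n_generated, survivors = survivors_new,
    pool_max_auc = NA)
  state$survivors <- survivors_new
  state$rounds[[length(state$rounds)]]$pool_max_auc <- pool_max_auc(state)
  if (!length(survivors_new))
    warning("round ", spec$name, ": no complex passed the gate")
  state
}

#' Run a multi-round refinement protocol
#'
#' Evaluates the starting models (when a library is given), then applies
#' the rounds in order, fanning one master seed out into per-round child
#' seeds.  The canonical protocol is three rounds with a shrinking
#' flexible set: pocket shell, ligand shell, then the two key residues
#' only.
#'
#' @param models list of starting [structure_model()] objects.
#' @param rounds list of [round_spec()].
#' @param engine a [docking_engine()].
#' @param gate a [model_gate()].
#' @param library screening library or `NULL`.
#' @param pocket a [pocket_definition()].
#' @param seed master seed.
#' @return the final [refinement_state()].
#' @export
run_protocol <- function(models, rounds, engine, gate, library, pocket,
                         seed = 1) {
  state <- refinement_state(models, pocket)
  if (!is.null(library)) {
    for (id in names(state$pool)) {
      ev <- evaluate_model(state$pool[[id]]$model, library, engine, pocket)
      state$pool[[id]]$metrics$auc <- ev$auc
      state$pool[[id]]$metrics$ef <- ev$ef
    }
  }
  for (ri in seq_along(rounds)) {
    state <- run_round(state, rounds[[ri]], engine, gate, library,
                       seed = split_seed(seed, ri))
    if (!length(state$survivors) && ri < length(rounds)) break
  }
  state
}

#' Rescore a pose against alanine mutants
#'
#' In-place rescoring of one pose against single-alanine variants of the
#' receptor: each listed residue is truncated to alanine
#' ([mutate_to_alanine()]), the unchanged pose is rescored, and the
#' score change relative to wild type is reported.  A drop in score on
#' mutating a residue indicates that residue's side chain contributes
#' binding contacts.
#'
#' @param engine a [docking_engine()].
#' @param model wild-type [structure_model()].
#' @param pose the [ligand_pose()] to rescore (placed in the pocket).
#' @param mutations character vector of residue keys to mutate.
#' @return data frame (`variant`, `score`, `delta`); the first row is
#'   the wild type with `delta` 0.
#' @export
mutant_rescore <- function(engine, model, pose, mutations = character(0)) {
  wt <- engine$score_in_place(model, pose)
  out <- data.frame(variant = "WT", score = wt, delta = 0,
                    stringsAsFactors = FALSE)
  for (key in mutations) {
    mut <- mutate_to_alanine(model, key)
    pose_m <- pose; pose_m$model_id <- mut$id
    s <- engine$score_in_place(mut, pose_m)
    out <- rbind(out, data.frame(variant = paste0(key, ">ALA"), score = s,
                                 delta = s - wt, stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}
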