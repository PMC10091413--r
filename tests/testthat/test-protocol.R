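# shared toy system for protocol tests
toy_system <- function(seed = 7) {
  toy <- make_toy_receptor(50, seed = seed)
  crit <- distance_criterion(toy$key_residues[1], toy$key_residues[2], 4.0)
  rounds <- list(
    round_spec("IFD1", "pocket_shell"),
    round_spec("IFD2", "ligand_shell"),
    round_spec("IFD3", "named", residues = toy$key_residues))
  list(toy = toy, crit = crit, rounds = rounds)
}

test_that("flexible-residue policies resolve as declared", {
  sys <- toy_system()
  toy <- sys$toy
  named <- round_spec("IFD3", "named", residues = toy$key_residues)
  expect_identical(flexible_residues(toy$model, named),
                   pocketforge:::sort_residue_keys(toy$key_residues))
  bad <- round_spec("IFD3", "named", residues = "B:999")
  expect_error(flexible_residues(toy$model, bad), "B:999")
  # ligand shell at 4 A: near residues in, far residues out
  ctr <- c(100, 0, 0)
  rows <- do.call(rbind, lapply(1:12, function(i) {
    th <- 2 * pi * i / 12
    r <- if (i <= 6) 3.5 else 6
    data.frame(serial = i, name = "CA", element = "C", resname = "GLY",
               chain = "A", resnum = i, insert = "",
               x = ctr[1] + r * cos(th), y = ctr[2] + r * sin(th),
               z = ctr[3])
  }))
  m <- structure_model("shellcase", rows)
  pose <- ligand_pose("l", "shellcase", matrix(ctr, 1, 3))
  got <- flexible_residues(m, round_spec("IFD2", "ligand_shell"), pose)
  expect_setequal(got, residue_key("A", 1:6))
})

test_that("flexible sets shrink strictly across the three rounds", {
  sys <- toy_system()
  eng <- mock_engine(seed = 3)
  gate <- model_gate(sys$crit, min_auc = NULL)
  st <- run_protocol(list(sys$toy$model), sys$rounds, eng, gate,
                     library = NULL, pocket = sys$toy$pocket, seed = 11)
  sizes <- vapply(st$rounds, function(r) max(r$flexible_sizes), 0)
  expect_length(sizes, 3)
  expect_true(all(diff(sizes) < 0))
  expect_equal(sizes[3], 2)  # only the two key residues
})

test_that("a rigged engine yields perfect separation; random scores ~0.5", {
  sys <- toy_system()
  lib <- data.frame(compound_id = sprintf("c%03d", 1:40),
                    label = rep(c("active", "inactive"), c(10, 30)))
  rig <- mock_engine(score_fun = function(cid, mid)
    if (cid %in% lib$compound_id[lib$label == "active"]) -10 -
      as.numeric(sub("c", "", cid)) / 100 else -1 -
      as.numeric(sub("c", "", cid)) / 100)
  ev <- evaluate_model(sys$toy$model, lib, rig, sys$toy$pocket)
  expect_equal(ev$auc, 1.0)
  expect_equal(ev$ef, ev$ef_max)
  # null calibration: random, label-blind scores give AUC near 0.5
  aucs <- vapply(1:20, function(s) {
    tab <- pocketforge:::with_seed(split_seed(11, s),
      setNames(runif(nrow(lib), -8, -2), lib$compound_id))
    rnd <- mock_engine(score_fun = function(cid, mid) tab[[cid]])
    evaluate_model(sys$toy$model, lib, rnd, sys$toy$pocket)$auc
  }, 0)
  expect_equal(mean(aucs), 0.5, tolerance = 0.1 / 0.5)
})

test_that("a 13/131 library with 7 actives in the top 21 prints EF15 0.50", {
  sys <- toy_system()
  lib <- data.frame(
    compound_id = sprintf("c%03d", 1:144),
    label = rep(c("active", "inactive"), c(13, 131)))
  # rig scores so actives 1-7 take ranks 1-7 and the other 6 actives sink
  rig <- mock_engine(score_fun = function(cid, mid) {
    i <- as.numeric(sub("c", "", cid))
    if (i <= 7) -20 + i else if (i <= 13) 50 + i else i
  })
  ev <- evaluate_model(sys$toy$model, lib, rig, sys$toy$pocket)
  expect_equal(round_half_up(ev$ef, 2), 0.50)
})

test_that("undocked compounds are recorded and ranked worst", {
  sys <- toy_system()
  lib <- data.frame(compound_id = c("a1", "a2", "i1", "i2"),
                    label = c("active", "active", "inactive", "inactive"))
  eng <- mock_engine(score_fun = function(cid, mid)
    if (cid == "a1") NA else -5 - nchar(cid) - match(cid, lib$compound_id))
  ev <- evaluate_model(sys$toy$model, lib, eng, sys$toy$pocket)
  expect_false(ev$records$docked[ev$records$compound_id == "a1"])
  expect_identical(ev$ranking$compound_id[4], "a1")
  expect_true(is.na(ev$ef))  # 4-compound library: top 15% is empty
})

test_that("gates count survivors by strict AUC and distance thresholds", {
  sys <- toy_system()
  gate <- model_gate(sys$crit, min_auc = 0.8)
  expect_true(pocketforge:::gate_passes(gate, 0.85, 1))
  expect_true(pocketforge:::gate_passes(gate, 0.81, 3.99))
  expect_false(pocketforge:::gate_passes(gate, 0.75, 1))
  expect_false(pocketforge:::gate_passes(gate, 0.80, 1))    # strict >
  expect_false(pocketforge:::gate_passes(gate, 0.85, 4.0))  # strict <
  expect_equal(sum(vapply(c(0.75, 0.81, 0.85),
                          function(a) pocketforge:::gate_passes(gate, a, 1),
                          TRUE)), 2)
  relaxed <- model_gate(sys$crit, min_auc = 0.8, strict_auc = FALSE)
  expect_true(pocketforge:::gate_passes(relaxed, 0.80, 1))
})

test_that("the distance gate agrees with the pose filter", {
  sys <- toy_system()
  complexes <- toy_complex_cloud(60, seed = 41)
  gate <- model_gate(sys$crit, min_auc = NULL)
  gate_keep <- vapply(complexes, function(cx)
    pocketforge:::gate_passes(gate, NA_real_,
                              monitor_distance(cx$pose, cx$model,
                                               sys$crit$resA,
                                               sys$crit$resB)), TRUE)
  filt_keep <- vapply(complexes, function(cx) cx$pose$pose_id, "") %in%
    vapply(filter_poses(complexes, sys$crit),
           function(cx) cx$pose$pose_id, "")
  expect_identical(gate_keep, filt_keep)
})

test_that("lineage is rooted, survivors subset the pool, AUC never degrades", {
  sys <- toy_system()
  lib <- data.frame(compound_id = sprintf("c%03d", 1:24),
                    label = rep(c("active", "inactive"), c(6, 18)))
  # deterministic, model-dependent scores so rounds genuinely differ
  eng <- mock_engine(n_poses = 3, score_fun = function(cid, mid) {
    i <- match(cid, lib$compound_id)
    base <- if (lib$label[i] == "active") -8 else -5
    base + (pocketforge:::hash31(paste(cid, mid)) %% 1000) / 250
  })
  gate <- model_gate(sys$crit, min_auc = 0.5)
  st <- run_protocol(list(sys$toy$model), sys$rounds, eng, gate,
                     library = lib, pocket = sys$toy$pocket, seed = 5)
  expect_true(all(st$survivors %in% names(st$pool)))
  # lineage: every parent is in the pool; roots are the starting models
  parents <- vapply(st$pool, function(e) e$parent, "")
  expect_true(all(is.na(parents) | parents %in% names(st$pool)))
  expect_identical(names(which(is.na(parents))), "toy")
  # retention: max pool AUC is non-decreasing round over round
  maxes <- vapply(st$rounds, function(r) r$pool_max_auc, 0)
  expect_true(all(diff(maxes) >= 0))
})

test_that("the full pipeline is bit-reproducible under one master seed", {
  sys <- toy_system()
  lib <- data.frame(compound_id = sprintf("c%03d", 1:24),
                    label = rep(c("active", "inactive"), c(6, 18)))
  eng <- mock_engine(n_poses = 2, score_fun = function(cid, mid) {
    base <- if (match(cid, lib$compound_id) <= 6) -8 else -5
    base + (pocketforge:::hash31(paste(cid, mid)) %% 1000) / 250
  })
  gate <- model_gate(sys$crit, min_auc = 0.5)
  run_once <- function() run_protocol(list(sys$toy$model), sys$rounds, eng,
                                      gate, library = lib,
                                      pocket = sys$toy$pocket, seed = 3)
  s1 <- run_once(); s2 <- run_once()
  expect_identical(serialize(s1, NULL), serialize(s2, NULL))
})

test_that("a round with zero survivors warns instead of failing", {
  sys <- toy_system()
  eng <- mock_engine(seed = 2)
  # an impossible gate: AUC above 1 cannot be reached
  gate <- model_gate(sys$crit, min_auc = 1, strict_auc = TRUE)
  lib <- data.frame(compound_id = sprintf("c%02d", 1:8),
                    label = rep(c("active", "inactive"), 4))
  st <- refinement_state(list(sys$toy$model), sys$toy$pocket)
  expect_warning(
    st2 <- run_round(st, sys$rounds[[1]], eng, gate, library = lib,
                     seed = 1),
    "no complex passed")
  expect_length(st2$survivors, 0)
  expect_gt(length(st2$pool), length(st$pool))  # complexes still pooled
  expect_error(run_round(st2, sys$rounds[[2]], eng, gate), "no surviving")
})

test_that("contact-based mutant rescoring equals the lost-contact count", {
  toy <- make_toy_receptor(50, seed = 7)
  eng <- mock_engine(contact_cutoff = 4.0)
  pose <- pocketforge:::synthetic_ligand("cmp1", toy$model$id,
                                         center = toy$pocket$center,
                                         seed = 13)
  # empty mutation list: wild-type row only
  wt_only <- mutant_rescore(eng, toy$model, pose)
  expect_equal(nrow(wt_only), 1)
  expect_identical(wt_only$variant, "WT")
  expect_equal(wt_only$delta, 0)
  # the oracle: contacts lost by truncation, counted directly
  key <- toy$key_residues[1]
  lig <- model_xyz(pose)
  res_rows <- pocketforge:::residue_rows(toy$model, key)
  removed <- res_rows[!toy$model$atoms$name[res_rows] %in%
                        c("N", "CA", "C", "O", "CB")]
  lost <- sum(vapply(removed, function(i) {
    p <- as.numeric(toy$model$atoms[i, c("x", "y", "z")])
    min(sqrt(rowSums(sweep(lig, 2, p)^2))) <= 4.0
  }, TRUE))
  expect_gt(lost, 0)  # the key leucine really does contact the ligand
  tab <- mutant_rescore(eng, toy$model, pose, mutations = key)
  expect_equal(tab$delta[2], lost)
  # locality: a residue far from the pose contributes delta 0
  far <- names(sort(vapply(residue_keys(toy$model), function(k)
    sqrt(sum((pocketforge:::residue_atom_xyz(toy$model, k) -
                centroid(pose))^2)), 0), decreasing = TRUE))[1]
  tab2 <- suppressWarnings(mutant_rescore(eng, toy$model, pose,
                                          mutations = far))
  expect_equal(tab2$delta[2], 0)
})
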