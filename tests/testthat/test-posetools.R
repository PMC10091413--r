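test_that("the 4 A monitor filter is strict and idempotent", {
  atoms <- data.frame(serial = 1:2, name = "CA", element = "C",
                      resname = "LEU", chain = "A", resnum = c(1, 2),
                      insert = "", x = c(-2, 2), y = 0, z = 0)
  m <- structure_model("t", atoms)
  crit <- distance_criterion("A:1", "A:2", 4.0)
  mk <- function(id, d) pose_complex(m, ligand_pose(id, "t",
                                                    matrix(c(0, d, 0), 1, 3)))
  kept <- filter_poses(list(mk("at3.99", 3.99), mk("at4.00", 4.0)), crit)
  expect_length(kept, 1)
  expect_identical(kept[[1]]$pose$pose_id, "at3.99")
  expect_equal(kept[[1]]$metrics$monitor_distance, 3.99)
  expect_identical(filter_poses(list(), crit), list())
  # idempotence
  expect_equal(length(filter_poses(kept, crit)), length(kept))
})

test_that("filtering 500 synthetic poses equals brute-force recomputation", {
  toy <- make_toy_receptor(50, seed = 7)
  complexes <- toy_complex_cloud(500, seed = 99)
  crit <- distance_criterion(toy$key_residues[1], toy$key_residues[2], 4.0)
  kept <- filter_poses(complexes, crit)
  keep_bf <- vapply(complexes, function(cx)
    bf_monitor(cx$pose, cx$model, crit$resA, crit$resB) < 4.0, TRUE)
  expect_identical(vapply(kept, function(cx) cx$pose$pose_id, ""),
                   vapply(complexes[keep_bf], function(cx) cx$pose$pose_id, ""))
  expect_gt(length(kept), 0)
  expect_lt(length(kept), length(complexes))
})

test_that("binding shell selects residues near the ligand centroid", {
  toy <- make_toy_receptor(50, seed = 7)
  pose_far <- ligand_pose("far", toy$model$id,
                          matrix(c(200, 200, 200), 1, 3))
  expect_length(binding_shell(toy$model, pose_far, 7), 0)
  # 12 residues placed at 5-6 A from a pocket point are all selected
  ctr <- c(50, 0, 0)
  rows <- do.call(rbind, lapply(1:12, function(i) {
    th <- 2 * pi * i / 12
    data.frame(serial = i, name = "CA", element = "C", resname = "GLY",
               chain = "A", resnum = i, insert = "",
               x = ctr[1] + (5 + i %% 2) * cos(th),
               y = ctr[2] + (5 + i %% 2) * sin(th), z = ctr[3])
  }))
  pocket12 <- structure_model("p12", rows)
  pose_ctr <- ligand_pose("c", "p12", matrix(ctr, 1, 3))
  expect_length(binding_shell(pocket12, pose_ctr, 7), 12)
  expect_error(ligand_pose("e", toy$model$id, matrix(0, 0, 3)),
               "at least one atom")
})

test_that("a pocket mimicking the reported distances gives a 12-residue shell", {
  # twelve lining residues within 7 A of the ligand centroid, the rest
  # of the receptor beyond it
  shell_resnums <- c(104, 105, 108, 159, 199, 202, 206, 255, 256, 276,
                     279, 280)
  far_resnums <- c(1:20, 300:310)
  mk_row <- function(i, num, r) {
    th <- 2 * pi * (i %% 17) / 17
    data.frame(serial = i, name = "CA", element = "C", resname = "LEU",
               chain = "A", resnum = num, insert = "",
               x = r * cos(th), y = r * sin(th), z = 0)
  }
  rows <- do.call(rbind, c(
    lapply(seq_along(shell_resnums), function(i)
      mk_row(i, shell_resnums[i], 5.5)),
    lapply(seq_along(far_resnums), function(i)
      mk_row(i + 50, far_resnums[i], 15))))
  m <- structure_model("hm_like", rows)
  pose <- ligand_pose("lig", "hm_like", matrix(0, 1, 3))
  shell <- binding_shell(m, pose, 7.0)
  expect_length(shell, 12)
  expect_setequal(shell, residue_key("A", shell_resnums))
})

test_that("pairwise pose RMSD matches brute force and uniform displacement", {
  toy <- make_toy_receptor(30, seed = 5)
  pose <- ligand_pose("p1", toy$model$id,
                      sweep(matrix(rnorm(12, sd = 0.5), 4, 3), 2,
                            c(0, 0, 0), "+"))
  cx1 <- pose_complex(toy$model, pose)
  # duplicate complexes: zero matrix
  cx1b <- cx1; cx1b$pose$pose_id <- "p1b"
  shell <- binding_shell(toy$model, pose, 9)
  m0 <- pairwise_pose_rmsd(list(cx1, cx1b), shell)
  expect_equal(max(abs(m0)), 0)
  # displacing every correspondence atom by 1 A gives RMSD exactly 1
  mod2 <- toy$model; mod2$id <- "toy2"
  mod2$atoms$x <- mod2$atoms$x + 1
  pose2 <- pose; pose2$pose_id <- "p2"; pose2$model_id <- "toy2"
  pose2$atoms$x <- pose2$atoms$x + 1
  cx2 <- pose_complex(mod2, pose2)
  m1 <- pairwise_pose_rmsd(list(cx1, cx2), shell)
  expect_equal(m1["p1", "p2"], 1.0, tolerance = 1e-12)
  # random ensemble: element-wise brute-force RMSD oracle
  cloud <- toy_complex_cloud(8, seed = 17, spread = 2)
  shell2 <- binding_shell(cloud[[1]]$model, cloud[[1]]$pose, 8)
  mm <- pairwise_pose_rmsd(cloud, shell2)
  expect_true(isSymmetric(mm))
  expect_equal(max(abs(diag(mm))), 0)
  for (i in 1:7) for (j in (i + 1):8) {
    a <- rbind(as.matrix(cloud[[i]]$model$atoms[
      pocketforge:::atom_res_keys(cloud[[i]]$model$atoms) %in% shell2,
      c("x", "y", "z")]), model_xyz(cloud[[i]]$pose))
    b <- rbind(as.matrix(cloud[[j]]$model$atoms[
      pocketforge:::atom_res_keys(cloud[[j]]$model$atoms) %in% shell2,
      c("x", "y", "z")]), model_xyz(cloud[[j]]$pose))
    expect_equal(mm[i, j], sqrt(mean(rowSums((a - b)^2))),
                 tolerance = 1e-9)
  }
})

test_that("pairwise RMSD is permutation-equivariant", {
  cloud <- toy_complex_cloud(6, seed = 21, spread = 2)
  shell <- binding_shell(cloud[[1]]$model, cloud[[1]]$pose, 8)
  m <- pairwise_pose_rmsd(cloud, shell)
  perm <- c(4, 1, 6, 2, 5, 3)
  m2 <- pairwise_pose_rmsd(cloud[perm], shell)
  expect_equal(m2, m[perm, perm])
})

test_that("average linkage merges nearest groups first with monotone heights", {
  d3 <- matrix(c(0, 1, 10, 1, 0, 10, 10, 10, 0), 3, 3,
               dimnames = list(letters[1:3], letters[1:3]))
  lk <- average_linkage(d3)
  lv2 <- pocketforge:::level_assignment(lk, 2)
  expect_equal(lv2[["a"]], lv2[["b"]])
  expect_false(lv2[["a"]] == lv2[["c"]])
  heights <- lk$hclust$height
  expect_true(all(diff(heights) >= 0))
  bad <- d3; bad[1, 2] <- NA
  expect_error(average_linkage(bad), "non-finite")
  bad2 <- d3; bad2[1, 2] <- 5
  expect_error(average_linkage(bad2), "symmetric")
})

test_that("well-separated planted pose clusters are recovered exactly at k", {
  cloud <- make_pose_cloud(k = 2, n_per_cluster = 8, within_sigma = 0.5,
                           between_sep = 10, seed = 4)
  # ligand-only distances isolate the planted structure
  ids <- vapply(cloud$poses, function(p) p$pose_id, "")
  n <- length(ids)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    d[i, j] <- d[j, i] <- rmsd(cloud$poses[[i]], cloud$poses[[j]])
  lk <- average_linkage(d)
  assign <- pocketforge:::level_assignment(lk, 2)
  expect_equal(mclust::adjustedRandIndex(assign[ids], cloud$labels), 1.0)
})

test_that("planted clusters are recovered with ARI >= 0.9 across 50 seeds", {
  ari <- vapply(1:50, function(s) {
    cloud <- make_pose_cloud(k = 4, n_per_cluster = 6, within_sigma = 0.5,
                             between_sep = 10, seed = s)
    ids <- vapply(cloud$poses, function(p) p$pose_id, "")
    n <- length(ids)
    d <- matrix(0, n, n, dimnames = list(ids, ids))
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      d[i, j] <- d[j, i] <- rmsd(cloud$poses[[i]], cloud$poses[[j]])
    assign <- pocketforge:::level_assignment(average_linkage(d), 4)
    mclust::adjustedRandIndex(assign[ids], cloud$labels)
  }, 0)
  expect_true(all(ari >= 0.9))
})

test_that("second-local-minimum scan follows the stated rule", {
  slm <- pocketforge:::second_local_min
  expect_equal(slm(c(5, 2, 4, 1, 6)), 4)   # minima at 2 and 4 -> second
  expect_equal(slm(c(5, 4, 3, 2, 6)), 4)   # single local minimum -> global
  expect_equal(slm(c(1, 2, 3, 4, 5)), 1)   # monotone rise: first is min
  expect_equal(slm(c(3, 1, 2, 0.5, 2, 0.2, 1)), 4)  # scan order, not depth
})

test_that("Kelley penalty selects the planted fine scale on two-scale data", {
  # 4 tight clusters grouped into 2 super-clusters
  set.seed(61)
  centers <- rbind(c(0, 0, 0), c(4, 0, 0), c(40, 0, 0), c(44, 0, 0))
  pts <- do.call(rbind, lapply(1:4, function(c0)
    sweep(matrix(rnorm(10 * 3, sd = 0.2), 10, 3), 2, centers[c0, ], "+")))
  d <- as.matrix(dist(pts))
  dimnames(d) <- list(seq_len(40), seq_len(40))
  lk <- average_linkage(d)
  prof <- kelley_select(lk, d)
  expect_equal(prof$selected_k, 4)
  # invariance under uniform scaling of the distances
  prof10 <- kelley_select(average_linkage(d * 10), d * 10)
  expect_equal(prof10$selected_k, prof$selected_k)
  expect_equal(prof10$penalty, prof$penalty, tolerance = 1e-9)
})

test_that("Kelley fallback returns the global minimum on structureless data", {
  set.seed(67)
  pts <- matrix(runif(60, 0, 10), 20, 3)
  d <- as.matrix(dist(pts)); dimnames(d) <- list(1:20, 1:20)
  lk <- average_linkage(d)
  prof <- kelley_select(lk, d)
  p <- prof$penalty
  n <- length(p)
  is_min <- vapply(seq_len(n), function(i)
    (i == 1 || p[i] < p[i - 1]) && (i == n || p[i] < p[i + 1]), TRUE)
  if (sum(is_min) < 2) expect_equal(prof$selected_k, prof$k[which.min(p)])
  else expect_equal(prof$selected_k, prof$k[which(is_min)[2]])
})

test_that("cluster representatives maximise the key metric deterministically", {
  toy <- make_toy_receptor(20, seed = 3)
  mk <- function(id, aucv) {
    pose <- ligand_pose(id, toy$model$id, matrix(rnorm(9), 3, 3))
    pose_complex(toy$model, pose, metrics = list(auc = aucv))
  }
  cxs <- list(mk("a", 0.7), mk("b", 0.9), mk("c", 0.8), mk("d", 0.6))
  assign <- c(a = 1, b = 1, c = 1, d = 2)
  reps <- cluster_representatives(assign, cxs)
  expect_identical(reps[["1"]]$pose$pose_id, "b")
  expect_identical(reps[["2"]]$pose$pose_id, "d")  # singleton cluster
  # tie broken lexicographically on pose id
  tied <- list(mk("z", 0.9), mk("y", 0.9))
  reps2 <- cluster_representatives(c(z = 1, y = 1), tied)
  expect_identical(reps2[["1"]]$pose$pose_id, "y")
  expect_error(cluster_representatives(assign, list(mk("a", 0.7)),
                                       "missing_metric"), "lacks metric")
})

test_that("planted per-cluster metric maxima are all recovered", {
  set.seed(71)
  toy <- make_toy_receptor(20, seed = 3)
  n_cl <- 34
  cxs <- list(); assign <- integer(0); planted <- character(n_cl)
  idx <- 0
  for (c0 in seq_len(n_cl)) {
    n_in <- sample(2:5, 1)
    best <- sample(n_in, 1)
    for (m in seq_len(n_in)) {
      idx <- idx + 1
      id <- sprintf("c%02d_m%d", c0, m)
      aucv <- if (m == best) 0.9 + c0 / 1000 else runif(1, 0.3, 0.8)
      pose <- ligand_pose(id, toy$model$id, matrix(rnorm(9), 3, 3))
      cxs[[idx]] <- pose_complex(toy$model, pose, metrics = list(auc = aucv))
      assign[id] <- c0
      if (m == best) planted[c0] <- id
    }
  }
  reps <- cluster_representatives(assign, cxs)
  expect_identical(unname(vapply(reps, function(cx) cx$pose$pose_id, "")),
                   planted)
})
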