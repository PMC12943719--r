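test_that("the toy pocket meets its construction contract", {
  p <- build_toy_pocket(0)
  a <- p$atoms
  expect_equal(sum(a$role == "water" & a$name == "OW"), 14L)
  expect_equal(sort(unique(a$resseq[a$role == "water"])), 1:14)
  expect_equal(sum(a$role == "ion"), 2L)
  expect_setequal(a$element[a$role == "ion"], c("ZN", "MG"))
  expect_true(any(a$resname == "GLN" & a$resseq == 443))
  expect_equal(sum(a$role == "ligand" & a$name == "OAC"), 1L)
  expect_gte(length(unique(a$resseq[a$role == "protein"])), 5L)
  # no non-covalent heavy-atom pair below 1.8 A
  xyz <- as.matrix(a[, c("x", "y", "z")])
  heavy <- which(toupper(a$element) != "H")
  dm <- as.matrix(dist(xyz[heavy, ])); diag(dm) <- Inf
  bonded <- matrix(FALSE, nrow(a), nrow(a))
  bonded[p$bonds] <- TRUE; bonded <- bonded | t(bonded)
  dm[bonded[heavy, heavy]] <- Inf
  expect_gte(min(dm), 1.8)
})

test_that("pocket generation is seed-deterministic and seed-sensitive", {
  expect_identical(write_structure(build_toy_pocket(3)),
                   write_structure(build_toy_pocket(3)))
  expect_false(identical(write_structure(build_toy_pocket(3)),
                         write_structure(build_toy_pocket(4))))
  # generation does not disturb the caller's RNG stream
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(build_toy_pocket(7)); after <- runif(1)
  expect_identical(before, after)
})

test_that("generated pockets round-trip and type cleanly", {
  for (seed in c(0, 21)) {
    p <- build_toy_pocket(seed)
    p2 <- read_structure(write_structure(p))
    expect_identical(table(p2$atoms$role), table(p$atoms$role))
    expect_no_warning(detect_hbonds(p2))
    expect_equal(nrow(detect_hbonds(p2)), 0L)  # resting pocket is quiet
  }
})

test_that("plant_hbond reproduces requested geometry to 1e-6", {
  cx <- build_toy_pocket(0)
  don <- list(resname = "GLN", resseq = 443L, name = "NE2",
              hydrogen = "HE21")
  acc <- list(resname = "LIG", resseq = 900L, name = "OAC")
  set.seed(17)
  for (i in 1:200) {
    d <- runif(1, 1.8, 3.4); ang <- runif(1, 121, 169)
    pl <- plant_hbond(cx, don, acc, d, ang)
    a <- pl$atoms
    xyz <- as.matrix(a[, c("x", "y", "z")])
    hi <- which(a$name == "HE21"); ni <- which(a$name == "NE2")
    oi <- which(a$name == "OAC")
    expect_equal(sqrt(sum((xyz[hi, ] - xyz[oi, ])^2)), d,
                 tolerance = 1e-6)
    expect_equal(compute_angle(xyz[ni, ], xyz[hi, ], xyz[oi, ]), ang,
                 tolerance = 1e-6)
    # nothing else moved
    moved <- which(rowSums(abs(xyz - as.matrix(
      cx$atoms[, c("x", "y", "z")]))) > 1e-12)
    expect_true(all(moved %in% c(hi, oi)))
  }
  expect_error(plant_hbond(cx, don,
                           list(resname = "LIG", resseq = 900L,
                                name = "XX"), 2.5, 150),
               "resolves to")
  # beyond-cutoff planting is detected by nothing
  far <- plant_hbond(cx, don, acc, 3.6, 150)
  expect_equal(nrow(detect_hbonds(far)), 0L)
})

test_that("simulated ensembles honour spread, labels and energy order", {
  topo <- build_toy_pocket(1)
  sim <- simulate_pose_ensemble(topo, n_poses = 40, n_clusters = 2,
                                intra_spread = 0, inter_separation = 30,
                                seed = 3)
  # zero spread: poses within one cluster are identical
  k1 <- which(sim$labels == 1)
  expect_equal(sim$ensemble$poses[[k1[1]]], sim$ensemble$poses[[k1[2]]])
  cl <- cluster_poses(sim$ensemble)
  expect_length(cl, 2L)
  expect_error(simulate_pose_ensemble(topo, cluster_weights = c(0.5, 0.4),
                                      n_clusters = 2),
               "sum to 1")
})

test_that("the class dataset plants exactly what the survey detects", {
  ds <- simulate_class_dataset(
    class_geometry_model(poses_per_ligand = 30), n_ligands_per_class = 2,
    seed = 5)
  expect_length(ds$ligands, 4L)
  for (lg in ds$ligands) {
    sv <- survey_ensemble(lg$ensemble)
    s <- sv$summaries$with_water
    tr <- lg$truth
    wat <- s$bonds[s$bonds$partner == "water", ]
    gln <- s$bonds[s$bonds$partner == "amino_acid", ]
    expect_equal(nrow(wat), sum(tr$water_count))
    expect_equal(nrow(gln), sum(tr$gln_bond))
    expect_equal(sort(wat$h_a_distance),
                 sort(unlist(tr$water_distances)), tolerance = 1e-6)
    expect_equal(sort(gln$h_a_distance),
                 sort(tr$gln_distance[tr$gln_bond]), tolerance = 1e-6)
    # all glutamine bonds hit the focus partner set
    expect_true(all(gln$donor_res == "GLN" & gln$donor_resseq == 443))
  }
})

test_that("the noiseless limit reproduces configured distances", {
  m <- class_geometry_model(water_distance_sd = 1e-6,
                            gln_bonds_per_pose_A = 1,
                            gln_bonds_per_pose_I = 1,
                            poses_per_ligand = 15)
  ds <- simulate_class_dataset(m, n_ligands_per_class = 1, seed = 2)
  for (lg in ds$ligands) {
    s <- survey_ensemble(lg$ensemble)$summaries$with_water
    wat <- s$bonds[s$bonds$partner == "water", ]
    gln <- s$bonds[s$bonds$partner == "amino_acid", ]
    wm <- if (lg$class == "A") m$water_distance_mean_A else
      m$water_distance_mean_I
    gm <- if (lg$class == "A") m$gln_distance_mean_A else
      m$gln_distance_mean_I
    if (nrow(wat)) expect_equal(mean(wat$h_a_distance), wm,
                                tolerance = 1e-3)
    expect_equal(nrow(gln), s$n_poses)  # rate 1: one bond every pose
    expect_equal(mean(gln$h_a_distance), gm, tolerance = 1e-3)
  }
})

test_that("model validation rejects infeasible settings", {
  expect_error(class_geometry_model(water_distance_mean_A = 4),
               "detectable window")
  expect_error(class_geometry_model(water_distance_sd = 0))
  expect_error(class_geometry_model(gln_bonds_per_pose_A = 1.4))
})

test_that("sample means track configured means over a full dataset", {
  m <- class_geometry_model(poses_per_ligand = 60)
  ds <- simulate_class_dataset(m, n_ligands_per_class = 4, seed = 8)
  pool <- function(cls) {
    dists <- unlist(lapply(ds$ligands, function(lg)
      if (lg$class == cls) unlist(lg$truth$water_distances)))
    counts <- unlist(lapply(ds$ligands, function(lg)
      if (lg$class == cls) lg$truth$water_count))
    list(d = dists, k = counts)
  }
  a <- pool("A"); i <- pool("I")
  expect_lt(abs(mean(a$d) - m$water_distance_mean_A),
            3 * sd(a$d) / sqrt(length(a$d)))
  expect_lt(abs(mean(i$d) - m$water_distance_mean_I),
            3 * sd(i$d) / sqrt(length(i$d)))
  expect_lt(abs(mean(a$k) - m$bonds_per_pose_A),
            3 * sd(a$k) / sqrt(length(a$k)))
  expect_lt(abs(mean(i$k) - m$bonds_per_pose_I),
            3 * sd(i$k) / sqrt(length(i$k)))
})
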