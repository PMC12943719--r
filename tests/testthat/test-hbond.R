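test_that("compute_angle handles canonical and random geometries", {
  expect_equal(compute_angle(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)), 180)
  expect_equal(compute_angle(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)), 90)
  expect_error(compute_angle(c(1, 0, 0), c(1, 0, 0), c(2, 0, 0)),
               "degenerate")
  set.seed(1)
  for (i in 1:1000) {
    p <- matrix(rnorm(9), 3)
    if (min(dist(p)) < 1e-3) next
    expect_equal(compute_angle(p[1, ], p[2, ], p[3, ]),
                 oracle_angle(p[1, ], p[2, ], p[3, ]), tolerance = 1e-9)
  }
})

test_that("planted geometry is detected with its exact values", {
  cx <- build_toy_pocket(0)
  planted <- plant_hbond(
    cx,
    donor_spec = list(resname = "GLN", resseq = 443L, name = "NE2",
                      hydrogen = "HE21"),
    acceptor_spec = list(resname = "LIG", resseq = 900L, name = "OAC"),
    distance = 2.50, angle = 150)
  b <- detect_hbonds(planted)
  expect_equal(nrow(b), 1L)
  expect_equal(b$h_a_distance, 2.50, tolerance = 1e-6)
  expect_equal(b$dha_angle, 150, tolerance = 1e-6)
  expect_equal(b$partner, "amino_acid")
  expect_equal(b$direction, "ligand-accepts")
})

test_that("criterion boundaries: strict distance, inclusive angles", {
  cx <- build_toy_pocket(0)
  plant <- function(d, a) plant_hbond(
    cx,
    donor_spec = list(resname = "GLN", resseq = 443L, name = "NE2",
                      hydrogen = "HE21"),
    acceptor_spec = list(resname = "LIG", resseq = 900L, name = "OAC"),
    distance = d, angle = a)
  expect_equal(nrow(detect_hbonds(plant(3.50, 150))), 0L)   # strict <
  expect_equal(nrow(detect_hbonds(plant(3.4999, 150))), 1L)
  expect_equal(nrow(detect_hbonds(plant(2.5, 120))), 1L)    # inclusive
  expect_equal(nrow(detect_hbonds(plant(2.5, 170))), 1L)    # inclusive
  expect_equal(nrow(detect_hbonds(plant(2.5, 175))), 0L)    # above 170
  expect_equal(nrow(detect_hbonds(plant(2.5, 119.9))), 0L)
})

test_that("detection equals the exhaustive all-pairs oracle", {
  n_hits <- 0L
  for (seed in 1:40) {
    cx <- random_pocket(seed)
    for (wat in c(TRUE, FALSE)) {
      got <- detect_hbonds(cx, include_water = wat)
      want <- oracle_hbonds(cx, include_water = wat)
      expect_identical(hbond_key(got), hbond_key(want))
      if (nrow(got)) {
        m <- match(hbond_key(want), hbond_key(got))
        expect_equal(got$h_a_distance[m], want$h_a_distance,
                     tolerance = 1e-9)
        expect_equal(got$dha_angle[m], want$dha_angle, tolerance = 1e-9)
      }
    }
    n_hits <- n_hits + nrow(detect_hbonds(cx))
  }
  expect_gt(n_hits, 50)  # the randomized pockets actually exercise bonds
})

test_that("every reported bond re-checks against its criteria", {
  crit <- hbond_criteria()
  for (seed in c(2, 9, 23)) {
    b <- detect_hbonds(random_pocket(seed), crit)
    expect_true(all(b$h_a_distance < crit$max_h_acceptor_distance))
    expect_true(all(b$dha_angle >= crit$angle_min &
                      b$dha_angle <= crit$angle_max))
  }
})

test_that("vacuum-mode bonds are a subset of with-water bonds", {
  for (seed in c(4, 15)) {
    cx <- random_pocket(seed)
    wet <- detect_hbonds(cx, include_water = TRUE)
    dry <- detect_hbonds(cx, include_water = FALSE)
    expect_true(all(hbond_key(dry) %in% hbond_key(wet)))
    expect_identical(hbond_key(dry),
                     hbond_key(wet[wet$partner != "water", ]))
  }
})

test_that("detection is invariant under rigid motion of the complex", {
  cx <- random_pocket(7)
  b1 <- detect_hbonds(cx)
  b2 <- detect_hbonds(new_complex(rigid_transform(cx, 5)$atoms))
  expect_identical(hbond_key(b1), hbond_key(b2))
  expect_equal(b1$h_a_distance, b2$h_a_distance, tolerance = 1e-9)
  expect_equal(b1$dha_angle, b2$dha_angle, tolerance = 1e-6)
})

test_that("focus results are the selector-restricted subset", {
  spec <- focus_spec()
  for (seed in c(3, 12, 31)) {
    cx <- random_pocket(seed)
    full <- detect_hbonds(cx)
    foc <- focus_interactions(cx, spec = spec)
    expect_true(all(hbond_key(foc) %in% hbond_key(full)))
    # manual restriction: OAC bonds against GLN 443 or waters 1/13
    oac_serial <- cx$atoms$serial[cx$atoms$name == "OAC"]
    inv <- full[full$acceptor_serial == oac_serial |
                  full$donor_serial == oac_serial, ]
    keep <- (inv$partner == "amino_acid" & inv$donor_res == "GLN" &
               inv$donor_resseq == 443) |
      (inv$partner == "water" & inv$donor_resseq %in% c(1, 13))
    expect_identical(hbond_key(foc), hbond_key(inv[keep, ]))
  }
  expect_error(
    focus_interactions(build_toy_pocket(0),
                       spec = focus_spec(ligand_atom = "^NOPE$")),
    "resolves to no ligand atom")
})

test_that("summarize_ligand computes the two survey parameters", {
  cx <- build_toy_pocket(0)
  p1 <- plant_hbond(
    cx,
    donor_spec = list(resname = "GLN", resseq = 443L, name = "NE2",
                      hydrogen = "HE21"),
    acceptor_spec = list(resname = "LIG", resseq = 900L, name = "OAC"),
    distance = 2.0, angle = 150)
  p2 <- plant_hbond(
    cx,
    donor_spec = list(resname = "GLN", resseq = 443L, name = "NE2",
                      hydrogen = "HE21"),
    acceptor_spec = list(resname = "LIG", resseq = 900L, name = "OAC"),
    distance = 3.0, angle = 140)
  bonds <- list(detect_hbonds(p1), detect_hbonds(p2))
  s <- summarize_ligand(bonds, mode = "with_water", ligand_id = "x")
  expect_equal(s$bonds_per_pose, 1.0)
  expect_equal(s$mean_h_a_distance, 2.5, tolerance = 1e-6)
  # 3 and 5 bonds over two poses average to 4
  fake <- detect_hbonds(p1)
  s2 <- summarize_ligand(list(fake[rep(1, 3), ], fake[rep(1, 5), ]))
  expect_equal(s2$bonds_per_pose, 4.0)
  expect_error(summarize_ligand(list()), "at least one pose")
  # no bonds: mean distance undefined
  s3 <- summarize_ligand(list(detect_hbonds(build_toy_pocket(0))))
  expect_equal(s3$bonds_per_pose, 0)
  expect_true(is.na(s3$mean_h_a_distance))
})

test_that("hydrogen-free structures warn and yield nothing", {
  txt <- paste(pdb_line("HETATM", 1, "O1", "LIG", "L", 1, 0, 0, 0, "O"),
               pdb_line("ATOM", 2, "O", "GLY", "A", 5, 3, 0, 0, "O"),
               sep = "\n")
  cx <- read_structure(txt)
  expect_warning(b <- detect_hbonds(cx), "no hydrogens")
  expect_equal(nrow(b), 0L)
})
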