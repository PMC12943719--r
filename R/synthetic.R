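# Synthetic binding pockets, planted hydrogen bonds, pose ensembles and
# two-class ligand datasets. The toy pocket is an abstract stand-in for
# a phosphodiesterase catalytic site: a glutamine-like probe residue
# numbered 443, fourteen binding-site waters (numbers 1 and 13 sitting
# by one Zn and one Mg ion) and a small ligand carrying an acetyl
# carbonyl oxygen named OAC.

# run code under a seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# deterministic sub-seed derivation, kept inside 32-bit integer range
sub_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(k)) %%
               2147483647)
}

unit <- function(v) v / sqrt(sum(v^2))

# deterministic unit vector perpendicular to u
perp <- function(u) {
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  unit(ref - sum(ref * u) * u)
}

# evenly spread unit vectors (spherical Fibonacci lattice)
fibonacci_sphere <- function(n) {
  k <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * k / n)
  theta <- pi * (1 + sqrt(5)) * k
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  if (!(lo < hi) || mean < lo - 6 * sd || mean > hi + 6 * sd)
    stop("infeasible truncation window [", lo, ", ", hi, "]")
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(2 * (n - length(out)) + 8, mean, sd)
    out <- c(out, x[x > lo & x < hi])
  }
  out[seq_len(n)]
}

atom_row <- function(serial, name, element, resname, resseq, chain, xyz,
                     record, role) {
  data.frame(serial = serial, name = name, element = element,
             resname = resname, resseq = resseq, chain = chain,
             x = xyz[1], y = xyz[2], z = xyz[3],
             record = record, role = role, stringsAsFactors = FALSE)
}

# one minimal protein residue: N-H, CA, C=O placed around `center` with
# the backbone axis along `axis`
residue_atoms <- function(resname, resseq, center, axis) {
  a <- unit(axis)
  p <- perp(a)
  rows <- list(
    list("N",  "N", center),
    list("H",  "H", center + 1.01 * p),
    list("CA", "C", center + 1.46 * a),
    list("C",  "C", center + 1.46 * a + 1.52 * unit(a + 0.4 * p)),
    list("O",  "O", center + 1.46 * a + 1.52 * unit(a + 0.4 * p) +
           1.23 * p)
  )
  do.call(rbind, lapply(rows, function(r)
    atom_row(0L, r[[1]], r[[2]], resname, resseq, "A", r[[3]],
             "ATOM", "protein")))
}

# glutamine-like side chain grafted radially inward from the backbone
gln_sidechain <- function(resseq, ca, inward) {
  u <- unit(inward)
  v <- perp(u)
  cb <- ca + 1.53 * u
  cg <- cb + 1.53 * unit(u + 0.25 * v)
  cd <- cg + 1.52 * u
  oe1 <- cd + 1.23 * unit(v - 0.3 * u)
  ne2 <- cd + 1.33 * unit(u - 0.3 * v)
  he21 <- ne2 + 1.01 * unit(u + 0.5 * v)
  he22 <- ne2 + 1.01 * unit(u - 0.9 * v)
  rows <- list(
    list("CB", "C", cb), list("CG", "C", cg), list("CD", "C", cd),
    list("OE1", "O", oe1), list("NE2", "N", ne2),
    list("HE21", "H", he21), list("HE22", "H", he22)
  )
  do.call(rbind, lapply(rows, function(r)
    atom_row(0L, r[[1]], r[[2]], "GLN", resseq, "A", r[[3]],
             "ATOM", "protein")))
}

water_atoms <- function(resseq, o_pos, dir1, dir2) {
  rows <- list(
    list("OW", "O", o_pos),
    list("HW1", "H", o_pos + 0.96 * dir1),
    list("HW2", "H", o_pos + 0.96 * dir2)
  )
  do.call(rbind, lapply(rows, function(r)
    atom_row(0L, r[[1]], r[[2]], "SOL", resseq, "W", r[[3]],
             "HETATM", "water")))
}

ligand_atoms <- function(label = "LIG") {
  # ethyl-acetyl stub: one acceptor (OAC, the acetyl carbonyl oxygen),
  # apolar elsewhere, so planted bonds are the only ligand bonds
  c1 <- c(-1.50, 0, 0)
  cac <- c(0, 0, 0)
  oac <- c(0, 0, 1.23)
  cme <- c(1.06, -1.06, 0)
  rows <- list(
    list("C1", "C", c1),
    list("H11", "H", c1 + c(-0.63, 0.89, 0)),
    list("H12", "H", c1 + c(-0.63, -0.63, 0.63)),
    list("H13", "H", c1 + c(-0.63, -0.63, -0.63)),
    list("CAC", "C", cac),
    list("OAC", "O", oac),
    list("CME", "C", cme),
    list("HM1", "H", cme + c(0.89, -0.63, 0)),
    list("HM2", "H", cme + c(0, -0.63, 0.89)),
    list("HM3", "H", cme + c(0, -0.63, -0.89))
  )
  do.call(rbind, lapply(rows, function(r)
    atom_row(0L, r[[1]], r[[2]], "LIG", 900L, "L", r[[3]],
             "HETATM", "ligand")))
}

POCKET_WATER_RADIUS <- 7.5
POCKET_PROTEIN_RADIUS <- 10.5
POCKET_GLN_CENTER <- c(0, 0, 12.5)  # glutamine backbone, up the +z axis
POCKET_GLN_DIR <- c(0, 0, 1)        # its side chain reaches down -z

# water lattice directions: a Fibonacci sphere with both polar points
# dropped, keeping the +z axis free for the glutamine side chain
pocket_water_dirs <- function(n) {
  fibonacci_sphere(n + 2L)[-c(1L, n + 2L), , drop = FALSE]
}

# rays along which water bonds are planted on the ligand acceptor: a
# 70-degree cone about +z, clear of the ligand body (below), the
# glutamine approach (+z axis) and the resting water/protein shells
PLANT_SLOTS <- 14L
MAX_PLANTED_WATERS <- 7L  # simultaneous bonds; keeps planted assemblies
                          # at >= 46 degrees so covalent typing is safe
plant_ray_dirs <- function(n = PLANT_SLOTS) {
  az <- (seq_len(n) - 1L) * 2 * pi / n
  cbind(sin(70 * pi / 180) * cos(az), sin(70 * pi / 180) * sin(az),
        rep(cos(70 * pi / 180), n))
}

#' Build a deterministic toy binding pocket
#'
#' Constructs a complex with five protein residues (a glutamine-like
#' probe residue numbered 443 among them), `n_waters` waters with
#' residue numbers 1..n (residue name `SOL`), one Zn and one Mg ion
#' placed by waters 1 and 13, and a ligand carrying a uniquely named
#' acetyl carbonyl oxygen `OAC` at the pocket centre. Geometry is
#' physically plausible (no non-covalent heavy-atom pair below 1.8 A)
#' and byte-identical across runs for the same seed.
#'
#' @param seed integer seed for the water jitter (default 0).
#' @param n_waters number of binding-site waters (default 14).
#' @param label ligand label.
#' @return a `dockhb_complex`.
#' @export
build_toy_pocket <- function(seed = 0, n_waters = 14, label = "LIG") {
  with_seed(sub_seed(seed, 1), {
    dirs <- pocket_water_dirs(n_waters)
    # four plain residues on a mid-latitude ring, clear of the +z axis
    prot_dirs <- fibonacci_sphere(6)[2:5, , drop = FALSE]

    blocks <- list()
    for (i in 1:4) {
      resseq <- c(440L, 441L, 442L, 444L)[i]
      center <- POCKET_PROTEIN_RADIUS * prot_dirs[i, ]
      blocks[[length(blocks) + 1L]] <-
        residue_atoms("GLY", resseq, center, axis = perp(unit(center)))
    }
    # the glutamine probe residue sits above the pocket; its side chain
    # reaches down the +z axis, stopping well outside the hydrogen-bond
    # window of the ligand acceptor
    gln <- residue_atoms("GLN", 443L, POCKET_GLN_CENTER, axis = c(1, 0, 0))
    ca <- as.numeric(gln[gln$name == "CA", c("x", "y", "z")])
    gln <- rbind(gln, gln_sidechain(443L, ca, inward = -POCKET_GLN_DIR))
    blocks[[length(blocks) + 1L]] <- gln

    blocks[[length(blocks) + 1L]] <- ligand_atoms(label)

    for (w in seq_len(n_waters)) {
      u <- dirs[w, ]
      o <- POCKET_WATER_RADIUS * u + stats::runif(3, -0.25, 0.25)
      v <- perp(u)
      d1 <- unit(u + 0.8 * v)
      d2 <- unit(u - 0.8 * v)
      blocks[[length(blocks) + 1L]] <- water_atoms(w, o, d1, d2)
    }

    # ions sit on the water-1 and water-13 rays, inside the resting
    # shell but clear of every planting ray and of the ligand
    ion_ids <- c(1L, min(13L, n_waters))
    ions <- rbind(
      atom_row(0L, "ZN", "ZN", "ZN", 501L, "I",
               5.2 * dirs[ion_ids[1], ], "HETATM", "ion"),
      atom_row(0L, "MG", "MG", "MG", 502L, "I",
               5.2 * dirs[ion_ids[2], ], "HETATM", "ion")
    )
    blocks[[length(blocks) + 1L]] <- ions

    atoms <- do.call(rbind, blocks)
    atoms$serial <- seq_len(nrow(atoms))
    new_complex(atoms, label = label)
  })
}

resolve_atom <- function(complex, spec, what = "atom") {
  atoms <- complex$atoms
  sel <- rep(TRUE, nrow(atoms))
  if (!is.null(spec$resname)) sel <- sel & atoms$resname == spec$resname
  if (!is.null(spec$resseq)) sel <- sel & atoms$resseq == spec$resseq
  if (!is.null(spec$name)) sel <- sel & atoms$name == spec$name
  idx <- which(sel)
  if (length(idx) != 1L)
    stop("selector for ", what, " (",
         paste(unlist(spec), collapse = "/"),
         ") resolves to ", length(idx), " atoms")
  idx
}

#' Plant a hydrogen bond at an exact geometry
#'
#' Repositions the donor's hydrogen along its existing bond direction
#' (bond length preserved) and moves the acceptor atom so the
#' hydrogen-acceptor distance and the donor-hydrogen-acceptor angle
#' equal the request to within 1e-6. No other atoms move.
#'
#' @param complex a `dockhb_complex`.
#' @param donor_spec list with `resname`/`resseq`/`name` identifying the
#'   donor heavy atom, plus `hydrogen` naming its hydrogen.
#' @param acceptor_spec list with `resname`/`resseq`/`name` identifying
#'   the acceptor atom.
#' @param distance target H...A distance in Angstrom (> 0).
#' @param angle target D-H...A angle in degrees, in `[0, 180]`.
#' @return the modified complex (covalent map kept from construction).
#' @export
plant_hbond <- function(complex, donor_spec, acceptor_spec,
                        distance, angle) {
  stopifnot(distance > 0, angle >= 0, angle <= 180)
  d_idx <- resolve_atom(complex, donor_spec[c("resname", "resseq", "name")],
                        "donor heavy atom")
  h_spec <- donor_spec
  h_spec$name <- donor_spec$hydrogen
  h_idx <- resolve_atom(complex, h_spec[c("resname", "resseq", "name")],
                        "donor hydrogen")
  a_idx <- resolve_atom(complex,
                        acceptor_spec[c("resname", "resseq", "name")],
                        "acceptor")
  xyz <- coords(complex)
  d <- xyz[d_idx, ]
  h0 <- xyz[h_idx, ]
  u <- unit(h0 - d)
  h <- d + sqrt(sum((h0 - d)^2)) * u
  a_rad <- angle * pi / 180
  v1 <- perp(u)
  v2 <- c(u[2] * v1[3] - u[3] * v1[2],
          u[3] * v1[1] - u[1] * v1[3],
          u[1] * v1[2] - u[2] * v1[1])
  others <- setdiff(seq_len(nrow(xyz)), c(d_idx, h_idx, a_idx))
  bonded <- unique(c(complex$bonds[complex$bonds[, 1] == a_idx, 2],
                     complex$bonds[complex$bonds[, 2] == a_idx, 1]))
  check <- setdiff(others, bonded)
  a <- NULL
  # the azimuth about the donor axis is unconstrained; scan it
  # deterministically for a collision-free placement
  for (az in seq(0, 330, by = 30) * pi / 180) {
    v <- cos(az) * v1 + sin(az) * v2
    w <- -u * cos(a_rad) + v * sin(a_rad)  # angle(h->d, h->a) = angle
    cand <- h + distance * w
    gap <- if (length(check))
      min(sqrt(colSums((t(xyz[check, , drop = FALSE]) - cand)^2)))
    else Inf
    if (gap >= 1.5) { a <- cand; break }
  }
  if (is.null(a))
    stop("placement error: no collision-free acceptor position at ",
         distance, " A / ", angle, " deg from the requested donor")
  complex$atoms[h_idx, c("x", "y", "z")] <- h
  complex$atoms[a_idx, c("x", "y", "z")] <- a
  complex
}

#' Class geometry model for the two-class synthetic dataset
#'
#' Defaults are the printed class statistics of the study the pipeline
#' emulates: water hydrogen-bond mean distances 2.64 A (active class A)
#' vs 2.18 A (low-active class I); water bonds per pose 1.47 vs 2.13;
#' glutamine-amide bond distances 2.77 vs 2.81 A at rates 0.8 vs 0.6
#' bonds per pose; 14 binding-site waters; 100 poses per ligand. The
#' distance spread (sd 0.2 A) is a generator choice - the source
#' statistics are means only.
#'
#' @param water_distance_mean_A,water_distance_mean_I mean H...A
#'   distance of ligand-water bonds per class (A).
#' @param water_distance_sd common distance spread (A).
#' @param bonds_per_pose_A,bonds_per_pose_I water-bond rates per pose.
#' @param gln_distance_mean_A,gln_distance_mean_I glutamine-amide bond
#'   mean distances (A).
#' @param gln_bonds_per_pose_A,gln_bonds_per_pose_I glutamine-amide bond
#'   rates per pose (must be in `[0, 1]`: at most one is planted).
#' @param n_waters number of pocket waters.
#' @param poses_per_ligand poses generated per ligand.
#' @param seed default dataset seed.
#' @return list of class `dockhb_geommodel`.
#' @export
class_geometry_model <- function(water_distance_mean_A = 2.64,
                                 water_distance_mean_I = 2.18,
                                 water_distance_sd = 0.2,
                                 bonds_per_pose_A = 1.47,
                                 bonds_per_pose_I = 2.13,
                                 gln_distance_mean_A = 2.77,
                                 gln_distance_mean_I = 2.81,
                                 gln_bonds_per_pose_A = 0.8,
                                 gln_bonds_per_pose_I = 0.6,
                                 n_waters = 14L,
                                 poses_per_ligand = 100L,
                                 seed = 0L) {
  means <- c(water_distance_mean_A, water_distance_mean_I,
             gln_distance_mean_A, gln_distance_mean_I)
  if (any(means <= 1.5 | means >= 3.5))
    stop("class mean distances must lie inside the detectable window ",
         "(1.5, 3.5) A")
  stopifnot(water_distance_sd > 0,
            bonds_per_pose_A >= 0, bonds_per_pose_I >= 0,
            gln_bonds_per_pose_A >= 0, gln_bonds_per_pose_A <= 1,
            gln_bonds_per_pose_I >= 0, gln_bonds_per_pose_I <= 1,
            n_waters >= 2, poses_per_ligand >= 1)
  structure(as.list(environment())[c(
    "water_distance_mean_A", "water_distance_mean_I", "water_distance_sd",
    "bonds_per_pose_A", "bonds_per_pose_I",
    "gln_distance_mean_A", "gln_distance_mean_I",
    "gln_bonds_per_pose_A", "gln_bonds_per_pose_I",
    "n_waters", "poses_per_ligand", "seed")],
    class = "dockhb_geommodel")
}

# place one water so that HW1 donates to the acceptor at (distance,
# angle) along pocket direction u; HW2 points away from the acceptor
place_water_donor <- function(xyz, rows, acceptor_pos, u, distance,
                              angle_deg) {
  a_rad <- angle_deg * pi / 180
  v <- perp(u)
  h1 <- acceptor_pos + distance * u
  # vertex at h1: vector to the acceptor is -u, so the donor direction w
  # must satisfy w . (-u) = cos(angle)
  w <- u * cos(pi - a_rad) + v * sin(pi - a_rad)
  ow <- h1 + 0.96 * w
  h2 <- ow + 0.96 * unit(ow - acceptor_pos)
  xyz[rows[1], ] <- ow
  xyz[rows[2], ] <- h1
  xyz[rows[3], ] <- h2
  xyz
}

# rebuild the glutamine amide so HE21 donates to the acceptor at the
# requested geometry; the rest of the side chain trails outward
place_gln_donor <- function(xyz, idx, acceptor_pos, u, distance,
                            angle_deg) {
  a_rad <- angle_deg * pi / 180
  v <- perp(u)
  h1 <- acceptor_pos + distance * u
  w <- u * cos(pi - a_rad) + v * sin(pi - a_rad)
  ne2 <- h1 + 1.01 * w
  out <- unit(ne2 - acceptor_pos)
  he22 <- ne2 + 1.01 * out
  cd <- ne2 + 1.33 * unit(out + 0.4 * v)
  oe1 <- cd + 1.23 * unit(out - 0.8 * v)
  cg <- cd + 1.52 * out
  cb <- cg + 1.53 * out
  xyz[idx["NE2"], ] <- ne2
  xyz[idx["HE21"], ] <- h1
  xyz[idx["HE22"], ] <- he22
  xyz[idx["CD"], ] <- cd
  xyz[idx["OE1"], ] <- oe1
  xyz[idx["CG"], ] <- cg
  xyz[idx["CB"], ] <- cb
  xyz
}

#' Simulate a pose ensemble with planted cluster structure
#'
#' Poses are drawn around `n_clusters` displaced copies of the topology
#' with per-atom jitter bounded by `intra_spread`; cluster energy levels
#' are shifted so cluster 1 holds the lowest minimum, cluster 2 the
#' next, and so on.
#'
#' @param topology a `dockhb_complex` template.
#' @param n_poses number of poses (default 100).
#' @param n_clusters number of planted clusters.
#' @param intra_spread maximum per-atom displacement within a cluster
#'   (A).
#' @param inter_separation distance between cluster centres (A); should
#'   exceed twice the clustering threshold for exact recovery.
#' @param cluster_weights sampling weights (must sum to 1); default
#'   equal.
#' @param energy_sd within-cluster energy spread (kcal/mol).
#' @param seed RNG seed.
#' @return list with `ensemble` (a `dockhb_ensemble`) and `labels`
#'   (integer ground-truth cluster of each pose).
#' @export
simulate_pose_ensemble <- function(topology, n_poses = 100,
                                   n_clusters = 3, intra_spread = 1.0,
                                   inter_separation = 20.0,
                                   cluster_weights = NULL,
                                   energy_sd = 0.2, seed = 0) {
  if (is.null(cluster_weights))
    cluster_weights <- rep(1 / n_clusters, n_clusters)
  if (abs(sum(cluster_weights) - 1) > 1e-8)
    stop("cluster_weights must sum to 1")
  with_seed(sub_seed(seed, 2), {
    base <- coords(topology)
    dirs <- fibonacci_sphere(max(n_clusters, 2L))
    centers <- lapply(seq_len(n_clusters), function(k)
      (k - 1L) * inter_separation * dirs[k, ])
    # guarantee every cluster is realised, remaining poses by weight
    labels <- c(seq_len(n_clusters),
                sample.int(n_clusters, n_poses - n_clusters,
                           replace = TRUE, prob = cluster_weights))
    labels <- labels[seq_len(n_poses)]
    poses <- lapply(seq_len(n_poses), function(i) {
      shift <- centers[[labels[i]]]
      jit <- matrix(stats::runif(3 * nrow(base), -1, 1), ncol = 3)
      nr <- sqrt(rowSums(jit^2))
      jit <- jit / pmax(nr, 1e-12) *
        (stats::runif(nrow(base))^(1 / 3) * intra_spread)
      sweep(base, 2, shift, "+") + jit
    })
    energies <- stats::rnorm(n_poses, 0, energy_sd)
    for (k in seq_len(n_clusters)) {
      in_k <- labels == k
      energies[in_k] <- energies[in_k] - min(energies[in_k]) +
        (-12 + 2 * (k - 1))
    }
    list(ensemble = new_ensemble(topology, poses, energies),
         labels = labels)
  })
}

#' Simulate the two-class ligand dataset
#'
#' For each synthetic ligand, generates `poses_per_ligand` pocket
#' conformations in which ligand-water hydrogen bonds are planted at a
#' Poisson count per pose (class rate, waters drawn among the pocket's
#' `n_waters`) with truncated-normal distances at the class mean, and a
#' glutamine-amide bond is planted as a Bernoulli event at the class
#' rate and class distance. All planted bonds satisfy the detection
#' criterion by construction and nothing else in the pocket does.
#'
#' @param model a [class_geometry_model()].
#' @param n_ligands_per_class ligands per class (default 8).
#' @param seed RNG seed (default: the model's).
#' @return list of class `dockhb_dataset`: `ligands` (list with
#'   `ligand_id`, `class`, `ensemble`, `truth`), `model`, `seed`. Each
#'   `truth` holds the realised planted counts and distances per pose.
#' @export
simulate_class_dataset <- function(model = class_geometry_model(),
                                   n_ligands_per_class = 8,
                                   seed = model$seed) {
  base <- build_toy_pocket(seed = seed, n_waters = model$n_waters)
  atoms <- base$atoms
  base_xyz <- coords(base)
  oac <- as.numeric(atoms[atoms$name == "OAC" & atoms$role == "ligand",
                          c("x", "y", "z")])
  water_rows <- lapply(seq_len(model$n_waters), function(w)
    which(atoms$role == "water" & atoms$resseq == w))
  rays <- plant_ray_dirs()
  gln_names <- c("NE2", "HE21", "HE22", "CD", "OE1", "CG", "CB")
  gidx <- vapply(gln_names, function(nm)
    which(atoms$resname == "GLN" & atoms$resseq == 443L &
            atoms$name == nm), 0L)
  gdir <- unit(POCKET_GLN_DIR)  # planted amide approaches from above

  classes <- c(rep("A", n_ligands_per_class),
               rep("I", n_ligands_per_class))
  ligands <- vector("list", length(classes))
  for (li in seq_along(classes)) {
    cls <- classes[li]
    wrate <- if (cls == "A") model$bonds_per_pose_A else
      model$bonds_per_pose_I
    wmean <- if (cls == "A") model$water_distance_mean_A else
      model$water_distance_mean_I
    grate <- if (cls == "A") model$gln_bonds_per_pose_A else
      model$gln_bonds_per_pose_I
    gmean <- if (cls == "A") model$gln_distance_mean_A else
      model$gln_distance_mean_I
    lig_id <- sprintf("%s%02d", cls, ((li - 1L) %% n_ligands_per_class) + 1L)

    res <- with_seed(sub_seed(seed, 100 + li), {
      np <- model$poses_per_ligand
      poses <- vector("list", np)
      truth <- list(water_count = integer(np),
                    water_distances = vector("list", np),
                    gln_bond = logical(np), gln_distance = rep(NA_real_, np))
      for (p in seq_len(np)) {
        xyz <- base_xyz
        kw <- min(stats::rpois(1, wrate),
                  min(MAX_PLANTED_WATERS, model$n_waters))
        if (kw > 0) {
          ws <- sample.int(model$n_waters, kw)
          # spread the planted assemblies over well-separated rays
          slots <- floor((seq_len(kw) - 1L) * PLANT_SLOTS / kw) + 1L
          dists <- rtruncnorm1(kw, wmean, model$water_distance_sd,
                               1.6, 3.45)
          angs <- stats::runif(kw, 130, 165)
          for (j in seq_len(kw))
            xyz <- place_water_donor(xyz, water_rows[[ws[j]]], oac,
                                     rays[slots[j], ], dists[j], angs[j])
          truth$water_distances[[p]] <- dists
        } else {
          truth$water_distances[[p]] <- numeric(0)
        }
        truth$water_count[p] <- kw
        if (stats::runif(1) < grate) {
          gd <- rtruncnorm1(1, gmean, model$water_distance_sd, 1.6, 3.45)
          ga <- stats::runif(1, 130, 165)
          xyz <- place_gln_donor(xyz, gidx, oac, gdir, gd, ga)
          truth$gln_bond[p] <- TRUE
          truth$gln_distance[p] <- gd
        }
        poses[[p]] <- xyz
      }
      energies <- stats::rnorm(np, -8, 1)
      list(poses = poses, energies = energies, truth = truth)
    })
    topo <- base
    topo$label <- lig_id
    ligands[[li]] <- list(
      ligand_id = lig_id, class = cls,
      ensemble = new_ensemble(topo, res$poses, res$energies),
      truth = res$truth
    )
  }
  structure(list(ligands = ligands, model = model, seed = seed),
            class = "dockhb_dataset")
}

#' Draw class-comparison samples from the geometry model alone
#'
#' Statistical-level counterpart of [simulate_class_dataset()]: draws
#' the pooled per-bond water distances (and per-pose counts) directly
#' from the model's truncated-normal/Poisson laws without building
#' structures. Used for Monte-Carlo power and type-I-error studies where
#' building thousands of pocket replicas would add nothing but time.
#'
#' @param model a [class_geometry_model()].
#' @param n_ligands_per_class ligands per class.
#' @param seed RNG seed.
#' @return list with `distances_A`, `distances_I` (pooled water-bond
#'   distances) and `counts_A`, `counts_I` (bonds per pose).
#' @export
simulate_class_statistics <- function(model = class_geometry_model(),
                                      n_ligands_per_class = 8,
                                      seed = 0) {
  with_seed(sub_seed(seed, 3), {
    np <- model$poses_per_ligand * n_ligands_per_class
    draw <- function(rate, mean) {
      counts <- pmin(stats::rpois(np, rate), model$n_waters)
      list(counts = counts,
           distances = rtruncnorm1(sum(counts), mean,
                                   model$water_distance_sd, 1.6, 3.45))
    }
    a <- draw(model$bonds_per_pose_A, model$water_distance_mean_A)
    i <- draw(model$bonds_per_pose_I, model$water_distance_mean_I)
    list(distances_A = a$distances, distances_I = i$distances,
         counts_A = a$counts, counts_I = i$counts)
  })
}
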