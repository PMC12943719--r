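# Fixtures built in code and independent oracles used across the suite.

# -- minimal hand-written PDB fragments ------------------------------------

pdb_line <- function(record, serial, name, resname, chain, resseq,
                     x, y, z, element) {
  sprintf("%-6s%5d %-4s %-4s%1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, ifelse(nchar(name) < 4, paste0(" ", name), name),
          resname, chain, resseq, x, y, z, 1.00, 0.00, element)
}

# one water molecule: O with two H at 0.96 A, 104.5 degrees apart
water_pdb_text <- function() {
  h1 <- 0.96 * c(1, 0, 0)
  h2 <- 0.96 * c(cos(104.5 * pi / 180), sin(104.5 * pi / 180), 0)
  paste(c(
    pdb_line("HETATM", 1, "OW", "HOH", "W", 1, 0, 0, 0, "O"),
    pdb_line("HETATM", 2, "HW1", "HOH", "W", 1, h1[1], h1[2], h1[3], "H"),
    pdb_line("HETATM", 3, "HW2", "HOH", "W", 1, h2[1], h2[2], h2[3], "H"),
    "END"), collapse = "\n")
}

# methane: C with 4 H, no donors/acceptors
methane_pdb_text <- function() {
  hs <- 1.09 / sqrt(3) * rbind(c(1, 1, 1), c(1, -1, -1),
                               c(-1, 1, -1), c(-1, -1, 1))
  paste(c(
    pdb_line("HETATM", 1, "C1", "MET", "L", 1, 0, 0, 0, "C"),
    sapply(1:4, function(i)
      pdb_line("HETATM", 1 + i, paste0("H", i), "MET", "L", 1,
               hs[i, 1], hs[i, 2], hs[i, 3], "H")),
    "END"), collapse = "\n")
}

# multi-model PDB text for an ensemble of a complex
ensemble_pdb_text <- function(complex, poses) {
  lines <- unlist(lapply(seq_along(poses), function(i) {
    cx <- complex
    cx$atoms[, c("x", "y", "z")] <- poses[[i]]
    c(sprintf("MODEL     %4d", i),
      head(write_structure(cx), -1),
      "ENDMDL")
  }))
  c(lines, "END")
}

# -- randomized pocket with scrambled waters (borderline geometries) -------

random_pocket <- function(seed) {
  cx <- build_toy_pocket(seed %% 50)
  set.seed(seed)
  atoms <- cx$atoms
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  oac <- as.numeric(atoms[atoms$name == "OAC", c("x", "y", "z")])
  heavy_fixed <- which(toupper(atoms$element) != "H" &
                         atoms$role != "water")
  for (w in unique(atoms$resseq[atoms$role == "water"])) {
    rows <- which(atoms$role == "water" & atoms$resseq == w)
    repeat {
      u <- rnorm(3); u <- u / sqrt(sum(u^2))
      o <- oac + runif(1, 2.0, 6.0) * u
      if (min(sqrt(colSums((t(xyz[heavy_fixed, , drop = FALSE]) - o)^2)))
          > 2.0) break
    }
    a1 <- rnorm(3); a1 <- a1 / sqrt(sum(a1^2))
    ref <- if (abs(a1[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    a2 <- ref - sum(ref * a1) * a1; a2 <- a2 / sqrt(sum(a2^2))
    ang <- 104.5 * pi / 180
    xyz[rows[1], ] <- o
    xyz[rows[2], ] <- o + 0.96 * a1
    xyz[rows[3], ] <- o + 0.96 * (cos(ang) * a1 + sin(ang) * a2)
  }
  atoms[, c("x", "y", "z")] <- xyz
  new_complex(atoms, label = cx$label)
}

# -- independent brute-force oracles ---------------------------------------

oracle_angle <- function(d, h, a) {
  u <- d - h; v <- a - h
  acos(max(-1, min(1, sum(u * v) /
                     (sqrt(sum(u^2)) * sqrt(sum(v^2)))))) * 180 / pi
}

# exhaustive all-pairs hydrogen-bond scan, written against the raw atom
# table only (its own hydrogen assignment, no package internals)
oracle_hbonds <- function(complex, cutoff = 3.5, amin = 120, amax = 170,
                          include_water = TRUE) {
  atoms <- complex$atoms
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  el <- toupper(atoms$element)
  n <- nrow(atoms)
  heavy <- which(el != "H")
  parent <- rep(NA_integer_, n)
  for (h in which(el == "H")) {
    d <- sqrt(colSums((t(xyz[heavy, , drop = FALSE]) - xyz[h, ])^2))
    parent[h] <- heavy[which.min(d)]
  }
  res <- NULL
  for (h in which(el == "H")) {
    dheavy <- parent[h]
    if (!(el[dheavy] %in% c("N", "O", "S"))) next
    if (atoms$role[dheavy] == "ion") next
    for (a in seq_len(n)) {
      if (!(el[a] %in% c("N", "O"))) next
      if (atoms$role[a] == "ion") next
      rd <- atoms$role[dheavy]; ra <- atoms$role[a]
      pair_ok <- (rd == "ligand" && ra %in% c("protein", "water")) ||
        (ra == "ligand" && rd %in% c("protein", "water"))
      if (!pair_ok) next
      dist <- sqrt(sum((xyz[h, ] - xyz[a, ])^2))
      if (dist >= cutoff) next
      ang <- oracle_angle(xyz[dheavy, ], xyz[h, ], xyz[a, ])
      if (ang < amin || ang > amax) next
      partner_idx <- if (rd == "ligand") a else dheavy
      if (!include_water && atoms$role[partner_idx] == "water") next
      res <- rbind(res, data.frame(
        donor_serial = atoms$serial[dheavy],
        hydrogen_serial = atoms$serial[h],
        acceptor_serial = atoms$serial[a],
        h_a_distance = dist, dha_angle = ang))
    }
  }
  if (is.null(res))
    return(data.frame(donor_serial = integer(0),
                      hydrogen_serial = integer(0),
                      acceptor_serial = integer(0),
                      h_a_distance = numeric(0), dha_angle = numeric(0)))
  res <- res[order(res$donor_serial, res$acceptor_serial,
                   res$hydrogen_serial), ]
  rownames(res) <- NULL
  res
}

hbond_key <- function(df) {
  df <- df[order(df$donor_serial, df$acceptor_serial,
                 df$hydrogen_serial), , drop = FALSE]
  paste(df$donor_serial, df$hydrogen_serial, df$acceptor_serial)
}

rigid_transform <- function(complex, seed = 1) {
  set.seed(seed)
  th <- runif(3, 0, 2 * pi)
  Rx <- rbind(c(1, 0, 0), c(0, cos(th[1]), -sin(th[1])),
              c(0, sin(th[1]), cos(th[1])))
  Ry <- rbind(c(cos(th[2]), 0, sin(th[2])), c(0, 1, 0),
              c(-sin(th[2]), 0, cos(th[2])))
  Rz <- rbind(c(cos(th[3]), -sin(th[3]), 0),
              c(sin(th[3]), cos(th[3]), 0), c(0, 0, 1))
  R <- Rx %*% Ry %*% Rz
  tvec <- runif(3, -20, 20)
  xyz <- as.matrix(complex$atoms[, c("x", "y", "z")])
  complex$atoms[, c("x", "y", "z")] <- sweep(xyz %*% t(R), 2, tvec, "+")
  complex
}
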