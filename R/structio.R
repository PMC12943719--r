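# Structure I/O: fixed-column PDB reading/writing, atom role partition,
# covalent inference and hydrogen-bond donor/acceptor typing.

WATER_RESNAMES <- c("HOH", "SOL", "WAT")
ION_ELEMENTS <- c("ZN", "MG", "NA", "CL", "K", "CA")

# single-bond covalent radii (Angstrom), Cordero et al. consensus values
COVALENT_RADII <- c(
  H = 0.31, C = 0.76, N = 0.71, O = 0.66, S = 1.05, P = 1.07,
  "F" = 0.57, CL = 1.02, BR = 1.20, "I" = 1.39,
  ZN = 1.22, MG = 1.41, "NA" = 1.66, K = 2.03, CA = 1.76
)

#' Construct a protein-ligand complex object
#'
#' A `dockhb_complex` holds an ordered atom table (one row per PDB
#' ATOM/HETATM record), a covalent bond map inferred from interatomic
#' distances, and a ligand label. Atoms are partitioned exhaustively and
#' disjointly into roles `ligand`, `protein`, `water`, `ion`.
#'
#' @param atoms data.frame with columns `serial`, `name`, `element`,
#'   `resname`, `resseq`, `chain`, `x`, `y`, `z`, `record`, `role`.
#' @param label ligand identifier carried through summaries.
#' @param build_bonds infer the covalent map on construction.
#' @return object of class `dockhb_complex` with elements `atoms`
#'   (data.frame), `bonds` (two-column integer matrix of atom row
#'   indices), `label`.
#' @export
new_complex <- function(atoms, label = "ligand", build_bonds = TRUE) {
  required <- c("serial", "name", "element", "resname", "resseq",
                "chain", "x", "y", "z", "record", "role")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols))
    stop("atoms table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite coordinates in atom table")
  if (any(!nzchar(atoms$element)))
    stop("empty element field in atom table")
  if (!all(atoms$role %in% c("ligand", "protein", "water", "ion")))
    stop("atom role outside {ligand, protein, water, ion}")
  rownames(atoms) <- NULL
  obj <- structure(
    list(atoms = atoms, bonds = NULL, label = label),
    class = "dockhb_complex"
  )
  if (build_bonds) obj$bonds <- infer_covalent_map(atoms)
  obj
}

#' @export
print.dockhb_complex <- function(x, ...) {
  tab <- table(x$atoms$role)
  cat("<dockhb_complex> '", x$label, "': ", nrow(x$atoms), " atoms (",
      paste(names(tab), tab, sep = "=", collapse = ", "), "), ",
      if (is.null(x$bonds)) 0L else nrow(x$bonds), " covalent bonds\n",
      sep = "")
  invisible(x)
}

coords <- function(complex) {
  as.matrix(complex$atoms[, c("x", "y", "z")])
}

element_of <- function(name, resname) {
  # PDB element guess from the atom name when columns 77-78 are blank
  nm <- gsub("[^A-Za-z]", "", name)
  up <- toupper(nm)
  two <- substr(up, 1, 2)
  if (two %in% c("ZN", "MG", "CL", "BR", "FE", "NA", "CA") &&
      toupper(resname) %in% c(two, "ZN", "MG", "CL", "BR", "NA", "CA"))
    return(two)
  substr(up, 1, 1)
}

assign_roles <- function(atoms) {
  role <- rep(NA_character_, nrow(atoms))
  resname <- toupper(atoms$resname)
  water <- resname %in% WATER_RESNAMES
  role[water] <- "water"
  # ion = single-atom residue whose element is a common ion
  key <- paste(atoms$chain, atoms$resseq, atoms$resname)
  sizes <- table(key)
  single <- sizes[key] == 1L
  ion <- !water & single & toupper(atoms$element) %in% ION_ELEMENTS
  role[ion] <- "ion"
  rest <- is.na(role)
  role[rest & atoms$record == "ATOM"] <- "protein"
  role[rest & atoms$record == "HETATM"] <- "ligand"
  role
}

infer_covalent_map <- function(atoms) {
  n <- nrow(atoms)
  if (n < 2L) return(matrix(integer(0), ncol = 2,
                            dimnames = list(NULL, c("i", "j"))))
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  el <- toupper(atoms$element)
  is_h <- el == "H"
  heavy <- which(!is_h)
  pairs <- matrix(integer(0), ncol = 2)

  # hydrogens: each H bonds to its nearest heavy atom within threshold
  for (h in which(is_h)) {
    d2 <- colSums((t(xyz[heavy, , drop = FALSE]) - xyz[h, ])^2)
    j <- heavy[which.min(d2)]
    lim <- if (el[j] == "S") 1.5 else 1.2
    if (sqrt(min(d2)) > lim)
      stop("hydrogen atom serial ", atoms$serial[h],
           " ('", atoms$name[h], "') has no heavy atom within ", lim, " A")
    pairs <- rbind(pairs, c(min(h, j), max(h, j)))
  }

  # heavy-heavy: distance <= covalent radii sum + 0.4 A, same-role
  # organic atoms only; metal ions coordinate, they do not bond
  hv <- heavy[!(atoms$role[heavy] %in% "ion")]
  if (length(hv) >= 2L) {
    r <- COVALENT_RADII[el[hv]]
    r[is.na(r)] <- 0.77
    dm <- as.matrix(stats::dist(xyz[hv, , drop = FALSE]))
    lim <- outer(r, r, "+") + 0.4
    hit <- which(dm <= lim & upper.tri(dm), arr.ind = TRUE)
    if (nrow(hit))
      pairs <- rbind(pairs, cbind(hv[hit[, 1]], hv[hit[, 2]]))
  }
  pairs <- unique(pairs)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  dimnames(pairs) <- list(NULL, c("i", "j"))
  pairs
}

parse_pdb_atoms <- function(lines) {
  sel <- grepl("^(ATOM  |HETATM)", lines)
  idx <- which(sel)
  if (!length(idx)) stop("no ATOM/HETATM records found")
  ln <- lines[idx]
  record <- trimws(substr(ln, 1, 6))
  serial <- suppressWarnings(as.integer(trimws(substr(ln, 7, 11))))
  name <- trimws(substr(ln, 13, 16))
  resname <- trimws(substr(ln, 18, 21))
  chain <- trimws(substr(ln, 22, 22))
  resseq <- suppressWarnings(as.integer(trimws(substr(ln, 23, 26))))
  x <- suppressWarnings(as.numeric(trimws(substr(ln, 31, 38))))
  y <- suppressWarnings(as.numeric(trimws(substr(ln, 39, 46))))
  z <- suppressWarnings(as.numeric(trimws(substr(ln, 47, 54))))
  element <- trimws(substr(ln, 77, 78))
  bad <- which(is.na(serial) | is.na(resseq) | is.na(x) | is.na(y) | is.na(z))
  if (length(bad))
    stop("malformed fixed-width PDB record at line ", idx[bad[1]],
         ": '", ln[bad[1]], "'")
  blank <- !nzchar(element)
  if (any(blank))
    element[blank] <- mapply(element_of, name[blank], resname[blank])
  atoms <- data.frame(
    serial = serial, name = name, element = toupper(element),
    resname = resname, resseq = resseq, chain = chain,
    x = x, y = y, z = z, record = record,
    stringsAsFactors = FALSE
  )
  atoms$role <- assign_roles(atoms)
  atoms
}

as_pdb_lines <- function(text) {
  if (length(text) == 1L && (file.exists(text) && !grepl("\n", text)))
    return(readLines(text, warn = FALSE))
  if (length(text) == 1L) return(strsplit(text, "\n", fixed = TRUE)[[1]])
  text
}

#' Read a PDB structure into a complex
#'
#' Parses fixed-column ATOM/HETATM records, assigns each atom one of the
#' roles ligand/protein/water/ion and infers the covalent map by
#' distance (H to nearest heavy atom within 1.2 A, 1.5 A for S;
#' heavy-heavy within the covalent-radii sum + 0.4 A).
#'
#' Waters are recognised by residue name (`HOH`, `SOL`, `WAT`), ions as
#' single-atom residues with element Zn/Mg/Na/Cl/K/Ca, remaining HETATM
#' records are ligand, remaining ATOM records protein.
#'
#' @param text a file path, a single string containing the file, or a
#'   character vector of lines.
#' @param label ligand label stored on the complex.
#' @return a [new_complex()] object.
#' @export
read_structure <- function(text, label = "ligand") {
  lines <- as_pdb_lines(text)
  new_complex(parse_pdb_atoms(lines), label = label)
}

format_pdb_line <- function(a) {
  sprintf("%-6s%5d %-4s %-4s%1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          a$record, a$serial,
          # atom names of 1-3 chars start in column 14 by convention
          ifelse(nchar(a$name) < 4, paste0(" ", a$name), a$name),
          a$resname, ifelse(nzchar(a$chain), a$chain, " "), a$resseq,
          a$x, a$y, a$z, 1.00, 0.00, a$element)
}

#' Write a complex as fixed-column PDB text
#'
#' Inverse of [read_structure()] at 3-decimal coordinate precision;
#' occupancy/B-factor are written as 1.00/0.00.
#'
#' @param complex a `dockhb_complex`.
#' @param path optional file path; when `NULL` the text is returned.
#' @return invisibly (path given) or visibly, a character vector of lines.
#' @export
write_structure <- function(complex, path = NULL) {
  lines <- c(format_pdb_line(complex$atoms), "END")
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Read a multi-model pose ensemble with a sidecar energy table
#'
#' MODEL/ENDMDL blocks must share atom count and order; energies are
#' matched by model number from a TSV with header
#' `model<TAB>energy_kcal_mol`.
#'
#' @param text PDB path/text with MODEL blocks (a file without MODEL
#'   records is treated as a single pose).
#' @param energies a data.frame with columns `model`, `energy_kcal_mol`,
#'   or a path to such a TSV.
#' @param label ligand label.
#' @return object of class `dockhb_ensemble`: `topology` (complex of the
#'   first model), `poses` (list of n x 3 coordinate matrices),
#'   `energies` (numeric), `n_poses`.
#' @export
read_ensemble <- function(text, energies, label = "ligand") {
  lines <- as_pdb_lines(text)
  starts <- grep("^MODEL", lines)
  if (is.character(energies) && length(energies) == 1L) {
    if (!file.exists(energies))
      stop("energies file not found: ", energies)
    energies <- utils::read.delim(energies, sep = "\t",
                                  stringsAsFactors = FALSE)
  }
  if (!all(c("model", "energy_kcal_mol") %in% names(energies)))
    stop("energy table must have columns 'model' and 'energy_kcal_mol'")
  if (!length(starts)) {
    blocks <- list(lines)
    model_no <- 1L
  } else {
    ends <- grep("^ENDMDL", lines)
    if (length(ends) != length(starts))
      stop("unbalanced MODEL/ENDMDL records")
    blocks <- Map(function(s, e) lines[(s + 1):(e - 1)], starts, ends)
    model_no <- as.integer(trimws(substr(lines[starts], 7, 20)))
  }
  parsed <- lapply(blocks, parse_pdb_atoms)
  n0 <- nrow(parsed[[1]])
  for (k in seq_along(parsed)) {
    if (nrow(parsed[[k]]) != n0 ||
        !identical(parsed[[k]]$name, parsed[[1]]$name))
      stop("topology error: model ", model_no[k],
           " does not match the atom count/order of model ", model_no[1])
  }
  e <- energies$energy_kcal_mol[match(model_no, energies$model)]
  if (anyNA(e))
    stop("missing energy row for model(s): ",
         paste(model_no[is.na(e)], collapse = ", "))
  topology <- new_complex(parsed[[1]], label = label)
  poses <- lapply(parsed, function(a) as.matrix(a[, c("x", "y", "z")]))
  new_ensemble(topology, poses, as.numeric(e))
}

#' Construct a pose ensemble
#'
#' @param topology a `dockhb_complex` giving atom identities shared by
#'   every pose.
#' @param poses list of coordinate matrices, one per pose, each with the
#'   topology's atom count and order.
#' @param energies numeric vector (kcal/mol, lower is better), one per pose.
#' @return object of class `dockhb_ensemble`.
#' @export
new_ensemble <- function(topology, poses, energies) {
  n <- nrow(topology$atoms)
  if (!all(vapply(poses, nrow, 0L) == n))
    stop("topology error: pose atom counts differ from topology")
  if (length(energies) != length(poses))
    stop("energies length (", length(energies),
         ") != number of poses (", length(poses), ")")
  structure(
    list(topology = topology, poses = poses,
         energies = as.numeric(energies), n_poses = length(poses)),
    class = "dockhb_ensemble"
  )
}

#' @export
print.dockhb_ensemble <- function(x, ...) {
  cat("<dockhb_ensemble> '", x$topology$label, "': ", x$n_poses,
      " poses x ", nrow(x$topology$atoms), " atoms, best energy ",
      format(min(x$energies)), " kcal/mol\n", sep = "")
  invisible(x)
}

#' Materialise one pose of an ensemble as a complex
#'
#' @param ensemble a `dockhb_ensemble`.
#' @param i pose index.
#' @return a `dockhb_complex` with the topology's atoms at pose `i`
#'   coordinates (covalent map rebuilt).
#' @export
pose_complex <- function(ensemble, i) {
  atoms <- ensemble$topology$atoms
  atoms[, c("x", "y", "z")] <- ensemble$poses[[i]]
  new_complex(atoms, label = ensemble$topology$label)
}

#' Type hydrogen-bond donors and acceptors
#'
#' Donors are every N/O/S heavy atom paired with each covalently bound
#' hydrogen; acceptors are every N and O atom (S optionally). Carbons
#' are never donors or acceptors; ions take no part.
#'
#' @param complex a `dockhb_complex` with a built covalent map.
#' @param include_sulfur_acceptors include S atoms as acceptors
#'   (default `FALSE`).
#' @return list with `donors` (data.frame of atom row indices `heavy`,
#'   `hydrogen`) and `acceptors` (integer vector of atom row indices).
#' @export
identify_donors_acceptors <- function(complex,
                                      include_sulfur_acceptors = FALSE) {
  atoms <- complex$atoms
  if (is.null(complex$bonds))
    stop("covalent map not built; construct with build_bonds = TRUE")
  el <- toupper(atoms$element)
  b <- complex$bonds
  donors <- data.frame(heavy = integer(0), hydrogen = integer(0))
  if (nrow(b)) {
    hi <- el[b[, 1]] == "H"
    hj <- el[b[, 2]] == "H"
    dh <- rbind(
      data.frame(heavy = b[hj, 1], hydrogen = b[hj, 2]),
      data.frame(heavy = b[hi, 2], hydrogen = b[hi, 1])
    )
    dh <- dh[el[dh$heavy] %in% c("N", "O", "S") &
               atoms$role[dh$heavy] != "ion", , drop = FALSE]
    donors <- dh[order(dh$heavy, dh$hydrogen), , drop = FALSE]
    rownames(donors) <- NULL
  }
  acc_el <- c("N", "O", if (include_sulfur_acceptors) "S")
  acceptors <- which(el %in% acc_el & atoms$role != "ion")
  list(donors = donors, acceptors = acceptors)
}
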