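# Geometric hydrogen-bond survey between ligand and enzyme/water.
#
# A bond is collected when the hydrogen-acceptor distance is strictly
# below the cutoff (default 3.5 A) and the donor-hydrogen-acceptor angle
# (vertex at the hydrogen) lies inclusively between 120 and 170 degrees.

#' Hydrogen-bond geometric criteria
#'
#' @param max_h_acceptor_distance cutoff on the hydrogen-acceptor
#'   distance in Angstrom; strict less-than (default 3.5).
#' @param angle_min,angle_max inclusive bounds on the D-H...A angle in
#'   degrees (defaults 120 and 170).
#' @return list of class `dockhb_criteria`.
#' @export
hbond_criteria <- function(max_h_acceptor_distance = 3.5,
                           angle_min = 120, angle_max = 170) {
  stopifnot(max_h_acceptor_distance > 0,
            angle_min >= 0, angle_min <= angle_max, angle_max <= 180)
  structure(list(max_h_acceptor_distance = max_h_acceptor_distance,
                 angle_min = angle_min, angle_max = angle_max),
            class = "dockhb_criteria")
}

#' Angle at the hydrogen between donor and acceptor
#'
#' @param d,h,a numeric length-3 coordinates of donor, hydrogen,
#'   acceptor (Angstrom).
#' @return angle in degrees in `[0, 180]`, vertex at `h`.
#' @export
compute_angle <- function(d, h, a) {
  u <- d - h
  v <- a - h
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0)
    stop("degenerate geometry: coincident points in angle computation")
  cosang <- sum(u * v) / (nu * nv)
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

# vectorised D-H...A angles for coordinate matrices (rows matched)
angles_deg <- function(D, H, A) {
  U <- D - H
  V <- A - H
  nu <- sqrt(rowSums(U^2))
  nv <- sqrt(rowSums(V^2))
  cosang <- rowSums(U * V) / (nu * nv)
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

empty_hbond_frame <- function() {
  data.frame(
    donor_serial = integer(0), hydrogen_serial = integer(0),
    acceptor_serial = integer(0),
    donor_name = character(0), acceptor_name = character(0),
    donor_res = character(0), acceptor_res = character(0),
    donor_resseq = integer(0), acceptor_resseq = integer(0),
    h_a_distance = numeric(0), dha_angle = numeric(0),
    partner = character(0), direction = character(0),
    stringsAsFactors = FALSE
  )
}

#' Detect ligand-enzyme and ligand-water hydrogen bonds
#'
#' Surveys every donor-hydrogen/acceptor pair in which one side belongs
#' to the ligand and the other to the protein or a binding-site water.
#' Ligand-internal bonds are not considered; ions never participate.
#' With `include_water = FALSE` ("vacuum" mode) bonds whose partner atom
#' is a water are dropped.
#'
#' @param complex a `dockhb_complex`.
#' @param criteria a [hbond_criteria()].
#' @param include_water keep bonds with water partners (default `TRUE`).
#' @return data.frame with one row per bond: donor/hydrogen/acceptor
#'   serials, names, residues, `h_a_distance` (A), `dha_angle` (deg),
#'   `partner` (`amino_acid` or `water`) and `direction`
#'   (`ligand-donates` or `ligand-accepts`), ordered by donor then
#'   acceptor serial.
#' @export
detect_hbonds <- function(complex, criteria = hbond_criteria(),
                          include_water = TRUE) {
  atoms <- complex$atoms
  da <- identify_donors_acceptors(complex)
  if (sum(toupper(atoms$element) == "H") == 0L)
    warning("complex '", complex$label,
            "' contains no hydrogens; all donor candidates skipped")
  donors <- da$donors
  acceptors <- da$acceptors
  if (!nrow(donors) || !length(acceptors)) return(empty_hbond_frame())

  role <- atoms$role
  xyz <- coords(complex)
  env_roles <- c("protein", "water")

  out <- list()
  pair_block <- function(don_idx, acc_idx, direction) {
    if (!length(don_idx) || !length(acc_idx)) return(NULL)
    dsub <- donors[don_idx, , drop = FALSE]
    grid_d <- rep(seq_len(nrow(dsub)), times = length(acc_idx))
    grid_a <- rep(acc_idx, each = nrow(dsub))
    H <- xyz[dsub$hydrogen[grid_d], , drop = FALSE]
    A <- xyz[grid_a, , drop = FALSE]
    dist <- sqrt(rowSums((H - A)^2))
    # 1e-9 numerical guard so geometry constructed exactly at a printed
    # boundary (3.5 A, 120/170 deg) resolves deterministically:
    # strictly-less on distance, inclusive on angles
    keep <- dist < criteria$max_h_acceptor_distance - 1e-9
    if (!any(keep)) return(NULL)
    grid_d <- grid_d[keep]; grid_a <- grid_a[keep]; dist <- dist[keep]
    D <- xyz[dsub$heavy[grid_d], , drop = FALSE]
    H <- xyz[dsub$hydrogen[grid_d], , drop = FALSE]
    A <- xyz[grid_a, , drop = FALSE]
    ang <- angles_deg(D, H, A)
    keep <- ang >= criteria$angle_min - 1e-9 &
      ang <= criteria$angle_max + 1e-9
    if (!any(keep)) return(NULL)
    grid_d <- grid_d[keep]; grid_a <- grid_a[keep]
    dist <- dist[keep]; ang <- ang[keep]
    hv <- dsub$heavy[grid_d]; hy <- dsub$hydrogen[grid_d]
    partner_idx <- if (direction == "ligand-donates") grid_a else hv
    data.frame(
      donor_serial = atoms$serial[hv], hydrogen_serial = atoms$serial[hy],
      acceptor_serial = atoms$serial[grid_a],
      donor_name = atoms$name[hv], acceptor_name = atoms$name[grid_a],
      donor_res = atoms$resname[hv], acceptor_res = atoms$resname[grid_a],
      donor_resseq = atoms$resseq[hv], acceptor_resseq = atoms$resseq[grid_a],
      h_a_distance = dist, dha_angle = ang,
      partner = ifelse(role[partner_idx] == "water", "water", "amino_acid"),
      direction = direction, stringsAsFactors = FALSE
    )
  }

  don_role <- role[donors$heavy]
  acc_role <- role[acceptors]
  out[[1]] <- pair_block(which(don_role == "ligand"),
                         acceptors[acc_role %in% env_roles],
                         "ligand-donates")
  out[[2]] <- pair_block(which(don_role %in% env_roles),
                         acceptors[acc_role == "ligand"],
                         "ligand-accepts")
  res <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(res) || !nrow(res)) return(empty_hbond_frame())
  if (!include_water) res <- res[res$partner != "water", , drop = FALSE]
  res <- res[order(res$donor_serial, res$acceptor_serial), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Focus specification for the acetyl-oxygen analysis
#'
#' Selects one ligand atom (by atom-name pattern) and the named partner
#' residues/waters of interest; defaults target the 5-acetyl carbonyl
#' oxygen against the catalytic-site glutamine 443 side-chain amide and
#' waters 1 and 13 (the two waters sitting by the Zn and Mg ions).
#'
#' @param ligand_atom regular expression matched against ligand atom
#'   names (default `"^OAC$"`, the generator's acetyl carbonyl oxygen).
#' @param residue_partners list of `c(resname, resseq)` character pairs.
#' @param water_partners integer vector of water residue numbers.
#' @return list of class `dockhb_focus`.
#' @export
focus_spec <- function(ligand_atom = "^OAC$",
                       residue_partners = list(c("GLN", "443")),
                       water_partners = c(1L, 13L)) {
  structure(list(ligand_atom = ligand_atom,
                 residue_partners = residue_partners,
                 water_partners = as.integer(water_partners)),
            class = "dockhb_focus")
}

#' Focused hydrogen-bond survey
#'
#' Restriction of [detect_hbonds()] output to bonds joining the selected
#' ligand atom with the named residue or water partners.
#'
#' @param complex a `dockhb_complex`.
#' @param criteria a [hbond_criteria()].
#' @param spec a [focus_spec()].
#' @param bonds optional precomputed [detect_hbonds()] result to filter
#'   (avoids recomputation inside pose loops).
#' @return data.frame in the [detect_hbonds()] layout.
#' @export
focus_interactions <- function(complex, criteria = hbond_criteria(),
                               spec = focus_spec(), bonds = NULL) {
  atoms <- complex$atoms
  lig_sel <- which(atoms$role == "ligand" & grepl(spec$ligand_atom, atoms$name))
  if (!length(lig_sel))
    stop("focus selector '", spec$ligand_atom,
         "' resolves to no ligand atom in complex '", complex$label, "'")
  lig_serials <- atoms$serial[lig_sel]
  if (is.null(bonds)) bonds <- detect_hbonds(complex, criteria,
                                             include_water = TRUE)
  if (!nrow(bonds)) return(bonds)

  res_keys <- vapply(spec$residue_partners,
                     function(p) paste(toupper(p[1]), as.integer(p[2])), "")
  wat <- spec$water_partners

  lig_is_acc <- bonds$acceptor_serial %in% lig_serials
  lig_is_don <- bonds$donor_serial %in% lig_serials
  partner_res <- ifelse(lig_is_acc, toupper(bonds$donor_res),
                        toupper(bonds$acceptor_res))
  partner_seq <- ifelse(lig_is_acc, bonds$donor_resseq, bonds$acceptor_resseq)
  partner_key <- paste(partner_res, partner_seq)
  keep <- (lig_is_acc | lig_is_don) &
    ((bonds$partner == "amino_acid" & partner_key %in% res_keys) |
       (bonds$partner == "water" & partner_seq %in% wat))
  out <- bonds[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarise hydrogen bonds over the poses of one ligand
#'
#' Computes the two per-ligand parameters of the survey: the number of
#' hydrogen bonds per conformation (pose) and the arithmetic mean of the
#' hydrogen-acceptor distance over all bonds of all poses, plus the same
#' quantities for the focused (acetyl-oxygen) subset.
#'
#' @param per_pose_bonds list (one element per pose) of
#'   [detect_hbonds()] data.frames.
#' @param mode `"vacuum"` or `"with_water"` (carried into the summary).
#' @param per_pose_focus optional list of [focus_interactions()] results.
#' @param ligand_id label for the summary row.
#' @return list of class `dockhb_summary` with fields `ligand_id`,
#'   `n_poses`, `bonds_per_pose`, `mean_h_a_distance`, `mode`,
#'   `focus_bonds_per_pose`, `focus_mean_distance`,
#'   `focus_partner_breakdown` (named tally) and `bonds` (row-bound
#'   detail with a `pose` column).
#' @export
summarize_ligand <- function(per_pose_bonds, mode = "with_water",
                             per_pose_focus = NULL, ligand_id = "ligand") {
  n_poses <- length(per_pose_bonds)
  if (n_poses < 1L) stop("summarize_ligand requires at least one pose")
  mode <- match.arg(mode, c("vacuum", "with_water"))
  all_bonds <- do.call(rbind, Map(function(b, k) {
    if (nrow(b)) cbind(pose = k, b) else NULL
  }, per_pose_bonds, seq_len(n_poses)))
  n_bonds <- if (is.null(all_bonds)) 0L else nrow(all_bonds)
  mean_dist <- if (n_bonds) mean(all_bonds$h_a_distance) else NA_real_

  focus_bpp <- NA_real_
  focus_mean <- NA_real_
  breakdown <- integer(0)
  if (!is.null(per_pose_focus)) {
    fb <- do.call(rbind, per_pose_focus)
    nf <- if (is.null(fb)) 0L else nrow(fb)
    focus_bpp <- nf / n_poses
    focus_mean <- if (nf) mean(fb$h_a_distance) else NA_real_
    if (nf) {
      key <- ifelse(fb$direction == "ligand-accepts",
                    paste0(fb$donor_res, fb$donor_resseq),
                    paste0(fb$acceptor_res, fb$acceptor_resseq))
      breakdown <- table(key)
    }
  }
  structure(list(
    ligand_id = ligand_id, n_poses = n_poses, mode = mode,
    bonds_per_pose = n_bonds / n_poses,
    mean_h_a_distance = mean_dist,
    focus_bonds_per_pose = focus_bpp,
    focus_mean_distance = focus_mean,
    focus_partner_breakdown = breakdown,
    bonds = if (is.null(all_bonds)) cbind(pose = integer(0),
                                          empty_hbond_frame()) else all_bonds
  ), class = "dockhb_summary")
}

#' @export
print.dockhb_summary <- function(x, ...) {
  cat("<dockhb_summary> '", x$ligand_id, "' (", x$mode, "): ",
      format(x$bonds_per_pose, digits = 4), " bonds/pose over ",
      x$n_poses, " poses, mean H...A ",
      format(x$mean_h_a_distance, digits = 4), " A\n", sep = "")
  invisible(x)
}

#' Flatten ligand summaries to the reporting table
#'
#' @param summaries list of `dockhb_summary` objects.
#' @return data.frame with columns `ligand_id`, `mode`, `n_poses`,
#'   `bonds_per_pose`, `mean_distance_A`, `focus_bonds_per_pose`,
#'   `focus_mean_distance_A`.
#' @export
summary_table <- function(summaries) {
  do.call(rbind, lapply(summaries, function(s) data.frame(
    ligand_id = s$ligand_id, mode = s$mode, n_poses = s$n_poses,
    bonds_per_pose = s$bonds_per_pose,
    mean_distance_A = s$mean_h_a_distance,
    focus_bonds_per_pose = s$focus_bonds_per_pose,
    focus_mean_distance_A = s$focus_mean_distance,
    stringsAsFactors = FALSE
  )))
}
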