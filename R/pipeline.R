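# Pipeline: cluster -> survey -> summarize -> class comparison, with a
# TSV report bundle.

#' Pipeline run configuration
#'
#' @param dataset a `dockhb_dataset` from [simulate_class_dataset()];
#'   when `NULL`, `input_dir` must name a directory holding one
#'   `<ligand>_poses.pdb` multi-model file plus `<ligand>_energies.tsv`
#'   per ligand.
#' @param input_dir directory of pose/energy files (ignored when
#'   `dataset` is given).
#' @param criteria a [hbond_criteria()].
#' @param clustering a [clustering_config()].
#' @param focus a [focus_spec()].
#' @param mode `"both"`, `"vacuum"` or `"with_water"`.
#' @param pose_use `"all"` (every pose of the selected clusters; the
#'   default) or `"representatives"` (cluster representatives only).
#' @param class_def a [class_definition()] used when ligand classes are
#'   not carried by the dataset.
#' @param activity optional activity table (data.frame or TSV path) for
#'   class assignment of file-based inputs.
#' @param alpha significance level for the class comparison.
#' @param seed seed recorded in outputs (datasets carry their own).
#' @param outdir output directory for the report bundle; created if
#'   missing.
#' @return list of class `dockhb_config`.
#' @export
run_config <- function(dataset = NULL, input_dir = NULL,
                       criteria = hbond_criteria(),
                       clustering = clustering_config(),
                       focus = focus_spec(),
                       mode = c("both", "vacuum", "with_water"),
                       pose_use = c("all", "representatives"),
                       class_def = class_definition(),
                       activity = NULL,
                       alpha = 0.05, seed = 0L, outdir = NULL) {
  mode <- match.arg(mode)
  pose_use <- match.arg(pose_use)
  if (is.null(dataset) && is.null(input_dir))
    stop("run_config needs either a dataset or an input_dir")
  structure(list(dataset = dataset, input_dir = input_dir,
                 criteria = criteria, clustering = clustering,
                 focus = focus, mode = mode, pose_use = pose_use,
                 class_def = class_def, activity = activity,
                 alpha = alpha, seed = as.integer(seed),
                 outdir = outdir),
            class = "dockhb_config")
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  slim <- config[setdiff(names(config), c("dataset", "outdir"))]
  writeLines(deparse(slim), tmp)
  unname(tools::md5sum(tmp))
}

write_report_tsv <- function(df, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Cluster, select and survey one pose ensemble
#'
#' Runs the clustering stage (greedy energy-seeded, lowest-energy
#' coverage selection), then the hydrogen-bond survey over the retained
#' poses in the requested mode(s).
#'
#' @param ensemble a `dockhb_ensemble`.
#' @param criteria a [hbond_criteria()].
#' @param clustering a [clustering_config()].
#' @param focus a [focus_spec()]; `NULL` skips the focused survey.
#' @param mode `"both"`, `"vacuum"` or `"with_water"`.
#' @param pose_use `"all"` poses of selected clusters or
#'   `"representatives"`.
#' @return list with `clusters`, `selected`, `pose_indices`, and
#'   `summaries` (one `dockhb_summary` per surveyed mode).
#' @export
survey_ensemble <- function(ensemble, criteria = hbond_criteria(),
                            clustering = clustering_config(),
                            focus = focus_spec(),
                            mode = c("both", "vacuum", "with_water"),
                            pose_use = c("all", "representatives")) {
  mode <- match.arg(mode)
  pose_use <- match.arg(pose_use)
  clusters <- cluster_poses(ensemble, clustering)
  selected <- select_covering_clusters(clusters, clustering,
                                       n_total = ensemble$n_poses)
  pose_idx <- if (pose_use == "all")
    sort(unlist(lapply(selected, `[[`, "member_indices")))
  else sort(vapply(selected, `[[`, 0L, "representative_index"))

  modes <- if (mode == "both") c("vacuum", "with_water") else mode
  wet <- vector("list", length(pose_idx))
  for (k in seq_along(pose_idx)) {
    cx <- pose_complex(ensemble, pose_idx[k])
    wet[[k]] <- detect_hbonds(cx, criteria, include_water = TRUE)
  }
  # focus filtering reuses the with-water detection; the selector is
  # resolved once against the topology
  focus_list <- NULL
  if (!is.null(focus)) {
    cx0 <- pose_complex(ensemble, pose_idx[1])
    focus_list <- lapply(wet, function(b)
      focus_interactions(cx0, criteria, focus, bonds = b))
  }
  summaries <- lapply(modes, function(m) {
    per_pose <- if (m == "vacuum")
      lapply(wet, function(b) b[b$partner != "water", , drop = FALSE])
    else wet
    summarize_ligand(per_pose, mode = m,
                     per_pose_focus = if (m == "with_water") focus_list,
                     ligand_id = ensemble$topology$label)
  })
  names(summaries) <- modes
  list(clusters = clusters, selected = selected,
       pose_indices = pose_idx, summaries = summaries)
}

read_input_dir <- function(input_dir) {
  pose_files <- sort(list.files(input_dir, pattern = "_poses\\.pdb$",
                                full.names = TRUE))
  if (!length(pose_files))
    stop("no *_poses.pdb files found in ", input_dir)
  lapply(pose_files, function(pf) {
    id <- sub("_poses\\.pdb$", "", basename(pf))
    ef <- file.path(input_dir, paste0(id, "_energies.tsv"))
    if (!file.exists(ef))
      stop("missing energies file: ", ef)
    list(ligand_id = id, class = NA_character_,
         ensemble = read_ensemble(pf, ef, label = id), truth = NULL)
  })
}

#' Run the full post-docking analysis pipeline
#'
#' Executes cluster -> survey -> summarize -> class comparison over all
#' ligands and writes the report bundle: `summary.tsv` (per ligand and
#' mode), `bonds.tsv` (per-bond detail), `clusters.tsv`,
#' `comparison.tsv` and `run.log`. Every output starts with a comment
#' line naming the configuration hash and seed. Partial outputs are
#' removed if any stage fails.
#'
#' @param config a [run_config()].
#' @return (invisibly) list with `summaries`, `clusters`, `comparisons`,
#'   `tables` and the output paths (when `config$outdir` is set).
#' @export
run_pipeline <- function(config) {
  ligands <- if (!is.null(config$dataset)) config$dataset$ligands
  else read_input_dir(config$input_dir)

  if (all(is.na(vapply(ligands, function(l) l$class, "")))) {
    act <- config$activity
    if (is.character(act)) act <- load_activity_table(act)
    if (!is.null(act)) {
      cls <- assign_modeling_class(act, config$class_def)
      for (k in seq_along(ligands)) {
        m <- match(ligands[[k]]$ligand_id, act$compound_id)
        if (!is.na(m)) ligands[[k]]$class <- cls[m]
      }
    }
  }

  all_sum <- list()
  all_bonds <- list()
  all_clusters <- list()
  for (lg in ligands) {
    sv <- tryCatch(
      survey_ensemble(lg$ensemble, config$criteria, config$clustering,
                      config$focus, config$mode, config$pose_use),
      error = function(e) stop("survey stage failed for ligand '",
                               lg$ligand_id, "': ", conditionMessage(e),
                               call. = FALSE))
    for (s in sv$summaries) {
      all_sum[[length(all_sum) + 1L]] <- s
      if (nrow(s$bonds))
        all_bonds[[length(all_bonds) + 1L]] <-
          cbind(ligand_id = s$ligand_id, mode = s$mode, s$bonds,
                class = lg$class)
    }
    ct <- cluster_table(sv$clusters)
    all_clusters[[length(all_clusters) + 1L]] <-
      cbind(ligand_id = lg$ligand_id, ct,
            selected = seq_len(nrow(ct)) <= length(sv$selected))
  }

  classes <- vapply(ligands, function(l) l$class, "")
  comparisons <- list()
  bonds_df <- if (length(all_bonds)) do.call(rbind, all_bonds) else NULL
  if (any(classes == "A", na.rm = TRUE) &&
      any(classes == "I", na.rm = TRUE) && !is.null(bonds_df)) {
    wb <- bonds_df[bonds_df$mode == "with_water" &
                     bonds_df$partner == "water", , drop = FALSE]
    if (sum(wb$class == "A") >= 2 && sum(wb$class == "I") >= 2)
      comparisons$water_distance <- compare_classes(
        wb$h_a_distance[wb$class == "A"],
        wb$h_a_distance[wb$class == "I"],
        alpha = config$alpha, metric_name = "water_h_a_distance_A")
    # per-pose water-bond counts pooled within class
    count_values <- function(cl) {
      unlist(lapply(ligands[classes == cl], function(lg) {
        s <- Filter(function(x) x$mode == "with_water",
                    all_sum[vapply(all_sum, function(x)
                      x$ligand_id == lg$ligand_id, TRUE)])
        if (!length(s)) return(NULL)
        b <- s[[1]]$bonds
        wat <- b[b$partner == "water", , drop = FALSE]
        tabulate(wat$pose, nbins = s[[1]]$n_poses)
      }))
    }
    ca <- count_values("A"); ci <- count_values("I")
    if (length(ca) >= 2 && length(ci) >= 2)
      comparisons$water_bonds_per_pose <- compare_classes(
        ca, ci, alpha = config$alpha,
        metric_name = "water_bonds_per_pose")
  }

  tables <- list(
    summary = summary_table(all_sum),
    bonds = bonds_df,
    clusters = do.call(rbind, all_clusters),
    comparison = if (length(comparisons)) comparison_table(comparisons)
  )

  paths <- NULL
  if (!is.null(config$outdir)) {
    dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
    hdr <- sprintf("# dockhb config=%s seed=%d", config_hash(config),
                   config$seed)
    paths <- file.path(config$outdir,
                       c("summary.tsv", "bonds.tsv", "clusters.tsv",
                         "comparison.tsv", "run.log"))
    names(paths) <- c("summary", "bonds", "clusters", "comparison", "log")
    ok <- FALSE
    on.exit(if (!ok) unlink(paths))
    write_report_tsv(tables$summary, paths["summary"], hdr)
    write_report_tsv(if (is.null(tables$bonds)) empty_hbond_frame()
                     else tables$bonds, paths["bonds"], hdr)
    write_report_tsv(tables$clusters, paths["clusters"], hdr)
    write_report_tsv(if (is.null(tables$comparison))
      data.frame(metric = character(0)) else tables$comparison,
      paths["comparison"], hdr)
    writeLines(c(hdr,
                 sprintf("ligands: %d", length(ligands)),
                 sprintf("mode: %s", config$mode),
                 sprintf("cutoff_A: %g", config$criteria$max_h_acceptor_distance),
                 sprintf("angle_window_deg: [%g, %g]",
                         config$criteria$angle_min, config$criteria$angle_max),
                 sprintf("rmsd_threshold_A: %g",
                         config$clustering$rmsd_threshold),
                 sprintf("coverage_fraction: %g",
                         config$clustering$coverage_fraction),
                 sprintf("alpha: %g", config$alpha)),
               paths["log"])
    ok <- TRUE
  }
  invisible(list(summaries = all_sum, comparisons = comparisons,
                 tables = tables, paths = paths))
}
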