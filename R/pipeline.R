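## End-to-end orchestration: build structures, run the BD ensemble,
## filter/cluster poses, compute contact statistics and tables, emit a
## reproducible run directory with a manifest.

#' Pipeline configuration
#'
#' Nested configuration for [run_pipeline()], serializable to YAML. All
#' defaults mirror the simulation constants of the protocol: 310.15 K,
#' dielectric 78, relative viscosity 1, 150 mM salt, 1.0/0.01 ps
#' timesteps, reaction at 3 contacts within 7.5 A, 4.5 A salt-bridge
#' cutoff, 45 degree orientation filter, 10 clusters, 10 layers at 4.8 A
#' rise.
#'
#' @param template `"tau"` for the packaged tau-like template, or a list
#'   with `sequence`, `layout`, `start_resno`, `buried`.
#' @param n_layers,rise,twist,n_protofilaments fibril geometry.
#' @param glycan_length,sulfation,repeat_rise glycan chain settings.
#' @param n_trajectories trajectories per (fibril, glycan) pair.
#' @param bd named list overriding [bd_params()] fields
#'   (e.g. `list(max_steps = 2e4, q_radius = 120)`).
#' @param solvent named list overriding [solvent_params()] fields.
#' @param contact_cutoff salt-bridge cutoff, A.
#' @param k_clusters Ward cluster count for bound poses.
#' @param angle_threshold orientation filter, degrees.
#' @param site_groups named list of composite sites.
#' @param analysis_site residue(s) whose bound poses feed the contact
#'   series; `NULL` picks the most populated site.
#' @param density_spacing,density_padding sulfur density grid settings.
#' @param seed base seed of the run.
#' @return object of class `pipeline_config` (a validated nested list).
#' @export
pipeline_config <- function(template = "tau", n_layers = 10L, rise = 4.8,
                            twist = 0, n_protofilaments = 1L,
                            glycan_length = 8L, sulfation = "full",
                            repeat_rise = 8.7,
                            n_trajectories = 1000L, bd = list(),
                            solvent = list(), contact_cutoff = 4.5,
                            k_clusters = 10L, angle_threshold = 45,
                            site_groups = list(), analysis_site = NULL,
                            density_spacing = 1.0, density_padding = 15,
                            seed = 1L) {
  cfg <- list(structure = list(template = template, n_layers = n_layers,
                               rise = rise, twist = twist,
                               n_protofilaments = n_protofilaments,
                               glycan_length = glycan_length,
                               sulfation = sulfation,
                               repeat_rise = repeat_rise),
              bd = c(list(n_trajectories = n_trajectories), bd),
              solvent = solvent,
              analysis = list(contact_cutoff = contact_cutoff,
                              k_clusters = k_clusters,
                              angle_threshold = angle_threshold,
                              site_groups = site_groups,
                              analysis_site = analysis_site),
              density = list(spacing = density_spacing,
                             padding = density_padding),
              seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  .validate_config(cfg)
  cfg
}

.validate_config <- function(cfg) {
  s <- cfg$structure
  stopifnot(s$n_layers >= 3, s$rise > 0, s$glycan_length >= 2,
            s$glycan_length %% 2 == 0,
            s$sulfation %in% c("full", "desulfated_2O", "desulfated_6O"),
            cfg$bd$n_trajectories >= 1,
            cfg$analysis$contact_cutoff > 0,
            cfg$analysis$k_clusters >= 1,
            cfg$analysis$angle_threshold >= 0,
            cfg$density$spacing > 0)
  invisible(cfg)
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file.
#' @return [read_config()] returns a `pipeline_config`;
#'   [write_config()] returns the path invisibly.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- c(raw$structure,
            list(n_trajectories = raw$bd$n_trajectories,
                 bd = raw$bd[setdiff(names(raw$bd), "n_trajectories")],
                 solvent = if (is.null(raw$solvent)) list() else raw$solvent,
                 seed = raw$seed),
            raw$analysis[c("contact_cutoff", "k_clusters",
                           "angle_threshold")],
            list(site_groups = if (is.null(raw$analysis$site_groups))
              list() else raw$analysis$site_groups,
              analysis_site = raw$analysis$analysis_site,
              density_spacing = raw$density$spacing,
              density_padding = raw$density$padding))
  args <- args[!vapply(args, is.null, logical(1)) | names(args) == "analysis_site"]
  do.call(pipeline_config, args)
}

#' @rdname read_config
#' @param cfg a [pipeline_config()].
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

# rolling polynomial fingerprint of the serialized config, for the manifest
.config_hash <- function(cfg) {
  bytes <- utf8ToInt(paste(deparse(unclass(cfg)), collapse = "\n"))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

.build_from_config <- function(cfg) {
  s <- cfg$structure
  tpl <- if (identical(s$template, "tau")) tau_template() else
    build_cross_section(s$template$sequence,
                        layout = s$template$layout,
                        start_resno = if (is.null(s$template$start_resno))
                          1L else s$template$start_resno,
                        buried = if (is.null(s$template$buried))
                          integer() else unlist(s$template$buried))
  fibril <- build_fibril(tpl, n_layers = s$n_layers, rise = s$rise,
                         twist = s$twist,
                         n_protofilaments = s$n_protofilaments)
  glycan <- build_glycan(s$glycan_length, s$sulfation, s$repeat_rise)
  list(fibril = fibril, glycan = glycan)
}

.bd_params_from_config <- function(cfg) {
  solv <- do.call(solvent_params, cfg$solvent)
  over <- cfg$bd[setdiff(names(cfg$bd), "n_trajectories")]
  do.call(bd_params, c(list(solvent = solv, seed = cfg$seed), over))
}

#' Run the full binding-site prediction pipeline
#'
#' Builds the fibril and glycan, runs the BD ensemble, writes the
#' per-site binding table, filters bound poses by the orientation angle,
#' clusters them with medoid selection (refining the medoids by local
#' rigid-body minimization), computes the salt-bridge contact series with
#' medians and the contact frequency map, the energy-per-contact
#' regression, and the sulfur density map. Re-running with the same
#' config and seed reproduces every output byte-for-byte (the log file
#' carries wall times and is excluded from that guarantee).
#'
#' @param config a [pipeline_config()].
#' @param outdir run directory (created if absent).
#' @return invisibly, a list with the in-memory results (`fibril`,
#'   `glycan`, `outcomes`, `table`, `poses`, `clusters`, `series`,
#'   `freq_map`, `regression`, `density`, `manifest`).
#' @export
run_pipeline <- function(config, outdir) {
  .validate_config(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  t_all <- proc.time()[3]
  log_lines <- character()
  note <- function(fmt, ...) {
    log_lines <<- c(log_lines, sprintf(fmt, ...))
  }

  models <- .build_from_config(config)
  fibril <- models$fibril; glycan <- models$glycan
  params <- .bd_params_from_config(config)
  write_pdb(fibril, file.path(outdir, "fibril.pdb"))
  write_pdb(glycan, file.path(outdir, "glycan.pdb"))

  t0 <- proc.time()[3]
  outcomes <- run_ensemble(fibril, glycan, config$bd$n_trajectories,
                           params)
  note("bd ensemble: %d trajectories in %.1f s", nrow(outcomes),
       proc.time()[3] - t0)
  write_outcomes(outcomes, file.path(outdir, "outcomes.tsv"))

  tb <- site_table(outcomes, sites = fibril$site_list,
                   site_groups = config$analysis$site_groups)
  write_site_table(tb, file.path(outdir, "site_table.tsv"))

  # bound poses: orientation filter and clustering at the analysis site
  poses <- attr(outcomes, "poses")
  bound_idx <- which(outcomes$status == "reacted")
  pose_tab <- data.frame(pose = bound_idx,
                         site = outcomes$site[bound_idx],
                         angle = vapply(bound_idx, function(i)
                           orientation_angle(fibril, glycan, poses[[i]]),
                           numeric(1)))
  pose_tab$aligned <- pose_tab$angle <= config$analysis$angle_threshold

  site_res <- config$analysis$analysis_site
  if (is.null(site_res) && nrow(pose_tab))
    site_res <- as.integer(names(which.max(table(pose_tab$site))))
  clusters <- NULL; series <- NULL; fmap <- NULL; reg <- NULL
  med_res <- med_hcg <- NA
  if (!is.null(site_res) && any(pose_tab$site %in% site_res &
                                  pose_tab$aligned)) {
    sel <- pose_tab$pose[pose_tab$site %in% site_res & pose_tab$aligned]
    feats <- t(vapply(sel, function(i)
      pose_features(poses[[i]], fibril, glycan, site_res),
      numeric(nrow(glycan$sulfurs))))
    k <- min(config$analysis$k_clusters, length(sel))
    clusters <- ward_cluster(feats, k)
    pose_tab$cluster <- NA_integer_
    pose_tab$cluster[match(sel, pose_tab$pose)] <- clusters$labels
    pose_tab$is_medoid <- pose_tab$pose %in% sel[clusters$medoid_indices]

    # refined medoids as the frame ensemble for contact statistics
    solv <- params$solvent
    refined <- lapply(sel[clusters$medoid_indices], function(i)
      refine_pose(fibril, glycan, poses[[i]], solv)$pose)
    cp <- contact_params(config$analysis$contact_cutoff)
    frames <- lapply(c(refined, poses[sel]), detect_contacts,
                     fibril = fibril, glycan = glycan, params = cp)
    series <- contact_series(frames)
    med_res <- median_bound(series, "residues", sites = site_res)$median
    med_hcg <- median_bound(series, "hcgs", sites = site_res)$median
    fmap <- frequency_map(series, glycan, fibril)
    write.table(cbind(unit_group = rownames(fmap),
                      as.data.frame(unclass(fmap))),
                file.path(outdir, "frequency_map.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write_contact_series(series, file.path(outdir, "contacts.tsv"))
    # medoid poses for downstream refinement
    for (j in seq_along(refined))
      write_pdb(glycan, file.path(outdir, sprintf("medoid_%02d.pdb", j)),
                pose = refined[[j]])

    # energy vs contact count over the bound, aligned poses
    counts <- vapply(poses[sel], function(p)
      nrow(detect_contacts(p, fibril, glycan, cp)), integer(1))
    energies <- vapply(poses[sel], function(p)
      interaction_energy(fibril, glycan, p, solv), numeric(1))
    if (length(counts) >= 3 && length(unique(counts)) >= 2)
      reg <- energy_per_contact(counts, energies)
  }
  if (nrow(pose_tab) && is.null(pose_tab$cluster)) {
    pose_tab$cluster <- NA_integer_; pose_tab$is_medoid <- FALSE
  }
  write.table(pose_tab, file.path(outdir, "pose_table.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  dens <- accumulate_density(outcomes, glycan,
                             density_grid_for(fibril,
                                              config$density$spacing,
                                              config$density$padding))
  write_dx(dens, file.path(outdir, "sulfur_density.dx"))

  manifest <- list(
    package_version = as.character(packageVersion("fibrilBD")),
    config = unclass(config), config_hash = .config_hash(config),
    seed = config$seed,
    n_trajectories = nrow(outcomes),
    n_reacted = sum(outcomes$status == "reacted"),
    n_escaped = sum(outcomes$status == "escaped"),
    n_max_steps = sum(outcomes$status == "max_steps"),
    analysis_site = site_res,
    median_residues_bound = med_res, median_hcgs_bound = med_hcg,
    energy_per_contact = if (is.null(reg)) NULL else
      list(slope = reg$slope, slope_se = reg$slope_se),
    density_counts = sum(dens$counts), density_overflow = dens$overflow,
    status = "ok")
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  note("pipeline total: %.1f s", proc.time()[3] - t_all)
  writeLines(log_lines, file.path(outdir, "log.txt"))

  invisible(list(fibril = fibril, glycan = glycan, outcomes = outcomes,
                 table = tb, poses = pose_tab, clusters = clusters,
                 series = series, freq_map = fmap, regression = reg,
                 density = dens, manifest = manifest))
}
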