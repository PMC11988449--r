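#' Pipeline configuration with frozen presets
#'
#' Two presets separate fidelity from testability. `"paper"` freezes the
#' full-scale study conditions of the workflow (30 generations x 25
#' simulations x 40 ns of adaptive sampling; 1000 microstates; MSM lag
#' 5 ns; tICA lag 1 ns with 4 retained components; top 100 reweighted
#' poses clustered at 2.5 Angstrom to 20 representatives; 3 replicates x
#' 2 force-field conditions of 150 ns; 15 Angstrom / 5-of-6 stability
#' rule; 4 Angstrom / 50% contacts; 2.0 / 1.5 Angstrom accessibility
#' thresholds). `"toy"` scales every stage to seconds on the synthetic
#' system while keeping the identical structure. Any field can be
#' overridden. The config round-trips losslessly through JSON.
#'
#' @param preset `"toy"` or `"paper"`.
#' @param seed global root seed; every stage derives a named child seed
#'   from it.
#' @param ... named overrides of top-level config blocks (lists are
#'   merged shallowly).
#' @return object of class `pipeline_config` (a named list).
#' @export
pipeline_config <- function(preset = c("toy", "paper"), seed = 1L, ...) {
  preset <- match.arg(preset)
  cfg <- if (preset == "paper") list(
    preset = "paper", mode = "external-data", seed = as.integer(seed),
    stages = c("sampling", "featurize", "msm", "reweight", "cluster",
               "screen", "access", "report"),
    fast = list(n_generations = 30, sims_per_generation = 25,
                sim_length_ns = 40, alpha = 1),
    msm = list(n_microstates = 1000, lag_ns = 5, tica_lag_ns = 1,
               n_tics = 4),
    reweight = list(kT = 0.596, top_k = 100,
                    mode = "effective-free-energy"),
    cluster = list(cutoff = 2.5, n_representatives = 20),
    screen = list(n_replicates = 3, conditions = c("ff1", "ff2"),
                  length_ns = 150, threshold = 15, min_pass = 5),
    contact = list(cutoff = 4.0, threshold = 0.5),
    access = list(open = 2.0, buried = 1.5, spacing = 0.5)
  ) else list(
    preset = "toy", mode = "toy", seed = as.integer(seed),
    stages = c("sampling", "featurize", "msm", "reweight", "cluster",
               "screen", "access", "report"),
    fast = list(n_generations = 8, sims_per_generation = 5,
                sim_length = 400, alpha = 1, radius = 0.4, stride = 10),
    toy = list(base_distance = 4, timestep = 0.01, kT = 1),
    receptor = list(open_radius = 3.0, buried_radius = 1.2,
                    shell_radius = 8, separation = 28),
    msm = list(n_microstates = 25, lag = 2, tica_lag = 1, n_tics = 2),
    surrogate = list(g0 = -4, slope = 1.5, noise_sd = 0.3),
    reweight = list(kT = 0.596, top_k = 40,
                    mode = "effective-free-energy"),
    cluster = list(cutoff = 2.5, n_representatives = 20),
    screen = list(n_replicates = 3, conditions = c("ff1", "ff2"),
                  length = 200, threshold = 15, min_pass = 5),
    contact = list(cutoff = 4.0, threshold = 0.5),
    access = list(open = 2.0, buried = 1.5, spacing = 0.5)
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(dots[[nm]]) && is.list(cfg[[nm]]))
      cfg[[nm]] <- utils::modifyList(cfg[[nm]], dots[[nm]])
    else cfg[[nm]] <- dots[[nm]]
  }
  structure(cfg, class = "pipeline_config")
}

#' Total adaptive-sampling simulation time of a configuration
#'
#' Generations x simulations-per-generation x simulation length. For the
#' full-scale preset this is 30 x 25 x 40 ns = 30 microseconds.
#'
#' @param config a [pipeline_config()].
#' @return list `total_ns`, `total_us`.
#' @export
total_sampling <- function(config) {
  f <- config$fast
  len_ns <- f$sim_length_ns %||% f$sim_length
  total <- f$n_generations * f$sims_per_generation * len_ns
  list(total_ns = total, total_us = total / 1000)
}

#' Run the end-to-end discovery pipeline on the synthetic system
#'
#' Executes sampling -> featurize -> msm -> reweight -> cluster -> screen
#' -> access -> report in order on the toy system: Brownian dynamics on
#' the three-basin pocket-opening landscape under the reward-driven
#' controller, pentamer-bead featurization, MSM estimation, surrogate
#' docking scores reweighted by the stationary distribution, pose
#' clustering, replicate stability screening against the planted
#' two-site sphere receptor, and tunnel-accessibility classification of
#' the surviving sites. Artifacts and a manifest (stage counts, seeds,
#' parameter hash, file hashes) are written under `dir`. Reruns with the
#' same config and seed are bit-identical.
#'
#' Stage dependencies are enforced: disabling a stage that a later
#' enabled stage needs is an error.
#'
#' @param config a [pipeline_config()] (toy mode).
#' @param dir run directory (created).
#' @return object of class `pipeline_run`: the manifest, stage results
#'   and `dir`, invisibly returned by its artifacts on disk.
#' @export
run_pipeline <- function(config = pipeline_config(), dir = tempfile("run")) {
  if (!inherits(config, "pipeline_config")) stopf("invalid config")
  stages <- config$stages
  deps <- list(featurize = "sampling", msm = "featurize",
               reweight = "msm", cluster = "reweight",
               screen = "cluster", access = "screen", report = "access")
  for (st in stages) for (d in deps[[st]]) if (!(d %in% stages))
    stopf("stage '%s' requires stage '%s', which is disabled", st, d)
  if (config$mode != "toy")
    stopf(paste("run_pipeline executes the bundled synthetic system",
                "(mode 'toy'); external data flows through the stage",
                "functions directly"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  res <- list(config = config, dir = dir)

  # --- sampling: reward-driven adaptive sampling on the toy landscape
  pot <- three_well_potential()
  fcfg <- fast_config(n_generations = config$fast$n_generations,
                      sims_per_generation = config$fast$sims_per_generation,
                      sim_length = config$fast$sim_length,
                      alpha = config$fast$alpha,
                      radius = config$fast$radius,
                      stride = config$fast$stride,
                      seed = child_seed(seed, "sampling"))
  archive <- run_fast(toy_engine(pot, config$toy$timestep, config$toy$kT),
                      fcfg, init = pot$centers[1, ],
                      featurize_fn = toy_featurize_fn(config$toy$base_distance))
  res$archive <- archive
  write.csv(archive$log, file.path(dir, "sampling_log.csv"),
            row.names = FALSE)

  # --- featurize: pentamer-bead embedding, nearest-atom loop-wall pairs
  ens <- toy_embed(archive$frames, base_distance = config$toy$base_distance)
  feats <- pairwise_distance_features(ens, list(loop = 101, wall = 1))
  res$features <- feats
  write_feature_csv(feats, file.path(dir, "features.csv"))

  # --- msm
  disc <- kmeans_discretize(feats, k = config$msm$n_microstates,
                            seed = child_seed(seed, "msm"))
  traj_id <- interaction(archive$provenance$generation,
                         archive$provenance$sim, drop = TRUE)
  labels <- split(disc$labels, traj_id)
  model <- build_msm(labels, tau = config$msm$lag, n_states = disc$k)
  res$discretization <- disc
  res$model <- model
  jsonlite::write_json(list(T = model$T, pi = model$pi,
                            active_set = model$active_set,
                            lag = model$lag,
                            centers = disc$centers),
                       file.path(dir, "msm.json"), digits = NA,
                       matrix = "rowmajor")

  # --- reweight: surrogate docking scores, Boltzmann reweighting
  openness <- directed_metric(feats) - config$toy$base_distance
  smod <- surrogate_score_model(g0 = config$surrogate$g0,
                                slope = config$surrogate$slope,
                                noise_sd = config$surrogate$noise_sd,
                                seed = child_seed(seed, "scores"))
  scores <- surrogate_scores(openness, smod)
  poses <- data.frame(conformation = scores$conformation,
                      state = disc$labels, score = scores$score)
  rcfg <- reweight_config(kT = config$reweight$kT,
                          mode = config$reweight$mode,
                          top_k = config$reweight$top_k)
  ranked <- reweight_poses(poses, model, rcfg)
  top <- select_top(ranked, rcfg$top_k)
  res$ranked <- ranked
  res$top <- top
  write.csv(as.data.frame(top), file.path(dir, "ranked_poses.csv"),
            row.names = FALSE)

  # --- receptor with planted open and buried sites; pose coordinates
  rc <- config$receptor
  half <- rc$separation / 2
  receptor <- build_sphere_receptor(list(
    list(center = c(-half, 0, 0), channel_radius = rc$open_radius,
         direction = c(-1, 0, 0)),
    list(center = c(half, 0, 0), channel_radius = rc$buried_radius,
         direction = c(1, 0, 0))),
    shell_radius = rc$shell_radius,
    seed = child_seed(seed, "receptor"))
  write_receptor_pdb(receptor, file.path(dir, "receptor.pdb"))
  write_ground_truth_json(receptor, file.path(dir, "receptor_truth.json"))
  res$receptor <- receptor
  # binding-mode assignment: the most-open half of the top conformations
  # docks into the open site, the rest into the buried cavity
  site_of <- ifelse(top$score <= stats::median(top$score), 1L, 2L)
  centers <- as.matrix(receptor$sites[, c("cx", "cy", "cz")])
  jit <- with_seed(child_seed(seed, "poses"),
                   matrix(rnorm(3 * nrow(top), 0, 0.4), ncol = 3))
  pose_coords <- lapply(seq_len(nrow(top)), function(i)
    matrix(centers[site_of[i], ] + jit[i, ], 1, 3))
  res$pose_site <- site_of

  # --- cluster
  clusters <- cluster_poses(pose_coords, cutoff = config$cluster$cutoff,
                            ids = top$conformation)
  reps <- representative_poses(clusters, config$cluster$n_representatives)
  rep_rows <- match(reps, top$conformation)
  res$clusters <- clusters
  res$representatives <- reps
  jsonlite::write_json(
    lapply(clusters$clusters, function(cl)
      list(representative = cl$representative, size = cl$size,
           members = cl$members)),
    file.path(dir, "pose_clusters.json"), auto_unbox = TRUE, digits = NA)

  # --- screen: replicate ligand traces per representative pose
  scfg <- config$screen
  plan <- plan_screen(length(reps), scfg$n_replicates, scfg$conditions,
                      scfg$length, seed = child_seed(seed, "screen"))
  verdicts <- lapply(seq_along(reps), function(p) {
    jobs <- plan[plan$pose == p, ]
    traces <- lapply(jobs$seed, function(sd)
      simulate_ligand_trace(scfg$length, stable = TRUE, seed = sd))
    stability_filter(traces, scfg$threshold, scfg$min_pass)
  })
  stable <- vapply(verdicts, `[[`, logical(1), "pass")
  res$plan <- plan
  res$verdicts <- verdicts
  verdict_df <- data.frame(
    pose = seq_along(reps), representative = reps,
    site = site_of[rep_rows],
    n_pass = vapply(verdicts, function(v) sum(v$replicate_pass), 1),
    stable = stable)
  write.csv(verdict_df, file.path(dir, "stability_verdicts.csv"),
            row.names = FALSE)

  # --- access: tunnel bottleneck from each surviving pose's ligand COM
  acfg <- accessibility_config(config$access$open, config$access$buried)
  grid <- build_grid(receptor, spacing = config$access$spacing)
  access_rows <- lapply(which(stable), function(p) {
    com <- colMeans(pose_coords[[rep_rows[p]]])
    cls <- classify_site(find_tunnels(grid, com, acfg), acfg)
    data.frame(pose = p, site = site_of[rep_rows[p]],
               bottleneck = cls$bottleneck, label = cls$label)
  })
  access_df <- do.call(rbind, access_rows)
  res$access <- access_df
  write.csv(access_df, file.path(dir, "accessibility.csv"),
            row.names = FALSE)

  # --- report: the pipeline funnel
  funnel <- data.frame(
    stage = c("conformations", "poses", "top_k", "clusters",
              "representatives", "stable", "accessible"),
    count = c(nrow(archive$frames), nrow(ranked), nrow(top),
              length(clusters$clusters), length(reps), sum(stable),
              sum(access_df$label == "open")))
  res$funnel <- funnel
  write.csv(funnel, file.path(dir, "funnel.csv"), row.names = FALSE)

  manifest <- list(
    package_version = as.character(utils::packageVersion("crypticsite")),
    seed = seed, preset = config$preset,
    parameter_hash = config_hash(config),
    stages = stages, funnel = funnel,
    artifact_md5 = as.list(tools::md5sum(
      sort(list.files(dir, full.names = TRUE), method = "radix"))))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  res$manifest <- manifest
  class(res) <- "pipeline_run"
  res
}

config_hash <- function(config) {
  js <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  tf <- tempfile(); writeLines(js, tf); on.exit(unlink(tf))
  unname(tools::md5sum(tf))
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("pipeline_run:", x$dir, "\n")
  print(x$funnel, row.names = FALSE)
  invisible(x)
}

#' Summarize a completed pipeline run directory
#'
#' Recounts the funnel from the stage artifacts on disk (independent of
#' the in-memory results) and reports the per-site verdicts. Incomplete
#' runs yield a flagged partial report.
#'
#' @param dir run directory produced by [run_pipeline()].
#' @return object of class `pipeline_report`: `funnel` (recounted),
#'   `accessibility`, `stability`, `complete`.
#' @export
pipeline_report <- function(dir) {
  if (!dir.exists(dir)) stopf("run directory '%s' does not exist", dir)
  need <- c("features.csv", "ranked_poses.csv", "pose_clusters.json",
            "stability_verdicts.csv", "accessibility.csv", "funnel.csv")
  have <- file.exists(file.path(dir, need))
  if (!any(have)) stopf("'%s' contains no pipeline artifacts", dir)
  complete <- all(have)
  feats <- if (have[1]) read.csv(file.path(dir, "features.csv")) else NULL
  ranked <- if (have[2]) read.csv(file.path(dir, "ranked_poses.csv")) else NULL
  clus <- if (have[3])
    jsonlite::read_json(file.path(dir, "pose_clusters.json")) else NULL
  verd <- if (have[4])
    read.csv(file.path(dir, "stability_verdicts.csv")) else NULL
  acc <- if (have[5]) read.csv(file.path(dir, "accessibility.csv")) else NULL
  funnel <- data.frame(
    stage = c("conformations", "top_k", "clusters", "representatives",
              "stable", "accessible"),
    count = c(if (is.null(feats)) NA else nrow(feats),
              if (is.null(ranked)) NA else nrow(ranked),
              if (is.null(clus)) NA else length(clus),
              if (is.null(verd)) NA else nrow(verd),
              if (is.null(verd)) NA else sum(verd$stable),
              if (is.null(acc)) NA else sum(acc$label == "open")))
  structure(list(funnel = funnel, accessibility = acc, stability = verd,
                 complete = complete, dir = dir),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("pipeline_report: %s%s\n", x$dir,
              if (x$complete) "" else "  [PARTIAL]"))
  print(x$funnel, row.names = FALSE)
  if (!is.null(x$accessibility)) {
    cat("site verdicts:\n")
    print(x$accessibility, row.names = FALSE)
  }
  invisible(x)
}
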