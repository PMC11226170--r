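# Orchestration: configuration, the shared data container, staged execution.

#' Default pipeline configuration
#'
#' Bundles the settings of every stage: feature windows for the sample type,
#' reconstruction, NMF, clustering and MFA parameters, and the simulation
#' phantom used when no measured data are supplied.
#'
#' @param sample_type `"bamboo"` or `"rice"`; selects the feature windows and
#'   whether starch maps are produced.
#' @param seed global RNG seed.
#' @param ... named overrides of any default listed below (see the returned
#'   list for the full set).
#' @return object of class `pipeline_config` (a nested list).
#' @export
pipeline_config <- function(sample_type = c("rice", "bamboo"), seed = 0, ...) {
  sample_type <- match.arg(sample_type)
  cfg <- list(
    sample_type = sample_type,
    seed = seed,
    windows = feature_windows(sample_type),
    phantom = list(n_voxels = 48, voxel_size = 5, outer_radius = 105,
                   wall_thickness = 55,
                   starch_gradient = if (sample_type == "rice") 1 else 0,
                   mfa_outer = 5, mfa_inner = 30),
    scan = list(angle_step = 3, q_step = 0.02, phi_step = 3,
                photon_scale = 0, ordering = "interleaved", n_groups = 8,
                damage_rate = 0),
    recon = list(algorithm = "mlem", n_iter = 100),
    nmf = list(k = if (sample_type == "rice") 3 else 2, max_iter = 500,
               tol = 1e-5),
    cluster = list(n_clusters = 3, n_init = 10, min_total = 0.05),
    mfa = list(peak_window = c(1.55, 1.65), baseline_window = c(1.8, 1.9),
               lambda1 = 0.01, lambda2 = 0.1, min_frac = 0.05),
    ci = list(min_frac = 0.05)
  )
  dots <- list(...)
  for (nm in names(dots)) cfg[[nm]] <- utils::modifyList(
    cfg[[nm]] %||% list(), if (is.list(dots[[nm]])) dots[[nm]] else
      stats::setNames(list(dots[[nm]]), nm)[[1]])
  structure(cfg, class = "pipeline_config")
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config a [pipeline_config()].
#' @param path file path.
#' @return `path` (write) or a `pipeline_config` (read).
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- pipeline_config(sample_type = cfg$sample_type %||% "rice",
                          seed = cfg$seed %||% 0)
  for (nm in names(cfg)) {
    base[[nm]] <- if (is.list(base[[nm]]) && is.list(cfg[[nm]]))
      utils::modifyList(base[[nm]], cfg[[nm]]) else cfg[[nm]]
  }
  # YAML round-trips numeric pairs as lists; flatten windows back to vectors
  base$windows <- lapply(base$windows, function(w) as.numeric(unlist(w)))
  for (nm in c("peak_window", "baseline_window"))
    base$mfa[[nm]] <- as.numeric(unlist(base$mfa[[nm]]))
  structure(base, class = "pipeline_config")
}

#' Open (or create) a scan container
#'
#' The shared dataset store of one tomography run: a directory holding one
#' serialized object per dataset under hierarchical names (`frames/scan`,
#' `sinograms/<feature>`, `tomograms/<feature>`, `nmf/...`, `cluster/...`,
#' `mfa/...`) plus a YAML manifest with provenance (stage, seed, config
#' hash). Any 2-D map can be exported as CSV with [export_csv()].
#'
#' @param path directory path (created if absent).
#' @return object of class `scan_container`.
#' @export
open_container <- function(path) {
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  structure(list(path = path), class = "scan_container")
}

.slot_path <- function(container, name)
  file.path(container$path, paste0(gsub("/", "__", name), ".rds"))

#' Store / fetch / list datasets in a container
#'
#' @param container a [open_container()] result.
#' @param name hierarchical dataset name, e.g. `"tomograms/cellulose"`.
#' @param value object to store.
#' @param provenance named list recorded in the manifest (stage, seed,
#'   config hash...).
#' @return `container_put` the container (invisibly); `container_get` the
#'   stored object (error if absent); `container_has` a logical;
#'   `container_ls` a character vector of names.
#' @export
container_put <- function(container, name, value, provenance = list()) {
  saveRDS(value, .slot_path(container, name))
  man_path <- file.path(container$path, "manifest.yaml")
  man <- if (file.exists(man_path)) yaml::read_yaml(man_path) else list()
  man[[name]] <- c(list(written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
                   provenance)
  yaml::write_yaml(man, man_path)
  invisible(container)
}

#' @rdname container_put
#' @export
container_get <- function(container, name) {
  p <- .slot_path(container, name)
  if (!file.exists(p))
    abort2(sprintf("dataset '%s' not found in container", name),
           "scatomo_missing_data")
  readRDS(p)
}

#' @rdname container_put
#' @export
container_has <- function(container, name)
  file.exists(.slot_path(container, name))

#' @rdname container_put
#' @export
container_ls <- function(container) {
  f <- list.files(container$path, pattern = "\\.rds$")
  gsub("__", "/", sub("\\.rds$", "", f))
}

#' Export a map (tomogram, sinogram or matrix) as CSV
#'
#' @param x a [tomogram()], [sinogram()] or plain matrix.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
export_csv <- function(x, path) {
  m <- if (inherits(x, c("tomogram", "sinogram"))) x$values else as.matrix(x)
  utils::write.table(m, path, sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

.provenance <- function(stage, config) {
  list(stage = stage, seed = config$seed,
       config_hash = rlang::hash(unclass(config)),
       package_version = as.character(utils::packageVersion("scatomo")))
}

.require_upstream <- function(container, name, stage_needed) {
  if (!container_has(container, name))
    abort2(sprintf("dataset '%s' missing; run stage '%s' first",
                   name, stage_needed), "scatomo_missing_data")
}

#' Run one stage of the analysis pipeline
#'
#' Stages: `simulate` (phantom scan into the container), `reduce`
#' (absorption sinogram + per-frame profiles), `maps` (feature sinograms +
#' tomograms + CI), `recon` is folded into `maps`, `nmf` (decomposition and
#' component tomograms), `cluster` (composition segmentation), `mfa`
#' (projection-averaged profile, per-phi stack, phi_a map), and `report`
#' (summary statistics of everything present). Each stage is deterministic
#' given identical inputs and config; outputs carry provenance (stage, seed,
#' config hash, package version) in the container manifest.
#'
#' @param stage one of `"simulate"`, `"reduce"`, `"maps"`, `"nmf"`,
#'   `"cluster"`, `"mfa"`, `"report"`, or `"all"`.
#' @param config a [pipeline_config()].
#' @param container a [open_container()] result.
#' @return the container, invisibly (the `report` stage returns its summary
#'   list).
#' @export
run_stage <- function(stage, config, container) {
  stopifnot(inherits(config, "pipeline_config"),
            inherits(container, "scan_container"))
  stages <- c("simulate", "reduce", "maps", "nmf", "cluster", "mfa", "report")
  stage <- match.arg(stage, c(stages, "all"))
  if (stage == "all") {
    for (s in stages[-length(stages)]) run_stage(s, config, container)
    return(run_stage("report", config, container))
  }
  prov <- .provenance(stage, config)
  switch(stage,
    simulate = {
      ph <- config$phantom
      phantom <- make_ring_phantom(
        n_voxels = ph$n_voxels, voxel_size = ph$voxel_size,
        outer_radius = ph$outer_radius, wall_thickness = ph$wall_thickness,
        starch_gradient = ph$starch_gradient,
        mfa_outer = ph$mfa_outer, mfa_inner = ph$mfa_inner)
      comps <- build_component_library(seq(0.04, 2.0, by = config$scan$q_step))
      if (config$sample_type == "bamboo") comps$starch <- NULL
      acq <- acquisition_config(
        angles = seq(0, 180, by = config$scan$angle_step),
        photon_scale = config$scan$photon_scale, seed = config$seed,
        ordering = config$scan$ordering, n_groups = config$scan$n_groups,
        damage_rate = config$scan$damage_rate)
      scan <- simulate_scan(phantom, comps, acq,
                            phi_grid = seq(-90, 90, by = config$scan$phi_step))
      container_put(container, "frames/scan", scan, prov)
      container_put(container, "truth/phantom", phantom, prov)
    },
    reduce = {
      .require_upstream(container, "frames/scan", "simulate")
      scan <- container_get(container, "frames/scan")
      container_put(container, "sinograms/absorption",
                    absorption_sinogram(scan), prov)
      container_put(container, "frames/corrected", correct_scan(scan), prov)
    },
    maps = {
      .require_upstream(container, "frames/corrected", "reduce")
      .require_upstream(container, "sinograms/absorption", "reduce")
      scan <- container_get(container, "frames/corrected")
      abs_sino <- container_get(container, "sinograms/absorption")
      center <- find_center(abs_sino)
      container_put(container, "recon/center", center, prov)
      wins <- config$windows
      tomos <- list()
      for (nm in names(wins)) {
        mode <- if (grepl("^starch", nm)) "baseline_subtracted" else "direct"
        sino <- build_sinogram(scan, wins[[nm]], mode = mode, feature = nm)
        container_put(container, paste0("sinograms/", nm), sino, prov)
        tomo <- iterative_recon(sino, algorithm = config$recon$algorithm,
                                n_iter = config$recon$n_iter, center = center)
        tomo <- normalize_tomogram(tomo, sino)
        tomos[[nm]] <- tomo
        container_put(container, paste0("tomograms/", nm), tomo, prov)
      }
      ci <- segal_ci(tomos$cellulose, tomos$amorphous,
                     width_cell = diff(wins$cellulose),
                     width_amorph = diff(wins$amorphous),
                     min_frac = config$ci$min_frac)
      container_put(container, "tomograms/ci", ci, prov)
    },
    nmf = {
      .require_upstream(container, "frames/corrected", "reduce")
      scan <- container_get(container, "frames/corrected")
      dec <- decompose_scan(scan, k = config$nmf$k,
                            recon_algorithm = "fbp",
                            seed = config$seed,
                            max_iter = config$nmf$max_iter,
                            tol = config$nmf$tol)
      container_put(container, "nmf/decomposition", dec, prov)
    },
    cluster = {
      .require_upstream(container, "nmf/decomposition", "nmf")
      dec <- container_get(container, "nmf/decomposition")
      comp <- normalize_composition(dec, min_total = config$cluster$min_total)
      seg <- kmeans_segment(comp, n_clusters = config$cluster$n_clusters,
                            seed = config$seed,
                            n_init = config$cluster$n_init)
      container_put(container, "cluster/result", seg, prov)
      container_put(container, "cluster/profiles",
                    cluster_profiles(seg, dec$basis, dec$shape), prov)
    },
    mfa = {
      .require_upstream(container, "frames/corrected", "reduce")
      scan <- container_get(container, "frames/corrected")
      prof <- projection_averaged_profile(scan, config$mfa$peak_window,
                                          config$mfa$baseline_window)
      container_put(container, "mfa/profile", prof, prov)
      basis <- build_mfa_basis(scan$phi_grid)
      container_put(container, "mfa/distribution",
                    nnls_regularized(basis, prof$intensity,
                                     config$mfa$lambda1, config$mfa$lambda2),
                    prov)
      center <- if (container_has(container, "recon/center"))
        container_get(container, "recon/center") else NULL
      stack <- per_phi_tomograms(scan, config$mfa$peak_window,
                                 config$mfa$baseline_window,
                                 algorithm = "fbp", center = center)
      container_put(container, "mfa/phi_stack", stack, prov)
      basis2 <- build_mfa_basis(stack$phi_grid)
      mm <- mfa_maps(stack, basis2, config$mfa$lambda1, config$mfa$lambda2,
                     min_frac = config$mfa$min_frac, distributions = FALSE)
      container_put(container, "mfa/phi_a_map", mm$phi_a, prov)
    },
    report = {
      rep <- list()
      if (container_has(container, "tomograms/ci")) {
        ci <- container_get(container, "tomograms/ci")$values
        rep$ci <- list(mean = mean(ci, na.rm = TRUE),
                       sd = sd(ci, na.rm = TRUE),
                       n_voxels = sum(!is.na(ci)))
      }
      if (container_has(container, "nmf/decomposition")) {
        dec <- container_get(container, "nmf/decomposition")
        rep$nmf <- list(k = dec$k, residual = dec$basis$residual)
      }
      if (container_has(container, "cluster/result")) {
        seg <- container_get(container, "cluster/result")
        rep$cluster <- list(n_clusters = seg$n_clusters,
                            inertia = seg$inertia, sizes = seg$sizes)
      }
      if (container_has(container, "mfa/phi_a_map")) {
        pa <- container_get(container, "mfa/phi_a_map")$values
        rep$mfa <- list(phi_a_mean = mean(pa, na.rm = TRUE),
                        phi_a_sd = sd(pa, na.rm = TRUE))
      }
      damage <- list()
      for (nm in container_ls(container)) {
        if (startsWith(nm, "sinograms/"))
          damage[[sub("sinograms/", "", nm)]] <-
            damage_score(container_get(container, nm))
      }
      rep$damage_scores <- damage
      container_put(container, "report/summary", rep, prov)
      return(rep)
    }
  )
  invisible(container)
}
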