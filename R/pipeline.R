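default_config <- function() {
  list(
    out_dir = "seedrsfc_run",
    cohort = list(n_relapse = 24, n_nonrelapse = 21, n_control = 22,
                  grid_dims = c(24, 24, 18), voxel_size = c(3.25, 3.25, 3),
                  n_volumes = 212, tr = 1.7),
    filter = list(f_lo = 0.01, f_hi = 0.1),
    smoothing_fwhm = 6,
    seeds = c("L_CMA", "R_CMA", "L_BLA", "R_BLA"),
    inference = list(voxel_p = 0.005, cluster_alpha = 0.05,
                     n_iterations = 1000, connectivity = 26,
                     onesample_voxel_p = 0.001),
    classifier = list(
      cutoff = 0.5,
      circuits = list(list(name = "cma_vmpfc", seed = "L_CMA"),
                      list(name = "bla_visual", seed = "R_BLA")),
      models = list(
        list(name = "m1_smoking", covariates = "years_smoking"),
        list(name = "m2_education", covariates = "years_education"),
        list(name = "m3_cma", circuits = "cma_vmpfc"),
        list(name = "m4_bla", circuits = "bla_visual"),
        list(name = "m5_rsfc", circuits = c("cma_vmpfc", "bla_visual")),
        list(name = "m6_rsfc_edu", circuits = c("cma_vmpfc", "bla_visual"),
             covariates = "years_education"),
        list(name = "m7_rsfc_edu_smk", circuits = c("cma_vmpfc", "bla_visual"),
             covariates = c("years_education", "years_smoking")))),
    seed = 1)
}

#' Validate a pipeline configuration
#'
#' Reads a YAML file (or takes a list), injects defaults for every missing
#' field (0.01-0.1 Hz band, 6 mm smoothing, voxel p = 0.005, cluster alpha =
#' 0.05, cutoff 0.5), and reports every problem found with its field path.
#'
#' @param config path to a YAML file, or a (possibly partial) config list.
#' @return validated `run_config` list.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config)) config <- list()
  def <- default_config()
  unknown <- setdiff(names(config), names(def))
  problems <- character(0)
  if (length(unknown))
    problems <- c(problems, paste0("unknown key(s): ",
                                   paste(unknown, collapse = ", ")))
  cfg <- modifyList(def, config[intersect(names(config), names(def))])
  # positional (unnamed) lists are replaced wholesale, not merged
  if (!is.null(config$classifier$models))
    cfg$classifier$models <- config$classifier$models
  if (!is.null(config$classifier$circuits))
    cfg$classifier$circuits <- config$classifier$circuits
  for (sub in c("cohort", "filter", "inference", "classifier")) {
    bad <- setdiff(names(cfg[[sub]]), names(def[[sub]]))
    if (length(bad))
      problems <- c(problems, paste0(sub, ": unknown key(s): ",
                                     paste(bad, collapse = ", ")))
  }
  f <- cfg$filter
  nyq <- 1 / (2 * cfg$cohort$tr)
  if (!(f$f_lo >= 0 && f$f_lo < f$f_hi && f$f_hi <= nyq))
    problems <- c(problems, sprintf(
      "filter: need 0 <= f_lo < f_hi <= Nyquist (%.4f), got [%g, %g]",
      nyq, f$f_lo, f$f_hi))
  if (cfg$smoothing_fwhm < 0)
    problems <- c(problems, "smoothing_fwhm: must be >= 0")
  inf <- cfg$inference
  if (!(inf$voxel_p > 0 && inf$voxel_p < 1))
    problems <- c(problems, "inference.voxel_p: must lie in (0,1)")
  if (!(inf$cluster_alpha > 0 && inf$cluster_alpha < 1))
    problems <- c(problems, "inference.cluster_alpha: must lie in (0,1)")
  if (inf$n_iterations < 100)
    problems <- c(problems, "inference.n_iterations: must be >= 100")
  if (!inf$connectivity %in% c(6, 18, 26))
    problems <- c(problems, "inference.connectivity: must be 6, 18 or 26")
  model_names <- vapply(cfg$classifier$models, `[[`, "", "name")
  if (anyDuplicated(model_names))
    problems <- c(problems, paste0("classifier.models: duplicate name(s): ",
      paste(unique(model_names[duplicated(model_names)]), collapse = ", ")))
  circuit_names <- vapply(cfg$classifier$circuits, `[[`, "", "name")
  for (m in cfg$classifier$models) {
    miss <- setdiff(m$circuits, circuit_names)
    if (length(miss))
      problems <- c(problems, paste0("classifier.models.", m$name,
        ": unknown circuit(s): ", paste(miss, collapse = ", ")))
  }
  counts <- unlist(cfg$cohort[c("n_relapse", "n_nonrelapse", "n_control")])
  if (any(counts < 2))
    problems <- c(problems, "cohort: all group counts must be >= 2")
  if (length(problems))
    stop("validation error:\n  ", paste(problems, collapse = "\n  "))
  class(cfg) <- "run_config"
  cfg
}

provenance <- function(dir, stage, params, inputs = character(0),
                       outputs = character(0)) {
  rec <- list(stage = stage, params = params,
              inputs = as.list(tools::md5sum(inputs)),
              outputs = as.character(outputs))
  path <- file.path(dir, paste0("provenance_", stage, ".json"))
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  path
}

require_artifact <- function(path, stage, needed_by) {
  if (!all(file.exists(path)))
    stop("dependency error: stage '", needed_by, "' requires outputs of '",
         stage, "' (missing: ", paste(path[!file.exists(path)], collapse = ", "),
         ")")
  invisible(path)
}

pipeline_grid <- function(cfg) {
  volume_grid(cfg$cohort$grid_dims, cfg$cohort$voxel_size)
}

load_seed_masks <- function(data_dir, grid, seed_names) {
  seg <- read_mask(file.path(data_dir, "masks", "segmentation.nii.gz"), grid)
  masks <- list()
  for (nm in seed_names) {
    if (grepl("CMA$", nm)) {
      cm <- read_volume(file.path(data_dir, "masks",
        paste0("prob_", nm, "_centromedial.nii.gz")), grid)$values
      sf <- read_volume(file.path(data_dir, "masks",
        paste0("prob_", nm, "_superficial.nii.gz")), grid)$values
      masks[[nm]] <- combine_cma(build_seed_mask(cm, 0.5, seg),
                                 build_seed_mask(sf, 0.5, seg))
    } else {
      pm <- read_volume(file.path(data_dir, "masks",
        paste0("prob_", nm, ".nii.gz")), grid)$values
      masks[[nm]] <- build_seed_mask(pm, 0.5, seg)
    }
  }
  masks
}

read_subject_scan <- function(data_dir, sid, grid, masks) {
  bold <- read_volume(file.path(data_dir, paste0(sid, "_bold.nii.gz")), grid)
  T <- dim(bold$values)[4]
  list(bold = matrix(bold$values, nrow = n_voxels(grid)),
       motion = read_motion(file.path(data_dir, paste0(sid, "_motion.txt")), T),
       masks = masks, grid = grid, tr = bold$tr)
}

#' Run the pipeline
#'
#' Orchestrates `simulate -> preprocess -> connectivity -> group -> loocv ->
#' report` from one validated configuration with deterministic seeding.
#' Each stage writes its artifacts plus a provenance record (parameters,
#' input checksums) under `out_dir`; reruns with the same config reproduce
#' identical numeric outputs.
#'
#' Stages:
#' * `simulate` - synthetic cohort (BOLD NIfTI, motion tables, masks,
#'   cohort TSV, truth manifest).
#' * `preprocess` - writes per-subject filtered/smoothed series and filtered
#'   nuisance designs (QC artifacts; downstream stages recompute in memory).
#' * `connectivity` - per subject x seed Fisher-z maps
#'   (`<subject>_<seed>_zmap.nii.gz`).
#' * `group` - one-sample control maps, relapse vs non-relapse contrasts,
#'   smoothness estimation, Monte-Carlo cluster-size threshold, cluster
#'   tables, covariate associations.
#' * `loocv` - leave-one-out cross-validated classification models.
#' * `report` - aggregate model summary table.
#'
#' @param config a `run_config` from [validate_config()] (or anything it
#'   accepts).
#' @param stages subset of stages to run (default all).
#' @return named list of stage outputs, invisibly.
#' @export
run_pipeline <- function(config = list(),
                         stages = c("simulate", "preprocess", "connectivity",
                                    "group", "loocv", "report")) {
  cfg <- if (inherits(config, "run_config")) config else validate_config(config)
  all_stages <- c("simulate", "preprocess", "connectivity", "group", "loocv",
                  "report")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  grid <- pipeline_grid(cfg)
  fspec <- filter_spec(cfg$filter$f_lo, cfg$filter$f_hi, cfg$cohort$tr)
  data_dir <- file.path(out, "data")
  zmap_dir <- file.path(out, "zmaps")
  group_dir <- file.path(out, "group")
  loocv_dir <- file.path(out, "loocv")
  results <- list()

  if ("simulate" %in% stages) {
    spec <- cohort_spec(cfg$cohort$n_relapse, cfg$cohort$n_nonrelapse,
                        cfg$cohort$n_control, cfg$cohort$grid_dims,
                        cfg$cohort$voxel_size, cfg$cohort$n_volumes,
                        cfg$cohort$tr, seed = child_seed(cfg$seed, 1))
    sim <- synthesize_cohort(spec, out_dir = data_dir)
    provenance(out, "simulate", cfg$cohort,
               outputs = c(sim$paths, file.path(data_dir, "cohort.tsv")))
    results$simulate <- sim$paths
  }

  cohort_path <- file.path(data_dir, "cohort.tsv")
  if (any(c("preprocess", "connectivity", "group", "loocv") %in% stages))
    require_artifact(cohort_path, "simulate",
                     setdiff(stages, c("simulate", "report"))[1])

  if ("preprocess" %in% stages) {
    cohort <- load_cohort(cohort_path)
    masks <- list(brain = read_mask(file.path(data_dir, "masks", "brain.nii.gz"), grid),
                  wm = read_mask(file.path(data_dir, "masks", "wm.nii.gz"), grid),
                  csf = read_mask(file.path(data_dir, "masks", "csf.nii.gz"), grid))
    prep_dir <- file.path(out, "preprocess")
    dir.create(prep_dir, showWarnings = FALSE)
    outs <- character(0)
    for (sid in cohort$subject_id) {
      scan <- read_subject_scan(data_dir, sid, grid, masks)
      pp <- preprocess_subject(scan, fspec, cfg$smoothing_fwhm)
      p1 <- file.path(prep_dir, paste0(sid, "_filtered.nii.gz"))
      p2 <- file.path(prep_dir, paste0(sid, "_smoothed.nii.gz"))
      write_volume(array(pp$filtered, c(grid$dims, ncol(pp$filtered))), p1,
                   grid, tr = scan$tr)
      write_volume(array(pp$smoothed, c(grid$dims, ncol(pp$smoothed))), p2,
                   grid, tr = scan$tr)
      p3 <- file.path(prep_dir, paste0(sid, "_nuisance.tsv"))
      write.table(unclass(pp$nuisance), p3, quote = FALSE, sep = "\t",
                  row.names = FALSE)
      outs <- c(outs, p1, p2, p3)
    }
    provenance(out, "preprocess",
               c(cfg$filter, list(smoothing_fwhm = cfg$smoothing_fwhm)),
               inputs = cohort_path, outputs = outs)
    results$preprocess <- outs
  }

  if ("connectivity" %in% stages) {
    cohort <- load_cohort(cohort_path)
    masks <- list(brain = read_mask(file.path(data_dir, "masks", "brain.nii.gz"), grid),
                  wm = read_mask(file.path(data_dir, "masks", "wm.nii.gz"), grid),
                  csf = read_mask(file.path(data_dir, "masks", "csf.nii.gz"), grid))
    seed_masks <- load_seed_masks(data_dir, grid, cfg$seeds)
    dir.create(zmap_dir, showWarnings = FALSE)
    outs <- character(0)
    for (sid in cohort$subject_id) {
      scan <- read_subject_scan(data_dir, sid, grid, masks)
      zm <- subject_zmaps(scan, seed_masks, fspec, cfg$smoothing_fwhm)
      for (nm in names(zm$z)) {
        zp <- file.path(zmap_dir, paste0(sid, "_", nm, "_zmap.nii.gz"))
        zv <- zm$z[[nm]]
        zv[is.na(zv)] <- 0
        write_volume(array(zv, grid$dims), zp, grid)
        outs <- c(outs, zp)
      }
    }
    provenance(out, "connectivity", list(seeds = cfg$seeds),
               inputs = cohort_path, outputs = outs)
    results$connectivity <- outs
  }

  if ("group" %in% stages) {
    results$group <- run_group_stage(cfg, grid, data_dir, zmap_dir, group_dir,
                                     out)
  }

  if ("loocv" %in% stages) {
    require_artifact(file.path(group_dir, "inference.json"), "group", "loocv")
    results$loocv <- run_loocv_stage(cfg, grid, data_dir, zmap_dir, group_dir,
                                     loocv_dir, out)
  }

  if ("report" %in% stages) {
    models_path <- file.path(loocv_dir, "models.tsv")
    require_artifact(models_path, "loocv", "report")
    rep_dir <- file.path(out, "report")
    dir.create(rep_dir, showWarnings = FALSE)
    models <- read.table(models_path, header = TRUE, sep = "\t")
    summary_path <- file.path(rep_dir, "summary.tsv")
    write.table(models, summary_path, quote = FALSE, sep = "\t",
                row.names = FALSE)
    provenance(out, "report", list(), inputs = models_path,
               outputs = summary_path)
    results$report <- summary_path
  }
  invisible(results)
}

load_zmaps <- function(zmap_dir, grid, subject_ids, seed_names) {
  V <- n_voxels(grid)
  out <- list()
  for (nm in seed_names) {
    Z <- matrix(NA_real_, length(subject_ids), V)
    for (i in seq_along(subject_ids)) {
      p <- file.path(zmap_dir, paste0(subject_ids[i], "_", nm, "_zmap.nii.gz"))
      require_artifact(p, "connectivity", "group")
      Z[i, ] <- as.vector(read_volume(p, grid)$values)
    }
    out[[nm]] <- Z
  }
  out
}

contrast_residual_maps <- function(z_maps, labels, mask) {
  g <- as.numeric(factor(labels)) - 1
  Q <- qr.Q(qr(cbind(1, g)))
  m <- as.vector(mask) != 0
  Y <- z_maps[, m, drop = FALSE]
  R <- Y - Q %*% crossprod(Q, Y)
  full <- matrix(0, nrow(z_maps), ncol(z_maps))
  full[, m] <- R
  full
}

run_group_stage <- function(cfg, grid, data_dir, zmap_dir, group_dir, out) {
  cohort <- load_cohort(file.path(data_dir, "cohort.tsv"))
  brain <- read_mask(file.path(data_dir, "masks", "brain.nii.gz"), grid)
  dir.create(group_dir, showWarnings = FALSE)
  inf <- cfg$inference
  zmaps <- load_zmaps(zmap_dir, grid, cohort$subject_id, cfg$seeds)
  cocaine <- cohort$group %in% c("relapse", "nonrelapse")
  controls <- cohort$group == "control"
  outs <- character(0)
  info <- list(seeds = list())
  all_reports <- list()
  for (nm in cfg$seeds) {
    Z <- zmaps[[nm]]
    # healthy-control one-sample connectivity map
    if (sum(controls) >= 2) {
      osm <- one_sample_map(Z[controls, , drop = FALSE], brain, grid)
      osm$contrast <- paste0(nm, " control one-sample")
      res_ctl <- sweep(Z[controls, , drop = FALSE], 2, colMeans(Z[controls, , drop = FALSE]))
      fw_ctl <- estimate_smoothness(res_ctl, brain, grid)
      km_ctl <- mc_cluster_size_threshold(brain, grid,
        round(fw_ctl * 4) / 4, inf$onesample_voxel_p, inf$cluster_alpha,
        inf$n_iterations, inf$connectivity,
        seed = child_seed(cfg$seed, 2))
      rep1 <- cluster_report(osm, km_ctl$k_min, inf$onesample_voxel_p,
                             inf$connectivity)
      p <- file.path(group_dir, paste0(nm, "_control_onesample_clusters.tsv"))
      write.table(rep1, p, quote = FALSE, sep = "\t", row.names = FALSE)
      outs <- c(outs, p)
    }
    # relapse vs non-relapse contrast
    labs <- factor(cohort$group[cocaine], levels = c("relapse", "nonrelapse"))
    smap <- group_contrast_map(Z[cocaine, , drop = FALSE], labs,
                               mask = brain, grid = grid,
                               contrast = paste0(nm, " relapse vs nonrelapse"))
    res <- contrast_residual_maps(Z[cocaine, , drop = FALSE], labs, brain)
    fw <- estimate_smoothness(res, brain, grid)
    km <- mc_cluster_size_threshold(brain, grid, round(fw * 4) / 4,
      inf$voxel_p, inf$cluster_alpha, inf$n_iterations, inf$connectivity,
      seed = child_seed(cfg$seed, 3))
    rep2 <- cluster_report(smap, km$k_min, inf$voxel_p, inf$connectivity)
    p <- file.path(group_dir, paste0(nm, "_contrast_clusters.tsv"))
    write.table(rep2, p, quote = FALSE, sep = "\t", row.names = FALSE)
    outs <- c(outs, p)
    all_reports[[nm]] <- rep2
    sv <- smap$values; sv[is.na(sv)] <- 0
    pmap <- file.path(group_dir, paste0(nm, "_contrast_F.nii.gz"))
    write_volume(array(sv, grid$dims), pmap, grid)
    outs <- c(outs, pmap)
    # covariate associations for surviving clusters
    cl <- Filter(function(x) x$size >= km$k_min,
                 extract_clusters(smap, inf$voxel_p, inf$connectivity))
    assoc <- data.frame()
    for (ci in seq_along(cl)) {
      mz <- rowMeans(Z[cocaine, cl[[ci]]$voxels, drop = FALSE])
      for (cov in c("years_education", "years_smoking")) {
        a <- covariate_association(mz, cohort[cocaine, cov])
        assoc <- rbind(assoc, data.frame(seed = nm, cluster = ci,
          covariate = cov, stat = a$stat, estimate = a$estimate,
          df = a$df, p = a$p))
      }
    }
    if (nrow(assoc)) {
      pa <- file.path(group_dir, paste0(nm, "_covariate_assoc.tsv"))
      write.table(assoc, pa, quote = FALSE, sep = "\t", row.names = FALSE)
      outs <- c(outs, pa)
    }
    info$seeds[[nm]] <- list(k_min = km$k_min, fwhm_est = fw,
                             n_clusters = nrow(rep2))
  }
  info_path <- file.path(group_dir, "inference.json")
  jsonlite::write_json(info, info_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  provenance(out, "group", cfg$inference, outputs = c(outs, info_path))
  list(reports = all_reports, info = info, outputs = outs)
}

run_loocv_stage <- function(cfg, grid, data_dir, zmap_dir, group_dir,
                            loocv_dir, out) {
  cohort <- load_cohort(file.path(data_dir, "cohort.tsv"))
  brain <- read_mask(file.path(data_dir, "masks", "brain.nii.gz"), grid)
  info <- jsonlite::read_json(file.path(group_dir, "inference.json"),
                              simplifyVector = TRUE)
  dir.create(loocv_dir, showWarnings = FALSE)
  inf <- cfg$inference
  cocaine <- cohort$group %in% c("relapse", "nonrelapse")
  ids <- cohort$subject_id[cocaine]
  labs <- factor(cohort$group[cocaine], levels = c("relapse", "nonrelapse"))
  covs <- cohort[cocaine, c("years_education", "years_smoking")]
  seeds_used <- unique(vapply(cfg$classifier$circuits, `[[`, "", "seed"))
  zmaps <- load_zmaps(zmap_dir, grid, ids, seeds_used)
  zc <- lapply(zmaps, identity)
  # full-sample reference cluster per circuit
  circuits <- list()
  for (cc in cfg$classifier$circuits) {
    smap <- group_contrast_map(zc[[cc$seed]], labs, mask = brain, grid = grid)
    km <- info$seeds[[cc$seed]]$k_min
    ref <- find_reference_cluster(smap, inf$voxel_p, km, inf$connectivity)
    if (is.null(ref))
      stop("loocv error: no reference cluster for circuit ", cc$name)
    circuits[[cc$name]] <- list(name = cc$name, seed = cc$seed,
                                reference = ref, k_min = km)
  }
  rows <- data.frame(); fold_rows <- data.frame()
  for (m in cfg$classifier$models) {
    mc <- circuits[m$circuits]
    k_min_use <- if (length(mc)) max(vapply(mc, `[[`, 0, "k_min")) else 1
    settings <- list(mask = brain, grid = grid, voxel_p = inf$voxel_p,
                     k_min = k_min_use, connectivity = inf$connectivity)
    spec <- predictor_spec(unname(mc),
                           covariates = if (is.null(m$covariates)) character(0)
                                        else m$covariates)
    rep <- run_loocv(zc, labs, covs, spec, settings, model_name = m$name)
    met <- rep$metrics
    rows <- rbind(rows, data.frame(model = m$name,
      sensitivity = round(met$sensitivity, 1),
      specificity = round(met$specificity, 1),
      accuracy = round(met$accuracy, 1),
      chi2 = round(rep$chisq$chisq, 2), p = signif(rep$chisq$p, 3)))
    for (f in rep$folds) {
      if (is.null(f)) next
      fold_rows <- rbind(fold_rows, data.frame(model = m$name,
        left_out = ids[f$left_out], prob = f$prob,
        predicted = ifelse(f$predicted, "relapse", "nonrelapse"),
        actual = as.character(labs[f$left_out])))
    }
  }
  models_path <- file.path(loocv_dir, "models.tsv")
  write.table(rows, models_path, quote = FALSE, sep = "\t", row.names = FALSE)
  folds_path <- file.path(loocv_dir, "folds.tsv")
  write.table(fold_rows, folds_path, quote = FALSE, sep = "\t",
              row.names = FALSE)
  provenance(out, "loocv", list(models = vapply(cfg$classifier$models,
                                                `[[`, "", "name")),
             outputs = c(models_path, folds_path))
  list(models = rows, outputs = c(models_path, folds_path))
}
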