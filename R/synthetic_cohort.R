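#' Cohort specification for the synthetic resting-BOLD generator
#'
#' Defaults emulate the study conditions the pipeline targets: 24 relapse,
#' 21 non-relapse and 22 control subjects, 6-minute resting scans of 212
#' volumes at TR 1.7 s, on a desk-scale 24 x 24 x 18 grid at
#' 3.25 x 3.25 x 3 mm.
#'
#' @param n_relapse,n_nonrelapse,n_control group sizes (each >= 2).
#' @param grid_dims voxels per axis.
#' @param voxel_size mm per axis.
#' @param n_volumes timepoints per scan.
#' @param tr repetition time, seconds.
#' @param seed master generator seed.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_relapse = 24, n_nonrelapse = 21, n_control = 22,
                        grid_dims = c(24, 24, 18),
                        voxel_size = c(3.25, 3.25, 3),
                        n_volumes = 212, tr = 1.7, seed = 1) {
  counts <- c(n_relapse, n_nonrelapse, n_control)
  if (any(counts < 2)) stop("validation error: all group counts must be >= 2")
  if (n_volumes < 8) stop("validation error: n_volumes too small")
  grid <- volume_grid(grid_dims, voxel_size)
  structure(list(n_relapse = n_relapse, n_nonrelapse = n_nonrelapse,
                 n_control = n_control, grid = grid,
                 n_volumes = as.integer(n_volumes), tr = tr, seed = seed),
            class = "cohort_spec")
}

box_mask <- function(grid, xr, yr, zr) {
  m <- array(FALSE, grid$dims)
  m[xr, yr, zr] <- TRUE
  m
}

#' Ground-truth manifest for the synthetic cohort
#'
#' Describes what is planted in the data: disjoint region masks (four
#' amygdala-like seed blocks, two cortical target blocks, WM and CSF blocks
#' inside an ellipsoidal brain), and circuits giving the group-wise coupling
#' weight between a seed's latent signal and its target region.
#'
#' Default couplings make both planted effects recoverable and are arbitrary
#' (no published effect sizes exist to anchor them): the "vmPFC-like" circuit
#' couples the left CMA seed at beta 0.6 (non-relapse, control) vs 0.2
#' (relapse); the "visual-like" circuit couples the right BLA seed at 0.1
#' (non-relapse) vs 0.5 (relapse, control).
#'
#' @param grid a [volume_grid()]; region boxes are scaled for the default
#'   24 x 24 x 18 grid and placed proportionally on other grids.
#' @param circuits optional list overriding the default circuits; each
#'   element is `list(name, seed, target, coupling = c(relapse=, nonrelapse=,
#'   control=))`.
#' @param noise_sd marginal standard deviation of the spatially smooth
#'   Gaussian noise field.
#' @param smoothness_fwhm spatial smoothness of the noise field, mm.
#' @param nuisance_weights length-8 weights (6 motion, WM, CSF) of the shared
#'   nuisance contamination added to brain voxels.
#' @param drift_coeffs quadratic drift polynomial coefficients over a
#'   time axis scaled to \[-1, 1\].
#' @return object of class `truth_manifest`.
#' @export
default_truth <- function(grid = volume_grid(c(24, 24, 18)),
                          circuits = NULL,
                          noise_sd = 1, smoothness_fwhm = 6,
                          nuisance_weights = c(rep(0.1, 6), 0.3, 0.3),
                          drift_coeffs = c(0, 0.5, 0.5)) {
  stopifnot(noise_sd > 0, smoothness_fwhm >= 0,
            length(nuisance_weights) == 8, length(drift_coeffs) == 3)
  d <- grid$dims
  # map a voxel range on the reference 24 x 24 x 18 grid to this grid via
  # half-open fractions, so disjoint reference boxes stay disjoint when scaled
  sc <- function(v, ax) {
    D <- c(24, 24, 18)[ax]
    lo <- floor((min(v) - 1) / D * d[ax]) + 1L
    hi <- floor(max(v) / D * d[ax])
    if (hi < lo) stop("truth error: grid too small for the default regions")
    lo:hi
  }
  ctr <- (d + 1) / 2
  ax <- d * 0.46
  idx <- expand.grid(i = seq_len(d[1]), j = seq_len(d[2]), k = seq_len(d[3]))
  brain <- array(((idx$i - ctr[1]) / ax[1])^2 + ((idx$j - ctr[2]) / ax[2])^2 +
                   ((idx$k - ctr[3]) / ax[3])^2 <= 1, d)
  seeds <- list(
    L_CMA = box_mask(grid, sc(15:17, 1), sc(11:13, 2), sc(7:9, 3)),
    R_CMA = box_mask(grid, sc(8:10, 1),  sc(11:13, 2), sc(7:9, 3)),
    L_BLA = box_mask(grid, sc(15:17, 1), sc(8:10, 2),  sc(7:9, 3)),
    R_BLA = box_mask(grid, sc(8:10, 1),  sc(8:10, 2),  sc(7:9, 3)))
  targets <- list(
    vmpfc  = box_mask(grid, sc(10:14, 1), sc(3:7, 2),   sc(9:12, 3)),
    visual = box_mask(grid, sc(10:14, 1), sc(18:22, 2), sc(8:11, 3)))
  wm  <- box_mask(grid, sc(11:13, 1), sc(11:13, 2), sc(4:6, 3))
  csf <- box_mask(grid, sc(11:13, 1), sc(15:17, 2), sc(4:6, 3))
  all_regions <- c(seeds, targets, list(wm = wm, csf = csf))
  counts <- Reduce(`+`, lapply(all_regions, function(m) array(as.integer(m), d)))
  if (max(counts) > 1L) stop("truth error: region masks overlap")
  brain <- brain | Reduce(`|`, all_regions)
  if (is.null(circuits)) circuits <- list(
    list(name = "cma_vmpfc", seed = "L_CMA", target = "vmpfc",
         coupling = c(relapse = 0.2, nonrelapse = 0.6, control = 0.6)),
    list(name = "bla_visual", seed = "R_BLA", target = "visual",
         coupling = c(relapse = 0.5, nonrelapse = 0.1, control = 0.5)))
  for (cc in circuits) {
    stopifnot(cc$seed %in% names(seeds), cc$target %in% names(targets),
              all(is.finite(cc$coupling)))
  }
  structure(list(grid = grid, brain = brain, seeds = seeds, targets = targets,
                 wm = wm, csf = csf, circuits = circuits, noise_sd = noise_sd,
                 smoothness_fwhm = smoothness_fwhm,
                 nuisance_weights = nuisance_weights,
                 drift_coeffs = drift_coeffs),
            class = "truth_manifest")
}

#' Probabilistic seed maps implied by the ground truth
#'
#' Returns one probabilistic map per seed component, mimicking atlas-derived
#' maps: probability 0.9 inside the true region, 0.25 in a one-voxel shell,
#' 0 elsewhere.  The CMA seeds are emitted as two components (centromedial +
#' superficial, split along the z axis) to exercise [combine_cma()];
#' thresholding at 0.5 inside the segmentation recovers the true region.
#'
#' @param truth a [default_truth()] manifest.
#' @return named list of 3D probability arrays.
#' @export
truth_seed_probmaps <- function(truth) {
  grid <- truth$grid
  dilate1 <- function(m) {
    sm <- smooth_gaussian(matrix(as.double(m), ncol = 1),
                          2 * max(grid$voxel_size), grid)
    array(as.numeric(sm) > 1e-3, grid$dims)
  }
  out <- list()
  for (nm in names(truth$seeds)) {
    m <- truth$seeds[[nm]]
    shell <- dilate1(m) & !m
    pm <- array(0, grid$dims); pm[m] <- 0.9; pm[shell] <- 0.25
    if (grepl("CMA$", nm)) {
      ks <- sort(unique(which(m, arr.ind = TRUE)[, 3]))
      split_k <- ks[length(ks)]
      cm <- pm; cm[, , split_k] <- pmin(pm[, , split_k], 0.25 * (pm[, , split_k] > 0))
      sf <- array(0, grid$dims); sf[, , split_k] <- pm[, , split_k]
      out[[paste0(nm, "_centromedial")]] <- cm
      out[[paste0(nm, "_superficial")]] <- sf
    } else {
      out[[nm]] <- pm
    }
  }
  out
}

#' Band-limited unit-variance random signal
#'
#' Draws independent Gaussian weights on the discrete-Fourier components
#' inside `[f_lo, f_hi]` so spectral power outside the band is exactly zero
#' by construction, then rescales to zero mean and unit empirical variance.
#'
#' @param n_volumes series length.
#' @param tr sampling interval, seconds.
#' @param f_lo,f_hi band edges, Hz (must lie within (0, Nyquist\]).
#' @param seed stream seed (see [rnorm_seeded()]).
#' @return numeric series of length `n_volumes`.
#' @export
make_band_limited_signal <- function(n_volumes, tr, f_lo = 0.01, f_hi = 0.1,
                                     seed = 1) {
  spec <- filter_spec(f_lo, f_hi, tr)
  B <- band_basis(n_volumes, spec)
  s <- drop(B %*% rnorm_seeded(ncol(B), seed))
  s / sd(s)
}

synth_covariates <- function(group, seed) {
  # Table-1-like covariate distributions per group (education yrs, smoking yrs)
  mu_edu <- c(relapse = 11.83, nonrelapse = 13.29, control = 13.91)
  sd_edu <- c(relapse = 1.88, nonrelapse = 2.05, control = 1.41)
  mu_smk <- c(relapse = 24.32, nonrelapse = 17.88, control = 0)
  sd_smk <- c(relapse = 9.32, nonrelapse = 9.07, control = 0)
  z <- rnorm_seeded(2, seed)
  edu <- round(pmax(8, mu_edu[group] + sd_edu[group] * z[1]), 1)
  smk <- round(pmax(0, mu_smk[group] + sd_smk[group] * z[2]), 1)
  c(years_education = unname(edu), years_smoking = unname(smk))
}

smooth_walk <- function(n, seed, scale = 1) {
  w <- cumsum(rnorm_seeded(n + 8, seed))
  k <- rep(1 / 9, 9)
  sm <- stats::filter(w, k, sides = 2)
  sm <- sm[5:(n + 4)]
  sm <- sm - mean(sm)
  m <- max(abs(sm))
  if (m > 0) sm <- sm / m * scale
  as.numeric(sm)
}

#' Synthesize one subject's resting scan
#'
#' Brain voxels receive a spatially smooth Gaussian noise field plus a shared
#' nuisance contamination (weighted motion, WM and CSF signals) and a
#' quadratic drift.  Each seed region carries its own band-limited latent
#' signal; each circuit's target region receives that latent scaled by the
#' group's coupling weight, so the nuisance-partialled seed-target
#' correlation has closed form beta / sqrt(beta^2 + noise_sd^2).
#'
#' @param spec a [cohort_spec()].
#' @param truth a [default_truth()] manifest on the same grid.
#' @param group `"relapse"`, `"nonrelapse"` or `"control"`.
#' @param seed subject-level stream seed.
#' @return a `subject_scan`: list with `bold` (voxels x time matrix),
#'   `motion` (T x 6), `masks` (brain/wm/csf/segmentation logical arrays),
#'   `grid`, `tr`.
#' @export
synthesize_subject <- function(spec, truth, group, seed) {
  grp <- as.character(group)
  if (!grp %in% cohort_groups)
    stop("validation error: unknown group: ", grp)
  check_same_grid(spec$grid, truth$grid, "truth manifest")
  grid <- spec$grid
  V <- n_voxels(grid); T <- spec$n_volumes
  X <- matrix(rnorm_seeded(V * T, child_seed(seed, 1)), V, T)
  if (truth$smoothness_fwhm > 0) {
    X <- smooth_gaussian(X, truth$smoothness_fwhm, grid)
    # exact unit marginal variance everywhere (renormalised edges included)
    X <- X * (truth$noise_sd / smooth_noise_sd_field(grid, truth$smoothness_fwhm))
  } else {
    X <- X * truth$noise_sd
  }
  # latent signal per seed region; circuit targets get scaled copies
  latents <- list()
  for (si in seq_along(truth$seeds)) {
    nm <- names(truth$seeds)[si]
    latents[[nm]] <- make_band_limited_signal(T, spec$tr,
                                              seed = child_seed(seed, 2, si))
    idx <- which(as.vector(truth$seeds[[nm]]))
    X[idx, ] <- rep(latents[[nm]], each = length(idx))
  }
  for (cc in truth$circuits) {
    beta <- cc$coupling[[grp]]
    if (beta != 0) {
      idx <- which(as.vector(truth$targets[[cc$target]]))
      X[idx, ] <- X[idx, ] + beta * rep(latents[[cc$seed]], each = length(idx))
    }
  }
  # nuisance signals: 6 motion walks (scaled to +/- 1 mm/deg), WM, CSF
  motion <- vapply(1:6, function(k) smooth_walk(T, child_seed(seed, 3, k)),
                   numeric(T))
  wm_sig <- make_band_limited_signal(T, spec$tr, seed = child_seed(seed, 4))
  csf_sig <- make_band_limited_signal(T, spec$tr, seed = child_seed(seed, 5))
  wm_idx <- which(as.vector(truth$wm)); csf_idx <- which(as.vector(truth$csf))
  X[wm_idx, ] <- 0.3 * X[wm_idx, ] + rep(wm_sig, each = length(wm_idx))
  X[csf_idx, ] <- 0.3 * X[csf_idx, ] + rep(csf_sig, each = length(csf_idx))
  contam <- drop(cbind(motion, wm_sig, csf_sig) %*% truth$nuisance_weights)
  bidx <- which(as.vector(truth$brain))
  X[bidx, ] <- X[bidx, ] + rep(contam, each = length(bidx))
  u <- seq(-1, 1, length.out = T)
  drift <- truth$drift_coeffs[1] + truth$drift_coeffs[2] * u +
    truth$drift_coeffs[3] * u^2
  X <- X + rep(drift, each = V)
  segmentation <- Reduce(`|`, truth$seeds)
  list(bold = X, motion = motion,
       masks = list(brain = truth$brain, wm = truth$wm, csf = truth$csf,
                    segmentation = segmentation),
       grid = grid, tr = spec$tr)
}

cohort_table_from_spec <- function(spec) {
  groups <- rep(c("relapse", "nonrelapse", "control"),
                c(spec$n_relapse, spec$n_nonrelapse, spec$n_control))
  n <- length(groups)
  ids <- sprintf("sub-%03d", seq_len(n))
  cov <- t(vapply(seq_len(n), function(i)
    synth_covariates(groups[i], child_seed(spec$seed, 10, i)),
    numeric(2)))
  data.frame(subject_id = ids, group = groups,
             years_education = cov[, 1], years_smoking = cov[, 2],
             stringsAsFactors = FALSE)
}

#' Synthesize a cohort, in memory or on disk
#'
#' Generates one scan per subject from per-subject child seeds fanned out of
#' `spec$seed`, so the same spec reproduces the identical dataset and any
#' subject can be regenerated alone.  With `out_dir`, writes NIfTI BOLD
#' series and masks, motion tables, probabilistic seed maps, the cohort TSV
#' and a JSON truth manifest; otherwise returns scans in memory.
#'
#' @param spec a [cohort_spec()].
#' @param truth a [default_truth()] manifest (defaults to one on the cohort spec's
#'   grid).
#' @param out_dir optional output directory.
#' @param scan_fun optional callback `function(scan, subject_row)`; when
#'   given (and `out_dir` is NULL) scans are not accumulated, only the
#'   callback results, keeping memory flat for large cohorts.
#' @return list with `cohort` (table), `truth`, and either `scans` (or
#'   callback results) or `paths`.
#' @export
synthesize_cohort <- function(spec, truth = default_truth(spec$grid),
                              out_dir = NULL, scan_fun = NULL) {
  cohort <- cohort_table_from_spec(spec)
  n <- nrow(cohort)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir) &&
        !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
      stop("I/O error: cannot create output directory: ", out_dir)
  }
  results <- vector("list", n)
  names(results) <- cohort$subject_id
  paths <- NULL
  if (!is.null(out_dir)) {
    grid <- spec$grid
    mask_dir <- file.path(out_dir, "masks")
    dir.create(mask_dir, showWarnings = FALSE)
    for (nm in c("brain", "wm", "csf")) {
      write_mask(truth[[nm]], file.path(mask_dir, paste0(nm, ".nii.gz")), grid)
    }
    write_mask(Reduce(`|`, truth$seeds),
               file.path(mask_dir, "segmentation.nii.gz"), grid)
    pms <- truth_seed_probmaps(truth)
    for (nm in names(pms)) {
      write_volume(pms[[nm]], file.path(mask_dir, paste0("prob_", nm, ".nii.gz")),
                   grid)
    }
  }
  for (i in seq_len(n)) {
    scan <- synthesize_subject(spec, truth, cohort$group[i],
                               seed = child_seed(spec$seed, 20, i))
    if (!is.null(out_dir)) {
      sid <- cohort$subject_id[i]
      bold_path <- file.path(out_dir, paste0(sid, "_bold.nii.gz"))
      write_volume(array(scan$bold, c(spec$grid$dims, spec$n_volumes)),
                   bold_path, spec$grid, tr = spec$tr)
      write_motion(scan$motion, file.path(out_dir, paste0(sid, "_motion.txt")))
      results[[i]] <- bold_path
    } else if (!is.null(scan_fun)) {
      results[[i]] <- scan_fun(scan, cohort[i, ])
    } else {
      results[[i]] <- scan
    }
  }
  out <- list(cohort = cohort, truth = truth, spec = spec)
  if (!is.null(out_dir)) {
    write_cohort(cohort, file.path(out_dir, "cohort.tsv"))
    manifest <- list(
      seed = spec$seed, n_volumes = spec$n_volumes, tr = spec$tr,
      grid = list(dims = spec$grid$dims, voxel_size = spec$grid$voxel_size),
      groups = as.list(table(cohort$group)),
      circuits = lapply(truth$circuits, function(cc)
        list(name = cc$name, seed = cc$seed, target = cc$target,
             coupling = as.list(cc$coupling))),
      noise_sd = truth$noise_sd, smoothness_fwhm = truth$smoothness_fwhm,
      subjects = cohort)
    jsonlite::write_json(manifest, file.path(out_dir, "truth_manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    out$paths <- unlist(results)
    out$dir <- out_dir
  } else {
    out$scans <- results
  }
  out
}
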