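#' Simulation configuration for a synthetic CT tumor cohort
#'
#' Defines the statistical structure of the phantom cohort the pipeline is
#' tested on: cohort size and molecular-subtype mix, the class-dependent
#' texture heterogeneity planted in the peritumoral band just outside the
#' tumor boundary,
#' scanner-manufacturer batch effects (additive HU offset plus a
#' noise-amplitude multiplier that destabilizes texture features), per-class
#' log-normal TMB distributions straddling the 15.5 mut/Mb cut-point, and
#' lesion geometry. Defaults mirror the study cohort: 150 patients at
#' subtype proportions 4% POLE / 29.3% MMR-D / 18.7% CN-low-like /
#' 48% CN-high-like, with MMR-D TMB draws placing roughly 90% of their mass
#' above 15.5 mut/Mb.
#'
#' @param n_patients cohort size
#' @param class_proportions named fractions over the four molecular subtypes;
#'   must sum to 1
#' @param rim_heterogeneity_effect named per-class multiplier (>= 0) of the
#'   extra high-frequency noise amplitude in the peritumoral band; the
#'   hypermutated classes carry a stronger boundary texture by default
#' @param rim_texture_sd base amplitude (HU) multiplied by the class effect
#' @param scanner_labels named assignment probabilities per manufacturer
#' @param scanner_shift named additive HU offset per manufacturer
#' @param scanner_noise_mult named per-manufacturer multiplier of the global
#'   noise sd; values away from 1 make intensity-driven features unstable
#'   across manufacturers, which the stability filter should remove
#' @param tmb_meanlog,tmb_sdlog named per-class log-TMB location and scale
#'   (mut/Mb)
#' @param clinical_correlation scales the class-dependence of age, histology,
#'   grade and stage between 0 (independent) and 1 (full default strength)
#' @param tumor_radius_range lesion semi-axis range in mm
#' @param voxel_spacing acquisition voxel size in mm
#' @param noise_sd global Gaussian image noise sd in HU
#' @param tumor_hu,background_hu mean intensities of lesion and background
#' @param shell_halfwidth width in mm of the peritumoral band that receives
#'   the planted texture
#' @param seed integer master seed
#' @return validated config list of class `SimulationConfig`
#' @export
simulationConfig <- function(
    n_patients = 150,
    class_proportions = c("POLE" = 0.04, "MMR-D" = 0.293,
                          "CN-low-like" = 0.187, "CN-high-like" = 0.48),
    rim_heterogeneity_effect = c("POLE" = 3, "MMR-D" = 3,
                                 "CN-low-like" = 1, "CN-high-like" = 1),
    rim_texture_sd = 8,
    scanner_labels = c("GE" = 0.5, "Siemens" = 0.3, "Philips" = 0.2),
    scanner_shift = c("GE" = 0, "Siemens" = 8, "Philips" = -6),
    scanner_noise_mult = c("GE" = 1, "Siemens" = 1.3, "Philips" = 0.8),
    tmb_meanlog = c("POLE" = log(80), "MMR-D" = log(40),
                    "CN-low-like" = log(5), "CN-high-like" = log(6)),
    tmb_sdlog = c("POLE" = 0.5, "MMR-D" = 0.75,
                  "CN-low-like" = 0.45, "CN-high-like" = 0.5),
    clinical_correlation = 1,
    tumor_radius_range = c(6, 11),
    voxel_spacing = c(1, 1, 1),
    noise_sd = 10,
    tumor_hu = 70,
    background_hu = 30,
    shell_halfwidth = 2,
    seed = 1L) {
  cfg <- list(n_patients = as.integer(n_patients),
              class_proportions = class_proportions,
              rim_heterogeneity_effect = rim_heterogeneity_effect,
              rim_texture_sd = rim_texture_sd,
              scanner_labels = scanner_labels,
              scanner_shift = scanner_shift,
              scanner_noise_mult = scanner_noise_mult,
              tmb_meanlog = tmb_meanlog, tmb_sdlog = tmb_sdlog,
              clinical_correlation = clinical_correlation,
              tumor_radius_range = tumor_radius_range,
              voxel_spacing = voxel_spacing,
              noise_sd = noise_sd, tumor_hu = tumor_hu,
              background_hu = background_hu,
              shell_halfwidth = shell_halfwidth,
              seed = as.integer(seed))
  validateSimulationConfig(cfg)
  class(cfg) <- "SimulationConfig"
  cfg
}

validateSimulationConfig <- function(cfg) {
  if (cfg$n_patients < 0) stop("n_patients must be >= 0")
  if (abs(sum(cfg$class_proportions) - 1) > 1e-9)
    stop("class proportions must sum to 1")
  if (any(cfg$class_proportions < 0)) stop("class proportions must be >= 0")
  if (any(cfg$tumor_radius_range <= 0)) stop("tumor radii must be > 0")
  if (any(cfg$rim_heterogeneity_effect < 0) || cfg$rim_texture_sd < 0 ||
      cfg$noise_sd < 0)
    stop("noise amplitudes must be >= 0")
  if (abs(sum(cfg$scanner_labels) - 1) > 1e-9)
    stop("scanner assignment probabilities must sum to 1")
  invisible(TRUE)
}

#' A null-cohort configuration
#'
#' Same geometry and noise as the default, but no planted class effect, no
#' scanner batch effect and class-independent clinical covariates, so the
#' only route to class separation is chance.
#'
#' @param ... overrides passed on to [simulationConfig()]
#' @return a `SimulationConfig`
#' @export
nullSimulationConfig <- function(...) {
  simulationConfig(
    rim_heterogeneity_effect = c("POLE" = 0, "MMR-D" = 0,
                                 "CN-low-like" = 0, "CN-high-like" = 0),
    scanner_shift = c("GE" = 0, "Siemens" = 0, "Philips" = 0),
    scanner_noise_mult = c("GE" = 1, "Siemens" = 1, "Philips" = 1),
    clinical_correlation = 0,
    ...)
}

#' Generate a single noisy ellipsoidal CT tumor phantom
#'
#' An ellipsoid of configured mean HU on a distinct background with Gaussian
#' noise; when `shellAmplitude > 0`, extra independent high-frequency texture
#' is injected in the peritumoral band within `shellHalfwidth` mm outside
#' the tumor boundary, emulating heterogeneity concentrated at the invasive
#' edge. Planting the signal outside the VOI keeps intratumoral features
#' class-blind, so discrimination must come through the rim differences --
#' the structure the pipeline is designed to detect.
#'
#' @param radii numeric(3), ellipsoid semi-axes in mm (> 0)
#' @param spacing voxel size in mm
#' @param tumorHU,backgroundHU mean intensities
#' @param noiseSD Gaussian noise sd (HU)
#' @param shellAmplitude sd (HU) of extra peritumoral texture; 0 disables
#' @param shellHalfwidth width in mm of the peritumoral band
#' @param gridDim grid size; by default sized so the tumor fits with >= 4 mm
#'   margin (room for the 3 mm dilation)
#' @param huOffset additive scanner intensity offset (HU)
#' @param seed integer seed; identical inputs give bitwise-identical output
#' @return list with `volume` ([CTVolume-class]) and `mask` ([VOIMask-class])
#' @export
generatePhantom <- function(radii, spacing = c(1, 1, 1), tumorHU = 70,
                            backgroundHU = 30, noiseSD = 10,
                            shellAmplitude = 0, shellHalfwidth = 2,
                            gridDim = NULL, huOffset = 0, seed = 1L) {
  radii <- rep_len(as.numeric(radii), 3)
  if (any(radii <= 0)) stop("tumor radii must be > 0")
  margin_mm <- 5
  if (is.null(gridDim))
    gridDim <- as.integer(2 * ceiling((radii + margin_mm) / spacing) + 1)
  half_extent <- (gridDim - 1) / 2 * spacing
  if (any(radii + 4 > half_extent))
    stop("grid too small: tumor needs >= 4 mm margin on every side")
  set.seed(seed)
  ax <- lapply(1:3, function(a)
    (seq_len(gridDim[a]) - (gridDim[a] + 1) / 2) * spacing[a])
  rho2 <- outer(outer((ax[[1]] / radii[1])^2, (ax[[2]] / radii[2])^2, `+`),
                (ax[[3]] / radii[3])^2, `+`)
  mask <- 1L * (rho2 <= 1)
  vox <- backgroundHU + (tumorHU - backgroundHU) * mask +
    rnorm(prod(gridDim), 0, noiseSD) + huOffset
  if (shellAmplitude > 0) {
    dout <- cpp_edt_sq(as.logical(mask), gridDim, spacing)
    shell <- mask == 0L & dout <= shellHalfwidth^2 + 1e-9
    vox[shell] <- vox[shell] + rnorm(sum(shell), 0, shellAmplitude)
  }
  list(volume = ctVolume(array(vox, dim = gridDim), spacing = spacing),
       mask = voiMask(array(mask, dim = gridDim), spacing = spacing))
}

#' Generate a synthetic phantom cohort
#'
#' Draws molecular subtype labels at the configured proportions, per-class
#' TMB from log-normal distributions, scanner assignments, class-correlated
#' clinical covariates, and one tumor phantom per patient with the
#' class-dependent boundary-shell texture and the scanner batch effect
#' applied. Everything is reproducible from `config$seed`.
#'
#' @param config a [simulationConfig()]
#' @return a [PhantomCohort-class]
#' @export
generateCohort <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  validateSimulationConfig(config)
  n <- config$n_patients
  classes <- names(config$class_proportions)
  set.seed(config$seed)
  if (n == 0) {
    return(new("PhantomCohort", volumes = list(), masks = list(),
               clinical = data.frame(), registry = list(),
               config = unclass(config)))
  }
  subtype <- sample(classes, n, replace = TRUE,
                    prob = config$class_proportions)
  scanner <- sample(names(config$scanner_labels), n, replace = TRUE,
                    prob = config$scanner_labels)
  tmb <- rlnorm(n, config$tmb_meanlog[subtype], config$tmb_sdlog[subtype])

  w <- config$clinical_correlation
  mix <- function(per_class, pooled) w * per_class + (1 - w) * pooled
  age_shift <- c("POLE" = -4, "MMR-D" = 0, "CN-low-like" = -2,
                 "CN-high-like" = 3)
  age <- round(rnorm(n, 64 + w * age_shift[subtype], 9))
  hist_levels <- c("endometrioid", "serous", "clear_cell", "carcinosarcoma",
                   "other_high_grade")
  hist_probs <- rbind(
    "POLE" = c(0.80, 0.05, 0.05, 0.05, 0.05),
    "MMR-D" = c(0.65, 0.05, 0.05, 0.10, 0.15),
    "CN-low-like" = c(0.90, 0.02, 0.02, 0.02, 0.04),
    "CN-high-like" = c(0.10, 0.40, 0.10, 0.25, 0.15))
  pooled_hist <- colMeans(hist_probs)
  histology <- vapply(seq_len(n), function(k)
    sample(hist_levels, 1,
           prob = mix(hist_probs[subtype[k], ], pooled_hist)),
    character(1))
  p_poor <- c("POLE" = 0.15, "MMR-D" = 0.30, "CN-low-like" = 0.05,
              "CN-high-like" = 0.45)
  grade <- ifelse(runif(n) < mix(p_poor[subtype], mean(p_poor)),
                  "poor", "well_moderate")
  p_extra <- c("POLE" = 0.35, "MMR-D" = 0.50, "CN-low-like" = 0.40,
               "CN-high-like" = 0.65)
  stage <- ifelse(runif(n) < mix(p_extra[subtype], mean(p_extra)),
                  "extra_uterine", "uterine_confined")

  r0 <- runif(n, config$tumor_radius_range[1], config$tumor_radius_range[2])
  ecc <- matrix(runif(3 * n, 0.85, 1.15), n, 3)
  lesion_seeds <- sample.int(.Machine$integer.max - 1L, n)

  volumes <- vector("list", n)
  masks <- vector("list", n)
  for (k in seq_len(n)) {
    ph <- generatePhantom(
      radii = r0[k] * ecc[k, ],
      spacing = config$voxel_spacing,
      tumorHU = config$tumor_hu, backgroundHU = config$background_hu,
      noiseSD = config$noise_sd * config$scanner_noise_mult[scanner[k]],
      shellAmplitude = config$rim_texture_sd *
        config$rim_heterogeneity_effect[subtype[k]],
      shellHalfwidth = config$shell_halfwidth,
      huOffset = config$scanner_shift[scanner[k]],
      seed = lesion_seeds[k])
    volumes[[k]] <- ph$volume
    masks[[k]] <- ph$mask
  }
  clinical <- data.frame(
    patient_id = sprintf("P%03d", seq_len(n)),
    age = age, histology = histology, grade = grade, stage = stage,
    scanner = scanner, subtype = subtype, tmb = tmb,
    stringsAsFactors = FALSE)
  registry <- list(
    shell_effects = config$rim_heterogeneity_effect,
    shell_amplitude_sd = config$rim_texture_sd,
    shell_halfwidth = config$shell_halfwidth,
    scanner_shift = config$scanner_shift,
    scanner_noise_mult = config$scanner_noise_mult,
    planted_region = "rim",
    lesion_seeds = lesion_seeds)
  new("PhantomCohort", volumes = volumes, masks = masks, clinical = clinical,
      registry = registry, config = unclass(config))
}

#' Write a phantom cohort to disk
#'
#' Volumes and masks as NIfTI-1 (`.nii.gz`), the clinical table as CSV and
#' the planted-effect registry as JSON.
#'
#' @param cohort a [PhantomCohort-class]
#' @param dir output directory (created if missing)
#' @return `dir`, invisibly
#' @export
writeCohort <- function(cohort, dir) {
  stopifnot(is(cohort, "PhantomCohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ids <- cohort@clinical$patient_id
  for (k in seq_along(ids)) {
    writeVolume(cohort@volumes[[k]],
                file.path(dir, paste0(ids[k], "_ct.nii.gz")))
    writeVolume(cohort@masks[[k]],
                file.path(dir, paste0(ids[k], "_tumor.nii.gz")))
  }
  write.csv(cohort@clinical, file.path(dir, "clinical.csv"),
            row.names = FALSE)
  jsonlite::write_json(cohort@registry[names(cohort@registry) !=
                                         "lesion_seeds"],
                       file.path(dir, "planted_registry.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
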