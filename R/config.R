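#' Default run configuration
#'
#' The full default configuration of the cohort simulation and analysis:
#' phantom grid, acquisition presets (`"v1"`: b=0 white-matter SNR 15;
#' `"v2"`: SNR 20), inter-series motion bounds, analysis thresholds, and
#' the bootstrap size B = 500.
#'
#' @param seed Base integer seed; per-subject seeds are derived from it.
#' @return A list of class `run_config`.
#' @export
default_config <- function(seed = 1) {
  structure(list(
    seed = as.integer(seed),
    cohort = list(
      n_subjects = 12L,
      n_mimics = 0L,
      lesion_volume_range_ml = c(0.05, 5),
      near_tract_fraction = 0.5
    ),
    phantom = list(
      grid_dim = c(96L, 96L, 48L),
      voxel_size = c(1.5, 1.5, 3)
    ),
    acquisition = list(
      b = 900,
      preset = "v1",
      snr = NULL,             # derived from preset when NULL
      motion = list(max_translation = 3, max_rotation = 3)
    ),
    analysis = list(
      bootstrap_b = 500L,
      k = 3,
      adc_max = 4e-3,
      isotropic_mm = 1,
      qc = list(supratentorial_min = 0.7, infratentorial_min = 0.1)
    ),
    output_dir = NULL
  ), class = "run_config")
}

preset_snr <- function(preset) switch(preset, v1 = 15, v2 = 20,
                                      stop("unknown preset: ", preset))

merge_config <- function(base, user, path = "") {
  for (nm in names(user)) {
    if (!nm %in% names(base))
      stop("unknown config key: ", paste0(path, nm))
    if (is.null(user[[nm]])) {
      base[nm] <- list(NULL)   # explicit NULL disables the feature
    } else if (is.list(base[[nm]]) && !is.null(names(base[[nm]]))) {
      if (!is.list(user[[nm]]))
        stop("config key ", paste0(path, nm), " must be a mapping")
      base[[nm]] <- merge_config(base[[nm]], user[[nm]],
                                 paste0(path, nm, "."))
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

validate_config <- function(cfg) {
  if (is.null(cfg$seed) || !is.finite(cfg$seed))
    stop("config must provide a seed")
  if (cfg$analysis$bootstrap_b < 1) stop("bootstrap_b must be >= 1")
  if (cfg$acquisition$b <= 0) stop("b must be > 0")
  if (any(cfg$phantom$voxel_size <= 0)) stop("voxel sizes must be > 0")
  if (cfg$cohort$n_subjects < 0 || cfg$cohort$n_mimics < 0)
    stop("subject counts must be >= 0")
  rng <- cfg$cohort$lesion_volume_range_ml
  if (length(rng) != 2L || any(rng <= 0) || rng[1] > rng[2])
    stop("lesion_volume_range_ml must be an increasing positive pair")
  if (is.null(cfg$acquisition$snr))
    cfg$acquisition$snr <- preset_snr(cfg$acquisition$preset)
  cfg
}

#' Load and validate a run configuration
#'
#' Reads a YAML or JSON configuration, fills defaults (b = 900 s/mm^2,
#' B = 500 bootstrap resamples, v1-like SNR preset, ...), rejects unknown
#' keys, and validates ranges.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated `run_config` list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(user$seed)) stop("config must provide a seed")
  cfg <- merge_config(unclass(default_config(user$seed)), user)
  cfg$seed <- as.integer(cfg$seed)
  cfg <- validate_config(cfg)
  class(cfg) <- "run_config"
  cfg
}

#' Normalise a configuration built in code
#'
#' Applies the same default-filling and validation as [load_config()] to a
#' partial configuration list.
#'
#' @param user Named list of overrides (must include `seed` or rely on the
#'   default seed 1).
#' @return A validated `run_config`.
#' @export
as_run_config <- function(user = list()) {
  seed <- if (!is.null(user$seed)) user$seed else 1L
  cfg <- merge_config(unclass(default_config(seed)), user)
  cfg <- validate_config(cfg)
  class(cfg) <- "run_config"
  cfg
}
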