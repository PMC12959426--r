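#' Generate a cohort dataset on disk
#'
#' Simulates `n_subjects` lesion subjects plus `n_mimics` stroke-mimic
#' subjects and writes, per subject, the b=0, the single-direction and the
#' three multi-direction diffusion volumes, the region and lesion masks
#' (NIfTI), and a ground-truth JSON; plus a cohort-level `manifest.json`
#' recording the configuration, seeds, true lesion volumes and produced
#' files.
#'
#' @param cfg A `run_config`.
#' @param dir Output directory (created if missing); defaults to
#'   `cfg$output_dir`.
#' @return The manifest, invisibly.
#' @export
generate_cohort <- function(cfg, dir = cfg$output_dir) {
  stopifnot(inherits(cfg, "run_config"), !is.null(dir))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n_total <- cfg$cohort$n_subjects + cfg$cohort$n_mimics
  subjects <- list()
  for (i in seq_len(n_total)) {
    mimic <- i > cfg$cohort$n_subjects
    sub <- simulate_subject(cfg, i, mimic = mimic)
    sdir <- file.path(dir, sub$id)
    dir.create(sdir, showWarnings = FALSE)
    paths <- list(b0 = file.path(sdir, "b0.nii.gz"),
                  dwi_sd = file.path(sdir, "dwi_sd_z.nii.gz"),
                  dwi_md = file.path(sdir, paste0("dwi_md_",
                                                  c("x", "y", "z"),
                                                  ".nii.gz")),
                  lesion = file.path(sdir, "lesion.nii.gz"))
    write_volume(sub$sd$b0, paths$b0)
    write_volume(sub$sd$dwi[[1]]$vol, paths$dwi_sd)
    for (j in 1:3)
      write_volume(sub$md$dwi[[j]]$vol, paths$dwi_md[j])
    write_volume(sub$truth$lesion, paths$lesion)
    for (nm in names(sub$truth$masks)) {
      p <- file.path(sdir, paste0("mask_", nm, ".nii.gz"))
      write_volume(sub$truth$masks[[nm]], p)
      paths[[paste0("mask_", nm)]] <- p
    }
    truth <- list(id = sub$id, seed = sub$seed, mimic = sub$mimic,
                  true_volume_ml = sub$true_volume_ml,
                  lesion_center_mm = sub$lesion_center,
                  qc_scores = as.list(sub$truth$qc_scores),
                  b = cfg$acquisition$b)
    jsonlite::write_json(truth, file.path(sdir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    subjects[[i]] <- c(truth, list(paths = paths))
  }
  cfg_json <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA,
                               null = "null")
  tmp <- tempfile(); writeLines(cfg_json, tmp)
  manifest <- list(config = unclass(cfg),
                   config_md5 = unname(tools::md5sum(tmp)),
                   subjects = subjects)
  unlink(tmp)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}

#' Load a subject's diffusion series from a cohort directory
#'
#' @param entry One element of a cohort manifest's `subjects` list.
#' @return List with `sd` and `md` `dwi_series`, the lesion mask, the
#'   region masks, and the truth record.
#' @export
load_subject <- function(entry) {
  b0 <- read_volume(entry$paths$b0)
  mk <- function(vols, dirs) {
    structure(list(b0 = b0,
                   dwi = Map(function(v, g) list(g = g, vol = v),
                             vols, dirs),
                   b = entry$b,
                   provenance = list(noise = "file", seed = entry$seed)),
              class = "dwi_series")
  }
  sd_series <- mk(list(read_volume(entry$paths$dwi_sd)),
                  list(c(0, 0, 1)))
  md_series <- mk(lapply(unlist(entry$paths$dwi_md), read_volume),
                  list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)))
  mask_names <- grep("^mask_", names(entry$paths), value = TRUE)
  masks <- lapply(entry$paths[mask_names], function(p) read_volume(p))
  names(masks) <- sub("^mask_", "", mask_names)
  list(sd = sd_series, md = md_series,
       lesion = read_volume(entry$paths$lesion), masks = masks,
       truth = entry[setdiff(names(entry), "paths")])
}

#' Cohort signal-uniformity analysis
#'
#' For every QC-passing subject, runs the processing chain and computes the
#' per-region signal standard deviation (lesion subtracted) on the
#' interpolated maps, for both sequence types and both map kinds (DWI
#' image and ADC map); then compares SD vs MD per region with the paired
#' Wilcoxon signed-rank test.
#'
#' @param cfg A `run_config`.
#' @param subjects Optional pre-simulated subject list (otherwise simulated
#'   from `cfg`).
#' @return List: `table` (long data frame: subject, sequence, map_kind,
#'   region, sd), `tests` (per region x map_kind Wilcoxon results),
#'   `n_excluded_qc`.
#' @export
run_uniformity <- function(cfg, subjects = NULL) {
  get_subject <- if (is.null(subjects)) {
    function(i) simulate_subject(cfg, i)   # one at a time: bounded memory
  } else {
    function(i) subjects[[i]]
  }
  n <- if (is.null(subjects)) cfg$cohort$n_subjects else length(subjects)
  qc <- cfg$analysis$qc
  n_excluded <- 0L
  rows <- list()
  for (i in seq_len(n)) {
    sub <- get_subject(i)
    if (!qc_gate(sub$truth$qc_scores, qc$supratentorial_min,
                 qc$infratentorial_min)) {
      n_excluded <- n_excluded + 1L
      next
    }
    proc <- process_subject(sub, cfg)
    masks <- proc$iso$masks[c("whole_brain", "white_matter",
                              "cortical_gm", "deep_gm")]
    maps <- list(sd_dwi = proc$iso$dwi_sd, md_dwi = proc$iso$trace_dwi,
                 sd_adc = proc$iso$adc_sd, md_adc = proc$iso$trace_adc)
    for (nm in names(maps)) {
      sds <- region_sd(maps[[nm]], masks, proc$iso$lesion)
      rows[[length(rows) + 1L]] <- data.frame(
        subject = sub$id,
        sequence = sub("_.*", "", nm),
        map_kind = sub(".*_", "", nm),
        region = names(sds), sd = unname(sds), row.names = NULL)
    }
  }
  tab <- do.call(rbind, rows)
  tests <- list()
  for (mk in unique(tab$map_kind)) {
    for (rg in unique(tab$region)) {
      sdv <- tab$sd[tab$map_kind == mk & tab$region == rg &
                    tab$sequence == "sd"]
      mdv <- tab$sd[tab$map_kind == mk & tab$region == rg &
                    tab$sequence == "md"]
      ok <- !is.na(sdv) & !is.na(mdv)
      tests[[paste(mk, rg, sep = ".")]] <-
        c(list(map_kind = mk, region = rg,
               n_md_lower = sum(mdv[ok] < sdv[ok]), n = sum(ok)),
          paired_wilcoxon(sdv[ok], mdv[ok]))
    }
  }
  list(table = tab, tests = tests, n_excluded_qc = n_excluded)
}

#' Cohort lesion-detection analysis
#'
#' Simulates (or accepts) a cohort, reads every subject on both sequence
#' types, and assembles the detection-record table; then computes, per
#' sequence type: ROC of detection against true lesion volume with the
#' Youden cut point; diagnostic accuracy (lesion subjects vs mimics) with
#' exact binomial CIs; and Fleiss kappa between two synthetic raters
#' (threshold multipliers `k` and `k + 0.5`) with a bootstrap CI,
#' restricted to lesions above `kappa_min_ml` (plus the mimics).
#'
#' @param cfg A `run_config`.
#' @param subjects Optional pre-simulated subject list.
#' @param kappa_min_ml Lesion-volume floor for the interrater analysis
#'   (default 1 mL, the reliably-seen size; `0` disables the floor).
#' @param reading `"dwi"` or `"adc"` reading map.
#' @return List: `records` (data frame), `roc`, `cutpoint`, `diagnostics`,
#'   `kappa` per sequence type.
#' @export
run_detection <- function(cfg, subjects = NULL, kappa_min_ml = 1,
                          reading = "adc") {
  get_subject <- if (is.null(subjects)) {
    function(i) simulate_subject(cfg, i,
                                 mimic = i > cfg$cohort$n_subjects)
  } else {
    function(i) subjects[[i]]
  }
  n <- if (is.null(subjects)) cfg$cohort$n_subjects + cfg$cohort$n_mimics
       else length(subjects)
  k <- cfg$analysis$k
  rows <- list()
  for (i in seq_len(n)) {
    sub <- get_subject(i)
    proc <- process_subject(sub, cfg)
    # pre-smooth the reading maps once; both raters share them
    for (nm in c("dwi_sd", "trace_dwi", "adc_sd", "trace_adc"))
      proc$iso[[nm]] <- masked_smooth(proc$iso[[nm]], proc$iso$parenchyma, 3)
    for (sq in c("sd", "md")) {
      r1 <- read_subject(proc, sub, sq, k = k, reading = reading,
                         smooth_mm = 0)
      r2 <- read_subject(proc, sub, sq, k = k + 0.5, reading = reading,
                         smooth_mm = 0)
      rows[[length(rows) + 1L]] <- data.frame(
        subject = sub$id, sequence = sq, mimic = sub$mimic,
        true_volume_ml = sub$true_volume_ml,
        detected = r1$detected, detected_rater2 = r2$detected,
        segmented_ml = r1$segmented_ml, row.names = NULL)
    }
  }
  records <- do.call(rbind, rows)
  out <- list(records = records)
  for (sq in c("sd", "md")) {
    rec <- records[records$sequence == sq, ]
    les <- rec[!rec$mimic, ]
    res <- list()
    if (nrow(les) >= 2 && any(les$detected) && !all(les$detected)) {
      res$roc <- roc_detection(les$true_volume_ml, les$detected)
      res$cutpoint <- youden_cutpoint(res$roc)
    }
    if (any(rec$mimic)) {
      mim <- rec[rec$mimic, ]
      res$diagnostics <- diagnostic_metrics(
        tp = sum(les$detected), fn = sum(!les$detected),
        tn = sum(!mim$detected), fp = sum(mim$detected))
    }
    kap <- rec[rec$mimic | rec$true_volume_ml > kappa_min_ml, ]
    ratings <- cbind(rater1 = as.integer(kap$detected),
                     rater2 = as.integer(kap$detected_rater2))
    res$kappa <- tryCatch(
      bootstrap_kappa(ratings, B = cfg$analysis$bootstrap_b,
                      seed = cfg$seed),
      error = function(e) list(error = conditionMessage(e)))
    out[[sq]] <- res
  }
  out
}
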