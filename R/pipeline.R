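#' Experiment configuration
#'
#' Bundles every tunable of a simulated volumetric-leaf-area experiment.
#' The defaults reproduce the package's reference bench conditions: 14
#' specimens (pieces to full leaves) spanning 60-3500 mm^2, a 0.001 g
#' balance, 0.01 mm micrometer reading noise with thickness sampled every
#' 2 cm, water at 22 degC, a 2000 mm^3 retainer, midrib share 2-8% of
#' volume with a +/-20% model mismatch, scans at 200 and 1200 dpi with
#' 1200 dpi as reference, and 100 virtual piles of 7.
#'
#' @param ... named overrides of the default fields (nested lists are
#'   merged field-wise).
#' @return object of class `vla_config`.
#' @examples
#' cfg <- vla_config(seed = 7, population = list(n = 10))
#' cfg$population$n
#' @export
vla_config <- function(...) {
  defaults <- list(
    population = list(
      n = 14L, area_range = c(60, 3500),
      midrib_fraction = c(0.02, 0.08), midrib_mismatch = 0.20,
      dim_mean = NULL, dim_cv = NULL),
    measurement = list(
      temperature = 22, balance_resolution = 0.001, weighing_noise_sd = 0,
      n_replicates = 3L, thickness_scheme = "every_2cm",
      thickness_noise_sd = 0.01,
      retainer_volume = 2000, retainer_weight = 20),
    optical = list(dpi = c(200L, 1200L), reference_dpi = 1200L),
    resampling = list(
      group_size = 7L, n_groups = 100L,
      thickness_population_n = 35L, thickness_k = 5L,
      thickness_groups = 100L, thickness_mean = 0.25, thickness_cv = 0.12),
    seed = 1L)
  # field-wise merge that, unlike modifyList(), keeps explicit NULLs (they
  # mark "use the built-in population defaults" and must survive YAML)
  merge_keep_null <- function(base, override) {
    for (nm in names(override)) base[nm] <- list(override[[nm]])
    base
  }
  overrides <- list(...)
  for (nm in names(overrides)) {
    if (is.list(defaults[[nm]]) && is.list(overrides[[nm]])) {
      defaults[[nm]] <- merge_keep_null(defaults[[nm]], overrides[[nm]])
    } else {
      defaults[[nm]] <- overrides[[nm]]
    }
  }
  structure(defaults, class = "vla_config")
}

#' @export
print.vla_config <- function(x, ...) {
  cat("VLA experiment configuration\n")
  cat(yaml::as.yaml(unclass(x)))
  invisible(x)
}

#' Read / write an experiment configuration as YAML
#'
#' The YAML round trip is lossless for every configuration field; each
#' pipeline run writes its resolved configuration beside its outputs.
#'
#' @param config a [vla_config()].
#' @param path file path.
#' @return `read_config` returns a `vla_config`; `write_config` the path,
#'   invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "vla_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  do.call(vla_config, yaml::read_yaml(path))
}

# Deterministic sub-seeds for the pipeline stages, all below 2^31.
stage_seeds <- function(seed, n = 8) {
  with_seed(seed, sample.int(.Machine$integer.max - 1, n))
}

#' Simulate a complete bench dataset
#'
#' Generates the specimen set with ground truth, the simulated suspension
#' weighing records, the sampled (noisy) mean thicknesses and the optical
#' areas at every configured resolution — everything the downstream
#' volumetry, agreement and resampling stages consume.
#'
#' @param config a [vla_config()].
#' @return list of class `vla_dataset`: `specimens` (list of
#'   [leaf_specimen()]), `truth` (ground-truth data.frame), `records`
#'   (named list of [suspension_record()]), and `measurements` (data.frame
#'   with measured thickness and per-dpi optical areas).
#' @export
simulate_dataset <- function(config = vla_config()) {
  stopifnot(inherits(config, "vla_config"))
  seeds <- stage_seeds(config$seed)
  pop <- config$population
  meas <- config$measurement
  params <- population_params()
  if (!is.null(pop$dim_mean) || !is.null(pop$dim_cv)) {
    params <- population_params(
      mean = unlist(pop$dim_mean) %||% params$mean,
      cv = unlist(pop$dim_cv) %||% params$cv)
  }
  specimens <- sample_leaf_pieces(
    n = pop$n, area_range = pop$area_range, params = params,
    midrib_fraction = pop$midrib_fraction,
    midrib_mismatch = pop$midrib_mismatch, seed = seeds[1])
  truth <- specimen_truth(specimens)
  records <- with_seed(seeds[2], {
    lapply(specimens, function(s) {
      simulate_suspension_weighing(
        true_volume(s, include_midrib = TRUE),
        temp = meas$temperature,
        retainer_volume = meas$retainer_volume,
        n_replicates = meas$n_replicates,
        noise_sd = meas$weighing_noise_sd,
        resolution = meas$balance_resolution)
    })
  })
  names(records) <- truth$specimen_id
  thickness <- with_seed(seeds[3], {
    vapply(specimens, function(s) {
      mean_thickness(s, scheme = meas$thickness_scheme,
                     noise_sd = meas$thickness_noise_sd)
    }, numeric(1))
  })
  dpis <- unique(c(config$optical$dpi, config$optical$reference_dpi))
  ola <- with_seed(seeds[4], {
    sapply(dpis, function(d) {
      vapply(specimens, function(s) {
        optical_area(s, d, rotation = runif(1, 0, pi), offset = runif(2, 0, 1))
      }, numeric(1))
    })
  })
  ola <- matrix(ola, nrow = length(specimens))
  colnames(ola) <- paste0("ola_", dpis, "dpi")
  measurements <- cbind(
    data.frame(specimen_id = truth$specimen_id, thickness = thickness),
    as.data.frame(ola))
  structure(list(specimens = specimens, truth = truth, records = records,
                 measurements = measurements, config = config),
            class = "vla_dataset")
}

#' Volumetry results for a simulated dataset
#'
#' Applies the suspension volumetry and the VLA estimator to every
#' specimen: retainer and leaf volumes from the weighing records, the
#' cylinder/cone midrib model from the specimen geometry (model selected by
#' completeness), and VLA with and without midrib exclusion.
#'
#' @param dataset a [simulate_dataset()] result.
#' @return data.frame with columns `specimen_id`, `V_r`, `V_l`, `V_m`,
#'   `V_l_excl`, `T_l`, `VLA_incl`, `VLA_excl`, `n_replicates_used`.
#' @export
measure_dataset <- function(dataset) {
  stopifnot(inherits(dataset, "vla_dataset"))
  meas <- dataset$config$measurement
  rows <- lapply(seq_along(dataset$specimens), function(i) {
    s <- dataset$specimens[[i]]
    rec <- dataset$records[[i]]
    rho <- water_density(rec$temp[1])
    V_r <- mean(retainer_volume(rec$dW_r, rec$temp))
    vol <- leaf_volume_suspension(rec, V_r = V_r,
                                  resolution = meas$balance_resolution)
    V_m <- midrib_model_volume(s)
    T_l <- dataset$measurements$thickness[i]
    data.frame(
      specimen_id = s$id, V_r = V_r, V_l = vol$V_l, V_m = V_m,
      V_l_excl = vol$V_l - V_m, T_l = T_l,
      VLA_incl = volumetric_leaf_area(vol$V_l, T_l),
      VLA_excl = volumetric_leaf_area(vol$V_l, T_l, V_m),
      n_replicates_used = vol$n_used)
  })
  do.call(rbind, rows)
}

#' Run the full virtual experiment
#'
#' Simulation, volumetry, optical measurement, method agreement, the
#' resolution study, the pile analysis and the thickness-sampling
#' experiment, in one seeded pipeline.
#'
#' @param config a [vla_config()].
#' @return object of class `vla_experiment`: list with the `dataset`, the
#'   volumetry table, the per-specimen agreement fits (midrib included and
#'   excluded), resolution-study NRMSEs, the [pile_analysis()] object, the
#'   [thickness_sampling_experiment()] result, and a flat `summary` of the
#'   headline statistics.
#' @export
run_experiment <- function(config = vla_config()) {
  seeds <- stage_seeds(config$seed)
  dataset <- simulate_dataset(config)
  volumetry <- measure_dataset(dataset)
  ref_col <- paste0("ola_", config$optical$reference_dpi, "dpi")
  ref_ola <- dataset$measurements[[ref_col]]
  agree_incl <- method_agreement(ref_ola, volumetry$VLA_incl,
                                 labels = c("OLA", "VLA (midrib incl.)"))
  agree_excl <- method_agreement(ref_ola, volumetry$VLA_excl,
                                 labels = c("OLA", "VLA (midrib excl.)"))
  res_nrmse <- data.frame(
    dpi = config$optical$dpi,
    nrmse_pct = vapply(config$optical$dpi, function(d) {
      nrmse(ref_ola, dataset$measurements[[paste0("ola_", d, "dpi")]])
    }, numeric(1)))
  rs <- config$resampling
  piles <- pile_analysis(volumetry$V_l, volumetry$T_l, ref_ola,
                         midrib_volumes = volumetry$V_m,
                         group_size = rs$group_size, n_groups = rs$n_groups,
                         seed = seeds[5])
  thick_pop <- with_seed(seeds[6], {
    rlnorm_mean_cv(rs$thickness_population_n, rs$thickness_mean,
                   rs$thickness_cv)
  })
  thick <- thickness_sampling_experiment(thick_pop, k = rs$thickness_k,
                                         n_groups = rs$thickness_groups,
                                         seed = seeds[7])
  summary <- data.frame(
    nrmse_incl_pct = agree_incl$nrmse_pct,
    nrmse_excl_pct = agree_excl$nrmse_pct,
    slope_incl = agree_incl$slope, slope_excl = agree_excl$slope,
    bias_incl = agree_incl$bias, bias_excl = agree_excl$bias,
    pile_nrmse_incl_pct = piles$agreement_incl$nrmse_pct,
    pile_nrmse_excl_pct = piles$agreement_excl$nrmse_pct,
    pile_slope_incl = piles$agreement_incl$slope,
    pile_slope_excl = piles$agreement_excl$slope,
    pile_bias_incl = piles$agreement_incl$bias,
    pile_bias_excl = piles$agreement_excl$bias,
    thickness_sampling_diff_pct = thick$pct_difference)
  structure(list(dataset = dataset, volumetry = volumetry,
                 agreement_incl = agree_incl, agreement_excl = agree_excl,
                 resolution_nrmse = res_nrmse, piles = piles,
                 thickness_sampling = thick, summary = summary,
                 config = config),
            class = "vla_experiment")
}

#' @export
print.vla_experiment <- function(x, ...) {
  cat(sprintf("Volumetric leaf-area experiment (n = %d specimens, seed = %d)\n",
              x$config$population$n, x$config$seed))
  cat(sprintf("  VLA vs OLA: NRMSE %.3f%% (midrib incl.) / %.3f%% (excl.); slopes %.4f / %.4f\n",
              x$summary$nrmse_incl_pct, x$summary$nrmse_excl_pct,
              x$summary$slope_incl, x$summary$slope_excl))
  cat(sprintf("  biases %.2f / %.2f mm^2\n",
              x$summary$bias_incl, x$summary$bias_excl))
  for (i in seq_len(nrow(x$resolution_nrmse))) {
    cat(sprintf("  OLA %d dpi vs %d dpi: NRMSE %.4f%%\n",
                x$resolution_nrmse$dpi[i], x$config$optical$reference_dpi,
                x$resolution_nrmse$nrmse_pct[i]))
  }
  cat(sprintf("  pile analysis: NRMSE %.3f%% / %.3f%%, slopes %.4f / %.4f\n",
              x$summary$pile_nrmse_incl_pct, x$summary$pile_nrmse_excl_pct,
              x$summary$pile_slope_incl, x$summary$pile_slope_excl))
  cat(sprintf("  thickness-sampling difference: %.3f%%\n",
              x$summary$thickness_sampling_diff_pct))
  invisible(x)
}

#' Write a simulated dataset (and optionally its scans) to disk
#'
#' Writes the ground-truth specimen table, the per-replicate weighing
#' records, the measurement table and the resolved configuration to
#' `outdir`, plus a `manifest.csv` with MD5 checksums. Scans are written as
#' PNG (dpi in both the metadata and the filename) at the smallest
#' configured resolution when `write_scans = TRUE`.
#'
#' @param config a [vla_config()].
#' @param outdir output directory (created if needed).
#' @param write_scans write PNG scans of every specimen?
#' @return the manifest data.frame, invisibly.
#' @export
vla_simulate <- function(config = vla_config(), outdir,
                         write_scans = FALSE) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  if (config$population$n >= 1) {
    dataset <- simulate_dataset(config)
    weighings <- do.call(rbind, lapply(names(dataset$records), function(id) {
      cbind(specimen_id = id, as.data.frame(dataset$records[[id]]))
    }))
    tabs <- list(specimens.csv = dataset$truth,
                 weighings.csv = weighings,
                 measurements.csv = dataset$measurements)
    for (nm in names(tabs)) {
      write.csv(tabs[[nm]], file.path(outdir, nm), row.names = FALSE)
      files <- c(files, nm)
    }
    if (write_scans) {
      d <- min(config$optical$dpi)
      seeds <- stage_seeds(config$seed)
      with_seed(seeds[8], {
        for (s in dataset$specimens) {
          p <- write_scan(render_scan(s, d, rotation = runif(1, 0, pi),
                                      offset = runif(2, 0, 1)), outdir)
          files <- c(files, basename(p))
        }
      })
    }
  }
  write_config(config, file.path(outdir, "config.yaml"))
  files <- c(files, "config.yaml")
  manifest <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(outdir, files))))
  write.csv(manifest, file.path(outdir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Run the full experiment and write all result tables
#'
#' @param config a [vla_config()].
#' @param outdir output directory.
#' @return the [run_experiment()] object, invisibly.
#' @export
vla_run_all <- function(config = vla_config(), outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  exp <- run_experiment(config)
  write.csv(exp$volumetry, file.path(outdir, "volumetry.csv"), row.names = FALSE)
  write.csv(exp$dataset$measurements, file.path(outdir, "measurements.csv"),
            row.names = FALSE)
  write.csv(exp$piles$piles, file.path(outdir, "piles.csv"), row.names = FALSE)
  write.csv(thickness_sampling_histogram(exp$thickness_sampling),
            file.path(outdir, "thickness_sampling_hist.csv"), row.names = FALSE)
  write.csv(exp$resolution_nrmse, file.path(outdir, "resolution_nrmse.csv"),
            row.names = FALSE)
  write.csv(exp$summary, file.path(outdir, "summary.csv"), row.names = FALSE)
  write_config(config, file.path(outdir, "config.yaml"))
  invisible(exp)
}

#' Compute leaf volume and VLA from user-supplied weighing records
#'
#' The field-use entry point: applies the suspension or SGB volumetry and
#' the VLA estimator to real measurements. `weights` is a data.frame or
#' CSV path with one row per replicate: columns `specimen_id`, `temp`, and
#' either `dW_r`/`dW_t` (suspension) or `W_r1`/`W_l1`/`W_T2` (and
#' optionally `W_r2`) for the SGB. `thickness` (data.frame or CSV:
#' `specimen_id`, `thickness`; several rows per specimen are averaged)
#' enables the VLA columns. Optional midrib columns in `weights`
#' (`midrib_length`, `midrib_diameter`, `complete_leaf`) enable the
#' midrib-excluded variant. Rows that fail validation are reported
#' per-specimen and skipped.
#'
#' @param weights data.frame or CSV path of weighing records.
#' @param thickness optional data.frame or CSV path of thickness readings.
#' @param method `"suspension"` or `"sgb"`.
#' @param V_r retainer volume in mm^3; derived from the record when `NULL`.
#' @return data.frame with `specimen_id`, `V_r`, `V_l`,
#'   `n_replicates_used`, and (when available) `V_m`, `T_l`, `VLA_incl`,
#'   `VLA_excl`; failed specimens are collected in attribute `"problems"`.
#' @export
measure_vla <- function(weights, thickness = NULL,
                        method = c("suspension", "sgb"), V_r = NULL) {
  method <- match.arg(method)
  if (is.character(weights)) weights <- read.csv(weights)
  if (is.character(thickness)) thickness <- read.csv(thickness)
  if (nrow(weights) == 0) {
    warning("empty weighing table: nothing to measure")
    return(data.frame(specimen_id = character(0), V_r = numeric(0),
                      V_l = numeric(0), n_replicates_used = integer(0)))
  }
  if (!"specimen_id" %in% names(weights)) {
    weights$specimen_id <- "sample-1"
  }
  t_mean <- NULL
  if (!is.null(thickness)) {
    t_mean <- tapply(thickness$thickness, thickness$specimen_id, mean)
  }
  problems <- character(0)
  rows <- list()
  for (id in unique(weights$specimen_id)) {
    w <- weights[weights$specimen_id == id, , drop = FALSE]
    res <- tryCatch({
      if (method == "suspension") {
        rec <- suspension_record(w$dW_r, w$dW_t, w$temp[1])
        vr <- V_r %||% mean(retainer_volume(rec$dW_r, rec$temp))
        vol <- leaf_volume_suspension(rec, V_r = vr)
      } else {
        rec <- sgb_record(W_r1 = w$W_r1[1], W_l1 = w$W_l1, W_T2 = w$W_T2,
                          temp = w$temp[1],
                          W_r2 = if ("W_r2" %in% names(w)) w$W_r2 else NA_real_)
        vr <- V_r %||%
          mean((rec$W_r1 - rec$W_r2) / water_density(rec$temp))
        vol <- leaf_volume_sgb(rec, V_r = vr)
      }
      out <- data.frame(specimen_id = id, V_r = vr, V_l = vol$V_l,
                        n_replicates_used = vol$n_used)
      if (all(c("midrib_length", "midrib_diameter") %in% names(w))) {
        model <- if (isTRUE(w$complete_leaf[1])) "cone" else "cylinder"
        out$V_m <- midrib_volume(w$midrib_length[1], w$midrib_diameter[1],
                                 model)
      }
      if (!is.null(t_mean) && id %in% names(t_mean)) {
        out$T_l <- unname(t_mean[id])
        out$VLA_incl <- volumetric_leaf_area(out$V_l, out$T_l)
        out$VLA_excl <- if (!is.null(out$V_m)) {
          volumetric_leaf_area(out$V_l, out$T_l, out$V_m)
        } else {
          NA_real_
        }
      }
      out
    }, error = function(e) {
      problems <<- c(problems, sprintf("%s: %s", id, conditionMessage(e)))
      NULL
    })
    if (!is.null(res)) rows[[length(rows) + 1]] <- res
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(specimen_id = character(0))
  if (length(problems)) {
    warning(sprintf("%d specimen(s) failed validation; see attr(result, 'problems')",
                    length(problems)))
    attr(out, "problems") <- problems
  }
  out
}
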