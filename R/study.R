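#' Study configuration
#'
#' The full factorial grid of the simulated phantom study: motion classes by
#' CT dataset type (AIP/MIP) by delivery method (gated/nongated) by planning
#' technique, with a number of independently seeded delivery sessions per
#' cell. Every stochastic stage (trace generation, imaging noise, film noise)
#' derives its seed from `base_seed`, so a config reproduces its report
#' bundle bit for bit.
#'
#' @param motion_classes Irregular motion classes in the grid.
#' @param n_delivery_seeds Delivery sessions per grid cell (>= 1); with both
#'   CT types in the grid, each motion class gets `2 * n_delivery_seeds`
#'   independently seeded sessions.
#' @param base_seed Master seed; all stage seeds are small offsets of it.
#' @param n_phases Phase bins for the geometry analysis (10 or 20).
#' @param phantom A [phantom_spec()].
#' @param acquisition An [acquisition_config()].
#' @param techniques Planning techniques to include.
#' @param ct_types CT dataset types used for ITV delineation.
#' @param gated_window Gated phase window in percent.
#' @param nongated_range Phase range of the nongated ITV (all phases).
#' @param ptv_margin Uniform GTV/ITV-to-PTV margin in mm.
#' @param dp Prescription dose in Gy.
#' @param film_noise_frac Film pixel-value noise fraction.
#' @param gamma A [gamma_criteria()].
#' @param trace_duration_4dct Imaging-session trace length in s.
#' @param output_dir Directory for the CSV report bundle (NULL = don't write).
#' @return An object of class `study_config`.
#' @export
study_config <- function(motion_classes = c("S-I", "A-I", "P-I", "P+A-I"),
                         n_delivery_seeds = 5L, base_seed = 2024L,
                         n_phases = 10L,
                         phantom = phantom_spec(),
                         acquisition = acquisition_config(n_phases = n_phases),
                         techniques = "sliding_window",
                         ct_types = c("AIP", "MIP"),
                         gated_window = c(30, 70),
                         nongated_range = c(0, 100),
                         ptv_margin = 5, dp = 6,
                         film_noise_frac = 0.003,
                         gamma = gamma_criteria(norm = dp),
                         trace_duration_4dct = 90,
                         output_dir = NULL) {
  acquisition$n_phases <- as.integer(n_phases)
  structure(list(
    motion_classes = motion_classes,
    n_delivery_seeds = as.integer(n_delivery_seeds),
    base_seed = as.integer(base_seed), n_phases = as.integer(n_phases),
    phantom = phantom, acquisition = acquisition,
    techniques = techniques, ct_types = ct_types,
    gated_window = gated_window, nongated_range = nongated_range,
    ptv_margin = ptv_margin, dp = dp,
    film_noise_frac = film_noise_frac, gamma = gamma,
    trace_duration_4dct = trace_duration_4dct,
    output_dir = output_dir
  ), class = "study_config")
}

#' Read a study configuration from YAML
#'
#' Scalar fields of [study_config()] can be overridden from a YAML file with
#' per-module sections (`study:`, `acquisition:`, `plan:`, `film:`,
#' `gamma:`).
#'
#' @param path YAML file path.
#' @return A `study_config`.
#' @export
read_study_config <- function(path) {
  y <- yaml::read_yaml(path)
  s <- y$study %||% list()
  acq <- do.call(acquisition_config, y$acquisition %||% list())
  gam <- do.call(gamma_criteria, y$gamma %||% list())
  if (is.null(s$n_phases) && !is.null(y$acquisition$n_phases)) {
    s$n_phases <- y$acquisition$n_phases
  }
  args <- c(s, list(acquisition = acq, gamma = gam))
  args <- args[names(args) %in% names(formals(study_config))]
  do.call(study_config, args)
}

# deterministic per-stage seeds, kept far apart and below 2^31
.stage_seed <- function(config, stage, i = 0L) {
  (config$base_seed * 7L + match(stage, c("imaging", "delivery", "film", "calibration")) * 10007L +
     as.integer(i) * 131L) %% 2000000011L
}

# trace for a motion class (regular -> pure sinusoid)
study_trace <- function(motion_class, seed, duration, rate = 25) {
  if (motion_class == "regular") {
    generate_regular(sinusoid_params(), duration = duration, rate = rate)
  } else {
    generate_irregular(breathing_spec(motion_class, seed = seed),
                       duration = duration, rate = rate)
  }
}

# 4D CT + projections + gated/nongated ITVs for one motion class
.class_geometry <- function(config, motion_class, seed) {
  trace <- study_trace(motion_class, seed, config$trace_duration_4dct)
  pvs <- simulate_4dct(config$phantom, trace, config$acquisition)
  aip <- project(pvs, "AIP")
  mip <- project(pvs, "MIP")
  gated <- config$gated_window
  nong <- config$nongated_range
  itv <- list(
    AIP = list(gated = segment_projection_itv(aip, pvs, gated),
               nongated = segment_projection_itv(aip, pvs, nong)),
    MIP = list(gated = segment_projection_itv(mip, pvs, gated),
               nongated = segment_projection_itv(mip, pvs, nong))
  )
  list(trace = trace, pvs = pvs, aip = aip, mip = mip, itv = itv)
}

#' ITV on a projection image restricted to a phase window
#'
#' The study delineates gated ITVs on MIP/AIP images rebuilt from the gated
#' phase subset. This helper projects the given phase subset and segments the
#' target on it; with the full phase range it reproduces the nongated
#' MIP/AIP ITV.
#'
#' The default delineation threshold on projections is 15% target occupancy
#' (`insert_HU + 0.15 * (target_HU - insert_HU)`, -666 HU with the default
#' materials), a lung-window-like setting standing in for the clinical
#' auto-contour-plus-manual-edit workflow: on AIP images the moving target is
#' smeared to a faint average, and the half-occupancy GTV rule would erase
#' most of it. See the methods vignette for the calibration reasoning.
#'
#' @param projection A `projection_volume` (used for its kind).
#' @param pvs The source `phase_volume_set`.
#' @param phase_range Phase window in percent.
#' @param threshold Optional segmentation threshold (HU); default 15%
#'   occupancy.
#' @return A `structure_mask` labelled `"ITV"`.
#' @export
segment_projection_itv <- function(projection, pvs, phase_range = c(0, 100),
                                   threshold = NULL) {
  kind <- attr(projection, "kind")
  if (is.null(threshold)) {
    spec <- attr(projection, "phantom_spec")
    if (is.null(spec)) stop_breathe4d("`threshold` required without phantom provenance")
    threshold <- spec$insert_HU + 0.15 * (spec$target_HU - spec$insert_HU)
  }
  sel <- pvs$phases >= phase_range[1] & pvs$phases <= phase_range[2]
  if (!any(sel)) stop_breathe4d("no phases in the requested range")
  sub <- project(pvs, kind, phases = pvs$phases[sel])
  m <- segment_target(sub, threshold)
  m$label <- "ITV"
  m
}

#' Run the simulated phantom study
#'
#' Executes the full pipeline over the configured grid — breathing traces,
#' 4D CT, MIP/AIP reconstruction, GTV/ITV/PTV delineation, planning, gated
#' and nongated delivery, synthetic film, gamma analysis — and emits the four
#' report tables: phase-by-phase target positions for regular motion
#' (`table2`), static/regular target volumetry (`table3`), irregular-pattern
#' ITV variations (`table4`), and passing rates with paired comparisons
#' (`table5`, `tests`). When `config$output_dir` is set the tables are also
#' written as `table2.csv` ... `table5.csv` plus `tests.csv` and a
#' `config.json` sidecar carrying the config hash stamped into every table.
#'
#' @param config A [study_config()].
#' @param progress Print stage progress to stderr.
#' @return Invisibly, a named list of tibbles plus the config hash.
#' @export
run_study <- function(config = study_config(), progress = FALSE) {
  stopifnot(inherits(config, "study_config"))
  say <- function(...) if (progress) message(sprintf(...))
  hash <- config_hash(config)
  phantom <- config$phantom
  vt <- itv_theoretical(phantom$target_radius, 0)

  ## --- regular-motion geometry: tables 2 and 3 -------------------------
  say("geometry: static + regular motion")
  static_ct <- simulate_static_ct(phantom, config$acquisition)
  gtv_static <- segment_target(static_ct)
  reg_trace <- study_trace("regular", .stage_seed(config, "imaging", 0L),
                           config$trace_duration_4dct)
  table2 <- dplyr::bind_rows(lapply(c(10L, 20L), function(np) {
    acq <- config$acquisition
    acq$n_phases <- np
    pvs <- simulate_4dct(phantom, reg_trace, acq)
    keep <- c(0, 25, 50, 75)
    tb <- phase_position_table(pvs, sinusoid_params())
    dplyr::mutate(tb[tb$phase %in% keep, ], ct_type = sprintf("%d-phase", np),
                  .before = 1)
  }))

  reg_pvs <- simulate_4dct(phantom, reg_trace, config$acquisition)
  reg_aip <- segment_projection_itv(project(reg_pvs, "AIP"), reg_pvs, config$nongated_range)
  reg_mip <- segment_projection_itv(project(reg_pvs, "MIP"), reg_pvs, config$nongated_range)
  itv_th <- itv_theoretical(phantom$target_radius, 2 * sinusoid_params()$A)
  table3 <- tibble(
    ct_type = c("static", "AIP", "MIP"),
    volume_cm3 = c(mask_volume_cm3(gtv_static), mask_volume_cm3(reg_aip),
                   mask_volume_cm3(reg_mip)),
    reference_cm3 = c(vt, itv_th, itv_th)
  )
  table3$variation_pct <- variation(table3$volume_cm3, table3$reference_cm3)

  ## --- irregular-motion geometry: table 4 ------------------------------
  geoms <- list()
  rows4 <- list()
  for (cl in config$motion_classes) {
    say("geometry: %s", cl)
    g <- .class_geometry(config, cl, .stage_seed(config, "imaging", match(cl, config$motion_classes)))
    geoms[[cl]] <- g["itv"]  # keep masks only
    for (dlv in c("gated", "nongated")) {
      va <- mask_volume_cm3(g$itv$AIP[[dlv]])
      vm <- mask_volume_cm3(g$itv$MIP[[dlv]])
      rows4[[paste(cl, dlv)]] <- tibble(
        phase_range = if (dlv == "gated") "gated 30%-70%" else "nongated (all phases)",
        motion_class = cl, delivery = dlv,
        itv_aip_cm3 = va, itv_mip_cm3 = vm,
        variation_aip_mip_pct = variation(va, vm))
    }
    rm(g)
  }
  table4 <- dplyr::bind_rows(rows4)

  ## --- dosimetry: table 5 ----------------------------------------------
  say("dosimetry: calibration + static chain")
  truth <- film_truth()
  cal <- make_calibration_data(noise_frac = config$film_noise_frac,
                               seed = .stage_seed(config, "calibration"))
  curve <- fit_calibration(cal$dose_gy, cal$net_od)

  score_one <- function(plan, trace, film_seed) {
    delivered <- deliver(plan, trace)
    scan <- simulate_film_response(delivered, truth,
                                   noise_frac = config$film_noise_frac,
                                   seed = film_seed)
    measured <- scan_to_dose(scan, curve)
    roi <- target_roi(gtv_static, plan$x, plan$y, 2)
    passing_rate(gamma_2d(plan$planned, measured, config$gamma, roi))
  }

  rows5 <- list()
  for (tech in config$techniques) {
    ptv_static <- expand_margin(gtv_static, config$ptv_margin)
    plan_static <- build_plan(ptv_static, plan_spec(tech, dp = config$dp))
    tt <- seq(0, plan_static$beam_on_time + 30, by = 1 / 25)
    flat <- new_motion_trace(tt, rep(0, length(tt)), 25, "static")
    pr <- score_one(plan_static, flat, .stage_seed(config, "film", 0L))
    rows5[[paste("static", tech)]] <- tibble(
      motion_class = "static", ct_type = "static", technique = tech,
      delivery = "static", seed_index = 0L, passing_rate = pr)
  }

  idx <- 1L
  for (cl in config$motion_classes) {
    for (ct in config$ct_types) {
      for (tech in config$techniques) {
        plans <- lapply(c(gated = "gated", nongated = "nongated"), function(dlv) {
          itv <- geoms[[cl]]$itv[[ct]][[dlv]]
          ptv <- expand_margin(itv, config$ptv_margin)
          gated <- dlv == "gated"
          build_plan(ptv, plan_spec(
            tech, dp = config$dp,
            gating_window = if (gated) config$gated_window else NULL,
            gate_corridor = if (gated) {
              gate_corridor_from_itv(itv, config$phantom$target_radius)
            }))
        })
        for (k in seq_len(config$n_delivery_seeds)) {
          say("dosimetry: %s %s %s session %d", cl, ct, tech, k)
          tr_seed <- .stage_seed(config, "delivery", idx)
          for (dlv in c("gated", "nongated")) {
            dur <- ceiling(plans[[dlv]]$beam_on_time /
                             (if (dlv == "gated") 0.12 else 0.95)) + 120
            trace <- study_trace(cl, tr_seed, duration = dur)
            pr <- score_one(plans[[dlv]], trace,
                            .stage_seed(config, "film", idx))
            rows5[[paste(cl, ct, tech, dlv, k)]] <- tibble(
              motion_class = cl, ct_type = ct, technique = tech,
              delivery = dlv, seed_index = k, passing_rate = pr)
            idx <- idx + 1L
          }
        }
      }
    }
  }
  table5 <- dplyr::bind_rows(rows5)

  ## --- paired comparisons ----------------------------------------------
  dyn <- table5[table5$delivery %in% c("gated", "nongated"), ]
  wide <- tidyr::pivot_wider(dyn, names_from = "delivery",
                             values_from = "passing_rate")
  tests <- dplyr::bind_rows(
    if (nrow(wide) >= 2) {
      dplyr::mutate(paired_comparison(wide$gated, wide$nongated),
                    comparison = "gated vs nongated (pooled)", .before = 1)
    },
    {
      byct <- tidyr::pivot_wider(dplyr::select(dyn, -"seed_index"),
                                 names_from = "ct_type",
                                 values_from = "passing_rate",
                                 values_fn = list)
      if (all(c("AIP", "MIP") %in% names(byct))) {
        byct <- tidyr::unnest(byct, c("AIP", "MIP"))
        dplyr::bind_rows(lapply(split(byct, byct$delivery), function(df) {
          if (nrow(df) < 2) return(NULL)
          dplyr::mutate(paired_comparison(df$AIP, df$MIP),
                        comparison = sprintf("AIP vs MIP (%s)", df$delivery[1]),
                        .before = 1)
        }))
      } else NULL
    }
  )

  out <- list(table2 = table2, table3 = table3, table4 = table4,
              table5 = table5, tests = tests, config_hash = hash)
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in c("table2", "table3", "table4", "table5", "tests")) {
      readr::write_csv(dplyr::mutate(out[[nm]], config_hash = hash),
                       file.path(config$output_dir, paste0(nm, ".csv")))
    }
    jsonlite::write_json(list(config_hash = hash,
                              base_seed = config$base_seed,
                              motion_classes = config$motion_classes,
                              n_delivery_seeds = config$n_delivery_seeds,
                              n_phases = config$n_phases),
                         file.path(config$output_dir, "config.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(out)
}

#' Hash of a study configuration
#'
#' MD5 of the JSON-serialized scalar configuration, stamped into every report
#' table so outputs can be traced to their config.
#'
#' @param config A `study_config`.
#' @return A character hash.
#' @export
config_hash <- function(config) {
  flat <- config
  flat$output_dir <- NULL
  flat$phantom <- unclass(flat$phantom)
  flat$acquisition <- unclass(flat$acquisition)
  flat$gamma <- unclass(flat$gamma)
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(flat, tmp, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tmp))
}
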