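# Cohort-level simulation, measurement and reporting: an end-to-end
# emulation of the 10-specimen study design. Each simulated specimen
# carries the six facet patches the study measured: the fourth CMC pair
# (concave hamate facet, convex metacarpal base), the fifth CMC pair
# (biconcave hamate / biconvex base), and the intermetacarpal facet pair
# (concave on the fourth, convex on the fifth metacarpal).

# Printed cohort envelopes (mm, degrees, percent) used for parameter
# draws; per-specimen values were never published, so draws are uniform
# over the reported ranges.
cohort_ranges <- list(
  hamate4_roc = c(4.12, 21.07),
  mc4_roc = c(4.59, 19.82),
  hamate5_radial = c(5.99, 10.82),
  hamate5_ulnar = c(7.75, 18.74),
  hamate5_div = c(14.3, 35.9),
  hamate5_ulnar_frac = c(19, 51.14),
  mc5_radial = c(6.03, 8.85),
  mc5_ulnar = c(5.71, 12.01),
  mc5_div = c(2, 18.7),
  mc5_ulnar_frac = c(18.9, 43.59),
  imc4_roc = c(6.97, 19.2),
  imc5_roc = c(7.9, 18.37)
)

#' Generate a simulated study cohort
#'
#' Draws per-specimen facet parameters uniformly from the published
#' cohort envelopes and generates ground-truthed meshes for all six
#' facets per specimen: single caps for the fourth CMC pair and the
#' intermetacarpal pair, bicondylar patches for the fifth CMC pair.
#' Roughly six of ten fourth-CMC hamate facets receive a flattened
#' dorsal region (each with probability 0.6), matching the study's
#' observed prevalence. Output is deterministic per seed.
#'
#' @param n_specimens Number of specimens (>= 1).
#' @param seed Integer seed controlling all draws and mesh noise.
#' @param noise_sd Scan-noise sd in mm (default 0.1).
#' @param resolution Mesh resolution in mm (default 0.3; cohort-scale
#'   runs use a coarser grid than single-facet analyses).
#' @return List with `facets` (named list of `generate_*` outputs, names
#'   `<specimen>_<role>`), `ground_truth` (tibble of generating
#'   parameters) and `manifest` (tibble: specimen_id, name, role, kind).
#' @export
generate_study_cohort <- function(n_specimens, seed = 1L, noise_sd = 0.1,
                                  resolution = 0.3) {
  if (n_specimens < 1) fm_abort("n_specimens must be >= 1", "fm_validation_error")
  rg <- cohort_ranges
  draws <- with_seed(seed, {
    lapply(seq_len(n_specimens), function(i) {
      list(
        hamate4_roc = runif(1, rg$hamate4_roc[1], rg$hamate4_roc[2]),
        hamate4_flat = rbinom(1, 1, 0.6) == 1,
        mc4_roc = runif(1, rg$mc4_roc[1], rg$mc4_roc[2]),
        h5_radial = runif(1, rg$hamate5_radial[1], rg$hamate5_radial[2]),
        h5_ulnar = runif(1, rg$hamate5_ulnar[1], rg$hamate5_ulnar[2]),
        h5_div = runif(1, rg$hamate5_div[1], rg$hamate5_div[2]),
        h5_frac = runif(1, rg$hamate5_ulnar_frac[1], rg$hamate5_ulnar_frac[2]),
        m5_radial = runif(1, rg$mc5_radial[1], rg$mc5_radial[2]),
        m5_ulnar = runif(1, rg$mc5_ulnar[1], rg$mc5_ulnar[2]),
        m5_div = runif(1, rg$mc5_div[1], rg$mc5_div[2]),
        m5_frac = runif(1, rg$mc5_ulnar_frac[1], rg$mc5_ulnar_frac[2]),
        imc4_roc = runif(1, rg$imc4_roc[1], rg$imc4_roc[2]),
        imc5_roc = runif(1, rg$imc5_roc[1], rg$imc5_roc[2]),
        cap_angle = runif(1, 35, 55),
        imc_angle = runif(1, 25, 40)
      )
    })
  })

  facets <- list()
  gt_rows <- list()
  for (i in seq_len(n_specimens)) {
    d <- draws[[i]]
    sid <- sprintf("spec%02d", i)
    sub_seed <- function(k) (seed * 1009L + i * 97L + k) %% 2147483629L

    add_cap <- function(role, roc, sense, flatten = FALSE, cap_angle = d$cap_angle, k = 0L) {
      spec <- cap_spec(roc, cap_angle, resolution = resolution, noise_sd = noise_sd,
                       sense = sense, seed = sub_seed(k))
      g <- if (flatten) {
        tryCatch(generate_flattened_cap(spec), fm_infeasible = function(e) {
          out <- generate_cap(spec)
          out$truth$flatten_failed <- TRUE
          out
        })
      } else {
        generate_cap(spec)
      }
      g$mesh$name <- paste(sid, role, sep = "_")
      facets[[g$mesh$name]] <<- g
      gt_rows[[length(gt_rows) + 1]] <<- tibble(
        specimen_id = sid, role = role, kind = "cap",
        true_roc = roc, sense = sense,
        flattened = if (flatten) is.null(g$truth$flatten_failed) else FALSE,
        true_radial_roc = NA_real_, true_ulnar_roc = NA_real_,
        true_divergence = NA_real_, true_ulnar_fraction = NA_real_
      )
    }
    add_bicondylar <- function(role, rr, ru, div, frac, sense, k) {
      g <- generate_bicondylar(bicondylar_spec(
        rr, ru, div, ulnar_area_target = frac, noise_sd = noise_sd,
        resolution = resolution, sense = sense, seed = sub_seed(k)
      ))
      g$mesh$name <- paste(sid, role, sep = "_")
      facets[[g$mesh$name]] <<- g
      gt_rows[[length(gt_rows) + 1]] <<- tibble(
        specimen_id = sid, role = role, kind = "bicondylar",
        true_roc = NA_real_, sense = sense, flattened = FALSE,
        true_radial_roc = rr, true_ulnar_roc = ru,
        true_divergence = g$truth$divergence,
        true_ulnar_fraction = g$truth$ulnar_area_fraction
      )
    }

    add_cap("hamate4", d$hamate4_roc, "concave", flatten = d$hamate4_flat, k = 1L)
    add_cap("mc4_base", d$mc4_roc, "convex", k = 2L)
    add_bicondylar("hamate5", d$h5_radial, d$h5_ulnar, d$h5_div, d$h5_frac, "concave", k = 3L)
    add_bicondylar("mc5_base", d$m5_radial, d$m5_ulnar, d$m5_div, d$m5_frac, "convex", k = 4L)
    add_cap("imc4", d$imc4_roc, "concave", cap_angle = d$imc_angle, k = 5L)
    add_cap("imc5", d$imc5_roc, "convex", cap_angle = d$imc_angle, k = 6L)
  }
  ground_truth <- dplyr::bind_rows(gt_rows)
  manifest <- tibble(
    specimen_id = ground_truth$specimen_id,
    name = names(facets),
    role = ground_truth$role,
    kind = ground_truth$kind
  )
  list(facets = facets, ground_truth = ground_truth, manifest = manifest)
}

#' Simulate a cohort and write it to disk
#'
#' Writes one directory per specimen containing binary PLY meshes, plus
#' `manifest.csv` (specimen_id, path, role, kind) and
#' `ground_truth.csv`. Re-running with the same seed reproduces
#' byte-identical ground truth.
#'
#' @inheritParams generate_study_cohort
#' @param dir Output directory (created if needed).
#' @return The manifest tibble (with `path` column), invisibly.
#' @export
simulate_cohort <- function(dir, n_specimens = 10, seed = 1L, noise_sd = 0.1,
                            resolution = 0.3) {
  cohort <- generate_study_cohort(n_specimens, seed = seed, noise_sd = noise_sd,
                                  resolution = resolution)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(nrow(cohort$manifest))
  for (k in seq_len(nrow(cohort$manifest))) {
    row <- cohort$manifest[k, ]
    sdir <- file.path(dir, row$specimen_id)
    dir.create(sdir, showWarnings = FALSE)
    paths[k] <- file.path(sdir, paste0(row$role, ".ply"))
    write_mesh(cohort$facets[[row$name]]$mesh, paths[k])
  }
  manifest <- dplyr::mutate(cohort$manifest, path = paths)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  write.csv(cohort$ground_truth, file.path(dir, "ground_truth.csv"), row.names = FALSE)
  invisible(manifest)
}

# Canonical generator axes double as the landmark orientation for
# simulated facets; real scans supply their own orientation JSON.
canonical_orientation <- function() {
  orientation_spec(c(1, 0, 0), c(0, 1, 0), source = "landmarks")
}

measure_one <- function(mesh, role, orientation = NULL, flat_threshold = 0.25) {
  frame <- build_frame(mesh, orientation)
  is_bicondylar <- role %in% c("hamate5", "mc5_base")
  is_imc <- role %in% c("imc4", "imc5")
  rep <- measure_facet(mesh, frame, flattening = identical(role, "hamate4"),
                       flat_threshold = flat_threshold)
  out <- dplyr::mutate(rep, role = role,
                       radial_roc = NA_real_, ulnar_roc = NA_real_,
                       radial_area_fraction = NA_real_, ulnar_area_fraction = NA_real_,
                       divergence_angle = NA_real_, roc_3pt = NA_real_)
  if (is_bicondylar) {
    bc <- partition_bicondylar(mesh, frame)
    out$radial_roc <- bc$radial_fit$radius
    out$ulnar_roc <- bc$ulnar_fit$radius
    out$radial_area_fraction <- bc$radial_area_fraction
    out$ulnar_area_fraction <- bc$ulnar_area_fraction
    out$divergence_angle <- bc$divergence_angle
  }
  if (is_imc) out$roc_3pt <- facet_three_point_roc(mesh, frame)
  out
}

#' Measure every facet of a cohort
#'
#' Accepts either the in-memory output of [generate_study_cohort()] or a
#' manifest tibble/CSV path with `path` and `role` columns (as written by
#' [simulate_cohort()]). Bicondylar decomposition runs on fifth-CMC
#' facets (`hamate5`, `mc5_base`), the three-point mid-axial radius on
#' intermetacarpal facets (`imc4`, `imc5`), and dorsal-flattening
#' detection on the fourth-CMC hamate facet. A facet that fails to
#' measure is recorded as a row with `status = "error"` and the run
#' continues; if every facet fails, an error is raised.
#'
#' @param x Cohort list, manifest tibble, or path to `manifest.csv`.
#' @param orientation An [orientation_spec()] applied to every facet;
#'   defaults to the simulated cohort's canonical landmark axes.
#' @param flat_threshold Flattening mean-error threshold in mm.
#' @return Tibble with one row per facet: identification, the
#'   [measure_facet()] columns, bicondylar and three-point columns where
#'   applicable, and `status`.
#' @export
measure_cohort <- function(x, orientation = canonical_orientation(),
                           flat_threshold = 0.25) {
  if (is.character(x) && length(x) == 1) x <- tibble::as_tibble(read.csv(x))
  if (is.list(x) && !is.data.frame(x) && !is.null(x$manifest)) {
    jobs <- dplyr::mutate(x$manifest,
                          mesh = purrr::map(.data$name, function(nm) x$facets[[nm]]$mesh))
  } else {
    jobs <- tibble::as_tibble(x)
    if (nrow(jobs) == 0) fm_abort("no input facets to measure", "fm_validation_error")
    jobs$mesh <- purrr::map(jobs$path, function(p) tryCatch(read_mesh(p), error = function(e) e))
    if (is.null(jobs$specimen_id)) jobs$specimen_id <- sprintf("s%02d", seq_len(nrow(jobs)))
  }
  if (nrow(jobs) == 0) fm_abort("no input facets to measure", "fm_validation_error")
  rows <- purrr::pmap(list(jobs$mesh, jobs$role, jobs$specimen_id), function(mesh, role, sid) {
    if (inherits(mesh, "error")) {
      return(tibble(specimen_id = sid, role = role, status = "error",
                    message = conditionMessage(mesh)))
    }
    tryCatch(
      dplyr::mutate(measure_one(mesh, role, orientation, flat_threshold),
                    specimen_id = sid, status = "ok", message = NA_character_),
      error = function(e) tibble(specimen_id = sid, role = role, status = "error",
                                 message = conditionMessage(e))
    )
  })
  out <- dplyr::bind_rows(rows)
  if (!any(out$status == "ok")) {
    fm_abort("every facet failed to measure", "fm_io_error")
  }
  front <- c("specimen_id", "role", "status")
  dplyr::select(out, dplyr::all_of(front), dplyr::everything())
}

#' Summarise cohort measurements as the study's tables do
#'
#' Produces a per-role summary of every numeric measurement column,
#' both numerically (`mean`, `min`, `max`, `n`) and formatted as
#' `"mean (min–max)"` to two decimals. When `dir` is given, writes the
#' per-facet table (`measurements.csv`), the formatted summary
#' (`summary.csv`) and a full-precision JSON (`report.json`).
#'
#' @param measurements Output of [measure_cohort()].
#' @param dir Optional output directory.
#' @return List with `summary` (long tibble: role, metric, mean, min,
#'   max, n, formatted) and `table` (wide tibble of formatted values).
#' @export
report_cohort <- function(measurements, dir = NULL) {
  required <- c("specimen_id", "role", "status")
  missing <- setdiff(required, names(measurements))
  if (length(missing) > 0) {
    fm_abort(sprintf("measurement table lacks column(s): %s", paste(missing, collapse = ", ")),
             "fm_schema_error")
  }
  ok <- dplyr::filter(measurements, .data$status == "ok")
  num_cols <- names(ok)[vapply(ok, is.numeric, logical(1))]
  long <- tidyr::pivot_longer(
    dplyr::select(ok, dplyr::all_of(c("role", num_cols))),
    dplyr::all_of(num_cols), names_to = "metric", values_to = "value"
  )
  summary <- dplyr::summarise(
    dplyr::group_by(dplyr::filter(long, !is.na(.data$value)), .data$role, .data$metric),
    mean = mean(.data$value), min = min(.data$value), max = max(.data$value),
    n = dplyr::n(), .groups = "drop"
  )
  summary <- dplyr::mutate(summary,
                           formatted = sprintf("%.2f (%.2f–%.2f)", .data$mean, .data$min, .data$max))
  table <- tidyr::pivot_wider(
    dplyr::select(summary, "role", "metric", "formatted"),
    names_from = "metric", values_from = "formatted"
  )
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(dplyr::select(measurements, -dplyr::any_of("mesh")),
              file.path(dir, "measurements.csv"), row.names = FALSE)
    write.csv(table, file.path(dir, "summary.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(
        measurements = dplyr::select(measurements, -dplyr::any_of("mesh")),
        summary = summary
      ),
      file.path(dir, "report.json"),
      dataframe = "rows", auto_unbox = TRUE, digits = NA, na = "null"
    )
  }
  list(summary = summary, table = table)
}
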