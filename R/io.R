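# CSV / JSON schemas: comma separated, '.' decimal, UTF-8, header required.

PROFILE_COLUMNS <- c("subject_id", "group", "layer", "eccentricity_um",
                     "thickness_um")

#' Read layer thickness profiles from CSV
#'
#' Expects columns `subject_id`, `group`, `layer`, `eccentricity_um`,
#' `thickness_um`. Rows are grouped by (subject, group, layer) into
#' [layer_profile()]s; rows arriving out of eccentricity order are sorted
#' with a warning, and malformed cells are reported with their file line
#' numbers.
#'
#' @param path path to the CSV file.
#' @return Named list of [layer_profile()]s (`<group>.<layer>` when one
#'   subject per group, else `<group>.<subject>.<layer>`).
#' @export
read_profiles <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- tryCatch(
    read.csv(path, colClasses = "character", check.names = TRUE),
    error = function(e) stop("schema error: ", conditionMessage(e))
  )
  missing <- setdiff(PROFILE_COLUMNS, names(raw))
  if (length(missing)) {
    stop("schema error: missing column(s) ", paste(missing, collapse = ", "))
  }
  if (nrow(raw) == 0L) stop("schema error: no data rows")
  lines <- seq_len(nrow(raw)) + 1L   # header is line 1
  for (col in c("eccentricity_um", "thickness_um")) {
    val <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(val))
    if (length(bad)) {
      stop("schema error: non-numeric ", col, " at line(s) ",
           paste(lines[bad], collapse = ", "))
    }
    raw[[col]] <- val
  }
  keys <- interaction(raw$subject_id, raw$group, raw$layer, drop = TRUE)
  profiles <- list()
  for (k in levels(keys)) {
    rows <- raw[keys == k, , drop = FALSE]
    if (is.unsorted(rows$eccentricity_um, strictly = TRUE)) {
      if (anyDuplicated(rows$eccentricity_um)) {
        stop("schema error: duplicate eccentricity for ", k, " at line(s) ",
             paste(lines[keys == k][duplicated(rows$eccentricity_um)],
                   collapse = ", "))
      }
      warning("rows for ", k, " were not sorted by eccentricity; sorting")
      rows <- rows[order(rows$eccentricity_um), , drop = FALSE]
    }
    p <- layer_profile(rows$layer[1L], rows$eccentricity_um,
                       rows$thickness_um,
                       subject_id = rows$subject_id[1L],
                       group = rows$group[1L])
    profiles[[paste(p$group, p$layer, sep = ".")]] <- p
  }
  profiles
}

#' Write layer profiles to CSV
#'
#' @param profiles a list of [layer_profile()]s, a single profile, or a
#'   data.frame already in the long schema.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  if (is_layer_profile(profiles)) profiles <- list(profiles)
  df <- if (is.data.frame(profiles)) profiles else
    do.call(rbind, lapply(profiles, as.data.frame))
  stopifnot(all(PROFILE_COLUMNS %in% names(df)))
  df <- df[, PROFILE_COLUMNS]
  # 17 significant digits: doubles survive the round trip bit-exactly
  for (col in c("eccentricity_um", "thickness_um")) {
    df[[col]] <- sprintf("%.17g", df[[col]])
  }
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an A-scan reflectivity profile from CSV
#'
#' Expects columns `depth_um` and `reflectivity`.
#'
#' @param path path to the CSV file.
#' @return A [reflectivity_profile()].
#' @export
read_ascan <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.csv(path)
  need <- c("depth_um", "reflectivity")
  if (!all(need %in% names(raw))) {
    stop("schema error: A-scan CSV needs columns ",
         paste(need, collapse = ", "))
  }
  if (nrow(raw) == 0L) stop("schema error: no data rows")
  reflectivity_profile(raw$depth_um, raw$reflectivity)
}

.REFERENCE_MD5 <- c(
  reference_table.csv = "9fa6bfffad532177cb750587850aa6af",
  reference_fc.csv = "3ea0ed295b608ebf0b8a763274253795"
)

#' Load the packaged reference summary table
#'
#' The group-level measurements the magnification model is validated
#' against: retardation and PG/C thickness, area and volume ratios for 3
#' preterm groups x 3 layers x 4 control eccentricities (300–900 µm), plus
#' the foveal-centre block (retinal thickness, foveal depth, summed IRL
#' thickness and FDA index per group, mean ± sd). The packaged files are
#' checksum-verified on load. The printed area and volume cells are for
#' comparison only; computations start from retardation and thickness
#' ratios.
#'
#' @return A list with data.frames `cells` (36 rows) and `fc` (4 rows).
#' @examples
#' ref <- load_reference_table()
#' subset(ref$cells, group == "PG3" & layer == "INL")
#' @export
load_reference_table <- function() {
  files <- names(.REFERENCE_MD5)
  paths <- vapply(files, function(f)
    system.file("extdata", f, package = "fovearrest"), character(1))
  if (any(paths == "")) stop("packaged reference data not found")
  sums <- tools::md5sum(paths)
  ok <- unname(sums) == unname(.REFERENCE_MD5)
  if (!all(ok)) {
    stop("integrity error: packaged reference data corrupted (",
         paste(files[!ok], collapse = ", "), ")")
  }
  cells <- read.csv(paths[[1L]])
  fc <- read.csv(paths[[2L]])
  stopifnot(nrow(cells) == 36L, nrow(fc) == 4L)
  list(cells = cells, fc = fc)
}

#' Recompute the reference area and volume cells from retardation
#'
#' Runs the areal-magnification model over the packaged reference table:
#' for each of the 36 cells the area ratio is recomputed as
#' `((E - R) / E)^2` from the tabulated retardation `R`, and the volume
#' ratio as thickness ratio x recomputed area ratio. Deviations from the
#' printed (2-decimal) cells quantify how well the pure lateral-geometry
#' model reproduces the published table; printed cells are rounded from
#' unrounded retardation, so deviations up to ~0.015 are expected.
#'
#' @return data.frame with the reference columns plus `area_computed`,
#'   `volume_computed`, `area_dev`, `volume_dev`; attributes
#'   `max_area_dev` and `max_volume_dev` carry the largest absolute
#'   deviations.
#' @examples
#' cmp <- reproduce_reference_table()
#' attr(cmp, "max_area_dev")
#' @export
reproduce_reference_table <- function() {
  ref <- load_reference_table()$cells
  ref$area_computed <- area_ratio(ref$eccentricity_um, ref$retardation_um)
  ref$volume_computed <- volume_ratio(ref$thickness_ratio,
                                      ref$area_computed)
  ref$area_dev <- ref$area_computed - ref$area_ratio
  ref$volume_dev <- ref$volume_computed - ref$volume_ratio
  attr(ref, "max_area_dev") <- max(abs(ref$area_dev))
  attr(ref, "max_volume_dev") <- max(abs(ref$volume_dev))
  ref
}

#' Read a cohort configuration from YAML or JSON
#'
#' The file mirrors [cohort_config()]: fields `seed`, `control_noise_sd`,
#' `truth_eccentricities`, `grid` (`min`, `max`, `step`), and `groups`, a
#' list of entries with `label`, `r_max`, `lambda`, optional `form` and
#' `noise_sd`.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return A [cohort_config()].
#' @export
read_cohort_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  groups <- lapply(seq_len(NROW(cfg$groups)), function(i) {
    g <- if (is.data.frame(cfg$groups)) as.list(cfg$groups[i, ]) else
      cfg$groups[[i]]
    list(
      label = g$label,
      warp = if (is.null(g$r_max)) NULL else warp_spec(
        g$r_max, g$lambda,
        form = if (is.null(g$form)) "saturating_exponential" else g$form
      ),
      noise_sd = if (is.null(g$noise_sd)) 0 else g$noise_sd
    )
  })
  grid <- if (is.null(cfg$grid)) default_grid() else
    seq(cfg$grid$min, cfg$grid$max, by = cfg$grid$step)
  cohort_config(
    groups = groups,
    grid = grid,
    control_noise_sd = if (is.null(cfg$control_noise_sd)) 0 else
      cfg$control_noise_sd,
    truth_eccentricities = if (is.null(cfg$truth_eccentricities))
      c(300, 500, 700, 900) else cfg$truth_eccentricities,
    seed = if (is.null(cfg$seed)) 1L else cfg$seed
  )
}

# PG/C thickness ratio at given eccentricities from fitted splines.
.cohort_thickness_ratios <- function(cohort, eccentricities,
                                     layers = c("GCL_IPL", "INL", "OPL"),
                                     smoothing = 0) {
  profiles <- cohort$profiles
  groups <- setdiff(unique(vapply(
    strsplit(names(profiles), ".", fixed = TRUE), `[[`, character(1), 1L
  )), "C")
  rows <- list()
  for (layer in layers) {
    fc_fit <- fit_thickness_spline(profiles[[paste("C", layer, sep = ".")]],
                                   smoothing)
    for (g in groups) {
      fg <- fit_thickness_spline(profiles[[paste(g, layer, sep = ".")]],
                                 smoothing)
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, layer = layer, eccentricity_um = eccentricities,
        thickness_ratio = thickness_ratio(pmax(fg(eccentricities), 0),
                                          pmax(fc_fit(eccentricities), 1e-9))
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Foveal-centre metrics per group from innermost samples of the profiles.
.cohort_fc_metrics <- function(cohort, threshold = 5) {
  profiles <- cohort$profiles
  groups <- unique(vapply(strsplit(names(profiles), ".", fixed = TRUE),
                          `[[`, character(1), 1L))
  at_fc <- function(g, layer) {
    p <- profiles[[paste(g, layer, sep = ".")]]
    p$samples$thickness_um[1L]
  }
  fc <- do.call(rbind, lapply(groups, function(g) data.frame(
    group = g,
    irlt_um = at_fc(g, "GCL_IPL") + at_fc(g, "INL"),
    oplt_um = at_fc(g, "OPL"),
    hfl_onlt_um = at_fc(g, "HFL_ONL")
  )))
  fc_metrics(fc, threshold = threshold)
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' simulate -> retardation -> indices -> magnification, writing every
#' intermediate table as CSV plus a JSON report to `out_dir`. The report
#' records the seed, configuration and package version, per-group
#' retardation summaries, foveal-centre metrics with FDA classification,
#' volume extremes at 300 µm, and (synthetic data only) the maximum
#' absolute deviation of estimated retardation from the analytic ground
#' truth.
#'
#' @param config a [cohort_config()]; its seed drives all randomness.
#' @param out_dir output directory, created if needed; `NULL` writes
#'   nothing.
#' @param smoothing spline smoothing for fitting (see
#'   [fit_thickness_spline()]).
#' @param eccentricities control eccentricities analysed (µm).
#' @param normal_curve optional normative displacement curve (data.frame
#'   `eccentricity_um`, `displacement_um`) for percent-of-normal columns.
#' @return A list with `cohort`, `retardation`, `summaries`,
#'   `thickness_ratios`, `fc`, `magnification`, `report` (invisibly if
#'   `out_dir` is set).
#' @examples
#' res <- run_pipeline(cohort_config(seed = 42), out_dir = NULL)
#' res$report$truth_max_abs_error_um
#' @export
run_pipeline <- function(config = cohort_config(), out_dir = NULL,
                         smoothing = 0,
                         eccentricities = c(300, 500, 700, 900),
                         normal_curve = NULL) {
  cohort <- generate_cohort(config)
  est <- cohort_retardation(cohort, eccentricities, smoothing = smoothing)
  ok <- est[est$status == "ok", , drop = FALSE]
  summaries <- lapply(split(ok, ok$group), group_summary)
  ratios <- .cohort_thickness_ratios(cohort, eccentricities,
                                     smoothing = smoothing)
  fc <- .cohort_fc_metrics(cohort)
  mag <- magnification_table(ok, ratios)
  if (!is.null(normal_curve)) {
    mag$pct_of_normal <- residual_displacement_pct(
      mag$retardation_um, normal_curve, mag$eccentricity_um
    )
  }
  truth_err <- if (nrow(cohort$truth)) {
    m <- merge(ok, cohort$truth,
               by = c("group", "layer", "eccentricity_um"))
    max(abs(m$retardation_um - m$true_retardation_um))
  } else NA_real_
  report <- list(
    package = "fovearrest",
    version = as.character(utils::packageVersion("fovearrest")),
    seed = config$seed,
    smoothing = smoothing,
    eccentricities = eccentricities,
    groups = vapply(config$groups, function(g) as.character(g$label),
                    character(1)),
    summaries = lapply(summaries, unclass),
    fc = fc,
    volume_extremes_300 = lapply(
      split(mag, mag$group),
      function(d) as.list(volume_extremes_at(d, 300))
    ),
    truth_max_abs_error_um = truth_err
  )
  result <- list(cohort = cohort, retardation = est, summaries = summaries,
                 thickness_ratios = ratios, fc = fc, magnification = mag,
                 report = report)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_profiles(cohort$data, file.path(out_dir, "profiles.csv"))
    write.csv(cohort$truth, file.path(out_dir, "ground_truth.csv"),
              row.names = FALSE, quote = FALSE)
    write.csv(est, file.path(out_dir, "retardation.csv"),
              row.names = FALSE, quote = FALSE)
    write.csv(fc, file.path(out_dir, "fc_metrics.csv"),
              row.names = FALSE, quote = FALSE)
    write.csv(mag, file.path(out_dir, "magnification.csv"),
              row.names = FALSE, quote = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(result))
  }
  result
}
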