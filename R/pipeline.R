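## Configuration-driven orchestration: runs selected analysis stages on
## input or synthetic data, compares groups with the declared
## normality-gated test choice, and exports plots with their underlying
## tables.

#' Build or read an analysis configuration
#'
#' A configuration names the inputs (paths to track/polyline/cloud files
#' or synthetic-generation parameters), selects analysis stages with their
#' parameters, and fixes the seed and output directory. Configurations
#' round-trip through YAML.
#'
#' @param x A named list, or a path to a YAML file containing one.
#' @return An object of class `analysis_config`.
#' @details Recognised top-level fields: `seed` (integer), `output_dir`,
#'   `inputs` (named list: `tracks`, `cloud`, `boundary`, ... each either a
#'   file path or a `simulate:` block with generator parameters), and
#'   `stages` (named list among `msd`, `summaries`, `drift`, `circ_anova`,
#'   `extents`, `distortion`, `width`, `thickness`, each a list of stage
#'   parameters). Referenced paths are checked before any stage runs.
#' @export
analysis_config <- function(x) {
  if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x)) stop("config file not found: ", x)
    x <- yaml::read_yaml(x)
  }
  if (!is.list(x)) stop("config must be a list or a YAML file path")
  if (is.null(x$seed)) x$seed <- 1L
  if (is.null(x$output_dir)) stop("config must name an 'output_dir'")
  if (is.null(x$stages) || !length(x$stages))
    stop("config selects no analysis stage")
  known <- c("msd", "summaries", "drift", "circ_anova", "extents",
             "distortion", "width", "thickness")
  bad <- setdiff(names(x$stages), known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  ## startup validation: every referenced path must exist
  for (nm in names(x$inputs)) {
    inp <- x$inputs[[nm]]
    if (is.character(inp) && !file.exists(inp))
      stop("input '", nm, "' references a missing file: ", inp)
  }
  structure(x, class = "analysis_config")
}

resolve_tracks_input <- function(inp, seed) {
  if (is.character(inp)) return(read_tracks(inp, dialect = "native"))
  if (is.list(inp) && !is.null(inp$simulate)) {
    s <- inp$simulate
    mk <- function(b, default_seed) {
      do.call(walk_config, c(b[setdiff(names(b), "seed")],
                             list(seed = if (is.null(b$seed)) default_seed else b$seed)))
    }
    op <- mk(s$op, seed)
    brain <- mk(s$brain, seed + 1L)
    shared <- if (is.null(s$shared_drift)) c(0, 0, 0) else as.numeric(s$shared_drift)
    return(simulate_cohorts(op, brain, shared))
  }
  stop("tracks input must be a file path or a simulate block")
}

resolve_cloud_input <- function(inp, seed) {
  if (is.list(inp) && !is.null(inp$simulate)) {
    s <- inp$simulate
    if (is.null(s$seed)) s$seed <- seed
    return(do.call(make_point_cloud, s))
  }
  if (is.character(inp)) {
    df <- utils::read.csv(inp)
    miss <- setdiff(c("ml_um", "dv_um", "ap_um"), names(df))
    if (length(miss)) stop("cloud CSV missing column(s): ",
                           paste(miss, collapse = ", "))
    fl <- if ("flag" %in% names(df)) df$flag else NULL
    return(labeled_point_cloud(cbind(df$ml_um, df$dv_um, df$ap_um), fl))
  }
  stop("cloud input must be a file path or a simulate block")
}

resolve_boundary_input <- function(inp, seed) {
  if (is.list(inp) && !is.null(inp$simulate))
    return(make_boundary(do.call(boundary_config, inp$simulate)))
  if (is.character(inp)) return(read_polyline(inp))
  stop("boundary input must be a file path or a simulate block")
}

run_stage <- function(name, expr, out_dir = NULL) {
  tryCatch(expr, error = function(e) {
    ## mark any already-written outputs as incomplete before aborting
    if (!is.null(out_dir) && dir.exists(out_dir))
      writeLines(paste0("stage '", name, "' failed: ",
                        conditionMessage(e)),
                 file.path(out_dir, "INCOMPLETE"))
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the configured analysis pipeline
#'
#' Executes the selected stages in dependency order (tracks are loaded or
#' simulated once; the drift stage feeds drift-corrected summaries), and
#' writes one tidy CSV per stage plus a JSON summary and a run manifest
#' (seed, parameters, package version — no timestamps, so identical
#' config + seed reproduces byte-identical outputs). A failing stage
#' aborts with the stage name.
#'
#' @param config An [analysis_config()], a list coercible to one, or a
#'   YAML path.
#' @return Invisibly, a named list of per-stage results and output files.
#' @export
run_pipeline <- function(config) {
  config <- if (inherits(config, "analysis_config")) config else
    analysis_config(config)
  out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) run_stage(name, expr, out_dir)
  set.seed(config$seed)
  results <- list()
  files <- character()
  summary_json <- list()
  stages <- config$stages

  tracks <- NULL
  needs_tracks <- any(c("msd", "summaries", "drift", "circ_anova") %in%
                        names(stages))
  if (needs_tracks)
    tracks <- stage("load_tracks",
                        resolve_tracks_input(config$inputs$tracks, config$seed))

  drift <- NULL
  if ("drift" %in% names(stages)) {
    p <- stages$drift
    drift <- stage("drift",
                       drift_series(tracks, p$reference_cohort))
    f <- file.path(out_dir, "drift.csv")
    utils::write.csv(as.data.frame(drift), f, row.names = FALSE, quote = FALSE)
    files <- c(files, f)
    results$drift <- drift
  }

  if ("msd" %in% names(stages)) {
    p <- stages$msd
    cur <- stage("msd", msd(tracks, cohort = p$cohort,
                                max_lag_fraction = if (is.null(p$max_lag_fraction)) 0.5
                                else p$max_lag_fraction))
    f <- file.path(out_dir, "msd.csv")
    utils::write.csv(as.data.frame(cur), f, row.names = FALSE, quote = FALSE)
    files <- c(files, f)
    results$msd <- cur
    summary_json$msd <- list(n_lags = nrow(cur),
                             slope_first_lags = msd_slope(cur, min(10L, nrow(cur))))
  }

  summaries <- NULL
  if ("summaries" %in% names(stages)) {
    p <- stages$summaries
    summaries <- stage("summaries",
      windowed_summaries(tracks, t_start = p$t_start,
                         window_len = p$window_len, n_windows = p$n_windows,
                         drift = if (isTRUE(p$drift_corrected)) drift else NULL,
                         cohort = p$cohort))
    f <- file.path(out_dir, "summaries.csv")
    utils::write.csv(as.data.frame(summaries), f, row.names = FALSE,
                     quote = FALSE)
    files <- c(files, f)
    results$summaries <- summaries
  }

  if ("circ_anova" %in% names(stages)) {
    p <- stages$circ_anova
    res <- stage("circ_anova", {
      if (is.null(summaries))
        stop("circ_anova requires the 'summaries' stage")
      ok <- !is.na(summaries$orientation_deg)
      cs <- circular_sample(summaries$orientation_deg[ok] * pi / 180,
                            summaries[[p$group_by %||% "cohort"]][ok])
      circ_anova_lrt(cs)
    })
    f <- file.path(out_dir, "circ_anova.json")
    jsonlite::write_json(
      list(statistic = res$statistic, df = res$df, p_value = res$p_value,
           group_mus_deg = lapply(res$group_fits, function(g) g$mu * 180 / pi),
           kappa = res$kappa_shared),
      f, auto_unbox = TRUE, digits = NA)
    files <- c(files, f)
    results$circ_anova <- res
    summary_json$circ_anova <- list(statistic = res$statistic,
                                    p_value = res$p_value)
  }

  if ("extents" %in% names(stages)) {
    p <- stages$extents
    res <- stage("extents", {
      cloud <- resolve_cloud_input(config$inputs$cloud, config$seed)
      if (!is.null(p$link_dist)) cloud <- flag_ectopic(cloud, p$link_dist)
      extent_box(cloud)
    })
    f <- file.path(out_dir, "extents.csv")
    utils::write.csv(data.frame(ml_um = res$ml, dv_um = res$dv,
                                ap_um = res$ap,
                                n_points_used = res$n_points_used,
                                n_ectopic_excluded = res$n_ectopic_excluded),
                     f, row.names = FALSE, quote = FALSE)
    files <- c(files, f)
    results$extents <- res
  }

  if ("distortion" %in% names(stages)) {
    res <- stage("distortion", {
      b <- resolve_boundary_input(config$inputs$boundary, config$seed)
      distortion_index(b)
    })
    f <- file.path(out_dir, "distortion.csv")
    utils::write.csv(data.frame(arc_length_um = res$arc_length,
                                endpoint_distance_um = res$endpoint_distance,
                                index = res$index),
                     f, row.names = FALSE, quote = FALSE)
    files <- c(files, f)
    results$distortion <- res
    summary_json$distortion_index <- res$index
  }

  if ("width" %in% names(stages)) {
    p <- stages$width
    res <- stage("width", {
      left <- resolve_boundary_input(config$inputs$left_boundary, config$seed)
      right <- resolve_boundary_input(config$inputs$right_boundary, config$seed)
      brain_width(left, right, dv_levels = as.numeric(p$dv_levels))
    })
    f <- file.path(out_dir, "width.csv")
    utils::write.csv(as.data.frame(res), f, row.names = FALSE, quote = FALSE)
    files <- c(files, f)
    results$width <- res
  }

  if ("thickness" %in% names(stages)) {
    p <- stages$thickness
    res <- stage("thickness", {
      inp <- config$inputs$interface
      region <- if (is.list(inp) && !is.null(inp$simulate)) {
        s <- inp$simulate
        if (is.null(s$seed)) s$seed <- config$seed
        do.call(make_interface, s)
      } else stop("thickness stage needs an 'interface' simulate input")
      interface_thickness(region,
                          step_px = if (is.null(p$step_px)) 100 else p$step_px)
    })
    f <- file.path(out_dir, "thickness.csv")
    utils::write.csv(data.frame(station = seq_len(res$n_samples),
                                thickness_nm = res$samples_nm),
                     f, row.names = FALSE, quote = FALSE)
    files <- c(files, f)
    results$thickness <- res
    summary_json$thickness_mean_nm <- res$mean_nm
  }

  manifest <- list(package = "placodetrack",
                   version = as.character(utils::packageVersion("placodetrack")),
                   seed = config$seed,
                   stages = names(stages),
                   parameters = stages)
  f <- file.path(out_dir, "run_manifest.json")
  jsonlite::write_json(manifest, f, auto_unbox = TRUE, digits = NA)
  files <- c(files, f)
  if (length(summary_json)) {
    f <- file.path(out_dir, "summary.json")
    jsonlite::write_json(summary_json, f, auto_unbox = TRUE, digits = NA)
    files <- c(files, f)
  }
  invisible(list(results = results, files = files))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Exact two-sided Mann-Whitney p by enumeration of rank assignments
## (midranks under ties); used when stats::wilcox.test cannot compute an
## exact p because of ties and the pooled sample is small.
exact_mw_p <- function(x, y) {
  pooled <- c(x, y)
  rk <- rank(pooled)
  n1 <- length(x); n <- length(pooled)
  w_obs <- sum(rk[seq_len(n1)])
  ew <- n1 * (n + 1) / 2
  sets <- utils::combn(n, n1)
  w_all <- apply(sets, 2, function(idx) sum(rk[idx]))
  mean(abs(w_all - ew) >= abs(w_obs - ew) - 1e-9)
}

#' Two-group comparison with normality-gated test choice
#'
#' Reproduces the study's comparison protocol: each group is checked for
#' normality (Shapiro–Wilk at alpha = 0.05, requiring n >= 3 per group);
#' if both groups pass, an unpaired two-tailed t test is run, otherwise a
#' Mann–Whitney (Wilcoxon rank-sum) test. The choice can be overridden
#' with `force_test`, in which case the override is recorded (a warning
#' is emitted when a t test is forced on data that failed the
#' pre-check). Test computation
#' is delegated to [stats::t.test()] / [stats::wilcox.test()]; when ties
#' block the exact rank-sum p and the pooled sample is small (n <= 18)
#' the exact two-sided p is computed by full enumeration.
#'
#' @param values_by_group Named list of two numeric vectors (each n >= 2).
#' @param force_test Optional `"t_two_tailed"` or `"mann_whitney"`.
#' @param metric Name of the compared quantity (free text, recorded).
#' @return An object of class `group_comparison`: metric, per-group
#'   mean/sem/n, `test`, `statistic`, `p_value`, `normality_p` and
#'   `test_reason`.
#' @export
compare_groups <- function(values_by_group, force_test = NULL,
                           metric = "value") {
  if (!is.list(values_by_group) || length(values_by_group) != 2L)
    stop("'values_by_group' must be a named list of exactly 2 groups")
  if (is.null(names(values_by_group)) || any(names(values_by_group) == ""))
    names(values_by_group) <- c("group1", "group2")
  x <- as.numeric(values_by_group[[1L]])
  y <- as.numeric(values_by_group[[2L]])
  if (length(x) < 2L || length(y) < 2L)
    stop("each group needs at least 2 values")
  if (!is.null(force_test))
    force_test <- match.arg(force_test, c("t_two_tailed", "mann_whitney"))
  norm_p <- c(NA_real_, NA_real_)
  can_check <- length(x) >= 3L && length(y) >= 3L
  if (can_check) {
    sw <- function(v) if (stats::sd(v) == 0) 0 else stats::shapiro.test(v)$p.value
    norm_p <- c(sw(x), sw(y))
  }
  normal <- can_check && all(norm_p > 0.05)
  if (is.null(force_test)) {
    test <- if (normal) "t_two_tailed" else "mann_whitney"
    reason <- if (!can_check)
      "normality pre-check not possible (n < 3); Mann-Whitney used"
    else if (normal) "both groups passed Shapiro-Wilk at alpha = 0.05"
    else "at least one group failed Shapiro-Wilk at alpha = 0.05"
  } else {
    test <- force_test
    reason <- "forced by caller"
    if (can_check && test == "t_two_tailed" && !normal)
      warning("forced test '", test,
              "' contradicts the normality pre-check; running it anyway")
  }
  if (test == "t_two_tailed") {
    if (stats::sd(x) == 0 && stats::sd(y) == 0)
      stop("zero variance in both groups; t test undefined")
    ht <- stats::t.test(x, y, alternative = "two.sided", var.equal = FALSE)
    statistic <- unname(ht$statistic)
    p <- ht$p.value
  } else {
    ties <- any(duplicated(c(x, y)))
    if (ties && length(x) + length(y) <= 18L) {
      statistic <- sum(rank(c(x, y))[seq_along(x)]) -
        length(x) * (length(x) + 1) / 2   # Mann-Whitney U of group 1
      p <- exact_mw_p(x, y)
    } else {
      ht <- suppressWarnings(stats::wilcox.test(x, y,
                                                alternative = "two.sided"))
      statistic <- unname(ht$statistic)
      p <- ht$p.value
    }
  }
  sem <- function(v) stats::sd(v) / sqrt(length(v))
  structure(list(metric = metric,
                 groups = names(values_by_group),
                 means = c(mean(x), mean(y)),
                 sems = c(sem(x), sem(y)),
                 n = c(length(x), length(y)),
                 test = test, statistic = statistic, p_value = p,
                 normality_p = norm_p, test_reason = reason),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("\tTwo-group comparison of '%s'\n\n", x$metric))
  for (i in 1:2)
    cat(sprintf("  %s: mean %.4g +/- %.3g sem (n = %d)\n",
                x$groups[i], x$means[i], x$sems[i], x$n[i]))
  cat(sprintf("  test: %s (%s)\n", x$test, x$test_reason))
  cat(sprintf("  statistic = %.4g, p-value = %.4g\n", x$statistic, x$p_value))
  invisible(x)
}

#' Export a rose plot and its underlying histogram table
#'
#' Writes a vector-graphic (PDF) polar histogram plus the CSV of bin
#' edges and counts it was drawn from. Re-exporting the same data
#' produces an identical CSV.
#'
#' @param histogram A [rose_histogram()].
#' @param path Output PDF path; the CSV gets the same stem with `.csv`.
#' @param main Plot title.
#' @return Invisibly, the two file paths.
#' @export
export_rose_plot <- function(histogram, path, main = "Track orientations") {
  stopifnot(inherits(histogram, "rose_histogram"))
  csv_path <- sub("\\.[^.]+$", ".csv", path)
  if (identical(csv_path, path)) csv_path <- paste0(path, ".csv")
  df <- data.frame(bin_start_deg = histogram$bin_start * 180 / pi,
                   bin_end_deg = histogram$bin_end * 180 / pi,
                   count = histogram$count)
  utils::write.csv(df, csv_path, row.names = FALSE, quote = FALSE)
  grDevices::pdf(path, width = 5, height = 5)
  on.exit(grDevices::dev.off())
  rmax <- max(histogram$count, 1)
  plot(NA, xlim = c(-rmax, rmax), ylim = c(-rmax, rmax), asp = 1,
       axes = FALSE, xlab = "", ylab = "", main = main)
  ## orientation convention of the study's plots: dorsal (0 deg) to the
  ## top, +ML to the right
  for (i in seq_len(nrow(histogram))) {
    th <- seq(histogram$bin_start[i], histogram$bin_end[i], length.out = 20)
    r <- histogram$count[i]
    if (r == 0) next
    polygon(c(0, r * sin(th), 0), c(0, r * cos(th), 0),
            col = "grey70", border = "grey30")
  }
  graphics::segments(-rmax, 0, rmax, 0, col = "grey80")
  graphics::segments(0, -rmax, 0, rmax, col = "grey80")
  invisible(c(path, csv_path))
}

#' Export MSD curves as a plot plus CSV
#'
#' @param curves A named list of [msd()] results (or a single one).
#' @param path Output PDF path; the CSV gets the same stem with `.csv`.
#' @return Invisibly, the two file paths.
#' @export
export_msd_plot <- function(curves, path) {
  if (inherits(curves, "msd_curve")) curves <- list(msd = curves)
  if (!length(curves) || !all(vapply(curves, inherits, TRUE, "msd_curve")))
    stop("'curves' must be msd_curve objects")
  if (any(!vapply(curves, nrow, 0L)))
    stop("empty MSD curve; nothing to export")
  if (is.null(names(curves))) names(curves) <- paste0("curve", seq_along(curves))
  df <- do.call(rbind, lapply(names(curves), function(nm) {
    cbind(series = nm, as.data.frame(curves[[nm]]))
  }))
  csv_path <- sub("\\.[^.]+$", ".csv", path)
  if (identical(csv_path, path)) csv_path <- paste0(path, ".csv")
  utils::write.csv(df, csv_path, row.names = FALSE, quote = FALSE)
  grDevices::pdf(path, width = 6, height = 4.5)
  on.exit(grDevices::dev.off())
  xl <- range(df$lag); yl <- range(df$msd)
  plot(NA, xlim = xl, ylim = yl, xlab = "lag (min)",
       ylab = expression(MSD ~ (mu * m^2)))
  for (i in seq_along(curves))
    graphics::lines(curves[[i]]$lag, curves[[i]]$msd, col = i, lwd = 2)
  graphics::legend("topleft", legend = names(curves), col = seq_along(curves),
                   lwd = 2, bty = "n")
  invisible(c(path, csv_path))
}
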