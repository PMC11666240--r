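## Tissue-scale measurements: placode extent dimensions with ectopic-cell
## exclusion, brain width profiles, boundary distortion index and EM
## interface thickness.

#' Placode extents along the embryonic axes
#'
#' Per-axis extent (max - min coordinate) of the main-flagged points of a
#' labelled point cloud. Ectopic cells — those physically separated from
#' the main cluster — are excluded, matching how placode dimensions are
#' measured on fixed embryos.
#'
#' @param cloud A [labeled_point_cloud()] with >= 1 main-flagged point.
#' @return An object of class `extent_box`: list with `ml`, `dv`, `ap`
#'   extents (micrometres), `n_points_used` and `n_ectopic_excluded`.
#' @export
extent_box <- function(cloud) {
  stopifnot(inherits(cloud, "labeled_point_cloud"))
  main <- cloud$flags == "main"
  if (!any(main)) stop("no main-flagged point in cloud")
  p <- cloud$points[main, , drop = FALSE]
  ext <- apply(p, 2, function(v) max(v) - min(v))
  structure(list(ml = unname(ext["ml"]), dv = unname(ext["dv"]),
                 ap = unname(ext["ap"]),
                 n_points_used = sum(main),
                 n_ectopic_excluded = sum(!main)),
            class = "extent_box")
}

#' @export
print.extent_box <- function(x, ...) {
  cat(sprintf("<extent_box> ML %.2f um, DV %.2f um, AP %.2f um (%d points used, %d ectopic excluded)\n",
              x$ml, x$dv, x$ap, x$n_points_used, x$n_ectopic_excluded))
  invisible(x)
}

#' Flag ectopic cells by single-linkage clustering
#'
#' Operationalises "physically separated from the main cluster":
#' single-linkage connected components at a distance threshold; the
#' largest component is the main cluster (ties broken towards the
#' component containing the medoid of all points) and every other point
#' is flagged ectopic. Pre-existing flags are overwritten.
#'
#' @param cloud A [labeled_point_cloud()] with >= 2 points.
#' @param link_dist Linkage threshold in micrometres (default 15, about
#'   two cell diameters).
#' @return The cloud with recomputed flags.
#' @export
flag_ectopic <- function(cloud, link_dist = 15) {
  stopifnot(inherits(cloud, "labeled_point_cloud"))
  if (!is.numeric(link_dist) || link_dist <= 0)
    stop("'link_dist' must be > 0")
  n <- nrow(cloud$points)
  if (n < 2L) stop("need at least 2 points to flag ectopic cells")
  d <- stats::dist(cloud$points)
  hc <- stats::hclust(d, method = "single")
  comp <- stats::cutree(hc, h = link_dist)
  sizes <- tabulate(comp)
  biggest <- which(sizes == max(sizes))
  if (length(biggest) > 1L) {
    dm <- as.matrix(d)
    medoid <- which.min(rowSums(dm))
    main_comp <- comp[medoid]
    if (!(main_comp %in% biggest)) main_comp <- biggest[1L]
  } else {
    main_comp <- biggest
  }
  cloud$flags <- ifelse(comp == main_comp, "main", "ectopic")
  cloud
}

interp_ml_at_dv <- function(polyline, dv_level, what = "level") {
  v <- polyline$vertices
  rng <- range(v[, "dv"])
  if (dv_level < rng[1L] - 1e-9 || dv_level > rng[2L] + 1e-9)
    stop(what, " dv = ", dv_level, " outside boundary DV span [",
         rng[1L], ", ", rng[2L], "]")
  stats::approx(v[, "dv"], v[, "ml"], xout = dv_level, ties = mean)$y
}

#' Brain width profile between left and right boundaries
#'
#' Measures the mediolateral width of the brain at a grid of query levels:
#' at each DV level the ML position of each boundary is obtained by linear
#' interpolation along the polyline and the width is right minus left.
#' With lists of boundaries indexed by AP level, widths are computed per
#' AP section (the standard 3 AP x 3 DV design).
#'
#' @param left,right Either single [boundary_polyline()] objects or named
#'   lists of them indexed by AP level.
#' @param dv_levels Numeric vector of DV query levels (micrometres).
#' @return An object of class `width_profile`: data frame with
#'   `ap_level`, `dv_level`, `width_um`.
#' @export
brain_width <- function(left, right, dv_levels) {
  single <- inherits(left, "boundary_polyline")
  if (single != inherits(right, "boundary_polyline"))
    stop("'left' and 'right' must both be polylines or both be lists")
  if (single) {
    left <- list(left); right <- list(right)
    ap_names <- NA_character_
  } else {
    if (length(left) != length(right) ||
        !identical(names(left), names(right)))
      stop("'left' and 'right' must have matching AP level names")
    ap_names <- if (is.null(names(left))) as.character(seq_along(left)) else
      names(left)
  }
  rows <- list()
  for (i in seq_along(left)) {
    for (dv in dv_levels) {
      ml_l <- interp_ml_at_dv(left[[i]], dv,
                              paste0("level (ap=", ap_names[i], ")"))
      ml_r <- interp_ml_at_dv(right[[i]], dv,
                              paste0("level (ap=", ap_names[i], ")"))
      w <- ml_r - ml_l
      if (w < 0)
        stop("boundaries cross (negative width ", signif(w, 4),
             ") at dv = ", dv, ", ap = ", ap_names[i])
      rows[[length(rows) + 1L]] <- data.frame(
        ap_level = ap_names[i], dv_level = dv, width_um = w,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("width_profile", "data.frame"))
}

#' Distortion index of a tissue boundary
#'
#' Total arc length of the boundary divided by the Euclidean distance
#' between its dorsal-most and ventral-most vertices. A straight boundary
#' scores 1; any bending, embedding or local intermixing of tissues
#' raises the index.
#'
#' @param boundary A [boundary_polyline()].
#' @return An object of class `distortion_index`: list with `arc_length`,
#'   `endpoint_distance` (micrometres) and `index`.
#' @export
distortion_index <- function(boundary) {
  stopifnot(inherits(boundary, "boundary_polyline"))
  v <- boundary$vertices
  arc <- polyline_length(v)
  i_dorsal <- which.max(v[, "dv"])
  i_ventral <- which.min(v[, "dv"])
  ep <- sqrt(sum((v[i_dorsal, ] - v[i_ventral, ])^2))
  if (ep < 1e-12)
    stop("dorsal-most and ventral-most vertices coincide; index undefined")
  structure(list(arc_length = arc, endpoint_distance = ep,
                 index = arc / ep),
            class = "distortion_index")
}

#' @export
print.distortion_index <- function(x, ...) {
  cat(sprintf("<distortion_index> %.4f (arc %.3f um / extremes distance %.3f um)\n",
              x$index, x$arc_length, x$endpoint_distance))
  invisible(x)
}

## minimal distance from point p (length-2) to a polyline vertex matrix
dist_point_polyline <- function(p, v) {
  a <- v[-nrow(v), , drop = FALSE]
  b <- v[-1L, , drop = FALSE]
  ab <- b - a
  ap <- cbind(p[1L] - a[, 1L], p[2L] - a[, 2L])
  len2 <- rowSums(ab^2)
  tt <- pmin(1, pmax(0, rowSums(ap * ab) / len2))
  proj <- a + ab * tt
  min(sqrt((p[1L] - proj[, 1L])^2 + (p[2L] - proj[, 2L])^2))
}

## point at arc-length s along polyline v
point_at_arclength <- function(v, s) {
  seg <- sqrt(rowSums(diff(v)^2))
  cum <- c(0, cumsum(seg))
  if (s > cum[length(cum)] + 1e-9)
    stop("station at arc length ", s, " beyond membrane length ",
         cum[length(cum)])
  i <- findInterval(s, cum, rightmost.closed = TRUE)
  i <- min(i, length(seg))
  f <- (s - cum[i]) / seg[i]
  v[i, ] + f * (v[i + 1L, ] - v[i, ])
}

#' Intercellular-gap thickness of one EM interface region
#'
#' Replicates the fixed-step EM sampling scheme: stations are placed every
#' `step_px` pixels of arc length along membrane A (at `step_px`,
#' `2*step_px`, ... up to the region length, giving
#' `floor(region_length_px/step_px)` measurements — 10 for a 1000-pixel
#' region sampled every 100 pixels); at each station the thickness is the
#' minimal distance from that point to membrane B, converted to
#' nanometres.
#'
#' @param region An [interface_region()].
#' @param step_px Sampling step in pixels (default 100).
#' @return An object of class `region_thickness`: list with `mean_nm`,
#'   `n_samples`, `samples_nm` and `step_px`.
#' @export
interface_thickness <- function(region, step_px = 100) {
  stopifnot(inherits(region, "interface_region"))
  if (!is.numeric(step_px) || step_px <= 0) stop("'step_px' must be > 0")
  L <- region$region_length_px
  if (L < step_px)
    stop("region (", L, " px) shorter than one sampling step (", step_px, " px)")
  n <- floor(L / step_px)
  stations <- step_px * seq_len(n)
  va <- region$membrane_a$vertices
  vb <- region$membrane_b$vertices
  samples_px <- vapply(stations, function(s) {
    p <- point_at_arclength(va, s)
    dist_point_polyline(p, vb)
  }, 0)
  if (any(samples_px <= 0))
    stop("membranes intersect at station(s) ",
         paste(stations[samples_px <= 0], collapse = ", "))
  samples_nm <- samples_px * region$px_size_nm
  structure(list(mean_nm = mean(samples_nm), n_samples = n,
                 samples_nm = samples_nm, step_px = step_px),
            class = "region_thickness")
}

#' Per-embryo mean intercellular-gap thickness
#'
#' Averages first per region, then per embryo (unweighted mean of region
#' means), matching how EM thickness data are summarised per animal.
#'
#' @param regions Either a numeric vector of per-region means (nm) or a
#'   list of `region_thickness` results.
#' @return An object of class `thickness_summary`: `per_region_means`,
#'   `embryo_mean` (nm), `n_regions`.
#' @export
thickness_embryo_mean <- function(regions) {
  if (is.list(regions) && length(regions) &&
      all(vapply(regions, inherits, TRUE, "region_thickness")))
    regions <- vapply(regions, `[[`, 0, "mean_nm")
  regions <- as.numeric(regions)
  if (!length(regions)) stop("no region means supplied")
  structure(list(per_region_means = regions,
                 embryo_mean = mean(regions),
                 n_regions = length(regions)),
            class = "thickness_summary")
}

#' @export
print.thickness_summary <- function(x, ...) {
  cat(sprintf("<thickness_summary> embryo mean %.2f nm over %d region(s)\n",
              x$embryo_mean, x$n_regions))
  invisible(x)
}
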