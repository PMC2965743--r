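#' Scan-line specification for simulated confocal line scans
#'
#' The scan line mimics a confocal line-scan recording: a straight line
#' parallel to the depth axis, offset `offset_um` (default 200 nm) from
#' the t-tubule wall at azimuthal angle `angle_deg` about the tubule axis
#' at the mouth. Because the tubule is widest at its mouth, the line is
#' placed at radial distance (mouth radius + offset) from the mouth
#' center, which keeps it at least `offset_um` outside the tubule along
#' its whole depth. Reference spots (defaults 0.17, 3.09 and 5.45 um
#' along the line) are the fixed positions at which the heterogeneity
#' statistic is evaluated.
#'
#' @param offset_um radial clearance from the tubule wall (um), > 0.
#' @param angle_deg azimuth about the tubule axis (degrees); 120 is the
#'   reference position, 60 the alternative.
#' @param spacing_um sample spacing along the line (um).
#' @param spots reference positions along the line (um depth).
#' @return object of class `linescan_spec`.
#' @export
linescan_spec <- function(offset_um = 0.2, angle_deg = 120,
                          spacing_um = 0.1,
                          spots = c(0.17, 3.09, 5.45)) {
  stopifnot(offset_um > 0, spacing_um > 0, all(spots >= 0))
  structure(list(offset_um = offset_um, angle_deg = angle_deg,
                 spacing_um = spacing_um, spots = spots),
            class = "linescan_spec")
}

# widest radius of the vertical (trunk/funnel) part of the tubule
tubule_mouth_radius <- function(mesh) {
  sk <- mesh$skeleton
  vert <- abs(sk[, 4] - sk[, 1]) + abs(sk[, 5] - sk[, 2]) < 1e-6 |
    sk[, 3] < 1e-9        # segments starting at the surface
  max(sk[vert, c(7, 8)])
}

# barycentric point location + interpolation weights for points in a mesh.
# Returns list(tet, weights) with one row per point; errors if a point is
# outside the mesh (beyond tolerance).
locate_points <- function(mesh, pts) {
  v <- mesh$vertices; tt <- mesh$tets
  a <- v[tt[, 1], , drop = FALSE]
  e1 <- v[tt[, 2], , drop = FALSE] - a
  e2 <- v[tt[, 3], , drop = FALSE] - a
  e3 <- v[tt[, 4], , drop = FALSE] - a
  # inverse of [e1 e2 e3] per tet via cofactors
  c11 <- e2[, 2] * e3[, 3] - e2[, 3] * e3[, 2]
  c12 <- e2[, 3] * e3[, 1] - e2[, 1] * e3[, 3]
  c13 <- e2[, 1] * e3[, 2] - e2[, 2] * e3[, 1]
  det <- e1[, 1] * c11 + e1[, 2] * c12 + e1[, 3] * c13
  c21 <- e3[, 2] * e1[, 3] - e3[, 3] * e1[, 2]
  c22 <- e3[, 3] * e1[, 1] - e3[, 1] * e1[, 3]
  c23 <- e3[, 1] * e1[, 2] - e3[, 2] * e1[, 1]
  c31 <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  c32 <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  c33 <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  n <- nrow(pts)
  tet_id <- integer(n); W <- matrix(0, n, 4)
  for (p in seq_len(n)) {
    dx <- pts[p, 1] - a[, 1]; dy <- pts[p, 2] - a[, 2]
    dz <- pts[p, 3] - a[, 3]
    l1 <- (dx * c11 + dy * c12 + dz * c13) / det
    l2 <- (dx * c21 + dy * c22 + dz * c23) / det
    l3 <- (dx * c31 + dy * c32 + dz * c33) / det
    l0 <- 1 - l1 - l2 - l3
    worst <- pmin(l0, l1, l2, l3)
    best <- which.max(worst)
    if (worst[best] < -1e-6)
      stop("point (", paste(signif(pts[p, ], 4), collapse = ", "),
           ") lies outside the mesh (e.g. scan line entering the ",
           "tubule lumen)")
    tet_id[p] <- best
    W[p, ] <- pmax(c(l0[best], l1[best], l2[best], l3[best]), 0)
    W[p, ] <- W[p, ] / sum(W[p, ])
  }
  list(tet = tet_id, weights = W)
}

#' Extract a simulated line-scan image from a 3-D solution
#'
#' Samples one concentration field along the scan line at every output
#' time by piecewise-linear interpolation within the containing
#' tetrahedra, producing a position x time matrix analogous to a
#' confocal line-scan image. Free Ca2+ is the default species; the
#' Fluo-3 complex (`"Fluo3"`) serves as the fluorescence proxy.
#'
#' @param solution a [run_3d()] result with recorded fields.
#' @param spec a [linescan_spec()].
#' @param species field to sample: `"Ca"` or a buffer name.
#' @return object of class `linescan_image`: list with `positions` (um,
#'   depth along the line), `times` (ms), `values` (position x time, uM),
#'   `species`, `line_origin`, `spec`.
#' @export
extract_linescan <- function(solution, spec = linescan_spec(),
                             species = "Ca") {
  stopifnot(inherits(solution, "solution"), inherits(spec, "linescan_spec"))
  if (is.null(solution$fields))
    stop("solution was run without recorded fields")
  if (!species %in% names(solution$fields))
    stop("unknown species: ", species)
  mesh <- solution$mesh
  mspec <- mesh$spec
  rho <- tubule_mouth_radius(mesh) + spec$offset_um
  th <- spec$angle_deg * pi / 180
  x0 <- mspec$mouth_center[1] + rho * cos(th)
  y0 <- mspec$mouth_center[2] + rho * sin(th)
  if (x0 < 0 || x0 > mspec$box_x || y0 < 0 || y0 > mspec$box_y)
    stop("scan line exits the box; reduce offset or change angle")
  zmax <- mspec$tubule_depth
  positions <- seq(0, zmax, by = spec$spacing_um)
  pts <- cbind(x0, y0, positions)
  loc <- locate_points(mesh, pts)
  fld <- solution$fields[[species]]
  vals <- matrix(0, length(positions), length(solution$time))
  for (j in 1:4)
    vals <- vals + loc$weights[, j] * fld[mesh$tets[loc$tet, j], ,
                                          drop = FALSE]
  structure(list(positions = positions, times = solution$time,
                 values = vals, species = species,
                 line_origin = c(x0, y0), spec = spec),
            class = "linescan_image")
}

#' @export
print.linescan_image <- function(x, ...) {
  cat(sprintf("linescan_image (%s): %d positions x %d times, range %.4f-%.4f uM\n",
              x$species, length(x$positions), length(x$times),
              min(x$values), max(x$values)))
  invisible(x)
}

# bilinear sample of a linescan image at (position, time)
linescan_value <- function(image, position, t) {
  vapply(position, function(p) {
    col <- stats::approx(image$times, seq_along(image$times), t,
                         rule = 2)$y
    c0 <- floor(col); c1 <- min(c0 + 1, length(image$times)); f <- col - c0
    v0 <- stats::approx(image$positions, image$values[, c0], p, rule = 2)$y
    v1 <- stats::approx(image$positions, image$values[, c1], p, rule = 2)$y
    (1 - f) * v0 + f * v1
  }, numeric(1))
}

#' Spatial Ca2+ heterogeneity (SCH)
#'
#' `SCH(t) = (max - min) / max` of the concentrations at the reference
#' spots along the scan line at time `t`: 0 for a spatially uniform
#' field, approaching 1 for strongly non-uniform fields. Scale-free:
#' invariant under uniform scaling of the concentrations.
#'
#' @param image a [extract_linescan()] result.
#' @param spots reference positions (um) along the line.
#' @param t time (ms), vectorized.
#' @return SCH value(s) in `[0, 1]`.
#' @export
compute_sch <- function(image, spots = image$spec$spots, t) {
  stopifnot(inherits(image, "linescan_image"))
  if (any(spots < min(image$positions) - 1e-9 |
            spots > max(image$positions) + 1e-9))
    stop("reference spots outside the scanned positions")
  vapply(t, function(tj) {
    v <- linescan_value(image, spots, tj)
    if (max(v) <= 0) stop("SCH undefined: maximal value is zero")
    (max(v) - min(v)) / max(v)
  }, numeric(1))
}

#' SCH report over the named epochs
#'
#' Evaluates SCH at the standard epochs: the LCC current peak, 70 ms
#' (pulse end), the global Ca2+ peak, 100 ms and 200 ms.
#'
#' @param image a [extract_linescan()] result.
#' @param global the matching `global_transient` (for the peak epochs).
#' @param lcc,protocol LCC template and protocol (for the current-peak
#'   epoch); defaults match the standard model.
#' @return data frame with `epoch`, `time` (ms), `sch`.
#' @export
sch_report <- function(image, global, lcc = lcc_params(),
                       protocol = voltage_protocol()) {
  t_ica <- lcc$tau_act * log(1 + lcc$tau_inact / lcc$tau_act)
  t_peak <- transient_metrics(global)$t_peak
  epochs <- c(t_ica_peak = t_ica, t_70ms = 70, t_ca_peak = t_peak,
              t_100ms = 100, t_200ms = 200)
  data.frame(epoch = names(epochs), time = as.numeric(epochs),
             sch = compute_sch(image, t = as.numeric(epochs)),
             row.names = NULL)
}

#' Peak metrics of a transient
#'
#' @param trace a `global_transient` data frame (uses its `Ca` column),
#'   or a numeric vector of values with `time` supplied.
#' @param time time grid (ms) when `trace` is a plain vector.
#' @return list with `peak` (uM), `t_peak` (ms; first occurrence on
#'   ties) and `value_at(t)` (linear interpolation).
#' @export
transient_metrics <- function(trace, time = NULL) {
  if (is.data.frame(trace)) {
    time <- trace$time
    vals <- trace$Ca
  } else {
    vals <- trace
  }
  if (!length(vals)) stop("empty trace")
  if (is.null(time) || length(time) != length(vals))
    stop("time grid missing or mismatched")
  i <- which.max(vals)
  list(peak = vals[i], t_peak = time[i],
       value_at = function(t) stats::approx(time, vals, t, rule = 2)$y)
}

#' Detect a propagating concentration front in a line-scan image
#'
#' Computes the first threshold-crossing (onset) time at every scanned
#' position (linear interpolation between frames). A front is
#' "initiated" when onset times increase monotonically over a contiguous
#' span of at least `min_span_um` starting near the external surface;
#' its speed is span / elapsed time over that window. The front
#' "faltered" if the monotone span ends before the last scanned
#' position.
#'
#' @param image a [extract_linescan()] result.
#' @param threshold concentration threshold (uM), above baseline.
#' @param min_span_um minimum monotone span to call initiation (um).
#' @return list with `initiated`, `onset` (per-position times, NA where
#'   never crossed), `span_um`, `speed_um_per_ms`, `faltered`.
#' @export
detect_front <- function(image, threshold, min_span_um = 1) {
  stopifnot(inherits(image, "linescan_image"))
  np <- length(image$positions)
  onset <- rep(NA_real_, np)
  for (p in seq_len(np)) {
    v <- image$values[p, ]
    j <- which(v >= threshold)[1]
    if (!is.na(j)) {
      if (j == 1L) onset[p] <- image$times[1]
      else {
        f <- (threshold - v[j - 1]) / (v[j] - v[j - 1])
        onset[p] <- image$times[j - 1] +
          f * (image$times[j] - image$times[j - 1])
      }
    }
  }
  # longest run of strictly increasing onset starting from the first
  # crossed position nearest the surface
  first <- which(!is.na(onset))[1]
  if (is.na(first))
    return(list(initiated = FALSE, onset = onset, span_um = 0,
                speed_um_per_ms = NA_real_, faltered = FALSE))
  run_end <- first
  while (run_end < np && !is.na(onset[run_end + 1]) &&
           onset[run_end + 1] > onset[run_end] - 1e-9 &&
           onset[run_end + 1] > onset[first])
    run_end <- run_end + 1
  span <- image$positions[run_end] - image$positions[first]
  dtt <- onset[run_end] - onset[first]
  initiated <- span >= min_span_um && dtt > 0
  list(initiated = initiated, onset = onset, span_um = span,
       speed_um_per_ms = if (initiated) span / dtt else NA_real_,
       faltered = initiated && run_end < np)
}
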