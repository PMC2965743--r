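#' T-tubule compartment specification
#'
#' Parametric description of the synthetic compartment: a box of
#' `box_x` x `box_y` um in the sarcolemmal plane and `box_depth` um deep,
#' with one t-tubule entering the top face at `mouth_center` and reaching
#' `tubule_depth` below the surface. The tubule is either a tree (`variant
#' = "branched"`): a wandering trunk with `n_branches` closed side
#' branches, trunk radius tapering from `radius_max` near the mouth to
#' `radius_min` at the terminus, plus a funnel-shaped mouth vestibule
#' flaring to `mouth_radius` at the surface; or an idealized straight
#' cylinder (`variant = "cylindrical"`) of radius
#' `(radius_min + radius_max)/2` with a closed hemispherical end and no
#' funnel. `seed` fixes the randomized trunk wander and branch placement;
#' identical spec and seed give identical meshes.
#'
#' The default values are calibrated so that the generated mesh reproduces
#' the morphometry of the imaging-derived compartment: volume ~23.31 um^3,
#' membrane area ~9.00 um^2 with ~64% of it t-tubular, tubule depth
#' 5.645 um, tubule diameters within the measured 0.19--0.469 um range.
#'
#' @param box_x,box_y top-face edge lengths (um).
#' @param box_depth box depth (um).
#' @param tubule_depth tubule reach below the surface (um), <
#'   `box_depth`.
#' @param radius_min,radius_max trunk radius range (um); cross-section
#'   diameters then span `[2*radius_min, 2*radius_max]`.
#' @param mouth_radius radius of the funnel opening at the surface (um);
#'   only used by the branched variant.
#' @param funnel_depth depth over which the mouth funnel tapers down to
#'   the trunk radius (um).
#' @param n_branches number of closed side branches (>= 1 for the
#'   branched variant).
#' @param branch_radius,branch_length side-branch radius and length (um).
#' @param mouth_center length-2 xy position of the mouth on the top face
#'   (um); default is the face center.
#' @param variant `"branched"` or `"cylindrical"`.
#' @param seed integer seed for the randomized skeleton.
#' @return object of class `ttubule_spec`.
#' @export
ttubule_spec <- function(box_x = 2, box_y = 2, box_depth = 5.96,
                         tubule_depth = 5.645,
                         radius_min = 0.095, radius_max = 0.155,
                         mouth_radius = 0.49, funnel_depth = 0.35,
                         n_branches = 2, branch_radius = 0.1,
                         branch_length = 0.6,
                         mouth_center = c(box_x / 2, box_y / 2),
                         variant = c("branched", "cylindrical"),
                         seed = 42L) {
  variant <- match.arg(variant)
  stopifnot(box_x > 0, box_y > 0, box_depth > 0,
            tubule_depth > 0, tubule_depth < box_depth,
            radius_min > 0, radius_min <= radius_max,
            length(mouth_center) == 2)
  if (variant == "branched") {
    stopifnot(n_branches >= 1, mouth_radius >= radius_max,
              funnel_depth > 0, funnel_depth < tubule_depth,
              branch_radius > 0, branch_length > 0)
  }
  structure(list(box_x = box_x, box_y = box_y, box_depth = box_depth,
                 tubule_depth = tubule_depth, radius_min = radius_min,
                 radius_max = radius_max, mouth_radius = mouth_radius,
                 funnel_depth = funnel_depth, n_branches = n_branches,
                 branch_radius = branch_radius,
                 branch_length = branch_length,
                 mouth_center = as.numeric(mouth_center),
                 variant = variant, seed = as.integer(seed)),
            class = "ttubule_spec")
}

# Build the tubule skeleton: a matrix of tapered-capsule segments with
# columns x0,y0,z0,x1,y1,z1,r0,r1. Deterministic in spec$seed. The tree
# is a trunk (funnel + wandering tapered shaft) with side branches; no
# cycles by construction.
ttubule_skeleton <- function(spec) {
  cx <- spec$mouth_center[1]; cy <- spec$mouth_center[2]
  if (spec$variant == "cylindrical") {
    r <- (spec$radius_min + spec$radius_max) / 2
    # capsule end: hemispherical cap at tubule_depth - r so the reach is
    # exactly tubule_depth
    seg <- matrix(c(cx, cy, 0, cx, cy, spec$tubule_depth - r, r, r),
                  nrow = 1)
    colnames(seg) <- c("x0", "y0", "z0", "x1", "y1", "z1", "r0", "r1")
    return(seg)
  }
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(spec$seed)

  segs <- list()
  # mouth funnel: radius flares from the trunk radius to mouth_radius at
  # the surface (t-tubule openings are funnel shaped)
  segs[[1]] <- c(cx, cy, 0, cx, cy, spec$funnel_depth,
                 spec$mouth_radius, spec$radius_max)
  # trunk: piecewise-linear wandering axis, radius tapering linearly from
  # radius_max (top) to radius_min (terminus)
  nseg <- 5L
  z <- seq(spec$funnel_depth, spec$tubule_depth, length.out = nseg + 1L)
  wander <- 0.12
  xs <- cx + c(0, cumsum(stats::runif(nseg - 1L, -wander, wander)), 0)
  ys <- cy + c(0, cumsum(stats::runif(nseg - 1L, -wander, wander)), 0)
  # keep terminus under the mouth; interior points already jittered
  rr <- spec$radius_max +
    (spec$radius_min - spec$radius_max) *
    (z - spec$funnel_depth) / (spec$tubule_depth - spec$funnel_depth)
  for (i in seq_len(nseg))
    segs[[length(segs) + 1L]] <-
      c(xs[i], ys[i], z[i], xs[i + 1L], ys[i + 1L], z[i + 1L],
        rr[i], rr[i + 1L])
  # side branches: attach to the trunk at random depths, run nearly
  # horizontally, ends are closed (rounded caps)
  zb <- stats::runif(spec$n_branches, 1.2, 0.8 * spec$tubule_depth)
  az <- stats::runif(spec$n_branches, 0, 2 * pi)
  for (b in seq_len(spec$n_branches)) {
    i <- findInterval(zb[b], z, all.inside = TRUE)
    f <- (zb[b] - z[i]) / (z[i + 1L] - z[i])
    p0 <- c(xs[i] + f * (xs[i + 1L] - xs[i]),
            ys[i] + f * (ys[i + 1L] - ys[i]), zb[b])
    dirv <- c(cos(az[b]), sin(az[b]), 0.25)
    dirv <- dirv / sqrt(sum(dirv^2))
    p1 <- p0 + spec$branch_length * dirv
    segs[[length(segs) + 1L]] <-
      c(p0, p1, spec$branch_radius, spec$branch_radius)
  }
  seg <- do.call(rbind, segs)
  colnames(seg) <- c("x0", "y0", "z0", "x1", "y1", "z1", "r0", "r1")
  seg
}

# Level-set function of the tubule lumen: positive outside the tubule
# (cytosol), negative inside. Distance to each tapered capsule is
# approximated as (distance to axis segment) - (radius at the clamped
# axial parameter); the zero level set is the exact tubule wall for
# vertical cross-sections and rounded (spherical) at segment ends, which
# closes every branch with a cap. p: n x 3 matrix.
tubule_sdf <- function(p, skeleton) {
  if (is.null(dim(p))) p <- matrix(p, ncol = 3)
  n <- nrow(p)
  d <- rep(Inf, n)
  for (i in seq_len(nrow(skeleton))) {
    s <- skeleton[i, ]
    a <- s[1:3]; b <- s[4:6]
    ab <- b - a
    L2 <- sum(ab^2)
    t <- ((p[, 1] - a[1]) * ab[1] + (p[, 2] - a[2]) * ab[2] +
            (p[, 3] - a[3]) * ab[3]) / L2
    t <- pmin(pmax(t, 0), 1)
    dx <- p[, 1] - (a[1] + t * ab[1])
    dy <- p[, 2] - (a[2] + t * ab[2])
    dz <- p[, 3] - (a[3] + t * ab[3])
    r <- s[7] + t * (s[8] - s[7])
    d <- pmin(d, sqrt(dx * dx + dy * dy + dz * dz) - r)
  }
  d
}

# --- structured background mesh -------------------------------------------

# Kuhn 6-tet decomposition of the unit cube; rows are tets, entries index
# the cube corner (dx, dy, dz) as 1 + dx + 2*dy + 4*dz. All cubes use the
# same decomposition, so shared faces carry identical diagonals and the
# global mesh is conforming.
.kuhn_paths <- rbind(c(1, 2, 4, 8), c(1, 2, 6, 8), c(1, 3, 4, 8),
                     c(1, 3, 7, 8), c(1, 5, 6, 8), c(1, 5, 7, 8))

box_grid_mesh <- function(box, h) {
  nx <- max(2L, round(box[1] / h)); ny <- max(2L, round(box[2] / h))
  nz <- max(2L, round(box[3] / h))
  xs <- seq(0, box[1], length.out = nx + 1L)
  ys <- seq(0, box[2], length.out = ny + 1L)
  zs <- seq(0, box[3], length.out = nz + 1L)
  nvx <- nx + 1L; nvy <- ny + 1L; nvz <- nz + 1L
  verts <- cbind(rep(xs, times = nvy * nvz),
                 rep(rep(ys, each = nvx), times = nvz),
                 rep(zs, each = nvx * nvy))
  vid <- function(i, j, k) 1L + i + nvx * (j + nvy * k)  # 0-based i,j,k
  ci <- rep(0:(nx - 1L), times = ny * nz)
  cj <- rep(rep(0:(ny - 1L), each = nx), times = nz)
  ck <- rep(0:(nz - 1L), each = nx * ny)
  corner <- cbind(vid(ci, cj, ck), vid(ci + 1L, cj, ck),
                  vid(ci, cj + 1L, ck), vid(ci + 1L, cj + 1L, ck),
                  vid(ci, cj, ck + 1L), vid(ci + 1L, cj, ck + 1L),
                  vid(ci, cj + 1L, ck + 1L), vid(ci + 1L, cj + 1L, ck + 1L))
  tets <- matrix(0L, nrow(corner) * 6L, 4L)
  for (t in 1:6)
    tets[seq.int(t, by = 6L, length.out = nrow(corner)), ] <-
      corner[, .kuhn_paths[t, ]]
  list(vertices = verts, tets = tets, nx = nx, ny = ny, nz = nz, h = h)
}

signed_tet_volume <- function(verts, tets) {
  a <- verts[tets[, 1], , drop = FALSE]
  b <- verts[tets[, 2], , drop = FALSE] - a
  c2 <- verts[tets[, 3], , drop = FALSE] - a
  d <- verts[tets[, 4], , drop = FALSE] - a
  (b[, 1] * (c2[, 2] * d[, 3] - c2[, 3] * d[, 2]) -
     b[, 2] * (c2[, 1] * d[, 3] - c2[, 3] * d[, 1]) +
     b[, 3] * (c2[, 1] * d[, 2] - c2[, 2] * d[, 1])) / 6
}

triangle_areas <- function(verts, tris) {
  a <- verts[tris[, 1], , drop = FALSE]
  u <- verts[tris[, 2], , drop = FALSE] - a
  v <- verts[tris[, 3], , drop = FALSE] - a
  cx <- u[, 2] * v[, 3] - u[, 3] * v[, 2]
  cy <- u[, 3] * v[, 1] - u[, 1] * v[, 3]
  cz <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
  0.5 * sqrt(cx * cx + cy * cy + cz * cz)
}

# Dompierre-style prism split: triangles (a1,a2,a3) and (b1,b2,b3) with
# ai over bi. Rotates the global minimum to position 1 and picks the
# third-quad diagonal through its smallest vertex; every quad diagonal
# then passes through the quad's minimum id, so neighbours agree.
split_prism <- function(a, b) {
  idx <- which.min(c(a, b))
  rot <- switch(((idx - 1L) %% 3L) + 1L, c(1L, 2L, 3L), c(2L, 3L, 1L),
                c(3L, 1L, 2L))
  if (idx > 3L) { tmp <- a; a <- b[rot]; b <- tmp[rot] } else {
    a <- a[rot]; b <- b[rot]
  }
  if (min(a[2], b[3]) < min(a[3], b[2]))
    rbind(c(a[1], a[2], a[3], b[3]), c(a[1], a[2], b[3], b[2]),
          c(a[1], b[2], b[3], b[1]))
  else
    rbind(c(a[1], a[2], a[3], b[2]), c(a[1], b[2], a[3], b[3]),
          c(a[1], b[2], b[3], b[1]))
}

# quad (q1,q2,q3,q4) in cyclic order -> two triangles, diagonal through
# the quad's minimum global id (neighbour-consistent)
split_quad <- function(q) {
  if (min(q[1], q[3]) < min(q[2], q[4]))
    rbind(q[c(1, 2, 3)], q[c(1, 3, 4)])
  else
    rbind(q[c(1, 2, 4)], q[c(2, 3, 4)])
}

#' Generate a labeled tetrahedral mesh of the compartment
#'
#' Meshes the cytosolic domain (box minus tubule lumen): a structured
#' box grid (six tetrahedra per cube) is carved along the tubule wall by
#' vertex snapping onto the zero level set of the tubule distance
#' function followed by marching-tetrahedra subdivision of the crossed
#' elements. Boundary facets are labeled `external_membrane` (top face,
#' minus the mouth opening), `ttubule_membrane` (tubule wall including
#' the closed branch-end caps) or `reflective` (the five remaining box
#' faces). Identical `spec` and seed give identical meshes.
#'
#' @param spec a [ttubule_spec()].
#' @param target_edge_length background grid spacing h (um); must not
#'   exceed the minimum tubule radius so the lumen is resolved by at
#'   least two elements across its smallest diameter.
#' @return object of class `labeled_mesh`: list with `vertices` (n x 3,
#'   um), `tets` (m x 4 vertex indices, positively oriented), `facets`
#'   (boundary triangles, f x 3), `facet_label`, `facet_area`,
#'   `facet_centroid`, `membrane_distance` (per-vertex distance to the
#'   membrane, um), `stats` (a `geometry_stats`), `spec`, `h`.
#' @export
generate_ttubule_mesh <- function(spec, target_edge_length = 0.07) {
  stopifnot(inherits(spec, "ttubule_spec"))
  h <- target_edge_length
  rmin <- if (spec$variant == "cylindrical")
    (spec$radius_min + spec$radius_max) / 2 else
      min(spec$radius_min, spec$branch_radius)
  if (h > rmin + 1e-12)
    stop("target_edge_length ", h, " um does not resolve the minimum ",
         "tubule radius ", rmin, " um (need h <= r_min)")
  skel <- ttubule_skeleton(spec)
  box <- c(spec$box_x, spec$box_y, spec$box_depth)
  # feasibility: tubule must stay strictly inside the side and bottom
  # faces (margin one cell)
  margin <- h
  lo <- pmin(skel[, 1] - skel[, 7], skel[, 4] - skel[, 8])
  hi <- pmax(skel[, 1] + skel[, 7], skel[, 4] + skel[, 8])
  loy <- pmin(skel[, 2] - skel[, 7], skel[, 5] - skel[, 8])
  hiy <- pmax(skel[, 2] + skel[, 7], skel[, 5] + skel[, 8])
  hiz <- pmax(skel[, 3] + skel[, 7], skel[, 6] + skel[, 8])
  if (any(lo < margin) || any(hi > box[1] - margin) ||
      any(loy < margin) || any(hiy > box[2] - margin) ||
      any(hiz > box[3] - margin))
    stop("infeasible geometry: tubule exits the box (adjust spec)")

  bg <- box_grid_mesh(box, h)
  verts <- bg$vertices
  nv <- nrow(verts)
  phi <- tubule_sdf(verts, skel)

  # vertices pinned to box planes may only move within those planes
  eps <- 1e-9
  fixx <- verts[, 1] < eps | verts[, 1] > box[1] - eps
  fixy <- verts[, 2] < eps | verts[, 2] > box[2] - eps
  fixz <- verts[, 3] < eps | verts[, 3] > box[3] - eps

  snap_tol <- 0.22 * h
  snap <- which(abs(phi) < snap_tol)
  if (length(snap)) {
    p <- verts[snap, , drop = FALSE]
    for (it in 1:4) {
      f0 <- tubule_sdf(p, skel)
      dstep <- 1e-4
      shift <- function(col) { q <- p; q[, col] <- q[, col] + dstep; q }
      gx <- (tubule_sdf(shift(1), skel) - f0) / dstep
      gy <- (tubule_sdf(shift(2), skel) - f0) / dstep
      gz <- (tubule_sdf(shift(3), skel) - f0) / dstep
      gx[fixx[snap]] <- 0; gy[fixy[snap]] <- 0; gz[fixz[snap]] <- 0
      g2 <- gx * gx + gy * gy + gz * gz
      g2[g2 < 1e-12] <- Inf
      p <- p - cbind(f0 * gx / g2, f0 * gy / g2, f0 * gz / g2)
    }
    resid <- abs(tubule_sdf(p, skel))
    moved <- sqrt(rowSums((p - verts[snap, , drop = FALSE])^2))
    ok <- resid < 1e-3 * h & moved < 0.45 * h
    verts[snap[ok], ] <- p[ok, , drop = FALSE]
    phi[snap[ok]] <- 0
    snap <- snap[ok]
  }
  # undo snaps that flatten elements
  for (pass in 1:3) {
    vol <- signed_tet_volume(verts, bg$tets)
    bad <- which(abs(vol) < 1e-5 * h^3)
    if (!length(bad)) break
    badv <- intersect(unique(as.vector(bg$tets[bad, ])), snap)
    if (!length(badv)) break
    verts[badv, ] <- bg$vertices[badv, , drop = FALSE]
    phi[badv] <- tubule_sdf(verts[badv, , drop = FALSE], skel)
    snap <- setdiff(snap, badv)
  }

  sgn <- integer(nv)
  sgn[phi > 0] <- 1L
  sgn[phi < 0] <- -1L

  tsgn <- matrix(sgn[bg$tets], ncol = 4L)
  nneg <- rowSums(tsgn < 0L)
  npos <- rowSums(tsgn > 0L)
  keep_whole <- which(nneg == 0L & npos > 0L)
  mixed <- which(nneg > 0L & npos > 0L)
  # rare all-zero slivers along the surface: classify by centroid
  zero4 <- which(nneg == 0L & npos == 0L)
  if (length(zero4)) {
    cen <- (verts[bg$tets[zero4, 1], ] + verts[bg$tets[zero4, 2], ] +
              verts[bg$tets[zero4, 3], ] + verts[bg$tets[zero4, 4], ]) / 4
    keep_whole <- c(keep_whole, zero4[tubule_sdf(cen, skel) > 0])
  }

  # cut points on sign-changing edges, shared across elements via an
  # edge key; located by bisection on the level-set function
  edge_pairs <- NULL
  if (length(mixed)) {
    tm <- bg$tets[mixed, , drop = FALSE]
    combs <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
    ee <- do.call(rbind, lapply(1:6, function(i)
      cbind(tm[, combs[i, 1]], tm[, combs[i, 2]])))
    ee <- cbind(pmin(ee[, 1], ee[, 2]), pmax(ee[, 1], ee[, 2]))
    ee <- ee[sgn[ee[, 1]] * sgn[ee[, 2]] < 0L, , drop = FALSE]
    ee <- unique(ee)
    edge_pairs <- ee
  }
  cut_id <- new.env(hash = TRUE)
  new_pts <- NULL
  if (!is.null(edge_pairs) && nrow(edge_pairs)) {
    a <- verts[edge_pairs[, 1], , drop = FALSE]
    b <- verts[edge_pairs[, 2], , drop = FALSE]
    ta <- rep(0, nrow(edge_pairs)); tb <- rep(1, nrow(edge_pairs))
    fa <- phi[edge_pairs[, 1]]
    for (it in 1:30) {
      tmid <- (ta + tb) / 2
      pm <- a + tmid * (b - a)
      fm <- tubule_sdf(pm, skel)
      same <- sign(fm) == sign(fa) | fm == 0
      ta[same] <- tmid[same]
      fa[same] <- fm[same]
      tb[!same] <- tmid[!same]
    }
    tcut <- (ta + tb) / 2
    new_pts <- a + tcut * (b - a)
    keys <- paste(edge_pairs[, 1], edge_pairs[, 2])
    for (i in seq_along(keys)) assign(keys[i], nv + i, envir = cut_id)
    verts <- rbind(verts, new_pts)
  }
  cut_of <- function(u, v) get(paste(min(u, v), max(u, v)), envir = cut_id)

  # subdivide mixed tets, keeping the positive (cytosolic) part
  sub <- vector("list", length(mixed))
  for (ii in seq_along(mixed)) {
    tv <- bg$tets[mixed[ii], ]
    s <- sgn[tv]
    negs <- tv[s < 0L]; poss <- tv[s > 0L]; zers <- tv[s == 0L]
    nn <- length(negs); np <- length(poss)
    piece <- NULL
    if (nn == 1L && np == 3L) {
      cpts <- c(cut_of(negs, poss[1]), cut_of(negs, poss[2]),
                cut_of(negs, poss[3]))
      piece <- split_prism(poss, cpts)
    } else if (nn == 1L && np == 2L) {       # one zero vertex
      c1 <- cut_of(negs, poss[1]); c2 <- cut_of(negs, poss[2])
      tri2 <- split_quad(c(poss[1], poss[2], c2, c1))
      piece <- cbind(tri2, zers[1])
    } else if (nn == 1L && np == 1L) {       # two zero vertices
      piece <- matrix(c(poss, zers[1], zers[2], cut_of(negs, poss)),
                      nrow = 1)
    } else if (nn == 2L && np == 2L) {
      a3 <- c(poss[1], cut_of(negs[1], poss[1]), cut_of(negs[2], poss[1]))
      b3 <- c(poss[2], cut_of(negs[1], poss[2]), cut_of(negs[2], poss[2]))
      piece <- split_prism(a3, b3)
    } else if (nn == 2L && np == 1L) {       # one zero vertex
      piece <- matrix(c(poss, zers[1], cut_of(negs[1], poss),
                        cut_of(negs[2], poss)), nrow = 1)
    } else if (nn == 3L && np == 1L) {
      piece <- matrix(c(poss, cut_of(negs[1], poss), cut_of(negs[2], poss),
                        cut_of(negs[3], poss)), nrow = 1)
    }
    sub[[ii]] <- piece
  }
  tets <- rbind(bg$tets[keep_whole, , drop = FALSE], do.call(rbind, sub))
  storage.mode(tets) <- "integer"

  # drop degenerate slivers, orient positively
  vol <- signed_tet_volume(verts, tets)
  flip <- vol < 0
  tets[flip, c(3, 4)] <- tets[flip, c(4, 3)]
  vol <- abs(vol)
  tiny <- vol < 1e-9 * h^3
  if (any(tiny)) { tets <- tets[!tiny, , drop = FALSE]; vol <- vol[!tiny] }
  if (any(vol <= 0)) stop("meshing failure: degenerate elements remain")

  # compact vertex numbering
  used <- sort(unique(as.vector(tets)))
  remap <- integer(nrow(verts)); remap[used] <- seq_along(used)
  verts <- verts[used, , drop = FALSE]
  tets <- matrix(remap[tets], ncol = 4L)

  mesh <- finish_labeled_mesh(verts, tets, box, skel, spec, h)
  mesh
}

# boundary extraction, labeling and stats for a tet mesh carved from a box
finish_labeled_mesh <- function(verts, tets, box, skel, spec, h) {
  faces <- rbind(tets[, c(2, 3, 4)], tets[, c(1, 4, 3)],
                 tets[, c(1, 2, 4)], tets[, c(1, 3, 2)])
  key <- cbind(pmin(faces[, 1], pmin(faces[, 2], faces[, 3])),
               faces[, 1] + faces[, 2] + faces[, 3] -
                 pmin(faces[, 1], pmin(faces[, 2], faces[, 3])) -
                 pmax(faces[, 1], pmax(faces[, 2], faces[, 3])),
               pmax(faces[, 1], pmax(faces[, 2], faces[, 3])))
  o <- order(key[, 1], key[, 2], key[, 3])
  ks <- key[o, , drop = FALSE]
  dup_prev <- c(FALSE, rowSums(ks[-1, , drop = FALSE] ==
                                 ks[-nrow(ks), , drop = FALSE]) == 3L)
  dup_next <- c(dup_prev[-1], FALSE)
  bnd <- o[!(dup_prev | dup_next)]
  facets <- faces[bnd, , drop = FALSE]

  ptol <- 1e-6
  on_plane <- function(coord, value)
    matrix(abs(verts[facets, coord] - value) < ptol, ncol = 3L)
  allrow <- function(m) m[, 1] & m[, 2] & m[, 3]
  top <- allrow(on_plane(3, 0))
  refl <- allrow(on_plane(3, box[3])) | allrow(on_plane(1, 0)) |
    allrow(on_plane(1, box[1])) | allrow(on_plane(2, 0)) |
    allrow(on_plane(2, box[2]))
  label <- rep("ttubule_membrane", nrow(facets))
  label[refl] <- "reflective"
  label[top] <- "external_membrane"

  area <- triangle_areas(verts, facets)
  if (any(area < 1e-14)) stop("degenerate boundary facets")
  centroid <- (verts[facets[, 1], , drop = FALSE] +
                 verts[facets[, 2], , drop = FALSE] +
                 verts[facets[, 3], , drop = FALSE]) / 3

  # analytic distance to the membrane (top face + tubule wall); the
  # reflective faces are excluded
  memb_dist <- pmin(verts[, 3], abs(tubule_sdf(verts, skel)))

  mesh <- structure(list(vertices = verts, tets = tets, facets = facets,
                         facet_label = label, facet_area = area,
                         facet_centroid = centroid,
                         membrane_distance = memb_dist,
                         spec = spec, h = h, box = box, skeleton = skel),
                    class = "labeled_mesh")
  mesh$stats <- compute_geometry_stats(mesh)
  mesh
}

#' Morphometric statistics of a labeled mesh
#'
#' Volumes are sums of (positively oriented) tetrahedron volumes; areas
#' are sums of boundary-facet areas per label. `ttubule_fraction` is the
#' t-tubular share of the membrane (external + t-tubular) area.
#' @param mesh a `labeled_mesh`.
#' @return object of class `geometry_stats` with `compartment_volume`
#'   (um^3), `total_membrane_area`, `ttubule_area`, `external_area`
#'   (um^2), `ttubule_fraction`, `radius_range` (um), `tubule_depth`
#'   (um); the last two are taken from the generating spec when present.
#' @export
compute_geometry_stats <- function(mesh) {
  stopifnot(inherits(mesh, "labeled_mesh"))
  vol <- signed_tet_volume(mesh$vertices, mesh$tets)
  if (any(vol <= 0)) stop("mesh contains non-positively-oriented elements")
  if (any(mesh$facet_area < 1e-14)) stop("degenerate boundary facets")
  a_tt <- sum(mesh$facet_area[mesh$facet_label == "ttubule_membrane"])
  a_ext <- sum(mesh$facet_area[mesh$facet_label == "external_membrane"])
  a_refl <- sum(mesh$facet_area[mesh$facet_label == "reflective"])
  spec <- mesh$spec
  structure(list(
    compartment_volume = sum(vol),
    total_membrane_area = a_tt + a_ext,
    ttubule_area = a_tt,
    external_area = a_ext,
    reflective_area = a_refl,
    ttubule_fraction = if (a_tt + a_ext > 0) a_tt / (a_tt + a_ext) else 0,
    radius_range = if (!is.null(spec)) c(spec$radius_min, spec$radius_max)
      else c(NA_real_, NA_real_),
    tubule_depth = if (!is.null(spec)) spec$tubule_depth else NA_real_),
    class = "geometry_stats")
}

#' @export
print.geometry_stats <- function(x, ...) {
  cat(sprintf("compartment volume: %.3f um^3\n", x$compartment_volume))
  cat(sprintf("membrane area:      %.3f um^2 (t-tubule %.3f, external %.3f)\n",
              x$total_membrane_area, x$ttubule_area, x$external_area))
  cat(sprintf("t-tubule fraction:  %.1f%%\n", 100 * x$ttubule_fraction))
  invisible(x)
}

#' @export
print.labeled_mesh <- function(x, ...) {
  cat(sprintf("labeled_mesh: %d vertices, %d tetrahedra, %d boundary facets\n",
              nrow(x$vertices), nrow(x$tets), nrow(x$facets)))
  print(x$stats)
  invisible(x)
}

#' Per-vertex distance to the membrane
#'
#' Euclidean distance from every mesh vertex to the nearest
#' membrane-labeled boundary facet (`external_membrane` or
#' `ttubule_membrane`); reflective faces are excluded. Used to zero the
#' stationary-buffer concentration within the sub-sarcolemmal exclusion
#' depth and to validate scan-line placement. Exact point-to-triangle
#' distances, computed blockwise.
#' @param mesh a `labeled_mesh`.
#' @return numeric vector, one distance (um) per vertex.
#' @export
distance_to_membrane_field <- function(mesh) {
  stopifnot(inherits(mesh, "labeled_mesh"))
  memb <- which(mesh$facet_label %in% c("external_membrane",
                                        "ttubule_membrane"))
  if (!length(memb)) stop("mesh has no membrane facets")
  P <- mesh$vertices
  d2 <- rep(Inf, nrow(P))
  chunk <- max(1L, floor(2e6 / nrow(P)))
  for (start in seq(1L, length(memb), by = chunk)) {
    idx <- memb[start:min(start + chunk - 1L, length(memb))]
    for (fi in idx)
      d2 <- pmin(d2, point_triangle_dist2(
        P, mesh$vertices[mesh$facets[fi, 1], ],
        mesh$vertices[mesh$facets[fi, 2], ],
        mesh$vertices[mesh$facets[fi, 3], ]))
  }
  sqrt(d2)
}

# squared distance from points P (n x 3) to triangle (a, b, c);
# region-based projection (Ericson), vectorized over points
point_triangle_dist2 <- function(P, a, b, c) {
  ab <- b - a; ac <- c - a
  ap <- sweep(P, 2, a)
  d1 <- ap %*% ab; d2 <- ap %*% ac
  bp <- sweep(P, 2, b)
  d3 <- bp %*% ab; d4 <- bp %*% ac
  cp <- sweep(P, 2, c)
  d5 <- cp %*% ab; d6 <- cp %*% ac
  va <- d3 * d6 - d5 * d4
  vb <- d5 * d2 - d1 * d6
  vc <- d1 * d4 - d3 * d2
  denom <- va + vb + vc
  v <- vb / denom; w <- vc / denom
  # interior by default
  u <- 1 - v - w
  # vertex regions
  v[d1 <= 0 & d2 <= 0] <- 0; w[d1 <= 0 & d2 <= 0] <- 0
  v[d3 >= 0 & d4 <= d3] <- 1; w[d3 >= 0 & d4 <= d3] <- 0
  v[d6 >= 0 & d5 <= d6] <- 0; w[d6 >= 0 & d5 <= d6] <- 1
  # edge ab
  eab <- vc <= 0 & d1 >= 0 & d3 <= 0
  t_ab <- ifelse(d1 - d3 != 0, d1 / (d1 - d3), 0)
  v[eab] <- t_ab[eab]; w[eab] <- 0
  # edge ac
  eac <- vb <= 0 & d2 >= 0 & d6 <= 0
  t_ac <- ifelse(d2 - d6 != 0, d2 / (d2 - d6), 0)
  v[eac] <- 0; w[eac] <- t_ac[eac]
  # edge bc
  ebc <- va <= 0 & (d4 - d3) >= 0 & (d5 - d6) >= 0
  t_bc <- ifelse((d4 - d3) + (d5 - d6) != 0,
                 (d4 - d3) / ((d4 - d3) + (d5 - d6)), 0)
  v[ebc] <- 1 - t_bc[ebc]; w[ebc] <- t_bc[ebc]
  q <- cbind(a[1] + v * ab[1] + w * ac[1],
             a[2] + v * ab[2] + w * ac[2],
             a[3] + v * ab[3] + w * ac[3])
  rowSums((P - q)^2)
}
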