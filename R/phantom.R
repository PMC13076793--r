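# Ground-truth absorber phantoms: stochastic capillary networks with exact
# centerline bookkeeping, plus razor-edge / carbon-fiber / dispersed-cell
# calibration targets.

new_phantom <- function(absorber, voxel_pitch_um, spec = NULL, nodes = NULL,
                        edges = NULL, polylines = NULL, kind = "vascular") {
  if (is.null(nodes))
    nodes <- data.frame(id = integer(), x = numeric(), y = numeric(),
                        z = numeric())
  if (is.null(edges))
    edges <- data.frame(edge_id = integer(), node_from = integer(),
                        node_to = integer(), radius_um = numeric(),
                        length_um = numeric())
  structure(list(absorber = absorber,
                 voxel_pitch_um = voxel_pitch_um,
                 spec = spec, nodes = nodes, edges = edges,
                 polylines = if (is.null(polylines)) list() else polylines,
                 kind = kind),
            class = "vascular_phantom")
}

#' @export
print.vascular_phantom <- function(x, ...) {
  d <- dim(x$absorber)
  cat(sprintf("<vascular_phantom: %s, %d x %d x %d voxels, %d segments, total length %.0f um>\n",
              x$kind, d[1], d[2], d[3], nrow(x$edges), sum(x$edges$length_um)))
  invisible(x)
}

phantom_grid_dim <- function(size_um, pitch_um) {
  pmax(1L, as.integer(round(size_um / pitch_um)))
}

# Arc length of a polyline matrix (n x 3, um) by piecewise integration.
polyline_length <- function(p) {
  if (nrow(p) < 2) return(0)
  d <- diff(p)
  sum(sqrt(rowSums(d^2)))
}

#' Total ground-truth centerline length
#'
#' Independent bookkeeping check: integrates every stored centerline polyline
#' rather than trusting the per-edge `length_um` column.
#'
#' @param phantom A `vascular_phantom`.
#' @return Total length in um.
#' @export
total_centerline_length <- function(phantom) {
  if (!length(phantom$polylines)) return(0)
  sum(vapply(phantom$polylines, polyline_length, numeric(1)))
}

rasterize_phantom <- function(polylines, radii, dims, pitch, extra_spheres = NULL) {
  vox <- integer(prod(dims))
  if (length(polylines)) {
    rows <- do.call(rbind, lapply(seq_along(polylines), function(i) {
      p <- polylines[[i]]
      cbind(i, p, radii[i])
    }))
    vox <- cpp_rasterize_tubes(as.integer(dims), as.numeric(pitch), rows)
  }
  if (!is.null(extra_spheres) && nrow(extra_spheres)) {
    sph <- cpp_rasterize_spheres(as.integer(dims), as.numeric(pitch),
                                 extra_spheres)
    vox <- pmax(vox, sph)
  }
  array(as.numeric(vox), dim = dims)
}

# One persistent random-walk centerline of target arc length, reflecting off
# an inner margin of the volume. The instantaneous direction wiggles around a
# fixed overall heading (mean-reverting, emulating guided sprout elongation);
# without the reversion term long walks can hairpin back onto themselves,
# which merges the tube in voxel space and corrupts the traced topology.
# step_um is also the polyline sampling pitch.
walk_segment <- function(start, dir, target_len, size_um, margin,
                         step_um = 3, ang_sd = 0.04, reversion = 0.05,
                         collide = NULL) {
  n_steps <- max(1L, ceiling(target_len / step_um))
  pts <- matrix(0, n_steps + 1L, 3)
  pts[1L, ] <- start
  pos <- start
  heading <- dir
  len <- 0
  n_used <- 1L
  for (s in seq_len(n_steps)) {
    step_len <- min(step_um, target_len - len)
    dir <- dir + reversion * (heading - dir) + rnorm(3, sd = ang_sd)
    dir <- dir / sqrt(sum(dir^2))
    nxt <- pos + dir * step_len
    for (a in 1:3) {
      if (nxt[a] < margin[a] || nxt[a] > size_um[a] - margin[a]) {
        dir[a] <- -dir[a]
        heading[a] <- -heading[a]
        nxt[a] <- pos[a] + dir[a] * step_len
        nxt[a] <- min(max(nxt[a], margin[a]), size_um[a] - margin[a])
      }
    }
    # steer away from previously grown vessels (self-assembly with contact
    # avoidance)
    if (!is.null(collide) && collide(nxt, s)) {
      placed <- FALSE
      for (try_ in 1:8) {
        cand <- dir + rnorm(3, sd = 0.45)
        cand <- cand / sqrt(sum(cand^2))
        if (sum(cand * dir) < 0.2) next  # keep moving forward
        alt <- pos + cand * step_len
        if (any(alt < margin | alt > size_um - margin)) next
        if (!collide(alt, s)) {
          dir <- cand
          heading <- cand
          nxt <- alt
          placed <- TRUE
          break
        }
      }
      if (!placed) break  # boxed in: terminate the sprout early
    }
    len <- len + sqrt(sum((nxt - pos)^2))
    pos <- nxt
    n_used <- s + 1L
    pts[n_used, ] <- pos
    if (len >= target_len - 1e-9) break
  }
  pts <- pts[seq_len(n_used), , drop = FALSE]
  list(points = pts, dir = dir, length = polyline_length(pts))
}

# Spatial hash of grown centerline points for contact queries, cell size
# >= the largest interaction distance (2 * r_max + clearance); the default
# clearance of 8 um keeps avoided tubes farther apart than the voxel
# diagonal, so 26-connectivity cannot bridge them after rasterization.
make_occupancy <- function(cell_um = 40) {
  env <- new.env(parent = emptyenv())
  key <- function(c3) paste(c3, collapse = "_")
  list(
    add = function(pts, radius, id) {
      cells <- floor(pts / cell_um)
      for (i in seq_len(nrow(pts))) {
        k <- key(cells[i, ])
        env[[k]] <- rbind(env[[k]], c(pts[i, ], radius, id))
      }
    },
    # exclude_ids: segments allowed to touch (the parent and sibling tubes
    # meeting at this sprout's junction)
    near = function(p, radius, clearance = 8, exclude_ids = integer()) {
      c0 <- floor(p / cell_um)
      for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
        m <- env[[key(c0 + c(dx, dy, dz))]]
        if (is.null(m)) next
        d2 <- (m[, 1] - p[1])^2 + (m[, 2] - p[2])^2 + (m[, 3] - p[3])^2
        hit <- d2 < (m[, 4] + radius + clearance)^2
        if (length(exclude_ids)) hit <- hit & !(m[, 5] %in% exclude_ids)
        if (any(hit)) return(TRUE)
      }
      FALSE
    }
  )
}

random_unit_vector <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}

# Daughter directions at a bifurcation: a planar pair tilted off the parent
# axis on opposite sides (random branch plane, 40-70 degree half-angles), as
# in real vascular bifurcations. Opposed daughters separate immediately;
# same-side daughters would run merged in voxel space for tens of um (their
# tubes overlap until the gap exceeds the two radii), corrupting tracing.
branch_directions <- function(parent_dir) {
  r <- rnorm(3)
  orth <- r - sum(r * parent_dir) * parent_dir
  orth <- orth / sqrt(sum(orth^2))
  lapply(c(1, -1), function(sgn) {
    ang <- runif(1, 40, 70) * pi / 180
    d <- cos(ang) * parent_dir + sgn * sin(ang) * orth
    d / sqrt(sum(d^2))
  })
}

#' Grow a synthetic vascular phantom
#'
#' Seeds `n_sprouts` sprout points uniformly in the hydrogel volume and grows
#' each into a branching tube network by a sprout-elongate-branch persistent
#' random walk. Segment arc lengths are drawn from the per-culture-day
#' log-normal defaults (see [phantom_spec()]); each finished segment either
#' terminates or branches into exactly two daughters, so every internal graph
#' node has degree 1 or 3 and traced branch-to-branch segments correspond
#' one-to-one to generated ones. Ground-truth centerlines, radii and exact
#' arc lengths are recorded in the returned graph. A non-control
#' `spec$condition` is applied through [apply_drug_effect()] after growth.
#'
#' Calling this function seeds R's RNG from `spec$rng_seed`; identical specs
#' give bit-identical phantoms.
#'
#' @param spec A [phantom_spec()].
#' @return A `vascular_phantom`: absorber array (1 inside vessels), node and
#'   edge tables, and centerline polylines.
#' @export
grow_vascular_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  margin <- rep(max(spec$vessel_radius_um), 3)
  min_len <- 10
  stop_if(any(spec$volume_size_um < min_len + 2 * margin),
          "volume too small to contain one minimum-length segment")
  dims <- phantom_grid_dim(spec$volume_size_um, spec$voxel_pitch_um)
  set.seed(spec$rng_seed)
  lp <- day_length_params(spec$culture_day)

  nodes <- list()
  edges <- list()
  polylines <- list()
  radii <- numeric()
  node_ct <- 0L
  edge_ct <- 0L
  add_node <- function(p) {
    node_ct <<- node_ct + 1L
    nodes[[node_ct]] <<- c(id = node_ct, x = p[1], y = p[2], z = p[3])
    node_ct
  }
  if (spec$n_sprouts > 0) {
    # stack of pending sprouts: list(start, dir, generation, parent node id)
    pending <- lapply(seq_len(spec$n_sprouts), function(i) {
      start <- margin + runif(3) * (spec$volume_size_um - 2 * margin)
      list(start = start, dir = random_unit_vector(), gen = 1L,
           node = NA_integer_)
    })
    occ <- make_occupancy(cell_um = 2 * max(spec$vessel_radius_um) + 10)
    edge_from <- integer()
    edge_to <- integer()
    r_max <- max(spec$vessel_radius_um)
    while (length(pending)) {
      job <- pending[[1L]]
      pending <- pending[-1L]
      L <- max(min_len, rlnorm(1, lp$meanlog, lp$sdlog))
      r <- runif(1, spec$vessel_radius_um[1], spec$vessel_radius_um[2])
      if (is.na(job$node)) {
        # root sprout: resample the seed point until it clears every
        # existing tube, so no sprout is born inside another vessel
        ok <- !occ$near(job$start, r_max)
        tries <- 0L
        while (!ok && tries < 50L) {
          job$start <- margin + runif(3) * (spec$volume_size_um - 2 * margin)
          ok <- !occ$near(job$start, r_max)
          tries <- tries + 1L
        }
        if (!ok) next
        from <- add_node(job$start)
        excl <- integer()
      } else {
        from <- job$node
        excl <- which(edge_from == from | edge_to == from)
      }
      # the parent and sibling tubes are touchable only while the daughter
      # clears the junction ball (~45 um); afterwards they are obstacles
      # like any other vessel, so reflected sprouts cannot re-enter them
      collide_fn <- function(p, s)
        occ$near(p, r, exclude_ids = if (s <= 15L) excl else integer())
      w <- walk_segment(job$start, job$dir, L, spec$volume_size_um, margin,
                        collide = collide_fn)
      # a sprout boxed in early gets fresh directions before giving up, so
      # drawn lengths are realized rather than truncated
      tries <- 0L
      while (w$length < 0.9 * L && tries < 3L) {
        w2 <- walk_segment(job$start, random_unit_vector(), L,
                           spec$volume_size_um, margin, collide = collide_fn)
        if (w2$length > w$length) w <- w2
        tries <- tries + 1L
      }
      if (nrow(w$points) < 2L || w$length < 1) next  # stillborn sprout
      edge_ct <- edge_ct + 1L
      occ$add(w$points, r, edge_ct)
      to <- add_node(w$points[nrow(w$points), ])
      edges[[edge_ct]] <- c(edge_id = edge_ct, node_from = from, node_to = to,
                            radius_um = r, length_um = w$length)
      edge_from[edge_ct] <- from
      edge_to[edge_ct] <- to
      polylines[[edge_ct]] <- w$points
      radii[edge_ct] <- r
      if (job$gen < spec$max_generations && runif(1) < spec$branch_prob) {
        endp <- w$points[nrow(w$points), ]
        for (d in branch_directions(w$dir)) {
          pending[[length(pending) + 1L]] <-
            list(start = endp, dir = d, gen = job$gen + 1L, node = to)
        }
      }
    }
  }
  nodes <- if (node_ct) as.data.frame(do.call(rbind, nodes)) else NULL
  edges <- if (edge_ct) as.data.frame(do.call(rbind, edges)) else NULL
  spheres <- NULL
  if (spec$include_spheroid) {
    spheres <- matrix(c(spec$volume_size_um[1] / 2,
                        spec$volume_size_um[2] / 2, 0, 100), 1, 4)
  }
  absorber <- rasterize_phantom(polylines, radii, dims, spec$voxel_pitch_um,
                                extra_spheres = spheres)
  ph <- new_phantom(absorber, spec$voxel_pitch_um, spec = spec, nodes = nodes,
                    edges = edges, polylines = polylines)
  if (spec$condition != "control") {
    ctrl_spec <- spec
    ctrl_spec$condition <- "control"
    ph$spec <- ctrl_spec
    ph <- apply_drug_effect(ph, spec$condition)
  }
  ph
}

# per-condition, per-depth survival probabilities (qualitative calibration:
# combination therapy suppresses most, all drugs suppress most strongly in
# the shallow 0-200 um slab near the spheroid seeding surface)
drug_survival <- function(condition, depth_um) {
  base <- switch(condition,
                 control = 1.0, TMZ = 0.55, SU = 0.50, combo = 0.25,
                 stop("unknown condition: ", condition, call. = FALSE))
  ifelse(depth_um < 200, base * 0.8, base)
}

#' Apply a drug-treatment suppression to a control phantom
#'
#' Prunes vessel segments with a depth-dependent Bernoulli survival factor
#' (control 1.0; TMZ 0.55; SU 0.50; combination 0.25; each further x0.8 for
#' segments whose mean depth lies in the shallow 0-200 um slab), then
#' re-rasterizes the absorber from the surviving centerlines. Expected vessel
#' density therefore orders control > monotherapy > combination in every
#' depth bin. Uses a seed derived from the phantom's `rng_seed` so the result
#' is reproducible.
#'
#' @param phantom A control `vascular_phantom`.
#' @param condition `"control"` (identity), `"TMZ"`, `"SU"` or `"combo"`.
#' @return The pruned `vascular_phantom`; `spec$condition` records the
#'   treatment.
#' @export
apply_drug_effect <- function(phantom, condition) {
  stopifnot(inherits(phantom, "vascular_phantom"))
  stop_if(!condition %in% c("control", "TMZ", "SU", "combo"),
          "unknown condition label: ", condition)
  stop_if(!is.null(phantom$spec) && phantom$spec$condition != "control",
          "apply_drug_effect expects a control-grown phantom")
  if (condition == "control") return(phantom)
  set.seed(phantom$spec$rng_seed + 7919L)
  if (!nrow(phantom$edges)) {
    phantom$spec$condition <- condition
    return(phantom)
  }
  mean_depth <- vapply(phantom$polylines, function(p) mean(p[, 3]), numeric(1))
  surv <- drug_survival(condition, mean_depth)
  keep <- runif(length(surv)) < surv
  phantom$edges <- phantom$edges[keep, , drop = FALSE]
  phantom$polylines <- phantom$polylines[keep]
  kept_nodes <- unique(c(phantom$edges$node_from, phantom$edges$node_to))
  phantom$nodes <- phantom$nodes[phantom$nodes$id %in% kept_nodes, , drop = FALSE]
  dims <- dim(phantom$absorber)
  spheres <- NULL
  if (isTRUE(phantom$spec$include_spheroid)) {
    spheres <- matrix(c(phantom$spec$volume_size_um[1] / 2,
                        phantom$spec$volume_size_um[2] / 2, 0, 100), 1, 4)
  }
  phantom$absorber <- rasterize_phantom(phantom$polylines,
                                        phantom$edges$radius_um, dims,
                                        phantom$voxel_pitch_um,
                                        extra_spheres = spheres)
  phantom$spec$condition <- condition
  phantom
}

#' Instrument calibration targets
#'
#' Builds the standard bench targets as absorber phantoms: a razor edge
#' (half-space absorber, for lateral-resolution ESF/LSF analysis), a carbon
#' fiber (single horizontal cylinder, for axial-resolution envelope fitting),
#' or a dispersed cell field (Poisson-placed spheres, for penetration-depth
#' measurement).
#'
#' @param kind `"edge"`, `"fiber"` or `"cell_field"`.
#' @param volume_size_um Target extent (x, y, z) um; defaults per kind.
#' @param voxel_pitch_um Grid pitch um; the edge target defaults to a fine
#'   0.2 um lateral pitch so the ESF is well sampled.
#' @param edge_x_um Edge position: absorber occupies `x < edge_x_um`.
#' @param fiber_diameter_um Fiber diameter (default 6; the nominal bench
#'   fiber is quoted as 6-10 um depending on source).
#' @param fiber_depth_um Fiber axis depth (default 300).
#' @param cell_density_mm3 Cell number density (default 2000, i.e. the
#'   2e6 cells/mL loading of the penetration-depth specimens).
#' @param cell_radius_um Cell radius (default 6).
#' @param rng_seed Seed for the Poisson cell placement.
#' @return A `vascular_phantom` (graph empty except for the fiber, whose
#'   centerline is recorded).
#' @export
make_calibration_target <- function(kind = c("edge", "fiber", "cell_field"),
                                    volume_size_um = NULL,
                                    voxel_pitch_um = NULL,
                                    edge_x_um = NULL,
                                    fiber_diameter_um = 6,
                                    fiber_depth_um = 300,
                                    cell_density_mm3 = 2000,
                                    cell_radius_um = 6,
                                    rng_seed = 1L) {
  kind <- match.arg(kind)
  if (kind == "edge") {
    if (is.null(volume_size_um)) volume_size_um <- c(60, 20, 30)
    if (is.null(voxel_pitch_um)) voxel_pitch_um <- c(0.2, 2, 3)
    stop_if(any(volume_size_um <= 0) || any(voxel_pitch_um <= 0),
            "dimensions must be positive")
    if (is.null(edge_x_um)) edge_x_um <- volume_size_um[1] / 2
    dims <- phantom_grid_dim(volume_size_um, voxel_pitch_um)
    x <- (seq_len(dims[1]) - 1L) * voxel_pitch_um[1]
    absorber <- array(0, dims)
    absorber[x < edge_x_um, , ] <- 1
    ph <- new_phantom(absorber, voxel_pitch_um, kind = "edge")
    ph$edge_x_um <- edge_x_um
    return(ph)
  }
  if (kind == "fiber") {
    stop_if(fiber_diameter_um <= 0, "fiber diameter must be positive")
    if (is.null(volume_size_um)) volume_size_um <- c(100, 60, 600)
    if (is.null(voxel_pitch_um)) voxel_pitch_um <- c(2, 2, 3)
    stop_if(any(volume_size_um <= 0) || any(voxel_pitch_um <= 0),
            "dimensions must be positive")
    dims <- phantom_grid_dim(volume_size_um, voxel_pitch_um)
    y0 <- volume_size_um[2] / 2
    poly <- rbind(c(0, y0, fiber_depth_um),
                  c(volume_size_um[1], y0, fiber_depth_um))
    absorber <- rasterize_phantom(list(poly), fiber_diameter_um / 2, dims,
                                  voxel_pitch_um)
    nodes <- data.frame(id = 1:2, x = poly[, 1], y = poly[, 2], z = poly[, 3])
    edges <- data.frame(edge_id = 1L, node_from = 1L, node_to = 2L,
                        radius_um = fiber_diameter_um / 2,
                        length_um = polyline_length(poly))
    ph <- new_phantom(absorber, voxel_pitch_um, nodes = nodes, edges = edges,
                      polylines = list(poly), kind = "fiber")
    ph$fiber_depth_um <- fiber_depth_um
    return(ph)
  }
  # cell field
  stop_if(cell_density_mm3 <= 0 || cell_radius_um <= 0,
          "cell density and radius must be positive")
  if (is.null(volume_size_um)) volume_size_um <- c(300, 300, 500)
  if (is.null(voxel_pitch_um)) voxel_pitch_um <- c(2, 2, 3)
  stop_if(any(volume_size_um <= 0) || any(voxel_pitch_um <= 0),
          "dimensions must be positive")
  dims <- phantom_grid_dim(volume_size_um, voxel_pitch_um)
  set.seed(rng_seed)
  vol_mm3 <- prod(volume_size_um) * 1e-9
  n <- stats::rpois(1, cell_density_mm3 * vol_mm3)
  if (n > 0) {
    centers <- cbind(runif(n, 0, volume_size_um[1]),
                     runif(n, 0, volume_size_um[2]),
                     runif(n, 0, volume_size_um[3]),
                     cell_radius_um)
    vox <- cpp_rasterize_spheres(as.integer(dims), as.numeric(voxel_pitch_um),
                                 centers)
    absorber <- array(as.numeric(vox), dims)
  } else {
    centers <- matrix(numeric(), 0, 4)
    absorber <- array(0, dims)
  }
  ph <- new_phantom(absorber, voxel_pitch_um, kind = "cell_field")
  ph$cells <- centers
  ph
}
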