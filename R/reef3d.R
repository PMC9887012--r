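# Coral-populated reef cross-sections and the rumple structural-complexity
# index. Colonies are placed at random positions and rotations on a
# substrate strip, resized from survey size distributions, until each
# taxon's summed planar area first reaches its target cover; the composite
# surface is a rasterized height field (max of substrate and colony
# surfaces per cell) whose rumple index is the ratio of triangulated 3D
# surface area to planar area.

#' Substrate strip from a bathymetry section
#'
#' Extracts the fore-reef stretch (by default) of a bathymetry profile as
#' the substrate strip on which colonies are placed; the strip follows the
#' bed elevation along-shore and is flat across its width.
#'
#' @param bathymetry A [generate_bathymetry()] profile.
#' @param section Section label to extract.
#' @param width Strip width (m).
#' @param relief_amp Amplitude (m) of the bare-substrate microtopography
#'   (carbonate framework and rubble retain decimetre-scale relief even
#'   when living cover is lost, which is why a fully disturbed reef keeps
#'   a structural complexity well above 1).
#' @param relief_scale Horizontal wavelength (m) of the microtopography.
#' @param relief_seed Seed of the deterministic relief field.
#' @return Object of class `reef_substrate`: list with `x` (local, from 0),
#'   `z` (bed elevation), `length`, `width`, relief parameters.
#' @export
substrate_from_bathymetry <- function(bathymetry, section = "fore_reef",
                                      width = 1, relief_amp = 0.055,
                                      relief_scale = 0.5, relief_seed = 1) {
  sel <- bathymetry$section == section
  if (!any(sel)) stop(sprintf("no '%s' section in bathymetry", section))
  x <- bathymetry$x[sel]
  z <- bathymetry$z[sel]
  structure(list(x = x - x[1], z = z, length = x[length(x)] - x[1],
                 width = width, relief_amp = relief_amp,
                 relief_scale = relief_scale, relief_seed = relief_seed),
            class = "reef_substrate")
}

#' Flat substrate strip
#'
#' Planar horizontal substrate, mainly for controlled tests (its own
#' rumple is exactly 1).
#'
#' @param length,width Strip dimensions (m).
#' @param z Bed elevation (m).
#' @return A `reef_substrate`.
#' @export
flat_substrate <- function(length = 160, width = 1, z = 0) {
  structure(list(x = c(0, length), z = c(z, z), length = length,
                 width = width),
            class = "reef_substrate")
}

#' Populate a substrate strip with coral colonies
#'
#' Colonies are added one at a time (random mesh from the bank, size
#' resampled from the survey size distribution, uniform-random position,
#' uniform rotation in `[-pi/2, pi/2]`) until each taxon's planar-area
#' fraction first reaches its target cover. Planar cover is counted by
#' summed footprint area by default (`cover_mode = "union"` counts the
#' union of footprints instead, preventing cover > 100% artefacts when
#' overlap is heavy).
#'
#' @param substrate A `reef_substrate`.
#' @param covers Named cover targets per taxon (fractions), or one row of a
#'   [generate_survey_table()] (all rows of one year).
#' @param size_samples Named list of `n x 3` size matrices per taxon (not
#'   needed when `covers` is a survey subset carrying its own samples).
#' @param shape_bank A `shape_bank`.
#' @param seed Integer seed.
#' @param cell Raster cell size (m) of the composite height field.
#' @param cover_mode `"sum"` or `"union"` footprint accounting.
#' @param max_colonies Safety bound on total placements.
#' @return Object of class `reef_cross_section`: `substrate`, `colonies`
#'   (data frame), `raster` (height-field matrix at grid nodes), `cell`,
#'   `cover_achieved`.
#' @export
populate_cross_section <- function(substrate, covers, size_samples = NULL,
                                   shape_bank, seed = 1, cell = 0.02,
                                   cover_mode = c("sum", "union"),
                                   max_colonies = 50000) {
  cover_mode <- match.arg(cover_mode)
  if (inherits(covers, "survey_table") || is.data.frame(covers)) {
    size_samples <- setNames(lapply(covers$size_samples, identity),
                             covers$taxon)
    covers <- setNames(covers$cover, covers$taxon)
  }
  if (any(covers < 0)) stop("cover targets must be in [0, 1]")
  if (sum(covers) > 1 + 1e-9) {
    stop("unreachable cover target: combined cover exceeds 1")
  }
  L <- substrate$length
  W <- substrate$width
  strip_area <- L * W
  nx <- max(2, round(L / cell))
  ny <- max(2, round(W / cell))
  # height field at grid nodes
  xg <- seq(0, L, length.out = nx + 1)
  zsub <- approx(substrate$x, substrate$z, xg, rule = 2)$y
  raster <- matrix(zsub, nx + 1, ny + 1)
  amp <- substrate$relief_amp %||% 0
  if (amp > 0) {
    lam <- substrate$relief_scale %||% 0.5
    set.seed(substrate$relief_seed %||% 1)
    yg <- seq(0, W, length.out = ny + 1)
    rel <- matrix(0, nx + 1, ny + 1)
    for (s in c(1, 0.43, 0.19)) { # three octaves of skeletal relief
      kx <- 2 * pi / (lam * s)
      a_s <- amp * s
      rel <- rel + a_s *
        outer(cos(kx * xg + runif(1, 0, 2 * pi)),
              cos(kx * yg + runif(1, 0, 2 * pi))) +
        a_s * outer(cos(kx * 0.77 * xg + runif(1, 0, 2 * pi)),
                    sin(kx * 1.13 * yg + runif(1, 0, 2 * pi)))
    }
    raster <- raster + rel
  }

  set.seed(seed)
  taxa <- names(covers)[covers > 0]
  for (tx in taxa) {
    ids <- shape_bank$manifest$id[shape_bank$manifest$taxon == tx]
    if (length(ids) == 0) {
      stop(sprintf("empty shape bank: no mesh for taxon '%s'", tx))
    }
    sz <- size_samples[[tx]]
    if (is.null(sz) || nrow(sz) == 0) {
      stop(sprintf("no size samples for taxon '%s'", tx))
    }
  }

  cols <- list()
  ncol_placed <- 0
  achieved <- setNames(numeric(base::length(covers)), names(covers))
  union_mask <- if (cover_mode == "union") {
    setNames(lapply(names(covers), function(t) {
      matrix(FALSE, nx, ny)
    }), names(covers))
  } else {
    NULL
  }

  for (tx in taxa) {
    target <- covers[[tx]] * strip_area
    ids <- shape_bank$manifest$id[shape_bank$manifest$taxon == tx]
    sz <- size_samples[[tx]]
    area_tx <- 0
    while (area_tx < target && ncol_placed < max_colonies) {
      id <- ids[sample.int(base::length(ids), 1)]
      srow <- sz[sample.int(nrow(sz), 1), ]
      w <- min(srow[1], L)
      l <- min(srow[2], W)
      h <- srow[3]
      rot <- runif(1, -pi / 2, pi / 2)
      rx <- w / 2
      ry <- l / 2
      # footprint must stay inside the strip
      ex <- abs(rx * cos(rot)) + abs(ry * sin(rot))
      ey <- abs(rx * sin(rot)) + abs(ry * cos(rot))
      px <- runif(1, min(ex, L / 2), max(L - ex, L / 2))
      py <- runif(1, min(ey, W / 2), max(W - ey, W / 2))
      if (cover_mode == "sum") {
        inc <- pi * rx * ry
      } else {
        msk <- ellipse_mask(nx, ny, cell, px, py, rx, ry, rot)
        new <- msk & !union_mask[[tx]]
        union_mask[[tx]][new] <- TRUE
        inc <- sum(new) * cell^2
      }
      area_tx <- area_tx + inc
      ncol_placed <- ncol_placed + 1
      cols[[ncol_placed]] <- data.frame(
        taxon = tx, x = px, y = py, width = w, length = l, height = h,
        rotation = rot, mesh_id = id, footprint = pi * rx * ry
      )
    }
    achieved[tx] <- area_tx / strip_area
  }

  colonies <- if (ncol_placed > 0) {
    do.call(rbind, cols)
  } else {
    data.frame(taxon = character(0), x = numeric(0), y = numeric(0),
               width = numeric(0), length = numeric(0), height = numeric(0),
               rotation = numeric(0), mesh_id = character(0),
               footprint = numeric(0))
  }

  # rasterize colonies (max of substrate and colony surfaces per node)
  for (i in seq_len(nrow(colonies))) {
    cc <- colonies[i, ]
    mesh <- shape_bank$meshes[[cc$mesh_id]]
    # colony base sits on the local substrate surface including relief
    ix0 <- pmin(pmax(round(cc$x / cell) + 1, 1), nx + 1)
    iy0 <- pmin(pmax(round(cc$y / cell) + 1, 1), ny + 1)
    z0 <- raster[ix0, iy0]
    m <- transform_mesh(mesh, cc$width, cc$length, cc$height, cc$rotation,
                        cc$x, cc$y, z0)
    pts <- mesh_points(m, spacing = cell * 0.8)
    ix <- round(pts[, 1] / cell) + 1
    iy <- round(pts[, 2] / cell) + 1
    ok <- ix >= 1 & ix <= nx + 1 & iy >= 1 & iy <= ny + 1
    if (!any(ok)) next
    idx <- ix[ok] + (iy[ok] - 1) * (nx + 1)
    zm <- bin_max_cpp(idx, pts[ok, 3], (nx + 1) * (ny + 1))
    upd <- zm > -Inf & zm > as.vector(raster)
    raster[upd] <- zm[upd]
  }

  structure(list(substrate = substrate, colonies = colonies,
                 raster = raster, cell = cell, cover_targets = covers,
                 cover_achieved = achieved, seed = seed),
            class = "reef_cross_section")
}

# boolean mask of an (rotated) ellipse footprint on the cell grid
ellipse_mask <- function(nx, ny, cell, px, py, rx, ry, rot) {
  xc <- (seq_len(nx) - 0.5) * cell - px
  yc <- (seq_len(ny) - 0.5) * cell - py
  X <- matrix(xc, nx, ny)
  Y <- matrix(yc, nx, ny, byrow = TRUE)
  cr <- cos(-rot)
  sr <- sin(-rot)
  U <- cr * X - sr * Y
  V <- sr * X + cr * Y
  (U / rx)^2 + (V / ry)^2 <= 1
}

#' @export
print.reef_cross_section <- function(x, ...) {
  cat(sprintf("reef_cross_section: %.0f x %.1f m strip, %d colonies\n",
              x$substrate$length, x$substrate$width, nrow(x$colonies)))
  cat("  cover achieved:",
      paste(sprintf("%s %.3f", names(x$cover_achieved), x$cover_achieved),
            collapse = ", "), "\n")
  invisible(x)
}

#' Rumple index (structural complexity)
#'
#' Ratio of true 3D surface area to planar projected area. For rasterized
#' height fields every cell is split into two triangles spanned by its
#' corner nodes; for triangulated meshes facet areas are summed and divided
#' by the summed projected facet areas. Always at least 1; exactly 1 for a
#' bare planar horizontal surface.
#'
#' @param surface A `reef_cross_section`, a `coral_mesh`, or a numeric
#'   matrix of surface heights at grid nodes.
#' @param cell Node spacing (m) when `surface` is a matrix.
#' @return Structural complexity (dimensionless, >= 1 for height fields).
#' @export
rumple_index <- function(surface, cell = NULL) {
  UseMethod("rumple_index")
}

#' @export
rumple_index.reef_cross_section <- function(surface, cell = NULL) {
  rumple_index(surface$raster, surface$cell)
}

#' @export
rumple_index.coral_mesh <- function(surface, cell = NULL) {
  ap <- mesh_planar_area(surface)
  if (ap <= 0) stop("degenerate footprint: zero projected area")
  mesh_surface_area(surface) / ap
}

#' @export
rumple_index.matrix <- function(surface, cell = NULL) {
  if (is.null(cell)) stop("`cell` is required for raster surfaces")
  a <- raster_area_cpp(surface, cell)
  if (a[2] <= 0) stop("degenerate footprint: zero planar area")
  a[1] / a[2]
}

#' Structural-complexity ensemble over survey years
#'
#' Builds `n_replicates` random reef cross-sections per survey year and
#' returns the rumple-index structural complexity of each replicate (the
#' per-year median and 5th-95th percentile "very likely range" are
#' available via [sc_summary()]).
#'
#' @param survey_table A [generate_survey_table()].
#' @param substrate A `reef_substrate`.
#' @param shape_bank A `shape_bank`.
#' @param n_replicates Replicates per year (100 at study scale).
#' @param seed Integer seed.
#' @param cell Raster cell size (m).
#' @param cover_mode Footprint accounting (see [populate_cross_section()]).
#' @return Data frame of class `sc_ensemble` with `year`, `replicate`, `sc`.
#' @export
complexity_ensemble <- function(survey_table, substrate, shape_bank,
                                n_replicates = 100, seed = 1, cell = 0.02,
                                cover_mode = "sum") {
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  years <- unique(survey_table$year)
  out <- vector("list", base::length(years) * n_replicates)
  k <- 0
  for (iy in seq_along(years)) {
    rows <- survey_table[survey_table$year == years[iy], ]
    for (r in seq_len(n_replicates)) {
      k <- k + 1
      s <- fan_seed(seed, (iy - 1) * n_replicates + r)
      cs <- populate_cross_section(substrate, rows, shape_bank = shape_bank,
                                   seed = s, cell = cell,
                                   cover_mode = cover_mode)
      out[[k]] <- data.frame(year = years[iy], replicate = r,
                             sc = rumple_index(cs))
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("sc_ensemble", "data.frame")
  res
}

#' Per-year structural complexity summary
#'
#' Median and 5th-95th percentile range of replicate structural
#' complexity.
#'
#' @param ensemble An `sc_ensemble`.
#' @return Data frame with `year`, `median`, `q05`, `q95`, `n`.
#' @export
sc_summary <- function(ensemble) {
  years <- sort(unique(ensemble$year))
  do.call(rbind, lapply(years, function(y) {
    s <- ensemble$sc[ensemble$year == y]
    data.frame(year = y, median = median(s),
               q05 = unname(quantile(s, 0.05, type = 7)),
               q95 = unname(quantile(s, 0.95, type = 7)), n = base::length(s))
  }))
}
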