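# Synthetic samples: 2D foil phantoms (per-pixel thickness maps) and 3D
# foam-with-insert phantoms (per-voxel occupancy fractions).

#' Construct a 2D phantom
#'
#' @param shape `c(rows, cols)` image shape.
#' @param pixel_um Pixel size in micrometres.
#' @param thickness Named list of element -> thickness map (um per pixel,
#'   matrices of dimension `shape`, all >= 0).
#' @return An object of class `phantom2d`.
#' @export
phantom2d <- function(shape, pixel_um, thickness = list()) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 2, all(shape > 0), pixel_um > 0)
  for (el in names(thickness)) {
    element_info(el)
    m <- thickness[[el]]
    if (!is.matrix(m) || !all(dim(m) == shape)) {
      stop(sprintf("thickness map for '%s' has wrong shape", el), call. = FALSE)
    }
    if (any(m < 0)) stop("thickness maps must be non-negative", call. = FALSE)
  }
  structure(list(shape = shape, pixel_um = pixel_um, thickness = thickness),
            class = "phantom2d")
}

#' @export
print.phantom2d <- function(x, ...) {
  cat(sprintf("<phantom2d> %d x %d pixels of %.3g um; elements: %s\n",
              x$shape[1], x$shape[2], x$pixel_um,
              if (length(x$thickness)) paste(names(x$thickness), collapse = ", ")
              else "(none)"))
  invisible(x)
}

#' Build a foil phantom from rectangular regions
#'
#' Each foil is a rectangle of constant thickness; overlapping regions
#' accumulate every element's thickness independently, and two regions of
#' the same element add.
#'
#' @param shape `c(rows, cols)`.
#' @param pixel_um Pixel size, micrometres.
#' @param foils List of `list(element =, thickness_um =, region = c(r0, r1,
#'   c0, c1))` entries (1-based inclusive row/col bounds).
#' @return A [phantom2d()].
#' @export
make_foil_phantom <- function(shape = c(512, 512), pixel_um = 11,
                              foils = list()) {
  maps <- list()
  for (f in foils) {
    r <- as.integer(f$region)
    if (length(r) != 4 || r[1] < 1 || r[3] < 1 || r[2] > shape[1] ||
        r[4] > shape[2] || r[1] > r[2] || r[3] > r[4]) {
      stop(sprintf("foil region [%s] outside the %d x %d image",
                   paste(f$region, collapse = ", "), shape[1], shape[2]),
           call. = FALSE)
    }
    if (is.null(maps[[f$element]])) {
      maps[[f$element]] <- matrix(0, shape[1], shape[2])
    }
    maps[[f$element]][r[1]:r[2], r[3]:r[4]] <-
      maps[[f$element]][r[1]:r[2], r[3]:r[4]] + f$thickness_um
  }
  phantom2d(shape, pixel_um, maps)
}

#' Rectangular region of interest
#'
#' @param r0,r1,c0,c1 Inclusive 1-based row and column bounds.
#' @return An integer vector of class `roi_rect`.
#' @export
roi_rect <- function(r0, r1, c0, c1) {
  stopifnot(r0 >= 1, c0 >= 1, r1 >= r0, c1 >= c0)
  structure(as.integer(c(r0, r1, c0, c1)), class = "roi_rect")
}

#' The two-foil test sample
#'
#' A 512 x 512, 11 um/pixel phantom with a 12 um rhodium foil and an 18 um
#' nickel foil sharing an overlap strip, together with the rectangular
#' regions of interest used by the quality metrics: `rh` (Rh only),
#' `residue` (Ni only), `overlap` (Rh + Ni) and `background` (no sample).
#'
#' @param shape `c(rows, cols)`; regions scale with the shape.
#' @param pixel_um Pixel size, micrometres.
#' @param rh_um,ni_um Foil thicknesses, micrometres.
#' @param overlap_element Element of the second foil (default `"Ni"`).
#' @return List with `phantom` and `rois`.
#' @export
foil_fixture <- function(shape = c(512, 512), pixel_um = 11, rh_um = 12,
                         ni_um = 18, overlap_element = "Ni") {
  sc <- function(f, n) pmax(1L, pmin(n, as.integer(round(f * n))))
  nr <- shape[1]; nc <- shape[2]
  rh_region <- c(sc(0.27, nr), sc(0.73, nr), sc(0.18, nc), sc(0.57, nc))
  ni_region <- c(sc(0.27, nr), sc(0.73, nr), sc(0.45, nc), sc(0.84, nc))
  phantom <- make_foil_phantom(shape, pixel_um, list(
    list(element = "Rh", thickness_um = rh_um, region = rh_region),
    list(element = overlap_element, thickness_um = ni_um, region = ni_region)))
  rois <- list(
    rh = roi_rect(sc(0.35, nr), sc(0.65, nr), sc(0.22, nc), sc(0.41, nc)),
    residue = roi_rect(sc(0.35, nr), sc(0.65, nr), sc(0.61, nc), sc(0.80, nc)),
    overlap = roi_rect(sc(0.35, nr), sc(0.65, nr), sc(0.47, nc), sc(0.55, nc)),
    background = roi_rect(sc(0.04, nr), sc(0.22, nr), sc(0.04, nc), sc(0.22, nc)))
  list(phantom = phantom, rois = rois)
}

#' Construct a 3D phantom
#'
#' @param shape `c(nz, ny, nx)` voxel grid.
#' @param voxel_um Voxel edge length, micrometres.
#' @param occupancy Named list of element -> occupancy array in `[0, 1]`,
#'   dimensions `shape`; per-voxel occupancies must sum to <= 1.
#' @return An object of class `phantom3d`.
#' @export
phantom3d <- function(shape, voxel_um, occupancy = list()) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3, all(shape > 0), voxel_um > 0)
  total <- 0
  for (el in names(occupancy)) {
    element_info(el)
    a <- occupancy[[el]]
    if (!is.array(a) || !all(dim(a) == shape)) {
      stop(sprintf("occupancy for '%s' has wrong shape", el), call. = FALSE)
    }
    if (any(a < 0) || any(a > 1)) {
      stop("occupancy fractions must lie in [0, 1]", call. = FALSE)
    }
    total <- total + a
  }
  if (length(occupancy) && any(total > 1 + 1e-9)) {
    stop("per-voxel occupancy fractions must sum to <= 1", call. = FALSE)
  }
  structure(list(shape = shape, voxel_um = voxel_um, occupancy = occupancy),
            class = "phantom3d")
}

#' @export
print.phantom3d <- function(x, ...) {
  cat(sprintf("<phantom3d> %d x %d x %d voxels of %.3g um; elements: %s\n",
              x$shape[1], x$shape[2], x$shape[3], x$voxel_um,
              if (length(x$occupancy)) paste(names(x$occupancy), collapse = ", ")
              else "(none)"))
  invisible(x)
}

#' Aluminium foam cube with an insert
#'
#' An aluminium cube, centred in the voxel grid and sized to stay inside
#' the reconstruction circle, with spherical voids carved by a seeded
#' pseudo-random process until the target void fraction is reached (within
#' 1%), and an optional rectangular rod insert (default rhodium, about a
#' quarter of the cube width) that replaces aluminium.
#'
#' @param shape `c(nz, ny, nx)` voxel grid (default 128^3).
#' @param voxel_um Voxel size, micrometres.
#' @param porosity Target void fraction of the cube, in `[0, 1)`.
#' @param cube_frac Cube edge as a fraction of the grid edge; the default
#'   0.68 keeps the rotated cube inside the field of view.
#' @param radius_range Void sphere radii, voxels, drawn uniformly.
#' @param insert `NULL`, or `list(element =, region = c(z0, z1, y0, y1, x0,
#'   x1))`; missing region places a central rod spanning ~1/4 of the cube
#'   width.
#' @param seed Integer seed for the carving process.
#' @return A [phantom3d()] with attributes `cube_mask` and
#'   `achieved_porosity`.
#' @export
make_foam_phantom <- function(shape = c(128, 128, 128), voxel_um = 11,
                              porosity = 0.4, cube_frac = 0.68,
                              radius_range = c(3, 8),
                              insert = list(element = "Rh"), seed = 1) {
  shape <- as.integer(shape)
  stopifnot(porosity >= 0, porosity < 1)
  nz <- shape[1]; ny <- shape[2]; nx <- shape[3]
  side <- round(cube_frac * min(ny, nx))
  cz <- (nz + 1) / 2; cy <- (ny + 1) / 2; cx <- (nx + 1) / 2
  zr <- round(cz + c(-1, 1) * min(nz, side) / 2 + c(1, 0))
  yr <- round(cy + c(-1, 1) * side / 2 + c(1, 0))
  xr <- round(cx + c(-1, 1) * side / 2 + c(1, 0))
  al <- array(0, shape)
  al[zr[1]:zr[2], yr[1]:yr[2], xr[1]:xr[2]] <- 1
  cube_mask <- al > 0
  cube_vox <- sum(cube_mask)

  if (porosity > 0) {
    set.seed(as.integer(seed))
    void <- 0
    tol <- 0.009
    max_spheres <- 100000L
    for (i in seq_len(max_spheres)) {
      if (void / cube_vox >= porosity - tol / 2) break
      r <- stats::runif(1, radius_range[1], radius_range[2])
      # shrink spheres as the target approaches so the last one cannot
      # overshoot the +/-1% tolerance
      r_cap <- (3 * (porosity + tol / 2 - void / cube_vox) * cube_vox /
                  (4 * pi))^(1 / 3)
      r <- max(1, min(r, r_cap))
      c0 <- c(stats::runif(1, zr[1], zr[2]), stats::runif(1, yr[1], yr[2]),
              stats::runif(1, xr[1], xr[2]))
      zi <- max(zr[1], floor(c0[1] - r)):min(zr[2], ceiling(c0[1] + r))
      yi <- max(yr[1], floor(c0[2] - r)):min(yr[2], ceiling(c0[2] + r))
      xi <- max(xr[1], floor(c0[3] - r)):min(xr[2], ceiling(c0[3] + r))
      d2 <- outer(outer((zi - c0[1])^2, (yi - c0[2])^2, "+"), (xi - c0[3])^2, "+")
      sub <- al[zi, yi, xi]
      newly <- sum(sub[d2 <= r^2])
      sub[d2 <= r^2] <- 0
      al[zi, yi, xi] <- sub
      void <- void + newly
    }
  }
  achieved <- if (porosity > 0) 1 - sum(cube_mask & (al > 0)) / cube_vox else 0
  occupancy <- list(Al = al)
  if (!is.null(insert)) {
    reg <- insert$region
    if (is.null(reg)) {
      w <- round(side / 8)  # half-width: rod spans ~1/4 of the cube width
      reg <- c(max(zr[1], round(cz - 0.3 * side)),
               min(zr[2], round(cz + 0.3 * side)),
               round(cy - w), round(cy + w), round(cx - w), round(cx + w))
    }
    reg <- as.integer(reg)
    if (any(reg[c(1, 3, 5)] < 1) || reg[2] > nz || reg[4] > ny || reg[6] > nx) {
      stop("insert region outside the voxel grid", call. = FALSE)
    }
    ins <- array(0, shape)
    ins[reg[1]:reg[2], reg[3]:reg[4], reg[5]:reg[6]] <- 1
    al[ins > 0] <- 0
    occupancy$Al <- al
    occupancy[[insert$element]] <- ins
  }
  p <- phantom3d(shape, voxel_um, occupancy)
  attr(p, "cube_mask") <- cube_mask
  attr(p, "achieved_porosity") <- achieved
  p
}

#' Projected areal thickness of a 3D phantom
#'
#' Sums occupancy along one axis and multiplies by the voxel size: the
#' areal thickness (um) each element presents to an axis-aligned beam.
#'
#' @param phantom A [phantom3d()].
#' @param axis Axis index to integrate over: 1 = z, 2 = y, 3 = x.
#' @return Named list of matrices (um).
#' @export
project_thickness <- function(phantom, axis = 2) {
  stopifnot(inherits(phantom, "phantom3d"), axis %in% 1:3)
  lapply(phantom$occupancy, function(a) {
    apply(a, setdiff(1:3, axis), sum) * phantom$voxel_um
  })
}

#' Extract one z-slice of a 3D phantom as a 2D phantom
#'
#' @param phantom A [phantom3d()].
#' @param z Slice index.
#' @return A [phantom2d()] whose thickness maps are occupancy * voxel size.
#' @export
phantom_slice <- function(phantom, z) {
  stopifnot(inherits(phantom, "phantom3d"), z >= 1, z <= phantom$shape[1])
  maps <- lapply(phantom$occupancy, function(a) {
    a[z, , ] * phantom$voxel_um
  })
  phantom2d(phantom$shape[2:3], phantom$voxel_um, maps)
}

#' Serialise a phantom to TIFF stacks plus a JSON sidecar
#'
#' @param phantom A [phantom2d()] or [phantom3d()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  is3d <- inherits(phantom, "phantom3d")
  maps <- if (is3d) phantom$occupancy else phantom$thickness
  for (el in names(maps)) {
    a <- maps[[el]]
    imgs <- if (is3d) lapply(seq_len(dim(a)[1]), function(z) a[z, , ]) else list(a)
    .write_scaled_tiff(imgs, file.path(dir, paste0(el, ".tif")))
  }
  meta <- list(kind = if (is3d) "phantom3d" else "phantom2d",
               shape = phantom$shape,
               voxel_um = if (is3d) phantom$voxel_um else phantom$pixel_um,
               elements = names(maps))
  jsonlite::write_json(meta, file.path(dir, "phantom.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read a phantom written by [write_phantom()]
#'
#' @param dir Directory containing the TIFF stacks and `phantom.json`.
#' @return A [phantom2d()] or [phantom3d()].
#' @export
read_phantom <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "phantom.json"),
                              simplifyVector = TRUE)
  maps <- lapply(meta$elements, function(el) {
    imgs <- .read_scaled_tiff(file.path(dir, paste0(el, ".tif")))
    if (meta$kind == "phantom2d") return(imgs[[1]])
    a <- array(0, meta$shape)
    for (z in seq_along(imgs)) a[z, , ] <- imgs[[z]]
    a
  })
  names(maps) <- meta$elements
  if (meta$kind == "phantom2d") {
    phantom2d(meta$shape, meta$voxel_um, maps)
  } else {
    phantom3d(meta$shape, meta$voxel_um, maps)
  }
}
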