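#' Phantom specification for synthetic cord/lesion masks
#'
#' Describes a 3-D voxel grid holding an elliptical spinal cord extruded along
#' the superior-inferior axis, plus a list of lesion primitives with exactly
#' known projected footprints. Primitives are axis-aligned boxes or per-slice
#' ellipses so that the ground-truth spared fractions can be enumerated
#' directly from the geometry, independently of the mask pipeline.
#'
#' @param grid_shape integer(3), voxel counts (nx, ny, nz); nz indexes the
#'   superior-inferior axis.
#' @param cord_radii numeric(2), cord ellipse semi-axes (rx, ry) in voxels.
#' @param lesion_shapes list of primitives. A box is
#'   `list(type = "box", x = c(x0, x1), y = c(y0, y1), z = c(z0, z1))`
#'   with 1-based inclusive index ranges; an ellipse is
#'   `list(type = "ellipse", center = c(cx, cy), radii = c(rx, ry), z = c(z0, z1))`.
#' @param voxel_size numeric(3), mm per axis (default 0.5 mm isotropic,
#'   matching the PAM50 template resolution).
#' @param seed optional integer recorded with the spec (used by
#'   [random_phantom_spec()]; the deterministic constructor itself draws
#'   nothing).
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(grid_shape = c(48L, 48L, 12L), cord_radii = c(14, 10),
                         lesion_shapes = list(), voxel_size = c(0.5, 0.5, 0.5),
                         seed = NULL) {
  assert_that(length(grid_shape) == 3 && all(grid_shape >= 1),
              "grid_shape must be three positive voxel counts")
  assert_that(length(cord_radii) == 2 && all(cord_radii > 0),
              "cord_radii must be positive")
  for (sh in lesion_shapes) validate_primitive(sh, grid_shape)
  structure(list(grid_shape = as.integer(grid_shape), cord_radii = cord_radii,
                 lesion_shapes = lesion_shapes, voxel_size = voxel_size,
                 seed = seed),
            class = "phantom_spec")
}

validate_primitive <- function(sh, grid_shape) {
  assert_that(is.list(sh) && !is.null(sh$type) &&
                sh$type %in% c("box", "ellipse"),
              "lesion primitive must be a box or ellipse")
  assert_that(length(sh$z) == 2 && sh$z[1] >= 1 && sh$z[2] <= grid_shape[3] &&
                sh$z[1] <= sh$z[2],
              "lesion primitive z-range outside grid")
  if (sh$type == "box") {
    assert_that(sh$x[1] >= 1 && sh$x[2] <= grid_shape[1] &&
                  sh$y[1] >= 1 && sh$y[2] <= grid_shape[2] &&
                  sh$x[1] <= sh$x[2] && sh$y[1] <= sh$y[2],
                "lesion box outside grid")
  } else {
    assert_that(all(sh$radii > 0), "lesion ellipse radii must be positive")
  }
  invisible(TRUE)
}

# 2-D footprint (logical nx-by-ny) of one primitive, by direct pixel test.
primitive_footprint <- function(sh, nx, ny) {
  fp <- matrix(FALSE, nx, ny)
  if (sh$type == "box") {
    fp[sh$x[1]:sh$x[2], sh$y[1]:sh$y[2]] <- TRUE
  } else {
    dx <- matrix(rep(seq_len(nx) - sh$center[1], ny), nx, ny)
    dy <- matrix(rep(seq_len(ny) - sh$center[2], each = nx), nx, ny)
    fp[(dx / sh$radii[1])^2 + (dy / sh$radii[2])^2 <= 1] <- TRUE
  }
  fp
}

#' Ground-truth spared profile by direct pixel enumeration
#'
#' Computes the projected composite-lesion footprint straight from the lesion
#' primitives (union of their 2-D footprints over pixels) and tallies spared
#' weight per region. This is the independent oracle for the mask-based
#' quantification pipeline: it never touches 3-D mask arrays or
#' [project_lesion_axial()].
#'
#' @param lesion_shapes list of primitives as in [phantom_spec()].
#' @param atlas an [make_region_atlas()] object on the phantom's axial grid.
#' @return `spared_tissue_profile` named vector (percent): total, anterior,
#'   posterior, left, right.
#' @export
enumerate_spared_profile <- function(lesion_shapes, atlas) {
  nx <- atlas$grid_shape[1]; ny <- atlas$grid_shape[2]
  proj <- matrix(FALSE, nx, ny)
  for (sh in lesion_shapes) proj <- proj | primitive_footprint(sh, nx, ny)
  spared_pct <- function(w) 100 * sum(w[!proj]) / sum(w)
  cw <- matrix(0, nx, ny); cw[atlas$cord_mask] <- 1
  spared_tissue_profile(
    total = spared_pct(cw),
    anterior = spared_pct(atlas$region_weights$anterior),
    posterior = spared_pct(atlas$region_weights$posterior),
    left = spared_pct(atlas$region_weights$left_lateral),
    right = spared_pct(atlas$region_weights$right_lateral))
}

#' Spared-tissue profile container
#'
#' Five spared percentages: whole cord plus the four white-matter regions.
#' These are the five MRI outcome variables of the association analysis.
#'
#' @param total,anterior,posterior,left,right percent spared, each in [0, 100].
#' @return Named numeric vector of class `spared_tissue_profile`.
#' @export
spared_tissue_profile <- function(total, anterior, posterior, left, right) {
  v <- c(spared_total = total, spared_anterior = anterior,
         spared_posterior = posterior, spared_left = left,
         spared_right = right)
  assert_that(all(is.finite(v)) && all(v >= -1e-9) && all(v <= 100 + 1e-9),
              "spared percentages must lie in [0, 100]")
  structure(pmin(pmax(v, 0), 100), class = "spared_tissue_profile")
}

#' @export
print.spared_tissue_profile <- function(x, ...) {
  cat("<spared_tissue_profile> (% spared)\n")
  print(round(unclass(x), 2))
  invisible(x)
}

#' Generate a cord/lesion phantom with known ground truth
#'
#' Builds binary 3-D cord and lesion masks from a [phantom_spec()] (the cord
#' ellipse extruded along the superior-inferior axis; the lesion the union of
#' the spec's primitives, clipped to nothing -- primitives must lie within the
#' cord) together with the ground-truth spared-tissue profile computed by the
#' independent enumeration oracle.
#'
#' @param spec a [phantom_spec()].
#' @param atlas optional [make_region_atlas()] on the matching axial grid;
#'   defaults to a binary atlas with the spec's cord geometry.
#' @return list with `study` (a [lesion_study()]), `truth`
#'   (a `spared_tissue_profile` from [enumerate_spared_profile()]) and `atlas`.
#' @export
make_cord_phantom <- function(spec, atlas = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  nx <- spec$grid_shape[1]; ny <- spec$grid_shape[2]; nz <- spec$grid_shape[3]
  if (is.null(atlas)) {
    atlas <- make_region_atlas(c(nx, ny), spec$cord_radii)
  }
  assert_that(all(atlas$grid_shape == spec$grid_shape[1:2]),
              "atlas grid does not match phantom axial grid")

  cord2d <- atlas$cord_mask
  cord <- array(rep(cord2d, nz), dim = c(nx, ny, nz))
  lesion <- array(FALSE, dim = c(nx, ny, nz))
  for (sh in spec$lesion_shapes) {
    fp <- primitive_footprint(sh, nx, ny)
    if (any(fp & !cord2d)) {
      stop2(sprintf("lesion primitive (%s) extends outside the cord cross-section",
                    sh$type))
    }
    for (z in sh$z[1]:sh$z[2]) lesion[, , z] <- lesion[, , z] | fp
  }
  study <- lesion_study(cord, lesion, voxel_size = spec$voxel_size)
  list(study = study,
       truth = enumerate_spared_profile(spec$lesion_shapes, atlas),
       atlas = atlas)
}

#' Draw a random phantom specification
#'
#' Samples 1-4 lesion primitives (boxes and per-slice ellipses) wholly inside
#' the cord cross-section, giving phantoms with varied spared-tissue profiles
#' for property tests and synthetic cohorts.
#'
#' @param seed integer seed; generation is fully reproducible.
#' @inheritParams phantom_spec
#' @param max_shapes maximum number of primitives (default 4).
#' @return a [phantom_spec()].
#' @export
random_phantom_spec <- function(seed, grid_shape = c(48L, 48L, 12L),
                                cord_radii = c(14, 10), max_shapes = 4L) {
  set.seed(seed)
  cx <- (grid_shape[1] + 1) / 2; cy <- (grid_shape[2] + 1) / 2
  n_shapes <- sample.int(max_shapes, 1)
  shapes <- vector("list", n_shapes)
  for (i in seq_len(n_shapes)) {
    z0 <- sample.int(grid_shape[3], 1)
    z1 <- min(grid_shape[3], z0 + sample.int(4, 1) - 1)
    if (runif(1) < 0.5) {
      # box inside the inscribed axis-aligned rectangle of the ellipse
      hw <- cord_radii / sqrt(2) - 0.6
      x0 <- cx + runif(1, -hw[1], hw[1] * 0.2)
      x1 <- x0 + runif(1, 0.5, hw[1] * 0.8)
      y0 <- cy + runif(1, -hw[2], hw[2] * 0.2)
      y1 <- y0 + runif(1, 0.5, hw[2] * 0.8)
      xi <- c(ceiling(x0), floor(min(x1, cx + hw[1])))
      yi <- c(ceiling(y0), floor(min(y1, cy + hw[2])))
      xi[2] <- max(xi); yi[2] <- max(yi)
      shapes[[i]] <- list(type = "box", x = xi, y = yi, z = c(z0, z1))
    } else {
      r <- c(runif(1, 1.5, cord_radii[1] / 3), runif(1, 1.5, cord_radii[2] / 3))
      # keep the ellipse inside the cord: centre within shrunken cord ellipse
      ang <- runif(1, 0, 2 * pi)
      rad <- runif(1, 0, 0.55)
      ctr <- c(cx + cos(ang) * rad * (cord_radii[1] - r[1] - 1),
               cy + sin(ang) * rad * (cord_radii[2] - r[2] - 1))
      shapes[[i]] <- list(type = "ellipse", center = ctr, radii = r,
                          z = c(z0, z1))
    }
  }
  phantom_spec(grid_shape = grid_shape, cord_radii = cord_radii,
               lesion_shapes = shapes, seed = seed)
}
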