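#' Template-space cord and lesion masks
#'
#' Container for a subject's binary spinal-cord and lesion masks on a common
#' 3-D voxel grid. By convention (and as enforced for manual segmentations),
#' the cord mask includes the lesion: every lesioned voxel is a cord voxel.
#'
#' @param cord_mask,lesion_mask 3-D logical (or 0/1) arrays of equal shape.
#' @param voxel_size numeric(3), mm per axis.
#' @param axis index of the superior-inferior axis (default 3); the other two
#'   axes span the axial plane.
#' @return An object of class `lesion_study`.
#' @export
lesion_study <- function(cord_mask, lesion_mask,
                         voxel_size = c(0.5, 0.5, 0.5), axis = 3L) {
  cord_mask <- array(as.logical(cord_mask), dim = dim(cord_mask))
  lesion_mask <- array(as.logical(lesion_mask), dim = dim(lesion_mask))
  assert_that(length(dim(cord_mask)) == 3 &&
                identical(dim(cord_mask), dim(lesion_mask)),
              "cord and lesion masks must be 3-D arrays of identical shape")
  assert_that(axis %in% 1:3, "axis must identify one of the three array axes")
  assert_that(!any(lesion_mask & !cord_mask),
              "lesion mask must be contained in the cord mask")
  structure(list(cord_mask = cord_mask, lesion_mask = lesion_mask,
                 voxel_size = voxel_size, axis = as.integer(axis)),
            class = "lesion_study")
}

#' @export
print.lesion_study <- function(x, ...) {
  d <- dim(x$cord_mask)
  cat("<lesion_study> grid ", paste(d, collapse = "x"),
      ", voxel ", paste(x$voxel_size, collapse = "x"), " mm, S-I axis ",
      x$axis, "\n  cord voxels: ", sum(x$cord_mask),
      ", lesion voxels: ", sum(x$lesion_mask), "\n", sep = "")
  invisible(x)
}

#' Project the lesion mask onto the axial plane
#'
#' Collapses the 3-D lesion mask along the superior-inferior axis by logical
#' union, producing the single composite axial lesion image used for
#' spared-tissue scoring: an axial pixel is lesioned iff the lesion occupies
#' that (x, y) position on any slice.
#'
#' @param study a [lesion_study()].
#' @return logical matrix on the axial grid.
#' @export
project_lesion_axial <- function(study) {
  stopifnot(inherits(study, "lesion_study"))
  apply(study$lesion_mask, setdiff(1:3, study$axis), any)
}

#' Percent spared weight of one region under a projected lesion
#'
#' @param projected_lesion logical axial matrix (from
#'   [project_lesion_axial()]).
#' @param region_weights nonnegative weight matrix on the same grid (binary
#'   masks are weights in 0/1).
#' @return percent spared: `100 * sum(weights over non-lesioned pixels) /
#'   sum(all weights)`.
#' @export
compute_spared_fraction <- function(projected_lesion, region_weights) {
  assert_that(identical(dim(projected_lesion), dim(region_weights)),
              "projected lesion and region weights must share a grid")
  assert_that(all(region_weights >= 0), "region weights must be nonnegative")
  tot <- sum(region_weights)
  assert_that(tot > 0, "region has zero total weight: spared fraction undefined")
  100 * sum(region_weights[!projected_lesion]) / tot
}

#' Five-region spared-tissue profile of a study
#'
#' Projects the lesion axially and scores percent spared tissue of the whole
#' cord and of the anterior, posterior, left-lateral and right-lateral
#' white-matter regions against the atlas.
#'
#' @param study a [lesion_study()], already on the atlas grid (after
#'   [slicewise_align()] if needed).
#' @param atlas an [make_region_atlas()]-style atlas on the matching axial
#'   grid.
#' @param total `"cord"` (default; score the whole axial cord mask, grey and
#'   white matter) or `"regions"` (score the union of the four region weight
#'   maps).
#' @return a [spared_tissue_profile()].
#' @export
spared_profile <- function(study, atlas, total = c("cord", "regions")) {
  total <- match.arg(total)
  proj <- project_lesion_axial(study)
  assert_that(identical(dim(proj), dim(atlas$cord_mask)),
              "study axial grid does not match atlas grid")
  tw <- if (total == "cord") {
    w <- matrix(0, nrow(proj), ncol(proj)); w[atlas$cord_mask] <- 1; w
  } else {
    Reduce(`+`, atlas$region_weights)
  }
  spared_tissue_profile(
    total = compute_spared_fraction(proj, tw),
    anterior = compute_spared_fraction(proj, atlas$region_weights$anterior),
    posterior = compute_spared_fraction(proj, atlas$region_weights$posterior),
    left = compute_spared_fraction(proj, atlas$region_weights$left_lateral),
    right = compute_spared_fraction(proj, atlas$region_weights$right_lateral))
}

slice_centroid <- function(m) {
  idx <- which(m, arr.ind = TRUE)
  c(mean(idx[, 1]), mean(idx[, 2]))
}

#' Slicewise centroid-and-scale alignment to a template cord
#'
#' A deliberately simple per-slice rigid alignment for phantom work: each
#' axial cord slice is translated so its centroid lands on the template cord
#' centroid and isotropically scaled so its area matches the template area
#' (scale `s = sqrt(template_area / subject_area)`), and the identical
#' transform is applied to the lesion slice. Nonlinear template registration
#' of clinical images is out of scope here; inputs to the quantification
#' pipeline are assumed already in template space.
#'
#' @param study a [lesion_study()].
#' @param template_cord_2d logical axial matrix, the template cord mask.
#' @return list with `study` (aligned [lesion_study()]) and `transforms`
#'   (data.frame: slice, dx, dy, scale, empty). Empty cord slices get the
#'   identity transform and are flagged in the `empty` column.
#' @export
slicewise_align <- function(study, template_cord_2d) {
  stopifnot(inherits(study, "lesion_study"))
  template_cord_2d <- as.matrix(template_cord_2d) > 0
  axial <- setdiff(1:3, study$axis)
  d <- dim(study$cord_mask)
  assert_that(identical(dim(template_cord_2d), d[axial]),
              "template grid does not match study axial grid")
  tc <- slice_centroid(template_cord_2d)
  ta <- sum(template_cord_2d)
  nz <- d[study$axis]
  nx <- d[axial][1]; ny <- d[axial][2]

  get_slice <- function(arr, z) {
    idx <- rep(list(quote(expr = )), 3)
    idx[[study$axis]] <- z
    do.call(`[`, c(list(arr), idx))
  }
  cord_out <- array(FALSE, dim = d)
  lesion_out <- array(FALSE, dim = d)
  set_slice <- function(arr, z, val) {
    idx <- rep(list(quote(expr = )), 3)
    idx[[study$axis]] <- z
    do.call(`[<-`, c(list(arr), idx, list(val)))
  }

  tr <- data.frame(slice = seq_len(nz), dx = 0, dy = 0, scale = 1,
                   empty = FALSE)
  px <- matrix(rep(seq_len(nx), ny), nx, ny)
  py <- matrix(rep(seq_len(ny), each = nx), nx, ny)
  for (z in seq_len(nz)) {
    cs <- get_slice(study$cord_mask, z)
    ls <- get_slice(study$lesion_mask, z)
    if (!any(cs)) {
      tr$empty[z] <- TRUE
      next
    }
    sc <- slice_centroid(cs)
    s <- sqrt(ta / sum(cs))
    tr$dx[z] <- tc[1] - sc[1]; tr$dy[z] <- tc[2] - sc[2]; tr$scale[z] <- s
    # inverse mapping: output pixel p samples subject at c_s + (p - c_t)/s
    sx <- round(sc[1] + (px - tc[1]) / s)
    sy <- round(sc[2] + (py - tc[2]) / s)
    ok <- sx >= 1 & sx <= nx & sy >= 1 & sy <= ny
    lin <- (pmax(sy, 1) - 1) * nx + pmax(sx, 1)
    cnew <- matrix(FALSE, nx, ny); lnew <- matrix(FALSE, nx, ny)
    cnew[ok] <- cs[lin[ok]]
    lnew[ok] <- ls[lin[ok]]
    cord_out <- set_slice(cord_out, z, cnew)
    lesion_out <- set_slice(lesion_out, z, lnew)
  }
  if (any(tr$empty)) {
    message(sum(tr$empty), " empty cord slice(s) left untransformed")
  }
  list(study = lesion_study(cord_out, lesion_out,
                            voxel_size = study$voxel_size, axis = study$axis),
       transforms = tr)
}
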