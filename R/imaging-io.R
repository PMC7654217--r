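as_nifti_volume <- function(arr, voxel_size) {
  img <- RNifti::asNifti(arr * 1)
  RNifti::pixdim(img) <- voxel_size
  img
}

#' Write cord and lesion masks as NIfTI volumes
#'
#' @param study a [lesion_study()].
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix, e.g. a subject id.
#' @return invisibly, the two file paths (`cord`, `lesion`).
#' @export
write_lesion_study <- function(study, dir, prefix = "sub") {
  stopifnot(inherits(study, "lesion_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(cord = file.path(dir, paste0(prefix, "_cord.nii.gz")),
             lesion = file.path(dir, paste0(prefix, "_lesion.nii.gz")))
  RNifti::writeNifti(as_nifti_volume(study$cord_mask, study$voxel_size),
                     paths["cord"])
  RNifti::writeNifti(as_nifti_volume(study$lesion_mask, study$voxel_size),
                     paths["lesion"])
  invisible(paths)
}

#' Read cord and lesion masks from NIfTI files
#'
#' Masks are binarized at 0.5, accommodating probabilistic inputs.
#'
#' @param cord_path,lesion_path NIfTI file paths.
#' @param axis superior-inferior axis index (default 3).
#' @return a [lesion_study()].
#' @export
read_lesion_study <- function(cord_path, lesion_path, axis = 3L) {
  cord <- RNifti::readNifti(cord_path)
  lesion <- RNifti::readNifti(lesion_path)
  vs <- RNifti::pixdim(cord)
  lesion_study(array(cord > 0.5, dim = dim(cord)),
               array(lesion > 0.5, dim = dim(lesion)),
               voxel_size = vs[seq_len(min(3, length(vs)))], axis = axis)
}

#' Write an axial region atlas as NIfTI volumes
#'
#' One single-slice volume per region weight map plus the whole-cord mask,
#' and a small JSON sidecar with the atlas geometry.
#'
#' @param atlas an [make_region_atlas()] object.
#' @param dir output directory.
#' @return invisibly, the written file paths.
#' @export
write_region_atlas <- function(atlas, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  vols <- c(atlas$region_weights, list(cord = atlas$cord_mask * 1))
  for (nm in names(vols)) {
    p <- file.path(dir, paste0("atlas_", nm, ".nii.gz"))
    arr <- array(vols[[nm]], dim = c(dim(vols[[nm]]), 1L))
    RNifti::writeNifti(RNifti::asNifti(arr * 1), p)
    paths[nm] <- p
  }
  meta <- file.path(dir, "atlas_meta.json")
  jsonlite::write_json(list(grid_shape = atlas$grid_shape,
                            cord_radii = atlas$cord_radii,
                            center = atlas$center,
                            weighting = atlas$weighting),
                       meta, auto_unbox = TRUE, digits = NA)
  paths["meta"] <- meta
  invisible(paths)
}

#' Read an axial region atlas written by [write_region_atlas()]
#'
#' @param dir directory holding the `atlas_*.nii.gz` volumes and sidecar.
#' @return an `axial_region_atlas` object.
#' @export
read_region_atlas <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "atlas_meta.json"),
                              simplifyVector = TRUE)
  regions <- c("anterior", "posterior", "left_lateral", "right_lateral")
  rw <- lapply(regions, function(r) {
    v <- RNifti::readNifti(file.path(dir, paste0("atlas_", r, ".nii.gz")))
    matrix(v, dim(v)[1], dim(v)[2])
  })
  names(rw) <- regions
  cord <- RNifti::readNifti(file.path(dir, "atlas_cord.nii.gz"))
  structure(list(region_weights = rw,
                 cord_mask = matrix(cord > 0.5, dim(cord)[1], dim(cord)[2]),
                 grid_shape = as.integer(meta$grid_shape),
                 cord_radii = meta$cord_radii, center = meta$center,
                 weighting = meta$weighting),
            class = "axial_region_atlas")
}

#' Write spared-tissue profiles to CSV
#'
#' One row per subject: `subject_id, spared_total, spared_anterior,
#' spared_posterior, spared_left, spared_right`, all in percent.
#'
#' @param profiles named list of [spared_tissue_profile()]s (names are
#'   subject ids) or a data.frame already in the output layout.
#' @param path output CSV path.
#' @return invisibly, the data.frame written.
#' @export
write_profiles_csv <- function(profiles, path) {
  df <- if (is.data.frame(profiles)) profiles else {
    cbind(data.frame(subject_id = names(profiles)),
          do.call(rbind, lapply(profiles, function(p)
            as.data.frame(as.list(unclass(p))))))
  }
  rownames(df) <- NULL
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
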