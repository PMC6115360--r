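# File formats: NIfTI volumes, CSV feature tables / cohort stats, YAML
# configs and ROI specs.

#' Read / write volumes as NIfTI
#'
#' Spacing is stored in the NIfTI pixdim header; intensities are HU.
#'
#' @param path File path (.nii or .nii.gz).
#' @return \code{readVolume}: an \linkS4class{ImageVolume}.
#' @export
readVolume <- function(path) {
  img <- RNifti::readNifti(path)
  ImageVolume(array(as.numeric(img), dim = dim(img)),
              spacing = RNifti::pixdim(img)[1:3])
}

#' @rdname readVolume
#' @param volume An \linkS4class{ImageVolume}.
#' @export
writeVolume <- function(volume, path) {
  img <- RNifti::asNifti(volume@voxels)
  RNifti::pixdim(img) <- volume@spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read / write long-format feature tables as CSV
#'
#' Canonical columns: manufacturer, scanner, protocol, material,
#' thickness_mm, preprocessing, feature, value.
#'
#' @param path CSV path.
#' @return \code{readFeatureTable}: a \linkS4class{FeatureTable}.
#' @export
readFeatureTable <- function(path) {
  FeatureTable(read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname readFeatureTable
#' @param table A \linkS4class{FeatureTable} or data.frame.
#' @export
writeFeatureTable <- function(table, path) {
  rec <- if (is(table, "FeatureTable")) table@records else
    as.data.frame(table)
  write.csv(rec, path, row.names = FALSE)
  invisible(path)
}

#' Read / write patient cohort stats as CSV
#'
#' Columns: feature, mu_p, sigma_p.
#'
#' @param path CSV path.
#' @param cohort Cohort label (read side).
#' @return \code{readCohortStats}: a \linkS4class{PatientCohortStats}.
#' @export
readCohortStats <- function(path, cohort = "cohort") {
  PatientCohortStats(cohort, read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname readCohortStats
#' @param stats A \linkS4class{PatientCohortStats}.
#' @export
writeCohortStats <- function(stats, path) {
  write.csv(stats@stats, path, row.names = FALSE)
  invisible(path)
}

#' Read a cylindrical ROI specification from YAML
#'
#' Expected keys: \code{center} (mm triple), \code{diameter_mm},
#' \code{height_mm}.
#'
#' @param path YAML path.
#' @return A \linkS4class{CylindricalROI}.
#' @export
readROI <- function(path) {
  y <- yaml::read_yaml(path)
  CylindricalROI(unlist(y$center), diameter = y$diameter_mm,
                 height = y$height_mm)
}

#' Read / write a study configuration as YAML
#'
#' @param path YAML path.
#' @return \code{readStudyConfig}: a study configuration list (see
#'   \code{\link{studyConfig}}).
#' @export
readStudyConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  # YAML maps come back as lists; restore the named-numeric sigma sets
  if (!is.null(cfg$sigmas)) cfg$sigmas <- lapply(cfg$sigmas, unlist)
  if (!is.null(cfg$feature_params))
    cfg$feature_params <- as.data.frame(cfg$feature_params)
  do.call(studyConfig, cfg)
}

#' @rdname readStudyConfig
#' @param config A study configuration list.
#' @export
writeStudyConfig <- function(config, path) {
  cfg <- unclass(config)
  # named numeric vectors serialize as YAML maps only when listed
  cfg$sigmas <- lapply(cfg$sigmas, as.list)
  yaml::write_yaml(cfg, path)
  invisible(path)
}
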