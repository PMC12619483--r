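#' Read a CT volume from NIfTI
#'
#' Reads a NIfTI-1 volume (.nii or .nii.gz) of signed attenuation values in
#' HU and its voxel spacing (pixdim, mm) into a [CTScan-class].
#'
#' @param path Path to the NIfTI file.
#' @return A [CTScan-class].
#' @export
readCTScan <- function(path) {
  if (!file.exists(path)) stopStructural("CT file not found: %s", path)
  img <- RNifti::readNifti(path)
  vals <- array(as.numeric(img), dim(img))
  if (length(dim(vals)) != 3L)
    stopStructural("expected a 3D NIfTI volume, got %dD", length(dim(vals)))
  CTScan(vals, spacing = RNifti::pixdim(img)[1:3])
}

#' Read a lobe mask from NIfTI
#'
#' Reads an integer-labelled NIfTI volume with the 0-6 lobe dialect (see
#' [lobeLabels]) into a [LobeMask-class].
#'
#' @param path Path to the NIfTI file.
#' @return A [LobeMask-class].
#' @export
readLobeMask <- function(path) {
  if (!file.exists(path)) stopStructural("lobe mask file not found: %s", path)
  img <- RNifti::readNifti(path)
  lab <- array(as.integer(round(as.numeric(img))), dim(img))
  if (length(dim(lab)) != 3L)
    stopStructural("expected a 3D NIfTI volume, got %dD", length(dim(lab)))
  LobeMask(lab, spacing = RNifti::pixdim(img)[1:3])
}

#' Write imaging objects to NIfTI
#'
#' @param x A [CTScan-class] or [LobeMask-class].
#' @param path Output path (.nii or .nii.gz).
#' @return The path, invisibly.
#' @export
writeNiftiVolume <- function(x, path) {
  arr <- if (is(x, "CTScan")) x@values else x@labels
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- voxelSpacing(x)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a cohort table
#'
#' Reads a cohort CSV following the column dictionary: `patient_id`,
#' `serum_aat` (mg/dl), `genotype`, `has_deficiency_allele`, `age` (years),
#' `sex`, `bmi` (kg/m^2), `pack_years`, `fev1_pct` (% predicted), `rv_l`
#' (litres), and optionally `phenotype` / `mid_predominant`. The serum group
#' is (re)derived from `serum_aat`.
#'
#' @param path Path to the CSV file.
#' @return A `data.frame` with a derived `group` column.
#' @export
readCohort <- function(path) {
  if (!file.exists(path)) stopStructural("cohort file not found: %s", path)
  co <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "serum_aat", "age", "sex", "bmi", "pack_years",
            "fev1_pct", "rv_l")
  miss <- setdiff(need, names(co))
  if (length(miss))
    stopStructural("cohort table lacks columns: %s", paste(miss, collapse = ", "))
  hda <- if ("has_deficiency_allele" %in% names(co))
    co$has_deficiency_allele else TRUE
  co$group <- assignSerumGroup(co$serum_aat, hda)$group
  co
}
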