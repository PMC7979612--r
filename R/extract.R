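# the 105 texture features of one discretized domain
texture_feature_set <- function(dz) {
  glcm <- glcm_feature_set(dz)
  ngtdm <- ngtdm_features(dz)
  glrlm_a <- glrlm_features(dz, "averaged")
  glrlm_m <- glrlm_features(dz, "merged")
  glszm <- glszm_features(dz)
  c(glcm, ngtdm, glrlm_a, glrlm_m, glszm)
}

#' Extract the full radiomics feature vector
#'
#' Evaluates every entry of the registry on one (already preprocessed)
#' volume: shape on the mask geometry, first-order intensity on the raw HU
#' values, texture at bin width 35 anchored at −950 HU on the original
#' domain, the 12 designated GLCM entries again at bin width 10, and per
#' stationary-wavelet band 17 intensity plus 105 texture features (bands
#' are discretized at width 35 anchored at their own in-mask minimum, since
#' filtered values are not on the HU scale).
#'
#' @param vol A [ct_volume()] (isotropically resampled in the default
#'   pipeline).
#' @param mask Nonempty logical array congruent with the volume.
#' @param registry Registry data frame (default [feature_registry()]).
#' @param anchor_hu Discretization anchor for the original HU domain
#'   (default −950).
#' @return Named numeric vector, one finite value per registry entry, in
#'   registry order.
#' @export
extract_all <- function(vol, mask, registry = feature_registry(),
                        anchor_hu = -950) {
  check_mask(vol, mask)
  known <- c(
    paste0("shape.", c("volume_ml", "surfaceArea_cm2", "sphericity", "maxDiameter3D")),
    paste0("int.", intensity_feature_names()),
    paste0("tex.", texture_feature_names())
  )
  unknown <- setdiff(registry$formula_id, known)
  if (length(unknown))
    stop("unknown formula id(s) in registry: ", paste(utils::head(unknown, 5), collapse = ", "))

  vals <- c()
  shape <- shape_features(mask, vol$spacing_mm)
  intens <- intensity_features(vol, mask)
  dz35 <- discretize(vol, mask, 35, anchor_hu = anchor_hu)
  tex35 <- texture_feature_set(dz35)
  dz10 <- discretize(vol, mask, 10, anchor_hu = anchor_hu)
  glcm10 <- glcm_feature_set(dz10)[glcm_b10_names()]
  names(glcm10) <- paste0(names(glcm10), ".b10")
  vals <- c(shape, intens, tex35, glcm10)

  bands_needed <- unique(registry$domain[registry$domain != "original"])
  if (length(bands_needed)) {
    bands <- wavelet_decompose(vol)
    int_band_names <- setdiff(intensity_feature_names(), c("minimum", "maximum"))
    for (b in bands_needed) {
      arr <- bands[[b]]
      if (is.null(arr)) stop("unknown wavelet band in registry: ", b)
      bi <- intensity_features(arr, mask, include = int_band_names)
      dzb <- discretize(arr, mask, 35, anchor_hu = NULL)
      bt <- texture_feature_set(dzb)
      both <- c(bi, bt)
      names(both) <- paste0(names(both), ".", b)
      vals <- c(vals, both)
    }
  }
  missing <- setdiff(registry$name, names(vals))
  if (length(missing))
    stop("registry entries not produced: ", paste(utils::head(missing, 5), collapse = ", "))
  out <- vals[registry$name]
  if (any(!is.finite(out)))
    stop("non-finite feature values: ",
         paste(utils::head(registry$name[!is.finite(out)], 5), collapse = ", "))
  out
}

#' Extract features for a list of phantoms / volumes
#'
#' Runs the fixed preprocessing chain (HU-window masking within the
#' provided lung mask, isotropic resampling, extraction) for each subject
#' and assembles the feature table.
#'
#' @param volumes List of `list(volume =, mask =)` entries (e.g. from
#'   [generate_volume()]).
#' @param ids Character vector of patient ids.
#' @param target_mm Isotropic resampling target (default 2 mm).
#' @param hu_low,hu_high HU window for [mask_lung()].
#' @param registry Feature registry.
#' @return Data frame: `patient_id` plus one column per registry entry.
#' @export
extract_cohort_features <- function(volumes, ids, target_mm = 2,
                                    hu_low = -950, hu_high = -150,
                                    registry = feature_registry()) {
  stopifnot(length(volumes) == length(ids))
  rows <- lapply(seq_along(volumes), function(i) {
    v <- volumes[[i]]
    win <- mask_lung(v$volume, hu_low, hu_high, largest_component = TRUE)
    m <- win & v$mask
    if (!any(m)) m <- win
    rs <- resample_isotropic(v$volume, m, target_mm)
    extract_all(rs$volume, rs$mask, registry)
  })
  tab <- as.data.frame(do.call(rbind, rows), check.names = FALSE)
  cbind(data.frame(patient_id = ids, stringsAsFactors = FALSE), tab)
}

#' Write a feature table as CSV (stable column order)
#' @param features Data frame from [extract_cohort_features()].
#' @param path CSV path.
#' @return `path` invisibly.
#' @export
write_features_csv <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}
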