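glcm_feature_names <- function() {
  c("jointMax", "jointAverage", "jointVariance", "jointEntropy",
    "sumAverage", "sumVariance", "sumEntropy", "diffAverage",
    "diffVariance", "diffEntropy", "jointEnergy", "contrast",
    "dissimilarity", "homogenity", "homogenity_n", "idm", "idm_n",
    "inverseVariance", "correlation", "autocorrelation", "clusterTendency",
    "clusterShade", "clusterProminence", "imc1", "imc2", "mcc")
}

# the 12 GLCM entries re-evaluated at bin width 10 (".b10" suffix)
glcm_b10_names <- function() {
  base <- c("contrast", "correlation", "homogenity", "homogenity_n",
            "jointEntropy", "jointEnergy")
  c(base, paste0("M_", base))
}

texture_feature_names <- function() {
  c(glcm_feature_names(), paste0("M_", glcm_feature_names()),
    c("coarseness", "neighContrast", "busyness", "complexity", "strength"),
    glrlm_feature_names(), paste0("M_", glrlm_feature_names()),
    glszm_feature_names())
}

wavelet_band_names <- function() {
  c("LLL", "LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH")
}

#' The default 1116-entry feature registry
#'
#' The ordered inventory of feature definitions the extractor evaluates:
#' 4 shape + 19 intensity + 105 texture features (52 GLCM as 26 averaged +
#' 26 merged `M_`, 5 NGTDM, 32 GLRLM as 16 averaged + 16 merged, 16 GLSZM)
#' at bin width 35 on the original HU domain; 12 designated GLCM entries
#' re-evaluated at bin width 10 (suffix `.b10`); and, per stationary-
#' wavelet band (8 bands, suffix `.LLL` .. `.HHH`), 17 intensity features
#' (all but minimum/maximum) plus the 105 texture features at bin width 35
#' — 122 per band, 976 in total, 1116 overall.
#'
#' @return Data frame with columns `name`, `class` (shape / intensity /
#'   texture / wavelet), `domain` (`original` or a band name), `bin_width`
#'   (`none`, `10` or `35`) and `formula_id`.
#' @export
feature_registry <- function() {
  rows <- list()
  add <- function(names, class, domain, bin, family) {
    data.frame(name = names, class = class, domain = domain,
               bin_width = bin, formula_id = paste0(family, ".", names),
               stringsAsFactors = FALSE)
  }
  shape_names <- c("volume_ml", "surfaceArea_cm2", "sphericity", "maxDiameter3D")
  rows[[1]] <- add(shape_names, "shape", "original", "none", "shape")
  rows[[2]] <- add(intensity_feature_names(), "intensity", "original", "none", "int")
  rows[[3]] <- add(texture_feature_names(), "texture", "original", "35", "tex")
  rows[[4]] <- data.frame(
    name = paste0(glcm_b10_names(), ".b10"), class = "texture",
    domain = "original", bin_width = "10",
    formula_id = paste0("tex.", glcm_b10_names()), stringsAsFactors = FALSE
  )
  band_rows <- lapply(wavelet_band_names(), function(b) {
    int_names <- setdiff(intensity_feature_names(), c("minimum", "maximum"))
    rbind(
      data.frame(name = paste0(int_names, ".", b), class = "wavelet",
                 domain = b, bin_width = "none",
                 formula_id = paste0("int.", int_names),
                 stringsAsFactors = FALSE),
      data.frame(name = paste0(texture_feature_names(), ".", b),
                 class = "wavelet", domain = b, bin_width = "35",
                 formula_id = paste0("tex.", texture_feature_names()),
                 stringsAsFactors = FALSE)
    )
  })
  out <- do.call(rbind, c(rows, band_rows))
  rownames(out) <- NULL
  stopifnot(!anyDuplicated(out$name))
  out
}

#' Write / read a feature registry as JSON
#' @param registry A registry data frame ([feature_registry()]).
#' @param path JSON file path.
#' @return `path` invisibly / the registry data frame.
#' @export
write_registry_json <- function(registry, path) {
  jsonlite::write_json(registry, path, dataframe = "rows", pretty = TRUE)
  invisible(path)
}

#' @rdname write_registry_json
#' @export
read_registry_json <- function(path) {
  as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
}
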