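#' Specification of a synthetic lung phantom
#'
#' Parameters for a single-lung (right-lung geometry) CT phantom: an
#' ellipsoidal lung of Gaussian parenchyma inside a soft-tissue body
#' surrounded by air, with a connected subpleural fibrosis region whose
#' texture is a controllable mix of ground-glass opacity, reticulation and
#' honeycombing.
#'
#' @param shape_voxels Integer length-3 grid size (>= 16 per axis).
#' @param spacing_mm Positive length-3 voxel spacing in mm.
#' @param base_hu_mean Mean parenchymal HU (default −850).
#' @param base_hu_sd Parenchymal HU standard deviation (default 40).
#' @param lesion_extent Fraction of lung voxels carrying fibrosis texture,
#'   in [0, 1].
#' @param lesion_mix Nonnegative length-3 proportions (ground-glass,
#'   reticulation, honeycombing); must sum to 1.
#' @param seed Integer seed; the phantom is a deterministic function of the
#'   spec.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(shape_voxels = c(64, 64, 64),
                         spacing_mm = c(1, 1, 1),
                         base_hu_mean = -850, base_hu_sd = 40,
                         lesion_extent = 0,
                         lesion_mix = c(1 / 3, 1 / 3, 1 / 3),
                         seed = 1L) {
  shape_voxels <- as.integer(shape_voxels)
  if (length(shape_voxels) != 3L || any(shape_voxels < 16L))
    stop("shape_voxels must be 3 integers >= 16")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 3)
  if (length(spacing_mm) != 3L || any(spacing_mm <= 0))
    stop("spacing_mm must be positive")
  if (!is.finite(lesion_extent) || lesion_extent < 0 || lesion_extent > 1)
    stop("lesion_extent must be in [0, 1]")
  lesion_mix <- as.numeric(lesion_mix)
  if (length(lesion_mix) != 3L || any(lesion_mix < 0) ||
      abs(sum(lesion_mix) - 1) > 1e-9)
    stop("lesion_mix must be 3 nonnegative proportions summing to 1")
  if (base_hu_sd <= 0) stop("base_hu_sd must be positive")
  structure(
    list(shape_voxels = shape_voxels, spacing_mm = spacing_mm,
         base_hu_mean = base_hu_mean, base_hu_sd = base_hu_sd,
         lesion_extent = lesion_extent, lesion_mix = lesion_mix,
         seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

#' Generate a lung CT phantom
#'
#' Renders the phantom described by a [phantom_spec()]: exterior air at
#' −1000 HU, an ellipsoidal soft-tissue body near 0 HU, and inside it an
#' ellipsoidal lung of `Normal(base_hu_mean, base_hu_sd)` parenchyma clipped
#' to [−1000, 100]. Fibrosis is painted on a connected subpleural region
#' (the lung voxels nearest a pleural seed point) covering `lesion_extent`
#' of the lung; within it, contiguous sub-regions get ground-glass (mean
#' shift to ≈ −650 HU), reticulation (additive periodic lattice, amplitude
#' 150 HU, period 4 voxels) and honeycombing (packed air cysts at −950 HU,
#' radius 2–4 voxels, with ≈ −300 HU walls) in the proportions of
#' `lesion_mix`. Deterministic for a fixed spec.
#'
#' @param spec A [phantom_spec()].
#' @return List with `volume` ([ct_volume()]), `mask` (logical lung
#'   ellipsoid), `lesion_map` (integer array: 0 none, 1 GGO, 2 reticulation,
#'   3 honeycombing) and `true_extent` (achieved lesion fraction).
#' @examples
#' ph <- generate_volume(phantom_spec(shape_voxels = c(24, 24, 24),
#'                                    lesion_extent = 0.3, seed = 7))
#' ph$true_extent
#' @export
generate_volume <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$shape_voxels
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)

  cx <- (d + 1) / 2
  xs <- seq_len(d[1]); ys <- seq_len(d[2]); zs <- seq_len(d[3])
  # normalized coordinates in [-1, 1] per axis
  nx <- (xs - cx[1]) / (d[1] / 2)
  ny <- (ys - cx[2]) / (d[2] / 2)
  nz <- (zs - cx[3]) / (d[3] / 2)
  R2 <- outer(outer(nx^2 / 0.9^2, ny^2 / 0.9^2, "+"), nz^2 / 0.95^2, "+")
  body <- R2 <= 1
  # lung: smaller ellipsoid, offset towards +x (right lung geometry)
  Rl <- outer(outer((nx - 0.15)^2 / 0.55^2, ny^2 / 0.6^2, "+"),
              nz^2 / 0.75^2, "+")
  lung <- Rl <= 1

  hu <- array(-1000, d)                       # exterior air
  hu[body] <- stats::rnorm(sum(body), 20, 15) # soft tissue
  n_lung <- sum(lung)
  hu[lung] <- stats::rnorm(n_lung, spec$base_hu_mean, spec$base_hu_sd)

  lesion_map <- array(0L, d)
  if (spec$lesion_extent > 0) {
    n_lesion <- round(spec$lesion_extent * n_lung)
    if (n_lesion > 0) {
      idx <- which(lung)
      co <- arrayInd(idx, d)
      # subpleural seed: the most lateral (+x) lung voxel near mid-height
      seed_vox <- co[which.max(co[, 1] - 0.25 * abs(co[, 2] - cx[2]) -
                                 0.25 * abs(co[, 3] - cx[3])), ]
      dist2 <- (co[, 1] - seed_vox[1])^2 + (co[, 2] - seed_vox[2])^2 +
        (co[, 3] - seed_vox[3])^2
      ord <- order(dist2, idx)
      lesion_idx <- idx[ord[seq_len(n_lesion)]]
      # split the lesion (ordered by distance from the pleura) into the
      # three texture sub-regions, proportions = lesion_mix
      n_sub <- round(spec$lesion_mix * n_lesion)
      n_sub[3] <- n_lesion - n_sub[1] - n_sub[2]
      if (n_sub[3] < 0) { n_sub[2] <- n_sub[2] + n_sub[3]; n_sub[3] <- 0 }
      bounds <- cumsum(n_sub)
      kinds <- rep(1:3, times = c(n_sub[1], n_sub[2], n_sub[3]))
      lesion_map[lesion_idx] <- kinds

      co_l <- arrayInd(lesion_idx, d)
      # ground-glass: mean shift to about -650 HU
      g <- kinds == 1L
      if (any(g)) hu[lesion_idx[g]] <- stats::rnorm(sum(g), -650, spec$base_hu_sd)
      # reticulation: additive periodic lattice, amplitude 150, period 4
      r <- kinds == 2L
      if (any(r)) {
        lat <- sin(2 * pi * co_l[r, 1] / 4) * sin(2 * pi * co_l[r, 2] / 4) +
          sin(2 * pi * co_l[r, 3] / 4)
        hu[lesion_idx[r]] <- hu[lesion_idx[r]] + 150 * lat / 2 + 100
      }
      # honeycombing: packed air cysts in a -300 HU wall matrix
      h <- kinds == 3L
      if (any(h)) {
        radius <- stats::runif(1, 2, 4)
        period <- 2 * radius + 1.5
        phase <- stats::runif(3, 0, period)
        dd <- sqrt(((co_l[h, 1] - phase[1]) %% period - period / 2)^2 +
                     ((co_l[h, 2] - phase[2]) %% period - period / 2)^2 +
                     ((co_l[h, 3] - phase[3]) %% period - period / 2)^2)
        hu[lesion_idx[h]] <- ifelse(dd <= radius, -950, -300)
      }
    }
  }
  hu[lung] <- pmin(pmax(hu[lung], -1000), 100)
  list(volume = ct_volume(hu, spacing_mm = spec$spacing_mm),
       mask = lung,
       lesion_map = lesion_map,
       true_extent = sum(lesion_map > 0L) / n_lung)
}

# save/restore the global RNG state so generators are pure functions
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
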