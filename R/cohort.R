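#' Generate a synthetic SSc-ILD cohort
#'
#' Draws clinical records for two GAP-stage groups with pulmonary-function
#' distributions matching the study population structure (GAP1 means/SDs:
#' FVC 98 ± 18, DLCO 79 ± 19, FEV1 93 ± 16, TLC 94 ± 21; GAP2: 65 ± 26,
#' 56 ± 23, 61 ± 11, 57 ± 23 percent predicted; median ages ≈ 58 vs 68;
#' mostly female). Every record is rejection-sampled until the GAP stage
#' computed from its own gender/age/FVC/DLCO ([gap_points()]) equals the
#' intended group label, so generator labels and the staging calculator
#' agree by construction. Each record carries a [phantom_spec()] whose
#' lesion extent grows with a per-patient severity latent derived from the
#' pulmonary-function deficit, so GAP2 lungs carry more fibrosis on
#' average.
#'
#' @param n_gap1,n_gap2 Nonnegative group sizes (study: 54 and 6).
#' @param seed Integer seed.
#' @param phantom_shape,phantom_spacing Geometry handed to each record's
#'   [phantom_spec()].
#' @return List with `clinical` (data frame: patient_id, gender, age,
#'   fvc_pct, dlco_pct, fev1_pct, tlc_pct, gap_points, gap_stage_true,
#'   lesion_extent) and `phantom_specs` (list of [phantom_spec()], one per
#'   row).
#' @examples
#' coh <- generate_cohort(5, 2, seed = 1)
#' table(coh$clinical$gap_stage_true)
#' @export
generate_cohort <- function(n_gap1, n_gap2, seed = 1L,
                            phantom_shape = c(48, 48, 48),
                            phantom_spacing = c(2, 2, 2)) {
  stopifnot(n_gap1 >= 0, n_gap2 >= 0)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  pft <- list(
    `1` = c(fvc = 98, fvc_sd = 18, dlco = 79, dlco_sd = 19,
            fev1 = 93, fev1_sd = 16, tlc = 94, tlc_sd = 21,
            age = 58, age_sd = 12, p_female = 48 / 54),
    `2` = c(fvc = 65, fvc_sd = 26, dlco = 56, dlco_sd = 23,
            fev1 = 61, fev1_sd = 11, tlc = 57, tlc_sd = 23,
            age = 68, age_sd = 7, p_female = 4 / 6)
  )

  draw_record <- function(stage_target, id) {
    p <- pft[[as.character(stage_target)]]
    for (try in seq_len(5000L)) {
      gender <- if (stats::runif(1) < p["p_female"]) "female" else "male"
      age <- stats::rnorm(1, p["age"], p["age_sd"])
      fvc <- stats::rnorm(1, p["fvc"], p["fvc_sd"])
      dlco <- stats::rnorm(1, p["dlco"], p["dlco_sd"])
      fev1 <- stats::rnorm(1, p["fev1"], p["fev1_sd"])
      tlc <- stats::rnorm(1, p["tlc"], p["tlc_sd"])
      if (age < 20 || age > 95 || min(fvc, dlco, fev1, tlc) <= 10) next
      gp <- gap_points(gender, age, fvc, dlco)
      if (gp$stage == stage_target) {
        return(data.frame(
          patient_id = id, gender = gender, age = age,
          fvc_pct = fvc, dlco_pct = dlco, fev1_pct = fev1, tlc_pct = tlc,
          gap_points = gp$points, gap_stage_true = stage_target,
          stringsAsFactors = FALSE
        ))
      }
    }
    stop("could not draw a record consistent with the requested GAP stage")
  }

  stages <- c(rep(1L, n_gap1), rep(2L, n_gap2))
  ids <- sprintf("P%03d", seq_along(stages))
  recs <- do.call(rbind, Map(draw_record, stages, ids))
  if (is.null(recs)) {
    recs <- data.frame(patient_id = character(), gender = character(),
                       age = numeric(), fvc_pct = numeric(),
                       dlco_pct = numeric(), fev1_pct = numeric(),
                       tlc_pct = numeric(), gap_points = integer(),
                       gap_stage_true = integer())
  }
  rownames(recs) <- NULL

  n <- nrow(recs)
  specs <- vector("list", n)
  extents <- numeric(n)
  if (n > 0) {
    # single severity latent: pulmonary-function deficit drives lesion load
    severity <- pmax(0, 1 - (recs$fvc_pct + recs$dlco_pct + recs$tlc_pct) / 300)
    extents <- pmin(0.6, pmax(0, 0.05 + 0.6 * severity + stats::rnorm(n, 0, 0.03)))
    # worse lungs shift texture mix from ground-glass towards honeycombing
    for (i in seq_len(n)) {
      s <- min(1, severity[i] / 0.5)
      mix <- c(1.2 - s, 0.6 + 0.2 * s, 0.2 + 0.8 * s)
      specs[[i]] <- phantom_spec(
        shape_voxels = phantom_shape, spacing_mm = phantom_spacing,
        lesion_extent = extents[i], lesion_mix = mix / sum(mix),
        seed = seed * 1000L + i
      )
    }
    recs$lesion_extent <- extents
  }
  list(clinical = recs, phantom_specs = specs)
}

#' Write / read a cohort clinical table as CSV
#' @param cohort Result of [generate_cohort()].
#' @param path CSV path.
#' @return `path` invisibly / the clinical data frame.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort$clinical, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Generate a feature table with planted class structure
#'
#' Builds the stand-in for an extracted radiomics table used to exercise the
#' selection and modeling stages: informative features with a standardized
#' class mean difference `d`, correlated feature clusters (latent factor +
#' small noise, intra-cluster Pearson r >= 0.8 by construction) and
#' independent standard-normal noise features.
#'
#' When `informative_in_clusters = TRUE`, the first `n_clusters` informative
#' features act as cluster latents: each cluster consists of one informative
#' feature (the cleanest copy of the latent) plus `cluster_size - 1`
#' noisier companions, all class-separated — the structure behind the
#' select-a-representative-per-cluster funnel. Otherwise clusters are pure
#' nuisance (no class signal) and informative features stand alone.
#'
#' @param n_per_class Length-2 integer vector (class 1, class 2).
#' @param n_informative Number of informative features.
#' @param n_noise Number of independent noise features.
#' @param n_clusters Number of correlated clusters.
#' @param cluster_size Features per cluster (default 5).
#' @param effect_size_d Standardized mean difference of informative
#'   features.
#' @param informative_in_clusters Couple informative features to cluster
#'   latents (default `FALSE`).
#' @param seed Integer seed.
#' @return Data frame with `patient_id`, `class` (factor GAP1/GAP2) and the
#'   feature columns; attributes `informative_names` and `cluster_map`
#'   (named integer vector, 0 = unclustered).
#' @export
generate_feature_table <- function(n_per_class, n_informative = 0,
                                   n_noise = 0, n_clusters = 0,
                                   cluster_size = 5, effect_size_d = 1,
                                   informative_in_clusters = FALSE,
                                   seed = 1L) {
  stopifnot(length(n_per_class) == 2, all(n_per_class >= 0),
            n_informative >= 0, n_noise >= 0, n_clusters >= 0,
            cluster_size >= 2)
  if (n_informative + n_noise + n_clusters == 0)
    stop("at least one feature must be requested")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  n <- sum(n_per_class)
  cls <- rep(c(0, 1), times = n_per_class)
  cols <- list()
  cluster_map <- integer(0)
  informative <- character(0)
  # companions share a class-independent latent factor u at noise 0.5
  # (pairwise r = 0.8 by construction); in the informative-cluster mode
  # the class shift sits only on the planted member (u + d * class), so
  # companions are collinear with it but carry no class signal of their
  # own - the structure the Gini-representative step is meant to resolve
  sigma_companion <- 0.5

  n_latent_inf <- if (informative_in_clusters) min(n_clusters, n_informative) else 0

  for (k in seq_len(n_clusters)) {
    u <- stats::rnorm(n)
    for (j in seq_len(cluster_size)) {
      if (k <= n_latent_inf && j == 1L) {
        nm <- sprintf("inf_c%02d", k)
        cols[[nm]] <- u + effect_size_d * cls
        informative <- c(informative, nm)
      } else {
        nm <- sprintf("clu%02d_f%02d", k, j)
        cols[[nm]] <- u + stats::rnorm(n, 0, sigma_companion)
      }
      cluster_map[nm] <- k
    }
  }
  for (j in seq_len(max(0, n_informative - n_latent_inf))) {
    nm <- sprintf("inf_%02d", j)
    cols[[nm]] <- stats::rnorm(n) + effect_size_d * cls
    cluster_map[nm] <- 0L
    informative <- c(informative, nm)
  }
  for (j in seq_len(n_noise)) {
    nm <- sprintf("noise_%03d", j)
    cols[[nm]] <- stats::rnorm(n)
    cluster_map[nm] <- 0L
  }

  out <- data.frame(
    patient_id = sprintf("S%03d", seq_len(n)),
    class = factor(ifelse(cls == 0, "GAP1", "GAP2"), levels = c("GAP1", "GAP2")),
    cols, check.names = FALSE, stringsAsFactors = FALSE
  )
  attr(out, "informative_names") <- informative
  attr(out, "cluster_map") <- cluster_map
  out
}
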