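#' Class-conditional lesion generator parameters
#'
#' Parameters of the synthetic ground-glass-nodule texture model: an
#' ellipsoidal lesion filled with a smoothed Gaussian random field.
#' `mean_hu` sets the intensity scale (which drives autocorrelation /
#' sum-average-type features), `smooth_len` the spatial correlation
#' length in voxels (which drives GLCM correlation and uniformity of
#' adjacent-pair intensities), `noise_sd` the marginal HU spread (which
#' drives histogram width, hence uniformity), and `core_fraction` the
#' probability of a brighter solid core (which fattens the intensity
#' tail, raising kurtosis and skewness).
#'
#' @param mean_hu mean lesion intensity (HU).
#' @param noise_sd in-mask HU standard deviation after smoothing (> 0).
#' @param smooth_len Gaussian smoothing sigma in voxels (>= 0).
#' @param core_fraction probability of a dense core in `[0, 1]`.
#' @param radius_range ellipsoid semi-axis range in voxels.
#' @param core_boost_hu added intensity inside the core.
#' @param core_radius_frac core semi-axes as a fraction of the lesion
#'   semi-axes: a small fraction gives a faint heavy tail (kurtosis), a
#'   large one a part-solid composition (broad intensity spread).
#' @param mean_jitter_sd between-lesion sd of the mean intensity (HU):
#'   cohort heterogeneity on top of the voxel noise.
#' @param texture_jitter between-lesion log-scale sd applied
#'   multiplicatively to `smooth_len` and `noise_sd` (lognormal
#'   factors), emulating the high coefficients of variation of real
#'   nodule cohorts.
#' @return list of class `class_params`.
#' @export
class_params <- function(mean_hu = -600, noise_sd = 100, smooth_len = 1,
                         core_fraction = 0, radius_range = c(3, 8),
                         core_boost_hu = 400, core_radius_frac = 0.4,
                         mean_jitter_sd = 0, texture_jitter = 0) {
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  if (smooth_len < 0) stop("smooth_len must be >= 0")
  if (core_fraction < 0 || core_fraction > 1)
    stop("core_fraction must be in [0, 1]")
  if (core_radius_frac <= 0 || core_radius_frac >= 1)
    stop("core_radius_frac must be in (0, 1)")
  structure(list(mean_hu = mean_hu, noise_sd = noise_sd,
                 smooth_len = smooth_len, core_fraction = core_fraction,
                 radius_range = as.numeric(radius_range),
                 core_boost_hu = core_boost_hu,
                 core_radius_frac = core_radius_frac,
                 mean_jitter_sd = mean_jitter_sd,
                 texture_jitter = texture_jitter),
            class = "class_params")
}

#' Cohort specification for the synthetic nodule generator
#'
#' Defaults mirror the clinical study design this package targets: 13
#' SPCH versus 49 LPA lesions, with the LPA group itself a mixture of an
#' easily separable subgroup (brighter, smoother lesions) and a hard
#' subgroup overlapping SPCH — the structure that motivates the
#' divide-and-conquer cascade.
#'
#' @param n_spch,n_lpa group sizes (defaults 13 and 49).
#' @param spch,lpa_easy,lpa_hard [class_params()] per subgroup.
#' @param lpa_easy_fraction share of LPA drawn from the easy subgroup.
#' @param grid_size cubic volume edge length in voxels.
#' @param background_hu lung background intensity.
#' @param background_sd background noise sd.
#' @param seed integer master seed; per-lesion seeds derive from it.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_spch = 13, n_lpa = 49,
                        spch = class_params(mean_hu = -650, noise_sd = 130,
                                            smooth_len = 0.55,
                                            core_fraction = 0.5,
                                            core_boost_hu = 340,
                                            core_radius_frac = 0.32,
                                            mean_jitter_sd = 30,
                                            texture_jitter = 0.35,
                                            radius_range = c(3, 8)),
                        lpa_easy = class_params(mean_hu = -480, noise_sd = 70,
                                                smooth_len = 2.4,
                                                core_fraction = 0.9,
                                                core_boost_hu = 320,
                                                core_radius_frac = 0.7,
                                                mean_jitter_sd = 60,
                                                texture_jitter = 0.35,
                                                radius_range = c(3, 10)),
                        lpa_hard = class_params(mean_hu = -770, noise_sd = 165,
                                                smooth_len = 0.25,
                                                core_fraction = 0.5,
                                                core_boost_hu = 650,
                                                core_radius_frac = 0.25,
                                                mean_jitter_sd = 30,
                                                texture_jitter = 0.35,
                                                radius_range = c(3, 8)),
                        lpa_easy_fraction = 2 / 3, grid_size = 48,
                        background_hu = -850, background_sd = 20, seed = 1) {
  if (n_spch < 1 || n_lpa < 1) stop("group counts must be >= 1")
  if (lpa_easy_fraction < 0 || lpa_easy_fraction > 1)
    stop("lpa_easy_fraction must be in [0, 1]")
  structure(list(n_spch = as.integer(n_spch), n_lpa = as.integer(n_lpa),
                 spch = spch, lpa_easy = lpa_easy, lpa_hard = lpa_hard,
                 lpa_easy_fraction = lpa_easy_fraction,
                 grid_size = as.integer(grid_size),
                 background_hu = background_hu, background_sd = background_sd,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' @rdname cohort_spec
#' @export
default_spec <- function(seed = 1) cohort_spec(seed = seed)

# Separable Gaussian smoothing with edge renormalisation; sigma in voxels.
gauss_smooth3 <- function(a, sigma) {
  if (sigma <= 0) return(a)
  h <- max(1L, ceiling(3 * sigma))
  w <- exp(-((-h:h)^2) / (2 * sigma^2))
  w <- w / sum(w)
  norm <- array(1, dim = dim(a))
  for (d in 1:3) {
    a <- conv_along(a, w, d)
    norm <- conv_along(norm, w, d)
  }
  a / norm
}

conv_along <- function(a, w, d) {
  dm <- dim(a)
  n <- dm[d]
  h <- (length(w) - 1L) / 2L
  out <- array(0, dim = dm)
  for (k in -h:h) {
    src <- (1:n) + k
    ok <- src >= 1 & src <= n
    if (!any(ok)) next
    dst <- which(ok)
    s <- src[ok]
    wk <- w[k + h + 1L]
    if (d == 1) out[dst, , ] <- out[dst, , ] + wk * a[s, , ]
    else if (d == 2) out[, dst, ] <- out[, dst, ] + wk * a[, s, ]
    else out[, , dst] <- out[, , dst] + wk * a[, , s]
  }
  out
}

#' Generate one synthetic nodule
#'
#' Draws an ellipsoidal lesion mask with random semi-axes, fills it with
#' a smoothed Gaussian random field (centred on `mean_hu` and scaled so
#' the in-mask sd equals `noise_sd`), optionally adds a brighter
#' concentric core, and embeds it in a noisy lung-like background.
#' Fully determined by `seed`.
#'
#' @param params a [class_params()].
#' @param seed integer seed for this lesion.
#' @param grid_size cubic grid edge (voxels).
#' @param background_hu,background_sd background intensity model.
#' @return list with `volume` ([ct_volume()]) and `mask`
#'   ([lesion_mask()]).
#' @export
generate_lesion <- function(params, seed, grid_size = 48,
                            background_hu = -850, background_sd = 20) {
  if (min(params$radius_range) < 1)
    stop("lesion radius below 1 voxel")
  if (2 * max(params$radius_range) + 2 > grid_size)
    stop("lesion radius too large for the grid")
  old <- .Random.seed_guard(seed)
  on.exit(old(), add = TRUE)

  g <- grid_size
  semi <- stats::runif(3, params$radius_range[1], params$radius_range[2])
  ctr <- (g + 1) / 2 + stats::runif(3, -1.5, 1.5)
  mean_hu <- params$mean_hu + stats::rnorm(1, sd = params$mean_jitter_sd)
  smooth_len <- params$smooth_len *
    exp(stats::rnorm(1, sd = params$texture_jitter))
  noise_sd <- params$noise_sd * exp(stats::rnorm(1, sd = params$texture_jitter))
  x <- seq_len(g)
  d2 <- outer(outer(((x - ctr[1]) / semi[1])^2,
                    ((x - ctr[2]) / semi[2])^2, "+"),
              ((x - ctr[3]) / semi[3])^2, "+")
  flags <- d2 <= 1
  if (!any(flags)) stop("lesion radius too small for the grid")

  # smoothed field over the lesion bounding box only (padded so edge
  # renormalisation does not touch in-mask voxels)
  h <- max(1L, ceiling(3 * smooth_len))
  lo <- pmax(1L, floor(ctr - semi) - h)
  hi <- pmin(g, ceiling(ctr + semi) + h)
  bd <- hi - lo + 1L
  field <- array(stats::rnorm(prod(bd)), dim = bd)
  field <- gauss_smooth3(field, smooth_len)
  flags_b <- flags[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  inm <- field[flags_b]
  inm <- inm - mean(inm)
  s <- stats::sd(inm)
  if (is.finite(s) && s > 0) inm <- inm / s * noise_sd

  has_core <- stats::runif(1) < params$core_fraction
  vox <- background_hu + stats::rnorm(g^3, sd = background_sd)
  dim(vox) <- c(g, g, g)
  vox[flags] <- mean_hu + inm
  if (has_core) {
    core <- d2 <= params$core_radius_frac^2
    vox[core] <- vox[core] + params$core_boost_hu
  }
  list(volume = ct_volume(vox), mask = lesion_mask(flags))
}

# Save/restore global RNG state around seeded generation.
.Random.seed_guard <- function(seed) {
  had <- exists(".Random.seed", envir = globalenv())
  old <- if (had) get(".Random.seed", envir = globalenv())
  set.seed(seed)
  function() {
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  }
}

#' Generate a full synthetic cohort
#'
#' Produces `n_spch + n_lpa` labelled lesions.  LPA cases are split
#' deterministically between the easy and hard subgroups by
#' `lpa_easy_fraction` (the first `round(n_lpa * fraction)` LPA cases
#' are easy).  Per-lesion seeds are `spec$seed * 10000 + case index`,
#' so the whole cohort is reproducible from the master seed.
#'
#' @param spec a [cohort_spec()].
#' @return list of class `nodule_cohort`; each element has `case_id`,
#'   `label` (`"SPCH"` / `"LPA"`), `subgroup`, `volume`, `mask`.
#' @export
generate_cohort <- function(spec = default_spec()) {
  n <- spec$n_spch + spec$n_lpa
  n_easy <- round(spec$n_lpa * spec$lpa_easy_fraction)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    if (i <= spec$n_spch) {
      label <- "SPCH"; sub <- "spch"; par <- spec$spch
    } else if (i - spec$n_spch <= n_easy) {
      label <- "LPA"; sub <- "easy"; par <- spec$lpa_easy
    } else {
      label <- "LPA"; sub <- "hard"; par <- spec$lpa_hard
    }
    les <- generate_lesion(par, seed = spec$seed * 10000L + i,
                           grid_size = spec$grid_size,
                           background_hu = spec$background_hu,
                           background_sd = spec$background_sd)
    out[[i]] <- list(case_id = sprintf("case_%03d", i), label = label,
                     subgroup = sub, volume = les$volume, mask = les$mask)
  }
  structure(out, class = "nodule_cohort", spec = spec)
}

#' Extract the feature table of a cohort
#'
#' @param cohort a [generate_cohort()] result (or a [cohort_spec()],
#'   which is generated first).
#' @param config an [extraction_config()].
#' @return data frame: `case_id`, `label`, then the 26 features.
#' @export
cohort_features <- function(cohort, config = extraction_config()) {
  if (inherits(cohort, "cohort_spec")) cohort <- generate_cohort(cohort)
  rows <- lapply(cohort, function(cs) {
    fv <- extract_features(cs$volume, cs$mask, config)
    cbind(data.frame(case_id = cs$case_id, label = cs$label,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(fv)))
  })
  do.call(rbind, rows)
}

#' Write a cohort to disk as NIfTI pairs plus a manifest
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return path of the manifest CSV, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  spec <- attr(cohort, "spec")
  rows <- lapply(cohort, function(cs) {
    vpath <- file.path(dir, paste0(cs$case_id, "_ct.nii.gz"))
    mpath <- file.path(dir, paste0(cs$case_id, "_mask.nii.gz"))
    write_nifti_volume(cs$volume, vpath)
    write_nifti_volume(cs$mask, mpath)
    data.frame(case_id = cs$case_id, label = cs$label,
               subgroup = cs$subgroup, volume = vpath, mask = mpath,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  manifest$seed <- if (!is.null(spec)) spec$seed else NA_integer_
  mpath <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mpath, row.names = FALSE)
  invisible(mpath)
}
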