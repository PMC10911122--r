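# Seeded synthetic speckle-image cohort generator with a planted intensity
# range whose per-subject mean is coupled to marker values. Emulates a
# two-group (sham/surgery) design of 12 subjects so the whole pipeline is
# testable without in-vivo data.

#' Parameters for the synthetic cohort generator
#'
#' Defaults emulate a 12-subject (6 sham, 6 surgery) rodent study: gamma
#' speckle background (shape 4, scale 16, mean 64), a planted intensity
#' range of 86-101, three coupled markers at coupling 0.9 whose latent
#' values are roughly 2-fold higher in the surgery group, and two null
#' markers independent of the images.
#'
#' @param n_subjects even count >= 4, split into two equal groups
#'   (default 12).
#' @param image_size `(height, width)` in pixels (default `c(128, 128)`).
#' @param gamma_shape,gamma_scale gamma speckle-background parameters
#'   (defaults 4 and 16); draws are rounded and clipped to `[0, L]`.
#' @param n_bumps number of per-subject texture components (default 10).
#'   Each subject's histogram deviates from the shared gamma background by
#'   a random mixture of Gaussian intensity bumps (centers uniform on
#'   `[0, L]`, spread uniform on `bump_sd`), emulating between-animal
#'   echotexture heterogeneity; without it all subjects share one histogram
#'   and every intensity range carries the same information.
#' @param bump_frac fraction of pixels drawn from the subject's bump
#'   mixture rather than the gamma background (default 0.5).
#' @param bump_sd range of bump standard deviations in intensity units
#'   (default `c(5, 15)`).
#' @param planted_range inclusive `[lo, hi]` intensity range carrying the
#'   planted signal (default `c(86, 101)`).
#' @param coupling target correlation in `[0, 1]` between each coupled
#'   marker and the subject's in-range mean (default 0.9); 1 means an exact
#'   affine relation, 0 makes every marker independent of the images.
#' @param group_effect additive shift of the latent brightness value for
#'   the surgery group (default 1, roughly a 2-fold marker difference on
#'   the lognormal(0, 0.4) latent scale).
#' @param n_coupled_markers,n_null_markers marker counts (defaults 3 and 2,
#'   mirroring CaMKII/ERK1/2/substance P vs CGRP/PAR2).
#' @param latent_sdlog lognormal sdlog of the latent values (default 0.4).
#' @param pixel_gain intensity units of in-range brightening per unit of
#'   latent value (default 3).
#' @param plant_fraction fraction of each subject's in-range pixels that
#'   are brightened (default 0.5).
#' @param roi_margin inset of the octagonal ROI from the image border in
#'   pixels (default 4).
#' @param L intensity ceiling (default 255).
#' @param seed integer master seed; all randomness flows from it through
#'   named substreams (images/ROIs, latents, planting, marker noise).
#' @return a `synth_params` list.
#' @export
synth_params <- function(n_subjects = 12L, image_size = c(128L, 128L),
                         gamma_shape = 4, gamma_scale = 16,
                         n_bumps = 10L, bump_frac = 0.5, bump_sd = c(5, 15),
                         planted_range = c(86L, 101L), coupling = 0.9,
                         group_effect = 1, n_coupled_markers = 3L,
                         n_null_markers = 2L, latent_sdlog = 0.4,
                         pixel_gain = 3, plant_fraction = 0.5,
                         roi_margin = 4L, L = 255L, seed = 1L) {
  if (n_subjects < 4L || n_subjects %% 2L != 0L) {
    stop("n_subjects must be even and >= 4")
  }
  if (coupling < 0 || coupling > 1) stop("coupling must lie in [0, 1]")
  if (planted_range[1] < 0 || planted_range[2] > L ||
      planted_range[1] > planted_range[2]) {
    stop("planted_range must be an interval within [0, ", L, "]")
  }
  structure(
    list(n_subjects = as.integer(n_subjects),
         image_size = as.integer(image_size),
         gamma_shape = gamma_shape, gamma_scale = gamma_scale,
         n_bumps = as.integer(n_bumps), bump_frac = bump_frac,
         bump_sd = bump_sd,
         planted_range = as.integer(planted_range), coupling = coupling,
         group_effect = group_effect,
         n_coupled_markers = as.integer(n_coupled_markers),
         n_null_markers = as.integer(n_null_markers),
         latent_sdlog = latent_sdlog, pixel_gain = pixel_gain,
         plant_fraction = plant_fraction, roi_margin = as.integer(roi_margin),
         L = as.integer(L), seed = as.integer(seed)),
    class = "synth_params"
  )
}

# deterministic 31-bit substream seed derived from the master seed
substream_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k * 9973) %% 2147483647)
}

synth_marker_names <- function(params) {
  coupled <- if (params$n_coupled_markers == 3L) {
    c("CaMKII", "ERK12", "SubstanceP")
  } else if (params$n_coupled_markers > 0L) {
    paste0("coupled", seq_len(params$n_coupled_markers))
  } else character(0)
  null <- if (params$n_null_markers == 2L) {
    c("CGRP", "PAR2")
  } else if (params$n_null_markers > 0L) {
    paste0("null", seq_len(params$n_null_markers))
  } else character(0)
  list(coupled = coupled, null = null)
}

# octagonal ROI inset from the borders, with small per-subject jitter
synth_roi <- function(h, w, margin, jitter) {
  m <- margin
  cx <- floor(min(h, w) / 6)
  vx <- c(m + cx, w - 1 - m - cx, w - 1 - m, w - 1 - m,
          w - 1 - m - cx, m + cx, m, m)
  vy <- c(m, m, m + cx, h - 1 - m - cx,
          h - 1 - m, h - 1 - m, h - 1 - m - cx, m + cx)
  roi_polygon(cbind(vx + jitter[1:8], vy + jitter[9:16]))
}

#' Generate a synthetic speckle-image cohort
#'
#' Each subject receives a gamma-speckle image, an octagonal polygonal ROI,
#' coupled marker values and independent null markers. Coupling is planted
#' by brightening a random subset of in-range ROI pixels proportionally to
#' the subject's latent value (clamped to stay within the planted range),
#' then setting each coupled marker to the subject's realized in-range mean
#' plus independent measurement noise calibrated so the population
#' correlation matches the coupling target (`coupling = 1` gives an exact
#' affine relation; `coupling = 0` gives markers independent of pixels and
#' no planting effect on markers).
#'
#' Fully reproducible: the same `params$seed` yields identical output.
#'
#' @param params a [synth_params] object.
#' @return a `synth_cohort`: list with `cohort` (a [subject_cohort]),
#'   `images` (named list of [gray_image]), `rois` (named list of
#'   [roi_polygon]), `masks`, `truth` (planted range, latent values,
#'   in-range means, coupled-marker names, realized correlations), and
#'   `params`.
#' @export
generate_cohort <- function(params) {
  stopifnot(inherits(params, "synth_params"))
  h <- params$image_size[1]; w <- params$image_size[2]
  lo <- params$planted_range[1]; hi <- params$planted_range[2]
  n <- params$n_subjects
  mass <- stats::pgamma(hi + 0.5, params$gamma_shape,
                        scale = params$gamma_scale) -
    stats::pgamma(lo - 0.5, params$gamma_shape, scale = params$gamma_scale)
  if (mass < 1e-8) {
    stop("infeasible params: background model places no pixels in the ",
         "planted range [", lo, ", ", hi, "]")
  }
  ids <- sprintf("S%02d", seq_len(n))
  group <- rep(c("sham", "surgery"), each = n / 2L)
  nm <- synth_marker_names(params)

  # substream 1: images and ROI jitter
  set.seed(substream_seed(params$seed, 1L))
  images <- vector("list", n); rois <- vector("list", n)
  masks <- vector("list", n)
  for (s in seq_len(n)) {
    px <- stats::rgamma(h * w, shape = params$gamma_shape,
                        scale = params$gamma_scale)
    if (params$n_bumps > 0L && params$bump_frac > 0) {
      ctr <- stats::runif(params$n_bumps, 0, params$L)
      bsd <- stats::runif(params$n_bumps, params$bump_sd[1],
                          params$bump_sd[2])
      nb <- floor(params$bump_frac * h * w)
      k <- sample.int(params$n_bumps, nb, replace = TRUE)
      idx <- sample.int(h * w, nb)
      px[idx] <- stats::rnorm(nb, ctr[k], bsd[k])
    }
    px <- pmin(pmax(round_half_away(px), 0), params$L)
    images[[s]] <- gray_image(matrix(px, h, w), L = params$L)
    jit <- stats::runif(16, -params$roi_margin / 2, params$roi_margin / 2)
    rois[[s]] <- synth_roi(h, w, params$roi_margin, jit)
    masks[[s]] <- rasterize_roi(rois[[s]], w, h)
  }

  # substream 2: latent brightness values (group effect enters here)
  set.seed(substream_seed(params$seed, 2L))
  z <- stats::rlnorm(n, meanlog = 0, sdlog = params$latent_sdlog) +
    params$group_effect * (group == "surgery")

  # substream 3: planting — brighten a random subset of in-range ROI pixels
  set.seed(substream_seed(params$seed, 3L))
  if (params$coupling > 0) {
    for (s in seq_len(n)) {
      img <- unclass(images[[s]])
      inr <- which(unclass(masks[[s]]) & img >= lo & img <= hi)
      if (length(inr) == 0L) next
      k <- floor(params$plant_fraction * length(inr))
      if (k == 0L) next
      sel <- sample(inr, k)
      delta <- round_half_away(params$pixel_gain * z[s])
      img[sel] <- pmin(img[sel] + delta, hi)
      images[[s]] <- gray_image(img, L = params$L)
    }
  }
  samples <- lapply(seq_len(n), function(s) {
    extract_sample(images[[s]], masks[[s]], subject_id = ids[s])
  })
  mu <- vapply(samples, function(sm) range_mean(sm, lo, hi), numeric(1))
  if (all(is.na(mu))) {
    stop("infeasible params: no subject has pixels in the planted range")
  }

  # substream 4: marker values and measurement noise
  set.seed(substream_seed(params$seed, 4L))
  markers <- list()
  realized <- numeric(0)
  for (mk in nm$coupled) {
    if (params$coupling == 0) {
      markers[[mk]] <- stats::rlnorm(n, 0, params$latent_sdlog)
    } else if (params$coupling == 1) {
      markers[[mk]] <- mu
    } else {
      noise_sd <- stats::sd(mu) * sqrt(1 / params$coupling^2 - 1)
      markers[[mk]] <- mu + stats::rnorm(n, 0, noise_sd)
    }
    realized[mk] <- if (stats::var(mu, na.rm = TRUE) > 0 &&
                        stats::var(markers[[mk]]) > 0) {
      stats::cor(markers[[mk]], mu, use = "complete.obs")
    } else NA_real_
  }
  for (mk in nm$null) {
    markers[[mk]] <- stats::rlnorm(n, 0, params$latent_sdlog)
  }
  markers <- as.data.frame(markers)

  names(images) <- names(rois) <- names(masks) <- names(samples) <- ids
  cohort <- subject_cohort(samples, group, markers, L = params$L)
  truth <- list(planted_range = c(lo, hi), latent = stats::setNames(z, ids),
                in_range_means = stats::setNames(mu, ids),
                coupled_markers = nm$coupled, null_markers = nm$null,
                realized_correlation = realized)
  structure(list(cohort = cohort, images = images, rois = rois,
                 masks = masks, truth = truth, params = params),
            class = "synth_cohort")
}

#' Generate a null cohort (all couplings zero)
#'
#' Identical to [generate_cohort()] with `coupling` forced to 0: no marker
#' is related to the images.
#'
#' @param params a [synth_params] object.
#' @return a `synth_cohort`.
#' @export
generate_null_cohort <- function(params) {
  params$coupling <- 0
  generate_cohort(params)
}

#' Write a synthetic cohort to disk as a plain-file fixture
#'
#' Writes `<id>.png` images, `<id>_roi.json` ROI files, `cohort_cohort.csv`
#' / `cohort_pixels.csv` tables and `truth.json` into `dir` — the layout
#' [run_pipeline()] consumes.
#'
#' @param gen a `synth_cohort` from [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synth_fixture <- function(gen, dir) {
  stopifnot(inherits(gen, "synth_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(gen$images)) {
    write_gray_png(gen$images[[id]], file.path(dir, paste0(id, ".png")))
    write_roi_json(gen$rois[[id]], file.path(dir, paste0(id, "_roi.json")))
  }
  write_cohort_csv(gen$cohort, file.path(dir, "cohort"))
  tr <- gen$truth
  tr$latent <- as.list(tr$latent)
  tr$in_range_means <- as.list(tr$in_range_means)
  tr$realized_correlation <- as.list(tr$realized_correlation)
  jsonlite::write_json(tr, file.path(dir, "truth.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(dir)
}

#' Read the ground truth written by [write_synth_fixture()]
#'
#' @param dir fixture directory.
#' @return list mirroring the `truth` element of a `synth_cohort`.
#' @export
read_ground_truth <- function(dir) {
  tr <- jsonlite::fromJSON(file.path(dir, "truth.json"))
  tr$latent <- unlist(tr$latent)
  tr$in_range_means <- unlist(tr$in_range_means)
  tr$realized_correlation <- unlist(tr$realized_correlation)
  tr
}
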