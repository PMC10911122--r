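# End-to-end orchestration: normalize -> ROI stats -> band tables -> group
# comparisons -> range search -> permutation test -> threshold maps.

#' Assemble a pipeline configuration
#'
#' @param input_dir directory holding `<id>.png` (or `.tif`) images,
#'   `<id>_roi.json` ROI files and the `cohort_cohort.csv` /
#'   `cohort_pixels.csv`-style cohort table (only `cohort_cohort.csv` is
#'   required: pixels are re-extracted from the images).
#' @param out_dir output directory for the report bundle.
#' @param normalize_T normalization ceiling (default 255).
#' @param global_minmax normalize with cohort-wide extremes instead of
#'   per-image extremes (default FALSE).
#' @param band_preset `"bands50"` (default), `"bands25"`, or a [band_spec].
#' @param min_pixels,min_width range-search admissibility (see
#'   [range_constraints()]).
#' @param n_perm permutations for the family-wise test (default 199; 0
#'   disables it).
#' @param seed integer seed recorded in the manifest and used by the
#'   permutation test.
#' @param markers marker names to search (default: all cohort markers).
#' @param sd_type `"population"` (default) or `"sample"`.
#' @param write_threshold_maps write per-subject overlay PNGs for each
#'   selected range (default TRUE).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(input_dir, out_dir, normalize_T = 255L,
                            global_minmax = FALSE, band_preset = "bands50",
                            min_pixels = 1L, min_width = 1L, n_perm = 199L,
                            seed = 1L, markers = NULL,
                            sd_type = "population",
                            write_threshold_maps = TRUE) {
  structure(
    list(input_dir = input_dir, out_dir = out_dir,
         normalize_T = as.integer(normalize_T),
         global_minmax = isTRUE(global_minmax), band_preset = band_preset,
         min_pixels = as.integer(min_pixels),
         min_width = as.integer(min_width), n_perm = as.integer(n_perm),
         seed = as.integer(seed), markers = markers, sd_type = sd_type,
         write_threshold_maps = isTRUE(write_threshold_maps)),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match the arguments of
#'   [pipeline_config()].
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(pipeline_config, cfg)
}

resolve_band_spec <- function(band_preset) {
  if (inherits(band_preset, "band_spec")) return(band_preset)
  switch(band_preset,
         bands50 = bands50(),
         bands25 = bands25(),
         stop("unknown band preset: ", band_preset))
}

find_image_path <- function(dir, id) {
  for (ext in c(".png", ".tif", ".tiff")) {
    p <- file.path(dir, paste0(id, ext))
    if (file.exists(p)) return(p)
  }
  NA_character_
}

#' Validate pipeline inputs
#'
#' Checks that the cohort table, images and ROI files exist and agree,
#' that images are readable 8-bit rasters, that ROI vertices fall inside
#' the image bounds, and that no marker is constant.
#'
#' @param config a [pipeline_config].
#' @return character vector of diagnostics (empty when all checks pass);
#'   entries are prefixed `error:` or `warning:`.
#' @export
validate_inputs <- function(config) {
  diags <- character(0)
  ct_path <- file.path(config$input_dir, "cohort_cohort.csv")
  if (!file.exists(ct_path)) {
    return(paste0("error: cohort table not found: ", ct_path))
  }
  tab <- utils::read.csv(ct_path, check.names = FALSE)
  if (anyDuplicated(tab$subject_id)) {
    diags <- c(diags, "error: duplicate subject ids in cohort table")
  }
  for (id in tab$subject_id) {
    ip <- find_image_path(config$input_dir, id)
    if (is.na(ip)) {
      diags <- c(diags, paste0("error: no image for subject ", id))
    } else {
      img <- tryCatch(read_gray_image(ip), error = function(e) e)
      if (inherits(img, "error")) {
        diags <- c(diags,
                   paste0("error: unreadable image for ", id, ": ",
                          conditionMessage(img)))
        img <- NULL
      }
      rp <- file.path(config$input_dir, paste0(id, "_roi.json"))
      if (!file.exists(rp)) {
        diags <- c(diags, paste0("error: no ROI file for subject ", id))
      } else if (!is.null(img)) {
        poly <- tryCatch(read_roi_json(rp), error = function(e) e)
        if (inherits(poly, "error")) {
          diags <- c(diags, paste0("error: unreadable ROI for ", id))
        } else {
          v <- poly$vertices
          if (any(v[, 1] < -0.5 | v[, 1] > ncol(img) - 0.5 |
                  v[, 2] < -0.5 | v[, 2] > nrow(img) - 0.5)) {
            diags <- c(diags,
                       paste0("warning: ROI vertices outside image for ", id))
          }
        }
      }
    }
  }
  mk <- setdiff(colnames(tab), c("subject_id", "group"))
  for (m in mk) {
    if (stats::var(tab[[m]], na.rm = TRUE) == 0) {
      diags <- c(diags, paste0("warning: marker ", m, " is constant"))
    }
  }
  diags
}

# group comparison of one numeric variable across the two cohort groups;
# returns NA cells when the test is degenerate
compare_groups <- function(values, group) {
  lev <- unique(group)
  a <- values[group == lev[1]]; b <- values[group == lev[2]]
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  empty <- data.frame(group_a = lev[1], group_b = lev[2],
                      mean_a = NA_real_, sem_a = NA_real_,
                      mean_b = NA_real_, sem_b = NA_real_,
                      t = NA_real_, p = NA_real_,
                      n_a = length(a), n_b = length(b))
  if (length(a) < 2L || length(b) < 2L) return(empty)
  gc <- tryCatch(student_t_test(a, b), error = function(e) NULL)
  if (is.null(gc)) {
    empty$mean_a <- mean(a); empty$mean_b <- mean(b)
    return(empty)
  }
  data.frame(group_a = lev[1], group_b = lev[2],
             mean_a = gc$mean_a, sem_a = gc$sem_a,
             mean_b = gc$mean_b, sem_b = gc$sem_b,
             t = gc$t_statistic, p = gc$p_two_tailed,
             n_a = gc$n_a, n_b = gc$n_b)
}

# pairwise-complete Pearson r/p; NA when < 3 pairs or degenerate
safe_pearson <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3L || stats::var(x[ok]) == 0 || stats::var(y[ok]) == 0) {
    return(data.frame(r = NA_real_, p = NA_real_, n = sum(ok)))
  }
  cr <- pearson(x[ok], y[ok])
  data.frame(r = cr$r, p = cr$p_two_tailed, n = cr$n)
}

#' Group comparisons of band statistics
#'
#' For every band and metric (`ei_percent`, `npv`, `sd`), compares the two
#' groups with the pooled-variance Student t-test and reports group means
#' with SEM.
#'
#' @param band_table output of [cohort_band_table()].
#' @return data.frame, one row per band x metric.
#' @export
band_group_comparisons <- function(band_table) {
  bands <- unique(band_table[, c("band_lo", "band_hi")])
  out <- list()
  for (i in seq_len(nrow(bands))) {
    sel <- band_table$band_lo == bands$band_lo[i]
    for (metric in c("ei_percent", "npv", "sd")) {
      cmp <- compare_groups(band_table[[metric]][sel],
                            band_table$group[sel])
      out[[length(out) + 1L]] <- cbind(
        data.frame(band_lo = bands$band_lo[i], band_hi = bands$band_hi[i],
                   metric = metric),
        cmp)
    }
  }
  do.call(rbind, out)
}

#' Band-by-marker correlation table
#'
#' Pearson r and two-tailed p between each marker and each band's EI%, NPV
#' and SD across subjects (pairwise exclusion of subjects missing a band;
#' `NA` when fewer than 3 complete pairs remain).
#'
#' @param band_table output of [cohort_band_table()].
#' @param cohort the [subject_cohort] the table came from.
#' @return data.frame, one row per marker x band x metric.
#' @export
band_marker_correlations <- function(band_table, cohort) {
  bands <- unique(band_table[, c("band_lo", "band_hi")])
  out <- list()
  for (m in marker_names(cohort)) {
    y <- cohort$markers[[m]]
    for (i in seq_len(nrow(bands))) {
      sel <- band_table$band_lo == bands$band_lo[i]
      sub <- band_table[sel, ]
      sub <- sub[match(cohort$subject_id, sub$subject_id), ]
      for (metric in c("ei_percent", "npv", "sd")) {
        sp <- safe_pearson(sub[[metric]], y)
        out[[length(out) + 1L]] <- cbind(
          data.frame(marker = m, band_lo = bands$band_lo[i],
                     band_hi = bands$band_hi[i], metric = metric),
          sp)
      }
    }
  }
  do.call(rbind, out)
}

#' Run the full analysis pipeline
#'
#' Reads images, ROIs and the cohort table from `config$input_dir`,
#' normalizes each image, extracts ROI pixel samples, and writes a report
#' bundle to `config$out_dir`:
#' \describe{
#'   \item{roi_stats.csv}{whole-ROI first-order statistics per subject}
#'   \item{band_table.csv}{per subject x band EI%, NPV, SD}
#'   \item{band_group_comparisons.csv}{group means +/- SEM, t, p per band
#'     and metric}
#'   \item{band_marker_correlations.csv}{r, p per marker x band x metric}
#'   \item{range_search.csv}{selected range, r, naive and permutation p,
#'     and group comparisons of range NPV/EI%/SD per marker}
#'   \item{range_per_subject.csv}{per-subject in-range statistics for each
#'     selected range}
#'   \item{thresholds/<marker>_<subject>.png}{threshold-map overlays}
#'   \item{manifest.json}{config, seed and package version}
#' }
#' Missing statistics propagate as empty CSV cells, never zeros.
#'
#' @param config a [pipeline_config].
#' @return invisibly, a list with the in-memory results (`cohort`,
#'   `roi_stats`, `band_table`, `band_comparisons`, `band_correlations`,
#'   `searches`, `out_dir`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  diags <- validate_inputs(config)
  errs <- grep("^error:", diags, value = TRUE)
  if (length(errs)) {
    stop("input validation failed:\n", paste(errs, collapse = "\n"))
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  tab <- utils::read.csv(file.path(config$input_dir, "cohort_cohort.csv"),
                         check.names = FALSE)
  ids <- tab$subject_id
  message("stage: load+normalize (", length(ids), " subjects)")
  raw <- lapply(ids, function(id) {
    read_gray_image(find_image_path(config$input_dir, id))
  })
  gmin <- if (config$global_minmax) min(vapply(raw, min, 0L)) else NULL
  gmax <- if (config$global_minmax) max(vapply(raw, max, 0L)) else NULL
  images <- lapply(raw, normalize_image, T = config$normalize_T,
                   f_min = gmin, f_max = gmax)
  samples <- list()
  masks <- list()
  for (i in seq_along(ids)) {
    poly <- read_roi_json(file.path(config$input_dir,
                                    paste0(ids[i], "_roi.json")))
    masks[[i]] <- rasterize_roi(poly, ncol(images[[i]]), nrow(images[[i]]))
    samples[[i]] <- extract_sample(images[[i]], masks[[i]],
                                   subject_id = ids[i])
  }
  names(samples) <- ids
  markers <- tab[, setdiff(colnames(tab), c("subject_id", "group")),
                 drop = FALSE]
  cohort <- subject_cohort(samples, tab$group, markers,
                           L = config$normalize_T)

  message("stage: whole-ROI statistics")
  roi_stats <- cbind(
    data.frame(subject_id = ids, group = tab$group),
    do.call(rbind, lapply(samples, whole_roi_stats,
                          sd_type = config$sd_type)))
  rownames(roi_stats) <- NULL
  write_report_csv(roi_stats, file.path(config$out_dir, "roi_stats.csv"))

  message("stage: band tables")
  spec <- resolve_band_spec(config$band_preset)
  band_table <- cohort_band_table(cohort, spec, sd_type = config$sd_type)
  write_report_csv(band_table, file.path(config$out_dir, "band_table.csv"))
  band_cmp <- band_group_comparisons(band_table)
  write_report_csv(band_cmp,
                   file.path(config$out_dir, "band_group_comparisons.csv"))
  band_cor <- band_marker_correlations(band_table, cohort)
  write_report_csv(band_cor,
                   file.path(config$out_dir, "band_marker_correlations.csv"))

  mks <- config$markers
  if (is.null(mks)) mks <- marker_names(cohort)
  constraints <- range_constraints(config$min_pixels, config$min_width)
  search_rows <- list()
  per_subj_rows <- list()
  searches <- list()
  if (config$write_threshold_maps) {
    dir.create(file.path(config$out_dir, "thresholds"),
               showWarnings = FALSE)
  }
  for (m in mks) {
    message("stage: range search for ", m)
    res <- search_best_range(cohort, m, constraints)
    searches[[m]] <- res
    p_fwe <- NA_real_
    if (config$n_perm > 0L) {
      message("stage: permutation test for ", m,
              " (", config$n_perm, " permutations)")
      pt <- max_r_permutation_test(cohort, m, constraints,
                                   n_perm = config$n_perm,
                                   seed = config$seed)
      p_fwe <- pt$p_fwe
    }
    cmp_npv <- compare_groups(res$per_subject$mean, res$per_subject$group)
    cmp_ei <- compare_groups(res$per_subject$ei_percent,
                             res$per_subject$group)
    cmp_sd <- compare_groups(res$per_subject$sd, res$per_subject$group)
    search_rows[[m]] <- data.frame(
      marker = m, lo = res$lo, hi = res$hi, r = res$r,
      p_naive = res$p_naive, p_fwe = p_fwe,
      n_subjects_used = res$n_subjects_used,
      n_ranges_evaluated = res$n_ranges_evaluated,
      npv_mean_a = cmp_npv$mean_a, npv_sem_a = cmp_npv$sem_a,
      npv_mean_b = cmp_npv$mean_b, npv_sem_b = cmp_npv$sem_b,
      npv_t = cmp_npv$t, npv_p = cmp_npv$p,
      ei_t = cmp_ei$t, ei_p = cmp_ei$p,
      sd_t = cmp_sd$t, sd_p = cmp_sd$p)
    per_subj_rows[[m]] <- cbind(data.frame(marker = m), res$per_subject)
    if (config$write_threshold_maps) {
      for (i in seq_along(ids)) {
        tm <- threshold_map(images[[i]], masks[[i]], res$lo, res$hi)
        write_threshold_png(images[[i]], tm,
                            file.path(config$out_dir, "thresholds",
                                      paste0(m, "_", ids[i], ".png")))
      }
    }
  }
  search_tab <- do.call(rbind, search_rows)
  rownames(search_tab) <- NULL
  write_report_csv(search_tab, file.path(config$out_dir, "range_search.csv"))
  per_subj <- do.call(rbind, per_subj_rows)
  rownames(per_subj) <- NULL
  write_report_csv(per_subj,
                   file.path(config$out_dir, "range_per_subject.csv"))

  manifest <- list(
    package = "echorange",
    version = as.character(utils::packageVersion("echorange")),
    seed = config$seed,
    config = unclass(config)[setdiff(names(config), "band_preset")],
    band_preset = if (inherits(config$band_preset, "band_spec")) {
      list(lo = config$band_preset$lo, hi = config$band_preset$hi)
    } else config$band_preset,
    n_subjects = length(ids),
    n_pixels = sum(lengths(cohort$samples)),
    markers = mks
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  invisible(list(cohort = cohort, roi_stats = roi_stats,
                 band_table = band_table, band_comparisons = band_cmp,
                 band_correlations = band_cor, searches = searches,
                 search_table = search_tab, out_dir = config$out_dir))
}

# CSV writer used for all report tables: missing cells become empty strings
write_report_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}
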