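# The subject cohort container: per-subject pixel samples, group labels and
# output-variable (marker) values.

#' Construct a subject cohort
#'
#' @param samples named list of [pixel_sample]s (or integer vectors), one per
#'   subject; names are the subject ids.
#' @param group character/factor of group labels (e.g., "sham"/"surgery"),
#'   one per subject.
#' @param markers data.frame of numeric output variables (one column per
#'   marker, one row per subject, same order as `samples`).
#' @param L intensity ceiling (default 255).
#' @return a `subject_cohort`: list with `subject_id`, `group`, `samples`
#'   (named list of integer vectors), `markers`, `L`.
#' @export
subject_cohort <- function(samples, group, markers, L = 255L) {
  ids <- names(samples)
  if (is.null(ids) || any(ids == "") || anyDuplicated(ids)) {
    stop("`samples` must be a named list with unique subject ids")
  }
  n <- length(samples)
  if (n < 3L) stop("a cohort needs at least 3 subjects")
  if (length(group) != n) stop("one group label per subject required")
  if (!is.data.frame(markers) || nrow(markers) != n) {
    stop("`markers` must be a data.frame with one row per subject")
  }
  vals <- lapply(samples, as_pixel_values)
  for (v in vals) {
    if (length(v) == 0L) stop("every subject needs a nonempty pixel sample")
    if (any(v < 0L) || any(v > L)) stop("pixel values out of [0, ", L, "]")
  }
  rownames(markers) <- ids
  structure(
    list(subject_id = ids, group = as.character(group), samples = vals,
         markers = markers, L = as.integer(L)),
    class = "subject_cohort"
  )
}

#' @export
print.subject_cohort <- function(x, ...) {
  cat(sprintf("<subject_cohort: %d subjects (%s), %d markers, L = %d>\n",
              length(x$subject_id),
              paste(sprintf("%d %s", table(x$group), names(table(x$group))),
                    collapse = ", "),
              ncol(x$markers), x$L))
  invisible(x)
}

#' Marker names of a cohort
#' @param cohort a [subject_cohort].
#' @return character vector.
#' @export
marker_names <- function(cohort) colnames(cohort$markers)

#' Write cohort tables to CSV
#'
#' Writes two files: `<stem>_cohort.csv` (subject_id, group, marker columns)
#' and `<stem>_pixels.csv` (long format: subject_id, value).
#'
#' @param cohort a [subject_cohort].
#' @param stem output path stem.
#' @return paths written, invisibly.
#' @export
write_cohort_csv <- function(cohort, stem) {
  tab <- cbind(data.frame(subject_id = cohort$subject_id,
                          group = cohort$group),
               cohort$markers)
  p1 <- paste0(stem, "_cohort.csv")
  utils::write.csv(tab, p1, row.names = FALSE)
  px <- data.frame(
    subject_id = rep(cohort$subject_id, lengths(cohort$samples)),
    value = unlist(cohort$samples, use.names = FALSE)
  )
  p2 <- paste0(stem, "_pixels.csv")
  utils::write.csv(px, p2, row.names = FALSE)
  invisible(c(p1, p2))
}

#' Read a cohort from the CSV pair written by [write_cohort_csv()]
#'
#' @param stem path stem used when writing.
#' @param L intensity ceiling (default 255).
#' @return a [subject_cohort].
#' @export
read_cohort_csv <- function(stem, L = 255L) {
  tab <- utils::read.csv(paste0(stem, "_cohort.csv"), check.names = FALSE)
  px <- utils::read.csv(paste0(stem, "_pixels.csv"))
  samples <- split(as.integer(px$value), factor(px$subject_id, levels = tab$subject_id))
  markers <- tab[, setdiff(colnames(tab), c("subject_id", "group")), drop = FALSE]
  subject_cohort(samples, tab$group, markers, L = L)
}
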