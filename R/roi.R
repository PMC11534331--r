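## Atlas-based aggregation and age-group / sex summaries.

#' Named region set over an integer atlas
#'
#' @param atlas 3-D integer label volume (0 = background).
#' @param labels named integer vector mapping region names to labels.
#'   Defaults to the 14-region cortical/subcortical set used throughout
#'   the lifespan analysis.
#' @return A `roi_set` object.
#' @export
roi_set <- function(atlas, labels = default_roi_labels()) {
  if (any(labels <= 0)) stop("labels must be positive", call. = FALSE)
  if (anyDuplicated(labels)) stop("labels must be unique", call. = FALSE)
  if (is.null(names(labels)) || any(!nzchar(names(labels))))
    stop("labels must be named", call. = FALSE)
  present <- labels %in% unique(as.integer(atlas))
  if (!all(present))
    stop("empty regions in atlas: ",
         paste(names(labels)[!present], collapse = ", "), call. = FALSE)
  structure(list(atlas = atlas, labels = labels), class = "roi_set")
}

#' @rdname roi_set
#' @export
default_roi_labels <- function() {
  stats::setNames(1:14,
    c("GM", "WM", "frontal", "temporal", "parietal", "ACC", "PCC",
      "precuneus", "caudate", "putamen", "amygdala", "hippocampus",
      "PHG", "MTL"))
}

#' Region means of a parameter map
#'
#' (Optionally weighted) mean over finite voxels of each named region.
#'
#' @param map 3-D numeric array aligned with the atlas.
#' @param roiset a [roi_set()].
#' @param weights optional nonnegative 3-D weight field (e.g. gray-matter
#'   density); a region whose finite voxels carry zero total weight is
#'   reported missing.
#' @return named numeric vector, one value per region.
#' @export
extract_roi_means <- function(map, roiset, weights = NULL) {
  stopifnot(inherits(roiset, "roi_set"))
  if (!all(dim(map) == dim(roiset$atlas)))
    stop("map and atlas must share a grid", call. = FALSE)
  if (!is.null(weights) && !all(dim(weights) == dim(map)))
    stop("weights grid mismatch", call. = FALSE)
  vapply(roiset$labels, function(lab) {
    sel <- roiset$atlas == lab & is.finite(map)
    if (!any(sel)) return(NA_real_)
    if (is.null(weights)) return(mean(map[sel]))
    w <- weights[sel]
    if (sum(w) <= 0) return(NA_real_)
    sum(map[sel] * w) / sum(w)
  }, numeric(1))
}

#' Assemble the cohort table
#'
#' Strict join of per-subject regional feature values onto a demographics
#' table by `subject_id`; any unmatched id on either side is an error.
#'
#' @param features `data.frame` with a `subject_id` column and one column
#'   per regional feature (e.g. `kw_GM`, `cbf_GM`, ...).
#' @param demographics `data.frame` with columns `subject_id`, `age`,
#'   `sex` (`"M"`/`"F"`), and optionally `race`, `icv`, `gm_density`.
#' @param units optional named character vector of unit tags to attach.
#' @return the joined cohort `data.frame` with a `units` attribute.
#' @export
build_cohort_table <- function(features, demographics, units = NULL) {
  for (d in list(features, demographics))
    if (!"subject_id" %in% names(d))
      stop("both tables need a subject_id column", call. = FALSE)
  if (anyDuplicated(demographics$subject_id) ||
      anyDuplicated(features$subject_id))
    stop("duplicate subject_id", call. = FALSE)
  only_f <- setdiff(features$subject_id, demographics$subject_id)
  only_d <- setdiff(demographics$subject_id, features$subject_id)
  if (length(only_f) || length(only_d))
    stop("unmatched subject ids; features-only: [",
         paste(only_f, collapse = ", "), "], demographics-only: [",
         paste(only_d, collapse = ", "), "]", call. = FALSE)
  out <- merge(demographics, features, by = "subject_id", sort = TRUE)
  base_units <- c(subject_id = "", age = "years", sex = "", race = "",
                  icv = "ml", gm_density = "")
  u <- stats::setNames(rep("", ncol(out)), names(out))
  hit <- intersect(names(u), names(base_units))
  u[hit] <- base_units[hit]
  if (!is.null(units)) u[names(units)] <- units
  attr(out, "units") <- u
  out
}

#' Default lifespan age bins
#'
#' Half-open bins `[8, 36)`, `[36, 62)`, `[62, 93)` — i.e. age groups
#' 8-35, 36-61 and 62-92 years.
#' @return numeric vector of bin edges.
#' @export
default_age_bins <- function() c(8, 36, 62, 93)

.bin_labels <- function(edges) {
  paste0(edges[-length(edges)], "-", edges[-1] - 1)
}

#' Assign ages to bins
#' @param age numeric ages, years.
#' @param edges bin edges as in [default_age_bins()].
#' @return factor of bin labels.
#' @export
age_bin <- function(age, edges = default_age_bins()) {
  cut(age, breaks = edges, right = FALSE, labels = .bin_labels(edges))
}

#' Relative sex difference, percent
#'
#' Reported as `(female - male) / female * 100`, rounded half away from
#' zero to one decimal, matching the convention used for group-mean
#' comparisons (positive = lower male values).
#'
#' @param f_mean,m_mean female and male group means.
#' @return percent difference, one decimal.
#' @export
sex_difference_percent <- function(f_mean, m_mean) {
  round_half_away((f_mean - m_mean) / f_mean * 100, 1)
}

#' Age-group and sex summary of cohort features
#'
#' Mean, SD (n-1 denominator) and count per age bin and sex for each
#' feature, one-way ANOVA across sexes within each bin, and the relative
#' sex difference of the bin means.
#'
#' @param cohort cohort `data.frame` with `age`, `sex` and feature columns.
#' @param features character vector of feature column names; default all
#'   numeric columns except demographics.
#' @param age_bins bin edges, see [default_age_bins()].
#' @return A `group_summary` object: `$cells` (bin x sex x feature means,
#'   SDs, counts), `$tests` (per bin x feature F statistic, p value and
#'   percent sex difference).
#' @export
group_summary <- function(cohort, features = NULL,
                          age_bins = default_age_bins()) {
  if (is.null(features)) {
    skip <- c("subject_id", "age", "sex", "race", "icv", "gm_density")
    features <- setdiff(names(cohort)[vapply(cohort, is.numeric, TRUE)],
                        skip)
  }
  if (any(cohort$age < age_bins[1] | cohort$age >= age_bins[length(age_bins)]))
    stop("ages outside the bin range", call. = FALSE)
  bin <- age_bin(cohort$age, age_bins)
  cells <- expand.grid(bin = levels(bin), sex = c("M", "F"),
                       feature = features, stringsAsFactors = FALSE)
  stat <- function(b, s, f, fun) {
    v <- cohort[[f]][bin == b & cohort$sex == s]
    v <- v[is.finite(v)]
    fun(v)
  }
  cells$n <- mapply(function(b, s, f) stat(b, s, f, length),
                    cells$bin, cells$sex, cells$feature)
  cells$mean <- mapply(function(b, s, f) stat(b, s, f, mean),
                       cells$bin, cells$sex, cells$feature)
  cells$sd <- mapply(function(b, s, f)
    stat(b, s, f, function(v) if (length(v) >= 2) stats::sd(v) else NA_real_),
    cells$bin, cells$sex, cells$feature)

  tests <- expand.grid(bin = levels(bin), feature = features,
                       stringsAsFactors = FALSE)
  fp <- mapply(function(b, f) {
    v <- cohort[[f]][bin == b]
    s <- cohort$sex[bin == b]
    ok <- is.finite(v)
    v <- v[ok]; s <- s[ok]
    if (length(unique(s)) < 2L || min(table(s)) < 2L)
      return(c(NA_real_, NA_real_))
    if (stats::var(v) == 0) return(c(0, 1))
    a <- stats::oneway.test(v ~ factor(s), var.equal = TRUE)
    c(unname(a$statistic), unname(a$p.value))
  }, tests$bin, tests$feature)
  tests$F <- fp[1, ]
  tests$p <- fp[2, ]
  tests$sex_diff_pct <- mapply(function(b, f) {
    fm <- cells$mean[cells$bin == b & cells$sex == "F" &
                       cells$feature == f]
    mm <- cells$mean[cells$bin == b & cells$sex == "M" &
                       cells$feature == f]
    if (!is.finite(fm) || !is.finite(mm)) return(NA_real_)
    sex_difference_percent(fm, mm)
  }, tests$bin, tests$feature)

  structure(list(cells = cells, tests = tests, age_bins = age_bins),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, digits = 1, ...) {
  cat("Age-group x sex summary\n")
  for (f in unique(x$cells$feature)) {
    cat("\n", f, ":\n", sep = "")
    sub <- x$cells[x$cells$feature == f, ]
    for (b in unique(sub$bin)) {
      row <- function(s) sub[sub$bin == b & sub$sex == s, ]
      m <- row("M"); fe <- row("F")
      tst <- x$tests[x$tests$bin == b & x$tests$feature == f, ]
      cat(sprintf(
        "  %-7s M %6.1f+-%-5.1f (n=%2d)  F %6.1f+-%-5.1f (n=%2d)  d%%=%5.1f  F=%.3g p=%.3g\n",
        b, m$mean, m$sd, m$n, fe$mean, fe$sd, fe$n,
        tst$sex_diff_pct, tst$F, tst$p))
    }
  }
  invisible(x)
}
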