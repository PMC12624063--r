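#' Grade scales
#'
#' The Fazekas scale rates periventricular and deep white matter
#' hyperintensities on 4 grades (0-3); the Brain Dock scale used in Japanese
#' brain screening is a 5-grade (0-4) variant that splits the most severe
#' Fazekas grade in two.
#'
#' @param name `"fazekas"` or `"braindock"`.
#' @return An object of class `grade_scale` with `name` and `grades`
#'   (contiguous integers from 0).
#' @export
grade_scale <- function(name = c("fazekas", "braindock")) {
  name <- match.arg(name)
  grades <- if (name == "fazekas") 0:3 else 0:4
  structure(list(name = name, grades = grades), class = "grade_scale")
}

#' Merge Brain Dock grades onto the Fazekas scale
#'
#' Brain Dock grades 3 and 4 are merged to Fazekas grade 3; grades 0-2 map to
#' themselves.
#'
#' @param grade Integer vector of Brain Dock grades in 0..4.
#' @return Integer vector of Fazekas grades in 0..3.
#' @export
braindock_to_fazekas <- function(grade) {
  if (any(!grade %in% 0:4)) stop("Brain Dock grades must lie in 0..4")
  as.integer(pmin(grade, 3L))
}

new_threshold_set <- function(thresholds, scale, lesion_type, method) {
  stopifnot(inherits(scale, "grade_scale"),
            lesion_type %in% c("PVH", "DWMH"),
            length(thresholds) == length(scale$grades) - 1L)
  structure(
    list(thresholds = as.numeric(thresholds), scale = scale,
         lesion_type = lesion_type, method = method),
    class = "threshold_set"
  )
}

#' Construct a grade-boundary threshold set
#'
#' @param thresholds Numeric vector of G-1 non-decreasing boundary thresholds
#'   on the volume-ratio axis (boundary g|g+1 at position g+1).
#' @param scale A [grade_scale()].
#' @param lesion_type `"PVH"` or `"DWMH"`.
#' @param method Label of the fitting method.
#' @return An object of class `threshold_set`.
#' @export
threshold_set <- function(thresholds, scale = grade_scale("fazekas"),
                          lesion_type = "PVH", method = "manual") {
  if (is.unsorted(thresholds)) stop("thresholds must be non-decreasing")
  new_threshold_set(thresholds, scale, lesion_type, method)
}

#' @export
print.threshold_set <- function(x, ...) {
  cat(sprintf("<threshold_set> %s %s (%s): %s\n", x$scale$name,
              x$lesion_type, x$method,
              paste(format(x$thresholds, digits = 5), collapse = ", ")))
  invisible(x)
}

#' Published Fazekas volume-ratio thresholds
#'
#' Default grade-boundary thresholds for the Fazekas scale obtained with the
#' Youden-neighbor strategy on a 137-subject graded training cohort: PVH
#' 0.00017 (0-1), 0.00402 (1-2), 0.00977 (2-3); DWMH 0.00013 (0-1), 0.00179
#' (1-2), 0.00743 (2-3). They make the grading pipeline usable without local
#' training data.
#'
#' @param lesion_type `"PVH"` or `"DWMH"`.
#' @return A [threshold_set()] on the Fazekas scale.
#' @export
default_thresholds <- function(lesion_type = c("PVH", "DWMH")) {
  lesion_type <- match.arg(lesion_type)
  th <- if (lesion_type == "PVH") c(0.00017, 0.00402, 0.00977)
  else c(0.00013, 0.00179, 0.00743)
  new_threshold_set(th, grade_scale("fazekas"), lesion_type,
                    "youden_neighbor (published defaults)")
}

check_training <- function(ratio, grade, scale, min_per_grade = 1L) {
  stopifnot(length(ratio) == length(grade), all(ratio >= 0))
  if (any(!grade %in% scale$grades)) {
    stop("grades outside the ", scale$name, " scale")
  }
  counts <- table(factor(grade, levels = scale$grades))
  missing <- scale$grades[counts < min_per_grade]
  if (length(missing) > 0) {
    stop("grade(s) ", paste(missing, collapse = ", "),
         " have fewer than ", min_per_grade, " training subjects")
  }
  invisible(counts)
}

#' Fit thresholds from per-grade density peaks
#'
#' Estimates the volume-ratio density of each grade by Gaussian kernel
#' density estimation and places the boundary threshold g|g+1 at the
#' arithmetic midpoint of the grade-g and grade-(g+1) density peaks. The
#' bandwidth is Silverman's rule of thumb with a floor of 1e-6 so that
#' near-constant samples still yield a usable (sharply peaked) density; peaks
#' are located by argmax on a 2048-point uniform grid over
#' [0, 1.05 * max(ratio)]. If the peaks are not monotone in grade the sorted
#' thresholds are returned with a warning.
#'
#' @param ratio Numeric vector of volume ratios (>= 0).
#' @param grade Integer vector of grades, same length.
#' @param scale A [grade_scale()]; every grade must have >= 2 subjects.
#' @param lesion_type `"PVH"` or `"DWMH"` (label only).
#' @return A `threshold_set` with attached `density_model`: per-grade list of
#'   `x`, `y` (density on the grid), `peak`, `bandwidth`.
#' @export
fit_thresholds_density <- function(ratio, grade, scale = grade_scale("fazekas"),
                                   lesion_type = "PVH") {
  check_training(ratio, grade, scale, min_per_grade = 2L)
  grid_max <- 1.05 * max(ratio)
  if (grid_max <= 0) grid_max <- 1e-6
  model <- lapply(scale$grades, function(g) {
    x <- ratio[grade == g]
    bw <- stats::bw.nrd0(x)
    bw <- max(bw, 1e-6)
    dens <- stats::density(x, bw = bw, from = 0, to = grid_max, n = 2048)
    list(grade = g, x = dens$x, y = dens$y, peak = dens$x[which.max(dens$y)],
         bandwidth = bw)
  })
  peaks <- vapply(model, `[[`, numeric(1), "peak")
  th <- (peaks[-1] + peaks[-length(peaks)]) / 2
  if (is.unsorted(th)) {
    warning("density peaks are non-monotone in grade; thresholds sorted")
    th <- sort(th)
  }
  out <- new_threshold_set(th, scale, lesion_type, "density")
  out$density_model <- model
  out
}

# exhaustive ROC over midpoint candidates for one binary boundary;
# positive call is ratio >= threshold
youden_scan <- function(neg, pos) {
  pooled <- sort(unique(c(neg, pos)))
  cand <- if (length(pooled) > 1) {
    (pooled[-1] + pooled[-length(pooled)]) / 2
  } else numeric()
  cand <- c(pooled[1] - max(1e-8, 1e-6 * abs(pooled[1])), cand)
  sens <- vapply(cand, function(t) mean(pos >= t), numeric(1))
  spec <- vapply(cand, function(t) mean(neg < t), numeric(1))
  j <- sens + spec - 1
  # max J; ties broken by higher sensitivity, then smaller threshold
  best <- order(-j, -sens, cand)[1]
  list(candidates = cand, sensitivity = sens, specificity = spec, j = j,
       chosen = cand[best], chosen_j = j[best],
       chosen_sensitivity = sens[best], chosen_specificity = spec[best])
}

#' Fit thresholds by Youden-index maximization
#'
#' Treats each grade boundary g|g+1 as a binary classification and chooses
#' the volume-ratio cutoff maximizing Youden's J = sensitivity +
#' specificity - 1. Two strategies: `"all"` groups every grade on each side
#' of the boundary (negatives: grades <= g, positives: grades >= g+1);
#' `"neighbor"` uses only the two adjacent grades. Candidate cutoffs are the
#' midpoints between consecutive distinct pooled ratios plus a sentinel below
#' the minimum, so the scan is exhaustive over all distinct confusion tables;
#' a subject is called positive when its ratio is >= the cutoff. Ties in J
#' are broken by higher sensitivity, then by the smaller cutoff.
#'
#' @param ratio Numeric vector of volume ratios (>= 0).
#' @param grade Integer vector of grades, same length.
#' @param scale A [grade_scale()].
#' @param strategy `"neighbor"` (default) or `"all"`.
#' @param lesion_type `"PVH"` or `"DWMH"` (label only).
#' @return A `threshold_set` with attached `roc`, one [youden_scan] record
#'   per boundary.
#' @export
fit_thresholds_youden <- function(ratio, grade, scale = grade_scale("fazekas"),
                                  strategy = c("neighbor", "all"),
                                  lesion_type = "PVH") {
  strategy <- match.arg(strategy)
  check_training(ratio, grade, scale, min_per_grade = 1L)
  gmax <- max(scale$grades)
  roc <- lapply(scale$grades[-length(scale$grades)], function(g) {
    if (strategy == "all") {
      neg <- ratio[grade <= g]
      pos <- ratio[grade >= g + 1]
    } else {
      neg <- ratio[grade == g]
      pos <- ratio[grade == g + 1]
    }
    if (length(neg) == 0 || length(pos) == 0) {
      stop("boundary ", g, "|", g + 1, " has an empty side under strategy '",
           strategy, "'")
    }
    c(list(boundary = g), youden_scan(neg, pos))
  })
  th <- vapply(roc, `[[`, numeric(1), "chosen")
  if (is.unsorted(th)) {
    warning("fitted thresholds are non-monotone across boundaries; sorted")
    th <- sort(th)
  }
  out <- new_threshold_set(th, scale, lesion_type,
                           paste0("youden_", strategy))
  out$roc <- roc
  out
}

#' Predict a grade from a volume ratio
#'
#' The grade is the number of boundary thresholds at or below the ratio:
#' thresholds act as inclusive lower bounds of the upper grade, so a ratio
#' exactly equal to a threshold receives the higher grade (the ROC
#' positive-call convention).
#'
#' @param ratio Numeric vector of volume ratios (>= 0).
#' @param thresholds A `threshold_set`.
#' @return Integer vector of grades on the threshold set's scale.
#' @examples
#' predict_grade(0.005, default_thresholds("PVH"))  # grade 2
#' @export
predict_grade <- function(ratio, thresholds) {
  stopifnot(inherits(thresholds, "threshold_set"))
  if (any(!is.finite(ratio)) || any(ratio < 0)) {
    stop("volume ratios must be finite and >= 0")
  }
  vapply(ratio, function(r) sum(r >= thresholds$thresholds), numeric(1)) |>
    as.integer()
}
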