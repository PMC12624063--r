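#' Dichotomize grades at a boundary
#'
#' Boundary g splits the scale into grades <= g (negative) and grades >= g+1
#' (positive): on the Fazekas scale boundary 0 is 0 vs 1/2/3, boundary 1 is
#' 0/1 vs 2/3, boundary 2 is 0/1/2 vs 3; the Brain Dock scale has a fourth
#' boundary 0/1/2/3 vs 4. This mirrors the clinical reading of whether a
#' subject lies above a diagnostic severity cut.
#'
#' @param grade Integer vector of grades on `scale`.
#' @param boundary Boundary index g with 0 <= g < G-1.
#' @param scale A [grade_scale()].
#' @return Logical vector, `TRUE` for the upper-grade (positive) group.
#' @export
boundary_split <- function(grade, boundary, scale = grade_scale("fazekas")) {
  if (any(!grade %in% scale$grades)) {
    stop("grades outside the ", scale$name, " scale")
  }
  if (length(boundary) != 1L || !boundary %in%
      scale$grades[-length(scale$grades)]) {
    stop("`boundary` must be an integer in 0..", max(scale$grades) - 1)
  }
  grade >= boundary + 1
}

#' Binary accuracy and F1
#'
#' F1 is computed for the positive (upper-grade) class and defined as 0 when
#' precision + recall is 0 (no true or predicted positives).
#'
#' @param gt,pred Logical vectors of equal length >= 1.
#' @return Named list `accuracy`, `f1`.
#' @export
binary_metrics <- function(gt, pred) {
  stopifnot(is.logical(gt), is.logical(pred))
  if (length(gt) != length(pred) || length(gt) == 0) {
    stop("`gt` and `pred` must have equal positive length")
  }
  tp <- sum(gt & pred); fp <- sum(!gt & pred); fn <- sum(gt & !pred)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  list(accuracy = mean(gt == pred), f1 = f1)
}

#' Multi-class accuracy, macro F1 and MAE
#'
#' Macro F1 averages per-grade F1 over the grades present in the union of
#' ground truth and prediction (absent grades are excluded rather than
#' counted as 0). MAE is the mean absolute difference of integer grades, so
#' it is computed on whichever scale the grades live on.
#'
#' @param gt,pred Integer grade vectors of equal length on `scale`.
#' @param scale A [grade_scale()].
#' @return Named list `accuracy`, `macro_f1`, `mae`.
#' @export
multiclass_metrics <- function(gt, pred, scale = grade_scale("fazekas")) {
  if (length(gt) != length(pred) || length(gt) == 0) {
    stop("`gt` and `pred` must have equal positive length")
  }
  if (any(!c(gt, pred) %in% scale$grades)) {
    stop("grades outside the ", scale$name, " scale")
  }
  present <- sort(unique(c(gt, pred)))
  f1s <- vapply(present, function(g) {
    binary_metrics(gt == g, pred == g)$f1
  }, numeric(1))
  list(accuracy = mean(gt == pred), macro_f1 = mean(f1s),
       mae = mean(abs(pred - gt)))
}

#' Cohen's kappa between two raters
#'
#' Chance-corrected agreement kappa = (p_o - p_e) / (1 - p_e), with observed
#' agreement p_o and chance agreement p_e from the product of the two raters'
#' marginal category frequencies. When both raters use a single identical
#' category (p_e = 1 with perfect agreement) kappa is returned as 1.
#'
#' @param a,b Vectors of ordinal grades, equal length >= 1.
#' @return Scalar kappa in [-1, 1].
#' @export
cohen_kappa <- function(a, b) {
  if (length(a) != length(b) || length(a) == 0) {
    stop("`a` and `b` must have equal positive length")
  }
  cats <- sort(unique(c(a, b)))
  pa <- as.vector(table(factor(a, cats))) / length(a)
  pb <- as.vector(table(factor(b, cats))) / length(b)
  po <- mean(a == b)
  pe <- sum(pa * pb)
  if (abs(1 - pe) < 1e-15) {
    return(if (po == 1) 1 else NaN)
  }
  (po - pe) / (1 - pe)
}

#' Fleiss' kappa for a fixed rater panel
#'
#' Standard Fleiss formulation for n subjects each rated by the same m >= 2
#' raters: per-subject agreement P_i from the category counts, overall
#' observed agreement as the mean P_i, and chance agreement from pooled
#' category proportions. Degenerate input in which every rating is a single
#' category has chance agreement 1; kappa is then undefined and returned as
#' NaN with a warning.
#'
#' @param ratings Matrix or data.frame, subjects in rows, raters in columns,
#'   no missing entries.
#' @return Scalar kappa in [-1, 1], or NaN for the degenerate case.
#' @export
fleiss_kappa <- function(ratings) {
  ratings <- as.matrix(ratings)
  if (any(is.na(ratings))) stop("rating matrix must be complete")
  n <- nrow(ratings); m <- ncol(ratings)
  if (n < 2 || m < 2) stop("need >= 2 subjects and >= 2 raters")
  cats <- sort(unique(as.vector(ratings)))
  counts <- t(apply(ratings, 1, function(r) {
    as.vector(table(factor(r, levels = cats)))
  }))
  if (length(cats) == 1L) counts <- matrix(m, nrow = n, ncol = 1)
  p_i <- (rowSums(counts^2) - m) / (m * (m - 1))
  p_bar <- mean(p_i)
  p_j <- colSums(counts) / (n * m)
  p_e <- sum(p_j^2)
  if (abs(1 - p_e) < 1e-15) {
    warning("all ratings share one category; Fleiss' kappa undefined")
    return(NaN)
  }
  (p_bar - p_e) / (1 - p_e)
}

#' Full grading performance report
#'
#' Produces the standard evaluation layout for automated grading against a
#' reference: per-boundary binary accuracy and F1 at every grade boundary of
#' the scale, plus multi-class accuracy, macro F1 and MAE, for each supplied
#' prediction source (e.g. an automated grader and a human expert).
#'
#' @param gt Integer vector of reference grades.
#' @param predictions Named list of integer grade vectors aligned with `gt`
#'   (e.g. `list(ai = ..., human = ...)`).
#' @param scale A [grade_scale()].
#' @return data.frame with one row per prediction source: boundary accuracy
#'   columns (`acc_0v1`, ...), boundary F1 columns, `multiclass_accuracy`,
#'   `multiclass_f1` (macro), `mae`.
#' @export
grading_report <- function(gt, predictions, scale = grade_scale("fazekas")) {
  stopifnot(is.list(predictions), length(predictions) >= 1,
            !is.null(names(predictions)))
  boundaries <- scale$grades[-length(scale$grades)]
  rows <- lapply(names(predictions), function(nm) {
    pred <- predictions[[nm]]
    per_b <- lapply(boundaries, function(g) {
      binary_metrics(boundary_split(gt, g, scale),
                     boundary_split(pred, g, scale))
    })
    mc <- multiclass_metrics(gt, pred, scale)
    row <- c(
      stats::setNames(vapply(per_b, `[[`, numeric(1), "accuracy"),
                      sprintf("acc_%dv%d", boundaries, boundaries + 1)),
      stats::setNames(vapply(per_b, `[[`, numeric(1), "f1"),
                      sprintf("f1_%dv%d", boundaries, boundaries + 1)),
      multiclass_accuracy = mc$accuracy,
      multiclass_f1 = mc$macro_f1,
      mae = mc$mae
    )
    cbind(data.frame(source = nm), as.data.frame(as.list(row)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Inter-rater agreement report
#'
#' Fleiss' kappa over a panel of human raters plus Cohen's kappa between an
#' automated grader and each human rater, with their mean.
#'
#' @param ratings Subjects x raters matrix (or data.frame) of human grades.
#' @param ai Integer vector of automated grades aligned with the rows.
#' @return List with `fleiss_kappa`, `cohen_kappa` (named per rater), and
#'   `mean_cohen_kappa`.
#' @export
agreement_report <- function(ratings, ai) {
  ratings <- as.matrix(ratings)
  stopifnot(length(ai) == nrow(ratings))
  ck <- vapply(seq_len(ncol(ratings)), function(j) {
    cohen_kappa(ai, ratings[, j])
  }, numeric(1))
  names(ck) <- colnames(ratings) %||% paste0("rater", seq_len(ncol(ratings)))
  list(fleiss_kappa = fleiss_kappa(ratings), cohen_kappa = ck,
       mean_cohen_kappa = mean(ck))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
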