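# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths: distances are computed point-to-point
# in mm, metrics by explicit loops over confusion cells.

# anisotropic Euclidean distance (mm) from every voxel center to the nearest
# foreground voxel center; O(grid x foreground), fine at test scale
oracle_distance_map <- function(mask, spacing) {
  shape <- dim(mask)
  ax <- lapply(1:3, function(a) (seq_len(shape[a]) - 1) * spacing[a])
  fg <- which(mask, arr.ind = TRUE)
  stopifnot(nrow(fg) > 0)
  src <- cbind(ax[[1]][fg[, 1]], ax[[2]][fg[, 2]], ax[[3]][fg[, 3]])
  grid <- as.matrix(expand.grid(i = seq_len(shape[1]), j = seq_len(shape[2]),
                                k = seq_len(shape[3])))
  pts <- cbind(ax[[1]][grid[, 1]], ax[[2]][grid[, 2]], ax[[3]][grid[, 3]])
  d2 <- outer(rowSums(pts^2), rep(1, nrow(src))) +
    outer(rep(1, nrow(pts)), rowSums(src^2)) - 2 * pts %*% t(src)
  d2[d2 < 0] <- 0
  array(sqrt(apply(d2, 1, min)), dim = shape)
}

# PV shell oracle: threshold the distance map, subtract the ventricles
oracle_pv_mask <- function(vent, spacing, radius_mm) {
  oracle_distance_map(vent, spacing) <= radius_mm + 1e-9 & !vent
}

# random binary mask with foreground probability p
random_mask <- function(shape, p = 0.05) {
  array(stats::runif(prod(shape)) < p, dim = shape)
}

# random spacing in the clinical FLAIR regime: in-plane 0.4-1.0 mm,
# slices 5-6 mm
random_spacing <- function() {
  inplane <- stats::runif(2, 0.4, 1.0)
  c(inplane, stats::runif(1, 5, 6))
}

# ---- naive metric implementations (loops, no shared code) ----

naive_accuracy <- function(gt, pred) {
  hits <- 0
  for (i in seq_along(gt)) if (gt[i] == pred[i]) hits <- hits + 1
  hits / length(gt)
}

naive_binary_f1 <- function(gt, pred) {
  tp <- fp <- fn <- 0
  for (i in seq_along(gt)) {
    if (gt[i] && pred[i]) tp <- tp + 1
    if (!gt[i] && pred[i]) fp <- fp + 1
    if (gt[i] && !pred[i]) fn <- fn + 1
  }
  if (2 * tp + fp + fn == 0) return(0)
  2 * tp / (2 * tp + fp + fn)
}

naive_macro_f1 <- function(gt, pred) {
  classes <- sort(unique(c(gt, pred)))
  mean(sapply(classes, function(g) naive_binary_f1(gt == g, pred == g)))
}

naive_mae <- function(gt, pred) {
  s <- 0
  for (i in seq_along(gt)) s <- s + abs(gt[i] - pred[i])
  s / length(gt)
}

naive_cohen_kappa <- function(a, b) {
  cats <- sort(unique(c(a, b)))
  n <- length(a)
  po <- naive_accuracy(a, b)
  pe <- 0
  for (c in cats) pe <- pe + (sum(a == c) / n) * (sum(b == c) / n)
  if (abs(1 - pe) < 1e-15) return(if (po == 1) 1 else NaN)
  (po - pe) / (1 - pe)
}

naive_fleiss_kappa <- function(mat) {
  n <- nrow(mat); m <- ncol(mat)
  cats <- sort(unique(as.vector(mat)))
  p_i <- numeric(n)
  for (i in seq_len(n)) {
    s <- 0
    for (c in cats) s <- s + sum(mat[i, ] == c)^2
    p_i[i] <- (s - m) / (m * (m - 1))
  }
  pj <- sapply(cats, function(c) sum(mat == c) / (n * m))
  pe <- sum(pj^2)
  if (abs(1 - pe) < 1e-15) return(NaN)
  (mean(p_i) - pe) / (1 - pe)
}

# exhaustive Youden oracle: try every midpoint + sentinel, return max J
naive_best_j <- function(neg, pos) {
  pooled <- sort(unique(c(neg, pos)))
  cand <- c(pooled[1] - 1, if (length(pooled) > 1)
    (pooled[-1] + pooled[-length(pooled)]) / 2 else numeric())
  best <- -Inf
  for (t in cand) {
    j <- mean(pos >= t) + mean(neg < t) - 1
    if (j > best) best <- j
  }
  best
}

# a small phantom spec with one clear PVH and one clear DWMH lesion
two_lesion_spec <- function(seed = 1L) {
  phantom_spec(
    lesions = data.frame(offset_mm = c(4, 24), radius_mm = c(3, 4),
                         class = c("PVH", "DWMH")),
    seed = seed
  )
}
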