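#' Pairwise Euclidean distances between signatures
#'
#' @param x a `signature_set` or a numeric matrix (rows = trials).
#' @return N x N symmetric matrix with zero diagonal.
#' @export
pairwise_signature_distances <- function(x) {
  if (inherits(x, "signature_set")) x <- x$vectors
  as.matrix(dist(x))
}

#' Classical multidimensional scaling of a gait-distance matrix
#'
#' Torgerson scaling: double-centred Gram matrix, top eigenvectors scaled by
#' the square root of their eigenvalues — deterministic up to axis sign.
#' Signs are canonicalized: when `speeds` is supplied the first axis is
#' flipped to correlate non-negatively with speed and the remaining axes to
#' correlate non-negatively with subject order (when `subjects` is supplied);
#' otherwise the largest-magnitude coordinate of each axis is made positive.
#'
#' @param d N x N distance matrix (or `dist`).
#' @param dim embedding dimension (default 3).
#' @param speeds,subjects optional trial metadata used for sign
#'   canonicalization.
#' @return object of class `mds_map`: `points` (N x dim), `eig`, `dist_cor`
#'   (Pearson correlation between input and embedded distances), `stress`
#'   (normalized residual), `method = "classical"`.
#' @export
mds_embed <- function(d, dim = 3, speeds = NULL, subjects = NULL) {
  D <- as.matrix(d)
  if (nrow(D) != ncol(D)) stop("distance matrix must be square")
  fit <- cmdscale(D, k = dim, eig = TRUE)
  pts <- fit$points
  if (ncol(pts) < dim) {
    warning(sprintf("only %d positive-eigenvalue axes; padding with zeros",
                    ncol(pts)))
    pts <- cbind(pts, matrix(0, nrow(pts), dim - ncol(pts)))
  }
  for (a in seq_len(dim)) {
    flip <- FALSE
    if (a == 1 && !is.null(speeds) && sd(pts[, a]) > 0) {
      flip <- cor(pts[, a], speeds) < 0
    } else if (a > 1 && !is.null(subjects) && sd(pts[, a]) > 0) {
      ord <- as.numeric(factor(subjects))
      flip <- isTRUE(cor(pts[, a], ord) < 0)
    } else {
      flip <- pts[which.max(abs(pts[, a])), a] < 0
    }
    if (flip) pts[, a] <- -pts[, a]
  }
  colnames(pts) <- c("X", "Y", "Z", paste0("A", seq_len(max(0, dim - 3))))[seq_len(dim)]
  dhat <- dist(pts)
  dvec <- as.dist(D)
  out <- list(points = pts, eig = fit$eig,
              dist_cor = suppressWarnings(cor(c(dvec), c(dhat))),
              stress = sqrt(sum((c(dvec) - c(dhat))^2) / sum(c(dvec)^2)),
              method = "classical")
  class(out) <- "mds_map"
  out
}

#' @export
print.mds_map <- function(x, ...) {
  cat(sprintf("mds_map: %d trials in %dD (distance correlation %.3f, stress %.3f)\n",
              nrow(x$points), ncol(x$points), x$dist_cor, x$stress))
  invisible(x)
}

#' Intra- vs inter-individual distance statistics
#'
#' Upper-triangle pairwise distances are split into intra-individual (same
#' subject) and inter-individual groups, z-scored with the pooled mean and SD
#' of all pairwise distances, and compared with a two-sided Mann-Whitney U
#' test. Lower-tail (z < -2) and upper-tail (z > 2) proportions are reported
#' per group.
#'
#' @param d N x N distance matrix.
#' @param subjects subject label per trial.
#' @return object of class `distance_stats`: `intra`, `inter` (raw),
#'   `intra_z`, `inter_z`, `prop_low` / `prop_high` (named per group), `mwu`
#'   (the test result), `p`.
#' @export
intra_inter_stats <- function(d, subjects) {
  D <- as.matrix(d)
  n <- nrow(D)
  if (length(subjects) != n) stop("subjects must match the distance matrix")
  singles <- names(which(table(subjects) == 1))
  if (length(singles))
    warning("subject(s) with a single trial contribute no intra distances: ",
            paste(singles, collapse = ", "))
  ut <- which(upper.tri(D), arr.ind = TRUE)
  same <- subjects[ut[, 1]] == subjects[ut[, 2]]
  intra <- D[ut][same]
  inter <- D[ut][!same]
  if (!length(intra) || !length(inter))
    stop("need at least 2 subjects with at least 2 trials each")
  all_d <- D[ut]
  s <- sd(all_d)
  if (s < 1e-300) {
    warning("all pairwise distances identical; z-scores set to 0")
    zi <- rep(0, length(intra)); ze <- rep(0, length(inter))
    mwu <- list(p.value = 1)
  } else {
    m <- mean(all_d)
    zi <- (intra - m) / s
    ze <- (inter - m) / s
    mwu <- suppressWarnings(wilcox.test(intra, inter, exact = FALSE))
  }
  out <- list(intra = intra, inter = inter, intra_z = zi, inter_z = ze,
              prop_low = c(intra = mean(zi < -2), inter = mean(ze < -2)),
              prop_high = c(intra = mean(zi > 2), inter = mean(ze > 2)),
              mwu = mwu, p = mwu$p.value)
  class(out) <- "distance_stats"
  out
}

#' @export
print.distance_stats <- function(x, ...) {
  cat(sprintf(paste0("distance_stats: %d intra / %d inter pairs; median z %.2f vs %.2f; ",
                     "MWU p = %.3g\n"),
              length(x$intra), length(x$inter), median(x$intra_z),
              median(x$inter_z), x$p))
  invisible(x)
}
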