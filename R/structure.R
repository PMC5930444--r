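#' Genomic identity-by-state distance matrix
#'
#' For each sample pair, per-SNP similarity is 1 - |d_i - d_j| / 2
#' (identical genotypes score 1, het vs hom 0.5, opposite homozygotes
#' 0), averaged over the SNPs called in both samples; the distance is
#' 1 minus that average IBS proportion.
#'
#' @param geno a [GenotypeData] with at least 2 samples.
#' @return symmetric n x n numeric matrix with zero diagonal, sample
#'   ids as dimnames, entries in \[0, 1\].
#' @export
ibsDistanceMatrix <- function(geno) {
  d <- geno@dosage
  if (nrow(d) < 2L) stop("need at least 2 samples")
  A <- list()
  for (k in 0:2) {
    m <- matrix(0, nrow(d), ncol(d))
    m[!is.na(d) & d == k] <- 1
    A[[k + 1]] <- m
  }
  # sum over shared SNPs of |d_i - d_j|
  absdiff <- A[[1]] %*% t(A[[2]]) + A[[2]] %*% t(A[[1]]) +
    2 * (A[[1]] %*% t(A[[3]]) + A[[3]] %*% t(A[[1]])) +
    A[[2]] %*% t(A[[3]]) + A[[3]] %*% t(A[[2]])
  called <- A[[1]] + A[[2]] + A[[3]]
  shared <- called %*% t(called)
  if (any(shared[upper.tri(shared)] == 0)) {
    ij <- which(shared == 0 & upper.tri(shared), arr.ind = TRUE)[1, ]
    stop(sprintf("samples '%s' and '%s' share no called SNP",
                 rownames(d)[ij[1]], rownames(d)[ij[2]]))
  }
  D <- absdiff / (2 * shared)
  diag(D) <- 0
  dimnames(D) <- list(rownames(d), rownames(d))
  D
}

#' Classical multidimensional scaling (principal coordinates)
#'
#' Torgerson PCoA: the squared distance matrix is double-centred
#' (-1/2 J D^2 J with J the centering projector) and eigendecomposed;
#' coordinates are eigenvectors scaled by the square root of their
#' (positive) eigenvalues. Axes are ordered by decreasing eigenvalue
#' and sign-fixed so that the first nonzero loading of each axis is
#' positive. Explained-variance fractions divide each retained
#' eigenvalue by the sum of all positive eigenvalues (negative
#' eigenvalues, which arise for non-Euclidean distances, are excluded
#' from the denominator).
#'
#' @param D symmetric distance matrix.
#' @param k number of axes requested; if fewer positive eigenvalues
#'   exist, fewer axes are returned with a warning.
#' @return list of class `MdsResult`: `points` (n x k' coordinate
#'   matrix), `eig` (all eigenvalues, descending), `explained`
#'   (fractions for the retained axes).
#' @export
classicalMds <- function(D, k = 2L) {
  D <- as.matrix(D)
  n <- nrow(D)
  stopifnot(k >= 1L, n >= 2L, ncol(D) == n)
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (D^2) %*% J
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  tol <- max(abs(e$values)) * 1e-9
  pos <- which(e$values > tol)
  kUse <- min(k, length(pos))
  if (kUse < k)
    warning(sprintf("only %d positive eigenvalue(s); returning %d axis/axes",
                    length(pos), kUse))
  if (kUse == 0L) {
    pts <- matrix(0, n, 0)
    rownames(pts) <- rownames(D)
    return(structure(list(points = pts, eig = e$values,
                          explained = numeric(0)), class = "MdsResult"))
  }
  vec <- e$vectors[, pos[seq_len(kUse)], drop = FALSE]
  # sign convention: first nonzero loading of each axis positive
  for (j in seq_len(ncol(vec))) {
    nz <- which(abs(vec[, j]) > 1e-12)
    if (length(nz) && vec[nz[1], j] < 0) vec[, j] <- -vec[, j]
  }
  lam <- e$values[pos[seq_len(kUse)]]
  pts <- sweep(vec, 2, sqrt(lam), "*")
  rownames(pts) <- rownames(D)
  colnames(pts) <- paste0("PCo", seq_len(kUse))
  structure(list(points = pts, eig = e$values,
                 explained = lam / sum(e$values[pos])),
            class = "MdsResult")
}

#' @export
print.MdsResult <- function(x, ...) {
  cat("MdsResult:", nrow(x$points), "samples,", ncol(x$points), "axes\n")
  if (length(x$explained))
    cat("  explained variance:",
        paste(sprintf("%.2f%%", 100 * x$explained), collapse = ", "), "\n")
  invisible(x)
}

#' Mean silhouette width of a binary partition of numeric values
#'
#' One-dimensional silhouette (Euclidean): for each point, a = mean
#' distance to its own group, b = mean distance to the other group,
#' silhouette = (b - a) / max(a, b). Positive mean width indicates the
#' two groups separate along the axis; used to quantify control-line
#' separation on the first principal coordinate.
#'
#' @param x numeric vector (e.g. PCo1 coordinates).
#' @param group logical vector, `TRUE` for one group.
#' @return mean silhouette width.
#' @export
silhouetteWidth <- function(x, group) {
  stopifnot(length(x) == length(group), any(group), any(!group))
  dd <- abs(outer(x, x, "-"))
  s <- vapply(seq_along(x), function(i) {
    own <- group == group[i]; own[i] <- FALSE
    a <- if (any(own)) mean(dd[i, own]) else 0
    b <- mean(dd[i, !(group == group[i])])
    if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }, 0)
  mean(s)
}
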