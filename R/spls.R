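#' Prevalence filter for sPLS feature blocks
#'
#' Keeps features with non-zero (and non-missing) values in at least
#' `threshold` of the samples (inclusive: a feature present in exactly half
#' the samples survives the default 50% filter).  The lipid (Y) block is
#' conventionally retained whole.
#'
#' @param X a [FeatureTable-class] or numeric matrix (samples x features).
#' @param threshold prevalence fraction.
#' @return object of the same kind as `X`, filtered.
#' @export
prevalenceFilterFeatures <- function(X, threshold = 0.5) {
  m <- if (is(X, "FeatureTable")) abundances(X) else as.matrix(X)
  if (!ncol(m)) stop("empty feature block")
  keep <- colMeans(!is.na(m) & m > 0) >= threshold
  if (!any(keep)) stop("no features pass the prevalence filter")
  if (is(X, "FeatureTable")) X[, which(keep)] else m[, keep, drop = FALSE]
}

.softThreshold <- function(u, keep) {
  if (keep >= length(u)) return(u)
  cut <- sort(abs(u), decreasing = TRUE)[keep + 1L]
  sign(u) * pmax(abs(u) - cut, 0)
}

#' Sparse partial least squares regression (NIPALS)
#'
#' Alternating singular directions of the X'Y cross-covariance with
#' soft-thresholding of the X loading to the `keepX` largest entries,
#' deflation in regression mode (both blocks deflated on the X scores).
#' Blocks are centered and unit-scaled by default.  Initialization is the
#' leading singular vector of X'Y, so the fit is deterministic.  Each
#' component's X loading is flipped so its largest-magnitude entry is
#' positive.
#'
#' @param X,Y numeric matrices or [FeatureTable-class] objects
#'   (samples x features), same samples.
#' @param ncomp number of components (<= rank).
#' @param keepX integer vector (recycled) of X features kept per component;
#'   `NULL` keeps all.
#' @param scale center and unit-scale both blocks.
#' @param tol,maxit convergence tolerance and iteration cap per component.
#' @return an [SplsModel-class].
#' @export
splsFit <- function(X, Y, ncomp = 2L, keepX = NULL, scale = TRUE,
                    tol = 1e-9, maxit = 500L) {
  X <- if (is(X, "FeatureTable")) abundances(X) else as.matrix(X)
  Y <- if (is(Y, "FeatureTable")) abundances(Y) else as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop("X and Y must share samples")
  n <- nrow(X); p <- ncol(X); q <- ncol(Y)
  ncomp <- as.integer(ncomp)
  if (is.null(keepX)) keepX <- p
  keepX <- as.integer(rep_len(keepX, ncomp))
  ctr <- function(M) {
    M <- scale(M, center = TRUE, scale = FALSE)
    if (scale) {
      s <- apply(M, 2L, stats::sd)
      s[s == 0] <- 1
      M <- sweep(M, 2L, s, "/")
    }
    M
  }
  Xc <- ctr(X); Yc <- ctr(Y)
  U <- matrix(0, p, ncomp, dimnames = list(colnames(X), paste0("comp", seq_len(ncomp))))
  V <- matrix(0, q, ncomp, dimnames = list(colnames(Y), colnames(U)))
  TT <- matrix(0, n, ncomp, dimnames = list(rownames(X), colnames(U)))
  W <- matrix(0, n, ncomp, dimnames = dimnames(TT))
  expCov <- numeric(ncomp)
  for (h in seq_len(ncomp)) {
    M <- crossprod(Xc, Yc)
    sv <- svd(M, nu = 1L, nv = 1L)
    u <- sv$u[, 1L]; v <- sv$v[, 1L]
    for (it in seq_len(maxit)) {
      uNew <- .softThreshold(drop(M %*% v), keepX[h])
      nrm <- sqrt(sum(uNew^2))
      if (nrm == 0) stop("sPLS component ", h, " collapsed to zero; reduce sparsity")
      uNew <- uNew / nrm
      vNew <- drop(crossprod(M, uNew))
      vNew <- vNew / sqrt(sum(vNew^2))
      delta <- max(max(abs(uNew - u)), max(abs(vNew - v)))
      u <- uNew; v <- vNew
      if (delta < tol) break
      if (it == maxit)
        stop(sprintf("sPLS component %d did not converge in %d iterations (last delta %.3g)",
                     h, maxit, delta))
    }
    if (u[which.max(abs(u))] < 0) { u <- -u; v <- -v }
    xi <- drop(Xc %*% u); om <- drop(Yc %*% v)
    U[, h] <- u; V[, h] <- v; TT[, h] <- xi; W[, h] <- om
    expCov[h] <- stats::cov(xi, om)
    # regression-mode deflation on the X score
    cvec <- drop(crossprod(Xc, xi)) / sum(xi^2)
    dvec <- drop(crossprod(Yc, xi)) / sum(xi^2)
    Xc <- Xc - xi %o% cvec
    Yc <- Yc - xi %o% dvec
  }
  new("SplsModel", Xloadings = U, Yloadings = V, Xscores = TT, Yscores = W,
      keepX = keepX, explainedCov = expCov)
}

#' Clustered association table from an sPLS model
#'
#' X-feature by Y-feature association scores from the low-rank loading
#' product `sum_h u_h v_h'` (optionally weighted by each component's
#' explained covariance), with rows and columns ordered by complete-linkage
#' clustering on the distance `1 - Pearson r` between association profiles.
#'
#' @param model an [SplsModel-class].
#' @param absolute use `1 - |r|` instead of `1 - r` as the distance.
#' @param covWeighted weight each component's loading product by its
#'   explained covariance instead of equally.
#' @return list with `association` (ordered matrix), `rowOrder`,
#'   `colOrder`, `rowDendrogram`, `colDendrogram`, and `pairs` (long-form
#'   table sorted by |score|).
#' @export
splsCluster <- function(model, absolute = FALSE, covWeighted = FALSE) {
  U <- model@Xloadings; V <- model@Yloadings
  w <- if (covWeighted) model@explainedCov else rep(1, ncol(U))
  A <- U %*% diag(w, ncol(U)) %*% t(V)
  ordRows <- seq_len(nrow(A)); ordCols <- seq_len(ncol(A))
  hcr <- hcc <- NULL
  distFrom <- function(M) {
    r <- suppressWarnings(stats::cor(t(M)))
    r[is.na(r)] <- 0; diag(r) <- 1
    if (absolute) stats::as.dist(1 - abs(r)) else stats::as.dist(1 - r)
  }
  if (nrow(A) > 2L) {
    hcr <- stats::hclust(distFrom(A), method = "complete")
    ordRows <- hcr$order
  }
  if (ncol(A) > 2L) {
    hcc <- stats::hclust(distFrom(t(A)), method = "complete")
    ordCols <- hcc$order
  }
  pairs <- expand.grid(x = rownames(A), y = colnames(A),
                       stringsAsFactors = FALSE)
  pairs$score <- as.vector(A)
  pairs <- pairs[order(-abs(pairs$score)), ]
  rownames(pairs) <- NULL
  list(association = A[ordRows, ordCols, drop = FALSE],
       rowOrder = rownames(A)[ordRows], colOrder = colnames(A)[ordCols],
       rowDendrogram = hcr, colDendrogram = hcc, pairs = pairs)
}
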