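## Least-absolute-deviation (median) regression via iteratively reweighted
## least squares; the objective is convex so IRLS from the OLS start
## converges to the LAD solution for practical purposes.
.ladFit <- function(X, y, maxit = 200L, tol = 1e-10) {
  b <- qr.coef(qr(X), y)
  for (i in seq_len(maxit)) {
    r <- drop(y - X %*% b)
    w <- sqrt(1 / pmax(abs(r), 1e-8))
    bNew <- qr.coef(qr(X * w), y * w)
    if (max(abs(bNew - b)) < tol) { b <- bNew; break }
    b <- bNew
  }
  drop(b)
}

## Rank-score test for the slope of interest in median regression: fit the
## restricted model (without x), score residual signs a_i = 1/2 - I(r < 0),
## project x off the restricted design, and refer
## T = sum(x~ a) / sqrt(tau(1-tau) sum(x~^2)) to N(0,1).
.rankScoreP <- function(y, x, Z) {
  br <- .ladFit(Z, y)
  r <- drop(y - Z %*% br)
  a <- 0.5 - (r < 0)
  xt <- drop(x - Z %*% qr.coef(qr(Z), x))
  ss <- sum(xt^2)
  if (ss <= 0) return(NA_real_)
  2 * stats::pnorm(-abs(sum(xt * a) / sqrt(0.25 * ss)))
}

#' Age-adjusted median (quantile) regression of metadata on ordination axes
#'
#' For each metadata variable and each of the first `nAxes` ordination
#' axes, fits the median regression `y = b0 + b1 axis + b2 age` on complete
#' cases, reports the raw coefficient `beta` together with the two scaled
#' versions used for reporting — `RC_range = beta x (max - min)` of the
#' axis scores and `RC_sd = beta x sd` of the axis scores — and a rank-score
#' p-value for `beta`, BH-adjusted across the whole variable x axis grid.
#' With fewer than `bootstrapBelow` complete cases a seeded (x, y)-pairs
#' bootstrap p-value (999 draws) replaces the rank-score test.
#'
#' @param metadata data.frame with an `age` column and the variables.
#' @param ord an [OrdinationResult-class] (or coordinate matrix).
#' @param variables character vector of metadata columns to test.
#' @param nAxes number of leading axes (default 3).
#' @param alpha significance level for the `significant` flag.
#' @param bootstrapBelow sample-size cutoff for the bootstrap fallback.
#' @param seed RNG seed (bootstrap fallback only).
#' @return data.frame: variable, axis, n, beta, rc_range, rc_sd, p, p_adj,
#'   significant.
#' @export
quantileAssoc <- function(metadata, ord, variables, nAxes = 3L,
                          alpha = 0.05, bootstrapBelow = 20L, seed = 1L) {
  pts <- if (is(ord, "OrdinationResult")) ordinationPoints(ord) else as.matrix(ord)
  nAxes <- min(nAxes, ncol(pts))
  rows <- list()
  for (v in variables) {
    if (!v %in% names(metadata)) stop("unknown metadata variable: ", v)
    for (ax in seq_len(nAxes)) {
      x <- pts[, ax]
      common <- intersect(rownames(pts), rownames(metadata))
      y <- metadata[common, v]
      age <- metadata[common, "age"]
      xx <- x[common]
      cc <- stats::complete.cases(y, age, xx)
      y <- y[cc]; age <- age[cc]; xx <- xx[cc]
      n <- length(y)
      if (n < 5L || stats::sd(xx) == 0 || stats::sd(y) == 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          variable = v, axis = paste0("PCo", ax), n = n,
          beta = if (n >= 5L && stats::sd(y) == 0) 0 else NA_real_,
          rc_range = NA_real_, rc_sd = NA_real_,
          p = if (n >= 5L && stats::sd(y) == 0) 1 else NA_real_)
        next
      }
      Z <- cbind(1, age)
      b <- .ladFit(cbind(1, xx, age), y)
      if (n < bootstrapBelow) {
        set.seed(seed + ax)
        bs <- replicate(999, {
          idx <- sample.int(n, replace = TRUE)
          .ladFit(cbind(1, xx[idx], age[idx]), y[idx])[2L]
        })
        se <- stats::sd(bs)
        p <- if (se > 0) 2 * stats::pnorm(-abs(b[2L] / se)) else NA_real_
      } else {
        p <- .rankScoreP(y, xx, Z)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, axis = paste0("PCo", ax), n = n,
        beta = b[2L],
        rc_range = b[2L] * (max(xx) - min(xx)),
        rc_sd = b[2L] * stats::sd(xx),
        p = p)
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out$significant <- !is.na(out$p_adj) & out$p_adj <= alpha
  out
}

#' Fisher's exact test for 2 x k contingency tables
#'
#' Fisher-Freeman-Halton exact p by enumeration over tables with fixed
#' margins (the network algorithm of [stats::fisher.test()]); a seeded
#' Monte Carlo fallback with reported standard error is used when the
#' enumeration budget (about 1e7 candidate tables) is exceeded.  A zero
#' row or column margin gives the degenerate p = 1.
#'
#' @param table matrix of non-negative integer counts, 2 x k (or r x c).
#' @param mcBudget candidate-table count above which simulation is used.
#' @param B Monte Carlo replicates.
#' @param seed RNG seed for the fallback.
#' @return list with `p`, `method`, and `se` (NA unless Monte Carlo).
#' @export
fisher2xk <- function(table, mcBudget = 1e7, B = 1e5, seed = 1L) {
  table <- as.matrix(table)
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be non-negative integers")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    return(list(p = 1, method = "degenerate (zero margin)", se = NA_real_))
  # upper bound on tables with fixed margins: each of the first c-1 columns
  # can be filled in at most choose(colsum + r - 1, r - 1) ways
  r <- nrow(table)
  cs <- colSums(table)
  candidates <- prod(choose(cs[-length(cs)] + r - 1, r - 1))
  if (is.finite(candidates) && candidates <= mcBudget) {
    p <- stats::fisher.test(table, workspace = 2e7)$p.value
    list(p = p, method = "exact", se = NA_real_)
  } else {
    set.seed(seed)
    p <- stats::fisher.test(table, simulate.p.value = TRUE, B = B)$p.value
    list(p = p, method = "monte-carlo", se = sqrt(p * (1 - p) / B))
  }
}

#' Cramér's V effect size for contingency tables
#'
#' `V = sqrt(chi2 / (n (min(r, c) - 1)))` with the uncorrected chi-square
#' statistic.  Zero margins give an undefined (NA) value with a warning.
#'
#' @param table matrix of non-negative counts.
#' @return numeric scalar.
#' @export
cramersV <- function(table) {
  table <- as.matrix(table)
  if (sum(table) <= 0) stop("empty table")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    warning("zero margin; Cramér's V undefined")
    return(NA_real_)
  }
  chi <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  sqrt(as.numeric(chi$statistic) /
         (sum(table) * (min(dim(table)) - 1)))
}

#' Derived clinical indices: HOMA-IR, insulin resistance, Matsuda
#'
#' `HOMA-IR = glucose x insulin / 405` (glucose mg/dl, insulin uU/ml);
#' insulin resistance is the strict `HOMA-IR > 2.5` rule.  The Matsuda
#' insulin-sensitivity index `10000 / sqrt(G0 I0 Gmean Imean)` is computed
#' when OGTT mean values are available; when only AUCs are present, means
#' are derived as AUC / `ogttMinutes`.  Non-positive inputs give NA.
#'
#' @param metadata data.frame with `fasting_glucose`, `fasting_insulin`,
#'   optionally `glucose_mean`/`insulin_mean` or `glucose_auc`/`insulin_auc`.
#' @param ogttMinutes OGTT duration used to convert AUCs to means.
#' @return the metadata with `homa_ir`, `insulin_resistant`, `matsuda`
#'   columns appended.
#' @export
clinicalIndices <- function(metadata, ogttMinutes = 120) {
  g <- metadata$fasting_glucose; i <- metadata$fasting_insulin
  bad <- !is.na(g) & !is.na(i) & (g <= 0 | i <= 0)
  homa <- ifelse(!is.na(g) & !is.na(i) & g > 0 & i > 0, g * i / 405, NA_real_)
  if (any(bad)) warning("non-positive glucose/insulin; HOMA-IR undefined for ",
                        sum(bad), " sample(s)")
  gm <- metadata$glucose_mean
  im <- metadata$insulin_mean
  if (is.null(gm) && !is.null(metadata$glucose_auc))
    gm <- metadata$glucose_auc / ogttMinutes
  if (is.null(im) && !is.null(metadata$insulin_auc))
    im <- metadata$insulin_auc / ogttMinutes
  matsuda <- rep(NA_real_, nrow(metadata))
  if (!is.null(gm) && !is.null(im)) {
    ok <- !is.na(g) & !is.na(i) & !is.na(gm) & !is.na(im) &
      g > 0 & i > 0 & gm > 0 & im > 0
    matsuda[ok] <- 10000 / sqrt(g[ok] * i[ok] * gm[ok] * im[ok])
  }
  metadata$homa_ir <- homa
  metadata$insulin_resistant <- !is.na(homa) & homa > 2.5
  metadata$insulin_resistant[is.na(homa)] <- NA
  metadata$matsuda <- matsuda
  metadata
}

#' YFAS behavioral stratification of the OB group
#'
#' Deterministic mapping: 3+ symptoms with food-addiction diagnosis gives
#' O_DHA, 3+ symptoms without diagnosis O_HA, 2 or fewer symptoms O_LA.
#' Applied to OB samples only (NW samples return NA, per the study design).
#' A diagnosis with fewer than 3 symptoms violates the instrument and is a
#' validation error.
#'
#' @param metadata data.frame with `yfas_symptoms`, `yfas_diagnosis`, and
#'   `weight_group`.
#' @return named factor with levels O_LA, O_HA, O_DHA (NA outside OB).
#' @export
yfasStratify <- function(metadata) {
  validateMetadata(metadata)
  s <- metadata$yfas_symptoms; d <- metadata$yfas_diagnosis
  ob <- !is.na(metadata$weight_group) & metadata$weight_group == "OB"
  out <- rep(NA_character_, nrow(metadata))
  out[ob & !is.na(s) & s >= 3 & !is.na(d) & d] <- "O_DHA"
  out[ob & !is.na(s) & s >= 3 & !is.na(d) & !d] <- "O_HA"
  out[ob & !is.na(s) & s <= 2] <- "O_LA"
  factor(setNames(out, rownames(metadata)),
         levels = c("O_LA", "O_HA", "O_DHA"))
}
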