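#' Correspondence analysis axis scores
#'
#' Singular value decomposition of the standardized residuals of the
#' correspondence matrix `P = X / n..`: `S = Dr^-1/2 (P - r c') Dc^-1/2`.
#' Row (sample) principal coordinates are `Dr^-1/2 U D_sigma`; per-axis
#' inertia shares are the squared singular values over total inertia (which
#' times the grand total equals the table's chi-square statistic).  The axis
#' sign is fixed so the food with the largest column mass has a non-negative
#' column coordinate on each axis.
#'
#' @param ffq non-negative food-frequency [FeatureTable-class] or matrix
#'   (samples x foods), no all-zero rows or columns.
#' @return list with `scores` (named axis-1 row scores), `rowCoords` (all
#'   axes), `colCoords`, `inertia` (per-axis share), `totalInertia`.
#' @export
correspondenceAxis <- function(ffq) {
  X <- if (is(ffq, "FeatureTable")) abundances(ffq) else as.matrix(ffq)
  if (any(X < 0)) stop("correspondence analysis needs non-negative input")
  tot <- sum(X)
  if (tot <= 0) stop("zero grand total")
  zr <- rowSums(X) == 0; zc <- colSums(X) == 0
  if (any(zr)) stop("all-zero row(s): ", paste(rownames(X)[zr], collapse = ", "))
  if (any(zc)) stop("all-zero column(s): ", paste(colnames(X)[zc], collapse = ", "))
  P <- X / tot
  r <- rowSums(P); c <- colSums(P)
  S <- diag(1 / sqrt(r)) %*% (P - r %o% c) %*% diag(1 / sqrt(c))
  sv <- svd(S)
  # a rank-1 (independence) table has no non-trivial axes; report zero scores
  keep <- seq_len(max(1L, sum(sv$d > 1e-12)))
  F <- diag(1 / sqrt(r)) %*% sv$u[, keep, drop = FALSE] %*%
    diag(sv$d[keep], length(keep))
  G <- diag(1 / sqrt(c)) %*% sv$v[, keep, drop = FALSE] %*%
    diag(sv$d[keep], length(keep))
  heavy <- which.max(c)
  for (j in seq_along(keep)) {
    if (G[heavy, j] < 0) { G[, j] <- -G[, j]; F[, j] <- -F[, j] }
  }
  rownames(F) <- rownames(X); rownames(G) <- colnames(X)
  inertia <- sv$d[keep]^2
  list(scores = setNames(F[, 1L], rownames(X)),
       rowCoords = F, colCoords = G,
       inertia = if (sum(inertia) > 0) inertia / sum(inertia)
                 else rep(NA_real_, length(inertia)),
       totalInertia = sum(sv$d^2))
}

#' Dietary groups by 1-D Ward clustering of CA axis-1 scores
#'
#' Ward linkage with Euclidean distance on the axis-1 scores, cut at `k`
#' (default 3).  Groups are labeled D1..Dk in increasing order of group
#' mean score.
#'
#' @param scores named numeric axis scores (or output of
#'   [correspondenceAxis()]).
#' @param k number of dietary groups (>= 2).
#' @return a [DietAssignment-class].
#' @export
dietaryGroups <- function(scores, k = 3L) {
  if (is.list(scores)) {
    inertia <- scores$inertia
    scores <- scores$scores
  } else inertia <- NA_real_
  k <- as.integer(k)
  if (k < 2L) stop("k must be at least 2")
  if (k > length(scores)) stop("k exceeds the number of samples")
  hc <- stats::hclust(stats::dist(scores), method = "ward.D2")
  cl <- stats::cutree(hc, k)
  mu <- tapply(scores, cl, mean)
  ord <- order(mu)
  map <- setNames(paste0("D", seq_len(k)), names(mu)[ord])
  groups <- factor(map[as.character(cl)], levels = paste0("D", seq_len(k)))
  names(groups) <- names(scores)
  new("DietAssignment", groups = groups, axisScores = scores,
      inertia = inertia, hfd = numeric(0))
}

#' Healthy Food Diversity index
#'
#' `HFD = hv_bar x BI`, where `BI = 1 - sum(s_i^2)` is the Berry index of
#' the consumption shares and `hv_bar = sum(hv_i s_i)` the share-weighted
#' mean health value — the number/distribution/health-value composition of
#' Drescher's index.  Samples with zero total consumption are undefined
#' (NA) and flagged with a warning.
#'
#' @param frequencies food [FeatureTable-class] or matrix (samples x foods)
#'   of consumption frequencies (converted to shares row-wise).
#' @param annotations data.frame with rownames (or `food` column) matching
#'   foods and an `hv` column in \[0, 1\].
#' @return named numeric vector of per-sample HFD values.
#' @export
hfdIndex <- function(frequencies, annotations) {
  m <- if (is(frequencies, "FeatureTable")) abundances(frequencies) else as.matrix(frequencies)
  if (!is.null(annotations$food)) rownames(annotations) <- annotations$food
  missing <- setdiff(colnames(m), rownames(annotations))
  if (length(missing))
    stop("food item(s) without annotation: ", paste(missing, collapse = ", "))
  hv <- annotations[colnames(m), "hv"]
  tot <- rowSums(m)
  out <- rep(NA_real_, nrow(m)); names(out) <- rownames(m)
  ok <- tot > 0
  if (any(!ok)) warning("zero total consumption; HFD undefined for: ",
                        paste(rownames(m)[!ok], collapse = ", "))
  s <- m[ok, , drop = FALSE] / tot[ok]
  bi <- 1 - rowSums(s^2)
  hvbar <- as.numeric(s %*% hv)
  out[ok] <- hvbar * bi
  out
}

#' Per-sample nutrient summaries from FFQ frequencies
#'
#' Daily energy from frequency x per-portion energy; fiber density in grams
#' per 1000 kcal; macronutrient shares as percent of macro energy using the
#' Atwater factors 4/4/9 kcal per gram.
#'
#' @param ffq food [FeatureTable-class] or matrix of daily frequencies.
#' @param annotations data.frame with `kcal`, `protein_g`, `carb_g`,
#'   `fat_g`, `fiber_g` per food.
#' @return data.frame: energy_kcal, fiber_g, fiber_per_1000kcal, protein_g,
#'   carb_g, fat_g, protein_pct, carb_pct, fat_pct.
#' @export
nutrientSummaries <- function(ffq, annotations) {
  m <- if (is(ffq, "FeatureTable")) abundances(ffq) else as.matrix(ffq)
  if (!is.null(annotations$food)) rownames(annotations) <- annotations$food
  missing <- setdiff(colnames(m), rownames(annotations))
  if (length(missing))
    stop("food item(s) without annotation: ", paste(missing, collapse = ", "))
  ann <- annotations[colnames(m), ]
  energy <- as.numeric(m %*% ann$kcal)
  fiber <- as.numeric(m %*% ann$fiber_g)
  pro <- as.numeric(m %*% ann$protein_g)
  carb <- as.numeric(m %*% ann$carb_g)
  fat <- as.numeric(m %*% ann$fat_g)
  fiberDensity <- ifelse(energy > 0, fiber / (energy / 1000), NA_real_)
  if (any(energy <= 0))
    warning("zero-energy sample(s); fiber density undefined for: ",
            paste(rownames(m)[energy <= 0], collapse = ", "))
  macroKcal <- 4 * pro + 4 * carb + 9 * fat
  data.frame(sample_id = rownames(m),
             energy_kcal = energy, fiber_g = fiber,
             fiber_per_1000kcal = fiberDensity,
             protein_g = pro, carb_g = carb, fat_g = fat,
             protein_pct = 100 * 4 * pro / macroKcal,
             carb_pct = 100 * 4 * carb / macroKcal,
             fat_pct = 100 * 9 * fat / macroKcal,
             row.names = rownames(m))
}

#' Diet x microbiota cluster cross-tabulation
#'
#' Counts and within-stratum percentages of every (dietary group, community
#' cluster) combination, overall and within NW / OB / behavioral strata
#' when available.  Empty combinations are reported as 0, never omitted.
#'
#' @param diet a [DietAssignment-class].
#' @param clusters a [ClusterAssignment-class].
#' @param metadata optional data.frame with `weight_group` (and YFAS
#'   columns for behavioral strata via [yfasStratify()]).
#' @return data.frame in long form: stratum, diet_group, cluster, n, pct.
#' @export
dietClusterCrosstab <- function(diet, clusters, metadata = NULL) {
  dg <- dietGroups(diet)
  cl <- clusterLabels(clusters)
  common <- intersect(names(dg), names(cl))
  dg <- dg[common]; cl <- cl[common]
  strata <- list(all = common)
  if (!is.null(metadata) && "weight_group" %in% names(metadata)) {
    wg <- metadata[common, "weight_group"]
    strata$NW <- common[!is.na(wg) & wg == "NW"]
    strata$OB <- common[!is.na(wg) & wg == "OB"]
    if (all(c("yfas_symptoms", "yfas_diagnosis") %in% names(metadata))) {
      beh <- yfasStratify(metadata[common, , drop = FALSE])
      for (g in c("O_LA", "O_HA", "O_DHA"))
        strata[[g]] <- common[!is.na(beh) & beh == g]
    }
  }
  out <- lapply(names(strata), function(st) {
    ss <- strata[[st]]
    tab <- table(diet_group = dg[ss], cluster = cl[ss])
    df <- as.data.frame(tab, stringsAsFactors = FALSE)
    names(df)[3L] <- "n"
    df$pct <- if (sum(df$n) > 0) 100 * df$n / sum(df$n) else NA_real_
    cbind(stratum = st, df)
  })
  do.call(rbind, out)
}
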