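#' Standardize a feature table
#'
#' Scales each column to zero mean and unit variance using the population
#' (divisor N) standard deviation, the preprocessing applied before the
#' principal component analysis. With unit-variance scaling the subsequent
#' PCA is the correlation-matrix PCA.
#'
#' @param x numeric matrix or data.frame of features (rows = subjects/sites)
#' @return list with elements scaled (matrix), center and scale (named
#'   numeric vectors)
#' @export
standardizeFeatures <- function(x) {
  x <- as.matrix(x)
  if (!is.numeric(x)) flim_error("flim_invalid_config",
                                 "feature table must be numeric")
  if (any(!is.finite(x)))
    flim_error("flim_invalid_config", "feature table contains non-finite values")
  ctr <- colMeans(x)
  scl <- apply(x, 2, pop_sd)
  zero <- scl == 0
  if (any(zero))
    flim_error("flim_degenerate_feature",
               "zero-variance feature(s): %s",
               paste(colnames(x)[zero], collapse = ", "))
  list(scaled = sweep(sweep(x, 2, ctr), 2, scl, "/"), center = ctr,
       scale = scl)
}

#' Fit the PCA severity model to a feature table
#'
#' Standardizes the table (population SD) and fits a principal component
#' analysis by singular value decomposition of the centred scaled table.
#' Components are the eigenvectors of the column covariance, ordered by
#' decreasing variance; the result is deterministic up to sign, which is
#' fixed later by \code{\link{orientPC1}}. PC1 of this model is the
#' severity axis.
#'
#' @param table data.frame or matrix; non-feature columns are ignored when
#'   \code{features} is given
#' @param features character vector naming the feature columns (default:
#'   all numeric columns)
#' @param k number of components to keep (default: all available,
#'   min(rows - 1, columns))
#' @return a \linkS4class{SeverityModel}
#' @export
fitSeverityModel <- function(table, features = NULL, k = NULL) {
  if (is.null(features))
    features <- colnames(table)[vapply(as.data.frame(table), is.numeric,
                                       logical(1))]
  x <- as.matrix(as.data.frame(table)[, features, drop = FALSE])
  if (nrow(x) < 3L || ncol(x) < 2L)
    flim_error("flim_invalid_config",
               "PCA needs at least 3 rows and 2 feature columns")
  kmax <- min(nrow(x) - 1L, ncol(x))
  if (is.null(k)) k <- kmax
  if (k < 1L || k > kmax)
    flim_error("flim_invalid_config",
               "k must lie in [1, %d] for a %d x %d table", kmax, nrow(x),
               ncol(x))
  std <- standardizeFeatures(x)
  pc <- prcomp(std$scaled, center = FALSE, scale. = FALSE)
  vars <- pc$sdev^2
  evr <- vars / sum(vars)
  new("SeverityModel", center = std$center, scale = std$scale,
      rotation = pc$rotation[, seq_len(k), drop = FALSE],
      explained_variance_ratio = evr, pc1_sign = 1,
      features = features)
}

#' Project feature rows onto the principal components
#'
#' Standardizes the input with the model's stored center/scale and applies
#' the rotation; the first column carries the orientation sign and is the
#' severity score. Linear in the inputs. The feature schema must match the
#' model exactly.
#'
#' @param model a \linkS4class{SeverityModel}
#' @param table data.frame/matrix with the model's feature columns, or a
#'   single named feature vector
#' @return matrix of scores (rows x components), columns PC1, PC2, ...
#' @export
projectScores <- function(model, table) {
  stopifnot(is(model, "SeverityModel"))
  if (is.numeric(table) && is.null(dim(table)))
    table <- as.data.frame(as.list(table))
  tbl <- as.data.frame(table)
  missing <- setdiff(model@features, colnames(tbl))
  if (length(missing))
    flim_error("flim_schema_mismatch", "missing feature column(s): %s",
               paste(missing, collapse = ", "))
  x <- as.matrix(tbl[, model@features, drop = FALSE])
  z <- sweep(sweep(x, 2, model@center), 2, model@scale, "/")
  sc <- z %*% model@rotation
  sc[, 1] <- sc[, 1] * model@pc1_sign
  colnames(sc) <- paste0("PC", seq_len(ncol(sc)))
  sc
}

#' Severity score (oriented PC1) of feature rows
#'
#' @inheritParams projectScores
#' @return numeric vector of oriented PC1 scores
#' @export
severityScore <- function(model, table) projectScores(model, table)[, 1]

#' Orient PC1 so larger scores mean more severe condition
#'
#' Chooses the sign of the first principal component so that the group mean
#' score of the least-severe label is not above that of the most-severe
#' label (low PC1 = healthy skin). Ties break toward +1. With absent or
#' single-valued labels the orientation is skipped with a warning and the
#' sign stays +1.
#'
#' @param model a \linkS4class{SeverityModel}
#' @param table feature table the model was fitted on
#' @param labels group label per row
#' @param order character vector of labels from least to most severe
#' @return the model with pc1_sign fixed
#' @export
orientPC1 <- function(model, table, labels,
                      order = c("control", "pseudo_control", "eczema",
                                "psoriasis")) {
  stopifnot(is(model, "SeverityModel"))
  if (missing(labels) || is.null(labels) ||
      length(unique(labels[!is.na(labels)])) < 2L) {
    flim_warning("flim_no_labels",
                 "fewer than 2 distinct labels; PC1 orientation skipped (sign +1)")
    model@pc1_sign <- 1
    return(model)
  }
  present <- order[order %in% labels]
  if (length(present) < 2L)
    flim_error("flim_invalid_config",
               "labels do not match the severity order %s",
               paste(order, collapse = " < "))
  model@pc1_sign <- 1
  sc <- projectScores(model, table)[, 1]
  lo <- mean(sc[labels == present[1]])
  hi <- mean(sc[labels == present[length(present)]])
  model@pc1_sign <- if (lo <= hi) 1 else -1
  model
}

#' Orient PC1 by the sign of one feature loading
#'
#' For analyses without an ordinal group label (e.g. the PASI analysis over
#' psoriasis subjects only), the severity axis is oriented so that a
#' feature known to increase with severity loads positively on PC1.
#'
#' @param model a \linkS4class{SeverityModel}
#' @param feature feature whose PC1 loading is forced non-negative
#'   (default: the inflamed-site epidermal thickness)
#' @return the model with pc1_sign fixed
#' @export
orientPC1ByFeature <- function(model,
                               feature = "dist_SG_SB_inflamed_um") {
  stopifnot(is(model, "SeverityModel"))
  if (!feature %in% model@features)
    flim_error("flim_schema_mismatch", "feature '%s' not in the model schema",
               feature)
  l <- model@rotation[feature, 1]
  model@pc1_sign <- if (l >= 0) 1 else -1
  model
}

#' Pearson product-moment correlation with validation
#'
#' @param x,y numeric vectors of equal length >= 3; both non-constant
#' @return correlation coefficient in [-1, 1]
#' @export
pearsonR <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    flim_error("flim_invalid_config",
               "need two equal-length vectors with n >= 3")
  if (pop_sd(x) == 0 || pop_sd(y) == 0)
    flim_error("flim_undefined_correlation",
               "correlation undefined for a constant input")
  cor(x, y)
}

#' Quantify group separation of severity scores
#'
#' Mean silhouette width of the group labels on the first two principal
#' component scores, plus the pairwise group-mean gaps along PC1 -- a
#' numerical summary of how distinctly the condition clusters separate.
#' Singleton groups are excluded with a warning.
#'
#' @param scores matrix of PC scores (>= 2 columns) as returned by
#'   \code{\link{projectScores}}
#' @param labels group label per row
#' @return list with mean_silhouette, per-group mean silhouettes, and the
#'   matrix of pairwise PC1 group-mean gaps
#' @export
groupSeparation <- function(scores, labels) {
  scores <- as.matrix(scores)
  if (ncol(scores) < 2L)
    flim_error("flim_invalid_config", "need at least 2 score columns")
  labels <- as.character(labels)
  tab <- table(labels)
  singles <- names(tab)[tab < 2L]
  if (length(singles)) {
    flim_warning("flim_singleton_group", "singleton group(s) excluded: %s",
                 paste(singles, collapse = ", "))
    keep <- !labels %in% singles
    scores <- scores[keep, , drop = FALSE]
    labels <- labels[keep]
  }
  if (length(unique(labels)) < 2L)
    flim_error("flim_invalid_config",
               "need at least 2 groups with >= 2 members")
  f <- factor(labels)
  sil <- cluster::silhouette(as.integer(f), dist(scores[, 1:2]))
  per_group <- tapply(sil[, "sil_width"], labels, mean)
  mu <- tapply(scores[, 1], labels, mean)
  gaps <- outer(mu, mu, `-`)
  list(mean_silhouette = mean(sil[, "sil_width"]),
       group_silhouette = per_group, pc1_group_means = mu,
       pc1_gaps = gaps)
}
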