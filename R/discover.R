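# Biomarker discovery statistics on the normalized amount matrix.
#
# The amount matrix is features x samples throughout this file; PLS-DA
# internally transposes to the conventional samples x variables layout.

#' Filter low-information features by interquartile range
#'
#' Ranks features by the interquartile range of their amounts across
#' samples and drops the lowest \code{1 - keep_fraction}. A no-op when
#' fewer than or exactly 250 features remain (small tables need no
#' variance filtering).
#'
#' @param X numeric matrix, features x samples.
#' @param keep_fraction Fraction of features to keep, in (0, 1].
#' @param min_features Tables with at most this many features pass
#'   through untouched (default 250); set 0 to always filter.
#' @return The filtered matrix.
#' @export
iqr_filter <- function(X, keep_fraction = 0.75, min_features = 250L) {
  if (!(keep_fraction > 0 && keep_fraction <= 1))
    stop("keep_fraction must be in (0, 1]")
  if (ncol(X) < 4L) stop("iqr_filter needs at least 4 samples")
  if (keep_fraction == 1 || nrow(X) <= min_features) return(X)
  iqr <- apply(X, 1, stats::IQR)
  n_keep <- ceiling(keep_fraction * nrow(X))
  keep <- rank(-iqr, ties.method = "first") <= n_keep
  X[keep, , drop = FALSE]
}

#' Generalized logarithm
#'
#' \code{glog(x) = log2((x + sqrt(x^2 + a^2)) / 2)}: behaves as log2 for
#' \code{x >> a} but stays finite at 0 (\code{glog(0) = log2(a/2)}),
#' stabilizing the variance of near-zero amounts.
#'
#' @param x numeric.
#' @param a transform offset; by default the smallest positive value in
#'   \code{x}.
#' @return transformed values.
#' @export
glog <- function(x, a = NULL) {
  if (is.null(a)) {
    pos <- x[x > 0]
    a <- if (length(pos)) min(pos) else 1
  }
  log2((x + sqrt(x^2 + a^2)) / 2)
}

#' Generalized-log transform and autoscale an amount matrix
#'
#' Applies [glog()] with a single offset (the smallest positive amount in
#' the matrix), then centers each feature to mean 0 and scales to unit
#' sample standard deviation. Features constant after the transform are
#' set to all zeros.
#'
#' @param X numeric matrix, features x samples, amounts >= 0.
#' @param a optional glog offset overriding the default.
#' @return Transformed matrix of the same shape, with attribute
#'   \code{"glog_a"} recording the offset used.
#' @export
glog_autoscale <- function(X, a = NULL) {
  if (any(X < 0)) stop("amounts must be non-negative")
  if (is.null(a)) {
    pos <- X[X > 0]
    a <- if (length(pos)) min(pos) else 1
  }
  Z <- glog(X, a)
  mu <- rowMeans(Z)
  sdv <- apply(Z, 1, stats::sd)
  const <- sdv == 0 | !is.finite(sdv)
  sdv[const] <- 1
  Z <- (Z - mu) / sdv
  Z[const, ] <- 0
  attr(Z, "glog_a") <- a
  Z
}

# internal: vectorized two-sample t-tests on rows.
# Returns p-values; Welch by default, pooled optional.
row_t_test <- function(A, B, var_equal = FALSE) {
  n1 <- ncol(A); n2 <- ncol(B)
  m1 <- rowMeans(A); m2 <- rowMeans(B)
  v1 <- rowSums((A - m1)^2) / (n1 - 1)
  v2 <- rowSums((B - m2)^2) / (n2 - 1)
  if (var_equal) {
    sp <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se2 <- sp * (1 / n1 + 1 / n2)
    df <- rep(n1 + n2 - 2, length(m1))
  } else {
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  t <- (m1 - m2) / sqrt(se2)
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  p[se2 == 0] <- ifelse(m1[se2 == 0] == m2[se2 == 0], 1, 0)
  p
}

#' Per-feature differential test between two groups
#'
#' Fold changes are computed on the untransformed amounts
#' (mean case / mean control); p-values come from two-tailed unpaired
#' t-tests (pooled variance by default) on the transformed matrix; q-values are
#' Benjamini-Hochberg. Features with zero control mean get an undefined
#' fold change (NA) and are excluded from volcano selection.
#'
#' @param amounts numeric matrix, features x samples, untransformed.
#' @param transformed matrix of the same shape after [glog_autoscale()];
#'   if NULL, tests run on \code{glog_autoscale(amounts)}.
#' @param groups character/factor of length ncol, two levels.
#' @param case,control group labels; default first/second level.
#' @param var_equal pooled-variance t-test if TRUE (default); FALSE for
#'   Welch. At n = 3 per group the Welch degrees of freedom (~2) cost
#'   most of the test's power, so the pooled test is the default.
#' @return data.frame: \code{feature_id}, \code{mean_case},
#'   \code{mean_control}, \code{fold_change}, \code{log2_fc},
#'   \code{p_raw}, \code{q_fdr}.
#' @export
differential_test <- function(amounts, groups, transformed = NULL,
                              case = NULL, control = NULL,
                              var_equal = TRUE) {
  groups <- as.character(groups)
  gl <- sort(unique(groups))
  if (length(gl) != 2L) stop("exactly two groups required, found ", length(gl))
  if (is.null(case)) case <- gl[1]
  if (is.null(control)) control <- gl[2]
  ci <- groups == case; ki <- groups == control
  if (sum(ci) < 2L || sum(ki) < 2L)
    stop("each group needs at least 2 samples")
  if (is.null(transformed)) transformed <- glog_autoscale(amounts)
  mean_case <- rowMeans(amounts[, ci, drop = FALSE])
  mean_control <- rowMeans(amounts[, ki, drop = FALSE])
  fc <- ifelse(mean_control > 0, mean_case / mean_control, NA_real_)
  n_undef <- sum(is.na(fc))
  if (n_undef > 0)
    message(n_undef, " feature(s) with zero control mean: fold change undefined")
  p <- row_t_test(transformed[, ci, drop = FALSE],
                  transformed[, ki, drop = FALSE], var_equal = var_equal)
  data.frame(
    feature_id = if (!is.null(rownames(amounts))) rownames(amounts)
    else paste0("F", seq_len(nrow(amounts))),
    mean_case = mean_case, mean_control = mean_control,
    fold_change = fc, log2_fc = log2(fc),
    p_raw = p, q_fdr = stats::p.adjust(p, method = "BH"),
    stringsAsFactors = FALSE
  )
}

#' Volcano selection
#'
#' Selects features with \code{q < q_max} and fold change strictly
#' greater than \code{fc_min} or strictly smaller than \code{1/fc_min}.
#'
#' @param stats data.frame from [differential_test()].
#' @param fc_min minimum fold change (default 2, strict).
#' @param q_max maximum FDR-adjusted p (default 0.05, strict).
#' @return \code{stats} with logical column \code{selected_volcano} added,
#'   plus attributes \code{n_up}, \code{n_down}, \code{pct_up}.
#' @export
volcano_select <- function(stats, fc_min = 2, q_max = 0.05) {
  ok <- !is.na(stats$fold_change)
  up <- ok & stats$q_fdr < q_max & stats$fold_change > fc_min
  down <- ok & stats$q_fdr < q_max & stats$fold_change < 1 / fc_min
  stats$selected_volcano <- up | down
  attr(stats, "n_up") <- sum(up)
  attr(stats, "n_down") <- sum(down)
  attr(stats, "pct_up") <- if (any(up | down)) 100 * sum(up) / sum(up | down)
  else NA_real_
  stats
}

#' Fit a PLS-DA model (NIPALS PLS1)
#'
#' Two-class partial least squares discriminant analysis: the class
#' labels are coded 0/1 and centered, and components are extracted by
#' the NIPALS algorithm with standard deflation of X. Deterministic given
#' input order.
#'
#' @param X numeric matrix, samples x features (transformed amounts).
#' @param y two-level factor/character/numeric of length nrow(X).
#' @param n_components number of latent components (default 2).
#' @return Object of class \code{plsda_model}: per-component \code{scores}
#'   (n x a), \code{weights} (p x a, unit norm), \code{loadings} (p x a),
#'   \code{y_loadings} (length a), \code{ssy} (Y variance explained per
#'   component), plus centering info for prediction.
#' @export
plsda_fit <- function(X, y, n_components = 2) {
  X <- as.matrix(X)
  yf <- as.numeric(factor(y)) - 1
  if (length(unique(yf)) != 2L) stop("y must have exactly two classes")
  n <- nrow(X); p <- ncol(X)
  if (n_components > min(n - 1L, p))
    stop("n_components must be <= min(n_samples - 1, n_features)")
  x_center <- colMeans(X)
  y_center <- mean(yf)
  E <- sweep(X, 2, x_center)
  f <- yf - y_center
  ss_y_tot <- sum(f^2)
  W <- matrix(0, p, n_components); P <- matrix(0, p, n_components)
  Tm <- matrix(0, n, n_components); q <- numeric(n_components)
  ssy <- numeric(n_components)
  for (a in seq_len(n_components)) {
    w <- crossprod(E, f)           # PLS1: weight direction in one step
    nw <- sqrt(sum(w^2))
    if (nw < .Machine$double.eps) {
      W <- W[, seq_len(a - 1L), drop = FALSE]
      P <- P[, seq_len(a - 1L), drop = FALSE]
      Tm <- Tm[, seq_len(a - 1L), drop = FALSE]
      q <- q[seq_len(a - 1L)]; ssy <- ssy[seq_len(a - 1L)]
      break
    }
    w <- w / nw
    t <- E %*% w
    tt <- sum(t^2)
    pl <- crossprod(E, t) / tt
    qa <- sum(f * t) / tt
    E <- E - t %*% t(pl)
    ssy[a] <- qa^2 * tt            # Y sum of squares explained by comp a
    f <- f - qa * t
    W[, a] <- w; P[, a] <- pl; Tm[, a] <- t; q[a] <- qa
  }
  structure(list(weights = W, loadings = P, scores = Tm, y_loadings = q,
                 ssy = ssy, ss_y_total = ss_y_tot,
                 x_center = x_center, y_center = y_center,
                 n_components = ncol(W),
                 classes = levels(factor(y))),
            class = "plsda_model")
}

#' @export
print.plsda_model <- function(x, ...) {
  cat(sprintf("plsda_model: %d component(s), %d features; Y variance explained per component: %s\n",
              x$n_components, nrow(x$weights),
              paste(sprintf("%.3f", x$ssy / x$ss_y_total), collapse = ", ")))
  invisible(x)
}

#' Predict centered class scores from a PLS-DA model
#'
#' @param object a \code{plsda_model}.
#' @param newdata samples x features matrix on the training scale.
#' @param ... unused.
#' @return numeric vector of predicted (uncentered) 0/1-coded responses.
#' @export
predict.plsda_model <- function(object, newdata, ...) {
  E <- sweep(as.matrix(newdata), 2, object$x_center)
  yhat <- rep(object$y_center, nrow(E))
  for (a in seq_len(object$n_components)) {
    t <- E %*% object$weights[, a]
    yhat <- yhat + object$y_loadings[a] * t
    E <- E - t %*% t(object$loadings[, a])
  }
  as.numeric(yhat)
}

#' Variable Importance in Projection scores
#'
#' \deqn{VIP_j = \sqrt{p \sum_a SSY_a (w_{ja}/\|w_a\|)^2 / \sum_a SSY_a}}
#' where \eqn{p} is the number of features and \eqn{SSY_a} the Y variance
#' explained by component \eqn{a}. By construction mean(VIP^2) = 1.
#'
#' @param model a \code{plsda_model}.
#' @return numeric vector of VIP scores, one per feature.
#' @export
vip_scores <- function(model) {
  if (sum(model$ssy) <= 0) stop("model explains no Y variance")
  p <- nrow(model$weights)
  w2 <- sweep(model$weights^2, 2,
              colSums(model$weights^2), "/")  # weights already unit norm
  sqrt(p * as.numeric(w2 %*% model$ssy) / sum(model$ssy))
}

#' Leave-one-out cross-validation of a PLS-DA model
#'
#' R2 is computed on training predictions, Q2 = 1 - PRESS/SS_tot with
#' PRESS accumulated over leave-one-out refits. A Q2 below
#' \code{warn_below} triggers an overfitting warning.
#'
#' @param X samples x features matrix.
#' @param y two-level labels.
#' @param n_components latent components (default 2).
#' @param warn_below warning threshold for Q2 (default 0.8).
#' @return list with \code{r2} and \code{q2}.
#' @export
crossvalidate <- function(X, y, n_components = 2, warn_below = 0.8) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 3L) stop("need at least 3 samples")
  yf <- as.numeric(factor(y)) - 1
  fit <- plsda_fit(X, y, n_components)
  yhat <- predict(fit, X)
  ss_tot <- sum((yf - mean(yf))^2)
  r2 <- 1 - sum((yf - yhat)^2) / ss_tot
  press <- 0
  for (i in seq_len(n)) {
    yi <- y[-i]
    if (length(unique(yi)) < 2L) { press <- press + (yf[i] - mean(yf[-i]))^2; next }
    a_i <- min(n_components, length(yi) - 1L)
    fit_i <- plsda_fit(X[-i, , drop = FALSE], yi, a_i)
    press <- press + (yf[i] - predict(fit_i, X[i, , drop = FALSE]))^2
  }
  q2 <- 1 - press / ss_tot
  if (q2 < warn_below)
    warning(sprintf("Q2 = %.3f < %.2f: model may be overfit or uninformative",
                    q2, warn_below))
  list(r2 = r2, q2 = q2)
}

#' Impact factor: combined biomarker index
#'
#' \code{IF = |log2 FC| * (-log10 p) * VIP}. Combines effect size,
#' statistical confidence and multivariate importance in one
#' non-negative score. p-values of 0 are clipped to the smallest
#' representable positive double.
#'
#' @param log2_fc per-feature log2 fold change.
#' @param p per-feature p-value in (0, 1] (the FDR-adjusted q by
#'   convention here; pass raw p if preferred).
#' @param vip per-feature VIP score.
#' @return numeric vector of impact factors.
#' @export
impact_factor <- function(log2_fc, p, vip) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p must be in [0, 1]")
  if (any(p == 0, na.rm = TRUE)) {
    message("p-value(s) of 0 clipped to .Machine$double.xmin")
    p[p == 0] <- .Machine$double.xmin
  }
  abs(log2_fc) * (-log10(p)) * vip
}

#' Combined univariate + multivariate selection
#'
#' Selects features passing both the volcano criterion and
#' \code{vip > vip_min}, ranked by impact factor descending; ties broken
#' by |log2 FC| then feature_id.
#'
#' @param stats data.frame carrying \code{selected_volcano}, \code{vip},
#'   \code{impact_factor}, \code{log2_fc}, \code{feature_id}.
#' @param vip_min VIP threshold (default 1, strict).
#' @return \code{stats} with \code{selected_combined} added, rows ordered
#'   by the ranking (selected first).
#' @export
combined_select <- function(stats, vip_min = 1) {
  stats$selected_combined <- stats$selected_volcano & stats$vip > vip_min
  ord <- order(-stats$selected_combined, -stats$impact_factor,
               -abs(stats$log2_fc), stats$feature_id)
  stats[ord, , drop = FALSE]
}

#' Distribution-free lower confidence limit of the median
#'
#' Order-statistic (exact binomial) two-sided 95\% confidence interval
#' for the median: the lower limit is the d-th order statistic, with d
#' the largest integer such that P(Binom(n, 1/2) < d) <= alpha/2.
#'
#' @param x numeric vector.
#' @param conf confidence level (default 0.95).
#' @return the lower confidence limit (a value of \code{x}).
#' @export
median_lcl <- function(x, conf = 0.95) {
  x <- sort(x[!is.na(x)])
  n <- length(x)
  if (n == 0L) stop("empty vector")
  if (n == 1L) return(x[1])
  alpha <- 1 - conf
  d <- 0L
  while (d + 1L <= n && stats::pbinom(d, n, 0.5) <= alpha / 2) d <- d + 1L
  x[max(d, 1L)]
}

#' Bootstrap lower confidence limit of the median
#'
#' Percentile-bootstrap alternative to [median_lcl()].
#'
#' @param x numeric vector.
#' @param conf confidence level.
#' @param n_boot bootstrap replicates.
#' @return lower confidence limit of the median.
#' @export
median_lcl_boot <- function(x, conf = 0.95, n_boot = 2000) {
  x <- x[!is.na(x)]
  meds <- vapply(seq_len(n_boot), function(i)
    stats::median(sample(x, replace = TRUE)), numeric(1))
  unname(stats::quantile(meds, (1 - conf) / 2, type = 1))
}

#' Class-level discrimination by median impact factor
#'
#' For each lipid class among the selected annotated features, the
#' median impact factor is compared against a global cutoff: the lower
#' 95\% confidence limit of the median IF over all selected features
#' ([median_lcl()]). Classes with median IF strictly above the cutoff
#' are flagged as discriminating. Classes with fewer than 3 members are
#' reported but flagged low-n.
#'
#' @param stats data.frame of selected features carrying
#'   \code{impact_factor} and \code{lipid_class}.
#' @param conf confidence level for the cutoff (default 0.95).
#' @return list with \code{cutoff} and \code{classes} (data.frame:
#'   \code{lipid_class}, \code{n_features}, \code{median_if},
#'   \code{passes_cutoff}, \code{low_n}).
#' @export
class_if_discrimination <- function(stats, conf = 0.95) {
  sel <- stats[!is.na(stats$lipid_class) & nzchar(stats$lipid_class), ,
               drop = FALSE]
  if (nrow(sel) == 0L) stop("no selected annotated features")
  cutoff <- median_lcl(sel$impact_factor, conf)
  sp <- split(sel$impact_factor, class_label(sel$lipid_class))
  classes <- data.frame(
    lipid_class = names(sp),
    n_features = vapply(sp, length, integer(1)),
    median_if = vapply(sp, stats::median, numeric(1)),
    stringsAsFactors = FALSE
  )
  classes$passes_cutoff <- classes$median_if > cutoff
  classes$low_n <- classes$n_features < 3L
  classes <- classes[order(-classes$median_if), , drop = FALSE]
  rownames(classes) <- NULL
  list(cutoff = cutoff, classes = classes)
}

#' Top discriminant features by impact factor
#'
#' @param stats data.frame carrying \code{impact_factor}, \code{log2_fc},
#'   \code{feature_id}.
#' @param n how many (default 100); fewer available returns all with a
#'   message.
#' @return \code{stats} rows, ranked, at most \code{n}.
#' @export
top_discriminants <- function(stats, n = 100) {
  ord <- order(-stats$impact_factor, -abs(stats$log2_fc), stats$feature_id)
  if (nrow(stats) < n) {
    message("only ", nrow(stats), " feature(s) available for top-", n)
    n <- nrow(stats)
  }
  stats[ord[seq_len(n)], , drop = FALSE]
}
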