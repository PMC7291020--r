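# Filtering, drift correction and normalization of the raw feature table.
#
# Stage order used by run_workflow(): blank_filter -> qc_cv_filter ->
# lowess_drift_correct -> protein_normalize (or tic_normalize) ->
# sum_isomers -> exclude_implausible. Filters operate on raw signals,
# drift is corrected before amount scaling.

#' Remove features not sufficiently above blank signal
#'
#' Keeps features whose mean sample intensity exceeds \code{min_fold}
#' times the mean blank intensity (strict \code{>}). Features absent from
#' blanks (blank mean 0) are kept: absence from solvent blanks is the
#' clean case.
#'
#' @param ft A [feature_table()].
#' @param min_fold Minimum sample/blank mean fold change (default 10).
#' @return Filtered feature table; intensities of surviving rows are
#'   untouched.
#' @export
blank_filter <- function(ft, min_fold = 10) {
  bl <- ft_cols(ft, "blank")
  sa <- ft_cols(ft, "sample")
  if (length(bl) == 0L)
    stop("no blank injections present; skip the blank-filter stage explicitly")
  if (length(sa) == 0L) stop("no sample injections present")
  blank_mean <- rowMeans(ft$intensities[, bl, drop = FALSE])
  sample_mean <- rowMeans(ft$intensities[, sa, drop = FALSE])
  keep <- blank_mean == 0 | sample_mean / blank_mean > min_fold
  message(sum(!keep), " feature(s) removed by blank filter")
  ft_subset_features(ft, keep)
}

#' Remove features with high coefficient of variation in QC injections
#'
#' Per feature, CV\% = 100 * sd / mean over the QC injections (sample
#' standard deviation, n-1 denominator). Features with CV \eqn{\ge}
#' \code{max_cv} or with QC mean 0 are excluded (inclusive threshold).
#'
#' @param ft A [feature_table()].
#' @param max_cv CV\% threshold (default 30).
#' @return Filtered feature table.
#' @export
qc_cv_filter <- function(ft, max_cv = 30) {
  qc <- ft_cols(ft, "qc")
  if (length(qc) < 3L)
    stop("qc_cv_filter needs at least 3 QC injections, found ", length(qc))
  q <- ft$intensities[, qc, drop = FALSE]
  mu <- rowMeans(q)
  sdv <- apply(q, 1, stats::sd)
  cv <- ifelse(mu > 0, 100 * sdv / mu, Inf)
  keep <- cv < max_cv
  message(sum(!keep), " feature(s) removed by QC CV filter (>= ", max_cv, "%)")
  ft_subset_features(ft, keep)
}

# internal: LOESS fit of QC intensity vs order, evaluated at all orders.
# Linear extrapolation beyond the outermost QC orders continues the end
# segments of the fit.
drift_fit_eval <- function(qc_order, qc_int, all_order, span, iter = 2L) {
  # lowess needs >= 4 in-window points to smooth at all (the tricube
  # weight of the farthest neighbour is 0); floor the span accordingly
  span <- min(1, max(span, 4.5 / length(qc_order)))
  fit0 <- stats::lowess(qc_order, qc_int, f = span, iter = 0)
  # robustness iterations degenerate when the plain fit is already exact
  # (residual MAD of 0); keep the plain fit in that case
  resid_scale <- max(abs(fit0$y - qc_int[order(qc_order)]))
  fit <- if (resid_scale < 1e-8 * max(abs(qc_int)) || iter == 0L) fit0
  else stats::lowess(qc_order, qc_int, f = span, iter = iter)
  x <- fit$x; y <- fit$y
  if (length(unique(x)) < 2L) return(rep(mean(y), length(all_order)))
  out <- stats::approx(x, y, xout = all_order, rule = 1, ties = mean)$y
  lo <- all_order < min(x); hi <- all_order > max(x)
  if (any(lo)) {
    s <- (y[2] - y[1]) / (x[2] - x[1])
    out[lo] <- y[1] + s * (all_order[lo] - x[1])
  }
  if (any(hi)) {
    n <- length(x)
    s <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
    out[hi] <- y[n] + s * (all_order[hi] - x[n])
  }
  out
}

#' Correct injection-order signal drift using QC injections
#'
#' Per feature, fits a robust locally weighted regression (LOESS, two
#' robustness iterations) of QC intensity against injection order,
#' evaluates the fit at every injection's order (linear
#' interpolation/extrapolation between QC orders), and divides each
#' intensity by fit/mean(fit over QCs), preserving the original scale.
#' Features whose fit is non-positive anywhere are left uncorrected with
#' a message.
#'
#' @param ft A [feature_table()] in state \code{"raw"}.
#' @param span LOESS smoothing span in (0, 1] (default 0.5).
#' @return Feature table in state \code{"drift_corrected"}.
#' @export
lowess_drift_correct <- function(ft, span = 0.5) {
  if (ft$state != "raw")
    stop("drift correction expects state 'raw', got '", ft$state, "'")
  qc <- ft_cols(ft, "qc")
  if (length(qc) < 5L)
    stop("drift correction needs at least 5 QC injections, found ", length(qc))
  qc_order <- ft$meta$order[qc]
  all_order <- ft$meta$order
  n_fallback <- 0L
  for (i in seq_len(nrow(ft$intensities))) {
    fit <- drift_fit_eval(qc_order, ft$intensities[i, qc], all_order, span)
    ref <- mean(fit[qc])
    if (any(fit <= 0) || !is.finite(ref) || ref <= 0) {
      n_fallback <- n_fallback + 1L
      next
    }
    ft$intensities[i, ] <- ft$intensities[i, ] / (fit / ref)
  }
  if (n_fallback > 0L)
    message(n_fallback, " feature(s) left uncorrected (non-positive drift fit)")
  ft$state <- "drift_corrected"
  ft
}

#' Normalize sample intensities by injected protein amount
#'
#' Amount = peak intensity / protein injected (micrograms), per sample
#' column. QC and blank columns have no protein value and are left
#' unscaled; they are ignored by downstream statistics.
#'
#' @param ft A [feature_table()] in state \code{"drift_corrected"} (or
#'   \code{"raw"} if the drift stage was skipped).
#' @return Feature table in state \code{"protein_normalized"}.
#' @export
protein_normalize <- function(ft) {
  if (!ft$state %in% c("raw", "drift_corrected"))
    stop("protein normalization expects state raw/drift_corrected, got '",
         ft$state, "'")
  sa <- ft_cols(ft, "sample")
  prot <- ft$meta$protein_ug[sa]
  if (any(is.na(prot) | prot <= 0))
    stop("protein_ug missing or non-positive for sample injection(s): ",
         paste(ft$meta$injection_id[sa][is.na(prot) | prot <= 0], collapse = ", "))
  ft$intensities[, sa] <- sweep(ft$intensities[, sa, drop = FALSE], 2, prot, "/")
  ft$state <- "protein_normalized"
  ft
}

#' Normalize each injection by its total ion count
#'
#' Divides every column by its sum and rescales by the mean column sum,
#' so post-normalization column sums are all equal and the overall scale
#' is preserved.
#'
#' @param ft A [feature_table()] in state raw or drift_corrected.
#' @return Feature table in state \code{"tic_normalized"}.
#' @export
tic_normalize <- function(ft) {
  if (!ft$state %in% c("raw", "drift_corrected"))
    stop("TIC normalization expects state raw/drift_corrected, got '",
         ft$state, "'")
  cs <- colSums(ft$intensities)
  if (any(cs == 0))
    stop("zero total ion count for injection(s): ",
         paste(ft$meta$injection_id[cs == 0], collapse = ", "))
  ft$intensities <- sweep(ft$intensities, 2, cs / mean(cs), "/")
  ft$state <- "tic_normalized"
  ft
}

#' Sum isomeric duplicate features
#'
#' Features sharing an identical sum composition (class + total carbons +
#' total double bonds + ether linkage) are merged by summing their
#' intensity rows; positional isomers cannot be distinguished in this
#' kind of experiment. The m/z, retention time, name and id score of the
#' most intense member are retained. Unannotated features are never
#' merged.
#'
#' @param ft A [feature_table()].
#' @return Feature table with isomers collapsed.
#' @export
sum_isomers <- function(ft) {
  f <- ft$features
  key <- ifelse(f$annotated,
                paste(f$lipid_class, f$total_carbons, f$total_double_bonds,
                      f$ether_linkage, sep = "|"),
                paste0("unann|", seq_len(nrow(f))))
  if (!anyDuplicated(key)) return(ft)
  tot <- rowSums(ft$intensities)
  ord <- order(-tot)  # representative = most intense member
  first_of_key <- ord[!duplicated(key[ord])]
  rep_idx <- first_of_key[match(key, key[first_of_key])]
  new_int <- rowsum(ft$intensities, group = key, reorder = FALSE)
  keys_out <- rownames(new_int)
  reps <- rep_idx[match(keys_out, key)]
  ft$features <- f[reps, , drop = FALSE]
  rownames(ft$features) <- NULL
  rownames(new_int) <- ft$features$feature_id
  ft$intensities <- new_int
  message(nrow(f) - length(keys_out), " isomeric duplicate row(s) merged")
  ft
}

#' Exclude chemically implausible annotated lipids
#'
#' Drops annotated features with more than \code{max_db} double bonds or,
#' when \code{drop_odd}, an odd total carbon number (odd-chain fatty
#' acids are rare in mammalian cells and usually reflect
#' misidentification). Unannotated features are untouched.
#'
#' @param ft A [feature_table()].
#' @param max_db Maximum plausible total double bonds (default 12).
#' @param drop_odd Drop odd-chain annotations (default TRUE).
#' @return Filtered feature table.
#' @export
exclude_implausible <- function(ft, max_db = 12, drop_odd = TRUE) {
  f <- ft$features
  drop <- f$annotated & (f$total_double_bonds > max_db |
                           (drop_odd & f$odd_chain))
  message(sum(drop), " implausible annotated feature(s) excluded")
  ft_subset_features(ft, !drop)
}

#' Per-class summed amounts with group comparison
#'
#' For each lipid class, the class amount in an injection is the sum of
#' the member feature amounts. Per-group means, the class fold change
#' (case/control) and a two-tailed unpaired t-test on the per-sample
#' class amounts are reported. Unannotated features are excluded.
#'
#' @param ft A normalized [feature_table()] (state protein_normalized or
#'   tic_normalized).
#' @param case,control Group labels; default: first two group labels in
#'   metadata order, case first.
#' @param var_equal Pooled-variance t-test if TRUE (default); Welch
#'   otherwise.
#' @return data.frame with one row per class: \code{lipid_class} (display
#'   label), \code{n_features}, \code{amount_case}, \code{amount_control},
#'   \code{class_fold_change}, \code{t_p_value}.
#' @export
class_totals <- function(ft, case = NULL, control = NULL, var_equal = TRUE) {
  if (!ft$state %in% c("protein_normalized", "tic_normalized"))
    stop("class_totals expects a normalized table, state is '", ft$state, "'")
  sa <- ft_cols(ft, "sample")
  groups <- ft$meta$group[sa]
  gl <- sort(unique(groups[nzchar(groups)]))
  if (is.null(case)) case <- gl[1]
  if (is.null(control)) control <- gl[2]
  ann <- ft$features$annotated
  if (!any(ann)) stop("no annotated features for class aggregation")
  cls <- ft$features$lipid_class[ann]
  amt <- rowsum(ft$intensities[ann, sa, drop = FALSE], group = cls)
  ci <- groups == case
  ki <- groups == control
  res <- lapply(rownames(amt), function(cl) {
    a <- amt[cl, ci]; b <- amt[cl, ki]
    p <- if (length(a) >= 2 && length(b) >= 2 &&
             (stats::sd(a) > 0 || stats::sd(b) > 0))
      stats::t.test(a, b, var.equal = var_equal)$p.value else NA_real_
    data.frame(lipid_class = class_label(cl),
               n_features = sum(cls == cl),
               amount_case = mean(a), amount_control = mean(b),
               class_fold_change = mean(a) / mean(b),
               t_p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out[order(-out$amount_case), , drop = FALSE]
}

#' Coefficient-of-variation profile of a stratum of injections
#'
#' Computes per-feature CV\% across a chosen stratum (a role such as
#' \code{"qc"}, or a sample group label) and the percentage of features
#' with CV below \code{threshold} ("acceptable features"). Comparing this
#' profile between normalization states shows whether a normalization
#' helps or hurts precision.
#'
#' @param ft A [feature_table()].
#' @param stratum Role (\code{"sample"}, \code{"qc"}, \code{"blank"}) or a
#'   group label.
#' @param threshold Acceptability threshold in CV\% (default 30).
#' @return List of class \code{cv_profile}: \code{group_label},
#'   \code{cv_values} (per-feature CV\%, NA where undefined),
#'   \code{pct_acceptable}, \code{threshold}.
#' @export
cv_profile <- function(ft, stratum = "qc", threshold = 30) {
  idx <- if (stratum %in% c("sample", "qc", "blank")) ft_cols(ft, stratum)
  else which(ft$meta$group == stratum & ft$meta$role == "sample")
  if (length(idx) < 3L)
    stop("stratum '", stratum, "' has ", length(idx),
         " injection(s); need at least 3")
  x <- ft$intensities[, idx, drop = FALSE]
  mu <- rowMeans(x)
  cv <- ifelse(mu > 0, 100 * apply(x, 1, stats::sd) / mu, NA_real_)
  ok <- !is.na(cv)
  structure(list(group_label = stratum, cv_values = cv,
                 pct_acceptable = 100 * sum(cv[ok] < threshold) / sum(ok),
                 threshold = threshold),
            class = "cv_profile")
}

#' @export
print.cv_profile <- function(x, ...) {
  cat(sprintf("cv_profile [%s]: %d features, %.1f%% acceptable (CV < %g%%), median CV %.1f%%\n",
              x$group_label, length(x$cv_values), x$pct_acceptable,
              x$threshold, stats::median(x$cv_values, na.rm = TRUE)))
  invisible(x)
}
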