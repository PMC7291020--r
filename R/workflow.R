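# End-to-end orchestration: preprocess -> discover -> enrich, with a
# provenance report recording the feature-count funnel and parameters.

#' Extract the sample-only amount matrix and group labels
#'
#' QC and blank columns carry no protein value and are excluded from
#' statistics; this helper pulls the sample columns and their groups.
#'
#' @param ft a [feature_table()].
#' @return list with \code{amounts} (features x samples matrix) and
#'   \code{groups} (character vector).
#' @export
sample_amounts <- function(ft) {
  sa <- ft_cols(ft, "sample")
  list(amounts = ft$intensities[, sa, drop = FALSE],
       groups = ft$meta$group[sa])
}

#' Default workflow configuration
#'
#' @return named list of all tunable parameters with their defaults:
#'   blank_min_fold 10, qc_max_cv 30, lowess_span 0.5, normalization
#'   "protein", max_double_bonds 12, drop_odd_chain TRUE,
#'   iqr_keep_fraction 0.75, fc_min 2, q_max 0.05, vip_min 1,
#'   n_components 2, if_p "q_fdr" (which p enters the impact factor),
#'   var_equal TRUE, top_n 100, run_enrichment TRUE.
#' @export
default_config <- function() {
  list(blank_min_fold = 10, qc_max_cv = 30, lowess_span = 0.5,
       normalization = "protein", max_double_bonds = 12,
       drop_odd_chain = TRUE, iqr_keep_fraction = 0.75,
       fc_min = 2, q_max = 0.05, vip_min = 1, n_components = 2,
       if_p = "q_fdr", var_equal = TRUE, top_n = 100,
       run_enrichment = TRUE, skip_blank_filter = FALSE,
       skip_drift_correction = FALSE)
}

#' Run the complete workflow on a feature table
#'
#' Executes the pipeline in a fixed order: blank filter, QC CV filter,
#' LOESS drift correction, protein (or TIC) normalization, isomer
#' summation, implausible-lipid exclusion, class totals; then IQR
#' filter, glog + autoscale, differential tests, volcano selection,
#' PLS-DA with VIP and leave-one-out validation, impact factors,
#' combined selection, class-median-IF discrimination, top
#' discriminants; then (optionally) ranked enrichment and composition
#' profiles. Returns all result tables plus a provenance report whose
#' stage-survival counts are non-increasing by construction.
#'
#' @param ft a raw [feature_table()].
#' @param config list as from [default_config()]; partial lists are
#'   merged over the defaults.
#' @param mapping optional term mapping for enrichment (default
#'   [demo_term_mapping()]).
#' @param out optional directory; when given, results are written as
#'   delimited text plus \code{report.json}.
#' @return list with \code{stats}, \code{classes}, \code{model}
#'   (\code{r2}, \code{q2}), \code{class_if}, \code{top},
#'   \code{enrichment}, \code{composition}, \code{report}.
#' @export
run_workflow <- function(ft, config = list(), mapping = NULL, out = NULL) {
  cfg <- utils::modifyList(default_config(), config)
  report <- list(package_version = as.character(utils::packageVersion("lipidflow")),
                 config = cfg, funnel = list())
  note <- function(stage, ftab) {
    report$funnel[[stage]] <<- nrow(ftab$features)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  note("input", ft)
  if (!cfg$skip_blank_filter && any(ft$meta$role == "blank")) {
    ft <- stage("blank_filter", blank_filter(ft, cfg$blank_min_fold))
    note("blank_filter", ft)
  }
  ft <- stage("qc_cv_filter", qc_cv_filter(ft, cfg$qc_max_cv))
  note("qc_cv_filter", ft)
  if (!cfg$skip_drift_correction && sum(ft$meta$role == "qc") >= 5) {
    ft <- stage("drift_correction", lowess_drift_correct(ft, cfg$lowess_span))
  }
  ft <- stage("normalization", switch(cfg$normalization,
                                      protein = protein_normalize(ft),
                                      tic = tic_normalize(ft),
                                      none = ft,
                                      stop("unknown normalization: ",
                                           cfg$normalization)))
  ft <- stage("sum_isomers", sum_isomers(ft))
  note("sum_isomers", ft)
  ft <- stage("exclude_implausible",
              exclude_implausible(ft, cfg$max_double_bonds, cfg$drop_odd_chain))
  note("exclude_implausible", ft)
  classes <- stage("class_totals",
                   class_totals(ft, var_equal = cfg$var_equal))

  sa <- sample_amounts(ft)
  X <- stage("iqr_filter", iqr_filter(sa$amounts, cfg$iqr_keep_fraction))
  report$funnel[["iqr_filter"]] <- nrow(X)
  Z <- stage("glog_autoscale", glog_autoscale(X))
  st <- stage("differential_test",
              differential_test(X, sa$groups, transformed = Z,
                                var_equal = cfg$var_equal))
  st <- volcano_select(st, cfg$fc_min, cfg$q_max)
  model <- stage("plsda", plsda_fit(t(Z), sa$groups, cfg$n_components))
  st$vip <- vip_scores(model)
  cvr <- stage("crossvalidation",
               suppressWarnings(crossvalidate(t(Z), sa$groups,
                                              cfg$n_components)))
  p_for_if <- if (cfg$if_p == "q_fdr") st$q_fdr else st$p_raw
  st$impact_factor <- impact_factor(st$log2_fc, p_for_if, st$vip)
  st <- combined_select(st, cfg$vip_min)
  report$funnel[["volcano_selected"]] <- sum(st$selected_volcano, na.rm = TRUE)
  report$funnel[["combined_selected"]] <- sum(st$selected_combined, na.rm = TRUE)

  fmatch <- match(st$feature_id, ft$features$feature_id)
  st$lipid_class <- ft$features$lipid_class[fmatch]
  st$name <- ft$features$name[fmatch]
  sel <- st[st$selected_combined, , drop = FALSE]
  class_if <- if (any(!is.na(sel$lipid_class)))
    class_if_discrimination(sel) else NULL
  top <- top_discriminants(if (nrow(sel)) sel else st,
                           min(cfg$top_n, max(nrow(sel), 1L)))

  enr <- NULL; comp <- NULL
  if (isTRUE(cfg$run_enrichment)) {
    ann <- parse_lipid_names(st$name)
    keep <- ann$annotated
    if (sum(keep) >= 10) {
      if (is.null(mapping)) mapping <- demo_term_mapping()
      enr <- tryCatch(suppressWarnings(
        ranked_enrichment(st$impact_factor[keep],
                          ann[keep, , drop = FALSE], mapping)),
        error = function(e) NULL)
      top_ann <- parse_lipid_names(top$name)
      comp <- tryCatch(list(
        top = composition_profile(top_ann),
        all = composition_profile(ann),
        tests = composition_tests(composition_profile(top_ann),
                                  composition_profile(ann))),
        error = function(e) NULL)
    }
  }
  model_summary <- list(r2 = cvr$r2, q2 = cvr$q2,
                        n_components = model$n_components,
                        cutoff = if (!is.null(class_if)) class_if$cutoff
                        else NA_real_)
  report$model <- model_summary

  res <- list(stats = st, classes = classes, model = model_summary,
              class_if = class_if, top = top, enrichment = enr,
              composition = comp, report = report, table = ft)
  if (!is.null(out)) {
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    cls_out <- if (!is.null(class_if)) {
      merge(classes, class_if$classes[c("lipid_class", "median_if",
                                        "passes_cutoff")],
            by = "lipid_class", all.x = TRUE)
    } else classes
    write_results(st, cls_out, out)
    jsonlite::write_json(
      list(r2 = cvr$r2, q2 = cvr$q2,
           funnel = report$funnel, config = cfg),
      file.path(out, "report.json"), auto_unbox = TRUE, digits = NA)
    if (!is.null(enr))
      utils::write.table(enr, file.path(out, "enrichment.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
  }
  res
}
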