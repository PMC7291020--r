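#' Construct a feature table
#'
#' The central container of the workflow: a dense non-negative intensity
#' matrix (features x injections) together with per-feature descriptors
#' (m/z, retention time, annotation, identification score) and
#' per-injection metadata (role, group, injection order, protein amount).
#'
#' @param features data.frame with columns \code{feature_id}, \code{mz},
#'   \code{rt}, \code{name}, \code{id_score}. Annotations are parsed on
#'   construction (columns \code{lipid_class}, \code{total_carbons},
#'   \code{total_double_bonds}, \code{ether_linkage}, \code{odd_chain},
#'   \code{annotated} are added).
#' @param meta data.frame with columns \code{injection_id}, \code{role}
#'   (one of sample/qc/blank), \code{group} (empty for qc/blank),
#'   \code{order} (unique positive integers), \code{protein_ug}
#'   (positive, required for samples).
#' @param intensities numeric matrix, rows matching \code{features},
#'   columns matching \code{meta$injection_id}.
#' @param state normalization state; one of \code{"raw"},
#'   \code{"drift_corrected"}, \code{"protein_normalized"},
#'   \code{"tic_normalized"}.
#' @return Object of class \code{feature_table}.
#' @export
feature_table <- function(features, meta, intensities, state = "raw") {
  stopifnot(is.data.frame(features), is.data.frame(meta))
  req_f <- c("feature_id", "mz", "rt", "name", "id_score")
  missing_f <- setdiff(req_f, names(features))
  if (length(missing_f))
    stop("feature table missing columns: ", paste(missing_f, collapse = ", "))
  req_m <- c("injection_id", "role", "group", "order", "protein_ug")
  missing_m <- setdiff(req_m, names(meta))
  if (length(missing_m))
    stop("metadata missing columns: ", paste(missing_m, collapse = ", "))

  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  if (nrow(intensities) != nrow(features) || ncol(intensities) != nrow(meta))
    stop(sprintf("intensity matrix is %d x %d but there are %d features and %d injections",
                 nrow(intensities), ncol(intensities), nrow(features), nrow(meta)))
  if (anyNA(intensities))
    stop("non-numeric or missing intensity values after coercion")
  if (any(intensities < 0))
    stop("negative intensities are not allowed")
  if (anyDuplicated(meta$order))
    stop("duplicate injection order values: ",
         paste(unique(meta$order[duplicated(meta$order)]), collapse = ", "))
  if (anyDuplicated(meta$injection_id))
    stop("duplicate injection ids")
  bad_role <- setdiff(unique(meta$role), c("sample", "qc", "blank"))
  if (length(bad_role))
    stop("unknown injection role(s): ", paste(bad_role, collapse = ", "))
  is_sample <- meta$role == "sample"
  if (any(is_sample & (is.na(meta$protein_ug) | meta$protein_ug <= 0)))
    stop("every sample injection needs protein_ug > 0")
  state <- match.arg(state, c("raw", "drift_corrected",
                              "protein_normalized", "tic_normalized"))

  if (!"annotated" %in% names(features)) {
    ann <- parse_lipid_names(features$name)
    features <- cbind(features,
                      ann[c("annotated", "lipid_class", "total_carbons",
                            "total_double_bonds", "ether_linkage", "odd_chain")])
  }
  rownames(intensities) <- features$feature_id
  colnames(intensities) <- meta$injection_id

  structure(list(features = features, meta = meta,
                 intensities = intensities, state = state),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d features x %d injections (%d sample, %d qc, %d blank), state = %s\n",
              nrow(x$features), nrow(x$meta),
              sum(x$meta$role == "sample"), sum(x$meta$role == "qc"),
              sum(x$meta$role == "blank"), x$state))
  cat(sprintf("  annotated features: %d\n", sum(x$features$annotated)))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$intensities)

# internal: subset rows (features), revalidating nothing heavy
ft_subset_features <- function(ft, keep) {
  ft$features <- ft$features[keep, , drop = FALSE]
  ft$intensities <- ft$intensities[keep, , drop = FALSE]
  rownames(ft$features) <- NULL
  ft
}

# internal: column indices by role
ft_cols <- function(ft, role) which(ft$meta$role == role)

#' Read a feature table and its injection metadata from delimited text
#'
#' Reads an alignment-export style table (columns \code{feature_id},
#' \code{mz}, \code{rt}, \code{name}, \code{id_score}, then one intensity
#' column per injection) plus a metadata table (\code{injection_id},
#' \code{role}, \code{group}, \code{order}, \code{protein_ug}). The
#' delimiter (tab or comma) is auto-detected from the header line.
#' Intensity columns must match metadata injection ids exactly; missing
#' intensity cells are read as 0 with a message.
#'
#' @param table_path Path to the feature table.
#' @param meta_path Path to the metadata table.
#' @return A [feature_table()] with state \code{"raw"}.
#' @export
read_feature_table <- function(table_path, meta_path) {
  tab <- read_delim_auto(table_path)
  meta <- read_delim_auto(meta_path)
  req_f <- c("feature_id", "mz", "rt", "name", "id_score")
  missing_f <- setdiff(req_f, names(tab))
  if (length(missing_f))
    stop("feature table missing columns: ", paste(missing_f, collapse = ", "))
  int_cols <- setdiff(names(tab), req_f)
  missing_in_meta <- setdiff(int_cols, meta$injection_id)
  if (length(missing_in_meta))
    stop("intensity column(s) absent from metadata: ",
         paste(missing_in_meta, collapse = ", "))
  missing_in_tab <- setdiff(meta$injection_id, int_cols)
  if (length(missing_in_tab))
    stop("metadata injection(s) absent from feature table: ",
         paste(missing_in_tab, collapse = ", "))

  m <- as.matrix(tab[, meta$injection_id, drop = FALSE])
  suppressWarnings(storage.mode(m) <- "double")
  n_na <- sum(is.na(m))
  if (n_na > 0) {
    raw <- as.matrix(tab[, meta$injection_id, drop = FALSE])
    non_empty_na <- is.na(m) & !(is.na(raw) | raw == "")
    if (any(non_empty_na))
      stop("non-numeric intensity value(s), e.g. '",
           raw[which(non_empty_na)[1]], "'")
    message(n_na, " missing intensity value(s) read as 0")
    m[is.na(m)] <- 0
  }
  meta$group[is.na(meta$group)] <- ""
  meta$order <- as.integer(meta$order)
  meta$protein_ug <- suppressWarnings(as.numeric(meta$protein_ug))
  feature_table(tab[req_f], meta, m, state = "raw")
}

# internal delimiter sniffing: tab wins if present in the header
read_delim_auto <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  hdr <- readLines(path, n = 1L)
  sep <- if (grepl("\t", hdr)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    comment.char = "", na.strings = c("NA", ""))
}

#' Write per-feature statistics and class summaries as delimited text
#'
#' Writes \code{features.tsv} (one row per feature, stable column order)
#' and \code{classes.tsv} under \code{dir}. Numbers are serialized at full
#' precision so a read-back round-trips bit-for-bit.
#'
#' @param stats data.frame of per-feature statistics (see
#'   [differential_test()] / [impact_factor()]).
#' @param summaries data.frame of class summaries (may have zero rows);
#'   see [class_totals()].
#' @param dir Output directory, created if needed.
#' @return Invisibly, the paths written.
#' @export
write_results <- function(stats, summaries, dir) {
  if (nrow(stats) == 0L) stop("no feature statistics to write")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- file.path(dir, "features.tsv")
  cp <- file.path(dir, "classes.tsv")
  write_tsv_full <- function(df, path) {
    num <- vapply(df, is.double, logical(1))
    df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  write_tsv_full(stats, fp)
  write_tsv_full(summaries, cp)
  invisible(c(features = fp, classes = cp))
}

#' Write a feature table and metadata as delimited text
#'
#' Inverse of [read_feature_table()]: emits \code{features.tsv} and
#' \code{meta.tsv} under \code{dir} at full numeric precision.
#'
#' @param ft A [feature_table()].
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_feature_table <- function(ft, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tab <- ft$features[c("feature_id", "mz", "rt", "name", "id_score")]
  tab$mz <- sprintf("%.17g", tab$mz)
  tab$rt <- sprintf("%.17g", tab$rt)
  ints <- as.data.frame(apply(ft$intensities, 2, function(x) sprintf("%.17g", x)),
                        check.names = FALSE, stringsAsFactors = FALSE)
  out <- cbind(tab, ints)
  meta <- ft$meta
  meta$protein_ug <- ifelse(is.na(meta$protein_ug), "",
                            sprintf("%.17g", meta$protein_ug))
  fp <- file.path(dir, "features.tsv")
  mp <- file.path(dir, "meta.tsv")
  utils::write.table(out, fp, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(meta, mp, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(features = fp, meta = mp))
}
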