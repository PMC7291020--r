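# Hand-built fixtures: tiny feature tables with fully controlled values.

make_meta <- function(roles, groups = NULL, protein = NULL) {
  n <- length(roles)
  if (is.null(groups)) groups <- ifelse(roles == "sample", "case", "")
  if (is.null(protein)) protein <- ifelse(roles == "sample", 10, NA_real_)
  data.frame(
    injection_id = sprintf("inj%02d", seq_len(n)),
    role = roles, group = groups, order = seq_len(n),
    protein_ug = protein, stringsAsFactors = FALSE
  )
}

make_ft <- function(intensities, roles, names = NULL, groups = NULL,
                    protein = NULL, state = "raw") {
  intensities <- as.matrix(intensities)
  nf <- nrow(intensities)
  if (is.null(names)) names <- sprintf("PC %d:2", seq(30, by = 2, length.out = nf))
  feats <- data.frame(
    feature_id = sprintf("F%03d", seq_len(nf)),
    mz = 500 + seq_len(nf), rt = 1 + 0.1 * seq_len(nf),
    name = names, id_score = 90, stringsAsFactors = FALSE
  )
  feature_table(feats, make_meta(roles, groups, protein), intensities,
                state = state)
}

# two-group meta shortcut: n case samples then n control samples
two_group_roles <- function(n_per_group, n_qc = 0, n_blank = 0) {
  list(
    roles = c(rep("blank", n_blank), rep("qc", n_qc),
              rep("sample", 2 * n_per_group)),
    groups = c(rep("", n_blank + n_qc),
               rep(c("case", "control"), each = n_per_group))
  )
}

quiet <- function(expr) suppressMessages(suppressWarnings(expr))
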