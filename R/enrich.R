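# Ranked term enrichment over a user-supplied term -> lipid mapping,
# plus acyl-chain saturation and ether/ester composition profiles.

#' Read a term mapping table
#'
#' TSV/CSV with columns \code{term_id}, \code{label}, \code{category},
#' \code{member_pattern}. A member pattern is either a lipid class code
#' (matches every lipid of that class) or a shorthand glob matched
#' against the annotation string (\code{*} wildcard). Multiple rows per
#' term accumulate members.
#'
#' @param path file path.
#' @return data.frame of the mapping rows.
#' @export
read_term_mapping <- function(path) {
  m <- read_delim_auto(path)
  req <- c("term_id", "label", "category", "member_pattern")
  missing <- setdiff(req, names(m))
  if (length(missing))
    stop("term mapping missing columns: ", paste(missing, collapse = ", "))
  m
}

#' Built-in demonstration term mapping
#'
#' A small class-based mapping in the style of a lipid ontology
#' (membrane component / organelle / physical-property terms over class
#' codes). Ships for tests and examples; real analyses should supply a
#' curated mapping.
#'
#' @return data.frame usable wherever a term mapping is expected.
#' @export
demo_term_mapping <- function() {
  rbind(
    data.frame(term_id = "T_membrane", label = "plasma membrane component",
               category = "cellular component",
               member_pattern = c("PC", "PE", "PS", "SM", "CL"),
               stringsAsFactors = FALSE),
    data.frame(term_id = "T_er", label = "endoplasmic reticulum",
               category = "cellular component",
               member_pattern = c("PC", "PI", "CE"), stringsAsFactors = FALSE),
    data.frame(term_id = "T_mito", label = "mitochondrion",
               category = "cellular component",
               member_pattern = c("CL", "PG", "PE"), stringsAsFactors = FALSE),
    data.frame(term_id = "T_storage", label = "lipid storage",
               category = "lipid function",
               member_pattern = c("TG", "DG", "CE"), stringsAsFactors = FALSE),
    data.frame(term_id = "T_sphingo", label = "sphingolipid signalling",
               category = "lipid function",
               member_pattern = c("Cer", "HexCer", "Hex2Cer", "GM3", "SM"),
               stringsAsFactors = FALSE),
    data.frame(term_id = "T_ether", label = "ether-linked phospholipid",
               category = "physical-chemical properties",
               member_pattern = c("PC O-*", "PC P-*", "PE O-*", "PE P-*"),
               stringsAsFactors = FALSE)
  )
}

# internal: resolve one pattern against annotations (data.frame from
# parse_lipid_names, plus raw_name). Class codes match the parsed class;
# anything containing glob metacharacters or whitespace matches raw_name.
resolve_pattern <- function(pattern, ann) {
  if (pattern %in% LIPID_CLASSES && !grepl("[*? ]", pattern)) {
    which(ann$annotated & ann$lipid_class == pattern)
  } else {
    rx <- utils::glob2rx(pattern)
    which(grepl(rx, ann$raw_name))
  }
}

#' Ranked enrichment over a term mapping
#'
#' For each term, a one-tailed Welch two-sample t-test compares the
#' ranking statistic of member lipids against non-members (alternative:
#' members rank higher). p-values are BH-corrected across terms; terms
#' with q < 0.05 are flagged enriched. Terms resolving fewer than
#' \code{min_members} lipids are dropped with a warning.
#'
#' @param ranking numeric vector of per-lipid statistics (e.g. the
#'   impact factor), named or aligned with \code{annotations}.
#' @param annotations data.frame from [parse_lipid_names()] (one row per
#'   lipid, aligned with \code{ranking}).
#' @param mapping data.frame in the layout of [demo_term_mapping()].
#' @param min_members minimum resolvable members per term (default 3).
#' @return data.frame sorted by q: \code{term_id}, \code{label},
#'   \code{category}, \code{n_members}, \code{t_stat}, \code{p},
#'   \code{q_fdr}, \code{enriched}.
#' @export
ranked_enrichment <- function(ranking, annotations, mapping,
                              min_members = 3L) {
  if (length(ranking) < 10L)
    stop("ranking must cover at least 10 lipids")
  if (length(ranking) != nrow(annotations))
    stop("ranking and annotations are not aligned")
  terms <- unique(mapping$term_id)
  rows <- list()
  for (tid in terms) {
    sub <- mapping[mapping$term_id == tid, , drop = FALSE]
    idx <- sort(unique(unlist(lapply(sub$member_pattern, resolve_pattern,
                                     ann = annotations))))
    if (length(idx) < min_members || length(idx) > length(ranking) - 2L) {
      warning("term ", tid, " dropped: ", length(idx), " resolvable member(s)")
      next
    }
    tt <- stats::t.test(ranking[idx], ranking[-idx],
                        alternative = "greater", var.equal = FALSE)
    rows[[tid]] <- data.frame(term_id = tid, label = sub$label[1],
                              category = sub$category[1],
                              n_members = length(idx),
                              t_stat = unname(tt$statistic),
                              p = tt$p.value, stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no resolvable terms")
  out <- do.call(rbind, rows)
  out$q_fdr <- stats::p.adjust(out$p, method = "BH")
  out$enriched <- out$q_fdr < 0.05
  out <- out[order(out$q_fdr, out$p), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Saturation and linkage composition of an annotated lipid set
#'
#' Classifies each annotated lipid as SFA (0 double bonds), MUFA (1) or
#' PUFA (>= 2) and, among glycerophospholipids, as ether- or
#' ester-linked. Percentages are over lipid species.
#'
#' @param annotations data.frame from [parse_lipid_names()]; unannotated
#'   rows are ignored.
#' @return list with \code{saturation} (data.frame bucket/count/pct) and
#'   \code{linkage} (data.frame over glycerophospholipids).
#' @export
composition_profile <- function(annotations) {
  ann <- annotations[annotations$annotated, , drop = FALSE]
  if (nrow(ann) == 0L) stop("no annotated lipids in subset")
  sat <- cut(ann$total_double_bonds, breaks = c(-1, 0, 1, Inf),
             labels = c("SFA", "MUFA", "PUFA"))
  sat_counts <- table(sat)
  gpl <- ann[ann$lipid_class %in% GPL_CLASSES, , drop = FALSE]
  link_counts <- c(ether = sum(gpl$ether_linkage != "none"),
                   ester = sum(gpl$ether_linkage == "none"))
  list(
    saturation = data.frame(bucket = names(sat_counts),
                            count = as.integer(sat_counts),
                            pct = 100 * as.integer(sat_counts) / nrow(ann),
                            stringsAsFactors = FALSE),
    linkage = data.frame(bucket = names(link_counts),
                         count = as.integer(link_counts),
                         pct = if (nrow(gpl)) 100 * as.integer(link_counts) / nrow(gpl)
                         else rep(NA_real_, 2),
                         stringsAsFactors = FALSE)
  )
}

#' Compare two composition profiles
#'
#' Saturation: chi-square goodness-of-fit of subset A's SFA/MUFA/PUFA
#' counts against subset B's proportions (falls back to a Monte-Carlo
#' exact test when any expected count is below 5 or an expected
#' proportion is zero with a nonzero observation). Linkage: exact
#' binomial test of A's ether count against B's ether proportion.
#'
#' @param profile_a,profile_b lists from [composition_profile()]; A is
#'   the subset of interest (e.g. top discriminants), B the reference.
#' @return list with \code{saturation_p} and \code{linkage_p}.
#' @export
composition_tests <- function(profile_a, profile_b) {
  oa <- profile_a$saturation$count
  pb <- profile_b$saturation$count / sum(profile_b$saturation$count)
  expected <- sum(oa) * pb
  use_exact <- any(expected < 5) || any(pb == 0 & oa > 0)
  sat_p <- if (any(pb == 0 & oa > 0)) {
    # zero expected proportion with nonzero observed: simulate from the
    # positive cells only after flooring proportions at a pseudo-count
    pb2 <- (profile_b$saturation$count + 0.5) /
      sum(profile_b$saturation$count + 0.5)
    stats::chisq.test(oa, p = pb2, simulate.p.value = TRUE, B = 5000)$p.value
  } else if (use_exact) {
    message("expected count < 5: Monte-Carlo exact test used for saturation")
    stats::chisq.test(oa, p = pb, simulate.p.value = TRUE, B = 5000)$p.value
  } else {
    stats::chisq.test(oa, p = pb)$p.value
  }
  la <- profile_a$linkage; lb <- profile_b$linkage
  n_eth <- la$count[la$bucket == "ether"]
  n_tot <- sum(la$count)
  p_ref <- lb$count[lb$bucket == "ether"] / sum(lb$count)
  link_p <- if (n_tot > 0 && is.finite(p_ref) && p_ref > 0 && p_ref < 1)
    stats::binom.test(n_eth, n_tot, p = p_ref)$p.value
  else NA_real_
  list(saturation_p = sat_p, linkage_p = link_p)
}
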