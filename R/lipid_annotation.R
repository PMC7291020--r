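#' Lipid classes recognized by the shorthand parser
#'
#' Class codes accepted by [parse_lipid_name()]. Covers the glycero- and
#' sphingolipid subclasses typical of an epithelial-cell lipidome plus
#' sterol esters, acylglycerols, free fatty acids, acylcarnitines and
#' cardiolipins. Anything else parses to an unannotated marker.
#'
#' @format Character vector of class codes.
#' @export
LIPID_CLASSES <- c(
  "Cer", "DhCer", "HexCer", "Hex2Cer", "GM3", "SM", "Sph",
  "PC", "PE", "PG", "PI", "PS", "PA", "LPC", "LPE", "LPG", "LPI", "LPS",
  "CL", "CE", "TG", "DG", "MG", "FA", "CAR", "ST"
)

# glycerophospholipid classes: the only ones where an ether (O-/P-) linkage
# is chemically meaningful
GPL_CLASSES <- c("PC", "PE", "PG", "PI", "PS", "PA",
                 "LPC", "LPE", "LPG", "LPI", "LPS", "CL")

#' Parse a lipid shorthand name
#'
#' Parses LIPID MAPS style shorthand annotations as emitted by common
#' alignment software. Both sum-composition names (\code{"PC 34:2"}) and
#' chain-resolved names (\code{"PC 16:0_18:2"}, \code{"Cer 18:1;2O/16:0"})
#' are accepted; chain-resolved forms are collapsed to the sum composition
#' by adding carbons and double bonds. Ether linkages are recognized both
#' as \code{"O-"}/\code{"P-"} prefixes and as trailing \code{"e"}/\code{"p"}
#' suffixes (dialects differ between software versions). Hydroxylation
#' suffixes (\code{";2O"}, \code{";O2"}) are ignored for the sum
#' composition.
#'
#' The parser is total: any string it cannot interpret (including an
#' unknown class code) yields an unannotated marker rather than an error.
#'
#' @param name Character scalar, the shorthand annotation.
#' @return A list of class \code{lipid_annotation} with elements
#'   \code{raw_name}, \code{annotated} (logical), \code{lipid_class},
#'   \code{total_carbons}, \code{total_double_bonds}, \code{ether_linkage}
#'   (\code{"none"}, \code{"O"} or \code{"P"}) and \code{odd_chain}.
#' @examples
#' parse_lipid_name("PC O-34:2")
#' parse_lipid_name("Cer 18:1;2O/16:0")
#' parse_lipid_name("Unknown m/z 512.2")
#' @export
parse_lipid_name <- function(name) {
  unann <- structure(list(
    raw_name = as.character(name)[1], annotated = FALSE,
    lipid_class = NA_character_, total_carbons = NA_integer_,
    total_double_bonds = NA_integer_, ether_linkage = NA_character_,
    odd_chain = NA
  ), class = "lipid_annotation")
  if (length(name) != 1L || is.na(name) || !nzchar(trimws(name))) return(unann)
  s <- trimws(name)

  # "<Class> <rest>" or "<Class>(<rest>)"
  m <- regmatches(s, regexec("^([A-Za-z][A-Za-z0-9]*)[ (]\\s*(.+?)\\)?$", s))[[1]]
  if (length(m) != 3L) return(unann)
  cls <- m[2]
  rest <- m[3]
  if (!cls %in% LIPID_CLASSES) return(unann)

  ether <- "none"
  # prefix dialect: "O-34:2", "P-16:0/18:1"
  if (grepl("^O-", rest)) { ether <- "O"; rest <- sub("^O-", "", rest) }
  else if (grepl("^P-", rest)) { ether <- "P"; rest <- sub("^P-", "", rest) }

  chains <- strsplit(rest, "[/_]")[[1]]
  tot_c <- 0L
  tot_db <- 0L
  for (ch in chains) {
    ch <- trimws(ch)
    # per-chain ether prefix (chain-resolved plasmanyl/plasmenyl)
    if (grepl("^O-", ch)) { ether <- "O"; ch <- sub("^O-", "", ch) }
    else if (grepl("^P-", ch)) { ether <- "P"; ch <- sub("^P-", "", ch) }
    # strip hydroxyl/oxygen suffixes like ";2O", ";O2", ";(2OH)"
    ch <- sub(";.*$", "", ch)
    # suffix dialect: trailing e/p marks an ether lipid
    if (grepl("[0-9]e$", ch)) { ether <- "O"; ch <- sub("e$", "", ch) }
    else if (grepl("[0-9]p$", ch)) { ether <- "P"; ch <- sub("p$", "", ch) }
    cm <- regmatches(ch, regexec("^([0-9]+):([0-9]+)$", ch))[[1]]
    if (length(cm) != 3L) return(unann)
    tot_c <- tot_c + as.integer(cm[2])
    tot_db <- tot_db + as.integer(cm[3])
  }
  if (tot_c < tot_db) return(unann)
  if (ether != "none" && !cls %in% GPL_CLASSES) ether <- "none"

  structure(list(
    raw_name = s, annotated = TRUE, lipid_class = cls,
    total_carbons = tot_c, total_double_bonds = tot_db,
    ether_linkage = ether, odd_chain = (tot_c %% 2L == 1L)
  ), class = "lipid_annotation")
}

#' Parse a vector of lipid names into an annotation data frame
#'
#' @param names Character vector of shorthand annotations.
#' @return data.frame with one row per name and the fields of
#'   [parse_lipid_name()].
#' @export
parse_lipid_names <- function(names) {
  ann <- lapply(names, parse_lipid_name)
  data.frame(
    raw_name = vapply(ann, `[[`, character(1), "raw_name"),
    annotated = vapply(ann, `[[`, logical(1), "annotated"),
    lipid_class = vapply(ann, `[[`, character(1), "lipid_class"),
    total_carbons = vapply(ann, `[[`, integer(1), "total_carbons"),
    total_double_bonds = vapply(ann, `[[`, integer(1), "total_double_bonds"),
    ether_linkage = vapply(ann, `[[`, character(1), "ether_linkage"),
    odd_chain = vapply(ann, `[[`, logical(1), "odd_chain"),
    stringsAsFactors = FALSE
  )
}

#' Display label for a lipid class
#'
#' Hex2Cer (di-hexosylceramide) is reported as LacCer (lactosylceramide)
#' in summaries, the name in common use.
#'
#' @param cls Character vector of class codes.
#' @return Character vector of display labels.
#' @export
class_label <- function(cls) {
  ifelse(cls == "Hex2Cer", "LacCer", cls)
}

#' @export
print.lipid_annotation <- function(x, ...) {
  if (!x$annotated) {
    cat("<unannotated> ", x$raw_name, "\n", sep = "")
  } else {
    cat(sprintf("%s %d:%d%s%s  (%s)\n", x$lipid_class, x$total_carbons,
                x$total_double_bonds,
                if (x$ether_linkage == "none") "" else paste0(" ether-", x$ether_linkage),
                if (x$odd_chain) " odd-chain" else "", x$raw_name))
  }
  invisible(x)
}
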