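## Hierarchical phenotype calling from marker positivity flags.
##
## A rule tree is an ordered list of levels; each level holds ordered rules
## (label, boolean expression over positivity flags, parent label).  Within a
## level the first matching rule wins; children are evaluated only on cells
## carrying the parent's label.  A cell's final phenotype is the deepest
## label it attained, with "Other" as the fallback for cells matching no
## root-level rule.

#' Construct a phenotype rule tree
#'
#' @param levels a list; each element is a data.frame (or list of lists) with
#'   columns/fields \code{label}, \code{expr} and, for levels below the
#'   first, \code{parent}.  Expressions use marker names combined with
#'   \code{AND}/\code{OR}/\code{NOT} (or \code{&}/\code{|}/\code{!}) and
#'   parentheses, e.g. \code{"PD1 AND LAG3 AND NOT TIM3"}.
#' @param markers character vector of marker names the expressions may use.
#' @return an object of class \code{phenotype_rules}.
#' @export
phenotype_rules <- function(levels, markers) {
  lv <- lapply(levels, function(l) {
    if (!is.data.frame(l))
      l <- do.call(rbind, lapply(l, function(r)
        data.frame(label = r$label, expr = r$expr,
                   parent = r$parent %||% NA_character_,
                   stringsAsFactors = FALSE)))
    if (!"parent" %in% names(l)) l$parent <- NA_character_
    l$label <- as.character(l$label)
    l$expr <- as.character(l$expr)
    l$parent <- as.character(l$parent)
    l
  })
  exprs <- lapply(lv, function(l) lapply(l$expr, parse_rule_expr, markers = markers))
  structure(list(levels = lv, compiled = exprs, markers = markers),
            class = "phenotype_rules")
}

# Translate the AND/OR/NOT grammar into an R expression and verify that all
# symbols are known markers.
parse_rule_expr <- function(expr, markers) {
  txt <- gsub("\\bAND\\b", "&", expr, ignore.case = TRUE)
  txt <- gsub("\\bOR\\b", "|", txt, ignore.case = TRUE)
  txt <- gsub("\\bNOT\\b", "!", txt, ignore.case = TRUE)
  e <- tryCatch(str2lang(txt), error = function(err)
    stop_config("cannot parse rule expression: ", expr))
  syms <- all.vars(e)
  ops <- setdiff(all.names(e), syms)
  if (!all(ops %in% c("&", "|", "!", "(")))
    stop_config("rule expression uses a disallowed operator: ", expr)
  unknown <- setdiff(syms, markers)
  if (length(unknown))
    stop_config("rule expression references unknown marker(s): ",
                paste(unknown, collapse = ", "), " in: ", expr)
  e
}

#' @export
print.phenotype_rules <- function(x, ...) {
  cat("Phenotype rule tree:", length(x$levels), "level(s)\n")
  for (i in seq_along(x$levels)) {
    l <- x$levels[[i]]
    cat("  level", i, "\n")
    for (j in seq_len(nrow(l)))
      cat(sprintf("    %-32s <- %s%s\n", l$label[j], l$expr[j],
                  ifelse(is.na(l$parent[j]), "", paste0("  [under ", l$parent[j], "]"))))
  }
  invisible(x)
}

#' Assign hierarchical phenotype labels
#'
#' Evaluates the rule tree on the positivity flags of a gated cell table (the
#' \code{pos_<marker>} columns produced by [apply_gates()]).  Every cell
#' receives exactly one label: the deepest rule label it matched, or
#' \code{"Other"} if no root-level rule matched.
#'
#' @param cells gated cell table with \code{pos_<marker>} columns.
#' @param rules a [phenotype_rules()] object (default:
#'   [default_phenotype_rules()]).
#' @return character vector of labels, one per row of \code{cells}.
#' @export
classify_cells <- function(cells, rules = default_phenotype_rules()) {
  stopifnot(inherits(rules, "phenotype_rules"))
  pos_cols <- paste0("pos_", rules$markers)
  have <- pos_cols %in% names(cells)
  env_list <- stats::setNames(
    lapply(seq_along(rules$markers), function(i) {
      if (have[i]) as.logical(cells[[pos_cols[i]]]) else rep(FALSE, nrow(cells))
    }),
    rules$markers)
  used <- unique(unlist(lapply(rules$compiled, function(l) lapply(l, all.vars))))
  missing <- used[!used %in% rules$markers[have]]
  if (length(missing))
    stop_config("cell table lacks positivity column(s) for marker(s): ",
                paste(missing, collapse = ", "))
  n <- nrow(cells)
  label <- rep("Other", n)
  for (li in seq_along(rules$levels)) {
    lv <- rules$levels[[li]]
    assigned <- rep(FALSE, n)
    new_label <- label
    for (ri in seq_len(nrow(lv))) {
      eligible <- if (is.na(lv$parent[ri])) rep(TRUE, n) else label == lv$parent[ri]
      match <- eligible & !assigned &
        eval(rules$compiled[[li]][[ri]], envir = env_list)
      new_label[match] <- lv$label[ri]
      assigned <- assigned | match
    }
    label <- new_label
  }
  label
}

#' Shipped default phenotype rule tree
#'
#' Encodes the marker logic used throughout the package: tumor cells are
#' SOX10 and/or PMEL positive; immune cells root at CD45 with T/B/
#' macrophage/myeloid branches; CD8 T cells resolve into naive
#' (LEF1+CD45RA+), resident memory (CD45RO+CD103+), memory (CD45RO+),
#' terminally exhausted (PD1+LAG3+TIM3+), partially exhausted
#' (PD1+LAG3+TIM3-), proliferative cytotoxic (GZMB+KI67+) and cytotoxic
#' (GZMB+) states; Tregs are CD4+FOXP3+; endothelium is CD31+.  More
#' specific rules precede less specific ones so overlaps resolve
#' most-specific-first.
#'
#' @return a [phenotype_rules()] object.
#' @export
default_phenotype_rules <- function() {
  markers <- c("SOX10", "PMEL", "CD45", "CD3E", "CD8A", "CD4", "FOXP3",
               "LEF1", "CD45RA", "CD45RO", "CD103", "GZMB", "PD1", "LAG3",
               "TIM3", "KI67", "CD68", "CD163", "CD206", "CD11C", "CD20",
               "CD31")
  l1 <- data.frame(
    label = c("Tumor", "Immune", "Endothelial"),
    expr = c("SOX10 OR PMEL", "CD45", "CD31"),
    parent = NA_character_)
  l2 <- data.frame(
    label = c("T cell", "B cell", "Macrophage", "Myeloid"),
    expr = c("CD3E", "CD20", "CD68 OR CD163 OR CD206", "CD11C"),
    parent = "Immune")
  l3 <- data.frame(
    label = c("Treg", "CD8 T"),
    expr = c("CD4 AND FOXP3", "CD8A"),
    parent = "T cell")
  l4 <- data.frame(
    label = c("naive CD8 T", "resident memory CD8 T", "memory CD8 T",
              "terminally exhausted CD8 T", "partially exhausted CD8 T",
              "proliferative cytotoxic CD8 T", "cytotoxic CD8 T"),
    expr = c("LEF1 AND CD45RA", "CD45RO AND CD103", "CD45RO",
             "PD1 AND LAG3 AND TIM3", "PD1 AND LAG3 AND NOT TIM3",
             "GZMB AND KI67", "GZMB"),
    parent = "CD8 T")
  phenotype_rules(list(l1, l2, l3, l4), markers)
}

#' Read a phenotype rule tree from YAML
#'
#' Layout: a list of levels, each with a \code{rules} list of
#' \code{\{label, expr, parent\}} entries, plus a top-level \code{markers}
#' vector.
#'
#' @param path YAML file path.
#' @return a [phenotype_rules()] object.
#' @export
read_phenotype_rules <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$markers) || is.null(y$levels))
    stop_config("rule YAML needs 'markers' and 'levels' entries")
  phenotype_rules(lapply(y$levels, function(l) l$rules %||% l), unlist(y$markers))
}

#' Phenotype label fractions
#'
#' Fraction of cells carrying each phenotype label; the tumor fraction of a
#' specimen is \code{phenotype_fractions(labels)["Tumor"]}.
#'
#' @param phenotypes character vector of labels.
#' @return named numeric vector of fractions summing to 1.
#' @export
phenotype_fractions <- function(phenotypes) {
  if (!length(phenotypes)) stop("no cells")
  tab <- table(phenotypes)
  as.vector(tab) / length(phenotypes) -> fr
  stats::setNames(fr, names(tab))
}
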