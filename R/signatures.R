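## Microregional transcriptomic signature scoring and association tests.
##
## Counts are normalized by median-of-ratios size factors, log10(x + 1)
## transformed, and scored per microregion with single-sample gene-set
## enrichment (ssGSEA, Barbie-style rank-weighted running sum as implemented
## in GSVA, weight exponent alpha = 0.25).  Scores can be min-max or z
## scaled per set, correlated between signatures within compartment strata
## (two-sided Pearson), and compared between groups with the Mann-Whitney U
## rank test.

#' Median-of-ratios size-factor normalization
#'
#' Per-gene geometric means over microregions form the reference (genes with
#' a zero count in any microregion are excluded from the reference); the
#' size factor of a microregion is the median ratio of its counts to the
#' reference, and normalized counts are counts divided by the size factor.
#'
#' @param counts genes x microregions numeric matrix, counts >= 0.
#' @return list: \code{normalized} matrix, \code{size_factors} vector.
#' @export
size_factor_normalize <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2L) stop("need at least 2 microregions")
  if (any(counts < 0)) stop("counts must be non-negative")
  usable <- rowSums(counts > 0) == ncol(counts)
  if (!any(usable))
    stop("size-factor normalization impossible: no gene has nonzero counts ",
         "in every microregion")
  ref <- exp(rowMeans(log(counts[usable, , drop = FALSE])))
  sf <- apply(counts[usable, , drop = FALSE], 2,
              function(col) stats::median(col / ref))
  list(normalized = sweep(counts, 2, sf, "/"), size_factors = sf)
}

#' Log10 transform with pseudocount
#'
#' \code{log10(x + 1)}; errors on negative input.
#'
#' @param x numeric matrix or vector of normalized counts.
#' @return transformed object of the same shape.
#' @export
log_transform <- function(x) {
  if (any(x < 0)) stop("log_transform requires non-negative values")
  log10(x + 1)
}

# single-sample score for one expression vector and one member index set
ssgsea_score_vector <- function(expr, in_set, alpha) {
  n <- length(expr)
  r <- rank(expr, ties.method = "average")     # highest expression -> rank n
  ord <- order(r, seq_len(n), decreasing = TRUE)
  ind <- in_set[ord]
  w <- r[ord]^alpha * ind
  cdf_in <- cumsum(w) / sum(w)
  cdf_out <- cumsum(!ind) / sum(!ind)
  sum(cdf_in - cdf_out)
}

#' Single-sample gene-set enrichment (ssGSEA)
#'
#' Barbie-style running-sum score per microregion and gene set: genes are
#' ordered by expression (descending, average ranks for ties); the score is
#' the sum over the ordered list of the difference between the weighted
#' in-set empirical CDF (gene weight = rank-from-bottom raised to
#' \code{alpha}, normalized over set members) and the unweighted out-of-set
#' ECDF.
#'
#' @param expr genes x microregions expression matrix (rownames = gene ids),
#'   or a named vector for a single microregion.
#' @param gene_sets named list of gene-id vectors.
#' @param alpha rank weight exponent (default 0.25, the conventional ssGSEA
#'   setting).
#' @return sets x microregions score matrix.
#' @export
ssgsea <- function(expr, gene_sets, alpha = 0.25) {
  if (is.null(dim(expr))) expr <- matrix(expr, ncol = 1,
                                         dimnames = list(names(expr), "s1"))
  expr <- as.matrix(expr)
  if (is.null(rownames(expr))) stop("expression matrix needs gene rownames")
  if (nrow(expr) < 2L) stop("need at least 2 genes")
  genes <- rownames(expr)
  scores <- matrix(NA_real_, length(gene_sets), ncol(expr),
                   dimnames = list(names(gene_sets), colnames(expr)))
  for (s in seq_along(gene_sets)) {
    in_set <- genes %in% gene_sets[[s]]
    k <- sum(in_set)
    if (k == 0L)
      stop("gene set '", names(gene_sets)[s], "' shares no genes with the matrix")
    if (k == length(genes))
      stop("gene set '", names(gene_sets)[s],
           "' covers every gene; out-of-set ECDF is degenerate")
    for (j in seq_len(ncol(expr)))
      scores[s, j] <- ssgsea_score_vector(expr[, j], in_set, alpha)
  }
  scores
}

#' Scale signature scores per set
#'
#' @param scores sets x microregions matrix.
#' @param method \code{"minmax"} (to [0,1]; constant rows become 0.5) or
#'   \code{"zscore"} (mean 0, SD 1; constant rows become 0).
#' @return scaled matrix of the same shape.
#' @export
scale_scores <- function(scores, method = c("minmax", "zscore")) {
  method <- match.arg(method)
  scores <- as.matrix(scores)
  t(apply(scores, 1, function(v) {
    if (method == "minmax") {
      rng <- range(v)
      if (diff(rng) == 0) rep(0.5, length(v))
      else (v - rng[1]) / diff(rng)
    } else {
      s <- stats::sd(v)
      if (is.na(s) || s == 0) rep(0, length(v)) else (v - mean(v)) / s
    }
  }))
}

#' Compartment-stratified Pearson correlation
#'
#' Two-sided Pearson correlation of two score vectors within each stratum;
#' the p-value comes from the t statistic
#' \code{r * sqrt((n - 2) / (1 - r^2))} on \code{n - 2} degrees of freedom.
#' Strata with n < 3 or zero variance yield NA with a flag.
#'
#' @param scores_x,scores_y numeric vectors (one value per microregion).
#' @param strata stratum label per microregion (e.g. compartment).
#' @param adjust \code{"none"} (default) or \code{"BH"} for a
#'   Benjamini-Hochberg adjusted column across strata.
#' @return data.frame: \code{stratum}, \code{r}, \code{p}, \code{n},
#'   \code{flag} (and \code{p_adj} when requested).
#' @export
stratified_correlation <- function(scores_x, scores_y, strata,
                                   adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  stopifnot(length(scores_x) == length(scores_y),
            length(scores_x) == length(strata))
  lv <- if (is.factor(strata)) levels(strata) else sort(unique(strata))
  rows <- lapply(lv, function(g) {
    i <- which(strata == g)
    x <- scores_x[i]; y <- scores_y[i]
    n <- length(i)
    if (n < 3L)
      return(data.frame(stratum = g, r = NA_real_, p = NA_real_, n = n,
                        flag = "n < 3", stringsAsFactors = FALSE))
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
      return(data.frame(stratum = g, r = NA_real_, p = NA_real_, n = n,
                        flag = "zero variance", stringsAsFactors = FALSE))
    r <- stats::cor(x, y)
    tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    data.frame(stratum = g, r = r, p = min(p, 1), n = n, flag = "",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (adjust == "BH") out$p_adj <- stats::p.adjust(out$p, "BH")
  out
}

#' Mann-Whitney U rank test
#'
#' Two-sided rank-sum comparison of two groups.  Exact null distribution for
#' combined n <= 20 without ties; normal approximation with tie correction
#' and continuity correction otherwise.
#'
#' @param group_a,group_b numeric vectors.
#' @return list: \code{U} (statistic of \code{group_a}), \code{p}
#'   (two-sided), \code{method}.
#' @export
rank_compare <- function(group_a, group_b) {
  if (!length(group_a) || !length(group_b)) stop("both groups must be non-empty")
  n1 <- length(group_a); n2 <- length(group_b)
  all_v <- c(group_a, group_b)
  r <- rank(all_v)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(all_v)
  has_ties <- any(ties > 1)
  if (!has_ties && n1 + n2 <= 20) {
    # exact two-sided p by doubling the smaller tail of the U distribution
    p <- 2 * min(stats::pwilcox(U, n1, n2),
                 1 - stats::pwilcox(U - 1, n1, n2))
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    n <- n1 + n2
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma <- sqrt(n1 * n2 / 12 * ((n + 1) - tie_term))
    num <- U - mu
    num <- num - 0.5 * sign(num)  # continuity correction
    z <- if (sigma > 0) num / sigma else 0
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal approximation (tie-corrected)"
  }
  list(U = U, p = min(p, 1), method = method)
}

#' Read gene sets from a GMT file
#'
#' Tab-separated lines: set name, description, member genes.
#'
#' @param path GMT file path.
#' @return named list of gene-id character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) stop("malformed GMT line: ", substr(l, 1, 60))
    unique(f[-(1:2)][nzchar(f[-(1:2)])])
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], "")
  sets
}

#' Write gene sets to a GMT file
#'
#' @param gene_sets named list of gene-id vectors.
#' @param path output path.
#' @param description description field (recycled).
#' @export
write_gmt <- function(gene_sets, path, description = "na") {
  lines <- vapply(names(gene_sets), function(nm)
    paste(c(nm, description, gene_sets[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}
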