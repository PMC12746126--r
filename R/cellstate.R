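## Per-cell proliferation and arrest state calls.
##
## The multivariate proliferation index (MPI) is a three-way call on five
## gate-scaled markers: three proliferation markers (KI67, CCNA2, CCNB1) and
## two cell-cycle arrest markers (p21, p27).  Arrest dominates: a cell
## positive for either arrest marker is MPI = -1 even when proliferation
## markers are expressed; otherwise any positive proliferation marker gives
## MPI = +1, and a cell positive for none of the five is MPI = 0.
## Quiescent cancer cells (QCCs) are KI67-negative and positive for p21
## and/or p27.

MPI_PROLIF <- c("KI67", "CCNA2", "CCNB1")
MPI_ARREST <- c("p21", "p27")

check_unit <- function(x, what) {
  if (anyNA(x) || any(x < 0 | x > 1))
    stop(what, " values must lie in [0, 1]")
  x
}

#' Multivariate proliferation index
#'
#' @param KI67,CCNA2,CCNB1 gate-scaled proliferation marker values in [0,1].
#' @param p21,p27 gate-scaled arrest marker values in [0,1].
#' @return integer vector in \{+1, 0, -1\}.
#' @examples
#' mpi(KI67 = 0.8, CCNA2 = 0.2, CCNB1 = 0.2, p21 = 0.1, p27 = 0.2)  # +1
#' mpi(KI67 = 0.8, CCNA2 = 0.2, CCNB1 = 0.2, p21 = 0.9, p27 = 0.2)  # -1
#' @export
mpi <- function(KI67, CCNA2, CCNB1, p21, p27) {
  args <- list(KI67 = KI67, CCNA2 = CCNA2, CCNB1 = CCNB1, p21 = p21, p27 = p27)
  if (any(vapply(args, is.null, TRUE)) ||
      any(vapply(args, length, 0L) == 0L))
    stop("all five MPI markers (KI67, CCNA2, CCNB1, p21, p27) are required")
  for (nm in names(args)) check_unit(args[[nm]], nm)
  arrest <- p21 > 0.5 | p27 > 0.5
  prolif <- KI67 > 0.5 | CCNA2 > 0.5 | CCNB1 > 0.5
  ifelse(arrest, -1L, ifelse(prolif, 1L, 0L))
}

#' Quiescent cancer cell flag
#'
#' TRUE iff the cell is KI67-negative (scaled value <= 0.5) and positive for
#' p21 and/or p27 (scaled value > 0.5).
#'
#' @param KI67,p21,p27 gate-scaled values in [0,1].
#' @return logical vector.
#' @export
qcc_flag <- function(KI67, p21, p27) {
  check_unit(KI67, "KI67"); check_unit(p21, "p21"); check_unit(p27, "p27")
  KI67 <= 0.5 & (p21 > 0.5 | p27 > 0.5)
}

#' Add MPI and QCC columns to a gated cell table
#'
#' @param cells table with \code{scaled_KI67}, \code{scaled_CCNA2},
#'   \code{scaled_CCNB1}, \code{scaled_p21}, \code{scaled_p27} columns.
#' @return the table with integer \code{mpi} and logical \code{qcc} columns.
#' @export
add_state_calls <- function(cells) {
  need <- paste0("scaled_", c(MPI_PROLIF, MPI_ARREST))
  missing <- setdiff(need, names(cells))
  if (length(missing))
    stop("cell table lacks scaled marker column(s): ",
         paste(missing, collapse = ", "))
  cells$mpi <- mpi(cells$scaled_KI67, cells$scaled_CCNA2, cells$scaled_CCNB1,
                   cells$scaled_p21, cells$scaled_p27)
  cells$qcc <- qcc_flag(cells$scaled_KI67, cells$scaled_p21, cells$scaled_p27)
  cells
}

#' Proliferation index with binomial uncertainty
#'
#' Fraction of positive cells with its binomial standard deviation
#' \code{sqrt(p(1-p)/n)}.
#'
#' @param flags logical vector (e.g. KI67 positivity of tumor cells).
#' @return named numeric: \code{fraction}, \code{sd}, \code{n}.
#' @export
proliferation_index <- function(flags) {
  flags <- as.logical(flags)
  n <- length(flags)
  if (n == 0L) stop("proliferation_index needs at least one cell")
  p <- mean(flags)
  c(fraction = p, sd = sqrt(p * (1 - p) / n), n = n)
}

#' Per-group composition of proliferation states
#'
#' For each group (domain, region, cluster, ...) reports the fractions of
#' MPI classes, the QCC fraction, and the four-way
#' KI67/p21/p27 composition (KI67+p21-p27-, KI67-p21+p27-, KI67-p21-p27+,
#' KI67-p21+p27+, Other), each with binomial SDs.  Empty groups give NA
#' rows.
#'
#' @param cells table with \code{mpi}, \code{qcc} and \code{pos_KI67},
#'   \code{pos_p21}, \code{pos_p27} columns.
#' @param groups group label per cell.
#' @return tidy data.frame with columns \code{group}, \code{partition},
#'   \code{state}, \code{fraction}, \code{sd}, \code{n}.
#' @export
state_composition <- function(cells, groups) {
  stopifnot(length(groups) == nrow(cells))
  lv <- if (is.factor(groups)) levels(groups) else sort(unique(groups))
  rows <- list()
  four_way <- function(k, p21, p27) {
    ifelse(k & !p21 & !p27, "KI67+p21-p27-",
    ifelse(!k & p21 & !p27, "KI67-p21+p27-",
    ifelse(!k & !p21 & p27, "KI67-p21-p27+",
    ifelse(!k & p21 & p27, "KI67-p21+p27+", "Other"))))
  }
  for (g in lv) {
    idx <- which(!is.na(groups) & groups == g)
    n <- length(idx)
    emit <- function(partition, state, frac) {
      sd <- if (n > 0) sqrt(frac * (1 - frac) / n) else NA_real_
      rows[[length(rows) + 1L]] <<- data.frame(
        group = g, partition = partition, state = state,
        fraction = frac, sd = sd, n = n, stringsAsFactors = FALSE)
    }
    if (n == 0L) {
      for (s in c("+1", "0", "-1")) emit("mpi", s, NA_real_)
      emit("qcc", "QCC", NA_real_)
      next
    }
    m <- cells$mpi[idx]
    emit("mpi", "+1", mean(m == 1))
    emit("mpi", "0", mean(m == 0))
    emit("mpi", "-1", mean(m == -1))
    emit("qcc", "QCC", mean(cells$qcc[idx]))
    if (all(c("pos_KI67", "pos_p21", "pos_p27") %in% names(cells))) {
      fw <- four_way(cells$pos_KI67[idx], cells$pos_p21[idx], cells$pos_p27[idx])
      for (s in c("KI67+p21-p27-", "KI67-p21+p27-", "KI67-p21-p27+",
                  "KI67-p21+p27+", "Other"))
        emit("ki67_p21_p27", s, mean(fw == s))
    }
  }
  do.call(rbind, rows)
}
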