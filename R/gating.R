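## Gate-based rescaling and marker positivity.
##
## Gating follows the convention used for multiplexed immunofluorescence:
## every marker has a manually (or synthetically) chosen gate intensity which
## is mapped to 0.5 on a rescaled [0, 1] axis; rescaled values strictly above
## 0.5 call the cell positive for the marker.

#' Per-marker gate configuration
#'
#' Builds and validates a gate table.  Each marker has three anchors on the
#' raw intensity axis: \code{low_anchor} (mapped to 0), \code{gate} (mapped
#' to 0.5) and \code{high_anchor} (mapped to 1).  Rescaling is
#' piecewise-linear between the anchors and clamped outside them.
#'
#' @param marker character vector of marker names.
#' @param gate numeric vector of gate intensities (mapped to 0.5).
#' @param low_anchor,high_anchor numeric vectors of anchor intensities; may
#'   be \code{NA}, in which case [apply_gates()] fills them from the 1st and
#'   99th intensity percentiles of the data.
#' @return a \code{data.frame} of class \code{gate_config} with columns
#'   \code{marker}, \code{low_anchor}, \code{gate}, \code{high_anchor}.
#' @export
gate_config <- function(marker, gate, low_anchor = NA_real_,
                        high_anchor = NA_real_) {
  gc <- data.frame(marker = as.character(marker),
                   low_anchor = as.numeric(low_anchor),
                   gate = as.numeric(gate),
                   high_anchor = as.numeric(high_anchor),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(gc$marker))
    stop_config("duplicated marker in gate configuration: ",
                paste(unique(gc$marker[duplicated(gc$marker)]), collapse = ", "))
  if (anyNA(gc$gate)) stop_config("every marker needs a gate value")
  bad <- !is.na(gc$low_anchor) & gc$low_anchor >= gc$gate
  bad <- bad | (!is.na(gc$high_anchor) & gc$high_anchor <= gc$gate)
  if (any(bad))
    stop_config("gate anchors must satisfy low_anchor < gate < high_anchor; ",
                "violated for: ", paste(gc$marker[bad], collapse = ", "))
  class(gc) <- c("gate_config", "data.frame")
  gc
}

#' Rescale raw intensities through a gate
#'
#' Piecewise-linear map sending \code{low_anchor} to 0, \code{gate} to 0.5
#' and \code{high_anchor} to 1, clamped to [0, 1] outside the anchors.  The
#' map is monotone non-decreasing.
#'
#' @param raw numeric vector of raw intensities.
#' @param low_anchor,gate,high_anchor anchors with
#'   \code{low_anchor < gate < high_anchor}.
#' @return numeric vector in [0, 1].
#' @examples
#' rescale_marker(c(100, 500, 1250, 2000), 100, 500, 2000)
#' @export
rescale_marker <- function(raw, low_anchor, gate, high_anchor) {
  if (!(is.finite(low_anchor) && is.finite(gate) && is.finite(high_anchor)))
    stop_config("gate anchors must be finite")
  if (!(low_anchor < gate && gate < high_anchor))
    stop_config("gate anchors must satisfy low_anchor < gate < high_anchor")
  lo <- 0.5 * (raw - low_anchor) / (gate - low_anchor)
  hi <- 0.5 + 0.5 * (raw - gate) / (high_anchor - gate)
  out <- ifelse(raw <= gate, lo, hi)
  pmin(1, pmax(0, out))
}

#' Call marker positivity on rescaled values
#'
#' A cell is positive for a marker iff its rescaled value is strictly greater
#' than 0.5; a value of exactly 0.5 (the gate itself) is negative.
#'
#' @param scaled numeric vector in [0, 1].
#' @return logical vector.
#' @export
call_positivity <- function(scaled) {
  if (anyNA(scaled) || any(scaled < 0 | scaled > 1))
    stop("scaled values must lie in [0, 1]")
  scaled > 0.5
}

#' Apply a gate configuration to a cell table
#'
#' Adds, for every gated marker, a \code{scaled_<marker>} column (rescaled
#' intensity in [0, 1]) and a \code{pos_<marker>} column (positivity flag).
#' Missing low/high anchors are filled per marker from the 1st/99th
#' percentiles of the raw intensities (widened minimally if the gate falls
#' outside that range).
#'
#' @param cells data.frame with one raw-intensity column per gated marker.
#' @param gates a [gate_config()].
#' @return the input data.frame with scaled/positivity columns appended.
#' @export
apply_gates <- function(cells, gates) {
  if (!inherits(gates, "gate_config")) gates <- as_gate_config(gates)
  missing <- setdiff(gates$marker, names(cells))
  if (length(missing))
    stop_config("cell table lacks gated marker column(s): ",
                paste(missing, collapse = ", "))
  for (i in seq_len(nrow(gates))) {
    m <- gates$marker[i]
    raw <- cells[[m]]
    lo <- gates$low_anchor[i]
    hi <- gates$high_anchor[i]
    g <- gates$gate[i]
    if (is.na(lo)) lo <- min(stats::quantile(raw, 0.01, names = FALSE), g * 0.999 - 1e-9)
    if (is.na(hi)) hi <- max(stats::quantile(raw, 0.99, names = FALSE), g * 1.001 + 1e-9)
    s <- rescale_marker(raw, lo, g, hi)
    cells[[paste0("scaled_", m)]] <- s
    cells[[paste0("pos_", m)]] <- call_positivity(s)
  }
  cells
}

# accept a plain data.frame / named list read from YAML
as_gate_config <- function(x) {
  if (is.data.frame(x))
    return(gate_config(x$marker, x$gate,
                       x$low_anchor %||% NA_real_, x$high_anchor %||% NA_real_))
  if (is.list(x)) {
    mk <- names(x)
    return(gate_config(mk,
                       gate = vapply(x, function(e) as.numeric(e$gate), 0),
                       low_anchor = vapply(x, function(e) as.numeric(e$low %||% e$low_anchor %||% NA_real_), 0),
                       high_anchor = vapply(x, function(e) as.numeric(e$high %||% e$high_anchor %||% NA_real_), 0)))
  }
  stop_config("cannot interpret gate configuration")
}

#' Read a gate configuration from YAML
#'
#' Expected layout: one top-level entry per marker with fields \code{gate}
#' and optional \code{low}/\code{high} anchors.
#'
#' @param path YAML file path.
#' @return a [gate_config()].
#' @export
read_gate_config <- function(path) {
  as_gate_config(yaml::read_yaml(path))
}
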