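## Seeded synthetic-tissue and microregion-count generators with ground truth.
##
## The generator states a simple but explicit world: rectangular tissue
## fields split into domains, each holding one or more circular tumor nests
## of uniformly scattered SOX10+/PMEL+ tumor cells, an ambient mix of immune
## and stromal cells, optional CD31+ vessels (cells strewn along a corridor
## around a polyline path) and an optional necrotic zone inside the
## peritumoral band where cell density is thinned to 20% of ambient and
## cells carry a DNA-debris flag.  Marker intensities follow a two-component
## log-normal model per marker (autofluorescence-level negative component,
## expression-level positive component); the geometric midpoint of the two
## component medians is the true gate.  Tumor cells carry a cell-cycle state
## (G1/S, S, G2/M, M, arrested, quiescent, neutral) that drives
## biologically-ordered marker co-expression: all cycling states are KI67+,
## G2/M adds CCNA2+CCNB1, M adds pH3, arrest states are KI67- with p21
## and/or p27 positive.

#' Marker panel used by the synthetic generator
#' @return character vector of marker names.
#' @export
synthetic_marker_panel <- function() {
  c("SOX10", "PMEL", "CD45", "CD3E", "CD8A", "CD4", "FOXP3", "LEF1",
    "CD45RA", "CD45RO", "CD103", "GZMB", "PD1", "LAG3", "TIM3", "KI67",
    "CCNA2", "CCNB1", "pH3", "p21", "p27", "CD68", "CD163", "CD206",
    "CD11C", "CD20", "CD31")
}

# positive-marker profile per true cell class (cell-cycle markers are added
# separately for tumor cells)
class_profiles <- function() {
  list(
    "Tumor" = c("SOX10", "PMEL"),
    "naive CD8 T" = c("CD45", "CD3E", "CD8A", "LEF1", "CD45RA"),
    "memory CD8 T" = c("CD45", "CD3E", "CD8A", "CD45RO"),
    "resident memory CD8 T" = c("CD45", "CD3E", "CD8A", "CD45RO", "CD103"),
    "cytotoxic CD8 T" = c("CD45", "CD3E", "CD8A", "GZMB"),
    "proliferative cytotoxic CD8 T" = c("CD45", "CD3E", "CD8A", "GZMB", "KI67"),
    "partially exhausted CD8 T" = c("CD45", "CD3E", "CD8A", "PD1", "LAG3"),
    "terminally exhausted CD8 T" = c("CD45", "CD3E", "CD8A", "PD1", "LAG3", "TIM3"),
    "Treg" = c("CD45", "CD3E", "CD4", "FOXP3"),
    "Macrophage" = c("CD45", "CD68", "CD163", "CD206"),
    "Myeloid" = c("CD45", "CD11C"),
    "B cell" = c("CD45", "CD20"),
    "Endothelial" = c("CD31"),
    "Other" = character(0))
}

# extra positive markers emitted by each tumor cell-cycle state
cellcycle_profiles <- function() {
  list(neutral = character(0),
       g1s = "KI67",
       s = "KI67",
       g2m = c("KI67", "CCNA2", "CCNB1"),
       m = c("KI67", "CCNA2", "CCNB1", "pH3"),
       arrested = c("p21", "p27"),
       quiescent = "p27")
}

#' Default two-component log-intensity marker model
#'
#' Negative (autofluorescence) component centred at 100 intensity units and
#' positive (expression) component at 1000, both with log-scale SD 0.4 — a
#' decade of separation at roughly 40% coefficient of variation, typical of
#' gate-separable immunofluorescence channels.
#'
#' @param markers marker names (default [synthetic_marker_panel()]).
#' @param neg_meanlog,pos_meanlog,sdlog model parameters on the log scale.
#' @return data.frame with one row per marker.
#' @export
default_marker_model <- function(markers = synthetic_marker_panel(),
                                 neg_meanlog = log(100),
                                 pos_meanlog = log(1000),
                                 sdlog = 0.4) {
  data.frame(marker = markers,
             neg_meanlog = neg_meanlog, neg_sdlog = sdlog,
             pos_meanlog = pos_meanlog, pos_sdlog = sdlog,
             stringsAsFactors = FALSE)
}

#' Default immune / stromal mixing proportions
#' @return named numeric vector summing to 1 over non-tumor cell classes.
#' @export
default_immune_mix <- function() {
  c("naive CD8 T" = 0.01, "memory CD8 T" = 0.08,
    "resident memory CD8 T" = 0.05, "cytotoxic CD8 T" = 0.10,
    "proliferative cytotoxic CD8 T" = 0.05,
    "partially exhausted CD8 T" = 0.05,
    "terminally exhausted CD8 T" = 0.04,
    "Treg" = 0.05, "Macrophage" = 0.10, "Myeloid" = 0.06,
    "B cell" = 0.06, "Other" = 0.35)
}

#' Default domain layout for a 2000 x 2000 um field
#'
#' Domain A (left half): one 350 um tumor nest plus one vessel; domain B
#' (right half): one 300 um nest with a necrotic sector in its peritumoral
#' band.
#'
#' @param field_size numeric length-2, field width/height in um.
#' @return list of domain specifications.
#' @export
default_domain_specs <- function(field_size = c(2000, 2000)) {
  w <- field_size[1]; h <- field_size[2]
  list(
    list(domain_id = "A",
         bounds = c(0, 0, w / 2, h),
         nests = list(list(center = c(0.30 * w, 0.30 * h), radius = 350)),
         tumor_fraction = 0.45,
         immune_mix = default_immune_mix(),
         necrosis = FALSE,
         vessels = list(list(path = rbind(c(0.075 * w, 0.85 * h),
                                          c(0.425 * w, 0.925 * h)),
                             halfwidth = 10, n_cells = 120))),
    list(domain_id = "B",
         bounds = c(w / 2, 0, w, h),
         nests = list(list(center = c(0.75 * w, 0.35 * h), radius = 300)),
         tumor_fraction = 0.40,
         immune_mix = default_immune_mix(),
         necrosis = TRUE,
         necrosis_zone = list(center = c(0.75 * w, 0.35 * h),
                              r_inner = 300, r_outer = 348,
                              theta = c(0, pi / 2)),
         vessels = list()))
}

#' Synthetic tissue configuration
#'
#' @param n_cells total number of cells to draw (before necrotic thinning).
#' @param field_size field width/height in um.
#' @param domain_specs list of domain specifications; see
#'   [default_domain_specs()] for the expected fields.
#' @param marker_model per-marker two-component model
#'   ([default_marker_model()]).
#' @param cellcycle_mix named proportions of tumor cell-cycle states over
#'   \code{neutral, g1s, s, g2m, m, arrested, quiescent}; must sum to 1.
#'   Defaults plant 28% cycling (MPI +1) and 20% arrest-positive (MPI -1)
#'   tumor cells.
#' @param band_width,vessel_radius geometric truth parameters (um) used to
#'   derive true region labels.
#' @param seed mandatory integer seed; the generator uses a single global
#'   RNG stream and restores the caller's RNG state on exit.
#' @return object of class \code{tissue_config}.
#' @export
tissue_config <- function(n_cells = 10000,
                          field_size = c(2000, 2000),
                          domain_specs = default_domain_specs(field_size),
                          marker_model = default_marker_model(),
                          cellcycle_mix = c(neutral = 0.52, g1s = 0.12,
                                            s = 0.08, g2m = 0.06, m = 0.02,
                                            arrested = 0.12, quiescent = 0.08),
                          band_width = 50, vessel_radius = 50,
                          seed) {
  if (missing(seed)) stop_config("tissue_config requires an explicit seed")
  n_cells <- as.integer(n_cells)
  if (is.na(n_cells) || n_cells <= 0L)
    stop_config("n_cells must be a positive count")
  if (length(field_size) != 2L || any(!is.finite(field_size)) || any(field_size <= 0))
    stop_config("field_size must be two positive lengths (um)")
  if (abs(sum(cellcycle_mix) - 1) > 1e-8 || any(cellcycle_mix < 0) || any(cellcycle_mix > 1))
    stop_config("cellcycle_mix proportions must lie in [0,1] and sum to 1")
  states <- c("neutral", "g1s", "s", "g2m", "m", "arrested", "quiescent")
  if (!all(names(cellcycle_mix) %in% states))
    stop_config("unknown cell-cycle state in cellcycle_mix")
  for (d in domain_specs) {
    tf <- d$tumor_fraction
    if (is.null(tf) || tf < 0 || tf > 1)
      stop_config("domain ", d$domain_id, ": tumor_fraction must be in [0,1]")
    mix <- d$immune_mix
    if (abs(sum(mix) - 1) > 1e-8 || any(mix < 0) || any(mix > 1))
      stop_config("domain ", d$domain_id,
                  ": immune_mix must lie in [0,1] and sum to 1")
    if (!all(names(mix) %in% names(class_profiles())))
      stop_config("domain ", d$domain_id, ": unknown class in immune_mix")
  }
  if (any(marker_model$pos_meanlog <= marker_model$neg_meanlog))
    stop_config("positive component location must exceed negative component ",
                "location for every marker")
  structure(list(n_cells = n_cells, field_size = as.numeric(field_size),
                 domain_specs = domain_specs, marker_model = marker_model,
                 cellcycle_mix = cellcycle_mix[states[states %in% names(cellcycle_mix)]],
                 band_width = band_width, vessel_radius = vessel_radius,
                 seed = as.integer(seed)),
            class = "tissue_config")
}

#' True gates implied by a marker model
#'
#' The true gate of each marker is the geometric midpoint of the two
#' component medians; anchors sit two log-SDs outside the component medians.
#'
#' @param marker_model data.frame as from [default_marker_model()].
#' @return a [gate_config()].
#' @export
true_gates <- function(marker_model) {
  gate_config(marker_model$marker,
              gate = exp((marker_model$neg_meanlog + marker_model$pos_meanlog) / 2),
              low_anchor = exp(marker_model$neg_meanlog - 2 * marker_model$neg_sdlog),
              high_anchor = exp(marker_model$pos_meanlog + 2 * marker_model$pos_sdlog))
}

# uniform draw inside a disk, vectorised
runif_disk <- function(n, center, radius) {
  r <- radius * sqrt(stats::runif(n))
  th <- stats::runif(n, 0, 2 * pi)
  cbind(center[1] + r * cos(th), center[2] + r * sin(th))
}

# distance from points to a polyline path (matrix of vertices)
dist_to_path <- function(pts, path) {
  d <- rep(Inf, nrow(pts))
  for (i in seq_len(nrow(path) - 1L)) {
    a <- path[i, ]; b <- path[i + 1L, ]
    ab <- b - a
    len2 <- sum(ab^2)
    t <- ((pts[, 1] - a[1]) * ab[1] + (pts[, 2] - a[2]) * ab[2]) / max(len2, 1e-12)
    t <- pmin(1, pmax(0, t))
    dx <- pts[, 1] - (a[1] + t * ab[1])
    dy <- pts[, 2] - (a[2] + t * ab[2])
    d <- pmin(d, sqrt(dx * dx + dy * dy))
  }
  d
}

in_necrosis_zone <- function(pts, zone) {
  dx <- pts[, 1] - zone$center[1]
  dy <- pts[, 2] - zone$center[2]
  r <- sqrt(dx * dx + dy * dy)
  th <- atan2(dy, dx) %% (2 * pi)
  lo <- zone$theta[1] %% (2 * pi); hi <- zone$theta[2] %% (2 * pi)
  ang <- if (lo <= hi) th >= lo & th <= hi else th >= lo | th <= hi
  r >= zone$r_inner & r <= zone$r_outer & ang
}

#' Generate a synthetic tissue with ground truth
#'
#' Draws a seeded cell table (coordinates in um, one raw-intensity column per
#' marker, a \code{debris} flag and \code{true_*} truth columns) plus a
#' truth object carrying the per-cell truth, the true gates, and the
#' configuration.  Deterministic given the config seed.  When a necrotic
#' zone is configured the returned table has slightly fewer than
#' \code{n_cells} rows because cells inside the zone are thinned to 20% of
#' ambient density.
#'
#' @param config a [tissue_config()].
#' @return list with elements \code{cells} (data.frame) and \code{truth}
#'   (list: \code{gates}, \code{config}).
#' @export
generate_tissue <- function(config) {
  stopifnot(inherits(config, "tissue_config"))
  with_seed(config$seed, generate_tissue_impl(config))
}

generate_tissue_impl <- function(config) {
  specs <- config$domain_specs
  areas <- vapply(specs, function(d)
    (d$bounds[3] - d$bounds[1]) * (d$bounds[4] - d$bounds[2]), 0)
  n_dom <- floor(config$n_cells * areas / sum(areas))
  rem <- config$n_cells - sum(n_dom)
  if (rem > 0) n_dom[seq_len(rem)] <- n_dom[seq_len(rem)] + 1L

  parts <- vector("list", length(specs))
  for (k in seq_along(specs)) {
    d <- specs[[k]]
    n_d <- n_dom[k]
    n_ves <- if (length(d$vessels))
      sum(vapply(d$vessels, function(v) v$n_cells %||% 100L, 0)) else 0L
    n_ves <- min(n_ves, n_d)
    n_free <- n_d - n_ves

    classes <- c("Tumor", names(d$immune_mix))
    probs <- c(d$tumor_fraction, (1 - d$tumor_fraction) * unname(d$immune_mix))
    cls <- sample(classes, n_free, replace = TRUE, prob = probs)

    xy <- matrix(NA_real_, n_free, 2)
    is_tum <- cls == "Tumor"
    if (any(is_tum)) {
      nests <- d$nests
      w <- vapply(nests, function(nn) nn$radius^2, 0)
      pick <- sample.int(length(nests), sum(is_tum), replace = TRUE, prob = w)
      for (j in seq_along(nests)) {
        sel <- which(is_tum)[pick == j]
        if (length(sel))
          xy[sel, ] <- runif_disk(length(sel), nests[[j]]$center, nests[[j]]$radius)
      }
    }
    if (any(!is_tum)) {
      m <- sum(!is_tum)
      xy[!is_tum, ] <- cbind(stats::runif(m, d$bounds[1], d$bounds[3]),
                             stats::runif(m, d$bounds[2], d$bounds[4]))
    }

    # vessel cells: strewn along the corridor around each path
    if (n_ves > 0L) {
      vxy <- NULL
      for (v in d$vessels) {
        nv <- min(v$n_cells %||% 100L, n_ves - NROW(vxy))
        if (nv <= 0L) next
        seg_len <- sqrt(rowSums((v$path[-1, , drop = FALSE] -
                                 v$path[-nrow(v$path), , drop = FALSE])^2))
        seg <- sample.int(length(seg_len), nv, replace = TRUE, prob = seg_len)
        t <- stats::runif(nv)
        a <- v$path[seg, , drop = FALSE]
        b <- v$path[seg + 1L, , drop = FALSE]
        base <- a + t * (b - a)
        dir <- (b - a) / pmax(sqrt(rowSums((b - a)^2)), 1e-12)
        normal <- cbind(-dir[, 2], dir[, 1])
        off <- stats::runif(nv, -(v$halfwidth %||% 10), v$halfwidth %||% 10)
        vxy <- rbind(vxy, base + off * normal)
      }
      xy <- rbind(xy, vxy)
      cls <- c(cls, rep("Endothelial", nrow(vxy)))
    }

    state <- rep(NA_character_, length(cls))
    ntum <- sum(cls == "Tumor")
    if (ntum)
      state[cls == "Tumor"] <- sample(names(config$cellcycle_mix), ntum,
                                      replace = TRUE,
                                      prob = config$cellcycle_mix)

    debris <- rep(FALSE, length(cls))
    if (isTRUE(d$necrosis) && !is.null(d$necrosis_zone)) {
      inz <- in_necrosis_zone(xy, d$necrosis_zone)
      drop <- inz & stats::runif(length(cls)) > 0.2
      keep <- !drop
      xy <- xy[keep, , drop = FALSE]
      cls <- cls[keep]; state <- state[keep]
      debris <- inz[keep]
    }

    parts[[k]] <- list(xy = xy, class = cls, state = state, debris = debris,
                       domain = rep(d$domain_id, length(cls)))
  }

  xy <- do.call(rbind, lapply(parts, `[[`, "xy"))
  cls <- unlist(lapply(parts, `[[`, "class"), use.names = FALSE)
  state <- unlist(lapply(parts, `[[`, "state"), use.names = FALSE)
  debris <- unlist(lapply(parts, `[[`, "debris"), use.names = FALSE)
  domain <- unlist(lapply(parts, `[[`, "domain"), use.names = FALSE)
  n <- length(cls)

  # marker intensities from the class-appropriate mixture component
  mm <- config$marker_model
  profiles <- class_profiles()
  ccp <- cellcycle_profiles()
  pos_mat <- matrix(FALSE, n, nrow(mm), dimnames = list(NULL, mm$marker))
  for (cl in unique(cls)) {
    rows <- cls == cl
    pos_mat[rows, profiles[[cl]]] <- TRUE
  }
  for (st in unique(state[!is.na(state)])) {
    rows <- !is.na(state) & state == st
    if (length(ccp[[st]])) pos_mat[rows, ccp[[st]]] <- TRUE
  }
  intens <- matrix(NA_real_, n, nrow(mm), dimnames = list(NULL, mm$marker))
  for (j in seq_len(nrow(mm))) {
    p <- pos_mat[, j]
    v <- numeric(n)
    v[p] <- stats::rlnorm(sum(p), mm$pos_meanlog[j], mm$pos_sdlog[j])
    v[!p] <- stats::rlnorm(sum(!p), mm$neg_meanlog[j], mm$neg_sdlog[j])
    intens[, j] <- v
  }

  region <- true_regions(xy, config)

  cells <- data.frame(cell_id = sprintf("c%06d", seq_len(n)),
                      x = xy[, 1], y = xy[, 2],
                      stringsAsFactors = FALSE)
  cells <- cbind(cells, as.data.frame(intens))
  cells$debris <- debris
  cells$true_class <- cls
  cells$true_state <- state
  cells$true_region <- region
  cells$true_domain <- domain

  list(cells = cells,
       truth = list(gates = true_gates(mm),
                    positivity = pos_mat,
                    config = config))
}

# geometric truth regions with the same precedence the analysis uses:
# tumor > necrotic > perivascular > peritumoral > distal
true_regions <- function(xy, config) {
  n <- nrow(xy)
  region <- rep("distal", n)
  in_band <- rep(FALSE, n)
  in_nest <- rep(FALSE, n)
  in_necro <- rep(FALSE, n)
  near_vessel <- rep(FALSE, n)
  for (d in config$domain_specs) {
    for (nst in d$nests) {
      r <- sqrt((xy[, 1] - nst$center[1])^2 + (xy[, 2] - nst$center[2])^2)
      in_nest <- in_nest | r <= nst$radius
      in_band <- in_band | (r > nst$radius & r <= nst$radius + config$band_width)
    }
    if (isTRUE(d$necrosis) && !is.null(d$necrosis_zone))
      in_necro <- in_necro | in_necrosis_zone(xy, d$necrosis_zone)
    for (v in d$vessels)
      near_vessel <- near_vessel | dist_to_path(xy, v$path) <= config$vessel_radius
  }
  region[in_band] <- "peritumoral"
  region[near_vessel & !in_nest] <- "perivascular"
  region[in_necro & in_band] <- "necrotic"
  region[in_nest] <- "tumor"
  region
}

## ------------------------------------------------------------------------
## Microregion count matrices

#' Default gene universe and gene sets for synthetic microregions
#'
#' Builds \code{n_genes} gene ids and deterministic block gene sets of
#' \code{set_size} genes each.
#'
#' @param n_genes size of the gene universe.
#' @param set_names names of the sets to carve out.
#' @param set_size genes per set.
#' @return list with \code{genes} and \code{gene_sets}.
#' @export
default_gene_universe <- function(n_genes = 1000,
                                  set_names = c("SIG_A", "SIG_B"),
                                  set_size = 50) {
  if (n_genes < length(set_names) * set_size + 1)
    stop_config("gene universe too small for the requested sets")
  genes <- sprintf("g%05d", seq_len(n_genes))
  sets <- stats::setNames(lapply(seq_along(set_names), function(i)
    genes[((i - 1) * set_size + 1):(i * set_size)]), set_names)
  list(genes = genes, gene_sets = sets)
}

#' Microregion specifications with compartment-restricted signature coupling
#'
#' Builds one spec per microregion with latent activities for two signatures
#' drawn from a Gaussian copula: correlated (rho \code{rho_by_compartment})
#' within the designated compartment, independent elsewhere — emulating a
#' peritumoral-only association between, e.g., a cell-death signature and a
#' T-cell signature.
#'
#' @param n_tumor,n_peritumoral microregions per compartment.
#' @param sets names of the two coupled signatures.
#' @param rho_peritumoral,rho_tumor latent correlation per compartment.
#' @param seed integer seed.
#' @return list of per-MR specs usable by [generate_mr_counts()].
#' @export
make_correlated_mr_specs <- function(n_tumor = 30, n_peritumoral = 30,
                                     sets = c("SIG_A", "SIG_B"),
                                     rho_peritumoral = 0.7, rho_tumor = 0,
                                     seed) {
  if (missing(seed)) stop_config("make_correlated_mr_specs requires a seed")
  stopifnot(length(sets) == 2L)
  with_seed(seed, {
    draw <- function(n, rho) {
      z1 <- stats::rnorm(n)
      z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
      cbind(stats::pnorm(z1), stats::pnorm(z2))  # activities in [0,1]
    }
    at <- draw(n_tumor, rho_tumor)
    ap <- draw(n_peritumoral, rho_peritumoral)
    specs <- vector("list", n_tumor + n_peritumoral)
    for (i in seq_len(n_tumor))
      specs[[i]] <- list(mr_id = sprintf("MR%03d", i), domain = "A",
                         compartment = "tumor",
                         activity = stats::setNames(at[i, ], sets))
    for (i in seq_len(n_peritumoral))
      specs[[n_tumor + i]] <- list(mr_id = sprintf("MR%03d", n_tumor + i),
                                   domain = "A", compartment = "peritumoral",
                                   activity = stats::setNames(ap[i, ], sets))
    specs
  })
}

#' Generate synthetic microregion count matrices
#'
#' Counts are negative-binomial around gene baseline means (log-normal across
#' genes) scaled by a per-MR library size factor; genes belonging to a
#' signature a microregion is active for receive a multiplicative mean shift
#' \code{effect_fold^activity}.  Deterministic given \code{seed}.
#'
#' @param n_genes gene universe size (ignored when \code{universe} given).
#' @param mr_specs list of per-MR specs: \code{mr_id}, \code{domain},
#'   \code{compartment}, optional \code{enrichment}, and \code{activity}
#'   (named numeric over gene-set names; values in [0,1]).
#' @param seed integer seed.
#' @param universe optional list from [default_gene_universe()].
#' @param effect_fold mean fold change at activity 1 (default 4).
#' @param dispersion negative-binomial size parameter (default 2).
#' @param libsize_sdlog log-SD of per-MR library size factors (default 0.15).
#' @return list: \code{counts} (genes x MRs integer matrix), \code{meta}
#'   (per-MR data.frame), \code{truth} (activities, gene_sets, size factors).
#' @export
generate_mr_counts <- function(n_genes = 1000, mr_specs, seed,
                               universe = NULL, effect_fold = 4,
                               dispersion = 2, libsize_sdlog = 0.15) {
  if (missing(seed)) stop_config("generate_mr_counts requires a seed")
  if (is.null(universe)) universe <- default_gene_universe(n_genes)
  genes <- universe$genes
  gene_sets <- universe$gene_sets
  for (s in names(gene_sets))
    if (!all(gene_sets[[s]] %in% genes))
      stop_config("gene set ", s, " references unknown gene(s)")
  n_mr <- length(mr_specs)
  stopifnot(n_mr >= 1L)
  with_seed(seed, {
    base <- stats::rlnorm(length(genes), meanlog = log(50), sdlog = 1)
    sf <- stats::rlnorm(n_mr, 0, libsize_sdlog)
    counts <- matrix(0L, length(genes), n_mr,
                     dimnames = list(genes,
                                     vapply(mr_specs, `[[`, "", "mr_id")))
    act <- matrix(0, n_mr, length(gene_sets),
                  dimnames = list(colnames(counts), names(gene_sets)))
    for (j in seq_len(n_mr)) {
      mu <- base
      a <- mr_specs[[j]]$activity
      for (s in names(a)) {
        if (!s %in% names(gene_sets))
          stop_config("MR spec references unknown gene set: ", s)
        act[j, s] <- a[[s]]
        idx <- match(gene_sets[[s]], genes)
        mu[idx] <- mu[idx] * effect_fold^a[[s]]
      }
      counts[, j] <- stats::rnbinom(length(genes), mu = mu * sf[j],
                                    size = dispersion)
    }
    meta <- data.frame(
      mr_id = colnames(counts),
      domain = vapply(mr_specs, function(s) s$domain %||% NA_character_, ""),
      compartment = vapply(mr_specs, function(s) s$compartment %||% NA_character_, ""),
      enrichment = vapply(mr_specs, function(s) s$enrichment %||% "full", ""),
      stringsAsFactors = FALSE)
    list(counts = counts, meta = meta,
         truth = list(activities = act, gene_sets = gene_sets,
                      size_factors = sf))
  })
}
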