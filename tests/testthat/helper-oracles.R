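# Independent brute-force oracles used by the unit and acceptance tests.
# These deliberately re-derive results from first principles (plain loops,
# exhaustive enumeration) and never call the code paths they check.

# full pairwise Euclidean distance matrix
brute_dist <- function(a, b) {
  m <- matrix(0, nrow(a), nrow(b))
  for (i in seq_len(nrow(a)))
    m[i, ] <- sqrt((b[, 1] - a[i, 1])^2 + (b[, 2] - a[i, 2])^2)
  m
}

# DBSCAN by exhaustive eps-connectivity: core points are connected
# components, border points join their nearest core point, rest is noise
oracle_dbscan <- function(pts, eps, min_pts) {
  n <- nrow(pts)
  d <- brute_dist(pts, pts)
  adj <- d <= eps
  core <- rowSums(adj) >= min_pts
  labels <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || labels[i]) next
    cl <- cl + 1L
    stack <- i
    while (length(stack)) {
      j <- stack[[1]]; stack <- stack[-1]
      if (labels[j]) next
      labels[j] <- cl
      stack <- c(stack, which(adj[j, ] & core & labels == 0L))
    }
  }
  for (i in which(!core)) {
    cand <- which(core & adj[i, ])
    if (length(cand)) labels[i] <- labels[cand[which.min(d[i, cand])]]
  }
  labels
}

# literal running-sum ssGSEA for one expression vector (Barbie convention:
# weight of a gene is its rank value, highest expression = largest)
oracle_ssgsea <- function(expr, set_genes, alpha = 0.25) {
  genes <- names(expr)
  n <- length(expr)
  rk <- rank(expr, ties.method = "average")
  ord <- order(rk, seq_len(n), decreasing = TRUE)
  in_set <- genes[ord] %in% set_genes
  denom_in <- sum(rk[genes %in% set_genes]^alpha)
  denom_out <- n - sum(in_set)
  score <- 0; cum_in <- 0; cum_out <- 0
  for (pos in seq_len(n)) {
    if (in_set[pos]) cum_in <- cum_in + rk[ord[pos]]^alpha
    else cum_out <- cum_out + 1
    score <- score + cum_in / denom_in - cum_out / denom_out
  }
  unname(score)
}

# exact two-sided Mann-Whitney p by full enumeration of group assignments
oracle_mwu_exact <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  vals <- c(a, b)
  r <- rank(vals)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  splits <- utils::combn(n1 + n2, n1)
  u_all <- apply(splits, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
}

# exhaustive 2^5 MPI truth table on positivity patterns
oracle_mpi <- function(ki67, ccna2, ccnb1, p21, p27) {
  if (p21 || p27) return(-1L)
  if (ki67 || ccna2 || ccnb1) return(1L)
  0L
}

# distance from one point to a polyline
oracle_path_dist <- function(pt, path) {
  best <- Inf
  for (i in seq_len(nrow(path) - 1)) {
    a <- path[i, ]; b <- path[i + 1, ]
    t <- sum((pt - a) * (b - a)) / sum((b - a)^2)
    t <- min(1, max(0, t))
    best <- min(best, sqrt(sum((pt - (a + t * (b - a)))^2)))
  }
  best
}

# single-domain tissue configuration used in parameter-recovery tests
simple_tissue_config <- function(tumor_fraction, n_cells, seed,
                                 field = c(1500, 1500)) {
  spec <- list(list(
    domain_id = "A", bounds = c(0, 0, field[1], field[2]),
    nests = list(list(center = field / 2, radius = 350)),
    tumor_fraction = tumor_fraction,
    immune_mix = default_immune_mix(),
    necrosis = FALSE, vessels = list()))
  tissue_config(n_cells = n_cells, field_size = field,
                domain_specs = spec, seed = seed)
}

# analytic expected observed positivity per marker given the generator truth:
# realized true-positive rate corrected by the model-implied FN/FP rates
expected_positivity <- function(sim) {
  mm <- sim$truth$config$marker_model
  gates <- true_gates(mm)
  p_true <- colMeans(sim$truth$positivity)
  fp <- 1 - stats::plnorm(gates$gate, mm$neg_meanlog, mm$neg_sdlog)
  fn <- stats::plnorm(gates$gate, mm$pos_meanlog, mm$pos_sdlog)
  stats::setNames(p_true * (1 - fn) + (1 - p_true) * fp, mm$marker)
}
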