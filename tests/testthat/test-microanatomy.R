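# Boundary reconstruction, DBSCAN, region assignment, composition, density.

test_that("DBSCAN agrees with the brute-force eps-connectivity oracle", {
  set.seed(101)
  for (rep in 1:4) {
    n <- sample(80:400, 1)
    # mixture of blobs and background noise
    pts <- rbind(
      cbind(rnorm(n %/% 2, 100, 15), rnorm(n %/% 2, 100, 15)),
      cbind(rnorm(n %/% 4, 400, 20), rnorm(n %/% 4, 380, 20)),
      cbind(runif(n - n %/% 2 - n %/% 4, 0, 500),
            runif(n - n %/% 2 - n %/% 4, 0, 500)))
    got <- cluster_dbscan(pts, eps = 25, min_samples = 8)
    want <- oracle_dbscan(pts, eps = 25, min_pts = 8)
    # same partition up to label renumbering, same noise set
    expect_identical(got == 0L, want == 0L)
    expect_equal(length(unique(got[got > 0])), length(unique(want[want > 0])))
    tab <- table(got[got > 0], want[got > 0])
    expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
  }
})

test_that("too few tumor cells give an empty polygon list", {
  pts <- cbind(runif(5, 0, 100), runif(5, 0, 100))
  expect_identical(reconstruct_tumor_boundaries(pts, region_model(dbscan_min_samples = 10)),
                   list())
})

test_that("a uniform disk yields one polygon capturing the points", {
  set.seed(7)
  th <- runif(200, 0, 2 * pi); r <- 100 * sqrt(runif(200))
  pts <- cbind(500 + r * cos(th), 500 + r * sin(th))
  model <- region_model(dbscan_eps = 30, dbscan_min_samples = 10)
  polys <- reconstruct_tumor_boundaries(pts, model)
  expect_length(polys, 1)
  inside <- sp::point.in.polygon(pts[, 1], pts[, 2],
                                 polys[[1]][, 1], polys[[1]][, 2]) > 0
  expect_gte(mean(inside), 0.95)
  # two disks far apart -> two polygons, count matching the oracle
  pts2 <- rbind(pts, pts + 1000)
  polys2 <- reconstruct_tumor_boundaries(pts2, model)
  expect_length(polys2, length(unique(oracle_dbscan(pts2, 30, 10)) |> setdiff(0L)))
  expect_length(polys2, 2)
})

test_that("boundary polygons are invariant to input point order", {
  set.seed(21)
  th <- runif(150, 0, 2 * pi); r <- 80 * sqrt(runif(150))
  pts <- cbind(r * cos(th), r * sin(th))
  model <- region_model(dbscan_eps = 30, dbscan_min_samples = 10)
  p1 <- reconstruct_tumor_boundaries(pts, model)[[1]]
  perm <- sample(nrow(pts))
  p2 <- reconstruct_tumor_boundaries(pts[perm, ], model)[[1]]
  expect_equal(polygon_area(p1), polygon_area(p2), tolerance = 1e-9)
  key <- function(p) paste(round(sort(p[, 1] + 1e3 * p[, 2]), 6), collapse = ",")
  expect_identical(key(p1), key(p2))
})

test_that("region precedence follows tumor > necrotic > perivascular > peritumoral", {
  square <- rbind(c(0, 0), c(100, 0), c(100, 100), c(0, 100))
  # dense far-away blob anchors the density distribution; two probes sit
  # 10 um outside the polygon in sparse space
  set.seed(3)
  blob <- cbind(rnorm(60, 500, 5), rnorm(60, 500, 5))
  cells <- data.frame(x = c(50, 110, 110, 800, blob[, 1]),
                      y = c(50, 50, 80, 800, blob[, 2]))
  debris <- c(FALSE, FALSE, TRUE, FALSE, rep(FALSE, 60))
  model <- region_model(peritumoral_band = 50, necrosis_density_quantile = 0.2)
  lab <- assign_regions(cells, list(square), model, debris_flags = debris)
  expect_equal(lab$region[1], "tumor")        # strictly inside
  expect_equal(lab$region[2], "peritumoral")  # 10 um out, debris-negative
  expect_equal(lab$region[3], "necrotic")     # 10 um out, debris + sparse
  expect_equal(lab$region[4], "distal")
  # perivascular beats peritumoral outside the tumor
  lab2 <- assign_regions(cells, list(square), model,
                         vessel_cells = cbind(115, 50), debris_flags = debris)
  expect_equal(lab2$region[2], "perivascular")
  expect_equal(lab2$region[1], "tumor")       # containment still wins
  expect_error(assign_regions(cells, list(square), model,
                              debris_flags = c(TRUE, FALSE)), "length")
})

test_that("region labels form a partition", {
  sim <- generate_tissue(tissue_config(n_cells = 2000, seed = 31))
  g <- apply_gates(sim$cells, sim$truth$gates)
  ph <- classify_cells(g)
  polys <- reconstruct_tumor_boundaries(g[ph == "Tumor", c("x", "y")], region_model())
  lab <- assign_regions(g, polys, region_model(), debris_flags = g$debris)
  expect_length(lab$region, nrow(g))
  expect_true(all(lab$region %in% c("tumor", "peritumoral", "necrotic",
                                    "perivascular", "distal")))
})

test_that("regional_composition normalizes per cell type", {
  groups <- rep(c("A", "B", "C", "D", "E"), times = c(50, 30, 10, 5, 5))
  types <- rep("CD8", 100)
  comp <- regional_composition(groups, types)
  expect_equal(as.numeric(comp["CD8", c("A", "B", "C", "D", "E")]),
               c(0.50, 0.30, 0.10, 0.05, 0.05))
  # single group -> all ones; absent type -> NA row
  comp2 <- regional_composition(rep("A", 10),
                                factor(rep("T", 10), levels = c("T", "B")))
  expect_equal(as.numeric(comp2["T", ]), 1)
  expect_true(all(is.na(comp2["B", ])))
  rs <- rowSums(comp)
  expect_equal(unname(rs["CD8"]), 1)
})

test_that("cell density uses the shoelace area in mm^2", {
  sq <- rbind(c(0, 0), c(500, 0), c(500, 500), c(0, 500))  # 0.25 mm^2
  expect_equal(cell_density(500, sq), 2000)
  expect_equal(cell_density(1000, sq), 4000)
  expect_equal(cell_density(0, sq), 0)
  expect_equal(polygon_area(sq), 500 * 500)  # shoelace = width x height
  degenerate <- rbind(c(0, 0), c(1, 1), c(2, 2))
  expect_error(cell_density(10, degenerate), "degenerate")
})

test_that("domains are assigned by point-in-polygon", {
  polys <- list(A = rbind(c(0, 0), c(100, 0), c(100, 100), c(0, 100)),
                B = rbind(c(200, 0), c(300, 0), c(300, 100), c(200, 100)))
  cells <- data.frame(x = c(50, 250, 150), y = c(50, 50, 50))
  expect_equal(assign_domains(cells, polys), c("A", "B", "none"))
})
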