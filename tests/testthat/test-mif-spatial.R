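full_markers <- function(...) {
  m <- setNames(rep(FALSE, length(MIF_MARKERS)), MIF_MARKERS)
  on <- c(...)
  m[on] <- TRUE
  as.list(m)
}

test_that("phenotype rules follow the documented priority order", {
  expect_identical(call_phenotype(full_markers("CD16", "CD56")), "NK")
  expect_identical(call_phenotype(full_markers("CD3", "CD4", "FOXP3")),
                   "Treg")
  expect_identical(call_phenotype(full_markers("CD3", "CD4")), "CD4T")
  expect_identical(call_phenotype(full_markers("CD3", "CD8")), "CD8T")
  expect_identical(call_phenotype(full_markers("CD3", "CD56")), "NKT")
  expect_identical(call_phenotype(full_markers("CD11b", "CD68")),
                   "CD11b_CD68")
  expect_identical(call_phenotype(full_markers("CD11b")), "Monocyte")
  expect_identical(call_phenotype(full_markers("CD68")), "Macrophage")
  expect_identical(call_phenotype(full_markers()), "other")
  # CD3+CD56+ wins over CD8 rule ordering ambiguity
  expect_identical(call_phenotype(full_markers("CD3", "CD56", "CD8")), "NKT")
})

test_that("missing marker keys are rejected by name", {
  m <- full_markers("CD3")
  m$FOXP3 <- NULL
  expect_error(call_phenotype(m), "FOXP3")
})

test_that("a straight border partitions cells by the 500 um band", {
  border <- mif_border(cbind(x = c(0, 0), y = c(-1000, 1000)),
                       tumor_point = c(500, 0))
  cells <- data.frame(x_um = c(300, 600, -600, 0, -499),
                      y_um = c(0, 0, 0, 0, 0))
  out <- partition_regions(cells, border, width = 500)
  expect_identical(as.character(out$region),
                   c("IM", "TN", "NLT", "IM", "IM"))
  expect_equal(out$border_dist_um, c(300, 600, 600, 0, 499))
})

test_that("polyline partition matches a dense-sampling distance oracle", {
  set.seed(21)
  # functional polyline x = f(y): tumor side is x > f(y)
  yy <- seq(0, 2000, length.out = 9)
  xx <- 1000 + cumsum(c(0, rnorm(8, 0, 150)))
  border <- mif_border(cbind(xx, yy), tumor_point = c(5000, 1000))
  cells <- data.frame(x_um = runif(200, 0, 2000), y_um = runif(200, 0, 2000))
  out <- partition_regions(cells, border, width = 500)
  # oracle: distance via dense point sampling along the border; side by
  # linear interpolation of f
  ts <- seq(0, 1, length.out = 2000)
  bx <- unlist(lapply(1:8, function(s) xx[s] + ts * (xx[s + 1] - xx[s])))
  by <- unlist(lapply(1:8, function(s) yy[s] + ts * (yy[s + 1] - yy[s])))
  for (i in seq_len(nrow(cells))) {
    d <- sqrt(min((cells$x_um[i] - bx)^2 + (cells$y_um[i] - by)^2))
    if (abs(d - 500) < 2) next    # oracle resolution guard at the boundary
    want <- if (d <= 500) "IM" else {
      if (cells$x_um[i] > approx(yy, xx, cells$y_um[i])$y) "TN" else "NLT"
    }
    expect_identical(as.character(out$region[i]), want)
    expect_lt(abs(out$border_dist_um[i] - d), 2)
  }
})

test_that("region labels are invariant under rigid motions", {
  set.seed(22)
  border <- mif_border(cbind(c(500, 600, 450, 700), c(0, 600, 1200, 2000)),
                       tumor_point = c(2000, 1000))
  cells <- data.frame(x_um = runif(100, 0, 2000),
                      y_um = runif(100, 0, 2000))
  r0 <- partition_regions(cells, border)$region
  th <- 0.73; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  shift <- c(333, -777)
  vc <- t(R %*% t(border$vertices)) + rep(shift, each = 4)
  tp <- as.numeric(R %*% border$tumor_point + shift)
  pc <- t(R %*% t(as.matrix(cells))) + rep(shift, each = 100)
  cells2 <- data.frame(x_um = pc[, 1], y_um = pc[, 2])
  r1 <- partition_regions(cells2, mif_border(vc, tumor_point = tp))$region
  expect_identical(r0, r1)
})

test_that("degenerate borders are rejected", {
  expect_error(mif_border(cbind(c(5, 5), c(7, 7)), tumor_point = c(1, 1)),
               "degenerate")
  expect_error(mif_border(cbind(c(0, 0), c(0, 10))), "tumor_point")
})

test_that("densities are counts over areas and sum across regions", {
  cells <- data.frame(x_um = runif(80), y_um = runif(80),
                      phenotype = rep(c("NK", "B"), c(50, 30)),
                      region = factor(rep(c("TN", "IM"), c(50, 30)),
                                      levels = c("TN", "IM", "NLT")))
  areas <- c(TN = 0.5, IM = 0.25, NLT = 0)
  d <- region_density(cells, areas, "NK")
  expect_equal(d$density_per_mm2[d$region == "TN"], 100)
  expect_equal(d$density_per_mm2[d$region == "IM"], 0)
  expect_true(is.na(d$density_per_mm2[d$region == "NLT"]))
  expect_equal(sum(d$n_cells), sum(cells$phenotype == "NK"))
})

test_that("a Poisson field density estimate lands in the sampling band", {
  f <- generate_mif_field(mif_spec(field_size_um = 2000,
                                   densities = c(NK = 200), seed = 31))
  cells <- partition_regions(f$cells, f$border)
  areas <- region_areas(f$border, c(0, 2000, 0, 2000), grid_n = 200)
  d <- region_density(cells, areas, "NK")
  for (r in c("TN", "IM", "NLT")) {
    a <- areas[[r]]
    est <- d$density_per_mm2[d$region == r]
    expect_lt(abs(est - 200), 3 * sqrt(200 / a))
  }
  expect_equal(sum(areas), 4, tolerance = 0.02)
})

test_that("Dunn z statistics match a first-principles computation", {
  vals <- c(1.2, 3.4, 2.2, 5.6, 4.4,
            2.1, 6.6, 5.2, 7.7, 6.1,
            9.1, 8.2, 7.5, 9.9, 8.8)
  grp <- rep(c("TN", "IM", "NLT"), each = 5)
  out <- dunn_test(vals, grp)
  for (i in seq_len(nrow(out))) {
    expect_equal(out$z[i],
                 brute_dunn_z(vals, grp, out$group1[i], out$group2[i]),
                 tolerance = 1e-12)
  }
  expect_equal(out$p_adjusted, pmin(out$p_value * 3, 1))
})

test_that("Dunn handles exchangeable and shifted groups correctly", {
  vals <- rep(c(1, 2, 3, 4, 5), 3)
  grp <- rep(c("a", "b", "c"), each = 5)
  out <- dunn_test(vals, grp)
  expect_equal(out$z, rep(0, 3))
  expect_equal(out$p_adjusted, rep(1, 3))
  set.seed(33)
  v2 <- c(rnorm(20), rnorm(20), rnorm(20, mean = 3))
  g2 <- rep(c("a", "b", "c"), each = 20)
  o2 <- dunn_test(v2, g2)
  expect_lt(o2$p_adjusted[o2$group1 == "a" & o2$group2 == "c"], 0.01)
  expect_error(dunn_test(c(1, 2, 3), c("a", "b", "c")), ">= 2 observations")
})

test_that("nearest-neighbor proximity applies the 300 um elimination", {
  cells <- data.frame(x_um = c(0, 100, 250), y_um = c(0, 0, 0),
                      phenotype = c("CD8T", "NK", "NK"))
  nn <- nearest_neighbor(cells, "CD8T", "NK")
  expect_equal(nn$mean_distance, 100)
  expect_identical(nn$n_retained, 1L)
  far <- data.frame(x_um = c(0, 400), y_um = c(0, 0),
                    phenotype = c("CD8T", "NK"))
  nn2 <- nearest_neighbor(far, "CD8T", "NK")
  expect_identical(nn2$n_retained, 0L)
  expect_true(is.na(nn2$mean_distance))
  expect_error(nearest_neighbor(cells, "CD8T", "Treg"), "no target cells")
})

test_that("nearest-neighbor matches the O(n*m) brute-force scan", {
  set.seed(41)
  cells <- data.frame(x_um = runif(300, 0, 1500),
                      y_um = runif(300, 0, 1500),
                      phenotype = rep(c("CD8T", "NK"), each = 150))
  nn <- nearest_neighbor(cells, "CD8T", "NK")
  src <- cells[cells$phenotype == "CD8T", ]
  tgt <- cells[cells$phenotype == "NK", ]
  brute <- numeric(150)
  for (i in 1:150) {
    best <- Inf
    for (j in 1:150) {
      dd <- sqrt((src$x_um[i] - tgt$x_um[j])^2 +
                   (src$y_um[i] - tgt$y_um[j])^2)
      if (dd < best) best <- dd
    }
    brute[i] <- best
  }
  expect_equal(nn$distances, brute)
  expect_equal(nn$mean_distance, mean(brute[brute <= 300]))
  # shrinking d_max never grows the retained set
  nn150 <- nearest_neighbor(cells, "CD8T", "NK", d_max = 150)
  expect_lte(nn150$n_retained, nn$n_retained)
  expect_true(all(nn150$retained <= 150))
})

test_that("density correlations match a rank-then-correlate oracle", {
  x <- c(3, 1, 4, 1, 5, 9, 2, 6, 5, 3)
  m <- cbind(NK = x, cDC = 2 * x, CD8T = c(9, 8, 7, 6, 5, 4, 3, 2, 1, 0),
             flat = rep(1, 10))
  dc <- density_correlation(m)
  expect_equal(dc$rho["NK", "cDC"], 1)
  expect_equal(dc$rho["NK", "CD8T"], cor(rank(x), rank(m[, "CD8T"])),
               tolerance = 1e-12)
  expect_true(is.na(dc$rho["NK", "flat"]))
  expect_identical(dc$rho, t(dc$rho))
  expect_equal(unname(diag(dc$rho)), rep(1, 4))
  expect_error(density_correlation(m[1:3, ]), ">= 4 samples")
})
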