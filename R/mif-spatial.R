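#' Call an immune phenotype from marker booleans
#'
#' Evaluates the marker-colocalization rules in a fixed most-specific-first
#' priority order: Treg (CD3+CD4+FOXP3+) before CD4+T; NK (CD3-CD16+CD56+)
#' and NKT (CD3+CD56+) before the T-cell rules; CD11b+CD68+ before
#' monocyte (CD11b+) and macrophage (CD68+); then CD8T (CD3+CD8+),
#' CD4T (CD3+CD4+), B (CD20+), cDC (CD11c+), MemoryT (CD45RO+),
#' Neutrophil (MPO+). Cells matching no rule are `"other"`.
#'
#' @param markers Named logical vector covering [MIF_MARKERS], or a
#'   data.frame with one logical column per marker (vectorized).
#' @return Phenotype label(s).
#' @export
call_phenotype <- function(markers) {
  if (is.data.frame(markers)) {
    miss <- setdiff(MIF_MARKERS, names(markers))
    if (length(miss)) stop("missing required marker column(s): ",
                           paste(miss, collapse = ", "))
    m <- markers
    get <- function(k) as.logical(m[[k]])
  } else {
    miss <- setdiff(MIF_MARKERS, names(markers))
    if (length(miss)) stop("missing required marker key(s): ",
                           paste(miss, collapse = ", "))
    get <- function(k) as.logical(markers[[k]])
  }
  n <- length(get("CD3"))
  out <- rep("other", n)
  rule <- function(cond, label) {
    out[out == "other" & cond] <<- label
  }
  rule(get("CD3") & get("CD4") & get("FOXP3"), "Treg")
  rule(!get("CD3") & get("CD16") & get("CD56"), "NK")
  rule(get("CD3") & get("CD56"), "NKT")
  rule(get("CD3") & get("CD8"), "CD8T")
  rule(get("CD3") & get("CD4"), "CD4T")
  rule(get("CD11b") & get("CD68"), "CD11b_CD68")
  rule(get("CD11c"), "cDC")
  rule(get("CD11b"), "Monocyte")
  rule(get("CD68"), "Macrophage")
  rule(get("CD20"), "B")
  rule(get("CD45RO"), "MemoryT")
  rule(get("MPO"), "Neutrophil")
  out
}

#' Tumor border annotation
#'
#' A polyline (open) or polygon (closed) in micrometer coordinates. For a
#' polyline the tumor side is identified by `tumor_point`, a reference
#' point known to lie on the tumor side; for a polygon the tumor is the
#' interior.
#'
#' @param vertices Two-column matrix (x, y) of border vertices, in um.
#' @param tumor_point Length-2 reference point on the tumor side
#'   (polyline only).
#' @param closed Treat the vertices as a closed polygon.
#' @return A `mif_border` list.
#' @export
mif_border <- function(vertices, tumor_point = NULL, closed = FALSE) {
  vertices <- as.matrix(vertices)
  stopifnot(ncol(vertices) == 2, nrow(vertices) >= 2)
  seg_len <- sqrt(rowSums((vertices[-1, , drop = FALSE] -
                           vertices[-nrow(vertices), , drop = FALSE])^2))
  if (sum(seg_len) <= 0) stop("degenerate border: zero total length")
  if (!closed && is.null(tumor_point)) {
    stop("polyline border needs a tumor_point to orient the tumor side")
  }
  structure(list(vertices = vertices, tumor_point = tumor_point,
                 closed = closed), class = "mif_border")
}

# Distance from points to each border segment; returns per-point minimum
# distance and the index/parameters of the nearest segment.
dist_to_border <- function(x, y, border) {
  v <- border$vertices
  nseg <- nrow(v) - 1 + as.integer(border$closed)
  n <- length(x)
  best <- rep(Inf, n); bseg <- rep(1L, n); bt <- rep(0, n)
  for (s in seq_len(nseg)) {
    a <- v[s, ]
    b <- v[if (s == nrow(v)) 1 else s + 1, ]
    ab <- b - a
    len2 <- sum(ab^2)
    t <- if (len2 == 0) rep(0, n) else
      pmin(pmax(((x - a[1]) * ab[1] + (y - a[2]) * ab[2]) / len2, 0), 1)
    dx <- x - (a[1] + t * ab[1]); dy <- y - (a[2] + t * ab[2])
    d <- sqrt(dx^2 + dy^2)
    upd <- d < best
    best[upd] <- d[upd]; bseg[upd] <- s; bt[upd] <- t[upd]
  }
  list(dist = best, seg = bseg, t = bt)
}

# Even-odd ray casting point-in-polygon.
in_polygon <- function(x, y, v) {
  n <- nrow(v)
  inside <- rep(FALSE, length(x))
  j <- n
  for (i in seq_len(n)) {
    xi <- v[i, 1]; yi <- v[i, 2]; xj <- v[j, 1]; yj <- v[j, 2]
    cross <- ((yi > y) != (yj > y)) &
      (x < (xj - xi) * (y - yi) / (yj - yi + 1e-300) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

# Which side of the border is "tumor"? Signed cross product at the nearest
# segment, oriented so the tumor_point reference is positive.
tumor_side <- function(x, y, border) {
  if (border$closed) return(in_polygon(x, y, border$vertices))
  v <- border$vertices
  side_sign <- function(px, py) {
    nb <- dist_to_border(px, py, border)
    a <- v[nb$seg, , drop = FALSE]
    b <- v[nb$seg + 1, , drop = FALSE]
    sign((b[, 1] - a[, 1]) * (py - a[, 2]) - (b[, 2] - a[, 2]) * (px - a[, 1]))
  }
  ref <- side_sign(border$tumor_point[1], border$tumor_point[2])
  if (ref == 0) stop("tumor_point lies exactly on the border")
  side_sign(x, y) * ref > 0
}

#' Partition cells into tumor nest, invasive margin and normal tissue
#'
#' The invasive margin (IM) is the band within `width` (default 500 um) of
#' the tumor border on either side; beyond the band, cells on the tumor
#' side are tumor nest (TN) and the rest normal liver tissue (NLT).
#'
#' @param cells Data frame with `x_um`, `y_um`.
#' @param border A [mif_border()].
#' @param width Band half-width in micrometers (500 each side).
#' @return `cells` with added `region` factor (TN/IM/NLT) and
#'   `border_dist_um`.
#' @export
partition_regions <- function(cells, border, width = 500) {
  stopifnot(inherits(border, "mif_border"), width > 0)
  if (nrow(cells) == 0) {
    cells$region <- factor(character(), levels = c("TN", "IM", "NLT"))
    cells$border_dist_um <- numeric()
    return(cells)
  }
  d <- dist_to_border(cells$x_um, cells$y_um, border)$dist
  tum <- tumor_side(cells$x_um, cells$y_um, border)
  region <- ifelse(d <= width, "IM", ifelse(tum, "TN", "NLT"))
  cells$region <- factor(region, levels = c("TN", "IM", "NLT"))
  cells$border_dist_um <- d
  cells
}

#' Approximate region areas within a rectangular field
#'
#' Labels a fine grid of sample points over the field and converts label
#' fractions to areas in mm^2 (numerical approximation; accuracy grows
#' with `grid_n`).
#'
#' @param border A [mif_border()].
#' @param field_bounds `c(xmin, xmax, ymin, ymax)` in um.
#' @param width IM band half-width, um.
#' @param grid_n Grid resolution per axis (default 300).
#' @return Named numeric vector: TN, IM, NLT areas in mm^2.
#' @export
region_areas <- function(border, field_bounds, width = 500, grid_n = 300) {
  gx <- seq(field_bounds[1], field_bounds[2], length.out = grid_n)
  gy <- seq(field_bounds[3], field_bounds[4], length.out = grid_n)
  pts <- expand.grid(x_um = gx, y_um = gy)
  lab <- partition_regions(pts, border, width)$region
  frac <- table(lab) / length(lab)
  tot <- (field_bounds[2] - field_bounds[1]) *
    (field_bounds[4] - field_bounds[3]) / 1e6
  stats::setNames(as.numeric(frac) * tot, names(frac))
}

#' Phenotype density per region
#'
#' @param cells Output of [partition_regions()] with a `phenotype` column.
#' @param areas Region areas in mm^2 (from [region_areas()]).
#' @param phenotype Phenotype label to count.
#' @return Data frame: `region`, `n_cells`, `area_mm2`, `density_per_mm2`
#'   (`NA` where the region has zero area).
#' @export
region_density <- function(cells, areas, phenotype) {
  regions <- c("TN", "IM", "NLT")
  out <- lapply(regions, function(r) {
    n <- sum(cells$region == r & cells$phenotype == phenotype, na.rm = TRUE)
    a <- if (r %in% names(areas)) areas[[r]] else 0
    data.frame(region = r, n_cells = n, area_mm2 = a,
               density_per_mm2 = if (a > 0) n / a else NA_real_)
  })
  do.call(rbind, out)
}

#' Dunn's multiple-comparisons test
#'
#' Nonparametric pairwise comparisons after Kruskal-Wallis: all samples are
#' pooled and ranked (mid-ranks for ties); each pair of groups is compared
#' by the difference in mean ranks over its standard error under the null,
#' with the tie correction, and p-values are adjusted for the number of
#' pairs (Bonferroni by default).
#'
#' @param values Numeric observations.
#' @param groups Group labels (>= 3 groups, >= 2 observations each).
#' @param p_adjust_method Passed to [stats::p.adjust()].
#' @return Data frame: `group1`, `group2`, `z`, `p_value`, `p_adjusted`.
#' @export
dunn_test <- function(values, groups, p_adjust_method = "bonferroni") {
  groups <- factor(groups)
  if (any(table(groups) < 2)) stop("every group needs >= 2 observations")
  if (nlevels(groups) < 3) stop("need >= 3 groups")
  N <- length(values)
  r <- rank(values)
  rbar <- tapply(r, groups, mean)
  ns <- tapply(r, groups, length)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  lev <- levels(groups)
  pairs <- utils::combn(lev, 2)
  out <- apply(pairs, 2, function(pr) {
    i <- pr[1]; j <- pr[2]
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / ns[[i]] + 1 / ns[[j]]))
    z <- (rbar[[i]] - rbar[[j]]) / se
    data.frame(group1 = i, group2 = j, z = z,
               p_value = 2 * stats::pnorm(-abs(z)))
  })
  out <- do.call(rbind, out)
  out$p_adjusted <- stats::p.adjust(out$p_value, method = p_adjust_method)
  rownames(out) <- NULL
  out
}

#' Nearest-neighbor proximity between two phenotypes
#'
#' For every source cell, the Euclidean distance from its nuclear center to
#' the closest target cell; distances over `d_max` (default 300 um) are
#' eliminated, and the mean is taken over the retained distances only.
#'
#' @param cells Data frame with `x_um`, `y_um`, `phenotype`.
#' @param source,target Phenotype labels.
#' @param d_max Elimination threshold in um.
#' @param breaks Histogram breaks (um) for the retained distances.
#' @return A `proximity_result` list: `distances` (all nearest distances),
#'   `retained`, `mean_distance` (`NA` if nothing retained), `n_source`,
#'   `n_retained`, `histogram`.
#' @export
nearest_neighbor <- function(cells, source, target, d_max = 300,
                             breaks = seq(0, 300, by = 20)) {
  src <- cells[cells$phenotype == source, , drop = FALSE]
  tgt <- cells[cells$phenotype == target, , drop = FALSE]
  if (nrow(tgt) == 0) stop("no target cells of phenotype ", target)
  if (nrow(src) == 0) {
    return(structure(list(distances = numeric(), retained = numeric(),
                          mean_distance = NA_real_, n_source = 0L,
                          n_retained = 0L, histogram = NULL),
                     class = "proximity_result"))
  }
  d <- vapply(seq_len(nrow(src)), function(i) {
    sqrt(min((src$x_um[i] - tgt$x_um)^2 + (src$y_um[i] - tgt$y_um)^2))
  }, numeric(1))
  keep <- d <= d_max
  retained <- d[keep]
  h <- if (length(retained)) {
    graphics::hist(retained, breaks = unique(c(breaks, max(breaks, retained))),
                   plot = FALSE)
  } else NULL
  structure(list(distances = d, retained = retained,
                 mean_distance = if (length(retained)) mean(retained)
                 else NA_real_,
                 n_source = nrow(src), n_retained = sum(keep),
                 histogram = h),
            class = "proximity_result")
}

#' Pairwise density correlations between phenotypes
#'
#' Spearman (default) or Pearson correlations of per-sample phenotype
#' densities, with p-values from [stats::cor.test()]. Constant columns
#' yield `NA` for their pairs.
#'
#' @param densities Samples x phenotypes numeric matrix or data frame.
#' @param method `"spearman"` or `"pearson"`.
#' @return List of symmetric matrices `rho` (unit diagonal) and `p_value`.
#' @export
density_correlation <- function(densities,
                                method = c("spearman", "pearson")) {
  method <- match.arg(method)
  m <- as.matrix(densities)
  if (nrow(m) < 4) stop("need >= 4 samples")
  k <- ncol(m)
  rho <- matrix(NA_real_, k, k, dimnames = list(colnames(m), colnames(m)))
  pv <- rho
  diag(rho) <- 1
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    if (stats::sd(m[, i]) == 0 || stats::sd(m[, j]) == 0) next
    ct <- suppressWarnings(stats::cor.test(m[, i], m[, j], method = method,
                                           exact = FALSE))
    rho[i, j] <- rho[j, i] <- unname(ct$estimate)
    pv[i, j] <- pv[j, i] <- ct$p.value
  }
  list(rho = rho, p_value = pv, method = method)
}
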