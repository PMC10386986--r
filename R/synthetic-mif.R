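#' Immune phenotypes and their marker definitions
#'
#' Phenotypes are called from boolean marker colocalization: Treg
#' (CD3+CD4+FOXP3+), NK (CD3-CD16+CD56+), NKT (CD3+CD56+), CD8T (CD3+CD8+),
#' CD4T (CD3+CD4+), MemoryT (CD45RO+), B (CD20+), cDC (CD11c+), Monocyte
#' (CD11b+), Macrophage (CD68+), CD11b_CD68 (CD11b+CD68+), Neutrophil (MPO+).
#'
#' @format Character vector of phenotype labels.
#' @export
MIF_PHENOTYPES <- c("Treg", "NK", "NKT", "CD8T", "CD4T", "MemoryT", "B",
                    "cDC", "Monocyte", "Macrophage", "CD11b_CD68",
                    "Neutrophil")

#' Markers used for phenotype calling
#' @format Character vector of the twelve phenotyping markers (panels 1-2).
#' @export
MIF_MARKERS <- c("CD3", "CD4", "CD8", "CD16", "CD56", "FOXP3",
                 "CD11b", "CD11c", "CD20", "CD68", "MPO", "CD45RO")

# Canonical marker pattern for each phenotype (all other markers FALSE).
phenotype_markers <- function(phenotype) {
  on <- switch(phenotype,
    Treg = c("CD3", "CD4", "FOXP3"),
    NK = c("CD16", "CD56"),
    NKT = c("CD3", "CD56"),
    CD8T = c("CD3", "CD8"),
    CD4T = c("CD3", "CD4"),
    MemoryT = "CD45RO",
    B = "CD20",
    cDC = "CD11c",
    Monocyte = "CD11b",
    Macrophage = "CD68",
    CD11b_CD68 = c("CD11b", "CD68"),
    Neutrophil = "MPO",
    stop("unknown phenotype: ", phenotype))
  m <- stats::setNames(rep(FALSE, length(MIF_MARKERS)), MIF_MARKERS)
  m[on] <- TRUE
  m
}

#' Specification of a synthetic multiplex-immunofluorescence field
#'
#' Emulates the mIF comparison between early-recurrence and non-recurrence
#' patients: the non-recurrence group has a higher NK-cell density and CD8+T
#' cells attracted toward NK cells (shorter nearest-neighbor distances);
#' the early-recurrence group has sparser, spatially independent NK cells
#' and more monocytes/macrophages.
#'
#' @param group `"none_recurrence"` or `"early_recurrence"`.
#' @param field_size_um Square field side length in micrometers.
#' @param densities Named vector, cells per mm^2 per phenotype; defaults
#'   depend on `group`.
#' @param nk_cd8_attraction In `[0, 1]`: probability that a CD8+T cell is
#'   placed near a random NK cell (Gaussian displacement, sd 40 um) instead
#'   of uniformly; 0 gives independent homogeneous Poisson patterns.
#' @param seed Integer seed.
#' @return A `mif_spec` list.
#' @export
mif_spec <- function(group = c("none_recurrence", "early_recurrence"),
                     field_size_um = 2000,
                     densities = NULL,
                     nk_cd8_attraction = NULL,
                     seed = 1L) {
  group <- match.arg(group)
  if (is.null(densities)) {
    densities <- c(Treg = 40, NK = 25, NKT = 30, CD8T = 120, CD4T = 110,
                   MemoryT = 90, B = 50, cDC = 45, Monocyte = 55,
                   Macrophage = 70, CD11b_CD68 = 25, Neutrophil = 35)
    if (group == "early_recurrence") {
      densities[c("NK", "cDC")] <- c(10, 30)
      densities[c("Monocyte", "Macrophage")] <- c(85, 105)
    }
  }
  if (is.null(nk_cd8_attraction)) {
    nk_cd8_attraction <- if (group == "none_recurrence") 0.35 else 0
  }
  stopifnot(field_size_um > 0, all(densities >= 0),
            nk_cd8_attraction >= 0, nk_cd8_attraction <= 1,
            all(names(densities) %in% MIF_PHENOTYPES))
  structure(list(group = group, field_size_um = field_size_um,
                 densities = densities,
                 nk_cd8_attraction = nk_cd8_attraction,
                 seed = as.integer(seed)),
            class = "mif_spec")
}

#' Generate a synthetic mIF cell table with a tumor border
#'
#' Each phenotype is an independent homogeneous Poisson point process at its
#' requested density over the square field, except that a fraction
#' `nk_cd8_attraction` of CD8+T cells is displaced to lie near NK cells.
#' Marker booleans are set to the phenotype's canonical pattern, so
#' [call_phenotype()] round-trips every cell. A vertical tumor border at
#' mid-field is returned (tumor side: larger x).
#'
#' @param spec A [mif_spec()].
#' @return List with `cells` (data.frame: x_um, y_um, phenotype, one logical
#'   column per marker) and `border` (a [mif_border()]).
#' @export
generate_mif_field <- function(spec) {
  stopifnot(inherits(spec, "mif_spec"))
  L <- spec$field_size_um
  area_mm2 <- (L / 1000)^2
  withr_seed(spec$seed, {
    tabs <- lapply(names(spec$densities), function(ph) {
      n <- stats::rpois(1, spec$densities[[ph]] * area_mm2)
      if (n == 0) return(NULL)
      data.frame(x_um = stats::runif(n, 0, L), y_um = stats::runif(n, 0, L),
                 phenotype = ph, stringsAsFactors = FALSE)
    })
    cells <- do.call(rbind, tabs)
    if (is.null(cells)) {
      cells <- data.frame(x_um = numeric(), y_um = numeric(),
                          phenotype = character())
    }
    nk <- cells[cells$phenotype == "NK", , drop = FALSE]
    w <- spec$nk_cd8_attraction
    if (w > 0 && nrow(nk) > 0) {
      is_cd8 <- which(cells$phenotype == "CD8T")
      pull <- is_cd8[stats::runif(length(is_cd8)) < w]
      if (length(pull)) {
        anchor <- sample(nrow(nk), length(pull), replace = TRUE)
        cells$x_um[pull] <- pmin(pmax(
          nk$x_um[anchor] + stats::rnorm(length(pull), sd = 40), 0), L)
        cells$y_um[pull] <- pmin(pmax(
          nk$y_um[anchor] + stats::rnorm(length(pull), sd = 40), 0), L)
      }
    }
  })
  if (nrow(cells)) {
    mk <- t(vapply(cells$phenotype, phenotype_markers,
                   logical(length(MIF_MARKERS))))
    rownames(mk) <- NULL
    cells <- cbind(cells, as.data.frame(mk))
  } else {
    for (m in MIF_MARKERS) cells[[m]] <- logical()
  }
  border <- mif_border(cbind(x = c(L / 2, L / 2), y = c(0, L)),
                       tumor_point = c(3 * L / 4, L / 2))
  list(cells = cells, border = border)
}

#' Write a cell table and border annotation to disk
#'
#' `cells.csv` has x_um, y_um, phenotype and one logical column per marker;
#' `border.geojson` is a GeoJSON LineString (coordinates in micrometers)
#' with a `tumor_point` property giving a reference point on the tumor side.
#'
#' @param field Output of [generate_mif_field()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_mif_field <- function(field, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(field$cells, file.path(dir, "cells.csv"),
                   row.names = FALSE)
  b <- field$border
  coords <- paste(sprintf("[%g, %g]", b$vertices[, 1], b$vertices[, 2]),
                  collapse = ", ")
  json <- sprintf(paste0(
    '{"type": "Feature", "geometry": {"type": "LineString", ',
    '"coordinates": [%s]}, "properties": {"tumor_point": [%g, %g]}}'),
    coords, b$tumor_point[1], b$tumor_point[2])
  writeLines(json, file.path(dir, "border.geojson"))
  invisible(dir)
}
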