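#' Specification of a synthetic transplant cohort
#'
#' Defines the conditions under which [generate_cohort()] simulates a
#' post-transplant hepatocellular-carcinoma cohort: per-patient latent tissue
#' scores drive an exponential recurrence hazard through known log-hazard
#' effects, with independent exponential censoring and administrative
#' censoring at the follow-up horizon.
#'
#' Defaults emulate a 380-patient cohort followed for 60 months with the
#' immune-cell category as the dominant prognostic tissue; tiles carry the
#' latent signal through their texture contrast.
#'
#' @param n_patients Number of patients (>= 2).
#' @param tiles_per_patient_per_class Tiles simulated per patient and class.
#' @param true_beta Named vector of log-hazard effects per unit latent score,
#'   one entry per tissue class ([TISSUE_CLASSES]).
#' @param baseline_hazard_rate Baseline recurrence hazard per month (> 0).
#' @param censoring_rate Exponential censoring rate per month (> 0).
#' @param recurrence_horizon Administrative follow-up cap in months.
#' @param tile_size_px Side length of generated tiles.
#' @param seed Integer seed fixing the full output.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_patients = 380,
                        tiles_per_patient_per_class = 4,
                        true_beta = c(TR = 0.3, NLT = 0, PA = 0.1,
                                      FT = 0.1, HNT = 0.2, IC = 0.7),
                        baseline_hazard_rate = 0.008,
                        censoring_rate = 0.01,
                        recurrence_horizon = 60,
                        tile_size_px = 64,
                        seed = 1L) {
  stopifnot(n_patients >= 2,
            baseline_hazard_rate > 0, censoring_rate > 0,
            recurrence_horizon > 0, tiles_per_patient_per_class >= 0)
  beta <- stats::setNames(rep(0, length(TISSUE_CLASSES)), TISSUE_CLASSES)
  beta[names(true_beta)] <- true_beta
  if (!all(names(true_beta) %in% TISSUE_CLASSES)) {
    stop("true_beta names must be tissue classes")
  }
  structure(list(n_patients = as.integer(n_patients),
                 tiles_per_patient_per_class =
                   as.integer(tiles_per_patient_per_class),
                 true_beta = beta,
                 baseline_hazard_rate = baseline_hazard_rate,
                 censoring_rate = censoring_rate,
                 recurrence_horizon = recurrence_horizon,
                 tile_size_px = as.integer(tile_size_px),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# Deterministic 31-bit sub-seed for patient/class/tile streams.
derive_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  h <- 0
  for (p in parts) h <- (h * 7919 + as.numeric(p) + 1) %% 2147483647
  as.integer(h)
}

#' Simulate a survival cohort with tissue-driven hazard
#'
#' Per patient, a latent score per tissue class is drawn i.i.d. standard
#' normal; the recurrence hazard is
#' `baseline_hazard_rate * exp(sum_t true_beta[t] * score_t)`.
#' Recurrence and censoring times are exponential; time to recurrence (TTR)
#' is their minimum capped at the horizon. Recurrence-free survival (RFS)
#' additionally allows an independent death event (rate fixed at a quarter
#' of the baseline hazard). Tiles are *described*, not materialized: each is
#' a deterministic function of the spec seed, patient, class and index, with
#' texture contrast `1 + 0.35 * tanh(score_t)` so appearance encodes risk;
#' use [cohort_tile()] to realize pixels.
#'
#' @param spec A [cohort_spec()].
#' @return A `synthetic_cohort` list with elements `patients` (data.frame:
#'   patient_id, ttr_months, recurrence_event, rfs_months, rfs_event, plus
#'   covariates age and sex), `latent_scores` (n x 6 matrix, the simulation
#'   truth), `tiles` (data.frame describing every tile) and `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_patients
  withr_seed(spec$seed, {
    z <- matrix(stats::rnorm(n * 6), n, 6,
                dimnames = list(NULL, TISSUE_CLASSES))
    lp <- drop(z %*% spec$true_beta)
    hazard <- spec$baseline_hazard_rate * exp(lp)
    t_rec <- stats::rexp(n, rate = hazard)
    t_cen <- stats::rexp(n, rate = spec$censoring_rate)
    t_dth <- stats::rexp(n, rate = spec$baseline_hazard_rate / 4)
    horizon <- spec$recurrence_horizon

    ttr <- pmin(t_rec, t_cen, horizon)
    ttr_event <- t_rec <= pmin(t_cen, horizon)
    rfs <- pmin(t_rec, t_dth, t_cen, horizon)
    rfs_event <- pmin(t_rec, t_dth) <= pmin(t_cen, horizon)

    patients <- data.frame(
      patient_id = sprintf("P%04d", seq_len(n)),
      ttr_months = round(ttr, 4),
      recurrence_event = ttr_event,
      rfs_months = round(rfs, 4),
      rfs_event = rfs_event,
      age = round(stats::rnorm(n, 55, 9), 1),
      sex = sample(c("M", "F"), n, replace = TRUE, prob = c(0.8, 0.2)),
      stringsAsFactors = FALSE
    )
  })
  k <- spec$tiles_per_patient_per_class
  tiles <- if (k > 0) {
    expand.grid(idx = seq_len(k), class = TISSUE_CLASSES,
                patient = seq_len(n), KEEP.OUT.ATTRS = FALSE,
                stringsAsFactors = FALSE)
  } else {
    data.frame(idx = integer(), class = character(), patient = integer())
  }
  if (nrow(tiles)) {
    tiles$patient_id <- sprintf("P%04d", tiles$patient)
    tiles$contrast <- 1 + 0.35 * tanh(z[cbind(tiles$patient,
                                              match(tiles$class,
                                                    TISSUE_CLASSES))])
    tiles$tile_seed <- mapply(derive_seed, spec$seed, tiles$patient,
                              match(tiles$class, TISSUE_CLASSES), tiles$idx)
  }
  structure(list(patients = patients, latent_scores = z,
                 tiles = tiles, spec = spec),
            class = "synthetic_cohort")
}

#' Realize one cohort tile
#'
#' @param cohort A `synthetic_cohort`.
#' @param patient_id Patient identifier (e.g. `"P0001"`).
#' @param cls Tissue class code.
#' @param idx Tile index within that patient/class.
#' @return A `tissue_tile` (see [generate_tissue_tile()]).
#' @export
cohort_tile <- function(cohort, patient_id, cls, idx = 1L) {
  rows <- cohort$tiles
  r <- rows[rows$patient_id == patient_id & rows$class == cls &
              rows$idx == idx, ]
  if (nrow(r) != 1) stop("no such tile: ", patient_id, "/", cls, "/", idx)
  generate_tissue_tile(cls, cohort$spec$tile_size_px, r$tile_seed,
                       contrast = r$contrast)
}

#' Serialize a cohort to CSV (and optionally PNG tiles)
#'
#' Writes `patients.csv` (and `tiles/<patient>/<class>/<idx>.png` when
#' `write_tiles = TRUE`) under `dir`. Deterministic: the same spec yields
#' byte-identical files.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @param write_tiles Also write PNG tiles (slow for large cohorts).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, write_tiles = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort$patients, file.path(dir, "patients.csv"),
                   row.names = FALSE)
  if (write_tiles) {
    for (i in seq_len(nrow(cohort$tiles))) {
      r <- cohort$tiles[i, ]
      d <- file.path(dir, "tiles", r$patient_id, r$class)
      dir.create(d, recursive = TRUE, showWarnings = FALSE)
      write_tile_png(cohort_tile(cohort, r$patient_id, r$class, r$idx),
                     file.path(d, paste0(r$idx, ".png")))
    }
  }
  invisible(dir)
}

#' Subset a cohort by patient
#' @param cohort A `synthetic_cohort`.
#' @param patient_ids Patients to keep.
#' @return A `synthetic_cohort` restricted to those patients.
#' @export
subset_cohort <- function(cohort, patient_ids) {
  keep <- cohort$patients$patient_id %in% patient_ids
  structure(list(patients = cohort$patients[keep, , drop = FALSE],
                 latent_scores = cohort$latent_scores[keep, , drop = FALSE],
                 tiles = cohort$tiles[cohort$tiles$patient_id %in%
                                        patient_ids, , drop = FALSE],
                 spec = cohort$spec),
            class = "synthetic_cohort")
}
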