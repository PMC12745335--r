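## Synthetic cohorts from the generative regional growth model, thrombus
## presence mapping, and patient-record bookkeeping.

#' Cohort specification for the generative growth model
#'
#' Regional growth is generated as
#' GR_im = beta0 + beta1 sigma_im + b0m + b1m sigma_im + eps_im with
#' patient-level random effects drawn from zero-mean normals.
#'
#' @param n_patients number of patients (>= 2).
#' @param beta0 fixed intercept (%/year).
#' @param beta1 fixed stress slope (%/(year.kPa)).
#' @param sd_b0 SD of random intercepts (%/year).
#' @param sd_b1 SD of random slopes (%/(year.kPa)).
#' @param sd_eps residual SD (%/year). The default reflects the spread of
#'   regional growth rates around the patient lines at the preset effect
#'   sizes (no reported estimate pins the residual directly).
#' @param n_regions regions per patient.
#' @param seed integer seed.
#' @export
cohort_spec <- function(n_patients = 9L, beta0 = 0, beta1 = 0.095,
                        sd_b0 = 27.8, sd_b1 = 0.13, sd_eps = 10,
                        n_regions = 38L, seed = 1L) {
  if (n_patients < 2) stop("need at least 2 patients")
  if (any(c(sd_b0, sd_b1, sd_eps) < 0)) stop("SDs must be non-negative")
  structure(list(n_patients = as.integer(n_patients), beta0 = beta0,
                 beta1 = beta1, sd_b0 = sd_b0, sd_b1 = sd_b1,
                 sd_eps = sd_eps, n_regions = as.integer(n_regions),
                 seed = as.integer(seed)), class = "cohort_spec")
}

#' Default regional stress generator
#'
#' Smooth per-region maximum-principal stress profiles typical of the
#' descending aorta at systole: a 50-400 kPa range with a patient-level
#' offset, a smooth axial trend and local variation.
#'
#' @param m patient index; `n_regions` regions.
#' @return stress in kPa per region.
#' @export
default_stress_generator <- function(m, n_regions) {
  i <- seq_len(n_regions) / n_regions
  base <- 150 + rnorm(1, 0, 40) +
    80 * sin(2 * pi * runif(1) + 2 * pi * i * runif(1, 0.5, 1.5)) +
    60 * i
  pmax(base + rnorm(n_regions, 0, 20), 20)
}

#' Generate a cohort of regional stress/growth observations
#'
#' Draws per-patient random effects and residuals from the generative
#' model of [cohort_spec()], with regional stress from `stress_generator`.
#' Pure function of (spec, seed).
#'
#' @param spec a [cohort_spec()].
#' @param stress_generator function(m, n_regions) returning regional stress
#'   (kPa); called inside the seeded RNG stream.
#' @return data frame with columns `patient_id`, `region`, `stress_kpa`,
#'   `growth_pct_per_year`; attributes `b0`, `b1` hold the drawn random
#'   effects (ground truth for recovery tests).
#' @export
make_cohort <- function(spec, stress_generator = default_stress_generator) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    b0 <- rnorm(spec$n_patients, 0, spec$sd_b0)
    b1 <- rnorm(spec$n_patients, 0, spec$sd_b1)
    rows <- lapply(seq_len(spec$n_patients), function(m) {
      stress <- stress_generator(m, spec$n_regions)
      eps <- rnorm(spec$n_regions, 0, spec$sd_eps)
      growth <- spec$beta0 + spec$beta1 * stress + b0[m] + b1[m] * stress + eps
      data.frame(patient_id = sprintf("S%02d", m),
                 region = seq_len(spec$n_regions),
                 stress_kpa = stress, growth_pct_per_year = growth)
    })
    out <- do.call(rbind, rows)
    attr(out, "b0") <- b0
    attr(out, "b1") <- b1
    out
  })
}

#' Per-node thrombus presence on a structured surface
#'
#' A node is thrombus-covered when the distance to the nearest thrombus
#' node is smaller than the node's local radius (its distance to the layer
#' center) -- the "calculated radius of the node". Inputs are assumed
#' ICP-aligned. With no thrombus nodes the map is all-absent.
#'
#' @param structured a `structured_surface`.
#' @param thrombus_nodes n x 3 matrix of thrombus node coordinates (or
#'   `NULL`).
#' @return binary matrix (n_layers x n_nodes).
#' @export
thrombus_presence <- function(structured, thrombus_nodes) {
  nl <- structured$n_layers; nn <- structured$n_nodes
  if (is.null(thrombus_nodes) || nrow(thrombus_nodes) == 0)
    return(matrix(0L, nl, nn))
  q <- matrix(aperm(structured$nodes, c(2, 1, 3)), nl * nn, 3)
  nnq <- nn_index(q, as.matrix(thrombus_nodes))
  local_r <- as.vector(t(vapply(seq_len(nl), function(j) {
    rel <- sweep(matrix(structured$nodes[j, , ], nn, 3), 2,
                 structured$layer_centers[j, ])
    sqrt(rowSums(rel^2))
  }, numeric(nn))))
  matrix(as.integer(nnq$dist < local_r), nl, nn, byrow = TRUE)
}

#' Regional thrombus indicator
#'
#' A region is thrombus-occupied (1) when the average of its node presence
#' values is strictly greater than 0.5.
#'
#' @param presence binary node matrix (n_layers x n_nodes).
#' @param partition a `region_partition`.
#' @return 0/1 vector over the descending regions.
#' @export
thrombus_region_indicator <- function(presence, partition) {
  avg <- region_average(presence, partition, n_nodes = ncol(presence))
  as.integer(!is.na(avg) & avg > 0.5)
}

#' Example patient records (admission inputs of a 9-patient cohort)
#'
#' Per-patient systolic/diastolic pressure (mmHg), systolic flow (L/min),
#' baseline and follow-up CTA dates, and thrombus status, as used by the
#' workflow scripts and the pressure-calibration checks.
#'
#' @return data frame of patient records.
#' @export
example_patients <- function() {
  path <- system.file("extdata", "patients.csv", package = "aortagrowth")
  if (path == "") path <- file.path("inst", "extdata", "patients.csv")
  out <- read.csv(path, stringsAsFactors = FALSE)
  out$baseline_date <- as.Date(out$baseline_date)
  out$followup_date <- as.Date(out$followup_date)
  out$thrombus_present <- as.logical(out$thrombus_present)
  validate_patient_records(out)
  out
}

validate_patient_records <- function(records) {
  stopifnot(all(records$sbp > records$dbp), all(records$dbp > 0),
            all(records$flow_lmin > 0),
            all(records$followup_date > records$baseline_date))
  invisible(records)
}

#' Follow-up duration and growth summaries
#'
#' Elapsed years are day differences / 365.25; medians and interquartile
#' ranges use the default linear-interpolation quantile convention
#' (`type = 7`), stated here because IQRs depend on it.
#'
#' @param records data frame with `baseline_date`, `followup_date`
#'   (Date or parseable), optionally `growth_mm_per_year`.
#' @param type quantile convention passed to [stats::quantile()].
#' @return list with `years` per patient, `median_years`, `iqr_years`, and
#'   (when growth is present) `median_growth`, `iqr_growth`.
#' @export
compute_followup_stats <- function(records, type = 7) {
  b <- as.Date(records$baseline_date); f <- as.Date(records$followup_date)
  if (any(f <= b)) stop("follow-up date not after baseline")
  years <- as.numeric(f - b) / 365.25
  out <- list(years = years, median_years = median(years),
              iqr_years = unname(quantile(years, c(0.25, 0.75), type = type)))
  if (!is.null(records$growth_mm_per_year)) {
    g <- records$growth_mm_per_year
    out$median_growth <- median(g)
    out$iqr_growth <- unname(quantile(g, c(0.25, 0.75), type = type))
  }
  out
}
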