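#' Configuration for the synthetic cohort simulator
#'
#' Builds a validated configuration for [simulate_cohort()]. The simulator
#' emulates the kind of longitudinal diagnosis stream found in an integrated
#' health system's data warehouse: per-patient event streams spanning years,
#' repeat encounters per acquired diagnosis, non-diagnostic V codes emitted as
#' noise, occasional same-day (coincident) first diagnoses, and a planted
#' directional hazard structure in which carrying diagnosis `i` multiplies the
#' per-timestep hazard of later acquiring diagnosis `j` by `kappa[i, j]`.
#'
#' Diagnostic codes are auto-labelled as consecutive three-digit ICD-9-style
#' strings starting at `code_start` (default "250", "251", ...), deliberately
#' outside the ranges removed by [network_exclusions()]. The hazard-multiplier
#' matrix defaults to a block structure: codes are split into
#' `n_blocks` contiguous community blocks, with multiplier `kappa_in` for
#' ordered pairs inside a block and `kappa_out` across blocks. Supplying
#' `multiplier_matrix` overrides the block construction (blocks are then only
#' used as ground-truth community labels).
#'
#' @param n_patients number of patients (positive integer).
#' @param n_codes number of diagnostic three-digit codes (positive integer).
#' @param timestep_days simulation timestep in days (default 30).
#' @param followup_years_range length-2 numeric, min and max follow-up years;
#'   each patient's window length is uniform on this range.
#' @param max_followup_years upper bound on follow-up; defaults to
#'   `followup_years_range[2]`.
#' @param baseline_hazard per-code probability of first acquisition per
#'   timestep, scalar or length `n_codes`, in `(0, 1)` (0 allowed: the code
#'   never fires spontaneously).
#' @param multiplier_matrix optional `n_codes x n_codes` nonnegative matrix of
#'   hazard multipliers `kappa[i, j]`; 1 means no effect; the diagonal is
#'   ignored.
#' @param n_blocks number of ground-truth community blocks (default 4).
#' @param kappa_in,kappa_out within-block and between-block hazard multipliers
#'   used when `multiplier_matrix` is `NULL`.
#' @param n_vcodes number of non-diagnostic V codes emitted as noise.
#' @param revisit_rate expected repeat encounters per acquired code per year;
#'   also the per-year intensity of V-code encounters.
#' @param coincident_prob probability that a new first occurrence is snapped
#'   onto an existing same-patient first-occurrence date.
#' @param code_start integer, first auto-generated diagnostic code label.
#' @param seed integer seed; identical configurations (including seed) give
#'   byte-identical event tables.
#'
#' @return A list of class `"sim_config"`.
#' @seealso [simulate_cohort()]
#' @export
sim_config <- function(n_patients = 2000L,
                       n_codes = 24L,
                       timestep_days = 30L,
                       followup_years_range = c(5, 16),
                       max_followup_years = NULL,
                       baseline_hazard = 0.003,
                       multiplier_matrix = NULL,
                       n_blocks = 4L,
                       kappa_in = 6,
                       kappa_out = 1,
                       n_vcodes = 3L,
                       revisit_rate = 1,
                       coincident_prob = 0.02,
                       code_start = 250L,
                       seed = 1L) {
  if (!is.numeric(n_patients) || length(n_patients) != 1L || n_patients < 1)
    stop("n_patients must be a positive integer")
  if (!is.numeric(n_codes) || length(n_codes) != 1L || n_codes < 1)
    stop("n_codes must be a positive integer")
  n_patients <- as.integer(n_patients)
  n_codes <- as.integer(n_codes)
  if (timestep_days < 1) stop("timestep_days must be a positive integer")
  if (length(followup_years_range) != 2L ||
      followup_years_range[1] < 0 ||
      followup_years_range[1] > followup_years_range[2])
    stop("followup_years_range must be (min, max) with 0 <= min <= max")
  if (is.null(max_followup_years)) max_followup_years <- followup_years_range[2]
  if (max_followup_years < followup_years_range[2])
    stop("max_followup_years below followup_years_range maximum")
  if (any(baseline_hazard < 0) || any(baseline_hazard >= 1))
    stop("baseline_hazard must lie in [0, 1)")
  if (!length(baseline_hazard) %in% c(1L, n_codes))
    stop("baseline_hazard must be scalar or length n_codes")
  if (coincident_prob < 0 || coincident_prob > 1)
    stop("coincident_prob must lie in [0, 1]")
  if (n_vcodes < 0) stop("n_vcodes must be nonnegative")
  if (revisit_rate < 0) stop("revisit_rate must be nonnegative")

  codes <- sprintf("%03d", code_start + seq_len(n_codes) - 1L)
  if (code_start + n_codes - 1L > 999L) stop("code_start + n_codes exceeds 999")

  n_blocks <- max(1L, min(as.integer(n_blocks), n_codes))
  block_labels <- sort(rep_len(seq_len(n_blocks), n_codes))

  if (is.null(multiplier_matrix)) {
    if (kappa_in < 0 || kappa_out < 0) stop("kappa multipliers must be >= 0")
    same <- outer(block_labels, block_labels, "==")
    multiplier_matrix <- ifelse(same, kappa_in, kappa_out)
    diag(multiplier_matrix) <- 1
  } else {
    multiplier_matrix <- as.matrix(multiplier_matrix)
    if (!all(dim(multiplier_matrix) == n_codes))
      stop("multiplier_matrix must be n_codes x n_codes")
    if (any(multiplier_matrix < 0)) stop("multiplier entries must be >= 0")
    diag(multiplier_matrix) <- 1  # kappa(i -> i) is ignored
  }
  dimnames(multiplier_matrix) <- list(codes, codes)

  structure(list(
    n_patients = n_patients, n_codes = n_codes, codes = codes,
    timestep_days = as.integer(timestep_days),
    followup_years_range = as.numeric(followup_years_range),
    max_followup_years = as.numeric(max_followup_years),
    baseline_hazard = rep_len(baseline_hazard, n_codes),
    multiplier_matrix = multiplier_matrix,
    community_labels = setNames(block_labels, codes),
    n_vcodes = as.integer(n_vcodes),
    revisit_rate = as.numeric(revisit_rate),
    coincident_prob = as.numeric(coincident_prob),
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Simulate a synthetic longitudinal diagnosis cohort
#'
#' Discrete-time per-patient simulation. At every timestep each not-yet
#' acquired diagnostic code `j` fires with probability
#' `min(1, baseline_hazard[j] * prod(kappa[i, j]))` over codes `i` already
#' acquired; the first firing creates that patient's first-occurrence event,
#' dated on a uniformly drawn day inside the timestep. Acquired codes emit
#' Poisson repeat encounters at `revisit_rate` per year until the end of
#' follow-up; V codes are emitted uniformly over the follow-up window; with
#' probability `coincident_prob` a new first occurrence is snapped onto an
#' existing same-patient first-occurrence date, creating same-day pairs.
#'
#' Per-patient random substreams are derived from the master seed so that
#' increasing `n_patients` leaves earlier patients' event streams unchanged.
#' Event codes carry a random sub-digit (e.g. `"253.4"`) so the three-digit
#' collapsing step is exercised downstream.
#'
#' @param config a [sim_config()] object.
#' @return A list with components:
#'   \describe{
#'     \item{events}{`data.frame` with columns `patient_id`, `birth_date`,
#'       `event_date` (both `Date`), `icd9_code`, sorted by patient, date,
#'       code.}
#'     \item{truth}{ground truth: `multiplier_matrix`, `community_labels`
#'       (named by code), and `realized_followup` in years (named by patient;
#'       last minus first event date over 365.25).}
#'   }
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_patients
  k <- config$n_codes
  codes <- config$codes
  kap <- config$multiplier_matrix
  h <- config$baseline_hazard
  step <- config$timestep_days
  vcodes <- if (config$n_vcodes > 0) sprintf("V%02d", seq_len(config$n_vcodes)) else character()

  old <- .save_rng_state()
  on.exit(.restore_rng_state(old), add = TRUE)

  set.seed(config$seed)
  # prefix-stable per-patient substreams: runif draws are sequential, so
  # growing n_patients never reshuffles earlier patients
  patient_seeds <- as.integer(floor(runif(n) * 2147483646)) + 1L
  origin <- as.Date("2000-01-01")

  out <- vector("list", n)
  for (p in seq_len(n)) {
    set.seed(patient_seeds[p])
    fy <- runif(1, config$followup_years_range[1], config$followup_years_range[2])
    window_days <- max(1L, as.integer(floor(fy * 365.25)))
    n_steps <- window_days %/% step
    start <- origin + sample.int(365L, 1L) - 1L
    age_at_start <- min(80, max(50, rnorm(1, 66, 5.5)))
    birth <- start - as.integer(round(age_at_start * 365.25))

    acquired <- logical(k)
    mult <- rep(1, k)          # running product of kappa from acquired codes
    first_day <- rep(NA_integer_, k)  # day offset within window
    for (t in seq_len(n_steps)) {
      un <- which(!acquired)
      if (!length(un)) break
      pfire <- pmin(1, h[un] * mult[un])
      u <- runif(length(un))
      fired <- un[u < pfire]
      for (j in fired) {
        day <- (t - 1L) * step + sample.int(step, 1L) - 1L
        prior <- first_day[!is.na(first_day)]
        if (length(prior) && runif(1) < config$coincident_prob)
          day <- prior[sample.int(length(prior), 1L)]
        first_day[j] <- day
        acquired[j] <- TRUE
        mult <- mult * kap[j, ]
      }
    }

    ev_code_idx <- which(!is.na(first_day))
    days <- first_day[ev_code_idx]
    code_lab <- codes[ev_code_idx]
    # repeat encounters for acquired codes
    for (ii in seq_along(ev_code_idx)) {
      remain <- (window_days - days[ii]) / 365.25
      nrep <- rpois(1, config$revisit_rate * max(0, remain))
      if (nrep > 0) {
        span <- max(1L, window_days - days[ii])
        rep_days <- days[ii] + sample.int(span, nrep, replace = TRUE)
        days <- c(days, rep_days)
        code_lab <- c(code_lab, rep(codes[ev_code_idx[ii]], nrep))
      }
    }
    # non-diagnostic V codes scattered uniformly over the window
    for (vc in vcodes) {
      nv <- rpois(1, config$revisit_rate * fy)
      if (nv > 0) {
        days <- c(days, sample.int(window_days, nv, replace = TRUE) - 1L)
        code_lab <- c(code_lab, rep(vc, nv))
      }
    }

    if (length(days)) {
      suffix <- sample(0:9, length(days), replace = TRUE)
      out[[p]] <- data.table(
        patient_id = sprintf("P%05d", p),
        birth_date = birth,
        event_date = start + days,
        icd9_code = paste0(code_lab, ".", suffix)
      )
    }
  }

  events <- if (any(!vapply(out, is.null, TRUE))) rbindlist(out) else
    data.table(patient_id = character(), birth_date = as.Date(character()),
               event_date = as.Date(character()), icd9_code = character())
  setorder(events, patient_id, event_date, icd9_code)

  realized <- rep(0, n)
  names(realized) <- sprintf("P%05d", seq_len(n))
  if (nrow(events)) {
    span <- events[, .(yrs = as.numeric(max(event_date) - min(event_date)) / 365.25),
                   by = patient_id]
    realized[span$patient_id] <- span$yrs
  }

  list(
    events = as.data.frame(events),
    truth = list(
      multiplier_matrix = config$multiplier_matrix,
      community_labels = config$community_labels,
      realized_followup = realized
    )
  )
}

#' Write simulator ground truth as structured text
#'
#' Serialises the planted multiplier matrix, community labels and realized
#' follow-up to a JSON file alongside a simulated event table.
#'
#' @param truth the `truth` component returned by [simulate_cohort()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(
    list(multiplier_matrix = truth$multiplier_matrix,
         codes = names(truth$community_labels),
         community_labels = as.list(truth$community_labels),
         realized_followup = as.list(round(truth$realized_followup, 6))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

.save_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
  invisible(NULL)
}
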