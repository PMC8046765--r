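#' Pipeline configuration
#'
#' Bundles every stage's settings for [run_pipeline()]. Exactly one of
#' `input` (a delimited event file, see [load_events()]) or `sim`
#' (a [sim_config()]) must be supplied; when simulating, the simulator's
#' seed is overridden by `seed` so one value reproduces the whole run.
#'
#' @param input path to an event CSV, or `NULL` to simulate.
#' @param sim a [sim_config()], or `NULL` to read `input`.
#' @param outdir output directory (created if needed).
#' @param min_followup_years follow-up filter threshold (default 5).
#' @param prevalence_threshold prevalence filter fraction (default 0.10).
#' @param rr_edge_threshold minimum RR for a network edge (default 1).
#' @param use_weights RR-weighted centralities and map equation (default).
#' @param damping PageRank damping (default 0.85).
#' @param infomap_runs restarts for [detect_communities()] (default 100).
#' @param tau map-equation teleportation probability (default 0.15).
#' @param focal_codes codes for ego views and the greedy trajectory; default
#'   is the top hub code.
#' @param labels_file optional tab-separated code-label map.
#' @param seed integer seed for every stochastic stage.
#' @param verbose log progress to stderr.
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(input = NULL, sim = NULL, outdir = tempfile("comorbidnet_"),
                            min_followup_years = 5,
                            prevalence_threshold = 0.10,
                            rr_edge_threshold = 1.0,
                            use_weights = TRUE,
                            damping = 0.85,
                            infomap_runs = 100L,
                            tau = 0.15,
                            focal_codes = NULL,
                            labels_file = NULL,
                            seed = 1L,
                            verbose = FALSE) {
  if (is.null(input) == is.null(sim))
    stop("supply exactly one of 'input' or 'sim'")
  if (!is.null(sim)) stopifnot(inherits(sim, "sim_config"))
  if (min_followup_years < 0) stop("min_followup_years must be >= 0")
  if (prevalence_threshold <= 0 || prevalence_threshold > 1)
    stop("prevalence_threshold must lie in (0, 1]")
  if (damping < 0 || damping >= 1) stop("damping must lie in [0, 1)")
  if (infomap_runs < 1) stop("infomap_runs must be at least 1")
  structure(list(
    input = input, sim = sim, outdir = outdir,
    min_followup_years = min_followup_years,
    prevalence_threshold = prevalence_threshold,
    rr_edge_threshold = rr_edge_threshold,
    use_weights = use_weights, damping = damping,
    infomap_runs = as.integer(infomap_runs), tau = tau,
    focal_codes = focal_codes, labels_file = labels_file,
    seed = as.integer(seed), verbose = isTRUE(verbose)
  ), class = "pipeline_config")
}

#' Read a diagnosis event table
#'
#' Comma-delimited UTF-8 with header; required columns `patient_id`,
#' `birth_date`, `event_date`, `icd9_code`; ISO 8601 (`YYYY-MM-DD`) dates;
#' `birth_date` may be empty. Rows with an unparseable `event_date` are
#' rejected with a warning and counted in the `n_rejected_dates` attribute.
#'
#' @param path file path.
#' @return data frame of events (dates as `Date`).
#' @export
load_events <- function(path) {
  if (!file.exists(path)) stop("event file not found: ", path)
  raw <- read.csv(path, colClasses = "character", check.names = TRUE)
  required <- c("patient_id", "birth_date", "event_date", "icd9_code")
  missing <- setdiff(required, names(raw))
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  ev_date <- as.Date(raw$event_date, format = "%Y-%m-%d")
  bad <- is.na(ev_date)
  if (any(bad))
    warning(sprintf("%d row(s) with unparseable event_date rejected", sum(bad)))
  bd <- as.Date(ifelse(raw$birth_date == "", NA, raw$birth_date),
                format = "%Y-%m-%d")
  out <- data.frame(patient_id = raw$patient_id[!bad],
                    birth_date = bd[!bad],
                    event_date = ev_date[!bad],
                    icd9_code = raw$icd9_code[!bad],
                    stringsAsFactors = FALSE)
  attr(out, "n_rejected_dates") <- sum(bad)
  out
}

#' Write a diagnosis event table
#'
#' Inverse of [load_events()]: comma-delimited with header, ISO dates,
#' empty string for missing birth dates.
#'
#' @param events event data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  out <- data.frame(
    patient_id = events$patient_id,
    birth_date = ifelse(is.na(events$birth_date),
                        "", format(events$birth_date, "%Y-%m-%d")),
    event_date = format(events$event_date, "%Y-%m-%d"),
    icd9_code = events$icd9_code)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the full comorbidity-network pipeline
#'
#' simulate/load -> collapse -> follow-up filter -> first occurrences ->
#' exclusions + prevalence filter -> RR matrix -> directed graph with
#' summary statistics and centralities -> map-equation communities ->
#' ego views and a greedy trajectory for the focal codes. All tables and
#' graph exports are written under `config$outdir` together with a
#' machine-readable run manifest.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) a result bundle: events, cohort summary, RR matrix,
#'   graph, statistics, centrality table, partition, ego views, manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  log <- function(...) if (config$verbose) message(sprintf(...))
  manifest <- list(package = "comorbidnet",
                   version = as.character(packageVersion("comorbidnet")),
                   r_version = paste(R.version$major, R.version$minor, sep = "."),
                   seed = config$seed,
                   config = .config_echo(config))

  # --- input -----------------------------------------------------------
  truth <- NULL
  n_rejected_dates <- 0L
  if (!is.null(config$sim)) {
    sim <- config$sim
    sim$seed <- config$seed
    log("simulating cohort: %d patients, %d codes", sim$n_patients, sim$n_codes)
    simres <- simulate_cohort(sim)
    events <- simres$events
    truth <- simres$truth
    write_events(events, file.path(config$outdir, "events.csv"))
    write_ground_truth(truth, file.path(config$outdir, "ground_truth.json"))
  } else {
    events <- load_events(config$input)
    n_rejected_dates <- attr(events, "n_rejected_dates")
  }
  n_raw <- nrow(events)

  # --- preprocess ------------------------------------------------------
  coll <- suppressWarnings(collapse_events(events))
  n_malformed <- coll$n_rejected + n_rejected_dates
  if (n_raw > 0 && n_malformed / (n_raw + n_rejected_dates) > 0.10)
    stop(sprintf("aborting: %d of %d rows malformed (> 10%%)",
                 n_malformed, n_raw + n_rejected_dates))
  events <- coll$events

  fu <- filter_followup(events, config$min_followup_years)
  cohort <- fu$patients
  log("follow-up filter: %d of %d patients retained",
      length(cohort), length(unique(events$patient_id)))

  labels <- if (!is.null(config$labels_file))
    read_code_labels(config$labels_file) else NULL

  prev <- prevalence_table(fu$events, cohort_size = length(cohort),
                           labels = labels)
  write.csv(prev, file.path(config$outdir, "prevalence.csv"), row.names = FALSE)
  summ <- cohort_summary(fu$events)

  fo <- first_occurrences(fu$events)
  observed <- sort(unique(fo$code3))
  diagnostic <- network_exclusions(observed)
  retained <- prevalence_filter(fo[fo$code3 %in% diagnostic, , drop = FALSE],
                                length(cohort), config$prevalence_threshold)
  log("codes: %d observed, %d after exclusions, %d after prevalence filter",
      length(observed), length(diagnostic), length(retained))

  counts <- list(n_events_raw = n_raw, n_events_malformed = n_malformed,
                 n_patients_raw = length(unique(events$patient_id)),
                 n_patients_cohort = length(cohort),
                 n_codes_observed = length(observed),
                 n_codes_diagnostic = length(diagnostic),
                 n_codes_network = length(retained))

  # --- relative risks --------------------------------------------------
  rrm <- rr_matrix(fo, retained, cohort)
  write.csv(rr_pairs(rrm), file.path(config$outdir, "rr_pairs.csv"),
            row.names = FALSE)

  # --- network ---------------------------------------------------------
  g <- build_graph(rrm, labels = labels, rr_threshold = config$rr_edge_threshold)
  stats <- graph_stats(g)
  cent <- NULL; part <- NULL; egos <- list(); trajectory <- NULL
  if (stats$n_edges > 0) {
    cent <- centrality_table(g, use_weights = config$use_weights,
                             damping = config$damping)
    write.csv(cent, file.path(config$outdir, "centrality.csv"),
              row.names = FALSE)
    part <- detect_communities(g, n_runs = config$infomap_runs,
                               seed = config$seed, tau = config$tau,
                               use_weights = config$use_weights)
    comm <- data.frame(code3 = names(part$membership),
                       community = unname(part$membership))
    write.csv(comm, file.path(config$outdir, "communities.csv"),
              row.names = FALSE)

    cent_by_code <- cent[match(igraph::V(g)$name, cent$code3), ]
    g <- igraph::set_vertex_attr(g, "hub", value = cent_by_code$hub)
    g <- igraph::set_vertex_attr(g, "authority", value = cent_by_code$authority)
    g <- igraph::set_vertex_attr(g, "pagerank", value = cent_by_code$pagerank)
    g <- igraph::set_vertex_attr(g, "community", value = as.integer(
      part$membership[igraph::V(g)$name]))
    igraph::write_graph(g, file.path(config$outdir, "graph.graphml"),
                        format = "graphml")
    igraph::write_graph(g, file.path(config$outdir, "graph.dot"),
                        format = "dot")
    write_gexf(g, file.path(config$outdir, "graph.gexf"))

    focal <- config$focal_codes
    if (is.null(focal)) focal <- cent$code3[1]  # top hub
    for (fc in intersect(focal, igraph::V(g)$name)) {
      egos[[fc]] <- list(successors = top_successors(g, fc),
                         predecessors = top_predecessors(g, fc))
      write.csv(egos[[fc]]$successors$table,
                file.path(config$outdir, sprintf("ego_%s_successors.csv", fc)),
                row.names = FALSE)
      write.csv(egos[[fc]]$predecessors$table,
                file.path(config$outdir, sprintf("ego_%s_predecessors.csv", fc)),
                row.names = FALSE)
    }
    if (length(intersect(focal, igraph::V(g)$name))) {
      trajectory <- greedy_max_rr_path(g, intersect(focal, igraph::V(g)$name)[1])
      write_dot_view(trajectory, file.path(config$outdir, "trajectory.dot"))
    }
  }

  manifest$counts <- counts
  manifest$graph_stats <- lapply(stats, function(x) if (is.na(x)) NULL else x)
  manifest$n_communities <- if (!is.null(part)) part$n_modules else NULL
  manifest$codelength_bits <- if (!is.null(part)) part$codelength else NULL
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  log("pipeline complete: outputs in %s", config$outdir)

  invisible(list(events = events, cohort = cohort, truth = truth,
                 summary = summ, prevalence = prev, first_occurrences = fo,
                 retained_codes = retained, rr = rrm, graph = g,
                 stats = stats, centrality = cent, partition = part,
                 egos = egos, trajectory = trajectory, manifest = manifest))
}

.config_echo <- function(config) {
  out <- config[!vapply(config, is.null, TRUE)]
  out$sim <- if (!is.null(config$sim))
    config$sim[c("n_patients", "n_codes", "timestep_days",
                 "followup_years_range", "baseline_hazard", "n_vcodes",
                 "revisit_rate", "coincident_prob")]
  class(out) <- NULL
  out
}
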