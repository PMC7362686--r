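#' Configuration for an end-to-end congruency run
#'
#' Bundles the input paths and analysis settings consumed by
#' [run_congruency()]. All paths are checked at construction; `outcomes`
#' is optional (the validity table is skipped without it).
#'
#' @param child,teacher,observed paths to the three adjacency CSVs
#'   (nominations, ratings, counts).
#' @param roster optional roster CSV (consent flags, availability); when
#'   absent the roster is taken from the adjacency labels.
#' @param outcomes optional outcome-score CSV (see [read_outcomes()]).
#' @param teacher_cutoffs integer rating cutoffs (default `c(1, 2, 3)`).
#' @param researcher_schemes list of [binarization specs][rating_scheme]
#'   or plain lists as accepted by [spec_from_list()].
#' @param n_permutations QAP permutations (default 10,000).
#' @param n_boot bootstrap resamples for the validity table (default
#'   1,000).
#' @param seed top-level seed recorded in every output.
#' @param out_dir report directory.
#' @return An object of class `"run_config"`.
#' @export
run_config <- function(child, teacher, observed, roster = NULL,
                       outcomes = NULL, teacher_cutoffs = c(1, 2, 3),
                       researcher_schemes = default_researcher_schemes(),
                       n_permutations = 10000, n_boot = 1000, seed = 1,
                       out_dir = "congruency_out") {
  paths <- c(child = child, teacher = teacher, observed = observed,
             roster = roster, outcomes = outcomes)
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop("input file(s) not found: ",
         paste(names(missing), missing, sep = " = ", collapse = "; "),
         call. = FALSE)
  }
  researcher_schemes <- lapply(researcher_schemes, function(s) {
    if (inherits(s, "binarization_spec")) s else spec_from_list(s)
  })
  structure(
    list(child = child, teacher = teacher, observed = observed,
         roster = roster, outcomes = outcomes,
         teacher_cutoffs = teacher_cutoffs,
         researcher_schemes = researcher_schemes,
         n_permutations = n_permutations, n_boot = n_boot,
         seed = as.integer(seed), out_dir = out_dir),
    class = "run_config"
  )
}

#' Run the full congruency analysis and write its report
#'
#' Reads the three informant networks (and optionally roster and outcome
#' scores), runs [congruency_grid()] and, when outcomes are supplied,
#' [validity_table()], and writes the report directory: the congruency
#' JSON and wide CSV tables, `densities.csv`, `validity_table.csv`, and a
#' `run_log.txt` recording the seed, package version and every threshold
#' actually applied (including the computed chance threshold and
#' frequency cutoffs). Reruns with an identical config are byte-identical.
#'
#' @param config a [run_config()].
#' @return the [congruency_grid()] report, invisibly, with the validity
#'   table attached as `$validity` when computed.
#' @export
run_congruency <- function(config) {
  stopifnot(inherits(config, "run_config"))
  noms <- read_adjacency(config$child, "nomination")
  ratings <- read_adjacency(config$teacher, "rating")
  counts <- read_adjacency(config$observed, "count")
  if (!is.null(config$roster)) {
    ros <- read_roster(config$roster)
    if (!identical(ros$child_ids, noms$roster$child_ids)) {
      stop("roster file order does not match adjacency labels: ",
           config$roster, call. = FALSE)
    }
    noms$roster <- ratings$roster <- counts$roster <- ros
  }
  ids <- noms$roster$child_ids
  if (!identical(ids, ratings$roster$child_ids) ||
      !identical(ids, counts$roster$child_ids)) {
    stop("the three networks are not on one shared roster", call. = FALSE)
  }
  child <- binary_network(noms$values, noms$roster, scheme = "native",
                          directed = TRUE)

  report <- congruency_grid(child, ratings, counts,
                            teacher_cutoffs = config$teacher_cutoffs,
                            researcher_schemes = config$researcher_schemes,
                            n_permutations = config$n_permutations,
                            seed = config$seed)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  write_congruency_report(report, config$out_dir)

  if (!is.null(config$outcomes)) {
    vt <- validity_table(child, ratings, counts,
                         read_outcomes(config$outcomes),
                         n_boot = config$n_boot, seed = config$seed)
    utils::write.csv(vt, file.path(config$out_dir, "validity_table.csv"),
                     row.names = FALSE)
    report$validity <- vt
  }

  n_eff <- effective_size(child)
  freq_rules <- Filter(function(s) s$family == "frequency",
                       config$researcher_schemes)
  log_lines <- c(
    paste0("netcongruency ", as.character(utils::packageVersion("netcongruency"))),
    paste0("seed: ", config$seed),
    paste0("n_permutations: ", config$n_permutations),
    paste0("effective_classroom_size: ", n_eff),
    paste0("ordered_dyads: ", n_dyads(child)),
    sprintf("chance_threshold: %.6f", chance_threshold(n_eff)),
    sprintf("twice_chance_threshold: %.6f", 2 * chance_threshold(n_eff)),
    paste0("teacher_cutoffs: ",
           paste(config$teacher_cutoffs, collapse = ", ")),
    vapply(freq_rules, function(s) {
      sprintf("frequency_cutoff[%s]: %g", scheme_label(s),
              frequency_cutoff(counts, s))
    }, character(1)),
    paste0("validity_table: ",
           if (is.null(config$outcomes)) "skipped (no outcomes supplied)"
           else paste0("written (n_boot = ", config$n_boot, ")"))
  )
  writeLines(log_lines, file.path(config$out_dir, "run_log.txt"))
  invisible(report)
}

#' Generate a synthetic classroom and write its input files
#'
#' Runs [generate_classroom()] and writes the classroom files (three
#' adjacency CSVs, roster, ground-truth affinity, calibration summary)
#' via [write_classroom()], so a synthetic run feeds [run_congruency()]
#' unchanged.
#'
#' @param config a [synthetic_config()], or the path to its YAML file.
#' @param out_dir output directory.
#' @return the [generate_classroom()] bundle, invisibly.
#' @export
run_simulate <- function(config = synthetic_config(), out_dir = "classroom") {
  if (is.character(config)) config <- read_synthetic_config(config)
  stopifnot(inherits(config, "synthetic_config"))
  data <- generate_classroom(config)
  write_classroom(data, out_dir)
  invisible(data)
}
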