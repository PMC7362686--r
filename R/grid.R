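#' Full informant-by-scheme congruency grid
#'
#' Runs the complete congruency analysis for one classroom:
#'
#' 1. pairwise QAP tests among the three untransformed informant networks
#'    (child nominations, teacher ratings, researcher counts);
#' 2. for every teacher rating cutoff and every researcher binarization
#'    scheme, QAP tests and Jaccard indices among the child network, the
#'    binarized teacher network and the binarized researcher network;
#' 3. densities of the child network and of every derived binary network.
#'
#' The child--teacher comparison depends only on the teacher cutoff and
#' the child--researcher comparison only on the researcher scheme; each is
#' computed once. All permutation draws derive from `seed`, so the report
#' is deterministic.
#'
#' @param child a [binary_network()] of peer nominations (directed).
#' @param teacher a [value_network()] of kind `"rating"`.
#' @param observed a [value_network()] of kind `"count"`.
#' @param teacher_cutoffs integer rating cutoffs to cross (default
#'   `c(1, 2, 3)`).
#' @param researcher_schemes list of [binarization specs][rating_scheme]
#'   for the count network (default [default_researcher_schemes()]).
#' @param n_permutations permutations per QAP test (default 10,000).
#' @param seed integer seed governing every permutation draw.
#' @return An object of class `"congruency_report"` with data-frame
#'   fields `qap_original`, `binary` (long grid with QAP r/p and Jaccard
#'   decomposition per informant pair), `densities`, plus
#'   `n_permutations` and `seed`.
#' @export
congruency_grid <- function(child, teacher, observed,
                            teacher_cutoffs = c(1, 2, 3),
                            researcher_schemes = default_researcher_schemes(),
                            n_permutations = 10000, seed = 1) {
  stopifnot(inherits(child, "binary_network"),
            inherits(teacher, "value_network"), teacher$kind == "rating",
            inherits(observed, "value_network"), observed$kind == "count")
  if (!length(teacher_cutoffs) || !length(researcher_schemes)) {
    stop("cutoff and scheme lists must be nonempty", call. = FALSE)
  }
  sub <- local({ k <- 0L; function() { k <<- k + 1L; derive_seed(seed, k) } })

  # a derived network can be degenerate (e.g. a saturated cutoff ties every
  # dyad); the comparison is then undefined and reported as NA rather than
  # aborting the rest of the grid
  qap_row <- function(pair, a, b, extra = list()) {
    seed_k <- sub()
    q <- tryCatch(qap_test(a, b, n_permutations, seed = seed_k),
                  error = function(e) {
                    message(pair, ": ", conditionMessage(e))
                    list(r_observed = NA_real_, p_greater = NA_real_,
                         p_two_sided = NA_real_)
                  })
    stats <- data.frame(r = q$r_observed, p_greater = q$p_greater,
                        p_two_sided = q$p_two_sided)
    if (length(extra)) {
      cbind(data.frame(pair = pair), as.data.frame(extra), stats)
    } else {
      cbind(data.frame(pair = pair), stats)
    }
  }

  qap_original <- rbind(
    qap_row("child_vs_teacher", child, teacher),
    qap_row("child_vs_researcher", child, observed),
    qap_row("teacher_vs_researcher", teacher, observed)
  )

  teacher_bin <- lapply(teacher_cutoffs, function(cc) binarize_rating(teacher, cc))
  names(teacher_bin) <- paste0("rating>=", teacher_cutoffs)
  researcher_bin <- suppressMessages(
    lapply(researcher_schemes, function(s) binarize(observed, s)))
  scheme_names <- vapply(researcher_schemes, scheme_label, character(1))
  names(researcher_bin) <- scheme_names

  jac_cols <- function(j) {
    data.frame(jaccard = j$jaccard, in_both = j$in_both,
               only_in_a = j$only_in_a, only_in_b = j$only_in_b)
  }
  rows <- list()
  for (i in seq_along(teacher_cutoffs)) {
    cc <- teacher_cutoffs[i]
    rows[[length(rows) + 1L]] <- cbind(
      qap_row("child_vs_teacher", child, teacher_bin[[i]],
              list(teacher_cutoff = cc, researcher_scheme = NA_character_)),
      jac_cols(jaccard(child, teacher_bin[[i]])))
  }
  for (j in seq_along(researcher_bin)) {
    rows[[length(rows) + 1L]] <- cbind(
      qap_row("child_vs_researcher", child, researcher_bin[[j]],
              list(teacher_cutoff = NA_real_,
                   researcher_scheme = scheme_names[j])),
      jac_cols(jaccard(child, researcher_bin[[j]])))
  }
  for (i in seq_along(teacher_cutoffs)) {
    for (j in seq_along(researcher_bin)) {
      rows[[length(rows) + 1L]] <- cbind(
        qap_row("teacher_vs_researcher", teacher_bin[[i]], researcher_bin[[j]],
                list(teacher_cutoff = teacher_cutoffs[i],
                     researcher_scheme = scheme_names[j])),
        jac_cols(jaccard(teacher_bin[[i]], researcher_bin[[j]])))
    }
  }
  binary <- do.call(rbind, rows)
  rownames(binary) <- NULL

  densities <- rbind(
    data.frame(network = "child_nominations",
               density = network_density(child)),
    data.frame(network = names(teacher_bin),
               density = vapply(teacher_bin, network_density, numeric(1))),
    data.frame(network = scheme_names,
               density = vapply(researcher_bin, network_density, numeric(1)))
  )
  rownames(densities) <- NULL

  structure(
    list(qap_original = qap_original, binary = binary, densities = densities,
         teacher_cutoffs = teacher_cutoffs, researcher_schemes = scheme_names,
         n_permutations = n_permutations, seed = seed),
    class = "congruency_report"
  )
}

#' @export
print.congruency_report <- function(x, ...) {
  cat("Congruency report (", x$n_permutations, "permutations, seed",
      x$seed, ")\n\nOriginal networks (QAP):\n")
  print(x$qap_original, row.names = FALSE)
  cat("\nDensities:\n")
  print(x$densities, row.names = FALSE)
  cat("\nBinary grid:", nrow(x$binary), "comparisons across",
      length(x$teacher_cutoffs), "teacher cutoffs x",
      length(x$researcher_schemes), "researcher schemes\n")
  invisible(x)
}

# wide informant-pair table: rows = researcher schemes + child nominations,
# columns = teacher cutoffs + child nominations
report_wide_table <- function(report, statistic = c("r", "jaccard")) {
  statistic <- match.arg(statistic)
  b <- report$binary
  cutoffs <- paste0("rating>=", report$teacher_cutoffs)
  schemes <- report$researcher_schemes
  out <- matrix(NA_real_, nrow = length(schemes) + 1L,
                ncol = length(cutoffs) + 1L,
                dimnames = list(c(schemes, "child_nominations"),
                                c(cutoffs, "child_nominations")))
  tr <- b[b$pair == "teacher_vs_researcher", ]
  for (k in seq_len(nrow(tr))) {
    out[tr$researcher_scheme[k], paste0("rating>=", tr$teacher_cutoff[k])] <-
      tr[[statistic]][k]
  }
  cr <- b[b$pair == "child_vs_researcher", ]
  out[cr$researcher_scheme, "child_nominations"] <- cr[[statistic]]
  ct <- b[b$pair == "child_vs_teacher", ]
  out["child_nominations", paste0("rating>=", ct$teacher_cutoff)] <-
    ct[[statistic]]
  out
}

#' Write a congruency report to disk
#'
#' Writes `congruency_report.json` (the full report), two wide CSV tables
#' (`qap_table.csv`, `jaccard_table.csv`; rows = researcher schemes plus
#' the child network, columns = teacher cutoffs plus the child network)
#' and `densities.csv`.
#'
#' @param report a [congruency_grid()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_congruency_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(qap_original = report$qap_original, binary = report$binary,
         densities = report$densities,
         n_permutations = report$n_permutations, seed = report$seed),
    file.path(dir, "congruency_report.json"),
    auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
  utils::write.csv(report_wide_table(report, "r"),
                   file.path(dir, "qap_table.csv"))
  utils::write.csv(report_wide_table(report, "jaccard"),
                   file.path(dir, "jaccard_table.csv"))
  utils::write.csv(report$densities, file.path(dir, "densities.csv"),
                   row.names = FALSE)
  invisible(dir)
}
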