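#' Default age-group brackets
#'
#' Four half-open brackets tiling 7-18 years: G1 \[7,11), G2 \[11,13),
#' G3 \[13,15), G4 \[15,18). "7 to 10 years" is read as through age 10,
#' i.e. below the 11th birthday, so the brackets tile without gaps.
#' Subjects younger than 7 (cohorts of this kind start around 6y4m) fall
#' outside all brackets and are excluded with a logged count, not errored.
#'
#' @return Data frame with columns `name`, `lower`, `upper`.
#' @export
default_age_groups <- function() {
  data.frame(
    name = c("G1", "G2", "G3", "G4"),
    lower = c(7, 11, 13, 15),
    upper = c(11, 13, 15, 18),
    stringsAsFactors = FALSE
  )
}

validate_age_groups <- function(spec) {
  stopifnot(is.data.frame(spec), all(c("name", "lower", "upper") %in% names(spec)))
  if (any(spec$lower >= spec$upper)) stop("age brackets must have lower < upper")
  o <- order(spec$lower)
  spec <- spec[o, , drop = FALSE]
  if (nrow(spec) > 1 && any(spec$upper[-nrow(spec)] > spec$lower[-1])) {
    stop("age brackets overlap")
  }
  spec
}

#' Assign ages to age groups
#'
#' Half-open bracket membership: `lower <= age < upper`. Ages outside all
#' brackets get `NA` (the row is excluded downstream, with a warning).
#'
#' @param age Numeric vector of ages in decimal years (> 0).
#' @param spec Bracket data frame, default [default_age_groups()].
#' @return Character vector of group labels (`NA` = unassigned).
#' @export
assign_age_group <- function(age, spec = default_age_groups()) {
  spec <- validate_age_groups(spec)
  if (any(!is.finite(age)) || any(age <= 0)) stop("ages must be finite and positive")
  out <- rep(NA_character_, length(age))
  for (i in seq_len(nrow(spec))) {
    hit <- age >= spec$lower[i] & age < spec$upper[i]
    out[hit] <- spec$name[i]
  }
  out
}

#' Split a cohort by Wits-appraisal severity
#'
#' Mild: Wits strictly greater than the threshold; severe: Wits smaller
#' than or equal to it. The default threshold of -3 mm is the conventional
#' cut between mild and severe Class III anteroposterior dysplasia.
#'
#' @param table A feature table with a `Wits` column.
#' @param threshold_mm Severity threshold in mm (default -3).
#' @return List with elements `mild` and `severe` (row order preserved).
#' @export
stratify_by_wits <- function(table, threshold_mm = -3.0) {
  if (!"Wits" %in% names(table)) stop("table lacks a Wits column")
  severe <- table$Wits <= threshold_mm
  if (anyNA(severe)) stop("missing Wits values")
  list(mild = table[!severe, , drop = FALSE],
       severe = table[severe, , drop = FALSE])
}

analyse_stratum <- function(tab, cutoff, top_k, min_clique, min_module, labels) {
  corr <- correlation_matrix(tab)
  graph <- threshold_graph(corr, cutoff = cutoff)
  topo <- topology_summary(graph, top_k = top_k)
  cliques <- maximal_cliques(graph, min_size = min_clique)
  pg <- power_decompose(graph, min_module = min_module)
  modules <- module_report(pg, labels = labels)
  list(corr = corr, graph = graph, topology = topo, cliques = cliques,
       power_graph = pg, modules = modules)
}

stratum_report_entry <- function(name, tab, res) {
  list(
    stratum = name,
    n = nrow(tab),
    n_edges = res$topology$n_edges,
    topology = topology_as_list(res$topology),
    cliques = lapply(res$cliques, as.list),
    modules = module_report_as_list(res$modules)
  )
}

#' Run the full stratified network analysis
#'
#' Stratifies a cohort by age group, optionally splits one group (default
#' the oldest, G4) into mild/severe Wits classes, and for every stratum runs
#' correlation matrix -> signed thresholded graph -> topology (degrees,
#' hubs, bridges, components) -> maximal cliques -> power-graph modules.
#' Strata with fewer than 3 subjects are skipped with an explicit report
#' entry (correlation undefined). The pipeline contains no randomness:
#' identical input and configuration give byte-identical reports.
#'
#' @param table A feature table.
#' @param cutoff Correlation threshold (default 0.40).
#' @param age_spec Bracket data frame, default [default_age_groups()].
#' @param wits_threshold_mm Severity cut in mm (default -3).
#' @param severity_group Age group to split by severity (default `"G4"`);
#'   `"all"` splits every group, `NULL`/`"none"` disables the split.
#' @param top_k Hub list size (default 3).
#' @param min_clique Minimum reported clique size (default 3).
#' @param min_module Minimum power-node size (default 2).
#' @param labels Optional named character vector feature -> category for
#'   module reports.
#' @param out_dir Optional output directory; when given, writes per stratum
#'   `corr_<stratum>.tsv`, `graph_<stratum>.graphml`,
#'   `topology_<stratum>.json`, `modules_<stratum>.json` and a consolidated
#'   `report.json`.
#' @return The consolidated report (a list), invisibly tagged with class
#'   `cohort_report`.
#' @export
run_pipeline <- function(table, cutoff = 0.40,
                         age_spec = default_age_groups(),
                         wits_threshold_mm = -3.0,
                         severity_group = "G4",
                         top_k = 3, min_clique = 3, min_module = 2,
                         labels = NULL, out_dir = NULL) {
  validate_feature_table(table)
  age_spec <- validate_age_groups(age_spec)
  group <- assign_age_group(table$age, age_spec)
  excluded <- sum(is.na(group))
  if (excluded > 0) {
    warning(excluded, " row(s) with ages outside all brackets excluded")
  }

  strata <- list()
  for (g in age_spec$name) {
    strata[[g]] <- table[!is.na(group) & group == g, , drop = FALSE]
  }
  sev_groups <- if (is.null(severity_group) ||
                    identical(severity_group, "none")) {
    character(0)
  } else if (identical(severity_group, "all")) {
    age_spec$name
  } else {
    stopifnot(severity_group %in% age_spec$name)
    severity_group
  }
  for (g in sev_groups) {
    parts <- stratify_by_wits(strata[[g]], wits_threshold_mm)
    strata[[paste0(g, "_mild")]] <- parts$mild
    strata[[paste0(g, "_severe")]] <- parts$severe
  }

  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  entries <- list()
  for (name in names(strata)) {
    tab <- strata[[name]]
    if (nrow(tab) < 3) {
      entries[[name]] <- list(stratum = name, n = nrow(tab),
                              skipped = "fewer than 3 subjects; correlation undefined")
      next
    }
    res <- tryCatch(
      analyse_stratum(tab, cutoff, top_k, min_clique, min_module, labels),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      entries[[name]] <- list(stratum = name, n = nrow(tab),
                              skipped = conditionMessage(res))
      next
    }
    entries[[name]] <- stratum_report_entry(name, tab, res)
    if (!is.null(out_dir)) {
      write_correlation_tsv(res$corr, file.path(out_dir, paste0("corr_", name, ".tsv")))
      write_graphml(res$graph, file.path(out_dir, paste0("graph_", name, ".graphml")))
      write_report_json(topology_as_list(res$topology),
                        file.path(out_dir, paste0("topology_", name, ".json")))
      write_report_json(module_report_as_list(res$modules),
                        file.path(out_dir, paste0("modules_", name, ".json")))
    }
  }

  age_sizes <- vapply(age_spec$name, function(g) nrow(strata[[g]]), 0L)
  stopifnot(sum(age_sizes) + excluded == nrow(table))

  report <- list(
    package = "cephnet",
    version = as.character(utils::packageVersion("cephnet")),
    config = list(
      cutoff = cutoff,
      wits_threshold_mm = wits_threshold_mm,
      severity_group = if (length(sev_groups)) sev_groups else "none",
      top_k = top_k, min_clique = min_clique, min_module = min_module,
      age_groups = lapply(seq_len(nrow(age_spec)), function(i) as.list(age_spec[i, ]))
    ),
    n_input = nrow(table),
    n_excluded_age = excluded,
    stratum_sizes = as.list(age_sizes),
    strata = entries
  )
  class(report) <- "cohort_report"
  if (!is.null(out_dir)) {
    write_report_json(unclass(report), file.path(out_dir, "report.json"))
  }
  invisible(report)
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("cohort report:", x$n_input, "subjects,", x$n_excluded_age,
      "excluded by age\n")
  for (e in x$strata) {
    if (!is.null(e$skipped)) {
      cat(sprintf("  %-10s n=%-4d skipped: %s\n", e$stratum, e$n, e$skipped))
    } else {
      cat(sprintf("  %-10s n=%-4d edges=%-3d hubs=%s bridges=%s modules=%d\n",
                  e$stratum, e$n, e$n_edges,
                  paste(vapply(e$topology$hubs, `[[`, "", "node"), collapse = ","),
                  if (length(e$topology$bridges))
                    paste(unlist(e$topology$bridges), collapse = ",") else "-",
                  length(e$modules$modules)))
    }
  }
  invisible(x)
}

# Deterministic JSON writer shared by all report artifacts.
write_report_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
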