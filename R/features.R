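#' Canonical cephalometric feature names
#'
#' The 21 variables of a standard lateral-cephalogram analysis, in their
#' canonical order: angles in degrees, linear distances in millimetres.
#' These names are the node set of every network the package builds and the
#' required feature columns of a cohort table.
#'
#' @return Character vector of length 21.
#' @export
#' @examples
#' ceph_features()
ceph_features <- function() {
  c(
    "SN", "Wits", "Co-A", "Co-Gn", "Ar-Go", "NS-GoGn", "NS-Ar",
    "ArGoMe", "SNA", "SNB", "IMPA", "ANB", "Interincisal", "PP-SN",
    "PP-PM", "NMe", "FMIA", "Overbite", "Overjet", "Go-Pg", "Co-Go"
  )
}

#' Short descriptions of the canonical features
#'
#' @return Named character vector keyed by feature name.
#' @export
ceph_feature_info <- function() {
  c(
    "SN"           = "anteroposterior length of the cranial base (mm)",
    "Wits"         = "Wits appraisal of anteroposterior jaw disharmony (mm)",
    "Co-A"         = "midfacial length, condylion to point A (mm)",
    "Co-Gn"        = "mandibular length, condylion to gnathion (mm)",
    "Ar-Go"        = "mandibular ramus height (mm)",
    "NS-GoGn"      = "divergence of the mandibular plane to the anterior cranial base (deg)",
    "NS-Ar"        = "saddle angle (deg)",
    "ArGoMe"       = "gonial angle (deg)",
    "SNA"          = "anteroposterior maxillary position to the anterior cranial base (deg)",
    "SNB"          = "anteroposterior mandibular position to the anterior cranial base (deg)",
    "IMPA"         = "lower incisor to mandibular plane angle (deg)",
    "ANB"          = "anteroposterior relation of maxilla and mandible (deg)",
    "Interincisal" = "angle between upper and lower incisor axes (deg)",
    "PP-SN"        = "palatal plane inclination to the anterior cranial base (deg)",
    "PP-PM"        = "palatal plane inclination to the mandibular plane (deg)",
    "NMe"          = "anterior facial height (mm)",
    "FMIA"         = "lower incisor to Frankfort plane angle (deg)",
    "Overbite"     = "vertical incisal overlap (mm)",
    "Overjet"      = "horizontal incisal distance (mm)",
    "Go-Pg"        = "mandibular body length, gonion to pogonion (mm)",
    "Co-Go"        = "posterior ramus length, condylion to gonion (mm)"
  )
}

#' Validate a cohort feature table
#'
#' Checks that `table` is a data frame carrying `subject_id`, `age` and all
#' 21 canonical feature columns exactly once, that ages are positive, and
#' (in strict mode) that feature columns contain no missing values.
#'
#' @param table A data frame (one row per subject).
#' @param strict Logical; if `TRUE` (default) any `NA` in a feature column is
#'   an error. Pairwise-complete correlation handling is opt-in downstream.
#' @return `table`, invisibly, on success.
#' @export
validate_feature_table <- function(table, strict = TRUE) {
  if (!is.data.frame(table)) stop("feature table must be a data frame")
  feats <- ceph_features()
  for (col in c("subject_id", "age")) {
    if (!col %in% names(table)) stop("feature table lacks column '", col, "'")
  }
  missing <- setdiff(feats, names(table))
  if (length(missing) > 0) {
    stop("feature table lacks feature column(s): ", paste(missing, collapse = ", "))
  }
  dup <- feats[vapply(feats, function(f) sum(names(table) == f), 0L) > 1L]
  if (length(dup) > 0) {
    stop("duplicated feature column(s): ", paste(dup, collapse = ", "))
  }
  if (any(!is.finite(table$age)) || any(table$age <= 0)) {
    stop("ages must be finite and positive")
  }
  for (f in feats) {
    v <- table[[f]]
    if (!is.numeric(v)) stop("feature column '", f, "' is not numeric")
    if (strict && anyNA(v)) stop("missing values in feature column '", f, "' (strict mode)")
  }
  invisible(table)
}

#' Read a cohort table from CSV
#'
#' @param path CSV file with header `subject_id,age[,group]` plus the 21
#'   canonical feature columns (see [ceph_features()]).
#' @param strict Passed to [validate_feature_table()].
#' @return A validated data frame.
#' @export
read_feature_table <- function(path, strict = TRUE) {
  tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  validate_feature_table(tab, strict = strict)
  tab
}

#' Write a cohort table to CSV
#'
#' @param table A feature table.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
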