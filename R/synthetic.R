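#' Specify a correlated feature block
#'
#' A block plants a common pairwise correlation among a set of features,
#' emulating the tightly coupled groups seen in craniofacial data (e.g.
#' structural skeletal features moving together).
#'
#' @param name Label for the block.
#' @param members Character vector of canonical feature names (length >= 1,
#'   no duplicates).
#' @param within_r Target pairwise Pearson correlation among members,
#'   in \[-1, 1\].
#' @return An object of class `block_spec`.
#' @export
block_spec <- function(name, members, within_r) {
  stopifnot(is.character(name), length(name) == 1)
  if (length(members) == 0) stop("block '", name, "' has no members")
  bad <- setdiff(members, ceph_features())
  if (length(bad) > 0) {
    stop("block '", name, "' has unknown feature(s): ", paste(bad, collapse = ", "))
  }
  if (anyDuplicated(members)) stop("block '", name, "' has duplicated members")
  if (!is.numeric(within_r) || length(within_r) != 1 || abs(within_r) > 1) {
    stop("within_r must be a scalar in [-1, 1]")
  }
  structure(list(name = name, members = members, within_r = within_r),
            class = "block_spec")
}

#' Specify a single planted cross-correlation
#'
#' Cross-links plant correlations between individual feature pairs outside
#' any block — typically the negative couplings between skeletal features and
#' compensatory dentoalveolar ones.
#'
#' @param feature_a,feature_b Distinct canonical feature names.
#' @param r Target correlation in \[-1, 1\].
#' @return An object of class `cross_link`.
#' @export
cross_link <- function(feature_a, feature_b, r) {
  bad <- setdiff(c(feature_a, feature_b), ceph_features())
  if (length(bad) > 0) stop("unknown feature(s): ", paste(bad, collapse = ", "))
  if (feature_a == feature_b) stop("cross_link endpoints must differ")
  if (!is.numeric(r) || length(r) != 1 || abs(r) > 1) stop("r must be in [-1, 1]")
  structure(list(feature_a = feature_a, feature_b = feature_b, r = r),
            class = "cross_link")
}

#' Configuration of a synthetic cohort
#'
#' Describes a cohort of untreated Class III female patients as a stated
#' world: per-age-group sample counts, planted correlation structure, and
#' marginal means/SDs for each measurement. The defaults reproduce the study
#' design this package targets: strata G1-G4 of 240/89/105/98 subjects
#' (total 532) and a Wits-appraisal distribution spanning the -3 mm
#' severity cut.
#'
#' @param n_per_group Named positive integer counts for groups G1..G4.
#' @param blocks List of [block_spec()] objects; member sets must be disjoint.
#' @param cross_links List of [cross_link()] objects.
#' @param background_r Correlation planted between all remaining pairs
#'   (default 0).
#' @param feature_means,feature_sds Named numeric vectors over the 21
#'   features; unspecified entries fall back to package defaults chosen as
#'   clinically plausible Class III values.
#' @param wits_mean,wits_sd Marginal mean/SD (mm) of the Wits appraisal;
#'   these override any `feature_means`/`feature_sds` entry for `Wits`.
#' @param seed Integer RNG seed; identical configs give bit-identical cohorts.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_per_group = c(G1 = 240, G2 = 89, G3 = 105, G4 = 98),
                             blocks = list(),
                             cross_links = list(),
                             background_r = 0,
                             feature_means = NULL,
                             feature_sds = NULL,
                             wits_mean = -3.5,
                             wits_sd = 2.5,
                             seed = 1L) {
  groups <- c("G1", "G2", "G3", "G4")
  if (!all(groups %in% names(n_per_group))) {
    stop("n_per_group must name all of G1, G2, G3, G4")
  }
  n_per_group <- n_per_group[groups]
  if (any(!is.finite(n_per_group)) || any(n_per_group <= 0) ||
      any(n_per_group != round(n_per_group))) {
    stop("all group counts must be positive integers")
  }
  means <- default_feature_means()
  sds <- default_feature_sds()
  if (!is.null(feature_means)) means[names(feature_means)] <- feature_means
  if (!is.null(feature_sds)) sds[names(feature_sds)] <- feature_sds
  means["Wits"] <- wits_mean
  sds["Wits"] <- wits_sd
  if (any(!is.finite(sds)) || any(sds <= 0)) stop("all feature sds must be positive")
  for (b in blocks) if (!inherits(b, "block_spec")) stop("blocks must be block_spec objects")
  for (cl in cross_links) if (!inherits(cl, "cross_link")) stop("cross_links must be cross_link objects")
  if (abs(background_r) > 1) stop("background_r must be in [-1, 1]")
  structure(list(
    n_per_group = n_per_group, blocks = blocks, cross_links = cross_links,
    background_r = background_r, feature_means = means, feature_sds = sds,
    wits_mean = wits_mean, wits_sd = wits_sd, seed = as.integer(seed)
  ), class = "synthetic_config")
}

# Plausible marginals for an untreated Class III female cohort; angles in
# degrees, distances in mm. Only the correlation structure matters to the
# downstream analysis — these set realistic scales.
default_feature_means <- function() {
  c("SN" = 68, "Wits" = -3.5, "Co-A" = 85, "Co-Gn" = 115, "Ar-Go" = 44,
    "NS-GoGn" = 34, "NS-Ar" = 124, "ArGoMe" = 128, "SNA" = 80, "SNB" = 80.5,
    "IMPA" = 85, "ANB" = -0.5, "Interincisal" = 131, "PP-SN" = 8,
    "PP-PM" = 26, "NMe" = 112, "FMIA" = 62, "Overbite" = 1, "Overjet" = 0,
    "Go-Pg" = 75, "Co-Go" = 55)
}

default_feature_sds <- function() {
  c("SN" = 3, "Wits" = 2.5, "Co-A" = 4, "Co-Gn" = 6, "Ar-Go" = 4,
    "NS-GoGn" = 5, "NS-Ar" = 5, "ArGoMe" = 6, "SNA" = 3.5, "SNB" = 3.5,
    "IMPA" = 6, "ANB" = 2, "Interincisal" = 8, "PP-SN" = 3, "PP-PM" = 5,
    "NMe" = 7, "FMIA" = 7, "Overbite" = 2, "Overjet" = 2, "Go-Pg" = 5,
    "Co-Go" = 5)
}

#' Default synthetic configuration with three planted modules
#'
#' Ships three qualitative feature groups with strong internal coupling
#' (within_r = 0.7) and two negative structural-to-adaptive cross-links
#' (r = -0.5): a mandibular-sagittal block, a maxillomandibular-divergence
#' block, and an adaptive-dentoalveolar block. The values are synthetic,
#' chosen for testability, not estimates from clinical data.
#'
#' @param seed RNG seed.
#' @inheritParams synthetic_config
#' @return A `synthetic_config`.
#' @export
default_synthetic_config <- function(seed = 1L,
                                     n_per_group = c(G1 = 240, G2 = 89, G3 = 105, G4 = 98)) {
  synthetic_config(
    n_per_group = n_per_group,
    blocks = list(
      block_spec("mandibular-sagittal", c("SNB", "Co-Gn", "Go-Pg"), 0.7),
      block_spec("maxillomandibular-divergence", c("NS-GoGn", "PP-PM", "NMe"), 0.7),
      block_spec("adaptive-dentoalveolar", c("IMPA", "FMIA", "Interincisal", "Overjet"), 0.7)
    ),
    cross_links = list(
      cross_link("NMe", "IMPA", -0.5),
      cross_link("SNB", "FMIA", -0.5)
    ),
    background_r = 0,
    seed = seed
  )
}

#' Assemble the planted target correlation matrix
#'
#' Builds the 21 x 21 symmetric target: `within_r` for same-block pairs, the
#' `cross_link` value for linked pairs, `background_r` elsewhere, unit
#' diagonal. Overlapping blocks, or a cross-link hitting a pair already fixed
#' by a block, are configuration errors.
#'
#' @param config A [synthetic_config()].
#' @return Numeric 21 x 21 matrix with feature dimnames.
#' @export
build_target_correlation <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  feats <- ceph_features()
  p <- length(feats)
  all_members <- unlist(lapply(config$blocks, `[[`, "members"))
  dup <- unique(all_members[duplicated(all_members)])
  if (length(dup) > 0) {
    stop("blocks overlap on feature(s): ", paste(dup, collapse = ", "))
  }
  m <- matrix(config$background_r, p, p, dimnames = list(feats, feats))
  in_block <- matrix(FALSE, p, p, dimnames = list(feats, feats))
  for (b in config$blocks) {
    idx <- match(b$members, feats)
    m[idx, idx] <- b$within_r
    in_block[idx, idx] <- TRUE
  }
  for (cl in config$cross_links) {
    i <- match(cl$feature_a, feats)
    j <- match(cl$feature_b, feats)
    if (in_block[i, j]) {
      stop("cross_link (", cl$feature_a, ", ", cl$feature_b,
           ") conflicts with a block assignment for the same pair")
    }
    m[i, j] <- cl$r
    m[j, i] <- cl$r
  }
  diag(m) <- 1
  m
}

#' Project a correlation matrix to the nearest positive semidefinite one
#'
#' Eigenvalue clipping at zero followed by symmetric rescaling to unit
#' diagonal, iterated until the smallest eigenvalue is above `-epsilon`.
#' A matrix that is already PSD with unit diagonal is returned unchanged, so
#' the operation is idempotent up to tolerance.
#'
#' @param m Symmetric square matrix.
#' @param epsilon Nonnegative tolerance on the smallest eigenvalue
#'   (default 1e-8).
#' @return A symmetric PSD matrix with unit diagonal.
#' @export
nearest_psd <- function(m, epsilon = 1e-8) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) stop("input must be a square matrix")
  if (max(abs(m - t(m))) > 1e-8) stop("input matrix is not symmetric")
  if (epsilon < 0) stop("epsilon must be nonnegative")
  m <- (m + t(m)) / 2
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) >= -epsilon && max(abs(diag(m) - 1)) < 1e-12) {
    return(m)
  }
  for (iter in seq_len(100)) {
    e <- eigen(m, symmetric = TRUE)
    vals <- pmax(e$values, 0)
    m <- e$vectors %*% (vals * t(e$vectors))
    d <- sqrt(pmax(diag(m), .Machine$double.eps))
    m <- m / tcrossprod(d)
    m <- (m + t(m)) / 2
    diag(m) <- 1
    ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) >= -epsilon) break
  }
  if (min(ev) < -epsilon) stop("PSD repair did not converge")
  m
}

#' Simulate a synthetic cohort with planted correlation structure
#'
#' Draws each group's subjects from a multivariate normal whose correlation
#' is the PSD-repaired planted target, scaled by the configured feature SDs
#' and shifted by the means. Ages are uniform inside each group's bracket
#' (G1 \[7,11), G2 \[11,13), G3 \[13,15), G4 \[15,18)). Generation is fully
#' reproducible from `config$seed`.
#'
#' @param config A [synthetic_config()].
#' @return A validated feature table with columns
#'   `subject_id, age, group` + the 21 features.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  feats <- ceph_features()
  target <- build_target_correlation(config)
  sigma <- nearest_psd(target)
  e <- eigen(sigma, symmetric = TRUE)
  if (min(e$values) < -1e-6) stop("PSD repair failure: min eigenvalue ", min(e$values))
  root <- e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))

  brackets <- default_age_groups()
  n_tot <- sum(config$n_per_group)
  p <- length(feats)

  old_seed <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed)

  ages <- numeric(0)
  groups <- character(0)
  for (g in brackets$name) {
    n_g <- config$n_per_group[[g]]
    lo <- brackets$lower[brackets$name == g]
    hi <- brackets$upper[brackets$name == g]
    ages <- c(ages, stats::runif(n_g, lo, hi))
    groups <- c(groups, rep(g, n_g))
  }
  z <- matrix(stats::rnorm(n_tot * p), n_tot, p)
  x <- z %*% root
  x <- sweep(x, 2, config$feature_sds[feats], `*`)
  x <- sweep(x, 2, config$feature_means[feats], `+`)
  colnames(x) <- feats

  tab <- data.frame(
    subject_id = sprintf("S%04d", seq_len(n_tot)),
    age = ages,
    group = groups,
    stringsAsFactors = FALSE,
    check.names = FALSE
  )
  tab <- cbind(tab, as.data.frame(x, check.names = FALSE))
  validate_feature_table(tab)
  tab
}
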