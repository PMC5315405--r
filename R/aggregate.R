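# Cross-receptor aggregation of bridging profiles through generic residue
# numbers, error bars from active-inactive structure pairs, and profile
# comparison.

#' Align per-receptor profiles on shared generic numbers
#'
#' Maps every profile's residues to generic position labels and assembles a
#' position-by-receptor score table restricted to positions present in every
#' profile (and, when given, in the whitelist). Positions that fail to map
#' are dropped; a generic number claimed by two residues of one receptor is
#' an error.
#'
#' @param profiles list of `bridging_profile` objects.
#' @param numbering numbering map from [load_numbering_map()], or `NULL` when
#'   the profiles' residue tables already carry `generic_number`.
#' @param whitelist optional character vector of generic numbers to keep
#'   (e.g. [default_whitelist()]); its order fixes the row order.
#' @return numeric matrix, rows = generic numbers, columns = receptor ids.
#' @export
align_profiles <- function(profiles, numbering = NULL, whitelist = NULL) {
  stopifnot(length(profiles) >= 1)
  per <- lapply(profiles, function(p) {
    gen <- if (is.null(numbering)) p$residues$generic_number
           else generic_numbers(numbering, p$receptor_id, p$residues)
    keep <- !is.na(gen) & gen != ""
    gen <- gen[keep]
    if (anyDuplicated(gen)) {
      stop(sprintf("receptor %s: generic number %s maps to multiple residues",
                   p$receptor_id, gen[duplicated(gen)][1]))
    }
    stats::setNames(p$scores[keep], gen)
  })
  shared <- Reduce(intersect, lapply(per, names))
  if (!is.null(whitelist)) shared <- whitelist[whitelist %in% shared]
  else shared <- sort_generic(shared)
  if (length(shared) == 0) stop("no generic positions shared by all profiles")
  tab <- vapply(per, function(v) v[shared], numeric(length(shared)))
  if (length(shared) == 1) tab <- matrix(tab, nrow = 1)
  rownames(tab) <- shared
  colnames(tab) <- vapply(profiles, `[[`, character(1), "receptor_id")
  tab
}

sort_generic <- function(x) {
  helix <- as.integer(sub("x.*", "", x))
  pos <- as.integer(sub(".*x", "", x))
  x[order(helix, pos)]
}

#' Average aligned profiles across receptors
#'
#' Unweighted mean per position; the error bar is the population standard
#' deviation across the contributing receptors.
#'
#' @param table position-by-receptor matrix from [align_profiles()].
#' @return an `aggregated_profile` data.frame: `position`, `mean_score`,
#'   `error`, `n_contributors`.
#' @export
average_profile <- function(table) {
  stopifnot(is.matrix(table), nrow(table) >= 1)
  m <- ncol(table)
  means <- rowMeans(table)
  err <- sqrt(rowMeans(table^2) - means^2)
  err[err < 0 | is.na(err)] <- 0
  out <- data.frame(position = rownames(table), mean_score = means,
                    error = err, n_contributors = m,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("aggregated_profile", "data.frame")
  out
}

#' Error bars from active-inactive structure pairs
#'
#' For every pair of one active and one inactive member of the ensemble, a
#' bridging profile is computed from that two-structure sub-ensemble. The
#' per-residue error is the population standard deviation of the scores
#' across pair-profiles; the mean pair-profile is returned alongside.
#' Partially active structures are excluded from pairing by default; set
#' `partial_as_active = TRUE` to group them with the active set.
#'
#' @param ensemble a `ca_ensemble` whose members carry state labels.
#' @param cutoff mean-distance cutoff in Angstrom.
#' @param zero_tol relative zero-eigenvalue threshold.
#' @param partial_as_active count `partially_active` members as active.
#' @return a list: `mean_scores`, `error` (per residue), `pair_scores`
#'   (residue x pair matrix), `n_pairs`, `residues`.
#' @export
pair_error_profile <- function(ensemble, cutoff = 12, zero_tol = 1e-9,
                               partial_as_active = FALSE) {
  st <- ensemble$members$state_label
  act <- which(st == "active" | (partial_as_active & st == "partially_active"))
  ina <- which(st == "inactive")
  if (length(act) == 0 || length(ina) == 0) {
    stop("pairing requires at least one active and one inactive member")
  }
  pairs <- expand.grid(active = act, inactive = ina)
  scores <- vapply(seq_len(nrow(pairs)), function(i) {
    sub <- subset_members(ensemble, c(pairs$active[i], pairs$inactive[i]))
    ensemble_profile(sub, cutoff = cutoff, zero_tol = zero_tol)$scores
  }, numeric(nrow(ensemble$residues)))
  if (nrow(ensemble$residues) == 1) scores <- matrix(scores, nrow = 1)
  means <- rowMeans(scores)
  err <- sqrt(rowMeans(scores^2) - means^2)
  err[err < 0 | is.na(err)] <- 0
  list(mean_scores = means, error = err, pair_scores = scores,
       n_pairs = nrow(pairs), residues = ensemble$residues)
}

#' Pearson correlation between two score profiles
#'
#' Standard product-moment correlation; constant input is an error since the
#' coefficient is undefined there.
#'
#' @param p,q equal-length numeric vectors (length >= 3).
#' @return correlation coefficient in \[-1, 1\].
#' @export
pearson_correlation <- function(p, q) {
  stopifnot(length(p) == length(q), length(p) >= 3)
  if (stats::sd(p) == 0 || stats::sd(q) == 0) {
    stop("correlation undefined for constant input")
  }
  stats::cor(p, q, method = "pearson")
}

#' Transmembrane-position whitelist
#'
#' Expands the packaged generic-number ranges covering the transmembrane
#' helical bundle (the region where positions are in one-to-one
#' correspondence across class A receptors) into an explicit position list.
#' The TM7 ranges deliberately skip 7x44.
#'
#' @param path optional override file: one `AxBB-AxBB` range or single
#'   position per line, `#` comments allowed.
#' @return character vector of generic numbers in range order.
#' @export
default_whitelist <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "tm_ranges.txt", package = "mechbridge",
                        mustWork = TRUE)
  }
  lines <- readLines(path)
  lines <- trimws(sub("#.*", "", lines))
  lines <- lines[lines != ""]
  unlist(lapply(lines, expand_generic_range), use.names = FALSE)
}

expand_generic_range <- function(range) {
  parts <- strsplit(range, "-", fixed = TRUE)[[1]]
  if (length(parts) == 1) return(parts)
  if (length(parts) != 2) stop("malformed range: ", range)
  h1 <- sub("x.*", "", parts[1]); h2 <- sub("x.*", "", parts[2])
  if (h1 != h2) stop("range spans helices: ", range)
  lo <- as.integer(sub(".*x", "", parts[1]))
  hi <- as.integer(sub(".*x", "", parts[2]))
  sprintf("%sx%02d", h1, lo:hi)
}
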