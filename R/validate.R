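# Static coordination-number baseline and ROC evaluation of per-position
# scores against a key-site list.

#' Coordination-number profile
#'
#' Counts, for every residue, the spatial neighbors whose mean C-alpha
#' distance over the ensemble falls below the cutoff (self excluded, bonded
#' neighbors included). This is the static contact-based centrality baseline
#' that mechanical bridging scores are compared against; cross-receptor
#' averaging reuses [align_profiles()] / [average_profile()] on the returned
#' profile object.
#'
#' @param stats a `fluct_stats` object.
#' @param cutoff contact cutoff in Angstrom (default 12, matching the
#'   coupling-network cutoff).
#' @param receptor_id label for downstream alignment.
#' @return a `bridging_profile`-shaped object whose `scores` are contact
#'   counts.
#' @export
coordination_profile <- function(stats, cutoff = 12, receptor_id = "network") {
  stopifnot(inherits(stats, "fluct_stats"))
  within <- stats$mean_distance < cutoff
  diag(within) <- FALSE
  structure(list(receptor_id = receptor_id, residues = stats$residues,
                 omega0 = NA_real_, scores = unname(rowSums(within)),
                 disconnects = logical(nrow(stats$residues))),
            class = "bridging_profile")
}

#' ROC curve of a score against a positive-position set
#'
#' Ranks positions by descending score and traces the true/false positive
#' rates. Tied scores are grouped at a single threshold, which makes the
#' trapezoidal area equal the rank-average (Mann-Whitney U) estimate of the
#' AUC.
#'
#' @param scores named numeric vector (names are position labels).
#' @param positives character vector of positive positions; must be a proper
#'   non-empty subset of the scored positions.
#' @return a `roc_result`: `thresholds` (descending), `tpr`, `fpr` (including
#'   the (0,0) and (1,1) endpoints) and `auc`.
#' @export
roc_curve <- function(scores, positives) {
  stopifnot(!is.null(names(scores)))
  labels <- names(scores) %in% positives
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) {
    stop("positives must be a proper non-empty subset of the scored positions")
  }
  if (!all(positives %in% names(scores))) {
    warning("positive position(s) absent from the scored set are ignored")
  }
  ord <- order(-scores)
  s <- scores[ord]; l <- labels[ord]
  grp <- cumsum(!duplicated(s))  # tie groups share a threshold
  tp <- cumsum(l); fp <- cumsum(!l)
  last <- !duplicated(grp, fromLast = TRUE)
  thresholds <- s[last]
  tpr <- c(0, tp[last] / n_pos)
  fpr <- c(0, fp[last] / n_neg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(thresholds = thresholds, tpr = tpr, fpr = fpr, auc = auc),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> %d thresholds, AUC = %.4f\n",
              length(x$thresholds), x$auc))
  invisible(x)
}

#' Top-k positions by score
#'
#' @param scores named numeric vector.
#' @param k number of positions to return (defaults to all).
#' @return character vector of `k` position labels in descending score
#'   order; ties broken by input order (stable).
#' @export
top_k <- function(scores, k = length(scores)) {
  stopifnot(k <= length(scores), !is.null(names(scores)))
  names(scores)[order(-scores)][seq_len(k)]
}

#' Packaged key functional-site list
#'
#' The consensus class A key-site positions (18 distinct generic numbers from
#' the sequence- and structure-based survey shipped with the package) used as
#' the default positive set for ROC validation. Any user-supplied list in the
#' same one-position-per-line format is accepted.
#'
#' @param path optional override file: one generic number per line, `#`
#'   comments allowed.
#' @return character vector of generic numbers.
#' @export
default_key_sites <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "key_sites.txt", package = "mechbridge",
                        mustWork = TRUE)
  }
  lines <- trimws(sub("#.*", "", readLines(path)))
  lines[lines != ""]
}

#' Write a ROC curve as TSV with an AUC summary line
#'
#' @param roc a `roc_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_roc_tsv <- function(roc, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# auc\t%.6f", roc$auc), con)
  df <- data.frame(threshold = c(NA, roc$thresholds),
                   fpr = roc$fpr, tpr = roc$tpr)
  suppressWarnings(utils::write.table(df, con, sep = "\t", quote = FALSE,
                                      row.names = FALSE))
  invisible(path)
}
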