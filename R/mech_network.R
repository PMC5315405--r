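# Distance-fluctuation statistics over an ensemble and the Gaussian-weighted
# local mechanical coupling network built from them.

#' Pairwise distance statistics over an ensemble
#'
#' For every residue pair (a, b) computes the mean C-alpha--C-alpha distance
#' and the distance fluctuation f_ab, the population standard deviation of
#' d_ab across ensemble members (second moment about the mean divided by the
#' member count M, not M - 1; evaluated in two-pass form for numerical
#' stability). Pairwise distances are
#' invariant under rigid-body motion of any member, so no superposition is
#' performed or needed.
#'
#' @param ensemble a `ca_ensemble` with at least two members.
#' @return a `fluct_stats` object: `mean_distance` and `fluctuation` (N x N
#'   symmetric matrices, Angstrom, zero diagonal) and `n_members`.
#' @export
distance_stats <- function(ensemble) {
  stopifnot(inherits(ensemble, "ca_ensemble"))
  m <- length(ensemble$coords)
  if (m < 2) stop("fluctuation analysis needs at least 2 ensemble members")
  n <- nrow(ensemble$residues)
  dists <- lapply(ensemble$coords, function(xyz) as.matrix(stats::dist(xyz)))
  mean_d <- Reduce(`+`, dists) / m
  # population variance in two-pass form: numerically equal to the raw-moment
  # expression <d^2> - <d>^2 but without its cancellation at large distances
  var_d <- Reduce(`+`, lapply(dists, function(d) (d - mean_d)^2)) / m
  fluct <- sqrt(var_d)
  dimnames(mean_d) <- NULL
  dimnames(fluct) <- NULL
  diag(mean_d) <- 0
  diag(fluct) <- 0
  structure(list(mean_distance = mean_d, fluctuation = fluct,
                 n_members = m, residues = ensemble$residues),
            class = "fluct_stats")
}

#' Covalent-chain adjacency mask
#'
#' Marks residue pairs that are consecutive along the polypeptide chain:
#' identical chain identifier and author numbers differing by exactly one.
#' Gaps in the retained residue set (e.g. a skipped residue) break adjacency,
#' as do chain boundaries. These bonded pairs are the couplings that node
#' deletion preserves.
#'
#' @param residues an ordered residue table.
#' @return an N x N logical matrix, symmetric, `FALSE` diagonal.
#' @export
bonded_mask <- function(residues) {
  n <- nrow(residues)
  same_chain <- outer(residues$chain_id, residues$chain_id, "==")
  dnum <- abs(outer(residues$seq_number, residues$seq_number, "-"))
  mask <- same_chain & dnum == 1L
  diag(mask) <- FALSE
  mask
}

#' Build the local mechanical coupling network
#'
#' Converts distance fluctuations into coupling strengths with a Gaussian
#' weighting, sigma_ab = exp(-f_ab^2 / (2 fbar^2)), restricted to residue
#' pairs whose mean C-alpha distance is below `cutoff`; couplings outside the
#' cutoff and the diagonal are zero. The sensitivity fbar is the mean of f_ab
#' over the unordered non-self pairs within the cutoff (bonded pairs
#' included). A fully rigid ensemble (all f_ab = 0, so fbar = 0) takes the
#' continuous limit sigma = 1 for every within-cutoff pair.
#'
#' @param stats a `fluct_stats` object.
#' @param bonded optional logical adjacency mask; defaults to
#'   [bonded_mask()] on the stats' residue table.
#' @param cutoff mean-distance cutoff in Angstrom (strict inequality;
#'   default 12).
#' @return a `mech_network`: `coupling` matrix, `cutoff`, `sensitivity`
#'   (fbar), `bonded` mask, `residues`.
#' @export
build_network <- function(stats, bonded = NULL, cutoff = 12) {
  stopifnot(inherits(stats, "fluct_stats"), cutoff > 0)
  if (is.null(bonded)) bonded <- bonded_mask(stats$residues)
  n <- nrow(stats$mean_distance)
  stopifnot(all(dim(bonded) == n))
  within <- stats$mean_distance < cutoff
  diag(within) <- FALSE
  if (!any(within)) stop("no residue pair within the cutoff distance")
  ut <- upper.tri(within) & within
  fbar <- mean(stats$fluctuation[ut])
  # fbar below the rigidity tolerance (1e-10 A, far below any physical
  # fluctuation) means the ensemble is rigid up to roundoff: take the
  # continuous limit sigma = 1 instead of amplifying numerical noise
  if (fbar <= 1e-10) fbar <- 0
  if (fbar > 0) {
    sigma <- exp(-stats$fluctuation^2 / (2 * fbar^2))
  } else {
    sigma <- matrix(1, n, n)  # rigid limit: f -> 0 faster than fbar
  }
  sigma[!within] <- 0
  diag(sigma) <- 0
  structure(list(coupling = sigma, cutoff = cutoff, sensitivity = fbar,
                 bonded = bonded, residues = stats$residues),
            class = "mech_network")
}

#' @export
print.mech_network <- function(x, ...) {
  n <- nrow(x$coupling)
  cat(sprintf(
    "<mech_network> %d residues, cutoff %.1f A, fbar %.4f A, %d couplings\n",
    n, x$cutoff, x$sensitivity, sum(x$coupling[upper.tri(x$coupling)] > 0)))
  invisible(x)
}

#' Write a square matrix with a residue-key header
#'
#' @param mat square numeric matrix.
#' @param residues residue table supplying the header keys.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(mat, residues, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(residues$key, collapse = "\t"), con)
  utils::write.table(format(mat, digits = 8, trim = TRUE), con, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
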