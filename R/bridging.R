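# Normalized-Laplacian spectrum of the coupling network, network softness,
# and the per-residue mechanical bridging score obtained by virtually
# deleting each residue's non-bonded couplings.

#' Symmetric normalized Laplacian spectrum
#'
#' Computes L = I - D^{-1/2} sigma D^{-1/2}, where D is the diagonal degree
#' matrix D_aa = sum_c sigma_ac, and its full eigendecomposition. Eigenvalues
#' are sorted ascending; small negative values within the numerical tolerance
#' are clipped to zero. An eigenvalue counts as zero when it is below
#' `zero_tol * max(lambda_max, 1)`; for a well-formed network the zero count
#' equals the number of connected components of the sigma > 0 graph. An
#' isolated node (zero degree) is its own component: its D^{-1/2} entry is set
#' to 0 and its diagonal entry contributes one exact zero eigenvalue.
#'
#' @param network a `mech_network` (or a bare symmetric coupling matrix).
#' @param zero_tol relative zero-eigenvalue threshold (default 1e-9).
#' @return a `laplacian_spectrum`: `matrix`, ascending `eigenvalues`,
#'   `vectors` (columns aligned with eigenvalues), `n_zero`, `zero_tol`.
#' @export
normalized_laplacian <- function(network, zero_tol = 1e-9) {
  sigma <- if (inherits(network, "mech_network")) network$coupling else network
  stopifnot(is.matrix(sigma), nrow(sigma) == ncol(sigma))
  n <- nrow(sigma)
  deg <- rowSums(sigma)
  if (all(deg == 0)) stop("all couplings are zero: empty network")
  dinv <- ifelse(deg > 0, 1 / sqrt(deg), 0)
  L <- -sigma * tcrossprod(dinv)
  diag(L) <- ifelse(deg > 0, 1, 0)
  eig <- eigen(L, symmetric = TRUE)
  values <- rev(eig$values)
  vectors <- eig$vectors[, rev(seq_len(n)), drop = FALSE]
  scale <- max(values[n], 1)
  values[values < 0 & values > -zero_tol * scale] <- 0
  n_zero <- sum(values < zero_tol * scale)
  structure(list(matrix = L, eigenvalues = values, vectors = vectors,
                 n_zero = n_zero, zero_tol = zero_tol),
            class = "laplacian_spectrum")
}

#' Network softness
#'
#' The sum of inverse eigenvalues of the normalized Laplacian, omitting the
#' zero eigenvalues (one per connected component). Softer networks -- closer
#' to falling apart into independent pieces -- have larger Omega.
#'
#' @param spectrum a `laplacian_spectrum`.
#' @return Omega, a positive scalar.
#' @export
softness <- function(spectrum) {
  stopifnot(inherits(spectrum, "laplacian_spectrum"))
  lam <- spectrum$eigenvalues
  if (spectrum$n_zero >= length(lam)) stop("all eigenvalues are zero")
  sum(1 / lam[(spectrum$n_zero + 1L):length(lam)])
}

#' Virtually delete a residue's non-bonded couplings
#'
#' Zeroes row and column `k` of the coupling matrix except at positions marked
#' bonded, leaving the residue in the network with only its covalent-chain
#' couplings. The operation is idempotent and keeps N constant, so softness
#' values before and after deletion are directly comparable.
#'
#' @param network a `mech_network`.
#' @param k residue index (1-based).
#' @return the modified `mech_network`.
#' @export
delete_node_couplings <- function(network, k) {
  stopifnot(inherits(network, "mech_network"),
            k >= 1, k <= nrow(network$coupling))
  nb <- !network$bonded[k, ]
  network$coupling[k, nb] <- 0
  network$coupling[nb, k] <- 0
  network
}

#' Mechanical bridging score profile
#'
#' Scores every residue k by the softening Delta_k = Omega_k - Omega_0 that
#' deleting its non-bonded couplings causes, where Omega is the sum of inverse
#' non-zero normalized-Laplacian eigenvalues. Residues whose couplings are all
#' bonded score exactly zero (deletion is a no-op). When a deletion
#' disconnects the network the extra zero eigenvalues are omitted from
#' Omega_k exactly as for Omega_0 and the residue is flagged; with
#' `mask_disconnecting = TRUE` such residues are scored `NA` instead,
#' reproducing the convention of excluding disconnection-prone positions.
#'
#' @param network a `mech_network`.
#' @param zero_tol relative zero-eigenvalue threshold.
#' @param mask_disconnecting replace scores of network-splitting residues
#'   with `NA`.
#' @param receptor_id optional label carried into the profile.
#' @return a `bridging_profile`: `residues`, `omega0`, `scores` (Delta_k),
#'   `disconnects` (logical), `receptor_id`.
#' @export
bridging_profile <- function(network, zero_tol = 1e-9,
                             mask_disconnecting = FALSE,
                             receptor_id = NULL) {
  stopifnot(inherits(network, "mech_network"))
  n <- nrow(network$coupling)
  spec0 <- normalized_laplacian(network, zero_tol)
  if (spec0$n_zero > 1) {
    warning(sprintf("coupling network has %d connected components",
                    spec0$n_zero))
  }
  omega0 <- softness(spec0)
  scores <- numeric(n)
  disconnects <- logical(n)
  for (k in seq_len(n)) {
    nonbonded <- network$coupling[k, ] > 0 & !network$bonded[k, ]
    if (!any(nonbonded)) next  # nothing to delete: Delta_k = 0
    pruned <- delete_node_couplings(network, k)
    spec_k <- tryCatch(normalized_laplacian(pruned, zero_tol),
                       error = function(e) {
                         stop(sprintf("eigendecomposition failed at residue %s: %s",
                                      network$residues$key[k],
                                      conditionMessage(e)))
                       })
    disconnects[k] <- spec_k$n_zero > spec0$n_zero
    scores[k] <- softness(spec_k) - omega0
  }
  if (mask_disconnecting) scores[disconnects] <- NA_real_
  structure(list(receptor_id = receptor_id %||% "network",
                 residues = network$residues,
                 omega0 = omega0, scores = scores,
                 disconnects = disconnects),
            class = "bridging_profile")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.bridging_profile <- function(x, ...) {
  cat(sprintf(
    "<bridging_profile> %s: %d residues, Omega0 = %.3f, max Delta = %.4f\n",
    x$receptor_id, length(x$scores), x$omega0, max(x$scores, na.rm = TRUE)))
  invisible(x)
}

#' Run the per-receptor scoring pipeline on an ensemble
#'
#' Convenience wrapper chaining [distance_stats()], [build_network()] and
#' [bridging_profile()].
#'
#' @param ensemble a `ca_ensemble`.
#' @param cutoff mean-distance cutoff in Angstrom.
#' @param zero_tol relative zero-eigenvalue threshold.
#' @param mask_disconnecting see [bridging_profile()].
#' @return a `bridging_profile`.
#' @export
ensemble_profile <- function(ensemble, cutoff = 12, zero_tol = 1e-9,
                             mask_disconnecting = FALSE) {
  stats <- distance_stats(ensemble)
  net <- build_network(stats, cutoff = cutoff)
  bridging_profile(net, zero_tol = zero_tol,
                   mask_disconnecting = mask_disconnecting,
                   receptor_id = ensemble$receptor_id)
}

#' Write a bridging profile as TSV
#'
#' Columns: residue_key, generic_number (blank when unmapped), score,
#' disconnection_flag.
#'
#' @param profile a `bridging_profile`.
#' @param path output path.
#' @param generic optional character vector of generic numbers aligned with
#'   the profile's residues.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profile, path, generic = NULL) {
  gen <- generic %||% profile$residues$generic_number
  gen[is.na(gen)] <- ""
  df <- data.frame(residue_key = profile$residues$key,
                   generic_number = gen,
                   score = profile$scores,
                   disconnection_flag = profile$disconnects)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
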