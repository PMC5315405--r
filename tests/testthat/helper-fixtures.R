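# Shared fixtures: direct constructors for networks and stats objects, tiny
# PDB writers, and random-network generators used across test files.

toy_residues <- function(n, chain = "A", start = 1L, names = "ALA") {
  mechbridge:::residue_table(chain_id = chain,
                             seq_number = seq(start, length.out = n),
                             residue_name = rep_len(names, n))
}

toy_network <- function(sigma, bonded = NULL, residues = NULL) {
  n <- nrow(sigma)
  if (is.null(bonded)) bonded <- matrix(FALSE, n, n)
  if (is.null(residues)) residues <- toy_residues(n)
  structure(list(coupling = sigma, cutoff = 12, sensitivity = 1,
                 bonded = bonded, residues = residues),
            class = "mech_network")
}

toy_stats <- function(mean_distance, fluctuation, n_members = 2L,
                      residues = NULL) {
  if (is.null(residues)) residues <- toy_residues(nrow(mean_distance))
  structure(list(mean_distance = mean_distance, fluctuation = fluctuation,
                 n_members = n_members, residues = residues),
            class = "fluct_stats")
}

chain_bonded <- function(n) {
  b <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1)) b[i, i + 1] <- b[i + 1, i] <- TRUE
  b
}

# random connected network: a bonded chain carrying random couplings plus
# sparse random non-bonded links
random_network <- function(n, extra_prob = 0.15) {
  bonded <- chain_bonded(n)
  sigma <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    sigma[i, i + 1] <- sigma[i + 1, i] <- runif(1, 0.2, 1)
  }
  extra <- which(upper.tri(sigma) & !bonded & runif(n * n) < extra_prob,
                 arr.ind = TRUE)
  for (r in seq_len(nrow(extra))) {
    w <- runif(1)
    sigma[extra[r, 1], extra[r, 2]] <- w
    sigma[extra[r, 2], extra[r, 1]] <- w
  }
  toy_network(sigma, bonded)
}

two_member_ensemble <- function(xyz1, xyz2, names = "ALA") {
  n <- nrow(xyz1)
  mechbridge:::new_ensemble(
    "toy", toy_residues(n, names = names), list(xyz1, xyz2),
    data.frame(structure_id = c("a", "b"), state_label = "unknown",
               stringsAsFactors = FALSE))
}

# PDB ATOM line at the standard fixed columns, with altloc support
pdb_atom_line <- function(serial, resname, chain, resno, x, y, z,
                          altloc = " ", occ = 1, elety = " CA ",
                          icode = " ") {
  sprintf("ATOM  %5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f",
          serial, elety, altloc, resname, chain, resno, icode, x, y, z,
          occ, 0)
}

write_toy_pdb <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}
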