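# Ingestion of C-alpha conformational ensembles from PDB files, plus the
# bookkeeping files (dataset manifest, generic residue numbering map) that tie
# structures to receptors and cross-receptor positions.

AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")

STATE_LEVELS <- c("active", "inactive", "partially_active", "unknown")

#' Residue key table
#'
#' Internal constructor for the ordered residue table shared by structure
#' models and ensembles: one row per C-alpha position, identified by chain,
#' author residue number and insertion code.
#'
#' @param chain_id character chain identifiers.
#' @param seq_number integer author residue numbers.
#' @param insertion_code insertion codes; blanks normalized to `""`.
#' @param residue_name 3-letter amino-acid codes.
#' @param generic_number optional generic position labels (`"AxBB"`), `NA`
#'   where unassigned.
#' @return a `data.frame` with one row per residue and a `key` column uniquely
#'   identifying each position within one structure.
#' @keywords internal
residue_table <- function(chain_id, seq_number, insertion_code = "",
                          residue_name, generic_number = NA_character_) {
  ins <- as.character(insertion_code)
  ins[is.na(ins) | ins == " "] <- ""
  df <- data.frame(chain_id = as.character(chain_id),
                   seq_number = as.integer(seq_number),
                   insertion_code = ins,
                   residue_name = as.character(residue_name),
                   generic_number = as.character(generic_number),
                   stringsAsFactors = FALSE)
  df$key <- paste(df$chain_id, df$seq_number, df$insertion_code, sep = "|")
  if (anyDuplicated(df$key)) {
    stop("duplicate residue identity (chain, number, insertion code) in one structure")
  }
  df
}

new_structure_model <- function(structure_id, residues, coordinates,
                                state_label = "unknown") {
  stopifnot(nrow(residues) == nrow(coordinates), all(is.finite(coordinates)))
  state_label <- match.arg(state_label, STATE_LEVELS)
  structure(list(structure_id = structure_id,
                 residues = residues,
                 coordinates = coordinates,
                 state_label = state_label),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("<structure_model> %s: %d C-alpha residues, state = %s\n",
              x$structure_id, nrow(x$residues), x$state_label))
  invisible(x)
}

#' Load C-alpha structure models from PDB files
#'
#' Reads standard PDB files (including multi-MODEL files, e.g. trajectory
#' frames exported as PDB models) and returns one `structure_model` per model,
#' keeping only C-alpha atoms of standard amino acids. Alternate locations are
#' resolved to the highest-occupancy record (first on ties); HETATM and
#' non-amino-acid records are dropped. Residues present in a file but lacking
#' a C-alpha atom are skipped with a warning.
#'
#' @param paths character vector of PDB file paths.
#' @param chain_filter optional chain identifier(s); other chains are dropped.
#' @param stride keep every `stride`-th MODEL of a multi-model file.
#' @param state_labels optional character vector (recycled to `length(paths)`)
#'   of activation-state labels attached to every model read from each file.
#' @return a list of `structure_model` objects, in file (and MODEL) order.
#' @examples
#' pdb <- tempfile(fileext = ".pdb")
#' writeLines(c(
#'   "ATOM      1  CA  GLY A   1       0.000   0.000   0.000  1.00  0.00",
#'   "ATOM      2  CA  ALA A   2       3.800   0.000   0.000  1.00  0.00",
#'   "END"), pdb)
#' load_structures(pdb)
#' @export
load_structures <- function(paths, chain_filter = NULL, stride = 1L,
                            state_labels = "unknown") {
  stopifnot(length(paths) >= 1, stride >= 1)
  state_labels <- rep_len(state_labels, length(paths))
  models <- list()
  for (i in seq_along(paths)) {
    path <- paths[[i]]
    pdb <- tryCatch(
      bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE),
      error = function(e) stop(sprintf("cannot parse '%s' as PDB: %s",
                                       path, conditionMessage(e)))
    )
    atoms <- pdb$atom
    atoms$row <- seq_len(nrow(atoms))
    aa <- atoms[atoms$type == "ATOM" & atoms$resid %in% AA3, , drop = FALSE]
    if (!is.null(chain_filter)) {
      aa <- aa[aa$chain %in% chain_filter, , drop = FALSE]
    }
    if (nrow(aa) == 0) stop(sprintf("no amino-acid ATOM records in '%s'", path))
    ins <- as.character(aa$insert)
    ins[is.na(ins)] <- ""
    aa$reskey <- paste(aa$chain, aa$resno, ins, sep = "|")
    ca <- aa[aa$elety == "CA", , drop = FALSE]
    missing_ca <- setdiff(unique(aa$reskey), unique(ca$reskey))
    if (length(missing_ca) > 0) {
      warning(sprintf("%s: %d residue(s) without a C-alpha atom skipped (%s)",
                      basename(path), length(missing_ca),
                      paste(utils::head(missing_ca, 3), collapse = ", ")))
    }
    if (nrow(ca) == 0) stop(sprintf("no C-alpha atoms in '%s'", path))
    # altloc: keep the highest-occupancy CA per residue, first record on ties
    occ <- ifelse(is.na(ca$o), 1, ca$o)
    keep <- ca[order(match(ca$reskey, unique(ca$reskey)), -occ,
                     seq_len(nrow(ca))), , drop = FALSE]
    keep <- keep[!duplicated(keep$reskey), , drop = FALSE]
    keep <- keep[order(keep$row), , drop = FALSE]

    res <- residue_table(chain_id = keep$chain, seq_number = keep$resno,
                         insertion_code = keep$insert,
                         residue_name = keep$resid)
    xyz_ind <- bio3d::atom2xyz(keep$row)
    xyz <- pdb$xyz
    if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
    n_models <- nrow(xyz)
    frames <- seq(1L, n_models, by = stride)
    base_id <- sub("\\.(pdb|ent)(\\.gz)?$", "", basename(path),
                   ignore.case = TRUE)
    for (m in frames) {
      coords <- matrix(xyz[m, xyz_ind], ncol = 3, byrow = TRUE)
      sid <- if (n_models > 1) sprintf("%s_m%d", base_id, m) else base_id
      models[[length(models) + 1L]] <-
        new_structure_model(sid, res, coords, state_labels[[i]])
    }
  }
  models
}

#' Build an ensemble on the common residue set
#'
#' Intersects the residue lists of two or more structure models on residue
#' identity (chain, author number, insertion code) requiring a consistent
#' amino-acid type, and restricts every model to that common set. Positions
#' whose residue name differs between models are excluded with a warning.
#' Ordering follows the first model.
#'
#' @param models list of `structure_model` objects (at least two).
#' @param receptor_id label attached to the resulting ensemble.
#' @return a `ca_ensemble`: common residue table, per-member coordinate
#'   matrices (rows aligned with the residue table) and member metadata.
#' @export
intersect_residues <- function(models, receptor_id = "ensemble") {
  stopifnot(length(models) >= 2)
  keysets <- lapply(models, function(m) m$residues$key)
  common <- Reduce(intersect, keysets)
  if (length(common) == 0) stop("no residues common to all models")
  # keep first-model order
  first <- models[[1]]$residues
  common <- first$key[first$key %in% common]
  names_by_model <- vapply(models, function(m) {
    idx <- match(common, m$residues$key)
    paste(m$residues$residue_name[idx])
  }, character(length(common)))
  if (length(common) == 1) names_by_model <- matrix(names_by_model, nrow = 1)
  consistent <- apply(names_by_model, 1, function(r) length(unique(r)) == 1)
  if (any(!consistent)) {
    warning(sprintf("%d shared position(s) excluded for residue-name mismatch",
                    sum(!consistent)))
    common <- common[consistent]
  }
  if (length(common) == 0) stop("no residues common to all models")
  residues <- first[match(common, first$key), , drop = FALSE]
  rownames(residues) <- NULL
  coords <- lapply(models, function(m) {
    m$coordinates[match(common, m$residues$key), , drop = FALSE]
  })
  members <- data.frame(
    structure_id = vapply(models, `[[`, character(1), "structure_id"),
    state_label = vapply(models, `[[`, character(1), "state_label"),
    stringsAsFactors = FALSE)
  new_ensemble(receptor_id, residues, coords, members)
}

new_ensemble <- function(receptor_id, residues, coords, members) {
  stopifnot(length(coords) == nrow(members),
            all(vapply(coords, nrow, 1L) == nrow(residues)))
  structure(list(receptor_id = receptor_id,
                 residues = residues,
                 coords = coords,
                 members = members),
            class = "ca_ensemble")
}

#' @export
print.ca_ensemble <- function(x, ...) {
  cat(sprintf("<ca_ensemble> %s: %d members x %d residues\n",
              x$receptor_id, length(x$coords), nrow(x$residues)))
  invisible(x)
}

#' Subset an ensemble to selected members
#'
#' @param ensemble a `ca_ensemble`.
#' @param which integer or logical member selector.
#' @return a `ca_ensemble` with the selected members.
#' @export
subset_members <- function(ensemble, which) {
  new_ensemble(ensemble$receptor_id, ensemble$residues,
               ensemble$coords[which],
               ensemble$members[which, , drop = FALSE])
}

#' Load a generic-numbering map
#'
#' Reads a tab-separated table with columns `receptor_id`, `chain_id`,
#' `seq_number`, `generic_number` assigning generic helix-position labels of
#' the form `"AxBB"` (helix number `A`, two-digit position `BB`, with the most
#' conserved residue of each helix at 50) to author residue positions.
#'
#' @param path TSV file path.
#' @return a data.frame keyed by (receptor_id, chain_id, seq_number).
#' @export
load_numbering_map <- function(path) {
  map <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("receptor_id", "chain_id", "seq_number", "generic_number")
  if (!all(need %in% names(map))) {
    stop("numbering map must have columns: ", paste(need, collapse = ", "))
  }
  map$seq_number <- as.integer(map$seq_number)
  bad <- !grepl("^[0-9]+x[0-9]{2}$", map$generic_number)
  if (any(bad)) {
    stop(sprintf("malformed generic number at line %d of '%s': '%s'",
                 which(bad)[1] + 1L, path, map$generic_number[which(bad)[1]]))
  }
  key <- paste(map$receptor_id, map$chain_id, map$seq_number, sep = "|")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    stop(sprintf("duplicate numbering-map key: %s", dup))
  }
  map$key <- key
  map
}

#' Look up generic numbers for an ensemble's residues
#'
#' @param map a numbering map from [load_numbering_map()].
#' @param receptor_id receptor whose rows of the map apply.
#' @param residues a residue table (from an ensemble or structure model).
#' @return character vector of generic numbers aligned with `residues`
#'   (`NA` where unmapped).
#' @export
generic_numbers <- function(map, receptor_id, residues) {
  key <- paste(receptor_id, residues$chain_id, residues$seq_number, sep = "|")
  map$generic_number[match(key, map$key)]
}

#' Read a dataset manifest
#'
#' A manifest lists one structure file per row with columns `receptor_id`,
#' `path`, `state`, `organism`. State tokens are normalized: `"p. active"`
#' variants become `partially_active`; `"active (?)"` counts as `active`.
#' Relative paths are resolved against the manifest location.
#'
#' @param path TSV file path.
#' @param check_paths verify that every structure file exists.
#' @return a data.frame with normalized `state` values.
#' @export
read_manifest <- function(path, check_paths = TRUE) {
  man <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("receptor_id", "path", "state", "organism")
  if (!all(need %in% names(man))) {
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  }
  man$state <- normalize_state(man$state)
  rel <- !grepl("^(/|[A-Za-z]:)", man$path)
  man$path[rel] <- file.path(dirname(path), man$path[rel])
  if (check_paths && !all(file.exists(man$path))) {
    stop("manifest refers to missing file(s): ",
         paste(man$path[!file.exists(man$path)], collapse = ", "))
  }
  man
}

normalize_state <- function(x) {
  y <- tolower(trimws(x))
  y[y %in% c("p. active", "p.active", "partially active",
             "partially_active")] <- "partially_active"
  y[y %in% c("active (?)", "active(?)")] <- "active"
  bad <- !(y %in% STATE_LEVELS)
  if (any(bad)) stop("unrecognized state label(s): ",
                     paste(unique(x[bad]), collapse = ", "))
  y
}

#' Write an ensemble (or one model) as a PDB file
#'
#' Serializes C-alpha traces to standard ATOM records, one MODEL/ENDMDL block
#' per ensemble member (a single-member ensemble is written without MODEL
#' wrappers). Coordinates are written at the 3-decimal precision of the PDB
#' format. The output re-ingests through [load_structures()].
#'
#' @param ensemble a `ca_ensemble`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ensemble_pdb <- function(ensemble, path) {
  res <- ensemble$residues
  n_mem <- length(ensemble$coords)
  con <- file(path, "w")
  on.exit(close(con))
  for (m in seq_len(n_mem)) {
    if (n_mem > 1) writeLines(sprintf("MODEL     %4d", m), con)
    xyz <- ensemble$coords[[m]]
    lines <- sprintf(
      "ATOM  %5d  CA  %3s %1s%4d%1s   %8.3f%8.3f%8.3f  1.00  0.00           C",
      seq_len(nrow(res)), res$residue_name, substr(res$chain_id, 1, 1),
      res$seq_number,
      ifelse(res$insertion_code == "", " ", res$insertion_code),
      xyz[, 1], xyz[, 2], xyz[, 3])
    writeLines(lines, con)
    if (n_mem > 1) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
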