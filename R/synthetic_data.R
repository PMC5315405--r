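# Synthetic C-alpha ensembles with planted quasi-rigid bodies, hinge
# residues and isotropic noise, so that every pipeline stage can be tested
# against a known ground truth without structure downloads.

#' Random self-avoiding C-alpha chain
#'
#' Generates an N x 3 coordinate matrix with fixed 3.8 Angstrom virtual
#' bonds and persistent random directions, rejection-sampled so that no
#' non-bonded pair comes closer than 3.4 Angstrom. Uses the current RNG
#' state.
#'
#' @param n number of residues (>= 3).
#' @param max_restarts full-chain restarts before giving up.
#' @return an n x 3 numeric matrix.
#' @keywords internal
saw_chain <- function(n, max_restarts = 50L) {
  stopifnot(n >= 3)
  for (attempt in seq_len(max_restarts)) {
    coords <- matrix(0, n, 3)
    dir <- random_unit()
    coords[2, ] <- coords[1, ] + 3.8 * dir
    ok <- TRUE
    for (i in 3:n) {
      placed <- FALSE
      for (try in 1:100) {
        nd <- 2 * dir + random_unit()  # persistent: semi-extended chain
        nd <- nd / sqrt(sum(nd^2))
        pos <- coords[i - 1, ] + 3.8 * nd
        prev <- coords[seq_len(i - 2), , drop = FALSE]
        if (min(sqrt(rowSums(sweep(prev, 2, pos)^2))) >= 3.4) {
          coords[i, ] <- pos
          dir <- nd
          placed <- TRUE
          break
        }
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) return(coords)
  }
  stop("failed to generate a self-avoiding chain")
}

random_unit <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

#' Uniform random rotation matrix (quaternion method)
#' @keywords internal
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

rotation_about_axis <- function(axis, theta) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

synthetic_residues <- function(n) {
  residue_table(chain_id = "A", seq_number = seq_len(n),
                residue_name = "ALA")
}

with_seed <- function(seed, code) {
  old <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(list = ".Random.seed",
                                   envir = globalenv())))
  set.seed(seed)
  force(code)
}

#' Rigid-body ensemble (null fixture)
#'
#' Every member is a random global rotation plus translation of the same
#' self-avoiding chain: pairwise distances are identical across members, so
#' the distance-fluctuation matrix is exactly zero.
#'
#' @param n_residues chain length (>= 3).
#' @param n_members ensemble size (>= 2).
#' @param seed RNG seed; generation is deterministic given the seed.
#' @return a list: `ensemble` (a `ca_ensemble`) and `truth`
#'   (a `synthetic_truth`).
#' @export
make_rigid_ensemble <- function(n_residues, n_members, seed = 1L) {
  stopifnot(n_residues >= 3, n_members >= 2)
  with_seed(seed, {
    base <- saw_chain(n_residues)
    # full precision: members are exact isometries of the base chain, so the
    # fluctuation matrix is zero to machine precision
    coords <- lapply(seq_len(n_members), function(m) {
      sweep(base %*% t(random_rotation()), 2, stats::runif(3, -50, 50), "+")
    })
    ens <- new_ensemble(
      "synthetic_rigid", synthetic_residues(n_residues), coords,
      data.frame(structure_id = sprintf("rigid_m%d", seq_len(n_members)),
                 state_label = "unknown", stringsAsFactors = FALSE))
    truth <- structure(list(body_assignment = rep(1L, n_residues),
                            hinge_residues = integer(0),
                            noise_sd = 0, n_members = n_members, seed = seed),
                       class = "synthetic_truth")
    list(ensemble = ens, truth = truth)
  })
}

#' Hinged rigid-body ensemble
#'
#' Builds a chain of consecutive rigid bodies joined at hinge residues. Each
#' ensemble member rotates body i+1 (and everything downstream) relative to
#' body i about the hinge C-alpha, around a fixed per-hinge axis, by an
#' independent random angle of magnitude at most `max_angle`; a random
#' global rigid transform and isotropic Gaussian noise of `noise_sd` per
#' coordinate are then applied. Members whose rigid geometry self-intersects
#' (non-bonded pair closer than 3.0 Angstrom before noise) are resampled up
#' to a bounded retry count. The ground truth records the body of every
#' residue and the hinge residues: the `hinge_width` residues on either side
#' of each body boundary.
#'
#' @param body_sizes integer vector of body lengths (>= 2 bodies of >= 8
#'   residues).
#' @param hinge_width residues per side of each boundary counted as hinge.
#' @param max_angle maximum inter-body rotation per member, degrees.
#' @param noise_sd isotropic positional noise, Angstrom.
#' @param n_members ensemble size (>= 2).
#' @param seed RNG seed.
#' @param angle_centers optional per-member matrix (n_members x n_hinges) of
#'   central hinge angles in degrees around which the random angles jitter;
#'   default all zero.
#' @param state_labels optional per-member state labels.
#' @param geometry optional reference geometry (`base` element of an earlier
#'   `hinge_fixture` with the same body sizes) to reuse instead of drawing a
#'   fresh chain and hinge axes.
#' @return a `hinge_fixture`: `ensemble`, `truth`, and the `base` geometry
#'   (reference coordinates, hinge pivots and axes) for derived fixtures.
#' @export
make_hinge_ensemble <- function(body_sizes, hinge_width = 1L, max_angle = 25,
                                noise_sd = 0.2, n_members = 20L, seed = 1L,
                                angle_centers = NULL, state_labels = NULL,
                                geometry = NULL) {
  stopifnot(length(body_sizes) >= 2, all(body_sizes >= 8), n_members >= 2,
            max_angle >= 0, noise_sd >= 0, hinge_width >= 1)
  n <- sum(body_sizes)
  n_h <- length(body_sizes) - 1L
  pivots <- cumsum(body_sizes)[seq_len(n_h)]
  if (is.null(angle_centers)) angle_centers <- matrix(0, n_members, n_h)
  stopifnot(nrow(angle_centers) == n_members, ncol(angle_centers) == n_h)
  with_seed(seed, {
    if (is.null(geometry)) {
      # bodies must interact only through the designated hinge region:
      # reject base geometries whose bodies come within coupling range away
      # from the hinge anywhere across the hinge-angle range
      ok <- FALSE
      for (attempt in 1:200) {
        base <- saw_chain(n)
        axes <- lapply(seq_len(n_h), function(i) random_unit())
        if (hinge_separated(base, pivots, axes, body_sizes, max_angle)) {
          ok <- TRUE
          break
        }
      }
      if (!ok) stop("could not place bodies with a clean hinge interface")
    } else {
      stopifnot(identical(as.integer(geometry$body_sizes),
                          as.integer(body_sizes)))
      base <- geometry$coords
      axes <- geometry$axes
    }
    coords <- vector("list", n_members)
    for (m in seq_len(n_members)) {
      placed <- FALSE
      for (try in 1:200) {
        ang <- angle_centers[m, ] +
          stats::runif(n_h, -max_angle, max_angle)
        xyz <- hinge_pose(base, pivots, axes, ang * pi / 180)
        if (min_nonbonded_dist(xyz) >= 3.0) { placed <- TRUE; break }
      }
      if (!placed) stop("hinge ensemble member self-intersects persistently")
      xyz <- sweep(xyz %*% t(random_rotation()), 2,
                   stats::runif(3, -50, 50), "+")
      if (noise_sd > 0) {
        xyz <- xyz + stats::rnorm(3 * n, 0, noise_sd)
        # quantize noisy members to PDB coordinate precision so that writing
        # the ensemble to PDB and re-ingesting reproduces results exactly;
        # noiseless members stay at full precision to preserve exact rigidity
        xyz <- round(xyz, 3)
      }
      coords[[m]] <- xyz
    }
    hinges <- sort(unique(unlist(lapply(pivots, function(p) {
      (p - hinge_width + 1L):(p + hinge_width)
    }))))
    body_id <- rep(seq_along(body_sizes), body_sizes)
    if (is.null(state_labels)) state_labels <- rep("unknown", n_members)
    ens <- new_ensemble(
      "synthetic_hinge", synthetic_residues(n), coords,
      data.frame(structure_id = sprintf("hinge_m%d", seq_len(n_members)),
                 state_label = state_labels, stringsAsFactors = FALSE))
    truth <- structure(list(body_assignment = body_id,
                            hinge_residues = hinges,
                            noise_sd = noise_sd, n_members = n_members,
                            seed = seed),
                       class = "synthetic_truth")
    structure(list(ensemble = ens, truth = truth,
                   base = list(coords = base, pivots = pivots, axes = axes,
                               body_sizes = body_sizes,
                               hinge_width = hinge_width,
                               max_angle = max_angle, noise_sd = noise_sd)),
              class = "hinge_fixture")
  })
}

hinge_pose <- function(base, pivots, axes, angles_rad) {
  xyz <- base
  cum <- diag(3)
  for (j in seq_along(pivots)) {
    p <- xyz[pivots[j], ]
    R <- rotation_about_axis(as.vector(cum %*% axes[[j]]), angles_rad[j])
    tail_idx <- (pivots[j] + 1L):nrow(xyz)
    xyz[tail_idx, ] <- sweep(sweep(xyz[tail_idx, , drop = FALSE], 2, p) %*%
                               t(R), 2, p, "+")
    cum <- R %*% cum
  }
  xyz
}

# TRUE when, over a grid of hinge angles spanning the motion range, residues
# of different bodies stay beyond `min_sep` unless both lie within `margin`
# positions of their shared boundary (the allowed hinge interface).
hinge_separated <- function(base, pivots, axes, body_sizes, max_angle,
                            margin = 4L, min_sep = 12.5) {
  n <- nrow(base)
  n_h <- length(pivots)
  body_id <- rep(seq_along(body_sizes), body_sizes)
  allowed <- matrix(FALSE, n, n)
  for (j in seq_len(n_h)) {
    lo <- (pivots[j] - margin + 1L):pivots[j]
    hi <- (pivots[j] + 1L):(pivots[j] + margin)
    allowed[lo, hi] <- TRUE
    allowed[hi, lo] <- TRUE
  }
  cross <- outer(body_id, body_id, "!=") & !allowed
  grid <- seq(-max_angle, max_angle, length.out = 5) * pi / 180
  for (g in grid) {
    xyz <- hinge_pose(base, pivots, axes, rep(g, n_h))
    d <- as.matrix(stats::dist(xyz))
    if (min(d[cross]) < min_sep) return(FALSE)
  }
  if (n_h > 1) {
    for (j in seq_len(n_h)) {
      for (g in grid[c(1, 5)]) {
        ang <- numeric(n_h); ang[j] <- g
        xyz <- hinge_pose(base, pivots, axes, ang)
        d <- as.matrix(stats::dist(xyz))
        if (min(d[cross]) < min_sep) return(FALSE)
      }
    }
  }
  TRUE
}

min_nonbonded_dist <- function(xyz) {
  d <- as.matrix(stats::dist(xyz))
  n <- nrow(d)
  sep <- abs(outer(seq_len(n), seq_len(n), "-"))
  min(d[sep > 1])
}

#' Two-state hinged ensemble for active/inactive pairing
#'
#' Reuses the geometry of a hinge fixture: "inactive" members jitter around
#' hinge angle 0 and "active" members around `state_angle_offset`, with the
#' fixture's `max_angle` jitter and `noise_sd` noise. State labels are
#' attached for [pair_error_profile()].
#'
#' @param fixture a `hinge_fixture` from [make_hinge_ensemble()].
#' @param n_active,n_inactive member counts (>= 1 each).
#' @param state_angle_offset hinge-angle offset of the active state, degrees.
#' @param seed RNG seed.
#' @return a `hinge_fixture` whose ensemble members carry state labels
#'   (inactive members first).
#' @export
make_state_ensemble <- function(fixture, n_active, n_inactive,
                                state_angle_offset = 30, seed = 1L) {
  stopifnot(inherits(fixture, "hinge_fixture"), n_active >= 1,
            n_inactive >= 1)
  b <- fixture$base
  n_members <- n_active + n_inactive
  n_h <- length(b$pivots)
  centers <- rbind(matrix(0, n_inactive, n_h),
                   matrix(state_angle_offset, n_active, n_h))
  out <- make_hinge_ensemble(
    body_sizes = b$body_sizes, hinge_width = b$hinge_width,
    max_angle = b$max_angle, noise_sd = b$noise_sd, n_members = n_members,
    seed = seed, angle_centers = centers,
    state_labels = rep(c("inactive", "active"), c(n_inactive, n_active)),
    geometry = b)
  out$ensemble$receptor_id <- "synthetic_states"
  out$ensemble$members$structure_id <-
    sprintf("%s_m%d", out$ensemble$members$state_label, seq_len(n_members))
  out
}
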