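# Canonical heavy side-chain atom names per residue type used by the toy
# protein. Backbone is N, CA, C, O for every residue.
.SIDECHAIN_ATOMS <- list(
  LYS = c("CB", "CG", "CD", "CE", "NZ"),
  ARG = c("CB", "CG", "CD", "NE", "CZ", "NH1", "NH2"),
  ASP = c("CB", "CG", "OD1", "OD2"),
  GLU = c("CB", "CG", "CD", "OE1", "OE2"),
  PHE = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ", "OH"),
  VAL = c("CB", "CG1", "CG2"),
  ILE = c("CB", "CG1", "CG2", "CD1"),
  LEU = c("CB", "CG", "CD1", "CD2"),
  ALA = "CB",
  GLY = character(0),
  PRO = c("CB", "CG", "CD")
)

#' Procedurally generated toy protein
#'
#' A single-chain 12-residue polypeptide with one residue of each type used
#' in contact classification (Lys, Arg, Asp, Glu, Phe, Tyr, Val, Ile, Leu,
#' Ala) plus glycine and proline, laid out on a ring with side chains
#' pointing outward. Atom names follow the PDB convention so side-chain and
#' backbone classification behaves as for a real structure; the geometry is
#' idealized, not stereochemically refined.
#'
#' @param radius ring radius for the alpha carbons, Angstrom.
#' @return a list with `atoms` (data.frame as for [trajectory_frames()]) and
#'   `xyz` (single-frame coordinate vector).
#' @export
toy_protein <- function(radius = 12) {
  res_names <- names(.SIDECHAIN_ATOMS)
  nres <- length(res_names)
  rows <- list()
  xyz <- numeric(0)
  eleno <- 0L
  for (j in seq_len(nres)) {
    th <- 2 * pi * (j - 1) / nres
    u <- c(cos(th), sin(th), 0)           # outward radial
    tv <- c(-sin(th), cos(th), 0)         # tangent
    ca <- radius * u
    resn <- res_names[j]
    add <- function(name, pos) {
      eleno <<- eleno + 1L
      rows[[length(rows) + 1L]] <<- data.frame(
        eleno = eleno, elety = name, resid = resn, chain = "A", resno = j,
        elesy = substr(name, 1, 1), stringsAsFactors = FALSE)
      xyz <<- c(xyz, pos)
    }
    add("N", ca - 1.45 * tv)
    add("CA", ca)
    add("C", ca + 1.52 * tv)
    add("O", ca + 1.52 * tv + c(0, 0, 1.23))
    sc <- .SIDECHAIN_ATOMS[[resn]]
    for (k in seq_along(sc)) {
      off <- (k %% 2) * 0.8 - 0.4
      add(sc[k], ca + (1.53 + 1.4 * (k - 1)) * u + off * tv +
            c(0, 0, 0.3 * ((k + 1) %% 2)))
    }
  }
  list(atoms = do.call(rbind, rows), xyz = xyz)
}

# Heavy-atom geometry of one ion, expressed along a unit ray: offsets from
# the nearest-point anchor (column 1 is along the ray, 2-3 span the plane
# perpendicular to it).
.ion_template <- function(species) {
  switch(species,
    SCN = list(elety = c("N", "C", "S"),
               elesy = c("N", "C", "S"),
               resid = "SCN",
               local = rbind(c(0, 0, 0), c(1.17, 0, 0), c(2.81, 0, 0))),
    GDM = list(elety = c("C", "N1", "N2", "N3"),
               elesy = c("C", "N", "N", "N"),
               resid = "GDM",
               local = rbind(c(0, 0, 0),
                             c(0.45, 1.26, 0),
                             c(0.45, -0.63, 1.09),
                             c(0.45, -0.63, -1.09))),
    stop("unknown ion species: ", species))
}

# Orthonormal frame whose first axis is the given unit vector.
.ray_frame <- function(dir) {
  a <- if (abs(dir[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e2 <- a - sum(a * dir) * dir
  e2 <- e2 / sqrt(sum(e2^2))
  e3 <- c(dir[2] * e2[3] - dir[3] * e2[2],
          dir[3] * e2[1] - dir[1] * e2[3],
          dir[1] * e2[2] - dir[2] * e2[1])
  cbind(dir, e2, e3)
}

#' Build synthetic trajectory frames with prescribed ion-protein distances
#'
#' Generates a [trajectory_frames()] set around the [toy_protein()]: in each
#' frame every ion is placed so that its minimum heavy-atom distance to any
#' protein heavy atom equals the assigned value to within `tol`. Placement
#' walks an ion template outward along a ray from a randomly chosen surface
#' atom and solves the exact minimum-distance condition by root finding;
#' placements that collide with already-placed ions are redrawn.
#'
#' @param plan per-frame distance assignments: a list of numeric vectors
#'   (one per frame, all the same length, all positive) or a single vector
#'   recycled over `n_frames`.
#' @param n_frames number of frames when `plan` is a single vector.
#' @param species ion species (`"SCN"` or `"GDM"`), scalar or one per ion.
#' @param seed integer seed controlling surface-atom choice and ray
#'   directions.
#' @param tol placement tolerance on the assigned minimum distance,
#'   Angstrom.
#' @param temperature_K temperature label attached to the frames.
#' @return a [trajectory_frames()] object; the realized plan is attached as
#'   attribute `plan` (n_frames x n_ions matrix of assigned distances).
#' @examples
#' fr <- make_frame_set(list(c(3.5, 3.9, 4.5)), seed = 1)
#' ions_in_shell(fr, cutoff = 4.0)  # 2
#' @export
make_frame_set <- function(plan, n_frames = NULL, species = "SCN", seed = 1,
                           tol = 1e-8, temperature_K = NA_real_) {
  if (!is.list(plan)) {
    if (is.null(n_frames)) n_frames <- 1L
    plan <- rep(list(as.numeric(plan)), n_frames)
  }
  nions <- unique(lengths(plan))
  if (length(nions) != 1L)
    stop("all frames must assign distances to the same number of ions")
  if (any(unlist(plan) <= 0)) stop("assigned distances must be positive")
  species <- rep_len(species, nions)
  set.seed(seed)

  prot <- toy_protein()
  pa <- prot$atoms
  pco <- matrix(prot$xyz, ncol = 3L, byrow = TRUE)
  heavy <- !(.is_hydrogen(pa$elety, pa$elesy))
  pheavy <- pco[heavy, , drop = FALSE]
  centroid <- colMeans(pheavy)

  templates <- lapply(species, .ion_template)
  ion_rows <- list()
  eleno <- max(pa$eleno)
  for (i in seq_len(nions)) {
    tm <- templates[[i]]
    ion_rows[[i]] <- data.frame(
      eleno = eleno + seq_along(tm$elety), elety = tm$elety,
      resid = tm$resid, chain = "B", resno = 100L + i,
      elesy = tm$elesy, stringsAsFactors = FALSE)
    eleno <- eleno + length(tm$elety)
  }
  atoms <- rbind(pa, do.call(rbind, ion_rows))

  place_ion <- function(target, tm, placed) {
    for (try in seq_len(200L)) {
      anchor <- pheavy[sample.int(nrow(pheavy), 1L), ]
      dir <- anchor - centroid + stats::rnorm(3, sd = 0.3)
      dir <- dir / sqrt(sum(dir^2))
      rot <- .ray_frame(dir)
      coords_at <- function(s) {
        sweep(tm$local %*% t(rot), 2L, anchor + s * dir, "+")
      }
      mind <- function(s) {
        sqrt(min(.cross_dist2(coords_at(s), pheavy))) - target
      }
      hi <- target + 40
      if (mind(hi) < 0) next
      root <- tryCatch(
        uniroot(mind, lower = 1e-6, upper = hi, tol = tol / 10)$root,
        error = function(e) NA_real_)
      if (is.na(root)) next
      co <- coords_at(root)
      if (length(placed) &&
          min(.cross_dist2(co, do.call(rbind, placed))) < 4)  # < 2 A apart
        next
      if (abs(mind(root)) > tol) next
      return(co)
    }
    stop("infeasible ion placement for assigned distance ", target)
  }

  xyz <- matrix(NA_real_, nrow = length(plan),
                ncol = 3L * nrow(atoms))
  for (f in seq_along(plan)) {
    placed <- list()
    for (i in seq_len(nions)) {
      placed[[i]] <- place_ion(plan[[f]][i], templates[[i]], placed)
    }
    co_all <- rbind(pco, do.call(rbind, placed))
    xyz[f, ] <- as.numeric(t(co_all))
  }
  fr <- trajectory_frames(atoms, xyz, temperature_K = temperature_K)
  attr(fr, "plan") <- do.call(rbind, plan)
  fr
}
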