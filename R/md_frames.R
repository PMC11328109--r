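# Residue names recognized as protein.
.AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL")

# Backbone heavy-atom names; everything else on a protein residue is side chain.
.BACKBONE <- c("N", "CA", "C", "O", "OXT")

# Default residue-name synonyms for the ion species of interest.
.ION_SYNONYMS <- c(SCN = "SCN", THC = "SCN", GDM = "GDM", GAI = "GDM")

.is_hydrogen <- function(elety, elesy) {
  sy <- toupper(trimws(elesy))
  hy <- sy == "H"
  # fall back to the atom-name convention when the element column is absent
  miss <- is.na(sy) | sy == ""
  hy[miss] <- grepl("^[0-9]*H", trimws(elety[miss]))
  hy
}

#' Trajectory frames with protein and ion atoms
#'
#' Container for multi-model trajectory snapshots of one topology: an atom
#' table shared by all frames plus one coordinate row per frame (bio3d `xyz`
#' layout, `3 * n_atoms` columns). Atoms are classified on construction:
#' protein vs ion (by residue name through `ion_synonyms`), hydrogen vs
#' heavy, backbone vs side chain.
#'
#' @param atoms data.frame with columns `eleno`, `elety`, `resid`, `chain`,
#'   `resno`, `elesy` (element symbol).
#' @param xyz numeric matrix, one row per frame, `3 * nrow(atoms)` columns.
#' @param ion_synonyms named character vector mapping residue names to ion
#'   species labels; defaults cover thiocyanate (`SCN`, `THC`) and
#'   guanidinium (`GDM`, `GAI`).
#' @param temperature_K optional temperature label for the frame set.
#' @return a `trajectory_frames` object.
#' @seealso [read_frames()], [make_frame_set()]
#' @export
trajectory_frames <- function(atoms, xyz, ion_synonyms = .ION_SYNONYMS,
                              temperature_K = NA_real_) {
  need <- c("eleno", "elety", "resid", "chain", "resno", "elesy")
  stopifnot(is.data.frame(atoms), all(need %in% names(atoms)))
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  if (ncol(xyz) != 3L * nrow(atoms))
    stop("xyz must have 3 * n_atoms columns")
  if (any(!is.finite(xyz))) stop("coordinates must be finite")
  atoms$resid <- toupper(trimws(atoms$resid))
  atoms$elety <- trimws(atoms$elety)
  atoms$is_hydrogen <- .is_hydrogen(atoms$elety, atoms$elesy)
  atoms$is_protein <- atoms$resid %in% .AA3
  atoms$species <- ifelse(atoms$resid %in% names(ion_synonyms),
                          unname(ion_synonyms[atoms$resid]), NA_character_)
  atoms$is_ion <- !is.na(atoms$species)
  atoms$is_sidechain <- atoms$is_protein & !(atoms$elety %in% .BACKBONE) &
    !atoms$is_hydrogen
  atoms$ion_id <- ifelse(atoms$is_ion,
                         paste(atoms$resid, atoms$chain, atoms$resno,
                               sep = "_"), NA_character_)
  ions <- unique(atoms$ion_id[atoms$is_ion])
  scn_bad <- vapply(ions[grepl("^SCN|^THC", ions)], function(id) {
    ele <- sort(toupper(atoms$elesy[which(atoms$ion_id %in% id)]))
    !identical(ele, c("C", "N", "S"))
  }, logical(1))
  if (any(scn_bad))
    stop("thiocyanate ions must have exactly atoms {S, C, N}: ",
         paste(names(scn_bad)[scn_bad], collapse = ", "))
  structure(list(atoms = atoms, xyz = xyz, n_frames = nrow(xyz),
                 temperature_K = temperature_K),
            class = "trajectory_frames")
}

#' @export
print.trajectory_frames <- function(x, ...) {
  cat(sprintf("Trajectory: %d frame(s), %d protein atoms, %d ion(s) [%s]\n",
              x$n_frames, sum(x$atoms$is_protein),
              length(unique(stats::na.omit(x$atoms$ion_id))),
              paste(unique(stats::na.omit(x$atoms$species)), collapse = ", ")))
  invisible(x)
}

# Coordinates of frame i as an n_atoms x 3 matrix.
frame_coords <- function(frames, i) {
  matrix(frames$xyz[i, ], ncol = 3L, byrow = TRUE)
}

#' Read trajectory frames from a multi-model PDB file
#'
#' Parses a standard `MODEL`/`ENDMDL`-delimited PDB (via bio3d) into a
#' [trajectory_frames()] object; a file without `MODEL` records yields a
#' single frame. Ions are recognized by residue name. Coordinate records are
#' pre-validated so that a malformed `ATOM`/`HETATM` line is reported with
#' its line number.
#'
#' @param path PDB file path.
#' @inheritParams trajectory_frames
#' @return a [trajectory_frames()] object.
#' @export
read_frames <- function(path, ion_synonyms = .ION_SYNONYMS,
                        temperature_K = NA_real_) {
  lines <- readLines(path)
  rec <- grepl("^(ATOM  |HETATM)", lines)
  for (i in which(rec)) {
    ln <- lines[i]
    ok <- nchar(ln) >= 54 &&
      !anyNA(suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                           substr(ln, 39, 46),
                                           substr(ln, 47, 54)))))
    if (!ok)
      stop("malformed coordinate record at line ", i, ": ", ln)
  }
  if (!any(rec)) stop("no ATOM/HETATM records in ", path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(as.numeric(xyz), nrow = 1L)
  trajectory_frames(pdb$atom[, c("eleno", "elety", "resid", "chain",
                                 "resno", "elesy")],
                    unclass(xyz), ion_synonyms = ion_synonyms,
                    temperature_K = temperature_K)
}

#' Write trajectory frames to a multi-model PDB file
#'
#' @param frames a [trajectory_frames()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_frames <- function(frames, path) {
  stopifnot(inherits(frames, "trajectory_frames"))
  a <- frames$atoms
  bio3d::write.pdb(file = path, xyz = frames$xyz, eleno = a$eleno,
                   elety = a$elety, resid = a$resid, chain = a$chain,
                   resno = a$resno, elesy = a$elesy)
  invisible(path)
}
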