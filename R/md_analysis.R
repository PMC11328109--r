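# Cross squared-distance matrix between two n x 3 coordinate blocks.
.cross_dist2 <- function(A, B) {
  outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
}

# Per-ion minimum distance to protein heavy atoms for one frame.
# Returns a named vector (ion_id -> distance, Angstrom).
.ion_min_dist <- function(frames, i, species = NULL, ion_element = NULL) {
  a <- frames$atoms
  prot <- which(a$is_protein & !a$is_hydrogen)
  if (!length(prot)) stop("frame has no protein heavy atoms")
  sel <- a$is_ion & !a$is_hydrogen
  if (!is.null(species)) sel <- sel & a$species %in% species
  if (!is.null(ion_element))
    sel <- sel & toupper(a$elesy) %in% toupper(ion_element)
  ion <- which(sel)
  if (!length(ion)) return(setNames(numeric(0), character(0)))
  co <- frame_coords(frames, i)
  d2 <- .cross_dist2(co[ion, , drop = FALSE], co[prot, , drop = FALSE])
  dmin <- sqrt(pmax(apply(d2, 1L, min), 0))
  tapply(dmin, a$ion_id[ion], min)
}

#' Count ions inside the first solvation shell
#'
#' An ion is counted as inside the shell when any of its heavy atoms lies
#' within `cutoff` of any protein heavy atom; hydrogens are excluded on both
#' sides. The default 4 Angstrom cutoff corresponds to the conventional
#' first-shell definition.
#'
#' @param frames a [trajectory_frames()] object.
#' @param cutoff shell thickness, Angstrom (> 0).
#' @param species ion species label(s) to count (default `"SCN"`); `NULL`
#'   counts all ions.
#' @return integer vector of in-shell ion counts, one per frame.
#' @export
ions_in_shell <- function(frames, cutoff = 4.0, species = "SCN") {
  stopifnot(inherits(frames, "trajectory_frames"), cutoff > 0)
  vapply(seq_len(frames$n_frames), function(i) {
    d <- .ion_min_dist(frames, i, species = species)
    sum(d <= cutoff)
  }, integer(1))
}

#' Shell-occupancy statistics over frames
#'
#' Histogram of the per-frame in-shell ion count, expressed as the
#' percentage of frames showing each count, plus the arithmetic mean count.
#'
#' @inheritParams ions_in_shell
#' @return a `shell_occupancy` list: `counts` (per frame), `histogram`
#'   (data.frame `count`, `n_frames`, `percent`), `mean`.
#' @export
occupancy_series <- function(frames, cutoff = 4.0, species = "SCN") {
  counts <- ions_in_shell(frames, cutoff = cutoff, species = species)
  tab <- table(factor(counts, levels = seq(min(counts), max(counts))))
  hist <- data.frame(count = as.integer(names(tab)),
                     n_frames = as.integer(tab),
                     percent = 100 * as.integer(tab) / length(counts))
  structure(list(counts = counts, histogram = hist, mean = mean(counts)),
            class = "shell_occupancy")
}

#' @export
print.shell_occupancy <- function(x, ...) {
  cat(sprintf("Shell occupancy over %d frame(s): mean %.2f ions, range %d-%d\n",
              length(x$counts), x$mean, min(x$counts), max(x$counts)))
  invisible(x)
}

#' Residue classification for contact statistics
#'
#' The default grouping used for side-chain contact statistics: lysine and
#' arginine are positive; aspartate and glutamate negative; phenylalanine
#' and tyrosine aromatic; valine, isoleucine, leucine and alanine aliphatic.
#' Glycine and proline (and anything else) are unclassified and excluded
#' from per-class counts.
#'
#' @return named character vector, residue name -> class.
#' @export
residue_class_map <- function() {
  c(LYS = "positive", ARG = "positive",
    ASP = "negative", GLU = "negative",
    PHE = "aromatic", TYR = "aromatic",
    VAL = "aliphatic", ILE = "aliphatic", LEU = "aliphatic",
    ALA = "aliphatic",
    GLY = "unclassified", PRO = "unclassified")
}

.CONTACT_CLASSES <- c("positive", "negative", "aromatic", "aliphatic")

#' Side-chain-mediated ion contacts in one frame
#'
#' A contact is an (ion, residue) pair in which any heavy ion atom lies
#' within `cutoff` of any heavy side-chain atom of the residue; each pair is
#' counted once per frame regardless of how many atom pairs are within the
#' cutoff (`per_atom = TRUE` switches to counting atom pairs instead).
#' Contacts are aggregated by residue class; unclassified residues are
#' skipped.
#'
#' @param frames a [trajectory_frames()] object.
#' @param frame frame index.
#' @param map residue-class map (see [residue_class_map()]).
#' @param cutoff contact cutoff, Angstrom.
#' @param species ion species label(s); `NULL` for all ions.
#' @param per_atom count ion-atom/side-chain-atom pairs instead of
#'   (ion, residue) pairs.
#' @return named integer vector over classes positive, negative, aromatic,
#'   aliphatic.
#' @export
side_chain_contacts <- function(frames, frame = 1L, map = residue_class_map(),
                                cutoff = 4.0, species = "SCN",
                                per_atom = FALSE) {
  stopifnot(inherits(frames, "trajectory_frames"), cutoff > 0)
  a <- frames$atoms
  sel <- a$is_ion & !a$is_hydrogen
  if (!is.null(species)) sel <- sel & a$species %in% species
  ion <- which(sel)
  out <- setNames(integer(length(.CONTACT_CLASSES)), .CONTACT_CLASSES)
  if (!length(ion)) return(out)
  cls <- unname(map[a$resid])
  sc <- which(a$is_sidechain & !is.na(cls) & cls %in% .CONTACT_CLASSES)
  classified <- which(a$is_protein & !is.na(cls) & cls %in% .CONTACT_CLASSES)
  res_all <- unique(paste(a$chain[classified], a$resno[classified]))
  res_sc <- unique(paste(a$chain[sc], a$resno[sc]))
  if (length(setdiff(res_all, res_sc)))
    warning("classified residue(s) without side-chain heavy atoms skipped: ",
            paste(setdiff(res_all, res_sc), collapse = ", "))
  if (!length(sc)) return(out)
  co <- frame_coords(frames, frame)
  d2 <- .cross_dist2(co[ion, , drop = FALSE], co[sc, , drop = FALSE])
  hit <- which(d2 <= cutoff^2, arr.ind = TRUE)
  if (!nrow(hit)) return(out)
  ion_id <- a$ion_id[ion][hit[, 1L]]
  res_id <- paste(a$chain[sc], a$resno[sc])[hit[, 2L]]
  res_cls <- cls[sc][hit[, 2L]]
  if (!per_atom) {
    keep <- !duplicated(paste(ion_id, res_id))
    res_cls <- res_cls[keep]
  }
  tab <- table(factor(res_cls, levels = .CONTACT_CLASSES))
  out[] <- as.integer(tab)
  out
}

#' Per-class contact statistics over frames
#'
#' Minimum, maximum and mean per-frame side-chain contact counts for each
#' residue class, the summary conventionally reported per amino-acid group
#' over a simulation.
#'
#' @inheritParams side_chain_contacts
#' @return a `contact_stats` data.frame: `class`, `min`, `max`, `mean`.
#' @export
contact_stats <- function(frames, map = residue_class_map(), cutoff = 4.0,
                          species = "SCN", per_atom = FALSE) {
  stopifnot(frames$n_frames >= 1L)
  per_frame <- vapply(seq_len(frames$n_frames), function(i)
    side_chain_contacts(frames, i, map = map, cutoff = cutoff,
                        species = species, per_atom = per_atom),
    setNames(integer(length(.CONTACT_CLASSES)), .CONTACT_CLASSES))
  per_frame <- matrix(per_frame, nrow = length(.CONTACT_CLASSES),
                      dimnames = list(.CONTACT_CLASSES, NULL))
  out <- data.frame(class = .CONTACT_CLASSES,
                    min = apply(per_frame, 1L, min),
                    max = apply(per_frame, 1L, max),
                    mean = apply(per_frame, 1L, mean),
                    row.names = NULL)
  class(out) <- c("contact_stats", "data.frame")
  out
}

#' Minimum-distance distribution of an ion atom to the protein surface
#'
#' For every frame and every ion of the selected species, the minimum
#' distance from the selected ion atom (by element, e.g. the thiocyanate
#' nitrogen or sulfur) to any protein heavy atom, binned into a histogram.
#' Protein hydrogens are excluded.
#'
#' @param frames a [trajectory_frames()] object.
#' @param ion_atom element symbol of the ion atom to track (`"N"` or `"S"`
#'   for thiocyanate).
#' @param bin_width histogram bin width, Angstrom.
#' @param species ion species label (default `"SCN"`).
#' @param max_range distances beyond this are dropped (default `Inf`).
#' @return a `min_distance_distribution` list: `distances` (all per-ion
#'   per-frame minima), `histogram` (data.frame `bin_left_A`, `count`,
#'   `frequency`).
#' @export
min_distance_distribution <- function(frames, ion_atom = c("N", "S"),
                                      bin_width = 0.05, species = "SCN",
                                      max_range = Inf) {
  stopifnot(inherits(frames, "trajectory_frames"), bin_width > 0)
  ion_atom <- match.arg(toupper(ion_atom[1]), c("N", "S", "C"))
  a <- frames$atoms
  if (!any(a$is_ion & a$species %in% species))
    stop("no ions of species ", paste(species, collapse = "/"),
         " in the frames")
  d <- unlist(lapply(seq_len(frames$n_frames), function(i)
    .ion_min_dist(frames, i, species = species, ion_element = ion_atom)),
    use.names = FALSE)
  kept <- d[d <= max_range]
  if (!length(kept)) {
    warning("all distances exceed max_range; empty histogram")
    hist <- data.frame(bin_left_A = numeric(0), count = integer(0),
                       frequency = numeric(0))
  } else {
    edges <- seq(floor(min(kept) / bin_width) * bin_width,
                 max(kept) + bin_width, by = bin_width)
    b <- findInterval(kept, edges, rightmost.closed = TRUE)
    tab <- table(factor(b, levels = seq_len(length(edges) - 1L)))
    hist <- data.frame(bin_left_A = edges[-length(edges)],
                       count = as.integer(tab),
                       frequency = as.integer(tab) / length(kept))
  }
  structure(list(distances = d, histogram = hist, bin_width = bin_width,
                 ion_atom = ion_atom),
            class = "min_distance_distribution")
}

#' Write an occupancy or distance histogram as TSV
#'
#' Occupancy histograms are written as `count<TAB>percent`; distance
#' histograms as `bin_left_A<TAB>frequency`.
#'
#' @param x a `shell_occupancy` or `min_distance_distribution` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_histogram_tsv <- function(x, path) {
  if (inherits(x, "shell_occupancy")) {
    df <- x$histogram[, c("count", "percent")]
  } else if (inherits(x, "min_distance_distribution")) {
    df <- x$histogram[, c("bin_left_A", "frequency")]
  } else stop("unsupported histogram object")
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
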