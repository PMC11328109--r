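# Independent oracles used across the suite. These deliberately avoid the
# package's own closed forms: bisection on the mass-action balance, exhaustive
# all-pairs geometry, and finite differences.

R_KJ <- 8.314462618e-3

# Saturation fraction by bisection on the per-site mass-action balance
# theta/(1-theta) = Kb * (L0 - theta*n*P0).
oracle_bound_fraction <- function(L0, P0, n, kb, iters = 200L) {
  vapply(seq_along(L0), function(i) {
    l <- L0[i]
    if (l == 0) return(0)
    lo <- 0; hi <- 1
    for (j in seq_len(iters)) {
      mid <- (lo + hi) / 2
      h <- mid - kb * (l - mid * n * P0) * (1 - mid)
      if (h > 0) hi <- mid else lo <- mid
    }
    (lo + hi) / 2
  }, numeric(1))
}

# Exhaustive per-ion minimum distance to protein heavy atoms (double loop).
oracle_ion_min_dists <- function(frames, i, element = NULL) {
  a <- frames$atoms
  co <- matrix(frames$xyz[i, ], ncol = 3, byrow = TRUE)
  prot <- which(a$is_protein & !a$is_hydrogen)
  ids <- unique(stats::na.omit(a$ion_id))
  out <- setNames(numeric(length(ids)), ids)
  for (k in seq_along(ids)) {
    sel <- which(!is.na(a$ion_id) & a$ion_id == ids[k] & !a$is_hydrogen)
    if (!is.null(element))
      sel <- sel[toupper(a$elesy[sel]) == toupper(element)]
    dmin <- Inf
    for (x in sel) for (y in prot)
      dmin <- min(dmin, sqrt(sum((co[x, ] - co[y, ])^2)))
    out[k] <- dmin
  }
  out
}

# Exhaustive per-class side-chain contact counts for one frame.
oracle_contacts <- function(frames, i, cutoff = 4, per_atom = FALSE) {
  a <- frames$atoms
  co <- matrix(frames$xyz[i, ], ncol = 3, byrow = TRUE)
  map <- residue_class_map()
  classes <- c("positive", "negative", "aromatic", "aliphatic")
  out <- setNames(integer(4), classes)
  sc <- which(a$is_sidechain & a$resid %in% names(map) &
                map[a$resid] %in% classes)
  ions <- unique(stats::na.omit(a$ion_id))
  for (id in ions) {
    ii <- which(!is.na(a$ion_id) & a$ion_id == id & !a$is_hydrogen)
    seen <- character(0)
    for (x in ii) for (y in sc) {
      if (sqrt(sum((co[x, ] - co[y, ])^2)) <= cutoff) {
        cls <- unname(map[a$resid[y]])
        key <- paste(a$chain[y], a$resno[y])
        if (per_atom) {
          out[cls] <- out[cls] + 1L
        } else if (!(key %in% seen)) {
          out[cls] <- out[cls] + 1L
          seen <- c(seen, key)
        }
      }
    }
  }
  out
}

# DSC simulation grid used throughout: brackets the heat transition with
# margin proportional to the reduced transition width RTd^2/dHd, bounded
# below by the stability maximum (cold-denaturation side) when dCp > 0.
dsc_grid <- function(p, widths = 25, step = 0.1) {
  hw <- max(30, widths * R_KJ * p$td^2 / p$dhd)
  tlo <- p$td - hw
  if (p$dcp > 0) tlo <- max(tlo, p$td * exp(-p$dhd / (p$dcp * p$td)))
  seq(tlo, p$td + hw, by = step)
}
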