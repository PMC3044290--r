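## Geometric hydrogen-bond detection and per-bond presence time series.
##
## A bond is identified across the whole trajectory by its (donor,
## hydrogen, acceptor) serial triple; identity persists through ticks
## where the bond is geometrically absent, which is what makes the m/l
## stability labelling well defined.

.donor_acceptor_elements <- c("N", "O", "S")

#' Geometric detection criteria
#'
#' Defaults are the widely used cutoffs: hydrogen-acceptor distance at
#' most 2.5 Angstrom, donor-acceptor distance at most 3.5 Angstrom, and
#' donor-hydrogen-acceptor angle at least 90 degrees. All thresholds are
#' configurable so the downstream pipeline is criteria-agnostic.
#'
#' @param max_ha max hydrogen-acceptor distance (Angstrom).
#' @param max_da max donor-acceptor distance (Angstrom).
#' @param min_angle min donor-hydrogen-acceptor angle (degrees).
#' @return An object of class `hb_criteria`.
#' @export
detection_criteria <- function(max_ha = 2.5, max_da = 3.5, min_angle = 90) {
  stopifnot(max_ha > 0, max_da > 0, min_angle >= 0, min_angle <= 180)
  structure(list(max_ha = max_ha, max_da = max_da, min_angle = min_angle),
            class = "hb_criteria")
}

## Candidate donor-H pairs and acceptor atoms for a trajectory.
hb_candidates <- function(trajectory) {
  a <- trajectory$atoms
  topo <- trajectory$topology
  el <- toupper(a$element)
  h_idx <- which(!is.na(topo$h_donor))
  d_idx <- topo$h_donor[h_idx]
  keep <- el[d_idx] %in% .donor_acceptor_elements
  h_idx <- h_idx[keep]
  d_idx <- d_idx[keep]
  acc_idx <- which(el %in% .donor_acceptor_elements)
  list(h = h_idx, d = d_idx, acc = acc_idx)
}

#' Detect hydrogen bonds in one conformation
#'
#' A triple (D, H, A) is reported iff D is an N/O/S atom covalently bonded
#' to H, A is an N/O/S atom not covalently bonded to H and distinct from D,
#' and the three `criteria` thresholds hold.
#'
#' @param trajectory an `hb_trajectory` (supplies atoms and topology).
#' @param tick zero-based tick index of the conformation to scan.
#' @param criteria an `hb_criteria` object.
#' @return data.frame with columns `donor_serial`, `hydrogen_serial`,
#'   `acceptor_serial`, one row per detected bond.
#' @export
detect_hbonds <- function(trajectory, tick = 0,
                          criteria = detection_criteria()) {
  cand <- hb_candidates(trajectory)
  if (length(cand$h) == 0) {
    warning("conformation has no paired hydrogens; no bonds detectable")
    return(empty_bond_frame())
  }
  xyz <- trajectory$coords[, , tick + 1L]
  hits <- detect_pairs(xyz, cand, trajectory$topology, criteria)
  s <- trajectory$atoms$serial
  data.frame(donor_serial = s[hits$d], hydrogen_serial = s[hits$h],
             acceptor_serial = s[hits$a])
}

empty_bond_frame <- function() {
  data.frame(donor_serial = integer(0), hydrogen_serial = integer(0),
             acceptor_serial = integer(0))
}

## Core geometric test, on atom indices. Returns index triples.
detect_pairs <- function(xyz, cand, topo, criteria) {
  nh <- length(cand$h)
  na_ <- length(cand$acc)
  if (nh == 0 || na_ == 0)
    return(list(d = integer(0), h = integer(0), a = integer(0)))
  HA <- matrix(0, nh, na_)
  for (dim_ in 1:3)
    HA <- HA + outer(xyz[cand$h, dim_], xyz[cand$acc, dim_], "-")^2
  HA <- sqrt(HA)
  hit <- which(HA <= criteria$max_ha, arr.ind = TRUE)
  if (nrow(hit) == 0)
    return(list(d = integer(0), h = integer(0), a = integer(0)))
  hi <- cand$h[hit[, 1]]
  di <- cand$d[hit[, 1]]
  ai <- cand$acc[hit[, 2]]
  ## acceptor must be neither the donor nor covalently bonded to H
  cov_h <- mapply(function(h, a) a %in% topo$neighbors[[h]], hi, ai)
  keep <- ai != di & !cov_h
  hi <- hi[keep]; di <- di[keep]; ai <- ai[keep]
  if (length(hi) == 0)
    return(list(d = integer(0), h = integer(0), a = integer(0)))
  dda <- dist_mat(xyz[di, , drop = FALSE], xyz[ai, , drop = FALSE])
  ang <- angle3_mat(xyz[di, , drop = FALSE], xyz[hi, , drop = FALSE],
                    xyz[ai, , drop = FALSE])
  keep <- dda <= criteria$max_da & !is.na(ang) & ang >= criteria$min_angle
  list(d = di[keep], h = hi[keep], a = ai[keep])
}

#' Build the per-bond presence matrix over a trajectory
#'
#' The bond set is the union over all ticks of detected (D, H, A) triples;
#' `presence[b, i]` is `TRUE` iff bond `b` is detected at tick `i - 1`.
#'
#' @param trajectory an `hb_trajectory`.
#' @param criteria an `hb_criteria` object.
#' @return list of class `hb_presence` with `bonds` (data.frame of serial
#'   triples plus atom indices) and `presence` (logical `n_bonds x n_ticks`
#'   matrix).
#' @export
build_presence_matrix <- function(trajectory,
                                  criteria = detection_criteria()) {
  cand <- hb_candidates(trajectory)
  nt <- n_ticks(trajectory)
  per_tick <- vector("list", nt)
  for (k in seq_len(nt)) {
    hits <- detect_pairs(trajectory$coords[, , k], cand,
                         trajectory$topology, criteria)
    per_tick[[k]] <- hits
  }
  key <- unlist(lapply(per_tick, function(h)
    paste(h$d, h$h, h$a, sep = "_")))
  if (length(key) == 0) {
    bonds <- cbind(empty_bond_frame(),
                   data.frame(d_idx = integer(0), h_idx = integer(0),
                              a_idx = integer(0)))
    return(structure(list(bonds = bonds,
                          presence = matrix(FALSE, 0, nt)),
                     class = "hb_presence"))
  }
  ukey <- unique(key)
  parts <- do.call(rbind, lapply(strsplit(ukey, "_"), as.integer))
  s <- trajectory$atoms$serial
  bonds <- data.frame(donor_serial = s[parts[, 1]],
                      hydrogen_serial = s[parts[, 2]],
                      acceptor_serial = s[parts[, 3]],
                      d_idx = parts[, 1], h_idx = parts[, 2],
                      a_idx = parts[, 3])
  presence <- matrix(FALSE, nrow(bonds), nt)
  for (k in seq_len(nt)) {
    h <- per_tick[[k]]
    if (length(h$d) == 0) next
    kk <- paste(h$d, h$h, h$a, sep = "_")
    presence[match(kk, ukey), k] <- TRUE
  }
  structure(list(bonds = bonds, presence = presence), class = "hb_presence")
}

#' Export detected occurrences as a tidy table
#'
#' @param presence an `hb_presence` object.
#' @return data.frame with columns `tick`, `donor_serial`,
#'   `hydrogen_serial`, `acceptor_serial` (tick is zero-based).
#' @export
occurrences_table <- function(presence) {
  idx <- which(presence$presence, arr.ind = TRUE)
  b <- presence$bonds[idx[, 1], , drop = FALSE]
  out <- data.frame(tick = idx[, 2] - 1L,
                    donor_serial = b$donor_serial,
                    hydrogen_serial = b$hydrogen_serial,
                    acceptor_serial = b$acceptor_serial)
  out[order(out$tick, out$donor_serial, out$hydrogen_serial,
            out$acceptor_serial), , drop = FALSE]
}
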