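## Per-occurrence predictor computation.
##
## The registry names the implemented predictor set; models must work with
## any registered subset. Time-varying numerical predictors are computed
## at every tick (whether or not the bond is geometrically present at that
## tick) so that trailing-window averages are complete; only ticks where
## the bond is present become data rows.

#' Default predictor registry
#'
#' Columns: `name`, `kind` ("numerical" or "categorical"), `time_varying`.
#' Registry order also serves as the deterministic tie-break order during
#' tree construction.
#'
#' @param names optional character subset to keep (registry order retained).
#' @return data.frame of class `hb_registry`.
#' @export
default_registry <- function(names = NULL) {
  reg <- data.frame(
    name = c("Dist_H_A", "Dist_D_A", "Dist_H_D", "Dist_D_AA",
             "Angle_D_H_A", "Angle_H_A_AA", "FIRST_energy",
             "Num_hb_spaceNbr", "Num_hb_spaceRgdNbr",
             "Ch_type", "Resi_name_H", "Resi_name_A", "Range"),
    kind = c(rep("numerical", 9), "categorical", "categorical",
             "categorical", "numerical"),
    time_varying = c(rep(TRUE, 9), rep(FALSE, 4)),
    stringsAsFactors = FALSE)
  if (!is.null(names)) {
    missing <- setdiff(names, reg$name)
    if (length(missing) > 0)
      stop("unknown predictors: ", paste(missing, collapse = ", "))
    reg <- reg[reg$name %in% names, , drop = FALSE]
    rownames(reg) <- NULL
  }
  class(reg) <- c("hb_registry", "data.frame")
  reg
}

registries_compatible <- function(a, b) {
  identical(a$name, b$name) && identical(a$kind, b$kind)
}

#' Geometric predictors for one occurrence
#'
#' @param d,h,a,aa length-3 coordinates of donor, hydrogen, acceptor and
#'   acceptor antecedent (`aa` may be `NULL` when the acceptor has no
#'   covalent neighbour; AA-dependent predictors are then `NA`).
#' @return named list: `Dist_H_A`, `Dist_D_A`, `Dist_H_D`, `Dist_D_AA`,
#'   `Angle_D_H_A`, `Angle_H_A_AA` (Angstrom / degrees).
#' @export
compute_geometric <- function(d, h, a, aa = NULL) {
  out <- list(
    Dist_H_A = vec_len(a - h),
    Dist_D_A = vec_len(a - d),
    Dist_H_D = vec_len(h - d),
    Dist_D_AA = if (is.null(aa)) NA_real_ else vec_len(aa - d),
    Angle_D_H_A = angle3(d, h, a),
    Angle_H_A_AA = if (is.null(aa)) NA_real_ else angle3(h, a, aa))
  out
}

## ---- hybridization --------------------------------------------------------

## sp2/sp3 assignment for common protein donors/acceptors, keyed by atom
## name (with a residue-specific override table). Unknown atoms default to
## sp3 with a one-time warning.
.sp2_atom_names <- c(
  "N", "O", "OXT",                                  # backbone amide/carbonyl
  "OD1", "OD2", "ND2",                              # ASP / ASN
  "OE1", "OE2", "NE2", "NE1",                       # GLU / GLN / TRP
  "NE", "NH1", "NH2",                               # ARG
  "ND1",                                            # HIS (NE2 shared above)
  "OH")                                             # TYR (conjugated)
.sp3_atom_names <- c("OG", "OG1", "NZ", "SG", "SD", "OW")

#' Hybridization state of a donor or acceptor atom
#'
#' @param atom_name PDB atom name (e.g. "N", "OG1").
#' @param resname three-letter residue code (reserved for overrides).
#' @return "sp2" or "sp3".
#' @export
hybridization <- function(atom_name, resname = NULL) {
  nm <- toupper(atom_name)
  out <- rep(NA_character_, length(nm))
  out[nm %in% .sp2_atom_names] <- "sp2"
  out[nm %in% .sp3_atom_names] <- "sp3"
  if (anyNA(out)) {
    warning("unknown hybridization for atom(s) ",
            paste(unique(nm[is.na(out)]), collapse = ", "),
            "; defaulting to sp3")
    out[is.na(out)] <- "sp3"
  }
  out
}

#' Mayo-form hydrogen-bond energy
#'
#' E = V0 * (5 (R0/R)^12 - 6 (R0/R)^10) * F(theta, phi) with R the
#' donor-acceptor distance, V0 = 8 kcal/mol, R0 = 2.8 Angstrom, and the
#' angular factor F chosen by the donor/acceptor hybridization pair:
#' sp3-sp3 cos^2(theta) G cos^2(phi - 109.5deg); sp3-sp2
#' cos^2(theta) G cos^2(phi); sp2-sp3 cos^4(theta) G^2; sp2-sp2
#' cos^2(theta) G cos^2(max(phi, 90deg)) (in-plane convention), where
#' G = exp(-(pi - theta)^6). F is zero for theta below 90 degrees and the
#' result is clamped to be non-positive.
#'
#' @param r_da donor-acceptor distance R (Angstrom).
#' @param theta donor-hydrogen-acceptor angle (degrees).
#' @param phi hydrogen-acceptor-antecedent angle (degrees); may be `NA`
#'   when the acceptor has no antecedent (the energy is then `NA` unless
#'   the hybridization case ignores phi).
#' @param donor_hyb,acceptor_hyb "sp2" or "sp3" (vectorised).
#' @param v0 well depth (kcal/mol). @param r0 equilibrium distance (Angstrom).
#' @return Energy in kcal/mol, always <= 0.
#' @export
compute_first_energy <- function(r_da, theta, phi,
                                 donor_hyb = "sp3", acceptor_hyb = "sp3",
                                 v0 = 8, r0 = 2.8) {
  n <- max(length(r_da), length(theta), length(phi),
           length(donor_hyb), length(acceptor_hyb))
  r_da <- rep_len(r_da, n); theta <- rep_len(theta, n)
  phi <- rep_len(phi, n)
  donor_hyb <- rep_len(donor_hyb, n); acceptor_hyb <- rep_len(acceptor_hyb, n)
  th <- theta * pi / 180
  ph <- phi * pi / 180
  G <- exp(-(pi - th)^6)
  ct2 <- cos(th)^2
  Fv <- rep(NA_real_, n)
  case <- paste(donor_hyb, acceptor_hyb, sep = "-")
  i <- case == "sp3-sp3"
  Fv[i] <- ct2[i] * G[i] * cos(ph[i] - 109.5 * pi / 180)^2
  i <- case == "sp3-sp2"
  Fv[i] <- ct2[i] * G[i] * cos(ph[i])^2
  i <- case == "sp2-sp3"
  Fv[i] <- cos(th[i])^4 * exp(-2 * (pi - th[i])^6)
  i <- case == "sp2-sp2"
  Fv[i] <- ct2[i] * G[i] * cos(pmax(ph[i], pi / 2))^2
  Fv[!is.na(theta) & theta < 90] <- 0
  radial <- v0 * (5 * (r0 / r_da)^12 - 6 * (r0 / r_da)^10)
  pmin(radial * Fv, 0)
}

#' Environment counts for one tick
#'
#' For every bond, counts the other bonds detected at the tick whose
#' hydrogen-acceptor midpoint lies within `radius` of this bond's
#' midpoint. `Num_hb_spaceRgdNbr` restricts the neighbours to bonds with
#' instantaneous Mayo energy at most `energy_cut` (an energy-filtered
#' approximation of membership in a rigid cluster).
#'
#' @param midpoints `n_bonds x 3` matrix of H-A midpoints.
#' @param present logical vector: bond detected at this tick.
#' @param energies instantaneous per-bond energies (kcal/mol).
#' @param radius neighbourhood radius (Angstrom, default 5).
#' @param energy_cut rigid-neighbour energy threshold (default -1).
#' @return list with integer vectors `Num_hb_spaceNbr`, `Num_hb_spaceRgdNbr`.
#' @export
compute_environment <- function(midpoints, present, energies,
                                radius = 5, energy_cut = -1) {
  n <- nrow(midpoints)
  nbr <- integer(n)
  rgd <- integer(n)
  if (n > 1) {
    d <- as.matrix(stats::dist(midpoints))
    close <- d <= radius
    diag(close) <- FALSE
    ok <- present
    strong <- ok & !is.na(energies) & energies <= energy_cut
    nbr <- as.integer(close %*% ok)
    rgd <- as.integer(close %*% strong)
  }
  list(Num_hb_spaceNbr = nbr, Num_hb_spaceRgdNbr = rgd)
}

#' Static (time-invariant) predictors for one bond
#'
#' @param trajectory an `hb_trajectory`.
#' @param d_idx,a_idx atom indices of donor and acceptor.
#' @return list: `Ch_type` in MM/MS/SM/SS (donor chain class then acceptor
#'   chain class), `Range` = |resnum(A) - resnum(D)| with a +1000 offset
#'   when donor and acceptor sit on different chains, `Resi_name_H`,
#'   `Resi_name_A` residue codes of the donor- and acceptor-side residues.
#' @export
compute_static <- function(trajectory, d_idx, a_idx) {
  at <- trajectory$atoms
  cls <- function(i) ifelse(at$is_main_chain[i], "M", "S")
  range_ <- abs(at$resnum[a_idx] - at$resnum[d_idx]) +
    1000L * (at$chain[a_idx] != at$chain[d_idx])
  list(Ch_type = paste0(cls(d_idx), cls(a_idx)),
       Range = as.numeric(range_),
       Resi_name_H = at$resname[d_idx],
       Resi_name_A = at$resname[a_idx])
}

#' Trailing-window average of time-varying predictors
#'
#' The value stored for tick i is the mean of the last `min(i + 1,
#' l_prime)` raw values ending at tick i (trailing, so no future
#' information leaks into the predictors). Categorical and time-invariant
#' predictors pass through untouched.
#'
#' @param series numeric matrix `n_ticks x n_predictors` of raw values.
#' @param l_prime window length in ticks (default 50).
#' @return matrix of the same shape, averaged column-wise.
#' @export
average_time_varying <- function(series, l_prime = 50) {
  apply(series, 2, trailing_mean, w = l_prime)
}

## Acceptor antecedent: the acceptor's covalent heavy neighbour; if there
## are several, the one nearest the hydrogen (on the first conformation).
acceptor_antecedent <- function(trajectory, a_idx, h_idx) {
  topo <- trajectory$topology
  el <- toupper(trajectory$atoms$element)
  xyz <- trajectory$coords[, , 1]
  vapply(seq_along(a_idx), function(i) {
    nb <- topo$neighbors[[a_idx[i]]]
    nb <- nb[el[nb] != "H"]
    if (length(nb) == 0) return(NA_integer_)
    if (length(nb) == 1) return(nb)
    dd <- dist_mat(xyz[nb, , drop = FALSE],
                   matrix(xyz[h_idx[i], ], length(nb), 3, byrow = TRUE))
    nb[which.min(dd)]
  }, integer(1))
}

## Raw per-tick time-varying predictor series for every bond in a
## presence object. Returns a list of n_ticks x 9 matrices (one per bond)
## with columns in registry order, plus per-bond hybridizations.
compute_predictor_series <- function(trajectory, presence,
                                     radius = 5, energy_cut = -1) {
  bonds <- presence$bonds
  nb <- nrow(bonds)
  nt <- n_ticks(trajectory)
  at <- trajectory$atoms
  aa_idx <- acceptor_antecedent(trajectory, bonds$a_idx, bonds$h_idx)
  dh <- hybridization(at$name[bonds$d_idx], at$resname[bonds$d_idx])
  ah <- hybridization(at$name[bonds$a_idx], at$resname[bonds$a_idx])
  cols <- c("Dist_H_A", "Dist_D_A", "Dist_H_D", "Dist_D_AA",
            "Angle_D_H_A", "Angle_H_A_AA", "FIRST_energy",
            "Num_hb_spaceNbr", "Num_hb_spaceRgdNbr")
  series <- lapply(seq_len(nb), function(b)
    matrix(NA_real_, nt, length(cols), dimnames = list(NULL, cols)))
  if (nb == 0) return(list(series = series, aa_idx = aa_idx,
                           donor_hyb = dh, acceptor_hyb = ah))
  ## geometry + energy, vectorised across ticks per bond
  for (b in seq_len(nb)) {
    D <- t(trajectory$coords[bonds$d_idx[b], , ])
    H <- t(trajectory$coords[bonds$h_idx[b], , ])
    A <- t(trajectory$coords[bonds$a_idx[b], , ])
    m <- series[[b]]
    m[, "Dist_H_A"] <- dist_mat(H, A)
    m[, "Dist_D_A"] <- dist_mat(D, A)
    m[, "Dist_H_D"] <- dist_mat(H, D)
    m[, "Angle_D_H_A"] <- angle3_mat(D, H, A)
    if (!is.na(aa_idx[b])) {
      AA <- t(trajectory$coords[aa_idx[b], , ])
      m[, "Dist_D_AA"] <- dist_mat(D, AA)
      m[, "Angle_H_A_AA"] <- angle3_mat(H, A, AA)
    }
    m[, "FIRST_energy"] <- compute_first_energy(
      m[, "Dist_D_A"], m[, "Angle_D_H_A"], m[, "Angle_H_A_AA"],
      dh[b], ah[b])
    series[[b]] <- m
  }
  ## environment counts per tick (need all bonds at once)
  for (k in seq_len(nt)) {
    Hk <- trajectory$coords[bonds$h_idx, , k, drop = FALSE][, , 1, drop = FALSE]
    Ak <- trajectory$coords[bonds$a_idx, , k, drop = FALSE][, , 1, drop = FALSE]
    mid <- (matrix(Hk, nb, 3) + matrix(Ak, nb, 3)) / 2
    energies <- vapply(seq_len(nb), function(b)
      series[[b]][k, "FIRST_energy"], numeric(1))
    env <- compute_environment(mid, presence$presence[, k], energies,
                               radius = radius, energy_cut = energy_cut)
    for (b in seq_len(nb)) {
      series[[b]][k, "Num_hb_spaceNbr"] <- env$Num_hb_spaceNbr[b]
      series[[b]][k, "Num_hb_spaceRgdNbr"] <- env$Num_hb_spaceRgdNbr[b]
    }
  }
  list(series = series, aa_idx = aa_idx, donor_hyb = dh, acceptor_hyb = ah)
}
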