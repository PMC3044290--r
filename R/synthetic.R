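## Synthetic trajectories and tables with exact ground truth.
##
## Each synthetic bond is an isolated D-H...A-AA atom cluster (clusters
## > 20 Angstrom apart, so environment counts are exactly known). The
## hydrogen-acceptor distance follows a stationary AR(1) process around a
## bond-specific equilibrium; the donor-hydrogen-acceptor angle jitters
## within [155, 180] degrees and the acceptor-antecedent angle around a
## per-bond regime. The construction guarantees that, whenever
## dist(H, A) <= 2.5, the other default detection criteria hold too, so
## ground-truth presence is exactly dist(H, A) <= max_ha computed from
## the PDB-rounded coordinates.

#' Configuration for the synthetic trajectory generator
#'
#' Defaults emulate the stated test world: 20 bonds observed over 2000
#' ticks at 1 ps spacing, equilibrium H-A distances spanning both sides
#' of the 2.5 Angstrom detection cutoff, AR(1) thermal fluctuation with
#' 0.9 per-tick autocorrelation and 0.25 Angstrom stationary spread.
#'
#' @param n_bonds number of bonds/clusters.
#' @param n_ticks trajectory length (must exceed l + l').
#' @param seed integer seed.
#' @param mu per-bond equilibrium H-A distance (Angstrom); recycled.
#'   Default spans 2.0 .. 3.0.
#' @param s per-bond stationary fluctuation sd (Angstrom); recycled.
#' @param rho AR(1) per-tick autocorrelation in \[0, 1).
#' @param angle_noise sd (degrees) of the per-tick jitter of both angles
#'   around their per-bond equilibria.
#' @param theta_range range of per-bond equilibrium donor-hydrogen-acceptor
#'   angles (degrees); each bond draws its own equilibrium once, as real
#'   bonds differ in geometry independently of their distance equilibrium.
#' @param phi_range range of per-bond equilibrium acceptor-antecedent
#'   angles (degrees), drawn likewise (ignored under `secondary_driver`).
#' @param secondary_driver when `TRUE`, bonds alternate between two
#'   acceptor-antecedent angle regimes (about 150 vs about 95 degrees) and
#'   the low-angle regime gets its fluctuation sd multiplied by
#'   `driver_s_factor`, making true stability depend on a second
#'   predictor (Angle_H_A_AA) beyond Dist_H_A.
#' @param driver_s_factor fluctuation inflation of the low-angle regime.
#' @param spacing cluster spacing (Angstrom, > 20).
#' @param delta_ps tick spacing (ps).
#' @param protein_label trajectory label.
#' @param crowded place clusters `crowded_spacing` apart instead, giving
#'   known non-zero environment counts (for testing neighbour features).
#' @param crowded_spacing spacing used in crowded mode (Angstrom).
#' @return list of class `hb_syn_config`.
#' @export
synthetic_config <- function(n_bonds = 20, n_ticks = 2000, seed = 1,
                             mu = NULL, s = 0.25, rho = 0.9,
                             angle_noise = 8, theta_range = c(110, 168),
                             phi_range = c(100, 160),
                             secondary_driver = FALSE,
                             driver_s_factor = 2.5, spacing = 30,
                             delta_ps = 1, protein_label = "synthetic",
                             crowded = FALSE, crowded_spacing = 4) {
  if (is.null(mu)) mu <- seq(2.0, 3.0, length.out = n_bonds)
  mu <- rep_len(mu, n_bonds)
  s <- rep_len(s, n_bonds)
  if (!(all(mu >= 1.6) && all(mu <= 3.6)))
    stop("equilibrium distances must lie in [1.6, 3.6] Angstrom")
  if (rho < 0 || rho >= 1) stop("rho must be in [0, 1)")
  structure(list(n_bonds = n_bonds, n_ticks = n_ticks, seed = seed,
                 mu = mu, s = s, rho = rho, angle_noise = angle_noise,
                 theta_range = theta_range, phi_range = phi_range,
                 secondary_driver = secondary_driver,
                 driver_s_factor = driver_s_factor, spacing = spacing,
                 delta_ps = delta_ps, protein_label = protein_label,
                 crowded = crowded, crowded_spacing = crowded_spacing),
            class = "hb_syn_config")
}

## donor/acceptor chemistry variants cycled over bonds; covers all four
## Ch_type classes and both hybridization states.
.syn_chem <- data.frame(
  d_name = c("N", "OG", "N", "OG"),
  h_name = c("H", "HG", "H", "HG"),
  a_name = c("O", "O", "OG1", "OG1"),
  aa_name = c("C", "C", "CB", "CB"),
  d_res = c("ALA", "SER", "GLY", "SER"),
  a_res = c("LEU", "VAL", "THR", "THR"),
  stringsAsFactors = FALSE)

#' Generate a synthetic trajectory with known ground truth
#'
#' @param config an `hb_syn_config` (see [synthetic_config()]).
#' @return list of class `hb_synthetic`: `trajectory` (an
#'   `hb_trajectory` whose coordinates are pre-rounded to PDB precision),
#'   `bonds` (serial triples with generator parameters), `presence`
#'   (ground-truth logical matrix, computed from the rounded coordinates
#'   against the default 2.5 Angstrom cutoff), and `config`.
#' @export
generate_trajectory <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "hb_syn_config"))
  nb <- config$n_bonds
  nt <- config$n_ticks
  ## isolated mode spreads clusters along x (> 20 A apart); crowded mode
  ## stacks them along z at crowded_spacing, which keeps every
  ## cross-cluster atom pair exactly >= crowded_spacing apart (no spurious
  ## covalent bonds or detections) while adjacent cluster midpoints stay
  ## within the default 5 A environment radius.
  offset_of <- function(b) {
    if (config$crowded) c(0, 0, (b - 1) * config$crowded_spacing)
    else c((b - 1) * config$spacing, 0, 0)
  }
  s_eff <- config$s
  coords <- array(0, dim = c(4 * nb, 3, nt))
  atoms <- vector("list", nb)
  phi_mean <- theta_mean <- numeric(nb)
  with_seed(config$seed, {
    ## per-bond equilibrium angles: bonds differ in geometry independently
    ## of their distance equilibrium (this keeps angle-contaminated
    ## predictors from acting as clean distance proxies)
    theta_mean <- stats::runif(nb, config$theta_range[1],
                               config$theta_range[2])
    phi_mean <- stats::runif(nb, config$phi_range[1], config$phi_range[2])
    if (config$secondary_driver) {
      weak <- seq_len(nb) %% 2L == 0L
      phi_mean[weak] <- 95
      phi_mean[!weak] <- 150
      s_eff[weak] <- s_eff[weak] * config$driver_s_factor
    }
    for (b in seq_len(nb)) {
      off <- offset_of(b)
      ## AR(1) around mu with stationary sd s_eff
      eps <- stats::rnorm(nt, 0, s_eff[b] * sqrt(1 - config$rho^2))
      d <- numeric(nt)
      d[1] <- config$mu[b] + stats::rnorm(1, 0, s_eff[b])
      for (k in 2:nt)
        d[k] <- config$mu[b] + config$rho * (d[k - 1] - config$mu[b]) + eps[k]
      d <- pmin(pmax(d, 1.55), 3.8)
      ## theta clipped to [95, 174]: above 95 the angle criterion holds
      ## with margin, and below 174 dist(D, A) = sqrt(1 + d^2
      ## - 2 d cos(theta)) stays under 3.495 whenever d <= 2.5, so
      ## presence is exactly dist(H, A) <= 2.5 even after PDB rounding
      theta <- pmin(pmax(stats::rnorm(nt, theta_mean[b],
                                      config$angle_noise), 95), 174)
      phi <- pmin(pmax(stats::rnorm(nt, phi_mean[b],
                                    config$angle_noise), 92), 178)
      ## in-plane construction: D at origin, H 1.0 along +x, A in the
      ## xy-plane at angle theta from the H->D direction, AA 1.4 from A
      ## at angle phi from the A->H direction.
      H <- matrix(rep(c(1, 0, 0), each = nt), nt, 3)
      beta <- (180 - theta) * pi / 180
      A <- H + d * cbind(cos(beta), sin(beta), 0)
      psi <- atan2(H[, 2] - A[, 2], H[, 1] - A[, 1])
      AA <- A + 1.4 * cbind(cos(psi - phi * pi / 180),
                            sin(psi - phi * pi / 180), 0)
      base <- (b - 1L) * 4L
      coords[base + 1, , ] <- t(matrix(off, nt, 3, byrow = TRUE))     # D
      coords[base + 2, , ] <- t(sweep(H, 2, off, "+"))                # H
      coords[base + 3, , ] <- t(sweep(A, 2, off, "+"))                # A
      coords[base + 4, , ] <- t(sweep(AA, 2, off, "+"))               # AA
      chem <- .syn_chem[(b - 1) %% nrow(.syn_chem) + 1, ]
      rng <- (b - 1) %% 8L + 1L
      atoms[[b]] <- data.frame(
        serial = base + 1L:4L,
        name = c(chem$d_name, chem$h_name, chem$a_name, chem$aa_name),
        element = c(substr(chem$d_name, 1, 1), "H",
                    substr(chem$a_name, 1, 1), "C"),
        resname = c(chem$d_res, chem$d_res, chem$a_res, chem$a_res),
        resnum = as.integer(c(10 * b, 10 * b, 10 * b + rng, 10 * b + rng)),
        chain = "A",
        is_main_chain = c(chem$d_name, chem$h_name, chem$a_name,
                          chem$aa_name) %in% .main_chain_names,
        stringsAsFactors = FALSE)
    }
  })
  ## PDB precision: three decimals; ground truth is computed from the
  ## rounded coordinates so that file round trips are exactly consistent.
  coords <- round(coords, 3)
  atoms <- do.call(rbind, atoms)
  traj <- hb_trajectory(atoms, coords, delta_ps = config$delta_ps,
                        protein_label = config$protein_label)
  h_idx <- 4 * (seq_len(nb) - 1) + 2
  a_idx <- 4 * (seq_len(nb) - 1) + 3
  dHA <- sapply(seq_len(nb), function(b)
    sqrt(colSums((coords[h_idx[b], , ] - coords[a_idx[b], , ])^2)))
  presence <- t(dHA) <= detection_criteria()$max_ha
  bonds <- data.frame(donor_serial = atoms$serial[h_idx - 1],
                      hydrogen_serial = atoms$serial[h_idx],
                      acceptor_serial = atoms$serial[a_idx],
                      mu = config$mu, s = s_eff, phi_mean = phi_mean)
  structure(list(trajectory = traj, bonds = bonds, presence = presence,
                 config = config),
            class = "hb_synthetic")
}

#' Ground-truth stability labels of a synthetic trajectory
#'
#' Applies the m/l window count to the generator's own presence matrix.
#'
#' @param synthetic an `hb_synthetic`.
#' @param l prediction window (ticks).
#' @return data.frame `(donor_serial, hydrogen_serial, acceptor_serial,
#'   tick, y)` with one row per present occurrence having a full window.
#' @export
synthetic_truth <- function(synthetic, l = 50) {
  pres <- synthetic$presence
  nt <- ncol(pres)
  rows <- lapply(seq_len(nrow(pres)), function(b) {
    p <- pres[b, ]
    ticks0 <- which(p) - 1L
    ticks0 <- ticks0[ticks0 <= nt - 1L - l]
    if (length(ticks0) == 0) return(NULL)
    cp <- cumsum(as.numeric(p))
    data.frame(donor_serial = synthetic$bonds$donor_serial[b],
               hydrogen_serial = synthetic$bonds$hydrogen_serial[b],
               acceptor_serial = synthetic$bonds$acceptor_serial[b],
               tick = ticks0,
               y = (cp[ticks0 + 1L + l] - cp[ticks0 + 1L]) / l)
  })
  do.call(rbind, rows)
}

#' Write a synthetic trajectory plus its ground-truth CSV
#'
#' @param synthetic an `hb_synthetic`.
#' @param pdb_path,truth_path output paths.
#' @export
write_synthetic <- function(synthetic, pdb_path, truth_path) {
  write_trajectory(synthetic$trajectory, pdb_path)
  idx <- which(synthetic$presence, arr.ind = TRUE)
  b <- synthetic$bonds[idx[, 1], , drop = FALSE]
  truth <- data.frame(tick = idx[, 2] - 1L,
                      donor_serial = b$donor_serial,
                      hydrogen_serial = b$hydrogen_serial,
                      acceptor_serial = b$acceptor_serial)
  truth <- truth[order(truth$tick, truth$donor_serial), , drop = FALSE]
  utils::write.csv(truth, truth_path, row.names = FALSE)
  invisible(pdb_path)
}

## ---- tabular generator ----------------------------------------------------

#' A threshold rule node for the table generator
#'
#' Builds an explicit ground-truth rule mapping predictor vectors to mean
#' stability: `rule_leaf(value)` is a constant; `rule_node(p, thr, left,
#' right)` sends rows with `p < thr` left. Categorical rules use
#' `subset` instead of `thr`.
#'
#' @param predictor predictor name. @param threshold numeric threshold.
#' @param subset character category subset (categorical rules).
#' @param left,right sub-rules or numbers (treated as leaves).
#' @export
rule_node <- function(predictor, threshold = NULL, left, right,
                      subset = NULL) {
  if (is.numeric(left)) left <- rule_leaf(left)
  if (is.numeric(right)) right <- rule_leaf(right)
  structure(list(predictor = predictor, threshold = threshold,
                 subset = subset, left = left, right = right),
            class = "hb_rule")
}

#' @rdname rule_node
#' @param value constant mean stability in \[0, 1\].
#' @export
rule_leaf <- function(value) {
  structure(list(value = value), class = "hb_rule")
}

#' Evaluate a ground-truth rule on predictor columns
#' @param rule an `hb_rule`. @param df data.frame of predictor columns.
#' @return numeric vector of mean stabilities.
#' @export
rule_predict <- function(rule, df) {
  if (!is.null(rule$value)) return(rep(rule$value, nrow(df)))
  v <- df[[rule$predictor]]
  left <- if (!is.null(rule$threshold)) v < rule$threshold
          else as.character(v) %in% rule$subset
  out <- numeric(nrow(df))
  out[left] <- rule_predict(rule$left, df[left, , drop = FALSE])
  out[!left] <- rule_predict(rule$right, df[!left, , drop = FALSE])
  out
}

#' Generate an i.i.d. data table from an explicit stability rule
#'
#' Predictors are drawn independently from simple field-plausible ranges
#' (distances uniform over detection-relevant windows, angles uniform,
#' categories uniform over their tokens); y = rule(x) plus optional
#' Gaussian noise, clipped to \[0, 1\] and quantised to multiples of 1/l
#' (a measured stability is always a count ratio m/l).
#'
#' @param n_rows number of rows.
#' @param rule an `hb_rule` ground-truth rule.
#' @param noise_sd sd of the additive noise (0 = noiseless).
#' @param seed integer seed.
#' @param registry predictor registry (default full registry).
#' @param l quantisation denominator (default 50).
#' @return An `hb_table`; the rule is attached as attribute `truth_rule`
#'   and the noiseless means as attribute `truth_mean`.
#' @export
generate_table <- function(n_rows, rule, noise_sd = 0, seed = 1,
                           registry = default_registry(), l = 50) {
  df <- with_seed(seed, {
    out <- data.frame(row.names = seq_len(n_rows))
    for (ri in seq_len(nrow(registry))) {
      p <- registry$name[ri]
      out[[p]] <- switch(p,
        Dist_H_A = stats::runif(n_rows, 1.6, 3.2),
        Dist_D_A = stats::runif(n_rows, 2.5, 4.0),
        Dist_H_D = stats::runif(n_rows, 0.95, 1.05),
        Dist_D_AA = stats::runif(n_rows, 3.0, 5.0),
        Angle_D_H_A = stats::runif(n_rows, 120, 180),
        Angle_H_A_AA = stats::runif(n_rows, 90, 180),
        FIRST_energy = -stats::runif(n_rows, 0, 8),
        Num_hb_spaceNbr = stats::rpois(n_rows, 2),
        Num_hb_spaceRgdNbr = stats::rpois(n_rows, 1),
        Ch_type = sample(c("MM", "MS", "SM", "SS"), n_rows, TRUE),
        Resi_name_H = sample(c("ALA", "SER", "GLY", "THR"), n_rows, TRUE),
        Resi_name_A = sample(c("LEU", "VAL", "THR", "ASP"), n_rows, TRUE),
        Range = sample(1:30, n_rows, TRUE),
        stats::runif(n_rows))
    }
    truth <- rule_predict(rule, out)
    ynoisy <- truth + if (noise_sd > 0) stats::rnorm(n_rows, 0, noise_sd) else 0
    out$y <- round(pmin(pmax(ynoisy, 0), 1) * l) / l
    attr(out, "truth_mean") <- truth
    out
  })
  truth <- attr(df, "truth_mean")
  tab <- as_hb_table(df, registry = registry, l = l)
  attr(tab, "truth_rule") <- rule
  attr(tab, "truth_mean") <- truth
  tab
}
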