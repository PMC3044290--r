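## Shared fixtures and independent oracles for the test suite.
## Everything is built in code; no data files.

## A hand-built trajectory: `spec` is a data.frame with columns
## name, element, resname, resnum, chain and one x/y/z triple per tick in
## the list `frames` (each an n x 3 matrix).
make_traj <- function(spec, frames, delta_ps = 1, label = "fixture") {
  atoms <- data.frame(serial = seq_len(nrow(spec)),
                      name = spec$name, element = spec$element,
                      resname = spec$resname, resnum = spec$resnum,
                      chain = spec$chain,
                      is_main_chain = spec$name %in%
                        c("N", "CA", "C", "O", "OXT", "H", "HA"),
                      stringsAsFactors = FALSE)
  coords <- array(NA_real_, c(nrow(spec), 3, length(frames)))
  for (k in seq_along(frames)) coords[, , k] <- frames[[k]]
  hb_trajectory(atoms, coords, delta_ps = delta_ps, protein_label = label)
}

## Minimal one-bond system: backbone N-H donor and carbonyl O=C acceptor.
## d_ha: H-A distance; theta: D-H-A angle (deg); collinear in the xy-plane.
one_bond_frame <- function(d_ha = 1.9, theta = 170, phi = 150) {
  D <- c(0, 0, 0)
  H <- c(1, 0, 0)
  beta <- (180 - theta) * pi / 180
  A <- H + d_ha * c(cos(beta), sin(beta), 0)
  psi <- atan2(H[2] - A[2], H[1] - A[1])
  AA <- A + 1.4 * c(cos(psi - phi * pi / 180), sin(psi - phi * pi / 180), 0)
  rbind(D, H, A, AA)
}

one_bond_spec <- data.frame(
  name = c("N", "H", "O", "C"), element = c("N", "H", "O", "C"),
  resname = c("ALA", "ALA", "GLY", "GLY"), resnum = c(10L, 10L, 6L, 6L),
  chain = "A", stringsAsFactors = FALSE)

one_bond_traj <- function(d_ha = 1.9, theta = 170, phi = 150, n_ticks = 1) {
  fr <- one_bond_frame(d_ha, theta, phi)
  make_traj(one_bond_spec, rep(list(fr), n_ticks))
}

random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
           2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
           2 * (b * d - a * c), 2 * (c * d + a * b), a^2 - b^2 - c^2 + d^2),
         3, 3, byrow = TRUE)
}

rigid_transform_traj <- function(traj, R, t) {
  for (k in seq_len(dim(traj$coords)[3]))
    traj$coords[, , k] <- traj$coords[, , k] %*% t(R) +
      matrix(t, dim(traj$coords)[1], 3, byrow = TRUE)
  traj
}

## ---- independent split oracle --------------------------------------------

## Score of a candidate split by direct variance computation (the
## definitional formula, no cumulative-sum algebra).
oracle_score <- function(y, left) {
  nl <- sum(left)
  if (nl == 0 || nl == length(y)) return(NA_real_)
  pv <- function(v) mean((v - mean(v))^2)
  pv(y) - nl / length(y) * pv(y[left]) -
    (length(y) - nl) / length(y) * pv(y[!left])
}

## Exhaustive best split: every numerical midpoint (plus the NA-block
## boundary) and every proper bipartition of every categorical predictor.
oracle_best_split <- function(data, y, registry) {
  best <- NULL
  consider <- function(p, kind, left, threshold = NULL, subset = NULL) {
    sc <- oracle_score(y, left)
    if (is.na(sc) || sc <= 1e-12) return(invisible(NULL))
    if (is.null(best) || sc > best$score + 1e-12)
      best <<- list(predictor = p, kind = kind, score = sc,
                    threshold = threshold, subset = subset)
    invisible(NULL)
  }
  for (ri in seq_len(nrow(registry))) {
    p <- registry$name[ri]
    x <- data[[p]]
    if (registry$kind[ri] == "numerical") {
      ux <- sort(unique(x[!is.na(x)]))
      thr <- if (length(ux) >= 2) (ux[-1] + ux[-length(ux)]) / 2 else numeric(0)
      if (any(is.na(x)) && length(ux) >= 1) thr <- c(ux[1], thr)
      for (r in thr) consider(p, "numerical", is.na(x) | x < r, threshold = r)
    } else {
      xx <- as.character(x)
      xx[is.na(xx)] <- "NA"
      lev <- sort(unique(xx))
      k <- length(lev)
      if (k >= 2) {
        ## bipartitions counted once: subsets containing lev[1]
        for (mask in 0:(2^(k - 1) - 1)) {
          sub <- lev[c(TRUE, as.logical(bitwAnd(mask, 2^(seq_len(k - 1) - 1))))]
          if (length(sub) == k) next
          consider(p, "categorical", xx %in% sub, subset = sub)
        }
      }
    }
  }
  best
}

## Random small table for property tests: 2 numerical + 2 categorical
## predictors under a simple bespoke registry.
random_small_table <- function(n, seed) {
  reg <- data.frame(name = c("x1", "x2", "c1", "c2"),
                    kind = c("numerical", "numerical",
                             "categorical", "categorical"),
                    time_varying = FALSE, stringsAsFactors = FALSE)
  class(reg) <- c("hb_registry", "data.frame")
  set.seed(seed)
  df <- data.frame(
    x1 = round(stats::runif(n), 2),          # duplicates force tie handling
    x2 = stats::rnorm(n),
    c1 = sample(letters[1:4], n, TRUE),
    c2 = sample(c("P", "Q", "R", "S", "T"), n, TRUE),
    y = stats::runif(n), stringsAsFactors = FALSE)
  as_hb_table(df, registry = reg)
}

expect_no_mismatch <- function(a, b, tol = 1e-10, info = NULL) {
  testthat::expect_lt(max(abs(a - b)), tol)
}
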