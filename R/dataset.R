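## Stability labelling and data-table assembly.
##
## One data row = one occurrence of one bond at one tick: the predictor
## vector describes the occurrence (time-varying values averaged over the
## trailing l' ticks), the label y = m/l is the fraction of the next l
## ticks at which the bond is present. Rows without a full l-tick future
## window are dropped rather than labelled on a truncated window.

#' Measured stability of an occurrence
#'
#' y = m/l where m counts the ticks i+1, ..., i+l at which the bond is
#' present. Returns `NA` (a row-skip signal, not an error) when the series
#' is too short to hold the full future window.
#'
#' @param presence logical presence vector (index 1 = tick 0).
#' @param i zero-based tick of the occurrence.
#' @param l prediction window in ticks (default 50; l * delta is the
#'   prediction horizon).
#' @return m/l in \[0, 1\], or `NA_real_`.
#' @export
measured_stability <- function(presence, i, l = 50) {
  if (i + l + 1L > length(presence)) return(NA_real_)
  mean(presence[(i + 2L):(i + 1L + l)])
}

#' Build a stability data table from a trajectory
#'
#' Detects bonds at every tick, computes and averages predictors, and
#' emits one labelled row per (bond, tick) at which the bond is present
#' and a full l-tick future window exists.
#'
#' @param trajectory an `hb_trajectory`.
#' @param criteria detection criteria ([detection_criteria()]).
#' @param registry predictor registry ([default_registry()]).
#' @param l prediction window (ticks, default 50).
#' @param l_prime thermal-noise averaging window (ticks, default 50).
#' @param radius environment neighbourhood radius (Angstrom, default 5).
#' @param presence optional precomputed `hb_presence` for `trajectory`.
#' @return An `hb_table`: a data.frame with key columns (`protein_label`,
#'   `tick`, serial triple), one column per registered predictor, and `y`;
#'   attributes `registry`, `l`, `l_prime`, `delta_ps`.
#' @export
build_table <- function(trajectory, criteria = detection_criteria(),
                        registry = default_registry(), l = 50, l_prime = 50,
                        radius = 5, presence = NULL) {
  nt <- n_ticks(trajectory)
  if (nt <= l + 1) {
    warning("trajectory shorter than l + 2 ticks; empty table")
    return(new_hb_table(NULL, registry, l, l_prime, trajectory$delta_ps))
  }
  if (is.null(presence)) presence <- build_presence_matrix(trajectory, criteria)
  bonds <- presence$bonds
  nb <- nrow(bonds)
  if (nb == 0)
    return(new_hb_table(NULL, registry, l, l_prime, trajectory$delta_ps))
  ps <- compute_predictor_series(trajectory, presence, radius = radius)
  tv_names <- registry$name[registry$time_varying]
  rows <- vector("list", nb)
  last_tick <- nt - 1L - l          # zero-based; need full future window
  for (b in seq_len(nb)) {
    pres <- presence$presence[b, ]
    ticks0 <- which(pres) - 1L
    ticks0 <- ticks0[ticks0 <= last_tick]
    if (length(ticks0) == 0) next
    avg <- average_time_varying(ps$series[[b]], l_prime)
    ## y via cumulative presence sums: m = #present in (i+1 .. i+l)
    cp <- cumsum(as.numeric(pres))
    y <- (cp[ticks0 + 1L + l] - cp[ticks0 + 1L]) / l
    static <- compute_static(trajectory, bonds$d_idx[b], bonds$a_idx[b])
    df <- data.frame(protein_label = trajectory$protein_label,
                     tick = ticks0,
                     donor_serial = bonds$donor_serial[b],
                     hydrogen_serial = bonds$hydrogen_serial[b],
                     acceptor_serial = bonds$acceptor_serial[b],
                     stringsAsFactors = FALSE)
    for (p in registry$name) {
      df[[p]] <- if (p %in% tv_names) avg[ticks0 + 1L, p]
                 else if (p %in% colnames(avg)) avg[ticks0 + 1L, p]
                 else rep(static[[p]], length(ticks0))
    }
    df$y <- y
    rows[[b]] <- df
  }
  out <- do.call(rbind, rows)
  new_hb_table(out, registry, l, l_prime, trajectory$delta_ps)
}

new_hb_table <- function(df, registry, l, l_prime, delta_ps) {
  if (is.null(df))
    df <- data.frame(protein_label = character(0), tick = integer(0),
                     donor_serial = integer(0), hydrogen_serial = integer(0),
                     acceptor_serial = integer(0), y = numeric(0))
  rownames(df) <- NULL
  structure(df, registry = registry, l = l, l_prime = l_prime,
            delta_ps = delta_ps, class = c("hb_table", "data.frame"))
}

#' @export
print.hb_table <- function(x, ...) {
  reg <- attr(x, "registry")
  cat(sprintf("<hb_table: %d rows, %d predictors, l = %d, l' = %d>\n",
              nrow(x), nrow(reg), attr(x, "l"), attr(x, "l_prime")))
  invisible(x)
}

## Construct an hb_table directly from a predictor data.frame + y
## (pure-ML workflows without structures).
#' Assemble a data table from in-memory predictor columns
#'
#' @param df data.frame holding one column per registered predictor plus `y`.
#' @param registry predictor registry describing the columns.
#' @param l,l_prime,delta_ps window metadata carried along.
#' @return An `hb_table`.
#' @export
as_hb_table <- function(df, registry = default_registry(),
                        l = 50, l_prime = 50, delta_ps = 1) {
  miss <- setdiff(c(registry$name, "y"), names(df))
  if (length(miss) > 0)
    stop("missing columns: ", paste(miss, collapse = ", "))
  if (is.null(df$protein_label))
    df$protein_label <- rep("table", nrow(df))
  if (is.null(df$tick)) df$tick <- seq_len(nrow(df)) - 1L
  for (k in c("donor_serial", "hydrogen_serial", "acceptor_serial"))
    if (is.null(df[[k]])) df[[k]] <- seq_len(nrow(df))
  new_hb_table(as.data.frame(df), registry, l, l_prime, delta_ps)
}

bond_key <- function(table) {
  paste(table$protein_label, table$donor_serial, table$hydrogen_serial,
        table$acceptor_serial, sep = "|")
}

#' Mix rows from several data tables
#'
#' Draws, from each table independently, a uniform random sample without
#' replacement of `ceiling(fraction * n_j)` rows and concatenates the
#' samples (stratified by table, as in the multi-trajectory training
#' protocol).
#'
#' @param tables list of `hb_table`s sharing one registry.
#' @param fraction fraction of each table to take, in (0, 1].
#' @param seed integer seed; the same seed reproduces the same mixture.
#' @return An `hb_table`.
#' @export
mix_tables <- function(tables, fraction = 0.1, seed = 1) {
  stopifnot(length(tables) >= 1, fraction > 0, fraction <= 1)
  reg <- attr(tables[[1]], "registry")
  for (t in tables[-1])
    if (!registries_compatible(reg, attr(t, "registry")))
      stop("tables have incompatible predictor registries")
  seeds <- derive_seeds(seed, length(tables))
  picked <- lapply(seq_along(tables), function(j) {
    tj <- tables[[j]]
    n <- nrow(tj)
    k <- min(n, ceiling(fraction * n))
    idx <- with_seed(seeds[j], sample.int(n, k))
    as.data.frame(tj)[sort(idx), , drop = FALSE]
  })
  new_hb_table(do.call(rbind, picked), reg, attr(tables[[1]], "l"),
               attr(tables[[1]], "l_prime"), attr(tables[[1]], "delta_ps"))
}

#' Split a table into training and validation parts by bond identity
#'
#' All rows of one bond land on the same side, preventing near-duplicate
#' leakage between training and validation. The validation side is the
#' prefix of a shuffled bond list whose row count is closest to
#' `validation_fraction` of the table.
#'
#' @param table an `hb_table` with at least two distinct bonds.
#' @param validation_fraction target fraction of rows, in (0, 1).
#' @param seed integer seed.
#' @return list with `train` and `validation` `hb_table`s.
#' @export
split_validation <- function(table, validation_fraction = 0.25, seed = 1) {
  stopifnot(validation_fraction > 0, validation_fraction < 1)
  key <- bond_key(table)
  bonds <- unique(key)
  if (length(bonds) < 2)
    stop("cannot partition a table with a single bond by bond identity")
  ord <- with_seed(seed, sample(bonds))
  counts <- as.numeric(table(key)[ord])
  target <- validation_fraction * nrow(table)
  cum <- cumsum(counts)
  ## prefix sizes 1 .. k-1; closest cumulative row count to target
  cand <- seq_len(length(bonds) - 1L)
  kbest <- cand[which.min(abs(cum[cand] - target))]
  val_bonds <- ord[seq_len(kbest)]
  in_val <- key %in% val_bonds
  reg <- attr(table, "registry")
  mk <- function(df) new_hb_table(df, reg, attr(table, "l"),
                                  attr(table, "l_prime"),
                                  attr(table, "delta_ps"))
  list(train = mk(as.data.frame(table)[!in_val, , drop = FALSE]),
       validation = mk(as.data.frame(table)[in_val, , drop = FALSE]))
}

#' Write / read a data table as CSV with a JSON sidecar
#'
#' The sidecar (`<path>.json`) stores the registry and the l, l', delta
#' metadata so a table round-trips without the structures.
#'
#' @param table an `hb_table`. @param path CSV file path.
#' @return `path` (write) or an `hb_table` (read).
#' @export
write_table_csv <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  meta <- list(registry = as.data.frame(attr(table, "registry")),
               l = attr(table, "l"), l_prime = attr(table, "l_prime"),
               delta_ps = attr(table, "delta_ps"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_table_csv
#' @export
read_table_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  reg <- as.data.frame(meta$registry)
  class(reg) <- c("hb_registry", "data.frame")
  miss <- setdiff(reg$name, names(df))
  if (length(miss) > 0)
    stop("table at ", path, " is missing registry column(s): ",
         paste(miss, collapse = ", "))
  new_hb_table(df, reg, meta$l, meta$l_prime, meta$delta_ps)
}
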