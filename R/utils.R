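#' @keywords internal
"_PACKAGE"

## Small numeric helpers shared across modules. All distances are in
## Angstrom, all angles in degrees, all times in picoseconds.

vec_len <- function(v) sqrt(sum(v^2))

#' Angle at the middle point of a three-point chain
#'
#' Returns the angle p1-p2-p3 in degrees, i.e. the angle between the
#' vectors p2->p1 and p2->p3. Degenerate (zero-length) arms yield `NA`
#' with a warning.
#'
#' @param p1,p2,p3 numeric length-3 coordinate vectors (Angstrom).
#' @return Angle in degrees in \[0, 180\], or `NA_real_`.
#' @export
angle3 <- function(p1, p2, p3) {
  u <- p1 - p2
  v <- p3 - p2
  nu <- vec_len(u)
  nv <- vec_len(v)
  if (nu == 0 || nv == 0) {
    warning("degenerate zero-length vector in angle computation")
    return(NA_real_)
  }
  ct <- sum(u * v) / (nu * nv)
  ct <- min(1, max(-1, ct))
  acos(ct) * 180 / pi
}

## Vectorised angle over aligned coordinate matrices (n x 3).
angle3_mat <- function(P1, P2, P3) {
  U <- P1 - P2
  V <- P3 - P2
  nu <- sqrt(rowSums(U^2))
  nv <- sqrt(rowSums(V^2))
  ct <- rowSums(U * V) / (nu * nv)
  ct[nu == 0 | nv == 0] <- NA_real_
  ct <- pmin(1, pmax(-1, ct))
  acos(ct) * 180 / pi
}

dist_mat <- function(P1, P2) sqrt(rowSums((P1 - P2)^2))

## Trailing-window mean: value at position i is the mean of the last
## min(i, w) entries ending at i. NAs are skipped; an all-NA window is NA.
trailing_mean <- function(x, w) {
  n <- length(x)
  if (w <= 1L || n == 0L) return(x)
  ok <- !is.na(x)
  xz <- ifelse(ok, x, 0)
  cs <- cumsum(xz)
  ck <- cumsum(as.numeric(ok))
  lag_s <- c(rep(0, min(w, n)), cs[seq_len(max(0L, n - w))])
  lag_k <- c(rep(0, min(w, n)), ck[seq_len(max(0L, n - w))])
  num <- cs - lag_s
  den <- ck - lag_k
  out <- num / den
  out[den == 0] <- NA_real_
  out
}

## Run code under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

## Derive a stream of sub-seeds from one master seed (kept below 2^31).
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

## FNV-1a hash of a character scalar, as 8 hex digits. Used to stamp
## artifacts with the configuration that produced them (no external
## digest dependency).
fnv1a_hash <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2147483648) , b) + (h >= 2147483648) * 2147483648
    ## 32-bit modular multiply by the FNV prime 16777619 = 2^24 + 403,
    ## done in pieces so every intermediate stays exactly representable.
    h <- (h * 403 + (h %% 256) * 16777216) %% 4294967296
  }
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}
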