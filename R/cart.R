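## Binary regression trees with variance-reduction splits and adaptive
## validation-set pruning.
##
## Split score: w = Var(y) - (nL/n) Var(yL) - (nR/n) Var(yR) with
## population variances, i.e. the per-sample SSE reduction. This makes
## the importance measure sum_s w(s) * n(s) equal to the SSE reduction
## contributed by each node.
##
## Conventions (all deterministic):
##   - numerical split: value < threshold goes left; missing values carry
##     a sentinel that always goes left;
##   - categorical split: value in subset goes left; missing values form
##     category "NA"; categories unseen at training time go right;
##   - ties in score are broken by registry order, then smaller threshold
##     (numerical) / smaller subset (categorical);
##   - pruning collapses the intermediate node of minimal growth-time
##     score, deepest first on ties.

.score_tol <- 1e-12

#' Variance-reduction score of a split
#'
#' @param y numeric response values at the node.
#' @param left_mask logical vector: TRUE for rows sent to the left child.
#' @return w = Var(y) - (nL/n) Var(yL) - (nR/n) Var(yR) (population
#'   variances), or `NA` if either side is empty.
#' @export
split_score <- function(y, left_mask) {
  n <- length(y)
  nl <- sum(left_mask)
  if (nl == 0L || nl == n) return(NA_real_)
  pvar <- function(v) mean((v - mean(v))^2)
  pvar(y) - (nl / n) * pvar(y[left_mask]) - ((n - nl) / n) * pvar(y[!left_mask])
}

## Best numerical split for one predictor via a sorted cumulative scan.
## Missing values sort first (always left). Returns list(threshold, score)
## or NULL.
best_numeric_split <- function(x, y) {
  n <- length(y)
  key <- ifelse(is.na(x), -Inf, x)
  ord <- order(key)
  ks <- key[ord]
  ys <- y[ord]
  cs <- cumsum(ys)
  cq <- cumsum(ys^2)
  S <- cs[n]; Q <- cq[n]
  cuts <- which(ks[-n] < ks[-1])      # boundary after position k
  if (length(cuts) == 0) return(NULL)
  nl <- cuts
  sse_l <- cq[cuts] - cs[cuts]^2 / nl
  sse_r <- (Q - cq[cuts]) - (S - cs[cuts])^2 / (n - nl)
  sse_tot <- Q - S^2 / n
  sc <- (sse_tot - sse_l - sse_r) / n
  best <- which.max(sc)               # first max = smaller threshold on ties
  k <- cuts[best]
  lo <- ks[k]; hi <- ks[k + 1]
  thr <- if (is.finite(lo)) (lo + hi) / 2 else hi  # NA-block boundary
  list(threshold = thr, score = sc[best])
}

## Best categorical split for one predictor via the mean-sorted prefix
## scan (optimal for least-squares binary splits). Returns
## list(subset, score) or NULL; the subset is the left side and always
## contains the category of smallest mean y.
best_categorical_split <- function(x, y) {
  x <- as.character(x)
  x[is.na(x)] <- "NA"
  lev <- sort(unique(x))
  k <- length(lev)
  if (k < 2) return(NULL)
  grp <- match(x, lev)
  n_c <- tabulate(grp, k)
  s_c <- vapply(seq_len(k), function(g) sum(y[grp == g]), numeric(1))
  m_c <- s_c / n_c
  ord <- order(m_c, lev)              # alphabetical tie-break for determinism
  n <- length(y)
  S <- sum(y); Q <- sum(y^2)
  cn <- cumsum(n_c[ord])
  cs <- cumsum(s_c[ord])
  j <- seq_len(k - 1)
  sse_tot <- Q - S^2 / n
  ## SSE within sides needs sums of squares per side; use the identity
  ## score = (S_L^2/n_L + S_R^2/n_R - S^2/n) / n  (Q terms cancel).
  sc <- (cs[j]^2 / cn[j] + (S - cs[j])^2 / (n - cn[j]) - S^2 / n) / n
  best <- which(sc >= max(sc))[1]     # smallest prefix on ties
  list(subset = sort(lev[ord[seq_len(best)]]), score = sc[best])
}

#' Best split over all registered predictors
#'
#' Numerical candidates are midpoints between consecutive distinct sorted
#' values; categorical candidates are prefix subsets of the categories
#' sorted by mean response (optimal for least squares). Ties in score are
#' broken by registry order, then smaller threshold / smaller subset.
#'
#' @param data data.frame view holding the registered predictor columns.
#' @param y numeric response.
#' @param registry predictor registry ([default_registry()]).
#' @return list of class `hb_split` (`predictor`, `kind`, `threshold` or
#'   `subset`, `score`), or `NULL` when no split has positive score.
#' @export
best_split <- function(data, y, registry) {
  best <- NULL
  for (ri in seq_len(nrow(registry))) {
    p <- registry$name[ri]
    if (is.null(data[[p]])) next
    cand <- if (registry$kind[ri] == "numerical")
      best_numeric_split(data[[p]], y)
    else
      best_categorical_split(data[[p]], y)
    if (is.null(cand) || !is.finite(cand$score)) next
    if (is.null(best) || cand$score > best$score + .score_tol) {
      best <- c(list(predictor = p, kind = registry$kind[ri]), cand)
    }
  }
  if (is.null(best) || best$score <= .score_tol) return(NULL)
  structure(best, class = "hb_split")
}

split_goes_left <- function(split, values) {
  if (split$kind == "numerical") {
    v <- values
    is.na(v) | v < split$threshold
  } else {
    v <- as.character(values)
    v[is.na(v)] <- "NA"
    v %in% split$subset
  }
}

#' Grow a regression tree
#'
#' Recursive top-down growth. A node becomes a leaf when the depth limit
#' is reached, fewer than `min_node_size` training rows fall into it, or
#' no split has positive score. The value stored at a leaf is the mean
#' measured stability of the training rows falling into it.
#'
#' @param table an `hb_table` (or data.frame with predictor columns and `y`).
#' @param registry predictor registry; defaults to the table's.
#' @param max_depth depth limit, root at depth 0 (default 5).
#' @param min_node_size a node with fewer rows becomes a leaf (default 10).
#' @return An object of class `hb_tree`.
#' @export
grow_tree <- function(table, registry = NULL, max_depth = 5,
                      min_node_size = 10) {
  if (is.null(registry)) registry <- attr(table, "registry")
  stopifnot(!is.null(registry))
  df <- as.data.frame(table)
  if (nrow(df) == 0) stop("cannot grow a tree from an empty table")
  y <- df$y
  counter <- new.env()
  counter$id <- 0L
  grow_node <- function(idx, depth) {
    counter$id <- counter$id + 1L
    node <- list(id = counter$id, depth = depth, n = length(idx),
                 mean = mean(y[idx]))
    if (depth < max_depth && length(idx) >= min_node_size) {
      sp <- best_split(df[idx, , drop = FALSE], y[idx], registry)
      if (!is.null(sp)) {
        left <- split_goes_left(sp, df[[sp$predictor]][idx])
        if (any(left) && any(!left)) {
          node$split <- sp
          node$left <- grow_node(idx[left], depth + 1L)
          node$right <- grow_node(idx[!left], depth + 1L)
        }
      }
    }
    node
  }
  root <- grow_node(seq_along(y), 0L)
  structure(list(root = root, max_depth = max_depth,
                 min_node_size = min_node_size, registry = registry,
                 n_train = nrow(df)),
            class = "hb_tree")
}

#' @export
print.hb_tree <- function(x, ...) {
  cat(sprintf("<hb_tree: %d nodes (%d leaves), trained on %d rows>\n",
              n_nodes(x), n_leaves(x), x$n_train))
  invisible(x)
}

walk_nodes <- function(node, fn) {
  fn(node)
  if (!is.null(node$split)) {
    walk_nodes(node$left, fn)
    walk_nodes(node$right, fn)
  }
  invisible(NULL)
}

#' Node and leaf counts of a tree
#' @param tree an `hb_tree`.
#' @export
n_nodes <- function(tree) {
  n <- 0L
  walk_nodes(tree$root, function(nd) n <<- n + 1L)
  n
}

#' @rdname n_nodes
#' @export
n_leaves <- function(tree) {
  n <- 0L
  walk_nodes(tree$root, function(nd) if (is.null(nd$split)) n <<- n + 1L)
  n
}

#' Predict stability for new occurrences
#'
#' Deterministic root-to-leaf descent: numerical splits send missing
#' values left; categorical splits send unseen categories right.
#'
#' @param object an `hb_tree`.
#' @param newdata data.frame of predictor columns (an `hb_table` works).
#' @param ... unused.
#' @return numeric vector of predicted stabilities in \[0, 1\].
#' @export
predict.hb_tree <- function(object, newdata, ...) {
  df <- as.data.frame(newdata)
  out <- numeric(nrow(df))
  descend <- function(node, idx) {
    if (length(idx) == 0) return(invisible(NULL))
    if (is.null(node$split)) {
      out[idx] <<- node$mean
      return(invisible(NULL))
    }
    if (is.null(df[[node$split$predictor]]))
      stop("newdata lacks predictor column: ", node$split$predictor)
    vals <- df[[node$split$predictor]][idx]
    left <- split_goes_left(node$split, vals)
    descend(node$left, idx[left])
    descend(node$right, idx[!left])
  }
  descend(object$root, seq_len(nrow(df)))
  out
}

## Collect intermediate nodes: data.frame(id, depth, score, predictor).
intermediate_nodes <- function(tree) {
  ids <- integer(0); depths <- integer(0); scores <- numeric(0)
  preds <- character(0)
  walk_nodes(tree$root, function(nd) {
    if (!is.null(nd$split)) {
      ids <<- c(ids, nd$id); depths <<- c(depths, nd$depth)
      scores <<- c(scores, nd$split$score)
      preds <<- c(preds, nd$split$predictor)
    }
  })
  data.frame(id = ids, depth = depths, score = scores, predictor = preds,
             stringsAsFactors = FALSE)
}

collapse_node <- function(node, target_id) {
  if (node$id == target_id) {
    node$split <- NULL
    node$left <- NULL
    node$right <- NULL
    return(node)
  }
  if (!is.null(node$split)) {
    node$left <- collapse_node(node$left, target_id)
    node$right <- collapse_node(node$right, target_id)
  }
  node
}

#' Prune a tree against a validation table
#'
#' Generates the full sequence of trees from the grown tree down to a
#' single leaf by repeatedly collapsing the intermediate node whose
#' growth-time split score is minimal (ties: deepest node first, then
#' registry order of the split predictor, then node id), then returns the
#' sequence member with the smallest validation mean square error (ties:
#' fewest nodes).
#'
#' @param tree an `hb_tree`.
#' @param validation a nonempty `hb_table`.
#' @return The selected (possibly unpruned) `hb_tree`.
#' @export
prune_tree <- function(tree, validation) {
  df <- as.data.frame(validation)
  if (nrow(df) == 0) stop("validation table is empty")
  reg_rank <- function(p) match(p, tree$registry$name)
  seqs <- list(tree)
  cur <- tree
  repeat {
    im <- intermediate_nodes(cur)
    if (nrow(im) == 0) break
    ord <- order(im$score, -im$depth, reg_rank(im$predictor), im$id)
    pick <- im$id[ord[1]]
    cur$root <- collapse_node(cur$root, pick)
    seqs[[length(seqs) + 1L]] <- cur
  }
  mse <- vapply(seqs, function(t)
    mean((predict(t, df) - df$y)^2), numeric(1))
  sizes <- vapply(seqs, n_nodes, integer(1))
  best <- order(mse, sizes)[1]
  seqs[[best]]
}

## ---- serialization --------------------------------------------------------

node_to_list <- function(node) {
  out <- list(id = node$id, depth = node$depth, n_fall = node$n,
              mean = node$mean)
  if (!is.null(node$split)) {
    s <- node$split
    out$split <- list(predictor = s$predictor, kind = s$kind, score = s$score)
    if (s$kind == "numerical") out$split$threshold <- s$threshold
    else out$split$subset <- as.list(s$subset)
    out$left <- node_to_list(node$left)
    out$right <- node_to_list(node$right)
  }
  out
}

node_from_list <- function(lst) {
  node <- list(id = lst$id, depth = lst$depth, n = lst$n_fall,
               mean = lst$mean)
  if (!is.null(lst$split)) {
    sp <- list(predictor = lst$split$predictor, kind = lst$split$kind,
               score = lst$split$score)
    if (sp$kind == "numerical") sp$threshold <- lst$split$threshold
    else sp$subset <- unlist(lst$split$subset)
    node$split <- structure(sp, class = "hb_split")
    node$left <- node_from_list(lst$left)
    node$right <- node_from_list(lst$right)
  }
  node
}

#' Write / read a tree as JSON
#'
#' The file stores the node structure (predictor, threshold or category
#' subset, score, n_fall, leaf means) plus the registry and training
#' provenance, so models round-trip exactly.
#'
#' @param tree an `hb_tree`. @param path JSON file path.
#' @param meta optional named list of provenance fields (seed, config hash,
#'   ...) embedded verbatim.
#' @return `path` (write) or an `hb_tree` (read).
#' @export
write_tree <- function(tree, path, meta = list()) {
  obj <- list(format = "hbstab-tree-1",
              registry = as.data.frame(tree$registry),
              max_depth = tree$max_depth,
              min_node_size = tree$min_node_size,
              n_train = tree$n_train,
              meta = meta,
              root = node_to_list(tree$root))
  ## digits = I(17): doubles round-trip exactly (17 significant digits)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_tree
#' @export
read_tree <- function(path) {
  obj <- jsonlite::read_json(path)
  reg <- data.frame(
    name = vapply(obj$registry, `[[`, "", "name"),
    kind = vapply(obj$registry, `[[`, "", "kind"),
    time_varying = vapply(obj$registry, `[[`, TRUE, "time_varying"),
    stringsAsFactors = FALSE)
  class(reg) <- c("hb_registry", "data.frame")
  structure(list(root = node_from_list(obj$root),
                 max_depth = obj$max_depth,
                 min_node_size = obj$min_node_size,
                 registry = reg, n_train = obj$n_train,
                 meta = obj$meta),
            class = "hb_tree")
}
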