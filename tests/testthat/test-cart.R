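test_that("split_score matches hand computation and the SSE identity", {
  ## y = (0,0,1,1) split perfectly: Var = 0.25 goes to 0
  expect_equal(split_score(c(0, 0, 1, 1), c(TRUE, TRUE, FALSE, FALSE)), 0.25)
  ## constant response: zero for every mask
  expect_equal(split_score(rep(0.7, 6), c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)), 0)
  ## empty side: undefined
  expect_true(is.na(split_score(c(0, 1), c(TRUE, TRUE))))
  ## random y, random masks: equals SSE-reduction / n
  set.seed(2)
  for (i in 1:20) {
    n <- sample(5:60, 1)
    y <- stats::runif(n)
    mask <- stats::runif(n) < 0.5
    if (!any(mask) || all(mask)) next
    sse <- function(v) sum((v - mean(v))^2)
    oracle <- (sse(y) - sse(y[mask]) - sse(y[!mask])) / n
    expect_lt(abs(split_score(y, mask) - oracle), 1e-12)
  }
})

test_that("best_split finds the textbook numerical threshold", {
  reg <- default_registry("Dist_H_A")
  df <- data.frame(Dist_H_A = c(1, 2, 3, 4))
  sp <- best_split(df, c(0, 0, 1, 1), reg)
  expect_equal(sp$predictor, "Dist_H_A")
  expect_equal(sp$threshold, 2.5)
  expect_equal(sp$score, 0.25)
  ## constant y: no split
  expect_null(best_split(df, rep(0.4, 4), reg))
  ## all predictors constant: no split
  expect_null(best_split(data.frame(Dist_H_A = rep(1, 4)), c(0, 0, 1, 1), reg))
})

test_that("best_split agrees with exhaustive enumeration (property)", {
  for (trial in 1:100) {
    tab <- random_small_table(n = sample(20:200, 1), seed = 1000 + trial)
    reg <- attr(tab, "registry")
    got <- best_split(as.data.frame(tab), tab$y, reg)
    want <- oracle_best_split(as.data.frame(tab), tab$y, reg)
    expect_equal(is.null(got), is.null(want))
    if (!is.null(got)) {
      expect_lt(abs(got$score - want$score), 1e-10)
      ## same partition on unique optima (sides may be labelled either way)
      if (got$predictor == want$predictor && got$kind == "categorical") {
        lev <- sort(unique(as.character(tab[[got$predictor]])))
        canon <- function(s) if (lev[1] %in% s) sort(s)
                             else sort(setdiff(lev, s))
        expect_equal(canon(got$subset), canon(want$subset))
      }
    }
  }
})

test_that("categorical subsets match brute force on a 3-level predictor", {
  reg <- structure(data.frame(name = "c1", kind = "categorical",
                              time_varying = FALSE),
                   class = c("hb_registry", "data.frame"))
  set.seed(8)
  for (i in 1:20) {
    df <- data.frame(c1 = sample(c("a", "b", "c"), 30, TRUE),
                     stringsAsFactors = FALSE)
    y <- stats::runif(30)
    got <- best_split(df, y, reg)
    want <- oracle_best_split(df, y, reg)
    expect_equal(got$score, want$score, tolerance = 1e-10)
    ## identical bipartition (canonicalised to the side holding "a" or
    ## its complement)
    canon <- function(s) if ("a" %in% s) sort(s)
                         else sort(setdiff(c("a", "b", "c"), s))
    expect_equal(canon(got$subset), canon(want$subset))
  }
})

test_that("grow_tree handles degenerate inputs per contract", {
  reg <- default_registry(c("Dist_H_A", "Range"))
  df <- data.frame(Dist_H_A = stats::runif(30), Range = 1:30,
                   y = rep(0.6, 30))
  tab <- as_hb_table(df, reg)
  tree <- grow_tree(tab)
  expect_null(tree$root$split)
  expect_equal(predict(tree, df), rep(0.6, 30))
  ## max_depth 0: single leaf at the global mean
  df2 <- df; df2$y <- stats::runif(30)
  tree2 <- grow_tree(as_hb_table(df2, reg), max_depth = 0)
  expect_equal(predict(tree2, df2), rep(mean(df2$y), 30))
  ## empty table: hard error
  expect_error(grow_tree(as_hb_table(df[0, ], reg)), "empty")
})

test_that("grow_tree recovers a noiseless depth-2 generative rule", {
  rule <- rule_node("Dist_H_A", 2.4,
                    rule_node("Angle_H_A_AA", 120, 0.75, 0.95),
                    rule_node("Angle_H_A_AA", 140, 0.20, 0.45))
  tab <- generate_table(10000, rule, noise_sd = 0, seed = 77)
  tree <- grow_tree(tab, max_depth = 5, min_node_size = 10)
  root <- tree$root
  expect_equal(root$split$predictor, "Dist_H_A")
  ## threshold within one inter-point gap of the true 2.4
  x <- sort(tab$Dist_H_A)
  gap <- max(diff(x))
  expect_lt(abs(root$split$threshold - 2.4), gap + 1e-9)
  expect_equal(root$left$split$predictor, "Angle_H_A_AA")
  expect_lt(abs(root$left$split$threshold - 120), 1)
  expect_equal(root$right$split$predictor, "Angle_H_A_AA")
  expect_lt(abs(root$right$split$threshold - 140), 1)
  ## leaves reproduce the rule means exactly (y quantised to 1/50)
  preds <- predict(tree, tab)
  expect_lt(max(abs(preds - tab$y)), 0.011)
})

test_that("node means conserve mass and respect size bounds", {
  syn <- generate_trajectory(synthetic_config(n_bonds = 10, n_ticks = 400,
                                              seed = 19))
  tab <- build_table(syn$trajectory)
  tree <- grow_tree(tab, max_depth = 5, min_node_size = 10)
  walk <- function(node) {
    if (is.null(node$split)) return(invisible(NULL))
    expect_equal(node$n, node$left$n + node$right$n)
    expect_equal(node$mean,
                 (node$left$n * node$left$mean +
                    node$right$n * node$right$mean) / node$n,
                 tolerance = 1e-12)
    expect_gte(node$n, 10)            # intermediate nodes respect the bound
    expect_lte(node$depth, 4)
    walk(node$left); walk(node$right)
  }
  walk(tree$root)
  ## training MSE non-increasing in max_depth
  mse <- vapply(0:5, function(d)
    mean((predict(grow_tree(tab, max_depth = d), tab) - tab$y)^2),
    numeric(1))
  expect_true(all(diff(mse) <= 1e-12))
})

test_that("pruning returns the full tree on noiseless self-validation and a
           single leaf on unrelated validation", {
  rule <- rule_node("Dist_H_A", 2.4, 0.92, 0.38)
  tab <- generate_table(2000, rule, noise_sd = 0, seed = 5)
  tree <- grow_tree(tab)
  pruned <- prune_tree(tree, tab)
  ## zero validation error at (a tree predicting like) the full tree:
  ## equal-MSE ties collapse to the smallest such tree, which still
  ## predicts identically
  expect_equal(predict(pruned, tab), predict(tree, tab))
  ## validation y independent of predictors: single leaf wins (10 seeds)
  for (s in 1:10) {
    tr <- generate_table(600, rule, noise_sd = 0.05, seed = 100 + s)
    noise <- generate_table(600, rule_leaf(0.5), noise_sd = 0.3,
                            seed = 200 + s)
    full <- grow_tree(tr, max_depth = 4)
    pr <- prune_tree(full, noise)
    expect_null(pr$root$split)
  }
})

test_that("the pruning sequence shrinks monotonically to one node", {
  syn <- generate_trajectory(synthetic_config(n_bonds = 8, n_ticks = 300,
                                              seed = 23))
  tab <- build_table(syn$trajectory)
  tree <- grow_tree(tab)
  ## replicate the collapse loop and check strict node-count decrease
  sizes <- n_nodes(tree)
  cur <- tree
  repeat {
    im <- hbstab:::intermediate_nodes(cur)
    if (nrow(im) == 0) break
    ord <- order(im$score, -im$depth, im$id)
    cur$root <- hbstab:::collapse_node(cur$root, im$id[ord[1]])
    sizes <- c(sizes, n_nodes(cur))
  }
  expect_true(all(diff(sizes) < 0))
  expect_equal(sizes[length(sizes)], 1)
})

test_that("prediction routes missing values left and unknown categories right", {
  reg <- structure(data.frame(name = c("x", "c"),
                              kind = c("numerical", "categorical"),
                              time_varying = FALSE),
                   class = c("hb_registry", "data.frame"))
  df <- data.frame(x = c(rep(1, 10), rep(3, 10)),
                   c = rep(c("a", "b"), 10),
                   y = c(rep(0.2, 10), rep(0.8, 10)),
                   stringsAsFactors = FALSE)
  tree <- grow_tree(as_hb_table(df, reg), min_node_size = 2)
  expect_equal(tree$root$split$predictor, "x")
  expect_equal(predict(tree, data.frame(x = NA_real_, c = "a")), 0.2)
  ## categorical split: build a tree where y is driven by c, then feed a
  ## category unseen at training time (routes right)
  df2 <- data.frame(x = 1, c = rep(c("a", "b"), 10),
                    y = rep(c(0.1, 0.9), 10), stringsAsFactors = FALSE)
  tree2 <- grow_tree(as_hb_table(df2, reg), min_node_size = 2)
  expect_equal(tree2$root$split$predictor, "c")
  expect_equal(tree2$root$split$subset, "a")
  expect_equal(predict(tree2, data.frame(x = 1, c = "zzz")),
               tree2$root$right$mean)
  ## training rows re-predicted equal their leaf means exactly
  expect_equal(predict(tree, df), df$y)
})

test_that("serialization round-trips predictions bit for bit", {
  syn <- generate_trajectory(synthetic_config(n_bonds = 8, n_ticks = 300,
                                              seed = 29))
  tab <- build_table(syn$trajectory)
  tree <- grow_tree(tab)
  f <- withr::local_tempfile(fileext = ".json")
  write_tree(tree, f, meta = list(seed = 29))
  back <- read_tree(f)
  expect_identical(predict(back, tab), predict(tree, tab))
  expect_equal(back$meta$seed, 29)
  expect_equal(n_nodes(back), n_nodes(tree))
})
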