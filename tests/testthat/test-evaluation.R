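## Four-row fixture used for the closed-form metric checks.
four_row_fixture <- function() {
  reg <- default_registry(c("Dist_H_A", "FIRST_energy"))
  as_hb_table(data.frame(Dist_H_A = c(1.8, 2.0, 2.6, 3.0),
                         FIRST_energy = c(-6, -5, -1, -0.5),
                         y = c(1.0, 0.9, 0.3, 0.0)), reg)
}

test_that("rmse matches hand arithmetic and a loop oracle", {
  tab <- four_row_fixture()
  expect_equal(rmse(tab$y, tab), 0)                        # perfect
  half <- as_hb_table(data.frame(Dist_H_A = c(2, 2), FIRST_energy = c(-1, -1),
                                 y = c(0, 1)),
                      default_registry(c("Dist_H_A", "FIRST_energy")))
  expect_equal(rmse(rep(0.5, 2), half), 0.5)               # constant model
  set.seed(4)
  for (i in 1:10) {
    n <- sample(3:40, 1)
    t2 <- as_hb_table(data.frame(Dist_H_A = stats::runif(n),
                                 FIRST_energy = -stats::runif(n),
                                 y = stats::runif(n)),
                      default_registry(c("Dist_H_A", "FIRST_energy")))
    pred <- stats::runif(n)
    acc <- 0
    for (j in seq_len(n)) acc <- acc + (pred[j] - t2$y[j])^2
    expect_equal(rmse(pred, t2), sqrt(acc / n), tolerance = 1e-12)
  }
  expect_error(rmse(numeric(0), four_row_fixture()[0, ]), "empty")
})

test_that("rbed follows its percent formula and sign conventions", {
  tab <- four_row_fixture()
  base <- base_model("global_mean", tab)
  expect_equal(rbed(base, base, tab), 0)                   # model = base
  ## forced arithmetic: RMSE 0.3 vs base 0.4 -> 25%
  y <- tab$y
  model_pred <- y + c(0.3, -0.3, 0.3, -0.3)
  base_pred <- y + c(0.4, -0.4, 0.4, -0.4)
  expect_equal(100 * (rmse(base_pred, tab) - rmse(model_pred, tab)) /
                 rmse(base_pred, tab), 25)
  expect_equal(rbed(model_pred, base_pred, tab), 25)
  ## a model worse than base: negative
  expect_lt(rbed(base_pred, model_pred, tab), 0)
  ## zero-RMSE base: undefined signal
  expect_error(rbed(model_pred, y, tab), "zero RMSE")
})

test_that("identification curve matches its definition on the fixture", {
  tab <- four_row_fixture()
  ## fraction 0.25: S = the single least stable row (y = 0)
  curve <- identification_curve(tab$y, tab, fraction = 0.25,
                                grid = c(0, 0.25, 0.5, 0.75, 1))
  expect_equal(curve$w_model, c(0, 1, 1, 1, 1))            # ideal ranking
  expect_equal(curve$w_ideal, curve$w_model)
  ## a model ranking the least stable row last finds it only at u = 1
  bad <- c(0.1, 0.2, 0.3, 0.9)                             # row 4 ranked last
  curve2 <- identification_curve(bad, tab, fraction = 0.25,
                                 grid = c(0, 0.25, 0.5, 0.75, 1))
  expect_equal(curve2$w_model, c(0, 0, 0, 0, 1))
  expect_error(identification_curve(tab$y, tab, fraction = 1.2), "fraction")
})

test_that("identification curves are monotone, anchored, and dominated by
           the ideal curve", {
  set.seed(11)
  syn <- generate_trajectory(synthetic_config(n_bonds = 12, n_ticks = 400,
                                              seed = 41))
  tab <- build_table(syn$trajectory)
  parts <- split_validation(tab, 0.3, seed = 1)
  tree <- grow_tree(parts$train)
  curve <- identification_curve(tree, parts$validation,
                                base_scores = -parts$validation$FIRST_energy)
  expect_equal(curve$w_model[1], 0)
  expect_equal(curve$w_model[nrow(curve)], 1)
  expect_true(all(diff(curve$w_model) >= 0))
  expect_true(all(diff(curve$w_ideal) >= 0))
  ## tie tolerance: ideal curve may share plateaus with the model curve
  expect_true(all(curve$w_model <= curve$w_ideal + 1e-9))
  expect_true(all(curve$w_base <= curve$w_ideal + 1e-9))
})

test_that("a random-ranking model hugs the diagonal in expectation", {
  set.seed(99)
  n <- 400
  reg <- default_registry("Dist_H_A")
  tab <- as_hb_table(data.frame(Dist_H_A = stats::runif(n),
                                y = stats::runif(n)), reg)
  grid <- seq(0, 1, by = 0.1)
  acc <- numeric(length(grid))
  for (i in 1:200) {
    curve <- identification_curve(sample(n), tab, grid = grid)
    acc <- acc + curve$w_model
  }
  expect_lt(max(abs(acc / 200 - grid)), 0.02)
})

test_that("predictor importance equals the node-walk sum w(s) * n(s)", {
  rule <- rule_node("Dist_H_A", 2.4,
                    rule_node("Angle_H_A_AA", 120, 0.70, 0.95), 0.30)
  tab <- generate_table(4000, rule, noise_sd = 0, seed = 13)
  tree <- grow_tree(tab, max_depth = 2)
  ## hand-walk the (at most 3) intermediate nodes
  acc <- c()
  walk <- function(nd) {
    if (is.null(nd$split)) return(invisible(NULL))
    acc[nd$split$predictor] <<- sum(acc[nd$split$predictor],
                                    nd$split$score * nd$n, na.rm = TRUE)
    walk(nd$left); walk(nd$right)
  }
  walk(tree$root)
  raw <- predictor_importance(tree, scale = FALSE)
  for (p in names(acc)) expect_equal(raw[[p]], acc[[p]], tolerance = 1e-12)
  ## unused predictors have zero importance and are excluded from scaling
  expect_true(all(raw[setdiff(names(raw), names(acc))] == 0))
  scaled <- predictor_importance(tree, scale = TRUE)
  used <- scaled[scaled > 0]
  expect_equal(min(used), 1)
  ## single-split tree: only predictor scales to exactly 1
  tree1 <- grow_tree(tab, max_depth = 1)
  imp1 <- predictor_importance(tree1, scale = TRUE)
  expect_equal(sum(imp1 > 0), 1)
  expect_equal(unname(imp1[imp1 > 0]), 1)
  ## all-leaf trees: empty map
  tree0 <- grow_tree(tab, max_depth = 0)
  expect_length(predictor_importance(tree0), 0)
})

test_that("leave-one-protein-out is deterministic and exchangeable", {
  rule <- rule_node("Dist_H_A", 2.4, 0.9,
                    rule_node("Angle_H_A_AA", 130, 0.25, 0.55))
  tabs <- lapply(1:3, function(s)
    generate_table(1200, rule, noise_sd = 0.08, seed = 300 + s))
  rep1 <- leave_one_protein_out(tabs, fraction = 0.5, n_models = 3, seed = 7)
  rep2 <- leave_one_protein_out(tabs, fraction = 0.5, n_models = 3, seed = 7)
  expect_identical(as.data.frame(rep1), as.data.frame(rep2))
  expect_equal(dim(as.data.frame(rep1)), c(3, 3))
  expect_equal(dim(attr(rep1, "rbed")), c(3, 3))
  ## i.i.d. tables from one rule: held-out RBED close to within-table RBED
  held <- rep1$mean_rbed
  self_parts <- split_validation(tabs[[1]], 0.25, seed = 1)
  self_tree <- prune_tree(grow_tree(self_parts$train), self_parts$validation)
  self_rbed <- rbed(self_tree, base_model("global_mean", self_parts$train),
                    tabs[[1]])
  expect_true(all(abs(held - self_rbed) < 5))
})
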