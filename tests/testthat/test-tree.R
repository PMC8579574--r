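test_that("a perfectly separable variable yields a depth-1 tree at the midpoint", {
  coh <- tibble::tibble(
    mcv = c(60, 61, 62, 63, 64, 71, 72, 73, 74, 75),
    label = rep(c("BTT", "IDA"), each = 5)
  )
  tr <- fit_greedy_tree(coh, predictors = "mcv", min_leaf = 2)
  info <- tidy(tr)
  expect_equal(sum(info$type == "split"), 1)
  expect_equal(info$threshold[info$type == "split"], (64 + 71) / 2)
  expect_equal(predict(tr, coh), coh$label)
})

test_that("a pure node is returned as a single leaf", {
  coh <- tibble::tibble(mcv = 1:10, label = "BTT")
  expect_error(fit_greedy_tree(coh), "two classes")
  # identical class mix on both sides of the only candidate split: no
  # impurity decrease is possible, so the root stays a leaf
  coh2 <- tibble::tibble(mcv = c(1, 1, 2, 2), label = c("BTT", "IDA", "BTT", "IDA"))
  tr <- fit_greedy_tree(coh2, predictors = "mcv", min_leaf = 1)
  expect_equal(glance(tr)$n_leaves, 1)
})

test_that("depth-2 trees solve a (slightly unbalanced) XOR layout", {
  # four point clusters at the corners of the unit square; opposite corners
  # share a class, and unequal cluster sizes give the midline splits a
  # strictly positive Gini decrease. Brute force over all axis-aligned
  # depth-2 trees certifies that perfect training accuracy is attainable,
  # then the greedy fitter must reach it.
  centers <- list(c(0, 0), c(1, 1), c(0, 1), c(1, 0))
  sizes <- c(12, 4, 4, 12)
  labels <- c("BTT", "BTT", "IDA", "IDA")
  pts <- purrr::map2(centers, seq_along(centers), function(ct, i) {
    tibble::tibble(x = rep(ct[1], sizes[i]), y = rep(ct[2], sizes[i]),
                   label = labels[i])
  }) |> dplyr::bind_rows()

  # oracle: enumerate root thresholds on x or y and, for each child, the
  # best single split; record the best achievable depth-2 accuracy
  acc_of <- function(pred) mean(pred == pts$label)
  best_child <- function(sub) {
    best <- max(table(sub$label)) / nrow(sub)
    for (f in c("x", "y")) {
      v <- sort(unique(sub[[f]]))
      for (t in (head(v, -1) + tail(v, -1)) / 2) {
        left <- sub[[f]] <= t
        acc <- (max(table(sub$label[left])) + max(table(sub$label[!left]))) / nrow(sub)
        best <- max(best, acc)
      }
    }
    best
  }
  brute_best <- 0
  for (f in c("x", "y")) {
    v <- sort(unique(pts[[f]]))
    for (t in (head(v, -1) + tail(v, -1)) / 2) {
      left <- pts[[f]] <= t
      acc <- (best_child(pts[left, ]) * sum(left) +
                best_child(pts[!left, ]) * sum(!left)) / nrow(pts)
      brute_best <- max(brute_best, acc)
    }
  }
  expect_equal(brute_best, 1)  # certified attainable

  tr <- fit_greedy_tree(pts, predictors = c("x", "y"), max_depth = 2,
                        min_leaf = 2)
  expect_equal(acc_of(predict(tr, pts)), 1)
})

test_that("fitting is deterministic", {
  coh <- tiny_cohort(40, 30)
  t1 <- fit_greedy_tree(coh)
  t2 <- fit_greedy_tree(coh)
  expect_identical(tidy(t1), tidy(t2))
})

test_that("monotone transforms of a predictor leave the partition unchanged", {
  coh <- tiny_cohort(30, 25)
  t1 <- fit_greedy_tree(coh)
  coh2 <- coh
  coh2$mcv <- exp(coh2$mcv / 20)  # strictly increasing
  t2 <- fit_greedy_tree(coh2)
  expect_equal(predict(t2, coh2), predict(t1, coh))
  # same fields split in the same order
  expect_equal(tidy(t2)$field, tidy(t1)$field)
})

test_that("tree-to-ruleset conversion agrees with direct traversal", {
  coh <- tiny_cohort(50, 35)
  tr <- fit_greedy_tree(coh)
  rs <- as_ruleset(tr)
  expect_equal(predict_ruleset(rs, coh), predict(tr, coh))
  audit <- audit_ruleset(rs)
  expect_true(audit$exclusive)
  expect_true(audit$exhaustive)
  # also on fresh records
  fresh <- tiny_cohort(20, 20, seed = 99)
  expect_equal(predict_ruleset(rs, fresh), predict(tr, fresh))
})

test_that("variable importance is normalized with unused fields at zero", {
  coh <- tibble::tibble(
    mcv = c(60, 61, 62, 63, 71, 72, 73, 74),
    hct = c(30, 31, 30, 31, 30, 31, 30, 31),
    label = rep(c("BTT", "IDA"), each = 4)
  )
  tr <- fit_greedy_tree(coh, predictors = c("hct", "mcv"), min_leaf = 2)
  imp <- variable_importance(tr)
  expect_equal(imp$importance[imp$field == "mcv"], 100)
  expect_equal(imp$importance[imp$field == "hct"], 0)

  pure <- tibble::tibble(mcv = c(1, 1, 2, 2), hct = 1:4,
                         label = c("BTT", "IDA", "BTT", "IDA"))
  tr2 <- fit_greedy_tree(pure, predictors = c("hct", "mcv"), min_leaf = 2)
  expect_true(all(variable_importance(tr2)$importance == 0))
})

test_that("on default synthetic cohorts MCV outranks the noise-like HCT", {
  coh <- generate_cohort(simulation_config(n_btt = 200, n_ida = 140, seed = 5))
  imp <- variable_importance(fit_greedy_tree(coh))
  expect_gt(imp$importance[imp$field == "mcv"],
            imp$importance[imp$field == "hct"])
})
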