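mk_em <- function(values, conditions = colnames(values)) {
  expression_matrix(values, data.frame(sample = colnames(values),
                                       condition = conditions,
                                       stringsAsFactors = FALSE))
}

test_that("expression calls follow the literal |log2| rule", {
  m <- matrix(c(0, 4, 1.5, 0.25,
                0, 2, 1.2, 1),
              nrow = 4, dimnames = list(paste0("g", 1:4), c("s1", "s2")))
  calls <- call_expression(mk_em(m))
  expect_equal(unname(calls$status[, "s1"]),
               c("not_expressed", "high", "low", "high"))
  expect_equal(calls$log2["g2", "s1"], 2)
  expect_true(is.na(calls$log2["g1", "s1"]))
  # FPKM 0.25 is |log2| = 2 >= 1 under the literal rule, low under log2_up
  alt <- call_expression(mk_em(m), rule = "log2_up")
  expect_equal(unname(alt$status[, "s1"]), c("not_expressed", "high", "low", "low"))
  # partition invariant
  for (cc in colnames(m))
    expect_equal(sum(calls$status[, cc] %in%
                       c("not_expressed", "low", "high")), nrow(m))
  s1 <- calls$summary[calls$summary$condition == "s1", ]
  expect_equal(s1$expressed, 3)
  expect_equal(s1$high_pct, round_half_away(100 * 2 / 3, 2))
  expect_error(call_expression(mk_em(m), high_threshold = 0), "high_threshold")
  mneg <- m; mneg[1, 1] <- -1
  expect_error(expression_matrix(mneg), "negative FPKM")
})

test_that("replicates are averaged before classification", {
  m <- matrix(c(3, 5, 3, 5), nrow = 1,
              dimnames = list("g1", c("a_r1", "a_r2", "b_r1", "b_r2")))
  em <- expression_matrix(m, data.frame(
    sample = colnames(m), condition = c("a", "a", "b", "b"),
    replicate = c(1, 2, 1, 2)))
  calls <- call_expression(em)
  expect_equal(calls$log2["g1", "a"], log2(4))
})

test_that("fold-change calls honour the zero rules and flip on swap", {
  m <- matrix(c(10, 10, 0, 10, 0,
                40, 2.6, 5, 0, 0),
              nrow = 5, dimnames = list(paste0("g", 1:5), c("day0", "day4")))
  fc <- fold_change_calls(mk_em(m), "day0")
  d <- fc$direction[, "day4"]
  expect_equal(unname(d), c("up", "down", "up", "down", "not_expressed"))
  expect_equal(fc$log2fc["g1", "day4"], 2)
  expect_equal(fc$log2fc["g3", "day4"], 10)    # newly expressed, capped
  expect_equal(fc$log2fc["g4", "day4"], -10)   # lost expression, capped
  # swap condition and baseline: up <-> down for all expressed genes
  m2 <- m[, c(2, 1)]; colnames(m2) <- c("day0", "day4")
  fc_sw <- fold_change_calls(mk_em(m2), "day0")
  d_sw <- fc_sw$direction[, "day4"]
  flip <- c(up = "down", down = "up", unchanged = "unchanged",
            not_expressed = "not_expressed")
  expect_equal(unname(d_sw), unname(flip[d]))
  # identical condition and baseline -> unchanged for expressed genes
  m3 <- cbind(day0 = m[, 1], day4 = m[, 1])
  fc_id <- fold_change_calls(mk_em(m3), "day0")
  expect_true(all(fc_id$direction[m[, 1] > 0, "day4"] == "unchanged"))
  expect_error(fold_change_calls(mk_em(m), "nope"), "baseline")
})

test_that("planted fold changes are recovered exactly without noise", {
  se <- simulate_expression(sim_config(seed = 3))
  fc <- fold_change_calls(se$matrix, "day0")
  truth <- se$truth
  d <- fc$direction[truth$gene, "day4"]
  expect_equal(unname(d[truth$call == "up"]),
               rep("up", sum(truth$call == "up")))
  expect_equal(unname(d[truth$call == "down"]),
               rep("down", sum(truth$call == "down")))
  expect_equal(unname(d[truth$call == "not_expressed"]),
               rep("not_expressed", sum(truth$call == "not_expressed")))
  expect_equal(unname(d[truth$call == "unchanged"]),
               rep("unchanged", sum(truth$call == "unchanged")))
  # dropout 1 -> everything silent
  cfg <- sim_config(seed = 3)
  cfg$expression$dropout <- 1
  se0 <- simulate_expression(cfg)
  expect_true(all(call_expression(se0$matrix)$status == "not_expressed"))
  # determinism
  expect_identical(simulate_expression(sim_config(seed = 3))$matrix$values,
                   se$matrix$values)
})

test_that("heatmap ordering permutes rows losslessly", {
  m <- matrix(1:6, nrow = 3, dimnames = list(c("g1", "g2", "g3"), c("a", "b")))
  expect_identical(heatmap_matrix(m, c("g1", "g2", "g3")), m)
  rev <- heatmap_matrix(m, c("g3", "g2", "g1"))
  expect_identical(rev, m[3:1, ])
  expect_error(heatmap_matrix(m, c("g1", "g2")), "permutation")
  expect_error(heatmap_matrix(m, c("g1", "g2", "gX")), "permutation")
})

test_that("expression TSV round-trips with metadata sidecar", {
  se <- simulate_expression(sim_config(seed = 4))
  dir <- withr::local_tempdir()
  mpath <- file.path(dir, "fpkm.tsv")
  metapath <- file.path(dir, "meta.tsv")
  utils::write.table(data.frame(gene = rownames(se$matrix$values),
                                se$matrix$values, check.names = FALSE),
                     mpath, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(se$matrix$metadata, metapath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  em2 <- read_expression_tsv(mpath, metapath)
  expect_equal(em2$values, se$matrix$values)
  expect_equal(em2$metadata$condition, se$matrix$metadata$condition)
})
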