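# Tag preprocessing: body-part reconstruction, array splitting, filtering,
# imputation and encoding.

mk_table <- function(df) {
  attr(df, "record_id") <- sprintf("R%03d", seq_len(nrow(df)))
  df
}

test_that("body-part reconstruction fills blanks by rule, never overwrites", {
  tab <- mk_table(data.frame(
    BodyPartExamined = c(NA, "HEAD", NA, NA),
    StudyDescription = c("ankle AP/LAT", "ankle AP", "cranium pa", "mystery"),
    stringsAsFactors = FALSE))
  rules <- data.frame(pattern = c("ankle", "cranium"),
                      source = "StudyDescription",
                      value = c("FOOT", "HEAD"), stringsAsFactors = FALSE)
  out <- reconstruct_bpe(tab, rules)
  expect_identical(out$BodyPartExamined, c("FOOT", "HEAD", "HEAD", NA))
  expect_identical(attr(out, "n_reconstructed"), 2L)
  # first matching rule wins
  rules2 <- rbind(data.frame(pattern = "ankle", source = "StudyDescription",
                             value = "LOWERLIMB"), rules)
  out2 <- reconstruct_bpe(tab, rules2)
  expect_identical(out2$BodyPartExamined[1], "LOWERLIMB")
  expect_error(reconstruct_bpe(tab, data.frame(pattern = "([", source = "x",
                                               value = "y")), "malformed")
  expect_error(reconstruct_bpe(tab, rules[0, ]), "nonempty")
})

test_that("array tags split into suffixed scalar columns, padding ragged rows", {
  tab <- mk_table(data.frame(a = c(1, 2)))
  tab$WindowCenter <- I(list(c(40, 400), c(50, 500)))
  out <- split_array_tags(tab)
  expect_identical(names(out), c("a", "WindowCenter_0", "WindowCenter_1"))
  expect_equal(out$WindowCenter_0, c(40, 50))
  expect_equal(out$WindowCenter_1, c(400, 500))
  expect_equal(out$a, c(1, 2))  # scalar column unchanged

  rag <- mk_table(data.frame(x = c(1, 2)))
  rag$w <- I(list(c(1, 2), c(3, 4, 5)))
  expect_message(out2 <- split_array_tags(rag), "ragged")
  expect_identical(names(out2), c("x", "w_0", "w_1", "w_2"))
  expect_equal(out2$w_2, c(NA, 5))
})

test_that("tag filtering applies fill-rate, identifier and constant rules", {
  n <- 100
  tab <- mk_table(data.frame(
    keep35 = c(rep(1:5, 7), rep(NA, 65)),        # fill rate exactly 0.35
    drop34 = c(rep(1:2, 17), rep(NA, 66)),       # fill rate 0.34
    constant = rep("x", n),
    ident = sprintf("uid%03d", seq_len(n)),      # all distinct characters
    good = rep(c("a", "b"), n / 2),
    stringsAsFactors = FALSE))
  out <- filter_tags(tab, fill_threshold = 0.35)
  expect_setequal(names(out), c("keep35", "good"))
  dropped <- attr(out, "dropped")
  expect_match(dropped[["drop34"]], "fill rate")
  expect_identical(dropped[["constant"]], "constant")
  expect_identical(dropped[["ident"]], "identifier")
  # idempotent, and identity when everything passes
  out2 <- filter_tags(out, fill_threshold = 0.35)
  expect_identical(names(out2), names(out))
  expect_equal(out2$good, out$good)
  expect_error(filter_tags(mk_table(data.frame(constant = rep(1, 10)))),
               "survive")
})

test_that("imputation completes tables and beats mean imputation under MCAR", {
  # identity on complete tables
  full <- mk_table(data.frame(a = rnorm(20), b = rnorm(20)))
  expect_identical(impute_missing(full), full)

  # single missing continuous cell with constant predictors -> column mean
  tab <- mk_table(data.frame(a = c(1, 2, 3, NA), b = rep("k", 4),
                             c = rep(5, 4), stringsAsFactors = FALSE))
  out <- impute_missing(tab, n_trees = 100, seed = 1)
  # constant predictors degenerate every tree to its root mean; the forest
  # average sits at the column mean up to bootstrap noise
  expect_equal(out$a[4], mean(c(1, 2, 3)), tolerance = 0.1)

  # MCAR masking of a structured table: forest recovers better than means
  set.seed(7)
  n <- 200
  z <- rnorm(n)
  truth <- data.frame(x1 = z + rnorm(n, 0, 0.1),
                      x2 = 2 * z + rnorm(n, 0, 0.1),
                      x3 = -z + rnorm(n, 0, 0.1),
                      g = ifelse(z > 0, "pos", "neg"),
                      stringsAsFactors = FALSE)
  masked <- truth
  holes <- matrix(runif(n * 3) < 0.2, n, 3)
  for (j in 1:3) masked[[j]][holes[, j]] <- NA
  masked <- mk_table(masked)
  imp <- impute_missing(masked, n_trees = 50, seed = 11)
  expect_false(anyNA(imp))
  rmse <- function(est) {
    sqrt(mean(unlist(lapply(1:3, function(j)
      (est[[j]][holes[, j]] - truth[[j]][holes[, j]])^2))))
  }
  mean_imp <- masked
  for (j in 1:3) {
    mean_imp[[j]][holes[, j]] <- mean(masked[[j]], na.rm = TRUE)
  }
  expect_lt(rmse(imp), rmse(mean_imp))
  expect_error(impute_missing(mk_table(data.frame(a = c(NA, NA), b = 1:2))),
               "all-missing")
})

test_that("encoding yields one-hot blocks and min-max scaled values in [0,1]", {
  tab <- mk_table(data.frame(cat = c("a", "b", "c", "a"),
                             num = c(0, 5, 10, 5), stringsAsFactors = FALSE))
  x <- encode_tags(tab)
  expect_equal(ncol(x), 4)  # 3 one-hot + 1 continuous
  onehot <- x[, startsWith(colnames(x), "cat=")]
  expect_equal(rowSums(onehot), rep(1, 4))
  expect_equal(unname(x[, "num"]), c(0, 0.5, 1, 0.5))
  expect_true(all(x >= 0 & x <= 1))

  # persisted encoder on new data: clipping and unseen-category zero block
  enc <- fit_tag_encoder(tab)
  new <- mk_table(data.frame(cat = c("b", "z"), num = c(-5, 20),
                             stringsAsFactors = FALSE))
  expect_message(x2 <- encode_tags(new, enc), "unseen")
  expect_equal(unname(x2[, "num"]), c(0, 1))  # clipped to training range
  expect_equal(sum(x2[2, startsWith(colnames(x2), "cat=")]), 0)
  expect_error(encode_tags(mk_table(data.frame(a = c(1, NA)))), "complete")
})

test_that("the fixture pipeline reconstructs nearly all recoverable blanks", {
  ds <- small_dataset()
  tab <- build_tag_table(ds)
  blank <- is.na(tab$BodyPartExamined)
  out <- reconstruct_bpe(tab, default_bpe_rules())
  recovered <- out$BodyPartExamined[blank] == ds$records$body_part[blank]
  expect_gte(mean(recovered), 0.95)
})
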