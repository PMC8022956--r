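ct_table <- function(rows) {
  do.call(rbind, lapply(rows, function(r) {
    data.frame(sample_id = r[[1]], tissue = r[[2]], stage = r[[3]],
               gene = r[[4]], ct = as.numeric(r[[5]]),
               rep = seq_along(r[[5]]), stringsAsFactors = FALSE)
  }))
}

test_that("equal Cts give fold 1 everywhere and the calibrator is exactly 1", {
  ct <- ct_table(list(
    list("rjf1", "dorsal", "D1", "HOXC10", c(25, 25, 25)),
    list("rjf1", "dorsal", "D1", "GAPDH", c(20, 20, 20)),
    list("silkie1", "cranial", "D1", "HOXC10", c(25, 25, 25)),
    list("silkie1", "cranial", "D1", "GAPDH", c(20, 20, 20))))
  out <- relative_expression(ct, "HOXC10", "GAPDH",
                             list(sample_id = "rjf1", tissue = "dorsal"))
  expect_equal(out$fold, c(1, 1))
  expect_equal(out$fold[out$sample_id == "rjf1"], 1)
})

test_that("one cycle below the calibrator doubles the fold", {
  ct <- ct_table(list(
    list("rjf1", "dorsal", "D1", "HOXC10", 25),
    list("rjf1", "dorsal", "D1", "GAPDH", 20),
    list("silkie1", "cranial", "D1", "HOXC10", 24),
    list("silkie1", "cranial", "D1", "GAPDH", 20)))
  out <- relative_expression(ct, "HOXC10", "GAPDH",
                             list(sample_id = "rjf1", tissue = "dorsal"))
  expect_equal(out$fold[out$sample_id == "silkie1"], 2)
})

test_that("technical replicates are averaged before the delta", {
  ct <- ct_table(list(
    list("rjf1", "dorsal", "D1", "HOXC10", c(20.0, 20.2, 20.4)),
    list("rjf1", "dorsal", "D1", "GAPDH", 20.2)))
  out <- relative_expression(ct, "HOXC10", "GAPDH",
                             list(sample_id = "rjf1", tissue = "dorsal"))
  expect_equal(out$dct, 20.2 - 20.2)
  expect_equal(out$fold, 1)
})

test_that("a constant shift of one gene rescales all folds log-linearly", {
  set.seed(3)
  samples <- sprintf("s%d", 1:6)
  ct <- do.call(rbind, lapply(samples, function(s) ct_table(list(
    list(s, "cranial", "E9", "HOXC8", runif(1, 18, 30)),
    list(s, "cranial", "E9", "GAPDH", runif(1, 18, 22))))))
  cal <- list(sample_id = "s1", tissue = "cranial")
  base <- relative_expression(ct, "HOXC8", "GAPDH", cal)
  shifted <- ct
  shifted$ct[shifted$gene == "HOXC8"] <- shifted$ct[shifted$gene == "HOXC8"] - 2
  out <- relative_expression(shifted, "HOXC8", "GAPDH", cal)
  # calibrator renormalises: relative folds are unchanged
  expect_equal(out$fold, base$fold)
  expect_equal(out$dct, base$dct - 2)
})

test_that("samples lacking the reference gene are omitted with a warning", {
  ct <- ct_table(list(
    list("rjf1", "dorsal", "D1", "HOXC10", 25),
    list("rjf1", "dorsal", "D1", "GAPDH", 20),
    list("lost", "cranial", "D1", "HOXC10", 23)))
  expect_warning(out <- relative_expression(
    ct, "HOXC10", "GAPDH", list(sample_id = "rjf1", tissue = "dorsal")),
    "lost")
  expect_false("lost" %in% out$sample_id)
  expect_error(suppressWarnings(relative_expression(
    ct, "HOXC10", "GAPDH", list(sample_id = "nope", tissue = "dorsal"))),
    "calibrator")
  bad <- ct; bad$ct[1] <- -1
  expect_error(relative_expression(
    bad, "HOXC10", "GAPDH", list(sample_id = "rjf1", tissue = "dorsal")),
    "positive")
})
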