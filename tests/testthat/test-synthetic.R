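test_that("design validation rejects impossible configurations", {
  expect_error(planted_design(n_relevant = -1), "non-negative")
  expect_error(planted_design(n_relevant = 0, n_redundant = 2,
                              n_interacting_pairs = 0, n_irrelevant = 0),
               "relevant")
  expect_error(planted_design(relevance_noise = 0.5), "0.5")
  expect_error(planted_design(n_relevant = 0, n_redundant = 0,
                              n_interacting_pairs = 0, n_irrelevant = 0),
               "at least one")
})

test_that("generation is reproducible and matches the design dimensions", {
  design <- planted_design(n_samples = 100, n_relevant = 2, n_redundant = 2,
                           n_interacting_pairs = 1, n_irrelevant = 3)
  a <- generate_dataset(design, seed = 5)
  b <- generate_dataset(design, seed = 5)
  expect_identical(a$data, b$data)
  expect_equal(dim(a$data), c(100L, 2L + 2L + 2L + 3L + 1L))
  expect_equal(table(a$roles$role),
               table(factor(c(rep("relevant", 2), rep("redundant", 2),
                              rep("interacting", 2), rep("irrelevant", 3)))))
  c_ <- generate_dataset(design, seed = 6)
  expect_false(identical(a$data, c_$data))
})

test_that("planted roles show the intended marginal and conditional signals", {
  design <- planted_design(n_samples = 1000, n_relevant = 1, n_redundant = 0,
                           n_interacting_pairs = 1, n_irrelevant = 2,
                           relevance_noise = 0)
  ds <- generate_dataset(design, seed = 7)
  cl <- ds$data$class
  # noiseless relevant copy carries the full class entropy
  expect_equal(mutual_information(ds$data$f1, cl), entropy(cl))
  # irrelevant features sit at the finite-sample noise floor (< 3/n bits)
  for (f in ds$roles$feature[ds$roles$role == "irrelevant"])
    expect_lt(mutual_information(ds$data[[f]], cl), 3 / 1000)
  # interacting pair: marginally silent, conditionally decisive
  pair <- ds$roles$feature[ds$roles$role == "interacting"]
  expect_lt(mutual_information(ds$data[[pair[1]]], cl), 3 / 1000)
  expect_gt(conditional_mutual_information(ds$data[[pair[1]]], cl,
                                           ds$data[[pair[2]]]), 0.98)
})

test_that("analytic MI matches the noise mixture and the empirical estimate", {
  expect_equal(expected_mi(planted_design(relevance_noise = 0), "relevant"), 1)
  # the 0.5 resampling limit is a flip-probability-0.25 channel
  hb <- function(p) -p * log2(p) - (1 - p) * log2(1 - p)
  expect_equal(expected_mi(planted_design(relevance_noise = 0.499),
                           "relevant"),
               1 - hb(0.2495), tolerance = 1e-12)
  expect_gt(expected_mi(planted_design(relevance_noise = 0.499), "relevant"),
            0)
  expect_equal(expected_mi(planted_design(), "interacting"), 0)
  expect_equal(expected_mi(planted_design(), "irrelevant"), 0)
  # Monte-Carlo convergence at large n
  design <- planted_design(n_samples = 100000, n_relevant = 1,
                           n_redundant = 1, n_interacting_pairs = 0,
                           n_irrelevant = 0, relevance_noise = 0.2,
                           redundancy_noise = 0.2)
  ds <- generate_dataset(design, seed = 8)
  expect_equal(mutual_information(ds$data$f1, ds$data$class),
               expected_mi(design, "relevant"), tolerance = 0.005)
  expect_equal(mutual_information(ds$data$f2, ds$data$class),
               expected_mi(design, "redundant"), tolerance = 0.005)
  expect_error(expected_mi(planted_design(n_classes = 3), "relevant"),
               "binary")
})

test_that("empirical MI of planted roles converges to the analytic value with n", {
  design_n <- function(n) planted_design(n_samples = n, n_relevant = 1,
                                         n_redundant = 0,
                                         n_interacting_pairs = 0,
                                         n_irrelevant = 0,
                                         relevance_noise = 0.3)
  target <- expected_mi(design_n(10), "relevant")
  errs <- vapply(c(1e3, 1e4, 1e5), function(n) {
    ds <- generate_dataset(design_n(n), seed = 9)
    abs(mutual_information(ds$data$f1, ds$data$class) - target)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))  # shrinking error with sample size
})

test_that("relevance-only rankings admit redundant copies; the conditional penalty never admits more", {
  design <- planted_design(n_samples = 500, n_relevant = 5, n_redundant = 5,
                           n_interacting_pairs = 1, n_irrelevant = 20,
                           relevance_noise = 0.1)
  counts <- vapply(1:20, function(seed) {
    ds <- generate_dataset(design, seed = seed)
    redundant <- ds$roles$feature[ds$roles$role == "redundant"]
    top_mim <- select_features(class ~ ., ds$data, criterion = "mim",
                               k = 10)$order
    top_nd <- select_features(class ~ ., ds$data, criterion = "ndcrfs",
                              k = 10)$order
    c(mim = sum(top_mim %in% redundant), nd = sum(top_nd %in% redundant))
  }, numeric(2))
  expect_true(all(counts["mim", ] > 0))
  # with strongly relevant sources, copies still clear the conditional
  # penalty (their conditional dependence stays below the sources'
  # relevance), so parity -- not superiority -- is the guaranteed outcome
  expect_true(all(counts["nd", ] <= counts["mim", ]))
})

test_that("dataset CSV + sidecar round-trip preserves values and hides roles", {
  design <- planted_design(n_samples = 50, n_relevant = 1, n_redundant = 0,
                           n_interacting_pairs = 1, n_irrelevant = 1)
  ds <- generate_dataset(design, seed = 10)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_dataset(ds, csv)
  sidecar <- sub("\\.csv$", ".roles.json", csv)
  expect_true(file.exists(sidecar))
  back <- read_dataset(csv)
  expect_equal(back$data, ds$data)
  expect_false(any(grepl("role", names(back$data))))
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  expect_equal(meta$seed, 10L)
  expect_equal(meta$roles$role, ds$roles$role)
})
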