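test_that("normalize_rates scales to unit L2 norm and preserves direction", {
  expect_equal(normalize_rates(c(3, 4)), c(0.6, 0.8))
  expect_equal(normalize_rates(c(5, 0, 0)), c(1, 0, 0))
  set.seed(1)
  raw <- runif(784) * 255
  out <- normalize_rates(raw)
  expect_equal(sqrt(sum(out^2)), 1, tolerance = 1e-9)
  # idempotent
  expect_equal(normalize_rates(out), out)
  expect_error(normalize_rates(rep(0, 10)), "silent sample")
  expect_error(normalize_rates(c(-1, 2)), "non-negative")
})

test_that("interarrival sampling follows the exponential law", {
  expect_identical(sample_interarrival(0), Inf)
  expect_error(sample_interarrival(-1), "non-negative")
  set.seed(7)
  draws <- vapply(seq_len(1e5), function(i) sample_interarrival(2), numeric(1))
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - 0.5), 4 * se)
  set.seed(42); a <- sample_interarrival(3)
  set.seed(42); b <- sample_interarrival(3)
  expect_identical(a, b)
})

test_that("pooled input events obey Poisson superposition and thinning", {
  set.seed(3)
  ev <- next_input_event(c(0, 0, 5, 0))
  expect_identical(ev$channel, 3L)
  set.seed(3)
  rates <- c(0.6, 0.8)
  n <- 1e5
  dts <- numeric(n); chs <- integer(n)
  for (i in seq_len(n)) {
    ev <- next_input_event(rates)
    dts[i] <- ev$dt; chs[i] <- ev$channel
  }
  # channel fraction within 4 SE of lambda_1 / sum(lambda)
  p <- 0.6 / 1.4
  se_p <- sqrt(p * (1 - p) / n)
  expect_lt(abs(mean(chs == 1) - p), 4 * se_p)
  # pooled interarrival mean within 4 SE of 1 / sum(lambda)
  se_m <- sd(dts) / sqrt(n)
  expect_lt(abs(mean(dts) - 1 / 1.4), 4 * se_m)
  expect_error(next_input_event(c(0, 0)), "positive")
})

test_that("spike counts per window are Poisson distributed", {
  set.seed(11)
  lambda <- 0.9; T <- 4
  counts <- vapply(seq_len(1e4), function(i) poisson_window_count(lambda, T),
                   integer(1))
  kmax <- max(counts)
  obs <- tabulate(counts + 1L, nbins = kmax + 1L)
  p <- dpois(0:kmax, lambda * T)
  # pool sparse upper tail so expected counts stay above 5
  keep <- which(p * length(counts) >= 5)
  cut <- max(keep)
  obs2 <- c(obs[seq_len(cut)], sum(obs[-seq_len(cut)]))
  p2 <- c(p[seq_len(cut)], 1 - sum(p[seq_len(cut)]))
  gof <- suppressWarnings(chisq.test(obs2, p = p2))
  expect_gt(gof$p.value, 0.001)
})

test_that("rate escalation preserves direction and scales magnitude", {
  r <- normalize_rates(c(1, 2, 3))
  expect_identical(escalate_rates(r, 0), r)
  expect_equal(sqrt(sum(escalate_rates(r, 2)^2)), 2.25)
  expect_equal(cosine(escalate_rates(r, 5), r), 1, tolerance = 1e-12)
})

test_that("IDX files round trip, including gzip, and bad magic is refused", {
  img <- matrix(as.integer(c(0, 255, 17, 3, 128, 64, 1, 2)), nrow = 2,
                byrow = TRUE)
  attr(img, "dims") <- c(2L, 2L)
  lbl <- c(7L, 2L)
  ipath <- tempfile(fileext = ".idx")
  lpath <- tempfile(fileext = ".idx")
  write_idx(img, ipath, "images")
  write_idx(lbl, lpath, "labels")
  back <- read_idx(ipath, "images")
  expect_identical(unclass(back)[seq_along(img)], as.integer(img))
  expect_identical(attr(back, "dims"), c(2L, 2L))
  expect_identical(read_idx(lpath, "labels"), lbl)
  # image magic passed as labels -> format error naming the offset
  expect_error(read_idx(ipath, "labels"), "magic")
  # gzip round trip detected from magic bytes
  gzpath <- tempfile(fileext = ".idx.gz")
  write_idx(img, gzpath, "images")
  expect_identical(attr(read_idx(gzpath, "images"), "dims"), c(2L, 2L))
  # paired dataset reader checks alignment
  ds <- read_idx_dataset(ipath, lpath)
  expect_identical(ds$y, lbl)
  expect_equal(nrow(ds$x), 2L)
})

test_that("synthetic datasets are reproducible and meet their dot targets", {
  cfg <- synthetic_config()
  set.seed(5)
  ds1 <- generate_synthetic(cfg)
  set.seed(5)
  ds2 <- generate_synthetic(cfg)
  expect_identical(ds1, ds2)
  realized <- attr(ds1, "realized")
  expect_gte(realized[["intra_dot"]], cfg$intra_dot_min)
  expect_lte(realized[["inter_dot"]], cfg$inter_dot_max)
  # unit-norm non-negative samples, grouped by ascending class
  expect_true(all(ds1$x >= 0))
  expect_equal(rowSums(ds1$x^2), rep(1, nrow(ds1$x)), tolerance = 1e-9)
  expect_identical(ds1$y, rep(0:3, each = cfg$samples_per_class))
})

test_that("zero synthetic noise reproduces cluster centers exactly", {
  set.seed(6)
  ds <- generate_synthetic(synthetic_config(noise_sd = 0,
                                            samples_per_class = 6L))
  centers <- attr(ds, "centers")
  cl <- attr(ds, "cluster")
  for (i in seq_len(nrow(ds$x))) {
    expect_equal(ds$x[i, ], centers[[ds$y[i] + 1L]][cl[i], ],
                 tolerance = 1e-12)
  }
})

test_that("synthetic config invariants are enforced", {
  expect_error(synthetic_config(inter_dot_max = 0.95), "inter_dot_max")
  expect_error(synthetic_config(dim = 8, n_classes = 4,
                                clusters_per_class = 3), "dim")
})

test_that("dataset split is stratified and partitions the samples", {
  set.seed(9)
  ds <- generate_synthetic(synthetic_config(samples_per_class = 20L))
  parts <- split_dataset(ds, 0.25)
  expect_equal(nrow(parts$train$x) + nrow(parts$test$x), nrow(ds$x))
  expect_equal(as.vector(table(parts$test$y)), rep(5L, 4L),
               ignore_attr = TRUE)
})
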