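# Co-occurrence statistics over pathway profiles.

make_profiles <- function(X, sizes = NULL, keys = NULL, quality = NULL) {
  df <- data.frame(genome_id = sprintf("g%04d", seq_len(nrow(X))))
  for (j in seq_len(ncol(X))) df[[paste0("pw", j)]] <- as.logical(X[, j])
  df$respiration <- "none"
  df$model_size <- if (is.null(sizes)) rep(100L, nrow(X)) else sizes
  df$seq_key <- if (is.null(keys)) NA_character_ else keys
  df$quality <- if (is.null(quality)) NA_real_ else quality
  df
}

test_that("deduplication keeps one best-quality representative per 16S key", {
  X <- matrix(TRUE, 5, 2)
  p <- make_profiles(X, keys = c("k1", "k1", "k1", "k2", NA),
                     quality = c(1, 9, 5, 2, 0))
  d <- deduplicate(p)
  expect_identical(nrow(d), 3L)                 # k1, k2, and the keyless one
  expect_true("g0002" %in% d$genome_id)         # top quality within k1
  expect_true("g0005" %in% d$genome_id)         # missing key retained
  # all-distinct keys: identity
  p2 <- make_profiles(X, keys = paste0("k", 1:5))
  expect_identical(deduplicate(p2)$genome_id, p2$genome_id)
  # ties broken by genome id order
  p3 <- make_profiles(X, keys = rep("k", 5), quality = rep(1, 5))
  expect_identical(deduplicate(p3)$genome_id, "g0001")
})

test_that("size classes split at the documented thresholds", {
  cls <- assign_size_classes(c(92, 93, 133, 134))
  expect_identical(as.character(cls), c("small", "medium", "medium", "large"))
  expect_identical(length(assign_size_classes(numeric(0))), 0L)
  cls2 <- assign_size_classes(40:163)
  expect_true(all(c("small", "medium", "large") %in% cls2))
})

test_that("phi coefficient equals the closed-form 2x2 value and the Pearson r", {
  a <- 30; b <- 10; cc <- 10; d <- 30; n <- a + b + cc + d
  x <- c(rep(1, a), rep(1, b), rep(0, cc), rep(0, d))
  y <- c(rep(1, a), rep(0, b), rep(1, cc), rep(0, d))
  phi <- (a * d - b * cc) / sqrt((a + b) * (cc + d) * (a + cc) * (b + d))
  X <- cbind(x, y)
  res <- pairwise_cooccurrence(make_profiles(X))
  expect_equal(res$pairs$r, phi)
  expect_equal(res$pairs$r, unname(cor(x, y)))
  expect_equal(phi, 0.5)
  # p from the t transform with n-2 df
  tstat <- phi * sqrt((n - 2) / (1 - phi^2))
  expect_equal(res$pairs$p, 2 * pt(-abs(tstat), n - 2))
})

test_that("r matrix is symmetric with unit diagonal; identical columns give r = 1", {
  set.seed(3)
  X <- matrix(rbinom(300, 1, 0.5), 100, 3)
  X[, 3] <- X[, 1]
  res <- pairwise_cooccurrence(make_profiles(X))
  R <- res$r_matrix
  expect_equal(R, t(R))
  expect_equal(unname(diag(R)), rep(1, 3))
  expect_equal(R["pw1", "pw3"], 1)
  p12 <- res$pairs[res$pairs$pathway_a == "pw1" & res$pairs$pathway_b == "pw3", ]
  expect_equal(p12$p, 0)
  # permutation invariance of profile order
  perm <- sample(nrow(X))
  res2 <- pairwise_cooccurrence(make_profiles(X[perm, ]))
  expect_equal(res2$r_matrix, R)
})

test_that("zero-variance pathways are flagged undefined, not NaN", {
  X <- cbind(rep(1, 50), rbinom(50, 1, 0.5))
  res <- pairwise_cooccurrence(make_profiles(X))
  expect_true(res$pairs$undefined[1])
  expect_true(is.na(res$pairs$r[1]))
  expect_false(res$pairs$significant[1])
})

test_that("a planted dependence is recovered as the strongest positive pair", {
  set.seed(9)
  n <- 400
  base <- rbinom(n, 1, 0.5)
  X <- cbind(butanol = base,
             butyrate = ifelse(runif(n) < 0.9, base, 1 - base),
             other1 = rbinom(n, 1, 0.4),
             other2 = rbinom(n, 1, 0.6))
  res <- pairwise_cooccurrence(make_profiles(X))
  top <- res$pairs[which.max(res$pairs$r), ]
  expect_setequal(c(top$pathway_a, top$pathway_b), c("pw1", "pw2"))
  expect_gt(top$r, 0.5)
})

test_that("type-I error is near the nominal level on independent columns", {
  set.seed(123)
  n <- 1000
  X <- matrix(rbinom(n * 12, 1, 0.5), n, 12)
  res <- pairwise_cooccurrence(make_profiles(X))
  npairs <- nrow(res$pairs)
  rate <- mean(res$pairs$significant)
  se <- sqrt(0.05 * 0.95 / npairs)
  expect_lt(abs(rate - 0.05), 3 * se + 1e-12)
  # Holm correction can only reduce the count of significant pairs
  resh <- pairwise_cooccurrence(make_profiles(X), holm = TRUE)
  expect_lte(sum(resh$pairs$significant), sum(res$pairs$significant))
})

test_that("summaries report the positive fraction among significant pairs only", {
  set.seed(21)
  n <- 300
  base <- rbinom(n, 1, 0.5)
  flip <- function(p) ifelse(runif(n) < p, base, 1 - base)
  X <- cbind(flip(0.95), flip(0.9), flip(0.92))
  res <- pairwise_cooccurrence(make_profiles(X))
  s <- summarize_cooccurrence(res)
  expect_equal(s$fraction_positive, 1)
  # plant one strongly negative pair
  X2 <- cbind(X, neg = 1 - base)
  s2 <- summarize_cooccurrence(pairwise_cooccurrence(make_profiles(X2)))
  expect_lt(s2$fraction_positive, 1)
})

test_that("size-class consistency compares sign and significance across strata", {
  set.seed(33)
  n <- 600
  sizes <- rep(c(60, 110, 150), each = n / 3)
  base <- rbinom(n, 1, 0.5)
  X <- cbind(a = base, b = ifelse(runif(n) < 0.9, base, 1 - base),
             c = rbinom(n, 1, 0.5))
  cons <- cooccurrence_consistency(make_profiles(X, sizes = sizes))
  ab <- cons$consistent[cons$pathway_a == "pw1" & cons$pathway_b == "pw2"]
  expect_true(ab)
})
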