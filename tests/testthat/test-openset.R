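mk_vec <- function(...) {
  v <- numeric(64)
  vals <- c(...)
  v[seq_along(vals)] <- vals
  v
}

test_that("standardization matches the hand-computed population convention", {
  # each dimension takes values {1, 2, 3}: mu = 2, sigma = sqrt(2/3)
  V <- matrix(rep(1:3, 64), nrow = 3)
  p <- fit_standardization(V)
  expect_equal(unname(p$mean), rep(2, 64))
  expect_equal(unname(p$sd), rep(sqrt(2 / 3), 64), tolerance = 1e-12)
  S <- standardize(p, V)
  expect_equal(S[, 1], c(-1.2247449, 0, 1.2247449), tolerance = 1e-6)
  # definitional: mean 0, population sd 1 per dimension
  expect_equal(colMeans(S), rep(0, 64), tolerance = 1e-12)
  expect_equal(sqrt(colMeans(S^2)), rep(1, 64), tolerance = 1e-12)
})

test_that("zero-variance dimensions standardize to zero via the epsilon floor", {
  V <- matrix(5, nrow = 4, ncol = 64)
  p <- fit_standardization(V)
  expect_equal(standardize(p, V), matrix(0, 4, 64), ignore_attr = TRUE)
  expect_error(fit_standardization(V[1, , drop = FALSE]), "at least 2")
})

test_that("cosine similarity satisfies its identities and rejects zero vectors", {
  v <- mk_vec(3, -1, 2)
  expect_equal(cosine_similarity(v, v), 1)
  expect_equal(cosine_similarity(v, 2.5 * v), 1)
  expect_equal(cosine_similarity(mk_vec(1), mk_vec(0, 1)), 0)
  expect_equal(cosine_similarity(mk_vec(1), -mk_vec(1)), -1)
  expect_error(cosine_similarity(numeric(64), v), "zero-norm")
  set.seed(1)
  for (i in 1:20) {
    a <- rnorm(64); b <- rnorm(64)
    s <- cosine_similarity(a, b)
    expect_gte(s, -1); expect_lte(s, 1)
  }
})

test_that("enrollment appends records and refits parameters from scratch", {
  set.seed(2)
  V1 <- matrix(rnorm(5 * 64), 5)
  V2 <- matrix(rnorm(3 * 64), 3)
  db <- enroll(feature_db(), V1, subject_id = c(1, 1, 2, 2, 2))
  expect_equal(nrow(db$vectors), 5)
  db <- enroll(db, V2, subject_id = 3)
  expect_equal(nrow(db$vectors), 8)
  # refit equals brute-force recomputation over all enrolled vectors
  brute <- fit_standardization(rbind(V1, V2))
  expect_equal(db$params$mean, brute$mean)
  expect_equal(db$params$sd, brute$sd)
  expect_equal(db$standardized, standardize(brute, rbind(V1, V2)))
})

test_that("identification self-matches, rejects strangers, and breaks ties low", {
  set.seed(3)
  V <- rbind(matrix(rnorm(4 * 64, mean = 2), 4),
             matrix(rnorm(4 * 64, mean = -2), 4))
  db <- enroll(feature_db(), V, subject_id = rep(c(7, 9), each = 4))
  # a subject's own gallery mean scores 1
  g7 <- colMeans(db$standardized[1:4, ])
  r <- identify(db, g7, threshold = 0.85, standardize_query = FALSE)
  expect_true(r$accepted)
  expect_equal(r$subject_id, 7)
  expect_equal(r$best_similarity, 1, tolerance = 1e-12)

  # a query orthogonal to both galleries is unknown at 0.85
  g9 <- colMeans(db$standardized[5:8, ])
  q <- rnorm(64)
  q <- q - sum(q * g7) / sum(g7^2) * g7
  q <- q - sum(q * g9) / sum(g9^2) * g9
  r2 <- identify(db, q, threshold = 0.85, standardize_query = FALSE)
  expect_false(r2$accepted)
  expect_true(is.na(r2$subject_id))
  expect_lt(abs(r2$best_similarity), 0.5)

  # constructed symmetric tie resolves to the lowest subject id, flagged
  Vt <- rbind(mk_vec(1, 0), mk_vec(1, 0), mk_vec(0, 1), mk_vec(0, 1))
  dbt <- enroll(feature_db(), Vt, subject_id = c(5, 5, 2, 2))
  rt <- identify(dbt, mk_vec(1, 1), threshold = -1)
  expect_true(rt$tie)
  expect_equal(rt$subject_id, 2)
  expect_equal(unname(diff(rt$scores)), 0, tolerance = 1e-12)

  expect_error(identify(feature_db(), mk_vec(1), 0.5), "empty")
})

test_that("identification is invariant to positive query scaling", {
  set.seed(4)
  V <- matrix(rnorm(6 * 64), 6)
  db <- enroll(feature_db(), V, subject_id = rep(1:3, each = 2))
  q <- rnorm(64)
  base <- identify(db, q, threshold = 0.5, standardize_query = FALSE)
  for (c in c(0.01, 0.5, 40)) {
    r <- identify(db, c * q, threshold = 0.5, standardize_query = FALSE)
    expect_equal(r$best_similarity, base$best_similarity, tolerance = 1e-12)
    expect_equal(r$scores, base$scores, tolerance = 1e-12)
    expect_identical(r$subject_id, base$subject_id)
  }
})

test_that("raising the threshold never turns an unknown verdict into a known one", {
  set.seed(5)
  V <- matrix(rnorm(8 * 64), 8)
  db <- enroll(feature_db(), V, subject_id = rep(1:4, each = 2))
  for (i in 1:10) {
    q <- rnorm(64)
    verdicts <- vapply(seq(-1, 1, by = 0.05), function(t)
      identify(db, q, threshold = t)$accepted, TRUE)
    # accepted must be a prefix: once unknown, always unknown as t rises
    expect_true(all(diff(verdicts) <= 0))
  }
})

test_that("a persisted database reproduces identification bit for bit", {
  set.seed(6)
  V <- matrix(rnorm(6 * 64), 6)
  db <- enroll(feature_db(gallery = "max"), V, subject_id = rep(1:2, 3))
  path <- tempfile(fileext = ".json")
  db_save(db, path)
  db2 <- db_load(path)
  expect_equal(db2$vectors, db$vectors, tolerance = 0)
  q <- rnorm(64)
  r1 <- identify(db, q, 0.3)
  r2 <- identify(db2, q, 0.3)
  expect_identical(r1$best_similarity, r2$best_similarity)
  expect_identical(r1$scores, r2$scores)
  expect_identical(r1$subject_id, r2$subject_id)
  unlink(path)
})

test_that("gallery standardization does not hurt the EER on separated subjects", {
  # three subjects with scale-confounded clusters: standardization removes
  # per-dimension scale, so the standardized sweep must do at least as well
  set.seed(7)
  centers <- matrix(rnorm(3 * 64, sd = 1), 3)
  scales <- runif(64, 0.2, 5)
  draw <- function(k, n) {
    t(replicate(n, (centers[k, ] + rnorm(64, sd = 0.8)) * scales))
  }
  enroll_all <- function(db) {
    for (k in 1:3) db <- enroll(db, draw(k, 6), subject_id = k)
    db
  }
  db_std <- enroll_all(feature_db())
  db_raw <- enroll_all(feature_db(standardize = FALSE))
  genuine_q <- do.call(rbind, lapply(1:3, draw, n = 4))
  genuine_id <- rep(1:3, each = 4)
  impostor_q <- t(replicate(12, rnorm(64, sd = 1.2) * scales))
  eer_of <- function(db) {
    g <- score_queries(db, genuine_q)$best_similarity
    i <- score_queries(db, impostor_q)$best_similarity
    sweep_thresholds(g, i)$eer
  }
  expect_lte(eer_of(db_std), eer_of(db_raw) + 1e-12)
})
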