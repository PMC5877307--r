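# From-scratch k-NN: distance, classification, split protocol, evaluation

test_that("euclidean distance basics and metric properties", {
  expect_equal(euclidean(c(0, 0), c(3, 4)), 5)
  expect_error(euclidean(1:3, 1:4), class = "sedentr_error")
  set.seed(3)
  for (i in 1:25) {
    x <- rnorm(6); y <- rnorm(6); z <- rnorm(6)
    expect_equal(euclidean(x, x), 0)
    expect_equal(euclidean(x, y), euclidean(y, x))
    expect_lte(euclidean(x, z), euclidean(x, y) + euclidean(y, z) + 1e-12)
  }
})

test_that("training_store enforces label sets and sizes", {
  X <- matrix(rnorm(12), 4)
  expect_error(training_store(X, c("still", "active", "tv", "still"),
                              "motion"), class = "sedentr_error")
  expect_error(training_store(X[0, , drop = FALSE], character(0), "motion"),
               class = "sedentr_error")
  st <- training_store(X, rep(c("still", "active"), 2), "motion")
  expect_equal(st$n, 4L)
  expect_equal(st$feature_length, 3L)
})

test_that("knn_classify handles singleton stores, majorities and ties", {
  st1 <- training_store(matrix(1:3, 1), "still", "motion")
  r <- knn_classify(c(1, 2, 4), st1)
  expect_equal(r$label, "still")
  expect_equal(r$neighbours, 1L)
  expect_equal(r$distances, 1)

  X <- rbind(c(0, 0), c(0.1, 0), c(5, 5))
  st <- training_store(X, c("active", "active", "still"), "motion")
  expect_equal(knn_classify(c(0, 0), st, k = 3)$label, "active")

  # vote tie at k=2: nearest neighbour's label wins
  st2 <- training_store(rbind(c(0, 0), c(1, 0)), c("still", "active"),
                        "motion")
  expect_equal(knn_classify(c(0.1, 0), st2, k = 2)$label, "still")

  # distance tie: lower insertion index wins
  st3 <- training_store(rbind(c(1, 0), c(-1, 0)), c("active", "still"),
                        "motion")
  expect_equal(knn_classify(c(0, 0), st3, k = 1)$label, "active")
})

test_that("knn_classify matches the exhaustive-scan oracle", {
  set.seed(99)
  X <- matrix(rnorm(100 * 6), 100)
  labs <- sample(c("still", "active"), 100, replace = TRUE)
  st <- training_store(X, labs, "motion")
  for (i in 1:20) {
    q <- rnorm(6)
    expect_identical(knn_classify(q, st, 3)$label, oracle_knn(q, X, labs, 3))
  }
})

test_that("adding a duplicate of the correct nearest neighbour never hurts", {
  set.seed(7)
  X <- matrix(rnorm(30 * 4), 30)
  labs <- sample(c("still", "active"), 30, replace = TRUE)
  st <- training_store(X, labs, "motion")
  for (i in 1:15) {
    q <- rnorm(4)
    r <- knn_classify(q, st, 3)
    if (labs[r$neighbours[1]] != r$label) next  # only correct-NN cases
    st2 <- training_store(rbind(X, X[r$neighbours[1], ]),
                          c(labs, labs[r$neighbours[1]]), "motion")
    expect_equal(knn_classify(q, st2, 3)$label, r$label)
  }
})

test_that("shuffling the store changes nothing without exact ties", {
  set.seed(17)
  X <- matrix(rnorm(50 * 3), 50)
  labs <- sample(c("tv", "pc", "unknown"), 50, replace = TRUE)
  st <- training_store(X, labs, "audio")
  perm <- sample(50)
  stp <- training_store(X[perm, ], labs[perm], "audio")
  for (i in 1:20) {
    q <- rnorm(3)
    expect_equal(knn_classify(q, st, 3)$label, knn_classify(q, stp, 3)$label)
  }
})

test_that("split_dataset honours the 60:10:30 protocol", {
  labs <- rep("still", 10)
  sp <- split_dataset(labs, seed = 4L)
  expect_equal(lengths(sp), c(train = 6L, validation = 1L, test = 3L))

  labs2 <- rep(c("still", "active"), each = 10)
  sp2 <- split_dataset(labs2, seed = 4L)
  for (part in sp2)
    expect_equal(sum(labs2[part] == "still"), sum(labs2[part] == "active"))
  expect_setequal(unlist(sp2), seq_along(labs2))  # disjoint + exhaustive
  expect_equal(sum(lengths(sp2)), length(labs2))

  expect_identical(split_dataset(labs2, seed = 4L), sp2)
  expect_error(split_dataset(c("a", "a", "b"), seed = 1L),
               class = "sedentr_error")
})

test_that("evaluate_store computes accuracy and the confusion matrix", {
  X <- rbind(c(0, 0), c(10, 10), c(0, 1), c(10, 11))
  labs <- c("still", "active", "still", "active")
  st <- training_store(X, labs, "motion")
  ev <- evaluate_store(st, X, labs, k = 1)
  expect_equal(ev$accuracy, 1.0)
  expect_equal(sum(diag(ev$confusion)), 4)

  ev2 <- evaluate_store(st, matrix(c(10, 10.4), 1), "still", k = 1)
  expect_equal(ev2$accuracy, 0.0)
  expect_equal(as.integer(ev2$confusion["still", "active"]), 1L)
  expect_error(evaluate_store(st, X[0, , drop = FALSE], character(0)),
               class = "sedentr_error")
})

test_that("store JSON round trip is bit-exact", {
  set.seed(31)
  X <- matrix(rnorm(40 * 6), 40)
  st <- training_store(X, sample(c("still", "active"), 40, TRUE), "motion")
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  save_store_json(st, path)
  st2 <- load_store_json(path)
  expect_identical(st2$features, st$features)
  expect_identical(st2$labels, st$labels)
  expect_identical(st2$stage, st$stage)
})
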