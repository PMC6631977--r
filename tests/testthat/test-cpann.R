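test_that("initialization is deterministic and uniform over classes", {
  m1 <- initMap(4, 3, seed = 5)
  m2 <- initMap(4, 3, seed = 5)
  expect_identical(m1@kohonenW, m2@kohonenW)
  expect_true(all(m1@outputW == 0.5))
  expect_false(identical(m1@kohonenW, initMap(4, 3, seed = 6)@kohonenW))
  expect_s4_class(initMap(1, 2), "CPANNModel")  # single-neuron map allowed
  expect_error(initMap(0, 2), "parameter error")
  expect_error(initMap(3, 0), "parameter error")
})

test_that("single-neuron training follows the w + lr*(x - w) closed form", {
  pts <- rbind(c(1, 5), c(3, 1))
  m <- initMap(1, 2, seed = 2, epochs = 1, lrStart = 0.3, lrEnd = 0.3)
  ## at S = 1 the raw weights rescale to the per-dimension score range
  lo <- apply(pts, 2, min); hi <- apply(pts, 2, max)
  w0 <- lo + m@kohonenW[1, ] * (hi - lo)
  tr <- trainCPANN(m, pts, c("mutant", "wild_type"), shuffle = FALSE)
  w1 <- w0 + 0.3 * (pts[1, ] - w0)
  w2 <- w1 + 0.3 * (pts[2, ] - w1)
  expect_equal(tr@kohonenW[1, ], w2, tolerance = 1e-12)
  ## output layer follows the same rule toward the one-hot labels
  o1 <- c(0.5, 0.5) + 0.3 * (c(1, 0) - c(0.5, 0.5))
  o2 <- o1 + 0.3 * (c(0, 1) - o1)
  expect_equal(unname(tr@outputW[1, ]), o2, tolerance = 1e-12)
})

test_that("radius-zero updates are independent of presentation order", {
  m <- initMap(2, 2, seed = 3, epochs = 1, lrStart = 0.4, lrEnd = 0.4)
  ## place neurons so the two inputs win different neurons (raw weights are
  ## rescaled to the data range at train time)
  m@kohonenW <- rbind(c(0.05, 0.05), c(0.95, 0.95), c(0.5, 0.2), c(0.2, 0.5))
  pts <- rbind(c(0, 0), c(10, 10))
  lab <- c("mutant", "wild_type")
  a <- trainCPANN(m, pts, lab, shuffle = FALSE)
  b <- trainCPANN(m, pts[2:1, ], lab[2:1], shuffle = FALSE)
  expect_equal(a@kohonenW, b@kohonenW, tolerance = 1e-12)
  expect_equal(a@outputW, b@outputW, tolerance = 1e-12)
})

test_that("training is deterministic and the output layer stays a simplex", {
  cl <- makeClusters()
  m <- initMap(3, 2, seed = 7, epochs = 40)
  t1 <- trainCPANN(m, cl$scores, cl$labels)
  t2 <- trainCPANN(initMap(3, 2, seed = 7, epochs = 40), cl$scores, cl$labels)
  expect_identical(t1@kohonenW, t2@kohonenW)
  expect_identical(predict(t1, cl$scores)$class, predict(t2, cl$scores)$class)
  expect_true(all(t1@outputW >= 0 & t1@outputW <= 1))
  expect_equal(unname(rowSums(t1@outputW)), rep(1, 9), tolerance = 1e-9)
})

test_that("a 2x2 map separates two clusters and matches the nearest-prototype oracle", {
  cl <- makeClusters()
  m <- trainCPANN(initMap(2, 2, seed = 1, epochs = 100), cl$scores, cl$labels)
  pred <- predict(m, cl$scores)$class
  expect_equal(100 * mean(pred == cl$labels), 100)
  oracle <- nearestPrototypeOracle(cl$scores, cl$labels, cl$scores)
  expect_identical(pred, unname(oracle))

  ## training accuracy non-decreasing with map size on separable data
  big <- trainCPANN(initMap(12, 2, seed = 1, epochs = 100),
                    cl$scores, cl$labels)
  accBig <- mean(predict(big, cl$scores)$class == cl$labels)
  expect_gte(accBig, mean(pred == cl$labels))
})

test_that("prediction uses the nearest neuron and validates state", {
  cl <- makeClusters()
  m <- trainCPANN(initMap(2, 2, seed = 1, epochs = 50), cl$scores, cl$labels)
  ## an input equal to a neuron weight wins that neuron
  for (n in c(1L, 4L)) {
    pr <- predict(m, rbind(m@kohonenW[n, ]))
    expect_equal(unname((pr$coords[1, 1] - 1) * 2 + pr$coords[1, 2]), n)
  }
  ## argmax of the winner's class weights decides the class
  pr <- predict(m, rbind(m@kohonenW[1, ]))
  expect_equal(pr$class, m@classLevels[which.max(m@outputW[1, ])])

  expect_error(predict(initMap(2, 2), cl$scores), "state error")
  expect_error(trainCPANN(initMap(2, 3), cl$scores, cl$labels), "shape error")
  expect_error(trainCPANN(initMap(2, 2), cl$scores,
                          rep("odd_label", 40)), "label error")
})

test_that("map projection partitions neurons and flags misclassified spectra", {
  cl <- makeClusters()
  m <- trainCPANN(initMap(3, 2, seed = 2, epochs = 60), cl$scores, cl$labels)
  meta <- data.frame(sample_id = cl$sampleIds, replicate = 1L,
                     label = cl$labels)
  rep <- projectMap(m, cl$scores, meta, role = "calibration")
  expect_equal(dim(rep$regions), c(3L, 3L))
  expect_true(all(rep$regions %in% c("mutant", "wild_type")))
  expect_equal(sum(table(rep$regions)), 9L)
  expect_equal(rep$placements$correct,
               rep$placements$predicted == rep$placements$label)
  expect_true(all(rep$placements$marker[rep$placements$label == "mutant"] == "M"))
  val <- projectMap(m, cl$scores, meta, role = "validation")
  expect_true(all(val$placements$marker %in% c("m", "w")))
  txt <- mapToText(rep)
  expect_length(txt, 3L)
})

test_that("grouped cross-validation keeps replicates together and scores separable data perfectly", {
  cl <- makeClusters(n = 30)
  ## give every sample 3 replicate spectra by jittering
  set.seed(33)
  scores <- cl$scores[rep(seq_len(60), each = 3), ] + rnorm(360, 0, 0.05)
  labels <- rep(cl$labels, each = 3)
  ids <- rep(cl$sampleIds, each = 3)
  cv <- crossValidate(scores, labels, ids, folds = 5, S = 2, seed = 4,
                      epochs = 60)
  expect_equal(cv$cacvPct, 100)
  ## all replicates of a sample share a fold
  perSample <- tapply(cv$predictions$fold, cv$predictions$sample_id,
                      function(f) length(unique(f)))
  expect_true(all(perSample == 1L))
  ## 60 samples in 5 folds: 12 samples / 36 spectra each
  expect_equal(unname(table(cv$predictions$fold[!duplicated(ids)])),
               rep(12L, 5L), ignore_attr = TRUE)
  expect_error(crossValidate(scores, labels, ids, folds = 61, S = 2),
               "parameter error")
})

test_that("label-shuffled cross-validation accuracy sits in the null band", {
  ## no class signal: held-out accuracy is Binomial(n, 1/2); check the
  ## pooled rate over 20 seeds against the 99% band around 50%
  correct <- integer(0)
  for (s in 1:20) {
    set.seed(100 + s)
    scores <- matrix(rnorm(80), 40, 2)
    labels <- sample(rep(c("mutant", "wild_type"), 20))
    ids <- sprintf("S%02d", 1:40)
    cv <- crossValidate(scores, labels, ids, folds = 5, S = 3, seed = s,
                        epochs = 15)
    correct <- c(correct, cv$predictions$predicted == cv$predictions$label)
  }
  n <- length(correct)
  half <- 2.576 * sqrt(0.25 / n)
  expect_gt(mean(correct), 0.5 - half)
  expect_lt(mean(correct), 0.5 + half)
})
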