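# The network is hand-written, so its backward pass is checked against the
# independent finite-difference oracle at tiny size, and its behavioural
# contracts (probability outputs, determinism, capacity) are exercised on
# small synthetic tasks.

ns <- asNamespace("gaitFatigue")

test_that("analytic gradients match finite differences for every tensor", {
  cfg <- tinyModelConfig()
  set.seed(1)
  B <- 4L; T <- 12L; C <- 2L
  X <- array(rnorm(B * T * C), c(B, T, C))
  y <- c(0L, 1L, 1L, 0L)
  params <- buildModel(cfg, c(T, C))@params
  fwd <- ns$.nnForward(params, X, cfg, keepCache = TRUE)
  grads <- ns$.nnBackward(params, cfg, fwd$cache, y)
  lossAt <- function(p) ns$.nnLoss(ns$.nnForward(p, X, cfg)$P, y)
  eps <- 1e-6
  for (nm in names(params)) {
    g <- grads[[nm]]
    idx <- sample(length(g), min(8L, length(g)))
    for (i in idx) {
      p1 <- params; p1[[nm]][i] <- p1[[nm]][i] + eps
      p2 <- params; p2[[nm]][i] <- p2[[nm]][i] - eps
      num <- (lossAt(p1) - lossAt(p2)) / (2 * eps)
      expect_lt(abs(num - g[i]) / max(1e-8, abs(num) + abs(g[i])), 1e-4,
                label = sprintf("relative gradient error of %s[%d]", nm, i))
    }
  }
})

test_that("seeded builds are bit-identical and report their size", {
  cfg <- tinyModelConfig()
  m1 <- buildModel(cfg, c(444L, 10L))
  m2 <- buildModel(cfg, c(444L, 10L))
  expect_identical(m1@params, m2@params)
  expect_identical(parameterCount(m1),
                   sum(vapply(m1@params, length, integer(1))))
  m3 <- buildModel(modelConfig(seed = 8L, convFilters = c(2L, 3L),
                               lstmUnits = 3L, denseUnits = 3L), c(444L, 10L))
  expect_false(identical(m1@params$Wc1, m3@params$Wc1))
  # input narrower than the pooled receptive field is refused
  expect_error(buildModel(cfg, c(3L, 2L)), "receptive field")
})

test_that("default architecture matches the published outline", {
  cfg <- modelConfig()
  expect_identical(cfg$convFilters, c(64L, 128L))
  expect_identical(cfg$lstmUnits, 64L)
  m <- buildModel(cfg, c(444L, 10L))
  expect_identical(ncol(m@params$Wd2), 2L)            # 2-unit softmax head
  expect_identical(ncol(m@params$Wl), 4L * 64L)       # one 64-unit LSTM
  out <- ns$.nnForward(m@params, array(rnorm(2 * 444 * 10),
                                       c(2, 444, 10)), cfg)
  expect_identical(dim(out$P), c(2L, 2L))
})

test_that("training learns a separable task and is seed-deterministic", {
  segs <- toySegmentSet(n = 40L, seed = 2L)
  cfg <- smallModelConfig(dropout = 0, seed = 5L)
  m <- trainModel(buildModel(cfg, c(444L, 2L)), segs)
  expect_true(all(c("trainLoss", "valLoss", "trainAcc", "valAcc") %in%
                  names(m@history)))
  expect_gte(utils::tail(m@history$trainAcc, 1L), 0.95)
  pr <- predictSegments(m, segs)
  expect_gte(mean(pr$label == segmentLabels(segs)), 0.95)

  m2 <- trainModel(buildModel(cfg, c(444L, 2L)), segs)
  expect_identical(m@params, m2@params)
  expect_identical(m@history, m2@history)
  expect_identical(predictSegments(m2, segs)$label, pr$label)
})

test_that("prediction outputs are probability vectors with documented ties", {
  segs <- toySegmentSet(n = 20L, seed = 3L)
  m <- trainModel(buildModel(tinyModelConfig(maxEpochs = 3L),
                             c(444L, 2L)), segs)
  pr <- predictSegments(m, segs)
  expect_lt(max(abs(rowSums(pr$prob) - 1)), 1e-5)
  expect_true(all(pr$prob >= 0))
  # duplicated segments get identical predictions (pointwise map)
  X <- segmentData(segs)[c(1L, 1L, 5L, 5L), , , drop = FALSE]
  prd <- predictSegments(m, X)
  expect_identical(prd$prob[1L, ], prd$prob[2L, ])
  expect_identical(prd$label[3L], prd$label[4L])
  # all-zero degenerate segment: finite probabilities, no NaN
  z <- array(0, c(1L, 444L, 2L))
  przero <- predictSegments(m, z)
  expect_true(all(is.finite(przero$prob)))
  expect_equal(sum(przero$prob), 1, tolerance = 1e-6)
  # width mismatch is refused
  expect_error(predictSegments(m, array(0, c(1L, 444L, 3L))), "width")
})

test_that("attention rows are probability vectors and permute with the batch", {
  segs <- toySegmentSet(n = 20L, seed = 4L)
  m <- trainModel(buildModel(tinyModelConfig(maxEpochs = 3L),
                             c(444L, 2L)), segs)
  A <- attentionWeights(m, segs, index = 1L)
  expect_identical(nrow(A), ncol(A))
  expect_true(all(A >= 0))
  expect_lt(max(abs(rowSums(A) - 1)), 1e-5)
  # the map is per-segment: reordering segments reorders the maps
  A7 <- attentionWeights(m, segs, index = 7L)
  X <- segmentData(segs)[c(7L, 1L), , , drop = FALSE]
  expect_equal(attentionWeights(m, X, index = 1L), A7, tolerance = 1e-12)
  # untrained models have no attention to report
  untrained <- methods::new("TrainedFatigueModel", params = m@params,
                            config = m@config,
                            history = m@history[0, ],
                            channelNames = m@channelNames,
                            classes = m@classes)
  expect_error(attentionWeights(untrained, segs), "not been trained")
})

test_that("the model can memorize a small shuffled-label set", {
  set.seed(6)
  n <- 20L; T <- 48L
  X <- array(rnorm(n * T * 2), c(n, T, 2))
  y <- sample(rep(c(0L, 1L), each = n %/% 2L))
  segs <- methods::new("SegmentSet", data = X, labels = y,
                       subjects = rep("S01", n),
                       channelNames = c("a", "b"),
                       windowFrames = T, hopFrames = 24L)
  cfg <- modelConfig(convFilters = c(8L, 16L), poolSizes = c(2L, 2L),
                     lstmUnits = 16L, denseUnits = 16L, dropout = 0,
                     learningRate = 5e-3, batchSize = 10L, maxEpochs = 150L,
                     patience = 150L, lrPatience = 150L,
                     valFraction = 0.1, seed = 13L)
  m <- trainModel(buildModel(cfg, c(T, 2L)), segs)
  pr <- predictSegments(m, segs)
  expect_gte(mean(pr$label == y), 0.99)
})

test_that("training requires both classes", {
  segs <- toySegmentSet(n = 10L, seed = 5L)
  onlyOne <- subsetSegments(segs, segmentLabels(segs) == 0L)
  expect_error(trainModel(buildModel(tinyModelConfig(), c(444L, 2L)),
                          onlyOne), "both classes")
})
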