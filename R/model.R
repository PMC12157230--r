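#' @include AllClasses.R nn.R
NULL

#' FatigueModel: an untrained CNN-LSTM-Attention classifier
#'
#' Seeded initial parameters plus the resolved configuration, produced by
#' \code{\link{buildModel}} and consumed by \code{\link{trainModel}}.
#'
#' @slot params named list of initial weights.
#' @slot config resolved configuration (see \code{\link{modelConfig}}).
#' @slot inputShape integer length-2: frames, channels.
#' @slot channelNames optional channel names (may be empty).
#' @exportClass FatigueModel
setClass("FatigueModel",
  slots = c(params = "list", config = "list", inputShape = "integer",
            channelNames = "character"))

setMethod("show", "FatigueModel", function(object) {
  np <- sum(vapply(object@params, length, integer(1)))
  cat(sprintf("FatigueModel (untrained): input %d x %d, %d parameters\n",
              object@inputShape[1L], object@inputShape[2L], np))
})

#' Configuration of the CNN-LSTM-Attention classifier
#'
#' The architecture is fixed in outline — two 1-D convolution + max-pooling
#' blocks (64 then 128 filters), one 64-unit LSTM returning its full state
#' sequence, single-head scaled dot-product self-attention over the LSTM
#' states, global average pooling over time, a ReLU dense layer and a 2-unit
#' softmax — while every unstated hyperparameter is exposed here with a
#' default.
#'
#' @param convFilters integer length-2, filters of the two conv layers.
#' @param convKernels integer length-2, kernel lengths (odd).
#' @param poolSizes integer length-2, non-overlapping max-pool widths.
#' @param lstmUnits LSTM state size.
#' @param denseUnits width of the dense layer before the softmax head.
#' @param dropout dropout rate applied after the second pooling block
#'   (training only, inverted dropout).
#' @param learningRate Adam learning rate.
#' @param batchSize mini-batch size.
#' @param maxEpochs epoch cap.
#' @param patience early-stopping patience (epochs without validation-loss
#'   improvement); best-validation weights are restored.
#' @param lrFactor,lrPatience learning-rate reduction on validation-loss
#'   plateau: multiply by \code{lrFactor} after \code{lrPatience} stale
#'   epochs.
#' @param valFraction fraction held out as the stratified validation split.
#' @param seed integer seed driving initialisation, the split, shuffling and
#'   dropout; identical configuration + seed reproduces identical training.
#' @return Named list of class \code{"ModelConfig"}.
#' @export
modelConfig <- function(convFilters = c(64L, 128L), convKernels = c(5L, 3L),
                        poolSizes = c(2L, 2L), lstmUnits = 64L,
                        denseUnits = 64L, dropout = 0.3,
                        learningRate = 1e-3, batchSize = 16L,
                        maxEpochs = 100L, patience = 10L,
                        lrFactor = 0.5, lrPatience = 5L,
                        valFraction = 0.2, seed = 42L) {
  cfg <- list(convFilters = as.integer(convFilters),
              convKernels = as.integer(convKernels),
              poolSizes = as.integer(poolSizes),
              lstmUnits = as.integer(lstmUnits),
              denseUnits = as.integer(denseUnits),
              dropout = dropout, learningRate = learningRate,
              batchSize = as.integer(batchSize),
              maxEpochs = as.integer(maxEpochs),
              patience = as.integer(patience), lrFactor = lrFactor,
              lrPatience = as.integer(lrPatience),
              valFraction = valFraction, seed = as.integer(seed))
  stopifnot(length(cfg$convFilters) == 2L, length(cfg$convKernels) == 2L,
            length(cfg$poolSizes) == 2L, all(cfg$convFilters > 0L),
            all(cfg$poolSizes > 0L), cfg$lstmUnits > 0L,
            cfg$dropout >= 0, cfg$dropout < 1,
            cfg$valFraction > 0, cfg$valFraction < 1)
  class(cfg) <- "ModelConfig"
  cfg
}

#' Reduced-size configuration for compact experiments
#'
#' Same architecture, smaller capacity (8/16 filters, 16 LSTM units, pool
#' width 4) and a tighter epoch budget. This is the configuration used for
#' the package's synthetic-cohort experiments, where the discrimination task
#' is far lower-dimensional than a real 35-subject cohort.
#'
#' @param ... overrides passed to \code{\link{modelConfig}}.
#' @return A \code{"ModelConfig"}.
#' @export
smallModelConfig <- function(...) {
  defaults <- list(convFilters = c(8L, 16L), convKernels = c(5L, 3L),
                   poolSizes = c(4L, 4L), lstmUnits = 16L, denseUnits = 16L,
                   dropout = 0.2, learningRate = 2e-3, batchSize = 16L,
                   maxEpochs = 30L, patience = 5L, lrPatience = 3L)
  args <- utils::modifyList(defaults, list(...))
  do.call(modelConfig, args)
}

.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Build an untrained model for a given input shape
#'
#' Initialises all weights (Glorot-uniform, forget-gate bias 1) from
#' \code{cfg$seed}; two builds with the same configuration and seed are
#' bit-identical.
#'
#' @param cfg a \code{\link{modelConfig}}.
#' @param inputShape integer length-2: frames per segment, channels.
#' @param channelNames optional channel names recorded with the model.
#' @return A \linkS4class{FatigueModel}.
#' @export
buildModel <- function(cfg, inputShape, channelNames = character(0)) {
  inputShape <- as.integer(inputShape)
  stopifnot(length(inputShape) == 2L, all(inputShape > 0L))
  ts <- .nnTimeSteps(inputShape[1L], cfg)
  if (ts["t2"] < 1L)
    stop(sprintf("buildModel: %d frames are shorter than the receptive field (pool %d x %d)",
                 inputShape[1L], cfg$poolSizes[1L], cfg$poolSizes[2L]))
  params <- .withSeed(cfg$seed, .nnInitParams(cfg, inputShape[2L]))
  methods::new("FatigueModel", params = params, config = unclass(cfg),
               inputShape = inputShape, channelNames = channelNames)
}

#' Number of trainable parameters
#'
#' @param model a \linkS4class{FatigueModel} or
#'   \linkS4class{TrainedFatigueModel}.
#' @return Integer scalar.
#' @export
parameterCount <- function(model) {
  sum(vapply(model@params, length, integer(1)))
}

.segTensor <- function(segments) {
  x <- segmentData(segments)
  storage.mode(x) <- "double"
  x
}

#' Train the classifier on a SegmentSet
#'
#' Performs a stratified (by label) 80:20 train/validation split of the
#' supplied segments, minimises the two-class cross-entropy with Adam,
#' reduces the learning rate on validation-loss plateaus, stops early when
#' the validation loss has not improved for \code{patience} epochs, and
#' restores the best-validation-loss weights. All randomness (split,
#' shuffling, dropout) derives from \code{cfg$seed}, so training is
#' deterministic.
#'
#' @param model a \linkS4class{FatigueModel} from \code{\link{buildModel}}.
#' @param segments a \linkS4class{SegmentSet} containing both classes.
#' @return A \linkS4class{TrainedFatigueModel}.
#' @export
trainModel <- function(model, segments) {
  cfg <- model@config
  X <- .segTensor(segments)
  y <- segmentLabels(segments)
  if (dim(X)[3L] != model@inputShape[2L])
    stop(sprintf("trainModel: segment width %d does not match model input width %d",
                 dim(X)[3L], model@inputShape[2L]))
  if (length(unique(y)) < 2L)
    stop("trainModel: training data must contain both classes")
  .withSeed(cfg$seed + 1L, {
    # stratified validation split
    valIdx <- integer(0)
    for (cl in c(0L, 1L)) {
      ic <- which(y == cl)
      nv <- max(1L, floor(cfg$valFraction * length(ic)))
      valIdx <- c(valIdx, sample(ic, nv))
    }
    trainIdx <- setdiff(seq_along(y), valIdx)
    Xtr <- X[trainIdx, , , drop = FALSE]; ytr <- y[trainIdx]
    Xva <- X[valIdx, , , drop = FALSE]; yva <- y[valIdx]
    params <- model@params
    adam <- .adamInit(params)
    lr <- cfg$learningRate
    best <- list(loss = Inf, params = params)
    wait <- 0L; lrWait <- 0L
    hist <- vector("list", cfg$maxEpochs)
    nTr <- length(ytr)
    for (epoch in seq_len(cfg$maxEpochs)) {
      ord <- sample(nTr)
      epLoss <- 0; epCorrect <- 0
      for (s in seq(1L, nTr, by = cfg$batchSize)) {
        idx <- ord[s:min(s + cfg$batchSize - 1L, nTr)]
        xb <- Xtr[idx, , , drop = FALSE]; yb <- ytr[idx]
        out <- .nnForward(params, xb, cfg, training = TRUE, keepCache = TRUE)
        grads <- .nnBackward(params, cfg, out$cache, yb)
        st <- .adamStep(params, grads, adam, lr)
        params <- st$params; adam <- st$state
        epLoss <- epLoss + .nnLoss(out$P, yb) * length(yb)
        epCorrect <- epCorrect +
          sum(max.col(out$P, ties.method = "first") == yb + 1L)
      }
      val <- .nnEvaluate(params, Xva, yva, cfg)
      hist[[epoch]] <- data.frame(
        epoch = epoch, trainLoss = epLoss / nTr, trainAcc = epCorrect / nTr,
        valLoss = val$loss, valAcc = val$acc, lr = lr)
      if (val$loss < best$loss - 1e-6) {
        best <- list(loss = val$loss, params = params)
        wait <- 0L; lrWait <- 0L
      } else {
        wait <- wait + 1L; lrWait <- lrWait + 1L
        if (lrWait >= cfg$lrPatience) {
          lr <- lr * cfg$lrFactor
          lrWait <- 0L
        }
        if (wait >= cfg$patience) break
      }
    }
    history <- do.call(rbind, hist[!vapply(hist, is.null, logical(1))])
    methods::new("TrainedFatigueModel",
      params = best$params, config = cfg, history = history,
      channelNames = if (length(model@channelNames)) model@channelNames
                     else channelNames(segments),
      classes = fatigueStates())
  })
}

#' Predict fatigue-state probabilities for segments
#'
#' @param model a \linkS4class{TrainedFatigueModel}.
#' @param segments a \linkS4class{SegmentSet} (or bare array
#'   segments x frames x channels) with the channel width the model was
#'   trained on.
#' @return List with \code{prob} (segments x 2 matrix, columns
#'   non_fatigued/fatigued, rows summing to 1), \code{label} (0/1, argmax;
#'   ties resolve to class 0), and \code{stateName}.
#' @export
predictSegments <- function(model, segments) {
  X <- if (methods::is(segments, "SegmentSet")) .segTensor(segments)
       else segments
  if (length(dim(X)) != 3L)
    stop("predictSegments: need a 3-D array (segments x frames x channels)")
  if (dim(X)[3L] != nrow(model@params$Wc1) / model@config$convKernels[1L])
    stop(sprintf("predictSegments: channel width %d does not match the trained width %d",
                 dim(X)[3L],
                 nrow(model@params$Wc1) %/% model@config$convKernels[1L]))
  cfg <- model@config
  n <- dim(X)[1L]
  prob <- matrix(0, n, 2L,
                 dimnames = list(NULL, model@classes))
  for (s in seq(1L, n, by = 64L)) {
    e <- min(s + 63L, n)
    out <- .nnForward(model@params, X[s:e, , , drop = FALSE], cfg)
    prob[s:e, ] <- out$P
  }
  lab <- max.col(prob, ties.method = "first") - 1L
  list(prob = prob, label = lab, stateName = model@classes[lab + 1L])
}

#' Attention weights of a trained model on one segment
#'
#' Runs the forward pass and returns the row-stochastic self-attention
#' matrix (attention timesteps x attention timesteps) for one segment, the
#' raw material of the attention heatmaps used to inspect which parts of a
#' gait sequence drive the classification.
#'
#' @param model a \linkS4class{TrainedFatigueModel}.
#' @param segments a \linkS4class{SegmentSet} or 3-D array.
#' @param index which segment to inspect (default 1).
#' @return Square matrix; each row is a probability vector.
#' @export
attentionWeights <- function(model, segments, index = 1L) {
  if (nrow(model@history) == 0L)
    stop("attentionWeights: model has not been trained")
  X <- if (methods::is(segments, "SegmentSet")) .segTensor(segments)
       else segments
  out <- .nnForward(model@params, X[index, , , drop = FALSE], model@config)
  A <- out$attn
  matrix(A[1L, , ], dim(A)[2L], dim(A)[3L])
}
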