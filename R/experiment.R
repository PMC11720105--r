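#' Scaled-down parameter-recovery experiment
#'
#' The self-contained end-to-end check of the pipeline: generate a synthetic
#' cohort with known misalignments, train the compact network on the
#' training split, evaluate on the held-out test split, and compare against
#' the identity baseline (predicting "no correction needed" for every
#' subject, whose rotation error is simply the misalignment magnitude). A
#' trained model recovering the planted rotations must beat that baseline
#' decisively.
#'
#' @param seed Integer seed driving cohort generation, training and
#'   evaluation.
#' @param nTrain,nTest Cohort split sizes (default 120 / 40).
#' @param epochs Training epochs (default 50).
#' @param nPoints Points per cloud (default 512).
#' @param augmentFactor Angle-scaling augmentations per training subject
#'   (default 30, the reference protocol's factor); each augmented sample
#'   carries its own independently sampled cloud, so the augmentation
#'   doubles as sampling-noise regularization.
#' @param verbose Print training progress.
#' @return List with `report` (an [EvalReport-class]), `medianRE`,
#'   `identityRE` (per-sample identity-baseline rotation errors),
#'   `identityMedianRE`, `model` and `history`.
#' @export
deskExperiment <- function(seed = 1L, nTrain = 120L, nTest = 40L,
                           epochs = 50L, nPoints = 512L, augmentFactor = 30L,
                           verbose = FALSE) {
  spec <- cohortSpec(nTrain = nTrain, nVal = 0L, nTest = nTest,
                     seed = seed)
  cohort <- generateCohort(spec)
  train <- cohortSplit(cohort, "train")
  if (augmentFactor > 1L)
    train <- augmentSamples(train, augmentSpec(factor = augmentFactor,
                                               seed = seed))
  netCfg <- deskNetworkConfig(seed = seed)
  trCfg <- deskTrainConfig(seed = seed, epochs = epochs)
  trCfg$nPoints <- as.integer(nPoints)
  fit <- trainNHPNet(train, netCfg, trCfg, verbose = verbose)
  test <- cohortSplit(cohort, "test")
  report <- evaluateNHP(test, fit$model, nPoints = nPoints, seed = seed)
  identityRE <- vapply(test, function(s)
    rotationError(diag(3), s$gtRotation), numeric(1))
  list(report = report,
       medianRE = stats::median(reportPerSample(report)$re),
       identityRE = identityRE,
       identityMedianRE = stats::median(identityRE),
       model = fit$model, history = fit$history)
}
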