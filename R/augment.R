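#' Specification of the angle-scaling augmentation
#'
#' Training samples are multiplied by drawing, per original sample and per
#' axis, a scale factor s in \[1 - relRange, 1 + relRange\] and setting the
#' augmented angle to s times the original. Scales are drawn in antithetic
#' pairs (s, 2 - s), so the mean of each augmented angle over an original's
#' group equals the original angle exactly — a plain uniform draw would
#' preserve the cohort means only in expectation. `factor` must therefore be
#' even when mean preservation is on.
#'
#' @param factor Augmentations per original sample (default 30).
#' @param relRange Relative perturbation bound in \[0, 1) (default 0.5,
#'   i.e. +/- 50 percent).
#' @param seed Integer seed.
#' @param preserveMean Use antithetic pairing (default TRUE).
#' @param keepOriginals Keep the originals alongside the augmentations
#'   (default FALSE: 90 originals become exactly 2700 samples).
#' @return A validated list of class `AugmentSpec`.
#' @export
augmentSpec <- function(factor = 30L, relRange = 0.5, seed = 1L,
                        preserveMean = TRUE, keepOriginals = FALSE) {
  if (factor < 1) stop("augmentSpec: factor must be >= 1")
  if (relRange < 0 || relRange >= 1)
    stop("augmentSpec: relRange must be in [0, 1)")
  if (preserveMean && factor %% 2 != 0)
    stop("augmentSpec: factor must be even when mean preservation is on")
  structure(list(factor = as.integer(factor), relRange = relRange,
                 seed = as.integer(seed), preserveMean = preserveMean,
                 keepOriginals = keepOriginals),
            class = "AugmentSpec")
}

#' Augment labelled samples by scaling their ground-truth angles
#'
#' For every original sample, `factor` augmented samples are created by
#' per-axis scaling of the ground-truth roll/pitch/yaw within the relative
#' bound; each augmented sample's acquired mesh is re-derived by rotating
#' the subject's canonical mesh by the transpose of the new ground-truth
#' rotation, so the round-trip property (acquired + ground truth =
#' canonical) holds for every augmented sample. An original angle of zero
#' never varies (a relative bound of a zero angle is zero) — a known
#' degeneracy of the scheme.
#'
#' @param samples List of labelled samples (see [generateCohort()]).
#' @param spec An [augmentSpec()].
#' @return List of augmented labelled samples of length
#'   `factor * length(samples)` (plus originals if kept).
#' @export
augmentSamples <- function(samples, spec = augmentSpec()) {
  stopifnot(inherits(spec, "AugmentSpec"))
  for (s in samples)
    if (is.null(s$gtAngles)) stop("augmentSamples: sample lacks gtAngles")
  out <- withr::with_seed(spec$seed, {
    lapply(samples, function(s) {
      scales <- .drawScales(spec)
      lapply(seq_len(spec$factor), function(a) {
        ang <- s$gtAngles * scales[a, ]
        gt <- eulerToMatrix(ang)
        acq <- applyRotation(s$canonical, t(gt))
        list(subjectId = sprintf("%s_aug%02d", s$subjectId, a),
             split = s$split, canonical = s$canonical, acquired = acq,
             gtRotation = gt,
             gtAngles = structure(ang, names = c("roll", "pitch", "yaw")))
      })
    })
  })
  aug <- do.call(c, out)
  if (spec$keepOriginals) c(samples, aug) else aug
}

# factor x 3 matrix of per-axis scales; antithetic pairs (s, 2 - s) make the
# column means exactly 1.
.drawScales <- function(spec) {
  if (spec$preserveMean) {
    half <- spec$factor %/% 2L
    s <- matrix(runif(half * 3, 1 - spec$relRange, 1 + spec$relRange),
                half, 3)
    rbind(s, 2 - s)
  } else {
    matrix(runif(spec$factor * 3, 1 - spec$relRange, 1 + spec$relRange),
           spec$factor, 3)
  }
}

#' Augment the training split of a cohort
#'
#' Applies [augmentSamples()] to the training samples and leaves the
#' validation and test splits untouched.
#'
#' @param cohort A [SkullCohort-class].
#' @param spec An [augmentSpec()].
#' @return A new [SkullCohort-class] with the augmented training split.
#' @export
augmentCohort <- function(cohort, spec = augmentSpec()) {
  tr <- cohortSplit(cohort, "train")
  rest <- cohort@samples[cohort@table$split != "train"]
  aug <- augmentSamples(tr, spec)
  samples <- c(aug, rest)
  new("SkullCohort", samples = samples, table = .cohortTable(samples),
      spec = cohort@spec)
}
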