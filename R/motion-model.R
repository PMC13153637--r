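## Inter- and intra-fraction linear motion models.
##
## The 104-component registration vector v is mapped to the 3D target
## position r by two linear models with intercept, fitted by truncated SVD:
##   v_mn = v_m + v'_mn  =>  r_mn = r_m + r'_mn
##   r_m   = f_inter(v_m)        (per-fraction means)
##   r'_mn = f_intra(v'_mn)      (within-fraction residuals)
## Singular values below w_max / R are dropped before inversion
## (R = 1.2 inter, 7.0 intra).

#' Bundle registration vectors and reference positions into observations
#'
#' @param v numeric n x 104 matrix of registration vectors (mm).
#' @param r numeric n x 3 matrix of reference target positions (mm).
#' @param patient,fraction integer vectors of length n.
#' @return a list of class \code{"motionObservations"}.
#' @export
motionObservations <- function(v, r, patient, fraction) {
  v <- as.matrix(v); r <- as.matrix(r)
  stopifnot(ncol(v) == 104L, ncol(r) == 3L, nrow(v) == nrow(r),
            length(patient) == nrow(v), length(fraction) == nrow(v),
            all(is.finite(v)), all(is.finite(r)))
  structure(list(v = v, r = r, patient = as.integer(patient),
                 fraction = as.integer(fraction)),
            class = "motionObservations")
}

#' Decompose observations into inter- and intra-fraction parts
#'
#' For every (patient, fraction) group, the inter-fraction state is the
#' arithmetic mean of the group's registration vectors and positions; the
#' intra-fraction residuals are the deviations from those means, so the
#' per-group residual means are exactly zero and mean + residual recomposes
#' each observation exactly.
#'
#' @param obs a [motionObservations()].
#' @return a list with \code{inter} (one row per fraction: \code{vm} k x
#'   104, \code{rm} k x 3, \code{patient}, \code{fraction}) and
#'   \code{intra} (per-observation residuals \code{vp}, \code{rp} plus the
#'   group index \code{group} of each observation into the inter rows).
#' @export
decomposeObservations <- function(obs) {
  stopifnot(inherits(obs, "motionObservations"))
  key <- paste(obs$patient, obs$fraction, sep = ":")
  if (any(table(key) < 1L)) stop("empty fraction")
  groups <- unique(key)
  gidx <- match(key, groups)
  k <- length(groups)
  vm <- matrix(0, k, ncol(obs$v)); rm_ <- matrix(0, k, 3)
  for (g in seq_len(k)) {
    rows <- gidx == g
    vm[g, ] <- colMeans(obs$v[rows, , drop = FALSE])
    rm_[g, ] <- colMeans(obs$r[rows, , drop = FALSE])
  }
  list(inter = list(vm = vm, rm = rm_,
                    patient = obs$patient[!duplicated(key)],
                    fraction = obs$fraction[!duplicated(key)]),
       intra = list(vp = obs$v - vm[gidx, , drop = FALSE],
                    rp = obs$r - rm_[gidx, , drop = FALSE],
                    group = gidx))
}

#' Fit a linear motion model by regularized singular value decomposition
#'
#' Solves \eqn{A x = b} with \eqn{A} the n x 105 design matrix (104
#' registration components plus an intercept column of ones) and \eqn{b}
#' the n x 3 positions, via \eqn{A = U W V^T} and
#' \eqn{x = V W^{-1} U^T b}, where reciprocals of singular values
#' \eqn{w_j < w_{max} / R} are set to zero before inversion to regularize
#' the solution (truncated SVD). With \code{literal = TRUE} the cutoff rule
#' is instead applied verbatim to the reciprocals \eqn{1/w_j < w_{max}/R},
#' which removes the \emph{largest} singular values; this variant exists
#' only to expose the difference and is not the default.
#'
#' @param v n x 104 matrix of registration vectors (mm).
#' @param r n x 3 matrix of target positions (mm).
#' @param cutoffRatio singular value cutoff ratio R (> 1); 1.2 for the
#'   inter-fraction model, 7.0 for the intra-fraction model.
#' @param kind \code{"inter"} or \code{"intra"}.
#' @param literal apply the cutoff to the reciprocals verbatim.
#' @return a \linkS4class{MotionModel}.
#' @export
fitMotionModel <- function(v, r, cutoffRatio, kind = c("inter", "intra"),
                           literal = FALSE) {
  kind <- match.arg(kind)
  v <- as.matrix(v); r <- as.matrix(r)
  stopifnot(ncol(v) == 104L, ncol(r) == 3L, nrow(v) >= 1L,
            cutoffRatio > 1)
  A <- cbind(v, 1)
  if (all(A == 0)) stop("all-zero design matrix")
  sv <- svd(A)
  w <- sv$d
  wmax <- max(w)
  if (wmax == 0) stop("all-zero design matrix")
  keep <- if (literal) !(1 / w < wmax / cutoffRatio) else
    w >= wmax / cutoffRatio
  winv <- ifelse(keep, 1 / w, 0)
  x <- sv$v %*% (winv * (t(sv$u) %*% r))
  new("MotionModel", coefficients = unname(x), kind = kind,
      cutoffRatio = as.numeric(cutoffRatio), retained = sum(keep),
      nObs = nrow(A))
}

#' Predict target positions from registration vectors
#'
#' Applies the fitted linear map: \code{[v, 1] \%*\% coefficients}.
#'
#' @param model a \linkS4class{MotionModel}.
#' @param v a length-104 vector or n x 104 matrix (mm).
#' @return a length-3 vector or n x 3 matrix of positions (mm).
#' @export
predictPosition <- function(model, v) {
  stopifnot(is(model, "MotionModel"))
  if (is.null(dim(v))) {
    if (length(v) != 104L) stop("v must have 104 components")
    drop(c(v, 1) %*% coefMatrix(model))
  } else {
    if (ncol(v) != 104L) stop("v must have 104 columns")
    unname(cbind(v, 1) %*% coefMatrix(model))
  }
}

#' Track a test set without daily volumetric imaging
#'
#' Scenario 1: no prior knowledge of the daily target position. Each test
#' fraction's mean registration vector \eqn{v_m} (computed from the test
#' patient's own images) is mapped through the inter-fraction model, and
#' the within-fraction deviations through the intra-fraction model:
#' \deqn{\hat r_{mn} = f_{inter}(v_m) + f_{intra}(v_{mn} - v_m).}
#'
#' @param interModel,intraModel fitted \linkS4class{MotionModel}s.
#' @param obs test-set [motionObservations()].
#' @return an n x 3 matrix of predicted positions (mm).
#' @export
trackWithoutDVI <- function(interModel, intraModel, obs) {
  dec <- decomposeObservations(obs)
  interPred <- predictPosition(interModel, dec$inter$vm)
  intraPred <- predictPosition(intraModel, dec$intra$vp)
  interPred[dec$intra$group, , drop = FALSE] + intraPred
}

#' Track a test set with daily volumetric imaging
#'
#' Scenario 2: pre-fraction volumetric imaging supplies the true mean
#' target position \eqn{r_m} of each fraction, so only the intra-fraction
#' deviations are predicted from the images:
#' \deqn{\hat r_{mn} = r_m + f_{intra}(v_{mn} - v_m).}
#'
#' @param intraModel a fitted \linkS4class{MotionModel}.
#' @param obs test-set [motionObservations()].
#' @param fractionMeans optional k x 3 matrix of known per-fraction mean
#'   positions in the order of the decomposed fractions; by default the
#'   test set's own per-fraction mean of \code{r} (the idealized daily
#'   volumetric imaging of the study design).
#' @return an n x 3 matrix of predicted positions (mm).
#' @export
trackWithDVI <- function(intraModel, obs, fractionMeans = NULL) {
  dec <- decomposeObservations(obs)
  rm_ <- if (is.null(fractionMeans)) dec$inter$rm else as.matrix(fractionMeans)
  if (nrow(rm_) != nrow(dec$inter$rm))
    stop("fractionMeans must supply one row per test fraction")
  intraPred <- predictPosition(intraModel, dec$intra$vp)
  rm_[dec$intra$group, , drop = FALSE] + intraPred
}

#' Summary statistics of tracking errors
#'
#' 3D error is the Euclidean norm of predicted minus reference; per-axis
#' errors are absolute component differences. Quartiles use linear
#' interpolation between order statistics (type 7).
#'
#' @param predicted,truth n x 3 matrices (mm).
#' @return a data.frame with one row per direction (left-right,
#'   antero-posterior, supero-inferior, 3D) and columns \code{min_mm},
#'   \code{lq_mm}, \code{median_mm}, \code{uq_mm}, \code{max_mm}.
#' @export
errorStats <- function(predicted, truth) {
  predicted <- as.matrix(predicted); truth <- as.matrix(truth)
  stopifnot(nrow(predicted) == nrow(truth), ncol(predicted) == 3L)
  if (nrow(predicted) == 0L) stop("empty input")
  diffs <- predicted - truth
  errs <- cbind(abs(diffs), sqrt(rowSums(diffs^2)))
  labels <- c("left-right", "antero-posterior", "supero-inferior", "3D")
  qs <- t(apply(errs, 2, stats::quantile,
                probs = c(0, 0.25, 0.5, 0.75, 1), type = 7))
  data.frame(direction = labels, min_mm = qs[, 1], lq_mm = qs[, 2],
             median_mm = qs[, 3], uq_mm = qs[, 4], max_mm = qs[, 5],
             row.names = NULL)
}

#' Leave-one-out cross validation of the motion models
#'
#' Each patient is held out in turn; the inter-fraction model (cutoff
#' R = \code{rInter}) and intra-fraction model (R = \code{rIntra}) are
#' fitted on the remaining patients and evaluated on the held-out patient
#' under both imaging scenarios. Pooled rows aggregate the per-image errors
#' across all held-out patients (not medians of medians). A fitting-set
#' table evaluates each fold's models on its own training patients
#' (no-DVI scenario).
#'
#' @param obs a [motionObservations()] with at least two patients.
#' @param rInter,rIntra singular value cutoff ratios (defaults 1.2, 7.0).
#' @return a list with \code{perPatient} (data.frame: patient, scenario,
#'   direction, quantile columns), \code{pooled} (same without patient),
#'   \code{fitting} (per-fold training-set summaries), \code{errors}
#'   (per-image 3D errors by patient and scenario) and \code{residuals}
#'   (per-image residual vectors, predicted minus reference, mm).
#' @export
loocvEvaluate <- function(obs, rInter = 1.2, rIntra = 7.0) {
  stopifnot(inherits(obs, "motionObservations"))
  pats <- sort(unique(obs$patient))
  if (length(pats) < 2L) stop("leave-one-out requires at least two patients")
  sub <- function(o, rows)
    motionObservations(o$v[rows, , drop = FALSE], o$r[rows, , drop = FALSE],
                       o$patient[rows], o$fraction[rows])
  perPatient <- list(); fitting <- list()
  poolPred <- list(noDVI = NULL, DVI = NULL); poolTruth <- NULL
  errRows <- list(); resRows <- list()
  for (p in pats) {
    test <- sub(obs, obs$patient == p)
    train <- sub(obs, obs$patient != p)
    dec <- decomposeObservations(train)
    inter <- fitMotionModel(dec$inter$vm, dec$inter$rm, rInter, "inter")
    intra <- fitMotionModel(dec$intra$vp, dec$intra$rp, rIntra, "intra")
    predNo <- trackWithoutDVI(inter, intra, test)
    predDvi <- trackWithDVI(intra, test)
    for (sc in c("noDVI", "DVI")) {
      pred <- if (sc == "noDVI") predNo else predDvi
      st <- errorStats(pred, test$r)
      st <- cbind(patient = p, scenario = sc, st)
      perPatient[[length(perPatient) + 1L]] <- st
      errRows[[length(errRows) + 1L]] <- data.frame(
        patient = p, scenario = sc,
        error_mm = sqrt(rowSums((pred - test$r)^2)))
      res <- pred - test$r
      resRows[[length(resRows) + 1L]] <- data.frame(
        patient = p, scenario = sc, fraction = test$fraction,
        dx_mm = res[, 1], dy_mm = res[, 2], dz_mm = res[, 3])
    }
    poolPred$noDVI <- rbind(poolPred$noDVI, predNo)
    poolPred$DVI <- rbind(poolPred$DVI, predDvi)
    poolTruth <- rbind(poolTruth, test$r)
    fitPred <- trackWithoutDVI(inter, intra, train)
    fitting[[length(fitting) + 1L]] <-
      cbind(heldOut = p, errorStats(fitPred, train$r))
  }
  pooled <- rbind(
    cbind(scenario = "noDVI", errorStats(poolPred$noDVI, poolTruth)),
    cbind(scenario = "DVI", errorStats(poolPred$DVI, poolTruth)))
  list(perPatient = do.call(rbind, perPatient), pooled = pooled,
       fitting = do.call(rbind, fitting), errors = do.call(rbind, errRows),
       residuals = do.call(rbind, resRows))
}
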