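# Pattern recognition: NIPALS PCA with Hotelling T2 limits, and linear /
# Mahalanobis discriminant classification on PC scores.

#' NIPALS principal component analysis
#'
#' Sequential NIPALS with deflation: for each component, power iteration
#' alternates `p = X't / t't` (normalized) and `t = X p` until the relative
#' change of the score vector falls below `tol`, then `X <- X - t p'`.
#' Loadings carry a fixed sign convention (largest-magnitude element
#' positive) so runs are comparable. Explained variance is each component's
#' share of the total centered sum of squares.
#'
#' @param X numeric matrix, samples in rows, variables in columns; or an
#'   [IRSpectraSet-class] (transposed internally).
#' @param k number of components, `<= min(nrow - 1, ncol)`.
#' @param tol relative convergence tolerance on the score vector
#'   (default 1e-9).
#' @param maxIter maximum iterations per component (default 1000); on
#'   non-convergence a warning reports the iteration count and the partial
#'   model is returned.
#' @param center mean-center columns first (default TRUE; disable only if
#'   `X` is already centered).
#' @return A [PCAModel-class].
#' @examples
#' X <- matrix(rnorm(8 * 30), 8, 30)
#' m <- pcaNipals(X, k = 3)
#' explainedVariance(m)
#' @export
pcaNipals <- function(X, k, tol = 1e-9, maxIter = 1000, center = TRUE) {
  if (is(X, "IRSpectraSet")) X <- t(intensities(X))
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (k > min(n - 1, p))
    stop("k must not exceed min(nrow - 1, ncol) = ", min(n - 1, p))
  ctr <- if (center) colMeans(X) else rep(0, p)
  X <- sweep(X, 2, ctr)
  totSS <- sum(X^2)
  if (totSS == 0)
    stop("zero-variance data matrix: all rows identical after centering")
  scoresM <- matrix(0, n, k); loadsM <- matrix(0, p, k)
  iters <- integer(k); conv <- logical(k)
  for (j in seq_len(k)) {
    t_vec <- X[, which.max(colSums(X^2))]
    if (all(t_vec == 0)) {                     # exhausted rank
      k <- j - 1L
      scoresM <- scoresM[, seq_len(k), drop = FALSE]
      loadsM <- loadsM[, seq_len(k), drop = FALSE]
      iters <- iters[seq_len(k)]; conv <- conv[seq_len(k)]
      break
    }
    for (it in seq_len(maxIter)) {
      p_vec <- crossprod(X, t_vec) / sum(t_vec^2)
      p_vec <- p_vec / sqrt(sum(p_vec^2))
      t_new <- X %*% p_vec
      delta <- sqrt(sum((t_new - t_vec)^2)) / sqrt(sum(t_new^2))
      t_vec <- t_new
      if (delta < tol) break
    }
    iters[j] <- it
    conv[j] <- delta < tol
    if (!conv[j])
      warning("component ", j, " did not converge within ", maxIter,
              " iterations (last relative change ", signif(delta, 3), ")")
    if (p_vec[which.max(abs(p_vec))] < 0) {    # sign convention
      p_vec <- -p_vec; t_vec <- -t_vec
    }
    scoresM[, j] <- t_vec; loadsM[, j] <- p_vec
    X <- X - tcrossprod(t_vec, p_vec)
  }
  ev <- 100 * colSums(scoresM^2) / totSS
  new("PCAModel", scores = scoresM, loadings = loadsM,
      explainedVariance = as.numeric(ev), center = as.numeric(ctr),
      totalSS = totSS, iterations = iters, converged = conv)
}

#' Hotelling T2 statistic and control limit
#'
#' `T2(i) = sum_j t_ij^2 / lambda_j` over the model's components, with
#' `lambda_j` the score variance of component j, against the F-distribution
#' control limit `k (n - 1) / (n - k) * F(1 - alpha; k, n - k)`.
#'
#' @param model a [PCAModel-class] with `k >= 1` components.
#' @param alpha significance level of the limit (default 0.05).
#' @return list with `t2` (per-sample statistic), `threshold`, `flagged`
#'   (logical), `alpha`.
#' @export
hotellingT2 <- function(model, alpha = 0.05) {
  S <- scores(model)
  n <- nrow(S); k <- ncol(S)
  if (k < 1) stop("model has no components")
  if (n <= k)
    stop("Hotelling limit undefined: need more samples than components")
  lambda <- apply(S, 2, stats::var)
  if (any(lambda == 0)) stop("zero-variance score component")
  t2 <- rowSums(sweep(S^2, 2, lambda, "/"))
  thr <- k * (n - 1) / (n - k) * stats::qf(1 - alpha, k, n - k)
  list(t2 = as.numeric(t2), threshold = thr, flagged = t2 > thr,
       alpha = alpha)
}

# stratified train indices: per class, a seeded random draw of round(f * n)
.stratifiedSplit <- function(labels, fraction, seed) {
  set.seed(seed)
  idx <- unlist(lapply(split(seq_along(labels), labels), function(i) {
    nTrain <- max(1L, min(length(i) - 1L, round(fraction * length(i))))
    sample(i, nTrain)
  }))
  sort(unname(idx))
}

.ridgeSolve <- function(S, m) {
  ok <- tryCatch({solve(S); TRUE}, error = function(e) FALSE)
  lam <- 0
  if (!ok || rcond(S) < 1e-12) {
    lam <- 1e-8 * sum(diag(S)) / m
    S <- S + diag(lam, m)
  }
  list(inv = solve(S), lambda = lam)
}

#' Discriminant classification of PC scores
#'
#' Fits class statistics on a stratified random training split and assigns
#' each sample to the class with the smallest squared Mahalanobis distance
#' to the class mean: under the pooled within-class covariance for
#' `kind = "linear"`, or under per-class covariances for
#' `kind = "mahalanobis"` (falling back to the pooled covariance, with a
#' warning, for classes with too few training samples). Near-singular
#' covariances are ridge-regularized with `lambda = 1e-8 * trace / m`.
#' Priors are equal by default (balanced designs); with unequal priors the
#' distance is penalized by `-2 log(prior)`.
#'
#' @param scores samples x m numeric matrix of PC scores (or any features).
#' @param labels class labels, one per row; >= 2 classes.
#' @param kind `"linear"` (pooled covariance) or `"mahalanobis"`
#'   (per-class).
#' @param split training fraction of each class (default 2/3).
#' @param seed RNG seed for the stratified split.
#' @param priors class priors; default equal.
#' @return An [LDAModel-class] with held-out and all-sample confusion
#'   matrices and accuracies.
#' @export
ldaFit <- function(scores, labels, kind = c("linear", "mahalanobis"),
                   split = 2 / 3, seed = 1, priors = NULL) {
  kind <- match.arg(kind)
  S <- as.matrix(scores); m <- ncol(S)
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("at least two classes are required")
  if (length(labels) != nrow(S)) stop("one label per sample is required")
  if (is.null(priors)) priors <- rep(1 / length(classes), length(classes))
  if (length(priors) != length(classes) || abs(sum(priors) - 1) > 1e-8)
    stop("priors must have one entry per class and sum to 1")
  names(priors) <- classes
  trainIdx <- .stratifiedSplit(labels, split, seed)
  trS <- S[trainIdx, , drop = FALSE]; trL <- labels[trainIdx]
  means <- t(vapply(classes, function(cl)
    colMeans(trS[trL == cl, , drop = FALSE]), numeric(m)))
  # pooled within-class covariance
  pooled <- matrix(0, m, m)
  for (cl in classes) {
    Xc <- sweep(trS[trL == cl, , drop = FALSE], 2, means[cl, ])
    pooled <- pooled + crossprod(Xc)
  }
  pooled <- pooled / (length(trainIdx) - length(classes))
  rp <- .ridgeSolve(pooled, m)
  classCovs <- list(); classInv <- list(); ridge <- rp$lambda
  if (kind == "mahalanobis") {
    for (cl in classes) {
      nc <- sum(trL == cl)
      if (nc <= m) {
        warning("class '", cl, "' has ", nc, " training samples for ", m,
                " score dimensions; falling back to the pooled covariance")
        classCovs[[cl]] <- pooled; classInv[[cl]] <- rp$inv
      } else {
        Sc <- stats::cov(trS[trL == cl, , drop = FALSE])
        rc <- .ridgeSolve(Sc, m)
        classCovs[[cl]] <- Sc; classInv[[cl]] <- rc$inv
        ridge <- max(ridge, rc$lambda)
      }
    }
  }
  d2 <- vapply(classes, function(cl) {
    inv <- if (kind == "linear") rp$inv else classInv[[cl]]
    D <- sweep(S, 2, means[cl, ])
    rowSums((D %*% inv) * D) - 2 * log(priors[cl])
  }, numeric(nrow(S)))
  pred <- classes[max.col(-d2, ties.method = "first")]
  role <- ifelse(seq_len(nrow(S)) %in% trainIdx, "train", "test")
  predictions <- data.frame(index = seq_len(nrow(S)), true = labels,
                            predicted = pred, role = role,
                            stringsAsFactors = FALSE)
  lv <- classes
  confAll <- table(factor(labels, lv), factor(pred, lv), dnn = c("true", "predicted"))
  ho <- role == "test"
  confHO <- table(factor(labels[ho], lv), factor(pred[ho], lv),
                  dnn = c("true", "predicted"))
  acc <- function(tb) if (sum(tb) == 0) NA_real_ else 100 * sum(diag(tb)) / sum(tb)
  new("LDAModel", kind = kind, classes = classes, classMeans = means,
      pooledCov = pooled, classCovs = classCovs, priors = unname(priors),
      ridge = ridge, trainIdx = as.integer(trainIdx),
      predictions = predictions, confusionHeldout = confHO,
      confusionAll = confAll, accuracyHeldout = acc(confHO),
      accuracyAll = acc(confAll))
}

#' Region PCA + PC-score LDA discrimination of sample groups
#'
#' Convenience composition of the discrimination workflow: extract a
#' wavenumber region, vector-normalize each spectrum over it, mean-center
#' across samples, fit NIPALS PCA with `k` components and classify the
#' first `m` PC scores with [ldaFit()].
#'
#' @param x an [IRSpectraSet-class].
#' @param region length-2 wavenumber interval; `NULL` for the full grid.
#' @param labels grouping: a `colData` column name (default `"dose"`) or a
#'   vector of labels, >= 2 groups with >= 2 samples each.
#' @param k number of PCs (default `min(10, n - 1, p)`).
#' @param m number of PC scores fed to the classifier. The default keeps the
#'   within-class covariance estimate well-determined at small n:
#'   `min(10, k, floor(minimum per-class training count / 2))` (feeding all
#'   10 PCs into a covariance fitted on a handful of spectra lets pure-noise
#'   components dominate the Mahalanobis metric).
#' @param kind,split,seed,priors passed to [ldaFit()].
#' @return list with `pca` ([PCAModel-class]), `lda` ([LDAModel-class]),
#'   `scoresTable` (tidy scores + labels), `explainedVariance`,
#'   `hotelling`, `accuracyHeldout`, `accuracyAll`.
#' @export
discriminateGroups <- function(x, region = NULL, labels = "dose",
                               k = NULL, m = NULL,
                               kind = c("linear", "mahalanobis"),
                               split = 2 / 3, seed = 1, priors = NULL) {
  kind <- match.arg(kind)
  if (is.character(labels) && length(labels) == 1) {
    if (!labels %in% colnames(colData(x)))
      stop("no '", labels, "' column in colData")
    labels <- as.character(colData(x)[[labels]])
  }
  labels <- as.character(labels)
  tab <- table(labels)
  if (length(tab) < 2 || any(tab < 2))
    stop("need >= 2 groups with >= 2 samples each")
  if (!is.null(region)) x <- extractRegion(x, region)
  x <- vectorNormalize(x)
  X <- t(intensities(x))
  if (is.null(k)) k <- min(10, nrow(X) - 1, ncol(X))
  pca <- pcaNipals(X, k = k, center = TRUE)
  kEff <- ncol(scores(pca))
  if (is.null(m)) {
    minTrain <- min(vapply(tab, function(n)
      max(1, min(n - 1, round(split * n))), numeric(1)))
    m <- max(1, min(10, kEff, floor(minTrain / 2)))
  }
  m <- min(m, kEff)
  lda <- ldaFit(scores(pca)[, seq_len(m), drop = FALSE], labels,
                kind = kind, split = split, seed = seed, priors = priors)
  st <- data.frame(sample_id = colnames(intensities(x)), label = labels,
                   scores(pca), check.names = FALSE)
  colnames(st)[-(1:2)] <- paste0("PC", seq_len(kEff))
  list(pca = pca, lda = lda, scoresTable = st,
       explainedVariance = explainedVariance(pca),
       hotelling = hotellingT2(pca),
       accuracyHeldout = lda@accuracyHeldout, accuracyAll = lda@accuracyAll)
}
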