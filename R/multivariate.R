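# Principal-component factor analysis with varimax rotation (plus KMO and
# Bartlett sphericity diagnostics), Fisher's linear discriminant analysis
# with Wilks' Lambda and Box's M, and leave-one-out cross-validation.

# ---- helpers ---------------------------------------------------------------

as_numeric_matrix <- function(X) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (!all(is.finite(X))) stop("non-finite values in data matrix")
  X
}

# Accept either a data matrix (subjects x variables) or a correlation matrix.
correlation_of <- function(x) {
  x <- as_numeric_matrix(x)
  p <- ncol(x)
  is_corr <- nrow(x) == p && isTRUE(all.equal(x, t(x), tolerance = 1e-10)) &&
    isTRUE(all.equal(unname(diag(x)), rep(1, p), tolerance = 1e-10))
  if (is_corr) return(x)
  if (nrow(x) < 2L) stop("need at least 2 observations")
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0))
    stop("zero-variance column(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "))
  stats::cor(x)
}

# ---- varimax rotation ------------------------------------------------------

# Kaiser-normalized varimax by pairwise planar rotations. Rows are scaled to
# unit communality before rotation and rescaled after, so communalities are
# preserved exactly. Orthogonal rotation also leaves L %*% t(L) unchanged.
varimax_rotate <- function(L, normalize = TRUE, tol = 1e-8, max_sweeps = 1000L) {
  L <- as.matrix(L)
  p <- nrow(L); k <- ncol(L)
  if (k < 2L) return(list(loadings = L, rotation = diag(k), sweeps = 0L))
  comm <- sqrt(rowSums(L^2))
  if (normalize) {
    if (any(comm == 0)) stop("variable with zero communality cannot be Kaiser-normalized")
    L <- L / comm
  }
  R <- diag(k)
  for (sweep in seq_len(max_sweeps)) {
    max_phi <- 0
    for (a in seq_len(k - 1L)) {
      for (b in seq.int(a + 1L, k)) {
        x <- L[, a]; y <- L[, b]
        u <- x^2 - y^2
        v <- 2 * x * y
        num <- 2 * (sum(u * v) - sum(u) * sum(v) / p)
        den <- sum(u^2 - v^2) - (sum(u)^2 - sum(v)^2) / p
        phi <- atan2(num, den) / 4
        if (abs(phi) > tol) {
          cs <- cos(phi); sn <- sin(phi)
          L[, a] <- cs * x + sn * y
          L[, b] <- -sn * x + cs * y
          G <- R[, c(a, b)]
          R[, a] <- cs * G[, 1L] + sn * G[, 2L]
          R[, b] <- -sn * G[, 1L] + cs * G[, 2L]
        }
        max_phi <- max(max_phi, abs(phi))
      }
    }
    if (max_phi <= tol) break
  }
  if (normalize) L <- L * comm
  list(loadings = L, rotation = R, sweeps = sweep)
}

# ---- sampling-adequacy diagnostics ----------------------------------------

#' Kaiser-Meyer-Olkin measure of sampling adequacy
#'
#' `KMO = sum(r^2) / (sum(r^2) + sum(q^2))` over off-diagonal entries, where
#' `r` are the observed correlations and `q` the anti-image partial
#' correlations (negatives of the scaled inverse correlation matrix). Values
#' near 1 indicate compact correlation structure suited to factor analysis;
#' values below about 0.5 indicate factor analysis is inappropriate. For two
#' variables with any nonzero correlation the index is exactly 0.5, since a
#' bivariate partial correlation equals the correlation itself.
#'
#' @param x data matrix (subjects x variables) or a correlation matrix.
#' @return value in `[0, 1]`.
#' @export
kmo <- function(x) {
  R <- correlation_of(x)
  Rinv <- tryCatch(solve(R), error = function(e)
    stop("correlation matrix is singular; KMO undefined"))
  d <- 1 / sqrt(diag(Rinv))
  Q <- -Rinv * outer(d, d)             # anti-image partial correlations
  off <- upper.tri(R)
  r2 <- sum(R[off]^2)
  q2 <- sum(Q[off]^2)
  val <- r2 / (r2 + q2)
  if (val < 0.5)
    warning(sprintf("KMO = %.3f < 0.5: factor analysis inappropriate", val))
  val
}

#' Bartlett's test of sphericity
#'
#' Tests whether the correlation matrix is the identity (no common structure
#' to factor). Statistic `-(n - 1 - (2p + 5)/6) * ln|R|` referred to a
#' chi-square with `p(p - 1)/2` degrees of freedom.
#'
#' @param x data matrix (subjects x variables) or a correlation matrix (then
#'   `n_obs` must be supplied).
#' @param n_obs number of observations when `x` is a correlation matrix.
#' @return list with `statistic`, `df`, `p_value`.
#' @export
bartlett_sphericity <- function(x, n_obs = NULL) {
  R <- correlation_of(x)
  x <- as.matrix(x)
  n <- if (nrow(x) == ncol(x) && !is.null(n_obs)) n_obs else nrow(x)
  if (is.null(n) || n <= 1) stop("need the number of observations")
  p <- ncol(R)
  detR <- det(R)
  if (detR <= 0) stop("correlation matrix has non-positive determinant")
  stat <- -(n - 1 - (2 * p + 5) / 6) * log(detR)
  df <- p * (p - 1) / 2
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

# ---- factor analysis -------------------------------------------------------

#' Principal-component factor analysis with varimax rotation
#'
#' Eigendecomposes the correlation matrix of the 15 pulse amplitudes (or any
#' variable set), retains factors with eigenvalue > 1 (Kaiser criterion),
#' and varimax-rotates the retained loadings with Kaiser normalization. The
#' percent of variance per factor is `eigenvalue / p * 100` (unrotated).
#' Each variable is assigned to the factor on which it loads highest in
#' absolute value, giving the grouped display familiar from factor tables.
#'
#' @param x data matrix (subjects x variables) or a correlation matrix (then
#'   pass `n_obs` for the Bartlett diagnostic).
#' @param n_obs observation count when `x` is a correlation matrix.
#' @param min_eigenvalue retention threshold (default 1, strictly greater).
#' @return a `factor_model`: `loadings` (variables x factors, rotated),
#'   `eigenvalues`, `pct_variance`, `n_factors`, `assignment` (max-loading
#'   factor per variable), `kmo`, `bartlett_stat`, `bartlett_p`, `R`
#'   (correlation matrix), `structureless` flag.
#' @export
factor_analysis <- function(x, n_obs = NULL, min_eigenvalue = 1) {
  xm <- as_numeric_matrix(x)
  is_corr <- nrow(xm) == ncol(xm) &&
    isTRUE(all.equal(xm, t(xm), tolerance = 1e-10)) &&
    isTRUE(all.equal(unname(diag(xm)), rep(1, ncol(xm)), tolerance = 1e-10))
  n <- if (is_corr) n_obs else nrow(xm)
  if (!is_corr && nrow(xm) <= ncol(xm))
    warning("fewer observations than would be comfortable (n <= p); ",
            "factor solution may be unstable")
  R <- correlation_of(xm)
  p <- ncol(R)
  if (is.null(colnames(R))) colnames(R) <- rownames(R) <- paste0("V", seq_len(p))
  if (det(R) <= 0)
    stop("singular correlation matrix; check for collinear columns: ",
         paste(colnames(R), collapse = ", "))

  eg <- eigen(R, symmetric = TRUE)
  keep <- which(eg$values > min_eigenvalue)
  # sampling-aware structure check: with independent variables the top sample
  # eigenvalue sits near the Marchenko-Pastur edge (1 + sqrt(p/n))^2, so a
  # maximum below ~that edge indicates no common structure even when a few
  # eigenvalues drift above 1 by chance
  edge <- if (!is.null(n) && is.finite(n)) (1 + sqrt(p / n))^2 else 1
  structureless <- max(eg$values) <= edge + 1e-8
  if (structureless)
    warning("largest eigenvalue ", format(max(eg$values), digits = 3),
            " is within sampling noise of an identity correlation; ",
            "data look structureless")
  loadings <- if (length(keep))
    eg$vectors[, keep, drop = FALSE] %*% diag(sqrt(eg$values[keep]), length(keep))
  else matrix(0, p, 0)
  if (length(keep) >= 2L) {
    rot <- varimax_rotate(loadings)
    loadings <- rot$loadings
  }
  if (length(keep)) {
    # orient each factor so its largest loading is positive (sign convention)
    for (f in seq_len(ncol(loadings))) {
      m <- which.max(abs(loadings[, f]))
      if (loadings[m, f] < 0) loadings[, f] <- -loadings[, f]
    }
    dimnames(loadings) <- list(colnames(R), paste0("f", seq_along(keep)))
  }
  assignment <- if (length(keep))
    apply(abs(loadings), 1L, which.max) else rep(NA_integer_, p)

  kmo_val <- tryCatch(kmo(R), warning = function(w) suppressWarnings(kmo(R)),
                      error = function(e) NA_real_)
  bart <- if (!is.null(n))
    tryCatch(bartlett_sphericity(R, n_obs = n), error = function(e) NULL)
  else NULL

  structure(list(
    loadings = loadings,
    eigenvalues = eg$values[keep],
    all_eigenvalues = eg$values,
    center = if (!is_corr) colMeans(xm) else NULL,
    scale = if (!is_corr) apply(xm, 2L, stats::sd) else NULL,
    pct_variance = eg$values[keep] / p * 100,
    n_factors = length(keep),
    assignment = assignment,
    kmo = kmo_val,
    bartlett_stat = if (!is.null(bart)) bart$statistic else NA_real_,
    bartlett_p = if (!is.null(bart)) bart$p_value else NA_real_,
    R = R,
    n_obs = n,
    structureless = structureless
  ), class = "factor_model")
}

#' @export
print.factor_model <- function(x, ...) {
  cat(sprintf("Factor model: %d factor(s) retained (eigenvalue > 1), %.1f%% of variance\n",
              x$n_factors, sum(x$pct_variance)))
  if (!is.na(x$kmo)) cat(sprintf("  KMO = %.3f", x$kmo))
  if (!is.na(x$bartlett_p))
    cat(sprintf("; Bartlett sphericity chi2 = %.2f (p = %.3g)", x$bartlett_stat, x$bartlett_p))
  cat("\n")
  if (x$n_factors > 0) {
    cat("Rotated loadings (variables grouped by dominant factor):\n")
    ord <- order(x$assignment, -apply(abs(x$loadings), 1L, max))
    print(round(x$loadings[ord, , drop = FALSE], 3))
  }
  invisible(x)
}

#' Factor scores by the regression (Thurstone) method
#'
#' Scores `F = Z R^{-1} L` where `Z` is the data standardized with the
#' training cohort's means and SDs, `R` the correlation matrix and `L` the
#' rotated loadings. New subjects are projected onto the training scale, so
#' held-out scoring (e.g. in cross-validation) is well defined.
#'
#' @param model a `factor_model` fitted on data (not on a bare correlation
#'   matrix).
#' @param x the data matrix the model was fitted on, or new data on the same
#'   variables.
#' @return subjects x factors score matrix.
#' @export
factor_scores <- function(model, x) {
  stopifnot(inherits(model, "factor_model"))
  if (model$n_factors == 0L) stop("no retained factors; scores undefined")
  if (is.null(model$center)) stop("model was fitted on a correlation matrix; ",
                                  "scores need the training data scale")
  x <- as_numeric_matrix(x)
  Z <- sweep(sweep(x, 2L, model$center), 2L, model$scale, "/")
  Z %*% solve(model$R, model$loadings)
}

# ---- Fisher's linear discriminant analysis ---------------------------------

#' Fisher's linear discriminant analysis for two classes
#'
#' Computes the discriminant direction `w = Sw^{-1} (mu_excess -
#' mu_deficient)` with `Sw` the pooled within-class covariance, scaled so the
#' pooled within-class variance of the discriminant score is 1 (the
#' canonical convention). Standardized coefficients are the raw coefficients
#' multiplied by the pooled within-class SD of each variable, so their
#' magnitudes compare each variable's contribution on a common scale. Scores
#' are oriented so the excess class sits higher. The decision cutoff is the
#' midpoint of the class score centroids, shifted by `-log(pi_e/pi_d) /
#' (centroid gap)` under proportional priors (the SPSS default with unequal
#' groups); `prior = "equal"` gives the plain midpoint. Ties at the cutoff
#' classify as excess. Wilks' Lambda and Box's M are attached as diagnostics.
#'
#' @param X subjects x features numeric matrix (or data.frame).
#' @param y labels, `"deficient"`/`"excess"`.
#' @param prior `"proportional"` (default) or `"equal"` class priors for the
#'   cutoff.
#' @return a `fisher_lda` model.
#' @export
fisher_lda <- function(X, y, prior = c("proportional", "equal")) {
  prior <- match.arg(prior)
  X <- as_numeric_matrix(X)
  y <- as.character(y)
  stopifnot(nrow(X) == length(y), all(y %in% PULSE_CLASSES))
  n <- nrow(X); p <- ncol(X)
  nd <- sum(y == "deficient"); ne <- sum(y == "excess")
  if (nd < 2L || ne < 2L) stop("need at least 2 subjects per class")
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(p))

  Xd <- X[y == "deficient", , drop = FALSE]
  Xe <- X[y == "excess", , drop = FALSE]
  mu_d <- colMeans(Xd); mu_e <- colMeans(Xe)
  Sw <- (crossprod(sweep(Xd, 2L, mu_d)) + crossprod(sweep(Xe, 2L, mu_e))) / (n - 2)
  w <- tryCatch(solve(Sw, mu_e - mu_d), error = function(e)
    stop("pooled within-class covariance is singular; ",
         "remove collinear features: ", paste(colnames(X), collapse = ", ")))
  # canonical scaling: unit pooled within-class score variance
  s2 <- drop(t(w) %*% Sw %*% w)
  if (s2 <= 0) stop("degenerate discriminant direction")
  w <- w / sqrt(s2)

  grand <- (nd * mu_d + ne * mu_e) / n
  constant <- -drop(crossprod(w, grand))
  score <- drop(X %*% w) + constant
  cen_d <- mean(score[y == "deficient"]); cen_e <- mean(score[y == "excess"])
  # orientation already guarantees cen_e > cen_d since w points mu_d -> mu_e
  pri <- if (prior == "proportional") c(d = nd / n, e = ne / n) else c(d = .5, e = .5)
  cutoff <- (cen_d + cen_e) / 2 - log(pri["e"] / pri["d"]) / (cen_e - cen_d)
  cutoff <- unname(cutoff)

  wl <- wilks_lambda(X, y)
  bm <- tryCatch(box_m(X, y), error = function(e) list(statistic = NA_real_, p_value = NA_real_))

  structure(list(
    raw_coefficients = w,
    standardized_coefficients = w * sqrt(diag(Sw)),
    constant = constant,
    cutoff = cutoff,
    class_means = c(deficient = cen_d, excess = cen_e),
    prior = prior,
    wilks_lambda = wl$lambda, wilks_p = wl$p_value,
    box_m = bm$statistic, box_m_p = bm$p_value,
    features = colnames(X),
    n = c(deficient = nd, excess = ne)
  ), class = "fisher_lda")
}

#' @export
print.fisher_lda <- function(x, ...) {
  cat("Fisher linear discriminant (deficient vs excess)\n")
  m <- cbind(raw = x$raw_coefficients, standardized = x$standardized_coefficients)
  print(round(m, 4))
  cat(sprintf("  cutoff = %.4f (%s priors); centroids: deficient %.3f, excess %.3f\n",
              x$cutoff, x$prior, x$class_means["deficient"], x$class_means["excess"]))
  cat(sprintf("  Wilks' Lambda = %.3f (p = %.3g); Box's M = %.2f (p = %.3g)\n",
              x$wilks_lambda, x$wilks_p, x$box_m, x$box_m_p))
  invisible(x)
}

#' Discriminant scores and class predictions
#'
#' @param object a [fisher_lda()] model.
#' @param newdata subjects x features matrix on the model's variables.
#' @param type `"class"` (default) or `"score"`.
#' @param ... unused.
#' @return predicted labels, or numeric scores.
#' @export
predict.fisher_lda <- function(object, newdata, type = c("class", "score"), ...) {
  type <- match.arg(type)
  newdata <- as_numeric_matrix(newdata)
  if (ncol(newdata) != length(object$raw_coefficients))
    stop("newdata must have ", length(object$raw_coefficients), " columns")
  score <- drop(newdata %*% object$raw_coefficients) + object$constant
  if (type == "score") return(score)
  ifelse(score >= object$cutoff, "excess", "deficient")
}

#' Wilks' Lambda for a two-class discriminant
#'
#' `Lambda = det(W) / det(T)` with `W` the within-class and `T` the total
#' SSCP matrix; significance by the Bartlett chi-square approximation
#' `-(n - 1 - (p + g)/2) ln(Lambda)` on `p` degrees of freedom (g = 2).
#'
#' @param X subjects x features matrix.
#' @param y binary labels.
#' @return list with `lambda`, `statistic`, `df`, `p_value`.
#' @export
wilks_lambda <- function(X, y) {
  X <- as_numeric_matrix(X)
  y <- as.character(y)
  n <- nrow(X); p <- ncol(X); g <- 2L
  cls <- unique(y)
  if (length(cls) != 2L) stop("need exactly two classes")
  W <- matrix(0, p, p)
  for (k in cls) {
    Xk <- X[y == k, , drop = FALSE]
    W <- W + crossprod(sweep(Xk, 2L, colMeans(Xk)))
  }
  Tt <- crossprod(sweep(X, 2L, colMeans(X)))
  dT <- det(Tt)
  if (dT <= 0) stop("singular total SSCP matrix")
  lambda <- det(W) / dT
  stat <- -(n - 1 - (p + g) / 2) * log(lambda)
  df <- p * (g - 1)
  list(lambda = lambda, statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Box's M test of equal class covariance matrices
#'
#' `M = (n - g) ln|Sp| - sum_k (n_k - 1) ln|S_k|` with the standard
#' chi-square approximation on `p(p+1)(g-1)/2` degrees of freedom.
#'
#' @param X subjects x features matrix.
#' @param y binary labels.
#' @return list with `statistic` (uncorrected M), `chi_sq` (corrected),
#'   `df`, `p_value`.
#' @export
box_m <- function(X, y) {
  X <- as_numeric_matrix(X)
  y <- as.character(y)
  cls <- unique(y)
  g <- length(cls)
  if (g != 2L) stop("need exactly two classes")
  n <- nrow(X); p <- ncol(X)
  Sp <- matrix(0, p, p)
  logdets <- numeric(g); nk <- integer(g)
  for (i in seq_along(cls)) {
    Xk <- X[y == cls[i], , drop = FALSE]
    nk[i] <- nrow(Xk)
    if (nk[i] <= p) stop("class '", cls[i], "' has too few subjects (", nk[i],
                         ") for a ", p, "-variable covariance")
    Sk <- stats::cov(Xk)
    dk <- det(Sk)
    if (dk <= 0) stop("singular covariance in class '", cls[i], "'")
    logdets[i] <- log(dk)
    Sp <- Sp + (nk[i] - 1) * Sk
  }
  Sp <- Sp / (n - g)
  dSp <- det(Sp)
  if (dSp <= 0) stop("singular pooled covariance")
  M <- (n - g) * log(dSp) - sum((nk - 1) * logdets)
  c1 <- (2 * p^2 + 3 * p - 1) / (6 * (p + 1) * (g - 1)) *
    (sum(1 / (nk - 1)) - 1 / (n - g))
  chi <- M * (1 - c1)
  df <- p * (p + 1) * (g - 1) / 2
  list(statistic = M, chi_sq = chi, df = df,
       p_value = stats::pchisq(chi, df, lower.tail = FALSE))
}

# ---- leave-one-out cross-validation ----------------------------------------

#' Leave-one-out cross-validation of any fit/predict pair
#'
#' For each subject, refits on the other `n - 1` and predicts the held-out
#' subject. `model_fitter(X, y)` must return an object whose
#' `predict(model, newdata)` yields `"deficient"`/`"excess"` labels. Folds
#' that lose a class are skipped with a warning and excluded from the table.
#'
#' @param model_fitter function of `(X, y)` returning a fitted model.
#' @param X subjects x features matrix.
#' @param y labels.
#' @param predict_fun optional predictor `function(model, newdata)`;
#'   defaults to the S3 `predict` method.
#' @return a `cv_result`: `table` ([confusion()] of held-out predictions),
#'   `per_subject` predicted labels (NA where a fold was invalid).
#' @export
loocv <- function(model_fitter, X, y, predict_fun = NULL) {
  X <- as_numeric_matrix(X)
  y <- as.character(y)
  n <- nrow(X)
  if (n < 3L) stop("leave-one-out needs at least 3 subjects")
  if (is.null(predict_fun)) predict_fun <- function(m, nd) predict(m, nd)
  pred <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    yi <- y[-i]
    if (length(unique(yi)) < 2L) {
      warning("fold ", i, " loses a class; prediction marked invalid")
      next
    }
    fit <- model_fitter(X[-i, , drop = FALSE], yi)
    pred[i] <- predict_fun(fit, X[i, , drop = FALSE])
  }
  ok <- !is.na(pred)
  structure(list(table = confusion(y[ok], pred[ok]), per_subject = pred),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("Leave-one-out cross-validation\n")
  print(x$table)
  invisible(x)
}
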