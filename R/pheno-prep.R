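# Box-Cox profile log-likelihood for a transform parameter lambda:
# llik(lambda) = -n/2 * log(sigma^2(z)) + (lambda - 1) * sum(log(y))
# with z = (y^lambda - 1)/lambda (log(y) at lambda = 0) and sigma^2 the
# ML (divide-by-n) variance of z.
.boxcoxLogLik <- function(y, lambda) {
  n <- length(y)
  z <- if (abs(lambda) < 1e-12) log(y) else (y^lambda - 1) / lambda
  s2 <- sum((z - mean(z))^2) / n
  -n / 2 * log(s2) + (lambda - 1) * sum(log(y))
}

#' Fit a Box-Cox normality transformation
#'
#' Finds the power-transform parameter maximizing the Box-Cox profile
#' log-likelihood over [-3, 3] (Brent search, tolerance 1e-6) and returns
#' the transformed values \code{(y^lambda - 1)/lambda} (log at lambda = 0).
#' The transform is monotone increasing in the data for every lambda, so
#' value order is preserved.
#'
#' @param values positive numeric vector (NAs ignored for fitting, kept as
#'   NA in the output).
#' @param shift optional non-negative constant added to values before
#'   fitting when non-positive values are present; \code{NULL} (default)
#'   makes non-positive values an error.
#' @return list with \code{lambda}, \code{transformed} (same length as
#'   input), \code{shift}, and \code{logLik} at the optimum.
#' @examples
#' fit <- boxcoxFit(rlnorm(500))
#' fit$lambda   # near 0: the log transform
#' @export
boxcoxFit <- function(values, shift = NULL) {
  ok <- !is.na(values)
  y <- values[ok]
  .stopIfNot(length(y) >= 3, "need at least 3 non-missing values")
  if (is.null(shift)) shift <- 0
  y <- y + shift
  if (any(y <= 0))
    stop("values must be positive; supply a shift for non-positive values",
         call. = FALSE)
  opt <- optimize(function(l) .boxcoxLogLik(y, l), interval = c(-3, 3),
                  maximum = TRUE, tol = 1e-6)
  lambda <- opt$maximum
  z <- rep(NA_real_, length(values))
  z[ok] <- if (abs(lambda) < 1e-12) log(y) else (y^lambda - 1) / lambda
  list(lambda = lambda, transformed = z, shift = shift,
       logLik = opt$objective)
}

#' Remove SD-distance outliers in a single pass
#'
#' Flags values whose absolute distance from the mean exceeds
#' \code{sdThreshold} sample standard deviations, where mean and SD are
#' computed once on all non-missing values before any removal. Because the
#' pass is single, re-applying at the same threshold removes nothing new
#' unless remaining points exceed the threshold under the recomputed
#' statistics.
#'
#' @param values numeric vector (may contain NA).
#' @param sdThreshold positive distance threshold in units of sample SD
#'   (default 10, which removes outliers of the scale reported for lipid
#'   phenotypes, 13-18 SD, without touching plausible tails).
#' @return list with \code{kept} (values with removed entries set NA),
#'   \code{removed} data.frame(index, value, sdDistance), and the
#'   \code{mean} and \code{sd} used.
#' @export
removeOutliers <- function(values, sdThreshold = 10) {
  .stopIfNot(sdThreshold > 0, "sdThreshold must be > 0")
  ok <- !is.na(values)
  .stopIfNot(sum(ok) >= 3, "need at least 3 non-missing values")
  mu <- mean(values[ok])
  s <- sd(values[ok])
  if (s == 0) {
    warning("zero standard deviation: no outliers removed")
    return(list(kept = values,
                removed = data.frame(index = integer(), value = numeric(),
                                     sdDistance = numeric()),
                mean = mu, sd = s))
  }
  dist <- abs(values - mu) / s
  drop <- which(ok & dist > sdThreshold)
  kept <- values
  kept[drop] <- NA_real_
  list(kept = kept,
       removed = data.frame(index = drop, value = values[drop],
                            sdDistance = dist[drop]),
       mean = mu, sd = s)
}

#' Body mass index from weight and height
#'
#' BMI = weight / (height / 100)^2, weight in kg and height in cm.
#'
#' @param weightKg numeric vector.
#' @param heightCm numeric vector (> 0), recycled against weight.
#' @return numeric vector of BMI values.
#' @examples
#' computeBmi(70, 175)  # 22.86
#' @export
computeBmi <- function(weightKg, heightCm) {
  .stopIfNot(all(heightCm > 0, na.rm = TRUE), "height must be positive")
  weightKg / (heightCm / 100)^2
}

#' Build a fixed-effect design matrix
#'
#' Constructs the X matrix of the mixed model: an intercept, classification
#' variables expanded to full-rank treatment-coded indicators (first level
#' as reference), and numeric covariables as-is. Rows correspond to records
#' with a non-missing response; a missing covariate on such a record is an
#' error.
#'
#' @param data data.frame holding the response and covariates.
#' @param response name of the response column (used only to select rows).
#' @param classVars character vector of classification-variable columns.
#' @param covars character vector of numeric covariable columns.
#' @return numeric matrix X with attribute \code{"rows"} giving the row
#'   indices of \code{data} it aligns with.
#' @export
buildDesign <- function(data, response, classVars = character(),
                        covars = character()) {
  .stopIfNot(all(c(response, classVars, covars) %in% names(data)),
             "all named columns must exist in data")
  rows <- which(!is.na(data[[response]]))
  sub <- data[rows, , drop = FALSE]
  for (v in c(classVars, covars))
    if (anyNA(sub[[v]]))
      stop("missing covariate '", v, "' for a phenotyped record",
           call. = FALSE)
  terms <- character()
  for (v in classVars) {
    f <- droplevels(as.factor(sub[[v]]))
    if (nlevels(f) >= 2L) {
      sub[[v]] <- f
      terms <- c(terms, v)
    } # single-level factors contribute only the intercept
  }
  terms <- c(terms, covars)
  fml <- if (length(terms)) stats::reformulate(terms) else ~1
  X <- stats::model.matrix(fml, data = sub)
  attr(X, "rows") <- rows
  attr(X, "assign") <- NULL
  attr(X, "contrasts") <- NULL
  X
}
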