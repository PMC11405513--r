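# Piecewise log-linear life-course model: methylation trajectories are
# approximately linear in g(R), where g is logarithmic in relative age
# before the young/old knot and linear after it, with a continuous first
# derivative at the knot.

#' Log-linear relative-age transform and its derivative
#'
#' With knot k (default 0.1): \code{g(R) = R/k - 1} for \code{R >= k} and
#' \code{g(R) = log(R/k)} for \code{R < k} (natural log); both branches
#' give \code{g(k) = 0} and derivative \code{1/k} at the knot, so value and
#' slope are continuous. The alternative \code{g2(R) = log(R/k)}
#' everywhere. With the default knot these are \code{10R - 1} /
#' \code{log(10R)}.
#'
#' @param R relative ages in [0, 1]; must be positive wherever the
#'   logarithmic branch applies.
#' @param which \code{"g"} (piecewise, default) or \code{"g2"}
#'   (all-logarithmic).
#' @param knot relative-age knot in (0, 1), default 0.1.
#' @return list with \code{value} and \code{deriv} (dg/dR) vectors.
#' @examples
#' loglinearTransform(0.5)$value    # 4
#' loglinearTransform(0.05)$value   # log(0.5)
#' @export
loglinearTransform <- function(R, which = c("g", "g2"), knot = 0.1) {
  which <- match.arg(which)
  stopifnot(knot > 0, knot < 1, all(R >= 0), all(R <= 1))
  logBranch <- if (which == "g") R < knot else rep(TRUE, length(R))
  if (any(logBranch & R == 0))
    stop("R = 0 on a logarithmic branch: transform undefined")
  value <- ifelse(logBranch, log(R / knot), R / knot - 1)
  deriv <- ifelse(logBranch, 1 / R, 1 / knot)
  list(value = value, deriv = deriv)
}

#' Fit the life-course model
#'
#' Least squares fit of \code{y = gamma0 + gamma1 * g(R)}. The
#' \code{StratumView} method regresses the standardized methylation on the
#' transformed relative ages; the default (numeric) method takes relative
#' ages and a response directly. A warning is issued when the relative ages
#' do not span both sides of the knot, since the piecewise shape is then
#' unidentified from the data.
#'
#' @param object a \linkS4class{StratumView}, or a numeric vector of
#'   relative ages.
#' @param y response vector (numeric method only).
#' @param transform \code{"g"} or \code{"g2"}.
#' @param knot relative-age knot, default 0.1.
#' @param stratumId label carried into the fit (numeric method).
#' @return a \linkS4class{LifeCourseFit}.
#' @export
setGeneric("fitLifeCourse",
  function(object, ...) standardGeneric("fitLifeCourse"))

#' @rdname fitLifeCourse
#' @export
setMethod("fitLifeCourse", "numeric",
  function(object, y, transform = c("g", "g2"), knot = 0.1,
           stratumId = NA_character_) {
    transform <- match.arg(transform)
    R <- object
    stopifnot(length(R) == length(y), length(R) >= 3, !anyNA(R), !anyNA(y))
    if (!(any(R < knot) && any(R >= knot)))
      warning("relative ages do not span both sides of the knot (",
              knot, "); piecewise shape unidentified")
    tv <- loglinearTransform(R, transform, knot)$value
    if (.popsd(tv) == 0)
      stop("constant transformed relative ages")
    fit <- lm(y ~ tv)
    new("LifeCourseFit", stratumId = as.character(stratumId),
        transform = transform, gamma0 = unname(coef(fit)[1]),
        gamma1 = unname(coef(fit)[2]),
        pearsonR = if (.popsd(y) > 0) cor(y, tv) else NA_real_,
        n = length(R), knot = knot)
  })

#' @rdname fitLifeCourse
#' @export
setMethod("fitLifeCourse", "StratumView",
  function(object, transform = c("g", "g2"), knot = 0.1) {
    scaled <- object@scaled
    if (anyNA(scaled))
      .degenerate("constant or insufficient methylation", object@stratumId)
    fitLifeCourse(object@relAges, scaled, transform = match.arg(transform),
                  knot = knot, stratumId = object@stratumId)
  })

#' Derivative-based AROCM from a life-course fit
#'
#' The rate of change per year of age implied by the fitted curve at a
#' reference relative age: \code{gamma1 * g'(R0) / L} (chain rule through
#' \code{R = A/L}). At or above the knot this is \code{gamma1 * (1/knot) / L}
#' (the old-animal rate); below the knot it is
#' \code{gamma1 / (R0 * L)} (the young-animal rate).
#'
#' @param fit a \linkS4class{LifeCourseFit}.
#' @param L maximum lifespan, years, positive.
#' @param R0 reference relative age in (0, 1].
#' @return rate per year.
#' @examples
#' # gamma1 = 0.5, L = 20: rate at R0 = 0.4 is 0.5 * 10 / 20 = 0.25
#' @export
derivativeAROCM <- function(fit, L, R0) {
  stopifnot(is(fit, "LifeCourseFit"), L > 0, R0 > 0, R0 <= 1)
  d <- loglinearTransform(R0, fit@transform, fit@knot)$deriv
  fit@gamma1 * d / L
}

#' Young/old rate proportionality constant
#'
#' Under the life-course model the young rate is a fixed multiple of the
#' old rate within a stratum: \code{AROCM_young = knot / R_young *
#' AROCM_old}, i.e. \code{1 / (10 R_young)} with the default knot. The
#' constant tends to 1 as the young reference age approaches the knot.
#'
#' @param Ryoung young reference relative age, in (0, knot).
#' @param knot relative-age knot, default 0.1.
#' @return proportionality constant.
#' @examples
#' youngOldRelation(0.05)   # 2
#' @export
youngOldRelation <- function(Ryoung, knot = 0.1) {
  stopifnot(all(Ryoung > 0), all(Ryoung < knot))
  knot / Ryoung
}
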