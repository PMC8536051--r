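#' @include methods.R
NULL

.fitResult <- function(coefficients, r_squared, n_points, model) {
  structure(list(coefficients = coefficients, r_squared = r_squared,
                 n_points = n_points, model = model),
            class = "vdfreqFit")
}

#' @export
print.vdfreqFit <- function(x, ...) {
  cat("OLS fit (", x$n_points, " points): r_squared = ",
      format(x$r_squared, digits = 4), "\n", sep = "")
  print(x$coefficients)
  invisible(x)
}

#' Ordinary least-squares line with coefficient of determination
#'
#' Simple linear regression of y on x. r_squared = 1 - SS_res/SS_tot equals
#' the squared Pearson correlation. A constant response is degenerate:
#' r_squared is defined as 0 with a warning.
#'
#' @param x predictor vector
#' @param y response vector, same length
#' @return a fit object: \code{coefficients} (intercept, slope),
#'   \code{r_squared}, \code{n_points}, and the underlying \code{lm} as
#'   \code{model}
#' @export
linearFit <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  if (stats::var(x) == 0) stop("x is constant; slope undefined")
  fit <- stats::lm(y ~ x)
  if (stats::var(y) == 0) {
    warning("constant response; r_squared set to 0")
    r2 <- 0
  } else {
    r2 <- 1 - sum(stats::resid(fit)^2) / sum((y - mean(y))^2)
  }
  .fitResult(stats::setNames(stats::coef(fit), c("intercept", "slope")),
             r2, length(x), fit)
}

#' Least-squares quadratic
#'
#' Degree-2 polynomial fit, used for the U-shaped relation between
#' population mean risk score and native-population vitamin D concentration.
#' Interpolates exactly at three distinct x.
#'
#' @param x predictor (population mean composite risk score)
#' @param y response (mean 25(OH)D3 concentration, ng/mL)
#' @return a fit object as in \code{\link{linearFit}}, coefficients
#'   (intercept, slope, quadratic)
#' @export
quadraticFit <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (length(unique(x)) < 3)
    stop("need at least three distinct x for a quadratic fit")
  fit <- stats::lm(y ~ x + I(x^2))
  r2 <- if (stats::var(y) == 0) 0 else
    1 - sum(stats::resid(fit)^2) / sum((y - mean(y))^2)
  .fitResult(stats::setNames(stats::coef(fit),
                             c("intercept", "slope", "quadratic")),
             r2, length(x), fit)
}

#' Difference regressions against a reference population
#'
#' For every non-reference population, forms the differences in vitamin D
#' concentration, mean risk score, and latitude relative to the reference
#' population, then fits concentration difference on score difference and on
#' latitude difference side by side. Comparing the two r_squared values asks
#' whether between-population concentration differences track genetics or
#' geography. Invariant to adding a constant to all concentrations or all
#' latitudes.
#'
#' @param phenotypes data.frame with columns \code{population},
#'   \code{concentration} (ng/mL), \code{latitude} (signed degrees),
#'   \code{grs} (mean composite score)
#' @param reference reference population label (default \code{"EUR"})
#' @return list: \code{grs_fit}, \code{latitude_fit} (fit objects) and
#'   \code{differences}, the per-population difference table
#' @export
differenceAnalysis <- function(phenotypes, reference = "EUR") {
  ph <- as.data.frame(phenotypes)
  stopifnot(all(c("population", "concentration", "latitude", "grs")
                %in% names(ph)))
  iref <- which(ph$population == reference)
  if (!length(iref)) stop("reference population not present: ", reference)
  iref <- iref[1L]
  rest <- ph[-iref, , drop = FALSE]
  if (nrow(rest) < 2) stop("need at least two non-reference populations")
  d <- data.frame(population = rest$population,
                  d_concentration = rest$concentration -
                    ph$concentration[iref],
                  d_grs = rest$grs - ph$grs[iref],
                  d_latitude = rest$latitude - ph$latitude[iref])
  list(grs_fit = linearFit(d$d_grs, d$d_concentration),
       latitude_fit = linearFit(d$d_latitude, d$d_concentration),
       differences = d)
}

#' Read a population phenotype table
#'
#' @param path TSV with columns \code{population},
#'   \code{concentration_ng_per_ml}, \code{latitude_deg}
#' @return data.frame with columns population, concentration, latitude
#' @export
readPhenotypeTable <- function(path) {
  tb <- utils::read.delim(path)
  need <- c("population", "concentration_ng_per_ml", "latitude_deg")
  miss <- setdiff(need, names(tb))
  if (length(miss))
    stop("phenotype file lacks column(s): ", paste(miss, collapse = ", "))
  if (any(tb$concentration_ng_per_ml <= 0))
    stop("concentrations must be positive")
  if (any(abs(tb$latitude_deg) > 90))
    stop("latitudes must lie in [-90, 90]")
  data.frame(population = tb$population,
             concentration = tb$concentration_ng_per_ml,
             latitude = tb$latitude_deg)
}
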