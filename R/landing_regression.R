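#' Nonlinear landing-height regression model
#'
#' One of the three forms used to relate landing height x (cm) to a
#' sagittal kinematic/kinetic variable: power \code{y = a x^b},
#' natural-log \code{y = a ln(x) + b} or exponential \code{y = a e^(b x)}.
#'
#' @param form one of \code{"power"}, \code{"log"}, \code{"exp"}.
#' @param a,b coefficients.
#' @param variable optional variable label.
#' @param r_squared optional reported R-squared.
#' @return object of class \code{regression_model}.
#' @export
regression_model <- function(form = c("power", "log", "exp"), a, b,
                             variable = NULL, r_squared = NULL) {
  form <- match.arg(form)
  if (!is.null(r_squared)) stopifnot(r_squared >= 0, r_squared <= 1)
  structure(list(form = form, a = a, b = b, variable = variable,
                 r_squared = r_squared),
            class = "regression_model")
}

#' Shipped height-regression models for the seven sagittal variables
#'
#' Coefficients of the literature-derived regressions of sagittal
#' kinematics/kinetics and vertical ground reaction force on landing height
#' (x in cm). Angles in degrees, moments in N.m/kg, vertical GRF in body
#' weights.
#'
#' @return named list of seven \code{\link{regression_model}}s.
#' @export
default_landing_models <- function() {
  list(
    hip_flex_angle    = regression_model("power", 3.3896, 0.557,
                                         "hip_flex_angle", 0.9418),
    knee_flex_angle   = regression_model("log", 14.769, -15.237,
                                         "knee_flex_angle", 0.9082),
    ankle_dorsi_angle = regression_model("exp", 8.1108, 0.0068,
                                         "ankle_dorsi_angle", 0.9811),
    hip_flex_moment   = regression_model("power", 0.0096, 0.7563,
                                         "hip_flex_moment", 0.9486),
    knee_flex_moment  = regression_model("power", 0.0699, 0.3704,
                                         "knee_flex_moment", 0.9129),
    ankle_dorsi_moment = regression_model("log", 0.1086, -0.2315,
                                          "ankle_dorsi_moment", 0.9187),
    vgrf              = regression_model("power", 0.4468, 0.542,
                                         "vgrf", 0.9463))
}

#' Evaluate a regression model at a landing height
#'
#' @param model a \code{\link{regression_model}}.
#' @param height landing height, cm (> 0); vectorised.
#' @return predicted value(s).
#' @export
evaluate_regression <- function(model, height) {
  if (any(height <= 0)) stop("height must be positive")
  switch(model$form,
         power = model$a * height^model$b,
         log   = model$a * log(height) + model$b,
         exp   = model$a * exp(model$b * height))
}

#' Fit a height-regression model
#'
#' Nonlinear least squares with a log-transform linearisation as the
#' initialiser: power and exponential forms are seeded from a linear fit in
#' log space and refined by \code{\link[minpack.lm]{nlsLM}}; the log form
#' is linear in its coefficients and solved exactly.
#'
#' @param heights landing heights, cm (at least 3 distinct, > 0).
#' @param values observed variable values.
#' @param form regression form; see \code{\link{regression_model}}.
#' @param variable optional label.
#' @return fitted \code{\link{regression_model}} with its R-squared.
#' @export
fit_regression <- function(heights, values,
                           form = c("power", "log", "exp"),
                           variable = NULL) {
  form <- match.arg(form)
  if (length(unique(heights)) < 3) stop("need at least 3 distinct heights")
  if (any(heights <= 0)) stop("heights must be positive")
  df <- data.frame(x = heights, y = values)
  if (form == "log") {
    lf <- stats::lm(y ~ log(x), data = df)
    a <- unname(stats::coef(lf)[2])
    b <- unname(stats::coef(lf)[1])
    if (is.na(a)) a <- 0 # degenerate: constant data
    pred <- a * log(df$x) + b
  } else {
    if (any(values <= 0))
      stop(sprintf("the %s form requires positive values", form))
    if (stats::sd(values) == 0) {
      # constant data: exact fit with a flat exponent
      return(regression_model(form, values[1], 0, variable, 1))
    }
    init <- if (form == "power") {
      lf <- stats::lm(log(y) ~ log(x), data = df)
      list(a = exp(unname(stats::coef(lf)[1])), b = unname(stats::coef(lf)[2]))
    } else {
      lf <- stats::lm(log(y) ~ x, data = df)
      list(a = exp(unname(stats::coef(lf)[1])), b = unname(stats::coef(lf)[2]))
    }
    if (!is.finite(init$b)) init$b <- 0
    fml <- if (form == "power") y ~ a * x^b else y ~ a * exp(b * x)
    fit <- minpack.lm::nlsLM(fml, data = df, start = init,
                             control = minpack.lm::nls.lm.control(maxiter = 200))
    a <- unname(stats::coef(fit)["a"])
    b <- unname(stats::coef(fit)["b"])
    pred <- stats::predict(fit)
  }
  ss_res <- sum((values - pred)^2)
  ss_tot <- sum((values - mean(values))^2)
  r2 <- if (ss_tot == 0) 1 else max(0, min(1, 1 - ss_res / ss_tot))
  regression_model(form, a, b, variable, r2)
}

#' Fit all three forms and keep the best
#'
#' Fits power, log and exponential models and returns the one with the
#' highest R-squared; ties within 1e-12 break deterministically in the
#' order power > log > exp. Forms whose positivity requirements the data
#' violate are skipped.
#'
#' @inheritParams fit_regression
#' @return the selected \code{\link{regression_model}}; attribute
#'   \code{candidates} holds the R-squared of every fitted form.
#' @export
select_best_form <- function(heights, values, variable = NULL) {
  forms <- c("power", "log", "exp")
  fits <- list()
  for (f in forms) {
    fits[[f]] <- tryCatch(fit_regression(heights, values, f, variable),
                          error = function(e) NULL)
  }
  fits <- Filter(Negate(is.null), fits)
  if (length(fits) == 0) stop("no form could be fitted")
  r2 <- vapply(fits, function(m) m$r_squared, numeric(1))
  best <- names(fits)[which(r2 >= max(r2) - 1e-12)][1] # tie-break by order
  out <- fits[[best]]
  attr(out, "candidates") <- r2
  out
}

#' Shipped frontal/transversal (coupled-plane) means
#'
#' The coupled-plane kinematics and kinetics depend only weakly on landing
#' height, so height-independent means are used. No tabulated values exist
#' for them; these defaults are package fixtures (angles in degrees,
#' moments in N.m/kg) and should be replaced with study-specific means
#' where available.
#'
#' @return named numeric vector.
#' @export
default_coupled_means <- function() {
  c(hip_add_angle = 4.0, hip_int_rot_angle = 3.0,
    knee_abd_angle = 5.0, knee_int_rot_angle = 8.0,
    ankle_inv_angle = 2.0,
    hip_add_moment = 0.40, knee_abd_moment = 0.35,
    knee_int_rot_moment = 0.10, ankle_inv_moment = 0.08)
}

#' Assemble a complete landing profile at a height
#'
#' Evaluates the seven sagittal regressions and attaches the
#' height-independent coupled-plane means.
#'
#' @param height landing height, cm.
#' @param coupled_means named numeric vector of coupled-plane values.
#' @param models list of seven regression models
#'   (default \code{\link{default_landing_models}}).
#' @param validity height range (cm) considered interpolation; heights
#'   above \code{warn_above} trigger an extrapolation warning (the
#'   regressions were built from drop tests at much lower heights).
#' @param warn_above extrapolation warning threshold, cm.
#' @return object of class \code{landing_profile}: list with \code{height},
#'   \code{sagittal} (named vector) and \code{coupled} (named vector).
#' @export
predict_profile <- function(height, coupled_means = default_coupled_means(),
                            models = default_landing_models(),
                            validity = c(10, 150), warn_above = 60) {
  if (height < validity[1] || height > validity[2])
    stop(sprintf("height %.1f cm outside validity range [%g, %g]",
                 height, validity[1], validity[2]))
  if (height > warn_above)
    warning(sprintf("height %.0f cm extrapolates beyond the %g cm range of the source data",
                    height, warn_above))
  sag <- vapply(models, evaluate_regression, numeric(1), height = height)
  structure(list(height = height, sagittal = sag, coupled = coupled_means),
            class = "landing_profile")
}
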