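# Retention-index calibration and binary linear RI prediction models.
#
# Reversed-phase retention times drift run-to-run; normalizing RT against a
# homologous series of DMED-labeled saturated fatty acids (C20-C30) gives a
# retention index that is stable across batches.  The calibrant RTs are
# linear in carbon number, RT = k * n + b, and the RI of an analyte is
# RI = 100 * (RT - b) / k, so a Cn calibrant has RI = 100 n by construction.
#
# Within a FAHFA family series sharing one HFA backbone, RI obeys two
# retention rules: it increases with the carbon number of the FA partner
# (x1) and decreases with the ester position (x2).  A two-predictor linear
# model RI = intercept + a * x1 + c * x2, fitted per backbone, predicts the
# RI of unmeasured regioisomers; predicted RIs drive annotation.

#' Fit the calibrant RT line
#'
#' Ordinary least squares of retention time on calibrant carbon number.
#'
#' @param obs data frame with columns `carbon_number` (integer) and
#'   `rt_min` (minutes), one row per calibrant.
#' @return an object of class `ri_calibration` with components `k` (slope,
#'   min/carbon), `b` (intercept, min), `r_squared` and `observations`.
#'   A fit with `r_squared < 0.95` triggers a warning (severe misfit of the
#'   homologous-series assumption) but is still returned.
#' @examples
#' cal <- fit_ri_calibration(data.frame(carbon_number = 20:30,
#'                                      rt_min = 0.3 * (20:30) + 1))
#' coef(cal)
#' @export
fit_ri_calibration <- function(obs) {
  stopifnot(is.data.frame(obs),
            all(c("carbon_number", "rt_min") %in% names(obs)))
  if (length(unique(obs$carbon_number)) < 2L) {
    stop("calibration needs at least 2 distinct carbon numbers")
  }
  if (any(obs$rt_min <= 0)) stop("calibrant retention times must be positive")
  fit <- stats::lm(rt_min ~ carbon_number, data = obs)
  r2 <- .r_squared(fit, obs$rt_min)
  k <- unname(stats::coef(fit)["carbon_number"])
  if (k <= 0) stop("calibration slope must be positive; got ", signif(k, 4))
  if (r2 < 0.95) {
    warning("calibration r-squared ", signif(r2, 4),
            " below 0.95; calibrant series may be unusable")
  }
  structure(
    list(k = k, b = unname(stats::coef(fit)["(Intercept)"]),
         r_squared = r2, observations = obs, fit = fit),
    class = "ri_calibration"
  )
}

#' @export
coef.ri_calibration <- function(object, ...) c(k = object$k, b = object$b)

#' @export
print.ri_calibration <- function(x, ...) {
  cat("Retention-index calibration: RT = k * carbon + b\n")
  cat(sprintf("  k = %.5f min/carbon, b = %.5f min, r-squared = %.5f (n = %d)\n",
              x$k, x$b, x$r_squared, nrow(x$observations)))
  invisible(x)
}

#' @export
plot.ri_calibration <- function(x, ...) {
  graphics::plot(x$observations$carbon_number, x$observations$rt_min,
                 xlab = "calibrant carbon number", ylab = "retention time (min)",
                 main = "Calibrant series", ...)
  graphics::abline(x$b, x$k, col = "steelblue")
  invisible(x)
}

#' Convert retention time to retention index, and back
#'
#' `rt_to_ri()` applies RI = 100 * (RT - b) / k; `ri_to_rt()` is its exact
#' affine inverse.  A calibrant with n carbons sitting exactly on the
#' calibration line maps to RI = 100 n.
#'
#' @param rt retention time(s), minutes.
#' @param ri retention index value(s).
#' @param cal an [fit_ri_calibration()] object.
#' @return numeric vector of RIs (or RTs).
#' @export
rt_to_ri <- function(rt, cal) {
  stopifnot(inherits(cal, "ri_calibration"))
  100 * (rt - cal$b) / cal$k
}

#' @rdname rt_to_ri
#' @export
ri_to_rt <- function(ri, cal) {
  stopifnot(inherits(cal, "ri_calibration"))
  cal$b + cal$k * ri / 100
}

#' Fit a binary linear RI prediction model for one HFA backbone
#'
#' Ordinary least squares of retention index on the FA carbon number (x1)
#' and the ester position (x2) over the regioisomers of one family series.
#'
#' @param obs data frame with columns `fa_carbon`, `ester_position`, `ri`.
#' @param hfa_key abbreviation of the fixed HFA backbone (e.g. `"14:0"`).
#' @return an object of class `ri_model` with the fitted `intercept`,
#'   `coef_fa_carbon`, `coef_ester_position`, `r_squared`, the observed
#'   predictor hulls (`fa_carbon_range`, `position_range`) and the
#'   underlying `lm` fit.
#' @examples
#' grid <- expand.grid(fa_carbon = 14:18, ester_position = 5:12)
#' grid$ri <- 1131 + 97 * grid$fa_carbon - 29 * grid$ester_position
#' fit_ri_model(grid, "14:0")
#' @export
fit_ri_model <- function(obs, hfa_key) {
  stopifnot(is.data.frame(obs),
            all(c("fa_carbon", "ester_position", "ri") %in% names(obs)))
  if (nrow(obs) < 3L) stop("need at least 3 observations")
  if (length(unique(obs$fa_carbon)) < 2L) {
    stop("rank-deficient design: fa_carbon takes a single value")
  }
  if (length(unique(obs$ester_position)) < 2L) {
    stop("rank-deficient design: ester_position takes a single value")
  }
  fit <- stats::lm(ri ~ fa_carbon + ester_position, data = obs)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design: collinear predictor ", paste(bad, collapse = ", "))
  }
  cf <- stats::coef(fit)
  structure(
    list(
      hfa_key = hfa_key,
      intercept = unname(cf["(Intercept)"]),
      coef_fa_carbon = unname(cf["fa_carbon"]),
      coef_ester_position = unname(cf["ester_position"]),
      r_squared = .r_squared(fit, obs$ri),
      fa_carbon_range = range(obs$fa_carbon),
      position_range = range(obs$ester_position),
      observations = obs,
      fit = fit
    ),
    class = "ri_model"
  )
}

# coefficient of determination without summary.lm's perfect-fit warning
.r_squared <- function(fit, y) {
  sst <- sum((y - mean(y))^2)
  if (sst == 0) return(1)
  max(0, min(1, 1 - sum(stats::residuals(fit)^2) / sst))
}

# manual constructor used for the shipped literature models
.ri_model <- function(hfa_key, intercept, coef_fa_carbon, coef_ester_position,
                      r_squared, fa_carbon_range, position_range) {
  structure(
    list(hfa_key = hfa_key, intercept = intercept,
         coef_fa_carbon = coef_fa_carbon,
         coef_ester_position = coef_ester_position, r_squared = r_squared,
         fa_carbon_range = fa_carbon_range, position_range = position_range,
         observations = NULL, fit = NULL),
    class = "ri_model"
  )
}

#' Shipped RI prediction models
#'
#' The three published cycle-prediction models for the saturated C14:0,
#' C16:0 and C18:0 HFA backbone series (FA partners C14-C18 saturated):
#' \itemize{
#'   \item C14:0: RI = 1131 + 97 x1 - 29 x2, r-squared 0.9989
#'   \item C16:0: RI = 1429 + 90 x1 - 29 x2, r-squared 0.9982
#'   \item C18:0: RI = 1704 + 83 x1 - 28 x2, r-squared 0.9976
#' }
#' where x1 is the FA carbon number and x2 the ester position.  The default
#' position grid is 5..12 per backbone.
#'
#' @return a named list of `ri_model` objects (`"14:0"`, `"16:0"`, `"18:0"`).
#' @export
shipped_ri_models <- function() {
  list(
    "14:0" = .ri_model("14:0", 1131, 97, -29, 0.9989, c(14L, 18L), c(5L, 12L)),
    "16:0" = .ri_model("16:0", 1429, 90, -29, 0.9982, c(14L, 18L), c(5L, 12L)),
    "18:0" = .ri_model("18:0", 1704, 83, -28, 0.9976, c(14L, 18L), c(5L, 12L))
  )
}

#' @export
coef.ri_model <- function(object, ...) {
  c(intercept = object$intercept,
    fa_carbon = object$coef_fa_carbon,
    ester_position = object$coef_ester_position)
}

#' @export
print.ri_model <- function(x, ...) {
  cat(sprintf("RI prediction model, HFA backbone %s:\n", x$hfa_key))
  cat(sprintf("  RI = %.4g + %.4g * fa_carbon %+.4g * ester_position (r-squared %.4f)\n",
              x$intercept, x$coef_fa_carbon, x$coef_ester_position, x$r_squared))
  cat(sprintf("  fitted hull: fa_carbon %d..%d, ester position %d..%d\n",
              x$fa_carbon_range[1], x$fa_carbon_range[2],
              x$position_range[1], x$position_range[2]))
  invisible(x)
}

#' @export
summary.ri_model <- function(object, ...) {
  if (is.null(object$fit)) {
    print(object)
    return(invisible(object))
  }
  summary(object$fit, ...)
}

#' @export
residuals.ri_model <- function(object, ...) {
  if (is.null(object$fit)) stop("shipped literature models carry no residuals")
  stats::residuals(object$fit)
}

#' Predict the retention index of a regioisomer
#'
#' @param model an `ri_model`.
#' @param fa_carbon FA carbon number(s) (x1).
#' @param position ester position(s) (x2).
#' @param warn_extrapolation warn when a query leaves the fitted hull
#'   (extrapolation is allowed; the family series themselves extrapolate
#'   within C14-C18).
#' @return predicted RI value(s).
#' @examples
#' predict_ri(shipped_ri_models()[["16:0"]], 16, 9)  # 2608
#' @export
predict_ri <- function(model, fa_carbon, position, warn_extrapolation = TRUE) {
  stopifnot(inherits(model, "ri_model"))
  if (warn_extrapolation &&
      (any(fa_carbon < model$fa_carbon_range[1] | fa_carbon > model$fa_carbon_range[2]) ||
       any(position < model$position_range[1] | position > model$position_range[2]))) {
    warning("prediction outside the fitted hull of the ", model$hfa_key,
            " backbone model (extrapolating)")
  }
  model$intercept + model$coef_fa_carbon * fa_carbon +
    model$coef_ester_position * position
}

#' @export
predict.ri_model <- function(object, newdata, ...) {
  stopifnot(is.data.frame(newdata),
            all(c("fa_carbon", "ester_position") %in% names(newdata)))
  predict_ri(object, newdata$fa_carbon, newdata$ester_position, ...)
}

#' Simulate noisy RI observations from a model
#'
#' Draws `nsim` replicate datasets on the model's predictor grid with
#' additive Gaussian noise, for coefficient-recovery studies.
#'
#' @param object an `ri_model`.
#' @param nsim number of replicate datasets.
#' @param seed optional seed, set once before drawing.
#' @param noise_sd Gaussian noise standard deviation in RI units.
#' @param grid data frame of `fa_carbon`, `ester_position` design points;
#'   defaults to the full integer grid of the model's ranges.
#' @param ... unused.
#' @return a list of `nsim` data frames with columns `fa_carbon`,
#'   `ester_position`, `ri`.
#' @export
simulate.ri_model <- function(object, nsim = 1, seed = NULL, noise_sd = 3,
                              grid = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(grid)) {
    grid <- expand.grid(
      fa_carbon = seq(object$fa_carbon_range[1], object$fa_carbon_range[2]),
      ester_position = seq(object$position_range[1], object$position_range[2])
    )
  }
  mu <- predict_ri(object, grid$fa_carbon, grid$ester_position,
                   warn_extrapolation = FALSE)
  lapply(seq_len(nsim), function(i) {
    out <- grid
    out$ri <- mu + stats::rnorm(nrow(grid), 0, noise_sd)
    out
  })
}

#' @export
plot.ri_model <- function(x, ...) {
  grid <- expand.grid(
    fa_carbon = seq(x$fa_carbon_range[1], x$fa_carbon_range[2]),
    ester_position = seq(x$position_range[1], x$position_range[2])
  )
  ri <- predict_ri(x, grid$fa_carbon, grid$ester_position,
                   warn_extrapolation = FALSE)
  graphics::matplot(
    matrix(grid$ester_position, ncol = length(unique(grid$fa_carbon))),
    matrix(ri, ncol = length(unique(grid$fa_carbon))),
    type = "b", pch = 1, lty = 1,
    xlab = "ester position", ylab = "retention index",
    main = sprintf("RI model, HFA backbone %s", x$hfa_key), ...
  )
  invisible(x)
}

#' Expand RI models into a prediction table
#'
#' One row per (FA carbon, ester position) grid point of each model,
#' tagged with its family key.  FA partners are taken as saturated, so a
#' model with FA range 14..18 spans five families.
#'
#' @param models list of `ri_model` objects (default: the shipped models).
#' @param positions optional integer vector of ester positions to use for
#'   every model (default: each model's own `position_range`).
#' @return data frame with columns `family`, `hfa`, `fa_carbon`,
#'   `ester_position`, `predicted_ri`.
#' @export
expand_predictions <- function(models = shipped_ri_models(), positions = NULL) {
  rows <- lapply(models, function(m) {
    pos <- if (is.null(positions)) {
      seq(m$position_range[1], m$position_range[2])
    } else {
      positions
    }
    grid <- expand.grid(
      fa_carbon = seq(m$fa_carbon_range[1], m$fa_carbon_range[2]),
      ester_position = pos
    )
    chain <- parse_shorthand(m$hfa_key)
    data.frame(
      family = vapply(grid$fa_carbon, function(cc) {
        family_key(fatty_acyl(cc, 0L), chain)
      }, character(1)),
      hfa = m$hfa_key,
      fa_carbon = grid$fa_carbon,
      ester_position = grid$ester_position,
      predicted_ri = predict_ri(m, grid$fa_carbon, grid$ester_position,
                                warn_extrapolation = FALSE),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read / write calibrant tables and prediction tables
#'
#' Calibrant files are TSV with columns `carbon_number`, `rt_min`;
#' prediction tables are CSV as produced by [expand_predictions()].
#'
#' @param path file path.
#' @param predictions prediction table.
#' @return data frames / `path` invisibly.
#' @export
read_calibrants <- function(path) {
  obs <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("carbon_number", "rt_min") %in% names(obs))) {
    stop("calibrant table needs columns carbon_number, rt_min")
  }
  obs
}

#' @rdname read_calibrants
#' @export
write_predictions <- function(predictions, path) {
  utils::write.csv(predictions, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
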