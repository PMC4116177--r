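# Validation-assay mathematics: fluorescence-polarization signal, one-site
# competition logistic fitting (IC50), Boltzmann two-state melt fitting
# (Tm), and cross-receptor fold-change classification.
#
# Both fitters follow the classic R modelling idiom: a fitting function
# returning a classed object with print/summary/coef/vcov/predict/plot/
# residuals/fitted/simulate methods. Nonlinear least squares is delegated
# to Levenberg-Marquardt (minpack.lm); unweighted, as plate readers give no
# per-well error model.

#' Fluorescence polarization from paired intensities
#'
#' `P = (F_par - F_perp) / (F_par + F_perp)`. The instrument literature
#' uses both "polarization" and "anisotropy" for this ratio; the formula
#' implemented is exactly the one above (the anisotropy proper would carry
#' `2 F_perp` in the denominator).
#'
#' @param f_parallel,f_perpendicular Non-negative fluorescence intensities
#'   (vectorised).
#' @return Polarization values in \[-1, 1\].
#' @export
polarization <- function(f_parallel, f_perpendicular) {
  if (any(f_parallel < 0) || any(f_perpendicular < 0))
    stop("fluorescence intensities must be non-negative")
  tot <- f_parallel + f_perpendicular
  if (any(tot == 0))
    stop("polarization undefined when both intensities are zero")
  (f_parallel - f_perpendicular) / tot
}

#' One-site competition curve container
#'
#' @param concentration Competitor concentrations in mol/L, strictly
#'   positive. Zero-concentration control wells must be excluded before
#'   fitting (they are reported separately by the plate reader utilities).
#' @param p Polarization values.
#' @param ligand,receptor Optional labels.
#' @return Data frame of class `CompetitionCurve`, ordered by
#'   concentration.
#' @export
competition_curve <- function(concentration, p, ligand = NA_character_,
                              receptor = NA_character_) {
  stopifnot(length(concentration) == length(p))
  if (any(concentration <= 0))
    stop("concentrations must be strictly positive (mol/L); drop ",
         "zero-concentration control wells before fitting")
  if (length(concentration) < 5L)
    stop("a competition curve needs at least 5 points")
  o <- order(concentration)
  out <- data.frame(concentration = concentration[o], p = p[o])
  attr(out, "ligand") <- ligand
  attr(out, "receptor") <- receptor
  class(out) <- c("CompetitionCurve", "data.frame")
  out
}

competition_model <- function(logx, min, max, log_ic50, hill) {
  min + (max - min) / (1 + 10^(hill * (logx - log_ic50)))
}

#' Fit a one-site competition logistic curve
#'
#' Least-squares fit, in log10-concentration space, of
#' `y = min + (max - min) / (1 + 10^(hill (log10 x - logIC50)))`.
#' In `three_param` mode (default) the hill slope is fixed at 1; in
#' `four_param` mode it is free. Starting values: `min = min(y)`,
#' `max = max(y)`, `logIC50` interpolated at half range, `hill = 1`.
#' Non-convergence or a degenerate (flat) curve is flagged on the result,
#' not raised.
#'
#' @param curve A `CompetitionCurve` (or data frame with `concentration`
#'   in mol/L and `p` columns).
#' @param mode `"three_param"` or `"four_param"`.
#' @return Object of class `competition_fit`: coefficients (`min`, `max`,
#'   `log_ic50`, `hill`), standard errors, `ic50` (mol/L), `rss`,
#'   `converged`, the underlying `nls` fit, data, and mode.
#' @export
fit_competition <- function(curve, mode = c("three_param", "four_param")) {
  mode <- match.arg(mode)
  df <- as.data.frame(curve)
  stopifnot(all(c("concentration", "p") %in% names(df)))
  if (any(df$concentration <= 0)) stop("concentrations must be positive")
  n_par <- if (mode == "three_param") 3L else 4L
  if (nrow(df) < n_par + 1L)
    stop("need at least ", n_par + 1L, " points to fit ", n_par,
         " parameters")
  dat <- data.frame(logx = log10(df$concentration), y = df$p)

  y_lo <- min(dat$y); y_hi <- max(dat$y)
  half <- (y_lo + y_hi) / 2
  # interpolate log-concentration at half range for the midpoint start
  o <- order(dat$logx)
  lx <- dat$logx[o]; yy <- dat$y[o]
  start_mid <- tryCatch(stats::approx(yy, lx, xout = half, ties = mean)$y,
                        error = function(e) NA_real_)
  if (!is.finite(start_mid)) start_mid <- stats::median(lx)

  fml <- if (mode == "three_param")
    y ~ competition_model(logx, min, max, log_ic50, 1)
  else
    y ~ competition_model(logx, min, max, log_ic50, hill)
  start <- list(min = y_lo, max = y_hi, log_ic50 = start_mid)
  if (mode == "four_param") start$hill <- 1

  fit <- tryCatch(
    minpack.lm::nlsLM(fml, data = dat, start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)

  out <- list(mode = mode, data = df,
              ligand = attr(curve, "ligand") %||% NA_character_,
              receptor = attr(curve, "receptor") %||% NA_character_)
  if (inherits(fit, "error")) {
    out$converged <- FALSE
    out$message <- conditionMessage(fit)
    out$coefficients <- c(min = NA_real_, max = NA_real_,
                          log_ic50 = NA_real_, hill = NA_real_)
    out$se <- out$coefficients
    out$rss <- NA_real_
    class(out) <- "competition_fit"
    return(out)
  }
  cf <- stats::coef(fit)
  if (mode == "three_param") cf["hill"] <- 1
  sm <- summary(fit)
  se <- sm$coefficients[, "Std. Error"]
  if (mode == "three_param") se["hill"] <- 0
  conv <- isTRUE(fit$convInfo$isConv) &&
    is.finite(cf["max"]) && is.finite(cf["min"]) &&
    (cf["max"] - cf["min"]) > 4 * sm$sigma  # flat curves are not a fit
  out$fit <- fit
  out$coefficients <- cf[c("min", "max", "log_ic50", "hill")]
  out$se <- se[c("min", "max", "log_ic50", "hill")]
  out$rss <- sum(stats::resid(fit)^2)
  out$sigma <- sm$sigma
  out$converged <- conv
  class(out) <- "competition_fit"
  out
}

#' @method coef competition_fit
#' @export
coef.competition_fit <- function(object, ...) object$coefficients

#' @method vcov competition_fit
#' @export
vcov.competition_fit <- function(object, ...) {
  if (is.null(object$fit)) stop("fit did not converge; no covariance")
  stats::vcov(object$fit)
}

#' @export
fitted.competition_fit <- function(object, ...) {
  cf <- object$coefficients
  competition_model(log10(object$data$concentration), cf["min"], cf["max"],
                    cf["log_ic50"], cf["hill"])
}

#' @method residuals competition_fit
#' @export
residuals.competition_fit <- function(object, ...)
  object$data$p - fitted(object)

#' @export
predict.competition_fit <- function(object, newdata = NULL, ...) {
  conc <- if (is.null(newdata)) object$data$concentration
  else if (is.data.frame(newdata)) newdata$concentration
  else newdata
  cf <- object$coefficients
  competition_model(log10(conc), cf["min"], cf["max"], cf["log_ic50"],
                    cf["hill"])
}

#' @export
print.competition_fit <- function(x, ...) {
  cat("One-site competition fit (", x$mode, ")",
      if (!is.na(x$receptor)) paste0(" [", x$receptor,
                                     if (!is.na(x$ligand))
                                       paste0(" x ", x$ligand), "]"),
      "\n", sep = "")
  if (!x$converged) cat("  NOT CONVERGED",
                        if (!is.null(x$message))
                          paste0(" (", x$message, ")"), "\n", sep = "")
  cf <- x$coefficients; se <- x$se
  for (nm in names(cf))
    cat(sprintf("  %-9s %12.5g  (se %.3g)\n", nm, cf[nm], se[nm]))
  if (is.finite(cf["log_ic50"]))
    cat(sprintf("  IC50 = %.4g mol/L (%.3g nM)\n", 10^cf["log_ic50"],
                1e9 * 10^cf["log_ic50"]))
  invisible(x)
}

#' @method summary competition_fit
#' @export
summary.competition_fit <- function(object, ...) {
  out <- list(coefficients = cbind(Estimate = object$coefficients,
                                   `Std. Error` = object$se),
              ic50 = unname(10^object$coefficients["log_ic50"]),
              ic50_se = unname(log(10) * 10^object$coefficients["log_ic50"] *
                                 object$se["log_ic50"]),  # delta method
              rss = object$rss, converged = object$converged,
              mode = object$mode, n = nrow(object$data))
  class(out) <- "summary.competition_fit"
  out
}

#' @export
print.summary.competition_fit <- function(x, ...) {
  cat("One-site competition fit (", x$mode, "), n = ", x$n, "\n", sep = "")
  print(signif(x$coefficients, 5))
  cat(sprintf("IC50 %.4g mol/L (se %.2g), RSS %.4g, converged: %s\n",
              x$ic50, x$ic50_se, x$rss, x$converged))
  invisible(x)
}

#' @method plot competition_fit
#' @export
plot.competition_fit <- function(x, n_grid = 200, ...) {
  df <- x$data
  graphics::plot(df$concentration, df$p, log = "x",
                 xlab = "competitor concentration (mol/L)",
                 ylab = "polarization", ...)
  if (x$converged) {
    grid <- 10^seq(log10(min(df$concentration)),
                   log10(max(df$concentration)), length.out = n_grid)
    graphics::lines(grid, predict(x, grid))
    graphics::abline(v = 10^x$coefficients["log_ic50"], lty = 3)
  }
  invisible(x)
}

#' @export
simulate.competition_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) return(with_seed(seed, simulate(object, nsim)))
  mu <- fitted(object)
  sd <- object$sigma %||% stats::sd(residuals(object))
  out <- as.data.frame(replicate(nsim, mu + stats::rnorm(length(mu), 0, sd)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

# ---------------------------------------------------------------------------

boltzmann_model <- function(temp, folded, unfolded, tm, width) {
  unfolded + (folded - unfolded) / (1 + exp((temp - tm) / width))
}

#' Thermal melt curve container
#'
#' @param temperature Temperatures in degrees Celsius, strictly increasing,
#'   within \[0, 120\].
#' @param signal CD intensity at 222 nm (arbitrary units).
#' @param receptor Optional label.
#' @return Data frame of class `MeltCurve`.
#' @export
melt_curve <- function(temperature, signal, receptor = NA_character_) {
  stopifnot(length(temperature) == length(signal))
  if (length(temperature) < 8L) stop("a melt curve needs at least 8 points")
  if (any(diff(temperature) <= 0))
    stop("temperatures must be strictly increasing")
  if (any(temperature < 0 | temperature > 120))
    stop("temperatures must lie in [0, 120] degrees C")
  out <- data.frame(temperature = temperature, signal = signal)
  attr(out, "receptor") <- receptor
  class(out) <- c("MeltCurve", "data.frame")
  out
}

#' Fit a two-state Boltzmann thermal denaturation curve
#'
#' Least-squares fit of
#' `signal(T) = unfolded + (folded - unfolded) / (1 + exp((T - Tm)/width))`,
#' the two-state unfolding sigmoid. The midpoint `Tm` is the melting
#' temperature; `width` sets the transition steepness (degrees C).
#'
#' @param curve A `MeltCurve` (or data frame with `temperature` and
#'   `signal`).
#' @return Object of class `melt_fit` with coefficients (`folded`,
#'   `unfolded`, `tm`, `slope_width`), standard errors, `rss`,
#'   `converged`, the underlying `nls` fit.
#' @export
fit_melt <- function(curve) {
  df <- as.data.frame(curve)
  stopifnot(all(c("temperature", "signal") %in% names(df)))
  dat <- data.frame(temp = df$temperature, y = df$signal)
  y_lo_T <- mean(dat$y[dat$temp <= stats::quantile(dat$temp, 0.15)])
  y_hi_T <- mean(dat$y[dat$temp >= stats::quantile(dat$temp, 0.85)])
  half <- (y_lo_T + y_hi_T) / 2
  tm0 <- dat$temp[which.min(abs(dat$y - half))]
  start <- list(folded = y_lo_T, unfolded = y_hi_T, tm = tm0, width = 2)

  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ boltzmann_model(temp, folded, unfolded, tm, width),
                      data = dat, start = start,
                      lower = c(-Inf, -Inf, -Inf, 1e-6),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)

  out <- list(data = df, receptor = attr(curve, "receptor") %||% NA_character_)
  if (inherits(fit, "error")) {
    out$converged <- FALSE
    out$message <- conditionMessage(fit)
    out$coefficients <- c(folded = NA_real_, unfolded = NA_real_,
                          tm = NA_real_, slope_width = NA_real_)
    out$se <- out$coefficients
    out$rss <- NA_real_
    class(out) <- "melt_fit"
    return(out)
  }
  cf <- stats::coef(fit)
  sm <- summary(fit)
  se <- sm$coefficients[, "Std. Error"]
  conv <- isTRUE(fit$convInfo$isConv) &&
    cf["tm"] >= min(dat$temp) && cf["tm"] <= max(dat$temp) &&
    abs(cf["folded"] - cf["unfolded"]) > 4 * sm$sigma
  out$fit <- fit
  out$coefficients <- c(folded = unname(cf["folded"]),
                        unfolded = unname(cf["unfolded"]),
                        tm = unname(cf["tm"]),
                        slope_width = unname(cf["width"]))
  out$se <- c(folded = unname(se["folded"]), unfolded = unname(se["unfolded"]),
              tm = unname(se["tm"]), slope_width = unname(se["width"]))
  out$rss <- sum(stats::resid(fit)^2)
  out$sigma <- sm$sigma
  out$converged <- conv
  class(out) <- "melt_fit"
  out
}

#' @method coef melt_fit
#' @export
coef.melt_fit <- function(object, ...) object$coefficients

#' @method vcov melt_fit
#' @export
vcov.melt_fit <- function(object, ...) {
  if (is.null(object$fit)) stop("fit did not converge; no covariance")
  stats::vcov(object$fit)
}

#' @export
fitted.melt_fit <- function(object, ...) {
  cf <- object$coefficients
  boltzmann_model(object$data$temperature, cf["folded"], cf["unfolded"],
                  cf["tm"], cf["slope_width"])
}

#' @method residuals melt_fit
#' @export
residuals.melt_fit <- function(object, ...)
  object$data$signal - fitted(object)

#' @export
predict.melt_fit <- function(object, newdata = NULL, ...) {
  temp <- if (is.null(newdata)) object$data$temperature
  else if (is.data.frame(newdata)) newdata$temperature
  else newdata
  cf <- object$coefficients
  boltzmann_model(temp, cf["folded"], cf["unfolded"], cf["tm"],
                  cf["slope_width"])
}

#' @export
print.melt_fit <- function(x, ...) {
  cat("Two-state Boltzmann melt fit",
      if (!is.na(x$receptor)) paste0(" [", x$receptor, "]"), "\n", sep = "")
  if (!x$converged) cat("  NOT CONVERGED\n")
  cat(sprintf("  Tm = %.2f +/- %.2f degC, width = %.2f degC\n",
              x$coefficients["tm"], x$se["tm"],
              x$coefficients["slope_width"]))
  cat(sprintf("  baselines: folded %.4g, unfolded %.4g\n",
              x$coefficients["folded"], x$coefficients["unfolded"]))
  invisible(x)
}

#' @method summary melt_fit
#' @export
summary.melt_fit <- function(object, ...) {
  out <- list(coefficients = cbind(Estimate = object$coefficients,
                                   `Std. Error` = object$se),
              tm = unname(object$coefficients["tm"]),
              tm_se = unname(object$se["tm"]),
              rss = object$rss, converged = object$converged,
              n = nrow(object$data))
  class(out) <- "summary.melt_fit"
  out
}

#' @export
print.summary.melt_fit <- function(x, ...) {
  cat("Two-state Boltzmann melt fit, n =", x$n, "\n")
  print(signif(x$coefficients, 5))
  cat(sprintf("Tm %.2f +/- %.2f degC, RSS %.4g, converged: %s\n",
              x$tm, x$tm_se, x$rss, x$converged))
  invisible(x)
}

#' @method plot melt_fit
#' @export
plot.melt_fit <- function(x, n_grid = 200, ...) {
  df <- x$data
  graphics::plot(df$temperature, df$signal,
                 xlab = "temperature (degC)", ylab = "CD signal (222 nm)",
                 ...)
  if (x$converged) {
    grid <- seq(min(df$temperature), max(df$temperature),
                length.out = n_grid)
    graphics::lines(grid, predict(x, grid))
    graphics::abline(v = x$coefficients["tm"], lty = 3)
  }
  invisible(x)
}

#' @export
simulate.melt_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) return(with_seed(seed, simulate(object, nsim)))
  mu <- fitted(object)
  sd <- object$sigma %||% stats::sd(residuals(object))
  out <- as.data.frame(replicate(nsim, mu + stats::rnorm(length(mu), 0, sd)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

# ---------------------------------------------------------------------------

CONC_UNIT_FACTORS <- c(M = 1, mM = 1e-3, uM = 1e-6, `µM` = 1e-6,
                       nM = 1e-9, pM = 1e-12)

#' Receptor x ligand affinity table
#'
#' @param receptor,ligand Character vectors.
#' @param ic50,se IC50 values and standard errors, positive, in `unit`.
#' @param unit Concentration unit per entry (`"nM"`, `"uM"`/`"µM"`, ...).
#' @return Data frame of class `AffinityTable` with an added
#'   `ic50_molar`/`se_molar` pair normalised to mol/L.
#' @export
affinity_table <- function(receptor, ligand, ic50, se, unit) {
  stopifnot(length(receptor) == length(ligand),
            length(ic50) == length(receptor),
            length(se) == length(receptor),
            length(unit) == length(receptor))
  if (any(ic50 <= 0) || any(se <= 0))
    stop("IC50 values and standard errors must be positive")
  fac <- CONC_UNIT_FACTORS[unit]
  if (anyNA(fac))
    stop("unresolvable concentration unit(s): ",
         paste(unique(unit[is.na(fac)]), collapse = ", "))
  out <- data.frame(receptor = receptor, ligand = ligand, ic50 = ic50,
                    se = se, unit = unit,
                    ic50_molar = ic50 * fac, se_molar = se * fac,
                    stringsAsFactors = FALSE)
  class(out) <- c("AffinityTable", "data.frame")
  out
}

#' Read an affinity table from a delimited file
#'
#' Expects columns `receptor`, `ligand`, `ic50`, `se`, `unit`.
#'
#' @param file Path to a TSV/CSV file.
#' @param sep Field separator (default tab).
#' @return An `AffinityTable`.
#' @export
read_affinity_table <- function(file, sep = "\t") {
  df <- utils::read.table(file, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, comment.char = "#")
  need <- c("receptor", "ligand", "ic50", "se", "unit")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("affinity table lacks column(s): ", paste(miss, collapse = ", "))
  affinity_table(df$receptor, df$ligand, df$ic50, df$se, df$unit)
}

#' Fold change in IC50 between two receptors
#'
#' For every ligand shared by the two receptors,
#' `fold = IC50(variant) / IC50(reference)` after unit normalisation to
#' mol/L; a fold below 1 means the variant binds more tightly. Direction is
#' classified by the +/- 1 SE interval-overlap rule: `improved` when the
#' variant interval lies entirely below the reference interval, `worsened`
#' when entirely above, `ns` otherwise. This operationalisation of
#' "significantly different" is a package convention (the interval rule),
#' not a formal hypothesis test.
#'
#' @param table An `AffinityTable`.
#' @param reference_receptor,variant_receptor Receptor names in the table.
#' @return Data frame of class `FoldChangeReport`: `ligand`,
#'   `ic50_reference`, `ic50_variant` (mol/L), `fold`, `direction`.
#' @export
fold_change <- function(table, reference_receptor, variant_receptor) {
  stopifnot(inherits(table, "AffinityTable"))
  ref <- table[table$receptor == reference_receptor, , drop = FALSE]
  var <- table[table$receptor == variant_receptor, , drop = FALSE]
  shared <- intersect(ref$ligand, var$ligand)
  if (length(shared) == 0L)
    stop("receptors '", reference_receptor, "' and '", variant_receptor,
         "' share no ligands")
  rows <- lapply(shared, function(lg) {
    r <- ref[ref$ligand == lg, ][1, ]
    v <- var[var$ligand == lg, ][1, ]
    fold <- v$ic50_molar / r$ic50_molar
    if (reference_receptor == variant_receptor) {
      dir <- "ns"
    } else {
      r_lo <- r$ic50_molar - r$se_molar; r_hi <- r$ic50_molar + r$se_molar
      v_lo <- v$ic50_molar - v$se_molar; v_hi <- v$ic50_molar + v$se_molar
      dir <- if (v_hi < r_lo) "improved" else if (v_lo > r_hi) "worsened"
      else "ns"
    }
    data.frame(ligand = lg, ic50_reference = r$ic50_molar,
               ic50_variant = v$ic50_molar, fold = fold, direction = dir,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "reference") <- reference_receptor
  attr(out, "variant") <- variant_receptor
  attr(out, "interval_rule") <- "non-overlap of +/- 1 SE intervals"
  class(out) <- c("FoldChangeReport", "data.frame")
  out
}

#' @export
print.FoldChangeReport <- function(x, ...) {
  cat("Fold change: ", attr(x, "variant"), " vs ", attr(x, "reference"),
      " (", attr(x, "interval_rule"), ")\n", sep = "")
  df <- as.data.frame(x)
  df$fold <- signif(df$fold, 3)
  df$ic50_reference <- signif(df$ic50_reference, 3)
  df$ic50_variant <- signif(df$ic50_variant, 3)
  print(df, row.names = FALSE)
  invisible(x)
}
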