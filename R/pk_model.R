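# One-compartment pharmacokinetics: closed-form simulation, log-scale
# least-squares fitting with multi-start, non-compartmental AUC,
# bioavailability and steady-state infusion planning.

#' Construct a plasma concentration-time dataset
#'
#' @param times sampling times in minutes, strictly increasing, >= 0.
#' @param concentrations plasma concentrations, same length, >= 0.
#' @param route `"iv"` (bolus) or `"sc"` (first-order absorption).
#' @param dose dose in mg/kg.
#' @param unit concentration unit tag, `"nM"` or `"ng/mL"`.
#' @param analyte analyte name (optional).
#' @param mw molecular weight in g/mol (needed for molar/mass conversion).
#' @return An object of class `pk_dataset`.
#' @export
pk_dataset <- function(times, concentrations, route = c("iv", "sc"),
                       dose, unit = "nM", analyte = NA_character_, mw = NA_real_) {
  route <- match.arg(route)
  stopifnot(length(times) == length(concentrations),
            all(times >= 0), all(concentrations >= 0),
            dose > 0, length(unit) == 1L)
  if (is.unsorted(times, strictly = TRUE))
    stop("times must be strictly increasing")
  structure(list(times = as.numeric(times),
                 concentrations = as.numeric(concentrations),
                 route = route, dose = dose, unit = unit,
                 analyte = analyte, mw = mw),
            class = "pk_dataset")
}

#' @export
print.pk_dataset <- function(x, ...) {
  cat(sprintf("<pk_dataset> %s, %s %g mg/kg, %d points over %g min [%s]\n",
              ifelse(is.na(x$analyte), "analyte", x$analyte), x$route,
              x$dose, length(x$times), max(x$times), x$unit))
  invisible(x)
}

#' Read / write PK datasets as TSV
#'
#' Columns: `time_min`, `concentration`, `unit`, `route`, `dose_mg_per_kg`,
#' `analyte`, `mw_g_per_mol`.
#'
#' @param path TSV file path.
#' @param ds a `pk_dataset`.
#' @return `read_pk_dataset` returns a `pk_dataset`.
#' @export
read_pk_dataset <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  pk_dataset(d$time_min, d$concentration, d$route[1], d$dose_mg_per_kg[1],
             d$unit[1], d$analyte[1], d$mw_g_per_mol[1])
}

#' @rdname read_pk_dataset
#' @export
write_pk_dataset <- function(ds, path) {
  utils::write.table(
    data.frame(time_min = ds$times, concentration = ds$concentrations,
               unit = ds$unit, route = ds$route, dose_mg_per_kg = ds$dose,
               analyte = ds$analyte, mw_g_per_mol = ds$mw),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Simulate one-compartment concentrations
#'
#' Closed-form solutions: i.v. bolus `C(t) = (D/V) exp(-ke t)`; s.c.
#' first-order absorption (Bateman)
#' `C(t) = F D ka / (V (ka - ke)) (exp(-ke t) - exp(-ka t))`, with the
#' limiting form `F D ka t / V exp(-ka t)` when `ka == ke`.
#'
#' @param params list with `ke` (1/min), `V` (volume term in dose-unit per
#'   concentration-unit), and for `"sc"` also `ka` (1/min) and `F`
#'   (bioavailability fraction, default 1).
#' @param dose dose in mg/kg.
#' @param route `"iv"` or `"sc"`.
#' @param times times in minutes, >= 0.
#' @return concentrations at `times`.
#' @export
pk_simulate <- function(params, dose, route = c("iv", "sc"), times) {
  route <- match.arg(route)
  stopifnot(all(times >= 0), params$ke > 0, params$V > 0)
  ke <- params$ke; V <- params$V
  if (route == "iv") return(dose / V * exp(-ke * times))
  ka <- params$ka; Fb <- if (is.null(params$F)) 1 else params$F
  stopifnot(ka > 0, Fb >= 0)
  if (isTRUE(all.equal(ka, ke)))
    Fb * dose * ka * times / V * exp(-ka * times)
  else
    Fb * dose * ka / (V * (ka - ke)) * (exp(-ke * times) - exp(-ka * times))
}

.pk_model_conc <- function(ds, ke, V, ka = NA) {
  if (ds$route == "iv")
    pk_simulate(list(ke = ke, V = V), ds$dose, "iv", ds$times)
  else
    pk_simulate(list(ke = ke, V = V, ka = ka, F = 1), ds$dose, "sc", ds$times)
}

#' Fit a one-compartment PK model
#'
#' Least squares on log concentrations (observations at or below `loq` are
#' excluded), with a multi-start grid over initial `(ka, ke)` to escape local
#' minima. For extravascular data, bioavailability is not separately
#' identifiable, so the volume term is reported as `V/F`; the absorption/
#' elimination labelling ambiguity ("flip-flop") is resolved by reporting the
#' parameterisation with `ka > ke`, with a warning when the alternative fits
#' equally well.
#'
#' @param ds a `pk_dataset` with at least 3 positive concentrations.
#' @param loq lower limit of quantification; concentrations <= `loq` are
#'   excluded from fitting. Default 0.
#' @return An object of class `pk_fit`: `ke`, `ka` (NA for i.v.), `V_over_F`,
#'   `t_half = log(2)/ke`, `AUC_0_inf`, `CL_over_F = dose/AUC`,
#'   `residual_norm`, plus the data.
#' @export
pk_fit <- function(ds, loq = 0) {
  stopifnot(inherits(ds, "pk_dataset"))
  use <- ds$concentrations > loq
  if (sum(use) < 3L)
    stop("need at least 3 concentrations above the LOQ to fit")
  t_obs <- ds$times[use]; c_obs <- ds$concentrations[use]
  lc <- log(c_obs)
  c_max <- max(c_obs)

  obj_iv <- function(par) {  # par = log(ke), log(V)
    mod <- .pk_model_conc(ds, exp(par[1]), exp(par[2]))[use]
    if (any(mod <= 0)) return(1e12)
    sum((lc - log(mod))^2)
  }
  obj_sc <- function(par) {  # par = log(ka), log(ke), log(V/F)
    mod <- .pk_model_conc(ds, exp(par[2]), exp(par[3]), exp(par[1]))[use]
    if (any(mod <= 0)) return(1e12)
    sum((lc - log(mod))^2)
  }

  ke_starts <- log(2) / c(5, 15, 30, 60, 120)
  fits <- list()
  if (ds$route == "iv") {
    for (ke0 in ke_starts) {
      v0 <- ds$dose / c_max
      o <- stats::optim(c(log(ke0), log(v0)), obj_iv,
                        method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-12))
      fits[[length(fits) + 1L]] <- o
    }
    best <- fits[[which.min(vapply(fits, `[[`, 0, "value"))]]
    ke <- exp(best$par[1]); V <- exp(best$par[2]); ka <- NA_real_
  } else {
    for (ke0 in ke_starts) for (mult in c(2, 5, 10)) {
      v0 <- ds$dose / (2 * c_max)
      o <- stats::optim(c(log(mult * ke0), log(ke0), log(v0)), obj_sc,
                        method = "Nelder-Mead",
                        control = list(maxit = 5000, reltol = 1e-12))
      fits[[length(fits) + 1L]] <- o
    }
    vals <- vapply(fits, `[[`, 0, "value")
    best <- fits[[which.min(vals)]]
    ka <- exp(best$par[1]); ke <- exp(best$par[2]); V <- exp(best$par[3])
    if (ka < ke) {  # flip-flop relabelling: identical curve with ka > ke
      V <- V * ke / ka
      tmp <- ka; ka <- ke; ke <- tmp
    }
    alt <- sort(vals)
    if (length(alt) > 1L && abs(alt[2] - alt[1]) < 1e-6 * (1 + alt[1])) {
      pars <- vapply(fits, function(f) sort(exp(f$par[1:2])), numeric(2))
      best_pair <- sort(c(ke, ka))
      distinct <- any(abs(pars[1, ] - best_pair[1]) > 0.10 * best_pair[1] &
                        vals < alt[1] + 1e-6 * (1 + alt[1]))
      if (distinct)
        warning("absorption/elimination labelling ambiguous (flip-flop): ",
                "an alternative parameterisation fits equally well")
    }
  }
  if (!is.finite(best$value) || best$value >= 1e12)
    stop("PK fit failed to converge; best residual sum of squares: ",
         format(min(vapply(fits, `[[`, 0, "value"))))
  auc <- ds$dose / (V * ke)   # model-based AUC_0_inf (dose/V scaled by 1/ke)
  structure(list(ke = ke, ka = ka, V_over_F = V,
                 t_half = log(2) / ke, AUC_0_inf = auc,
                 CL_over_F = ds$dose / auc,
                 residual_norm = sqrt(best$value),
                 sigma = sqrt(best$value / max(1, sum(use) -
                                                 ifelse(ds$route == "iv", 2, 3))),
                 n_obs = sum(use), loq = loq, data = ds),
            class = "pk_fit")
}

#' @export
print.pk_fit <- function(x, digits = 4, ...) {
  cat(sprintf("<pk_fit> one-compartment, route %s\n", x$data$route))
  cat(sprintf("  ke = %.*g /min  (t1/2 = %.*g min)\n", digits, x$ke,
              digits, x$t_half))
  if (!is.na(x$ka)) cat(sprintf("  ka = %.*g /min\n", digits, x$ka))
  cat(sprintf("  V/F = %.*g, CL/F = %.*g per min, AUC_0_inf = %.*g\n",
              digits, x$V_over_F, digits, x$CL_over_F, digits, x$AUC_0_inf))
  invisible(x)
}

#' @export
coef.pk_fit <- function(object, ...) {
  c(ke = object$ke, ka = object$ka, V_over_F = object$V_over_F)
}

#' @export
summary.pk_fit <- function(object, ...) {
  out <- list(coefficients = coef(object), t_half = object$t_half,
              AUC_0_inf = object$AUC_0_inf, CL_over_F = object$CL_over_F,
              residual_norm = object$residual_norm, n_obs = object$n_obs,
              route = object$data$route)
  class(out) <- "summary.pk_fit"
  out
}

#' @export
print.summary.pk_fit <- function(x, ...) {
  cat("One-compartment PK fit (", x$route, "), ", x$n_obs,
      " observations\n", sep = "")
  print(x$coefficients)
  cat(sprintf("t1/2 = %.4g min, AUC_0_inf = %.4g, CL/F = %.4g per min, log-residual norm = %.3g\n",
              x$t_half, x$AUC_0_inf, x$CL_over_F, x$residual_norm))
  invisible(x)
}

#' @export
predict.pk_fit <- function(object, times = NULL, ...) {
  if (is.null(times)) times <- object$data$times
  ds <- object$data
  if (ds$route == "iv")
    pk_simulate(list(ke = object$ke, V = object$V_over_F), ds$dose, "iv", times)
  else
    pk_simulate(list(ke = object$ke, V = object$V_over_F, ka = object$ka,
                     F = 1), ds$dose, "sc", times)
}

#' @export
residuals.pk_fit <- function(object, ...) {
  use <- object$data$concentrations > object$loq
  r <- rep(NA_real_, length(use))
  r[use] <- log(object$data$concentrations[use]) -
    log(predict(object)[use])
  r
}

#' @export
plot.pk_fit <- function(x, n = 200, log = "y", ...) {
  ds <- x$data
  tt <- seq(min(ds$times), max(ds$times), length.out = n)
  pred <- predict(x, tt)
  keep <- ds$concentrations > 0 | log != "y"
  graphics::plot(ds$times[keep], ds$concentrations[keep], log = log,
                 xlab = "time (min)",
                 ylab = paste0("concentration (", ds$unit, ")"), ...)
  graphics::lines(tt[pred > 0], pred[pred > 0])
  invisible(x)
}

#' @export
simulate.pk_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- predict(object)
  out <- replicate(nsim,
                   mu * exp(stats::rnorm(length(mu), 0, object$sigma)),
                   simplify = FALSE)
  as.data.frame(stats::setNames(out, paste0("sim_", seq_len(nsim))))
}

#' Non-compartmental AUC
#'
#' `AUC_0_last` by the linear-up/log-down trapezoid; `AUC_0_inf` adds
#' `C_last / lambda_z`, with the terminal slope `lambda_z` estimated by
#' log-linear regression on the last `n_terminal` (>= 3) positive points.
#'
#' @param ds a `pk_dataset` with >= 2 points.
#' @param n_terminal number of terminal positive points for the `lambda_z`
#'   regression, default 3.
#' @return list with `auc_0_last`, `auc_0_inf` (NA when `lambda_z` cannot be
#'   estimated) and `lambda_z`.
#' @export
nca_auc <- function(ds, n_terminal = 3L) {
  stopifnot(inherits(ds, "pk_dataset"), length(ds$times) >= 2L,
            n_terminal >= 3L)
  t <- ds$times; y <- ds$concentrations
  seg <- numeric(length(t) - 1L)
  for (i in seq_along(seg)) {
    dt <- t[i + 1L] - t[i]
    if (y[i] > 0 && y[i + 1L] > 0 && y[i + 1L] < y[i])
      seg[i] <- (y[i] - y[i + 1L]) / log(y[i] / y[i + 1L]) * dt  # log-down
    else
      seg[i] <- (y[i] + y[i + 1L]) / 2 * dt                      # linear-up
  }
  auc_last <- sum(seg)
  pos <- which(y > 0)
  if (length(pos) < n_terminal)
    return(list(auc_0_last = auc_last, auc_0_inf = NA_real_,
                lambda_z = NA_real_))
  term <- utils::tail(pos, n_terminal)
  fit <- stats::lm(log(y[term]) ~ t[term])
  lambda_z <- -unname(stats::coef(fit)[2])
  if (!is.finite(lambda_z) || lambda_z <= 0)
    return(list(auc_0_last = auc_last, auc_0_inf = NA_real_,
                lambda_z = NA_real_))
  c_last <- y[max(pos)]
  list(auc_0_last = auc_last, auc_0_inf = auc_last + c_last / lambda_z,
       lambda_z = lambda_z)
}

#' Bioavailability from paired i.v. / s.c. datasets
#'
#' `F = (AUC_sc / D_sc) / (AUC_iv / D_iv)` using non-compartmental
#' `AUC_0_inf` on each arm.
#'
#' @param iv,sc `pk_dataset` objects for the same analyte and unit.
#' @return list with `F` (fraction) and `percent`.
#' @export
bioavailability <- function(iv, sc) {
  stopifnot(inherits(iv, "pk_dataset"), inherits(sc, "pk_dataset"))
  if (iv$unit != sc$unit)
    stop("i.v. and s.c. datasets must share a concentration unit")
  if (all(sc$concentrations == 0))
    return(list(F = 0, percent = 0))
  a_iv <- nca_auc(iv)$auc_0_inf
  a_sc <- nca_auc(sc)$auc_0_inf
  if (is.na(a_iv) || is.na(a_sc))
    stop("AUC_0_inf undefined on one arm; cannot compute bioavailability")
  f <- (a_sc / sc$dose) / (a_iv / iv$dose)
  list(F = f, percent = 100 * f)
}

#' Steady-state mass delivery rate for a target concentration
#'
#' Constant-rate (osmotic-pump) infusion rate needed to hold a steady-state
#' plasma concentration: `rate = Css * CL/F`, converted to mg/kg/day. With
#' concentrations fitted in nM the dose-normalised clearance already carries
#' the mass-per-mole factor and `rate = Css_nM * CL/F * 1440`; with mass
#' units (ng/mL) the molar target is first converted via the molecular
#' weight, `Css_ng_per_mL = Css_nM * MW / 1000`.
#'
#' @param target_css_nm target steady-state concentration in nM.
#' @param fit a `pk_fit` (provides `CL_over_F` per minute in data units).
#' @param mw molecular weight in g/mol; required when the fitted data are in
#'   mass units.
#' @return infusion rate in mg/kg/day.
#' @export
steady_state_rate <- function(target_css_nm, fit, mw = fit$data$mw) {
  stopifnot(inherits(fit, "pk_fit"), target_css_nm >= 0)
  unit <- fit$data$unit
  if (unit %in% c("nM", "nmol/L")) {
    target_css_nm * fit$CL_over_F * 1440
  } else if (unit %in% c("ng/mL", "ug/L")) {
    if (is.na(mw) || is.null(mw) || mw <= 0)
      stop("molecular weight (g/mol) required to convert a molar target for mass-unit data")
    (target_css_nm * mw / 1000) * fit$CL_over_F * 1440
  } else {
    stop("unsupported concentration unit: ", unit)
  }
}
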