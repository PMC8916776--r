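#' Two-state equilibrium unfolding
#'
#' Urea titrations of a folded <-> unfolded two-state equilibrium are
#' described by a free energy linear in denaturant, dG(u) = dG_unf - m*u,
#' giving a logistic folded fraction with midpoint Cm = dG_unf / m.  CD
#' titrations are fit by maximum likelihood with linear folded and unfolded
#' baselines and a noise scale linear in urea; pulse-proteolysis band
#' intensities are fit with flat baselines, the m-value fixed to its
#' CD-estimated value and constant noise (equivalent to nonlinear least
#' squares).
#'
#' @name two-state-unfolding
NULL

#' Gas constant, kJ mol-1 K-1
#' @export
R_GAS <- 8.314e-3

#' Fraction of molecules folded at a urea concentration
#'
#' Logistic in urea: exp((dG - m u)/RT) / (1 + exp((dG - m u)/RT)),
#' evaluated overflow-safely; equals 1/2 at the midpoint u = dG/m.
#'
#' @param urea Urea concentration(s), M.
#' @param dG Unfolding free energy at 0 M urea, kJ mol-1.
#' @param m m-value, kJ mol-1 M-1 (must be > 0).
#' @param temperature Kelvin (default 298.15).
#' @export
fraction_folded <- function(urea, dG, m, temperature = 298.15) {
  stopifnot(m > 0, temperature > 0)
  plogis((dG - m * urea) / (R_GAS * temperature))
}

unfolding_mean <- function(urea, dG, m, s_unf, b_unf, s_fold, b_fold,
                           temperature) {
  ff <- fraction_folded(urea, dG, m, temperature)
  (s_unf + b_unf * urea) + (s_fold + b_fold * urea) * ff
}

#' An unfolding titration table
#'
#' @param urea Urea concentrations, M (>= 6 points).
#' @param signal CD millidegrees or band intensity (arbitrary units).
#' @param assay `"cd"` or `"proteolysis"`.
#' @param temperature Kelvin.
#' @return A tibble with the assay and temperature as attributes.
#' @export
unfolding_curve <- function(urea, signal, assay = c("cd", "proteolysis"),
                            temperature = 298.15) {
  assay <- match.arg(assay)
  stopifnot(length(urea) == length(signal), length(urea) >= 6, all(urea >= 0))
  out <- tibble(urea = urea, signal = signal)
  attr(out, "assay") <- assay
  attr(out, "temperature") <- temperature
  out
}

# a usable titration must bracket the transition: mostly folded at the low
# end of the urea range and mostly unfolded at the high end
check_transition_spanned <- function(u, dG, m, temperature) {
  ff_lo <- fraction_folded(min(u), dG, m, temperature)
  ff_hi <- fraction_folded(max(u), dG, m, temperature)
  if (ff_lo < 0.7 || ff_hi > 0.3) {
    abort(sprintf(
      "Titration does not span the transition (folded fraction %.2f-%.2f over the urea range).",
      ff_hi, ff_lo),
      class = "satmut_fit_failure")
  }
  invisible(TRUE)
}

cd_nll <- function(par, urea, signal, temperature) {
  mu <- unfolding_mean(urea, par[1], par[2], par[3], par[4], par[5], par[6],
                       temperature)
  sigma <- par[7] + par[8] * urea
  if (any(sigma <= 0)) return(1e10)
  -sum(dnorm(signal, mu, sigma, log = TRUE))
}

#' Maximum-likelihood fit of a CD urea titration
#'
#' Jointly fits (dG, m, both linear baselines, and the two noise-scale
#' parameters) by maximising the normal log-likelihood whose mean is the
#' unfolded baseline plus the folded component times the folded fraction and
#' whose scale is `sigma_constant + sigma_proportional * urea`.  A multistart
#' over 8 evenly spaced midpoint guesses guards against local optima;
#' standard errors come from the observed information (numerical Hessian) at
#' the optimum.
#'
#' @param curve A CD [unfolding_curve()] (>= 8 points spanning the
#'   transition).
#' @param m_init Initial m-value, kJ mol-1 M-1 (default 5).
#' @return A `stability_fit` object.
#' @export
fit_cd_curve <- function(curve, m_init = 5) {
  stopifnot(identical(attr(curve, "assay"), "cd"))
  if (nrow(curve) < 8) {
    abort("CD fit needs >= 8 titration points.", class = "satmut_fit_failure")
  }
  u <- curve$urea
  y <- curve$signal
  temperature <- attr(curve, "temperature")
  lo_u <- y[u <= stats::quantile(u, 0.2)]
  hi_u <- y[u >= stats::quantile(u, 0.8)]
  s_unf0 <- mean(hi_u)
  s_fold0 <- mean(lo_u) - s_unf0
  midpoints <- seq(min(u) + 0.05 * diff(range(u)),
                   max(u) - 0.05 * diff(range(u)), length.out = 8)
  lower <- c(-50, 0.2, -Inf, -Inf, -Inf, -Inf, 1e-8, 0)
  upper <- c(200, 50, Inf, Inf, Inf, Inf, Inf, Inf)
  # stage 1: least-squares fit of the six mean parameters, multistarted over
  # midpoint guesses -- far better conditioned than the joint likelihood
  rss_fn <- function(p) {
    mu <- unfolding_mean(u, p[1], p[2], p[3], p[4], p[5], p[6], temperature)
    sum((y - mu)^2)
  }
  best_mean <- NULL
  for (cm in midpoints) {
    start <- c(m_init * cm, m_init, s_unf0, 0, s_fold0, 0)
    fit <- tryCatch(
      optim(start, rss_fn, method = "L-BFGS-B",
            lower = lower[1:6], upper = upper[1:6],
            control = list(maxit = 500, factr = 1e4)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best_mean) || fit$value < best_mean$value)) {
      best_mean <- fit
    }
  }
  if (is.null(best_mean)) {
    abort("CD fit failed to converge from any start.",
          class = "satmut_fit_failure")
  }
  # stage 2: noise scale from the residuals; stage 3: joint ML polish
  sig0 <- max(sqrt(best_mean$value / length(u)), 1e-7)
  best <- list(par = c(best_mean$par, sig0, 0), value = Inf)
  for (i in 1:6) {
    polish <- tryCatch(
      optim(best$par, cd_nll, urea = u, signal = y, temperature = temperature,
            method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = 500, factr = 1e4)),
      error = function(e) NULL)
    if (is.null(polish) || polish$value > best$value - 1e-10) break
    best <- polish
  }
  if (!is.finite(best$value)) {
    abort("CD fit failed to converge.", class = "satmut_fit_failure")
  }
  par <- best$par
  if (par[2] >= upper[2] - 1e-6) {
    abort("m-value ran to its bound: no identifiable transition in range.",
          class = "satmut_fit_failure")
  }
  # step sizes proportional to parameter scale: the noise parameters can sit
  # orders of magnitude below the signal parameters
  ndeps <- pmax(1e-4 * abs(par), 1e-7)
  hess <- tryCatch(optimHess(par, cd_nll, urea = u, signal = y,
                             temperature = temperature,
                             control = list(ndeps = ndeps)),
                   error = function(e) NULL)
  se <- rep(NA_real_, length(par))
  if (!is.null(hess)) {
    # parameters pinned at a bound make the full Hessian indefinite;
    # standard errors come from the interior block only
    free <- which(par > lower + 1e-6 & par < upper - 1e-6)
    vc <- tryCatch(solve(hess[free, free, drop = FALSE]),
                   error = function(e) NULL)
    if (!is.null(vc)) {
      d <- diag(vc)
      d[d <= 0] <- NA_real_
      se[free] <- sqrt(d)
    }
  }
  if (is.na(se[1]) || se[1] > 0.25 * max(abs(par[1]), 1)) {
    abort("CD fit is degenerate (no identifiable transition in range).",
          class = "satmut_fit_failure")
  }
  check_transition_spanned(u, par[1], par[2], temperature)
  new_stability_fit(
    assay = "cd", dG_unf = unname(par[1]), m_value = unname(par[2]),
    baselines = c(signal_unfolded = unname(par[3]),
                  slope_unfolded = unname(par[4]),
                  signal_folded = unname(par[5]),
                  slope_folded = unname(par[6])),
    noise = c(sigma_constant = unname(par[7]),
              sigma_proportional = unname(par[8])),
    se = setNames(se, c("dG_unf", "m_value", "signal_unfolded",
                        "slope_unfolded", "signal_folded", "slope_folded",
                        "sigma_constant", "sigma_proportional")),
    log_likelihood = -best$value, temperature = temperature,
    n_points = length(u))
}

#' Fit a pulse-proteolysis titration with the m-value fixed
#'
#' Band intensities report the folded fraction directly, so the model is
#' `signal_unfolded + signal_folded * fraction_folded` with flat baselines,
#' the m-value constrained to its CD estimate, and constant normal noise --
#' equivalent to nonlinear least squares in dG alone (the baselines enter
#' linearly and are profiled out).
#'
#' @param curve A proteolysis [unfolding_curve()].
#' @param m_fixed CD-estimated m-value, kJ mol-1 M-1 (> 0).
#' @return A `stability_fit` object.
#' @export
fit_proteolysis_curve <- function(curve, m_fixed) {
  stopifnot(identical(attr(curve, "assay"), "proteolysis"))
  if (!is.numeric(m_fixed) || length(m_fixed) != 1L || m_fixed <= 0) {
    abort("`m_fixed` must be a positive scalar.", class = "satmut_precondition")
  }
  u <- curve$urea
  y <- curve$signal
  temperature <- attr(curve, "temperature")
  profile_rss <- function(dG) {
    ff <- fraction_folded(u, dG, m_fixed, temperature)
    fit <- lm(y ~ ff)
    sum(stats::residuals(fit)^2)
  }
  span <- m_fixed * range(u)
  opt <- optimize(profile_rss, lower = span[1] - 2 * m_fixed,
                  upper = span[2] + 2 * m_fixed)
  dG <- opt$minimum
  ff <- fraction_folded(u, dG, m_fixed, temperature)
  lin <- lm(y ~ ff)
  s_unf <- unname(coef(lin)[1])
  s_fold <- unname(coef(lin)[2])
  n <- length(u)
  rss <- sum(stats::residuals(lin)^2)
  sigma <- sqrt(rss / max(n - 3, 1))
  check_transition_spanned(u, dG, m_fixed, temperature)
  # observed information for (dG, s_unf, s_fold) via the Gauss-Newton JtJ
  eps <- 1e-5 * max(abs(dG), 1)
  dff <- (fraction_folded(u, dG + eps, m_fixed, temperature) -
            fraction_folded(u, dG - eps, m_fixed, temperature)) / (2 * eps)
  J <- cbind(s_fold * dff, 1, ff)
  vc <- tryCatch(solve(crossprod(J)) * sigma^2, error = function(e) NULL)
  if (is.null(vc)) {
    abort("Proteolysis fit is degenerate (flat curve).",
          class = "satmut_fit_failure")
  }
  se <- sqrt(pmax(diag(vc), 0))
  ll <- sum(dnorm(y, s_unf + s_fold * ff, sigma, log = TRUE))
  new_stability_fit(
    assay = "proteolysis", dG_unf = dG, m_value = m_fixed,
    baselines = c(signal_unfolded = s_unf, slope_unfolded = 0,
                  signal_folded = s_fold, slope_folded = 0),
    noise = c(sigma = sigma),
    se = c(dG_unf = se[1], signal_unfolded = se[2], signal_folded = se[3]),
    log_likelihood = ll, temperature = temperature, n_points = n,
    m_fixed = TRUE)
}

new_stability_fit <- function(assay, dG_unf, m_value, baselines, noise, se,
                              log_likelihood, temperature, n_points,
                              m_fixed = FALSE) {
  structure(
    list(assay = assay, dG_unf = dG_unf, m_value = m_value,
         midpoint_Cm = dG_unf / m_value, baselines = baselines, noise = noise,
         se = se, log_likelihood = log_likelihood, temperature = temperature,
         n_points = n_points, m_fixed = m_fixed),
    class = "stability_fit")
}

#' @export
print.stability_fit <- function(x, ...) {
  cat(sprintf(
    "<stability_fit> %s: dG_unf = %.2f +/- %.2f kJ/mol, m = %.2f%s, Cm = %.2f M\n",
    x$assay, x$dG_unf, x$se[["dG_unf"]], x$m_value,
    if (x$m_fixed) " (fixed)" else "", x$midpoint_Cm))
  invisible(x)
}

#' @export
tidy.stability_fit <- function(x, ...) {
  params <- c(dG_unf = x$dG_unf, m_value = x$m_value, x$baselines, x$noise)
  tibble(term = names(params), estimate = unname(params),
         std.error = unname(x$se[names(params)]))
}

#' @export
glance.stability_fit <- function(x, ...) {
  tibble(assay = x$assay, dG_unf = x$dG_unf, m_value = x$m_value,
         midpoint_Cm = x$midpoint_Cm, log_likelihood = x$log_likelihood,
         n_points = x$n_points)
}

#' @export
autoplot.stability_fit <- function(object, curve, ...) {
  grid <- tibble(urea = seq(0, max(curve$urea), length.out = 200))
  b <- object$baselines
  grid$signal <- unfolding_mean(grid$urea, object$dG_unf, object$m_value,
                                b[["signal_unfolded"]], b[["slope_unfolded"]],
                                b[["signal_folded"]], b[["slope_folded"]],
                                object$temperature)
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$urea, y = .data$signal)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = object$midpoint_Cm, linetype = "dashed") +
    ggplot2::labs(x = "[urea] (M)", y = "signal") +
    ggplot2::theme_minimal()
}

#' Ligand contribution to apparent unfolding free energy
#'
#' Saturating a folded-state-specific ligand stabilises the protein; raising
#' the ligand (GDP) concentration between assays adds
#' `RT * ln((1 + [L]new/KD) / (1 + [L]old/KD))` to the apparent dG_unf.  In
#' the tight-binding limit (KD -> 0) this tends to `RT * ln(new/old)`, and it
#' vanishes as KD -> infinity; the correction is antisymmetric in
#' new <-> old.
#'
#' @param gdp_new,gdp_old New and old ligand concentrations (same units,
#'   conventionally uM; both > 0).
#' @param K_D Dissociation constant in the same units; `0` selects the
#'   tight-binding limit.
#' @param temperature Kelvin.
#' @return Contribution in kJ mol-1.
#' @examples
#' ligand_contribution(100, 36, K_D = 0, temperature = 298)  # ~2.53 kJ/mol
#' @export
ligand_contribution <- function(gdp_new, gdp_old, K_D = 0,
                                temperature = 298.15) {
  if (!all(gdp_new > 0, gdp_old > 0) || K_D < 0 || temperature <= 0) {
    abort("Concentrations must be positive and K_D non-negative.",
          class = "satmut_precondition")
  }
  rt <- R_GAS * temperature
  if (K_D == 0) return(rt * log(gdp_new / gdp_old))
  rt * log((1 + gdp_new / K_D) / (1 + gdp_old / K_D))
}
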