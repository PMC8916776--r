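#' Exchange-kinetics decay fitting
#'
#' Hydrogen-deuterium exchange followed by NMR yields, for each assigned
#' residue, the decay of an integrated peak volume with exchange time; GDP
#' release assays yield an analogous fluorescence decay.  Each series is fit
#' to a single exponential `A * exp(-k t)` (optionally with a floating
#' offset for MS-style data), and only fits with R^2 > 0.7 against the
#' mean-only model are kept -- a conservative filter against multi-phase or
#' noisy decays.
#'
#' @name exchange-kinetics
NULL

#' A per-residue (or per-probe) decay series
#'
#' @param times Strictly increasing time points (>= 4); hours for HDX,
#'   seconds for fluorescence.
#' @param values Signal at each time.
#' @param id Residue or probe identifier.
#' @export
decay_series <- function(times, values, id = "probe") {
  stopifnot(length(times) == length(values), length(times) >= 4,
            all(diff(times) > 0))
  out <- tibble(time = times, value = values)
  attr(out, "id") <- id
  out
}

#' Fit a single-exponential decay
#'
#' Log-linear regression on the positive values initialises `A` and `k`;
#' nonlinear least squares (Levenberg-Marquardt) then refines them.  R^2 is
#' computed against the mean-only model, and the fit is kept only when
#' R^2 > `r2_min` and the fitted rate is positive.  Pathological inputs
#' (flat series, negative rate) are marked not-kept with a diagnostic rather
#' than raising an error.
#'
#' @param series A [decay_series()] or tibble with `time` and `value`.
#' @param offset If `TRUE`, fit `A * exp(-k t) + c` (MS-style plateau).
#' @param r2_min Goodness-of-fit threshold (default 0.7, strict).
#' @return An `exchange_fit` object.
#' @export
fit_exponential <- function(series, offset = FALSE, r2_min = 0.7) {
  t <- series$time
  y <- series$value
  id <- attr(series, "id") %||% "probe"
  not_kept <- function(reason) {
    structure(list(id = id, amplitude = NA_real_, rate_k_obs = NA_real_,
                   offset = if (offset) NA_real_ else 0,
                   tau = NA_real_, r_squared = NA_real_, kept = FALSE,
                   diagnostic = reason, n_points = length(t)),
              class = "exchange_fit")
  }
  if (sd(y) == 0) return(not_kept("values are constant"))
  pos <- y > 0
  if (sum(pos) >= 2) {
    init_fit <- lm(log(y[pos]) ~ t[pos])
    k0 <- max(-unname(coef(init_fit)[2]), 1e-8)
    A0 <- unname(exp(coef(init_fit)[1]))
  } else {
    k0 <- 1 / max(t)
    A0 <- max(abs(y))
  }
  df <- data.frame(t = t, y = y)
  fit <- tryCatch({
    if (offset) {
      minpack.lm::nlsLM(y ~ A * exp(-k * t) + c0, data = df,
                        start = list(A = A0, k = k0, c0 = min(y)),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    } else {
      minpack.lm::nlsLM(y ~ A * exp(-k * t), data = df,
                        start = list(A = A0, k = k0),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    }
  }, error = function(e) NULL)
  if (is.null(fit)) return(not_kept("nonlinear fit did not converge"))
  cf <- coef(fit)
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((y - mean(y))^2)
  r2 <- 1 - rss / tss
  if (cf[["k"]] <= 0) {
    out <- not_kept("fitted rate is non-positive")
    out$r_squared <- r2
    return(out)
  }
  structure(list(id = id, amplitude = unname(cf[["A"]]),
                 rate_k_obs = unname(cf[["k"]]),
                 offset = if (offset) unname(cf[["c0"]]) else 0,
                 tau = 1 / unname(cf[["k"]]), r_squared = r2,
                 kept = r2 > r2_min, diagnostic = NA_character_,
                 n_points = length(t)),
            class = "exchange_fit")
}

#' @export
print.exchange_fit <- function(x, ...) {
  if (is.na(x$rate_k_obs)) {
    cat(sprintf("<exchange_fit> %s: not kept (%s)\n", x$id, x$diagnostic))
  } else {
    cat(sprintf(
      "<exchange_fit> %s: k = %.4g, tau = %.4g, R^2 = %.3f (%s)\n",
      x$id, x$rate_k_obs, x$tau, x$r_squared,
      if (x$kept) "kept" else "excluded"))
  }
  invisible(x)
}

#' @export
tidy.exchange_fit <- function(x, ...) {
  tibble(id = x$id, amplitude = x$amplitude, rate_k_obs = x$rate_k_obs,
         tau = x$tau, r_squared = x$r_squared, kept = x$kept)
}

#' Keep only well-fit decays
#'
#' Strict filter: a fit is kept iff `r_squared > r2_min` (a fit at exactly
#' the threshold is excluded).
#'
#' @param fits List of `exchange_fit` objects.
#' @param r2_min Threshold (default 0.7).
#' @export
filter_fits <- function(fits, r2_min = 0.7) {
  keep <- vapply(fits, function(f) {
    isTRUE(!is.na(f$r_squared) && f$r_squared > r2_min &&
             !is.na(f$rate_k_obs) && f$rate_k_obs > 0)
  }, logical(1))
  fits[keep]
}

#' Mutant-over-wild-type rate fold change
#'
#' @param mutant,wildtype Kept `exchange_fit` objects for the same residue.
#' @return `k_obs(mutant) / k_obs(wildtype)`; > 1 means faster exchange
#'   (less protection) in the mutant.
#' @export
fold_change <- function(mutant, wildtype) {
  if (!isTRUE(mutant$kept) || !isTRUE(wildtype$kept)) {
    abort("Fold change undefined: one of the fits was not kept.",
          class = "satmut_undefined_fold_change")
  }
  mutant$rate_k_obs / wildtype$rate_k_obs
}

#' Five-level fold-change category
#'
#' Bins a mutant/WT rate ratio for structure colouring: ratios below 1/3 are
#' `much_slower`, \[1/3, 1/2) `slower`, \[1/2, 2\] `similar`, (2, 3\]
#' `faster`, above 3 `much_faster`.  Exact 2x and 3x boundaries fall in the
#' inner bin.
#'
#' @param ratio Positive rate ratio(s).
#' @return Factor with the five ordered levels.
#' @export
bin_fold_change <- function(ratio) {
  if (any(!is.finite(ratio)) || any(ratio <= 0)) {
    abort("Fold-change ratios must be positive.", class = "satmut_precondition")
  }
  levels <- c("much_slower", "slower", "similar", "faster", "much_faster")
  idx <- ifelse(ratio < 1 / 3, 1L,
         ifelse(ratio < 1 / 2, 2L,
         ifelse(ratio <= 2, 3L,
         ifelse(ratio <= 3, 4L, 5L))))
  factor(levels[idx], levels = levels, ordered = TRUE)
}

#' Fit every residue in a long-form decay table
#'
#' @param data Tibble with columns `residue`, `time`, `value`.
#' @param offset,r2_min Passed to [fit_exponential()].
#' @return Tibble with one row per residue: amplitude, `rate_k_obs`, `tau`,
#'   `r_squared`, `kept`.
#' @export
fit_decay_table <- function(data, offset = FALSE, r2_min = 0.7) {
  data |>
    group_by(.data$residue) |>
    dplyr::group_modify(function(d, key) {
      s <- decay_series(d$time, d$value, id = as.character(key$residue[1]))
      tidy(fit_exponential(s, offset = offset, r2_min = r2_min))[-1]
    }) |>
    ungroup()
}

#' Mutant-vs-WT fold-change table with bins
#'
#' Joins two per-residue fit tables (from [fit_decay_table()]), keeps
#' residues where both fits passed the R^2 filter, and reports the rate fold
#' change with its five-level bin.
#'
#' @param mutant_fits,wt_fits Per-residue fit tables.
#' @export
fold_change_table <- function(mutant_fits, wt_fits) {
  inner_join(filter(mutant_fits, .data$kept),
             filter(wt_fits, .data$kept),
             by = "residue", suffix = c("_mut", "_wt")) |>
    mutate(fold_change = .data$rate_k_obs_mut / .data$rate_k_obs_wt,
           bin = bin_fold_change(.data$fold_change)) |>
    select("residue", "rate_k_obs_mut", "rate_k_obs_wt", "fold_change", "bin")
}
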