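#' Boltzmann probability of inducing an interictal discharge
#'
#' The probability that a light flash of intensity `LI` induces an
#' interictal discharge follows the rising Boltzmann sigmoid
#' \deqn{P(LI) = 1 - \frac{1}{1 + e^{(LI - LI_0)/\Delta}},}
#' i.e. a logistic CDF with midpoint `LI0` and slope `Delta`.  The
#' implementation is underflow-safe for `|LI - LI0| / Delta` up to several
#' hundred.
#'
#' @param LI Light intensity (percent of maximum); vectorized.
#' @param LI0 Midpoint (percent of maximum).
#' @param Delta Slope parameter (percent of maximum, positive).
#' @return Probability in `(0, 1)`, strictly increasing in `LI`.
#' @examples
#' boltzmann_p(0.40, LI0 = 0.40, Delta = 0.007)  # 0.5
#' @export
boltzmann_p <- function(LI, LI0 = 0.40, Delta = 0.007) {
  stopifnot(Delta > 0)
  plogis((LI - LI0) / Delta)
}

boltzmann_nll <- function(li, y, LI0, Delta) {
  # numerically stable Bernoulli negative log-likelihood:
  # log P = plogis(log.p), log(1-P) = plogis of the negated argument
  z <- (li - LI0) / Delta
  -sum(y * plogis(z, log.p = TRUE) + (1 - y) * plogis(-z, log.p = TRUE))
}

fit_boltzmann_one <- function(li, y, delta_min = 1e-4) {
  if (length(unique(y)) < 2) {
    abort("single-class outcomes: Boltzmann fit is not identified",
          class = "ictalsim_fit_error")
  }
  # start the midpoint near the empirical 50% crossing
  p_hat <- tapply(y, li, mean)
  lv <- as.numeric(names(p_hat))
  start_LI0 <- lv[which.min(abs(p_hat - 0.5))]
  if (!is.finite(start_LI0)) start_LI0 <- mean(li)
  start_delta <- max(delta_min * 10, diff(range(li)) / 20)

  obj <- function(par) boltzmann_nll(li, y, par[1], exp(par[2]))
  fit <- optim(c(start_LI0, log(start_delta)), obj, method = "L-BFGS-B",
               lower = c(min(li) - diff(range(li)), log(delta_min)),
               upper = c(max(li) + diff(range(li)), log(diff(range(li)))),
               control = list(maxit = 500))
  boundary <- fit$par[2] <= log(delta_min) + 1e-8
  list(LI0 = fit$par[1], Delta = exp(fit$par[2]),
       logLik = -fit$value, boundary = boundary,
       convergence = fit$convergence)
}

#' Fit the Boltzmann dose-response curve to binary outcomes
#'
#' Maximum-likelihood Bernoulli fit of [boltzmann_p()] to
#' light-intensity/outcome records, optionally per brain slice.  The
#' "averaged" curve reported alongside per-slice fits is the mean of the
#' per-slice parameters with their SEMs (the convention under which the
#' midpoint and slope carry standard errors across slices); a pooled fit
#' over all records is always provided as well.  `Delta` is bounded below
#' at `1e-4` so the likelihood stays finite under complete separation;
#' fits on that bound are flagged as boundary fits.
#'
#' @param data Data frame with columns `li_percent` (light intensity,
#'   percent of maximum) and `outcome` (0/1), plus `slice_id` when fitting
#'   per slice.
#' @param per_slice Fit each slice separately and average the parameters?
#' @return An object of class `"boltzmann_fit"`: a list with `pooled`
#'   (tibble of `LI0`, `Delta`, `logLik`, `boundary`), and when
#'   `per_slice = TRUE` also `per_slice` (one row per slice) and `averaged`
#'   (`LI0`, `LI0_sem`, `Delta`, `Delta_sem`, `n_slices`).  `tidy()`,
#'   `glance()` and `autoplot()` methods are provided.
#' @export
fit_boltzmann <- function(data, per_slice = FALSE) {
  stopifnot(is.data.frame(data),
            all(c("li_percent", "outcome") %in% names(data)))
  if (any(data$li_percent < 0)) abort("light intensities must be >= 0")
  if (!all(data$outcome %in% c(0, 1))) abort("outcomes must be 0/1")

  res <- list(data = as_tibble(data))
  if (per_slice) {
    if (!"slice_id" %in% names(data)) {
      abort("per-slice fitting needs a `slice_id` column")
    }
    by_slice <- split(data, data$slice_id)
    fits <- imap(by_slice, function(d, id) {
      f <- tryCatch(
        fit_boltzmann_one(d$li_percent, d$outcome),
        ictalsim_fit_error = function(e) {
          abort(sprintf("slice %s: %s", id, conditionMessage(e)),
                class = "ictalsim_fit_error")
        }
      )
      tibble(slice_id = id, LI0 = f$LI0, Delta = f$Delta,
             logLik = f$logLik, boundary = f$boundary)
    })
    per <- list_rbind(fits)
    sem <- function(x) if (length(x) > 1) sd(x) / sqrt(length(x)) else NA_real_
    res$per_slice <- per
    res$averaged <- tibble(
      LI0 = mean(per$LI0), LI0_sem = sem(per$LI0),
      Delta = mean(per$Delta), Delta_sem = sem(per$Delta),
      n_slices = nrow(per)
    )
  }
  pooled <- fit_boltzmann_one(data$li_percent, data$outcome)
  res$pooled <- tibble(LI0 = pooled$LI0, Delta = pooled$Delta,
                       logLik = pooled$logLik, boundary = pooled$boundary)
  structure(res, class = "boltzmann_fit")
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  cat("<boltzmann_fit> P(IID) = 1 - 1 / (1 + exp((LI - LI0) / Delta))\n")
  cat(sprintf("  pooled: LI0 = %.4f, Delta = %.5f%s\n",
              x$pooled$LI0, x$pooled$Delta,
              if (x$pooled$boundary) " (boundary fit)" else ""))
  if (!is.null(x$averaged)) {
    cat(sprintf(
      "  averaged over %d slices: LI0 = %.4f +/- %.4f, Delta = %.5f +/- %.5f\n",
      x$averaged$n_slices, x$averaged$LI0, x$averaged$LI0_sem,
      x$averaged$Delta, x$averaged$Delta_sem
    ))
  }
  invisible(x)
}

#' @export
tidy.boltzmann_fit <- function(x, ...) {
  if (is.null(x$averaged)) {
    tibble(term = c("LI0", "Delta"),
           estimate = c(x$pooled$LI0, x$pooled$Delta),
           std.error = NA_real_)
  } else {
    tibble(term = c("LI0", "Delta"),
           estimate = c(x$averaged$LI0, x$averaged$Delta),
           std.error = c(x$averaged$LI0_sem, x$averaged$Delta_sem))
  }
}

#' @export
glance.boltzmann_fit <- function(x, ...) {
  tibble(
    LI0 = x$pooled$LI0, Delta = x$pooled$Delta,
    logLik = x$pooled$logLik, boundary = x$pooled$boundary,
    n = nrow(x$data),
    n_slices = if (is.null(x$per_slice)) NA_integer_
               else nrow(x$per_slice)
  )
}

#' Brute-force likelihood grid search for the Boltzmann fit
#'
#' Exhaustive maximization of the Bernoulli likelihood over an explicit
#' `LI0` x `Delta` grid.  Serves as the independent oracle for
#' [fit_boltzmann()] on small datasets and as its fallback for pathological
#' inputs.
#'
#' @param data Data frame with `li_percent` and `outcome` columns.
#' @param li0_grid,delta_grid Numeric grids to search.
#' @return One-row tibble with `LI0`, `Delta` and `logLik` of the grid
#'   maximum.
#' @export
fit_boltzmann_grid <- function(data,
                               li0_grid = seq(0.30, 0.50, by = 5e-4),
                               delta_grid = exp(seq(log(1e-4), log(0.1),
                                                    length.out = 60))) {
  li <- data$li_percent; y <- data$outcome
  grid <- expand.grid(LI0 = li0_grid, Delta = delta_grid)
  nll <- map_dbl(seq_len(nrow(grid)),
                 function(i) boltzmann_nll(li, y, grid$LI0[i], grid$Delta[i]))
  best <- which.min(nll)
  tibble(LI0 = grid$LI0[best], Delta = grid$Delta[best], logLik = -nll[best])
}
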