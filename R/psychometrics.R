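#' Tabulate raw 2AFC responses per comparison level
#'
#' Collapses trial-level two-alternative forced-choice responses into
#' per-level counts and proportions. Presentation order is marginalised out:
#' only which stimulus was called "most slippery" matters, so shuffling the
#' rows never changes the table.
#'
#' @param responses Data frame with columns `level_um` (comparison vibration
#'   amplitude, micrometres) and `chose_comparison` (logical or 0/1: the
#'   comparison stimulus was called the most slippery). An optional
#'   `participant` column is preserved as a grouping variable when
#'   `by_participant = TRUE`.
#' @param reference_um Vibration amplitude of the reference (highest
#'   friction) stimulus, default `1e-3` micrometres.
#' @param by_participant Tabulate per participant rather than pooled.
#' @return A tibble with columns `level_um`, `n_trials`, `n_correct`,
#'   `proportion` (plus `participant` when requested), sorted by level, with
#'   the reference level stored in the `reference_um` attribute. An empty
#'   input yields an empty table.
#' @export
proportion_table <- function(responses, reference_um = 1e-3,
                             by_participant = FALSE) {
  stopifnot(is.data.frame(responses))
  if (nrow(responses) == 0) {
    out <- tibble::tibble(level_um = numeric(), n_trials = integer(),
                          n_correct = integer(), proportion = numeric())
    attr(out, "reference_um") <- reference_um
    return(out)
  }
  stopifnot(all(c("level_um", "chose_comparison") %in% names(responses)))
  if (!is.numeric(responses$level_um) || anyNA(responses$level_um)) {
    stop("unknown or missing comparison level labels", call. = FALSE)
  }
  keys <- if (by_participant && "participant" %in% names(responses)) {
    c("participant", "level_um")
  } else "level_um"
  out <- responses |>
    dplyr::mutate(chose_comparison = as.logical(.data$chose_comparison)) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(n_trials = dplyr::n(),
                     n_correct = sum(.data$chose_comparison),
                     .groups = "drop") |>
    dplyr::mutate(proportion = .data$n_correct / .data$n_trials) |>
    dplyr::arrange(dplyr::across(dplyr::all_of(keys)))
  attr(out, "reference_um") <- reference_um
  out
}

#' Fit a 2AFC psychometric function and extract the 75% threshold
#'
#' Maximum-likelihood fit of a two-alternative forced-choice psychometric
#' curve to per-level correct counts. The default family is a cumulative
#' Gaussian with the chance floor fixed at `guess = 0.5` and a fixed lapse
#' rate:
#' \deqn{P(x) = \gamma + (1 - \gamma - \lambda)\,
#'       \Phi\!\left(\frac{x - m}{s}\right).}
#' The discrimination threshold is the stimulus level at which the fitted
#' probability of calling the comparison most slippery equals
#' `threshold_p` (default 0.75), read off the lapse-corrected curve:
#' \eqn{x_{75} = m + s\,\Phi^{-1}\!\big((p - \gamma)/(1-\gamma-\lambda)\big)}.
#'
#' Datasets carrying no usable gradient — every response correct, every
#' level at or below chance, or no variation across levels — are returned
#' with `converged = FALSE` rather than an arbitrary extrapolation.
#'
#' @param data A table from [proportion_table()] (columns `level_um`,
#'   `n_trials`, `n_correct`), or a raw response data frame, which is
#'   tabulated first. At least 3 levels with trials are required.
#' @param guess Chance performance floor (0.5 for 2AFC).
#' @param lapse Fixed lapse rate (default 0.02).
#' @param threshold_p Probability level defining the threshold.
#' @return An object of class `psychometric_fit` with fields `threshold_um`,
#'   `midpoint_um`, `spread_um`, `slope_per_um` (curve slope at the
#'   midpoint), `guess`, `lapse`, `converged`, `extrapolated`, `logLik`, and
#'   `table` (the data with a `fitted` column). Supports [tidy()],
#'   [glance()], `predict()` and [ggplot2::autoplot()].
#' @export
fit_psychometric <- function(data, guess = 0.5, lapse = 0.02,
                             threshold_p = 0.75) {
  if (!all(c("level_um", "n_trials", "n_correct") %in% names(data))) {
    data <- proportion_table(data)
  }
  tab <- dplyr::filter(data, .data$n_trials > 0)
  if (nrow(tab) < 3) stop("need at least 3 levels with trials", call. = FALSE)
  if (any(tab$n_correct < 0 | tab$n_correct > tab$n_trials)) {
    stop("n_correct must lie in [0, n_trials]", call. = FALSE)
  }
  x <- tab$level_um; n <- tab$n_trials; k <- tab$n_correct
  p_obs <- k / n
  span <- 1 - guess - lapse
  identifiable <- !(all(k == n) || all(p_obs <= guess + 1e-12) ||
                      stats::var(p_obs) == 0)

  pfun <- function(x, m, s) guess + span * pnorm((x - m) / s)
  nll <- function(par) {
    m <- par[1]; s <- exp(par[2])
    p <- pmin(pmax(pfun(x, m, s), 1e-9), 1 - 1e-9)
    -sum(k * log(p) + (n - k) * log(1 - p))
  }
  # moment start: midpoint near the level crossing mid-performance
  pmid <- guess + span / 2
  m0 <- tryCatch(approx(p_obs, x, xout = pmid, ties = mean)$y,
                 error = function(e) NA_real_)
  if (!is.finite(m0)) m0 <- median(x)
  s0 <- max(diff(range(x)) / 4, 1e-3)
  fit <- NULL
  converged <- FALSE
  if (identifiable) {
    fit <- tryCatch(optim(c(m0, log(s0)), nll, method = "BFGS",
                          control = list(maxit = 500, reltol = 1e-12)),
                    error = function(e) NULL)
    converged <- !is.null(fit) && fit$convergence == 0 &&
      all(is.finite(fit$par))
  }
  if (converged) {
    m <- fit$par[1]; s <- exp(fit$par[2])
    ll <- -fit$value
  } else {
    m <- NA_real_; s <- NA_real_; ll <- NA_real_
  }
  z <- (threshold_p - guess) / span
  thr <- if (converged && z > 0 && z < 1) m + s * qnorm(z) else NA_real_
  slope <- if (converged) span * stats::dnorm(0) / s else NA_real_
  tab$fitted <- if (converged) pfun(x, m, s) else NA_real_
  structure(list(threshold_um = thr, midpoint_um = m, spread_um = s,
                 slope_per_um = slope, guess = guess, lapse = lapse,
                 threshold_p = threshold_p, converged = converged,
                 extrapolated = is.finite(thr) &&
                   (thr < min(x) || thr > max(x)),
                 logLik = ll, table = tibble::as_tibble(tab)),
            class = "psychometric_fit")
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat("2AFC psychometric fit (cumulative Gaussian, guess =", x$guess,
      ", lapse =", x$lapse, ")\n")
  if (!x$converged) {
    cat("  NOT identifiable / not converged\n")
  } else {
    cat(sprintf("  %.0f%% threshold: %.3f um%s\n", 100 * x$threshold_p,
                x$threshold_um,
                if (isTRUE(x$extrapolated)) " (extrapolated)" else ""))
    cat(sprintf("  midpoint %.3f um, spread %.3f um, slope %.3f /um\n",
                x$midpoint_um, x$spread_um, x$slope_per_um))
  }
  invisible(x)
}

#' Predict 2AFC performance from a fitted psychometric curve
#'
#' @param object A `psychometric_fit`.
#' @param newdata Numeric vector of stimulus levels (micrometres).
#' @param ... Unused.
#' @return Fitted probabilities of choosing the comparison.
#' @export
predict.psychometric_fit <- function(object, newdata = NULL, ...) {
  if (!object$converged) stop("fit did not converge", call. = FALSE)
  if (is.null(newdata)) newdata <- object$table$level_um
  span <- 1 - object$guess - object$lapse
  object$guess +
    span * pnorm((newdata - object$midpoint_um) / object$spread_um)
}

#' Correlate discrimination performance with the divergence cue
#'
#' Spearman rank correlation between the inter-stimulus difference in mean
#' divergence and the correctness of the slipperiness judgement, with a
#' binned response curve for plotting. Ties are mid-ranked.
#'
#' @param summaries Data frame with columns `divergence_diff` (comparison
#'   minus reference mean divergence) and `correct` (logical or 0/1).
#' @param bins Number of equal-count bins for the binned curve.
#' @return A list with `rho` (Spearman), `p_value`, `n`, and `curve`
#'   (tibble `divergence_mid`, `p_correct`, `n`).
#' @export
discrimination_vs_divergence <- function(summaries, bins = 6) {
  stopifnot(is.data.frame(summaries),
            all(c("divergence_diff", "correct") %in% names(summaries)))
  d <- summaries$divergence_diff
  cc <- as.numeric(summaries$correct)
  keep <- is.finite(d) & is.finite(cc)
  d <- d[keep]; cc <- cc[keep]
  if (length(d) < 10) stop("need at least 10 paired records", call. = FALSE)
  if (sd(d) == 0 || sd(cc) == 0) {
    stop("correlation undefined for constant input", call. = FALSE)
  }
  ct <- suppressWarnings(stats::cor.test(d, cc, method = "spearman"))
  qs <- quantile(d, probs = seq(0, 1, length.out = bins + 1), names = FALSE)
  grp <- cut(d, breaks = unique(qs), include.lowest = TRUE)
  curve <- tibble::tibble(d = d, correct = cc, grp = grp) |>
    dplyr::group_by(.data$grp) |>
    dplyr::summarise(divergence_mid = median(.data$d),
                     p_correct = mean(.data$correct),
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::select(-dplyr::any_of("grp"))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = length(d),
       curve = curve)
}
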