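# Cluster-lability kinetics: normalization of 458-nm absorbance decay
# traces, first-order-plus-plateau fitting with AICc model selection, and
# the stable/labile temperature panel.
#
# The source experiment is qualitative (absorbance loss over hours at
# 310-318 K); the first-order model A(t) = c + (1 - c) exp(-k t) and the
# 0.2-total-loss labile rule are this package's operationalization and are
# labelled as such in every report.

.LABILE_LOSS_MIN <- 0.2

#' Construct an absorbance decay trace
#'
#' @param time_min Strictly increasing time points (minutes).
#' @param a458 Absorbance at 458 nm (AU), same length.
#' @param temperature_K Measurement temperature (K).
#' @param label Sample label (e.g. `"WT-oxidized"`, `"H87C"`).
#' @return A `decay_trace` object.
#' @export
decay_trace <- function(time_min, a458, temperature_K = NA_real_,
                        label = "sample") {
  time_min <- as.numeric(time_min)
  a458 <- as.numeric(a458)
  stopifnot(length(time_min) == length(a458))
  if (any(diff(time_min) <= 0)) stop("time points must be strictly increasing")
  structure(list(time_min = time_min, a458 = a458,
                 temperature_K = as.numeric(temperature_K),
                 label = label, normalized = FALSE),
            class = "decay_trace")
}

#' @export
print.decay_trace <- function(x, ...) {
  cat(sprintf("decay_trace '%s': %d points, %.0f-%.0f min, T = %s K%s\n",
              x$label, length(x$time_min), min(x$time_min), max(x$time_min),
              ifelse(is.na(x$temperature_K), "?", x$temperature_K),
              if (x$normalized) " (normalized)" else ""))
  invisible(x)
}

#' Normalize a trace to its initial absorbance
#'
#' Divides by the mean of the first three points (robust to single-point
#' noise at t = 0), making the trace dimensionless and ~1 at the start.
#'
#' @param t A `decay_trace`.
#' @return The normalized `decay_trace`.
#' @export
normalize_trace <- function(t) {
  stopifnot(inherits(t, "decay_trace"))
  a0 <- mean(t$a458[seq_len(min(3, length(t$a458)))])
  if (!is.finite(a0) || a0 <= 0) {
    stop("nonpositive initial absorbance; cannot normalize")
  }
  t$a458 <- t$a458 / a0
  t$normalized <- TRUE
  t
}

aicc <- function(rss, n, p) {
  # p counts mean-model parameters + 1 for the error variance
  n * log(rss / n) + 2 * p + 2 * p * (p + 1) / max(n - p - 1, 1e-9)
}

#' Fit a first-order lability model to a decay trace
#'
#' Fits `A(t) = c + (a - c) exp(-k t)` with plateau `c` in \[0, 1\] and
#' `k >= 0` by bounded Levenberg-Marquardt least squares, alongside the
#' flat model `A(t) = const`, and selects between them by AICc. The
#' amplitude `a` (~1 after normalization) is left free rather than pinned
#' at 1: the three-point normalization window only estimates the true
#' initial absorbance, and anchoring the amplitude to that estimate
#' propagates its error into a systematic underestimate of `k` for fast
#' decays. The trace is labelled `"labile"` only when the exponential
#' model wins AND the fitted total loss over the observation window,
#' `(a - c)(1 - exp(-k t_end))`, is at least 0.2; otherwise `"stable"`.
#'
#' @param t A normalized `decay_trace` with >= 5 points (see
#'   [normalize_trace()]).
#' @return A `lability_fit`: `model`, `k` (1/min), `k_se`, `plateau`,
#'   `total_loss`, `classification`, `aicc_flat`, `aicc_exp`,
#'   `converged`.
#' @export
fit_decay <- function(t) {
  stopifnot(inherits(t, "decay_trace"))
  if (!t$normalized) t <- normalize_trace(t)
  if (length(t$time_min) < 5) stop("need >= 5 points to fit")
  tt <- t$time_min
  y <- t$a458
  n <- length(y)

  rss_flat <- sum((y - mean(y))^2)
  a_flat <- aicc(max(rss_flat, 1e-300), n, 2)

  # starting values: plateau from the tail, rate from a log-linear probe
  c0 <- max(min(min(y), 0.99), 0)
  pos <- y - c0 > 1e-3
  k0 <- if (sum(pos) >= 2) {
    sl <- stats::coef(stats::lm(log(y[pos] - c0 + 1e-6) ~ tt[pos]))[2]
    max(-sl, 1e-4)
  } else 1e-3

  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ c + (a - c) * exp(-k * tt),
                      start = list(c = c0, k = k0, a = y[1]),
                      lower = c(0, 0, 0), upper = c(1, Inf, Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)

  if (is.null(fit)) {
    return(structure(list(model = "flat", k = 0, k_se = NA_real_,
                          plateau = mean(y), total_loss = 0,
                          classification = "stable",
                          aicc_flat = a_flat, aicc_exp = NA_real_,
                          converged = FALSE,
                          rule = "first-order operationalization (0.2-loss)"),
                     class = "lability_fit"))
  }
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients["k", "Std. Error"],
                 error = function(e) NA_real_)
  rss_exp <- sum(stats::resid(fit)^2)
  a_exp <- aicc(max(rss_exp, 1e-300), n, 4)
  loss <- (cf["a"] - cf["c"]) * (1 - exp(-cf["k"] * max(tt)))
  exp_wins <- a_exp < a_flat
  labile <- exp_wins && loss >= .LABILE_LOSS_MIN
  structure(list(model = if (exp_wins) "first-order" else "flat",
                 k = unname(cf["k"]), k_se = unname(se),
                 plateau = unname(cf["c"]), total_loss = unname(loss),
                 classification = if (labile) "labile" else "stable",
                 aicc_flat = a_flat, aicc_exp = a_exp,
                 converged = TRUE,
                 rule = "first-order operationalization (0.2-loss)"),
            class = "lability_fit")
}

#' @export
print.lability_fit <- function(x, ...) {
  cat(sprintf("lability_fit: %s, k = %.4g /min, plateau = %.3f, loss = %.3f -> %s\n",
              x$model, x$k, x$plateau, x$total_loss, x$classification))
  invisible(x)
}

#' Temperature panel of lability fits
#'
#' Fits every trace, tabulates per-temperature results side by side per
#' sample label, and flags a strictly monotone rate-versus-temperature
#' trend (Spearman rank correlation of (T, k) equal to 1 within a label).
#'
#' @param traces List of `decay_trace` objects spanning >= 2 temperatures.
#' @return A `lability_panel` data frame (columns `label`,
#'   `temperature_K`, `model`, `k_per_min`, `plateau`, `total_loss`,
#'   `classification`) with attribute `monotone_k` (named logical per
#'   label).
#' @export
temperature_panel <- function(traces) {
  stopifnot(is.list(traces), length(traces) >= 2)
  temps <- vapply(traces, function(x) x$temperature_K, numeric(1))
  labels <- vapply(traces, function(x) x$label, character(1))
  if (length(unique(temps[is.finite(temps)])) < 2) {
    stop("panel needs at least 2 distinct temperatures")
  }
  if (anyDuplicated(paste(labels, temps))) {
    stop("duplicate temperature + label combination in panel")
  }
  fits <- lapply(traces, fit_decay)
  out <- data.frame(
    label = labels, temperature_K = temps,
    model = vapply(fits, `[[`, "", "model"),
    k_per_min = vapply(fits, `[[`, 0, "k"),
    plateau = vapply(fits, `[[`, 0, "plateau"),
    total_loss = vapply(fits, `[[`, 0, "total_loss"),
    classification = vapply(fits, `[[`, "", "classification"))
  out <- out[order(out$label, out$temperature_K), , drop = FALSE]
  rownames(out) <- NULL
  mono <- vapply(split(out, out$label), function(d) {
    if (nrow(d) < 2 || stats::sd(d$k_per_min) == 0) return(FALSE)
    isTRUE(all.equal(suppressWarnings(
      stats::cor(d$temperature_K, d$k_per_min, method = "spearman")), 1))
  }, logical(1))
  structure(out, monotone_k = mono,
            class = c("lability_panel", "data.frame"))
}

#' Read decay traces from CSV
#'
#' Expects columns `time_min`, `A458`, `temperature_K`, `label`; one trace
#' per (label, temperature) combination.
#'
#' @param path CSV file.
#' @return List of `decay_trace` objects.
#' @export
read_decay_traces <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_min", "A458", "temperature_K", "label")
  if (!all(need %in% names(df))) {
    stop("traces CSV must have columns: ", paste(need, collapse = ", "))
  }
  keys <- unique(df[, c("label", "temperature_K")])
  lapply(seq_len(nrow(keys)), function(r) {
    d <- df[df$label == keys$label[r] &
              df$temperature_K == keys$temperature_K[r], ]
    d <- d[order(d$time_min), ]
    decay_trace(d$time_min, d$A458, keys$temperature_K[r], keys$label[r])
  })
}
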