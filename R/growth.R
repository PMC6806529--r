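#' Fit the logistic growth model to one culture's intensity time series
#'
#' Estimates the cell proliferation parameters (CPPs) of a spotted culture
#' by nonlinear least squares on the logistic model
#' \deqn{G(t) = K / (1 + e^{-r (t - l)})}
#' where `K` is the carrying capacity (intensity units), `r` the maximum
#' specific rate (1/h) and `l` the time at which `G(l) = K/2` (hours).
#' Optimization uses Levenberg-Marquardt ([minpack.lm::nlsLM]) with bounds
#' `K` in (0, 2 max(y)], `r` in (0, 10], `l` in [0, 2 horizon], which keep
#' the solver in the identifiable region. Starting values are `K0 = max(y)`,
#' with `r0` and `l0` from a log-odds (logit) regression of the mid-phase
#' points, under which the model is linear: `logit(y/K) = r (t - l)`.
#'
#' A culture that yields no usable curve (flat trace, solver failure,
#' fitted `K` below `k_floor`, or a fitted half-time `l` outside the
#' observed window, in which case the curve -- and hence the L parameter --
#' is unidentifiable from the data) is flagged `no_growth` and reported with
#' `K = 0`, `r = 0`, `l = NA` and `AUC = 0`. Library-level thresholding
#' against the reference strain (fitted `K` below 5% of the reference median
#' at dose 0) is applied by [fit_cpps()], which knows the reference context.
#'
#' @param times observation times, hours, strictly increasing, length >= 4.
#' @param intensities non-negative image intensities, same length.
#' @param k_floor absolute lower bound on fitted `K` below which the culture
#'   is declared `no_growth` (default 1e-3 intensity units).
#' @return object of class `"logistic_fit"`: list with `K`, `r`, `l`, `auc`
#'   (analytic integral of the fitted curve over the observation window),
#'   `rss`, `growth_flag` (`"growth"`/`"no_growth"`), `n`, and the data.
#' @seealso [fit_cpps()], [logistic_auc()]
#' @examples
#' t <- seq(0, 40, 2)
#' y <- 100 / (1 + exp(-0.3 * (t - 10)))
#' fit <- fit_logistic(t, y)
#' coef(fit)
#' @export
fit_logistic <- function(times, intensities, k_floor = 1e-3) {
  if (length(times) != length(intensities))
    stop("times and intensities must have equal length")
  if (length(times) < 4L)
    stop("at least 4 time points are required to fit 3 parameters")
  if (any(!is.finite(times)) || any(!is.finite(intensities)))
    stop("non-finite values in the time series")
  if (is.unsorted(times, strictly = TRUE))
    stop("times must be strictly increasing")
  horizon <- max(times)

  flat <- diff(range(intensities)) <= max(1e-12, 1e-6 * max(abs(intensities)))
  fit <- if (flat) NULL else .fit_logistic_lm(times, intensities, horizon)
  if (is.null(fit) || fit$K < k_floor ||
      fit$l < min(times) || fit$l > max(times)) {
    return(structure(list(K = 0, r = 0, l = NA_real_, auc = 0,
                          rss = sum((intensities - mean(intensities))^2),
                          growth_flag = "no_growth", n = length(times),
                          times = times, intensities = intensities),
                     class = "logistic_fit"))
  }
  fit$auc <- logistic_auc(fit$K, fit$r, fit$l, min(times), horizon)
  fit$growth_flag <- "growth"
  fit$n <- length(times)
  fit$times <- times
  fit$intensities <- intensities
  structure(fit, class = "logistic_fit")
}

.logistic_start <- function(t, y, horizon) {
  K0 <- max(y)
  mid <- y > 0.05 * K0 & y < 0.95 * K0
  if (sum(mid) >= 2) {
    z <- log(y[mid] / (K0 - y[mid]))
    sl <- stats::coef(stats::lm(z ~ t[mid]))
    r0 <- unname(sl[2]); l0 <- unname(-sl[1] / sl[2])
  } else {
    r0 <- NA_real_; l0 <- NA_real_
  }
  if (!is.finite(r0) || r0 <= 0) r0 <- 4 / max(diff(range(t)), 1)
  if (!is.finite(l0) || l0 < 0 || l0 > 2 * horizon)
    l0 <- t[which(y >= K0 / 2)[1]]
  if (!is.finite(l0)) l0 <- stats::median(t)
  c(K = K0, r = min(r0, 10), l = min(max(l0, 0), 2 * horizon))
}

.fit_logistic_lm <- function(t, y, horizon) {
  start <- .logistic_start(t, y, horizon)
  lower <- c(K = 1e-8, r = 1e-4, l = 0)
  upper <- c(K = 2 * max(y), r = 10, l = 2 * horizon)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ K / (1 + exp(-r * (t - l))),
                      start = as.list(start), lower = lower, upper = upper,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL, warning = function(w) NULL)
  if (is.null(fit)) return(NULL)
  cf <- stats::coef(fit)
  list(K = unname(cf["K"]), r = unname(cf["r"]), l = unname(cf["l"]),
       rss = sum(stats::residuals(fit)^2))
}

#' Analytic area under a fitted logistic curve
#'
#' The antiderivative of `K / (1 + exp(-r (t - l)))` is
#' `K (t + log(1 + exp(-r (t - l))) / r)`, evaluated here with an
#' overflow-stable softplus. In the step-function limit (`r -> Inf`) the
#' area over `[0, T]` tends to `K (T - l)`.
#'
#' @param K,r,l logistic parameters (`r > 0`).
#' @param lower,upper integration bounds, hours.
#' @return the integral (intensity x hours); 0 for a zero-width window.
#' @export
logistic_auc <- function(K, r, l, lower, upper) {
  if (upper < lower) stop("upper must be >= lower")
  softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))
  antideriv <- function(t) K * (t + softplus(-r * (t - l)) / r)
  antideriv(upper) - antideriv(lower)
}

#' @export
coef.logistic_fit <- function(object, ...) {
  c(K = object$K, r = object$r, l = object$l)
}

#' @export
predict.logistic_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$times else
    if (is.list(newdata)) newdata$times else newdata
  if (object$growth_flag == "no_growth") return(rep(0, length(t)))
  object$K / (1 + exp(-object$r * (t - object$l)))
}

#' @export
residuals.logistic_fit <- function(object, ...) {
  object$intensities - predict(object)
}

#' @export
print.logistic_fit <- function(x, ...) {
  if (x$growth_flag == "no_growth") {
    cat("Logistic fit: no growth curve (flat or unfittable trace)\n")
  } else {
    cat(sprintf(
      "Logistic fit: K = %.4g, r = %.4g /h, l = %.4g h, AUC = %.4g (rss %.3g, n = %d)\n",
      x$K, x$r, x$l, x$auc, x$rss, x$n))
  }
  invisible(x)
}

#' @export
plot.logistic_fit <- function(x, ...) {
  plot(x$times, x$intensities, xlab = "time (h)", ylab = "intensity", ...)
  if (x$growth_flag == "growth") {
    tt <- seq(min(x$times), max(x$times), length.out = 200)
    graphics::lines(tt, x$K / (1 + exp(-x$r * (tt - x$l))))
  }
  invisible(x)
}

#' Fit CPPs for every culture in a time-series table
#'
#' Applies [fit_logistic()] to each (strain, medium, dose, replicate)
#' culture and then applies the library-level no-growth rule: a fitted
#' carrying capacity below `no_growth_frac` of the reference median `K` at
#' dose 0 (per medium) is reclassified as `no_growth` with `K = r = 0`.
#' When no reference cultures are present the relative rule is skipped and
#' only per-culture criteria apply.
#'
#' @param timeseries long data.frame with columns `strain_id`, `medium`,
#'   `dose`, `replicate`, `time_h`, `intensity`.
#' @param reference_id strain identifier of the reference cultures.
#' @param no_growth_frac fraction of the reference median dose-0 `K` below
#'   which a culture is called `no_growth`.
#' @return data.frame of class `c("cpp_table", "data.frame")` with one row
#'   per culture: `strain_id`, `medium`, `dose`, `replicate`, `K`, `r`, `l`,
#'   `auc`, `rss`, `growth_flag`.
#' @export
fit_cpps <- function(timeseries, reference_id = "REF", no_growth_frac = 0.05) {
  need <- c("strain_id", "medium", "dose", "replicate", "time_h", "intensity")
  miss <- setdiff(need, names(timeseries))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  key <- interaction(timeseries$strain_id, timeseries$medium,
                     timeseries$dose, timeseries$replicate, drop = TRUE)
  idx <- split(seq_len(nrow(timeseries)), key)
  out <- vector("list", length(idx))
  for (i in seq_along(idx)) {
    rows <- idx[[i]]
    ord <- rows[order(timeseries$time_h[rows])]
    f <- fit_logistic(timeseries$time_h[ord], timeseries$intensity[ord])
    out[[i]] <- data.frame(strain_id = timeseries$strain_id[ord[1]],
                           medium = timeseries$medium[ord[1]],
                           dose = timeseries$dose[ord[1]],
                           replicate = timeseries$replicate[ord[1]],
                           K = f$K, r = f$r, l = f$l, auc = f$auc,
                           rss = f$rss, growth_flag = f$growth_flag,
                           stringsAsFactors = FALSE)
  }
  cpps <- do.call(rbind, out)
  cpps <- cpps[order(cpps$medium, cpps$strain_id, cpps$dose, cpps$replicate), ]
  rownames(cpps) <- NULL
  # relative no-growth rule against the same-medium reference at dose 0
  for (m in unique(cpps$medium)) {
    ref0 <- cpps$strain_id == reference_id & cpps$medium == m &
      cpps$dose == min(cpps$dose) & cpps$growth_flag == "growth"
    if (!any(ref0)) next
    thr <- no_growth_frac * stats::median(cpps$K[ref0])
    low <- cpps$medium == m & cpps$growth_flag == "growth" & cpps$K < thr
    if (any(low)) {
      cpps$growth_flag[low] <- "no_growth"
      cpps$K[low] <- 0; cpps$r[low] <- 0
      cpps$l[low] <- NA_real_; cpps$auc[low] <- 0
    }
  }
  class(cpps) <- c("cpp_table", "data.frame")
  cpps
}
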