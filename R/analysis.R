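#' Contrast schemes for condition effects
#'
#' Two coding schemes are supported. *Dummy* coding estimates each
#' condition's difference from a reference level (intact sentences in the
#' source experiments). *Backwards difference* coding estimates the
#' difference between each level and the level preceding it in the ordered
#' condition list, so every step of increasing degradation gets its own
#' coefficient.
#'
#' @param scheme `"dummy"` or `"backwards_difference"`.
#' @param levels Ordered character vector of condition levels.
#' @param reference Reference level (dummy coding only; default the first
#'   level).
#' @return An object of class `contrast_scheme`.
#' @export
contrast_scheme <- function(scheme = c("dummy", "backwards_difference"),
                            levels, reference = levels[1]) {
  scheme <- match.arg(scheme)
  if (anyDuplicated(levels)) stop("levels must be distinct", call. = FALSE)
  if (length(levels) < 2) stop("need at least 2 levels", call. = FALSE)
  if (scheme == "dummy" && !reference %in% levels)
    stop("reference must be one of the levels", call. = FALSE)
  s <- list(scheme = scheme, levels = levels,
            reference = if (scheme == "dummy") reference else NA_character_)
  class(s) <- "contrast_scheme"
  s
}

#' Contrast coding matrix
#'
#' Returns the levels x contrasts coding matrix of a [contrast_scheme()].
#' For dummy coding these are indicator columns for each non-reference
#' level. For backwards-difference coding the columns are such that, in a
#' balanced noise-free fit with an intercept, fitted contrast `j` equals
#' `mean(level j+1) - mean(level j)` (the successive-differences coding).
#'
#' @param scheme A [contrast_scheme()].
#' @return Numeric matrix with `length(levels)` rows, dimnames set.
#' @export
contrast_matrix <- function(scheme) {
  stopifnot(inherits(scheme, "contrast_scheme"))
  L <- length(scheme$levels)
  if (scheme$scheme == "dummy") {
    others <- setdiff(scheme$levels, scheme$reference)
    C <- matrix(0, L, L - 1,
                dimnames = list(scheme$levels, paste0(others, "_vs_", scheme$reference)))
    for (j in seq_along(others)) C[others[j], j] <- 1
  } else {
    C <- matrix(0, L, L - 1,
                dimnames = list(scheme$levels,
                                paste0(scheme$levels[-1], "_minus_", scheme$levels[-L])))
    for (j in seq_len(L - 1)) {
      C[seq_len(j), j] <- -(L - j) / L
      C[(j + 1):L, j] <- j / L
    }
  }
  C
}

# hypothesis weights: rows = contrasts, cols = levels; applied to a vector
# of per-level means these give the fitted contrasts of the coding matrix
contrast_weights <- function(scheme) {
  C <- contrast_matrix(scheme)
  W <- solve(cbind(`(Intercept)` = 1, C))[-1, , drop = FALSE]
  colnames(W) <- rownames(C)
  W
}

#' Estimate condition contrasts with a two-stage cluster bootstrap
#'
#' A design-based stand-in for a mixed-effects regression of condition on
#' response: stage one collapses the response table to per-participant
#' condition means (averaging over items or regions of interest); stage two
#' applies the contrast scheme to each participant's means and reports the
#' across-participant mean of each contrast with a percentile bootstrap
#' confidence interval obtained by resampling participants (clusters) with
#' replacement. Deterministic given `seed`.
#'
#' @param data A response table: data.frame with columns `participant`,
#'   `condition`, `value` (and usually `unit`). Every
#'   (participant, condition) cell must contain at least one observation.
#' @param scheme A [contrast_scheme()]; its levels must all be present in
#'   `data`.
#' @param n_boot Number of bootstrap resamples (default 5000). Fewer than
#'   100 triggers a warning.
#' @param seed Integer seed for the bootstrap.
#' @param conf_level Confidence level (default 0.95).
#' @return An object of class `effect_fit` with `print()`, `summary()`,
#'   `coef()`, `confint()` and `plot()` methods. The `estimates` element is
#'   a data.frame with columns `contrast`, `estimate`, `lower`, `upper`,
#'   `n_clusters`.
#' @seealso [accuracy_summary()] for Bernoulli outcomes.
#' @export
estimate_effects <- function(data, scheme, n_boot = 5000, seed = 1L,
                             conf_level = 0.95) {
  two_stage_fit(data, scheme, n_boot, seed, conf_level, stage1 = "mean")
}

#' Condition contrasts for accuracy data on the log-odds scale
#'
#' As [estimate_effects()], but stage one computes each participant's
#' log-odds of success per condition, with a 0.5 continuity correction
#' (`log((successes + 0.5) / (failures + 0.5))`) so that all-correct and
#' all-wrong cells stay finite — the design-based analogue of a logistic
#' mixed model.
#'
#' @inheritParams estimate_effects
#' @param data A response table whose `value` column is 0/1.
#' @return An `effect_fit`; estimates are differences in log-odds.
#' @export
accuracy_summary <- function(data, scheme, n_boot = 5000, seed = 1L,
                             conf_level = 0.95) {
  if (!all(data$value %in% c(0, 1)))
    stop("accuracy_summary expects 0/1 outcomes", call. = FALSE)
  two_stage_fit(data, scheme, n_boot, seed, conf_level, stage1 = "logodds")
}

two_stage_fit <- function(data, scheme, n_boot, seed, conf_level, stage1) {
  stopifnot(inherits(scheme, "contrast_scheme"))
  data <- as.data.frame(data)
  need <- c("participant", "condition", "value")
  if (!all(need %in% names(data)))
    stop("data must have columns ", paste(need, collapse = ", "), call. = FALSE)
  data <- data[data$condition %in% scheme$levels, , drop = FALSE]
  participants <- sort(unique(data$participant))
  missing <- character()
  for (p in participants) {
    have <- unique(data$condition[data$participant == p])
    miss <- setdiff(scheme$levels, have)
    if (length(miss))
      missing <- c(missing, paste0(p, ":", miss))
  }
  if (length(missing))
    stop("missing (participant, condition) cells: ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (n_boot < 100)
    warning("n_boot < 100; confidence intervals will be unstable", call. = FALSE)

  # stage 1: participant x condition summary
  agg <- if (stage1 == "mean") {
    tapply(data$value, list(data$participant, data$condition), mean)
  } else {
    tapply(data$value, list(data$participant, data$condition), function(v) {
      s <- sum(v)
      log((s + 0.5) / (length(v) - s + 0.5))
    })
  }
  M <- agg[participants, scheme$levels, drop = FALSE]

  # stage 2: per-participant contrasts, then cluster bootstrap
  W <- contrast_weights(scheme)
  Cp <- M %*% t(W)  # participants x contrasts
  est <- colMeans(Cp)
  np <- nrow(Cp)
  boot <- with_seed(seed, {
    idx <- matrix(sample.int(np, np * n_boot, replace = TRUE), nrow = n_boot)
    t(apply(idx, 1, function(ii) colMeans(Cp[ii, , drop = FALSE])))
  })
  if (nrow(W) == 1) boot <- matrix(c(boot), ncol = 1)  # single-contrast guard
  a <- (1 - conf_level) / 2
  ci <- apply(boot, 2, stats::quantile, probs = c(a, 1 - a), names = FALSE)

  fit <- list(
    estimates = data.frame(
      contrast = rownames(W),
      estimate = unname(est),
      lower = ci[1, ],
      upper = ci[2, ],
      n_clusters = np,
      stringsAsFactors = FALSE),
    scheme = scheme,
    stage1 = stage1,
    participant_means = M,
    participant_contrasts = Cp,
    n_boot = n_boot,
    seed = seed,
    conf_level = conf_level
  )
  class(fit) <- "effect_fit"
  fit
}

#' @export
print.effect_fit <- function(x, ...) {
  cat("Two-stage cluster-bootstrap condition contrasts (",
      x$scheme$scheme, " coding, ", x$n_clusters %||% x$estimates$n_clusters[1],
      " participants, ", x$n_boot, " resamples)\n", sep = "")
  df <- x$estimates
  df$estimate <- signif(df$estimate, 4)
  df$lower <- signif(df$lower, 4)
  df$upper <- signif(df$upper, 4)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
summary.effect_fit <- function(object, ...) {
  out <- object$estimates
  out$excludes_zero <- out$lower > 0 | out$upper < 0
  structure(list(estimates = out, scheme = object$scheme,
                 stage1 = object$stage1, n_boot = object$n_boot,
                 conf_level = object$conf_level),
            class = "summary.effect_fit")
}

#' @export
print.summary.effect_fit <- function(x, ...) {
  cat("Condition-effect estimates (", x$scheme$scheme, " coding; ",
      100 * x$conf_level, "% percentile bootstrap CIs; stage 1 = ",
      if (x$stage1 == "mean") "participant means" else "participant log-odds",
      ")\n", sep = "")
  df <- x$estimates
  df$estimate <- signif(df$estimate, 4)
  df$lower <- signif(df$lower, 4)
  df$upper <- signif(df$upper, 4)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
coef.effect_fit <- function(object, ...) {
  stats::setNames(object$estimates$estimate, object$estimates$contrast)
}

#' @export
confint.effect_fit <- function(object, parm, level, ...) {
  ci <- as.matrix(object$estimates[, c("lower", "upper")])
  rownames(ci) <- object$estimates$contrast
  colnames(ci) <- paste0(100 * c((1 - object$conf_level) / 2,
                                 1 - (1 - object$conf_level) / 2), " %")
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
plot.effect_fit <- function(x, ...) {
  df <- x$estimates
  n <- nrow(df)
  graphics::plot(df$estimate, seq_len(n), xlim = range(c(df$lower, df$upper, 0)),
                 ylim = c(0.5, n + 0.5), yaxt = "n", pch = 19,
                 xlab = "estimate", ylab = "", ...)
  graphics::segments(df$lower, seq_len(n), df$upper, seq_len(n))
  graphics::abline(v = 0, lty = 2, col = "grey50")
  graphics::axis(2, at = seq_len(n), labels = df$contrast, las = 1, cex.axis = 0.7)
  invisible(x)
}
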