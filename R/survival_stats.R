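as_surv_records <- function(records) {
  stopifnot(is.data.frame(records), all(c("time", "event") %in% names(records)))
  if (nrow(records) == 0L) stop_domain("survival: empty record set")
  if (any(records$time <= 0)) stop_domain("survival: times must be positive")
  records
}

#' Kaplan-Meier survival curve and mean/median survival
#'
#' Product-limit estimator over one cohort. With no censoring (the model has
#' 100% mortality, so every KO record is an event) the estimated mean
#' survival equals the arithmetic mean of the death ages, and the curve drops
#' 1/n at each distinct death time (ties stack).
#'
#' @param records Data frame with `time` (age at death, days) and `event`
#'   (TRUE = death observed).
#' @return List of class `km_curve`: `time`, `surv` (step function values
#'   after each distinct time), `n`, `mean` (restricted mean to the last
#'   event time), `median`.
#' @export
km_curve <- function(records) {
  records <- as_surv_records(records)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = records)
  s <- summary(fit)
  tt <- fit$time
  ss <- fit$surv
  # restricted mean: integral of S(t) up to the last observed time
  steps <- diff(c(0, tt))
  mean_surv <- sum(steps * c(1, ss[-length(ss)]))
  med <- unname(stats::quantile(fit, probs = 0.5)$quantile)
  structure(list(
    time = tt, surv = ss, n = nrow(records),
    mean = mean_surv, median = med
  ), class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: n = %d, mean survival %.1f days, median %.1f days\n",
              x$n, x$mean, x$median))
  invisible(x)
}

#' Log-rank (Mantel-Cox) comparison of two survival curves
#'
#' Standard Mantel-Cox statistic over the pooled distinct event times;
#' symmetric in group order. Identical groups give statistic 0 and p = 1.
#'
#' @param group_a,group_b Data frames with `time` and `event`.
#' @return List: `chisq`, `df`, `p`.
#' @export
logrank_test <- function(group_a, group_b) {
  group_a <- as_surv_records(group_a)
  group_b <- as_surv_records(group_b)
  d <- rbind(
    data.frame(time = group_a$time, event = group_a$event, g = "A"),
    data.frame(time = group_b$time, event = group_b$event, g = "B")
  )
  sd_fit <- survival::survdiff(survival::Surv(time, event) ~ g, data = d)
  chisq <- unname(sd_fit$chisq)
  list(chisq = chisq, df = 1L, p = pchisq(chisq, df = 1, lower.tail = FALSE))
}

#' Mantel-Haenszel hazard ratio with 95% confidence interval
#'
#' HR = (O_A/E_A) / (O_B/E_B) from the log-rank observed/expected table, with
#' the log-scale confidence interval SE(log HR) = sqrt(1/E_A + 1/E_B).
#' Satisfies HR(A, B) = 1 / HR(B, A).
#'
#' @inheritParams logrank_test
#' @param conf_level Confidence level (default 0.95).
#' @return List: `hr`, `ci` (length-2), `obs`, `exp`.
#' @export
hazard_ratio_mh <- function(group_a, group_b, conf_level = 0.95) {
  group_a <- as_surv_records(group_a)
  group_b <- as_surv_records(group_b)
  if (!any(group_a$event) || !any(group_b$event)) {
    stop_domain("hazard_ratio_mh: both groups need at least one event")
  }
  d <- rbind(
    data.frame(time = group_a$time, event = group_a$event, g = "A"),
    data.frame(time = group_b$time, event = group_b$event, g = "B")
  )
  d$g <- factor(d$g, levels = c("A", "B"))
  sd_fit <- survival::survdiff(survival::Surv(time, event) ~ g, data = d)
  O <- sd_fit$obs
  E <- sd_fit$exp
  if (any(E <= 0)) stop_domain("hazard_ratio_mh: zero expected events in a group; HR undefined")
  hr <- (O[1] / E[1]) / (O[2] / E[2])
  se <- sqrt(1 / E[1] + 1 / E[2])
  z <- qnorm(1 - (1 - conf_level) / 2)
  list(hr = unname(hr),
       ci = unname(exp(log(hr) + c(-1, 1) * z * se)),
       obs = unname(O), exp = unname(E))
}
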