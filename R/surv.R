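# Survival machinery: product-limit curves, log-rank tests, proportional-
# hazards fits (via the survival package, Efron ties) and the maximally
# selected log-rank cutpoint.

# Administrative truncation at a follow-up horizon (years): later times are
# censored at the horizon.
.truncateFollowup <- function(times, events, years) {
  if (is.null(years)) return(list(times = times, events = events))
  horizon <- years * 365.25
  over <- times > horizon
  times[over] <- horizon
  events[over] <- 0L
  list(times = times, events = events)
}

#' Kaplan-Meier curves per group
#'
#' Product-limit estimate per group after administrative censoring at the
#' follow-up horizon.
#'
#' @param times positive survival times (days).
#' @param events 0/1 event indicators.
#' @param groups group label per subject.
#' @param truncateYears follow-up horizon in years (`NULL` disables).
#' @return Named list of per-group data.frames (`time`, `n.risk`,
#'   `n.event`, `n.censor`, `surv`).
#' @export
kmFit <- function(times, events, groups = rep("all", length(times)),
                  truncateYears = 10) {
  stopifnot(all(times > 0), all(events %in% c(0, 1)))
  groups <- as.character(groups)
  if (any(table(factor(groups)) == 0) || !length(times))
    stop("empty group")
  tr <- .truncateFollowup(times, as.integer(events), truncateYears)
  out <- lapply(split(seq_along(times), groups), function(idx) {
    sf <- survival::survfit(survival::Surv(tr$times[idx], tr$events[idx]) ~ 1)
    data.frame(time = sf$time, n.risk = sf$n.risk, n.event = sf$n.event,
               n.censor = sf$n.censor, surv = sf$surv)
  })
  out
}

#' Log-rank test
#'
#' Observed-minus-expected statistic over pooled event times with
#' hypergeometric variance; chi-square p on (groups - 1) degrees of
#' freedom.
#'
#' @inheritParams kmFit
#' @param truncateYears optional follow-up horizon in years applied before
#'   testing (`NULL`, the default, uses the full follow-up).
#' @return List with `statistic`, `df`, `p`.
#' @export
logrankTest <- function(times, events, groups, truncateYears = NULL) {
  groups <- factor(as.character(groups))
  if (nlevels(groups) < 2) stop("log-rank needs >= 2 groups")
  if (sum(events) < 1) stop("log-rank needs >= 1 event")
  tr <- .truncateFollowup(times, as.integer(events), truncateYears)
  sd <- survival::survdiff(survival::Surv(tr$times, tr$events) ~ groups)
  df <- nlevels(groups) - 1
  list(statistic = unname(sd$chisq), df = df,
       p = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Cox proportional-hazards fit
#'
#' Partial-likelihood fit with Efron tie handling (Newton-Raphson via the
#' survival package). Constant covariates, more covariates than subjects,
#' and monotone-likelihood (perfect separation) fits are errors.
#'
#' @inheritParams kmFit
#' @param covariates data.frame or matrix of covariates (one column each).
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return `CoxFit` data.frame: one row per covariate with `beta`, `HR`,
#'   `se`, 95% CI bounds and Wald `p`; log partial likelihood and n are
#'   attributes.
#' @export
coxFit <- function(times, events, covariates, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  covariates <- as.data.frame(covariates)
  if (nrow(covariates) != length(times))
    stop("covariate rows must match the number of subjects")
  if (length(times) <= ncol(covariates))
    stop("need more subjects than covariates")
  isConst <- vapply(covariates, function(v) length(unique(v)) < 2, TRUE)
  if (any(isConst))
    stop("constant covariate(s): ",
         paste(colnames(covariates)[isConst], collapse = ", "))
  dat <- cbind(data.frame(.time = times, .event = as.integer(events)),
               covariates)
  fit <- survival::coxph(survival::Surv(.time, .event) ~ ., data = dat,
                         ties = ties)
  if (!is.null(fit$info) && any(is.na(stats::coef(fit))))
    stop("Cox fit failed")
  beta <- stats::coef(fit)
  if (any(is.na(beta)) || any(abs(beta) > 15))
    stop("monotone partial likelihood (perfect separation?)")
  se <- sqrt(diag(fit$var))
  out <- data.frame(term = names(beta), beta = unname(beta),
                    HR = exp(unname(beta)), se = se,
                    lower95 = exp(unname(beta) - 1.96 * se),
                    upper95 = exp(unname(beta) + 1.96 * se),
                    p = 2 * stats::pnorm(-abs(unname(beta) / se)),
                    row.names = NULL)
  attr(out, "logLik") <- fit$loglik[2]
  attr(out, "n") <- fit$n
  attr(out, "ties") <- ties
  out
}

# Standardized two-group log-rank statistic z = (O1 - E1) / sqrt(V) for the
# "high" group indicator, computed over distinct event times. O(n) after one
# sort; used by the cutpoint scan and tested against survdiff.
logrankZ <- function(times, events, high) {
  ord <- order(times)
  t <- times[ord]
  e <- events[ord]
  g <- as.integer(high[ord])
  n <- length(t)
  atRisk <- n - seq_len(n) + 1L
  atRisk1 <- rev(cumsum(rev(g)))
  first <- !duplicated(t)
  dTot <- rev(cumsum(rev(e)))
  d1Tot <- rev(cumsum(rev(e * g)))
  idx <- which(first)
  nextIdx <- c(idx[-1], n + 1L)
  d <- dTot[idx] - c(dTot[nextIdx[-length(idx)]], 0)
  d1 <- d1Tot[idx] - c(d1Tot[nextIdx[-length(idx)]], 0)
  nr <- atRisk[idx]
  nr1 <- atRisk1[idx]
  use <- d > 0 & nr > 1
  U <- sum(d1[use] - d[use] * nr1[use] / nr[use])
  V <- sum(d[use] * (nr1[use] / nr[use]) * (1 - nr1[use] / nr[use]) *
             (nr[use] - d[use]) / (nr[use] - 1))
  if (V <= 0) return(NA_real_)
  U / sqrt(V)
}

#' Maximally selected log-rank cutpoint
#'
#' Scans the distinct score values that leave at least `ceiling(minprop * n)`
#' subjects on each side, computes the standardized two-group log-rank
#' statistic at each candidate split (high = score strictly greater than the
#' candidate), and selects the candidate maximizing the absolute
#' standardized statistic (smallest value on ties).
#'
#' @inheritParams kmFit
#' @param score numeric per-subject score with >= 2 distinct values.
#' @param minprop minimum proportion of subjects per group.
#' @return A [CutpointResult-class].
#' @export
survCutpoint <- function(times, events, score, minprop = 0.1) {
  n <- length(score)
  if (n < 10) stop("need >= 10 subjects")
  if (length(unique(score)) < 2) stop("score must have >= 2 distinct values")
  minN <- ceiling(minprop * n)
  cand <- sort(unique(score))
  nBelow <- cumsum(table(factor(score, levels = cand)))
  ok <- nBelow >= minN & (n - nBelow) >= minN
  cand <- cand[ok]
  if (!length(cand)) stop("no admissible cutpoint candidate")
  z <- vapply(cand, function(cc) logrankZ(times, events, score > cc),
              numeric(1))
  stats_df <- data.frame(cutpoint = cand, z = z)
  best <- which(abs(z) == max(abs(z), na.rm = TRUE))[1]
  cutoff <- cand[best]
  sizes <- c(low = sum(score <= cutoff), high = sum(score > cutoff))
  new("CutpointResult", cutoff = cutoff, statistics = stats_df,
      minprop = minprop, groupSizes = as.integer(sizes) |>
        stats::setNames(c("low", "high")))
}
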