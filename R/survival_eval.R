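# Kaplan-Meier estimation and pairwise log-rank comparison of predicted
# subtypes. The two-group log-rank statistic is computed directly from the
# pooled risk set (standard aggregated formulation for tied event times);
# tests cross-check it against survival::survdiff.

#' Kaplan-Meier survival estimate for one group
#'
#' Product-limit estimator (via `survival::survfit`): right-continuous,
#' non-increasing, starting at 1.
#'
#' @param tab a `SurvivalTable` (rows of one group).
#' @return A data.frame with columns `time`, `n_risk`, `n_event`, `surv`,
#'   the step function evaluated at the observed times.
#' @export
km_estimate <- function(tab) {
  stopifnot(inherits(tab, "SurvivalTable"))
  if (nrow(tab) == 0) stop("empty survival table", call. = FALSE)
  fit <- survival::survfit(survival::Surv(tab$time, tab$event) ~ 1)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             surv = fit$surv)
}

#' Two-group log-rank test
#'
#' Observed-versus-expected events over the pooled risk set, with the
#' standard hypergeometric variance and aggregated handling of tied event
#' times; the statistic is chi-squared with 1 df.
#'
#' @param g1,g2 `SurvivalTable`s for the two groups (both non-empty; at
#'   least one event overall).
#' @return List with `statistic` (chi-square), `p_value`, `observed` and
#'   `expected` events in group 1.
#' @export
logrank_test <- function(g1, g2) {
  stopifnot(inherits(g1, "SurvivalTable"), inherits(g2, "SurvivalTable"))
  if (nrow(g1) == 0 || nrow(g2) == 0)
    stop("both groups must be non-empty", call. = FALSE)
  time <- c(g1$time, g2$time)
  event <- c(g1$event, g2$event)
  grp1 <- c(rep(TRUE, nrow(g1)), rep(FALSE, nrow(g2)))
  if (sum(event) == 0)
    stop("log-rank undefined: no events in the pooled data", call. = FALSE)
  event_times <- sort(unique(time[event == 1]))
  o1 <- e1 <- v <- 0
  for (t in event_times) {
    at_risk <- time >= t
    n_j <- sum(at_risk)
    n1_j <- sum(at_risk & grp1)
    d_j <- sum(event == 1 & time == t)
    d1_j <- sum(event == 1 & time == t & grp1)
    o1 <- o1 + d1_j
    e1 <- e1 + d_j * n1_j / n_j
    if (n_j > 1)
      v <- v + d_j * (n1_j / n_j) * (1 - n1_j / n_j) * (n_j - d_j) / (n_j - 1)
  }
  if (v == 0) return(list(statistic = 0, p_value = 1, observed = o1,
                          expected = e1))
  chi <- (o1 - e1)^2 / v
  list(statistic = chi, p_value = stats::pchisq(chi, df = 1, lower.tail = FALSE),
       observed = o1, expected = e1)
}

#' Pairwise log-rank matrix over predicted subtypes
#'
#' One two-group log-rank test per unordered class pair, reported as a
#' symmetric matrix of `-log10(p)`. Pairs with zero pooled events yield
#' `NA` (flagged missing) rather than a number. No multiplicity correction
#' is applied by default, matching raw pairwise reporting; `bonferroni =
#' TRUE` multiplies the p-values by the number of pairs tested.
#'
#' @param groups a `SubtypeLabelSet` (typically predicted labels).
#' @param survival a `SurvivalTable` covering the labeled samples.
#' @param bonferroni apply Bonferroni correction over the pairs.
#' @return A k x k symmetric matrix of `-log10(p)` with `NA` diagonal.
#' @export
pairwise_logrank <- function(groups, survival, bonferroni = FALSE) {
  stopifnot(inherits(groups, "SubtypeLabelSet"),
            inherits(survival, "SurvivalTable"))
  surv <- survival[survival$sample %in% names(groups$labels), , drop = FALSE]
  surv$group <- unname(groups$labels[surv$sample])
  present <- intersect(groups$scheme$classes, unique(surv$group))
  if (length(present) < 2)
    stop("need >= 2 classes with samples", call. = FALSE)
  k <- length(present)
  out <- matrix(NA_real_, k, k, dimnames = list(present, present))
  pairs <- utils::combn(present, 2)
  n_pairs <- ncol(pairs)
  for (j in seq_len(n_pairs)) {
    a <- pairs[1, j]; b <- pairs[2, j]
    ta <- surv[surv$group == a, , drop = FALSE]
    tb <- surv[surv$group == b, , drop = FALSE]
    class(ta) <- class(tb) <- c("SurvivalTable", "data.frame")
    if (sum(ta$event) + sum(tb$event) == 0) next  # flagged missing cell
    p <- logrank_test(ta, tb)$p_value
    if (bonferroni) p <- min(1, p * n_pairs)
    out[a, b] <- out[b, a] <- -log10(p)
  }
  out
}
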