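.joinClinical <- function(scores, clinical, fields) {
  if (anyDuplicated(clinical$sample)) stop("duplicate sample ids in clinical")
  m <- merge(scores, clinical, by = "sample", sort = FALSE)
  keep <- stats::complete.cases(m[, fields, drop = FALSE])
  if (any(!keep)) {
    message(sum(!keep), " sample(s) dropped for missing clinical fields")
  }
  m[keep, , drop = FALSE]
}

#' One-way ANOVA of CI score across tumor grades
#'
#' Tests whether the mean signature score differs across grade strata;
#' singleton grade groups are excluded with a warning. Per-grade median and
#' quartile summaries are returned alongside the F statistic.
#'
#' @param scores a score table from [scoreSamples()] (column \code{score}).
#' @param clinical data.frame with columns \code{sample} and \code{grade}.
#' @return list with \code{f}, \code{pvalue}, \code{df} and a per-grade
#'   \code{summary} data.frame (n, median, q25, q75).
#' @export
gradeAssociation <- function(scores, clinical) {
  m <- .joinClinical(scores, clinical, c("score", "grade"))
  m$grade <- droplevels(factor(m$grade))
  sizes <- table(m$grade)
  if (any(sizes < 2)) {
    warning("singleton grade group(s) excluded: ",
            paste(names(sizes)[sizes < 2], collapse = ", "))
    m <- m[m$grade %in% names(sizes)[sizes >= 2], ]
    m$grade <- droplevels(m$grade)
  }
  if (nlevels(m$grade) < 2) stop("need at least 2 grade groups with >= 2 samples")
  grandMean <- mean(m$score)
  groups <- split(m$score, m$grade)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - grandMean)^2,
                    numeric(1)))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  df1 <- length(groups) - 1L
  df2 <- nrow(m) - length(groups)
  if (ssw == 0) {
    f <- if (ssb == 0) 0 else Inf
    p <- if (ssb == 0) 1 else 0
  } else {
    f <- (ssb / df1) / (ssw / df2)
    p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  }
  summ <- do.call(rbind, lapply(names(groups), function(g) {
    q <- stats::quantile(groups[[g]], c(0.25, 0.5, 0.75))
    data.frame(grade = g, n = length(groups[[g]]), median = q[[2]],
               q25 = q[[1]], q75 = q[[3]], stringsAsFactors = FALSE)
  }))
  list(f = f, pvalue = p, df = c(df1, df2), summary = summ)
}

#' Chi-square test of grade composition across CI groups
#'
#' Pearson chi-square on the CI-group-by-grade contingency table, asking
#' whether CI-Hi and CI-Lo patients have different grade make-ups.
#'
#' @param scores a dichotomized score table (column \code{group}).
#' @param clinical data.frame with columns \code{sample} and \code{grade}.
#' @return list with \code{statistic}, \code{pvalue}, \code{df}, the
#'   contingency \code{table} and the percent \code{composition} per group.
#' @export
gradeCompositionTest <- function(scores, clinical) {
  if (!"group" %in% names(scores)) stop("run dichotomize() first")
  m <- .joinClinical(scores, clinical, c("group", "grade"))
  tab <- table(group = droplevels(factor(m$group)),
               grade = droplevels(factor(m$grade)))
  if (any(dim(tab) < 2)) stop("need 2 CI groups and >= 2 grades")
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected == 0)) {
    stop("zero expected cell count; consider pooling grades")
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), pvalue = ct$p.value,
       df = unname(ct$parameter), table = tab,
       composition = prop.table(tab, margin = 1) * 100)
}

#' Survival analysis of CI-Hi vs CI-Lo
#'
#' Fits a univariate Cox proportional-hazards model with the CI group as
#' the only covariate (CI-Lo is the reference, Breslow tie handling by
#' default), so the hazard ratio below 1 means CI-Hi patients have lower
#' hazard (longer survival). Also runs the two-group log-rank test and
#' computes Kaplan-Meier product-limit curves with numbers at risk.
#'
#' @param scores a dichotomized score table (column \code{group}).
#' @param clinical data.frame with columns \code{sample}, \code{time}
#'   (> 0) and \code{event} (0/1).
#' @param ties Cox tie-handling method (default \code{"breslow"}).
#' @param atRiskTimes time points for the at-risk table; defaults to six
#'   equally spaced points over follow-up.
#' @return list with \code{hazardRatio}, \code{hrCi95}, \code{coxPvalue}
#'   (Wald), \code{logrankPvalue}, \code{km} (per-group step functions:
#'   time, survival, atRisk) and \code{atRisk} (counts at
#'   \code{atRiskTimes}).
#' @export
survivalAnalysis <- function(scores, clinical, ties = "breslow",
                             atRiskTimes = NULL) {
  if (!"group" %in% names(scores)) stop("run dichotomize() first")
  m <- .joinClinical(scores, clinical, c("group", "time", "event"))
  if (any(m$time <= 0)) stop("survival times must be positive")
  if (!all(m$event %in% c(0, 1))) stop("event must be 0/1")
  m$group <- factor(m$group, levels = c("CI-Lo", "CI-Hi"))
  events <- tapply(m$event, m$group, sum)
  if (any(is.na(events)) || any(events == 0)) {
    stop("a CI group has no events; cannot fit the Cox model (events: ",
         paste(names(events), unname(events), sep = "=", collapse = ", "),
         ")")
  }
  if (any(events < 3)) {
    warning("fewer than 3 events in a group; estimates will be unstable")
  }
  surv <- survival::Surv(m$time, m$event)
  cox <- survival::coxph(surv ~ group, data = m, ties = ties)
  sc <- summary(cox)
  hr <- unname(sc$coefficients[1, "exp(coef)"])
  ci <- unname(sc$conf.int[1, c("lower .95", "upper .95")])
  coxP <- unname(sc$coefficients[1, "Pr(>|z|)"])
  sd <- survival::survdiff(surv ~ group, data = m)
  logrankP <- stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE)
  fit <- survival::survfit(surv ~ group, data = m)
  strata <- rep(names(fit$strata), fit$strata)
  km <- lapply(split(seq_along(fit$time), strata), function(idx) {
    data.frame(time = fit$time[idx], survival = fit$surv[idx],
               atRisk = fit$n.risk[idx], events = fit$n.event[idx])
  })
  names(km) <- sub("^group=", "", names(km))
  if (is.null(atRiskTimes)) {
    atRiskTimes <- pretty(c(0, max(m$time)), n = 6)
  }
  sfit <- summary(fit, times = atRiskTimes, extend = TRUE)
  atRisk <- data.frame(time = sfit$time,
                       group = sub("^group=", "", as.character(sfit$strata)),
                       atRisk = sfit$n.risk)
  list(hazardRatio = hr, hrCi95 = ci, coxPvalue = coxP,
       logrankPvalue = logrankP, km = km, atRisk = atRisk,
       nEvents = events, n = table(m$group))
}
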