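#' Compare groups by t-test or one-way ANOVA with SNK post hoc
#'
#' Two groups are compared with Student's (pooled-variance) two-sample
#' t-test; three or more with one-way ANOVA followed by the
#' Student-Newman-Keuls (SNK) step-down procedure on studentized ranges at
#' alpha = 0.05.
#'
#' @param samples named list of numeric vectors, one per group (each n >= 2).
#' @param test `"auto"` (t-test for 2 groups, ANOVA + SNK otherwise),
#'   `"t_test"` or `"anova_snk"`.
#' @param alpha significance level for SNK decisions.
#'
#' @return List of class `group_comparison`: per-group `means`, `sem`, `n`;
#'   `test`; `statistic`; `p_value`; and for ANOVA a `snk` data.frame of
#'   pairwise decisions.
#' @export
compare_groups <- function(samples, test = c("auto", "t_test", "anova_snk"),
                           alpha = 0.05) {
  test <- match.arg(test)
  stopifnot(is.list(samples), length(samples) >= 2)
  if (is.null(names(samples)) || any(names(samples) == "")) {
    names(samples) <- paste0("group", seq_along(samples))
  }
  n <- vapply(samples, length, integer(1))
  if (any(n < 2)) stop("each group needs n >= 2")
  if (test == "auto") test <- if (length(samples) == 2) "t_test" else "anova_snk"
  means <- vapply(samples, mean, numeric(1))
  sems <- vapply(samples, function(v) stats::sd(v) / sqrt(length(v)), numeric(1))
  if (test == "t_test") {
    if (length(samples) != 2) stop("t_test requires exactly 2 groups")
    ht <- stats::t.test(samples[[1]], samples[[2]], var.equal = TRUE)
    out <- list(means = means, sem = sems, n = n, test = "t_test",
                statistic = unname(ht$statistic), p_value = ht$p.value,
                snk = NULL)
  } else {
    values <- unlist(samples, use.names = FALSE)
    groups <- factor(rep(names(samples), n), levels = names(samples))
    fit <- stats::aov(values ~ groups)
    tab <- summary(fit)[[1]]
    out <- list(means = means, sem = sems, n = n, test = "anova_snk",
                statistic = tab["groups", "F value"],
                p_value = tab["groups", "Pr(>F)"],
                snk = snk_posthoc(values, groups, alpha = alpha))
  }
  structure(out, class = "group_comparison")
}

# Student-Newman-Keuls step-down on studentized ranges. Means are ranked
# (ties broken by group label order); the largest span is tested first and
# non-significant spans block all pairs they contain.
snk_posthoc <- function(values, groups, alpha = 0.05) {
  fit <- stats::aov(values ~ groups)
  mse <- sum(stats::residuals(fit)^2) / stats::df.residual(fit)
  df <- stats::df.residual(fit)
  gm <- tapply(values, groups, mean)
  gn <- tapply(values, groups, length)
  ord <- order(gm, match(names(gm), levels(groups)))
  gm <- gm[ord]; gn <- gn[ord]
  k <- length(gm)
  pairs <- utils::combn(k, 2)
  res <- data.frame(group1 = character(0), group2 = character(0),
                    diff = numeric(0), q = numeric(0), span = integer(0),
                    p = numeric(0), significant = logical(0))
  blocked <- matrix(FALSE, k, k)
  # iterate spans from widest to narrowest (step-down)
  for (span in k:2) {
    for (i in seq_len(k - span + 1)) {
      j <- i + span - 1L
      se <- sqrt(mse / 2 * (1 / gn[i] + 1 / gn[j]))
      q <- abs(gm[j] - gm[i]) / se
      p <- stats::ptukey(q, nmeans = span, df = df, lower.tail = FALSE)
      sig <- !blocked[i, j] && p < alpha
      if (!sig) {
        # block every pair nested inside a non-significant span
        for (a in i:j) for (b in i:j) blocked[a, b] <- TRUE
      }
      res <- rbind(res, data.frame(
        group1 = names(gm)[i], group2 = names(gm)[j],
        diff = unname(gm[j] - gm[i]), q = unname(q), span = span,
        p = unname(p), significant = sig))
    }
  }
  res
}

# Significance tier flags matching the conventional */**/*** annotation.
p_flags <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}
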