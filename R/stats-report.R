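# Statistical layer: two-way interaction ANOVA, one-way ANOVA with
# Tukey-Kramer or Dunnett post hoc tests, Lilliefors normality check, and
# mean +/- SEM reporting.

#' Two-way ANOVA interaction test (age x genotype style designs)
#'
#' Type-II sums of squares: the interaction sum of squares is the reduction
#' in residual SS from adding the interaction to the additive model, tested
#' against the full model's mean square error.  For balanced designs this
#' coincides with the classical decomposition.
#'
#' @param data data.frame with the two factor columns and a value column.
#' @param factor_a,factor_b,value column names.
#' @return list(F, df1, df2, p, table) where `table` is the model
#'   comparison anova.
#' @export
twoway_interaction <- function(data, factor_a = "age", factor_b = "genotype",
                               value = "value") {
  stopifnot(all(c(factor_a, factor_b, value) %in% names(data)))
  a <- factor(data[[factor_a]]); b <- factor(data[[factor_b]])
  y <- data[[value]]
  if (any(!is.finite(y))) stop("missing values in tested cells")
  if (nlevels(a) < 2L || nlevels(b) < 2L)
    stop("both factors need at least 2 levels")
  cnt <- table(a, b)
  if (any(cnt == 0L)) {
    bad <- which(cnt == 0L, arr.ind = TRUE)[1, ]
    stop("empty design cell: ", factor_a, "=", levels(a)[bad[1]], ", ",
         factor_b, "=", levels(b)[bad[2]])
  }
  if (any(cnt < 2L))
    stop("at least 2 replicates per cell required")
  full <- stats::lm(y ~ a + b + a:b)
  add <- stats::lm(y ~ a + b)
  cmp <- stats::anova(add, full)
  structure(list(F = cmp$F[2], df1 = cmp$Df[2], df2 = cmp$Res.Df[2],
                 p = cmp$`Pr(>F)`[2], table = cmp),
            class = "gj_anova_interaction")
}

#' @export
print.gj_anova_interaction <- function(x, ...) {
  cat(sprintf("<two-way interaction> F(%d, %d) = %.4g, p = %.4g\n",
              x$df1, x$df2, x$F, x$p))
  invisible(x)
}

significance_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns")))
}

#' One-way ANOVA post hoc comparisons (Tukey-Kramer or Dunnett)
#'
#' Tukey-Kramer adjusts all pairwise comparisons via the studentized range
#' distribution (with the Kramer unequal-n standard error); Dunnett compares
#' every group to a named control, adjusting via the many-to-one
#' multivariate-t distribution (evaluated by numerical integration).
#' Stars follow the conventional thresholds *P < 0.05, **P < 0.01,
#' ***P < 0.001.
#'
#' @param data data.frame with a group column and a value column.
#' @param method `"tukey_kramer"` or `"dunnett"`.
#' @param control control group name (required for Dunnett).
#' @param group,value column names.
#' @return data.frame: comparison, estimate, se, statistic, p_adj, stars.
#' @export
oneway_posthoc <- function(data, method = c("tukey_kramer", "dunnett"),
                           control = NULL, group = "group", value = "value") {
  method <- match.arg(method)
  g <- factor(data[[group]])
  y <- data[[value]]
  k <- nlevels(g)
  if (k < 2L) stop("at least 2 groups required")
  ns <- tapply(y, g, length)
  ms <- tapply(y, g, mean)
  df <- length(y) - k
  mse <- sum(tapply(y, g, function(v) sum((v - mean(v))^2))) / df
  lev <- levels(g)
  if (method == "tukey_kramer") {
    pairs <- utils::combn(k, 2)
    out <- apply(pairs, 2, function(pr) {
      i <- pr[1]; j <- pr[2]
      est <- ms[j] - ms[i]
      se <- sqrt(mse * (1 / ns[i] + 1 / ns[j]))    # comparison SE
      q <- abs(est) * sqrt(2) / se                 # studentized range scale
      p <- stats::ptukey(q, k, df, lower.tail = FALSE)
      data.frame(comparison = paste(lev[j], "-", lev[i]),
                 estimate = unname(est), se = unname(se),
                 statistic = unname(q), p_adj = unname(p))
    })
    out <- do.call(rbind, out)
  } else {
    if (is.null(control)) stop("Dunnett test requires a named control group")
    if (!control %in% lev) stop("control group '", control, "' not found")
    others <- setdiff(lev, control)
    n0 <- ns[control]
    ti <- vapply(others, function(gr) {
      (ms[gr] - ms[control]) / sqrt(mse * (1 / ns[gr] + 1 / n0))
    }, numeric(1))
    lam <- vapply(others, function(gr) {
      sqrt((1 / n0) / (1 / ns[gr] + 1 / n0))
    }, numeric(1))
    p_adj <- vapply(ti, function(tv)
      1 - pdunnett(abs(tv), lam, df), numeric(1))
    out <- data.frame(comparison = paste(others, "-", control),
                      estimate = unname(ms[others] - ms[control]),
                      se = unname(sqrt(mse * (1 / ns[others] + 1 / n0))),
                      statistic = unname(ti), p_adj = pmin(1, pmax(0, p_adj)))
  }
  out$stars <- significance_stars(out$p_adj)
  rownames(out) <- NULL
  out
}

# P(max_i |T_i| <= q) for the many-to-one comparison vector with
# correlations lambda_i * lambda_j and `df` error degrees of freedom,
# by Simpson quadrature over the control variate z0 and the pooled-sd
# scale u = s/sigma.
pdunnett <- function(q, lambda, df) {
  if (q <= 0) return(0)
  a <- sqrt(1 - lambda^2)   # coefficient of the group-specific normal
  inner <- function(u) {
    z <- seq(-8, 8, length.out = 161)
    w <- simpson_weights(z)
    f <- vapply(z, function(z0) {
      prod(pnorm((q * u + lambda * z0) / a) -
           pnorm((-q * u + lambda * z0) / a))
    }, numeric(1))
    sum(w * stats::dnorm(z) * f)
  }
  u <- seq(1e-3, 4, length.out = 241)
  wu <- simpson_weights(u)
  fu <- 2 * df * u * stats::dchisq(df * u^2, df)
  sum(wu * fu * vapply(u, inner, numeric(1)))
}

simpson_weights <- function(x) {
  n <- length(x)
  stopifnot(n %% 2 == 1L)
  h <- x[2] - x[1]
  w <- rep(c(2, 4), length.out = n)
  w[1] <- 1; w[n] <- 1
  w * h / 3
}

#' Kolmogorov-Smirnov normality check with estimated moments
#'
#' Lilliefors-type KS test of composite normality (moments estimated from
#' the data), with the Dallal-Wilkinson approximation for the corrected
#' p-value; the output flags the approximation.
#'
#' @param values numeric vector, n >= 5; zero variance is an error.
#' @return list(D, p, n, method) of class `gj_ks_test`.
#' @export
normality_check <- function(values) {
  x <- values[is.finite(values)]
  n <- length(x)
  if (n < 5L) stop("at least 5 observations required")
  if (stats::sd(x) == 0) stop("degenerate sample: zero variance")
  z <- sort((x - mean(x)) / stats::sd(x))
  p_hat <- stats::pnorm(z)
  d_plus <- max(seq_len(n) / n - p_hat)
  d_minus <- max(p_hat - (seq_len(n) - 1) / n)
  D <- max(d_plus, d_minus)
  # Dallal-Wilkinson approximation (the "corrected P"); valid for p < 0.1,
  # otherwise Stephens' modified-statistic polynomial
  nd <- if (n > 100) 100 else n
  Kd <- if (n > 100) D * (n / 100)^0.49 else D
  p <- exp(-7.01256 * Kd^2 * (nd + 2.78019) +
           2.99587 * Kd * sqrt(nd + 2.78019) - 0.122119 +
           0.974598 / sqrt(nd) + 1.67997 / nd)
  if (p > 0.1) {
    KK <- (sqrt(n) - 0.01 + 0.85 / sqrt(n)) * D
    p <- if (KK <= 0.302) 1
    else if (KK <= 0.5)
      2.76773 - 19.828315 * KK + 80.709644 * KK^2 -
        138.55152 * KK^3 + 81.218052 * KK^4
    else if (KK <= 0.9)
      -4.901232 + 40.662806 * KK - 97.490286 * KK^2 +
        94.029866 * KK^3 - 32.355711 * KK^4
    else if (KK <= 1.31)
      6.198765 - 19.558097 * KK + 23.186922 * KK^2 -
        12.234627 * KK^3 + 2.423045 * KK^4
    else 0
  }
  structure(list(D = D, p = min(1, max(0, p)), n = n,
                 method = "Lilliefors KS (Dallal-Wilkinson approximation)"),
            class = "gj_ks_test")
}

#' @export
print.gj_ks_test <- function(x, ...) {
  cat(sprintf("<%s> D = %.4f, p = %.4g (n = %d)\n", x$method, x$D, x$p, x$n))
  invisible(x)
}

#' Group summaries as mean +/- SEM
#'
#' @param data data.frame.
#' @param group,value column names.
#' @return data.frame(group, n, mean, sem).
#' @export
summarize_groups <- function(data, group = "group", value = "value") {
  g <- factor(data[[group]]); y <- data[[value]]
  out <- data.frame(group = levels(g),
                    n = as.integer(tapply(y, g, length)),
                    mean = as.numeric(tapply(y, g, mean)),
                    sem = as.numeric(tapply(y, g, function(v)
                      stats::sd(v) / sqrt(length(v)))))
  rownames(out) <- NULL
  out
}

#' Markdown report of group summaries and post hoc comparisons
#'
#' @param data data.frame with group and value columns.
#' @param method post hoc method passed to [oneway_posthoc()].
#' @param control control group for Dunnett.
#' @param group,value column names.
#' @param file optional path to write the report to.
#' @return the report lines, invisibly when written to file.
#' @export
report_markdown <- function(data, method = "tukey_kramer", control = NULL,
                            group = "group", value = "value", file = NULL) {
  sm <- summarize_groups(data, group, value)
  ph <- oneway_posthoc(data, method = method, control = control,
                       group = group, value = value)
  lines <- c("# Group report", "",
             "## Means +/- SEM", "",
             "| group | n | mean | SEM |", "|---|---|---|---|",
             sprintf("| %s | %d | %.4g | %.4g |",
                     sm$group, sm$n, sm$mean, sm$sem),
             "", paste0("## Post hoc (", method, ")"), "",
             "| comparison | estimate | p (adj) | |", "|---|---|---|---|",
             sprintf("| %s | %.4g | %.4g | %s |",
                     ph$comparison, ph$estimate, ph$p_adj, ph$stars))
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}
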