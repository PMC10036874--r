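#' Paired t-test with Cohen's d
#'
#' Classical paired t on per-participant condition means:
#' `t = mean(x - y) / (sd(x - y) / sqrt(n))`, two-sided p on `n - 1`
#' degrees of freedom, and the paired-design effect size `d = t / sqrt(n)`.
#'
#' @param x,y paired numeric vectors (one value per participant).
#' @return A `paired_t_result`: list with `t`, `df`, `p`, `d`, `mean_diff`,
#'   `n`.
#' @export
paired_t <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  d <- x - y
  n <- length(d)
  s <- sd(d)
  m <- mean(d)
  if (s == 0) {
    if (m != 0)
      stop("differences have zero variance but nonzero mean: t is infinite",
           call. = FALSE)
    tval <- 0
  } else {
    tval <- m / (s / sqrt(n))
  }
  structure(list(t = tval, df = n - 1L,
                 p = 2 * stats::pt(-abs(tval), n - 1),
                 d = tval / sqrt(n), mean_diff = m, n = n),
            class = "paired_t_result")
}

#' @export
print.paired_t_result <- function(x, ...) {
  cat(sprintf("paired t(%d) = %.3f, p = %.4g, d = %.3f\n",
              x$df, x$t, x$p, x$d))
  invisible(x)
}

## JZS integrand: marginal likelihood of t under the g-mixture
## representation of the Cauchy(0, r) prior on standardised effect size
jzs_integrand <- function(g, t, n, r) {
  nu <- n - 1
  (1 + n * g)^(-0.5) *
    (1 + t^2 / ((1 + n * g) * nu))^(-(nu + 1) / 2) *
    r / sqrt(2 * pi) * g^(-1.5) * exp(-r^2 / (2 * g))
}

#' Jeffreys-Zellner-Siow Bayes factor for a paired/one-sample t-design
#'
#' Two-sided default Bayes factor BF10 with a Cauchy(0, `r`) prior on the
#' standardised effect size: the marginal likelihood of the observed t
#' under the alternative (integrated numerically over the prior via its
#' inverse-gamma g-mixture) divided by its likelihood under the point
#' null. `r = 0.707` is the conventional medium prior scale.
#'
#' @param t observed t statistic.
#' @param n number of (pairs of) observations.
#' @param r Cauchy prior scale.
#' @return A `bayes_factor_result`: list with `bf10`, `bf01`, `t`, `n`,
#'   `r`, and the quadrature `rel_error` estimate.
#' @export
jzs_bf10 <- function(t, n, r = 0.707) {
  stopifnot(n >= 2, r > 0, is.finite(t))
  nu <- n - 1
  num <- stats::integrate(jzs_integrand, 0, Inf, t = t, n = n, r = r,
                          rel.tol = 1e-9, abs.tol = 0,
                          stop.on.error = FALSE)
  if (num$message != "OK" || !is.finite(num$value) || num$value <= 0)
    stop("quadrature for the JZS Bayes factor failed to converge: ",
         num$message, call. = FALSE)
  denom <- (1 + t^2 / nu)^(-(nu + 1) / 2)
  bf <- num$value / denom
  structure(list(bf10 = bf, bf01 = 1 / bf, t = t, n = n, r = r,
                 rel_error = num$abs.error / num$value),
            class = "bayes_factor_result")
}

#' @export
print.bayes_factor_result <- function(x, ...) {
  cat(sprintf("BF10(%.3g) = %.4g (BF01 = %.4g) at t = %.3g, n = %d\n",
              x$r, x$bf10, x$bf01, x$t, x$n))
  invisible(x)
}

#' Bayes-factor sensitivity over prior scales
#'
#' @param t,n as in [jzs_bf10()].
#' @param r_grid Cauchy prior scales to evaluate.
#' @return Data frame with `r` and `bf10`.
#' @export
bf_sensitivity <- function(t, n, r_grid = c(0.5, 0.707, 1, 1.41)) {
  data.frame(r = r_grid,
             bf10 = vapply(r_grid, function(r) jzs_bf10(t, n, r)$bf10, 0))
}

#' Two-by-two-by-two repeated-measures ANOVA
#'
#' Classical within-subject decomposition for a fully crossed 2x2x2
#' design with one observation per participant per cell. Every effect
#' (three mains, three two-way and the three-way interaction) has one
#' degree of freedom; each is tested against its own effect-by-subject
#' interaction: `F = MS_effect / MS_(effect x subject)` on `(1, n - 1)`
#' degrees of freedom. Eta squared is classical,
#' `SS_effect / SS_total`, where the total sums every within-subject
#' source (not partial eta squared).
#'
#' @param data long data frame.
#' @param dv name of the response column.
#' @param id name of the participant column.
#' @param factors names of the three two-level factor columns.
#' @return An `anova_table` data frame: `effect`, `df1`, `df2`, `F`, `p`,
#'   `eta_sq`.
#' @export
rm_anova_2x2x2 <- function(data, dv = "value", id = "participant",
                           factors = c("cs_type", "modality", "phase")) {
  stopifnot(length(factors) == 3, all(c(dv, id, factors) %in% names(data)))
  y <- data[[dv]]
  subj <- factor(data[[id]])
  lv <- lapply(factors, function(f) {
    fac <- factor(data[[f]])
    if (nlevels(fac) != 2)
      stop(sprintf("factor '%s' must have exactly 2 levels", f), call. = FALSE)
    fac
  })
  n <- nlevels(subj)
  cell <- interaction(lv[[1]], lv[[2]], lv[[3]], drop = FALSE)
  counts <- table(subj, cell)
  if (any(counts != 1))
    stop("incomplete design: need exactly one observation per participant ",
         "per cell (8 cells)", call. = FALSE)

  ss_total <- sum((y - mean(y))^2)
  ## each 2^3 effect is a single +/-1 contrast over the 8 cells; with
  ## per-subject contrast sums D_s: SS_effect = (sum D_s)^2 / (8 n),
  ## SS_effect-by-subject = sum D_s^2 / 8 - SS_effect
  codes <- lapply(lv, function(f) ifelse(as.integer(f) == 1, 1, -1))
  names(codes) <- factors
  effects <- list()
  for (k in 1:3) {
    for (cmb in utils::combn(3, k, simplify = FALSE)) {
      w <- Reduce(`*`, codes[cmb])
      D <- tapply(w * y, subj, sum)
      ss_eff <- sum(D)^2 / (8 * n)
      ss_err <- sum(D^2) / 8 - ss_eff
      Fval <- if (ss_eff == 0) 0 else (ss_eff / 1) / (ss_err / (n - 1))
      effects[[length(effects) + 1]] <- data.frame(
        effect = paste(factors[cmb], collapse = ":"),
        df1 = 1L, df2 = n - 1L, F = Fval,
        p = if (ss_eff == 0) 1 else stats::pf(Fval, 1, n - 1, lower.tail = FALSE),
        eta_sq = if (ss_total == 0) 0 else ss_eff / ss_total,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, effects)
  class(out) <- c("anova_table", "data.frame")
  attr(out, "n") <- n
  attr(out, "ss_total") <- ss_total
  out
}

#' @export
print.anova_table <- function(x, ...) {
  cat(sprintf("Repeated-measures ANOVA (n = %d)\n", attr(x, "n")))
  df <- as.data.frame(x)
  df$F <- sprintf("%.3f", df$F)
  df$p <- format.pval(df$p, digits = 3)
  df$eta_sq <- sprintf("%.4f", df$eta_sq)
  print(df, row.names = FALSE)
  invisible(x)
}
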