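#' Variance of a product of independent random variables
#'
#' For independent X and Y with means \code{mx}, \code{my} and variances
#' \code{vx}, \code{vy}:
#' \deqn{Var(XY) = (Var(X)+E[X]^2)(Var(Y)+E[Y]^2) - E[X]^2 E[Y]^2}
#' which equals the expanded identity
#' \eqn{Var(X)Var(Y) + Var(X)E[Y]^2 + Var(Y)E[X]^2}.
#'
#' @param mx,vx mean and variance of X.
#' @param my,vy mean and variance of Y.
#' @return variance of the product XY (nonnegative for valid inputs).
#' @export
product_variance <- function(mx, vx, my, vy) {
  if (any(c(vx, vy) < 0)) stop("variances must be nonnegative")
  (vx + mx^2) * (vy + my^2) - mx^2 * my^2
}

#' Epistatic deviation of a double mutant under the multiplicative null
#'
#' Given relative fitness estimates for two single mutants (x, y) and their
#' double mutant (xy), the epistatic deviation is
#' \deqn{\epsilon = \bar w_{xy} - \bar w_x \bar w_y}
#' Its variance combines the double mutant's variance with the variance of
#' the product of the (independent) single-mutant estimates
#' (see [product_variance()]):
#' \deqn{Var(\epsilon) = Var(\bar w_{xy}) + Var(\bar w_x \bar w_y)}
#' The test statistic is \eqn{t = \epsilon / \sqrt{Var(\epsilon)}} with
#' \code{df} degrees of freedom (default: the double mutant's replicate count
#' minus one) and a two-tailed p-value.
#'
#' @param wx,wy,wxy single-row data.frames or lists with elements
#'   \code{w_bar}, \code{variance} (variance of the mean) and, for
#'   \code{wxy}, \code{n} (replicate count, >= 2). Rows of the
#'   [summarize_fitness()] output work directly.
#' @param df degrees of freedom for the t-test; default \code{wxy$n - 1}.
#' @return list of class \code{"epistasis_estimate"} with \code{epsilon},
#'   \code{var_product}, \code{var_epsilon}, \code{t_stat}, \code{df},
#'   \code{p_two_tailed} and a \code{degenerate} flag (TRUE when
#'   \eqn{Var(\epsilon) = 0} with \eqn{\epsilon \neq 0}; p is then 0 with a
#'   warning).
#' @export
epistatic_deviation <- function(wx, wy, wxy, df = NULL) {
  for (w in list(wx, wy, wxy)) {
    if (!is.finite(w$w_bar) || !is.finite(w$variance)) {
      stop("all three estimates need finite mean and variance")
    }
    if (w$variance < 0) stop("negative input variance")
  }
  if (is.null(wxy$n) || wxy$n < 2) stop("double mutant needs n >= 2 replicates")
  if (is.null(df)) df <- wxy$n - 1
  eps <- wxy$w_bar - wx$w_bar * wy$w_bar
  vp <- product_variance(wx$w_bar, wx$variance, wy$w_bar, wy$variance)
  ve <- wxy$variance + vp
  degenerate <- FALSE
  if (abs(eps) < 1e-12 * max(1, abs(wxy$w_bar))) eps <- 0
  if (ve > 0) {
    t_stat <- eps / sqrt(ve)
    p <- 2 * stats::pt(-abs(t_stat), df = df)
  } else if (eps == 0) {
    t_stat <- 0; p <- 1
  } else {
    warning("zero Var(epsilon) with nonzero epsilon; p reported as 0")
    t_stat <- sign(eps) * Inf; p <- 0; degenerate <- TRUE
  }
  structure(list(epsilon = eps, var_product = vp, var_epsilon = ve,
                 t_stat = t_stat, df = df, p_two_tailed = p,
                 degenerate = degenerate),
            class = "epistasis_estimate")
}

#' @export
print.epistasis_estimate <- function(x, ...) {
  cat(sprintf("epsilon = %.4g (Var = %.4g), t = %.3f, df = %d, p = %.4g\n",
              x$epsilon, x$var_epsilon, x$t_stat, as.integer(x$df),
              x$p_two_tailed))
  invisible(x)
}

#' Epistasis table for a set of double mutants
#'
#' Convenience wrapper applying [epistatic_deviation()] to every double
#' mutant listed in a pairing table, using a fitness summary table for the
#' component estimates.
#'
#' @param fitness data.frame from [summarize_fitness()].
#' @param pairing data.frame with columns \code{double_id},
#'   \code{rho_single_id}, \code{rpoB_single_id}.
#' @return data.frame with one row per double mutant x temperature.
#' @export
epistasis_table <- function(fitness, pairing) {
  key <- paste(fitness$genotype, fitness$temperature)
  rows <- list()
  for (i in seq_len(nrow(pairing))) {
    for (temp in unique(fitness$temperature)) {
      pick <- function(id) {
        j <- match(paste(id, temp), key)
        if (is.na(j)) NULL else fitness[j, ]
      }
      wx <- pick(pairing$rho_single_id[i])
      wy <- pick(pairing$rpoB_single_id[i])
      wxy <- pick(pairing$double_id[i])
      if (is.null(wx) || is.null(wy) || is.null(wxy)) next
      e <- epistatic_deviation(wx, wy, wxy)
      rows[[length(rows) + 1L]] <- data.frame(
        double_id = pairing$double_id[i], temperature = temp,
        epsilon = e$epsilon, var_epsilon = e$var_epsilon,
        var_product = e$var_product, t_stat = e$t_stat, df = e$df,
        p = e$p_two_tailed, w_x = wx$w_bar, w_xy = wxy$w_bar,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pooled epistasis across double mutants at one temperature
#'
#' One-sample two-tailed t-test of the mean epistatic deviation against zero
#' with \eqn{df = n - 1}, and the 95% confidence-interval half-width
#' \eqn{t_{0.975, n-1} \cdot SE}.
#'
#' @param eps numeric vector of per-pair epistatic deviations.
#' @return list with \code{mean_epsilon}, \code{ci95_halfwidth},
#'   \code{t_stat}, \code{df}, \code{p}, \code{n} and a \code{degenerate}
#'   flag set when the values are literally constant (t reported as 0,
#'   p = 1).
#' @export
pooled_epistasis <- function(eps) {
  n <- length(eps)
  if (n < 2) stop("pooled_epistasis needs >= 2 values")
  m <- mean(eps)
  s <- stats::sd(eps)
  if (s == 0) {
    return(list(mean_epsilon = m, ci95_halfwidth = 0,
                t_stat = 0, df = n - 1, p = 1, n = n, degenerate = TRUE))
  }
  se <- s / sqrt(n)
  t_stat <- m / se
  list(mean_epsilon = m,
       ci95_halfwidth = stats::qt(0.975, n - 1) * se,
       t_stat = t_stat, df = n - 1,
       p = 2 * stats::pt(-abs(t_stat), n - 1), n = n, degenerate = FALSE)
}

#' ANOVA of epistatic deviations across temperatures
#'
#' One-way fixed-effects ANOVA of per-pair epistatic deviations with
#' environment (temperature) as the factor, testing whether the magnitude
#' and distribution of epistasis varies across environments.
#'
#' @param eps numeric vector of epistatic deviations.
#' @param temperature factor-like vector of the same length.
#' @return list with \code{f}, \code{df1}, \code{df2}, \code{p}.
#' @export
epistasis_anova <- function(eps, temperature) {
  g <- factor(temperature)
  if (nlevels(g) < 2) stop("need >= 2 temperature groups")
  if (any(table(g) < 2)) stop("each temperature group needs >= 2 values")
  fit <- stats::anova(stats::lm(eps ~ g))
  list(f = fit[["F value"]][1], df1 = fit$Df[1], df2 = fit$Df[2],
       p = fit[["Pr(>F)"]][1])
}

#' Diminishing-returns regression
#'
#' Regresses the fitness effect of the foreground (rpoB) mutation on the
#' fitness of the background (rho single mutant) it was placed on. Under
#' diminishing returns the slope is negative: fitter backgrounds gain less.
#' The effect is the ratio \eqn{\bar w_{xy} / \bar w_x} by default
#' (a relative gain), or the difference \eqn{\bar w_{xy} - \bar w_x}.
#' Fit on the combined data and, when \code{allele} is given, separately per
#' foreground allele.
#'
#' @param w_single background (rho single mutant) mean fitness values.
#' @param w_double corresponding double-mutant mean fitness values.
#' @param allele optional foreground-allele label per pair.
#' @param effect \code{"ratio"} (default) or \code{"difference"}.
#' @return data.frame with one row per subgroup (\code{"combined"} plus each
#'   allele): \code{slope}, \code{intercept}, \code{p_slope}, \code{n}.
#' @export
diminishing_returns <- function(w_single, w_double, allele = NULL,
                                effect = c("ratio", "difference")) {
  effect <- match.arg(effect)
  if (length(w_single) != length(w_double)) stop("length mismatch")
  y <- if (effect == "ratio") w_double / w_single else w_double - w_single
  fit_one <- function(x, y, label) {
    if (length(x) < 3) stop("diminishing_returns needs >= 3 pairs (", label, ")")
    fit <- summary(stats::lm(y ~ x))
    data.frame(subgroup = label, slope = fit$coefficients[2, 1],
               intercept = fit$coefficients[1, 1],
               p_slope = fit$coefficients[2, 4], n = length(x),
               stringsAsFactors = FALSE)
  }
  out <- fit_one(w_single, y, "combined")
  if (!is.null(allele)) {
    for (a in unique(allele)) {
      sel <- allele == a
      out <- rbind(out, fit_one(w_single[sel], y[sel], a))
    }
  }
  rownames(out) <- NULL
  out
}
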