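#' Relative fitness from a competition assay
#'
#' Computes the relative fitness \eqn{w_r} of a mutant competed head-to-head
#' against a reference (ancestral) strain as the ratio of the two competitors'
#' Malthusian parameters over one growth cycle:
#' \deqn{w_r = \frac{\ln(D \cdot N^f_{mut} / N^i_{mut})}
#'                  {\ln(D \cdot N^f_{anc} / N^i_{anc})}}
#' where the counts are initial/final colony counts of each competitor and
#' \eqn{D} is the net fold-expansion of the culture over the cycle (100 for
#' the standard serial-transfer protocol with a 100-fold daily dilution).
#'
#' All arguments are vectorized.
#'
#' @param ni_mut,nf_mut initial and final colony counts of the mutant.
#' @param ni_anc,nf_anc initial and final colony counts of the ancestor.
#' @param dilution net fold-expansion \eqn{D} per cycle (dimensionless,
#'   >= 1). Default 100.
#' @return numeric vector of relative fitness values.
#' @examples
#' relative_fitness(100, 10000, 100, 10000)          # identical growth -> 1
#' relative_fitness(100, 400, 100, 200, dilution = 1) # ln4/ln2 = 2
#' @export
relative_fitness <- function(ni_mut, nf_mut, ni_anc, nf_anc, dilution = 100) {
  counts <- cbind(ni_mut, nf_mut, ni_anc, nf_anc)
  if (any(!is.finite(counts)) || any(counts <= 0)) {
    stop("uncountable assay: all four colony counts must be positive")
  }
  if (any(dilution < 1)) stop("dilution factor must be >= 1")
  m_mut <- log(dilution * nf_mut / ni_mut)
  m_anc <- log(dilution * nf_anc / ni_anc)
  if (any(m_anc == 0)) {
    stop("degenerate denominator: ancestor Malthusian parameter is zero")
  }
  m_mut / m_anc
}

#' Read a competition-assay table
#'
#' Expects a TSV with header columns \code{genotype}, \code{temperature},
#' \code{replicate}, \code{bio_replicate}, \code{ni_mut}, \code{nf_mut},
#' \code{ni_anc}, \code{nf_anc} and optionally \code{dilution} (default 100).
#'
#' @param file path to the TSV file.
#' @return data.frame of assays.
#' @export
read_competition_assays <- function(file) {
  x <- utils::read.delim(file, stringsAsFactors = FALSE)
  need <- c("genotype", "temperature", "replicate", "bio_replicate",
            "ni_mut", "nf_mut", "ni_anc", "nf_anc")
  missing <- setdiff(need, names(x))
  if (length(missing)) {
    stop("competition table is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  if (is.null(x$dilution)) x$dilution <- 100
  x
}

#' Per-genotype relative fitness summaries
#'
#' Groups assays by genotype and temperature, estimates the mean relative
#' fitness \eqn{\bar w_r}, its variance (variance of the mean, \eqn{s^2/n}),
#' a two-tailed one-sample t-test against \eqn{\bar w_r = 1} with
#' \eqn{df = n - 1}, and Bonferroni-adjusted p-values across the whole family
#' of genotype-by-temperature tests.
#'
#' @param assays data.frame as returned by [read_competition_assays()], or any
#'   data.frame with the same columns.
#' @param average_bio if TRUE, technical replicates are averaged within
#'   biological replicates before summarizing, so n counts biological
#'   replicates. Default FALSE (all assays pooled).
#' @return data.frame with one row per genotype x temperature: \code{w_bar},
#'   \code{variance} (of the mean), \code{s2} (per-assay sample variance),
#'   \code{n}, \code{t_vs_one}, \code{df}, \code{p_raw}, \code{p_bonferroni}.
#'   Groups with a single replicate get NA variance and withheld tests.
#' @export
summarize_fitness <- function(assays, average_bio = FALSE) {
  w <- relative_fitness(assays$ni_mut, assays$nf_mut,
                        assays$ni_anc, assays$nf_anc, assays$dilution)
  d <- data.frame(genotype = assays$genotype,
                  temperature = assays$temperature,
                  bio = assays$bio_replicate, w = w,
                  stringsAsFactors = FALSE)
  if (average_bio) {
    d <- stats::aggregate(w ~ genotype + temperature + bio, d, mean)
  }
  groups <- split(d, list(d$genotype, d$temperature), drop = TRUE)
  out <- do.call(rbind, lapply(groups, function(g) {
    n <- nrow(g)
    wb <- mean(g$w)
    if (n >= 2) {
      s2 <- stats::var(g$w)
      se <- sqrt(s2 / n)
      if (se > 0) {
        t_stat <- (wb - 1) / se
        p <- 2 * stats::pt(-abs(t_stat), df = n - 1)
      } else {
        t_stat <- if (wb == 1) 0 else sign(wb - 1) * Inf
        p <- if (wb == 1) 1 else 0
      }
      data.frame(genotype = g$genotype[1], temperature = g$temperature[1],
                 w_bar = wb, variance = s2 / n, s2 = s2, n = n,
                 t_vs_one = t_stat, df = n - 1, p_raw = p,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(genotype = g$genotype[1], temperature = g$temperature[1],
                 w_bar = wb, variance = NA_real_, s2 = NA_real_, n = n,
                 t_vs_one = NA_real_, df = NA_real_, p_raw = NA_real_,
                 stringsAsFactors = FALSE)
    }
  }))
  rownames(out) <- NULL
  m <- sum(!is.na(out$p_raw))
  out$p_bonferroni <- pmin(out$p_raw * m, 1)
  out
}

#' ANOVA across biological replicates within a genotype
#'
#' One-way fixed-effects ANOVA of per-assay relative fitness on biological
#' replicate, run separately for each genotype x temperature group. Used to
#' check that biological replicates are exchangeable before pooling assays.
#'
#' @param assays data.frame of competition assays (see
#'   [read_competition_assays()]).
#' @return data.frame with \code{genotype}, \code{temperature}, \code{f},
#'   \code{df1}, \code{df2}, \code{p}.
#' @export
replicate_anova <- function(assays) {
  w <- relative_fitness(assays$ni_mut, assays$nf_mut,
                        assays$ni_anc, assays$nf_anc, assays$dilution)
  d <- data.frame(genotype = assays$genotype,
                  temperature = assays$temperature,
                  bio = factor(assays$bio_replicate), w = w)
  groups <- split(d, list(d$genotype, d$temperature), drop = TRUE)
  out <- do.call(rbind, lapply(groups, function(g) {
    tab <- table(g$bio[, drop = TRUE])
    if (length(tab) < 2 || any(tab < 2)) {
      bad <- names(tab)[tab < 2]
      stop("replicate_anova needs >= 2 biological replicates with >= 2 assays",
           " each in group ", g$genotype[1], " @ ", g$temperature[1],
           if (length(bad)) paste0(" (offending replicate: ",
                                   paste(bad, collapse = ", "), ")"))
    }
    fit <- stats::anova(stats::lm(w ~ bio, data = g))
    data.frame(genotype = g$genotype[1], temperature = g$temperature[1],
               f = fit[["F value"]][1], df1 = fit$Df[1], df2 = fit$Df[2],
               p = fit[["Pr(>F)"]][1], stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Fit exponential growth to a growth curve
#'
#' Finds the linear component of the exponential phase by sliding windows of
#' at least \code{min_window} consecutive points over the natural-log cell
#' density and picking the window maximizing the regression R-squared subject
#' to a positive slope; ties are broken toward the earliest (then longest)
#' window. The slope of that window is the maximum growth rate
#' \eqn{\mu_{max}} (per hour).
#'
#' @param times numeric vector of strictly increasing times (hours).
#' @param densities cell densities (cells/ml, all > 0), same length.
#' @param min_window minimum number of points per window (>= 5).
#' @param yield one of \code{"max"} (final yield = maximum observed density;
#'   default) or \code{"window"} (density at the last point of the fitted
#'   window).
#' @return list of class \code{"growth_fit"} with \code{mu_max},
#'   \code{window} (index range used), \code{r_squared} and
#'   \code{final_yield}. A curve with no positively sloped window (e.g. a
#'   flat curve) returns \code{mu_max = 0}.
#' @export
fit_growth <- function(times, densities, min_window = 5,
                       yield = c("max", "window")) {
  yield <- match.arg(yield)
  n <- length(times)
  if (n < 5) stop("growth curve needs at least 5 points")
  if (length(densities) != n) stop("times and densities differ in length")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(densities <= 0)) stop("densities must be positive")
  if (min_window < 5) stop("min_window must be >= 5")
  y <- log(densities)
  best <- NULL
  for (len in min_window:n) {
    for (start in seq_len(n - len + 1)) {
      idx <- start:(start + len - 1)
      fit <- stats::lm.fit(cbind(1, times[idx]), y[idx])
      slope <- fit$coefficients[2]
      if (!is.finite(slope) || slope <= 0) next
      ss_tot <- sum((y[idx] - mean(y[idx]))^2)
      r2 <- if (ss_tot > 0) 1 - sum(fit$residuals^2) / ss_tot else 1
      better <- is.null(best) ||
        r2 > best$r_squared + 1e-12 ||
        (abs(r2 - best$r_squared) <= 1e-12 &&
           (start < best$window[1] ||
              (start == best$window[1] && len > diff(best$window) + 1)))
      if (better) {
        best <- list(mu_max = unname(slope), window = c(start, start + len - 1),
                     r_squared = min(max(r2, 0), 1))
      }
    }
  }
  if (is.null(best)) {
    best <- list(mu_max = 0, window = c(1L, n), r_squared = 0)
  }
  best$final_yield <- if (yield == "max") max(densities) else
    densities[best$window[2]]
  class(best) <- "growth_fit"
  best
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf(
    "Exponential fit: mu_max = %.4g /h (points %d-%d, R^2 = %.4f), yield = %.4g\n",
    x$mu_max, x$window[1], x$window[2], x$r_squared, x$final_yield))
  invisible(x)
}

#' Compare growth parameters between two genotype sets
#'
#' Welch two-sample two-tailed t-test on a growth parameter (e.g.
#' \code{mu_max} or \code{final_yield}) extracted from two sets of growth
#' fits or given directly as numeric vectors.
#'
#' @param a,b numeric vectors, or lists of \code{growth_fit} objects.
#' @param parameter which fit component to compare when lists are given.
#' @return list with \code{t}, \code{df}, \code{p}, \code{mean_a},
#'   \code{mean_b}.
#' @export
compare_growth <- function(a, b, parameter = "mu_max") {
  pull <- function(x) {
    if (is.numeric(x)) x else vapply(x, function(f) f[[parameter]], numeric(1))
  }
  a <- pull(a); b <- pull(b)
  if (length(a) < 2 || length(b) < 2) stop("need >= 2 fits per side")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    same <- isTRUE(all.equal(mean(a), mean(b)))
    return(list(t = if (same) 0 else sign(mean(a) - mean(b)) * Inf,
                df = length(a) + length(b) - 2,
                p = if (same) 1 else 0, mean_a = mean(a), mean_b = mean(b)))
  }
  tt <- stats::t.test(a, b)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_a = mean(a), mean_b = mean(b))
}
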