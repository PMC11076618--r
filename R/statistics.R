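#' Benjamini-Hochberg adjusted p-values (q-values)
#'
#' Step-up false-discovery-rate adjustment:
#' `q_(i) = min_{j >= i} m p_(j) / j`, clipped at 1 and mapped back to the
#' input order.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return vector of q-values.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Cohen's d effect size
#'
#' Unsigned standardised mean difference
#' `|mean_a - mean_b| / s_pooled` with the pooled standard deviation
#' `s_pooled = sqrt(((n_a - 1) s_a^2 + (n_b - 1) s_b^2) / (n_a + n_b - 2))`.
#'
#' @param group_a,group_b numeric vectors, each of length >= 2.
#' @return the magnitude d; `NA` with a warning when the pooled sd is 0.
#' @export
cohens_d <- function(group_a, group_b) {
  na <- length(group_a)
  nb <- length(group_b)
  if (na < 2 || nb < 2) stop("each group needs n >= 2")
  sp <- sqrt(((na - 1) * stats::var(group_a) + (nb - 1) * stats::var(group_b)) /
               (na + nb - 2))
  if (sp == 0) {
    warning("zero pooled sd; Cohen's d undefined")
    return(NA_real_)
  }
  abs(mean(group_a) - mean(group_b)) / sp
}

#' Effect-size category
#'
#' Bins the magnitude of Cohen's d: \[0, 0.2) none, \[0.2, 0.5) small,
#' \[0.5, 0.8) medium, \[0.8, Inf) large.
#'
#' @param d non-negative effect size(s).
#' @return character vector of categories.
#' @export
effect_category <- function(d) {
  if (any(d < 0, na.rm = TRUE)) stop("d must be >= 0 (unsigned magnitude)")
  out <- ifelse(d >= 0.8, "large",
                ifelse(d >= 0.5, "medium",
                       ifelse(d >= 0.2, "small", "none")))
  out[is.na(d)] <- NA_character_
  out
}

#' Two-sample t-test for nerve morphometrics
#'
#' @param group_a,group_b numeric vectors, n >= 2 each.
#' @param var.equal assume equal variances (classical two-sample t-test);
#'   default `FALSE` (Welch).
#' @return two-sided p-value; `NA` with a warning when both groups have
#'   zero variance.
#' @export
nerve_ttest <- function(group_a, group_b, var.equal = FALSE) {
  if (length(group_a) < 2 || length(group_b) < 2) stop("each group needs n >= 2")
  if (stats::var(group_a) == 0 && stats::var(group_b) == 0) {
    warning("zero variance in both groups; t-test undefined")
    return(NA_real_)
  }
  t.test(group_a, group_b, var.equal = var.equal)$p.value
}

#' Boxplot summary following the whisker convention Q1/Q3 +/- 1.5 IQR
#'
#' Quartiles use linear interpolation (`quantile()` type 7). Whisker end
#' points are `Q1 - 1.5 IQR` and `Q3 + 1.5 IQR`; outliers are exactly the
#' points beyond the whiskers.
#'
#' @param values numeric vector, n >= 1.
#' @return list with `q1`, `median`, `mean`, `q3`, `whisker_lo`,
#'   `whisker_hi`, `outliers`.
#' @export
boxplot_summary <- function(values) {
  if (length(values) < 1) stop("need at least one value")
  qs <- quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- qs[3] - qs[1]
  lo <- qs[1] - 1.5 * iqr
  hi <- qs[3] + 1.5 * iqr
  list(q1 = qs[1], median = qs[2], mean = mean(values), q3 = qs[3],
       whisker_lo = lo, whisker_hi = hi,
       outliers = values[values < lo | values > hi])
}

#' Significance annotation string
#'
#' Convention: `*` q <= 0.1, `**` q < 0.01, `***` q < 0.001,
#' `****` q < 0.0001, `ns` otherwise.
#'
#' @param q adjusted p-value(s).
#' @return character vector of labels.
#' @export
significance_label <- function(q) {
  ifelse(q < 1e-4, "****",
         ifelse(q < 1e-3, "***",
                ifelse(q < 1e-2, "**",
                       ifelse(q <= 0.1, "*", "ns"))))
}

#' Fit the per-metric linear mixed model and extract pairwise contrasts
#'
#' One model per metric across all experimental conditions:
#' `metric ~ condition + (1 | animal)` -- the animal is a random factor
#' because the analysis includes multiple images per animal, and inference
#' must not treat images as independent replicates. Degrees of freedom for
#' each pairwise contrast use the Satterthwaite approximation; p-values
#' are Benjamini-Hochberg adjusted across the contrast family of this
#' metric, and significance means q < `alpha` (default 0.1). Pairwise
#' Cohen's d (on the modelling scale) with its category is attached.
#'
#' Ratio-valued metrics (FTR) are modelled on the log scale, which keeps
#' the ratio positive and makes animal effects additive;
#' `estimate_ratio = exp(estimate)` back-transforms each contrast.
#'
#' A fit with zero estimated animal variance sits on the boundary of the
#' parameter space; it is kept (it reduces to the fixed-effects model) and
#' flagged via `boundary_fit`.
#'
#' @param table per-image metrics data frame containing `animal_id`, the
#'   metric column, and the condition columns.
#' @param metric name of the metric column.
#' @param condition_cols columns whose combination defines the
#'   experimental condition.
#' @param log_transform model on the log scale; default `TRUE` for
#'   `metric = "ftr"`.
#' @param contrasts optional character vector selecting contrast labels
#'   (as printed, e.g. `"CT_nPCA - SHAM_nPCA"`); default all pairwise.
#' @param alpha significance level on q-values.
#' @return object of class `metric_lmm` with a `results` data frame
#'   (contrast, estimate, se, df, p, q, d, d_category, significant, label)
#'   plus the fitted model.
#' @export
fit_metric_lmm <- function(table, metric, condition_cols = c("group", "side", "region"),
                           log_transform = identical(metric, "ftr"),
                           contrasts = NULL, alpha = 0.1) {
  condition_cols <- intersect(condition_cols, names(table))
  if (length(condition_cols) == 0) stop("no condition columns found in table")
  if (!metric %in% names(table)) stop(sprintf("metric '%s' not in table", metric))
  if (!"animal_id" %in% names(table)) stop("table must contain 'animal_id'")

  df <- data.frame(
    value = table[[metric]],
    condition = factor(do.call(paste, c(table[condition_cols], sep = "_"))),
    animal = factor(table$animal_id)
  )
  bad <- !is.finite(df$value) | (log_transform & df$value <= 0)
  if (any(bad)) {
    message(sprintf("dropping %d row(s) with undefined %s", sum(bad), metric))
    df <- df[!bad, ]
  }
  if (log_transform) df$value <- log(df$value)
  per_cond_animals <- tapply(df$animal, df$condition,
                             function(a) length(unique(a)))
  if (any(per_cond_animals < 2)) {
    stop("each condition needs at least 2 animals")
  }

  fit <- lmerTest::lmer(value ~ condition + (1 | animal), data = df)
  boundary <- lme4::isSingular(fit)
  if (boundary) {
    message("boundary fit: estimated animal variance is zero; ",
            "model reduces to the fixed-effects fit")
  }
  emm <- emmeans::emmeans(fit, "condition", lmer.df = "satterthwaite")
  ctr <- summary(emmeans::contrast(emm, method = "pairwise", adjust = "none"),
                 infer = c(TRUE, TRUE))

  res <- data.frame(
    contrast = as.character(ctr$contrast),
    estimate = ctr$estimate, se = ctr$SE, df = ctr$df,
    ci_lo = ctr$lower.CL, ci_hi = ctr$upper.CL,
    p = ctr$p.value, stringsAsFactors = FALSE
  )
  if (!is.null(contrasts)) {
    keep <- res$contrast %in% contrasts
    if (!any(keep)) stop("none of the requested contrasts found")
    res <- res[keep, , drop = FALSE]
  }
  res$q <- bh_adjust(res$p)
  groups <- split(df$value, df$condition)
  pair <- strsplit(res$contrast, " - ", fixed = TRUE)
  res$d <- vapply(pair, function(pr) {
    pr <- gsub("^\\(|\\)$", "", pr)   # emmeans wraps non-syntactic levels
    a <- groups[[pr[1]]]
    b <- groups[[pr[2]]]
    if (length(a) < 2 || length(b) < 2) return(NA_real_)
    suppressWarnings(cohens_d(a, b))
  }, numeric(1))
  res$d_category <- effect_category(res$d)
  res$significant <- res$q < alpha
  res$label <- significance_label(res$q)
  if (log_transform) res$estimate_ratio <- exp(res$estimate)
  rownames(res) <- NULL

  structure(list(results = res, model = fit, metric = metric,
                 log_transform = log_transform, alpha = alpha,
                 boundary_fit = boundary, data = df),
            class = "metric_lmm")
}

#' @export
print.metric_lmm <- function(x, digits = 3, ...) {
  cat(sprintf("Linear mixed model for '%s'%s: value ~ condition + (1 | animal)\n",
              x$metric, if (x$log_transform) " (log scale)" else ""))
  cat(sprintf("Satterthwaite df; BH-adjusted q; significance at q < %g%s\n\n",
              x$alpha, if (x$boundary_fit) "; boundary fit (animal variance 0)" else ""))
  print(format(x$results[, c("contrast", "estimate", "se", "df", "p", "q",
                             "d", "d_category", "label")],
               digits = digits), row.names = FALSE)
  invisible(x)
}

#' @export
summary.metric_lmm <- function(object, ...) {
  list(metric = object$metric, alpha = object$alpha,
       n_contrasts = nrow(object$results),
       n_significant = sum(object$results$significant),
       boundary_fit = object$boundary_fit,
       results = object$results)
}

#' Boxplot panel of a fitted metric across conditions
#'
#' Draws one box per condition following the summary convention of
#' [boxplot_summary()]: box from Q1 to Q3, horizontal line at the median,
#' white dot at the mean, whiskers at Q1/Q3 +/- 1.5 IQR, black dots for
#' outliers.
#'
#' @param x a `metric_lmm`.
#' @param ... unused.
#' @return `x`, invisibly.
#' @export
plot.metric_lmm <- function(x, ...) {
  groups <- split(x$data$value, x$data$condition)
  k <- length(groups)
  rng <- range(unlist(groups))
  pad <- diff(rng) * 0.1 + 1e-9
  plot(NULL, xlim = c(0.5, k + 0.5), ylim = rng + c(-pad, pad),
       xaxt = "n", xlab = "", ylab = if (x$log_transform)
         paste0("log(", x$metric, ")") else x$metric)
  axis(1, at = seq_len(k), labels = names(groups), las = 2, cex.axis = 0.7)
  for (i in seq_len(k)) {
    s <- boxplot_summary(groups[[i]])
    inr <- groups[[i]][groups[[i]] >= s$whisker_lo & groups[[i]] <= s$whisker_hi]
    rect(i - 0.3, s$q1, i + 0.3, s$q3, col = gray(0.9))
    segments(i - 0.3, s$median, i + 0.3, s$median, lwd = 2)
    segments(i, s$q3, i, max(inr))
    segments(i, s$q1, i, min(inr))
    points(i, s$mean, pch = 21, bg = "white", cex = 1.2)
    if (length(s$outliers)) points(rep(i, length(s$outliers)), s$outliers, pch = 16)
  }
  invisible(x)
}

#' Simulate a per-image metric table from the mixed-model generative law
#'
#' Direct simulation of the statistics layer's assumed data-generating
#' process: per animal a random intercept with sd `animal_sd`, per image a
#' residual with sd `resid_sd`, added to its condition mean. Used for
#' calibration and parameter-recovery checks of [fit_metric_lmm()]
#' without rendering images.
#'
#' @param condition_means named numeric vector of condition means (on the
#'   modelling scale).
#' @param animals_per_condition animals in each condition.
#' @param images_per_animal images per animal.
#' @param animal_sd,resid_sd standard deviations of the random intercept
#'   and the image-level residual.
#' @param crossed if `TRUE`, every animal is observed under every
#'   condition (side/region-like, within-animal); if `FALSE` animals are
#'   nested in conditions (group-like).
#' @param seed integer seed.
#' @return data frame with `animal_id`, `condition`, `value`.
#' @export
simulate_metric_table <- function(condition_means, animals_per_condition,
                                  images_per_animal, animal_sd = 0.3,
                                  resid_sd = 0.2, crossed = FALSE, seed = 1L) {
  with_seed(seed, {
    conds <- names(condition_means)
    if (crossed) {
      animals <- sprintf("a%02d", seq_len(animals_per_condition))
      a_eff <- setNames(rnorm(length(animals), 0, animal_sd), animals)
      grid <- expand.grid(animal_id = animals, condition = conds,
                          img = seq_len(images_per_animal),
                          stringsAsFactors = FALSE)
    } else {
      animals <- sprintf("%s_a%02d", rep(conds, each = animals_per_condition),
                         seq_len(animals_per_condition))
      a_eff <- setNames(rnorm(length(animals), 0, animal_sd), animals)
      grid <- expand.grid(animal_id = animals, img = seq_len(images_per_animal),
                          stringsAsFactors = FALSE)
      grid$condition <- sub("_a[0-9]+$", "", grid$animal_id)
    }
    grid$value <- condition_means[grid$condition] + a_eff[grid$animal_id] +
      rnorm(nrow(grid), 0, resid_sd)
    grid[, c("animal_id", "condition", "value")]
  })
}
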