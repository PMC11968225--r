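#' Simulate band-fraction records with known distance slopes
#'
#' Generates the hierarchical data structure the distance-trend model is
#' designed for: per group and timepoint, each mouse contributes several
#' replicate images; each image contributes one fraction-positive value per
#' depth band, equal to the cell-level truth
#' `intercept + slope * mid_depth` plus a mouse random intercept, a
#' replicate (image) random intercept, and residual noise.
#'
#' @param slopes Data frame with columns `group`, `timepoint`, `slope`
#'   (fraction per um) and optionally `intercept`.
#' @param intercept Default intercept where `slopes$intercept` is absent.
#' @param n_mice Mice per group.
#' @param n_replicates Replicate images per mouse and timepoint.
#' @param n_bands Depth bands per image.
#' @param band_width_um Band width (default 100 um).
#' @param sd_mouse,sd_replicate,sd_noise SDs of the mouse intercept,
#'   replicate intercept, and residual (fraction units).
#' @param seed Integer seed.
#' @return `band_fractions` data frame (schema of [band_profile()]).
#' @export
simulate_band_records <- function(slopes, intercept = 0.5, n_mice = 3,
                                  n_replicates = 3, n_bands = 10,
                                  band_width_um = 100, sd_mouse = 0.02,
                                  sd_replicate = 0.01, sd_noise = 0.01,
                                  seed = 1L) {
  if (is.null(slopes$intercept)) slopes$intercept <- intercept
  mids <- (seq_len(n_bands) - 0.5) * band_width_um
  rows <- list()
  with_seed(derive_seed(seed, "bands"), {
    for (g in unique(slopes$group)) {
      mouse_eff <- rnorm(n_mice, 0, sd_mouse)
      for (m in seq_len(n_mice)) {
        mid <- sprintf("%s_m%02d", g, m)
        sl_g <- slopes[slopes$group == g, , drop = FALSE]
        for (r in seq_len(nrow(sl_g))) {
          tp <- sl_g$timepoint[r]
          for (rep in seq_len(n_replicates)) {
            rep_eff <- rnorm(1, 0, sd_replicate)
            y <- sl_g$intercept[r] + sl_g$slope[r] * mids + mouse_eff[m] +
              rep_eff + rnorm(n_bands, 0, sd_noise)
            rows[[length(rows) + 1L]] <- data.frame(
              image_id = sprintf("%s_t%s_r%d", mid, tp, rep),
              group = g, timepoint = tp, mouse_id = mid, replicate = rep,
              stain = "DAPI", band = seq_len(n_bands), mid_depth_um = mids,
              fraction_positive = y,
              band_area_um2 = NA_real_)
          }
        }
      }
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("band_fractions", "data.frame")
  out
}

#' Fit the distance-trend linear mixed model
#'
#' Models fraction-positive against depth from the implant edge with group,
#' timepoint and distance (and all their interactions) as fixed effects and
#' random intercepts for mouse and for replicate image nested within mouse
#' — the model behind the spatial-gradient analysis.  Fit by REML via
#' `lmerTest::lmer` so that downstream inference uses Satterthwaite degrees
#' of freedom.  Factors with a single observed level are dropped from the
#' fixed-effect formula automatically.
#'
#' @param records A `band_fractions` table ([band_profile()] or
#'   [simulate_band_records()]).
#' @param random Character subset of `c("mouse", "replicate")`; `NULL` or
#'   empty fits ordinary least squares instead.
#' @param logit If `TRUE`, model `qlogis(fraction)` instead of the identity
#'   scale (identity is the default, matching the banded-fraction analysis).
#' @param reml Use REML (default) or ML.
#' @return Object of class `distance_trend`: list with the fitted `model`,
#'   the prepared `data`, flags `singular`/`converged`, the fixed-effect
#'   `formula`, and `random`.
#' @export
#' @examples
#' sl <- data.frame(group = c("Hep", "NoHep"), timepoint = 1,
#'                  slope = c(-3e-4, -1e-4))
#' rec <- simulate_band_records(sl, seed = 2)
#' fit <- fit_distance_trend(rec)
#' coef(fit)["distance"]
fit_distance_trend <- function(records, random = c("mouse", "replicate"),
                               logit = FALSE, reml = TRUE) {
  df <- as.data.frame(records)
  need <- c("group", "timepoint", "mouse_id", "replicate", "mid_depth_um",
            "fraction_positive")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("records lack columns: %s", paste(miss, collapse = ", "))
  df$group <- factor(df$group)
  df$timepoint <- factor(df$timepoint)
  df$mouse <- factor(df$mouse_id)
  df$image <- factor(interaction(df$mouse_id, df$timepoint, df$replicate, drop = TRUE))
  df$distance <- df$mid_depth_um
  df$y <- if (logit) qlogis(pmin(pmax(df$fraction_positive, 1e-6), 1 - 1e-6))
          else df$fraction_positive
  if (length(unique(df$distance)) < 2)
    stopf("need at least two distinct distances to estimate a trend")
  fvars <- c("group", "timepoint")[c(nlevels(df$group) > 1, nlevels(df$timepoint) > 1)]
  rhs <- paste(c(fvars, "distance"), collapse = " * ")
  fixed <- as.formula(paste("y ~", rhs))
  X <- model.matrix(fixed, df)
  if (qr(X)$rank < ncol(X)) {
    q <- qr(X)
    aliased <- colnames(X)[q$pivot[seq(q$rank + 1, ncol(X))]]
    stopf("fixed-effect design is rank deficient; aliased terms: %s",
          paste(aliased, collapse = ", "))
  }
  random <- intersect(random %||% character(0), c("mouse", "replicate"))
  if (length(random) == 0) {
    model <- lm(fixed, data = df)
    singular <- FALSE
    converged <- TRUE
  } else {
    re <- c(mouse = "(1 | mouse)", replicate = "(1 | image)")[random]
    form <- as.formula(paste("y ~", rhs, "+", paste(re, collapse = " + ")))
    model <- lmerTest::lmer(form, data = df, REML = reml,
                            control = lme4::lmerControl(check.conv.singular = "ignore"))
    singular <- lme4::isSingular(model)
    converged <- length(model@optinfo$conv$lme4$messages %||% character(0)) == 0
    if (singular) {
      vc <- lme4::VarCorr(model)
      warning(sprintf(
        "singular fit: some variance components are zero (%s)",
        paste(sprintf("%s=%.3g", names(vc),
                      vapply(vc, function(v) v[1, 1], numeric(1))), collapse = ", ")),
        call. = FALSE)
    }
  }
  structure(list(model = model, data = df, formula = fixed, random = random,
                 logit = logit, reml = reml, singular = singular,
                 converged = converged, fvars = fvars),
            class = "distance_trend")
}

#' @export
print.distance_trend <- function(x, ...) {
  cat("Distance-trend model of fraction positive vs depth\n")
  cat("  fixed:  ", deparse(x$formula), "\n")
  cat("  random: ", if (length(x$random)) paste(x$random, collapse = " + ") else "none", "\n")
  cat("  obs:    ", nrow(x$data), "\n")
  if (x$singular) cat("  note:    singular fit (zero variance component)\n")
  sl <- tryCatch(marginal_slopes(x), error = function(e) NULL)
  if (!is.null(sl)) {
    cat("Marginal distance slopes (fraction per um):\n")
    print(as.data.frame(sl), digits = 4)
  }
  invisible(x)
}

#' @export
summary.distance_trend <- function(object, ...) summary(object$model, ...)

#' @export
coef.distance_trend <- function(object, ...) {
  if (inherits(object$model, "lm")) coef(object$model) else lme4::fixef(object$model)
}

#' @export
predict.distance_trend <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(predict(object$model, ...))
  newdata$distance <- newdata$distance %||% newdata$mid_depth_um
  predict(object$model, newdata = newdata, re.form = NA, ...)
}

#' @export
residuals.distance_trend <- function(object, ...) residuals(object$model, ...)

#' Plot fitted distance trends with confidence bands
#'
#' Draws the model's marginal fraction-vs-depth line for each group x
#' timepoint cell with its 95% confidence band, over the observed band
#' fractions.
#'
#' @param x A `distance_trend` fit.
#' @param n_grid Number of distance grid points.
#' @param ... Passed to [plot()].
#' @export
plot.distance_trend <- function(x, n_grid = 50, ...) {
  df <- x$data
  grid_d <- seq(min(df$distance), max(df$distance), length.out = n_grid)
  specs <- if (length(x$fvars)) as.formula(paste("~", paste(x$fvars, collapse = "*")))
           else ~1
  emm <- emmeans::emmeans(x$model, specs, at = list(distance = grid_d),
                          by = "distance", data = df)
  s <- as.data.frame(emm)
  cell <- if (length(x$fvars)) interaction(s[x$fvars], drop = TRUE) else factor("all")
  cols <- seq_along(levels(cell))
  plot(df$distance, df$y, pch = 16, cex = 0.4, col = "grey60",
       xlab = "depth from implant edge (um)", ylab = "fraction positive", ...)
  for (i in seq_along(levels(cell))) {
    si <- s[cell == levels(cell)[i], ]
    si <- si[order(si$distance), ]
    polygon(c(si$distance, rev(si$distance)),
            c(si$lower.CL, rev(si$upper.CL)),
            col = adjustcolor(cols[i], alpha.f = 0.2), border = NA)
    lines(si$distance, si$emmean, col = cols[i], lwd = 2)
  }
  legend("topright", legend = levels(cell), col = cols, lwd = 2, bty = "n")
  invisible(x)
}

#' Marginal distance slopes per group and timepoint
#'
#' The estimated linear trend of fraction-positive in depth for every group
#' x timepoint cell, with standard error, degrees of freedom
#' (Satterthwaite for mixed fits) and 95% confidence interval — the
#' emtrends-style slope readout.
#'
#' @param fit A `distance_trend` from [fit_distance_trend()].
#' @param level Confidence level (default 0.95).
#' @return `slope_estimates` data frame: factor columns, `slope`, `SE`,
#'   `df`, `lower`, `upper`; the emmGrid is attached as attribute
#'   `"emtrends"` for contrast computation.
#' @export
marginal_slopes <- function(fit, level = 0.95) {
  df <- fit$data
  specs <- if (length(fit$fvars)) as.formula(paste("~", paste(fit$fvars, collapse = "*")))
           else ~1
  emt <- emmeans::emtrends(fit$model, specs, var = "distance", data = df)
  s <- as.data.frame(summary(emt, infer = c(TRUE, FALSE), level = level))
  names(s)[names(s) == "distance.trend"] <- "slope"
  ci_cols <- intersect(c("lower.CL", "upper.CL", "asymp.LCL", "asymp.UCL"), names(s))
  names(s)[names(s) == ci_cols[1]] <- "lower"
  names(s)[names(s) == ci_cols[2]] <- "upper"
  attr(s, "emtrends") <- emt
  attr(s, "level") <- level
  class(s) <- c("slope_estimates", "data.frame")
  s
}

#' Pairwise contrasts of distance slopes
#'
#' All pairwise differences of the marginal distance slopes across group x
#' timepoint cells, with multiplicity-adjusted p-values (Tukey family by
#' default, matching the post-hoc convention used alongside the model).
#'
#' @param slopes A `slope_estimates` table from [marginal_slopes()].
#' @param adjust `"tukey"` (default), `"holm"`, or `"none"`.
#' @param by Optional factor name to compare within (e.g. `"timepoint"` for
#'   group contrasts at each timepoint).
#' @return `slope_contrasts` data frame: `contrast`, `estimate`, `SE`,
#'   `df`, `p_value`.
#' @export
slope_contrasts <- function(slopes, adjust = c("tukey", "holm", "none"), by = NULL) {
  adjust <- match.arg(adjust)
  emt <- attr(slopes, "emtrends")
  if (is.null(emt)) stopf("slopes must come from marginal_slopes()")
  ctr <- emmeans::contrast(emt, method = "pairwise", adjust = adjust, by = by)
  s <- as.data.frame(summary(ctr))
  names(s)[names(s) == "p.value"] <- "p_value"
  names(s)[names(s) == "estimate"] <- "estimate"
  class(s) <- c("slope_contrasts", "data.frame")
  s
}
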