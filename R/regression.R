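#' Fit a multilinear morphology-to-metabolism model
#'
#' Ordinary least squares with intercept on raw (uncentered) predictor
#' scales, so the intercept is interpretable as the response at the origin
#' of the morphospace. A light wrapper around \code{stats::lm} that stores
#' the data for the importance procedures and fails loudly (naming the
#' collinear columns) when the design is rank deficient instead of
#' silently aliasing them.
#'
#' @param formula Model formula, e.g. \code{mo2_formula("mo2net")}.
#' @param data Data frame with no missing values in the model variables;
#'   needs more rows than coefficients for a full-rank fit.
#' @return Object of class \code{hover_lm}: \code{coefficients},
#'   \code{r2}, \code{residuals}, \code{fitted}, plus the underlying
#'   \code{lm} and the data.
#' @examples
#' fit <- hover_lm(y ~ x, data.frame(x = 0:2, y = c(1, 3, 5)))
#' coef(fit)  # intercept 1, slope 2
#' @export
hover_lm <- function(formula, data) {
  mf <- stats::model.frame(formula, data)
  if (anyNA(mf)) stop("missing values in model variables")
  fit <- lm(formula, data)
  if (anyNA(coef(fit))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  y <- stats::model.response(mf)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst == 0) 1 else 1 - sum(residuals(fit)^2) / sst
  structure(list(coefficients = coef(fit), r2 = r2,
                 residuals = unname(residuals(fit)),
                 fitted = unname(fitted(fit)),
                 formula = formula, lm = fit, data = data),
            class = "hover_lm")
}

#' @export
print.hover_lm <- function(x, digits = 4, ...) {
  cat("Multilinear regression (", deparse(x$formula), ")\n", sep = "")
  print(round(x$coefficients, digits))
  cat(sprintf("R2 = %.4f on %d observations\n", x$r2, length(x$fitted)))
  invisible(x)
}

#' @export
summary.hover_lm <- function(object, ...) summary(object$lm, ...)

#' @export
coef.hover_lm <- function(object, ...) object$coefficients

#' @export
predict.hover_lm <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  unname(predict(object$lm, newdata = newdata, ...))
}

#' @export
residuals.hover_lm <- function(object, ...) object$residuals

#' @export
fitted.hover_lm <- function(object, ...) object$fitted

#' Variable importance by coefficient-of-determination degradation
#'
#' Quantifies each predictor's contribution by how much the model's
#' explanatory power degrades when the predictor is removed
#' (\code{method = "drop"}: refit without it, \code{dR2 = R2_full -
#' R2_reduced}) or when its values are randomly shuffled
#' (\code{method = "permute"}: mean over \code{n_perm} seeded shuffles of
#' \code{R2_full - R2_shuffled}). The two procedures usually agree on the
#' ranking when effects are well separated.
#'
#' @param object A \code{\link{hover_lm}}.
#' @param method \code{"drop"}, \code{"permute"} or \code{"both"}.
#' @param n_perm Number of permutations (>= 1) for the permute method.
#' @param seed Seed for the shuffles.
#' @return Data frame (class \code{importance_table}) with one row per
#'   predictor and columns \code{dr2_drop} and/or \code{dr2_permute};
#'   attributes record \code{n_perm}, \code{seed}, \code{r2_full}.
#' @export
importance <- function(object, method = c("both", "drop", "permute"),
                       n_perm = 999, seed = 1L) {
  stopifnot(inherits(object, "hover_lm"))
  method <- match.arg(method)
  terms_ <- attr(stats::terms(object$formula), "term.labels")
  if (method %in% c("permute", "both") && n_perm < 1)
    stop("n_perm must be >= 1 for the permutation method")
  out <- data.frame(predictor = terms_, stringsAsFactors = FALSE)
  if (method %in% c("drop", "both")) {
    out$dr2_drop <- vapply(terms_, function(tm) {
      f2 <- stats::update.formula(object$formula,
                                  paste(". ~ . -", tm))
      object$r2 - hover_lm(f2, object$data)$r2
    }, numeric(1))
  }
  if (method %in% c("permute", "both")) {
    out$dr2_permute <- with_seed(seed, function() {
      vapply(terms_, function(tm) {
        drops <- vapply(seq_len(n_perm), function(k) {
          d2 <- object$data
          d2[[tm]] <- sample(d2[[tm]])
          object$r2 - hover_lm(object$formula, d2)$r2
        }, numeric(1))
        mean(drops)
      }, numeric(1))
    })
  }
  structure(out, n_perm = if (method != "drop") n_perm else NA_integer_,
            seed = seed, r2_full = object$r2,
            class = c("importance_table", "data.frame"))
}

#' Assign species to low/high metabolic groups
#'
#' Species above the across-species mean of either metric — net hovering
#' cost or the hover-to-rest ratio — are assigned to the high group (G2);
#' all others to the low group (G1). "Above" is strict, so a species
#' exactly at the mean stays in G1.
#'
#' @param mo2net Per-species net MO2 values.
#' @param ratio Per-species hover/rest ratios (same length/names).
#' @return Character vector of \code{"G1"}/\code{"G2"} (named if inputs
#'   are), with attribute \code{means = c(mo2net, ratio)}. If every value
#'   of both metrics is identical a warning is raised and all species are
#'   G1 (nothing is above average).
#' @export
assign_groups <- function(mo2net, ratio) {
  stopifnot(length(mo2net) == length(ratio), length(mo2net) >= 2)
  m1 <- mean(mo2net); m2 <- mean(ratio)
  high <- mo2net > m1 | ratio > m2
  if (!any(high))
    warning("no species above average on either metric: all assigned G1")
  out <- ifelse(high, "G2", "G1")
  names(out) <- names(mo2net)
  attr(out, "means") <- c(mo2net = m1, ratio = m2)
  out
}

#' Species-level comparisons of metabolic rates
#'
#' Classical decomposition of per-individual MO2: a one-way ANOVA across
#' species, Tukey HSD pairwise contrasts, optional per-species
#' hover-vs-rest comparisons, and an optional Welch t-test between the
#' low (G1) and high (G2) metabolic groups. Species with fewer than 2
#' replicates are excluded with a warning; a fit with (near) zero
#' within-group variance is flagged \code{degenerate}.
#'
#' @param mo2 Numeric vector of individual MO2 values.
#' @param species Factor/character of species labels (same length).
#' @param condition Optional \code{"hover"}/\code{"rest"} labels for the
#'   within-species comparisons.
#' @param groups Optional named map species -> \code{"G1"}/\code{"G2"}
#'   (e.g. from \code{\link{assign_groups}}) for the between-group t-test.
#' @param alpha Significance level for the Tukey family (default 0.05).
#' @return List of class \code{species_tests}: \code{anova}
#'   (\code{F}, \code{p}, \code{df}), \code{tukey}, \code{within_species}
#'   (per-species hover vs rest t-tests), \code{group_test},
#'   \code{degenerate}, \code{excluded}.
#' @export
species_tests <- function(mo2, species, condition = NULL, groups = NULL,
                          alpha = 0.05) {
  stopifnot(length(mo2) == length(species))
  species <- as.character(species)
  tab <- table(species)
  small <- names(tab)[tab < 2]
  if (length(small) > 0) {
    warning("excluding species with a single replicate: ",
            paste(small, collapse = ", "))
    keep <- !species %in% small
    mo2 <- mo2[keep]; species <- species[keep]
    if (!is.null(condition)) condition <- condition[keep]
  }
  if (length(unique(species)) < 2) stop("need >= 2 species with replicates")
  sp <- factor(species)
  fit <- aov(mo2 ~ sp)
  an <- summary(fit)[[1]]
  ssw <- an["Residuals", "Sum Sq"]
  sst <- sum(an[, "Sum Sq"])
  degenerate <- is.finite(sst) && sst > 0 && ssw / sst < 1e-12
  res <- list(
    anova = list(F = an[1, "F value"], p = an[1, "Pr(>F)"],
                 df = unname(an[, "Df"])),
    tukey = TukeyHSD(fit, conf.level = 1 - alpha)$sp,
    degenerate = degenerate,
    excluded = small)
  if (!is.null(condition)) {
    res$within_species <- lapply(split(seq_along(mo2), species),
                                 function(ix) {
      h <- mo2[ix][condition[ix] == "hover"]
      r <- mo2[ix][condition[ix] == "rest"]
      if (length(h) < 2 || length(r) < 2) return(NULL)
      tt <- t.test(h, r)
      list(t = unname(tt$statistic), p = tt$p.value,
           mean_hover = mean(h), mean_rest = mean(r))
    })
  }
  if (!is.null(groups)) {
    g <- groups[species]
    if (length(unique(na.omit(g))) == 2) {
      tt <- t.test(mo2 ~ g)
      res$group_test <- list(t = unname(tt$statistic), p = tt$p.value,
                             means = tt$estimate)
    }
  }
  class(res) <- "species_tests"
  res
}

#' @export
print.species_tests <- function(x, ...) {
  cat(sprintf("One-way ANOVA across species: F = %.3f, p = %.4g%s\n",
              x$anova$F, x$anova$p,
              if (x$degenerate) " [degenerate: no within-group variance]"
              else ""))
  if (!is.null(x$group_test))
    cat(sprintf("G1 vs G2 (Welch): t = %.3f, p = %.4g\n",
                x$group_test$t, x$group_test$p))
  invisible(x)
}
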