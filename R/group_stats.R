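#' One-way ANOVA for a metric across subject groups
#'
#' Classical between/within mean-square F test with (k - 1, N - k) degrees
#' of freedom, used as the omnibus test before pairwise comparisons.
#'
#' @param values Numeric vector of per-subject metric values.
#' @param groups Group label per value (factor or character).
#' @return List with `F`, `p`, `df` (length-2), `k`, `n`.
#' @export
anova_oneway <- function(values, groups) {
  groups <- check_groups(values, groups)
  if (diff(range(values)) == 0)
    stop("undefined F: no variance between or within groups")
  fit <- stats::aov(values ~ groups)
  tab <- summary(fit)[[1]]
  if (!is.finite(tab[1, "F value"]))
    stop("undefined F: no variance between or within groups")
  list(F = tab[1, "F value"], p = tab[1, "Pr(>F)"],
       df = tab[["Df"]], k = nlevels(groups), n = length(values))
}

#' Tukey HSD pairwise comparisons
#'
#' Studentized-range-based adjusted p-values for every pair of groups,
#' controlling the family-wise error rate of the all-pairs comparison.
#'
#' @inheritParams anova_oneway
#' @return A symmetric k x k matrix of adjusted p-values (diagonal `NA`).
#' @export
tukey_hsd <- function(values, groups) {
  groups <- check_groups(values, groups)
  tk <- stats::TukeyHSD(stats::aov(values ~ groups))$groups
  lev <- levels(groups)
  p <- matrix(NA_real_, nlevels(groups), nlevels(groups),
              dimnames = list(lev, lev))
  pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
  for (i in seq_along(pairs)) {
    a <- pairs[[i]][1]; b <- pairs[[i]][2]
    p[a, b] <- p[b, a] <- tk[i, "p adj"]
  }
  p
}

check_groups <- function(values, groups) {
  if (length(values) != length(groups)) stop("values/groups length mismatch")
  if (any(!is.finite(values))) stop("values must be finite")
  groups <- droplevels(factor(groups))
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(table(groups) < 2)) stop("each group needs at least 2 values")
  groups
}

#' Leave-one-out linear discriminant classification of subjects
#'
#' Fisher LDA with pooled within-class covariance, assessed by
#' leave-one-out cross-validation: each subject is classified by a model
#' trained on all others, and accuracy is the fraction assigned to the
#' correct diagnosis group. Features are z-scored on each training fold
#' (the four saccadic metrics have heterogeneous units), the pooled
#' covariance carries a small ridge (`1e-6 * trace(S)/d`) to survive tiny
#' groups, and class priors are uniform by default (group sizes reflect
#' recruitment, not prevalence).
#'
#' @param features Numeric matrix or data.frame, one row per subject.
#' @param groups Group label per row.
#' @param priors `"uniform"` (default) or `"proportional"` to group size.
#' @return List of class `lda_loo`: `accuracy`, `confusion` (true x
#'   predicted counts), `predicted`.
#' @export
lda_loo <- function(features, groups, priors = c("uniform", "proportional")) {
  priors <- match.arg(priors)
  X <- as.matrix(features)
  storage.mode(X) <- "double"
  if (any(!is.finite(X))) stop("features must be finite")
  groups <- droplevels(factor(groups))
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  n <- nrow(X)
  pred <- character(n)
  for (i in seq_len(n)) {
    tr_x <- X[-i, , drop = FALSE]
    tr_g <- droplevels(groups[-i])
    mu <- colMeans(tr_x)
    sdv <- apply(tr_x, 2, stats::sd)
    sdv[sdv == 0] <- 1
    z <- scale(tr_x, center = mu, scale = sdv)
    z0 <- (X[i, ] - mu) / sdv
    pred[i] <- lda_classify(z, tr_g, z0, priors)
  }
  pred <- factor(pred, levels = levels(groups))
  conf <- table(true = groups, predicted = pred)
  structure(list(accuracy = mean(pred == groups),
                 confusion = conf, predicted = pred),
            class = "lda_loo")
}

# Fisher LDA with ridge-regularized pooled covariance; returns the
# predicted class label for a single observation x0
lda_classify <- function(z, g, z0, priors) {
  lev <- levels(g)
  d <- ncol(z)
  means <- t(vapply(lev, function(l) colMeans(z[g == l, , drop = FALSE]),
                    numeric(d)))
  centered <- z - means[as.integer(g), , drop = FALSE]
  S <- crossprod(centered) / (nrow(z) - length(lev))
  S <- S + diag(1e-6 * sum(diag(S)) / d, d)
  Sinv <- tryCatch(solve(S), error = function(e)
    stop("singular pooled covariance after regularization"))
  pri <- if (priors == "uniform") rep(1 / length(lev), length(lev))
         else as.numeric(table(g)[lev]) / length(g)
  disc <- vapply(seq_along(lev), function(k) {
    mk <- means[k, ]
    drop(z0 %*% Sinv %*% mk) - 0.5 * drop(mk %*% Sinv %*% mk) + log(pri[k])
  }, 0)
  lev[which.max(disc)]
}

#' @export
print.lda_loo <- function(x, ...) {
  cat(sprintf("<lda_loo> leave-one-out accuracy: %.1f%% (n = %d)\n",
              100 * x$accuracy, sum(x$confusion)))
  print(x$confusion)
  invisible(x)
}
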