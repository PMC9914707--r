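check_counts <- function(counts) {
  counts <- as.numeric(counts)
  if (any(counts < 0) || any(is.na(counts)))
    stop("counts must be non-negative and finite")
  if (any(abs(counts - round(counts)) > 1e-8))
    stop("richness estimators need integer counts, not proportions; ",
         "supply the raw count table")
  round(counts)
}

#' Chao1 richness estimate (bias-corrected)
#'
#' S_chao1 = S_obs + F1 (F1 - 1) / (2 (F2 + 1)), with F1 the number of
#' singleton features and F2 the number of doubletons. Always >=
#' observed richness; an all-zero sample has richness 0.
#'
#' @param counts integer count vector for one sample (one entry per
#'   feature). Proportions are rejected: the estimator is undefined on
#'   relative abundances.
#' @return Estimated richness.
#' @examples
#' chao1(c(1, 1, 2, 3))  # 4.5
#' @export
chao1 <- function(counts) {
  counts <- check_counts(counts)
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' ACE richness estimate (classic)
#'
#' Abundance-based coverage estimator: features with count <=
#' `rare_cutoff` form the rare class; S_ace = S_abund + S_rare / C_ace
#' + (F1 / C_ace) * gamma^2, with sample coverage C_ace = 1 - F1 /
#' N_rare and gamma^2 the squared coefficient of variation of the rare
#' class, floored at 0. When every rare individual is a singleton
#' (C_ace = 0) the estimator is undefined and the function falls back
#' to [chao1()] with a warning.
#'
#' @inheritParams chao1
#' @param rare_cutoff abundance boundary of the rare class (default 10).
#' @return Estimated richness.
#' @export
ace <- function(counts, rare_cutoff = 10) {
  counts <- check_counts(counts)
  s_obs <- sum(counts > 0)
  if (s_obs == 0) return(0)
  rare <- counts[counts > 0 & counts <= rare_cutoff]
  s_abund <- sum(counts > rare_cutoff)
  s_rare <- length(rare)
  if (s_rare == 0) return(s_obs)
  n_rare <- sum(rare)
  f1 <- sum(rare == 1)
  c_ace <- 1 - f1 / n_rare
  if (c_ace == 0) {
    warning("all rare individuals are singletons (coverage 0); ",
            "falling back to Chao1")
    return(chao1(counts))
  }
  i <- seq_len(rare_cutoff)
  fi <- vapply(i, function(k) sum(rare == k), numeric(1))
  gamma2 <- if (n_rare > 1) {
    max(s_rare / c_ace * sum(i * (i - 1) * fi) /
          (n_rare * (n_rare - 1)) - 1, 0)
  } else 0
  s_abund + s_rare / c_ace + f1 / c_ace * gamma2
}

#' Per-sample alpha diversity (Chao1 and ACE)
#'
#' @param counts sample x feature integer count matrix (samples in
#'   rows) or data.frame.
#' @param rare_cutoff passed to [ace()].
#' @return data.frame: `sample_id`, `observed`, `chao1`, `ace`.
#' @export
alpha_diversity <- function(counts, rare_cutoff = 10) {
  counts <- as.matrix(counts)
  ids <- rownames(counts) %||% paste0("sample", seq_len(nrow(counts)))
  data.frame(
    sample_id = ids,
    observed = apply(counts, 1, function(x) sum(x > 0)),
    chao1 = apply(counts, 1, chao1),
    ace = apply(counts, 1, ace, rare_cutoff = rare_cutoff),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Principal-component ordination of an abundance table
#'
#' PCA of the sample x feature table: column-mean-centred, unscaled
#' singular-value decomposition, components ordered by explained
#' variance. The sign of each component is fixed by making its
#' largest-magnitude loading positive, so recomputation is
#' reproducible. An optional Hellinger transform (square root of
#' relative abundance) is available for compositional data.
#'
#' @param x sample x feature numeric matrix or data.frame.
#' @param n_components number of components to return.
#' @param hellinger apply the Hellinger transform before the SVD.
#' @return List of class `fucolink_pca` with `scores` (samples x
#'   components), `loadings`, `explained_variance` (proportions of
#'   total variance) and `sdev`.
#' @export
pca_ordination <- function(x, n_components = 2, hellinger = FALSE) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("ordination needs >= 2 samples")
  if (hellinger) x <- sqrt(sweep(x, 1, rowSums(x), "/"))
  fit <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(fit$rotation))
  scores <- fit$x[, seq_len(k), drop = FALSE]
  loadings <- fit$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i_max <- which.max(abs(loadings[, j]))
    if (loadings[i_max, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  ev <- fit$sdev^2
  structure(list(scores = scores, loadings = loadings,
                 explained_variance = (ev / sum(ev))[seq_len(k)],
                 sdev = fit$sdev[seq_len(k)]),
            class = "fucolink_pca")
}

#' @export
print.fucolink_pca <- function(x, ...) {
  cat("PCA ordination:", nrow(x$scores), "samples,",
      ncol(x$scores), "components\n")
  cat("explained variance:",
      paste0(sprintf("%.1f%%", 100 * x$explained_variance),
             collapse = ", "), "\n")
  invisible(x)
}

#' Per-feature three-group comparison (one-way ANOVA + Tukey HSD)
#'
#' For every feature, tests for a group difference in abundance by
#' one-way ANOVA and follows with Tukey honestly-significant-difference
#' pairwise comparisons across all group pairs. Features with zero
#' variance (identical values everywhere) cannot be tested and are
#' flagged `degenerate` with NA statistics rather than raising an
#' error. No multiple-testing correction is applied by default;
#' `p_adjust = "BH"` adds a Benjamini-Hochberg adjusted column and
#' bases the `significant` call on it.
#'
#' @param abundance sample x feature numeric matrix or data.frame.
#' @param groups factor or character vector of group labels, one per
#'   sample (>= 2 groups with >= 2 samples each).
#' @param alpha significance level for the `significant` flag.
#' @param p_adjust `"none"` (default) or `"BH"`.
#' @return data.frame: `feature_id`, `anova_F`, `anova_p`, one Tukey
#'   adjusted-p column per group pair (`tukey_<B>_vs_<A>`),
#'   `significant`, `degenerate` (and `anova_p_adj` under BH).
#' @export
group_test <- function(abundance, groups, alpha = 0.05,
                       p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  abundance <- as.matrix(abundance)
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need >= 2 groups")
  if (any(table(groups) < 2)) stop("every group needs >= 2 samples")
  if (length(groups) != nrow(abundance))
    stop("one group label per sample required")
  features <- colnames(abundance) %||% paste0("f", seq_len(ncol(abundance)))
  pairs <- utils::combn(levels(groups), 2)
  pair_names <- paste0("tukey_", pairs[2, ], "_vs_", pairs[1, ])
  res <- lapply(seq_len(ncol(abundance)), function(j) {
    v <- abundance[, j]
    if (stats::var(v) == 0) {
      tk <- stats::setNames(rep(NA_real_, ncol(pairs)), pair_names)
      return(c(list(anova_F = NA_real_, anova_p = NA_real_),
               as.list(tk), list(degenerate = TRUE)))
    }
    fit <- stats::aov(v ~ groups)
    tab <- summary(fit)[[1]]
    tk_tab <- stats::TukeyHSD(fit)$groups
    tk_key <- paste0("tukey_", sub("-", "_vs_", rownames(tk_tab), fixed = TRUE))
    tk <- stats::setNames(tk_tab[, "p adj"], tk_key)[pair_names]
    c(list(anova_F = tab[1, "F value"], anova_p = tab[1, "Pr(>F)"]),
      as.list(stats::setNames(as.numeric(tk), pair_names)),
      list(degenerate = FALSE))
  })
  out <- data.frame(feature_id = features,
                    do.call(rbind, lapply(res, as.data.frame)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  if (p_adjust == "BH") {
    out$anova_p_adj <- stats::p.adjust(out$anova_p, method = "BH")
    out$significant <- !is.na(out$anova_p_adj) & out$anova_p_adj < alpha
  } else {
    out$significant <- !is.na(out$anova_p) & out$anova_p < alpha
  }
  out
}
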