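# Cache of permutation index matrices, keyed by n (n <= 9).
.perm_cache <- new.env(parent = emptyenv())

perm_matrix <- function(n) {
  key <- as.character(n)
  if (!is.null(.perm_cache[[key]])) return(.perm_cache[[key]])
  gen <- function(v) {
    if (length(v) <= 1) return(matrix(v, nrow = 1))
    do.call(rbind, lapply(seq_along(v), function(i)
      cbind(v[i], gen(v[-i]))))
  }
  m <- gen(seq_len(n))
  .perm_cache[[key]] <- m
  m
}

#' Spearman rank correlation with exact small-sample p-value
#'
#' Computes rho on mid-ranks (ties allowed). For n <= `exact_max_n`
#' (default 9) the two-sided p-value is exact: the observed |rho| is
#' compared against its full permutation null, enumerating all n!
#' orderings of one rank vector. For larger n the usual large-sample
#' t approximation t = rho sqrt((n-2)/(1-rho^2)) is used. Group sizes
#' in small diet studies (4-6 mice) make the asymptotic p unreliable,
#' hence the exact default there.
#'
#' @param x,y numeric vectors of equal length n >= 4.
#' @param exact_max_n largest n for exact permutation enumeration.
#' @return List: `rho`, `p_value`, `method` ("exact", "t-approx" or
#'   "degenerate"), `n`. A constant vector gives `rho = NA` flagged
#'   degenerate, not an error.
#' @export
spearman_cor <- function(x, y, exact_max_n = 9) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 4) stop("need n >= 4 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, p_value = NA_real_,
                method = "degenerate", n = n))
  rx <- rank(x)
  ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= exact_max_n) {
    perms <- perm_matrix(n)
    ryc <- ry - mean(ry)
    rxc <- rx - mean(rx)
    ry_perm <- matrix(ryc[perms], nrow = nrow(perms))
    rho_perm <- as.numeric(ry_perm %*% rxc) /
      (sqrt(sum(rxc^2)) * sqrt(sum(ryc^2)))
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
    method <- "exact"
  } else {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    method <- "t-approx"
  }
  list(rho = rho, p_value = min(p, 1), method = method, n = n)
}

#' Significance stars for p-values
#'
#' `***` p < 0.001, `**` p < 0.01, `*` p < 0.05, empty otherwise
#' (the usual footnote convention of correlation report tables).
#'
#' @param p numeric p-values.
#' @return Character vector of star codes ("" for NA).
#' @export
p_stars <- function(p) {
  out <- ifelse(is.na(p), "",
                ifelse(p < 0.001, "***",
                       ifelse(p < 0.01, "**",
                              ifelse(p < 0.05, "*", ""))))
  as.character(out)
}

#' Correlate every feature's abundance with host bodyweight
#'
#' Spearman rank correlation of each column of the abundance table
#' against bodyweight, pooled across diet groups (one rho per
#' feature), with significance stars. Results are sorted by |rho|
#' descending. No multiple-testing correction by default; `"BH"` adds
#' an adjusted column and stars it instead.
#'
#' @param abundance sample x feature matrix or data.frame; row names
#'   are sample ids.
#' @param phenotype data.frame with columns `sample_id` and
#'   `bodyweight`; the sample sets must match.
#' @param exact_max_n passed to [spearman_cor()].
#' @param p_adjust `"none"` (default) or `"BH"`.
#' @return data.frame: `feature_id`, `rho`, `p_value`, `method`,
#'   `stars` (and `p_adj` under BH).
#' @export
correlate_features <- function(abundance, phenotype, exact_max_n = 9,
                               p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  abundance <- as.matrix(abundance)
  ids <- rownames(abundance) %||% paste0("sample", seq_len(nrow(abundance)))
  extra <- setdiff(ids, phenotype$sample_id)
  missing <- setdiff(phenotype$sample_id, ids)
  if (length(extra) || length(missing))
    stop("sample sets differ between abundance and phenotype tables; ",
         "abundance-only: [", paste(extra, collapse = ", "),
         "], phenotype-only: [", paste(missing, collapse = ", "), "]")
  w <- phenotype$bodyweight[match(ids, phenotype$sample_id)]
  features <- colnames(abundance) %||% paste0("f", seq_len(ncol(abundance)))
  res <- lapply(seq_len(ncol(abundance)), function(j)
    spearman_cor(abundance[, j], w, exact_max_n = exact_max_n))
  out <- data.frame(
    feature_id = features,
    rho = vapply(res, `[[`, numeric(1), "rho"),
    p_value = vapply(res, `[[`, numeric(1), "p_value"),
    method = vapply(res, `[[`, character(1), "method"),
    stringsAsFactors = FALSE)
  if (p_adjust == "BH") {
    out$p_adj <- stats::p.adjust(out$p_value, method = "BH")
    out$stars <- p_stars(out$p_adj)
  } else {
    out$stars <- p_stars(out$p_value)
  }
  out <- out[order(-abs(out$rho), out$feature_id, na.last = TRUE), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
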