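#' Jensen-Shannon divergence between two distributions
#'
#' JSD(P, Q) = H(M) - (H(P) + H(Q)) / 2 with M = (P + Q) / 2 and H the
#' Shannon entropy in the configured log base. With base 2 the value
#' lies in `[0, 1]`; 0 iff P = Q, 1 for disjoint supports. `0 * log 0`
#' is taken as 0, and because M > 0 wherever P or Q > 0 no pseudocounts
#' are needed.
#'
#' @param p,q numeric probability vectors on the same support, or
#'   [gene_class_profile()] objects sharing a category universe (use
#'   [align_category_universe()] first otherwise).
#' @param base logarithm base for the entropy (default 2).
#' @return A single non-negative number.
#' @examples
#' jsd(c(1, 0), c(0, 1))        # 1 (maximal, base 2)
#' jsd(c(1, 0), c(0.5, 0.5))    # 0.311278
#' @export
jsd <- function(p, q, base = 2) {
  if (inherits(p, "gene_class_profile") ||
      inherits(q, "gene_class_profile")) {
    if (!(inherits(p, "gene_class_profile") &&
          inherits(q, "gene_class_profile")))
      stop("p and q must both be profiles or both numeric vectors")
    if (!identical(p$categories, q$categories))
      stop("profiles are on different category universes; apply ",
           "align_category_universe() first")
    p <- p$probabilities
    q <- q$probabilities
  }
  if (length(p) != length(q))
    stop("p and q must have equal length")
  if (any(p < 0) || any(q < 0))
    stop("negative probabilities")
  if (abs(sum(p) - 1) > 1e-6 || abs(sum(q) - 1) > 1e-6)
    stop("inputs must be normalised distributions (sum to 1 within 1e-6)")
  H <- function(x) {
    x <- x[x > 0]
    -sum(x * log(x, base = base))
  }
  m <- (p + q) / 2
  max(H(m) - (H(p) + H(q)) / 2, 0)
}

#' Reference panel of known fucoidan degraders
#'
#' Bundles the gene-class profiles of experimentally validated
#' seaweed-polysaccharide-degrading strains (the study design uses a
#' 12-strain panel: eight Lentimonas spp., Mariniflexile fucanivorans,
#' Kiritimatiellales sp. and relatives). Profiles are placed on a
#' shared category universe at construction.
#'
#' @param profiles list of [gene_class_profile()] objects (>= 1).
#' @return An object of class `reference_panel`.
#' @export
reference_panel <- function(profiles) {
  if (inherits(profiles, "gene_class_profile")) profiles <- list(profiles)
  if (!length(profiles)) stop("a reference panel needs >= 1 profile")
  profiles <- align_category_universe(profiles)
  structure(list(profiles = profiles,
                 names = vapply(profiles, `[[`, "", "genome_id")),
            class = "reference_panel")
}

#' @export
print.reference_panel <- function(x, ...) {
  cat("reference_panel:", length(x$profiles), "strains,",
      length(x$profiles[[1]]$categories), "categories\n")
  invisible(x)
}

#' Score one genome for fucoidan-degrading potential
#'
#' Computes the Jensen-Shannon divergence of the genome's gene-class
#' distribution to every panel member and keeps the minimum. A genome
#' is called a potential fucoidan degrader when its minimum divergence
#' is strictly below the threshold (default 0.0558, base-2 scale).
#'
#' @param profile a [gene_class_profile()].
#' @param panel a [reference_panel()] or list of profiles.
#' @param threshold classification cutoff on min JSD (strict `<`).
#' @param base log base passed to [jsd()].
#' @return One-row data.frame: `genome_id`, `min_jsd`,
#'   `best_reference` (argmin, ties broken by panel order),
#'   `is_degrader`, `threshold`.
#' @export
score_genome <- function(profile, panel, threshold = 0.0558, base = 2) {
  if (!inherits(panel, "reference_panel")) panel <- reference_panel(panel)
  aligned <- align_category_universe(c(list(profile), panel$profiles))
  d <- vapply(aligned[-1], function(r) jsd(aligned[[1]], r, base = base),
              numeric(1))
  i <- which.min(d)
  data.frame(genome_id = profile$genome_id,
             min_jsd = d[[i]],
             best_reference = panel$names[[i]],
             is_degrader = d[[i]] < threshold,
             threshold = threshold,
             stringsAsFactors = FALSE)
}

#' Score many genomes against the degrader panel
#'
#' @param profiles list of [gene_class_profile()] objects.
#' @inheritParams score_genome
#' @return data.frame of per-genome scores (order-preserving) with
#'   attributes `n_total` and `n_degraders`.
#' @export
score_all <- function(profiles, panel, threshold = 0.0558, base = 2) {
  if (!inherits(panel, "reference_panel")) panel <- reference_panel(panel)
  if (inherits(profiles, "gene_class_profile")) profiles <- list(profiles)
  out <- if (length(profiles) == 0) {
    data.frame(genome_id = character(), min_jsd = numeric(),
               best_reference = character(), is_degrader = logical(),
               threshold = numeric(), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, lapply(profiles, function(p) {
      tryCatch(score_genome(p, panel, threshold = threshold, base = base),
               error = function(e)
                 stop("scoring genome '", p$genome_id, "': ",
                      conditionMessage(e), call. = FALSE))
    }))
  }
  rownames(out) <- NULL
  attr(out, "n_total") <- nrow(out)
  attr(out, "n_degraders") <- sum(out$is_degrader)
  out
}

#' Classify pre-computed minimum divergences
#'
#' Applies the strict degrader rule (`min_jsd < threshold`) directly to
#' a vector of minimum Jensen-Shannon divergences, e.g. values printed
#' in a published report.
#'
#' @param min_jsd numeric vector of minimum divergences.
#' @inheritParams score_genome
#' @return Logical vector of degrader calls.
#' @export
degrader_call <- function(min_jsd, threshold = 0.0558) {
  stopifnot(is.numeric(min_jsd), all(min_jsd >= 0, na.rm = TRUE))
  min_jsd < threshold
}

#' Panel-internal divergence percentiles
#'
#' Reports percentiles of the pairwise JSD values inside the reference
#' panel. A helper for judging where a classification threshold sits
#' relative to panel-internal spread; it makes no claim to derive any
#' particular published cutoff.
#'
#' @param panel a [reference_panel()].
#' @param probs percentile probabilities.
#' @inheritParams jsd
#' @return Named numeric vector of percentiles, with attribute
#'   `pairwise` holding all pairwise divergences.
#' @export
calibrate_threshold <- function(panel, probs = c(0.5, 0.9, 0.95, 1),
                                base = 2) {
  if (!inherits(panel, "reference_panel")) panel <- reference_panel(panel)
  n <- length(panel$profiles)
  if (n < 2) stop("need >= 2 panel members for internal divergences")
  idx <- utils::combn(n, 2)
  d <- apply(idx, 2, function(ij)
    jsd(panel$profiles[[ij[1]]], panel$profiles[[ij[2]]], base = base))
  out <- stats::quantile(d, probs = probs)
  attr(out, "pairwise") <- d
  out
}

#' @rdname score_all
#' @param scores result of `score_all()`.
#' @param path output TSV path.
#' @export
write_scores <- function(scores, path) {
  utils::write.table(scores, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
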