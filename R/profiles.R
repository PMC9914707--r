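#' Gene-class profile of a genome
#'
#' A `gene_class_profile` is a genome's probability distribution over
#' functional gene categories (e.g. ortholog-group classes): the object
#' compared between genomes by Jensen-Shannon divergence. Probabilities
#' are non-negative and sum to 1 whenever the genome contributed at
#' least one classified gene.
#'
#' @param genome_id single genome identifier.
#' @param categories character vector of unique category labels.
#' @param probabilities numeric vector, same length as `categories`,
#'   non-negative, summing to 1 (tolerance 1e-6) when `n_genes > 0`.
#' @param n_genes number of genes counted into the distribution.
#' @return An object of class `gene_class_profile`.
#' @export
gene_class_profile <- function(genome_id, categories, probabilities,
                               n_genes = NA_integer_) {
  categories <- as.character(categories)
  probabilities <- as.numeric(probabilities)
  if (length(categories) != length(probabilities))
    stop("categories and probabilities must have equal length")
  if (anyDuplicated(categories))
    stop("category labels must be unique")
  if (any(probabilities < -1e-12))
    stop("probabilities must be non-negative")
  if (!is.na(n_genes) && n_genes > 0 &&
      abs(sum(probabilities) - 1) > 1e-6)
    stop("probabilities must sum to 1 (got ", sum(probabilities), ")")
  structure(
    list(genome_id = as.character(genome_id),
         categories = categories,
         probabilities = pmax(probabilities, 0),
         n_genes = as.integer(n_genes)),
    class = "gene_class_profile")
}

#' @export
print.gene_class_profile <- function(x, ...) {
  cat("gene_class_profile:", x$genome_id,
      sprintf("(%d categories, %s genes)\n", length(x$categories),
              ifelse(is.na(x$n_genes), "?", x$n_genes)))
  invisible(x)
}

validate_annotations <- function(annotations) {
  need <- c("genome_id", "gene_id", "category",
            "is_protein_coding", "is_cazyme")
  miss <- setdiff(need, names(annotations))
  if (length(miss))
    stop("annotation table is missing column(s): ",
         paste(miss, collapse = ", "))
  key <- paste(annotations$genome_id, annotations$gene_id)
  if (anyDuplicated(key))
    stop("duplicated (genome_id, gene_id) pairs in annotation table")
  bad <- annotations$is_cazyme & !annotations$is_protein_coding
  if (any(bad, na.rm = TRUE))
    stop("CAZyme-flagged gene(s) not marked protein-coding: ",
         paste(utils::head(annotations$gene_id[bad], 3), collapse = ", "))
  invisible(annotations)
}

#' Build a gene-class profile from an annotation table
#'
#' Counts one unit per gene into its functional category and normalises
#' to a probability distribution (the "relative abundance of the main
#' gene categories" of the genome). Genes without a category are either
#' dropped (default) or pooled into a reserved `"unclassified"` label.
#'
#' @param annotations data.frame with columns `genome_id`, `gene_id`,
#'   `category` (NA or "" = unclassified), `is_protein_coding`,
#'   `is_cazyme`.
#' @param genome_id genome to profile; must be present in the table.
#' @param include_unclassified pool category-less genes into an
#'   `"unclassified"` class instead of dropping them.
#' @return A [gene_class_profile()].
#' @examples
#' ann <- data.frame(genome_id = "g1", gene_id = paste0("x", 1:4),
#'                   category = c("A", "A", "B", "B"),
#'                   is_protein_coding = TRUE, is_cazyme = FALSE)
#' build_profile(ann, "g1")
#' @export
build_profile <- function(annotations, genome_id,
                          include_unclassified = FALSE) {
  validate_annotations(annotations)
  rows <- annotations[annotations$genome_id == genome_id, , drop = FALSE]
  if (nrow(rows) == 0)
    stop("genome '", genome_id, "' not present in annotation table")
  cat_lab <- as.character(rows$category)
  missing_cat <- is.na(cat_lab) | cat_lab == ""
  if (include_unclassified) {
    cat_lab[missing_cat] <- "unclassified"
  } else {
    cat_lab <- cat_lab[!missing_cat]
  }
  if (length(cat_lab) == 0)
    stop("genome '", genome_id, "' has no classified genes; ",
         "cannot build an empty profile (set include_unclassified = TRUE ",
         "to pool unannotated genes)")
  counts <- table(cat_lab)
  counts <- counts[order(names(counts))]
  gene_class_profile(genome_id,
                     categories = names(counts),
                     probabilities = as.numeric(counts) / sum(counts),
                     n_genes = sum(counts))
}

#' Place profiles on a shared category universe
#'
#' Jensen-Shannon divergence needs both distributions on the same
#' support; this expands every profile to the sorted union of all
#' category labels, filling absent categories with probability 0.
#'
#' @param profiles list of [gene_class_profile()] objects.
#' @return List of profiles over the identical, sorted category union.
#' @export
align_category_universe <- function(profiles) {
  if (!length(profiles)) stop("empty profile list")
  stopifnot(all(vapply(profiles, inherits, TRUE, "gene_class_profile")))
  universe <- sort(unique(unlist(lapply(profiles, `[[`, "categories"))))
  lapply(profiles, function(p) {
    prob <- stats::setNames(numeric(length(universe)), universe)
    prob[p$categories] <- p$probabilities
    gene_class_profile(p$genome_id, universe, as.numeric(prob), p$n_genes)
  })
}

#' CAZyme fraction of a genome
#'
#' Percentage of a genome's protein-coding genes annotated as
#' carbohydrate-active enzymes (CAZymes) -- a proxy for
#' polysaccharide-utilisation capacity.
#'
#' @inheritParams build_profile
#' @return Percentage in `[0, 100]` (not rounded; the report layer
#'   formats to one decimal).
#' @examples
#' ann <- data.frame(genome_id = "akk", gene_id = seq_len(2475),
#'                   category = "K", is_protein_coding = TRUE,
#'                   is_cazyme = rep(c(TRUE, FALSE), c(176, 2299)))
#' round(cazyme_fraction(ann, "akk"), 1)  # 7.1
#' @export
cazyme_fraction <- function(annotations, genome_id) {
  validate_annotations(annotations)
  rows <- annotations[annotations$genome_id == genome_id, , drop = FALSE]
  if (nrow(rows) == 0)
    stop("genome '", genome_id, "' not present in annotation table")
  n_pc <- sum(rows$is_protein_coding)
  if (n_pc == 0)
    stop("genome '", genome_id, "' has no protein-coding genes")
  100 * sum(rows$is_cazyme) / n_pc
}

#' Read / write gene-class profiles as TSV
#'
#' Long-format TSV with columns `genome_id`, `category`, `probability`
#' (and optionally `n_genes`).
#'
#' @param path file path.
#' @return `read_profiles()`: a list of [gene_class_profile()].
#' @export
read_profiles <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("genome_id", "category", "probability")
  if (!all(need %in% names(d)))
    stop("profile TSV must have columns: ", paste(need, collapse = ", "))
  lapply(split(d, factor(d$genome_id, levels = unique(d$genome_id))),
         function(g) {
           n <- if ("n_genes" %in% names(g)) g$n_genes[1] else NA_integer_
           gene_class_profile(g$genome_id[1], g$category,
                              g$probability, n)
         })
}

#' @rdname read_profiles
#' @param profiles list of profiles to write.
#' @export
write_profiles <- function(profiles, path) {
  if (inherits(profiles, "gene_class_profile")) profiles <- list(profiles)
  d <- do.call(rbind, lapply(profiles, function(p)
    data.frame(genome_id = p$genome_id, category = p$categories,
               probability = p$probabilities, n_genes = p$n_genes,
               stringsAsFactors = FALSE)))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
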