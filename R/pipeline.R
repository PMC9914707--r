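#' Pipeline configuration
#'
#' File paths and decision knobs for [run_pipeline()]. The defaults
#' reproduce the study's stated cutoffs exactly: degrader threshold
#' 0.0558 on base-2 JSD, link filter alignment length > 300 bp and
#' identity > 99% (both strict), alpha 0.05.
#'
#' @param panel path to the reference-panel profile TSV.
#' @param mag_profiles path to the MAG profile TSV.
#' @param abundance path to the sample x MAG relative-abundance TSV
#'   (first column `sample_id`).
#' @param phenotype path to the phenotype TSV (`sample_id`,
#'   `bodyweight`, `group`).
#' @param hits path to a 12-column tabular alignment hit file, or NULL
#'   to align `queries` vs `subjects` internally.
#' @param queries,subjects FASTA paths for internal alignment (used
#'   when `hits` is NULL).
#' @param taxonomy optional taxonomy-map TSV (`repseq_id`, `taxonomy`).
#' @param counts optional count-table TSV for alpha diversity.
#' @param outdir directory for all written artifacts.
#' @param threshold degrader min-JSD cutoff (strict `<`).
#' @param min_alignment_length,min_identity link-filter cutoffs
#'   (strict `>`).
#' @param alpha significance level for group tests.
#' @param log_base JSD log base.
#' @param seed recorded in the report header (the pipeline itself is
#'   deterministic given its inputs).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(panel, mag_profiles, abundance, phenotype,
                            hits = NULL, queries = NULL, subjects = NULL,
                            taxonomy = NULL, counts = NULL,
                            outdir = ".",
                            threshold = 0.0558,
                            min_alignment_length = 300,
                            min_identity = 99,
                            alpha = 0.05,
                            log_base = 2,
                            seed = NA_integer_) {
  structure(list(panel = panel, mag_profiles = mag_profiles,
                 abundance = abundance, phenotype = phenotype,
                 hits = hits, queries = queries, subjects = subjects,
                 taxonomy = taxonomy, counts = counts, outdir = outdir,
                 threshold = threshold,
                 min_alignment_length = min_alignment_length,
                 min_identity = min_identity, alpha = alpha,
                 log_base = log_base, seed = seed),
            class = "pipeline_config")
}

#' Run the full inference pipeline
#'
#' Orchestrates the chain profiles -> degrader scores -> 16S links ->
#' community statistics -> bodyweight correlations and assembles the
#' integrated per-MAG report (one row per MAG present in the abundance
#' table, sorted by |rho| descending): Spearman rho with stars,
#' minimum JS divergence and degrader call, and the linked 16S
#' representative with taxonomy, identity and alignment length (NA
#' when no accepted link exists). Every stage writes its table under
#' `outdir`, so each step is independently re-runnable and
#' inspectable; the report header records every decision knob because
#' several (log base, strictness, pooling) are conventions that must
#' not stay silent. The run is deterministic given config + inputs.
#'
#' @param config a [pipeline_config()].
#' @return The integrated report data.frame (invisible attributes:
#'   `scores`, `links`, `correlations`, `group_tests`, `diversity`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  panel <- stage("panel", reference_panel(read_profiles(config$panel)))
  mags <- stage("profiles", read_profiles(config$mag_profiles))
  scores <- stage("degrader", score_all(mags, panel,
                                        threshold = config$threshold,
                                        base = config$log_base))
  write_scores(scores, file.path(config$outdir, "degrader_scores.tsv"))

  taxonomy <- if (!is.null(config$taxonomy))
    utils::read.delim(config$taxonomy, stringsAsFactors = FALSE) else NULL
  hits <- stage("alignment", {
    if (!is.null(config$hits)) {
      read_hits(config$hits)
    } else if (!is.null(config$queries) && !is.null(config$subjects)) {
      q <- Biostrings::readDNAStringSet(config$queries)
      s <- Biostrings::readDNAStringSet(config$subjects)
      align_all(q, s)
    } else NULL
  })
  links <- if (!is.null(hits)) {
    l <- stage("linker", link_hits(hits, taxonomy_map = taxonomy,
                                   min_length = config$min_alignment_length,
                                   min_identity = config$min_identity))
    write_links(l, file.path(config$outdir, "links.tsv"))
    l
  } else NULL

  abundance <- stage("abundance", read_matrix_tsv(config$abundance))
  phenotype <- stage("phenotype",
                     utils::read.delim(config$phenotype,
                                       stringsAsFactors = FALSE))
  corr <- stage("correlation", correlate_features(abundance, phenotype))
  utils::write.table(corr, file.path(config$outdir, "correlations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  gt <- stage("group_test",
              group_test(abundance,
                         phenotype$group[match(rownames(abundance),
                                               phenotype$sample_id)],
                         alpha = config$alpha))
  utils::write.table(gt, file.path(config$outdir, "group_tests.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  ord <- stage("ordination", pca_ordination(abundance))
  utils::write.table(
    data.frame(sample_id = rownames(ord$scores), ord$scores,
               stringsAsFactors = FALSE),
    file.path(config$outdir, "ordination.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  div <- if (!is.null(config$counts)) {
    d <- stage("diversity", alpha_diversity(read_matrix_tsv(config$counts)))
    utils::write.table(d, file.path(config$outdir, "diversity.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    d
  } else NULL

  report <- stage("report",
                  build_report(scores, links, corr, colnames(abundance)))
  # report invariants: the filter and threshold rules hold on every row
  stopifnot(all(!report$is_degrader |
                  report$min_jsd < config$threshold),
            all(!report$linked |
                  (report$alignment_length > config$min_alignment_length &
                     report$percent_identity > config$min_identity)))
  header <- c(
    "# fucolink integrated report",
    paste0("# version = ",
           as.character(utils::packageVersion("fucolink"))),
    paste0("# degrader_threshold = ", format(config$threshold)),
    paste0("# jsd_log_base = ", format(config$log_base),
           " (JSD in [0,1]; threshold assumed on this scale)"),
    paste0("# link_filter = alignment_length > ",
           format(config$min_alignment_length),
           " bp AND identity > ", format(config$min_identity),
           " % (both strict)"),
    paste0("# alpha = ", format(config$alpha)),
    paste0("# correlation = Spearman, pooled across groups, ",
           "exact permutation p for n <= 9"),
    paste0("# seed = ", format(config$seed)))
  path <- file.path(config$outdir, "integrated_report.tsv")
  writeLines(header, path)
  suppressWarnings(
    utils::write.table(report, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, append = TRUE))
  attr(report, "scores") <- scores
  attr(report, "links") <- links
  attr(report, "correlations") <- corr
  attr(report, "group_tests") <- gt
  attr(report, "diversity") <- div
  report
}

build_report <- function(scores, links, corr, mag_ids) {
  acc <- if (!is.null(links)) links[links$accepted, , drop = FALSE]
  else links
  rows <- lapply(mag_ids, function(id) {
    s <- scores[scores$genome_id == id, , drop = FALSE]
    cr <- corr[corr$feature_id == id, , drop = FALSE]
    a <- if (!is.null(acc)) acc[acc$mag_id == id, , drop = FALSE] else NULL
    linked <- !is.null(a) && nrow(a) > 0
    if (linked) a <- a[1, , drop = FALSE]  # first accepted link
    data.frame(
      mag_id = id,
      rho = if (nrow(cr)) cr$rho else NA_real_,
      stars = if (nrow(cr)) cr$stars else "",
      p_value = if (nrow(cr)) cr$p_value else NA_real_,
      min_jsd = if (nrow(s)) s$min_jsd else NA_real_,
      is_degrader = if (nrow(s)) s$is_degrader else NA,
      linked = linked,
      repseq_id = if (linked) a$repseq_id else NA_character_,
      taxonomy = if (linked) a$taxonomy else NA_character_,
      percent_identity = if (linked) a$percent_identity else NA_real_,
      alignment_length = if (linked) a$alignment_length else NA_integer_,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-abs(out$rho), out$mag_id, na.last = TRUE), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Render the key-MAG report table
#'
#' Formats selected rows of an integrated report in the layout of a
#' published key-species table: Spearman rho with significance stars,
#' minimum JS divergence to 4 decimals, and the linked 16S
#' representative's taxonomy, identity (3 decimals) and integer
#' alignment length -- or a single `NA` where the MAG has no accepted
#' 16S hit.
#'
#' @param report output of [run_pipeline()] (or any data.frame with
#'   the same columns).
#' @param selection MAG ids to print, in order; must all be present.
#' @return Character-matrix-backed data.frame of formatted cells.
#' @export
render_table1 <- function(report, selection = report$mag_id) {
  unknown <- setdiff(selection, report$mag_id)
  if (length(unknown))
    stop("unknown MAG id(s) in selection: ",
         paste(unknown, collapse = ", "))
  rows <- report[match(selection, report$mag_id), , drop = FALSE]
  fmt_rho <- ifelse(is.na(rows$rho), "NA",
                    paste0(sprintf("%.3f", rows$rho),
                           ifelse(rows$stars == "", " (p > 0.05)",
                                  paste0(" (", rows$stars, ")"))))
  blast <- ifelse(!rows$linked, "NA",
                  paste(rows$repseq_id, rows$taxonomy,
                        sprintf("%.3f", rows$percent_identity),
                        rows$alignment_length))
  out <- data.frame(
    `MAG` = rows$mag_id,
    `Spearman correlation (MAG vs. bodyweight)` = fmt_rho,
    `Minimum JS divergence` = sprintf("%.4f", rows$min_jsd),
    `16S rRNA blasted against MAG` = blast,
    check.names = FALSE, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
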