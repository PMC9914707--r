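#' Read a 12-column tabular alignment hit file
#'
#' Parses the standard 12-column tab-separated local-alignment output
#' dialect (query id, subject id, percent identity, alignment length,
#' mismatches, gap opens, query start/end, subject start/end, e-value,
#' bit score). The MAG id is derived from the subject gene id, which
#' binning tools build as `<bin>_<gene index>`: by default everything
#' before the last `_` is the MAG id.
#'
#' @param path hit file path (no header).
#' @param mag_id_fun function mapping subject ids to MAG ids; default
#'   strips the trailing `_<suffix>`.
#' @return data.frame of hits with columns `query_id`, `subject_id`,
#'   `mag_id`, `percent_identity`, `alignment_length`, `mismatches`,
#'   `gap_opens`, `q_start`, `q_end`, `s_start`, `s_end`, `evalue`,
#'   `bit_score`. Empty file gives a 0-row data.frame with a warning.
#' @export
read_hits <- function(path,
                      mag_id_fun = function(s) sub("_[^_]*$", "", s)) {
  cols <- c("query_id", "subject_id", "percent_identity",
            "alignment_length", "mismatches", "gap_opens",
            "q_start", "q_end", "s_start", "s_end", "evalue", "bit_score")
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    warning("empty hit file: ", path)
    d <- as.data.frame(stats::setNames(
      rep(list(character(0)), length(cols)), cols))
    d$mag_id <- character(0)
    return(hit_table(d))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(parts)
  if (any(nfield != 12))
    stop("malformed hit file '", path, "': line ",
         which(nfield != 12)[1], " has ", nfield[nfield != 12][1],
         " fields (expected 12)")
  d <- as.data.frame(do.call(rbind, parts), stringsAsFactors = FALSE)
  names(d) <- cols
  num <- c("percent_identity", "mismatches", "gap_opens", "q_start",
           "q_end", "s_start", "s_end", "evalue", "bit_score",
           "alignment_length")
  d[num] <- lapply(d[num], as.numeric)
  d$alignment_length <- as.integer(d$alignment_length)
  d$mag_id <- mag_id_fun(d$subject_id)
  hit_table(d)
}

hit_table <- function(d) {
  if (nrow(d)) {
    if (any(d$alignment_length < 1))
      stop("alignment_length must be >= 1")
    if (any(d$percent_identity < 0 | d$percent_identity > 100))
      stop("percent_identity must lie in [0, 100]")
  }
  d
}

#' @rdname read_hits
#' @param hits hit data.frame to write (12 standard columns, no header).
#' @export
write_hits <- function(hits, path) {
  cols <- c("query_id", "subject_id", "percent_identity",
            "alignment_length", "mismatches", "gap_opens",
            "q_start", "q_end", "s_start", "s_end", "evalue", "bit_score")
  utils::write.table(hits[cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Local alignment of a 16S query against a MAG gene
#'
#' Smith-Waterman local alignment under nucleotide-search-style scoring
#' (match +2, mismatch -3, gap open 5, gap extend 2). Identity is
#' 100 x matches / alignment columns and length counts alignment
#' columns including gaps, matching the tabular-output convention.
#' With `both_strands = TRUE` the reverse complement of the query is
#' also tried and the higher-scoring strand reported.
#'
#' @param query,subject nucleotide sequences (character or
#'   `Biostrings::DNAString`) over A, C, G, T, N.
#' @param query_id,subject_id ids recorded in the hit.
#' @param match,mismatch,gap_open,gap_extend scoring parameters
#'   (penalties as positive costs).
#' @param both_strands also search the reverse complement of the query.
#' @param mag_id_fun as in [read_hits()].
#' @return One-row hit data.frame in the [read_hits()] layout.
#' @export
align_local <- function(query, subject, query_id = "query",
                        subject_id = "subject",
                        match = 2, mismatch = -3,
                        gap_open = 5, gap_extend = 2,
                        both_strands = TRUE,
                        mag_id_fun = function(s) sub("_[^_]*$", "", s)) {
  query <- Biostrings::DNAString(as.character(query))
  subject <- Biostrings::DNAString(as.character(subject))
  if (length(query) == 0 || length(subject) == 0)
    stop("empty sequence")
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = match, mismatch = mismatch, baseOnly = FALSE)
  one <- function(q) Biostrings::pairwiseAlignment(
    q, subject, type = "local", substitutionMatrix = mat,
    gapOpening = gap_open, gapExtension = gap_extend)
  aln <- one(query)
  if (both_strands) {
    rev_aln <- one(Biostrings::reverseComplement(query))
    if (Biostrings::score(rev_aln) > Biostrings::score(aln)) aln <- rev_aln
  }
  p <- as.character(Biostrings::alignedPattern(aln))
  s <- as.character(Biostrings::alignedSubject(aln))
  len <- nchar(p)
  nmat <- Biostrings::nmatch(aln)
  count_gaps <- function(z) {
    runs <- gregexpr("-+", z)[[1]]
    if (runs[1] == -1) c(cols = 0L, opens = 0L)
    else c(cols = sum(attr(runs, "match.length")), opens = length(runs))
  }
  gp <- count_gaps(p)
  gs <- count_gaps(s)
  mism <- len - nmat - gp[["cols"]] - gs[["cols"]]
  pat <- Biostrings::pattern(aln)
  sbj <- Biostrings::subject(aln)
  hit_table(data.frame(
    query_id = query_id, subject_id = subject_id,
    mag_id = mag_id_fun(subject_id),
    percent_identity = 100 * nmat / len,
    alignment_length = as.integer(len),
    mismatches = mism, gap_opens = gp[["opens"]] + gs[["opens"]],
    q_start = BiocGenerics::start(pat), q_end = BiocGenerics::end(pat),
    s_start = BiocGenerics::start(sbj), s_end = BiocGenerics::end(sbj),
    evalue = NA_real_, bit_score = Biostrings::score(aln),
    stringsAsFactors = FALSE))
}

#' Align every 16S query against every MAG gene
#'
#' Convenience all-vs-all wrapper over [align_local()] for desk-scale
#' fixtures; large searches should ingest precomputed tabular hits via
#' [read_hits()] instead.
#'
#' @param queries,subjects named character vectors or `DNAStringSet`s.
#' @param ... passed to [align_local()].
#' @return Hit data.frame, one row per (query, subject) pair.
#' @export
align_all <- function(queries, subjects, ...) {
  qn <- names(queries)
  sn <- names(subjects)
  queries <- stats::setNames(as.character(queries),
                             qn %||% paste0("q", seq_along(queries)))
  subjects <- stats::setNames(as.character(subjects),
                              sn %||% paste0("s", seq_along(subjects)))
  do.call(rbind, lapply(names(queries), function(qn)
    do.call(rbind, lapply(names(subjects), function(sn)
      align_local(queries[[qn]], subjects[[sn]],
                  query_id = qn, subject_id = sn, ...)))))
}

#' Link 16S sequences to MAGs by the alignment-hit filter
#'
#' A 16S representative sequence and a MAG are considered to come from
#' the same strain only when the best hit between them has alignment
#' length strictly greater than `min_length` (default 300 bp) and
#' percent identity strictly greater than `min_identity` (default 99).
#' Per (mag_id, query_id) pair the best hit is kept first (highest
#' identity, then longest alignment, then first seen), so multi-HSP
#' hits are not double counted. All qualifying pairs are retained;
#' MAGs or queries participating in more than one accepted link are
#' flagged `multi_link` rather than forced into a bijection.
#'
#' @param hits hit data.frame from [read_hits()], [align_local()] or
#'   [align_all()].
#' @param taxonomy_map optional data.frame with columns `repseq_id`,
#'   `taxonomy`: the 16S classification transferred to linked MAGs.
#' @param min_length alignment-length cutoff in bp (strict `>`).
#' @param min_identity percent-identity cutoff (strict `>`).
#' @return data.frame of link records: `mag_id`, `repseq_id`,
#'   `taxonomy`, `percent_identity`, `alignment_length`, `accepted`,
#'   `multi_link`.
#' @export
link_hits <- function(hits, taxonomy_map = NULL,
                      min_length = 300, min_identity = 99) {
  if (nrow(hits) == 0) {
    return(data.frame(mag_id = character(), repseq_id = character(),
                      taxonomy = character(), percent_identity = numeric(),
                      alignment_length = integer(), accepted = logical(),
                      multi_link = logical(), stringsAsFactors = FALSE))
  }
  ord <- order(hits$mag_id, hits$query_id,
               -hits$percent_identity, -hits$alignment_length)
  h <- hits[ord, , drop = FALSE]
  best <- h[!duplicated(paste(h$mag_id, h$query_id, sep = "\r")), ,
            drop = FALSE]
  # restore first-seen order of the (mag, query) pairs
  first_seen <- match(paste(best$mag_id, best$query_id, sep = "\r"),
                      paste(hits$mag_id, hits$query_id, sep = "\r"))
  best <- best[order(first_seen), , drop = FALSE]
  out <- data.frame(
    mag_id = best$mag_id,
    repseq_id = best$query_id,
    taxonomy = NA_character_,
    percent_identity = best$percent_identity,
    alignment_length = best$alignment_length,
    accepted = best$alignment_length > min_length &
      best$percent_identity > min_identity,
    stringsAsFactors = FALSE)
  if (!is.null(taxonomy_map)) {
    out$taxonomy <- taxonomy_map$taxonomy[
      match(out$repseq_id, taxonomy_map$repseq_id)]
  }
  acc <- out[out$accepted, , drop = FALSE]
  out$multi_link <- out$accepted &
    (out$mag_id %in% acc$mag_id[duplicated(acc$mag_id)] |
       out$repseq_id %in% acc$repseq_id[duplicated(acc$repseq_id)])
  rownames(out) <- NULL
  out
}

#' @rdname link_hits
#' @param links link data.frame to write.
#' @param path output TSV path.
#' @export
write_links <- function(links, path) {
  utils::write.table(links, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
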