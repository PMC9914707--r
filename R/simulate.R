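#' Simulation configuration
#'
#' Parameters of the synthetic-data generators. Defaults mirror the
#' study design the pipeline targets: a 12-strain reference panel of
#' known fucoidan degraders, three diet groups (Control = low-fat,
#' Model = high-fat, SjC = high-fat + polysaccharide) with 4 mice
#' each, and a MAG catalogue in which a known subset are planted
#' perturbed copies of panel members.
#'
#' @param seed integer master seed; every generator draws from a
#'   substream derived from it, so any subset of outputs is
#'   reproducible.
#' @param n_categories number of functional gene categories (>= 2).
#' @param n_panel reference-panel size.
#' @param n_mags number of MAGs to simulate.
#' @param n_planted_degraders MAGs planted as perturbed panel copies
#'   (<= `n_mags`).
#' @param degrader_noise Dirichlet perturbation scale for planted
#'   degraders; a planted profile is drawn from
#'   Dirichlet(reference / degrader_noise), so smaller values give
#'   smaller divergence from the panel (0.003 puts planted minimum
#'   JSD around 0.02-0.04, inside the 0.0558 decision region).
#' @param n_samples_per_group mice per diet group.
#' @param group_names ordered group labels.
#' @param effect_size planted log-scale group shift for differential
#'   features (0 = null).
#' @param assoc_strength planted monotone abundance-bodyweight
#'   association in [-1, 1] (0 = null); the magnitude scales the
#'   bodyweight coefficient on the log-abundance scale.
#' @param n_differential number of features with a planted group
#'   effect.
#' @param n_associated number of features with a planted bodyweight
#'   association (disjoint from the differential set).
#' @param noise_sd log-scale sample noise standard deviation.
#' @param depth sequencing depth for the multinomial count table.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1,
                              n_categories = 50,
                              n_panel = 12,
                              n_mags = 60,
                              n_planted_degraders = 10,
                              degrader_noise = 0.003,
                              n_samples_per_group = 4,
                              group_names = c("Control", "Model", "SjC"),
                              effect_size = 2,
                              assoc_strength = 0.8,
                              n_differential = 8,
                              n_associated = 6,
                              noise_sd = 0.5,
                              depth = 50000) {
  cfg <- list(seed = as.integer(seed), n_categories = as.integer(n_categories),
              n_panel = as.integer(n_panel), n_mags = as.integer(n_mags),
              n_planted_degraders = as.integer(n_planted_degraders),
              degrader_noise = degrader_noise,
              n_samples_per_group = as.integer(n_samples_per_group),
              group_names = as.character(group_names),
              effect_size = effect_size, assoc_strength = assoc_strength,
              n_differential = as.integer(n_differential),
              n_associated = as.integer(n_associated),
              noise_sd = noise_sd, depth = as.integer(depth))
  if (cfg$n_categories < 2) stop("n_categories must be >= 2")
  if (cfg$n_panel < 1) stop("n_panel must be >= 1")
  if (cfg$n_planted_degraders > cfg$n_mags)
    stop("n_planted_degraders must be <= n_mags")
  if (cfg$degrader_noise < 0) stop("degrader_noise must be >= 0")
  if (abs(cfg$assoc_strength) > 1)
    stop("assoc_strength must lie in [-1, 1]")
  if (cfg$effect_size < 0) stop("effect_size must be >= 0")
  if (cfg$n_differential + cfg$n_associated > cfg$n_mags)
    stop("n_differential + n_associated must be <= n_mags")
  structure(cfg, class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("simulation_config (seed", x$seed, "):",
      x$n_mags, "MAGs /", x$n_panel, "panel strains /",
      x$n_categories, "categories;",
      length(x$group_names), "groups x", x$n_samples_per_group, "\n")
  invisible(x)
}

# Concentration used for panel members around the shared base: high,
# so panel gene-class profiles are "quite similar" to one another.
PANEL_CONCENTRATION <- 5000

#' Generate the reference-panel profiles
#'
#' Draws one smooth base gene-class distribution and samples each
#' panel strain as a small Dirichlet perturbation of it, emulating a
#' panel of fucoidan degraders whose category distributions are
#' closely similar. The draw is verified: if any pairwise JSD reaches
#' the classification threshold the whole panel is resampled (bounded
#' retries), so panel-internal divergences sit strictly inside the
#' decision region by construction.
#'
#' @param config a [simulation_config()].
#' @param threshold JSD bound the panel must satisfy internally.
#' @param max_retries resampling attempts before giving up.
#' @return List of `n_panel` [gene_class_profile()] objects named
#'   `panel01`, `panel02`, ...
#' @export
gen_panel_profiles <- function(config, threshold = 0.0558,
                               max_retries = 10) {
  stopifnot(inherits(config, "simulation_config"))
  cats <- sprintf("cat%03d", seq_len(config$n_categories))
  with_substream(config$seed, 1L, {
    for (attempt in seq_len(max_retries)) {
      base <- rdirichlet(1, rep(5, config$n_categories))[1, ]
      prof <- rdirichlet(config$n_panel, base * PANEL_CONCENTRATION)
      ok <- TRUE
      if (config$n_panel > 1) {
        for (i in seq_len(config$n_panel - 1))
          for (j in seq(i + 1, config$n_panel))
            if (jsd(prof[i, ], prof[j, ]) >= threshold) ok <- FALSE
      }
      if (ok) {
        return(lapply(seq_len(config$n_panel), function(i)
          gene_class_profile(sprintf("panel%02d", i), cats, prof[i, ],
                             n_genes = NA_integer_)))
      }
    }
    stop("panel similarity constraint not met after ", max_retries,
         " attempts; degenerate noise parameters")
  })
}

#' Generate MAG profiles with planted degraders
#'
#' The first `n_planted_degraders` positions (shuffled) are perturbed
#' copies of randomly chosen panel members -- genomes whose gene-class
#' distribution stays close to the degrader panel. Background MAGs are
#' drawn around an independent base distribution and sit far from the
#' panel. Ground truth records which MAG is which.
#'
#' @param config a [simulation_config()].
#' @param panel output of [gen_panel_profiles()].
#' @return List with `profiles` (list of [gene_class_profile()], ids
#'   `bin.1` ... `bin.n`) and `truth` (data.frame `genome_id`,
#'   `is_degrader`, `panel_source`).
#' @export
gen_mag_profiles <- function(config, panel) {
  stopifnot(inherits(config, "simulation_config"))
  cats <- panel[[1]]$categories
  k <- length(cats)
  with_substream(config$seed, 2L, {
    flags <- rep(FALSE, config$n_mags)
    flags[sample.int(config$n_mags, config$n_planted_degraders)] <- TRUE
    bg_base <- rdirichlet(1, rep(1, k))[1, ]
    source_id <- rep(NA_character_, config$n_mags)
    profiles <- vector("list", config$n_mags)
    for (i in seq_len(config$n_mags)) {
      if (flags[i]) {
        ref <- sample.int(length(panel), 1)
        source_id[i] <- panel[[ref]]$genome_id
        p <- if (config$degrader_noise == 0) {
          panel[[ref]]$probabilities
        } else {
          rdirichlet(1, panel[[ref]]$probabilities /
                       config$degrader_noise)[1, ]
        }
      } else {
        p <- rdirichlet(1, bg_base * 50 + 1e-8)[1, ]
      }
      profiles[[i]] <- gene_class_profile(paste0("bin.", i), cats, p,
                                          n_genes = NA_integer_)
    }
    list(profiles = profiles,
         truth = data.frame(genome_id = paste0("bin.", seq_len(config$n_mags)),
                            is_degrader = flags,
                            panel_source = source_id,
                            stringsAsFactors = FALSE))
  })
}

#' Generate abundance and bodyweight tables with planted effects
#'
#' Builds a sample x MAG relative-abundance table by softmax of
#' per-feature log-abundances: baseline + planted group shift
#' (differential features) + planted bodyweight coefficient
#' (associated features) + Gaussian noise. Bodyweight is group mean +
#' Gaussian noise with means ordered Model > SjC > Control, the
#' high-fat-diet obesity pattern; only the ordering matters
#' downstream. A multinomial count table at the configured depth is
#' returned alongside for the richness estimators.
#'
#' Setting `effect_size = 0` and `assoc_strength = 0` gives an exact
#' null: groups and bodyweight carry no information about any feature.
#' At `assoc_strength = 1` with `noise_sd = 0`, planted associated
#' features are strictly monotone in bodyweight even after closure
#' (the softmax derivative keeps the planted sign).
#'
#' @param config a [simulation_config()].
#' @param truth optional ground truth from [gen_mag_profiles()]; used
#'   only for feature ids.
#' @return List: `abundance` (rows sum to 1), `counts` (integer
#'   matrix, same shape), `phenotype` (data.frame `sample_id`,
#'   `bodyweight`, `group`), `truth` (data.frame `feature_id`,
#'   `is_differential`, `is_associated`, `assoc_sign`).
#' @export
gen_abundance_and_phenotype <- function(config, truth = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  n_feat <- config$n_mags
  feat_ids <- if (!is.null(truth)) truth$genome_id else
    paste0("bin.", seq_len(n_feat))
  n_g <- length(config$group_names)
  n <- n_g * config$n_samples_per_group
  groups <- factor(rep(config$group_names, each = config$n_samples_per_group),
                   levels = config$group_names)
  sample_ids <- paste0(as.character(groups), "_",
                       rep(seq_len(config$n_samples_per_group), times = n_g))
  with_substream(config$seed, 3L, {
    # bodyweight: Model heaviest, SjC partially restored, Control lean
    means <- c(32, 45, 38)[seq_len(n_g)]
    w <- stats::rnorm(n, mean = means[as.integer(groups)], sd = 1.5)

    pick <- sample.int(n_feat, config$n_differential + config$n_associated)
    diff_idx <- pick[seq_len(config$n_differential)]
    assoc_idx <- pick[config$n_differential + seq_len(config$n_associated)]
    is_diff <- seq_len(n_feat) %in% diff_idx
    is_assoc <- seq_len(n_feat) %in% assoc_idx
    assoc_sign <- integer(n_feat)
    assoc_sign[assoc_idx] <- sample(c(-1L, 1L), config$n_associated,
                                    replace = TRUE)
    diff_sign <- integer(n_feat)
    diff_sign[diff_idx] <- sample(c(-1L, 1L), config$n_differential,
                                  replace = TRUE)

    mu <- stats::rnorm(n_feat, 0, 1)
    eta <- matrix(mu, n, n_feat, byrow = TRUE)
    # group shift loads on the Model (high-fat) group, the Fig-2/3 shape
    model_ind <- as.numeric(groups == config$group_names[min(2, n_g)])
    eta <- eta + outer(model_ind, diff_sign * config$effect_size)
    wz <- (w - mean(w)) / stats::sd(w)
    eta <- eta + outer(wz, assoc_sign * abs(config$assoc_strength))
    eta <- eta + matrix(stats::rnorm(n * n_feat, 0, config$noise_sd),
                        n, n_feat)
    x <- exp(eta)
    x <- sweep(x, 1, rowSums(x), "/")
    dimnames(x) <- list(sample_ids, feat_ids)
    counts <- t(apply(x, 1, function(p)
      stats::rmultinom(1, size = config$depth, prob = p)[, 1]))
    dimnames(counts) <- dimnames(x)
    list(abundance = x, counts = counts,
         phenotype = data.frame(sample_id = sample_ids, bodyweight = w,
                                group = as.character(groups),
                                stringsAsFactors = FALSE),
         truth = data.frame(feature_id = feat_ids,
                            is_differential = is_diff,
                            is_associated = is_assoc,
                            assoc_sign = assoc_sign,
                            stringsAsFactors = FALSE))
  })
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_dna <- function(seq, positions) {
  v <- strsplit(seq, "")[[1]]
  for (p in positions) v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
  paste(v, collapse = "")
}

#' Generate a 16S-vs-MAG-gene sequence fixture
#'
#' Plants five query/subject pairs that exercise the link filter
#' (alignment length > 300 bp AND identity > 99%) on every side of
#' both cutoffs: a 430 bp exact embedded copy (pass), a 310 bp copy
#' with 2 mismatches (pass, identity 99.35), a 66 bp exact copy
#' (length fail), a 400 bp copy with 8 mismatches (identity fail,
#' 98.0), and a 100 bp copy with 3 mismatches (both fail). Each 16S
#' query is embedded in a distinct MAG gene with random flanks;
#' mismatches are kept away from segment ends so the local alignment
#' spans the full planted segment.
#'
#' @param config a [simulation_config()].
#' @return List: `queries` and `subjects` (named character vectors of
#'   DNA), `expected` (data.frame `repseq_id`, `mag_id`,
#'   `expected_identity`, `expected_length`, `expected_link`),
#'   `taxonomy` (data.frame `repseq_id`, `taxonomy`).
#' @export
gen_sequence_fixture <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_substream(config$seed, 4L, {
    cases <- data.frame(
      repseq_id = paste0("repseq", 1:5),
      mag_id = paste0("bin.", 1:5),
      seg_len = c(430L, 310L, 66L, 400L, 100L),
      n_mismatch = c(0L, 2L, 0L, 8L, 3L),
      stringsAsFactors = FALSE)
    cases$expected_identity <-
      100 * (cases$seg_len - cases$n_mismatch) / cases$seg_len
    cases$expected_length <- cases$seg_len
    cases$expected_link <- cases$expected_length > 300 &
      cases$expected_identity > 99
    queries <- character(5)
    subjects <- character(5)
    for (i in 1:5) {
      q <- random_dna(cases$seg_len[i])
      seg <- q
      if (cases$n_mismatch[i] > 0) {
        # interior positions, >= 20 bp from either end, well separated
        pos <- round(seq(25, cases$seg_len[i] - 25,
                         length.out = cases$n_mismatch[i]))
        seg <- mutate_dna(q, pos)
      }
      queries[i] <- q
      subjects[i] <- paste0(random_dna(150), seg, random_dna(150))
    }
    names(queries) <- cases$repseq_id
    names(subjects) <- paste0(cases$mag_id, "_00001")
    taxonomy <- data.frame(
      repseq_id = cases$repseq_id,
      taxonomy = c("g_Akkermansia", "g_Muribaculum", "g_Desulfovibrio",
                   "f_Lachnospiraceae", "g_Alistipes"),
      stringsAsFactors = FALSE)
    list(queries = queries, subjects = subjects,
         expected = cases[c("repseq_id", "mag_id", "expected_identity",
                            "expected_length", "expected_link")],
         taxonomy = taxonomy)
  })
}

#' Write a complete synthetic dataset to a directory
#'
#' Runs all generators and writes every pipeline input as plain text:
#' panel and MAG profile TSVs, abundance / count / phenotype /
#' ground-truth TSVs, query and subject FASTA files, a taxonomy map,
#' and the configuration as YAML.
#'
#' @param config a [simulation_config()].
#' @param outdir output directory (created if needed).
#' @return Invisibly, a named list of the written file paths.
#' @export
simulate_dataset <- function(config, outdir) {
  stopifnot(inherits(config, "simulation_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  panel <- gen_panel_profiles(config)
  mags <- gen_mag_profiles(config, panel)
  ab <- gen_abundance_and_phenotype(config, mags$truth)
  fx <- gen_sequence_fixture(config)
  paths <- list(
    config = file.path(outdir, "config.yaml"),
    panel = file.path(outdir, "panel_profiles.tsv"),
    mags = file.path(outdir, "mag_profiles.tsv"),
    abundance = file.path(outdir, "abundance.tsv"),
    counts = file.path(outdir, "counts.tsv"),
    phenotype = file.path(outdir, "phenotype.tsv"),
    truth_mags = file.path(outdir, "truth_degraders.tsv"),
    truth_features = file.path(outdir, "truth_features.tsv"),
    queries = file.path(outdir, "repseqs.fasta"),
    subjects = file.path(outdir, "mag_genes.fasta"),
    taxonomy = file.path(outdir, "taxonomy.tsv"),
    expected_links = file.path(outdir, "truth_links.tsv"))
  yaml::write_yaml(unclass(config), paths$config)
  write_profiles(panel, paths$panel)
  write_profiles(mags$profiles, paths$mags)
  write_matrix_tsv(ab$abundance, paths$abundance)
  write_matrix_tsv(ab$counts, paths$counts)
  utils::write.table(ab$phenotype, paths$phenotype, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(mags$truth, paths$truth_mags, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(ab$truth, paths$truth_features, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(fx$queries),
                              paths$queries)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(fx$subjects),
                              paths$subjects)
  utils::write.table(fx$taxonomy, paths$taxonomy, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(fx$expected, paths$expected_links, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}

write_matrix_tsv <- function(m, path) {
  d <- data.frame(sample_id = rownames(m), m, check.names = FALSE,
                  stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_matrix_tsv <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE,
                         stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  m
}
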