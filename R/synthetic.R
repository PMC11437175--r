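#' Specification of a synthetic metagenomic community
#'
#' Describes the fixture community used throughout the test suite: a small
#' taxonomy (families > genera > species under a single domain/phylum/class/
#' order chain), species-specific base composition drawn hierarchically from
#' Dirichlet distributions (so sibling species are more similar than distant
#' ones), and log-normal per-sample species abundances with log-normal
#' per-contig noise.
#'
#' @param n_species Total species (distributed round-robin over genera).
#' @param n_genera Genera (distributed round-robin over families).
#' @param n_families Families (all under one order).
#' @param n_samples Number of abundance samples.
#' @param contigs_per_species Contigs simulated per species.
#' @param contig_length_range Min/max contig length in bp.
#' @param composition_alpha Dirichlet concentration of family-level base
#'   compositions around uniform; smaller = more divergent.
#' @param hierarchy_concentration Dirichlet concentration tying genus
#'   compositions to their family and species to their genus; larger = more
#'   similar siblings.
#' @param abundance_sigma Log-sd of per-sample species abundance around the
#'   species' base abundance.
#' @param contig_depth_sigma Log-sd of per-contig depth noise.
#' @param seed Integer seed; identical seeds give byte-identical communities.
#' @return List of class `community_spec`.
#' @export
community_spec <- function(n_species = 8, n_genera = 2, n_families = 2,
                           n_samples = 3, contigs_per_species = 50,
                           contig_length_range = c(2000, 6000),
                           composition_alpha = 8,
                           hierarchy_concentration = 150,
                           abundance_sigma = 1,
                           contig_depth_sigma = 0.25,
                           seed = 1L) {
  stopifnot(n_species >= 1, n_genera >= 1, n_families >= 1,
            n_genera >= n_families, n_species >= n_genera,
            n_samples >= 1, contigs_per_species >= 1,
            length(contig_length_range) == 2,
            contig_length_range[1] >= 4,
            diff(contig_length_range) >= 0)
  structure(as.list(environment()), class = "community_spec")
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

#' Generate a synthetic community
#'
#' Draws the taxonomy, species base compositions, contig sequences (i.i.d.
#' bases from the species composition), and a contigs x samples depth table
#' (species log-normal abundance per sample times log-normal contig noise).
#' Deterministic for a given spec seed.
#'
#' @param spec A [community_spec()].
#' @return List of class `community`: `sequences` (named
#'   [Biostrings::DNAStringSet]), `depths` (matrix, contigs x samples),
#'   `truth` (an `annotation_set` of full 7-rank lineages), `species_of`
#'   (named character vector: contig id -> species path), and
#'   `compositions` (species base-frequency matrix).
#' @export
generate_community <- function(spec) {
  stopifnot(inherits(spec, "community_spec"))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(spec$seed)

  family_of_genus <- rep(seq_len(spec$n_families),
                         length.out = spec$n_genera)
  genus_of_species <- rep(seq_len(spec$n_genera),
                          length.out = spec$n_species)
  lineage_of_species <- lapply(seq_len(spec$n_species), function(s) {
    g <- genus_of_species[s]
    f <- family_of_genus[g]
    c("Bacteria", "Phylum1", "Class1", "Order1",
      sprintf("Family%d", f), sprintf("Genus%d", g),
      sprintf("Species%d", s))
  })

  fam_comp <- t(vapply(seq_len(spec$n_families), function(f)
    rdirichlet1(rep(spec$composition_alpha, 4)), numeric(4)))
  gen_comp <- t(vapply(seq_len(spec$n_genera), function(g)
    rdirichlet1(spec$hierarchy_concentration * fam_comp[family_of_genus[g], ]),
    numeric(4)))
  sp_comp <- t(vapply(seq_len(spec$n_species), function(s)
    rdirichlet1(spec$hierarchy_concentration * gen_comp[genus_of_species[s], ]),
    numeric(4)))
  colnames(sp_comp) <- c("A", "C", "G", "T")

  n_contigs <- spec$n_species * spec$contigs_per_species
  contig_sp <- rep(seq_len(spec$n_species), each = spec$contigs_per_species)
  contig_ids <- sprintf("contig_%04d", seq_len(n_contigs))
  lens <- sample(spec$contig_length_range[1]:spec$contig_length_range[2],
                 n_contigs, replace = TRUE)
  seqs <- vapply(seq_len(n_contigs), function(i) {
    paste(sample(c("A", "C", "G", "T"), lens[i], replace = TRUE,
                 prob = sp_comp[contig_sp[i], ]), collapse = "")
  }, character(1))
  sequences <- Biostrings::DNAStringSet(stats::setNames(seqs, contig_ids))

  base_ab <- exp(stats::rnorm(spec$n_species, 0, 1))
  sp_depth <- base_ab * matrix(
    exp(stats::rnorm(spec$n_species * spec$n_samples, 0,
                     spec$abundance_sigma)),
    spec$n_species, spec$n_samples)
  depths <- 10 * sp_depth[contig_sp, , drop = FALSE] *
    matrix(exp(stats::rnorm(n_contigs * spec$n_samples, 0,
                            spec$contig_depth_sigma)),
           n_contigs, spec$n_samples)
  dimnames(depths) <- list(contig_ids,
                           sprintf("sample%d", seq_len(spec$n_samples)))

  truth <- annotation_set(
    stats::setNames(lineage_of_species[contig_sp], contig_ids),
    source_name = "ground_truth")
  species_of <- stats::setNames(
    vapply(lineage_of_species[contig_sp], paste, character(1),
           collapse = ";"),
    contig_ids)
  structure(list(sequences = sequences, depths = depths, truth = truth,
                 species_of = species_of, compositions = sp_comp,
                 spec = spec),
            class = "community")
}

#' Write a community to disk
#'
#' Emits the exact dialects consumed by the readers: `contigs.fna`,
#' `depths.tsv` and `truth.tsv` under `dir`.
#' @param community A `community`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the three paths.
#' @export
write_community <- function(community, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(dir, "contigs.fna")
  Biostrings::writeXStringSet(community$sequences, fasta)
  depths <- file.path(dir, "depths.tsv")
  write_depths(community$depths, depths)
  truth <- file.path(dir, "truth.tsv")
  write_annotations(community$truth, truth)
  c(fasta = fasta, depths = depths, truth = truth)
}

#' Corrupt a truth annotation set into imperfect classifier output
#'
#' Emulates the error modes of real classifiers, applied independently per
#' contig: with probability `drop_rate` the lineage is emptied; with
#' `truncate_rate` it is cut at a uniformly random rank above its deepest;
#' with `error_rate` the species label is replaced by a different species,
#' preferring a sibling within the same genus with probability 0.5 (matching
#' the observed confusion structure between related taxa). Deterministic per
#' seed.
#'
#' @param truth An `annotation_set` of full lineages.
#' @param tree Optional `taxtree` for sibling lookup; defaults to the tree
#'   built from `truth`.
#' @param error_rate,drop_rate,truncate_rate Rates in `[0, 1]` summing to at
#'   most 1.
#' @param seed Integer seed.
#' @return A corrupted `annotation_set`.
#' @export
corrupt_annotations <- function(truth, tree = NULL, error_rate = 0,
                                drop_rate = 0, truncate_rate = 0, seed = 1L) {
  stopifnot(error_rate >= 0, drop_rate >= 0, truncate_rate >= 0,
            error_rate + drop_rate + truncate_rate <= 1)
  if (is.null(tree)) tree <- build_taxtree(truth)
  sp_nodes <- tree$nodes[tree$nodes$rank == 7, , drop = FALSE]
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  lineages <- truth$lineages
  u <- stats::runif(length(lineages))
  for (i in seq_along(lineages)) {
    lab <- lineages[[i]]
    if (length(lab) == 0) next
    if (u[i] < drop_rate) {
      lineages[[i]] <- character(0)
    } else if (u[i] < drop_rate + truncate_rate) {
      if (length(lab) > 1)
        lineages[[i]] <- lab[seq_len(sample.int(length(lab) - 1, 1))]
    } else if (u[i] < drop_rate + truncate_rate + error_rate) {
      if (length(lab) < 7) next          # only species labels are perturbed
      genus_path <- paste(lab[1:6], collapse = ";")
      sp_path <- paste(lab, collapse = ";")
      siblings <- sp_nodes$path[startsWith(sp_nodes$path,
                                           paste0(genus_path, ";")) &
                                  sp_nodes$path != sp_path]
      others <- sp_nodes$path[sp_nodes$path != sp_path]
      pool <- if (length(siblings) > 0 && stats::runif(1) < 0.5) siblings
        else others
      if (length(pool) == 0) next        # single-species tree: nothing to swap
      new_path <- pool[sample.int(length(pool), 1)]
      lineages[[i]] <- strsplit(new_path, ";", fixed = TRUE)[[1]]
    }
  }
  annotation_set(lineages,
                 source_name = paste0(truth$source_name, "_corrupted"))
}
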