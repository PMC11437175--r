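# Shared fixtures: all test data is generated in code.

# Small network for unit tests where only mechanics are under test.
fast_config <- function(seed = 1L, ...) {
  args <- utils::modifyList(list(hidden_sizes = c(32, 32), epochs = 15,
                                 batch_size = 128, seed = seed), list(...))
  do.call(network_config, args)
}

# Fixture-scale training regime for the full synthetic community.
fixture_config <- function(seed = 1L, ...) {
  args <- utils::modifyList(list(epochs = 50, batch_size = 256, seed = seed),
                            list(...))
  do.call(network_config, args)
}

# The default synthetic community (8 species / 2 genera / 2 families,
# 3 samples, 50 contigs per species, 2-6 kb contigs).
default_community <- function(seed = 1L, ...) {
  generate_community(community_spec(seed = seed, ...))
}

# A deliberately well-separated two-species community: maximally divergent
# base compositions and distinct abundance profiles.
two_species_community <- function(seed = 1L, contigs_per_species = 100) {
  generate_community(community_spec(
    n_species = 2, n_genera = 2, n_families = 2, n_samples = 3,
    contigs_per_species = contigs_per_species,
    composition_alpha = 2, hierarchy_concentration = 500,
    abundance_sigma = 1.5, seed = seed))
}

# Tiny hand-built tree {A;B;C, A;B;D}.
tiny_tree <- function() {
  build_taxtree(annotation_set(list(x = c("A", "B", "C"),
                                    y = c("A", "B", "D"))))
}

# Species-level full-path label per contig from an annotation set.
species_path_of <- function(annotations) {
  vapply(annotations$lineages, function(lab)
    if (length(lab) == 7) paste(lab, collapse = ";") else NA_character_,
    character(1))
}

# Random taxonomy tree with at most max_leaves leaves, for property tests.
random_tree <- function(max_leaves = 50) {
  n_lin <- sample.int(max_leaves, 1)
  lineages <- lapply(seq_len(n_lin), function(i) {
    depth <- sample.int(7, 1)
    labs <- character(depth)
    for (d in seq_len(depth)) labs[d] <- sprintf("r%d_%d", d, sample.int(3, 1))
    labs
  })
  names(lineages) <- paste0("c", seq_len(n_lin))
  build_taxtree(annotation_set(lineages))
}
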