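# Shared builders for test fixtures. Everything is generated in code.

make_gene_records <- function(n, family = "A1", species = "FOC",
                              transcript = rep("", n)) {
  tibble::tibble(
    gene_id = sprintf("G%03d", seq_len(n)),
    species_id = species,
    family_id = family,
    transcript_id = transcript,
    truncated = FALSE,
    signal_peptide = FALSE,
    topology = "unknown"
  )
}

make_meta <- function(n_species = 4) {
  tibble::tibble(
    species_id = c("FOC", sprintf("SP%02d", seq_len(n_species - 1))),
    taxon_group = paste0("G", rep_len(1:2, n_species)),
    hematophagous = rep_len(c(TRUE, FALSE), n_species)
  )
}

write_counts_fixture <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  counts <- file.path(dir, "counts.tsv")
  meta <- file.path(dir, "meta.tsv")
  writeLines(c("family\tFOC\tSP01", "A1\t1\t1", "C2\t3\t0"), counts)
  writeLines(c("species_id\ttaxon_group\thematophagous",
               "FOC\tHemiptera\t1", "SP01\tDiptera\t0"), meta)
  list(counts = counts, meta = meta)
}

# Exact two-sided Mann-Whitney p by literal enumeration of all label
# assignments (independent oracle for the dynamic-programming implementation).
brute_force_mwu_p <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  m_obs <- min(u_obs, n1 * length(b) - u_obs)
  sets <- utils::combn(length(pooled), n1)
  ms <- apply(sets, 2, function(idx) {
    u <- sum(r[idx]) - n1 * (n1 + 1) / 2
    min(u, n1 * length(b) - u)
  })
  mean(ms <= m_obs + 1e-9)
}

# Exhaustive maximal monospecific clade: check every node's tip set.
brute_force_max_clade <- function(tree, prefix) {
  n_tip <- length(tree$tip.label)
  focal <- startsWith(tree$tip.label, prefix)
  best <- if (any(focal)) 1L else 0L
  pp <- ape::prop.part(tree)
  for (i in seq_len(tree$Nnode)) {
    tips <- tree$tip.label[pp[[i]]]
    if (all(startsWith(tips, prefix))) best <- max(best, length(tips))
  }
  best
}

# A mock archetype-length sequence with the mapped features planted, for
# self-alignment feature reports.
mock_archetype_sequence <- function(map, archetype) {
  f <- map$features[[archetype]]
  len <- max(f$catalytic_positions, f$cysteine_positions,
             f$proline_loop_window, f$glyc_triad_positions) + 5
  q <- rep("A", len)
  q[f$catalytic_positions] <- "D"
  q[f$cysteine_positions] <- "C"
  q[f$first_proline] <- "P"
  q[f$proline_loop_window] <- "P"
  q[f$glyc_triad_positions] <- f$glyc_triad_residues
  paste(q, collapse = "")
}

# Sequence over the synthetic subsite coordinates carrying one archetype's
# residues everywhere.
subsite_query <- function(map, archetype) {
  ss <- map$subsites
  q <- rep("A", max(ss$coord))
  q[ss$coord] <- ss[[archetype]]
  paste(q, collapse = "")
}

# Deterministic ladder join of Newick units.
ladder_join <- function(units) {
  Reduce(function(a, b) paste0("(", a, ",", b, ")"), units)
}

# Tree with `clade` as one monophyletic block; every stray focal tip is
# paired with an outgroup tip so the planted clade stays maximal.
build_membership_newick <- function(clade, stray, outgroups) {
  stopifnot(length(outgroups) >= length(stray) + 1)
  pairs <- mapply(function(f, o) paste0("(", f, ",", o, ")"),
                  stray, outgroups[seq_along(stray)])
  rest <- outgroups[-seq_along(stray)]
  if (length(stray) == 0) rest <- outgroups
  paste0(ladder_join(c(ladder_join(clade), pairs, rest)), ";")
}

write_pdb_fixture <- function(lines, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "toy.pdb")
  writeLines(lines, path)
  path
}
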