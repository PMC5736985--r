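# Seeded generators with planted ground truth for every pipeline input:
# overdispersed count matrices with planted expansions, trees with planted
# maximal monospecific clades, contig tables realising each neighborhood
# rule, Dirichlet-multinomial alignments with entropy-controlled columns,
# and toy structures with closed-form exposure. Every generator is a pure
# function of its parameters and `seed`.

#' Simulate a species x family count matrix with planted expansions
#'
#' Counts are negative-binomial per family (heavy right tail, as real
#' peptidase family sizes are), with species metadata assigning roughly a
#' third of species as hematophagous across `n_groups` taxon groups. Planted
#' expansions come in two kinds: `target = "focal"` sets the focal species'
#' count to `ceiling(fold * baseline_mean)` — the effect is planted exactly,
#' so recovery rates measure the screen rather than sampling noise in the
#' plant — and `target = "hema"` multiplies the negative-binomial mean by
#' `fold` in every hematophagous species.
#'
#' @param n_species,n_families panel dimensions (`n_species >= 3`).
#' @param baseline_mean negative-binomial mean per family (default 3, the
#'   scale of a typical peptidase family).
#' @param dispersion negative-binomial size parameter (default 1.5; smaller
#'   is more overdispersed).
#' @param planted tibble/data frame with columns `family` (index or name),
#'   `target` (`"focal"`/`"hema"`), `fold` (>= 1), or `NULL`.
#' @param seed integer seed.
#' @param n_groups number of taxon groups (default 4).
#' @return list with `counts` (long tibble as from [read_count_matrix()];
#'   the focal species is `"FOC"`) and `truth` (the planted table).
#' @export
simulate_count_matrix <- function(n_species = 19, n_families = 30,
                                  baseline_mean = 3, dispersion = 1.5,
                                  planted = NULL, seed = 1, n_groups = 4) {
  if (n_species < 3) abort("need at least 3 species")
  if (!is.null(planted) && any(planted$fold < 1)) abort("fold must be >= 1")
  withr::with_seed(seed, {
    species <- c("FOC", sprintf("SP%02d", seq_len(n_species - 1)))
    groups <- paste0("G", rep_len(seq_len(n_groups), n_species))
    hema <- rep_len(c(TRUE, FALSE, FALSE), n_species)
    hema[1] <- TRUE   # the focal species is a blood feeder
    meta <- tibble(species_id = species, taxon_group = groups,
                   hematophagous = hema)
    fams <- sprintf("F%03d", seq_len(n_families))
    truth <- if (is.null(planted)) {
      tibble(family = character(0), target = character(0), fold = numeric(0))
    } else {
      tibble(
        family = if (is.numeric(planted$family)) fams[planted$family]
                 else as.character(planted$family),
        target = planted$target, fold = planted$fold
      )
    }
    counts <- matrix(
      rnbinom(n_families * n_species, size = dispersion, mu = baseline_mean),
      nrow = n_families
    )
    for (k in seq_len(nrow(truth))) {
      fi <- match(truth$family[k], fams)
      if (truth$target[k] == "focal") {
        counts[fi, 1] <- as.integer(ceiling(truth$fold[k] * baseline_mean))
      } else {
        counts[fi, meta$hematophagous] <- rnbinom(
          sum(meta$hematophagous), size = dispersion,
          mu = truth$fold[k] * baseline_mean)
      }
    }
    tbl <- tibble(
      family = factor(rep(fams, each = n_species), levels = fams),
      species_id = factor(rep(species, times = n_families), levels = species),
      count = as.integer(t(counts))
    ) |>
      left_join(meta, by = "species_id")
    tbl$species_id <- factor(as.character(tbl$species_id), levels = species)
    list(counts = tbl, truth = truth)
  })
}

# join a list of subtree Newick fragments into one random binary topology
join_random <- function(units) {
  while (length(units) > 1) {
    i <- sample.int(length(units), 2)
    merged <- paste0("(", units[[i[1]]], ":", round(runif(1, 0.1, 1), 3),
                     ",", units[[i[2]]], ":", round(runif(1, 0.1, 1), 3), ")")
    units <- c(units[-i], merged)
  }
  units[[1]]
}

#' Simulate a tree with a planted maximal monospecific clade
#'
#' Builds a random binary topology in which exactly `clade_size` of the
#' `n_focal` focal tips (labels `FOC...`) form a monospecific clade, and no
#' larger one exists: every remaining focal tip is attached as sister to a
#' non-focal tip (labels `OTH...`), so any clade strictly containing the
#' planted one, or two stray focal tips, also contains a non-focal tip.
#'
#' @param n_focal number of focal tips.
#' @param n_other number of non-focal tips; must be at least
#'   `n_focal - clade_size`, and at least 1 when the clade is not the whole
#'   tree.
#' @param clade_size planted clade size (`1 <= clade_size <= n_focal`).
#' @param seed integer seed.
#' @return list with `newick` (string), `tree` (parsed) and `truth`
#'   (`clade_size`, `clade_tips`).
#' @export
simulate_tree_with_clade <- function(n_focal, n_other, clade_size, seed = 1) {
  if (clade_size < 1 || clade_size > n_focal) {
    abort("clade_size must be between 1 and n_focal")
  }
  n_stray <- n_focal - clade_size
  if (n_other < n_stray) {
    abort("need n_other >= n_focal - clade_size to keep the planted clade maximal")
  }
  if (n_stray > 0 && n_other == 0) abort("stray focal tips need non-focal partners")
  withr::with_seed(seed, {
    focal <- sprintf("FOC%03d", seq_len(n_focal))
    other <- if (n_other > 0) sprintf("OTH%03d", seq_len(n_other)) else character(0)
    clade_tips <- focal[seq_len(clade_size)]
    stray <- setdiff(focal, clade_tips)
    clade_nwk <- join_random(as.list(clade_tips))
    pair_nwk <- map2(stray, other[seq_along(stray)], function(f, o) {
      paste0("(", f, ":", round(runif(1, 0.1, 1), 3), ",", o, ":",
             round(runif(1, 0.1, 1), 3), ")")
    })
    loose <- as.list(other[setdiff(seq_along(other), seq_along(stray))])
    units <- c(list(clade_nwk), pair_nwk, loose)
    if (length(units) == 1) {
      nwk <- paste0(units[[1]], ";")
    } else {
      # keep the planted clade a child of the root only alongside non-focal
      # context; join_random over all units guarantees its sister subtree
      # contains at least one non-focal tip
      nwk <- paste0(join_random(units), ";")
    }
    list(newick = nwk, tree = parse_newick(nwk),
         truth = list(clade_size = clade_size, clade_tips = clade_tips))
  })
}

#' Simulate a contig gene table with planted neighborhood verdicts
#'
#' Each planted case realises one branch of the neighborhood rule cascade:
#' `"lone"` (candidate alone on its contig, inconclusive), `"genuine"`
#' (metazoan neighbor), `"contamination"` (microbial neighbors, no introns)
#' and `"conflict"` (microbial neighbors plus introns). Filler contigs carry
#' ordinary metazoan genes.
#'
#' @param planted character vector over
#'   `c("lone", "genuine", "contamination", "conflict")`.
#' @param n_filler number of extra non-candidate metazoan genes.
#' @param seed integer seed.
#' @return list with `genes` (contig table) and `truth` (tibble `gene_id`,
#'   `planted`, `expected_verdict`).
#' @export
simulate_contigs <- function(planted = c("lone", "genuine", "contamination",
                                         "conflict"),
                             n_filler = 6, seed = 1) {
  kinds <- c("lone", "genuine", "contamination", "conflict")
  if (!all(planted %in% kinds)) {
    abort(paste0("planted kinds must be among: ", paste(kinds, collapse = ", ")))
  }
  withr::with_seed(seed, {
    rows <- list(); truth <- list()
    for (i in seq_along(planted)) {
      kind <- planted[i]
      contig <- sprintf("ctg%03d", i)
      cand <- sprintf("CAND%03d", i)
      introns <- if (kind == "conflict") sample(1:3, 1) else 0L
      rows[[length(rows) + 1]] <- tibble(
        gene_id = cand, contig_id = contig, order_index = 2L,
        best_hit_taxon = sample(c("bacteria", "virus"), 1),
        intron_count = as.integer(introns), is_candidate = TRUE,
        family_id = sample(c("M74", "N6", "S24", "S29"), 1)
      )
      if (kind != "lone") {
        nb_taxon <- switch(kind, genuine = "metazoa",
                           contamination = "bacteria", conflict = "bacteria")
        for (pos in c(1L, 3L)) {
          rows[[length(rows) + 1]] <- tibble(
            gene_id = sprintf("NB%03d_%d", i, pos), contig_id = contig,
            order_index = pos, best_hit_taxon = nb_taxon,
            intron_count = sample(0:4, 1), is_candidate = FALSE,
            family_id = NA_character_
          )
        }
      }
      truth[[i]] <- tibble(
        gene_id = cand, planted = kind,
        expected_verdict = switch(kind, lone = "inconclusive",
                                  genuine = "genuine_insertion",
                                  contamination = "contamination_suspect",
                                  conflict = "inconclusive")
      )
    }
    if (n_filler > 0) {
      rows[[length(rows) + 1]] <- tibble(
        gene_id = sprintf("FILL%03d", seq_len(n_filler)),
        contig_id = sprintf("ctgF%02d", seq_len(n_filler)),
        order_index = 1L, best_hit_taxon = "metazoa",
        intron_count = as.integer(sample(0:6, n_filler, replace = TRUE)),
        is_candidate = FALSE, family_id = NA_character_
      )
    }
    list(genes = validate_contig_genes(bind_rows(rows)),
         truth = bind_rows(truth))
  })
}

#' Simulate an alignment with entropy-controlled columns
#'
#' Every column draws residue frequencies from a symmetric Dirichlet over
#' the 20 amino acids and then samples `n_rows` residues from them.
#' Columns listed in `high_entropy_cols` use `concentration_high`
#' (near-uniform frequencies, entropy near `log2(20)`); all others use
#' `concentration_low` (one residue dominates, entropy near 0).
#'
#' @param n_rows,n_cols alignment dimensions.
#' @param high_entropy_cols integer positions of the planted variable
#'   columns.
#' @param concentration_low,concentration_high Dirichlet concentration per
#'   symbol (defaults 0.05 and 10).
#' @param seed integer seed.
#' @return list with `alignment` (named character vector) and `truth`
#'   (`high_entropy_cols`).
#' @export
simulate_alignment <- function(n_rows = 50, n_cols = 40,
                               high_entropy_cols = integer(0),
                               concentration_low = 0.05,
                               concentration_high = 10, seed = 1) {
  if (any(high_entropy_cols < 1 | high_entropy_cols > n_cols)) {
    abort("high_entropy_cols out of range")
  }
  withr::with_seed(seed, {
    mat <- matrix("", nrow = n_rows, ncol = n_cols)
    for (j in seq_len(n_cols)) {
      alpha <- if (j %in% high_entropy_cols) concentration_high
               else concentration_low
      w <- rgamma(20, shape = alpha, rate = 1)
      if (sum(w) == 0) w[sample.int(20, 1)] <- 1
      mat[, j] <- sample(AA20, n_rows, replace = TRUE, prob = w / sum(w))
    }
    aln <- setNames(apply(mat, 1, paste, collapse = ""),
                    sprintf("row%03d", seq_len(n_rows)))
    list(alignment = aln, truth = list(high_entropy_cols = high_entropy_cols))
  })
}

pdb_atom_line <- function(serial, name, resname, chain, resno, x, y, z,
                          element) {
  sprintf("ATOM  %5d %-4s %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          serial, name, resname, chain, resno, x, y, z, element)
}

#' Generate toy PDB structures with closed-form exposure
#'
#' Three kinds: `"isolated_atoms"` (carbon atoms 100 A apart; each atom's
#' SASA equals the isolated-sphere area `4 * pi * (r + probe)^2`),
#' `"two_spheres"` (two carbons at distance `d`; SASA follows the analytic
#' two-sphere cap formula), and `"exposed_helix"` (a wide poly-lysine spiral
#' whose residues are all fully solvent-exposed).
#'
#' @param kind structure kind.
#' @param n number of atoms (`isolated_atoms`) or residues
#'   (`exposed_helix`).
#' @param d center distance in Angstrom for `two_spheres`.
#' @param seed integer seed (geometry is deterministic; the seed only feeds
#'   the jitter-free defaults and is kept for interface uniformity).
#' @return list with `pdb` (character vector of PDB lines) and `truth`
#'   (closed-form expectations).
#' @export
toy_structure <- function(kind = c("isolated_atoms", "two_spheres",
                                   "exposed_helix"),
                          n = 3, d = 2.0, seed = 1) {
  kind <- match.arg(kind)
  rc <- unname(VDW_RADII["C"])
  if (kind == "isolated_atoms") {
    lines <- map_chr(seq_len(n), function(i) {
      pdb_atom_line(i, "CA", "GLY", "A", i, (i - 1) * 100, 0, 0, "C")
    })
    truth <- list(atom_area = 4 * pi * (rc + 1.4)^2)
  } else if (kind == "two_spheres") {
    lines <- c(
      pdb_atom_line(1, "CA", "GLY", "A", 1, 0, 0, 0, "C"),
      pdb_atom_line(2, "CA", "GLY", "A", 2, d, 0, 0, "C")
    )
    truth <- list(total_area = two_sphere_sasa(rc, rc, d, probe = 1.4))
  } else {
    # wide spiral: consecutive residues ~15 A apart, side chain pointing out
    lines <- character(0); serial <- 0
    for (i in seq_len(n)) {
      ang <- 2 * pi * i / max(n, 8)
      cx <- 40 * cos(ang); cy <- 40 * sin(ang); cz <- 15 * i
      at <- list(
        c("N", -1.2, 0, 0), c("CA", 0, 0, 0), c("C", 1.2, 0, 0),
        c("O", 1.8, 1.0, 0), c("CB", 0, 1.5, 0.8), c("CG", 0, 3.0, 1.4),
        c("CD", 0, 4.5, 2.0), c("CE", 0, 6.0, 2.6), c("NZ", 0, 7.4, 3.2)
      )
      for (a in at) {
        serial <- serial + 1
        lines <- c(lines, pdb_atom_line(
          serial, a[[1]], "LYS", "A", i,
          cx + as.numeric(a[[2]]), cy + as.numeric(a[[3]]),
          cz + as.numeric(a[[4]]),
          substr(a[[1]], 1, 1)))
      }
    }
    truth <- list(n_lys = n, all_exposed = TRUE)
  }
  list(pdb = c(lines, "END"), truth = truth)
}

#' Analytic SASA of two intersecting probe-expanded spheres
#'
#' Closed-form accessible area of two atoms with van der Waals radii
#' `r1`, `r2` at center distance `d`: each expanded sphere (radius
#' `r + probe`) loses the spherical cap buried inside the other.
#'
#' @param r1,r2 van der Waals radii.
#' @param d center distance.
#' @param probe probe radius.
#' @return total accessible area in square Angstrom.
#' @export
two_sphere_sasa <- function(r1, r2, d, probe = 1.4) {
  e1 <- r1 + probe; e2 <- r2 + probe
  if (d >= e1 + e2) return(4 * pi * (e1^2 + e2^2))
  if (d <= abs(e1 - e2)) {
    # one sphere swallowed: only the larger contributes
    return(4 * pi * max(e1, e2)^2)
  }
  # cap heights from the intersection plane
  h1 <- e1 - (d^2 + e1^2 - e2^2) / (2 * d)
  h2 <- e2 - (d^2 + e2^2 - e1^2) / (2 * d)
  4 * pi * e1^2 - 2 * pi * e1 * h1 + 4 * pi * e2^2 - 2 * pi * e2 * h2
}
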