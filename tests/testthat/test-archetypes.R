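test_that("the shipped archetype map satisfies the schema", {
  map <- read_archetype_map()
  expect_s3_class(map, "pep_archetype_map")
  expect_setequal(names(map$features), c("pepsin", "renin", "cathepsinD"))
  for (f in map$features) {
    expect_length(f$catalytic_positions, 2)
    expect_length(f$cysteine_positions, 6)
    expect_length(f$proline_loop_window, 3)
    expect_length(f$glyc_triad_positions, 3)
  }
  sizes <- table(map$subsites$subsite)
  expect_equal(unname(sizes[c("S4", "S3", "S2", "S1", "S1p", "S2p")]),
               c(3L, 8L, 9L, 9L, 5L, 5L), ignore_attr = TRUE)
})

test_that("an archetype aligned to itself retains every mapped feature", {
  map <- read_archetype_map()
  for (arch in c("cathepsinD", "pepsin", "renin")) {
    q <- mock_archetype_sequence(map, arch)
    rep <- conserved_feature_report(q, map, archetype = arch)
    expect_equal(rep$catalytic_count, 2)
    expect_equal(rep$cysteines_present, 6)
    expect_equal(rep$proline_loop_count, 3)
    expect_equal(rep$glyc_triad_matches, 3)
  }
})

test_that("partial feature retention is counted, degenerate queries score zero", {
  map <- read_archetype_map()
  q <- strsplit(mock_archetype_sequence(map, "cathepsinD"), "")[[1]]
  # knock one loop proline out: two remain
  q[map$features$cathepsinD$proline_loop_window[2]] <- "G"
  rep <- conserved_feature_report(paste(q, collapse = ""), map, "cathepsinD")
  expect_equal(rep$proline_loop_count, 2)

  all_ala <- paste(rep("A", 400), collapse = "")
  rep0 <- conserved_feature_report(all_ala, map, "cathepsinD")
  expect_equal(rep0$catalytic_count, 0)
  expect_equal(rep0$cysteines_present, 0)
  expect_equal(rep0$proline_loop_count, 0)
  expect_length(rep0$sequon_positions[[1]], 0)

  expect_error(conserved_feature_report("ACD", map, "cathepsinD"),
               "shorter than the largest mapped position")
})

test_that("S4 residues Ala/Ser/Leu match cathepsin D at all three positions", {
  map <- read_archetype_map()
  q <- rep("-", max(map$subsites$coord))
  s4 <- map$subsites[map$subsites$subsite == "S4", ]
  q[s4$coord] <- c("A", "S", "L")
  prof <- subsite_profile(paste(q, collapse = ""), map)
  s4p <- prof[prof$subsite == "S4", ]
  expect_equal(s4p$sharing_class,
               c("cathepsinD_only", "all_three", "pepsin+cathepsinD"))
  m <- attr(prof, "matches")
  expect_equal(m$cathepsinD[m$subsite == "S4"], 3)
})

test_that("a query identical to one archetype matches it at every subsite position", {
  map <- read_archetype_map()
  for (arch in c("pepsin", "renin", "cathepsinD")) {
    prof <- subsite_profile(subsite_query(map, arch), map)
    expect_true(all(grepl(arch, prof$sharing_class, fixed = TRUE) |
                      prof$sharing_class == "all_three"))
    m <- attr(prof, "matches")
    expect_equal(sum(m[[arch]]), nrow(prof))
  }
})

test_that("sharing classes equal a set-membership oracle on random queries", {
  map <- read_archetype_map()
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  withr::with_seed(13, {
    for (rep in 1:10) {
      q <- sample(aa, max(map$subsites$coord), replace = TRUE)
      prof <- subsite_profile(paste(q, collapse = ""), map)
      for (i in seq_len(nrow(prof))) {
        members <- c("pepsin", "renin", "cathepsinD")[
          c(prof$pepsin[i], prof$renin[i], prof$cathepsinD[i]) ==
            prof$query_residue[i]]
        cls <- prof$sharing_class[i]
        if (length(members) == 0) expect_equal(cls, "novel")
        else if (length(members) == 3) expect_equal(cls, "all_three")
        else if (length(members) == 1) expect_equal(cls, paste0(members, "_only"))
        else expect_setequal(strsplit(cls, "+", fixed = TRUE)[[1]], members)
      }
    }
  })
})

test_that("the convenience aligner recovers archetype coordinates for a gapped query", {
  arch <- "MKWVTFISLLFLFSSAYSRGVFRRDAHKSEVAHRFKDLGEENFKALVLIA"
  query <- paste0(substr(arch, 1, 20), substr(arch, 31, 50))  # internal deletion
  aligned <- align_to_archetype(query, arch)
  expect_equal(nchar(aligned), nchar(arch))
  expect_equal(substr(aligned, 1, 20), substr(arch, 1, 20))
  expect_equal(gsub("-", "", aligned), query)
})
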