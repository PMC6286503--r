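make_rease <- function(name, type, site, species, evidence = "predicted") {
  rease_record(name, type, site, species, evidence)
}

test_that("experimental pairs join sites to genomes through shared hosts", {
  set.seed(101)
  g <- genome_record("P1", random_dna(500), host_species = "escherichia_coli")
  reases <- list(
    make_rease("EcoRI", "II", "GAATTC", "Escherichia coli", "proved"),
    make_rease("StySKI", "I", "GAATTC", "escherichia_coli"),
    make_rease("ShortSite", "II", "GA", "escherichia_coli", "proved"),
    make_rease("Foreign", "II", "GGATCC", "bacillus_subtilis", "proved")
  )
  pairs <- build_experimental_pairs(list(g), reases)
  expect_equal(nrow(pairs), 1L)        # GA too short, GGATCC wrong host
  expect_equal(pairs$site, "GAATTC")
  expect_equal(pairs$rm_types, "I,II") # union over matching enzymes
  expect_equal(pairs$evidence_best, "proved")
})

test_that("genomes without hosts and host-less enzyme tables give no pairs", {
  set.seed(102)
  g_nohost <- genome_record("P1", random_dna(500))
  g_hosted <- genome_record("P2", random_dna(500), host_species = "x_y")
  reases <- list(make_rease("R1", "II", "GAATTC", "other_species"))
  expect_equal(nrow(build_experimental_pairs(list(g_nohost), reases)), 0L)
  expect_equal(nrow(build_experimental_pairs(list(g_hosted), reases)), 0L)
})

test_that("control pairs are the exact Cartesian product", {
  pairs <- build_control_pairs(c("g1", "g2", "g3"), c("GAATTC", "GGATCC"),
                               "control1")
  expect_equal(nrow(pairs), 6L)
  expect_equal(unique(pairs$dataset), "control1")
  expect_true(all(pairs$rm_types == ""))
  # duplicated site text after trimming counts once
  pairs2 <- build_control_pairs(c("g1", "g2"), c("GATC", "NGATCN"))
  expect_equal(nrow(pairs2), 2L)
})

test_that("the experimental dataset is contained in control dataset 1", {
  set.seed(103)
  gs <- list(
    genome_record("P1", random_dna(400), host_species = "escherichia_coli"),
    genome_record("P2", random_dna(400), host_species = "bacillus_subtilis")
  )
  reases <- list(
    make_rease("EcoRI", "II", "GAATTC", "escherichia_coli", "proved"),
    make_rease("BsuRI", "II", "GGCC", "bacillus_subtilis", "proved")
  )
  exp_pairs <- build_experimental_pairs(gs, reases)
  catalog <- unique(vapply(reases, function(r) r$site$text, character(1)))
  ctl <- build_control_pairs(gs, catalog, "control1")
  expect_equal(nrow(ctl), 4L)
  key <- function(df) paste(df$genome_id, df$site)
  expect_true(all(key(exp_pairs) %in% key(ctl)))
})

test_that("effective R-M type folds orthodox subtypes and rejects junk", {
  expect_equal(assign_effective_type("IIG"), "IIG")
  expect_equal(assign_effective_type("IIM"), "IIM")
  expect_equal(assign_effective_type("IIP"), "II")
  expect_equal(assign_effective_type("IIS"), "II")
  expect_equal(assign_effective_type("I"), "I")
  expect_error(assign_effective_type("V"), "'V'")
})

test_that("dereplication groups near-identical genomes and keeps the longest", {
  set.seed(104)
  base <- random_dna(6000)
  gs <- list(
    genome_record("a_copy", base),
    genome_record("b_copy", base),                       # byte-identical
    genome_record("c_far", mutate_seq(base, 0.05, 1)),   # ~95% identity
    genome_record("d_near", mutate_seq(base, 0.002, 2))  # ~99.8% identity
  )
  out <- dereplicate(gs)
  reps <- vapply(representatives(out), `[[`, character(1), "genome_id")
  # {a_copy, b_copy, d_near} cluster (longest/lex-smallest wins), c_far alone
  expect_setequal(reps, c("a_copy", "c_far"))
  # permutation invariance
  out2 <- dereplicate(rev(gs))
  reps2 <- vapply(representatives(out2), `[[`, character(1), "genome_id")
  expect_setequal(reps2, reps)
})

test_that("dereplication keeps the longest genome per taxon first", {
  set.seed(105)
  gs <- list(
    genome_record("long", random_dna(4000), taxon_id = "t1"),
    genome_record("short", random_dna(3000), taxon_id = "t1"),
    genome_record("other", random_dna(3000), taxon_id = "t2")
  )
  reps <- vapply(representatives(dereplicate(gs)), `[[`, character(1),
                 "genome_id")
  expect_setequal(reps, c("long", "other"))
})

test_that("genomes shorter than k survive dereplication with a warning", {
  set.seed(106)
  gs <- list(genome_record("tiny", "ACGTACGT"),
             genome_record("big", random_dna(2000)))
  expect_warning(out <- dereplicate(gs), "shorter than k")
  expect_length(representatives(out), 2L)
})
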