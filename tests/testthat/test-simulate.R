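test_that("fixture specs validate sizes, margin and origin totals", {
  expect_error(hgt_fixture_spec(class_sizes = c(confirmed_bitscore = -1L)),
               class = "potworm_usage_error")
  expect_error(hgt_fixture_spec(bitscore_margin = 0.5),
               class = "potworm_usage_error")
  expect_error(hgt_fixture_spec(class_sizes = c(confirmed_bitscore = 2L),
                                origin_distribution = c(bacteria = 1L)),
               "sum to the confirmed total", class = "potworm_usage_error")
  expect_error(hgt_fixture_spec(class_sizes = c(bogus = 1L)),
               class = "potworm_usage_error")
})

test_that("an all-zero spec with background genes reports all zeros", {
  fix <- generate_hgt_fixture(hgt_fixture_spec(
    class_sizes = c(confirmed_bitscore = 0L), n_background = 5L, seed = 2))
  rep <- run_hgt_pipeline(fix$hits, fix$genes, fix$reads, fix$trees)$report
  expect_equal(rep$n_candidates, 0L)
  expect_equal(rep$n_confirmed_total, 0L)
  expect_true(all(fix$truth$class == "not_candidate"))
})

test_that("pipeline decisions recover the planted truth exactly", {
  spec <- hgt_fixture_spec(
    class_sizes = c(confirmed_bitscore = 2L, rejected_no_linkage = 1L,
                    phylo_rejected = 1L),
    n_background = 3L, seed = 7)
  fix <- generate_hgt_fixture(spec)
  res <- run_hgt_pipeline(fix$hits, fix$genes, fix$reads, fix$trees)
  d <- res$decisions
  cmp <- dplyr::left_join(fix$truth, d[c("gene_id", "stage")], by = "gene_id")
  expect_equal(cmp$stage, cmp$class)
})

test_that("the seed contract gives identical structure, different coordinates", {
  spec7 <- hgt_fixture_spec(class_sizes = c(confirmed_bitscore = 2L,
                                            rejected_no_linkage = 1L,
                                            phylo_rejected = 1L),
                            n_background = 3L, seed = 7)
  spec8 <- hgt_fixture_spec(class_sizes = c(confirmed_bitscore = 2L,
                                            rejected_no_linkage = 1L,
                                            phylo_rejected = 1L),
                            n_background = 3L, seed = 8)
  f7a <- generate_hgt_fixture(spec7)
  f7b <- generate_hgt_fixture(spec7)
  f8 <- generate_hgt_fixture(spec8)
  expect_identical(f7a$hits, f7b$hits)
  expect_identical(f7a$genes, f7b$genes)
  expect_identical(f7a$truth, f7b$truth)
  expect_identical(table(f7a$truth$class), table(f8$truth$class))
  expect_false(identical(f7a$hits$bitscore, f8$hits$bitscore))
  expect_false(identical(f7a$genes$end, f8$genes$end))
})

test_that("written fixtures re-parse and reproduce the in-memory pipeline run", {
  fix <- generate_hgt_fixture(hgt_fixture_spec(seed = 21))
  dir <- tempfile()
  paths <- write_hgt_fixture(fix, dir)
  hits <- dplyr::bind_rows(lapply(
    grep("^hits_", names(paths), value = TRUE),
    function(nm) read_hit_table(paths[[nm]], sub("^hits_", "", nm))))
  genes <- read_gene_models(paths$genes)
  reads <- read_read_intervals(paths$reads, "paf")
  trees <- read_gene_trees(paths$trees)
  r_disk <- run_hgt_pipeline(hits, genes, reads, trees)
  r_mem <- run_hgt_pipeline(fix$hits, fix$genes, fix$reads, fix$trees)
  expect_equal(r_disk$report, r_mem$report)
  expect_equal(dplyr::arrange(r_disk$decisions, gene_id)$stage,
               dplyr::arrange(r_mem$decisions, gene_id)$stage)
  truth <- readr::read_tsv(paths$truth, show_col_types = FALSE)
  expect_equal(nrow(truth), nrow(fix$genes))
})

test_that("family fixtures respect the analytic feasibility bound", {
  expect_error(generate_family_counts_fixture(n_species = 4, n_expanded = 1),
               "infeasible", class = "potworm_usage_error")
  expect_error(generate_family_counts_fixture(n_species = 5, n_contracted = 1),
               "infeasible", class = "potworm_usage_error")
  # 4 species without planted outliers is fine
  ok <- generate_family_counts_fixture(n_species = 4, n_expanded = 0,
                                       n_contracted = 0, n_lineage = 2,
                                       n_neutral = 5, seed = 1)
  expect_equal(nrow(ok$truth), 7L)
})

test_that("an empty family fixture is an empty matrix with headers", {
  fix <- generate_family_counts_fixture(n_expanded = 0, n_contracted = 0,
                                        n_lineage = 0, n_neutral = 0, seed = 1)
  expect_equal(nrow(as.data.frame(fix$counts)), 0L)
  expect_equal(length(species_ids(fix$counts)), 9L)
  d <- tempfile()
  paths <- write_family_fixture(fix, d)
  reread <- read_counts_matrix(paths$counts, "Ecrypticus")
  expect_equal(nrow(as.data.frame(reread)), 0L)
})

test_that("family fixtures are recovered by the z-score analysis", {
  fix <- generate_family_counts_fixture(n_species = 9, n_expanded = 3,
                                        n_contracted = 3, n_lineage = 4,
                                        n_neutral = 30, seed = 5)
  z <- family_zscores(fix$counts)
  focal <- z[z$species_id == "Ecrypticus", ]
  st <- setNames(focal$status, focal$orthogroup_id)
  truth <- fix$truth
  expect_true(all(st[truth$orthogroup_id[truth$class == "expanded"]] == "expanded"))
  expect_true(all(st[truth$orthogroup_id[truth$class == "contracted"]] == "contracted"))
  expect_equal(sort(lineage_specific_families(fix$counts)),
               sort(truth$orthogroup_id[truth$class == "lineage_specific"]))
  neutral <- truth$orthogroup_id[truth$class == "neutral"]
  expect_false(any(st[neutral] %in% c("expanded", "contracted")))
})

test_that("genome fixtures honour forced lengths and the N50 oracle", {
  fix <- generate_genome_fixture(n_scaffolds = 5,
                                 scaffold_lengths = c(5000, 4000, 3000, 2000, 1000),
                                 seed = 1)
  stats <- compute_assembly_stats(fix$scaffolds, min_len_bp = 1)
  expect_equal(stats$n50_bp, 4000L)
  expect_equal(stats$l50, 2L)
})

test_that("genome fixtures are byte-identical per seed", {
  f1 <- generate_genome_fixture(n_scaffolds = 6, seed = 4)
  f2 <- generate_genome_fixture(n_scaffolds = 6, seed = 4)
  expect_identical(f1$scaffolds$sequence, f2$scaffolds$sequence)
  d1 <- tempfile(); d2 <- tempfile()
  write_genome_fixture(f1, d1); write_genome_fixture(f2, d2)
  expect_identical(readLines(file.path(d1, "assembly.fasta")),
                   readLines(file.path(d2, "assembly.fasta")))
  # and the FASTA re-parses to the same table
  expect_equal(as.data.frame(read_fasta(file.path(d1, "assembly.fasta"))),
               as.data.frame(f1$scaffolds))
})
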