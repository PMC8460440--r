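empty_reads <- tibble::tibble(read_id = character(0), scaffold_id = character(0),
                              start = integer(0), end = integer(0))

test_that("an empty hit table yields an all-zero report", {
  genes <- mk_genes(c("g1", "g2"), "s1", c(100, 5000), c(2000, 7000))
  hits <- mk_hits()[0, ]
  hits <- mk_hit("x", "bacteria", 1)[0, ]
  res <- run_hgt_pipeline(hits, genes, empty_reads)
  expect_equal(res$report$n_candidates, 0L)
  expect_equal(res$report$n_confirmed_total, 0L)
  expect_true(all(res$decisions$stage == "not_candidate"))
  expect_equal(nrow(res$origin), 0L)
})

test_that("a hand-built micro fixture hits every stage as planted", {
  # candA: bitscore-confirmable; candB: tree-confirmable; candC: tree-rejected;
  # candD: no native neighbour; nat1..nat4 native genes; bg1 sub-threshold
  genes <- mk_genes(
    c("nat1", "candA", "nat2", "candB", "nat3", "candC", "nat4", "candD", "bg1"),
    c("s1", "s1", "s1", "s2", "s2", "s3", "s3", "s4", "s5"),
    c(1000, 5000, 9000, 5000, 9000, 5000, 9000, 5000, 1000),
    c(3000, 7000, 11000, 7000, 11000, 7000, 11000, 7000, 2000))
  hits <- mk_hits(
    mk_hit("candA", "bacteria", 200), mk_hit("candA", "metazoa_excl_annelida", 20),
    mk_hit("candB", "plants", 300), mk_hit("candB", "metazoa_excl_annelida", 120),
    mk_hit("candC", "fungi", 250), mk_hit("candC", "metazoa_excl_annelida", 130),
    mk_hit("candD", "bacteria", 180), mk_hit("candD", "metazoa_excl_annelida", 30),
    mk_hit("bg1", "bacteria", 80), mk_hit("bg1", "metazoa_excl_annelida", 70)
  )
  reads <- tibble::tibble(
    read_id = c("rA", "rB", "rC"), scaffold_id = c("s1", "s2", "s3"),
    start = c(6500L, 6500L, 6500L), end = c(9600L, 9600L, 9600L))
  trees <- list(
    candB = ape::read.tree(text = "((candB,plants|p1),metazoa_excl_annelida|m1);"),
    candC = ape::read.tree(text = "((candC,metazoa_excl_annelida|m1),fungi|f1);"))
  res <- run_hgt_pipeline(hits, genes, reads, trees)
  d <- setNames(res$decisions$stage, res$decisions$gene_id)
  expect_equal(unname(d[c("candA", "candB", "candC", "candD", "bg1", "nat1")]),
               c("confirmed_bitscore", "phylo_confirmed", "phylo_rejected",
                 "rejected_no_linkage", "not_candidate", "not_candidate"))
  expect_equal(res$report$n_candidates, 4L)
  expect_equal(res$report$n_confirmed_total, 2L)
  expect_equal(sort(res$origin$taxon_group), c("bacteria", "plants"))
  expect_equal(res$origin$percent, c(50, 50))
})

test_that("candidates needing a missing tree are phylo_missing, not confirmed", {
  genes <- mk_genes(c("nat1", "candB"), "s1", c(1000, 5000), c(3000, 7000))
  hits <- mk_hits(mk_hit("candB", "plants", 300),
                  mk_hit("candB", "metazoa_excl_annelida", 120))
  reads <- tibble::tibble(read_id = "r", scaffold_id = "s1",
                          start = 2500L, end = 5600L)
  res <- run_hgt_pipeline(hits, genes, reads, trees = list())
  expect_equal(res$decisions$stage[res$decisions$gene_id == "candB"],
               "phylo_missing")
  expect_equal(res$report$n_phylo_tested, 1L)
  expect_equal(res$report$n_confirmed_total, 0L)
})

test_that("stage counts conserve across the pipeline on random fixtures", {
  for (seed in c(5, 17, 91)) {
    spec <- hgt_fixture_spec(
      class_sizes = c(rejected_no_linkage = 3L, confirmed_bitscore = 2L,
                      phylo_confirmed = 4L, phylo_rejected = 2L),
      n_background = 6L, seed = seed)
    fix <- generate_hgt_fixture(spec)
    rep <- run_hgt_pipeline(fix$hits, fix$genes, fix$reads, fix$trees)$report
    expect_equal(rep$n_candidates,
                 rep$n_rejected_linkage + rep$n_confirmed_bitscore +
                   rep$n_phylo_tested)
    expect_equal(rep$n_phylo_tested,
                 rep$n_phylo_confirmed + rep$n_phylo_rejected +
                   rep$n_phylo_missing)
    expect_equal(rep$n_confirmed_total,
                 rep$n_confirmed_bitscore + rep$n_phylo_confirmed)
  }
})

test_that("origin percentages round half away from zero to one decimal", {
  s <- tibble::tibble(
    gene_id = sprintf("g%02d", 1:32),
    best_nonmetazoan_group = rep(c("bacteria", "plants", "fungi", "archaea"),
                                 times = c(19, 8, 4, 1)))
  org <- attribute_origin(s$gene_id, s)
  expect_equal(org$taxon_group, c("bacteria", "plants", "fungi", "archaea"))
  expect_equal(org$percent, c(59.4, 25.0, 12.5, 3.1))
  expect_equal(sum(org$percent), 100, tolerance = 0.2)

  one <- attribute_origin("g01", s)
  expect_equal(one$percent, 100)
  expect_equal(nrow(attribute_origin(character(0), s)), 0L)
})

test_that("the pipeline is deterministic across repeated runs", {
  fix <- generate_hgt_fixture(hgt_fixture_spec(seed = 3))
  r1 <- run_hgt_pipeline(fix$hits, fix$genes, fix$reads, fix$trees)
  r2 <- run_hgt_pipeline(fix$hits, fix$genes, fix$reads, fix$trees)
  expect_identical(r1$decisions, r2$decisions)
  expect_identical(r1$report, r2$report)
  expect_identical(r1$origin, r2$origin)
})

test_that("tidy/glance/autoplot expose the result components", {
  fix <- generate_hgt_fixture(hgt_fixture_spec(seed = 3))
  res <- run_hgt_pipeline(fix$hits, fix$genes, fix$reads, fix$trees)
  expect_identical(generics::tidy(res), res$decisions)
  expect_identical(generics::glance(res), res$report)
  expect_s3_class(ggplot2::autoplot(res), "ggplot")
  expect_s3_class(ggplot2::autoplot(res, type = "origin"), "ggplot")
  expect_output(print(res), "candidates")
})
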