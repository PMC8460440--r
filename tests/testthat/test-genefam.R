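test_that("z-scores match hand-computed values and the +/-2 rule", {
  # single large outlier among 9 species: z = (n-1)/sqrt(n) = 8/3
  cm <- mk_counts(matrix(c(129, rep(1, 8)), nrow = 1))
  z <- family_zscores(cm)
  zf <- z[z$species_id == "focal", ]
  expect_equal(zf$z, 8 / 3, tolerance = 1e-12)
  expect_equal(zf$status, "expanded")
  expect_true(zf$eligible)

  # constant family: sd 0, z undefined
  z0 <- family_zscores(mk_counts(matrix(3, nrow = 1, ncol = 9)))
  expect_true(all(is.na(z0$z)))
  expect_true(all(z0$status == "undefined_sd"))

  # 5 species: z = 4/sqrt(5) < 2 even for the analytic maximum
  z5 <- family_zscores(mk_counts(matrix(c(20, 2, 2, 2, 2), nrow = 1)))
  zf5 <- z5[z5$species_id == "focal", ]
  expect_equal(zf5$z, 4 / sqrt(5), tolerance = 1e-12)
  expect_equal(zf5$status, "neither")
})

test_that("population-sd mode is pinned against the sample-sd default", {
  cm <- mk_counts(matrix(c(20, 2, 2, 2, 2), nrow = 1))
  zs <- family_zscores(cm, sd_mode = "sample")
  zp <- family_zscores(cm, sd_mode = "population")
  f <- function(z) z$z[z$species_id == "focal"]
  expect_equal(f(zs), 4 / sqrt(5), tolerance = 1e-12)   # 1.789: neither
  expect_equal(f(zp), 2, tolerance = 1e-12)             # exactly 2: expanded
  expect_equal(zp$status[zp$species_id == "focal"], "expanded")
})

test_that("eligibility needs the focal species plus three represented others", {
  # focal present, only 2 others represented
  z <- family_zscores(mk_counts(matrix(c(5, 1, 1, 0, 0, 0, 0, 0, 0), nrow = 1)))
  expect_true(all(z$status == "ineligible"))
  # focal absent
  z2 <- family_zscores(mk_counts(matrix(c(0, 4, 4, 4, 4, 0, 0, 0, 0), nrow = 1)))
  expect_true(all(z2$status == "ineligible"))
  expect_false(any(z2$eligible))
  # exactly 3 others
  z3 <- family_zscores(mk_counts(matrix(c(25, 1, 1, 1, 0, 0, 0, 0, 0), nrow = 1)))
  expect_true(all(z3$eligible))
})

test_that("per-family z-scores sum to zero and are scale-invariant", {
  set.seed(31)
  m <- matrix(rpois(40 * 9, 3), ncol = 9)
  z <- family_zscores(mk_counts(m))
  sums <- tapply(z$z, z$orthogroup_id, function(x) sum(x))
  defined <- !is.na(sums)
  expect_true(all(abs(sums[defined]) < 1e-9))

  z2 <- family_zscores(mk_counts(m * 7L))
  expect_equal(z$z, z2$z, tolerance = 1e-12)
})

test_that("lineage-specific families are focal-only rows", {
  m <- rbind(c(4, 0, 0), c(0, 0, 0), c(1, 0, 0), c(2, 1, 0), c(0, 3, 0))
  cm <- mk_counts(m)
  expect_equal(lineage_specific_families(cm), c("OG0001", "OG0003"))
})

test_that("shared families implement subset and exclusive Venn semantics", {
  m <- rbind(c(1, 1, 1), c(2, 0, 1), c(0, 1, 1), c(3, 0, 0))
  cm <- mk_counts(m)
  sp <- species_ids(cm)

  expect_equal(shared_families(cm, sp)$count, 1L)         # all-positive row
  expect_equal(shared_families(cm, sp[1])$ids, c("OG0001", "OG0002", "OG0004"))

  # exclusive Venn regions partition the non-empty families
  regions <- unlist(lapply(1:3, function(k) combn(sp, k, simplify = FALSE)),
                    recursive = FALSE)
  tot <- sum(vapply(regions, function(r) {
    shared_families(cm, r, exclusive = TRUE)$count
  }, integer(1)))
  expect_equal(tot, sum(rowSums(m) > 0))

  expect_error(shared_families(cm, "nope"), "unknown species",
               class = "potworm_usage_error")
  expect_error(shared_families(cm, character(0)), class = "potworm_usage_error")
})

test_that("lineage-specific and all-species-shared families are disjoint", {
  set.seed(13)
  m <- matrix(rpois(200 * 5, 1), ncol = 5)
  cm <- mk_counts(m)
  expect_length(intersect(lineage_specific_families(cm),
                          shared_families(cm, species_ids(cm))$ids), 0)
})

test_that("expansion ranking orders by focal count, then z, then id", {
  # three clear expansions with focal counts 129, 44, 26 among 9 species
  m <- rbind(c(129, rep(1, 8)), c(26, rep(1, 8)), c(44, rep(1, 8)))
  z <- family_zscores(mk_counts(m))
  top <- rank_expansions(z)
  expect_equal(top$count, c(129L, 44L, 26L))
  expect_equal(top$orthogroup_id, c("OG0001", "OG0003", "OG0002"))

  # tie on count: larger z (tighter non-focal spread) first
  m2 <- rbind(c(30, rep(2, 8)), c(30, c(2, 2, 2, 2, 2, 2, 2, 9)))
  z2 <- family_zscores(mk_counts(m2))
  top2 <- rank_expansions(z2)
  expect_equal(top2$count, c(30L, 30L))
  expect_equal(top2$orthogroup_id[1], "OG0001")
  expect_gt(top2$z[1], top2$z[2])

  none <- rank_expansions(family_zscores(mk_counts(matrix(1, 2, 9))))
  expect_equal(nrow(none), 0L)
})

test_that("collinear blocks classify as palindrome, tandem or inter-scaffold", {
  genes <- mk_genes(c("a1", "a2", "b1", "b2", "c1"),
                    c("s15", "s15", "s129", "s129", "s52"),
                    c(100, 5000, 100, 5000, 100),
                    c(1000, 6000, 1000, 6000, 1000),
                    strand = c("+", "-", "+", "+", "+"))
  pal <- tibble::tibble(gene_a = "a1", gene_b = "a2")
  expect_equal(classify_collinear_block(pal, genes), "palindrome")
  tan <- tibble::tibble(gene_a = "b1", gene_b = "b2")
  expect_equal(classify_collinear_block(tan, genes), "tandem")
  inter <- tibble::tibble(gene_a = "a1", gene_b = "c1")
  expect_equal(classify_collinear_block(inter, genes), "inter_scaffold")
  expect_error(classify_collinear_block(tibble::tibble(gene_a = "zz", gene_b = "a1"),
                                        genes),
               "unknown gene", class = "potworm_usage_error")
})

test_that("z-scores need at least two species", {
  tbl <- tibble::tibble(orthogroup = "OG1", only = 3L)
  cm <- potworm:::new_orthogroup_counts(tbl, "only")
  expect_error(family_zscores(cm), class = "potworm_usage_error")
})
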