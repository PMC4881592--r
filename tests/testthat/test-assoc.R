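test_that("association tables load with validation and preserved row order", {
  assoc <- load_fixture("table3")
  expect_s3_class(assoc, "mirna_assoc")
  expect_equal(dim(assoc), c(90L, 7L))
  expect_equal(colnames(assoc),
               c("Colon", "Prostate", "Pancreatic", "Lung", "Breast",
                 "Bladder", "Kidney"))
  expect_equal(rownames(assoc)[1], "miR-124a")

  # one-row machine-dialect table
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("mirna\tColon\tProstate\tPancreatic\tLung\tBreast\tBladder\tKidney",
               "miR-x\tv\t\t\t\t\t\t"), f)
  one <- read_association_table(f)
  expect_equal(dim(one), c(1L, 7L))
  expect_equal(sum(one), 1L)
  expect_equal(unname(target_vector(one, "miR-x")), c(1L, rep(0L, 6)))
})

test_that("malformed association tables are rejected with informative errors", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("mirna\tColon\tLung", "miR-a\tv\t", "miR-a\t\tv"), f)
  expect_error(read_association_table(f), "duplicate miRNA.*miR-a")

  writeLines(c("mirna\tColon\tLung", "miR-a\tv\t", "miR-b\t\t"), f)
  expect_error(read_association_table(f), "all-zero.*miR-b")

  writeLines(c("mirna\tColon\tLung", "miR-a\tv\tx"), f)
  expect_error(read_association_table(f), "unknown cell token 'x'.*miR-a.*Lung")

  expect_error(target_vector(load_fixture("table3"), "miR-nope"), "unknown miRNA")
})

test_that("target vectors match the published worked examples", {
  assoc <- load_fixture("table3")
  expect_equal(unname(target_vector(assoc, "miR-124a")), c(1L, 1L, 1L, 1L, 1L, 1L, 0L))
  expect_equal(unname(target_vector(assoc, "miR-146")), c(1L, 0L, 0L, 1L, 0L, 1L, 1L))
  v18 <- target_vector(assoc, "miR-18")
  expect_equal(sum(v18), 1L)
  expect_equal(names(v18)[v18 == 1], "Lung")
})

test_that("group extraction partitions by identical rows", {
  assoc <- load_fixture("table3")
  g <- extract_groups(assoc)
  expect_length(g$members, 41)
  expect_setequal(unlist(g$members), rownames(assoc))
  # group count equals number of distinct rows (hash-set oracle)
  keys <- apply(unclass(assoc), 1, paste, collapse = "")
  expect_equal(length(g$members), length(unique(keys)))
  # all members share their pattern
  for (i in seq_along(g$members)) {
    for (m in g$members[[i]])
      expect_equal(unname(target_vector(assoc, m)), unname(g$patterns[i, ]))
  }
  # degenerate shapes
  all_same <- as_mirna_assoc(matrix(1L, 4, 3,
    dimnames = list(paste0("m", 1:4), paste0("d", 1:3))))
  expect_length(extract_groups(all_same)$members, 1)
  distinct <- as_mirna_assoc(diag(3) |> `dimnames<-`(list(paste0("m", 1:3),
                                                          paste0("d", 1:3))))
  expect_length(extract_groups(distinct)$members, 3)
})

test_that("group extraction is idempotent and row-permutation invariant", {
  set.seed(42)
  assoc <- load_fixture("table3")
  g1 <- extract_groups(assoc)
  as_sets <- function(g) sort(vapply(g$members, function(m)
    paste(sort(m), collapse = ","), character(1)))
  for (rep in 1:5) {
    perm <- sample(nrow(assoc))
    ga <- extract_groups(as_mirna_assoc(unclass(assoc)[perm, ]))
    expect_equal(as_sets(ga), as_sets(g1))
    # ids contiguous from 1 in first-appearance order
    expect_equal(unique(unname(ga$assignment)), seq_along(ga$members))
  }
  expect_identical(extract_groups(assoc)$assignment, g1$assignment)
})

test_that("euclidean distances between target vectors follow the binary formula", {
  assoc <- load_fixture("table3")
  d <- vector_distance_matrix(assoc)
  expect_equal(d["miR-124a", "miR-146"], 2)          # sqrt(4 differing sites)
  expect_equal(d["miR-124a", "miR-9"], 0)            # identical rows
  expect_true(isSymmetric(d))
  expect_equal(unname(diag(d)), rep(0, 90))
  two <- as_mirna_assoc(matrix(c(1L, 0L, 0L, 0L, 1L, 0L), 2, byrow = TRUE,
    dimnames = list(c("a", "b"), c("x", "y", "z"))))
  expect_equal(vector_distance_matrix(two)["a", "b"], sqrt(2))
})

test_that("UPGMA trees are ultrametric with hand-checked merge heights", {
  # two leaves at distance d merge at height d/2
  d2 <- matrix(c(0, 3, 3, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  t2 <- upgma_tree(d2)
  expect_equal(t2$height, 1.5)
  # hand-executed three-leaf case
  d3 <- matrix(c(0, 1, 4, 1, 0, 4, 4, 4, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  t3 <- upgma_tree(d3)
  expect_equal(t3$height, c(0.5, 2))
  expect_equal(sort(enumerate_clades(t3)[[1]]), c("A", "B"))

  # ultrametricity + monotone heights on random matrices, via ape round-trip
  set.seed(7)
  for (rep in 1:5) {
    d <- random_distance_matrix(9)
    tr <- upgma_tree(d)
    expect_true(all(diff(tr$height) >= -1e-12))
    ph <- ape::read.tree(text = write_newick(tr))
    depths <- ape::node.depth.edgelength(ph)[seq_along(ph$tip.label)]
    expect_lt(max(depths) - min(depths), 1e-9)
  }
})

test_that("UPGMA agrees with hclust average linkage on tie-free matrices", {
  set.seed(99)
  for (rep in 1:5) {
    d <- random_distance_matrix(10)
    mine <- upgma_tree(d)
    ref <- stats::hclust(stats::as.dist(d), method = "average")
    expect_equal(sort(mine$height * 2), sort(ref$height), tolerance = 1e-10)
    key <- function(cl) sort(vapply(cl, paste, character(1), collapse = "|"))
    expect_equal(key(enumerate_clades(mine)), key(hclust_clades(ref)))
  }
})

test_that("target-group members tie at height zero in the fixture dendrogram", {
  assoc <- load_fixture("table3")
  g <- extract_groups(assoc)
  tr <- upgma_tree(vector_distance_matrix(assoc))
  zero_part <- stats::cutree(tr, h = 0)
  # the zero-height partition is exactly the target-group partition
  expect_equal(length(unique(zero_part)), length(g$members))
  expect_true(all(tapply(zero_part[names(g$assignment)], g$assignment,
                         function(v) length(unique(v)) == 1)))
  # and any nonzero merge comes after all zero merges
  expect_true(all(diff(tr$height >= 1e-12) >= 0))
})
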