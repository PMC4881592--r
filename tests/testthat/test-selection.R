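# build a linkage tree with a prescribed nested structure by crafting
# distances: leaves listed earlier join at smaller heights
make_tree <- function(...) {
  groups <- list(...)
  labs <- unique(unlist(groups))
  n <- length(labs)
  d <- matrix(10, n, n, dimnames = list(labs, labs))
  h <- 1
  for (g in groups) {
    d[g, g] <- pmin(d[g, g], h)
    h <- h + 1
  }
  diag(d) <- 0
  single_linkage_tree(d)
}

make_groups <- function(assignment, n_diseases = 3) {
  pats <- diag(n_diseases)[rep_len(seq_len(n_diseases), max(assignment)), ,
                           drop = FALSE]
  m <- pats[assignment, , drop = FALSE]
  storage.mode(m) <- "integer"
  dimnames(m) <- list(names(assignment), paste0("d", seq_len(n_diseases)))
  extract_groups(as_mirna_assoc(m))
}

test_that("selection emits maximal clades fully inside one target group", {
  # clades: {A,B}, {C,E}, then everything; group {A,B,C,D}
  tr <- make_tree(c("A", "B"), c("C", "E"), c("A", "B", "C", "E", "D"))
  grp <- make_groups(c(A = 1, B = 1, C = 1, D = 1, E = 2))
  sel <- select_biomarkers(tr, grp, min_set_size = 2)
  expect_equal(selection_key(sel$sets), "1:A,B")
  # with min_set_size = 1, D's maximal in-group clade is itself
  sel1 <- select_biomarkers(tr, grp, min_set_size = 1)
  expect_setequal(selection_key(sel1$sets), c("1:A,B", "1:C", "1:D", "2:E"))

  # a group forming one whole clade comes back as a single full set
  tr2 <- make_tree(c("X", "Y", "Z"), c("X", "Y", "Z", "W"))
  grp2 <- make_groups(c(X = 1, Y = 1, Z = 1, W = 2))
  sel2 <- select_biomarkers(tr2, grp2)
  expect_equal(selection_key(sel2$sets), c("1:X,Y,Z"))

  # no clade of size >= 2 inside any group: empty report
  tr3 <- make_tree(c("A", "C"), c("A", "C", "B", "D"))
  grp3 <- make_groups(c(A = 1, B = 1, C = 2, D = 2))
  expect_length(select_biomarkers(tr3, grp3)$sets, 0)
  expect_equal(nrow(report_to_table(select_biomarkers(tr3, grp3))), 0)
})

test_that("a group split across branches yields several disjoint sets", {
  # mirrors the published bladder-group mechanism: one target group whose
  # members sit in separate phylogenetic branches gives one set per branch
  tr <- make_tree(c("m1", "m2"), c("m3", "m4"),
                  c("m1", "m2", "q1"), c("m3", "m4", "q2"),
                  c("m1", "m2", "q1", "m3", "m4", "q2"))
  grp <- make_groups(c(m1 = 1, m2 = 1, m3 = 1, m4 = 1, q1 = 2, q2 = 2))
  sel <- select_biomarkers(tr, grp)
  expect_setequal(selection_key(sel$sets), c("1:m1,m2", "1:m3,m4"))
  members <- lapply(sel$sets, `[[`, "members")
  expect_length(intersect(members[[1]], members[[2]]), 0)
})

test_that("selected sets satisfy both containments and maximality", {
  set.seed(2024)
  for (rep in 1:20) {
    n <- sample(6:12, 1)
    labs <- sprintf("m%02d", seq_len(n))
    d <- random_distance_matrix(n, labs)
    tr <- single_linkage_tree(d)
    grp <- make_groups(stats::setNames(sample(1:3, n, replace = TRUE), labs))
    sel <- select_biomarkers(tr, grp)
    clade_keys <- vapply(enumerate_clades(tr), paste, character(1),
                         collapse = "|")
    for (s in sel$sets) {
      expect_true(paste(s$members, collapse = "|") %in% clade_keys)
      expect_true(all(s$members %in% grp$members[[s$group_id]]))
      expect_identical(s$members, s$supporting_clade)
    }
    # maximality within each group
    keys <- selection_key(sel$sets)
    for (i in seq_along(sel$sets)) for (j in seq_along(sel$sets)) {
      if (i == j || sel$sets[[i]]$group_id != sel$sets[[j]]$group_id) next
      expect_false(all(sel$sets[[i]]$members %in% sel$sets[[j]]$members))
    }
    # raising min_set_size never adds sets nor enlarges any
    sel3 <- select_biomarkers(tr, grp, min_set_size = 3)
    expect_lte(length(sel3$sets), length(sel$sets))
    expect_true(all(selection_key(sel3$sets) %in% selection_key(sel$sets)))
  }
})

test_that("selection equals the exhaustive subset-scan oracle", {
  set.seed(4242)
  for (rep in 1:30) {
    n <- sample(5:9, 1)
    labs <- sprintf("m%02d", seq_len(n))
    tr <- single_linkage_tree(random_distance_matrix(n, labs))
    grp <- make_groups(stats::setNames(sample(1:3, n, replace = TRUE), labs))
    for (msz in 1:2) {
      sel <- select_biomarkers(tr, grp, min_set_size = msz)
      ora <- oracle_select(tr, grp, min_set_size = msz)
      expect_equal(selection_key(sel$sets), selection_key(ora),
                   info = sprintf("rep %d msz %d", rep, msz))
    }
  }
})

test_that("singleton groups and missing sequences are handled explicitly", {
  tr <- make_tree(c("A", "B"), c("A", "B", "C"))
  grp <- make_groups(c(A = 1, B = 1, C = 2, Z = 3))
  # Z has no sequence: excluded with a message, selection still works
  expect_message(sel <- select_biomarkers(tr, grp), "excluding.*Z")
  expect_equal(selection_key(sel$sets), "1:A,B")
  expect_equal(sel$excluded, "Z")
  # singleton group C only appears with the explicit flag
  sel_s <- suppressMessages(
    select_biomarkers(tr, grp, include_singleton_groups = TRUE))
  expect_setequal(selection_key(sel_s$sets), c("1:A,B", "2:C"))
  expect_error(select_biomarkers(tr, grp, min_set_size = 0), "min_set_size")
  grp_off <- make_groups(c(P = 1, Q = 1))
  expect_error(select_biomarkers(tr, grp_off), "share no miRNA")
})

test_that("selection tables are deterministic and disease-labelled", {
  tr <- make_tree(c("A", "B"), c("C", "D"), c("A", "B", "C", "D", "E"))
  pats <- matrix(c(0L, 0L, 1L,   # E: pancreatic-like single disease
                   1L, 1L, 0L,   # A,B
                   1L, 1L, 0L), 3, byrow = TRUE)
  m <- rbind(A = pats[2, ], B = pats[2, ], C = c(1L, 0L, 1L),
             D = c(1L, 0L, 1L), E = pats[1, ])
  colnames(m) <- c("Colon", "Breast", "Pancreatic")
  grp <- extract_groups(as_mirna_assoc(m))
  sel <- select_biomarkers(tr, grp, min_set_size = 1)
  tab <- report_to_table(sel)
  expect_equal(names(tab),
               c("mirnas", "cancers", "group_id", "pattern", "supporting_clade"))
  # ordered by pattern cardinality ascending
  card <- vapply(strsplit(tab$pattern, ""), function(x) sum(x == "1"), numeric(1))
  expect_true(all(diff(card) >= 0))
  expect_equal(tab$cancers[tab$mirnas == "E"], "Pancreatic")
  expect_equal(tab$mirnas[1], "E")
})
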