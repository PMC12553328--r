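catalog6 <- protein_catalog(paste0("p", 1:6))

test_that("pair lists are canonicalized, de-duplicated, and validated against the catalog", {
  path <- tempfile()
  writeLines(c("p1\tp2", "p2\tp1", "p1\tp2"), path)
  ps <- read_pairs(path, catalog6, quiet = TRUE)
  expect_identical(nrow(ps), 1L)
  expect_identical(ps$id1, "p1")
  expect_identical(attr(ps, "n_dropped"), 2L)

  writeLines(character(0), path)
  expect_identical(nrow(read_pairs(path, catalog6)), 0L)

  writeLines(c("p1\tp2", "p3\tpX"), path)
  expect_error(read_pairs(path, catalog6), "absent from the catalog.*pX")

  writeLines(c("p1\tp2", "justonefield"), path)
  expect_error(read_pairs(path, catalog6), "line 2")

  # comments and blank lines are ignored; self-pairs dropped by default
  writeLines(c("# a comment", "", "p4\tp3", "p5\tp5"), path)
  ps2 <- read_pairs(path, catalog6, quiet = TRUE)
  expect_identical(cbind(ps2$id1, ps2$id2), cbind("p3", "p4"))
})

test_that("bipartite pair sets keep the first-catalog protein first, never flipped", {
  catB <- protein_catalog(c("q1", "q2"))
  ps <- candidate_pairs(c("p5", "p1"), c("q1", "q2"), catalog6, catB)
  expect_identical(ps$id1, c("p1", "p5"))
  expect_identical(ps$id2, c("q2", "q1"))
  expect_error(candidate_pairs("q1", "p1", catalog6, catB), "absent")
})

test_that("bucketed pairs partition the candidate set by normalized block pair", {
  part <- block_partition(catalog6, 3L)  # blocks {p1,p2} {p3,p4} {p5,p6}
  ps <- candidate_pairs(c("p1", "p1", "p5"), c("p2", "p4", "p6"), catalog6)
  buckets <- bucket_pairs(ps, part)
  expect_setequal(names(buckets), c("1,1", "1,2", "3,3"))
  expect_identical(lengths(buckets)[sort(names(buckets))],
                   c("1,1" = 1L, "1,2" = 1L, "3,3" = 1L))

  # exhaustive: all 15 pairs of 6 proteins, bucket sizes forced by membership
  pos <- brute_pairs(6L)
  all15 <- candidate_pairs(catalog6$ids[pos[, 1L]], catalog6$ids[pos[, 2L]],
                           catalog6)
  b <- bucket_pairs(all15, part)
  expect_identical(
    lengths(b)[c("1,1", "1,2", "1,3", "2,2", "2,3", "3,3")],
    c("1,1" = 1L, "1,2" = 4L, "1,3" = 4L, "2,2" = 1L, "2,3" = 4L,
      "3,3" = 1L))
  expect_identical(sum(lengths(b)), 15L)
})

test_that("sparse selections name exactly the proteins each block must load", {
  part <- block_partition(catalog6, 3L)
  ps <- candidate_pairs(c("p1", "p1"), c("p2", "p4"), catalog6)
  buckets <- bucket_pairs(ps, part)
  off <- sparse_selection(buckets, 1L, 2L)
  expect_identical(off, list(first = "p1", second = "p4"))
  diag <- sparse_selection(buckets, 1L, 1L)
  expect_setequal(diag$first, c("p1", "p2"))
  expect_identical(diag$first, diag$second)
  empty <- sparse_selection(buckets, 2L, 3L)
  expect_identical(empty, list(first = character(0), second = character(0)))
})

test_that("step enumeration yields products off-diagonal and combinations on it", {
  cat7 <- protein_catalog(paste0("x", 1:7))
  part <- block_partition(cat7, 2L)  # sizes 4, 3
  off <- enumerate_step_pairs("all_pairs", part, 1L, 2L)
  expect_identical(nrow(off), 12L)
  diag <- enumerate_step_pairs("all_pairs", part, 1L, 1L)
  expect_identical(nrow(diag), 6L)
  diag_self <- enumerate_step_pairs("all_pairs", part, 1L, 1L,
                                    include_self = TRUE)
  expect_identical(nrow(diag_self), 10L)
  expect_true(any(diag_self$id1 == diag_self$id2))
})

test_that("flattening any serpentine schedule yields each unordered pair exactly once", {
  # exhaustive sweep over catalog sizes and all admissible block counts
  for (n in c(2:12, 19L, 30L)) {
    catal <- protein_catalog(sprintf("n%02d", seq_len(n)))
    expected <- all_pair_keys(catal)
    for (B in seq_len(n)) {
      part <- block_partition(catal, B)
      s <- serpentine_schedule(B)
      got <- unlist(lapply(seq_len(length(s)), function(t) {
        tasks <- enumerate_step_pairs("all_pairs", part, s$i[t], s$j[t])
        sprintf("%s|%s", tasks$id1, tasks$id2)
      }))
      expect_identical(sort(got), sort(expected),
                       label = sprintf("n=%d B=%d", n, B))
    }
  }
})

test_that("bucketed enumeration over the schedule reproduces any candidate set exactly", {
  set.seed(404)
  catal <- protein_catalog(sprintf("c%02d", 1:20))
  pos <- sample_pair_fraction(20, 0.4, seed = 5L)
  ps <- candidate_pairs(catal$ids[pos[, 1L]], catal$ids[pos[, 2L]], catal)
  expected <- sort(sprintf("%s|%s", ps$id1, ps$id2))
  for (B in c(1L, 3L, 7L, 20L)) {
    part <- block_partition(catal, B)
    buckets <- bucket_pairs(ps, part)
    s <- serpentine_schedule(B)
    got <- unlist(lapply(seq_len(length(s)), function(t) {
      tasks <- enumerate_step_pairs("some_pairs", part, s$i[t], s$j[t],
                                    buckets = buckets)
      sprintf("%s|%s", tasks$id1, tasks$id2)
    }))
    expect_identical(sort(got), expected, label = sprintf("B=%d", B))
  }
})

test_that("bipartite enumeration over its schedule covers exactly the m x n cross pairs", {
  catA <- protein_catalog(paste0("a", 1:5))
  catB <- protein_catalog(paste0("b", 1:8))
  expected <- sort(as.vector(outer(catA$ids, catB$ids, paste, sep = "|")))
  for (p in 1:3) for (q in c(1L, 4L)) {
    pa <- block_partition(catA, p); pb <- block_partition(catB, q)
    s <- bipartite_schedule(p, q)
    got <- unlist(lapply(seq_len(length(s)), function(t) {
      tasks <- enumerate_step_pairs("bipartite", pa, s$i[t], s$j[t],
                                    partition2 = pb)
      sprintf("%s|%s", tasks$id1, tasks$id2)
    }))
    expect_identical(sort(got), expected, label = sprintf("p=%d q=%d", p, q))
  }
})
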