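sims4x5 <- function() {
  matrix(seq(0.1, 1, length.out = 20), 4, 5,
         dimnames = list(paste0("s", 1:4), paste0("t", 1:5)))
}

test_that("matrix decoding and encoding invert each other", {
  sims <- sims4x5()
  M <- matrix(0, 4, 5, dimnames = dimnames(sims))
  expect_equal(nrow(matrix_to_alignment(M, sims)), 0L)

  M["s1", "t2"] <- 1
  M["s3", "t5"] <- 1
  A <- matrix_to_alignment(M, sims)
  expect_equal(nrow(A), 2L)
  expect_setequal(paste(A$e1, A$e2), c("s1 t2", "s3 t5"))
  expect_equal(sort(A$conf), sort(c(sims["s1", "t2"], sims["s3", "t5"])))

  o1 <- new_ontology(data.frame(id = paste0("s", 1:4), name = paste0("s", 1:4)))
  o2 <- new_ontology(data.frame(id = paste0("t", 1:5), name = paste0("t", 1:5)))
  expect_equal(alignment_to_matrix(A, o1, o2), M)

  sims_na <- sims
  sims_na["s1", "t2"] <- NA
  expect_error(matrix_to_alignment(M, sims_na), "undefined")
})

test_that("approximated metrics follow their definitions", {
  o1 <- new_ontology(data.frame(id = paste0("s", 1:4), name = paste0("s", 1:4)))
  o2 <- new_ontology(data.frame(id = paste0("t", 1:5), name = paste0("t", 1:5)))
  A2 <- new_alignment(data.frame(e1 = c("s1", "s2"), e2 = c("t1", "t2"),
                                 conf = c(0.8, 1.0)))
  empty <- new_alignment()

  expect_equal(recall_prime(A2, o1, o2), 0.5)  # 2 / min(4, 5)
  expect_equal(recall_prime(empty, o1, o2), 0)
  full <- new_alignment(data.frame(e1 = paste0("s", 1:4),
                                   e2 = paste0("t", 1:4), conf = 1))
  expect_equal(recall_prime(full, o1, o2), 1)

  expect_equal(precision_prime(A2), 0.9)
  expect_equal(precision_prime(empty), 0)
  expect_equal(precision_prime(full), 1)

  # harmonic mean: fixed point at p = r, hand value at p=0.9, r=0.5
  expect_equal(f_measure_prime(full, o1, o2), 1)
  A_mixed <- new_alignment(data.frame(e1 = c("s1", "s2"),
                                      e2 = c("t1", "t2"), conf = 0.9))
  p <- precision_prime(A_mixed); r <- recall_prime(A_mixed, o1, o2)
  expect_equal(r, 0.5)
  expect_equal(2 * p * r / (p + r), 0.642857142857, tolerance = 1e-10)
  expect_equal(f_measure_prime(A_mixed, o1, o2), 2 * p * r / (p + r))
  expect_equal(f_measure_prime(empty, o1, o2), 0)
})

test_that("the fitness lies between precision' and recall' and is monotone in each", {
  o1 <- new_ontology(data.frame(id = paste0("s", 1:6), name = paste0("s", 1:6)))
  o2 <- new_ontology(data.frame(id = paste0("t", 1:6), name = paste0("t", 1:6)))
  withr::local_seed(8)
  for (rep in 1:15) {
    k <- sample(1:6, 1)
    A <- new_alignment(data.frame(e1 = paste0("s", 1:k), e2 = paste0("t", 1:k),
                                  conf = runif(k)))
    p <- precision_prime(A)
    r <- recall_prime(A, o1, o2)
    f <- f_measure_prime(A, o1, o2)
    expect_gte(f, min(p, r) - 1e-12)
    expect_lte(f, max(p, r) + 1e-12)
  }
  hm <- function(p, r) if (p + r == 0) 0 else 2 * p * r / (p + r)
  grid <- seq(0.05, 1, by = 0.05)
  for (r in c(0.2, 0.7)) {
    expect_true(all(diff(sapply(grid, hm, r = r)) > 0))
  }
})

test_that("adding a correspondence moves precision' toward its confidence", {
  A <- new_alignment(data.frame(e1 = c("s1", "s2"), e2 = c("t1", "t2"),
                                conf = c(0.6, 0.8)))
  above <- new_alignment(rbind(as.data.frame(A)[c("e1", "e2", "conf")],
                               data.frame(e1 = "s3", e2 = "t3", conf = 0.95)))
  below <- new_alignment(rbind(as.data.frame(A)[c("e1", "e2", "conf")],
                               data.frame(e1 = "s3", e2 = "t3", conf = 0.2)))
  expect_gt(precision_prime(above), precision_prime(A))
  expect_lt(precision_prime(below), precision_prime(A))
})

test_that("reference-based evaluation matches set arithmetic", {
  ref <- new_alignment(data.frame(e1 = c("s1", "s2", "s3"),
                                  e2 = c("t1", "t2", "t3"), conf = 1))
  expect_equal(evaluate_against_reference(ref, ref),
               list(precision = 1, recall = 1, f_measure = 1))
  disjoint <- new_alignment(data.frame(e1 = "s9", e2 = "t9", conf = 1))
  expect_equal(evaluate_against_reference(disjoint, ref),
               list(precision = 0, recall = 0, f_measure = 0))
  expect_error(evaluate_against_reference(ref, new_alignment()), "empty")

  withr::local_seed(13)
  universe <- expand.grid(e1 = paste0("s", 1:5), e2 = paste0("t", 1:5),
                          stringsAsFactors = FALSE)
  for (rep in 1:10) {
    A <- universe[sample(nrow(universe), 6), ]
    R <- universe[sample(nrow(universe), 4), ]
    A$conf <- 1; R$conf <- 1
    got <- evaluate_against_reference(new_alignment(A), new_alignment(R))
    hits <- length(intersect(paste(A$e1, A$e2), paste(R$e1, R$e2)))
    expect_equal(got$precision, hits / 6)
    expect_equal(got$recall, hits / 4)
  }
})

test_that("greedy cardinality repair yields 1:1 subsets preferring confidence", {
  sims <- sims4x5()
  M <- matrix(0, 4, 5, dimnames = dimnames(sims))
  M["s1", "t1"] <- 1; M["s2", "t2"] <- 1
  expect_equal(enforce_single_cardinality(M, sims), M)  # already 1:1

  conflict <- matrix(0, 4, 5, dimnames = dimnames(sims))
  conflict["s1", "t1"] <- 1; conflict["s1", "t3"] <- 1
  sims2 <- sims; sims2["s1", "t1"] <- 0.9; sims2["s1", "t3"] <- 0.4
  rep1 <- enforce_single_cardinality(conflict, sims2)
  expect_equal(unname(rep1["s1", "t1"]), 1)
  expect_equal(unname(rep1["s1", "t3"]), 0)

  withr::local_seed(20)
  for (rep in 1:10) {
    M <- matrix(rbinom(20, 1, 0.5), 4, 5, dimnames = dimnames(sims))
    S <- matrix(runif(20), 4, 5, dimnames = dimnames(sims))
    R <- enforce_single_cardinality(M, S)
    expect_true(all(rowSums(R) <= 1))
    expect_true(all(colSums(R) <= 1))
    expect_true(all(R <= M))          # subset of input cells
    expect_lte(sum(R), sum(M))
    # a 1-cell alone in its row and column always survives
    lone_rows <- which(rowSums(M) == 1)
    for (i in lone_rows) {
      j <- which(M[i, ] == 1)
      if (sum(M[, j]) == 1) expect_equal(unname(R[i, j]), 1)
    }
  }
})

test_that("alignment files round-trip through the RDF format and CSV sidecar", {
  A <- new_alignment(data.frame(e1 = c("http://x#a", "http://x#b"),
                                e2 = c("http://y#p", "http://y#q"),
                                conf = c(0.87654321, 1)),
                     source = "SRC", target = "TGT")
  rdf <- withr::local_tempfile(fileext = ".rdf")
  write_alignment(A, rdf)
  back <- read_alignment(rdf)
  expect_equal(as.data.frame(back), as.data.frame(A),
               tolerance = 1e-9)
  expect_equal(attr(back, "source"), "SRC")
  # confidences carry at least 6 decimals in both files
  expect_match(paste(readLines(rdf), collapse = ""), "0\\.8765432")
  csv <- sub("\\.rdf$", ".csv", rdf)
  expect_true(file.exists(csv))
  expect_match(readLines(csv)[2], "0\\.8765432")
  back_csv <- read_alignment(csv)
  expect_equal(back_csv$conf, A$conf, tolerance = 1e-9)

  empty_rdf <- withr::local_tempfile(fileext = ".rdf")
  write_alignment(new_alignment(), empty_rdf)
  expect_equal(nrow(read_alignment(empty_rdf)), 0L)
})

test_that("alignment invariants are enforced at construction", {
  expect_error(new_alignment(data.frame(e1 = "a", e2 = "b", conf = 1.2)),
               "\\[0, 1\\]")
  expect_error(new_alignment(data.frame(e1 = c("a", "a"), e2 = c("b", "b"),
                                        conf = c(0.5, 0.6))),
               "duplicate")
})
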