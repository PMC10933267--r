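test_that("correlation matrix has the expected structure and exact values", {
  m <- rbind(b1 = c(1, 2, 3), b2 = c(3, 2, 1), b3 = c(1, 2, 3.0001),
             b4 = c(2, 5, 4))
  cl <- correlation_cluster(m)
  expect_equal(cl$correlation["b1", "b2"], -1, tolerance = 1e-12)
  expect_true(all(abs(cl$correlation) <= 1 + 1e-12))
  expect_equal(diag(cl$correlation), c(b1 = 1, b2 = 1, b3 = 1, b4 = 1))
  expect_equal(cl$correlation, t(cl$correlation))
  # near-identical rows merge first at near-zero height
  expect_lt(cl$hclust$height[1], 1e-3)
  first <- rownames(m)[-cl$hclust$merge[1, ]]
  expect_setequal(first, c("b1", "b3"))
})

test_that("identical bait rows have correlation 1 and merge at height 0", {
  m <- rbind(a = c(5, 1, 2), b = c(5, 1, 2), c = c(9, 4, 0))
  cl <- correlation_cluster(m)
  expect_equal(cl$correlation["a", "b"], 1)
  expect_equal(cl$hclust$height[1], 0)
})

test_that("constant bait rows are excluded from clustering with a warning", {
  m <- rbind(a = c(1, 2, 3), b = c(4, 4, 4), c = c(3, 1, 2))
  expect_warning(cl <- correlation_cluster(m), "constant")
  expect_identical(cl$excluded, "b")
  expect_true(all(is.na(cl$correlation["b", ])))
  expect_setequal(cl$hclust$labels, c("a", "c"))
  expect_match(cl$newick, "a")
})

test_that("Ward linkage heights match a brute-force variance-increase oracle", {
  set.seed(6)
  for (trial in 1:5) {
    X <- matrix(rnorm(5 * 4, sd = 3), 5, 4,
                dimnames = list(paste0("b", 1:5), NULL))
    hc <- stats::hclust(stats::dist(X), method = "ward.D2")
    expect_equal(sort(hc$height), oracle_ward_heights(X),
                 tolerance = 1e-9)
  }
})

test_that("method overlap partitions the prey union", {
  got <- method_overlap(c("A", "B", "C"), c("B", "C", "D"))
  expect_identical(got, c(only_bioid = 1L, both = 2L, only_apms = 1L))
  same <- method_overlap(c("A", "B"), c("B", "A"))
  expect_identical(same, c(only_bioid = 0L, both = 2L, only_apms = 0L))
  # counts sum to the union size, also via data.frame input
  bio <- data.frame(bait_id = c("x", "y"), prey_id = c("A", "B"))
  ap <- data.frame(bait_id = "z", prey_id = c("B", "E"))
  got2 <- method_overlap(bio, ap)
  expect_identical(sum(got2), length(union(c("A", "B"), c("B", "E"))))
})

test_that("prey sharing counts baits per prey and ranks hubs", {
  hci <- data.frame(
    bait_id = c("b1", "b2", "b3", "b1", "b4", "b5", "b1"),
    prey_id = c("X", "X", "X", "Y", "Y", "Z", "Z"))
  sh <- prey_sharing(hci)
  expect_identical(sh$n_baits[sh$prey_id == "X"], 3L)
  expect_identical(sh$n_baits[sh$prey_id == "Z"], 2L)
  expect_identical(attr(sh, "hubs"), "X")
  # a prey in every bait set counts n; duplicates within a bait count once
  dup <- rbind(hci, data.frame(bait_id = "b1", prey_id = "X"))
  expect_identical(prey_sharing(dup)$n_baits[1], 3L)
})

test_that("novelty annotation partitions HCIs against known-PPI lists", {
  hci <- data.frame(bait_id = rep("b1", 10),
                    prey_id = sprintf("p%02d", 1:10))
  known <- data.frame(bait_id = "b1", prey_id = c("p01", "p02", "p03"))
  nv <- novelty_annotation(hci, known)
  expect_identical(nv$per_bait$n_known, 3L)
  expect_identical(nv$per_bait$n_novel, 7L)
  # empty known list -> all novel; full list -> zero novel
  all_novel <- novelty_annotation(hci, known[0, ])
  expect_identical(all_novel$per_bait$n_novel, 10L)
  none_novel <- novelty_annotation(hci, hci)
  expect_identical(none_novel$per_bait$n_novel, 0L)
})

test_that("Fisher p-values match exhaustive hypergeometric enumeration", {
  # the worked 2x2 example
  expect_equal(oracle_fisher(8, 2, 1, 9), 0.005477, tolerance = 1e-4)
  study <- setNames(lapply(1:10, function(i)
    if (i <= 8) "prey" else "none"), paste0("s", 1:10))
  ref <- setNames(lapply(1:10, function(i)
    if (i <= 1) "prey" else "none"), paste0("r", 1:10))
  got <- fisher_vs_reference(study, ref, preys = "prey")
  expect_equal(got$p, oracle_fisher(8, 2, 1, 9), tolerance = 1e-10)
  expect_identical(got$direction, "over")

  # equal proportions -> p = 1
  s2 <- setNames(lapply(1:10, function(i)
    if (i <= 5) "q" else "none"), paste0("s", 1:10))
  r2 <- setNames(lapply(1:10, function(i)
    if (i <= 5) "q" else "none"), paste0("rr", 1:10))
  expect_equal(fisher_vs_reference(s2, r2, preys = "q")$p, 1)

  # random tables with margins <= 30 against the enumeration oracle
  set.seed(12)
  for (i in 1:100) {
    a <- sample(0:15, 1); b <- sample(0:15, 1)
    c <- sample(0:15, 1); d <- sample(0:15, 1)
    if (a + b == 0 || c + d == 0) next
    p_impl <- stats::fisher.test(matrix(c(a, b, c, d), 2,
                                        byrow = TRUE))$p.value
    expect_equal(p_impl, oracle_fisher(a, b, c, d), tolerance = 1e-10)
  }
})

test_that("BH adjustment is monotone in p-rank and at least p", {
  study <- split(sprintf("p%02d", c(1:10, 1:6, 1:3)),
                 rep(c("s1", "s2", "s3"), c(10, 6, 3)))
  ref <- split(sprintf("p%02d", c(7:10, 9:10)),
               rep(c("r1", "r2"), c(4, 2)))
  got <- fisher_vs_reference(study, ref)
  got <- got[order(got$p), ]
  expect_true(all(diff(got$q) >= -1e-12))
  expect_true(all(got$q >= got$p - 1e-12))
  expect_error(fisher_vs_reference(study, list()), "zero-size")
})

test_that("expression cross-referencing applies the strict RPKM threshold", {
  expr <- data.frame(
    gene_id = rep(c("g1", "g2", "g3", "g4", "g5"), each = 2),
    stage = rep(c("zygote", "8cell"), 5),
    rpkm = c(0, 0,  0.2, 1.0,  0.5, 3,  2, 0.1,  5, 9))
  res <- expression_crossref(paste0("g", 1:5), expr, threshold = 1)
  # g1 all zero: excluded; g2 max exactly 1.0 under strict >: excluded
  expect_setequal(res$retained, c("g3", "g4", "g5"))
  expect_identical(res$n, 3L)
  incl <- expression_crossref(paste0("g", 1:5), expr, threshold = 1,
                              strict = FALSE)
  expect_true("g2" %in% incl$retained)
  miss <- expression_crossref(c("g1", "absent"), expr)
  expect_identical(miss$missing, "absent")
})

test_that("interactome matrix fills missing bait-prey cells with zero", {
  x <- data.frame(bait_id = c("b1", "b1", "b2"),
                  prey_id = c("pA", "pB", "pB"),
                  avg_spec = c(5, 2, 7))
  m <- interactome_matrix(x)
  expect_equal(m["b2", "pA"], 0)
  expect_equal(m["b1", "pA"], 5)
  expect_identical(dim(m), c(2L, 2L))
})
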