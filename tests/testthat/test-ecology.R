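abund_tbl <- function(m, ids = sprintf("s%d", seq_len(nrow(m)))) {
  colnames(m) <- colnames(m) %||% sprintf("f%d", seq_len(ncol(m)))
  dplyr::bind_cols(tibble::tibble(sample_id = ids), tibble::as_tibble(m))
}

test_that("alpha diversity matches closed forms", {
  x <- abund_tbl(rbind(c(0.25, 0.25, 0.25, 0.25),
                       c(1, 0, 0, 0),
                       c(0.5, 0.25, 0.25, 0)))
  ad <- alpha_diversity(x)
  expect_equal(ad$richness, c(4L, 1L, 3L))
  expect_equal(ad$shannon[1], log(4), tolerance = 1e-12)
  expect_equal(ad$pielou[1], 1, tolerance = 1e-12)
  expect_equal(ad$shannon[2], 0)
  expect_equal(ad$pielou[2], 0)
  expect_equal(ad$shannon[3], 1.0397, tolerance = 1e-4)
  expect_equal(ad$pielou[3], 1.0397208 / log(3), tolerance = 1e-6)
  expect_warning(alpha_diversity(abund_tbl(rbind(c(0, 0), c(1, 1)))),
                 "all-zero")
})

test_that("Bray-Curtis matches its definition and properties", {
  x <- abund_tbl(rbind(c(1, 2, 3), c(3, 2, 1), c(1, 2, 3)))
  d <- as.matrix(bray_curtis(x))
  expect_equal(d["s1", "s2"], 4 / 12, tolerance = 1e-12)
  expect_equal(d["s1", "s3"], 0)
  disjoint <- abund_tbl(rbind(c(1, 1, 0, 0), c(0, 0, 2, 2)))
  expect_equal(as.numeric(bray_curtis(disjoint)), 1)

  # symmetry, bounds, scale invariance
  withr::with_seed(5, {
    m <- matrix(rexp(60), 6, 10)
    d1 <- as.matrix(bray_curtis(abund_tbl(m)))
    expect_equal(d1, t(d1))
    expect_true(all(d1 >= 0 & d1 <= 1))
    d2 <- as.matrix(bray_curtis(abund_tbl(7 * m)))
    expect_equal(d1, d2, tolerance = 1e-12)
  })

  expect_error(bray_curtis(abund_tbl(rbind(c(-1, 1), c(1, 1)))),
               "non-negative")
  expect_warning(bray_curtis(abund_tbl(rbind(c(0, 0), c(0, 0), c(1, 1)))),
                 "all-zero")
  # outlier exclusion drops samples before computing
  d3 <- bray_curtis(x, exclude = "s3")
  expect_equal(attr(d3, "Size"), 2L)
})

test_that("PCoA reproduces Euclidean configurations and PCA", {
  withr::with_seed(9, {
    pts <- cbind(rnorm(8), rnorm(8))
    d <- stats::dist(pts)
    attr(d, "Labels") <- sprintf("s%d", 1:8)
    ord <- pcoa(d)
    co <- as.matrix(ord$coordinates[-1])
    expect_equal(as.matrix(stats::dist(co)),
                 unname(as.matrix(d)), tolerance = 1e-9,
                 ignore_attr = TRUE)
    # equivalence with PCA scores up to sign
    pc <- prcomp(pts)$x
    for (j in 1:2) {
      expect_equal(abs(co[, j]), abs(pc[, j]), tolerance = 1e-9,
                   ignore_attr = TRUE)
    }
  })
})

test_that("PCoA handles degenerate and collinear configurations", {
  d0 <- as.dist(matrix(0, 4, 4))
  ord0 <- pcoa(d0)
  expect_equal(ncol(ord0$coordinates), 1)  # no retained axes
  expect_true(all(abs(ord0$eigenvalues) < 1e-12))

  dc <- stats::dist(c(0, 1, 3))
  ordc <- pcoa(dc)
  expect_equal(length(ordc$proportion_explained), 1)
  gaps <- diff(sort(ordc$coordinates$Axis1))
  expect_equal(gaps[2] / gaps[1], 2, tolerance = 1e-9)

  expect_error(pcoa(stats::dist(c(0, 1))), ">= 3")
})

test_that("factor fitting recovers perfect splits and stays null-calibrated", {
  # 12 + 12 samples: a chance permutation recreating the exact split (which
  # would tie the observed r2) has probability 2/choose(24,12) per draw
  withr::with_seed(61, {
    co <- tibble::tibble(
      sample_id = sprintf("s%d", 1:24),
      Axis1 = c(rep(-1, 12), rep(1, 12)) + rnorm(24, 0, 1e-3),
      Axis2 = rnorm(24, 0, 1e-3))
  })
  labs <- rep(c("a", "b"), each = 12)
  fit <- factor_fit(co, labs, n_perm = 9999, seed = 1)
  expect_gt(fit$effect, 0.99)
  expect_equal(fit$p_raw, 1e-4)

  # identical centroids and spread: r2 near zero
  co2 <- tibble::tibble(sample_id = sprintf("s%d", 1:40),
                        Axis1 = rep(rnorm(20), 2),
                        Axis2 = rep(rnorm(20), 2))
  fit2 <- factor_fit(co2, rep(c("a", "b"), each = 20), n_perm = 199,
                     seed = 2)
  expect_lt(fit2$effect, 0.01)

  expect_error(factor_fit(co, rep("a", 24)), "2 groups")
})

test_that("factor_fit agrees with vegan envfit on the same coordinates", {
  withr::with_seed(31, {
    co <- matrix(rnorm(40), 20, 2)
    labs <- rep(c("a", "b"), each = 10)
    ours <- factor_fit(abund_tbl(co) %>%
                         dplyr::rename(Axis1 = f1, Axis2 = f2),
                       labs, n_perm = 499, seed = 3)
    ef <- vegan::envfit(co, data.frame(g = factor(labs)), permutations = 0)
    expect_equal(ours$effect, unname(ef$factors$r), tolerance = 1e-10)
  })
})

test_that("vector fitting finds direction and r2 of linear gradients", {
  withr::with_seed(13, {
    co <- tibble::tibble(sample_id = sprintf("s%d", 1:15),
                         Axis1 = rnorm(15), Axis2 = rnorm(15))
    f1 <- vector_fit(co, co$Axis1, n_perm = 199, seed = 1)
    expect_equal(f1$effect, 1, tolerance = 1e-12)
    dir1 <- f1$direction[[1]]
    expect_equal(abs(dir1[1]), 1, tolerance = 1e-9)
    expect_equal(dir1[2], 0, tolerance = 1e-9, ignore_attr = TRUE)

    # equal mix of both axes (orthonormalised to make the maths exact)
    q <- qr.Q(qr(cbind(co$Axis1 - mean(co$Axis1),
                       co$Axis2 - mean(co$Axis2))))
    co2 <- tibble::tibble(sample_id = co$sample_id,
                          Axis1 = q[, 1], Axis2 = q[, 2])
    f2 <- vector_fit(co2, q[, 1] + q[, 2], n_perm = 199, seed = 1)
    expect_equal(abs(f2$direction[[1]]), c(1, 1) / sqrt(2),
                 tolerance = 1e-9, ignore_attr = TRUE)
    expect_error(vector_fit(co, rep(1, 15)), "constant")
  })
})

test_that("vector_fit agrees with vegan envfit vectors", {
  withr::with_seed(37, {
    co <- matrix(rnorm(40), 20, 2)
    y <- co[, 1] + 0.5 * co[, 2] + rnorm(20, 0, 0.3)
    ours <- vector_fit(abund_tbl(co) %>%
                         dplyr::rename(Axis1 = f1, Axis2 = f2),
                       y, n_perm = 499, seed = 5)
    ef <- vegan::envfit(co, data.frame(y = y), permutations = 0)
    expect_equal(ours$effect, unname(ef$vectors$r), tolerance = 1e-10)
  })
})

test_that("mantel correlation is exact under identity and monotone maps", {
  withr::with_seed(41, {
    pts <- matrix(rnorm(20), 10, 2)
    d <- stats::dist(pts)
    m1 <- mantel_test(d, d, n_perm = 99, seed = 1)
    expect_equal(m1$effect, 1)
    m2 <- mantel_test(d, d^2, n_perm = 99, seed = 1)  # monotone transform
    expect_equal(m2$effect, 1)
    expect_gte(m1$p_raw, 1 / 100)

    d2 <- stats::dist(matrix(rnorm(20), 10, 2))
    ours <- mantel_test(d, d2, n_perm = 499, seed = 7)
    vg <- vegan::mantel(d, d2, method = "spearman", permutations = 0)
    expect_equal(ours$effect, unname(vg$statistic), tolerance = 1e-10)

    dm <- as.matrix(d2); rownames(dm) <- colnames(dm) <- letters[1:10]
    da <- as.matrix(d); rownames(da) <- colnames(da) <- LETTERS[1:10]
    expect_error(mantel_test(da, dm), "ids")
    expect_error(mantel_test(stats::dist(c(0, 1, 3)),
                             stats::dist(c(0, 1, 4))), ">= 4")
  })
})

test_that("UPGMA trees have expected heights, topology and order invariance", {
  d2 <- matrix(c(0, 3, 3, 0), 2, 2,
               dimnames = list(c("A", "B"), c("A", "B")))
  tr2 <- upgma(d2)
  expect_equal(sort(tr2$tip.label), c("A", "B"))
  expect_equal(unname(tr2$edge.length), c(1.5, 1.5))

  d3 <- matrix(c(0, 1, 10,
                 1, 0, 10,
                 10, 10, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr3 <- upgma(d3)
  # A and B join first: C is the outgroup
  ab <- ape::getMRCA(tr3, c("A", "B"))
  expect_equal(ab, 5L)  # internal node below the root

  perm <- c("C", "A", "B")
  tr3p <- upgma(d3[perm, perm])
  expect_true(ape::all.equal.phylo(tr3, tr3p))

  nw <- tempfile(fileext = ".nwk")
  write_newick(tr3, nw)
  expect_true(ape::all.equal.phylo(ape::read.tree(nw), tr3))
})

test_that("autoscaling and presence filtering follow their rules", {
  x <- abund_tbl(cbind(f1 = c(1, 2, 3), f2 = c(5, 5, 5), f3 = c(0, 1, 4)))
  expect_warning(sc <- autoscale(x), "constant")
  expect_false("f2" %in% names(sc))
  expect_equal(sc$f1, c(-1, 0, 1))
  expect_equal(colMeans(as.matrix(sc[-1])), c(f1 = 0, f3 = 0),
               tolerance = 1e-12)
  # idempotence
  sc2 <- autoscale(sc)
  expect_equal(as.matrix(sc2[-1]), as.matrix(sc[-1]), tolerance = 1e-12)

  # inclusive >= 50% presence boundary at 15/30 and 14/30
  m <- matrix(0, 30, 2, dimnames = list(NULL, c("keep", "drop")))
  m[1:15, 1] <- 1
  m[1:14, 2] <- 1
  pf <- presence_filter(abund_tbl(m), 0.5)
  expect_true("keep" %in% names(pf))
  expect_false("drop" %in% names(pf))
  pf0 <- presence_filter(abund_tbl(m), 0)
  expect_equal(ncol(pf0), 3)

  # min-shift makes autoscaled data Bray-Curtis compatible
  shifted <- min_shift_nonneg(sc)
  expect_true(all(as.matrix(shifted[-1]) >= 0))
  expect_s3_class(suppressWarnings(bray_curtis(shifted)), "dist")
})
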