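mk_mats <- function(meth_rows, geno_rows, inds) {
  meth <- do.call(rbind, meth_rows)
  geno <- do.call(rbind, geno_rows)
  colnames(meth) <- colnames(geno) <- inds
  rownames(meth) <- paste0("chr1:", seq_len(nrow(meth)) * 50 + 5)
  rownames(geno) <- paste0("chr1:", seq_len(nrow(geno)) * 50)
  list(meth = meth, geno = geno,
       pairs = data.frame(cpg = rownames(meth)[seq_len(min(nrow(meth), nrow(geno)))],
                          snp = rownames(geno)[seq_len(min(nrow(meth), nrow(geno)))]))
}

test_that("the exact additive case fits slope 100 through the origin", {
  m <- mk_mats(list(c(0, 50, 100)), list(c(0, 0.5, 1)), c("i1", "i2", "i3"))
  fits <- suppressWarnings(fit_genotype_models(m$meth, m$geno, m$pairs))
  expect_equal(nrow(fits), 1)
  expect_equal(fits$slope, 100, tolerance = 1e-9)
  expect_equal(fits$intercept, 0, tolerance = 1e-9)
  expect_lt(fits$p, 1e-6)
})

test_that("OLS estimates equal the closed-form normal-equation oracle", {
  set.seed(31)
  for (rep in 1:25) {
    n <- sample(4:8, 1)
    g <- sample(c(0, 0.5, 1), n, replace = TRUE)
    if (length(unique(g)) < 2) next
    y <- 30 + 40 * g + rnorm(n, 0, 30)
    y <- y - mean(y) + 50  # keep sd high enough to pass the filter
    y <- y * (30 / max(sd(y), 1e-9))
    m <- mk_mats(list(y), list(g), paste0("i", seq_len(n)))
    fits <- fit_genotype_models(m$meth, m$geno, m$pairs, sd_min = 0)
    beta <- cov(g, y) / var(g)
    alpha <- mean(y) - beta * mean(g)
    expect_equal(fits$slope, beta, tolerance = 1e-9)
    expect_equal(fits$intercept, alpha, tolerance = 1e-9)
    # ANOVA F p equals the analytic F-tail for the simple regression
    rss1 <- sum((y - alpha - beta * g)^2)
    rss0 <- sum((y - mean(y))^2)
    f <- (rss0 - rss1) / (rss1 / (n - 2))
    expect_equal(fits$p, pf(f, 1, n - 2, lower.tail = FALSE), tolerance = 1e-9)
  }
})

test_that("the F-test is invariant under allele relabelling (g -> 1 - g)", {
  set.seed(5)
  g <- c(0, 0, 0.5, 0.5, 1, 1)
  y <- c(10, 20, 40, 60, 80, 95)
  m1 <- mk_mats(list(y), list(g), paste0("i", 1:6))
  m2 <- mk_mats(list(y), list(1 - g), paste0("i", 1:6))
  f1 <- fit_genotype_models(m1$meth, m1$geno, m1$pairs)
  f2 <- fit_genotype_models(m2$meth, m2$geno, m2$pairs)
  expect_equal(f1$p, f2$p, tolerance = 1e-12)
  expect_equal(f1$slope, -f2$slope, tolerance = 1e-9)
})

test_that("low-variance CpGs and monomorphic SNPs are filtered out", {
  m <- mk_mats(list(c(50, 52, 55, 51), c(0, 40, 80, 99)),
               list(c(0, 0.5, 1, 0.5), c(0.5, 0.5, 0.5, 0.5)),
               paste0("i", 1:4))
  fits <- fit_genotype_models(m$meth, m$geno, m$pairs, sd_min = 25)
  expect_equal(nrow(fits), 0)  # first pair fails sd, second fails genotypes
})

test_that("prediction is exact for a training point of a perfect fit and degenerate inputs behave", {
  m <- mk_mats(list(c(0, 50, 100)), list(c(0, 0.5, 1)), c("i1", "i2", "i3"))
  fits <- suppressWarnings(fit_genotype_models(m$meth, m$geno, m$pairs))
  # two perfect pairs are needed for a defined R^2
  fits2 <- rbind(fits, fits)
  fits2$cpg[2] <- "chr1:999"; fits2$snp[2] <- "chr1:900"
  g <- c("chr1:50" = 1, "chr1:900" = 0)
  obs <- c("chr1:55" = 100, "chr1:999" = 0)
  pred <- predict_methylation(fits2, g, obs)
  expect_true(pred$defined)
  expect_equal(pred$r2, 1, tolerance = 1e-9)
  expect_equal(pred$table$predicted, c(100, 0), tolerance = 1e-9)
  # all genotypes zero: every prediction collapses to the intercept
  g0 <- c("chr1:50" = 0, "chr1:900" = 0)
  pred0 <- predict_methylation(fits2, g0, obs)
  expect_true(all(abs(pred0$table$predicted - fits2$intercept) < 1e-9))
  # no overlap: flagged undefined
  predNA <- predict_methylation(fits2, c("chrX:1" = 1), obs)
  expect_false(predNA$defined)
})

test_that("held-out prediction from planted effects attains high accuracy", {
  fx <- small_fixture()
  # truth-level check at the model layer: methylation percent equal to
  # 100 * mean propensity of the two haplotypes, genotype from truth
  tr <- fx$hs$truth
  geno_tr <- tr[tr$class == "genotype" & !is.na(tr$cpg_pos), ]
  ids <- fx$ped$id[fx$ped$assayed]
  meth <- sapply(ids, function(id) {
    sapply(seq_len(nrow(geno_tr)), function(i) {
      p1 <- haplotype_propensities(fx$hs, id, "h1", geno_tr$chrom[i])[geno_tr$cpg_pos[i]]
      p2 <- haplotype_propensities(fx$hs, id, "h2", geno_tr$chrom[i])[geno_tr$cpg_pos[i]]
      50 * (p1 + p2)
    })
  })
  geno <- sapply(ids, function(id) {
    h <- fx$hs$haps[[id]]
    idx <- match(geno_tr$snp_id, fx$hs$snps$snp_id)
    (h$h1$alleles[idx] + h$h2$alleles[idx]) / 2
  })
  rownames(meth) <- paste0(geno_tr$chrom, ":", geno_tr$cpg_pos)
  rownames(geno) <- paste0(geno_tr$chrom, ":", geno_tr$snp_pos, "#", geno_tr$snp_id)
  pairs <- data.frame(cpg = rownames(meth), snp = rownames(geno))
  fam <- c("A", "B", "C", "D", "E", "F")
  fits <- suppressWarnings(fit_genotype_models(meth[, fam], geno[, fam], pairs, sd_min = 15))
  expect_gt(sum(fits$significant), 3)
  for (id in c("G", "H")) {
    pred <- predict_methylation(fits, geno[, id], meth[, id])
    expect_true(pred$defined)
    expect_gt(pred$r2, 0.9)  # noiseless truth: the linear model is exact
  }
})

test_that("clustering merges identical profiles first and ranks CpGs by variance", {
  meth <- rbind(c(0, 0, 100, 100), c(10, 10, 90, 95), c(50, 50, 50, 50))
  rownames(meth) <- c("chr1:10", "chr1:20", "chr1:30")
  colnames(meth) <- c("a", "a2", "b", "c")
  cl <- cluster_individuals(meth, top_n = 2)
  expect_setequal(cl$cpgs, c("chr1:10", "chr1:20"))  # constant CpG dropped
  h <- cl$hclust
  first <- sort(h$merge[1, ])
  expect_equal(sort(h$labels[-first]), c("a", "a2"))
  expect_equal(h$height[1], 0)
  expect_match(cl$newick, "^\\(")
  # constant matrix: all heights zero with a warning
  flat <- matrix(50, 5, 3, dimnames = list(paste0("chr1:", 1:5), c("x", "y", "z")))
  expect_warning(cluster_individuals(flat), "zero")
})

test_that("family members cluster together against an unrelated out-group on planted truth", {
  fx <- small_fixture()
  tr <- fx$hs$truth
  eff <- tr[tr$class %in% c("genotype", "imprinted") & !is.na(tr$cpg_pos), ]
  ids <- fx$ped$id[fx$ped$assayed]
  meth <- sapply(ids, function(id) {
    sapply(seq_len(nrow(eff)), function(i) {
      p1 <- haplotype_propensities(fx$hs, id, "h1", eff$chrom[i])[eff$cpg_pos[i]]
      p2 <- haplotype_propensities(fx$hs, id, "h2", eff$chrom[i])[eff$cpg_pos[i]]
      50 * (sum(p1, na.rm = TRUE) + sum(p2, na.rm = TRUE))
    })
  })
  rownames(meth) <- paste0(eff$chrom, ":", eff$cpg_pos)
  cl <- cluster_individuals(meth, top_n = nrow(meth))
  co <- stats::cophenetic(cl$hclust)
  m <- as.matrix(co)
  sons <- mean(m["E", "D"], m["E", "C"], m["F", "D"], m["F", "C"])
  strangers <- mean(c(m["E", "G"], m["E", "H"], m["F", "G"], m["F", "H"]))
  expect_lt(sons, strangers)
})
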