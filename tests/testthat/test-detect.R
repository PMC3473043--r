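test_that("mutual information matches closed forms and the joint-histogram oracle", {
  # two identical binary columns, half 0s half 1s: MI = 1 bit
  b <- structure(list(bits = cbind(rep(0:1, each = 4), rep(0:1, each = 4)),
                      order = 1:8, total_sum = 8), class = "binary_msa")
  m <- mi_matrix(b)
  expect_equal(m[1, 2], 1, tolerance = 1e-12)

  # a constant column against anything: MI = 0
  cc <- cbind(rep(1L, 8), rep(0:1, 4))
  m2 <- mi_matrix(cc)
  expect_equal(m2[1, 2], 0, tolerance = 1e-12)

  # toy alignment vs. brute-force frequency tables
  set.seed(501)
  aln <- random_alignment(6, 3, alphabet = c("A", "C", "D"))
  m3 <- mi_matrix(aln)
  o <- oracle_mi(aln$seqs)
  expect_equal(off_diag(bare(m3)), off_diag(o), tolerance = 1e-12)

  # with gaps, rows are excluded pairwise
  set.seed(502)
  g <- random_alignment(12, 4, alphabet = c("A", "C"), gap_frac = 0.2)
  expect_equal(off_diag(bare(mi_matrix(g))),
               off_diag(oracle_mi_nogap(g$seqs)), tolerance = 1e-12)

  # constant alignment gives an all-zero matrix, not an error
  const <- as_msa(matrix("A", 4, 3))
  expect_true(all(mi_matrix(const) == 0))
})

test_that("average product correction matches the arithmetic oracle", {
  # constant off-diagonal matrix collapses to zero
  m <- matrix(3, 4, 4); diag(m) <- 0
  out <- apc(m)
  expect_equal(off_diag(bare(out)), rep(0, 12), tolerance = 1e-12)

  set.seed(503)
  r <- matrix(runif(25, 1, 2), 5, 5); r <- (r + t(r)) / 2
  expect_equal(off_diag(bare(apc(r))), off_diag(oracle_apc(r)),
               tolerance = 1e-12)

  # corrected row means are near zero relative to the input scale
  rm_out <- sapply(1:5, function(i) mean(bare(apc(r))[i, -i]))
  expect_lt(max(abs(rm_out)), 0.05 * mean(abs(off_diag(r))))
})

test_that("ZPX2 equals the per-row z-score oracle and is nonnegative", {
  m <- matrix(2, 5, 5)
  expect_true(all(off_diag(bare(zpx2(m))) == 0))  # sigma = 0 rule

  set.seed(504)
  r <- matrix(rnorm(16), 4, 4); r <- r + t(r)
  z <- zpx2(r)
  expect_equal(off_diag(bare(z)), off_diag(oracle_zpx2(r)),
               tolerance = 1e-10)
  expect_true(all(off_diag(bare(z)) >= 0))
  expect_error(zpx2(matrix(1, 2, 2)), "at least 3")
})

test_that("ZPX2 is invariant under simultaneous row/column permutation", {
  set.seed(505)
  r <- matrix(rnorm(49), 7, 7); r <- r + t(r)
  perm <- sample(7)
  expect_equal(bare(zpx2(r[perm, perm])),
               bare(zpx2(r))[perm, perm], tolerance = 1e-12)
})

test_that("binary covariance matches the textbook oracle", {
  set.seed(506)
  bits <- matrix(rbinom(50, 1, 0.4), 10, 5)
  b <- structure(list(bits = bits, order = 1:10, total_sum = sum(bits)),
                 class = "binary_msa")
  expect_equal(bare(binary_covariance(b)), oracle_cov(bits),
               tolerance = 1e-12)
  # identical columns: diagonal variance appears at the pair
  eq <- cbind(bits[, 1], bits[, 1])
  expect_equal(stats::var(bits[, 1]),
               bare(binary_covariance(eq))[1, 2], tolerance = 1e-12)
  # constant columns covary with nothing
  expect_true(all(binary_covariance(cbind(rep(1, 6), rep(0, 6))) == 0))
})

test_that("global covariance collapse takes block Frobenius norms", {
  set.seed(507)
  aln <- random_alignment(10, 10)
  gb <- global_diff_binary(aln, as.integer(resort_order(aln)))
  full <- expanded_covariance(gb)
  expect_equal(dim(full), c(210L, 210L))
  col <- collapse_global_cov(gb)
  expect_equal(dim(col), c(10L, 10L))
  # oracle: per-block norms of the full covariance
  for (i in c(1, 4)) for (j in c(2, 10)) {
    blk <- full[(i - 1) * 21 + 1:21, (j - 1) * 21 + 1:21]
    expect_equal(col[i, j], sqrt(sum(blk^2)), tolerance = 1e-10)
  }
  expect_true(all(col >= 0))
  expect_error(collapse_global_cov(matrix(0, 4, 20)), "divisible")
})

test_that("MI/COV merging rescales by least squares", {
  set.seed(508)
  mi <- matrix(runif(36), 6, 6); mi <- (mi + t(mi)) / 2; diag(mi) <- 0
  # cov identical to mi: merged is mi (a = 1, b = 0)
  expect_equal(bare(merge_mi_cov(mi, mi)), mi, tolerance = 1e-12)
  # cov = 2 * mi: regression rescales, merged is again mi
  expect_equal(bare(merge_mi_cov(mi, 2 * mi)), mi, tolerance = 1e-12)
  # random pair: coefficients match the closed-form least squares
  cv <- matrix(runif(36), 6, 6); cv <- (cv + t(cv)) / 2; diag(cv) <- 0
  x <- cv[upper.tri(cv)]; y <- mi[upper.tri(mi)]
  a <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  b <- mean(y) - a * mean(x)
  expect_equal(bare(merge_mi_cov(mi, cv)), (mi + a * cv + b) / 2,
               tolerance = 1e-12)
  expect_warning(merge_mi_cov(mi, matrix(1, 6, 6)), "degenerate")
})

test_that("composite binary pipelines equal their manual composition", {
  set.seed(509)
  ev <- evolve_msa(sim_config(n_pos = 30, branching = c(4, 5),
                              cycles = c(40, 4), mut_prob = 0.03,
                              n_covarions = 3, rec_prob = 0.05,
                              crossovers = c(10, 20), n_seq = 24),
                   seed = 99)
  aln <- ev$msa
  ord <- resort_order(aln)
  b <- diff_binary(aln, ord)

  manual_db <- zpx2(merge_mi_cov(mi_matrix(b), binary_covariance(b)))
  expect_equal(bare(db_zpx2(aln)), bare(manual_db), tolerance = 1e-12)

  gb <- global_diff_binary(aln, ord)
  manual_dgb <- zpx2(merge_mi_cov(mi_matrix(b), collapse_global_cov(gb)))
  expect_equal(bare(dgb_zpx2(aln)), bare(manual_dgb),
               tolerance = 1e-12)

  manual_nb <- zpx2(mi_matrix(normal_binary(aln, ord)))
  expect_equal(bare(nb_zpx2(aln)), bare(manual_nb), tolerance = 1e-12)

  # deterministic: a second run gives the identical matrix
  expect_identical(bare(db_zpx2(aln)), bare(db_zpx2(aln)))
})

test_that("composite pipelines return all-zero scores for identical sequences", {
  dup <- as_msa(matrix(rep(c("A", "C", "D", "E", "F"), each = 4), 4, 5))
  # the covariance term is degenerate (all-zero bits), which the merge
  # step reports before falling back to the MI matrix
  expect_true(all(suppressWarnings(db_zpx2(dup)) == 0))
  expect_true(all(suppressWarnings(dgb_zpx2(dup)) == 0))
  expect_true(all(nb_zpx2(dup) == 0))
})

test_that("strong covarions rank at the top of the composite scores", {
  # 100 x 60 simulated MSAs with 5 covarion pairs: all 5 pairs should
  # appear within the top 15 scores in at least 80% of replicates
  top15_hit <- c(db = 0, dgb = 0, nb = 0)
  n_rep <- 10
  for (s in seq_len(n_rep)) {
    cfg <- sim_config(n_pos = 60, branching = c(5, 19), cycles = c(280, 5),
                      mut_prob = 0.021, n_covarions = 5, cov_prob = 0.05,
                      rec_prob = 0.01, crossovers = c(20, 40), n_seq = 100)
    ev <- evolve_msa(cfg, seed = 9000 + s)
    tp <- ev$record$covarion_pairs
    for (mth in names(top15_hit)) {
      sc <- switch(mth, db = db_zpx2(ev$msa), dgb = dgb_zpx2(ev$msa),
                   nb = nb_zpx2(ev$msa))
      ut <- which(upper.tri(sc), arr.ind = TRUE)
      o <- order(-sc[ut], ut[, 1], ut[, 2])
      top <- ut[o[1:15], , drop = FALSE]
      allin <- all(apply(tp, 1, function(pr)
        any(top[, 1] == min(pr) & top[, 2] == max(pr))))
      top15_hit[mth] <- top15_hit[mth] + allin
    }
  }
  expect_gte(top15_hit["db"], 0.8 * n_rep)
  expect_gte(top15_hit["dgb"], 0.8 * n_rep)
  expect_gte(top15_hit["nb"], 0.8 * n_rep)
})

test_that("OMES matches contingency-table computations", {
  # perfectly coupled two-symbol columns over 8 rows
  aln <- as_msa(cbind(rep(c("A", "C"), each = 4), rep(c("D", "E"), each = 4)))
  sc <- omes(aln)
  # obs 4 vs exp 2 in two cells: 2 * (4-2)^2 / 8 = 1
  expect_equal(sc[1, 2], 1, tolerance = 1e-12)

  # invariant column pair scores zero
  const <- as_msa(cbind(rep("A", 8), rep("D", 8)))
  expect_equal(bare(omes(const))[1, 2], 0)

  set.seed(510)
  r <- random_alignment(10, 4, alphabet = c("A", "C", "D"), gap_frac = 0.15)
  expect_equal(off_diag(bare(omes(r))), off_diag(oracle_omes(r$seqs)),
               tolerance = 1e-10)

  # independent uniform columns, large n: score tends to zero
  set.seed(511)
  big <- as_msa(cbind(sample(c("A", "C"), 4000, TRUE),
                      sample(c("D", "E"), 4000, TRUE)))
  expect_lt(bare(omes(big))[1, 2], 0.1)
})

test_that("score matrices are symmetric with the diagonal convention", {
  set.seed(512)
  aln <- random_alignment(12, 8)
  for (sc in list(mi_matrix(aln), omes(aln), nb_zpx2(aln))) {
    m <- bare(sc)
    expect_equal(m, t(m), tolerance = 1e-12)
    expect_equal(unique(diag(m)), min(off_diag(m)), tolerance = 1e-12)
  }
})
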