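# Shortest Hamming distance to the significance boundary: moves, the fast
# walk algorithm, the BFS oracle, and the sensitivity audit.

test_that("legal move sets match the lattice geometry", {
  # interior point: all six single-individual changes
  mv <- legal_moves(3, 4, 10)
  expect_equal(nrow(mv), 6)
  expect_setequal(paste(mv$dr0, mv$dr1),
                  c("1 0", "1 -1", "0 -1", "-1 0", "-1 1", "0 1"))
  # corner (R, 0): only r0 can donate
  mv <- legal_moves(10, 0, 10)
  expect_setequal(paste(mv$dr0, mv$dr1), c("-1 0", "-1 1"))
  # corner (0, 0): only r2 can donate
  mv <- legal_moves(0, 0, 10)
  expect_setequal(paste(mv$dr0, mv$dr1), c("1 0", "0 1"))
  # corner (0, R): r1 can donate either way
  mv <- legal_moves(0, 10, 10)
  expect_setequal(paste(mv$dr0, mv$dr1), c("1 -1", "0 -1"))
  expect_error(legal_moves(7, 7, 10), "r0")
})

test_that("each legal move changes x by 1 or 2 and re-genotypes one case", {
  for (r0 in 0:6) for (r1 in 0:(6 - r0)) {
    mv <- legal_moves(r0, r1, 6)
    dx <- 2 * mv$dr0 + mv$dr1
    expect_true(all(abs(dx) %in% c(1, 2)))
    # exactly one genotype class loses one record and another gains one
    dr2 <- -(mv$dr0 + mv$dr1)
    expect_true(all(abs(mv$dr0) + abs(mv$dr1) + abs(dr2) == 2))
  }
})

test_that("fast walk agrees with the BFS oracle across spaces and thresholds", {
  controls <- list(c(40, 40, 20), c(70, 25, 5), c(10, 30, 60))
  for (R in c(3, 6, 9)) for (ct in controls) for (p in c(0.05, 1e-3)) {
    sp <- table_space(R, ct[1], ct[2], ct[3])
    for (i in seq_len(nrow(sp))) {
      f <- hamming_distance(sp$r0[i], sp$r1[i], sp$r2[i],
                            ct[1], ct[2], ct[3], p)
      b <- hamming_distance_bfs(sp$r0[i], sp$r1[i], sp$r2[i],
                                ct[1], ct[2], ct[3], p)
      expect_identical(f$distance, b$distance)
      expect_identical(f$score, b$score)
      expect_identical(f$significant, b$significant)
    }
  }
})

test_that("score sign convention follows the significance status", {
  thr <- chi2_threshold(0.05)
  sp <- table_space(8, 40, 40, 20)
  for (i in seq_len(nrow(sp))) {
    res <- hamming_distance(sp$r0[i], sp$r1[i], sp$r2[i], 40, 40, 20, thr)
    sig <- allelic_chi2(sp$r0[i], sp$r1[i], sp$r2[i], 40, 40, 20) >= thr$c
    expect_identical(res$significant, sig)
    expect_gte(res$distance, 1L)
    if (sig) {
      expect_identical(res$score, res$distance - 1L)
      expect_gte(res$score, 0L)
    } else {
      expect_identical(res$score, -res$distance)
      expect_lt(res$score, 0L)
    }
  }
})

test_that("a significant table one move from the boundary scores h = 0", {
  # find such a table by enumeration, then assert the definition's d+ = 1
  thr <- chi2_threshold(0.05)
  sp <- score_hamming(table_space(10, 40, 40, 20), thr)
  one_away <- dplyr::filter(sp, .data$significant,
                            .data$hamming_distance == 1L)
  expect_gt(nrow(one_away), 0)
  expect_true(all(one_away$hamming == 0L))
  # verify the certificate: some neighbour is insignificant
  for (i in seq_len(nrow(one_away))) {
    mv <- legal_moves(one_away$r0[i], one_away$r1[i], 10)
    nb_sig <- vapply(seq_len(nrow(mv)), function(j) {
      allelic_chi2(one_away$r0[i] + mv$dr0[j], one_away$r1[i] + mv$dr1[j],
                   10 - (one_away$r0[i] + mv$dr0[j]) -
                     (one_away$r1[i] + mv$dr1[j]),
                   40, 40, 20) >= thr$c
    }, logical(1))
    expect_true(any(!nb_sig))
  }
})

test_that("unreachable significance falls back to one step past the corner", {
  # control row at MAF 1/2 with R = 3: the whole space is insignificant at
  # a strict threshold, so h = -(1 + min(d1, d2)) with d1 = r0 + r1,
  # d2 = R - r0
  R <- 3
  sp <- table_space(R, 25, 50, 25)
  for (i in seq_len(nrow(sp))) {
    f <- hamming_distance(sp$r0[i], sp$r1[i], sp$r2[i], 25, 50, 25, 1e-6)
    b <- hamming_distance_bfs(sp$r0[i], sp$r1[i], sp$r2[i],
                              25, 50, 25, 1e-6)
    d1 <- sp$r0[i] + sp$r1[i]
    d2 <- R - sp$r0[i]
    expect_identical(f$score, -(1L + as.integer(min(d1, d2))))
    expect_identical(f$score, b$score)
    expect_match(f$branch, "^corner")
  }
})

test_that("symmetric spaces give distances symmetric under r0 <-> r2", {
  # control MAF 1/2 makes the chi-square profile symmetric about the
  # vertex x = R; swapping r0 and r2 mirrors a table to x -> 2R - x and
  # swaps the roles of the two walks, so distances must match
  R <- 10
  thr <- chi2_threshold(0.05)
  sp <- table_space(R, 25, 50, 25)
  for (i in seq_len(nrow(sp))) {
    a <- hamming_distance(sp$r0[i], sp$r1[i], sp$r2[i], 25, 50, 25, thr)
    b <- hamming_distance(sp$r2[i], sp$r1[i], sp$r0[i], 25, 50, 25, thr)
    expect_identical(a$distance, b$distance)
    expect_identical(a$score, b$score)
  }
})

test_that("significant tables and monomorphic control rows are guarded", {
  # monomorphic control rows are refused
  expect_error(hamming_distance(2, 2, 2, 10, 0, 0, 0.05), "monomorphic",
               ignore.case = TRUE)
  expect_error(hamming_distance(2, 2, 2, 0, 0, 10, 0.05), "monomorphic",
               ignore.case = TRUE)
  # a threshold below the grid minimum leaves no insignificant table
  expect_error(hamming_distance(2, 0, 0, 2, 0, 1, 0.9), "insignificant")
  expect_error(hamming_distance_bfs(2, 0, 0, 2, 0, 1, 0.9), "insignificant")
})

test_that("score is non-increasing as the threshold c grows", {
  sp <- table_space(9, 40, 40, 20)
  ps <- c(0.2, 0.05, 1e-2, 1e-3, 1e-5)   # c increasing
  for (i in seq_len(nrow(sp))) {
    hs <- vapply(ps, function(p) {
      hamming_distance(sp$r0[i], sp$r1[i], sp$r2[i], 40, 40, 20, p)$score
    }, integer(1))
    expect_true(all(diff(hs) <= 0))
  }
})

test_that("panel scoring matches per-table results and is order-equivariant", {
  withr::local_seed(104)
  panel <- simulate_panel(50, 12, 40, seed = 9)
  scored <- score_hamming(panel, 0.05)
  for (i in sample(nrow(panel), 10)) {
    expect_identical(
      scored$hamming[i],
      hamming_distance_bfs(panel$r0[i], panel$r1[i], panel$r2[i],
                           panel$s0[i], panel$s1[i], panel$s2[i],
                           0.05)$score
    )
  }
  perm <- sample(nrow(panel))
  expect_identical(score_hamming(panel[perm, ], 0.05)$hamming,
                   scored$hamming[perm])
  # per-SNP refusal names the SNP
  bad <- dplyr::bind_rows(
    panel[1:2, ],
    tibble::tibble(snp_id = "mono", r0 = 5L, r1 = 0L, r2 = 7L,
                   s0 = 40, s1 = 0, s2 = 0)
  )
  expect_error(score_hamming(bad, 0.05), "mono")
})

test_that("empirical sensitivity is exactly 1 on crossable spaces, never more", {
  withr::local_seed(105)
  for (rep in 1:8) {
    R <- sample(4:14, 1)
    maf <- runif(1, 0.1, 0.5)
    S <- sample(c(50, 100), 1)
    ct <- hwe_control_genotypes(maf, S)
    p <- sample(c(0.05, 1e-3), 1)
    sens <- hamming_sensitivity(R, ct$s0, ct$s1, ct$s2, p)
    expect_lte(sens, 1L)
    scored <- score_hamming(table_space(R, ct$s0, ct$s1, ct$s2), p)
    if (any(scored$significant) && !all(scored$significant)) {
      expect_identical(sens, 1L)
    }
  }
  # R = 1 degenerate space (3 tables)
  expect_lte(hamming_sensitivity(1, 40, 40, 20, 0.05), 1L)
})
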