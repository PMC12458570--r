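bruteRank <- function(v)
  vapply(v, function(x) 1 + sum(v > x) + (sum(v == x) - 1) / 2, numeric(1))

test_that("ranking gives 1 to the largest score and averages ties", {
  expect_equal(rankScores(c(0.9, 0.1, 0.5)), c(1, 3, 2))
  expect_equal(rankScores(c(0.5, 0.5)), c(1.5, 1.5))
  expect_equal(rankScores(42), 1)
  set.seed(9)
  v <- stats::runif(100)
  expect_equal(rankScores(v), bruteRank(v))
  vt <- sample(c(v, v[1:10]))
  expect_equal(rankScores(vt), bruteRank(vt))
  expect_error(rankScores(c(1, NA)), "finite")
  expect_error(rankScores(c(1, Inf)), "finite")
  expect_error(rankScores(numeric()), "non-empty")
})

test_that("informative score is the weighted rank sum with printed defaults", {
  one <- informativeScore(data.frame(s_edv = 1, s_edc = 1, s_blf = 1))
  expect_equal(one$s_i, 1.0)    # rank 1 on all three axes

  # frame with ranks (2, 3, 1) scores 0.4*2 + 0.2*3 + 0.4*1 = 1.8
  df <- data.frame(s_edv = c(0.5, 0.9, 0.1), s_edc = c(0.1, 0.2, 0.3),
                   s_blf = c(9, 5, 1))
  out <- informativeScore(df)
  expect_equal(out$rank_edv[1], 2)
  expect_equal(out$rank_edc[1], 3)
  expect_equal(out$rank_blf[1], 1)
  expect_equal(out$s_i[1], 1.8)
  expect_equal(out$s_i,
               0.4 * out$rank_edv + 0.2 * out$rank_edc + 0.4 * out$rank_blf)

  # rank-sum identity: mean fused score is (n+1)/2 when there are no ties
  set.seed(2)
  for (n in c(5, 17, 40)) {
    d <- data.frame(s_edv = stats::runif(n), s_edc = stats::runif(n),
                    s_blf = stats::runif(n))
    expect_equal(mean(informativeScore(d)$s_i), (n + 1) / 2)
  }

  expect_error(informativeScore(df, weights = c(0.5, 0.2, 0.4)),
               "summing to 1")
  expect_error(informativeScore(df, weights = c(-0.2, 0.6, 0.6)),
               "non-negative|summing")
  expect_error(informativeScore(data.frame(s_edv = 1)), "columns")
})

test_that("top-k selection is complete, order-invariant, and dominance-safe", {
  set.seed(4)
  n <- 12
  d <- data.frame(frame_index = 0:(n - 1), s_edv = stats::runif(n),
                  s_edc = stats::runif(n), s_blf = stats::runif(n))
  out <- informativeScore(d)
  selAll <- selectTopK(out, n)
  expect_setequal(selAll, 0:(n - 1))
  expect_equal(selAll,
               out$frame_index[order(out$s_i, -out$s_edv, out$frame_index)])

  perm <- sample(n)
  outP <- informativeScore(d[perm, ])
  expect_setequal(selectTopK(outP, 4), selectTopK(out, 4))

  # a frame best on every axis wins top-1
  d$s_edv[3] <- 2; d$s_edc[3] <- 2; d$s_blf[3] <- 99
  expect_equal(selectTopK(informativeScore(d), 1), d$frame_index[3])

  # weak dominance on all three raw scores never worsens the fused score
  set.seed(6)
  for (rep in 1:20) {
    dd <- data.frame(frame_index = 0:7, s_edv = stats::runif(8),
                     s_edc = stats::runif(8), s_blf = stats::runif(8))
    oo <- informativeScore(dd)
    for (i in 1:8) for (j in 1:8) {
      if (dd$s_edv[i] >= dd$s_edv[j] && dd$s_edc[i] >= dd$s_edc[j] &&
          dd$s_blf[i] >= dd$s_blf[j])
        expect_lte(oo$s_i[i], oo$s_i[j])
    }
  }

  expect_error(selectTopK(out, 0), "k")
  expect_error(selectTopK(out, n + 1), "k")
})

test_that("top-k ties break by larger view score, then smaller frame index", {
  t2 <- informativeScore(data.frame(frame_index = 0:1,
                                    s_edv = c(0.3, 0.7),
                                    s_edc = c(0.5, 0.5),
                                    s_blf = c(0.7, 0.3)))
  expect_equal(t2$s_i[1], t2$s_i[2])
  expect_equal(selectTopK(t2, 1), 1)

  t3 <- informativeScore(data.frame(frame_index = c(5L, 2L),
                                    s_edv = c(0.5, 0.5),
                                    s_edc = c(0.5, 0.5),
                                    s_blf = c(0.5, 0.5)))
  expect_equal(selectTopK(t3, 1), 2)
})
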