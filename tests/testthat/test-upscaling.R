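test_that("attainable yield applies the 80%/70% factors and checks inputs", {
  expect_equal(attainable_yield(10, "irrigated"), 8.0)
  expect_equal(attainable_yield(7.0, "rainfed_lowland"), 4.9)
  expect_equal(attainable_yield(7.0, "rainfed_upland"), 4.9)
  expect_error(attainable_yield(5, "paddy"), "unknown regime")
  expect_error(attainable_yield(-1, "irrigated"), ">= 0")

  # internal consistency with published regional magnitudes: an irrigated
  # yield potential of 9.9 gives attainable 7.92; a 3.7 gap then amounts to
  # ~47% of attainable
  att <- attainable_yield(9.9, "irrigated")
  expect_equal(att, 7.92)
  expect_equal(round(100 * 3.7 / att), 47)
})

test_that("exploitable gap arithmetic, including closed (negative) gaps", {
  g <- exploitable_gap(6.0, 6.0)
  expect_equal(g$gap, 0)
  g2 <- exploitable_gap(6.0, 2.9)
  expect_equal(g2$gap, 3.1)
  expect_equal(g2$gap_fraction, 3.1 / 6.0)
  g3 <- exploitable_gap(6.0, 7.0)  # farmers above the attainable level
  expect_lt(g3$gap, 0)
  expect_true(g3$closed)
  expect_error(exploitable_gap(0, 1), "> 0")
})

test_that("area-weighted mean matches arithmetic cases and its invariants", {
  expect_equal(area_weighted_mean(c(2, 4, 6), c(1, 1, 1)), 4)
  expect_equal(area_weighted_mean(c(5, 99), c(1, 0)), 5)
  expect_equal(area_weighted_mean(c(4, 10), c(3, 1)), 5.5)
  expect_error(area_weighted_mean(c(1, 2), c(0, 0)), "positive sum")
  expect_error(area_weighted_mean(1:3, 1:2), "length")

  set.seed(31)
  for (i in 1:20) {
    v <- runif(6, -5, 20)
    w <- runif(6, 0.01, 10)
    m <- area_weighted_mean(v, w)
    expect_gte(m, min(v)); expect_lte(m, max(v))
    expect_equal(area_weighted_mean(v, w * 7.3), m)  # weight-scale invariance
  }
})

test_that("stability metrics match hand arithmetic and a literal oracle", {
  s <- stability_metrics(rep(5, 8))
  expect_equal(s$cv, 0)
  expect_equal(s$semidev, 0)

  s2 <- stability_metrics(c(4, 6))
  expect_equal(s2$cv, 100 * sqrt(2) / 5)        # ~28.28%
  expect_equal(s2$semidev, sqrt(0.5))           # ~0.707

  set.seed(8)
  x <- runif(25, 2, 9)
  s3 <- stability_metrics(x)
  dev <- x - mean(x)
  expect_equal(s3$semidev, sqrt(mean(ifelse(dev < 0, dev, 0)^2)))
  expect_equal(s3$cv, 100 * sd(x) / mean(x))
  expect_error(stability_metrics(c(1, -1)), "zero-mean")
  expect_error(stability_metrics(4), "2 years")
})

# Literal step-by-step replay of the selection rules, kept independent of the
# package implementation.
replay_selection <- function(cand, overlaps, national, cz_min = 0.05,
                             max_ov = 0.20, target = 0.50) {
  shares <- sapply(split(cand$area_ha, cand$climate_zone), sum) / national
  cand <- cand[shares[cand$climate_zone] > cz_min, ]
  cand <- cand[order(-cand$area_ha, cand$id), ]
  ov <- function(a, b) {
    hit <- overlaps[(overlaps$id_a == a & overlaps$id_b == b) |
                      (overlaps$id_a == b & overlaps$id_b == a), "fraction"]
    if (length(hit)) max(hit) else 0
  }
  chosen <- character(0); cov <- 0
  for (i in seq_len(nrow(cand))) {
    if (cov >= target) break
    if (all(sapply(chosen, ov, a = cand$id[i]) <= max_ov)) {
      chosen <- c(chosen, cand$id[i])
      cov <- cov + cand$area_ha[i] / national
    }
  }
  chosen
}

test_that("buffer selection handles the canonical hand cases", {
  # one buffer already covering 60% of national area is selected alone
  one <- data.frame(id = "b1", climate_zone = "cz1", area_ha = 60)
  sel <- select_reference_buffers(one, NULL, national_area_ha = 100)
  expect_equal(sel$id, "b1")
  expect_equal(attr(sel, "coverage"), 0.6)

  # second-largest overlaps the first by 30% -> skipped; third (5%) taken
  cand <- data.frame(id = c("b1", "b2", "b3"), climate_zone = "cz1",
                     area_ha = c(40, 30, 20))
  ovl <- data.frame(id_a = c("b1", "b1"), id_b = c("b2", "b3"),
                    fraction = c(0.30, 0.05))
  sel2 <- select_reference_buffers(cand, ovl, national_area_ha = 100)
  expect_equal(sel2$id, c("b1", "b3"))

  expect_error(select_reference_buffers(cand[0, ], NULL, 100), "empty")
})

test_that("greedy selection equals the rule-replay oracle on random candidate sets", {
  for (seed in 1:6) {
    set.seed(seed)
    n <- 8
    cand <- data.frame(id = sprintf("b%02d", 1:n),
                       climate_zone = sample(c("cz1", "cz2", "cz3"), n,
                                             replace = TRUE),
                       area_ha = round(runif(n, 5, 40), 1))
    pairs <- t(combn(cand$id, 2))
    pick <- runif(nrow(pairs)) < 0.3
    ovl <- data.frame(id_a = pairs[pick, 1], id_b = pairs[pick, 2],
                      fraction = round(runif(sum(pick), 0, 0.5), 2))
    national <- sum(cand$area_ha) * 1.5
    sel <- suppressWarnings(
      select_reference_buffers(cand, ovl, national_area_ha = national))
    expect_identical(sel$id, replay_selection(cand, ovl, national))

    # never two selected buffers overlapping by more than 20%
    if (nrow(sel) > 1) {
      for (i in 1:(nrow(sel) - 1)) for (j in (i + 1):nrow(sel)) {
        hit <- ovl[(ovl$id_a == sel$id[i] & ovl$id_b == sel$id[j]) |
                     (ovl$id_a == sel$id[j] & ovl$id_b == sel$id[i]),
                   "fraction"]
        if (length(hit)) expect_lte(max(hit), 0.20)
      }
    }
  }
})

test_that("selection coverage is non-decreasing in the candidate pool and shortfalls warn", {
  cand <- data.frame(id = sprintf("b%d", 1:5), climate_zone = "cz1",
                     area_ha = c(10, 9, 8, 7, 6))
  national <- 200  # even all five cover only 20%
  expect_warning(sel <- select_reference_buffers(cand, NULL, national),
                 "shortfall")
  covs <- sapply(2:5, function(k) {
    attr(suppressWarnings(
      select_reference_buffers(cand[1:k, ], NULL, national)), "coverage")
  })
  expect_true(all(diff(covs) >= 0))
})
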