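test_that("r_squared reproduces worked values and degenerate cases", {
  r <- r_squared(c(1, 1), c(2, 2))
  expect_equal(r$r, -1, tolerance = 1e-12)
  expect_equal(r$r2, 1, tolerance = 1e-12)

  r2 <- r_squared(c(1, 2, 3), c(3, 4, 5))
  expect_equal(r2$r2, 0.6, tolerance = 1e-12)

  expect_equal(r_squared(c(2, 4), c(1, 5))$r2, 0, tolerance = 1e-12)
  expect_error(r_squared(c(1, 1), c(1, 1)), "variance")
  expect_error(r_squared(numeric(0), c(1, 2)), "non-empty")
})

test_that("Eq. r is the point-biserial Pearson correlation (1000 random cases)", {
  set.seed(100)
  for (i in 1:1000) {
    n1 <- sample(2:30, 1); n2 <- sample(2:30, 1)
    w1 <- rnorm(n1, mean = runif(1, -2, 2), sd = runif(1, 0.5, 2))
    w2 <- rnorm(n2, mean = runif(1, -2, 2))
    r <- r_squared(w1, w2)$r
    pearson <- stats::cor(c(w1, w2), c(rep(1, n1), rep(0, n2)))
    expect_equal(r, pearson, tolerance = 1e-10)
  }
})

test_that("r-squared is invariant under affine transforms and antisymmetric in r", {
  set.seed(3)
  w1 <- rnorm(20); w2 <- rnorm(25, 1)
  base <- r_squared(w1, w2)
  tr <- r_squared(-3.2 * w1 + 7, -3.2 * w2 + 7)
  expect_equal(tr$r2, base$r2, tolerance = 1e-12)
  flip <- r_squared(w2, w1)
  expect_equal(flip$r, -base$r, tolerance = 1e-12)
  expect_equal(flip$r2, base$r2, tolerance = 1e-12)
})

make_proj <- function(weights, labels, channel_labels) {
  mon <- default_montage(32)
  structure(list(weights = weights, K = dim(weights)[3], labels = labels,
                 channel_labels = channel_labels,
                 montage = mon[match(channel_labels, mon$label), ]),
            class = "projection_table")
}

test_that("rsq_topography localizes planted effects and stays null without them", {
  set.seed(17)
  chs <- c("C3", "C1", "Cz", "C2", "C4")
  labels <- rep(c("rest", "thumb"), each = 120)
  w <- array(rnorm(240 * 5), c(240, 5, 1))
  w[labels == "thumb", 2, 1] <- w[labels == "thumb", 2, 1] + 2
  mp <- rsq_topography(make_proj(w, labels, chs), pair = c("thumb", "rest"),
                       k_or_band = "PC1")
  expect_equal(mp$channel[which.max(mp$r2)], "C1")
  expect_true(all(mp$r2 >= 0 & mp$r2 <= 1))
  expect_equal(mp$r^2, mp$r2, tolerance = 1e-12)

  # same distribution in both conditions: all r2 small at n >= 100/group
  w0 <- array(rnorm(240 * 5), c(240, 5, 1))
  mp0 <- rsq_topography(make_proj(w0, labels, chs), pair = c("thumb", "rest"),
                        k_or_band = "PC1")
  expect_lt(max(mp0$r2), 0.1)

  # swapping the pair flips r, keeps r2
  mps <- rsq_topography(make_proj(w, labels, chs), pair = c("rest", "thumb"),
                        k_or_band = "PC1")
  expect_equal(mps$r, -mp$r, tolerance = 1e-12)
  expect_error(rsq_topography(make_proj(w, labels, chs),
                              pair = c("thumb", "pinky"), k_or_band = "PC1"),
               "pinky")
})

test_that("channel selection ranks by r2 with stable ties and unions maps", {
  mk_map <- function(r2, chans) {
    df <- data.frame(channel = chans, x = 0, y = 0, r = sqrt(r2), r2 = r2)
    attr(df, "pair") <- c("a", "b"); attr(df, "feature") <- "PC1"
    class(df) <- c("rsq_map", "data.frame")
    df
  }
  chans <- paste0("ch", 1:6)
  m1 <- mk_map(c(0.5, 0.9, 0.1, 0.9, 0.3, 0.05), chans)
  s1 <- select_channels(m1, top_n = 3)
  expect_equal(s1$channels, c("ch1", "ch2", "ch4"))   # tie 0.9 kept in index order
  s2 <- select_channels(list(m1, mk_map(c(0, 0, 0.8, 0, 0.7, 0.9), chans)),
                        top_n = 3)
  expect_setequal(s2$channels, c("ch1", "ch2", "ch3", "ch4", "ch5", "ch6"))
  expect_equal(select_channels(list(m1, m1), top_n = 3)$channels, s1$channels)
  expect_equal(length(select_channels(m1, top_n = 99)$channels), 6)
})

test_that("mu/beta channels come from the annotated C3/C4 neighbourhood", {
  mon <- default_montage(64)
  sel <- mu_beta_channels(mon, hand = "right")
  expect_length(sel$channels, 9)
  expect_true("C3" %in% sel$channels)
  expect_setequal(sel$channels,
                  c("C3", "FC5", "FC3", "FC1", "C5", "C1", "CP5", "CP3", "CP1"))
  sel_l <- mu_beta_channels(mon, hand = "left")
  expect_true("C4" %in% sel_l$channels)

  mon2 <- mon
  attr(mon2, "neighbors") <- NULL
  expect_error(mu_beta_channels(mon2), "neighbour")
  mon3 <- mon[mon$label != "C3", ]
  attr(mon3, "neighbors") <- attr(mon, "neighbors")
  expect_error(mu_beta_channels(mon3), "C3")
})

test_that("topography CSV export round-trips channel values", {
  mon <- default_montage(32)
  df <- data.frame(channel = mon$label[1:5], x = mon$x[1:5], y = mon$y[1:5],
                   r2 = runif(5))
  path <- tempfile(fileext = ".csv")
  write_topography_csv(df, path, value = "r2")
  back <- utils::read.csv(path, stringsAsFactors = FALSE)
  expect_equal(back$channel, df$channel)
  expect_equal(back$value, df$r2, tolerance = 1e-12)
})
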