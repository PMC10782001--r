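binary_profile <- function(id, bits) {
  score_profile(id, "bin", bits, binary = bits)
}
zero_profile <- function(id, L) binary_profile(id, rep(0L, L))

test_that("the eight markers evaluate the worked examples", {
  # L=10, predicted disordered at positions 1-2: the run is shorter than 4 so
  # there is no putative IDR, but the composite still sums over all
  # predicted-disordered residues
  e10 <- ref_entry("p", strrep("A", 10), rep(0L, 10))
  dis <- binary_profile("p", c(1, 1, rep(0, 8)))
  m <- compute_markers(e10, dis, zero_profile("p", 10), zero_profile("p", 10))
  expect_equal(m$composite, (0 + 1) / 10)
  expect_equal(m$n_putative_idrs, 0L)
  expect_equal(m$min_terminus_distance, 11L)
  expect_equal(m$putative_content, 0.2)

  # no predicted disorder at all
  m0 <- compute_markers(e10, zero_profile("p", 10), zero_profile("p", 10),
                        zero_profile("p", 10))
  expect_equal(m0$composite, 0)
  expect_equal(m0$putative_content, 0)
  expect_equal(m0$n_putative_idrs, 0L)
  expect_equal(m0$max_idr_len, 0L)

  # L=5 fully predicted disordered: distances 0,1,2,1,0
  e5 <- ref_entry("q", strrep("A", 5), rep(0L, 5))
  m5 <- compute_markers(e5, binary_profile("q", rep(1L, 5)),
                        zero_profile("q", 5), zero_profile("q", 5))
  expect_equal(m5$composite, 4 / 5)
  expect_equal(m5$n_putative_idrs, 1L)
  expect_equal(m5$max_idr_len, 5L)
  expect_equal(m5$min_terminus_distance, 0L)
})

test_that("composite is bounded by max terminus distance times content", {
  set.seed(17)
  for (rep in 1:40) {
    L <- sample(4:120, 1)
    bits <- sample(0:1, L, replace = TRUE)
    e <- ref_entry("p", strrep("A", L), rep(0L, L))
    m <- compute_markers(e, binary_profile("p", bits), zero_profile("p", L),
                         zero_profile("p", L))
    expect_lte(m$composite, floor((L - 1) / 2) * m$putative_content + 1e-12)
    expect_lte(m$max_idr_len, m$seq_length)
  }
})

test_that("competitive split applies the floor and confidence-bound rules", {
  panel <- matrix(0.9, nrow = 3, ncol = 19,
                  dimnames = list(c("A", "B", "C"), NULL))
  panel["C", ] <- seq(0.70, 0.95, length.out = 19)
  af2 <- c(A = 1.0, B = 0.80, C = NA_real_)
  s <- competitive_split(af2, panel, auc_floor = 0.814)
  expect_equal(s$competitive, "A")      # dominates the panel
  expect_equal(s$rest, "B")             # below the floor regardless of interval
  expect_true("C" %in% s$excluded)      # undefined AUC

  # brute-force oracle over a grid of configurations
  set.seed(23)
  for (rep in 1:30) {
    n <- 25
    ids <- sprintf("P%02d", 1:n)
    af2 <- stats::setNames(runif(n, 0.5, 1), ids)
    panel <- matrix(runif(n * 19, 0.5, 1), n, 19, dimnames = list(ids, NULL))
    floor_ <- 0.75
    s <- competitive_split(af2, panel, floor_)
    manual <- ids[vapply(ids, function(i) {
      lower <- mean(panel[i, ]) - 1.96 * sd(panel[i, ]) / sqrt(19)
      af2[[i]] > floor_ && af2[[i]] >= lower
    }, TRUE)]
    expect_setequal(s$competitive, manual)
    expect_setequal(union(s$competitive, s$rest), ids)
  }
})

test_that("marker distribution comparison detects shifts and degeneracy", {
  set.seed(31)
  n <- 100
  ids <- sprintf("P%03d", 1:(2 * n))
  split <- structure(list(competitive = ids[1:n], rest = ids[(n + 1):(2 * n)]),
                     class = "competitive_split")
  markers <- data.frame(id = ids,
                        shifted = c(rnorm(n, 0), rnorm(n, 2)),
                        same = rnorm(2 * n),
                        constant = rep(3, 2 * n))
  res <- compare_marker_distributions(split, markers)
  expect_lt(res$p_value[res$marker == "shifted"], 0.001)
  expect_gt(res$p_value[res$marker == "same"], 0.05)
  expect_true(res$degenerate[res$marker == "constant"])
  expect_equal(res$p_value[res$marker == "constant"], 1)

  # copied groups: no marker can differ
  split_same <- structure(list(competitive = ids[1:n], rest = ids[1:n]),
                          class = "competitive_split")
  res_same <- compare_marker_distributions(split_same, markers)
  expect_true(all(res_same$p_value > 0.9))
})

test_that("below-median selection is strict and matches a brute-force filter", {
  markers <- data.frame(id = c("A", "B", "C"),
                        seq_length = c(10, 50, 30),
                        composite = c(0.1, 0.5, 0.3))
  med <- c(seq_length = 30, composite = 0.3)
  expect_equal(marker_select(markers, med, c("seq_length", "composite")), "A")
  # C sits exactly on both medians: excluded by strict '<'

  set.seed(41)
  for (rep in 1:20) {
    n <- 50
    mk <- data.frame(id = sprintf("P%02d", 1:n), a = runif(n), b = runif(n))
    med <- c(a = median(mk$a), b = runif(1))
    got <- marker_select(mk, med, c("a", "b"))
    expect_setequal(got, mk$id[mk$a < med["a"] & mk$b < med["b"]])
    # relaxing a median can only grow the set
    med2 <- med; med2["b"] <- med2["b"] + 0.2
    expect_true(all(got %in% marker_select(mk, med2, c("a", "b"))))
  }
})
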