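test_that("collinear chain metrics are exact", {
  m <- cbind(seq(0, 15, by = 0.5), 0, 0)   # 31 sites, spacing 0.5 nm
  met <- conformer_metrics(m)
  expect_equal(met$l_c, 15)
  expect_equal(met$R, 15)
  expect_equal(met$b_c, 0.5)
  expect_equal(met$R_g, brute_rg(m), tolerance = 1e-12)
})

test_that("folded chain: R collapses while contour length is preserved", {
  up <- cbind(0, 0, seq(0, 5, by = 0.5))
  down <- cbind(1e-3, 0, seq(4.5, 0, by = -0.5))
  m <- rbind(up, down)
  met <- conformer_metrics(m)
  expect_lt(met$R, 0.01)
  expect_gt(met$l_c, 10)
})

test_that("R_g matches the brute-force second moment on random chains", {
  set.seed(42)
  for (k in 1:5) {
    m <- matrix(rnorm(30), ncol = 3)
    met <- conformer_metrics(m)
    expect_equal(met$R_g, brute_rg(m), tolerance = 1e-12)
    expect_lte(met$R, met$l_c + 1e-12)
  }
})

test_that("metrics require at least two sites", {
  expect_error(conformer_metrics(matrix(0, 1, 3)), "at least 2")
})

test_that("representative selection finds the density mode of a Gaussian cloud", {
  set.seed(7)
  n <- 400
  met <- tibble::tibble(id = 1:n,
                        R_g = rnorm(n, mean = 3, sd = 0.3),
                        R = rnorm(n, mean = 8, sd = 1))
  reps <- select_representatives(met, percentile = 25)
  expect_setequal(reps$role, c("mode", "max_R", "min_R"))
  # mode within 0.5 sd of the true mean in both coordinates
  mode <- reps[reps$role == "mode", ]
  expect_lt(abs(mode$R_g - 3), 0.15)
  expect_lt(abs(mode$R - 8), 0.5)
  # extrema bracket the mode and are members of the cloud
  expect_gte(reps$R[reps$role == "max_R"], mode$R)
  expect_lte(reps$R[reps$role == "min_R"], mode$R)
  expect_true(all(reps$id %in% met$id))
})

test_that("three distinct points: mode is the densest-neighbourhood point", {
  # two nearby points and one outlier: brute-force densest is in the pair
  met <- tibble::tibble(id = 1:3, R_g = c(1, 1.05, 5), R = c(2, 2.05, 9))
  reps <- select_representatives(met, percentile = 99)
  expect_true(reps$id[reps$role == "mode"] %in% c(1, 2))
})

test_that("degenerate ensemble returns the unique conformer thrice", {
  met <- tibble::tibble(id = 1:5, R_g = 2, R = 4)
  expect_warning(reps <- select_representatives(met), "degenerate")
  expect_equal(nrow(reps), 3)
  expect_true(all(reps$R_g == 2))
})
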