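din <- read_property_table("dinucleotide")
tri <- read_property_table("trinucleotide")

test_that("bundled property tables are complete and standardized", {
  expect_equal(din$unit, 2L)
  expect_equal(dim(din$values), c(16, 15))
  expect_equal(tri$unit, 3L)
  expect_equal(dim(tri$values), c(64, 12))
  expect_equal(unname(colMeans(din$values)), rep(0, 15), tolerance = 1e-6)
  expect_equal(unname(apply(din$values, 2, sd)), rep(1, 15),
               tolerance = 1e-6)
})

test_that("DNP/TNP composition encoding has the printed dimensions", {
  set.seed(3)
  s <- paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
  expect_equal(ncol(property_encode(s, din)), 240)
  expect_equal(ncol(property_encode(s, tri)), 768)

  # single-composition sequence: only AA (AAA) entries nonzero, each equal
  # to 1 x property value
  v <- property_encode("AAAA", din)[1, ]
  nz <- v[v != 0]
  expect_true(all(grepl("_AA$", names(nz))))
  expect_equal(unname(v[paste0(din$properties, "_AA")]),
               unname(din$values["AA", ]))
  v3 <- property_encode("AAAA", tri)[1, ]
  expect_equal(unname(v3[paste0(tri$properties, "_AAA")]),
               unname(tri$values["AAA", ]))

  # oracle: hand-computed frequency x value for a 4-base sequence
  v2 <- property_encode("ACGT", din)[1, ]
  expect_equal(unname(v2[paste0(din$properties[1], "_AC")]),
               (1 / 3) * din$values["AC", 1])
})

test_that("ACC encoding matches dimensions and a direct covariance oracle", {
  set.seed(8)
  s <- paste(sample(c("A", "C", "G", "T"), 120, TRUE), collapse = "")
  dacc <- acc_encode(s, din, lag = 4)
  expect_equal(ncol(dacc), 15 * 4 + 15 * 14 * 4)     # 900
  tacc <- acc_encode(s, tri, lag = 4)
  expect_equal(ncol(tacc), 12 * 4 + 12 * 11 * 4)     # 576

  # homopolymer: constant signal -> all covariances 0
  expect_equal(sum(abs(acc_encode(strrep("A", 50), din))), 0)

  # independent scalar oracle for AC and CC at one lag
  sig <- vapply(seq_len(nchar(s) - 1),
                function(i) substr(s, i, i + 1), character(1))
  for (p in c(1, 7)) {
    v <- din$values[sig, p]
    W <- length(v); g <- 3
    ac <- sum((v[1:(W - g)] - mean(v)) * (v[(1 + g):W] - mean(v))) / (W - g)
    expect_equal(unname(dacc[1, sprintf("AC_%s_lag%d", din$properties[p],
                                        g)]), ac)
  }
  v1 <- din$values[sig, 2]; v2 <- din$values[sig, 5]
  W <- length(v1); g <- 2
  cc <- sum((v1[1:(W - g)] - mean(v1)) * (v2[(1 + g):W] - mean(v2))) /
    (W - g)
  expect_equal(unname(dacc[1, sprintf("CC_%s_%s_lag%d", din$properties[2],
                                      din$properties[5], g)]), cc)

  expect_error(acc_encode("ACGTA", din, lag = 4), "<= lag")
})

test_that("PseKNC satisfies its contract and a hand oracle", {
  set.seed(5)
  s <- paste(sample(c("A", "C", "G", "T"), 100, TRUE), collapse = "")
  for (k in 2:4) {
    v <- pseknc_encode(s, k = k, lambda = 4, w = 0.2, table = din)
    expect_equal(ncol(v), 4^k + 4)
    expect_equal(sum(v[1, ]), 1, tolerance = 1e-12)
    expect_true(all(v[1, ] >= 0))
  }

  # homopolymer: theta = 0, vector = pure frequency (single 1)
  h <- pseknc_encode(strrep("A", 30), k = 2, lambda = 4, table = din)
  expect_equal(unname(h[1, "f_AA"]), 1)
  expect_equal(sum(h[1, ] != 0), 1)
  expect_equal(unname(h[1, paste0("theta_", 1:4)]), rep(0, 4))

  # 4-base worked example, independent scalar evaluation of the equations
  one_prop <- din
  one_prop$values <- din$values[, 1, drop = FALSE]
  one_prop$properties <- din$properties[1]
  v <- pseknc_encode("ACGT", k = 2, lambda = 1, w = 0.2,
                     table = one_prop)[1, ]
  P <- din$values[, 1]
  # dinucleotides AC, CG, GT; theta_1 = mean of (P[d_i] - P[d_{i+1}])^2
  theta1 <- mean(c((P["AC"] - P["CG"])^2, (P["CG"] - P["GT"])^2))
  denom <- 1 + 0.2 * theta1
  expect_equal(unname(v["f_AC"]), (1 / 3) / denom)
  expect_equal(unname(v["f_CG"]), (1 / 3) / denom)
  expect_equal(unname(v["f_AA"]), 0)
  expect_equal(unname(v["theta_1"]), 0.2 * theta1 / denom)

  expect_error(pseknc_encode("ACGT", k = 2, lambda = 4, table = din),
               "lambda")
})
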