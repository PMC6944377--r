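# parameter grid used across the analytic checks
.grid <- expand.grid(nu = c(0.8, 1, 2.63, 6), p = c(0, 0.035, 0.2),
                     T = c(1, 2, 6))

test_that("all interference densities are non-negative and normalize to 1", {
  for (i in seq_len(nrow(.grid))) {
    sp <- theory_spec(T = .grid$T[i], nu = .grid$nu[i], p = .grid$p[i])
    x <- seq(0.001, 4, length.out = 40)
    expect_true(all(f_reg(x, sp) >= 0))
    expect_true(all(g_reg(x, sp) >= 0))
    expect_true(all(segment_length_density(x, sp) >= 0))
    for (fn in list(f_reg, g_reg, nearest_crossover_density,
                    segment_length_density)) {
      I <- stats::integrate(function(u) fn(u, sp), 0, Inf,
                            rel.tol = 1e-10)$value
      expect_equal(I, 1, tolerance = 1e-6)
    }
  }
})

test_that("densities have the stated means and boundary values", {
  for (i in which(.grid$T == 2)) {
    sp <- theory_spec(T = 2, nu = .grid$nu[i], p = .grid$p[i])
    mf <- stats::integrate(function(u) u * f_reg(u, sp), 0, Inf,
                           rel.tol = 1e-10)$value
    expect_equal(mf, 1 / (1 - sp$p), tolerance = 1e-6)
    expect_equal(g_reg(0, sp), 1 - sp$p)
    expect_equal(nearest_crossover_density(0, sp), 2 * sp$T)
    mphi <- stats::integrate(function(u) u * segment_length_density(u, sp),
                             0, Inf, rel.tol = 1e-10)$value
    expect_equal(mphi, 1 / (2 * sp$T), tolerance = 1e-6)
  }
})

test_that("nu = 1 reduces every interference expression to its Poisson form", {
  x <- seq(0, 3, length.out = 61)
  for (p in c(0.02, 0.2)) {
    for (T in c(1, 3)) {
      sp <- theory_spec(T = T, nu = 1, p = p)
      expect_lt(max(abs(f_reg(x, sp) - (1 - p) * exp(-(1 - p) * x))), 1e-8)
      expect_lt(max(abs(g_reg(x, sp) - (1 - p) * exp(-(1 - p) * x))), 1e-8)
      expect_lt(max(abs(nearest_crossover_density(x, sp) -
                          2 * T * exp(-2 * T * x))), 1e-8)
      expect_lt(max(abs(segment_length_density(x, sp) -
                          2 * T * exp(-2 * T * x))), 1e-8)
    }
  }
})

test_that("phi equals the negative scaled derivative of h", {
  sp <- theory_spec(T = 2, nu = 6, p = 0.035)
  x <- seq(0.05, 2, length.out = 30)
  eps <- 1e-6
  dh <- (nearest_crossover_density(x + eps, sp) -
           nearest_crossover_density(x - eps, sp)) / (2 * eps)
  expect_equal(segment_length_density(x, sp), -dh / (2 * sp$T),
               tolerance = 1e-5)
})

test_that("the finite-chromosome density has total mass 1 with its atom", {
  for (prm in list(c(1, 6, 0.035), c(4, 2.63, 0.2), c(6, 6, 0.035))) {
    sp <- theory_spec(T = prm[1], nu = prm[2], p = prm[3], L = 2.8)
    fin <- segment_length_density_finite(0.5, sp)
    I <- stats::integrate(function(u) {
      segment_length_density_finite(u, sp)$density
    }, 0, sp$L, rel.tol = 1e-9)$value
    expect_equal(I + fin$atom, 1, tolerance = 1e-6)
  }
  sp <- theory_spec(T = 2, nu = 6, p = 0.035, L = 2.8)
  expect_error(segment_length_density_finite(3, sp), "\\[0, L\\]")
  expect_error(theory_spec(T = 2, nu = 6, p = 1), "regulated")
  # closed-form CDF agrees with numerical integration of the density
  for (q in c(0.2, 1, 2.5)) {
    I <- stats::integrate(function(u) {
      segment_length_density_finite(u, sp)$density
    }, 0, q, rel.tol = 1e-10)$value
    expect_equal(segment_length_cdf_finite(q, sp), I, tolerance = 1e-8)
  }
})

test_that("the Poisson special case matches the closed finite-chromosome form", {
  T <- 2; L <- 2.8
  x <- seq(0, L, length.out = 50)
  pois <- segment_length_density_poisson(x, T, L)
  # analytic normalization: continuous integral + atom = 1 exactly
  I <- stats::integrate(function(u) segment_length_density_poisson(u, T, L)$density,
                        0, L, rel.tol = 1e-11)$value
  expect_equal(I + pois$atom, 1, tolerance = 1e-9)
  expect_equal(pois$atom, exp(-2 * T * L) / (2 * T * L + 1))
  # nu = 1 interference machinery reproduces the same finite density
  sp <- theory_spec(T = T, nu = 1, p = 1e-9, L = L)
  fin <- segment_length_density_finite(x, sp)
  expect_equal(fin$density, pois$density, tolerance = 1e-6)
  expect_equal(fin$atom, pois$atom, tolerance = 1e-6)
  # long chromosome: finite and infinite forms agree for short lengths;
  # the exact Poisson ratio is (2 + 2T(L - x)) / (2TL + 1), i.e. within
  # (2Tx - 1) / (2TL + 1) of 1
  sp50 <- theory_spec(T = 6, nu = 1, p = 1e-9, L = 50)
  xs <- seq(0.01, 1, length.out = 20)
  rel <- abs(segment_length_density_finite(xs, sp50)$density /
               segment_length_density(xs, sp50) - 1)
  expect_lt(max(rel - abs(2 * 6 * xs - 1) / (2 * 6 * 50 + 1)), 1e-4)
  expect_lt(max(rel[xs <= 0.45]), 0.01)
})

test_that("interference suppresses short segments relative to Poisson", {
  for (nu in c(2.63, 6, 10)) {
    for (p in c(0, 0.05)) {
      sp <- theory_spec(T = 1, nu = nu, p = p)
      expect_lt(segment_length_density(1e-6, sp) / (2 * sp$T), 1)
    }
  }
})

test_that("series truncation at k = 50 is converged", {
  x <- seq(0.01, 10, length.out = 30)
  for (prm in list(c(6, 0.035), c(2.63, 0.2), c(0.8, 0))) {
    a <- theory_spec(T = 2, nu = prm[1], p = prm[2], k_max = 50)
    b <- theory_spec(T = 2, nu = prm[1], p = prm[2], k_max = 100)
    expect_lt(max(abs(f_reg(x, a) - f_reg(x, b))), 1e-10)
    expect_lt(max(abs(g_reg(x, a) - g_reg(x, b))), 1e-10)
  }
})

test_that("empirical nearest-crossover distances match h by KS", {
  withr::with_seed(31, {
    sp <- theory_spec(T = 1, nu = 4.5, p = 0.06)
    par <- interference_params(4.5, 0.06)
    d <- vapply(seq_len(2e4), function(i) {
      x1 <- sample_stahl_crossovers(6, par)
      x2 <- sample_stahl_crossovers(6, par)
      m <- suppressWarnings(min(x1, x2))
      if (is.finite(m)) m else NA_real_
    }, numeric(1L))
    d <- d[!is.na(d)]
    # closed-form CDF: H(q) = 1 - exp(-2pTq) * G_reg_tail(q)^(2T)
    cdf <- function(q) {
      1 - exp(-2 * sp$p * sp$T * q) * G_reg_tail(q, sp)^(2 * sp$T)
    }
    ks <- suppressWarnings(stats::ks.test(d, cdf))
    expect_gt(ks$p.value, 0.01)
  })
})

test_that("the constant-rate inhomogeneous-Poisson density is exact", {
  m <- genetic_map(list(`1` = data.frame(pos = c(1, 1e8), male = c(0, 100),
                                         female = c(0, 100))), "sex-specific")
  grid <- ss_rate_grid(m, "1", step = 1e5)
  T <- 2; n_f <- 2
  cr <- 4 * 1e-8  # 4 meioses x 1 cM/Mb in Morgans/bp
  L <- grid$L
  x <- c(0, 1e6, 5e6, 2e7, 5e7)
  anal <- cr * (L - x) * exp(-cr * x) / L + exp(-cr * x) / L
  expect_equal(ss_interarrival_density(x, grid, n_f, T), anal,
               tolerance = 1e-6)
  # identical male/female rates: the n_f mixture collapses
  d0 <- ss_interarrival_density(x, grid, 0, T)
  d4 <- ss_interarrival_density(x, grid, 4, T)
  expect_equal(d0, d4, tolerance = 1e-12)
  expect_equal(ss_mixture_density(x, grid, T), d0, tolerance = 1e-12)
  expect_error(ss_interarrival_density(1, grid, 5, 2), "0..2T")
})

test_that("meiosis-count weights mix a binomial with the ancestor coin", {
  w1 <- ss_meiosis_weights(1)
  expect_equal(w1$weight[w1$n_f == 0], 0.5)  # both transmitting meioses male
  expect_equal(w1$weight[w1$n_f == 2], 0.5)
  expect_equal(sum(w1$weight), 1)
  w3 <- ss_meiosis_weights(3)
  expect_equal(sum(w3$weight), 1)
  expect_equal(w3$weight[w3$n_f == 3],
               0.5 * stats::dbinom(3, 4, 0.5) + 0.5 * stats::dbinom(1, 4, 0.5))
})

test_that("pooled crossovers at fixed meiosis sexes follow the Eq-2 density", {
  m <- make_synthetic_map(n_chrom = 1, phys_len = 1.5e8, male_len = 120,
                          female_factor = 1.57, n_knots = 31, roughness = 0.4,
                          seed = 5)
  grid <- ss_rate_grid(m, "1", step = 1e4)
  df <- m$chromosomes[["1"]]
  T <- 2; n_f <- 1; n_m <- 3
  Lf <- (df$female[31] - df$female[1]) / 100
  Lm <- (df$male[31] - df$male[1]) / 100
  withr::with_seed(42, {
    lens <- vector("list", 8000)
    for (r in seq_len(8000)) {
      xof <- map_interpolate(m, "1", df$female[1] +
                               100 * sample_poisson_crossovers(Lf),
                             sex = "female", direction = "gen2phys")
      xom <- unlist(lapply(seq_len(n_m), function(i) {
        map_interpolate(m, "1", df$male[1] +
                          100 * sample_poisson_crossovers(Lm),
                        sex = "male", direction = "gen2phys")
      }))
      ev <- sort(c(xof, xom)) - 1  # offsets from the chromosome start
      if (length(ev)) lens[[r]] <- diff(c(0, ev))
    }
    lens <- unlist(lens)
  })
  brk <- seq(0, grid$L, length.out = 13)
  obs <- graphics::hist(lens, breaks = brk, plot = FALSE)$counts
  pr <- bin_probs(function(u) ss_interarrival_density(u, grid, n_f, T), brk)
  expect_gt(chisq_gof(obs, pr)$p.value, 0.01)
})

test_that("simulated sex-specific Poisson IBD lengths track the n_f mixture", {
  m <- make_synthetic_map(n_chrom = 1, phys_len = 1.5e8, male_len = 120,
                          female_factor = 1.57, n_knots = 31, roughness = 0.4,
                          seed = 5)
  grid <- ss_rate_grid(m, "1", step = 1e4)
  T <- 2
  sim <- simulate_pedigree(relationship_preset("half-cousin", T = T), m,
                           model = "ss-poisson", n = 20000, seed = 77)
  keep <- sim$ibd$phys_end < 1.5e8  # the end-censored interval is excluded
  len <- (sim$ibd$phys_end - sim$ibd$phys_start + 1)[keep]
  brk <- seq(0, grid$L, length.out = 13)
  obs <- graphics::hist(pmin(len, grid$L), breaks = brk, plot = FALSE)$counts
  pr <- bin_probs(function(u) ss_mixture_density(u, grid, T), brk)
  expc <- pr / sum(pr) * sum(obs)
  keep2 <- expc >= 500
  # IBD segments are a length-biased subset of inter-crossover blocks, so
  # agreement is close but not exact; require the bulk bins within 10%
  expect_lt(max(abs(obs[keep2] - expc[keep2]) / expc[keep2]), 0.10)
})
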