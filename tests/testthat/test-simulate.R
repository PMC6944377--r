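test_that("haplotype runs tile every chromosome exactly once", {
  m <- make_synthetic_map(n_chrom = 2, phys_len = 8e7, male_len = 90,
                          female_factor = 1.57, n_knots = 15,
                          roughness = 0.3, seed = 6)
  sim <- simulate_pedigree(relationship_preset("cousin", k = 1), m,
                           model = "ss-intf", n = 25, seed = 8,
                           output = "both")
  lens <- map_lengths(m)
  fh <- founder_hap_ids(sim$pedigree)
  for (r in c(1, 13, 25)) {
    for (lab in sim$pedigree$ind$label[sim$pedigree$print_idx]) {
      ind <- sim_individual(sim, r, lab)
      for (cc in names(ind)) {
        for (h in c("h1", "h2")) {
          runs <- ind[[cc]][[h]]
          expect_true(all(diff(runs$ends) > 0))
          expect_equal(runs$ends[length(runs$ends)],
                       lens$phys_end[lens$chrom == cc])
          expect_true(all(runs$ids %in% fh$founder_id))
          expect_true(all(diff(runs$ids) != 0))  # canonical merging
        }
      }
    }
  }
})

test_that("a gamete with no crossovers copies one parental haplotype at random", {
  # a map with (essentially) zero genetic length never samples a crossover
  m <- genetic_map(list(`1` = data.frame(pos = c(1, 1e6), male = c(0, 1e-9),
                                         female = c(0, 1e-9))), "sex-specific")
  h1 <- list(ends = 1e6, ids = 1L)
  h2 <- list(ends = 1e6, ids = 2L)
  withr::with_seed(10, {
    picks <- vapply(seq_len(1e4), function(i) {
      meiosis_gamete(h1, h2, m, "1", "male", model = "sa-poisson")$ids[1L]
    }, integer(1L))
  })
  bt <- stats::binom.test(sum(picks == 1L), length(picks), 0.5)
  expect_gt(bt$p.value, 0.001)
})

test_that("a crossover at the genetic midpoint switches at the interpolated bp", {
  m <- toy_linear_map()
  h1 <- list(ends = 2e6, ids = 1L)
  h2 <- list(ends = 2e6, ids = 2L)
  bp <- floor(map_interpolate(m, "1", 0.5, sex = "male", direction = "gen2phys"))
  g <- recombine_haplotype(h1, h2, bp, start = 1L)
  expect_equal(g$ends, c(1.5e6, 2e6))
  expect_equal(g$ids, c(1L, 2L))
  # double crossover inside one bp cancels
  g2 <- recombine_haplotype(h1, h2, c(bp, bp), start = 1L)
  expect_equal(g2$ids, 1L)
  # same-id adjacent runs merge: switching into a region with the same
  # founder id leaves a single chromosome-length run
  h3 <- list(ends = c(1.2e6, 2e6), ids = c(3L, 1L))
  g3 <- recombine_haplotype(h1, h3, 1.7e6, start = 1L)
  expect_equal(g3$ends, 2e6)
  expect_equal(g3$ids, 1L)
})

test_that("crossover counts per meiosis are Poisson under the Poisson model", {
  withr::with_seed(11, {
    L <- 2.3
    counts <- vapply(seq_len(1e5), function(i) {
      length(sample_poisson_crossovers(L))
    }, numeric(1L))
    kmax <- max(counts)
    obs <- tabulate(counts + 1L, nbins = kmax + 1L)
    pr <- stats::dpois(0:kmax, L)
    gof <- chisq_gof(obs, c(pr[-length(pr)], 1 - sum(pr[-length(pr)])))
    expect_gt(gof$p.value, 0.01)
  })
})

test_that("full siblings have the expected mean IBD proportions under any model", {
  g <- make_synthetic_genome(seed = 2)
  for (mod in c("sa-poisson", "ss-intf")) {
    sim <- simulate_pedigree(relationship_preset("full-sib"), g, model = mod,
                             n = 4000, seed = 21)
    s <- ibd_summary(sim)
    expect_lt(abs(mean(s$proportion) - 0.5),
              3 * stats::sd(s$proportion) / sqrt(nrow(s)))
    expect_lt(abs(mean(s$k2) - 0.25), 3 * stats::sd(s$k2) / sqrt(nrow(s)))
  }
})

test_that("simulations are deterministic given the seed", {
  m <- make_synthetic_map(n_chrom = 1, phys_len = 5e7, male_len = 70,
                          female_factor = 1.57, n_knots = 9, seed = 1)
  a <- simulate_pedigree(relationship_preset("full-sib"), m, "ss-intf",
                         n = 200, seed = 33, output = "both")
  b <- simulate_pedigree(relationship_preset("full-sib"), m, "ss-intf",
                         n = 200, seed = 33, output = "both")
  expect_identical(a$ibd, b$ibd)
  expect_identical(a$haps, b$haps)
  expect_identical(a$sexes, b$sexes)
  # seg files are byte-identical too
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_seg(a, f1); write_seg(b, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_equal(read_seg(f1)$length_cM, round(a$ibd$length_cM, 6))
})

test_that("model and map dialects must be compatible", {
  mavg <- sex_averaged_map(toy_linear_map())
  expect_error(simulate_pedigree(relationship_preset("full-sib"), mavg,
                                 model = "ss-intf", n = 1),
               "sex-specific map")
  expect_silent(invisible(simulate_pedigree(relationship_preset("full-sib"),
                                            mavg, model = "sa-poisson",
                                            n = 2, seed = 1)))
})

test_that("dimorphic maps give maternal half-siblings more segments", {
  g <- make_synthetic_genome(seed = 2)
  mat <- ibd_summary(simulate_pedigree(parse_relationship("half-sib-maternal"),
                                       g, "ss-intf", n = 2000, seed = 41))
  pat <- ibd_summary(simulate_pedigree(parse_relationship("half-sib-paternal"),
                                       g, "ss-intf", n = 2000, seed = 42))
  se <- sqrt(stats::var(mat$n_segments) / nrow(mat) +
               stats::var(pat$n_segments) / nrow(pat))
  expect_gt(mean(mat$n_segments) - mean(pat$n_segments), 5 * se)
})

test_that("fam tables carry replicate families with consistent parent sexes", {
  m <- toy_linear_map()
  sim <- simulate_pedigree(relationship_preset("full-sib"), m, n = 3, seed = 2)
  f <- withr::local_tempfile()
  write_fam(sim, f)
  fam <- utils::read.table(f, sep = "\t",
                           col.names = c("family", "id", "father", "mother",
                                         "sex", "pheno"))
  expect_equal(nrow(fam), 3L * nrow(sim$pedigree$ind))
  expect_true(all(fam$pheno == -9L))
  expect_true(all(fam$sex %in% 1:2))
  kids <- fam[fam$father != "0", ]
  expect_true(all(fam$sex[match(kids$father, fam$id)] == 1L))
  expect_true(all(fam$sex[match(kids$mother, fam$id)] == 2L))
})
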