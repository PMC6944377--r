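# 2-chromosome toy setup: markers every 100 kb, founder alleles chosen so
# every founder haplotype is identifiable at every site (multi-allelic).
toy_geno_setup <- function(n_rep = 2, seed = 19) {
  m <- genetic_map(list(`1` = data.frame(pos = c(1, 1e7), male = c(0, 60),
                                         female = c(0, 90)),
                        `2` = data.frame(pos = c(1, 5e6), male = c(0, 40),
                                         female = c(0, 55))),
                   "sex-specific")
  sim <- simulate_pedigree(relationship_preset("full-sib"), m, "ss-poisson",
                           n = n_rep, seed = seed, output = "both")
  pos <- list(`1` = seq(1e5, 1e7, by = 1e5), `2` = seq(1e5, 5e6, by = 1e5))
  n_var <- sum(lengths(pos))
  n_founders <- sum(sim$pedigree$ind$founder)
  gt <- matrix(NA_character_, n_var, n_founders)
  colnames(gt) <- paste0("S", seq_len(n_founders))
  for (k in seq_len(n_founders)) gt[, k] <- sprintf("%d|%d", 2 * k - 2, 2 * k - 1)
  alt <- paste(seq_len(2 * n_founders - 1), collapse = ",")  # fake multi-allelic alts
  vcf <- withr::local_tempfile(fileext = ".vcf", .local_envir = parent.frame())
  write_toy_vcf(vcf, rep(c("1", "2"), lengths(pos)), unlist(pos),
                "A", alt, gt)
  list(map = m, sim = sim, vcf = vcf, pos = pos)
}

test_that("founder assignment is an injective, seeded draw", {
  a <- assign_founders(paste0("S", 1:4), paste0("F", 1:4), seed = 1)
  expect_setequal(unname(a), paste0("S", 1:4))
  expect_identical(a, assign_founders(paste0("S", 1:4), paste0("F", 1:4), seed = 1))
  expect_error(assign_founders(paste0("S", 1:3), paste0("F", 1:4)),
               "at least 4")
})

test_that("with zero error the descendant mosaic equals the founder alleles", {
  s <- toy_geno_setup()
  phased <- read_phased_vcf(s$vcf)
  gm <- synthesize_genotypes(s$sim, phased,
                             model = error_model(0, 0, 0), seed = 4)
  # independent reconstruction: founder-id lookup at each marker
  fh <- founder_hap_ids(s$sim$pedigree)
  withr::with_seed(4, {
    for (r in seq_len(s$sim$n)) {
      amap <- match(sample(phased$samples, nrow(fh) / 2), phased$samples)
      for (lab in c("sib1", "sib2")) {
        ind <- sim_individual(s$sim, r, lab)
        col <- sprintf("%s%d_%s", s$sim$pedigree$name, r, lab)
        want <- unlist(lapply(names(s$pos), function(cc) {
          sapply(s$pos[[cc]], function(p) {
            f1 <- .id_at(ind[[cc]]$h1, p); f2 <- .id_at(ind[[cc]]$h2, p)
            a <- function(fid) {
              k <- amap[(fid + 1) %/% 2]; h <- 2 - (fid %% 2)
              phased$alleles[1L, 2 * (k - 1) + h]  # site-independent alleles
            }
            sprintf("%d|%d", a(f1), a(f2))
          })
        }))
        expect_identical(unname(gm$gt[, col]), unname(want))
      }
    }
  })
})

test_that("allele-sharing IBD at informative markers equals tracked segments", {
  s <- toy_geno_setup(n_rep = 3, seed = 23)
  phased <- read_phased_vcf(s$vcf)
  gm <- synthesize_genotypes(s$sim, phased, model = error_model(0, 0, 0),
                             seed = 6)
  # founder haplotypes are globally distinguishable, so allele sharing at a
  # marker reveals the IBD type exactly
  share <- function(g1, g2) {
    a <- as.integer(strsplit(g1, "|", fixed = TRUE)[[1L]])
    b <- as.integer(strsplit(g2, "|", fixed = TRUE)[[1L]])
    max((a[1] == b[1]) + (a[2] == b[2]), (a[1] == b[2]) + (a[2] == b[1]))
  }
  for (r in seq_len(s$sim$n)) {
    c1 <- sprintf("%s%d_sib1", s$sim$pedigree$name, r)
    c2 <- sprintf("%s%d_sib2", s$sim$pedigree$name, r)
    got <- mapply(share, gm$gt[, c1], gm$gt[, c2])
    seg <- s$sim$ibd[s$sim$ibd$rep == r, ]
    want <- integer(nrow(gm$fixed))
    for (i in seq_len(nrow(seg))) {
      hit <- gm$fixed$chrom == seg$chrom[i] & gm$fixed$pos >= seg$phys_start[i] &
        gm$fixed$pos <= seg$phys_end[i]
      want[hit] <- ifelse(seg$type[i] == "IBD2", 2L, 1L)
    }
    expect_equal(unname(got), want)
  }
})

test_that("the error and missingness model perturbs genotypes as specified", {
  m <- toy_linear_map()
  sim <- simulate_pedigree(relationship_preset("parent-child"), m,
                           n = 1, seed = 2, output = "both")
  pos <- seq(1e6 + 1e4, 2e6, by = 1e4)
  gt <- matrix(rep("0|1", length(pos) * 3), ncol = 3,
               dimnames = list(NULL, c("S1", "S2", "S3")))
  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_toy_vcf(vcf, "1", pos, "A", "C", gt)
  phased <- read_phased_vcf(vcf)

  # err_rate = 1 on all-heterozygous sites: all outputs homozygous, the two
  # classes each about half
  g1 <- synthesize_genotypes(sim, phased, model = error_model(1, 0, 0), seed = 3)
  expect_true(all(g1$gt %in% c("0|0", "1|1")))
  n11 <- sum(g1$gt == "1|1")
  expect_gt(stats::binom.test(n11, length(g1$gt), 0.5)$p.value, 0.001)

  # miss_rate = 1: everything missing
  g2 <- synthesize_genotypes(sim, phased, model = error_model(0, 1, 0), seed = 3)
  expect_true(all(g2$gt == ".|."))

  # hom sites + err_hom_rate = 1: errors flip to the opposite homozygote
  gt0 <- matrix(rep("0|0", length(pos) * 3), ncol = 3,
                dimnames = list(NULL, c("S1", "S2", "S3")))
  write_toy_vcf(vcf, "1", pos, "A", "C", gt0)
  g3 <- synthesize_genotypes(sim, read_phased_vcf(vcf),
                             model = error_model(1, 0, 1), seed = 3)
  expect_true(all(g3$gt == "1|1"))

  # multi-allelic sites never receive errors
  gtm <- matrix(rep("0|2", length(pos) * 3), ncol = 3,
                dimnames = list(NULL, c("S1", "S2", "S3")))
  write_toy_vcf(vcf, "1", pos, "A", "C,G", gtm)
  g4 <- synthesize_genotypes(sim, read_phased_vcf(vcf),
                             model = error_model(1, 0, 0), seed = 3)
  expect_true(all(g4$gt == "0|2"))
})

test_that("unphased input and off-map sites are handled", {
  m <- toy_linear_map()
  sim <- simulate_pedigree(relationship_preset("parent-child"), m,
                           n = 1, seed = 2, output = "both")
  vcf <- withr::local_tempfile(fileext = ".vcf")
  gt <- matrix(c("0/1", "0|1", "0|1", "0|1", "0|1", "0|1"), nrow = 2,
               dimnames = list(NULL, c("S1", "S2", "S3")))
  write_toy_vcf(vcf, "1", c(1.2e6, 1.4e6), "A", "C", gt)
  expect_error(read_phased_vcf(vcf), "phased")

  gt2 <- matrix(rep("0|1", 9), nrow = 3, dimnames = list(NULL, paste0("S", 1:3)))
  write_toy_vcf(vcf, "1", c(5e5, 1.2e6, 1.4e6), "A", "C", gt2)  # first off-map
  expect_message(
    g <- synthesize_genotypes(sim, read_phased_vcf(vcf),
                              model = error_model(0, 0, 0), seed = 1),
    "1 site")
  expect_equal(nrow(g$fixed), 2L)
})

test_that("synthesized genotypes round-trip through VCF", {
  s <- toy_geno_setup()
  phased <- read_phased_vcf(s$vcf)
  gm <- synthesize_genotypes(s$sim, phased, model = error_model(0, 0, 0),
                             seed = 9, keep_founders = TRUE)
  out <- withr::local_tempfile(fileext = ".vcf")
  write_phased_vcf(gm, out)
  back <- read_phased_vcf(out)
  expect_equal(back$samples, gm$samples)
  expect_equal(back$fixed$pos, gm$fixed$pos)
  re <- matrix(sprintf("%d|%d",
                       back$alleles[, seq(1, ncol(back$alleles), 2)],
                       back$alleles[, seq(2, ncol(back$alleles), 2)]),
               nrow = nrow(back$fixed))
  expect_equal(as.vector(re), as.vector(gm$gt))
})
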