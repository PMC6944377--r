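# Shared fixtures and oracles, built in code at test time.

# two-knot linear map: 1 Mb to 2 Mb, 0 to 1 cM (both sexes equal)
toy_linear_map <- function() {
  genetic_map(list(`1` = data.frame(pos = c(1e6, 2e6), male = c(0, 1),
                                    female = c(0, 1))),
              dialect = "sex-specific")
}

# short chromosome at bp resolution for brute-force IBD checks
toy_bp_map <- function(n_bp = 2000, cM = 50) {
  genetic_map(list(`1` = data.frame(pos = c(1, n_bp), male = c(0, cM),
                                    female = c(0, cM))),
              dialect = "sex-specific")
}

# dimorphic single chromosome used by the theory-vs-simulation checks:
# sex-averaged genetic length 2.8 Morgans
fig6_chromosome <- function() {
  make_synthetic_map(n_chrom = 1, phys_len = 280e6,
                     male_len = 280 * 2 / 2.57, female_factor = 1.57,
                     n_knots = 57, roughness = 0.25, seed = 11)
}

# founder-id lookup at a physical position
.id_at <- function(hap, pos) {
  hap$ids[findInterval(pos, hap$ends, left.open = TRUE) + 1L]
}

# brute-force per-bp IBD oracle: exhaustive founder-id comparison at every
# mapped bp, independent of the sweep implementation
brute_ibd <- function(a, b, map) {
  out <- NULL
  for (cc in names(a)) {
    df <- map$chromosomes[[cc]]
    pos <- df$pos[1L]:df$pos[nrow(df)]
    a1 <- .id_at(a[[cc]]$h1, pos); a2 <- .id_at(a[[cc]]$h2, pos)
    b1 <- .id_at(b[[cc]]$h1, pos); b2 <- .id_at(b[[cc]]$h2, pos)
    type <- pmax((a1 == b1) + (a2 == b2), (a1 == b2) + (a2 == b1))
    r <- rle(type)
    hi <- cumsum(r$lengths); lo <- hi - r$lengths + 1L
    keep <- r$values > 0
    if (any(keep)) {
      out <- rbind(out, data.frame(chrom = cc, phys_start = pos[lo[keep]],
                                   phys_end = pos[hi[keep]],
                                   type = c("IBD1", "IBD2")[r$values[keep]]))
    }
  }
  out
}

# wrap per-chromosome haplotype pairs as the individual_haps class
as_individual <- function(haps_by_chrom, label = "x") {
  structure(haps_by_chrom, class = "individual_haps", label = label)
}

# trapezoid bin probabilities for a density evaluated on a fine subgrid
bin_probs <- function(dens_fun, breaks, npts = 40L) {
  vapply(seq_len(length(breaks) - 1L), function(i) {
    xs <- seq(breaks[i], breaks[i + 1L], length.out = npts)
    d <- dens_fun(xs)
    sum((d[-1L] + d[-npts]) / 2 * diff(xs))
  }, numeric(1L))
}

# chi-square GOF of counts against bin probabilities, merging cells with
# expected count below `min_exp` into one
chisq_gof <- function(obs, probs, min_exp = 5) {
  expc <- probs / sum(probs) * sum(obs)
  low <- expc < min_exp
  if (any(low)) {
    obs <- c(obs[!low], sum(obs[low]))
    probs <- c(probs[!low], sum(probs[low]))
  }
  suppressWarnings(stats::chisq.test(obs, p = probs / sum(probs)))
}

# write a small phased VCF for genotype-synthesis tests
write_toy_vcf <- function(path, chrom, pos, ref, alt, gt) {
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", colnames(gt)), collapse = "\t"))
  body <- paste(chrom, pos, ".", ref, alt, ".", "PASS", ".", "GT",
                apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  path
}
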