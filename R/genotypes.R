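#' Genotyping error and missingness model
#'
#' Per-site, per-individual error and missingness applied when
#' synthesizing genotypes.  An error at a truly heterozygous site turns it
#' into either homozygous class with equal probability; an error at a
#' homozygous site makes it heterozygous, except that with probability
#' `err_hom_rate` it becomes the opposite homozygote.  Missingness is
#' applied after (and overrides) error.  Errors only affect biallelic
#' sites; missingness affects all sites.
#'
#' @param err_rate per-site error probability (default `1e-3`).
#' @param miss_rate per-site missingness probability (default `1e-3`).
#' @param err_hom_rate probability that an error at a homozygous site
#'   produces the opposite homozygote rather than a heterozygote
#'   (default 0).
#' @return an object of class `error_model`.
#' @export
error_model <- function(err_rate = 1e-3, miss_rate = 1e-3, err_hom_rate = 0) {
  rates <- c(err_rate, miss_rate, err_hom_rate)
  if (any(!is.finite(rates)) || any(rates < 0) || any(rates > 1)) {
    stop("all rates must lie in [0, 1]", call. = FALSE)
  }
  structure(list(err_rate = err_rate, miss_rate = miss_rate,
                 err_hom_rate = err_hom_rate), class = "error_model")
}

#' Assign input samples to pedigree founders
#'
#' Draws an injective assignment of phased input samples to founders,
#' uniformly at random, deterministic given `seed`.
#'
#' @param input_samples character vector of available sample names.
#' @param founders character vector of founder labels.
#' @param seed integer seed.
#' @return named character vector mapping founder label to sample name.
#' @export
assign_founders <- function(input_samples, founders, seed = NULL) {
  if (length(input_samples) < length(founders)) {
    stop(sprintf("need at least %d input samples for %d founders (have %d)",
                 length(founders), length(founders), length(input_samples)),
         call. = FALSE)
  }
  with_seed(seed, {
    stats::setNames(sample(input_samples, length(founders)), founders)
  })
}

#' Read a phased VCF into haplotype matrices
#'
#' Thin wrapper over `vcfR` that checks phasing and exposes the allele
#' matrix in the layout the genotype synthesizer uses.
#'
#' @param path VCF path (optionally gzipped).
#' @return list with `fixed` (data frame `chrom, pos, id, ref, alt`),
#'   `samples`, and `alleles`, an integer matrix of allele indices with one
#'   row per variant and two columns per sample (columns `2k-1`, `2k` are
#'   the two haplotypes of sample `k`); `NA` encodes missing alleles.
#' @export
read_phased_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the 'vcfR' package", call. = FALSE)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (any(grepl("/", gt, fixed = TRUE), na.rm = TRUE)) {
    stop("input VCF must be phased ('|' genotype separator)", call. = FALSE)
  }
  n_var <- nrow(gt)
  n_s <- ncol(gt)
  alleles <- matrix(NA_integer_, n_var, 2L * n_s)
  sp <- strsplit(as.vector(gt), "|", fixed = TRUE)
  a1 <- suppressWarnings(as.integer(vapply(sp, `[`, character(1L), 1L)))
  a2 <- suppressWarnings(as.integer(vapply(sp, function(x) if (length(x) >= 2L) x[2L] else NA_character_, character(1L))))
  alleles[, seq(1L, 2L * n_s, by = 2L)] <- matrix(a1, n_var, n_s)
  alleles[, seq(2L, 2L * n_s, by = 2L)] <- matrix(a2, n_var, n_s)
  fx <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  list(fixed = data.frame(chrom = fx$CHROM, pos = as.numeric(fx$POS),
                          id = fx$ID, ref = fx$REF, alt = fx$ALT,
                          stringsAsFactors = FALSE),
       samples = colnames(gt), alleles = alleles)
}

#' Synthesize genotypes for simulated individuals
#'
#' Copies alleles from phased input haplotypes, randomly assigned to the
#' pedigree founders (injectively within each replicate), to every printed
#' descendant using the tracked founder-segment identifiers and end
#' points, then applies the [error_model()].  Variant sites outside the
#' simulated map span are dropped with a message.
#'
#' @param sim a `relsim_sim` simulated with haplotype output.
#' @param phased a phased input set from [read_phased_vcf()] (or a list of
#'   the same shape).
#' @param model an [error_model()].
#' @param keep_founders also emit genotypes for founder individuals.
#' @param seed integer seed.
#' @return object of class `relsim_genotypes`: list with `fixed` (variant
#'   table), `samples` (output ids `<pedigree><rep>_<label>`), and `gt`
#'   (character matrix of phased genotypes `"a|b"`, `".|."` for missing).
#' @export
synthesize_genotypes <- function(sim, phased, model = error_model(),
                                 keep_founders = FALSE, seed = NULL) {
  if (is.null(sim$haps)) stop("simulate with output = 'haplotypes' or 'both'", call. = FALSE)
  if (!inherits(model, "error_model")) stop("`model` must be an error_model", call. = FALSE)
  ped <- sim$pedigree
  founders <- ped$ind$label[ped$ind$founder]
  n_f <- length(founders)
  if (length(phased$samples) < n_f) {
    stop(sprintf("need at least %d input samples for %d founders (have %d)",
                 n_f, n_f, length(phased$samples)), call. = FALSE)
  }

  # restrict to mapped spans
  ml <- sim$map_lengths
  fx <- phased$fixed
  ok <- rep(FALSE, nrow(fx))
  for (i in seq_len(nrow(ml))) {
    ok <- ok | (fx$chrom == ml$chrom[i] & fx$pos >= ml$phys_start[i] &
                  fx$pos <= ml$phys_end[i])
  }
  if (any(!ok)) {
    message(sprintf("dropping %d site(s) outside the mapped span", sum(!ok)))
  }
  fx <- fx[ok, , drop = FALSE]
  alleles <- phased$alleles[ok, , drop = FALSE]
  n_var <- nrow(fx)
  biallelic <- !grepl(",", fx$alt, fixed = TRUE)

  out_labels <- ped$ind$label[ped$print_idx]
  if (keep_founders) out_labels <- unique(c(founders, out_labels))
  with_seed(seed, {
    cols <- list()
    ids <- character(0)
    for (r in seq_len(sim$n)) {
      amap <- match(sample(phased$samples, n_f), phased$samples) # founder -> sample index
      hr <- sim$haps[sim$haps$rep == r, , drop = FALSE]
      for (lab in out_labels) {
        al <- matrix(NA_integer_, n_var, 2L)
        if (lab %in% founders) {
          k <- amap[match(lab, founders)]
          al[, 1L] <- alleles[, 2L * k - 1L]
          al[, 2L] <- alleles[, 2L * k]
        } else {
          hi <- hr[hr$ind == lab, , drop = FALSE]
          if (!nrow(hi)) next
          for (h in 1:2) {
            for (cc in unique(fx$chrom)) {
              vsel <- which(fx$chrom == cc)
              hc <- hi[hi$hap == h & hi$chrom == cc, , drop = FALSE]
              run <- findInterval(fx$pos[vsel], hc$end_bp, left.open = TRUE) + 1L
              fid <- hc$founder_id[run]
              # founder id -> (founder k, haplotype fh) -> input allele column
              k <- amap[(fid + 1L) %/% 2L]
              fh <- 2L - (fid %% 2L)
              al[vsel, h] <- alleles[cbind(vsel, 2L * (k - 1L) + fh)]
            }
          }
        }
        gtv <- .apply_error_model(al, biallelic, model)
        cols[[length(cols) + 1L]] <- gtv
        ids <- c(ids, sprintf("%s%d_%s", ped$name, r, lab))
      }
    }
    gt <- do.call(cbind, cols)
    colnames(gt) <- ids
    structure(list(fixed = fx, samples = ids, gt = gt),
              class = "relsim_genotypes")
  })
}

.apply_error_model <- function(al, biallelic, model) {
  n <- nrow(al)
  a1 <- al[, 1L]
  a2 <- al[, 2L]
  err <- if (model$err_rate > 0) {
    stats::runif(n) < model$err_rate & biallelic & !is.na(a1) & !is.na(a2)
  } else rep(FALSE, n)
  if (any(err)) {
    het <- err & a1 != a2
    hom <- err & a1 == a2
    if (any(het)) { # either homozygous class, equal probability
      allele <- ifelse(stats::runif(sum(het)) < 0.5, 0L, 1L)
      a1[het] <- allele
      a2[het] <- allele
    }
    if (any(hom)) {
      opp <- hom & stats::runif(n) < model$err_hom_rate
      flip_het <- hom & !opp
      a1[opp] <- 1L - a1[opp]
      a2[opp] <- 1L - a2[opp]
      if (any(flip_het)) { # heterozygous, random phase
        first <- stats::runif(sum(flip_het)) < 0.5
        a1[flip_het] <- ifelse(first, 0L, 1L)
        a2[flip_het] <- 1L - a1[flip_het]
      }
    }
  }
  gt <- paste0(a1, "|", a2)
  gt[is.na(a1) | is.na(a2)] <- ".|."
  if (model$miss_rate > 0) gt[stats::runif(n) < model$miss_rate] <- ".|."
  gt
}

#' Write synthesized genotypes as a phased VCF
#'
#' @param x a `relsim_genotypes` object.
#' @param path output path (plain-text VCF).
#' @return `path`, invisibly.
#' @export
write_phased_vcf <- function(x, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=relsim",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", x$samples), collapse = "\t"))
  fx <- x$fixed
  body <- paste(fx$chrom, format(fx$pos, scientific = FALSE, trim = TRUE),
                ifelse(is.na(fx$id) | fx$id == "", ".", fx$id),
                fx$ref, fx$alt, ".", "PASS", ".", "GT",
                apply(x$gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}
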