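#' Exact pairwise IBD segments from tracked founder haplotypes
#'
#' Sweeps the merged breakpoints of the four haplotypes of two simulated
#' individuals.  On each interval the founder ids of `a`'s haplotypes are
#' matched to `b`'s under maximal matching: two matches to distinct
#' haplotypes give IBD2, one gives IBD1.  Adjacent intervals of the same
#' type are merged; output does not depend on the order of `a` and `b`.
#' This is the pure-R reference implementation of the sweep the compiled
#' engine performs; both must agree exactly.
#'
#' @param a,b `individual_haps` objects from [sim_individual()] (simulated
#'   from the same founder pool).
#' @param map the [genetic_map()] used for the simulation.
#' @return data frame with columns `chrom, phys_start, phys_end, type`
#'   (`"IBD1"`/`"IBD2"`), `gen_start, gen_end` (sex-averaged cM),
#'   `length_cM`.
#' @export
ibd_segments <- function(a, b, map) {
  stopifnot(inherits(a, "individual_haps"), inherits(b, "individual_haps"))
  chroms <- names(a)
  out <- lapply(chroms, function(cc) {
    df <- .map_chrom(map, cc)
    haps <- list(a[[cc]]$h1, a[[cc]]$h2, b[[cc]]$h1, b[[cc]]$h2)
    E <- sort(unique(unlist(lapply(haps, `[[`, "ends"))))
    start0 <- df$pos[1L]
    # founder id of each haplotype on each interval (intervals end at E)
    idm <- vapply(haps, function(h) h$ids[findInterval(E, h$ends, left.open = TRUE) + 1L],
                  integer(length(E)))
    idm <- matrix(idm, nrow = length(E))
    m1 <- (idm[, 1L] == idm[, 3L]) + (idm[, 2L] == idm[, 4L])
    m2 <- (idm[, 1L] == idm[, 4L]) + (idm[, 2L] == idm[, 3L])
    type <- pmax(m1, m2)
    starts <- c(start0, E[-length(E)] + 1)
    runs <- rle(type)
    hi <- cumsum(runs$lengths)
    lo <- hi - runs$lengths + 1L
    keep <- runs$values > 0L
    if (!any(keep)) return(NULL)
    seg <- data.frame(chrom = cc, phys_start = starts[lo[keep]],
                      phys_end = E[hi[keep]],
                      type = c("IBD1", "IBD2")[runs$values[keep]])
    seg$gen_start <- sex_averaged_coordinate(map, cc, seg$phys_start)
    seg$gen_end <- sex_averaged_coordinate(map, cc, seg$phys_end)
    seg$length_cM <- seg$gen_end - seg$gen_start
    seg
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1L))])
  if (is.null(out)) {
    out <- data.frame(chrom = character(), phys_start = numeric(),
                      phys_end = numeric(), type = character(),
                      gen_start = numeric(), gen_end = numeric(),
                      length_cM = numeric())
  }
  rownames(out) <- NULL
  out
}

#' Summary IBD statistics for one pair
#'
#' `k1` and `k2` are the fractions of the genome (in sex-averaged genetic
#' units) shared IBD1 and IBD2; the IBD proportion is the diploid sharing
#' fraction `k2 + k1 / 2` and the kinship coefficient is `k2 / 2 + k1 / 4`.
#' An empty segment list is valid (distant relatives may share nothing)
#' and gives all-zero statistics.
#'
#' @param segments data frame from [ibd_segments()] (or one pair's rows of
#'   a `relsim_sim` IBD table).
#' @param map the [genetic_map()] used for the simulation, which supplies
#'   the total map length.
#' @return list with `k1, k2, proportion, kinship, n_segments, total_cM`.
#' @export
ibd_stats <- function(segments, map) {
  tot <- sum(map_lengths(map)$avg_cM)
  len1 <- sum(segments$length_cM[segments$type == "IBD1"])
  len2 <- sum(segments$length_cM[segments$type == "IBD2"])
  k1 <- len1 / tot
  k2 <- len2 / tot
  list(k1 = k1, k2 = k2,
       proportion = k2 + k1 / 2,
       kinship = k2 / 2 + k1 / 4,
       n_segments = nrow(segments),
       total_cM = len1 + len2)
}

#' Per-pair IBD summaries across replicates
#'
#' Aggregates a simulation's IBD segment table into one row per replicate
#' and printed pair, including pairs that share no segments.
#'
#' @param sim a `relsim_sim` with IBD output.
#' @return data frame with columns `rep, id1, id2, k1, k2, proportion,
#'   kinship, n_segments, total_cM`.
#' @export
ibd_summary <- function(sim) {
  tot <- sum(sim$map_lengths$avg_cM)
  ped <- sim$pedigree
  pair_lab <- data.frame(id1 = ped$ind$label[ped$pairs[, 1L]],
                         id2 = ped$ind$label[ped$pairs[, 2L]])
  base <- data.frame(rep = rep(seq_len(sim$n), each = nrow(pair_lab)),
                     id1 = rep(pair_lab$id1, sim$n),
                     id2 = rep(pair_lab$id2, sim$n))
  key <- function(r, i1, i2) paste(r, i1, i2, sep = "\r")
  x <- sim$ibd
  if (nrow(x)) {
    kx <- key(x$rep, x$id1, x$id2)
    g <- factor(kx, levels = key(base$rep, base$id1, base$id2))
    is1 <- x$type == "IBD1"
    len1 <- tapply(x$length_cM * is1, g, sum, default = 0)
    len2 <- tapply(x$length_cM * !is1, g, sum, default = 0)
    nseg <- tapply(rep(1, nrow(x)), g, sum, default = 0)
    len1[is.na(len1)] <- 0
    len2[is.na(len2)] <- 0
    nseg[is.na(nseg)] <- 0
  } else {
    len1 <- len2 <- nseg <- rep(0, nrow(base))
  }
  base$k1 <- as.numeric(len1) / tot
  base$k2 <- as.numeric(len2) / tot
  base$proportion <- base$k2 + base$k1 / 2
  base$kinship <- base$k2 / 2 + base$k1 / 4
  base$n_segments <- as.integer(nseg)
  base$total_cM <- as.numeric(len1) + as.numeric(len2)
  rownames(base) <- NULL
  base
}

#' Map a kinship coefficient to a degree of relatedness
#'
#' Uses the standard powers-of-two kinship ranges (as popularized by the
#' KING software): degree `d` corresponds to kinship in
#' `(2^-(d + 1.5), 2^-(d + 0.5)]`.  Kinship above `2^-1.5` (~0.354) is a
#' duplicate / monozygotic twin; kinship at or below the `max_degree`
#' lower bound is unrelated.
#'
#' @param kinship numeric vector of kinship coefficients in `[0, 0.5]`.
#' @param max_degree deepest degree to report (default 13).
#' @return integer vector: 0 for duplicate/MZ, `d` for degree-`d` relatives,
#'   `NA` for unrelated.
#' @export
degree_of_relatedness <- function(kinship, max_degree = 13L) {
  stopifnot(all(kinship >= 0 & kinship <= 0.5))
  out <- rep(NA_integer_, length(kinship))
  out[kinship > 2^-1.5] <- 0L
  for (d in seq_len(max_degree)) {
    out[kinship > 2^-(d + 1.5) & kinship <= 2^-(d + 0.5)] <- d
  }
  out
}
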