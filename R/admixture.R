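#' Simulate a recently admixed haplotype
#'
#' Builds the pedigree of a two-way admixture event `T` generations ago:
#' every ancestor couple in generation 1 consists of one member from
#' population A and one from population B, and the focal individual
#' descends from all of them through a complete binary ancestor tree.  One
#' admixed haplotype per chromosome is generated (the haplotype descending
#' from the admixed lineage; the spouse side is a single unmodeled
#' founder).  Founder haplotypes are labeled by population, adjacent
#' segments descending from the same population are merged, and the first
#' and last segments of each chromosome are flagged as censored (their
#' true lengths are cut off by the chromosome ends).
#'
#' @param T generations since admixture (>= 2; `T = 2` corresponds to a
#'   grandchild of the mixed couples).
#' @param map a [genetic_map()].
#' @param model one of [crossover_models()].
#' @param interference a [sexed_interference()] set (interference models).
#' @param n number of replicate admixed individuals.
#' @param seed integer seed.
#' @return data frame of local-ancestry segments with columns `rep, chrom,
#'   start, end` (sex-averaged genetic coordinates, Morgans from the
#'   chromosome start), `length` (Morgans), `population` (`"A"`/`"B"`),
#'   `censored`.
#' @export
simulate_admixed <- function(T, map, model = "sa-poisson", interference = NULL,
                             n = 1L, seed = NULL) {
  if (T < 2) stop("T must be >= 2", call. = FALSE)
  ped <- admixture_pedigree(T)
  sim <- simulate_pedigree(ped, map, model = model, interference = interference,
                           n = n, seed = seed, output = "haplotypes")
  fh <- founder_hap_ids(ped)
  fh$pop <- ped$ind$pop[fh$ind]
  pop_of <- fh$pop[order(fh$founder_id)]

  h <- sim$haps[sim$haps$hap == 1L, , drop = FALSE] # gamete of the admixed parent
  h$pop <- pop_of[h$founder_id]
  # sex-averaged genetic coordinate of each run end, per chromosome
  h$gen_end <- NA_real_
  for (cc in unique(h$chrom)) {
    i <- h$chrom == cc
    h$gen_end[i] <- sex_averaged_coordinate(map, cc, h$end_bp[i])
  }
  # offset so coordinates run from 0 at the chromosome start
  first_cM <- vapply(sim$chroms, function(cc) {
    df <- map$chromosomes[[cc]]
    if (map$dialect == "sex-specific") (df$male[1L] + df$female[1L]) / 2 else df$avg[1L]
  }, numeric(1L))
  h$gen_end <- (h$gen_end - first_cM[h$chrom]) / 100

  # merge adjacent same-population runs within rep x chrom
  grp <- paste(h$rep, h$chrom, sep = "\r")
  new_run <- c(TRUE, grp[-1L] != grp[-nrow(h)] | h$pop[-1L] != h$pop[-nrow(h)])
  seg_id <- cumsum(new_run)
  last <- c(new_run[-1L], TRUE)
  segs <- data.frame(rep = h$rep[new_run], chrom = h$chrom[new_run],
                     end = h$gen_end[last], population = h$pop[new_run])
  chrom_start <- c(TRUE, !(segs$rep[-1L] == segs$rep[-nrow(segs)] &
                             segs$chrom[-1L] == segs$chrom[-nrow(segs)]))
  segs$start <- ifelse(chrom_start, 0, c(0, segs$end[-nrow(segs)]))
  segs$length <- segs$end - segs$start
  # Only the segment cut off by the chromosome's far end is censored: the
  # crossover processes start fresh at the chromosome start, so the first
  # segment is a valid waiting-time draw, while the last is only known to
  # exceed its observed length.  A whole-chromosome segment is censored
  # (once).  This makes T_hat = 2 * switches / total length, the rate MLE.
  segs$censored <- c(chrom_start[-1L], TRUE)
  segs[, c("rep", "chrom", "start", "end", "length", "population", "censored")]
}

#' Pedigree of a two-way admixture event
#'
#' The complete binary ancestor tree behind [simulate_admixed()]: `2^(T-2)`
#' generation-1 founder couples, each mixing one population-A and one
#' population-B member; one focal individual `T` generations below whose
#' first haplotype is the admixed gamete.
#'
#' @param T generations since admixture (>= 2).
#' @return a `pedigree` with founder `pop` labels and the focal individual
#'   printed.
#' @export
admixture_pedigree <- function(T) {
  if (T < 2) stop("T must be >= 2", call. = FALSE)
  env <- .new_ped_builder(sprintf("admix-T%d", T))
  n1 <- 2L^(T - 2L) # generation-1 couples
  for (cpl in seq_len(n1)) {
    a <- .ped_add(env, sprintf("g1-c%d-A", cpl), pop = "A")
    b <- .ped_add(env, sprintf("g1-c%d-B", cpl), pop = "B")
    .ped_couple(env, a, b)
  }
  members_prev <- matrix(seq_len(2L * n1), ncol = 2L, byrow = TRUE)
  if (T >= 3L) {
    for (g in 2:(T - 1L)) {
      n_g <- 2L^(T - 1L - g)
      members <- integer(2L * n_g)
      for (j in seq_len(2L * n_g)) {
        par <- members_prev[j, ]
        members[j] <- .ped_add(env, sprintf("g%d-i%d", g, j), parent1 = par[1L],
                               parent2 = par[2L], generation = g)
      }
      members_prev <- matrix(members, ncol = 2L, byrow = TRUE)
      for (j in seq_len(n_g)) .ped_couple(env, members_prev[j, 1L], members_prev[j, 2L])
    }
  }
  par <- members_prev[1L, ]
  p_T <- .ped_add(env, sprintf("g%d-parent", T), parent1 = par[1L],
                  parent2 = par[2L], generation = T)
  spouse <- .ped_add(env, "spouse", generation = T)
  .ped_couple(env, p_T, spouse)
  focal <- .ped_add(env, "focal", parent1 = p_T, parent2 = spouse,
                    generation = T + 1L)
  .ped_finish(env, focal, 1L,
              pairs = matrix(integer(), ncol = 2L))
}

#' Maximum likelihood estimate of time since admixture
#'
#' Local ancestry switches accumulate at rate `T / 2` per Morgan, so
#' uncensored tract lengths are exponential with that rate while tracts
#' cut off by chromosome ends only contribute survival terms.  Maximizing
#' the censored-exponential likelihood gives
#' `T_hat = 2 (n - m) / sum(x_i)` where `n` is the number of segments,
#' `m` of them censored, and `x_i` are all segment lengths in Morgans
#' (censored segments contribute to the denominator but not to `n - m`).
#' When every segment is censored (`n = m`, no interior switch) the
#' estimate is 0 and the fit is flagged degenerate.
#'
#' @param lengths segment lengths, Morgans.
#' @param censored logical vector: does the segment abut a chromosome end?
#' @return list with `T_hat`, `n`, `m`, `total_len`, `degenerate`.
#' @export
estimate_T <- function(lengths, censored) {
  n <- length(lengths)
  if (n < 1L) stop("need at least one segment", call. = FALSE)
  if (length(censored) != n) stop("lengths and censored must match", call. = FALSE)
  m <- sum(censored)
  tot <- sum(lengths)
  degenerate <- n == m
  T_hat <- if (degenerate) 0 else 2 * (n - m) / tot
  if (degenerate) warning("all segments censored: degenerate fit, T_hat = 0",
                          call. = FALSE)
  list(T_hat = T_hat, n = n, m = m, total_len = tot, degenerate = degenerate)
}

#' Per-replicate admixture-time estimates
#'
#' Applies [estimate_T()] to each replicate of a [simulate_admixed()]
#' segment table.
#'
#' @param segments data frame from [simulate_admixed()].
#' @return data frame with one row per replicate: `rep, n, m, total_len,
#'   T_hat, degenerate`.
#' @export
estimate_T_replicates <- function(segments) {
  reps <- sort(unique(segments$rep))
  out <- lapply(reps, function(r) {
    s <- segments[segments$rep == r, ]
    est <- suppressWarnings(estimate_T(s$length, s$censored))
    data.frame(rep = r, n = est$n, m = est$m, total_len = est$total_len,
               T_hat = est$T_hat, degenerate = est$degenerate)
  })
  do.call(rbind, out)
}
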