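#' Crossover model labels
#'
#' The four crossover models combine a genetic map dialect with an
#' inter-crossover distance model: `"ss-intf"` (sex-specific map,
#' Housworth-Stahl interference), `"ss-poisson"`, `"sa-intf"`
#' (sex-averaged map, interference), `"sa-poisson"`.
#'
#' @return character vector of the four model labels.
#' @export
crossover_models <- function() c("ss-intf", "ss-poisson", "sa-intf", "sa-poisson")

# Resolve map + model + interference into the per-chromosome structures the
# engine consumes: list of list(pos, male, female) in cM, and per-chromosome
# (nu, p) per sex.  For sex-averaged models both sex axes carry the
# averaged map and the sex-averaged interference parameters.
.resolve_model <- function(map, model, interference) {
  model <- match.arg(model, crossover_models())
  sex_specific <- startsWith(model, "ss")
  intf <- endsWith(model, "intf")
  if (sex_specific && map$dialect != "sex-specific") {
    stop("model '", model, "' requires a sex-specific map", call. = FALSE)
  }
  chroms <- map_chroms(map)
  engine_maps <- lapply(chroms, function(cc) {
    df <- map$chromosomes[[cc]]
    if (sex_specific) {
      list(pos = as.numeric(df$pos), male = df$male, female = df$female)
    } else {
      avg <- if (map$dialect == "sex-specific") (df$male + df$female) / 2 else df$avg
      list(pos = as.numeric(df$pos), male = avg, female = avg)
    }
  })
  nc <- length(chroms)
  if (intf) {
    if (is.null(interference)) interference <- default_interference()
    tab <- resolve_interference(interference, chroms)
    if (sex_specific) {
      par <- list(nu_f = tab$nu_female, p_f = tab$p_female,
                  nu_m = tab$nu_male, p_m = tab$p_male)
    } else {
      avg <- lapply(seq_len(nc), function(i) {
        sex_averaged_interference(interference_params(tab$nu_female[i], tab$p_female[i]),
                                  interference_params(tab$nu_male[i], tab$p_male[i]))
      })
      nu_a <- vapply(avg, `[[`, numeric(1L), "nu")
      p_a <- vapply(avg, `[[`, numeric(1L), "p")
      par <- list(nu_f = nu_a, p_f = p_a, nu_m = nu_a, p_m = p_a)
    }
  } else {
    par <- list(nu_f = rep(1, nc), p_f = rep(1, nc),
                nu_m = rep(1, nc), p_m = rep(1, nc))
  }
  list(model = model, interference = intf, engine_maps = engine_maps,
       chroms = chroms, params = par)
}

#' Simulate replicate pedigrees
#'
#' Transmits founder haplotype segments through a pedigree for `n`
#' independent replicates under one of the four crossover models, tracking
#' exact founder-segment descent.  Parent sexes are assigned randomly per
#' replicate unless fixed by the pedigree; under sex-specific models each
#' meiosis samples crossovers on the genetic axis of the parent's sex.
#' Output IBD segments carry physical (bp) and sex-averaged genetic (cM)
#' coordinates regardless of the map dialect used for simulation.
#'
#' @param ped a [relationship_preset()], [parse_def()] element, or other
#'   `pedigree` object.
#' @param map a [genetic_map()].
#' @param model one of [crossover_models()].
#' @param interference a [sexed_interference()] parameter set; required
#'   only by the interference models (defaults to [default_interference()]).
#' @param n number of replicates (defaults to `ped$copies`).
#' @param seed integer seed; the caller's RNG state is restored on exit.
#' @param output `"ibd"` (pairwise IBD segments for the pedigree's printed
#'   pairs), `"haplotypes"` (founder-segment mosaics of printed
#'   individuals), or `"both"`.
#' @return an object of class `relsim_sim` with elements `ibd` (data frame:
#'   `rep, id1, id2, chrom, phys_start, phys_end, type, gen_start, gen_end,
#'   length_cM`), `haps` (data frame of haplotype runs, if requested),
#'   `sexes` (replicate-by-individual matrix, 1 = male, 2 = female),
#'   `pedigree`, `model`, and `map_lengths`.
#' @export
simulate_pedigree <- function(ped, map, model = "sa-poisson",
                              interference = NULL, n = NULL, seed = NULL,
                              output = c("ibd", "haplotypes", "both")) {
  stopifnot(inherits(ped, "pedigree"), inherits(map, "genetic_map"))
  output <- match.arg(output)
  if (is.null(n)) n <- ped$copies
  if (n < 1L) stop("`n` must be >= 1", call. = FALSE)
  res <- .resolve_model(map, model, interference)
  want_ibd <- output %in% c("ibd", "both")
  want_haps <- output %in% c("haplotypes", "both")
  raw <- with_seed(seed, cpp_sim_pedigree(
    res$engine_maps,
    ifelse(is.na(ped$ind$parent1), -1L, ped$ind$parent1 - 1L),
    ifelse(is.na(ped$ind$parent2), -1L, ped$ind$parent2 - 1L),
    ped$ind$sex_fixed,
    matrix(ped$couples - 1L, ncol = 2L),
    res$interference,
    res$params$nu_f, res$params$p_f, res$params$nu_m, res$params$p_m,
    ped$print_idx - 1L,
    matrix(ped$pairs - 1L, ncol = 2L),
    as.integer(n), want_ibd, want_haps))
  labels <- ped$ind$label
  out <- list(pedigree = ped, model = res$model, n = as.integer(n),
              chroms = res$chroms, map_lengths = map_lengths(map),
              sexes = raw$sexes)
  if (want_ibd) {
    ibd <- raw$ibd
    ibd$id1 <- labels[ibd$id1]
    ibd$id2 <- labels[ibd$id2]
    ibd$chrom <- res$chroms[ibd$chrom]
    ibd$type <- c("IBD1", "IBD2")[ibd$type]
    names(ibd)[names(ibd) == "start_bp"] <- "phys_start"
    names(ibd)[names(ibd) == "end_bp"] <- "phys_end"
    ibd$length_cM <- ibd$gen_end - ibd$gen_start
    out$ibd <- ibd
  }
  if (want_haps) {
    haps <- raw$haps
    haps$ind <- labels[haps$ind]
    haps$chrom <- res$chroms[haps$chrom]
    out$haps <- haps
  }
  structure(out, class = "relsim_sim")
}

#' @export
print.relsim_sim <- function(x, ...) {
  cat(sprintf("<relsim_sim> '%s', model %s, %d replicate(s)\n",
              x$pedigree$name, x$model, x$n))
  if (!is.null(x$ibd)) cat(sprintf("  %d IBD segment(s)\n", nrow(x$ibd)))
  if (!is.null(x$haps)) cat(sprintf("  haplotype runs for %d printed individual(s)\n",
                                    length(x$pedigree$print_idx)))
  invisible(x)
}

#' Extract one simulated individual's haplotypes
#'
#' @param sim a `relsim_sim` produced with haplotype output.
#' @param rep replicate number.
#' @param label individual label (see `sim$pedigree$ind$label`).
#' @return an object of class `individual_haps`: a list with one element
#'   per chromosome, each containing haplotypes `h1` and `h2` as lists with
#'   `ends` (bp, strictly increasing, last = chromosome end) and `ids`
#'   (founder haplotype identifiers).
#' @export
sim_individual <- function(sim, rep, label) {
  if (is.null(sim$haps)) stop("simulation was run without haplotype output", call. = FALSE)
  h <- sim$haps[sim$haps$rep == rep & sim$haps$ind == label, , drop = FALSE]
  if (!nrow(h)) stop(sprintf("no haplotypes for individual '%s' in replicate %d", label, rep),
                     call. = FALSE)
  out <- lapply(sim$chroms, function(cc) {
    hc <- h[h$chrom == cc, , drop = FALSE]
    list(h1 = list(ends = hc$end_bp[hc$hap == 1L], ids = hc$founder_id[hc$hap == 1L]),
         h2 = list(ends = hc$end_bp[hc$hap == 2L], ids = hc$founder_id[hc$hap == 2L]))
  })
  names(out) <- sim$chroms
  structure(out, class = "individual_haps", label = label)
}

#' Recombine two parental haplotypes into a gamete
#'
#' Pure-R reference implementation of the copy mechanism of meiosis: the
#' gamete copies runs from the starting haplotype up to each successive
#' crossover breakpoint, switching source haplotype at every crossover.
#' Zero-length runs (two crossovers inside one bp) cancel and adjacent runs
#' with the same founder id merge.
#'
#' @param h1,h2 haplotypes: lists with `ends` (bp, strictly increasing;
#'   last element is the chromosome end) and `ids` (founder ids).
#' @param breakpoints sorted physical crossover positions (bp, integral;
#'   a crossover at real-valued position x corresponds to `floor(x)`).
#' @param start 1 or 2: which haplotype begins the gamete.
#' @return a haplotype (list with `ends`, `ids`).
#' @export
recombine_haplotype <- function(h1, h2, breakpoints, start = 1L) {
  stopifnot(start %in% c(1L, 2L))
  src <- list(h1, h2)
  chrom_end <- h1$ends[length(h1$ends)]
  stopifnot(chrom_end == h2$ends[length(h2$ends)])
  ends <- numeric(0)
  ids <- integer(0)
  push <- function(e, id) {
    n <- length(ends)
    if (n > 0L) {
      if (e <= ends[n]) return(invisible())
      if (ids[n] == id) {
        ends[n] <<- e
        return(invisible())
      }
    }
    ends[n + 1L] <<- e
    ids[n + 1L] <<- id
  }
  cur <- start
  prev <- -Inf
  for (b in c(breakpoints, chrom_end)) {
    s <- src[[cur]]
    for (jj in which(s$ends < b & s$ends > prev)) push(s$ends[jj], s$ids[jj])
    k <- which(s$ends >= b)[1L]
    if (!is.na(k) && b > prev) push(b, s$ids[k])
    prev <- max(prev, b)
    cur <- 3L - cur
  }
  list(ends = ends, ids = ids)
}

#' Sample one gamete from a parent
#'
#' R-level composition of crossover sampling, genetic-to-physical
#' interpolation and [recombine_haplotype()], mirroring the compiled
#' engine's meiosis for a single chromosome.  Crossovers are sampled on the
#' genetic axis of `parent_sex` (the sex-averaged axis for `"sa-*"`
#' models).
#'
#' @param h1,h2 the parent's two haplotypes for `chrom` (see
#'   [recombine_haplotype()]).
#' @param map a [genetic_map()].
#' @param chrom chromosome label.
#' @param parent_sex `"male"` or `"female"`.
#' @param model one of [crossover_models()].
#' @param interference a [sexed_interference()] set (interference models).
#' @return a haplotype (list with `ends`, `ids`).
#' @export
meiosis_gamete <- function(h1, h2, map, chrom, parent_sex = c("male", "female"),
                           model = "sa-poisson", interference = NULL) {
  parent_sex <- match.arg(parent_sex)
  model <- match.arg(model, crossover_models())
  if (!chrom %in% map_chroms(map)) {
    stop(sprintf("chromosome '%s' missing from map", chrom), call. = FALSE)
  }
  sex_specific <- startsWith(model, "ss")
  if (sex_specific && map$dialect != "sex-specific") {
    stop("model '", model, "' requires a sex-specific map", call. = FALSE)
  }
  axis <- if (sex_specific) parent_sex else "averaged"
  df <- .map_chrom(map, chrom)
  g <- .gen_col(map, df, axis)
  L <- (g[length(g)] - g[1L]) / 100
  if (endsWith(model, "intf")) {
    if (is.null(interference)) interference <- default_interference()
    tab <- resolve_interference(interference, chrom)
    pr <- if (sex_specific) {
      if (parent_sex == "male") interference_params(tab$nu_male, tab$p_male)
      else interference_params(tab$nu_female, tab$p_female)
    } else {
      sex_averaged_interference(interference_params(tab$nu_female, tab$p_female),
                                interference_params(tab$nu_male, tab$p_male))
    }
    xo <- sample_stahl_crossovers(L, pr)
  } else {
    xo <- sample_poisson_crossovers(L)
  }
  bp <- floor(map_interpolate(map, chrom, g[1L] + xo * 100, sex = axis,
                              direction = "gen2phys"))
  start <- if (stats::runif(1) < 0.5) 1L else 2L
  recombine_haplotype(h1, h2, bp, start)
}

#' Write IBD segments in seg format
#'
#' Tab-separated columns `id1 id2 chrom phys_start phys_end type gen_start
#' gen_end length_cM`; genetic coordinates are always sex-averaged cM.
#' Individual ids are prefixed with the pedigree name and replicate number.
#'
#' @param sim a `relsim_sim` with IBD output.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_seg <- function(sim, path) {
  x <- sim$ibd
  id1 <- sprintf("%s%d_%s", sim$pedigree$name, x$rep, x$id1)
  id2 <- sprintf("%s%d_%s", sim$pedigree$name, x$rep, x$id2)
  df <- data.frame(id1 = id1, id2 = id2, chrom = x$chrom,
                   phys_start = format(x$phys_start, scientific = FALSE, trim = TRUE),
                   phys_end = format(x$phys_end, scientific = FALSE, trim = TRUE),
                   type = x$type,
                   gen_start = sprintf("%.6f", x$gen_start),
                   gen_end = sprintf("%.6f", x$gen_end),
                   length_cM = sprintf("%.6f", x$length_cM))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a seg file written by [write_seg()]
#' @param path seg file path.
#' @return data frame with the seg columns.
#' @export
read_seg <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("id1", "id2", "chrom", "phys_start",
                                        "phys_end", "type", "gen_start",
                                        "gen_end", "length_cM"),
                          colClasses = c("character", "character", "character",
                                        "numeric", "numeric", "character",
                                        "numeric", "numeric", "numeric"))
  df
}

#' Write a 6-column pedigree (fam) table for a simulation
#'
#' Columns: family, id, father, mother, sex (1 = male, 2 = female),
#' phenotype (-9).  One family per replicate; founders' parents are 0.
#'
#' @param sim a `relsim_sim`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fam <- function(sim, path) {
  ped <- sim$pedigree
  n_ind <- nrow(ped$ind)
  rows <- vector("list", sim$n)
  for (r in seq_len(sim$n)) {
    sex <- sim$sexes[r, ]
    fam <- sprintf("%s%d", ped$name, r)
    father <- mother <- rep("0", n_ind)
    for (i in seq_len(n_ind)) {
      if (!is.na(ped$ind$parent1[i])) {
        ps <- c(ped$ind$parent1[i], ped$ind$parent2[i])
        fa <- ps[sex[ps] == 1L][1L]
        mo <- ps[sex[ps] == 2L][1L]
        father[i] <- sprintf("%s_%s", fam, ped$ind$label[fa])
        mother[i] <- sprintf("%s_%s", fam, ped$ind$label[mo])
      }
    }
    rows[[r]] <- data.frame(family = fam,
                            id = sprintf("%s_%s", fam, ped$ind$label),
                            father = father, mother = mother,
                            sex = sex, phenotype = -9L)
  }
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
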