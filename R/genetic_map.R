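#' Genetic map objects
#'
#' A `genetic_map` holds, per chromosome, a table of knots pairing physical
#' positions (1-based bp) with cumulative genetic positions (cM).  Two
#' dialects are supported: `"sex-specific"` maps carry separate male and
#' female columns; `"sex-averaged"` maps carry a single averaged column.
#' For sex-specific maps the sex-averaged coordinate at any position is
#' defined as the midpoint of the male and female coordinates.
#'
#' @param chromosomes named list of data frames.  For the sex-specific
#'   dialect each data frame has columns `pos`, `male`, `female`; for the
#'   sex-averaged dialect, columns `pos` and `avg`.  `pos` is bp (strictly
#'   increasing), genetic columns are cM (non-decreasing).
#' @param dialect `"sex-specific"` or `"sex-averaged"`.
#'
#' @return An object of class `genetic_map`.
#' @export
genetic_map <- function(chromosomes, dialect = c("sex-specific", "sex-averaged")) {
  dialect <- match.arg(dialect)
  if (!is.list(chromosomes) || length(chromosomes) == 0L ||
      is.null(names(chromosomes)) || anyDuplicated(names(chromosomes))) {
    stop("`chromosomes` must be a non-empty, uniquely named list", call. = FALSE)
  }
  cols <- if (dialect == "sex-specific") c("male", "female") else "avg"
  nms <- names(chromosomes)
  chromosomes <- lapply(nms, function(nm) {
    df <- chromosomes[[nm]]
    if (!all(c("pos", cols) %in% names(df))) {
      stop(sprintf("chromosome '%s': expected columns pos, %s", nm,
                   paste(cols, collapse = ", ")), call. = FALSE)
    }
    df <- as.data.frame(df)[, c("pos", cols)]
    .check_chrom_knots(df, nm, cols)
    df
  })
  names(chromosomes) <- nms
  structure(list(chromosomes = chromosomes, dialect = dialect),
            class = "genetic_map")
}

.check_chrom_knots <- function(df, nm, cols, lines = NULL) {
  n <- nrow(df)
  if (n < 2L) {
    stop(sprintf("malformed map: chromosome '%s' has fewer than 2 knots", nm),
         call. = FALSE)
  }
  if (any(!is.finite(df$pos)) || any(df$pos < 1)) {
    stop(sprintf("malformed map: chromosome '%s' has invalid physical positions", nm),
         call. = FALSE)
  }
  bad <- which(diff(df$pos) <= 0)
  if (length(bad)) {
    where <- if (is.null(lines)) sprintf("knot %d", bad[1L] + 1L)
             else sprintf("line %d", lines[bad[1L] + 1L])
    stop(sprintf("malformed map: physical positions not strictly increasing on chromosome '%s' (%s)",
                 nm, where), call. = FALSE)
  }
  for (cl in cols) {
    g <- df[[cl]]
    if (any(!is.finite(g))) {
      stop(sprintf("malformed map: non-finite genetic positions on chromosome '%s'", nm),
           call. = FALSE)
    }
    bad <- which(diff(g) < 0)
    if (length(bad)) {
      where <- if (is.null(lines)) sprintf("knot %d", bad[1L] + 1L)
               else sprintf("line %d", lines[bad[1L] + 1L])
      stop(sprintf("malformed map: %s genetic positions decrease on chromosome '%s' (%s)",
                   cl, nm, where), call. = FALSE)
    }
  }
  invisible(df)
}

#' @export
print.genetic_map <- function(x, ...) {
  lens <- map_lengths(x)
  cat(sprintf("<genetic_map> %s dialect, %d chromosome(s)\n",
              x$dialect, length(x$chromosomes)))
  print(lens, row.names = FALSE)
  invisible(x)
}

#' Chromosome names of a genetic map
#' @param map a `genetic_map`.
#' @return character vector of chromosome labels, in map order.
#' @export
map_chroms <- function(map) names(map$chromosomes)

.map_chrom <- function(map, chrom) {
  df <- map$chromosomes[[as.character(chrom)]]
  if (is.null(df)) {
    stop(sprintf("chromosome '%s' is not in the map", chrom), call. = FALSE)
  }
  df
}

.gen_col <- function(map, df, sex) {
  if (map$dialect == "sex-averaged") return(df$avg)
  switch(sex,
         male     = df$male,
         female   = df$female,
         averaged = (df$male + df$female) / 2)
}

#' Genetic and physical lengths per chromosome
#'
#' @param map a `genetic_map`.
#' @return data frame with one row per chromosome: physical start/end (bp)
#'   and genetic length (cM) per applicable sex plus the sex-averaged length.
#' @export
map_lengths <- function(map) {
  out <- lapply(names(map$chromosomes), function(nm) {
    df <- map$chromosomes[[nm]]
    base <- data.frame(chrom = nm, phys_start = df$pos[1L],
                       phys_end = df$pos[nrow(df)], stringsAsFactors = FALSE)
    if (map$dialect == "sex-specific") {
      base$male_cM <- diff(range(df$male))
      base$female_cM <- diff(range(df$female))
      base$avg_cM <- (base$male_cM + base$female_cM) / 2
    } else {
      base$avg_cM <- diff(range(df$avg))
    }
    base
  })
  do.call(rbind, out)
}

#' Read a genetic map file
#'
#' The file is whitespace-delimited plain text, one knot per line, with
#' `#`-prefixed header/comment lines permitted.  Columns are
#' `chrom phys_bp male_cM female_cM` for the sex-specific dialect and
#' `chrom phys_bp avg_cM` for the sex-averaged dialect.  Chromosomes appear
#' in the output in order of first appearance in the file.
#'
#' @param path path to the map file.
#' @param dialect `"sex-specific"` or `"sex-averaged"`.
#' @return a [genetic_map()].
#' @export
read_genetic_map <- function(path, dialect = c("sex-specific", "sex-averaged")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop(sprintf("map file '%s' does not exist", path), call. = FALSE)
  raw <- readLines(path)
  keep <- which(!grepl("^\\s*(#|$)", raw))
  if (!length(keep)) stop("malformed map: no data lines", call. = FALSE)
  fields <- strsplit(trimws(raw[keep]), "\\s+")
  ncol_exp <- if (dialect == "sex-specific") 4L else 3L
  nf <- lengths(fields)
  if (any(nf != ncol_exp)) {
    stop(sprintf("malformed map: expected %d columns, got %d at line %d",
                 ncol_exp, nf[which(nf != ncol_exp)[1L]],
                 keep[which(nf != ncol_exp)[1L]]), call. = FALSE)
  }
  m <- do.call(rbind, fields)
  chrom <- m[, 1L]
  num <- apply(m[, -1L, drop = FALSE], 2L, as.numeric)
  num <- matrix(num, nrow = nrow(m))
  if (any(is.na(num))) {
    bad <- keep[which(rowSums(is.na(num)) > 0)[1L]]
    stop(sprintf("malformed map: non-numeric field at line %d", bad), call. = FALSE)
  }
  cols <- if (dialect == "sex-specific") c("male", "female") else "avg"
  chroms <- unique(chrom)
  out <- lapply(chroms, function(cc) {
    idx <- which(chrom == cc)
    df <- data.frame(pos = num[idx, 1L])
    for (j in seq_along(cols)) df[[cols[j]]] <- num[idx, j + 1L]
    .check_chrom_knots(df, cc, cols, lines = keep[idx])
    df
  })
  names(out) <- chroms
  structure(list(chromosomes = out, dialect = dialect), class = "genetic_map")
}

#' Write a genetic map file
#'
#' Emits the same whitespace-delimited format that [read_genetic_map()]
#' reads, with a single `#` header line naming the columns.
#'
#' @param map a `genetic_map`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_genetic_map <- function(map, path) {
  cols <- if (map$dialect == "sex-specific") c("male_cM", "female_cM") else "avg_cM"
  hdr <- paste(c("#chrom", "phys_bp", cols), collapse = "\t")
  lines <- unlist(lapply(names(map$chromosomes), function(nm) {
    df <- map$chromosomes[[nm]]
    gcols <- if (map$dialect == "sex-specific") cbind(df$male, df$female) else cbind(df$avg)
    paste(nm, format(df$pos, scientific = FALSE, trim = TRUE),
          apply(gcols, 1L, function(r) paste(format(r, digits = 15, trim = TRUE),
                                             collapse = "\t")),
          sep = "\t")
  }))
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Interpolate between physical and genetic coordinates
#'
#' Piecewise-linear interpolation between the flanking knots of a map,
#' exact at knots.  No extrapolation is performed: values outside the
#' chromosome's mapped span raise an error, mirroring the convention that
#' the crossover rate is zero outside the mapped region.  In the
#' genetic-to-physical direction, a value falling on a plateau of the
#' genetic column resolves to the leftmost knot carrying that value.
#'
#' @param map a `genetic_map`.
#' @param chrom chromosome label.
#' @param value coordinate(s) to convert: bp for `"phys2gen"`, cM for
#'   `"gen2phys"`.
#' @param sex `"male"`, `"female"`, or `"averaged"`; which genetic axis to
#'   use.  Ignored (single axis) for sex-averaged maps.
#' @param direction `"phys2gen"` or `"gen2phys"`.
#' @return numeric vector of converted coordinates (real-valued; physical
#'   positions are not rounded here).
#' @export
map_interpolate <- function(map, chrom, value,
                            sex = c("averaged", "male", "female"),
                            direction = c("phys2gen", "gen2phys")) {
  sex <- match.arg(sex)
  direction <- match.arg(direction)
  df <- .map_chrom(map, chrom)
  g <- .gen_col(map, df, sex)
  p <- df$pos
  if (direction == "phys2gen") {
    if (any(value < p[1L] | value > p[length(p)])) {
      stop(sprintf("physical position outside mapped span [%s, %s] of chromosome '%s'",
                   p[1L], p[length(p)], chrom), call. = FALSE)
    }
    stats::approx(p, g, xout = value, method = "linear", ties = "ordered")$y
  } else {
    if (any(value < g[1L] | value > g[length(g)])) {
      stop(sprintf("genetic position outside mapped span [%g, %g] cM of chromosome '%s'",
                   g[1L], g[length(g)], chrom), call. = FALSE)
    }
    .gen2phys(g, p, value)
  }
}

# leftmost-knot convention on plateaus of the genetic column
.gen2phys <- function(g, p, u) {
  n <- length(g)
  j <- findInterval(u, g, left.open = TRUE) + 1L   # first knot with g >= u
  out <- numeric(length(u))
  at_knot <- j <= n & abs(g[pmin(j, n)] - u) == 0
  out[at_knot] <- p[j[at_knot]]
  off <- which(!at_knot)
  if (length(off)) {
    i <- j[off] - 1L                                # last knot with g < u
    out[off] <- p[i] + (u[off] - g[i]) / (g[i + 1L] - g[i]) * (p[i + 1L] - p[i])
  }
  out
}

#' Sex-averaged genetic coordinate at a physical position
#'
#' For sex-specific maps, returns the midpoint of the male and female
#' genetic coordinates at `phys`.  For sex-averaged maps this is simply the
#' (single) genetic coordinate.
#'
#' @inheritParams map_interpolate
#' @param phys physical position(s), bp.
#' @return sex-averaged genetic coordinate(s), cM.
#' @export
sex_averaged_coordinate <- function(map, chrom, phys) {
  map_interpolate(map, chrom, phys, sex = "averaged", direction = "phys2gen")
}

#' Generate a synthetic genetic map
#'
#' Builds a deterministic (given `seed`) multi-chromosome sex-specific map
#' for tests and simulation studies.  Every chromosome has physical length
#' `phys_len`, male genetic length `male_len` and female genetic length
#' `female_factor * male_len`.  The default `female_factor` reflects the
#' observation that human females average about 1.57 times as many
#' autosomal crossovers per meiosis as males.  With `roughness = 0` both
#' genetic columns are linear in physical position; larger values introduce
#' log-normal variation in the local cM/bp rate, independently per sex, so
#' that male and female maps differ in shape as well as length.
#'
#' @param n_chrom number of chromosomes.
#' @param phys_len physical length per chromosome, bp.
#' @param male_len male genetic length per chromosome, cM.
#' @param female_factor ratio of female to male genetic length.
#' @param n_knots knots per chromosome (>= 2).
#' @param roughness non-negative; standard deviation of the log local rate.
#' @param seed integer seed; the generator restores the caller's RNG state.
#' @return a sex-specific [genetic_map()] with chromosomes named `"1"`,
#'   `"2"`, ...
#' @export
make_synthetic_map <- function(n_chrom = 1L, phys_len = 100e6, male_len = 100,
                               female_factor = 1.57, n_knots = 101L,
                               roughness = 0, seed = 1L) {
  if (n_chrom < 1L || n_knots < 2L) stop("n_chrom >= 1 and n_knots >= 2 required", call. = FALSE)
  if (male_len < 0 || female_factor <= 0 || roughness < 0) {
    stop("male_len >= 0, female_factor > 0 and roughness >= 0 required", call. = FALSE)
  }
  with_seed(seed, {
    chroms <- lapply(seq_len(n_chrom), function(i) {
      pos <- round(seq(1, phys_len, length.out = n_knots))
      inc <- function(total) {
        w <- exp(stats::rnorm(n_knots - 1L, sd = roughness))
        cumsum(c(0, w / sum(w))) * total
      }
      data.frame(pos = pos, male = inc(male_len),
                 female = inc(male_len * female_factor))
    })
    names(chroms) <- as.character(seq_len(n_chrom))
    genetic_map(chroms, dialect = "sex-specific")
  })
}

#' Generate a synthetic human-like autosomal genome map
#'
#' A convenience wrapper producing 22 chromosomes whose male and female
#' genetic lengths decrease from chromosome 1 to 22 and sum to roughly the
#' human autosomal totals (about 28 Morgans male, 44 Morgans female, a
#' female:male ratio of 1.57), with physical lengths from about 250 Mb down
#' to 50 Mb.  Intended as a stand-in for real human maps in tests and
#' desk-scale experiments.
#'
#' @param n_chrom number of chromosomes (default 22).
#' @param male_total total male genetic length across chromosomes, cM.
#' @param female_factor female:male genetic length ratio.
#' @param roughness,n_knots,seed as in [make_synthetic_map()].
#' @return a sex-specific [genetic_map()].
#' @export
make_synthetic_genome <- function(n_chrom = 22L, male_total = 2800,
                                  female_factor = 1.57, n_knots = 51L,
                                  roughness = 0.3, seed = 1L) {
  w <- seq(2.6, 1, length.out = n_chrom)
  male_lens <- male_total * w / sum(w)
  phys_lens <- round(seq(250e6, 50e6, length.out = n_chrom))
  with_seed(seed, {
    chroms <- lapply(seq_len(n_chrom), function(i) {
      pos <- round(seq(1, phys_lens[i], length.out = n_knots))
      inc <- function(total) {
        wts <- exp(stats::rnorm(n_knots - 1L, sd = roughness))
        cumsum(c(0, wts / sum(wts))) * total
      }
      data.frame(pos = pos, male = inc(male_lens[i]),
                 female = inc(male_lens[i] * female_factor))
    })
    names(chroms) <- as.character(seq_len(n_chrom))
    genetic_map(chroms, dialect = "sex-specific")
  })
}

#' Collapse a sex-specific map to its sex-averaged dialect
#'
#' @param map a sex-specific `genetic_map`.
#' @return a sex-averaged `genetic_map` whose genetic column at every knot
#'   is the midpoint of the male and female columns.
#' @export
sex_averaged_map <- function(map) {
  if (map$dialect == "sex-averaged") return(map)
  chroms <- lapply(map$chromosomes, function(df) {
    data.frame(pos = df$pos, avg = (df$male + df$female) / 2)
  })
  genetic_map(chroms, dialect = "sex-averaged")
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's state afterwards.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_seed) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (has_seed) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    })
    set.seed(seed)
  }
  expr
}
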