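#' Crossover interference parameters
#'
#' Parameters of the Housworth-Stahl two-pathway model of crossover
#' placement: a fraction `p` of crossovers escape interference and follow a
#' Poisson process, while the remainder arise by thinning (probability 1/2
#' per chiasma, reflecting the absence of chromatid interference) a
#' stationary renewal process of chiasmata whose inter-arrival distances
#' are gamma distributed with shape `nu` and rate `2 * nu * (1 - p)`
#' Morgans^-1.
#'
#' @param nu gamma shape, > 0.  `nu = 1` recovers the Poisson model.
#' @param p escape fraction in `[0, 1]`.
#' @return an object of class `interference_params`.
#' @export
interference_params <- function(nu, p) {
  if (!is.numeric(nu) || length(nu) != 1L || !is.finite(nu) || nu <= 0) {
    stop("`nu` must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(p) || length(p) != 1L || !is.finite(p) || p < 0 || p > 1) {
    stop("`p` must be a single number in [0, 1]", call. = FALSE)
  }
  structure(list(nu = as.numeric(nu), p = as.numeric(p)),
            class = "interference_params")
}

#' @export
print.interference_params <- function(x, ...) {
  cat(sprintf("<interference_params> nu = %g, p = %g\n", x$nu, x$p))
  invisible(x)
}

#' Sex-resolved interference parameters
#'
#' Bundles female and male `(nu, p)` pairs, optionally per chromosome.  The
#' table form has one row per chromosome plus an optional genome-wide
#' default row with chromosome label `"*"`; every simulated chromosome must
#' resolve to exactly one pair per sex.
#'
#' @param female,male [interference_params()] used genome-wide.
#' @param table alternatively, a data frame with columns
#'   `chrom, nu_female, p_female, nu_male, p_male` (chromosome `"*"` is the
#'   genome-wide default).  Exactly one of `female`/`male` or `table` must
#'   be given.
#' @return an object of class `sexed_interference`.
#' @export
sexed_interference <- function(female = NULL, male = NULL, table = NULL) {
  if (!is.null(table)) {
    need <- c("chrom", "nu_female", "p_female", "nu_male", "p_male")
    if (!all(need %in% names(table))) {
      stop("table needs columns ", paste(need, collapse = ", "), call. = FALSE)
    }
    table$chrom <- as.character(table$chrom)
    if (anyDuplicated(table$chrom)) stop("duplicate chromosome rows", call. = FALSE)
    for (i in seq_len(nrow(table))) {
      interference_params(table$nu_female[i], table$p_female[i])
      interference_params(table$nu_male[i], table$p_male[i])
    }
    return(structure(list(table = as.data.frame(table)[, need]),
                     class = "sexed_interference"))
  }
  if (!inherits(female, "interference_params") || !inherits(male, "interference_params")) {
    stop("`female` and `male` must be interference_params objects", call. = FALSE)
  }
  tab <- data.frame(chrom = "*", nu_female = female$nu, p_female = female$p,
                    nu_male = male$nu, p_male = male$p, stringsAsFactors = FALSE)
  structure(list(table = tab), class = "sexed_interference")
}

#' @export
print.sexed_interference <- function(x, ...) {
  cat("<sexed_interference>\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Resolve interference parameters for a set of chromosomes
#'
#' @param params a [sexed_interference()] object.
#' @param chroms character vector of chromosome labels.
#' @return data frame with one row per requested chromosome and columns
#'   `chrom, nu_female, p_female, nu_male, p_male`.
#' @export
resolve_interference <- function(params, chroms) {
  tab <- params$table
  idx <- match(as.character(chroms), tab$chrom)
  star <- match("*", tab$chrom)
  idx[is.na(idx)] <- star
  if (anyNA(idx)) {
    stop(sprintf("no interference parameters for chromosome '%s' and no '*' default",
                 chroms[which(is.na(idx))[1L]]), call. = FALSE)
  }
  out <- tab[idx, , drop = FALSE]
  out$chrom <- as.character(chroms)
  rownames(out) <- NULL
  out
}

#' Read an interference parameter file
#'
#' Whitespace-delimited lines `chrom nu_female p_female nu_male p_male`;
#' `#` comments permitted; a line with chromosome `*` supplies a
#' genome-wide default.
#'
#' @param path file path.
#' @return a [sexed_interference()] object.
#' @export
read_interference_params <- function(path) {
  if (!file.exists(path)) stop(sprintf("file '%s' does not exist", path), call. = FALSE)
  raw <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", raw)
  fields <- strsplit(trimws(raw[keep]), "\\s+")
  if (any(lengths(fields) != 5L)) stop("expected 5 columns per line", call. = FALSE)
  m <- do.call(rbind, fields)
  tab <- data.frame(chrom = m[, 1L],
                    nu_female = as.numeric(m[, 2L]), p_female = as.numeric(m[, 3L]),
                    nu_male = as.numeric(m[, 4L]), p_male = as.numeric(m[, 5L]),
                    stringsAsFactors = FALSE)
  sexed_interference(table = tab)
}

#' Write an interference parameter file
#' @param params a [sexed_interference()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_interference_params <- function(params, path) {
  tab <- params$table
  writeLines(c("#chrom\tnu_female\tp_female\tnu_male\tp_male",
               sprintf("%s\t%g\t%g\t%g\t%g", tab$chrom, tab$nu_female,
                       tab$p_female, tab$nu_male, tab$p_male)), path)
  invisible(path)
}

#' Default human-range interference parameters
#'
#' Genome-wide female and male `(nu, p)` values in the range of published
#' human estimates: interference is somewhat stronger in males (larger
#' `nu`), and a small fraction of crossovers escapes interference in both
#' sexes.  Used wherever simulations need interference parameters and none
#' are supplied.
#'
#' @return a [sexed_interference()] object.
#' @export
default_interference <- function() {
  sexed_interference(female = interference_params(5.0, 0.02),
                     male   = interference_params(7.5, 0.05))
}

#' Sex-averaged interference parameters
#'
#' Combines female and male two-pathway parameters into a single pair for
#' use with a sex-averaged map.  The escape fractions average
#' arithmetically, `p_a = (p_f + p_m) / 2`.  Because every `nu` yields the
#' same mean inter-chiasma distance `1 / (2 (1 - p))`, a simple average of
#' shapes would not put the averaged distribution midway between the sexes;
#' instead `nu_a` is chosen so that the variance of the averaged
#' inter-chiasma distribution equals the mean of the male and female
#' variances, giving `nu_a = (1 / (2 nu_f) + 1 / (2 nu_m))^-1`.
#'
#' @param female,male [interference_params()] for each sex.
#' @return an [interference_params()] object with the averaged values.
#' @export
sex_averaged_interference <- function(female, male) {
  if (!inherits(female, "interference_params") || !inherits(male, "interference_params")) {
    stop("`female` and `male` must be interference_params objects", call. = FALSE)
  }
  p_a <- (female$p + male$p) / 2
  nu_a <- 1 / (1 / (2 * female$nu) + 1 / (2 * male$nu))
  interference_params(nu_a, p_a)
}
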