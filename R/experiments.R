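#' Summary statistics of a sample
#'
#' Mean, standard deviation (n - 1 denominator), quartiles (linear
#' interpolation between closest ranks, the common "type 7" convention),
#' minimum and maximum.
#'
#' @param values numeric vector (non-empty; `sd` needs n >= 2).
#' @return named list: `n, mean, sd, q25, q50, q75, min, max`.
#' @export
summarize_stat <- function(values) {
  if (!length(values)) stop("empty input", call. = FALSE)
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  list(n = length(values), mean = mean(values),
       sd = if (length(values) >= 2L) stats::sd(values) else NA_real_,
       q25 = q[1L], q50 = q[2L], q75 = q[3L],
       min = min(values), max = max(values))
}

#' Bootstrap standard error of a statistic
#'
#' Standard deviation of the statistic across `B` with-replacement
#' resamples of the input.
#'
#' @param values numeric vector (n >= 2).
#' @param statistic function of a numeric vector (default `mean`).
#' @param B number of bootstrap resamples (default 1000).
#' @param seed integer seed (RNG state restored on exit).
#' @return bootstrap standard error.
#' @export
bootstrap_se <- function(values, statistic = mean, B = 1000L, seed = NULL) {
  if (length(values) < 2L) stop("need n >= 2", call. = FALSE)
  if (B < 2L) stop("B must be >= 2", call. = FALSE)
  n <- length(values)
  with_seed(seed, {
    reps <- vapply(seq_len(B), function(b) {
      statistic(values[sample.int(n, n, replace = TRUE)])
    }, numeric(1L))
    stats::sd(reps)
  })
}

#' Separation of two estimates in standard errors
#'
#' `D = |theta_model - theta_real| / sqrt(se_model^2 + se_real^2)`, the
#' number of combined standard errors separating two point estimates.
#'
#' @param theta_model,theta_real point estimates.
#' @param se_model,se_real their standard errors (not both zero).
#' @return the non-negative separation `D`.
#' @export
d_statistic <- function(theta_model, se_model, theta_real, se_real) {
  if (se_model < 0 || se_real < 0) stop("standard errors must be >= 0", call. = FALSE)
  den <- sqrt(se_model^2 + se_real^2)
  if (den == 0) stop("both standard errors are zero: D undefined", call. = FALSE)
  abs(theta_model - theta_real) / den
}

#' Read a key-value experiment configuration file
#'
#' Lines of the form `key = value`; `#` comments and blank lines ignored.
#' Recognized keys: `name`, `relationships` (comma-separated labels, see
#' [parse_relationship()]), `models` (comma-separated, see
#' [crossover_models()]), `pairs` (replicates per cell), `bootstrap`
#' (resamples), `map` (`"synthetic-genome"` or a sex-specific map file
#' path), `interference` (`"default"` or a parameter file path).
#'
#' @param path config file path.
#' @return named list of configuration values.
#' @export
read_experiment_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config '%s' does not exist", path), call. = FALSE)
  raw <- readLines(path)
  lines <- raw[!grepl("^\\s*(#|$)", raw)]
  eq <- regexpr("=", lines, fixed = TRUE)
  if (any(eq < 0L)) {
    stop("malformed config line: ", lines[which(eq < 0L)[1L]], call. = FALSE)
  }
  out <- stats::setNames(
    as.list(trimws(substr(lines, eq + 1L, nchar(lines)))),
    trimws(substr(lines, 1L, eq - 1L)))
  for (key in c("pairs", "bootstrap")) {
    if (!is.null(out[[key]])) out[[key]] <- as.integer(out[[key]])
  }
  for (key in c("relationships", "models")) {
    if (!is.null(out[[key]])) out[[key]] <- trimws(strsplit(out[[key]], ",")[[1L]])
  }
  out
}

#' Run a relationship-by-model simulation experiment
#'
#' For every combination of relationship and crossover model in the
#' configuration, simulates the requested number of relative pairs,
#' computes per-pair IBD summaries, and returns a tidy table of summary
#' statistics (IBD proportion, IBD2 fraction, segment count, total segment
#' length, and the fraction of pairs sharing at least one segment) with
#' bootstrap standard errors for the mean and standard deviation.
#'
#' @param config a list (see [read_experiment_config()]) or a config file
#'   path.
#' @param map optional [genetic_map()] overriding the config's map.
#' @param interference optional [sexed_interference()] overriding the
#'   config's interference parameters.
#' @param scale multiplier applied to the configured pair count (use < 1
#'   for desk-scale runs).
#' @param seed integer seed; each relationship-model cell draws from an
#'   independent substream derived from it.
#' @return data frame with columns `relationship, model, statistic, n,
#'   mean, sd, q25, q50, q75, min, max, se_mean, se_sd`.
#' @export
run_experiment <- function(config, map = NULL, interference = NULL,
                           scale = 1, seed = 1L) {
  if (is.character(config)) config <- read_experiment_config(config)
  rels <- config$relationships
  models <- config$models
  if (is.null(rels) || is.null(models)) {
    stop("config needs `relationships` and `models`", call. = FALSE)
  }
  n_pairs <- max(2L, as.integer(ceiling((config$pairs %||% 1000L) * scale)))
  B <- config$bootstrap %||% 1000L
  if (is.null(map)) {
    map_spec <- config$map %||% "synthetic-genome"
    map <- if (identical(map_spec, "synthetic-genome")) make_synthetic_genome()
           else read_genetic_map(map_spec, dialect = "sex-specific")
  }
  if (is.null(interference)) {
    intf_spec <- config$interference %||% "default"
    interference <- if (identical(intf_spec, "default")) default_interference()
                    else read_interference_params(intf_spec)
  }
  cell <- 0L
  rows <- list()
  for (rel in rels) {
    ped <- parse_relationship(rel)
    for (model in models) {
      cell <- cell + 1L
      sim <- simulate_pedigree(ped, map, model = model,
                               interference = interference, n = n_pairs,
                               seed = seed * 10000L + cell)
      s <- ibd_summary(sim)
      feats <- list(proportion = s$proportion, ibd2 = s$k2,
                    n_segments = as.numeric(s$n_segments),
                    total_cM = s$total_cM,
                    sharing = as.numeric(s$n_segments > 0))
      for (st in names(feats)) {
        v <- feats[[st]]
        sm <- summarize_stat(v)
        se_mean <- bootstrap_se(v, mean, B = B, seed = seed * 10000L + cell)
        se_sd <- bootstrap_se(v, stats::sd, B = B, seed = seed * 10000L + cell + 1L)
        rows[[length(rows) + 1L]] <- data.frame(
          relationship = rel, model = model, statistic = st, n = sm$n,
          mean = sm$mean, sd = sm$sd, q25 = sm$q25, q50 = sm$q50,
          q75 = sm$q75, min = sm$min, max = sm$max,
          se_mean = se_mean, se_sd = se_sd)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
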