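#' Theory specification for IBD segment lengths under interference
#'
#' Bundles the parameters of the closed-form renewal-process densities:
#' `T` generations to the common ancestor (the pair is separated by `2T`
#' meioses), the Housworth-Stahl shape `nu` and escape fraction `p` (on the
#' sex-averaged axis), the chromosome genetic length `L` in Morgans (may be
#' `Inf`), and the series truncation `k_max`.  Increasing `k_max` beyond
#' the default changes the densities negligibly for lengths up to several
#' Morgans.
#'
#' @param T generations to the common ancestor (>= 1).
#' @param nu gamma shape > 0.
#' @param p escape fraction in `[0, 1)` (at `p = 1` the regulated pathway
#'   has zero rate and the densities are undefined; use the Poisson
#'   forms).
#' @param L chromosome genetic length, Morgans (> 0, default `Inf`).
#' @param k_max series truncation (default 50).
#' @return an object of class `theory_spec`.
#' @export
theory_spec <- function(T, nu, p, L = Inf, k_max = 50L) {
  if (T < 1) stop("T must be >= 1", call. = FALSE)
  if (nu <= 0) stop("nu must be positive", call. = FALSE)
  if (p < 0 || p >= 1) {
    stop("p must lie in [0, 1); the p = 1 limit has no regulated pathway",
         call. = FALSE)
  }
  if (L <= 0) stop("L must be positive", call. = FALSE)
  if (k_max < 1L) stop("k_max must be >= 1", call. = FALSE)
  structure(list(T = T, nu = nu, p = p, L = L, k_max = as.integer(k_max)),
            class = "theory_spec")
}

#' Density of the distance between regulated crossovers
#'
#' The inter-crossover distance on the regulated (interference) pathway,
#' after probability-1/2 thinning of the gamma chiasma renewal: a mixture
#' over the number `k` of skipped chiasmata of gamma densities with shape
#' `k * nu` and rate `2 * nu * (1 - p)`, with geometric weights `2^-k`.
#' Its mean is `1 / (1 - p)` Morgans.
#'
#' @param x distance(s), Morgans (>= 0).
#' @param spec a [theory_spec()].
#' @return density values.
#' @export
f_reg <- function(x, spec) {
  stopifnot(inherits(spec, "theory_spec"))
  if (any(x < 0)) stop("x must be >= 0", call. = FALSE)
  nu <- spec$nu
  rate <- 2 * nu * (1 - spec$p)
  k <- seq_len(spec$k_max)
  out <- numeric(length(x))
  pos <- x > 0
  if (any(pos)) {
    lx <- log(x[pos])
    # log term_k(x) = -k log 2 + (k nu - 1) log x - rate x + k nu log rate - lgamma(k nu)
    lt <- outer(lx, k * nu - 1) + rep(-rate * x[pos], times = length(k)) +
      matrix(rep(-k * log(2) + k * nu * log(rate) - lgamma(k * nu),
                 each = sum(pos)), nrow = sum(pos))
    out[pos] <- rowSums(exp(lt))
  }
  if (any(!pos)) { # x = 0: only a k with k*nu == 1 contributes
    v <- 0
    exact <- which(abs(k * nu - 1) < 1e-12)
    if (length(exact)) v <- 2^-exact[1L] * rate
    if (nu < 1) v <- Inf # k nu - 1 < 0 for k = 1: density diverges at 0
    out[!pos] <- v
  }
  out
}

#' Density of the distance from a random site to the next regulated crossover
#'
#' Stationary-renewal forward-recurrence density of [f_reg()]:
#' `g_reg(x) = (1 - p) * (1 - F_reg(x))`, expressed through regularized
#' upper incomplete gamma functions.  `g_reg(0) = 1 - p`.
#'
#' @inheritParams f_reg
#' @return density values.
#' @export
g_reg <- function(x, spec) {
  stopifnot(inherits(spec, "theory_spec"))
  if (any(x < 0)) stop("x must be >= 0", call. = FALSE)
  nu <- spec$nu
  rate <- 2 * nu * (1 - spec$p)
  k <- seq_len(spec$k_max)
  # sum_k 2^-k Q(k nu, rate x), Q the regularized upper incomplete gamma
  acc <- numeric(length(x))
  for (kk in k) {
    acc <- acc + 2^-kk * stats::pgamma(rate * x, shape = kk * nu, lower.tail = FALSE)
  }
  (1 - spec$p) * acc
}

#' Upper tail of the forward-recurrence distribution
#'
#' `G_reg_tail(x) = integral of g_reg from x to infinity`, evaluated in
#' closed form via the identity
#' `int_0^x Q(a, c y) dy = x Q(a, c x) + (a / c) P(a + 1, c x)`
#' (`P`/`Q` the regularized lower/upper incomplete gamma functions).
#'
#' @inheritParams f_reg
#' @return tail probabilities in `[0, 1]`.
#' @export
G_reg_tail <- function(x, spec) {
  stopifnot(inherits(spec, "theory_spec"))
  if (any(x < 0)) stop("x must be >= 0", call. = FALSE)
  nu <- spec$nu
  rate <- 2 * nu * (1 - spec$p)
  k <- seq_len(spec$k_max)
  acc <- numeric(length(x))
  for (kk in k) {
    a <- kk * nu
    acc <- acc + 2^-kk *
      (x * stats::pgamma(rate * x, shape = a, lower.tail = FALSE) +
         (a / rate) * stats::pgamma(rate * x, shape = a + 1))
  }
  pmax(0, pmin(1, 1 - (1 - spec$p) * acc))
}

#' Density of the distance to the nearest crossover across 2T meioses
#'
#' The minimum over the `2T` independent meioses separating the pair, each
#' contributing a regulated and a free (escape) pathway:
#' `h(x) = 2T exp(-2 p T x) G_reg_tail(x)^(2T - 1)
#'   (g_reg(x) + p * G_reg_tail(x))`, with `h(0) = 2T`.
#'
#' @inheritParams f_reg
#' @return density values.
#' @export
nearest_crossover_density <- function(x, spec) {
  T2 <- 2 * spec$T
  Gt <- G_reg_tail(x, spec)
  T2 * exp(-spec$p * T2 * x) * Gt^(T2 - 1) * (g_reg(x, spec) + spec$p * Gt)
}

#' Density of the length of a randomly chosen inter-crossover interval
#'
#' The infinite-chromosome IBD segment-length density under the
#' sex-averaged interference model, obtained from the superposition of the
#' `2T` renewal processes as `-(1 / 2T) d h / d x`:
#' \deqn{\phi(x) = e^{-2pTx} \tilde G^{2T-1} [4pT g + (2T-1) g^2 / \tilde G
#'   + (1-p) f + 2 p^2 T \tilde G]}
#' with `f = f_reg`, `g = g_reg`, `\tilde G = G_reg_tail`.  Its mean is
#' `1 / (2T)` Morgans.
#'
#' @inheritParams f_reg
#' @return density values.
#' @export
segment_length_density <- function(x, spec) {
  T2 <- 2 * spec$T
  p <- spec$p
  Gt <- G_reg_tail(x, spec)
  g <- g_reg(x, spec)
  f <- f_reg(x, spec)
  exp(-p * T2 * x) *
    ((T2 - 1) * g^2 * Gt^(T2 - 2) +
       Gt^(T2 - 1) * (2 * p * T2 * g + (1 - p) * f) +
       p^2 * T2 * Gt^T2)
}

#' Segment-length density on a finite chromosome
#'
#' Applies the finite-chromosome correction for a stationary partition
#' process: with `mu = 1 / (2T)` the mean interval length,
#' `phi_L(x) = (2 S(x) + (L - x) phi(x)) / (L + mu)` for `0 <= x < L`,
#' where `S(x)` is the upper tail of [segment_length_density()], plus a
#' point mass at `x = L` (a segment spanning the whole chromosome) of
#' `(int_L^Inf S) / (L + mu)`.  The tail `S(x)` equals
#' `nearest_crossover_density(x) / (2T)` and is evaluated in closed form;
#' the atom requires one numerical integral.  The continuous part and the
#' atom are returned separately so that total mass is testable.
#'
#' @param x length(s), Morgans, in `[0, L]`.
#' @param spec a [theory_spec()] with finite `L`.
#' @return list with `density` (continuous part at `x`) and `atom` (mass
#'   at `L`).
#' @export
segment_length_density_finite <- function(x, spec) {
  stopifnot(inherits(spec, "theory_spec"))
  if (!is.finite(spec$L)) stop("spec$L must be finite", call. = FALSE)
  if (any(x < 0) || any(x > spec$L)) {
    stop("x must lie in [0, L]", call. = FALSE)
  }
  T2 <- 2 * spec$T
  mu <- 1 / T2
  S <- function(u) nearest_crossover_density(u, spec) / T2   # upper tail of phi
  denom <- spec$L + mu
  dens <- (2 * S(x) + (spec$L - x) * segment_length_density(x, spec)) / denom
  atom <- stats::integrate(function(u) S(u), spec$L, Inf,
                           rel.tol = 1e-10, abs.tol = 1e-12)$value / denom
  list(density = dens, atom = atom)
}

#' Poisson-model segment-length density
#'
#' The no-interference counterparts: on an infinite chromosome
#' `phi(x) = 2T exp(-2Tx)`; on a finite chromosome of length `L` Morgans
#' the continuous part is `2T exp(-2Tx) (2 + 2T (L - x)) / (2TL + 1)` with
#' an atom `exp(-2TL) / (2TL + 1)` at `x = L`.
#'
#' @param x length(s), Morgans.
#' @param T generations to the common ancestor.
#' @param L chromosome length, Morgans; `Inf` for the infinite-chromosome
#'   density.
#' @return for infinite `L`, density values; otherwise a list with
#'   `density` and `atom`.
#' @export
segment_length_density_poisson <- function(x, T, L = Inf) {
  T2 <- 2 * T
  if (!is.finite(L)) return(T2 * exp(-T2 * x))
  if (any(x < 0) || any(x > L)) stop("x must lie in [0, L]", call. = FALSE)
  list(density = T2 * exp(-T2 * x) * (2 + T2 * (L - x)) / (T2 * L + 1),
       atom = exp(-T2 * L) / (T2 * L + 1))
}

#' Cumulative mass of the finite-chromosome segment-length distribution
#'
#' The continuous cumulative distribution of
#' [segment_length_density_finite()] in closed form.  Writing `H` for the
#' CDF of the nearest-crossover distance (`H(x) = 1 - exp(-2pTx)
#' G_reg_tail(x)^(2T)`) and `h` for its density, the mass on `[0, x]` is
#' `(H(x) / (2T) + L - (L - x) h(x) / (2T)) / (L + 1 / (2T)) - C(0)`;
#' adding the atom at `L` brings the total to 1.  Used for exact bin
#' probabilities when comparing simulated histograms with the theory.
#'
#' @param x length(s), Morgans, in `[0, L]`.
#' @param spec a [theory_spec()] with finite `L`.
#' @return cumulative probabilities (continuous part only, i.e. excluding
#'   the atom at `L`).
#' @export
segment_length_cdf_finite <- function(x, spec) {
  stopifnot(inherits(spec, "theory_spec"))
  if (!is.finite(spec$L)) stop("spec$L must be finite", call. = FALSE)
  if (any(x < 0) || any(x > spec$L)) stop("x must lie in [0, L]", call. = FALSE)
  T2 <- 2 * spec$T
  Hcdf <- function(u) 1 - exp(-spec$p * T2 * u) * G_reg_tail(u, spec)^T2
  h <- nearest_crossover_density(x, spec)
  raw <- function(u, hu) (Hcdf(u) / T2 + spec$L - (spec$L - u) * hu / T2)
  (raw(x, h) - raw(0, T2)) / (spec$L + 1 / T2)
}

# ---------------------------------------------------------------------------
# Sex-specific Poisson theory: inhomogeneous-Poisson inter-crossover density

#' Piecewise-constant crossover rates on a physical grid
#'
#' Discretizes one chromosome of a sex-specific map into bins of `step` bp
#' with constant male and female crossover rates (Morgans per bp) in each
#' bin, the discretization under which the inhomogeneous-Poisson
#' inter-crossover density is evaluated.
#'
#' @param map a sex-specific [genetic_map()].
#' @param chrom chromosome label.
#' @param step bin width, bp (default `1e4`).
#' @return object of class `ss_rate_grid`: list with `edges` (bin edges,
#'   bp, relative to the chromosome start), `lam_f`, `lam_m` (rates per
#'   bin), and `L` (chromosome physical span, bp).
#' @export
ss_rate_grid <- function(map, chrom, step = 1e4) {
  if (map$dialect != "sex-specific") stop("need a sex-specific map", call. = FALSE)
  df <- .map_chrom(map, chrom)
  span <- df$pos[nrow(df)] - df$pos[1L]
  edges <- unique(c(seq(0, span, by = step), span))
  at <- df$pos[1L] + edges
  gf <- stats::approx(df$pos, df$female, xout = at, ties = "ordered")$y / 100
  gm <- stats::approx(df$pos, df$male, xout = at, ties = "ordered")$y / 100
  structure(list(edges = edges,
                 lam_f = diff(gf) / diff(edges),
                 lam_m = diff(gm) / diff(edges),
                 L = span),
            class = "ss_rate_grid")
}

#' Weights of female meiosis counts for cousin-type pairs
#'
#' For pairs separated by `2T` meioses through a common ancestor whose sex
#' is random, the number of female transmissions is
#' `n_f = n_fi + 2 n_fa` with `n_fi ~ Binomial(2T - 2, 1/2)` (the
#' intermediate meioses) and `n_fa ~ Bernoulli(1/2)` (the transmitting
#' ancestor, who contributes two meioses of the same sex).
#'
#' @param T generations to the common ancestor (>= 1).
#' @return data frame with columns `n_f` (0..2T) and `weight` (sums to 1).
#' @export
ss_meiosis_weights <- function(T) {
  n_f <- 0:(2 * T)
  w <- 0.5 * stats::dbinom(n_f, 2 * T - 2, 0.5) +
    0.5 * stats::dbinom(n_f - 2L, 2 * T - 2, 0.5)
  data.frame(n_f = n_f, weight = w)
}

.ss_lambda <- function(grid, n_f, n_m) {
  grid$lam_f * n_f + grid$lam_m * n_m
}

# rate and cumulative rate lookups at arbitrary physical offsets
.ss_bin <- function(edges, nbins, u) {
  pmin(pmax(findInterval(u, edges), 1L), nbins)
}

.ss_lam_at <- function(lam, edges, u) {
  lam[.ss_bin(edges, length(lam), u)]
}

.ss_Lam_at <- function(lam, edges, u) {
  Lam <- c(0, cumsum(lam * diff(edges)))
  i <- .ss_bin(edges, length(lam), u)
  Lam[i] + (u - edges[i]) * lam[i]
}

#' Inter-crossover distance density under a sex-specific Poisson model
#'
#' For `n_f` female and `2T - n_f` male meioses, crossovers along physical
#' coordinates form an inhomogeneous Poisson process with rate
#' `lambda(x) = lambda_f(x) n_f + lambda_m(x) n_m`.  The density of the
#' distance between consecutive events on a chromosome of physical length
#' `L` is
#' `phi(x) = (1 / Lambda(L)) int_0^(L-x) lambda(y) lambda(y + x)
#'    exp(-[Lambda(y + x) - Lambda(y)]) dy + lambda(x) exp(-Lambda(x)) /
#'    Lambda(L)`,
#' the second term covering the first (left-censored) interval.  Integrals
#' are evaluated as sums over the rate grid's bins.
#'
#' @param x physical distance(s), bp, in `[0, L]`.
#' @param grid an [ss_rate_grid()].
#' @param n_f number of female meioses (0..2T).
#' @param T generations to the common ancestor.
#' @return density values (per bp).
#' @export
ss_interarrival_density <- function(x, grid, n_f, T) {
  stopifnot(inherits(grid, "ss_rate_grid"))
  n_m <- 2 * T - n_f
  if (n_f < 0 || n_m < 0) stop("n_f must lie in 0..2T", call. = FALSE)
  lam <- .ss_lambda(grid, n_f, n_m)
  if (all(lam == 0)) stop("all-zero crossover rate", call. = FALSE)
  edges <- grid$edges
  widths <- diff(edges)
  mids <- edges[-length(edges)] + widths / 2
  Lam <- c(0, cumsum(lam * widths))      # cumulative rate at bin edges
  LamL <- Lam[length(Lam)]
  lam_at <- function(u) lam[.ss_bin(edges, length(lam), u)]
  Lam_at <- function(u) {
    i <- .ss_bin(edges, length(lam), u)
    Lam[i] + (u - edges[i]) * lam[i]
  }
  Lam_mid <- Lam_at(mids)
  vapply(x, function(xx) {
    keep <- mids + xx <= grid$L
    t1 <- if (any(keep)) {
      u2 <- mids[keep] + xx
      sum(lam[keep] * lam_at(u2) * exp(-(Lam_at(u2) - Lam_mid[keep])) *
            widths[keep]) / LamL
    } else 0
    t1 + lam_at(xx) * exp(-Lam_at(xx)) / LamL
  }, numeric(1L))
}

#' Mixture inter-crossover density over female meiosis counts
#'
#' Averages [ss_interarrival_density()] over the [ss_meiosis_weights()]
#' distribution of `n_f`, giving the unconditional segment-length density
#' under the sex-specific Poisson model.  When the male and female rate
#' functions coincide the mixture collapses to a single term.
#'
#' @inheritParams ss_interarrival_density
#' @return density values (per bp).
#' @export
ss_mixture_density <- function(x, grid, T) {
  w <- ss_meiosis_weights(T)
  acc <- numeric(length(x))
  for (i in seq_len(nrow(w))) {
    if (w$weight[i] > 0) {
      acc <- acc + w$weight[i] * ss_interarrival_density(x, grid, w$n_f[i], T)
    }
  }
  acc
}
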