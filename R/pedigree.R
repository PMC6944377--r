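# Pedigree structures: an internal graph of individuals plus the metadata
# the simulation engine needs (couples for sex assignment, printed members,
# pairs for IBD extraction).

.new_ped_builder <- function(name) {
  env <- new.env(parent = emptyenv())
  env$name <- name
  env$label <- character()
  env$parent1 <- integer()
  env$parent2 <- integer()
  env$sex_fixed <- integer()
  env$generation <- integer()
  env$couples <- matrix(integer(), ncol = 2L)
  env$pop <- character()
  env
}

.ped_add <- function(env, label, parent1 = NA_integer_, parent2 = NA_integer_,
                     sex = 0L, generation = 1L, pop = NA_character_) {
  env$label <- c(env$label, label)
  env$parent1 <- c(env$parent1, parent1)
  env$parent2 <- c(env$parent2, parent2)
  env$sex_fixed <- c(env$sex_fixed, as.integer(sex))
  env$generation <- c(env$generation, as.integer(generation))
  env$pop <- c(env$pop, pop)
  length(env$label)
}

.ped_couple <- function(env, a, b) {
  env$couples <- rbind(env$couples, c(a, b))
}

.ped_finish <- function(env, print_idx, copies = 1L, pairs = NULL) {
  founder <- is.na(env$parent1)
  if (is.null(pairs)) {
    pairs <- if (length(print_idx) >= 2L) t(utils::combn(print_idx, 2L))
             else matrix(integer(), ncol = 2L)
  }
  structure(list(name = env$name,
                 ind = data.frame(label = env$label, parent1 = env$parent1,
                                  parent2 = env$parent2,
                                  sex_fixed = env$sex_fixed,
                                  generation = env$generation,
                                  founder = founder,
                                  pop = env$pop, stringsAsFactors = FALSE),
                 couples = env$couples,
                 print_idx = as.integer(print_idx),
                 pairs = matrix(as.integer(pairs), ncol = 2L),
                 copies = as.integer(copies)),
            class = "pedigree")
}

#' @export
print.pedigree <- function(x, ...) {
  cat(sprintf("<pedigree> '%s': %d individuals (%d founders), %d printed, %d pair(s), %d cop%s\n",
              x$name, nrow(x$ind), sum(x$ind$founder), length(x$print_idx),
              nrow(x$pairs), x$copies, if (x$copies == 1L) "y" else "ies"))
  invisible(x)
}

#' Founder haplotype identifiers of a pedigree
#'
#' Founder haplotype ids are consecutive integers assigned in individual
#' order (generation order, then founder order), two per founder, and are
#' stable for a given pedigree.
#'
#' @param ped a `pedigree`.
#' @return data frame with columns `ind` (row index), `label`, `hap` (1 or
#'   2) and `founder_id`.
#' @export
founder_hap_ids <- function(ped) {
  f <- which(ped$ind$founder)
  data.frame(ind = rep(f, each = 2L),
             label = rep(ped$ind$label[f], each = 2L),
             hap = rep(1:2, length(f)),
             founder_id = seq_len(2L * length(f)))
}

.sex_code <- function(s) switch(s, none = 0L, random = 0L, male = 1L, female = 2L,
                                stop("unknown sex spec '", s, "'", call. = FALSE))

# one lineage chain below `top`: `extra` additional generations, each child
# coupled with a fresh founder spouse; returns index of the last child.
.extend_lineage <- function(env, top, extra, gen0, lineage_sex, tag) {
  cur <- top
  for (j in seq_len(extra)) {
    sp <- .ped_add(env, sprintf("%s-sp%d", tag, j), generation = gen0 + j - 1L)
    .ped_couple(env, cur, sp)
    child_sex <- if (j < extra) lineage_sex else 0L
    ch <- .ped_add(env, sprintf("%s-g%d", tag, j), parent1 = cur, parent2 = sp,
                   sex = child_sex, generation = gen0 + j)
    cur <- ch
  }
  cur
}

#' Build a pedigree for a standard relationship
#'
#' Constructs the internal pedigree graph for common pairwise
#' relationships.  Descendant lineages can be forced through one sex
#' (`lineage_sex`), which fixes the sex of every reproducing non-founder;
#' spouses take the opposite sex, and founder common ancestors remain a
#' male/female couple.
#'
#' @param kind one of `"parent-child"`, `"full-sib"`, `"half-sib"`,
#'   `"grandparent"`, `"cousin"`, `"half-cousin"`.
#' @param k cousin degree (`kind = "cousin"`): `k = 1` gives first cousins.
#' @param removals extra generations separating the second member
#'   (`kind = "cousin"`), e.g. `k = 1, removals = 1` gives first cousins
#'   once removed.
#' @param T generations to the single common ancestor
#'   (`kind = "half-cousin"`): `T = 1` gives half-siblings.
#' @param n_sibs number of siblings (`kind = "full-sib"`).
#' @param lineage_sex `"random"`, `"female"` or `"male"`: sex of reproducing
#'   non-founders on the connecting lineages.
#' @param shared_parent_sex `"random"`, `"mother"` or `"father"`: sex of the
#'   shared parent (`kind = "half-sib"`) or of the transmitting parent
#'   (`kind = "parent-child"`, `"grandparent"`).
#' @param copies default replicate count carried by the pedigree.
#' @return a `pedigree` object whose printed members are the related pair
#'   (or all `n_sibs` siblings).
#' @export
relationship_preset <- function(kind = c("parent-child", "full-sib", "half-sib",
                                         "grandparent", "cousin", "half-cousin"),
                                k = 1L, removals = 0L, T = 1L, n_sibs = 2L,
                                lineage_sex = c("random", "female", "male"),
                                shared_parent_sex = c("random", "mother", "father"),
                                copies = 1L) {
  kind <- match.arg(kind)
  lineage_sex <- match.arg(lineage_sex)
  shared_parent_sex <- match.arg(shared_parent_sex)
  lsex <- switch(lineage_sex, random = 0L, female = 2L, male = 1L)
  psex <- switch(shared_parent_sex, random = 0L, mother = 2L, father = 1L)

  env <- .new_ped_builder(kind)
  if (kind == "parent-child") {
    p1 <- .ped_add(env, "parent", sex = psex)
    p2 <- .ped_add(env, "spouse")
    .ped_couple(env, p1, p2)
    ch <- .ped_add(env, "child", parent1 = p1, parent2 = p2, generation = 2L)
    return(.ped_finish(env, c(p1, ch), copies))
  }
  if (kind == "full-sib") {
    p1 <- .ped_add(env, "father", sex = 1L)
    p2 <- .ped_add(env, "mother", sex = 2L)
    .ped_couple(env, p1, p2)
    sibs <- vapply(seq_len(n_sibs), function(i) {
      .ped_add(env, sprintf("sib%d", i), parent1 = p1, parent2 = p2,
               generation = 2L)
    }, integer(1L))
    return(.ped_finish(env, sibs, copies))
  }
  if (kind == "half-sib") {
    s <- .ped_add(env, "shared-parent", sex = psex)
    a1 <- .ped_add(env, "spouse1")
    a2 <- .ped_add(env, "spouse2")
    .ped_couple(env, s, a1)
    .ped_couple(env, s, a2)
    k1 <- .ped_add(env, "half-sib1", parent1 = s, parent2 = a1, generation = 2L)
    k2 <- .ped_add(env, "half-sib2", parent1 = s, parent2 = a2, generation = 2L)
    return(.ped_finish(env, c(k1, k2), copies))
  }
  if (kind == "grandparent") {
    g1 <- .ped_add(env, "grandparent1")
    g2 <- .ped_add(env, "grandparent2")
    .ped_couple(env, g1, g2)
    par <- .ped_add(env, "parent", parent1 = g1, parent2 = g2, sex = psex,
                    generation = 2L)
    sp <- .ped_add(env, "parent-spouse", generation = 2L)
    .ped_couple(env, par, sp)
    gc <- .ped_add(env, "grandchild", parent1 = par, parent2 = sp, generation = 3L)
    return(.ped_finish(env, c(g1, gc), copies))
  }
  if (kind == "cousin") {
    if (k < 1L || removals < 0L) stop("need k >= 1 and removals >= 0", call. = FALSE)
    f1 <- .ped_add(env, "ancestor1")
    f2 <- .ped_add(env, "ancestor2")
    .ped_couple(env, f1, f2)
    out <- integer(2L)
    for (b in 1:2) {
      extra <- k + (b - 1L) * removals   # meioses below the sibling
      sib <- .ped_add(env, sprintf("b%d-sib", b), parent1 = f1, parent2 = f2,
                      sex = if (extra > 0L) lsex else 0L, generation = 2L)
      out[b] <- if (extra == 0L) sib
                else .extend_lineage(env, sib, extra, 2L, lsex, sprintf("b%d", b))
    }
    env$name <- if (removals > 0L) sprintf("cousin-%d-removed-%d", k, removals)
                else sprintf("cousin-%d", k)
    return(.ped_finish(env, out, copies))
  }
  # half-cousin: single founder common ancestor, T meioses on each side
  if (T < 1L) stop("need T >= 1", call. = FALSE)
  ca <- .ped_add(env, "common-ancestor")
  out <- integer(2L)
  for (b in 1:2) {
    sp <- .ped_add(env, sprintf("b%d-ca-sp", b))
    .ped_couple(env, ca, sp)
    ch <- .ped_add(env, sprintf("b%d-g1", b), parent1 = ca, parent2 = sp,
                   sex = if (T > 1L) lsex else 0L, generation = 2L)
    out[b] <- if (T == 1L) ch
              else .extend_lineage(env, ch, T - 1L, 2L, lsex, sprintf("b%d", b))
  }
  env$name <- sprintf("half-cousin-T%d", T)
  .ped_finish(env, out, copies)
}

#' Parse a relationship label
#'
#' Labels used by experiment configurations: `"full-sib"`, `"parent-child"`,
#' `"grandparent"`, `"half-sib"`, `"half-sib-maternal"`,
#' `"half-sib-paternal"`, `"cousin-<k>"`, `"cousin-<k>-removed-<r>"`,
#' `"half-cousin-T<T>"`, with an optional `"-female"`/`"-male"` suffix
#' forcing the lineage sex.
#'
#' @param label relationship label string.
#' @return a `pedigree` object.
#' @export
parse_relationship <- function(label) {
  lineage <- "random"
  base <- label
  if (grepl("-(female|male)$", base) && !grepl("^half-sib", base)) {
    lineage <- sub("^.*-(female|male)$", "\\1", base)
    base <- sub("-(female|male)$", "", base)
  }
  if (base %in% c("full-sib", "parent-child", "grandparent", "half-sib")) {
    return(relationship_preset(base, lineage_sex = lineage))
  }
  if (base == "half-sib-maternal") {
    return(relationship_preset("half-sib", shared_parent_sex = "mother"))
  }
  if (base == "half-sib-paternal") {
    return(relationship_preset("half-sib", shared_parent_sex = "father"))
  }
  m <- regmatches(base, regexec("^cousin-([0-9]+)(-removed-([0-9]+))?$", base))[[1L]]
  if (length(m)) {
    r <- if (m[4L] == "") 0L else as.integer(m[4L])
    return(relationship_preset("cousin", k = as.integer(m[2L]), removals = r,
                               lineage_sex = lineage))
  }
  m <- regmatches(base, regexec("^half-cousin-T([0-9]+)$", base))[[1L]]
  if (length(m)) {
    return(relationship_preset("half-cousin", T = as.integer(m[2L]),
                               lineage_sex = lineage))
  }
  stop(sprintf("unknown relationship label '%s'", label), call. = FALSE)
}

#' Parse pedigree definition (def) text
#'
#' Each block starts with `def <name> <copies> <n_generations> [M|F]`
#' followed by per-generation lines `<generation> <n_print> [<n_branches>]`.
#' Generation 1 is a single founder couple; generation 2 defaults to 2
#' branches (children of that couple); later generations default to one
#' child per branch, with each reproducing child's spouse a new founder.
#' When `<n_branches>` grows between generations, each branch splits into
#' `n_branches[g] / n_branches[g-1]` children (the ratio must be an
#' integer).  `n_print` individuals per branch are printed: capacity 2 in
#' generation 1 (the couple), 1 elsewhere.  An `M` or `F` suffix forces all
#' reproducing non-founders to that sex (spouses take the opposite sex).
#' Unlisted generations print nobody and keep the default branch counts.
#'
#' @param text def-file content (single string or character vector of lines).
#' @return list of `pedigree` objects, one per `def` block, each carrying
#'   its replicate count in `$copies`.
#' @export
parse_def <- function(text) {
  lines <- if (length(text) == 1L && grepl("\n", text)) {
    strsplit(text, "\n")[[1L]]
  } else text
  keep <- which(!grepl("^\\s*(#|$)", lines))
  toks <- lapply(keep, function(i) strsplit(trimws(lines[i]), "\\s+")[[1L]])
  blocks <- list()
  cur <- NULL
  flush <- function(cur) {
    if (is.null(cur)) return(NULL)
    .build_def_pedigree(cur)
  }
  for (j in seq_along(toks)) {
    tk <- toks[[j]]
    ln <- keep[j]
    if (tk[1L] == "def") {
      if (!is.null(cur)) blocks[[length(blocks) + 1L]] <- flush(cur)
      if (length(tk) < 4L || length(tk) > 5L) {
        stop(sprintf("parse error at line %d: expected 'def name copies n_gen [M|F]'", ln),
             call. = FALSE)
      }
      copies <- suppressWarnings(as.integer(tk[3L]))
      n_gen <- suppressWarnings(as.integer(tk[4L]))
      if (is.na(copies) || copies < 1L) {
        stop(sprintf("parse error at line %d: copies must be a positive integer", ln),
             call. = FALSE)
      }
      if (is.na(n_gen) || n_gen < 2L) {
        stop(sprintf("parse error at line %d: a pedigree needs >= 2 generations", ln),
             call. = FALSE)
      }
      forced <- 0L
      if (length(tk) == 5L) {
        forced <- switch(tk[5L], M = 1L, F = 2L,
                         stop(sprintf("parse error at line %d: unknown token '%s'",
                                      ln, tk[5L]), call. = FALSE))
      }
      cur <- list(name = tk[2L], copies = copies, n_gen = n_gen,
                  forced = forced, plan = list())
    } else {
      if (is.null(cur)) {
        stop(sprintf("parse error at line %d: generation line before any 'def'", ln),
             call. = FALSE)
      }
      if (length(tk) < 2L || length(tk) > 3L) {
        stop(sprintf("parse error at line %d: expected '<gen> <n_print> [<n_branches>]'", ln),
             call. = FALSE)
      }
      v <- suppressWarnings(as.integer(tk))
      if (anyNA(v)) {
        stop(sprintf("parse error at line %d: unknown token", ln), call. = FALSE)
      }
      if (v[1L] < 1L || v[1L] > cur$n_gen) {
        stop(sprintf("parse error at line %d: generation %d outside 1..%d",
                     ln, v[1L], cur$n_gen), call. = FALSE)
      }
      cur$plan[[length(cur$plan) + 1L]] <-
        list(gen = v[1L], n_print = v[2L],
             n_branches = if (length(v) == 3L) v[3L] else NA_integer_, line = ln)
    }
  }
  if (!is.null(cur)) blocks[[length(blocks) + 1L]] <- flush(cur)
  if (!length(blocks)) stop("no 'def' blocks found", call. = FALSE)
  blocks
}

.build_def_pedigree <- function(spec) {
  n_gen <- spec$n_gen
  explicit <- rep(NA_integer_, n_gen)
  n_print <- integer(n_gen)
  for (pl in spec$plan) {
    if (!is.na(pl$n_branches)) {
      if (pl$gen == 1L && pl$n_branches != 1L) {
        stop(sprintf("parse error at line %d: generation 1 has a single branch", pl$line),
             call. = FALSE)
      }
      explicit[pl$gen] <- pl$n_branches
    }
    n_print[pl$gen] <- pl$n_print
  }
  n_branches <- integer(n_gen)
  n_branches[1L] <- 1L
  n_branches[2L] <- if (is.na(explicit[2L])) 2L else explicit[2L]
  if (n_gen >= 3L) {
    for (g in 3:n_gen) {
      n_branches[g] <- if (is.na(explicit[g])) n_branches[g - 1L] else explicit[g]
    }
  }
  for (g in seq_len(n_gen)) {
    cap <- if (g == 1L) 2L else 1L
    if (n_print[g] < 0L || n_print[g] > cap) {
      stop(sprintf("parse error in '%s': n_print %d exceeds branch capacity %d in generation %d",
                   spec$name, n_print[g], cap, g), call. = FALSE)
    }
    if (g >= 2L && n_branches[g] %% n_branches[g - 1L] != 0L) {
      stop(sprintf("parse error in '%s': branch count %d in generation %d is not a multiple of %d",
                   spec$name, n_branches[g], g, n_branches[g - 1L]), call. = FALSE)
    }
  }

  env <- .new_ped_builder(spec$name)
  print_idx <- integer()
  f1 <- .ped_add(env, "g1-f1")
  f2 <- .ped_add(env, "g1-f2")
  .ped_couple(env, f1, f2)
  if (n_print[1L] >= 1L) print_idx <- c(print_idx, f1)
  if (n_print[1L] == 2L) print_idx <- c(print_idx, f2)
  branch_member <- list(c(f1, f2)) # generation 1: the couple acts as one branch
  for (g in 2:n_gen) {
    per <- n_branches[g] / n_branches[g - 1L]
    members <- integer(n_branches[g])
    for (b in seq_len(n_branches[g - 1L])) {
      par <- branch_member[[b]]
      if (length(par) == 1L) { # give the reproducing member a founder spouse
        sp <- .ped_add(env, sprintf("g%d-b%d-sp", g - 1L, b), generation = g - 1L)
        .ped_couple(env, par, sp)
        par <- c(par, sp)
      }
      for (cb in seq_len(per)) {
        idx <- (b - 1L) * per + cb
        reproduces <- g < n_gen
        ch <- .ped_add(env, sprintf("g%d-b%d-i1", g, idx), parent1 = par[1L],
                       parent2 = par[2L],
                       sex = if (reproduces) spec$forced else 0L, generation = g)
        members[idx] <- ch
        if (n_print[g] >= 1L) print_idx <- c(print_idx, ch)
      }
    }
    branch_member <- as.list(members)
  }
  .ped_finish(env, print_idx, spec$copies)
}
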