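# Sequence design: seeded multi-objective genetic algorithm (NSGA-II
# style: fast non-dominated sorting, crowding distance, binary
# tournament, mu+lambda survivor selection) over the pre- and
# post-aptamer regions, plus a brute-force enumerator for tiny spaces.

.rna_alphabet <- c("A", "C", "G", "U")

# sample() treats a scalar first argument as 1:n; this helper always
# samples from the elements of x
resample <- function(x, size = 1L) x[sample.int(length(x), size)]

#' Design specification for riboswitch sequence optimization
#'
#' @param aptamer an \code{\link{aptamer_spec}} (held fixed by all
#'   variation operators).
#' @param cds RNA string beginning with the start codon.
#' @param mode \code{"ON"} or \code{"OFF"}.
#' @param length_range min/max combined length of the designed pre- and
#'   post-aptamer regions, nt (default 44-55).
#' @param pre_scaffold,post_scaffold fixed sequences flanking the
#'   designed regions (5' of the designed pre; 3' of the designed post,
#'   e.g. a fixed SD cassette), excluded from \code{length_range}.
#' @param forbidden_motifs subsequences disallowed in designed regions
#'   (default "AUG", to avoid spurious start codons in the 5' UTR).
#' @param pop_size,generations,mutation_rate,crossover_rate,indel_rate
#'   GA controls; mutation is per-base, crossover one-point per region,
#'   indels move the region lengths within \code{length_range}.
#' @param seed integer; all GA randomness flows from it and it is
#'   recorded in the output.
#' @param calib \code{\link{calibration_params}}.
#' @return object of class \code{design_spec}.
#' @export
design_spec <- function(aptamer, cds, mode = c("OFF", "ON"),
                        length_range = c(44L, 55L),
                        pre_scaffold = "", post_scaffold = "",
                        forbidden_motifs = "AUG",
                        pop_size = 100L, generations = 50L,
                        mutation_rate = 0.05, crossover_rate = 0.9,
                        indel_rate = 0.1, seed = 1L,
                        calib = calibration_params()) {
  mode <- match.arg(toupper(mode), c("OFF", "ON"))
  stopifnot(inherits(aptamer, "aptamer_spec"),
            length(length_range) == 2L, length_range[1] <= length_range[2],
            length_range[1] >= 0L, length_range[2] <= 200L,
            pop_size >= 4L, generations >= 1L)
  cds <- as_rna(cds)
  pre_scaffold <- if (nzchar(pre_scaffold)) as_rna(pre_scaffold) else ""
  post_scaffold <- if (nzchar(post_scaffold)) as_rna(post_scaffold) else ""
  upstream_max <- nchar(pre_scaffold) + nchar(post_scaffold) +
    nchar(aptamer$sequence) + length_range[2]
  if (upstream_max < nchar(calib$anti_sd) + calib$spacing_range[1]) {
    stop("design error: length_range plus scaffolds and aptamer leaves only ",
         upstream_max, " nt of 5' UTR, too short to host an SD sequence")
  }
  structure(list(aptamer = aptamer, cds = cds, mode = mode,
                 length_range = as.integer(length_range),
                 pre_scaffold = pre_scaffold, post_scaffold = post_scaffold,
                 forbidden_motifs = forbidden_motifs,
                 pop_size = as.integer(pop_size),
                 generations = as.integer(generations),
                 mutation_rate = mutation_rate,
                 crossover_rate = crossover_rate, indel_rate = indel_rate,
                 seed = as.integer(seed), calib = calib),
            class = "design_spec")
}

spec_construct <- function(spec, pre, post, name = "candidate") {
  riboswitch_construct(name, paste0(spec$pre_scaffold, pre), spec$aptamer,
                       paste0(post, spec$post_scaffold), spec$cds, spec$mode)
}

motif_free <- function(spec, pre, post) {
  if (length(spec$forbidden_motifs) == 0L) return(TRUE)
  for (mo in spec$forbidden_motifs) {
    if ((nzchar(pre) && grepl(mo, pre, fixed = TRUE)) ||
        (nzchar(post) && grepl(mo, post, fixed = TRUE))) return(FALSE)
  }
  TRUE
}

# score a (pre, post) pair; objectives are all maximized:
# (r_max, TIR of the designed-high state, -TIR of the designed-low state)
evaluate_candidate <- function(spec, pre, post, cache = NULL) {
  key <- paste(pre, post, sep = "|")
  if (!is.null(cache)) {
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
  }
  pred <- evaluate_switch(spec_construct(spec, pre, post), Inf, spec$calib)
  objectives <- if (spec$mode == "ON") {
    c(r_max = pred$r_max, tir_on = pred$tir_bound, neg_tir_off = -pred$tir_unbound)
  } else {
    c(r_max = pred$r_max, tir_on = pred$tir_unbound, neg_tir_off = -pred$tir_bound)
  }
  cand <- structure(list(pre_aptamer = pre, post_aptamer = post,
                         prediction = pred, objectives = objectives),
                    class = "design_candidate")
  if (!is.null(cache)) cache[[key]] <- cand
  cand
}

dominates <- function(a, b) all(a >= b) && any(a > b)

#' Pareto filter: the mutually non-dominated subset
#'
#' All objectives are maximized. The result is ordered by descending
#' first objective (r_max), ties broken lexicographically on the
#' designed sequences for determinism.
#'
#' @param candidates non-empty list of \code{design_candidate}.
#' @return list of class \code{pareto_set}.
#' @export
pareto_filter <- function(candidates) {
  if (length(candidates) == 0L) stop("pareto_filter needs >= 1 candidate")
  keys <- vapply(candidates, function(x)
    paste(x$pre_aptamer, x$post_aptamer, sep = "|"), "")
  candidates <- candidates[!duplicated(keys)]
  obj <- t(vapply(candidates, `[[`, numeric(3), "objectives"))
  n <- nrow(obj)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && keep[i] && dominates(obj[j, ], obj[i, ])) {
        keep[i] <- FALSE
        break
      }
    }
  }
  out <- candidates[keep]
  key <- vapply(out, function(x) paste(x$pre_aptamer, x$post_aptamer, sep = "|"), "")
  r <- vapply(out, function(x) x$objectives[["r_max"]], 0)
  out <- out[order(-r, key, method = "radix")]
  class(out) <- "pareto_set"
  out
}

#' @export
print.pareto_set <- function(x, ...) {
  cat("<pareto_set>", length(x), "non-dominated candidate(s)\n")
  print(as.data.frame(x))
  invisible(x)
}

#' @export
as.data.frame.pareto_set <- function(x, ...) {
  data.frame(
    pre_aptamer = vapply(x, `[[`, "", "pre_aptamer"),
    post_aptamer = vapply(x, `[[`, "", "post_aptamer"),
    r_max = vapply(x, function(c) c$objectives[["r_max"]], 0),
    tir_bound = vapply(x, function(c) c$prediction$tir_bound, 0),
    tir_unbound = vapply(x, function(c) c$prediction$tir_unbound, 0)
  )
}

# --- GA internals ---------------------------------------------------------

random_region <- function(len) {
  if (len == 0L) return("")
  paste(sample(.rna_alphabet, len, replace = TRUE), collapse = "")
}

random_individual <- function(spec) {
  for (try in 1:200) {
    L <- resample(seq(spec$length_range[1], spec$length_range[2]))
    lp <- resample(0:L)
    pre <- random_region(lp)
    post <- random_region(L - lp)
    if (motif_free(spec, pre, post)) return(list(pre = pre, post = post))
  }
  stop("design error: could not sample a motif-free individual in 200 tries; ",
       "forbidden motifs may be infeasible at the requested lengths")
}

mutate_region <- function(s, rate) {
  if (!nzchar(s)) return(s)
  chars <- strsplit(s, "")[[1]]
  hit <- stats::runif(length(chars)) < rate
  if (any(hit)) {
    chars[hit] <- sample(.rna_alphabet, sum(hit), replace = TRUE)
  }
  paste(chars, collapse = "")
}

indel_region <- function(s, grow_ok, shrink_ok) {
  n <- nchar(s)
  grow <- if (grow_ok && (!shrink_ok || stats::runif(1) < 0.5)) TRUE
          else if (shrink_ok) FALSE else return(s)
  if (grow) {
    pos <- resample(0:n)
    paste0(substr(s, 1, pos), sample(.rna_alphabet, 1L),
           substr(s, pos + 1L, n))
  } else {
    if (n == 0L) return(s)
    pos <- resample(seq_len(n))
    paste0(substr(s, 1, pos - 1L), substr(s, pos + 1L, n))
  }
}

cross_regions <- function(a, b) {
  ka <- resample(0:nchar(a))
  kb <- resample(0:nchar(b))
  paste0(substr(a, 1, ka), substr(b, kb + 1L, nchar(b)))
}

make_offspring <- function(spec, p1, p2) {
  for (try in 1:50) {
    pre <- if (stats::runif(1) < spec$crossover_rate)
      cross_regions(p1$pre, p2$pre) else p1$pre
    post <- if (stats::runif(1) < spec$crossover_rate)
      cross_regions(p1$post, p2$post) else p1$post
    pre <- mutate_region(pre, spec$mutation_rate)
    post <- mutate_region(post, spec$mutation_rate)
    L <- nchar(pre) + nchar(post)
    if (stats::runif(1) < spec$indel_rate) {
      pre <- indel_region(pre, L < spec$length_range[2], L > spec$length_range[1])
      L <- nchar(pre) + nchar(post)
    }
    if (stats::runif(1) < spec$indel_rate) {
      post <- indel_region(post, L < spec$length_range[2], L > spec$length_range[1])
      L <- nchar(pre) + nchar(post)
    }
    if (L >= spec$length_range[1] && L <= spec$length_range[2] &&
        motif_free(spec, pre, post)) {
      return(list(pre = pre, post = post))
    }
  }
  random_individual(spec)
}

nds_ranks <- function(obj) {
  n <- nrow(obj)
  rank <- integer(n)
  dominated_by <- lapply(seq_len(n), function(i) integer(0))
  n_dom <- integer(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && dominates(obj[i, ], obj[j, ])) {
        dominated_by[[i]] <- c(dominated_by[[i]], j)
      } else if (i != j && dominates(obj[j, ], obj[i, ])) {
        n_dom[i] <- n_dom[i] + 1L
      }
    }
  }
  front <- which(n_dom == 0L)
  r <- 1L
  while (length(front) > 0L) {
    rank[front] <- r
    nxt <- integer(0)
    for (i in front) {
      for (j in dominated_by[[i]]) {
        n_dom[j] <- n_dom[j] - 1L
        if (n_dom[j] == 0L) nxt <- c(nxt, j)
      }
    }
    front <- unique(nxt)
    r <- r + 1L
  }
  rank
}

crowding_distance <- function(obj) {
  n <- nrow(obj)
  d <- numeric(n)
  if (n <= 2L) return(rep(Inf, n))
  for (m in seq_len(ncol(obj))) {
    o <- order(obj[, m])
    d[o[1]] <- Inf
    d[o[n]] <- Inf
    span <- obj[o[n], m] - obj[o[1], m]
    if (span > 0) {
      for (k in 2:(n - 1L)) {
        d[o[k]] <- d[o[k]] + (obj[o[k + 1L], m] - obj[o[k - 1L], m]) / span
      }
    }
  }
  d
}

#' Design riboswitch sequences by multi-objective genetic algorithm
#'
#' Evolves the designed pre- and post-aptamer regions to maximize the
#' predicted regulation ratio at ligand saturation (R_max) together with
#' the translation rate of the intended high state and (negated) that of
#' the intended low state, keeping the aptamer fixed. Deterministic
#' given \code{spec$seed}; the returned set is the non-dominated front
#' over every candidate evaluated during the run.
#'
#' @param spec a \code{\link{design_spec}}.
#' @param verbose print per-generation best R_max.
#' @return a \code{pareto_set}; attributes \code{seed},
#'   \code{n_evaluated} and \code{best_r_max_trace}.
#' @export
design_switches <- function(spec, verbose = FALSE) {
  stopifnot(inherits(spec, "design_spec"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$seed)

  cache <- new.env(parent = emptyenv())
  archive <- new.env(parent = emptyenv())
  score <- function(ind) {
    cand <- evaluate_candidate(spec, ind$pre, ind$post, cache)
    archive[[paste(ind$pre, ind$post, sep = "|")]] <- cand
    cand
  }

  pop <- lapply(seq_len(spec$pop_size), function(k) random_individual(spec))
  cands <- lapply(pop, score)
  trace <- numeric(0)
  for (gen in seq_len(spec$generations)) {
    obj <- t(vapply(cands, `[[`, numeric(3), "objectives"))
    rank <- nds_ranks(obj)
    crowd <- numeric(length(cands))
    for (r in unique(rank)) {
      idx <- which(rank == r)
      crowd[idx] <- crowding_distance(obj[idx, , drop = FALSE])
    }
    tournament <- function() {
      ij <- sample(length(cands), 2L)
      i <- ij[1]; j <- ij[2]
      if (rank[i] < rank[j]) i
      else if (rank[j] < rank[i]) j
      else if (crowd[i] >= crowd[j]) i else j
    }
    children <- lapply(seq_len(spec$pop_size), function(k) {
      make_offspring(spec, pop[[tournament()]], pop[[tournament()]])
    })
    child_cands <- lapply(children, score)

    all_pop <- c(pop, children)
    all_cands <- c(cands, child_cands)
    all_obj <- t(vapply(all_cands, `[[`, numeric(3), "objectives"))
    all_rank <- nds_ranks(all_obj)
    all_crowd <- numeric(length(all_cands))
    for (r in unique(all_rank)) {
      idx <- which(all_rank == r)
      all_crowd[idx] <- crowding_distance(all_obj[idx, , drop = FALSE])
    }
    ord <- order(all_rank, -all_crowd)
    sel <- ord[seq_len(spec$pop_size)]
    # elitist guarantee: the best-R_max individual always survives
    best_i <- which.max(all_obj[, 1])
    if (!best_i %in% sel) sel[length(sel)] <- best_i
    pop <- all_pop[sel]
    cands <- all_cands[sel]
    trace <- c(trace, max(all_obj[, 1]))
    if (verbose) {
      message(sprintf("generation %d: best R_max %.4g (%d evaluated)",
                      gen, trace[gen], length(ls(archive))))
    }
  }
  out <- pareto_filter(as.list(mget(ls(archive), archive)))
  attr(out, "seed") <- spec$seed
  attr(out, "n_evaluated") <- length(ls(archive))
  attr(out, "best_r_max_trace") <- trace
  out
}

#' Search-space size of the designed regions
#'
#' Number of sequences of combined designed length L is 4^L (times the
#' number of pre/post splits when both regions are free). Reported on a
#' log10 scale to avoid overflow.
#'
#' @param length combined designed length, nt (vectorized).
#' @return floor of log10 of 4^length.
#' @export
log10_design_space <- function(length) floor(length * log10(4))

#' Exhaustively enumerate a tiny design space
#'
#' Brute-force oracle: evaluates every sequence with combined designed
#' length within \code{spec$length_range} and returns the global optimum
#' by R_max (ties broken lexicographically). Refuses spaces larger than
#' \code{max_space} with a size estimate.
#'
#' @param spec a \code{\link{design_spec}} with tiny lengths.
#' @param max_space refusal threshold on the number of candidates.
#' @return list: \code{best} (a \code{design_candidate}), \code{n_enumerated},
#'   \code{candidates} (all, in enumeration order).
#' @export
brute_force_design <- function(spec, max_space = 1e5) {
  lens <- seq(spec$length_range[1], spec$length_range[2])
  total <- sum((lens + 1) * 4^lens)
  if (total > max_space) {
    stop("design space has ~", format(total, big.mark = ","),
         " candidates, above the brute-force limit of ", max_space)
  }
  all_cands <- list()
  for (L in lens) {
    for (lp in 0:L) {
      pres <- if (lp == 0L) "" else
        apply(do.call(expand.grid, rep(list(.rna_alphabet), lp)), 1,
              paste, collapse = "")
      posts <- if (L - lp == 0L) "" else
        apply(do.call(expand.grid, rep(list(.rna_alphabet), L - lp)), 1,
              paste, collapse = "")
      for (pre in pres) {
        for (post in posts) {
          if (!motif_free(spec, pre, post)) next
          all_cands[[length(all_cands) + 1L]] <-
            evaluate_candidate(spec, pre, post)
        }
      }
    }
  }
  if (length(all_cands) == 0L) stop("no motif-free candidate in the space")
  key <- vapply(all_cands, function(x)
    paste(x$pre_aptamer, x$post_aptamer, sep = "|"), "")
  r <- vapply(all_cands, function(x) x$objectives[["r_max"]], 0)
  best <- all_cands[[order(-r, key, method = "radix")[1]]]
  list(best = best, n_enumerated = length(all_cands), candidates = all_cands)
}
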