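# Interface to the ViennaRNA folding engine (RNAfold / RNAduplex).
# All folding in the package runs with the Turner 2004 parameter set and
# dangling-end contributions disabled (-d0); temperature is configurable.

.fold_cache <- new.env(parent = emptyenv())

#' Normalize an RNA sequence
#'
#' Uppercases, maps T to U, strips whitespace and validates the alphabet.
#' All sequence input in the package passes through this function, so
#' results are invariant to T/U spelling and stray whitespace.
#'
#' @param x character scalar (or vector) of sequence(s).
#' @return character of the same length, RNA alphabet (A/C/G/U).
#' @export
as_rna <- function(x) {
  x <- gsub("[[:space:]]+", "", toupper(as.character(x)))
  x <- chartr("T", "U", x)
  bad <- grepl("[^ACGU]", x)
  if (any(bad)) {
    stop("invalid RNA alphabet in sequence(s): ",
         paste(substr(x[bad], 1, 30), collapse = ", "), call. = FALSE)
  }
  x
}

# pair table: partner index per position, 0 if unpaired; errors on imbalance
pair_table <- function(structure) {
  chars <- strsplit(structure, "")[[1]]
  pt <- integer(length(chars))
  stack <- integer(0)
  for (k in seq_along(chars)) {
    if (chars[k] == "(") {
      stack <- c(stack, k)
    } else if (chars[k] == ")") {
      if (length(stack) == 0L) stop("unbalanced brackets in structure", call. = FALSE)
      i <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pt[i] <- k
      pt[k] <- i
    }
  }
  if (length(stack) > 0L) stop("unbalanced brackets in structure", call. = FALSE)
  pt
}

.canonical_pairs <- c(AU = TRUE, UA = TRUE, GC = TRUE, CG = TRUE, GU = TRUE, UG = TRUE)

# Validate a folding constraint string against its sequence.
# Syntax: '.' unconstrained, 'x' forced unpaired, '(' ')' forced pair.
validate_constraint <- function(sequence, constraint) {
  if (is.null(constraint)) return(invisible(NULL))
  if (nchar(constraint) != nchar(sequence)) {
    stop("constraint length (", nchar(constraint), ") != sequence length (",
         nchar(sequence), ")", call. = FALSE)
  }
  if (grepl("[^.x()]", constraint)) {
    stop("constraint may only contain '.', 'x', '(' and ')'", call. = FALSE)
  }
  pt <- pair_table(constraint)
  seq_chars <- strsplit(sequence, "")[[1]]
  paired <- which(pt > 0 & seq_len(length(pt)) < pt)
  for (i in paired) {
    j <- pt[i]
    if (j - i < 4L) {
      stop("contradictory constraint: forced pair ", i, "-", j,
           " leaves a hairpin loop shorter than 3 nt", call. = FALSE)
    }
    duo <- paste0(seq_chars[i], seq_chars[j])
    if (!isTRUE(.canonical_pairs[duo])) {
      stop("contradictory constraint: ", seq_chars[i], i, "-", seq_chars[j], j,
           " is not a canonical base pair", call. = FALSE)
    }
  }
  invisible(NULL)
}

vienna_binary <- function(tool) {
  path <- Sys.which(tool)
  if (!nzchar(path)) {
    stop("ViennaRNA tool '", tool, "' not found on PATH; install ViennaRNA >= 2.4",
         call. = FALSE)
  }
  path
}

#' Fold one or more RNA sequences at minimum free energy
#'
#' Thin, cached wrapper around \code{RNAfold} using the Turner 2004
#' nearest-neighbor parameters with dangling-end energies disabled.
#' Constraints use \code{'.'} (unconstrained), \code{'x'} (forced
#' unpaired) and matched \code{'('}/\code{')'} (forced pair, enforced).
#'
#' @param sequences character vector of RNA sequences (T accepted).
#' @param constraints optional character vector of constraint strings
#'   (recycled NULL means unconstrained); each must match its sequence
#'   length.
#' @param temperature folding temperature in kelvin (default 310.15).
#' @return a list of fold states, each with \code{structure},
#'   \code{dg_fold} (kcal/mol) and \code{constraint}.
#' @export
fold_mfe_batch <- function(sequences, constraints = NULL, temperature = 310.15) {
  sequences <- as_rna(sequences)
  n <- length(sequences)
  if (is.null(constraints)) constraints <- rep(NA_character_, n)
  if (length(constraints) != n) stop("constraints must match sequences in length")
  constraints <- ifelse(is.na(constraints),
                        vapply(sequences, function(s) strrep(".", nchar(s)), ""),
                        constraints)
  for (k in seq_len(n)) validate_constraint(sequences[k], constraints[k])

  keys <- paste(sequences, constraints, format(temperature), sep = "|")
  out <- vector("list", n)
  todo <- integer(0)
  for (k in seq_len(n)) {
    hit <- .fold_cache[[keys[k]]]
    if (is.null(hit)) todo <- c(todo, k) else out[[k]] <- hit
  }
  if (length(todo) > 0L) {
    idx <- todo[!duplicated(keys[todo])]
    input <- character(0)
    for (k in idx) input <- c(input, paste0(">s", k), sequences[k], constraints[k])
    res <- system2(
      vienna_binary("RNAfold"),
      args = c("--noPS", "-d0", "-C", "--batch", "--enforceConstraint",
               "-T", format(temperature - 273.15)),
      input = input, stdout = TRUE, stderr = FALSE
    )
    res <- res[nzchar(res)]
    headers <- grep("^>", res)
    if (length(headers) != length(idx)) {
      stop("RNAfold returned ", length(headers), " records for ",
           length(idx), " sequences", call. = FALSE)
    }
    for (h in seq_along(headers)) {
      k <- idx[h]
      line <- res[headers[h] + 2L]
      m <- regmatches(line, regexec("^([.()]+)\\s+\\(\\s*(-?[0-9.]+)\\)", line))[[1]]
      if (length(m) != 3L) stop("unparseable RNAfold output: ", line, call. = FALSE)
      st <- list(structure = m[2], dg_fold = as.numeric(m[3]),
                 constraint = constraints[k])
      class(st) <- "fold_state"
      .fold_cache[[keys[k]]] <- st
    }
    for (k in todo) out[[k]] <- .fold_cache[[keys[k]]]
  }
  out
}

#' @rdname fold_mfe_batch
#' @param sequence a single RNA sequence.
#' @param constraint optional constraint string.
#' @export
fold_mfe <- function(sequence, constraint = NULL, temperature = 310.15) {
  fold_mfe_batch(sequence, if (is.null(constraint)) NULL else constraint,
                 temperature = temperature)[[1]]
}

#' @export
print.fold_state <- function(x, ...) {
  cat(x$structure, sprintf("(%.2f kcal/mol)\n", x$dg_fold))
  invisible(x)
}

#' Optimal RNA-RNA duplex between two strands
#'
#' Wraps \code{RNAduplex} (-d0, Turner 2004): the most favorable
#' intermolecular hybrid between any subsequence of \code{query} and any
#' subsequence of \code{target}. When no duplex with negative free energy
#' exists the result is flagged \code{no_site} with energy 0.
#'
#' @param queries,targets character vectors of RNA sequences (paired up).
#' @param temperature kelvin.
#' @return list of duplex results: \code{energy} (kcal/mol),
#'   \code{query_span}/\code{target_span} (1-based inclusive),
#'   \code{structure}, \code{no_site}.
#' @export
duplex_fold_batch <- function(queries, targets, temperature = 310.15) {
  queries <- as_rna(queries)
  targets <- as_rna(targets)
  n <- length(queries)
  if (length(targets) != n) stop("queries and targets must pair up")
  input <- as.vector(rbind(queries, targets))
  res <- system2(vienna_binary("RNAduplex"),
                 args = c("-d0", "-T", format(temperature - 273.15)),
                 input = input, stdout = TRUE, stderr = FALSE)
  res <- res[nzchar(res) & !grepl("^>", res)]
  if (length(res) != n) {
    stop("RNAduplex returned ", length(res), " lines for ", n, " pairs",
         call. = FALSE)
  }
  lapply(seq_len(n), function(k) {
    m <- regmatches(res[k], regexec(
      "^(\\S+)\\s+(\\d+),(\\d+)\\s*:\\s*(\\d+),(\\d+)\\s+\\(\\s*(-?[0-9.]+)\\)", res[k]))[[1]]
    if (length(m) != 7L) stop("unparseable RNAduplex output: ", res[k], call. = FALSE)
    e <- as.numeric(m[7])
    no_site <- e >= 0 || m[3] == "0"
    if (no_site) {
      return(list(energy = 0, query_span = NULL, target_span = NULL,
                  structure = NULL, no_site = TRUE))
    }
    # RNAduplex spans may include unpaired flanking positions; trim the
    # spans to the outermost paired positions
    halves <- strsplit(m[2], "&", fixed = TRUE)[[1]]
    trim <- function(span, db) {
      lead <- nchar(sub("[()].*$", "", db))
      trail <- nchar(sub("^.*[()]", "", db))
      c(span[1] + lead, span[2] - trail)
    }
    list(
      energy = e,
      query_span = as.integer(trim(as.integer(m[3:4]), halves[1])),
      target_span = as.integer(trim(as.integer(m[5:6]), halves[2])),
      structure = m[2],
      no_site = FALSE
    )
  })
}

#' @rdname duplex_fold_batch
#' @param query,target single RNA sequences.
#' @export
duplex_fold <- function(query, target, temperature = 310.15) {
  duplex_fold_batch(query, target, temperature = temperature)[[1]]
}

# drop memoised folds (mainly for tests that probe engine settings)
clear_fold_cache <- function() {
  rm(list = ls(.fold_cache), envir = .fold_cache)
  invisible(NULL)
}
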