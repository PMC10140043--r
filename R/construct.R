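# Riboswitch constructs: pre-aptamer | aptamer | post-aptamer | CDS,
# assembly into one mRNA record and the aptamer structural constraint.

#' A riboswitch construct
#'
#' The assembled mRNA is \code{pre + aptamer$sequence + post + cds}; the
#' post-aptamer region carries the SD and spacer, and the CDS begins with
#' the start codon. \code{mode} declares the design intent: ON switches
#' activate translation upon protein binding, OFF switches repress it.
#'
#' @param name identifier.
#' @param pre_aptamer,post_aptamer RNA strings (may be empty).
#' @param aptamer an \code{\link{aptamer_spec}}.
#' @param cds RNA string beginning with AUG/GUG/UUG; must extend at
#'   least 13 nt so the ribosome footprint fits.
#' @param mode \code{"ON"} or \code{"OFF"}.
#' @return object of class \code{riboswitch_construct}.
#' @export
riboswitch_construct <- function(name, pre_aptamer, aptamer, post_aptamer,
                                 cds, mode = c("OFF", "ON")) {
  mode <- match.arg(toupper(mode), c("OFF", "ON"))
  stopifnot(inherits(aptamer, "aptamer_spec"))
  pre_aptamer <- if (nzchar(pre_aptamer)) as_rna(pre_aptamer) else ""
  post_aptamer <- if (nzchar(post_aptamer)) as_rna(post_aptamer) else ""
  cds <- as_rna(cds)
  if (!substr(cds, 1, 3) %in% c("AUG", "GUG", "UUG")) {
    stop("cds must begin with a start codon (AUG/GUG/UUG)")
  }
  if (nchar(cds) < 13L) stop("cds must be >= 13 nt (ribosome footprint)")
  structure(list(name = as.character(name), pre_aptamer = pre_aptamer,
                 aptamer = aptamer, post_aptamer = post_aptamer,
                 cds = cds, mode = mode),
            class = "riboswitch_construct")
}

#' Assemble a construct into an mRNA record
#'
#' @param x a \code{\link{riboswitch_construct}}.
#' @return the assembled \code{\link{mrna_record}}, with attributes
#'   \code{aptamer_range} (1-based inclusive span of the aptamer in the
#'   assembled sequence).
#' @export
assemble_mrna <- function(x) {
  stopifnot(inherits(x, "riboswitch_construct"))
  seqs <- paste0(x$pre_aptamer, x$aptamer$sequence, x$post_aptamer, x$cds)
  cds_start <- nchar(x$pre_aptamer) + nchar(x$aptamer$sequence) +
    nchar(x$post_aptamer) + 1L
  m <- mrna_record(x$name, seqs, cds_start)
  attr(m, "aptamer_range") <- c(nchar(x$pre_aptamer) + 1L,
                                nchar(x$pre_aptamer) + nchar(x$aptamer$sequence))
  m
}

#' Global constraint locking the aptamer in its protein-bound structure
#'
#' Dots everywhere except the aptamer positions, which carry the
#' aptamer's declared bound structure.
#'
#' @param x a \code{\link{riboswitch_construct}}.
#' @return a constraint string of assembled-mRNA length.
#' @export
bound_constraint <- function(x) {
  paste0(strrep(".", nchar(x$pre_aptamer)), x$aptamer$bound_structure,
         strrep(".", nchar(x$post_aptamer) + nchar(x$cds)))
}

#' @export
print.riboswitch_construct <- function(x, ...) {
  cat("<riboswitch_construct>", x$name, sprintf("[%s switch]", x$mode),
      "sensing", x$aptamer$ligand_name, "\n")
  cat("  pre:", nchar(x$pre_aptamer), "nt | aptamer:",
      nchar(x$aptamer$sequence), "nt | post:", nchar(x$post_aptamer),
      "nt | cds:", nchar(x$cds), "nt\n")
  invisible(x)
}

#' Read / write construct sets as TSV
#'
#' Columns: name, pre_aptamer, post_aptamer, cds, mode. The aptamer
#' (shared across the set) is supplied separately.
#'
#' @param path file path.
#' @param aptamer an \code{\link{aptamer_spec}} shared by the set.
#' @export
read_constructs_tsv <- function(path, aptamer) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(d)), function(k) {
    riboswitch_construct(d$name[k], d$pre_aptamer[k], aptamer,
                         d$post_aptamer[k], d$cds[k], d$mode[k])
  })
}

#' @rdname read_constructs_tsv
#' @param constructs list of \code{riboswitch_construct}.
#' @export
write_constructs_tsv <- function(constructs, path) {
  d <- data.frame(
    name = vapply(constructs, `[[`, "", "name"),
    pre_aptamer = vapply(constructs, `[[`, "", "pre_aptamer"),
    post_aptamer = vapply(constructs, `[[`, "", "post_aptamer"),
    cds = vapply(constructs, `[[`, "", "cds"),
    mode = vapply(constructs, `[[`, "", "mode")
  )
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write assembled constructs as FASTA with region offsets in the header
#'
#' Header format:
#' \code{>name pre=1-20 aptamer=21-40 post=41-60 cds=61-120 mode=OFF}.
#' @param constructs list of \code{riboswitch_construct}.
#' @param path file path.
#' @export
write_constructs_fasta <- function(constructs, path) {
  set <- Biostrings::BStringSet(vapply(constructs, function(x)
    paste0(x$pre_aptamer, x$aptamer$sequence, x$post_aptamer, x$cds), ""))
  names(set) <- vapply(constructs, function(x) {
    np <- nchar(x$pre_aptamer); na <- nchar(x$aptamer$sequence)
    ns <- nchar(x$post_aptamer); nc <- nchar(x$cds)
    sprintf("%s pre=%d-%d aptamer=%d-%d post=%d-%d cds=%d-%d mode=%s",
            x$name, 1L, np, np + 1L, np + na, np + na + 1L,
            np + na + ns, np + na + ns + 1L, np + na + ns + nc, x$mode)
  }, "")
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
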