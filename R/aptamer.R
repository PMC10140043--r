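# Aptamer specifications: the design-spec input (sequence, protein-bound
# structure, dissociation constant), YAML io, and toy fixture aptamers.

#' Aptamer specification
#'
#' The three experimental inputs the design engine needs about a
#' protein-binding aptamer: its sequence, its secondary structure when
#' bound by the protein (dot-bracket), and the dissociation constant.
#'
#' @param name identifier.
#' @param sequence RNA string.
#' @param bound_structure dot-bracket of the protein-bound conformation,
#'   same length as \code{sequence}.
#' @param kd dissociation constant, molar, > 0.
#' @param ligand_name protein ligand name.
#' @return object of class \code{aptamer_spec}.
#' @export
aptamer_spec <- function(name, sequence, bound_structure, kd,
                         ligand_name = "") {
  sequence <- as_rna(sequence)
  if (nchar(bound_structure) != nchar(sequence)) {
    stop("bound_structure length must equal sequence length")
  }
  if (grepl("[^.()]", bound_structure)) {
    stop("bound_structure must be dot-bracket ('.', '(', ')')")
  }
  validate_constraint(sequence, bound_structure)
  if (!is.numeric(kd) || length(kd) != 1L || !is.finite(kd) || kd <= 0) {
    stop("kd must be a single positive number (molar)")
  }
  structure(list(name = as.character(name), sequence = sequence,
                 bound_structure = bound_structure, kd = kd,
                 ligand_name = as.character(ligand_name)),
            class = "aptamer_spec")
}

#' @export
print.aptamer_spec <- function(x, ...) {
  cat("<aptamer_spec>", x$name, "binding", x$ligand_name,
      sprintf("(Kd = %.3g nM)\n", x$kd * 1e9))
  cat(" ", x$sequence, "\n ", x$bound_structure, "\n")
  invisible(x)
}

#' Read / write aptamer specifications as YAML
#'
#' YAML fields: name, sequence, structure, kd_nM, ligand.
#' @param path file path.
#' @export
read_aptamer_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  aptamer_spec(y$name, y$sequence, y$structure, y$kd_nM * 1e-9,
               ligand_name = if (is.null(y$ligand)) "" else y$ligand)
}

#' @rdname read_aptamer_yaml
#' @param aptamer an \code{aptamer_spec}.
#' @export
write_aptamer_yaml <- function(aptamer, path) {
  yaml::write_yaml(list(name = aptamer$name, sequence = aptamer$sequence,
                        structure = aptamer$bound_structure,
                        kd_nM = aptamer$kd * 1e9,
                        ligand = aptamer$ligand_name), path)
  invisible(path)
}

#' Construct a toy aptamer with a verified bound structure
#'
#' Builds a small hairpin (or bulged hairpin) whose declared bound
#' structure is provably its own MFE structure, verified by folding.
#' These stand in, as synthetic fixtures, for experimentally
#' characterized protein-binding aptamers.
#'
#' @param kind \code{"hairpin"} or \code{"bulged_hairpin"}.
#' @param stem_len base pairs in the (total) stem, >= 3.
#' @param loop_len loop nucleotides, >= 3.
#' @param kd dissociation constant, molar.
#' @param name identifier.
#' @param ligand_name ligand label.
#' @param temperature kelvin, for the verification fold.
#' @return an \code{\link{aptamer_spec}} whose \code{bound_structure}
#'   equals the MFE structure of its sequence.
#' @export
toy_aptamer <- function(kind = c("hairpin", "bulged_hairpin"),
                        stem_len = 4L, loop_len = 4L, kd = 1e-8,
                        name = NULL, ligand_name = "toy protein",
                        temperature = 310.15) {
  kind <- match.arg(kind)
  stopifnot(stem_len >= 3L, loop_len >= 3L)
  stem5 <- paste(rep(c("G", "C"), length.out = stem_len), collapse = "")
  stem3 <- chartr("GC", "CG", paste(rev(strsplit(stem5, "")[[1]]), collapse = ""))
  loops <- c(strrep("A", loop_len),
             paste(rep(c("A", "A", "C"), length.out = loop_len), collapse = ""),
             paste(rep(c("U", "A"), length.out = loop_len), collapse = ""))
  for (loop in loops) {
    if (kind == "hairpin") {
      seqs <- paste0(stem5, loop, stem3)
      db <- paste0(strrep("(", stem_len), strrep(".", loop_len),
                   strrep(")", stem_len))
    } else {
      outer <- max(1L, stem_len %/% 2L)
      inner <- stem_len - outer
      if (inner < 1L) stop("bulged hairpin needs stem_len >= 2")
      o5 <- substr(stem5, 1L, outer)
      i5 <- substr(stem5, outer + 1L, stem_len)
      i3 <- substr(stem3, 1L, inner)
      o3 <- substr(stem3, inner + 1L, stem_len)
      seqs <- paste0(o5, "A", i5, loop, i3, o3)
      db <- paste0(strrep("(", outer), ".", strrep("(", inner),
                   strrep(".", loop_len), strrep(")", inner),
                   strrep(")", outer))
    }
    fs <- fold_mfe(seqs, temperature = temperature)
    if (identical(fs$structure, db)) {
      if (is.null(name)) name <- paste0("toy_", kind, "_s", stem_len, "l", loop_len)
      return(aptamer_spec(name, seqs, db, kd, ligand_name = ligand_name))
    }
  }
  stop("could not realize a ", kind, " with stem ", stem_len, " and loop ",
       loop_len, " whose MFE equals the declared structure; ",
       "last attempt folded to ", fs$structure, " instead of ", db)
}
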