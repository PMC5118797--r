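## Selection mini-language: conjunctions of simple predicates resolved
## against a structure_model. Deterministic and order-stable.

#' Resolve a selection expression to atom indices
#'
#' The expression is a conjunction of predicates joined by \code{" and "}.
#' Supported predicates:
#' \itemize{
#'   \item \code{all}, \code{protein}, \code{water}, \code{hetero}
#'   \item \code{calpha}, \code{backbone}, \code{sidechain}, \code{heavy}
#'   \item \code{residues A-B} / \code{residues A} (residue labels,
#'     inclusive of both endpoints)
#'   \item \code{resname XXX}, \code{name CA}
#'   \item \code{group:NAME} (a named group on the model)
#'   \item any predicate may be negated with a leading \code{not }
#' }
#' Residue ranges refer to the residue \emph{labels} (original PDB numbering),
#' so literature residue names keep their meaning regardless of internal
#' indexing.
#'
#' @param model structure_model.
#' @param expression selection string, or an integer vector of atom indices
#'   (passed through after validation).
#' @return Sorted integer vector of 1-based atom indices; an empty
#'   resolution is an error.
#' @export
resolve_selection <- function(model, expression) {
  if (is.numeric(expression)) {
    idx <- sort(unique(as.integer(expression)))
    if (length(idx) == 0L) stopf("selection resolves to no atoms")
    if (any(idx < 1L | idx > n_atoms(model)))
      stopf("selection has out-of-range atom indices")
    return(idx)
  }
  if (!is.character(expression) || length(expression) != 1L)
    stopf("selection must be a single string or an index vector")
  tokens <- trimws(strsplit(expression, "\\s+and\\s+")[[1]])
  tokens <- tokens[nzchar(tokens)]
  if (length(tokens) == 0L) stopf("empty selection expression")
  keep <- rep(TRUE, n_atoms(model))
  for (tok in tokens) {
    neg <- grepl("^not\\s+", tok)
    if (neg) tok <- sub("^not\\s+", "", tok)
    m <- selection_predicate(model, tok)
    keep <- keep & (if (neg) !m else m)
  }
  idx <- which(keep)
  if (length(idx) == 0L)
    stopf("selection '%s' resolves to no atoms", expression)
  idx
}

selection_predicate <- function(model, tok) {
  at <- model$atoms
  res_amino <- model$residues$is_amino[match(at$residue_index,
                                             model$residues$residue_index)]
  res_water <- model$residues$is_water[match(at$residue_index,
                                             model$residues$residue_index)]
  if (tok == "all") return(rep(TRUE, nrow(at)))
  if (tok == "protein") return(res_amino)
  if (tok == "water") return(res_water)
  if (tok == "hetero") return(!res_amino & !res_water)
  if (tok == "calpha") return(at$atom_class == "calpha")
  if (tok == "backbone") return(at$atom_class %in% c("backbone", "calpha"))
  if (tok == "sidechain") return(at$atom_class == "sidechain")
  if (tok == "heavy" || tok == "noh") return(!at$is_hydrogen)
  if (grepl("^group:", tok)) {
    g <- sub("^group:", "", tok)
    if (is.null(model$groups[[g]]))
      stopf("unknown group '%s' in selection", g)
    m <- rep(FALSE, nrow(at)); m[model$groups[[g]]] <- TRUE
    return(m)
  }
  if (grepl("^residues?\\s+", tok)) {
    rng <- sub("^residues?\\s+", "", tok)
    parts <- strsplit(rng, "-", fixed = TRUE)[[1]]
    lo <- suppressWarnings(as.integer(parts[1]))
    hi <- if (length(parts) > 1) suppressWarnings(as.integer(parts[2])) else lo
    if (is.na(lo) || is.na(hi)) stopf("bad residue range '%s'", tok)
    labs <- model$residues$label[match(at$residue_index,
                                       model$residues$residue_index)]
    return(labs >= lo & labs <= hi)
  }
  if (grepl("^resname\\s+", tok)) {
    rn <- toupper(sub("^resname\\s+", "", tok))
    return(toupper(at$resname) == rn)
  }
  if (grepl("^name\\s+", tok)) {
    nm <- toupper(sub("^name\\s+", "", tok))
    return(toupper(at$name) == nm)
  }
  stopf("unknown selection token '%s'", tok)
}
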